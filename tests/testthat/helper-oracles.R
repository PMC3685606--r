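# Independent oracles: a literal repeat-until-fixpoint rule applier working
# on its own set representation, reachability via igraph, and exhaustive
# path enumeration for shortest-path checks.

oracle_canon <- function(f) {
  if (f[1] %in% c("exp-to", "CONN", "COMM3")) {
    if (f[2] > f[3]) f[c(2, 3)] <- f[c(3, 2)]
  }
  f
}

oracle_key <- function(f) paste(oracle_canon(f), collapse = "|")

# Canonical fact keys of a knowledge base (symmetric / commutative relations
# with sorted first arguments), for set comparison against the oracle.
kb_fact_keys <- function(kb) {
  sort(vapply(seq_len(nrow(kb$facts)), function(j) {
    f <- kb$facts[j, ]
    oracle_key(c(f$relation, f$arg1,
                 if (!is.na(f$arg2)) f$arg2, if (!is.na(f$arg3)) f$arg3))
  }, character(1)))
}

# Naive saturation: apply every location, exposure and communication rule by
# literal enumeration over the current fact list, repeating until nothing
# new is produced. Returns the sorted canonical key set.
naive_saturated_keys <- function(kb) {
  kinds <- stats::setNames(kb$individuals$kind, kb$individuals$id)
  subk <- stats::setNames(kb$individuals$cvs_subkind, kb$individuals$id)
  is_fluid <- function(x) !is.na(kinds[x]) && kinds[x] == "TissueFluid"
  is_cvs <- function(x) !is.na(kinds[x]) && kinds[x] == "CVSPortion"

  facts <- lapply(seq_len(nrow(kb$facts)), function(j) {
    f <- kb$facts[j, ]
    c(f$relation, f$arg1, if (!is.na(f$arg2)) f$arg2, if (!is.na(f$arg3)) f$arg3)
  })
  have <- new.env(parent = emptyenv())
  for (f in facts) assign(oracle_key(f), TRUE, have)
  sel <- function(rel) Filter(function(f) f[1] == rel, facts)
  # both orientations of a symmetric binary relation, as 2-vectors
  sym2 <- function(rel) {
    out <- list()
    for (f in sel(rel)) out <- c(out, list(f[2:3], f[c(3, 2)]))
    unique(out)
  }
  add <- function(f) {
    k <- oracle_key(f)
    if (exists(k, have)) return(FALSE)
    assign(k, TRUE, have)
    facts <<- c(facts, list(f))
    TRUE
  }

  caps <- unique(c(names(subk)[!is.na(subk) & subk == "capillary"],
                   vapply(sel("cap-of"), `[`, character(1), 2)))
  chambers <- names(subk)[!is.na(subk) & subk == "chamber"]

  repeat {
    changed <- FALSE
    for (oc in sel("occurs-in")) for (pa in sel("participates-in"))
      if (pa[3] == oc[2])
        changed <- add(c("fnd-in", pa[2], oc[3])) || changed
    for (pb in sel("prod-by")) for (pt in sel("postp_t")) {
      if (pt[2] != pb[2]) next
      if (pt[3] == "Ltec") {
        for (ts in sel("ts-of")) if (ts[2] == pb[3])
          for (tf in sel("tf-of")) if (tf[3] == ts[3])
            changed <- add(c("fnd-in-postp", pb[2], tf[2])) || changed
      }
      if (pt[3] == "Ltpm") {
        for (pm in sel("pm-of")) if (pm[3] == pb[3]) {
          changed <- add(c("fnd-in-postp", pb[2], pm[2])) || changed
          changed <- add(c("att-to", pb[2], pm[2])) || changed
        }
        for (e in sym2("exp-to")) if (e[1] == pb[3] && e[2] != pb[2])
          changed <- add(c("exp-to", pb[2], e[2])) || changed
      }
    }
    for (fp in sel("fnd-in-postp"))
      changed <- add(c("fnd-in", fp[2], fp[3])) || changed
    for (tf in sel("tf-of")) for (ts in sel("ts-of")) if (tf[3] == ts[3])
      changed <- add(c("exp-to", tf[2], ts[2])) || changed
    for (fn in sel("fnd-in")) {
      if (!is_fluid(fn[3]) || fn[2] == fn[3]) next
      changed <- add(c("exp-to", fn[2], fn[3])) || changed
      for (e in sym2("exp-to")) if (e[1] == fn[3] && e[2] != fn[2])
        changed <- add(c("exp-to", fn[2], e[2])) || changed
      for (fn2 in sel("fnd-in"))
        if (fn2[3] == fn[3] && fn2[2] != fn[2])
          changed <- add(c("exp-to", fn[2], fn2[2])) || changed
    }
    for (pm in sel("pm-of")) for (e in sym2("exp-to"))
      if (e[1] == pm[3] && is_fluid(e[2]))
        changed <- add(c("exp-to", pm[2], e[2])) || changed
    for (tf in sel("tf-of")) for (cp in sel("cap-of")) if (tf[3] == cp[3])
      changed <- add(c("COMM3", tf[2], cp[2], "cnv")) || changed
    for (cn in sel("CONN")) {
      if (is_cvs(cn[2]) && is_cvs(cn[3]))
        changed <- add(c("COMM3", cn[2], cn[3], "adv")) || changed
      if (is_fluid(cn[2]) && is_fluid(cn[3]))
        changed <- add(c("COMM3", cn[2], cn[3], "dif")) || changed
    }
    for (tf in sel("tf-of"))
      if (is_cvs(tf[3]) && !tf[3] %in% caps && !tf[3] %in% chambers)
        changed <- add(c("COMM3", tf[3], tf[2], "cnv")) || changed
    if (!changed) break
  }
  sort(unlist(lapply(facts, oracle_key)))
}

# Reachability oracle: undirected reachability over capability-filtered
# communication edges, via igraph; start sites included only when they have
# at least one incident filtered edge.
bfs_reachable_oracle <- function(kb, starts, capabilities) {
  comm <- kb$facts[kb$facts$relation == "COMM3" &
                     kb$facts$arg3 %in% capabilities, , drop = FALSE]
  if (nrow(comm) == 0L || length(capabilities) == 0L) return(character(0))
  g <- igraph::graph_from_data_frame(comm[, c("arg1", "arg2")], directed = FALSE)
  out <- character(0)
  for (s in intersect(starts, igraph::V(g)$name)) {
    comp <- igraph::V(g)$name[igraph::subcomponent(g, s)]
    if (igraph::degree(g, s) > 0) out <- c(out, comp)
  }
  sort(unique(out))
}

# Exhaustive enumeration of simple directed edge paths between two nodes;
# returns the minimum-weight path, ties broken by lexicographically smallest
# edge-id sequence. NULL when unreachable.
enum_best_path <- function(edges, start, goal) {
  best <- NULL
  best_w <- Inf
  lex_lt <- function(a, b) {
    n <- min(length(a), length(b))
    for (i in seq_len(n)) {
      if (a[i] < b[i]) return(TRUE)
      if (a[i] > b[i]) return(FALSE)
    }
    length(a) < length(b)
  }
  recurse <- function(node, visited, path, w) {
    if (node == goal) {
      if (w < best_w || (w == best_w && (is.null(best) || lex_lt(path, best)))) {
        best <<- path
        best_w <<- w
      }
      return(invisible())
    }
    idx <- which(edges$from == node & !(edges$to %in% visited))
    for (j in idx)
      recurse(edges$to[j], c(visited, edges$to[j]), c(path, edges$id[j]),
              w + edges$weight[j])
  }
  if (start == goal) return(character(0))
  recurse(start, start, character(0), 0)
  best
}

# Random small directed multigraph wrapped as a cvs_graph.
random_multigraph <- function(seed, unit_weights = FALSE) {
  set.seed(seed)
  n <- sample(3:8, 1)
  m <- sample(n:(2L * n), 1)
  from <- paste0("n", sample(n, m, replace = TRUE))
  to <- paste0("n", sample(n, m, replace = TRUE))
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  edges <- data.frame(
    id = sprintf("e%02d", seq_along(from)),
    from = from, to = to,
    weight = if (unit_weights) 1 else sample(1:3, length(from), replace = TRUE),
    vessel = NA_character_,
    stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = sort(unique(c(from, to)))),
            class = "cvs_graph")
}
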