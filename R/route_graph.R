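# Traversal graphs and route construction.
#
# Two graphs are built from a saturated knowledge base: a directed
# multigraph of the cardiovascular system whose edges are CVS portions and
# whose nodes are the boundaries between them (direction = blood flow), and
# an undirected exchange graph whose nodes are tissue-fluid compartments and
# the vessels they exchange with, and whose edges are the inter-endothelial
# boundary spaces crossed during convective exchange.

# -- CVS graph ---------------------------------------------------------------

#' Build the cardiovascular-system graph
#'
#' Every CVS portion becomes exactly one directed edge; nodes are boundary
#' points between portions, obtained by identifying the downstream end of a
#' portion with the upstream end of each portion it connects to. Parallel
#' vessels between the same boundaries are preserved as distinct edges.
#'
#' @param kb A knowledge base (its `CONN` facts are read in asserted,
#'   blood-flow, orientation).
#' @return A `cvs_graph` object: `edges` data frame (`id`, `from`, `to`,
#'   `weight`, `vessel`) and `nodes` character vector.
#' @export
build_cvs_graph <- function(kb) {
  .pr_check_kb(kb)
  ind <- kb$individuals
  portions <- sort(ind$id[ind$kind == "CVSPortion"])
  conn <- .pr_rel2(kb, "CONN", c("from", "to"))
  is_cvs <- function(x) x %in% portions
  # a CONN fact tying a CVS portion to something never declared as a portion
  # (nor as a tissue fluid, which has its own diffusion edges) is a curation
  # error in the connectivity KB
  other <- ifelse(is_cvs(conn$from), conn$to, conn$from)
  other_kind <- ind$kind[match(other, ind$id)]
  bad <- xor(is_cvs(conn$from), is_cvs(conn$to)) &
    (is.na(other_kind) | !other_kind %in% c("TissueFluid"))
  if (any(bad))
    pr_stop("DanglingConnection", "CONN fact links CVS portion to a non-portion: %s -> %s",
            conn$from[bad][1], conn$to[bad][1])
  conn <- conn[is_cvs(conn$from) & is_cvs(conn$to), , drop = FALSE]

  # union-find over portion end slots: head of x coincides with tail of y
  slots <- c(paste0(portions, ":t"), paste0(portions, ":h"))
  parent <- stats::setNames(slots, slots)
  find <- function(s) { while (parent[[s]] != s) s <- parent[[s]]; s }
  for (j in seq_len(nrow(conn))) {
    a <- find(paste0(conn$from[j], ":h"))
    b <- find(paste0(conn$to[j], ":t"))
    if (a != b) parent[[max(a, b)]] <- min(a, b)
  }
  rep_of <- vapply(slots, find, character(1))
  # deterministic node name: lexicographically smallest member slot
  node_of <- stats::setNames(paste0("n::", rep_of), slots)
  vessel <- ind$vessel[match(portions, ind$id)]
  edges <- data.frame(
    id = portions,
    from = unname(node_of[paste0(portions, ":t")]),
    to = unname(node_of[paste0(portions, ":h")]),
    weight = 1,
    vessel = vessel,
    stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = sort(unique(c(edges$from, edges$to)))),
            class = "cvs_graph")
}

#' @export
print.cvs_graph <- function(x, ...) {
  cat(sprintf("<CVS graph: %d portions (edges), %d boundary nodes>\n",
              nrow(x$edges), length(x$nodes)))
  invisible(x)
}

#' Convert a traversal graph to an igraph object
#'
#' @param g A `cvs_graph` or `tf_graph`.
#' @return An igraph graph (directed for the CVS graph, undirected for the
#'   exchange graph), with edge attribute `name` carrying compartment or
#'   boundary identifiers.
#' @export
as_igraph <- function(g) UseMethod("as_igraph")

#' @export
as_igraph.cvs_graph <- function(g) {
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("from", "to")], directed = TRUE, vertices = g$nodes)
  igraph::E(ig)$name <- g$edges$id
  igraph::E(ig)$weight <- g$edges$weight
  ig
}

#' @export
as_igraph.tf_graph <- function(g) {
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("from", "to")], directed = FALSE, vertices = g$nodes)
  igraph::E(ig)$name <- g$edges$boundary
  ig
}

#' Export a traversal graph to GraphML
#'
#' @param g A `cvs_graph` or `tf_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}

#' Is the CVS graph a single closed circuit?
#'
#' @param g A `cvs_graph`.
#' @return `TRUE` when every boundary node lies in one strongly connected
#'   component.
#' @export
cvs_is_closed_circuit <- function(g) {
  igraph::is_connected(as_igraph(g), mode = "strong")
}

# -- tissue-fluid exchange graph --------------------------------------------

.pr_boundary_id <- function(a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  sprintf("BND::%s::%s", lo, hi)
}

#' Build the tissue-fluid exchange graph
#'
#' Nodes are tissue-fluid compartments and the CVS portions they exchange
#' with (capillaries, and non-capillary vessels with their own tissue
#' fluid); every convective communication fact yields exactly one edge,
#' whose attribute is a boundary-space compartment with a deterministic
#' identifier (`BND::<a>::<b>`, arguments in lexicographic order) unless one
#' was declared.
#'
#' @param kb A saturated knowledge base (saturated internally if needed).
#' @return A `tf_graph` object: `edges` data frame (`from`, `to`,
#'   `boundary`) and `nodes` character vector.
#' @export
build_tf_graph <- function(kb) {
  kb <- saturate(.pr_check_kb(kb))
  comm <- kb$facts[kb$facts$relation == "COMM3" & kb$facts$arg3 == "cnv", , drop = FALSE]
  edges <- data.frame(
    from = comm$arg1, to = comm$arg2,
    boundary = .pr_boundary_id(comm$arg1, comm$arg2),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$boundary, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$from, edges$to)))),
            class = "tf_graph")
}

#' @export
print.tf_graph <- function(x, ...) {
  cat(sprintf("<tissue-fluid exchange graph: %d nodes, %d boundary edges>\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Hop distances from a tissue fluid in the exchange graph; returns the
# nearest CVS-portion node (ties broken lexicographically).
.pr_nearest_cvs <- function(kb, tf, what) {
  ind <- kb$individuals
  k <- ind$kind[match(tf, ind$id)]
  if (is.na(k) || k != "TissueFluid")
    pr_stop("KindViolation", "'%s' is not a tissue-fluid compartment", tf)
  g <- build_tf_graph(kb)
  if (!tf %in% g$nodes)
    pr_stop("NoEntryPoint", "tissue fluid '%s' has no convective connection", tf)
  adj <- split(c(g$edges$to, g$edges$from), c(g$edges$from, g$edges$to))
  cvs_ids <- ind$id[ind$kind == "CVSPortion"]
  dist <- 0L
  seen <- tf
  frontier <- tf
  while (length(frontier)) {
    dist <- dist + 1L
    frontier <- setdiff(sort(unique(unlist(adj[frontier], use.names = FALSE))), seen)
    if (!length(frontier)) break
    hit <- frontier[frontier %in% cvs_ids]
    if (length(hit)) return(hit[1])  # frontier sorted: lexicographic tie-break
    seen <- c(seen, frontier)
  }
  pr_stop("NoEntryPoint", "no CVS %s point reachable from tissue fluid '%s'", what, tf)
}

#' Find the vascular entry point for a tissue fluid
#'
#' The CVS portion (typically a capillary bed, or a vessel exchanging with
#' its own tissue fluid) closest to the given tissue-fluid compartment in
#' the exchange graph; ties are broken lexicographically by identifier.
#'
#' @param kb A knowledge base.
#' @param tf Tissue-fluid compartment identifier.
#' @return A CVS portion identifier.
#' @export
find_cvs_entry <- function(kb, tf) {
  kb <- saturate(.pr_check_kb(kb))
  .pr_nearest_cvs(kb, tf, "entry")
}

#' Find the vascular exit point for a tissue fluid
#'
#' Mirror of [find_cvs_entry()] with respect to the route's absolute end.
#'
#' @inheritParams find_cvs_entry
#' @return A CVS portion identifier.
#' @export
find_cvs_exit <- function(kb, tf) {
  kb <- saturate(.pr_check_kb(kb))
  .pr_nearest_cvs(kb, tf, "exit")
}

# -- deterministic shortest path --------------------------------------------

# TRUE when edge-id sequence a orders strictly before b.
.pr_lex_lt <- function(a, b) {
  n <- min(length(a), length(b))
  if (n > 0L) {
    for (i in seq_len(n)) {
      if (a[i] < b[i]) return(TRUE)
      if (a[i] > b[i]) return(FALSE)
    }
  }
  length(a) < length(b)
}

# Dijkstra on a directed multigraph with lexicographic tie-breaking on the
# edge-id sequence among equal-weight shortest paths. Weights must be
# positive. Returns the edge-id sequence (character(0) if start == goal) or
# NULL when the goal is unreachable.
.pr_dijkstra_lex <- function(edges, start, goal) {
  nodes <- unique(c(edges$from, edges$to, start, goal))
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  paths <- stats::setNames(vector("list", length(nodes)), nodes)
  done <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  dist[start] <- 0
  paths[[start]] <- character(0)
  out_edges <- split(seq_len(nrow(edges)), edges$from)
  repeat {
    open <- names(dist)[!done & is.finite(dist)]
    if (!length(open)) break
    u <- open[1]
    for (v in open[-1]) {
      if (dist[v] < dist[u] ||
          (dist[v] == dist[u] && .pr_lex_lt(paths[[v]], paths[[u]]))) u <- v
    }
    done[u] <- TRUE
    if (u == goal) break
    idx <- out_edges[[u]]
    if (!is.null(idx)) {
      for (j in idx[order(edges$id[idx], method = "radix")]) {
        v <- edges$to[j]
        nd <- dist[u] + edges$weight[j]
        np <- c(paths[[u]], edges$id[j])
        if (nd < dist[v] || (nd == dist[v] && .pr_lex_lt(np, paths[[v]]))) {
          dist[v] <- nd
          paths[[v]] <- np
        }
      }
    }
  }
  if (!is.finite(dist[goal])) return(NULL)
  paths[[goal]]
}

#' Shortest route through the cardiovascular graph
#'
#' The minimal-weight directed edge path from the entry portion's downstream
#' boundary to the exit portion's upstream boundary, with the entry portion
#' prepended and the exit portion appended. Edge weights default to 1 per
#' portion and may be overridden per edge; among equal-weight shortest paths
#' the lexicographically smallest edge-id sequence is returned, so results
#' are deterministic.
#'
#' @param g A `cvs_graph`.
#' @param entry,exit CVS portion (edge) identifiers.
#' @param weights Optional named numeric vector of per-edge weight
#'   overrides.
#' @return Character vector of CVS portion identifiers, entry first.
#' @export
shortest_cvs_route <- function(g, entry, exit, weights = NULL) {
  if (!inherits(g, "cvs_graph")) pr_stop("NotAGraph", "expected a 'cvs_graph'")
  edges <- g$edges
  if (!is.null(weights)) {
    i <- match(names(weights), edges$id)
    if (anyNA(i)) pr_stop("UnknownEdge", "weight override for unknown portion")
    edges$weight[i] <- unname(weights)
  }
  if (any(edges$weight <= 0)) pr_stop("InvalidWeight", "edge weights must be positive")
  ei <- match(entry, edges$id)
  xi <- match(exit, edges$id)
  if (is.na(ei)) pr_stop("UnknownEdge", "entry portion '%s' is not in the graph", entry)
  if (is.na(xi)) pr_stop("UnknownEdge", "exit portion '%s' is not in the graph", exit)
  if (entry == exit) return(entry)
  start <- edges$to[ei]
  goal <- edges$from[xi]
  if (start == goal) return(c(entry, exit))
  p <- .pr_dijkstra_lex(edges, start, goal)
  if (is.null(p))
    pr_stop("NoPath", "no directed path from '%s' to '%s'", entry, exit)
  c(entry, p, exit)
}

# -- route elicitation -------------------------------------------------------

.pr_require_capability <- function(kb, protein, modality, stage) {
  caps <- unique(kb_query(kb, "CMTP_t", c(protein, NA))$arg2)
  if (!modality %in% caps)
    pr_stop("NoRoute", "mover '%s' cannot %s: %s", protein,
            c(adv = "advect", dif = "diffuse", cnv = "convect")[modality], stage)
}

#' Elicit a candidate anatomical route between two proteins
#'
#' Runs the full endocrine pipeline: triage assigns mover and fixed roles;
#' the subtending translocation fixes the absolute start (the mover's
#' post-production tissue fluid) and absolute end (the tissue fluid exposed
#' to the fixed partner's membrane); the route is then built in three legs
#' \enumerate{
#'   \item from the start fluid across a boundary space into the vascular
#'     entry point,
#'   \item the shortest directed path through the cardiovascular graph from
#'     entry to exit,
#'   \item across a boundary space from the exit vessel into the end fluid,
#' }
#' and summarised by vessel-level condensation and the transport-modality
#' footprint. The mover must be capable of each modality the route uses
#' (diffusion within fluids, convection across boundary spaces, advection
#' along the bloodstream).
#'
#' @param kb A knowledge base.
#' @param a,b Protein identifiers (mover/fixed roles are inferred).
#' @param expand_macro Unfold macro-region edges (e.g. the pulmonary
#'   circulation) into their member subgraph's own shortest path.
#' @param weights Optional per-edge weight overrides for the CVS search.
#' @return A `phys_route` object: `interaction`, `spec`, `legs`,
#'   `raw_path`, `condensed`, `footprint`.
#' @export
elicit_route <- function(kb, a, b, expand_macro = FALSE, weights = NULL) {
  kb <- saturate(.pr_check_kb(kb))
  hyp <- classify_interaction(kb, a, b)
  if (hyp$scenario != "endocrine_one_mover")
    pr_stop("UnsupportedScenario",
            "route elicitation requires the endocrine scenario, got '%s'", hyp$scenario)
  spec <- subtending_translocation(kb, a, b)
  mover <- spec$object

  if (spec$from_loc == spec$to_loc) {
    raw <- spec$from_loc
    legs <- list(leg1 = raw, leg2 = character(0), leg3 = character(0))
  } else {
    .pr_require_capability(kb, mover, "dif", "cannot move within tissue fluid")
    .pr_require_capability(kb, mover, "cnv",
                           "cannot cross from tissue fluid into the vasculature")
    .pr_require_capability(kb, mover, "adv", "cannot travel along the bloodstream")
    entry <- tryCatch(find_cvs_entry(kb, spec$from_loc),
                      physroute_NoEntryPoint = function(e)
                        pr_stop("NoRoute", "leg 1 failed: %s", conditionMessage(e)))
    exit <- tryCatch(find_cvs_exit(kb, spec$to_loc),
                     physroute_NoEntryPoint = function(e)
                       pr_stop("NoRoute", "leg 3 failed: %s", conditionMessage(e)))
    g <- build_cvs_graph(kb)
    leg2 <- tryCatch(shortest_cvs_route(g, entry, exit, weights = weights),
                     physroute_NoPath = function(e)
                       pr_stop("NoRoute", "leg 2 failed: %s", conditionMessage(e)))
    if (expand_macro) leg2 <- .pr_expand_macros(kb, g, leg2)
    leg1 <- c(spec$from_loc, .pr_boundary_id(spec$from_loc, entry), entry)
    leg3 <- c(exit, .pr_boundary_id(exit, spec$to_loc), spec$to_loc)
    legs <- list(leg1 = leg1, leg2 = leg2, leg3 = leg3)
    raw <- c(leg1, leg2[-1], leg3[-1])  # junction compartments appear once
  }

  membership <- .pr_vessel_membership(kb, raw)
  condensed <- condense_path(raw, membership)
  fp <- footprint(condensed, kb_kinds(kb, raw))
  structure(list(interaction = hyp, spec = spec, legs = legs, raw_path = raw,
                 condensed = condensed, footprint = fp),
            class = "phys_route")
}

# Vessel-membership labels for condensation, from the compartments' vessel
# metadata (identity for unmapped ids).
.pr_vessel_membership <- function(kb, ids) {
  v <- kb$individuals$vessel[match(ids, kb$individuals$id)]
  out <- ifelse(is.na(v), ids, v)
  stats::setNames(out, ids)
}

# Substitute macro-region edges by their member subgraph's shortest path.
.pr_expand_macros <- function(kb, g, leg2) {
  ind <- kb$individuals
  out <- character(0)
  for (p in leg2) {
    sk <- ind$cvs_subkind[match(p, ind$id)]
    if (!is.na(sk) && sk == "macro_region") {
      members <- ind$id[!is.na(ind$vessel) & ind$vessel == p & ind$kind == "CVSPortion"]
      sub <- g$edges[g$edges$id %in% members, , drop = FALSE]
      macro <- g$edges[g$edges$id == p, ]
      first <- sub$id[sub$from == macro$from]
      last <- sub$id[sub$to == macro$to]
      if (length(members) && length(first) && length(last)) {
        sg <- structure(list(edges = sub, nodes = unique(c(sub$from, sub$to))),
                        class = "cvs_graph")
        out <- c(out, shortest_cvs_route(sg, sort(first)[1], sort(last)[1]))
        next
      }
    }
    out <- c(out, p)
  }
  out
}

#' @export
print.phys_route <- function(x, ...) {
  cat(sprintf("<route for %s: %s -> %s>\n", x$interaction$id,
              x$spec$from_loc, x$spec$to_loc))
  cat(sprintf("  raw path: %d compartments; condensed: %d groups\n",
              length(x$raw_path), length(x$condensed$groups)))
  cat("  footprint:", paste(x$footprint$steps$modality, collapse = " - "), "\n")
  invisible(x)
}

#' Serialise a route to JSON
#'
#' @param route A `phys_route`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return A JSON string (invisibly when written to `path`).
#' @export
route_to_json <- function(route, path = NULL) {
  stopifnot(inherits(route, "phys_route"))
  obj <- list(
    interaction = list(id = route$interaction$id,
                       pair = route$interaction$pair,
                       scenario = route$interaction$scenario,
                       mover = route$interaction$mover,
                       fixed = route$interaction$fixed),
    spec = list(id = route$spec$id, interaction = route$spec$interaction,
                object = route$spec$object, from_loc = route$spec$from_loc,
                to_loc = route$spec$to_loc),
    legs = route$legs,
    raw_path = route$raw_path,
    condensed = lapply(route$condensed$groups, function(g)
      list(label = g$label, members = g$members, span = g$span)),
    footprint = lapply(seq_len(nrow(route$footprint$steps)), function(i)
      list(modality = route$footprint$steps$modality[i],
           from_group = route$footprint$steps$from[i],
           to_group = route$footprint$steps$to[i]))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(js, path, useBytes = TRUE)
    return(invisible(js))
  }
  js
}
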