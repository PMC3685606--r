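# Forward-chaining rule engine: location and exposure axioms, communication
# axioms, accessibility as reachability closure, and the interaction /
# translocation consequences built on them.
#
# Derived facts carry provenance "derived(<rule-id>)". Rule ids name what the
# rule does:
#   found-by-participation  participants of a process are found where it occurs
#   found-postp             a post-production site is a site the protein is found in
#   postp-secreted          secreted product -> producer tissue's fluid
#   postp-membrane          membrane product -> producer's plasma membrane (+ att-to)
#   expose-tissue           a tissue's fluid and structure portions are exposed
#   expose-in-fluid         an entity is exposed to the fluid it is found in
#   expose-via-fluid        ... and to whatever that fluid is exposed to
#   expose-via-producer     a membrane product is exposed to whatever its producer is
#   expose-shared-fluid     two entities in one fluid portion are exposed
#   expose-membrane-fluid   a plasma membrane is exposed to fluids its structure is
#   comm-capillary          organ tissue fluid <-> organ capillaries, convection
#   comm-flow               connected CVS portions, advection (blood-flow direction)
#   comm-vessel-wall        non-capillary, non-chamber vessel <-> its own tissue fluid
#   comm-tissue-fluid       connected tissue-fluid portions, diffusion
#   access-step / access-recursive    reachability over communication edges
#   found-where-access      an accessible site is a site the entity can be found in
#   interact-via-route      access to an exposed site licenses interaction
#   transloc-endpoints      endpoints of the subtending translocation

.pr_rel2 <- function(kb, rel, names = c("arg1", "arg2")) {
  d <- kb$facts[kb$facts$relation == rel, c("arg1", "arg2"), drop = FALSE]
  rownames(d) <- NULL
  names(d) <- names
  d
}

# Symmetric view (both orientations) of a binary relation.
.pr_rel2_sym <- function(kb, rel, names = c("arg1", "arg2")) {
  d <- .pr_rel2(kb, rel)
  if (nrow(d)) {
    d <- unique(rbind(d, data.frame(arg1 = d$arg2, arg2 = d$arg1,
                                    stringsAsFactors = FALSE)))
  }
  names(d) <- names
  d
}

.pr_fluid_ids <- function(kb) {
  kb$individuals$id[kb$individuals$kind == "TissueFluid"]
}

.pr_new2 <- function(relation, arg1, arg2) {
  if (length(arg1) == 0L)
    return(data.frame(relation = character(), arg1 = character(),
                      arg2 = character(), arg3 = character(), stringsAsFactors = FALSE))
  unique(data.frame(relation = relation, arg1 = arg1, arg2 = arg2,
                    arg3 = NA_character_, stringsAsFactors = FALSE))
}

.pr_new3 <- function(relation, arg1, arg2, arg3) {
  if (length(arg1) == 0L)
    return(data.frame(relation = character(), arg1 = character(),
                      arg2 = character(), arg3 = character(), stringsAsFactors = FALSE))
  unique(data.frame(relation = relation, arg1 = arg1, arg2 = arg2, arg3 = arg3,
                    stringsAsFactors = FALSE))
}

#' Derive location and exposure facts to fixpoint
#'
#' Applies the post-production localisation and exposure axioms until no new
#' fact can be added: secreted products are placed in their producer tissue's
#' fluid, membrane products in (and attached to) their producer's plasma
#' membrane; a tissue's fluid and structure portions are mutually exposed;
#' entities are exposed to the fluid they are found in, to whatever that
#' fluid is exposed to, and to each other when sharing a fluid; membrane
#' products inherit their producer's exposures. Exposure is symmetric and is
#' deliberately not closed transitively. Idempotent.
#'
#' @param kb A knowledge base.
#' @return The knowledge base with derived `fnd-in`, `fnd-in-postp`,
#'   `att-to` and `exp-to` facts added.
#' @export
derive_location_exposure <- function(kb) {
  .pr_check_kb(kb)
  guard <- 0L
  repeat {
    guard <- guard + 1L
    stopifnot(guard < 1000L)  # bounded by the finite fact space on valid input
    added <- 0L

    pb  <- .pr_rel2(kb, "prod-by", c("prod", "producer"))
    pt  <- .pr_rel2(kb, "postp_t", c("prod", "loctype"))
    tsf <- .pr_rel2(kb, "ts-of", c("ts", "tissue"))
    tff <- .pr_rel2(kb, "tf-of", c("tf", "tissue"))
    pmf <- .pr_rel2(kb, "pm-of", c("pm", "owner"))
    fluids <- .pr_fluid_ids(kb)

    # found-by-participation
    oc <- .pr_rel2(kb, "occurs-in", c("proc", "site"))
    pa <- .pr_rel2(kb, "participates-in", c("part", "proc"))
    m <- merge(pa, oc, by = "proc")
    r <- .pr_assert_df(kb, .pr_new2("fnd-in", m$part, m$site),
                       "derived(found-by-participation)")
    kb <- r$kb; added <- added + r$n

    # postp-secreted: a secreted product is found in its producer tissue's fluid
    sec <- pt$prod[pt$loctype == "Ltec"]
    m <- pb[pb$prod %in% sec, , drop = FALSE]
    m <- merge(m, tsf, by.x = "producer", by.y = "ts")
    m <- merge(m, tff, by = "tissue")
    r <- .pr_assert_df(kb, .pr_new2("fnd-in-postp", m$prod, m$tf),
                       "derived(postp-secreted)")
    kb <- r$kb; added <- added + r$n

    # postp-membrane: a membrane product is found in, and attached to, the
    # plasma membrane of its producer
    mem <- pt$prod[pt$loctype == "Ltpm"]
    m <- pb[pb$prod %in% mem, , drop = FALSE]
    m <- merge(m, pmf, by.x = "producer", by.y = "owner")
    r <- .pr_assert_df(kb, .pr_new2("fnd-in-postp", m$prod, m$pm),
                       "derived(postp-membrane)")
    kb <- r$kb; added <- added + r$n
    r <- .pr_assert_df(kb, .pr_new2("att-to", m$prod, m$pm),
                       "derived(postp-membrane)")
    kb <- r$kb; added <- added + r$n

    # found-postp: a post-production site is a site the protein is found in
    fp <- .pr_rel2(kb, "fnd-in-postp", c("ent", "site"))
    r <- .pr_assert_df(kb, .pr_new2("fnd-in", fp$ent, fp$site),
                       "derived(found-postp)")
    kb <- r$kb; added <- added + r$n

    fnd <- .pr_rel2(kb, "fnd-in", c("ent", "site"))
    exps <- .pr_rel2_sym(kb, "exp-to", c("from", "to"))

    # expose-tissue: a tissue's fluid and structure portions are exposed
    m <- merge(tff, tsf, by = "tissue")
    r <- .pr_assert_df(kb, .pr_new2("exp-to", m$tf, m$ts),
                       "derived(expose-tissue)")
    kb <- r$kb; added <- added + r$n

    # expose-in-fluid
    infl <- fnd[fnd$site %in% fluids & fnd$ent != fnd$site, , drop = FALSE]
    r <- .pr_assert_df(kb, .pr_new2("exp-to", infl$ent, infl$site),
                       "derived(expose-in-fluid)")
    kb <- r$kb; added <- added + r$n

    # expose-via-fluid: exposed to whatever the containing fluid is exposed to
    m <- merge(infl, exps, by.x = "site", by.y = "from")
    m <- m[m$ent != m$to, , drop = FALSE]
    r <- .pr_assert_df(kb, .pr_new2("exp-to", m$ent, m$to),
                       "derived(expose-via-fluid)")
    kb <- r$kb; added <- added + r$n

    # expose-via-producer: a membrane product inherits its producer's exposures
    m <- pb[pb$prod %in% mem, , drop = FALSE]
    m <- merge(m, exps, by.x = "producer", by.y = "from")
    m <- m[m$prod != m$to, , drop = FALSE]
    r <- .pr_assert_df(kb, .pr_new2("exp-to", m$prod, m$to),
                       "derived(expose-via-producer)")
    kb <- r$kb; added <- added + r$n

    # expose-shared-fluid
    m <- merge(infl, infl, by = "site")
    m <- m[m$ent.x != m$ent.y, , drop = FALSE]
    r <- .pr_assert_df(kb, .pr_new2("exp-to", m$ent.x, m$ent.y),
                       "derived(expose-shared-fluid)")
    kb <- r$kb; added <- added + r$n

    # expose-membrane-fluid: the plasma membrane of a tissue structure is
    # exposed to any fluid its structure is exposed to
    m <- merge(pmf, exps, by.x = "owner", by.y = "from")
    m <- m[m$to %in% fluids, , drop = FALSE]
    r <- .pr_assert_df(kb, .pr_new2("exp-to", m$pm, m$to),
                       "derived(expose-membrane-fluid)")
    kb <- r$kb; added <- added + r$n

    if (added == 0L) break
  }
  kb
}

#' Derive communication facts
#'
#' Adds ternary `COMM3` facts: an organ's tissue fluid communicates
#' convectively with the organ's capillaries; connected cardiovascular
#' portions communicate advectively in the direction of blood flow; every
#' non-capillary, non-chamber vessel communicates convectively with its own
#' tissue fluid; connected tissue-fluid portions communicate diffusively.
#' `COMM3` is commutative in its first two positions.
#'
#' @param kb A knowledge base.
#' @return The knowledge base with derived `COMM3` facts.
#' @export
derive_communication <- function(kb) {
  .pr_check_kb(kb)
  ind <- kb$individuals
  cvs_ids <- ind$id[ind$kind == "CVSPortion"]
  fluids <- .pr_fluid_ids(kb)
  cap_ids <- unique(c(ind$id[!is.na(ind$cvs_subkind) & ind$cvs_subkind == "capillary"],
                      .pr_rel2(kb, "cap-of")$arg1))
  chamber_ids <- ind$id[!is.na(ind$cvs_subkind) & ind$cvs_subkind == "chamber"]

  tff <- .pr_rel2(kb, "tf-of", c("tf", "tissue"))
  cpf <- .pr_rel2(kb, "cap-of", c("cap", "tissue"))
  conn <- .pr_rel2(kb, "CONN", c("from", "to"))

  # comm-capillary
  m <- merge(tff, cpf, by = "tissue")
  r <- .pr_assert_df(kb, .pr_new3("COMM3", m$tf, m$cap, "cnv"),
                     "derived(comm-capillary)")
  kb <- r$kb

  # comm-flow (advection along asserted blood-flow connections)
  m <- conn[conn$from %in% cvs_ids & conn$to %in% cvs_ids, , drop = FALSE]
  r <- .pr_assert_df(kb, .pr_new3("COMM3", m$from, m$to, "adv"),
                     "derived(comm-flow)")
  kb <- r$kb

  # comm-vessel-wall: vessels other than capillaries and cardiac chambers
  m <- tff[tff$tissue %in% setdiff(cvs_ids, c(cap_ids, chamber_ids)), , drop = FALSE]
  r <- .pr_assert_df(kb, .pr_new3("COMM3", m$tissue, m$tf, "cnv"),
                     "derived(comm-vessel-wall)")
  kb <- r$kb

  # comm-tissue-fluid
  m <- conn[conn$from %in% fluids & conn$to %in% fluids, , drop = FALSE]
  r <- .pr_assert_df(kb, .pr_new3("COMM3", m$from, m$to, "dif"),
                     "derived(comm-tissue-fluid)")
  kb <- r$kb

  kb
}

#' Saturate a knowledge base
#'
#' Runs [derive_location_exposure()] and [derive_communication()] to joint
#' fixpoint and marks the knowledge base saturated. Saturation is idempotent
#' and its result is independent of rule-application order (the rule set is
#' function-free over a finite domain).
#'
#' @param kb A knowledge base.
#' @return The saturated knowledge base.
#' @export
saturate <- function(kb) {
  .pr_check_kb(kb)
  if (isTRUE(kb$saturated)) return(kb)
  repeat {
    before <- nrow(kb$facts)
    kb <- derive_location_exposure(kb)
    kb <- derive_communication(kb)
    if (nrow(kb$facts) == before) break
  }
  kb$saturated <- TRUE
  kb
}

# Start sites of a protein: post-production sites plus asserted fnd-in sites.
.pr_start_sites <- function(kb, protein) {
  fp <- kb_query(kb, "fnd-in-postp", c(protein, NA))$arg2
  fi <- kb$facts[kb$facts$relation == "fnd-in" & kb$facts$arg1 == protein &
                   kb$facts$provenance %in% c("asserted", "derived(found-postp)",
                                              "derived(found-by-participation)"), ]
  sort(unique(c(fp, fi$arg2)))
}

#' Compartments accessible to a protein
#'
#' The set of compartments reachable from the protein's start site(s) by
#' traversing communication edges whose modality the protein is capable of
#' (its `CMTP_t` facts). This is the transitive closure of the access
#' axioms: one communication step from a site the protein is found in, then
#' recursion over accessible sites. A protein with no capabilities can
#' access nothing; a start site is included only when it can be re-entered
#' through communication edges.
#'
#' @param kb A knowledge base (saturated internally if needed).
#' @param protein Protein identifier.
#' @return Sorted character vector of compartment identifiers.
#' @export
accessible_set <- function(kb, protein) {
  kb <- saturate(.pr_check_kb(kb))
  starts <- .pr_start_sites(kb, protein)
  if (length(starts) == 0L)
    pr_stop("NoStartSite", "protein '%s' has no recorded location", protein)
  caps <- unique(kb_query(kb, "CMTP_t", c(protein, NA))$arg2)
  if (length(caps) == 0L) return(character(0))
  comm <- kb$facts[kb$facts$relation == "COMM3" & kb$facts$arg3 %in% caps, , drop = FALSE]
  if (nrow(comm) == 0L) return(character(0))
  adj <- split(c(comm$arg2, comm$arg1), c(comm$arg1, comm$arg2))
  acc <- character(0)
  frontier <- starts
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, acc)
    acc <- c(acc, nxt)
    frontier <- nxt
  }
  sort(acc)
}

#' Materialise accessibility facts for a protein
#'
#' Adds `acc` facts for every compartment in [accessible_set()] and, since
#' an accessible site is a site the entity can be found in, corresponding
#' `fnd-in` facts. The found-where-access consequence is materialised only
#' for the computed accessible set; it is not fed back into the
#' post-production rules (potential location is not production).
#'
#' @inheritParams accessible_set
#' @return The updated knowledge base.
#' @export
derive_accessibility <- function(kb, protein) {
  kb <- saturate(.pr_check_kb(kb))
  acc <- accessible_set(kb, protein)
  if (length(acc)) {
    r <- .pr_assert_df(kb, .pr_new2("acc", protein, acc), "derived(access-step)")
    kb <- r$kb
    r <- .pr_assert_df(kb, .pr_new2("fnd-in", protein, acc),
                       "derived(found-where-access)")
    kb <- r$kb
  }
  kb
}

.pr_exposed_set <- function(kb, x) {
  sort(unique(kb_query(kb, "exp-to", c(x, NA))$arg2))
}

#' Can two proteins interact via some route?
#'
#' True when one protein can access (or is found in) a compartment to which
#' the other is exposed. The witness compartment is chosen
#' deterministically as the lexicographically smallest such compartment,
#' preferring the first protein as mover on ties.
#'
#' @param kb A knowledge base.
#' @param a,b Protein identifiers.
#' @return A list with elements `interacts` (logical), `mover`, `witness`
#'   (`NA` when no route exists), of class `pr_interaction_verdict`.
#' @export
can_interact_via_some_route <- function(kb, a, b) {
  kb <- saturate(.pr_check_kb(kb))
  presence <- function(p) sort(unique(c(.pr_start_sites(kb, p), accessible_set(kb, p))))
  w_a <- intersect(presence(a), .pr_exposed_set(kb, b))
  w_b <- intersect(presence(b), .pr_exposed_set(kb, a))
  out <- list(interacts = FALSE, mover = NA_character_, witness = NA_character_)
  if (length(w_a) && (!length(w_b) || min(w_a) <= min(w_b))) {
    out <- list(interacts = TRUE, mover = a, witness = min(w_a))
  } else if (length(w_b)) {
    out <- list(interacts = TRUE, mover = b, witness = min(w_b))
  }
  structure(out, class = "pr_interaction_verdict")
}

#' @export
print.pr_interaction_verdict <- function(x, ...) {
  if (x$interacts) {
    cat(sprintf("interaction possible; mover = %s, witness compartment = %s\n",
                x$mover, x$witness))
  } else cat("no interaction route found\n")
  invisible(x)
}

# Post-production location type of a protein: explicit postp_t fact, else
# inferred from the kind of its post-production site (tissue fluid implies a
# secreted product, a plasma membrane or tissue structure a membrane-bound
# one).
.pr_postp_type <- function(kb, p) {
  t <- kb_query(kb, "postp_t", c(p, NA))$arg2
  if (length(t)) return(t[1])
  sites <- kb_query(kb, "fnd-in-postp", c(p, NA))$arg2
  kinds <- kb$individuals$kind[match(sites, kb$individuals$id)]
  if (any(kinds == "TissueFluid", na.rm = TRUE)) return("Ltec")
  if (any(kinds %in% c("PlasmaMembrane", "TissueStructure"), na.rm = TRUE)) return("Ltpm")
  NA_character_
}

#' The translocation subtending an endocrine interaction
#'
#' When one protein is a secreted (extracellular) product and the other a
#' plasma-membrane product, an interaction between them requires a
#' subtending translocation: the secreted protein moves from its
#' post-production site to the tissue fluid to which the membrane housing
#' the fixed partner is exposed. The translocation individual is skolemised
#' deterministically from the interaction identifier.
#'
#' @param kb A knowledge base.
#' @param a,b Protein identifiers.
#' @return A `transloc_spec` object (fields `id`, `interaction`, `object`,
#'   `from_loc`, `to_loc`, `fixed`), or `NULL` when the antecedent fails
#'   (e.g. two secreted proteins).
#' @export
subtending_translocation <- function(kb, a, b) {
  kb <- saturate(.pr_check_kb(kb))
  ta <- .pr_postp_type(kb, a)
  tb <- .pr_postp_type(kb, b)
  pair <- c(ta, tb)
  if (any(is.na(pair)) || !("Ltec" %in% pair && "Ltpm" %in% pair)) return(NULL)
  mover <- if (ta == "Ltec") a else b
  fixed <- if (ta == "Ltec") b else a
  from <- sort(kb_query(kb, "fnd-in-postp", c(mover, NA))$arg2)
  if (length(from) == 0L)
    pr_stop("NoStartSite", "protein '%s' has no post-production site", mover)
  sites <- kb_query(kb, "fnd-in-postp", c(fixed, NA))$arg2
  kinds <- kb$individuals$kind[match(sites, kb$individuals$id)]
  # the membrane the fixed partner sits in: its PM post-production site, or
  # the plasma membrane of its (tissue-structure) site
  membranes <- sites[kinds == "PlasmaMembrane"]
  if (length(membranes) == 0L) {
    pmf <- .pr_rel2(kb, "pm-of")
    membranes <- pmf$arg1[pmf$arg2 %in% sites]
  }
  base <- if (length(membranes)) membranes else sites
  fluids <- .pr_fluid_ids(kb)
  tf_declared <- unique(.pr_rel2(kb, "tf-of")$arg1)
  cand <- character(0)
  for (v in base) {
    ex <- .pr_exposed_set(kb, v)
    cand <- c(cand, ex[ex %in% fluids & ex %in% tf_declared])
  }
  cand <- sort(unique(cand))
  if (length(cand) == 0L)
    pr_stop("NoTarget", "no tissue fluid is exposed to the membrane of '%s'", fixed)
  if (length(cand) > 1L)
    pr_stop("AmbiguousTarget", "multiple candidate target fluids for '%s': %s",
            fixed, paste(cand, collapse = ", "))
  interaction <- sprintf("int::%s::%s", mover, fixed)
  structure(list(
    id = sprintf("transloc::%s", interaction),
    interaction = interaction,
    object = mover,
    from_loc = from[1],
    to_loc = cand,
    fixed = fixed
  ), class = "transloc_spec")
}

#' @export
print.transloc_spec <- function(x, ...) {
  cat(sprintf("<translocation %s: %s moves %s -> %s (subtends %s)>\n",
              x$id, x$object, x$from_loc, x$to_loc, x$interaction))
  invisible(x)
}
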