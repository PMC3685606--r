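# Triage: classify a protein pair into an interaction scenario and assign
# mover/fixed roles from the subcellular types of their post-production
# sites.

.pr_scenarios <- c("colocated_direct", "endocrine_one_mover", "both_movers",
                   "membrane_membrane_unsupported", "cytoplasmic_unsupported")

#' Classify a protein-pair interaction
#'
#' The scenario is determined by the proteins' post-production location
#' types. A secreted (extracellular) product facing a membrane-bound one is
#' the endocrine case: the secreted protein is the mover (the ligand is free
#' to move, the membrane-bound receptor is not). Two secreted products can
#' meet anywhere both can reach (`both_movers`), or interact directly when
#' they share a post-production fluid (`colocated_direct`). Two
#' membrane-bound proteins would require cell translocation and any
#' cytoplasmic partner would require intracellular pathways; both are
#' reported as typed unsupported scenarios rather than errors.
#'
#' @param kb A knowledge base.
#' @param a,b Protein identifiers.
#' @return An `interaction_hypothesis` object: fields `id`, `pair`,
#'   `scenario`, `mover`, `fixed`.
#' @export
#' @examples
#' kb <- make_kb()
#' kb <- assert_fact(kb, "postp_t", c("h", "Ltec"))
#' kb <- assert_fact(kb, "postp_t", c("r", "Ltpm"))
#' classify_interaction(kb, "h", "r")$scenario  # endocrine_one_mover
classify_interaction <- function(kb, a, b) {
  kb <- .pr_check_kb(kb)
  ta <- .pr_postp_type(kb, a)
  tb <- .pr_postp_type(kb, b)
  if (is.na(ta))
    pr_stop("MissingLocationType", "no post-production location type for '%s'", a)
  if (is.na(tb))
    pr_stop("MissingLocationType", "no post-production location type for '%s'", b)
  mover <- NA_character_
  fixed <- NA_character_
  if (ta == "Ltcyt" || tb == "Ltcyt") {
    scenario <- "cytoplasmic_unsupported"
  } else if (ta == "Ltpm" && tb == "Ltpm") {
    scenario <- "membrane_membrane_unsupported"
  } else if (ta == "Ltec" && tb == "Ltec") {
    kb2 <- saturate(kb)
    shared <- intersect(kb_query(kb2, "fnd-in-postp", c(a, NA))$arg2,
                        kb_query(kb2, "fnd-in-postp", c(b, NA))$arg2)
    fluids <- .pr_fluid_ids(kb2)
    scenario <- if (length(intersect(shared, fluids))) "colocated_direct" else "both_movers"
  } else {
    scenario <- "endocrine_one_mover"
    mover <- if (ta == "Ltec") a else b
    fixed <- if (ta == "Ltec") b else a
  }
  pr <- sort(c(a, b))
  structure(list(
    id = sprintf("int::%s::%s", pr[1], pr[2]),
    pair = c(a, b),
    scenario = scenario,
    mover = mover,
    fixed = fixed
  ), class = "interaction_hypothesis")
}

#' @export
print.interaction_hypothesis <- function(x, ...) {
  cat(sprintf("<interaction %s: %s>\n", x$id, x$scenario))
  if (!is.na(x$mover))
    cat(sprintf("  mover = %s, fixed = %s\n", x$mover, x$fixed))
  invisible(x)
}
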