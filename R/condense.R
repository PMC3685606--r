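# Route summarisation: vessel-level condensation of a raw compartment
# sequence and the physiological-communication footprint.

#' Condense a raw route by vessel membership
#'
#' Groups maximal runs of consecutive compartments sharing a membership
#' label (compartments that are portions of the same vessel are taken to be
#' equivalent); compartments without a label form singleton groups under
#' their own identifier. Non-consecutive occurrences of the same label are
#' never merged, so flattening the groups reproduces the input exactly.
#'
#' @param raw_path Character vector of compartment identifiers in route
#'   order.
#' @param membership Named character vector mapping identifiers to vessel or
#'   group labels; unmapped identifiers label themselves.
#' @return A `condensed_path` object: `groups` is an ordered list of
#'   `list(label, members, span)` where `span` is the `c(first, last)` index
#'   range in the raw path.
#' @export
#' @examples
#' condense_path(c("a1", "b1", "a2"), c(a1 = "A", a2 = "A", b1 = "B"))
condense_path <- function(raw_path, membership = NULL) {
  raw_path <- as.character(raw_path)
  labels <- raw_path
  if (!is.null(membership)) {
    m <- membership[raw_path]
    labels <- unname(ifelse(is.na(m), raw_path, m))
  }
  groups <- list()
  if (length(raw_path)) {
    r <- rle(labels)
    stop_i <- cumsum(r$lengths)
    start_i <- stop_i - r$lengths + 1L
    groups <- lapply(seq_along(r$values), function(k) {
      list(label = r$values[k],
           members = raw_path[start_i[k]:stop_i[k]],
           span = c(start_i[k], stop_i[k]))
    })
  }
  structure(list(groups = groups, raw_path = raw_path, labels = labels),
            class = "condensed_path")
}

#' @export
print.condensed_path <- function(x, ...) {
  cat(sprintf("<condensed path: %d compartments in %d groups>\n",
              length(x$raw_path), length(x$groups)))
  for (k in seq_along(x$groups)) {
    g <- x$groups[[k]]
    cat(sprintf("  C%d: %s (%d)\n", k, g$label, length(g$members)))
  }
  invisible(x)
}

#' Flatten a condensed path back to its raw sequence
#'
#' @param condensed A `condensed_path`.
#' @return Character vector of compartment identifiers.
#' @export
flatten_condensed <- function(condensed) {
  stopifnot(inherits(condensed, "condensed_path"))
  unlist(lapply(condensed$groups, `[[`, "members"), use.names = FALSE)
}

.pr_modality_of_kind <- c(TissueFluid = "Diffusion",
                          BoundarySpace = "Convection",
                          CVSPortion = "Advection")

#' Transport-modality footprint of a condensed route
#'
#' Assigns each compartment its transport modality — diffusion within
#' tissue fluid, convection across boundary spaces, advection within
#' cardiovascular portions of any subkind — and run-length encodes the
#' per-group modalities into maximal same-modality steps. The footprint is
#' invariant under condensation refinement: computing it from the raw
#' compartments or from any grouping of them yields the same step sequence.
#'
#' @param condensed A `condensed_path` (or raw character vector, taken as
#'   singleton groups).
#' @param kinds Named character vector mapping every member identifier to a
#'   compartment kind (`TissueFluid`, `BoundarySpace`, or `CVSPortion`).
#' @return A `phys_footprint` object: `steps` data frame with columns
#'   `modality`, `from`, `to` (condensed-group index range), and
#'   `group_modality`, the per-group modality vector.
#' @export
footprint <- function(condensed, kinds) {
  if (!inherits(condensed, "condensed_path"))
    condensed <- condense_path(as.character(condensed))
  group_mod <- vapply(condensed$groups, function(g) {
    k <- kinds[g$members]
    mod <- .pr_modality_of_kind[k]
    if (anyNA(mod))
      pr_stop("UnknownKind", "no compartment kind for '%s'",
              g$members[is.na(mod)][1])
    u <- unique(unname(mod))
    if (length(u) != 1L)
      pr_stop("UnknownKind", "group '%s' mixes transport modalities", g$label)
    u
  }, character(1))
  steps <- data.frame(modality = character(), from = integer(), to = integer(),
                      stringsAsFactors = FALSE)
  if (length(group_mod)) {
    r <- rle(group_mod)
    to <- cumsum(r$lengths)
    steps <- data.frame(modality = r$values, from = to - r$lengths + 1L, to = to,
                        stringsAsFactors = FALSE)
  }
  structure(list(steps = steps, group_modality = group_mod),
            class = "phys_footprint")
}

#' @export
print.phys_footprint <- function(x, ...) {
  for (i in seq_len(nrow(x$steps))) {
    s <- x$steps[i, ]
    rng <- if (s$from == s$to) sprintf("C%d", s$from) else sprintf("C%d-%d", s$from, s$to)
    cat(sprintf("%d. %s: %s\n", i, s$modality, rng))
  }
  invisible(x)
}
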