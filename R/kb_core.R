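# Typed fact store over a closed relation vocabulary for anatomical
# connectivity and protein-localisation ground facts.

# Canonical transport-modality tokens (lower case, as asserted in fact files).
.pr_modality_map <- c(
  adv = "adv", advection = "adv",
  dif = "dif", diffusion = "dif",
  cnv = "cnv", conv = "cnv", convection = "cnv"
)

# Subcellular location types of post-production sites.
.pr_loctype_map <- c(ltcyt = "Ltcyt", ltpm = "Ltpm", ltec = "Ltec")

# Individual kinds. Compartments proper are the first five; the rest name
# other individuals a KB may declare (tissues/organs, proteins, processes).
.pr_kinds <- c("TissueStructure", "TissueFluid", "CVSPortion", "PlasmaMembrane",
               "BoundarySpace", "Tissue", "Protein", "Interaction",
               "Translocation", "Other")

.pr_cvs_subkinds <- c("capillary", "venule", "arteriole", "vessel_segment",
                      "chamber", "macro_region")

# Closed relation vocabulary. `roles` drive both validation and the kind
# inferred for auto-declared individuals: a concrete kind name declares the
# argument as that kind; "tissue" accepts Tissue or CVSPortion individuals
# (cardiovascular portions are tissues); "modality"/"loctype" are closed
# token sets, not individuals.
.pr_relations <- list(
  "Protein"            = list(arity = 1L, roles = "Protein"),
  "Interaction"        = list(arity = 1L, roles = "Interaction"),
  "Translocation"      = list(arity = 1L, roles = "Translocation"),
  "cvs"                = list(arity = 1L, roles = "CVSPortion"),
  "acc"                = list(arity = 2L, roles = c(NA, NA)),
  "att-to"             = list(arity = 2L, roles = c(NA, NA)),
  "cap-of"             = list(arity = 2L, roles = c("capillary", "tissue")),
  "CIVSR"              = list(arity = 2L, roles = c(NA, NA)),
  "CMTP_t"             = list(arity = 2L, roles = c(NA, "modality")),
  "CONN"               = list(arity = 2L, roles = c(NA, NA), symmetric = TRUE),
  "COMM3"              = list(arity = 3L, roles = c(NA, NA, "modality"),
                              commutative12 = TRUE),
  "exp-to"             = list(arity = 2L, roles = c(NA, NA), symmetric = TRUE,
                              canonical_sort = TRUE),
  "fnd-in"             = list(arity = 2L, roles = c(NA, NA)),
  "fnd-in-postp"       = list(arity = 2L, roles = c(NA, NA)),
  "from-loc"           = list(arity = 2L, roles = c("Translocation", NA)),
  "int-btw"            = list(arity = 3L, roles = c(NA, NA, "Interaction")),
  "occurs-in"          = list(arity = 2L, roles = c(NA, NA)),
  "participates-in"    = list(arity = 2L, roles = c(NA, NA)),
  "postp_t"            = list(arity = 2L, roles = c(NA, "loctype")),
  "prod-by"            = list(arity = 2L, roles = c(NA, NA)),
  "pm-of"              = list(arity = 2L, roles = c("PlasmaMembrane", NA)),
  "tf-of"              = list(arity = 2L, roles = c("TissueFluid", "tissue")),
  "to-loc"             = list(arity = 2L, roles = c("Translocation", NA)),
  "trans-subtends-int" = list(arity = 2L, roles = c("Translocation", "Interaction")),
  "tr-obj"             = list(arity = 2L, roles = c("Translocation", NA)),
  "ts-of"              = list(arity = 2L, roles = c("TissueStructure", "tissue")),
  # Accepted by the vocabulary; no rule consumes them.
  "tr-site"            = list(arity = 2L, roles = c("Translocation", NA)),
  "fnd-in-loc-type"    = list(arity = 2L, roles = c(NA, "loctype"))
)

pr_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(paste0("physroute_", class), "physroute_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

.pr_relspec <- function(relation) {
  spec <- .pr_relations[[relation]]
  if (is.null(spec))
    pr_stop("UnknownRelation", "relation '%s' is not in the vocabulary", relation)
  spec
}

#' Create an empty knowledge base
#'
#' A knowledge base holds a set of named individuals (compartments, tissues,
#' proteins, processes) and a set of ground facts over a closed relation
#' vocabulary. Facts are either asserted or derived by the forward-chaining
#' rules (see [saturate()]).
#'
#' @return An object of class `physkb`.
#' @seealso [assert_fact()], [kb_query()], [load_facts()]
#' @export
#' @examples
#' kb <- make_kb()
#' kb <- assert_fact(kb, "Protein", "anp")
make_kb <- function() {
  structure(list(
    individuals = data.frame(
      id = character(), kind = character(), cvs_subkind = character(),
      label = character(), vessel = character(), stringsAsFactors = FALSE),
    facts = data.frame(
      relation = character(), arg1 = character(), arg2 = character(),
      arg3 = character(), provenance = character(), stringsAsFactors = FALSE),
    saturated = TRUE
  ), class = "physkb")
}

.pr_check_kb <- function(kb) {
  if (!inherits(kb, "physkb"))
    pr_stop("NotAKnowledgeBase", "expected a 'physkb' object")
  kb
}

#' Declare or update a named individual
#'
#' Individuals are normally auto-declared on first use in a fact, with a kind
#' inferred from the relation's argument signature; explicit declaration sets
#' or overrides compartment metadata (kind, CVS subkind, vessel membership).
#'
#' @param kb A knowledge base.
#' @param id Identifier string.
#' @param kind One of `r paste(.pr_kinds, collapse=", ")`.
#' @param cvs_subkind For `CVSPortion` individuals only: one of capillary,
#'   venule, arteriole, vessel_segment, chamber, macro_region.
#' @param label Human-readable name (defaults to `id`).
#' @param vessel Identifier of the named vessel (or macro region) this
#'   segment belongs to; drives vessel-level condensation.
#' @return The updated knowledge base.
#' @export
kb_declare <- function(kb, id, kind = "Other", cvs_subkind = NA_character_,
                       label = NA_character_, vessel = NA_character_) {
  .pr_check_kb(kb)
  if (!kind %in% .pr_kinds)
    pr_stop("KindViolation", "unknown individual kind '%s'", kind)
  if (!is.na(cvs_subkind)) {
    if (kind != "CVSPortion")
      pr_stop("KindViolation", "cvs_subkind only applies to CVSPortion individuals ('%s')", id)
    if (!cvs_subkind %in% .pr_cvs_subkinds)
      pr_stop("KindViolation", "unknown CVS subkind '%s'", cvs_subkind)
  }
  ind <- kb$individuals
  i <- match(id, ind$id)
  if (is.na(i)) {
    kb$individuals <- rbind(ind, data.frame(
      id = id, kind = kind, cvs_subkind = cvs_subkind,
      label = if (is.na(label)) id else label, vessel = vessel,
      stringsAsFactors = FALSE))
  } else {
    old <- ind$kind[i]
    if (old != "Other" && kind != "Other" && old != kind)
      pr_stop("KindViolation", "individual '%s' already declared as %s, cannot redeclare as %s",
              id, old, kind)
    if (kind != "Other") ind$kind[i] <- kind
    if (!is.na(cvs_subkind)) {
      if (!is.na(ind$cvs_subkind[i]) && ind$cvs_subkind[i] != cvs_subkind)
        pr_stop("KindViolation", "CVS subkind conflict for '%s' (%s vs %s)",
                id, ind$cvs_subkind[i], cvs_subkind)
      ind$cvs_subkind[i] <- cvs_subkind
    }
    if (!is.na(label)) ind$label[i] <- label
    if (!is.na(vessel)) ind$vessel[i] <- vessel
    kb$individuals <- ind
  }
  kb
}

# Declare (or kind-check) one fact argument under a role.
.pr_declare_role <- function(kb, id, role) {
  if (is.na(role)) {
    if (!id %in% kb$individuals$id) kb <- kb_declare(kb, id, "Other")
    return(kb)
  }
  if (role == "tissue") {
    i <- match(id, kb$individuals$id)
    if (is.na(i)) return(kb_declare(kb, id, "Tissue"))
    k <- kb$individuals$kind[i]
    if (!k %in% c("Tissue", "CVSPortion", "Other"))
      pr_stop("KindViolation", "'%s' is a %s, not a tissue or CVS portion", id, k)
    if (k == "Other") kb$individuals$kind[i] <- "Tissue"
    return(kb)
  }
  if (role == "capillary")
    return(kb_declare(kb, id, "CVSPortion", cvs_subkind = "capillary"))
  kb_declare(kb, id, role)
}

# Normalise a fact's tokens and check arity; returns c(arg1, arg2, arg3).
.pr_normalize_args <- function(relation, args) {
  spec <- .pr_relspec(relation)
  args <- as.character(args)
  if (length(args) != spec$arity)
    pr_stop("ArityMismatch", "relation '%s' takes %d argument(s), got %d",
            relation, spec$arity, length(args))
  for (i in seq_along(args)) {
    role <- spec$roles[i]
    if (!is.na(role) && role == "modality") {
      tok <- .pr_modality_map[tolower(args[i])]
      if (is.na(tok))
        pr_stop("KindViolation", "'%s' is not a transport modality (adv/dif/cnv)", args[i])
      args[i] <- unname(tok)
    } else if (!is.na(role) && role == "loctype") {
      tok <- .pr_loctype_map[tolower(args[i])]
      if (is.na(tok))
        pr_stop("KindViolation", "'%s' is not a location type (Ltcyt/Ltpm/Ltec)", args[i])
      args[i] <- unname(tok)
    }
  }
  if (isTRUE(spec$canonical_sort)) args[1:2] <- sort(args[1:2])
  c(args, rep(NA_character_, 3L - length(args)))
}

.pr_fact_key <- function(relation, a1, a2, a3) {
  paste(relation, a1, ifelse(is.na(a2), "", a2), ifelse(is.na(a3), "", a3),
        sep = "\x1f")
}

# All keys under which an existing fact must be recognised (symmetry /
# commutativity in the first two positions).
.pr_fact_keys_all <- function(relation, a1, a2, a3) {
  spec <- .pr_relations[[relation]]
  keys <- .pr_fact_key(relation, a1, a2, a3)
  if (isTRUE(spec$symmetric) || isTRUE(spec$commutative12))
    keys <- c(keys, .pr_fact_key(relation, a2, a1, a3))
  keys
}

.pr_kb_keys <- function(kb) {
  with(kb$facts, .pr_fact_key(relation, arg1, arg2, arg3))
}

#' Assert a ground fact
#'
#' The relation must belong to the closed vocabulary; arity and argument
#' kinds are checked at assertion time, and individuals are auto-declared
#' with a kind inferred from the relation's signature. Re-asserting a fact
#' (including the flipped form of a symmetric or commutative relation) is a
#' no-op.
#'
#' @param kb A knowledge base.
#' @param relation Relation symbol.
#' @param args Character vector of arguments.
#' @param provenance `"asserted"` or `"derived(<rule-id>)"`.
#' @return The updated knowledge base.
#' @export
#' @examples
#' kb <- make_kb()
#' kb <- assert_fact(kb, "CMTP_t", c("anp", "adv"))
assert_fact <- function(kb, relation, args, provenance = "asserted") {
  .pr_check_kb(kb)
  a <- .pr_normalize_args(relation, args)
  spec <- .pr_relations[[relation]]
  for (i in seq_len(spec$arity)) {
    role <- spec$roles[i]
    if (is.na(role) || !role %in% c("modality", "loctype"))
      kb <- .pr_declare_role(kb, a[i], role)
  }
  keys <- .pr_fact_keys_all(relation, a[1], a[2], a[3])
  if (!any(keys %in% .pr_kb_keys(kb))) {
    kb$facts <- rbind(kb$facts, data.frame(
      relation = relation, arg1 = a[1], arg2 = a[2], arg3 = a[3],
      provenance = provenance, stringsAsFactors = FALSE))
    if (identical(provenance, "asserted")) kb$saturated <- FALSE
  }
  kb
}

# Bulk assertion used by the rule engine and the generator: `new` is a
# data frame with columns relation, arg1, arg2, arg3 (already normalised
# token-wise by the callers for derived facts). Returns list(kb, n_added).
.pr_assert_df <- function(kb, new, provenance) {
  if (nrow(new) == 0L) return(list(kb = kb, n = 0L))
  # normalise row by row (cheap relative to the joins producing them)
  for (j in seq_len(nrow(new))) {
    a <- .pr_normalize_args(new$relation[j],
                            stats::na.omit(c(new$arg1[j], new$arg2[j], new$arg3[j])))
    new$arg1[j] <- a[1]; new$arg2[j] <- a[2]; new$arg3[j] <- a[3]
  }
  # declare individuals
  for (j in seq_len(nrow(new))) {
    spec <- .pr_relations[[new$relation[j]]]
    a <- c(new$arg1[j], new$arg2[j], new$arg3[j])
    for (i in seq_len(spec$arity)) {
      role <- spec$roles[i]
      if (is.na(role) || !role %in% c("modality", "loctype"))
        kb <- .pr_declare_role(kb, a[i], role)
    }
  }
  existing <- .pr_kb_keys(kb)
  keep <- logical(nrow(new))
  seen <- character(0)
  for (j in seq_len(nrow(new))) {
    keys <- .pr_fact_keys_all(new$relation[j], new$arg1[j], new$arg2[j], new$arg3[j])
    if (!any(keys %in% existing) && !any(keys %in% seen)) {
      keep[j] <- TRUE
      seen <- c(seen, keys[1])
    }
  }
  added <- new[keep, , drop = FALSE]
  if (nrow(added)) {
    added$provenance <- provenance
    kb$facts <- rbind(kb$facts, added)
  }
  list(kb = kb, n = nrow(added))
}

#' Query facts by pattern
#'
#' Matches asserted and derived facts against a relation and an argument
#' pattern; `NA` entries are wildcards. Symmetric relations (`exp-to`,
#' `CONN`) match in both argument orders and `COMM3` matches commutatively
#' in its first two positions; matches are returned in the pattern's
#' orientation. Rows are ordered lexicographically by bound arguments so
#' downstream results are reproducible.
#'
#' @param kb A knowledge base.
#' @param relation Relation symbol (must be in the vocabulary).
#' @param args Optional character vector of the relation's arity with `NA`
#'   wildcards; `NULL` matches everything.
#' @return A data frame with columns `relation`, `arg1..arg3`, `provenance`.
#' @export
kb_query <- function(kb, relation, args = NULL) {
  .pr_check_kb(kb)
  spec <- .pr_relspec(relation)
  d <- kb$facts[kb$facts$relation == relation, , drop = FALSE]
  if (isTRUE(spec$symmetric) || isTRUE(spec$commutative12)) {
    flipped <- d
    flipped$arg1 <- d$arg2; flipped$arg2 <- d$arg1
    d <- unique(rbind(d, flipped))
  }
  if (!is.null(args)) {
    if (length(args) != spec$arity)
      pr_stop("ArityMismatch", "pattern for '%s' must have %d argument(s)",
              relation, spec$arity)
    pat <- rep(NA_character_, 3L)
    for (i in seq_along(args)) {
      if (is.na(args[i])) next
      role <- spec$roles[i]
      pat[i] <- if (!is.na(role) && role == "modality") {
        unname(.pr_modality_map[tolower(args[i])])
      } else if (!is.na(role) && role == "loctype") {
        unname(.pr_loctype_map[tolower(args[i])])
      } else args[i]
    }
    if (!is.na(pat[1])) d <- d[d$arg1 == pat[1], , drop = FALSE]
    if (!is.na(pat[2])) d <- d[!is.na(d$arg2) & d$arg2 == pat[2], , drop = FALSE]
    if (!is.na(pat[3])) d <- d[!is.na(d$arg3) & d$arg3 == pat[3], , drop = FALSE]
  }
  d[order(d$arg1, d$arg2, d$arg3, method = "radix"), , drop = FALSE]
}

#' @rdname kb_query
#' @export
kb_holds <- function(kb, relation, args) {
  nrow(kb_query(kb, relation, args)) > 0L
}

#' Number of facts in a knowledge base
#' @param kb A knowledge base.
#' @param provenance Optional filter: `"asserted"` keeps asserted facts only.
#' @export
n_facts <- function(kb, provenance = NULL) {
  .pr_check_kb(kb)
  if (is.null(provenance)) return(nrow(kb$facts))
  if (identical(provenance, "asserted"))
    return(sum(kb$facts$provenance == "asserted"))
  sum(startsWith(kb$facts$provenance, "derived"))
}

#' Validate knowledge-base invariants
#'
#' Re-checks that every fact uses a vocabulary relation with correct arity,
#' that every identifier appearing in a fact is declared, and that no fact
#' is stored twice (including flipped symmetric forms).
#'
#' @param kb A knowledge base.
#' @return `kb`, invisibly; raises a classed error on violation.
#' @export
validate_kb <- function(kb) {
  .pr_check_kb(kb)
  f <- kb$facts
  for (j in seq_len(nrow(f))) {
    spec <- .pr_relspec(f$relation[j])
    a <- c(f$arg1[j], f$arg2[j], f$arg3[j])
    if (sum(!is.na(a)) != spec$arity)
      pr_stop("ArityMismatch", "stored fact %s has wrong arity", f$relation[j])
    for (i in seq_len(spec$arity)) {
      role <- spec$roles[i]
      if (!is.na(role) && role == "modality") {
        if (!a[i] %in% c("adv", "dif", "cnv"))
          pr_stop("KindViolation", "bad modality token '%s'", a[i])
      } else if (!is.na(role) && role == "loctype") {
        if (!a[i] %in% c("Ltcyt", "Ltpm", "Ltec"))
          pr_stop("KindViolation", "bad location-type token '%s'", a[i])
      } else if (!a[i] %in% kb$individuals$id) {
        pr_stop("UndeclaredIndividual", "fact %s references undeclared individual '%s'",
                f$relation[j], a[i])
      }
    }
  }
  keys <- .pr_kb_keys(kb)
  if (anyDuplicated(keys))
    pr_stop("DuplicateFact", "duplicate fact: %s", keys[duplicated(keys)][1])
  sym <- f$relation %in% names(Filter(function(s) isTRUE(s$symmetric) || isTRUE(s$commutative12),
                                      .pr_relations))
  if (any(sym)) {
    flip <- .pr_fact_key(f$relation[sym], f$arg2[sym], f$arg1[sym], f$arg3[sym])
    straight <- f$arg1[sym] == f$arg2[sym]
    if (any(flip[!straight] %in% keys))
      pr_stop("DuplicateFact", "symmetric fact stored in both orders")
  }
  invisible(kb)
}

#' @export
print.physkb <- function(x, ...) {
  cat(sprintf("<physroute knowledge base: %d individuals, %d facts (%d asserted, %d derived)%s>\n",
              nrow(x$individuals), nrow(x$facts),
              sum(x$facts$provenance == "asserted"),
              sum(x$facts$provenance != "asserted"),
              if (x$saturated) ", saturated" else ""))
  invisible(x)
}

# ---- fact-file I/O ---------------------------------------------------------

#' Read a fact file into a knowledge base
#'
#' Two dialects are supported. TSV: one fact per line, tab-separated
#' (relation, then arguments), `#` comment lines, UTF-8; optional `!ind`
#' directive lines (`!ind <id> <kind> <subkind> <vessel> <label>`) carry
#' individual declarations so that compartment metadata round-trips. JSON:
#' either a bare array of `{"relation": ..., "args": [...]}` objects or an
#' object `{"individuals": [...], "facts": [...]}` as written by
#' [write_facts()].
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"json"`.
#' @return A knowledge base.
#' @export
load_facts <- function(path, dialect = c("tsv", "json")) {
  dialect <- match.arg(dialect)
  kb <- make_kb()
  if (dialect == "tsv") {
    lines <- readLines(path, encoding = "UTF-8")
    for (ln in seq_along(lines)) {
      line <- trimws(lines[ln])
      if (line == "" || startsWith(line, "#")) next
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      ok <- tryCatch({
        if (parts[1] == "!ind") {
          fld <- c(parts[-1], rep(NA, 5))[1:5]
          fld[fld %in% c("", ".")] <- NA
          kb <- kb_declare(kb, fld[1], kind = ifelse(is.na(fld[2]), "Other", fld[2]),
                           cvs_subkind = fld[3], vessel = fld[4], label = fld[5])
        } else {
          rel <- parts[1]
          spec <- .pr_relspec(rel)
          args <- parts[-1]
          prov <- "asserted"
          if (length(args) == spec$arity + 1L) {  # trailing provenance column
            prov <- args[length(args)]
            args <- args[-length(args)]
          }
          kb <- assert_fact(kb, rel, args, provenance = prov)
        }
        TRUE
      }, physroute_error = function(e) e)
      if (!isTRUE(ok))
        pr_stop("ParseError", "%s, line %d: %s", path, ln, conditionMessage(ok))
    }
  } else {
    obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    inds <- NULL
    fcts <- obj
    if (!is.null(names(obj))) {
      inds <- obj$individuals
      fcts <- obj$facts
    }
    for (ind in inds) {
      kb <- kb_declare(kb, ind$id, kind = ind$kind %||% "Other",
                       cvs_subkind = ind$cvs_subkind %||% NA_character_,
                       vessel = ind$vessel %||% NA_character_,
                       label = ind$label %||% NA_character_)
    }
    for (k in seq_along(fcts)) {
      fc <- fcts[[k]]
      ok <- tryCatch({
        kb <- assert_fact(kb, fc$relation, unlist(fc$args),
                          provenance = fc$provenance %||% "asserted")
        TRUE
      }, physroute_error = function(e) e)
      if (!isTRUE(ok))
        pr_stop("ParseError", "%s, fact %d: %s", path, k, conditionMessage(ok))
    }
  }
  kb
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a knowledge base to a fact file
#'
#' Facts are written in deterministic (sorted) order; loading the result
#' reproduces the same fact set. Derived facts are included only on request
#' and carry their provenance.
#'
#' @param kb A knowledge base.
#' @param path Output file path.
#' @param dialect `"tsv"` or `"json"`.
#' @param include_derived Also write derived facts (flagged with their rule
#'   provenance).
#' @return `path`, invisibly.
#' @export
write_facts <- function(kb, path, dialect = c("tsv", "json"),
                        include_derived = FALSE) {
  .pr_check_kb(kb)
  dialect <- match.arg(dialect)
  f <- kb$facts
  if (!include_derived) f <- f[f$provenance == "asserted", , drop = FALSE]
  f <- f[order(f$relation, f$arg1, f$arg2, f$arg3, method = "radix"), , drop = FALSE]
  ind <- kb$individuals
  ind <- ind[order(ind$id, method = "radix"), , drop = FALSE]
  if (dialect == "tsv") {
    enc <- function(x) ifelse(is.na(x), ".", x)
    lines <- c(
      "# physroute fact file (TSV dialect)",
      sprintf("!ind\t%s\t%s\t%s\t%s\t%s", ind$id, enc(ind$kind),
              enc(ind$cvs_subkind), enc(ind$vessel), enc(ind$label)),
      vapply(seq_len(nrow(f)), function(j) {
        a <- c(f$arg1[j], f$arg2[j], f$arg3[j])
        a <- a[!is.na(a)]
        prov <- if (f$provenance[j] == "asserted") character(0) else f$provenance[j]
        paste(c(f$relation[j], a, prov), collapse = "\t")
      }, character(1))
    )
    writeLines(lines, path, useBytes = TRUE)
  } else {
    fl <- lapply(seq_len(nrow(f)), function(j) {
      a <- c(f$arg1[j], f$arg2[j], f$arg3[j])
      list(relation = f$relation[j], args = as.list(a[!is.na(a)]),
           provenance = f$provenance[j])
    })
    il <- lapply(seq_len(nrow(ind)), function(j) {
      x <- as.list(ind[j, ])
      x[!vapply(x, is.na, logical(1))]
    })
    jsonlite::write_json(list(individuals = il, facts = fl), path,
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  invisible(path)
}

#' Compartment kinds for a set of identifiers
#'
#' Kind lookup used by footprint computation on KB-driven routes; generated
#' boundary-space identifiers (prefix `BND`) are recognised even when not
#' declared as individuals.
#'
#' @param kb A knowledge base.
#' @param ids Character vector of identifiers.
#' @return Named character vector of kinds.
#' @export
kb_kinds <- function(kb, ids) {
  k <- kb$individuals$kind[match(ids, kb$individuals$id)]
  k[is.na(k) & startsWith(ids, "BND")] <- "BoundarySpace"
  names(k) <- ids
  k
}
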