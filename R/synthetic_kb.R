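# Deterministic generator of toy human-circulation knowledge bases, the
# hormone/receptor demonstration facts, and the packaged reference-route
# fixture.

#' Parameters for the synthetic circulation generator
#'
#' Defaults describe the study conditions of the packaged demonstration: a
#' 44-segment aorta run ending at the left-kidney branch, a right kidney and
#' a gut branch upstream, a pulmonary macro-region, and the heart wall as a
#' vascularised organ drained directly into the right atrium by a cardiac
#' vein. Topology is a pure function of the parameters; `seed` is retained
#' for interface stability but no part of generation is random.
#'
#' @param n_aorta_segments Number of aorta segments (positive integer).
#' @param organs Named list; each entry a list with `branch` (aorta segment
#'   the organ's artery leaves from), `n_arterioles` and `n_venules`
#'   (segment counts of the organ's arteriolar and venular chains).
#' @param include_pulmonary Include the pulmonary macro-region (otherwise
#'   the right ventricle connects directly to the left heart).
#' @param seed Integer, recorded only.
#' @return A `body_params` object.
#' @export
body_params <- function(n_aorta_segments = 44,
                        organs = list(
                          kidney_L = list(branch = 44, n_arterioles = 1, n_venules = 1),
                          kidney_R = list(branch = 42, n_arterioles = 1, n_venules = 1),
                          gut      = list(branch = 20, n_arterioles = 1, n_venules = 1)),
                        include_pulmonary = TRUE,
                        seed = 1L) {
  if (!is.numeric(n_aorta_segments) || n_aorta_segments < 1 ||
      n_aorta_segments != round(n_aorta_segments))
    pr_stop("InvalidParams", "n_aorta_segments must be a positive integer")
  if (!is.list(organs) || length(organs) == 0L || is.null(names(organs)) ||
      any(names(organs) == ""))
    pr_stop("InvalidParams", "organs must be a non-empty named list")
  for (nm in names(organs)) {
    o <- organs[[nm]]
    o$n_arterioles <- o$n_arterioles %||% 1
    o$n_venules <- o$n_venules %||% 1
    if (is.null(o$branch) || o$branch < 1 || o$branch > n_aorta_segments)
      pr_stop("InvalidParams", "organ '%s': branch position outside the aorta", nm)
    if (o$n_arterioles < 1 || o$n_venules < 1)
      pr_stop("InvalidParams", "organ '%s': segment counts must be >= 1", nm)
    if (grepl("[^A-Za-z0-9_]", nm))
      pr_stop("InvalidParams", "organ name '%s' must be alphanumeric", nm)
    organs[[nm]] <- o
  }
  structure(list(n_aorta_segments = as.integer(n_aorta_segments),
                 organs = organs,
                 include_pulmonary = isTRUE(include_pulmonary),
                 seed = as.integer(seed)),
            class = "body_params")
}

#' Generate a synthetic circulation knowledge base
#'
#' Builds a closed-circuit toy human circulation: a three-segment right
#' atrium, the right ventricle, pulmonary and left-heart macro-regions
#' (each with a small unfoldable member subgraph), the aorta chain, and per
#' organ an artery, arteriolar chain, capillary bed, venular chain and vein
#' returning to the right atrium via the vena cava. The heart wall is itself
#' a vascularised organ whose venules drain through a cardiac-vein chain
#' directly into the right atrium. Every tissue and every non-capillary
#' vessel carries a tissue-fluid compartment; every CVS portion an
#' endothelium tissue structure; every portion except capillaries and
#' cardiac chambers a smooth-muscle tissue structure; every tissue structure
#' the plasma membrane of its cells. Output is deterministic for fixed
#' parameters.
#'
#' @param params A [body_params()] object.
#' @return A validated, unsaturated knowledge base.
#' @export
generate_body_kb <- function(params = body_params()) {
  if (!inherits(params, "body_params"))
    pr_stop("InvalidParams", "params must be created with body_params()")
  n <- params$n_aorta_segments
  organs <- params$organs
  # the aorta must terminate in an organ branch to close the circuit
  if (!any(vapply(organs, function(o) o$branch == n, logical(1))))
    organs$distal_body <- list(branch = n, n_arterioles = 1, n_venules = 1)

  inds <- list()
  facts <- list()
  dec <- function(id, kind, subkind = NA_character_, vessel = NA_character_) {
    inds[[length(inds) + 1L]] <<- data.frame(
      id = id, kind = kind, cvs_subkind = subkind, label = id, vessel = vessel,
      stringsAsFactors = FALSE)
  }
  fact <- function(relation, a1, a2 = NA_character_, a3 = NA_character_) {
    facts[[length(facts) + 1L]] <<- data.frame(
      relation = relation, arg1 = a1, arg2 = a2, arg3 = a3,
      stringsAsFactors = FALSE)
  }
  portion <- function(id, subkind, vessel = NA_character_) {
    dec(id, "CVSPortion", subkind, vessel)
    fact("cvs", id)
  }
  conn <- function(a, b) fact("CONN", a, b)

  # heart chambers
  ra <- sprintf("RA-%d", 1:3)
  for (p in ra) portion(p, "chamber", "right_atrium")
  portion("RV", "chamber")
  conn(ra[1], ra[2]); conn(ra[2], ra[3]); conn(ra[3], "RV")

  # pulmonary circulation and left heart as macro-regions with parallel
  # member chains between the same boundaries
  portion("LH", "macro_region")
  portion("LA", "chamber", "LH")
  portion("LV", "chamber", "LH")
  conn("LA", "LV")
  if (params$include_pulmonary) {
    portion("PC", "macro_region")
    portion("PA-1", "vessel_segment", "PC")
    portion("CAP-lungs", "capillary", "PC")
    portion("PV-1", "vessel_segment", "PC")
    conn("RV", "PC"); conn("RV", "PA-1")
    conn("PA-1", "CAP-lungs"); conn("CAP-lungs", "PV-1")
    conn("PV-1", "LA"); conn("PC", "LA"); conn("PC", "LH")
  } else {
    conn("RV", "LA"); conn("RV", "LH")
  }
  ao <- sprintf("AO-%d", seq_len(n))
  for (p in ao) portion(p, "vessel_segment", "aorta")
  conn("LV", ao[1]); conn("LH", ao[1])
  for (i in seq_len(n - 1L)) conn(ao[i], ao[i + 1L])

  # vena cava and cardiac vein return paths
  vc <- c("VC-1", "VC-2")
  for (p in vc) portion(p, "vessel_segment", "vena_cava")
  conn(vc[1], vc[2]); conn(vc[2], ra[1])
  cv <- c("CV-1", "CV-2")
  for (p in cv) portion(p, "vessel_segment", "cardiac_vein")
  conn(cv[1], cv[2]); conn(cv[2], ra[1])

  organ_tissue <- function(name) {
    # tissue, tissue structure, tissue fluid, capillary bed, plasma membrane
    dec(name, "Tissue")
    cap <- paste0("CAP-", name)
    fact("ts-of", paste0("TS-", name), name)
    fact("tf-of", paste0("TF-", name), name)
    fact("cap-of", cap, name)
    fact("pm-of", paste0("PM-TS-", name), paste0("TS-", name))
    cap
  }

  # heart wall: supplied from the aortic root, drained by the cardiac vein
  heart_cap <- organ_tissue("heart_wall")
  dec(heart_cap, "CVSPortion", "capillary")
  portion("ART-heart_wall-1", "vessel_segment", "artery_heart_wall")
  portion("ARTL-heart_wall-1", "arteriole", "arterioles_heart_wall")
  portion("VNL-heart_wall-1", "venule", "venules_heart_wall")
  conn(ao[1], "ART-heart_wall-1")
  conn("ART-heart_wall-1", "ARTL-heart_wall-1")
  conn("ARTL-heart_wall-1", heart_cap)
  conn(heart_cap, "VNL-heart_wall-1")
  conn("VNL-heart_wall-1", cv[1])

  for (nm in names(organs)) {
    o <- organs[[nm]]
    cap <- organ_tissue(nm)
    dec(cap, "CVSPortion", "capillary")
    art <- sprintf("ART-%s-1", nm)
    portion(art, "vessel_segment", paste0("artery_", nm))
    conn(ao[o$branch], art)
    artl <- sprintf("ARTL-%s-%d", nm, seq_len(o$n_arterioles))
    for (p in artl) portion(p, "arteriole", paste0("arterioles_", nm))
    conn(art, artl[1])
    for (i in seq_len(o$n_arterioles - 1L)) conn(artl[i], artl[i + 1L])
    conn(artl[length(artl)], cap)
    vnl <- sprintf("VNL-%s-%d", nm, seq_len(o$n_venules))
    for (p in vnl) portion(p, "venule", paste0("venules_", nm))
    conn(cap, vnl[1])
    for (i in seq_len(o$n_venules - 1L)) conn(vnl[i], vnl[i + 1L])
    vein <- sprintf("VEIN-%s-1", nm)
    portion(vein, "vessel_segment", paste0("vein_", nm))
    conn(vnl[length(vnl)], vein)
    conn(vein, vc[1])
  }

  ind_df <- do.call(rbind, inds)
  # endothelium for all CVS portions; smooth muscle for vessel-like portions
  # (not capillaries, not cardiac chambers, not macro-regions); tissue fluid
  # for every non-capillary vessel; plasma membranes of each structure
  is_portion <- ind_df$kind == "CVSPortion"
  for (j in which(is_portion)) {
    p <- ind_df$id[j]
    sk <- ind_df$cvs_subkind[j]
    fact("ts-of", paste0("EN-", p), p)
    fact("pm-of", paste0("PM-EN-", p), paste0("EN-", p))
    if (sk %in% c("vessel_segment", "arteriole", "venule")) {
      fact("ts-of", paste0("SM-", p), p)
      fact("pm-of", paste0("PM-SM-", p), paste0("SM-", p))
      fact("tf-of", paste0("TF-", p), p)
    }
  }

  kb <- make_kb()
  kb$individuals <- unique(do.call(rbind, inds))
  r <- .pr_assert_df(kb, unique(do.call(rbind, facts)), "asserted")
  kb <- r$kb
  kb$saturated <- FALSE
  validate_kb(kb)
  kb
}

#' Attach the demonstration hormone/receptor facts
#'
#' Asserts a secreted natriuretic-peptide-like hormone (`anp`): a product of
#' the atrial heart-wall tissue structure, secreted extracellularly, capable
#' of advection, diffusion and convection; and its membrane-bound receptor
#' (`anpr`): a plasma-membrane product of the smooth muscle of the first
#' left-kidney arteriole segment.
#'
#' @param kb A knowledge base produced by [generate_body_kb()] (must
#'   contain the heart-wall tissue fluid and left-kidney arteriolar smooth
#'   muscle).
#' @return The updated knowledge base.
#' @export
attach_case_study_proteins <- function(kb) {
  .pr_check_kb(kb)
  need <- c("TF-heart_wall", "TS-heart_wall", "SM-ARTL-kidney_L-1")
  missing <- setdiff(need, c(kb$individuals$id,
                             kb$facts$arg1[kb$facts$relation %in% c("tf-of", "ts-of")]))
  if (length(missing))
    pr_stop("MissingAnatomy", "knowledge base lacks required anatomy: %s",
            paste(missing, collapse = ", "))
  kb <- assert_fact(kb, "Protein", "anp")
  kb <- assert_fact(kb, "prod-by", c("anp", "TS-heart_wall"))
  kb <- assert_fact(kb, "postp_t", c("anp", "Ltec"))
  kb <- assert_fact(kb, "CMTP_t", c("anp", "adv"))
  kb <- assert_fact(kb, "CMTP_t", c("anp", "dif"))
  kb <- assert_fact(kb, "CMTP_t", c("anp", "cnv"))
  kb <- assert_fact(kb, "Protein", "anpr")
  kb <- assert_fact(kb, "prod-by", c("anpr", "SM-ARTL-kidney_L-1"))
  kb <- assert_fact(kb, "postp_t", c("anpr", "Ltpm"))
  kb
}

#' Load the packaged reference-route fixture
#'
#' The packaged transcription of the published demonstration route: the raw
#' 60-compartment sequence from the right-atrium tissue fluid to the
#' left-kidney tissue fluid, the 14-group vessel-membership map used to
#' condense it (with a finer sub-vessel map distinguishing the right-atrium
#' chamber run from the right ventricle inside the heart group), the
#' compartment kinds, and the printed 5-step modality footprint.
#'
#' @return A list: `raw_path` (character, length 60), `membership` (named
#'   character vector, id to group label), `submembership` (named character
#'   vector refining the heart group), `kinds` (named character vector, id
#'   to compartment kind), `footprint` (data frame `modality`, `from`,
#'   `to`).
#' @export
load_reference_fixture <- function() {
  dir <- system.file("extdata", package = "physroute", mustWork = TRUE)
  raw <- readLines(file.path(dir, "anp-route-raw.txt"), encoding = "UTF-8")
  raw <- trimws(raw)
  raw <- raw[raw != "" & !startsWith(raw, "#")]
  mem <- utils::read.delim(file.path(dir, "anp-route-membership.tsv"),
                           comment.char = "#", stringsAsFactors = FALSE)
  membership <- character(0)
  submembership <- character(0)
  for (j in seq_len(nrow(mem))) {
    span <- mem$span[j]
    ids <- if (grepl("..", span, fixed = TRUE)) {
      ends <- strsplit(span, "..", fixed = TRUE)[[1]]
      i1 <- match(ends[1], raw); i2 <- match(ends[2], raw)
      if (is.na(i1) || is.na(i2))
        pr_stop("ParseError", "membership span '%s' not found in the raw path", span)
      raw[i1:i2]
    } else span
    membership[ids] <- mem$label[j]
    sub <- mem$sublabel[j]
    submembership[ids] <- if (is.na(sub) || sub == "") mem$label[j] else sub
  }
  kinds <- ifelse(startsWith(raw, "TF-"), "TissueFluid",
                  ifelse(startsWith(raw, "BND-"), "BoundarySpace", "CVSPortion"))
  names(kinds) <- raw
  fp <- utils::read.delim(file.path(dir, "anp-route-footprint.tsv"),
                          comment.char = "#", stringsAsFactors = FALSE)
  list(raw_path = raw, membership = membership, submembership = submembership,
       kinds = kinds, footprint = fp)
}
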