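# Shared fixtures built in code.

# Memoised default synthetic body (saturated, with the demonstration
# proteins attached): several files exercise it and generation is the
# slowest step.
.kb_cache <- new.env(parent = emptyenv())

default_body_kb <- function() {
  if (is.null(.kb_cache$body)) {
    kb <- attach_case_study_proteins(generate_body_kb())
    .kb_cache$body <- saturate(kb)
  }
  .kb_cache$body
}

# One-organ toy: a tissue with structure, fluid, capillary bed and plasma
# membranes, plus a short vascular loop through it.
toy_organ_kb <- function(organ = "organ") {
  kb <- make_kb()
  kb <- assert_fact(kb, "ts-of", c(paste0("TS-", organ), organ))
  kb <- assert_fact(kb, "tf-of", c(paste0("TF-", organ), organ))
  kb <- assert_fact(kb, "cap-of", c(paste0("CAP-", organ), organ))
  kb <- assert_fact(kb, "pm-of", c(paste0("PM-TS-", organ), paste0("TS-", organ)))
  kb
}

# Small random knowledge base exercising the location/exposure/communication
# rules: a few organs, a vascular chain threading their capillaries, and
# proteins with random producers, location types and capabilities.
random_rule_kb <- function(seed) {
  set.seed(seed)
  kb <- make_kb()
  n_org <- sample(1:3, 1)
  orgs <- paste0("org", seq_len(n_org))
  for (t in orgs) {
    kb <- assert_fact(kb, "ts-of", c(paste0("TS-", t), t))
    if (runif(1) < 0.9) kb <- assert_fact(kb, "tf-of", c(paste0("TF-", t), t))
    if (runif(1) < 0.7) {
      kb <- assert_fact(kb, "cap-of", c(paste0("CAP-", t), t))
      kb <- kb_declare(kb, paste0("CAP-", t), "CVSPortion", cvs_subkind = "capillary")
    }
    if (runif(1) < 0.8)
      kb <- assert_fact(kb, "pm-of", c(paste0("PM-TS-", t), paste0("TS-", t)))
  }
  n_v <- sample(2:5, 1)
  vs <- paste0("V", seq_len(n_v))
  for (i in seq_along(vs)) {
    kb <- assert_fact(kb, "cvs", vs[i])
    kb <- kb_declare(kb, vs[i], "CVSPortion", cvs_subkind = "vessel_segment")
    if (runif(1) < 0.5) kb <- assert_fact(kb, "tf-of", c(paste0("TF-", vs[i]), vs[i]))
    if (i > 1) kb <- assert_fact(kb, "CONN", c(vs[i - 1], vs[i]))
  }
  for (t in orgs) {
    cap <- paste0("CAP-", t)
    if (cap %in% kb$individuals$id && runif(1) < 0.8) {
      kb <- assert_fact(kb, "CONN", c(vs[sample(n_v, 1)], cap))
      kb <- assert_fact(kb, "CONN", c(cap, vs[sample(n_v, 1)]))
    }
  }
  n_p <- sample(1:3, 1)
  for (p in paste0("prot", seq_len(n_p))) {
    kb <- assert_fact(kb, "Protein", p)
    kb <- assert_fact(kb, "prod-by", c(p, paste0("TS-", sample(orgs, 1))))
    kb <- assert_fact(kb, "postp_t", c(p, sample(c("Ltec", "Ltpm", "Ltcyt"), 1)))
    for (m in sample(c("adv", "dif", "cnv"), sample(0:3, 1)))
      kb <- assert_fact(kb, "CMTP_t", c(p, m))
  }
  if (runif(1) < 0.3) {
    kb <- assert_fact(kb, "occurs-in", c("proc1", orgs[1]))
    kb <- assert_fact(kb, "participates-in", c("prot1", "proc1"))
  }
  kb
}

# Random body-generator parameters; always includes the left kidney so the
# demonstration proteins can be attached.
random_params <- function(seed) {
  set.seed(seed)
  n <- sample(2:8, 1)
  organs <- list(kidney_L = list(branch = sample(n, 1),
                                 n_arterioles = sample(1:2, 1),
                                 n_venules = sample(1:2, 1)))
  for (k in seq_len(sample(0:2, 1)))
    organs[[paste0("organ", k)]] <- list(branch = sample(n, 1),
                                         n_arterioles = sample(1:2, 1),
                                         n_venules = sample(1:2, 1))
  body_params(n, organs, include_pulmonary = runif(1) < 0.7, seed = seed)
}
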