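test_that("a secreted product is placed in its producer tissue's fluid", {
  kb <- make_kb()
  kb <- assert_fact(kb, "prod-by", c("h", "myoTS"))
  kb <- assert_fact(kb, "postp_t", c("h", "Ltec"))
  kb <- assert_fact(kb, "ts-of", c("myoTS", "atrium"))
  kb <- assert_fact(kb, "tf-of", c("TF_a", "atrium"))
  kb <- derive_location_exposure(kb)
  expect_true(kb_holds(kb, "fnd-in-postp", c("h", "TF_a")))
  expect_true(kb_holds(kb, "fnd-in", c("h", "TF_a")))
  expect_true(kb_holds(kb, "exp-to", c("h", "TF_a")))
})

test_that("a membrane product is attached to its producer's plasma membrane", {
  kb <- make_kb()
  kb <- assert_fact(kb, "prod-by", c("r", "smcTS"))
  kb <- assert_fact(kb, "postp_t", c("r", "Ltpm"))
  kb <- assert_fact(kb, "pm-of", c("PM_s", "smcTS"))
  kb <- derive_location_exposure(kb)
  expect_true(kb_holds(kb, "fnd-in-postp", c("r", "PM_s")))
  expect_true(kb_holds(kb, "att-to", c("r", "PM_s")))
})

test_that("saturating an empty knowledge base derives nothing and is idempotent", {
  kb <- saturate(make_kb())
  expect_equal(n_facts(kb), 0L)
  kb2 <- random_rule_kb(11)
  s1 <- saturate(kb2)
  s2 <- saturate(derive_communication(derive_location_exposure(s1)))
  expect_setequal(kb_fact_keys(s1), kb_fact_keys(s2))
})

test_that("exposure is symmetric but never closed transitively", {
  kb <- make_kb()
  # one structure shared by two tissues, each with its own fluid
  kb <- assert_fact(kb, "ts-of", c("TSx", "tissueA"))
  kb <- assert_fact(kb, "ts-of", c("TSx", "tissueB"))
  kb <- assert_fact(kb, "tf-of", c("TF_A", "tissueA"))
  kb <- assert_fact(kb, "tf-of", c("TF_B", "tissueB"))
  kb <- saturate(kb)
  expect_true(kb_holds(kb, "exp-to", c("TF_A", "TSx")))
  expect_true(kb_holds(kb, "exp-to", c("TSx", "TF_A")))  # symmetric match
  expect_true(kb_holds(kb, "exp-to", c("TF_B", "TSx")))
  # transitivity would link the two fluids through the shared structure
  expect_false(kb_holds(kb, "exp-to", c("TF_A", "TF_B")))
})

test_that("saturation matches the naive fixpoint oracle on random knowledge bases", {
  for (seed in 1:15) {
    kb <- random_rule_kb(seed)
    expect_lte(nrow(kb$individuals), 30L)
    got <- kb_fact_keys(saturate(kb))
    want <- naive_saturated_keys(kb)
    expect_identical(got, want, label = sprintf("seed %d impl", seed),
                     expected.label = sprintf("seed %d oracle", seed))
  }
})

test_that("organ fluids exchange with capillaries, vessels with their own fluid, capillaries excepted", {
  kb <- toy_organ_kb("kidney")
  kb <- assert_fact(kb, "cvs", "A")
  kb <- kb_declare(kb, "A", "CVSPortion", cvs_subkind = "arteriole")
  kb <- assert_fact(kb, "tf-of", c("TF_A", "A"))
  kb <- kb_declare(kb, "CAP-kidney", "CVSPortion", cvs_subkind = "capillary")
  kb <- assert_fact(kb, "tf-of", c("TF_C", "CAP-kidney"))  # declared but inert
  kb <- saturate(kb)
  expect_true(kb_holds(kb, "COMM3", c("TF-kidney", "CAP-kidney", "cnv")))
  expect_true(kb_holds(kb, "COMM3", c("A", "TF_A", "cnv")))
  expect_false(kb_holds(kb, "COMM3", c("CAP-kidney", "TF_C", "cnv")))
})

test_that("a protein without capabilities can access nothing", {
  kb <- toy_organ_kb()
  kb <- assert_fact(kb, "Protein", "p")
  kb <- assert_fact(kb, "fnd-in", c("p", "TF-organ"))
  expect_identical(accessible_set(kb, "p"), character(0))
  expect_error(accessible_set(kb, "nowhere-protein"),
               class = "physroute_NoStartSite")
})

test_that("accessibility equals undirected reachability over capability-filtered edges", {
  for (seed in 1:40) {
    set.seed(seed)
    kb <- make_kb()
    n <- sample(4:12, 1)
    nodes <- paste0("c", seq_len(n))
    m <- sample(3:(2L * n), 1)
    for (j in seq_len(m)) {
      ab <- sample(nodes, 2)
      kb <- assert_fact(kb, "COMM3", c(ab[1], ab[2], sample(c("adv", "dif", "cnv"), 1)))
    }
    start <- sample(nodes, 1)
    kb <- assert_fact(kb, "Protein", "p")
    kb <- assert_fact(kb, "fnd-in", c("p", start))
    caps <- sample(c("adv", "dif", "cnv"), sample(0:3, 1))
    for (cp in caps) kb <- assert_fact(kb, "CMTP_t", c("p", cp))
    kb <- saturate(kb)
    expect_identical(accessible_set(kb, "p"),
                     bfs_reachable_oracle(kb, start, caps),
                     label = sprintf("seed %d", seed))
  }
})

test_that("accessibility is monotone in capabilities", {
  for (seed in 41:50) {
    set.seed(seed)
    kb <- make_kb()
    nodes <- paste0("c", 1:8)
    for (j in 1:10) {
      ab <- sample(nodes, 2)
      kb <- assert_fact(kb, "COMM3", c(ab[1], ab[2], sample(c("adv", "dif", "cnv"), 1)))
    }
    kb <- assert_fact(kb, "fnd-in", c("p", nodes[1]))
    kb1 <- assert_fact(kb, "CMTP_t", c("p", "dif"))
    kb2 <- assert_fact(kb1, "CMTP_t", c("p", "adv"))
    kb3 <- assert_fact(kb2, "CMTP_t", c("p", "cnv"))
    a1 <- accessible_set(kb1, "p"); a2 <- accessible_set(kb2, "p")
    a3 <- accessible_set(kb3, "p")
    expect_true(all(a1 %in% a2))
    expect_true(all(a2 %in% a3))
  }
})

test_that("materialised accessibility adds acc and fnd-in facts only for reachable sites", {
  kb <- toy_organ_kb()
  kb <- assert_fact(kb, "cvs", "V1")
  kb <- assert_fact(kb, "CONN", c("CAP-organ", "V1"))
  kb <- assert_fact(kb, "prod-by", c("p", "TS-organ"))
  kb <- assert_fact(kb, "postp_t", c("p", "Ltec"))
  kb <- assert_fact(kb, "CMTP_t", c("p", "cnv"))
  kb <- derive_accessibility(kb, "p")
  # convection reaches the capillaries; advection into V1 is beyond p's powers
  expect_true(kb_holds(kb, "acc", c("p", "CAP-organ")))
  expect_true(kb_holds(kb, "fnd-in", c("p", "CAP-organ")))
  expect_false(kb_holds(kb, "acc", c("p", "V1")))
})

test_that("two secreted proteins sharing a fluid can interact there", {
  kb <- toy_organ_kb()
  for (p in c("p1", "p2")) {
    kb <- assert_fact(kb, "prod-by", c(p, "TS-organ"))
    kb <- assert_fact(kb, "postp_t", c(p, "Ltec"))
  }
  v <- can_interact_via_some_route(kb, "p1", "p2")
  expect_true(v$interacts)
  expect_equal(v$witness, "TF-organ")
})

test_that("an immobile mover far from its fixed partner cannot interact", {
  kb <- toy_organ_kb("near")
  kb2 <- toy_organ_kb("far")
  kb$individuals <- unique(rbind(kb$individuals, kb2$individuals))
  kb$facts <- unique(rbind(kb$facts, kb2$facts))
  kb <- assert_fact(kb, "prod-by", c("lig", "TS-near"))
  kb <- assert_fact(kb, "postp_t", c("lig", "Ltec"))  # no capabilities at all
  kb <- assert_fact(kb, "prod-by", c("rec", "TS-far"))
  kb <- assert_fact(kb, "postp_t", c("rec", "Ltpm"))
  v <- can_interact_via_some_route(kb, "lig", "rec")
  expect_false(v$interacts)
})

test_that("the subtending translocation runs from the secretion fluid to the receptor's fluid", {
  kb <- default_body_kb()
  sp <- subtending_translocation(kb, "anp", "anpr")
  expect_equal(sp$object, "anp")
  expect_equal(sp$from_loc, "TF-heart_wall")
  expect_equal(sp$to_loc, "TF-ARTL-kidney_L-1")
  expect_equal(sp$id, "transloc::int::anp::anpr")
  # argument order does not matter; the skolem name is role-determined
  sp2 <- subtending_translocation(kb, "anpr", "anp")
  expect_identical(sp2$id, sp$id)
  expect_identical(sp2$to_loc, sp$to_loc)
  # cross-check against an exhaustive scan of the exposure facts
  pm <- kb_query(kb, "fnd-in-postp", c("anpr", NA))$arg2
  exposed <- kb_query(kb, "exp-to", c(pm, NA))$arg2
  fluids <- kb$individuals$id[kb$individuals$kind == "TissueFluid"]
  expect_identical(sort(intersect(exposed, fluids)), sp$to_loc)
})

test_that("no translocation subtends a pair of secreted proteins", {
  kb <- toy_organ_kb()
  for (p in c("p1", "p2")) {
    kb <- assert_fact(kb, "prod-by", c(p, "TS-organ"))
    kb <- assert_fact(kb, "postp_t", c(p, "Ltec"))
  }
  expect_null(subtending_translocation(kb, "p1", "p2"))
})

test_that("a receptor structure bathed by two fluids is reported as ambiguous", {
  kb <- toy_organ_kb("site")
  kb <- assert_fact(kb, "ts-of", c("SMx", "t1"))
  kb <- assert_fact(kb, "ts-of", c("SMx", "t2"))
  kb <- assert_fact(kb, "tf-of", c("TF1", "t1"))
  kb <- assert_fact(kb, "tf-of", c("TF2", "t2"))
  kb <- assert_fact(kb, "pm-of", c("PMx", "SMx"))
  kb <- assert_fact(kb, "prod-by", c("rec", "SMx"))
  kb <- assert_fact(kb, "postp_t", c("rec", "Ltpm"))
  kb <- assert_fact(kb, "prod-by", c("lig", "TS-site"))
  kb <- assert_fact(kb, "postp_t", c("lig", "Ltec"))
  expect_error(subtending_translocation(kb, "lig", "rec"),
               class = "physroute_AmbiguousTarget")
})
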