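chain_kb <- function(n, prefix = "S") {
  kb <- make_kb()
  ids <- sprintf("%s%d", prefix, seq_len(n))
  for (p in ids) kb <- assert_fact(kb, "cvs", p)
  for (i in seq_len(n - 1L)) kb <- assert_fact(kb, "CONN", c(ids[i], ids[i + 1L]))
  list(kb = kb, ids = ids)
}

test_that("a linear chain of portions yields one edge per portion and n+1 nodes", {
  ch <- chain_kb(5)
  g <- build_cvs_graph(ch$kb)
  expect_equal(nrow(g$edges), 5L)
  expect_equal(length(g$nodes), 6L)
  expect_setequal(g$edges$id, ch$ids)
})

test_that("the edge multiset of the graph equals the knowledge base's portion set", {
  for (seed in c(3, 9, 27)) {
    kb <- generate_body_kb(random_params(seed))
    g <- build_cvs_graph(kb)
    portions <- kb$individuals$id[kb$individuals$kind == "CVSPortion"]
    expect_setequal(g$edges$id, portions)
    expect_equal(nrow(g$edges), length(portions))  # exactly one edge each
  }
})

test_that("the synthetic body is one strongly connected closed circuit", {
  g <- build_cvs_graph(default_body_kb())
  expect_true(cvs_is_closed_circuit(g))
})

test_that("connections into undeclared portions are rejected", {
  kb <- make_kb()
  kb <- assert_fact(kb, "cvs", "V1")
  kb <- assert_fact(kb, "CONN", c("V1", "mystery"))
  expect_error(build_cvs_graph(kb), class = "physroute_DanglingConnection")
})

test_that("the exchange graph has one boundary edge per convective link and none at chambers", {
  kb <- saturate(toy_organ_kb("kidney"))
  tg <- build_tf_graph(kb)
  expect_equal(nrow(tg$edges), 1L)
  expect_equal(tg$edges$boundary, "BND::CAP-kidney::TF-kidney")

  body <- default_body_kb()
  tgb <- build_tf_graph(body)
  expect_true(any(tgb$edges$from == "TF-heart_wall" & tgb$edges$to == "CAP-heart_wall" |
                    tgb$edges$to == "TF-heart_wall" & tgb$edges$from == "CAP-heart_wall"))
  # atrial chamber segments have no tissue-fluid connection
  expect_false(any(grepl("^RA-", tgb$nodes)))
  expect_false(any(grepl("^RV$", tgb$nodes)))
})

test_that("vascular entry and exit points are the nearest exchanging portions", {
  body <- default_body_kb()
  expect_equal(find_cvs_entry(body, "TF-heart_wall"), "CAP-heart_wall")
  # a vessel's own tissue fluid enters/exits through that vessel itself
  expect_equal(find_cvs_exit(body, "TF-ARTL-kidney_L-1"), "ARTL-kidney_L-1")
  expect_error(find_cvs_entry(body, "RA-1"), class = "physroute_KindViolation")

  # equidistant capillary beds: lexicographic tie-break
  kb <- make_kb()
  kb <- assert_fact(kb, "tf-of", c("TF-o", "o"))
  kb <- assert_fact(kb, "cap-of", c("capB", "o"))
  kb <- assert_fact(kb, "cap-of", c("capA", "o"))
  expect_equal(find_cvs_entry(kb, "TF-o"), "capA")

  kb2 <- make_kb()
  kb2 <- assert_fact(kb2, "tf-of", c("TF-x", "x"))
  expect_error(find_cvs_entry(kb2, "TF-x"), class = "physroute_NoEntryPoint")
})

test_that("the whole chain is the shortest route from its first to its last portion", {
  ch <- chain_kb(6)
  g <- build_cvs_graph(ch$kb)
  expect_equal(shortest_cvs_route(g, "S1", "S6"), ch$ids)
  expect_equal(shortest_cvs_route(g, "S3", "S3"), "S3")
  expect_equal(shortest_cvs_route(g, "S3", "S4"), c("S3", "S4"))
  expect_error(shortest_cvs_route(g, "S4", "S2"), class = "physroute_NoPath")
  expect_error(shortest_cvs_route(g, "S1", "S99"), class = "physroute_UnknownEdge")
})

test_that("the shorter of two parallel branches is chosen, and weights can override", {
  kb <- make_kb()
  for (p in c("in", "out", "a1", "a2", "a3", "b1", "b2", "b3", "b4", "b5"))
    kb <- assert_fact(kb, "cvs", p)
  for (e in list(c("in", "a1"), c("a1", "a2"), c("a2", "a3"), c("a3", "out"),
                 c("in", "b1"), c("b1", "b2"), c("b2", "b3"), c("b3", "b4"),
                 c("b4", "b5"), c("b5", "out")))
    kb <- assert_fact(kb, "CONN", e)
  g <- build_cvs_graph(kb)
  expect_equal(shortest_cvs_route(g, "in", "out"),
               c("in", "a1", "a2", "a3", "out"))
  # making the short branch expensive diverts the route
  w <- c(a1 = 10, a2 = 10, a3 = 10)
  expect_equal(shortest_cvs_route(g, "in", "out", weights = w),
               c("in", "b1", "b2", "b3", "b4", "b5", "out"))
})

test_that("equal-length parallel edges are broken lexicographically by edge id", {
  edges <- data.frame(
    id = c("mB", "mA", "zz"),
    from = c("n1", "n1", "n2"),
    to = c("n2", "n2", "n3"),
    weight = 1, vessel = NA_character_, stringsAsFactors = FALSE)
  g <- structure(list(edges = edges, nodes = c("n1", "n2", "n3")), class = "cvs_graph")
  # two identical parallel middle edges: mA wins over mB
  edges2 <- rbind(edges, data.frame(id = c("s", "t"), from = c("n0", "n3"),
                                    to = c("n1", "n4"), weight = 1,
                                    vessel = NA_character_))
  g2 <- structure(list(edges = edges2, nodes = paste0("n", 0:4)), class = "cvs_graph")
  expect_equal(shortest_cvs_route(g2, "s", "t"), c("s", "mA", "zz", "t"))
})

test_that("the deterministic search agrees with exhaustive enumeration on small multigraphs", {
  checked <- 0L
  for (seed in 1:40) {
    g <- random_multigraph(seed, unit_weights = seed %% 2 == 0)
    edges <- g$edges
    if (nrow(edges) < 2L) next
    set.seed(seed + 1000)
    pick <- sample(nrow(edges), 2)
    entry <- edges$id[pick[1]]; exit <- edges$id[pick[2]]
    want_mid <- enum_best_path(edges, edges$to[pick[1]], edges$from[pick[2]])
    got <- tryCatch(shortest_cvs_route(g, entry, exit),
                    physroute_NoPath = function(e) NULL)
    if (is.null(want_mid) && edges$to[pick[1]] != edges$from[pick[2]]) {
      expect_null(got, label = sprintf("seed %d (unreachable)", seed))
    } else {
      expect_equal(got, c(entry, want_mid, exit), label = sprintf("seed %d", seed))
      # and the igraph distance agrees with the middle-leg weight
      ig <- as_igraph(g)
      d <- igraph::distances(ig, edges$to[pick[1]], edges$from[pick[2]],
                             mode = "out", weights = igraph::E(ig)$weight)
      expect_equal(sum(edges$weight[match(want_mid, edges$id)]), as.numeric(d))
    }
    checked <- checked + 1L
  }
  expect_gte(checked, 30L)
})

test_that("the elicited route crosses fluid, boundary, capillary and returns through an arteriole", {
  body <- default_body_kb()
  r <- elicit_route(body, "anp", "anpr")
  raw <- r$raw_path
  kinds <- kb_kinds(body, raw)
  subk <- body$individuals$cvs_subkind[match(raw, body$individuals$id)]
  expect_equal(unname(kinds[1]), "TissueFluid")
  expect_equal(unname(kinds[2]), "BoundarySpace")
  expect_equal(subk[3], "capillary")
  expect_equal(subk[length(raw) - 2L], "arteriole")
  expect_equal(unname(kinds[length(raw) - 1L]), "BoundarySpace")
  expect_equal(unname(kinds[length(raw)]), "TissueFluid")
  # legs concatenate without gaps or duplicated junctions
  expect_identical(raw, c(r$legs$leg1, r$legs$leg2[-1], r$legs$leg3[-1]))
  expect_equal(raw[1], r$spec$from_loc)
  expect_equal(raw[length(raw)], r$spec$to_loc)
})

test_that("a mover lacking convection fails at the fluid-vessel crossing", {
  kb <- generate_body_kb()
  kb <- assert_fact(kb, "Protein", "h")
  kb <- assert_fact(kb, "prod-by", c("h", "TS-heart_wall"))
  kb <- assert_fact(kb, "postp_t", c("h", "Ltec"))
  kb <- assert_fact(kb, "CMTP_t", c("h", "dif"))
  kb <- assert_fact(kb, "CMTP_t", c("h", "adv"))
  kb <- assert_fact(kb, "prod-by", c("r", "SM-ARTL-kidney_L-1"))
  kb <- assert_fact(kb, "postp_t", c("r", "Ltpm"))
  err <- tryCatch(elicit_route(kb, "h", "r"),
                  physroute_NoRoute = function(e) conditionMessage(e))
  expect_match(err, "convect")
})

test_that("colocated mover and receptor give a single-fluid route", {
  kb <- generate_body_kb()
  kb <- attach_case_study_proteins(kb)
  kb <- assert_fact(kb, "prod-by", c("localrec", "TS-heart_wall"))
  kb <- assert_fact(kb, "postp_t", c("localrec", "Ltpm"))
  r <- elicit_route(kb, "anp", "localrec")
  expect_identical(r$raw_path, "TF-heart_wall")
  expect_equal(r$footprint$steps$modality, "Diffusion")
})

test_that("non-endocrine pairs are refused with a typed scenario error", {
  kb <- toy_organ_kb()
  kb <- assert_fact(kb, "pm-of", c("PMx", "TS-organ"))
  for (p in c("r1", "r2")) {
    kb <- assert_fact(kb, "prod-by", c(p, "TS-organ"))
    kb <- assert_fact(kb, "postp_t", c(p, "Ltpm"))
  }
  expect_error(elicit_route(kb, "r1", "r2"),
               class = "physroute_UnsupportedScenario")
})

test_that("macro-region edges can be unfolded into their member subgraph", {
  body <- default_body_kb()
  r <- elicit_route(body, "anp", "anpr")
  expect_true(all(c("PC", "LH") %in% r$raw_path))
  rx <- elicit_route(body, "anp", "anpr", expand_macro = TRUE)
  expect_false(any(c("PC", "LH") %in% rx$raw_path))
  expect_true(all(c("PA-1", "CAP-lungs", "PV-1", "LA", "LV") %in% rx$raw_path))
  # unfolding only refines the advective stretch; the footprint is unchanged
  expect_equal(rx$footprint$steps$modality, r$footprint$steps$modality)
})

test_that("graphs export to GraphML", {
  g <- build_cvs_graph(default_body_kb())
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, f)
  expect_true(file.exists(f) && file.info(f)$size > 0)
})
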