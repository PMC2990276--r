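cfg <- space_config(dimension = 200, seed_count = 10, global_seed = 11)

test_that("indirect-neighbor reports match a brute-force filter-then-rank oracle", {
  odb <- random_odb(120, 25, seed = 23)
  m <- build_rri(odb, cfg)
  s <- semantic_concept_matrix(m)
  for (cue in c("c001", "c010", "c020")) {
    got <- nearest_indirect_neighbors(m, cue, k = 8, odb)
    allowed <- setdiff(colnames(s), cue)
    allowed <- allowed[!vapply(allowed, oracle_cooccur, logical(1), odb = odb, a = cue)]
    want <- head(oracle_rank(s[, allowed, drop = FALSE], s[, cue]), 8)
    expect_identical(got$concept, want)
    for (cand in got$concept) expect_false(oracle_cooccur(odb, cue, cand))
  }
  expect_error(nearest_indirect_neighbors(m, "nope", 5, odb), "unknown cue")
})

test_that("total screening yields an empty report with an explanatory status", {
  # every other concept co-occurs with the cue
  odb <- occurrence_db(list(d1 = c("q", "r"), d2 = c("q", "s"), d3 = c("q", "t")))
  m <- build_rri(odb, cfg)
  rep <- nearest_indirect_neighbors(m, "q", k = 5, odb)
  expect_equal(nrow(rep), 0L)
  expect_match(attr(rep, "status"), "screened")
})

test_that("evaluating against the past itself gives exactly zero precision", {
  odb <- random_odb(80, 20, seed = 31)
  m <- build_rri(odb, cfg)
  test_concepts <- sprintf("c%03d", 1:10)
  ev <- evaluate_open(m, odb, odb, test_concepts, k = 10)
  expect_identical(ev$per_concept$precision, rep(0, 10))
  expect_identical(ev$mean, 0)
})

test_that("precision is the fraction of indirect neighbors hit in the future", {
  # hand-built split: cue 'q' has 12 candidates, exactly 4 of the retrieved 10
  # co-occur with it in the future slice
  past <- occurrence_db(c(
    list(p0 = "q"),
    stats::setNames(lapply(sprintf("m%02d", 1:12), identity), sprintf("p%d", 1:12))
  ))
  m <- build_rri(past, cfg)
  retrieved <- nearest_indirect_neighbors(m, "q", k = 10, past)$concept
  future <- occurrence_db(stats::setNames(
    lapply(retrieved[1:4], function(x) c("q", x)), sprintf("f%d", 1:4)))
  ev <- evaluate_open(m, past, future, "q", k = 10)
  expect_equal(ev$per_concept$precision, 0.4)
  expect_error(evaluate_open(m, past, occurrence_db(list()), "q"), "named list")
})

test_that("strength profile bins pool every retrieved candidate", {
  odb <- random_odb(60, 15, seed = 37)
  m <- build_rri(odb, cfg)
  ev <- evaluate_open(m, odb, odb, c("c001", "c002"), k = 5)
  sp <- ev$strength_profile
  expect_true(all(sp$hit_fraction >= 0 & sp$hit_fraction <= 1))
  expect_true(all(sp$n_hits <= sp$n_candidates))
})

test_that("logical leap retrieves second-order associates only", {
  f <- withr::local_tempfile(fileext = ".tsv")
  smad_fixture(f)
  m <- build_psi(read_predications(f), space_config(dimension = 500, global_seed = 1))
  leap <- logical_leap(m, "smad_proteins", k = 3)
  expect_equal(leap$concept[1], "latent_tgf_beta_binding_protein")
  # the shared partner itself is excluded (it is a *direct* associate)
  expect_false("transforming_growth_factor_beta" %in% leap$concept)
  expect_error(logical_leap(m, "unknown_cue"), "no predication")
})

test_that("middle-term recovery finds and verifies a unique bridge", {
  pdb <- make_pdb(subject = c("a", "b", "u"),
                  predicate = c("CAUSES", "TREATS", "CAUSES"),
                  object = c("m", "m", "v"))
  m <- build_psi(pdb, space_config(dimension = 500, global_seed = 2))
  mt <- middle_term(m, "a", "b", k = 1)
  expect_equal(mt$concept, "m")
  expect_true(mt$verified)
  expect_error(middle_term(m, "a", "zzz"), "unknown concept")
})

test_that("middle-term verification agrees with an exhaustive predication scan", {
  pdb <- random_pdb(200, 30, seed = 43)
  m <- build_psi(pdb, space_config(dimension = 300, global_seed = 4))
  concepts <- colnames(m$store$semantic)
  withr::with_seed(7, {
    for (i in 1:15) {
      ab <- sample(concepts, 2)
      mt <- middle_term(m, ab[1], ab[2], k = 5)
      for (j in seq_len(nrow(mt))) {
        brute <- length(oracle_link(pdb, ab[1], mt$concept[j])) > 0 &&
          length(oracle_link(pdb, ab[2], mt$concept[j])) > 0
        expect_identical(mt$verified[j], brute)
      }
    }
  })
})

test_that("occurrence-based bridging finds and verifies shared-citation bridges", {
  odb <- occurrence_db(list(d1 = c("A", "M"), d2 = c("M", "B"), d3 = c("A", "N"),
                            d4 = c("P", "Q")))
  m <- build_rri(odb, cfg)
  br <- bridging_concepts(m, "A", "B", k = 3, past_odb = odb)
  expect_equal(br$concept[1], "M")
  expect_true(br$verified[1])
  # a pair with no common neighbor verifies nothing
  br2 <- bridging_concepts(m, "P", "B", k = 3, past_odb = odb)
  expect_false(any(br2$verified))
  # verification equals the exhaustive co-occurrence scan
  for (j in seq_len(nrow(br))) {
    expect_identical(br$verified[j],
                     oracle_cooccur(odb, "A", br$concept[j]) &&
                       oracle_cooccur(odb, "B", br$concept[j]))
  }
})

test_that("link networks keep only predication-supported edges", {
  pdb <- make_pdb(subject = c("A", "B", "X", "Y"),
                  predicate = "ISA",
                  object = c("X", "Y", "Z", "Z"))
  m <- build_psi(pdb, space_config(dimension = 500, global_seed = 5))
  net <- link_concepts(m, c("A", "B"), k = 5)
  # every retained edge is supported by at least one predication
  for (j in seq_len(nrow(net$edges))) {
    expect_gt(length(oracle_link(pdb, net$edges$from[j], net$edges$to[j])), 0)
  }
  # the cues are joined through interposed concepts
  g <- as_igraph(net)
  expect_true(is.finite(igraph::distances(g, "A", "B")[1, 1]))
  # directly linked cues keep their edge
  pdb2 <- make_pdb(c("A", "A"), "CAUSES", c("B", "C"))
  net2 <- link_concepts(build_psi(pdb2, cfg), c("A", "B"), k = 2)
  expect_true(any((net2$edges$from == "A" & net2$edges$to == "B") |
                    (net2$edges$from == "B" & net2$edges$to == "A")))
  expect_error(link_concepts(m, "A"), "at least two cues")
})

test_that("the paired permutation test separates signal from exchange noise", {
  x <- c(rep(0.4, 20), rep(0.2, 10))
  y <- rep(0.05, 30)
  expect_lt(paired_permutation_pvalue(x, y, n_perm = 2000, seed = 3), 0.01)
  same <- withr::with_seed(4, rnorm(30))
  expect_gt(paired_permutation_pvalue(same, same + 0, n_perm = 500, seed = 5), 0.4)
  expect_error(paired_permutation_pvalue(1:3, 1:4), "paired")
})
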