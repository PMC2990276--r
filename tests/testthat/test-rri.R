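cfg20 <- space_config(dimension = 20, seed_count = 4, global_seed = 2, weighting = "none")

test_that("document vectors are weighted sums of token elemental vectors", {
  odb <- occurrence_db(list(d1 = "A", d2 = c("A", "B")))
  m <- build_rri(odb, cfg20)
  expect_equal(m$doc_vectors[, "d1"], elemental_vector("C:A", cfg20))
  expect_equal(m$doc_vectors[, "d2"],
               elemental_vector("C:A", cfg20) + elemental_vector("C:B", cfg20))
  # idf weighting scales each token by log(N/df)
  cfg_idf <- space_config(dimension = 20, seed_count = 4, global_seed = 2, weighting = "idf")
  m2 <- build_rri(odb, cfg_idf)
  expect_equal(m2$doc_vectors[, "d2"],
               log(2 / 2) * elemental_vector("C:A", cfg_idf) +
                 log(2 / 1) * elemental_vector("C:B", cfg_idf))
})

test_that("semantic vectors accumulate the documents a token occurs in", {
  odb <- occurrence_db(list(d1 = c("A", "B"), d2 = c("B", "C")))
  m <- build_rri(odb, cfg20)
  s <- m$store$semantic
  # token in exactly one document is proportional to that document vector
  expect_equal(cosine(s[, "C:A"], m$doc_vectors[, "d1"]), 1)
  # unit norm after finalization
  expect_equal(sqrt(colSums(s^2)), rep(1, ncol(s)), ignore_attr = TRUE,
               tolerance = 1e-9)
  # identical citation sets give identical semantic vectors
  odb2 <- occurrence_db(list(d1 = c("X", "Y", "A"), d2 = c("X", "Y", "B")))
  m2 <- build_rri(odb2, cfg20)
  expect_equal(m2$store$semantic[, "C:X"], m2$store$semantic[, "C:Y"])
})

test_that("indirect co-occurrence yields above-chance similarity", {
  cfg <- space_config(dimension = 200, seed_count = 10, global_seed = 31, weighting = "none")
  odb <- occurrence_db(list(
    d1 = c("x", "z"), d2 = c("z", "y"),
    d3 = c("a", "b"), d4 = c("c", "d"), d5 = c("e", "f"), d6 = c("g", "h")
  ))
  m <- build_rri(odb, cfg)
  s <- semantic_concept_matrix(m)
  indirect <- cosine(s[, "x"], s[, "y"])
  # null distribution: concept pairs with no direct or shared-document relation
  null_pool <- c("a", "c", "e", "g", "b", "d", "f", "h")
  null_pairs <- t(utils::combn(null_pool, 2))
  null_pairs <- null_pairs[!apply(null_pairs, 1, function(p) {
    oracle_cooccur(odb, p[1], p[2])  # drop directly co-occurring pairs
  }), , drop = FALSE]
  null_cos <- apply(null_pairs, 1, function(p) {
    cosine(s[, p[1]], s[, p[2]])
  })
  expect_gt(indirect, quantile(null_cos, 0.95))
})

test_that("duplicating every document leaves all cosines unchanged", {
  odb <- random_odb(40, 15, seed = 6)
  doubled <- occurrence_db(c(
    stats::setNames(odb$concepts, odb$citation_ids),
    stats::setNames(odb$concepts, paste0(odb$citation_ids, "_copy"))
  ))
  cfg <- space_config(dimension = 100, seed_count = 6, global_seed = 3, weighting = "none")
  s1 <- semantic_concept_matrix(build_rri(odb, cfg))
  s2 <- semantic_concept_matrix(build_rri(doubled, cfg))
  expect_equal(s1, s2[, colnames(s1)])
})

test_that("document order does not change the learned space", {
  odb <- random_odb(60, 20, seed = 13)
  perm <- withr::with_seed(1, sample(odb$n_citations))
  shuffled <- occurrence_db(stats::setNames(odb$concepts[perm], odb$citation_ids[perm]))
  cfg <- space_config(dimension = 100, seed_count = 6, global_seed = 5, weighting = "idf")
  s1 <- semantic_concept_matrix(build_rri(odb, cfg))
  s2 <- semantic_concept_matrix(build_rri(shuffled, cfg))
  expect_equal(s1[, sort(colnames(s1))], s2[, sort(colnames(s2))])
})

test_that("translate maps terms to distributionally matching concepts", {
  # a term with exactly concept C's citation distribution ranks C first
  odb <- occurrence_db(
    list(d1 = c("C", "D"), d2 = c("C", "E"), d3 = c("D", "E"), d4 = "E"),
    terms = list(d1 = "tc", d2 = "tc")
  )
  cfg <- space_config(dimension = 100, seed_count = 6, global_seed = 8, weighting = "none")
  m <- build_rri(odb, cfg)
  expect_equal(translate(m, "tc", k = 1)$concept, "C")
  expect_error(translate(m, "unseen_term"), "no query term known")
  expect_message(res <- translate(m, c("tc", "unseen"), k = 2), "ignoring")
  expect_equal(res$concept[1], "C")
})

test_that("planted term-concept alignment is recovered across global seeds", {
  hits <- 0L
  for (seed in 1:20) {
    corpus <- withr::with_seed(seed + 100, {
      pool <- sprintf("k%02d", 1:10)
      sets <- lapply(1:30, function(i) sample(pool, 3))
      names(sets) <- sprintf("d%02d", 1:30)
      term_sets <- lapply(sets, function(cs) if ("k01" %in% cs) "t_planted" else character())
      list(sets = sets, terms = term_sets)
    })
    odb <- occurrence_db(corpus$sets, corpus$terms)
    m <- build_rri(odb, space_config(dimension = 200, seed_count = 10, global_seed = seed))
    if ("k01" %in% translate(m, "t_planted", k = 3)$concept) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("screened search excludes exactly the direct co-occurrences", {
  odb <- random_odb(100, 20, seed = 17)
  cfg <- space_config(dimension = 100, seed_count = 6, global_seed = 7)
  m <- build_rri(odb, cfg)
  cue <- "c001"
  rep_screen <- general_search(m, cue, k = 10, screen = TRUE, odb = odb)
  for (cand in rep_screen$concept) {
    expect_false(oracle_cooccur(odb, cue, cand))
  }
  # unscreened search ranks a superset; its non-co-occurring prefix is the
  # screened result
  rep_all <- general_search(m, cue, k = ncol(semantic_concept_matrix(m)),
                            screen = FALSE)
  keep <- !vapply(rep_all$concept, oracle_cooccur, logical(1), odb = odb, a = cue)
  expect_identical(head(rep_all$concept[keep], 10), rep_screen$concept)
  expect_error(general_search(m, "not_a_concept", odb = odb), "unknown cue")
  expect_error(general_search(m, cue, screen = TRUE), "odb")
})
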