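test_that("predication parsing keeps good lines and applies filter rules", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "C1\tsmad_proteins\tINTERACTS_WITH\tC2\ttgf_beta\tPMID:1",
    "C3\tx\tPROCESS_OF\tC4\ty\tPMID:2",
    "C5\tx\tNEG_TREATS\tC6\ty\tPMID:3",
    "C7\tbroken line with too few fields",
    "C8\ta\tCAUSES\tC9\tb\tPMID:4"
  ), f)
  pdb <- suppressMessages(read_predications(f))
  expect_equal(nrow(pdb$predications), 2L)
  expect_setequal(pdb$predications$predicate, c("INTERACTS_WITH", "CAUSES"))
  expect_equal(pdb$n_malformed, 1L)
  expect_equal(pdb$n_filtered, 2L)

  # negation / PROCESS_OF filters can be switched off
  keep_all <- filter_rules(drop_negations = FALSE, drop_predicates = character())
  expect_equal(nrow(suppressMessages(read_predications(f, keep_all))$predications), 4L)
})

test_that("empty and missing predication files are handled explicitly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), f)
  expect_warning(pdb <- read_predications(f), "empty")
  expect_equal(nrow(pdb$predications), 0L)
  expect_error(read_predications(file.path(tempdir(), "nope.tsv")), "no such")
})

test_that("predication databases round-trip through TSV", {
  pdb <- random_pdb(80, 25, seed = 11)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_predications(pdb, f)
  expect_equal(read_predications(f)$predications, pdb$predications)
})

test_that("occurrence parsing builds consistent frequency and co-occurrence indexes", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cit1\tC:A C:B T:apple", "cit2\tC:B C:C"), f)
  odb <- read_occurrences(f)
  expect_true(direct_cooccurrence(odb, "A", "B"))
  expect_false(direct_cooccurrence(odb, "A", "C"))  # no shared citation
  expect_equal(unname(odb$concept_freq[c("A", "B", "C")]), c(1L, 2L, 1L))
  expect_equal(names(odb$term_index), "apple")

  # duplicated citation ids merge
  writeLines(c("cit1\tC:A", "cit1\tC:B"), f)
  odb2 <- suppressMessages(read_occurrences(f))
  expect_equal(odb2$n_citations, 1L)
  expect_true(direct_cooccurrence(odb2, "A", "B"))
})

test_that("concept frequencies match an independent per-line recount", {
  odb <- random_odb(100, 30, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_occurrences(odb, f)
  reread <- read_occurrences(f)
  lines <- readLines(f)
  recount <- table(unlist(lapply(strsplit(lines, "\t"), function(x) {
    toks <- strsplit(x[2], " ")[[1]]
    unique(substring(toks[startsWith(toks, "C:")], 3))
  })))
  for (cc in names(recount)) {
    expect_equal(unname(reread$concept_freq[[cc]]), unname(as.integer(recount[[cc]])))
  }
  # cooccur symmetry + oracle agreement on a sample of pairs
  pool <- names(reread$concept_freq)
  withr::with_seed(9, {
    for (i in 1:50) {
      ab <- sample(pool, 2)
      expect_identical(direct_cooccurrence(reread, ab[1], ab[2]),
                       direct_cooccurrence(reread, ab[2], ab[1]))
      expect_identical(direct_cooccurrence(reread, ab[1], ab[2]),
                       oracle_cooccur(reread, ab[1], ab[2]))
    }
  })
})

test_that("self co-occurrence is true exactly when the concept occurs", {
  odb <- occurrence_db(list(d1 = c("A", "B")))
  expect_true(direct_cooccurrence(odb, "A", "A"))
  expect_false(direct_cooccurrence(odb, "Z", "Z"))
})

test_that("predication links match an exhaustive scan of the triple list", {
  pdb <- random_pdb(120, 15, seed = 21)
  pool <- sprintf("c%03d", 1:15)
  withr::with_seed(5, {
    for (i in 1:40) {
      ab <- sample(pool, 2)
      got <- predication_link(pdb, ab[1], ab[2])
      want <- oracle_link(pdb, ab[1], ab[2])
      expect_equal(nrow(got), length(want))
      if (length(want)) {
        expect_setequal(paste(got$predicate, got$role),
                        vapply(want, paste, "", collapse = " "))
      }
    }
  })
  expect_equal(nrow(predication_link(pdb, "absent1", "absent2")), 0L)
})

test_that("test-concept selection respects inclusive bounds and seeds", {
  # one concept 4x as subject (ineligible), one exactly 5x (eligible),
  # one eligible but at the exact frequency cap
  pdb <- make_pdb(subject = c(rep("low", 4), rep("ok", 5), rep("cap", 5)),
                  predicate = "CAUSES",
                  object = sprintf("o%02d", 1:14))
  cites <- c(lapply(1:3, function(i) c("low", "ok")),
             lapply(1:3, function(i) "cap"))
  names(cites) <- sprintf("cit%d", 1:6)
  odb <- occurrence_db(cites)
  rules <- filter_rules(max_concept_freq = 3, min_subject_count = 5)
  got <- select_test_concepts(pdb, odb, rules, n = 2, seed = 1)
  expect_setequal(got, c("ok", "cap"))  # 'low' fails the subject bound
  expect_error(select_test_concepts(pdb, odb, rules, n = 3, seed = 1), "shortfall")

  big <- random_pdb(300, 40, seed = 2)
  bigodb <- random_odb(150, 40, seed = 2)
  r <- filter_rules(min_subject_count = 2)
  s1 <- select_test_concepts(big, bigodb, r, n = 10, seed = 99)
  s2 <- select_test_concepts(big, bigodb, r, n = 10, seed = 99)
  expect_identical(s1, s2)
  expect_equal(length(unique(s1)), 10L)
})

test_that("tightening filter rules never grows the eligible concept set", {
  pdb <- random_pdb(300, 40, seed = 7)
  odb <- random_odb(200, 40, seed = 7)
  eligible <- function(rules) {
    sc <- subject_counts(pdb)
    freq_ok <- names(odb$concept_freq)[odb$concept_freq <= rules$max_concept_freq]
    intersect(freq_ok, names(sc)[sc >= rules$min_subject_count])
  }
  loose <- eligible(filter_rules(max_concept_freq = 50, min_subject_count = 1))
  for (cap in c(30, 15, 5)) {
    for (minsub in c(2, 4, 8)) {
      tight <- eligible(filter_rules(max_concept_freq = cap, min_subject_count = minsub))
      expect_true(all(tight %in% loose))
    }
  }
})
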