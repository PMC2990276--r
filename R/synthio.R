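#' Specification of a synthetic discovery corpus
#'
#' Defines the structure of a generated corpus with known ground truth,
#' standing in for a time-sliced biomedical literature. The generator plants
#' two kinds of structure on top of Zipf-distributed background noise:
#'
#' * **predication chains** *A -> B <- C*: two predications sharing the
#'   middle concept B, so that logical-leap retrieval from A should surface
#'   C, and middle-term recovery on (A, C) should return B;
#' * **indirect future pairs** (X, Y): X and Y never co-occur in the past
#'   slice but each co-occurs with the same dedicated bridge concepts, and
#'   they co-occur directly in the future slice -- the gold standard for the
#'   open-discovery harness.
#'
#' Planted pairs are guaranteed (and re-verified after generation) never to
#' co-occur in the past slice.
#'
#' @param n_concepts,n_terms,n_citations Corpus sizes (past slice).
#' @param concepts_per_citation Mean number of concepts per background
#'   citation (Poisson, at least 1).
#' @param n_chains Number of planted predication chains.
#' @param n_future_pairs Number of planted indirect pairs.
#' @param bridges_per_pair Dedicated bridge concepts per planted pair.
#' @param n_noise_predications Background predications drawn over the
#'   background concept pool.
#' @param predicate_vocab Predicate labels to draw from.
#' @param zipf_exponent Exponent of the background concept frequency
#'   distribution (heavy-tailed, like real concept statistics).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_concepts = 1500, n_terms = 300, n_citations = 2000,
                       concepts_per_citation = 5, n_chains = 200,
                       n_future_pairs = 100, bridges_per_pair = 3,
                       n_noise_predications = 2500,
                       predicate_vocab = predicate_template("biological")$predicates,
                       zipf_exponent = 1.1, seed = 1L) {
  spec <- structure(
    list(n_concepts = n_concepts, n_terms = n_terms, n_citations = n_citations,
         concepts_per_citation = concepts_per_citation, n_chains = n_chains,
         n_future_pairs = n_future_pairs, bridges_per_pair = bridges_per_pair,
         n_noise_predications = n_noise_predications,
         predicate_vocab = as.character(predicate_vocab),
         zipf_exponent = zipf_exponent, seed = as.integer(seed)),
    class = "synth_spec"
  )
  reserved <- 3 * n_chains + (2 + bridges_per_pair) * n_future_pairs
  if (reserved > n_concepts) {
    abort(sprintf(paste("infeasible spec: 3*n_chains + (2+bridges_per_pair)*n_future_pairs",
                        "= %d exceeds n_concepts = %d"), reserved, n_concepts))
  }
  if (n_concepts - reserved < 50) {
    abort("infeasible spec: fewer than 50 background concepts remain after planting")
  }
  if (n_citations <= 2 * bridges_per_pair * n_future_pairs) {
    abort("infeasible spec: n_citations leaves no room for background citations")
  }
  if (length(spec$predicate_vocab) == 0) abort("infeasible spec: empty predicate_vocab")
  spec
}

zipf_weights <- function(n, exponent) (1 / seq_len(n))^exponent

#' Generate a synthetic past/future corpus with ground truth
#'
#' Writes four files into `dir`: `past_occurrences.tsv` and
#' `future_occurrences.tsv` (the two time slices, in the format read by
#' [read_occurrences()]), `predications.tsv` (read by
#' [read_predications()]), and `manifest.json`, which lists every planted
#' chain and future pair. Generation is byte-deterministic given the spec
#' (including its seed). After writing, the past slice is re-read and
#' audited: if any planted pair co-occurs in it, generation aborts.
#'
#' @param spec A [synth_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths) and `manifest`
#'   (the parsed manifest: `chains` and `future_pairs` tibbles plus pools).
#' @export
generate_corpus <- function(spec = synth_spec(), dir) {
  stopifnot(inherits(spec, "synth_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  concepts <- sprintf("C%05d", seq_len(spec$n_concepts))
  terms <- sprintf("t%04d", seq_len(spec$n_terms))

  nc <- spec$n_chains; np <- spec$n_future_pairs; bp <- spec$bridges_per_pair
  chain_ids <- matrix(concepts[seq_len(3 * nc)], ncol = 3, byrow = TRUE)  # A, B, C
  off <- 3 * nc
  pair_ids <- matrix(concepts[off + seq_len(2 * np)], ncol = 2, byrow = TRUE)  # X, Y
  off <- off + 2 * np
  bridge_ids <- matrix(concepts[off + seq_len(bp * np)], ncol = bp, byrow = TRUE)
  off <- off + bp * np
  background <- concepts[(off + 1):spec$n_concepts]
  alias <- stats::setNames(terms[(seq_along(background) - 1) %% spec$n_terms + 1],
                           background)

  res <- withr::with_seed(spec$seed, {
    # --- past occurrences -----------------------------------------------
    ids <- character(); toks <- list()
    for (i in seq_len(np)) {
      for (b in seq_len(bp)) {
        ids <- c(ids, sprintf("PAST:P%03d:B%dX", i, b), sprintf("PAST:P%03d:B%dY", i, b))
        toks <- c(toks, list(c(pair_ids[i, 1], bridge_ids[i, b])),
                  list(c(bridge_ids[i, b], pair_ids[i, 2])))
      }
    }
    n_bg <- spec$n_citations - length(ids)
    wz <- zipf_weights(length(background), spec$zipf_exponent)
    bg_sets <- lapply(seq_len(n_bg), function(i) {
      size <- 1 + rpois(1, max(spec$concepts_per_citation - 1, 0))
      unique(sample(background, min(size, length(background)), prob = wz))
    })
    ids <- c(ids, sprintf("PAST:B%05d", seq_len(n_bg)))
    toks <- c(toks, bg_sets)
    term_sets <- lapply(toks, function(cs) {
      al <- unname(alias[cs[cs %in% names(alias)]])
      al <- al[stats::runif(length(al)) < 0.8]
      noise <- if (stats::runif(1) < 0.2) sample(terms, 1,
        prob = zipf_weights(length(terms), spec$zipf_exponent)) else character()
      unique(c(al, noise))
    })
    past <- list(ids = ids, concepts = toks, terms = term_sets)

    # --- future occurrences ---------------------------------------------
    fids <- character(); ftoks <- list()
    for (i in seq_len(np)) {
      fids <- c(fids, sprintf("FUT:P%03d:1", i), sprintf("FUT:P%03d:2", i))
      ftoks <- c(ftoks, list(pair_ids[i, ]), list(pair_ids[i, ]))
    }
    n_fbg <- max(round(spec$n_citations / 4), 1)
    fbg <- lapply(seq_len(n_fbg), function(i) {
      size <- 1 + rpois(1, max(spec$concepts_per_citation - 1, 0))
      unique(sample(background, min(size, length(background)), prob = wz))
    })
    fids <- c(fids, sprintf("FUT:B%05d", seq_len(n_fbg)))
    ftoks <- c(ftoks, fbg)
    future <- list(ids = fids, concepts = ftoks)

    # --- predications ----------------------------------------------------
    pred_a <- sample(spec$predicate_vocab, nc, replace = TRUE)
    pred_c <- sample(spec$predicate_vocab, nc, replace = TRUE)
    chains <- tibble(a = chain_ids[, 1], middle = chain_ids[, 2], c = chain_ids[, 3],
                     predicate_a = pred_a, predicate_c = pred_c)
    noise_s <- sample(background, spec$n_noise_predications, replace = TRUE)
    noise_o <- sample(background, spec$n_noise_predications, replace = TRUE)
    fix <- noise_s == noise_o
    while (any(fix)) {
      noise_o[fix] <- sample(background, sum(fix), replace = TRUE)
      fix <- noise_s == noise_o
    }
    preds <- tibble(
      subject_id = c(chains$a, chains$c, noise_s),
      predicate = c(pred_a, pred_c, sample(spec$predicate_vocab,
                                           spec$n_noise_predications, replace = TRUE)),
      object_id = c(chains$middle, chains$middle, noise_o),
      citation_id = c(sprintf("PRED:CH%03d:1", seq_len(nc)),
                      sprintf("PRED:CH%03d:2", seq_len(nc)),
                      sprintf("PRED:N%05d", seq_len(spec$n_noise_predications)))
    )
    preds$subject_name <- paste0("name_", preds$subject_id)
    preds$object_name <- paste0("name_", preds$object_id)
    list(past = past, future = future, chains = chains, preds = preds)
  })

  paths <- list(past = file.path(dir, "past_occurrences.tsv"),
                future = file.path(dir, "future_occurrences.tsv"),
                predications = file.path(dir, "predications.tsv"),
                manifest = file.path(dir, "manifest.json"))
  write_occurrences(new_occurrence_db(res$past$ids, res$past$concepts, res$past$terms),
                    paths$past)
  write_occurrences(new_occurrence_db(res$future$ids, res$future$concepts,
                                      rep(list(character()), length(res$future$ids))),
                    paths$future)
  write_predications(predication_db(res$preds), paths$predications)

  future_pairs <- tibble(a = pair_ids[, 1], b = pair_ids[, 2],
                         bridges = lapply(seq_len(np), function(i) bridge_ids[i, ]))
  manifest <- list(
    spec = unclass(spec),
    chains = res$chains,
    future_pairs = future_pairs,
    background = background,
    aliases = tibble(concept = names(alias), term = unname(alias))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")

  # audit: no planted pair may co-occur in the past slice
  past_db <- read_occurrences(paths$past)
  bad <- vapply(seq_len(np), function(i) {
    direct_cooccurrence(past_db, pair_ids[i, 1], pair_ids[i, 2])
  }, logical(1))
  if (any(bad)) {
    abort(sprintf("generator invariant violated: %d planted pair(s) co-occur in the past slice",
                  sum(bad)))
  }
  invisible(list(paths = paths, manifest = manifest))
}

#' Read a corpus manifest back
#'
#' @param path Path to a `manifest.json` written by [generate_corpus()].
#' @return A list with `spec`, `chains`, `future_pairs` (tibbles), and the
#'   background/alias pools.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$chains <- as_tibble(m$chains)
  m$future_pairs <- as_tibble(m$future_pairs)
  m$aliases <- as_tibble(m$aliases)
  m
}

#' The smad worked-example fixture
#'
#' Writes a small predication file containing the two canonical predications
#' of the worked example --
#' `smad_proteins INTERACTS_WITH transforming_growth_factor_beta` and
#' `latent_tgf_beta_binding_protein INTERACTS_WITH
#' transforming_growth_factor_beta` -- plus seeded random distractor
#' predications over a disjoint set of distractor concepts. On the space
#' built from this fixture, a logical leap from `smad_proteins` should
#' retrieve `latent_tgf_beta_binding_protein` (they share the middle term),
#' and middle-term recovery on the two should return
#' `transforming_growth_factor_beta`, verified by both predications.
#'
#' @param path Output TSV path.
#' @param n_distractors Number of distractor predications (default 50).
#' @param n_distractor_concepts Size of the distractor concept pool
#'   (default 30; shares no concept with the planted predications).
#' @param seed Seed for the distractor draw.
#' @return `path`, invisibly.
#' @export
smad_fixture <- function(path = tempfile(fileext = ".tsv"),
                         n_distractors = 50, n_distractor_concepts = 30,
                         seed = 42L) {
  planted <- tibble(
    subject_id = c("smad_proteins", "latent_tgf_beta_binding_protein"),
    predicate = "INTERACTS_WITH",
    object_id = "transforming_growth_factor_beta",
    citation_id = c("PMID:1", "PMID:2")
  )
  pool <- sprintf("distractor_%02d", seq_len(n_distractor_concepts))
  vocab <- predicate_template("biological")$predicates
  noise <- withr::with_seed(seed, {
    s <- sample(pool, n_distractors, replace = TRUE)
    o <- sample(pool, n_distractors, replace = TRUE)
    fix <- s == o
    while (any(fix)) {
      o[fix] <- sample(pool, sum(fix), replace = TRUE)
      fix <- s == o
    }
    tibble(subject_id = s, predicate = sample(vocab, n_distractors, replace = TRUE),
           object_id = o, citation_id = sprintf("PMID:D%03d", seq_len(n_distractors)))
  })
  preds <- dplyr::bind_rows(planted, noise)
  preds$subject_name <- preds$subject_id
  preds$object_name <- preds$object_id
  write_predications(predication_db(preds), path)
  invisible(path)
}

#' Generate a retrieval benchmark predication database
#'
#' Draws a random predication set in which every concept participates in a
#' bounded number of distinct predications (each concept gets its own cap,
#' uniform on `1..max_per_concept`, so low-degree concepts are represented).
#' The returned database is its own ground truth: a concept's true partners
#' are exactly the other concepts it shares a predication with, so
#' encode/retrieve fidelity of a predication space can be scored directly.
#'
#' @param n_concepts Number of concepts (default 1000).
#' @param max_per_concept Upper bound on distinct predications per concept
#'   (default 20).
#' @param n_predications Target number of distinct triples (default 6000;
#'   fewer are returned if the caps bind first).
#' @param predicate_vocab Predicate labels to draw from.
#' @param seed Integer seed.
#' @return A `predication_db`.
#' @export
generate_psi_benchmark <- function(n_concepts = 1000, max_per_concept = 20,
                                   n_predications = 6000,
                                   predicate_vocab = predicate_template("biological")$predicates,
                                   seed = 1L) {
  concepts <- sprintf("B%04d", seq_len(n_concepts))
  withr::with_seed(seed, {
    caps <- sample.int(max_per_concept, n_concepts, replace = TRUE)
    counts <- integer(n_concepts)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    subj <- integer(n_predications); obj <- integer(n_predications)
    n_acc <- 0L
    attempts <- 0L
    max_attempts <- 50L * n_predications
    while (n_acc < n_predications && attempts < max_attempts) {
      attempts <- attempts + 1L
      s <- sample.int(n_concepts, 1L); o <- sample.int(n_concepts, 1L)
      if (s == o || counts[s] >= caps[s] || counts[o] >= caps[o]) next
      key <- paste0(s, "_", o)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      n_acc <- n_acc + 1L
      subj[n_acc] <- s; obj[n_acc] <- o
      counts[s] <- counts[s] + 1L; counts[o] <- counts[o] + 1L
    }
    subj <- subj[seq_len(n_acc)]; obj <- obj[seq_len(n_acc)]
    preds <- tibble(
      subject_id = concepts[subj],
      subject_name = concepts[subj],
      predicate = sample(predicate_vocab, n_acc, replace = TRUE),
      object_id = concepts[obj],
      object_name = concepts[obj],
      citation_id = sprintf("PRED:%05d", seq_len(n_acc))
    )
    predication_db(preds)
  })
}

#' True predication partners of every concept
#'
#' Ground-truth helper: for each concept in a predication database, the set
#' of distinct other concepts it shares a predication with.
#'
#' @param pdb A `predication_db`.
#' @return A named list of character vectors.
#' @export
predication_partners <- function(pdb) {
  p <- pdb$predications
  edges <- tibble(a = c(p$subject_id, p$object_id), b = c(p$object_id, p$subject_id))
  edges <- dplyr::distinct(edges)
  split(edges$b, edges$a)
}
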