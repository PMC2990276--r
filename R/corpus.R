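#' Predication filtering rules
#'
#' Rules applied when reading a predication file and when selecting
#' evaluation test concepts. Negated predications and a configurable set of
#' uninformative predicates (by default `PROCESS_OF`) are dropped at parse
#' time. The frequency bounds are used by [select_test_concepts()]: a test
#' concept must occur no more than `max_concept_freq` times in the occurrence
#' corpus (high-frequency concepts carry little information content) and at
#' least `min_subject_count` times as the subject of a predication (so that
#' it is actually represented in the predication space). Both bounds are
#' inclusive.
#'
#' Negation detection: a predicate is treated as negated when it starts with
#' `"NEG_"` or is listed in `negation_predicates` explicitly.
#'
#' @param drop_negations Drop negated predications? Default `TRUE`.
#' @param drop_predicates Predicate labels to drop (default `"PROCESS_OF"`).
#' @param negation_prefixes Prefixes marking negated predicates.
#' @param negation_predicates Extra explicit negated predicate labels.
#' @param max_concept_freq Inclusive upper bound on corpus frequency of a
#'   test concept (default 100000).
#' @param min_subject_count Inclusive lower bound on the number of
#'   predications with the concept as subject (default 5).
#' @return An object of class `filter_rules`.
#' @export
filter_rules <- function(drop_negations = TRUE,
                         drop_predicates = "PROCESS_OF",
                         negation_prefixes = "NEG_",
                         negation_predicates = character(),
                         max_concept_freq = 100000,
                         min_subject_count = 5) {
  if (max_concept_freq <= 0) abort("`max_concept_freq` must be positive")
  if (min_subject_count < 0) abort("`min_subject_count` must be non-negative")
  structure(
    list(drop_negations = isTRUE(drop_negations),
         drop_predicates = as.character(drop_predicates),
         negation_prefixes = as.character(negation_prefixes),
         negation_predicates = as.character(negation_predicates),
         max_concept_freq = max_concept_freq,
         min_subject_count = min_subject_count),
    class = "filter_rules"
  )
}

is_negated_predicate <- function(predicate, rules) {
  hit <- predicate %in% rules$negation_predicates
  for (p in rules$negation_prefixes) {
    hit <- hit | startsWith(predicate, p)
  }
  hit
}

new_predication_db <- function(predications, n_malformed = 0L, n_filtered = 0L) {
  structure(list(predications = predications,
                 n_malformed = as.integer(n_malformed),
                 n_filtered = as.integer(n_filtered)),
            class = "predication_db")
}

#' Read a predication file
#'
#' Parses a tab-separated predication file (one subject-predicate-object
#' triple per line, with citation provenance) into an indexed predication
#' database, applying [filter_rules()] as it goes. The expected layout has
#' six columns and no header:
#' `subject_id  subject_name  predicate  object_id  object_name  citation_id`.
#' Lines with fewer than six fields, or with an empty subject, predicate, or
#' object, are counted as malformed and skipped with a message -- large
#' machine-extracted predication dumps are noisy and a bad line should never
#' abort a build.
#'
#' @param path Path to a UTF-8 TSV file.
#' @param rules A [filter_rules()]; negated and dropped predicates are
#'   removed from the returned database.
#' @return A `predication_db`: a list with `predications` (a tibble with the
#'   six columns above), `n_malformed`, and `n_filtered`. A database with
#'   zero surviving predications triggers a warning.
#' @export
read_predications <- function(path, rules = filter_rules()) {
  if (!file.exists(path)) abort(sprintf("no such predication file: %s", path))
  stopifnot(inherits(rules, "filter_rules"))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, function(f) length(f) >= 6L && all(nzchar(f[c(1L, 3L, 4L)])),
               logical(1))
  n_malformed <- sum(!ok)
  if (n_malformed > 0) {
    inform(sprintf("skipped %d malformed predication line(s)", n_malformed))
  }
  fields <- fields[ok]
  preds <- tibble(
    subject_id = vapply(fields, `[[`, "", 1L),
    subject_name = vapply(fields, `[[`, "", 2L),
    predicate = toupper(vapply(fields, `[[`, "", 3L)),
    object_id = vapply(fields, `[[`, "", 4L),
    object_name = vapply(fields, `[[`, "", 5L),
    citation_id = vapply(fields, `[[`, "", 6L)
  )
  drop <- preds$predicate %in% rules$drop_predicates
  if (rules$drop_negations) {
    drop <- drop | is_negated_predicate(preds$predicate, rules)
  }
  n_filtered <- sum(drop)
  preds <- preds[!drop, , drop = FALSE]
  if (nrow(preds) == 0L) {
    warn("no predications survived parsing and filtering: empty database")
  }
  new_predication_db(preds, n_malformed, n_filtered)
}

#' Construct a predication database from a tibble
#'
#' In-memory counterpart of [read_predications()] for programmatically
#' generated predications (no filtering applied).
#'
#' @param predications A tibble/data.frame with columns `subject_id`,
#'   `subject_name`, `predicate`, `object_id`, `object_name`, `citation_id`.
#' @return A `predication_db`.
#' @export
predication_db <- function(predications) {
  need <- c("subject_id", "subject_name", "predicate",
            "object_id", "object_name", "citation_id")
  missing <- setdiff(need, names(predications))
  if (length(missing)) abort(paste("missing columns:", paste(missing, collapse = ", ")))
  new_predication_db(as_tibble(predications)[need])
}

#' @export
print.predication_db <- function(x, ...) {
  cat(sprintf("<predication_db> %d predications (%d malformed, %d filtered at parse)\n",
              nrow(x$predications), x$n_malformed, x$n_filtered))
  invisible(x)
}

#' Write a predication database back to TSV
#'
#' Inverse of [read_predications()]: the written file parses back to an
#' identical database (under rules that do not drop anything further).
#'
#' @param pdb A `predication_db`.
#' @param path Output file path.
#' @export
write_predications <- function(pdb, path) {
  stopifnot(inherits(pdb, "predication_db"))
  utils::write.table(pdb$predications, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-concept subject counts
#'
#' Number of predications in which each concept appears as the subject.
#'
#' @param pdb A `predication_db`.
#' @return A named integer vector.
#' @export
subject_counts <- function(pdb) {
  stopifnot(inherits(pdb, "predication_db"))
  tab <- table(pdb$predications$subject_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Direct predication links between two concepts
#'
#' All `(predicate, role)` combinations under which concepts `a` and `b`
#' appear together in a predication; `role` is the role of `a`. Used to
#' verify that a candidate middle term really is connected to both cue
#' concepts by a chain of predications.
#'
#' @param pdb A `predication_db`.
#' @param a,b Concept identifiers.
#' @return A tibble with columns `predicate` and `role` (possibly empty).
#' @export
predication_link <- function(pdb, a, b) {
  stopifnot(inherits(pdb, "predication_db"))
  p <- pdb$predications
  as_sub <- p$subject_id == a & p$object_id == b
  as_obj <- p$object_id == a & p$subject_id == b
  out <- tibble(
    predicate = c(p$predicate[as_sub], p$predicate[as_obj]),
    role = c(rep("subject", sum(as_sub)), rep("object", sum(as_obj)))
  )
  dplyr::distinct(out)
}

#' All predication partners of a concept
#'
#' The inverted index entry for one concept: each distinct
#' `(predicate, role, other)` combination it participates in.
#'
#' @param pdb A `predication_db`.
#' @param concept Concept identifier.
#' @return A tibble with columns `predicate`, `role`, `other`.
#' @export
concept_links <- function(pdb, concept) {
  stopifnot(inherits(pdb, "predication_db"))
  p <- pdb$predications
  as_sub <- p$subject_id == concept
  as_obj <- p$object_id == concept
  out <- tibble(
    predicate = c(p$predicate[as_sub], p$predicate[as_obj]),
    role = c(rep("subject", sum(as_sub)), rep("object", sum(as_obj))),
    other = c(p$object_id[as_sub], p$subject_id[as_obj])
  )
  dplyr::distinct(out)
}

# ---- occurrence corpus -------------------------------------------------------

new_occurrence_db <- function(citation_ids, concepts, terms) {
  n <- length(citation_ids)
  concept_index <- invert_sets(concepts)
  term_index <- invert_sets(terms)
  structure(
    list(citation_ids = citation_ids,
         concepts = concepts, terms = terms,
         concept_index = concept_index, term_index = term_index,
         concept_freq = lengths(concept_index),
         term_freq = lengths(term_index),
         n_citations = n),
    class = "occurrence_db"
  )
}

# token -> integer positions of the citations containing it
invert_sets <- function(sets) {
  if (length(sets) == 0L) return(list())
  lens <- lengths(sets)
  split(rep(seq_along(sets), lens), unlist(sets, use.names = FALSE))
}

#' Read an occurrence file
#'
#' Parses a per-citation concept/term occurrence file into an indexed
#' occurrence database. Each line is `citation_id<TAB>tokens`, where tokens
#' are space-separated and tagged `C:<concept_id>` or `T:<term>` so that both
#' vocabularies are distributed over one common set of documents (which is
#' what allows term-to-concept translation). Untagged tokens are counted as
#' malformed and skipped. Lines that repeat a citation id are merged into one
#' citation (with a message). Citations whose token list is empty are
#' skipped.
#'
#' @param path Path to a UTF-8 TSV file.
#' @return An `occurrence_db`: citation sets plus inverted concept/term
#'   indexes and per-token citation frequencies.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such occurrence file: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, "", 1L)
  toks <- lapply(fields, function(f) {
    if (length(f) < 2L) character() else strsplit(f[[2L]], " ", fixed = TRUE)[[1L]]
  })
  if (anyDuplicated(ids)) {
    inform(sprintf("merging %d duplicate citation id(s)", sum(duplicated(ids))))
    toks <- lapply(split(toks, ids)[unique(ids)], function(x) unlist(x, use.names = FALSE))
    ids <- unique(ids)
  }
  n_bad <- 0L
  concepts <- vector("list", length(ids))
  terms <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    tk <- unique(toks[[i]])
    tk <- tk[nzchar(tk)]
    is_c <- startsWith(tk, "C:")
    is_t <- startsWith(tk, "T:")
    n_bad <- n_bad + sum(!is_c & !is_t)
    cs <- substring(tk[is_c], 3L)
    ts <- substring(tk[is_t], 3L)
    concepts[[i]] <- cs[nzchar(cs)]
    terms[[i]] <- ts[nzchar(ts)]
  }
  if (n_bad > 0) inform(sprintf("skipped %d untagged token(s)", n_bad))
  keep <- lengths(concepts) + lengths(terms) > 0L
  if (any(!keep)) inform(sprintf("skipped %d empty citation(s)", sum(!keep)))
  new_occurrence_db(ids[keep], concepts[keep], terms[keep])
}

#' Construct an occurrence database in memory
#'
#' @param citations A named list: citation id -> character vector of concept
#'   ids.
#' @param terms Optional named list (same names) of term tokens per citation.
#' @return An `occurrence_db`.
#' @export
occurrence_db <- function(citations, terms = NULL) {
  ids <- names(citations)
  if (is.null(ids) || any(!nzchar(ids))) abort("`citations` must be a named list")
  if (is.null(terms)) {
    terms <- rep(list(character()), length(ids))
  } else {
    terms <- terms[ids]
    terms[vapply(terms, is.null, logical(1))] <- list(character())
  }
  new_occurrence_db(ids, lapply(unname(citations), unique), lapply(unname(terms), unique))
}

#' @export
print.occurrence_db <- function(x, ...) {
  cat(sprintf("<occurrence_db> %d citations, %d concepts, %d terms\n",
              x$n_citations, length(x$concept_index), length(x$term_index)))
  invisible(x)
}

#' Write an occurrence database back to TSV
#'
#' @param odb An `occurrence_db`.
#' @param path Output file path.
#' @export
write_occurrences <- function(odb, path) {
  stopifnot(inherits(odb, "occurrence_db"))
  tag <- function(prefix, x) if (length(x)) paste0(prefix, x) else character()
  lines <- vapply(seq_len(odb$n_citations), function(i) {
    toks <- c(tag("C:", odb$concepts[[i]]), tag("T:", odb$terms[[i]]))
    paste0(odb$citation_ids[i], "\t", paste(toks, collapse = " "))
  }, "")
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Do two concepts co-occur in any citation?
#'
#' `TRUE` iff some citation contains both `a` and `b`. A concept trivially
#' co-occurs with itself whenever it occurs at all; self-pairs are excluded
#' from all neighbor rankings upstream, so this convention is inert there
#' but fixed for verification scans. Unknown concepts yield `FALSE`.
#'
#' @param odb An `occurrence_db`.
#' @param a,b Concept identifiers.
#' @return A logical scalar.
#' @export
direct_cooccurrence <- function(odb, a, b) {
  stopifnot(inherits(odb, "occurrence_db"))
  ia <- odb$concept_index[[a]]
  if (is.null(ia)) return(FALSE)
  if (a == b) return(TRUE)
  ib <- odb$concept_index[[b]]
  if (is.null(ib)) return(FALSE)
  length(intersect(ia, ib)) > 0L
}

# All concepts sharing at least one citation with `a` (excluding `a`).
cooccurring_concepts <- function(odb, a) {
  ia <- odb$concept_index[[a]]
  if (is.null(ia)) return(character())
  setdiff(unique(unlist(odb$concepts[ia], use.names = FALSE)), a)
}

#' Select evaluation test concepts
#'
#' Uniformly samples `n` distinct concepts eligible for time-sliced
#' evaluation: each must occur no more than `rules$max_concept_freq` times in
#' the occurrence corpus and at least `rules$min_subject_count` times as the
#' subject of a predication (both bounds inclusive). Sampling is
#' deterministic given `seed`.
#'
#' @param pdb A `predication_db` (source of subject counts).
#' @param odb An `occurrence_db` (source of corpus frequencies).
#' @param rules A [filter_rules()].
#' @param n Number of concepts to draw.
#' @param seed Integer seed for the draw.
#' @return A character vector of `n` concept identifiers.
#' @export
select_test_concepts <- function(pdb, odb, rules = filter_rules(), n, seed = 1L) {
  stopifnot(inherits(pdb, "predication_db"), inherits(odb, "occurrence_db"))
  sc <- subject_counts(pdb)
  freq_ok <- names(odb$concept_freq)[odb$concept_freq <= rules$max_concept_freq]
  subj_ok <- names(sc)[sc >= rules$min_subject_count]
  eligible <- sort(intersect(freq_ok, subj_ok))
  if (length(eligible) < n) {
    abort(sprintf("only %d eligible concepts, %d requested (shortfall %d)",
                  length(eligible), n, n - length(eligible)))
  }
  withr::with_seed(seed, sample(eligible, n))
}
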