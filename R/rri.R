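#' Build a reflective random indexing (RRI) space
#'
#' Learns one dense semantic vector per concept and per term from their
#' distribution over a common set of citations. The cycle is: (1) every token
#' (concept or term) gets a deterministic sparse ternary elemental vector;
#' (2) each document vector is the weighted sum of the elemental vectors of
#' the tokens it contains; (3) each token's semantic vector is the normalized
#' sum of the vectors of the documents it occurs in. Tokens that occur in
#' similar documents end up with similar semantic vectors even when they
#' never co-occur directly, which is what makes the space usable for open
#' discovery. Additional reflective cycles (rebuilding document vectors from
#' the learned semantic vectors and re-accumulating) are supported via
#' `cycles`, but one cycle is the default behavior.
#'
#' Because both terms and concepts are distributed over the same documents,
#' the space also supports statistical term-to-concept mapping ([translate()]).
#'
#' @param odb An `occurrence_db` from [read_occurrences()] or
#'   [occurrence_db()].
#' @param config A [space_config()]; `config$weighting` sets the global token
#'   weight used in step (2): `"idf"` is `log(N/df)`, `"log_entropy"` is
#'   `1 - log(df)/log(N)`, `"none"` is 1.
#' @param cycles Number of reflective iterations (default 1).
#' @return An object of class `rri_model`: a list with `store` (the
#'   [vector_store()] holding the semantic layer over tagged token names),
#'   `doc_vectors`, `vocab`, `config`, and `cycles`.
#' @export
#' @examples
#' odb <- occurrence_db(list(d1 = c("A", "B"), d2 = c("B", "C")))
#' m <- build_rri(odb, space_config(dimension = 100, weighting = "none"))
#' general_search(m, "A", k = 2, screen = FALSE)
build_rri <- function(odb, config = space_config(), cycles = 1L) {
  stopifnot(inherits(odb, "occurrence_db"), inherits(config, "space_config"))
  if (odb$n_citations == 0L) abort("occurrence database is empty")
  if (cycles < 1L) abort("`cycles` must be at least 1")

  tag <- function(prefix, x) if (length(x)) paste0(prefix, x) else character()
  concept_tokens <- tag("C:", names(odb$concept_index))
  term_tokens <- tag("T:", names(odb$term_index))
  tokens <- c(concept_tokens, term_tokens)
  df <- c(odb$concept_freq, odb$term_freq)
  n_docs <- odb$n_citations
  w <- token_weights(df, n_docs, config$weighting)

  # token-by-document incidence
  idx <- c(odb$concept_index, odb$term_index)
  b <- Matrix::sparseMatrix(
    i = rep(seq_along(tokens), lengths(idx)),
    j = unlist(idx, use.names = FALSE),
    x = 1,
    dims = c(length(tokens), n_docs)
  )

  e <- elemental_matrix(tokens, config)
  d <- as.matrix(e %*% Matrix::Diagonal(x = w) %*% b)
  s <- as.matrix(d %*% Matrix::t(b))
  if (cycles > 1L) {
    for (i in seq_len(cycles - 1L)) {
      sn <- normalize_columns(s, warn_zero = FALSE)
      d <- as.matrix(sn %*% Matrix::Diagonal(x = w) %*% b)
      s <- as.matrix(d %*% Matrix::t(b))
    }
  }
  colnames(s) <- tokens
  colnames(d) <- odb$citation_ids
  s <- normalize_columns(s)

  structure(
    list(store = vector_store(config, semantic = s),
         doc_vectors = d,
         vocab = tibble(name = substring(tokens, 3L),
                        kind = rep(c("concept", "term"),
                                   c(length(concept_tokens), length(term_tokens)))),
         config = config, cycles = as.integer(cycles), n_citations = n_docs),
    class = "rri_model"
  )
}

token_weights <- function(df, n_docs, weighting) {
  switch(weighting,
    none = rep(1, length(df)),
    idf = log(n_docs / df),
    log_entropy = 1 - log(pmax(df, 1)) / log(max(n_docs, 2))
  )
}

#' @export
print.rri_model <- function(x, ...) {
  cat(sprintf("<rri_model> d=%d, %d tokens (%d concepts, %d terms), %d citations, %d cycle(s)\n",
              x$config$dimension, nrow(x$vocab), sum(x$vocab$kind == "concept"),
              sum(x$vocab$kind == "term"), x$n_citations, x$cycles))
  invisible(x)
}

# Semantic vectors for the concept vocabulary, untagged column names.
semantic_concept_matrix <- function(model) UseMethod("semantic_concept_matrix")

#' @export
semantic_concept_matrix.rri_model <- function(model) {
  m <- model$store$semantic
  m <- m[, startsWith(colnames(m), "C:"), drop = FALSE]
  colnames(m) <- substring(colnames(m), 3L)
  m
}

#' @export
semantic_concept_matrix.psi_model <- function(model) model$store$semantic

#' @export
semantic_concept_matrix.random_model <- function(model) model$store$semantic

model_tag <- function(model) {
  switch(class(model)[1],
         rri_model = "RRI", psi_model = "PSI", random_model = "RANDOM",
         toupper(class(model)[1]))
}

# Normalized sum of the semantic vectors of `cues` (untagged concept ids for
# PSI/random, tagged names resolved internally for RRI).
combined_cue_vector <- function(model, cues) {
  m <- semantic_concept_matrix(model)
  missing <- setdiff(cues, colnames(m))
  if (length(missing)) {
    abort(paste("unknown cue concept(s):", paste(missing, collapse = ", ")))
  }
  q <- rowSums(m[, cues, drop = FALSE])
  n <- sqrt(sum(q^2))
  if (n == 0) abort("combined cue vector has zero content")
  q / n
}

#' Map free-text terms to concepts
#'
#' Statistical term-to-concept translation: the query is the normalized sum
#' of the semantic vectors of the given terms, and the result is the ranked
#' list of nearest concept vectors. Because terms and concepts share one
#' document space, a term and a concept that are distributed alike rank each
#' other highly.
#'
#' @param model An `rri_model`.
#' @param terms Character vector of term tokens; at least one must be known
#'   to the model.
#' @param k Number of concepts to return.
#' @return A tibble with columns `concept` and `cosine`.
#' @export
translate <- function(model, terms, k = 5) {
  stopifnot(inherits(model, "rri_model"))
  s <- model$store$semantic
  tagged <- paste0("T:", terms)
  known <- tagged %in% colnames(s)
  if (!any(known)) {
    abort(paste("no query term known to the model:",
                paste(terms[!known], collapse = ", ")))
  }
  if (any(!known)) {
    inform(paste("ignoring unknown term(s):", paste(terms[!known], collapse = ", ")))
  }
  q <- rowSums(s[, tagged[known], drop = FALSE])
  res <- knn_matrix(semantic_concept_matrix(model), q, k)
  dplyr::rename(res, concept = "name")
}

#' Screened general-association search
#'
#' Ranks concepts by cosine similarity of their semantic vectors to the
#' normalized sum of the cue vectors. With `screen = TRUE` (open-discovery
#' mode) every candidate that co-occurs directly with *any* cue concept in
#' the occurrence corpus is screened out, leaving only indirect neighbors.
#' Cue concepts themselves are always excluded.
#'
#' @param model An `rri_model` (or any model with concept semantic vectors).
#' @param cues One or more concept identifiers.
#' @param k Number of candidates to return after screening.
#' @param screen Screen out direct co-occurrences? Default `TRUE`.
#' @param odb An `occurrence_db`; required when `screen = TRUE`.
#' @return A `discovery_report` tibble with columns `concept`, `cosine`,
#'   `screened`, `verified`; candidates are the top `k` unscreened names.
#'   Attributes carry the cues, model tag, and parameters.
#' @export
general_search <- function(model, cues, k = 10, screen = TRUE, odb = NULL) {
  m <- semantic_concept_matrix(model)
  q <- combined_cue_vector(model, cues)
  screened_names <- character()
  if (screen) {
    if (is.null(odb)) abort("`odb` is required when `screen = TRUE`")
    screened_names <- unique(unlist(lapply(cues, cooccurring_concepts, odb = odb)))
  }
  ranked_report(m, q, k, cues = cues, screened_names = screened_names,
                tag = model_tag(model),
                params = list(k = k, screen = screen))
}

#' Random elemental baseline model
#'
#' A null model for the open-discovery harness: each concept is represented
#' by its (normalized) random sparse elemental vector only, so similarity
#' reflects nothing but chance coordinate overlap. Rankings from this model
#' are the floor against which learned spaces are compared.
#'
#' @param odb An `occurrence_db` supplying the concept vocabulary.
#' @param config A [space_config()].
#' @return An object of class `random_model`.
#' @export
random_baseline <- function(odb, config = space_config()) {
  stopifnot(inherits(odb, "occurrence_db"))
  e <- elemental_matrix(names(odb$concept_index), config)
  structure(list(store = vector_store(config, semantic = normalize_columns(e)),
                 config = config),
            class = "random_model")
}
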