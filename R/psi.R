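#' Predicate-role permutations and binding
#'
#' Each predicate is assigned a deterministic permutation of the coordinates
#' `1..d` (a seeded Fisher-Yates shuffle keyed by the predicate name and the
#' global seed). Applying the permutation to a concept's elemental vector
#' yields a near-orthogonal elemental vector for the predicate-argument
#' pair, which is how predication structure is encoded without growing the
#' space. The subject role uses the permutation itself and the object role
#' its inverse, so binding is directional and exactly invertible:
#' `bind_vector(bind_vector(v, P, "subject"), P, "object")` returns `v`
#' bit-exactly.
#'
#' @param predicate Predicate label.
#' @param config A [space_config()].
#' @param role `"subject"` or `"object"`.
#' @param v Numeric vector of length `d`.
#' @return `predicate_permutation()`: an integer permutation of `1..d`;
#'   `bind_vector()`: the permuted vector.
#' @export
predicate_permutation <- function(predicate, config, role = c("subject", "object")) {
  role <- match.arg(role)
  stopifnot(inherits(config, "space_config"))
  p <- .seeded_permutation(as.character(predicate), config$dimension,
                           as.double(config$global_seed))
  if (role == "object") order(p) else p
}

#' @rdname predicate_permutation
#' @export
bind_vector <- function(v, predicate, role = c("subject", "object"),
                        config) {
  role <- match.arg(role)
  if (length(v) != config$dimension) abort("vector dimension does not match config")
  v[predicate_permutation(predicate, config, role)]
}

#' Predicate templates
#'
#' Named sets of predicates used to restrict searches to biological or
#' clinical relations. The shipped sets live in
#' `inst/extdata/predicate_templates.yaml` and are editable; `"custom"`
#' takes an explicit predicate set.
#'
#' @param name `"biological"`, `"clinical"`, or `"custom"`.
#' @param predicates Character vector of predicate labels (required for
#'   `"custom"`, overrides the shipped set otherwise).
#' @return An object of class `predicate_template`.
#' @export
predicate_template <- function(name = c("biological", "clinical", "custom"),
                               predicates = NULL) {
  name <- match.arg(name)
  if (is.null(predicates)) {
    if (name == "custom") abort("a custom template needs an explicit predicate set")
    path <- system.file("extdata", "predicate_templates.yaml", package = "semleap")
    predicates <- yaml::read_yaml(path)[[name]]
  }
  predicates <- toupper(as.character(predicates))
  if (length(predicates) == 0L) abort("a predicate template must be non-empty")
  structure(list(name = name, predicates = predicates), class = "predicate_template")
}

#' Build a predication-based semantic indexing (PSI) space
#'
#' Encodes a filtered predication database into semantic vectors. For each
#' predication *A --P--> B*, the semantic vector of A accumulates the
#' subject-bound elemental vector of B plus B's raw elemental vector, and
#' symmetrically the semantic vector of B accumulates the object-bound (and
#' raw) elemental vector of A:
#' `semantic(A) += bind(P, subject, e(B)) + e(B)` and
#' `semantic(B) += bind(P, object, e(A)) + e(A)`.
#' The raw elemental term guarantees that two concepts occurring in
#' predications with the same third concept acquire similar semantic vectors
#' even when the predicate types differ -- the property that logical-leap
#' retrieval relies on. All semantic vectors are normalized to unit length
#' at finalization.
#'
#' By default every predication instance contributes once per citation
#' (frequency-weighted encoding); set `unique_triples = TRUE` to encode each
#' distinct triple once regardless of how many citations assert it.
#'
#' @param pdb A `predication_db`, already filtered (see [filter_rules()]).
#' @param config A [space_config()].
#' @param unique_triples Encode each distinct triple once? Default `FALSE`.
#' @return An object of class `psi_model`: a list with `store` (elemental
#'   and semantic layers over concept ids), `pdb`, `config`,
#'   `unique_triples`.
#' @export
#' @examples
#' pdb <- predication_db(tibble::tibble(
#'   subject_id = "a", subject_name = "a", predicate = "INTERACTS_WITH",
#'   object_id = "b", object_name = "b", citation_id = "PMID:1"))
#' m <- build_psi(pdb, space_config(dimension = 100))
#' direct_search(m, "a", k = 1)
build_psi <- function(pdb, config = space_config(), unique_triples = FALSE) {
  stopifnot(inherits(pdb, "predication_db"), inherits(config, "space_config"))
  p <- pdb$predications
  if (nrow(p) == 0L) abort("cannot build a space from an empty predication database")
  if (unique_triples) {
    p <- dplyr::distinct(p, .data$subject_id, .data$predicate, .data$object_id,
                         .keep_all = TRUE)
  }
  concepts <- sort(unique(c(p$subject_id, p$object_id)))
  d <- config$dimension
  e <- elemental_matrix(concepts, config)
  s <- matrix(0, d, length(concepts), dimnames = list(NULL, concepts))

  for (pred in sort(unique(p$predicate))) {
    rows <- which(p$predicate == pred)
    perm <- predicate_permutation(pred, config, "subject")
    inv <- order(perm)
    si <- match(p$subject_id[rows], concepts)
    oi <- match(p$object_id[rows], concepts)
    # into subjects: bound + raw elemental of the object
    eo <- e[, oi, drop = FALSE]
    agg <- rowsum(t(eo[perm, , drop = FALSE] + eo), group = si)
    cols <- as.integer(rownames(agg))
    s[, cols] <- s[, cols] + t(agg)
    # into objects: inverse-bound + raw elemental of the subject
    es <- e[, si, drop = FALSE]
    agg <- rowsum(t(es[inv, , drop = FALSE] + es), group = oi)
    cols <- as.integer(rownames(agg))
    s[, cols] <- s[, cols] + t(agg)
  }
  s <- normalize_columns(s)
  structure(
    list(store = vector_store(config, elemental = e, semantic = s),
         pdb = pdb, config = config, unique_triples = unique_triples),
    class = "psi_model"
  )
}

#' @export
print.psi_model <- function(x, ...) {
  cat(sprintf("<psi_model> d=%d, %d concepts, %d predications%s\n",
              x$config$dimension, ncol(x$store$semantic), nrow(x$pdb$predications),
              if (x$unique_triples) " (unique triples)" else ""))
  invisible(x)
}

#' Direct predication search
#'
#' Retrieves the concepts most strongly associated with a cue according to
#' the predications it occurs in, by ranking candidates on the cosine
#' between the cue's semantic vector and a candidate *probe* vector. With no
#' predicate restriction the probe is the candidate's elemental vector; with
#' `predicate` (and the cue's `role` in it) the probe adds the
#' correspondingly bound elemental vector, making the search specific to
#' that predicate type; with a [predicate_template()] the probe admits every
#' predicate in the template (both roles).
#'
#' @param model A `psi_model`.
#' @param cue Concept identifier with a semantic vector.
#' @param k Number of candidates.
#' @param predicate Optional single predicate label.
#' @param role Role of the *cue* in the predicate (default `"subject"`, i.e.
#'   candidates are retrieved as objects).
#' @param template Optional [predicate_template()] restricting admissible
#'   predicates when no single `predicate` is given.
#' @return A `discovery_report` tibble (`concept`, `cosine`, `screened`,
#'   `verified`).
#' @export
direct_search <- function(model, cue, k = 10, predicate = NULL,
                          role = c("subject", "object"), template = NULL) {
  stopifnot(inherits(model, "psi_model"))
  role <- match.arg(role)
  s <- model$store$semantic
  if (!cue %in% colnames(s)) abort(sprintf("unknown cue concept: %s", cue))
  e <- model$store$elemental
  cfg <- model$config
  sv <- s[, cue]
  if (!is.null(template) && is.null(predicate)) {
    stopifnot(inherits(template, "predicate_template"))
    # each candidate scored by its best admissible predicate type; the probe
    # is the bound vector alone -- the raw elemental term is shared by every
    # predicate and would defeat the restriction
    scores <- rep(-Inf, ncol(e))
    for (pred in template$predicates) {
      for (rl in c("subject", "object")) {
        perm <- predicate_permutation(pred, cfg, rl)
        sc <- as.vector(crossprod(e[perm, , drop = FALSE], sv)) /
          sqrt(colSums(e^2))
        scores <- pmax(scores, sc)
      }
    }
    keep <- colnames(e) != cue
    ord <- order(-scores[keep], colnames(e)[keep])
    top <- head(ord, k)
    return(new_discovery_report(
      tibble(concept = colnames(e)[keep][top], cosine = scores[keep][top],
             screened = FALSE, verified = NA),
      cues = cue, tag = "PSI",
      params = list(k = k, template = template$name)))
  }
  probe <- e
  if (!is.null(predicate)) {
    perm <- predicate_permutation(predicate, cfg, role)
    probe <- probe + e[perm, , drop = FALSE]
  }
  ranked_report(probe, sv, k, cues = cue, screened_names = character(),
                tag = "PSI",
                params = list(k = k, predicate = predicate, role = role))
}
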