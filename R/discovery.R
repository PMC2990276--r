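new_discovery_report <- function(candidates, cues, tag, params,
                                 n_screened = 0L, status = NULL) {
  out <- as_tibble(candidates)
  class(out) <- c("discovery_report", class(out))
  attr(out, "cues") <- cues
  attr(out, "model_tag") <- tag
  attr(out, "params") <- params
  attr(out, "n_screened") <- as.integer(n_screened)
  attr(out, "status") <- status
  out
}

# Rank columns of `m` against `query`, drop cues and screened names, return
# the top-k survivors as a discovery_report. Ties broken lexicographically.
ranked_report <- function(m, query, k, cues, screened_names, tag, params) {
  res <- knn_matrix(m, query, ncol(m), exclude = cues)
  screened <- res$name %in% screened_names
  n_screened <- sum(screened)
  res <- res[!screened, , drop = FALSE]
  res <- head(res, k)
  status <- if (nrow(res) == 0L) "all candidates screened or excluded"
  new_discovery_report(
    tibble(concept = res$name, cosine = res$cosine,
           screened = FALSE, verified = NA),
    cues = cues, tag = tag, params = params,
    n_screened = n_screened, status = status
  )
}

#' @export
print.discovery_report <- function(x, ...) {
  cat(sprintf("# Discovery report [%s] cues: %s (%d screened out)\n",
              attr(x, "model_tag"), paste(attr(x, "cues"), collapse = ", "),
              attr(x, "n_screened")))
  if (!is.null(attr(x, "status"))) cat("# status:", attr(x, "status"), "\n")
  NextMethod()
}

#' Nearest indirect neighbors (open discovery)
#'
#' The core open-discovery operation: the `k` concepts whose semantic
#' vectors are most similar to the cue's, restricted to concepts that never
#' occur in any citation together with the cue in the (past) occurrence
#' corpus. The cue itself is always excluded. Direct neighbors are screened
#' out precisely because a co-occurring association is already known; what
#' remains is the model's ranking of plausible *unreported* connections.
#'
#' @param model An `rri_model`, `psi_model`, or `random_model`.
#' @param cue Concept identifier.
#' @param k Number of indirect neighbors.
#' @param past_odb The `occurrence_db` used for screening.
#' @return A `discovery_report` tibble; empty (with a status attribute) when
#'   every candidate co-occurs with the cue.
#' @export
nearest_indirect_neighbors <- function(model, cue, k = 10, past_odb) {
  stopifnot(inherits(past_odb, "occurrence_db"))
  m <- semantic_concept_matrix(model)
  if (!cue %in% colnames(m)) abort(sprintf("unknown cue concept: %s", cue))
  ranked_report(m, m[, cue], k, cues = cue,
                screened_names = cooccurring_concepts(past_odb, cue),
                tag = model_tag(model), params = list(k = k, screen = "citation"))
}

#' Time-sliced open-discovery evaluation
#'
#' Evaluates a model's ability to predict future co-occurrence: for each
#' test concept the `k` nearest indirect neighbors are retrieved in the past
#' corpus (no direct co-occurrence with the cue), and precision is the
#' fraction of them that *do* co-occur directly with the cue in the future
#' corpus. Because every candidate was unconnected in the past slice, each
#' hit is an approximation of an open discovery. The result also bins all
#' retrieved candidates by association strength (cosine, bins of width 0.1
#' over `[0, 1]`) and reports the hit fraction per bin, profiling how
#' predictive strong associations are compared to weak ones.
#'
#' @param model An `rri_model`, `psi_model`, or `random_model` built from
#'   the past corpus.
#' @param past_odb,future_odb `occurrence_db` objects for the two time
#'   slices.
#' @param test_concepts Concepts to evaluate (see [select_test_concepts()]).
#' @param k Neighbors per concept (default 10).
#' @return An object of class `open_eval`: `per_concept` (tibble with
#'   `concept`, `precision`, `n_candidates`, `mean_cosine`), `mean`, `sem`
#'   (sample SD / sqrt(n)), `strength_profile`, `k`, `model_tag`.
#' @export
evaluate_open <- function(model, past_odb, future_odb, test_concepts, k = 10) {
  stopifnot(inherits(past_odb, "occurrence_db"), inherits(future_odb, "occurrence_db"))
  if (future_odb$n_citations == 0L) abort("future corpus is empty")
  m <- semantic_concept_matrix(model)
  missing <- setdiff(test_concepts, colnames(m))
  if (length(missing)) {
    abort(paste("test concept(s) not in model:", paste(missing, collapse = ", ")))
  }
  all_cos <- double()
  all_hit <- logical()
  rows <- lapply(test_concepts, function(cue) {
    rep <- nearest_indirect_neighbors(model, cue, k, past_odb)
    hit <- vapply(rep$concept, function(cand) direct_cooccurrence(future_odb, cue, cand),
                  logical(1))
    all_cos <<- c(all_cos, rep$cosine)
    all_hit <<- c(all_hit, hit)
    tibble(concept = cue, precision = sum(hit) / k,
           n_candidates = nrow(rep),
           mean_cosine = if (nrow(rep)) mean(rep$cosine) else NA_real_)
  })
  per_concept <- dplyr::bind_rows(rows)
  profile <- strength_profile(all_cos, all_hit)
  structure(
    list(per_concept = per_concept,
         mean = mean(per_concept$precision),
         sem = sd(per_concept$precision) / sqrt(nrow(per_concept)),
         strength_profile = profile, k = k, model_tag = model_tag(model)),
    class = "open_eval"
  )
}

strength_profile <- function(cosines, hits, width = 0.1) {
  keep <- cosines >= 0
  bin <- pmin(floor(cosines[keep] / width), 1 / width - 1)
  tb <- tibble(bin_low = bin * width, hit = hits[keep])
  out <- dplyr::summarise(dplyr::group_by(tb, .data$bin_low),
                          n_candidates = dplyr::n(),
                          n_hits = sum(.data$hit),
                          hit_fraction = mean(.data$hit), .groups = "drop")
  dplyr::arrange(dplyr::mutate(out, bin_high = .data$bin_low + width), .data$bin_low)
}

#' @export
print.open_eval <- function(x, ...) {
  cat(sprintf("<open_eval> [%s] mean precision@%d = %.3f +/- %.3f (SEM, n=%d)\n",
              x$model_tag, x$k, x$mean, x$sem, nrow(x$per_concept)))
  invisible(x)
}

#' Logical-leap retrieval of second-order associates
#'
#' Retrieves concepts likely to be connected to the cue through a shared
#' predication partner (a "middle term") *without* enumerating middle terms:
#' second-order structure is already encoded in the semantic vectors, so a
#' plain nearest-neighbor search among semantic vectors surfaces it. By
#' default, concepts that share a direct predication with the cue are
#' excluded, leaving only genuinely second-order candidates.
#'
#' @param model A `psi_model`.
#' @param cue Concept identifier; must have a semantic vector (i.e. occur in
#'   at least one predication).
#' @param k Number of candidates.
#' @param exclude_direct Exclude direct predication partners? Default `TRUE`.
#' @return A `discovery_report` tibble.
#' @export
logical_leap <- function(model, cue, k = 10, exclude_direct = TRUE) {
  stopifnot(inherits(model, "psi_model"))
  s <- model$store$semantic
  if (!cue %in% colnames(s)) {
    abort(sprintf("concept '%s' occurs in no predication: no semantic vector", cue))
  }
  screened <- if (exclude_direct) unique(concept_links(model$pdb, cue)$other) else character()
  ranked_report(s, s[, cue], k, cues = cue, screened_names = screened,
                tag = "PSI", params = list(k = k, screen = "predication"))
}

#' Recover the middle term linking two concepts
#'
#' Closed discovery in the predication space: the query is the normalized
#' sum of the semantic vectors of `a` and `b`, and candidates are ranked in
#' the *elemental* layer -- the concept whose elemental vector both semantic
#' vectors accumulated is exactly the shared predication partner. Each
#' candidate is verified against the predication database: `verified` is
#' `TRUE` iff the candidate occurs in at least one predication with `a` and
#' at least one with `b`, i.e. iff it completes an explicit chain of
#' predications between them.
#'
#' @param model A `psi_model`.
#' @param a,b Concept identifiers with semantic vectors.
#' @param k Number of candidates (default 1: the single most strongly
#'   associated middle term).
#' @param pdb Predication database used for verification (defaults to the
#'   model's).
#' @return A tibble with columns `concept`, `cosine`, `verified`.
#' @export
middle_term <- function(model, a, b, k = 1, pdb = model$pdb) {
  stopifnot(inherits(model, "psi_model"))
  s <- model$store$semantic
  for (x in c(a, b)) {
    if (!x %in% colnames(s)) abort(sprintf("unknown concept: %s", x))
  }
  q <- s[, a] + s[, b]
  res <- knn_matrix(model$store$elemental, q, k, exclude = c(a, b))
  tibble(
    concept = res$name, cosine = res$cosine,
    verified = unname(vapply(res$name, function(mid) {
      nrow(predication_link(pdb, a, mid)) > 0 && nrow(predication_link(pdb, b, mid)) > 0
    }, logical(1)))
  )
}

#' Find bridging concepts for an indirect pair
#'
#' Closed discovery in an occurrence-based space: ranks the nearest semantic
#' neighbors of the normalized sum of the vectors of `a` and `b`, and marks
#' each candidate `verified` iff it co-occurs directly with *both* `a` and
#' `b` in the past corpus -- i.e. iff it is an explicit bridge between the
#' two literatures.
#'
#' @param model An `rri_model` (any model with concept semantic vectors
#'   works).
#' @param a,b Concept identifiers.
#' @param k Number of candidates (default 10).
#' @param past_odb `occurrence_db` used for verification.
#' @return A tibble with columns `concept`, `cosine`, `verified`.
#' @export
bridging_concepts <- function(model, a, b, k = 10, past_odb) {
  stopifnot(inherits(past_odb, "occurrence_db"))
  m <- semantic_concept_matrix(model)
  for (x in c(a, b)) {
    if (!x %in% colnames(m)) abort(sprintf("unknown concept: %s", x))
  }
  q <- m[, a] + m[, b]
  res <- knn_matrix(m, q, k, exclude = c(a, b))
  tibble(
    concept = res$name, cosine = res$cosine,
    verified = unname(vapply(res$name, function(mid) {
      direct_cooccurrence(past_odb, a, mid) && direct_cooccurrence(past_odb, b, mid)
    }, logical(1)))
  )
}

#' Link multiple concepts through a scaled association network
#'
#' Retrieves the `k` nearest neighbors of the combined cue vector, forms the
#' pairwise cosine matrix over the group (cues included), converts it to
#' distances, and applies Pathfinder scaling so that only the most
#' significant associations remain -- typically a sparse, tree-like network
#' in which the cues are connected through interposed concepts. For a
#' predication space, every retained edge is annotated with the predicates
#' directly linking its endpoints, and edges supported by no predication at
#' all are pruned (a purely geometric association between concepts that
#' never occur in a predication together is not shown as a link).
#'
#' @param model An `rri_model` or `psi_model`.
#' @param cues Two or more concept identifiers.
#' @param k Neighbors of the combined vector to include.
#' @param params A [pathfinder_params()].
#' @return A `proximity_network`; its `edges` tibble gains `cosine` and (for
#'   predication spaces) `predicates` columns.
#' @export
link_concepts <- function(model, cues, k = 10, params = pathfinder_params()) {
  if (length(cues) < 2L) abort("`link_concepts()` needs at least two cues")
  m <- semantic_concept_matrix(model)
  q <- combined_cue_vector(model, cues)
  if (inherits(model, "psi_model")) {
    # Direct partners surface in the elemental layer, second-order relatives
    # in the semantic layer; the linking group needs both.
    nb_sem <- knn_matrix(m, q, k, exclude = cues)
    en <- normalize_columns(model$store$elemental, warn_zero = FALSE)
    en <- en[, colnames(en) %in% colnames(m), drop = FALSE]
    nb_ele <- knn_matrix(en, q, k, exclude = cues)
    group <- unique(c(cues, nb_ele$name, nb_sem$name))
    # proximity along predication structure: symmetrized semantic-elemental
    raw <- crossprod(m[, group, drop = FALSE], en[, group, drop = FALSE])
    cos_mat <- (raw + t(raw)) / 2
    diag(cos_mat) <- 1
  } else {
    nb <- knn_matrix(m, q, k, exclude = cues)
    group <- c(cues, nb$name)
    cos_mat <- crossprod(m[, group, drop = FALSE])
  }
  dist_mat <- cosine_to_distance(cos_mat, params$transform)
  net <- pfnet(dist_mat, params)
  if (nrow(net$edges)) {
    net$edges$cosine <- cos_mat[cbind(match(net$edges$from, group),
                                      match(net$edges$to, group))]
  } else {
    net$edges$cosine <- double()
  }
  if (inherits(model, "psi_model")) {
    support <- vapply(seq_len(nrow(net$edges)), function(i) {
      links <- predication_link(model$pdb, net$edges$from[i], net$edges$to[i])
      if (nrow(links) == 0L) NA_character_ else paste(unique(links$predicate), collapse = ";")
    }, NA_character_)
    net$edges$predicates <- support
    net$edges <- net$edges[!is.na(support), , drop = FALSE]
  }
  net
}

#' One-sided paired permutation test
#'
#' Sign-flip permutation test that the paired differences `x - y` have mean
#' greater than zero; used to compare per-concept precisions of two models
#' over the same test concepts.
#'
#' @param x,y Numeric vectors of equal length (paired observations).
#' @param n_perm Number of sign-flip permutations.
#' @param seed Integer seed.
#' @return The permutation p-value (add-one corrected).
#' @export
paired_permutation_pvalue <- function(x, y, n_perm = 5000, seed = 1L) {
  if (length(x) != length(y)) abort("`x` and `y` must be paired (equal length)")
  d <- x - y
  obs <- mean(d)
  ge <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      mean(d * sample(c(-1, 1), length(d), replace = TRUE)) >= obs
    }, logical(1)))
  })
  (1 + ge) / (n_perm + 1)
}
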