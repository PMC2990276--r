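#' Configuration of a semantic vector space
#'
#' All spaces in semleap share one configuration: the dimensionality `d` of
#' every vector, the number `s` of non-zero entries in each sparse ternary
#' elemental vector (`s/2` entries of +1 and `s/2` of -1), a global seed from
#' which every elemental vector and predicate permutation is derived
#' deterministically, and the global term-weighting scheme applied when
#' occurrence-based document vectors are accumulated.
#'
#' Elemental vectors are near-orthogonal by construction: for the default
#' `d = 500`, `s = 10`, the expected absolute cosine between two random
#' elemental vectors is about 0.02.
#'
#' @param dimension Vector dimensionality `d` (default 500).
#' @param seed_count Number `s` of non-zero entries per elemental vector;
#'   must be positive and even (default 10).
#' @param global_seed Integer seed; the sole source of randomness for
#'   elemental vectors and permutations.
#' @param weighting Global weighting applied to token elemental vectors when
#'   building document vectors: `"idf"` (log(N/df), the default), `"none"`,
#'   or `"log_entropy"`.
#' @return An object of class `space_config`.
#' @export
#' @examples
#' cfg <- space_config(dimension = 100, global_seed = 7)
#' e <- elemental_vector("merlot", cfg)
#' sum(e != 0)
space_config <- function(dimension = 500L, seed_count = 10L, global_seed = 1L,
                         weighting = c("idf", "none", "log_entropy")) {
  weighting <- match.arg(weighting)
  dimension <- as.integer(dimension)
  seed_count <- as.integer(seed_count)
  if (is.na(dimension) || dimension < 1L) abort("`dimension` must be a positive integer")
  if (is.na(seed_count) || seed_count < 2L || seed_count %% 2L != 0L) {
    abort("`seed_count` must be a positive even integer")
  }
  if (seed_count > dimension) {
    abort(sprintf("seed_count (%d) exceeds dimension (%d): infeasible sparsity",
                  seed_count, dimension))
  }
  structure(
    list(dimension = dimension, seed_count = seed_count,
         global_seed = as.integer(global_seed), weighting = weighting),
    class = "space_config"
  )
}

#' @export
print.space_config <- function(x, ...) {
  cat(sprintf("<space_config> d=%d, s=%d, seed=%d, weighting=%s\n",
              x$dimension, x$seed_count, x$global_seed, x$weighting))
  invisible(x)
}

#' Deterministic sparse ternary elemental vectors
#'
#' An elemental vector is a fixed random signature assigned to a term,
#' concept, or other named entity: `s` of its `d` coordinates are non-zero,
#' half +1 and half -1. It is a pure function of the owner name and the
#' global seed, so it can be regenerated at any time without storage and is
#' unaffected by the order in which a corpus is traversed. Distinct names
#' yield near-orthogonal vectors with high probability, which is what lets a
#' sum of elemental vectors act as a reduced-dimensional record of the set of
#' names it contains.
#'
#' @param name Owner name (non-empty string).
#' @param names Character vector of owner names.
#' @param config A [space_config()].
#' @return `elemental_vector()`: a numeric vector of length `d`.
#'   `elemental_matrix()`: a `d x length(names)` matrix with `names` as
#'   column names.
#' @export
elemental_vector <- function(name, config) {
  drop(elemental_matrix(name, config))
}

#' @rdname elemental_vector
#' @export
elemental_matrix <- function(names, config) {
  stopifnot(inherits(config, "space_config"))
  names <- as.character(names)
  if (length(names) == 0L) {
    return(matrix(0, config$dimension, 0))
  }
  if (anyNA(names) || any(!nzchar(names))) abort("owner names must be non-empty")
  cs <- .elemental_coords(names, config$dimension, config$seed_count,
                          as.double(config$global_seed))
  m <- matrix(0, config$dimension, length(names), dimnames = list(NULL, names))
  idx <- cbind(as.vector(cs$coords),
               rep(seq_along(names), each = config$seed_count))
  m[idx] <- as.vector(cs$signs)
  m
}

#' Cosine similarity
#'
#' The normalized scalar product of two vectors of equal dimension; the
#' association metric used throughout the package.
#'
#' @param u,v Numeric vectors of the same length; neither may be all-zero.
#' @return A number in `[-1, 1]`.
#' @export
cosine <- function(u, v) {
  if (length(u) != length(v)) abort("vectors differ in dimension")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("cosine is undefined for an all-zero vector")
  sum(u * v) / (nu * nv)
}

# Normalize columns of a matrix to unit Euclidean norm; zero columns dropped.
normalize_columns <- function(m, warn_zero = TRUE) {
  nrm <- sqrt(colSums(m^2))
  zero <- nrm < 1e-12
  if (any(zero) && warn_zero) {
    inform(sprintf("dropping %d zero-content vector(s): %s",
                   sum(zero), paste(head(colnames(m)[zero], 5), collapse = ", ")))
  }
  m <- m[, !zero, drop = FALSE]
  sweep(m, 2, nrm[!zero], "/")
}

#' Create a vector store
#'
#' A vector store holds two layers of named vectors sharing one
#' [space_config()]: an *elemental* layer of sparse ternary signatures and a
#' *semantic* layer of dense, unit-norm learned vectors. All similarity
#' search ([knn()]) is an exhaustive cosine scan, so results are exact.
#'
#' @param config A [space_config()].
#' @param elemental,semantic Optional `d x n` matrices with column names.
#' @return An object of class `vector_store`.
#' @export
vector_store <- function(config, elemental = NULL, semantic = NULL) {
  stopifnot(inherits(config, "space_config"))
  d <- config$dimension
  elemental <- elemental %||% matrix(0, d, 0)
  semantic <- semantic %||% matrix(0, d, 0)
  for (m in list(elemental, semantic)) {
    if (nrow(m) != d) abort("layer dimension does not match config")
    if (ncol(m) > 0 && anyDuplicated(colnames(m))) abort("duplicate vector names in a layer")
  }
  structure(list(config = config, elemental = elemental, semantic = semantic),
            class = "vector_store")
}

#' @export
print.vector_store <- function(x, ...) {
  cat(sprintf("<vector_store> d=%d | %d elemental, %d semantic vectors\n",
              x$config$dimension, ncol(x$elemental), ncol(x$semantic)))
  invisible(x)
}

#' Exact k-nearest-neighbor search by cosine
#'
#' Ranks every vector in the requested layer by cosine similarity to the
#' query and returns the top `k`, excluding any names in `exclude`. Ties are
#' broken lexicographically by name so output is deterministic. The scan is
#' exhaustive; no approximate indexing is used.
#'
#' @param store A [vector_store()] (or an object with one at `$store`).
#' @param query Numeric vector of length `d`.
#' @param k Number of neighbors to return (at least 1); fewer are returned
#'   when the layer is small.
#' @param layer `"semantic"` (default) or `"elemental"`.
#' @param exclude Character vector of names to leave out of the ranking.
#' @return A tibble with columns `name` and `cosine`, in descending cosine
#'   order.
#' @export
knn <- function(store, query, k = 10, layer = c("semantic", "elemental"),
                exclude = character()) {
  layer <- match.arg(layer)
  if (inherits(store, c("rri_model", "psi_model"))) store <- store$store
  stopifnot(inherits(store, "vector_store"))
  m <- store[[layer]]
  if (ncol(m) == 0) abort(sprintf("the %s layer is empty", layer))
  knn_matrix(m, query, k, exclude)
}

# Rank columns of `m` by cosine to `query`; exact exhaustive scan.
knn_matrix <- function(m, query, k, exclude = character()) {
  if (k < 1) abort("`k` must be at least 1")
  if (length(query) != nrow(m)) abort("query dimension does not match store")
  qn <- sqrt(sum(query^2))
  if (qn == 0) abort("cosine is undefined for an all-zero query")
  keep <- !(colnames(m) %in% exclude)
  m <- m[, keep, drop = FALSE]
  if (ncol(m) == 0) {
    return(tibble(name = character(), cosine = double()))
  }
  sims <- as.vector(crossprod(m, query)) / (sqrt(colSums(m^2)) * qn)
  ord <- order(-sims, colnames(m))
  top <- head(ord, k)
  tibble(name = colnames(m)[top], cosine = sims[top])
}

#' Save and load vector stores
#'
#' `save_store()` serializes a [vector_store()] (or a fitted model carrying
#' one) with a validated header; `load_store()` restores it bit-exactly,
#' refusing files that are not semleap stores or whose layers disagree with
#' their recorded dimension. `export_store_text()` writes a plain-text
#' interoperability dump: one line per vector, `layer name v1 ... vd`.
#'
#' @param x A [vector_store()], [build_rri()] or [build_psi()] result.
#' @param path File path.
#' @return `load_store()` returns the saved object; others return `path`
#'   invisibly.
#' @export
save_store <- function(x, path) {
  payload <- list(magic = "semleap-store", format = 1L, object = x)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_store
#' @export
load_store <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  payload <- tryCatch(readRDS(path), error = function(e) {
    abort(sprintf("'%s' is not a readable semleap store (%s)", path, conditionMessage(e)))
  })
  if (!is.list(payload) || !identical(payload$magic, "semleap-store")) {
    abort(sprintf("'%s' is not a semleap store: bad header", path))
  }
  obj <- payload$object
  st <- if (inherits(obj, "vector_store")) obj else obj$store
  if (!inherits(st, "vector_store")) abort("store payload is corrupted")
  d <- st$config$dimension
  if (nrow(st$elemental) != d || nrow(st$semantic) != d) {
    abort("store payload is corrupted: layer dimension mismatch")
  }
  obj
}

#' @rdname save_store
#' @export
export_store_text <- function(x, path) {
  st <- if (inherits(x, "vector_store")) x else x$store
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#semleap-store d=%d s=%d seed=%d weighting=%s",
                     st$config$dimension, st$config$seed_count,
                     st$config$global_seed, st$config$weighting), con)
  for (layer in c("elemental", "semantic")) {
    m <- st[[layer]]
    for (j in seq_len(ncol(m))) {
      writeLines(paste(layer, colnames(m)[j],
                       paste(formatC(m[, j], format = "g", digits = 17), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}
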