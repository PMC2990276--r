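#' Pathfinder scaling parameters
#'
#' Pathfinder network scaling keeps an edge only when no admissible path
#' between its endpoints is cheaper under the Minkowski r-metric: the cost
#' of a path is `(sum(w_i^r))^(1/r)`, reducing to the maximum edge weight
#' when `r = Inf`. `q` bounds the number of edges a competing path may use.
#' The defaults `r = Inf`, `q = n - 1` give the sparsest standard network
#' (which always contains a minimum spanning tree of the input), appropriate
#' for legible displays of concept associations.
#'
#' @param r Minkowski exponent, `>= 1` (default `Inf`).
#' @param q Maximum path length in edges, between 2 and `n - 1`; `NULL`
#'   (default) means `n - 1`.
#' @param transform How cosine similarities become distances:
#'   `"one_minus_cosine"` (`d = 1 - cos`, the default) or `"inverse_cosine"`
#'   (`d = 1/cos` for positive cosines, no edge otherwise). The two agree in
#'   rank order but not in sums, so they can differ for finite `r`.
#' @return An object of class `pathfinder_params`.
#' @export
pathfinder_params <- function(r = Inf, q = NULL,
                              transform = c("one_minus_cosine", "inverse_cosine")) {
  transform <- match.arg(transform)
  if (!is.numeric(r) || length(r) != 1L || r < 1) abort("`r` must be a number >= 1")
  if (!is.null(q)) {
    q <- as.integer(q)
    if (is.na(q) || q < 2L) abort("`q` must be at least 2")
  }
  structure(list(r = r, q = q, transform = transform), class = "pathfinder_params")
}

#' Convert a cosine similarity matrix to distances
#'
#' @param cos_mat Symmetric cosine matrix with unit diagonal.
#' @param transform See [pathfinder_params()].
#' @return A symmetric non-negative distance matrix with zero diagonal;
#'   non-positive cosines map to `Inf` (no edge) under `"inverse_cosine"`.
#' @export
cosine_to_distance <- function(cos_mat,
                               transform = c("one_minus_cosine", "inverse_cosine")) {
  transform <- match.arg(transform)
  cos_mat <- as.matrix(cos_mat)
  d <- switch(transform,
    one_minus_cosine = pmax(1 - cos_mat, 0),
    inverse_cosine = ifelse(cos_mat > 0, 1 / cos_mat, Inf)
  )
  diag(d) <- 0
  # symmetrize away floating-point asymmetry from crossprod
  (d + t(d)) / 2
}

# min over k of rcompose(D[i,k], A[k,j]); rcompose is + on the w^r scale or
# max when r = Inf.
compose_paths <- function(d, a, use_max) {
  n <- nrow(d)
  out <- matrix(Inf, n, n)
  for (j in seq_len(n)) {
    m <- if (use_max) pmax(d, matrix(a[, j], n, n, byrow = TRUE))
         else d + matrix(a[, j], n, n, byrow = TRUE)
    out[, j] <- do.call(pmin, lapply(seq_len(n), function(k) m[, k]))
  }
  out
}

#' Pathfinder network scaling (PFNET)
#'
#' Computes the Pathfinder network of a distance matrix: edge `(i, j)` is
#' retained iff its weight does not exceed the cost of any path of at most
#' `q` edges between `i` and `j` under the Minkowski r-metric. Ties (a path
#' exactly as cheap as the edge) retain the edge, which preserves the
#' classical property that the `r = Inf`, `q = n - 1` network contains every
#' minimum-spanning-tree edge. Entries of `Inf` or `NA` denote absent edges.
#'
#' Internally the `q = n - 1` case runs a Floyd-Warshall-style closure under
#' the r-metric (by repeated path doubling), and bounded `q` uses a
#' length-limited dynamic program; both operate on the `w^r` scale so no
#' roots are taken.
#'
#' @param weights Symmetric, non-negative distance matrix with zero
#'   diagonal. Row/column names become node names.
#' @param params A [pathfinder_params()].
#' @return An object of class `proximity_network`: `nodes`, `weights` (the
#'   input), `edges` (tibble `from`, `to`, `weight` with weights unchanged
#'   from the input), and `params`.
#' @export
#' @examples
#' w <- matrix(c(0, 1, 3, 1, 0, 1, 3, 1, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' pfnet(w, pathfinder_params(r = 1))$edges  # a-c beaten by the 2-edge path
pfnet <- function(weights, params = pathfinder_params()) {
  stopifnot(inherits(params, "pathfinder_params"))
  w <- as.matrix(weights)
  n <- nrow(w)
  if (n != ncol(w)) abort("`weights` must be square")
  w[is.na(w)] <- Inf
  if (any(w < 0)) abort("`weights` must be non-negative")
  asym <- !((w == t(w)) | (abs(w - t(w)) <= 1e-9))  # Inf == Inf is symmetric
  asym[is.na(asym)] <- TRUE
  if (any(asym)) abort("`weights` must be symmetric")
  if (any(diag(w) != 0)) abort("`weights` must have a zero diagonal")
  if (is.null(rownames(w))) rownames(w) <- colnames(w) <- paste0("V", seq_len(n))
  nodes <- rownames(w)
  q <- params$q %||% max(n - 1L, 2L)
  q <- min(q, max(n - 1L, 2L))

  use_max <- is.infinite(params$r)
  a <- if (use_max) w else w^params$r
  diag(a) <- Inf  # paths use edges, not the zero self-loop
  d <- a
  if (q >= n - 1L) {
    repeat {  # path doubling to convergence
      nxt <- pmin(d, compose_paths(d, d, use_max))
      if (all(nxt == d)) break
      d <- nxt
    }
  } else {
    len <- 1L
    while (len < q) {
      d <- pmin(d, compose_paths(d, a, use_max))
      len <- len + 1L
    }
  }

  tol <- 1e-9
  retained <- is.finite(a) & a <= d * (1 + tol) + 1e-12
  idx <- which(retained & upper.tri(retained), arr.ind = TRUE)
  edges <- tibble(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                  weight = w[idx])
  structure(list(nodes = nodes, weights = w, edges = edges,
                 params = pathfinder_params(params$r, q, params$transform)),
            class = "proximity_network")
}

#' @export
print.proximity_network <- function(x, ...) {
  cat(sprintf("<proximity_network> %d nodes, %d retained edges (r=%s, q=%d)\n",
              length(x$nodes), nrow(x$edges),
              if (is.infinite(x$params$r)) "Inf" else format(x$params$r),
              x$params$q))
  invisible(x)
}

#' Convert a proximity network to an igraph object
#'
#' @param net A `proximity_network`.
#' @return An undirected `igraph` graph with edge attributes from the
#'   network's edge tibble.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "proximity_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Write and read scaled networks
#'
#' `write_network()` exports a `proximity_network` as GraphML or JSON
#' node-link, preserving node labels and all edge attributes (weight,
#' cosine, predicate annotations). `read_network()` re-reads either format
#' into an equivalent network; the weight matrix is reconstructed from the
#' retained edges (absent pairs become `Inf`).
#'
#' @param net A `proximity_network`.
#' @param path Output path.
#' @param format `"graphml"` or `"json"`.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns a `proximity_network`.
#' @export
write_network <- function(net, path, format = c("graphml", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "proximity_network"))
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    payload <- list(nodes = lapply(net$nodes, function(n) list(id = n)),
                    links = net$edges,
                    params = list(r = if (is.infinite(net$params$r)) "inf" else net$params$r,
                                  q = net$params$q, transform = net$params$transform))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- igraph::V(g)$name
    ed <- igraph::as_data_frame(g, what = "edges")
    edges <- as_tibble(ed)
  } else {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    nodes <- if (length(payload$nodes)) payload$nodes$id else character()
    edges <- as_tibble(payload$links)
    if (nrow(edges) == 0L) edges <- tibble(from = character(), to = character(),
                                           weight = double())
  }
  w <- matrix(Inf, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  diag(w) <- 0
  if (nrow(edges)) {
    i <- match(edges$from, nodes); j <- match(edges$to, nodes)
    w[cbind(i, j)] <- w[cbind(j, i)] <- edges$weight
  }
  structure(list(nodes = nodes, weights = w, edges = edges,
                 params = pathfinder_params()),
            class = "proximity_network")
}
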