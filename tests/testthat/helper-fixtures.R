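# Small programmatic fixtures and independent brute-force oracles shared
# across the suite. Oracles deliberately avoid the package's own index
# structures and matrix shortcuts.

make_pdb <- function(subject, predicate, object, citation = NULL) {
  n <- length(subject)
  predication_db(tibble::tibble(
    subject_id = subject, subject_name = subject,
    predicate = predicate, object_id = object, object_name = object,
    citation_id = citation %||% sprintf("PMID:%03d", seq_len(n))
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

random_pdb <- function(n_preds, n_concepts, seed = 1) {
  withr::with_seed(seed, {
    pool <- sprintf("c%03d", seq_len(n_concepts))
    s <- sample(pool, n_preds, replace = TRUE)
    o <- sample(pool, n_preds, replace = TRUE)
    while (any(s == o)) o[s == o] <- sample(pool, sum(s == o), replace = TRUE)
    make_pdb(s, sample(c("INTERACTS_WITH", "CAUSES", "TREATS"), n_preds, TRUE), o)
  })
}

random_odb <- function(n_citations, n_concepts, mean_size = 4, seed = 1) {
  withr::with_seed(seed, {
    pool <- sprintf("c%03d", seq_len(n_concepts))
    sets <- lapply(seq_len(n_citations), function(i) {
      unique(sample(pool, min(1 + rpois(1, mean_size - 1), n_concepts)))
    })
    names(sets) <- sprintf("cit%04d", seq_len(n_citations))
    occurrence_db(sets)
  })
}

# Exhaustive co-occurrence scan straight over the citation sets.
oracle_cooccur <- function(odb, a, b) {
  any(vapply(odb$concepts, function(cs) (a %in% cs) && (b %in% cs), logical(1)))
}

# Exhaustive predication-link scan over the raw predication rows.
oracle_link <- function(pdb, a, b) {
  p <- pdb$predications
  out <- list()
  for (i in seq_len(nrow(p))) {
    if (p$subject_id[i] == a && p$object_id[i] == b) {
      out[[length(out) + 1]] <- c(p$predicate[i], "subject")
    }
    if (p$object_id[i] == a && p$subject_id[i] == b) {
      out[[length(out) + 1]] <- c(p$predicate[i], "object")
    }
  }
  unique(out)
}

# Rank every column of `m` against `query` using scalar cosine() calls only.
oracle_rank <- function(m, query, exclude = character()) {
  nm <- setdiff(colnames(m), exclude)
  sims <- vapply(nm, function(n) cosine(m[, n], query), 0)
  nm[order(-sims, nm)]
}

# Pathfinder oracle: edge (i,j) is removed iff some simple path of <= q edges
# costs strictly less than the direct weight under the Minkowski r-metric.
# DFS enumeration of simple paths with monotone-cost pruning at the edge's
# own weight (sound for r >= 1 and positive weights).
oracle_pfnet_edges <- function(w, r, q) {
  n <- nrow(w)
  pcost <- function(ws) if (is.infinite(r)) max(ws) else sum(ws^r)^(1 / r)
  beaten <- function(i, j) {
    target_cost <- w[i, j]
    found <- FALSE
    visited <- rep(FALSE, n)
    dfs <- function(v, ws) {
      if (found) return()
      for (u in seq_len(n)) {
        if (visited[u] || is.infinite(w[v, u]) || u == i) next
        ws2 <- c(ws, w[v, u])
        if (length(ws2) > q) next
        cost <- pcost(ws2)
        if (cost >= target_cost - 1e-9) next  # monotone: extensions only grow
        if (u == j) { found <<- TRUE; return() }
        visited[u] <<- TRUE
        dfs(u, ws2)
        visited[u] <<- FALSE
      }
    }
    visited[i] <- TRUE
    # direct edge is a 1-edge path of cost == target; competitors need >= 2 edges
    dfs(i, numeric(0))
    found
  }
  keep <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (is.finite(w[i, j]) && !beaten(i, j)) keep[[length(keep) + 1]] <- c(i, j)
    }
  }
  keep
}

random_distance_matrix <- function(n, density = 0.5, seed = 1) {
  withr::with_seed(seed, {
    w <- matrix(Inf, n, n, dimnames = list(paste0("n", 1:n), paste0("n", 1:n)))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (runif(1) < density) w[i, j] <- w[j, i] <- runif(1, 0.1, 1)
      }
    }
    diag(w) <- 0
    w
  })
}

edge_set <- function(net) {
  if (nrow(net$edges) == 0) return(character())
  sort(paste(pmin(net$edges$from, net$edges$to), pmax(net$edges$from, net$edges$to)))
}
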