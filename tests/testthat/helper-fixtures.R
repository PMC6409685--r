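# Fixture builders and independent oracles shared across the suite.

# Quick network from a vector of "a-b" edge strings.
net_of <- function(...) {
  pairs <- strsplit(c(...), "-", fixed = TRUE)
  ppi_network(tibble::tibble(
    from = vapply(pairs, `[[`, character(1), 1),
    to = vapply(pairs, `[[`, character(1), 2)
  ))
}

# Weighted digraph straight from vectors (directed rows).
weighted_of <- function(from, to, ecc, bio, nodes = NULL) {
  w <- tibble::tibble(from = from, to = to, ecc_weight = ecc, bio_weight = bio)
  attr(w, "nodes") <- nodes %||% sort(unique(c(from, to)))
  class(w) <- c("weighted_ppi", class(w))
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Erdos-Renyi ppi_network on n labelled nodes.
random_net <- function(n, p) {
  pairs <- utils::combn(sprintf("N%02d", seq_len(n)), 2)
  keep <- stats::runif(ncol(pairs)) < p
  ppi_network(
    tibble::tibble(from = pairs[1, keep], to = pairs[2, keep]),
    nodes = sprintf("N%02d", seq_len(n))
  )
}

# Brute-force ECC oracle: explicit common-neighbour enumeration.
ecc_brute <- function(net, u, v) {
  e <- net$edges
  nbr <- function(x) unique(c(e$to[e$from == x], e$from[e$to == x]))
  nu <- nbr(u)
  nv <- nbr(v)
  (length(intersect(nu, nv)) + 1) / min(length(nu), length(nv))
}

# Exhaustive-path Wang oracle: S_A(t) = max over all child-to-parent paths
# from A to t of the product of contribution factors along the path.
wang_brute <- function(dag, term) {
  e <- dag$edges
  fac <- dag$factors
  best <- new.env(parent = emptyenv())
  walk <- function(t, value) {
    if (is.null(best[[t]]) || value > best[[t]]) best[[t]] <- value
    up <- which(e$child == t)
    for (k in up) walk(e$parent[k], value * fac[[e$relation[k]]])
  }
  walk(term, 1)
  s <- unlist(as.list(best))
  s[order(names(s))]
}

go_similarity_brute <- function(dag, ann, u, v) {
  svec <- function(p) {
    terms <- ann$term[ann$protein == p]
    out <- numeric(0)
    for (t in terms) {
      s <- wang_brute(dag, t)
      all_t <- union(names(out), names(s))
      out <- pmax(out[all_t], s[all_t], na.rm = TRUE)
      names(out) <- all_t
    }
    out
  }
  su <- svec(u)
  sv <- svec(v)
  if (length(su) == 0 || length(sv) == 0) return(0)
  shared <- intersect(names(su), names(sv))
  (sum(su[shared]) + sum(sv[shared])) / (sum(su) + sum(sv))
}

# Random DAG on k terms; edges always child(higher index) -> parent(lower),
# so acyclicity holds by construction.
random_dag <- function(k, extra = 0.3) {
  terms <- sprintf("T%02d", seq_len(k))
  child <- integer(0)
  parent <- integer(0)
  for (i in seq_len(k)[-1]) {
    n_par <- sample(1:min(2, i - 1), 1)
    parent <- c(parent, sample(seq_len(i - 1), n_par))
    child <- c(child, rep(i, n_par))
  }
  rel <- sample(c("is_a", "part_of"), length(child), replace = TRUE,
                prob = c(1 - extra, extra))
  go_dag(terms, tibble::tibble(
    child = terms[child], parent = terms[parent], relation = rel
  ))
}

as_annotations <- function(df) {
  class(df) <- c("go_annotations", class(df))
  df
}

# Dense eigen-decomposition oracle for the two-channel HITS fixed point.
# B, E are from->to weight matrices; the iteration drives the authority
# vector with t(B) %*% t(E) and the hub vector with t(E) %*% t(B).
hits_eigen_oracle <- function(wnet) {
  nodes <- attr(wnet, "nodes")
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  B <- matrix(0, n, n)
  E <- matrix(0, n, n)
  B[cbind(idx[wnet$from], idx[wnet$to])] <- wnet$bio_weight
  E[cbind(idx[wnet$from], idx[wnet$to])] <- wnet$ecc_weight
  dominant <- function(M) {
    eg <- eigen(M)
    v <- Re(eg$vectors[, which.max(abs(Re(eg$values)))])
    v <- abs(v)
    v / max(v)
  }
  list(
    authority = dominant(t(B) %*% t(E)),
    hub = dominant(t(E) %*% t(B)),
    nodes = nodes
  )
}

# Random two-channel weighted digraph on <= n_max nodes with strictly
# positive weights. A directed n-cycle plus one chord closing an
# (n-1)-cycle keeps both channel matrices primitive (irreducible and
# aperiodic - the Perron regime where the fixed point is unique); random
# extra arcs provide the asymmetry.
random_weighted_digraph <- function(n_max = 8, p = 0.5) {
  n <- sample(3:n_max, 1)
  nodes <- sprintf("N%d", seq_len(n))
  cyc <- data.frame(
    from = c(nodes, nodes[n]),
    to = c(nodes[c(2:n, 1)], nodes[2])
  )
  grid <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, ]
  grid <- grid[!(paste(grid$from, grid$to) %in% paste(cyc$from, cyc$to)), ]
  g <- rbind(cyc, grid[stats::runif(nrow(grid)) < p, ])
  weighted_of(
    g$from, g$to,
    ecc = stats::runif(nrow(g), 0.1, 1),
    bio = stats::runif(nrow(g), 0.1, 3),
    nodes = nodes
  )
}
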