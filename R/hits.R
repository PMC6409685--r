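#' Weighted HITS iteration on a two-channel digraph
#'
#' Runs the hub/authority iteration on the weighted bidirectional network.
#' The authority score of a protein aggregates biological evidence and the
#' hub score aggregates topology: at iteration m,
#' \deqn{a_m(v) = \sum_{(u,v)} bio(u,v) \, h_{m-1}(u), \qquad
#'       h_m(v) = \sum_{(u,v)} ecc(u,v) \, a_{m-1}(u),}
#' after which each vector is divided by its maximum. Iteration stops when
#' the summed L1 change \eqn{|a_m - a_{m-1}| + |h_m - h_{m-1}|} drops below
#' `gamma`, or at `max_iter`. With non-negative weights the scores stay
#' non-negative and, after normalization, the maximum of each vector is
#' exactly 1 (Perron-Frobenius regime: the fixed point is the dominant
#' eigenvector of the channel-product matrix, max-normalized).
#'
#' In the network produced by [build_weighted_network()] both channels are
#' symmetric per edge, so the result does not depend on how the two
#' directions of an interaction were ordered in the input file.
#'
#' @param wnet A `weighted_ppi` tibble (columns `from`, `to`, `ecc_weight`,
#'   `bio_weight`; rows are directed edges). Weights must be non-negative and
#'   each channel must carry at least one positive weight.
#' @param gamma Convergence tolerance on the summed L1 change (> 0).
#' @param max_iter Maximum number of iterations (>= 1).
#' @param initial Initial score assigned to every protein (default 1, the
#'   standard HITS start).
#' @return A tibble of class `hsep_hits` with columns `protein`, `authority`,
#'   `hub`, plus attributes `iterations` (integer) and `converged` (logical).
#' @examples
#' net <- ppi_network(data.frame(c("A", "A"), c("B", "C")))
#' w <- build_weighted_network(net)  # topology only: bio defaults to 0
#' @export
weighted_hits <- function(wnet, gamma = 1e-10, max_iter = 1000, initial = 1) {
  if (!is.data.frame(wnet) ||
      !all(c("from", "to", "ecc_weight", "bio_weight") %in% names(wnet))) {
    abort("`wnet` must have columns from, to, ecc_weight, bio_weight.")
  }
  if (nrow(wnet) == 0) abort("Empty weighted network.")
  if (gamma <= 0) abort("`gamma` must be positive.")
  if (max_iter < 1) abort("`max_iter` must be at least 1.")
  if (any(wnet$ecc_weight < 0) || any(wnet$bio_weight < 0)) {
    abort("HITS requires non-negative edge weights.")
  }
  if (all(wnet$bio_weight == 0)) abort("Degenerate channel: all bio weights are zero.")
  if (all(wnet$ecc_weight == 0)) abort("Degenerate channel: all ecc weights are zero.")

  nodes <- attr(wnet, "nodes") %||% sort(unique(c(wnet$from, wnet$to)))
  n <- length(nodes)
  idx <- setNames(seq_len(n), nodes)
  i <- idx[wnet$from]
  j <- idx[wnet$to]
  B <- Matrix::sparseMatrix(i = i, j = j, x = wnet$bio_weight, dims = c(n, n))
  E <- Matrix::sparseMatrix(i = i, j = j, x = wnet$ecc_weight, dims = c(n, n))

  a <- rep(initial, n)
  h <- rep(initial, n)
  converged <- FALSE
  iter <- 0L
  for (m in seq_len(max_iter)) {
    iter <- m
    a_new <- as.numeric(Matrix::crossprod(B, h))  # a(v) = sum_u bio(u,v) h(u)
    h_new <- as.numeric(Matrix::crossprod(E, a))  # h(v) = sum_u ecc(u,v) a(u)
    if (max(a_new) == 0 || max(h_new) == 0) {
      abort("Degenerate channel: score vector collapsed to zero during iteration.")
    }
    a_new <- a_new / max(a_new)
    h_new <- h_new / max(h_new)
    delta <- sum(abs(a_new - a)) + sum(abs(h_new - h))
    a <- a_new
    h <- h_new
    if (delta < gamma) {
      converged <- TRUE
      break
    }
  }
  out <- tibble(protein = nodes, authority = a, hub = h)
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  class(out) <- c("hsep_hits", class(out))
  out
}

#' Write HITS scores to TSV
#'
#' @param hits A `hsep_hits` tibble from [weighted_hits()].
#' @param path Output path (columns: protein, authority, hub).
#' @return `path`, invisibly.
#' @export
write_hits_scores <- function(hits, path) {
  stopifnot(inherits(hits, "hsep_hits"))
  readr::write_tsv(as_tibble(hits), path)
  invisible(path)
}
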