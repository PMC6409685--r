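#' Run the full essential-protein ranking pipeline
#'
#' Convenience wrapper chaining the whole method: weight the network
#' ([build_weighted_network()]), run the weighted HITS iteration
#' ([weighted_hits()]), score every protein at each alpha of the grid
#' ([hsep_score()]) and combine the top-`top_n` candidate lists by ensemble
#' majority vote ([ensemble_vote()]).
#'
#' @inheritParams build_weighted_network
#' @param alpha_grid Mixing weights; default the 11-point grid
#'   \{0, 0.1, ..., 1\}.
#' @param top_n Top-list size per ranking; default the top 1% of the network
#'   ([top_fraction_count()]).
#' @param threshold Vote threshold T (strict majority with the default grid).
#' @param gamma,max_iter Convergence controls for [weighted_hits()].
#' @return A list of class `hsep_result` with elements `weighted` (the
#'   weighted digraph), `hits`, `rankings` (one per alpha) and `ensemble`.
#' @export
rank_essential_proteins <- function(net, expr = NULL, dag = NULL, ann = NULL,
                                    loc = NULL, mode = c("hsep", "hsp"),
                                    alpha_grid = seq(0, 1, by = 0.1),
                                    top_n = NULL, threshold = 5,
                                    gamma = 1e-10, max_iter = 1000) {
  mode <- match.arg(mode)
  wnet <- build_weighted_network(net, expr, dag, ann, loc, mode = mode)
  hits <- weighted_hits(wnet, gamma = gamma, max_iter = max_iter)
  top_n <- top_n %||% top_fraction_count(length(net$nodes), 0.01)
  rankings <- purrr::map(alpha_grid, function(a) hsep_score(hits, a))
  ensemble <- ensemble_vote(rankings, n = top_n, threshold = threshold)
  structure(
    list(weighted = wnet, hits = hits, rankings = rankings, ensemble = ensemble),
    class = "hsep_result"
  )
}

#' @export
print.hsep_result <- function(x, ...) {
  cat(sprintf(
    "<hsep_result> %d proteins; HITS %s in %d iteration(s); %d predicted essential\n",
    nrow(x$hits),
    if (attr(x$hits, "converged")) "converged" else "did not converge",
    attr(x$hits, "iterations"),
    length(x$ensemble$essential_set)
  ))
  invisible(x)
}

#' Consensus ranking of an ensemble
#'
#' Orders proteins by descending vote count, breaking ties by descending
#' mean score over the alpha grid and then by protein identifier. This is the
#' single ranking used when a top-k recovery of the ensemble is needed.
#'
#' @param ensemble A `hsep_ensemble` (or a `hsep_result`, whose ensemble is
#'   used).
#' @return A tibble with columns `protein`, `em`, `mean_score`, `rank`.
#' @export
consensus_ranking <- function(ensemble) {
  if (inherits(ensemble, "hsep_result")) ensemble <- ensemble$ensemble
  stopifnot(inherits(ensemble, "hsep_ensemble"))
  ensemble$votes |> mutate(rank = row_number())
}
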