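#' Blend authority and hub into a single essentiality score
#'
#' The final per-protein score is the convex combination
#' \deqn{score(v) = \alpha \, a(v) + (1 - \alpha) \, h(v),}
#' so `alpha = 1` ranks purely by biological evidence (authority) and
#' `alpha = 0` purely by topology (hub). Ties are broken by ascending
#' protein identifier so top-n cuts are deterministic.
#'
#' @param hits A `hsep_hits` tibble from [weighted_hits()].
#' @param alpha Mixing weight in \[0, 1\].
#' @return A tibble of class `hsep_ranking` with columns `protein`, `score`,
#'   `rank`, sorted by descending score; `alpha` is stored as an attribute.
#' @export
hsep_score <- function(hits, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    abort("`alpha` must be a single number in [0, 1].")
  }
  out <- tibble(
    protein = hits$protein,
    score = alpha * hits$authority + (1 - alpha) * hits$hub
  ) |>
    arrange(desc(.data$score), .data$protein) |>
    mutate(rank = row_number())
  attr(out, "alpha") <- alpha
  class(out) <- c("hsep_ranking", class(out))
  out
}

#' Size of a top-fraction candidate cut
#'
#' Number of proteins in the "top f" of a ranking over `total` proteins:
#' `total * fraction` rounded half-up to the nearest integer, with a floor of
#' one protein. This reproduces the usual printed candidate-set sizes, e.g.
#' the top 1% of 5093 proteins is 51.
#'
#' @param total Number of ranked proteins.
#' @param fraction Fraction in (0, 1].
#' @return An integer count >= 1.
#' @export
top_fraction_count <- function(total, fraction) {
  stopifnot(total >= 1, fraction > 0, fraction <= 1)
  max(1L, as.integer(floor(total * fraction + 0.5)))
}

#' Ensemble majority vote over an alpha grid of rankings
#'
#' Takes the top-`n` candidate list X_i of each ranking (one per mixing
#' weight alpha), counts for every protein the number of lists containing it,
#' \deqn{EM(v) = \sum_i [v \in X_i],}
#' and calls essential the proteins with `EM(v) > threshold` (strictly). The
#' defaults elsewhere in the package follow the standard grid of k = 11
#' alphas \{0, 0.1, ..., 1\} with threshold T = 5, i.e. a strict majority of
#' the lists.
#'
#' @param rankings A list of `hsep_ranking` objects over the same protein
#'   set.
#' @param n Top-list size (<= number of proteins).
#' @param threshold Vote threshold T; a protein is predicted essential iff
#'   its vote count strictly exceeds it.
#' @return An object of class `hsep_ensemble`: a list with `votes` (tibble
#'   `protein`, `em`, `mean_score`, `essential`, sorted by descending `em`,
#'   then descending mean score, then protein ID), `candidate_sets` (the
#'   X_i), `candidate_union`, `essential_set`, `alpha_grid`, `n` and
#'   `threshold`.
#' @export
ensemble_vote <- function(rankings, n, threshold = 5) {
  if (!is.list(rankings) || length(rankings) == 0) {
    abort("`rankings` must be a non-empty list of rankings.")
  }
  node_sets <- purrr::map(rankings, function(r) sort(r$protein))
  if (!all(purrr::map_lgl(node_sets[-1], identical, node_sets[[1]]))) {
    abort("All rankings must cover the same protein set.")
  }
  if (n > length(node_sets[[1]])) abort("`n` exceeds the number of proteins.")
  k <- length(rankings)
  candidate_sets <- purrr::map(rankings, function(r) head(r$protein, n))
  em_tab <- table(unlist(candidate_sets))
  proteins <- node_sets[[1]]
  em <- as.integer(em_tab[proteins])
  em[is.na(em)] <- 0L
  mean_score <- purrr::reduce(
    purrr::map(rankings, function(r) setNames(r$score, r$protein)[proteins]),
    `+`
  ) / k
  votes <- tibble(
    protein = proteins, em = em, mean_score = unname(mean_score),
    essential = em > threshold
  ) |>
    arrange(desc(.data$em), desc(.data$mean_score), .data$protein)
  structure(
    list(
      votes = votes,
      candidate_sets = candidate_sets,
      candidate_union = sort(unique(unlist(candidate_sets))),
      essential_set = votes$protein[votes$essential],
      alpha_grid = purrr::map_dbl(rankings, function(r) attr(r, "alpha") %||% NA_real_),
      n = n,
      threshold = threshold
    ),
    class = "hsep_ensemble"
  )
}

#' @export
print.hsep_ensemble <- function(x, ...) {
  cat(sprintf(
    "<hsep_ensemble> k = %d rankings, top n = %d, threshold T = %d\n",
    length(x$candidate_sets), x$n, as.integer(x$threshold)
  ))
  cat(sprintf(
    "  %d candidates, %d predicted essential (EM > T)\n",
    length(x$candidate_union), length(x$essential_set)
  ))
  invisible(x)
}

#' Write a ranking or ensemble result to TSV
#'
#' @param x A `hsep_ranking` or `hsep_ensemble`.
#' @param path Output path. Rankings: columns protein, score, rank.
#'   Ensembles: columns protein, em, essential (0/1).
#' @return `path`, invisibly.
#' @export
write_ranking <- function(x, path) {
  if (inherits(x, "hsep_ranking")) {
    readr::write_tsv(as_tibble(x), path)
  } else if (inherits(x, "hsep_ensemble")) {
    readr::write_tsv(
      x$votes |> mutate(essential = as.integer(.data$essential)) |>
        select("protein", "em", "essential"),
      path
    )
  } else {
    abort("`x` must be a hsep_ranking or hsep_ensemble.")
  }
  invisible(path)
}
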