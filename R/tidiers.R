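#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy HITS scores
#'
#' @param x A `hsep_hits` object.
#' @param ... Unused.
#' @return A plain tibble with columns `protein`, `authority`, `hub`.
#' @method tidy hsep_hits
#' @export
tidy.hsep_hits <- function(x, ...) {
  as_tibble(unclass_tbl(x))
}

#' One-row summary of a HITS fit
#'
#' @param x A `hsep_hits` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_proteins`, `iterations`, `converged`.
#' @method glance hsep_hits
#' @export
glance.hsep_hits <- function(x, ...) {
  tibble(
    n_proteins = nrow(x),
    iterations = attr(x, "iterations"),
    converged = attr(x, "converged")
  )
}

#' Tidy an ensemble vote
#'
#' @param x A `hsep_ensemble` object.
#' @param ... Unused.
#' @return The vote tibble: `protein`, `em`, `mean_score`, `essential`.
#' @method tidy hsep_ensemble
#' @export
tidy.hsep_ensemble <- function(x, ...) {
  x$votes
}

#' One-row summary of an ensemble vote
#'
#' @param x A `hsep_ensemble` object.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `n`, `threshold`, `n_candidates`,
#'   `n_essential`.
#' @method glance hsep_ensemble
#' @export
glance.hsep_ensemble <- function(x, ...) {
  tibble(
    k = length(x$candidate_sets),
    n = x$n,
    threshold = x$threshold,
    n_candidates = length(x$candidate_union),
    n_essential = length(x$essential_set)
  )
}

#' Plot a precision-recall curve
#'
#' @param object A `hsep_pr_curve` from [pr_curve()].
#' @param ... Unused.
#' @return A ggplot: recall on x, precision on y.
#' @method autoplot hsep_pr_curve
#' @export
autoplot.hsep_pr_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(unclass_tbl(object)),
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision") +
    ggplot2::theme_minimal()
}

#' Plot authority against hub scores
#'
#' @param object A `hsep_hits` object.
#' @param ... Unused.
#' @return A ggplot scatter of hub (x) vs authority (y), one point per
#'   protein.
#' @method autoplot hsep_hits
#' @export
autoplot.hsep_hits <- function(object, ...) {
  ggplot2::ggplot(as_tibble(unclass_tbl(object)),
                  ggplot2::aes(x = .data$hub, y = .data$authority)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Hub (topology)", y = "Authority (biology)") +
    ggplot2::theme_minimal()
}

# strip the package's subclass so downstream verbs see a plain tibble
unclass_tbl <- function(x) {
  class(x) <- setdiff(class(x), c(
    "hsep_hits", "hsep_ranking", "hsep_pr_curve", "hsep_eval",
    "confusion_counts", "expression_profiles", "go_annotations", "weighted_ppi"
  ))
  x
}
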