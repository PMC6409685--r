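#' Confusion counts against a known essential list
#'
#' Partitions the evaluation universe: TP are known essentials predicted
#' essential, FP non-essentials predicted essential, FN known essentials
#' missed, TN non-essentials correctly left out. Known proteins outside the
#' universe are ignored (the network defines the universe).
#'
#' @param predicted Character vector of predicted-essential identifiers; must
#'   be a subset of `universe`.
#' @param known Character vector of known essential identifiers.
#' @param universe Character vector of all proteins under evaluation
#'   (typically the network's node set).
#' @return A one-row tibble of class `confusion_counts` with integer columns
#'   `tp`, `fp`, `tn`, `fn` summing to `length(unique(universe))`.
#' @export
confusion_counts <- function(predicted, known, universe) {
  universe <- unique(universe)
  predicted <- unique(predicted)
  if (!all(predicted %in% universe)) {
    abort("`predicted` must be a subset of `universe`.")
  }
  pos <- intersect(known, universe)
  tp <- length(intersect(predicted, pos))
  fp <- length(predicted) - tp
  fn <- length(pos) - tp
  tn <- length(universe) - tp - fp - fn
  out <- tibble(tp = tp, fp = fp, tn = tn, fn = fn)
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Six summary statistics of a confusion table
#'
#' Sensitivity SN = TP/(TP+FN), specificity SP = TN/(TN+FP), positive
#' predictive value PPV = TP/(TP+FP), negative predictive value
#' NPV = TN/(TN+FN), F-measure = 2·SN·PPV/(SN+PPV) and accuracy
#' ACC = (TP+TN)/(TP+TN+FP+FN). A statistic whose denominator is zero is
#' reported as 0 with a warning so batch tables stay numeric.
#'
#' @param counts A `confusion_counts` row (or anything with fields
#'   `tp`, `fp`, `tn`, `fn`).
#' @return A one-row tibble of class `hsep_eval` with columns `sn`, `sp`,
#'   `ppv`, `npv`, `f_measure`, `acc`, all in \[0, 1\].
#' @export
eval_statistics <- function(counts) {
  tp <- counts$tp
  fp <- counts$fp
  tn <- counts$tn
  fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) abort("All confusion counts are zero.")
  safe <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s has a zero denominator; reporting 0.", what))
      return(0)
    }
    num / den
  }
  sn <- safe(tp, tp + fn, "SN")
  sp <- safe(tn, tn + fp, "SP")
  ppv <- safe(tp, tp + fp, "PPV")
  npv <- safe(tn, tn + fn, "NPV")
  f <- if (sn + ppv == 0) {
    warn("F-measure has a zero denominator; reporting 0.")
    0
  } else {
    2 * sn * ppv / (sn + ppv)
  }
  out <- tibble(
    sn = sn, sp = sp, ppv = ppv, npv = npv,
    f_measure = f, acc = (tp + tn) / total
  )
  class(out) <- c("hsep_eval", class(out))
  out
}

#' Precision-recall curve of a ranking
#'
#' For every prefix length n of the ranking, precision(n) = TP(n)/n and
#' recall(n) = TP(n)/P, where TP(n) counts known essentials among the top n
#' and P is the total number of known essentials. Recall is non-decreasing
#' in n.
#'
#' @param ranking A `hsep_ranking` (or any tibble with a `protein` column in
#'   rank order).
#' @param known Non-empty character vector of known essential identifiers.
#' @return A tibble of class `hsep_pr_curve` with columns `n`, `precision`,
#'   `recall`; `attr(, "total_positives")` stores P.
#' @export
pr_curve <- function(ranking, known) {
  known <- unique(known)
  if (length(known) == 0) abort("`known` must be non-empty.")
  hits <- ranking$protein %in% known
  tp_n <- cumsum(hits)
  n <- seq_along(tp_n)
  out <- tibble(n = n, precision = tp_n / n, recall = tp_n / length(known))
  attr(out, "total_positives") <- length(known)
  class(out) <- c("hsep_pr_curve", class(out))
  out
}

#' Degree centrality baseline
#'
#' Node degree per protein — the classic centrality-lethality baseline
#' against which the weighted-HITS ranking is compared. Isolated nodes score
#' 0.
#'
#' @param net A [ppi_network()].
#' @return A tibble with columns `protein`, `degree`, sorted by descending
#'   degree then protein identifier.
#' @export
degree_centrality <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  deg <- table(factor(c(net$edges$from, net$edges$to), levels = net$nodes))
  tibble(protein = net$nodes, degree = as.integer(deg)) |>
    arrange(desc(.data$degree), .data$protein)
}

#' Density of an interaction network
#'
#' For N proteins and E undirected interactions, density = 2E / (N(N-1)):
#' the fraction of possible interactions observed.
#'
#' @param n_proteins Number of proteins N (>= 2).
#' @param n_interactions Number of undirected interactions E.
#' @return A single numeric density.
#' @examples
#' interaction_density(5093, 24743)
#' @export
interaction_density <- function(n_proteins, n_interactions) {
  stopifnot(n_proteins >= 2, n_interactions >= 0)
  2 * n_interactions / (n_proteins * (n_proteins - 1))
}
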