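# Sparse adjacency of a ppi_network, nodes in net$nodes order.
adjacency_sparse <- function(net) {
  n <- length(net$nodes)
  idx <- setNames(seq_len(n), net$nodes)
  i <- idx[net$edges$from]
  j <- idx[net$edges$to]
  Matrix::sparseMatrix(
    i = c(i, j), j = c(j, i), x = 1,
    dims = c(n, n), dimnames = list(net$nodes, net$nodes)
  )
}

#' Edge clustering coefficients of a network
#'
#' For every interaction \{u, v\}, the edge clustering coefficient
#' \deqn{ECC(u,v) = \frac{|N_u \cap N_v| + 1}{\min(d_u, d_v)}}
#' where \eqn{N_u} is the neighbour set and \eqn{d_u} the degree. It measures
#' how tightly the two connected proteins are embedded in shared triangles
#' and always lies in (0, 1]; an isolated edge scores 1.
#'
#' @param net A [ppi_network()].
#' @return A tibble with columns `from`, `to`, `ecc`, one row per undirected
#'   edge (ECC is symmetric).
#' @export
edge_clustering <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  e <- net$edges
  if (nrow(e) == 0) return(tibble(from = character(), to = character(), ecc = numeric()))
  A <- adjacency_sparse(net)
  deg <- Matrix::rowSums(A)
  CN <- A %*% A  # (i, j) entry = number of common neighbours
  idx <- setNames(seq_along(net$nodes), net$nodes)
  i <- idx[e$from]
  j <- idx[e$to]
  common <- CN[cbind(i, j)]
  tibble(from = e$from, to = e$to,
         ecc = unname((common + 1) / pmin(deg[i], deg[j])))
}

#' @describeIn edge_clustering ECC of a single edge; errors if \{u, v\} is
#'   not an interaction of `net`.
#' @param u,v Protein identifiers joined by an edge of `net`.
#' @export
edge_clustering_coefficient <- function(net, u, v) {
  tab <- edge_clustering(net)
  a <- pmin(u, v)
  b <- pmax(u, v)
  hit <- tab$from == a & tab$to == b
  if (!any(hit)) abort(sprintf("{%s, %s} is not an edge of the network.", u, v))
  tab$ecc[which(hit)[1]]
}

#' Pearson correlation of two expression profiles
#'
#' Standard Pearson correlation coefficient between the time-course profiles
#' of two proteins, in \[-1, 1\]. A profile with zero variance yields 0 by
#' convention (the ratio is otherwise 0/0), and `NA` is returned when a
#' protein has no expression row so the caller can apply the missing-data
#' rule.
#'
#' @param expr An `expression_profiles` tibble ([read_expression_profiles()]).
#' @param u,v Protein identifiers.
#' @return A single numeric value, or `NA` if either protein is absent.
#' @export
expression_correlation <- function(expr, u, v) {
  m <- expression_matrix(expr)
  if (!(u %in% rownames(m)) || !(v %in% rownames(m))) return(NA_real_)
  x <- m[u, ]
  y <- m[v, ]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

expression_matrix <- function(expr) {
  m <- as.matrix(expr[-1])
  rownames(m) <- expr$protein
  m
}

#' Wang semantic values of a GO term's ancestor closure
#'
#' Computes the Wang S-values for a term A: S_A(A) = 1 and, walking up the
#' DAG, S_A(t) = max over child terms t' of t on a path from A of
#' `factor(relation) * S_A(t')`. The contribution factors live on the DAG
#' (defaults 0.8 for `is_a`, 0.6 for `part_of`).
#'
#' @param dag A [go_dag()].
#' @param term A term identifier present in the DAG.
#' @return A tibble with columns `term`, `s_value`, covering exactly the
#'   ancestor closure of `term` (the term itself included).
#' @export
wang_s_values <- function(dag, term) {
  s <- wang_s_vector(dag, term)
  tibble(term = names(s), s_value = unname(s))
}

# Named numeric S-value vector over the ancestor closure; relaxation to a
# fixed point (monotone, bounded by factor^depth, so at most |closure| passes).
wang_s_vector <- function(dag, term) {
  if (!(term %in% dag$terms)) abort(sprintf("Unknown GO term '%s'.", term))
  s <- c(1)
  names(s) <- term
  e <- dag$edges
  fac <- dag$factors[e$relation]
  repeat {
    changed <- FALSE
    known <- e$child %in% names(s)
    cand <- fac[known] * s[e$child[known]]
    parents <- e$parent[known]
    if (length(parents) > 0) {
      best <- tapply(cand, parents, max)
      for (p in names(best)) {
        if (is.na(s[p]) || best[[p]] > s[[p]]) {
          s[p] <- best[[p]]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  s
}

# Protein-level S-vector: max over the protein's annotated terms of each
# term's S-values; union of ancestor closures.
protein_s_vector <- function(dag, terms, cache = NULL) {
  out <- numeric(0)
  for (t in terms) {
    s <- if (!is.null(cache)) {
      if (is.null(cache[[t]])) cache[[t]] <- wang_s_vector(dag, t)
      cache[[t]]
    } else {
      wang_s_vector(dag, t)
    }
    all_terms <- union(names(out), names(s))
    out <- pmax(
      setNames(out[all_terms], all_terms),
      setNames(s[all_terms], all_terms),
      na.rm = TRUE
    )
  }
  out
}

#' GO semantic similarity between two proteins (Wang method)
#'
#' With T_u the union of ancestor closures of u's annotated terms and
#' S_u(t) the maximum Wang S-value of t over those terms, the similarity is
#' \deqn{\frac{\sum_{t \in T_u \cap T_v} (S_u(t) + S_v(t))}
#'            {\sum_{t \in T_u} S_u(t) + \sum_{t \in T_v} S_v(t)}}
#' It lies in \[0, 1\], is symmetric, and is 0 when either protein carries no
#' annotation.
#'
#' @param dag A [go_dag()].
#' @param ann A `go_annotations` tibble ([read_go_annotations()]).
#' @param u,v Protein identifiers.
#' @return A single numeric similarity.
#' @export
go_similarity <- function(dag, ann, u, v) {
  tu <- ann$term[ann$protein == u]
  tv <- ann$term[ann$protein == v]
  go_similarity_from_terms(dag, tu, tv)
}

go_similarity_from_terms <- function(dag, tu, tv, cache = NULL) {
  su <- protein_s_vector(dag, tu, cache)
  sv <- protein_s_vector(dag, tv, cache)
  if (length(su) == 0 || length(sv) == 0) return(0)
  shared <- intersect(names(su), names(sv))
  (sum(su[shared]) + sum(sv[shared])) / (sum(su) + sum(sv))
}

#' Shared-compartment co-localization score
#'
#' For an interaction \{u, v\}, C(u, v) is the number of subcellular
#' compartments annotated to both proteins, and C_max is the maximum C over
#' all edges of the network at hand. The score is C / C_max in \[0, 1\]
#' (0 when no edge of the network shares any compartment).
#'
#' @param loc Localization tibble ([read_localizations()]).
#' @param net The [ppi_network()] over which C_max is taken.
#' @param u,v Protein identifiers.
#' @return A single numeric score.
#' @export
localization_score <- function(loc, net, u, v) {
  counts <- shared_compartment_counts(net, loc)
  cmax <- max(c(0, counts$c))
  if (cmax == 0) return(0)
  comp <- split(loc$compartment, loc$protein)
  cuv <- length(intersect(comp[[u]] %||% character(), comp[[v]] %||% character()))
  cuv / cmax
}

# Per-edge shared-compartment counts C(u, v).
shared_compartment_counts <- function(net, loc) {
  comp <- split(loc$compartment, loc$protein)
  e <- net$edges
  c_uv <- purrr::map2_int(e$from, e$to, function(a, b) {
    length(intersect(comp[[a]] %||% character(), comp[[b]] %||% character()))
  })
  tibble(from = e$from, to = e$to, c = c_uv)
}

#' Build the weighted bidirectional interaction network
#'
#' Attaches the two weight channels to every directed edge of the
#' bidirectional digraph: `ecc_weight`, the edge clustering coefficient
#' (network topology), and `bio_weight`, the sum of biological evidence
#' \deqn{w = \max(PCC, 0) + GO\_sim + SL}
#' (gene-expression Pearson correlation clamped at zero, Wang GO semantic
#' similarity, and shared-compartment score). In mode `"hsp"` only the
#' expression term is used. A protein missing from an annotation source
#' contributes 0 through that source, so partial coverage never disconnects
#' the graph. All four per-edge quantities are symmetric, so both directions
#' of an edge carry the same weights.
#'
#' @param net A [ppi_network()]; must have at least one edge.
#' @param expr Optional `expression_profiles`.
#' @param dag,ann Optional [go_dag()] and annotations (ignored in mode
#'   `"hsp"`).
#' @param loc Optional localization tibble (ignored in mode `"hsp"`).
#' @param mode `"hsep"` (all three biological sources) or `"hsp"`
#'   (expression only).
#' @return A `weighted_ppi`: a tibble with columns `from`, `to`,
#'   `ecc_weight`, `bio_weight`, one row per *directed* edge (2 rows per
#'   interaction), with the node set in `attr(, "nodes")`. `bio_weight` lies
#'   in \[0, 3\] for `"hsep"` and \[0, 1\] for `"hsp"`; `ecc_weight` in
#'   (0, 1\].
#' @export
build_weighted_network <- function(net, expr = NULL, dag = NULL, ann = NULL,
                                   loc = NULL, mode = c("hsep", "hsp")) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "ppi_network"))
  if (nrow(net$edges) == 0) abort("Empty network: nothing to weight.")
  e <- edge_clustering(net)

  pcc <- numeric(nrow(e))
  if (!is.null(expr)) {
    m <- expression_matrix(expr)
    sds <- apply(m, 1, stats::sd)
    z <- m - rowMeans(m)
    ok <- sds > 0
    z[ok, ] <- z[ok, , drop = FALSE] / sds[ok]
    z[!ok, ] <- 0
    have <- e$from %in% rownames(m) & e$to %in% rownames(m)
    if (any(have)) {
      num <- rowSums(z[e$from[have], , drop = FALSE] * z[e$to[have], , drop = FALSE])
      pcc[have] <- num / (ncol(m) - 1)
    }
  }
  pcc <- pmax(pcc, 0)

  gos <- numeric(nrow(e))
  if (mode == "hsep" && !is.null(dag) && !is.null(ann)) {
    cache <- new.env(parent = emptyenv())
    by_protein <- split(ann$term, ann$protein)
    svecs <- new.env(parent = emptyenv())
    svec_of <- function(p) {
      if (is.null(svecs[[p]])) {
        svecs[[p]] <- protein_s_vector(dag, by_protein[[p]] %||% character(), cache)
      }
      svecs[[p]]
    }
    totals <- new.env(parent = emptyenv())
    gos <- purrr::map2_dbl(e$from, e$to, function(a, b) {
      su <- svec_of(a)
      sv <- svec_of(b)
      if (length(su) == 0 || length(sv) == 0) return(0)
      shared <- intersect(names(su), names(sv))
      (sum(su[shared]) + sum(sv[shared])) / (sum(su) + sum(sv))
    })
  }

  sl <- numeric(nrow(e))
  if (mode == "hsep" && !is.null(loc)) {
    counts <- shared_compartment_counts(net, loc)
    cmax <- max(c(0, counts$c))
    if (cmax > 0) sl <- counts$c / cmax
  }

  half <- tibble(
    from = e$from, to = e$to,
    ecc_weight = e$ecc,
    bio_weight = pcc + gos + sl
  )
  out <- bind_rows(
    half,
    tibble(
      from = half$to, to = half$from,
      ecc_weight = half$ecc_weight, bio_weight = half$bio_weight
    )
  )
  attr(out, "nodes") <- net$nodes
  attr(out, "mode") <- mode
  class(out) <- c("weighted_ppi", class(out))
  out
}

#' Serialize / read a weighted network
#'
#' The on-disk form is a 4-column TSV — `source`, `target`, `weight`,
#' `channel` (`ecc` or `bio`) — with one row per directed edge and channel;
#' [read_weighted_network()] inverts [write_weighted_network()] exactly.
#'
#' @param wnet A `weighted_ppi` ([build_weighted_network()]).
#' @param path File path.
#' @return `path` invisibly (writer); a `weighted_ppi` (reader).
#' @export
write_weighted_network <- function(wnet, path) {
  stopifnot(inherits(wnet, "weighted_ppi"))
  long <- bind_rows(
    tibble(source = wnet$from, target = wnet$to, weight = wnet$ecc_weight, channel = "ecc"),
    tibble(source = wnet$from, target = wnet$to, weight = wnet$bio_weight, channel = "bio")
  ) |> arrange(.data$source, .data$target, .data$channel)
  readr::write_tsv(long, path)
  invisible(path)
}

#' @rdname write_weighted_network
#' @export
read_weighted_network <- function(path) {
  long <- readr::read_tsv(path, col_types = "ccdc", progress = FALSE)
  wide <- long |>
    tidyr::pivot_wider(names_from = "channel", values_from = "weight") |>
    transmute(
      from = .data$source, to = .data$target,
      ecc_weight = .data$ecc, bio_weight = .data$bio
    ) |>
    arrange(.data$from, .data$to)
  attr(wide, "nodes") <- sort(unique(c(wide$from, wide$to)))
  class(wide) <- c("weighted_ppi", class(wide))
  wide
}
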