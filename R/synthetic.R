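#' Configuration for the synthetic benchmark generator
#'
#' Describes a download-free benchmark with the statistical structure the
#' weighted-HITS ranking assumes: a background Erdős–Rényi interaction
#' network containing a denser planted "essential" module whose members
#' co-express, are annotated in one branch of the GO DAG, and share a
#' subcellular compartment.
#'
#' Defaults: 200 proteins with a 20-protein module, background edge
#' probability 0.02 against 0.4 inside the module, 36 expression time points
#' (three 12-point cycles, the shape of classic yeast metabolic-cycle
#' time courses) with Gaussian noise sd 0.5 around the shared module profile,
#' a 50-term GO DAG of depth 4, and the 11 canonical compartments.
#'
#' @param n_proteins,n_essential Total protein count and planted module size
#'   (`n_essential < n_proteins`).
#' @param background_edge_prob,module_edge_prob Edge probabilities, both in
#'   \[0, 1\] with `module_edge_prob > background_edge_prob`.
#' @param n_timepoints Expression time points (>= 2).
#' @param expression_noise_sd Noise sd around the module's shared profile.
#' @param n_go_terms,dag_depth Size and maximum depth of the random GO DAG.
#' @param n_compartments Number of compartments drawn from the canonical
#'   vocabulary (<= 11).
#' @param seed Integer seed; fully determines the generated bundle.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_proteins = 200, n_essential = 20,
                             background_edge_prob = 0.02,
                             module_edge_prob = 0.4,
                             n_timepoints = 36, expression_noise_sd = 0.5,
                             n_go_terms = 50, dag_depth = 4,
                             n_compartments = 11, seed = 42) {
  if (n_essential >= n_proteins) abort("`n_essential` must be smaller than `n_proteins`.")
  for (p in c(background_edge_prob, module_edge_prob)) {
    if (p < 0 || p > 1) abort("Edge probabilities must lie in [0, 1].")
  }
  if (module_edge_prob <= background_edge_prob) {
    abort("`module_edge_prob` must exceed `background_edge_prob`.")
  }
  if (n_timepoints < 2) abort("`n_timepoints` must be at least 2.")
  if (n_go_terms < 3) abort("`n_go_terms` must be at least 3.")
  if (n_compartments < 1 || n_compartments > length(hsep_compartments)) {
    abort(sprintf("`n_compartments` must be in 1..%d.", length(hsep_compartments)))
  }
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      n_essential = as.integer(n_essential),
      background_edge_prob = background_edge_prob,
      module_edge_prob = module_edge_prob,
      n_timepoints = as.integer(n_timepoints),
      expression_noise_sd = expression_noise_sd,
      n_go_terms = as.integer(n_go_terms),
      dag_depth = as.integer(dag_depth),
      n_compartments = as.integer(n_compartments),
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Generate a synthetic benchmark bundle
#'
#' Draws, from one seed, all five inputs of the ranking pipeline plus ground
#' truth:
#' * a simple undirected network — every pair of module members is joined
#'   with probability `module_edge_prob`, every other pair with
#'   `background_edge_prob`;
#' * expression profiles — module members share one sinusoidal time course
#'   (period 12) plus `N(0, sd^2)` noise; background proteins are independent
#'   `N(0, 1)`;
#' * a random GO DAG (tree of `is_a` links plus ~20% extra `part_of` links,
#'   acyclic by construction) in which module members are annotated with 2-3
#'   terms from a single branch and background proteins with 1-3 terms drawn
#'   anywhere;
#' * a localization table giving every module member one shared compartment
#'   (plus 0-2 extras) and background proteins 1-3 random compartments;
#' * the planted essential identifier set.
#'
#' The same seed always yields an identical bundle; the global RNG state is
#' left untouched.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_bundle` with elements `network`,
#'   `expression`, `dag`, `annotations`, `localizations`, `essential` and
#'   `config`.
#' @export
generate_bundle <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_bundle_impl(config))
}

generate_bundle_impl <- function(cfg) {
  proteins <- sprintf("P%04d", seq_len(cfg$n_proteins))
  essential <- if (cfg$n_essential > 0) sort(sample(proteins, cfg$n_essential)) else character()
  in_module <- proteins %in% essential

  # network: upper-triangle Bernoulli draws with module pairs densified
  pairs <- which(upper.tri(matrix(0, cfg$n_proteins, cfg$n_proteins)), arr.ind = TRUE)
  p_edge <- ifelse(in_module[pairs[, 1]] & in_module[pairs[, 2]],
                   cfg$module_edge_prob, cfg$background_edge_prob)
  keep <- runif(nrow(pairs)) < p_edge
  net <- ppi_network(
    tibble(from = proteins[pairs[keep, 1]], to = proteins[pairs[keep, 2]]),
    nodes = proteins
  )

  # expression: shared periodic profile for the module, independent noise
  tt <- seq_len(cfg$n_timepoints)
  base <- sin(2 * pi * tt / 12)
  vals <- matrix(rnorm(cfg$n_proteins * cfg$n_timepoints), nrow = cfg$n_proteins)
  vals[in_module, ] <- matrix(rep(base, each = sum(in_module)), nrow = sum(in_module)) +
    matrix(rnorm(sum(in_module) * cfg$n_timepoints, sd = cfg$expression_noise_sd),
           nrow = sum(in_module))
  expr <- as_tibble(vals, .name_repair = function(x) sprintf("t%02d", seq_along(x)))
  expr <- bind_cols(tibble(protein = proteins), expr)
  class(expr) <- c("expression_profiles", class(expr))

  # GO DAG: random is_a tree capped at dag_depth, plus part_of shortcuts to
  # lower-index terms (indices increase away from the root, so acyclic)
  n_terms <- cfg$n_go_terms
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  depth <- integer(n_terms)
  parent <- integer(n_terms)
  for (i in seq_len(n_terms)[-1]) {
    cand <- which(depth[seq_len(i - 1)] < cfg$dag_depth)
    parent[i] <- if (length(cand) == 1) cand else sample(cand, 1)
    depth[i] <- depth[parent[i]] + 1L
  }
  edges <- tibble(
    child = terms[seq_len(n_terms)[-1]],
    parent = terms[parent[-1]],
    relation = "is_a"
  )
  n_extra <- max(1L, round(0.2 * n_terms))
  extra_child <- sample(3:n_terms, n_extra, replace = TRUE)
  extra_parent <- vapply(extra_child, function(j) {
    cand <- setdiff(seq_len(j - 1), parent[j])
    if (length(cand) == 1) cand else sample(cand, 1)
  }, integer(1))
  edges <- bind_rows(edges, tibble(
    child = terms[extra_child], parent = terms[extra_parent], relation = "part_of"
  )) |> distinct(.data$child, .data$parent, .keep_all = TRUE)
  dag <- go_dag(terms, edges)

  # module branch: subtree under a depth-1 term (largest, for headroom)
  children_of <- split(seq_len(n_terms)[-1], parent[-1])
  subtree <- function(root) {
    out <- root
    frontier <- root
    while (length(frontier) > 0) {
      nxt <- unlist(children_of[as.character(frontier)], use.names = FALSE)
      out <- c(out, nxt)
      frontier <- nxt
    }
    out
  }
  depth1 <- which(depth == 1L)
  branch_sizes <- vapply(depth1, function(r) length(subtree(r)), integer(1))
  branch <- terms[subtree(depth1[which.max(branch_sizes)])]
  ann_rows <- purrr::map(proteins, function(p) {
    if (p %in% essential) {
      k <- sample(2:3, 1)
      tibble(protein = p, term = sample(branch, min(k, length(branch))))
    } else {
      k <- sample(1:3, 1)
      tibble(protein = p, term = sample(terms, k))
    }
  })
  ann <- bind_rows(ann_rows) |> distinct(.data$protein, .data$term)
  class(ann) <- c("go_annotations", class(ann))

  # localization: one shared module compartment + random extras
  comps <- hsep_compartments[seq_len(cfg$n_compartments)]
  shared <- sample(comps, 1)
  loc_rows <- purrr::map(proteins, function(p) {
    if (p %in% essential) {
      extras <- sample(setdiff(comps, shared), sample(0:2, 1))
      tibble(protein = p, compartment = c(shared, extras))
    } else {
      tibble(protein = p, compartment = sample(comps, sample(1:3, 1)))
    }
  })
  loc <- bind_rows(loc_rows) |> distinct(.data$protein, .data$compartment)

  structure(
    list(
      network = net, expression = expr, dag = dag, annotations = ann,
      localizations = loc, essential = essential, config = cfg
    ),
    class = "synthetic_bundle"
  )
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(
    "<synthetic_bundle> %d proteins (%d planted essential), %d interactions, seed %d\n",
    length(x$network$nodes), length(x$essential), nrow(x$network$edges),
    x$config$seed
  ))
  invisible(x)
}

#' Write a synthetic bundle to a directory
#'
#' Serializes all five inputs in the formats the readers accept:
#' `network.tsv` (edge list), `expression.tsv`, `go.obo`, `annotations.tsv`,
#' `localizations.tsv` and `essential.txt`.
#'
#' @param bundle A `synthetic_bundle` from [generate_bundle()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_ppi_edges(bundle$network, file.path(dir, "network.tsv"))
  readr::write_tsv(as_tibble(bundle$expression), file.path(dir, "expression.tsv"))
  write_obo(bundle$dag, file.path(dir, "go.obo"))
  readr::write_tsv(as_tibble(bundle$annotations), file.path(dir, "annotations.tsv"),
                   col_names = FALSE)
  readr::write_tsv(bundle$localizations, file.path(dir, "localizations.tsv"),
                   col_names = FALSE)
  writeLines(bundle$essential, file.path(dir, "essential.txt"))
  invisible(dir)
}

#' Write a GO DAG as OBO 1.2
#'
#' @param dag A [go_dag()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "go_dag"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  by_child <- split(dag$edges, dag$edges$child)
  for (t in dag$terms) {
    writeLines(c("[Term]", paste0("id: ", t), paste0("name: ", t)), con)
    ns <- dag$namespaces[[t]] %||% NULL
    if (!is.null(ns) && !is.na(ns)) writeLines(paste0("namespace: ", ns), con)
    e <- by_child[[t]]
    if (!is.null(e)) {
      for (r in seq_len(nrow(e))) {
        if (e$relation[r] == "is_a") {
          writeLines(paste0("is_a: ", e$parent[r]), con)
        } else {
          writeLines(paste0("relationship: ", e$relation[r], " ", e$parent[r]), con)
        }
      }
    }
    writeLines("", con)
  }
  invisible(path)
}
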