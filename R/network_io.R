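#' Construct a protein-protein interaction network
#'
#' A `ppi_network` is a simple undirected graph over opaque protein
#' identifiers: no self-loops, no duplicate edges (in either orientation),
#' every edge endpoint present in the node set. Nodes with no interactions
#' are allowed.
#'
#' @param edges A data frame (or tibble) with two character columns, one row
#'   per interaction. Self-loops and duplicates are removed.
#' @param nodes Optional character vector of node identifiers; defaults to
#'   the union of edge endpoints. Endpoints missing from `nodes` are added.
#' @return A `ppi_network`: a list with elements `nodes` (character) and
#'   `edges` (tibble with columns `from`, `to`, stored with `from < to`).
#' @examples
#' ppi_network(data.frame(a = c("A", "B"), b = c("B", "C")))
#' @export
ppi_network <- function(edges = NULL, nodes = character()) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble(from = character(), to = character())
  } else {
    if (ncol(edges) < 2) abort("`edges` needs two columns (interacting pair).")
    edges <- tibble(
      from = as.character(edges[[1]]),
      to = as.character(edges[[2]])
    )
  }
  # canonical orientation so {a,b} and {b,a} collapse to one row
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges <- edges |>
    filter(.data$from != .data$to) |>
    distinct(.data$from, .data$to) |>
    arrange(.data$from, .data$to)
  nodes <- sort(union(as.character(nodes), c(edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf(
    "<ppi_network> %d proteins, %d interactions\n",
    length(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' Read a PPI edge list
#'
#' Reads a two-column delimited file of interacting protein pairs and returns
#' a simple undirected network: repeated interactions (in either orientation)
#' and self-interactions are removed, as is standard when preparing
#' high-throughput interaction data.
#'
#' @param path Path to a two-column (tab- or whitespace-delimited) text file.
#'   Blank lines are ignored.
#' @param case_fold If `TRUE`, protein identifiers are lower-cased before
#'   matching. Default `FALSE`: matching is exact and case-sensitive.
#' @return A [ppi_network()].
#' @export
read_ppi_edges <- function(path, case_fold = FALSE) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[\t ]+")
  bad <- which(lengths(fields) != 2)
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed edge list line %d: expected 2 columns, found %d.",
      idx[bad[1]], lengths(fields)[bad[1]]
    ))
  }
  if (length(fields) == 0) return(ppi_network())
  m <- do.call(rbind, fields)
  if (case_fold) m <- tolower(m)
  ppi_network(tibble(from = m[, 1], to = m[, 2]))
}

#' Write a PPI edge list
#'
#' Serializes a network back to the two-column TSV accepted by
#' [read_ppi_edges()]; write-then-read is the identity on `ppi_network`
#' objects up to isolated nodes (which an edge list cannot carry).
#'
#' @param net A [ppi_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ppi_edges <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  readr::write_tsv(net$edges, path, col_names = FALSE)
  invisible(path)
}

#' Expand an undirected network to its bidirectional digraph
#'
#' Every undirected interaction \{u, v\} becomes the two ordered pairs
#' (u, v) and (v, u), so the directed edge count is exactly twice the
#' undirected one. This is the skeleton onto which the topological and
#' biological weight channels are attached.
#'
#' @param net A [ppi_network()].
#' @return A tibble with columns `from`, `to`, one row per directed edge.
#' @export
as_bidirected <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  e <- net$edges
  bind_rows(e, tibble(from = e$to, to = e$from))
}

#' Read gene-expression profiles
#'
#' Expects a TSV whose first column is the protein identifier and whose
#' remaining columns are numeric expression values over T >= 2 time points,
#' g(u, i) for protein u at time i.
#'
#' @param path Path to the expression TSV (header row expected).
#' @return A tibble of class `expression_profiles`: column `protein` followed
#'   by T numeric columns. Duplicate protein rows are an error (averaging
#'   silently would hide an upstream identifier problem).
#' @export
read_expression_profiles <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(x) < 3) abort("Expression table needs an ID column and >= 2 time points.")
  names(x)[1] <- "protein"
  x$protein <- as.character(x$protein)
  if (anyDuplicated(x$protein)) {
    abort(sprintf(
      "Duplicate expression rows for protein(s): %s",
      paste(unique(x$protein[duplicated(x$protein)]), collapse = ", ")
    ))
  }
  vals <- x[-1]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    abort("All expression columns after the first must be numeric.")
  }
  class(x) <- c("expression_profiles", class(x))
  x
}

#' Construct a GO DAG
#'
#' Holds the term set, the directed child-to-parent edges labelled with their
#' relation (`is_a` or `part_of`), and the per-relation semantic contribution
#' factors used by the Wang similarity measure.
#'
#' @param terms Character vector of term identifiers.
#' @param edges Tibble with columns `child`, `parent`, `relation`.
#' @param factors Named numeric vector of contribution factors in (0, 1);
#'   defaults to the published Wang values, 0.8 for `is_a` and 0.6 for
#'   `part_of`.
#' @param namespaces Optional named character vector mapping term -> ontology
#'   aspect (e.g. `biological_process`).
#' @return A `go_dag` object.
#' @export
go_dag <- function(terms, edges = NULL,
                   factors = c(is_a = 0.8, part_of = 0.6),
                   namespaces = NULL) {
  terms <- unique(as.character(terms))
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble(child = character(), parent = character(), relation = character())
  } else {
    edges <- tibble(
      child = as.character(edges$child),
      parent = as.character(edges$parent),
      relation = as.character(edges$relation)
    )
  }
  if (any(factors <= 0 | factors >= 1)) {
    abort("Contribution factors must lie strictly inside (0, 1).")
  }
  missing <- setdiff(c(edges$child, edges$parent), terms)
  if (length(missing) > 0) {
    abort(sprintf("DAG edges reference unknown terms: %s", paste(missing, collapse = ", ")))
  }
  bad_rel <- setdiff(unique(edges$relation), names(factors))
  if (length(bad_rel) > 0) {
    abort(sprintf("No contribution factor for relation(s): %s", paste(bad_rel, collapse = ", ")))
  }
  dag <- structure(
    list(terms = terms, edges = edges, factors = factors, namespaces = namespaces),
    class = "go_dag"
  )
  if (dag_has_cycle(dag)) abort("Ontology graph contains a cycle; a DAG is required.")
  dag
}

# Kahn topological check over child->parent links.
dag_has_cycle <- function(dag) {
  if (nrow(dag$edges) == 0) return(FALSE)
  terms <- dag$terms
  out_deg <- table(factor(dag$edges$child, levels = terms))
  parents_of <- split(dag$edges$parent, factor(dag$edges$child, levels = terms))
  incoming <- split(dag$edges$child, factor(dag$edges$parent, levels = terms))
  deg <- as.integer(out_deg)
  names(deg) <- terms
  queue <- terms[deg == 0L]
  seen <- 0L
  while (length(queue) > 0) {
    t <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (c in incoming[[t]]) {
      deg[[c]] <- deg[[c]] - 1L
      if (deg[[c]] == 0L) queue <- c(queue, c)
    }
  }
  seen < length(terms)
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf(
    "<go_dag> %d terms, %d edges (%s)\n",
    length(x$terms), nrow(x$edges),
    paste(sprintf("%s=%.2g", names(x$factors), x$factors), collapse = ", ")
  ))
  invisible(x)
}

#' Read a GO DAG from an OBO 1.2 file
#'
#' Parses `[Term]` stanzas, keeping `is_a` and `relationship: part_of` links
#' (other relationship types carry no contribution factor and are ignored).
#' Obsolete terms are dropped. Acyclicity is enforced.
#'
#' @param path Path to an OBO 1.2 file.
#' @param factors Contribution factors passed to [go_dag()].
#' @param aspect Optional ontology namespace (e.g. `"biological_process"`);
#'   if given, only terms of that aspect (and links among them) are kept.
#' @return A [go_dag()].
#' @export
read_go_obo <- function(path, factors = c(is_a = 0.8, part_of = 0.6),
                        aspect = NULL) {
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id) && !isTRUE(cur$obsolete)) {
      terms[[cur$id]] <- cur
    }
    terms
  }
  for (line in lines) {
    line <- sub("!.*$", "", line)  # strip trailing comments
    line <- trimws(line)
    if (line == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(is_a = character(), part_of = character())
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", line)) {  # other stanza type
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(line)) next
    if (grepl("^id:", line)) cur$id <- trimws(sub("^id:", "", line))
    if (grepl("^namespace:", line)) cur$namespace <- trimws(sub("^namespace:", "", line))
    if (grepl("^is_a:", line)) {
      cur$is_a <- c(cur$is_a, strsplit(trimws(sub("^is_a:", "", line)), "[\t ]+")[[1]][1])
    }
    if (grepl("^relationship:", line)) {
      f <- strsplit(trimws(sub("^relationship:", "", line)), "[\t ]+")[[1]]
      if (length(f) >= 2 && f[1] == "part_of") cur$part_of <- c(cur$part_of, f[2])
    }
    if (grepl("^is_obsolete:\\s*true", line)) cur$obsolete <- TRUE
  }
  terms <- flush(cur, terms)
  if (length(terms) == 0) abort(sprintf("No [Term] stanzas found in '%s'.", path))
  ids <- names(terms)
  ns <- vapply(terms, function(t) t$namespace %||% NA_character_, character(1))
  if (!is.null(aspect)) {
    ids <- ids[!is.na(ns) & ns == aspect]
    ns <- ns[ids]
  }
  edge_rows <- purrr::map(terms[ids], function(t) {
    bind_rows(
      tibble(parent = intersect(t$is_a, ids), relation = "is_a"),
      tibble(parent = intersect(t$part_of, ids), relation = "part_of")
    ) |> mutate(child = t$id, .before = 1)
  })
  edges <- bind_rows(edge_rows)
  go_dag(ids, edges, factors = factors,
         namespaces = if (all(is.na(ns))) NULL else setNames(ns, ids))
}

#' Read protein GO annotations
#'
#' Accepts either a two-column TSV (protein, GO term) or a GAF 2.x file
#' (column 2 = object ID, column 5 = GO ID; comment lines start with `!`).
#' Annotations naming terms absent from the companion DAG are dropped with a
#' warning, so every retained term is resolvable for semantic similarity.
#'
#' @param path Annotation file path.
#' @param dag The companion [go_dag()].
#' @param format `"auto"` (default; sniffs GAF by column count / `!gaf`
#'   header), `"tsv"` or `"gaf"`.
#' @return A tibble of class `go_annotations` with columns `protein`, `term`
#'   (one row per annotation, deduplicated).
#' @export
read_go_annotations <- function(path, dag, format = c("auto", "tsv", "gaf")) {
  format <- match.arg(format)
  stopifnot(inherits(dag, "go_dag"))
  lines <- readLines(path, warn = FALSE)
  data_lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "!")]
  if (format == "auto") {
    ncols <- if (length(data_lines) > 0) {
      length(strsplit(data_lines[[1]], "\t", fixed = TRUE)[[1]])
    } else 2L
    format <- if (ncols >= 15 || any(startsWith(lines, "!gaf"))) "gaf" else "tsv"
  }
  if (length(data_lines) == 0) {
    ann <- tibble(protein = character(), term = character())
  } else {
    fields <- strsplit(data_lines, "\t", fixed = TRUE)
    if (format == "gaf") {
      short <- which(lengths(fields) < 5)
      if (length(short) > 0) abort("GAF row with fewer than 5 columns.")
      ann <- tibble(
        protein = vapply(fields, `[[`, character(1), 2L),
        term = vapply(fields, `[[`, character(1), 5L)
      )
    } else {
      bad <- which(lengths(fields) != 2)
      if (length(bad) > 0) {
        abort(sprintf("Malformed annotation line (expected 2 columns): %s", data_lines[bad[1]]))
      }
      ann <- tibble(
        protein = vapply(fields, `[[`, character(1), 1L),
        term = vapply(fields, `[[`, character(1), 2L)
      )
    }
  }
  unknown <- !(ann$term %in% dag$terms)
  if (any(unknown)) {
    warn(sprintf(
      "Dropping %d annotation(s) with GO terms absent from the DAG: %s",
      sum(unknown), paste(unique(ann$term[unknown]), collapse = ", ")
    ))
    ann <- ann[!unknown, ]
  }
  ann <- distinct(ann, .data$protein, .data$term)
  class(ann) <- c("go_annotations", class(ann))
  ann
}

#' Read a subcellular localization table
#'
#' Two-column TSV: protein identifier, compartment name. One protein may
#' occupy several compartments (one row each).
#'
#' @param path Localization file path.
#' @param compartments Allowed compartment vocabulary; rows naming other
#'   compartments are dropped with a warning. Use `NULL` to accept any name.
#'   Defaults to the eleven canonical compartments ([hsep_compartments]).
#' @return A tibble with columns `protein`, `compartment` (deduplicated).
#' @export
read_localizations <- function(path, compartments = hsep_compartments) {
  x <- readr::read_tsv(path,
    col_names = c("protein", "compartment"),
    col_types = "cc", progress = FALSE
  )
  if (!is.null(compartments)) {
    bad <- !(x$compartment %in% compartments)
    if (any(bad)) {
      warn(sprintf(
        "Dropping %d localization row(s) outside the compartment vocabulary: %s",
        sum(bad), paste(unique(x$compartment[bad]), collapse = ", ")
      ))
      x <- x[!bad, ]
    }
  }
  distinct(x, .data$protein, .data$compartment)
}

#' Read a list of known essential proteins
#'
#' @param path Text file with one protein identifier per line (blank lines
#'   ignored).
#' @return A character vector of unique identifiers.
#' @export
read_essential_ids <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Annotation coverage of a network
#'
#' Reports, for each annotation source, how many network proteins it covers.
#' Proteins missing from a source keep a zero contribution from that source
#' during weighting rather than losing their edges.
#'
#' @param net A [ppi_network()].
#' @param expr,ann,loc Optional expression profiles, GO annotations and
#'   localization table as returned by the respective readers.
#' @return A tibble with columns `source`, `covered`, `uncovered`.
#' @export
annotation_coverage <- function(net, expr = NULL, ann = NULL, loc = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  n <- length(net$nodes)
  row <- function(source, ids) {
    covered <- sum(net$nodes %in% ids)
    tibble(source = source, covered = covered, uncovered = n - covered)
  }
  out <- list()
  if (!is.null(expr)) out$expr <- row("expression", expr$protein)
  if (!is.null(ann)) out$ann <- row("go_annotation", unique(ann$protein))
  if (!is.null(loc)) out$loc <- row("localization", unique(loc$protein))
  bind_rows(out)
}
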