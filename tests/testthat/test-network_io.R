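test_that("edge lists are cleaned to a simple network", {
  path <- withr::local_tempfile(lines = c("A\tB", "B\tA", "A\tA", "A\tC"))
  net <- read_ppi_edges(path)
  expect_setequal(net$nodes, c("A", "B", "C"))
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$edges, tibble::tibble(from = c("A", "A"), to = c("B", "C")))
})

test_that("empty and malformed edge files are handled", {
  empty <- withr::local_tempfile(lines = character())
  net <- read_ppi_edges(empty)
  expect_length(net$nodes, 0)
  expect_equal(nrow(net$edges), 0)

  bad <- withr::local_tempfile(lines = c("A\tB", "", "A\tB\tC"))
  expect_error(read_ppi_edges(bad), "line 3")
})

test_that("edge list shape contract holds at interactome scale", {
  # synthetic fixture with the shape of a curated yeast interactome:
  # 5093 proteins, 24743 unique pairs (plus injected duplicates/self-loops)
  withr::local_seed(101)
  n <- 5093
  ids <- sprintf("Y%04d", seq_len(n))
  a <- sample.int(n, 60000, replace = TRUE)
  b <- sample.int(n, 60000, replace = TRUE)
  ok <- a != b
  a <- a[ok]
  b <- b[ok]
  key <- paste(pmin(a, b), pmax(a, b))
  uni <- !duplicated(key)
  stopifnot(sum(uni) >= 24743)
  from <- a[uni][1:24743]
  to <- b[uni][1:24743]
  lines <- paste(ids[from], ids[to], sep = "\t")
  lines <- c(lines, paste(ids[to[1:50]], ids[from[1:50]], sep = "\t"),
             paste(ids[1:20], ids[1:20], sep = "\t"))
  path <- withr::local_tempfile(lines = lines)
  net <- read_ppi_edges(path)
  expect_equal(nrow(net$edges), 24743)
  expect_lte(length(net$nodes), 5093)
})

test_that("write-then-read round-trips a network", {
  withr::local_seed(7)
  net <- random_net(15, 0.3)
  path <- withr::local_tempfile()
  write_ppi_edges(net, path)
  again <- read_ppi_edges(path)
  expect_equal(again$edges, net$edges)
})

test_that("bidirection doubles the edge count", {
  expect_equal(nrow(as_bidirected(ppi_network())), 0)
  tri <- net_of("A-B", "B-C", "A-C")
  expect_equal(nrow(as_bidirected(tri)), 6)
  two <- as_bidirected(net_of("A-B"))
  expect_setequal(paste(two$from, two$to), c("A B", "B A"))
  withr::local_seed(11)
  for (i in 1:5) {
    net <- random_net(sample(5:20, 1), runif(1, 0.1, 0.5))
    expect_equal(nrow(as_bidirected(net)), 2 * nrow(net$edges))
  }
})

test_that("expression reader enforces shape and uniqueness", {
  path <- withr::local_tempfile(
    lines = c("protein\tt1\tt2\tt3", "A\t1\t2\t3", "B\t3\t2\t1")
  )
  expr <- read_expression_profiles(path)
  expect_s3_class(expr, "expression_profiles")
  expect_equal(ncol(expr) - 1, 3)
  expect_equal(expr$protein, c("A", "B"))

  dup <- withr::local_tempfile(
    lines = c("protein\tt1\tt2", "A\t1\t2", "A\t3\t4")
  )
  expect_error(read_expression_profiles(dup), "Duplicate")
})

test_that("OBO parsing keeps is_a/part_of links and rejects cycles", {
  obo <- withr::local_tempfile(lines = c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "is_a: GO:0000001 ! root",
    "relationship: part_of GO:0000001", "",
    "[Term]", "id: GO:0000003", "is_a: GO:0000002", "is_obsolete: true", ""
  ))
  dag <- read_go_obo(obo)
  expect_setequal(dag$terms, c("GO:0000001", "GO:0000002"))
  expect_equal(sort(dag$edges$relation), c("is_a", "part_of"))

  cyc <- withr::local_tempfile(lines = c(
    "[Term]", "id: GO:0000001", "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000002", "is_a: GO:0000001", ""
  ))
  expect_error(read_go_obo(cyc), "cycle")
})

test_that("annotations with unknown terms are dropped with a warning", {
  dag <- go_dag(c("GO:1", "GO:2"),
                tibble::tibble(child = "GO:2", parent = "GO:1", relation = "is_a"))
  path <- withr::local_tempfile(lines = c("P1\tGO:1", "P2\tGO:9"))
  expect_warning(ann <- read_go_annotations(path, dag), "GO:9")
  expect_equal(nrow(ann), 1)
  expect_equal(ann$protein, "P1")
})

test_that("GAF rows are parsed by columns 2 and 5", {
  dag <- go_dag("GO:1")
  gaf_row <- paste(c("DB", "P7", "SYM", "", "GO:1", rep("x", 12)), collapse = "\t")
  path <- withr::local_tempfile(lines = c("!gaf-version: 2.2", gaf_row))
  ann <- read_go_annotations(path, dag)
  expect_equal(ann, as_annotations(tibble::tibble(protein = "P7", term = "GO:1")))
})

test_that("localization vocabulary is enforced and coverage reported", {
  path <- withr::local_tempfile(lines = c(
    "P1\tnucleus", "P1\tcytosol", "P2\tnucleus", "P3\twarp core"
  ))
  expect_warning(loc <- read_localizations(path), "warp core")
  expect_equal(nrow(loc), 3)

  net <- net_of("P1-P2", "P2-P4")
  cov <- annotation_coverage(net, loc = loc)
  expect_equal(cov$covered, 2)   # P1, P2 in network; P3 outside; P4 uncovered
  expect_equal(cov$uncovered, 1)
})

test_that("node order in the input never changes downstream scores", {
  withr::local_seed(23)
  net <- random_net(12, 0.4)
  e <- net$edges
  perm <- sample(nrow(e))
  flip <- runif(nrow(e)) < 0.5
  shuffled <- tibble::tibble(
    from = ifelse(flip, e$to, e$from)[perm],
    to = ifelse(flip, e$from, e$to)[perm]
  )
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  readr::write_tsv(e, p1, col_names = FALSE)
  readr::write_tsv(shuffled, p2, col_names = FALSE)
  n1 <- read_ppi_edges(p1)
  n2 <- read_ppi_edges(p2)
  expr <- tibble::tibble(protein = n1$nodes)
  vals <- matrix(rnorm(length(n1$nodes) * 6), ncol = 6,
                 dimnames = list(NULL, paste0("t", 1:6)))
  expr <- dplyr::bind_cols(expr, tibble::as_tibble(vals))
  class(expr) <- c("expression_profiles", class(expr))
  w1 <- build_weighted_network(n1, expr)
  w2 <- build_weighted_network(n2, expr)
  h1 <- weighted_hits(w1, gamma = 1e-12)
  h2 <- weighted_hits(w2, gamma = 1e-12)
  expect_equal(h1$hub, h2$hub, tolerance = 1e-10)
})
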