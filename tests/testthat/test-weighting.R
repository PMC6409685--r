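test_that("edge clustering coefficient matches hand-worked cases", {
  tri <- net_of("u-v", "v-w", "u-w")
  expect_equal(edge_clustering_coefficient(tri, "u", "v"), 1.0)
  path4 <- net_of("a-b", "b-c", "c-d")
  expect_equal(edge_clustering_coefficient(path4, "b", "c"), 0.5)
  iso <- net_of("a-b")
  expect_equal(edge_clustering_coefficient(iso, "a", "b"), 1.0)
  expect_error(edge_clustering_coefficient(path4, "a", "d"), "not an edge")
})

test_that("ECC is symmetric, in (0,1], and matches brute-force enumeration", {
  withr::local_seed(42)
  for (i in 1:100) {
    net <- random_net(sample(4:30, 1), runif(1, 0.1, 0.6))
    if (nrow(net$edges) == 0) next
    tab <- edge_clustering(net)
    expect_true(all(tab$ecc > 0 & tab$ecc <= 1))
    for (r in sample(nrow(tab), min(5, nrow(tab)))) {
      u <- tab$from[r]
      v <- tab$to[r]
      expect_equal(tab$ecc[r], ecc_brute(net, u, v))
      expect_equal(
        edge_clustering_coefficient(net, u, v),
        edge_clustering_coefficient(net, v, u)
      )
    }
  }
})

test_that("expression correlation follows the Pearson/zero-variance conventions", {
  expr <- tibble::tibble(
    protein = c("a", "b", "c", "d"),
    t1 = c(1, 1, 2, 5), t2 = c(2, 2, 2, 1), t3 = c(3, 3, 2, 4)
  )
  class(expr) <- c("expression_profiles", class(expr))
  expect_equal(expression_correlation(expr, "a", "b"), 1.0)
  rev_expr <- expr
  rev_expr[2, 2:4] <- as.list(c(3, 2, 1))
  expect_equal(expression_correlation(rev_expr, "a", "b"), -1.0)
  expect_equal(expression_correlation(expr, "a", "c"), 0.0)  # zero variance
  expect_true(is.na(expression_correlation(expr, "a", "zz")))
  expect_equal(
    expression_correlation(expr, "a", "d"),
    stats::cor(c(1, 2, 3), c(5, 1, 4))
  )
})

test_that("Wang S-values follow the decayed-ancestor recursion", {
  root <- go_dag("R")
  expect_equal(wang_s_values(root, "R"),
               tibble::tibble(term = "R", s_value = 1))
  two <- go_dag(c("A", "B"),
                tibble::tibble(child = "A", parent = "B", relation = "is_a"))
  expect_equal(wang_s_values(two, "A"),
               tibble::tibble(term = c("A", "B"), s_value = c(1, 0.8)))
  three <- go_dag(c("A", "B", "C"), tibble::tibble(
    child = c("A", "B"), parent = c("B", "C"), relation = "is_a"
  ))
  s <- wang_s_values(three, "A")
  expect_equal(s$s_value[s$term == "C"], 0.64)
  expect_error(wang_s_values(three, "Z"), "Unknown")
})

test_that("S-values take the best path when several exist", {
  # A -is_a-> B -is_a-> D and A -part_of-> D: 0.8*0.8 = 0.64 beats 0.6
  dag <- go_dag(c("A", "B", "D"), tibble::tibble(
    child = c("A", "B", "A"), parent = c("B", "D", "D"),
    relation = c("is_a", "is_a", "part_of")
  ))
  s <- wang_s_values(dag, "A")
  expect_equal(s$s_value[s$term == "D"], 0.64)
})

test_that("GO similarity matches hand fixtures and the path-enumeration oracle", {
  dag <- go_dag(c("A", "B"),
                tibble::tibble(child = "A", parent = "B", relation = "is_a"))
  ann <- as_annotations(tibble::tibble(protein = c("u", "v"), term = c("A", "B")))
  expect_equal(go_similarity(dag, ann, "u", "v"), 1.8 / 2.8)

  same <- as_annotations(tibble::tibble(protein = c("u", "v"), term = c("A", "A")))
  expect_equal(go_similarity(dag, same, "u", "v"), 1.0)

  # disjoint components -> no shared ancestors
  dag2 <- go_dag(c("A", "B", "C", "D"), tibble::tibble(
    child = c("A", "C"), parent = c("B", "D"), relation = "is_a"
  ))
  disj <- as_annotations(tibble::tibble(protein = c("u", "v"), term = c("A", "C")))
  expect_equal(go_similarity(dag2, disj, "u", "v"), 0.0)

  # unannotated protein -> 0
  expect_equal(go_similarity(dag, as_annotations(
    tibble::tibble(protein = "u", term = "A")
  ), "u", "v"), 0.0)

  withr::local_seed(99)
  for (i in 1:25) {
    dag <- random_dag(sample(5:15, 1))
    ann <- as_annotations(tibble::tibble(
      protein = rep(c("u", "v"), each = 2),
      term = sample(dag$terms, 4, replace = TRUE)
    ) |> dplyr::distinct())
    got <- go_similarity(dag, ann, "u", "v")
    want <- go_similarity_brute(dag, ann, "u", "v")
    expect_equal(got, want)
    expect_gte(got, 0)
    expect_lte(got, 1)
    expect_equal(got, go_similarity(dag, ann, "v", "u"))
  }
})

test_that("localization score normalizes shared compartments by the network max", {
  loc <- tibble::tibble(
    protein = c("a", "a", "b", "b", "c", "d"),
    compartment = c("nucleus", "cytosol", "nucleus", "cytosol", "nucleus", "vacuole")
  )
  net <- net_of("a-b", "a-c", "c-d")
  expect_equal(localization_score(loc, net, "a", "b"), 1.0)   # C = C_max = 2
  expect_equal(localization_score(loc, net, "a", "c"), 0.5)   # C = 1, C_max = 2
  expect_equal(localization_score(loc, net, "c", "d"), 0.0)
  # no edge shares anything -> C_max = 0 -> all scores 0
  none <- tibble::tibble(protein = c("a", "b"), compartment = c("nucleus", "vacuole"))
  expect_equal(localization_score(none, net_of("a-b"), "a", "b"), 0)
})

test_that("weighted network combines the channels per mode", {
  tri <- net_of("A-B", "B-C", "A-C")
  expr <- tibble::tibble(
    protein = c("A", "B", "C"),
    t1 = c(1, 1, 1), t2 = c(2, 2, 2), t3 = c(1, 1, 1), t4 = c(0, 0, 0)
  )
  class(expr) <- c("expression_profiles", class(expr))
  dag <- go_dag("GO:1")
  ann <- as_annotations(tibble::tibble(protein = c("A", "B", "C"), term = "GO:1"))
  loc <- tibble::tibble(protein = c("A", "B", "C"), compartment = "nucleus")

  w <- build_weighted_network(tri, expr, dag, ann, loc, mode = "hsep")
  expect_equal(nrow(w), 6)  # both directions
  expect_true(all(w$ecc_weight == 1))
  expect_true(all(abs(w$bio_weight - 3) < 1e-12))

  w_hsp <- build_weighted_network(tri, expr, dag, ann, loc, mode = "hsp")
  expect_true(all(abs(w_hsp$bio_weight - 1) < 1e-12))

  # protein with no annotation of any kind contributes 0 biologically
  square <- net_of("A-B", "B-C", "A-C", "C-Z")
  w2 <- build_weighted_network(square, expr, dag, ann, loc, mode = "hsep")
  z_rows <- w2$from == "Z" | w2$to == "Z"
  expect_true(all(w2$bio_weight[z_rows] == 0))
  expect_true(all(w2$ecc_weight[z_rows] > 0))

  expect_error(build_weighted_network(ppi_network()), "nothing to weight")
})

test_that("negative expression correlation is clamped to zero", {
  net <- net_of("A-B")
  expr <- tibble::tibble(protein = c("A", "B"), t1 = c(1, 3), t2 = c(2, 2), t3 = c(3, 1))
  class(expr) <- c("expression_profiles", class(expr))
  w <- build_weighted_network(net, expr, mode = "hsp")
  expect_equal(unique(w$bio_weight), 0)
})

test_that("weighted network round-trips through the 4-column TSV", {
  withr::local_seed(5)
  net <- random_net(10, 0.4)
  expr <- tibble::tibble(protein = net$nodes)
  vals <- matrix(rnorm(length(net$nodes) * 5), ncol = 5,
                 dimnames = list(NULL, paste0("t", 1:5)))
  expr <- dplyr::bind_cols(expr, tibble::as_tibble(vals))
  class(expr) <- c("expression_profiles", class(expr))
  w <- build_weighted_network(net, expr)
  path <- withr::local_tempfile()
  write_weighted_network(w, path)
  again <- read_weighted_network(path)
  orig <- dplyr::arrange(tibble::as_tibble(w), from, to)
  got <- dplyr::arrange(tibble::as_tibble(again), from, to)
  expect_equal(got$ecc_weight, orig$ecc_weight)
  expect_equal(got$bio_weight, orig$bio_weight)
})
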