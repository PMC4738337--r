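test_that("diff_vector is the difference of side means", {
  vals <- matrix(c(3, 5, 1, 1, 3, 5, 1, 1), 2, 4,
                 dimnames = list(c("g1", "g2"),
                                 c("t1", "r1", "t2", "r2")))
  x <- toy_matrix(vals)
  suppressMessages({
    d <- diff_vector(x, "t1", "r1")
  })
  expect_equal(as.vector(d), c(3 - 1, 5 - 1), ignore_attr = TRUE)

  # tumour set equal to reference set: zero vector
  d0 <- diff_vector(x, c("t1", "t2"), c("t1", "t2"))
  expect_equal(as.vector(d0), c(0, 0), ignore_attr = TRUE)

  # permutation within a side changes nothing
  d1 <- diff_vector(x, c("t1", "t2"), c("r1", "r2"))
  d2 <- diff_vector(x, c("t2", "t1"), c("r2", "r1"))
  expect_identical(d1, d2)

  expect_error(diff_vector(x, character(0), "r1"), "empty")
  expect_error(diff_vector(x, "nope", "r1"), "nope")
})

test_that("match_orthologs intersects the vectors through a 1:1 map", {
  da <- c(a1 = 1, a2 = 2, a3 = 3)
  db <- c(b1 = 5, b3 = 7)
  map <- ortholog_map(c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  suppressMessages(m <- match_orthologs(da, db, map))
  expect_identical(m$n, 2L)
  expect_equal(m$a, c(1, 3))
  expect_equal(m$b, c(5, 7))

  full <- ortholog_map(names(da), names(da))
  m2 <- match_orthologs(da, stats::setNames(da * 2, names(da)), full)
  expect_identical(m2$n, 3L)

  multi <- ortholog_map(c("a1", "a1"), c("b1", "b3"))
  expect_error(match_orthologs(da, db, multi), "1:1")
  none <- ortholog_map("zz", "yy")
  expect_error(match_orthologs(da, db, none), "no ortholog pair")
})

test_that("agdex_score matches hand-computed cosines and its symmetries", {
  d <- c(2, 1, -1)
  expect_equal(agdex_score(d, d), 1)
  expect_equal(agdex_score(d, -d), -1)
  expect_equal(agdex_score(c(2, 1, -1), c(1, 1, 0)), 3 / sqrt(12))

  set.seed(8)
  a <- stats::rnorm(20); b <- stats::rnorm(20)
  s <- agdex_score(a, b)
  for (c_pos in c(0.5, 3)) {
    expect_equal(agdex_score(c_pos * a, b), s)
  }
  expect_equal(agdex_score(-2 * a, b), -s)
  perm <- sample(20)
  expect_equal(agdex_score(a[perm], b[perm]), s)

  expect_warning(s0 <- agdex_score(c(0, 0), c(1, 2)), "all-zero")
  expect_true(is.na(s0))
  expect_error(agdex_score(1, c(1, 2)), "equal length")
})

test_that("exhaustive permutation p matches full enumeration with the add-one rule", {
  # dA = dB = (1,2,3): only the identity permutation reaches |score| = 1,
  # so p = (1 + 1) / (3! + 1) = 2/7
  res <- agdex_permutation_p(c(1, 2, 3), c(1, 2, 3))
  expect_true(res$exhaustive)
  expect_identical(res$n_perm, 6L)
  expect_equal(res$p, 2 / 7)

  # enumeration oracle on a 4-gene case
  da <- c(1, -2, 3, 0.5)
  db <- c(2, 1, -1, 0.25)
  obs <- agdex_score(da, db)
  perms <- NULL
  for (i in 1:4) for (j in setdiff(1:4, i)) for (k in setdiff(1:4, c(i, j))) {
    perms <- rbind(perms, c(i, j, k, setdiff(1:4, c(i, j, k))))
  }
  scores <- apply(perms, 1, function(ix) agdex_score(da, db[ix]))
  expected <- (1 + sum(abs(scores) >= abs(obs) - 1e-12)) / (24 + 1)
  got <- agdex_permutation_p(da, db)
  expect_identical(got$n_perm, 24L)
  expect_equal(got$p, expected)
})

test_that("Monte-Carlo permutation p is deterministic and near the exhaustive value", {
  set.seed(17)
  da <- stats::rnorm(6)
  db <- stats::rnorm(6)
  exact <- agdex_permutation_p(da, db)$p
  mc1 <- agdex_permutation_p(da, db, n_perm = 20000, seed = 42,
                             exhaustive_limit = 0)
  mc2 <- agdex_permutation_p(da, db, n_perm = 20000, seed = 42,
                             exhaustive_limit = 0)
  expect_identical(mc1$p, mc2$p)
  expect_false(mc1$exhaustive)
  expect_lt(abs(mc1$p - exact), 0.01)
})

test_that("agdex matrix recovers linked pairs and transposes under role swap", {
  sim <- simulate_two_species(sim_params(rho = 1), seed = 2)
  ann_a <- sim$annotation[sim$annotation$species == "mouse", ]
  ann_b <- sim$annotation[sim$annotation$species == "human", ]
  res <- suppressMessages(
    agdex_matrix(sim$a, ann_a, sim$b, ann_b, sim$map,
                 reference_a = "cortex", reference_b = "cortex",
                 n_perm = 50, seed = 9))
  linked <- sim$truth$linked
  for (i in seq_len(nrow(linked))) {
    row <- res$scores[linked$a[i], ]
    expect_identical(names(which.max(row)), linked$b[i])
  }
  expect_true(all(res$p > 0 & res$p <= 1))
  # swapping species transposes the score matrix
  map_rev <- ortholog_map(sim$map$gene_b, sim$map$gene_a)
  rev <- suppressMessages(
    agdex_matrix(sim$b, ann_b, sim$a, ann_a, map_rev,
                 reference_a = "cortex", reference_b = "cortex",
                 n_perm = 1, seed = 9))
  expect_equal(rev$scores, t(res$scores))
})

test_that("a group compared with itself through an identity map scores 1", {
  sim <- simulate_two_species(small_sim_params(), seed = 12)
  ann <- check_annotation(sim$a, sim$annotation)
  idmap <- ortholog_map(gene_ids(sim$a), gene_ids(sim$a))
  tum <- ann$sample_id[ann$group == "G1"]
  ref <- ann$sample_id[ann$group == "cortex"]
  res <- agdex_pair(sim$a, sim$a, tum, ref, tum, ref, idmap, n_perm = 10,
                    seed = 1)
  expect_equal(res$score, 1)
})

test_that("centroid correlation ranks planted progenitors first", {
  sim <- simulate_two_species(sim_params(), seed = 6)
  ann <- check_annotation(sim$a, sim$annotation)
  tum <- ann$sample_id[ann$role == "tumour"]
  xt <- expression_matrix(unclass(sim$a)[, tum], "mouse")
  filt <- suppressMessages(apply_filters(xt))
  prog <- sim$truth$progenitors$a
  xr <- expression_matrix(
    unclass(sim$a)[, unlist(prog), drop = FALSE], "mouse")
  lab <- sim$truth$labels$a[tum]
  r <- centroid_correlation(filt$matrix, lab, xr, prog)
  expect_true(all(r >= -1 & r <= 1))
  for (g in rownames(r)) {
    expect_identical(colnames(r)[which.max(r[g, ])], paste0("prog_", g))
  }
})

test_that("centroid correlation closed cases and degenerate input", {
  vals <- matrix(c(1, 2, 3, 4,
                   1, 2, 3, 4,
                   4, 3, 2, 1), 4, 3,
                 dimnames = list(paste0("g", 1:4), c("t1", "t2", "r1")))
  x <- toy_matrix(vals)
  r <- centroid_correlation(
    toy_matrix(vals[, 1:2, drop = FALSE]), c("G", "G"),
    toy_matrix(vals[, 3, drop = FALSE]), list(self = "r1"))
  expect_equal(unname(r["G", "self"]), -1)
  r_self <- centroid_correlation(
    toy_matrix(vals[, 1:2, drop = FALSE]), c("G", "G"),
    toy_matrix(vals[, 1, drop = FALSE]), list(copy = "t1"))
  expect_equal(unname(r_self["G", "copy"]), 1)

  small <- toy_matrix(matrix(1:4, 2, 2,
                             dimnames = list(c("g1", "g2"), c("a", "b"))))
  expect_error(centroid_correlation(small, c("G", "G"), small,
                                    list(s = "a")), "fewer than 3")
})
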