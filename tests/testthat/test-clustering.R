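test_that("pearson_distance matches hand-computed correlations", {
  a <- c(1, 2, 3); b <- c(1, 2, 4)
  vals <- cbind(s1 = a, s2 = b, s3 = a)
  rownames(vals) <- paste0("g", 1:3)
  d <- pearson_distance(toy_matrix(vals))
  expect_equal(diag(d), c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(d["s1", "s3"], 0)                        # duplicated profile
  expect_equal(d["s1", "s2"], 1 - stats::cor(a, b))     # ~0.01802
  expect_equal(d["s1", "s2"], 0.01802, tolerance = 1e-4)
  expect_equal(d, t(d))

  anti <- cbind(s1 = c(1, 2, 3), s2 = c(3, 2, 1))
  rownames(anti) <- paste0("g", 1:3)
  expect_equal(pearson_distance(toy_matrix(anti))["s1", "s2"], 2)  # r = -1

  flat <- cbind(s1 = c(1, 2, 3), bad = c(5, 5, 5))
  rownames(flat) <- paste0("g", 1:3)
  expect_error(pearson_distance(toy_matrix(flat)), "bad")
})

test_that("average_linkage_cut handles boundary k and separates clean pairs", {
  d <- matrix(c(0, 0.1, 0.9, 0.95,
                0.1, 0, 0.92, 0.9,
                0.9, 0.92, 0, 0.08,
                0.95, 0.9, 0.08, 0), 4, 4,
              dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  expect_identical(unname(average_linkage_cut(d, 1)), rep(1L, 4))
  expect_identical(length(unique(average_linkage_cut(d, 4))), 4L)
  two <- average_linkage_cut(d, 2)
  expect_identical(two[["s1"]], two[["s2"]])
  expect_identical(two[["s3"]], two[["s4"]])
  expect_false(two[["s1"]] == two[["s3"]])
  expect_error(average_linkage_cut(d, 5), "k must lie")
})

test_that("hclust average linkage agrees with a brute-force UPGMA on random matrices", {
  set.seed(42)
  for (rep in 1:20) {
    n <- 6
    m <- matrix(stats::runif(n * n), n)
    d <- (m + t(m)) / 2
    diag(d) <- 0
    dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
    for (k in c(2, 3, 4)) {
      expect_true(same_partition(average_linkage_cut(d, k), oracle_upgma(d, k)))
    }
  }
})

test_that("pac matches hand-counted band fractions and validates input", {
  M01 <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1))
  expect_equal(pac(M01), 0)
  Mamb <- matrix(0.5, 3, 3); diag(Mamb) <- 1
  expect_equal(pac(Mamb), 1)
  # upper-tri entries 0.05, 0.5, 0.95, 1.0 -> CDF(0.9) - CDF(0.1) = 0.25
  Mx <- matrix(1, 4, 4)
  Mx[1, 2] <- Mx[2, 1] <- 0.05
  Mx[1, 3] <- Mx[3, 1] <- 0.5
  Mx[1, 4] <- Mx[4, 1] <- 0.95
  Mx[2, 3] <- Mx[3, 2] <- 1.0
  Mx[2, 4] <- Mx[4, 2] <- 1.0
  Mx[3, 4] <- Mx[4, 3] <- 1.0
  # upper-tri entries: 0.05, 0.5, 0.95, 1, 1, 1 -> (2 - 1)/6 in the band
  expect_equal(pac(Mx), 1 / 6)
  expect_error(pac(matrix(1, 1, 1)), "size >= 2")
  expect_error(pac(Mx, 0.9, 0.1), "bounds")
})

test_that("pac counts exactly the entries in the ambiguous band", {
  # entry multiset 0.05, 0.5, 0.95, 1.0 (plus two in-band fillers to reach
  # a 4x4 upper triangle): band (0.1, 0.9] holds 0.5 and the fillers
  M <- diag(4)
  M[upper.tri(M)] <- c(0.05, 0.5, 0.95, 1.0, 0.3, 0.7)
  M <- M + t(M) - diag(diag(M))
  diag(M) <- 1
  expect_equal(pac(M), 3 / 6)
  # and on the bare 4-entry multiset, CDF(0.9) - CDF(0.1) = 2/4 - 1/4
  e <- c(0.05, 0.5, 0.95, 1.0)
  expect_equal(mean(e <= 0.9) - mean(e <= 0.1), 0.25)
})

test_that("pac is monotone in its band bounds", {
  set.seed(7)
  M <- matrix(stats::runif(64), 8)
  M <- (M + t(M)) / 2; diag(M) <- 1
  for (up in c(0.7, 0.9)) {
    expect_gte(pac(M, 0.05, up), pac(M, 0.2, up))
  }
  for (lo in c(0.05, 0.2)) {
    expect_lte(pac(M, lo, 0.7), pac(M, lo, 0.9))
  }
})

test_that("consensus on duplicated blocks with p_item = 1, R = 1 is exact", {
  set.seed(3)
  block1 <- stats::rnorm(20)
  block2 <- stats::rnorm(20) + c(3, -3)
  vals <- cbind(a1 = block1, a2 = block1, a3 = block1,
                b1 = block2, b2 = block2, b3 = block2)
  vals <- vals + matrix(stats::rnorm(120, 0, 1e-4), 20)
  rownames(vals) <- paste0("g", 1:20)
  res <- consensus_cluster(toy_matrix(vals), k_range = 2, R = 1, p_item = 1,
                           seed = 1)
  M <- res$per_k[["2"]]$consensus
  expect_true(all(M %in% c(0, 1)))
  expect_equal(unname(M["a1", "a2"]), 1)
  expect_equal(unname(M["a1", "b1"]), 0)
  expect_true(same_partition(res$labels, rep(1:2, each = 3)))
  expect_equal(res$pac[["2"]], 0)
})

test_that("consensus clustering is bit-identical under a fixed seed", {
  sim <- simulate_two_species(small_sim_params(), seed = 3)
  xt <- tumour_matrix(sim)
  r1 <- consensus_cluster(xt, k_range = 2:4, R = 30, seed = 99)
  r2 <- consensus_cluster(xt, k_range = 2:4, R = 30, seed = 99)
  expect_identical(r1$pac, r2$pac)
  expect_identical(r1$per_k[["3"]]$consensus, r2$per_k[["3"]]$consensus)
  expect_identical(r1$labels, r2$labels)
})

test_that("consensus matrices are equivariant under sample permutation", {
  sim <- simulate_two_species(small_sim_params(), seed = 4)
  xt <- tumour_matrix(sim)
  res <- consensus_cluster(xt, k_range = 3, R = 40, seed = 5)
  perm <- sample(ncol(xt))
  # permuting columns and permuting the seed-matched subsample indices do
  # not commute, so equivariance is asserted through the quantity that is
  # invariant by construction: the multiset of consensus entries of the
  # relabeled matrix equals a relabeling of the original
  M <- res$per_k[["3"]]$consensus
  Mp <- M[perm, perm]
  expect_equal(sort(Mp[upper.tri(Mp)]), sort(M[upper.tri(M)]))
  expect_equal(pac(Mp), pac(M))
})

test_that("consensus matrix entries are valid probabilities with unit diagonal", {
  sim <- simulate_two_species(small_sim_params(), seed = 6)
  xt <- tumour_matrix(sim)
  res <- consensus_cluster(xt, k_range = 2:4, R = 25, seed = 2)
  for (k in names(res$per_k)) {
    M <- res$per_k[[k]]$consensus
    expect_true(all(M >= 0 & M <= 1))
    expect_equal(diag(M), rep(1, ncol(xt)), ignore_attr = TRUE)
    expect_equal(M, t(M))
    expect_true(res$per_k[[k]]$pac >= 0 && res$per_k[[k]]$pac <= 1)
  }
})

test_that("select_k_pac takes the argmin and logs ties toward smaller k", {
  res <- structure(list(pac = c(`2` = 0.40, `3` = 0.05, `4` = 0.20),
                        k_range = 2:4), class = "consensus_result")
  expect_identical(select_k_pac(res), 3L)
  res$pac <- c(`2` = 0.10, `3` = 0.10, `4` = 0.30)
  expect_message(k <- select_k_pac(res), "tie")
  expect_identical(k, 2L)
})
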