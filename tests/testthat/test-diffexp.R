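test_that("welch_test reproduces closed-form cases", {
  same <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # hand evaluation: means 2.5/4.5, both variances 5/3, se^2 = 5/6,
  # t = -2/sqrt(5/6) ~ -2.1909, Satterthwaite df = 6, p ~ 0.0707
  worked <- welch_test(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(worked$t, -2.190890, tolerance = 1e-6)
  expect_equal(worked$df, 6)
  expect_equal(worked$p, 0.071, tolerance = 1e-2)

  degen <- welch_test(c(0, 0), c(1, 1))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 0)
  expect_equal(welch_test(c(2, 2), c(2, 2))$p, 1)

  expect_error(welch_test(1, c(1, 2)), "at least 2")
})

test_that("welch_test agrees with a brute-force oracle and with stats::t.test", {
  set.seed(123)
  for (i in 1:1000) {
    a <- stats::rnorm(sample(2:8, 1), sd = stats::runif(1, 0.5, 2))
    b <- stats::rnorm(sample(2:8, 1), mean = stats::runif(1, -1, 1))
    got <- welch_test(a, b)
    ref <- oracle_welch(a, b)
    expect_equal(got$t, ref$t, tolerance = 1e-10)
    expect_equal(got$df, ref$df, tolerance = 1e-10)
    expect_equal(got$p, ref$p, tolerance = 1e-10)
  }
  # independent cross-check against the standard implementation
  set.seed(5)
  for (i in 1:25) {
    a <- stats::rnorm(6); b <- stats::rnorm(7, 0.5)
    got <- welch_test(a, b)
    tt <- stats::t.test(a, b)
    expect_equal(got$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(got$df, unname(tt$parameter), tolerance = 1e-12)
    expect_equal(got$p, tt$p.value, tolerance = 1e-12)
  }
})

test_that("bh_adjust reproduces hand step-up evaluations and validates input", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_identical(bh_adjust(numeric(0)), numeric(0))
})

test_that("bh_adjust is permutation-equivariant, monotone, and matches the oracle", {
  set.seed(9)
  for (i in 1:20) {
    p <- stats::runif(50)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    perm <- sample(50)
    expect_equal(bh_adjust(p[perm]), q[perm])
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    expect_true(all(q >= p - 1e-12) && all(q <= 1))
  }
})

test_that("differential_table applies the Welch/BH/fold-change rules per gene", {
  set.seed(31)
  base <- matrix(stats::rnorm(5 * 8, 5, 0.01), 5, 8)
  base[3, 5:8] <- base[3, 5:8] + 2        # planted gene, fc = +2, tiny noise
  dimnames(base) <- list(paste0("g", 1:5), paste0("s", 1:8))
  x <- toy_matrix(base)
  lab <- rep(c("A", "B"), each = 4)
  tab <- differential_table(x, lab, "B", "A")
  expect_identical(tab$gene_id, paste0("g", 1:5))
  expect_identical(which(tab$passes), 3L)
  expect_equal(tab$fc[3], 2, tolerance = 0.05)
  expect_true(all(tab$q >= tab$p - 1e-12))
  expect_true(all(tab$q <= 1))

  # symmetry: permuting samples within groups changes nothing
  perm <- c(sample(1:4), sample(5:8))
  tab2 <- differential_table(toy_matrix(base[, perm]), lab[perm], "B", "A")
  expect_equal(tab2, tab)

  expect_error(differential_table(x, lab, "A", "C"), "fewer than 2")
})

test_that("a gene identical across groups never passes", {
  vals <- matrix(rep(c(1, 2, 3, 4), times = 6), 4, 6,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  tab <- differential_table(toy_matrix(vals), rep(c("A", "B"), 3), "A", "B")
  expect_true(all(tab$fc == 0))
  expect_false(any(tab$passes))
})

test_that("group_signatures requires winning every pairwise comparison", {
  set.seed(77)
  n_per <- 4
  vals <- matrix(stats::rnorm(6 * 12, 5, 0.05), 6, 12,
                 dimnames = list(paste0("g", 1:6),
                                 paste0("s", 1:12)))
  lab <- rep(c("G1", "G2", "G3"), each = n_per)
  vals[1, lab == "G1"] <- vals[1, lab == "G1"] + 3   # up in G1 vs both
  vals[2, lab == "G2"] <- vals[2, lab == "G2"] + 3   # up in G2 vs both
  vals[3, lab == "G1"] <- vals[3, lab == "G1"] + 3   # up in G1 vs G2 only
  vals[3, lab == "G3"] <- vals[3, lab == "G3"] + 3   # ... flat vs G3
  x <- toy_matrix(vals)
  sig <- group_signatures(x, lab)
  expect_identical(sig$G1, "g1")
  expect_identical(sig$G2, "g2")
  expect_identical(sig$G3, character(0))
  # disjointness
  all_genes <- unlist(sig)
  expect_identical(anyDuplicated(all_genes), 0L)

  # two identical groups: every signature empty
  flat <- toy_matrix(matrix(stats::rnorm(4 * 8, 3, 0.01), 4, 8,
                            dimnames = list(paste0("g", 1:4),
                                            paste0("s", 1:8))))
  sig0 <- group_signatures(flat, rep(c("A", "B"), each = 4))
  expect_true(all(lengths(sig0) == 0))

  expect_error(group_signatures(x, c(lab[-1], "G9")), "G9")
})

test_that("ddct evaluates the closed form", {
  expect_equal(ddct(20, 20, 20, 20), 1)
  expect_equal(ddct(21, 20, 20, 20), 0.5)   # ddCt = 1
  expect_equal(ddct(18, 20, 20, 20), 4)     # ddCt = -2
  expect_error(ddct(Inf, 20, 20, 20))
})
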