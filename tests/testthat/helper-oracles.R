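# Independent reference implementations used as oracles. They favour
# clarity over speed and stay separate from the package's code paths.

# Scalar Welch test evaluated literally from the textbook formulas.
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Literal step-up Benjamini-Hochberg evaluation.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Naive UPGMA agglomeration over an explicit cluster list.
oracle_upgma <- function(d, k) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          dd <- mean(d[clusters[[i]], clusters[[j]]])
          if (dd < best_d) {
            best_d <- dd
            best <- c(i, j)
          }
        }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  labels
}

# Partition comparison ignoring label names.
same_partition <- function(a, b) {
  mclust::adjustedRandIndex(a, b) == 1
}

# Small simulation shape used across tests: one species with three groups,
# no linkage, no progenitors.
small_sim_params <- function(...) {
  sim_params(groups_a = c("G1", "G2", "G3"), groups_b = c("H1", "H2"),
             samples_per_group = 10,
             linked = data.frame(a = character(0), b = character(0)),
             n_core = 60, n_specific = 40, n_background = 60,
             n_invariant = 60, n_reference = 3, progenitor_samples = 0, ...)
}

# Tumour-sample submatrix of one species of a simulation.
tumour_matrix <- function(sim, side = "a") {
  x <- sim[[side]]
  ann <- check_annotation(x, sim$annotation)
  tum <- ann$sample_id[ann$role == "tumour"]
  expression_matrix(unclass(x)[, tum, drop = FALSE], expr_species(x))
}

# Deterministic toy expression matrix.
toy_matrix <- function(values, species = "test") {
  expression_matrix(values, species)
}
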