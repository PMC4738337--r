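#' Pearson correlation distance between samples
#'
#' `d(i, j) = 1 - r(i, j)` where `r` is the Pearson correlation of the two
#' samples' gene vectors, so distances lie in `[0, 2]` with zero diagonal.
#'
#' @param x An [expression_matrix()] or plain genes x samples numeric matrix.
#' @return A symmetric numeric matrix with sample identifiers as dimnames.
#' @export
pearson_distance <- function(x) {
  vals <- unclass(x)
  if (ncol(vals) < 2L) {
    stop("need at least 2 samples", call. = FALSE)
  }
  sds <- apply(vals, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance sample(s): ",
         paste(colnames(vals)[sds == 0], collapse = ", "), call. = FALSE)
  }
  d <- 1 - stats::cor(vals)
  diag(d) <- 0
  d
}

#' Cut an average-linkage (UPGMA) tree into k groups
#'
#' Agglomerates with the unweighted mean of cross-pair distances and cuts the
#' tree to exactly `k` groups. Deterministic given the distance matrix.
#'
#' @param d Symmetric distance matrix (e.g. from [pearson_distance()]).
#' @param k Number of groups, `1 <= k <= n`.
#' @return Integer cluster labels named by sample identifier.
#' @export
average_linkage_cut <- function(d, k) {
  n <- nrow(d)
  if (k > n || k < 1L) {
    stop("k must lie in 1..", n, ", got ", k, call. = FALSE)
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  stats::cutree(hc, k = k)
}

#' Proportion of ambiguous clustering of a consensus matrix
#'
#' Empirical CDF over the strictly upper-triangular consensus entries,
#' evaluated as `CDF(upper) - CDF(lower)`: the fraction of sample pairs whose
#' consensus lies in the ambiguous band `(lower, upper]`. Low PAC means most
#' pairs either always or never co-cluster.
#'
#' @param M Consensus matrix (symmetric, entries in `[0, 1]`).
#' @param lower,upper Band bounds, `0 <= lower < upper <= 1`; defaults 0.1
#'   and 0.9.
#' @return A number in `[0, 1]`.
#' @export
pac <- function(M, lower = 0.1, upper = 0.9) {
  if (!is.matrix(M) || nrow(M) < 2L || nrow(M) != ncol(M)) {
    stop("M must be a square matrix of size >= 2", call. = FALSE)
  }
  if (!(lower >= 0 && lower < upper && upper <= 1)) {
    stop("bounds must satisfy 0 <= lower < upper <= 1", call. = FALSE)
  }
  e <- M[upper.tri(M)]
  mean(e <= upper) - mean(e <= lower)
}

#' Consensus clustering with PAC model selection
#'
#' For each candidate `k`: draw `R` subsamples of `ceiling(p_item * n)`
#' samples without replacement, cluster each by Pearson distance and
#' average linkage cut at `k`, and record for every sample pair the fraction
#' of co-sampled draws in which it co-clustered. Final labels re-cluster
#' `1 - M` by average linkage; `k` is selected by minimum [pac()].
#' Subsample `r` uses seed `seed + r`, so results are reproducible and the
#' same subsamples serve every `k`.
#'
#' @param x An [expression_matrix()] (genes x samples) of the samples to
#'   cluster.
#' @param k_range Candidate group counts, default `2:7`.
#' @param R Number of resamplings (the published analyses used 1000).
#' @param p_item Fraction of samples per draw (no feature resampling).
#' @param seed Integer seed; all randomness derives from it.
#' @param pac_lower,pac_upper Band passed to [pac()].
#' @return An object of class `consensus_result`: list with `per_k` (for each
#'   k: `consensus`, `labels`, `pac`), `pac` (named vector), `selected_k`,
#'   `ties` (logical), and the resampling parameters.
#' @export
consensus_cluster <- function(x, k_range = 2:7, R = 1000, p_item = 0.8,
                              seed = 1, pac_lower = 0.1, pac_upper = 0.9) {
  vals <- unclass(x)
  n <- ncol(vals)
  if (max(k_range) >= n) {
    stop("max(k_range) must be smaller than the sample count (", n, ")",
         call. = FALSE)
  }
  if (R < 1L) {
    stop("R must be >= 1", call. = FALSE)
  }
  n_sub <- ceiling(p_item * n)
  if (n_sub < max(k_range)) {
    stop("p_item too small: subsamples of ", n_sub,
         " samples cannot be cut into ", max(k_range), " groups", call. = FALSE)
  }
  co_sampled <- matrix(0, n, n)
  co_clustered <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_clustered) <- as.character(k_range)
  for (r in seq_len(R)) {
    set.seed(seed + r)
    idx <- sort(sample.int(n, n_sub))
    co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
    d <- pearson_distance(vals[, idx, drop = FALSE])
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    cuts <- stats::cutree(hc, k = k_range)
    if (length(k_range) == 1L) {
      cuts <- matrix(cuts, ncol = 1L)
    }
    for (j in seq_along(k_range)) {
      lab <- cuts[, j]
      same <- outer(lab, lab, `==`) * 1
      kk <- as.character(k_range[j])
      co_clustered[[kk]][idx, idx] <- co_clustered[[kk]][idx, idx] + same
    }
  }
  never <- co_sampled == 0 & upper.tri(co_sampled)
  if (any(never)) {
    warning(sum(never), " sample pair(s) were never co-sampled; their ",
            "consensus is reported as 0", call. = FALSE)
  }
  ids <- colnames(vals)
  per_k <- lapply(k_range, function(k) {
    M <- co_clustered[[as.character(k)]]
    M <- ifelse(co_sampled > 0, M / pmax(co_sampled, 1), 0)
    diag(M) <- 1
    dimnames(M) <- list(ids, ids)
    labels <- average_linkage_cut(1 - M, k)
    list(consensus = M, labels = labels,
         pac = pac(M, pac_lower, pac_upper))
  })
  names(per_k) <- as.character(k_range)
  pac_k <- vapply(per_k, `[[`, numeric(1L), "pac")
  res <- structure(list(
    per_k = per_k, pac = pac_k, k_range = k_range,
    R = R, p_item = p_item, seed = seed,
    pac_lower = pac_lower, pac_upper = pac_upper
  ), class = "consensus_result")
  res$selected_k <- select_k_pac(res)
  res$labels <- per_k[[as.character(res$selected_k)]]$labels
  res
}

#' Select k by minimum PAC
#'
#' Returns the candidate `k` with the lowest proportion of ambiguous
#' clustering; ties break toward the smaller `k` and are reported.
#'
#' @param result A `consensus_result` from [consensus_cluster()].
#' @return The selected integer `k`.
#' @export
select_k_pac <- function(result) {
  pac_k <- result$pac
  best <- min(pac_k)
  hits <- result$k_range[pac_k == best]
  if (length(hits) > 1L) {
    message("PAC tie among k = ", paste(hits, collapse = ", "),
            "; selecting k = ", min(hits))
  }
  min(hits)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: R = %d, p_item = %.2f, seed = %d\n",
              x$R, x$p_item, x$seed))
  cat("PAC by k:\n")
  print(round(x$pac, 4))
  cat("selected k:", x$selected_k, "\n")
  invisible(x)
}
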