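#' Welch two-sample t-test
#'
#' Unequal-variance t statistic
#' `t = (mean(a) - mean(b)) / sqrt(s2a/na + s2b/nb)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from the
#' t distribution. When both groups have zero variance the statistic is
#' degenerate: `p = 1` if the means agree, else `p = 0`, and the result is
#' flagged.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A list with `t`, `df`, `p` and `degenerate`.
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("both groups need at least 2 values", call. = FALSE)
  }
  res <- welch_rows(matrix(a, nrow = 1L), matrix(b, nrow = 1L))
  list(t = res$t[1L], df = res$df[1L], p = res$p[1L],
       degenerate = res$degenerate[1L])
}

# Row-wise Welch test: A and B are genes x samples matrices over the two
# groups. Vectorized so genome-wide tables stay fast.
welch_rows <- function(A, B) {
  na <- ncol(A)
  nb <- ncol(B)
  ma <- rowMeans(A)
  mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1L)
  vb <- rowSums((B - mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  degenerate <- se2 == 0
  t_stat <- ifelse(degenerate, ifelse(ma == mb, 0, Inf * sign(ma - mb)),
                   (ma - mb) / sqrt(se2))
  df <- ifelse(degenerate, NA_real_,
               se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L)))
  p <- ifelse(degenerate, ifelse(ma == mb, 1, 0),
              2 * stats::pt(-abs(t_stat), df))
  list(t = t_stat, df = df, p = p, degenerate = degenerate,
       mean_a = ma, mean_b = mb)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: `q_i` is the minimum over ranks
#' `j >= rank(i)` of `p_(j) * m / j`, capped at 1, with input order preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) {
    return(numeric(0))
  }
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-gene differential expression between two groups
#'
#' For every gene: fold change as the difference of group means on the log2
#' scale (`fc = mean_a - mean_b`, so `|fc| >= 1.2` means a linear ratio of at
#' least `2^1.2 ~ 2.3`), Welch test, BH adjustment across all tested genes,
#' and a pass flag combining `q <= alpha` (or raw `p <= alpha` when
#' `adjust = FALSE`) with `|fc| >= min_abs_fc`.
#'
#' @param x An [expression_matrix()].
#' @param labels Group label per sample: either a vector aligned with the
#'   columns of `x` or a named vector keyed by sample identifier.
#' @param group_a,group_b The two labels to compare (`fc > 0` means higher in
#'   `group_a`).
#' @param alpha Significance threshold, default 0.05.
#' @param min_abs_fc Minimum absolute log2 fold change, default 1.2.
#' @param adjust Use BH-adjusted q (default) or raw p for the pass flag.
#' @return A data.frame with one row per gene: `gene_id`, `mean_a`, `mean_b`,
#'   `fc`, `t`, `df`, `p`, `q`, `degenerate`, `passes`.
#' @export
differential_table <- function(x, labels, group_a, group_b, alpha = 0.05,
                               min_abs_fc = 1.2, adjust = TRUE) {
  labels <- align_labels(x, labels)
  for (g in c(group_a, group_b)) {
    if (sum(labels == g) < 2L) {
      stop("group '", g, "' has fewer than 2 samples", call. = FALSE)
    }
  }
  A <- unclass(x)[, labels == group_a, drop = FALSE]
  B <- unclass(x)[, labels == group_b, drop = FALSE]
  w <- welch_rows(A, B)
  q <- bh_adjust(w$p)
  fc <- w$mean_a - w$mean_b
  crit <- if (adjust) q else w$p
  out <- data.frame(
    gene_id = gene_ids(x),
    mean_a = w$mean_a, mean_b = w$mean_b, fc = fc,
    t = w$t, df = w$df, p = w$p, q = q,
    degenerate = w$degenerate,
    passes = crit <= alpha & abs(fc) >= min_abs_fc,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# Resolve labels to a vector aligned with the matrix columns.
align_labels <- function(x, labels) {
  ids <- sample_ids(x)
  if (!is.null(names(labels))) {
    missing_samp <- setdiff(ids, names(labels))
    if (length(missing_samp) > 0L) {
      stop("no label for sample(s): ", paste(missing_samp, collapse = ", "),
           call. = FALSE)
    }
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop("labels length (", length(labels),
         ") does not match sample count (", length(ids), ")", call. = FALSE)
  }
  as.character(labels)
}

#' Group-specific overexpression signatures
#'
#' A gene belongs to the signature of group `G` iff, in every pairwise
#' comparison of `G` against each other group, it is significant
#' (`q <= alpha`, or raw `p <= alpha` when `adjust = FALSE`) with a log2 fold
#' change of at least `+min_fc` in `G`'s favour. BH adjustment is applied
#' within each pairwise comparison. Signatures built this way are disjoint
#' across groups.
#'
#' @param x An [expression_matrix()].
#' @param labels Group label per sample (see [differential_table()]).
#' @param alpha,min_fc,adjust Thresholds as in [differential_table()].
#' @return A named list of gene identifier vectors (one per group, in the
#'   matrix's gene order), with the thresholds stored as attributes
#'   `alpha`, `min_fc`, `adjust`.
#' @export
group_signatures <- function(x, labels, alpha = 0.05, min_fc = 1.2,
                             adjust = TRUE) {
  labels <- align_labels(x, labels)
  groups <- unique(labels)
  if (length(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  small <- groups[vapply(groups, function(g) sum(labels == g) < 2L, logical(1L))]
  if (length(small) > 0L) {
    stop("group(s) with fewer than 2 samples: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  sig <- lapply(groups, function(g) {
    keep <- rep(TRUE, nrow(x))
    for (h in setdiff(groups, g)) {
      tab <- differential_table(x, labels, g, h, alpha = alpha,
                                min_abs_fc = min_fc, adjust = adjust)
      keep <- keep & tab$passes & tab$fc >= min_fc
    }
    gene_ids(x)[keep]
  })
  names(sig) <- groups
  attr(sig, "alpha") <- alpha
  attr(sig, "min_fc") <- min_fc
  attr(sig, "adjust") <- adjust
  sig
}

#' Relative quantification by the 2^-ddCt method
#'
#' `ddCt = (Ct_target_sample - Ct_control_sample) -
#' (Ct_target_calibrator - Ct_control_calibrator)`; the relative quantity is
#' `2^-ddCt`. The control gene is the internal normalizer (e.g. TBP) and the
#' calibrator the baseline sample.
#'
#' @param ct_target_sample,ct_control_sample Cycle thresholds in the sample
#'   of interest for the target and control gene.
#' @param ct_target_calibrator,ct_control_calibrator Cycle thresholds in the
#'   calibrator sample.
#' @return The relative expression quantity `2^-ddCt`.
#' @export
ddct <- function(ct_target_sample, ct_control_sample,
                 ct_target_calibrator, ct_control_calibrator) {
  stopifnot(is.finite(ct_target_sample), is.finite(ct_control_sample),
            is.finite(ct_target_calibrator), is.finite(ct_control_calibrator))
  dd <- (ct_target_sample - ct_control_sample) -
    (ct_target_calibrator - ct_control_calibrator)
  2^(-dd)
}
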