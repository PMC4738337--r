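#' Relative interquartile range of one gene
#'
#' Spread of a gene's log2 values relative to its median:
#' `max(Q3 - Q2, Q2 - Q1) / Q2` under the default symmetric reading.
#' Quartiles use linear interpolation between order statistics at positions
#' `(n - 1) * p` (R's type-7 convention). Genes with `Q2 = 0` get `NA` — they
#' are flagged, never turned into division errors.
#'
#' Two literal variants are selectable for audit: `"methods"` uses
#' `max(Q3 - Q2, Q1 - Q3) / Q2` and `"legend"` uses
#' `max(Q3 - Q2, Q1 - Q2) / Q2`; with ordered quartiles both reduce to
#' `(Q3 - Q2) / Q2` since their second argument is never positive.
#'
#' @param values Numeric vector of length >= 3.
#' @param formula `"symmetric"` (default), `"methods"` or `"legend"`.
#' @return A single number >= 0 for the default formula, or `NA` when the
#'   median is zero.
#' @export
riqr <- function(values, formula = c("symmetric", "methods", "legend")) {
  formula <- match.arg(formula)
  if (length(values) < 3L) {
    stop("riqr needs at least 3 values, got ", length(values), call. = FALSE)
  }
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), names = FALSE,
                       type = 7)
  if (q[2L] == 0) {
    return(NA_real_)
  }
  second <- switch(formula,
                   symmetric = q[2L] - q[1L],
                   methods = q[1L] - q[3L],
                   legend = q[1L] - q[2L])
  max(q[3L] - q[2L], second) / q[2L]
}

#' Filter an expression matrix to expressed and variable genes
#'
#' Two sequential per-gene rules precede all clustering:
#' \enumerate{
#'   \item background: keep a gene iff its maximum log2 value across samples
#'     is at least `background` (default 1.2), so a gene expressed in even a
#'     single subgroup survives; a mean-based alternative is available;
#'   \item variability: among background-passing genes, keep those with
#'     [riqr()] at least `riqr_threshold` (default 0.75) and defined.
#' }
#' The variability flag implies the background flag (filters in sequence).
#'
#' @param x An [expression_matrix()].
#' @param background Background threshold on the log2 scale.
#' @param riqr_threshold Minimum relative IQR.
#' @param background_stat Statistic compared against `background`: `"max"`
#'   (default) or `"mean"`.
#' @param riqr_formula Passed to [riqr()].
#' @return A list with `matrix` (the surviving genes, original order) and
#'   `report`, a data.frame over every input gene with columns `gene_id`,
#'   `max_log2`, `q1`, `q2`, `q3`, `riqr`, `passed_background`,
#'   `passed_variability`.
#' @export
apply_filters <- function(x, background = 1.2, riqr_threshold = 0.75,
                          background_stat = c("max", "mean"),
                          riqr_formula = "symmetric") {
  background_stat <- match.arg(background_stat)
  if (ncol(x) < 3L) {
    stop("need at least 3 samples to compute quartiles", call. = FALSE)
  }
  vals <- unclass(x)
  stat <- if (background_stat == "max") {
    apply(vals, 1L, max)
  } else {
    rowMeans(vals)
  }
  q <- t(apply(vals, 1L, stats::quantile, probs = c(0.25, 0.5, 0.75),
               names = FALSE, type = 7))
  second <- switch(riqr_formula,
                   symmetric = q[, 2L] - q[, 1L],
                   methods = q[, 1L] - q[, 3L],
                   legend = q[, 1L] - q[, 2L],
                   stop("unknown riqr formula: ", riqr_formula, call. = FALSE))
  r <- pmax(q[, 3L] - q[, 2L], second) / q[, 2L]
  r[q[, 2L] == 0] <- NA_real_
  passed_bg <- stat >= background
  passed_var <- passed_bg & !is.na(r) & r >= riqr_threshold
  report <- data.frame(
    gene_id = gene_ids(x),
    max_log2 = apply(vals, 1L, max),
    q1 = q[, 1L], q2 = q[, 2L], q3 = q[, 3L],
    riqr = r,
    passed_background = passed_bg,
    passed_variability = passed_var,
    stringsAsFactors = FALSE
  )
  rownames(report) <- NULL
  if (!any(passed_var)) {
    stop("no gene passes both filters; review the background (",
         background, ") and RIQR (", riqr_threshold, ") thresholds",
         call. = FALSE)
  }
  list(
    matrix = expression_matrix(vals[passed_var, , drop = FALSE],
                               expr_species(x)),
    report = report
  )
}
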