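#' Non-negative matrix factorization with multiplicative KL updates
#'
#' Factorizes a non-negative matrix `V` (genes x samples) as `V ~ W H` with
#' `W >= 0` (genes x k) and `H >= 0` (k x samples) by the standard
#' multiplicative update scheme minimizing the Kullback-Leibler divergence
#' `D(V || WH) = sum(V log(V / WH) - V + WH)`. Each of `runs` random restarts
#' records a sample connectivity matrix (`c(i, j) = 1` iff samples i and j
#' share the same argmax row of `H`); their mean is the consensus
#' connectivity, whose stability across restarts is summarized by the
#' cophenetic correlation between `1 - consensus` and the cophenetic
#' distances of its average-linkage tree. Run `r` uses seed `seed + r`.
#'
#' @param V Non-negative numeric matrix (an [expression_matrix()] works).
#' @param k Factorization rank, `k < min(dim(V))`.
#' @param runs Random restarts (the published analyses used 30).
#' @param max_iter Maximum multiplicative updates per run.
#' @param tol Relative objective change below which a run stops.
#' @param seed Integer seed.
#' @param clip_at_zero If `TRUE`, negative entries are clipped to 0 before
#'   factorization; by default they are an error, because silent shifting
#'   changes the KL geometry.
#' @return An object of class `nmf_result`: list with `W`, `H` (best run by
#'   final objective), `connectivity` (consensus over runs), `cophenetic`,
#'   `objective` (per-run traces), `k`, `runs`, `seed`, and `labels`
#'   (argmax-of-H sample assignment of the best run).
#' @export
nmf_factorize <- function(V, k, runs = 30, max_iter = 2000, tol = 1e-6,
                          seed = 1, clip_at_zero = FALSE) {
  V <- unclass(V)
  if (any(V < 0)) {
    if (!clip_at_zero) {
      stop("V contains negative entries; set clip_at_zero = TRUE to clip",
           call. = FALSE)
    }
    V[V < 0] <- 0
  }
  n_genes <- nrow(V)
  n_samples <- ncol(V)
  if (k >= min(n_genes, n_samples)) {
    stop("k must be smaller than min(dim(V)) = ", min(n_genes, n_samples),
         call. = FALSE)
  }
  eps <- .Machine$double.eps
  pos <- V > 0
  v_pos <- V[pos]
  v_sum <- sum(V)
  kl_div <- function(WH) {
    sum(v_pos * log(v_pos / WH[pos])) - v_sum + sum(WH)
  }
  check_every <- 10L
  best <- NULL
  traces <- vector("list", runs)
  connect <- matrix(0, n_samples, n_samples)
  for (r in seq_len(runs)) {
    set.seed(seed + r)
    W <- matrix(stats::runif(n_genes * k), n_genes, k)
    H <- matrix(stats::runif(k * n_samples), k, n_samples)
    WH <- W %*% H
    obj <- kl_div(WH)
    trace <- obj
    for (it in seq_len(max_iter)) {
      # H update: H <- H * (t(W) %*% (V/WH)) / colSums(W)
      H <- H * (crossprod(W, V / (WH + eps))) / (colSums(W) + eps)
      WH <- W %*% H
      # W update: W <- W * ((V/WH) %*% t(H)) / rowSums(H)
      W <- W * ((V / (WH + eps)) %*% t(H)) / rep(rowSums(H) + eps,
                                                 each = n_genes)
      WH <- W %*% H
      if (it %% check_every == 0L || it == max_iter) {
        new_obj <- kl_div(WH)
        trace <- c(trace, new_obj)
        if (abs(obj - new_obj) <= tol * max(abs(obj), 1)) {
          obj <- new_obj
          break
        }
        obj <- new_obj
      }
    }
    traces[[r]] <- trace
    lab <- apply(H, 2L, which.max)
    connect <- connect + outer(lab, lab, `==`) * 1
    if (is.null(best) || obj < best$objective) {
      best <- list(W = W, H = H, objective = obj, labels = lab, run = r)
    }
  }
  connect <- connect / runs
  dimnames(connect) <- list(colnames(V), colnames(V))
  coph <- nmf_cophenetic(connect)
  structure(list(
    W = best$W, H = best$H, labels = stats::setNames(best$labels, colnames(V)),
    best_run = best$run, best_objective = best$objective,
    connectivity = connect, cophenetic = coph,
    objective = traces, k = k, runs = runs, seed = seed
  ), class = "nmf_result")
}

# Cophenetic correlation of a consensus connectivity matrix: correlation
# between the dissimilarity 1 - C and the tree-implied distances of its
# average-linkage clustering. A perfectly stable (0/1 block) consensus has
# zero-variance dissimilarities off the blocks only; cor() then degenerates,
# and stability is reported as 1.
nmf_cophenetic <- function(C) {
  d <- stats::as.dist(1 - C)
  hc <- stats::hclust(d, method = "average")
  cd <- stats::cophenetic(hc)
  if (stats::sd(d) == 0 || stats::sd(cd) == 0) {
    if (all(abs(d - cd) < 1e-12)) {
      return(1)
    }
    return(NA_real_)
  }
  stats::cor(d, cd)
}

#' Run NMF over a range of ranks
#'
#' Calls [nmf_factorize()] for each `k` and selects the rank with the best
#' cophenetic correlation.
#'
#' @param V Non-negative matrix.
#' @param k_range Candidate ranks, default `2:7`.
#' @inheritParams nmf_factorize
#' @return An object of class `nmf_scan`: list with `per_k` (named list of
#'   `nmf_result`), `cophenetic` (named vector) and `selected_k`.
#' @export
nmf_scan <- function(V, k_range = 2:7, runs = 30, max_iter = 2000, tol = 1e-6,
                     seed = 1, clip_at_zero = FALSE) {
  per_k <- lapply(k_range, function(k) {
    nmf_factorize(V, k, runs = runs, max_iter = max_iter, tol = tol,
                  seed = seed + 1000L * match(k, k_range),
                  clip_at_zero = clip_at_zero)
  })
  names(per_k) <- as.character(k_range)
  res <- structure(list(
    per_k = per_k,
    cophenetic = vapply(per_k, `[[`, numeric(1L), "cophenetic"),
    k_range = k_range
  ), class = "nmf_scan")
  res$selected_k <- select_k_cophenetic(res)
  res$labels <- per_k[[as.character(res$selected_k)]]$labels
  res
}

#' Select the NMF rank by cophenetic correlation
#'
#' Argmax of the cophenetic correlation over candidate ranks; ties break
#' toward the smaller rank and are reported. The full score vector stays
#' available for human judgement.
#'
#' @param results An `nmf_scan` (or any list with `cophenetic` and `k_range`).
#' @return The selected integer rank.
#' @export
select_k_cophenetic <- function(results) {
  coph <- results$cophenetic
  best <- max(coph, na.rm = TRUE)
  hits <- results$k_range[!is.na(coph) & coph == best]
  if (length(hits) > 1L) {
    message("cophenetic tie among k = ", paste(hits, collapse = ", "),
            "; selecting k = ", min(hits))
  }
  min(hits)
}

#' @export
print.nmf_result <- function(x, ...) {
  cat(sprintf("nmf_result: k = %d, %d runs, cophenetic = %.4f\n",
              x$k, x$runs, x$cophenetic))
  invisible(x)
}

#' @export
print.nmf_scan <- function(x, ...) {
  cat("cophenetic by k:\n")
  print(round(x$cophenetic, 4))
  cat("selected k:", x$selected_k, "\n")
  invisible(x)
}
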