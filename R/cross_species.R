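#' Differential expression vector of a tumour group against a reference
#'
#' Per gene, the mean log2 expression over the tumour samples minus the mean
#' over the reference samples (e.g. prefrontal cortex).
#'
#' @param x An [expression_matrix()].
#' @param tumour_samples,reference_samples Sample identifiers present in `x`.
#' @return A named numeric vector (one entry per gene of `x`) with attributes
#'   `species`, `n_tumour`, `n_reference`.
#' @export
diff_vector <- function(x, tumour_samples, reference_samples) {
  for (side in list(tumour = tumour_samples, reference = reference_samples)) {
    if (length(side) == 0L) {
      stop("empty sample set", call. = FALSE)
    }
  }
  missing_samp <- setdiff(c(tumour_samples, reference_samples), sample_ids(x))
  if (length(missing_samp) > 0L) {
    stop("sample(s) absent from matrix: ",
         paste(missing_samp, collapse = ", "), call. = FALSE)
  }
  if (length(tumour_samples) < 2L || length(reference_samples) < 2L) {
    message("diff_vector: a side has a single sample; means are that sample")
  }
  vals <- unclass(x)
  d <- rowMeans(vals[, tumour_samples, drop = FALSE]) -
    rowMeans(vals[, reference_samples, drop = FALSE])
  attr(d, "species") <- expr_species(x)
  attr(d, "n_tumour") <- length(tumour_samples)
  attr(d, "n_reference") <- length(reference_samples)
  d
}

#' Match two differential vectors through a 1:1 ortholog map
#'
#' Retains exactly the ortholog pairs whose genes are present in both
#' vectors, ordered deterministically by the species-A identifier.
#'
#' @param da,db Named differential vectors (see [diff_vector()]).
#' @param map An [ortholog_map()] already reduced to 1:1 (see [to_1to1()]).
#' @return A list with `a` and `b` (matched numeric vectors of equal length),
#'   `pairs` (the retained map rows) and `n` (pair count).
#' @export
match_orthologs <- function(da, db, map) {
  if (anyDuplicated(map$gene_a) || anyDuplicated(map$gene_b)) {
    stop("map is not 1:1; apply to_1to1() first", call. = FALSE)
  }
  keep <- map$gene_a %in% names(da) & map$gene_b %in% names(db)
  n_dropped <- sum(!keep)
  pairs <- map[keep, , drop = FALSE]
  pairs <- pairs[order(pairs$gene_a), , drop = FALSE]
  rownames(pairs) <- NULL
  if (nrow(pairs) == 0L) {
    stop("no ortholog pair matches both vectors", call. = FALSE)
  }
  if (n_dropped > 0L) {
    message("match_orthologs: dropped ", n_dropped,
            " pair(s) absent from a vector")
  }
  list(a = unname(da[pairs$gene_a]), b = unname(db[pairs$gene_b]),
       pairs = pairs, n = nrow(pairs))
}

#' Agreement-of-differential-expression score
#'
#' Cosine agreement of two matched differential vectors:
#' `sum(da * db) / sqrt(sum(da^2) * sum(db^2))`, in `[-1, 1]`. Positive
#' scores mean the two species move the same orthologs in the same
#' direction relative to their references.
#'
#' @param da_matched,db_matched Numeric vectors of equal length >= 2.
#' @return The agreement score, or `NA` (with a warning) when either vector
#'   is all zero.
#' @export
agdex_score <- function(da_matched, db_matched) {
  if (length(da_matched) != length(db_matched)) {
    stop("matched vectors must have equal length", call. = FALSE)
  }
  if (length(da_matched) < 2L) {
    stop("need at least 2 matched genes", call. = FALSE)
  }
  na2 <- sum(da_matched^2)
  nb2 <- sum(db_matched^2)
  if (na2 == 0 || nb2 == 0) {
    warning("all-zero differential vector; agreement undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(da_matched * db_matched) / sqrt(na2 * nb2)
}

#' Permutation p-value for an agreement score
#'
#' Null scores come from random permutations of `db`'s entries over the
#' ortholog index; the two-sided p-value uses the add-one rule
#' `p = (1 + #\{|score_perm| >= |score_obs|\}) / (n_perm + 1)`, so p is never
#' zero. When the pair count is at most `exhaustive_limit` (default 8), all
#' `n!` permutations are enumerated instead of sampled, with the same rule.
#'
#' @param da,db Matched numeric vectors of equal length.
#' @param n_perm Monte-Carlo permutation count (ignored when exhaustive).
#' @param seed Integer seed for the Monte-Carlo draw.
#' @param exhaustive_limit Maximum length for exhaustive enumeration.
#' @return A list with `p`, `score`, `n_perm` (permutations actually used),
#'   `exhaustive` and `seed`.
#' @export
agdex_permutation_p <- function(da, db, n_perm = 1000, seed = 1,
                                exhaustive_limit = 8) {
  obs <- agdex_score(da, db)
  if (is.na(obs)) {
    return(list(p = NA_real_, score = obs, n_perm = 0L, exhaustive = FALSE,
                seed = seed))
  }
  n <- length(db)
  if (n <= exhaustive_limit) {
    perms <- all_permutations(n)
    scores <- apply(perms, 1L, function(idx) agdex_score(da, db[idx]))
    n_used <- nrow(perms)
    exhaustive <- TRUE
  } else {
    if (n_perm < 1L) {
      stop("n_perm must be >= 1", call. = FALSE)
    }
    set.seed(seed)
    scores <- vapply(seq_len(n_perm), function(i) {
      agdex_score(da, db[sample.int(n)])
    }, numeric(1L))
    n_used <- n_perm
    exhaustive <- FALSE
  }
  p <- (1 + sum(abs(scores) >= abs(obs) - 1e-12)) / (n_used + 1)
  list(p = p, score = obs, n_perm = n_used, exhaustive = exhaustive,
       seed = seed)
}

# All permutations of 1..n as a matrix with one permutation per row.
all_permutations <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- sub
    rest[rest >= first] <- rest[rest >= first] + 1L
    cbind(first, rest, deparse.level = 0L)
  }))
}

#' AGDEX agreement between one group pair
#'
#' Assembles [diff_vector()], [match_orthologs()], [agdex_score()] and
#' [agdex_permutation_p()] for one (species A group, species B group) pair.
#'
#' @param xa,xb Expression matrices of the two species.
#' @param tumour_a,tumour_b,reference_a,reference_b Sample identifier sets.
#' @param map 1:1 [ortholog_map()].
#' @param n_perm,seed Passed to [agdex_permutation_p()].
#' @return A list with `score`, `n_orthologs`, `p_perm`, `n_perm`, `seed`,
#'   `null_type`.
#' @export
agdex_pair <- function(xa, xb, tumour_a, reference_a, tumour_b, reference_b,
                       map, n_perm = 1000, seed = 1) {
  da <- diff_vector(xa, tumour_a, reference_a)
  db <- diff_vector(xb, tumour_b, reference_b)
  m <- match_orthologs(da, db, map)
  pp <- agdex_permutation_p(m$a, m$b, n_perm = n_perm, seed = seed)
  list(score = pp$score, n_orthologs = m$n, p_perm = pp$p,
       n_perm = pp$n_perm, seed = seed, null_type = "gene_permutation")
}

#' AGDEX matrix over all group pairs of two species
#'
#' One agreement result per (species A group, species B group) pair, each
#' computed from that group's differential vector against its species'
#' designated reference samples.
#'
#' @param xa,xb Expression matrices.
#' @param ann_a,ann_b Annotation data.frames (columns `sample_id`, `species`,
#'   `group`, `role`).
#' @param map 1:1 [ortholog_map()].
#' @param reference_a,reference_b Group label(s) in each annotation whose
#'   samples form the reference set.
#' @param groups_a,groups_b Tumour groups to compare; default all
#'   tumour-role groups.
#' @param n_perm,seed Permutation settings; pair (i, j) derives its seed
#'   deterministically from `seed`.
#' @return An object of class `agdex_matrix`: list with `scores` and `p`
#'   (groups_a x groups_b matrices), `n_orthologs`, and `results` (the per-
#'   pair lists).
#' @export
agdex_matrix <- function(xa, ann_a, xb, ann_b, map, reference_a, reference_b,
                         groups_a = NULL, groups_b = NULL,
                         n_perm = 1000, seed = 1) {
  ga <- resolve_groups(ann_a, groups_a)
  gb <- resolve_groups(ann_b, groups_b)
  ref_a <- ann_a$sample_id[ann_a$group %in% reference_a]
  ref_b <- ann_b$sample_id[ann_b$group %in% reference_b]
  if (length(ref_a) == 0L || length(ref_b) == 0L) {
    stop("reference group(s) resolve to no samples", call. = FALSE)
  }
  scores <- matrix(NA_real_, length(ga), length(gb), dimnames = list(ga, gb))
  pmat <- scores
  results <- list()
  for (i in seq_along(ga)) {
    for (j in seq_along(gb)) {
      tum_a <- ann_a$sample_id[ann_a$group == ga[i]]
      tum_b <- ann_b$sample_id[ann_b$group == gb[j]]
      res <- tryCatch(
        agdex_pair(xa, xb, tum_a, ref_a, tum_b, ref_b, map,
                   n_perm = n_perm,
                   seed = seed + 131L * i + j),
        error = function(e) {
          stop("AGDEX pair (", ga[i], ", ", gb[j], "): ",
               conditionMessage(e), call. = FALSE)
        })
      scores[i, j] <- res$score
      pmat[i, j] <- res$p_perm
      results[[paste(ga[i], gb[j], sep = "|")]] <- res
    }
  }
  structure(list(scores = scores, p = pmat,
                 n_orthologs = results[[1L]]$n_orthologs,
                 results = results, seed = seed, n_perm = n_perm),
            class = "agdex_matrix")
}

resolve_groups <- function(ann, groups) {
  if (is.null(groups)) {
    groups <- unique(ann$group[ann$role == "tumour"])
  }
  missing_g <- setdiff(groups, ann$group)
  if (length(missing_g) > 0L) {
    stop("group(s) absent from annotation: ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  }
  groups
}

#' @export
print.agdex_matrix <- function(x, ...) {
  cat("AGDEX scores (", x$n_orthologs, " orthologs, ",
      x$n_perm, " permutations):\n", sep = "")
  print(round(x$scores, 3))
  invisible(x)
}

#' Centroid correlation of tumour groups against reference profiles
#'
#' Pearson correlation between the mean log2 profile (centroid) of each
#' tumour group and the centroid of each reference set, over a shared gene
#' universe — the cell-of-origin style comparison. Filtering to expressed
#' and variable genes is expected to have happened upstream; pass the
#' filtered matrices.
#'
#' @param tumour_matrix [expression_matrix()] holding the tumour samples.
#' @param tumour_groups Group label per tumour sample (vector aligned to the
#'   columns, or named by sample identifier).
#' @param reference_matrix [expression_matrix()] holding reference samples
#'   (same identifier scheme; may be the same object as `tumour_matrix`).
#' @param reference_sets Named list of reference sample identifier vectors,
#'   or a label vector over `reference_matrix`'s columns.
#' @param genes Optional gene identifiers to restrict to; default the
#'   intersection of the two matrices' genes.
#' @param zscore Per-gene z-scoring of centroids before correlating
#'   (default off; raw log2 centroids).
#' @return A matrix of Pearson r, tumour groups in rows, reference sets in
#'   columns.
#' @export
centroid_correlation <- function(tumour_matrix, tumour_groups,
                                 reference_matrix, reference_sets,
                                 genes = NULL, zscore = FALSE) {
  tumour_groups <- align_labels(tumour_matrix, tumour_groups)
  if (!is.list(reference_sets)) {
    lab <- align_labels(reference_matrix, reference_sets)
    reference_sets <- split(sample_ids(reference_matrix), lab)
  }
  if (is.null(genes)) {
    genes <- intersect(gene_ids(tumour_matrix), gene_ids(reference_matrix))
  }
  if (length(genes) < 3L) {
    stop("fewer than 3 shared genes", call. = FALSE)
  }
  tg <- unique(tumour_groups)
  cent_t <- vapply(tg, function(g) {
    rowMeans(unclass(tumour_matrix)[genes, tumour_groups == g, drop = FALSE])
  }, numeric(length(genes)))
  cent_r <- vapply(reference_sets, function(s) {
    rowMeans(unclass(reference_matrix)[genes, s, drop = FALSE])
  }, numeric(length(genes)))
  if (zscore) {
    # per-gene standardization within each platform's centroid block
    cent_t <- t(scale(t(cent_t)))
    cent_r <- t(scale(t(cent_r)))
    keep <- stats::complete.cases(cent_t) & stats::complete.cases(cent_r)
    cent_t <- cent_t[keep, , drop = FALSE]
    cent_r <- cent_r[keep, , drop = FALSE]
    if (nrow(cent_t) < 3L) {
      stop("fewer than 3 shared genes after z-scoring", call. = FALSE)
    }
  }
  r <- stats::cor(cent_t, cent_r)
  rownames(r) <- tg
  colnames(r) <- names(reference_sets)
  r
}
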