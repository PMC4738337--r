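#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end run with their published-analysis
#' defaults: background threshold 1.2, relative-IQR threshold 0.75,
#' consensus clustering with 1000 resamplings, NMF with 30 runs, Welch/BH
#' significance at 0.05 with |log2 FC| >= 1.2, and 1000 AGDEX permutations.
#'
#' @return A named list of defaults.
#' @export
default_config <- function() {
  list(
    background = 1.2,
    riqr = 0.75,
    k_min = 2L,
    k_max = 7L,
    resamplings = 1000L,
    p_item = 0.8,
    nmf_runs = 30L,
    nmf_max_iter = 2000L,
    nmf_clip = TRUE,
    alpha = 0.05,
    min_fc = 1.2,
    adjust = TRUE,
    n_perm = 1000L,
    reference_a = "cortex",
    reference_b = "cortex",
    seed = 1L
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a named list, or a path to a YAML or JSON file, and returns the
#' fully-resolved configuration with defaults applied — or the complete list
#' of violations, without stopping at the first.
#'
#' @param config Named list of overrides, or a file path.
#' @return A list with `config` (resolved, or `NULL` when invalid) and
#'   `errors` (character vector, empty when valid).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  defaults <- default_config()
  errors <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    errors <- c(errors, paste0("unknown key(s): ",
                               paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config[intersect(names(config),
                                                      names(defaults))])
  check_num <- function(key, lo, hi, lo_open = FALSE) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
        v < lo || v > hi || (lo_open && v <= lo)) {
      errors <<- c(errors, sprintf("%s must lie in %s%g, %g]", key,
                                   if (lo_open) "(" else "[", lo, hi))
    }
  }
  check_num("background", -Inf, Inf)
  check_num("riqr", 0, Inf)
  check_num("alpha", 0, 1, lo_open = TRUE)
  check_num("min_fc", 0, Inf)
  check_num("p_item", 0, 1, lo_open = TRUE)
  check_num("resamplings", 1, Inf)
  check_num("nmf_runs", 1, Inf)
  check_num("n_perm", 1, Inf)
  if (!is.numeric(cfg$k_min) || !is.numeric(cfg$k_max) ||
      cfg$k_min < 2 || cfg$k_max < cfg$k_min) {
    errors <- c(errors, "k range must satisfy 2 <= k_min <= k_max")
  }
  if (length(errors) > 0L) {
    return(list(config = NULL, errors = errors))
  }
  cfg$k_min <- as.integer(cfg$k_min)
  cfg$k_max <- as.integer(cfg$k_max)
  cfg$seed <- as.integer(cfg$seed)
  list(config = cfg, errors = character(0))
}

#' Run the full cross-species analysis
#'
#' Per species: filter to expressed and variable genes (tumour samples
#' only), then the three subgrouping routes — average-linkage hierarchical
#' clustering, consensus clustering with PAC selection, and KL-NMF with
#' cophenetic selection — plus a three-way concordance table of adjusted
#' Rand indices; then group signatures on the consensus partition, the
#' AGDEX matrix between the two species' annotated groups, and centroid
#' correlations of each species' tumour groups against its progenitor
#' reference sets. Every stochastic stage derives its seed from
#' `config$seed`; a stage failure aborts with the stage name.
#'
#' @param xa,xb [expression_matrix()] for species A and B.
#' @param annotation Joint annotation data.frame (both species).
#' @param map [ortholog_map()]; reduced to 1:1 with the default drop policy
#'   if it is not already.
#' @param config Named list of overrides, or a path, passed through
#'   [validate_config()].
#' @param out_dir Optional directory: writes `filter_report_<sp>.tsv`,
#'   `labels_<method>_<sp>.tsv`, `model_selection_<sp>.tsv`,
#'   `signatures_<sp>.tsv`, `agdex.tsv`, `correlations_<sp>.tsv` and
#'   `manifest.json` (parameters, seed, per-file MD5 hashes, warnings).
#' @return A list with per-species results (`species_a`, `species_b`:
#'   filter, consensus, nmf, hier labels, concordance, signatures,
#'   correlations), `agdex`, the resolved `config`, and `manifest`.
#' @export
run_pipeline <- function(xa, xb, annotation, map, config = list(),
                         out_dir = NULL) {
  val <- validate_config(config)
  if (length(val$errors) > 0L) {
    stop("invalid configuration:\n  ", paste(val$errors, collapse = "\n  "),
         call. = FALSE)
  }
  cfg <- val$config
  if (is.null(map)) {
    stop("stage 'validate': AGDEX requested but no ortholog map supplied",
         call. = FALSE)
  }
  warnings_log <- character(0)
  note <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = note),
             error = function(e) {
               stop("stage '", name, "' failed: ", conditionMessage(e),
                    call. = FALSE)
             })
  }
  if (anyDuplicated(map$gene_a) || anyDuplicated(map$gene_b)) {
    map <- to_1to1(map)
  }

  run_species <- function(x, offset) {
    ann <- stage("annotation", check_annotation(x, annotation))
    tum <- ann$sample_id[ann$role == "tumour"]
    xt <- expression_matrix(unclass(x)[, tum, drop = FALSE], expr_species(x))
    filt <- stage("filter",
                  apply_filters(xt, background = cfg$background,
                                riqr_threshold = cfg$riqr))
    k_range <- cfg$k_min:min(cfg$k_max, ncol(filt$matrix) - 1L)
    cons <- stage("consensus",
                  consensus_cluster(filt$matrix, k_range = k_range,
                                    R = cfg$resamplings, p_item = cfg$p_item,
                                    seed = cfg$seed + offset))
    nmf <- stage("nmf",
                 nmf_scan(filt$matrix, k_range = k_range, runs = cfg$nmf_runs,
                          max_iter = cfg$nmf_max_iter,
                          seed = cfg$seed + offset + 500L,
                          clip_at_zero = cfg$nmf_clip))
    hier <- stage("hierarchical",
                  average_linkage_cut(pearson_distance(filt$matrix),
                                      cons$selected_k))
    parts <- list(hierarchical = hier, consensus = cons$labels,
                  nmf = nmf$per_k[[as.character(cons$selected_k)]]$labels)
    concordance <- stage("concordance", {
      pairs <- utils::combn(names(parts), 2L)
      data.frame(
        method_1 = pairs[1L, ], method_2 = pairs[2L, ],
        ari = apply(pairs, 2L, function(pr) {
          mclust::adjustedRandIndex(parts[[pr[1L]]], parts[[pr[2L]]])
        }), stringsAsFactors = FALSE)
    })
    sigs <- stage("signatures", {
      lab <- stats::setNames(paste0("C", cons$labels), names(cons$labels))
      sizes <- table(lab)
      if (any(sizes < 2L)) {
        warning("dropping singleton cluster(s) from signatures: ",
                paste(names(sizes)[sizes < 2L], collapse = ", "),
                call. = FALSE)
        lab <- lab[lab %in% names(sizes)[sizes >= 2L]]
      }
      if (length(unique(lab)) < 2L) {
        warning("fewer than 2 multi-sample clusters; signatures skipped",
                call. = FALSE)
        list()
      } else {
        # signatures are sought genome-wide: the invariance filter serves
        # clustering, while significance is the test's own job
        xs <- expression_matrix(unclass(xt)[, names(lab), drop = FALSE],
                                expr_species(xt))
        group_signatures(xs, lab, alpha = cfg$alpha,
                         min_fc = cfg$min_fc, adjust = cfg$adjust)
      }
    })
    prog <- unique(ann$group[ann$role == "reference" &
                               startsWith(ann$group, "prog_")])
    corr <- NULL
    if (length(prog) > 0L) {
      corr <- stage("centroid_correlation", {
        ref_sets <- lapply(prog, function(g) ann$sample_id[ann$group == g])
        names(ref_sets) <- prog
        truth_lab <- stats::setNames(ann$group, ann$sample_id)[tum]
        xr <- expression_matrix(
          unclass(x)[gene_ids(filt$matrix), unlist(ref_sets), drop = FALSE],
          expr_species(x))
        centroid_correlation(filt$matrix, truth_lab, xr, ref_sets)
      })
    }
    list(annotation = ann, filter = filt, consensus = cons, nmf = nmf,
         hier = hier, partitions = parts, concordance = concordance,
         signatures = sigs, correlations = corr)
  }

  res_a <- run_species(xa, 0L)
  res_b <- run_species(xb, 10000L)

  ann_a <- annotation[annotation$species == expr_species(xa), , drop = FALSE]
  ann_b <- annotation[annotation$species == expr_species(xb), , drop = FALSE]
  # tumour-role groups are compared; cortex and progenitor samples carry the
  # reference role and enter only as the designated reference sets
  agdex <- stage("agdex",
                 agdex_matrix(xa, ann_a, xb, ann_b, map,
                              reference_a = cfg$reference_a,
                              reference_b = cfg$reference_b,
                              groups_a = NULL, groups_b = NULL,
                              n_perm = cfg$n_perm,
                              seed = cfg$seed + 20000L))
  out <- list(species_a = res_a, species_b = res_b, agdex = agdex,
              config = cfg, warnings = warnings_log)
  if (!is.null(out_dir)) {
    out$manifest <- write_pipeline_outputs(out, xa, xb, out_dir)
  }
  out
}

# Serialize the pipeline results as plain TSV/JSON under out_dir and return
# the manifest (parameters, seed, per-file MD5 hashes, warnings). Timestamps
# are deliberately absent so reruns are byte-identical.
write_pipeline_outputs <- function(res, xa, xb, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
  }
  for (side in c("a", "b")) {
    r <- res[[paste0("species_", side)]]
    put(r$filter$report, sprintf("filter_report_%s.tsv", side))
    lab_df <- data.frame(sample_id = names(r$partitions$consensus),
                         hierarchical = unname(r$partitions$hierarchical),
                         consensus = unname(r$partitions$consensus),
                         nmf = unname(r$partitions$nmf))
    put(lab_df, sprintf("labels_%s.tsv", side))
    model <- data.frame(k = r$consensus$k_range,
                        pac = unname(r$consensus$pac),
                        cophenetic = unname(r$nmf$cophenetic))
    model$selected_by_pac <- model$k == r$consensus$selected_k
    model$selected_by_cophenetic <- model$k == r$nmf$selected_k
    put(model, sprintf("model_selection_%s.tsv", side))
    sig_df <- data.frame(
      group = rep(names(r$signatures), lengths(r$signatures)),
      gene_id = unlist(r$signatures, use.names = FALSE))
    if (nrow(sig_df) == 0L) {
      sig_df <- data.frame(group = character(0), gene_id = character(0))
    }
    put(sig_df, sprintf("signatures_%s.tsv", side))
    put(r$concordance, sprintf("concordance_%s.tsv", side))
    if (!is.null(r$correlations)) {
      put(data.frame(group = rownames(r$correlations), r$correlations,
                     check.names = FALSE),
          sprintf("correlations_%s.tsv", side))
    }
  }
  put(data.frame(group_a = rownames(res$agdex$scores)[row(res$agdex$scores)],
                 group_b = colnames(res$agdex$scores)[col(res$agdex$scores)],
                 score = as.vector(res$agdex$scores),
                 p_perm = as.vector(res$agdex$p)),
      "agdex.tsv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("crossdex")),
    parameters = res$config,
    seed = res$config$seed,
    species = c(expr_species(xa), expr_species(xb)),
    selected_k = list(a = res$species_a$consensus$selected_k,
                      b = res$species_b$consensus$selected_k),
    selected_k_nmf = list(a = res$species_a$nmf$selected_k,
                          b = res$species_b$nmf$selected_k),
    warnings = res$warnings,
    hashes = as.list(tools::md5sum(sort(files)))
  )
  names(manifest$hashes) <- basename(names(manifest$hashes))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}
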