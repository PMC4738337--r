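#' Parameters for the two-species simulation
#'
#' Describes a pair of ortholog-linked expression datasets with planted
#' subgroups, shared cross-species programs, reference tissues, and the gene
#' classes both pre-clustering filters act on. Defaults mirror the study
#' design the pipeline targets: a mouse-like species with five tumour groups
#' (two rhabdoid entities plus medulloblastoma, neuroblastoma and lymphoma
#' controls) and a human-like species with six, with four linked pairs.
#'
#' Marker (program) genes follow an on/off model: their off-state baseline
#' sits near the detection floor (`marker_baseline_mean`, default 0.6 log2
#' units) and the group effect `delta` switches them on. When a species has
#' four or more groups, each marker gene is also expressed in one random
#' second group (lineage co-expression), so markers vary in 2/K of the
#' tumour cohort — enough for a quartile-based invariance filter to see
#' them; for linked pairs the second group is mirrored across species
#' through the linkage, keeping shared programs aligned over orthologs.
#' Non-marker genes (invariant and
#' bystander ortholog genes) follow the broad baseline law
#' (`baseline_mean`, `baseline_sd`). Linked group pairs share their program
#' through the ortholog core: a fraction `rho` of the program genes keeps a
#' concordant sign across species, the rest draw an independent sign.
#'
#' @param groups_a,groups_b Ordered tumour group labels per species.
#' @param samples_per_group Tumour samples per group.
#' @param linked data.frame with columns `a`, `b` (group labels) and
#'   optionally `rho`; linked programs live in the ortholog core.
#' @param rho Default agreement fraction in `[0, 1]` for linked pairs
#'   without their own `rho`.
#' @param program_size Genes per group program.
#' @param program_private_fraction Fraction of each program expressed only
#'   in its own group (group-specific markers, the substrate of pairwise
#'   signatures); the rest is shared with the gene's second group. Private
#'   status is mirrored across species for linked programs.
#' @param delta Group effect size, log2 units.
#' @param sigma Sample noise standard deviation, log2 units.
#' @param baseline_mean,baseline_sd Baseline law for non-marker genes.
#' @param marker_baseline_mean,marker_baseline_sd Off-state law for marker
#'   genes.
#' @param sign_up_fraction Fraction of each program that are "up" markers
#'   (on in their groups, off in the cortex reference); the count is exact
#'   and the order random. Down markers invert the pattern.
#' @param activity_jitter Half-width of the per-tumour program activity
#'   factor `u ~ U(1 - j, 1 + j)` scaling each tumour's deviation from the
#'   reference profile (tumour purity / differentiation state). Symmetric
#'   around 1, so expected group effects remain `delta`; 0 disables it.
#' @param noise_cv Log-scale spread of the per-sample noise level: sample
#'   `s` draws its noise standard deviation as
#'   `sigma * exp(N(0, noise_cv))` (RNA quality and hybridization
#'   variability differ between arrays); 0 gives homoscedastic samples.
#' @param n_factors,factor_sd Latent co-expression factors: each sample
#'   draws `n_factors` standard-normal scores and each gene a loading
#'   `N(0, factor_sd)`; their product adds gene-wise correlated deviations
#'   (proliferation, stress, stromal content). Background and invariant
#'   genes are exempt so their filter guarantees stay exact. 0 disables.
#' @param n_core Ortholog core size (must hold all linked programs).
#' @param n_specific Species-specific bystander genes beyond the unlinked
#'   programs.
#' @param n_background Genes kept uniformly below the 1.2 background
#'   threshold.
#' @param n_invariant Genes with near-zero spread (they pass background,
#'   fail the relative-IQR filter).
#' @param invariant_sd Noise level of invariant genes.
#' @param n_reference Cortex-like reference samples per species (baseline
#'   profile only).
#' @param progenitor_samples Samples per progenitor reference set; 0
#'   disables progenitor sets.
#' @param progenitor_fraction How far a progenitor profile moves from the
#'   cortex profile toward its group's profile.
#' @param species_a,species_b Species labels.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(groups_a = c("Mb", "Nb", "lymph", "mEIC", "mIC"),
                       groups_b = c("MB", "NB", "hIC1", "hIC3", "hEC", "hIC2"),
                       samples_per_group = 5,
                       linked = data.frame(
                         a = c("Mb", "Nb", "mIC", "mEIC"),
                         b = c("MB", "NB", "hIC2", "hEC"),
                         stringsAsFactors = FALSE),
                       rho = 0.8,
                       program_size = 40,
                       program_private_fraction = 0.5,
                       delta = 2,
                       sigma = 0.5,
                       baseline_mean = 6, baseline_sd = 1.5,
                       marker_baseline_mean = 0.6, marker_baseline_sd = 0.15,
                       sign_up_fraction = 0.5,
                       activity_jitter = 0,
                       noise_cv = 0,
                       n_factors = 0, factor_sd = 0.3,
                       n_core = 300, n_specific = 100,
                       n_background = 150, n_invariant = 150,
                       invariant_sd = 0.01,
                       n_reference = 5,
                       progenitor_samples = 3, progenitor_fraction = 0.7,
                       species_a = "mouse", species_b = "human") {
  p <- list(groups_a = groups_a, groups_b = groups_b,
            samples_per_group = samples_per_group, linked = linked, rho = rho,
            program_size = program_size,
            program_private_fraction = program_private_fraction,
            delta = delta, sigma = sigma,
            baseline_mean = baseline_mean, baseline_sd = baseline_sd,
            marker_baseline_mean = marker_baseline_mean,
            marker_baseline_sd = marker_baseline_sd,
            sign_up_fraction = sign_up_fraction,
            activity_jitter = activity_jitter,
            noise_cv = noise_cv,
            n_factors = n_factors, factor_sd = factor_sd,
            n_core = n_core, n_specific = n_specific,
            n_background = n_background, n_invariant = n_invariant,
            invariant_sd = invariant_sd, n_reference = n_reference,
            progenitor_samples = progenitor_samples,
            progenitor_fraction = progenitor_fraction,
            species_a = species_a, species_b = species_b)
  counts <- c(samples_per_group = samples_per_group,
              program_size = program_size,
              n_core = n_core, n_reference = n_reference)
  if (any(counts <= 0)) {
    stop("counts must be positive: ",
         paste(names(counts)[counts <= 0], collapse = ", "), call. = FALSE)
  }
  if (!is.null(linked$rho)) {
    p$linked$rho <- linked$rho
  } else if (nrow(linked) > 0L) {
    p$linked$rho <- rho
  }
  if (nrow(p$linked) > 0L && any(p$linked$rho < 0 | p$linked$rho > 1)) {
    stop("rho must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(groups_a) || anyDuplicated(groups_b)) {
    stop("group labels must be unique within a species", call. = FALSE)
  }
  bad <- c(setdiff(p$linked$a, groups_a), setdiff(p$linked$b, groups_b))
  if (length(bad) > 0L) {
    stop("linked group(s) not in the group lists: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(p$linked$a) || anyDuplicated(p$linked$b)) {
    stop("a group may appear in at most one linked pair", call. = FALSE)
  }
  if (nrow(p$linked) * program_size > n_core) {
    stop("linked programs (", nrow(p$linked) * program_size,
         " genes) exceed the ortholog core (", n_core, ")", call. = FALSE)
  }
  structure(p, class = "sim_params")
}

#' Generate a linked two-species expression dataset
#'
#' Draws both species' matrices, the ortholog map, a joint sample
#' annotation, and the planted ground truth, fully reproducible from
#' `seed`. See [sim_params()] for the generative model.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @return A list with `a`, `b` ([expression_matrix()]), `map`
#'   ([ortholog_map()], 1:1 by construction), `annotation` (both species),
#'   and `truth` (labels, per-group programs with signs, linked table,
#'   reference and progenitor sample ids).
#' @export
simulate_two_species <- function(params = sim_params(), seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  linked <- params$linked
  n_linked <- nrow(linked)
  m <- params$program_size

  # ortholog core slots for linked programs: pair p owns slots
  # ((p-1)m+1):(pm) in both species
  core_slots <- lapply(seq_len(n_linked), function(p) ((p - 1L) * m + 1L):(p * m))

  # Secondary "on" group per marker gene: when a species has >= 4 tumour
  # groups, a group's fraction of the cohort (1/K) falls below the quarter
  # of samples a quartile-based invariance filter can see, so each marker is
  # also expressed in one random second group (lineage co-expression). With
  # K <= 3 no second group is needed (or drawn).
  n_up <- round(m * params$sign_up_fraction)
  draw_sign <- function() {
    # balanced programs: an exact count of up markers, in random order
    sample(rep(c(1L, -1L), c(n_up, m - n_up)))
  }
  draw_second <- function(g, pool) {
    pool <- setdiff(pool, g)
    if (length(pool) == 0L) {
      return(rep(g, m))
    }
    pool[sample.int(length(pool), m, replace = TRUE)]
  }

  # cross-species program signs and seconds: A draws freely; B copies the
  # sign with prob rho and, for concordant genes, mirrors the second group
  # through the linkage so shared programs stay aligned over orthologs
  link_of <- stats::setNames(linked$b, linked$a)
  signs_a <- seconds_a <- signs_b <- seconds_b <- vector("list", n_linked)
  share_a <- length(params$groups_a) >= 4L
  share_b <- length(params$groups_b) >= 4L
  for (p in seq_len(n_linked)) {
    signs_a[[p]] <- draw_sign()
    seconds_a[[p]] <- if (share_a) {
      draw_second(linked$a[p], linked$a)
    } else {
      rep(linked$a[p], m)
    }
    concordant <- stats::runif(m) < linked$rho[p]
    ind_sign <- draw_sign()
    ind_second <- if (share_b) {
      draw_second(linked$b[p], linked$b)
    } else {
      rep(linked$b[p], m)
    }
    signs_b[[p]] <- ifelse(concordant, signs_a[[p]], ind_sign)
    seconds_b[[p]] <- if (share_b) {
      mirrored <- unname(link_of[seconds_a[[p]]])
      bad <- is.na(mirrored) | mirrored == linked$b[p]
      mirrored[bad] <- ind_second[bad]
      ifelse(concordant, mirrored, ind_second)
    } else {
      rep(linked$b[p], m)
    }
    n_priv <- round(m * params$program_private_fraction)
    if (n_priv > 0L) {
      seconds_a[[p]][seq_len(n_priv)] <- linked$a[p]
      seconds_b[[p]][seq_len(n_priv)] <- linked$b[p]
    }
  }

  build <- function(side) {
    groups <- if (side == "a") params$groups_a else params$groups_b
    species <- if (side == "a") params$species_a else params$species_b
    prefix <- if (side == "a") "a" else "b"
    K <- length(groups)
    unlinked <- setdiff(groups, if (side == "a") linked$a else linked$b)
    n_genes <- params$n_core + length(unlinked) * m + params$n_specific +
      params$n_background + params$n_invariant
    gid <- sprintf("%s_g%05d", prefix, seq_len(n_genes))
    idx_core <- seq_len(params$n_core)
    idx_unlinked <- params$n_core + seq_len(length(unlinked) * m)
    idx_background <- n_genes - params$n_background - params$n_invariant +
      seq_len(params$n_background)
    idx_invariant <- n_genes - params$n_invariant + seq_len(params$n_invariant)

    # per-group program slots (gene indices), signs and per-gene seconds
    share <- K >= 4L
    programs <- stats::setNames(vector("list", K), groups)
    for (p in seq_len(n_linked)) {
      g <- if (side == "a") linked$a[p] else linked$b[p]
      programs[[g]] <- list(
        idx = idx_core[core_slots[[p]]],
        sign = if (side == "a") signs_a[[p]] else signs_b[[p]],
        second = if (side == "a") seconds_a[[p]] else seconds_b[[p]])
    }
    for (u in seq_along(unlinked)) {
      idx <- params$n_core + ((u - 1L) * m + 1L):(u * m)
      programs[[unlinked[u]]] <- list(
        idx = idx,
        sign = draw_sign(),
        second = {
          sec <- if (share) draw_second(unlinked[u], groups) else
            rep(unlinked[u], m)
          n_priv <- round(m * params$program_private_fraction)
          if (n_priv > 0L) sec[seq_len(n_priv)] <- unlinked[u]
          sec
        })
    }

    marker_idx <- sort(unlist(lapply(programs, `[[`, "idx")))
    baseline <- stats::rnorm(n_genes, params$baseline_mean, params$baseline_sd)
    baseline[marker_idx] <- stats::rnorm(length(marker_idx),
                                         params$marker_baseline_mean,
                                         params$marker_baseline_sd)

    # mean profile per column state: tumour groups + cortex
    states <- c(groups, "cortex")
    mu <- matrix(baseline, n_genes, length(states),
                 dimnames = list(gid, states))
    for (g in groups) {
      pr <- programs[[g]]
      for (i in seq_len(m)) {
        on_groups <- unique(c(g, pr$second[i]))
        if (pr$sign[i] > 0L) {
          # up marker: off everywhere, on (+delta) in its on-set groups
          mu[pr$idx[i], on_groups] <- mu[pr$idx[i], on_groups] + params$delta
        } else {
          # down marker: on everywhere (incl. cortex) except its on-set
          off_states <- setdiff(states, on_groups)
          mu[pr$idx[i], off_states] <- mu[pr$idx[i], off_states] +
            params$delta
        }
      }
    }

    # samples: tumours, cortex, optional progenitor sets
    col_state <- c(rep(groups, each = params$samples_per_group),
                   rep("cortex", params$n_reference))
    col_group <- col_state
    col_role <- c(rep("tumour", K * params$samples_per_group),
                  rep("reference", params$n_reference))
    if (params$progenitor_samples > 0L) {
      col_state <- c(col_state, rep(groups, each = params$progenitor_samples))
      col_group <- c(col_group,
                     rep(paste0("prog_", groups),
                         each = params$progenitor_samples))
      col_role <- c(col_role,
                    rep("reference", K * params$progenitor_samples))
    }
    n_samples <- length(col_state)
    sid <- paste0(prefix, "_", col_group, "_",
                  stats::ave(seq_len(n_samples), col_group, FUN = seq_along))

    vals <- matrix(0, n_genes, n_samples, dimnames = list(gid, sid))
    prog_range <- K * params$samples_per_group + params$n_reference
    n_tum <- K * params$samples_per_group
    j_half <- params$activity_jitter
    # heteroscedastic samples (RNA quality / hybridization variability)
    noise_sd <- params$sigma *
      exp(stats::rnorm(n_samples, 0, params$noise_cv))
    # latent co-expression factors: coherent per-sample deviations shared
    # across genes (proliferation, stress, stromal content, ...)
    n_fac <- params$n_factors
    if (n_fac > 0L) {
      loadings <- matrix(stats::rnorm(n_genes * n_fac, 0, params$factor_sd),
                         n_genes, n_fac)
      scores <- matrix(stats::rnorm(n_samples * n_fac), n_fac, n_samples)
      factor_term <- loadings %*% scores
    } else {
      factor_term <- 0
    }
    for (j in seq_len(n_samples)) {
      state_mu <- mu[, col_state[j]]
      if (j > prog_range) {
        # progenitor: cortex profile moved toward the group profile
        state_mu <- mu[, "cortex"] +
          params$progenitor_fraction * (state_mu - mu[, "cortex"])
      } else if (j <= n_tum && j_half > 0) {
        # tumour purity / program activity: each tumour expresses its
        # deviation from the reference profile at a sample-specific level,
        # symmetric around 1 so expected group effects stay at delta
        u <- stats::runif(1L, 1 - j_half, 1 + j_half)
        state_mu <- mu[, "cortex"] + u * (state_mu - mu[, "cortex"])
      }
      vals[, j] <- state_mu + stats::rnorm(n_genes, 0, noise_sd[j])
    }
    vals <- vals + factor_term
    # invariant genes: near-zero spread around their baseline
    vals[idx_invariant, ] <- baseline[idx_invariant] +
      stats::rnorm(params$n_invariant * n_samples, 0, params$invariant_sd)
    # background genes: uniformly below the 1.2 threshold
    vals[idx_background, ] <- stats::runif(params$n_background * n_samples,
                                           0, 1.15)

    list(matrix = expression_matrix(vals, species),
         annotation = data.frame(sample_id = sid, species = species,
                                 group = col_group, role = col_role,
                                 stringsAsFactors = FALSE),
         programs = lapply(programs, function(pr) {
           data.frame(gene_id = gid[pr$idx], sign = pr$sign,
                      second_group = pr$second, stringsAsFactors = FALSE)
         }),
         gid = gid)
  }

  a <- build("a")
  b <- build("b")
  map <- ortholog_map(a$gid[seq_len(params$n_core)],
                      b$gid[seq_len(params$n_core)],
                      provenance = "simulated 1:1 core")
  annotation <- rbind(a$annotation, b$annotation)
  tumour_a <- a$annotation$role == "tumour"
  tumour_b <- b$annotation$role == "tumour"
  truth <- list(
    labels = list(
      a = stats::setNames(a$annotation$group[tumour_a],
                          a$annotation$sample_id[tumour_a]),
      b = stats::setNames(b$annotation$group[tumour_b],
                          b$annotation$sample_id[tumour_b])),
    programs = list(a = a$programs, b = b$programs),
    linked = params$linked,
    reference = list(
      a = a$annotation$sample_id[a$annotation$group == "cortex"],
      b = b$annotation$sample_id[b$annotation$group == "cortex"]),
    progenitors = list(
      a = split(a$annotation$sample_id[startsWith(a$annotation$group, "prog_")],
                a$annotation$group[startsWith(a$annotation$group, "prog_")]),
      b = split(b$annotation$sample_id[startsWith(b$annotation$group, "prog_")],
                b$annotation$group[startsWith(b$annotation$group, "prog_")])),
    params = params, seed = seed
  )
  list(a = a$matrix, b = b$matrix, map = map, annotation = annotation,
       truth = truth)
}

#' Generate a pure-noise (all-null) dataset
#'
#' Baseline plus homoscedastic noise, no group structure: the fixture for
#' type-I-error and false-discovery-rate calibration.
#'
#' @param genes Gene count.
#' @param samples_per_group Samples per group.
#' @param groups Number of (null) groups.
#' @param sigma Noise standard deviation, log2 units.
#' @param seed Integer seed.
#' @param baseline_mean,baseline_sd Baseline law.
#' @return A list with `matrix`, `annotation` and `truth = "all-null"`.
#' @export
generate_null <- function(genes = 1000, samples_per_group = 5, groups = 2,
                          sigma = 0.5, seed = 1,
                          baseline_mean = 6, baseline_sd = 1.5) {
  stopifnot(genes > 0, samples_per_group > 0, groups > 0, sigma >= 0)
  set.seed(seed)
  n <- samples_per_group * groups
  gid <- sprintf("null_g%05d", seq_len(genes))
  grp <- rep(paste0("group", seq_len(groups)), each = samples_per_group)
  sid <- paste0("s_", grp, "_",
                rep(seq_len(samples_per_group), times = groups))
  baseline <- stats::rnorm(genes, baseline_mean, baseline_sd)
  vals <- baseline + matrix(stats::rnorm(genes * n, 0, sigma), genes, n)
  dimnames(vals) <- list(gid, sid)
  list(matrix = expression_matrix(vals, "null"),
       annotation = data.frame(sample_id = sid, species = "null",
                               group = grp, role = "tumour",
                               stringsAsFactors = FALSE),
       truth = "all-null")
}
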