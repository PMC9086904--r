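# Synthetic three-group cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes, with
# no anatomical realism: per-region voxel gray-matter values are drawn from
# two-component Gaussian mixtures whose means load on shared latent
# factors, so regions close in latent space have similar distributions and
# the thresholded KLS networks acquire community structure and small-world
# organization. Three groups mirror the study design: essential tremor
# with poor sleep (SleET, n = 45), essential tremor with normal sleep
# (NorET, n = 59) and healthy controls (HC, n = 66). A planted global
# effect makes one group's networks more random (higher integration), and
# a planted correlation ties one region's expected degree to tremor
# severity.

.GROUPS <- c("SleET", "NorET", "HC")

# group-level clinical distributions: mean/sd per instrument, sex as the
# observed male fraction. Values follow the study's demographic table.
.CLIN_DEFAULTS <- list(
  SleET = list(age = c(54.29, 14.783), sex_m = 13 / 45,
               edu = c(10.27, 4.059), duration = c(11.80, 10.612),
               trs_a = c(6.53, 4.916), trs_b = c(14.09, 7.885),
               trs_c = c(5.02, 5.483), psqi = c(17.55, 5.509),
               mmse = c(26.89, 3.164), hama = c(9.20, 6.147),
               hamd = c(9.89, 6.147)),
  NorET = list(age = c(53.69, 14.695), sex_m = 20 / 59,
               edu = c(11.36, 4.246), duration = c(11.86, 9.952),
               trs_a = c(5.31, 3.715), trs_b = c(8.61, 6.571),
               trs_c = c(3.10, 3.759), psqi = c(3.91, 2.933),
               mmse = c(27.17, 4.568), hama = c(4.66, 4.622),
               hamd = c(4.25, 4.241)),
  HC = list(age = c(52.55, 11.169), sex_m = 21 / 66,
            edu = c(10.583, 3.914), duration = NULL,
            trs_a = NULL, trs_b = NULL, trs_c = NULL,
            psqi = c(2.64, 2.377), mmse = c(27.94, 1.788),
            hama = c(3.79, 3.571), hamd = c(2.91, 2.653))
)

#' Specification of a synthetic cohort
#'
#' @param group_sizes named integer vector of subjects per group; names
#'   must be `SleET`, `NorET`, `HC`; defaults 45/59/66.
#' @param n_rois number of atlas regions (default 116; names from
#'   [aal116_labels()] when 116, `ROI001`.. otherwise).
#' @param voxels_per_roi length-2 integer range of voxels per region
#'   (default 200-2000); each region's count is cohort-fixed, like real
#'   atlas region sizes.
#' @param latent_dim number of shared latent factors driving inter-region
#'   similarity (default 4).
#' @param planted_edges optional data.frame with columns `roi_a`, `roi_b`
#'   (1-based region indices), `group`, `effect`; positive effects pull
#'   the pair's mixture parameters together (raising KLS) in that group
#'   only, negative effects push them apart. Effects must be finite and
#'   <= 1.
#' @param planted_global_effect scalar >= 0: randomization strength added
#'   to `planted_global_group`'s networks. It shrinks the shared geometry
#'   and inflates region-level noise, so thresholded networks become more
#'   integrated (higher global efficiency), mirroring the poor-sleep
#'   group's reported shift toward randomization. Default 0.6.
#' @param planted_global_group group receiving the global effect.
#' @param trs_degree_rho planted partial correlation between the expected
#'   degree of `trs_target_roi` and the tremor rating scale total within
#'   `trs_group` (default -0.35); set to 0 to disable.
#' @param trs_target_roi region whose degree drives tremor severity
#'   (default `Thalamus_L`; under a non-default parcellation the default
#'   falls back to a mid-list region).
#' @param trs_group group in which the correlation is planted.
#' @param seed integer seed; a fixed seed makes the whole cohort
#'   byte-identical across runs.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(SleET = 45, NorET = 59, HC = 66),
                        n_rois = 116,
                        voxels_per_roi = c(200, 2000),
                        latent_dim = 4,
                        planted_edges = NULL,
                        planted_global_effect = 0.6,
                        planted_global_group = "SleET",
                        trs_degree_rho = -0.35,
                        trs_target_roi = "Thalamus_L",
                        trs_group = "SleET",
                        seed = 1) {
  if (is.null(names(group_sizes))) names(group_sizes) <- .GROUPS
  if (!setequal(names(group_sizes), .GROUPS)) {
    stop("group_sizes must be named SleET, NorET, HC")
  }
  group_sizes <- group_sizes[.GROUPS]
  if (any(group_sizes < 2)) stop("each group needs at least 2 subjects")
  .check_scalar(n_rois, "n_rois", 3)
  if (length(voxels_per_roi) != 2 || any(voxels_per_roi < 10) ||
      voxels_per_roi[1] > voxels_per_roi[2]) {
    stop("voxels_per_roi must be an increasing range with minimum >= 10")
  }
  .check_scalar(latent_dim, "latent_dim", 1)
  .check_scalar(planted_global_effect, "planted_global_effect", 0)
  if (!planted_global_group %in% .GROUPS) stop("unknown group for global effect")
  .check_scalar(trs_degree_rho, "trs_degree_rho", -0.999, 0.999)
  if (!trs_group %in% .GROUPS) stop("unknown trs_group")
  if (!is.null(planted_edges)) {
    need <- c("roi_a", "roi_b", "group", "effect")
    if (!is.data.frame(planted_edges) || !all(need %in% names(planted_edges))) {
      stop("planted_edges needs columns roi_a, roi_b, group, effect")
    }
    if (any(planted_edges$roi_a < 1 | planted_edges$roi_a > n_rois |
            planted_edges$roi_b < 1 | planted_edges$roi_b > n_rois)) {
      stop("planted_edges references an unknown ROI index (valid: 1..",
           n_rois, ")")
    }
    if (any(planted_edges$roi_a == planted_edges$roi_b)) {
      stop("planted_edges must connect two distinct regions")
    }
    if (!all(planted_edges$group %in% .GROUPS)) {
      stop("planted_edges references an unknown group")
    }
    if (any(!is.finite(planted_edges$effect)) ||
        any(planted_edges$effect > 1)) {
      stop("planted edge effects must be finite and <= 1")
    }
  }
  .check_scalar(seed, "seed")
  roi_names <- if (n_rois == 116) {
    aal116_labels()$name
  } else {
    sprintf("ROI%03d", seq_len(n_rois))
  }
  if (!trs_target_roi %in% roi_names) {
    if (identical(trs_target_roi, "Thalamus_L")) {
      # default target under a non-default parcellation: use a mid-list region
      trs_target_roi <- roi_names[ceiling(n_rois / 2)]
    } else {
      stop("trs_target_roi '", trs_target_roi,
           "' is not among the cohort's regions")
    }
  }
  structure(
    list(group_sizes = group_sizes, n_rois = as.integer(n_rois),
         voxels_per_roi = as.integer(voxels_per_roi),
         latent_dim = as.integer(latent_dim),
         planted_edges = planted_edges,
         planted_global_effect = planted_global_effect,
         planted_global_group = planted_global_group,
         trs_degree_rho = trs_degree_rho,
         trs_target_roi = trs_target_roi, trs_group = trs_group,
         seed = as.integer(seed), roi_names = roi_names),
    class = "cohort_spec"
  )
}

# fixed mixture shape parameters (arbitrary GMV units)
.GEN <- list(center = 5, b_sd = 0.5, beta = 0.5, tau = 0.15,
             s1 = 0.6, s2 = 0.8, d_mean = 1.2, d_sd = 0.3, w_sd = 0.7,
             w_jitter = 0.3, a_sd = 0.1, deg_sparsity = 0.2)

# cohort-level region parameters, drawn once per seed
.cohort_params <- function(spec) {
  with_seed(derive_seed(spec$seed, "cohort"), {
    n <- spec$n_rois
    list(
      z = matrix(stats::rnorm(n * spec$latent_dim), n, spec$latent_dim),
      b = stats::rnorm(n, .GEN$center, .GEN$b_sd),
      d = .GEN$d_mean + stats::rnorm(n, 0, .GEN$d_sd),
      w0 = stats::rnorm(n, 0, .GEN$w_sd),
      vox = sample(spec$voxels_per_roi[1]:spec$voxels_per_roi[2], n,
                   replace = TRUE)
    )
  })
}

# per-subject mixture parameters (means, weights, offsets) for all regions
.subject_params <- function(spec, pars, subject_id, group) {
  g <- if (group == spec$planted_global_group) {
    spec$planted_global_effect
  } else {
    0
  }
  shrink <- 1 / (1 + g)
  with_seed(derive_seed(spec$seed, subject_id), {
    n <- spec$n_rois
    f <- stats::rnorm(spec$latent_dim)
    a <- stats::rnorm(1, 0, .GEN$a_sd)
    eps <- stats::rnorm(n, 0, .GEN$tau * (1 + g))
    mu <- .GEN$center + shrink * (pars$b - .GEN$center) + a +
      .GEN$beta * shrink * as.numeric(pars$z %*% f) /
        sqrt(spec$latent_dim) + eps
    w <- stats::plogis(pars$w0 + .GEN$w_jitter * stats::rnorm(n))
    d <- pars$d
    pe <- spec$planted_edges
    if (!is.null(pe)) {
      pe <- pe[pe$group == group, , drop = FALSE]
      for (r in seq_len(nrow(pe))) {
        i <- pe$roi_a[r]; j <- pe$roi_b[r]; ef <- pe$effect[r]
        mu_bar <- (mu[i] + mu[j]) / 2
        mu[c(i, j)] <- mu[c(i, j)] + ef * (mu_bar - mu[c(i, j)])
        w_bar <- (w[i] + w[j]) / 2
        w[c(i, j)] <- w[c(i, j)] + ef * (w_bar - w[c(i, j)])
        d_bar <- (d[i] + d[j]) / 2
        d[c(i, j)] <- d[c(i, j)] + ef * (d_bar - d[c(i, j)])
      }
    }
    list(mu = mu, w = w, d = d, noise_seed = stats::runif(1))
  })
}

# analytic first two moments of each region's mixture
.mix_moments <- function(sp) {
  m <- sp$mu + (1 - sp$w) * sp$d
  v <- sp$w * .GEN$s1^2 + (1 - sp$w) * .GEN$s2^2 +
    sp$w * (1 - sp$w) * sp$d^2
  list(m = m, v = v)
}

# expected degree of every region for one subject: Gaussian-approximation
# KLS between region pairs, thresholded at the reference sparsity
.expected_degree <- function(sp, sparsity = .GEN$deg_sparsity) {
  mo <- .mix_moments(sp)
  n <- length(mo$m)
  vr <- outer(mo$v, mo$v, function(a, b) a / b + b / a - 2)
  dm <- outer(mo$m, mo$m, "-")^2 * outer(1 / mo$v, 1 / mo$v, "+")
  kl <- 0.5 * (vr + dm)
  sim <- exp(-kl)
  diag(sim) <- 0
  k <- round(sparsity * n * (n - 1) / 2)
  ut <- sim[upper.tri(sim)]
  thr <- sort(ut, decreasing = TRUE)[k]
  adj <- (sim >= thr)
  diag(adj) <- FALSE
  rowSums(adj)
}

.draw_voxels <- function(sp, vox, roi_names, subject_id, seed) {
  with_seed(derive_seed(seed, paste0(subject_id, "|voxels")), {
    n <- length(vox)
    samples <- vector("list", n)
    for (r in seq_len(n)) {
      v <- vox[r]
      comp1 <- stats::runif(v) < sp$w[r]
      means <- sp$mu[r] + ifelse(comp1, 0, sp$d[r])
      sds <- ifelse(comp1, .GEN$s1, .GEN$s2)
      samples[[r]] <- stats::rnorm(v, means, sds)
    }
    names(samples) <- roi_names
    roi_sample_set(subject_id, samples)
  })
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# one subject's clinical record; scores are integer and clipped to the
# instrument range, with PSQI clipped to the side consistent with the
# subject's sleep group (the generator emulates a post-screening sample)
.draw_clinical <- function(spec, subject_id, group) {
  p <- .CLIN_DEFAULTS[[group]]
  with_seed(derive_seed(spec$seed, paste0(subject_id, "|clinical")), {
    rn <- function(ms) stats::rnorm(1, ms[1], ms[2])
    age <- .clip(rn(p$age), 30, 90)
    sex <- if (stats::runif(1) < p$sex_m) "M" else "F"
    edu <- round(.clip(rn(p$edu), 0, 25))
    if (group == "HC") {
      duration <- NA_real_; onset <- NA_real_
      trs_a <- NA_real_; trs_b <- NA_real_; trs_c <- NA_real_
    } else {
      duration <- .clip(rn(p$duration), 0.5, age - 20)
      onset <- age - duration
      trs_a <- round(.clip(rn(p$trs_a), 0, 28))
      trs_b <- round(.clip(rn(p$trs_b), 0, 36))
      trs_c <- round(.clip(rn(p$trs_c), 0, 28))
    }
    psqi <- switch(group,
      SleET = round(.clip(rn(p$psqi), 6, 21)),
      NorET = round(.clip(rn(p$psqi), 0, 5)),
      HC = round(.clip(rn(p$psqi), 0, 21))
    )
    mmse <- round(.clip(rn(p$mmse), 24, 30))
    hama <- round(.clip(rn(p$hama), 0, 14))
    hamd <- round(.clip(rn(p$hamd), 0, 17))
    data.frame(
      subject_id = subject_id, group = group, age = round(age, 1),
      sex = sex, education = edu, onset_age = round(onset, 1),
      duration = round(duration, 1),
      TRS = trs_a + trs_b + trs_c, TRS_A = trs_a, TRS_B = trs_b,
      TRS_C = trs_c, PSQI = psqi, MMSE = mmse, HAMA = hama, HAMD = hamd,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a synthetic cohort
#'
#' Draws one [roi_sample_set] per subject plus a clinical table with the
#' group structure, instrument ranges and planted effects described in
#' [cohort_spec()]. Each subject is generated from an independent RNG
#' substream hashed from its id, so cohorts are reproducible regardless of
#' subject order and identical for a fixed seed. When
#' `spec$trs_degree_rho` is nonzero, [plant_degree_trs_correlation()] is
#' applied as a final step.
#'
#' @param spec a [cohort_spec].
#' @param include_samples draw voxel samples (`TRUE`, default) or only the
#'   clinical table, analytic parameters and expected degrees (`FALSE`,
#'   much faster; sufficient for clinical-correlation studies).
#' @return object of class `morph_cohort`: `samples` (named list of
#'   [roi_sample_set] or `NULL`), `table` (clinical data.frame),
#'   `expected_degree` (subjects x regions matrix of analytic degrees at
#'   the reference sparsity), `roi_names`, `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(), include_samples = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  pars <- .cohort_params(spec)
  ids <- unlist(lapply(.GROUPS, function(g) {
    sprintf("%s%03d", g, seq_len(spec$group_sizes[[g]]))
  }))
  groups <- rep(.GROUPS, spec$group_sizes)
  n_sub <- length(ids)
  samples <- if (include_samples) vector("list", n_sub) else NULL
  rows <- vector("list", n_sub)
  ed <- matrix(NA_real_, n_sub, spec$n_rois,
               dimnames = list(ids, spec$roi_names))
  for (s in seq_len(n_sub)) {
    sp <- .subject_params(spec, pars, ids[s], groups[s])
    ed[s, ] <- .expected_degree(sp)
    if (include_samples) {
      samples[[s]] <- .draw_voxels(sp, pars$vox, spec$roi_names, ids[s],
                                   spec$seed)
    }
    rows[[s]] <- .draw_clinical(spec, ids[s], groups[s])
  }
  if (include_samples) names(samples) <- ids
  cohort <- structure(
    list(samples = samples, table = do.call(rbind, rows),
         expected_degree = ed, roi_names = spec$roi_names, spec = spec),
    class = "morph_cohort"
  )
  if (spec$trs_degree_rho != 0) {
    cohort <- plant_degree_trs_correlation(
      cohort, target_roi = spec$trs_target_roi, rho = spec$trs_degree_rho,
      group = spec$trs_group
    )
  }
  cohort
}

#' @export
print.morph_cohort <- function(x, ...) {
  tb <- table(x$table$group)[.GROUPS]
  cat(sprintf(
    "morph_cohort: %d subjects (SleET %d / NorET %d / HC %d), %d regions%s\n",
    nrow(x$table), tb[1], tb[2], tb[3], length(x$roi_names),
    if (is.null(x$samples)) " (no voxel samples)" else ""))
  invisible(x)
}

#' Plant a degree-tremor correlation in a cohort
#'
#' Rewrites the tremor rating scale (TRS) total of one group as a linear
#' function of each subject's expected degree at `target_roi` plus
#' Gaussian noise, calibrated so the population correlation is `rho`. The
#' rewritten scores keep the group's original TRS mean and spread and the
#' subscale scores are rescaled proportionally.
#'
#' @param cohort a `morph_cohort`.
#' @param target_roi region name driving the correlation.
#' @param rho target correlation, `|rho| < 1`.
#' @param group group in which to plant (default `SleET`).
#' @return the modified cohort.
#' @export
plant_degree_trs_correlation <- function(cohort, target_roi = "Thalamus_L",
                                         rho = -0.35, group = "SleET") {
  stopifnot(inherits(cohort, "morph_cohort"))
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (!target_roi %in% cohort$roi_names) {
    stop("unknown target region: ", target_roi)
  }
  if (!group %in% .GROUPS) stop("unknown group: ", group)
  idx <- which(cohort$table$group == group)
  deg <- cohort$expected_degree[idx, target_roi]
  if (stats::sd(deg) == 0) {
    stop("degenerate degree variance at ", target_roi,
         ": cannot calibrate a correlation")
  }
  old <- cohort$table$TRS[idx]
  m <- mean(old); sdev <- stats::sd(old)
  if (sdev == 0) sdev <- 1
  z_deg <- as.numeric(scale(deg))
  new_trs <- with_seed(
    derive_seed(cohort$spec$seed, paste0("plant|", target_roi, "|", group)),
    {
      e <- stats::rnorm(length(idx))
      tz <- rho * z_deg + sqrt(1 - rho^2) * e
      round(pmax(0, m + sdev * tz))
    }
  )
  ratio <- ifelse(cohort$table$TRS[idx] > 0,
                  new_trs / cohort$table$TRS[idx], 1)
  for (col in c("TRS_A", "TRS_B", "TRS_C")) {
    cohort$table[[col]][idx] <- round(cohort$table[[col]][idx] * ratio)
  }
  cohort$table$TRS[idx] <- new_trs
  cohort
}

#' Write a cohort to disk
#'
#' One ROI sample TSV per subject (`<subject_id>.tsv`) plus the clinical
#' table `cohort.tsv`, all under `dir`.
#'
#' @param cohort a `morph_cohort` generated with voxel samples.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "morph_cohort"))
  if (is.null(cohort$samples)) {
    stop("cohort was generated without voxel samples")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rs in cohort$samples) {
    write_roi_table(rs, file.path(dir, paste0(rs$subject_id, ".tsv")))
  }
  utils::write.table(cohort$table, file.path(dir, "cohort.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Export one synthetic subject as NIfTI volumes
#'
#' Packs a subject's region samples into a synthetic 3-D grid (regions
#' laid out consecutively, no anatomy) and writes a gray-matter map plus
#' a matching integer label volume, for exercising the imaging reader.
#'
#' @param roi_samples a [roi_sample_set].
#' @param gm_path,atlas_path output NIfTI paths.
#' @param labels integer labels to assign each region (defaults to the
#'   set stored in the sample set).
#' @return invisible list with the two paths.
#' @export
export_synthetic_nifti <- function(roi_samples, gm_path, atlas_path,
                                   labels = NULL) {
  stopifnot(inherits(roi_samples, "roi_sample_set"))
  if (is.null(labels)) labels <- roi_samples$roi_labels
  n_vox <- sum(vapply(roi_samples$samples, length, 1L))
  side <- ceiling(n_vox^(1 / 3))
  dims <- c(side, side, ceiling(n_vox / side^2))
  total <- prod(dims)
  gm <- numeric(total)
  atlas <- integer(total)
  pos <- 1L
  for (r in seq_along(roi_samples$samples)) {
    v <- roi_samples$samples[[r]]
    gm[pos:(pos + length(v) - 1)] <- v
    atlas[pos:(pos + length(v) - 1)] <- labels[r]
    pos <- pos + length(v)
  }
  write_nifti(array(gm, dims), gm_path, datatype = "float64")
  write_nifti(array(atlas, dims), atlas_path, datatype = "int16")
  invisible(list(gm = gm_path, atlas = atlas_path))
}
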