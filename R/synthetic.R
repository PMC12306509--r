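#' Configuration for the synthetic volumetric cohort
#'
#' Defines the generative conditions for a two-group aging cohort with planted
#' regional gray-matter differences, cognition wired to regional volume, and
#' group-specific longitudinal decline in a planted region.
#'
#' @param grid_dims integer triple, voxels per axis (default 24^3).
#' @param voxel_size_mm isotropic voxel edge in mm (default 1.5).
#' @param n_per_group subjects per exposure group (>= 4).
#' @param effect_regions list of regions, each `list(center = <0-based voxel
#'   triple>, radius_mm = <r>, d = <standardized effect size>)`; the exposed
#'   group is shifted by `d` pooled SDs inside each region (negative `d` =
#'   exposed deficit).
#' @param cognitive_weights named list, one entry per cognitive domain; each a
#'   numeric vector of weights over `effect_regions` linking regional mean GMV
#'   to the domain score. Domains absent from the list are pure noise.
#' @param noise_sd SD of the Gaussian voxel noise field before smoothing, and
#'   of the additive noise on cognitive domain scores (z-scale units).
#' @param smooth_fwhm_mm FWHM of the Gaussian kernel applied to the noise
#'   field, in mm (default 8).
#' @param decline_rate_base annual fractional change of baseline GMV applied to
#'   everyone everywhere (negative = atrophy; default -0.005/yr).
#' @param decline_rate_delta extra annual fractional change applied to the
#'   exposed group inside `decline_region` (default -0.01/yr).
#' @param decline_rate_subject_sd SD of the per-subject random deviation of
#'   the annual rate, shared across voxels (inter-individual variability in
#'   aging speed; default 0.004/yr).
#' @param decline_rate_voxel_sd SD of the spatially smooth per-voxel rate
#'   noise field within each subject (default 0.004/yr).
#' @param decline_region index into `effect_regions` naming the planted decline
#'   region (default 1).
#' @param followup_interval_years mean inter-scan interval (default 3.2 y).
#' @param followup_jitter_sd SD of per-subject interval jitter in years.
#' @param age_shift_years mean age excess of the exposed group before matching
#'   (default +3 y), giving the matcher known work.
#' @param tests_per_domain number of raw test scores generated per domain
#'   (language gets a single test).
#' @param seed integer seed governing all randomness in the generator.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(grid_dims = c(24L, 24L, 24L),
                         voxel_size_mm = 1.5,
                         n_per_group = 40L,
                         effect_regions = list(list(center = c(12, 12, 12),
                                                    radius_mm = 6, d = 0)),
                         cognitive_weights = list(),
                         noise_sd = 0.1,
                         smooth_fwhm_mm = 8,
                         decline_rate_base = -0.005,
                         decline_rate_delta = -0.01,
                         decline_rate_subject_sd = 0.004,
                         decline_rate_voxel_sd = 0.004,
                         decline_region = 1L,
                         followup_interval_years = 3.2,
                         followup_jitter_sd = 0.3,
                         age_shift_years = 3,
                         tests_per_domain = 2L,
                         seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 4L),
            voxel_size_mm > 0, n_per_group >= 4L, noise_sd > 0,
            followup_interval_years > 0, followup_jitter_sd >= 0)
  for (r in effect_regions) {
    if (r$radius_mm <= 0) stop("effect region radius must be positive")
    if (any(r$center < 0) || any(r$center >= grid_dims))
      stop("effect region center outside the grid: (",
           paste(r$center, collapse = ","), ")")
  }
  cfg <- list(grid_dims = grid_dims, voxel_size_mm = voxel_size_mm,
              n_per_group = as.integer(n_per_group),
              effect_regions = effect_regions,
              cognitive_weights = cognitive_weights,
              noise_sd = noise_sd, smooth_fwhm_mm = smooth_fwhm_mm,
              decline_rate_base = decline_rate_base,
              decline_rate_delta = decline_rate_delta,
              decline_rate_subject_sd = decline_rate_subject_sd,
              decline_rate_voxel_sd = decline_rate_voxel_sd,
              decline_region = as.integer(decline_region),
              followup_interval_years = followup_interval_years,
              followup_jitter_sd = followup_jitter_sd,
              age_shift_years = age_shift_years,
              tests_per_domain = as.integer(tests_per_domain),
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' Cognitive domains modelled by the pipeline
#' @return Character vector of the six domain names.
#' @export
cognitive_domains <- function() {
  c("memory", "visual_spatial", "processing_speed",
    "executive_function", "working_memory", "language")
}

# boolean sphere mask around a 0-based center, radius in mm on voxel centers
sphere_mask <- function(dims, voxel_mm, center, radius_mm) {
  co <- voxel_coords(seq_len(prod(dims)), dims)
  d2 <- (co[, 1] - center[1])^2 + (co[, 2] - center[2])^2 +
        (co[, 3] - center[3])^2
  array(d2 * voxel_mm^2 <= radius_mm^2, dim = dims)
}

# smooth radial "brain" base pattern: plateau 0.45 falling to 0 at the edge
base_pattern <- function(dims, voxel_mm) {
  co <- voxel_coords(seq_len(prod(dims)), dims)
  ctr <- (dims - 1) / 2
  r <- sqrt(((co[, 1] - ctr[1]) / dims[1])^2 +
            ((co[, 2] - ctr[2]) / dims[2])^2 +
            ((co[, 3] - ctr[3]) / dims[3])^2)   # 0 at center, 0.87 at corner
  v <- 0.45 * plogis((0.38 - r) * 25)
  array(v, dim = dims)
}

#' Generate a complete synthetic baseline cohort
#'
#' Produces smooth non-negative gray-matter volumes for two groups (`DD`, the
#' exposed low-use group, and `ODD`, the control group) with the configured
#' standardized effects planted inside spherical regions, demographics with a
#' known pre-matching age imbalance, an ICT-use frequency item consistent with
#' group membership, raw cognitive test scores wired to regional GMV through
#' the configured weights, and a ground-truth record for recovery tests.
#'
#' Each subject's volume is the fixed radial base pattern plus a smoothed
#' Gaussian noise field; exposed-group voxels inside each effect region are
#' then shifted by `d` times the empirical pooled voxel SD, so the planted
#' standardized effect equals `d` by construction.
#'
#' @param config a [synth_config()].
#' @return A list with elements `phenotypes` (data.frame), `volumes`
#'   (`cohort_volumes`), `cognition` (data.frame of raw test scores plus the
#'   `ict_frequency` item), and `truth` (a `synthetic_truth` list holding the
#'   planted voxel masks, effect sizes, cognitive weights, and decline rates).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  dims <- config$grid_dims; vmm <- config$voxel_size_mm
  n <- 2L * config$n_per_group
  V <- prod(dims)
  with_seed(config$seed, {
    group <- rep(c("DD", "ODD"), each = config$n_per_group)
    ids <- sprintf("S%04d", seq_len(n))

    base <- as.vector(base_pattern(dims, vmm))
    dat <- matrix(0, n, V)
    for (s in seq_len(n)) {
      noise <- array(rnorm(V, sd = config$noise_sd), dim = dims)
      dat[s, ] <- base + as.vector(smooth_gaussian(noise, config$smooth_fwhm_mm, vmm))
    }

    # plant standardized shifts in the exposed (DD) group
    masks <- lapply(config$effect_regions, function(r)
      sphere_mask(dims, vmm, r$center, r$radius_mm))
    pooled_sd <- apply(dat, 2, stats::sd)
    exposed <- group == "DD"
    for (i in seq_along(masks)) {
      idx <- which(as.vector(masks[[i]]))
      d <- config$effect_regions[[i]]$d
      if (d != 0 && length(idx))
        dat[exposed, idx] <- dat[exposed, idx] +
          rep(d * pooled_sd[idx], each = sum(exposed))
    }
    dat[dat < 0] <- 0
    vols <- cohort_volumes(dat, dims, vmm, ids)

    # demographics: exposed group older pre-matching; other covariates balanced
    age <- stats::rnorm(n, mean = 72, sd = 5) +
      ifelse(exposed, config$age_shift_years, 0)
    gender <- stats::rbinom(n, 1, 0.5)
    education <- pmax(6, round(stats::rnorm(n, 11, 3)))
    hypertension <- stats::rbinom(n, 1, 0.35)
    diabetes <- stats::rbinom(n, 1, 0.2)
    hyperlipemia <- stats::rbinom(n, 1, 0.25)
    tiv <- stats::rnorm(n, 1450, 120)
    ict <- ifelse(exposed, sample(0:2, n, replace = TRUE),
                  sample(4:5, n, replace = TRUE))
    phen <- data.frame(id = ids, group = group, age = age, gender = gender,
                       education = education, hypertension = hypertension,
                       diabetes = diabetes, hyperlipemia = hyperlipemia,
                       tiv = tiv, stringsAsFactors = FALSE)

    # latent domain scores: weighted regional mean GMV (z-scaled) + noise
    region_means <- sapply(masks, function(m) rowMeans(dat[, as.vector(m), drop = FALSE]))
    region_z <- scale(region_means)
    domains <- cognitive_domains()
    latent <- matrix(stats::rnorm(n * length(domains), sd = config$noise_sd),
                     n, length(domains), dimnames = list(ids, domains))
    for (dn in names(config$cognitive_weights)) {
      w <- config$cognitive_weights[[dn]]
      latent[, dn] <- latent[, dn] + as.vector(region_z %*% w)
    }

    # raw tests: per-domain one-factor model with loadings 0.9, 0.7, ...
    cog <- data.frame(id = ids, ict_frequency = ict, stringsAsFactors = FALSE)
    for (dn in domains) {
      k <- if (dn == "language") 1L else config$tests_per_domain
      load <- seq(0.9, 0.5, length.out = max(k, 2))[seq_len(k)]
      for (t in seq_len(k)) {
        u_sd <- sqrt(max(1 - load[t]^2, 0.05))
        cog[[sprintf("%s_t%d", dn, t)]] <-
          load[t] * as.vector(scale(latent[, dn])) + stats::rnorm(n, sd = u_sd)
      }
    }

    truth <- structure(list(
      planted_voxel_masks = masks,
      true_effect_sizes = vapply(config$effect_regions, `[[`, numeric(1), "d"),
      true_cognitive_weights = config$cognitive_weights,
      true_latent_domains = latent,
      decline_rate_base = config$decline_rate_base,
      decline_rate_delta = config$decline_rate_delta,
      decline_region = config$decline_region
    ), class = "synthetic_truth")

    list(phenotypes = phen, volumes = vols, cognition = cog, truth = truth)
  })
}

#' Generate the follow-up timepoint for a synthetic cohort
#'
#' Applies the planted multiplicative decline rule voxel-wise:
#' `V_t2 = V_t1 * (1 + rate * interval)`. The per-subject per-voxel annual
#' rate is the base rate everywhere, plus the configured delta for
#' exposed-group voxels inside the planted decline region, plus a per-subject
#' random deviation shared across voxels (individual aging speed) and a
#' spatially smooth within-subject voxel noise field — both needed so that
#' group contrasts on rate maps face realistic between-subject variability.
#' The realized rate matrix is returned as `true_rate` for recovery tests.
#' Negative follow-up values are clipped to zero and counted.
#'
#' @param cohort output of [generate_cohort()].
#' @param config the same [synth_config()].
#' @return A list with `volumes_t2` (`cohort_volumes`), `phenotypes` (the
#'   baseline table with an `interval_years` column added), and `n_clipped`
#'   (count of voxels clipped at zero).
#' @export
generate_followup <- function(cohort, config) {
  stopifnot(inherits(config, "synth_config"))
  vols <- cohort$volumes
  n <- n_subjects(vols)
  with_seed(config$seed + 1L, {
    interval <- config$followup_interval_years +
      stats::rnorm(n, sd = config$followup_jitter_sd)
    interval <- pmax(interval, 0.5)

    rate <- matrix(config$decline_rate_base, n, prod(vols$dims))
    dm <- cohort$truth$planted_voxel_masks[[config$decline_region]]
    exposed <- cohort$phenotypes$group == "DD"
    rate[exposed, as.vector(dm)] <- rate[exposed, as.vector(dm)] +
      config$decline_rate_delta
    if (config$decline_rate_subject_sd > 0)
      rate <- rate + stats::rnorm(n, sd = config$decline_rate_subject_sd)
    if (config$decline_rate_voxel_sd > 0) {
      for (s in seq_len(n)) {
        f <- smooth_gaussian(array(stats::rnorm(prod(vols$dims)), dim = vols$dims),
                             config$smooth_fwhm_mm, vols$voxel_mm)
        f <- (f - mean(f)) / stats::sd(f)
        rate[s, ] <- rate[s, ] + config$decline_rate_voxel_sd * as.vector(f)
      }
    }

    dat2 <- vols$data * (1 + rate * interval)
    n_clipped <- sum(dat2 < 0)
    dat2[dat2 < 0] <- 0
    phen <- cohort$phenotypes
    phen$interval_years <- interval
    list(volumes_t2 = cohort_volumes(dat2, vols$dims, vols$voxel_mm,
                                     rownames(vols$data)),
         phenotypes = phen, n_clipped = n_clipped,
         true_rate = rate)
  })
}

#' Build a synthetic integer-labelled atlas by region growing
#'
#' Partitions the in-mask voxels into `n_regions` connected parcels by
#' multi-source breadth-first region growing from randomly chosen seed voxels
#' (6-connectivity), a stand-in for an anatomical parcellation on the synthetic
#' grid.
#'
#' @param mask a `brain_mask` (see [build_mask()]) or logical 3D array.
#' @param n_regions number of parcels (>= 1, <= in-mask voxel count).
#' @param seed integer seed for seed-voxel choice and tie-breaking.
#' @return Integer 3D array; 0 outside the mask, labels 1..n_regions inside.
#' @export
make_atlas <- function(mask, n_regions, seed = 1L) {
  m <- if (inherits(mask, "brain_mask")) mask$mask else mask
  stopifnot(is.array(m), length(dim(m)) == 3L)
  dims <- dim(m)
  inmask <- which(as.vector(m))
  if (n_regions < 1L) stop("n_regions must be >= 1")
  if (n_regions > length(inmask))
    stop("n_regions (", n_regions, ") exceeds in-mask voxel count (",
         length(inmask), ")")
  lab <- integer(prod(dims))
  with_seed(seed, {
    seeds <- sample(inmask, n_regions)
    lab[seeds] <- seq_len(n_regions)
    frontier <- seeds
    offs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
    while (length(frontier)) {
      co <- voxel_coords(frontier, dims)
      nxt <- integer(0)
      for (o in seq_len(6)) {
        nb <- coords_to_index(sweep(co, 2, offs[o, ], "+"), dims)
        ok <- !is.na(nb) & lab[nb] == 0L & as.vector(m)[nb]
        # first-come labelling; duplicates within a wave resolved by order
        nb <- nb[ok]; src <- frontier[ok]
        keep <- !duplicated(nb)
        nb <- nb[keep]; src <- src[keep]
        still <- lab[nb] == 0L
        lab[nb[still]] <- lab[src[still]]
        nxt <- c(nxt, nb[still])
      }
      frontier <- nxt
    }
    # voxels in disconnected mask islands: assign to nearest seed
    left <- inmask[lab[inmask] == 0L]
    if (length(left)) {
      co_l <- voxel_coords(left, dims)
      co_s <- voxel_coords(seeds, dims)
      for (i in seq_along(left)) {
        d2 <- colSums((t(co_s) - co_l[i, ])^2)
        lab[left[i]] <- which.min(d2)
      }
    }
  })
  array(lab, dim = dims)
}

#' Mean value per atlas region
#'
#' @param vol 3D numeric array or vector over the grid.
#' @param atlas integer label array from [make_atlas()] (0 = outside).
#' @return Named numeric vector of per-region means.
#' @export
region_means <- function(vol, atlas) {
  v <- as.vector(vol); lab <- as.vector(atlas)
  keep <- lab > 0L
  tapply(v[keep], lab[keep], mean)
}
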