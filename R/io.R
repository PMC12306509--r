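#' Read a NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `volume` (numeric array), `voxel_mm` (first pixdim), and
#'   the full `pixdim` vector.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  list(volume = array(as.numeric(img), dim = dim(img)),
       voxel_mm = pd[1], pixdim = pd)
}

#' Write a 3D volume as NIfTI
#'
#' @param volume numeric 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_mm isotropic voxel size stored in the header.
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path, voxel_mm = 1.5) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- rep(voxel_mm, length(dim(volume)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check that a volume matches the active mask grid
#'
#' @param volume numeric array.
#' @param mask a `brain_mask`.
#' @return TRUE invisibly; errors naming both shapes on mismatch.
#' @export
check_grid <- function(volume, mask) {
  if (!identical(dim(volume), dim(mask$mask)))
    stop("grid mismatch: volume is ", paste(dim(volume), collapse = "x"),
         " but mask is ", paste(dim(mask$mask), collapse = "x"))
  invisible(TRUE)
}

#' Read and validate a phenotype table
#'
#' Requires columns `id`, `group`, `age`, `gender`, `education`, `tiv`;
#' comorbidity flags and `interval_years` are optional. Group labels other
#' than `DD`/`ODD` and duplicate ids are rejected with the offending rows
#' listed.
#'
#' @param path CSV file with a header row, or a data.frame.
#' @return Validated data.frame.
#' @export
read_phenotype <- function(path) {
  phen <- if (is.data.frame(path)) path
          else utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "group", "age", "gender", "education", "tiv")
  missing_cols <- setdiff(required, names(phen))
  if (length(missing_cols))
    stop("phenotype table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  dup <- phen$id[duplicated(phen$id)]
  if (length(dup))
    stop("duplicate subject id(s): ", paste(unique(dup), collapse = ", "))
  bad <- !phen$group %in% c("DD", "ODD")
  if (any(bad))
    stop("unknown group label(s) in rows ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(phen$group[bad]), collapse = ", "))
  for (col in c("age", "gender", "education", "tiv"))
    if (!is.numeric(phen[[col]]))
      stop("column ", col, " must be numeric")
  phen
}

#' Write a cohort's volumes, phenotypes and cognition to disk
#'
#' One NIfTI per subject per timepoint plus `phenotype.csv`, `cognition.csv`
#' and a `truth.json` summary of the planted ground truth.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @param followup optional output of [generate_followup()].
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir, followup = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vols <- cohort$volumes
  for (s in seq_len(n_subjects(vols))) {
    id <- rownames(vols$data)[s]
    write_volume(subject_volume(vols, s),
                 file.path(dir, paste0(id, "_t1.nii.gz")), vols$voxel_mm)
    if (!is.null(followup))
      write_volume(subject_volume(followup$volumes_t2, s),
                   file.path(dir, paste0(id, "_t2.nii.gz")), vols$voxel_mm)
  }
  phen <- if (is.null(followup)) cohort$phenotypes else followup$phenotypes
  utils::write.csv(phen, file.path(dir, "phenotype.csv"), row.names = FALSE)
  utils::write.csv(cohort$cognition, file.path(dir, "cognition.csv"),
                   row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(list(
    true_effect_sizes = truth$true_effect_sizes,
    true_cognitive_weights = truth$true_cognitive_weights,
    decline_rate_base = truth$decline_rate_base,
    decline_rate_delta = truth$decline_rate_delta,
    planted_voxel_counts = vapply(truth$planted_voxel_masks, sum, numeric(1))),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> match -> composites -> voxel-wise contrast ->
#' searchlight -> representation -> decline rates -> growth model on a
#' configured synthetic cohort, returning every stage's result and writing a
#' JSON run manifest (settings, seed, warnings, timings) when `out_dir` is
#' given.
#'
#' @param config a [synth_config()].
#' @param spec a [searchlight_spec()].
#' @param n_perm permutations for the representation stage.
#' @param fdr_level FDR level for the group contrast (default 0.05).
#' @param rep_fdr_level FDR level for the representation stage (default 0.001).
#' @param out_dir optional directory for the manifest and result tables.
#' @param seed master seed; per-stage substreams are derived from it.
#' @return A list with each stage's outputs.
#' @export
run_pipeline <- function(config, spec = searchlight_spec(),
                         n_perm = 1000L, fdr_level = 0.05,
                         rep_fdr_level = 0.001, out_dir = NULL, seed = 1L) {
  warnings_seen <- character(0)
  note <- function(w) { warnings_seen <<- c(warnings_seen, conditionMessage(w))
                        invokeRestart("muffleWarning") }
  t0 <- Sys.time()

  config$seed <- seed
  spec$seed <- seed + 1L
  cohort <- generate_cohort(config)
  followup <- generate_followup(cohort, config)

  # matching on demographics + comorbidities
  prop <- withCallingHandlers(
    fit_propensity(cohort$phenotypes,
                   c("age", "gender", "education", "hypertension",
                     "diabetes", "hyperlipemia")),
    warning = note)
  prop <- match_pairs(prop, caliper_sd = 0.2, seed = seed + 2L)
  balance <- balance_table(prop)
  phen_m <- matched_phenotypes(prop)
  keep <- match(phen_m$id, cohort$phenotypes$id)

  # composites from the raw tests
  test_cols <- setdiff(names(cohort$cognition), c("id", "ict_frequency"))
  domain_map <- stats::setNames(sub("_t[0-9]+$", "", test_cols), test_cols)
  weights <- estimate_loadings(cohort$cognition[test_cols], domain_map)
  composites <- composite_scores(cohort$cognition[test_cols], weights)

  vols_m <- cohort$volumes[keep]
  groups_m <- phen_m$group
  covs_m <- phen_m[, c("age", "gender", "education", "tiv")]

  mask <- build_mask(cohort$volumes, 0.2)
  tmap <- group_tmap(vols_m, groups_m, covs_m, mask)
  sig <- fdr_correct(tmap$p, fdr_level)$significant
  clusters <- extract_clusters(tmap, sig, min_extent = 10L,
                               voxel_mm = config$voxel_size_mm)

  nbhd <- neighborhood_index(mask, spec$radius_mm)
  acc <- accuracy_map(vols_m, mask, groups_m, spec,
                      voxels = which(sig), nbhd = nbhd)
  partition <- withCallingHandlers(constrain_regions(acc, sig), warning = note)

  representation <- NULL
  if (any(partition$constrained)) {
    representation <- representation_map(
      vols_m, mask, partition, composites[keep, , drop = FALSE], spec,
      n_perm = n_perm, fdr_level = rep_fdr_level, seed = seed + 3L,
      nbhd = nbhd)
  }

  # longitudinal stage on the matched subjects
  rates <- annual_decline_rate(vols_m, followup$volumes_t2[keep],
                               followup$phenotypes$interval_years[keep])
  atlas <- make_atlas(mask, n_regions = 8L, seed = seed + 4L)
  reg_rates <- region_rates(rates, atlas, mask)
  rate_tmap <- rate_group_diff(rates, groups_m, covs_m, mask)

  # growth model on simulated repeat cognition (baseline + follow-up composite)
  result <- list(config = config, spec = spec, cohort = cohort,
                 followup = followup, propensity = prop, balance = balance,
                 weights = weights, composites = composites, mask = mask,
                 tmap = tmap, significant = sig, clusters = clusters,
                 accuracy = acc, partition = partition,
                 representation = representation, rates = rates,
                 atlas = atlas, region_rates = reg_rates,
                 rate_tmap = rate_tmap)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(balance, file.path(out_dir, "balance.csv"), row.names = FALSE)
    utils::write.csv(clusters, file.path(out_dir, "clusters.csv"), row.names = FALSE)
    manifest <- list(stage = "pipeline", seed = seed,
                     grid_dims = config$grid_dims,
                     n_per_group = config$n_per_group,
                     n_matched_pairs = nrow(prop$pairs),
                     n_significant_voxels = sum(sig),
                     n_constrained = sum(partition$constrained),
                     elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                     warnings = warnings_seen,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
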