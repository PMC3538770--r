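#' Write a 3D volume to a NIfTI-1 file
#'
#' Data are stored as float32 with the voxel size recorded in the header.
#'
#' @param x 3D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size mm per axis, length 3.
#' @return the path, invisibly.
#' @export
write_volume <- function(x, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' @param path NIfTI file path.
#' @return list with `data` (plain 3D array) and `voxel_size` (mm).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D volume, got ", length(dim(img)), "D: ", path,
         call. = FALSE)
  list(data = array(as.numeric(img), dim(img)),
       voxel_size = as.numeric(RNifti::pixdim(img))[1:3])
}

#' Read a phase volume, normalising units to wrapped radians
#'
#' Phase is expected in radians wrapped to (-pi, pi]. If values beyond pi
#' are found the volume is assumed to be in degrees, converted, and a
#' warning is raised; in either case the result is re-wrapped.
#'
#' @param path NIfTI file path.
#' @return as [read_volume()], with `data` guaranteed in (-pi, pi].
#' @export
read_phase_volume <- function(path) {
  v <- read_volume(path)
  tol <- 1e-6
  if (any(abs(v$data) > pi + tol)) {
    warning("phase values beyond pi found in ", basename(path),
            ": interpreting as degrees and converting to radians",
            call. = FALSE)
    v$data <- v$data * pi / 180
  }
  v$data <- wrap_phase(v$data)
  v
}

#' Read a magnitude/phase pair into a complex_gre_volume
#'
#' @param magnitude_path,phase_path NIfTI file paths.
#' @param te,b0,handedness acquisition metadata (not stored in NIfTI-1).
#' @return a [complex_gre_volume()].
#' @export
read_gre_pair <- function(magnitude_path, phase_path, te = 12, b0 = 3,
                          handedness = c("left", "right")) {
  handedness <- match.arg(handedness)
  mag <- read_volume(magnitude_path)
  ph <- read_phase_volume(phase_path)
  if (!identical(dim(mag$data), dim(ph$data)))
    stop("magnitude shape ", paste(dim(mag$data), collapse = "x"),
         " does not match phase shape ", paste(dim(ph$data), collapse = "x"),
         call. = FALSE)
  complex_gre_volume(mag$data, ph$data, te = te, b0 = b0,
                     handedness = handedness, voxel_size = mag$voxel_size)
}

#' Write / read a cohort table as TSV
#'
#' @param cohort data.frame from [simulate_cohort()].
#' @param path TSV path.
#' @return the path (write) or the data.frame (read).
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write lesion calls as TSV
#'
#' Columns: id, cx, cy, cz, n_voxels, mean_phase_rad, swi_contrast, label.
#'
#' @param calls a `lesion_calls` data.frame.
#' @param path TSV path.
#' @export
write_lesions_tsv <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate -> reconstruct -> detect/classify -> evaluate -> stats
#' and writes every artifact plus a manifest (parameters, seed, MD5 hash of
#' each output) to the output directory. Identical configuration and seed
#' yield identical manifest hashes.
#'
#' @param config named list (or path to a YAML/JSON file) with optional
#'   entries `phantom` (arguments to [phantom_spec()]; `sources` given as
#'   lists of [susceptibility_source()] arguments), `recon` (arguments to
#'   [recon_params()]), `detection` (arguments to [detection_params()]),
#'   `cohort` (arguments to [simulate_cohort()]) and `seed`.
#' @param out_dir output directory, created if absent.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)

  ph_args <- config$phantom %||% list()
  if (!is.null(ph_args$sources))
    ph_args$sources <- lapply(ph_args$sources, function(s)
      do.call(susceptibility_source, s))
  if (is.null(ph_args$seed)) ph_args$seed <- seed
  spec <- do.call(phantom_spec, ph_args)
  sim <- simulate_phantom(spec)

  rp <- do.call(recon_params, config$recon %||% list())
  recon <- reconstruct_swi(sim$volume, rp)

  dp <- do.call(detection_params, config$detection %||% list())
  calls <- classify_lesions(recon, dp, spec$handedness)
  evaluation <- evaluate_against_truth(calls, sim$truth, spec$voxel_size)

  co_args <- config$cohort %||% list()
  if (is.null(co_args$seed)) co_args$seed <- seed
  cohort <- do.call(simulate_cohort, co_args)
  tables <- build_study_tables(cohort)
  stats_report <- cohort_report(tables)

  vx <- spec$voxel_size
  paths <- c(
    magnitude = "magnitude.nii.gz", phase = "phase.nii.gz",
    chi = "chi.nii.gz", field = "field.nii.gz",
    truth_labels = "truth_labels.nii.gz",
    filtered_phase = "filtered_phase.nii.gz", mask = "mask.nii.gz",
    swi = "swi.nii.gz", mip = "mip.nii.gz"
  )
  full <- file.path(out_dir, paths)
  names(full) <- names(paths)
  write_volume(sim$volume$magnitude, full[["magnitude"]], vx)
  write_volume(sim$volume$phase, full[["phase"]], vx)
  write_volume(sim$chi, full[["chi"]], vx)
  write_volume(sim$field, full[["field"]], vx)
  write_volume(sim$truth$label_volume + 0, full[["truth_labels"]], vx)
  write_volume(recon$filtered_phase$phase_hp, full[["filtered_phase"]], vx)
  write_volume(recon$mask$mask, full[["mask"]], vx)
  write_volume(recon$swi, full[["swi"]], vx)
  write_volume(recon$mip, full[["mip"]],
               c(vx[1:2], vx[3] * rp$mip_depth))

  tsvs <- c(sources = "sources.tsv", lesions = "lesions.tsv",
            evaluation = "evaluation.tsv", cohort = "cohort.tsv",
            metrics = "metrics.tsv")
  tfull <- file.path(out_dir, tsvs)
  names(tfull) <- names(tsvs)
  utils::write.table(sim$truth$source_table, tfull[["sources"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_lesions_tsv(calls, tfull[["lesions"]])
  utils::write.table(evaluation$counts, tfull[["evaluation"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_cohort_tsv(cohort, tfull[["cohort"]])
  utils::write.table(stats_report, tfull[["metrics"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  outputs <- c(full, tfull)
  manifest <- list(
    seed = seed,
    config = config,
    outputs = lapply(seq_along(outputs), function(i)
      list(name = names(outputs)[i], file = basename(outputs[[i]]),
           md5 = unname(tools::md5sum(outputs[[i]]))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Tabular report of cohort-level diagnostic statistics
#'
#' One row per (table, metric): the hemorrhage-by-disease detection rates
#' and Fisher p-value, and the five accuracy metrics of each modality's
#' calcification detection against CT.
#'
#' @param tables output of [build_study_tables()].
#' @return data.frame with columns `quantity`, `value`, `numerator`,
#'   `denominator`.
#' @export
cohort_report <- function(tables) {
  rows <- list()
  add <- function(quantity, value, num = NA, den = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, value = value, numerator = num, denominator = den)
  }
  ht <- tables$hemorrhage_by_disease
  r_cancer <- detection_rate(ht[1, 1], sum(ht[1, ]))
  r_bph <- detection_rate(ht[2, 1], sum(ht[2, ]))
  add("hemorrhage_rate_cancer_pct", r_cancer$percent,
      r_cancer$detected, r_cancer$total)
  add("hemorrhage_rate_bph_pct", r_bph$percent, r_bph$detected, r_bph$total)
  add("hemorrhage_fisher_p", fisher_exact(ht)$p_two_sided)
  for (nm in intersect(c("calcification_swi", "calcification_conv_mri"),
                       names(tables))) {
    dm <- suppressWarnings(diagnostic_metrics(tables[[nm]]))
    for (m in c("sensitivity", "specificity", "accuracy", "ppv", "npv")) {
      e <- dm[[m]]
      add(paste0(nm, "_", m, "_pct"),
          if (is.na(e$estimate)) NA_real_ else percent_1dp(e$estimate),
          e$numerator, e$denominator)
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
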