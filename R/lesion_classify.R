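#' Detection parameters for hypointense foci
#'
#' Operationalises "low signal on SWI" numerically: a voxel is hypointense
#' when its SWI value falls below `intensity_ratio_threshold` times the local
#' median background; candidates are connected components of such voxels.
#' These thresholds are engineering defaults — the study this package models
#' used visual reads, so none of these values comes from it.
#'
#' @param intensity_ratio_threshold fraction in (0, 1); default 0.7.
#' @param background_window odd voxel count for the in-plane local median
#'   background; default 15.
#' @param min_size minimum component size in voxels; default 3.
#' @param connectivity 6, 18 or 26 (face / edge / corner neighbours).
#' @param phase_margin_eps radians; foci with |mean filtered phase| below
#'   this margin are labelled indeterminate. Default 0.05.
#' @return object of class `detection_params`.
#' @export
detection_params <- function(intensity_ratio_threshold = 0.7,
                             background_window = 15L,
                             min_size = 3L,
                             connectivity = 26L,
                             phase_margin_eps = 0.05) {
  if (intensity_ratio_threshold <= 0 || intensity_ratio_threshold >= 1)
    stop("`intensity_ratio_threshold` must be in (0, 1)", call. = FALSE)
  background_window <- as.integer(background_window)
  if (background_window < 3L || background_window %% 2L == 0L)
    stop("`background_window` must be an odd integer >= 3", call. = FALSE)
  if (min_size < 1L) stop("`min_size` must be >= 1", call. = FALSE)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  if (phase_margin_eps < 0) stop("`phase_margin_eps` must be >= 0", call. = FALSE)
  structure(
    list(intensity_ratio_threshold = intensity_ratio_threshold,
         background_window = background_window,
         min_size = as.integer(min_size),
         connectivity = as.integer(connectivity),
         phase_margin_eps = phase_margin_eps),
    class = "detection_params"
  )
}

# In-plane local median background, slice by slice (constant-time median
# filter from EBImage; input rescaled to [0,1] as the filter requires).
local_median_background <- function(swi, window) {
  dims <- dim(swi)
  r <- (window - 1L) %/% 2L
  mx <- max(swi)
  if (mx <= 0) return(array(0, dims))
  bg <- array(0, dims)
  for (z in seq_len(dims[3])) {
    sl <- swi[, , z] / mx
    bg[, , z] <- EBImage::medianFilter(sl, size = r) * mx
  }
  bg
}

# Neighbour offsets for 6/18/26-connectivity in 3D.
connectivity_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1,
                 "18" = nz >= 1 & rowSums(off != 0) <= 2,
                 "26" = nz >= 1)
  off[keep, , drop = FALSE]
}

# Label connected components of a logical 3D array. Returns an integer array
# (0 = background) with components numbered in order of their smallest linear
# index (column-major: x fastest, then y, then z).
label_components_3d <- function(mask, connectivity = 26L) {
  dims <- dim(mask)
  labels <- array(0L, dims)
  off <- connectivity_offsets(connectivity)
  idx <- which(mask)
  if (!length(idx)) return(labels)
  coords <- arrayInd(idx, dims)
  lookup <- array(0L, dims)
  lookup[idx] <- seq_along(idx)
  visited <- logical(length(idx))
  current <- 0L
  for (start in seq_along(idx)) {
    if (visited[start]) next
    current <- current + 1L
    queue <- start
    visited[start] <- TRUE
    while (length(queue)) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      labels[idx[v]] <- current
      p <- coords[v, ]
      nb <- sweep(off, 2, p, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      ni <- lookup[nb]
      ni <- ni[ni > 0L]
      ni <- ni[!visited[ni]]
      if (length(ni)) {
        visited[ni] <- TRUE
        queue <- c(queue, ni)
      }
    }
  }
  labels
}

#' Detect hypointense foci on an SWI volume
#'
#' Thresholds the SWI volume against `intensity_ratio_threshold` times the
#' in-plane local median background, labels connected components at the
#' requested connectivity, and keeps components of at least `min_size`
#' voxels. Ordering is deterministic: ascending smallest linear voxel index.
#'
#' @param swi 3D array (e.g. the `swi` element of [reconstruct_swi()]).
#' @param params a [detection_params()].
#' @return list of foci; each focus is a list with `id`, `voxels` (n x 3
#'   integer matrix of x, y, z indices), `centroid` (grid coordinates) and
#'   `n_voxels`. Empty list (with a warning) on an all-zero volume.
#' @export
detect_hypointense_foci <- function(swi, params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  if (all(swi == 0)) {
    warning("all-zero SWI volume: no detectable background", call. = FALSE)
    return(list())
  }
  bg <- local_median_background(swi, params$background_window)
  hypo <- (bg > 0) & (swi < params$intensity_ratio_threshold * bg)
  labels <- label_components_3d(hypo, params$connectivity)
  n_comp <- max(labels)
  out <- list()
  for (i in seq_len(n_comp)) {
    vox <- which(labels == i)
    if (length(vox) < params$min_size) next
    coords <- arrayInd(vox, dim(swi))
    out[[length(out) + 1L]] <- list(
      id = length(out) + 1L,
      voxels = coords,
      centroid = colMeans(coords),
      n_voxels = nrow(coords)
    )
  }
  out
}

#' Classify a focus as hemorrhage or calcification by filtered-phase sign
#'
#' The discrimination rule: hemorrhage (paramagnetic blood products) and
#' calcification (diamagnetic) take opposite signs on the filtered phase
#' image. With a left-handed acquisition, mean filtered phase below
#' `-eps` means hemorrhage and above `+eps` means calcification; a
#' right-handed acquisition inverts the rule. "Mixed signal dominated by"
#' one sign is operationalised as the sign of the focus-mean phase.
#'
#' @param focus a focus from [detect_hypointense_foci()] (or any list with a
#'   `voxels` matrix).
#' @param filtered_phase a `filtered_phase_volume` (or bare phase array).
#' @param handedness `"left"` or `"right"`.
#' @param eps indeterminacy margin in radians.
#' @return list with `label` (`"hemorrhage"`, `"calcification"` or
#'   `"indeterminate"`) and `mean_filtered_phase`.
#' @export
classify_focus <- function(focus, filtered_phase,
                           handedness = c("left", "right"), eps = 0.05) {
  handedness <- match.arg(handedness)
  phase <- if (inherits(filtered_phase, "filtered_phase_volume"))
    filtered_phase$phase_hp else filtered_phase
  if (is.null(focus$voxels) || nrow(focus$voxels) == 0L)
    stop("empty focus: no voxels to classify", call. = FALSE)
  if (any(focus$voxels < 1) || any(focus$voxels > rep(dim(phase),
                                                      each = nrow(focus$voxels))))
    stop("focus voxels fall outside the phase grid", call. = FALSE)
  mp <- mean(phase[focus$voxels])
  signed <- if (handedness == "left") mp else -mp
  label <- if (signed < -eps) "hemorrhage"
           else if (signed > eps) "calcification"
           else "indeterminate"
  list(label = label, mean_filtered_phase = mp)
}

#' Detect and classify all hypointense foci
#'
#' Runs [detect_hypointense_foci()] then [classify_focus()] on each focus and
#' attaches the SWI contrast (1 - mean SWI inside / local background).
#'
#' @param recon a `swi_recon` from [reconstruct_swi()].
#' @param params a [detection_params()].
#' @param handedness phase sign convention of the acquisition.
#' @return object of class `lesion_calls`: data.frame with one row per focus
#'   (`id`, `cx`, `cy`, `cz`, `n_voxels`, `mean_phase_rad`, `swi_contrast`,
#'   `label`) and the focus list as attribute `"foci"`.
#' @export
classify_lesions <- function(recon, params = detection_params(),
                             handedness = c("left", "right")) {
  handedness <- match.arg(handedness)
  stopifnot(inherits(recon, "swi_recon"))
  foci <- detect_hypointense_foci(recon$swi, params)
  bg <- local_median_background(recon$swi, params$background_window)
  rows <- lapply(foci, function(f) {
    cl <- classify_focus(f, recon$filtered_phase, handedness,
                         params$phase_margin_eps)
    mean_bg <- mean(bg[f$voxels])
    data.frame(
      id = f$id, cx = f$centroid[1], cy = f$centroid[2], cz = f$centroid[3],
      n_voxels = f$n_voxels,
      mean_phase_rad = cl$mean_filtered_phase,
      swi_contrast = if (mean_bg > 0) 1 - mean(recon$swi[f$voxels]) / mean_bg
                     else NA_real_,
      label = cl$label
    )
  })
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), cx = numeric(0), cy = numeric(0),
               cz = numeric(0), n_voxels = integer(0),
               mean_phase_rad = numeric(0), swi_contrast = numeric(0),
               label = character(0))
  structure(calls, foci = foci, class = c("lesion_calls", "data.frame"))
}

#' Score lesion calls against phantom ground truth
#'
#' Greedy one-to-one matching: all call/truth pairs within `match_radius`
#' (mm, centroid-to-centre) are considered in ascending distance; each call
#' and each truth source is used at most once. A matched call counts as a
#' true positive only when labels agree; a label mismatch counts as both a
#' false positive (the call) and a false negative (the missed truth).
#' Unmatched truth sources are false negatives; unmatched calls are false
#' positives.
#'
#' @param calls a `lesion_calls` data.frame (from [classify_lesions()]).
#' @param truth ground truth from [build_susceptibility_map()].
#' @param voxel_size mm per axis.
#' @param match_radius maximum centroid distance in mm; default 5.
#' @return list with `counts` (data.frame: kind, tp, fp, fn), `matches`
#'   (data.frame: call id, truth id, distance_mm, call label, truth kind,
#'   correct) and `n_correct` / `n_matched`.
#' @export
evaluate_against_truth <- function(calls, truth, voxel_size = c(1, 1, 3),
                                   match_radius = 5) {
  tab <- truth$source_table
  n_calls <- nrow(calls)
  n_truth <- nrow(tab)
  pairs <- NULL
  if (n_calls && n_truth) {
    cc <- as.matrix(calls[, c("cx", "cy", "cz")])
    tc <- as.matrix(tab[, c("cx", "cy", "cz")])
    d <- outer(seq_len(n_calls), seq_len(n_truth), Vectorize(function(i, j) {
      sqrt(sum(((cc[i, ] - tc[j, ]) * voxel_size)^2))
    }))
    cand <- which(d <= match_radius, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_call <- logical(n_calls); used_truth <- logical(n_truth)
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_call[i] && !used_truth[j]) {
          used_call[i] <- TRUE; used_truth[j] <- TRUE; keep[k] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand))
        pairs <- data.frame(
          call_id = calls$id[cand[, 1]], truth_id = tab$id[cand[, 2]],
          distance_mm = d[cand],
          call_label = calls$label[cand[, 1]], truth_kind = tab$kind[cand[, 2]],
          correct = calls$label[cand[, 1]] == tab$kind[cand[, 2]]
        )
    }
  }
  if (is.null(pairs))
    pairs <- data.frame(call_id = integer(0), truth_id = integer(0),
                        distance_mm = numeric(0), call_label = character(0),
                        truth_kind = character(0), correct = logical(0))
  kinds <- c("hemorrhage", "calcification")
  counts <- do.call(rbind, lapply(kinds, function(k) {
    tp <- sum(pairs$correct & pairs$truth_kind == k)
    fn <- sum(tab$kind == k) - tp
    fp <- sum(calls$label == k) - tp
    data.frame(kind = k, tp = tp, fp = fp, fn = fn)
  }))
  list(counts = counts, matches = pairs,
       n_correct = sum(pairs$correct), n_matched = nrow(pairs))
}
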