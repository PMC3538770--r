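#' Reconstruction parameters
#'
#' Defaults follow the standard SWI recipe: a 64 x 64 central k-space
#' low-pass (Hann-windowed) for the homodyne high-pass phase filter, a
#' fourth-power negative-phase mask, and a minimum-intensity projection over
#' two sections.
#'
#' @param filter_size two positive integers: in-plane extent of the central
#'   k-space window removed by the high-pass filter.
#' @param window `"hann"` (default) or `"boxcar"` k-space window shape.
#' @param mask_exponent positive integer power applied to the phase mask.
#' @param mip_depth positive integer: slices per minimum-intensity slab.
#' @return object of class `recon_params`.
#' @export
recon_params <- function(filter_size = c(64L, 64L),
                         window = c("hann", "boxcar"),
                         mask_exponent = 4L, mip_depth = 2L) {
  window <- match.arg(window)
  filter_size <- as.integer(filter_size)
  if (length(filter_size) != 2L || any(filter_size < 1L))
    stop("`filter_size` must be two positive integers", call. = FALSE)
  if (mask_exponent < 1L) stop("`mask_exponent` must be >= 1", call. = FALSE)
  if (mip_depth < 1L) stop("`mip_depth` must be >= 1", call. = FALSE)
  structure(
    list(filter_size = filter_size, window = window,
         mask_exponent = as.integer(mask_exponent),
         mip_depth = as.integer(mip_depth)),
    class = "recon_params"
  )
}

# Central k-space window of width L on an axis of n samples, in unshifted
# (DFT) frequency order. Defined symmetrically about DC on integer frequency
# indices q: Hann taper 0.5*(1 + cos(2*pi*q/L)) on |q| <= L/2 (zero at the
# endpoints), or a flat boxcar on the same support. Symmetry about DC makes
# the homodyne filter exactly odd under complex conjugation of the input.
kspace_window_1d <- function(n, L, window) {
  q <- fft_freq(n, 1) * n  # integer frequency indices in fft() layout
  w <- numeric(n)
  inside <- abs(q) <= L / 2
  w[inside] <- switch(window,
    hann = 0.5 * (1 + cos(2 * pi * q[inside] / L)),
    boxcar = 1
  )
  w
}

#' Homodyne high-pass filter of the phase image
#'
#' Forms the complex image m * exp(i phi) slice by slice, divides it by its
#' low-pass version (central `filter_size` k-space lines, windowed), and
#' returns the phase of the quotient. Constant and slowly varying phase —
#' the background static-field contribution — is suppressed; local,
#' high-spatial-frequency susceptibility phase passes. Complex division makes
#' the filter robust to phase wraps without explicit unwrapping.
#'
#' Voxels where the low-pass image is exactly zero have undefined quotient
#' phase; they are set to 0 and counted in `n_zero_lowpass`.
#'
#' @param vol a [complex_gre_volume()].
#' @param params a [recon_params()]; `filter_size` must be strictly smaller
#'   than the in-plane matrix.
#' @return object of class `filtered_phase_volume`: list with `phase_hp`
#'   (radians, (-pi, pi]), `provenance` (the params) and `n_zero_lowpass`.
#' @export
highpass_filter_phase <- function(vol, params = recon_params()) {
  stopifnot(inherits(vol, "complex_gre_volume"), inherits(params, "recon_params"))
  dims <- dim(vol$magnitude)
  if (any(params$filter_size >= dims[1:2]))
    stop("`filter_size` (", paste(params$filter_size, collapse = "x"),
         ") must be smaller than the in-plane matrix (",
         paste(dims[1:2], collapse = "x"), ")", call. = FALSE)
  wx <- kspace_window_1d(dims[1], params$filter_size[1], params$window)
  wy <- kspace_window_1d(dims[2], params$filter_size[2], params$window)
  W <- outer(wx, wy)
  phase_hp <- array(0, dims)
  n_zero <- 0L
  for (z in seq_len(dims[3])) {
    cx <- vol$magnitude[, , z] * exp(1i * vol$phase[, , z])
    lp <- fft(fft(cx) * W, inverse = TRUE) / prod(dims[1:2])
    # a real slice has a mathematically real low-pass (W is symmetric about
    # DC); drop the FFT's residual imaginary part so zero phase in gives
    # exactly zero filtered phase out
    if (all(vol$phase[, , z] == 0))
      lp <- complex(real = Re(lp), imaginary = 0)
    q <- Arg(cx) - Arg(lp)
    zero <- Mod(lp) == 0
    n_zero <- n_zero + sum(zero)
    q[zero] <- 0
    phase_hp[, , z] <- wrap_phase(q)
  }
  structure(
    list(phase_hp = phase_hp, provenance = params, n_zero_lowpass = n_zero),
    class = "filtered_phase_volume"
  )
}

#' Negative-phase mask
#'
#' Maps filtered phase to a multiplicative mask: non-negative phase (0 to
#' 180 degrees) maps to 1; negative phase ramps linearly from 1 at 0 degrees
#' down to 0 at -180 degrees. With a left-handed acquisition, paramagnetic
#' (blood-product) voxels carry negative filtered phase and are darkened.
#'
#' @param fp a `filtered_phase_volume` (or a bare array of wrapped phases in
#'   radians).
#' @return object of class `negative_phase_mask`: list with `mask`, an array
#'   in \[0, 1\].
#' @export
make_phase_mask <- function(fp) {
  phase <- if (inherits(fp, "filtered_phase_volume")) fp$phase_hp else fp
  if (any(phase <= -pi - 1e-12) || any(phase > pi + 1e-12))
    stop("phase must be wrapped to (-pi, pi]", call. = FALSE)
  mask <- ifelse(phase < 0, 1 + phase / pi, 1)
  mask <- pmin(pmax(mask, 0), 1)
  if (is.array(phase)) dim(mask) <- dim(phase)
  structure(list(mask = mask), class = "negative_phase_mask")
}

#' Multiply the magnitude image by the phase mask
#'
#' The mask is raised to the `m`-th power (default 4 — "multiplied four
#' times") and applied voxelwise, so the susceptibility-weighted image never
#' exceeds the original magnitude.
#'
#' @param magnitude nonnegative array.
#' @param mask a `negative_phase_mask` (or bare array in \[0, 1\]).
#' @param m positive integer exponent.
#' @return array `magnitude * mask^m`.
#' @export
apply_mask <- function(magnitude, mask, m = 4L) {
  mk <- if (inherits(mask, "negative_phase_mask")) mask$mask else mask
  if (!identical(dim(magnitude), dim(mk)))
    stop("magnitude (", paste(dim(magnitude), collapse = "x"),
         ") and mask (", paste(dim(mk), collapse = "x"),
         ") shapes differ", call. = FALSE)
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  magnitude * mk^m
}

#' Minimum-intensity projection over slabs of slices
#'
#' Partitions the slice axis into consecutive non-overlapping slabs of
#' `depth` slices (the trailing slab may be shorter) and projects each slab
#' voxelwise by minimum, emphasising dark susceptibility structures.
#'
#' @param swi 3D array.
#' @param depth slices per slab (>= 1, <= number of slices).
#' @return list with `mip` (3D array, `ceiling(nz / depth)` sections) and
#'   `slabs` (data.frame: section, first_slice, last_slice).
#' @export
min_intensity_projection <- function(swi, depth = 2L) {
  if (depth < 1L) stop("`depth` must be >= 1", call. = FALSE)
  dims <- dim(swi)
  if (depth > dims[3])
    stop("`depth` exceeds the number of slices", call. = FALSE)
  n_sect <- ceiling(dims[3] / depth)
  mip <- array(NA_real_, c(dims[1:2], n_sect))
  slabs <- data.frame(section = seq_len(n_sect),
                      first_slice = (seq_len(n_sect) - 1L) * depth + 1L)
  slabs$last_slice <- pmin(slabs$first_slice + depth - 1L, dims[3])
  for (s in seq_len(n_sect)) {
    zr <- slabs$first_slice[s]:slabs$last_slice[s]
    mip[, , s] <- apply(swi[, , zr, drop = FALSE], c(1, 2), min)
  }
  list(mip = mip, slabs = slabs)
}

#' Full SWI reconstruction
#'
#' Deterministic composition: homodyne high-pass phase filter, negative-phase
#' mask, fourth-power mask multiplication against the original magnitude,
#' minimum-intensity projection. All intermediates are returned for
#' inspection.
#'
#' @param vol a [complex_gre_volume()].
#' @param params a [recon_params()].
#' @return object of class `swi_recon`: list with `filtered_phase`, `mask`,
#'   `swi` (array), `mip`, `slabs`, `params` and the input `voxel_size`.
#' @export
reconstruct_swi <- function(vol, params = recon_params()) {
  fp <- highpass_filter_phase(vol, params)
  mask <- make_phase_mask(fp)
  swi <- apply_mask(vol$magnitude, mask, params$mask_exponent)
  proj <- min_intensity_projection(swi, params$mip_depth)
  structure(
    list(filtered_phase = fp, mask = mask, swi = swi,
         mip = proj$mip, slabs = proj$slabs, params = params,
         voxel_size = vol$voxel_size),
    class = "swi_recon"
  )
}

#' @export
print.swi_recon <- function(x, ...) {
  cat(sprintf(
    "swi_recon %s | filter %s (%s), mask^%d, mIP depth %d (%d sections)\n",
    paste(dim(x$swi), collapse = "x"),
    paste(x$params$filter_size, collapse = "x"), x$params$window,
    x$params$mask_exponent, x$params$mip_depth, dim(x$mip)[3]))
  invisible(x)
}
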