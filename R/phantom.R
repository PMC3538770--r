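# Proton gyromagnetic ratio, rad / s / T.
GAMMA_RAD_PER_S_PER_T <- 2 * pi * 42.577e6

#' Declare a spherical susceptibility source
#'
#' A source is a homogeneous sphere of susceptibility shift `delta_chi`
#' (ppm, relative to the tissue background) centred at continuous voxel
#' coordinates. Blood products are paramagnetic (`delta_chi > 0`,
#' `kind = "hemorrhage"`); calcification is diamagnetic (`delta_chi < 0`,
#' `kind = "calcification"`). T2*-like signal loss inside the source is
#' modelled by a constant fractional magnitude attenuation.
#'
#' @param center numeric length-3, continuous voxel coordinates (x, y, z;
#'   1-based grid units).
#' @param radius sphere radius in mm.
#' @param delta_chi susceptibility shift in ppm; sign must match `kind`.
#' @param kind `"hemorrhage"` or `"calcification"`.
#' @param magnitude_attenuation fraction in \[0, 1\] by which the magnitude is
#'   multiplied inside the source (default 0.5).
#' @return an object of class `susceptibility_source`.
#' @export
susceptibility_source <- function(center, radius, delta_chi,
                                  kind = c("hemorrhage", "calcification"),
                                  magnitude_attenuation = 0.5) {
  kind <- match.arg(kind)
  if (length(center) != 3L || !all(is.finite(center)))
    stop("`center` must be 3 finite voxel coordinates", call. = FALSE)
  stopifnot_scalar(radius, "radius", positive = TRUE)
  stopifnot_scalar(delta_chi, "delta_chi")
  if (kind == "hemorrhage" && delta_chi <= 0)
    stop("hemorrhage sources must have delta_chi > 0 (paramagnetic)", call. = FALSE)
  if (kind == "calcification" && delta_chi >= 0)
    stop("calcification sources must have delta_chi < 0 (diamagnetic)", call. = FALSE)
  if (magnitude_attenuation < 0 || magnitude_attenuation > 1)
    stop("`magnitude_attenuation` must be in [0, 1]", call. = FALSE)
  structure(
    list(center = as.numeric(center), radius = radius, delta_chi = delta_chi,
         kind = kind, magnitude_attenuation = magnitude_attenuation),
    class = "susceptibility_source"
  )
}

#' Declare a gradient-echo phantom
#'
#' Collects the grid geometry, acquisition parameters, background-phase
#' polynomial, noise level and susceptibility sources that define one
#' synthetic acquisition. Acquisition defaults follow a 3 T prostate SWI
#' protocol (TE 12 ms, 3 mm slices); the default grid is a desk-scale
#' 96 x 96 x 32 at 1 x 1 x 3 mm rather than a full acquisition matrix.
#'
#' `handedness` fixes the sign convention linking a positive field shift to
#' phase at the echo: `"left"` means phase = -gamma * dB * TE, so paramagnetic
#' sources acquire negative local phase.
#'
#' @param grid_shape integer length-3, all >= 16. Third axis is the slice
#'   (main-field) axis.
#' @param voxel_size mm per axis, length 3.
#' @param b0 main field strength in tesla.
#' @param te echo time in ms.
#' @param handedness `"left"` or `"right"` phase sign convention.
#' @param background_phase_coeffs named numeric vector of polynomial
#'   coefficients (radians) over normalised coordinates in \[-1, 1\]; allowed
#'   names: `1, x, y, z, xx, yy, zz, xy, xz, yz`.
#' @param noise_sd standard deviation of the Gaussian noise added to each
#'   complex channel, relative to unit tissue magnitude.
#' @param sources list of [susceptibility_source()] objects.
#' @param seed integer seed for the noise stream.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 32L),
                         voxel_size = c(1, 1, 3),
                         b0 = 3.0, te = 12,
                         handedness = c("left", "right"),
                         background_phase_coeffs = c(x = 0.4, y = -0.3,
                                                     xx = 0.8, yy = 0.6),
                         noise_sd = 0.05,
                         sources = list(),
                         seed = 1L) {
  handedness <- match.arg(handedness)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("`grid_shape` must be 3 integers, all >= 16", call. = FALSE)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive lengths (mm)", call. = FALSE)
  stopifnot_scalar(b0, "b0", positive = TRUE)
  stopifnot_scalar(te, "te", positive = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  allowed <- c("1", "x", "y", "z", "xx", "yy", "zz", "xy", "xz", "yz")
  if (length(background_phase_coeffs) &&
      (is.null(names(background_phase_coeffs)) ||
       !all(names(background_phase_coeffs) %in% allowed)))
    stop("background_phase_coeffs names must be among: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  for (s in sources) {
    if (!inherits(s, "susceptibility_source"))
      stop("all `sources` must be susceptibility_source objects", call. = FALSE)
    if (any(s$center < 1) || any(s$center > grid_shape))
      stop("source centred at (", paste(signif(s$center, 4), collapse = ", "),
           ") lies outside the grid", call. = FALSE)
  }
  structure(
    list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
         b0 = b0, te = te, handedness = handedness,
         background_phase_coeffs = background_phase_coeffs,
         noise_sd = noise_sd, sources = sources, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Rasterise phantom sources into a susceptibility map with ground truth
#'
#' Each source writes its `delta_chi` into every voxel whose centre lies
#' within `radius` mm of the source centre; background susceptibility is 0.
#' Overlapping sources are an error (truth labels would be ambiguous).
#'
#' @param spec a [phantom_spec()].
#' @return a list with
#'   \describe{
#'     \item{chi}{3D array of susceptibility in ppm,}
#'     \item{truth}{a `ground_truth` list with `label_volume` (integer array,
#'       0 background / 1 hemorrhage / 2 calcification), `source_id_volume`
#'       (0 = background), and `source_table` (data.frame: id, kind, cx, cy,
#'       cz, radius_mm, delta_chi, magnitude_attenuation).}
#'   }
#' @export
build_susceptibility_map <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  chi <- array(0, dims)
  labels <- array(0L, dims)
  ids <- array(0L, dims)
  kind_code <- c(hemorrhage = 1L, calcification = 2L)
  n <- length(spec$sources)
  tab <- data.frame(
    id = integer(0), kind = character(0), cx = numeric(0), cy = numeric(0),
    cz = numeric(0), radius_mm = numeric(0), delta_chi = numeric(0),
    magnitude_attenuation = numeric(0)
  )
  for (i in seq_len(n)) {
    s <- spec$sources[[i]]
    inside <- sphere_voxels(dims, spec$voxel_size, s$center, s$radius)
    clash <- ids[inside] != 0L
    if (any(clash)) {
      other <- ids[inside][clash][1L]
      stop(sprintf("sources %d and %d overlap; overlap semantics are undefined",
                   other, i), call. = FALSE)
    }
    chi[inside] <- s$delta_chi
    labels[inside] <- kind_code[[s$kind]]
    ids[inside] <- i
    tab <- rbind(tab, data.frame(
      id = i, kind = s$kind, cx = s$center[1], cy = s$center[2],
      cz = s$center[3], radius_mm = s$radius, delta_chi = s$delta_chi,
      magnitude_attenuation = s$magnitude_attenuation
    ))
  }
  truth <- structure(
    list(label_volume = labels, source_id_volume = ids, source_table = tab),
    class = "ground_truth"
  )
  list(chi = chi, truth = truth)
}

# Logical array: voxel centres within radius (mm) of a centre given in
# continuous 1-based voxel coordinates.
sphere_voxels <- function(dims, voxel_size, center, radius) {
  dx2 <- ((seq_len(dims[1]) - center[1]) * voxel_size[1])^2
  dy2 <- ((seq_len(dims[2]) - center[2]) * voxel_size[2])^2
  dz2 <- ((seq_len(dims[3]) - center[3]) * voxel_size[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  array(d2 <= radius^2, dims)
}

#' Susceptibility-to-field forward model (k-space dipole kernel)
#'
#' Computes the fractional field perturbation dB/B0 (in ppm, same unit as
#' the input) induced by a susceptibility distribution, using the
#' Lorentz-sphere-corrected dipole kernel
#' `D(k) = 1/3 - kz^2 / |k|^2`, with `D(0) := 0` so the mean field shift over
#' the volume is exactly zero. The third array axis is the main-field (z)
#' axis. Periodic boundary conditions are implied by the DFT.
#'
#' @param chi 3D array of susceptibility (ppm).
#' @param voxel_size mm per axis, length 3 (anisotropic voxels supported).
#' @return real 3D array, fractional field shift in ppm.
#' @export
dipole_field <- function(chi, voxel_size = c(1, 1, 1)) {
  if (!is.array(chi) || length(dim(chi)) != 3L)
    stop("`chi` must be a 3D array", call. = FALSE)
  if (!all(is.finite(chi)))
    stop("`chi` contains non-finite values", call. = FALSE)
  dims <- dim(chi)
  kx <- fft_freq(dims[1], voxel_size[1])
  ky <- fft_freq(dims[2], voxel_size[2])
  kz <- fft_freq(dims[3], voxel_size[3])
  k2 <- outer(outer(kx^2, ky^2, `+`), kz^2, `+`)
  kz2 <- outer(array(0, dims[1:2]) + 0,  kz^2, `+`)  # broadcast kz^2 over x,y
  dim(kz2) <- dims
  D <- 1 / 3 - kz2 / k2
  D[k2 == 0] <- 0
  Re(fft(fft(chi) * D, inverse = TRUE)) / prod(dims)
}

# Evaluate the background polynomial on normalised [-1,1]^3 coordinates.
background_phase_field <- function(coeffs, dims) {
  out <- array(0, dims)
  if (!length(coeffs)) return(out)
  norm_coord <- function(n) if (n == 1L) 0 else 2 * (seq_len(n) - 1) / (n - 1) - 1
  x <- norm_coord(dims[1]); y <- norm_coord(dims[2]); z <- norm_coord(dims[3])
  ones <- function(n) rep(1, n)
  term <- function(fx, fy, fz)
    outer(outer(fx, fy, `*`), fz, `*`)
  basis <- list(
    "1"  = term(ones(dims[1]), ones(dims[2]), ones(dims[3])),
    "x"  = term(x, ones(dims[2]), ones(dims[3])),
    "y"  = term(ones(dims[1]), y, ones(dims[3])),
    "z"  = term(ones(dims[1]), ones(dims[2]), z),
    "xx" = term(x^2, ones(dims[2]), ones(dims[3])),
    "yy" = term(ones(dims[1]), y^2, ones(dims[3])),
    "zz" = term(ones(dims[1]), ones(dims[2]), z^2),
    "xy" = term(x, y, ones(dims[3])),
    "xz" = term(x, ones(dims[2]), z),
    "yz" = term(ones(dims[1]), y, z)
  )
  for (nm in names(coeffs)) out <- out + coeffs[[nm]] * basis[[nm]]
  out
}

#' Synthesise a complex gradient-echo volume from a field map
#'
#' Applies the single-compartment static-dephasing signal model: local phase
#' accrues as `s * gamma * B0 * dB/B0 * TE` (s = -1 for left handedness,
#' +1 for right), a smooth polynomial background phase is added, magnitude is
#' 1 in tissue and attenuated inside each source, independent Gaussian noise
#' of sd `noise_sd` is added to the real and imaginary channels, and
#' magnitude/phase are re-extracted (Rician magnitude noise). Phase is
#' wrapped to (-pi, pi].
#'
#' @param field_shift fractional field map in ppm, as from [dipole_field()].
#' @param truth ground truth from [build_susceptibility_map()].
#' @param spec the [phantom_spec()] that produced both.
#' @return an object of class `complex_gre_volume`: list with `magnitude`,
#'   `phase` (radians, (-pi, pi]), `te`, `b0`, `handedness`, `voxel_size`.
#' @export
synthesize_complex_image <- function(field_shift, truth, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!identical(dim(field_shift), as.integer(spec$grid_shape)) &&
      !identical(dim(field_shift), spec$grid_shape))
    stop("`field_shift` grid does not match the phantom grid", call. = FALSE)
  s <- if (spec$handedness == "left") -1 else 1
  phase <- s * GAMMA_RAD_PER_S_PER_T * spec$b0 * (field_shift * 1e-6) *
    (spec$te * 1e-3) +
    background_phase_field(spec$background_phase_coeffs, spec$grid_shape)
  magnitude <- array(1, spec$grid_shape)
  for (i in seq_len(nrow(truth$source_table))) {
    inside <- truth$source_id_volume == truth$source_table$id[i]
    magnitude[inside] <- magnitude[inside] *
      truth$source_table$magnitude_attenuation[i]
  }
  cplx <- magnitude * exp(1i * phase)
  if (spec$noise_sd > 0) {
    n <- length(cplx)
    noise <- with_seed(spec$seed, {
      complex(real = stats::rnorm(n, sd = spec$noise_sd),
              imaginary = stats::rnorm(n, sd = spec$noise_sd))
    })
    cplx <- cplx + array(noise, spec$grid_shape)
  }
  complex_gre_volume(
    magnitude = array(Mod(cplx), spec$grid_shape),
    phase = array(wrap_phase(Arg(cplx)), spec$grid_shape),
    te = spec$te, b0 = spec$b0, handedness = spec$handedness,
    voxel_size = spec$voxel_size
  )
}

#' Run the full phantom synthesis chain
#'
#' Convenience wrapper: susceptibility map, dipole forward model, complex
#' signal synthesis.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a `complex_gre_volume`), `chi`, `field` and
#'   `truth`.
#' @export
simulate_phantom <- function(spec) {
  m <- build_susceptibility_map(spec)
  field <- dipole_field(m$chi, spec$voxel_size)
  vol <- synthesize_complex_image(field, m$truth, spec)
  list(volume = vol, chi = m$chi, field = field, truth = m$truth)
}

#' Simulate a patient cohort with per-modality lesion detection flags
#'
#' Emulates the structure of a two-arm prostate cohort (cancer vs benign
#' prostatic hyperplasia, BPH): each patient may carry a hemorrhagic and/or a
#' calcified lesion, drawn per-arm from `prevalence`, and each lesion present
#' is detected by each modality independently with the probability in
#' `detect_probs`. Defaults reproduce the rates of the study cohort this
#' package models: hemorrhage prevalence 19/23 (cancer) vs 1/53 (BPH) with
#' perfect SWI detection, conventional-MRI hemorrhage sensitivity 7/19;
#' calcification prevalence 5/23 vs 17/53 with CT as a perfect gold standard,
#' perfect SWI detection and conventional-MRI sensitivity 3/22.
#'
#' @param n_cancer,n_bph patient counts per arm.
#' @param detect_probs named list with elements `hemorrhage` and
#'   `calcification`, each a named probability vector over modalities
#'   `c(swi=, conv_mri=, ct=)`.
#' @param prevalence named list, same shape, with per-arm lesion prevalences
#'   `c(cancer=, bph=)`.
#' @param seed integer seed.
#' @return data.frame in long format: `patient_id`, `disease`, `lesion_kind`,
#'   `present`, `swi_detected`, `conv_mri_detected`, `ct_detected` (one row
#'   per patient per lesion kind).
#' @export
simulate_cohort <- function(n_cancer = 23L, n_bph = 53L,
                            detect_probs = list(
                              hemorrhage = c(swi = 1, conv_mri = 7 / 19, ct = 0),
                              calcification = c(swi = 1, conv_mri = 3 / 22, ct = 1)
                            ),
                            prevalence = list(
                              hemorrhage = c(cancer = 19 / 23, bph = 1 / 53),
                              calcification = c(cancer = 5 / 23, bph = 17 / 53)
                            ),
                            seed = 1L) {
  stopifnot(n_cancer >= 0, n_bph >= 0)
  for (k in c("hemorrhage", "calcification")) {
    p <- detect_probs[[k]]
    if (is.null(p) || any(p < 0) || any(p > 1))
      stop("detect_probs$", k, " must be probabilities in [0, 1]", call. = FALSE)
    q <- prevalence[[k]]
    if (is.null(q) || any(q < 0) || any(q > 1))
      stop("prevalence$", k, " must be probabilities in [0, 1]", call. = FALSE)
  }
  n <- n_cancer + n_bph
  disease <- rep(c("cancer", "bph"), c(n_cancer, n_bph))
  with_seed(seed, {
    rows <- lapply(c("hemorrhage", "calcification"), function(kind) {
      prev <- unname(prevalence[[kind]][disease])
      present <- stats::runif(n) < prev
      det <- vapply(c("swi", "conv_mri", "ct"), function(mod) {
        present & (stats::runif(n) < detect_probs[[kind]][[mod]])
      }, logical(n))
      data.frame(
        patient_id = seq_len(n), disease = disease, lesion_kind = kind,
        present = present,
        swi_detected = det[, 1], conv_mri_detected = det[, 2],
        ct_detected = det[, 3]
      )
    })
    out <- do.call(rbind, rows)
    out[order(out$patient_id, out$lesion_kind), , drop = FALSE]
  })
}

#' Random multi-source phantom specification
#'
#' Places non-overlapping spherical sources uniformly at random (rejection
#' sampling with a 2 mm clearance between spheres and a margin from the grid
#' boundary), drawing radius and |delta_chi| uniformly from the given ranges.
#' Hemorrhages get positive, calcifications negative susceptibility. The
#' default susceptibility and size ranges (0.2-1 ppm, 2-6 mm) are plausible
#' placeholders for prostatic lesions, not literature-calibrated values.
#'
#' @param n_hemorrhage,n_calcification source counts.
#' @param delta_chi_range range of |delta_chi| in ppm.
#' @param radius_range range of radii in mm.
#' @param seed integer seed (also used for the noise stream).
#' @param ... further arguments to [phantom_spec()].
#' @return a [phantom_spec()].
#' @export
random_phantom_spec <- function(n_hemorrhage = 10L, n_calcification = 10L,
                                delta_chi_range = c(0.2, 1),
                                radius_range = c(2, 6),
                                seed = 1L, ...) {
  base <- phantom_spec(seed = seed, ...)
  n <- n_hemorrhage + n_calcification
  kinds <- rep(c("hemorrhage", "calcification"),
               c(n_hemorrhage, n_calcification))
  sources <- with_seed(seed, {
    placed <- list()
    attempts <- 0L
    while (length(placed) < n) {
      attempts <- attempts + 1L
      if (attempts > 10000L)
        stop("could not place ", n, " non-overlapping sources; ",
             "reduce counts or radii", call. = FALSE)
      r <- stats::runif(1, radius_range[1], radius_range[2])
      margin <- (r + 2) / base$voxel_size  # stay clear of the boundary
      ctr <- 1 + margin + stats::runif(3) * (base$grid_shape - 1 - 2 * margin)
      ok <- TRUE
      for (p in placed) {
        gap <- sqrt(sum(((ctr - p$center) * base$voxel_size)^2))
        if (gap < r + p$radius + 2) { ok <- FALSE; break }
      }
      if (!ok) next
      k <- kinds[length(placed) + 1L]
      dchi <- stats::runif(1, delta_chi_range[1], delta_chi_range[2])
      placed[[length(placed) + 1L]] <- susceptibility_source(
        center = ctr, radius = r,
        delta_chi = if (k == "hemorrhage") dchi else -dchi, kind = k)
    }
    placed
  })
  base$sources <- sources
  base
}

# -- complex_gre_volume -------------------------------------------------------

#' Construct a complex gradient-echo volume
#'
#' Paired magnitude and wrapped-phase grids plus the acquisition metadata the
#' reconstruction needs.
#'
#' @param magnitude nonnegative 3D array.
#' @param phase 3D array in radians; values are validated to lie in
#'   (-pi, pi].
#' @param te echo time, ms.
#' @param b0 field strength, tesla.
#' @param handedness `"left"` or `"right"`.
#' @param voxel_size mm per axis.
#' @return object of class `complex_gre_volume`.
#' @export
complex_gre_volume <- function(magnitude, phase, te = 12, b0 = 3,
                               handedness = c("left", "right"),
                               voxel_size = c(1, 1, 3)) {
  handedness <- match.arg(handedness)
  if (!is.array(magnitude) || !is.array(phase) ||
      !identical(dim(magnitude), dim(phase)))
    stop("`magnitude` and `phase` must be congruent 3D arrays (shapes ",
         paste(dim(magnitude), collapse = "x"), " vs ",
         paste(dim(phase), collapse = "x"), ")", call. = FALSE)
  if (length(dim(magnitude)) != 3L)
    stop("volumes must be 3D", call. = FALSE)
  if (any(magnitude < 0)) stop("`magnitude` must be >= 0", call. = FALSE)
  if (any(phase <= -pi - 1e-12) || any(phase > pi + 1e-12))
    stop("`phase` must be wrapped to (-pi, pi]", call. = FALSE)
  structure(
    list(magnitude = magnitude, phase = phase, te = te, b0 = b0,
         handedness = handedness, voxel_size = as.numeric(voxel_size)),
    class = "complex_gre_volume"
  )
}

#' @export
print.complex_gre_volume <- function(x, ...) {
  cat(sprintf("complex_gre_volume %s | TE %g ms, B0 %g T, %s-handed, voxels %s mm\n",
              paste(dim(x$magnitude), collapse = "x"), x$te, x$b0,
              x$handedness, paste(x$voxel_size, collapse = "x")))
  invisible(x)
}
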