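# Shared fixture builders. Everything is generated in code at test time.

# Small noiseless two-source phantom: one paramagnetic, one diamagnetic.
two_source_spec <- function(noise_sd = 0, handedness = "left", seed = 7L) {
  phantom_spec(
    grid_shape = c(96L, 96L, 32L), voxel_size = c(1, 1, 3),
    handedness = handedness, noise_sd = noise_sd, seed = seed,
    sources = list(
      susceptibility_source(c(30, 48, 16), 4, +0.5, "hemorrhage"),
      susceptibility_source(c(66, 48, 16), 4, -0.5, "calcification")
    )
  )
}

# Brute-force voxel-by-voxel sphere membership, independent of
# sphere_voxels()/build_susceptibility_map() internals.
brute_count_inside <- function(dims, voxel_size, center, radius) {
  n <- 0L
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      d2 <- sum((((c(i, j, k)) - center) * voxel_size)^2)
      if (d2 <= radius^2) n <- n + 1L
    }
  n
}

# Plain DFT-matrix homodyne filter for one slice: an fft()-free oracle for
# the high-pass phase filter (small slices only).
homodyne_oracle_slice <- function(mag, phase, filter_size, window = "hann") {
  n1 <- nrow(mag); n2 <- ncol(mag)
  dft <- function(n) {
    j <- seq_len(n) - 1
    exp(-2i * pi * outer(j, j) / n)
  }
  F1 <- dft(n1); F2 <- dft(n2)
  cx <- mag * exp(1i * phase)
  K <- F1 %*% cx %*% F2
  w1 <- swiprost:::kspace_window_1d(n1, filter_size[1], window)
  w2 <- swiprost:::kspace_window_1d(n2, filter_size[2], window)
  lp <- (Conj(F1) %*% (K * outer(w1, w2)) %*% Conj(F2)) / (n1 * n2)
  wrap_phase(Arg(cx) - Arg(lp))
}

# Exact two-sided Fisher p by explicit enumeration with factorial() on exact
# integer ratios (independent of lchoose and of stats::fisher.test).
fisher_enum_oracle <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  pt <- function(x) {
    # hypergeometric point probability via prod of ratios (stable at n ~ 100)
    exp(sum(log(seq_len(r1))) + sum(log(seq_len(r2))) +
        sum(log(seq_len(c1))) + sum(log(seq_len(n - c1))) -
        sum(log(seq_len(n))) - sum(log(seq_len(x))) -
        sum(log(seq_len(r1 - x))) - sum(log(seq_len(c1 - x))) -
        sum(log(seq_len(r2 - c1 + x))))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, pt, numeric(1))
  p_obs <- pt(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
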