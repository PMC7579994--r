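# Small, fast phantom spec for unit tests; override any field via `...`.
small_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(shape = c(64, 48, 48), spacing_mm = 0.5, gap_mm = 2,
         posterior_gap_mm = 4, noise_sd = 0, seed = seed),
    list(...))
  do.call(phantom_spec, args)
}

# Tiny uniform voxel volume for arithmetic checks.
uniform_volume <- function(hu, dims = c(5, 5, 4), spacing = 1) {
  voxel_volume(array(hu, dim = dims), spacing)
}

# Independent point-in-finite-cylinder test used as a brute-force oracle:
# written from the parametric segment definition, not the package's
# separable-projection code path.
oracle_in_cylinder <- function(p, start, end, radius) {
  d <- end - start
  len <- sqrt(sum(d^2))
  u <- d / len
  v <- p - start
  t <- sum(v * u)
  perp <- v - t * u
  t >= 0 && t <= len && sqrt(sum(perp^2)) <= radius + 1e-9
}

# Brute-force closest distance between two point sets, one loop at a time.
oracle_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d <- sqrt(colSums((t(b) - a[i, ])^2))
    best <- min(best, min(d))
  }
  best
}
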