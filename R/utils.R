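#' @keywords internal
"_PACKAGE"

# Run code with a fixed RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Shift a logical 3D array by one voxel along `axis` in direction `dir`
# (+1 or -1); cells shifted in from outside the grid are FALSE.
shift_logical <- function(a, axis, dir) {
  d <- dim(a)
  out <- array(FALSE, dim = d)
  idx_src <- idx_dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  n <- d[axis]
  if (n == 1L) return(out)
  if (dir > 0) {
    idx_dst[[axis]] <- 2:n
    idx_src[[axis]] <- 1:(n - 1L)
  } else {
    idx_dst[[axis]] <- 1:(n - 1L)
    idx_src[[axis]] <- 2:n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# 6-connectivity erosion: TRUE where the voxel and all face neighbours are
# TRUE; grid border counts as outside.
erode6 <- function(mask, n = 1L) {
  out <- mask
  for (i in seq_len(n)) {
    nb <- out
    for (axis in 1:3) {
      nb <- nb & shift_logical(out, axis, +1L) & shift_logical(out, axis, -1L)
    }
    out <- nb
  }
  out
}

# Boundary voxels under 6-connectivity: in the mask with >= 1 face
# neighbour outside it (the grid border is outside).
boundary6 <- function(mask) {
  mask & !erode6(mask, 1L)
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("%s must be finite", what), call. = FALSE)
  }
  invisible(x)
}
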