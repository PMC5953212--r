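# internal helpers

dim3 <- function(grid) grid@dims

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-300) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# linear index <-> (i,j,k) on a grid
ijkToLinear <- function(grid, ijk) {
  d <- grid@dims
  as.integer(ijk[, 1] + (ijk[, 2] - 1L) * d[1] + (ijk[, 3] - 1L) * d[1] * d[2])
}

linearToIjk <- function(grid, idx) {
  d <- grid@dims
  idx0 <- idx - 1L
  i <- idx0 %% d[1]
  j <- (idx0 %/% d[1]) %% d[2]
  k <- idx0 %/% (d[1] * d[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

# Shift-and-combine binary dilation: voxel k is set iff mask is set at
# k - offset for some integer offset row. Offsets in voxel index units.
dilateByOffsets <- function(mask, offsets) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (r in seq_len(nrow(offsets))) {
    di <- offsets[r, 1]; dj <- offsets[r, 2]; dk <- offsets[r, 3]
    xlo <- max(1L, 1L + di); xhi <- min(d[1], d[1] + di)
    ylo <- max(1L, 1L + dj); yhi <- min(d[2], d[2] + dj)
    zlo <- max(1L, 1L + dk); zhi <- min(d[3], d[3] + dk)
    if (xlo > xhi || ylo > yhi || zlo > zhi) next
    xs <- xlo:xhi; ys <- ylo:yhi; zs <- zlo:zhi
    out[xs, ys, zs] <- out[xs, ys, zs] | mask[xs - di, ys - dj, zs - dk]
  }
  out
}

fmtNum <- function(x, digits = 4) format(round(x, digits), trim = TRUE)
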