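## Internal helpers shared across modules: frame-stack coercion, quaternion
## algebra and the icosahedron vertex set used by the blob-shell model.

## Coerce a frame stack (3-D array, list of matrices, list of RawFrame /
## PhotonFrame objects, or a single matrix) to a 3-D array [row, col, frame].
.stackArray <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 3L) return(frames)
  if (is.matrix(frames)) return(array(frames, dim = c(dim(frames), 1L)))
  if (is.list(frames)) {
    mats <- lapply(frames, function(f) {
      if (is.matrix(f)) f
      else if (is(f, "RawFrame")) f@data
      else if (is(f, "CalibratedFrame")) f@data
      else if (is(f, "PhotonFrame")) f@counts
      else stop("cannot interpret stack element of class ", class(f)[1L])
    })
    d <- dim(mats[[1L]])
    if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1L))))
      stop("frames in a stack must share a common shape")
    return(array(unlist(mats, use.names = FALSE), dim = c(d, length(mats))))
  }
  stop("cannot interpret object of class ", class(frames)[1L], " as a frame stack")
}

## Deterministic per-frame RNG substream: frames are reproducible given the
## run seed and independent of simulation order.  Kept below 2^31 - 1.
.frameSeed <- function(seed, index) {
  s <- (abs(as.double(seed)) * 48271 + as.double(index) * 1664525 + 12345) %%
    2147483629
  as.integer(s)
}

## Uniform random unit quaternions (rows), via normalized 4-D Gaussians.
randomQuaternion <- function(n = 1L) {
  q <- matrix(rnorm(4L * n), nrow = n)
  q <- q / sqrt(rowSums(q^2))
  ## canonical sign: first component non-negative
  flip <- q[, 1L] < 0
  q[flip, ] <- -q[flip, ]
  q
}

## Rotation matrix from a unit quaternion (w, x, y, z).
quatToMat <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

## Quaternion for a rotation of `angle` radians about `axis`.
axisAngleQuat <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

## The 12 vertices of a regular icosahedron, unit circumradius, rows.
icosahedronVertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0,  1,  phi), c(0, -1,  phi), c(0,  1, -phi), c(0, -1, -phi),
    c( 1,  phi, 0), c(-1,  phi, 0), c( 1, -phi, 0), c(-1, -phi, 0),
    c( phi, 0,  1), c( phi, 0, -1), c(-phi, 0,  1), c(-phi, 0, -1)
  )
  v / sqrt(1 + phi^2)
}
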