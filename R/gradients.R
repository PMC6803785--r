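#' Diffusion gradient tables
#'
#' A gradient table pairs each volume of a DWI acquisition with its
#' diffusion weighting `b` (s/mm^2) and unit gradient direction. Volumes
#' with `b = 0` carry the zero vector.
#'
#' @param bvals Numeric vector of b-values, one per volume (s/mm^2).
#' @param bvecs Numeric 3 x n matrix of gradient directions (columns are
#'   volumes). Directions for `b > 0` volumes must have unit Euclidean norm;
#'   `b = 0` volumes must carry the zero vector.
#' @return An object of class `gradient_table`: a list with elements
#'   `bvals` and `bvecs`.
#' @seealso [make_gradient_table()]
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L)
    stop("bvecs must be a 3 x n matrix (rows x/y/z)")
  if (length(bvals) != ncol(bvecs))
    stop("bvals and bvecs describe different numbers of volumes")
  if (!any(bvals == 0))
    stop("gradient table must contain at least one b=0 entry")
  dimnames(bvecs) <- NULL
  nrm <- sqrt(colSums(bvecs^2))
  nz <- bvals > 0
  if (any(abs(nrm[nz] - 1) > 1e-9))
    stop("nonzero-b directions must have unit norm (tolerance 1e-9)")
  if (any(nrm[!nz] > 1e-9))
    stop("b=0 entries must carry the zero direction vector")
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_table")
}

#' @export
length.gradient_table <- function(x) length(x$bvals)

#' @export
print.gradient_table <- function(x, ...) {
  shells <- sort(unique(x$bvals))
  cat("<gradient_table> ", length(x), " volumes; b = {",
      paste(shells, collapse = ", "), "} s/mm^2; ",
      sum(x$bvals == 0), " b=0\n", sep = "")
  invisible(x)
}

#' Quasi-uniform unit directions on the sphere
#'
#' Deterministic spherical-Fibonacci lattice: point k of n has
#' z = 1 - (2k+1)/n and azimuth k times the golden angle. Near-uniform
#' coverage with no randomness, so the same `n` always yields the same set.
#'
#' @param n Number of directions.
#' @return n x 3 matrix of unit row vectors.
#' @keywords internal
fibonacci_directions <- function(n) {
  k <- seq_len(n) - 1
  z <- 1 - (2 * k + 1) / n
  phi <- k * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Build a single-shell gradient table
#'
#' One `b = 0` baseline volume followed by `n_directions` diffusion-weighted
#' volumes at b-value `b`, with directions placed on a deterministic
#' spherical-Fibonacci lattice. The default mirrors a 128-direction b = 800
#' s/mm^2 acquisition.
#'
#' @param n_directions Number of diffusion-weighted directions (>= 6, the
#'   minimum to determine a symmetric tensor). Note that the 6-point
#'   Fibonacci lattice happens to lie on a common central quadric and
#'   therefore does not itself determine a tensor; use >= 7 directions
#'   when the table will feed a tensor fit.
#' @param b Diffusion weighting of the shell (s/mm^2, > 0).
#' @return A [gradient_table] with `1 + n_directions` entries; entry 1 is
#'   the b = 0 baseline.
#' @examples
#' gt <- make_gradient_table(128, 800)
#' length(gt)       # 129
#' sum(gt$bvals == 800)
#' @export
make_gradient_table <- function(n_directions = 128, b = 800) {
  if (n_directions < 6)
    stop("n_directions must be >= 6: fewer directions leave the tensor underdetermined")
  if (b <= 0) stop("b must be > 0")
  dirs <- fibonacci_directions(n_directions)
  gradient_table(
    bvals = c(0, rep(b, n_directions)),
    bvecs = cbind(c(0, 0, 0), t(dirs))
  )
}

#' Monoexponential tensor forward signal
#'
#' Evaluates the Stejskal-Tanner single-tensor signal
#' `S_i = s0 * exp(-b_i * g_i' D g_i)` for every entry of a gradient table.
#' The b = 0 entries return `s0` exactly.
#'
#' @param s0 Baseline (non-diffusion-weighted) signal, > 0.
#' @param D Symmetric positive semidefinite 3 x 3 diffusion tensor (mm^2/s).
#' @param gradients A [gradient_table].
#' @return Numeric vector of signals, one per gradient-table entry.
#' @examples
#' gt <- make_gradient_table(6, 800)
#' tensor_signal(1000, diag(3) * 1e-3, gt)[1]  # 1000 at b=0
#' @export
tensor_signal <- function(s0, D, gradients) {
  stopifnot(inherits(gradients, "gradient_table"))
  if (s0 <= 0) stop("s0 must be > 0")
  D <- as.matrix(D)
  if (!all(dim(D) == c(3, 3)) || max(abs(D - t(D))) > 1e-12 * max(1, max(abs(D))))
    stop("D must be a symmetric 3 x 3 matrix")
  g <- gradients$bvecs
  q <- colSums(g * (D %*% g))   # g_i' D g_i per volume
  s0 * exp(-gradients$bvals * q)
}

#' Design matrix of the log-linear tensor model
#'
#' Row i is `(1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz)`
#' so that `X %*% c(ln s0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) = ln S`.
#'
#' @keywords internal
tensor_design_matrix <- function(gradients) {
  b <- gradients$bvals
  g <- t(gradients$bvecs)
  cbind(
    1,
    -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
    -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
    -2 * b * g[, 2] * g[, 3]
  )
}

#' Expand a packed 6-vector (xx, yy, zz, xy, xz, yz) to a 3 x 3 tensor
#' @keywords internal
tensor_from_vec6 <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

#' Pack a symmetric 3 x 3 tensor as (xx, yy, zz, xy, xz, yz)
#' @keywords internal
vec6_from_tensor <- function(D) {
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}
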