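#' Deterministic tracking parameters
#'
#' Step size, curvature bound, FA termination threshold and length limits
#' for single-tensor streamline tracking. The curvature bound is enforced
#' per step as a maximum turning angle `2 * asin(step / (2 * R))`, the
#' exact discrete analogue of a circular arc of radius `R`. The published
#' 0.15 termination cutoff is an FOD-amplitude threshold; for a
#' single-tensor tracker the natural analogue is an FA threshold, which is
#' what `termination_cutoff` means here.
#'
#' @param step Step size in mm (default 0.1).
#' @param min_curvature_radius Minimum radius of curvature in mm
#'   (default 1).
#' @param termination_cutoff FA below which tracking stops (default 0.15).
#' @param min_length Minimum streamline length in mm (default 5).
#' @param max_length Maximum streamline length in mm (default 250).
#' @return An object of class `tracking_params`.
#' @export
tracking_params <- function(step = 0.1, min_curvature_radius = 1,
                            termination_cutoff = 0.15,
                            min_length = 5, max_length = 250) {
  vals <- c(step, min_curvature_radius, termination_cutoff,
            min_length, max_length)
  if (any(vals <= 0)) stop("all tracking parameters must be > 0")
  if (min_length >= max_length) stop("min_length must be < max_length")
  structure(list(step = step, min_curvature_radius = min_curvature_radius,
                 termination_cutoff = termination_cutoff,
                 min_length = min_length, max_length = max_length,
                 max_angle = 2 * asin(min(1, step / (2 * min_curvature_radius)))),
            class = "tracking_params")
}

#' Seed points from a mask
#'
#' `per_voxel` points per mask voxel, uniformly jittered inside each voxel
#' (or at voxel centers with `jitter = FALSE`); deterministic for a given
#' seed.
#'
#' @param mask Logical 3D mask.
#' @param per_voxel Seeds per voxel (>= 1).
#' @param seed Integer RNG seed.
#' @param voxel_size Voxel size in mm.
#' @param jitter If `FALSE`, place seeds at voxel centers.
#' @return n x 3 matrix of seed coordinates in mm.
#' @export
seed_points <- function(mask, per_voxel = 1, seed = 1, voxel_size = 1,
                        jitter = TRUE) {
  if (per_voxel < 1) stop("per_voxel must be >= 1")
  idx <- which(as.logical(mask))
  if (!length(idx)) stop("empty seed region")
  centers <- (arrayInd(idx, dim(mask)) - 1) * voxel_size
  pts <- centers[rep(seq_len(nrow(centers)), each = per_voxel), , drop = FALSE]
  if (jitter) {
    off <- with_seed(seed,
      matrix(stats::runif(length(pts), -0.5, 0.5) * voxel_size, ncol = 3))
    pts <- pts + off
  }
  unname(pts)
}

# Trilinear interpolation of a (prod(gs) x k) flattened field at point
# p (mm). Returns NULL outside the grid or touching an invalid voxel.
interp_field <- function(flat, gs, voxel_size, p) {
  cvox <- p / voxel_size                # continuous 0-based voxel coords
  i0 <- floor(cvox)
  if (any(i0 < 0) || any(i0 > gs - 2 + 1e-9)) {
    # allow points in the outer half-voxel by clamping the cell
    i0 <- pmin(pmax(i0, 0), gs - 2)
    if (any(cvox < -0.5) || any(cvox > gs - 0.5)) return(NULL)
  }
  f <- pmin(pmax(cvox - i0, 0), 1)
  w <- c((1 - f[1]) * (1 - f[2]) * (1 - f[3]),
         f[1] * (1 - f[2]) * (1 - f[3]),
         (1 - f[1]) * f[2] * (1 - f[3]),
         f[1] * f[2] * (1 - f[3]),
         (1 - f[1]) * (1 - f[2]) * f[3],
         f[1] * (1 - f[2]) * f[3],
         (1 - f[1]) * f[2] * f[3],
         f[1] * f[2] * f[3])
  corner <- cbind(c(0, 1, 0, 1, 0, 1, 0, 1),
                  c(0, 0, 1, 1, 0, 0, 1, 1),
                  c(0, 0, 0, 0, 1, 1, 1, 1))
  lin <- (i0[1] + corner[, 1] + 1) +
    gs[1] * (i0[2] + corner[, 2]) +
    gs[1] * gs[2] * (i0[3] + corner[, 3])
  vals <- flat[lin, , drop = FALSE]
  if (anyNA(vals)) {
    keep <- rowSums(is.na(vals)) == 0
    if (!any(keep)) return(NULL)
    w <- w[keep] / sum(w[keep])
    vals <- vals[keep, , drop = FALSE]
  }
  drop(crossprod(vals, w))
}

#' Single-tensor deterministic streamline tracking
#'
#' From each seed, integrates bidirectionally along the principal
#' eigenvector of the trilinearly interpolated tensor (the six unique
#' elements are interpolated component-wise, then eigen-decomposed; the
#' direction sign is aligned with the previous step). A streamline
#' terminates when the interpolated FA falls below the cutoff, the point
#' leaves the grid, the length reaches `max_length`, or the turning angle
#' exceeds the curvature bound. Streamlines shorter than `min_length` are
#' discarded.
#'
#' @param seeds n x 3 matrix of seed points in mm ([seed_points()]).
#' @param field A `tensor_field` from [fit_tensor_loglinear()].
#' @param fa An FA [scalar_map] aligned with `field` (defaults to the FA
#'   of `field`).
#' @param params A [tracking_params] object.
#' @return An object of class `streamlines`: list with `points` (list of
#'   m x 3 matrices in mm), `seed_index` (originating seed row), and
#'   `params`.
#' @export
track <- function(seeds, field, fa = NULL, params = tracking_params()) {
  stopifnot(inherits(field, "tensor_field"),
            inherits(params, "tracking_params"))
  if (is.null(fa)) fa <- eigen_metrics(field)$FA
  gs <- dim(field$valid)
  if (!all(dim(fa) == gs)) stop("FA map geometry does not match the field")
  seeds <- matrix(seeds, ncol = 3)
  vs <- field$voxel_size
  tflat <- array(field$tensors, c(prod(gs), 6))
  faflat <- matrix(as.numeric(fa), ncol = 1)

  fa_at <- function(p) {
    v <- interp_field(faflat, gs, vs, p)
    if (is.null(v)) NA_real_ else v
  }
  dir_at <- function(p) {
    tv <- interp_field(tflat, gs, vs, p)
    if (is.null(tv)) return(NULL)
    eigen(tensor_from_vec6(tv), symmetric = TRUE)$vectors[, 1]
  }

  max_steps <- ceiling(params$max_length / params$step)
  cos_bound <- cos(params$max_angle)

  walk <- function(p0, v0) {
    pts <- matrix(NA_real_, max_steps + 1L, 3)
    pts[1, ] <- p0
    v <- v0
    n <- 1L
    while (n <= max_steps) {
      u <- dir_at(pts[n, ])
      if (is.null(u)) break
      if (sum(u * v) < 0) u <- -u
      if (n > 1L && sum(u * v) < cos_bound) break   # curvature bound
      pnext <- pts[n, ] + params$step * u
      fnext <- fa_at(pnext)
      if (is.na(fnext) || fnext < params$termination_cutoff) break
      n <- n + 1L
      pts[n, ] <- pnext
      v <- u
    }
    pts[seq_len(n), , drop = FALSE]
  }

  out_pts <- list(); out_seed <- integer(0)
  for (i in seq_len(nrow(seeds))) {
    p0 <- seeds[i, ]
    f0 <- fa_at(p0)
    if (is.na(f0) || f0 < params$termination_cutoff) next
    v0 <- dir_at(p0)
    if (is.null(v0)) next
    fwd <- walk(p0, v0)
    bwd <- walk(p0, -v0)
    pts <- rbind(bwd[rev(seq_len(nrow(bwd)))[-nrow(bwd)], , drop = FALSE], fwd)
    len <- (nrow(pts) - 1) * params$step
    if (len < params$min_length) next
    out_pts[[length(out_pts) + 1L]] <- pts
    out_seed <- c(out_seed, i)
  }
  structure(list(points = out_pts, seed_index = out_seed, params = params),
            class = "streamlines")
}

#' @export
print.streamlines <- function(x, ...) {
  lens <- vapply(x$points, nrow, integer(1))
  cat("<streamlines> ", length(x$points), " streamlines",
      if (length(lens)) paste0("; length ",
        paste(signif(range((lens - 1) * x$params$step), 4),
              collapse = " .. "), " mm"),
      "\n", sep = "")
  invisible(x)
}

# TRUE for each streamline that has any point inside `mask`.
streamlines_hit <- function(streams, mask, voxel_size) {
  gs <- dim(mask)
  vapply(streams$points, function(pts) {
    vox <- round(pts / voxel_size) + 1
    keep <- vox[, 1] >= 1 & vox[, 1] <= gs[1] &
            vox[, 2] >= 1 & vox[, 2] <= gs[2] &
            vox[, 3] >= 1 & vox[, 3] <= gs[3]
    if (!any(keep)) return(FALSE)
    any(mask[vox[keep, , drop = FALSE]])
  }, logical(1))
}

#' Tract-disruption assay
#'
#' Counts, for pre- and post-treatment streamline sets seeded in a distal
#' region (e.g. the fimbria analogue), how many streamlines reach a far
#' target beyond the lesion and how many enter the lesion core. An intact
#' tract carries streamlines to the target; an ablated core with
#' sub-cutoff FA interrupts them.
#'
#' @param streamlines_pre,streamlines_post `streamlines` objects from
#'   [track()].
#' @param lesion_core Logical mask of the lesion core.
#' @param distal_seed Logical mask of the seeding region (recorded in the
#'   output for provenance).
#' @param far_target Logical mask of the far target region.
#' @param voxel_size Voxel size in mm.
#' @return Data frame with one row per timepoint: `timepoint`,
#'   `n_streamlines`, `n_seed_voxels`, `n_reach_target`, `n_enter_core`.
#' @export
disruption_assay <- function(streamlines_pre, streamlines_post,
                             lesion_core, distal_seed, far_target,
                             voxel_size) {
  if (!all(dim(lesion_core) == dim(far_target)) ||
      !all(dim(lesion_core) == dim(distal_seed)))
    stop("assay masks must share geometry")
  row_for <- function(tp, streams) {
    data.frame(
      timepoint = tp,
      n_streamlines = length(streams$points),
      n_seed_voxels = sum(distal_seed),
      n_reach_target = sum(streamlines_hit(streams, far_target, voxel_size)),
      n_enter_core = if (any(lesion_core))
        sum(streamlines_hit(streams, lesion_core, voxel_size)) else 0L
    )
  }
  rbind(row_for("pre", streamlines_pre), row_for("post", streamlines_post))
}

# ---- streamline file output ----------------------------------------------

#' Write streamlines as whitespace-delimited text
#'
#' One point per line (x y z in mm), one blank line between streamlines.
#'
#' @param streams A `streamlines` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_streamlines_text <- function(streams, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (pts in streams$points) {
    writeLines(apply(pts, 1, function(r)
      paste(format(r, digits = 9, trim = TRUE), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read streamlines from the text format written by
#' [write_streamlines_text()]
#'
#' @param path Input path.
#' @return List of m x 3 point matrices.
#' @export
read_streamlines_text <- function(path) {
  lines <- readLines(path)
  groups <- split(lines, cumsum(lines == ""))
  groups <- lapply(groups, function(g) g[g != ""])
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  lapply(unname(groups), function(g)
    do.call(rbind, lapply(strsplit(trimws(g), "\\s+"), as.numeric)))
}

#' Write streamlines in TrackVis TRK format
#'
#' Version-2 TRK with the grid's voxel size, an identity voxel-to-world
#' rotation, and RAS voxel order. Point coordinates are converted from
#' the package's world mm convention (voxel centers at integer multiples
#' of the voxel size) to TrackVis "voxel-mm" convention (origin at the
#' corner of voxel 0), i.e. shifted by half a voxel.
#'
#' @param streams A `streamlines` object.
#' @param path Output path (.trk).
#' @param grid_shape Integer 3-vector of grid dimensions.
#' @param voxel_size Voxel size in mm.
#' @return Invisibly, `path`.
#' @export
write_trk <- function(streams, path, grid_shape, voxel_size) {
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s, width) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(width - length(raw))), con)
  }
  wchar("TRACK", 6)
  writeBin(as.integer(grid_shape), con, size = 2)            # dim
  writeBin(rep(as.numeric(voxel_size), 3), con, size = 4)    # voxel_size
  writeBin(rep(0, 3), con, size = 4)                         # origin
  writeBin(0L, con, size = 2)                                # n_scalars
  wchar("", 200)                                             # scalar names
  writeBin(0L, con, size = 2)                                # n_properties
  wchar("", 200)                                             # property names
  affine <- diag(c(rep(voxel_size, 3), 1))                   # vox_to_ras
  affine[1:3, 4] <- -voxel_size / 2                          # corner origin
  writeBin(as.numeric(t(affine)), con, size = 4)
  wchar("", 444)                                             # reserved
  wchar("RAS", 4)                                            # voxel_order
  wchar("", 4)                                               # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4)   # orientation
  wchar("", 2)                                               # pad1
  writeBin(rep(as.raw(0), 6), con)                           # invert/swap
  writeBin(length(streams$points), con, size = 4)            # n_count
  writeBin(2L, con, size = 4)                                # version
  writeBin(1000L, con, size = 4)                             # hdr_size
  for (pts in streams$points) {
    writeBin(nrow(pts), con, size = 4)
    vox_mm <- pts + voxel_size / 2
    writeBin(as.numeric(t(vox_mm)), con, size = 4)
  }
  invisible(path)
}

#' Read a TRK file written by [write_trk()]
#'
#' Minimal reader for round-trip checks: parses the header dimensions and
#' voxel size and converts points back to world mm.
#'
#' @param path Input path.
#' @return List with `points` (list of m x 3 matrices, world mm),
#'   `grid_shape`, `voxel_size`.
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 6)[1:5])
  if (magic != "TRACK") stop("not a TRK file")
  dim3 <- readBin(con, "integer", 3, size = 2)
  vs <- readBin(con, "numeric", 3, size = 4)
  seek(con, 988)
  n_count <- readBin(con, "integer", 1, size = 4)
  version <- readBin(con, "integer", 1, size = 4)
  hdr <- readBin(con, "integer", 1, size = 4)
  if (hdr != 1000) stop("unexpected TRK header size")
  pts <- vector("list", n_count)
  for (i in seq_len(n_count)) {
    m <- readBin(con, "integer", 1, size = 4)
    xyz <- matrix(readBin(con, "numeric", 3 * m, size = 4), m, 3,
                  byrow = TRUE)
    pts[[i]] <- xyz - vs[1] / 2
  }
  list(points = pts, grid_shape = dim3, voxel_size = vs[1])
}
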