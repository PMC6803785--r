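# Shift a 3D logical array by one voxel along an axis, zero-filling.
shift3d <- function(mask, axis, by) {
  out <- array(FALSE, dim(mask))
  n <- dim(mask)[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) seq_len(n - by) else seq(1 - by, n)
  dst <- if (by > 0) seq(1 + by, n) else seq_len(n + by)
  ix <- list(seq_len(dim(mask)[1]), seq_len(dim(mask)[2]), seq_len(dim(mask)[3]))
  src_ix <- ix; src_ix[[axis]] <- src
  dst_ix <- ix; dst_ix[[axis]] <- dst
  out[dst_ix[[1]], dst_ix[[2]], dst_ix[[3]]] <-
    mask[src_ix[[1]], src_ix[[2]], src_ix[[3]]]
  out
}

#' One-voxel 6-connected binary dilation
#'
#' Face-adjacent (6-connected) structuring element, one iteration: the
#' discrete analogue of a 1-voxel radial grow at isotropic resolution.
#' Voxels beyond the grid are treated as background.
#'
#' @param mask Logical 3D array.
#' @return Logical 3D array.
#' @export
dilate6 <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  out <- mask
  for (axis in 1:3) {
    out <- out | shift3d(mask, axis, 1L) | shift3d(mask, axis, -1L)
  }
  out
}

#' One-voxel 6-connected binary erosion
#'
#' @inheritParams dilate6
#' @return Logical 3D array.
#' @export
erode6 <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  out <- mask
  for (axis in 1:3) {
    out <- out & shift3d(mask, axis, 1L) & shift3d(mask, axis, -1L)
  }
  out
}

#' 26-connected component labeling of a 3D mask
#'
#' Breadth-first labeling over the foreground voxels; two voxels are
#' connected if they differ by at most one along every axis (vertex
#' adjacency).
#'
#' @param mask Logical 3D array.
#' @return Integer 3D array: 0 for background, 1..k component labels.
#' @export
label_components26 <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  gs <- dim(mask)
  labels <- array(0L, gs)
  fg <- which(mask)
  if (!length(fg)) return(labels)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  lab <- 0L
  for (start in fg) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      here <- arrayInd(queue, gs)
      nxt <- integer(0)
      for (o in seq_len(nrow(offs))) {
        nb <- sweep(here, 2, offs[o, ], "+")
        keep <- nb[, 1] >= 1 & nb[, 1] <= gs[1] &
                nb[, 2] >= 1 & nb[, 2] <= gs[2] &
                nb[, 3] >= 1 & nb[, 3] <= gs[3]
        if (!any(keep)) next
        lin <- nb[keep, 1] + gs[1] * (nb[keep, 2] - 1) +
          gs[1] * gs[2] * (nb[keep, 3] - 1)
        new <- lin[mask[lin] & labels[lin] == 0L]
        if (length(new)) {
          labels[new] <- lab
          nxt <- c(nxt, new)
        }
      }
      queue <- unique(nxt)
    }
  }
  labels
}

#' Voxel-fraction cutoff intensity for lesion delineation
#'
#' Returns the smallest intensity value present in the brain-masked image
#' such that the voxels strictly brighter than it make up less than
#' `fraction` of the brain volume (and at least one voxel). With the
#' default 1.1% fraction this reproduces the histogram-tail rule used to
#' separate the hyperintense lesion from normal brain on the MDWI map.
#'
#' @param mdwi 3D intensity array ([scalar_map] or bare array).
#' @param brain Logical 3D brain mask.
#' @param fraction Maximum supra-cutoff voxel fraction, in (0, 1);
#'   default 0.011.
#' @return The cutoff intensity (a value present in the image).
#' @examples
#' img <- array(1:1000, c(10, 10, 10))
#' select_cutoff(img, array(TRUE, c(10, 10, 10)))  # 990
#' @export
select_cutoff <- function(mdwi, brain, fraction = 0.011) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  if (!all(dim(mdwi) == dim(brain)))
    stop("image and brain mask geometry differ")
  vals <- as.numeric(mdwi)[as.logical(brain)]
  vals <- vals[!is.na(vals)]
  n <- length(vals)
  if (!n) stop("brain mask is empty")
  tab <- sort(unique(vals))
  counts <- tabulate(match(vals, tab), length(tab))
  greater <- n - cumsum(counts)          # voxels strictly above each value
  ok <- greater > 0 & greater / n < fraction
  if (!any(ok))
    stop("degenerate image: no cutoff leaves a nonempty supra-threshold ",
         "set below the requested fraction")
  tab[which(ok)[1]]
}

#' Extract the lesion as the brightest supra-cutoff component
#'
#' Thresholds the image at `cutoff`, labels the supra-cutoff voxels with
#' 26-connectivity, and returns the connected component containing the
#' global maximum intensity (ties broken by lowest linear voxel index).
#' The result is the "lesion boundary" region from which the layered
#' masks are derived.
#'
#' @param mdwi 3D intensity array.
#' @param cutoff Intensity cutoff, typically from [select_cutoff()].
#' @param brain Logical 3D brain mask.
#' @return Logical 3D lesion mask.
#' @export
extract_lesion <- function(mdwi, cutoff, brain) {
  if (!all(dim(mdwi) == dim(brain)))
    stop("image and brain mask geometry differ")
  supra <- !is.na(mdwi) & (mdwi > cutoff) & as.logical(brain)
  dim(supra) <- dim(brain)
  if (!any(supra)) stop("no lesion found: supra-cutoff set is empty")
  labels <- label_components26(supra)
  supra_idx <- which(supra)
  peak <- supra_idx[which.max(mdwi[supra_idx])]   # which.max: first = lowest index
  labels == labels[peak]
}

#' Lesion layers from one-voxel erosion and dilation
#'
#' From the thresholded contiguous region ("lesion boundary"), derives:
#' `core` (one-voxel 6-connected erosion, trimming partial-volume voxels),
#' `boundary_shell` (region minus core), `outer_shell` (one-voxel dilation
#' minus region, the peri-lesional rim), and `nested_outer` (the full
#' dilation). `core` and `boundary_shell` partition the region exactly.
#'
#' @param region Logical 3D mask of the segmented lesion.
#' @return An object of class `lesion_layers`: list of logical masks
#'   `region`, `core`, `boundary_shell`, `outer_shell`, `nested_outer`.
#' @export
make_layers <- function(region) {
  region <- array(as.logical(region), dim(region))
  if (!any(region)) stop("region is empty")
  core <- erode6(region)
  if (!any(core))
    warning("empty core: one-voxel erosion removed the whole region")
  nested_outer <- dilate6(region)
  structure(list(region = region, core = core,
                 boundary_shell = region & !core,
                 outer_shell = nested_outer & !region,
                 nested_outer = nested_outer),
            class = "lesion_layers")
}

#' @export
print.lesion_layers <- function(x, ...) {
  cat("<lesion_layers> region ", sum(x$region), " vox = core ", sum(x$core),
      " + boundary ", sum(x$boundary_shell), "; outer shell ",
      sum(x$outer_shell), "\n", sep = "")
  invisible(x)
}

#' Volume of a binary mask
#'
#' @param mask Logical/0-1 3D array.
#' @param voxel_size Isotropic voxel size in mm.
#' @return Volume in mm^3 (`count * voxel_size^3`).
#' @export
mask_volume <- function(mask, voxel_size) {
  sum(as.logical(mask)) * voxel_size^3
}

#' Ellipsoidal sonication treatment-cell volume
#'
#' The treatment cell is modeled as a prolate ellipsoid with the given
#' cross-sectional diameter and length:
#' `V = (4/3) * pi * (d/2)^2 * (L/2)`. A 4 mm x 10 mm cell gives
#' 83.78 mm^3.
#'
#' @param cross_diameter Cross-sectional diameter in mm.
#' @param length Cell length in mm.
#' @return Volume in mm^3.
#' @examples
#' treatment_cell_volume(4, 10)  # 83.77580
#' @export
treatment_cell_volume <- function(cross_diameter, length) {
  if (cross_diameter <= 0 || length <= 0)
    stop("cell dimensions must be positive")
  (4 / 3) * pi * (cross_diameter / 2)^2 * (length / 2)
}

#' Lesion volume from serial histology sections
#'
#' Sum of per-slide lesion areas times the slide thickness
#' (200 micron = 0.2 mm sectioning by default).
#'
#' @param slice_areas Numeric vector of per-slide lesion areas in mm^2.
#' @param slice_thickness Slide thickness in mm (default 0.2).
#' @return Volume in mm^3.
#' @export
histology_volume <- function(slice_areas, slice_thickness = 0.2) {
  if (any(slice_areas < 0)) stop("slice areas must be >= 0")
  if (slice_thickness <= 0) stop("slice thickness must be > 0")
  sum(slice_areas * slice_thickness)
}

#' Segment a lesion and report layer volumes
#'
#' Runs [select_cutoff()], [extract_lesion()] and [make_layers()] and
#' assembles a per-mask volume table.
#'
#' @param mdwi 3D MDWI intensity array.
#' @param brain Logical brain mask.
#' @param voxel_size Voxel size in mm.
#' @param fraction Cutoff voxel fraction (default 0.011).
#' @return List with `cutoff`, `layers` ([make_layers()] result), and
#'   `volumes`, a data frame with columns `mask_name`, `voxel_count`,
#'   `volume_mm3`, `cutoff_intensity`, `fraction_used`.
#' @export
segment_lesion <- function(mdwi, brain, voxel_size, fraction = 0.011) {
  cutoff <- select_cutoff(mdwi, brain, fraction)
  region <- extract_lesion(mdwi, cutoff, brain)
  layers <- make_layers(region)
  nm <- c("region", "core", "boundary_shell", "outer_shell", "nested_outer")
  counts <- vapply(layers[nm], sum, numeric(1))
  volumes <- data.frame(
    mask_name = nm,
    voxel_count = as.integer(counts),
    volume_mm3 = counts * voxel_size^3,
    cutoff_intensity = cutoff,
    fraction_used = fraction,
    row.names = NULL
  )
  list(cutoff = cutoff, layers = layers, volumes = volumes)
}
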