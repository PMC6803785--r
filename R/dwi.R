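#' 4D diffusion-weighted volume
#'
#' Container pairing a 4D intensity array (x, y, z, volume) with its voxel
#' geometry and gradient table. The package uses an axis-aligned identity
#' world transform: voxel `(i, j, k)` (0-based) has its center at
#' `(i, j, k) * voxel_size` mm.
#'
#' @param data 4D numeric array of nonnegative intensities.
#' @param voxel_size Isotropic voxel edge length in mm (> 0).
#' @param gradients A [gradient_table] whose length matches `dim(data)[4]`.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, voxel_size, gradients) {
  stopifnot(inherits(gradients, "gradient_table"))
  if (length(dim(data)) != 4L)
    stop("data must be a 4D array (x, y, z, volume)")
  if (dim(data)[4] != length(gradients))
    stop("4th-axis length (", dim(data)[4], ") does not match gradient table (",
         length(gradients), ")")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a single positive number (mm)")
  if (min(data) < 0)
    stop("intensities must be >= 0")
  structure(list(data = data, voxel_size = voxel_size, gradients = gradients),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<dwi_volume> ", paste(d[1:3], collapse = " x "), " grid, ",
      d[4], " volumes, ", x$voxel_size, " mm isotropic\n", sep = "")
  print(x$gradients)
  invisible(x)
}

#' Scalar map
#'
#' A 3D per-voxel scalar with its metric kind and units attached. Most
#' package functions also accept a bare 3D array where a scalar map is
#' expected.
#'
#' @param data 3D numeric array (`NA` marks invalid voxels).
#' @param metric One of `"FA"`, `"MD"`, `"AD"`, `"RD"`, `"ADC"`, `"MDWI"`.
#' @param units Unit string; defaults follow the metric (mm^2/s for
#'   diffusivities, dimensionless FA, intensity for MDWI).
#' @return A numeric 3D array of class `scalar_map` with attributes
#'   `metric` and `units`.
#' @export
scalar_map <- function(data, metric, units = NULL) {
  metric <- match.arg(metric, c("FA", "MD", "AD", "RD", "ADC", "MDWI"))
  if (is.null(units))
    units <- switch(metric, FA = "dimensionless", MDWI = "intensity", "mm^2/s")
  if (length(dim(data)) != 3L) stop("scalar map data must be 3D")
  structure(data, metric = metric, units = units,
            class = c("scalar_map", "array"))
}

#' @export
print.scalar_map <- function(x, ...) {
  cat("<scalar_map> ", attr(x, "metric"), " [", attr(x, "units"), "] ",
      paste(dim(x), collapse = " x "),
      "; range ", paste(signif(range(x, na.rm = TRUE), 4), collapse = " .. "),
      "\n", sep = "")
  invisible(x)
}

#' Mean diffusion-weighted image (MDWI)
#'
#' Voxel-wise arithmetic mean over all volumes of the acquisition,
#' b = 0 baseline included. Thermal lesions with suppressed diffusivity
#' appear hyperintense on this map because their diffusion-weighted
#' volumes attenuate less.
#'
#' @param dwi A [dwi_volume].
#' @return A `"MDWI"` [scalar_map].
#' @export
compute_mdwi <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_volume"))
  d <- dim(dwi$data)
  m <- rowMeans(array(dwi$data, c(prod(d[1:3]), d[4])), na.rm = FALSE)
  scalar_map(array(m, d[1:3]), "MDWI")
}

#' Apparent diffusion coefficient from mean signals
#'
#' Single-shell monoexponential estimate
#' `ADC = -(1/b) * ln(Sdw / S0)`, where `Sdw` is the voxel mean over all
#' `b > 0` volumes and `S0` the mean over `b = 0` volumes. Unlike the
#' tensor-trace MD this averages the *signal* over directions before
#' taking the log, so in anisotropic tissue `ADC <= MD` (convexity of the
#' exponential). Voxels with a nonpositive signal ratio are `NA`.
#'
#' @param dwi A [dwi_volume] with exactly one nonzero b-value.
#' @return An `"ADC"` [scalar_map] in mm^2/s.
#' @export
compute_adc <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_volume"))
  bv <- dwi$gradients$bvals
  shells <- unique(bv[bv > 0])
  if (length(shells) != 1L)
    stop("ADC requires a single nonzero b shell; found b = {",
         paste(sort(shells), collapse = ", "), "}")
  b <- shells
  d <- dim(dwi$data)
  flat <- array(dwi$data, c(prod(d[1:3]), d[4]))
  s0 <- rowMeans(flat[, bv == 0, drop = FALSE])
  sdw <- rowMeans(flat[, bv > 0, drop = FALSE])
  ratio <- sdw / s0
  adc <- ifelse(is.finite(ratio) & ratio > 0, -log(ratio) / b, NA_real_)
  scalar_map(array(adc, d[1:3]), "ADC")
}

# ---- file I/O -------------------------------------------------------------

#' Read a DWI dataset from NIfTI-1 + FSL-style bval/bvec files
#'
#' The bval file is one whitespace-separated row; the bvec file has three
#' rows (x, y, z components). Directions whose norm deviates from 1 (and
#' from 0 for b = 0 entries) are renormalized with a warning.
#'
#' @param image_path Path to a 4D NIfTI-1 file.
#' @param bval_path,bvec_path Paths to the gradient text files.
#' @return A [dwi_volume].
#' @export
read_dwi <- function(image_path, bval_path, bvec_path) {
  for (p in c(image_path, bval_path, bvec_path))
    if (!file.exists(p)) stop("cannot read '", p, "': no such file")
  img <- RNifti::readNifti(image_path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))    # drop NIfTI header attributes
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bvecs) != 3L)
    stop("bvec file must have exactly three rows (x, y, z)")
  if (length(bvals) != dim(arr)[4] || ncol(bvecs) != dim(arr)[4])
    stop("gradient files describe ", length(bvals), "/", ncol(bvecs),
         " volumes but image has ", dim(arr)[4])
  nrm <- sqrt(colSums(bvecs^2))
  fix <- bvals > 0 & abs(nrm - 1) > 1e-9
  if (any(fix)) {
    warning(sum(fix), " gradient direction(s) renormalized to unit length")
    bvecs[, fix] <- sweep(bvecs[, fix, drop = FALSE], 2, nrm[fix], "/")
  }
  bvecs[, bvals == 0] <- 0
  pd <- RNifti::pixdim(img)[1:3]
  if (diff(range(pd)) > 1e-4 * mean(pd))
    stop("anisotropic voxels (", paste(signif(pd, 4), collapse = " x "),
         " mm) are not supported; resample to isotropic first")
  dimnames(bvecs) <- NULL
  dwi_volume(arr, voxel_size = pd[1], gradients = gradient_table(bvals, bvecs))
}

#' Write a DWI dataset as NIfTI-1 + bval/bvec
#'
#' @param dwi A [dwi_volume].
#' @param image_path Output NIfTI path (`.nii` or `.nii.gz`).
#' @param bval_path,bvec_path Output gradient text paths.
#' @return Invisibly, `image_path`.
#' @export
write_dwi <- function(dwi, image_path, bval_path, bvec_path) {
  stopifnot(inherits(dwi, "dwi_volume"))
  write_nifti_array(dwi$data, image_path, dwi$voxel_size)
  write_gradients(dwi$gradients, bval_path, bvec_path)
  invisible(image_path)
}

#' Write bval/bvec text files (FSL dialect)
#' @param gradients A [gradient_table].
#' @param bval_path,bvec_path Output paths.
#' @return Invisibly, `bval_path`.
#' @export
write_gradients <- function(gradients, bval_path, bvec_path) {
  stopifnot(inherits(gradients, "gradient_table"))
  writeLines(paste(format(gradients$bvals, trim = TRUE), collapse = " "),
             bval_path)
  writeLines(apply(gradients$bvecs, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE), collapse = " ")), bvec_path)
  invisible(bval_path)
}

#' Write a numeric array as NIfTI-1 with an identity-orientation header
#' @keywords internal
write_nifti_array <- function(arr, path, voxel_size) {
  nd <- length(dim(arr))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(voxel_size, min(nd, 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D mask NIfTI as a logical array
#' @param path NIfTI file containing zeros and ones.
#' @return Logical 3D array.
#' @export
read_mask <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) != 3L) stop("mask must be a 3D volume")
  arr > 0.5
}
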