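#' Per-voxel diffusion tensor field
#'
#' Result of [fit_tensor_loglinear()]: packed tensors, fitted baseline,
#' descending non-negative eigenvalues, orthonormal eigenvector triads,
#' and a validity mask. Eigen-quantities are defined only where
#' `valid` is `TRUE`.
#'
#' @name tensor_field
#' @keywords internal
NULL

new_tensor_field <- function(tensors, s0_map, evals, evecs, valid,
                             voxel_size, n_clamped) {
  structure(list(tensors = tensors, s0_map = s0_map, eigenvalues = evals,
                 eigenvectors = evecs, valid = valid,
                 voxel_size = voxel_size, n_clamped = n_clamped),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("<tensor_field> ", paste(dim(x$valid), collapse = " x "), " grid; ",
      sum(x$valid), " valid voxels; ", x$n_clamped,
      " voxels with negative eigenvalues clamped to 0\n", sep = "")
  invisible(x)
}

#' Log-linear least-squares diffusion tensor fit
#'
#' Fits, at every masked voxel with strictly positive intensities, the
#' log-linearized monoexponential model
#' `ln S_i = ln s0 - b_i g_i' D g_i` by ordinary least squares for the six
#' unique tensor elements and `ln s0`. Voxels with any nonpositive
#' intensity are marked invalid rather than clipped (the log is undefined
#' and clipping would bias the fit). Negative eigenvalues, which noise can
#' produce, are clamped to zero after decomposition; the count of affected
#' voxels is recorded in the returned field and reported as a message.
#'
#' @param dwi A [dwi_volume] with at least one b = 0 and six b > 0 volumes.
#' @param mask Logical 3D array of voxels to fit; `NULL` fits voxels whose
#'   mean intensity is positive.
#' @return A `tensor_field` list: `tensors` (4D, packed xx,yy,zz,xy,xz,yz),
#'   `s0_map`, `eigenvalues` (4D, descending), `eigenvectors`
#'   (5D, `[, , , i, j]` = component i of eigenvector j), `valid`,
#'   `voxel_size`, `n_clamped`.
#' @export
fit_tensor_loglinear <- function(dwi, mask = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  gt <- dwi$gradients
  if (sum(gt$bvals > 0) < 6 || sum(gt$bvals == 0) < 1 || length(gt) < 7)
    stop("insufficient data: need >= 6 b>0 volumes and >= 1 b=0 volume")
  d <- dim(dwi$data)
  gs <- d[1:3]
  flat <- array(dwi$data, c(prod(gs), d[4]))
  if (is.null(mask)) {
    mask <- array(rowMeans(flat) > 0, gs)
  } else {
    if (!all(dim(mask) == gs)) stop("mask geometry does not match the image")
    mask <- array(as.logical(mask), gs)
  }
  idx <- which(mask)
  S <- flat[idx, , drop = FALSE]
  ok <- rowSums(S <= 0) == 0L
  fit_idx <- idx[ok]

  valid <- array(FALSE, gs); valid[fit_idx] <- TRUE
  tensors <- array(NA_real_, c(gs, 6))
  s0_map <- array(NA_real_, gs)
  evals <- array(NA_real_, c(gs, 3))
  evecs <- array(NA_real_, c(gs, 3, 3))
  if (!length(fit_idx))
    return(new_tensor_field(tensors, s0_map, evals, evecs, valid,
                            dwi$voxel_size, 0L))

  X <- tensor_design_matrix(gt)
  qrX <- qr(X)
  if (qrX$rank < 7L)
    stop("degenerate gradient scheme: the diffusion directions do not ",
         "determine all six tensor elements (design rank ", qrX$rank, " < 7)")
  beta <- qr.coef(qrX, t(log(S[ok, , drop = FALSE])))    # 7 x nvox

  nvox <- length(fit_idx)
  ev_mat <- matrix(NA_real_, nvox, 3)
  evec_mat <- matrix(NA_real_, nvox, 9)
  clamped <- logical(nvox)
  for (v in seq_len(nvox)) {
    e <- eigen(tensor_from_vec6(beta[2:7, v]), symmetric = TRUE)
    if (e$values[3] < 0) {
      clamped[v] <- TRUE
      e$values <- pmax(e$values, 0)
    }
    ev_mat[v, ] <- e$values            # eigen() returns descending order
    evec_mat[v, ] <- e$vectors
  }
  n_clamped <- sum(clamped)
  if (n_clamped > 0)
    message("fit_tensor_loglinear: clamped negative eigenvalues to 0 in ",
            n_clamped, " of ", nvox, " voxels")

  flat_t <- array(tensors, c(prod(gs), 6)); flat_t[fit_idx, ] <- t(beta[2:7, ])
  tensors <- array(flat_t, c(gs, 6))
  s0_map[fit_idx] <- exp(beta[1, ])
  flat_e <- array(evals, c(prod(gs), 3)); flat_e[fit_idx, ] <- ev_mat
  evals <- array(flat_e, c(gs, 3))
  flat_v <- array(evecs, c(prod(gs), 9)); flat_v[fit_idx, ] <- evec_mat
  evecs <- array(flat_v, c(gs, 3, 3))

  new_tensor_field(tensors, s0_map, evals, evecs, valid,
                   dwi$voxel_size, n_clamped)
}

#' Fractional anisotropy from eigenvalue triples
#'
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`, defined as 0
#' when all eigenvalues are 0. Values are clipped to `[0, 1]` to absorb
#' floating-point round-off at the stick limit.
#'
#' @param l1,l2,l3 Eigenvalue vectors (any order).
#' @return FA values in `[0, 1]`.
#' @export
fa_from_eigenvalues <- function(l1, l2, l3) {
  mb <- (l1 + l2 + l3) / 3
  num <- sqrt((l1 - mb)^2 + (l2 - mb)^2 + (l3 - mb)^2)
  den <- sqrt(l1^2 + l2^2 + l3^2)
  fa <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  pmin(pmax(fa, 0), 1)
}

#' Tensor-derived scalar maps
#'
#' Axial diffusivity `AD = lambda1`, radial diffusivity
#' `RD = (lambda2 + lambda3)/2`, mean diffusivity
#' `MD = (lambda1 + lambda2 + lambda3)/3`, and fractional anisotropy
#' ([fa_from_eigenvalues()]). Invalid voxels propagate as `NA`.
#'
#' @param field A `tensor_field` from [fit_tensor_loglinear()].
#' @return Named list of [scalar_map]s: `FA`, `MD`, `AD`, `RD`.
#' @export
eigen_metrics <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  gs <- dim(field$valid)
  slice <- function(k) array(field$eigenvalues[, , , k], gs)
  l1 <- slice(1); l2 <- slice(2); l3 <- slice(3)
  list(FA = scalar_map(fa_from_eigenvalues(l1, l2, l3), "FA"),
       MD = scalar_map((l1 + l2 + l3) / 3, "MD"),
       AD = scalar_map(l1, "AD"),
       RD = scalar_map((l2 + l3) / 2, "RD"))
}

#' All five diffusion scalar maps plus MDWI for one acquisition
#'
#' Convenience wrapper running the tensor fit, [eigen_metrics()],
#' [compute_adc()] and [compute_mdwi()].
#'
#' @inheritParams fit_tensor_loglinear
#' @return List with `field` (the `tensor_field`) and `maps` (named list
#'   `FA`, `MD`, `AD`, `RD`, `ADC`, `MDWI`).
#' @export
compute_scalar_maps <- function(dwi, mask = NULL) {
  field <- fit_tensor_loglinear(dwi, mask)
  maps <- eigen_metrics(field)
  maps$ADC <- compute_adc(dwi)
  maps$MDWI <- compute_mdwi(dwi)
  list(field = field, maps = maps)
}

#' Write scalar maps as NIfTI files
#'
#' Writes one file per map named `<prefix>_<metric>.nii.gz` (lower-case
#' metric names).
#'
#' @param maps Named list of [scalar_map]s (3D arrays).
#' @param prefix Output path prefix.
#' @param voxel_size Voxel size in mm.
#' @return Invisibly, the written paths.
#' @export
write_scalar_maps <- function(maps, prefix, voxel_size) {
  paths <- character(0)
  for (nm in names(maps)) {
    p <- paste0(prefix, "_", tolower(nm), ".nii.gz")
    arr <- maps[[nm]]
    attributes(arr) <- list(dim = dim(arr))
    arr[is.na(arr)] <- 0
    write_nifti_array(arr, p, voxel_size)
    paths <- c(paths, p)
  }
  invisible(paths)
}
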