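#' Specification of a synthetic DWI phantom
#'
#' Describes a small-animal-brain-like phantom: an ellipsoidal brain of
#' mildly anisotropic background tissue, a C-shaped anterior-posterior
#' white-matter tract (fornix analogue), a strongly anisotropic reference
#' region (splenium analogue, oriented left-right), and an ellipsoidal
#' focal lesion centered on the tract apex whose diffusivity suppression
#' peaks at the core and decays linearly with normalized ellipsoidal
#' radius. Defaults emulate a 1 mm isotropic, one b=0 + 128-direction
#' b=800 s/mm^2 acquisition.
#'
#' Geometry is defined in mm with voxel centers at integer multiples of
#' `voxel_size` (0-based indices, identity world transform). Secondary
#' structures scale with the grid so reduced-size phantoms keep the same
#' layout.
#'
#' @param grid_shape Integer 3-vector of voxel counts per axis.
#' @param voxel_size Isotropic voxel size in mm.
#' @param tissue_eigenvalues Named list with descending eigenvalue triples
#'   (mm^2/s) for `background`, `tract`, and `reference` tissue.
#' @param lesion_center Lesion center in mm, or `NULL` to place it on the
#'   tract apex.
#' @param lesion_semi_axes Ellipsoid semi-axes in mm (x, y, z).
#' @param lesion_core_scale Diffusivity scale factor at the lesion core,
#'   in (0, 1]; 1 disables the lesion (null phantom).
#' @param aniso_loss_threshold Fractional diffusivity suppression
#'   (`1 - scale`) beyond which tissue anisotropy is fully destroyed;
#'   between no suppression and this level, anisotropy fades linearly.
#' @param s0 Baseline signal (arbitrary intensity units).
#' @param noise_sigma Rician noise level per channel, same units as `s0`.
#' @param n_directions,b_value Gradient scheme passed to
#'   [make_gradient_table()].
#' @param brain_semi_axes Brain ellipsoid semi-axes in mm, or `NULL` for
#'   grid-proportional defaults.
#' @param tract_radius Tract tube radius in mm.
#' @param seed Integer seed controlling the noise draws.
#' @return An object of class `phantom_spec` (a validated list).
#' @export
phantom_spec <- function(grid_shape = c(64L, 80L, 56L),
                         voxel_size = 1,
                         tissue_eigenvalues = list(
                           background = c(0.75, 0.70, 0.65) * 1e-3,
                           tract      = c(1.7, 0.3, 0.3) * 1e-3,
                           reference  = c(1.7, 0.3, 0.3) * 1e-3),
                         lesion_center = NULL,
                         lesion_semi_axes = c(4, 4, 6),
                         lesion_core_scale = 0.45,
                         aniso_loss_threshold = 0.15,
                         s0 = 1000,
                         noise_sigma = 20,
                         n_directions = 128,
                         b_value = 800,
                         brain_semi_axes = NULL,
                         tract_radius = 2,
                         seed = 42L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L), voxel_size > 0)
  for (nm in c("background", "tract", "reference")) {
    ev <- tissue_eigenvalues[[nm]]
    if (is.null(ev) || length(ev) != 3L)
      stop("tissue_eigenvalues$", nm, " must be an eigenvalue triple")
    if (any(diff(ev) > 0) || any(ev < 0))
      stop("tissue_eigenvalues$", nm, " must be sorted descending and >= 0")
  }
  if (lesion_core_scale <= 0 || lesion_core_scale > 1)
    stop("lesion_core_scale must lie in (0, 1]")
  if (aniso_loss_threshold <= 0 || aniso_loss_threshold > 1)
    stop("aniso_loss_threshold must lie in (0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (s0 <= 0) stop("s0 must be > 0")
  extent <- grid_shape * voxel_size
  if (is.null(brain_semi_axes))
    brain_semi_axes <- extent / 2 * c(0.75, 0.80, 0.65)
  centre <- (grid_shape - 1) / 2 * voxel_size
  if (is.null(lesion_center)) {
    z_base <- centre[3] - brain_semi_axes[3] / 3
    lesion_center <- c(centre[1], centre[2], z_base + 0.44 * brain_semi_axes[3])
  }
  structure(list(
    grid_shape = grid_shape, voxel_size = voxel_size,
    tissue_eigenvalues = tissue_eigenvalues,
    lesion_center = lesion_center, lesion_semi_axes = lesion_semi_axes,
    lesion_core_scale = lesion_core_scale,
    aniso_loss_threshold = aniso_loss_threshold,
    s0 = s0, noise_sigma = noise_sigma,
    n_directions = n_directions, b_value = b_value,
    brain_semi_axes = brain_semi_axes, tract_radius = tract_radius,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> grid ", paste(x$grid_shape, collapse = " x "),
      " @ ", x$voxel_size, " mm; b=", x$b_value, " x ", x$n_directions,
      " dirs; core scale ", x$lesion_core_scale,
      "; sigma ", x$noise_sigma, "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Radial lesion diffusivity scale profile
#'
#' Scale factor applied to tissue diffusivity as a function of normalized
#' ellipsoidal radius `r`: equals `core_scale` at the core (`r = 0`),
#' rises linearly to 1 at the lesion boundary (`r = 1`), and is 1 outside.
#' The suppression therefore peaks at the core and decays radially.
#'
#' @param r Normalized ellipsoidal radius (>= 0); vectorized.
#' @param core_scale Scale at the core, in (0, 1].
#' @return Scale factors in `[core_scale, 1]`.
#' @examples
#' lesion_scale_profile(c(0, 0.5, 1, 2), 0.5)  # 0.5 0.75 1 1
#' @export
lesion_scale_profile <- function(r, core_scale) {
  if (any(r < 0)) stop("r must be >= 0")
  if (core_scale <= 0 || core_scale > 1)
    stop("core_scale must lie in (0, 1]")
  core_scale + (1 - core_scale) * pmin(r, 1)
}

# Run an expression with a temporary RNG seed, restoring caller state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Voxel-center coordinate grids (mm) for a phantom spec.
phantom_grids <- function(spec) {
  gs <- spec$grid_shape; vs <- spec$voxel_size
  list(x = (seq_len(gs[1]) - 1) * vs,
       y = (seq_len(gs[2]) - 1) * vs,
       z = (seq_len(gs[3]) - 1) * vs)
}

# Logical mask of an axis-aligned ellipsoid given center/semi-axes in mm.
ellipsoid_mask <- function(spec, center, semi) {
  g <- phantom_grids(spec)
  dx2 <- ((g$x - center[1]) / semi[1])^2
  dy2 <- ((g$y - center[2]) / semi[2])^2
  dz2 <- ((g$z - center[3]) / semi[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

# Tract centerline sample points and unit tangents. The centerline runs
# anterior-posterior (y axis) with a sinusoidal superior arch in z,
# an arc gentle enough to satisfy a 1 mm curvature-radius bound.
tract_centerline <- function(spec, n = 400) {
  gs <- spec$grid_shape; vs <- spec$voxel_size
  centre <- (gs - 1) / 2 * vs
  bsa <- spec$brain_semi_axes
  t <- seq(0, 1, length.out = n)
  y0 <- centre[2] - 0.78 * bsa[2]
  y1 <- centre[2] + 0.78 * bsa[2]
  z_base <- centre[3] - bsa[3] / 3
  amp <- 0.44 * bsa[3]
  pts <- cbind(centre[1], y0 + (y1 - y0) * t, z_base + amp * sin(pi * t))
  tang <- cbind(0, y1 - y0, amp * pi * cos(pi * t))
  tang <- tang / sqrt(rowSums(tang^2))
  list(points = pts, tangents = tang)
}

# Tract tube mask plus per-voxel tangent directions (n_tract x 3).
tract_mask_and_tangents <- function(spec) {
  g <- phantom_grids(spec)
  cl <- tract_centerline(spec)
  gs <- spec$grid_shape
  rad <- spec$tract_radius
  # restrict the search to the tube's bounding box
  xr <- which(abs(g$x - cl$points[1, 1]) <= rad + spec$voxel_size)
  yr <- which(g$y >= min(cl$points[, 2]) - rad & g$y <= max(cl$points[, 2]) + rad)
  zr <- which(g$z >= min(cl$points[, 3]) - rad & g$z <= max(cl$points[, 3]) + rad)
  cand <- as.matrix(expand.grid(x = xr, y = yr, z = zr))
  pts <- cbind(g$x[cand[, 1]], g$y[cand[, 2]], g$z[cand[, 3]])
  # nearest centerline sample per candidate voxel
  d2 <- outer(rowSums(pts^2), rowSums(cl$points^2), "+") -
    2 * pts %*% t(cl$points)
  nearest <- max.col(-d2, ties.method = "first")
  dmin <- sqrt(pmax(0, d2[cbind(seq_len(nrow(d2)), nearest)]))
  inside <- dmin <= rad
  mask <- array(FALSE, gs)
  mask[cand[inside, , drop = FALSE]] <- TRUE
  list(mask = mask,
       voxels = cand[inside, , drop = FALSE],
       tangents = cl$tangents[nearest[inside], , drop = FALSE],
       arc_t = (nearest[inside] - 1) / (nrow(cl$points) - 1))
}

# Tensor 6-vector (xx,yy,zz,xy,xz,yz) for eigenvalues along a given axis,
# transverse eigenvalues isotropic in the perpendicular plane.
tensor_vec6_axial <- function(ev, axis) {
  lam_perp <- (ev[2] + ev[3]) / 2
  u <- axis / sqrt(sum(axis^2))
  D <- lam_perp * diag(3) + (ev[1] - lam_perp) * tcrossprod(u)
  vec6_from_tensor(D)
}

#' Generate a pre/post-treatment DWI phantom pair with ground truth
#'
#' Builds the tissue tensor field described by a [phantom_spec], evaluates
#' the monoexponential forward signal for every brain voxel, applies the
#' focal lesion to the post-treatment tensor field, and adds seeded Rician
#' noise (two independent draws for the pre and post volumes). Voxels
#' outside the brain are zero.
#'
#' The lesion maps each affected tensor to
#' `D' = s * (lam3 * I + a * (D - lam3 * I))`, where `s` is
#' [lesion_scale_profile()] at the voxel's normalized ellipsoidal radius,
#' `lam3` the tensor's smallest eigenvalue, and `a` an anisotropy-retention
#' factor falling linearly from 1 to 0 as the local suppression `1 - s`
#' grows to `aniso_loss_threshold`. Every eigenvalue is non-increasing
#' under this map, so each lesion voxel attenuates less in every gradient
#' direction and the mean DWI is hyperintense by construction; in
#' isotropic tissue the map reduces to plain eigenvalue scaling by `s`.
#' At `lesion_core_scale = 1` the map is the identity (null phantom).
#'
#' @param spec A [phantom_spec].
#' @return A list with elements `pre` and `post` ([dwi_volume]s), `truth`
#'   (logical masks: `brain`, `lesion`, `tract`, `reference`,
#'   `distal_seed`, `far_target`), `tensors_pre`/`tensors_post` (4D arrays
#'   of packed ground-truth tensors), and the `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape; vs <- spec$voxel_size
  centre <- (gs - 1) / 2 * vs
  bsa <- spec$brain_semi_axes
  ev <- spec$tissue_eigenvalues

  brain <- ellipsoid_mask(spec, centre, bsa)
  lesion <- ellipsoid_mask(spec, spec$lesion_center, spec$lesion_semi_axes)
  if (any(lesion & !brain))
    stop("invalid geometry: lesion ellipsoid extends outside the brain mask")

  tr <- tract_mask_and_tangents(spec)
  ref_center <- centre + c(0, 0.64 * bsa[2], 0.36 * bsa[3])
  ref_semi <- c(0.21 * bsa[1], 0.0625 * bsa[2], 0.11 * bsa[3])
  reference <- ellipsoid_mask(spec, ref_center, ref_semi)
  if (any(tr$mask & !brain) || any(reference & !brain))
    stop("invalid geometry: tract or reference region extends outside the brain mask")
  if (any(reference & tr$mask))
    stop("invalid geometry: reference region overlaps the tract")

  # tract-disruption assay regions: tube ends on either side of the lesion
  g <- phantom_grids(spec)
  ymm <- array(rep(g$y, each = gs[1]), gs)
  distal_seed <- tr$mask & ymm < centre[2] - 0.61 * bsa[2]
  far_target <- tr$mask & ymm > centre[2] + 0.61 * bsa[2]

  # per-voxel packed tensors over the brain
  brain_idx <- which(brain)
  nvox <- length(brain_idx)
  Dmat <- matrix(rep(tensor_vec6_axial(ev$background, c(1, 0, 0)), nvox),
                 nrow = 6)
  colmap <- array(NA_integer_, gs); colmap[brain_idx] <- seq_len(nvox)
  tvox <- tr$voxels
  tcols <- colmap[tvox]
  for (i in seq_len(nrow(tvox)))
    Dmat[, tcols[i]] <- tensor_vec6_axial(ev$tract, tr$tangents[i, ])
  ref_cols <- colmap[which(reference)]
  Dmat[, ref_cols] <- tensor_vec6_axial(ev$reference, c(1, 0, 0))

  # normalized ellipsoidal radius of every brain voxel w.r.t. the lesion
  vox_ijk <- arrayInd(brain_idx, gs)
  pmm <- (vox_ijk - 1) * vs
  rles <- sqrt(((pmm[, 1] - spec$lesion_center[1]) / spec$lesion_semi_axes[1])^2 +
               ((pmm[, 2] - spec$lesion_center[2]) / spec$lesion_semi_axes[2])^2 +
               ((pmm[, 3] - spec$lesion_center[3]) / spec$lesion_semi_axes[3])^2)

  Dpost <- Dmat
  inles <- which(rles < 1)
  if (length(inles) && spec$lesion_core_scale < 1) {
    s <- lesion_scale_profile(rles[inles], spec$lesion_core_scale)
    a <- pmax(0, pmin(1, 1 - (1 - s) / spec$aniso_loss_threshold))
    lam3 <- smallest_eigenvalue_vec6(Dmat[, inles, drop = FALSE])
    iso <- rbind(lam3, lam3, lam3, 0, 0, 0)
    Dpost[, inles] <- sweep(
      iso + sweep(Dmat[, inles, drop = FALSE] - iso, 2, a, "*"),
      2, s, "*")
  }

  gt <- make_gradient_table(spec$n_directions, spec$b_value)
  B6 <- -tensor_design_matrix(gt)[, -1]      # rows: b * (gx^2, ..., 2 gy gz)
  signal_for <- function(D6) spec$s0 * exp(-(B6 %*% D6))

  Spre <- signal_for(Dmat)
  Spost <- signal_for(Dpost)

  nvol <- length(gt)
  noisy <- function(S) {
    if (spec$noise_sigma == 0) return(S)
    n1 <- matrix(stats::rnorm(length(S), sd = spec$noise_sigma), nrow(S))
    n2 <- matrix(stats::rnorm(length(S), sd = spec$noise_sigma), nrow(S))
    sqrt((S + n1)^2 + n2^2)
  }
  with_seed(spec$seed, {
    Spre <- noisy(Spre)
    Spost <- noisy(Spost)
  })

  to_volume <- function(S) {
    flat <- matrix(0, prod(gs), nvol)
    flat[brain_idx, ] <- t(S)
    dim(flat) <- c(gs, nvol)
    dwi_volume(flat, vs, gt)
  }
  pack_field <- function(D6) {
    flat <- matrix(NA_real_, prod(gs), 6)
    flat[brain_idx, ] <- t(D6)
    dim(flat) <- c(gs, 6)
    flat
  }

  list(pre = to_volume(Spre), post = to_volume(Spost),
       truth = list(brain = brain, lesion = lesion, tract = tr$mask,
                    reference = reference, distal_seed = distal_seed,
                    far_target = far_target),
       tensors_pre = pack_field(Dmat), tensors_post = pack_field(Dpost),
       spec = spec)
}

# Smallest eigenvalue of packed symmetric 3x3 tensors (6 x n matrix),
# via the closed-form symmetric 3x3 eigenvalue solution.
smallest_eigenvalue_vec6 <- function(D6) {
  apply(D6, 2, function(v) min(eigen(tensor_from_vec6(v),
                                     symmetric = TRUE,
                                     only.values = TRUE)$values))
}

#' Write a phantom to disk (NIfTI + bval/bvec + config echo)
#'
#' Writes `pre.nii.gz`, `post.nii.gz`, one mask per truth entry
#' (`mask_<name>.nii.gz`), `bvals`/`bvecs`, and `phantom_spec.txt`, a
#' key = value echo of the generating specification for provenance.
#'
#' @param phantom Result of [make_phantom()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- phantom$spec$voxel_size
  write_dwi(phantom$pre, file.path(dir, "pre.nii.gz"),
            file.path(dir, "bvals"), file.path(dir, "bvecs"))
  write_dwi(phantom$post, file.path(dir, "post.nii.gz"),
            file.path(dir, "bvals"), file.path(dir, "bvecs"))
  for (nm in names(phantom$truth))
    write_nifti_array(phantom$truth[[nm]] + 0L,
                      file.path(dir, paste0("mask_", nm, ".nii.gz")), vs)
  writeLines(spec_to_config(phantom$spec), file.path(dir, "phantom_spec.txt"))
  invisible(dir)
}

# Flat key = value echo of a phantom spec (parseable by read_config()).
spec_to_config <- function(spec) {
  fmt <- function(v) {
    if (is.character(v)) return(paste0('"', v, '"'))
    v <- format(v, digits = 17, trim = TRUE, scientific = FALSE)
    if (length(v) > 1) paste0("[", paste(v, collapse = ", "), "]") else v
  }
  c("[phantom]",
    paste0("grid_shape = ", fmt(spec$grid_shape)),
    paste0("voxel_size = ", fmt(spec$voxel_size)),
    paste0("background_eigenvalues = ", fmt(spec$tissue_eigenvalues$background)),
    paste0("tract_eigenvalues = ", fmt(spec$tissue_eigenvalues$tract)),
    paste0("reference_eigenvalues = ", fmt(spec$tissue_eigenvalues$reference)),
    paste0("lesion_center = ", fmt(spec$lesion_center)),
    paste0("lesion_semi_axes = ", fmt(spec$lesion_semi_axes)),
    paste0("lesion_core_scale = ", fmt(spec$lesion_core_scale)),
    paste0("aniso_loss_threshold = ", fmt(spec$aniso_loss_threshold)),
    paste0("s0 = ", fmt(spec$s0)),
    paste0("noise_sigma = ", fmt(spec$noise_sigma)),
    paste0("n_directions = ", fmt(spec$n_directions)),
    paste0("b_value = ", fmt(spec$b_value)),
    paste0("brain_semi_axes = ", fmt(spec$brain_semi_axes)),
    paste0("tract_radius = ", fmt(spec$tract_radius)),
    paste0("seed = ", fmt(spec$seed)))
}
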