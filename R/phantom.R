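#' Specification of a synthetic abdominal CT phantom
#'
#' Describes a stylized abdominal CT volume: an elliptical trunk with
#' subcutaneous-fat rim, muscle wall, paraspinal muscles and visceral-fat
#' interior; a vertebral column of `n_vertebrae` bodies separated by disc
#' gaps rising from a pelvic bone ring; lungs in the cranial third; and
#' optional hard-case variants (arms in the field of view, a high-density
#' vertebral implant emulating cementoplasty). Geometry is intentionally
#' stylized: the downstream operators only rely on contrast, topology and
#' HU statistics, not on anatomical shape detail.
#'
#' Coordinates: axis 1 of the voxel grid is craniocaudal (slice 0 is the
#' most caudal), axis 2 anteroposterior (posterior = positive), axis 3
#' left-right. The z position of slice `k` (0-based) is `k * spacing_z` mm.
#'
#' @param shape_vox integer vector (n_slices, n_rows, n_cols).
#' @param spacing_mm numeric vector (z, y, x) voxel spacing in mm, all > 0.
#' @param n_vertebrae number of vertebral bodies in the column (>= 5).
#' @param l3_index_from_caudal which vertebral body is L3, counting from the
#'   pelvis (L5 = 1, L4 = 2, L3 = 3).
#' @param body_halfaxes_mm named vector `c(ap = , lr = )`: trunk ellipse
#'   semi-axes in mm.
#' @param tissue_hu named list mapping tissue to `c(mean, sd)` HU for
#'   `air`, `lung`, `muscle`, `VAT`, `SAT`, `bone`, `implant`. Defaults
#'   center the standard analysis windows (muscle \[-29, 150\], adipose
#'   \[-500, -30\]) with margin. Per-voxel draws are truncated at +/- 3 sd
#'   so every labelled voxel is guaranteed to fall inside its window.
#' @param arms_present logical: add arm cylinders lateral to the trunk.
#' @param implant_present logical: fill one of the five most caudal
#'   vertebral bodies with implant-density material.
#' @param noise_sd_hu additional global Gaussian HU noise (>= 0).
#' @param patient_height_m patient height in metres (> 0).
#' @param seed integer seed making the phantom fully reproducible.
#' @param column_base_mm z position (mm) of the caudal end of the first
#'   vertebral body.
#' @param vert_height_mm vertebral body height in mm (default 35, with 8 mm
#'   discs, consistent with a ~40 mm lumbar segment).
#' @param disc_mm intervertebral disc gap in mm.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_vox = c(100L, 64L, 64L),
                         spacing_mm = c(4, 6, 6),
                         n_vertebrae = 8L,
                         l3_index_from_caudal = 3L,
                         body_halfaxes_mm = c(ap = 95, lr = 125),
                         tissue_hu = list(
                           air = c(-1000, 0), lung = c(-800, 50),
                           muscle = c(45, 15), VAT = c(-90, 20),
                           SAT = c(-105, 20), bone = c(400, 100),
                           implant = c(1500, 100)),
                         arms_present = FALSE,
                         implant_present = FALSE,
                         noise_sd_hu = 0,
                         patient_height_m = 1.70,
                         seed = 0L,
                         column_base_mm = 80,
                         vert_height_mm = 35,
                         disc_mm = 8) {
  spec <- structure(list(
    shape_vox = as.integer(shape_vox), spacing_mm = as.numeric(spacing_mm),
    n_vertebrae = as.integer(n_vertebrae),
    l3_index_from_caudal = as.integer(l3_index_from_caudal),
    body_halfaxes_mm = body_halfaxes_mm, tissue_hu = tissue_hu,
    arms_present = isTRUE(arms_present),
    implant_present = isTRUE(implant_present),
    noise_sd_hu = as.numeric(noise_sd_hu),
    patient_height_m = as.numeric(patient_height_m), seed = as.integer(seed),
    column_base_mm = column_base_mm, vert_height_mm = vert_height_mm,
    disc_mm = disc_mm), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Validate a phantom specification
#'
#' Checks the structural invariants: positive spacing, at least five
#' vertebrae with L3 index in range, muscle mean +/- 3 sd inside
#' \[-29, 150\] HU, fat means +/- 3 sd inside \[-500, -30\] HU, bone mean
#' above 150, lung mean below -500, and the L3 vertebral body inside the
#' volume. Called by [phantom_spec()]; exported for reuse on modified specs.
#'
#' @param spec a `phantom_spec`.
#' @return the spec, invisibly; stops with a validation error otherwise.
#' @export
validate_phantom_spec <- function(spec) {
  fail <- function(msg) stop("invalid phantom spec: ", msg, call. = FALSE)
  if (length(spec$shape_vox) != 3 || any(spec$shape_vox < 8))
    fail("shape_vox must be 3 positive integers (>= 8 voxels per axis)")
  if (length(spec$spacing_mm) != 3 || any(spec$spacing_mm <= 0))
    fail("spacing must be strictly positive")
  if (spec$n_vertebrae < 5) fail("n_vertebrae must be >= 5")
  if (spec$l3_index_from_caudal < 1 ||
      spec$l3_index_from_caudal > spec$n_vertebrae)
    fail("l3_index_from_caudal out of range")
  th <- spec$tissue_hu
  need <- c("air", "lung", "muscle", "VAT", "SAT", "bone", "implant")
  if (!all(need %in% names(th))) fail("tissue_hu is missing tissues")
  win_ok <- function(t, w) th[[t]][1] - 3 * th[[t]][2] >= w[1] &&
    th[[t]][1] + 3 * th[[t]][2] <= w[2]
  if (!win_ok("muscle", HU_WINDOW_MUSCLE))
    fail("muscle mean +/- 3 sd must lie in [-29, 150] HU")
  if (!win_ok("VAT", HU_WINDOW_FAT) || !win_ok("SAT", HU_WINDOW_FAT))
    fail("fat means +/- 3 sd must lie in [-500, -30] HU")
  if (th$bone[1] <= 150) fail("bone mean must exceed 150 HU")
  if (th$lung[1] >= -500) fail("lung mean must be below -500 HU")
  if (spec$noise_sd_hu < 0) fail("noise_sd_hu must be >= 0")
  if (spec$patient_height_m <= 0) fail("patient height must be positive")
  g <- phantom_geometry(spec)
  z_extent <- (spec$shape_vox[1] - 1) * spec$spacing_mm[1]
  if (g$l3_extent[1] < 0 || g$l3_extent[2] > z_extent)
    fail("L3 vertebral body does not fit inside the volume")
  invisible(spec)
}

# Derived geometric quantities shared by the volume and single-slice
# painters.
phantom_geometry <- function(spec) {
  sz <- spec$spacing_mm[1]
  z_extent <- (spec$shape_vox[1] - 1) * sz
  h <- spec$vert_height_mm
  d <- spec$disc_mm
  base <- spec$column_base_mm
  vert_lo <- base + (seq_len(spec$n_vertebrae) - 1) * (h + d)
  i3 <- spec$l3_index_from_caudal
  l3_z <- vert_lo[i3] + h / 2
  list(z_extent = z_extent, vert_lo = vert_lo, vert_hi = vert_lo + h,
       l3_z = l3_z, l3_extent = c(vert_lo[i3], vert_lo[i3] + h),
       l3_slice = as.integer(round_half_up(l3_z / sz)),
       pelvis_range = c(max(0, base - 70), base - 4),
       lung_range = c(max(base + h, z_extent - 110), z_extent - 15),
       lung_cz = z_extent - 60, lung_az = 48,
       spine_r = 16, implant_r = 12)
}

# Construction tissue codes (distinct from ground-truth label codes).
CONSTR_CODES <- c(air = 0L, lung = 1L, SAT = 2L, muscle = 3L, VAT = 4L,
                  bone = 5L, disc = 6L, implant = 7L, other = 9L)

# Whole-volume painter: identical geometry to paint_slice, vectorized over
# z (a phantom at 1 mm slice spacing paints in a fraction of a second).
paint_volume <- function(spec, geom, implant_vert) {
  nz <- spec$shape_vox[1]; ny <- spec$shape_vox[2]; nx <- spec$shape_vox[3]
  sz <- spec$spacing_mm[1]; sy <- spec$spacing_mm[2]
  sx <- spec$spacing_mm[3]
  dims <- c(nz, ny, nx)
  z <- (seq_len(nz) - 1) * sz
  yv <- (seq_len(ny) - 1 - (ny - 1) / 2) * sy
  xv <- (seq_len(nx) - 1 - (nx - 1) / 2) * sx
  X <- array(rep(xv, each = nz * ny), dims)
  Y <- array(rep(rep(yv, each = nz), nx), dims)

  zc <- geom$z_extent / 2
  s <- 1 - 0.08 * ((z - zc) / (geom$z_extent / 2))^2  # length nz, recycles
  a_ap <- spec$body_halfaxes_mm[["ap"]] * s
  a_lr <- spec$body_halfaxes_mm[["lr"]] * s
  rho <- sqrt((X / a_lr)^2 + (Y / a_ap)^2)

  tis <- array(CONSTR_CODES[["air"]], dims)
  inside <- rho <= 1
  interior <- rho <= 0.70
  abdominal <- z >= geom$pelvis_range[2] & z <= geom$lung_range[1]
  tis[inside & rho > 0.84] <- CONSTR_CODES[["SAT"]]
  tis[inside & rho <= 0.84 & rho > 0.70] <- CONSTR_CODES[["muscle"]]
  tis[interior & abdominal] <- CONSTR_CODES[["VAT"]]
  tis[interior & !abdominal] <- CONSTR_CODES[["other"]]

  ys <- 0.45 * a_ap
  tis[((X / 55)^2 + ((Y - ys) / 32)^2) <= 1 & interior] <-
    CONSTR_CODES[["muscle"]]

  in_spine <- (X^2 + (Y - ys)^2) <= geom$spine_r^2 & interior
  vid <- integer(nz)  # vertebra id per slice, 0 = none
  for (k in seq_len(spec$n_vertebrae))
    vid[z >= geom$vert_lo[k] & z <= geom$vert_hi[k]] <- k
  in_column <- z >= geom$vert_lo[1] & z <= geom$vert_hi[spec$n_vertebrae]
  tis[in_spine & (vid == 0 & in_column)] <- CONSTR_CODES[["disc"]]
  tis[in_spine & vid > 0] <- CONSTR_CODES[["bone"]]
  if (!is.na(implant_vert)) {
    core <- (X^2 + (Y - ys)^2) <= geom$implant_r^2 & interior
    tis[core & vid == implant_vert] <- CONSTR_CODES[["implant"]]
  }

  in_pelvis <- z >= geom$pelvis_range[1] & z <= geom$pelvis_range[2]
  tis[rho > 0.55 & rho <= 0.70 & in_pelvis] <- CONSTR_CODES[["bone"]]

  in_lung_z <- z >= geom$lung_range[1] & z <= geom$lung_range[2]
  zt <- ((z - geom$lung_cz) / geom$lung_az)^2
  for (side in c(-1, 1)) {
    lung <- (((X - side * 0.45 * a_lr) / (0.30 * a_lr))^2 +
             ((Y + 0.15 * a_ap) / (0.55 * a_ap))^2 + zt) <= 1 &
      interior & in_lung_z
    tis[lung] <- CONSTR_CODES[["lung"]]
  }

  arm <- array(FALSE, dims)
  if (spec$arms_present) {
    half_fov <- (nx - 1) / 2 * sx
    xa <- min(spec$body_halfaxes_mm[["lr"]] + 6 + 20, half_fov - 22)
    for (side in c(-1, 1)) {
      d2 <- (X - side * xa)^2 + Y^2
      rim <- d2 <= 20^2 & d2 > 14^2 & !inside
      core <- d2 <= 14^2 & !inside
      tis[rim] <- CONSTR_CODES[["SAT"]]
      tis[core] <- CONSTR_CODES[["muscle"]]
      tis[d2 <= 4^2 & !inside] <- CONSTR_CODES[["bone"]]
      arm <- arm | rim | core
    }
  }
  list(tissue = tis, arm = arm)
}

# Paint one axial slice: returns construction code matrix and an arm mask.
paint_slice <- function(spec, geom, z, implant_vert) {
  nz <- spec$shape_vox[1]; ny <- spec$shape_vox[2]; nx <- spec$shape_vox[3]
  sy <- spec$spacing_mm[2]; sx <- spec$spacing_mm[3]
  yv <- (seq_len(ny) - 1 - (ny - 1) / 2) * sy
  xv <- (seq_len(nx) - 1 - (nx - 1) / 2) * sx
  Y <- matrix(yv, ny, nx)
  X <- matrix(xv, ny, nx, byrow = TRUE)

  zc <- geom$z_extent / 2
  s <- 1 - 0.08 * ((z - zc) / (geom$z_extent / 2))^2
  a_ap <- spec$body_halfaxes_mm[["ap"]] * s
  a_lr <- spec$body_halfaxes_mm[["lr"]] * s
  rho <- sqrt((X / a_lr)^2 + (Y / a_ap)^2)

  tis <- matrix(CONSTR_CODES[["air"]], ny, nx)
  inside <- rho <= 1
  interior <- rho <= 0.70
  abdominal <- z >= geom$pelvis_range[2] && z <= geom$lung_range[1]
  tis[inside & rho > 0.84] <- CONSTR_CODES[["SAT"]]
  tis[inside & rho <= 0.84 & rho > 0.70] <- CONSTR_CODES[["muscle"]]
  tis[interior] <- if (abdominal) CONSTR_CODES[["VAT"]] else
    CONSTR_CODES[["other"]]

  # paraspinal muscle block around the spine
  ys <- 0.45 * a_ap
  paraspinal <- ((X / 55)^2 + ((Y - ys) / 32)^2) <= 1 & interior
  tis[paraspinal] <- CONSTR_CODES[["muscle"]]

  # vertebral column: bodies are bone (or implant), gaps are disc tissue
  in_spine <- (X^2 + (Y - ys)^2) <= geom$spine_r^2 & interior
  k <- which(z >= geom$vert_lo & z <= geom$vert_hi)
  if (length(k) == 1) {
    tis[in_spine] <- CONSTR_CODES[["bone"]]
    if (!is.na(implant_vert) && k == implant_vert) {
      core <- (X^2 + (Y - ys)^2) <= geom$implant_r^2 & interior
      tis[core] <- CONSTR_CODES[["implant"]]
    }
  } else if (z >= geom$vert_lo[1] && z <= geom$vert_hi[spec$n_vertebrae]) {
    tis[in_spine] <- CONSTR_CODES[["disc"]]
  }

  # pelvic bone ring
  if (z >= geom$pelvis_range[1] && z <= geom$pelvis_range[2])
    tis[rho > 0.55 & rho <= 0.70] <- CONSTR_CODES[["bone"]]

  # lungs: two ellipsoids in the cranial third, confined to the interior
  if (z >= geom$lung_range[1] && z <= geom$lung_range[2]) {
    for (side in c(-1, 1)) {
      lung <- (((X - side * 0.45 * a_lr) / (0.30 * a_lr))^2 +
               ((Y + 0.15 * a_ap) / (0.55 * a_ap))^2 +
               ((z - geom$lung_cz) / geom$lung_az)^2) <= 1 & interior
      tis[lung] <- CONSTR_CODES[["lung"]]
    }
  }

  arm <- matrix(FALSE, ny, nx)
  if (spec$arms_present) {
    half_fov <- (nx - 1) / 2 * sx
    xa <- min(spec$body_halfaxes_mm[["lr"]] + 6 + 20, half_fov - 22)
    for (side in c(-1, 1)) {
      d2 <- (X - side * xa)^2 + Y^2
      rim <- d2 <= 20^2 & d2 > 14^2
      core <- d2 <= 14^2
      bone <- d2 <= 4^2
      tis[rim & !inside] <- CONSTR_CODES[["SAT"]]
      tis[core & !inside] <- CONSTR_CODES[["muscle"]]
      tis[bone & !inside] <- CONSTR_CODES[["bone"]]
      arm <- arm | ((rim | core) & !inside)
    }
  }
  list(tissue = tis, arm = arm)
}

# Map construction codes + arm mask to ground-truth label codes.
constr_to_labels <- function(tis, arm) {
  lab <- matrix(TISSUE_CODES[["background"]], nrow(tis), ncol(tis))
  lab[tis %in% c(CONSTR_CODES[["bone"]], CONSTR_CODES[["disc"]],
                 CONSTR_CODES[["implant"]], CONSTR_CODES[["other"]],
                 CONSTR_CODES[["lung"]])] <- TISSUE_CODES[["other"]]
  lab[tis == CONSTR_CODES[["muscle"]]] <- TISSUE_CODES[["SM"]]
  lab[tis == CONSTR_CODES[["VAT"]]] <- TISSUE_CODES[["VAT"]]
  lab[tis == CONSTR_CODES[["SAT"]]] <- TISSUE_CODES[["SAT"]]
  lab[arm] <- TISSUE_CODES[["background"]]
  lab
}

# Draw HU for a construction-code array: truncated-normal per tissue, then
# optional global noise, clamped to the valid HU range and rounded to
# integers (CT stores integer HU).
draw_hu <- function(tis, spec) {
  hu <- array(0, dim = dim(tis))
  params <- list(
    "0" = spec$tissue_hu$air, "1" = spec$tissue_hu$lung,
    "2" = spec$tissue_hu$SAT, "3" = spec$tissue_hu$muscle,
    "4" = spec$tissue_hu$VAT, "5" = spec$tissue_hu$bone,
    "6" = c(90, 10), "7" = spec$tissue_hu$implant, "9" = c(40, 15))
  for (code in names(params)) {
    m <- tis == as.integer(code)
    n <- sum(m)
    if (n == 0) next
    p <- params[[code]]
    hu[m] <- p[1] + p[2] * pmax(pmin(rnorm(n), 3), -3)
  }
  if (spec$noise_sd_hu > 0)
    hu <- hu + rnorm(length(hu), sd = spec$noise_sd_hu)
  array(as.integer(round_half_up(pmin(pmax(hu, HU_RANGE[1]), HU_RANGE[2]))),
        dim = dim(tis))
}

#' Generate a synthetic abdominal CT phantom
#'
#' Builds the full 3-D HU volume and its ground truth from a
#' [phantom_spec()]. Deterministic given `spec$seed`: the same spec always
#' yields a bit-identical volume.
#'
#' @param spec a validated [phantom_spec()].
#' @param return_construction also return the per-voxel construction masks
#'   (tissue code array, arm mask, body mask) used by the painter; intended
#'   for validation against the generator's own geometry.
#' @return a list with elements `volume` (a [ct_volume()]), `truth` (list
#'   with `l3_z_mm`, `l3_slice_index` (0-based), `vertebra_extent_mm`,
#'   `tissue_labels` (a [tissue_label_map()] of the L3 slice), `height_m`,
#'   `lung_z_mm`, `pelvis_z_mm`, `implant_vertebra`, `spec`) and, when
#'   requested, `construction`.
#' @export
generate_phantom <- function(spec, return_construction = FALSE) {
  validate_phantom_spec(spec)
  geom <- phantom_geometry(spec)
  nz <- spec$shape_vox[1]; ny <- spec$shape_vox[2]; nx <- spec$shape_vox[3]
  sz <- spec$spacing_mm[1]
  with_seed(spec$seed, {
    implant_vert <- if (spec$implant_present)
      sample.int(min(5L, spec$n_vertebrae), 1) else NA_integer_
    pv <- paint_volume(spec, geom, implant_vert)
    tis <- pv$tissue
    arm <- pv$arm
    hu <- draw_hu(tis, spec)

    lung_vox <- which(tis == CONSTR_CODES[["lung"]], arr.ind = TRUE)
    lung_z <- if (nrow(lung_vox) > 0) mean(lung_vox[, 1] - 1) * sz else NA
    pelvis_vox <- which(tis == CONSTR_CODES[["bone"]] &
                          !arm, arr.ind = TRUE)
    pelvis_vox <- pelvis_vox[(pelvis_vox[, 1] - 1) * sz <
                               spec$column_base_mm, , drop = FALSE]
    pelvis_z <- if (nrow(pelvis_vox) > 0) mean(pelvis_vox[, 1] - 1) * sz
      else NA

    l3_slice <- min(max(geom$l3_slice, 0L), nz - 1L)
    labels <- constr_to_labels(tis[l3_slice + 1, , ], arm[l3_slice + 1, , ])
    truth <- list(
      l3_z_mm = geom$l3_z, l3_slice_index = l3_slice,
      vertebra_extent_mm = geom$l3_extent,
      tissue_labels = tissue_label_map(labels, spec$spacing_mm[2:3]),
      height_m = spec$patient_height_m,
      lung_z_mm = lung_z, pelvis_z_mm = pelvis_z,
      implant_vertebra = implant_vert, spec = spec)
    out <- list(volume = ct_volume(hu, spec$spacing_mm), truth = truth)
    if (return_construction) {
      body <- tis != CONSTR_CODES[["air"]] & tis != CONSTR_CODES[["lung"]] &
        !arm
      out$construction <- list(tissue = tis, arm = arm, body = body)
    }
    out
  })
}

#' Generate only the L3 axial slice of a phantom
#'
#' Paints and draws HU for the single ground-truth L3 slice of the phantom
#' described by `spec`, which is much cheaper than [generate_phantom()] when
#' only the body-composition task is of interest. The HU noise realization
#' differs from the corresponding full volume (the RNG stream is shorter)
#' but slice geometry and labels are identical.
#'
#' @inheritParams generate_phantom
#' @return list with `hu` (matrix, HU), `labels` (a [tissue_label_map()]),
#'   `l3_z_mm`, `height_m`, `spec`.
#' @export
generate_l3_sample <- function(spec) {
  validate_phantom_spec(spec)
  geom <- phantom_geometry(spec)
  sz <- spec$spacing_mm[1]
  with_seed(spec$seed, {
    implant_vert <- if (spec$implant_present)
      sample.int(min(5L, spec$n_vertebrae), 1) else NA_integer_
    l3_slice <- min(max(geom$l3_slice, 0L), spec$shape_vox[1] - 1L)
    ps <- paint_slice(spec, geom, l3_slice * sz, implant_vert)
    hu <- draw_hu(ps$tissue, spec)
    list(hu = matrix(hu, nrow(ps$tissue), ncol(ps$tissue)),
         labels = tissue_label_map(constr_to_labels(ps$tissue, ps$arm),
                                   spec$spacing_mm[2:3]),
         l3_z_mm = geom$l3_z, height_m = spec$patient_height_m, spec = spec)
  })
}

#' Default per-phantom variability for cohort generation
#'
#' The jitter ranges emulate the diversity of a multi-scanner clinical
#' cohort: slice thickness drawn from \{1, 2.5, 5\} mm, body size +/- ~15%,
#' L3 position via the column base, vertebral height +/- 15%, heights
#' 1.50-1.95 m, and hard-case fractions (20% arms in field, 10% implants).
#'
#' @return a named list of jitter ranges understood by [cohort_specs()].
#' @export
cohort_variability <- function() {
  list(spacing_z_mm = c(1, 2.5, 5),
       body_scale = c(0.85, 1.08),
       column_base_mm = c(-25, 25),
       vert_height_scale = c(0.85, 1.15),
       height_m = c(1.50, 1.95),
       arm_fraction = 0.2,
       implant_fraction = 0.1)
}

#' Draw the jittered specs of a phantom cohort
#'
#' Pure function of `(n, base_spec, variability, seed)`. The draw order is
#' fixed and documented so the sampling can be recomputed independently:
#' with the RNG seeded by `seed`, first `n` phantom seeds
#' (`sample.int(.Machine$integer.max, n)`), then slice thickness
#' (`sample(spacing_z_mm, n, replace = TRUE)`, drawn only when a
#' `spacing_z_mm` set is given), then `runif(n)` each for body scale,
#' column-base shift, vertebral-height scale and height (always drawn,
#' even for degenerate ranges), and finally `runif(n) < fraction` for
#' arms and for implants.
#'
#' @param n number of phantoms (>= 1).
#' @param base_spec the [phantom_spec()] to jitter.
#' @param variability jitter ranges, see [cohort_variability()]; fields may
#'   be omitted to keep the base value (an empty list jitters nothing).
#' @param seed integer seed.
#' @return list of `n` `phantom_spec` objects.
#' @export
cohort_specs <- function(n, base_spec = phantom_spec(),
                         variability = cohort_variability(), seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  v <- variability
  rng <- function(field, default) if (is.null(v[[field]])) default else
    v[[field]]
  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max, n)
    spacing <- if (is.null(v$spacing_z_mm))
      rep(base_spec$spacing_mm[1], n) else
      sample(v$spacing_z_mm, n, replace = TRUE)
    # raw uniforms are drawn unconditionally (and scaled by hand) so the
    # documented draw order holds even for degenerate jitter ranges
    scaled <- function(range) range[1] + (range[2] - range[1]) * runif(n)
    bscale <- scaled(rng("body_scale", c(1, 1)))
    cbase <- scaled(rng("column_base_mm", c(0, 0)))
    vhs <- scaled(rng("vert_height_scale", c(1, 1)))
    height <- scaled(rng("height_m", rep(base_spec$patient_height_m, 2)))
    arms <- runif(n) < rng("arm_fraction", 0)
    implant <- runif(n) < rng("implant_fraction", 0)

    z_extent <- (base_spec$shape_vox[1] - 1) * base_spec$spacing_mm[1]
    lapply(seq_len(n), function(i) {
      s <- base_spec
      s$spacing_mm[1] <- spacing[i]
      s$shape_vox[1] <- as.integer(round(z_extent / spacing[i]) + 1)
      s$body_halfaxes_mm <- base_spec$body_halfaxes_mm * bscale[i]
      s$column_base_mm <- base_spec$column_base_mm + cbase[i]
      s$vert_height_mm <- base_spec$vert_height_mm * vhs[i]
      s$disc_mm <- base_spec$disc_mm * vhs[i]
      s$patient_height_m <- height[i]
      s$arms_present <- arms[i]
      s$implant_present <- implant[i]
      s$seed <- seeds[i]
      validate_phantom_spec(s)
      s
    })
  })
}

#' Generate a cohort of phantoms
#'
#' Draws `n` jittered specs with [cohort_specs()] and generates each
#' phantom. Reproducible: a pure function of `(base_spec, variability,
#' seed)`.
#'
#' @inheritParams cohort_specs
#' @return list of `n` results of [generate_phantom()].
#' @export
generate_cohort <- function(n, base_spec = phantom_spec(),
                            variability = cohort_variability(), seed = 1L) {
  specs <- cohort_specs(n, base_spec, variability, seed)
  lapply(specs, generate_phantom)
}
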