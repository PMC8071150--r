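# Synthetic mouse micro-CBCT phantoms and HU-to-material calibration.
#
# The generator emulates the imaging chain's outputs, not the imaging
# physics: parametric head / thorax / abdomen anatomies on a 0.2 mm
# isotropic grid with body thickness 1.5--2.7 cm along the beam axis,
# +-40 HU noise injection, block-mean grid degradation to 0.4 / 0.8 mm,
# and a five-class stoichiometric-style calibration (air, lung, adipose,
# water-equivalent soft tissue, bone) with a continuous HU-to-density ramp.
#
# Coordinate convention: array axis 1 is the beam axis for lateral
# irradiation, axis 2 for anterior; voxel centers at (i - 0.5) * spacing;
# depth is measured from the phantom entrance surface.

.HU_MIN <- -1000
.HU_MAX <- 3000

voxel_phantom <- function(hu, spacing_mm, region, seed = NA_integer_) {
  stopifnot(length(dim(hu)) == 3)
  if (any(hu < .HU_MIN - 1e-9) || any(hu > .HU_MAX + 1e-9)) {
    stop("HU values must lie in [-1000, 3000]", call. = FALSE)
  }
  structure(list(hu = hu, spacing_mm = spacing_mm, region = region,
                 seed = seed),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$hu)
  cat(sprintf(
    "<voxel_phantom> %s: %d x %d x %d voxels at %.1f mm (%.1f x %.1f x %.1f mm), HU [%d, %d]\n",
    x$region, d[1], d[2], d[3], x$spacing_mm,
    d[1] * x$spacing_mm, d[2] * x$spacing_mm, d[3] * x$spacing_mm,
    round(min(x$hu)), round(max(x$hu))))
  invisible(x)
}

# Evaluate an expression with a seeded, restored RNG state.
with_phantom_seed <- function(seed, expr) {
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

#' Uniform water-cylinder phantom
#'
#' The biological-sample target as a voxel volume: HU = 0 everywhere,
#' 40 mm along the beam axis, 0.2 mm isotropic voxels.
#'
#' @param lateral_mm Transverse extent, mm.
#' @return A `voxel_phantom`.
#' @export
make_water_cylinder <- function(lateral_mm = 8) {
  n_lat <- round(lateral_mm / 0.2)
  voxel_phantom(array(0, dim = c(200, n_lat, n_lat)), 0.2, "water")
}

#' Synthetic mouse phantom
#'
#' Parametric anatomy, deterministic given `seed`:
#' * `brain`: soft-tissue ellipsoid inside a 0.6 mm bone (skull) shell,
#'   head width 16 mm along the beam axis;
#' * `lungs`: 20 mm thorax with two low-HU lung lobes (textured around
#'   -500 HU), a soft-tissue mediastinum and bone rib studs;
#' * `intestine`: 25.6 mm abdomen of soft tissue with randomized gas
#'   pockets.
#'
#' Body thicknesses along the lateral beam axis stay within the study's
#' 1.5--2.7 cm mouse range. All tissue HU include mild voxel texture so
#' grid degradation has realistic partial-volume behaviour.
#'
#' @param region `"brain"`, `"lungs"` or `"intestine"`.
#' @param seed Integer seed (default 1).
#' @return A `voxel_phantom` with 0.2 mm spacing.
#' @export
make_mouse_phantom <- function(region = c("brain", "lungs", "intestine"),
                               seed = 1L) {
  region <- match.arg(region)
  with_phantom_seed(seed, {
    dims <- switch(region,
                   brain = c(80, 64, 64),
                   lungs = c(100, 80, 60),
                   intestine = c(128, 96, 64))
    sp <- 0.2
    cx <- (seq_len(dims[1]) - 0.5) * sp - dims[1] * sp / 2
    cy <- (seq_len(dims[2]) - 0.5) * sp - dims[2] * sp / 2
    cz <- (seq_len(dims[3]) - 0.5) * sp - dims[3] * sp / 2
    X <- array(cx, dims)
    Y <- array(rep(cy, each = dims[1]), dims)
    Z <- array(rep(cz, each = dims[1] * dims[2]), dims)
    hu <- array(-1000, dims)
    texture <- function(idx, sd_hu) round(stats::rnorm(sum(idx), 0, sd_hu))

    if (region == "brain") {
      a <- 8.0; b <- 6.2; c <- 6.2       # outer skull semi-axes, mm
      r_out <- (X / a)^2 + (Y / b)^2 + (Z / c)^2
      shell <- 0.6                        # skull thickness, mm
      r_in <- (X / (a - shell))^2 + (Y / (b - shell))^2 + (Z / (c - shell))^2
      hu[r_out <= 1] <- 700               # bone shell
      inside <- r_in <= 1
      hu[inside] <- 40 + texture(inside, 8)   # brain soft tissue
    } else if (region == "lungs") {
      a <- 10.0; b <- 7.8                 # thorax semi-axes, mm
      body <- (X / a)^2 + (Y / b)^2 <= 1
      hu[body] <- 25 + texture(body, 8)
      for (s in c(-1, 1)) {
        lobe <- ((X - s * 4.9) / 3.6)^2 + (Y / 4.6)^2 + (Z / 5.2)^2 <= 1
        hu[lobe] <- -520 + texture(lobe, 45)
      }
      # rib studs on the body surface, periodic along the long axis
      rib_band <- abs((Z + 100 * sp) %% 2.4) < 0.8
      rib <- body & ((X / (a - 0.7))^2 + (Y / (b - 0.7))^2 > 1) & rib_band
      hu[rib] <- 650 + texture(rib, 30)
    } else {                              # intestine / abdomen
      a <- 12.8; b <- 9.6
      body <- (X / a)^2 + (Y / b)^2 <= 1
      hu[body] <- 30 + texture(body, 10)
      n_gas <- 24
      gx <- stats::runif(n_gas, -0.75 * a, 0.75 * a)
      gy <- stats::runif(n_gas, -0.75 * b, 0.75 * b)
      gz <- stats::runif(n_gas, min(cz) * 0.8, max(cz) * 0.8)
      gr <- stats::runif(n_gas, 0.5, 1.5)
      for (g in seq_len(n_gas)) {
        pocket <- body &
          ((X - gx[g])^2 + (Y - gy[g])^2 + (Z - gz[g])^2 <= gr[g]^2)
        hu[pocket] <- -800
      }
    }
    voxel_phantom(pmin(pmax(hu, .HU_MIN), .HU_MAX), sp, region, seed)
  })
}

#' Inject HU noise into a phantom
#'
#' `"uniform-offset"` (the budget scenario, matching the study's modification
#' of whole CBCT images in the range of +-40 HU) shifts every voxel by
#' `amplitude`; `"voxelwise"` adds independent uniform noise in
#' `[-amplitude, amplitude]` per voxel (exploratory). HU are clipped to the
#' valid range.
#'
#' @param phantom A `voxel_phantom`.
#' @param amplitude Signed offset (uniform-offset mode) or half-width
#'   (voxelwise mode), HU.
#' @param mode Noise mode.
#' @param seed Seed for the voxelwise mode.
#' @return The modified `voxel_phantom`.
#' @export
add_hu_noise <- function(phantom, amplitude = 40,
                         mode = c("uniform-offset", "voxelwise"), seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "uniform-offset") {
    hu <- phantom$hu + amplitude
  } else {
    if (amplitude < 0) stop("amplitude must be >= 0 in voxelwise mode",
                            call. = FALSE)
    hu <- with_phantom_seed(seed, {
      phantom$hu + stats::runif(length(phantom$hu), -amplitude, amplitude)
    })
  }
  phantom$hu <- pmin(pmax(hu, .HU_MIN), .HU_MAX)
  phantom
}

#' Degrade the phantom grid by block-mean pooling
#'
#' Emulates a coarser imaging grid (0.2 -> 0.4 or 0.8 mm): HU are averaged
#' over cubic blocks, conserving total HU mass exactly. Dose calculation
#' still scores on the 0.2 mm grid (materials are nearest-neighbour
#' upsampled when a column is extracted).
#'
#' @param phantom A `voxel_phantom`.
#' @param new_spacing_mm Target spacing; must be an integer multiple of the
#'   current spacing and divide the volume evenly.
#' @return The resampled `voxel_phantom`.
#' @export
resample_phantom <- function(phantom, new_spacing_mm) {
  k <- new_spacing_mm / phantom$spacing_mm
  if (abs(k - round(k)) > 1e-9 || k < 1) {
    stop("new spacing must be an integer multiple of the current spacing",
         call. = FALSE)
  }
  k <- as.integer(round(k))
  if (k == 1L) return(phantom)
  d <- dim(phantom$hu)
  if (any(d %% k != 0)) {
    stop("volume dimensions must be divisible by the pooling factor",
         call. = FALSE)
  }
  nd <- d %/% k
  # block mean, folding one axis at a time
  x <- phantom$hu
  dim(x) <- c(k, nd[1], d[2], d[3])            # split axis 1
  x <- colMeans(x)                              # (n1/k, n2, n3)
  dim(x) <- c(nd[1], k, nd[2], d[3])            # split axis 2
  x <- colMeans(aperm(x, c(2, 1, 3, 4)))        # (n1/k, n2/k, n3)
  dim(x) <- c(nd[1], nd[2], k, nd[3])           # split axis 3
  x <- colMeans(aperm(x, c(3, 1, 2, 4)))        # (n1/k, n2/k, n3/k)
  phantom$hu <- x
  phantom$spacing_mm <- new_spacing_mm
  phantom
}

# ---- HU calibration -------------------------------------------------------

#' Default HU-to-material calibration
#'
#' Five contiguous material classes covering HU [-1000, 3000] with a
#' continuous density ramp: the standard single-slope CT calibration
#' rho = 1 + HU/1000 below water (floored at air density) and a shallower
#' bone slope of 6e-4 g/cm^3 per HU above. The soft-tissue class is
#' water-equivalent, anchoring HU = 0 exactly to water at 1.000 g/cm^3.
#'
#' @param materials Material set.
#' @return An object of class `hu_calibration`.
#' @export
hu_calibration <- function(materials = default_materials()) {
  breaks <- data.frame(
    hu_min = c(-1000, -850, -200, -30, 120),
    hu_max = c(-850, -200, -30, 120, 3000),
    material = c("air", "lung", "adipose", "water", "bone"),
    stringsAsFactors = FALSE
  )
  structure(list(breaks = breaks, materials = materials,
                 density_fn = function(hu) {
                   ifelse(hu <= 0, pmax(1 + hu / 1000, 1.205e-3),
                          1 + 6e-4 * hu)
                 }),
            class = "hu_calibration")
}

#' Convert a phantom (or HU vector) to materials and densities
#'
#' @param hu HU values (any shape).
#' @param calibration An [hu_calibration()].
#' @param i_value_scale Multiplicative I-value scale applied to the tissue
#'   classes (see [assign_tissue_i_values()]).
#' @return List with `material` (names, same shape as `hu`), `density`
#'   (g/cm^3) and `materials` (the possibly I-scaled material set).
#' @export
hu_to_material <- function(hu, calibration = hu_calibration(),
                           i_value_scale = 1) {
  if (any(hu < .HU_MIN - 1e-9 | hu > .HU_MAX + 1e-9)) {
    stop("HU outside the calibration domain [-1000, 3000]", call. = FALSE)
  }
  br <- calibration$breaks
  idx <- findInterval(hu, c(br$hu_min, .HU_MAX + 1), rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(br))
  mats <- assign_tissue_i_values(calibration$materials, i_value_scale)
  list(material = array(br$material[idx], dim = if (is.null(dim(hu))) length(hu) else dim(hu)),
       density = calibration$density_fn(hu),
       materials = mats)
}

#' Scale tissue I-values
#'
#' Applies the +-6% tissue I-value uncertainty scenario: multiplies the
#' I-value of every tissue class (lung, adipose, water-equivalent soft
#' tissue, bone) by `scale`. Beamline materials and air are untouched.
#'
#' @param materials Material set.
#' @param scale Factor in [0.94, 1.06].
#' @return The modified material set.
#' @export
assign_tissue_i_values <- function(materials, scale = 1) {
  if (scale < 0.94 || scale > 1.06) {
    stop("tissue I-value scale must lie in [0.94, 1.06]", call. = FALSE)
  }
  if (scale == 1) return(materials)
  for (nm in c("lung", "adipose", "water", "bone")) {
    materials[[nm]]$i_value <- materials[[nm]]$i_value * scale
  }
  materials
}

# ---- Phantom columns ------------------------------------------------------

# Extract the central axial HU column of a phantom along the requested
# beam direction, upsampled back to 0.2 mm when the grid was degraded.
phantom_column <- function(phantom, axis = c("lateral", "anterior")) {
  axis <- match.arg(axis)
  d <- dim(phantom$hu)
  hu <- switch(axis,
               lateral = phantom$hu[, ceiling(d[2] / 2), ceiling(d[3] / 2)],
               anterior = phantom$hu[ceiling(d[1] / 2), , ceiling(d[3] / 2)])
  k <- as.integer(round(phantom$spacing_mm / .GRID_DZ_MM))
  if (k > 1L) hu <- rep(hu, each = k)     # nearest-neighbour upsampling
  hu
}

#' Depth dose along a phantom column
#'
#' Converts the central voxel column to a layered medium through the HU
#' calibration, trims the surrounding air so depth 0 is the phantom
#' entrance surface, appends a backing water tank (the study places one
#' behind the mouse to track the Bragg peak), and computes the Bragg curve.
#'
#' @param state A `beam_state` (mouse irradiations use the scatterer
#'   configuration).
#' @param phantom A `voxel_phantom`.
#' @param axis Beam direction: `"lateral"` (array axis 1) or `"anterior"`
#'   (array axis 2).
#' @param calibration An [hu_calibration()].
#' @param i_value_scale Tissue I-value scale (see
#'   [assign_tissue_i_values()]).
#' @param backing_water_mm Water tank length appended behind the phantom.
#' @param ... Passed to [bragg_curve()].
#' @return A `depth_dose`; depth 0 at the phantom entrance.
#' @export
phantom_depth_dose <- function(state, phantom, axis = "lateral",
                               calibration = hu_calibration(),
                               i_value_scale = 1, backing_water_mm = 25,
                               ...) {
  hu <- phantom_column(phantom, axis)
  conv <- hu_to_material(hu, calibration, i_value_scale)
  cls <- conv$material
  body <- which(cls != "air")
  if (length(body) == 0) stop("column does not intersect the phantom body",
                              call. = FALSE)
  keep <- body[1]:body[length(body)]     # interior gas pockets stay
  mats <- conv$materials[cls[keep]]
  density <- conv$density[keep]
  thickness <- rep(.GRID_DZ_MM, length(keep))
  if (backing_water_mm > 0) {
    mats <- c(mats, list(default_materials()$water))
    density <- c(density, 1.000)
    thickness <- c(thickness, backing_water_mm)
  }
  medium <- layered_medium(mats, density, thickness,
                           provenance = "phantom column")
  bragg_curve(state, medium, ...)
}
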