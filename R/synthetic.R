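#' Virtual water phantom and chamber geometry
#'
#' Describes the QA measurement setup the toy dose engine irradiates: a
#' rectangular water phantom with a cylindrical Farmer-type chamber at the
#' isocenter, chamber axis perpendicular to the gantry rotation plane.
#' Defaults reproduce the standard solid-water QA setup: 30x30x17 cm^3
#' phantom, 0.3 cm dose voxels, chamber at 8.5 cm depth, 100 cm SAD, and a
#' 0.65 cm^3 active volume (radius 0.3 cm, length 2.3 cm).
#'
#' Coordinates: isocenter at (0,0,0); x is the leaf-travel direction, y the
#' leaf-stack/chamber-axis direction, z vertical. The gantry rotates in the
#' x-z plane, angle 0 placing the source on +z (beam pointing down).
#'
#' @param size Phantom extent in cm, length-3 (x, y, z).
#' @param voxel Isotropic voxel size in cm.
#' @param sad Source-axis distance in cm.
#' @param chamber_depth Depth of the isocenter below the beam-entry surface
#'   at gantry 0, in cm.
#' @param chamber_radius,chamber_length Active air-cavity cylinder (cm).
#' @param contour_radius,contour_length Outer chamber contour cylinder (cm);
#'   the structure DVH metrics are computed on. The outer wall of a
#'   Farmer-type chamber (~0.7 cm diameter) is what gets contoured on the
#'   dose grid, and unlike the 0.3 cm cavity radius it rasterizes to a
#'   genuine 3D volume on a 0.3 cm lattice.
#' @param attenuation_mu Effective linear attenuation coefficient (1/cm);
#'   default 0.049, typical of a 6 MV photon beam in water.
#' @param penumbra_sigma Gaussian penumbra width (cm) of the aperture edges.
#' @param noise_sd_pct Pseudo-measurement noise SD in percent.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(30, 30, 17), voxel = 0.3, sad = 100,
                         chamber_depth = 8.5, chamber_radius = 0.3,
                         chamber_length = 2.3, contour_radius = 0.36,
                         contour_length = 2.4, attenuation_mu = 0.049,
                         penumbra_sigma = 0.3, noise_sd_pct = 0.5) {
  if (length(size) == 1L) size <- rep(size, 3L)
  check_finite(size, "size"); check_finite(voxel, "voxel")
  stopifnot(all(size > 0), voxel > 0, sad > 0, chamber_depth > 0)
  dims <- round(size / voxel)
  if (any(abs(dims * voxel - size) > voxel))
    stop_imrtqa("voxel must divide the phantom extents to within one voxel")
  # Lattice centered on the isocenter (chamber center), with any offset of
  # the chamber from the phantom mid-plane snapped to whole voxels. Keeping
  # the voxel centers mirror-symmetric about the chamber avoids spurious
  # sampling asymmetries in the chamber-volume averages; the effective
  # surface depth is chamber_depth up to half a voxel of quantization.
  z_shift <- round((chamber_depth - size[3L] / 2) / voxel) * voxel
  origin <- c(-dims[1L] * voxel / 2, -dims[2L] * voxel / 2,
              -dims[3L] * voxel / 2 + z_shift)
  if (chamber_radius >= min(size[1L] / 2, size[3L] - chamber_depth,
                            chamber_depth) ||
      chamber_length / 2 >= size[2L] / 2)
    stop_imrtqa("chamber must lie fully inside the phantom")
  structure(
    list(size = as.numeric(size), voxel = as.numeric(voxel), sad = sad,
         chamber_depth = chamber_depth, chamber_radius = chamber_radius,
         chamber_length = chamber_length, contour_radius = contour_radius,
         contour_length = contour_length, attenuation_mu = attenuation_mu,
         penumbra_sigma = penumbra_sigma, noise_sd_pct = noise_sd_pct,
         dims = as.integer(dims), origin = origin),
    class = "phantom_spec")
}

#' Empty dose grid and chamber masks on a phantom lattice
#'
#' @param spec A [phantom_spec()].
#' @return `phantom_grid()` returns a zero [dose_grid()];
#'   `chamber_cylinder_mask()` the air-cavity mask,
#'   `chamber_contour_mask()` the outer chamber-contour mask (the structure
#'   DVH metrics are evaluated on), and `chamber_sphere_mask()` the
#'   cavity-equal-volume water-sphere mask, all at the isocenter.
#' @export
phantom_grid <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dose_grid(spec$origin, spec$voxel, array(0, spec$dims))
}

#' @rdname phantom_grid
#' @export
chamber_cylinder_mask <- function(spec) {
  m <- cylinder_mask(phantom_grid(spec), c(0, 0, 0), spec$chamber_radius,
                     spec$chamber_length, name = "chamber")
  if (!any(m$voxels))
    stop_imrtqa("chamber radius ", spec$chamber_radius,
                " cm is below the lattice resolution (voxel ", spec$voxel,
                " cm): no voxel center falls inside the cavity")
  m
}

#' @rdname phantom_grid
#' @export
chamber_contour_mask <- function(spec) {
  m <- cylinder_mask(phantom_grid(spec), c(0, 0, 0), spec$contour_radius,
                     spec$contour_length, name = "chamber_contour")
  if (!any(m$voxels))
    stop_imrtqa("chamber contour radius ", spec$contour_radius,
                " cm is below the lattice resolution")
  m
}

#' @rdname phantom_grid
#' @export
chamber_sphere_mask <- function(spec) {
  vol <- pi * spec$chamber_radius^2 * spec$chamber_length
  r <- (3 * vol / (4 * pi))^(1 / 3)
  sphere_mask(phantom_grid(spec), c(0, 0, 0), r, name = "water_sphere")
}

#' Generate a randomized multi-beam step-and-shoot plan
#'
#' Beams are placed at evenly spaced gantry angles over the full circle.
#' With `modulation = 0` every segment is the same static rectangular
#' aperture, so the plan's modulation complexity score is exactly 1. As
#' `modulation` rises toward 1 the segments turn into the discretized
#' sliding-window pattern of dynamic IMRT: a narrowing slit (down to a
#' quarter of the field at full modulation) sweeping across the field from
#' segment to segment, with independent per-leaf edge jitter, a random
#' lateral shift per segment, and unequal segment MU weights — jagged,
#' smaller, offset apertures and a lower MCS.
#'
#' @param n_beams Number of beams (`>= 1`).
#' @param n_segments Segments per beam.
#' @param modulation Modulation depth in `[0, 1]`.
#' @param seed Integer seed; the plan is a pure function of the arguments.
#' @param n_leaf_pairs Leaf pairs per bank.
#' @param leaf_width Leaf width (cm) in the stack direction.
#' @param field_size Base aperture side (cm).
#' @return An [rt_plan()].
#' @export
generate_plan <- function(n_beams, n_segments = 6, modulation = 0.6,
                          seed = 1, n_leaf_pairs = 20, leaf_width = 0.5,
                          field_size = 8) {
  stopifnot(n_beams >= 1, n_segments >= 1,
            modulation >= 0, modulation <= 1)
  with_seed(seed, {
    angles <- (seq_len(n_beams) - 1) * 360 / n_beams
    y_centers <- (seq_len(n_leaf_pairs) - (n_leaf_pairs + 1) / 2) * leaf_width
    open_rows <- abs(y_centers) <= field_size / 2
    beams <- lapply(angles, function(theta) {
      beam_mu <- stats::runif(1, 50, 150)
      # each beam aims its aperture envelope off-axis by its own amount, as
      # clinical beams conform to an off-center target from their own
      # direction; collapsed delivery stacks these gradients along one axis
      beam_offset <- modulation * stats::runif(1, -3.5, 3.5)
      w <- exp(modulation * stats::rnorm(n_segments))
      w <- w / sum(w) * beam_mu
      # slit width shrinks and its center sweeps across the field as
      # modulation grows; at modulation 0 every segment is the full field
      width <- field_size * (1 - 0.75 * modulation)
      sweep <- if (n_segments > 1)
        ((seq_len(n_segments) - 1) / (n_segments - 1) - 0.5) *
          (field_size - width) else rep(0, n_segments)
      segs <- lapply(seq_len(n_segments), function(i) {
        left <- rep(0, n_leaf_pairs)
        right <- rep(0, n_leaf_pairs)
        shift <- beam_offset + modulation * stats::runif(1, -0.5, 0.5)
        nr <- sum(open_rows)
        left[open_rows] <- sweep[i] + width / 2 + shift -
          modulation * stats::runif(nr, 0, 0.25)
        right[open_rows] <- sweep[i] - width / 2 + shift +
          modulation * stats::runif(nr, 0, 0.25)
        left <- pmax(left, right)
        mlc_segment(left, right, w[i])
      })
      rt_beam(gantry_deg = theta, segments = segs, beam_mu = beam_mu)
    })
    rt_plan(plan_id = sprintf("synthetic-seed%d", as.integer(seed)),
            beams = beams)
  })
}

# Per-beam-angle geometry shared by all segments: projected isocenter-plane
# coordinates (u along leaf travel, w along the leaf stack), leaf-pair index
# per voxel, and the attenuation * inverse-square factor.
.beam_geometry <- function(theta_deg, spec, n_leaf_pairs, leaf_width) {
  g <- phantom_grid(spec)
  th <- theta_deg * pi / 180
  s <- spec$sad * c(sin(th), 0, cos(th))     # source position
  cx <- axis_centers(g, 1L); cy <- axis_centers(g, 2L)
  cz <- axis_centers(g, 3L)
  d <- g$dims
  vx <- array(rep(cx, times = d[2L] * d[3L]), d)
  vy <- array(rep(rep(cy, each = d[1L]), times = d[3L]), d)
  vz <- array(rep(cz, each = d[1L] * d[2L]), d)
  dx <- vx - s[1L]; dy <- vy - s[2L]; dz <- vz - s[3L]
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  # unit beam axis from source toward isocenter is -s / sad
  axis_comp <- -(dx * s[1L] + dz * s[3L]) / spec$sad
  t <- spec$sad / axis_comp                  # scale to the isocenter plane
  u <- t * (dx * cos(th) - dz * sin(th))     # leaf-travel coordinate
  w <- t * dy                                # leaf-stack coordinate
  # water-equivalent depth: ray entry into the phantom box
  lo <- g$origin; hi <- g$origin + d * g$spacing
  eps <- 1e-12
  dxs <- ifelse(abs(dx) < eps, eps, dx)
  dys <- ifelse(abs(dy) < eps, eps, dy)
  dzs <- ifelse(abs(dz) < eps, eps, dz)
  t_in <- pmax(pmin((lo[1L] - s[1L]) / dxs, (hi[1L] - s[1L]) / dxs),
               pmin((lo[2L] - s[2L]) / dys, (hi[2L] - s[2L]) / dys),
               pmin((lo[3L] - s[3L]) / dzs, (hi[3L] - s[3L]) / dzs))
  depth <- pmax(1 - t_in, 0) * dist
  attn <- exp(-spec$attenuation_mu * depth) * (spec$sad / dist)^2
  # leaf-pair index along the stack (NA outside the bank)
  v_lo <- -n_leaf_pairs * leaf_width / 2
  idx <- floor((w - v_lo) / leaf_width) + 1
  idx[idx < 1 | idx > n_leaf_pairs] <- NA_integer_
  list(grid = g, u = u, idx = idx, attn = attn, leaf_width = leaf_width)
}

#' Toy divergent-aperture dose engine
#'
#' A deterministic geometric stand-in for a per-beam dose calculation. For
#' each segment, every voxel center is projected along the divergent ray
#' from the gantry-angle-dependent source position to the isocenter plane;
#' the segment contributes
#' `mu_weight/100 * fluence * exp(-mu * depth) * (SAD / source-voxel distance)^2`,
#' where the fluence is the aperture indicator of the voxel's leaf pair with
#' Gaussian-smoothed edges (`penumbra_sigma`) in the leaf-travel direction,
#' and `depth` is the water-equivalent path from the phantom surface.
#' Segments are summed. The engine models no scatter, no leaf transmission
#' and no spectral effects; it is a fast geometric emulator, not a
#' dosimetric engine, and its output is in nominal Gy (100 MU of open field
#' give ~1 Gy before attenuation).
#'
#' @param beam An [rt_beam()].
#' @param spec A [phantom_spec()].
#' @param leaf_width Leaf width (cm) matching the plan's MLC.
#' @return A [dose_grid()] of the beam dose.
#' @export
toy_beam_dose <- function(beam, spec, leaf_width = 0.5) {
  stopifnot(inherits(beam, "rt_beam"), inherits(spec, "phantom_spec"))
  A <- n_leaf_pairs(beam)
  geom <- .beam_geometry(beam$gantry_deg, spec, A, leaf_width)
  .segments_dose(beam$segments, geom, spec)
}

.segments_dose <- function(segments, geom, spec) {
  total <- array(0, geom$grid$dims)
  sigma <- spec$penumbra_sigma
  ok <- !is.na(geom$idx)
  u_ok <- geom$u[ok]; idx_ok <- geom$idx[ok]; attn_ok <- geom$attn[ok]
  acc <- numeric(sum(ok))
  # penumbra across leaf rows: mix each voxel's row with its neighbours
  # using the Gaussian integrated over the leaf width (evaluated at row
  # centers); rows outside the bank contribute zero fluence
  lw <- geom$leaf_width
  wc <- stats::pnorm(lw / 2 / sigma) - stats::pnorm(-lw / 2 / sigma)
  ws <- stats::pnorm(1.5 * lw / sigma) - stats::pnorm(0.5 * lw / sigma)
  wts <- c(ws, wc, ws) / (wc + 2 * ws)
  A <- length(segments[[1L]]$left_positions)
  row_fluence <- function(s, idx) {
    inb <- !is.na(idx) & idx >= 1L & idx <= A
    fl <- numeric(length(idx))
    i <- idx[inb]
    fl[inb] <- stats::pnorm((s$left_positions[i] - u_ok[inb]) / sigma) -
      stats::pnorm((s$right_positions[i] - u_ok[inb]) / sigma)
    fl
  }
  for (s in segments) {
    if (s$mu_weight == 0) next
    fl <- wts[1L] * row_fluence(s, idx_ok - 1L) +
          wts[2L] * row_fluence(s, idx_ok) +
          wts[3L] * row_fluence(s, idx_ok + 1L)
    acc <- acc + (s$mu_weight / 100) * fl * attn_ok
  }
  total[ok] <- acc
  dose_grid(geom$grid$origin, geom$grid$spacing, total)
}

# All per-beam doses of a plan, computing the per-angle geometry once per
# unique gantry angle (collapsed plans share a single geometry).
toy_plan_doses <- function(plan, spec, leaf_width = 0.5) {
  stopifnot(inherits(plan, "rt_plan"))
  angles <- vapply(plan$beams, `[[`, numeric(1), "gantry_deg")
  out <- vector("list", length(plan$beams))
  for (theta in unique(angles)) {
    js <- which(angles == theta)
    geom <- .beam_geometry(theta, spec, n_leaf_pairs(plan$beams[[js[1L]]]),
                           leaf_width)
    for (j in js)
      out[[j]] <- .segments_dose(plan$beams[[j]]$segments, geom, spec)
  }
  out
}

#' The 10x10 cm^2 reference field as a beam object
#'
#' A single static rectangular segment of the given side length, used as the
#' reference field in the [k_qclin()] surrogate computation.
#'
#' @param side Field side (cm), default 10.
#' @param mu Monitor units.
#' @param n_leaf_pairs,leaf_width MLC geometry.
#' @return An [rt_beam()] at gantry 0.
#' @export
reference_field_beam <- function(side = 10, mu = 100, n_leaf_pairs = 20,
                                 leaf_width = 0.5) {
  y_centers <- (seq_len(n_leaf_pairs) - (n_leaf_pairs + 1) / 2) * leaf_width
  open_rows <- abs(y_centers) <= side / 2
  left <- ifelse(open_rows, side / 2, 0)
  right <- ifelse(open_rows, -side / 2, 0)
  rt_beam(0, list(mlc_segment(left, right, mu)), mu)
}

#' Simulate one QA patient: paired rotated and collapsed deliveries
#'
#' Generates a seeded plan, computes per-beam toy dose grids for the rotated
#' delivery (planned gantry angles) and the collapsed delivery (every beam
#' at `collapsed_angle`), assigns each beam grid a deterministic Type-A
#' pseudo-uncertainty that scales like particle statistics
#' (`u0 * sqrt(mean beam chamber dose / beam chamber dose)`, capped at
#' 10%), and draws one noisy scalar pseudo-measurement of the chamber dose
#' per mode. The pseudo-measurement emulates an *uncorrected* chamber-derived
#' dose: the cavity-average dose scaled by the reference-field
#' water-to-cavity ratio, times `(1 + e)` with
#' `e ~ N(0, noise_sd_pct / 100)`; multiplying it by the plan's
#' [k_qclin()] factor recovers the water-sphere dose up to noise.
#'
#' @param config List of study-condition settings; recognized entries (with
#'   defaults): `n_beams` (9), `n_segments` (6), `modulation` (0.6),
#'   `collapsed_angle` (0), `spec` ([phantom_spec()]), `leaf_width` (0.5),
#'   `u0_pct` (0.25).
#' @param seed Integer seed; the full case is a pure function of
#'   `(config, seed)`.
#' @return An object of class `synthetic_case` with the plan, per-beam dose
#'   grids for both modes, the two pseudo-measurements, and the inputs.
#' @export
simulate_patient <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(
    list(n_beams = 9, n_segments = 6, modulation = 0.6, collapsed_angle = 0,
         spec = phantom_spec(), leaf_width = 0.5, u0_pct = 0.25),
    config)
  spec <- cfg$spec
  plan <- generate_plan(cfg$n_beams, cfg$n_segments, cfg$modulation,
                        seed = seed, leaf_width = cfg$leaf_width)
  rotated <- toy_plan_doses(plan, spec, cfg$leaf_width)
  collapsed_plan <- collapse_plan(plan, cfg$collapsed_angle)
  collapsed <- toy_plan_doses(collapsed_plan, spec, cfg$leaf_width)

  chamber <- chamber_cylinder_mask(spec)
  assign_unc <- function(doses) {
    ch <- vapply(doses, function(g) mean(g$values[chamber$voxels]),
                 numeric(1))
    ref <- mean(ch)
    u <- ifelse(ch > 0, cfg$u0_pct * sqrt(ref / pmax(ch, 1e-12)), 10)
    u <- pmin(u, 10)
    Map(function(g, ui) { g$rel_uncertainty_pct <- ui; g }, doses, u)
  }
  rotated <- assign_unc(rotated)
  collapsed <- assign_unc(collapsed)

  # reference-field water/cavity ratio for the pseudo-measurement model
  sphere <- chamber_sphere_mask(spec)
  ref_dose <- toy_beam_dose(reference_field_beam(
    n_leaf_pairs = n_leaf_pairs(plan$beams[[1L]]),
    leaf_width = cfg$leaf_width), spec, cfg$leaf_width)
  ref_ratio <- mean(ref_dose$values[sphere$voxels]) /
    mean(ref_dose$values[chamber$voxels])

  meas <- with_seed(seed + 1000003, {
    sapply(list(rotated, collapsed), function(doses) {
      total <- sum_beam_doses(doses)
      dair <- mean(total$values[chamber$voxels])
      dair * ref_ratio * (1 + stats::rnorm(1, 0, spec$noise_sd_pct / 100))
    })
  })

  structure(
    list(plan = plan, collapsed_plan = collapsed_plan,
         rotated_beam_doses = rotated, collapsed_beam_doses = collapsed,
         pseudo_measurement_rotated = meas[[1L]],
         pseudo_measurement_collapsed = meas[[2L]],
         reference_beam_dose = ref_dose,
         seed = seed, config = cfg),
    class = "synthetic_case")
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat("synthetic QA case (seed ", x$seed, "): ", length(x$plan$beams),
      " beams, modulation ", x$config$modulation, "\n", sep = "")
  cat("  pseudo-measurements [Gy]: rotated ",
      format(x$pseudo_measurement_rotated, digits = 5), ", collapsed ",
      format(x$pseudo_measurement_collapsed, digits = 5), "\n", sep = "")
  invisible(x)
}
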