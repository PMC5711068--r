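# Toy-engine and generator checks run on a reduced lattice (0.6 cm voxels)
# where a full-resolution grid is not needed; the physics checks are
# resolution-independent.
# the chamber radius is scaled with the voxel so the cavity stays resolved
coarse_spec <- function(...) {
  phantom_spec(voxel = 0.6, chamber_radius = 0.5, contour_radius = 0.55, ...)
}

test_that("phantom lattice is voxel-consistent and chamber-centered", {
  spec <- phantom_spec()
  expect_equal(spec$dims, c(100L, 100L, 57L))
  g <- phantom_grid(spec)
  # voxel centers are mirror-symmetric about the isocenter on every axis
  for (ax in 1:3) {
    cen <- imrtqa:::axis_centers(g, ax)
    expect_equal(cen, -rev(cen))
  }
  ch <- chamber_cylinder_mask(spec)
  # Farmer-like cavity: on the lattice, the rasterized volume approximates
  # the 0.65 cc cylinder to within the voxelization error
  expect_gt(ch$volume_cc, 0.4); expect_lt(ch$volume_cc, 1.1)
  sp <- chamber_sphere_mask(spec)
  expect_gt(sp$volume_cc, 0.4); expect_lt(sp$volume_cc, 1.1)
  expect_error(phantom_spec(chamber_length = 40), "inside the phantom")
})

test_that("generated plans are seeded, valid and modulation-responsive", {
  p1 <- generate_plan(7, 5, 0.5, seed = 9)
  p2 <- generate_plan(7, 5, 0.5, seed = 9)
  expect_identical(p1, p2)
  expect_length(p1$beams, 7)
  # gantry angles span the full circle
  ang <- vapply(p1$beams, `[[`, numeric(1), "gantry_deg")
  expect_gte(diff(range(ang)), 180)
  # modulation 0 is the static rectangular plan: MCS exactly 1
  expect_equal(plan_mcs(generate_plan(5, 4, 0, seed = 3)), 1)
  # mean MCS strictly decreases with modulation depth
  levels <- c(0, 0.25, 0.5, 0.75, 1)
  mean_mcs <- vapply(levels, function(m) {
    mean(vapply(1:15, function(s)
      plan_mcs(generate_plan(5, 5, m, seed = s)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_mcs) < 0))
})

test_that("central-axis dose follows attenuation times inverse square", {
  # odd lateral dims put a voxel-center column exactly on the beam axis
  spec <- phantom_spec(size = c(30.3, 30.3, 17.1), voxel = 0.3)
  g <- toy_beam_dose(reference_field_beam(), spec)
  d <- spec$dims
  prof <- g$values[(d[1] + 1) / 2, (d[2] + 1) / 2, ]
  z <- imrtqa:::axis_centers(g, 3)
  z_top <- spec$origin[3] + d[3] * spec$voxel
  fluence <- pnorm(5 / spec$penumbra_sigma) - pnorm(-5 / spec$penumbra_sigma)
  closed <- fluence * exp(-spec$attenuation_mu * (z_top - z)) *
    (spec$sad / (spec$sad - z))^2
  expect_equal(prof, closed, tolerance = 1e-6)
})

test_that("opposed beams are mirror images on a symmetric phantom", {
  spec <- phantom_spec(size = c(15, 15, 15), chamber_depth = 7.5,
                       voxel = 0.3)
  seg <- mlc_segment(rep(3, 20), rep(-3, 20), 50)
  g0 <- toy_beam_dose(rt_beam(0, list(seg)), spec)
  g180 <- toy_beam_dose(rt_beam(180, list(seg)), spec)
  flipped <- g180$values[, , rev(seq_len(dim(g180$values)[3]))]
  expect_equal(g0$values, flipped, tolerance = 1e-12)
  # 90 vs 270 mirror in x likewise
  g90 <- toy_beam_dose(rt_beam(90, list(seg)), spec)
  g270 <- toy_beam_dose(rt_beam(270, list(seg)), spec)
  expect_equal(g90$values,
               g270$values[rev(seq_len(dim(g270$values)[1])), , ],
               tolerance = 1e-12)
})

test_that("zero-MU segments deposit nothing and doses stay finite", {
  spec <- coarse_spec()
  b <- rt_beam(0, list(mlc_segment(rep(2, 20), rep(-2, 20), 0),
                       mlc_segment(rep(2, 20), rep(-2, 20), 10)))
  g <- toy_beam_dose(b, spec)
  half <- toy_beam_dose(rt_beam(0, list(mlc_segment(rep(2, 20),
                                                    rep(-2, 20), 10))), spec)
  expect_equal(g$values, half$values)
  expect_true(all(is.finite(g$values)) && all(g$values >= 0))
})

test_that("simulated cases are deterministic and MU-consistent", {
  cfg <- list(n_beams = 5, n_segments = 3, spec = coarse_spec())
  c1 <- simulate_patient(cfg, seed = 21)
  c2 <- simulate_patient(cfg, seed = 21)
  expect_identical(c1, c2)
  # collapse preserves the total MU exactly
  expect_identical(c1$collapsed_plan$plan_mu, c1$plan$plan_mu)
  expect_true(all(vapply(c1$collapsed_plan$beams, `[[`, numeric(1),
                         "gantry_deg") == 0))
  # per-beam dose lists match the plan one-to-one
  expect_length(c1$rotated_beam_doses, 5)
  expect_length(c1$collapsed_beam_doses, 5)
  # complexity identical across modes
  expect_identical(plan_mcs(c1$plan), plan_mcs(c1$collapsed_plan))
  # chamber dose positive, pseudo-measurements near it
  ch <- chamber_cylinder_mask(cfg$spec)
  tot <- sum_beam_doses(c1$rotated_beam_doses)
  expect_gt(mean(tot$values[ch$voxels]), 0)
  expect_gt(c1$pseudo_measurement_rotated, 0)
})

test_that("a generated case feeds the full metric chain coherently", {
  cfg <- list(n_beams = 6, n_segments = 3, modulation = 0.5,
              spec = coarse_spec())
  case <- simulate_patient(cfg, seed = 8)
  rep <- run_comparison(case)
  expect_s3_class(rep, "qa_report")
  for (mode in c("rotated", "collapsed")) {
    m <- rep[[mode]]
    expect_true(is.finite(m$hi) && m$hi >= 0)
    expect_true(m$coin >= 0 && m$coin <= 1)
    expect_true(m$intersection_fraction >= 0 &&
                m$intersection_fraction <= 1)
    expect_gt(m$k_qclin, 0.9); expect_lt(m$k_qclin, 1.1)
    expect_gt(m$chamber_mean_dose_gy, 0)
    expect_true(is.finite(m$combined_uncertainty_pct))
  }
  expect_identical(rep$rotated$mcs_plan, rep$collapsed$mcs_plan)
})

test_that("an unmodulated crossfire plan is homogeneous at the chamber", {
  cfg <- list(n_beams = 8, n_segments = 2, modulation = 0,
              spec = coarse_spec())
  case <- simulate_patient(cfg, seed = 4)
  rep <- run_comparison(case)
  # every beam covers the chamber; HI limited only by engine gradients
  expect_equal(rep$rotated$intersection_fraction, 1)
  expect_equal(rep$collapsed$intersection_fraction, 1)
  expect_lt(rep$rotated$hi, 0.05)
  expect_equal(rep$mcs_plan, 1)
})
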