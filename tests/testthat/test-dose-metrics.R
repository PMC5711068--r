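test_that("cumulative DVH is the exact voxel-rank curve", {
  g <- dose_grid(c(0, 0, 0), 1, array(c(1, 2, 3, 4), c(4, 1, 1)))
  m <- structure_mask("s", array(TRUE, c(4, 1, 1)), g)
  dvh <- cumulative_dvh(g, m)
  expect_equal(dvh$dose_edges, c(1, 2, 3, 4))
  expect_equal(dvh$cum_volume_fraction, c(1, 0.75, 0.5, 0.25))
  # uniform dose: a single step at the dose value
  gu <- dose_grid(c(0, 0, 0), 1, array(2, c(3, 3, 1)))
  mu <- structure_mask("s", array(TRUE, c(3, 3, 1)), gu)
  du <- cumulative_dvh(gu, mu)
  expect_equal(du$dose_edges, 2)
  expect_equal(du$cum_volume_fraction, 1)
  # scaling doses scales edges, not fractions
  g2 <- dose_grid(c(0, 0, 0), 1, g$values * 3)
  d2 <- cumulative_dvh(g2, m)
  expect_equal(d2$dose_edges, dvh$dose_edges * 3)
  expect_equal(d2$cum_volume_fraction, dvh$cum_volume_fraction)
  expect_error(cumulative_dvh(g, structure_mask("e", array(FALSE, c(4, 1, 1)),
                                                g)), "empty")
})

test_that("dose_at_volume follows the descending voxel-rank convention", {
  g <- dose_grid(c(0, 0, 0), 1, array(1:100, c(100, 1, 1)))
  m <- structure_mask("s", array(TRUE, c(100, 1, 1)), g)
  dvh <- cumulative_dvh(g, m)
  expect_equal(dose_at_volume(dvh, 2), 99)
  expect_equal(dose_at_volume(dvh, 98), 3)
  expect_equal(dose_at_volume(dvh, 100), 1)
  expect_error(dose_at_volume(dvh, 0), "volume_pct")
})

test_that("DVH quantities agree with a brute-force sort on random grids", {
  for (seed in 1:8) {
    g <- random_grid(seed, dims = c(11, 9, 7))
    set.seed(seed + 500)
    mask_arr <- array(runif(prod(dim(g$values))) < 0.4, dim(g$values))
    if (!any(mask_arr)) next
    m <- structure_mask("s", mask_arr, g)
    doses <- g$values[mask_arr]
    dvh <- cumulative_dvh(g, m)
    for (pct in c(2, 25, 50, 98, 100))
      expect_equal(dose_at_volume(dvh, pct),
                   oracle_dose_at_volume(doses, pct))
    expect_equal(homogeneity_index(g, m), oracle_hi(doses))
  }
})

test_that("homogeneity index limits and scale invariance hold", {
  gu <- dose_grid(c(0, 0, 0), 1, array(5, c(4, 4, 2)))
  mu <- structure_mask("s", array(TRUE, c(4, 4, 2)), gu)
  expect_equal(homogeneity_index(gu, mu), 0)
  g <- dose_grid(c(0, 0, 0), 1, array(1:100, c(100, 1, 1)))
  m <- structure_mask("s", array(TRUE, c(100, 1, 1)), g)
  expect_equal(homogeneity_index(g, m), (99 - 3) / 50.5)
  gk <- dose_grid(c(0, 0, 0), 1, g$values * 7.3)
  expect_equal(homogeneity_index(gk, m), homogeneity_index(g, m))
})

test_that("mask expansion is a Euclidean dilation", {
  g <- dose_grid(c(0, 0, 0), 1, array(0, c(7, 7, 7)))
  single <- array(FALSE, c(7, 7, 7)); single[4, 4, 4] <- TRUE
  m <- structure_mask("pt", single, g)
  expect_identical(expand_mask(m, 0)$voxels, m$voxels)
  # margin of one voxel spacing: the 7-voxel face-neighbour cross
  e1 <- expand_mask(m, 1)
  expect_equal(sum(e1$voxels), 7)
  expect_true(all(e1$voxels[cbind(c(4, 3, 5, 4, 4, 4, 4),
                                  c(4, 4, 4, 3, 5, 4, 4),
                                  c(4, 4, 4, 4, 4, 3, 5))]))
  # against a brute-force distance check, including anisotropic spacing
  ga <- dose_grid(c(0, 0, 0), c(0.5, 1, 2), array(0, c(9, 7, 5)))
  set.seed(31)
  arr <- array(runif(9 * 7 * 5) < 0.05, c(9, 7, 5))
  arr[5, 4, 3] <- TRUE
  ma <- structure_mask("s", arr, ga)
  margin <- 1.6
  got <- expand_mask(ma, margin)
  centers <- as.matrix(expand.grid(x = (1:9 - 0.5) * 0.5,
                                   y = (1:7 - 0.5) * 1,
                                   z = (1:5 - 0.5) * 2))
  true_idx <- which(arr)
  want <- vapply(seq_len(nrow(centers)), function(i) {
    d2 <- colSums((t(centers[true_idx, , drop = FALSE]) - centers[i, ])^2)
    any(d2 <= margin^2)
  }, logical(1))
  expect_identical(as.vector(got$voxels), want)
  # dilation is monotone in the margin and contains the original
  expect_true(all(got$voxels[arr]))
  expect_true(all(got$voxels | !expand_mask(ma, 0.8)$voxels))
})

test_that("COIN matches direct counting and is scale invariant", {
  # chamber fully covered, half the shell covered: COIN = 1 * 100/200
  vals <- array(0, c(10, 10, 6))
  ch <- array(FALSE, c(10, 10, 6)); ch[3:7, 3:6, 2:6] <- TRUE   # 100 voxels
  sh <- array(FALSE, c(10, 10, 6)); sh[1:10, 1:8, 2:6] <- TRUE  # 400 voxels
  vals[ch] <- 2
  extra <- which(sh & !ch)[1:100]
  vals[extra] <- 3                               # 200 shell voxels >= RI = 2
  g <- dose_grid(c(0, 0, 0), 1, vals)
  cm <- structure_mask("ch", ch, g); sm <- structure_mask("sh", sh, g)
  expect_equal(conformity_index(g, cm, sm), 0.5)
  expect_equal(conformity_index(dose_grid(c(0, 0, 0), 1, vals * 4), cm, sm),
               0.5)
  # random grids against the counting oracle
  for (seed in 1:6) {
    g <- random_grid(seed, dims = c(8, 8, 6))
    ch <- array(FALSE, c(8, 8, 6)); ch[4:5, 4:5, 3:4] <- TRUE
    cm <- structure_mask("ch", ch, g)
    sm <- expand_mask(cm, 1.2)
    got <- conformity_index(g, cm, sm)
    expect_equal(got, oracle_coin(g$values, ch, sm$voxels))
    expect_gte(got, 0); expect_lte(got, 1)
  }
  expect_error(conformity_index(g, sm, cm), "contain")
})

test_that("beam-chamber intersection threshold behaves monotonically", {
  g <- dose_grid(c(0, 0, 0), 1, array(0, c(20, 5, 5)))
  ch <- array(FALSE, c(20, 5, 5)); ch[10:11, 3, 3] <- TRUE
  cm <- structure_mask("ch", ch, g)
  vals <- array(0, c(20, 5, 5))
  vals[8:13, , ] <- 1; vals[10:11, , ] <- 0.6; vals[1, 1, 1] <- 1
  beam_on <- dose_grid(c(0, 0, 0), 1, vals)
  off <- array(0, c(20, 5, 5)); off[1:3, , ] <- 1
  beam_off <- dose_grid(c(0, 0, 0), 1, off)
  expect_true(beam_intersects_chamber(beam_on, cm, 0.5))
  expect_false(beam_intersects_chamber(beam_off, cm, 0.5))
  expect_false(beam_intersects_chamber(
    dose_grid(c(0, 0, 0), 1, array(0, c(20, 5, 5))), cm))
  # monotone in the threshold: intersection at t2 > t1 implies it at t1
  thresholds <- seq(0.05, 0.95, by = 0.05)
  hits <- vapply(thresholds, function(t)
    beam_intersects_chamber(beam_on, cm, t), logical(1))
  expect_true(all(diff(as.integer(hits)) <= 0))
  expect_equal(intersection_fraction(list(beam_on, beam_off, beam_on), cm,
                                     0.5), 2 / 3)
  expect_equal(intersection_fraction(rep(list(beam_on), 4), cm, 0.5), 1)
  # 5 of 7 intersecting
  expect_equal(intersection_fraction(
    c(rep(list(beam_on), 5), rep(list(beam_off), 2)), cm, 0.5), 5 / 7)
})

test_that("beam dose summation is lattice-checked and order-invariant", {
  g1 <- random_grid(1); g2 <- random_grid(2); g3 <- random_grid(3)
  s <- sum_beam_doses(list(g1, g2, g3))
  expect_equal(s$values, g1$values + g2$values + g3$values)
  expect_equal(sum_beam_doses(list(g1, g1))$values, 2 * g1$values)
  perm <- sum_beam_doses(list(g3, g1, g2))
  expect_equal(perm$values, s$values)
  shifted <- dose_grid(c(1, 0, 0), g1$spacing, g1$values)
  expect_error(sum_beam_doses(list(g1, shifted)), "lattice")
})

test_that("combined uncertainty follows the quadrature-over-n rule", {
  expect_equal(combined_uncertainty(0.4), 0.4)
  expect_equal(combined_uncertainty(rep(0.6, 4)), 0.3)
  # equal-uncertainty identity i/sqrt(n), against the direct formula
  for (n in 1:10) {
    i <- 0.7
    brute <- sqrt(sum(rep(i, n)^2)) / n
    expect_equal(combined_uncertainty(rep(i, n)), i / sqrt(n))
    expect_equal(combined_uncertainty(rep(i, n)), brute)
  }
  expect_error(combined_uncertainty(numeric(0)), "empty")
  expect_error(combined_uncertainty(c(0.1, 0.2), n = 3), "must equal")
})

test_that("percent RMS difference matches hand arithmetic", {
  expect_equal(percent_rms_difference(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(percent_rms_difference(1.02, 1.00), 2.0)
  expect_equal(percent_rms_difference(c(1.03, 0.97), c(1, 1)), 3.0)
  expect_error(percent_rms_difference(1, 0), "> 0")
})
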