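test_that("posmax is the positional range of the open leaves", {
  expect_equal(segment_posmax(c(0, 1, 2), rep(TRUE, 3)), 2)
  expect_equal(segment_posmax(c(5, 5, 5), rep(TRUE, 3)), 0)
  expect_equal(segment_posmax(c(0, 9, 2), c(FALSE, TRUE, FALSE)), 0)
  expect_error(segment_posmax(c(1, 2), c(FALSE, FALSE)), "no open leaves")
})

test_that("LSV matches hand evaluation and its degenerate conventions", {
  # three open leaves at [0,1,2] in both banks: each bank factor
  # ((2-1)+(2-1)) / (2*2) = 0.5, product 0.25
  seg <- mlc_segment(c(0, 1, 2), c(-2, -1, 0), 6)
  expect_equal(segment_lsv(seg, rep(TRUE, 3)), 0.25)
  # aligned banks (posmax = 0) are perfectly regular
  expect_equal(segment_lsv(mlc_segment(c(3, 3), c(-3, -3), 1), c(TRUE, TRUE)),
               1)
  # a single open leaf is perfectly regular
  expect_equal(segment_lsv(mlc_segment(c(3, 0), c(-3, 0), 1),
                           c(TRUE, FALSE)), 1)
})

test_that("AAV matches hand evaluation and its limits", {
  s <- mlc_segment(c(1, 3), c(-1, -1), 5)
  expect_equal(segment_aav(s, c(3, 3), c(-1, -1)), 0.75)
  # segment equal to the beam maximal aperture
  m <- mlc_segment(c(3, 3), c(-1, -1), 5)
  expect_equal(segment_aav(m, c(3, 3), c(-1, -1)), 1)
  # fully closed segment
  z <- mlc_segment(c(0, 0), c(0, 0), 5)
  expect_equal(segment_aav(z, c(3, 3), c(-1, -1)), 0)
  expect_error(segment_aav(z, c(0, 0), c(0, 0)), "never opens")
})

test_that("beam and plan MCS are MU-weighted means with the right limits", {
  # a static rectangular beam scores exactly 1
  rect <- rt_beam(0, list(mlc_segment(c(4, 4, 4), c(-4, -4, -4), 50)))
  expect_equal(beam_mcs(rect), 1)
  # two equal-MU segments with AAV*LSV of 1 and 0.5:
  # seg b has half the max aperture per leaf and aligned banks
  a <- mlc_segment(c(4, 4), c(-4, -4), 10)
  b <- mlc_segment(c(2, 2), c(-2, -2), 10)
  expect_equal(beam_mcs(rt_beam(0, list(a, b))), 0.75)
  # MU-weighted plan mean: beams with MCS 1 (MU 100) and 0.5 (MU 300)
  beam1 <- rt_beam(0, list(mlc_segment(c(4, 4), c(-4, -4), 100)))
  beam2 <- rt_beam(90, list(mlc_segment(c(4, 4), c(-4, -4), 150),
                            mlc_segment(c(0, 0), c(0, 0), 150)))
  expect_equal(beam_mcs(beam2), 0.5)
  expect_equal(plan_mcs(rt_plan("p", list(beam1, beam2))), 0.625)
  # scaling all segment MUs uniformly leaves the beam score unchanged
  scaled <- rt_beam(0, list(mlc_segment(c(4, 4), c(-4, -4), 30),
                            mlc_segment(c(2, 2), c(-2, -2), 30)))
  expect_equal(beam_mcs(scaled), beam_mcs(rt_beam(0, list(a, b))))
})

test_that("plan MCS equals the brute-force double sum over segments", {
  for (seed in 1:10) {
    p <- random_plan(seed, n_beams = 3, n_segments = 5)
    expect_equal(plan_mcs(p), oracle_plan_mcs(p), tolerance = 1e-12)
  }
})

test_that("all complexity scores stay in [0, 1] over random segments", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(2:12, 1)
    right <- runif(n, -6, 3)
    left <- right + runif(n, 0, 8)
    s <- mlc_segment(left, right, 1)
    open <- open_leaves(s)
    if (any(open)) {
      lsv <- segment_lsv(s, open)
      expect_gte(lsv, 0); expect_lte(lsv, 1)
    }
    aav <- segment_aav(s, left + runif(n, 0, 1), right - runif(n, 0, 1))
    expect_gte(aav, 0); expect_lte(aav, 1)
  }
  for (seed in 1:20) {
    m <- plan_mcs(random_plan(seed))
    expect_gte(m, 0); expect_lte(m, 1)
  }
})

test_that("more jagged leaf sequences never raise the LSV", {
  # at fixed posmax, growing adjacent differences lower the bank factor
  base <- c(0, 1, 2, 3, 4)
  jag <- c(0, 3, 1, 4, 2)   # same range, larger adjacent jumps
  s_base <- mlc_segment(base, base - 5, 1)
  s_jag <- mlc_segment(jag, jag - 5, 1)
  expect_gt(segment_lsv(s_base, rep(TRUE, 5)),
            segment_lsv(s_jag, rep(TRUE, 5)))
})

test_that("plan_complexity aggregates per-segment scores coherently", {
  p <- random_plan(5)
  cs <- plan_complexity(p)
  expect_s3_class(cs, "complexity_scores")
  expect_equal(cs$mcs_plan, plan_mcs(p))
  expect_true(cs$mcs_plan >= min(cs$mcs_beam) - 1e-12 &&
              cs$mcs_plan <= max(cs$mcs_beam) + 1e-12)
  expect_equal(nrow(cs$segments), sum(vapply(p$beams, function(b)
    length(b$segments), integer(1))))
})
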