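# Shared fixtures and independent brute-force oracles.

# Small random plan with valid invariants (not via generate_plan, so plan
# construction and the generator can be checked against each other).
random_plan <- function(seed, n_beams = 3, n_segments = 4, n_leaves = 8) {
  set.seed(seed)
  beams <- lapply(seq_len(n_beams), function(j) {
    segs <- lapply(seq_len(n_segments), function(i) {
      right <- runif(n_leaves, -5, 2)
      left <- right + runif(n_leaves, 0, 6)
      mlc_segment(left, right, runif(1, 1, 40))
    })
    rt_beam(runif(1, 0, 360), segs)
  })
  rt_plan(sprintf("random-%d", seed), beams)
}

# Small dose grid with uniform random values.
random_grid <- function(seed, dims = c(6, 5, 4), spacing = 0.5) {
  set.seed(seed)
  dose_grid(c(0, 0, 0), spacing, array(runif(prod(dims), 0, 4), dims))
}

# Brute-force D_x%: sort masked voxel doses descending, take the
# ceil(x/100 * n)-th.
oracle_dose_at_volume <- function(doses, volume_pct) {
  sort(doses, decreasing = TRUE)[ceiling(volume_pct / 100 * length(doses))]
}

oracle_hi <- function(doses) {
  (oracle_dose_at_volume(doses, 2) - oracle_dose_at_volume(doses, 98)) /
    mean(doses)
}

# Brute-force COIN by direct voxel counting.
oracle_coin <- function(values, chamber, shell) {
  ri <- mean(values[chamber])
  v_ch_ri <- sum(values[chamber] >= ri)
  (v_ch_ri / sum(chamber)) * (v_ch_ri / sum(values[shell] >= ri))
}

# Brute-force MCS as the double sum over all segments of the plan.
oracle_plan_mcs <- function(plan, gap_threshold = 0.05) {
  total <- 0
  for (beam in plan$beams) {
    A <- length(beam$segments[[1]]$left_positions)
    maxl <- apply(vapply(beam$segments, `[[`, numeric(A), "left_positions"),
                  1, max)
    maxr <- apply(vapply(beam$segments, `[[`, numeric(A), "right_positions"),
                  1, min)
    for (s in beam$segments) {
      open <- s$left_positions - s$right_positions > gap_threshold
      if (!any(open)) next
      bank <- function(pos) {
        p <- pos[open]
        pm <- max(p) - min(p)
        if (length(p) == 1 || pm == 0) return(1)
        acc <- 0
        for (i in seq_len(length(p) - 1))
          acc <- acc + pm - abs(p[i] - p[i + 1])
        acc / ((length(p) - 1) * pm)
      }
      lsv <- bank(s$left_positions) * bank(s$right_positions)
      aav <- sum(s$left_positions - s$right_positions) / sum(maxl - maxr)
      total <- total + aav * lsv * s$mu_weight / plan$plan_mu
    }
  }
  total
}
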