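toy_normative <- function(on_frac = 0.4, G = 10) {
  on <- c(rep(1L, round(on_frac * G)), rep(0L, G - round(on_frac * G)))
  mask <- activation_mask(on, 0.4)
  mask$on <- on
  list(mask = mask)
}

toy_profile <- function(values) {
  structure(list(values = values, muscle = NULL, anchor = "TOE_OFF",
                 n_steps_averaged = 1, silent = all(values == 0)),
            class = "gait_cycle_profile")
}

test_that("a patient identical to the normative scores T = 1", {
  # normative-like profile: 1.0 on the on-region (40% of grid), 0.2 off
  G <- 10
  norm <- toy_normative(0.4, G)
  vals <- ifelse(norm$mask$on == 1, 1.0, 0.2)
  prof <- toy_profile(vals)
  mask <- activation_mask(prof, 0.4)
  r <- gait_metric(prof, mask, norm)
  expect_equal(r$T, 1)
  expect_equal(r$M, 0.4 / (0.4 + 0.12), tolerance = 1e-12)
  expect_equal(r$gm, (0.4 / 0.52 + 1) / 2, tolerance = 1e-12)
})

test_that("a constant always-on patient scores the normative duty cycle", {
  G <- 10
  norm <- toy_normative(0.4, G)
  prof <- toy_profile(rep(1, G))
  mask <- activation_mask(prof, 0.4)
  r <- gait_metric(prof, mask, norm)
  expect_equal(r$M, 0.4)
  expect_equal(r$T, 0.4)
  expect_equal(r$gm, 0.4)
})

test_that("activity exactly out of phase is penalized to M = 0", {
  G <- 10
  norm <- toy_normative(0.2, G)
  vals <- ifelse(norm$mask$on == 1, 0, 1)
  prof <- toy_profile(vals)
  mask <- activation_mask(prof, 0.4)
  r <- gait_metric(prof, mask, norm)
  expect_equal(r$M, 0)
  expect_equal(r$T, 0)
  expect_lt(r$gm, 0.05)
  # a fully silent patient: M defined as 0, T rewards joint silence
  silent <- toy_profile(rep(0, G))
  rs <- gait_metric(silent, activation_mask(silent), norm)
  expect_equal(rs$M, 0)
  expect_equal(rs$T, 0.8)
})

test_that("gm is bounded, scale-invariant and grid-checked", {
  set.seed(41)
  norm <- toy_normative(0.4, 20)
  for (i in 1:20) {
    vals <- abs(rnorm(20))
    prof <- toy_profile(vals)
    mask <- activation_mask(prof, 0.4)
    r <- gait_metric(prof, mask, norm)
    expect_true(r$gm >= 0 && r$gm <= 1)
    expect_equal(r$gm, (r$M + r$T) / 2)
    r2 <- gait_metric(toy_profile(vals * 7), mask, norm)
    expect_equal(r2$gm, r$gm, tolerance = 1e-12)
  }
  expect_error(gait_metric(toy_profile(rnorm(5)),
                           activation_mask(rnorm(5)), norm),
               class = "emgait_grid_mismatch")
})

test_that("gm composition modes agree on ordering", {
  norm <- toy_normative(0.4, 10)
  vals <- ifelse(norm$mask$on == 1, 1, 0.1)
  prof <- toy_profile(vals)
  mask <- activation_mask(prof, 0.4)
  g_mean <- gait_metric(prof, mask, norm, composition = "mean")
  g_prod <- gait_metric(prof, mask, norm, composition = "product")
  g_geom <- gait_metric(prof, mask, norm, composition = "geometric")
  expect_equal(g_prod$gm, g_mean$M * g_mean$T)
  expect_equal(g_geom$gm, sqrt(g_mean$M * g_mean$T))
  expect_true(g_prod$gm <= g_geom$gm && g_geom$gm <= g_mean$gm)
})

test_that("bdsi matches hand substitutions of its formula", {
  m <- c(1, 1, 0, 0, 1, 0, 1, 0, 0, 0)
  expect_equal(bdsi(m, m)$bdsi, 100)
  expect_equal(bdsi(m, 1 - m)$bdsi, 0)
  # 4 joint-on and 2 joint-off of N=10 -> 60
  a <- c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0)
  b <- c(1, 1, 1, 1, 0, 0, 0, 0, 1, 1)
  r <- bdsi(a, b)
  expect_equal(r$on_matches, 4)
  expect_equal(r$off_matches, 2)
  expect_equal(r$bdsi, 60)
  expect_error(bdsi(a, b[1:5]), class = "emgait_grid_mismatch")
})

test_that("bdsi equals the direct-counting oracle on all small grids", {
  for (n in 1:7) {
    masks <- all_masks(n)
    pairs <- expand.grid(i = seq_len(nrow(masks)), j = seq_len(nrow(masks)))
    got <- mapply(function(i, j) bdsi(masks[i, ], masks[j, ])$bdsi,
                  pairs$i, pairs$j)
    want <- mapply(function(i, j) bdsi_oracle(masks[i, ], masks[j, ]),
                   pairs$i, pairs$j)
    expect_identical(got, want)
  }
})

test_that("bdsi is symmetric and respects identity/complement on larger grids", {
  set.seed(99)
  for (n in 8:12) {
    masks <- all_masks(n)
    ids <- vapply(seq_len(nrow(masks)), function(i)
      bdsi(masks[i, ], masks[i, ])$bdsi, 0)
    comps <- vapply(seq_len(nrow(masks)), function(i)
      bdsi(masks[i, ], 1 - masks[i, ])$bdsi, 0)
    expect_true(all(ids == 100))
    expect_true(all(comps == 0))
    ij <- matrix(sample(nrow(masks), 600, replace = TRUE), ncol = 2)
    got <- apply(ij, 1, function(p) bdsi(masks[p[1], ], masks[p[2], ])$bdsi)
    want <- apply(ij, 1, function(p) bdsi_oracle(masks[p[1], ], masks[p[2], ]))
    sym <- apply(ij, 1, function(p) bdsi(masks[p[2], ], masks[p[1], ])$bdsi)
    expect_identical(got, want)
    expect_identical(got, sym)
  }
})

test_that("muscle couples pool by unweighted mean", {
  gm_vals <- c(TA = 0.4, SOL = 0.6, RF = 0.5, ST = 0.5)
  expect_equal(group_index(gm_vals, "DISTAL"), 0.5)
  expect_equal(group_index(gm_vals, "PROXIMAL"), 0.5)
  expect_equal(group_index(gm_vals, "AGONISTS"), 0.55)
  expect_equal(group_index(gm_vals, "ANTAGONISTS"), 0.45)
  bdsi_vals <- c(RF = 60, ST = 100)
  expect_equal(group_index(bdsi_vals, "PROXIMAL"), 80)
  expect_error(group_index(c(TA = 1), "DISTAL"),
               class = "emgait_missing_muscle")
})
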