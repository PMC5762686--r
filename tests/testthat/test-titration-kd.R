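test_that("bound fraction solves the binding quadratic", {
  expect_equal(bound_fraction(100, 0, 5), 0)
  expect_equal(bound_fraction(100, 150, 0), 1)   # stoichiometric, excess ligand
  expect_equal(bound_fraction(100, 100, 100), 0.381966, tolerance = 1e-6)
  # the root satisfies Pt pb^2 - (Pt+Lt+Kd) pb + Lt = 0
  withr::local_seed(2)
  for (i in 1:20) {
    Pt <- runif(1, 10, 500); Lt <- runif(1, 0, 1000); Kd <- runif(1, 0.01, 100)
    pb <- bound_fraction(Pt, Lt, Kd)
    expect_equal(Pt * pb^2 - (Pt + Lt + Kd) * pb + Lt, 0, tolerance = 1e-6)
    expect_lte(pb, min(1, Lt / Pt) + 1e-12)
  }
})

test_that("bound fraction is monotone in ligand and in affinity", {
  Lt <- seq(0, 400, by = 20)
  pb <- bound_fraction(100, Lt, 5)
  expect_true(all(diff(pb) >= 0))
  kds <- c(0.01, 0.1, 1, 10, 100)
  pbk <- vapply(kds, function(k) bound_fraction(100, 150, k), numeric(1))
  expect_true(all(diff(pbk) <= 0))
  expect_error(bound_fraction(-1, 10, 1), "positive")
})

test_that("line shape reduces to pure Lorentzians at the population endpoints", {
  p <- exchange_params(nu_apo = 0, nu_holo = 120, R2_apo = 25, R2_holo = 30,
                       koff = 50)
  grid <- default_grid(0, 120)
  apo <- simulate_lineshape(p, 0, grid)
  expect_equal(apo, 25 / (25^2 + (2 * pi * (grid - 0))^2), tolerance = 1e-12)
  expect_equal(grid[which.max(apo)], grid[which.min(abs(grid - 0))])
  holo <- simulate_lineshape(p, 1, grid)
  expect_equal(holo, 30 / (30^2 + (2 * pi * (grid - 120))^2), tolerance = 1e-12)
})

test_that("slow exchange resolves two peaks with population-weighted areas", {
  # koff far below the 200 Hz separation
  p <- exchange_params(nu_apo = -100, nu_holo = 100, R2_apo = 20, R2_holo = 20,
                       koff = 1)
  grid <- seq(-600, 600, length.out = 8192)
  y <- simulate_lineshape(p, 0.5, grid)
  left <- grid < 0
  a_left <- sum(y[left]) * diff(grid)[1]
  a_right <- sum(y[!left]) * diff(grid)[1]
  expect_equal(a_left / (a_left + a_right), 0.5, tolerance = 0.01)
  expect_equal(grid[which.max(y * left)], -100, tolerance = 2)
  expect_equal(grid[which.max(y * !left)], 100, tolerance = 2)
  # uneven populations follow (1-pb, pb)
  y3 <- simulate_lineshape(p, 0.3, grid)
  expect_equal(sum(y3[!left]) / sum(y3), 0.3, tolerance = 0.015)
})

test_that("fast exchange collapses to one peak at the weighted mean frequency", {
  p <- exchange_params(nu_apo = -100, nu_holo = 100, R2_apo = 20, R2_holo = 20,
                       koff = 2e5)
  grid <- seq(-600, 600, length.out = 8192)
  for (pb in c(0.25, 0.5, 0.8)) {
    y <- simulate_lineshape(p, pb, grid)
    expect_equal(grid[which.max(y)], (1 - pb) * -100 + pb * 100, tolerance = 2)
  }
})

test_that("spectrum integral is conserved across populations and rates", {
  grid <- seq(-3000, 3000, length.out = 2^15)
  areas <- c()
  for (koff in c(5, 50, 5000)) {
    p <- exchange_params(0, 120, 25, 30, koff)
    for (pb in c(0, 0.2, 0.5, 0.9, 1)) {
      areas <- c(areas, sum(simulate_lineshape(p, pb, grid)) * diff(grid)[1])
    }
  }
  expect_equal(areas, rep(0.5, length(areas)), tolerance = 0.02)
})

test_that("frequency-domain solution matches the time-domain FID oracle", {
  p <- exchange_params(nu_apo = 0, nu_holo = 150, R2_apo = 25, R2_holo = 35,
                       koff = 80)
  grid <- seq(-400, 550, length.out = 101)
  for (pb in c(0.2, 0.6)) {
    direct <- simulate_lineshape(p, pb, grid)
    oracle <- lineshape_fft_oracle(p, pb, grid)
    expect_equal(direct, oracle, tolerance = 1e-4)
  }
})

test_that("noiseless titration traces round-trip through the generator", {
  ser <- gen_titration(Kd = 5, koff = 50, Pt = 100, seed = 4)
  r93 <- ser$traces[ser$traces$residue_id == 93 & ser$traces$ratio == 0, ]
  p <- exchange_params(0, 120, 25, 30, 50)
  expect_identical(r93$intensity, simulate_lineshape(p, 0, r93$frequency_hz))
  # saturation: high ratio at tight Kd approaches the pure holo trace
  sat <- gen_titration(Kd = 0.01, koff = 50, Pt = 100, ratios = c(0, 1, 10),
                       seed = 4)
  top <- sat$traces[sat$traces$residue_id == 93 & sat$traces$ratio == 10, ]
  expect_equal(top$intensity, simulate_lineshape(p, 1, top$frequency_hz),
               tolerance = 1e-3)
})

test_that("Kd fitting recovers the planted constant from noiseless data", {
  ser <- gen_titration(Kd = 5, koff = 50, Pt = 100, seed = 1)
  f <- fit_kd(ser)
  expect_lt(abs(f$kd - 5) / 5, 0.01)
  expect_lt(abs(f$koff - 50) / 50, 0.05)
  expect_true(f$converged)
})

test_that("a perturbation-free titration is flagged unidentifiable", {
  res <- data.frame(residue_id = 1L, nu_apo = 0, nu_holo = 0,
                    R2_apo = 25, R2_holo = 25)
  ser <- gen_titration(Kd = 5, koff = 50, Pt = 100, residues = res, seed = 1)
  expect_warning(f <- fit_kd(ser), "unidentifiable")
  expect_true(f$unidentifiable)
  expect_true(is.na(f$kd))
})

test_that("fast-exchange shift fitting recovers Kd and flags saturation", {
  ratios <- seq(0, 4, by = 0.5)
  pb <- bound_fraction(50, ratios * 50, 10)
  shifts <- 100 + pb * 80
  f <- fast_exchange_kd(shifts, Pt = 50, ratios = ratios)
  expect_equal(f$kd, 10, tolerance = 1e-3)
  expect_equal(f$delta_holo, 180, tolerance = 0.01)
  # saturating series: every point already at the holo shift
  fs <- suppressWarnings(fast_exchange_kd(c(100, rep(180, 8)), 50, ratios))
  expect_true(fs$at_boundary)
  # 1% noise keeps recovery within 10%
  withr::local_seed(8)
  errs <- vapply(1:10, function(i) {
    noisy <- shifts + rnorm(length(shifts), sd = 0.8)
    # noise legitimately breaks strict monotonicity; the advisory is expected
    f <- suppressWarnings(fast_exchange_kd(noisy, 50, ratios))
    abs(f$kd - 10) / 10
  }, numeric(1))
  expect_lt(mean(errs), 0.10)
})
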