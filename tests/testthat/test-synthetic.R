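test_that("plasma input function matches its closed form and limits", {
  p <- feng_input_params(A1 = 800, A2 = 20, A3 = 10,
                         lambda1 = 4.0, lambda2 = 0.5, lambda3 = 0.01)
  expect_equal(feng_input(p, 0), 0)
  # independent scalar evaluation at t = 0.25
  t <- 0.25
  expected <- (800 * t - 20 - 10) * exp(-4 * t) + 20 * exp(-0.5 * t) + 10 * exp(-0.01 * t)
  expect_equal(feng_input(p, t), expected, tolerance = 1e-12)
  # all exponents negative: the curve decays to zero
  expect_lt(feng_input(p, 1e4), 1e-6)
  # vectorized and clipped at zero
  expect_true(all(feng_input(p, seq(0, 60, by = 0.5)) >= 0))
  expect_error(feng_input_params(lambda1 = 0.1, lambda2 = 0.5, lambda3 = 0.01),
               "lambda1 > lambda2")
})

test_that("reference TAC generator reproduces the constant-input closed form", {
  sched <- default_frame_schedule()
  K1 <- 0.2; theta <- 0.25; cc <- 5
  ref <- simulate_reference_tac(sched, input = function(t) rep(cc, length(t)),
                                K1_ref = K1, k2prime = theta, noise_scale = 0)
  # frame mean of K1*c*(1 - exp(-theta t))/theta, integrated analytically
  a <- sched$frame_start; b <- a + sched$frame_duration
  expected <- K1 * cc / theta *
    (1 - (exp(-theta * a) - exp(-theta * b)) / (theta * (b - a)))
  expect_equal(ref$activity, expected, tolerance = 1e-6)
})

test_that("reference TAC generator handles zero input and is seed-reproducible", {
  sched <- default_frame_schedule()
  z <- simulate_reference_tac(sched, input = function(t) numeric(length(t)),
                              noise_scale = 0)
  expect_equal(z$activity, rep(0, nrow(sched)))
  a <- simulate_reference_tac(sched, noise_scale = 0.1, seed = 11)
  b <- simulate_reference_tac(sched, noise_scale = 0.1, seed = 11)
  expect_identical(a$activity, b$activity)
  expect_error(simulate_reference_tac(sched[0, ], noise_scale = 0), "empty")
})

test_that("SRTM target generator satisfies its construction identities", {
  ref <- simulate_reference_tac()
  # R1 = 1, k2a = k2prime: target is the reference itself
  same <- simulate_target_tac_srtm(ref, R1 = 1, k2a = 0.1, k2prime = 0.1)
  expect_equal(same$activity, ref$activity, tolerance = 1e-10)
  # zero reference gives zero target
  zref <- simulate_reference_tac(input = function(t) numeric(length(t)),
                                 noise_scale = 0)
  ztar <- simulate_target_tac_srtm(zref, R1 = 0.8, k2a = 0.05, k2prime = 0.1)
  expect_equal(ztar$activity, rep(0, length(zref$activity)))
  # generated curve's best-fit DVR equals R1 k2prime / k2a
  tar <- simulate_target_tac_srtm(ref, R1 = 0.8, k2a = 0.05, k2prime = 0.1)
  fit <- fit_srtm2(tar, ref, k2prime = 0.1)
  expect_equal(fit$DVR, 1.6, tolerance = 2e-3)
})

test_that("cohort simulation recovers spec means noise-free and is deterministic", {
  g <- data.frame(region = c("SC1", "SC3"), mean_dvr = c(1, 0.72),
                  sd_dvr = c(0, 0), mean_r1 = c(1, 1))
  spec <- cohort_spec(groups = list(sham = g, SCI = g),
                      n_per_group = c(sham = 1L, SCI = 1L),
                      noise_scale = 0, seed = 3L, K1_ref_sd = 0)
  co <- simulate_cohort(spec)
  fits <- fit_cohort_srtm2(co$tacs, reference_region = "SC1", k2prime = 0.1)
  expect_equal(fits$DVR, rep(0.72, 2), tolerance = 1e-3)
  # byte-identical tables under a fixed seed
  co2 <- simulate_cohort(spec)
  expect_identical(co$tacs, co2$tacs)
  expect_identical(co$truth, co2$truth)
})

test_that("cohort truth-table DVR mean converges to the spec mean", {
  g <- data.frame(region = c("SC1", "SC3"), mean_dvr = c(1, 0.72),
                  sd_dvr = c(0, 0.066), mean_r1 = c(1, 1))
  spec <- cohort_spec(groups = list(sham = g), n_per_group = c(sham = 200L),
                      noise_scale = 0, seed = 5L)
  tr <- simulate_cohort(spec)$truth
  m <- mean(tr$true_DVR[tr$region == "SC3"])
  expect_lt(abs(m - 0.72), 3 * 0.066 / sqrt(200))
})

test_that("cohort spec validation catches malformed groups", {
  g1 <- data.frame(region = c("SC1", "SC3"), mean_dvr = c(1, 0.72),
                   sd_dvr = c(0, 0.1), mean_r1 = c(1, 1))
  g2 <- data.frame(region = c("SC1", "SC4"), mean_dvr = c(1, 0.7),
                   sd_dvr = c(0, 0.1), mean_r1 = c(1, 1))
  expect_error(cohort_spec(groups = list(a = g1, b = g2),
                           n_per_group = c(a = 2L, b = 2L)),
               "same regions")
  expect_error(cohort_spec(groups = list(a = g1), n_per_group = c(a = 0L)),
               "n_per_group")
  expect_error(cohort_spec(groups = list(a = g1), n_per_group = c(a = 2L),
                           reference_region = "BS"),
               "reference_region")
})

test_that("DWI simulator reproduces closed-form signals", {
  sch <- default_diffusion_scheme(b = 1000)
  # zero tensor: every signal is S0
  z <- simulate_dwi(matrix(0, 2, 6), sch, S0 = 500, sigma = 0)
  expect_equal(as.numeric(z), rep(500, 2 * length(sch$bvalues)))
  # isotropic tensor: all b=1000 signals are S0 exp(-b d) regardless of direction
  d <- 0.7e-3
  iso <- simulate_dwi(matrix(c(d, d, d, 0, 0, 0), 1), sch, S0 = 1000, sigma = 0)
  nz <- sch$bvalues > 0
  expect_equal(as.numeric(iso[1, nz]), rep(1000 * exp(-1000 * d), sum(nz)),
               tolerance = 1e-7)
  # prolate tensor with gradient along its principal axis: S = S0 exp(-1.7)
  ax <- c(1, 0, 0)
  sch2 <- diffusion_scheme(c(0, rep(1000, 6)),
                           rbind(c(0, 0, 0), ax,
                                 c(0, 1, 0), c(0, 0, 1),
                                 cbind(1, 1, 0) / sqrt(2),
                                 cbind(1, 0, 1) / sqrt(2),
                                 cbind(0, 1, 1) / sqrt(2)))
  prol <- matrix(c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0), 1)
  s <- simulate_dwi(prol, sch2, S0 = 1000, sigma = 0)
  expect_equal(as.numeric(s[1, 2]), 1000 * exp(-1.7), tolerance = 1e-10)
})

test_that("DWI simulator rejects non-PSD tensors and shows Rician bias", {
  sch <- default_diffusion_scheme()
  bad <- array(0, c(2, 1, 1, 6))
  bad[2, 1, 1, ] <- c(-1e-3, 1e-3, 1e-3, 0, 0, 0)
  expect_error(simulate_dwi(bad, sch), "\\(2, 1, 1\\).*positive semi-definite")
  # at low SNR (S0/sigma < 2) the magnitude-signal mean exceeds the truth
  zero <- matrix(0, 400, 6)
  s <- simulate_dwi(zero, sch, S0 = 1, sigma = 0.6, seed = 2)
  expect_gt(mean(s), 1)
  # sigma = 0 deterministic; fixed seed reproducible
  s1 <- simulate_dwi(zero, sch, S0 = 1, sigma = 0.6, seed = 9)
  s2 <- simulate_dwi(zero, sch, S0 = 1, sigma = 0.6, seed = 9)
  expect_identical(as.numeric(s1), as.numeric(s2))
})

test_that("gradient tables round-trip through FSL bval/bvec files", {
  sch <- default_diffusion_scheme()
  pre <- file.path(tempdir(), "grad")
  write_fsl_gradients(sch, pre)
  back <- read_fsl_gradients(paste0(pre, ".bval"), paste0(pre, ".bvec"))
  expect_equal(back$bvalues, sch$bvalues)
  expect_equal(back$directions, sch$directions, tolerance = 1e-9,
               ignore_attr = TRUE)
})
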