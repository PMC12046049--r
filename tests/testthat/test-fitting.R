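test_that("noise-free homodimer titrations are recovered exactly", {
  kd <- 75.9e-9
  d <- gen_titration(kd, f_total_series = kd * 10^seq(-1, 2,
                                                      length.out = 8),
                     noise_sd = 0, seed = 1)
  f <- fit_kd(d, "homodimer")
  expect_lt(abs(f$kd - kd) / kd, 1e-6)
  expect_equal(f$sd, 0)
  expect_s3_class(f, "kd_fit")
  expect_equal(unname(coef(f)), f$kd)
})

test_that("noise-free heterodimer titrations are recovered exactly", {
  kd_het <- 3.9e-9; kd_homo <- 75.9e-9
  d <- gen_titration(kd_homo, kd_het,
                     f_total_series = 10^seq(-8, -5.5, length.out = 8),
                     h_total = 5e-6, noise_sd = 0, seed = 1)
  f <- fit_kd(d, "heterodimer", kd_homo = c(kd_homo, 0))
  expect_lt(abs(f$kd - kd_het) / kd_het, 1e-6)
})

test_that("noisy titrations recover the truth within 3 SD", {
  kd <- 75.9e-9
  ser <- kd * 10^seq(-1, 2, length.out = 8)
  hits <- vapply(1:20, function(seed) {
    d <- gen_titration(kd, f_total_series = ser, noise_sd = 0.02,
                       seed = seed)
    f <- suppressWarnings(fit_kd(d, "homodimer"))
    abs(f$kd - kd) <= 3 * f$sd
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("estimator error shrinks as the noise vanishes", {
  kd <- 2e-8
  ser <- kd * 10^seq(-1, 2, length.out = 8)
  med_err <- vapply(c(0.05, 0.01, 0.002), function(s) {
    errs <- vapply(1:12, function(seed) {
      d <- gen_titration(kd, f_total_series = ser, noise_sd = s,
                         seed = 100 + seed)
      abs(suppressWarnings(fit_kd(d, "homodimer"))$kd - kd) / kd
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("fits are invariant to concentration units and point order", {
  kd <- 5e-8
  d <- gen_titration(kd, f_total_series = kd * 10^seq(-1, 2,
                                                      length.out = 8),
                     noise_sd = 0.02, seed = 7)
  f1 <- fit_kd(d, "homodimer")
  # same observations expressed in nM
  d_nm <- as.data.frame(d)
  d_nm$f_total <- d_nm$f_total * 1e9
  d_nm$h_total <- d_nm$h_total * 1e9
  f2 <- fit_kd(titration_data(d_nm, unit = "nM"), "homodimer")
  expect_equal(f1$kd, f2$kd, tolerance = 1e-9)
  # permuted row order
  d_perm <- titration_data(as.data.frame(d)[rev(seq_len(nrow(d))), ])
  f3 <- fit_kd(d_perm, "homodimer")
  expect_equal(f1$kd, f3$kd, tolerance = 1e-9)
})

test_that("degenerate replicate counts and flat data are flagged", {
  kd <- 1e-7
  d <- gen_titration(kd, f_total_series = kd * 10^seq(-1, 2,
                                                      length.out = 8),
                     n_replicates = 1, noise_sd = 0, seed = 1)
  expect_warning(f <- fit_kd(d, "homodimer"), "single replicate")
  expect_equal(f$sd, 0)
  # concentrations far below KD: all-monomer, no curvature
  d_flat <- gen_titration(1e-3, f_total_series = 10^seq(-9, -8,
                                                        length.out = 4),
                          noise_sd = 0, seed = 1)
  expect_warning(fb <- fit_kd(d_flat, "homodimer"), "bracket")
  expect_true("boundary" %in% fb$flags)
})

test_that("the constrained peptide isotherm fit round-trips", {
  kd <- 100e-6
  L <- kd * 10^seq(-1.5, 1.5, length.out = 9)
  d <- data.frame(ligand_total = rep(L, 3),
                  replicate = rep(1:3, each = 9),
                  fraction_bound = rep(peptide_isotherm(kd, L), 3))
  f <- fit_kd(d, "peptide")
  expect_lt(abs(f$kd - kd) / kd, 1e-6)
  # the fitted curve passes through 0.5 at L = KD
  expect_equal(predict(f, f$kd), 0.5, tolerance = 1e-9)
})

test_that("non-binding peptide data pin the estimate at the bracket", {
  d <- data.frame(ligand_total = 10^seq(-6, -4, length.out = 6),
                  replicate = 1,
                  fraction_bound = rep(1e-4, 6))
  w <- capture_warnings(f <- fit_kd(d, "peptide"))
  expect_true(any(grepl("poorly constrained", w)))
  expect_true(any(grepl("bracket", w)))
  expect_true("boundary" %in% f$flags)
  expect_gt(f$kd, 1e-3)
})

test_that("heterodimer fit propagates the homodimer KD uncertainty", {
  kd_het <- 1e-8; kd_homo <- 75.9e-9
  d <- gen_titration(kd_homo, kd_het,
                     f_total_series = kd_het * 10^seq(-1, 2,
                                                      length.out = 8),
                     h_total = 5 * kd_het, noise_sd = 0, seed = 3)
  f0 <- fit_kd(d, "heterodimer", kd_homo = c(kd_homo, 0))
  f1 <- fit_kd(d, "heterodimer", kd_homo = c(kd_homo, 8.4e-9))
  expect_gte(f1$sd, f0$sd)
  expect_gt(f1$sd, 0)
  expect_error(fit_kd(d, "heterodimer"), "kd_homo")
})

test_that("bootstrap uncertainty is seeded, sane, and guarded", {
  kd <- 5e-8
  ser <- kd * 10^seq(-1, 2, length.out = 8)
  clean <- gen_titration(kd, f_total_series = ser, noise_sd = 0,
                         seed = 1)
  b0 <- bootstrap_kd(clean, n_boot = 100, seed = 5)
  expect_lt(b0$sd / b0$kd, 1e-8)
  noisy <- gen_titration(kd, f_total_series = ser, noise_sd = 0.02,
                         seed = 2)
  b1 <- bootstrap_kd(noisy, n_boot = 100, seed = 5)
  b2 <- bootstrap_kd(noisy, n_boot = 100, seed = 5)
  expect_identical(b1$boot_kds, b2$boot_kds)
  # bootstrap SD within a factor 2 of the Monte-Carlo truth SD
  mc <- vapply(1:30, function(s)
    suppressWarnings(fit_kd(gen_titration(kd, f_total_series = ser,
                                          noise_sd = 0.02, seed = 200 + s),
                            "homodimer", replicates = "mean"))$kd,
    numeric(1))
  expect_gt(b1$sd, stats::sd(mc) / 2)
  expect_lt(b1$sd, stats::sd(mc) * 2)
  expect_error(bootstrap_kd(noisy, n_boot = 50), "n_boot")
})

test_that("fit methods produce consistent predictions and residuals", {
  kd <- 1e-7
  d <- gen_titration(kd, f_total_series = kd * 10^seq(-1, 2,
                                                      length.out = 8),
                     noise_sd = 0.01, seed = 11)
  f <- fit_kd(d, "homodimer")
  pr <- predict(f)
  expect_true(all(abs(rowSums(pr[, c("monomer", "homodimer",
                                     "heterodimer", "h_monomer")]) - 1)
                  < 1e-9))
  r <- residuals(f)
  expect_equal(length(r), nrow(d))
  expect_lt(sqrt(mean(r^2)), 0.05)
  sim <- simulate(f, nsim = 1, seed = 2)
  expect_s3_class(sim, "titration_data")
  expect_output(print(summary(f)), "per-replicate")
})
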