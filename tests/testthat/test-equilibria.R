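test_that("solve_species handles the empty-F and tight-capping limits", {
  st <- solve_species(eq_system(1e-8, 1e-8, f_total = 0,
                                h_total = 1e-6))
  expect_equal(st$f_mono, 0)
  expect_equal(st$f_dimer, 0)
  expect_equal(st$fh_hetero, 0)
  expect_equal(st$h_mono, 1e-6)

  # infinitely tight heterodimer caps all F as FH
  st <- solve_species(eq_system(75.9e-9, 1e-15, f_total = 1e-6,
                                h_total = 2e-6))
  expect_equal(st$fh_hetero, 1e-6, tolerance = 1e-6)
  expect_lt(st$f_dimer / 1e-6, 1e-6)
})

test_that("solve_species matches the analytic homodimer solution", {
  kd <- 75.9e-9; ft <- 1e-6
  st <- solve_species(eq_system(kd, f_total = ft))
  cf <- homodimer_closed_form(kd, ft)
  expect_equal(st$f_mono, cf$f_mono, tolerance = 1e-10)
  expect_equal(st$f_dimer, cf$f_dimer, tolerance = 1e-10)
  # frozen values from the quadratic root at kd = 75.9 nM, f = 1 uM
  expect_equal(st$f_mono, 1.7675453437077398e-07, tolerance = 1e-9)
  expect_equal(st$f_dimer, 4.116227328146129e-07, tolerance = 1e-9)
})

test_that("closed form obeys its trivial limits and rejects bad input", {
  z <- homodimer_closed_form(1e-8, 0)
  expect_equal(z$f_mono, 0)
  expect_equal(z$f_dimer, 0)
  # dilution limit: essentially no dimer
  d <- homodimer_closed_form(1e-6, 1e-12)
  expect_lt(d$f_dimer / 1e-12, 1e-5)
  expect_error(homodimer_closed_form(-1, 1e-6), "kd_homo")
  expect_error(eq_system(0, 1e-9, 1e-6, 0), "> 0")
  expect_error(eq_system(1e-9, 1e-9, NA, 0), "finite")
})

test_that("mass balance and equilibrium residuals hold on random systems", {
  set.seed(42)
  for (i in 1:150) {
    kd_h <- 10^runif(1, -10, -3)
    kd_x <- 10^runif(1, -10, -3)
    ft <- 10^runif(1, -9, -4)
    ht <- 10^runif(1, -9, -4)
    st <- solve_species(eq_system(kd_h, kd_x, ft, ht))
    expect_lt(abs(st$f_mono + 2 * st$f_dimer + st$fh_hetero - ft) / ft,
              1e-9)
    expect_lt(abs(st$h_mono + st$fh_hetero - ht) / ht, 1e-9)
    if (st$f_dimer > 0)
      expect_lt(abs(st$f_mono^2 / st$f_dimer - kd_h) / kd_h, 1e-9)
    if (st$fh_hetero > 0)
      expect_lt(abs(st$f_mono * st$h_mono / st$fh_hetero - kd_x) / kd_x,
                1e-9)
  }
})

test_that("disabling the heterodimer reduces to the homodimer system", {
  kd <- 5e-8; ft <- 3e-7
  st <- solve_species(eq_system(kd, Inf, ft, h_total = 1e-6))
  cf <- homodimer_closed_form(kd, ft)
  expect_equal(st$f_mono, cf$f_mono, tolerance = 1e-10)
  expect_equal(st$fh_hetero, 0)
  expect_equal(st$h_mono, 1e-6)
})

test_that("simulate_titration returns normalised, monotone fractions", {
  kd <- 1e-7
  ser <- kd * 10^seq(-1, 2, length.out = 8)
  tt <- simulate_titration(kd, f_total_series = ser)
  sums <- rowSums(tt[, -1])
  expect_true(all(abs(sums - 1) < 1e-12))
  # dimer-subunit fraction non-decreasing in f_total
  sub <- sapply(ser, function(ft) {
    s <- homodimer_closed_form(kd, ft); 2 * s$f_dimer / ft
  })
  expect_true(all(diff(sub) >= -1e-12))
  # single-point species-molar check against the closed form
  one <- simulate_titration(kd, f_total_series = kd)
  s <- homodimer_closed_form(kd, kd)
  expect_equal(one$frac_homodimer,
               s$f_dimer / (s$f_mono + s$f_dimer), tolerance = 1e-12)
  expect_error(simulate_titration(kd, f_total_series = numeric(0)),
               "empty")
  expect_error(simulate_titration(kd, f_total_series = c(2e-7, 1e-7)),
               "ascending")
})

test_that("a tighter heterodimer out-competes the homodimer pointwise", {
  kd_homo <- 1e-7; kd_het <- 1e-9; ht <- 5e-6
  ser <- 10^seq(-8, -6, length.out = 6)  # F never depletes H
  tt <- simulate_titration(kd_homo, kd_het, ser, h_total = ht)
  expect_true(all(tt$frac_heterodimer > tt$frac_homodimer))
})

test_that("per-subunit weighting doubles the dimer signal", {
  kd <- 1e-7
  a <- simulate_titration(kd, f_total_series = kd)
  b <- simulate_titration(kd, f_total_series = kd,
                          signal_model = "per-subunit")
  s <- homodimer_closed_form(kd, kd)
  expect_equal(b$frac_homodimer,
               2 * s$f_dimer / (s$f_mono + 2 * s$f_dimer),
               tolerance = 1e-12)
  expect_gt(b$frac_homodimer, a$frac_homodimer)
})

test_that("the 1:1 isotherm honours its identities", {
  expect_equal(peptide_isotherm(1e-4, 1e-4), 0.5)
  expect_equal(peptide_isotherm(1e-4, 0), 0)
  expect_equal(peptide_isotherm(100e-6, 300e-6), 0.75)
  # depletion mode converges to the approximation as receptor -> 0
  approx <- peptide_isotherm(1e-5, 3e-5)
  exact <- peptide_isotherm(1e-5, 3e-5, receptor_total = 1e-9,
                            mode = "exact_depletion")
  expect_equal(exact, approx, tolerance = 1e-3)
  # with heavy depletion, bound fraction is below the approximation
  deep <- peptide_isotherm(1e-6, 5e-6, receptor_total = 4e-6,
                           mode = "exact_depletion")
  expect_lt(deep, peptide_isotherm(1e-6, 5e-6))
  expect_error(peptide_isotherm(-1, 1e-6), "kd")
})

test_that("molar conversion is exact for tagged units", {
  expect_equal(as_molar(75.9, "nM"), 75.9e-9)
  expect_equal(as_molar(1, "uM"), 1e-6)
  expect_equal(as_molar(c(1, 2), "mM"), c(1e-3, 2e-3))
})
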