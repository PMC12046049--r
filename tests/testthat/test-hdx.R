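test_that("theoretical maximum uptake counts exchange-competent amides", {
  expect_equal(max_uptake("GSAMG"), 4)
  expect_equal(max_uptake("APPA"), 1)
  expect_equal(max_uptake("AA"), 1)
  expect_equal(max_uptake("PAAA"), 3)  # N-terminal Pro costs nothing extra
  expect_error(max_uptake("AXZ"), "valid")
  expect_error(max_uptake("A"), "length")
})

test_that("identical states give zero, insignificant differences", {
  peps <- gen_peptide_map(60, 10, 6, seed = 5)
  h <- gen_hdx(peps, noise_sd = 0, seed = 1)
  d <- uptake_difference(h$table, "bound", "free")
  expect_true(all(d$delta == 0))
  expect_true(all(!d$significant))
})

test_that("state swap negates every difference", {
  peps <- gen_peptide_map(60, 10, 6, seed = 5)
  h <- gen_hdx(peps, protection = rep(c(1, 4), length.out = nrow(peps)),
               noise_sd = 0.05, seed = 2)
  d1 <- uptake_difference(h$table, "bound", "free")
  d2 <- uptake_difference(h$table, "free", "bound")
  expect_equal(d1$delta, -d2$delta, tolerance = 1e-12)
  expect_equal(d1$significant, d2$significant)
})

test_that("protection appears as negative interface deltas only", {
  peps <- gen_peptide_map(120, 11, 7, seed = 3, boundaries = c(41, 74))
  interface <- peps$start >= 41 & peps$end <= 73
  h <- gen_hdx(peps, protection = ifelse(interface, 10, 1),
               noise_sd = 0.05, seed = 4)
  d <- uptake_difference(h$table, "bound", "free")
  d <- d[d$timepoint_s == 500, ]
  expect_true(all(d$delta[interface] < 0))
  expect_true(all(d$significant[interface]))
  expect_true(all(abs(d$delta[!interface]) < 0.3))
})

test_that("the t machinery matches stats::t.test on raw replicates", {
  set.seed(9)
  for (i in 1:20) {
    a <- rnorm(3, 5, 0.3); b <- rnorm(3, 4.5, 0.1)
    rec <- data.frame(delta = mean(a) - mean(b),
                      sd_a = sd(a), sd_b = sd(b), n_a = 3, n_b = 3)
    out <- hdx_significance(rec, alpha = 0.01)
    expect_equal(out$p_value,
                 t.test(a, b, var.equal = TRUE)$p.value,
                 tolerance = 1e-12)
    welch <- hdx_significance(rec, alpha = 0.01, method = "welch")
    expect_equal(welch$p_value, t.test(a, b)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("degenerate and extreme records follow the stated conventions", {
  zero <- data.frame(delta = 0.5, sd_a = 0, sd_b = 0, n_a = 3, n_b = 3)
  expect_warning(out <- hdx_significance(zero), "convention")
  expect_true(out$significant)
  expect_true(out$degenerate)
  null0 <- data.frame(delta = 0, sd_a = 0, sd_b = 0, n_a = 3, n_b = 3)
  expect_false(hdx_significance(null0)$significant)
  big <- data.frame(delta = 0.5, sd_a = 0.05, sd_b = 0.05,
                    n_a = 3, n_b = 3)
  expect_true(hdx_significance(big)$significant)
  expect_error(hdx_significance(data.frame(delta = 1, sd_a = 1,
                                           sd_b = 1, n_a = 1, n_b = 3)),
               "replicates")
})

test_that("detection power rises with the true effect size", {
  power_at <- function(delta_da, n_trials = 300) {
    set.seed(round(delta_da * 1000))
    mean(vapply(seq_len(n_trials), function(i) {
      a <- rnorm(3, 0, 0.05); b <- rnorm(3, delta_da, 0.05)
      rec <- data.frame(delta = mean(a) - mean(b), sd_a = sd(a),
                        sd_b = sd(b), n_a = 3, n_b = 3)
      hdx_significance(rec)$significant
    }, logical(1)))
  }
  p <- vapply(c(0.05, 0.15, 0.4), power_at, numeric(1))
  expect_true(all(diff(p) > 0))
})

test_that("Bonferroni and the pooled-threshold variant behave sensibly", {
  peps <- gen_peptide_map(120, 11, 7, seed = 3)
  h <- gen_hdx(peps, protection = rep(c(1, 3), length.out = nrow(peps)),
               noise_sd = 0.05, seed = 8)
  d <- uptake_difference(h$table, "bound", "free")
  d_bonf <- hdx_significance(d, bonferroni = TRUE)
  expect_lte(sum(d_bonf$significant), sum(d$significant))
  d_pool <- hdx_significance(d, method = "pooled")
  expect_type(d_pool$significant, "logical")
  expect_true(all(d_pool$ci_halfwidth > 0))
})

test_that("residue projection honours rules and marks missing coverage", {
  rec <- data.frame(sequence = c("AAAAAAAAAAA", "CCCCCCCCCCC"),
                    start = c(10, 15), end = c(20, 25),
                    timepoint_s = 500,
                    delta = c(-3, -1), sd_a = 0.05, sd_b = 0.05,
                    n_a = 3, n_b = 3,
                    fraction_of_max = c(-0.3, -0.1),
                    significant = TRUE)
  pr <- project_to_residues(rec, rule = "max_protection",
                            residues = 5:30)
  expect_true(all(is.na(pr$value[pr$resno < 10])))   # no data, not 0
  expect_equal(pr$value[pr$resno == 12], -0.3)
  expect_equal(pr$value[pr$resno == 17], -0.3)       # overlap: most protected
  expect_equal(pr$value[pr$resno == 23], -0.1)
  pr_min <- project_to_residues(rec, rule = "min_abs", residues = 17)
  expect_equal(pr_min$value, -0.1)
  pr_mean <- project_to_residues(rec, rule = "mean", residues = 17)
  expect_equal(pr_mean$value, -0.2)
  rec$significant <- FALSE
  expect_error(project_to_residues(rec), "significant")
})

test_that("missing replicate cells exclude the peptide with a warning", {
  peps <- gen_peptide_map(40, 10, 8, seed = 6)
  h <- gen_hdx(peps, seed = 2)
  tab <- h$table
  drop <- tab$sequence == peps$sequence[1] & tab$replicate == 3 &
    tab$state == "free"
  tab <- tab[!drop, ]
  expect_warning(d <- uptake_difference(tab, "bound", "free"),
                 "excluded")
  expect_false(peps$sequence[1] %in% d$sequence)
})

test_that("Woods-plot export writes the expected columns", {
  peps <- gen_peptide_map(40, 10, 8, seed = 6)
  h <- gen_hdx(peps, seed = 2)
  d <- uptake_difference(h$table, "bound", "free")
  f <- tempfile(fileext = ".csv")
  write_woods_csv(d, f)
  back <- utils::read.csv(f)
  expect_named(back, c("start", "end", "timepoint_s", "delta",
                       "ci_halfwidth", "significant",
                       "fraction_of_max"))
  expect_equal(nrow(back), nrow(d))
})
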