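test_that("both fitters recover generating parameters exactly on noiseless data", {
  for (pars in list(c(Km = 1, Vmax = 1), c(Km = 56, Vmax = 57788))) {
    d <- generate_kinetics_data(Km = pars["Km"], Vmax = pars["Vmax"],
                                mode = "none")
    lb <- fit_lineweaver_burk(d, 0)
    nl <- fit_mm_nonlinear(d, 0)
    expect_equal(lb$Km, unname(pars["Km"]), tolerance = 1e-9)
    expect_equal(lb$Vmax, unname(pars["Vmax"]), tolerance = 1e-9)
    expect_equal(nl$Km, lb$Km, tolerance = 1e-6)
    expect_equal(nl$Vmax, lb$Vmax, tolerance = 1e-6)
  }
})

test_that("degenerate kinetics inputs error informatively", {
  d <- generate_kinetics_data(Km = 10, Vmax = 100, mode = "none",
                              S = c(5, 50, 500))
  d$velocity[2] <- 0
  expect_error(fit_lineweaver_burk(d, 0), "positive velocities")
  expect_error(fit_lineweaver_burk(generate_kinetics_data(S = c(10, 100)), 0),
               "3 distinct")
  expect_error(kinetics_dataset(c(-1, 2, 3), c(1, 1, 1)), "positive")
})

test_that("Vmax scales with velocity units while Km is unchanged", {
  d <- generate_kinetics_data(Km = 37, Vmax = 1200, mode = "none",
                              noise_cv = 0.05, reps = 3, seed = 9)
  f1 <- fit_lineweaver_burk(d, 0)
  d2 <- d; d2$velocity <- d$velocity * 7.5
  f2 <- fit_lineweaver_burk(d2, 0)
  expect_equal(f2$Km, f1$Km, tolerance = 1e-9)
  expect_equal(f2$Vmax, f1$Vmax * 7.5, tolerance = 1e-9)
})

test_that("median Km error stays below 10% at 5% noise (simulation study)", {
  errs <- vapply(1:200, function(s) {
    d <- generate_kinetics_data(Km = 56, Vmax = 57788, mode = "none",
                                noise_cv = 0.05, reps = 3, seed = s)
    abs(fit_mm_nonlinear(d, 0)$Km - 56) / 56
  }, 0)
  expect_lt(median(errs), 0.10)
})

test_that("noiseless noncompetitive data gives the exact mode and Ki", {
  d <- generate_kinetics_data(Km = 56, Vmax = 57788,
                              mode = "noncompetitive", Ki = 20,
                              inhibitor_levels = c(15, 25))
  fits <- lapply(c(0, 15, 25), function(i) fit_mm_nonlinear(d, i))
  call <- classify_inhibition(fits[[1]], fits[-1])
  expect_equal(call$mode, "noncompetitive")
  expect_equal(call$Ki, 20, tolerance = 1e-6)
})

test_that("competitive data (apparent Km rising, Vmax flat) is called competitive", {
  d <- generate_kinetics_data(Km = 56, Vmax = 57788, mode = "competitive",
                              Ki = 10, inhibitor_levels = 20)  # Km_app x3
  fits <- lapply(c(0, 20), function(i) fit_lineweaver_burk(d, i))
  call <- classify_inhibition(fits[[1]], fits[[2]])
  expect_equal(call$mode, "competitive")
  expect_equal(call$Ki, 10, tolerance = 1e-6)
})

test_that("identical control and inhibited fits yield mode none, and inputs are checked", {
  d <- generate_kinetics_data(Km = 56, Vmax = 57788, mode = "none",
                              inhibitor_levels = 15)
  fits <- lapply(c(0, 15), function(i) fit_lineweaver_burk(d, i))
  call <- classify_inhibition(fits[[1]], fits[[2]])
  expect_equal(call$mode, "none")
  expect_true(is.na(call$Ki))
  expect_error(classify_inhibition(fits[[1]], list()), "at least one")
})

test_that("mode classification is reliable under 5% multiplicative noise", {
  correct <- 0L
  n_runs <- 100L
  for (s in seq_len(n_runs)) {
    mode <- if (s %% 2 == 0) "competitive" else "noncompetitive"
    d <- generate_kinetics_data(Km = 56, Vmax = 57788, mode = mode, Ki = 20,
                                inhibitor_levels = c(15, 25),
                                noise_cv = 0.05, reps = 3, seed = 1000 + s)
    fits <- lapply(c(0, 15, 25), function(i) fit_mm_nonlinear(d, i))
    call <- classify_inhibition(fits[[1]], fits[-1])
    if (call$mode == mode) correct <- correct + 1L
  }
  expect_gte(correct / n_runs, 0.95)
})

test_that("4PL fitting recovers generating curves and rescales with dose units", {
  dr <- generate_dose_response(IC50 = 16, hill = 1, top = 100, bottom = 0)
  fit <- fit_ic50(dr$dose, dr$response)
  expect_equal(fit$IC50, 16, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-4)
  expect_gt(fit$top, fit$bottom)

  dr2 <- generate_dose_response(IC50 = 1, hill = 1.5, top = 1, bottom = 0.1,
                                doses = 10^seq(-3, 3, length.out = 13))
  fit2 <- fit_ic50(dr2$dose, dr2$response)
  expect_equal(fit2$IC50, 1, tolerance = 1e-6)

  fit3 <- fit_ic50(dr$dose * 1000, dr$response)   # nM instead of uM
  expect_equal(fit3$IC50, 16000, tolerance = 1e-4)
  expect_error(fit_ic50(c(1, 2, 3), c(1, 2, 3)), "4 distinct")
  expect_error(fit_ic50(rep(c(1, 10, 100, 1000), 2), rep(1, 8)),
               "degenerate")
})

test_that("median IC50 error stays below 15% at 5% noise (simulation study)", {
  errs <- vapply(1:150, function(s) {
    dr <- generate_dose_response(IC50 = 16, hill = 1, top = 100, bottom = 0,
                                 noise_cv = 0.05, reps = 2, seed = s)
    abs(fit_ic50(dr$dose, dr$response)$IC50 - 16) / 16
  }, 0)
  expect_lt(median(errs), 0.15)
})

test_that("mutant inhibition is normalised within each variant", {
  tab <- normalize_mutant_inhibition(c(WT = 30, R186A = 81),
                                     c(WT = 100, R186A = 90))
  expect_equal(tab$inhibition_pct, c(70, 10))
  expect_equal(normalize_mutant_inhibition(5, 5)$inhibition_pct, 0)
  expect_equal(normalize_mutant_inhibition(5, 10)$inhibition_pct, 50)
  expect_error(normalize_mutant_inhibition(1, 0), "non-positive control")
})

test_that("kinetics CSV reading validates its schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  d <- generate_kinetics_data(Km = 5, Vmax = 10, mode = "none")
  write.csv(data.frame(substrate_uM = d$substrate, inhibitor_uM = d$inhibitor,
                       replicate = d$replicate, velocity = d$velocity),
            path, row.names = FALSE)
  back <- read_kinetics_csv(path)
  expect_equal(fit_lineweaver_burk(back, 0)$Km, 5, tolerance = 1e-9)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_kinetics_csv(bad), "missing column")
})
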