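# Hill fitting: exact round trips, noisy recovery, invariances, and the
# viability-plate pipeline.

test_that("noiseless Hill data are recovered exactly", {
  conc <- c(1, 3, 10, 30, 100)
  dat <- data.frame(concentration = conc,
                    response = hill_curve(conc, 10, 2))
  f <- fit_hill(dat, direction = "increasing")
  expect_lt(abs(f$ec50 - 10) / 10, 1e-6)
  expect_lt(abs(f$hill_n - 2) / 2, 1e-6)
  expect_true(f$converged)
  # curve value at EC50 is the plateau midpoint
  expect_equal(predict(f, f$ec50), (f$top + f$bottom) / 2)

  # grid round trip across the (EC50, n) plane
  for (e in c(0.1, 10, 100)) {
    for (n in c(0.5, 2, 5)) {
      cg <- exp(seq(log(e / 30), log(e * 30), length.out = 9))
      d <- data.frame(concentration = cg,
                      response = hill_curve(cg, e, n, top = 0.9,
                                            bottom = 0.1))
      fg <- fit_hill(d, direction = "increasing")
      expect_lt(abs(fg$ec50 - e) / e, 1e-6)
      expect_lt(abs(fg$hill_n - n) / n, 1e-6)
    }
  }
})

test_that("decreasing curves and constraints work", {
  conc <- exp(seq(log(0.5), log(200), length.out = 8))
  resp <- hill_curve(conc, 7.8, 2, top = 1, bottom = 0)
  f <- fit_hill(data.frame(concentration = conc, response = 1 - resp),
                direction = "decreasing",
                constraints = list(bottom = 0, top = 1))
  expect_lt(abs(f$ec50 - 7.8) / 7.8, 1e-6)
  expect_equal(f$top, 1)
  expect_equal(f$bottom, 0)
  expect_lte(f$bottom, f$top)
  # auto direction detection
  fa <- fit_hill(data.frame(concentration = conc, response = 1 - resp))
  expect_equal(fa$direction, "decreasing")
})

test_that("fit_hill rejects unidentifiable and malformed inputs", {
  expect_error(fit_hill(data.frame(concentration = c(1, 2, 3),
                                   response = c(0, 0.5, 1))),
               "4 distinct")
  expect_error(fit_hill(data.frame(concentration = c(1, 3, 10, 30),
                                   response = rep(1, 4))),
               "unidentifiable")
  expect_error(fit_hill(data.frame(concentration = c(-1, 3, 10, 30),
                                   response = c(0, 0.3, 0.6, 1))),
               "> 0")
})

test_that("fit_hill is scale-equivariant and order-invariant", {
  conc <- c(1, 3, 10, 30, 100)
  resp <- hill_curve(conc, 10, 2)
  f1 <- fit_hill(data.frame(concentration = conc, response = resp))
  f2 <- fit_hill(data.frame(concentration = conc * 10, response = resp))
  expect_equal(f2$ec50 / f1$ec50, 10, tolerance = 1e-6)
  expect_equal(f2$hill_n, f1$hill_n, tolerance = 1e-6)
  ord <- c(4, 2, 5, 1, 3)
  f3 <- fit_hill(data.frame(concentration = conc[ord],
                            response = resp[ord]))
  expect_equal(f3$ec50, f1$ec50, tolerance = 1e-9)
})

test_that("noisy simulation study recovers EC50 within 10% (median)", {
  conc <- exp(seq(log(1), log(100), length.out = 6))
  errs <- vapply(1:60, function(s) {
    tab <- gen_dose_response("hill", list(ec50 = 10, n = 2), conc,
                             n_reps = 3, noise_sd = 0.05, seed = s)
    f <- fit_hill(tab, direction = "increasing",
                  constraints = list(bottom = 0, top = 1))
    abs(f$ec50 - 10) / 10
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("compare_binding_killing classifies cooperativity", {
  conc <- exp(seq(log(0.5), log(100), length.out = 9))
  bind <- fit_hill(data.frame(concentration = conc,
                              response = hill_curve(conc, 5.1, 1.1)))
  kill <- fit_hill(data.frame(concentration = conc,
                              response = hill_curve(conc, 10.2, 3.2)))
  rep_ <- compare_binding_killing(bind, kill)
  expect_equal(rep_$hill_n_ratio, 3.2 / 1.1, tolerance = 1e-4)
  expect_equal(rep_$binding_class, "non-cooperative")
  expect_equal(rep_$killing_class, "cooperative")
  same <- compare_binding_killing(bind, bind)
  expect_equal(same$ec50_ratio, 1)
  expect_equal(same$hill_n_ratio, 1)
  expect_equal(same$binding_class, same$killing_class)
  bad <- bind; bad$converged <- FALSE
  expect_error(compare_binding_killing(bad, kill), "converged")
})

test_that("ic50_from_viability reproduces a synthetic plate", {
  conc <- exp(seq(log(1), log(60), length.out = 7))
  make_plate <- function(noise, seed) {
    set.seed(seed)
    viab <- hill_curve(conc, 7.8, 2, top = 0, bottom = 1) # decreasing
    rows <- do.call(rbind, lapply(1:3, function(r) {
      sig <- c(1, viab) * (1 + rnorm(length(conc) + 1, sd = noise))
      data.frame(concentration = c(0, conc), a450 = 0.2 + sig,
                 a620 = 0.2)
    }))
    rows
  }
  res <- ic50_from_viability(make_plate(0.02, 1))
  expect_equal(res$fit$ec50, 7.8, tolerance = 0.1)
  expect_equal(res$fit$direction, "decreasing")
  # control wells with A620 > A450 are flagged and excluded
  plate <- make_plate(0.02, 2)
  plate$a620[1] <- plate$a450[1] + 1
  expect_warning(res2 <- ic50_from_viability(plate), "excluded")
  expect_equal(res2$excluded_wells, 1L)
  # treated == control everywhere -> viability flat -> unidentifiable
  flat <- data.frame(concentration = rep(c(0, conc), 3),
                     a450 = 1.2, a620 = 0.2)
  expect_error(ic50_from_viability(flat), "unidentifiable")
  expect_error(ic50_from_viability(data.frame(concentration = conc,
                                              a450 = 1, a620 = 0)),
               "no control")
})
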