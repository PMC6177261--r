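# SPR 1:1 kinetics: association, dissociation, derived quantities.

test_that("the association model has its closed-form limits", {
  ## at t = 0 only the refractive-index jump remains
  expect_equal(eval_association(0, 1e-8, 1e6, 0.01, 100, RRI = 7,
                                cD = 0.3), 7, tolerance = 1e-12)
  ## without drift, t -> infinity approaches the binding plateau
  plateau <- 1e6 * 1e-8 * 100 / (1e6 * 1e-8 + 0.01) + 7
  expect_equal(eval_association(1e6, 1e-8, 1e6, 0.01, 100, RRI = 7,
                                cD = 0), plateau, tolerance = 1e-9)
})

test_that("global association fits recover the generating rates", {
  c0 <- c(2.5e-9, 5e-9, 1e-8, 2e-8, 4e-8)
  sim <- simulate_sensorgram(kon = 1e6, koff = 0.01, Rmax = 100,
                             RRI = 5, cD = 0.01, c0_list = c0,
                             t_assoc = 120, t_dissoc = 0, dt = 1,
                             noise_sd = 0.5, seed = 2)
  fit <- fit_association(sim$association)
  expect_lt(abs(fit$kon / 1e6 - 1), 0.10)
  expect_lt(abs(fit$koff / 0.01 - 1), 0.10)
  expect_equal(fit$KD, fit$koff / fit$kon, tolerance = 1e-12)
  expect_equal(fit$tau * fit$koff, 1, tolerance = 1e-12)
  expect_error(fit_association(sim$association[1:2]), ">= 3")
})

test_that("kobs linearisation agrees with the global fit on clean data", {
  c0 <- c(2.5e-9, 5e-9, 1e-8, 2e-8, 4e-8)
  sim <- simulate_sensorgram(1e6, 0.01, 100, RRI = 0, cD = 0,
                             c0_list = c0, t_assoc = 120, t_dissoc = 0,
                             dt = 1, noise_sd = 0, seed = 1)
  kobs <- vapply(sim$association, function(sg)
    fit_association_single(sg, drift = FALSE)$kobs, numeric(1))
  lin <- kobs_linear_fit(kobs, c0)
  expect_lt(abs(lin$kon / 1e6 - 1), 0.05)
  expect_lt(abs(lin$koff / 0.01 - 1), 0.05)
  ## observed rates are linear in concentration ("perfect fit" warning
  ## from summary.lm is exactly the point here)
  expect_gt(suppressWarnings(summary(lin$fit)$r.squared), 1 - 1e-8)
})

test_that("dissociation fits recover the off-rate", {
  ## exact single exponential
  t <- seq(100, 400, by = 1)
  sg <- sensorgram(t, 80 * exp(-0.05 * (t - 100)) + 3, 1e-8,
                   phase = "dissociation")
  fit <- fit_dissociation(sg)
  expect_lt(abs(fit$koff / 0.05 - 1), 1e-6)
  expect_equal(fit$tau, 1 / fit$koff, tolerance = 1e-12)
  ## a constant trace cannot be fit
  flat <- sensorgram(t, rep(50, length(t)), 1e-8, "dissociation")
  expect_error(fit_dissociation(flat), "does not decay")
  ## cross-method consistency on jointly simulated data
  c0 <- c(5e-9, 1e-8, 2e-8, 4e-8, 8e-8)
  sim <- simulate_sensorgram(1e6, 0.02, 100, RRI = 2, cD = 0,
                             c0_list = c0, t_assoc = 200, t_dissoc = 300,
                             dt = 0.5, noise_sd = 0.3, seed = 4)
  ga <- fit_association(sim$association)
  kd <- vapply(sim$dissociation, function(sg)
    fit_dissociation(sg)$koff, numeric(1))
  expect_lt(abs(stats::median(kd) / ga$koff - 1), 0.15)
})

test_that("residence time is the reciprocal off-rate", {
  expect_equal(residence_time(list(koff = 0.01)), 100)
  expect_equal(residence_time(1), 1)
  expect_error(residence_time(list(koff = -1)))
  ## tau ratio is the inverse koff ratio
  a <- list(koff = 0.004); b <- list(koff = 0.02)
  expect_equal(residence_time(a) / residence_time(b),
               b$koff / a$koff, tolerance = 1e-12)
})

test_that("preference comparisons reproduce the fold-change arithmetic", {
  mkfit <- function(KA) structure(list(KA = KA, Kd = 1 / KA),
                                  class = "quadratic_binding_fit")
  ## equal affinities: no shift
  eq <- compare_preference(mkfit(1e8), mkfit(1e8), mkfit(1e8),
                           mkfit(1e8))
  expect_equal(eq$shift, 1)
  ## a 25x BM gain with a 10x ZM loss gives a 250-fold shift
  cp <- compare_preference(mkfit(1e7), mkfit(1e8),
                           mkfit(25 * 1e7), mkfit(1e8 / 10))
  expect_equal(cp$shift, 250, tolerance = 1e-12)
  expect_equal(cp$fold_BM, 25, tolerance = 1e-12)
  expect_equal(cp$fold_ZM, 0.1, tolerance = 1e-12)
  ## swapping the proteins inverts the shift exactly
  sw <- compare_preference(mkfit(25 * 1e7), mkfit(1e8 / 10),
                           mkfit(1e7), mkfit(1e8))
  expect_equal(sw$log10_shift, -cp$log10_shift, tolerance = 1e-12)
  ## equilibrium and kinetic affinities do not mix silently
  kin <- structure(list(KD = 1e-8, koff = 0.01, kon = 1e6, tau = 100),
                   class = "kinetic_fit")
  expect_error(compare_preference(mkfit(1e8), kin, mkfit(1e8),
                                  mkfit(1e8)), "allow_mixed")
  mixed <- compare_preference(mkfit(1e8), kin, mkfit(1e8), mkfit(1e8),
                              allow_mixed = TRUE)
  expect_equal(mixed$preference_A, 1, tolerance = 1e-12)
})

test_that("sensorgram TSVs round-trip", {
  c0 <- c(5e-9, 2e-8)
  sim <- simulate_sensorgram(1e6, 0.02, 80, RRI = 3, cD = 0.005,
                             c0_list = c0, t_assoc = 60, t_dissoc = 60,
                             dt = 2, noise_sd = 0.2, seed = 5)
  curves <- c(sim$association, sim$dissociation)
  f <- tempfile(fileext = ".tsv")
  write_sensorgrams(curves, f)
  back <- read_sensorgrams(f)
  expect_length(back, 4L)
  orig_key <- sort(vapply(curves, function(sg)
    paste(attr(sg, "c0"), attr(sg, "phase")), character(1)))
  back_key <- sort(vapply(back, function(sg)
    paste(attr(sg, "c0"), attr(sg, "phase")), character(1)))
  expect_identical(orig_key, back_key)
})
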