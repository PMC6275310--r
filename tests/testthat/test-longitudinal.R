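acc_row <- function(p, cid, w, acc) {
  data.frame(perceiver = p, classroom_id = cid, wave_id = w, accuracy = acc,
             stringsAsFactors = FALSE)
}
tr_row <- function(cid, w, t) {
  data.frame(classroom_id = cid, wave_id = w, transitivity = t,
             stringsAsFactors = FALSE)
}

test_that("assemble_long_table disaggregates transitivity around the first wave", {
  acc <- rbind(acc_row("P1", "K", 0, 0.5), acc_row("P1", "K", 1, 0.6),
               acc_row("P1", "K", 2, 0.4), acc_row("P2", "K", 0, 0.3),
               acc_row("P2", "K", 1, 0.2))
  tr <- rbind(tr_row("K", 0, 0.50), tr_row("K", 1, 0.60), tr_row("K", 2, 0.55))
  lt <- assemble_long_table(acc, tr, verbose = FALSE)
  p1 <- lt[lt$participant == "P1", ]
  expect_equal(p1$transitivity_t0, rep(0.50, 3))
  expect_equal(p1$transitivity_change, c(0, 0.10, 0.05))
  expect_equal(p1$time, 0:2)
  # disaggregation identity on every row
  expect_equal(lt$transitivity_t0 + lt$transitivity_change, lt$transitivity)
  # change is exactly zero at each participant's first observed wave
  first <- !duplicated(lt$participant)
  expect_equal(lt$transitivity_change[first], rep(0, sum(first)))
})

test_that("participants below min_waves are dropped and counted", {
  acc <- rbind(acc_row("P1", "K", 0, 0.5), acc_row("P1", "K", 1, 0.6),
               acc_row("P2", "K", 1, 0.3))
  tr <- rbind(tr_row("K", 0, 0.5), tr_row("K", 1, 0.6))
  expect_message(lt <- assemble_long_table(acc, tr), "1 participant")
  expect_identical(unique(lt$participant), "P1")
  expect_identical(attr(lt, "n_excluded_participants"), 1L)
})

test_that("t0 means the first OBSERVED wave, not calendar wave 0", {
  acc <- rbind(acc_row("P1", "K", 1, 0.5), acc_row("P1", "K", 2, 0.6))
  tr <- rbind(tr_row("K", 0, 0.9), tr_row("K", 1, 0.4), tr_row("K", 2, 0.5))
  lt <- assemble_long_table(acc, tr, verbose = FALSE)
  expect_equal(unique(lt$transitivity_t0), 0.4)
  expect_equal(lt$time, 1:2)
})

test_that("classroom switchers take each wave's own classroom transitivity", {
  acc <- rbind(acc_row("P1", "K1", 0, 0.5), acc_row("P1", "K2", 1, 0.6))
  tr <- rbind(tr_row("K1", 0, 0.40), tr_row("K1", 1, 0.80), tr_row("K2", 1, 0.70))
  lt <- assemble_long_table(acc, tr, verbose = FALSE)
  expect_equal(lt$transitivity, c(0.40, 0.70))
  expect_equal(lt$transitivity_change, c(0, 0.30))
})

test_that("rows with undefined transitivity are excluded and counted", {
  acc <- rbind(acc_row("P1", "K", 0, 0.5), acc_row("P1", "K", 1, 0.6),
               acc_row("P1", "K", 2, 0.7))
  tr <- rbind(tr_row("K", 0, 0.5), tr_row("K", 1, NA_real_), tr_row("K", 2, 0.6))
  expect_message(lt <- assemble_long_table(acc, tr), "undefined classroom transitivity")
  expect_identical(nrow(lt), 2L)
  expect_identical(attr(lt, "n_missing_transitivity"), 1L)
  # dangling classroom-wave reference is an error, not silent
  expect_error(assemble_long_table(acc, tr[1:2, ], verbose = FALSE),
               "no transitivity record")
})

test_that("fixed effects match an OLS oracle when the intercept variance hits zero", {
  # balanced panel simulated with zero between-person variance; REML puts the
  # intercept variance on the boundary and the GLS fit collapses to OLS
  tab <- simulate_from_model(60, 3, beta = c(0.2, 0.01, 0.4, 0.3),
                             sigma2_intercept = 0, sigma2_residual = 0.02,
                             seed = 2026)
  fit <- fit_random_intercept(tab)
  expect_equal(fit$sigma2_intercept, 0, tolerance = 1e-10)
  ols <- stats::lm(accuracy ~ time + transitivity_t0 + transitivity_change, tab)
  expect_equal(fit$fixed$estimate, unname(stats::coef(ols)), tolerance = 1e-4)
})

test_that("a single replicate recovers the generating fixed effects", {
  tab <- simulate_from_model(150, 3, beta = c(0.1, 0, 0.5, 0.5),
                             sigma2_intercept = 0.01, sigma2_residual = 0.01,
                             seed = 81)
  fit <- fit_random_intercept(tab)
  expect_identical(fit$n_participants, 150L)
  expect_identical(fit$n_observations, 450L)
  expect_identical(fit$df_method, "Satterthwaite")
  expect_equal(fit$fixed$estimate, c(0.1, 0, 0.5, 0.5), tolerance = 0.12)
  expect_gt(fit$sigma2_intercept, 0)
  expect_gt(fit$sigma2_residual, 0)
})

test_that("singular designs raise classed errors naming the predictor", {
  tab <- simulate_from_model(20, 3, seed = 5)
  tab$transitivity_change <- 0  # transitivity constant over time
  expect_error(fit_random_intercept(tab), "transitivity_change",
               class = "scmnet_singular_design")
  tab2 <- simulate_from_model(20, 3, seed = 6)
  tab2$accuracy <- 1  # no accuracy variance (e.g. noiseless reports)
  expect_error(fit_random_intercept(tab2), class = "scmnet_singular_design")
  tab3 <- simulate_from_model(20, 3, seed = 7)
  tab3$transitivity_t0 <- 1 - tab3$time  # collinear with time
  expect_error(fit_random_intercept(tab3), class = "scmnet_singular_design")
  expect_error(fit_random_intercept(simulate_from_model(20, 3, seed = 8)[1:3, ]),
               "at least 2 participants")
})

test_that("shifting all transitivity values moves only the intercept", {
  tab <- simulate_from_model(50, 3, seed = 33)
  fit1 <- fit_random_intercept(tab)
  shift <- 0.25
  tab2 <- tab
  tab2$transitivity <- tab2$transitivity + shift
  tab2$transitivity_t0 <- tab2$transitivity_t0 + shift
  fit2 <- fit_random_intercept(tab2)
  est <- function(f, term) f$fixed$estimate[f$fixed$term == term]
  expect_equal(est(fit2, "transitivity_t0"), est(fit1, "transitivity_t0"),
               tolerance = 1e-6)
  expect_equal(est(fit2, "transitivity_change"), est(fit1, "transitivity_change"),
               tolerance = 1e-6)
  expect_equal(est(fit2, "intercept"),
               est(fit1, "intercept") - shift * est(fit1, "transitivity_t0"),
               tolerance = 1e-6)
})

test_that("coefficients translate into expected accuracy differences", {
  fit <- scm_model_fit(estimates = c(intercept = 0.01, time = 0.01,
                                     transitivity_t0 = 0.67,
                                     transitivity_change = 0.62),
                       n_participants = 145L, n_observations = 357L)
  expect_equal(predicted_accuracy_difference(fit, "transitivity_t0", 0.10), 0.067)
  expect_equal(predicted_accuracy_difference(fit, "transitivity_change", 0.10), 0.062)
  expect_equal(predicted_accuracy_difference(fit, "transitivity_t0", 0), 0)
  expect_error(predicted_accuracy_difference(fit, "slope", 0.1))
})
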