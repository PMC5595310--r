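test_that("noiseless year-interaction coefficients reproduce the generating values", {
  set.seed(21)
  tr <- simulate_traits(20, 0)
  beta <- 0.01
  panel <- noiseless_panel(tr, 10, b_temp = beta)
  fit <- fit_attribute_year_model(panel,
                                  model_spec(confounders = "habitat_breadth"))
  yf <- coef(fit)[fit$group == "year_focal"]
  # reference coding: coefficient for year t is beta * (t - 1)
  expect_lt(max(abs(yf - beta * (2:10 - 1))), 1e-6)
  yc <- coef(fit)[fit$group == "year_confounder"]
  expect_lt(max(abs(yc)), 1e-6)
  # full-mode in-sample predictions reproduce the observations
  pr <- predict_abundances(fit, panel, mode = "full")
  expect_lt(max(abs(pr$abundance / panel$abundance - 1)), 1e-8)
})

test_that("AR(1) residual correlation is recovered", {
  set.seed(22)
  tr <- simulate_traits(50, 0)
  panel <- ar1_panel(tr, 25, slope_temp = 0.02, rho = 0.5, sd = 0.3)
  fit <- fit_attribute_year_model(panel,
                                  model_spec(confounders = "habitat_breadth"))
  expect_lt(abs(fit$rho - 0.5), 0.1)
})

test_that("year-interaction slopes are recovered on average across replicates", {
  set.seed(23)
  b <- 0.03
  est <- replicate(20, {
    tr <- simulate_traits(30, 0)
    panel <- ar1_panel(tr, 10, slope_temp = b, sd = 0.2, sp_sd = 0.2)
    fit <- fit_attribute_year_model(
      panel, model_spec(confounders = "habitat_breadth"))
    unname(coef(fit)[fit$group == "year_focal"][9])  # final year vs year 1
  })
  target <- b * 9
  expect_lt(abs(mean(est) - target), 3 * sd(est) / sqrt(length(est)))
})

test_that("temp_only predictions equal full predictions when confounder interactions are zero", {
  set.seed(24)
  tr <- simulate_traits(15, -0.4)
  panel <- ar1_panel(tr, 8, slope_temp = 0.03, slope_hab = 0.02, sd = 0.15)
  fit <- fit_attribute_year_model(panel,
                                  model_spec(confounders = "habitat_breadth"))
  fit$coefficients[fit$group == "year_confounder"] <- 0
  expect_identical(predict_abundances(fit, panel, "temp_only"),
                   predict_abundances(fit, panel, "full"))
  # and then the two modelled CTI variants coincide exactly
  m1 <- modelled_cti(fit, panel, tr)
  m2 <- modelled_uncorrected_cti(fit, panel, tr)
  expect_equal(m1$cti, m2$cti)
})

test_that("temp_only within-species year ratios ignore confounder values", {
  set.seed(25)
  tr <- simulate_traits(12, 0)
  panel <- ar1_panel(tr, 6, slope_temp = 0.04, slope_hab = 0.03, sd = 0.1)
  fit <- fit_attribute_year_model(panel,
                                  model_spec(confounders = "habitat_breadth"))
  pr1 <- predict_abundances(fit, panel, "temp_only")
  # permute confounder values among species, holding the fit fixed: levels
  # shift (main effect retained) but year-to-year ratios are unchanged
  perm <- panel
  sp <- unique(panel$species)
  shuffled <- sample(sp)
  perm$habitat_breadth <- tr$habitat_breadth[match(shuffled, tr$species)][
    match(perm$species, sp)]
  pr2 <- predict_abundances(fit, perm, "temp_only")
  year_ratios <- function(pr) {
    base <- pr$abundance[pr$year == 1]
    names(base) <- pr$species[pr$year == 1]
    pr$abundance[pr$year > 1] / base[pr$species[pr$year > 1]]
  }
  expect_equal(year_ratios(pr1), year_ratios(pr2))
})

test_that("collinearity guard trips above the threshold and can be overridden", {
  set.seed(26)
  tr <- simulate_traits(25, 0.95)
  panel <- ar1_panel(tr, 6, slope_temp = 0.02, sd = 0.1)
  expect_error(
    fit_attribute_year_model(panel, model_spec(confounders = "habitat_breadth")),
    "collinearity guard")
  fit <- fit_attribute_year_model(
    panel, model_spec(confounders = "habitat_breadth", force = TRUE))
  expect_s3_class(fit, "attribute_year_model")
})

test_that("rank deficiency is reported with the aliased terms", {
  set.seed(27)
  tr <- simulate_traits(10, 0)
  panel <- ar1_panel(tr, 5, slope_temp = 0.02, sd = 0.1)
  panel$copy <- panel$temp_pref  # perfect alias of the focal trait
  expect_error(
    fit_attribute_year_model(panel, model_spec(confounders = "copy")),
    "collinearity guard")
  expect_error(
    fit_attribute_year_model(panel, model_spec(confounders = "copy",
                                               force = TRUE)),
    "rank deficient")
})

test_that("fitting is deterministic", {
  set.seed(28)
  tr <- simulate_traits(15, -0.3)
  panel <- ar1_panel(tr, 8, slope_temp = 0.02, rho = 0.3, sd = 0.2)
  f1 <- fit_attribute_year_model(panel,
                                 model_spec(confounders = "habitat_breadth"))
  f2 <- fit_attribute_year_model(panel,
                                 model_spec(confounders = "habitat_breadth"))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$rho, f2$rho)
})

test_that("fixed effects agree with an independent nlme::lme fit", {
  set.seed(29)
  tr <- simulate_traits(20, -0.3)
  panel <- ar1_panel(tr, 10, slope_temp = 0.03, slope_hab = -0.02,
                     rho = 0.4, sd = 0.2, sp_sd = 0.3)
  fit <- fit_attribute_year_model(panel,
                                  model_spec(confounders = "habitat_breadth"))
  d <- panel
  d$lab <- log(d$abundance)
  d$fYear <- factor(d$year)
  d$tp <- d$temp_pref - mean(tr$temp_pref)
  d$hb <- d$habitat_breadth - mean(tr$habitat_breadth)
  d$cy <- d$year - mean(unique(d$year))
  lfit <- nlme::lme(lab ~ fYear + tp + hb + fYear:tp + fYear:hb,
                    random = list(species = nlme::pdDiag(~ 1 + cy)),
                    correlation = nlme::corAR1(form = ~ year | species),
                    data = d, method = "ML",
                    control = nlme::lmeControl(maxIter = 200,
                                               msMaxIter = 200,
                                               opt = "optim"))
  nm <- gsub("habitat_breadth", "hb",
             gsub("temp_pref", "tp", names(coef(fit))))
  expect_lt(max(abs(coef(fit) - nlme::fixef(lfit)[nm])), 1e-4)
  expect_lt(abs(fit$rho -
                  coef(lfit$modelStruct$corStruct, unconstrained = FALSE)),
            0.05)
  expect_gte(fit$logLik, as.numeric(logLik(lfit)) - 1e-2)
})

test_that("modelled-uncorrected CTI equals the original CTI on saturated noiseless data", {
  set.seed(30)
  tr <- simulate_traits(18, -0.5)
  panel <- noiseless_panel(tr, 8, b_temp = 0.03, b_hab = 0.04)
  fit <- fit_attribute_year_model(panel,
                                  model_spec(confounders = "habitat_breadth"))
  orig <- cti_series(panel, tr, variant = "original")
  unc <- modelled_uncorrected_cti(fit, panel, tr)
  expect_lt(max(abs(unc$cti - orig$cti)), 1e-8)
  # the corrected series differs (it removes the habitat-year effects)...
  mod <- modelled_cti(fit, panel, tr)
  expect_gt(max(abs(mod$cti - orig$cti)), 0.01)
  # ...except in the base year, where main effects keep them aligned
  expect_lt(abs(mod$cti[1] - orig$cti[1]), 1e-8)
})

test_that("randomized-attribute averaging matches coefficient dropping", {
  set.seed(31)
  tr <- simulate_traits(20, -0.6)
  panel <- ar1_panel(tr, 8, slope_temp = 0.04, slope_hab = 0.04, sd = 0.15)
  fit <- fit_attribute_year_model(panel,
                                  model_spec(confounders = "habitat_breadth"))
  # identity when confounder effects are zero
  fit0 <- fit
  fit0$coefficients[fit0$group %in% c("year_confounder",
                                      "main_confounder")] <- 0
  expect_equal(randomized_attribute_cti(fit0, panel, tr, n_draws = 3,
                                        seed = 1)$cti,
               modelled_cti(fit0, panel, tr)$cti)
  # seeded reproducibility
  r1 <- randomized_attribute_cti(fit, panel, tr, n_draws = 10, seed = 7)
  r2 <- randomized_attribute_cti(fit, panel, tr, n_draws = 10, seed = 7)
  expect_identical(r1$cti, r2$cti)
  expect_error(randomized_attribute_cti(fit, panel, tr, n_draws = 0), "n_draws")
  # Monte-Carlo noise shrinks with the number of draws
  set.seed(99)
  few <- replicate(8, randomized_attribute_cti(fit, panel, tr,
                                               n_draws = 2)$cti[8])
  many <- replicate(8, randomized_attribute_cti(fit, panel, tr,
                                                n_draws = 40)$cti[8])
  expect_lt(sd(many), sd(few))
})

test_that("information-criterion comparison detects attribute interactions", {
  set.seed(32)
  tr <- simulate_traits(25, 0)
  # no confounders: the two candidate models are identical -> tie
  panel <- ar1_panel(tr, 6, slope_temp = 0.03, sd = 0.15)
  cmp <- compare_interaction_models(panel, model_spec())
  expect_equal(cmp$preferred, "tie")
  # strong true focal x confounder interaction -> interaction model wins
  panel2 <- ar1_panel(tr, 6, slope_temp = 0.03, sd = 0.15)
  panel2$abundance <- panel2$abundance *
    exp(0.8 * panel2$temp_pref * panel2$habitat_breadth)
  cmp2 <- compare_interaction_models(
    panel2, model_spec(confounders = "habitat_breadth"))
  expect_equal(cmp2$preferred, "interaction")
  # without a true interaction the simpler model is usually preferred
  set.seed(33)
  pref <- replicate(10, {
    trr <- simulate_traits(20, 0)
    pp <- ar1_panel(trr, 6, slope_temp = 0.03, slope_hab = 0.02,
                    sd = 0.2, sp_sd = 0.2)
    compare_interaction_models(
      pp, model_spec(confounders = "habitat_breadth"))$preferred
  })
  expect_gte(sum(pref == "no_interaction"), 6)
})

test_that("prediction rejects unknown species and years", {
  set.seed(34)
  tr <- simulate_traits(10, 0)
  panel <- ar1_panel(tr, 5, slope_temp = 0.02, sd = 0.1)
  fit <- fit_attribute_year_model(panel,
                                  model_spec(confounders = "habitat_breadth"))
  bad_sp <- panel[1, ]; bad_sp$species <- "novel"
  expect_error(predict_abundances(fit, bad_sp), "species")
  bad_yr <- panel[1, ]; bad_yr$year <- 99L
  expect_error(predict_abundances(fit, bad_yr), "years")
})
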