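# Prediction machinery for the modelled CTI.  The correction consists of
# predicting abundances from the fitted model while excluding the
# year-interaction effects of all non-temperature attributes: year-to-year
# differences in the predictions are then driven by temperature preference
# alone, while the retained main effects keep the year-1 community identical
# to the observed one.

#' Predict abundances from a fitted attribute-by-year model
#'
#' @param model an `attribute_year_model` from [fit_attribute_year_model()].
#' @param panel panel rows (species, year, trait columns) to predict for;
#'   species and years must be among those used for fitting.
#' @param mode `"full"`: all fixed effects; `"temp_only"`: the
#'   year-by-confounder interaction coefficients are dropped (set to zero),
#'   retaining all main effects and the year-by-focal-trait interactions.
#' @return data frame `species, year, abundance` with predictions on the
#'   natural scale (plain exponential of the log-scale fit); species random
#'   intercepts are included, random continuous-year slopes are not.
#' @export
predict_abundances <- function(model, panel, mode = c("full", "temp_only")) {
  stopifnot(inherits(model, "attribute_year_model"))
  mode <- match.arg(mode)
  unknown <- setdiff(unique(panel$species), model$ranef$species)
  if (length(unknown))
    stop("species not in fitted model: ", paste(unknown, collapse = ", "))
  dm <- build_design(panel, model$meta)  # errors on unknown years/levels
  beta <- model$coefficients
  if (mode == "temp_only")
    beta[model$group == "year_confounder"] <- 0
  eta <- drop(dm$X %*% beta) +
    model$ranef$intercept[match(panel$species, model$ranef$species)]
  data.frame(species = panel$species, year = panel$year,
             abundance = exp(eta), stringsAsFactors = FALSE)
}

#' Modelled (corrected) CTI
#'
#' The CTI computed from model-predicted abundances in which the
#' year-interaction effects of every confounding attribute have been
#' removed, so that year-to-year changes in the weights reflect temperature
#' preference alone.
#'
#' @inheritParams predict_abundances
#' @param traits a [trait_table()] covering the panel species.
#' @return a `cti_series` with variant `"modelled"`.
#' @export
modelled_cti <- function(model, panel, traits) {
  pred <- predict_abundances(model, panel, mode = "temp_only")
  out <- cti_series(pred, traits, variant = "original")
  out$variant <- "modelled"
  out
}

#' Modelled-uncorrected CTI
#'
#' The CTI computed from predictions retaining all fixed effects.  If the
#' model captures the community dynamics, this series should track the
#' original CTI closely; it is the model-adequacy check.
#'
#' @inheritParams modelled_cti
#' @return a `cti_series` with variant `"modelled_uncorrected"`.
#' @export
modelled_uncorrected_cti <- function(model, panel, traits) {
  pred <- predict_abundances(model, panel, mode = "full")
  out <- cti_series(pred, traits, variant = "original")
  out$variant <- "modelled_uncorrected"
  out
}

#' Modelled CTI via randomized-attribute averaging
#'
#' Alternative route to the corrected CTI: instead of dropping the
#' year-by-confounder coefficients, the confounder values are repeatedly
#' permuted among species (one shared permutation per draw, preserving the
#' joint confounder distribution), full-model predictions are computed for
#' each draw, and the predictions are averaged across draws before the CTI
#' is calculated.  Averaging breaks the covariation between the confounders
#' and the focal trait, so the two routes agree up to Monte-Carlo error.
#'
#' @inheritParams modelled_cti
#' @param n_draws number of permutation draws (default 100).
#' @param seed integer seed for reproducibility.
#' @return a `cti_series` with variant `"modelled"` and attribute
#'   `method = "randomized_attribute"`; attribute `draw_cti` holds the
#'   per-draw CTI matrix (years x draws) for Monte-Carlo error assessment.
#' @export
randomized_attribute_cti <- function(model, panel, traits, n_draws = 100L,
                                     seed = NULL) {
  if (n_draws < 1L) stop("n_draws must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  confs <- model$meta$confounders
  if (!length(confs)) return(modelled_cti(model, panel, traits))
  sp <- sort(unique(panel$species))
  sp_rows <- match(panel$species, sp)
  sp_level <- panel[match(sp, panel$species), confs, drop = FALSE]
  acc <- NULL
  draw_mat <- NULL
  for (d in seq_len(n_draws)) {
    perm <- sample.int(length(sp))
    pp <- panel
    for (cf in confs) pp[[cf]] <- sp_level[[cf]][perm][sp_rows]
    pred <- predict_abundances(model, pp, mode = "full")
    acc <- if (is.null(acc)) pred$abundance else acc + pred$abundance
    ds <- cti_series(pred, traits, variant = "original")
    draw_mat <- cbind(draw_mat, ds$cti)
  }
  pred <- data.frame(species = panel$species, year = panel$year,
                     abundance = acc / n_draws, stringsAsFactors = FALSE)
  out <- cti_series(pred, traits, variant = "original")
  out$variant <- "modelled"
  attr(out, "method") <- "randomized_attribute"
  attr(out, "draw_cti") <- draw_mat
  out
}

#' Compare models with and without the attribute interaction
#'
#' Fits the model twice -- without and with the focal-by-confounder
#' interaction terms -- and reports an information-criterion comparison
#' (marginal-likelihood AIC).
#'
#' @inheritParams fit_attribute_year_model
#' @return list with `table` (data frame: model, npar, logLik, AIC) and
#'   `preferred` (`"no_interaction"`, `"interaction"`, or `"tie"` when the
#'   AIC difference is below 1e-8).
#' @export
compare_interaction_models <- function(panel, spec = model_spec()) {
  spec_no <- spec; spec_no$include_attribute_interaction <- FALSE
  spec_yes <- spec; spec_yes$include_attribute_interaction <- TRUE
  m0 <- fit_attribute_year_model(panel, spec_no)
  m1 <- fit_attribute_year_model(panel, spec_yes)
  tab <- data.frame(model = c("no_interaction", "interaction"),
                    npar = c(m0$npar, m1$npar),
                    logLik = c(m0$logLik, m1$logLik),
                    AIC = c(m0$AIC, m1$AIC), stringsAsFactors = FALSE)
  d <- m0$AIC - m1$AIC
  preferred <- if (abs(d) < 1e-8) "tie" else if (d < 0) "no_interaction"
  else "interaction"
  list(table = tab, preferred = preferred,
       models = list(no_interaction = m0, interaction = m1))
}
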