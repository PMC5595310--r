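# Validation simulator: a hypothetical community whose log abundances grow
# linearly in two species attributes -- temperature preference (the climate
# signal) and habitat breadth (tolerance to land-use change, the
# confounder).  The "true" CTI is the index of a community driven by
# temperature preference alone, simulated without observation error; the
# observed community adds the habitat effect and one of four error models.

#' Simulation configuration
#'
#' @param n_species number of species (default 50).
#' @param n_years number of annual censuses (default 20).
#' @param b_temp per-unit-trait effect of temperature preference on log
#'   annual growth (default 0.05).
#' @param b_habitat effect of habitat breadth on log annual growth
#'   (default 0.05, same magnitude as the temperature effect).
#' @param trait_correlation correlation r between temperature preference and
#'   habitat breadth (default 0; the covariation scenario uses -0.6).
#' @param error_model `"poisson"` (demographic stochasticity),
#'   `"overdispersion"` (an extra log-scale normal deviate before the
#'   Poisson draw), `"measure_temp"` / `"measure_both"` (Poisson dynamics
#'   plus measurement error in the analyst's trait table), or `"none"`
#'   (deterministic dynamics, for testing).
#' @param overdispersion_sd standard deviation of the log-scale
#'   overdispersion deviate; default twice the magnitude of the trait
#'   effect, `2 * abs(b_temp)`.
#' @param measurement_r target correlation between measured and actual trait
#'   values (default 0.7).
#' @param n_reps replicates for scenario runs (default 500).
#' @param N0 initial abundance of every species in year 1 (default 100).
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species = 50L, n_years = 20L, b_temp = 0.05,
                       b_habitat = 0.05, trait_correlation = 0,
                       error_model = c("poisson", "overdispersion",
                                       "measure_temp", "measure_both",
                                       "none"),
                       overdispersion_sd = NULL, measurement_r = 0.7,
                       n_reps = 500L, N0 = 100, seed = NULL) {
  error_model <- match.arg(error_model)
  if (n_species < 2L) stop("n_species must be >= 2")
  if (n_years < 2L) stop("n_years must be >= 2")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (abs(trait_correlation) > 1) stop("|trait_correlation| must be <= 1")
  if (measurement_r <= 0 || measurement_r > 1)
    stop("measurement_r must be in (0, 1]")
  if (is.null(overdispersion_sd)) overdispersion_sd <- 2 * abs(b_temp)
  structure(list(n_species = as.integer(n_species),
                 n_years = as.integer(n_years),
                 b_temp = b_temp, b_habitat = b_habitat,
                 trait_correlation = trait_correlation,
                 error_model = error_model,
                 overdispersion_sd = overdispersion_sd,
                 measurement_r = measurement_r,
                 n_reps = as.integer(n_reps), N0 = N0, seed = seed),
            class = "sim_config")
}

#' Draw correlated species traits
#'
#' Temperature preference and habitat breadth are standard-normal marginals
#' with correlation `r` (bivariate normal construction).
#'
#' @param n_species number of species.
#' @param r trait correlation in `[-1, 1]`.
#' @param seed optional integer seed.
#' @return a [trait_table()] with columns `temp_pref` and `habitat_breadth`.
#' @export
simulate_traits <- function(n_species, r = 0, seed = NULL) {
  if (abs(r) > 1) stop("|r| must be <= 1")
  if (!is.null(seed)) set.seed(seed)
  z1 <- stats::rnorm(n_species)
  z2 <- stats::rnorm(n_species)
  hb <- r * z1 + sqrt(1 - r^2) * z2
  trait_table(data.frame(
    species = sprintf("sp%03d", seq_len(n_species)),
    temp_pref = z1, habitat_breadth = hb, stringsAsFactors = FALSE))
}

# core growth recursion: year 1 is N0 exactly; afterwards the expected
# abundance multiplies by exp(growth_s) each year and realized counts are
# drawn per error model (demographic stochasticity propagates: the mean for
# year t uses the realized count of year t-1, so extinction is absorbing)
sim_dynamics <- function(growth, n_years, N0, error_model,
                         overdispersion_sd = 0) {
  n <- length(growth)
  N <- matrix(0, n, n_years)
  N[, 1L] <- N0
  for (t in 2L:n_years) {
    eta <- growth
    if (error_model == "overdispersion")
      eta <- eta + stats::rnorm(n, 0, overdispersion_sd)
    mu <- N[, t - 1L] * exp(eta)
    if (any(!is.finite(mu)) || any(mu > 1e12))
      stop("expected abundance overflow; use smaller effects or a shorter horizon")
    N[, t] <- if (error_model == "none") mu else stats::rpois(n, mu)
  }
  N
}

#' Simulate a community time series
#'
#' Expected dynamics follow
#' `log N[s,t] = log N[s,t-1] + b_temp * temp_pref[s] + b_habitat * habitat_breadth[s]`,
#' with realized counts drawn per the configured error model.  The
#' measurement-error models use Poisson dynamics here; they perturb the
#' analyst's trait table (see [measured_traits()]), never the generator.
#'
#' @param traits a [trait_table()] with `temp_pref` and `habitat_breadth`.
#' @param config a [sim_config()].
#' @return a [community_ts()] over years `1:n_years`.
#' @export
simulate_community <- function(traits, config) {
  stopifnot(inherits(traits, "trait_table"), inherits(config, "sim_config"))
  if (!"habitat_breadth" %in% names(traits))
    stop("traits must include 'habitat_breadth'")
  if (nrow(traits) != config$n_species)
    stop("traits cover ", nrow(traits), " species, config expects ",
         config$n_species)
  growth <- config$b_temp * traits$temp_pref +
    config$b_habitat * traits$habitat_breadth
  dyn_error <- if (config$error_model %in% c("measure_temp", "measure_both"))
    "poisson" else config$error_model
  N <- sim_dynamics(growth, config$n_years, config$N0, dyn_error,
                    config$overdispersion_sd)
  community_ts(data.frame(
    species = rep(traits$species, config$n_years),
    year = rep(seq_len(config$n_years), each = nrow(traits)),
    abundance = as.vector(N), stringsAsFactors = FALSE))
}

#' Add measurement error to trait values
#'
#' Adds an independent normal deviate with standard deviation
#' `sd(x) * sqrt(1 / r^2 - 1)`, which makes the correlation between measured
#' and actual values equal `r` in expectation.  Applied once per replicate:
#' traits are mis-measured and then held fixed across years.
#'
#' @param traits a [trait_table()].
#' @param which character vector of continuous trait columns to perturb.
#' @param r target measured-vs-actual correlation in (0, 1].
#' @return the trait table with the named columns perturbed.
#' @export
measured_traits <- function(traits, which, r) {
  if (r <= 0 || r > 1) stop("r must be in (0, 1]")
  out <- traits
  for (v in which) {
    x <- out[[v]]
    sd_e <- stats::sd(x) * sqrt(1 / r^2 - 1)
    out[[v]] <- x + stats::rnorm(length(x), 0, sd_e)
  }
  out
}

#' True CTI of a temperature-only community
#'
#' Simulates the community with the habitat effect forced to zero and no
#' observation error, and returns its original (abundance-weighted) CTI.
#' This is the reference series: the CTI that results when temperature
#' preference alone drives the dynamics.
#'
#' @param config a [sim_config()].
#' @param traits a [trait_table()].
#' @return a `cti_series` with variant `"true"`.
#' @export
true_cti <- function(config, traits) {
  cfg <- config
  cfg$b_habitat <- 0
  cfg$error_model <- "none"
  comm <- simulate_community(traits, cfg)
  idx <- standardize_to_index(comm, base_year = 1L)
  al <- align_community_traits(idx, traits)
  out <- cti_series(al$panel, al$traits, variant = "original")
  out$variant <- "true"
  out
}

percentile_summary <- function(x) {
  c(mean = mean(x), lo = unname(stats::quantile(x, 0.025, names = FALSE)),
    hi = unname(stats::quantile(x, 0.975, names = FALSE)))
}

#' Run a simulation scenario
#'
#' For each replicate: draw traits, compute the deterministic true CTI,
#' simulate the observed community (habitat effect plus error model),
#' standardize to indices, compute the original CTI, fit the
#' attribute-by-year model on the analyst's (possibly mis-measured) traits
#' and compute the modelled CTI.  Summaries are per-year means and 95%
#' percentile Monte-Carlo intervals of (variant - true) across replicates.
#'
#' @param config a [sim_config()]; `config$seed` seeds the whole run.
#' @param fit_model fit the correction model per replicate (default TRUE;
#'   set FALSE to summarize only original vs true, which is much faster).
#' @param analyst list of analyst-model options: `extra_noise_predictor`
#'   (add a pure-noise confounder) and `three_way` (add the
#'   temperature-by-habitat product as a further year-interacted term,
#'   emulating a superfluous three-way interaction).
#' @return a `cti_sim_result`: list with `trajectories` (rep, year, variant,
#'   cti), `bias` (variant, year, mean, lo, hi of variant - true),
#'   `n_failed`, and `config`.
#' @export
run_scenario <- function(config, fit_model = TRUE,
                         analyst = list(extra_noise_predictor = FALSE,
                                        three_way = FALSE)) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  traj <- vector("list", config$n_reps)
  n_failed <- 0L
  for (rep_i in seq_len(config$n_reps)) {
    traits <- simulate_traits(config$n_species, config$trait_correlation)
    true_s <- true_cti(config, traits)
    comm <- simulate_community(traits, config)
    idx <- suppressWarnings(standardize_to_index(comm, base_year = 1L,
                                                 zero_policy = "floor"))
    an_traits <- traits
    if (config$error_model == "measure_temp")
      an_traits <- measured_traits(an_traits, "temp_pref",
                                   config$measurement_r)
    if (config$error_model == "measure_both")
      an_traits <- measured_traits(an_traits,
                                   c("temp_pref", "habitat_breadth"),
                                   config$measurement_r)
    confs <- "habitat_breadth"
    if (isTRUE(analyst$extra_noise_predictor)) {
      an_traits$noise_attr <- stats::rnorm(nrow(an_traits))
      attr(an_traits, "attribute_types") <-
        c(attr(an_traits, "attribute_types"), noise_attr = "continuous")
      confs <- c(confs, "noise_attr")
    }
    if (isTRUE(analyst$three_way)) {
      an_traits$temp_x_habitat <- an_traits$temp_pref * an_traits$habitat_breadth
      attr(an_traits, "attribute_types") <-
        c(attr(an_traits, "attribute_types"), temp_x_habitat = "continuous")
      confs <- c(confs, "temp_x_habitat")
    }
    al <- align_community_traits(idx, an_traits)
    orig <- cti_series(al$panel, al$traits, variant = "original")
    pieces <- list(
      data.frame(rep = rep_i, year = true_s$year, variant = "true",
                 cti = true_s$cti),
      data.frame(rep = rep_i, year = orig$year, variant = "original",
                 cti = orig$cti))
    if (fit_model) {
      fit <- tryCatch(
        fit_attribute_year_model(
          al$panel, model_spec(confounders = confs, force = TRUE)),
        error = function(e) e)
      if (inherits(fit, "error")) {
        n_failed <- n_failed + 1L
        next
      }
      mod <- modelled_cti(fit, al$panel, al$traits)
      pieces <- c(pieces, list(
        data.frame(rep = rep_i, year = mod$year, variant = "modelled",
                   cti = mod$cti)))
    }
    traj[[rep_i]] <- do.call(rbind, pieces)
  }
  if (n_failed > 0.2 * config$n_reps)
    stop("more than 20% of replicate model fits failed (", n_failed, "/",
         config$n_reps, ")")
  trajectories <- do.call(rbind, traj)
  rownames(trajectories) <- NULL
  variants <- setdiff(unique(trajectories$variant), "true")
  bias_rows <- list()
  for (v in variants) for (y in seq_len(config$n_years)) {
    vv <- trajectories[trajectories$variant == v & trajectories$year == y, ]
    tt <- trajectories[trajectories$variant == "true" &
                         trajectories$year == y, ]
    d <- vv$cti[match(tt$rep, vv$rep)] - tt$cti
    d <- d[!is.na(d)]
    s <- percentile_summary(d)
    bias_rows[[length(bias_rows) + 1L]] <-
      data.frame(variant = v, year = y, mean = s["mean"], lo = s["lo"],
                 hi = s["hi"], stringsAsFactors = FALSE)
  }
  bias <- do.call(rbind, bias_rows)
  rownames(bias) <- NULL
  structure(list(trajectories = trajectories, bias = bias,
                 n_failed = n_failed, config = config),
            class = "cti_sim_result")
}

#' @export
print.cti_sim_result <- function(x, ...) {
  cat("CTI simulation scenario: r = ", x$config$trait_correlation,
      ", error = ", x$config$error_model, ", ",
      x$config$n_reps, " replicates (", x$n_failed, " failed fits)\n",
      sep = "")
  fy <- x$bias[x$bias$year == max(x$bias$year), ]
  cat("final-year bias (variant - true):\n")
  print(fy, row.names = FALSE, ...)
  invisible(x)
}

#' Bias of the original CTI over a scenario grid
#'
#' Sweeps trait correlation, effect size and community size and reports the
#' final-year bias `true - original` per grid cell (mean and 95% percentile
#' Monte-Carlo interval across replicates).  No correction model is fitted.
#'
#' @param base_config a [sim_config()] providing defaults and the seed.
#' @param r_values trait correlations to sweep.
#' @param b_values effect sizes (applied to both traits); default just the
#'   base config's `b_temp`.
#' @param n_species_values community sizes; default the base config's.
#' @param n_reps replicates per cell (default the base config's).
#' @return data frame: `r, b, n_species, mean, lo, hi, n_reps`.
#' @export
bias_grid <- function(base_config, r_values,
                      b_values = base_config$b_temp,
                      n_species_values = base_config$n_species,
                      n_reps = base_config$n_reps) {
  stopifnot(inherits(base_config, "sim_config"))
  if (!length(r_values)) stop("empty grid")
  if (!is.null(base_config$seed)) set.seed(base_config$seed)
  rows <- list()
  for (r in r_values) for (b in b_values) for (ns in n_species_values) {
    final_bias <- numeric(n_reps)
    for (i in seq_len(n_reps)) {
      cfg <- base_config
      cfg$trait_correlation <- r
      cfg$b_temp <- b; cfg$b_habitat <- b
      cfg$n_species <- as.integer(ns)
      cfg$seed <- NULL
      traits <- simulate_traits(ns, r)
      true_s <- true_cti(cfg, traits)
      comm <- simulate_community(traits, cfg)
      idx <- suppressWarnings(standardize_to_index(comm, base_year = 1L,
                                                   zero_policy = "floor"))
      al <- align_community_traits(idx, traits)
      orig <- cti_series(al$panel, al$traits, variant = "original")
      ylast <- max(true_s$year)
      final_bias[i] <- true_s$cti[true_s$year == ylast] -
        orig$cti[orig$year == ylast]
    }
    s <- percentile_summary(final_bias)
    rows[[length(rows) + 1L]] <-
      data.frame(r = r, b = b, n_species = ns, mean = s["mean"],
                 lo = s["lo"], hi = s["hi"], n_reps = n_reps)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Robustness of the correction to analyst-model assumptions
#'
#' Re-runs the covariation scenario with (a) the baseline analyst model,
#' (b) an extra randomly generated predictor with no true effect, and
#' (c) a superfluous temperature-by-habitat product term interacted with
#' year (a three-way interaction absent from the generating dynamics).
#'
#' @param config a [sim_config()] (typically the covariation scenario).
#' @return list of `cti_sim_result` objects named `baseline`,
#'   `extra_noise_predictor`, `three_way`.
#' @export
robustness_suite <- function(config) {
  base_seed <- if (is.null(config$seed)) 1L else config$seed
  variants <- list(
    baseline = list(extra_noise_predictor = FALSE, three_way = FALSE),
    extra_noise_predictor = list(extra_noise_predictor = TRUE,
                                 three_way = FALSE),
    three_way = list(extra_noise_predictor = FALSE, three_way = TRUE))
  out <- lapply(seq_along(variants), function(i) {
    cfg <- config
    cfg$seed <- base_seed + (i - 1L)
    run_scenario(cfg, fit_model = TRUE, analyst = variants[[i]])
  })
  names(out) <- names(variants)
  out
}
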