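# small deterministic builders shared across test files

make_trait_table <- function(prefs, ...) {
  trait_table(data.frame(species = sprintf("s%02d", seq_along(prefs)),
                         temp_pref = prefs, ..., stringsAsFactors = FALSE))
}

# panel whose log abundance is an exact linear function of year x traits
noiseless_panel <- function(traits, n_years, b_temp, b_hab = 0) {
  grid <- expand.grid(species = traits$species, year = seq_len(n_years),
                      stringsAsFactors = FALSE)
  panel <- merge(grid, as.data.frame(traits), by = "species")
  hb <- if ("habitat_breadth" %in% names(panel)) panel$habitat_breadth else 0
  panel$abundance <- exp(b_temp * panel$year * panel$temp_pref +
                           b_hab * panel$year * hb)
  panel[order(panel$species, panel$year), ]
}

# panel with per-species AR(1) log-scale noise around a year x trait trend
ar1_panel <- function(traits, n_years, slope_temp, slope_hab = 0, rho = 0,
                      sd = 0.2, sp_sd = 0) {
  rows <- lapply(seq_len(nrow(traits)), function(s) {
    e <- if (rho == 0) stats::rnorm(n_years, 0, sd)
    else as.numeric(stats::arima.sim(list(ar = rho), n_years,
                                     sd = sd * sqrt(1 - rho^2)))
    hb <- if ("habitat_breadth" %in% names(traits))
      traits$habitat_breadth[s] else 0
    data.frame(species = traits$species[s], year = seq_len(n_years),
               abundance = exp(slope_temp * seq_len(n_years) *
                                 traits$temp_pref[s] +
                                 slope_hab * seq_len(n_years) * hb +
                                 stats::rnorm(1, 0, sp_sd) + e),
               stringsAsFactors = FALSE)
  })
  panel <- merge(do.call(rbind, rows), as.data.frame(traits), by = "species")
  panel[order(panel$species, panel$year), ]
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
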