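# Seeded synthetic survey fixtures.  Real long-term community surveys
# (national breeding-bird indices, winter bottom-trawl catch series) are
# large external datasets; these generators emulate their structure --
# community size, census span, attribute classes and the direction of the
# trait-confounder association -- so that the full pipeline can be
# exercised end to end on data of realistic shape.

#' Generate a synthetic survey fixture
#'
#' `birds_like`: 36 terrestrial species censused annually 1981-2013, with a
#' categorical habitat attribute (farmland, forest, urban; n = 13, 16, 7)
#' whose mean temperature preference is ordered urban > farmland > forest.
#' Growth combines a temperature effect (0.01 per degree C per year) with
#' habitat-class effects (farmland declining, forest increasing), so both
#' climate and land-use signals are present and covary.
#'
#' `fish_like`: 33 demersal species censused annually 1980-2013, with a
#' 4-level exploitation class (none, minor, moderate, high; warm-preferring
#' species tend to be unexploited) plus continuous log maximum body length
#' (longer fish prefer cooler water).  Growth combines a temperature effect
#' with a negative exploitation effect.
#'
#' Dynamics are simulated with Poisson error from an initial abundance of
#' 100 and written as plain CSV.  Identical seeds give byte-identical files.
#'
#' @param profile `"birds_like"` or `"fish_like"`.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return list with paths `community` and `traits`, plus the generated
#'   `community_ts` and `trait_table` objects, invisibly usable directly.
#' @export
generate_fixture <- function(profile = c("birds_like", "fish_like"),
                             seed = 1L, dir = tempdir()) {
  profile <- match.arg(profile)
  set.seed(seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (profile == "birds_like") {
    habitat <- rep(c("farmland", "forest", "urban"), c(13L, 16L, 7L))
    n <- length(habitat)
    tp_mean <- c(farmland = 13.0, forest = 12.0, urban = 13.8)
    traits_df <- data.frame(
      species = sprintf("bird%02d", seq_len(n)),
      temp_pref = stats::rnorm(n, tp_mean[habitat], 1.0),
      habitat = habitat, stringsAsFactors = FALSE)
    class_eff <- c(farmland = -0.020, forest = 0.010, urban = 0)
    growth <- 0.010 * (traits_df$temp_pref - mean(traits_df$temp_pref)) +
      class_eff[habitat]
    years <- 1981:2013
  } else {
    exploitation <- rep(c("none", "minor", "moderate", "high"),
                        c(9L, 8L, 9L, 7L))
    n <- length(exploitation)
    tp_mean <- c(none = 10.5, minor = 10.0, moderate = 9.6, high = 9.2)
    temp_pref <- stats::rnorm(n, tp_mean[exploitation], 0.8)
    log_max_length <- stats::rnorm(
      n, 3.2 + 0.5 * (exploitation %in% c("moderate", "high")) -
        0.15 * (temp_pref - mean(temp_pref)), 0.3)
    traits_df <- data.frame(
      species = sprintf("fish%02d", seq_len(n)),
      temp_pref = temp_pref, exploitation = exploitation,
      log_max_length = log_max_length, stringsAsFactors = FALSE)
    expl_eff <- c(none = 0.010, minor = 0, moderate = -0.015, high = -0.030)
    growth <- 0.010 * (temp_pref - mean(temp_pref)) + expl_eff[exploitation]
    years <- 1980:2013
  }
  N <- sim_dynamics(growth, length(years), 100, "poisson")
  comm <- community_ts(data.frame(
    species = rep(traits_df$species, length(years)),
    year = rep(years, each = n),
    abundance = as.vector(N), stringsAsFactors = FALSE))
  traits <- trait_table(traits_df)
  community_path <- file.path(dir, paste0(profile, "_community.csv"))
  traits_path <- file.path(dir, paste0(profile, "_traits.csv"))
  write_community(comm, community_path)
  write_traits(traits, traits_path)
  list(community = community_path, traits = traits_path,
       community_ts = comm, trait_table = traits)
}
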