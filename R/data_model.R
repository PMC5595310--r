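#' @keywords internal
"_PACKAGE"

# ---- community time series ----------------------------------------------

#' Construct a community time series
#'
#' A community time series is a long-format panel of abundances: one row per
#' observed (species, year) pair.  Abundances must be non-negative and finite;
#' at most one record per species-year is allowed.  Missing species-year cells
#' are permitted (unbalanced panel) and simply contribute no row.
#'
#' @param data data frame with columns `species`, `year`, `abundance` (or
#'   columns renameable via `column_map`).
#' @param column_map named character vector mapping the canonical names
#'   `species`, `year`, `abundance` to the column names present in `data`.
#' @return A `community_ts`: a data frame with columns `species` (character),
#'   `year` (integer) and `abundance` (double), sorted by species then year,
#'   with attribute `census_years` (sorted unique years).
#' @export
community_ts <- function(data,
                         column_map = c(species = "species", year = "year",
                                        abundance = "abundance")) {
  need <- c("species", "year", "abundance")
  if (!all(need %in% names(column_map)))
    stop("column_map must name 'species', 'year' and 'abundance'")
  missing_cols <- setdiff(unname(column_map[need]), names(data))
  if (length(missing_cols))
    stop("missing column(s) in community data: ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(species = as.character(data[[column_map["species"]]]),
                    year = data[[column_map["year"]]],
                    abundance = as.numeric(data[[column_map["abundance"]]]),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$species)) || any(!nzchar(out$species)))
    stop("species identifiers must be non-missing, non-empty strings")
  yr <- out$year
  if (any(is.na(yr)) || any(yr != round(yr)))
    stop("years must be non-missing integers")
  out$year <- as.integer(round(yr))
  bad <- which(is.na(out$abundance) | !is.finite(out$abundance) |
                 out$abundance < 0)
  if (length(bad))
    stop("abundance must be finite and >= 0; offending rows: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  key <- paste(out$species, out$year, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop("duplicate (species, year) records: ",
         paste(gsub("\r", "/", utils::head(dups, 5L)), collapse = ", "))
  }
  out <- out[order(out$species, out$year), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "census_years") <- sort(unique(out$year))
  class(out) <- c("community_ts", "data.frame")
  out
}

#' Read a community abundance CSV
#'
#' Expects a comma-separated, UTF-8 file with a header row and columns
#' mappable to `species`, `year`, `abundance`.
#'
#' @inheritParams community_ts
#' @param path path to the CSV file.
#' @return a [community_ts()] object.
#' @export
read_community <- function(path,
                           column_map = c(species = "species", year = "year",
                                          abundance = "abundance")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  community_ts(df, column_map = column_map)
}

#' Write a community time series to CSV
#'
#' Inverse of [read_community()]: writes columns `species,year,abundance`.
#'
#' @param x a `community_ts`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_community <- function(x, path) {
  stopifnot(inherits(x, "community_ts"))
  utils::write.csv(as.data.frame(x)[, c("species", "year", "abundance")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.community_ts <- function(x, ...) {
  yrs <- attr(x, "census_years")
  cat("Community time series: ", length(unique(x$species)), " species, ",
      length(yrs), " census years (", min(yrs), "-", max(yrs), ")\n", sep = "")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

# ---- trait table ---------------------------------------------------------

#' Construct a species trait table
#'
#' Holds each species' temperature preference (degrees C) together with any
#' number of additional attributes, each declared continuous or categorical.
#' Every species must carry a value for every attribute (no missing cells).
#'
#' @param data data frame with columns `species`, `temp_pref`, plus one
#'   column per attribute.
#' @param attribute_types optional named character vector giving, for each
#'   attribute column, `"continuous"` or `"categorical"`.  Unnamed attributes
#'   are inferred: numeric columns are continuous, everything else
#'   categorical.
#' @return A `trait_table`: data frame with `species`, `temp_pref` and the
#'   attribute columns (categorical ones as factors), with attribute
#'   `attribute_types`.
#' @export
trait_table <- function(data, attribute_types = NULL) {
  if (!all(c("species", "temp_pref") %in% names(data)))
    stop("trait data must have columns 'species' and 'temp_pref'")
  out <- as.data.frame(data, stringsAsFactors = FALSE)
  out$species <- as.character(out$species)
  if (anyDuplicated(out$species))
    stop("duplicate species in trait table: ",
         paste(unique(out$species[duplicated(out$species)]), collapse = ", "))
  out$temp_pref <- as.numeric(out$temp_pref)
  if (any(!is.finite(out$temp_pref)))
    stop("temp_pref must be finite for every species")
  attrs <- setdiff(names(out), c("species", "temp_pref"))
  types <- character(0)
  for (a in attrs) {
    ty <- if (!is.null(attribute_types) && a %in% names(attribute_types))
      match.arg(attribute_types[[a]], c("continuous", "categorical"))
    else if (is.numeric(out[[a]])) "continuous" else "categorical"
    if (anyNA(out[[a]]))
      stop("attribute '", a, "' has missing values")
    if (ty == "continuous") {
      out[[a]] <- as.numeric(out[[a]])
      if (any(!is.finite(out[[a]])))
        stop("continuous attribute '", a, "' must be finite")
    } else {
      out[[a]] <- factor(as.character(out[[a]]),
                         levels = sort(unique(as.character(out[[a]]))))
    }
    types[a] <- ty
  }
  out <- out[order(out$species), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "attribute_types") <- types
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Read a species trait CSV
#'
#' Expects columns `species,temp_pref,<attr1>,...`.  Attribute types follow
#' the header convention of [trait_table()]: numeric columns are continuous
#' unless overridden through `attribute_types`.
#'
#' @inheritParams trait_table
#' @param path path to the CSV file.
#' @return a [trait_table()] object.
#' @export
read_traits <- function(path, attribute_types = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  trait_table(df, attribute_types = attribute_types)
}

#' Write a trait table to CSV
#' @param x a `trait_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_traits <- function(x, path) {
  stopifnot(inherits(x, "trait_table"))
  df <- as.data.frame(x)
  for (a in names(attr(x, "attribute_types")))
    if (is.factor(df[[a]])) df[[a]] <- as.character(df[[a]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attribute names and types of a trait table
#' @param x a `trait_table`.
#' @return named character vector attribute -> "continuous"/"categorical".
#' @export
attribute_types <- function(x) {
  stopifnot(inherits(x, "trait_table"))
  attr(x, "attribute_types")
}

# ---- standardization -----------------------------------------------------

#' Standardize abundances to an index of 100 in a base year
#'
#' Rescales every species' trajectory so that its value in the base year is
#' 100: `index(s, t) = 100 * abundance(s, t) / abundance(s, base_year)`.
#' This prevents initially dominant species from driving the community index
#' throughout the series.  The log-scale model downstream cannot accept
#' zeros, so a zero policy applies to all values:
#' \describe{
#'   \item{`strict`}{(default) any zero abundance is an error.}
#'   \item{`floor`}{zeros are replaced by half the smallest positive
#'     abundance of that species (with a warning) before scaling.}
#' }
#'
#' @param series a [community_ts()].
#' @param base_year base census year; defaults to the first census year.
#' @param zero_policy `"strict"` or `"floor"`.
#' @return a `community_ts` of indices, additionally of class
#'   `abundance_index` with attribute `base_year`; every species has value
#'   exactly 100 at `base_year` and all values are strictly positive.
#' @export
standardize_to_index <- function(series, base_year = NULL,
                                 zero_policy = c("strict", "floor")) {
  stopifnot(inherits(series, "community_ts"))
  zero_policy <- match.arg(zero_policy)
  yrs <- attr(series, "census_years")
  if (is.null(base_year)) base_year <- yrs[1L]
  if (!base_year %in% series$year)
    stop("base year ", base_year, " has no records")
  df <- as.data.frame(series)
  if (any(df$abundance == 0)) {
    if (zero_policy == "strict")
      stop("zero abundances present under strict zero policy (species: ",
           paste(unique(df$species[df$abundance == 0]), collapse = ", "),
           "); use zero_policy = 'floor' or remove the species")
    for (sp in unique(df$species[df$abundance == 0])) {
      rows <- df$species == sp
      pos <- df$abundance[rows & df$abundance > 0]
      if (!length(pos))
        stop("species '", sp, "' has no positive abundance; cannot floor")
      df$abundance[rows & df$abundance == 0] <- min(pos) / 2
    }
    warning("zero abundances floored to half the species' smallest positive value")
  }
  base <- df[df$year == base_year, c("species", "abundance")]
  missing_base <- setdiff(unique(df$species), base$species)
  if (length(missing_base))
    stop("species absent in base year ", base_year, ": ",
         paste(missing_base, collapse = ", "))
  denom <- base$abundance[match(df$species, base$species)]
  df$abundance <- 100 * df$abundance / denom
  out <- community_ts(df)
  attr(out, "base_year") <- as.integer(base_year)
  class(out) <- c("abundance_index", class(out))
  out
}

# ---- align ---------------------------------------------------------------

#' Join a community time series with a trait table
#'
#' Inner-joins on species; species present in only one input are reported and
#' dropped from the panel.
#'
#' @param series a [community_ts()].
#' @param traits a [trait_table()].
#' @return list with elements `panel` (data frame: species, year, abundance,
#'   temp_pref, attribute columns), `traits` (trait table restricted to the
#'   matched species), `series_only` and `traits_only` (character vectors of
#'   unmatched species).
#' @export
align_community_traits <- function(series, traits) {
  stopifnot(inherits(series, "community_ts"), inherits(traits, "trait_table"))
  sp_s <- unique(series$species)
  sp_t <- traits$species
  common <- intersect(sp_s, sp_t)
  if (!length(common))
    stop("no species shared between community series and trait table")
  panel <- merge(as.data.frame(series), as.data.frame(traits),
                 by = "species", all = FALSE, sort = FALSE)
  panel <- panel[order(panel$species, panel$year), , drop = FALSE]
  rownames(panel) <- NULL
  tr <- traits[traits$species %in% common, , drop = FALSE]
  rownames(tr) <- NULL
  attr(tr, "attribute_types") <- attr(traits, "attribute_types")
  class(tr) <- class(traits)
  list(panel = panel,
       traits = tr,
       series_only = setdiff(sp_s, sp_t),
       traits_only = setdiff(sp_t, sp_s))
}
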