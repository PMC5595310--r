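# Community temperature index: community-weighted mean of species'
# temperature preferences.  The weighted variant uses relative abundances;
# the presence/absence variant weights every present species equally.

#' Relative abundances for one census year
#'
#' Normalizes a vector of per-species abundances to weights summing to 1.
#'
#' @param abundances named numeric vector (names = species), all >= 0, at
#'   least one positive.
#' @return named numeric vector of weights in `[0, 1]` summing to 1.
#' @export
relative_abundance <- function(abundances) {
  if (is.null(names(abundances)) || any(!nzchar(names(abundances))))
    stop("abundances must be named by species")
  if (any(!is.finite(abundances)) || any(abundances < 0))
    stop("abundances must be finite and >= 0")
  tot <- sum(abundances)
  if (tot <= 0)
    stop("all abundances are zero: relative abundance (and CTI) undefined")
  abundances / tot
}

#' Abundance-weighted community temperature index
#'
#' `CTI = sum_s temp_pref_s * w_s` with `w` the relative abundances.
#'
#' @param weights named weight vector as from [relative_abundance()].
#' @param traits a [trait_table()] covering every weighted species.
#' @return CTI in degrees C.
#' @export
compute_cti <- function(weights, traits) {
  stopifnot(inherits(traits, "trait_table"))
  idx <- match(names(weights), traits$species)
  if (anyNA(idx))
    stop("species missing from trait table: ",
         paste(names(weights)[is.na(idx)], collapse = ", "))
  sum(traits$temp_pref[idx] * weights)
}

#' Presence/absence community temperature index
#'
#' Unweighted mean temperature preference over the species present; isolates
#' CTI dynamics driven by species turnover rather than abundance change.
#'
#' @param present character vector of present species.
#' @param traits a [trait_table()].
#' @return CTI in degrees C.
#' @export
compute_cti_presence <- function(present, traits) {
  if (!length(present)) stop("presence set is empty: CTI undefined")
  w <- stats::setNames(rep(1 / length(present), length(present)), present)
  compute_cti(w, traits)
}

#' Per-year CTI series from an aligned panel
#'
#' @param panel aligned panel from [align_community_traits()] (or any data
#'   frame with columns species, year, abundance).
#' @param traits a [trait_table()].
#' @param variant `"original"` (abundance-weighted) or `"presence_absence"`.
#' @param presence_threshold abundance strictly above which a species counts
#'   as present (presence variant only).
#' @return a `cti_series`: data frame with columns `year`, `variant`, `cti`.
#' @export
cti_series <- function(panel, traits,
                       variant = c("original", "presence_absence"),
                       presence_threshold = 0) {
  variant <- match.arg(variant)
  yrs <- sort(unique(panel$year))
  cti <- vapply(yrs, function(y) {
    slice <- panel[panel$year == y, , drop = FALSE]
    ab <- stats::setNames(slice$abundance, slice$species)
    if (variant == "original") {
      compute_cti(relative_abundance(ab), traits)
    } else {
      compute_cti_presence(names(ab)[ab > presence_threshold], traits)
    }
  }, numeric(1))
  new_cti_series(yrs, variant, cti)
}

new_cti_series <- function(years, variant, values) {
  out <- data.frame(year = as.integer(years), variant = variant, cti = values,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cti_series", "data.frame")
  out
}

#' @export
print.cti_series <- function(x, ...) {
  cat("CTI series (", x$variant[1L], "), ", nrow(x), " years\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Bind CTI series of several variants into one table
#' @param ... `cti_series` objects.
#' @return a `cti_series` data frame stacking the inputs.
#' @export
bind_cti_series <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("cti_series", "data.frame")
  out
}
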