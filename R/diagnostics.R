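# Supporting analyses: do the confounders covary with temperature
# preference, do they explain long-term abundance trends (the screening
# step recommended before applying the correction), which quartile of the
# temperature-preference distribution drives the CTI trend, and loess
# smoothing of CTI series.

#' Test covariation between the focal trait and another attribute
#'
#' Linear-model F test of `focal ~ other`.  For a continuous attribute the
#' Pearson correlation is also reported; for a categorical attribute,
#' per-level summaries.
#'
#' @param traits a [trait_table()].
#' @param focal name of the focal trait column (default `"temp_pref"`).
#' @param other name of the attribute to test against.
#' @return list with `statistic` (F), `df` (numerator, denominator), `p`,
#'   `r` (continuous attributes only, else NA) and `groups` (categorical
#'   attributes: level, n, mean).
#' @export
covariation_test <- function(traits, focal = "temp_pref", other) {
  stopifnot(inherits(traits, "trait_table"))
  for (v in c(focal, other))
    if (!v %in% names(traits)) stop("no attribute column '", v, "'")
  y <- traits[[focal]]
  x <- traits[[other]]
  if (stats::var(y) == 0) stop("'", focal, "' has zero variance")
  if ((is.numeric(x) && stats::var(x) == 0) ||
      (!is.numeric(x) && length(unique(x)) < 2L))
    stop("'", other, "' has zero variance")
  if (!is.numeric(x)) {
    tb <- table(x)
    if (any(tb < 2L))
      warning("categorical level(s) with fewer than 2 species: ",
              paste(names(tb)[tb < 2L], collapse = ", "))
  }
  fit <- stats::lm(y ~ x)
  an <- stats::anova(fit)
  out <- list(statistic = an$`F value`[1L],
              df = c(an$Df[1L], an$Df[2L]),
              p = an$`Pr(>F)`[1L],
              r = if (is.numeric(x)) stats::cor(y, x) else NA_real_,
              groups = if (!is.numeric(x))
                do.call(rbind, lapply(split(y, x), function(g)
                  data.frame(n = length(g), mean = mean(g))))
              else NULL)
  class(out) <- "covariation_test"
  out
}

#' @export
print.covariation_test <- function(x, ...) {
  cat("Covariation test: F(", x$df[1L], ",", x$df[2L], ") = ",
      format(x$statistic, digits = 4), ", p = ",
      format.pval(x$p, digits = 3), sep = "")
  if (!is.na(x$r)) cat(", Pearson r = ", format(x$r, digits = 3), sep = "")
  cat("\n")
  if (!is.null(x$groups)) print(x$groups, ...)
  invisible(x)
}

# pooled lag-1 autocorrelation of residuals over consecutive years within
# species; used by the feasible-GLS trend test
lag1_rho <- function(resid, species, year) {
  num <- 0; den <- 0
  for (ii in split(seq_along(resid), species)) {
    o <- ii[order(year[ii])]
    if (length(o) < 2L) next
    consec <- diff(year[o]) == 1L
    e1 <- resid[o][-length(o)][consec]
    e2 <- resid[o][-1L][consec]
    num <- num + sum(e1 * e2)
    den <- den + sum(resid[o]^2)
  }
  if (den <= 0) return(0)
  max(min(num / den, 0.99), -0.99)
}

#' Long-term trend effects of species attributes
#'
#' One multiple regression of logged abundances on continuous year
#' interacted with every attribute jointly, with AR(1) errors between
#' consecutive census years within species (feasible GLS: the regression and
#' the lag-1 residual autocorrelation are iterated to convergence).  The
#' year-by-attribute interaction coefficients are the per-year log-abundance
#' trend effects; 95% CIs use the normal convention estimate +/- 1.96 SE.
#' For categorical attributes all pairwise level contrasts are reported and
#' the largest is flagged.
#'
#' @param panel aligned panel with columns `species`, `year`, `abundance`
#'   (strictly positive) and the attribute columns.
#' @param attributes character vector of attribute columns to test
#'   (including, typically, `temp_pref`).
#' @param max_iter,tol iteration control for the rho update.
#' @return a `trend_test` list: `effects` (data frame: attribute, term,
#'   estimate, se, lo, hi), `contrasts` (pairwise categorical contrasts with
#'   a `largest` flag; NULL if no categorical attribute), `rho`, `sigma2`.
#' @export
trend_test <- function(panel, attributes, max_iter = 25L, tol = 1e-8) {
  need <- c("species", "year", "abundance", attributes)
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel lacks column(s): ", paste(miss, collapse = ", "))
  if (any(panel$abundance <= 0)) stop("abundances must be strictly positive")
  if (length(unique(panel$year)) < 3L) stop("need at least 3 census years")
  panel <- panel[order(panel$species, panel$year), , drop = FALSE]
  df <- data.frame(cyear = panel$year - mean(unique(panel$year)))
  for (a in attributes)
    df[[a]] <- if (is.numeric(panel[[a]])) panel[[a]]
  else factor(as.character(panel[[a]]))
  ff <- stats::as.formula(paste(
    "~ cyear * (", paste(attributes, collapse = " + "), ")"))
  X <- stats::model.matrix(ff, df)
  y <- log(panel$abundance)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")

  rho <- 0
  beta <- NULL
  for (it in seq_len(max_iter)) {
    # GLS given rho, species-blocked AR(1) weights
    A <- matrix(0, ncol(X), ncol(X)); rhs <- numeric(ncol(X))
    for (ii in split(seq_len(nrow(X)), panel$species)) {
      U <- chol(ar1_cor(panel$year[ii], rho))
      tX <- backsolve(U, X[ii, , drop = FALSE], transpose = TRUE)
      ty <- backsolve(U, y[ii], transpose = TRUE)
      A <- A + crossprod(tX)
      rhs <- rhs + crossprod(tX, ty)[, 1L]
    }
    beta_new <- solve(A, rhs)
    resid <- y - drop(X %*% beta_new)
    rho_new <- lag1_rho(resid, panel$species, panel$year)
    done <- !is.null(beta) && max(abs(beta_new - beta)) < tol &&
      abs(rho_new - rho) < tol
    beta <- beta_new; rho <- rho_new
    if (done) break
  }
  resid <- y - drop(X %*% beta)
  rss <- 0
  for (ii in split(seq_len(nrow(X)), panel$species)) {
    U <- chol(ar1_cor(panel$year[ii], rho))
    rss <- rss + sum(backsolve(U, resid[ii], transpose = TRUE)^2)
  }
  sigma2 <- rss / (nrow(X) - ncol(X))
  # refresh A at the final rho for the vcov
  A <- matrix(0, ncol(X), ncol(X))
  for (ii in split(seq_len(nrow(X)), panel$species)) {
    U <- chol(ar1_cor(panel$year[ii], rho))
    tX <- backsolve(U, X[ii, , drop = FALSE], transpose = TRUE)
    A <- A + crossprod(tX)
  }
  V <- sigma2 * solve(A)
  dimnames(V) <- list(colnames(X), colnames(X))
  beta <- stats::setNames(beta, colnames(X))

  inter <- grep("^cyear:", colnames(X), value = TRUE)
  eff <- data.frame(
    term = inter,
    estimate = beta[inter],
    se = sqrt(pmax(diag(V)[inter], 0)), stringsAsFactors = FALSE)
  eff$lo <- eff$estimate - 1.96 * eff$se
  eff$hi <- eff$estimate + 1.96 * eff$se
  rownames(eff) <- NULL

  contrasts <- NULL
  for (a in attributes) {
    if (is.numeric(panel[[a]])) next
    lev <- levels(df[[a]])
    cols <- paste0("cyear:", a, lev)
    rows <- list()
    for (i in seq_along(lev)) for (j in seq_along(lev)) {
      if (j <= i) next
      v <- stats::setNames(numeric(ncol(X)), colnames(X))
      if (cols[j] %in% names(v)) v[cols[j]] <- 1
      if (cols[i] %in% names(v)) v[cols[i]] <- -1
      est <- sum(v * beta)
      se <- sqrt(drop(t(v) %*% V %*% v))
      rows[[length(rows) + 1L]] <- data.frame(
        attribute = a, contrast = paste(lev[j], "vs", lev[i]),
        estimate = est, se = se, lo = est - 1.96 * se,
        hi = est + 1.96 * se, stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      cc <- do.call(rbind, rows)
      cc$largest <- abs(cc$estimate) == max(abs(cc$estimate))
      contrasts <- rbind(contrasts, cc)
    }
  }
  if (!is.null(contrasts)) rownames(contrasts) <- NULL
  structure(list(effects = eff, contrasts = contrasts, rho = rho,
                 sigma2 = sigma2, coefficients = beta, vcov = V),
            class = "trend_test")
}

#' @export
print.trend_test <- function(x, ...) {
  cat("Attribute effects on long-term abundance trends (AR(1) rho = ",
      format(x$rho, digits = 3), "):\n", sep = "")
  print(x$effects, row.names = FALSE, digits = 4)
  if (!is.null(x$contrasts)) {
    cat("pairwise categorical contrasts (largest flagged):\n")
    print(x$contrasts, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Warm- and cool-quartile abundance trends
#'
#' Splits species into the upper and lower quartiles of temperature
#' preference (top and bottom `ceiling(n/4)` species; ties broken by species
#' identifier) and reports the per-year geometric mean abundance of each
#' group.  Rising warm-quartile curves indicate gains of warm-adapted
#' species; falling cool-quartile curves indicate declines of cool-adapted
#' species -- two very different mechanisms behind the same CTI increase.
#'
#' @param panel aligned panel with columns `species`, `year`, `abundance`
#'   (strictly positive, e.g. standardized indices) and `temp_pref`.
#' @return a `quartile_trend` list: `trend` (data frame: year, group,
#'   geometric_mean), `members` (list: warm, cool species vectors).
#' @export
quartile_mechanism <- function(panel) {
  need <- c("species", "year", "abundance", "temp_pref")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel lacks column(s): ", paste(miss, collapse = ", "))
  if (any(panel$abundance <= 0))
    stop("abundances must be strictly positive for geometric means")
  sp <- panel[!duplicated(panel$species), c("species", "temp_pref")]
  if (nrow(sp) < 4L) stop("need at least 4 species to form quartiles")
  k <- ceiling(nrow(sp) / 4)
  ord <- sp$species[order(sp$temp_pref, sp$species)]
  cool <- ord[seq_len(k)]
  warm <- rev(ord)[seq_len(k)]
  rows <- list()
  for (y in sort(unique(panel$year))) {
    sl <- panel[panel$year == y, ]
    for (g in c("warm", "cool")) {
      ab <- sl$abundance[sl$species %in% (if (g == "warm") warm else cool)]
      if (!length(ab)) next
      rows[[length(rows) + 1L]] <- data.frame(
        year = y, group = g, geometric_mean = exp(mean(log(ab))),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(trend = do.call(rbind, rows),
                 members = list(warm = warm, cool = cool)),
            class = "quartile_trend")
}

#' @export
print.quartile_trend <- function(x, ...) {
  cat("Quartile mechanism: ", length(x$members$warm),
      " warm / ", length(x$members$cool), " cool species\n", sep = "")
  print(utils::head(x$trend, 10L), row.names = FALSE, ...)
  invisible(x)
}

#' Loess smoothing of a CTI series
#'
#' Locally weighted polynomial regression (tricube weights, no robustness
#' iterations) evaluated at the census years, with a pointwise 95% band from
#' the smoother's standard errors.
#'
#' @param series a `cti_series` (single variant) or data frame with columns
#'   `year` and `cti`.
#' @param span loess span in (0, 1] (default 0.75).
#' @param degree local polynomial degree, 0, 1 or 2 (default 2).
#' @return data frame: `year, fit, se, lo, hi`.
#' @export
loess_trend <- function(series, span = 0.75, degree = 2L) {
  if (!all(c("year", "cti") %in% names(series)))
    stop("series must have columns 'year' and 'cti'")
  if (length(unique(series$variant)) > 1L)
    stop("smooth one CTI variant at a time")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (!degree %in% 0:2) stop("degree must be 0, 1 or 2")
  n <- nrow(series)
  if (n < max(4L, degree + 2L))
    stop("need at least ", max(4L, degree + 2L), " points")
  fit <- stats::loess(cti ~ year, data = series, span = span,
                      degree = degree, family = "gaussian",
                      control = stats::loess.control(surface = "direct",
                                                     iterations = 1L))
  pr <- stats::predict(fit, newdata = series, se = TRUE)
  data.frame(year = series$year, fit = as.numeric(pr$fit),
             se = as.numeric(pr$se.fit),
             lo = as.numeric(pr$fit - 1.96 * pr$se.fit),
             hi = as.numeric(pr$fit + 1.96 * pr$se.fit))
}
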