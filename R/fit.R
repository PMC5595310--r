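# Panel regression behind the modelled CTI.
#
# log N_{s,t} = a + b_t fYear_t + b Temp.pref_s + b Attribute_s
#               + b_{t} fYear_t:Temp.pref_s + b_{t} fYear_t:Attribute_s
#               + Sp_s + cYear_s * t + e_{s,t}
#
# with e AR(1) within species across consecutive census years, Sp_s random
# species intercepts and cYear_s random species slopes on continuous year,
# both recentred to sum to zero.  Estimation is maximum likelihood: for any
# (rho, variance ratios) the fixed effects are the GLS solution, species
# blocks being independent; the three covariance parameters are profiled out
# and optimized numerically.  Deterministic given data and settings.

#' Specify the attribute-by-year model
#'
#' @param focal name of the focal trait column (default `"temp_pref"`).
#' @param confounders character vector of confounding attribute columns.
#' @param include_attribute_interaction include the focal-by-confounder
#'   interaction (main-effect level) for every confounder?
#' @param collinearity_limit refuse to fit when the absolute Pearson
#'   correlation between the focal trait and any continuous confounder
#'   exceeds this (default 0.7); strong covariation makes the separation of
#'   year effects ill-conditioned.
#' @param force fit even when the collinearity guard trips.
#' @param control list: `maxit` (optimizer iterations, default 500),
#'   `reltol` (default 1e-10).
#' @return a `model_spec` list.
#' @export
model_spec <- function(focal = "temp_pref", confounders = character(0),
                       include_attribute_interaction = FALSE,
                       collinearity_limit = 0.7, force = FALSE,
                       control = list()) {
  if (focal %in% confounders)
    stop("focal trait must not be listed among the confounders")
  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-8), control)
  structure(list(focal = focal, confounders = confounders,
                 include_attribute_interaction = include_attribute_interaction,
                 collinearity_limit = collinearity_limit, force = force,
                 control = ctrl),
            class = "model_spec")
}

# Build the fixed-effects design matrix; meta carries everything needed to
# rebuild the same columns for new panel rows at prediction time.
build_design <- function(panel, meta) {
  df <- data.frame(fYear = factor(panel$year, levels = meta$year_levels))
  if (anyNA(df$fYear))
    stop("panel contains years outside the fitted census years")
  vars <- c(meta$focal, meta$confounders)
  for (v in vars) {
    if (!v %in% names(panel)) stop("panel lacks attribute column '", v, "'")
    if (v %in% names(meta$centers)) {
      df[[v]] <- as.numeric(panel[[v]]) - meta$centers[[v]]
    } else {
      x <- factor(as.character(panel[[v]]), levels = meta$attr_levels[[v]])
      if (anyNA(x))
        stop("attribute '", v, "' has levels unseen at fit time")
      df[[v]] <- x
    }
  }
  terms <- c("fYear", vars, paste0("fYear:", meta$focal))
  for (cf in meta$confounders) terms <- c(terms, paste0("fYear:", cf))
  if (meta$include_attribute_interaction)
    for (cf in meta$confounders)
      terms <- c(terms, paste0(meta$focal, ":", cf))
  ff <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  mm <- stats::model.matrix(ff, df)
  tl <- attr(stats::terms(ff), "term.labels")
  assign <- attr(mm, "assign")
  group <- character(ncol(mm))
  group[assign == 0] <- "intercept"
  for (k in seq_along(tl)) {
    lab <- tl[k]
    g <- if (lab == "fYear") "year_main"
    else if (lab == meta$focal) "main_focal"
    else if (lab %in% meta$confounders) "main_confounder"
    else if (lab == paste0("fYear:", meta$focal)) "year_focal"
    else if (lab %in% paste0("fYear:", meta$confounders)) "year_confounder"
    else "attribute_interaction"
    group[assign == k] <- g
  }
  list(X = mm, group = group)
}

ar1_struct <- function(years) {
  # lag matrix and same-run mask of an AR(1) process over consecutive
  # census years; runs separated by gaps are treated as independent
  T <- length(years)
  run <- cumsum(c(1L, diff(years) != 1L))
  list(lag = abs(outer(seq_len(T), seq_len(T), "-")),
       same = outer(run, run, "=="))
}

ar1_cor <- function(years, rho) {
  s <- ar1_struct(years)
  (rho^s$lag) * s$same  # rho^0 = 1 on the diagonal, including rho = 0
}

#' Fit the attribute-by-year abundance model
#'
#' Fits, by maximum likelihood, a regression of log abundance indices on
#' year (as a factor), the focal trait, the confounding attributes, and the
#' year interactions of all of them, with AR(1) errors between consecutive
#' census years within species, random species intercepts and random species
#' slopes on continuous year.  The first census year is the reference level,
#' so all year-interaction coefficients are zero in year 1 and the model
#' intercept refers to year 1.  Continuous covariates are mean-centred
#' internally (predictions are returned on the original scale).  Random
#' effects are best linear unbiased predictions recentred to sum to zero;
#' the intercept absorbs the removed mean so predictions are unchanged.
#'
#' @param panel aligned panel (see [align_community_traits()]) with columns
#'   `species`, `year`, `abundance` (strictly positive; logged internally)
#'   and the trait columns named in `spec`.
#' @param spec a [model_spec()].
#' @return an `attribute_year_model`: list with elements `coefficients`,
#'   `group` (column classification), `rho`, `sigma2`, `var_sp`, `var_cyear`,
#'   `ranef` (data frame species / intercept / cyear, each summing to zero),
#'   `logLik`, `AIC`, `n`, `meta`, `spec`, `optim` (convergence trace).
#' @export
fit_attribute_year_model <- function(panel, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  need <- c("species", "year", "abundance", spec$focal, spec$confounders)
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel lacks column(s): ", paste(miss, collapse = ", "))
  if (any(panel$abundance <= 0))
    stop("abundances must be strictly positive for the log-scale model; ",
         "apply standardize_to_index() with an appropriate zero policy first")
  if (length(unique(panel$year)) < 2L) stop("need at least 2 census years")
  if (length(unique(panel$species)) < 2L) stop("need at least 2 species")

  # collinearity guard on species-level trait values
  sp_level <- panel[!duplicated(panel$species), , drop = FALSE]
  cont_conf <- spec$confounders[vapply(spec$confounders, function(v)
    is.numeric(panel[[v]]), logical(1))]
  for (cf in cont_conf) {
    r <- stats::cor(sp_level[[spec$focal]], sp_level[[cf]])
    if (is.finite(r) && abs(r) > spec$collinearity_limit && !spec$force)
      stop("collinearity guard: |cor(", spec$focal, ", ", cf, ")| = ",
           format(abs(r), digits = 3), " exceeds ", spec$collinearity_limit,
           "; the year effects of the two attributes cannot be separated ",
           "reliably (use force = TRUE to override)")
  }

  meta <- list(
    year_levels = as.character(sort(unique(panel$year))),
    focal = spec$focal, confounders = spec$confounders,
    include_attribute_interaction = spec$include_attribute_interaction,
    centers = c(
      stats::setNames(mean(sp_level[[spec$focal]]), spec$focal),
      if (length(cont_conf))
        vapply(cont_conf, function(v) mean(sp_level[[v]]), numeric(1))),
    attr_levels = stats::setNames(lapply(
      setdiff(spec$confounders, cont_conf),
      function(v) sort(unique(as.character(panel[[v]])))),
      setdiff(spec$confounders, cont_conf)))

  panel <- panel[order(panel$species, panel$year), , drop = FALSE]
  dm <- build_design(panel, meta)
  X <- dm$X
  y <- log(panel$abundance)
  n <- length(y)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; aliased terms: ",
         paste(aliased, collapse = ", "))
  }

  sp_idx <- split(seq_len(n), panel$species)
  cyear_center <- mean(as.numeric(meta$year_levels))
  blocks <- lapply(sp_idx, function(ii) {
    yrs <- panel$year[ii]
    s <- ar1_struct(yrs)
    cy <- yrs - cyear_center
    list(X = X[ii, , drop = FALSE], y = y[ii], years = yrs,
         cy = cy, lag = s$lag, same = s$same, cc = tcrossprod(cy))
  })

  # balanced panels share one covariance block across species, allowing a
  # single Cholesky and stacked backsolves per likelihood evaluation
  balanced <- length(unique(vapply(blocks, function(b)
    paste(b$years, collapse = ","), character(1)))) == 1L
  nS <- length(blocks)
  Tb <- length(blocks[[1L]]$years)

  # profiled negative log-likelihood over (rho, var ratios)
  gls_pass <- function(rho, g_sp, g_cy) {
    if (balanced) {
      b1 <- blocks[[1L]]
      M <- g_sp + g_cy * b1$cc + (rho^b1$lag) * b1$same
      U <- tryCatch(chol(M), error = function(e) NULL)
      if (is.null(U)) return(NULL)
      tXall <- matrix(backsolve(U, matrix(X, Tb), transpose = TRUE), n, p)
      tY <- backsolve(U, matrix(y, Tb), transpose = TRUE)
      A <- crossprod(tXall)
      rhs <- crossprod(tXall, as.vector(tY))[, 1L]
      yWy <- sum(tY^2)
      logdet <- nS * 2 * sum(log(diag(U)))
    } else {
      A <- matrix(0, p, p); rhs <- numeric(p); yWy <- 0; logdet <- 0
      for (k in seq_along(blocks)) {
        b <- blocks[[k]]
        M <- g_sp + g_cy * b$cc + (rho^b$lag) * b$same
        U <- tryCatch(chol(M), error = function(e) NULL)
        if (is.null(U)) return(NULL)
        tX <- backsolve(U, b$X, transpose = TRUE)
        ty <- backsolve(U, b$y, transpose = TRUE)
        A <- A + crossprod(tX)
        rhs <- rhs + crossprod(tX, ty)[, 1L]
        yWy <- yWy + sum(ty^2)
        logdet <- logdet + 2 * sum(log(diag(U)))
      }
    }
    chA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(chA)) return(NULL)
    beta <- backsolve(chA, backsolve(chA, rhs, transpose = TRUE))
    rss <- max(yWy - sum(rhs * beta), 0)
    sigma2 <- max(rss / n, 1e-12)
    nll <- 0.5 * (n * log(2 * pi * sigma2) + logdet + rss / sigma2)
    list(beta = beta, sigma2 = sigma2, nll = nll, logdet = logdet)
  }
  nll_fun <- function(par) {
    res <- gls_pass(tanh(par[1L]), exp(par[2L]), exp(par[3L]))
    if (is.null(res) || !is.finite(res$nll)) return(1e10)
    res$nll
  }
  opt <- stats::optim(c(0, log(0.5), log(0.05)), nll_fun,
                      method = "Nelder-Mead",
                      control = list(maxit = spec$control$maxit,
                                     reltol = spec$control$reltol))
  restarts <- 0L
  while (opt$convergence != 0L && restarts < 2L) {
    # restart the simplex from the current best point (cures simplex
    # degeneracy, which also arises legitimately when residual variance
    # hits its floor on noise-free data)
    restarts <- restarts + 1L
    opt2 <- stats::optim(opt$par, nll_fun, method = "Nelder-Mead",
                         control = list(maxit = spec$control$maxit,
                                        reltol = spec$control$reltol))
    if (opt2$value <= opt$value) opt <- opt2 else break
  }
  degenerate <- gls_pass(tanh(opt$par[1L]), exp(opt$par[2L]),
                         exp(opt$par[3L]))$sigma2 <= 1e-10
  if (opt$convergence != 0L && !degenerate)
    stop("covariance-parameter optimization did not converge (code ",
         opt$convergence, " after ", opt$counts[1L], " evaluations, ",
         restarts, " restarts)")
  rho <- tanh(opt$par[1L]); g_sp <- exp(opt$par[2L]); g_cy <- exp(opt$par[3L])
  if (degenerate) {
    # noise-free data: every GLS solution coincides with OLS, which is
    # better conditioned than the weighted solve at extreme covariance
    # parameters
    rho <- 0; g_sp <- 1e-8; g_cy <- 1e-8
    fin <- gls_pass(rho, g_sp, g_cy)
    fin$beta <- qr.coef(qrX, y)
  } else {
    fin <- gls_pass(rho, g_sp, g_cy)
  }
  beta <- stats::setNames(fin$beta, colnames(X))

  # BLUPs of the species effects, then recentred to sum to zero
  b_sp <- numeric(length(blocks)); b_cy <- numeric(length(blocks))
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    M <- g_sp + g_cy * b$cc + (rho^b$lag) * b$same
    r <- b$y - b$X %*% beta
    Minv_r <- tryCatch(solve(M, r), error = function(e)
      solve(M + diag(1e-8 * max(diag(M)), nrow(M)), r))
    b_sp[k] <- g_sp * sum(Minv_r)
    b_cy[k] <- g_cy * sum(b$cy * Minv_r)
  }
  sp_shift <- mean(b_sp)
  b_sp <- b_sp - sp_shift
  beta["(Intercept)"] <- beta["(Intercept)"] + sp_shift
  b_cy <- b_cy - mean(b_cy)

  ll <- -fin$nll
  npar <- p + 3L + 1L  # beta, sigma2, rho, two variance ratios
  structure(list(
    coefficients = beta, group = dm$group,
    rho = rho, sigma2 = fin$sigma2,
    var_sp = g_sp * fin$sigma2, var_cyear = g_cy * fin$sigma2,
    ranef = data.frame(species = names(sp_idx), intercept = b_sp,
                       cyear = b_cy, stringsAsFactors = FALSE),
    logLik = ll, AIC = -2 * ll + 2 * npar, n = n, npar = npar,
    meta = meta, spec = spec,
    optim = list(convergence = opt$convergence, counts = opt$counts,
                 value = opt$value)),
    class = "attribute_year_model")
}

#' @export
print.attribute_year_model <- function(x, ...) {
  cat("Attribute-by-year abundance model\n")
  cat("  ", length(x$ranef$species), " species, ",
      length(x$meta$year_levels), " years, n = ", x$n, "\n", sep = "")
  cat("  focal: ", x$meta$focal,
      if (length(x$meta$confounders))
        paste0("; confounders: ", paste(x$meta$confounders, collapse = ", ")),
      "\n", sep = "")
  cat("  rho = ", format(x$rho, digits = 3),
      ", sigma2 = ", format(x$sigma2, digits = 3),
      ", var(Sp) = ", format(x$var_sp, digits = 3),
      ", var(cYear) = ", format(x$var_cyear, digits = 3), "\n", sep = "")
  cat("  logLik = ", format(x$logLik, digits = 6),
      ", AIC = ", format(x$AIC, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
coef.attribute_year_model <- function(object, ...) object$coefficients

#' @export
logLik.attribute_year_model <- function(object, ...) {
  structure(object$logLik, df = object$npar, class = "logLik")
}
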