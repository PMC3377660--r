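#' Control parameters for [lme_varexp()]
#'
#' @param reltol relative convergence tolerance on the log-likelihood.
#' @param maxit maximum optimizer iterations per start.
#' @param starts matrix of deterministic starting values, one row per
#'   start: column 1 is log(tau/sigma), remaining columns (recycled over
#'   variance strata) are variance exponents. Multiple starts guard
#'   against local optima on these small, ill-conditioned surfaces.
#' @return A list of class \code{lme_control}.
#' @export
lme_control <- function(reltol = 1e-12, maxit = 5000,
                        starts = rbind(c(-0.5, 0), c(-3, 0), c(1, 0),
                                       c(-0.5, 0.7), c(-0.5, -0.7))) {
  structure(list(reltol = reltol, maxit = maxit, starts = starts),
            class = "lme_control")
}

# Profiled (restricted) log-likelihood machinery. The marginal covariance
# of core i is V_i = sigma^2 * (diag(exp(2 delta_k t_ij)) + r^2 J) with
# r = tau/sigma; sigma^2 and the fixed effects are profiled out
# analytically, leaving only (log r, delta_k) for the optimizer. The
# rank-one structure of the random intercept is absorbed with the
# Woodbury identity, so every quantity is a grouped weighted sum and no
# per-core decomposition is needed.
.lme_profile <- function(theta, env) {
  ri <- env$random_intercept
  nd <- env$n_delta
  r2 <- if (ri) exp(2 * theta[1]) else 0
  delta <- if (nd > 0) theta[(ri + 1):(ri + nd)] else numeric(0)
  dvec <- if (nd > 0) delta[env$strat_idx] else rep(0, env$n)
  ex <- 2 * dvec * env$tvec
  if (any(abs(ex) > 60) || !is.finite(r2)) return(NULL)  # overflow guard
  w <- exp(ex)
  u <- 1 / w
  X <- env$X; y <- env$y; p <- env$p
  Xu <- X * u
  XtWX <- crossprod(X, Xu)
  XtWy <- drop(crossprod(Xu, y))
  ytWy <- sum(y^2 * u)
  logdet <- sum(ex)
  if (ri) {
    s_g <- drop(env$Gmat %*% u)
    Mx <- env$Gmat %*% Xu
    My <- drop(env$Gmat %*% (y * u))
    c_g <- r2 / (1 + r2 * s_g)
    XtWX <- XtWX - crossprod(Mx, Mx * c_g)
    XtWy <- XtWy - drop(crossprod(Mx, My * c_g))
    ytWy <- ytWy - sum(My^2 * c_g)
    logdet <- logdet + sum(log1p(r2 * s_g))
  }
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  beta <- backsolve(ch, backsolve(ch, XtWy, transpose = TRUE))
  rss <- max(ytWy - sum(beta * XtWy), 1e-300)
  n <- env$n
  if (env$reml) {
    np <- n - p
    s2 <- rss / np
    ll <- -0.5 * (np * (log(2 * pi) + log(s2) + 1) + logdet +
                    2 * sum(log(diag(ch))))
  } else {
    s2 <- rss / n
    ll <- -0.5 * (n * (log(2 * pi) + log(s2) + 1) + logdet)
  }
  list(ll = ll, beta = beta, sigma2 = s2, XtWX = XtWX, r2 = r2,
       delta = delta, w = w)
}

#' Random-intercept linear mixed model with an exponential variance
#' function
#'
#' Fits, by maximum likelihood or REML, the model
#' \deqn{y_{ij} = x_{ij}' \beta + a_i + \varepsilon_{ij}, \quad
#'   a_i \sim N(0, \tau^2), \quad
#'   \varepsilon_{ij} \sim N(0, \sigma^2 e^{2 \delta_{k(ij)} t_{ij}}),}
#' the standard repeated-measures model for sealed-core incubation time
#' series: core identity enters as a random intercept and the residual
#' spread may grow (or shrink) exponentially with time, optionally with a
#' separate exponent per stratum (e.g. treatment). Estimation maximizes
#' the profiled (restricted) Gaussian likelihood over
#' \eqn{(\log \tau/\sigma, \delta_k)} with deterministic multi-start
#' optimization; \eqn{\sigma^2} and \eqn{\beta} are profiled analytically
#' and the fixed effects are the GLS estimates at the optimum.
#'
#' @param fixed model formula for the fixed effects, e.g.
#'   \code{pool ~ time_d * treatment}.
#' @param data data frame containing all variables.
#' @param group name of the grouping (core identity) column.
#' @param var_time name of the variance covariate column (typically time
#'   in days), or \code{NULL} for homoscedastic residuals.
#' @param var_strata name of a factor column giving one variance exponent
#'   per stratum, or \code{NULL} for a single exponent. Requires
#'   \code{var_time}.
#' @param random_intercept include the per-group random intercept
#'   (\code{FALSE} gives a generalized least-squares fit).
#' @param method \code{"REML"} (default, parameter reporting) or
#'   \code{"ML"} (likelihood-ratio model comparison).
#' @param fix optional list fixing variance parameters instead of
#'   estimating them: elements \code{ratio} (tau/sigma) and/or
#'   \code{delta} (vector over strata).
#' @param control a [lme_control()].
#' @return An object of class \code{lme_varexp} with methods
#'   \code{print}, \code{summary}, \code{coef}, \code{vcov},
#'   \code{logLik}, \code{fitted}, \code{residuals}, \code{predict},
#'   \code{simulate} and \code{ranef}. Key components: \code{coefficients},
#'   \code{se}, \code{tau}, \code{sigma}, \code{delta} (named per
#'   stratum), \code{loglik}, \code{n_params}.
#' @seealso [lr_test()], [backward_select()], [icc()],
#'   [lme_diagnostics()].
#' @export
lme_varexp <- function(fixed, data, group = "core_id", var_time = NULL,
                       var_strata = NULL, random_intercept = TRUE,
                       method = c("REML", "ML"), fix = NULL,
                       control = lme_control()) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data), group %in% names(data))
  if (!is.null(var_strata) && is.null(var_time)) {
    stop("a variance stratum requires a variance covariate (var_time)")
  }
  mf <- stats::model.frame(fixed, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) stop("singular fixed-effects design")
  grp <- factor(data[[group]])
  if (random_intercept && nlevels(grp) < 2) {
    stop("at least 2 groups are required for a random intercept")
  }
  tvec <- if (is.null(var_time)) rep(0, n) else as.numeric(data[[var_time]])
  strat <- if (is.null(var_strata)) factor(rep("all", n)) else
    factor(data[[var_strata]])
  n_delta <- if (is.null(var_time)) 0L else nlevels(strat)

  Gmat <- matrix(0, nlevels(grp), n)
  Gmat[cbind(as.integer(grp), seq_len(n))] <- 1
  env <- list(X = X, y = y, n = n, p = p, Gmat = Gmat,
              group_rows = split(seq_len(n), grp),
              tvec = tvec, strat_idx = as.integer(strat),
              n_delta = n_delta, random_intercept = random_intercept,
              reml = method == "REML")

  fix_ratio <- if (!is.null(fix$ratio)) log(fix$ratio) else NULL
  fix_delta <- if (!is.null(fix$delta)) rep_len(fix$delta, max(n_delta, 1)) else NULL
  free_r <- random_intercept && is.null(fix_ratio)
  free_d <- n_delta > 0 && is.null(fix_delta)
  npar <- free_r + if (free_d) n_delta else 0L

  build_theta <- function(free) {
    th <- numeric(0)
    if (random_intercept) {
      th <- c(th, if (free_r) free[1] else fix_ratio)
    }
    if (n_delta > 0) {
      th <- c(th, if (free_d) free[(free_r + 1):(free_r + n_delta)]
              else fix_delta)
    }
    th
  }
  objective <- function(free) {
    res <- .lme_profile(build_theta(free), env)
    if (is.null(res) || !is.finite(res$ll)) 1e10 else -res$ll
  }

  if (npar == 0) {
    opt_free <- numeric(0); conv <- TRUE
  } else {
    starts <- control$starts
    start_list <- lapply(seq_len(nrow(starts)), function(i) {
      s <- numeric(0)
      if (free_r) s <- c(s, starts[i, 1])
      if (free_d) s <- c(s, rep(starts[i, 2], n_delta))
      s
    })
    best <- NULL
    for (s in start_list) {
      o <- if (npar == 1) {
        stats::optim(s, objective, method = "Brent",
                     lower = -15, upper = 8,
                     control = list(maxit = control$maxit))
      } else {
        stats::optim(s, objective, method = "Nelder-Mead",
                     control = list(reltol = control$reltol,
                                    maxit = control$maxit))
      }
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (npar > 1) {  # polish from the best start
      best <- stats::optim(best$par, objective, method = "Nelder-Mead",
                           control = list(reltol = control$reltol,
                                          maxit = control$maxit))
    }
    if (best$value >= 1e10) {
      stop("lme_varexp did not converge: likelihood not finite at any start")
    }
    opt_free <- best$par; conv <- TRUE
  }

  res <- .lme_profile(build_theta(opt_free), env)
  if (is.null(res)) stop("lme_varexp: likelihood undefined at the optimum")
  sigma <- sqrt(res$sigma2)
  tau <- if (random_intercept) sqrt(res$r2) * sigma else 0
  delta <- if (n_delta > 0) stats::setNames(res$delta, levels(strat)) else
    stats::setNames(numeric(0), character(0))
  vc <- res$sigma2 * chol2inv(chol(res$XtWX))
  dimnames(vc) <- list(colnames(X), colnames(X))
  beta <- stats::setNames(drop(res$beta), colnames(X))

  # BLUPs of the random intercepts: a_i = r^2 1' W_i^{-1} (y_i - X_i beta)
  marg <- drop(X %*% beta)
  rmar <- y - marg
  ranef <- stats::setNames(rep(0, nlevels(grp)), levels(grp))
  if (random_intercept) {
    for (gname in levels(grp)) {
      g <- env$group_rows[[gname]]
      wi <- res$w[g]
      ranef[gname] <- res$r2 * sum(rmar[g] / wi) /
        (1 + res$r2 * sum(1 / wi))
    }
  }
  fitted_c <- marg + ranef[as.character(grp)]

  n_params <- p + 1L + as.integer(random_intercept) + n_delta

  structure(list(
    coefficients = beta, se = sqrt(diag(vc)), vcov = vc,
    sigma = sigma, tau = tau, delta = delta,
    loglik = res$ll, method = method, n = n, p = p, n_params = n_params,
    fitted_marginal = marg, fitted = unname(fitted_c),
    residuals = unname(y - fitted_c), ranef = ranef,
    weights = res$w, groups = grp, var_time = tvec, var_strata = strat,
    y = y, formula = fixed, group = group,
    var_time_name = var_time, var_strata_name = var_strata,
    random_intercept = random_intercept, converged = conv,
    call = match.call()
  ), class = "lme_varexp")
}

#' @export
print.lme_varexp <- function(x, digits = 4, ...) {
  cat(sprintf("Linear mixed model (%s), random intercept by %s%s\n",
              x$method, x$group,
              if (!x$random_intercept) " [disabled: GLS fit]" else ""))
  cat("  fixed: ", deparse(x$formula), "\n")
  cat(sprintf("  logLik %.4f | sigma %.4g | tau %.4g\n",
              x$loglik, x$sigma, x$tau))
  if (length(x$delta)) {
    cat("  variance exponents (per stratum, SD = sigma*exp(delta*t)):\n")
    print(round(x$delta, digits))
  }
  cat("  fixed effects:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.lme_varexp <- function(object, ...) object$coefficients

#' @export
vcov.lme_varexp <- function(object, ...) object$vcov

#' @export
logLik.lme_varexp <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' @export
fitted.lme_varexp <- function(object, level = 1, ...) {
  if (level == 0) object$fitted_marginal else object$fitted
}

#' @param type \code{"response"} (raw, observed minus conditional fitted)
#'   or \code{"standardized"} (divided by the modelled residual SD
#'   \eqn{\sigma e^{\delta_k t}}).
#' @rdname lme_varexp
#' @export
residuals.lme_varexp <- function(object,
                                 type = c("response", "standardized"),
                                 ...) {
  type <- match.arg(type)
  r <- object$residuals
  if (type == "standardized") r / (object$sigma * sqrt(object$weights)) else r
}

#' @export
predict.lme_varexp <- function(object, newdata = NULL, level = 1, ...) {
  if (is.null(newdata)) return(fitted(object, level))
  X <- stats::model.matrix(stats::delete.response(stats::terms(object$formula)),
                           newdata)
  out <- drop(X %*% object$coefficients)
  if (level == 1) {
    g <- as.character(newdata[[object$group]])
    known <- g %in% names(object$ranef)
    out[known] <- out[known] + object$ranef[g[known]]
  }
  out
}

#' @export
simulate.lme_varexp <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  grp <- object$groups
  sd_obs <- object$sigma * sqrt(object$weights)
  out <- replicate(nsim, {
    a <- stats::rnorm(nlevels(grp), 0, object$tau)
    object$fitted_marginal + a[as.integer(grp)] +
      stats::rnorm(object$n, 0, sd_obs)
  })
  as.data.frame(out)
}

#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @export
ranef.lme_varexp <- function(object, ...) object$ranef

#' @export
summary.lme_varexp <- function(object, ...) {
  tt <- cbind(Estimate = object$coefficients, `Std.Error` = object$se,
              `t value` = object$coefficients / object$se)
  df <- object$n - object$p
  tt <- cbind(tt, `p value` = 2 * stats::pt(-abs(tt[, 3]), df))
  structure(list(fit = object, coefficients = tt, df = df),
            class = "summary.lme_varexp")
}

#' @export
print.summary.lme_varexp <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nFixed effects (t on %d residual df):\n", x$df))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  if (x$fit$random_intercept) {
    t0 <- if (length(x$fit$delta)) {
      stats::setNames(vapply(names(x$fit$delta), function(s)
        icc(x$fit, at_time = 0, stratum = s), numeric(1)),
        names(x$fit$delta))
    } else icc(x$fit, at_time = 0)
    cat("\nIntraclass correlation at t = 0:\n"); print(round(t0, 4))
  }
  invisible(x)
}

#' Likelihood-ratio test between nested mixed-model fits
#'
#' L = 2 (logLik_full - logLik_reduced), referred to a chi-squared
#' distribution on the difference in parameter count. For tests of a
#' variance component on the boundary of its space (e.g. random-intercept
#' SD = 0), set \code{boundary = TRUE} to use the 50:50 mixture
#' \eqn{0.5\chi^2_{df-1} + 0.5\chi^2_{df}} correction; the returned
#' \code{corrected} flag records this.
#'
#' Fixed-effect comparisons must use ML fits; REML likelihoods are only
#' comparable when the fixed design is unchanged.
#'
#' @param full,reduced two [lme_varexp()] fits, reduced nested in full.
#' @param boundary apply the boundary mixture correction.
#' @return An object of class \code{lr_test}: list with \code{L_ratio},
#'   \code{df}, \code{p_value}, \code{corrected}.
#' @export
lr_test <- function(full, reduced, boundary = FALSE) {
  stopifnot(inherits(full, "lme_varexp"), inherits(reduced, "lme_varexp"))
  if (full$n != reduced$n) stop("fits use different numbers of observations")
  if (reduced$n_params >= full$n_params) {
    stop("models are not nested: reduced must have fewer parameters")
  }
  if (full$p != reduced$p && (full$method != "ML" || reduced$method != "ML")) {
    stop("fixed-effect comparisons require ML fits")
  }
  L <- 2 * (full$loglik - reduced$loglik)
  if (L < -1e-6) {
    warning(sprintf("negative likelihood ratio (%.3g): optimizer tolerance", L))
  }
  L <- max(L, 0)
  df <- full$n_params - reduced$n_params
  p <- if (boundary) {
    lower <- if (df >= 2) stats::pchisq(L, df - 1, lower.tail = FALSE) else
      as.numeric(L <= 0)
    0.5 * lower + 0.5 * stats::pchisq(L, df, lower.tail = FALSE)
  } else {
    stats::pchisq(L, df, lower.tail = FALSE)
  }
  structure(list(L_ratio = L, df = df, p_value = p, corrected = boundary),
            class = "lr_test")
}

#' @export
print.lr_test <- function(x, ...) {
  cat(sprintf("L.Ratio = %.4g, df = %d, %s = %.4g\n", x$L_ratio, x$df,
              if (x$corrected) "p_corr" else "p", x$p_value))
  invisible(x)
}

#' Backward selection of the fixed structure by likelihood-ratio tests
#'
#' Starting from a maximal fixed structure (typically
#' \code{response ~ time * treatment}), repeatedly tests every droppable
#' term (respecting marginality: an interaction shields its main effects)
#' with ML likelihood-ratio tests, drops the least significant term whose
#' p exceeds \code{alpha}, and stops when every remaining term is
#' significant. The final model is refitted by REML for parameter
#' reporting. The selection trail records every test performed.
#'
#' @param fixed maximal fixed-effects formula.
#' @param data data frame.
#' @param alpha retention threshold (default 0.05).
#' @param ... passed to [lme_varexp()] (group, var_time, var_strata, ...).
#' @return List with \code{fit} (REML fit of the selected model),
#'   \code{formula}, and \code{trail} (data frame: step, term, L_ratio,
#'   df, p_value, dropped).
#' @export
backward_select <- function(fixed, data, alpha = 0.05, ...) {
  current <- fixed
  trail <- list()
  step <- 0L
  repeat {
    cand <- stats::drop.scope(current)
    if (!length(cand)) break
    fit_full <- lme_varexp(current, data, method = "ML", ...)
    tests <- lapply(cand, function(tm) {
      red <- stats::update(current, paste(". ~ . -", tm))
      lr_test(fit_full, lme_varexp(red, data, method = "ML", ...))
    })
    step <- step + 1L
    ps <- vapply(tests, function(t) t$p_value, numeric(1))
    worst <- which.max(ps)
    trail[[step]] <- data.frame(
      step = step, term = cand,
      L_ratio = vapply(tests, function(t) t$L_ratio, numeric(1)),
      df = vapply(tests, function(t) t$df, numeric(1)),
      p_value = ps,
      dropped = seq_along(cand) == worst & ps[worst] > alpha,
      stringsAsFactors = FALSE)
    if (ps[worst] <= alpha) break
    current <- stats::update(current, paste(". ~ . -", cand[worst]))
  }
  list(fit = lme_varexp(current, data, method = "REML", ...),
       formula = current,
       trail = do.call(rbind, c(trail, list(make.row.names = FALSE))))
}

#' Intraclass correlation of a fitted mixed model
#'
#' Proportion of total variance attributable to the grouping (core)
#' random effect, at a given value of the variance covariate:
#' \deqn{ICC(t) = \tau^2 / (\tau^2 + \sigma^2 e^{2\delta_k t}).}
#'
#' @param fit an [lme_varexp()] fit.
#' @param at_time value of the variance covariate.
#' @param stratum variance stratum name (required when the fit is
#'   stratified).
#' @return Dimensionless correlation in [0, 1].
#' @export
icc <- function(fit, at_time = 0, stratum = NULL) {
  stopifnot(inherits(fit, "lme_varexp"))
  d <- if (!length(fit$delta)) 0 else if (length(fit$delta) == 1) {
    fit$delta[[1]]
  } else {
    if (is.null(stratum)) stop("stratified fit: supply a stratum name")
    if (!stratum %in% names(fit$delta)) stop("unknown stratum: ", stratum)
    fit$delta[[stratum]]
  }
  v_e <- fit$sigma^2 * exp(2 * d * at_time)
  unname(fit$tau^2 / (fit$tau^2 + v_e))
}

#' Plot-ready residual diagnostics of a mixed-model fit
#'
#' Standardized (conditional) residuals with their fitted values and
#' normal theoretical quantiles, for residual-vs-fitted and Q-Q displays.
#'
#' @param fit an [lme_varexp()] fit.
#' @return A data frame sorted by standardized residual with columns
#'   \code{observed}, \code{fitted}, \code{residual},
#'   \code{std_residual}, \code{theoretical_quantile}; one row per
#'   observation.
#' @export
lme_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "lme_varexp"))
  sr <- residuals(fit, type = "standardized")
  ord <- order(sr)
  data.frame(observed = fit$y[ord], fitted = fit$fitted[ord],
             residual = fit$residuals[ord], std_residual = sr[ord],
             theoretical_quantile = stats::qnorm(stats::ppoints(fit$n)),
             row.names = NULL)
}
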