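#' Box-Cox power transformation
#'
#' \eqn{y(\lambda) = (y^\lambda - 1)/\lambda} for \eqn{\lambda \neq 0}
#' and \eqn{\ln y} at \eqn{\lambda = 0}.
#'
#' @param y strictly positive values.
#' @param lambda power parameter.
#' @return Transformed values.
#' @export
boxcox_transform <- function(y, lambda) {
  if (any(y <= 0)) stop("Box-Cox requires strictly positive values")
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

#' Profile-likelihood estimate of the Box-Cox parameter
#'
#' Maximizes the Box-Cox profile log-likelihood
#' \deqn{\ell(\lambda) = -\tfrac{n}{2}\log \widehat{\sigma}^2(\lambda) +
#'   (\lambda - 1) \sum \log y,}
#' where \eqn{\widehat{\sigma}^2(\lambda)} is the residual variance of
#' the transformed data around the supplied model (a group structure, or
#' a grand mean). A coarse grid over \code{interval} brackets the
#' optimum, which is then refined by golden-section search
#' (\code{stats::optimize}).
#'
#' @param y strictly positive response values.
#' @param groups optional grouping factor; when supplied the residual
#'   variance is taken around the group means (the transformation is
#'   estimated jointly across groups, not per group).
#' @param interval search interval for lambda.
#' @return List with \code{lambda}, \code{loglik} at the optimum, and
#'   \code{profile} (data frame \code{lambda}, \code{loglik} of the
#'   coarse grid).
#' @export
boxcox_lambda <- function(y, groups = NULL, interval = c(-5, 5)) {
  if (any(y <= 0)) stop("Box-Cox requires strictly positive values")
  n <- length(y)
  g <- if (is.null(groups)) factor(rep(1, n)) else factor(groups)
  slog <- sum(log(y))
  prof <- function(lam) {
    z <- boxcox_transform(y, lam)
    rss <- sum((z - stats::ave(z, g))^2)
    -n / 2 * log(rss / n) + (lam - 1) * slog
  }
  grid <- seq(interval[1], interval[2], by = 0.25)
  ll <- vapply(grid, prof, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-8)
  list(lambda = opt$maximum, loglik = opt$objective,
       profile = data.frame(lambda = grid, loglik = ll))
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition via [stats::lm()]/[stats::anova()].
#' Equal within-group values with unequal means produce an infinite F,
#' flagged in the result.
#'
#' @param values numeric response.
#' @param groups grouping factor (>= 2 groups, >= 2 values per group).
#' @return List with \code{F}, \code{df_between}, \code{df_within},
#'   \code{p_value}, \code{ms_within}, and \code{infinite} flag.
#' @export
anova_oneway <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("at least 2 groups are required")
  if (any(table(g) < 2)) stop("at least 2 values per group are required")
  a <- suppressWarnings(stats::anova(stats::lm(values ~ g)))
  f <- a$`F value`[1]
  inf <- a$`Mean Sq`[1] > 0 &&
    a$`Mean Sq`[2] <= 1e-12 * a$`Mean Sq`[1]
  if (inf) f <- Inf
  list(F = f, df_between = a$Df[1], df_within = a$Df[2],
       p_value = if (inf) 0 else a$`Pr(>F)`[1],
       ms_within = a$`Mean Sq`[2], infinite = inf)
}

#' Tukey honest-significant-difference comparisons
#'
#' All pairwise group comparisons with studentized-range (Tukey-Kramer)
#' adjusted p-values: \eqn{q = |\bar y_a - \bar y_b| /
#' \sqrt{MSW (1/n_a + 1/n_b)/2}} referred to the studentized-range
#' distribution on (k, df_within).
#'
#' @inheritParams anova_oneway
#' @return Data frame with one row per pair: \code{comparison},
#'   \code{estimate} (difference of means), \code{q}, \code{p_adj}.
#' @export
tukey_hsd <- function(values, groups) {
  g <- factor(groups)
  aov1 <- anova_oneway(values, g)
  k <- nlevels(g)
  means <- tapply(values, g, mean)
  ns <- table(g)
  pairs <- utils::combn(levels(g), 2)
  out <- apply(pairs, 2, function(pr) {
    a <- pr[1]; b <- pr[2]
    diff <- means[[b]] - means[[a]]
    se <- sqrt(aov1$ms_within * (1 / ns[[a]] + 1 / ns[[b]]) / 2)
    q <- abs(diff) / se
    data.frame(comparison = paste(b, "-", a), estimate = diff, q = q,
               p_adj = stats::ptukey(q, k, aov1$df_within,
                                     lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Box-Cox, ANOVA and Tukey comparisons for end-point group data
#'
#' The comparison pipeline for end-point quantities (bacterial uptake,
#' BGE): estimate a joint Box-Cox transformation across groups, apply it,
#' run one-way ANOVA and Tukey HSD on the transformed scale.
#'
#' @inheritParams anova_oneway
#' @return List with \code{lambda}, \code{anova} and \code{tukey}.
#' @export
group_comparison <- function(values, groups) {
  bc <- boxcox_lambda(values, groups)
  z <- boxcox_transform(values, bc$lambda)
  list(lambda = bc$lambda, anova = anova_oneway(z, groups),
       tukey = tukey_hsd(z, groups))
}
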