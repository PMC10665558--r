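# Phylogenetic generalized least squares and grade-shift machinery.

# internal: GLS fit of y on design X under covariance C (up to a scalar).
# Returns coefficients, SEs ((n - p)-divisor sigma2), RSS in the whitened
# space, and ML log-likelihoods of the model and the intercept-only null.
gls_core <- function(C, X, y) {
  n <- length(y)
  p <- ncol(X)
  kap <- kappa(C, exact = FALSE)
  if (kap > 1e10) {
    warning("phylogenetic covariance is ill-conditioned (condition number ",
            format(kap, digits = 3), ")")
  }
  U <- chol(C)
  Xw <- whiten(U, X)
  yw <- whiten(U, y)
  XtX <- crossprod(Xw)
  if (rcond(XtX) < 1e-12) {
    stop("singular design (is the predictor constant?)")
  }
  XtXi <- solve(XtX)
  beta <- drop(XtXi %*% crossprod(Xw, yw))
  res_w <- yw - Xw %*% beta
  rss <- sum(res_w^2)
  sigma2 <- rss / (n - p)
  se <- sqrt(sigma2 * diag(XtXi))
  ldC <- 2 * sum(log(diag(U)))
  s2_ml <- rss / n
  ll <- -0.5 * (n * log(2 * pi * s2_ml) + ldC + n)
  # intercept-only null for R2_likelihood
  onew <- whiten(U, matrix(1, n, 1))
  mu0 <- sum(onew * yw) / sum(onew^2)
  rss0 <- sum((yw - mu0 * onew)^2)
  ll0 <- -0.5 * (n * log(2 * pi * rss0 / n) + ldC + n)
  list(beta = beta, se = se, rss = rss, sigma2 = sigma2, XtXi = XtXi,
       logLik = ll, logLik_null = ll0, U = U, df = n - p, n = n)
}

#' Phylogenetic generalized least squares regression
#'
#' Fits `y = a + b x` with error covariance proportional to the phylogenetic
#' covariance of the (pruned) tree under the chosen model transform:
#' `beta = (X' C^-1 X)^-1 X' C^-1 y`. Standard errors use the (n - 2)
#' divisor (standard GLS practice); confidence intervals use t-quantiles
#' with n - 2 degrees of freedom, which matters at small n. The ML
#' log-likelihood and the intercept-only null are retained for
#' `R2_likelihood = 1 - exp(-(2/n) (lnL - lnL0))`. With an identity
#' covariance (star model) the fit reduces exactly to OLS.
#'
#' @param tree a `"phylo"` object (pruned automatically to the data).
#' @param x named numeric vector: predictor (log10 scale by convention;
#'   cerebral or rest-of-cerebellum volume is the predictor in the standard
#'   analyses).
#' @param y named numeric vector: response (log10 scale).
#' @param cov_model covariance model tag passed to [transform_covariance()].
#' @param params parameter list for the transform.
#' @return object of class `"pgls_fit"` with coefficients, SEs, 95/99% CIs,
#'   `sigma2`, `logLik`, `logLik_null`, `r2_lik`, `n`, residuals and fitted
#'   values (species order of the pruned tree).
#' @export
pgls_fit <- function(tree, x, y, cov_model = "bm", params = list()) {
  stopifnot(!is.null(names(x)), !is.null(names(y)))
  common <- intersect(names(x)[!is.na(x)], names(y)[!is.na(y)])
  if (length(common) < 3) stop("need at least 3 species with x and y")
  tree <- match_tree_traits(tree, common)
  ord <- tree$tip.label
  C <- transform_covariance(phylo_vcv(tree), cov_model, params)
  X <- cbind(intercept = 1, slope = x[ord])
  fit <- gls_core(C, X, y[ord])
  q95 <- stats::qt(0.975, fit$df)
  q99 <- stats::qt(0.995, fit$df)
  ci <- function(q) cbind(lower = fit$beta - q * fit$se,
                          upper = fit$beta + q * fit$se)
  n <- fit$n
  out <- list(coefficients = stats::setNames(fit$beta, c("intercept", "slope")),
              se = stats::setNames(fit$se, c("intercept", "slope")),
              ci95 = ci(q95), ci99 = ci(q99),
              sigma2 = fit$sigma2, df.residual = fit$df, n = n,
              logLik = fit$logLik, logLik_null = fit$logLik_null,
              r2_lik = 1 - exp(-(2 / n) * (fit$logLik - fit$logLik_null)),
              cov_model = cov_model, params = params,
              species = ord,
              fitted = drop(X %*% fit$beta),
              residuals = y[ord] - drop(X %*% fit$beta),
              x = x[ord], y = y[ord], tree = tree)
  rownames(out$ci95) <- rownames(out$ci99) <- c("intercept", "slope")
  class(out) <- "pgls_fit"
  out
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit (", x$cov_model, " covariance), n = ", x$n, "\n", sep = "")
  tab <- cbind(estimate = x$coefficients, se = x$se,
               ci95_lower = x$ci95[, 1], ci95_upper = x$ci95[, 2])
  print(signif(tab, 5))
  cat("sigma2 =", signif(x$sigma2, 4),
      " logLik =", format(x$logLik, digits = 7),
      " R2_lik =", signif(x$r2_lik, 4), "\n")
  invisible(x)
}

#' Isometry classification from a PGLS slope
#'
#' Compares the slope's 95% and 99% confidence intervals against a null
#' slope (1 for volume-volume isometry). If the null lies inside the CI the
#' scaling is `isometric` at that level; a null below the CI means the slope
#' is significantly larger (`hyper-allometric`); a null above the CI means
#' `hypo-allometric`. The two levels are reported separately, never
#' collapsed.
#'
#' @param fit a `"pgls_fit"`.
#' @param null_slope the isometric expectation (default 1).
#' @return list with `call95`, `call99`, the slope and both CIs.
#' @export
isometry_test <- function(fit, null_slope = 1.0) {
  classify <- function(ci) {
    if (null_slope < ci[1]) "hyper-allometric"
    else if (null_slope > ci[2]) "hypo-allometric"
    else "isometric"
  }
  list(slope = unname(fit$coefficients["slope"]),
       null_slope = null_slope,
       ci95 = fit$ci95["slope", ], ci99 = fit$ci99["slope", ],
       call95 = classify(fit$ci95["slope", ]),
       call99 = classify(fit$ci99["slope", ]))
}

#' Phylogenetic ANCOVA (grade-shift test)
#'
#' Tests whether a binary species partition differs in regression intercept
#' (grade), slope, or both, by comparing the restricted PGLS design
#' `[1, x]` against a design augmented with the group dummy and/or the
#' group x interaction. The F statistic
#' `[(RSS_r - RSS_f) / dp] / [RSS_f / (n - p_f)]` is computed in the
#' whitened (phylogenetically decorrelated) space and referred to
#' `F(dp, n - p_f)`.
#'
#' @param tree a `"phylo"` object.
#' @param x,y named numeric vectors (log10 scale).
#' @param groups named factor/character/logical with exactly two levels
#'   partitioning the modeled species; each group needs >= 2 species.
#' @param vary which component differs in the full model.
#' @param cov_model,params covariance transform, as in [pgls_fit()].
#' @return object of class `"grade_shift_test"`: `vary`, `F`, `p_value`,
#'   degrees of freedom, and coefficient lists of restricted and full
#'   models.
#' @export
pancova <- function(tree, x, y, groups,
                    vary = c("intercept", "slope", "both"),
                    cov_model = "bm", params = list()) {
  vary <- match.arg(vary)
  stopifnot(!is.null(names(groups)))
  common <- intersect(intersect(names(x)[!is.na(x)], names(y)[!is.na(y)]),
                      names(groups)[!is.na(groups)])
  if (length(setdiff(intersect(names(x), names(y)), names(groups))) > 0) {
    stop("groups do not cover all modeled species: ",
         paste(setdiff(intersect(names(x), names(y)), names(groups)),
               collapse = ", "))
  }
  tree <- match_tree_traits(tree, common)
  ord <- tree$tip.label
  g <- factor(groups[ord])
  if (nlevels(g) != 2) stop("groups must have exactly two levels")
  if (any(table(g) < 2)) stop("each group needs at least 2 species")
  C <- transform_covariance(phylo_vcv(tree), cov_model, params)
  xo <- x[ord]
  yo <- y[ord]
  d <- as.numeric(g == levels(g)[2])
  Xr <- cbind(1, xo)
  Xf <- switch(vary,
               intercept = cbind(1, xo, d),
               slope = cbind(1, xo, d * xo),
               both = cbind(1, xo, d, d * xo))
  fr <- gls_core(C, Xr, yo)
  ff <- gls_core(C, Xf, yo)
  dp <- ncol(Xf) - ncol(Xr)
  df2 <- length(yo) - ncol(Xf)
  Fstat <- max(0, ((fr$rss - ff$rss) / dp) / (ff$rss / df2))
  out <- list(vary = vary, F = Fstat,
              p_value = stats::pf(Fstat, dp, df2, lower.tail = FALSE),
              df = c(dp, df2), n = length(yo),
              groups = stats::setNames(as.character(g), ord),
              coef_restricted = fr$beta, coef_full = ff$beta,
              rss_restricted = fr$rss, rss_full = ff$rss)
  class(out) <- "grade_shift_test"
  out
}

#' @export
print.grade_shift_test <- function(x, ...) {
  cat("Phylogenetic ANCOVA, varying ", x$vary, ": F(", x$df[1], ", ",
      x$df[2], ") = ", signif(x$F, 5), ", Pr(>F) = ",
      signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' Compare pooled and per-group fits via likelihood R-squared and Fisher Z
#'
#' `R2_lik = 1 - exp(-(2/n) (lnL_model - lnL_null))`; with `r = sqrt(R2)`,
#' the two group correlations are compared by Fisher's R-to-Z:
#' `Z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided
#' normal p.
#'
#' @param fit_pooled,fit_g1,fit_g2 `"pgls_fit"` objects on the pooled data
#'   and the two species subsets.
#' @return list with the three R2_lik values, `r1`, `r2`, `Z`, `p_value`.
#' @export
fit_comparison <- function(fit_pooled, fit_g1, fit_g2) {
  n1 <- fit_g1$n
  n2 <- fit_g2$n
  if (n1 <= 3 || n2 <= 3) {
    stop("comparison refused: both groups need n > 3")
  }
  r1 <- sqrt(max(fit_g1$r2_lik, 0))
  r2 <- sqrt(max(fit_g2$r2_lik, 0))
  Z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(r2_pooled = fit_pooled$r2_lik, r2_g1 = fit_g1$r2_lik,
       r2_g2 = fit_g2$r2_lik, r1 = r1, r2 = r2, Z = Z,
       p_value = 2 * stats::pnorm(-abs(Z)))
}

#' Log-log allometry plot with PGLS fit and isometric reference
#'
#' Base-graphics scatter of the fitted data with the PGLS line, 95% and 99%
#' confidence bands on the mean response (display only; isometry calls use
#' the slope CI) and a unit-slope reference line through the fitted
#' intercept.
#'
#' @param fit a `"pgls_fit"`.
#' @param xlab,ylab axis labels.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the band coordinates.
#' @export
plot_allometry <- function(fit, xlab = "log10 x", ylab = "log10 y", ...) {
  graphics::plot(fit$x, fit$y, pch = 19, xlab = xlab, ylab = ylab, ...)
  b <- fit$coefficients
  xs <- seq(min(fit$x), max(fit$x), length.out = 100)
  graphics::abline(b[1], b[2], lwd = 2)
  Xg <- cbind(1, xs)
  # mean-response bands from the coefficient covariance
  covb <- fit$sigma2 * solve(crossprod(
    whiten(chol(transform_covariance(phylo_vcv(fit$tree), fit$cov_model,
                                     fit$params)),
           cbind(1, fit$x))))
  sef <- sqrt(rowSums((Xg %*% covb) * Xg))
  q95 <- stats::qt(0.975, fit$df.residual)
  q99 <- stats::qt(0.995, fit$df.residual)
  yhat <- drop(Xg %*% b)
  graphics::lines(xs, yhat + q95 * sef, lty = 3)
  graphics::lines(xs, yhat - q95 * sef, lty = 3)
  graphics::lines(xs, yhat + q99 * sef, lty = 3, col = "red")
  graphics::lines(xs, yhat - q99 * sef, lty = 3, col = "red")
  graphics::abline(b[1] + (b[2] - 1) * mean(fit$x), 1, col = "blue")
  invisible(data.frame(x = xs, fit = yhat, se = sef))
}
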