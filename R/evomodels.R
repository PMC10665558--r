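# Multivariate Gaussian machinery for trait-evolution models.
#
# Under every model handled here the stacked trait vector is multivariate
# normal with covariance R (x) C(theta): R is the among-trait covariance,
# C(theta) the among-species covariance produced by transform_covariance().
# Missing entries are handled by deleting the corresponding rows/columns of
# the stacked covariance (exact for these Gaussian models).

# Profile log-likelihood of the Kronecker model for a fixed species
# covariance C. Complete data: closed-form ML of z0 and R. Missing data:
# numerical maximization over z0 and chol(R), started at complete-case
# estimates. Y is an n x p matrix with species in rows.
kron_profile <- function(C, Y) {
  n <- nrow(Y)
  p <- ncol(Y)
  if (!anyNA(Y)) {
    U <- chol(C)
    one_w <- whiten(U, matrix(1, n, 1))
    Yw <- whiten(U, Y)
    denom <- sum(one_w^2)
    z0 <- drop(crossprod(one_w, Yw)) / denom
    Rw <- Yw - one_w %*% rbind(z0)
    R <- crossprod(Rw) / n
    ldC <- 2 * sum(log(diag(U)))
    ldR <- determinant(R, logarithm = TRUE)$modulus
    if (!is.finite(ldR)) return(list(logLik = -Inf, z0 = z0, R = R))
    ll <- -0.5 * (n * p * log(2 * pi) + n * ldR + p * ldC + n * p)
    return(list(logLik = as.numeric(ll), z0 = z0, R = R))
  }
  # missing data: optimize over z0 (p) and log-chol(R) (p(p+1)/2)
  obs <- !is.na(Y)
  cc_R <- stats::cov(Y, use = "pairwise.complete.obs") / mean(diag(C))
  cc_R[!is.finite(cc_R)] <- 0
  # pairwise-complete covariances need not be PSD: floor the spectrum
  ed <- eigen((cc_R + t(cc_R)) / 2, symmetric = TRUE)
  ed$values <- pmax(ed$values, max(ed$values, 1e-4) * 1e-3)
  cc_R <- ed$vectors %*% (ed$values * t(ed$vectors))
  L0 <- t(chol(cc_R))
  start <- c(colMeans(Y, na.rm = TRUE),
             diag_log_chol(L0))
  nll <- function(par) {
    z0 <- par[seq_len(p)]
    L <- chol_from_par(par[-seq_len(p)], p)
    R <- L %*% t(L)
    V <- kronecker(R, C)            # trait-major blocks
    mu <- rep(z0, each = nrow(Y))
    keep <- as.vector(obs)
    yv <- as.vector(Y)[keep]
    Vk <- V[keep, keep, drop = FALSE]
    ll <- tryCatch(mvn_loglik(yv, mu[keep], Vk), error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  z0 <- opt$par[seq_len(p)]
  L <- chol_from_par(opt$par[-seq_len(p)], p)
  R <- L %*% t(L)
  names(z0) <- colnames(Y)
  dimnames(R) <- list(colnames(Y), colnames(Y))
  list(logLik = -opt$value, z0 = z0, R = R,
       convergence = opt$convergence)
}

# lower-triangular Cholesky <-> unconstrained parameters (log on diagonal)
diag_log_chol <- function(L) {
  p <- nrow(L)
  par <- c()
  for (j in seq_len(p)) {
    par <- c(par, log(L[j, j]), if (j < p) L[(j + 1):p, j])
  }
  par
}
chol_from_par <- function(par, p) {
  L <- matrix(0, p, p)
  k <- 1
  for (j in seq_len(p)) {
    L[j, j] <- exp(par[k])
    k <- k + 1
    if (j < p) {
      L[(j + 1):p, j] <- par[k:(k + p - j - 1)]
      k <- k + p - j
    }
  }
  L
}

#' Fit a trait-evolution model by maximum likelihood
#'
#' Fits Brownian motion (`bm`), the star-phylogeny model (`bm_star`,
#' i.e. Pagel's lambda fixed at 0), free Pagel's `lambda`, scalar-alpha
#' Ornstein-Uhlenbeck (`ou`), per-trait-alpha OU with a diagonal trait
#' covariance (`ou_diag`), or Early Burst (`eb`) to one or more continuous
#' traits (typically log10 volumes) on a phylogeny. The variance convention
#' is ML (n-divisor) throughout, so AIC values are comparable across models.
#' Shape parameters are profiled on a grid plus local refinement
#' (tolerance 1e-8 on the log-likelihood).
#'
#' @param tree a `"phylo"` object.
#' @param traits species x trait matrix or data.frame with species rownames
#'   (or a named vector for a single trait). May contain `NA`s, which are
#'   removed by row-deletion on the stacked covariance.
#' @param model model tag.
#' @return an object of class `"evo_fit"`: model tag, `z0` (root states),
#'   `R` (trait covariance per unit branch length; `sigma2 = diag(R)`),
#'   shape parameter(s), `logLik`, `k` (free-parameter count, itemized in
#'   `k_detail`), `AIC = 2k - 2 logLik`, `n`, `p`.
#' @export
fit_model <- function(tree, traits,
                      model = c("bm", "bm_star", "lambda", "ou", "ou_diag", "eb")) {
  model <- match.arg(model)
  if (is.vector(traits) && !is.null(names(traits))) {
    traits <- matrix(traits, ncol = 1,
                     dimnames = list(names(traits), "trait"))
  }
  traits <- as.matrix(traits)
  if (is.null(rownames(traits))) stop("traits must have species rownames")
  keep <- rowSums(!is.na(traits)) > 0
  traits <- traits[keep, , drop = FALSE]
  if (nrow(traits) < 2) stop("need at least 2 species")
  tree <- match_tree_traits(tree, rownames(traits))
  C0 <- phylo_vcv(tree)
  Y <- traits[tree$tip.label, , drop = FALSE]
  C0 <- C0[rownames(Y), rownames(Y)]
  n <- nrow(Y)
  p <- ncol(Y)
  depth <- max(diag(C0))

  profile_for <- function(Ct) kron_profile(Ct, Y)

  if (model == "ou_diag") {
    # independent per-trait OU fits: diagonal R, per-trait alpha
    alphas <- numeric(p)
    z0 <- numeric(p)
    s2 <- numeric(p)
    ll <- 0
    for (j in seq_len(p)) {
      yj <- Y[, j]
      ok <- !is.na(yj)
      Cj <- C0[ok, ok, drop = FALSE]
      f <- function(la) {
        a <- exp(la)
        kron_profile(transform_covariance(Cj, "ou", list(alpha = a)),
                     cbind(yj[ok]))$logLik
      }
      grid <- log(10^seq(-4, 1, length.out = 8) / depth)
      vals <- vapply(grid, f, 0)
      best <- grid[which.max(vals)]
      op <- stats::optimize(f, lower = best - 1.5, upper = best + 1.5,
                            maximum = TRUE, tol = 1e-8)
      if (op$objective < max(vals)) {
        op <- list(maximum = best, objective = max(vals))
      }
      alphas[j] <- exp(op$maximum)
      pr <- kron_profile(
        transform_covariance(C0[ok, ok, drop = FALSE], "ou",
                             list(alpha = alphas[j])), cbind(yj[ok]))
      z0[j] <- pr$z0
      s2[j] <- pr$R[1, 1]
      ll <- ll + pr$logLik
    }
    k <- 3 * p
    fit <- list(model = model, z0 = stats::setNames(z0, colnames(Y)),
                R = diag(s2, p), sigma2 = stats::setNames(s2, colnames(Y)),
                shape = stats::setNames(alphas, colnames(Y)),
                logLik = ll, k = k,
                k_detail = c(root_states = p, rates = p, alphas = p),
                AIC = 2 * k - 2 * ll, n = n, p = p, tree = tree)
    class(fit) <- "evo_fit"
    return(fit)
  }

  shape <- NULL
  if (model == "bm") {
    pr <- profile_for(C0)
  } else if (model == "bm_star") {
    pr <- profile_for(transform_covariance(C0, "star"))
  } else {
    # 1-D profile over the shape parameter
    if (model == "lambda") {
      f <- function(lam) profile_for(
        transform_covariance(C0, "lambda", list(lambda = lam)))$logLik
      grid <- c(0, 0.25, 0.5, 0.75, 1)
      vals <- vapply(grid, f, 0)
      op <- stats::optimize(f, lower = 0, upper = 1, maximum = TRUE,
                            tol = 1e-8)
      shape <- if (op$objective >= max(vals)) op$maximum else
        grid[which.max(vals)]
      pr <- profile_for(transform_covariance(C0, "lambda",
                                             list(lambda = shape)))
      names(shape) <- "lambda"
    } else if (model == "ou") {
      f <- function(la) profile_for(
        transform_covariance(C0, "ou", list(alpha = exp(la))))$logLik
      grid <- log(10^seq(-4, 1, length.out = 8) / depth)
      vals <- vapply(grid, f, 0)
      best <- grid[which.max(vals)]
      op <- stats::optimize(f, lower = best - 1.5, upper = best + 1.5,
                            maximum = TRUE, tol = 1e-8)
      la <- if (op$objective >= max(vals)) op$maximum else best
      shape <- stats::setNames(exp(la), "alpha")
      pr <- profile_for(transform_covariance(C0, "ou",
                                             list(alpha = shape[[1]])))
    } else { # eb
      f <- function(lr) profile_for(
        transform_covariance(C0, "eb", list(r = -exp(lr))))$logLik
      grid <- log(10^seq(-6, 0.5, length.out = 8) / depth)
      vals <- vapply(grid, f, 0)
      f0 <- profile_for(C0)$logLik   # r = 0 boundary (equals BM)
      best <- grid[which.max(vals)]
      op <- stats::optimize(f, lower = best - 1.5, upper = best + 1.5,
                            maximum = TRUE, tol = 1e-8)
      lr <- if (op$objective >= max(vals)) op$maximum else best
      if (f0 >= max(op$objective, max(vals))) {
        shape <- c(r = 0)
        pr <- profile_for(C0)
      } else {
        shape <- stats::setNames(-exp(lr), "r")
        pr <- profile_for(transform_covariance(C0, "eb",
                                               list(r = shape[[1]])))
      }
    }
  }
  n_shape <- length(shape)
  k <- p + p * (p + 1) / 2 + n_shape
  ll <- pr$logLik
  fit <- list(model = model,
              z0 = stats::setNames(as.numeric(pr$z0), colnames(Y)),
              R = pr$R, sigma2 = stats::setNames(diag(pr$R), colnames(Y)),
              shape = shape, logLik = ll, k = k,
              k_detail = c(root_states = p, R_entries = p * (p + 1) / 2,
                           shape = n_shape),
              AIC = 2 * k - 2 * ll, n = n, p = p,
              convergence = pr$convergence %||% 0, tree = tree)
  class(fit) <- "evo_fit"
  fit
}

#' @export
print.evo_fit <- function(x, ...) {
  cat("Trait-evolution model fit [", x$model, "]\n", sep = "")
  cat("  species:", x$n, " traits:", x$p, "\n")
  if (!is.null(x$shape)) {
    cat("  shape:", paste(names(x$shape), signif(x$shape, 4),
                          sep = " = ", collapse = ", "), "\n")
  }
  cat("  logLik:", format(x$logLik, digits = 8),
      " k:", x$k, " AIC:", format(x$AIC, digits = 8), "\n")
  invisible(x)
}

#' Rank model fits by AIC
#'
#' Sorts by AIC (lower is better) and labels support relative to the best
#' model: a difference below 4 is `comparable`, 4-7 `significantly less`
#' support, 7-10 `weak`, above 10 `none`.
#'
#' @param fits list of `"evo_fit"` objects on identical data.
#' @return data.frame: model, logLik, k, AIC, delta_aic, support.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  np <- vapply(fits, function(f) c(f$n, f$p), numeric(2))
  if (any(np[1, ] != np[1, 1]) || any(np[2, ] != np[2, 1])) {
    stop("fits are not on identical data (n or p differ)")
  }
  tab <- data.frame(
    model = vapply(fits, function(f) f$model, ""),
    logLik = vapply(fits, function(f) f$logLik, 0),
    k = vapply(fits, function(f) f$k, 0),
    AIC = vapply(fits, function(f) f$AIC, 0),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AIC), ]
  tab$delta_aic <- tab$AIC - tab$AIC[1]
  tab$support <- cut(tab$delta_aic, c(-Inf, 4, 7, 10, Inf), right = FALSE,
                     labels = c("comparable", "significantly less",
                                "weak", "none"))
  # boundary conventions: delta in [4,7] is "significantly less", (7,10] weak
  tab$support <- as.character(tab$support)
  tab$support[tab$delta_aic == 7] <- "significantly less"
  tab$support[tab$delta_aic == 10] <- "weak"
  rownames(tab) <- NULL
  tab
}

#' Chi-squared test of full vs absent phylogenetic signal
#'
#' Compares the Brownian model with Pagel's lambda fixed at 1 against the
#' star-phylogeny model (lambda = 0). Both have the same free-parameter
#' count; the statistic is `2 (lnL_lambda1 - lnL_lambda0)` and the p-value
#' uses a chi-squared reference with `df = 1` (a convention, flagged in the
#' output; the models are not nested in the usual sense). Positive
#' statistics favor full phylogenetic signal.
#'
#' @param fit_lambda1 `"evo_fit"` under `bm` (lambda = 1).
#' @param fit_lambda0 `"evo_fit"` under `bm_star` (lambda = 0).
#' @return list with `statistic`, `df`, `p_value`, `note`.
#' @export
lrt_fixed_lambda <- function(fit_lambda1, fit_lambda0) {
  if (fit_lambda1$n != fit_lambda0$n || fit_lambda1$p != fit_lambda0$p) {
    stop("fits are not on the same data")
  }
  if (fit_lambda1$k != fit_lambda0$k) {
    stop("fits do not have equal parameter counts")
  }
  stat <- 2 * (fit_lambda1$logLik - fit_lambda0$logLik)
  p <- stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
  list(statistic = stat, df = 1, p_value = p,
       note = paste("df = 1 by convention; the two fixed-lambda models",
                    "have equal parameter counts"))
}

#' Ancestral character estimation under Brownian motion
#'
#' GLS/ML joint reconstruction of internal-node states for one trait under
#' BM (lambda = 1). With `C` the tip covariance, `c_a` the covariances
#' between node `a` and the tips (shared root-to-MRCA path lengths) and
#' `z0` the GLS root state, the estimate is
#' `z_a = z0 + c_a' C^-1 (y - z0)` with conditional variance
#' `sigma2 * (t_a - c_a' C^-1 c_a + (1 - c_a' C^-1 1)^2 / (1' C^-1 1))`
#' (the last term propagates root-state uncertainty). 95% CI is the
#' estimate +/- 1.96 SD; on back-transform to mm3 the log-scale CI is
#' exponentiated.
#'
#' @param tree a `"phylo"` object.
#' @param trait named numeric vector (one value per tip; log10 scale in the
#'   standard workflow). Tips without data must have been excluded from the
#'   supplied `fit` as well.
#' @param fit optional `"evo_fit"` from [fit_model()] with `model = "bm"`;
#'   fitted on the fly when omitted. Its `sigma2` scales the CIs.
#' @return object of class `"ace_bm"`: data.frame with `node` (ape ids,
#'   root first), `estimate`, `variance`, `ci_lower`, `ci_upper`, plus
#'   attributes `sigma2` and `root`.
#' @export
ace_bm <- function(tree, trait, fit = NULL) {
  stopifnot(!is.null(names(trait)))
  trait <- trait[!is.na(trait)]
  tree <- match_tree_traits(tree, names(trait))
  if (is.null(fit)) {
    fit <- fit_model(tree, trait, "bm")
  } else {
    if (fit$model != "bm") stop("ace_bm requires a BM (lambda = 1) fit")
    if (fit$n != length(trait)) {
      stop("trait tips and model fit cover different species sets")
    }
  }
  sigma2 <- unname(fit$sigma2[1])
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  C <- phylo_vcv(tree)
  y <- trait[rownames(C)]
  depths <- node_depths(tree)
  # ancestors of each node (including itself), root = n + 1
  parent <- integer(n + m)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n + 1L
  anc_path <- function(v) {
    path <- v
    while (v != root) {
      v <- parent[v]
      path <- c(path, v)
    }
    path
  }
  # descendant tip sets
  desc <- vector("list", n + m)
  for (i in seq_len(n)) desc[[i]] <- i
  for (e in ape::postorder(tree)) {
    desc[[tree$edge[e, 1]]] <- c(desc[[tree$edge[e, 1]]],
                                 desc[[tree$edge[e, 2]]])
  }
  tip_anc <- lapply(seq_len(n), anc_path)
  U <- chol(C)
  one <- matrix(1, n, 1)
  one_w <- whiten(U, one)
  y_w <- whiten(U, matrix(y, ncol = 1))
  denom <- sum(one_w^2)
  z0 <- sum(one_w * y_w) / denom
  nodes <- root:(n + m)
  est <- numeric(m)
  va <- numeric(m)
  for (idx in seq_along(nodes)) {
    a <- nodes[idx]
    a_anc <- anc_path(a)
    a_desc <- desc[[a]]
    ca <- vapply(seq_len(n), function(i) {
      if (i %in% a_desc) return(depths[a])
      common <- intersect(tip_anc[[i]], a_anc)
      max(depths[common])
    }, 0)
    ca_w <- whiten(U, matrix(ca, ncol = 1))
    est[idx] <- z0 + sum(ca_w * (y_w - z0 * one_w))
    va[idx] <- sigma2 * (depths[a] - sum(ca_w^2) +
                           (1 - sum(ca_w * one_w))^2 / denom)
    va[idx] <- max(va[idx], 0)
  }
  hw <- 1.96 * sqrt(va)
  out <- data.frame(node = nodes, estimate = est, variance = va,
                    ci_lower = est - hw, ci_upper = est + hw)
  attr(out, "sigma2") <- sigma2
  attr(out, "root") <- est[1]
  class(out) <- c("ace_bm", "data.frame")
  out
}

#' Back-transform a log10-scale ancestral reconstruction to volumes
#'
#' Exponentiates the estimates and CI bounds (`10^x`), the convention for a
#' log10-trait workflow; the CI stays a log-scale (hence asymmetric) CI.
#'
#' @param ace an `"ace_bm"` result on the log10 scale.
#' @return data.frame with node, volume and exponentiated CI bounds.
#' @export
ace_backtransform <- function(ace) {
  data.frame(node = ace$node, volume = 10^ace$estimate,
             ci_lower = 10^ace$ci_lower, ci_upper = 10^ace$ci_upper)
}
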