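test_that("BM fit matches closed forms and the dense Gaussian oracle", {
  # 2-tip closed form: root is the GLS mean, rate the n-divisor ML estimate
  f2 <- fit_model(parse_newick("(A:1,B:1);"), c(A = 0, B = 2), "bm")
  expect_equal(unname(f2$z0), 1)
  expect_equal(unname(f2$sigma2), 1)
  expect_equal(f2$AIC, 2 * f2$k - 2 * f2$logLik)

  set.seed(11)
  for (i in 1:12) {
    tr <- rand_coal_tree(sample(4:8, 1))
    n <- ape::Ntip(tr)
    p <- sample(1:2, 1)
    Y <- matrix(rnorm(n * p, 3), n, p,
                dimnames = list(tr$tip.label, paste0("t", 1:p)))
    fit <- fit_model(tr, Y, "bm")
    C <- phylo_vcv(tr)[rownames(Y), rownames(Y)]
    V <- kronecker(fit$R, C)
    ll <- oracle_mvn_ll(as.vector(Y), rep(fit$z0, each = n), V)
    expect_equal(fit$logLik, as.numeric(ll), tolerance = 1e-6)
    expect_equal(fit$AIC, 2 * fit$k - 2 * fit$logLik)
  }
})

test_that("missing entries are handled by stacked-covariance row deletion", {
  set.seed(21)
  tr <- rand_coal_tree(7)
  Y <- matrix(rnorm(14, 3), 7, 2,
              dimnames = list(tr$tip.label, c("a", "b")))
  Yna <- Y
  Yna[2, 1] <- NA
  fit <- fit_model(tr, Yna, "bm")
  # oracle: maximize the row-deleted dense Gaussian likelihood numerically
  C <- phylo_vcv(tr)[rownames(Y), rownames(Y)]
  keep <- !is.na(as.vector(Yna))
  yv <- as.vector(Yna)[keep]
  nll <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 30)) return(1e10)
    R <- matrix(c(exp(par[3]), par[5], par[5], exp(par[4])), 2)
    R <- R %*% R
    V <- kronecker(R, C)[keep, keep]
    mu <- rep(par[1:2], each = 7)[keep]
    if (any(!is.finite(V))) return(1e10)
    ed <- eigen(V, symmetric = TRUE)
    if (min(ed$values) <= 0) return(1e10)
    0.5 * (length(yv) * log(2 * pi) + sum(log(ed$values)) +
             sum((t(ed$vectors) %*% (yv - mu))^2 / ed$values))
  }
  # the reported likelihood must equal the dense row-deleted density at the
  # fitted parameters ...
  Rhat <- fit$R
  Vhat <- kronecker(Rhat, C)[keep, keep]
  muhat <- rep(fit$z0, each = 7)[keep]
  expect_equal(fit$logLik,
               as.numeric(oracle_mvn_ll(yv, muhat, Vhat)),
               tolerance = 1e-6)
  # ... and be at least as good as an independent numerical maximization
  op <- optim(c(3, 3, log(0.5), log(0.5), 0), nll, method = "BFGS",
              control = list(maxit = 1000, reltol = 1e-12))
  expect_gte(fit$logLik, -op$value - 1e-4)
})

test_that("lambda and star structures coincide when there is no signal", {
  set.seed(5)
  star <- ape::stree(8, "star")
  star$edge.length <- rep(10, 8)
  star$tip.label <- paste0("sp", 1:8)
  x <- setNames(rnorm(8, 2), star$tip.label)
  f1 <- fit_model(star, x, "bm")
  f0 <- fit_model(star, x, "bm_star")
  expect_equal(f1$logLik, f0$logLik, tolerance = 1e-10)
})

test_that("BM rate is recovered from simulated data at study scale", {
  tr <- fixture_tree()
  s2 <- replicate(300, {
    d <- simulate_allometric_traits(tr, sigma2_x = 0.05, sigma2_e = 0,
                                    seed = sample.int(1e6, 1))
    fit_model(tr, setNames(d$log10_x, d$species), "bm")$sigma2[[1]]
  })
  expect_lt(abs(median(s2) - 0.05) / 0.05, 0.10)
})

test_that("AIC ranking labels support classes by the 4/7/10 thresholds", {
  mk <- function(model, aic) {
    structure(list(model = model, logLik = -aic / 2, k = 0, AIC = aic,
                   n = 34, p = 3), class = "evo_fit")
  }
  tab <- compare_models(list(mk("bm", 6209.62), mk("eb", 6216.25)))
  expect_equal(tab$delta_aic[2], 6.63)
  expect_equal(tab$support[2], "significantly less")
  tab2 <- compare_models(list(mk("bm", -19.13), mk("ou_diag", -16.03)))
  expect_equal(tab2$delta_aic[2], 3.10)
  expect_equal(tab2$support[2], "comparable")
  tab3 <- compare_models(list(mk("bm", 100), mk("eb", 100), mk("ou", 111)))
  expect_equal(tab3$delta_aic[2], 0)
  expect_equal(tab3$support[2], "comparable")
  expect_equal(tab3$support[3], "none")
})

test_that("fixed-lambda chi-squared test favors the generating structure", {
  tr <- fixture_tree()
  # identical likelihoods give statistic 0, p = 1
  x <- setNames(rnorm(34), tr$tip.label)
  f <- fit_model(tr, x, "bm")
  l0 <- lrt_fixed_lambda(f, f)
  expect_equal(l0$statistic, 0)
  expect_equal(l0$p_value, 1)
  expect_equal(l0$df, 1)

  set.seed(31)
  stats_bm <- replicate(150, {
    d <- simulate_allometric_traits(tr, sigma2_x = 0.05, sigma2_e = 0,
                                    seed = sample.int(1e6, 1))
    x <- setNames(d$log10_x, d$species)
    lrt_fixed_lambda(fit_model(tr, x, "bm"),
                     fit_model(tr, x, "bm_star"))$statistic
  })
  expect_gte(mean(stats_bm > 0), 0.95)

  stats_star <- replicate(150, {
    d <- simulate_allometric_traits(tr, sigma2_x = 0.05, sigma2_e = 0,
                                    lambda = 0, seed = sample.int(1e6, 1))
    x <- setNames(d$log10_x, d$species)
    lrt_fixed_lambda(fit_model(tr, x, "bm"),
                     fit_model(tr, x, "bm_star"))$statistic
  })
  expect_lt(mean(stats_star), 0)
})

test_that("shape-parameter models nest BM correctly", {
  tr <- fixture_tree()
  d <- simulate_allometric_traits(tr, sigma2_x = 0.05, sigma2_e = 0,
                                  seed = 99)
  x <- setNames(d$log10_x, d$species)
  fb <- fit_model(tr, x, "bm")
  fl <- fit_model(tr, x, "lambda")
  fe <- fit_model(tr, x, "eb")
  fo <- fit_model(tr, x, "ou")
  # free-shape fits can only improve the likelihood
  expect_gte(fl$logLik + 1e-6, fb$logLik)
  expect_gte(fe$logLik + 1e-6, fb$logLik)
  # but pay an AIC penalty when BM generated the data
  expect_equal(fl$k, fb$k + 1)
  expect_true(all(c(fl$shape >= 0, fl$shape <= 1)))
  expect_lte(fe$shape[["r"]], 0)
  expect_gt(fo$shape[["alpha"]], 0)
})

test_that("ancestral estimates equal the GLS oracle and ape::ace", {
  # 2-tip closed form: inverse-branch-length weighting
  t2 <- parse_newick("(A:2,B:1);")
  a2 <- ace_bm(t2, c(A = 1, B = 4))
  expect_equal(a2$estimate[1], (1 / 2 + 4 / 1) / (1 / 2 + 1 / 1))

  # all tips equal -> flat reconstruction
  t4 <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  ac <- ace_bm(t4, c(A = 2, B = 2, C = 2, D = 2))
  expect_equal(ac$estimate, rep(2, 3))
  expect_equal(ac$variance, rep(0, 3), tolerance = 1e-12)

  set.seed(41)
  for (i in 1:8) {
    tr <- rand_coal_tree(sample(4:8, 1))
    x <- setNames(rnorm(ape::Ntip(tr), 3), tr$tip.label)
    fit <- fit_model(tr, x, "bm")
    mine <- ace_bm(tr, x, fit)
    orc <- oracle_ace(tr, x, fit$sigma2[[1]])
    expect_equal(mine$estimate, orc$estimate, tolerance = 1e-8)
    expect_equal(mine$variance, orc$variance, tolerance = 1e-8)
    ape_ace <- suppressWarnings(
      ape::ace(x, tr, type = "continuous", method = "REML"))
    expect_equal(mine$estimate, unname(ape_ace$ace), tolerance = 1e-4)
    # CI brackets the estimate
    expect_true(all(mine$ci_lower <= mine$estimate),
                all(mine$ci_upper >= mine$estimate))
  }
})

test_that("ACE root is invariant to tip ordering", {
  tr <- rand_coal_tree(8)
  set.seed(53)
  x <- setNames(rnorm(8, 3), tr$tip.label)
  a1 <- ace_bm(tr, x)
  a2 <- ace_bm(tr, x[sample(names(x))])
  expect_equal(a1$estimate[1], a2$estimate[1], tolerance = 1e-12)
})

test_that("log-scale CIs exponentiate on back-transform", {
  tr <- rand_coal_tree(6)
  set.seed(61)
  x <- setNames(rnorm(6, 3, 0.5), tr$tip.label)
  a <- ace_bm(tr, x)
  b <- ace_backtransform(a)
  expect_equal(b$volume, 10^a$estimate)
  expect_equal(b$ci_lower, 10^a$ci_lower)
})
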