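test_that("PGLS equals OLS under the star covariance", {
  set.seed(71)
  for (i in 1:30) {
    n <- sample(5:20, 1)
    tr <- rand_coal_tree(n)
    x <- setNames(rnorm(n), tr$tip.label)
    y <- setNames(1 + 0.8 * x + rnorm(n, sd = 0.3), tr$tip.label)
    fit <- pgls_fit(tr, x, y, cov_model = "star")
    # star covariance is diag(depth), proportional to I on an ultrametric
    # tree, so coefficients and SEs must be exactly OLS
    ols <- lm(y[fit$species] ~ x[fit$species])
    expect_equal(unname(fit$coefficients), unname(coef(ols)),
                 tolerance = 1e-10)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ols)))),
                 tolerance = 1e-10)
  }
})

test_that("PGLS matches the dense GLS oracle and nlme::gls", {
  tr <- parse_newick(paste0("(((A:2,B:2):3,(C:1,D:1):4):5,",
                            "(E:6,F:6):4);"))
  x <- c(A = 1.2, B = 0.8, C = 2.1, D = 1.9, E = 3.0, F = 2.7)
  y <- c(A = 1.0, B = 1.1, C = 2.4, D = 2.2, E = 3.3, F = 3.1)
  fit <- pgls_fit(tr, x, y)
  C <- phylo_vcv(tr)[fit$species, fit$species]
  orc <- oracle_gls(C, cbind(1, x[fit$species]), y[fit$species])
  expect_equal(unname(fit$coefficients), unname(orc$beta), tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(orc$se), tolerance = 1e-10)

  dd <- data.frame(x = x[fit$species], y = y[fit$species],
                   sp = fit$species)
  gf <- nlme::gls(y ~ x, data = dd,
                  correlation = ape::corBrownian(1, fit$tree, form = ~sp))
  expect_equal(unname(fit$coefficients), unname(coef(gf)), tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(gf)))),
               tolerance = 1e-8)

  # exact line: slope 2, intercept 0, vanishing residual variance
  y2 <- setNames(2 * x, names(x))
  f2 <- pgls_fit(tr, x, y2)
  expect_equal(unname(f2$coefficients), c(0, 2), tolerance = 1e-10)
  expect_lt(f2$sigma2, 1e-20)
  expect_error(pgls_fit(tr, setNames(rep(1, 6), names(x)), y), "singular")
})

test_that("confidence intervals nest and drive isometry calls", {
  tr <- fixture_tree()
  d <- simulate_allometric_traits(tr, slope = 1.3, seed = 17)
  fit <- pgls_fit(tr, setNames(d$log10_x, d$species),
                  setNames(d$log10_y, d$species))
  expect_true(fit$ci99["slope", 1] <= fit$ci95["slope", 1])
  expect_true(fit$ci99["slope", 2] >= fit$ci95["slope", 2])
  iso <- isometry_test(fit)
  expect_true(iso$call95 %in% c("isometric", "hyper-allometric",
                                "hypo-allometric"))
  # interval arithmetic cases
  f_hyper <- fit
  f_hyper$ci95[] <- c(0, 1.05, 1, 1.50)
  f_hyper$ci99[] <- c(0, 1.02, 1, 1.60)
  expect_equal(isometry_test(f_hyper)$call95, "hyper-allometric")
  f_iso <- fit
  f_iso$ci95[] <- c(0, 0.90, 1, 1.05)
  expect_equal(isometry_test(f_iso)$call95, "isometric")
  f_hypo <- fit
  f_hypo$ci95[] <- c(0, 0.80, 1, 0.95)
  expect_equal(isometry_test(f_hypo)$call95, "hypo-allometric")
})

test_that("slope CI coverage is nominal under the generating model", {
  tr <- fixture_tree()
  cover <- replicate(400, {
    d <- simulate_allometric_traits(tr, slope = 1, seed = sample.int(1e6, 1))
    ci <- pgls_fit(tr, setNames(d$log10_x, d$species),
                   setNames(d$log10_y, d$species))$ci95["slope", ]
    ci[1] <= 1 && 1 <= ci[2]
  })
  expect_gte(mean(cover), 0.91)
  expect_lte(mean(cover), 0.99)
})

test_that("pANCOVA detects injected shifts and stays flat under the null", {
  tr <- fixture_tree()
  # cercopithecoid clade (10 tips): the grouping used for power checks
  clade <- c("Colobus_polykomos", "Trachypithecus_germaini",
             "Semnopithecus_entellus", "Macaca_mulatta",
             "Macaca_fascicularis", "Papio_hamadryas",
             "Lophocebus_albigena", "Cercocebus_atys",
             "Chlorocebus_aethiops", "Cercopithecus_cephus")
  # identical generating line in both groups, vary = both -> tiny F
  d0 <- simulate_allometric_traits(tr, sigma2_e = 0, seed = 5)
  g <- setNames(ifelse(d0$species %in% clade, "in", "out"), d0$species)
  t0 <- pancova(tr, setNames(d0$log10_x, d0$species),
                setNames(d0$log10_y, d0$species), g, vary = "both")
  expect_lt(t0$F, 1e-10)

  # slope shifts are well identified: delta_b = 0.2 detected almost always
  set.seed(83)
  p_slope <- replicate(120, {
    d <- simulate_allometric_traits(tr, seed = sample.int(1e6, 1))
    d <- inject_grade_shift(d, clade, delta_b = 0.2)
    pancova(tr, setNames(d$log10_x, d$species),
            setNames(d$log10_y, d$species), g, vary = "slope")$p_value
  })
  expect_gte(mean(p_slope < 0.05), 0.70)

  # intercept shifts are weakly identified for a monophyletic clade (its
  # shared Brownian drift mimics a grade shift): power at delta_a = 0.3 sits
  # near 0.5 under study-calibrated noise, far above the 5% null rate
  p_int <- replicate(120, {
    d <- simulate_allometric_traits(tr, seed = sample.int(1e6, 1))
    d <- inject_grade_shift(d, clade, delta_a = 0.3)
    pancova(tr, setNames(d$log10_x, d$species),
            setNames(d$log10_y, d$species), g, vary = "intercept")$p_value
  })
  expect_gte(mean(p_int < 0.05), 0.35)

  expect_error(pancova(tr, setNames(d0$log10_x, d0$species),
                       setNames(d0$log10_y, d0$species),
                       setNames(rep("a", 34), d0$species)),
               "two levels")
})

test_that("likelihood R-squared and Fisher Z behave at the boundaries", {
  tr <- fixture_tree()
  d <- simulate_allometric_traits(tr, seed = 29)
  x <- setNames(d$log10_x, d$species)
  y <- setNames(d$log10_y, d$species)
  fit <- pgls_fit(tr, x, y)
  expect_gte(fit$r2_lik, 0)
  expect_lte(fit$r2_lik, 1)
  # model identical to null: regress on pure noise predictor
  set.seed(97)
  # equal r, equal n -> Z = 0, p = 1
  cmp0 <- fit_comparison(fit, fit, fit)
  expect_equal(cmp0$Z, 0)
  expect_equal(cmp0$p_value, 1)
  # arithmetic oracle: r1 = .9 (n=20), r2 = .5 (n=20)
  mk <- function(r2, n) structure(list(r2_lik = r2, n = n),
                                  class = "pgls_fit")
  cmp <- fit_comparison(mk(0.5, 34), mk(0.81, 20), mk(0.25, 20))
  expect_equal(cmp$Z, (atanh(0.9) - atanh(0.5)) / sqrt(2 / 17))
  expect_error(fit_comparison(mk(0.5, 34), mk(0.8, 3), mk(0.2, 20)),
               "refused")
})
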