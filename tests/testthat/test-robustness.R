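test_that("degenerate factor range reproduces the baseline in every replicate", {
  tr <- fixture_tree()
  d <- simulate_allometric_traits(tr, seed = 19)
  x <- setNames(d$log10_x, d$species)
  y <- setNames(d$log10_y, d$species)
  base <- pgls_fit(tr, x, y)
  rep1 <- shrinkage_simulation(tr, x, y, "within_brain", c(1, 1),
                               n_sims = 25, seed = 4)
  expect_true(all(rep1$replicates$slope == base$coefficients[["slope"]]))
  expect_true(all(rep1$replicates$intercept ==
                    base$coefficients[["intercept"]]))
})

test_that("shrinkage reports are bit-identical under the same seed", {
  tr <- fixture_tree()
  d <- simulate_allometric_traits(tr, seed = 19)
  x <- setNames(d$log10_x, d$species)
  y <- setNames(d$log10_y, d$species)
  r1 <- shrinkage_simulation(tr, x, y, "within_brain", c(0.91, 1.1),
                             n_sims = 50, seed = 123)
  r2 <- shrinkage_simulation(tr, x, y, "within_brain", c(0.91, 1.1),
                             n_sims = 50, seed = 123)
  expect_identical(r1$replicates, r2$replicates)
  expect_identical(r1$slope_quantiles, r2$slope_quantiles)
  r3 <- shrinkage_simulation(tr, x, y, "within_brain", c(0.91, 1.1),
                             n_sims = 50, seed = 124)
  expect_false(identical(r1$replicates, r3$replicates))
})

test_that("across-brain factors leave the slope expectation at baseline", {
  tr <- fixture_tree()
  d <- simulate_allometric_traits(tr, seed = 19)
  x <- setNames(d$log10_x, d$species)
  y <- setNames(d$log10_y, d$species)
  base <- pgls_fit(tr, x, y)$coefficients[["slope"]]
  rep_a <- shrinkage_simulation(tr, x, y, "across_brain", c(0.5, 2.0),
                                n_sims = 400, seed = 7)
  mc_se <- sd(rep_a$replicates$slope) / sqrt(400)
  expect_lt(abs(mean(rep_a$replicates$slope) - base), 4 * mc_se + 1e-6)
})

test_that("within-brain perturbation of isometric data brackets slope 1", {
  tr <- fixture_tree()
  # exactly isometric data: the baseline slope is 1, so the factor noise
  # spreads replicates symmetrically around it
  d <- simulate_allometric_traits(tr, slope = 1, sigma2_e = 0, seed = 77)
  rep_w <- shrinkage_simulation(tr, setNames(d$log10_x, d$species),
                                setNames(d$log10_y, d$species),
                                "within_brain", c(0.91, 1.1),
                                n_sims = 300, seed = 8)
  expect_lt(rep_w$slope_quantiles[["q2.5"]], 1)
  expect_gt(rep_w$slope_quantiles[["q97.5"]], 1)
})

test_that("narrowing the factor range shrinks the slope spread monotonically", {
  tr <- fixture_tree()
  d <- simulate_allometric_traits(tr, seed = 19)
  x <- setNames(d$log10_x, d$species)
  y <- setNames(d$log10_y, d$species)
  ranges <- list(c(0.5, 2), c(0.67, 1.5), c(0.8, 1.25), c(0.91, 1.1),
                 c(0.97, 1.03))
  iqrs <- vapply(ranges, function(fr) {
    r <- shrinkage_simulation(tr, x, y, "within_brain", fr,
                              n_sims = 200, seed = 11)
    IQR(r$replicates$slope)
  }, 0)
  expect_true(all(diff(iqrs) < 0))
})

test_that("subset comparison refits both sides and refuses degenerate masks", {
  tr <- fixture_tree()
  d <- simulate_allometric_traits(tr, seed = 33)
  x <- setNames(d$log10_x, d$species)
  y <- setNames(d$log10_y, d$species)
  mask <- setNames(seq_along(x) <= 20, names(x))
  sc <- suppressWarnings(subset_compare(tr, x, y, mask, label = "museum"))
  expect_equal(sc$fit_in$n, 20)
  expect_equal(sc$fit_out$n, 14)
  expect_s3_class(sc$test, "grade_shift_test")
  all_in <- setNames(rep(TRUE, 34), names(x))
  expect_error(subset_compare(tr, x, y, all_in), "fewer than 3")

  # homogeneous data: grouping should rarely look significant
  set.seed(13)
  pvals <- replicate(60, {
    dd <- simulate_allometric_traits(tr, seed = sample.int(1e6, 1))
    m <- setNames(sample(c(TRUE, FALSE), 34, replace = TRUE,
                         prob = c(0.6, 0.4)), dd$species)
    if (sum(m) < 3 || sum(!m) < 3) return(NA_real_)
    suppressWarnings(
      subset_compare(tr, setNames(dd$log10_x, dd$species),
                     setNames(dd$log10_y, dd$species), m))$test$p_value
  })
  expect_gte(mean(pvals >= 0.05, na.rm = TRUE), 0.85)
})

test_that("literature filter excludes exactly the factor-2 violations", {
  traits <- data.frame(
    species = c("a", "b", "c", "d", "e"),
    cerebellum_mm3 = c(100, 201, 49, 100, 100),
    cerebrum_mm3 = c(1000, 1000, 1000, 2010, 1000))
  ref <- data.frame(
    species = c("a", "b", "c", "d", "e"),
    trait = c("cerebellum_mm3", "cerebellum_mm3", "cerebellum_mm3",
              "cerebrum_mm3", "cerebrum_mm3"),
    reference_mm3 = c(100, 100, 100, 1000, 1000))
  out <- literature_outlier_filter(traits, ref, factor = 2)
  expect_equal(nrow(out$exclusions), 3)
  expect_setequal(out$exclusions$species, c("b", "c", "d"))
  expect_true(is.na(out$filtered$cerebellum_mm3[2]))
  # boundary: exactly 2x is retained
  out2 <- literature_outlier_filter(
    data.frame(species = "a", cerebellum_mm3 = 200),
    data.frame(species = "a", trait = "cerebellum_mm3",
               reference_mm3 = 100))
  expect_equal(nrow(out2$exclusions), 0)
  # exclusion log round-trips: reapplying reproduces the filtered table
  redo <- traits
  for (i in seq_len(nrow(out$exclusions))) {
    redo[[out$exclusions$trait[i]]][out$exclusions$row[i]] <- NA
  }
  expect_identical(redo, out$filtered)
})
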