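# Measurement-error robustness battery: shrinkage simulations,
# provenance-subset comparisons, literature-based outlier exclusion.

#' Shrinkage / variability simulation for a PGLS regression
#'
#' Reruns the PGLS of `y` on `x` on `n_sims` perturbed datasets. In
#' `within_brain` mode each species' response trait is multiplied by an
#' independent random factor (emulating differential shrinkage between the
#' two regions of one brain); in `across_brain` mode both traits of a
#' species are multiplied by one shared factor (whole-specimen size error).
#' Factors are drawn per species, log-uniform on `factor_range` by default
#' (one global factor would cancel on a log-log regression and cannot
#' produce any slope spread). Traits are supplied on the log10 scale, so a
#' factor `f` adds `log10(f)`.
#'
#' @param tree a `"phylo"` object.
#' @param x,y named log10 trait vectors (the perturbed trait is `y`,
#'   cerebellar volume in the standard analysis).
#' @param mode `"within_brain"` or `"across_brain"`.
#' @param factor_range length-2 numeric `(lo, hi)`, both positive.
#' @param n_sims number of simulated datasets (study setting: 10000).
#' @param seed RNG seed (required: reports must be reproducible).
#' @param distribution `"loguniform"` (default) or `"uniform"` factor draw.
#' @param cov_model,params covariance transform, as in [pgls_fit()].
#' @return object of class `"robustness_report"`: per-replicate slopes,
#'   intercepts and 95% isometry calls; slope quantiles (2.5/50/97.5%);
#'   fraction of replicates per isometry class; the unperturbed baseline
#'   fit; and a config echo.
#' @export
shrinkage_simulation <- function(tree, x, y,
                                 mode = c("within_brain", "across_brain"),
                                 factor_range = c(0.91, 1.1),
                                 n_sims = 10000, seed,
                                 distribution = c("loguniform", "uniform"),
                                 cov_model = "bm", params = list()) {
  mode <- match.arg(mode)
  distribution <- match.arg(distribution)
  if (missing(seed)) stop("seed is required")
  if (n_sims < 1) stop("n_sims must be >= 1")
  lo <- factor_range[1]
  hi <- factor_range[2]
  if (!(lo > 0 && hi > 0 && lo <= hi)) {
    stop("factor_range must satisfy 0 < lo <= hi")
  }
  baseline <- pgls_fit(tree, x, y, cov_model, params)
  ord <- baseline$species
  tree_m <- baseline$tree
  C <- transform_covariance(phylo_vcv(tree_m), cov_model, params)
  U <- chol(C)
  n <- length(ord)
  xo <- x[ord]
  yo <- y[ord]
  one_w <- whiten(U, matrix(1, n, 1))
  set.seed(seed)
  draw <- function() {
    if (lo == hi) return(rep(lo, n))
    if (distribution == "loguniform") exp(stats::runif(n, log(lo), log(hi)))
    else stats::runif(n, lo, hi)
  }
  slope <- intercept <- numeric(n_sims)
  call95 <- character(n_sims)
  for (s in seq_len(n_sims)) {
    f <- log10(draw())
    if (mode == "within_brain") {
      ys <- yo + f
      xs <- xo
    } else {
      ys <- yo + f
      xs <- xo + f
    }
    Xw <- whiten(U, cbind(1, xs))
    yw <- whiten(U, ys)
    XtXi <- solve(crossprod(Xw))
    beta <- drop(XtXi %*% crossprod(Xw, yw))
    rss <- sum((yw - Xw %*% beta)^2)
    se_b <- sqrt(rss / (n - 2) * XtXi[2, 2])
    q <- stats::qt(0.975, n - 2)
    ci <- beta[2] + c(-1, 1) * q * se_b
    slope[s] <- beta[2]
    intercept[s] <- beta[1]
    call95[s] <- if (1 < ci[1]) "hyper-allometric"
    else if (1 > ci[2]) "hypo-allometric" else "isometric"
  }
  qs <- stats::quantile(slope, c(0.025, 0.5, 0.975), names = FALSE)
  out <- list(
    replicates = data.frame(slope = slope, intercept = intercept,
                            isometry95 = call95),
    slope_quantiles = stats::setNames(qs, c("q2.5", "q50", "q97.5")),
    isometry_fractions = c(
      hypo = mean(call95 == "hypo-allometric"),
      isometric = mean(call95 == "isometric"),
      hyper = mean(call95 == "hyper-allometric")),
    baseline = baseline,
    config = list(mode = mode, factor_range = c(lo, hi), n_sims = n_sims,
                  seed = seed, distribution = distribution,
                  cov_model = cov_model))
  class(out) <- "robustness_report"
  out
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("Shrinkage simulation [", x$config$mode, "], factors ",
      x$config$factor_range[1], "-", x$config$factor_range[2], ", ",
      x$config$n_sims, " replicates\n", sep = "")
  cat("  slope 2.5/50/97.5%:",
      paste(signif(x$slope_quantiles, 4), collapse = " / "), "\n")
  cat("  isometry calls:",
      paste(names(x$isometry_fractions),
            signif(x$isometry_fractions, 3), sep = "=", collapse = "  "),
      "\n")
  invisible(x)
}

#' Compare PGLS fits inside and outside a data subset
#'
#' Splits the species into a subset (e.g. one museum provenance) and its
#' complement, refits the PGLS in each (trees pruned automatically), and
#' tests the species-level grouping with a phylogenetic ANCOVA.
#'
#' @param tree a `"phylo"` object.
#' @param x,y named log10 trait vectors.
#' @param subset_mask named logical: `TRUE` for subset membership.
#' @param label subset label used in the output.
#' @param vary pANCOVA component to vary (default `"both"`).
#' @return list with `fit_in`, `fit_out`, `test` (a
#'   `"grade_shift_test"`) and `label`.
#' @export
subset_compare <- function(tree, x, y, subset_mask, label = "subset",
                           vary = "both") {
  stopifnot(!is.null(names(subset_mask)), is.logical(subset_mask))
  common <- intersect(names(x)[!is.na(x)], names(y)[!is.na(y)])
  m <- subset_mask[common]
  if (anyNA(m)) {
    stop("subset_mask does not cover species: ",
         paste(common[is.na(m)], collapse = ", "))
  }
  sp_in <- common[m]
  sp_out <- common[!m]
  if (length(sp_out) < 3) {
    stop("complement of '", label, "' leaves fewer than 3 species; ",
         "refusing to fit")
  }
  if (length(sp_in) < 3) {
    stop("subset '", label, "' has fewer than 3 species; refusing to fit")
  }
  fit_in <- pgls_fit(tree, x[sp_in], y[sp_in])
  fit_out <- pgls_fit(tree, x[sp_out], y[sp_out])
  groups <- stats::setNames(ifelse(m, label, paste0("non-", label)), common)
  test <- pancova(tree, x[common], y[common], groups, vary = vary)
  list(fit_in = fit_in, fit_out = fit_out, test = test, label = label)
}

#' Exclude observations that contradict literature reference volumes
#'
#' An observation is excluded iff it differs from the reference by more than
#' `factor` in either direction (`value > factor * ref` or
#' `value < ref / factor`). Every exclusion is logged with both values, and
#' the log round-trips: applying it to the original table reproduces the
#' filtered table.
#'
#' @param traits specimen or species table with `species` and trait columns.
#' @param reference long-format reference table: `species`, `trait`,
#'   `reference_mm3`.
#' @param factor exclusion factor (default 2).
#' @return list with `filtered` (table with violating cells set `NA`) and
#'   `exclusions` (log of species, trait, value, reference).
#' @export
literature_outlier_filter <- function(traits, reference, factor = 2.0) {
  stopifnot(all(c("species", "trait", "reference_mm3") %in% names(reference)),
            factor > 0)
  filtered <- traits
  logs <- list()
  for (i in seq_len(nrow(reference))) {
    sp <- reference$species[i]
    tc <- reference$trait[i]
    ref <- reference$reference_mm3[i]
    if (!tc %in% names(filtered)) next
    rows <- which(normalize_species(filtered$species) == normalize_species(sp))
    for (r in rows) {
      v <- filtered[[tc]][r]
      if (is.na(v)) next
      if (v > factor * ref || v < ref / factor) {
        logs[[length(logs) + 1]] <- data.frame(
          row = r, species = filtered$species[r], trait = tc,
          value = v, reference_mm3 = ref, factor = factor,
          stringsAsFactors = FALSE)
        filtered[[tc]][r] <- NA_real_
      }
    }
  }
  list(filtered = filtered,
       exclusions = if (length(logs)) do.call(rbind, logs) else
         data.frame(row = integer(), species = character(),
                    trait = character(), value = numeric(),
                    reference_mm3 = numeric(), factor = numeric()))
}
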