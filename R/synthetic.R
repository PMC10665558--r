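# Synthetic-data generator: pure-birth trees, Brownian allometric traits,
# intraspecific specimen replicates, grade-shift injection. Every stochastic
# call requires an explicit seed so reports are reproducible bit-for-bit.

#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Forward simulation: the root splits at time 0 into two lineages; with `k`
#' lineages the next split occurs after an Exponential(`k * birth_rate`)
#' wait on a uniformly chosen lineage, until `n_tips` lineages exist, plus a
#' final Exponential(`n_tips * birth_rate`) hang time. Expected depth is
#' `sum_{k=2}^{n} 1 / (k * birth_rate)`. Tips are labelled `sp1..spN`.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per million years; the default 0.042
#'   gives an expected depth of ~74 My at 34 tips, the scale of a primate
#'   crown group.
#' @param seed RNG seed (required).
#' @return an ultrametric `"phylo"` object.
#' @export
simulate_tree <- function(n_tips, birth_rate = 0.042, seed) {
  stopifnot(n_tips >= 2, birth_rate > 0)
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  # lineage records: parent (temp id), start time; internal split log
  parent <- c(NA_integer_, 1L, 1L)      # temp id 1 = root
  height <- c(0, NA_real_, NA_real_)    # split height for internals
  active <- c(2L, 3L)
  t_now <- 0
  next_id <- 4L
  while (length(active) < n_tips) {
    k <- length(active)
    t_now <- t_now + stats::rexp(1, rate = k * birth_rate)
    i <- active[sample.int(k, 1)]
    height[i] <- t_now
    parent <- c(parent, i, i)
    height <- c(height, NA_real_, NA_real_)
    active <- c(setdiff(active, i), next_id, next_id + 1L)
    next_id <- next_id + 2L
  }
  t_end <- t_now + stats::rexp(1, rate = n_tips * birth_rate)
  is_tip <- is.na(height)
  height[is_tip] <- t_end
  m <- length(parent)
  # ape ids: tips 1..n in creation order, internals n+1.. in creation order
  ape_id <- integer(m)
  ape_id[is_tip] <- seq_len(n_tips)
  ape_id[!is_tip] <- n_tips + seq_len(sum(!is_tip))
  edge <- cbind(ape_id[parent[-1]], ape_id[-1])
  edge_length <- height[-1] - height[parent[-1]]
  tree <- list(edge = edge, edge.length = edge_length,
               Nnode = sum(!is_tip),
               tip.label = paste0("sp", seq_len(n_tips)))
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  validate_phylo(tree)
}

#' Simulate species traits coupled by a log-log allometry
#'
#' The predictor trait `x` evolves by Brownian motion (rate `sigma2_x`) on
#' the lambda-transformed tree from a root value; an independent Brownian
#' residual `e` (rate `sigma2_e`) is added to the allometric line:
#' `y = intercept + slope * x + e`. Both traits are on the log10 scale;
#' back-transformed mm3 columns are included. Defaults reproduce the scale
#' of the bundled study data (log10 cerebral volume root ~4, empirical BM
#' rates ~0.005 and ~0.0007 per My).
#'
#' @param tree a `"phylo"` object.
#' @param intercept,slope allometric line coefficients (log10 units).
#' @param sigma2_x,sigma2_e Brownian rates of predictor and residual
#'   (log10-units^2 per My).
#' @param lambda Pagel's lambda of the generating covariance in `[0, 1]`.
#' @param x_root root state of the predictor (log10 mm3).
#' @param residual_model `"bm"` (default): residuals evolve by Brownian
#'   motion on the same tree, which is what makes PGLS the correct
#'   estimator; `"iid"`: independent residuals with the same tip variance
#'   (`sigma2_e * depth`), useful to demonstrate PGLS/OLS divergence.
#' @param seed RNG seed (required).
#' @return data.frame: species, `log10_x`, `log10_y`, `x_mm3`, `y_mm3`.
#' @export
simulate_allometric_traits <- function(tree, intercept = 0, slope = 1,
                                       sigma2_x = 0.005, sigma2_e = 0.0007,
                                       lambda = 1, x_root = 4,
                                       residual_model = c("bm", "iid"),
                                       seed) {
  if (missing(seed)) stop("seed is required")
  residual_model <- match.arg(residual_model)
  stopifnot(sigma2_x > 0, sigma2_e >= 0, lambda >= 0, lambda <= 1)
  set.seed(seed)
  C <- transform_covariance(phylo_vcv(tree), "lambda", list(lambda = lambda))
  n <- nrow(C)
  Ux <- chol(sigma2_x * C)
  x <- x_root + drop(t(Ux) %*% stats::rnorm(n))
  e <- if (sigma2_e == 0) rep(0, n)
  else if (residual_model == "bm") drop(t(chol(sigma2_e * C)) %*% stats::rnorm(n))
  else stats::rnorm(n, sd = sqrt(sigma2_e * diag(C)))
  y <- intercept + slope * x + e
  data.frame(species = rownames(C), log10_x = x, log10_y = y,
             x_mm3 = 10^x, y_mm3 = 10^y,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Solve the lognormal scale s such that median(|exp(s Z) - 1|) = target,
# i.e. specimen = median * exp(s Z) has expected raw MAD% = 100 * target.
# P(|e^{sZ} - 1| <= t) = Phi(log(1 + t)/s) - Phi(log(1 - t)/s) for t < 1.
lognormal_scale_for_mad <- function(mad_frac) {
  if (mad_frac == 0) return(0)
  if (mad_frac >= 1) stop("MAD% must be below 100%")
  med_abs <- function(s) {
    f <- function(t) stats::pnorm(log1p(t) / s) -
      stats::pnorm(log1p(-t) / s) - 0.5
    stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  stats::uniroot(function(s) med_abs(s) - mad_frac,
                 c(1e-8, 5), tol = 1e-12)$root
}

#' Simulate intraspecific specimen replicates around species medians
#'
#' Specimen volumes are the species median times lognormal noise,
#' `exp(s Z)`, with the scale `s` calibrated numerically so the expected raw
#' MAD as a percentage of the median equals `mad_pct` (volumes stay
#' positive; the analysis log-transforms them).
#'
#' @param species_table data.frame with `species` and trait columns (mm3).
#' @param mad_pct named numeric: target MAD% per trait column (recycled to
#'   all traits if unnamed scalar).
#' @param n_per_species specimens per species.
#' @param seed RNG seed (required).
#' @param trait_cols trait columns to perturb.
#' @return specimen-level data.frame with `specimen_id`, `species` and the
#'   trait columns.
#' @export
simulate_specimens <- function(species_table, mad_pct, n_per_species, seed,
                               trait_cols = NULL) {
  if (missing(seed)) stop("seed is required")
  stopifnot(all(mad_pct >= 0), n_per_species >= 1)
  if (is.null(trait_cols)) {
    trait_cols <- intersect(TRAIT_COLUMNS, names(species_table))
  }
  if (is.null(names(mad_pct))) {
    mad_pct <- stats::setNames(rep(mad_pct[1], length(trait_cols)),
                               trait_cols)
  }
  set.seed(seed)
  scales <- vapply(trait_cols, function(tc)
    lognormal_scale_for_mad((mad_pct[[tc]] %||% 0) / 100), 0)
  rows <- lapply(seq_len(nrow(species_table)), function(i) {
    out <- data.frame(
      specimen_id = paste0(species_table$species[i], "_",
                           seq_len(n_per_species)),
      species = species_table$species[i], stringsAsFactors = FALSE)
    for (tc in trait_cols) {
      med <- species_table[[tc]][i]
      out[[tc]] <- if (is.na(med)) NA_real_ else
        med * exp(scales[tc] * stats::rnorm(n_per_species))
    }
    out
  })
  do.call(rbind, rows)
}

#' Inject a clade-specific grade shift into a trait table
#'
#' For clade members, the response is replaced by
#' `y + delta_a + delta_b * x` (log10 scale); other species are untouched.
#' Used to generate power-study datasets for the phylogenetic ANCOVA.
#'
#' @param trait_table data.frame from [simulate_allometric_traits()] (needs
#'   `species`, `log10_x`, `log10_y`).
#' @param clade_species character vector, a subset of the table's species.
#' @param delta_a intercept shift (log10 units).
#' @param delta_b slope shift.
#' @return the table with shifted `log10_y` (and `y_mm3` recomputed).
#' @export
inject_grade_shift <- function(trait_table, clade_species,
                               delta_a = 0, delta_b = 0) {
  miss <- setdiff(clade_species, trait_table$species)
  if (length(miss) > 0) {
    stop("clade species not in table: ", paste(miss, collapse = ", "))
  }
  sel <- trait_table$species %in% clade_species
  trait_table$log10_y[sel] <- trait_table$log10_y[sel] + delta_a +
    delta_b * trait_table$log10_x[sel]
  if ("y_mm3" %in% names(trait_table)) {
    trait_table$y_mm3 <- 10^trait_table$log10_y
  }
  trait_table
}
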