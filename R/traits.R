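TRAIT_COLUMNS <- c("cerebellum_mm3", "cerebrum_mm3", "ansiform_mm3")

#' Load a specimen/species trait table from CSV or TSV
#'
#' The file must have a header naming a `species` column and at least one
#' volume column. `#`-prefixed lines are treated as comments. A `unit` column
#' is honored: values are stored in mm3, with `cm3` rows converted
#' (`x 1000`). A `specimen_id` column, when present, must be unique.
#'
#' @param path path to a `.csv` or `.tsv`/`.txt` file.
#' @param trait_cols names of the volume columns to validate; defaults to any
#'   of `cerebellum_mm3`, `cerebrum_mm3`, `ansiform_mm3` present.
#' @return a `data.frame` of typed rows.
#' @export
load_trait_table <- function(path, trait_cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = TRUE)
  names(tab) <- tolower(names(tab))
  if (!"species" %in% names(tab)) {
    stop("load error: no 'species' column in ", path)
  }
  if (any(!nzchar(trimws(tab$species)) | is.na(tab$species))) {
    stop("load error: empty species name in row(s) ",
         paste(which(!nzchar(trimws(tab$species)) | is.na(tab$species)),
               collapse = ", "))
  }
  if (is.null(trait_cols)) trait_cols <- intersect(TRAIT_COLUMNS, names(tab))
  if (length(trait_cols) == 0) {
    stop("load error: no trait column found (expected one of ",
         paste(TRAIT_COLUMNS, collapse = ", "), ")")
  }
  if ("unit" %in% names(tab)) {
    cm3 <- tolower(trimws(tab$unit)) %in% c("cm3", "cm^3")
    for (tc in trait_cols) tab[[tc]][cm3] <- tab[[tc]][cm3] * 1000
    tab$unit <- NULL
  }
  for (tc in trait_cols) {
    bad <- which(!is.na(tab[[tc]]) & tab[[tc]] <= 0)
    if (length(bad) > 0) {
      stop("load error: non-positive ", tc, " in row(s) ",
           paste(bad, collapse = ", "))
    }
  }
  if ("specimen_id" %in% names(tab)) {
    dup <- which(duplicated(tab$specimen_id))
    if (length(dup) > 0) {
      stop("load error: duplicate specimen id in row(s) ",
           paste(dup, collapse = ", "))
    }
  }
  tab
}

#' Species-level medians, MADs and variability
#'
#' Per species and trait: specimen count, median volume, raw median absolute
#' deviation (no 1.4826 normal-consistency factor) and the MAD as a
#' percentage of the median. MAD% is reported only for species with at least
#' `min_n_for_variability` specimens; below that it is `NA` (a one- or
#' two-specimen MAD says nothing about intraspecific variability).
#'
#' @param table specimen table with a `species` column and trait columns.
#' @param trait_cols trait columns to summarize (default: the standard
#'   volume columns present).
#' @param min_n_for_variability minimum specimen count for MAD%.
#' @return long `data.frame`: species, trait, n, median, mad, mad_pct.
#' @export
summarize_species <- function(table, trait_cols = NULL,
                              min_n_for_variability = 4) {
  stopifnot(nrow(table) > 0, "species" %in% names(table))
  if (is.null(trait_cols)) trait_cols <- intersect(TRAIT_COLUMNS, names(table))
  out <- do.call(rbind, lapply(split(table, table$species), function(d) {
    do.call(rbind, lapply(trait_cols, function(tc) {
      v <- d[[tc]][!is.na(d[[tc]])]
      if (length(v) == 0) return(NULL)
      med <- stats::median(v)
      md <- stats::median(abs(v - med))
      data.frame(species = d$species[1], trait = tc, n = length(v),
                 median = med, mad = md,
                 mad_pct = if (length(v) >= min_n_for_variability)
                   100 * md / med else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out[order(out$species, out$trait), ]
}

#' Normality and boxplot-fence outlier screen
#'
#' For every species x trait with at least `min_n` specimens: a Shapiro-Wilk
#' normality p-value and flags for specimens outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`. Species with fewer specimens are skipped
#' with a message, never an error. Flagging is separate from exclusion:
#' downstream exclusion is the caller's decision.
#'
#' @param table specimen table.
#' @param trait_cols trait columns to screen.
#' @param min_n minimum specimens for screening (default 4).
#' @return list with `normality` (species, trait, n, shapiro_p) and
#'   `outliers` (one row per flagged specimen with the fence bounds).
#' @export
screen_outliers <- function(table, trait_cols = NULL, min_n = 4) {
  stopifnot(nrow(table) > 0, "species" %in% names(table))
  if (is.null(trait_cols)) trait_cols <- intersect(TRAIT_COLUMNS, names(table))
  norm <- list()
  outl <- list()
  for (sp in unique(table$species)) {
    d <- table[table$species == sp, , drop = FALSE]
    for (tc in trait_cols) {
      keep <- !is.na(d[[tc]])
      v <- d[[tc]][keep]
      if (length(v) < min_n) {
        if (length(v) > 0) {
          message("screen skipped for ", sp, " / ", tc,
                  " (n = ", length(v), " < ", min_n, ")")
        }
        next
      }
      p <- if (length(unique(v)) > 1) stats::shapiro.test(v)$p.value else NA_real_
      norm[[length(norm) + 1]] <- data.frame(
        species = sp, trait = tc, n = length(v), shapiro_p = p,
        stringsAsFactors = FALSE)
      q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      lo <- q[1] - 1.5 * iqr
      hi <- q[2] + 1.5 * iqr
      bad <- which(v < lo | v > hi)
      if (length(bad) > 0) {
        ids <- if ("specimen_id" %in% names(d)) d$specimen_id[keep][bad] else
          paste0(sp, "#", bad)
        outl[[length(outl) + 1]] <- data.frame(
          specimen_id = ids, species = sp, trait = tc, value = v[bad],
          lower = lo, upper = hi, stringsAsFactors = FALSE)
      }
    }
  }
  list(
    normality = if (length(norm)) do.call(rbind, norm) else
      data.frame(species = character(), trait = character(),
                 n = integer(), shapiro_p = numeric()),
    outliers = if (length(outl)) do.call(rbind, outl) else
      data.frame(specimen_id = character(), species = character(),
                 trait = character(), value = numeric(),
                 lower = numeric(), upper = numeric())
  )
}

#' Volume ratios between cerebello-cerebral components
#'
#' Computes `100 * cerebellum / cerebrum` and `100 * ansiform / cerebellum`
#' from species medians. Display columns are rounded to 2 decimals half away
#' from zero; the unrounded values are retained. When a specimen-level table
#' is supplied, the median of per-specimen ratios and its raw MAD are added
#' for species with multiple specimens (the convention used for
#' multi-specimen rows of the bundled study table).
#'
#' @param species_table data.frame with `species`, `cerebellum_mm3`,
#'   `cerebrum_mm3` and optionally `ansiform_mm3` (species medians).
#' @param specimens optional specimen-level table with the same columns.
#' @return data.frame of unrounded and display ratios per species.
#' @export
compute_ratios <- function(species_table, specimens = NULL) {
  stopifnot(all(c("species", "cerebellum_mm3", "cerebrum_mm3") %in%
                  names(species_table)))
  r1 <- 100 * species_table$cerebellum_mm3 / species_table$cerebrum_mm3
  r2 <- if ("ansiform_mm3" %in% names(species_table))
    100 * species_table$ansiform_mm3 / species_table$cerebellum_mm3
  else rep(NA_real_, nrow(species_table))
  out <- data.frame(
    species = species_table$species,
    ratio_cbl_cbr = r1,
    ratio_ans_cbl = r2,
    ratio_cbl_cbr_display = round_half_away(r1, 2),
    ratio_ans_cbl_display = round_half_away(r2, 2),
    stringsAsFactors = FALSE)
  if (!is.null(specimens)) {
    per <- lapply(split(specimens, specimens$species), function(d) {
      rr <- 100 * d$cerebellum_mm3 / d$cerebrum_mm3
      rr <- rr[!is.na(rr)]
      if (length(rr) < 2) return(NULL)
      data.frame(species = d$species[1],
                 ratio_cbl_cbr_specimen_median = stats::median(rr),
                 ratio_cbl_cbr_specimen_mad =
                   stats::median(abs(rr - stats::median(rr))),
                 stringsAsFactors = FALSE)
    })
    per <- do.call(rbind, per)
    if (!is.null(per)) out <- merge(out, per, by = "species", all.x = TRUE)
  }
  out
}

#' Append log10-transformed trait columns
#'
#' @param table data.frame with positive volume columns.
#' @param trait_cols columns to transform.
#' @return `table` with `log10_<trait>` columns appended.
#' @export
log10_transform <- function(table, trait_cols = NULL) {
  if (is.null(trait_cols)) trait_cols <- intersect(TRAIT_COLUMNS, names(table))
  for (tc in trait_cols) {
    if (any(!is.na(table[[tc]]) & table[[tc]] <= 0)) {
      stop("non-positive values in ", tc, " cannot be log-transformed")
    }
    table[[paste0("log10_", tc)]] <- log10(table[[tc]])
  }
  table
}

#' Jerison encephalization quotient
#'
#' `EQ = brain / (0.12 * P^(2/3))` with `P` the body mass. The reference
#' allometry was calibrated with brain and body in grams; callers supplying
#' volumes (mm3 ~ mg at unit density) should keep units consistent.
#'
#' @param brain brain size (same unit family as the reference allometry).
#' @param body_mass_g body mass in grams.
#' @return numeric EQ values.
#' @export
encephalization_quotient <- function(brain, body_mass_g) {
  stopifnot(all(brain > 0, na.rm = TRUE), all(body_mass_g > 0, na.rm = TRUE))
  if (any(body_mass_g < 20, na.rm = TRUE)) {
    warning("some body masses are < 20; are they in kg rather than g?")
  }
  brain / (0.12 * body_mass_g^(2 / 3))
}

#' Standardized residuals from the brain-body regression
#'
#' Ordinary least squares of log10 brain size on log10 body mass; each
#' species' residual is divided by the residual standard deviation
#' (`sqrt(RSS / (n - 2))`), giving the "standard deviations from the
#' regression" scale used for encephalization plots.
#'
#' @param log_brain numeric vector, log10 brain volume.
#' @param log_body numeric vector, log10 body mass.
#' @return data.frame with fitted values, residuals and standardized
#'   residuals; the OLS coefficients are attached as attribute `coef`.
#' @export
brain_body_residuals <- function(log_brain, log_body) {
  ok <- !is.na(log_brain) & !is.na(log_body)
  if (sum(ok) < 3) stop("need at least 3 species with both measures")
  xb <- log_body[ok]
  yb <- log_brain[ok]
  fit <- stats::lm(yb ~ xb)
  s <- stats::sigma(fit)
  degenerate <- s < 1e-10 * max(abs(yb), 1)  # exactly collinear data
  out <- data.frame(index = which(ok),
                    fitted = stats::fitted(fit),
                    residual = stats::residuals(fit),
                    std_residual = if (degenerate) rep(0, sum(ok))
                    else stats::residuals(fit) / s)
  attr(out, "coef") <- stats::coef(fit)
  out
}
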