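# Bundled study inputs: the 34-species median volume table and a synthetic
# time-calibrated stand-in chronogram.

#' The bundled 34-species cerebello-cerebral volume table
#'
#' Species-median cerebellar, cerebral and (for 13 species) ansiform volumes
#' in mm3, with raw MADs for the six species with >= 4 specimens, the ratio
#' cells as printed in the source table, flags for the ratio cells that are
#' exactly recomputable from the printed medians (half-away-from-zero
#' rounding, 2 dp; the remaining cells were evidently computed from
#' unrounded specimen data and are frozen as non-recomputable), clade
#' annotations (suborder, ape membership) and outlier notes. Values are
#' literal constants read from `inst/extdata/primate_ccs_volumes.csv`,
#' never regenerated.
#'
#' @return list with `species` (the 34-row table), `verified_cells`
#'   (long-format curated list of recomputable ratio cells) and
#'   `n_ansiform` (count of species with ansiform data).
#' @export
make_study_fixture <- function() {
  path <- system.file("extdata", "primate_ccs_volumes.csv",
                      package = "ccsallometry")
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  ver <- rbind(
    data.frame(species = tab$species, ratio = "cbl_cbr",
               printed = tab$ratio_cbl_cbr_printed,
               verified = tab$ratio_cbl_cbr_verified == 1,
               stringsAsFactors = FALSE),
    data.frame(species = tab$species, ratio = "ans_cbl",
               printed = tab$ratio_ans_cbl_printed,
               verified = !is.na(tab$ratio_ans_cbl_verified) &
                 tab$ratio_ans_cbl_verified == 1,
               stringsAsFactors = FALSE))
  ver <- ver[!is.na(ver$printed), ]
  rownames(ver) <- NULL
  list(species = tab, verified_cells = ver,
       n_ansiform = sum(!is.na(tab$ansiform_mm3)))
}

#' The bundled synthetic consensus chronogram
#'
#' A stand-in time-calibrated phylogeny for the 34 study species, assembled
#' once from standard published primate divergence-time estimates (root
#' depth 74 My). It is synthetic: analyses aiming at exact reproduction
#' should use a dated consensus tree from a primate phylogeny resource
#' (e.g. 10kTrees) via [parse_newick()]; pass such a tree wherever this one
#' is used. Provenance is recorded in the tree file's bracket comment.
#'
#' @return a `"phylo"` object with 34 tips.
#' @export
study_tree <- function() {
  path <- system.file("extdata", "synthetic_consensus_chronogram.nwk",
                      package = "ccsallometry")
  parse_newick(paste(readLines(path), collapse = ""))
}

#' Log10 trait vectors for the standard study regressions
#'
#' Convenience accessor building the named log10 vectors used by the four
#' standard PGLS regressions: cerebellum ~ cerebrum over all species;
#' cerebellum ~ cerebrum, ansiform ~ rest-of-cerebellum (cerebellum minus
#' ansiform, computed) and ansiform ~ cerebrum over the complete-data
#' (ansiform) subset.
#'
#' @param fixture optional result of [make_study_fixture()].
#' @return list of named log10 vectors: `cerebellum`, `cerebrum`,
#'   `ansiform`, `rest_of_cerebellum` (the latter two only for the
#'   ansiform subset), plus `ape_mask` and `suborder`.
#' @export
study_traits <- function(fixture = make_study_fixture()) {
  tab <- fixture$species
  nm <- tab$species
  sub <- !is.na(tab$ansiform_mm3)
  list(
    cerebellum = stats::setNames(log10(tab$cerebellum_mm3), nm),
    cerebrum = stats::setNames(log10(tab$cerebrum_mm3), nm),
    ansiform = stats::setNames(log10(tab$ansiform_mm3[sub]), nm[sub]),
    rest_of_cerebellum = stats::setNames(
      log10(tab$cerebellum_mm3[sub] - tab$ansiform_mm3[sub]), nm[sub]),
    ape_mask = stats::setNames(tab$is_ape == 1, nm),
    suborder = stats::setNames(tab$suborder, nm))
}
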