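#' Classify mutant/wild-type modification ratios
#'
#' Applies the ratio-matrix legend semantics: ratios below the undetectable
#' threshold (default 0.02; the sentinel 0.00001 marks ribonucleosides
#' undetectable in the mutant) are `undetectable`, otherwise below 0.6
#' `decreased`, above 1.5 `increased`, else `unchanged`. Inequalities are
#' strict, so boundary values fall to the milder label.
#'
#' @param mat numeric matrix, mutant strains x analytes, of
#'   mutant/wild-type ratios (>= 0; sentinel 0.00001 honored).
#' @param thresholds named list/vector with `undetectable`, `decreased`,
#'   `increased`; must satisfy 0 < undetectable < decreased <= 1 <= increased.
#' @return A `ratio_classification`: character matrix of labels with the same
#'   dimnames, attribute `thresholds`.
#' @examples
#' m <- matrix(c(0.00001, 0.55, 1.0, 1.6), 1,
#'             dimnames = list("mut", c("a", "b", "c", "d")))
#' classify_ratios(m)
#' @export
classify_ratios <- function(mat,
                            thresholds = c(undetectable = 0.02,
                                           decreased = 0.6,
                                           increased = 1.5)) {
  x <- as.matrix(mat)
  th <- as.list(thresholds)
  if (!(th$undetectable > 0 && th$undetectable < th$decreased &&
        th$decreased <= 1 && th$increased >= 1))
    stop("thresholds must satisfy 0 < undetectable < decreased <= 1 <= increased")
  if (any(x < 0, na.rm = TRUE)) stop("negative ratio in matrix")
  lab <- ifelse(x < th$undetectable, "undetectable",
                ifelse(x < th$decreased, "decreased",
                       ifelse(x > th$increased, "increased", "unchanged")))
  structure(lab, thresholds = th,
            class = c("ratio_classification", class(lab)))
}

#' Infer enzyme-product links from a classified ratio matrix
#'
#' A modification abolished in a deletion strain (undetectable ratio)
#' implicates the deleted gene in that modification's biosynthesis; a
#' significant decrease implicates it more weakly. Links are gated on the
#' per-cell significance flag when one is supplied (the ratio-table
#' convention underlines t-test p < 0.05 cells); without flags all
#' classified cells are reported, with a warning.
#'
#' @param classification a `ratio_classification` from [classify_ratios()].
#' @param ratios the ratio matrix the classification came from (for sorting).
#' @param significance optional logical matrix of per-cell significance.
#' @return data.frame sorted by ascending ratio: `strain`, `short_name`,
#'   `ratio`, `strength` (`"abolished"` for undetectable cells, `"reduced"`
#'   for decreased cells).
#' @export
infer_enzyme_products <- function(classification, ratios,
                                  significance = NULL) {
  lab <- unclass(classification)
  x <- as.matrix(ratios)
  stopifnot(identical(dim(lab), dim(x)))
  if (is.null(significance)) {
    warning("no significance flags supplied: reporting links ungated")
    significance <- matrix(TRUE, nrow(x), ncol(x), dimnames = dimnames(x))
  }
  hit <- (lab %in% c("undetectable", "decreased")) & as.logical(significance)
  hit <- matrix(hit, nrow(x), ncol(x))
  idx <- which(hit, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(strain = character(0), short_name = character(0),
                      ratio = numeric(0), strength = character(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(
    strain = rownames(x)[idx[, 1]],
    short_name = colnames(x)[idx[, 2]],
    ratio = x[idx],
    strength = ifelse(lab[idx] == "undetectable", "abolished", "reduced"),
    stringsAsFactors = FALSE)
  out <- out[order(out$ratio, out$strain, out$short_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank candidate redundant enzyme pairs by profile correlation
#'
#' Strong covariance between the modification profiles of two deletion
#' strains suggests the deleted enzymes act in the same pathway or share
#' substrates (redundancy). Pairs with correlation above `strong` are tiered
#' `strong`; pairs in (`weak`, `strong`] are `moderate`; the rest are
#' dropped.
#'
#' @param cm a `correlation_matrix` from [profile_correlation()] on the
#'   mutant ratio profiles.
#' @param strong,weak tier thresholds (defaults 0.8 and 0.5).
#' @return data.frame ranked by descending correlation: `strain1`, `strain2`,
#'   `correlation`, `tier`.
#' @export
redundancy_candidates <- function(cm, strong = 0.8, weak = 0.5) {
  x <- as.matrix(cm)
  stopifnot(nrow(x) == ncol(x), weak < strong)
  nm <- rownames(x)
  pairs <- which(upper.tri(x), arr.ind = TRUE)
  cc <- x[pairs]
  keep <- !is.na(cc) & cc > weak
  out <- data.frame(
    strain1 = nm[pairs[keep, 1]], strain2 = nm[pairs[keep, 2]],
    correlation = cc[keep],
    tier = ifelse(cc[keep] > strong, "strong", "moderate"),
    stringsAsFactors = FALSE)
  out <- out[order(-out$correlation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-dosage check for heterozygote strains
#'
#' A diploid heterozygote of an essential modification gene is expected to
#' retain roughly half the wild-type modification level; this packages that
#' expectation as a per-strain report row.
#'
#' @param ratio observed mutant/wild-type ratio(s).
#' @param expected expected ratio under one functional copy (default 0.5).
#' @param tolerance allowed absolute deviation (default 0.15).
#' @return data.frame: `ratio`, `expected`, `tolerance`, `consistent`.
#' @examples
#' gene_dosage_check(0.6)  # ~40% reduction: consistent with gene dosage
#' @export
gene_dosage_check <- function(ratio, expected = 0.5, tolerance = 0.15) {
  stopifnot(all(ratio >= 0))
  data.frame(ratio = ratio, expected = expected, tolerance = tolerance,
             consistent = abs(ratio - expected) <= tolerance)
}

#' Canonical tRNA positions of the profiled modifications
#'
#' Static annotation mapping each modification to its canonical position(s)
#' in yeast cytoplasmic tRNA (wobble 34, anticodon-adjacent 37, variable arm
#' 44, core positions 26/46, ...). Reference data for report decoration
#' only; nothing is computed from it.
#'
#' @return data.frame with `short_name`, `positions`, `note`.
#' @export
modification_positions <- function() {
  path <- system.file("extdata", "modification_positions.tsv",
                      package = "trnamrm", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
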