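#' Consequence classes treated as having a strong effect on gene function
#'
#' @return Character vector of the retained consequence classes.
#' @export
strong_effect_classes <- function() {
  c("missense", "nonsense", "splice_site", "frameshift", "inframe_indel")
}

#' Default consequence synonym map
#'
#' Annotation tools emit different vocabularies for the same consequence
#' (Sequence Ontology terms, SnpEff effect names, short labels). This map
#' normalizes the common dialects onto the package's five strong-effect
#' classes plus `other`; anything unmapped and not already a known class is
#' classed `other`.
#'
#' @return Named character vector: input term -> normalized class.
#' @export
consequence_synonyms <- function() {
  c(
    missense_variant = "missense",
    missense = "missense",
    stop_gained = "nonsense",
    stop_lost = "nonsense",
    nonsense = "nonsense",
    splice_acceptor_variant = "splice_site",
    splice_donor_variant = "splice_site",
    splice_site = "splice_site",
    frameshift_variant = "frameshift",
    frameshift = "frameshift",
    inframe_insertion = "inframe_indel",
    inframe_deletion = "inframe_indel",
    inframe_indel = "inframe_indel",
    synonymous_variant = "other",
    synonymous = "other",
    intron_variant = "other",
    intergenic_variant = "other"
  )
}

#' Normalize a consequence annotation vector
#'
#' @param x Character vector of consequence terms.
#' @param synonyms Named map as produced by [consequence_synonyms()].
#' @return Character vector over the normalized vocabulary.
#' @export
normalize_consequence <- function(x, synonyms = consequence_synonyms()) {
  out <- unname(synonyms[x])
  known <- c(strong_effect_classes(), "other")
  out[is.na(out) & x %in% known] <- x[is.na(out) & x %in% known]
  out[is.na(out)] <- "other"
  out
}

#' Keep variants with a predicted strong effect on gene function
#'
#' Retains missense, nonsense, splice-site, frameshift, and in-frame
#' insertion/deletion variants; everything else (synonymous, intronic, UTR,
#' ...) is removed. Input order is preserved and records are not modified.
#'
#' @param variants Variant tibble with a `consequence` column (normalized or
#'   raw; raw terms are normalized via `synonyms` for the test only).
#' @param keep_classes Consequence classes to retain.
#' @param synonyms Synonym map for normalization.
#' @return The retained subset of `variants`.
#' @export
filter_functional <- function(variants,
                              keep_classes = strong_effect_classes(),
                              synonyms = consequence_synonyms()) {
  cls <- normalize_consequence(variants$consequence, synonyms)
  variants[cls %in% keep_classes, , drop = FALSE]
}

#' Keep variants predicted deleterious by both SIFT and CADD
#'
#' Retains variants with SIFT at or below `sift_max` and CADD at or above
#' `cadd_min` (both boundaries inclusive, as printed in the source screen).
#' A variant missing either score cannot demonstrate deleteriousness and is
#' excluded (with a message), not an error.
#'
#' @param variants Variant tibble with `sift` and `cadd` columns.
#' @param sift_max Maximum SIFT score, default 0.05.
#' @param cadd_min Minimum phred-scaled CADD score, default 25.
#' @return The retained subset of `variants`.
#' @export
filter_deleterious <- function(variants, sift_max = 0.05, cadd_min = 25) {
  stopifnot(is.finite(sift_max), is.finite(cadd_min))
  missing_score <- is.na(variants$sift) | is.na(variants$cadd)
  if (any(missing_score)) {
    inform(sprintf(
      "%d variant(s) lack a SIFT or CADD score and fail the deleteriousness filter",
      sum(missing_score)), class = "gvb_missing_annotation")
  }
  keep <- !missing_score & variants$sift <= sift_max & variants$cadd >= cadd_min
  variants[keep, , drop = FALSE]
}
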