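#' Configuration for gene-wise variant burden (GVB) scoring
#'
#' The GVB score of a gene for one individual is the geometric mean of the
#' SIFT scores of the coding variants the individual carries in that gene,
#' restricted to variants with SIFT below `inclusion_threshold`. An individual
#' carrying no qualifying variant scores exactly 1 (no burden). Because SIFT
#' can be exactly 0 (fully intolerant substitutions) and a literal geometric
#' mean would then collapse to 0 for every carrier regardless of the rest of
#' the gene, scores are floored at `sift_floor` before averaging.
#'
#' Variants listed in `recessive_masked_variants` contribute only when
#' homozygous: heterozygous calls are ignored. This is how a common variant
#' with a recessive phenotypic effect (the default, CRIM1 rs3821169) is kept
#' from diluting the burden score of the large heterozygote-carrier class.
#'
#' @param inclusion_threshold Variants with SIFT at or above this value are
#'   excluded from the burden (strict `<` comparison). Default 0.7.
#' @param sift_floor Minimum SIFT value substituted for scores below it
#'   (notably SIFT = 0) before taking the geometric mean. Default 0.001.
#' @param recessive_masked_variants Character vector of variant ids whose
#'   heterozygous genotypes are ignored. Default `"rs3821169"`.
#' @param count_homozygous_twice If `TRUE`, a homozygous (non-masked) variant
#'   contributes its SIFT score twice to the geometric mean; the default
#'   `FALSE` counts each carried site once regardless of zygosity.
#' @return A `gvb_config` list.
#' @export
#' @examples
#' gvb_config()
gvb_config <- function(inclusion_threshold = 0.7,
                       sift_floor = 0.001,
                       recessive_masked_variants = "rs3821169",
                       count_homozygous_twice = FALSE) {
  if (!(sift_floor > 0 && sift_floor < inclusion_threshold &&
        inclusion_threshold <= 1)) {
    abort("require 0 < sift_floor < inclusion_threshold <= 1",
          class = "gvb_config_error")
  }
  structure(
    list(
      inclusion_threshold = inclusion_threshold,
      sift_floor = sift_floor,
      recessive_masked_variants = as.character(recessive_masked_variants),
      count_homozygous_twice = isTRUE(count_homozygous_twice)
    ),
    class = "gvb_config"
  )
}

#' Gene-wise variant burden score for one subject and one gene
#'
#' @param genotype Integer vector of alternate-allele counts (0, 1, 2 or `NA`)
#'   over one gene's variants for a single subject.
#' @param sift Numeric vector of SIFT scores aligned with `genotype`; `NA`
#'   means the variant has no SIFT annotation and is skipped (with a message).
#' @param variant_id Character vector of variant ids aligned with `genotype`
#'   (used to apply recessive masking).
#' @param config A [gvb_config()].
#' @return A single score in (0, 1]; 1 when no qualifying variant is carried.
#' @export
#' @examples
#' # two carried deleterious variants, one excluded by the SIFT < 0.7 rule
#' gene_gvb(c(1, 1, 2), c(0.2, 0.05, 0.8), c("v1", "v2", "v3"))
gene_gvb <- function(genotype, sift, variant_id, config = gvb_config()) {
  stopifnot(length(genotype) == length(sift),
            length(genotype) == length(variant_id))
  assert_genotype_values(genotype)
  if (length(genotype) == 0L) return(1)

  masked <- variant_id %in% config$recessive_masked_variants
  carried <- !is.na(genotype) &
    ifelse(masked, genotype == 2L, genotype >= 1L)

  no_sift <- carried & is.na(sift)
  if (any(no_sift)) {
    inform(sprintf("skipping %d carried variant(s) without a SIFT score: %s",
                   sum(no_sift), paste(variant_id[no_sift], collapse = ", ")),
           class = "gvb_missing_sift")
  }
  keep <- carried & !is.na(sift) & sift < config$inclusion_threshold
  if (!any(keep)) return(1)

  s <- pmax(sift[keep], config$sift_floor)
  if (config$count_homozygous_twice) {
    w <- ifelse(!masked[keep] & genotype[keep] == 2L, 2, 1)
    s <- rep(s, times = w)
  }
  geometric_mean(s)
}

#' Multigene GVB composition
#'
#' The burden score for a gene set is the geometric mean of its member genes'
#' scores (the k-th root of their product). The composition is order-invariant
#' and associative, and a singleton set returns the gene score unchanged.
#'
#' @param scores Numeric vector of per-gene GVB scores, each in (0, 1].
#' @return A single score in (0, 1].
#' @export
#' @examples
#' multigene_gvb(c(1, 1, 0.001)) # a single fully deleterious gene among three
multigene_gvb <- function(scores) {
  if (length(scores) == 0L) {
    abort("multigene_gvb() requires at least one gene score",
          class = "gvb_contract_error")
  }
  if (any(!is.finite(scores)) || any(scores <= 0) || any(scores > 1)) {
    abort("gene scores must lie in (0, 1]", class = "gvb_contract_error")
  }
  geometric_mean(scores)
}

#' Per-subject GVB profiles over a cohort
#'
#' Computes a gene-level GVB score for every gene appearing in any requested
#' gene set, plus a composed score per set, for every subject in the genotype
#' table.
#'
#' @param variants Variant annotation tibble with columns `variant_id`,
#'   `gene`, `sift` (others ignored).
#' @param genotypes Wide genotype tibble: a `subject_id` column plus one
#'   integer column per variant id.
#' @param gene_sets List of character vectors of gene symbols; unnamed sets
#'   are labelled by `paste(genes, collapse = ",")`. Defaults to the two- and
#'   three-gene thiopurine models.
#' @param config A [gvb_config()].
#' @return A tibble with `subject_id`, one column per gene, and one column per
#'   gene-set label.
#' @export
profile_cohort <- function(variants, genotypes,
                           gene_sets = list(
                             c("NUDT15", "TPMT"),
                             c("NUDT15", "TPMT", "CRIM1")
                           ),
                           config = gvb_config()) {
  labels <- names(gene_sets) %||% rep("", length(gene_sets))
  labels <- ifelse(labels == "",
                   map_chr(gene_sets, paste, collapse = ","), labels)
  genes <- unique(unlist(gene_sets))

  gmat <- as.matrix(genotypes[, setdiff(names(genotypes), "subject_id"),
                              drop = FALSE])
  out <- tibble(subject_id = genotypes$subject_id)
  for (g in genes) {
    vg <- variants[variants$gene == g & variants$variant_id %in% colnames(gmat), ]
    if (nrow(vg) == 0L) {
      inform(sprintf("gene %s has no variants in the input; scores set to 1", g),
             class = "gvb_empty_gene")
      out[[g]] <- rep(1, nrow(out))
    } else {
      sub <- gmat[, vg$variant_id, drop = FALSE]
      out[[g]] <- apply(sub, 1L, gene_gvb,
                        sift = vg$sift, variant_id = vg$variant_id,
                        config = config)
    }
  }
  for (i in seq_along(gene_sets)) {
    out[[labels[i]]] <- apply(
      as.matrix(out[gene_sets[[i]]]), 1L, multigene_gvb)
  }
  out
}
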