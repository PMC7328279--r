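#' Default star-allele function table for NUDT15 and TPMT
#'
#' A small editable table mapping star alleles to CPIC-style functional
#' status. Following the February 2019 guideline update, NUDT15*9 defaults to
#' `no_function`; set `nudt15_star9 = "uncertain"` to restore the earlier
#' classification.
#'
#' @param nudt15_star9 Function assigned to NUDT15*9, `"no_function"`
#'   (default) or `"uncertain"`.
#' @return Tibble: `gene`, `allele`, `fn`.
#' @export
allele_function_table <- function(nudt15_star9 = c("no_function", "uncertain")) {
  nudt15_star9 <- match.arg(nudt15_star9)
  tibble(
    gene = c(rep("NUDT15", 4L), rep("TPMT", 4L)),
    allele = c("*1", "*2", "*3", "*9", "*1", "*2", "*3A", "*3C"),
    fn = c("normal", "no_function", "no_function", nudt15_star9,
           "normal", "no_function", "no_function", "no_function")
  )
}

#' Metabolizer phenotype from a star-allele diplotype
#'
#' Two normal-function alleles give a normal metabolizer (NM); exactly one
#' no-function allele an intermediate metabolizer (IM); two no-function
#' alleles a poor metabolizer (PM). Any allele of uncertain function makes
#' the call indeterminate.
#'
#' @param diplotypes Tibble: `subject_id`, `gene`, `allele1`, `allele2`.
#' @param fn_table Function table as from [allele_function_table()].
#' @return Tibble: `subject_id`, `gene`, `phenotype` in
#'   `c("NM", "IM", "PM", "indeterminate")`.
#' @export
#' @examples
#' d <- tibble::tibble(subject_id = "s1", gene = "NUDT15",
#'                     allele1 = "*1", allele2 = "*9")
#' assign_phenotype(d)
assign_phenotype <- function(diplotypes, fn_table = allele_function_table()) {
  lookup <- setNames(fn_table$fn, paste(fn_table$gene, fn_table$allele))
  f1 <- lookup[paste(diplotypes$gene, diplotypes$allele1)]
  f2 <- lookup[paste(diplotypes$gene, diplotypes$allele2)]
  unknown <- is.na(f1) | is.na(f2)
  if (any(unknown)) {
    bad <- unique(c(diplotypes$allele1[is.na(f1)], diplotypes$allele2[is.na(f2)]))
    abort(sprintf("allele(s) absent from the function table: %s",
                  paste(bad, collapse = ", ")),
          class = "gvb_config_error")
  }
  n_nofn <- (f1 == "no_function") + (f2 == "no_function")
  phen <- dplyr::case_when(
    f1 == "uncertain" | f2 == "uncertain" ~ "indeterminate",
    n_nofn == 0L ~ "NM",
    n_nofn == 1L ~ "IM",
    n_nofn == 2L ~ "PM"
  )
  tibble(subject_id = diplotypes$subject_id, gene = diplotypes$gene,
         phenotype = phen)
}

#' Combined two-gene risk class
#'
#' A subject is classed NM only when both NUDT15 and TPMT phenotypes are NM;
#' any IM or PM call routes to the PM+IM risk arm. Indeterminate phenotypes
#' are treated conservatively as non-NM (logged).
#'
#' @param phenotypes Output of [assign_phenotype()] covering both genes.
#' @param genes The two genes forming the combined class.
#' @return Tibble: `subject_id`, `risk` in `c("PM+IM", "NM")`.
#' @export
combined_risk <- function(phenotypes, genes = c("NUDT15", "TPMT")) {
  ph <- phenotypes[phenotypes$gene %in% genes, ]
  missing_gene <- ph |>
    count(.data$subject_id) |>
    filter(.data$n < length(genes))
  if (nrow(missing_gene) > 0L) {
    abort("every subject needs a phenotype call for both genes",
          class = "gvb_data_error")
  }
  if (any(ph$phenotype == "indeterminate")) {
    inform(sprintf("%d indeterminate call(s) routed to the PM+IM risk arm",
                   sum(ph$phenotype == "indeterminate")),
           class = "gvb_indeterminate")
  }
  ph |>
    summarise(risk = if (all(.data$phenotype == "NM")) "NM" else "PM+IM",
              .by = "subject_id")
}

#' Select both-wildtype subjects
#'
#' Restricts a subject table to those whose combined NUDT15/TPMT risk class
#' is NM (carrying no pharmacogenetic variant in either gene); cohort labels
#' and all other columns are preserved.
#'
#' @param subjects Subject tibble with `subject_id`.
#' @param risk Output of [combined_risk()].
#' @return The NM subset of `subjects`.
#' @export
select_both_wt <- function(subjects, risk) {
  stopifnot(all(subjects$subject_id %in% risk$subject_id))
  nm <- risk$subject_id[risk$risk == "NM"]
  subjects[subjects$subject_id %in% nm, , drop = FALSE]
}
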