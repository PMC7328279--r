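#' Write a synthetic cohort to VCF and phenotype/diplotype tables
#'
#' Emits a plain-text VCF 4.2 (1-based coordinates, unphased diploid GT,
#' `./.` for missing calls, INFO keys `GENE`, `CSQ`, `SIFT`, `CADD`), a
#' tab-separated phenotype table (`subject_id`, `age`, `sex`, `cohort`,
#' `dip`), and a diplotype table (`subject_id`, `gene`, `allele1`,
#' `allele2`). A read of these files reproduces the cohort.
#'
#' @param cohort A `gvb_cohort` from [simulate_cohort()].
#' @param prefix Output path prefix; files are written as `<prefix>.vcf`,
#'   `<prefix>.phenotypes.tsv`, `<prefix>.diplotypes.tsv`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, prefix) {
  paths <- c(vcf = paste0(prefix, ".vcf"),
             phenotypes = paste0(prefix, ".phenotypes.tsv"),
             diplotypes = paste0(prefix, ".diplotypes.tsv"))
  write_variant_vcf(cohort$variants, cohort$genotypes, paths["vcf"])
  readr::write_tsv(cohort$subjects, paths["phenotypes"])
  readr::write_tsv(cohort$diplotypes, paths["diplotypes"])
  invisible(paths)
}

.num_info <- function(x) {
  format(x, digits = 15, scientific = FALSE, trim = TRUE)
}

#' Write annotated variants and genotypes as VCF 4.2
#'
#' @param variants Variant tibble (`variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `consequence`, `sift`, `cadd`).
#' @param genotypes Wide genotype tibble (`subject_id` + variant columns);
#'   may cover zero subjects for a header-only file.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, genotypes, path) {
  subjects <- genotypes$subject_id
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gvburden",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=SIFT,Number=1,Type=Float,Description=\"SIFT score\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"CADD phred score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", subjects), collapse = "\t")
  )
  gt_string <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  body <- character(nrow(variants))
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, ]
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    info <- c(paste0("GENE=", v$gene), paste0("CSQ=", v$consequence))
    if (!is.na(v$sift)) info <- c(info, paste0("SIFT=", .num_info(v$sift)))
    if (!is.na(v$cadd)) info <- c(info, paste0("CADD=", .num_info(v$cadd)))
    g <- genotypes[[v$variant_id]]
    gt <- ifelse(is.na(g), "./.", gt_string[as.character(g)])
    body[i] <- paste(c(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".",
                       "PASS", paste(info, collapse = ";"), "GT", gt),
                     collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

.parse_info <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
  unname(vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
                character(1)))
}

# value for alt-allele k of a possibly comma-separated (Number=A) field
.alt_value <- function(x, k, n_alt) {
  parts <- strsplit(x %||% NA_character_, ",", fixed = TRUE)[[1]]
  if (length(parts) == 0L || all(is.na(parts))) return(NA_character_)
  if (length(parts) == 1L) parts else if (k <= length(parts)) parts[k]
  else NA_character_
}

.parse_score <- function(x, what, id) {
  if (is.na(x) || x == "" || x == ".") return(NA_real_)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) {
    warn(sprintf("unparseable %s value '%s' at %s; recorded as absent",
                 what, x, id), class = "gvb_parse_warning")
  }
  v
}

#' Read an annotated VCF into variants and genotypes
#'
#' Parses a VCF 4.x file carrying gene symbol, consequence class, SIFT and
#' CADD annotations as INFO fields. Multi-allelic records are decomposed
#' into one variant per ALT allele; the genotype of a non-focal alternate
#' allele counts as 0 for the focal allele. Subject order follows the VCF
#' header. Unparseable SIFT/CADD values are recorded as absent with a
#' warning.
#'
#' @param path VCF path.
#' @param annotation_keys Named character vector mapping the roles `gene`,
#'   `csq`, `sift`, `cadd` to the INFO keys that carry them.
#' @param synonyms Consequence synonym map (see [consequence_synonyms()]).
#' @return List: `variants` (annotation tibble), `genotypes` (wide tibble),
#'   `subjects` (character vector in header order).
#' @export
read_annotated_vcf <- function(path,
                               annotation_keys = c(gene = "GENE", csq = "CSQ",
                                                   sift = "SIFT", cadd = "CADD"),
                               synonyms = consequence_synonyms()) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  has_gt_block <- ncol(vcf@gt) >= 1L
  subjects <- if (has_gt_block) colnames(vcf@gt)[-1] else character()

  empty <- tibble(variant_id = character(), chrom = character(),
                  pos = integer(), ref = character(), alt = character(),
                  gene = character(), consequence = character(),
                  sift = numeric(), cadd = numeric())
  if (nrow(fix) == 0L) {
    gt_tbl <- tibble(subject_id = subjects)
    return(list(variants = empty, genotypes = gt_tbl, subjects = subjects))
  }
  if (length(subjects) > 0L) {
    fmt <- vcf@gt[, 1]
    if (any(is.na(fmt)) || !all(grepl("(^|:)GT(:|$)", fmt))) {
      abort("VCF records lack a GT entry in FORMAT", class = "gvb_format_error")
    }
  }

  rows <- list()
  gcols <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    info <- fix[i, "INFO"]
    base_id <- fix[i, "ID"]
    gt_raw <- if (length(subjects) > 0L) {
      gt_field <- vcf@gt[i, -1]
      gt_idx <- match("GT", strsplit(vcf@gt[i, 1], ":", fixed = TRUE)[[1]])
      vapply(strsplit(gt_field, ":", fixed = TRUE), `[`, character(1), gt_idx)
    } else character()
    sift_raw <- .parse_info(info, annotation_keys[["sift"]])
    cadd_raw <- .parse_info(info, annotation_keys[["cadd"]])
    for (k in seq_along(alts)) {
      vid <- if (is.na(base_id) || base_id == ".") {
        paste(fix[i, "CHROM"], fix[i, "POS"], fix[i, "REF"], alts[k], sep = ":")
      } else if (length(alts) > 1L) {
        paste(base_id, alts[k], sep = ":")
      } else base_id
      rows[[length(rows) + 1L]] <- tibble(
        variant_id = vid,
        chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[k],
        gene = .parse_info(info, annotation_keys[["gene"]]),
        consequence = normalize_consequence(
          .parse_info(info, annotation_keys[["csq"]]), synonyms),
        sift = .parse_score(.alt_value(sift_raw, k, length(alts)), "SIFT", vid),
        cadd = .parse_score(.alt_value(cadd_raw, k, length(alts)), "CADD", vid)
      )
      if (length(subjects) > 0L) {
        alleles <- strsplit(gt_raw, "[/|]")
        # vcfR surfaces "./." as NA in the genotype matrix
        gcols[[vid]] <- unname(vapply(alleles, function(a) {
          if (length(a) == 0L || anyNA(a) || any(a == ".")) NA_integer_
          else sum(a == as.character(k))
        }, integer(1)))
      }
    }
  }
  variants <- list_rbind(rows)
  genotypes <- bind_cols(tibble(subject_id = subjects), as_tibble(gcols))
  list(variants = variants, genotypes = genotypes, subjects = subjects)
}

#' Read a phenotype table
#'
#' @param path Tab-separated file with header `subject_id`, `age`, `sex`,
#'   `cohort`, `dip`.
#' @return Subject tibble.
#' @export
read_phenotypes <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(), age = readr::col_double(),
    sex = readr::col_character(), cohort = readr::col_character(),
    dip = readr::col_double()))
}

#' Read a diplotype table
#'
#' @param path Tab-separated file with header `subject_id`, `gene`,
#'   `allele1`, `allele2`.
#' @return Diplotype tibble.
#' @export
read_diplotypes <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}
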