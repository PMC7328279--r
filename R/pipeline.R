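#' Pipeline run configuration
#'
#' Bundles every stage's parameters into one reproducible configuration:
#' the simulation conditions (or paths to existing input files), the
#' discovery/replication significance cutoffs, the SIFT/CADD deleteriousness
#' thresholds, the GVB parameters, the DIP cutoffs evaluated, and the seed.
#'
#' @param out_dir Output directory for stage outputs and the manifest.
#' @param seed Master seed; also used for the simulated cohort unless `sim`
#'   overrides it.
#' @param sim A [sim_config()] (its seed defaults to `seed`).
#' @param gvb A [gvb_config()].
#' @param p_max_discovery,p_max_replication Screen cutoffs (strict `<`).
#' @param sift_max,cadd_min Deleteriousness thresholds.
#' @param dip_cutoffs DIP cutoffs (in %) for the evaluation stage.
#' @param boot_n Bootstrap resamples for AUC confidence intervals.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "filter", "assoc", "gvb", "phenotype", "evaluate")` in
#'   that order. Later stages require earlier ones.
#' @return A `gvb_run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L,
                       sim = sim_config(seed = seed),
                       gvb = gvb_config(),
                       p_max_discovery = 0.01, p_max_replication = 0.05,
                       sift_max = 0.05, cadd_min = 25,
                       dip_cutoffs = c(15, 25, 35, 45, 60, 80, 100),
                       boot_n = 2000,
                       stages = c("simulate", "filter", "assoc", "gvb",
                                  "phenotype", "evaluate")) {
  all_stages <- c("simulate", "filter", "assoc", "gvb", "phenotype", "evaluate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  structure(
    list(out_dir = out_dir, seed = seed, sim = sim, gvb = gvb,
         p_max_discovery = p_max_discovery,
         p_max_replication = p_max_replication,
         sift_max = sift_max, cadd_min = cadd_min,
         dip_cutoffs = dip_cutoffs, boot_n = boot_n,
         stages = all_stages[all_stages %in% stages]),
    class = "gvb_run_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a flat YAML file whose keys match [run_config()] arguments
#' (`out_dir`, `seed`, `p_max_discovery`, ...; `n_subjects` and
#' `missing_rate` feed the simulation config).
#'
#' @param path YAML file path.
#' @return A `gvb_run_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- as.integer(y$seed %||% 1L)
  sim_args <- y[intersect(names(y), names(formals(sim_config)))]
  sim_args$seed <- seed
  args <- y[intersect(names(y), setdiff(names(formals(run_config)),
                                        c("sim", "gvb")))]
  args$seed <- seed
  args$sim <- do.call(sim_config, sim_args)
  do.call(run_config, args)
}

.log_stage <- function(log_path, msg) {
  line <- paste0("[", msg, "]")
  inform(msg, class = "gvb_pipeline_log")
  cat(msg, "\n", file = log_path, append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> write/read -> filter -> associate (discovery
#' screen + replication) -> GVB scoring -> star-allele phenotyping ->
#' classifier evaluation, writing each stage's table under `out_dir`
#' together with a JSON manifest (parameters, seed, package version, file
#' checksums). Re-running the same configuration reproduces byte-identical
#' result tables.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results (`cohort`,
#'   `variants`, `candidates`, `replication`, `profiles`, `phenotypes`,
#'   `risk`, `evaluation`, `single_gene`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "gvb_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  on_fail <- function(stage, err) {
    cat("FAILED", stage, conditionMessage(err),
        file = file.path(config$out_dir, "FAILED"))
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(err)), class = "gvb_pipeline_error")
  }
  res <- list(paths = character())
  add_out <- function(name, obj) {
    p <- file.path(config$out_dir, paste0(name, ".tsv"))
    readr::write_tsv(obj, p)
    res$paths[name] <<- p
    p
  }

  # -- simulate ---------------------------------------------------------
  .log_stage(log_path, sprintf("simulate: n=%d seed=%s",
                               config$sim$n_subjects, format(config$seed)))
  stage <- "simulate"
  tryCatch({
    cohort <- simulate_cohort(config$sim)
    paths <- write_cohort(cohort, file.path(config$out_dir, "cohort"))
    res$paths <- c(res$paths, paths)
    res$cohort <- cohort
  }, error = function(e) on_fail(stage, e))
  if (identical(config$stages, "simulate")) {
    write_manifest(config, res)
    return(invisible(res))
  }

  # round-trip through the on-disk representation so every downstream stage
  # consumes exactly what an external VCF/TSV input would provide
  vcf_in <- read_annotated_vcf(res$paths[["vcf"]])
  subjects <- read_phenotypes(res$paths[["phenotypes"]])
  diplotypes <- read_diplotypes(res$paths[["diplotypes"]])

  if ("filter" %in% config$stages) {
    stage <- "filter"
    tryCatch({
      functional <- filter_functional(vcf_in$variants)
      res$variants <- functional
      .log_stage(log_path, sprintf(
        "filter: %d variants read, %d strong-effect", nrow(vcf_in$variants),
        nrow(functional)))
      add_out("variants_functional", functional)
    }, error = function(e) on_fail(stage, e))
  }

  phenotypes <- assign_phenotype(diplotypes)
  risk <- combined_risk(phenotypes)
  res$phenotypes <- phenotypes
  res$risk <- risk
  if ("phenotype" %in% config$stages) {
    .log_stage(log_path, sprintf("phenotype: %d NM / %d subjects",
                                 sum(risk$risk == "NM"), nrow(risk)))
    add_out("metabolizer", left_join(phenotypes, risk, by = "subject_id"))
  }

  if ("assoc" %in% config$stages) {
    stage <- "assoc"
    tryCatch({
      both_wt <- select_both_wt(subjects, risk)
      disc <- both_wt[both_wt$cohort == "discovery", ]
      repl <- both_wt[both_wt$cohort == "replication", ]
      gt <- vcf_in$genotypes
      cand <- discovery_screen(
        res$variants %||% filter_functional(vcf_in$variants),
        gt[match(disc$subject_id, gt$subject_id), ], disc,
        p_max = config$p_max_discovery,
        sift_max = config$sift_max, cadd_min = config$cadd_min)
      repres <- replicate_candidates(
        cand, gt[match(repl$subject_id, gt$subject_id), ], repl,
        p_max = config$p_max_replication)
      .log_stage(log_path, sprintf(
        "assoc: %d candidates (p<%g), %d replicated", nrow(cand),
        config$p_max_discovery, sum(repres$replicated)))
      res$candidates <- cand
      res$replication <- repres
      add_out("association_screen", attr(cand, "screen"))
      add_out("candidates", as_tibble(cand))
      add_out("replication", repres)
    }, error = function(e) on_fail(stage, e))
  }

  if ("gvb" %in% config$stages) {
    stage <- "gvb"
    tryCatch({
      profiles <- profile_cohort(vcf_in$variants, vcf_in$genotypes,
                                 config = config$gvb)
      res$profiles <- profiles
      .log_stage(log_path, sprintf("gvb: %d subjects scored", nrow(profiles)))
      add_out("gvb_scores", profiles)
    }, error = function(e) on_fail(stage, e))
  }

  if ("evaluate" %in% config$stages) {
    stage <- "evaluate"
    tryCatch({
      ev <- map(config$dip_cutoffs, function(ct) {
        compare_models(subjects, res$profiles, risk, dip_cutoff = ct,
                       boot_n = config$boot_n, seed = config$seed)
      }) |> list_rbind()
      sg <- map(c("CRIM1", "NUDT15", "TPMT"), function(g) {
        single_gene_contribution(subjects, res$profiles, phenotypes,
                                 vcf_in$genotypes, g,
                                 dip_cutoffs = config$dip_cutoffs,
                                 boot_n = config$boot_n, seed = config$seed)
      }) |> list_rbind()
      res$evaluation <- ev
      res$single_gene <- sg
      .log_stage(log_path, sprintf("evaluate: %d predictor x cohort x cutoff rows",
                                   nrow(ev)))
      add_out("evaluation", ev)
      add_out("single_gene_auc", sg)
    }, error = function(e) on_fail(stage, e))
  }

  write_manifest(config, res)
  invisible(res)
}

write_manifest <- function(config, res) {
  manifest <- list(
    package = "gvburden",
    version = as.character(utils::packageVersion("gvburden")),
    seed = config$seed,
    parameters = list(
      n_subjects = config$sim$n_subjects,
      discovery_fraction = config$sim$discovery_fraction,
      p_max_discovery = config$p_max_discovery,
      p_max_replication = config$p_max_replication,
      sift_max = config$sift_max, cadd_min = config$cadd_min,
      gvb = unclass(config$gvb)[c("inclusion_threshold", "sift_floor",
                                  "recessive_masked_variants")],
      dip_cutoffs = config$dip_cutoffs, boot_n = config$boot_n,
      stages = config$stages
    ),
    checksums = as.list(tools::md5sum(unname(res$paths)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
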