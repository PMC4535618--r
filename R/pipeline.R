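# End-to-end orchestration: one config, structured logging, reproducible
# outputs.

#' Build a pipeline configuration
#'
#' Collects input paths and analysis parameters with the pipeline's default
#' thresholds (150 kb windows stepped by half, pooled MAF >= 0.05, >= 10
#' SNPs per window, ZHp < -2, SIFT <= 0.05). Unknown fields are an error.
#'
#' @param vcf,breed_map,genome,gene_models,reference,known_sites,sift_table,chip
#'   Input file paths (any may be `NULL` where a stage is to be skipped).
#' @param outdir Output directory.
#' @param window_size,step,maf_threshold,min_snps,zhp_threshold,
#'   sift_threshold,maf_scope Analysis parameters (see [scan_sweeps()] and
#'   [sift_classify()]).
#' @param seed Master seed for the simulate stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf = NULL, breed_map = NULL, genome = NULL,
                            gene_models = NULL, reference = NULL,
                            known_sites = NULL,
                            sift_table = NULL, chip = NULL,
                            outdir = "sweepherd_out",
                            window_size = 150000, step = window_size / 2,
                            maf_threshold = 0.05, min_snps = 10,
                            zhp_threshold = -2, sift_threshold = 0.05,
                            maf_scope = "cohort", seed = 1) {
  if (window_size <= 0 || step <= 0 || min_snps < 0) {
    abort("window parameters must be positive")
  }
  if (maf_threshold <= 0 || maf_threshold > 0.5) {
    abort("`maf_threshold` must lie in (0, 0.5]")
  }
  if (sift_threshold < 0 || sift_threshold > 1) {
    abort("`sift_threshold` must lie in [0, 1]")
  }
  structure(
    list(vcf = vcf, breed_map = breed_map, genome = genome,
         gene_models = gene_models, reference = reference,
         known_sites = known_sites,
         sift_table = sift_table, chip = chip, outdir = outdir,
         window_size = window_size, step = step,
         maf_threshold = maf_threshold, min_snps = min_snps,
         zhp_threshold = zhp_threshold, sift_threshold = sift_threshold,
         maf_scope = maf_scope, seed = seed),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' CLI or caller overrides take precedence over the file, which takes
#' precedence over the package defaults.
#'
#' @param path Path to a YAML file whose keys match [pipeline_config()]
#'   arguments.
#' @param overrides Named list of values overriding the file.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

log_line <- function(log_path, ...) {
  msg <- sprintf(...)
  inform(msg)
  if (!is.null(log_path)) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), msg, "\n",
        sep = "", file = log_path, append = TRUE)
  }
}

run_stage <- function(name, log_path, expr) {
  log_line(log_path, "[%s] start", name)
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
          parent = e)
  })
}

#' Simulate a cohort and write it to disk
#'
#' Wraps [simulate_cohort()] and [write_cohort()]; refuses to write into a
#' non-empty directory unless `force = TRUE`. A manifest recording the seed
#' and parameters is written alongside the data, so identical configs
#' reproduce byte-identical cohorts.
#'
#' @param config A `pipeline_config` (uses `outdir` and `seed`).
#' @param genome,breeds,sweeps,chip Simulation specs (defaults: a
#'   5 x 4 Mb genome, [default_breeds()], no sweeps, a 5,000-probe chip).
#' @param force Overwrite a non-empty output directory?
#' @param ... Passed to [simulate_cohort()].
#' @return The written file paths, invisibly.
#' @export
run_simulate <- function(config,
                         genome = genome_spec(paste0("chr", 1:5),
                                              rep(4e6, 5)),
                         breeds = default_breeds(), sweeps = NULL,
                         chip = chip_spec(5000), force = FALSE, ...) {
  outdir <- config$outdir
  if (dir.exists(outdir) && length(dir(outdir)) > 0 && !force) {
    abort(sprintf("output directory '%s' is not empty (use force = TRUE)",
                  outdir))
  }
  cohort <- simulate_cohort(genome, breeds = breeds, sweeps = sweeps,
                            chip = chip, seed = config$seed, ...)
  write_cohort(cohort, outdir)
}

#' Run the full analysis pipeline
#'
#' Executes annotation, QC (Ti/Tv and novelty), the per-breed sweep scan,
#' population structure, and chip concordance on the configured inputs, and
#' writes one table per result plus a machine-readable JSON summary and a
#' run log. Stages whose inputs are not configured are skipped (a missing
#' SIFT table, for instance, leaves nsSNPs unscored).
#'
#' @param config A `pipeline_config` with input paths set.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  for (f in c("vcf", "breed_map", "genome")) {
    if (is.null(config[[f]])) abort(sprintf("config lacks required '%s'", f))
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  cat("", file = log_path)
  params_header <- sprintf(
    "# window_size=%g step=%g maf=%g[%s] min_snps=%d zhp<%g sift<=%g",
    config$window_size, config$step, config$maf_threshold, config$maf_scope,
    config$min_snps, config$zhp_threshold, config$sift_threshold
  )
  write_table <- function(x, name) {
    path <- file.path(outdir, name)
    writeLines(params_header, path)
    suppressMessages(readr::write_tsv(x, path, append = TRUE,
                                      col_names = TRUE))
    path
  }
  summary <- list(parameters = config[c(
    "window_size", "step", "maf_threshold", "min_snps", "zhp_threshold",
    "sift_threshold", "maf_scope"
  )])

  calls <- run_stage("load", log_path, {
    read_vcf_genotypes(config$vcf)
  })
  breed_map <- read_breed_map(config$breed_map)
  calls$samples$breed <-
    breed_map$breed[match(calls$samples$sample, breed_map$sample)]
  genome <- read_genome_table(config$genome)
  presence <- breed_presence(calls, breed_map)
  breeds <- unique(breed_map$breed)

  # annotation + QC
  annotated <- NULL
  if (!is.null(config$gene_models)) {
    annotated <- run_stage("annotate", log_path, {
      gm <- read_gene_models(config$gene_models)
      ref_path <- config$reference %||%
        file.path(dirname(config$gene_models), "reference.fa")
      reference <- Biostrings::readDNAStringSet(ref_path)
      names(reference) <- sub(" .*", "", names(reference))
      ann <- classify_variants(calls$sites, gm, reference)
      if (!is.null(config$known_sites)) {
        ann <- flag_novel(ann, read_known_sites(config$known_sites))
      }
      if (!is.null(config$sift_table)) {
        ann <- sift_classify(ann, read_sift_table(config$sift_table),
                             threshold = config$sift_threshold)
      } else {
        ann$sift_score <- NA_real_
        ann$sift_class <- "unscored"
      }
      ann
    })
    write_table(annotated, "annotated_variants.tsv")
    catsum <- category_summary(annotated, presence)
    write_table(catsum, "category_summary.tsv")
    nssp <- breed_specific_nssnps(annotated, presence)
    write_table(nssp, "breed_specific_nssnps.tsv")
    summary$categories <- setNames(as.list(catsum$total), catsum$field)
    summary$breed_specific_nssnps <-
      as.list(table(factor(nssp$breed, levels = breeds)))
  }

  qc <- run_stage("qc", log_path, {
    per_breed <- purrr::map(breeds, function(b) {
      present <- presence[[b]]
      bind_cols(tibble(breed = b), titv(calls$sites[present, ]))
    }) |> bind_rows()
    overall <- bind_cols(tibble(breed = "all"), titv(calls$sites))
    bind_rows(overall, per_breed)
  })
  write_table(qc, "titv.tsv")
  summary$titv <- setNames(as.list(qc$ratio), qc$breed)
  if (!is.null(annotated) && "novel" %in% names(annotated)) {
    summary$novel_fraction <- novelty_fraction(annotated)
    log_line(log_path, "[qc] novel fraction %.3f", summary$novel_fraction)
  }

  scan <- run_stage("scan", log_path, {
    scan_sweeps(calls, breed_map, genome,
                window_size = config$window_size, step = config$step,
                maf_threshold = config$maf_threshold,
                min_snps = config$min_snps,
                zhp_threshold = config$zhp_threshold,
                maf_scope = config$maf_scope)
  })
  write_table(scan$windows, "windows.tsv")
  write_table(scan$calls, "sweep_calls.tsv")
  bed <- scan$calls |>
    mutate(name = .data$breed, score = round(-100 * .data$zhp)) |>
    select("chrom", "start", "end", "name", "score")
  readr::write_tsv(bed, file.path(outdir, "sweep_calls.bed"),
                   col_names = FALSE)
  summary$scan <- glance(scan)

  structure_res <- run_stage("structure", log_path, {
    sim <- genotype_similarity(calls$dosage)
    k2p <- pairwise_k2p(calls)
    tree <- nj_tree(k2p$distances)
    list(similarity = sim, k2p = k2p, tree = tree)
  })
  ape::write.tree(structure_res$tree, file.path(outdir, "nj_tree.nwk"))
  sim_tbl <- as_tibble(structure_res$similarity, rownames = "sample")
  write_table(sim_tbl, "similarity_matrix.tsv")

  if (!is.null(config$chip)) {
    conc <- run_stage("concordance", log_path, {
      genotype_concordance(read_chip_genotypes(config$chip), calls)
    })
    write_table(conc, "concordance.tsv")
    summary$concordance_mean <- mean(conc$rate)
  }

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  log_line(log_path, "[done] outputs in %s", outdir)
  invisible(summary)
}
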