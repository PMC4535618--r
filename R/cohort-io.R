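# File-format plumbing: writing a simulated cohort to disk and reading the
# pipeline's standard inputs back (VCF via vcfR, GFF3 via rtracklayer,
# FASTA via Biostrings, plain TSV via readr).

#' Write a simulated cohort to disk
#'
#' Emits every input file the analysis pipeline consumes, plus truth files:
#' \itemize{
#'   \item `cohort.vcf` — multi-sample VCF 4.2 with phased GT and AD;
#'   \item `breeds.tsv` — sample-to-breed map;
#'   \item `genome.tsv` — chromosome lengths;
#'   \item `genes.gff3` — canonical gene models;
#'   \item `reference.fa` — reference sequence;
#'   \item `known_sites.tsv` — dbSNP stand-in position list;
#'   \item `sift_scores.tsv` — SIFT scores for a subset of coding SNPs;
#'   \item `chip_genotypes.tsv` — chip calls with injected error/missingness;
#'   \item `truth/sweeps.bed`, `truth/frequencies.tsv`,
#'     `truth/manifest.json` — simulation truth and parameters.
#' }
#'
#' @param cohort A `pig_cohort` from [simulate_cohort()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) abort(sprintf("cannot create '%s'", outdir))
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  paths <- c(
    vcf = file.path(outdir, "cohort.vcf"),
    breeds = file.path(outdir, "breeds.tsv"),
    genome = file.path(outdir, "genome.tsv"),
    genes = file.path(outdir, "genes.gff3"),
    reference = file.path(outdir, "reference.fa"),
    known_sites = file.path(outdir, "known_sites.tsv"),
    sift = file.path(outdir, "sift_scores.tsv"),
    chip = file.path(outdir, "chip_genotypes.tsv"),
    truth_sweeps = file.path(outdir, "truth", "sweeps.bed"),
    truth_freqs = file.path(outdir, "truth", "frequencies.tsv"),
    manifest = file.path(outdir, "truth", "manifest.json")
  )

  write_vcf(cohort, paths[["vcf"]])
  readr::write_tsv(cohort$samples, paths[["breeds"]])
  readr::write_tsv(cohort$genome, paths[["genome"]])
  write_gene_models(cohort$gene_models, paths[["genes"]])
  Biostrings::writeXStringSet(cohort$reference, paths[["reference"]])
  readr::write_tsv(cohort$known_sites, paths[["known_sites"]])
  if (!is.null(cohort$sift)) {
    readr::write_tsv(cohort$sift, paths[["sift"]])
  }
  if (!is.null(cohort$chip_genotypes)) {
    readr::write_tsv(cohort$chip_genotypes, paths[["chip"]])
  }
  if (!is.null(cohort$sweeps) && nrow(cohort$sweeps) > 0) {
    bed <- cohort$sweeps |>
      mutate(name = purrr::map_chr(.data$breeds, paste, collapse = ",")) |>
      select("chrom", "start", "end", "name")
    readr::write_tsv(bed, paths[["truth_sweeps"]], col_names = FALSE)
  }
  readr::write_tsv(cohort$snps, paths[["truth_freqs"]])
  manifest <- list(
    seed = cohort$params$seed,
    known_fraction = cohort$params$known_fraction,
    ti_fraction = cohort$params$ti_fraction,
    chip = if (!is.null(cohort$chip)) unclass(cohort$chip),
    breeds = cohort$breeds,
    n_snps = nrow(cohort$snps),
    files = basename(unname(paths))
  )
  jsonlite::write_json(manifest, paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# Serialize the cohort as a VCF 4.2 text file (phased GT plus AD).
write_vcf <- function(cohort, path) {
  snps <- cohort$snps
  odd <- seq(1, nrow(cohort$haplotypes), by = 2)
  h1 <- t(cohort$haplotypes[odd, , drop = FALSE])
  h2 <- t(cohort$haplotypes[odd + 1, , drop = FALSE])
  ref_ad <- t(cohort$reads$ref_reads)
  alt_ad <- t(cohort$reads$alt_reads)
  gt <- matrix(paste0(h1, "|", h2, ":", ref_ad, ",", alt_ad), nrow = nrow(h1))
  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepherd_cohort_simulator",
    sprintf("##contig=<ID=%s,length=%d>",
            cohort$genome$chrom, as.integer(cohort$genome$length)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allelic depths for the ref and alt alleles\">"),
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           paste(cohort$samples$sample, collapse = "\t"))
  )
  body <- do.call(paste, c(
    list(snps$chrom, as.integer(snps$pos), ".", snps$ref, snps$alt,
         ".", "PASS", ".", "GT:AD"),
    lapply(seq_len(ncol(gt)), function(j) gt[, j]),
    list(sep = "\t")
  ))
  writeLines(c(meta, body), path)
  invisible(path)
}

# Serialize gene models to GFF3 (gene/mRNA parents plus feature rows).
write_gene_models <- function(gene_models, path) {
  tx <- gene_models |>
    group_by(.data$transcript, .data$gene, .data$chrom, .data$strand,
             .data$coding) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  attr_tx <- sprintf("ID=%s;Parent=%s;gene_name=%s;biotype=%s",
                     tx$transcript, tx$gene, tx$gene,
                     ifelse(tx$coding, "protein_coding", "non_coding"))
  gene_lines <- paste(tx$chrom, "sweepherd", "gene", tx$start, tx$end,
                      ".", tx$strand, ".",
                      sprintf("ID=%s;Name=%s", tx$gene, tx$gene), sep = "\t")
  tx_lines <- paste(tx$chrom, "sweepherd", "mRNA", tx$start, tx$end,
                    ".", tx$strand, ".", attr_tx, sep = "\t")
  feat <- gene_models
  phase <- rep(".", nrow(feat))
  feat_lines <- paste(feat$chrom, "sweepherd", feat$type, feat$start,
                      feat$end, ".", feat$strand, phase,
                      sprintf("Parent=%s;gene_name=%s",
                              feat$transcript, feat$gene), sep = "\t")
  writeLines(c("##gff-version 3", gene_lines, tx_lines, feat_lines), path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Keeps `exon`, `CDS`, `five_prime_UTR` and `three_prime_UTR` rows and
#' resolves each feature's transcript and gene from its `Parent` /
#' `gene_name` attributes.
#'
#' @param path Path to a GFF3 file.
#' @return A gene-model tibble as produced by [simulate_gene_models()].
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  keep <- df$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  feat <- df[keep, ]
  parent <- vapply(feat$Parent, function(p) p[1], character(1))
  gene <- if ("gene_name" %in% names(feat)) feat$gene_name else parent
  out <- tibble(
    chrom = as.character(feat$seqnames),
    start = feat$start, end = feat$end,
    strand = as.character(feat$strand),
    type = as.character(feat$type),
    transcript = parent, gene = gene
  )
  coding_tx <- unique(out$transcript[out$type == "CDS"])
  out$coding <- out$transcript %in% coding_tx
  arrange(out, .data$chrom, .data$start, .data$type)
}

#' Read a multi-sample VCF into the call-set structure used throughout
#'
#' Parses GT and AD with vcfR. Multi-allelic records are dropped with a
#' message (the analyses treat SNPs as biallelic major/minor).
#'
#' @param path Path to a VCF (optionally gzipped).
#' @return A list of class `cohort_calls`: `sites` tibble (`chrom`, `pos`,
#'   `ref`, `alt`), integer matrices `dosage`, `hap1`, `hap2`, `ref_ad`,
#'   `alt_ad` (variants x samples; haplotype matrices are `NA` for unphased
#'   records), and `samples` (sample names, breed unset).
#' @export
read_vcf_genotypes <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    inform(sprintf("dropping %d multi-allelic record(s)", sum(multi)))
    vcf <- vcf[!multi, ]
    fix <- vcfR::getFIX(vcf)
  }
  sites <- tibble(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"]
  )
  gt <- vcfR::extract.gt(vcf, element = "GT")
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  phased <- substr(gt, 2, 2) == "|"
  to_int <- function(x) {
    x[!x %in% c("0", "1")] <- NA
    matrix(as.integer(x), nrow = nrow(gt), dimnames = dimnames(gt))
  }
  h1 <- to_int(a1)
  h2 <- to_int(a2)
  dosage <- h1 + h2
  h1[!phased] <- NA_integer_
  h2[!phased] <- NA_integer_
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (all(is.na(ad))) abort("VCF has no AD field")
  ref_ad <- vcfR::masplit(ad, record = 1L, sort = 0L, decreasing = 0L)
  alt_ad <- vcfR::masplit(ad, record = 2L, sort = 0L, decreasing = 0L)
  structure(
    list(sites = sites, dosage = dosage, hap1 = h1, hap2 = h2,
         ref_ad = ref_ad, alt_ad = alt_ad,
         samples = tibble(sample = colnames(gt), breed = NA_character_)),
    class = "cohort_calls"
  )
}

#' Read the standard tab-separated pipeline inputs
#'
#' @param path Path to the file.
#' @return A tibble (`read_breed_map`: `sample`, `breed`;
#'   `read_genome_table`: a [genome_spec()]; `read_known_sites`: `chrom`,
#'   `pos`; `read_sift_table`: `transcript`, `chrom`, `pos`, `alt`, `score`;
#'   `read_chip_genotypes`: `animal`, `chrom`, `pos`, `allele1`, `allele2`).
#' @export
read_breed_map <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(out, c("sample", "breed"), "breed map")
  out
}

#' @rdname read_breed_map
#' @export
read_genome_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(out, c("chrom", "length"), "genome table")
  genome_spec(out$chrom, out$length)
}

#' @rdname read_breed_map
#' @export
read_known_sites <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(out, c("chrom", "pos"), "known sites")
  out
}

#' @rdname read_breed_map
#' @export
read_sift_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(out, c("chrom", "pos", "alt", "score"), "SIFT table")
  out
}

#' @rdname read_breed_map
#' @export
read_chip_genotypes <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(allele1 = "c", allele2 = "c"))
  assert_columns(out, c("animal", "chrom", "pos", "allele1", "allele2"),
                 "chip genotypes")
  out
}
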