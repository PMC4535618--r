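# Cohort simulator: frequency model, sweeps, genotypes, read counts,
# serialization.

test_that("Balding-Nichols frequencies degenerate correctly and are reproducible", {
  g <- genome_spec("chr1", 5e5)
  br <- dplyr::bind_rows(
    breed_model("A", fst = 0, n_individuals = 2),
    breed_model("B", fst = 0.2, n_individuals = 2)
  )
  f1 <- simulate_frequencies(g, br, seed = 3)
  expect_identical(f1$A, f1$p_anc)          # fst = 0: exact copy
  expect_false(identical(f1$B, f1$p_anc))
  expect_true(all(f1$B >= 0 & f1$B <= 1))
  expect_true(all(diff(f1$pos) > 0))
  f2 <- simulate_frequencies(g, br, seed = 3)
  expect_identical(f1, f2)                  # same seed, same table
  f3 <- simulate_frequencies(g, br, seed = 4)
  expect_false(identical(f1, f3))
  expect_error(simulate_frequencies(g[0, ], br, 1), "empty genome")
  expect_error(simulate_frequencies(g, br[0, ], 1), "no breeds")
})

test_that("simulated differentiation recovers the target Fst", {
  # moment estimator oracle: with s2 = (p1 - p2)^2 / 2 and pbar the pair
  # mean, E[s2] / E[pbar(1-pbar) + s2/2] equals Fst exactly under
  # Balding-Nichols
  g <- genome_spec("chr1", 5e6)     # ~10,000 SNPs at 1/500 bp
  br <- dplyr::bind_rows(
    breed_model("A", fst = 0.2, n_individuals = 2),
    breed_model("B", fst = 0.2, n_individuals = 2)
  )
  f <- simulate_frequencies(g, br, seed = 11)
  expect_gt(nrow(f), 9000)
  s2 <- (f$A - f$B)^2 / 2
  pbar <- (f$A + f$B) / 2
  fst_hat <- sum(s2) / sum(pbar * (1 - pbar) + s2 / 2)
  expect_lt(abs(fst_hat - 0.2), 0.05)
})

test_that("apply_sweeps pins the minor allele only where and for whom it should", {
  g <- genome_spec("chr1", 1e5)
  f <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 5000L, 9000L, 60000L),
    p_anc = 0.5, A = c(0.3, 0.8, 0.5, 0.3), B = c(0.4, 0.4, 0.4, 0.4)
  )
  sw <- sweep_spec("chr1", 0, 10000, "A", residual_maf = 0)
  out <- apply_sweeps(f, sw, g)
  expect_equal(out$A, c(0, 1, 0, 0.3))   # fixed inside; alt-major goes to 1;
                                          # tie at 0.5 resolves to ref-major
  expect_equal(out$B, f$B)               # unaffected breed untouched
  expect_error(apply_sweeps(f, sweep_spec("chr1", 0, 2e5, "A"), g),
               "off the chromosome")
  expect_error(apply_sweeps(f, sweep_spec("chrX", 0, 10, "A"), g),
               "not in the genome")
})

test_that("genotypes follow Hardy-Weinberg sampling", {
  g <- genome_spec("chr1", 1e5)
  n_snp <- 4000
  f <- tibble::tibble(chrom = "chr1", pos = seq_len(n_snp),
                      p_anc = 0.5, A = 0.5)
  f$A[1:5] <- 1                      # fixed alt sites
  br <- breed_model("A", fst = 0.2, n_individuals = 20)
  gt <- simulate_genotypes(f, br, seed = 9)
  expect_equal(dim(gt$haplotypes), c(40L, n_snp))
  expect_true(all(gt$haplotypes[, 1:5] == 1L))
  dos <- haplotype_dosage(gt$haplotypes)
  het <- mean(dos[, -(1:5)] == 1L)
  expect_lt(abs(het - 0.5), 0.01)    # 2pq at p = 0.5
  gt2 <- simulate_genotypes(f, br, seed = 9)
  expect_identical(gt$haplotypes, gt2$haplotypes)
})

test_that("read counts follow the depth and error model", {
  f <- tibble::tibble(chrom = "chr1", pos = seq_len(10000),
                      p_anc = 0.5, A = 0)
  br <- breed_model("A", fst = 0.1, n_individuals = 2, mean_depth = 12,
                    base_error = 0)
  gt <- simulate_genotypes(f, br, seed = 2)
  rc <- simulate_read_counts(gt, br, seed = 2)
  expect_true(all(rc$alt_reads == 0))           # error-free hom-ref
  depth <- rc$ref_reads + rc$alt_reads
  expect_lt(abs(mean(depth) - 12), 0.2)         # Poisson mean over 10k sites

  # a heterozygote at depth ~1000 reads half alt
  f2 <- tibble::tibble(chrom = "chr1", pos = 1:500, p_anc = 0.5, A = 0.5)
  br2 <- breed_model("A", fst = 0.1, n_individuals = 1, mean_depth = 1000,
                     base_error = 0)
  gt2 <- simulate_genotypes(f2, br2, seed = 5)
  rc2 <- simulate_read_counts(gt2, br2, seed = 5)
  dos2 <- haplotype_dosage(gt2$haplotypes)
  het_sites <- which(dos2[1, ] == 1)
  frac <- rc2$alt_reads[1, het_sites] /
    (rc2$ref_reads[1, het_sites] + rc2$alt_reads[1, het_sites])
  expect_true(all(abs(frac - 0.5) < 0.05))
})

test_that("pooled read fractions recover the cohort allele frequencies at depth 1000", {
  g <- genome_spec("chr1", 2.5e5)
  br <- breed_model("A", fst = 0.15, n_individuals = 10, mean_depth = 1000,
                    base_error = 0.001)
  f <- simulate_frequencies(g, br, seed = 21)
  gt <- simulate_genotypes(f, br, seed = 21)
  rc <- simulate_read_counts(gt, br, seed = 21)
  pooled_frac <- colSums(rc$alt_reads) /
    colSums(rc$ref_reads + rc$alt_reads)
  # at depth 1000 the pooled read fraction converges on the frequency the
  # sampled haplotypes actually carry
  sample_freq <- colMeans(haplotype_dosage(gt$haplotypes)) / 2
  expect_lt(max(abs(pooled_frac - sample_freq)), 0.03)
})

test_that("sweep regions fail the per-breed MAF filter almost everywhere", {
  co <- study_cohort()
  calls <- as_calls(co)
  sw <- study_sweeps()
  n_inside <- 0
  n_failed <- 0
  for (b in co$breeds$name) {
    pooled <- pool_breed_counts(calls, co$samples, b)
    inside <- rep(FALSE, nrow(pooled))
    for (i in seq_len(nrow(sw))) {
      inside <- inside | (pooled$chrom == sw$chrom[i] &
                            pooled$pos > sw$start[i] &
                            pooled$pos <= sw$end[i])
    }
    kept <- maf_filter(pooled[inside, ], 0.05)
    n_inside <- n_inside + sum(inside)
    n_failed <- n_failed + (sum(inside) - nrow(kept))
  }
  expect_gte(n_failed / n_inside, 0.9)
})

test_that("the written cohort round-trips and honours its stated fractions", {
  co <- tiny_cohort()
  outdir <- withr::local_tempdir()
  paths <- write_cohort(co, outdir)
  calls <- read_vcf_genotypes(paths[["vcf"]])
  expect_true(all(calls$dosage == t(co$dosage)))
  expect_true(all(calls$ref_ad == t(co$reads$ref_reads)))
  expect_true(all(calls$alt_ad == t(co$reads$alt_reads)))
  expect_identical(calls$sites$pos, as.integer(co$snps$pos))

  # known-sites fraction 0.745 -> ~25.5% novel on re-ingest
  known <- read_known_sites(paths[["known_sites"]])
  flagged <- flag_novel(calls$sites, known)
  expect_lt(abs(novelty_fraction(flagged) - 0.255), 0.02)

  # chip has exactly n_probes probe positions for every genotyped animal
  chip <- read_chip_genotypes(paths[["chip"]])
  expect_equal(dplyr::n_distinct(chip$pos, chip$chrom), 300L)
  expect_true(all(table(chip$animal) == 300L))

  gm <- read_gene_models(paths[["genes"]])
  expect_equal(nrow(gm), nrow(co$gene_models))
  expect_setequal(unique(gm$type),
                  c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"))
})

test_that("identical seeds reproduce byte-identical cohort files", {
  g <- genome_spec("chr1", 2e5)
  br <- breed_model("A", 0.2, 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(g, br, chip = chip_spec(50), seed = 13), d1)
  write_cohort(simulate_cohort(g, br, chip = chip_spec(50), seed = 13), d2)
  for (f in c("cohort.vcf", "genes.gff3", "reference.fa",
              "chip_genotypes.tsv", "known_sites.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  d3 <- withr::local_tempdir()
  write_cohort(simulate_cohort(g, br, chip = chip_spec(50), seed = 14), d3)
  expect_false(identical(readLines(file.path(d1, "cohort.vcf")),
                         readLines(file.path(d3, "cohort.vcf"))))
})

test_that("designed ORFs are real open reading frames", {
  co <- tiny_cohort()
  cds <- co$gene_models[co$gene_models$type == "CDS", ]
  for (txid in unique(cds$transcript)[1:5]) {
    rows <- cds[cds$transcript == txid, ]
    rows <- rows[order(rows$start), ]
    seq_asc <- paste0(as.character(Biostrings::extractAt(
      co$reference[[rows$chrom[1]]],
      IRanges::IRanges(rows$start, rows$end)
    )), collapse = "")
    if (rows$strand[1] == "-") {
      seq_asc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq_asc)
      ))
    }
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(seq_asc)))
    expect_identical(substr(aa, 1, 1), "M")
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})
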