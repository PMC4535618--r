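# Pooled-heterozygosity scan: pooling, filtering, windowing, Hp, ZHp, calls.

test_that("pooling sums allele depths per breed with the stated tie rule", {
  sites <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L, 300L),
                          ref = "A", alt = "G")
  ref_ad <- cbind(s1 = c(10, 5, 0), s2 = c(8, 2, 0), s3 = c(9, 3, 0))
  alt_ad <- cbind(s1 = c(2, 5, 0), s2 = c(1, 2, 0), s3 = c(0, 3, 0))
  calls <- make_calls(sites, ref_ad, alt_ad)
  pooled <- pool_breed_counts(calls, calls$samples, "A")
  expect_equal(nrow(pooled), 2L)                # zero-read site dropped
  expect_equal(pooled$major_count[1], 27)       # (10,2)+(8,1)+(9,0)
  expect_equal(pooled$minor_count[1], 3)
  expect_equal(pooled$major_allele[1], "A")
  expect_equal(pooled$major_allele[2], "A")     # tie (10, 10): ref is major
  expect_equal(pooled$major_count[2], 10)
  expect_equal(pooled$minor_count[2], 10)

  calls$ref_ad[2, "s2"] <- NA
  expect_error(pool_breed_counts(calls, calls$samples, "A"),
               "missing AD for sample 's2' at chr1:200")
  expect_error(pool_breed_counts(calls, calls$samples, "Z"), "no samples")
})

test_that("the MAF filter removes strictly-below-threshold SNPs", {
  pooled <- tibble::tibble(
    breed = "A", chrom = "chr1", pos = c(1L, 2L, 3L),
    major_allele = "A", minor_allele = "G",
    major_count = c(96, 95, 50), minor_count = c(4, 5, 50)
  )
  out <- maf_filter(pooled, 0.05)
  expect_identical(out$pos, c(2L, 3L))   # 0.04 removed, 0.05 and 0.5 kept
  expect_error(maf_filter(pooled, 0), "threshold")
  expect_error(maf_filter(pooled, 0.6), "threshold")
})

test_that("window tiling matches the closed form and brute-force enumeration", {
  g <- genome_spec("chr1", 3e5)
  w <- make_windows(g)
  expect_equal(nrow(w), 3L)
  expect_equal(w$start, c(0, 75000, 150000))
  expect_equal(w$end, c(150000, 225000, 300000))
  expect_equal(nrow(make_windows(genome_spec("chr1", 150000))), 1L)
  expect_equal(nrow(make_windows(genome_spec("chr1", 149999))), 0L)

  withr::with_seed(42, {
    lengths <- sample(1e5:2e6, 50)
  })
  for (L in lengths) {
    got <- nrow(make_windows(genome_spec("chr1", L)))
    brute <- 0
    s <- 0
    while (s + 150000 <= L) {
      brute <- brute + 1
      s <- s + 75000
    }
    expect_equal(got, brute)
    if (L >= 150000) {
      expect_equal(got, floor((L - 150000) / 75000) + 1)
    }
  }
})

test_that("window Hp matches hand arithmetic and the exclusion rule", {
  g <- genome_spec("chr1", 150000)
  w <- make_windows(g)
  mk <- function(n, maj, minc) {
    tibble::tibble(breed = "A", chrom = "chr1",
                   pos = as.integer(seq(1000, by = 1000, length.out = n)),
                   major_allele = "A", minor_allele = "G",
                   major_count = maj, minor_count = minc)
  }
  st <- window_hp(mk(10, 9, 3), w)
  expect_equal(st$sum_maj, 90)
  expect_equal(st$sum_min, 30)
  expect_equal(st$hp, 0.375)              # 2*90*30 / 120^2
  expect_false(st$excluded)

  expect_equal(window_hp(mk(10, 12, 0), w)$hp, 0)        # homozygous window
  expect_equal(window_hp(mk(10, 6, 6), w)$hp, 0.5)       # max heterozygosity

  st9 <- window_hp(mk(9, 9, 3), w)
  expect_true(st9$excluded)               # fewer than 10 SNPs
  expect_true(is.na(st9$hp))
})

test_that("window membership uses the (start, end] convention", {
  g <- genome_spec("chr1", 3e5)
  w <- make_windows(g)
  pooled <- tibble::tibble(
    breed = "A", chrom = "chr1",
    pos = c(1L, 75000L, 75001L, 150000L, 150001L, 300000L),
    major_allele = "A", minor_allele = "G",
    major_count = 10, minor_count = 5
  )
  st <- window_hp(pooled, w, min_snps = 1)
  # window [0, 150000]: positions 1..150000; [75000, 225000]: 75001..225000
  expect_equal(st$n_snps, c(4L, 3L, 2L))
  # interior SNPs fall in exactly two windows
  expect_equal(sum(st$n_snps), 9L)
})

test_that("ZHp standardization matches the worked example and its invariants", {
  st <- tibble::tibble(
    chrom = "chr1", start = c(0, 75000, 150000),
    end = c(150000, 225000, 300000), index = 1:3, breed = "A",
    n_snps = 20L, sum_maj = 100, sum_min = 50,
    hp = c(0.1, 0.2, 0.3), excluded = FALSE
  )
  z <- zhp_transform(st)
  expect_equal(z$zhp, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(mean(z$zhp), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z$zhp^2)), 1, tolerance = 1e-12)

  st_flat <- dplyr::mutate(st, hp = 0.2)
  expect_error(zhp_transform(st_flat), "identical Hp")
  expect_error(zhp_transform(st[1, ]), "at least 2 retained")
})

test_that("sweep calling is strict and annotates overlapping genes", {
  st <- tibble::tibble(
    chrom = "chr1", start = c(0, 75000, 150000),
    end = c(150000, 225000, 300000), index = 1:3, breed = "A",
    n_snps = 20L, sum_maj = 100, sum_min = 50,
    hp = 0.1, excluded = FALSE, zhp = c(-2.0, -2.96, 0.5)
  )
  gm <- tibble::tibble(chrom = "chr1", start = 80000, end = 90000,
                       strand = "+", type = "exon", transcript = "T1",
                       gene = "CLDN1", coding = TRUE)
  calls <- call_sweeps(st, threshold = -2, gene_models = gm)
  expect_equal(nrow(calls), 1L)          # -2.0 exactly is NOT called
  expect_equal(calls$zhp, -2.96)
  expect_equal(calls$genes, "CLDN1")
  expect_equal(nrow(call_sweeps(st[0, ])), 0L)
})

test_that("per-SNP Hp endpoints match the worked values", {
  pooled <- tibble::tibble(
    breed = "A", chrom = "chr1", pos = c(10L, 20L, 30L),
    major_allele = "A", minor_allele = "G",
    major_count = c(6, 12, 9), minor_count = c(6, 0, 3)
  )
  tr <- per_snp_hp_track(pooled, "chr1", 0, 100)
  expect_equal(tr$hp_snp, c(0.5, 0, 0.375))
  expect_equal(nrow(per_snp_hp_track(pooled, "chr1", 500, 600)), 0L)
})

test_that("window Hp agrees with a brute-force re-read of the VCF", {
  co <- tiny_cohort()
  outdir <- withr::local_tempdir()
  paths <- write_cohort(co, outdir)
  calls <- read_vcf_genotypes(paths[["vcf"]])
  pooled <- pool_breed_counts(calls, co$samples, "A")
  w <- make_windows(tiny_genome())
  st <- window_hp(pooled, w)

  # oracle: parse the VCF text directly and sum AD per window
  lines <- readLines(paths[["vcf"]])
  header <- strsplit(lines[grepl("^#CHROM", lines)], "\t")[[1]]
  body <- strsplit(lines[!grepl("^#", lines)], "\t")
  a_cols <- which(header %in% co$samples$sample[co$samples$breed == "A"])
  for (k in c(1, 5, 9)) {
    win <- st[st$chrom == "chr1", ][k, ]
    sum_maj <- 0
    sum_min <- 0
    n <- 0
    for (rec in body) {
      if (rec[1] != "chr1") next
      p <- as.integer(rec[2])
      if (p <= win$start || p > win$end) next
      ads <- vapply(rec[a_cols], function(x) {
        as.integer(strsplit(strsplit(x, ":")[[1]][2], ",")[[1]])
      }, integer(2))
      ref_sum <- sum(ads[1, ])
      alt_sum <- sum(ads[2, ])
      if (ref_sum + alt_sum == 0) next
      n <- n + 1
      sum_maj <- sum_maj + max(ref_sum, alt_sum)
      sum_min <- sum_min + min(ref_sum, alt_sum)
    }
    expect_equal(win$n_snps, n)
    expect_equal(win$sum_maj, sum_maj)
    expect_equal(win$sum_min, sum_min)
    expect_equal(win$hp, 2 * sum_maj * sum_min / (sum_maj + sum_min)^2)
  }
})

test_that("a breed-private sweep depresses its own windows only", {
  co <- tiny_cohort()
  scan <- scan_sweeps(as_calls(co), co$samples, tiny_genome())
  sw <- tiny_sweep()
  in_sweep <- scan$windows$chrom == sw$chrom &
    scan$windows$start < sw$end & scan$windows$end > sw$start
  a_in <- scan$windows$zhp[in_sweep & scan$windows$breed == "A"]
  a_out <- scan$windows$zhp[!in_sweep & scan$windows$breed == "A" &
                              !scan$windows$excluded]
  b_in <- scan$windows$zhp[in_sweep & scan$windows$breed == "B"]
  expect_lt(max(a_in), min(a_out))      # swept windows are the lowest
  expect_gt(mean(b_in), -2)             # unaffected breed is not called there
  expect_true(all(scan$calls$breed == "A"))
  # hp range invariant
  hp <- scan$windows$hp[!scan$windows$excluded]
  expect_true(all(hp >= 0 & hp <= 0.5))
})

test_that("the scan is deterministic and tidies into tables", {
  co <- tiny_cohort()
  s1 <- scan_sweeps(as_calls(co), co$samples, tiny_genome())
  s2 <- scan_sweeps(as_calls(co), co$samples, tiny_genome())
  expect_identical(s1$windows, s2$windows)
  expect_s3_class(tidy(s1), "tbl_df")
  g <- glance(s1)
  expect_setequal(g$breed, c("A", "B"))
  expect_true(all(g$n_windows == g$n_excluded + g$n_retained))
})
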