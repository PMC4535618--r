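# Multi-breed cohort simulator.
#
# All randomness flows from one master seed through named sub-streams
# ("frequencies", "genes", "reference", "alleles", "genotypes", "reads",
# "known", "sift", "chip"), so each stage is independently reproducible.

#' Simulate ancestral and per-breed allele frequencies
#'
#' Ancestral alternate-allele frequencies are drawn from Uniform(0.05, 0.95)
#' (avoiding degenerate monomorphic sites); each breed's frequency is drawn
#' from the Balding-Nichols distribution, i.e. Beta with mean equal to the
#' ancestral frequency and variance governed by the breed's Fst. A breed with
#' Fst = 0 reproduces the ancestral frequency exactly.
#'
#' @param genome A [genome_spec()] tibble.
#' @param breeds A breed tibble, e.g. [default_breeds()].
#' @param seed Master seed (sub-stream "frequencies").
#' @param snp_density Expected SNPs per bp; defaults to the genome's.
#'
#' @return A tibble with one row per SNP: `chrom`, `pos` (1-based, strictly
#'   increasing within a chromosome), `p_anc`, and one alternate-allele
#'   frequency column per breed.
#' @export
simulate_frequencies <- function(genome, breeds, seed,
                                 snp_density = genome_snp_density(genome)) {
  if (nrow(genome) == 0) abort("empty genome")
  if (nrow(breeds) == 0) abort("no breeds supplied")
  with_stream(seed, "frequencies", {
    sites <- purrr::pmap(genome, function(chrom, length, ...) {
      n <- max(1L, stats::rpois(1, length * snp_density))
      n <- min(n, length)
      tibble(chrom = chrom, pos = sort(sample.int(length, n)))
    }) |>
      bind_rows()
    sites$p_anc <- stats::runif(nrow(sites), 0.05, 0.95)
    for (i in seq_len(nrow(breeds))) {
      fst <- breeds$fst[i]
      p <- sites$p_anc
      sites[[breeds$name[i]]] <- if (fst == 0) {
        p
      } else {
        stats::rbeta(length(p), p * (1 - fst) / fst,
                     (1 - p) * (1 - fst) / fst)
      }
    }
    sites
  })
}

#' Embed selective sweeps into a frequency table
#'
#' For every SNP inside a sweep interval, the affected breeds' minor-allele
#' frequency is set to the sweep's `residual_maf`. The major allele is the
#' currently more frequent allele in that breed at that SNP (reference wins a
#' tie). SNPs outside the intervals, and unaffected breeds, are untouched.
#'
#' @param freqs A frequency table from [simulate_frequencies()].
#' @param sweeps A tibble of [sweep_spec()] rows.
#' @param genome The [genome_spec()] used to generate `freqs` (interval
#'   validation).
#'
#' @return The modified frequency table.
#' @export
apply_sweeps <- function(freqs, sweeps, genome) {
  if (is.null(sweeps) || nrow(sweeps) == 0) {
    return(freqs)
  }
  for (i in seq_len(nrow(sweeps))) {
    sw <- sweeps[i, ]
    len <- genome$length[match(sw$chrom, genome$chrom)]
    if (is.na(len)) {
      abort(sprintf("sweep chromosome '%s' is not in the genome", sw$chrom))
    }
    if (sw$end > len) {
      abort(sprintf("sweep interval %s:%d-%d runs off the chromosome",
                    sw$chrom, sw$start, sw$end))
    }
    inside <- freqs$chrom == sw$chrom &
      freqs$pos > sw$start & freqs$pos <= sw$end
    for (breed in sw$breeds[[1]]) {
      if (!breed %in% names(freqs)) {
        abort(sprintf("sweep names unknown breed '%s'", breed))
      }
      f <- freqs[[breed]][inside]
      # frequencies are alt-allele frequencies; alt is major iff f > 0.5
      freqs[[breed]][inside] <- ifelse(f > 0.5,
                                       1 - sw$residual_maf, sw$residual_maf)
    }
  }
  freqs
}

#' Simulate phased genotypes under Hardy-Weinberg equilibrium
#'
#' Each haplotype allele is an independent Bernoulli draw from the breed's
#' alternate-allele frequency.
#'
#' @param freqs Frequency table ([simulate_frequencies()], possibly after
#'   [apply_sweeps()]).
#' @param breeds Breed tibble.
#' @param seed Master seed (sub-stream "genotypes").
#'
#' @return A list with `haplotypes`, an integer matrix of 0/1 alleles with
#'   `2 * sum(n_individuals)` rows (two consecutive rows per individual) and
#'   one column per SNP, and `samples`, a tibble mapping sample to breed.
#' @export
simulate_genotypes <- function(freqs, breeds, seed) {
  n_snp <- nrow(freqs)
  with_stream(seed, "genotypes", {
    blocks <- list()
    samples <- list()
    for (i in seq_len(nrow(breeds))) {
      breed <- breeds$name[i]
      n <- breeds$n_individuals[i]
      p <- freqs[[breed]]
      h <- matrix(stats::rbinom(2L * n * n_snp, 1L, rep(p, each = 2L * n)),
                  nrow = 2L * n)
      ids <- sprintf("%s_%02d", breed, seq_len(n))
      rownames(h) <- paste0(rep(ids, each = 2), c("_1", "_2"))
      blocks[[i]] <- h
      samples[[i]] <- tibble(sample = ids, breed = breed)
    }
    list(haplotypes = do.call(rbind, blocks), samples = bind_rows(samples))
  })
}

#' Collapse a phased haplotype matrix to per-individual allele dosages
#'
#' @param haplotypes The haplotype matrix from [simulate_genotypes()].
#' @return An integer matrix of 0/1/2 dosages, individuals in rows.
#' @export
haplotype_dosage <- function(haplotypes) {
  odd <- seq(1, nrow(haplotypes), by = 2)
  d <- haplotypes[odd, , drop = FALSE] + haplotypes[odd + 1, , drop = FALSE]
  rownames(d) <- sub("_1$", "", rownames(haplotypes)[odd])
  d
}

#' Simulate per-individual sequencing read counts
#'
#' Depth at each individual-site is Poisson with the breed's mean depth; each
#' read reports one of the individual's two haplotype alleles chosen
#' uniformly, flipped with the breed's per-read base error probability. So a
#' read is an alternate-allele read with probability
#' `dosage/2 * (1 - 2e) + e`.
#'
#' @param genotypes The list returned by [simulate_genotypes()].
#' @param breeds Breed tibble.
#' @param seed Master seed (sub-stream "reads").
#'
#' @return A list of integer matrices `ref_reads` and `alt_reads`
#'   (individuals x SNPs); their sum is the sampled depth.
#' @export
simulate_read_counts <- function(genotypes, breeds, seed) {
  dosage <- haplotype_dosage(genotypes$haplotypes)
  samples <- genotypes$samples
  depth_mean <- breeds$mean_depth[match(samples$breed, breeds$name)]
  err <- breeds$base_error[match(samples$breed, breeds$name)]
  n_ind <- nrow(dosage)
  n_snp <- ncol(dosage)
  with_stream(seed, "reads", {
    depth <- matrix(stats::rpois(n_ind * n_snp, rep(depth_mean, n_snp)),
                    nrow = n_ind)
    p_alt <- dosage / 2 * (1 - 2 * rep(err, n_snp)) + rep(err, n_snp)
    alt <- matrix(stats::rbinom(n_ind * n_snp, depth, p_alt), nrow = n_ind)
    ref <- depth - alt
    dimnames(ref) <- dimnames(alt) <- dimnames(dosage)
    list(ref_reads = ref, alt_reads = alt)
  })
}

# --- gene models -----------------------------------------------------------

# Map a slice [from, to] of spliced-transcript coordinates back to genomic
# intervals. `ex_start`/`ex_end` are exon intervals in transcript order
# (genomically ascending for "+", descending for "-").
tx_slice_to_genomic <- function(ex_start, ex_end, strand, from, to) {
  lens <- ex_end - ex_start + 1
  cum <- cumsum(lens)
  out <- list()
  for (i in seq_along(lens)) {
    lo <- cum[i] - lens[i] + 1
    hi <- cum[i]
    a <- max(from, lo)
    b <- min(to, hi)
    if (a > b) next
    if (strand == "+") {
      out[[length(out) + 1]] <- c(ex_start[i] + (a - lo),
                                  ex_start[i] + (b - lo))
    } else {
      out[[length(out) + 1]] <- c(ex_end[i] - (b - lo),
                                  ex_end[i] - (a - lo))
    }
  }
  m <- do.call(rbind, out)
  tibble(start = m[, 1], end = m[, 2])
}

#' Simulate canonical gene models
#'
#' Places non-overlapping transcripts (one per gene, 2-5 exons each) along
#' every chromosome. A stated fraction are protein coding, with a 5' UTR, a
#' CDS whose length is a multiple of 3, and a 3' UTR; the rest are
#' non-coding (exons only). This deliberately simplifies real gene
#' annotation: one transcript per gene, no overlapping loci, no alternative
#' splicing.
#'
#' @param genome A [genome_spec()] tibble.
#' @param seed Master seed (sub-stream "genes").
#' @param genes_per_mb Expected gene count per megabase.
#' @param coding_fraction Fraction of transcripts that are protein coding.
#'
#' @return A tibble of feature rows: `chrom`, `start`, `end` (1-based,
#'   inclusive), `strand`, `type` (one of `exon`, `CDS`, `five_prime_UTR`,
#'   `three_prime_UTR`), `transcript`, `gene`, `coding`.
#' @export
simulate_gene_models <- function(genome, seed, genes_per_mb = 10,
                                 coding_fraction = 0.85) {
  with_stream(seed, "genes", {
    rows <- list()
    gene_i <- 0
    for (ci in seq_len(nrow(genome))) {
      chrom <- genome$chrom[ci]
      chrom_len <- genome$length[ci]
      gap_mean <- max(1e6 / genes_per_mb, 2e4)
      cur <- 1 + sample(2000:20000, 1)
      repeat {
        n_ex <- sample(2:5, 1)
        ex_len <- sample(150:450, n_ex, replace = TRUE)
        intr_len <- if (n_ex > 1) sample(200:1500, n_ex - 1, TRUE) else integer()
        span <- sum(ex_len) + sum(intr_len)
        if (cur + span > chrom_len - 2000) break
        gene_i <- gene_i + 1
        strand <- sample(c("+", "-"), 1)
        coding <- stats::runif(1) < coding_fraction
        gene <- sprintf("GENE%04d", gene_i)
        txid <- sprintf("TX%04d", gene_i)
        # genomic exon intervals, ascending
        ex_start <- cur + cumsum(c(0, head(ex_len, -1) + intr_len))
        ex_end <- ex_start + ex_len - 1
        base <- tibble(chrom = chrom, strand = strand,
                       transcript = txid, gene = gene, coding = coding)
        rows[[length(rows) + 1]] <-
          bind_cols(base[rep(1, n_ex), ],
                    tibble(start = ex_start, end = ex_end, type = "exon"))
        if (coding) {
          # exons in transcript order for coordinate mapping
          ord <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
          tes <- ex_start[ord]
          tee <- ex_end[ord]
          total <- sum(ex_len)
          utr5 <- sample(30:120, 1)
          utr3 <- sample(50:250, 1)
          utr3 <- min(utr3, total - utr5 - 12)
          cds0 <- total - utr5 - utr3
          utr3 <- utr3 + cds0 %% 3
          cds_len <- total - utr5 - utr3
          pieces <- list(
            five_prime_UTR = c(1, utr5),
            CDS = c(utr5 + 1, utr5 + cds_len),
            three_prime_UTR = c(utr5 + cds_len + 1, total)
          )
          for (ty in names(pieces)) {
            iv <- tx_slice_to_genomic(tes, tee, strand,
                                      pieces[[ty]][1], pieces[[ty]][2])
            rows[[length(rows) + 1]] <-
              bind_cols(base[rep(1, nrow(iv)), ],
                        tibble(start = iv$start, end = iv$end, type = ty))
          }
        }
        cur <- cur + span + sample(round(gap_mean / 2):round(gap_mean * 3 / 2), 1)
      }
    }
    bind_rows(rows) |>
      select("chrom", "start", "end", "strand", "type",
             "transcript", "gene", "coding") |>
      arrange(.data$chrom, .data$start, .data$type)
  })
}

# --- reference sequence ----------------------------------------------------

#' Build a reference genome sequence consistent with the gene models
#'
#' Random background sequence, with every coding transcript's spliced CDS
#' overwritten by a designed open reading frame (ATG start, sense codons, one
#' stop) and canonical GT/AG splice dinucleotides written into each intron.
#'
#' @param genome A [genome_spec()] tibble.
#' @param gene_models Output of [simulate_gene_models()].
#' @param seed Master seed (sub-stream "reference").
#'
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
build_reference <- function(genome, gene_models, seed) {
  bases <- c("A", "C", "G", "T")
  sense_codons <- {
    all3 <- do.call(paste0, expand.grid(bases, bases, bases,
                                        stringsAsFactors = FALSE))
    setdiff(all3, c("TAA", "TAG", "TGA"))
  }
  stops <- c("TAA", "TAG", "TGA")
  with_stream(seed, "reference", {
    seqs <- purrr::pmap(genome, function(chrom, length, ...) {
      chars <- bases[sample.int(4, length, replace = TRUE)]
      gm <- gene_models[gene_models$chrom == chrom, ]
      for (txid in unique(gm$transcript)) {
        tx <- gm[gm$transcript == txid, ]
        strand <- tx$strand[1]
        # splice dinucleotides from the exon structure
        ex <- tx[tx$type == "exon", ]
        ex <- ex[order(ex$start), ]
        if (nrow(ex) > 1) {
          for (k in seq_len(nrow(ex) - 1)) {
            gs <- ex$end[k] + 1
            ge <- ex$start[k + 1] - 1
            if (ge - gs + 1 < 4) next
            if (strand == "+") {
              chars[gs:(gs + 1)] <- c("G", "T")
              chars[(ge - 1):ge] <- c("A", "G")
            } else {
              chars[(ge - 1):ge] <- c("A", "C")   # complement of reversed GT
              chars[gs:(gs + 1)] <- c("C", "T")   # complement of reversed AG
            }
          }
        }
        if (!tx$coding[1]) next
        cds <- tx[tx$type == "CDS", ]
        cds <- cds[order(cds$start, decreasing = (strand == "-")), ]
        pos <- unlist(purrr::map2(cds$start, cds$end, function(s, e) {
          if (strand == "+") seq(s, e) else seq(e, s)
        }))
        n_codon <- length(pos) / 3
        orf <- c("ATG",
                 sample(sense_codons, n_codon - 2, replace = TRUE),
                 sample(stops, 1))
        cds_chars <- strsplit(paste0(orf, collapse = ""), "")[[1]]
        if (strand == "+") {
          chars[pos] <- cds_chars
        } else {
          chars[pos] <- complement_base(cds_chars)
        }
      }
      paste0(chars, collapse = "")
    })
    Biostrings::DNAStringSet(setNames(unlist(seqs), genome$chrom))
  })
}

#' Assign reference and alternate alleles to simulated SNPs
#'
#' The reference allele is the base of the reference sequence at the SNP
#' position; the alternate is the transition partner with probability
#' `ti_fraction`, otherwise one of the two transversions, uniformly. The
#' default 2:1 transition:transversion mix matches the genome-wide Ti/Tv of
#' roughly 2 expected in mammalian resequencing.
#'
#' @param freqs Frequency table (alt-allele frequencies).
#' @param reference A [Biostrings::DNAStringSet] named by chromosome.
#' @param seed Master seed (sub-stream "alleles").
#' @param ti_fraction Probability that a SNP is a transition.
#'
#' @return `freqs` with `ref` and `alt` columns added.
#' @export
assign_alleles <- function(freqs, reference, seed, ti_fraction = 2 / 3) {
  bases <- c("A", "C", "G", "T")
  ref <- character(nrow(freqs))
  for (chrom in unique(freqs$chrom)) {
    idx <- which(freqs$chrom == chrom)
    ref[idx] <- strsplit(as.character(
      Biostrings::extractAt(reference[[chrom]],
                            IRanges::IRanges(freqs$pos[idx], width = 1))
    ), NULL) |> unlist()
  }
  with_stream(seed, "alleles", {
    is_ti <- stats::runif(nrow(freqs)) < ti_fraction
    alt <- ifelse(is_ti, TRANSITION_PARTNER[ref], NA)
    tv_idx <- which(!is_ti)
    if (length(tv_idx) > 0) {
      alt[tv_idx] <- vapply(ref[tv_idx], function(b) {
        sample(setdiff(bases, c(b, TRANSITION_PARTNER[b])), 1)
      }, character(1))
    }
    freqs$ref <- ref
    freqs$alt <- unname(alt)
    freqs
  })
}

# --- chip ------------------------------------------------------------------

#' Simulate chip genotypes with injected error and missingness
#'
#' Probes are drawn uniformly (without replacement) from the simulated SNP
#' positions; the first `animals_per_breed` animals of each breed are
#' genotyped. With probability `genotype_error` a call is flipped to a
#' uniformly chosen different genotype; with probability `missing_rate` it is
#' set missing (alleles reported as "."). Alleles are reported as
#' reference-strand bases.
#'
#' @param snps SNP table with `chrom`, `pos`, `ref`, `alt`.
#' @param dosage Dosage matrix (individuals x SNPs) from
#'   [haplotype_dosage()].
#' @param samples Sample-to-breed tibble.
#' @param chip A [chip_spec()].
#' @param seed Master seed (sub-stream "chip").
#'
#' @return A tibble: `animal`, `chrom`, `pos`, `allele1`, `allele2`.
#' @export
simulate_chip <- function(snps, dosage, samples, chip, seed) {
  if (chip$n_probes > nrow(snps)) {
    abort("`n_probes` exceeds the number of simulated SNPs")
  }
  with_stream(seed, "chip", {
    probe_idx <- sort(sample.int(nrow(snps), chip$n_probes))
    animals <- samples |>
      group_by(.data$breed) |>
      slice_head(n = chip$animals_per_breed) |>
      ungroup() |>
      pull(.data$sample)
    out <- list()
    for (a in animals) {
      g <- dosage[a, probe_idx]
      flip <- stats::runif(length(g)) < chip$genotype_error
      if (any(flip)) {
        g[flip] <- vapply(g[flip], function(x) sample(setdiff(0:2, x), 1),
                          numeric(1))
      }
      miss <- stats::runif(length(g)) < chip$missing_rate
      ref <- snps$ref[probe_idx]
      alt <- snps$alt[probe_idx]
      a1 <- ifelse(g >= 1, alt, ref)
      a2 <- ifelse(g == 2, alt, ref)
      a1[miss] <- "."
      a2[miss] <- "."
      out[[a]] <- tibble(animal = a, chrom = snps$chrom[probe_idx],
                         pos = snps$pos[probe_idx], allele1 = a1, allele2 = a2)
    }
    bind_rows(out)
  })
}

# --- cohort assembly -------------------------------------------------------

#' Simulate a complete multi-breed cohort
#'
#' Runs the full generator: frequencies, sweeps, gene models, reference
#' sequence, alleles, phased genotypes, read counts, known-sites list, SIFT
#' score table and chip genotypes.
#'
#' @param genome A [genome_spec()].
#' @param breeds Breed tibble (default [default_breeds()]).
#' @param sweeps Optional tibble of [sweep_spec()] rows.
#' @param chip Optional [chip_spec()]; `NULL` skips the chip.
#' @param seed Master seed for all sub-streams.
#' @param known_fraction Fraction of SNP positions placed on the known-sites
#'   list (default 0.745, i.e. about 25.5% of sites are novel on re-ingest).
#' @param ti_fraction Transition fraction for [assign_alleles()].
#' @param sift_coverage Fraction of coding SNPs given a SIFT score.
#' @param genes_per_mb,coding_fraction Passed to [simulate_gene_models()].
#'
#' @return A list of class `pig_cohort` bundling every simulated component
#'   and the truth needed by tests (frequencies, sweep intervals, error
#'   rates).
#' @export
simulate_cohort <- function(genome, breeds = default_breeds(), sweeps = NULL,
                            chip = chip_spec(5000), seed = 1,
                            known_fraction = 0.745, ti_fraction = 2 / 3,
                            sift_coverage = 0.8, genes_per_mb = 10,
                            coding_fraction = 0.85) {
  freqs <- simulate_frequencies(genome, breeds, seed)
  freqs <- apply_sweeps(freqs, sweeps, genome)
  gene_models <- simulate_gene_models(genome, seed,
                                      genes_per_mb = genes_per_mb,
                                      coding_fraction = coding_fraction)
  reference <- build_reference(genome, gene_models, seed)
  snps <- assign_alleles(freqs, reference, seed, ti_fraction = ti_fraction)
  genotypes <- simulate_genotypes(snps, breeds, seed)
  reads <- simulate_read_counts(genotypes, breeds, seed)
  dosage <- haplotype_dosage(genotypes$haplotypes)

  known_sites <- with_stream(seed, "known", {
    keep <- stats::runif(nrow(snps)) < known_fraction
    snps[keep, c("chrom", "pos")]
  })

  cds <- gene_models[gene_models$type == "CDS", ]
  sift <- NULL
  if (nrow(cds) > 0) {
    snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                     IRanges::IRanges(snps$pos, width = 1))
    cds_gr <- GenomicRanges::GRanges(cds$chrom,
                                     IRanges::IRanges(cds$start, cds$end))
    hits <- GenomicRanges::findOverlaps(snp_gr, cds_gr)
    coding_snp <- unique(S4Vectors::queryHits(hits))
    tx_of <- cds$transcript[S4Vectors::subjectHits(hits)[
      match(coding_snp, S4Vectors::queryHits(hits))]]
    sift <- with_stream(seed, "sift", {
      keep <- stats::runif(length(coding_snp)) < sift_coverage
      tibble(
        transcript = tx_of[keep],
        chrom = snps$chrom[coding_snp[keep]],
        pos = snps$pos[coding_snp[keep]],
        alt = snps$alt[coding_snp[keep]],
        score = stats::runif(sum(keep))
      )
    })
  }

  chip_geno <- if (!is.null(chip)) {
    simulate_chip(snps, dosage, genotypes$samples, chip, seed)
  }

  structure(
    list(
      genome = genome, breeds = breeds, sweeps = sweeps, chip = chip,
      snps = snps, gene_models = gene_models, reference = reference,
      haplotypes = genotypes$haplotypes, samples = genotypes$samples,
      dosage = dosage, reads = reads, known_sites = known_sites,
      sift = sift, chip_genotypes = chip_geno,
      params = list(seed = seed, known_fraction = known_fraction,
                    ti_fraction = ti_fraction, sift_coverage = sift_coverage)
    ),
    class = "pig_cohort"
  )
}

#' Turn a simulated cohort into the call set the analysis functions expect
#'
#' Produces the same structure [read_vcf_genotypes()] yields after a VCF
#' round trip: a sites tibble plus variants-by-samples matrices.
#'
#' @param cohort A `pig_cohort` from [simulate_cohort()].
#' @return A list of class `cohort_calls` with elements `sites` (`chrom`,
#'   `pos`, `ref`, `alt`), `dosage`, `hap1`, `hap2`, `ref_ad`, `alt_ad`
#'   (variants x samples) and `samples`.
#' @export
as_calls <- function(cohort) {
  odd <- seq(1, nrow(cohort$haplotypes), by = 2)
  hap1 <- t(cohort$haplotypes[odd, , drop = FALSE])
  hap2 <- t(cohort$haplotypes[odd + 1, , drop = FALSE])
  colnames(hap1) <- colnames(hap2) <- sub("_1$", "", colnames(hap1))
  structure(
    list(
      sites = cohort$snps[, c("chrom", "pos", "ref", "alt")],
      dosage = t(cohort$dosage),
      hap1 = hap1,
      hap2 = hap2,
      ref_ad = t(cohort$reads$ref_reads),
      alt_ad = t(cohort$reads$alt_reads),
      samples = cohort$samples
    ),
    class = "cohort_calls"
  )
}
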