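# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- builder()
  }
  .fixture_cache[[key]]
}

# A small two-breed cohort with one breed-private sweep — quick enough for
# module tests.
tiny_genome <- function() genome_spec(c("chr1", "chr2"), c(1e6, 8e5))

tiny_breeds <- function() {
  dplyr::bind_rows(
    breed_model("A", fst = 0.2, n_individuals = 6),
    breed_model("B", fst = 0.1, n_individuals = 6)
  )
}

tiny_sweep <- function() sweep_spec("chr1", 3e5, 6e5, "A", residual_maf = 0.01)

tiny_cohort <- function() {
  memo("tiny_cohort", function() {
    simulate_cohort(tiny_genome(), tiny_breeds(), sweeps = tiny_sweep(),
                    chip = chip_spec(300, genotype_error = 0.01,
                                     missing_rate = 0.02),
                    seed = 7)
  })
}

# The study-scale cohort: 5 chromosomes x 4 Mb, one SNP per ~500 bp, five
# breeds of 10 animals at ~12x, and three 300 kb sweeps shared by all breeds
# (residual MAF 0.01). Chip: 5,000 probes with 1% genotype error.
study_genome <- function() genome_spec(paste0("chr", 1:5), rep(4e6, 5))

study_breeds <- function() {
  dplyr::bind_rows(
    breed_model("KWB", 0.25, 10, 12, 0.001),
    breed_model("KNP", 0.18, 10, 12, 0.001),
    breed_model("DUR", 0.12, 10, 12, 0.001),
    breed_model("LAN", 0.10, 10, 12, 0.001),
    breed_model("YOR", 0.10, 10, 12, 0.001)
  )
}

study_sweeps <- function() {
  all5 <- c("KWB", "KNP", "DUR", "LAN", "YOR")
  dplyr::bind_rows(
    sweep_spec("chr1", 1.0e6, 1.3e6, all5, residual_maf = 0.01),
    sweep_spec("chr2", 2.0e6, 2.3e6, all5, residual_maf = 0.01),
    sweep_spec("chr4", 0.5e6, 0.8e6, all5, residual_maf = 0.01)
  )
}

study_cohort <- function() {
  memo("study_cohort", function() {
    simulate_cohort(study_genome(), study_breeds(), sweeps = study_sweeps(),
                    chip = chip_spec(5000, genotype_error = 0.01,
                                     missing_rate = 0),
                    seed = 55)
  })
}

study_scan <- function() {
  memo("study_scan", function() {
    co <- study_cohort()
    scan_sweeps(as_calls(co), co$samples, study_genome())
  })
}

# Build a cohort_calls object by hand for small worked examples.
make_calls <- function(sites, ref_ad, alt_ad, dosage = NULL, breed = "A") {
  samples <- colnames(ref_ad)
  structure(
    list(sites = sites, dosage = dosage, hap1 = NULL, hap2 = NULL,
         ref_ad = ref_ad, alt_ad = alt_ad,
         samples = tibble::tibble(sample = samples, breed = breed)),
    class = "cohort_calls"
  )
}

# A 200 bp hand-built annotation fixture: one plus-strand coding gene with a
# designed ORF, one non-coding two-exon gene, and every category reachable.
annotation_fixture <- function() {
  memo("annotation_fixture", function() {
    chars <- rep("A", 200)
    # coding gene G1/T1 on +: exons 11-40 and 61-100; UTR5 11-20;
    # CDS 21-40 + 61-79 (39 bp, 13 codons); UTR3 80-100; intron 41-60
    orf <- c("ATG", "TGG", "CTG", "GCT", "TAC", "CAT", "GAC", "TTC",
             "AAG", "GGA", "CCA", "TCC", "TAA")
    cds_chars <- strsplit(paste0(orf, collapse = ""), "")[[1]]
    cds_pos <- c(21:40, 61:79)
    chars[cds_pos] <- cds_chars
    chars[41:42] <- c("G", "T")   # donor
    chars[59:60] <- c("A", "G")   # acceptor
    chars[141:142] <- c("G", "T")
    chars[149:150] <- c("A", "G")
    reference <- Biostrings::DNAStringSet(
      c(c1 = paste0(chars, collapse = ""))
    )
    gm <- dplyr::bind_rows(
      tibble::tibble(chrom = "c1", start = c(11, 61), end = c(40, 100),
                     strand = "+", type = "exon",
                     transcript = "T1", gene = "G1", coding = TRUE),
      tibble::tibble(chrom = "c1", start = 11, end = 20, strand = "+",
                     type = "five_prime_UTR",
                     transcript = "T1", gene = "G1", coding = TRUE),
      tibble::tibble(chrom = "c1", start = c(21, 61), end = c(40, 79),
                     strand = "+", type = "CDS",
                     transcript = "T1", gene = "G1", coding = TRUE),
      tibble::tibble(chrom = "c1", start = 80, end = 100, strand = "+",
                     type = "three_prime_UTR",
                     transcript = "T1", gene = "G1", coding = TRUE),
      tibble::tibble(chrom = "c1", start = c(120, 151), end = c(140, 170),
                     strand = "+", type = "exon",
                     transcript = "T2", gene = "G2", coding = FALSE)
    )
    list(reference = reference, gene_models = gm, chars = chars)
  })
}

# Independent coding-effect oracle: mutate the chromosome sequence itself,
# re-extract the transcript's spliced CDS, translate reference and mutant
# proteins with Biostrings, and diff them.
translation_oracle <- function(cohort, chrom, p, altb, txid) {
  tx <- cohort$gene_models[cohort$gene_models$transcript == txid &
                             cohort$gene_models$type == "CDS", ]
  tx <- tx[order(tx$start), ]
  strand <- tx$strand[1]
  get_cds <- function(sequence) {
    s <- paste0(as.character(Biostrings::extractAt(
      sequence, IRanges::IRanges(tx$start, tx$end)
    )), collapse = "")
    if (strand == "-") {
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)
      ))
    }
    s
  }
  ref_seq <- cohort$reference[[chrom]]
  mut_seq <- Biostrings::replaceLetterAt(ref_seq, p, altb)
  translate_chr <- function(s) {
    strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(s), no.init.codon = TRUE
    )), "")[[1]]
  }
  p_ref <- translate_chr(get_cds(ref_seq))
  p_alt <- translate_chr(get_cds(mut_seq))
  diffs <- which(p_ref != p_alt)
  if (length(diffs) == 0) {
    return("synonymous_coding")
  }
  d <- diffs[1]
  if (d == 1 && p_ref[1] == "M" && p_alt[1] != "M") {
    "start_lost"
  } else if (p_alt[d] == "*" && p_ref[d] != "*") {
    "stop_gained"
  } else if (p_ref[d] == "*" && p_alt[d] != "*") {
    "stop_lost"
  } else {
    "non_synonymous_coding"
  }
}

# Draw random single-base substitutions inside the cohort's CDS intervals.
random_coding_variants <- function(cohort, n, seed) {
  cds <- cohort$gene_models[cohort$gene_models$type == "CDS", ]
  withr::with_seed(seed, {
    rows <- cds[sample.int(nrow(cds), n, replace = TRUE), ]
    pos <- rows$start +
      floor(stats::runif(n) * (rows$end - rows$start + 1))
    ref <- vapply(seq_len(n), function(i) {
      as.character(Biostrings::extractAt(
        cohort$reference[[rows$chrom[i]]],
        IRanges::IRanges(pos[i], width = 1)
      ))
    }, character(1))
    alt <- vapply(ref, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
  })
  tibble::tibble(chrom = rows$chrom, pos = as.integer(pos), ref = ref,
                 alt = unname(alt), transcript_true = rows$transcript)
}

# Mirror the annotation fixture to the minus strand: reverse-complement the
# chromosome and reflect every interval (position p -> L + 1 - p).
mirror_fixture <- function(fx) {
  L <- length(fx$chars)
  rc <- rev(unname(c(A = "T", C = "G", G = "C", T = "A")[fx$chars]))
  reference <- Biostrings::DNAStringSet(c(c1 = paste0(rc, collapse = "")))
  gm <- fx$gene_models
  new_start <- L + 1 - gm$end
  new_end <- L + 1 - gm$start
  gm$start <- new_start
  gm$end <- new_end
  gm$strand <- ifelse(gm$strand == "+", "-", "+")
  list(reference = reference, gene_models = gm, L = L)
}
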