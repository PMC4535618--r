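# Pooled-heterozygosity selective-sweep scan.
#
# Hp for a window is 2 * sum_maj * sum_min / (sum_maj + sum_min)^2, where
# sum_maj and sum_min are the window's summed major- and minor-allele read
# counts pooled over a breed's samples; Hp is 0 at complete homozygosity and
# 0.5 at complete heterozygosity. ZHp is the genome-wide Z-transformation of
# Hp per breed; strongly negative windows are sweep candidates.

#' Pool allele read depths over one breed's samples
#'
#' Sums reference and alternate allele depths (AD) across the breed's
#' samples at every biallelic SNP, and labels the larger sum the major
#' allele (ties go to the reference allele). SNPs with zero total reads in
#' the breed are dropped.
#'
#' @param calls A `cohort_calls` object ([read_vcf_genotypes()] or
#'   [as_calls()]).
#' @param breed_map Tibble with `sample` and `breed`.
#' @param breed Breed to pool.
#'
#' @return A tibble: `breed`, `chrom`, `pos`, `major_allele`,
#'   `minor_allele`, `major_count`, `minor_count`.
#' @export
pool_breed_counts <- function(calls, breed_map, breed) {
  samples <- breed_map$sample[breed_map$breed == breed]
  if (length(samples) == 0) abort(sprintf("breed '%s' has no samples", breed))
  missing <- setdiff(samples, colnames(calls$ref_ad))
  if (length(missing) > 0) {
    abort(sprintf("sample(s) not in the VCF: %s",
                  paste(missing, collapse = ", ")))
  }
  ref_ad <- calls$ref_ad[, samples, drop = FALSE]
  alt_ad <- calls$alt_ad[, samples, drop = FALSE]
  if (anyNA(ref_ad) || anyNA(alt_ad)) {
    bad <- which(is.na(ref_ad) | is.na(alt_ad), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "missing AD for sample '%s' at %s:%d",
      samples[bad[["col"]]], calls$sites$chrom[bad[["row"]]],
      calls$sites$pos[bad[["row"]]]
    ))
  }
  ref_sum <- rowSums(ref_ad)
  alt_sum <- rowSums(alt_ad)
  ref_major <- ref_sum >= alt_sum   # tie: reference allele is major
  out <- tibble(
    breed = breed,
    chrom = calls$sites$chrom,
    pos = calls$sites$pos,
    major_allele = ifelse(ref_major, calls$sites$ref, calls$sites$alt),
    minor_allele = ifelse(ref_major, calls$sites$alt, calls$sites$ref),
    major_count = ifelse(ref_major, ref_sum, alt_sum),
    minor_count = ifelse(ref_major, alt_sum, ref_sum)
  )
  out[out$major_count + out$minor_count > 0, ]
}

#' Filter pooled counts on minor allele frequency
#'
#' Retains SNPs whose pooled minor-allele read fraction is at least
#' `threshold` (SNPs with MAF strictly below the threshold are removed).
#' When the table holds several breeds the filter is applied per breed, so a
#' SNP may survive in one breed and not another.
#'
#' @param pooled A pooled-counts tibble from [pool_breed_counts()].
#' @param threshold MAF threshold in `(0, 0.5]`; default 0.05.
#' @return The filtered tibble.
#' @export
maf_filter <- function(pooled, threshold = 0.05) {
  if (threshold <= 0 || threshold > 0.5) {
    abort("`threshold` must lie in (0, 0.5]")
  }
  maf <- pooled$minor_count / (pooled$major_count + pooled$minor_count)
  pooled[maf >= threshold, ]
}

#' Tile a genome with fixed-size, 50 percent overlapping windows
#'
#' Windows are 0-based half-open `[start, start + size)`; per chromosome
#' they start at 0, advance by `step`, and are emitted while
#' `start + size <= chromosome length` (no partial trailing windows). A
#' chromosome shorter than `size` yields no windows.
#'
#' @param genome A [genome_spec()] tibble.
#' @param size Window size in bp (default 150 kb).
#' @param step Step in bp (default `size / 2`, i.e. 50 percent overlap).
#' @return A tibble: `chrom`, `start`, `end`, `index` (ordinal within
#'   chromosome).
#' @export
make_windows <- function(genome, size = 150000, step = size / 2) {
  if (size <= 0 || step <= 0) abort("`size` and `step` must be positive")
  purrr::pmap(genome, function(chrom, length, ...) {
    if (length < size) {
      return(tibble(chrom = character(), start = numeric(),
                    end = numeric(), index = integer()))
    }
    starts <- seq(0, length - size, by = step)
    tibble(chrom = chrom, start = starts, end = starts + size,
           index = seq_along(starts))
  }) |>
    bind_rows()
}

#' Window-level pooled heterozygosity
#'
#' Sums each window's major and minor pooled read counts and computes
#' `hp = 2 * sum_maj * sum_min / (sum_maj + sum_min)^2`. A 1-based SNP
#' position `p` belongs to window `[s, e)` iff `s < p <= e`; with 50 percent
#' overlap every interior SNP falls in exactly two windows, by design.
#' Windows holding fewer than `min_snps` SNPs (of those present in
#' `pooled`, i.e. after whatever MAF filtering was applied upstream) are
#' flagged `excluded` and receive no Hp.
#'
#' @param pooled Pooled counts (one or more breeds).
#' @param windows Window tibble from [make_windows()].
#' @param min_snps Minimum SNPs per retained window (default 10).
#' @return A tibble with one row per window and breed: window coordinates
#'   plus `breed`, `n_snps`, `sum_maj`, `sum_min`, `hp`, `excluded`.
#' @export
window_hp <- function(pooled, windows, min_snps = 10) {
  win_gr <- GenomicRanges::GRanges(
    windows$chrom, IRanges::IRanges(windows$start + 1, windows$end)
  )
  out <- list()
  for (b in unique(pooled$breed)) {
    pb <- pooled[pooled$breed == b, ]
    snp_gr <- GenomicRanges::GRanges(pb$chrom,
                                     IRanges::IRanges(pb$pos, width = 1))
    hits <- GenomicRanges::findOverlaps(snp_gr, win_gr)
    agg <- tibble(
      w = S4Vectors::subjectHits(hits),
      maj = pb$major_count[S4Vectors::queryHits(hits)],
      min = pb$minor_count[S4Vectors::queryHits(hits)]
    ) |>
      group_by(.data$w) |>
      summarise(n_snps = dplyr::n(), sum_maj = sum(.data$maj),
                sum_min = sum(.data$min), .groups = "drop")
    st <- windows |> mutate(breed = b, n_snps = 0L, sum_maj = 0, sum_min = 0)
    st$n_snps[agg$w] <- agg$n_snps
    st$sum_maj[agg$w] <- agg$sum_maj
    st$sum_min[agg$w] <- agg$sum_min
    tot <- st$sum_maj + st$sum_min
    st$hp <- ifelse(tot > 0, 2 * st$sum_maj * st$sum_min / tot^2, NA_real_)
    st$excluded <- st$n_snps < min_snps
    st$hp[st$excluded] <- NA_real_
    out[[b]] <- st
  }
  bind_rows(out) |>
    select("chrom", "start", "end", "index", "breed",
           "n_snps", "sum_maj", "sum_min", "hp", "excluded")
}

#' Z-transform window Hp genome-wide per breed
#'
#' `zhp = (hp - mean) / sd`, with the mean and the population (divisor-n)
#' standard deviation taken over all retained (non-excluded) windows of the
#' breed, genome-wide. Retained ZHp values therefore have mean 0 and
#' standard deviation 1 by construction.
#'
#' @param stats Window statistics from [window_hp()].
#' @return `stats` with a `zhp` column (`NA` for excluded windows).
#' @export
zhp_transform <- function(stats) {
  stats |>
    group_by(.data$breed) |>
    group_modify(function(df, key) {
      hp <- df$hp[!df$excluded]
      if (length(hp) < 2) {
        abort(sprintf(
          "breed '%s': need at least 2 retained windows to standardize",
          key$breed
        ))
      }
      m <- mean(hp)
      s <- sqrt(mean((hp - m)^2))
      if (s == 0) {
        abort(sprintf(
          "breed '%s': all retained windows have identical Hp (sd = 0)",
          key$breed
        ))
      }
      df$zhp <- (df$hp - m) / s
      df
    }) |>
    ungroup()
}

#' Call candidate selective sweeps
#'
#' Returns the windows whose ZHp is strictly below `threshold`, sorted by
#' ascending ZHp. With gene models supplied, each call is annotated with the
#' overlapping gene names (interval intersection, either strand).
#'
#' @param stats Window statistics with `zhp` ([zhp_transform()]).
#' @param threshold ZHp threshold (default -2; strict `<`).
#' @param gene_models Optional gene-model tibble.
#' @return The calling windows, with `threshold` and (optionally) `genes`
#'   columns.
#' @export
call_sweeps <- function(stats, threshold = -2, gene_models = NULL) {
  calls <- stats |>
    filter(!.data$excluded, !is.na(.data$zhp), .data$zhp < threshold) |>
    arrange(.data$zhp) |>
    mutate(threshold = threshold)
  if (!is.null(gene_models) && nrow(calls) > 0) {
    spans <- gene_models |>
      group_by(.data$gene, .data$chrom) |>
      summarise(start = min(.data$start), end = max(.data$end),
                .groups = "drop")
    gene_gr <- GenomicRanges::GRanges(
      spans$chrom, IRanges::IRanges(spans$start, spans$end)
    )
    call_gr <- GenomicRanges::GRanges(
      calls$chrom, IRanges::IRanges(calls$start + 1, calls$end)
    )
    hits <- GenomicRanges::findOverlaps(call_gr, gene_gr)
    genes <- rep(NA_character_, nrow(calls))
    if (length(hits) > 0) {
      byq <- split(spans$gene[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits))
      genes[as.integer(names(byq))] <-
        vapply(byq, paste, character(1), collapse = ",")
    }
    calls$genes <- genes
  }
  calls
}

#' Per-SNP Hp track over a region
#'
#' Computes each SNP's own pooled heterozygosity,
#' `2 * major * minor / (major + minor)^2`, for the SNPs of `pooled` inside
#' the region (0-based half-open, like windows). Used to draw per-SNP
#' homozygosity tracks across a candidate locus.
#'
#' @param pooled Pooled counts (one or more breeds).
#' @param chrom Chromosome name.
#' @param start,end Region bounds in bp.
#' @return A tibble: `breed`, `chrom`, `pos`, `major_count`, `minor_count`,
#'   `hp_snp` (in `[0, 0.5]`).
#' @export
per_snp_hp_track <- function(pooled, chrom, start, end) {
  reg <- pooled[pooled$chrom == chrom &
                  pooled$pos > start & pooled$pos <= end, ]
  tot <- reg$major_count + reg$minor_count
  reg$hp_snp <- ifelse(tot > 0, 2 * reg$major_count * reg$minor_count / tot^2,
                       NA_real_)
  reg[, c("breed", "chrom", "pos", "major_count", "minor_count", "hp_snp")]
}

#' Run the full selective-sweep scan
#'
#' Pools allele depths per breed, applies the MAF filter, tiles the genome
#' with 50 percent overlapping windows, computes Hp and ZHp per breed, and
#' calls sweep candidates.
#'
#' `maf_scope` controls where the MAF filter is computed. With `"cohort"`
#' (the default) the minor-allele fraction is taken from reads pooled over
#' the whole cohort, and the retained SNP set is shared by all breeds: a
#' SNP fixed in one breed but segregating in the others stays in, which is
#' what lets near-fixed sweep regions depress that breed's window Hp rather
#' than vanish from its window counts. With `"breed"` the filter is applied
#' to each breed's own pooled counts, as a per-breed QC would.
#'
#' @param calls A `cohort_calls` object.
#' @param breed_map Tibble with `sample`, `breed`.
#' @param genome A [genome_spec()] tibble.
#' @param window_size,step Window tiling (default 150 kb, 75 kb).
#' @param maf_threshold Pooled MAF threshold (default 0.05).
#' @param min_snps Minimum SNPs per retained window (default 10).
#' @param zhp_threshold Sweep-calling ZHp threshold (default -2).
#' @param maf_scope `"cohort"` or `"breed"` (see Details).
#' @param gene_models Optional gene models for annotating calls.
#'
#' @return An object of class `hp_scan`: a list with `windows` (all window
#'   statistics), `calls`, `pooled` (post-filter pooled counts) and
#'   `params`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
scan_sweeps <- function(calls, breed_map, genome,
                        window_size = 150000, step = window_size / 2,
                        maf_threshold = 0.05, min_snps = 10,
                        zhp_threshold = -2,
                        maf_scope = c("cohort", "breed"),
                        gene_models = NULL) {
  maf_scope <- match.arg(maf_scope)
  breeds <- unique(breed_map$breed)
  pooled <- purrr::map(breeds, ~ pool_breed_counts(calls, breed_map, .x))
  if (maf_scope == "cohort") {
    in_map <- intersect(breed_map$sample, colnames(calls$ref_ad))
    tot_ref <- rowSums(calls$ref_ad[, in_map, drop = FALSE], na.rm = TRUE)
    tot_alt <- rowSums(calls$alt_ad[, in_map, drop = FALSE], na.rm = TRUE)
    tot <- tot_ref + tot_alt
    keep <- tot > 0 & pmin(tot_ref, tot_alt) / pmax(tot, 1) >= maf_threshold
    keys <- paste(calls$sites$chrom, calls$sites$pos)[keep]
    pooled <- purrr::map(pooled,
                         ~ .x[paste(.x$chrom, .x$pos) %in% keys, ])
  } else {
    pooled <- purrr::map(pooled, maf_filter, threshold = maf_threshold)
  }
  pooled <- bind_rows(pooled)
  windows <- make_windows(genome, size = window_size, step = step)
  stats <- window_hp(pooled, windows, min_snps = min_snps) |>
    zhp_transform()
  sweep_calls <- call_sweeps(stats, threshold = zhp_threshold,
                             gene_models = gene_models)
  structure(
    list(
      windows = stats, calls = sweep_calls, pooled = pooled,
      params = list(window_size = window_size, step = step,
                    maf_threshold = maf_threshold, min_snps = min_snps,
                    zhp_threshold = zhp_threshold, maf_scope = maf_scope)
    ),
    class = "hp_scan"
  )
}

#' @rdname scan_sweeps
#' @param x An `hp_scan` object.
#' @param ... Unused.
#' @export
tidy.hp_scan <- function(x, ...) {
  x$windows
}

#' @rdname scan_sweeps
#' @export
glance.hp_scan <- function(x, ...) {
  x$windows |>
    group_by(.data$breed) |>
    summarise(
      n_windows = dplyr::n(),
      n_excluded = sum(.data$excluded),
      n_retained = sum(!.data$excluded),
      min_zhp = min(.data$zhp, na.rm = TRUE),
      max_zhp = max(.data$zhp, na.rm = TRUE),
      n_calls = sum(!.data$excluded &
                      .data$zhp < x$params$zhp_threshold, na.rm = TRUE),
      .groups = "drop"
    )
}

#' @export
print.hp_scan <- function(x, ...) {
  cat("<hp_scan>\n")
  cat(sprintf(
    "  %d windows x %d breeds (size %g bp, step %g bp, MAF >= %g [%s], >= %d SNPs)\n",
    dplyr::n_distinct(paste(x$windows$chrom, x$windows$start)),
    dplyr::n_distinct(x$windows$breed),
    x$params$window_size, x$params$step, x$params$maf_threshold,
    x$params$maf_scope, x$params$min_snps
  ))
  cat(sprintf("  %d sweep calls at ZHp < %g\n",
              nrow(x$calls), x$params$zhp_threshold))
  invisible(x)
}
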