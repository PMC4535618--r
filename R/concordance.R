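# Chip-versus-sequencing genotype concordance.

#' Per-animal genotype concordance between chip and sequencing calls
#'
#' A probe is concordant iff its unordered allele pair equals the animal's
#' sequencing-derived genotype at that position (alleles compared as
#' reference-strand bases). The denominator is always the full probe count:
#' probes with a missing chip call, a missing sequencing call, or absent
#' from the call set count against the rate. Probes absent from the call
#' set can optionally be treated as homozygous-reference sequencing calls
#' (`absent_as_homref`, default on — appropriate when the VCF is a
#' cohort-wide variant file that omits sites where no animal varies), which
#' requires `ref_alleles` to know the reference base there.
#'
#' @param chip Chip genotypes: `animal`, `chrom`, `pos`, `allele1`,
#'   `allele2` ("." = missing).
#' @param calls A `cohort_calls` object.
#' @param animal_map Optional tibble (`animal`, `sample`) reconciling chip
#'   animal ids with VCF sample names; by default ids are assumed to match.
#' @param absent_as_homref Treat probes absent from the call set as
#'   homozygous reference?
#' @param ref_alleles Optional tibble (`chrom`, `pos`, `ref`) giving the
#'   reference base at probe positions missing from the call set.
#' @return A tibble of class `concordance_report`: `animal`, `n_probes`,
#'   `n_concordant`, `rate`.
#' @export
genotype_concordance <- function(chip, calls, animal_map = NULL,
                                 absent_as_homref = TRUE,
                                 ref_alleles = NULL) {
  assert_columns(chip, c("animal", "chrom", "pos", "allele1", "allele2"),
                 "chip genotypes")
  animals <- unique(chip$animal)
  if (is.null(animal_map)) {
    animal_map <- tibble(animal = animals, sample = animals)
  }
  missing_map <- setdiff(animals, animal_map$animal)
  if (length(missing_map) > 0) {
    abort(sprintf("chip animal(s) missing from the animal map: %s",
                  paste(missing_map, collapse = ", ")))
  }
  samples <- animal_map$sample[match(animals, animal_map$animal)]
  absent <- setdiff(samples, colnames(calls$dosage))
  if (length(absent) > 0) {
    abort(sprintf("animal(s) absent from the call set: %s",
                  paste(absent, collapse = ", ")))
  }

  site_key <- paste(calls$sites$chrom, calls$sites$pos)
  out <- purrr::map2(animals, samples, function(a, s) {
    probes <- chip[chip$animal == a, ]
    idx <- match(paste(probes$chrom, probes$pos), site_key)
    chip_missing <- probes$allele1 == "." | probes$allele2 == "."
    # unordered chip pair
    chip_pair <- paste(pmin(probes$allele1, probes$allele2),
                       pmax(probes$allele1, probes$allele2))
    seq_pair <- rep(NA_character_, nrow(probes))
    found <- !is.na(idx)
    if (any(found)) {
      dos <- calls$dosage[idx[found], s]
      ref <- calls$sites$ref[idx[found]]
      alt <- calls$sites$alt[idx[found]]
      a1 <- ifelse(dos >= 1, alt, ref)
      a2 <- ifelse(dos == 2, alt, ref)
      seq_pair[found] <- ifelse(is.na(dos), NA_character_,
                                paste(pmin(a1, a2), pmax(a1, a2)))
    }
    if (absent_as_homref && any(!found) && !is.null(ref_alleles)) {
      ridx <- match(paste(probes$chrom, probes$pos)[!found],
                    paste(ref_alleles$chrom, ref_alleles$pos))
      rb <- ref_alleles$ref[ridx]
      seq_pair[!found] <- ifelse(is.na(rb), NA_character_, paste(rb, rb))
    }
    concord <- !chip_missing & !is.na(seq_pair) & chip_pair == seq_pair
    tibble(animal = a, n_probes = nrow(probes),
           n_concordant = sum(concord),
           rate = sum(concord) / nrow(probes))
  }) |>
    bind_rows()
  class(out) <- c("concordance_report", class(out))
  out
}

#' Harmonize chip alleles against the call set's ref/alt pairs
#'
#' Flips a probe's alleles to their complements when neither reported
#' allele matches the site's ref/alt pair but the complements do (a strand
#' flip). Ambiguous A/T and C/G probes cannot be disambiguated; they are an
#' error unless `drop_ambiguous` is set, in which case they are removed.
#'
#' @param chip Chip genotype tibble.
#' @param sites Sites tibble (`chrom`, `pos`, `ref`, `alt`).
#' @param drop_ambiguous Drop ambiguous A/T and C/G probes instead of
#'   erroring?
#' @return The harmonized chip tibble.
#' @export
harmonize_chip_strand <- function(chip, sites, drop_ambiguous = FALSE) {
  idx <- match(paste(chip$chrom, chip$pos), paste(sites$chrom, sites$pos))
  ref <- sites$ref[idx]
  alt <- sites$alt[idx]
  ambiguous <- !is.na(idx) &
    paste(pmin(ref, alt), pmax(ref, alt)) %in% c("A T", "C G")
  if (any(ambiguous)) {
    if (!drop_ambiguous) {
      abort(sprintf(
        "%d ambiguous A/T or C/G probe(s); set `drop_ambiguous = TRUE`",
        sum(ambiguous)
      ))
    }
    chip <- chip[!ambiguous, ]
    idx <- idx[!ambiguous]
    ref <- ref[!ambiguous]
    alt <- alt[!ambiguous]
  }
  called <- chip$allele1 != "." & chip$allele2 != "."
  on_site <- !is.na(idx) & called
  ca1 <- complement_base(chip$allele1)
  ca2 <- complement_base(chip$allele2)
  need_flip <- on_site &
    !(chip$allele1 == ref | chip$allele1 == alt) &
    !(chip$allele2 == ref | chip$allele2 == alt)
  flip_ok <- need_flip & (ca1 == ref | ca1 == alt) & (ca2 == ref | ca2 == alt)
  flip_ok[is.na(flip_ok)] <- FALSE
  chip$allele1[flip_ok] <- complement_base(chip$allele1[flip_ok])
  chip$allele2[flip_ok] <- complement_base(chip$allele2[flip_ok])
  chip
}
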