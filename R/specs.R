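#' Describe a genome as an ordered table of chromosomes
#'
#' A genome specification is a tibble with one row per chromosome and an
#' expected SNP density used by the cohort simulator.
#'
#' @param chrom Character vector of unique chromosome names, in order.
#' @param length Integer vector of chromosome lengths in base pairs (> 0).
#' @param snp_density Expected SNPs per base pair (default one per 500 bp).
#'
#' @return A tibble with columns `chrom` and `length`, carrying the
#'   `snp_density` as an attribute (see [genome_snp_density()]).
#' @export
#'
#' @examples
#' genome_spec(c("chr1", "chr2"), c(4e6, 4e6))
genome_spec <- function(chrom, length, snp_density = 1 / 500) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0) abort("a genome needs at least one chromosome")
  if (anyDuplicated(chrom)) abort("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0)) {
    abort("chromosome lengths must be positive")
  }
  if (!is.finite(snp_density) || snp_density <= 0) {
    abort("`snp_density` must be positive")
  }
  out <- tibble(chrom = chrom, length = length)
  attr(out, "snp_density") <- snp_density
  out
}

#' @rdname genome_spec
#' @param genome A genome specification tibble.
#' @export
genome_snp_density <- function(genome) {
  attr(genome, "snp_density") %||% (1 / 500)
}

#' Describe the breeds of a simulated cohort
#'
#' Each breed is parameterized by its differentiation from the shared
#' ancestral population (Fst under the Balding-Nichols model), its number of
#' sequenced individuals, its mean sequencing depth, and a per-read base
#' error probability.
#'
#' @param name Breed label.
#' @param fst Balding-Nichols differentiation parameter in `[0, 1)`.
#' @param n_individuals Number of diploid individuals (>= 1).
#' @param mean_depth Expected reads per individual per site (> 0).
#' @param base_error Per-read probability of reporting the wrong allele,
#'   in `[0, 0.5)`.
#'
#' @return A one-row tibble; bind several with [dplyr::bind_rows()] or use
#'   [default_breeds()].
#' @export
breed_model <- function(name, fst, n_individuals, mean_depth = 12,
                        base_error = 0.001) {
  if (fst < 0 || fst >= 1) abort("`fst` must lie in [0, 1)")
  if (n_individuals < 1) abort("`n_individuals` must be >= 1")
  if (mean_depth <= 0) abort("`mean_depth` must be > 0")
  if (base_error < 0 || base_error >= 0.5) {
    abort("`base_error` must lie in [0, 0.5)")
  }
  tibble(
    name = as.character(name), fst = fst,
    n_individuals = as.integer(n_individuals),
    mean_depth = mean_depth, base_error = base_error
  )
}

#' Default five-breed cohort model
#'
#' A wild-boar analogue plus four domesticated-breed analogues, with sample
#' sizes and mean depths matching a published 55-animal, five-breed pig
#' resequencing cohort (10/10/6/14/15 animals at roughly 11-13x). The
#' differentiation parameters are fixture choices (the wild analogue most
#' differentiated), not estimates of any real population.
#'
#' @return A five-row breed tibble.
#' @export
default_breeds <- function() {
  bind_rows(
    breed_model("KWB", fst = 0.25, n_individuals = 10, mean_depth = 11.21),
    breed_model("KNP", fst = 0.18, n_individuals = 10, mean_depth = 11.74),
    breed_model("DUR", fst = 0.12, n_individuals = 6,  mean_depth = 11.60),
    breed_model("LAN", fst = 0.10, n_individuals = 14, mean_depth = 12.93),
    breed_model("YOR", fst = 0.10, n_individuals = 15, mean_depth = 10.96)
  )
}

#' Describe a selective sweep to embed in the simulated cohort
#'
#' Inside the interval, the affected breeds' minor-allele frequencies are
#' pushed to `residual_maf`, emulating a genomic region driven to
#' near-fixation by selection.
#'
#' @param chrom Chromosome name.
#' @param start,end Interval in base pairs, 0-based half-open (BED-like);
#'   `0 <= start < end`.
#' @param breeds Character vector of affected breed names.
#' @param residual_maf Frequency the minor allele is pushed to, in
#'   `[0, 0.05)`.
#'
#' @return A one-row tibble with a `breeds` list-column.
#' @export
sweep_spec <- function(chrom, start, end, breeds, residual_maf = 0.01) {
  if (start < 0 || start >= end) abort("need 0 <= start < end")
  if (residual_maf < 0 || residual_maf >= 0.05) {
    abort("`residual_maf` must lie in [0, 0.05)")
  }
  tibble(
    chrom = as.character(chrom), start = as.numeric(start),
    end = as.numeric(end), breeds = list(as.character(breeds)),
    residual_maf = residual_maf
  )
}

#' Describe the genotyping chip applied to the simulated cohort
#'
#' @param n_probes Number of probes drawn uniformly from simulated SNP
#'   positions (>= 1).
#' @param genotype_error Per-genotype probability of flipping the call to a
#'   uniformly chosen different genotype, in `[0, 1)`.
#' @param missing_rate Per-genotype missing probability, in `[0, 1)`.
#' @param animals_per_breed How many animals per breed are genotyped on the
#'   chip (default 5, capped at the breed size).
#'
#' @return A list of class `chip_spec`.
#' @export
chip_spec <- function(n_probes, genotype_error = 0.01, missing_rate = 0,
                      animals_per_breed = 5) {
  if (n_probes < 1) abort("`n_probes` must be >= 1")
  if (genotype_error < 0 || genotype_error >= 1) {
    abort("`genotype_error` must lie in [0, 1)")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1)")
  }
  structure(
    list(
      n_probes = as.integer(n_probes), genotype_error = genotype_error,
      missing_rate = missing_rate,
      animals_per_breed = as.integer(animals_per_breed)
    ),
    class = "chip_spec"
  )
}
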