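---
title: "Methods: pooled-heterozygosity sweep scanning and cohort QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-heterozygosity sweep scanning and cohort QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the parameter choices and
the deliberate design decisions behind `sweepherd`. It is the place to
look when a default seems arbitrary: every one of them is argued here.

## The pooled-heterozygosity scan

### Model

Selection that drives a haplotype toward fixation leaves a local deficit
of heterozygosity. The scan detects it from read counts rather than called
genotypes: at every biallelic SNP the reference and alternate allele
depths (`AD`) are summed over a breed's animals, the larger sum is the
major allele, and for a genomic window the statistic is

$$
H_p \;=\; \frac{2\,\Sigma_{maj}\,\Sigma_{min}}{(\Sigma_{maj}+\Sigma_{min})^2},
$$

with $\Sigma_{maj}, \Sigma_{min}$ the window's summed major-/minor-allele
read counts. $H_p$ lives in $[0, 0.5]$: 0 when the window's reads are all
major allele (complete homozygosity), 0.5 when the sums balance. Some
descriptions of this statistic print the denominator unsquared; that form
is unbounded and inconsistent with the stated 0–0.5 range, so the squared
form — the one that actually has that range — is used here.

Per breed, $H_p$ is standardized genome-wide over all retained windows,
$ZH_p = (H_p - \bar H_p)/\sigma_{H_p}$ with the population (divisor-$n$)
standard deviation, so retained $ZH_p$ have mean 0 and sd 1 by
construction (tested to $10^{-9}$). Windows with $ZH_p < -2$ (strict) are
sweep candidates. The Z-transformation is genome-wide rather than
per-chromosome; with per-chromosome standardization a chromosome carrying
a strong sweep would partially absorb its own signal into the local mean.

### Windows and coordinate conventions

Windows are 150 kb, stepped by 75 kb (50% overlap), 0-based half-open
`[s, s+150000)`, starting at 0 on each chromosome and emitted while
`start + size <= L` — no partial trailing windows, so a chromosome of
length `L >= size` carries exactly `floor((L - size)/step) + 1` windows.
A 1-based SNP position `p` belongs to `[s, e)` iff `s < p <= e`. Stated
once here, used everywhere; every interior SNP falls in exactly two
windows by design.

### Filters and their scope

Two filters precede $H_p$:

* **MAF filter** (default threshold 0.05, strict `<` removal): a SNP is
  kept iff its pooled minor-allele read fraction is at least the
  threshold.
* **Window exclusion** (default 10): windows with fewer than 10 retained
  SNPs get no $H_p$ and never enter the standardization.

The one genuinely open design question is *where* the MAF is computed,
and it matters more than it looks. If each breed filters on its own
pooled counts, a region swept to near-fixation in one breed loses nearly
all of its SNPs in exactly that breed — the windows then fail the 10-SNP
rule and silently vanish instead of scoring low. The signal the scan
exists to find would delete itself. `scan_sweeps()` therefore defaults to
`maf_scope = "cohort"`: the MAF is computed from reads pooled over the
whole cohort, where a site fixed in one breed but segregating in the
others survives, and the per-breed window statistics are computed over
that shared SNP set. `maf_scope = "breed"` gives the literal per-breed
behaviour for comparison, and `maf_filter()` itself always operates per
breed. Under cohort scope, the window-exclusion count is the number of
cohort-retained SNPs at which the breed has reads; under breed scope it
is the number of SNPs polymorphic (MAF ≥ threshold) in the breed's own
pool.

### Ties, degenerate input, multi-allelics

Equal pooled counts make the reference allele the major one —
deterministic and reference-stable. SNPs with zero reads in a breed are
dropped from that breed's pool. Multi-allelic records are dropped at VCF
ingest with a message; the statistic is defined on biallelic major/minor
counts. Standardization refuses to run on fewer than two retained windows
or on a genome whose retained windows all share one $H_p$ (sd = 0); both
are errors, not silent NA.

## Functional annotation

One category per SNP, twelve categories, precedence most-severe-first:
splice-site acceptor > splice-site donor > start lost > stop gained >
stop lost > non-synonymous > synonymous > 5′ UTR > 3′ UTR > non-coding
exon > intron > intergenic. A single-category assignment is what makes
category counts partition the SNP set (tested as an invariant). Splice
sites are the two intronic bases flanking each exon, donor at the
transcript-5′ end of the intron, acceptor at the 3′ end. Coding effects
substitute the alternate base into the affected codon on the coding
strand and compare amino acids under the standard code; a
whole-CDS-translation oracle (mutate the chromosome, re-extract and
translate the spliced CDS, diff the proteins) checks 1,000 random coding
SNPs per run, and a strand-mirroring metamorphic test checks that minus-
strand classification equals plus-strand classification of the
reverse-complemented locus. One canonical transcript per gene is assumed
given in the gene-model input; variants hitting several transcripts take
the highest-precedence (first) assignment.

SIFT classification is score ≤ 0.05 damaging, > 0.05 tolerant, absent
unscored; scores outside [0, 1] are an error. Novelty is matched by
position by default — the convention of dbSNP-era comparisons — with an
allele-aware mode behind a flag. Ti/Tv counts A↔G and C↔T as transitions
and reports an undefined (NA) ratio when no transversions exist, never
infinity. A breed-specific nsSNP is one whose alternate allele is seen in
exactly one breed (at least one carrier).

## Population structure

Pairwise similarity is the fraction of identical unphased genotypes over
pairwise-complete sites. The Kimura two-parameter distance between two
diploid individuals takes the transition (P) and transversion (Q)
difference proportions as the mean over the four cross-haplotype
comparisons; with dosages $k, m$ at a site the mean mismatch is
$(k + m - km)/2$, so the distance depends only on dosages — phased and
unphased input agree, and a het-vs-hom comparison contributes half a
difference to the bin (Ti or Tv) that the site's ref/alt pair dictates.
Sites are Ti or Tv sites by their ref/alt pair; denominators are
pairwise-complete site counts, matching the similarity convention.
Saturated pairs ($1 - 2P - Q \le 0$ or $1 - 2Q \le 0$) are an error
naming the domain violation rather than a silent NaN.

Neighbour joining is the classic Saitou–Nei agglomeration: join the pair
minimizing $(n-2)d_{ij} - r_i - r_j$, branch lengths from the three-point
formulas, matrix reduction $d_{uk} = (d_{ik} + d_{jk} - d_{ij})/2$. Ties
break on the lowest (row, column) index, so runs are reproducible.
Negative branch lengths — possible on non-additive input — are clamped to
zero with the deficit moved to the sibling branch, preserving the pair
distance. On additive matrices the generating topology and branch lengths
are recovered exactly (tested to $10^{-9}$ against a path-length oracle
on random 5–12-leaf trees, and cross-checked against an independent NJ
implementation on noisy matrices). Each animal is one tip; the
four-comparison average is how a diploid pair collapses to one distance.

## Chip concordance

A probe is concordant iff its unordered allele pair equals the
sequencing genotype at that position. The denominator is the full probe
count — probes missing on either side count against the rate, which is
what makes the rate an end-to-end accuracy figure rather than a
matched-sites agreement. Probes absent from the call set can be treated
as homozygous-reference sequencing calls (`absent_as_homref`, default on,
needs a reference-base lookup), the right reading when the VCF is a
cohort-wide variant file that omits invariant sites; the flag turns the
alternative (count them as unmatched) on. Strand flips are not
auto-detected; `harmonize_chip_strand()` flips probes whose complements
match ref/alt and refuses ambiguous A/T and C/G probes unless told to
drop them.

## The cohort simulator

The generator's defaults are the study conditions, chosen once:

* **Cohort**: five breeds, 55 animals (10/10/6/14/15) at mean depths
  11.21/11.74/11.60/12.93/10.96× — the shape of a published five-breed
  pig resequencing cohort.
* **Differentiation**: Balding–Nichols — per breed, the alternate-allele
  frequency at a SNP with ancestral frequency $p$ is
  $\mathrm{Beta}\!\big(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$.
  Default $F$ per breed: 0.25/0.18/0.12/0.10/0.10, the wild-boar
  analogue most differentiated. These are fixture choices within a
  realistic livestock range, not estimates of any real population;
  $F = 0$ reproduces the ancestral frequency exactly.
* **Ancestral frequencies**: Uniform(0.05, 0.95), so monomorphic and
  near-degenerate sites do not dominate; configurable.
* **SNP density**: one per 500 bp expected (Poisson), positions uniform
  without replacement.
* **Genotypes**: Hardy–Weinberg, two independent Bernoulli haplotypes per
  individual, phased in the VCF.
* **Reads**: per individual-site depth Poisson(breed mean); each read
  picks one haplotype uniformly and is flipped with base error 0.001, so
  an individual with dosage $k$ yields alternate reads
  $\mathrm{Bin}(\text{depth},\, \tfrac k2(1-2e)+e)$. Reads are simulated
  per animal and pooled downstream, as real pipelines do — the VCF stays
  per-sample.
* **Alleles**: the reference base comes from the generated reference
  sequence; the alternate is the transition partner with probability 2/3,
  else a uniform transversion, giving the genome-wide Ti/Tv ≈ 2 expected
  in mammals.
* **Sweeps**: inside a sweep interval the affected breeds' minor-allele
  frequency is set to `residual_maf` (default 0.01); the major allele is
  whichever is currently more frequent in the breed, reference winning a
  tie at exactly 0.5.
* **Gene models**: non-overlapping one-transcript genes, 2–5 exons, ~10
  genes/Mb, 85% coding with 5′ UTR / CDS (length divisible by 3, designed
  ATG…stop ORF with no internal stops written into the reference) / 3′
  UTR, GT/AG splice dinucleotides. This is a deliberate simplification —
  no overlapping loci, no alternative splicing, no UTR introns.
* **Known sites**: 74.5% of SNP positions, so a re-ingested cohort shows
  ≈25.5% novel sites.
* **SIFT table**: 80% of coding SNPs scored, scores Uniform(0, 1).
* **Chip**: probes drawn uniformly from SNP positions, five animals per
  breed, a genotype error flips a call to a uniformly chosen different
  genotype, missingness is independent; alleles are reference-strand
  bases.

All randomness flows from one master seed through named sub-streams
(frequencies, genes, reference, alleles, genotypes, reads, known, sift,
chip), so identical seeds give byte-identical cohorts and each stage is
independently reproducible.

### What the simulator does not emulate

No linkage disequilibrium or recombination structure (sites are
independent given the breed frequencies), no demographic history beyond
the single-$F$ island model, no indels or multi-allelic sites, no sex
chromosomes, no mapping or calling artefacts (the VCF is "perfectly
called" up to read sampling). Passing tests therefore demonstrate that
the statistics recover what they are defined to recover under clean
sampling noise — not robustness to LD, batch effects or caller error.

### Validation fixture and problem sizes

The heavier properties run on a simulated study cohort: 5 chromosomes ×
4 Mb, one SNP per ~500 bp (~40,000 SNPs), five breeds × 10 animals at
12× with base error 0.001, three 300 kb sweeps at residual MAF 0.01, a
5,000-probe chip with 1% genotype error, master seed 55. On it, the scan
recovers all three sweeps with ≥90% precision at $ZH_p < -2$, breeds are
monophyletic on the NJ tree with every within-breed similarity above
every between-breed one, and the chip error is recovered in the
concordance rate within three binomial standard errors.

Two fixture-design notes. First, the validation sweeps are shared by all
five breeds (domestication-style) rather than private to one: with a
breed-private sweep, the unaffected breeds' $ZH_p$ is essentially
standard normal, whose ~2% lower tail below −2 puts a floor of false
calls under any implementation; shared sweeps inflate every breed's
$H_p$ variance, compress the null tail, and make precision a meaningful
check of the machinery rather than of Gaussian tail mass. Breed-private
sweeps are exercised separately (the swept breed's windows score lowest;
the other breed's do not call). Second, the per-breed MAF-failure
property of sweep SNPs (≥90% fail at residual MAF 0.01) is intrinsically
marginal at 10 animals × 12×: a single heterozygous carrier among 20
haplotypes contributes an expected read fraction of exactly 0.05, the
threshold itself, so the property sits near 0.90 by construction
(measured 0.904 on the fixture) — worth knowing before changing breed
sizes or depths.

## Known limitations

* The scan reports windows, not boundaries; overlapping windows mean a
  single sweep surfaces as a run of calls.
* Gene annotation handles SNPs against single-transcript gene models
  only; no indels, no multi-transcript reporting, no effect ontology
  beyond the twelve categories.
* K2P distances saturate on very divergent pairs; the error is
  deliberate, but it means the tree stage needs within-species input.
* The concordance stage assumes chip alleles are already on the
  reference strand unless `harmonize_chip_strand()` is applied, and A/T
  and C/G probes are inherently unresolvable there.
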