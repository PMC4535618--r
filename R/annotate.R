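# Functional SNP annotation: one of twelve effect categories per SNP against
# canonical gene models, Ti/Tv and novelty QC, SIFT classification, and
# breed-specific nsSNP extraction.

#' The twelve SNP effect categories, in precedence order
#'
#' Every SNP receives exactly one category. Where a SNP could belong to
#' several (e.g. it hits two features), the most severe wins, in this order:
#' splice-site acceptor, splice-site donor, start lost, stop gained, stop
#' lost, non-synonymous coding, synonymous coding, 5' UTR, 3' UTR,
#' non-coding exon, intron, intergenic.
#'
#' @export
SNP_CATEGORIES <- c(
  "splice_site_acceptor", "splice_site_donor", "start_lost", "stop_gained",
  "stop_lost", "non_synonymous_coding", "synonymous_coding", "utr_5",
  "utr_3", "non_coding_exon", "intron", "intergenic"
)

FUNCTIONAL_CLASS <- c(
  non_synonymous_coding = "missense",
  stop_gained = "nonsense",
  synonymous_coding = "silent"
)

# Intron intervals and 2-bp splice sites for every multi-exon transcript.
# Donor = the 2 intronic bases at the transcript-5' end of each intron,
# acceptor = the 2 at its transcript-3' end.
splice_features <- function(gene_models) {
  ex <- gene_models[gene_models$type == "exon", ]
  out <- list(intron = list(), donor = list(), acceptor = list())
  for (txid in unique(ex$transcript)) {
    e <- ex[ex$transcript == txid, ]
    e <- e[order(e$start), ]
    if (nrow(e) < 2) next
    gs <- e$end[-nrow(e)] + 1
    ge <- e$start[-1] - 1
    ok <- ge >= gs
    gs <- gs[ok]
    ge <- ge[ok]
    if (length(gs) == 0) next
    strand <- e$strand[1]
    base <- tibble(chrom = e$chrom[1], transcript = txid, gene = e$gene[1])
    out$intron[[txid]] <- bind_cols(base[rep(1, length(gs)), ],
                                    tibble(start = gs, end = ge))
    if (strand == "+") {
      don <- tibble(start = gs, end = pmin(gs + 1, ge))
      acc <- tibble(start = pmax(ge - 1, gs), end = ge)
    } else {
      don <- tibble(start = pmax(ge - 1, gs), end = ge)
      acc <- tibble(start = gs, end = pmin(gs + 1, ge))
    }
    out$donor[[txid]] <- bind_cols(base[rep(1, length(gs)), ], don)
    out$acceptor[[txid]] <- bind_cols(base[rep(1, length(gs)), ], acc)
  }
  purrr::map(out, bind_rows)
}

overlap_first <- function(var_gr, feat) {
  if (is.null(feat) || nrow(feat) == 0) {
    return(integer(0))
  }
  gr <- GenomicRanges::GRanges(feat$chrom,
                               IRanges::IRanges(feat$start, feat$end))
  hits <- GenomicRanges::findOverlaps(var_gr, gr, select = "first")
  hits
}

# Spliced CDS sequence of a transcript, in coding orientation.
spliced_cds <- function(cds_rows, reference) {
  cds_rows <- cds_rows[order(cds_rows$start), ]
  chrom <- cds_rows$chrom[1]
  pieces <- as.character(Biostrings::extractAt(
    reference[[chrom]],
    IRanges::IRanges(cds_rows$start, cds_rows$end)
  ))
  seq_asc <- paste0(pieces, collapse = "")
  if (cds_rows$strand[1] == "-") {
    seq_asc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq_asc))
    )
  }
  seq_asc
}

# 1-based offset of genomic position `pos` within the spliced CDS.
cds_offset <- function(cds_rows, pos) {
  strand <- cds_rows$strand[1]
  cds_rows <- cds_rows[order(cds_rows$start, decreasing = (strand == "-")), ]
  lens <- cds_rows$end - cds_rows$start + 1
  cum <- cumsum(c(0, lens))
  for (i in seq_len(nrow(cds_rows))) {
    if (pos >= cds_rows$start[i] && pos <= cds_rows$end[i]) {
      within <- if (strand == "+") pos - cds_rows$start[i] + 1
                else cds_rows$end[i] - pos + 1
      return(cum[i] + within)
    }
  }
  NA_integer_
}

#' Classify SNPs into the twelve effect categories
#'
#' Assigns each biallelic SNP the single highest-precedence category (see
#' [SNP_CATEGORIES]) against the supplied canonical gene models. Coding
#' effects substitute the alternate base into the affected codon on the
#' coding strand and compare the translated amino acids under the standard
#' genetic code.
#'
#' @param variants Tibble with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param gene_models Gene-model tibble ([simulate_gene_models()] /
#'   [read_gene_models()]).
#' @param reference A [Biostrings::DNAStringSet] named by chromosome. The
#'   variant `ref` bases are checked against it; a disagreement is an error.
#'
#' @return `variants` with columns `category`, `functional_class`
#'   (`missense`, `nonsense`, `silent` or `none`), `gene`, `transcript`.
#' @export
classify_variants <- function(variants, gene_models, reference) {
  assert_columns(variants, c("chrom", "pos", "ref", "alt"), "variants")
  n <- nrow(variants)
  # reference agreement check
  for (chrom in unique(variants$chrom)) {
    idx <- which(variants$chrom == chrom)
    refb <- unlist(strsplit(as.character(Biostrings::extractAt(
      reference[[chrom]], IRanges::IRanges(variants$pos[idx], width = 1)
    )), NULL))
    bad <- which(refb != variants$ref[idx])
    if (length(bad) > 0) {
      abort(sprintf(
        "variant ref allele disagrees with the reference at %s:%d (%s vs %s)",
        chrom, variants$pos[idx[bad[1]]], variants$ref[idx[bad[1]]],
        refb[bad[1]]
      ))
    }
  }

  if (!"coding" %in% names(gene_models)) {
    coding_tx <- unique(gene_models$transcript[gene_models$type == "CDS"])
    gene_models$coding <- gene_models$transcript %in% coding_tx
  }
  var_gr <- GenomicRanges::GRanges(variants$chrom,
                                   IRanges::IRanges(variants$pos, width = 1))
  category <- rep(NA_character_, n)
  gene <- rep(NA_character_, n)
  transcript <- rep(NA_character_, n)

  take <- function(feat, label) {
    hit <- overlap_first(var_gr, feat)
    if (length(hit) == 0) return(invisible())
    sel <- is.na(category) & !is.na(hit)
    category[sel] <<- label
    gene[sel] <<- feat$gene[hit[sel]]
    transcript[sel] <<- feat$transcript[hit[sel]]
    invisible()
  }

  sp <- splice_features(gene_models)
  take(sp$acceptor, "splice_site_acceptor")
  take(sp$donor, "splice_site_donor")

  # coding effects
  cds <- gene_models[gene_models$type == "CDS", ]
  if (nrow(cds) > 0) {
    hit <- overlap_first(var_gr, cds)
    idx <- which(is.na(category) & !is.na(hit))
    cds_cache <- new.env(parent = emptyenv())
    code <- Biostrings::GENETIC_CODE
    for (i in idx) {
      txid <- cds$transcript[hit[i]]
      tx_rows <- cds[cds$transcript == txid, ]
      key <- txid
      if (is.null(cds_cache[[key]])) {
        cds_cache[[key]] <- spliced_cds(tx_rows, reference)
      }
      cds_seq <- cds_cache[[key]]
      off <- cds_offset(tx_rows, variants$pos[i])
      strand <- tx_rows$strand[1]
      alt_coding <- if (strand == "+") variants$alt[i]
                    else complement_base(variants$alt[i])
      codon_i <- (off - 1) %/% 3 + 1
      pos_in <- off - (codon_i - 1) * 3
      ref_codon <- substr(cds_seq, 3 * codon_i - 2, 3 * codon_i)
      alt_codon <- ref_codon
      substr(alt_codon, pos_in, pos_in) <- alt_coding
      ref_aa <- code[[ref_codon]]
      alt_aa <- code[[alt_codon]]
      category[i] <- if (codon_i == 1 && ref_aa == "M" && alt_aa != "M") {
        "start_lost"
      } else if (alt_aa == "*" && ref_aa != "*") {
        "stop_gained"
      } else if (ref_aa == "*" && alt_aa != "*") {
        "stop_lost"
      } else if (ref_aa != alt_aa) {
        "non_synonymous_coding"
      } else {
        "synonymous_coding"
      }
      gene[i] <- tx_rows$gene[1]
      transcript[i] <- txid
    }
  }

  take(gene_models[gene_models$type == "five_prime_UTR", ], "utr_5")
  take(gene_models[gene_models$type == "three_prime_UTR", ], "utr_3")
  take(gene_models[gene_models$type == "exon" & !gene_models$coding, ],
       "non_coding_exon")
  take(sp$intron, "intron")
  category[is.na(category)] <- "intergenic"

  variants$category <- category
  variants$functional_class <-
    unname(ifelse(category %in% names(FUNCTIONAL_CLASS),
                  FUNCTIONAL_CLASS[category], "none"))
  variants$gene <- gene
  variants$transcript <- transcript
  variants
}

#' Transition/transversion summary
#'
#' Transitions are A<->G and C<->T; everything else is a transversion. With
#' zero transversions the ratio is reported as `NA` (undefined), not
#' infinity.
#'
#' @param variants Tibble with `ref` and `alt` single-base alleles.
#' @return A one-row tibble: `transitions`, `transversions`, `ratio`.
#' @export
titv <- function(variants) {
  ti <- sum(is_transition(variants$ref, variants$alt))
  tv <- nrow(variants) - ti
  tibble(
    transitions = ti, transversions = tv,
    ratio = if (tv == 0) NA_real_ else ti / tv
  )
}

#' Flag novel SNPs against a known-sites list
#'
#' A variant is novel iff it is absent from `known_sites`. Matching is by
#' position by default; `by_allele = TRUE` additionally requires the
#' alternate allele to match (`known_sites` then needs an `alt` column).
#'
#' @param variants Tibble with `chrom`, `pos` (and `alt` for allele-aware
#'   matching).
#' @param known_sites Tibble with `chrom`, `pos` (and optionally `alt`).
#' @param by_allele Match alleles as well as positions?
#' @return `variants` with a logical `novel` column.
#' @export
flag_novel <- function(variants, known_sites, by_allele = FALSE) {
  if (by_allele) {
    assert_columns(known_sites, c("chrom", "pos", "alt"), "known sites")
    keys <- paste(known_sites$chrom, known_sites$pos, known_sites$alt)
    variants$novel <- !paste(variants$chrom, variants$pos,
                             variants$alt) %in% keys
  } else {
    keys <- paste(known_sites$chrom, known_sites$pos)
    variants$novel <- !paste(variants$chrom, variants$pos) %in% keys
  }
  variants
}

#' @rdname flag_novel
#' @export
novelty_fraction <- function(variants) {
  assert_columns(variants, "novel", "variants")
  mean(variants$novel)
}

#' Classify nsSNPs as damaging or tolerant from a SIFT score table
#'
#' A scored SNP is `damaging` iff its SIFT score is `<= threshold` (default
#' 0.05) and `tolerant` otherwise; SNPs absent from the table are
#' `unscored`. Scores outside `[0, 1]` are an error.
#'
#' @param variants Tibble with `chrom`, `pos`, `alt`.
#' @param sift_table Tibble with `chrom`, `pos`, `alt`, `score`.
#' @param threshold Damaging threshold (default 0.05).
#' @return `variants` with `sift_score` and `sift_class` columns.
#' @export
sift_classify <- function(variants, sift_table, threshold = 0.05) {
  assert_columns(sift_table, c("chrom", "pos", "alt", "score"), "SIFT table")
  if (any(sift_table$score < 0 | sift_table$score > 1)) {
    abort("SIFT scores must lie in [0, 1]")
  }
  joined <- variants |>
    left_join(
      sift_table |>
        select("chrom", "pos", "alt", sift_score = "score") |>
        distinct(.data$chrom, .data$pos, .data$alt, .keep_all = TRUE),
      by = c("chrom", "pos", "alt")
    )
  joined$sift_class <- dplyr::case_when(
    is.na(joined$sift_score) ~ "unscored",
    joined$sift_score <= threshold ~ "damaging",
    TRUE ~ "tolerant"
  )
  joined
}

#' Per-breed presence of the alternate allele
#'
#' A SNP is present in a breed iff at least one of the breed's individuals
#' carries the alternate allele.
#'
#' @param calls A `cohort_calls` object.
#' @param breed_map Tibble with `sample`, `breed`.
#' @return A tibble of `chrom`, `pos` plus one logical column per breed.
#' @export
breed_presence <- function(calls, breed_map) {
  out <- calls$sites[, c("chrom", "pos")]
  for (b in unique(breed_map$breed)) {
    samples <- intersect(breed_map$sample[breed_map$breed == b],
                         colnames(calls$dosage))
    out[[b]] <- rowSums(calls$dosage[, samples, drop = FALSE] > 0,
                        na.rm = TRUE) > 0
  }
  out
}

#' Extract breed-specific non-synonymous SNPs
#'
#' A non-synonymous SNP is breed specific iff its alternate allele is
#' observed in exactly one breed.
#'
#' @param annotated Output of [classify_variants()].
#' @param presence Output of [breed_presence()].
#' @return A tibble of breed-specific nsSNPs: `breed`, `chrom`, `pos`,
#'   `ref`, `alt`, `gene`.
#' @export
breed_specific_nssnps <- function(annotated, presence) {
  breeds <- setdiff(names(presence), c("chrom", "pos"))
  ns <- annotated |>
    filter(.data$category == "non_synonymous_coding") |>
    inner_join(presence, by = c("chrom", "pos"))
  pres_mat <- as.matrix(ns[, breeds, drop = FALSE])
  n_present <- rowSums(pres_mat)
  specific <- ns[n_present == 1, , drop = FALSE]
  if (nrow(specific) == 0) {
    return(tibble(breed = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character(), gene = character()))
  }
  specific$breed <- breeds[max.col(as.matrix(specific[, breeds]))]
  specific |>
    select("breed", "chrom", "pos", "ref", "alt", "gene") |>
    arrange(.data$breed, .data$chrom, .data$pos)
}

#' Summarize annotated SNPs as a per-breed category table
#'
#' Counts, per breed and in total, the SNPs in each of the twelve effect
#' categories plus the transition/transversion and
#' missense/nonsense/silent tallies — the shape of a cohort annotation
#' summary table.
#'
#' @param annotated Output of [classify_variants()].
#' @param presence Optional output of [breed_presence()]; adds one count
#'   column per breed (SNPs whose alternate allele is observed in that
#'   breed).
#' @return A tibble with a `field` column and count columns.
#' @export
category_summary <- function(annotated, presence = NULL) {
  count_block <- function(vars) {
    cats <- table(factor(vars$category, levels = SNP_CATEGORIES))
    tv <- titv(vars)
    c(
      SNP = nrow(vars),
      transition = tv$transitions,
      transversion = tv$transversions,
      as.integer(cats) |> setNames(SNP_CATEGORIES),
      missense = sum(vars$functional_class == "missense"),
      nonsense = sum(vars$functional_class == "nonsense"),
      silent = sum(vars$functional_class == "silent")
    )
  }
  out <- tibble(field = names(count_block(annotated)),
                total = unname(count_block(annotated)))
  if (!is.null(presence)) {
    joined <- annotated |> inner_join(presence, by = c("chrom", "pos"))
    for (b in setdiff(names(presence), c("chrom", "pos"))) {
      out[[b]] <- unname(count_block(joined[joined[[b]], , drop = FALSE]))
    }
  }
  out
}
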