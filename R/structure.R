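# Population structure: pairwise genotype similarity, Kimura two-parameter
# distances and a neighbour-joining tree.

#' Pairwise genotype-similarity matrix
#'
#' Similarity between two individuals is the number of identical unphased
#' genotypes divided by the number of sites where both calls are
#' non-missing (pairwise-complete comparison).
#'
#' @param dosage Genotype dosage matrix (variants x samples), values 0/1/2
#'   or `NA`.
#' @return A symmetric numeric matrix in `[0, 1]` with unit diagonal,
#'   labelled by sample.
#' @export
genotype_similarity <- function(dosage) {
  valid <- !is.na(dosage)
  storage.mode(valid) <- "double"
  compared <- crossprod(valid)
  match_count <- matrix(0, ncol(dosage), ncol(dosage))
  for (g in 0:2) {
    ind <- (dosage == g) & valid
    ind[is.na(ind)] <- FALSE
    storage.mode(ind) <- "double"
    match_count <- match_count + crossprod(ind)
  }
  if (any(compared == 0)) {
    bad <- which(compared == 0, arr.ind = TRUE)[1, ]
    abort(sprintf("samples '%s' and '%s' share no comparable sites",
                  colnames(dosage)[bad[1]], colnames(dosage)[bad[2]]))
  }
  sim <- match_count / compared
  diag(sim) <- 1
  dimnames(sim) <- list(colnames(dosage), colnames(dosage))
  sim
}

#' Kimura two-parameter distance
#'
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`, where `P` and `Q` are the
#' transition and transversion difference proportions. Vectorized;
#' monotone increasing in both arguments on the valid domain.
#'
#' @param P Transition difference proportion(s), `>= 0`.
#' @param Q Transversion difference proportion(s), `>= 0`; `P + Q <= 1`.
#' @return Distance(s). Saturated pairs (`1 - 2P - Q <= 0` or
#'   `1 - 2Q <= 0`) are an error.
#' @export
k2p_distance <- function(P, Q) {
  if (any(P < 0 | Q < 0 | P + Q > 1)) {
    abort("need P >= 0, Q >= 0 and P + Q <= 1")
  }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (any(w1 <= 0 | w2 <= 0)) {
    abort("saturated pair: log-domain violation (1-2P-Q or 1-2Q is <= 0)")
  }
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise K2P distance matrix over individuals
#'
#' For each pair of diploid individuals, the transition (P) and transversion
#' (Q) difference proportions are the mean mismatch fractions over the four
#' cross-haplotype comparisons, computed over sites where both individuals
#' are called. Whether a mismatching site counts as a transition or a
#' transversion is decided by the site's ref/alt base pair. The four-way
#' average depends only on allele dosages, so phased and unphased input give
#' identical distances; a het-vs-hom comparison contributes 1/2 a
#' difference.
#'
#' @param calls A `cohort_calls` object, or a dosage matrix via `dosage`
#'   and `sites`.
#' @param dosage Optional dosage matrix (variants x samples) overriding
#'   `calls$dosage`.
#' @param sites Optional sites tibble (`chrom`, `pos`, `ref`, `alt`).
#' @return A list with `distances` (symmetric matrix, zero diagonal), `P`,
#'   `Q` and `n_sites` matrices.
#' @export
pairwise_k2p <- function(calls = NULL, dosage = calls$dosage,
                        sites = calls$sites) {
  ti_site <- is_transition(sites$ref, sites$alt)
  valid <- !is.na(dosage)
  storage.mode(valid) <- "double"
  d0 <- dosage
  d0[is.na(d0)] <- 0
  n_sites <- crossprod(valid)
  if (any(n_sites == 0)) {
    bad <- which(n_sites == 0, arr.ind = TRUE)[1, ]
    abort(sprintf("samples '%s' and '%s' share no comparable sites",
                  colnames(dosage)[bad[1]], colnames(dosage)[bad[2]]))
  }
  # mean mismatches over the 4 cross-haplotype comparisons at one site:
  # (k(2-m) + m(2-k)) / 4 = (k + m - k*m) / 2 for dosages k, m
  mismatch_sum <- function(sel) {
    ds <- d0[sel, , drop = FALSE]
    vs <- valid[sel, , drop = FALSE]
    (crossprod(ds, vs) + crossprod(vs, ds) - crossprod(ds)) / 2
  }
  P <- mismatch_sum(ti_site) / n_sites
  Q <- mismatch_sum(!ti_site) / n_sites
  # an individual against itself is identical by definition
  diag(P) <- 0
  diag(Q) <- 0
  d <- k2p_distance(P, Q)
  dimnames(d) <- dimnames(P) <- dimnames(Q) <-
    list(colnames(dosage), colnames(dosage))
  list(distances = d, P = P, Q = Q, n_sites = n_sites)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classic agglomerative neighbour joining: repeatedly join the pair
#' minimizing the Q-criterion `(n-2) d_ij - r_i - r_j`, assign branch
#' lengths from the three-point formulas, and reduce the matrix. Ties are
#' broken by lowest (row, column) index for reproducibility. Negative
#' branch lengths are clamped to zero with the deficit moved to the sibling
#' branch. On an additive (tree-realizable) matrix the generating topology
#' and branch lengths are recovered exactly.
#'
#' @param d A symmetric distance matrix with labelled rows/columns, or a
#'   [stats::dist].
#' @return An unrooted `phylo` tree (class from \pkg{ape}) with branch
#'   lengths; write it with [ape::write.tree()].
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  labels <- rownames(d) %||% paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 3) abort("neighbour joining needs at least 3 taxa")
  if (any(d < 0) || any(abs(d - t(d)) > 1e-8)) {
    abort("`d` must be a symmetric non-negative distance matrix")
  }
  # each active node carries a growing Newick fragment
  node <- labels
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  while (n > 3) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # lowest (row, col) among minima, scanning upper triangle row-major
    qmin <- min(q)
    cand <- which(q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]
    j <- cand[1, 2]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    if (bi < 0) {
      bj <- bj + bi
      bi <- 0
    }
    if (bj < 0) {
      bi <- bi + bj
      bj <- 0
    }
    merged <- sprintf("(%s:%s,%s:%s)", node[i], fmt(bi), node[j], fmt(bj))
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    node <- c(node[keep], merged)
    n <- n - 1
  }
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    node[1], fmt(b1), node[2], fmt(b2), node[3], fmt(b3))
  tree <- ape::read.tree(text = newick)
  # read.tree turns underscores into spaces; restore the input labels
  tree$tip.label <- gsub(" ", "_", tree$tip.label)
  tree
}
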