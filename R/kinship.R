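#' Identity-by-state counts for a sample pair
#'
#' Per jointly-called site, IBS = `2 - |dosage_a - dosage_b|`: opposite
#' homozygotes are IBS0, hom/het pairs IBS1, identical dosages (including
#' het/het) IBS2.
#'
#' @param gm A [geno_matrix()].
#' @param id_a,id_b Sample ids.
#' @return Named integer vector `c(ibs0, ibs1, ibs2)`.
#' @export
ibs_counts <- function(gm, id_a, id_b) {
  ga <- gm$geno[, sample_index(gm, id_a)]
  gb <- gm$geno[, sample_index(gm, id_b)]
  ok <- !is.na(ga) & !is.na(gb)
  if (!any(ok)) stop("no jointly-called sites for ", id_a, " / ", id_b)
  ibs <- 2L - abs(ga[ok] - gb[ok])
  c(ibs0 = sum(ibs == 0L), ibs1 = sum(ibs == 1L), ibs2 = sum(ibs == 2L))
}

#' IBS similarity DST
#'
#' `DST = (IBS2 + 0.5*IBS1) / (IBS0 + IBS1 + IBS2)`.
#'
#' @param counts Vector `c(ibs0, ibs1, ibs2)` from [ibs_counts()].
#' @return DST in `[0, 1]`; `NA` when the total is zero.
#' @export
dst <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  unname((counts[3] + 0.5 * counts[2]) / tot)
}

#' Method-of-moments IBD estimation for a sample pair
#'
#' PLINK-style moments: expected counts of each IBS class under IBD state
#' 0/1/2 are computed from cohort allele frequencies with small-sample bias
#' corrections, the observed IBS counts are solved sequentially for
#' `(P0, P1, P2)`, estimates are clamped to `[0, 1]` and renormalized, and
#' `PI_HAT = P2 + 0.5 * P1`.
#'
#' @param gm A [geno_matrix()].
#' @param id_a,id_b Sample ids.
#' @param freq_samples Samples whose genotypes estimate allele frequencies
#'   (default: the whole cohort, pair included).
#' @return One-row data frame: `id_a`, `id_b`, `ibs0..2`, `dst`,
#'   `p0`, `p1`, `p2`, `pi_hat`, `n_sites`.
#' @export
ibd_moments <- function(gm, id_a, id_b, freq_samples = NULL) {
  ja <- sample_index(gm, id_a); jb <- sample_index(gm, id_b)
  ga <- gm$geno[, ja]; gb <- gm$geno[, jb]
  sc <- site_counts(gm, freq_samples)
  p <- sc$p
  Na <- sc$m
  use <- !is.na(ga) & !is.na(gb) & !is.na(p) & p > 0 & p < 1 & Na >= 4
  if (!any(use)) stop("no polymorphic jointly-called sites")
  ga <- ga[use]; gb <- gb[use]; p <- p[use]; Na <- as.double(Na[use])
  q <- 1 - p
  # bias-corrected products of allele frequencies (Purcell et al. 2007 style)
  cf <- Na / (Na - 1) * Na / (Na - 2)
  cf3 <- cf * Na / (Na - 3)
  xp1 <- (p * Na - 1) / (p * Na)
  xp2 <- (p * Na - 2) / (p * Na)
  xp3 <- (p * Na - 3) / (p * Na)
  xq1 <- (q * Na - 1) / (q * Na)
  xq2 <- (q * Na - 2) / (q * Na)
  xq3 <- (q * Na - 3) / (q * Na)
  e00 <- 2 * p^2 * q^2 * xp1 * xq1 * cf3
  e10 <- 4 * p^3 * q * xp1 * xp2 * cf3 + 4 * p * q^3 * xq1 * xq2 * cf3
  e20 <- p^4 * xp1 * xp2 * xp3 * cf3 + q^4 * xq1 * xq2 * xq3 * cf3 +
    4 * p^2 * q^2 * xp1 * xq1 * cf3
  e11 <- 2 * p^2 * q * xp1 * cf + 2 * p * q^2 * xq1 * cf
  e21 <- p^3 * xp1 * xp2 * cf + q^3 * xq1 * xq2 * cf +
    p^2 * q * xp1 * cf + p * q^2 * xq1 * cf
  E00 <- sum(e00); E10 <- sum(e10); E20 <- sum(e20)
  E11 <- sum(e11); E21 <- sum(e21)
  L <- length(p)
  ibs <- 2L - abs(ga - gb)
  N0 <- sum(ibs == 0L); N1 <- sum(ibs == 1L); N2 <- sum(ibs == 2L)
  z0 <- N0 / E00
  z1 <- (N1 - z0 * E10) / E11
  z2 <- (N2 - z0 * E20 - z1 * E21) / L
  z <- pmax(c(z0, z1, z2), 0)
  if (sum(z) > 0) z <- z / sum(z) else z <- c(1, 0, 0)
  data.frame(id_a = id_a, id_b = id_b,
             ibs0 = N0, ibs1 = N1, ibs2 = N2,
             dst = (N2 + 0.5 * N1) / L,
             p0 = z[1], p1 = z[2], p2 = z[3],
             pi_hat = z[3] + 0.5 * z[2], n_sites = L)
}

#' All pairwise IBD estimates
#'
#' @param gm A [geno_matrix()].
#' @param samples Optional subset of sample ids.
#' @param freq_samples Samples used for allele frequencies.
#' @return Data frame with one row per unordered pair, as in
#'   [ibd_moments()].
#' @export
kinship_pairs <- function(gm, samples = NULL, freq_samples = NULL) {
  ids <- samples %||% gm$samples
  if (length(ids) < 2) stop("need at least two samples")
  prs <- combn(ids, 2)
  out <- lapply(seq_len(ncol(prs)), function(k)
    ibd_moments(gm, prs[1, k], prs[2, k], freq_samples))
  do.call(rbind, out)
}

#' Prune related samples by PI_HAT
#'
#' While any retained pair exceeds the threshold, the lower-quality member
#' is removed (ties go against the lexicographically larger id); the result
#' has no retained pair above the threshold.
#'
#' @param pairs Data frame with `id_a`, `id_b`, `pi_hat` (e.g. from
#'   [kinship_pairs()]).
#' @param quality Named numeric vector of per-sample quality (e.g. mean
#'   depth).
#' @param pi_hat_threshold Relatedness cutoff (default 0.2).
#' @return Character vector of retained sample ids.
#' @export
prune_related <- function(pairs, quality, pi_hat_threshold = 0.2) {
  kept <- names(quality)
  if (is.null(kept)) stop("quality must be a named vector")
  repeat {
    live <- pairs$id_a %in% kept & pairs$id_b %in% kept &
      pairs$pi_hat > pi_hat_threshold
    if (!any(live)) break
    r <- which(live)[1]
    a <- pairs$id_a[r]; b <- pairs$id_b[r]
    qa <- quality[[a]]; qb <- quality[[b]]
    drop <- if (qa < qb) a else if (qb < qa) b else max(a, b)
    kept <- setdiff(kept, drop)
  }
  kept
}

#' IBS distance matrix
#'
#' `distance(a, b) = 1 - DST(a, b)`; zero diagonal, symmetric.
#'
#' @param gm A [geno_matrix()].
#' @param samples Optional subset.
#' @return Square symmetric matrix with sample-id dimnames.
#' @export
ibs_distance_matrix <- function(gm, samples = NULL) {
  ids <- samples %||% gm$samples
  if (length(ids) < 2) stop("need at least two samples")
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- 1 - dst(ibs_counts(gm, ids[i], ids[j]))
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via \pkg{ape}); negative branch lengths are
#' clamped to zero with a warning.
#'
#' @param distmatrix Square symmetric matrix, `n >= 3`.
#' @param labels Optional tip labels (defaults to the matrix dimnames).
#' @return Newick string (with trailing newline stripped).
#' @export
nj_tree <- function(distmatrix, labels = NULL) {
  distmatrix <- as.matrix(distmatrix)
  if (nrow(distmatrix) != ncol(distmatrix) ||
      !isTRUE(all.equal(distmatrix, t(distmatrix), tolerance = 1e-8)))
    stop("distance matrix must be square and symmetric")
  if (nrow(distmatrix) < 3) stop("need at least 3 taxa")
  if (!is.null(labels)) dimnames(distmatrix) <- list(labels, labels)
  tr <- ape::nj(stats::as.dist(distmatrix))
  if (any(tr$edge.length < 0)) {
    warning("negative branch lengths clamped to zero")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  ape::write.tree(tr)
}

#' ABBA-BABA (Patterson's) D statistic
#'
#' Frequency-weighted site patterns over populations P1, P2, P3 and an
#' outgroup: `ABBA = sum (1-p1) p2 p3 (1-p4)`,
#' `BABA = sum p1 (1-p2) p3 (1-p4)`, `D = (ABBA-BABA)/(ABBA+BABA)`, with a
#' block-jackknife Z score over consecutive blocks of `block_snps` usable
#' sites.
#'
#' @param gm A [geno_matrix()].
#' @param p1,p2,p3,outgroup Character vectors of sample ids per population.
#' @param block_snps Jackknife block size in SNPs (default 5000).
#' @return List of class `dstat`: `d`, `z`, `abba`, `baba`, `n_sites`,
#'   `n_blocks`.
#' @export
patterson_d <- function(gm, p1, p2, p3, outgroup, block_snps = 5000) {
  pops <- list(p1, p2, p3, outgroup)
  if (length(intersect(outgroup, c(p1, p2, p3))))
    stop("outgroup must be distinct from P1-P3")
  fr <- sapply(pops, function(ids) site_counts(gm, ids)$p)
  ok <- rowSums(is.na(fr)) == 0
  fr <- fr[ok, , drop = FALSE]
  if (!nrow(fr)) stop("no sites covered in all four populations")
  abba <- (1 - fr[, 1]) * fr[, 2] * fr[, 3] * (1 - fr[, 4])
  baba <- fr[, 1] * (1 - fr[, 2]) * fr[, 3] * (1 - fr[, 4])
  A <- sum(abba); B <- sum(baba)
  if (A + B == 0) stop("ABBA + BABA is zero; D undefined")
  d <- (A - B) / (A + B)
  blk <- (seq_len(nrow(fr)) - 1) %/% block_snps
  nb <- length(unique(blk))
  z <- NA_real_
  if (nb >= 2) {
    dj <- vapply(unique(blk), function(b) {
      keep <- blk != b
      (sum(abba[keep]) - sum(baba[keep])) /
        (sum(abba[keep]) + sum(baba[keep]))
    }, numeric(1))
    se <- sqrt((nb - 1) / nb * sum((dj - mean(dj))^2))
    if (se > 0) z <- d / se
  }
  structure(list(d = d, z = z, abba = A, baba = B,
                 n_sites = nrow(fr), n_blocks = nb),
            class = "dstat")
}

#' @export
#' @method print dstat
print.dstat <- function(x, ...) {
  cat(sprintf("Patterson's D = %.4f (Z = %.2f, %d sites, %d blocks)\n",
              x$d, x$z, x$n_sites, x$n_blocks))
  invisible(x)
}

#' D from precomputed weighted pattern sums
#'
#' @param abba,baba Weighted ABBA and BABA sums.
#' @return `(abba - baba) / (abba + baba)`.
#' @export
d_stat <- function(abba, baba) {
  if (abba + baba == 0) stop("ABBA + BABA is zero; D undefined")
  (abba - baba) / (abba + baba)
}
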