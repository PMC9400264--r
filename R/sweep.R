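# major/minor allele observation counts within a population, per site;
# ties are broken by labeling the alphabetically smaller base as major
site_maj_min <- function(gm, pop) {
  sc <- site_counts(gm, pop)
  n_ref <- sc$m - sc$alt
  n_alt <- sc$alt
  maj <- pmax(n_ref, n_alt)
  min_ <- pmin(n_ref, n_alt)
  tie <- n_ref == n_alt
  if (any(tie)) {
    # counts equal: labels irrelevant for Hp, but fix major deterministically
    ref_major <- gm$sites$ref[tie] <= gm$sites$alt[tie]
    maj[tie] <- ifelse(ref_major, n_ref[tie], n_alt[tie])
    min_[tie] <- ifelse(ref_major, n_alt[tie], n_ref[tie])
  }
  list(maj = maj, min = min_)
}

#' Windowed pooled heterozygosity Hp
#'
#' `Hp = 2 * sum(n_MAJ) * sum(n_MIN) / (sum(n_MAJ) + sum(n_MIN))^2`, the
#' sums running over the window's SNPs, with `n_MAJ`/`n_MIN` the major and
#' minor allele observation counts in the focal population. Windows with
#' `min_snps` or fewer SNPs are undefined (`NA`).
#'
#' @param gm A [geno_matrix()].
#' @param pop Character vector of focal-population sample ids.
#' @param windows Window table from [make_windows()]; defaults to 40-kb
#'   tiles.
#' @param min_snps Minimum SNP count for eligibility (default 10,
#'   "more than 10 SNPs").
#' @return `windows` with added `n_snps` and `hp` columns.
#' @export
hp_windows <- function(gm, pop, windows = NULL, min_snps = 10) {
  if (!length(pop)) stop("empty population")
  if (is.null(windows)) {
    if (is.null(gm$scaffold_lengths))
      stop("no windows given and gm carries no scaffold lengths")
    windows <- make_windows(gm$scaffold_lengths, 40000)
  }
  mm <- site_maj_min(gm, pop)
  idx <- assign_windows(gm, windows)
  ok <- !is.na(idx)
  nw <- nrow(windows)
  windows$n_snps <- tabulate(idx[ok], nbins = nw)
  smaj <- rep(0, nw); smin <- rep(0, nw)
  am <- tapply(mm$maj[ok], idx[ok], sum)
  an <- tapply(mm$min[ok], idx[ok], sum)
  smaj[as.integer(names(am))] <- am
  smin[as.integer(names(an))] <- an
  tot <- smaj + smin
  windows$hp <- ifelse(windows$n_snps > min_snps & tot > 0,
                       2 * smaj * smin / tot^2, NA_real_)
  windows
}

#' Hp for a single window
#'
#' @inheritParams hp_windows
#' @param window One-row window (list or data frame with `scaffold`,
#'   `start`, `end`).
#' @return Hp value (`NA` when ineligible).
#' @export
hp_window <- function(gm, pop, window, min_snps = 10) {
  w <- data.frame(scaffold = window$scaffold, start = window$start,
                  end = window$end)
  hp_windows(gm, pop, w, min_snps)$hp
}

#' Genome-wide zHp standardization
#'
#' `zHp = (x - mu) / sigma` with `mu`, `sigma` the mean and (sample)
#' standard deviation of all defined window Hp values.
#'
#' @param hp Numeric vector of window Hp values (`NA` allowed).
#' @return Vector of zHp values (NA where Hp was undefined); attributes
#'   `mu` and `sigma`.
#' @export
zhp_standardize <- function(hp) {
  x <- hp[!is.na(hp)]
  if (length(x) < 2) stop("need at least two defined Hp windows")
  mu <- mean(x)
  sigma <- sd(x)
  if (sigma == 0) stop("Hp has zero variance; zHp undefined")
  structure((hp - mu) / sigma, mu = mu, sigma = sigma)
}

# Weir & Cockerham (1984) per-site variance components a, b, c for two
# populations, from genotype data (r = 2; h = observed heterozygote freq).
wc_site_components <- function(nA, pA, hA, nB, pB, hB) {
  r <- 2
  n_bar <- (nA + nB) / r
  n_c <- (r * n_bar - (nA^2 + nB^2) / (r * n_bar)) / (r - 1)
  p_bar <- (nA * pA + nB * pB) / (r * n_bar)
  s2 <- (nA * (pA - p_bar)^2 + nB * (pB - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (nA * hA + nB * hB) / (r * n_bar)
  a <- n_bar / n_c *
    (s2 - 1 / (n_bar - 1) *
       (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) /
       (4 * n_bar) * h_bar)
  c <- h_bar / 2
  list(a = a, b = b, c = c)
}

#' Windowed Weir-Cockerham F_ST
#'
#' Per-site variance components `a`, `b`, `c` (Weir & Cockerham 1984) are
#' combined per window as the ratio of sums `sum(a) / sum(a+b+c)`; windows
#' with fewer than `min_snps` usable SNPs (both populations with at least 2
#' called diploids) are undefined.
#'
#' @param gm A [geno_matrix()].
#' @param pop_a,pop_b Sample id vectors for the two populations.
#' @param windows Window table; defaults to 40-kb tiles.
#' @param min_snps Minimum usable SNPs per window (default 10).
#' @return `windows` with added `n_snps` (usable sites) and `fst` columns.
#' @export
wc_fst_windows <- function(gm, pop_a, pop_b, windows = NULL, min_snps = 10) {
  if (is.null(windows)) {
    if (is.null(gm$scaffold_lengths))
      stop("no windows given and gm carries no scaffold lengths")
    windows <- make_windows(gm$scaffold_lengths, 40000)
  }
  ja <- sample_index(gm, pop_a); jb <- sample_index(gm, pop_b)
  ga <- gm$geno[, ja, drop = FALSE]; gb <- gm$geno[, jb, drop = FALSE]
  nA <- rowSums(!is.na(ga)); nB <- rowSums(!is.na(gb))
  ok <- nA >= 2 & nB >= 2
  pA <- rowSums(ga, na.rm = TRUE) / (2 * nA)
  pB <- rowSums(gb, na.rm = TRUE) / (2 * nB)
  hA <- rowSums(ga == 1L, na.rm = TRUE) / nA
  hB <- rowSums(gb == 1L, na.rm = TRUE) / nB
  comp <- wc_site_components(nA, pA, hA, nB, pB, hB)
  idx <- assign_windows(gm, windows)
  use <- ok & !is.na(idx)
  nw <- nrow(windows)
  windows$n_snps <- tabulate(idx[use], nbins = nw)
  su_a <- rep(0, nw); su_abc <- rep(0, nw)
  ta <- tapply(comp$a[use], idx[use], sum)
  tabc <- tapply((comp$a + comp$b + comp$c)[use], idx[use], sum)
  su_a[as.integer(names(ta))] <- ta
  su_abc[as.integer(names(tabc))] <- tabc
  windows$fst <- ifelse(windows$n_snps >= min_snps & su_abc > 0,
                        su_a / su_abc, NA_real_)
  windows
}

#' Dual-threshold top-quantile sweep candidates
#'
#' The F_ST threshold is the empirical `(1 - quantile)` quantile of defined
#' window F_ST values and the zHp threshold the `quantile` quantile of
#' defined zHp values (linear interpolation between order statistics);
#' a window is a candidate iff `F_ST >= fst_threshold` and
#' `zHp <= zhp_threshold`. Candidates are returned sorted by zHp ascending.
#'
#' @param fst_stats Output of [wc_fst_windows()].
#' @param zhp_stats Window table with a `zhp` column (see
#'   [zhp_standardize()]); must describe the same windows.
#' @param quantile Tail mass (default 0.01, i.e. top 1 percent).
#' @return List: `windows` (merged table with `passes_fst`, `passes_zhp`,
#'   `is_overlap`), `overlap` (candidate subset, zHp ascending),
#'   `fst_threshold`, `zhp_threshold`.
#' @export
dual_threshold_overlap <- function(fst_stats, zhp_stats, quantile = 0.01) {
  key_f <- paste(fst_stats$scaffold, fst_stats$start, fst_stats$end)
  key_z <- paste(zhp_stats$scaffold, zhp_stats$start, zhp_stats$end)
  m <- match(key_f, key_z)
  if (anyNA(m)) stop("fst and zhp statistics must cover the same windows")
  w <- fst_stats[c("scaffold", "start", "end")]
  w$fst <- fst_stats$fst
  w$zhp <- zhp_stats$zhp[m]
  def <- !is.na(w$fst) & !is.na(w$zhp)
  if (sum(def) < 100)
    warning("fewer than 100 defined windows; empirical quantiles unstable")
  fst_thr <- stats::quantile(w$fst[!is.na(w$fst)], 1 - quantile,
                             type = 7, names = FALSE)
  zhp_thr <- stats::quantile(w$zhp[!is.na(w$zhp)], quantile,
                             type = 7, names = FALSE)
  w$passes_fst <- !is.na(w$fst) & w$fst >= fst_thr
  w$passes_zhp <- !is.na(w$zhp) & w$zhp <= zhp_thr
  w$is_overlap <- w$passes_fst & w$passes_zhp
  ov <- w[w$is_overlap, , drop = FALSE]
  ov <- ov[order(ov$zhp), , drop = FALSE]
  list(windows = w, overlap = ov,
       fst_threshold = fst_thr, zhp_threshold = zhp_thr)
}

#' Diversity profile around a sweep candidate
#'
#' Pi and Tajima's D in `subwindow`-bp tiles over the candidate window
#' extended by `flank` bp on both sides, clipped at scaffold ends.
#'
#' @param gm A [geno_matrix()].
#' @param hit_window One-row window (`scaffold`, `start`, `end`).
#' @param pop Optional focal-population sample ids.
#' @param flank Flank size in bp (default 500 kb).
#' @param subwindow Tile size in bp (default 10 kb).
#' @return Tile table with `n_snps`, `pi`, `tajima_d`.
#' @export
flank_profile <- function(gm, hit_window, pop = NULL, flank = 500000,
                          subwindow = 10000) {
  sc <- hit_window$scaffold
  L <- if (!is.null(gm$scaffold_lengths) &&
           sc %in% names(gm$scaffold_lengths))
    gm$scaffold_lengths[[sc]] else Inf
  a <- max(0, hit_window$start - flank)
  b <- min(L, hit_window$end + flank)
  starts <- a + subwindow * (seq_len(ceiling((b - a) / subwindow)) - 1)
  tiles <- data.frame(scaffold = sc, start = starts,
                      end = pmin(starts + subwindow, b))
  p <- pi_windows(gm, tiles, samples = pop)
  d <- tajima_d_windows(gm, tiles, samples = pop)
  p$tajima_d <- d$tajima_d
  p
}

#' Annotate windows with overlapping genes
#'
#' Any-overlap (at least 1 bp, half-open BED semantics) between windows and
#' gene intervals; a gene starting exactly at a window's end does not
#' overlap it.
#'
#' @param windows Window table (`scaffold`, `start`, `end`; 0-based
#'   half-open).
#' @param gene_bed Path to a BED file (`chrom`, `start`, `end`, `name`) or
#'   an equivalently named data frame.
#' @return `windows` with a `genes` list-column plus attribute
#'   `"all_genes"`, the deduplicated overall gene list.
#' @export
annotate_genes <- function(windows, gene_bed) {
  genes <- if (is.character(gene_bed)) {
    g <- rtracklayer::import(gene_bed, format = "BED")
    data.frame(scaffold = as.character(GenomicRanges::seqnames(g)),
               start = GenomicRanges::start(g) - 1L,
               end = GenomicRanges::end(g),
               name = g$name %||% paste0("gene", seq_along(g)))
  } else as.data.frame(gene_bed)
  if (is.null(genes$name)) genes$name <- paste0("gene", seq_len(nrow(genes)))
  wr <- GenomicRanges::GRanges(
    windows$scaffold,
    IRanges::IRanges(start = windows$start + 1L, end = windows$end))
  gr <- GenomicRanges::GRanges(
    genes$scaffold,
    IRanges::IRanges(start = genes$start + 1L, end = genes$end))
  hits <- GenomicRanges::findOverlaps(wr, gr)
  lst <- split(genes$name[S4Vectors::subjectHits(hits)],
               factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(windows))))
  windows$genes <- lapply(lst, function(x) sort(unique(x)))
  attr(windows, "all_genes") <- sort(unique(genes$name[S4Vectors::subjectHits(hits)]))
  windows
}

#' One-call selective-sweep scan
#'
#' Computes window Hp for the focal population, standardizes it genome-wide
#' to zHp, computes windowed Weir-Cockerham F_ST between the focal and the
#' contrast population, and applies the dual top-quantile overlap rule.
#'
#' @param gm A [geno_matrix()].
#' @param pop_a Focal population sample ids (scanned for low Hp).
#' @param pop_b Contrast population sample ids.
#' @param window_size Window size in bp (default 40 kb).
#' @param quantile Tail mass for both thresholds (default 0.01).
#' @param min_snps Window eligibility (default 10).
#' @return As [dual_threshold_overlap()], with `hp` included in `windows`.
#' @export
sweep_scan <- function(gm, pop_a, pop_b, window_size = 40000,
                       quantile = 0.01, min_snps = 10) {
  windows <- make_windows(gm$scaffold_lengths, window_size)
  hp <- hp_windows(gm, pop_a, windows, min_snps)
  hp$zhp <- as.numeric(zhp_standardize(hp$hp))
  fst <- wc_fst_windows(gm, pop_a, pop_b, windows, min_snps)
  res <- dual_threshold_overlap(fst, hp, quantile)
  res$windows$hp <- hp$hp
  res
}
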