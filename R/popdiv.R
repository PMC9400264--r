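# Per-site unbiased pairwise-diversity contribution: 2*p*(1-p) * m/(m-1)
# with m the number of called alleles. Equals the mean pairwise difference
# 2*c*(m-c)/(m*(m-1)) for alt count c.
site_pi_terms <- function(gm, samples = NULL) {
  sc <- site_counts(gm, samples)
  ok <- sc$m >= 2
  term <- rep(0, n_sites(gm))
  term[ok] <- 2 * sc$p[ok] * (1 - sc$p[ok]) * sc$m[ok] / (sc$m[ok] - 1)
  list(term = term, m = sc$m, alt = sc$alt)
}

#' Windowed nucleotide diversity
#'
#' Per window, `pi = sum_sites 2*p*(1-p) * m/(m-1) / window_size`, `m` the
#' non-missing allele count at the site; windows without variants get 0.
#'
#' @param gm A [geno_matrix()].
#' @param windows Window table from [make_windows()]; defaults to 40-kb tiles
#'   over the scaffold lengths carried by `gm`.
#' @param samples Optional sample subset defining the population.
#' @param size Window size used when `windows` is NULL.
#' @return `windows` with added `n_snps` and `pi` columns.
#' @export
pi_windows <- function(gm, windows = NULL, samples = NULL, size = 40000) {
  if (is.null(windows)) {
    if (is.null(gm$scaffold_lengths))
      stop("no windows given and gm carries no scaffold lengths")
    windows <- make_windows(gm$scaffold_lengths, size)
  }
  terms <- site_pi_terms(gm, samples)
  idx <- assign_windows(gm, windows)
  ok <- !is.na(idx)
  windows$n_snps <- tabulate(idx[ok], nbins = nrow(windows))
  psum <- rep(0, nrow(windows))
  agg <- tapply(terms$term[ok], idx[ok], sum)
  psum[as.integer(names(agg))] <- agg
  windows$pi <- psum / (windows$end - windows$start)
  windows
}

tajima_constants <- function(n) {
  # Tajima (1989) normalizing constants for n sampled chromosomes
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' `D = (pi_abs - S/a1) / sqrt(e1*S + e2*S*(S-1))`, with the 1989 constants
#' computed from `n` chromosomes taken as twice the site-wise minimum of
#' non-missing diploids across the window's segregating sites, and `pi_abs`
#' the window sum of per-site mean pairwise differences. Undefined (`NA`)
#' when the window has fewer than 3 segregating sites or fewer than 4
#' chromosomes.
#'
#' @inheritParams pi_windows
#' @return `windows` with added `n_snps` (segregating sites among the used
#'   samples) and `tajima_d` columns.
#' @export
tajima_d_windows <- function(gm, windows = NULL, samples = NULL, size = 10000) {
  if (is.null(windows)) {
    if (is.null(gm$scaffold_lengths))
      stop("no windows given and gm carries no scaffold lengths")
    windows <- make_windows(gm$scaffold_lengths, size)
  }
  sc <- site_counts(gm, samples)
  seg <- sc$m >= 2 & sc$alt > 0 & sc$alt < sc$m
  idx <- assign_windows(gm, windows)
  pi_term <- ifelse(seg, 2 * sc$p * (1 - sc$p) * sc$m / pmax(sc$m - 1, 1), 0)
  windows$n_snps <- 0L
  windows$tajima_d <- NA_real_
  use <- which(seg & !is.na(idx))
  if (!length(use)) return(windows)
  by_win <- split(use, idx[use])
  for (wname in names(by_win)) {
    w <- as.integer(wname)
    s <- by_win[[wname]]
    S <- length(s)
    windows$n_snps[w] <- S
    n <- min(sc$m[s])
    if (S < 3 || n < 4) next
    k <- tajima_constants(n)
    pa <- sum(pi_term[s])
    windows$tajima_d[w] <- (pa - S / k$a1) /
      sqrt(k$e1 * S + k$e2 * S * (S - 1))
  }
  windows
}

#' Per-sample heterozygosity rate
#'
#' Number of heterozygous genotypes divided by the genome length.
#'
#' @param gm A [geno_matrix()].
#' @param sample Sample id.
#' @param genome_length Denominator in bp; defaults to the sum of scaffold
#'   lengths carried by `gm`.
#' @return Heterozygous genotypes per bp.
#' @export
heterozygosity_rate <- function(gm, sample, genome_length = NULL) {
  j <- sample_index(gm, sample)
  genome_length <- genome_length %||% sum(gm$scaffold_lengths)
  stopifnot_scalar_pos(genome_length, "genome_length")
  sum(gm$geno[, j] == 1L, na.rm = TRUE) / genome_length
}

#' Call runs of homozygosity for one sample
#'
#' Deterministic run-growing over the sorted site sequence: maximal runs of
#' consecutive calls containing at most `max_het` heterozygotes and
#' `max_missing` missing genotypes, trimmed to homozygous end sites, are
#' accepted iff their span is at least `min_kb` kb and they contain at least
#' `min_snps` homozygous SNPs. Accepted segments are disjoint per sample.
#'
#' @param gm A [geno_matrix()].
#' @param sample Sample id.
#' @param min_snps Minimum SNPs inside a segment (default 10).
#' @param min_kb Minimum span in kb (default 40).
#' @param max_missing Maximum missing calls tolerated inside (default 2).
#' @param max_het Maximum heterozygous calls tolerated inside (default 0).
#' @return Data frame of segments: `sample`, `scaffold`, `start`, `end`
#'   (0-based half-open), `length`, `n_snps`, `n_missing`.
#' @export
call_roh <- function(gm, sample, min_snps = 10, min_kb = 40,
                     max_missing = 2, max_het = 0) {
  j <- sample_index(gm, sample)
  out <- list()
  for (sc in unique(gm$sites$scaffold)) {
    s <- which(gm$sites$scaffold == sc)
    g <- gm$geno[s, j]
    pos <- gm$sites$pos[s]
    het <- !is.na(g) & g == 1L
    mis <- is.na(g)
    n <- length(g)
    left <- 1L
    nh <- 0L; nm <- 0L
    last_end <- 0L  # last accepted segment's end index, for disjointness
    flush <- function(l, r) {
      # trim to homozygous endpoints
      while (l <= r && (het[l] || mis[l])) l <- l + 1L
      while (r >= l && (het[r] || mis[r])) r <- r - 1L
      if (l > r) return(NULL)
      nh_in <- sum(!het[l:r] & !mis[l:r])
      span_start <- pos[l] - 1L
      span_end <- pos[r]
      if (span_end - span_start >= min_kb * 1000 && nh_in >= min_snps)
        data.frame(sample = sample, scaffold = sc,
                   start = span_start, end = span_end,
                   length = span_end - span_start,
                   n_snps = nh_in, n_missing = sum(mis[l:r]))
      else NULL
    }
    r <- 0L
    for (i in seq_len(n)) {
      nh <- nh + het[i]; nm <- nm + mis[i]
      while (nh > max_het || nm > max_missing) {
        nh <- nh - het[left]; nm <- nm - mis[left]
        left <- left + 1L
      }
      # maximal window ending at i is [left, i]; emit when the next site
      # would shrink it or the scaffold ends
      nxt_breaks <- i == n ||
        (nh + het[i + 1] > max_het) || (nm + mis[i + 1] > max_missing)
      if (nxt_breaks && left > last_end) {
        seg <- flush(max(left, last_end + 1L), i)
        if (!is.null(seg)) {
          out[[length(out) + 1]] <- seg
          last_end <- i
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(sample = character(), scaffold = character(),
                      start = numeric(), end = numeric(), length = numeric(),
                      n_snps = integer(), n_missing = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bin ROH segments into the four canonical length classes
#'
#' Classes: `<100 kb`, `[100, 500) kb`, `[500, 1000) kb`, `>=1000 kb`.
#'
#' @param segments Segment table from [call_roh()].
#' @return Named integer vector of counts.
#' @export
bin_roh <- function(segments) {
  br <- c(0, 100e3, 500e3, 1000e3, Inf)
  lab <- c("<100kb", "100-500kb", "500-1000kb", ">1000kb")
  if (!nrow(segments)) return(setNames(rep(0L, 4), lab))
  setNames(as.integer(table(cut(segments$length, br, labels = lab,
                                right = FALSE))), lab)
}

#' Genomic inbreeding coefficient from ROH
#'
#' `F_ROH` = summed segment length / genome length.
#'
#' @param segments Segment table from [call_roh()] (one sample).
#' @param genome_length Total genome length in bp.
#' @return F_ROH in `[0, 1]`.
#' @export
f_roh <- function(segments, genome_length) {
  stopifnot_scalar_pos(genome_length, "genome_length")
  if (!nrow(segments)) return(0)
  for (sm in unique(segments$sample)) {
    for (sc in unique(segments$scaffold)) {
      s <- segments[segments$sample == sm & segments$scaffold == sc, ]
      if (nrow(s) < 2) next
      s <- s[order(s$start), ]
      if (any(s$start[-1] < s$end[-nrow(s)]))
        stop("overlapping ROH segments for sample ", sm)
    }
  }
  sum(segments$length) / genome_length
}

#' Flag low-diversity windows and merge them into LROH runs
#'
#' Windows with `pi < pi_threshold` are flagged; maximal runs of consecutive
#' flagged windows per scaffold are merged and reported with their total
#' span.
#'
#' @param window_stats Output of [pi_windows()].
#' @param pi_threshold Strict upper bound on pi (default 1e-4).
#' @return List: `windows` (input with logical `lroh` column) and `runs`
#'   (data frame `scaffold`, `start`, `end`, `n_windows`, `span`).
#' @export
flag_lroh <- function(window_stats, pi_threshold = 1e-4) {
  ws <- window_stats
  ws$lroh <- ws$pi < pi_threshold
  runs <- list()
  for (sc in unique(ws$scaffold)) {
    w <- ws[ws$scaffold == sc, ]
    w <- w[order(w$start), ]
    r <- rle(w$lroh)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      runs[[length(runs) + 1]] <- data.frame(
        scaffold = sc, start = w$start[starts[k]], end = w$end[ends[k]],
        n_windows = r$lengths[k],
        span = w$end[ends[k]] - w$start[starts[k]])
    }
  }
  runs <- if (length(runs)) do.call(rbind, runs) else
    data.frame(scaffold = character(), start = numeric(), end = numeric(),
               n_windows = integer(), span = numeric())
  list(windows = ws, runs = runs)
}

#' Linkage-disequilibrium decay
#'
#' r-squared is the squared sample correlation of dosage vectors over
#' jointly non-missing samples, for all intra-scaffold pairs up to
#' `max_dist`; pairs are binned by distance and the decay length is the
#' first distance (linear interpolation between bin midpoints) at which the
#' binned mean crosses `r2_target` from above (`NA` when the curve never
#' exceeds or never drops below it).
#'
#' @param gm A [geno_matrix()].
#' @param samples Optional sample subset.
#' @param max_dist Maximum pair distance in bp (default 500 kb).
#' @param bin_bp Distance bin width (default 1 kb).
#' @param r2_target Crossing level summarized as the decay length
#'   (default 0.3).
#' @return List: `points` (data frame `bin_mid`, `mean_r2`, `n_pairs`) and
#'   `decay_length` in bp.
#' @export
ld_decay <- function(gm, samples = NULL, max_dist = 500000, bin_bp = 1000,
                     r2_target = 0.3) {
  g <- gm$geno
  if (!is.null(samples)) g <- g[, sample_index(gm, samples), drop = FALSE]
  dists <- numeric(); r2s <- numeric()
  for (sc in unique(gm$sites$scaffold)) {
    s <- which(gm$sites$scaffold == sc)
    if (length(s) < 2) next
    gs <- t(g[s, , drop = FALSE])
    keep <- apply(gs, 2, function(x) stats::var(x, na.rm = TRUE)) > 0
    keep[is.na(keep)] <- FALSE
    s <- s[keep]; gs <- gs[, keep, drop = FALSE]
    if (length(s) < 2) next
    cc <- suppressWarnings(cor(gs, use = "pairwise.complete.obs"))^2
    pos <- gm$sites$pos[s]
    dd <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(dd)
    sel <- ut & dd <= max_dist & !is.na(cc)
    dists <- c(dists, dd[sel])
    r2s <- c(r2s, cc[sel])
  }
  if (!length(dists)) stop("no usable site pairs for LD decay")
  bin <- floor(dists / bin_bp)
  mid <- (bin + 0.5) * bin_bp
  pts <- data.frame(bin_mid = sort(unique(mid)))
  agg_m <- tapply(r2s, mid, mean)
  agg_n <- tapply(r2s, mid, length)
  pts$mean_r2 <- as.numeric(agg_m[as.character(pts$bin_mid)])
  pts$n_pairs <- as.integer(agg_n[as.character(pts$bin_mid)])
  decay <- NA_real_
  above <- pts$mean_r2 >= r2_target
  if (any(above) && any(!above)) {
    # first downward crossing
    for (i in seq_len(nrow(pts) - 1)) {
      if (above[i] && !above[i + 1]) {
        x0 <- pts$bin_mid[i]; x1 <- pts$bin_mid[i + 1]
        y0 <- pts$mean_r2[i]; y1 <- pts$mean_r2[i + 1]
        decay <- x0 + (y0 - r2_target) / (y0 - y1) * (x1 - x0)
        break
      }
    }
  }
  list(points = pts, decay_length = decay)
}

#' Method-of-moments inbreeding coefficient for one sample
#'
#' `F = (O_hom - E_hom) / (L_used - E_hom)` with
#' `E_hom = sum_sites [1 - 2*p*(1-p) * m/(m-1)]`, allele frequencies
#' estimated from `freq_samples` (default: all samples). Negative values
#' indicate heterozygosity excess.
#'
#' @param gm A [geno_matrix()].
#' @param sample Sample id.
#' @param freq_samples Samples used for allele-frequency estimation.
#' @return F (may be negative); `NA` when no usable site remains.
#' @export
inbreeding_f <- function(gm, sample, freq_samples = NULL) {
  j <- sample_index(gm, sample)
  sc <- site_counts(gm, freq_samples)
  g <- gm$geno[, j]
  use <- !is.na(g) & sc$m >= 2 & sc$p > 0 & sc$p < 1
  if (!any(use)) return(NA_real_)
  ehet <- 2 * sc$p[use] * (1 - sc$p[use]) * sc$m[use] / (sc$m[use] - 1)
  e_hom <- sum(1 - ehet)
  o_hom <- sum(g[use] != 1L)
  L <- sum(use)
  if (abs(L - e_hom) < .Machine$double.eps) return(NA_real_)
  (o_hom - e_hom) / (L - e_hom)
}
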