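# independent oracle: mean pairwise difference per site from explicit
# enumeration of all allele pairs, summed over sites, divided by span
pi_bruteforce <- function(geno, span) {
  tot <- 0
  for (i in seq_len(nrow(geno))) {
    g <- geno[i, ]
    g <- g[!is.na(g)]
    if (length(g) < 2) next
    # expand diploids into alleles
    al <- unlist(lapply(g, function(d) c(as.integer(d >= 1), as.integer(d == 2))))
    prs <- combn(length(al), 2)
    tot <- tot + mean(al[prs[1, ]] != al[prs[2, ]])
  }
  tot / span
}

test_that("windowed pi matches the haplotype-pair enumeration oracle", {
  # printed example: one site, 2 diploids, dosages (0, 2), 40-kb window
  gm <- toy_gm(matrix(c(0L, 2L), 1, 2), pos = 5000L, L = 40000)
  pw <- pi_windows(gm, size = 40000)
  expect_equal(pw$pi, (2 * 0.5 * 0.5 * 4 / 3) / 40000, tolerance = 1e-12)
  expect_equal(pw$pi, pi_bruteforce(gm$geno, 40000), tolerance = 1e-12)
  # random matrices with missingness
  set.seed(42)
  for (k in 1:20) {
    g <- matrix(rbinom(8 * 6, 2, runif(1, 0.1, 0.9)), 8, 6)
    g[sample(length(g), 5)] <- NA
    gm <- toy_gm(g, pos = sort(sample(1:39999, 8)), L = 40000)
    expect_equal(pi_windows(gm, size = 40000)$pi,
                 pi_bruteforce(gm$geno, 40000), tolerance = 1e-12)
  }
  # monomorphic sites and empty windows contribute zero
  gm0 <- toy_gm(matrix(0L, 3, 4), L = 80000)
  expect_equal(pi_windows(gm0, size = 40000)$pi, c(0, 0))
})

test_that("pi is invariant to allele relabeling and aggregates linearly", {
  set.seed(7)
  g <- matrix(rbinom(40, 2, 0.4), 10, 4)
  gm <- toy_gm(g, pos = c(1:5 * 1000L, 40001L + 1:5 * 1000L), L = 80000)
  flipped <- toy_gm(2L - g, pos = gm$sites$pos, L = 80000)
  expect_equal(pi_windows(gm, size = 40000)$pi,
               pi_windows(flipped, size = 40000)$pi)
  parts <- pi_windows(gm, size = 40000)
  whole <- pi_windows(gm, size = 80000)
  expect_equal(whole$pi,
               sum(parts$pi * (parts$end - parts$start)) / 80000)
})

# independent transcription of the 1989 statistic for the test's use
tajima_oracle <- function(geno, pos, span_start, span_end) {
  called <- 2 * colSums(!is.na(t(geno)))
  m <- apply(geno, 1, function(g) 2 * sum(!is.na(g)))
  alt <- rowSums(geno, na.rm = TRUE)
  seg <- m >= 2 & alt > 0 & alt < m
  S <- sum(seg)
  n <- min(m[seg])
  if (S < 3 || n < 4) return(NA_real_)
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  pi_abs <- sum(sapply(which(seg), function(i) {
    c_ <- alt[i]; mm <- m[i]
    2 * c_ * (mm - c_) / (mm * (mm - 1))
  }))
  (pi_abs - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

test_that("Tajima's D agrees with the direct formula oracle", {
  # all-singleton configuration is negative
  g <- matrix(0L, 16, 5)
  for (i in 1:16) g[i, (i - 1) %% 5 + 1] <- 1L
  gm <- toy_gm(g, pos = 1:16 * 500L, L = 10000)
  d <- tajima_d_windows(gm, size = 10000)$tajima_d
  expect_lt(d, 0)
  expect_equal(d, tajima_oracle(g, gm$sites$pos, 0, 10000), tolerance = 1e-10)
  # random matrices
  set.seed(33)
  for (k in 1:15) {
    g <- matrix(rbinom(12 * 6, 2, runif(1, 0.1, 0.9)), 12, 6)
    g[sample(length(g), 4)] <- NA
    gm <- toy_gm(g, pos = sort(sample(1:9999, 12)), L = 10000)
    got <- tajima_d_windows(gm, size = 10000)$tajima_d
    expect_equal(got, tajima_oracle(g, gm$sites$pos, 0, 10000),
                 tolerance = 1e-10)
  }
  # undefined below three segregating sites
  g2 <- matrix(c(0L, 1L, 0L, 0L), 1, 4)
  expect_true(is.na(tajima_d_windows(toy_gm(g2, L = 10000),
                                     size = 10000)$tajima_d))
})

test_that("heterozygosity rate counts het genotypes per bp", {
  g <- matrix(c(1L, 1L, 0L, 2L, 1L, NA), 3, 2)
  gm <- toy_gm(g, L = 1e6)
  expect_equal(heterozygosity_rate(gm, "s1", 1e6), 2 / 1e6)
  expect_equal(heterozygosity_rate(gm, "s2", 1e6), 1 / 1e6)
  expect_equal(heterozygosity_rate(toy_gm(matrix(0L, 3, 2), L = 1e6),
                                   "s1", 1e6), 0)
  expect_error(heterozygosity_rate(gm, "nope"), "unknown sample")
})

test_that("ROH calling honors both thresholds with exact boundaries", {
  # 60-kb homozygous run with 25 SNPs flanked by hets -> recovered
  pos <- c(1000L, seq(2000L, 60000L, length.out = 25), 61500L, 70000L)
  pos <- as.integer(round(pos))
  g <- matrix(2L, length(pos), 1)
  g[1, 1] <- 1L; g[27, 1] <- 1L; g[28, 1] <- 1L
  gm <- toy_gm(g, pos = pos, L = 100000)
  seg <- call_roh(gm, "s1")
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start, 2000 - 1)
  expect_equal(seg$end, 60000)
  expect_equal(seg$n_snps, 25)
  # 30-kb run is rejected by the 40-kb rule even with plenty of SNPs
  pos2 <- as.integer(seq(1000L, 31000L, length.out = 30))
  g2 <- matrix(2L, 30, 1)
  expect_equal(nrow(call_roh(toy_gm(g2, pos = pos2, L = 50000), "s1")), 0)
  # enough span but too few SNPs is rejected too
  pos3 <- as.integer(seq(1000L, 81000L, length.out = 8))
  expect_equal(nrow(call_roh(toy_gm(matrix(2L, 8, 1), pos = pos3, L = 1e5),
                             "s1")), 0)
  # fully heterozygous sample yields nothing
  expect_equal(nrow(call_roh(toy_gm(matrix(1L, 50, 1),
                                    pos = 1:50 * 2000L, L = 2e5), "s1")), 0)
  # tolerated missing calls do not break a run; a third one does
  posm <- as.integer(seq(1000L, 61000L, length.out = 25))
  gmiss <- matrix(2L, 25, 1); gmiss[c(5, 10), 1] <- NA
  expect_equal(nrow(call_roh(toy_gm(gmiss, pos = posm, L = 1e5), "s1")), 1)
  gmiss3 <- gmiss; gmiss3[15, 1] <- NA
  segs3 <- call_roh(toy_gm(gmiss3, pos = posm, L = 1e5), "s1")
  expect_true(all(segs3$n_missing <= 2))
})

test_that("ROH length bins and F_ROH behave arithmetically", {
  segs <- data.frame(sample = "x", scaffold = paste0("c", 1:4),
                     start = 0, end = c(50e3, 150e3, 600e3, 1500e3),
                     length = c(50e3, 150e3, 600e3, 1500e3),
                     n_snps = 100L, n_missing = 0L)
  expect_equal(unname(bin_roh(segs)), c(1L, 1L, 1L, 1L))
  expect_equal(sum(bin_roh(segs)), nrow(segs))
  expect_equal(unname(bin_roh(segs[0, ])), rep(0L, 4))
  expect_equal(f_roh(segs[0, ], 1e6), 0)
  one <- segs[4, ]; one$start <- 0; one$end <- 1e6; one$length <- 1e6
  expect_equal(f_roh(one, 1e6), 1)
  overlapping <- rbind(segs[1, ], segs[1, ])
  overlapping$scaffold <- "c1"
  expect_error(f_roh(overlapping, 1e6), "overlap")
})

test_that("LROH flagging uses a strict threshold and merges runs", {
  ws <- data.frame(scaffold = "s1", start = 0:5 * 40000,
                   end = 1:6 * 40000,
                   pi = c(2e-4, 9.9e-5, 5e-5, 8e-5, 2e-4, 1e-4))
  out <- flag_lroh(ws)
  expect_equal(out$windows$lroh, c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(nrow(out$runs), 1)
  expect_equal(out$runs$span, 120000)
  none <- flag_lroh(transform(ws, pi = pi + 1))
  expect_equal(nrow(none$runs), 0)
})

test_that("LD decay reflects planted correlation structure", {
  # duplicated site pair has r2 = 1
  g <- rbind(c(0, 1, 2, 1, 0, 2, 1, 1), c(0, 1, 2, 1, 0, 2, 1, 1))
  ld <- ld_decay(toy_gm(g, pos = c(1000L, 3000L)), bin_bp = 1000)
  expect_equal(ld$points$mean_r2, 1)
  # independent sites: mean r2 near the 1/n finite-sample floor
  gi <- random_gm(80, 25, seed = 15)
  ldi <- ld_decay(gi, max_dist = 100000, bin_bp = 10000)
  expect_lt(abs(mean(ldi$points$mean_r2) - 1 / 25), 0.03)
  expect_true(is.na(ldi$decay_length))  # never exceeds 0.3
  # planted monotone decay: the crossing is interpolated between the
  # bracketing bins (recomputed from the returned points)
  set.seed(99)
  base <- rbinom(40, 2, 0.5)
  noise_at <- function(k) {
    g <- base
    flip <- sample(40, k)
    g[flip] <- rbinom(length(flip), 2, 0.5)
    g
  }
  g <- do.call(rbind, lapply(c(0, 2, 4, 8, 12, 18, 24, 32, 40), noise_at))
  gm <- toy_gm(g, pos = as.integer(0:8 * 5000 + 1000), L = 1e5)
  ld2 <- ld_decay(gm, max_dist = 50000, bin_bp = 5000)
  pts <- ld2$points
  above <- pts$mean_r2 >= 0.3
  i <- which(above[-nrow(pts)] & !above[-1])[1]
  expect_false(is.na(ld2$decay_length))
  expect_gt(ld2$decay_length, pts$bin_mid[i])
  expect_lt(ld2$decay_length, pts$bin_mid[i + 1])
  y <- approx(pts$bin_mid[c(i, i + 1)], pts$mean_r2[c(i, i + 1)],
              xout = ld2$decay_length)$y
  expect_equal(y, 0.3, tolerance = 1e-9)
})

test_that("inbreeding F recovers planted values with slope near one", {
  # excess heterozygosity at 50/50 sites is negative
  g <- matrix(1L, 50, 4)
  g[, 3] <- 0L; g[, 4] <- 2L   # keep frequencies at 0.5
  gm <- toy_gm(g)
  expect_lt(inbreeding_f(gm, "s1"), 0)
  # parameter recovery over a grid of planted f
  fs <- c(0, 0.1, 0.25, 0.5)
  est <- sapply(seq_along(fs), function(k) {
    cfg <- sim_config(seed = 400 + k, n_scaffolds = 2,
                      scaffold_length = 5e5,
                      groups = data.frame(name = c("A", "B"), n = c(15L, 4L),
                                          theta = c(1e-3, 1e-3),
                                          f = c(fs[k], 0)),
                      sex_design = list(n_z = 0, n_w = 0))
    co <- simulate_cohort(cfg)
    A <- co$samples$id[co$samples$group == "A"]
    mean(sapply(A, function(sm) inbreeding_f(co$gm, sm, freq_samples = A)))
  })
  expect_lt(abs(est[3] - 0.25), 0.05)
  slope <- coef(lm(est ~ fs))[2]
  expect_lt(abs(slope - 1), 0.1)
})
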