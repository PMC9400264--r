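#' Configuration for a synthetic resequencing cohort
#'
#' Collects every knob of the generator and validates it once. The defaults
#' emulate a small multi-species resequencing design: two groups with strongly
#' contrasting diversity, ~20x coverage, one Z and one W scaffold alongside
#' the autosomal scaffolds, and an effect-category mix dominated by missense
#' and synonymous changes.
#'
#' @param seed Integer master seed; it fully determines every output via
#'   fixed per-stage child seeds.
#' @param n_scaffolds Number of autosomal scaffolds carrying SNVs.
#' @param scaffold_length Length of each scaffold in bp.
#' @param groups Data frame with columns `name`, `n` (samples, >= 2),
#'   `theta` (per-bp scaled mutation rate, > 0), `f` (inbreeding, in [0,1])
#'   and optionally `n_females`.
#' @param sweeps Optional data frame of planted sweeps on the first (focal)
#'   group: `scaffold`, `start`, `end` (0-based half-open bp),
#'   `diversity_scale` in (0,1], `divergence_shift` in [0,1]. Rows with
#'   scale 1 and shift 0 are no-ops and recorded nowhere.
#' @param relatives Optional data frame planting related samples:
#'   `type` in `parent_offspring`, `full_sib`, `half_sib`; `group` the
#'   founder group drawn from.
#' @param roh Optional data frame planting homozygous tracts:
#'   `sample`, `scaffold`, `start`, `end` (0-based half-open bp).
#' @param sex_design List with `n_z`, `n_w`: numbers of Z and W scaffolds
#'   (depth/STR simulation only; they carry no SNVs).
#' @param coverage_mean Mean autosomal sequencing depth (x).
#' @param str_design List with `n_kinship` (planted pedigree-grade loci:
#'   4-bp unit, >= 5 alleles, complete calls), `n_autosomal` (unconstrained
#'   loci), `n_w` (true W-linked sex markers), `n_w_bad` (W-scaffold loci
#'   violating the sex-marker rule), `unit` (unit length for planted kinship
#'   loci, 2-6 bp), `n_alleles` (range for unconstrained loci).
#' @param effect_mix Named proportions over
#'   `frameshift, stopgain, stoploss, splicing, missense, synonymous, other`;
#'   either one vector for all groups or a named list per group. Must sum
#'   to 1 (+/- 1e-9).
#' @param filter_fail_frac Fraction of records whose INFO annotations are
#'   drawn from the failing side of the GATK hard filter.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_scaffolds = 3,
                       scaffold_length = 1e6,
                       groups = data.frame(
                         name = c("GCO", "GSA"), n = c(14L, 11L),
                         theta = c(2e-3, 2e-4), f = c(0, 0)),
                       sweeps = NULL,
                       relatives = NULL,
                       roh = NULL,
                       sex_design = list(n_z = 1, n_w = 1),
                       coverage_mean = 20,
                       str_design = list(n_kinship = 10, n_autosomal = 20,
                                         n_w = 10, n_w_bad = 3,
                                         unit = 4, n_alleles = c(2, 8)),
                       effect_mix = c(frameshift = 0.02, stopgain = 0.01,
                                      stoploss = 0.005, splicing = 0.015,
                                      missense = 0.25, synonymous = 0.35,
                                      other = 0.35),
                       filter_fail_frac = 0.05) {
  stopifnot_scalar_pos(scaffold_length, "scaffold_length")
  stopifnot_scalar_pos(n_scaffolds, "n_scaffolds")
  if (!all(c("name", "n", "theta", "f") %in% names(groups)))
    stop("groups needs columns name, n, theta, f")
  if (any(groups$n < 2)) stop("group sizes must be >= 2")
  if (any(groups$theta <= 0)) stop("theta must be positive")
  if (any(groups$f < 0 | groups$f > 1)) stop("inbreeding f must lie in [0,1]")
  if (is.null(groups$n_females)) groups$n_females <- pmin(groups$n %/% 2L, groups$n - 1L)
  if (any(groups$n_females < 0 | groups$n_females > groups$n))
    stop("n_females out of range")
  if (!is.null(sweeps) && nrow(sweeps)) {
    if (any(sweeps$diversity_scale <= 0 | sweeps$diversity_scale > 1))
      stop("diversity_scale must lie in (0, 1]")
    if (any(sweeps$divergence_shift < 0 | sweeps$divergence_shift > 1))
      stop("divergence_shift must lie in [0, 1]")
    if (any(sweeps$start < 0 | sweeps$end > scaffold_length |
            sweeps$start >= sweeps$end))
      stop("sweep coordinates must lie within simulated scaffolds")
  }
  if (!is.null(relatives) && nrow(relatives)) {
    ok <- relatives$type %in% c("parent_offspring", "full_sib", "half_sib")
    if (!all(ok)) stop("unknown relative type(s)")
    if (!all(relatives$group %in% groups$name)) stop("unknown relative group")
  }
  str_defaults <- list(n_kinship = 10, n_autosomal = 20, n_w = 10,
                       n_w_bad = 3, unit = 4, n_alleles = c(2, 8))
  str_design <- utils::modifyList(str_defaults, str_design)
  if (!str_design$unit %in% 2:6)
    stop("STR unit length must lie in 2..6 bp")
  sex_defaults <- list(n_z = 1, n_w = 1)
  sex_design <- utils::modifyList(sex_defaults, sex_design)
  mixes <- if (is.list(effect_mix) && !is.data.frame(effect_mix))
    effect_mix else list(effect_mix)
  for (m in mixes) {
    if (abs(sum(m) - 1) > 1e-9)
      stop("effect_mix proportions must sum to 1")
    if (!all(names(m) %in% EFFECT_CATEGORIES))
      stop("unknown effect category in effect_mix")
  }
  structure(list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
                 scaffold_length = scaffold_length, groups = groups,
                 sweeps = sweeps, relatives = relatives, roh = roh,
                 sex_design = sex_design, coverage_mean = coverage_mean,
                 str_design = str_design, effect_mix = effect_mix,
                 filter_fail_frac = filter_fail_frac),
            class = "sim_config")
}

EFFECT_CATEGORIES <- c("frameshift", "stopgain", "stoploss", "splicing",
                       "missense", "synonymous", "other")

# scaffold name/length/class table implied by a config
scaffold_table <- function(config) {
  auto <- sprintf("scaf%02d", seq_len(config$n_scaffolds))
  z <- if (config$sex_design$n_z > 0)
    sprintf("scafZ%02d", seq_len(config$sex_design$n_z)) else character()
  w <- if (config$sex_design$n_w > 0)
    sprintf("scafW%02d", seq_len(config$sex_design$n_w)) else character()
  data.frame(scaffold = c(auto, z, w),
             length = config$scaffold_length,
             class = rep(c("autosome", "Z", "W"),
                         c(length(auto), length(z), length(w))))
}

#' Simulate a genotyped cohort with planted, recorded truth
#'
#' Segregating sites per group and scaffold are drawn with count
#' `Poisson(theta * L * a_n)` (`a_n` the Watterson harmonic number for the
#' group's `2n` chromosomes); derived-allele counts follow the neutral
#' spectrum `p(i) proportional to 1/i`. For non-inbred groups the drawn count
#' is placed exactly on the `2n` chromosomes (so windowed diversity is
#' unbiased for theta); for `f > 0` genotypes are drawn per sample under
#' Hardy-Weinberg with inbreeding. Sweep regions thin and rarefy the focal
#' group's private sites by `diversity_scale` and, independently per site
#' with probability `divergence_shift`, fix the focal group for the
#' alternate allele. Relatives are built by Mendelian gamete draws from
#' stored parental genotypes; planted homozygous tracts are delimited by a
#' forced heterozygote at the first site flanking each end. INFO annotations
#' are drawn from passing distributions except for a `filter_fail_frac`
#' fraction of records given one violating value.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort`: `gm` (the [geno_matrix()]),
#'   `samples` (id, group, sex, quality, derived), `truth` (planted sweeps,
#'   relative pairs with expected PI_HAT, scaffold sex classes, sample sexes,
#'   per-group theta, planted ROH tracts, hard-filter violators).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  scafs <- scaffold_table(config)
  auto <- scafs$scaffold[scafs$class == "autosome"]
  L <- config$scaffold_length
  groups <- config$groups
  ng <- nrow(groups)
  focal <- groups$name[1]

  ## per-group segregating sites
  site_list <- with_seed(derive_seed(config$seed, "sites"), {
    out <- list()
    for (g in seq_len(ng)) {
      n2 <- 2L * groups$n[g]
      a_n <- sum(1 / seq_len(n2 - 1))
      sfs_w <- 1 / seq_len(n2 - 1)
      for (sc in auto) {
        S <- rpois(1, groups$theta[g] * L * a_n)
        if (S == 0) next
        pos <- sort(sample.int(L, min(S, L)))
        cnt <- sample.int(n2 - 1, length(pos), replace = TRUE, prob = sfs_w)
        out[[length(out) + 1]] <- data.frame(
          scaffold = sc, pos = pos, group = g, count = cnt)
      }
    }
    do.call(rbind, out)
  })
  if (is.null(site_list) || nrow(site_list) == 0)
    stop("no segregating sites simulated; increase theta or L")

  ## sweep planting on the focal group
  truth_sweeps <- NULL
  sw <- config$sweeps
  if (!is.null(sw) && nrow(sw)) {
    sw <- sw[sw$diversity_scale < 1 | sw$divergence_shift > 0, , drop = FALSE]
    if (nrow(sw)) truth_sweeps <- sw
  }
  fixed_key <- character()
  if (!is.null(truth_sweeps)) {
    # deterministic, evenly spread fraction picker: selecting site k iff
    # floor(k*frac) increments keeps the planted fraction uniform across
    # sub-windows of the region instead of binomially variable
    pick_frac <- function(n, frac) {
      if (n == 0) return(logical(0))
      k <- seq_len(n)
      floor(k * frac) > floor((k - 1) * frac)
    }
    drop <- rep(FALSE, nrow(site_list))
    for (r in seq_len(nrow(truth_sweeps))) {
      reg <- site_list$scaffold == truth_sweeps$scaffold[r] &
        (site_list$pos - 1) >= truth_sweeps$start[r] &
        (site_list$pos - 1) < truth_sweeps$end[r]
      scale <- truth_sweeps$diversity_scale[r]
      foc <- which(reg & site_list$group == 1)
      drop[foc] <- !pick_frac(length(foc), scale)
      keepfoc <- setdiff(foc, foc[drop[foc]])
      site_list$count[keepfoc] <- pmax(1L, as.integer(
        ceiling(site_list$count[keepfoc] * scale)))
      shift <- truth_sweeps$divergence_shift[r]
      cand <- which(reg & !drop)
      hit <- cand[pick_frac(length(cand), shift)]
      fixed_key <- c(fixed_key,
                     paste(site_list$scaffold[hit], site_list$pos[hit]))
    }
    site_list <- site_list[!drop, , drop = FALSE]
  }

  ## union site table; collisions across groups resolved by keeping the first
  key <- paste(site_list$scaffold, site_list$pos)
  site_list <- site_list[!duplicated(key), , drop = FALSE]
  ord <- order(site_list$scaffold, site_list$pos)
  site_list <- site_list[ord, , drop = FALSE]
  S <- nrow(site_list)
  key <- paste(site_list$scaffold, site_list$pos)

  ## generating frequency per site per group (alt-allele)
  pmat <- matrix(0, S, ng)
  for (g in seq_len(ng)) {
    sel <- site_list$group == g
    pmat[sel, g] <- site_list$count[sel] / (2 * groups$n[g])
  }
  pmat[key %in% fixed_key, 1] <- 1

  ## founder genotypes
  geno <- with_seed(derive_seed(config$seed, "geno"), {
    cols <- list()
    for (g in seq_len(ng)) {
      n <- groups$n[g]
      f <- groups$f[g]
      gmat <- matrix(0L, S, n)
      p <- pmat[, g]
      fix1 <- p >= 1
      gmat[fix1, ] <- 2L
      seg <- which(p > 0 & p < 1)
      if (f == 0) {
        own <- seg[site_list$group[seg] == g]
        for (s in own) {
          slots <- sample.int(2L * n, site_list$count[s])
          gmat[s, ] <- tabulate((slots - 1L) %/% 2L + 1L, nbins = n)
        }
        # sites segregating here but originating elsewhere (rescaled sweep
        # residuals) fall back to binomial draws
        other <- setdiff(seg, own)
        for (s in other)
          gmat[s, ] <- rbinom(n, 2, p[s])
      } else {
        for (s in seg) {
          ps <- p[s]; qs <- 1 - ps
          pr <- c(f * qs + (1 - f) * qs^2, (1 - f) * 2 * ps * qs,
                  f * ps + (1 - f) * ps^2)
          gmat[s, ] <- sample(0:2, n, replace = TRUE, prob = pr)
        }
      }
      cols[[g]] <- gmat
    }
    do.call(cbind, cols)
  })
  ids <- unlist(lapply(seq_len(ng), function(g)
    paste0(groups$name[g], seq_len(groups$n[g]))))
  grp_of <- rep(groups$name, groups$n)

  ## sexes: first n_females of each group female, the rest male
  sexes <- unlist(lapply(seq_len(ng), function(g)
    rep(c("F", "M"), c(groups$n_females[g],
                       groups$n[g] - groups$n_females[g]))))

  ## relatives by Mendelian gamete draws
  truth_pairs <- NULL
  rel <- config$relatives
  if (!is.null(rel) && nrow(rel)) {
    res <- with_seed(derive_seed(config$seed, "relatives"), {
      gam_geno <- function(gv) ifelse(gv == 2L, 1L,
                                      ifelse(gv == 0L, 0L, rbinom(length(gv), 1, 0.5)))
      gam_freq <- function(p) rbinom(length(p), 1, p)
      newg <- list(); newid <- character(); newgrp <- character()
      pairs <- list()
      cursor <- setNames(rep(1L, ng), groups$name)
      for (r in seq_len(nrow(rel))) {
        gname <- rel$group[r]
        gi <- match(gname, groups$name)
        pfreq <- pmat[, gi]
        take <- function() {
          k <- cursor[[gname]]
          if (k > groups$n[gi]) stop("not enough founders in group ", gname)
          cursor[[gname]] <<- k + 1L
          which(ids == paste0(gname, k))
        }
        tag <- paste0("rel", r)
        if (rel$type[r] == "parent_offspring") {
          pcol <- take()
          child <- gam_geno(geno[, pcol]) + gam_freq(pfreq)
          newg[[length(newg) + 1]] <- child
          cid <- paste0(tag, "_child")
          newid <- c(newid, cid); newgrp <- c(newgrp, gname)
          pairs[[length(pairs) + 1]] <- data.frame(
            id_a = ids[pcol], id_b = cid, type = "parent_offspring",
            expected_pi_hat = 0.5)
        } else if (rel$type[r] == "full_sib") {
          pcol <- take(); qcol <- take()
          s1 <- gam_geno(geno[, pcol]) + gam_geno(geno[, qcol])
          s2 <- gam_geno(geno[, pcol]) + gam_geno(geno[, qcol])
          sid <- paste0(tag, c("_sib1", "_sib2"))
          newg <- c(newg, list(s1, s2))
          newid <- c(newid, sid); newgrp <- c(newgrp, gname, gname)
          pairs[[length(pairs) + 1]] <- data.frame(
            id_a = sid[1], id_b = sid[2], type = "full_sib",
            expected_pi_hat = 0.5)
        } else { # half_sib
          pcol <- take()
          h1 <- gam_geno(geno[, pcol]) + gam_freq(pfreq)
          h2 <- gam_geno(geno[, pcol]) + gam_freq(pfreq)
          hid <- paste0(tag, c("_half1", "_half2"))
          newg <- c(newg, list(h1, h2))
          newid <- c(newid, hid); newgrp <- c(newgrp, gname, gname)
          pairs[[length(pairs) + 1]] <- data.frame(
            id_a = hid[1], id_b = hid[2], type = "half_sib",
            expected_pi_hat = 0.25)
        }
      }
      list(geno = do.call(cbind, newg), ids = newid, grp = newgrp,
           pairs = do.call(rbind, pairs))
    })
    geno <- cbind(geno, res$geno)
    sexes <- c(sexes, rep_len(c("M", "F"), length(res$ids)))
    grp_of <- c(grp_of, res$grp)
    derived <- c(rep(FALSE, length(ids)), rep(TRUE, length(res$ids)))
    ids <- c(ids, res$ids)
    truth_pairs <- res$pairs
  } else derived <- rep(FALSE, length(ids))

  ## planted homozygous tracts (with heterozygous delimiters at both ends)
  truth_roh <- NULL
  if (!is.null(config$roh) && nrow(config$roh)) {
    rows <- list()
    geno <- with_seed(derive_seed(config$seed, "roh"), {
      for (r in seq_len(nrow(config$roh))) {
        sm <- match(config$roh$sample[r], ids)
        if (is.na(sm)) stop("unknown roh sample: ", config$roh$sample[r])
        sc <- config$roh$scaffold[r]
        a <- config$roh$start[r]; b <- config$roh$end[r]
        onsc <- which(site_list$scaffold == sc)
        inside <- onsc[(site_list$pos[onsc] - 1) >= a &
                         (site_list$pos[onsc] - 1) < b]
        if (length(inside) == 0) next
        p_here <- pmat[inside, match(grp_of[sm], groups$name)]
        geno[inside, sm] <- 2L * rbinom(length(inside), 1, p_here)
        before <- onsc[site_list$pos[onsc] - 1 < a]
        after <- onsc[site_list$pos[onsc] - 1 >= b]
        if (length(before)) geno[max(before), sm] <- 1L
        if (length(after)) geno[min(after), sm] <- 1L
        rows[[length(rows) + 1]] <- data.frame(
          sample = ids[sm], scaffold = sc, start = a, end = b,
          site_start = min(site_list$pos[inside]) - 1,
          site_end = max(site_list$pos[inside]),
          n_snps = length(inside))
      }
      geno
    })
    truth_roh <- do.call(rbind, rows)
  }

  ## INFO annotations: pass/fail mixture for the GATK hard filter
  info <- with_seed(derive_seed(config$seed, "info"), {
    fail <- runif(S) < config$filter_fail_frac
    df <- data.frame(
      QD = pmax(2.01, rnorm(S, 25, 5)),
      FS = pmin(19.9, rexp(S, 1 / 3)),
      MQ = pmax(40.01, rnorm(S, 55, 3)),
      SOR = pmin(2.99, pmax(0.1, rnorm(S, 1.2, 0.4))),
      MQRankSum = pmax(-1.99, rnorm(S, 0, 0.5)),
      ReadPosRankSum = pmax(-4.99, rnorm(S, 0, 1)))
    which_fail <- sample.int(6, S, replace = TRUE)
    bad <- list(QD = function(k) runif(k, 0, 1.99),
                FS = function(k) runif(k, 20.1, 60),
                MQ = function(k) runif(k, 10, 39.9),
                SOR = function(k) runif(k, 3.01, 9),
                MQRankSum = function(k) runif(k, -8, -2.01),
                ReadPosRankSum = function(k) runif(k, -12, -5.01))
    for (j in seq_along(INFO_KEYS)) {
      sel <- fail & which_fail == j
      df[[INFO_KEYS[j]]][sel] <- bad[[INFO_KEYS[j]]](sum(sel))
    }
    attr(df, "fail") <- fail
    df
  })

  quality <- with_seed(derive_seed(config$seed, "quality"),
                       round(rnorm(length(ids), config$coverage_mean, 2), 2))

  bases <- with_seed(derive_seed(config$seed, 7L), {
    rf <- sample(c("A", "C", "G", "T"), S, replace = TRUE)
    al <- sample(c("A", "C", "G", "T"), S, replace = TRUE)
    clash <- rf == al
    al[clash] <- chartr("ACGT", "CGTA", rf[clash])
    list(ref = rf, alt = al)
  })

  sites <- data.frame(scaffold = site_list$scaffold, pos = site_list$pos,
                      ref = bases$ref, alt = bases$alt,
                      origin_group = groups$name[site_list$group])
  sites <- cbind(sites, info)
  lens <- setNames(scafs$length, scafs$scaffold)
  gm <- geno_matrix(geno, sites, ids, lens)

  samples <- data.frame(id = ids, group = grp_of, sex = sexes,
                        quality = quality, derived = derived)
  truth <- list(
    sweeps = truth_sweeps,
    pairs = truth_pairs,
    scaffold_class = setNames(scafs$class, scafs$scaffold),
    sexes = setNames(sexes, ids),
    group_theta = setNames(groups$theta, groups$name),
    roh = truth_roh,
    filter_fail = key[attr(info, "fail")])
  structure(list(gm = gm, samples = samples, truth = truth, config = config),
            class = "sim_cohort")
}

#' @export
#' @method print sim_cohort
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", n_sites(x$gm), "sites,", nrow(x$samples), "samples (",
      paste(unique(x$samples$group), collapse = ", "), ")\n")
  invisible(x)
}

#' Simulate per-sample per-scaffold mean read depth
#'
#' Depth is truncated-normal around `coverage_mean * copy_ratio` with
#' coefficient of variation 0.1, where the copy ratio follows the ZW system:
#' autosomes 1 in both sexes, Z 1 in males (ZZ) and 0.5 in females (ZW),
#' W 0 in males and 0.5 in females.
#'
#' @param config A [sim_config()].
#' @param samples Sample table with `id` and `sex` (e.g. from
#'   [simulate_cohort()]).
#' @return Long data frame `sample`, `scaffold`, `mean_depth`.
#' @export
simulate_depth_profiles <- function(config, samples) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (!all(c("M", "F") %in% samples$sex))
    stop("need at least one male and one female sample")
  scafs <- scaffold_table(config)
  ratio <- function(cls, sex)
    switch(cls, autosome = 1,
           Z = if (sex == "M") 1 else 0.5,
           W = if (sex == "M") 0 else 0.5)
  with_seed(derive_seed(config$seed, "depth"), {
    grid <- expand.grid(sample = samples$id, scaffold = scafs$scaffold,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$sex <- samples$sex[match(grid$sample, samples$id)]
    cls <- scafs$class[match(grid$scaffold, scafs$scaffold)]
    mu <- config$coverage_mean *
      mapply(ratio, cls, grid$sex)
    grid$mean_depth <- pmax(0, rnorm(nrow(grid), mu, 0.1 * mu))
    grid$sex <- NULL
    grid
  })
}

#' Simulate an STR genotype table
#'
#' Autosomal loci follow a stepwise model (allele lengths are multiples of
#' the unit); planted kinship loci have a 4-bp unit, at least five distinct
#' alleles and complete calls; W-linked marker loci are emitted as two equal
#' allele lengths in females and missing in males, plus a few W-scaffold
#' decoys violating that rule.
#'
#' @param config A [sim_config()].
#' @param truth Truth list from [simulate_cohort()] (provides sample sexes
#'   and scaffold classes).
#' @return Data frame `locus_id`, `scaffold`, `pos`, `unit`, then one
#'   `"a1/a2"` (or `"./."`) column per sample. Attribute `"truth"` lists the
#'   planted `kinship_ids` and `w_marker_ids`.
#' @export
simulate_str_table <- function(config, truth) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  sexes <- truth$sexes
  cls <- truth$scaffold_class
  auto <- names(cls)[cls == "autosome"]
  wsc <- names(cls)[cls == "W"]
  d <- config$str_design
  ids <- names(sexes)
  with_seed(derive_seed(config$seed, "str"), {
    rows <- list()
    gcols <- list()
    emit <- function(scaffold, unit, geno_strings) {
      rows[[length(rows) + 1]] <<- data.frame(
        scaffold = scaffold, pos = sample.int(config$scaffold_length, 1),
        unit = unit)
      gcols[[length(gcols) + 1]] <<- geno_strings
    }
    draw_locus <- function(unit, n_alleles, missing_rate,
                           force_spectrum = FALSE) {
      lens <- unit * (sample(5:15, 1) + seq_len(n_alleles) - 1)
      w <- runif(n_alleles) + 0.2
      a1 <- sample(lens, length(ids), replace = TRUE, prob = w)
      a2 <- sample(lens, length(ids), replace = TRUE, prob = w)
      if (force_spectrum)  # planted panels must expose every allele
        a1[seq_len(min(n_alleles, length(ids)))] <-
          lens[seq_len(min(n_alleles, length(ids)))]
      g <- paste0(pmin(a1, a2), "/", pmax(a1, a2))
      g[runif(length(ids)) < missing_rate] <- "./."
      g
    }
    for (k in seq_len(d$n_kinship))
      emit(auto[(k - 1) %% length(auto) + 1], 4L,
           draw_locus(4L, sample(5:min(8, length(ids)), 1), 0,
                      force_spectrum = TRUE))
    n_kin <- length(rows)
    for (k in seq_len(d$n_autosomal)) {
      u <- sample(2:6, 1)
      emit(auto[(k - 1) %% length(auto) + 1], u,
           draw_locus(u, sample(2:8, 1), 0.05))
    }
    w_marker_rows <- integer()
    if (length(wsc)) {
      for (k in seq_len(d$n_w)) {
        lens <- d$unit * (sample(5:15, 1) + 0:2)
        g <- rep("./.", length(ids))
        fem <- sexes == "F"
        lf <- sample(lens, sum(fem), replace = TRUE)
        g[fem] <- paste0(lf, "/", lf)
        emit(wsc[(k - 1) %% length(wsc) + 1], d$unit, g)
        w_marker_rows <- c(w_marker_rows, length(rows))
      }
      for (k in seq_len(d$n_w_bad)) {
        lens <- d$unit * (sample(5:15, 1) + 0:2)
        g <- rep("./.", length(ids))
        fem <- which(sexes == "F")
        lf <- sample(lens, length(fem), replace = TRUE)
        g[fem] <- paste0(lf, "/", lf)
        if (k %% 2 == 0 && length(fem)) {
          # heterozygous female violates hemizygosity
          g[fem[1]] <- paste0(lens[1], "/", lens[2])
        } else {
          # a called male violates deletion-in-males
          ml <- which(sexes == "M")[1]
          g[ml] <- paste0(lens[1], "/", lens[1])
        }
        emit(wsc[(k - 1) %% length(wsc) + 1], d$unit, g)
      }
    }
    tab <- do.call(rbind, rows)
    tab <- cbind(data.frame(locus_id = sprintf("STR%04d", seq_len(nrow(tab)))),
                 tab)
    gmatrix <- do.call(cbind, gcols)
    gtab <- as.data.frame(t(gmatrix), stringsAsFactors = FALSE)
    names(gtab) <- ids
    out <- cbind(tab, gtab)
    rownames(out) <- NULL
    attr(out, "truth") <- list(
      kinship_ids = out$locus_id[seq_len(n_kin)],
      w_marker_ids = out$locus_id[w_marker_rows])
    out
  })
}

#' Assign variant-effect categories by a multinomial mix
#'
#' Each site receives one category from the effect vocabulary according to
#' the configured (optionally group-specific) proportions; sites are keyed by
#' the group whose polymorphism generated them.
#'
#' @param config A [sim_config()].
#' @param gm Genotype matrix from [simulate_cohort()] (its site table carries
#'   the originating group).
#' @return Data frame `scaffold`, `pos`, `category`.
#' @export
simulate_effect_labels <- function(config, gm) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (n_sites(gm) == 0)
    return(data.frame(scaffold = character(), pos = integer(),
                      category = character()))
  mix_for <- function(gname) {
    m <- if (is.list(config$effect_mix) && !is.data.frame(config$effect_mix))
      config$effect_mix[[gname]] %||% config$effect_mix[[1]]
    else config$effect_mix
    full <- setNames(rep(0, length(EFFECT_CATEGORIES)), EFFECT_CATEGORIES)
    full[names(m)] <- m
    full
  }
  with_seed(derive_seed(config$seed, "effects"), {
    grp <- gm$sites$origin_group %||% rep(config$groups$name[1], n_sites(gm))
    cat <- character(n_sites(gm))
    for (gname in unique(grp)) {
      sel <- grp == gname
      mx <- mix_for(gname)
      cat[sel] <- sample(EFFECT_CATEGORIES, sum(sel), replace = TRUE,
                         prob = mx)
    }
    data.frame(scaffold = gm$sites$scaffold, pos = gm$sites$pos,
               category = cat)
  })
}

#' Simulate correlated populations with optional introgression
#'
#' A dedicated generator for gene-flow statistics: ancestral allele
#' frequencies follow the neutral `1/p` density, each population drifts from
#' the ancestor under a Balding-Nichols model with differentiation
#' `f_drift`, and an admixture fraction `gamma` pulls the recipient
#' population's frequencies toward the donor's before genotypes are drawn.
#'
#' @param n_snps Number of independent sites.
#' @param n_per_pop Diploid samples per population (P1, P2, P3, outgroup).
#' @param f_drift Balding-Nichols differentiation per population.
#' @param gamma Admixture fraction from P3 into P2 (0 = no gene flow).
#' @param seed Integer seed.
#' @return List: `gm` (a [geno_matrix()]) and `pops` (named list of sample
#'   id vectors `P1`, `P2`, `P3`, `OUT`).
#' @export
simulate_introgression <- function(n_snps = 20000, n_per_pop = 5,
                                   f_drift = 0.2, gamma = 0, seed = 1) {
  stopifnot_scalar_pos(n_snps, "n_snps")
  with_seed(seed, {
    lo <- 0.05; hi <- 0.95
    p_anc <- lo * exp(runif(n_snps) * log(hi / lo))
    bn <- function(p) {
      a <- p * (1 - f_drift) / f_drift
      b <- (1 - p) * (1 - f_drift) / f_drift
      stats::rbeta(n_snps, a, b)
    }
    p1 <- bn(p_anc); p2 <- bn(p_anc); p3 <- bn(p_anc); p4 <- bn(p_anc)
    if (gamma > 0) p2 <- (1 - gamma) * p2 + gamma * p3
    draw <- function(p) matrix(rbinom(n_snps * n_per_pop, 2, p),
                               nrow = n_snps)
    geno <- cbind(draw(p1), draw(p2), draw(p3), draw(p4))
    ids <- paste0(rep(c("P1_", "P2_", "P3_", "OUT_"), each = n_per_pop),
                  seq_len(n_per_pop))
    sites <- data.frame(scaffold = "scaf01",
                        pos = seq_len(n_snps) * 100L,
                        ref = "A", alt = "G")
    gm <- geno_matrix(geno, sites, ids,
                      setNames(n_snps * 100 + 100, "scaf01"))
    list(gm = gm, pops = split(ids, rep(c("P1", "P2", "P3", "OUT"),
                                        each = n_per_pop)))
  })
}
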