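INFO_KEYS <- c("QD", "FS", "MQ", "SOR", "MQRankSum", "ReadPosRankSum")

#' Read a multi-sample VCF into a genotype matrix
#'
#' Only biallelic SNVs are retained; multiallelic records and indels are
#' counted and reported via the `"excluded"` attribute. Genotypes are mapped
#' to alternate-allele dosage; phased and unphased calls are treated
#' identically. The GATK INFO annotations used by [hard_filter_variants()]
#' are carried into the site table when present.
#'
#' @param path Path to a VCF 4.x file.
#' @param sample_subset Optional character vector restricting the samples.
#' @return A [geno_matrix()] with attribute `excluded`
#'   (`c(multiallelic =, indel =)`).
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  indel <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L)
  keep <- !multi & !indel & ref != alt & alt != "."
  excluded <- c(multiallelic = sum(multi), indel = sum(indel))

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, colnames(v@gt)[-1]))
  samples <- colnames(gt)
  if (!is.null(sample_subset)) {
    miss <- setdiff(sample_subset, samples)
    if (length(miss)) stop("samples not in VCF: ", paste(miss, collapse = ", "))
    gt <- gt[, sample_subset, drop = FALSE]
    samples <- sample_subset
  }
  gt <- gt[keep, , drop = FALSE]
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dos <- suppressWarnings(as.integer(a1) + as.integer(a2))
  dos <- matrix(dos, nrow = sum(keep))

  sites <- data.frame(scaffold = fix[keep, "CHROM"],
                      pos = as.integer(fix[keep, "POS"]),
                      ref = ref[keep], alt = alt[keep])
  info <- fix[keep, "INFO"]
  info[is.na(info)] <- ""
  for (key in INFO_KEYS) {
    m <- regexpr(paste0("(?:^|;)", key, "=([^;]+)"), info, perl = TRUE)
    val <- rep(NA_real_, length(info))
    hit <- m > 0
    val[hit] <- suppressWarnings(as.numeric(
      sub(paste0("^;?", key, "="), "", regmatches(info, m))))
    sites[[key]] <- val
  }

  lens <- scaffold_lengths_from_meta(v@meta)
  gm <- geno_matrix(dos, sites, samples, lens)
  attr(gm, "excluded") <- excluded
  gm
}

scaffold_lengths_from_meta <- function(meta) {
  ct <- grep("^##contig=", meta, value = TRUE)
  if (!length(ct)) return(NULL)
  id <- sub(".*ID=([^,>]+).*", "\\1", ct)
  len <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", ct)))
  if (anyNA(len)) return(NULL)
  setNames(len, id)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Deterministic plain-text emission (GT genotypes, the hard-filter INFO keys
#' when present, contig lines from `scaffold_lengths`), so identical inputs
#' produce byte-identical files.
#'
#' @param gm A [geno_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=wgspop")
  if (!is.null(gm$scaffold_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(gm$scaffold_lengths),
                          as.integer(gm$scaffold_lengths)))
  desc <- c(QD = "Variant quality by depth", FS = "Fisher strand bias (phred)",
            MQ = "RMS mapping quality", SOR = "Symmetric odds ratio",
            MQRankSum = "Mapping quality rank-sum",
            ReadPosRankSum = "Read position rank-sum")
  present <- INFO_KEYS[INFO_KEYS %in% names(gm$sites)]
  hdr <- c(hdr,
           sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="%s">',
                   present, desc[present]),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  n <- n_sites(gm)
  if (n > 0) {
    info <- rep("", n)
    for (key in present) {
      v <- gm$sites[[key]]
      piece <- ifelse(is.na(v), "", paste0(key, "=", formatC(v, digits = 4, format = "f")))
      info <- ifelse(piece == "", info,
                     ifelse(info == "", piece, paste(info, piece, sep = ";")))
    }
    info[info == ""] <- "."
    gtc <- c("0/0", "0/1", "1/1")
    gt <- matrix(gtc[gm$geno + 1L], nrow = n)
    gt[is.na(gm$geno)] <- "./."
    lines <- paste(gm$sites$scaffold, gm$sites$pos, ".", gm$sites$ref,
                   gm$sites$alt, ".", "PASS", info, "GT",
                   apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  } else lines <- character()
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Apply GATK-style hard filters to variant sites
#'
#' A site is removed iff any criterion fires: `QD < 2.0`, `FS > 20.0`,
#' `MQ < 40.0`, `SOR > 3.0`, `MQRankSum < -2.0`, `ReadPosRankSum < -5.0`
#' (defaults). An absent annotation never fires its criterion.
#'
#' @param gm A [geno_matrix()] whose site table may carry the INFO columns.
#' @param thresholds Named list overriding any of the six defaults.
#' @return Filtered `geno_matrix`; attribute `"hard_filter"` holds the number
#'   removed and the per-criterion counts.
#' @export
hard_filter_variants <- function(gm,
                                 thresholds = list(QD = 2.0, FS = 20.0,
                                                   MQ = 40.0, SOR = 3.0,
                                                   MQRankSum = -2.0,
                                                   ReadPosRankSum = -5.0)) {
  defaults <- list(QD = 2.0, FS = 20.0, MQ = 40.0, SOR = 3.0,
                   MQRankSum = -2.0, ReadPosRankSum = -5.0)
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown))
    stop("unknown threshold key(s): ", paste(unknown, collapse = ", "))
  thr <- utils::modifyList(defaults, thresholds)
  # direction of each rule: "lt" removes when value < threshold
  dir <- c(QD = "lt", FS = "gt", MQ = "lt", SOR = "gt",
           MQRankSum = "lt", ReadPosRankSum = "lt")
  n <- n_sites(gm)
  fails <- matrix(FALSE, n, length(thr), dimnames = list(NULL, names(thr)))
  for (key in names(thr)) {
    v <- gm$sites[[key]]
    if (is.null(v)) next
    f <- if (dir[[key]] == "lt") v < thr[[key]] else v > thr[[key]]
    fails[, key] <- !is.na(v) & f
  }
  bad <- rowSums(fails) > 0
  out <- subset_geno(gm, sites = !bad)
  attr(out, "hard_filter") <- list(n_removed = sum(bad),
                                   by_criterion = colSums(fails),
                                   thresholds = thr)
  out
}

#' Intersect two variant call sets
#'
#' Keeps sites whose `(scaffold, pos, ref, alt)` occur in both inputs;
#' genotypes are taken from `a`. Sites sharing a position but conflicting in
#' ref/alt are dropped and counted.
#'
#' @param a,b [geno_matrix()] objects called against the same reference.
#' @return `geno_matrix` with attribute `"conflicts"` (count of positions
#'   present in both sets with disagreeing alleles).
#' @export
intersect_variant_sets <- function(a, b) {
  key_pos_a <- paste(a$sites$scaffold, a$sites$pos)
  key_pos_b <- paste(b$sites$scaffold, b$sites$pos)
  key_a <- paste(key_pos_a, a$sites$ref, a$sites$alt)
  key_b <- paste(key_pos_b, b$sites$ref, b$sites$alt)
  keep <- key_a %in% key_b
  conflicts <- sum(key_pos_a %in% key_pos_b & !keep)
  out <- subset_geno(a, sites = keep)
  attr(out, "conflicts") <- conflicts
  out
}

#' Greedy linkage-disequilibrium pruning
#'
#' Sliding a window of `window_snps` sites in steps of `step` along each
#' scaffold, drops the later member of any retained pair whose dosage
#' correlation squared exceeds `r2_max` (left-to-right greedy), so the
#' surviving set has no within-window pair above the cutoff.
#'
#' @param gm A [geno_matrix()].
#' @param r2_max Maximum tolerated r-squared (default 0.5).
#' @param window_snps,step Window extent and slide, in SNPs.
#' @return Pruned `geno_matrix`.
#' @export
ld_prune <- function(gm, r2_max = 0.5, window_snps = 50, step = 5) {
  if (r2_max <= 0 || r2_max > 1) stop("r2_max must lie in (0, 1]")
  n <- n_sites(gm)
  if (n < 2) return(gm)
  keep <- rep(TRUE, n)
  for (sc in unique(gm$sites$scaffold)) {
    idx <- which(gm$sites$scaffold == sc)
    if (length(idx) < 2) next
    starts <- seq(1, length(idx), by = step)
    for (s in starts) {
      w <- idx[s:min(s + window_snps - 1, length(idx))]
      w <- w[keep[w]]
      if (length(w) < 2) next
      r2 <- suppressWarnings(
        cor(t(gm$geno[w, , drop = FALSE]), use = "pairwise.complete.obs"))^2
      r2[is.na(r2)] <- 0
      for (j in 2:length(w)) {
        if (!keep[w[j]]) next
        earlier <- w[seq_len(j - 1)]
        # exact duplicates (r2 == 1) always drop, even at r2_max = 1
        hit <- r2[seq_len(j - 1), j] > r2_max |
          r2[seq_len(j - 1), j] > 1 - 1e-12
        if (any(keep[earlier] & hit))
          keep[w[j]] <- FALSE
      }
    }
  }
  subset_geno(gm, sites = keep)
}
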