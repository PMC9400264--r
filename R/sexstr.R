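# Parse "a1/a2" STR genotype strings into a 2-row integer matrix of allele
# lengths (NA for "./." or partial calls).
str_genotype_columns <- function(strs) {
  meta <- c("locus_id", "scaffold", "pos", "unit")
  setdiff(names(strs), meta)
}

parse_str_genotypes <- function(strs) {
  ids <- str_genotype_columns(strs)
  a1 <- a2 <- matrix(NA_integer_, nrow(strs), length(ids),
                     dimnames = list(strs$locus_id, ids))
  for (j in seq_along(ids)) {
    g <- strs[[ids[j]]]
    parts <- strsplit(g, "/", fixed = TRUE)
    v1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
    v2 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
    both <- !is.na(v1) & !is.na(v2)
    a1[both, j] <- v1[both]
    a2[both, j] <- v2[both]
  }
  list(a1 = a1, a2 = a2, samples = ids)
}

#' Two-pass depth normalization
#'
#' Pass one divides each sample's scaffold depths by its upper-quantile
#' (80th percentile) depth — autosomes are the highest-depth class in both
#' sexes (Z and W sit at half or zero copy), so this baseline is robust even
#' when sex scaffolds are numerous — and classifies scaffolds provisionally;
#' pass two recomputes the normalizer as the median over provisionally
#' autosomal scaffolds only.
#'
#' @param depths Long data frame `sample`, `scaffold`, `mean_depth`
#'   (e.g. from [simulate_depth_profiles()]).
#' @param sexes Named character vector (`"M"`/`"F"`) per sample.
#' @param scaffold_lengths Optional named lengths, forwarded to the
#'   provisional classification's short-scaffold rule.
#' @return List of class `depth_norm`: `table` (input plus
#'   `normalized_depth`), `normalizer` (per sample), `sexes`.
#' @export
normalize_depth <- function(depths, sexes, scaffold_lengths = NULL) {
  if (length(unique(depths$scaffold)) < 2)
    stop("cannot normalize from a single scaffold")
  if (!all(c("M", "F") %in% sexes))
    stop("need at least one male and one female")
  norm_with <- function(scafs, stat = median) {
    nz <- tapply(depths$mean_depth[depths$scaffold %in% scafs],
                 depths$sample[depths$scaffold %in% scafs], stat)
    if (any(nz <= 0 | is.na(nz)))
      stop("sample(s) with non-positive baseline depth: ",
           paste(names(nz)[nz <= 0 | is.na(nz)], collapse = ", "))
    nz
  }
  n1 <- norm_with(unique(depths$scaffold),
                  stat = function(x) quantile(x, 0.8, names = FALSE))
  tab <- depths
  tab$normalized_depth <- tab$mean_depth / as.numeric(n1[tab$sample])
  prov <- classify_scaffolds(
    structure(list(table = tab, normalizer = n1, sexes = sexes),
              class = "depth_norm"),
    scaffold_lengths = scaffold_lengths)
  auto <- prov$scaffold[prov$cls == "autosome"]
  if (!length(auto)) auto <- unique(depths$scaffold)
  n2 <- norm_with(auto)
  tab$normalized_depth <- tab$mean_depth / as.numeric(n2[tab$sample])
  structure(list(table = tab, normalizer = n2, sexes = sexes),
            class = "depth_norm")
}

#' @export
#' @method print depth_norm
print.depth_norm <- function(x, ...) {
  cat("depth_norm:", length(x$normalizer), "samples,",
      length(unique(x$table$scaffold)), "scaffolds\n")
  invisible(x)
}

#' Classify scaffolds as autosome, Z or W from sexed depth ratios
#'
#' With `ratio_m`/`ratio_f` the mean normalized depth over males/females:
#' W iff `ratio_m < 0.1` and `ratio_f` in `[0.3, 0.7]`; Z iff `ratio_m` in
#' `[0.8, 1.2]` and `ratio_f` in `[0.3, 0.7]`; autosome iff both in
#' `[0.8, 1.2]`; otherwise ambiguous. Scaffolds shorter than `min_len` are
#' forced ambiguous. The thresholds reflect ZW copy numbers (males ZZ,
#' females ZW) with generous noise margins.
#'
#' @param norm A `depth_norm` from [normalize_depth()].
#' @param sexes Optional named sex vector overriding the one stored in
#'   `norm`.
#' @param min_len Minimum scaffold length for a confident call (default
#'   50 kb); only applied when `scaffold_lengths` is given.
#' @param scaffold_lengths Optional named lengths.
#' @param w_male_max,z_range,f_range Classification thresholds.
#' @return Data frame `scaffold`, `ratio_m`, `ratio_f`, `cls`.
#' @export
classify_scaffolds <- function(norm, sexes = NULL, min_len = 50000,
                               scaffold_lengths = NULL,
                               w_male_max = 0.1,
                               z_range = c(0.8, 1.2),
                               f_range = c(0.3, 0.7)) {
  sexes <- sexes %||% norm$sexes
  tab <- norm$table
  males <- names(sexes)[sexes == "M"]
  females <- names(sexes)[sexes == "F"]
  if (!length(males) || !length(females))
    stop("need both sexes to classify scaffolds")
  rm_ <- tapply(tab$normalized_depth[tab$sample %in% males],
                tab$scaffold[tab$sample %in% males], mean)
  rf_ <- tapply(tab$normalized_depth[tab$sample %in% females],
                tab$scaffold[tab$sample %in% females], mean)
  scafs <- sort(unique(tab$scaffold))
  ratio_m <- as.numeric(rm_[scafs])
  ratio_f <- as.numeric(rf_[scafs])
  in_rng <- function(x, r) x >= r[1] & x <= r[2]
  cls <- ifelse(ratio_m < w_male_max & in_rng(ratio_f, f_range), "W",
         ifelse(in_rng(ratio_m, z_range) & in_rng(ratio_f, f_range), "Z",
         ifelse(in_rng(ratio_m, z_range) & in_rng(ratio_f, z_range),
                "autosome", "ambiguous")))
  if (!is.null(scaffold_lengths)) {
    short <- scaffold_lengths[scafs] < min_len
    cls[!is.na(short) & short] <- "ambiguous"
  }
  data.frame(scaffold = scafs, ratio_m = ratio_m, ratio_f = ratio_f,
             cls = cls)
}

#' Call sample sex from W-scaffold depth
#'
#' `w_ratio` is each sample's mean normalized depth over W scaffolds:
#' male iff `w_ratio < 0.1` (ZZ carries no W), female iff `w_ratio > 0.3`,
#' otherwise ambiguous.
#'
#' @param norm A `depth_norm` from [normalize_depth()].
#' @param w_scaffolds Character vector of W scaffold names.
#' @param male_max,female_min Thresholds on `w_ratio`.
#' @return Data frame `sample`, `w_ratio`, `sex`.
#' @export
call_sample_sex <- function(norm, w_scaffolds, male_max = 0.1,
                            female_min = 0.3) {
  if (!length(w_scaffolds)) stop("no W scaffolds supplied")
  tab <- norm$table[norm$table$scaffold %in% w_scaffolds, ]
  if (!nrow(tab)) stop("depth table has no rows for the W scaffolds")
  wr <- tapply(tab$normalized_depth, tab$sample, mean)
  data.frame(sample = names(wr), w_ratio = as.numeric(wr),
             sex = ifelse(wr < male_max, "M",
                   ifelse(wr > female_min, "F", "ambiguous")),
             row.names = NULL)
}

#' Select STR loci for kinship panels
#'
#' Keeps loci with the required repeat-unit length, at least `min_alleles`
#' distinct allele lengths ("allele types greater than four" read strictly
#' as >= 5), and, when `require_complete`, no missing genotype in the
#' cohort.
#'
#' @param strs STR table (`locus_id`, `scaffold`, `pos`, `unit`, one
#'   genotype column per sample).
#' @param unit_len Required unit length in bp (default 4).
#' @param min_alleles Minimum distinct allele count (default 5).
#' @param require_complete Drop loci with any missing call (default TRUE).
#' @return Subset of `strs`.
#' @export
filter_kinship_strs <- function(strs, unit_len = 4, min_alleles = 5,
                                require_complete = TRUE) {
  pg <- parse_str_genotypes(strs)
  n_alleles <- vapply(seq_len(nrow(strs)), function(i)
    length(unique(stats::na.omit(c(pg$a1[i, ], pg$a2[i, ])))), integer(1))
  complete <- rowSums(is.na(pg$a1)) == 0
  keep <- strs$unit == unit_len & n_alleles >= min_alleles &
    (!require_complete | complete)
  strs[keep, , drop = FALSE]
}

#' Polymorphism information content
#'
#' Botstein et al. (1980) closed form:
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @param allele_freqs Numeric allele frequencies summing to 1.
#' @return PIC in `[0, 1)`.
#' @export
pic <- function(allele_freqs) {
  if (!length(allele_freqs)) stop("empty allele spectrum")
  if (abs(sum(allele_freqs) - 1) > 1e-6)
    stop("allele frequencies must sum to 1")
  p2 <- allele_freqs^2
  cross <- sum(p2)^2 - sum(p2^2)  # = sum_{i != j} p_i^2 p_j^2
  1 - sum(p2) - cross
}

# Empirical allele-length frequency spectrum of one locus
str_allele_freqs <- function(pg, i) {
  a <- stats::na.omit(c(pg$a1[i, ], pg$a2[i, ]))
  if (!length(a)) return(numeric())
  tab <- table(a)
  setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' PIC for every locus of an STR table
#'
#' @param strs STR table.
#' @return Named numeric vector of PIC values (NA for loci without calls).
#' @export
str_pic <- function(strs) {
  pg <- parse_str_genotypes(strs)
  vapply(seq_len(nrow(strs)), function(i) {
    f <- str_allele_freqs(pg, i)
    if (!length(f)) NA_real_ else pic(f)
  }, numeric(1)) |> setNames(strs$locus_id)
}

#' Select W-linked sex-marker STRs
#'
#' Keeps loci on W scaffolds where every female carries a called genotype
#' with two equal allele lengths (hemizygosity shows as homozygosity) and
#' every male is missing (the W is absent in ZZ males).
#'
#' @param strs STR table.
#' @param w_scaffolds W scaffold names.
#' @param sexes Named sex vector (`"M"`/`"F"`) covering the table's samples.
#' @return Subset of `strs`.
#' @export
select_sex_strs <- function(strs, w_scaffolds, sexes) {
  pg <- parse_str_genotypes(strs)
  males <- pg$samples[sexes[pg$samples] == "M"]
  females <- pg$samples[sexes[pg$samples] == "F"]
  if (!length(females)) stop("no female samples")
  keep <- vapply(seq_len(nrow(strs)), function(i) {
    if (!strs$scaffold[i] %in% w_scaffolds) return(FALSE)
    fa1 <- pg$a1[i, females]; fa2 <- pg$a2[i, females]
    ok_f <- all(!is.na(fa1)) && all(fa1 == fa2)
    ok_m <- !length(males) || all(is.na(pg$a1[i, males]))
    ok_f && ok_m
  }, logical(1))
  strs[keep, , drop = FALSE]
}

#' Mean major/minor allele-length difference
#'
#' Per locus, the absolute bp difference between the most and second-most
#' frequent allele lengths (frequency ties resolved toward the smaller
#' length as major), averaged over loci with at least two alleles.
#'
#' @param strs STR table.
#' @return Mean absolute difference in bp (`NA` if all loci are
#'   monomorphic); attribute `"per_locus"` holds the per-locus values.
#' @export
major_minor_diff <- function(strs) {
  pg <- parse_str_genotypes(strs)
  per <- vapply(seq_len(nrow(strs)), function(i) {
    a <- stats::na.omit(c(pg$a1[i, ], pg$a2[i, ]))
    if (length(unique(a)) < 2) return(NA_real_)
    tab <- sort(table(a), decreasing = TRUE)
    lens <- as.integer(names(tab))
    # stable ordering: frequency desc, then length asc
    o <- order(-as.numeric(tab), lens)
    abs(lens[o][1] - lens[o][2])
  }, numeric(1))
  if (all(is.na(per))) return(structure(NA_real_, per_locus = per))
  structure(mean(per, na.rm = TRUE),
            per_locus = setNames(per, strs$locus_id))
}
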