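#' Severity class of a variant-effect category
#'
#' Frameshift, stop-gain, stop-loss and splicing changes are classed as
#' strong deleterious variants; missense and synonymous changes as slight
#' deleterious variants; anything else is unclassified. Common annotation
#' synonyms (`stop_gained`, `frameshift_variant`, ...) are normalized first.
#'
#' @param category Character vector of effect categories (case-insensitive).
#' @return Character vector in `{"strong", "slight", "unclassified"}`.
#' @export
classify_severity <- function(category) {
  syn <- c(stop_gained = "stopgain", "stop gain" = "stopgain",
           stop_lost = "stoploss", "stop loss" = "stoploss",
           frameshift_variant = "frameshift",
           splice_site = "splicing", splicing_variant = "splicing",
           splice_acceptor_variant = "splicing",
           splice_donor_variant = "splicing",
           missense_variant = "missense",
           synonymous_variant = "synonymous",
           nonsynonymous = "missense", nonsynonymous_snv = "missense",
           synonymous_snv = "synonymous")
  x <- tolower(trimws(category))
  mapped <- syn[x]
  x[!is.na(mapped)] <- mapped[!is.na(mapped)]
  strong <- c("frameshift", "stopgain", "stoploss", "splicing")
  slight <- c("missense", "synonymous")
  ifelse(x %in% strong, "strong",
         ifelse(x %in% slight, "slight", "unclassified"))
}

#' Zygosity-stratified deleterious-load proportions for one sample
#'
#' For each zygosity (dosage 2 = homozygous alt, 1 = heterozygous), the
#' proportion of that sample's classified variant genotypes that are strong
#' (resp. slight); reference-homozygous and missing genotypes are excluded,
#' as are sites whose category is unclassified.
#'
#' @param gm A [geno_matrix()].
#' @param effects Data frame `scaffold`, `pos`, `category` (e.g. from
#'   [simulate_effect_labels()]).
#' @param sample Sample id.
#' @return Data frame `sample`, `zygosity`, `class`, `count`, `denominator`,
#'   `proportion` (NA when the denominator is zero).
#' @export
load_proportions <- function(gm, effects, sample) {
  j <- sample_index(gm, sample)
  key_gm <- paste(gm$sites$scaffold, gm$sites$pos)
  key_ef <- paste(effects$scaffold, effects$pos)
  sev <- classify_severity(effects$category)[match(key_gm, key_ef)]
  g <- gm$geno[, j]
  out <- list()
  for (zy in c("homozygous", "heterozygous")) {
    dose <- if (zy == "homozygous") 2L else 1L
    sel <- !is.na(g) & g == dose & !is.na(sev) & sev != "unclassified"
    denom <- sum(sel)
    for (cl in c("strong", "slight")) {
      cnt <- sum(sel & sev == cl)
      out[[length(out) + 1]] <- data.frame(
        sample = sample, zygosity = zy, class = cl, count = cnt,
        denominator = denom,
        proportion = if (denom > 0) cnt / denom else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Compare per-sample load proportions between two groups
#'
#' Two-sided Wilcoxon rank-sum test on per-sample proportions (exact null
#' for combined n <= 20 without ties, normal approximation with continuity
#' correction otherwise); a t-test alternative is available.
#'
#' @param profiles_a,profiles_b Numeric vectors of per-sample proportions.
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @return List `statistic`, `p_value`, `method`, `n_a`, `n_b`.
#' @export
compare_groups <- function(profiles_a, profiles_b,
                           method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  a <- profiles_a[!is.na(profiles_a)]
  b <- profiles_b[!is.na(profiles_b)]
  if (length(a) < length(profiles_a) || length(b) < length(profiles_b))
    warning("undefined proportions dropped")
  if (length(a) < 3 || length(b) < 3)
    stop("need at least 3 defined proportions per group")
  if (method == "wilcoxon") {
    exact <- (length(a) + length(b)) <= 20 &&
      !anyDuplicated(c(a, b))
    ht <- suppressWarnings(
      wilcox.test(a, b, exact = exact, correct = TRUE))
  } else {
    ht <- stats::t.test(a, b)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = method, n_a = length(a), n_b = length(b))
}

#' Divergence-based mutation rate
#'
#' `mu = d * g / (2 * T)`: genome-wide nucleotide divergence `d` (fraction),
#' generation time `g` (years) and divergence time `T` (years) give the
#' per-site per-generation mutation rate.
#'
#' @param d Nucleotide divergence in `[0, 1]`.
#' @param g Generation time in years.
#' @param T_years Divergence time in years.
#' @return Mutations per site per generation.
#' @export
estimate_mutation_rate <- function(d, g, T_years) {
  if (!is.numeric(d) || d < 0 || d > 1) stop("d must lie in [0, 1]")
  stopifnot_scalar_pos(g, "g")
  stopifnot_scalar_pos(T_years, "T_years")
  d * g / (2 * T_years)
}
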