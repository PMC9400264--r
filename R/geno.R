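#' Genotype matrix of biallelic SNVs
#'
#' The central container of the package: an integer matrix of alternate-allele
#' dosages (rows = sites, columns = samples; values 0/1/2 or `NA` for missing)
#' together with per-site metadata and, optionally, scaffold lengths taken
#' from a VCF header.
#'
#' @param geno Integer matrix, sites x samples, values in `{0,1,2,NA}`.
#' @param sites Data frame with at least `scaffold`, `pos` (1-based, as in
#'   VCF), `ref`, `alt` (single bases). Extra columns (e.g. the GATK INFO
#'   annotations `QD`, `FS`, `MQ`, `SOR`, `MQRankSum`, `ReadPosRankSum`) are
#'   carried along.
#' @param samples Character vector of unique sample ids, one per column.
#' @param scaffold_lengths Optional named numeric vector of scaffold lengths
#'   in bp.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, sites, samples, scaffold_lengths = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(sites))
    stop("geno and sites disagree on the number of sites")
  if (ncol(geno) != length(samples))
    stop("geno and samples disagree on the number of samples")
  if (anyDuplicated(samples))
    stop("sample ids must be unique")
  needed <- c("scaffold", "pos", "ref", "alt")
  if (!all(needed %in% names(sites)))
    stop("sites must have columns: ", paste(needed, collapse = ", "))
  if (nrow(sites) > 0) {
    if (any(sites$pos < 1)) stop("positions must be >= 1 (VCF convention)")
    bad <- nchar(sites$ref) != 1L | nchar(sites$alt) != 1L |
      sites$ref == sites$alt
    if (any(bad)) stop("sites must be biallelic SNVs (single base, ref != alt)")
    ord <- order(sites$scaffold, sites$pos)
    sites <- sites[ord, , drop = FALSE]
    geno <- geno[ord, , drop = FALSE]
    if (anyDuplicated(paste(sites$scaffold, sites$pos)))
      stop("duplicate (scaffold, pos) entries")
    rng <- range(geno, na.rm = TRUE)
    if (nrow(geno) > 0 && any(!is.na(geno)) && (rng[1] < 0 || rng[2] > 2))
      stop("dosages must lie in {0, 1, 2}")
  }
  rownames(sites) <- NULL
  structure(list(geno = geno, sites = sites,
                 samples = as.character(samples),
                 scaffold_lengths = scaffold_lengths),
            class = "geno_matrix")
}

#' @export
#' @method print geno_matrix
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$sites), "biallelic SNVs x",
      length(x$samples), "samples\n")
  if (nrow(x$sites) > 0)
    cat("  scaffolds:", length(unique(x$sites$scaffold)), "\n")
  if (!is.null(x$scaffold_lengths))
    cat("  total scaffold length:",
        format(sum(x$scaffold_lengths), big.mark = ","), "bp\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

n_sites <- function(gm) nrow(gm$geno)

sample_index <- function(gm, ids) {
  idx <- match(ids, gm$samples)
  if (anyNA(idx))
    stop("unknown sample(s): ", paste(ids[is.na(idx)], collapse = ", "))
  idx
}

#' Subset a genotype matrix
#'
#' @param gm A [geno_matrix()].
#' @param sites Integer or logical index over sites.
#' @param samples Character vector of sample ids (or integer index).
#' @return A `geno_matrix`.
#' @export
subset_geno <- function(gm, sites = NULL, samples = NULL) {
  g <- gm$geno
  st <- gm$sites
  sm <- gm$samples
  if (!is.null(sites)) {
    g <- g[sites, , drop = FALSE]
    st <- st[sites, , drop = FALSE]
  }
  if (!is.null(samples)) {
    j <- if (is.character(samples)) sample_index(gm, samples) else samples
    g <- g[, j, drop = FALSE]
    sm <- sm[j]
  }
  geno_matrix(g, st, sm, gm$scaffold_lengths)
}

# Per-site alternate-allele count, called-allele count and frequency,
# restricted to a sample subset when given.
site_counts <- function(gm, samples = NULL) {
  g <- gm$geno
  if (!is.null(samples))
    g <- g[, sample_index(gm, samples), drop = FALSE]
  m <- 2L * rowSums(!is.na(g))
  alt <- rowSums(g, na.rm = TRUE)
  list(alt = alt, m = m, p = ifelse(m > 0, alt / m, NA_real_))
}

#' Tile scaffolds into non-overlapping windows
#'
#' Windows are 0-based half-open intervals tiling each scaffold from 0; a
#' final partial window (shorter than `size`) is kept and flagged.
#'
#' @param scaffold_lengths Named numeric vector of scaffold lengths (bp).
#' @param size Window size in bp (default 40 kb).
#' @return Data frame with `scaffold`, `start`, `end`, `partial`.
#' @export
make_windows <- function(scaffold_lengths, size = 40000) {
  stopifnot_scalar_pos(size, "size")
  if (is.null(names(scaffold_lengths)) || any(scaffold_lengths <= 0))
    stop("scaffold_lengths must be a named vector of positive lengths")
  out <- lapply(names(scaffold_lengths), function(sc) {
    L <- scaffold_lengths[[sc]]
    start <- size * (seq_len(ceiling(L / size)) - 1)
    end <- pmin(start + size, L)
    data.frame(scaffold = sc, start = start, end = end,
               partial = (end - start) < size)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Map each site to its window index (row of `windows`); NA when a site falls
# in no window. Window assignment uses pos - 1 (0-based) against half-open
# windows.
assign_windows <- function(gm, windows) {
  idx <- rep(NA_integer_, n_sites(gm))
  for (sc in unique(gm$sites$scaffold)) {
    w <- which(windows$scaffold == sc)
    if (!length(w)) next
    s <- which(gm$sites$scaffold == sc)
    p0 <- gm$sites$pos[s] - 1
    ws <- windows$start[w]
    we <- windows$end[w]
    k <- findInterval(p0, ws)
    ok <- k >= 1 & p0 < we[pmax(k, 1)]
    idx[s[ok]] <- w[k[ok]]
  }
  idx
}
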