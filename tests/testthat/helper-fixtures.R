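# Small in-code fixtures shared across test files.

# Build a geno_matrix from a plain dosage matrix (sites x samples); positions
# default to 1 kb spacing on one scaffold.
toy_gm <- function(geno, pos = NULL, scaffold = "s1", L = NULL,
                   ref = NULL, alt = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  pos <- pos %||% (seq_len(n) * 1000L)
  L <- L %||% (max(pos) + 1000)
  sites <- data.frame(scaffold = scaffold, pos = pos,
                      ref = ref %||% rep("A", n),
                      alt = alt %||% rep("G", n))
  ids <- paste0("s", seq_len(ncol(geno)))
  geno_matrix(geno, sites, ids, setNames(L, scaffold[1]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random dosage matrix with controlled allele frequencies
random_gm <- function(n_sites, n_samples, seed, maf = NULL) {
  set.seed(seed)
  p <- maf %||% runif(n_sites, 0.05, 0.95)
  g <- matrix(rbinom(n_sites * n_samples, 2, p), nrow = n_sites)
  toy_gm(g)
}

# a default small simulated cohort reused by several files
cached_cohort <- local({
  env <- new.env()
  function() {
    if (is.null(env$co)) {
      cfg <- sim_config(
        seed = 20240901, n_scaffolds = 2, scaffold_length = 4e5,
        groups = data.frame(name = c("GCO", "GSA"), n = c(10L, 8L),
                            theta = c(1e-3, 1e-4), f = c(0, 0),
                            n_females = c(4L, 4L)),
        relatives = data.frame(type = c("parent_offspring", "half_sib"),
                               group = "GCO"))
      env$co <- simulate_cohort(cfg)
    }
    env$co
  }
})
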