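#' Run the full analysis pipeline from one configuration
#'
#' Stages run in dependency order (simulate -> filter -> diversity ->
#' kinship -> sweep -> sex/STR -> load), each writing its outputs before the
#' next starts; all randomness flows from the single configured seed, so a
#' rerun with an identical configuration reproduces identical outputs.
#'
#' The configuration (YAML file or equivalent list) either names input files
#' (`vcf`, `depth`, `str`, `effects`, `metadata`) or carries a `simdata`
#' block of [sim_config()] arguments; `params` holds optional per-stage
#' blocks (`filter`, `popdiv`, `kinship`, `sweep`, `sexstr`, `mutload`),
#' `outdir` the output directory and `seed` the master seed.
#'
#' @param config Path to a YAML file or a list.
#' @param outdir Output directory (overrides the config entry).
#' @return The run report (also written as `report.json`): per-stage record
#'   counts, thresholds used, seed and md5 provenance of the stage inputs.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("simdata", "vcf", "depth", "str", "effects", "metadata",
             "gene_bed", "params", "outdir", "seed", "log_level")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  outdir <- outdir %||% config$outdir %||% stop("no output directory given")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  params <- config$params %||% list()
  report <- list(seed = seed, stages = list())
  note <- function(name, rec) {
    message("[", name, "] done")
    report$stages[[name]] <<- rec
  }

  ## stage: inputs (simulate or load)
  if (!is.null(config$simdata)) {
    sc_args <- config$simdata
    sc_args$seed <- seed
    for (nm in c("groups", "sweeps", "relatives", "roh"))
      if (!is.null(sc_args[[nm]]) && !is.data.frame(sc_args[[nm]]))
        sc_args[[nm]] <- do.call(rbind, lapply(sc_args[[nm]], as.data.frame))
    cfg <- do.call(sim_config, sc_args)
    cohort <- simulate_cohort(cfg)
    gm <- cohort$gm
    samples <- cohort$samples
    depth <- simulate_depth_profiles(cfg, samples)
    strs <- simulate_str_table(cfg, cohort$truth)
    effects <- simulate_effect_labels(cfg, gm)
    write_vcf(gm, file.path(outdir, "cohort.vcf"))
    wt <- function(x, f) utils::write.table(
      x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(samples, "samples.tsv")
    wt(depth, "depth.tsv")
    wt(strs, "str.tsv")
    wt(effects, "effects.tsv")
    jsonlite::write_json(
      list(sweeps = cohort$truth$sweeps, pairs = cohort$truth$pairs,
           scaffold_class = as.list(cohort$truth$scaffold_class),
           sexes = as.list(cohort$truth$sexes)),
      file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
    note("simulate", list(n_sites = n_sites(gm), n_samples = nrow(samples)))
  } else {
    if (is.null(config$vcf) || is.null(config$metadata))
      stop("config needs either a simdata block or vcf + metadata inputs")
    gm <- read_vcf(config$vcf)
    samples <- utils::read.table(config$metadata, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
    depth <- if (!is.null(config$depth))
      utils::read.table(config$depth, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE) else NULL
    strs <- if (!is.null(config$str))
      utils::read.table(config$str, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE, check.names = FALSE)
    else NULL
    effects <- if (!is.null(config$effects))
      utils::read.table(config$effects, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE) else NULL
    note("load", list(n_sites = n_sites(gm), n_samples = nrow(samples)))
  }

  ## stage: hard filter
  fp <- params$filter %||% list()
  gmf <- do.call(hard_filter_variants, c(list(gm), fp))
  hf <- attr(gmf, "hard_filter")
  write_vcf(gmf, file.path(outdir, "filtered.vcf"))
  note("filter", list(n_in = n_sites(gm), n_removed = hf$n_removed,
                      n_out = n_sites(gmf), thresholds = hf$thresholds))

  ## stage: diversity
  pp <- params$popdiv %||% list()
  wsize <- pp$window_size %||% 40000
  groups <- split(samples$id, samples$group)
  pi_tabs <- lapply(names(groups), function(g) {
    t <- pi_windows(gmf, samples = groups[[g]], size = wsize)
    t$group <- g
    t
  })
  pi_tab <- do.call(rbind, pi_tabs)
  utils::write.table(pi_tab, file.path(outdir, "pi_windows.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  glen <- sum(gmf$scaffold_lengths)
  sample_stats <- do.call(rbind, lapply(samples$id, function(sm) {
    segs <- call_roh(gmf, sm,
                     min_snps = pp$roh_min_snps %||% 10,
                     min_kb = pp$roh_min_kb %||% 40)
    data.frame(id = sm,
               het_rate = heterozygosity_rate(gmf, sm, glen),
               f_inbreed = inbreeding_f(
                 gmf, sm,
                 freq_samples = groups[[samples$group[samples$id == sm]]]),
               n_roh = nrow(segs),
               f_roh = f_roh(segs, glen))
  }))
  utils::write.table(sample_stats, file.path(outdir, "sample_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("popdiv", list(n_windows = nrow(pi_tab), window_size = wsize))

  ## stage: kinship (within groups: pooled frequencies across diverged
  ## groups would mimic IBD between unrelated cross-group pairs)
  kp <- params$kinship %||% list()
  pairs <- do.call(rbind, lapply(groups, function(ids) {
    if (length(ids) < 2) return(NULL)
    kinship_pairs(gmf, ids, freq_samples = ids)
  }))
  rownames(pairs) <- NULL
  utils::write.table(pairs, file.path(outdir, "kinship_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  quality <- setNames(samples$quality %||% rep(1, nrow(samples)),
                      samples$id)
  kept <- prune_related(pairs, quality,
                        kp$pi_hat_threshold %||% 0.2)
  writeLines(kept, file.path(outdir, "unrelated_samples.txt"))
  tree <- NULL
  if (length(kept) >= 3) {
    D <- ibs_distance_matrix(gmf, kept)
    tree <- nj_tree(D)
    writeLines(tree, file.path(outdir, "ibs_nj.nwk"))
  }
  note("kinship", list(n_pairs = nrow(pairs), n_kept = length(kept)))

  ## stage: sweep scan
  sp <- params$sweep %||% list()
  grp_names <- names(groups)
  pop_a <- if (!is.null(sp$pop_a)) groups[[sp$pop_a]] else groups[[1]]
  founders <- if (is.null(samples$derived)) samples$id else
    samples$id[!samples$derived]
  pop_b <- if (!is.null(sp$pop_b)) groups[[sp$pop_b]] else
    setdiff(founders, pop_a)
  scan <- NULL
  if (length(pop_a) >= 2 && length(pop_b) >= 2) {
    scan <- sweep_scan(gmf, pop_a, pop_b,
                       window_size = sp$window_size %||% 40000,
                       quantile = sp$quantile %||% 0.01)
    utils::write.table(scan$windows, file.path(outdir, "sweep_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(fst_threshold = scan$fst_threshold,
                              zhp_threshold = scan$zhp_threshold,
                              n_overlap = nrow(scan$overlap)),
                         file.path(outdir, "sweep_thresholds.json"),
                         auto_unbox = TRUE, digits = NA)
    note("sweep", list(n_windows = nrow(scan$windows),
                       n_overlap = nrow(scan$overlap),
                       fst_threshold = scan$fst_threshold,
                       zhp_threshold = scan$zhp_threshold))
  }

  ## stage: sex scaffolds + STR panels
  if (!is.null(depth)) {
    xp <- params$sexstr %||% list()
    sexes <- setNames(samples$sex, samples$id)
    norm <- normalize_depth(depth, sexes)
    cls <- classify_scaffolds(norm)
    utils::write.table(cls, file.path(outdir, "scaffold_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    wsc <- cls$scaffold[cls$cls == "W"]
    if (length(wsc)) {
      sexcall <- call_sample_sex(norm, wsc)
      utils::write.table(sexcall, file.path(outdir, "sex_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(strs)) {
      kin <- filter_kinship_strs(strs,
                                 unit_len = xp$unit_len %||% 4,
                                 min_alleles = xp$min_alleles %||% 5)
      sex <- if (length(wsc)) select_sex_strs(strs, wsc, sexes) else
        strs[0, , drop = FALSE]
      utils::write.table(kin, file.path(outdir, "str_kinship_panel.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(sex, file.path(outdir, "str_sex_panel.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      note("sexstr", list(n_w_scaffolds = length(wsc),
                          n_kinship_strs = nrow(kin),
                          n_sex_strs = nrow(sex)))
    } else note("sexstr", list(n_w_scaffolds = length(wsc)))
  }

  ## stage: deleterious load
  if (!is.null(effects)) {
    mp <- params$mutload %||% list()
    prof <- do.call(rbind, lapply(samples$id, function(sm)
      load_proportions(gmf, effects, sm)))
    utils::write.table(prof, file.path(outdir, "load_profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cmp <- NULL
    if (length(groups) >= 2) {
      pick <- function(g) {
        x <- prof[prof$zygosity == "homozygous" & prof$class == "strong" &
                    prof$sample %in% groups[[g]], "proportion"]
        x
      }
      a <- pick(grp_names[1]); b <- pick(grp_names[2])
      if (sum(!is.na(a)) >= 3 && sum(!is.na(b)) >= 3) {
        cmp <- compare_groups(a, b, method = mp$method %||% "wilcoxon")
        jsonlite::write_json(
          c(list(groups = grp_names[1:2],
                 metric = "homozygous_strong_proportion"), cmp),
          file.path(outdir, "load_comparison.json"),
          auto_unbox = TRUE, digits = NA)
      }
    }
    note("mutload", list(n_profiles = nrow(prof),
                         p_value = cmp$p_value %||% NA))
  }

  ## provenance + report
  written <- list.files(outdir, full.names = TRUE)
  written <- written[basename(written) != "report.json"]
  report$provenance <- as.list(tools::md5sum(sort(written)))
  names(report$provenance) <- basename(names(report$provenance))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(report)
}
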