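## End-to-end orchestration: config-driven runs (simulate -> filter -> scan
## -> class tests -> report), stage-tagged error handling, logging to stderr,
## and data-first figures (every figure has a TSV twin).

log_msg <- function(level, ...) {
  message(sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%H:%M:%S"), paste0(...)))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Build a run configuration
#'
#' Either `sim` (a [sim_config()] or preset name) for simulation mode, or
#' `posterior_path` (+ `gene_map_path`) for file mode — not both.
#'
#' @param out_dir Output directory.
#' @param sim Optional [sim_config()] or preset name (`"CALL"`, `"CHAF"`,
#'   `"HUEX-STAC"`).
#' @param posterior_path,gene_map_path,focal_genes_path Input files for file
#'   mode.
#' @param lo,hi Posterior confidence thresholds.
#' @param mito_site Optional `"chrom:pos"` selector of the mitochondrial AIM.
#' @param statistics Which per-AIM statistics to aggregate per gene and test
#'   (any of `"Dprime"`, `"r2"`, `"allele_freq"`); by default D'/r2 when the
#'   mitochondrial haplotype segregates and allele frequency when it is
#'   fixed.
#' @param n_perm,contrast,fraction,sided Test parameters (see
#'   [permutation_class_test()] and [top_fraction_enrichment()]).
#' @param hard_calls Compute LD from hard-thresholded calls instead of raw
#'   dosages.
#' @param seed Seed for the run (simulation and permutations).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       sim = NULL,
                       posterior_path = NULL,
                       gene_map_path = NULL,
                       focal_genes_path = NULL,
                       lo = 0.2, hi = 0.8,
                       mito_site = NULL,
                       statistics = NULL,
                       n_perm = 9999,
                       contrast = c("interacting_nmt", "non_nmt"),
                       fraction = 0.01,
                       sided = "one",
                       hard_calls = FALSE,
                       seed = 1L) {
  if (!is.null(sim) && !is.null(posterior_path))
    stop("give either a simulation config or input paths, not both",
         call. = FALSE)
  if (is.null(sim) && is.null(posterior_path))
    stop("one of sim or posterior_path is required", call. = FALSE)
  if (is.character(sim)) sim <- sim_preset(sim, seed = seed)
  structure(list(out_dir = out_dir, sim = sim,
                 posterior_path = posterior_path,
                 gene_map_path = gene_map_path,
                 focal_genes_path = focal_genes_path,
                 lo = lo, hi = hi, mito_site = mito_site,
                 statistics = statistics, n_perm = as.integer(n_perm),
                 contrast = contrast, fraction = fraction, sided = sided,
                 hard_calls = hard_calls, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; a `sim:` mapping is
#' passed to [sim_config()] (or, when it is a bare string, to
#' [sim_preset()]). `sim$incompat_loci` may be a list of mappings with keys
#' `gene_id`, `s`, `h`, `matched`.
#'
#' @param path YAML file path.
#' @param overrides Named list of values overriding the file (e.g. from
#'   command-line flags).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y <- utils::modifyList(y, overrides)
  if (!is.null(y$sim) && is.list(y$sim)) {
    sim_args <- y$sim
    if (!is.null(sim_args$chromosomes))
      sim_args$chromosomes <- unlist(sim_args$chromosomes)
    if (!is.null(sim_args$incompat_loci))
      sim_args$incompat_loci <- do.call(
        rbind, lapply(sim_args$incompat_loci, as.data.frame))
    if (!is.null(y$seed) && is.null(sim_args$seed))
      sim_args$seed <- y$seed
    y$sim <- do.call(sim_config, sim_args)
  }
  do.call(run_config, y)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full mitonuclear scan pipeline
#'
#' Executes simulate (or read) -> confidence filter -> mitochondrial
#' haplotype calls -> per-AIM statistics -> per-gene aggregation -> class
#' tests -> outlier and enrichment reports, writing every result table and a
#' machine-readable run manifest to `config$out_dir`. When the mitochondrial
#' haplotype is effectively fixed (monomorphic among called individuals), the
#' LD stage is skipped with a logged notice and the per-gene allele-frequency
#' analysis is run instead.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of in-memory results (`summaries`, `per_aim`,
#'   `gene_stats`, `anova`, `permutation`, `enrichment`, `outliers`,
#'   `manifest`, plus `mito_fixed`).
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  inputs <- stage("input", {
    if (!is.null(config$sim)) {
      log_msg("INFO", "simulating dataset (seed ", config$sim$seed, ")")
      ds <- simulate_dataset(config$sim)
      list(posteriors = ds$posteriors, sites = ds$sites, genes = ds$genes,
           truth = ds$truth)
    } else {
      for (p in c(config$posterior_path, config$gene_map_path))
        if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
      pt <- read_posterior_table(config$posterior_path)
      list(posteriors = pt$posteriors, sites = pt$sites,
           genes = read_gene_map(config$gene_map_path), truth = NULL)
    }
  })
  focal <- if (!is.null(config$focal_genes_path))
    stage("input", read_focal_genes(config$focal_genes_path))
  else if (!is.null(config$sim)) inputs$truth$selected_genes
  else character()

  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$sim))
    write_sim_dataset(list(posteriors = inputs$posteriors,
                           sites = inputs$sites, genes = inputs$genes,
                           truth = inputs$truth, config = config$sim),
                      file.path(out, "simulated"))

  filtered <- stage("filter",
                    filter_posteriors(inputs$posteriors, config$lo, config$hi))
  calls <- stage("mito_calls",
                 call_mito_haplotype(filtered, inputs$sites,
                                     mito_site = config$mito_site,
                                     lo = config$lo, hi = config$hi))
  summaries <- stage("summaries",
                     population_summaries(filtered, inputs$sites, calls))
  mito_freq <- summaries$mito_haplotype_freq
  mito_fixed <- any(is.na(mito_freq)) || min(mito_freq) == 0
  if (mito_fixed)
    log_msg("NOTICE", "mitochondrial haplotype is monomorphic among called ",
            "individuals; skipping the LD stage and running the ",
            "allele-frequency analysis")
  stats_wanted <- config$statistics %||%
    (if (mito_fixed) "allele_freq" else c("Dprime", "r2"))
  if (mito_fixed && any(stats_wanted %in% c("Dprime", "r2")))
    stop("stage 'ld_scan' failed: mitonuclear LD requested but the ",
         "mitochondrial AIM is monomorphic (haplotype fixed); use the ",
         "allele-frequency analysis instead", call. = FALSE)

  mapping <- stage("gene_mapping",
                   map_aims_to_genes(inputs$sites, inputs$genes))
  per_aim <- NULL
  gene_stats <- list()
  if (any(stats_wanted %in% c("Dprime", "r2"))) {
    per_aim <- stage("ld_scan",
                     scan_mitonuclear_ld(filtered, inputs$sites, calls,
                                         hard_calls = config$hard_calls,
                                         lo = config$lo, hi = config$hi))
    for (st in intersect(stats_wanted, c("Dprime", "r2"))) {
      vals <- rep(NA_real_, nrow(inputs$sites))
      vals[inputs$sites$compartment == "nuclear"] <- per_aim[[st]]
      gene_stats[[st]] <- stage("aggregate",
                                aggregate_per_gene(vals, mapping,
                                                   inputs$genes, st))
    }
  }
  if ("allele_freq" %in% stats_wanted)
    gene_stats$allele_freq <- stage(
      "allele_freq", allele_freq_per_gene(filtered, inputs$sites, mapping,
                                          inputs$genes))

  results <- list(summaries = summaries, per_aim = per_aim,
                  gene_stats = gene_stats, mito_fixed = mito_fixed,
                  anova = list(), permutation = list(), enrichment = list(),
                  outliers = list())
  for (st in names(gene_stats)) {
    gs <- gene_stats[[st]]
    results$anova[[st]] <- stage("anova", one_way_anova(gs))
    results$permutation[[st]] <- stage(
      "permutation",
      permutation_class_test(gs, contrast = config$contrast,
                             n_perm = config$n_perm,
                             seed = sub_seed(config$seed, 300L),
                             sided = config$sided))
    if (nrow(gs) >= 1 / config$fraction) {
      results$enrichment[[st]] <- stage(
        "enrichment", top_fraction_enrichment(gs, fraction = config$fraction))
    } else {
      log_msg("NOTICE", "too few genes (", nrow(gs),
              ") for top-fraction enrichment at fraction ", config$fraction,
              "; skipping")
    }
    results$outliers[[st]] <- stage("outliers", zscore_outliers(gs, focal))
  }

  stage("write", {
    if (!is.null(per_aim)) write_tsv(per_aim, file.path(out, "per_aim_stats.tsv"))
    for (st in names(gene_stats)) {
      write_tsv(gene_stats[[st]],
                file.path(out, paste0("per_gene_", st, ".tsv")))
      write_tsv(results$outliers[[st]],
                file.path(out, paste0("outliers_", st, ".tsv")))
      if (!is.null(results$enrichment[[st]]))
        write_tsv(results$enrichment[[st]],
                  file.path(out, paste0("enrichment_", st, ".tsv")))
    }
    anova_tab <- do.call(rbind, lapply(names(results$anova), function(st) {
      a <- results$anova[[st]]
      p <- results$permutation[[st]]
      data.frame(statistic = st, F = a$F, p_anova = a$p,
                 T_obs = p$T_obs, p_perm = p$p_perm, n_perm = p$n_perm,
                 contrast = paste(p$contrast, collapse = "-"),
                 sided = p$sided, stringsAsFactors = FALSE)
    }))
    write_tsv(anova_tab, file.path(out, "class_tests.tsv"))
    class_summ <- do.call(rbind, lapply(names(results$anova), function(st)
      cbind(statistic = st, results$anova[[st]]$per_class)))
    write_tsv(class_summ, file.path(out, "class_summaries.tsv"))
    write_tsv(summaries$per_individual,
              file.path(out, "individual_ancestry.tsv"))
    manifest <- list(
      package = "mitoscan",
      version = as.character(utils::packageVersion("mitoscan")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      mode = if (!is.null(config$sim)) "simulate" else "files",
      parameters = config[c("lo", "hi", "mito_site", "n_perm", "contrast",
                            "fraction", "sided", "hard_calls")],
      statistics = stats_wanted,
      mito_fixed = mito_fixed,
      mean_nuclear_ancestry = summaries$mean_nuclear_ancestry,
      mito_haplotype_freq = as.list(mito_freq),
      sim = if (!is.null(config$sim))
        config$sim[setdiff(names(config$sim), "incompat_loci")]
    )
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null",
                         digits = NA, force = TRUE)
  })
  results$manifest_path <- file.path(out, "manifest.json")
  log_msg("INFO", "scan complete: ", out)
  invisible(results)
}

#' In-memory analysis of a posterior matrix
#'
#' The computational core of [run_scan()] without any file I/O: applies the
#' confidence filter, calls mitochondrial haplotypes, computes either the
#' per-AIM mitonuclear LD scan (when the haplotype segregates) or per-gene
#' allele frequencies (when it is fixed), and aggregates per gene.
#'
#' @param posteriors Posterior matrix (unfiltered).
#' @param sites AIM site table.
#' @param genes Gene annotation table.
#' @param statistic `"Dprime"`, `"r2"` or `"allele_freq"`; `NULL` picks
#'   D' when the mito haplotype segregates and allele frequency otherwise.
#' @param lo,hi Confidence thresholds.
#' @param min_haplotype_calls Minimum number of called individuals required
#'   for *each* mitochondrial haplotype before LD statistics are attempted
#'   (default 2, the smallest value for which the estimators are defined).
#' @param hard_calls Passed to [scan_mitonuclear_ld()].
#' @return A list with `gene_stats` (per-gene table, or `NULL` if the
#'   requested LD statistic is undefined), `per_aim`, `calls`,
#'   `mito_counts` (named major/minor call counts), `mito_segregating`, and
#'   `statistic`.
#' @export
analyze_dataset <- function(posteriors, sites, genes, statistic = NULL,
                            lo = 0.2, hi = 0.8, min_haplotype_calls = 2,
                            hard_calls = FALSE) {
  filtered <- filter_posteriors(posteriors, lo, hi)
  calls <- call_mito_haplotype(filtered, sites, lo = lo, hi = hi)
  counts <- c(major = sum(calls == "major", na.rm = TRUE),
              minor = sum(calls == "minor", na.rm = TRUE))
  segregating <- min(counts) >= min_haplotype_calls
  statistic <- statistic %||% (if (segregating) "Dprime" else "allele_freq")
  mapping <- map_aims_to_genes(sites, genes)
  per_aim <- NULL
  gene_stats <- NULL
  if (statistic %in% c("Dprime", "r2")) {
    if (segregating) {
      per_aim <- scan_mitonuclear_ld(filtered, sites, calls,
                                     hard_calls = hard_calls,
                                     lo = lo, hi = hi)
      vals <- rep(NA_real_, nrow(sites))
      vals[sites$compartment == "nuclear"] <- per_aim[[statistic]]
      gene_stats <- aggregate_per_gene(vals, mapping, genes, statistic)
    }
  } else {
    gene_stats <- allele_freq_per_gene(filtered, sites, mapping, genes)
  }
  list(gene_stats = gene_stats, per_aim = per_aim, calls = calls,
       mito_counts = counts, mito_segregating = segregating,
       statistic = statistic)
}

#' Generate report figures and their data tables
#'
#' Produces the three standard views of a run — per-class distributions of a
#' gene-level LD statistic, the per-individual ancestry histogram stacked by
#' mitochondrial haplotype, and per-class allele-frequency boxplots — as PDF
#' figures, each with a TSV twin holding exactly the plotted numbers so
#' figures are re-derivable and comparable by data rather than pixels. Gene
#' classes with no genes are omitted with a warning.
#'
#' @param results Result list from [run_scan()].
#' @param out_dir Directory for figures and TSV twins.
#' @return Invisibly, the paths written.
#' @export
make_report <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  save_fig <- function(plot, name) {
    p <- file.path(out_dir, paste0(name, ".pdf"))
    grDevices::pdf(p, width = 7, height = 5)
    print(plot)
    grDevices::dev.off()
    p
  }
  for (st in names(results$gene_stats)) {
    gs <- results$gene_stats[[st]]
    empty <- setdiff(GENE_CLASSES, unique(gs$gene_class))
    if (length(empty))
      warning("omitting empty gene class(es) from report: ",
              paste(empty, collapse = ", "), call. = FALSE)
    twin <- file.path(out_dir, paste0("fig_class_", st, ".tsv"))
    write_tsv(gs[, c("gene_id", "gene_class", "value")], twin)
    plt <- if (st == "allele_freq") {
      ggplot2::ggplot(gs, ggplot2::aes(x = .data$gene_class,
                                       y = .data$value,
                                       fill = .data$gene_class)) +
        ggplot2::geom_boxplot(show.legend = FALSE) +
        ggplot2::labs(x = NULL, y = "major-parent allele frequency",
                      title = "Per-gene allele frequency by gene class")
    } else {
      ggplot2::ggplot(gs, ggplot2::aes(x = .data$value,
                                       fill = .data$gene_class)) +
        ggplot2::geom_density(alpha = 0.5) +
        ggplot2::labs(x = paste0("per-gene ", st), fill = "gene class",
                      title = paste0("Mitonuclear ", st, " by gene class"))
    }
    paths <- c(paths, twin, save_fig(plt, paste0("fig_class_", st)))
  }
  pi <- results$summaries$per_individual
  twin <- file.path(out_dir, "fig_ancestry_histogram.tsv")
  write_tsv(pi, twin)
  if (!is.null(pi$mito)) {
    plt <- ggplot2::ggplot(pi, ggplot2::aes(x = .data$mean_ancestry,
                                            fill = .data$mito)) +
      ggplot2::geom_histogram(bins = 30, position = "stack") +
      ggplot2::labs(x = "proportion of nuclear genome from major parent",
                    y = "individuals", fill = "mito haplotype",
                    title = "Genome-wide ancestry by mitochondrial haplotype")
    paths <- c(paths, twin, save_fig(plt, "fig_ancestry_histogram"))
  }
  invisible(paths)
}
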