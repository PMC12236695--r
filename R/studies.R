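## Reproducible simulation studies: calibration of the class tests under the
## null and power/sensitivity of the scan under mitonuclear selection.
## These wrap the generator presets and the analysis pipeline into seeded,
## table-returning study runners.

## Per-replicate seeds derived from one study seed.
replicate_seeds <- function(seed, n) {
  vapply(seq_len(n), function(i) sub_seed(seed, i), 0)
}

#' Type-I calibration of the permutation class test
#'
#' Simulates an exchangeable null — i.i.d. gene-level values with randomly
#' assigned gene classes — and records the one-sided permutation p-value of
#' the interacting vs non-n-mt contrast for each replicate. Under this null
#' the p-values are uniform, so the empirical type-I error at any alpha
#' matches alpha up to Monte Carlo noise.
#'
#' @param n_rep Number of null replicates (default 500).
#' @param n_perm Permutations per replicate (default 999).
#' @param class_sizes Named or unnamed integer vector of genes per class in
#'   the order interacting / non-interacting / non-n-mt.
#' @param seed Study seed.
#' @return A list with `p` (vector of p-values), `type1` (share of
#'   `p <= 0.05`) and `ks_p` (Kolmogorov-Smirnov uniformity p-value).
#' @export
study_permutation_calibration <- function(n_rep = 500, n_perm = 999,
                                          class_sizes = c(10L, 20L, 30L),
                                          seed = 1L) {
  seeds <- replicate_seeds(seed, n_rep)
  p <- vapply(seq_len(n_rep), function(i) {
    with_seed(seeds[i], {
      n <- sum(class_sizes)
      gs <- data.frame(
        gene_id = sprintf("g%05d", seq_len(n)),
        gene_class = sample(rep(GENE_CLASSES, class_sizes)),
        statistic = "allele_freq",
        value = stats::rnorm(n),
        stringsAsFactors = FALSE
      )
      permutation_class_test(gs, n_perm = n_perm,
                             seed = sub_seed(seeds[i], 77L))$p_perm
    })
  }, 0)
  list(p = p, type1 = mean(p <= 0.05),
       ks_p = suppressWarnings(stats::ks.test(p, "punif"))$p.value)
}

#' Type-I calibration of the gene-class ANOVA on neutral simulations
#'
#' Runs neutral (no selection) hybrid-population simulations with the
#' demography of a segregating-mitogenome population and applies the
#' standard analysis: confidence filter, mito haplotype calls, per-AIM D',
#' per-gene averaging, one-way class ANOVA. The LD statistic is defined only
#' in replicates where both mitochondrial haplotypes are still called
#' (genetic drift fixes the maternally inherited haplotype in a substantial
#' share of replicates at these population sizes); the rejection rate is
#' computed over those replicates. Because gene classes are assigned to gene
#' positions at random and no locus is under selection, rejections at
#' alpha = 0.05 should occur at the nominal rate.
#'
#' @param n_sim Number of neutral replicates (default 200).
#' @param n_individuals Census size per replicate (default 100).
#' @param n_aims_per_chrom Nuclear AIMs per chromosome (default 1000, two
#'   chromosomes).
#' @param scale Gene-count scale for the CALL-like preset (default 0.02,
#'   i.e. 407 genes).
#' @param seed Study seed.
#' @return A `data.frame` with one row per replicate (`seed`, `segregating`,
#'   `p_anova`) plus attribute `rejection_rate` (share of `p < 0.05` among
#'   segregating replicates).
#' @export
study_neutral_type1 <- function(n_sim = 200, n_individuals = 100,
                                n_aims_per_chrom = 1000, scale = 0.02,
                                seed = 1L) {
  seeds <- replicate_seeds(seed, n_sim)
  rows <- lapply(seq_len(n_sim), function(i) {
    cfg <- sim_preset("CALL", scale = scale, n_chrom = 2,
                      n_individuals = n_individuals,
                      n_aims_per_chrom = n_aims_per_chrom,
                      seed = seeds[i])
    ds <- simulate_dataset(cfg)
    res <- analyze_dataset(ds$posteriors, ds$sites, ds$genes,
                           statistic = "Dprime")
    p <- NA_real_
    if (!is.null(res$gene_stats))
      p <- tryCatch(one_way_anova(res$gene_stats)$p,
                    error = function(e) NA_real_)
    data.frame(seed = seeds[i], segregating = res$mito_segregating,
               p_anova = p)
  })
  out <- do.call(rbind, rows)
  attr(out, "rejection_rate") <- mean(out$p_anova < 0.05, na.rm = TRUE)
  out
}

#' Sensitivity of the scan to selection at a subset of interacting genes
#'
#' The scaled-down analogue of asking whether selection on a handful of
#' interacting n-mt genes is detectable: CALL-like demography (segregating
#' mitogenome, 46 generations, census 281) with embryonic-lethal recessive
#' incompatibilities (`s = 1`, `h = 0`, both mitonuclear directions) at a
#' chosen fraction of the interacting n-mt genes. For each seed and selected
#' fraction the study records whether the mitochondrial haplotype is still
#' segregating (strong incompatibility selection itself tends to purge the
#' polymorphism in a panmictic population — see the methods vignette), the
#' class-ANOVA p-value on per-gene D', and how many truly selected genes
#' exceed the Z > 2 outlier threshold.
#'
#' @param n_seeds Seeds per selected fraction (default 20).
#' @param selected_fractions Fractions of the interacting n-mt genes placed
#'   under selection (default `c(0.07, 0.25, 0.5)`).
#' @param s,h Selection coefficient and dominance of the incompatibility
#'   (defaults 1 and 0: recessive lethality of mismatched homozygotes).
#' @param n_interacting,n_noninteracting,n_non Gene-class counts of the
#'   study gene map (defaults 30/120/450).
#' @param n_individuals Census size (default 281).
#' @param n_aims_per_chrom Nuclear AIMs per chromosome (default 1000, two
#'   chromosomes).
#' @param seed Study seed.
#' @return A `data.frame` with one row per (fraction, seed): `fraction`,
#'   `seed`, `n_selected`, `segregating`, `p_anova`, `n_flagged` (selected
#'   genes with Z > 2), `n_scored` (selected genes present in the per-gene
#'   table).
#' @export
study_sensitivity <- function(n_seeds = 20,
                              selected_fractions = c(0.07, 0.25, 0.5),
                              s = 1, h = 0,
                              n_interacting = 30, n_noninteracting = 120,
                              n_non = 450,
                              n_individuals = 281, n_aims_per_chrom = 1000,
                              seed = 1L) {
  gm <- list(n_interacting = n_interacting,
             n_noninteracting = n_noninteracting, n_non = n_non)
  rows <- list()
  for (fi in seq_along(selected_fractions)) {
    frac <- selected_fractions[fi]
    n_sel <- max(1L, floor(frac * n_interacting + 0.5))
    seeds <- replicate_seeds(sub_seed(seed, 1000L + fi), n_seeds)
    for (i in seq_len(n_seeds)) {
      base <- list(n_individuals = n_individuals, n_generations = 46,
                   admixture_prop = 0.522, mito_init_freq = 0.637,
                   chromosomes = c(chr1 = 1, chr2 = 1),
                   n_aims_per_chrom = n_aims_per_chrom,
                   gene_map = gm, seed = seeds[i])
      genes <- build_gene_map(do.call(sim_config, base))
      inter <- genes$gene_id[genes$gene_class == "interacting_nmt"]
      sel <- inter[round(seq(1, length(inter), length.out = n_sel))]
      il <- rbind(
        data.frame(gene_id = sel, s = s, h = h, matched = "major"),
        data.frame(gene_id = sel, s = s, h = h, matched = "minor"))
      cfg <- do.call(sim_config, c(base, list(incompat_loci = il)))
      ds <- simulate_dataset(cfg)
      res <- analyze_dataset(ds$posteriors, ds$sites, ds$genes,
                             statistic = "Dprime")
      p <- NA_real_
      n_flag <- NA_integer_
      n_scored <- NA_integer_
      if (!is.null(res$gene_stats)) {
        p <- tryCatch(one_way_anova(res$gene_stats)$p,
                      error = function(e) NA_real_)
        z <- zscore_outliers(res$gene_stats, focal_genes = sel)
        n_flag <- sum(z$is_focal & z$is_outlier)
        n_scored <- sum(z$is_focal)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = frac, seed = seeds[i], n_selected = n_sel,
        segregating = res$mito_segregating, p_anova = p,
        n_flagged = n_flag, n_scored = n_scored)
    }
  }
  do.call(rbind, rows)
}

#' Selection response in a population fixed for one mitochondrial haplotype
#'
#' HUEX-STAC-like regime: the founding mothers all carry the major-parent
#' mitogenome (`mito_init_freq = 1`), so mitonuclear LD is undefined and the
#' analysis compares per-gene major-parent (matched) allele frequencies
#' across gene classes instead. Every interacting n-mt gene carries a weak
#' incompatibility with the fixed mitogenome (`matched = "major"`): the
#' polygenic regime the class-level test is designed to detect. Weak
#' per-locus selection is essential at this genome scale — strong selection
#' at many loci both collapses the effective population size through
#' viability load and sweeps whole chromosomes, dragging the non-n-mt
#' background to fixation and erasing the class contrast (see the methods
#' vignette). Each selected run is paired with a neutral run of identical
#' demography for comparison of the permutation test.
#'
#' @param n_seeds Number of paired (selected, neutral) replicates
#'   (default 20).
#' @param s,h Selection coefficient and dominance at every interacting gene
#'   (defaults 0.12 and 0.5).
#' @param n_generations Generations since admixture (default 263).
#' @param n_individuals Census size (default 100).
#' @param n_chrom Chromosomes of 1 Morgan (default 6; a larger genome keeps
#'   hitchhiking around selected loci local).
#' @param n_aims_per_chrom Nuclear AIMs per chromosome (default 250).
#' @param n_perm Permutations for the class test (default 999).
#' @param seed Study seed.
#' @return A `data.frame`, one row per seed: class means
#'   (`mean_interacting`, `mean_non`) and permutation p-values for the
#'   selected (`p_sel`) and neutral (`p_neut`) runs.
#' @export
study_fixed_mito <- function(n_seeds = 20, s = 0.12, h = 0.5,
                             n_generations = 263, n_individuals = 100,
                             n_chrom = 6, n_aims_per_chrom = 250,
                             n_perm = 999, seed = 1L) {
  gm <- list(n_interacting = 15, n_noninteracting = 60, n_non = 225)
  chroms <- stats::setNames(rep(1, n_chrom), paste0("chr", seq_len(n_chrom)))
  seeds <- replicate_seeds(sub_seed(seed, 2000L), n_seeds)
  rows <- lapply(seq_len(n_seeds), function(i) {
    base <- list(n_individuals = n_individuals,
                 n_generations = n_generations,
                 admixture_prop = 0.846, mito_init_freq = 1.0,
                 chromosomes = chroms,
                 n_aims_per_chrom = n_aims_per_chrom,
                 gene_map = gm, seed = seeds[i])
    genes <- build_gene_map(do.call(sim_config, base))
    inter <- genes$gene_id[genes$gene_class == "interacting_nmt"]
    il <- data.frame(gene_id = inter, s = s, h = h, matched = "major")
    one_run <- function(cfg) {
      ds <- simulate_dataset(cfg)
      res <- analyze_dataset(ds$posteriors, ds$sites, ds$genes,
                             statistic = "allele_freq")
      gs <- res$gene_stats
      list(
        mean_interacting =
          mean(gs$value[gs$gene_class == "interacting_nmt"]),
        mean_non = mean(gs$value[gs$gene_class == "non_nmt"]),
        p = permutation_class_test(gs, n_perm = n_perm,
                                   seed = sub_seed(seeds[i], 5L))$p_perm)
    }
    sel <- one_run(do.call(sim_config, c(base, list(incompat_loci = il))))
    neut <- one_run(do.call(sim_config, base))
    data.frame(seed = seeds[i],
               mean_interacting = sel$mean_interacting,
               mean_non = sel$mean_non,
               p_sel = sel$p,
               mean_interacting_neut = neut$mean_interacting,
               mean_non_neut = neut$mean_non,
               p_neut = neut$p)
  })
  do.call(rbind, rows)
}
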