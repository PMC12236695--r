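# Forward simulator: gene-map construction, tract bookkeeping, neutral
# calibration, maternal mito inheritance, selection response, and the
# posterior emission model.

test_that("gene maps preserve requested class counts and scale like the presets", {
  cfg <- tiny_sim_config(gene_map = list(n_interacting = 2,
                                         n_noninteracting = 3, n_non = 5))
  genes <- build_gene_map(cfg)
  expect_equal(nrow(genes), 10L)
  expect_equal(unname(table(factor(genes$gene_class,
                                   c("interacting_nmt", "noninteracting_nmt",
                                     "non_nmt")))),
               c(2L, 3L, 5L), ignore_attr = TRUE)
  expect_true(all(genes$start <= genes$end))
  # non-overlap within chromosome
  for (chr in unique(genes$chrom)) {
    g <- genes[genes$chrom == chr, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }

  # genome-wide counts 148 : 883 : 19312 scaled 1:100 with round-half-up and
  # the non-n-mt class absorbing the remainder
  cfg2 <- sim_preset("CALL", scale = 0.01)
  gm <- cfg2$gene_map
  expect_equal(c(gm$n_interacting, gm$n_noninteracting, gm$n_non),
               c(1L, 9L, 193L))

  too_many <- tiny_sim_config(
    chromosomes = c(chr1 = 1e-6),
    gene_map = list(n_interacting = 0, n_noninteracting = 0, n_non = 500))
  expect_error(build_gene_map(too_many), "exceed available chromosome span")
})

test_that("full clustering places all interacting genes consecutively", {
  cfg <- tiny_sim_config(
    chromosomes = c(chr1 = 1, chr2 = 1), n_individuals = 10,
    gene_map = list(n_interacting = 6, n_noninteracting = 10, n_non = 24,
                    cluster_fraction = 1.0))
  genes <- build_gene_map(cfg)
  inter <- genes[genes$gene_class == "interacting_nmt", ]
  expect_equal(length(unique(inter$chrom)), 1L)
  g <- genes[genes$chrom == inter$chrom[1], ]
  g <- g[order(g$start), ]
  idx <- which(g$gene_class == "interacting_nmt")
  expect_equal(idx, seq(min(idx), length.out = 6L))
})

test_that("ancestry tracts tile each chromosome exactly", {
  cfg <- tiny_sim_config(n_individuals = 30, n_generations = 15,
                         chromosomes = c(chr1 = 0.8, chr2 = 1.7))
  sim <- simulate_population(cfg)
  for (ind in sim$population$individuals)
    for (ci in seq_along(cfg$chromosomes))
      for (hap in ind$chroms[[ci]]) {
        expect_lt(abs(hap$ends[length(hap$ends)] -
                        unname(cfg$chromosomes[ci])), 1e-9)
        expect_true(all(diff(hap$ends) > 0))
        expect_equal(length(hap$ends), length(hap$anc))
        if (length(hap$anc) > 1)
          expect_true(all(diff(hap$anc) != 0))  # adjacent tracts merged
      }
})

test_that("generation zero is pure parental and mito follows the mother pool", {
  cfg <- tiny_sim_config(n_generations = 0, n_individuals = 50)
  sim <- simulate_population(cfg)
  expect_true(all(sim$truth$dosage %in% c(0, 1)))

  cfg_fixed <- tiny_sim_config(mito_init_freq = 1, admixture_prop = 0.5,
                               n_generations = 10)
  sim_fixed <- simulate_population(cfg_fixed)
  expect_equal(sim_fixed$truth$mito_freq, 1)
})

test_that("neutral simulations estimate the admixture proportion without bias", {
  means <- vapply(1:20, function(seed) {
    cfg <- tiny_sim_config(n_individuals = 100, n_generations = 20,
                           n_aims_per_chrom = 40, seed = seed)
    simulate_population(cfg)$truth$mean_ancestry
  }, 0)
  mc_se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.5), 3 * mc_se)
})

test_that("viability selection raises the matched allele frequency at the locus", {
  wins <- vapply(1:20, function(seed) {
    cfg0 <- tiny_sim_config(n_individuals = 100, n_generations = 50,
                            mito_init_freq = 1, n_aims_per_chrom = 60,
                            seed = seed)
    genes <- build_gene_map(cfg0)
    target <- genes$gene_id[genes$gene_class == "interacting_nmt"][1]
    cfg <- tiny_sim_config(n_individuals = 100, n_generations = 50,
                           mito_init_freq = 1, n_aims_per_chrom = 60,
                           seed = seed,
                           incompat_loci = data.frame(
                             gene_id = target, s = 0.5, h = 0.5,
                             matched = "major"))
    ds <- simulate_dataset(cfg)
    mapping <- map_aims_to_genes(ds$sites, ds$genes)
    truth_nuc <- ds$truth$dosage
    per_aim <- rowMeans(truth_nuc)
    sel_freq <- mean(per_aim[mapping[[target]]])
    genome_freq <- mean(per_aim[ds$sites$compartment == "nuclear"])
    sel_freq > genome_freq
  }, NA)
  expect_gte(sum(wins), 18)
})

test_that("extreme selection against every genotype extinguishes the population", {
  cfg <- suppressWarnings(tiny_sim_config(
    n_individuals = 20, n_generations = 3,
    admixture_prop = 0, mito_init_freq = 1,
    incompat_loci = data.frame(gene_id = "gene_00001", s = 1, h = 1,
                               matched = "major")))
  expect_error(suppressWarnings(simulate_population(cfg)),
               "extinction at generation 1")
})

test_that("posterior emission is exact in the noiseless limit and seeded", {
  cfg <- tiny_sim_config(posterior_noise_kappa = Inf, lowconf_fraction = 0)
  ds <- simulate_dataset(cfg)
  expect_identical(ds$posteriors, ds$truth$dosage)

  cfg_lc <- tiny_sim_config(posterior_noise_kappa = Inf, lowconf_fraction = 1)
  ds_lc <- simulate_dataset(cfg_lc)
  filtered <- filter_posteriors(ds_lc$posteriors)
  expect_true(all(is.na(filtered)))

  cfg_noise <- tiny_sim_config(posterior_noise_kappa = 30,
                               lowconf_fraction = 0.05, seed = 9L)
  ds1 <- simulate_dataset(cfg_noise)
  ds2 <- simulate_dataset(cfg_noise)
  expect_identical(ds1$posteriors, ds2$posteriors)
  expect_identical(ds1$truth$dosage, ds2$truth$dosage)
  expect_false(identical(ds1$posteriors, ds1$truth$dosage))
  expect_true(all(ds1$posteriors >= 0 & ds1$posteriors <= 1))
})

test_that("a fixed seed makes the whole dataset byte-identical on disk", {
  cfg <- tiny_sim_config(posterior_noise_kappa = 40, lowconf_fraction = 0.1,
                         seed = 5L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_sim_dataset(simulate_dataset(cfg), d1)
  write_sim_dataset(simulate_dataset(cfg), d2)
  for (f in c("posteriors.tsv", "gene_map.tsv", "truth.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(tiny_sim_config(n_individuals = 1), "at least 2")
  expect_error(tiny_sim_config(admixture_prop = 1.2), "fraction")
  expect_error(tiny_sim_config(chromosomes = c(chr1 = -1)), "positive")
  expect_error(tiny_sim_config(posterior_noise_kappa = 0), "positive")
  expect_error(tiny_sim_config(
    incompat_loci = data.frame(gene_id = "g", s = 2, h = 0, matched = "major")),
    "s and dominance")
  expect_error(simulate_population(tiny_sim_config(
    incompat_loci = data.frame(gene_id = "nope", s = 0.1, h = 0,
                               matched = "major"))),
    "unknown genes")
})

test_that("preset parameters reproduce the published population summaries", {
  tab <- population_presets()
  call <- sim_preset("CALL")
  expect_equal(call$admixture_prop, 0.522)
  expect_equal(call$n_generations, 46L)
  expect_equal(call$mito_init_freq, 0.637)
  expect_equal(call$n_individuals, 281L)
  huex <- sim_preset("HUEX-STAC")
  expect_equal(huex$n_generations, 263L)
  expect_equal(huex$mito_init_freq, 1.0)
  expect_equal(tab$n_interacting[tab$preset == "CHAF"], 148L)
})
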