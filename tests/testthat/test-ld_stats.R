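# Mito haplotype calling, frequency estimation, the D / D' / r2 machinery,
# per-gene aggregation and Z-score outliers.

test_that("mito haplotype calls threshold posteriors at the confidence bounds", {
  sites <- aim_sites(c("chr1", "mito"), c(1L, 45L), c("nuclear", "mito"))
  m <- rbind(c(0.5, 0.5, 0.5), c(0.95, 0.03, 0.5))
  colnames(m) <- c("a", "b", "c")
  expect_equal(unname(call_mito_haplotype(m, sites)),
               c("major", "minor", NA))
  m_fixed <- rbind(c(0.5, 0.5, 0.5), c(1, 1, 1))
  expect_true(all(call_mito_haplotype(m_fixed, sites) == "major"))
  # selector and compartment validation
  expect_error(call_mito_haplotype(m, sites, mito_site = "chr9:1"), "not found")
  expect_error(call_mito_haplotype(m, sites, mito_site = "chr1:1"),
               "not a mitochondrial AIM")
  nuc_only <- aim_sites("chr1", 1L, "nuclear")
  expect_error(call_mito_haplotype(m[1, , drop = FALSE], nuc_only),
               "exactly one mitochondrial AIM")
})

test_that("allele frequency is the mean posterior dosage over non-missing fish", {
  expect_equal(allele_freq(c(1.0, 0.5, 0.0, 0.5)), 0.5)
  expect_equal(allele_freq(c(1.0, 1.0)), 1.0)
  expect_equal(allele_freq(c(0.9, NA, 0.1)), 0.5)
  expect_true(is.na(allele_freq(c(NA_real_, NA_real_))))
})

test_that("joint frequencies are pairwise-complete and marginal-consistent", {
  f <- joint_freq(c(1, 1, 0, 0), c("major", "major", "minor", "minor"))
  expect_equal(f[c("pA", "pB", "pAB")], list(pA = 0.5, pB = 0.5, pAB = 0.5))
  f2 <- joint_freq(c(1, 0), c("major", "major"))
  expect_equal(f2[c("pA", "pB", "pAB")], list(pA = 0.5, pB = 1.0, pAB = 0.5))
  f3 <- joint_freq(c(1, NA), c("major", "major"))
  expect_true(is.na(f3$pA) && f3$n == 1L)

  # independence oracle: dosages drawn independently of mito, pAB ~ pA * pB
  set.seed(11)
  n <- 1e4
  d <- runif(n)
  calls <- ifelse(rbinom(n, 1, 0.4) == 1, "major", "minor")
  f4 <- joint_freq(d, calls)
  se <- sd(d * (calls == "major")) / sqrt(n)
  expect_lt(abs(f4$pAB - f4$pA * f4$pB), 3 * se)
})

test_that("D, D' and r2 match the haplotype-counting oracle on worked cases", {
  # 100 haplotypes: 50 AB, 10 Ab, 20 aB, 20 ab
  o1 <- counting_ld(50, 10, 20, 20)
  got1 <- ld_from_freqs(o1$pA, o1$pB, o1$pAB)
  expect_equal(got1$D, 0.08)
  expect_equal(got1$Dmax, 0.18)
  expect_equal(got1$Dprime, o1$Dprime, tolerance = 1e-12)
  expect_equal(got1$Dprime, 0.4444444, tolerance = 1e-6)
  expect_equal(got1$r2, 0.126984, tolerance = 1e-5)

  # 35 AB, 25 Ab, 35 aB, 5 ab: repulsion
  o2 <- counting_ld(35, 25, 35, 5)
  got2 <- ld_from_freqs(o2$pA, o2$pB, o2$pAB)
  expect_equal(got2$D, -0.07)
  expect_equal(got2$Dmax, 0.12)
  expect_equal(got2$Dprime, -0.5833333, tolerance = 1e-6)
  expect_equal(got2$r2, 0.0972222, tolerance = 1e-6)

  # independence and complete coupling
  expect_equal(ld_from_freqs(0.5, 0.5, 0.25)[, c("D", "Dprime", "r2")],
               data.frame(D = 0, Dprime = 0, r2 = 0))
  expect_equal(ld_from_freqs(0.5, 0.5, 0.5)[, c("D", "Dprime", "r2")],
               data.frame(D = 0.25, Dprime = 1, r2 = 1))

  # monomorphic marginals give missing, not zero
  expect_true(all(is.na(ld_from_freqs(1, 0.5, 0.5)[, c("Dprime", "r2")])))
  expect_error(ld_from_freqs(0.2, 0.2, 0.9), "invalid")
})

test_that("posterior-based LD equals haplotype counting on hard populations", {
  set.seed(21)
  for (rep in 1:200) {
    pop <- random_hard_population(n = sample(10:50, 1))
    counts <- hard_population_counts(pop)
    oracle <- do.call(counting_ld, as.list(unname(counts)))
    f <- joint_freq((pop$a1 + pop$a2) / 2,
                    ifelse(pop$mito == 1, "major", "minor"))
    got <- ld_from_freqs(f$pA, f$pB, f$pAB)
    expect_equal(f$pA, oracle$pA, tolerance = 1e-12)
    expect_equal(f$pAB, oracle$pAB, tolerance = 1e-12)
    expect_equal(got$D, oracle$D, tolerance = 1e-12)
    expect_equal(got$Dprime, oracle$Dprime, tolerance = 1e-12)
    expect_equal(got$r2, oracle$r2, tolerance = 1e-12)
  }
})

test_that("LD invariants hold and relabeling flips the sign of D and D'", {
  set.seed(31)
  n <- 1e4
  pA <- runif(n)
  pB <- runif(n)
  lo <- pmax(0, pA + pB - 1)
  hi <- pmin(pA, pB)
  pAB <- lo + runif(n) * (hi - lo)
  ld <- ld_from_freqs(pA, pB, pAB)
  ok <- !is.na(ld$Dprime)
  expect_true(all(abs(ld$D[ok]) <= ld$Dmax[ok] + 1e-12))
  expect_true(all(abs(ld$Dprime[ok]) <= 1 + 1e-9))
  expect_true(all(ld$r2[ok] >= 0 & ld$r2[ok] <= 1 + 1e-9))
  expect_true(all(ld$r2[ok] <= ld$Dprime[ok]^2 + 1e-12))
  expect_true(all(sign(ld$Dprime[ok]) == sign(ld$D[ok])))

  flipped <- ld_from_freqs(1 - pA, pB, pB - pAB)
  expect_equal(flipped$D[ok], -ld$D[ok], tolerance = 1e-12)
  expect_equal(flipped$Dprime[ok], -ld$Dprime[ok], tolerance = 1e-12)
  expect_equal(flipped$r2[ok], ld$r2[ok], tolerance = 1e-12)
})

test_that("the genome scan couples to the mito indicator and guards degeneracy", {
  sites <- aim_sites(c(rep("chr1", 3), "mito"), c(1L, 2L, 3L, 45L),
                     c(rep("nuclear", 3), "mito"))
  ind <- c(1, 1, 0, 0, 1, 0)
  m <- rbind(ind, ind, ind, ind)  # nuclear AIMs identical to mito indicator
  colnames(m) <- paste0("f", 1:6)
  calls <- call_mito_haplotype(m, sites)
  sc <- scan_mitonuclear_ld(m, sites, calls)
  expect_equal(nrow(sc), 3L)  # mito AIM excluded
  expect_true(all(sc$Dprime == 1))
  expect_true(all(sc$r2 == 1))

  all_minor <- m
  all_minor[4, ] <- 0
  sc2 <- scan_mitonuclear_ld(all_minor, sites,
                             call_mito_haplotype(all_minor, sites))
  expect_true(all(is.na(sc2$Dprime)))  # pB = 0 everywhere

  mito_only <- sites[4, , drop = FALSE]
  expect_error(scan_mitonuclear_ld(m[4, , drop = FALSE], mito_only,
                                   calls), "no nuclear AIMs")
})

test_that("hard-call mode reproduces dosage results on already-hard data", {
  sites <- aim_sites(c("chr1", "chr1", "mito"), c(1L, 2L, 45L),
                     c("nuclear", "nuclear", "mito"))
  m <- rbind(c(1, 0, 1, 0), c(0, 0, 1, 1), c(1, 1, 0, 0))
  colnames(m) <- paste0("f", 1:4)
  calls <- call_mito_haplotype(m, sites)
  soft <- scan_mitonuclear_ld(m, sites, calls)
  hard <- scan_mitonuclear_ld(m, sites, calls, hard_calls = TRUE)
  expect_equal(soft, hard)
})

test_that("admixture LD is positive early and decays with generations", {
  mean_dprime <- function(gens, seed) {
    cfg <- tiny_sim_config(n_individuals = 100, n_generations = gens,
                           n_aims_per_chrom = 100,
                           posterior_noise_kappa = Inf, seed = seed)
    rep <- scan_replicate(cfg)
    if (is.null(rep)) NA_real_ else mean(rep$per_aim$Dprime, na.rm = TRUE)
  }
  early <- vapply(1:10, function(s) mean_dprime(2, s), 0)
  late <- vapply(1:10, function(s) mean_dprime(12, s + 100), 0)
  expect_gt(mean(early, na.rm = TRUE), 0)
  expect_gt(mean(early, na.rm = TRUE), mean(late, na.rm = TRUE))
})

test_that("per-gene aggregation averages non-missing AIMs and drops empty genes", {
  genes <- gene_annotation(c("g1", "g2", "g3"), rep("chr1", 3),
                           c(1L, 10L, 20L), c(5L, 15L, 25L),
                           c("interacting_nmt", "non_nmt", "non_nmt"))
  mapping <- list(g1 = c(1L, 2L), g2 = c(3L, 4L), g3 = 5L)
  values <- c(0.2, 0.4, 0.2, NA, NA)
  gs <- aggregate_per_gene(values, mapping, genes, "Dprime")
  expect_equal(gs$value[gs$gene_id == "g1"], 0.3)
  expect_equal(gs$value[gs$gene_id == "g2"], 0.2)
  expect_equal(gs$n_aims[gs$gene_id == "g2"], 1L)
  expect_false("g3" %in% gs$gene_id)  # all-missing gene dropped

  # invariant to AIM order and duplication of a missing AIM
  mapping2 <- list(g1 = c(2L, 1L), g2 = c(4L, 3L, 4L), g3 = 5L)
  expect_equal(aggregate_per_gene(values, mapping2, genes, "Dprime")$value,
               gs$value)
})

test_that("Z-score outliers use the n-1 sd and a strict one-sided threshold", {
  # nine values with mean 10 and sample sd exactly 2: the focal value 14
  # sits exactly at Z = 2 and must NOT be flagged (strict >)
  gs <- data.frame(gene_id = sprintf("g%02d", 1:9),
                   gene_class = "non_nmt",
                   value = c(rep(10, 7), 14, 6))
  expect_equal(mean(gs$value), 10)
  expect_equal(sd(gs$value), 2)
  z <- zscore_outliers(gs)
  expect_equal(z$zscore[z$gene_id == "g08"], 2)
  expect_false(z$is_outlier[z$gene_id == "g08"])
  expect_equal(z$zscore[z$gene_id == "g01"], 0)
  expect_true(z$is_outlier[z$gene_id == "g08"] == FALSE &&
                sum(z$is_outlier) == 0)
  expect_error(zscore_outliers(data.frame(gene_id = c("a", "b"),
                                          gene_class = "non_nmt",
                                          value = c(1, 1))),
               "degenerate")
})

test_that("simulated shifted genes are recovered as Z outliers", {
  hits <- vapply(1:20, function(seed) {
    set.seed(seed)
    gs <- data.frame(
      gene_id = sprintf("g%04d", 1:1005),
      gene_class = c(rep("non_nmt", 1000), rep("interacting_nmt", 5)),
      value = c(rnorm(1000), rnorm(5, mean = 4))
    )
    z <- zscore_outliers(gs, focal_genes = sprintf("g%04d", 1001:1005))
    sum(z$is_focal & z$is_outlier)
  }, 0L)
  expect_gte(sum(hits >= 4), 18)
})

test_that("per-gene allele frequencies average AIM frequencies within genes", {
  sites <- aim_sites(c("chr1", "chr1", "mito"), c(1L, 2L, 45L),
                     c("nuclear", "nuclear", "mito"))
  genes <- gene_annotation("g1", "chr1", 1L, 2L, "interacting_nmt")
  m <- rbind(c(0.8, 0.8), c(0.9, 0.9), c(1, 1))
  colnames(m) <- c("f1", "f2")
  mapping <- map_aims_to_genes(sites, genes)
  gs <- allele_freq_per_gene(m, sites, mapping, genes)
  expect_equal(gs$value, 0.85)
  expect_equal(gs$statistic, "allele_freq")

  all_one <- m
  all_one[1:2, ] <- 1
  expect_equal(allele_freq_per_gene(all_one, sites, mapping, genes)$value, 1)
})
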