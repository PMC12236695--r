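# Independent oracles and small fixtures used across the suite. These are
# deliberately naive (counting, enumeration, sums of squares) and share no
# code with the package implementation they check.

# Brute-force LD from a 2x2 table of haplotype counts (AB, Ab, aB, ab).
counting_ld <- function(n_AB, n_Ab, n_aB, n_ab) {
  n <- n_AB + n_Ab + n_aB + n_ab
  pA <- (n_AB + n_Ab) / n
  pB <- (n_AB + n_aB) / n
  pAB <- n_AB / n
  D <- pAB - pA * pB
  Dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  Dprime <- if (D == 0) 0 else D / Dmax
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  list(pA = pA, pB = pB, pAB = pAB, D = D, Dmax = Dmax,
       Dprime = Dprime, r2 = r2)
}

# Random diploid population with hard allele calls and known mito haplotypes.
random_hard_population <- function(n = 30) {
  repeat {
    a1 <- rbinom(n, 1, runif(1, 0.2, 0.8))
    a2 <- rbinom(n, 1, runif(1, 0.2, 0.8))
    mito <- rbinom(n, 1, runif(1, 0.2, 0.8))
    # require polymorphic marginals so LD is defined
    if (length(unique(c(a1, a2))) == 2 && length(unique(mito)) == 2) break
  }
  list(a1 = a1, a2 = a2, mito = mito)
}

# Haplotype counts for the 2n allele copies of a hard population (each allele
# copy pairs with the individual's mito haplotype).
hard_population_counts <- function(pop) {
  alleles <- c(pop$a1, pop$a2)
  mito <- rep(pop$mito, 2)
  c(n_AB = sum(alleles == 1 & mito == 1),
    n_Ab = sum(alleles == 1 & mito == 0),
    n_aB = sum(alleles == 0 & mito == 1),
    n_ab = sum(alleles == 0 & mito == 0))
}

# From-scratch one-way ANOVA F via the sums-of-squares decomposition.
ss_anova_F <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  k <- length(unique(groups))
  N <- length(values)
  (ssb / (k - 1)) / (ssw / (N - k))
}

# Exact permutation tail probability by full enumeration (small n only):
# P(T_perm >= T_obs) for T = mean(group X) - mean(group Y).
exhaustive_perm_tail <- function(values, is_x, is_y, two_sided = FALSE) {
  n <- length(values)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  score <- if (two_sided) abs else identity
  t_obs <- mean(values[is_x]) - mean(values[is_y])
  ts <- vapply(perms(values), function(p) mean(p[is_x]) - mean(p[is_y]), 0)
  mean(score(ts) >= score(t_obs) - 1e-12 * max(1, abs(t_obs)))
}

# Exact upper-tail hypergeometric by combinatorial summation.
hyper_tail <- function(k, K, N, n_draw) {
  j <- k:min(K, n_draw)
  sum(exp(lchoose(K, j) + lchoose(N - K, n_draw - j) - lchoose(N, n_draw)))
}

# Small, fast simulation configuration for unit tests.
tiny_sim_config <- function(...) {
  args <- utils::modifyList(list(
    n_individuals = 40, n_generations = 5,
    admixture_prop = 0.5, mito_init_freq = 0.5,
    chromosomes = c(chr1 = 1), n_aims_per_chrom = 50,
    gene_map = list(n_interacting = 2, n_noninteracting = 3, n_non = 5),
    posterior_noise_kappa = Inf, lowconf_fraction = 0, seed = 1L
  ), list(...))
  do.call(sim_config, args)
}

# One complete simulate-and-scan replicate; returns NULL when the requested
# LD statistic is undefined (mito haplotype effectively fixed).
scan_replicate <- function(cfg, statistic = "Dprime", min_calls = 2) {
  ds <- simulate_dataset(cfg)
  res <- analyze_dataset(ds$posteriors, ds$sites, ds$genes,
                         statistic = statistic,
                         min_haplotype_calls = min_calls)
  if (is.null(res$gene_stats)) return(NULL)
  c(res, list(truth = ds$truth, genes = ds$genes))
}
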