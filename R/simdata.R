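## Forward-in-time simulator of admixed diploid populations with maternal
## mitochondrial inheritance and viability selection against mismatched
## mitonuclear genotypes. Emits AIM posterior matrices plus ground truth so
## the whole downstream analysis is testable without external data.
##
## Haplotypes are ancestry-tract lists on a genetic map (Morgans); a fixed
## linear map (1 Morgan = 25 Mb) converts to the physical coordinates used in
## output files. Ancestry labels: 1 = major parent, 0 = minor parent.

#' Simulation configuration
#'
#' Bundles and validates all parameters of the hybrid-population simulator.
#'
#' @param n_individuals Census population size (constant across generations),
#'   at least 2.
#' @param n_generations Generations simulated after the founding admixture
#'   event (0 = founders only).
#' @param admixture_prop Fraction of founding genomes drawn from the major
#'   parent species, in `[0, 1]`.
#' @param mito_init_freq Fraction of founding mothers carrying the
#'   major-parent mitogenome, in `[0, 1]`; `1.0` gives a population fixed for
#'   the major-parent haplotype. Founders are pure parentals with matching
#'   mitogenome, so the founding male major fraction is set to
#'   `2 * admixture_prop - mito_init_freq` (clamped to `[0, 1]` with a
#'   warning) to keep the genome-wide founding proportion at
#'   `admixture_prop`.
#' @param chromosomes Named numeric vector of chromosome genetic lengths in
#'   Morgans (names are chromosome ids), all positive.
#' @param n_aims_per_chrom Number of nuclear AIMs per chromosome, evenly
#'   spaced along the genetic map.
#' @param gene_map List with integer counts `n_interacting`,
#'   `n_noninteracting`, `n_non` of genes per class, and optional
#'   `cluster_fraction` (fraction of interacting n-mt genes placed in
#'   consecutive intervals on one chromosome, default 0) and
#'   `gene_width_frac` (fraction of each gene slot covered by the gene
#'   interval, default 0.6).
#' @param incompat_loci `data.frame` (or NULL) with columns `gene_id`, `s`
#'   (selection coefficient in `[0, 1]`), `h` (dominance in `[0, 1]`) and
#'   `matched` (`"major"` or `"minor"`): which parent's mitogenome this
#'   nuclear gene is coadapted with. Individuals carrying that mitogenome
#'   survive with probability `1 - s * g(d)` per locus, where `d` is the
#'   fraction of their two alleles at the locus not derived from the matched
#'   parent and `g(0) = 0`, `g(1/2) = h`, `g(1) = 1`. Listing a gene once per
#'   parent makes the incompatibility symmetric.
#' @param posterior_noise_kappa Concentration of posterior emission noise
#'   (> 0); `Inf` emits true dosages exactly.
#' @param lowconf_fraction Fraction of emitted posteriors resampled uniformly
#'   from (0.2, 0.8), emulating low-confidence calls that the standard
#'   confidence filter removes.
#' @param seed Integer seed; a fixed seed makes every simulator output
#'   byte-identical across runs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 100,
                       n_generations = 46,
                       admixture_prop = 0.5,
                       mito_init_freq = 0.5,
                       chromosomes = c(chr1 = 1, chr2 = 1),
                       n_aims_per_chrom = 500,
                       gene_map = list(n_interacting = 2,
                                       n_noninteracting = 9,
                                       n_non = 189),
                       incompat_loci = NULL,
                       posterior_noise_kappa = 50,
                       lowconf_fraction = 0.02,
                       seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_generations = as.integer(n_generations),
    admixture_prop = admixture_prop,
    mito_init_freq = mito_init_freq,
    chromosomes = chromosomes,
    n_aims_per_chrom = as.integer(n_aims_per_chrom),
    gene_map = utils::modifyList(
      list(cluster_fraction = 0, gene_width_frac = 0.6), gene_map),
    incompat_loci = incompat_loci,
    posterior_noise_kappa = posterior_noise_kappa,
    lowconf_fraction = lowconf_fraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  frac_in_01 <- function(x) is.numeric(x) && length(x) == 1 &&
    !is.na(x) && x >= 0 && x <= 1
  if (cfg$n_individuals < 2)
    stop("n_individuals must be at least 2", call. = FALSE)
  if (cfg$n_generations < 0)
    stop("n_generations must be non-negative", call. = FALSE)
  for (f in c("admixture_prop", "mito_init_freq", "lowconf_fraction"))
    if (!frac_in_01(cfg[[f]]))
      stop(f, " must be a fraction in [0, 1]", call. = FALSE)
  if (!frac_in_01(cfg$gene_map$cluster_fraction))
    stop("gene_map$cluster_fraction must be in [0, 1]", call. = FALSE)
  if (!is.numeric(cfg$chromosomes) || !length(cfg$chromosomes) ||
      any(cfg$chromosomes <= 0))
    stop("chromosomes must be a named vector of positive Morgan lengths",
         call. = FALSE)
  if (is.null(names(cfg$chromosomes)) || anyDuplicated(names(cfg$chromosomes)))
    stop("chromosome names must be present and unique", call. = FALSE)
  if (cfg$n_aims_per_chrom < 1)
    stop("n_aims_per_chrom must be at least 1", call. = FALSE)
  gm <- cfg$gene_map
  if (any(unlist(gm[c("n_interacting", "n_noninteracting", "n_non")]) < 0))
    stop("gene counts must be non-negative", call. = FALSE)
  if (!is.numeric(cfg$posterior_noise_kappa) || cfg$posterior_noise_kappa <= 0)
    stop("posterior_noise_kappa must be positive (possibly Inf)",
         call. = FALSE)
  if (!is.null(cfg$incompat_loci)) {
    il <- cfg$incompat_loci
    stopifnot(is.data.frame(il),
              all(c("gene_id", "s", "h", "matched") %in% names(il)))
    if (any(il$s < 0 | il$s > 1) || any(il$h < 0 | il$h > 1))
      stop("selection coefficients s and dominance h must lie in [0, 1]",
           call. = FALSE)
    if (!all(il$matched %in% c("major", "minor")))
      stop("incompat_loci$matched must be 'major' or 'minor'", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Hybrid-population simulation configuration\n")
  cat(sprintf("  individuals: %d   generations: %d   seed: %d\n",
              x$n_individuals, x$n_generations, x$seed))
  cat(sprintf("  admixture proportion: %.3f   founding mito freq: %.3f\n",
              x$admixture_prop, x$mito_init_freq))
  cat(sprintf("  chromosomes: %d (total %.2f Morgans), %d AIMs each\n",
              length(x$chromosomes), sum(x$chromosomes), x$n_aims_per_chrom))
  gm <- x$gene_map
  cat(sprintf("  genes: %d interacting / %d non-interacting / %d non-n-mt\n",
              gm$n_interacting, gm$n_noninteracting, gm$n_non))
  cat(sprintf("  selected loci: %d\n",
              if (is.null(x$incompat_loci)) 0L else nrow(x$incompat_loci)))
  invisible(x)
}

## Published per-population summaries used to parameterise the presets:
## founding admixture proportion, generations since admixture, major-parent
## mitochondrial haplotype frequency, census size, and genome-wide gene-class
## counts (interacting n-mt : non-interacting n-mt : non-n-mt).
POPULATION_PRESETS <- data.frame(
  preset = c("CALL", "CHAF", "HUEX-STAC"),
  admixture_prop = c(0.522, 0.682, 0.846),
  n_generations = c(46L, 46L, 263L),
  mito_init_freq = c(0.637, 0.936, 1.0),
  n_individuals = c(281L, 250L, 255L),
  n_interacting = c(148L, 148L, 162L),
  n_noninteracting = c(883L, 883L, 947L),
  n_non = c(19312L, 19307L, 20544L),
  stringsAsFactors = FALSE
)

#' Published hybrid-population summaries behind the presets
#'
#' Returns the per-population parameter table used by [sim_preset()]:
#' admixture proportion, generations since initial admixture, founding
#' major-parent mitochondrial frequency, census size and per-class gene
#' counts for the three Xiphophorus hybrid populations (CALL and CHAF on the
#' Calnali river, X. birchmanni x X. malinche; HUEX-STAC on the Santa Cruz
#' river, X. birchmanni x X. cortezi, fixed for the X. cortezi mitogenome).
#'
#' @return A `data.frame`, one row per population preset.
#' @export
population_presets <- function() POPULATION_PRESETS

## Round-half-up scaling of gene-class counts: the two n-mt classes round
## half-up, the non-n-mt count absorbs the remainder so that the scaled total
## equals round_half_up(total * scale).
scale_gene_counts <- function(counts, scale) {
  rhu <- function(x) floor(x + 0.5)
  stopifnot(length(counts) == 3, scale > 0)
  total <- rhu(sum(counts) * scale)
  k1 <- rhu(counts[1] * scale)
  k2 <- rhu(counts[2] * scale)
  k3 <- total - k1 - k2
  if (k3 < 0) stop("scale too small for gene counts", call. = FALSE)
  as.integer(c(k1, k2, k3))
}

#' Preset simulation scenarios modelled on the study populations
#'
#' Builds a [sim_config()] whose demographic parameters (admixture
#' proportion, generations since admixture, founding mitochondrial haplotype
#' frequency, census size) follow one of the three hybrid populations, with
#' gene-class counts scaled down from the genome-wide values by `scale`
#' (round half up for the two n-mt classes; the non-n-mt count absorbs the
#' rounding remainder so the scaled total is exact).
#'
#' `"HUEX-STAC"` reproduces the fixed-mitogenome regime
#' (`mito_init_freq = 1`); `"CALL"` and `"CHAF"` have segregating
#' mitochondrial haplotypes, so mitonuclear LD is computable.
#'
#' @param preset `"CALL"`, `"CHAF"` or `"HUEX-STAC"`.
#' @param scale Gene-count scaling factor (default 0.01, i.e. 1:100).
#' @param n_chrom Number of simulated chromosomes (1 Morgan each); the
#'   genome is down-scaled along with the gene counts.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()]
#'   (e.g. `n_individuals`, `n_aims_per_chrom`, `incompat_loci`).
#' @return A `sim_config`.
#' @export
sim_preset <- function(preset = c("CALL", "CHAF", "HUEX-STAC"),
                       scale = 0.01, n_chrom = 4, seed = 1L, ...) {
  preset <- match.arg(preset)
  row <- POPULATION_PRESETS[POPULATION_PRESETS$preset == preset, ]
  counts <- scale_gene_counts(
    c(row$n_interacting, row$n_noninteracting, row$n_non), scale)
  chroms <- rep(1, n_chrom)
  names(chroms) <- paste0("chr", seq_len(n_chrom))
  defaults <- list(
    n_individuals = row$n_individuals,
    n_generations = row$n_generations,
    admixture_prop = row$admixture_prop,
    mito_init_freq = row$mito_init_freq,
    chromosomes = chroms,
    gene_map = list(n_interacting = counts[1],
                    n_noninteracting = counts[2],
                    n_non = counts[3]),
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

#' Build a synthetic gene map
#'
#' Lays the configured number of genes of each class out as non-overlapping
#' 1-based inclusive intervals: gene slots are spread evenly over the
#' chromosomes in proportion to genetic length, each gene occupies the
#' central `gene_width_frac` of its slot, and class labels are assigned to
#' slots by a seeded random permutation. With `cluster_fraction > 0`, that
#' fraction of the interacting n-mt genes is instead placed in consecutive
#' slots on the chromosome with the most slots, emulating genomic regions
#' with a high density of n-mt genes.
#'
#' @param config A [sim_config()].
#' @return A gene annotation `data.frame` (see [gene_annotation()]).
#' @export
build_gene_map <- function(config) {
  validate_sim_config(config)
  gm <- config$gene_map
  counts <- c(gm$n_interacting, gm$n_noninteracting, gm$n_non)
  n_genes <- sum(counts)
  if (n_genes == 0)
    return(gene_annotation(character(), character(), integer(), integer(),
                           character()))
  lens <- config$chromosomes
  # apportion slots to chromosomes proportionally (largest remainder)
  raw <- n_genes * lens / sum(lens)
  slots <- floor(raw)
  rem <- n_genes - sum(slots)
  if (rem > 0) {
    extra <- order(raw - slots, decreasing = TRUE)[seq_len(rem)]
    slots[extra] <- slots[extra] + 1L
  }
  # gene intervals: central fraction of each equal-width slot, in bp
  slot_tab <- do.call(rbind, lapply(seq_along(lens), function(ci) {
    k <- slots[ci]
    if (k == 0) return(NULL)
    width <- lens[ci] / k
    lo <- (seq_len(k) - 1) * width + width * (1 - gm$gene_width_frac) / 2
    hi <- lo + width * gm$gene_width_frac
    data.frame(chrom = names(lens)[ci],
               start = morgan_to_bp(lo), end = morgan_to_bp(hi),
               stringsAsFactors = FALSE)
  }))
  overlaps <- any(vapply(split(slot_tab, slot_tab$chrom), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    nrow(g) > 1 && any(g$start[-1] <= g$end[-nrow(g)])
  }, NA))
  if (any(slot_tab$end <= slot_tab$start) || overlaps)
    stop("configuration error: requested genes exceed available chromosome ",
         "span (gene intervals would overlap or collapse below 1 bp)",
         call. = FALSE)
  classes <- with_seed(sub_seed(config$seed, 101L), {
    lab <- rep(NA_character_, n_genes)
    n_cl <- floor(gm$cluster_fraction * counts[1] + 0.5)
    slot_of_chrom <- rep(seq_along(lens), slots)
    if (n_cl > 1) {
      big <- which.max(slots)
      cand <- which(slot_of_chrom == big)
      if (length(cand) < n_cl)
        stop("cluster_fraction requires ", n_cl,
             " consecutive slots on one chromosome", call. = FALSE)
      start_at <- sample.int(length(cand) - n_cl + 1L, 1L)
      lab[cand[start_at + seq_len(n_cl) - 1L]] <- GENE_CLASSES[1]
    } else n_cl <- 0L
    pool <- c(rep(GENE_CLASSES[1], counts[1] - n_cl),
              rep(GENE_CLASSES[2], counts[2]),
              rep(GENE_CLASSES[3], counts[3]))
    lab[is.na(lab)] <- sample(pool)
    lab
  })
  gene_annotation(sprintf("gene_%05d", seq_len(n_genes)),
                  slot_tab$chrom, slot_tab$start, slot_tab$end, classes)
}

## --- core genetics -------------------------------------------------------

## A haplotype is list(ends = numeric, anc = integer): segment i covers the
## half-open genetic interval [ends[i-1], ends[i]) with ends[0] = 0 and the
## final end equal to the chromosome length; anc is 1 (major) or 0 (minor).

new_haplotype <- function(L, anc) list(ends = L, anc = as.integer(anc))

## Ancestry label at genetic positions x (vector), half-open segments.
hap_at <- function(hap, x) hap$anc[findInterval(x, hap$ends) + 1L]

## One meiosis on one chromosome: Poisson(L) crossovers at uniform positions,
## random starting haplotype, alternating after each crossover. The tract
## merge runs in compiled code (src/gamete.cpp); crossover draws come from
## the R RNG so the configured seed fixes the whole simulation.
meiosis <- function(h1, h2, L) {
  cpp_gamete(h1$ends, h1$anc, h2$ends, h2$anc, L)
}

## Fitness of one offspring given its per-locus diploid ancestry and mito.
## loci: data.frame with chrom_idx, pos_m, s, h, matched_anc (1/0), queried
## with one vectorised tract lookup per chromosome.
offspring_fitness <- function(chroms, mito, loci) {
  if (is.null(loci) || !nrow(loci)) return(1)
  active <- loci$matched_anc == mito
  if (!any(active)) return(1)
  w <- 1
  for (ci in unique(loci$chrom_idx[active])) {
    sel <- active & loci$chrom_idx == ci
    pos <- loci$pos_m[sel]
    pair <- chroms[[ci]]
    a1 <- hap_at(pair[[1L]], pos)
    a2 <- hap_at(pair[[2L]], pos)
    d <- ((a1 != mito) + (a2 != mito)) / 2
    g <- ifelse(d == 0, 0, ifelse(d == 1, 1, loci$h[sel]))
    w <- w * prod(1 - loci$s[sel] * g)
    if (w == 0) return(0)
  }
  w
}

#' AIM site table implied by a simulation configuration
#'
#' Nuclear AIMs are evenly spaced along each chromosome's genetic map and
#' reported in physical coordinates (1 Morgan = 25 Mb); one designated
#' mitochondrial AIM (`mito:45`) represents the non-recombining mitogenome.
#'
#' @param config A [sim_config()].
#' @return An AIM site table (see [aim_sites()]).
#' @export
sim_aim_sites <- function(config) {
  lens <- config$chromosomes
  k <- config$n_aims_per_chrom
  tab <- do.call(rbind, lapply(seq_along(lens), function(ci) {
    pos_m <- (seq_len(k) - 0.5) / k * lens[ci]
    data.frame(chrom = names(lens)[ci], pos = morgan_to_bp(pos_m),
               compartment = "nuclear", stringsAsFactors = FALSE)
  }))
  rbind(tab, data.frame(chrom = "mito", pos = 45L, compartment = "mito",
                        stringsAsFactors = FALSE))
}

#' Simulate a hybrid population forward in time
#'
#' Founders are pure parental individuals (major-parent genomes in proportion
#' `admixture_prop`, with the founding maternal major-mitogenome fraction
#' `mito_init_freq`; a founder's mitogenome matches its nuclear parent).
#' Each later generation is produced by random mating (mother sampled from
#' females, father from males, with replacement), recombination with
#' Poisson(chromosome length in Morgans) crossovers at uniform genetic
#' positions, strictly maternal mitochondrial transmission, and viability
#' selection: an offspring survives with probability
#' `prod(1 - s * g(d))` over the configured incompatibility loci (see
#' [sim_config()]). The census size is held constant by resampling surviving
#' offspring; sexes are assigned in equal numbers each generation.
#'
#' @param config A [sim_config()]; the seed makes the run reproducible.
#' @param genes Optional gene map from [build_gene_map()] (rebuilt from the
#'   config if omitted); needed to resolve `incompat_loci` gene ids.
#' @return A list with `population` (class `sim_population`: per-individual
#'   tract haplotypes, mito haplotype, sex) and `truth` (class `sim_truth`:
#'   true ancestry dosage matrix at every AIM, selected gene ids, realized
#'   mean nuclear ancestry and mito haplotype frequency).
#' @export
simulate_population <- function(config, genes = NULL) {
  validate_sim_config(config)
  if (is.null(genes)) genes <- build_gene_map(config)
  loci <- NULL
  if (!is.null(config$incompat_loci) && nrow(config$incompat_loci)) {
    il <- config$incompat_loci
    miss <- setdiff(il$gene_id, genes$gene_id)
    if (length(miss))
      stop("incompat_loci reference unknown genes: ",
           paste(miss, collapse = ", "), call. = FALSE)
    gi <- match(il$gene_id, genes$gene_id)
    loci <- data.frame(
      chrom_idx = match(genes$chrom[gi], names(config$chromosomes)),
      pos_m = bp_to_morgan((genes$start[gi] + genes$end[gi]) / 2),
      s = il$s, h = il$h,
      matched_anc = ifelse(il$matched == "major", 1L, 0L)
    )
  }
  n <- config$n_individuals
  lens <- config$chromosomes
  pop <- with_seed(config$seed, {
    sex <- rep(c("F", "M"), length.out = n)
    n_f <- sum(sex == "F")
    n_m <- n - n_f
    p_f <- config$mito_init_freq
    p_m <- (n * config$admixture_prop - n_f * p_f) / n_m
    if (p_m < 0 || p_m > 1) {
      warning("founding male major fraction clamped to [0, 1]; realized ",
              "admixture proportion will deviate from admixture_prop",
              call. = FALSE)
      p_m <- min(1, max(0, p_m))
    }
    parent <- integer(n)
    parent[sex == "F"] <- stats::rbinom(n_f, 1L, p_f)
    parent[sex == "M"] <- stats::rbinom(n_m, 1L, p_m)
    inds <- lapply(seq_len(n), function(i) {
      list(chroms = lapply(lens, function(L)
             list(new_haplotype(L, parent[i]), new_haplotype(L, parent[i]))),
           mito = parent[i], sex = sex[i])
    })
    for (gen in seq_len(config$n_generations)) {
      females <- which(vapply(inds, `[[`, "", "sex") == "F")
      males <- setdiff(seq_len(n), females)
      if (!length(females) || !length(males))
        stop("population extinction at generation ", gen,
             ": a sex died out", call. = FALSE)
      offspring <- vector("list", n)
      accepted <- 0L
      attempts <- 0L
      sex_next <- sample(rep(c("F", "M"), length.out = n))
      while (accepted < n) {
        attempts <- attempts + 1L
        if (attempts > 200L * n)
          stop("population extinction at generation ", gen,
               ": viability selection rejected all offspring", call. = FALSE)
        mo <- inds[[females[sample.int(length(females), 1L)]]]
        fa <- inds[[males[sample.int(length(males), 1L)]]]
        chroms <- lapply(seq_along(lens), function(ci) {
          list(meiosis(mo$chroms[[ci]][[1L]], mo$chroms[[ci]][[2L]],
                       lens[ci]),
               meiosis(fa$chroms[[ci]][[1L]], fa$chroms[[ci]][[2L]],
                       lens[ci]))
        })
        w <- offspring_fitness(chroms, mo$mito, loci)
        if (w < 1 && stats::runif(1L) > w) next
        accepted <- accepted + 1L
        offspring[[accepted]] <- list(chroms = chroms, mito = mo$mito,
                                      sex = sex_next[accepted])
      }
      inds <- offspring
    }
    inds
  })
  structure(list(individuals = pop, chromosomes = lens,
                 config = config, genes = genes),
            class = "sim_population") -> population
  truth <- sim_truth(population)
  list(population = population, truth = truth)
}

## Ground truth: diploid ancestry dosage at every AIM for every individual.
sim_truth <- function(population) {
  config <- population$config
  sites <- sim_aim_sites(config)
  lens <- population$chromosomes
  n <- length(population$individuals)
  dosage <- matrix(NA_real_, nrow(sites), n,
                   dimnames = list(paste0(sites$chrom, ":", sites$pos),
                                   sprintf("ind_%03d", seq_len(n))))
  for (ci in seq_along(lens)) {
    rows <- which(sites$chrom == names(lens)[ci])
    pos_m <- bp_to_morgan(sites$pos[rows])
    for (i in seq_len(n)) {
      pair <- population$individuals[[i]]$chroms[[ci]]
      dosage[rows, i] <- (hap_at(pair[[1L]], pos_m) +
                            hap_at(pair[[2L]], pos_m)) / 2
    }
  }
  mito <- vapply(population$individuals, `[[`, 0L, "mito")
  dosage[sites$compartment == "mito", ] <- mito
  selected <- if (is.null(config$incompat_loci)) character() else
    unique(config$incompat_loci$gene_id)
  structure(list(
    dosage = dosage, sites = sites, selected_genes = selected,
    mean_ancestry = mean(dosage[sites$compartment == "nuclear", ]),
    mito_freq = mean(mito)
  ), class = "sim_truth")
}

#' Emit noisy ancestry posteriors from a simulated population
#'
#' Each true dosage `t` is emitted as a draw from
#' `Beta(1 + kappa * t, 1 + kappa * (1 - t))` — a perturbation with mode at
#' `t` that stays in `[0, 1]` and sharpens as the concentration `kappa`
#' grows; `kappa = Inf` emits `t` exactly. A `lowconf_fraction` of entries is
#' then resampled uniformly from (0.2, 0.8), emulating low-confidence calls
#' that the standard 0.2/0.8 confidence filter removes.
#'
#' @param population,truth Output of [simulate_population()].
#' @param config The same [sim_config()] (defaults to the one stored in
#'   `population`).
#' @return A list with `posteriors` (matrix, sites x individuals) and
#'   `sites` (AIM site table; last row is the mitochondrial AIM).
#' @export
emit_posteriors <- function(population, truth, config = population$config) {
  t_mat <- truth$dosage
  kappa <- config$posterior_noise_kappa
  with_seed(sub_seed(config$seed, 202L), {
    m <- if (is.infinite(kappa)) t_mat else {
      tv <- as.vector(t_mat)
      matrix(stats::rbeta(length(tv), 1 + kappa * tv, 1 + kappa * (1 - tv)),
             nrow(t_mat), ncol(t_mat), dimnames = dimnames(t_mat))
    }
    if (config$lowconf_fraction > 0) {
      k <- round(config$lowconf_fraction * length(m))
      idx <- sample.int(length(m), k)
      m[idx] <- stats::runif(k, 0.2, 0.8)
    }
    list(posteriors = m, sites = truth$sites)
  })
}

#' Simulate a complete analysis-ready dataset
#'
#' Convenience wrapper: builds the gene map, runs the forward simulation and
#' emits posteriors.
#'
#' @param config A [sim_config()].
#' @return A list with `posteriors`, `sites`, `genes`, `truth`, `population`
#'   and `config`.
#' @export
simulate_dataset <- function(config) {
  genes <- build_gene_map(config)
  sim <- simulate_population(config, genes)
  em <- emit_posteriors(sim$population, sim$truth, config)
  list(posteriors = em$posteriors, sites = em$sites, genes = genes,
       truth = sim$truth, population = sim$population, config = config)
}

#' Write a simulated dataset to disk
#'
#' Writes the posterior table, gene map and ground-truth dosages as TSV files
#' (posterior-table format as read by [read_posterior_table()]); `#` header
#' lines record the seed.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_sim_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed_line <- paste0("seed=", dataset$config$seed)
  paths <- c(
    posteriors = file.path(dir, "posteriors.tsv"),
    genes = file.path(dir, "gene_map.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_posterior_table(dataset$posteriors, dataset$sites,
                        paths[["posteriors"]], comments = seed_line)
  write_gene_map(dataset$genes, paths[["genes"]], comments = seed_line)
  write_posterior_table(dataset$truth$dosage, dataset$sites, paths[["truth"]],
                        comments = c(seed_line,
                                     paste0("selected_genes=",
                                            paste(dataset$truth$selected_genes,
                                                  collapse = ","))))
  invisible(paths)
}
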