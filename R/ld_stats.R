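## Core mitonuclear statistics: mito haplotype calling, allele and joint
## frequency estimation from posterior dosages, D / D' / r2 per AIM,
## per-gene averaging, Z-score outliers, and per-gene allele frequencies for
## populations fixed for one mitochondrial haplotype.

#' Call the mitochondrial haplotype of each individual
#'
#' The mitogenome is non-recombining, so a single designated mitochondrial
#' AIM represents it: posteriors at or above `hi` are called `major`, at or
#' below `lo` are called `minor`, and intermediate or missing values are left
#' uncalled (`NA`).
#'
#' @param posteriors Posterior matrix (ideally already passed through
#'   [filter_posteriors()]).
#' @param sites AIM site table matching the matrix rows.
#' @param mito_site Optional `"chrom:pos"` selector; by default the single
#'   row with compartment `"mito"` is used (an error if there is none or more
#'   than one).
#' @param lo,hi Call thresholds (defaults 0.2/0.8).
#' @return Character vector (one element per individual) with values
#'   `"major"`, `"minor"` or `NA`.
#' @export
call_mito_haplotype <- function(posteriors, sites, mito_site = NULL,
                                lo = 0.2, hi = 0.8) {
  validate_aim_sites(sites)
  stopifnot(nrow(posteriors) == nrow(sites))
  if (is.null(mito_site)) {
    row <- which(sites$compartment == "mito")
    if (length(row) != 1L)
      stop("expected exactly one mitochondrial AIM, found ", length(row),
           "; use mito_site = 'chrom:pos' to choose one", call. = FALSE)
  } else {
    key <- paste0(sites$chrom, ":", sites$pos)
    row <- which(key == mito_site)
    if (length(row) != 1L)
      stop("mito site '", mito_site, "' not found", call. = FALSE)
    if (sites$compartment[row] != "mito")
      stop("site '", mito_site, "' is not a mitochondrial AIM", call. = FALSE)
  }
  p <- posteriors[row, ]
  calls <- rep(NA_character_, length(p))
  calls[!is.na(p) & p >= hi] <- "major"
  calls[!is.na(p) & p <= lo] <- "minor"
  names(calls) <- colnames(posteriors)
  calls
}

#' Major-parent allele frequency from posterior dosages
#'
#' The per-individual posteriors at an AIM are summed (equivalently averaged)
#' over non-missing individuals as a proxy for the frequency of the
#' major-parent allele.
#'
#' @param dosages Numeric vector of per-individual dosages in `[0, 1]`.
#' @return The mean of the non-missing values, or `NA` if all are missing.
#' @export
allele_freq <- function(dosages) {
  if (all(is.na(dosages))) return(NA_real_)
  mean(dosages, na.rm = TRUE)
}

#' Two-locus frequencies of a nuclear AIM and the mitochondrial haplotype
#'
#' Over individuals with both a nuclear dosage and a mitochondrial call
#' (pairwise-complete deletion): `pA` is the mean nuclear dosage, `pB` the
#' fraction of major-parent mitogenomes, and `pAB` the mean of
#' `dosage x indicator(mito == major)` — the frequency of the matched
#' (major-with-major) combination. This estimator keeps the marginals
#' consistent (summing `pAB` over the two mito states returns `pA`) and
#' reduces to haplotype counting when dosages are hard 0/1 calls.
#'
#' @param dosages Per-individual nuclear dosages.
#' @param calls Per-individual mitochondrial calls (`"major"`/`"minor"`/`NA`),
#'   same individual order.
#' @return A list with `pA`, `pB`, `pAB`, `n` (complete individuals); all
#'   frequencies `NA` when fewer than 2 complete individuals exist.
#' @export
joint_freq <- function(dosages, calls) {
  stopifnot(length(dosages) == length(calls))
  ok <- !is.na(dosages) & !is.na(calls)
  n <- sum(ok)
  if (n < 2L)
    return(list(pA = NA_real_, pB = NA_real_, pAB = NA_real_, n = n))
  d <- dosages[ok]
  b <- as.numeric(calls[ok] == "major")
  list(pA = mean(d), pB = mean(b), pAB = mean(d * b), n = n)
}

#' Linkage disequilibrium from two-locus frequencies
#'
#' Computes the classical two-locus disequilibrium statistics with the
#' mitogenome as locus B:
#' \deqn{D = p_{AB} - p_A p_B}
#' \deqn{D' = D / D_{max},\quad
#'   D_{max} = \min(p_A(1-p_B), (1-p_A)p_B) \; \mathrm{if}\; D > 0;\;
#'   \min(p_A p_B, (1-p_A)(1-p_B)) \; \mathrm{if}\; D < 0}
#' \deqn{r^2 = D^2 / (p_A(1-p_A)\,p_B(1-p_B))}
#' with `D' = 0` when `D = 0`. Both alleles are labelled by the same parent
#' species, so positive values mean matched parental combinations are in
#' excess. When either marginal frequency is 0 or 1 the statistics are
#' undefined and returned as `NA` (not 0), so monomorphic sites never bias
#' downstream averages.
#'
#' Vectorised over the three frequency arguments.
#'
#' @param pA,pB,pAB Frequencies satisfying `0 <= pA, pB <= 1` and
#'   `max(0, pA + pB - 1) <= pAB <= min(pA, pB)` (elementwise; a small
#'   numerical tolerance is allowed).
#' @return A `data.frame` with columns `D`, `Dmax`, `Dprime`, `r2`.
#' @export
ld_from_freqs <- function(pA, pB, pAB) {
  k <- max(length(pA), length(pB), length(pAB))
  pA <- rep_len(as.numeric(pA), k)
  pB <- rep_len(as.numeric(pB), k)
  pAB <- rep_len(as.numeric(pAB), k)
  tol <- 1e-9
  ok <- !is.na(pA) & !is.na(pB) & !is.na(pAB)
  bad <- ok & (pA < -tol | pA > 1 + tol | pB < -tol | pB > 1 + tol |
                 pAB < pmax(0, pA + pB - 1) - tol |
                 pAB > pmin(pA, pB) + tol)
  if (any(bad))
    stop(sprintf(
      "invalid two-locus frequencies (pA=%g, pB=%g, pAB=%g)",
      pA[which(bad)[1]], pB[which(bad)[1]], pAB[which(bad)[1]]),
      call. = FALSE)
  D <- pAB - pA * pB
  Dmax <- ifelse(D >= 0,
                 pmin(pA * (1 - pB), (1 - pA) * pB),
                 pmin(pA * pB, (1 - pA) * (1 - pB)))
  mono <- ok & (pA <= tol | pA >= 1 - tol | pB <= tol | pB >= 1 - tol)
  Dprime <- ifelse(D == 0, 0, D / Dmax)
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  D[mono] <- Dmax[mono] <- Dprime[mono] <- r2[mono] <- NA_real_
  data.frame(D = D, Dmax = Dmax, Dprime = Dprime, r2 = r2)
}

#' Genome-wide mitonuclear LD scan
#'
#' Computes `D`, `D'` and `r2` between every nuclear AIM and the
#' mitochondrial haplotype. Individuals missing either value at an AIM are
#' dropped for that AIM only (pairwise-complete deletion); AIMs with fewer
#' than 2 complete individuals or a monomorphic marginal are reported as
#' `NA`. The mitochondrial AIM itself is excluded from the scan.
#'
#' @param posteriors Filtered posterior matrix.
#' @param sites AIM site table.
#' @param calls Mitochondrial calls from [call_mito_haplotype()].
#' @param hard_calls If `TRUE`, nuclear dosages are first hard-thresholded
#'   (`>= hi` to 1, `<= lo` to 0, otherwise missing) so LD is computed from
#'   discrete calls rather than raw posterior dosages (the default).
#' @param lo,hi Thresholds used when `hard_calls = TRUE`.
#' @return A `data.frame`, one row per nuclear AIM, with `chrom`, `pos`,
#'   `pA`, `pB`, `pAB`, `D`, `Dmax`, `Dprime`, `r2`, `n_used`.
#' @export
scan_mitonuclear_ld <- function(posteriors, sites, calls,
                                hard_calls = FALSE, lo = 0.2, hi = 0.8) {
  validate_aim_sites(sites)
  stopifnot(nrow(posteriors) == nrow(sites),
            length(calls) == ncol(posteriors))
  nuc <- sites$compartment == "nuclear"
  if (!any(nuc)) stop("no nuclear AIMs to scan", call. = FALSE)
  m <- posteriors[nuc, , drop = FALSE]
  if (hard_calls) {
    hard <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
    hard[!is.na(m) & m >= hi] <- 1
    hard[!is.na(m) & m <= lo] <- 0
    m <- hard
  }
  called <- !is.na(calls)
  m <- m[, called, drop = FALSE]
  b <- as.numeric(calls[called] == "major")
  present <- !is.na(m)
  m0 <- m
  m0[!present] <- 0
  n_used <- rowSums(present)
  sA <- rowSums(m0)
  sB <- as.vector(present %*% b)
  sAB <- as.vector(m0 %*% b)
  pA <- sA / n_used
  pB <- sB / n_used
  pAB <- sAB / n_used
  few <- n_used < 2L
  pA[few] <- pB[few] <- pAB[few] <- NA_real_
  ld <- ld_from_freqs(pA, pB, pAB)
  data.frame(chrom = sites$chrom[nuc], pos = sites$pos[nuc],
             pA = pA, pB = pB, pAB = pAB, ld, n_used = n_used,
             stringsAsFactors = FALSE)
}

#' Average a per-AIM statistic within genes
#'
#' Averaging within genes limits pseudo-replication from the many AIMs a
#' single gene contains. The mean is unweighted over the gene's non-missing
#' per-AIM values; genes whose AIMs are all missing are dropped.
#'
#' @param values Numeric vector of per-AIM values, indexed like the `sites`
#'   rows that `mapping` refers to.
#' @param mapping Named list from [map_aims_to_genes()] (gene id to AIM row
#'   indices).
#' @param genes Gene annotation table (supplies `gene_class`).
#' @param statistic Name of the statistic being averaged (recorded in the
#'   output, e.g. `"Dprime"`).
#' @return A `data.frame` with `gene_id`, `gene_class`, `statistic`, `value`
#'   (the within-gene mean) and `n_aims` (non-missing AIMs used).
#' @export
aggregate_per_gene <- function(values, mapping, genes, statistic = "value") {
  validate_gene_annotation(genes)
  ids <- names(mapping)
  means <- vapply(mapping, function(idx) {
    v <- values[idx]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  n_aims <- vapply(mapping, function(idx) sum(!is.na(values[idx])), 0L)
  keep <- !is.na(means)
  out <- data.frame(
    gene_id = ids[keep],
    gene_class = genes$gene_class[match(ids[keep], genes$gene_id)],
    statistic = statistic,
    value = unname(means[keep]),
    n_aims = unname(n_aims[keep]),
    stringsAsFactors = FALSE
  )
  out[order(out$gene_id), , drop = FALSE]
}

#' Per-gene major-parent allele frequencies
#'
#' The analysis used for populations fixed for one mitochondrial haplotype,
#' where mitonuclear LD is undefined: the major-parent allele frequency at
#' each AIM ([allele_freq()]) averaged within each gene.
#'
#' @param posteriors Filtered posterior matrix.
#' @param sites AIM site table.
#' @param mapping Named list from [map_aims_to_genes()].
#' @param genes Gene annotation table.
#' @return A `data.frame` as from [aggregate_per_gene()] with statistic
#'   `"allele_freq"`.
#' @export
allele_freq_per_gene <- function(posteriors, sites, mapping, genes) {
  validate_aim_sites(sites)
  stopifnot(nrow(posteriors) == nrow(sites))
  per_aim <- rowMeans(posteriors, na.rm = TRUE)
  per_aim[rowSums(!is.na(posteriors)) == 0L] <- NA_real_
  per_aim[sites$compartment != "nuclear"] <- NA_real_
  aggregate_per_gene(per_aim, mapping, genes, statistic = "allele_freq")
}

#' Z-score standardisation and outlier flagging of per-gene statistics
#'
#' Standardises each gene's statistic against the distribution over all genes
#' (`z = (value - mean) / sd`, sample sd with the `n - 1` denominator) and
#' flags genes more than `threshold` standard deviations *above* the mean
#' (one-sided, strict inequality) as outliers. Focal genes of prior interest
#' can be highlighted.
#'
#' @param gene_stats A per-gene statistic table from [aggregate_per_gene()]
#'   or [allele_freq_per_gene()].
#' @param focal_genes Optional character vector of gene ids to flag in the
#'   report.
#' @param threshold Z-score outlier threshold (default 2).
#' @return `gene_stats` with added columns `zscore`, `is_outlier`
#'   (`zscore > threshold`) and `is_focal`, sorted by decreasing `zscore`.
#' @export
zscore_outliers <- function(gene_stats, focal_genes = NULL, threshold = 2) {
  stopifnot(is.data.frame(gene_stats),
            all(c("gene_id", "value") %in% names(gene_stats)))
  v <- gene_stats$value
  if (sum(!is.na(v)) < 2L)
    stop("need at least 2 genes with defined values", call. = FALSE)
  s <- stats::sd(v, na.rm = TRUE)
  if (s == 0)
    stop("degenerate distribution: all gene values identical", call. = FALSE)
  out <- gene_stats
  out$zscore <- (v - mean(v, na.rm = TRUE)) / s
  out$is_outlier <- !is.na(out$zscore) & out$zscore > threshold
  out$is_focal <- out$gene_id %in% (focal_genes %||% character())
  out[order(-out$zscore), , drop = FALSE]
}
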