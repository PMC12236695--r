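## Population-level hypothesis tests on per-gene statistics: one-way ANOVA
## across the three gene classes, a permutation null for class differences,
## top-fraction enrichment, and cross-population correlation of focal genes.

per_class_summary <- function(gene_stats) {
  cls <- factor(gene_stats$gene_class, levels = GENE_CLASSES)
  do.call(rbind, lapply(levels(cls), function(cl) {
    v <- gene_stats$value[cls == cl]
    data.frame(gene_class = cl, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' One-way ANOVA of a per-gene statistic across gene classes
#'
#' Fixed-effects one-way analysis of variance (via [stats::lm()] and
#' [stats::anova()]) testing whether gene class (interacting n-mt,
#' non-interacting n-mt, non-n-mt) has an effect on the gene-level statistic.
#' Gene-level means enter unweighted, matching the per-gene averaging used to
#' limit pseudo-replication.
#'
#' @param gene_stats Per-gene statistic table ([aggregate_per_gene()]) with
#'   columns `gene_class` and `value`; every represented class must have at
#'   least 2 genes.
#' @return An object of class `class_test`: a list with `method`,
#'   `statistic` (name), `F`, `p`, `df`, and `per_class` (n/mean/sd table).
#' @export
one_way_anova <- function(gene_stats) {
  stopifnot(is.data.frame(gene_stats),
            all(c("gene_class", "value") %in% names(gene_stats)))
  gs <- gene_stats[!is.na(gene_stats$value), , drop = FALSE]
  counts <- table(gs$gene_class)
  if (length(counts) < 2)
    stop("need at least 2 gene classes, found ", length(counts),
         call. = FALSE)
  small <- names(counts)[counts < 2]
  if (length(small))
    stop("gene class with fewer than 2 genes: ",
         paste(small, collapse = ", "), call. = FALSE)
  fit <- stats::lm(value ~ gene_class,
                   data = transform(gs, gene_class = factor(gene_class)))
  an <- stats::anova(fit)
  structure(list(
    method = "one-way ANOVA",
    statistic = gs$statistic[1] %||% "value",
    F = an[1, "F value"],
    p = an[1, "Pr(>F)"],
    df = c(an[1, "Df"], an[2, "Df"]),
    per_class = per_class_summary(gs)
  ), class = "class_test")
}

#' @export
print.class_test <- function(x, ...) {
  cat(sprintf("%s on per-gene %s\n", x$method, x$statistic))
  if (!is.null(x$F))
    cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n", x$df[1], x$df[2], x$F, x$p))
  if (!is.null(x$p_perm))
    cat(sprintf("  permutation p = %.4g (%d permutations, %s-sided, %s - %s, seed %s)\n",
                x$p_perm, x$n_perm, x$sided, x$contrast[1], x$contrast[2],
                x$seed %||% "none"))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Permutation test for a difference in class means
#'
#' Tests the observed difference in mean gene-level statistic between two
#' gene classes (`T = mean(classX) - mean(classY)`) against a null built by
#' randomly reassigning the values across all gene labels (class sizes held
#' fixed) `n_perm` times. The p-value uses the add-one estimator
#' `(b + 1) / (n_perm + 1)`, where `b` counts permuted statistics at least as
#' extreme as observed; one-sided (upper) by default, reflecting the
#' directional hypothesis that mitochondrially interacting genes show
#' *higher* matched ancestry, with a two-sided option on `|T|`.
#'
#' @param gene_stats Per-gene statistic table.
#' @param contrast Ordered pair of class labels `(classX, classY)`; default
#'   interacting n-mt minus non-n-mt.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional integer seed for the permutation stream.
#' @param sided `"one"` (upper tail) or `"two"` (on `|T|`).
#' @return A `class_test` object with `T_obs`, `p_perm`, `n_perm`, `seed`,
#'   `contrast`, `sided` and the per-class summary.
#' @export
permutation_class_test <- function(gene_stats,
                                   contrast = c("interacting_nmt", "non_nmt"),
                                   n_perm = 9999, seed = NULL,
                                   sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(is.data.frame(gene_stats),
            all(c("gene_class", "value") %in% names(gene_stats)))
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  if (!all(contrast %in% gene_stats$gene_class))
    stop("contrast classes not both present: ",
         paste(setdiff(contrast, gene_stats$gene_class), collapse = ", "),
         call. = FALSE)
  gs <- gene_stats[!is.na(gene_stats$value), , drop = FALSE]
  v <- gs$value
  ix <- gs$gene_class == contrast[1]
  iy <- gs$gene_class == contrast[2]
  t_obs <- mean(v[ix]) - mean(v[iy])
  score <- if (sided == "one") identity else abs
  # ties are counted as "at least as extreme" up to float round-off so the
  # estimator stays valid (conservative) when many permutations tie exactly
  tie_tol <- 1e-12 * max(1, abs(t_obs))
  run <- function() {
    t_perm <- vapply(seq_len(n_perm), function(i) {
      p <- sample(v)
      mean(p[ix]) - mean(p[iy])
    }, 0)
    sum(score(t_perm) >= score(t_obs) - tie_tol)
  }
  b <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(list(
    method = "permutation test (class reassignment)",
    statistic = gs$statistic[1] %||% "value",
    T_obs = t_obs,
    p_perm = (b + 1) / (n_perm + 1),
    n_perm = as.integer(n_perm),
    seed = seed,
    contrast = contrast,
    sided = sided,
    per_class = per_class_summary(gs)
  ), class = "class_test")
}

#' Gene-class enrichment in the top fraction of genes
#'
#' Ranks genes by a statistic, takes the top `fraction` (ties at the cutoff
#' all included, so the realised top set may exceed `ceiling(fraction * N)`),
#' and tests each gene class for overrepresentation in the top set with an
#' exact upper-tail hypergeometric test.
#'
#' @param gene_stats Per-gene statistic table.
#' @param fraction Top fraction of genes to take (default 0.01, the top 1%).
#' @return A `data.frame`, one row per gene class, with `gene_class`,
#'   `K_class` (class size among tested genes), `n_top` (realised top-set
#'   size), `k_in_top` and `p_hyper` (upper-tail hypergeometric p-value).
#' @export
top_fraction_enrichment <- function(gene_stats, fraction = 0.01) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  gs <- gene_stats[!is.na(gene_stats$value), , drop = FALSE]
  N <- nrow(gs)
  if (N < 1 / fraction)
    stop("need at least ", ceiling(1 / fraction), " genes for fraction ",
         fraction, call. = FALSE)
  k_top <- ceiling(fraction * N)
  cutoff <- sort(gs$value, decreasing = TRUE)[k_top]
  in_top <- gs$value >= cutoff
  n_top <- sum(in_top)
  do.call(rbind, lapply(GENE_CLASSES, function(cl) {
    K <- sum(gs$gene_class == cl)
    k <- sum(in_top & gs$gene_class == cl)
    p <- if (K == 0) NA_real_ else
      stats::phyper(k - 1, K, N - K, n_top, lower.tail = FALSE)
    data.frame(gene_class = cl, K_class = K, n_top = n_top, k_in_top = k,
               p_hyper = p, stringsAsFactors = FALSE)
  }))
}

#' Cross-population correlation of focal-gene statistics
#'
#' Pearson correlation between per-gene statistics of two populations,
#' restricted to a set of focal genes (e.g. genes previously implicated in
#' mitonuclear incompatibilities) present in both. The p-value is the
#' two-sided t-transform p from [stats::cor.test()].
#'
#' @param stats_a,stats_b Per-gene statistic tables for the two populations.
#' @param focal_genes Character vector of focal gene ids; at least 3 must be
#'   present in both tables.
#' @return A list with `r`, `p`, `n` (shared focal genes) and `genes`.
#' @export
cross_population_correlation <- function(stats_a, stats_b, focal_genes) {
  shared <- intersect(intersect(focal_genes, stats_a$gene_id),
                      stats_b$gene_id)
  if (length(shared) < 3)
    stop("need at least 3 focal genes present in both populations, found ",
         length(shared), call. = FALSE)
  va <- stats_a$value[match(shared, stats_a$gene_id)]
  vb <- stats_b$value[match(shared, stats_b$gene_id)]
  ct <- stats::cor.test(va, vb, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared),
       genes = shared)
}
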