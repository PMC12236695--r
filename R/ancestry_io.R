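## Readers/writers for posterior tables and gene annotations, the
## posterior-confidence filter, and AIM-to-gene interval mapping.
##
## Conventions: all coordinates are 1-based inclusive; the missing-value
## sentinel in files is "NA"; lines starting "#" are metadata and skipped.

#' Construct and validate an AIM site table
#'
#' An AIM (ancestry-informative marker) site table has one row per marker with
#' its chromosome, 1-based position and compartment (`"nuclear"` or `"mito"`).
#'
#' @param chrom Character vector of chromosome identifiers.
#' @param pos Integer vector of 1-based positions.
#' @param compartment Character vector, each `"nuclear"` or `"mito"`.
#' @return A `data.frame` with columns `chrom`, `pos`, `compartment`.
#' @export
aim_sites <- function(chrom, pos, compartment) {
  sites <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    compartment = as.character(compartment),
    stringsAsFactors = FALSE
  )
  validate_aim_sites(sites)
  sites
}

validate_aim_sites <- function(sites) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "compartment") %in% names(sites)))
  if (!all(sites$compartment %in% c("nuclear", "mito")))
    stop("compartment must be 'nuclear' or 'mito'", call. = FALSE)
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos) in AIM sites: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  invisible(sites)
}

#' Construct and validate a gene annotation table
#'
#' Genes are genomic intervals (1-based inclusive) carrying one of the three
#' functional class labels: `"interacting_nmt"` (mitochondrially targeted,
#' physically interacting with mitochondrially encoded products),
#' `"noninteracting_nmt"` (mitochondrially targeted, not interacting) and
#' `"non_nmt"` (no mitochondrial function).
#'
#' @param gene_id Unique gene identifiers.
#' @param chrom Chromosome of each gene.
#' @param start,end 1-based inclusive interval bounds, `start <= end`.
#' @param gene_class One of the three class labels per gene.
#' @return A `data.frame` with the five columns above.
#' @export
gene_annotation <- function(gene_id, chrom, start, end, gene_class) {
  genes <- data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    gene_class = as.character(gene_class),
    stringsAsFactors = FALSE
  )
  validate_gene_annotation(genes)
  genes
}

validate_gene_annotation <- function(genes) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "start", "end", "gene_class")
                %in% names(genes)))
  if (anyDuplicated(genes$gene_id))
    stop("gene_id values must be unique", call. = FALSE)
  if (any(genes$start > genes$end))
    stop("gene intervals must satisfy start <= end", call. = FALSE)
  bad <- setdiff(unique(genes$gene_class), GENE_CLASSES)
  if (length(bad))
    stop("unknown gene_class: ", paste(bad, collapse = ", "),
         "; expected one of ", paste(GENE_CLASSES, collapse = ", "),
         call. = FALSE)
  invisible(genes)
}

#' Read a posterior table
#'
#' Parses a tab-separated table with header columns `chrom`, `pos`,
#' `compartment` followed by one column per individual. Values are
#' major-parent ancestry posteriors on the dosage scale in `[0, 1]`, or `NA`.
#' Lines starting with `#` are metadata and skipped.
#'
#' @param path Path to the TSV file.
#' @return A list with `posteriors` (numeric matrix, sites x individuals,
#'   rownames `"chrom:pos"`) and `sites` (the AIM site table, original row
#'   order preserved).
#' @seealso [write_posterior_table()] for the loss-free inverse.
#' @export
read_posterior_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "compartment")
  if (!all(need %in% names(tab)[seq_len(min(3, ncol(tab)))]))
    stop("posterior table must start with header columns ",
         paste(need, collapse = ", "), ": ", path, call. = FALSE)
  sites <- aim_sites(tab$chrom, tab$pos, tab$compartment)
  ind_cols <- setdiff(names(tab), need)
  if (!length(ind_cols)) stop("no individual columns in ", path, call. = FALSE)
  if (anyDuplicated(ind_cols))
    stop("duplicate individual ids in header of ", path, call. = FALSE)
  m <- as.matrix(tab[, ind_cols, drop = FALSE])
  if (!is.numeric(m)) {
    suppressWarnings(storage.mode(m) <- "double")
    bad_parse <- is.na(m) & !(as.matrix(tab[, ind_cols, drop = FALSE]) %in%
                                c("NA", NA))
    if (any(bad_parse)) {
      ij <- which(bad_parse, arr.ind = TRUE)[1, ]
      stop(sprintf("non-numeric posterior at row %d, individual '%s' in %s",
                   ij[1], ind_cols[ij[2]], path), call. = FALSE)
    }
  }
  out_of_range <- !is.na(m) & (m < 0 | m > 1)
  if (any(out_of_range)) {
    ij <- which(out_of_range, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "posterior value %g outside [0, 1] at site %s:%d, individual '%s'",
      m[ij[1], ij[2]], sites$chrom[ij[1]], sites$pos[ij[1]], ind_cols[ij[2]]),
      call. = FALSE)
  }
  rownames(m) <- paste0(sites$chrom, ":", sites$pos)
  list(posteriors = m, sites = sites)
}

#' Write a posterior table
#'
#' Inverse of [read_posterior_table()]: writes the sites and posterior matrix
#' as a TSV, optionally preceded by `#`-prefixed metadata lines (e.g. the
#' simulation seed).
#'
#' @param posteriors Numeric matrix, sites x individuals, values in `[0, 1]`
#'   or `NA`.
#' @param sites AIM site table matching the matrix rows.
#' @param path Output path.
#' @param comments Character vector of metadata lines, written as `#`-prefixed
#'   header lines.
#' @export
write_posterior_table <- function(posteriors, sites, path,
                                  comments = character()) {
  validate_aim_sites(sites)
  stopifnot(nrow(posteriors) == nrow(sites))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("#", sub("^#", "", comments)), con)
  tab <- data.frame(sites, posteriors, check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' BED-like 5-column TSV (`chrom`, `start`, `end`, `gene_id`, `gene_class`)
#' in which, unlike BED proper, coordinates are 1-based inclusive; files
#' written by [write_gene_map()] declare this with a
#' `#coords=1-based-inclusive` header line.
#'
#' @param path Path to the TSV file.
#' @return A validated gene annotation `data.frame`
#'   (columns `gene_id`, `chrom`, `start`, `end`, `gene_class`).
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, comment.char = "#", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end",
                                         "gene_id", "gene_class"))
  gene_annotation(tab$gene_id, tab$chrom, tab$start, tab$end, tab$gene_class)
}

#' Write a gene annotation table
#'
#' @param genes Gene annotation `data.frame`.
#' @param path Output path.
#' @param comments Extra `#` metadata lines (the coordinate-convention line is
#'   always written).
#' @export
write_gene_map <- function(genes, path, comments = character()) {
  validate_gene_annotation(genes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#coords=1-based-inclusive",
               if (length(comments)) paste0("#", sub("^#", "", comments))),
             con)
  utils::write.table(genes[, c("chrom", "start", "end", "gene_id",
                               "gene_class")],
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a focal-gene list
#'
#' One gene id per line; `#` lines and blank lines are ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of gene ids.
#' @export
read_focal_genes <- function(path) {
  x <- readLines(path)
  x <- trimws(x[!grepl("^\\s*(#|$)", x)])
  unique(x)
}

#' Remove low-confidence posterior calls
#'
#' Ancestry posteriors strictly between `lo` and `hi` carry little information
#' about the underlying genotype and are set to missing; values at or beyond
#' the thresholds (including exactly `lo` or `hi`) are retained. The operation
#' is idempotent.
#'
#' @param posteriors Posterior matrix.
#' @param lo,hi Confidence thresholds, `0 <= lo < hi <= 1`. Defaults 0.2/0.8.
#' @return The matrix with low-confidence entries set to `NA`.
#' @export
filter_posteriors <- function(posteriors, lo = 0.2, hi = 0.8) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi || lo < 0 || hi > 1)
    stop("thresholds must satisfy 0 <= lo < hi <= 1", call. = FALSE)
  posteriors[!is.na(posteriors) & posteriors > lo & posteriors < hi] <- NA_real_
  posteriors
}

#' Map AIMs to the genes containing them
#'
#' An AIM is assigned to every gene whose 1-based inclusive interval
#' `[start, end]` contains its position on the same chromosome; overlapping
#' genes therefore share AIMs, and AIMs in no gene are unassigned.
#'
#' @param sites AIM site table.
#' @param genes Gene annotation table.
#' @return Named list, one element per gene with at least one AIM: integer
#'   indices into `sites` rows. Deterministic and invariant to input row order
#'   (indices always ascending).
#' @export
map_aims_to_genes <- function(sites, genes) {
  validate_aim_sites(sites)
  validate_gene_annotation(genes)
  out <- structure(list(), names = character())
  for (chr in unique(genes$chrom)) {
    site_idx <- which(sites$chrom == chr)
    if (!length(site_idx)) next
    ord <- order(sites$pos[site_idx])
    pos_sorted <- sites$pos[site_idx][ord]
    idx_sorted <- site_idx[ord]
    g <- genes[genes$chrom == chr, , drop = FALSE]
    # first site with pos >= start .. last site with pos <= end
    from <- findInterval(g$start - 1L, pos_sorted) + 1L
    to <- findInterval(g$end, pos_sorted)
    for (i in seq_len(nrow(g))) {
      if (from[i] > to[i]) next
      out[[g$gene_id[i]]] <- sort(idx_sorted[from[i]:to[i]])
    }
  }
  if (!length(out)) return(out)
  out[order(names(out))]
}

#' Population-level ancestry summaries
#'
#' Computes the quantities used to characterise a hybrid population: the
#' average major-parent nuclear ancestry (mean over all non-missing nuclear
#' posteriors), the mitochondrial haplotype frequencies among called
#' individuals, and each individual's mean nuclear ancestry (the per-fish
#' genome-wide proportion used for ancestry histograms).
#'
#' @param posteriors Filtered posterior matrix.
#' @param sites AIM site table matching the matrix rows.
#' @param mito_calls Optional per-individual haplotype calls from
#'   [call_mito_haplotype()].
#' @return A list with `mean_nuclear_ancestry`, `mito_haplotype_freq` (named
#'   numeric: fraction `major` and `minor` among non-missing calls; `NULL` if
#'   no calls supplied), `n_individuals`, and `per_individual` (data.frame
#'   with `individual`, `mean_ancestry`, `n_sites`, and `mito` if calls were
#'   supplied).
#' @export
population_summaries <- function(posteriors, sites, mito_calls = NULL) {
  validate_aim_sites(sites)
  stopifnot(nrow(posteriors) == nrow(sites))
  nuc <- posteriors[sites$compartment == "nuclear", , drop = FALSE]
  if (all(is.na(nuc)))
    stop("no data: all nuclear posteriors are missing", call. = FALSE)
  per_ind <- data.frame(
    individual = colnames(nuc) %||% paste0("ind", seq_len(ncol(nuc))),
    mean_ancestry = colMeans(nuc, na.rm = TRUE),
    n_sites = colSums(!is.na(nuc)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  mito_freq <- NULL
  if (!is.null(mito_calls)) {
    called <- mito_calls[!is.na(mito_calls)]
    mito_freq <- c(major = mean(called == "major"),
                   minor = mean(called == "minor"))
    per_ind$mito <- as.character(mito_calls)
  }
  list(mean_nuclear_ancestry = mean(nuc, na.rm = TRUE),
       mito_haplotype_freq = mito_freq,
       n_individuals = ncol(nuc),
       per_individual = per_ind)
}
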