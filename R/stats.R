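#' Construct a presence/absence amplification matrix
#'
#' A taxa-by-loci boolean table of amplification/sequencing success, with an
#' explicit mask of which (taxon, locus) pairs were actually attempted.
#' Untested cells (NA in the input) are never counted as successes or
#' failures.
#'
#' @param mat Matrix or data frame of 1/0/NA (or logical/NA) with taxa as
#'   rows (rownames) and loci as columns.
#' @return A `presence_matrix`: list with logical matrices `present` and
#'   `tested`.
#' @export
presence_matrix <- function(mat) {
  m <- as.matrix(mat)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("presence matrix needs taxon rownames and locus colnames")
  storage.mode(m) <- "double"
  if (any(!m %in% c(0, 1, NA)))
    stop("presence matrix cells must be 1, 0 or NA")
  tested <- !is.na(m)
  present <- !is.na(m) & m == 1
  structure(list(present = present, tested = tested), class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: %d taxa x %d loci (%d tested cells, %d amplified)\n",
              nrow(x$present), ncol(x$present), sum(x$tested), sum(x$present)))
  invisible(x)
}

#' Read a presence/absence matrix from TSV
#'
#' Expects taxa in rows (first column = taxon name) and loci in columns,
#' cells 1/0/NA for amplified/failed/untested.
#'
#' @param path TSV path.
#' @return A [presence_matrix()].
#' @export
read_presence_matrix <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  rn <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- rn
  presence_matrix(m)
}

#' Path to the bundled marker-validation presence matrix
#'
#' The packaged 9-taxa x 12-loci amplification matrix from the wet-lab
#' validation of the teleost EPIC panel (reference-genome retrievals
#' excluded; every cell was attempted).
#'
#' @return File path of the TSV fixture.
#' @export
teleost_panel_path <- function() {
  system.file("extdata", "teleost_epic_panel_presence.tsv", package = "epicmine",
              mustWork = TRUE)
}

.check_locus <- function(m, locus) {
  if (!locus %in% colnames(m$present)) stop("unknown locus: ", locus)
}

.check_taxon <- function(m, taxon) {
  if (!taxon %in% rownames(m$present)) stop("unknown taxon: ", taxon)
}

#' Per-locus amplification success rate
#'
#' Amplified count over tested count for one locus. The value is exact;
#' round only for display.
#'
#' @param m A [presence_matrix()].
#' @param locus Locus name.
#' @return Fraction in `[0, 1]`.
#' @export
success_rate <- function(m, locus) {
  stopifnot(inherits(m, "presence_matrix"))
  .check_locus(m, locus)
  n_tested <- sum(m$tested[, locus])
  if (n_tested == 0) stop("locus ", locus, " was tested in no taxon")
  sum(m$present[, locus]) / n_tested
}

#' Number of taxa in which a locus amplified
#'
#' @inheritParams success_rate
#' @return Integer count.
#' @export
taxa_amplified <- function(m, locus) {
  stopifnot(inherits(m, "presence_matrix"))
  .check_locus(m, locus)
  sum(m$present[, locus])
}

#' Shared-amplifiability statistic for a taxon pair
#'
#' The proportion of markers amplified in both of two taxa among those
#' amplified in either, restricted to loci tested in both: 0 means no shared
#' markers, 1 means all markers shared. Symmetric and bounded in `[0, 1]`.
#' (The original description names this DA, a "difference of amplifiability",
#' but its definition and range make it a similarity; [da()] is an alias.)
#'
#' @param m A [presence_matrix()].
#' @param taxon_i,taxon_j Taxon names.
#' @return Fraction in `[0, 1]`; an empty union (neither taxon amplified any
#'   commonly tested locus) is an error, not 0.
#' @export
amplifiability_similarity <- function(m, taxon_i, taxon_j) {
  stopifnot(inherits(m, "presence_matrix"))
  .check_taxon(m, taxon_i); .check_taxon(m, taxon_j)
  both_tested <- m$tested[taxon_i, ] & m$tested[taxon_j, ]
  if (!any(both_tested))
    stop("taxa ", taxon_i, " and ", taxon_j, " share no tested locus")
  a <- m$present[taxon_i, both_tested]
  b <- m$present[taxon_j, both_tested]
  n_union <- sum(a | b)
  if (n_union == 0)
    stop("amplifiability similarity undefined: no marker amplified in either ",
         taxon_i, " or ", taxon_j)
  sum(a & b) / n_union
}

#' @rdname amplifiability_similarity
#' @export
da <- amplifiability_similarity

#' Pairwise shared-amplifiability matrix
#'
#' [amplifiability_similarity()] for every taxon pair; undefined pairs
#' (empty union) become `NA` with a warning instead of an error.
#'
#' @param m A [presence_matrix()].
#' @return Symmetric numeric matrix with unit diagonal (where defined).
#' @export
da_matrix <- function(m) {
  stopifnot(inherits(m, "presence_matrix"))
  taxa <- rownames(m$present)
  out <- matrix(NA_real_, length(taxa), length(taxa),
                dimnames = list(taxa, taxa))
  for (i in seq_along(taxa)) for (j in seq_len(i)) {
    v <- tryCatch(amplifiability_similarity(m, taxa[i], taxa[j]),
                  error = function(e) { warning(conditionMessage(e)); NA_real_ })
    out[i, j] <- out[j, i] <- v
  }
  out
}

.p_dist_pair <- function(a, b, comparable = c("ACGT")) {
  ai <- strsplit(toupper(a), "")[[1]]
  bi <- strsplit(toupper(b), "")[[1]]
  if (length(ai) != length(bi))
    stop("aligned sequences must have equal lengths")
  ok <- ai %in% c("A", "C", "G", "T") & bi %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n == 0) stop("no comparable sites between the two sequences")
  c(d = sum(ai[ok] != bi[ok]) / n, n = n)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites over comparable sites. Sites with a gap or
#' ambiguity code (anything outside A/C/G/T) in either sequence are excluded
#' (pairwise deletion).
#'
#' @param aligned_i,aligned_j Gapped, equal-length aligned sequences
#'   (character or `DNAString`).
#' @return Fraction in `[0, 1]`; the number of compared sites is attached as
#'   attribute `n_sites`.
#' @examples
#' p_distance("ACGT", "ACGA")    # 0.25
#' p_distance("AC-GT", "ACTGA")  # 0.25: 4 comparable sites, 1 difference
#' @export
p_distance <- function(aligned_i, aligned_j) {
  a <- if (is.character(aligned_i)) aligned_i else as.character(aligned_i)
  b <- if (is.character(aligned_j)) aligned_j else as.character(aligned_j)
  v <- .p_dist_pair(a, b)
  structure(unname(v["d"]), n_sites = unname(v["n"]))
}

#' Pairwise p-distance matrix from a multiple alignment
#'
#' Uncorrected p-distances for every taxon pair of an alignment. With
#' `deletion = "pairwise"` (default) each pair uses all sites comparable for
#' that pair; `"complete"` first drops every column containing a gap or
#' ambiguity in any taxon.
#'
#' @param aln Named character vector or `DNAStringSet` of equal-length
#'   aligned sequences.
#' @param deletion `"pairwise"` or `"complete"`.
#' @return Symmetric matrix of distances with zero diagonal; the per-pair
#'   compared-site counts are attached as attribute `n_sites`.
#' @export
p_distance_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  if (methods::is(aln, "DNAStringSet")) aln <- as.character(aln)
  stopifnot(is.character(aln), !is.null(names(aln)))
  if (length(unique(nchar(aln))) != 1)
    stop("aligned sequences must have equal lengths")
  if (deletion == "complete") {
    mat <- do.call(rbind, strsplit(toupper(aln), ""))
    keep <- apply(mat, 2, function(col) all(col %in% c("A", "C", "G", "T")))
    if (!any(keep)) stop("no site free of gaps/ambiguity in all taxa")
    aln <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
    names(aln) <- rownames(mat)
  }
  taxa <- names(aln)
  d <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  ns <- matrix(NA_integer_, length(taxa), length(taxa),
               dimnames = list(taxa, taxa))
  diag(ns) <- nchar(aln)[1]
  for (i in seq_along(taxa)) for (j in seq_len(i - 1L)) {
    v <- .p_dist_pair(aln[[i]], aln[[j]])
    d[i, j] <- d[j, i] <- v["d"]
    ns[i, j] <- ns[j, i] <- v["n"]
  }
  structure(d, n_sites = ns)
}

#' Absolute intron-size difference between two taxa at one locus
#'
#' @param sizes Matrix or data frame of intron sizes in bp, taxa as rows
#'   (rownames), loci as columns.
#' @param taxon_i,taxon_j Taxon names.
#' @param locus Locus name.
#' @return Absolute difference in bp.
#' @export
intron_size_difference <- function(sizes, taxon_i, taxon_j, locus) {
  sizes <- as.matrix(sizes)
  stopifnot(all(c(taxon_i, taxon_j) %in% rownames(sizes)),
            locus %in% colnames(sizes))
  a <- sizes[taxon_i, locus]; b <- sizes[taxon_j, locus]
  if (is.na(a) || is.na(b))
    stop("intron size missing for ", locus, " in one of the taxa")
  abs(a - b)
}

#' Pearson correlation with exact t-based p-value
#'
#' Standard product-moment correlation; the two-sided p-value comes from the
#' exact t transform of r on n - 2 degrees of freedom (via
#' [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return A `correlation_result`: list with `r`, `n` and `p_value`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), n = length(x),
                 p_value = ct$p.value),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, two-sided p = %.3g)\n",
              x$r, x$n, x$p_value))
  invisible(x)
}

#' Intron-size difference vs genetic distance scatter data
#'
#' For every unordered taxon pair and every locus where both taxa have an
#' intron size, pairs the absolute intron-size difference with the taxa's
#' p-distance — the data behind the size-vs-distance relationship — and
#' computes their Pearson correlation.
#'
#' @param sizes Intron-size matrix (taxa x loci, bp, NA = missing).
#' @param pdist Square p-distance matrix over (at least) the same taxa.
#' @return List with `data` (columns `taxon_i`, `taxon_j`, `locus`,
#'   `size_difference`, `p_distance`) and `correlation`
#'   (a [pearson_cor()] result, or NULL when fewer than 3 points).
#' @export
intron_vs_distance <- function(sizes, pdist) {
  sizes <- as.matrix(sizes)
  taxa <- intersect(rownames(sizes), rownames(pdist))
  rows <- list()
  for (i in seq_along(taxa)) for (j in seq_len(i - 1L)) {
    for (locus in colnames(sizes)) {
      a <- sizes[taxa[i], locus]; b <- sizes[taxa[j], locus]
      if (is.na(a) || is.na(b)) next
      rows[[length(rows) + 1L]] <- data.frame(
        taxon_i = taxa[i], taxon_j = taxa[j], locus = locus,
        size_difference = abs(a - b),
        p_distance = pdist[taxa[i], taxa[j]], stringsAsFactors = FALSE)
    }
  }
  data <- if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon_i = character(), taxon_j = character(),
               locus = character(), size_difference = numeric(),
               p_distance = numeric(), stringsAsFactors = FALSE)
  corr <- if (nrow(data) >= 3)
    tryCatch(pearson_cor(data$size_difference, data$p_distance),
             error = function(e) NULL) else NULL
  list(data = data, correlation = corr)
}

#' Shared amplifiability vs genetic distance scatter data
#'
#' For every unordered taxon pair (diagonal excluded), pairs the
#' shared-amplifiability statistic with the taxa's p-distance and computes
#' their Pearson correlation — the basis for judging how far amplification
#' success in one taxon transfers to another.
#'
#' @param m A [presence_matrix()].
#' @param pdist Square p-distance matrix over (at least) the matrix's taxa.
#' @return List with `data` (columns `taxon_i`, `taxon_j`, `da`,
#'   `p_distance`) and `correlation` (a [pearson_cor()] result or NULL).
#' @export
amplifiability_vs_distance <- function(m, pdist) {
  stopifnot(inherits(m, "presence_matrix"))
  taxa <- intersect(rownames(m$present), rownames(pdist))
  rows <- list()
  for (i in seq_along(taxa)) for (j in seq_len(i - 1L)) {
    v <- tryCatch(amplifiability_similarity(m, taxa[i], taxa[j]),
                  error = function(e) NA_real_)
    if (is.na(v)) next
    rows[[length(rows) + 1L]] <- data.frame(
      taxon_i = taxa[i], taxon_j = taxa[j], da = v,
      p_distance = pdist[taxa[i], taxa[j]], stringsAsFactors = FALSE)
  }
  data <- if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon_i = character(), taxon_j = character(), da = numeric(),
               p_distance = numeric(), stringsAsFactors = FALSE)
  corr <- if (nrow(data) >= 3)
    tryCatch(pearson_cor(data$da, data$p_distance),
             error = function(e) NULL) else NULL
  list(data = data, correlation = corr)
}

#' Write per-locus amplification statistics as TSV
#'
#' Columns: locus, taxa tested, taxa amplified, success rate.
#'
#' @param m A [presence_matrix()].
#' @param out_path Output path.
#' @return The per-locus stats data frame, invisibly.
#' @export
write_locus_stats <- function(m, out_path) {
  stopifnot(inherits(m, "presence_matrix"))
  loci <- colnames(m$present)
  tab <- data.frame(
    locus = loci,
    n_tested = vapply(loci, function(l) sum(m$tested[, l]), integer(1)),
    n_amplified = vapply(loci, function(l) taxa_amplified(m, l), integer(1)),
    success_rate = vapply(loci, function(l) success_rate(m, l), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  write.table(tab, out_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Write a square named matrix as TSV
#'
#' Used for the pairwise shared-amplifiability and p-distance matrices.
#'
#' @param mat Square matrix with dimnames.
#' @param out_path Output path.
#' @export
write_square_matrix <- function(mat, out_path) {
  tab <- data.frame(taxon = rownames(mat), as.data.frame(unclass(mat)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, out_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_path)
}
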