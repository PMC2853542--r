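#' Alignment scoring scheme
#'
#' Parameters for the affine-gap local aligner. The defaults reproduce the
#' scoring used throughout the marker-discovery pipeline: match +1 and a
#' deliberately mild mismatch penalty of -1 (instead of the megablast-style
#' -3), so that alignments of coding exons extend across occasional
#' low-identity patches rather than fragmenting. Gap costs follow the classic
#' nucleotide-BLAST convention: a gap run of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param match Positive reward for an identical A/C/G/T pair.
#' @param mismatch Penalty (<= 0) for any non-identical pair. Any pair
#'   involving an ambiguous base (N) is charged this penalty; N never matches,
#'   not even against another N.
#' @param gap_open Non-negative cost charged once per gap run.
#' @param gap_extend Non-negative cost charged per gapped position.
#' @return A `scoring_scheme` object (a validated list).
#' @examples
#' scoring_scheme()                  # the pipeline default (+1 / -1 / 5 / 2)
#' scoring_scheme(mismatch = -3)     # the conventional stringent alternative
#' @export
scoring_scheme <- function(match = 1, mismatch = -1, gap_open = 5,
                           gap_extend = 2) {
  stopifnot(is.numeric(match), length(match) == 1, match > 0)
  stopifnot(is.numeric(mismatch), length(mismatch) == 1, mismatch <= 0)
  # accept penalties given as negative numbers; store as costs
  gap_open <- abs(gap_open)
  gap_extend <- abs(gap_extend)
  structure(
    list(match = match, mismatch = mismatch,
         gap_open = gap_open, gap_extend = gap_extend),
    class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("scoring_scheme: match %+g, mismatch %+g, gap open %g, gap extend %g\n",
              x$match, x$mismatch, x$gap_open, x$gap_extend))
  invisible(x)
}

.as_seq_string <- function(x, what = "sequence") {
  if (inherits(x, "DNAString") || inherits(x, "DNAStringSet"))
    x <- as.character(x)
  if (!is.character(x) || length(x) != 1 || is.na(x))
    stop(what, " must be a single character string or DNAString")
  x <- toupper(x)
  if (nchar(x) == 0) stop(what, " must be non-empty")
  x
}

#' Optimal affine-gap local alignment of two nucleotide sequences
#'
#' Exact Smith-Waterman dynamic programming with Gotoh affine-gap states.
#' Returns the single optimal local alignment; among co-optimal alignments
#' the engine deterministically reports the one ending earliest in the
#' dynamic-programming matrix (query position first, then subject position),
#' with traceback preferring substitution columns over gaps. A score of 0
#' (no positive-scoring pair of substrings) yields an empty alignment, not
#' an error.
#'
#' @param query,subject Nucleotide sequences (character or `DNAString`),
#'   non-empty, case-insensitive.
#' @param scoring A [scoring_scheme()].
#' @param query_id,subject_id Optional identifiers carried into the result.
#' @return A `local_alignment` object: list with `score`, 1-based inclusive
#'   `q_start`/`q_end`/`s_start`/`s_end`, `n_columns` (aligned columns,
#'   gap columns included), `n_matches`, `n_gap_columns`, and the aligned
#'   strings `q_aln`/`s_aln`.
#' @examples
#' local_align("ACGTACGT", "ACGTACGT")$score   # 8
#' local_align("ACGT", "ACGA")$score           # 3: best block is "ACG"
#' @export
local_align <- function(query, subject, scoring = scoring_scheme(),
                        query_id = NULL, subject_id = NULL) {
  stopifnot(inherits(scoring, "scoring_scheme"))
  q <- .as_seq_string(query, "query")
  s <- .as_seq_string(subject, "subject")
  res <- .sw_align_cpp(q, s, scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend)
  res$query_id <- query_id
  res$subject_id <- subject_id
  res$query_length <- nchar(q)
  res$subject_length <- nchar(s)
  class(res) <- "local_alignment"
  res
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("local_alignment: score %g, %d columns (%d matches, %d gaps)\n",
              x$score, x$n_columns, x$n_matches, x$n_gap_columns))
  if (x$n_columns > 0) {
    cat(sprintf("  query   %d..%d  %s\n", x$q_start, x$q_end, x$q_aln))
    cat(sprintf("  subject %d..%d  %s\n", x$s_start, x$s_end, x$s_aln))
  }
  invisible(x)
}

#' Identity and coverage of a local alignment
#'
#' Converts a [local_align()] result into a homology hit carrying the two
#' quantities every pipeline filter consumes: identity, the fraction of
#' identical columns over all aligned columns (gap columns count in the
#' denominator, the convention of BLAST-style tools), and coverage, the
#' fraction of the full query sequence covered by the aligned (non-gap)
#' query bases. An empty alignment yields identity 0 and coverage 0.
#'
#' @param aln A `local_alignment`.
#' @param query_len Full length of the query sequence in bp; defaults to the
#'   length recorded in `aln`.
#' @return A one-row data frame with columns `query`, `subject`, `identity`,
#'   `coverage`, `score`, `q_start`, `q_end`, `s_start`, `s_end`,
#'   `n_columns`, `n_matches`, `n_gap_columns`.
#' @export
hit_metrics <- function(aln, query_len = aln$query_length) {
  stopifnot(inherits(aln, "local_alignment"))
  if (aln$n_columns == 0) {
    identity <- 0
    coverage <- 0
    qspan <- 0L
  } else {
    qspan <- aln$q_end - aln$q_start + 1L
    if (query_len < qspan)
      stop("query_len is smaller than the aligned query span")
    identity <- aln$n_matches / aln$n_columns
    coverage <- qspan / query_len
  }
  data.frame(
    query = if (is.null(aln$query_id)) NA_character_ else aln$query_id,
    subject = if (is.null(aln$subject_id)) NA_character_ else aln$subject_id,
    identity = identity, coverage = coverage, score = aln$score,
    q_start = if (aln$n_columns) aln$q_start else NA_integer_,
    q_end = if (aln$n_columns) aln$q_end else NA_integer_,
    s_start = if (aln$n_columns) aln$s_start else NA_integer_,
    s_end = if (aln$n_columns) aln$s_end else NA_integer_,
    n_columns = aln$n_columns, n_matches = aln$n_matches,
    n_gap_columns = aln$n_gap_columns,
    stringsAsFactors = FALSE)
}

.empty_hits <- function() {
  data.frame(query = character(), subject = character(), identity = numeric(),
             coverage = numeric(), score = numeric(), q_start = integer(),
             q_end = integer(), s_start = integer(), s_end = integer(),
             n_columns = integer(), n_matches = integer(),
             n_gap_columns = integer(), stringsAsFactors = FALSE)
}

#' All-vs-all local alignment search between two segment sets
#'
#' Aligns every query segment against every subject segment and reports all
#' hits at or above `min_score`. Self-pairs (identical segment ids) are never
#' reported, so a set searched against itself yields only cross-hits — the
#' input of the single-copy filter. Hits are ordered per query by descending
#' score, ties broken by subject id.
#'
#' @param query_set,subject_set Data frames with columns `segment_id` and
#'   `seq` (see [read_genome()]); `subject_set` defaults to `query_set`.
#' @param scoring A [scoring_scheme()].
#' @param min_score Minimum alignment score to report.
#' @return A hit data frame as in [hit_metrics()].
#' @export
search_all <- function(query_set, subject_set = query_set,
                       scoring = scoring_scheme(), min_score = 0) {
  stopifnot(is.data.frame(query_set),
            all(c("segment_id", "seq") %in% names(query_set)))
  stopifnot(is.data.frame(subject_set),
            all(c("segment_id", "seq") %in% names(subject_set)))
  if (anyDuplicated(query_set$segment_id) || anyDuplicated(subject_set$segment_id))
    stop("segment ids must be unique within each set")
  if (nrow(query_set) == 0) return(.empty_hits())
  out <- vector("list", nrow(query_set) * nrow(subject_set))
  k <- 0L
  for (i in seq_len(nrow(query_set))) {
    for (j in seq_len(nrow(subject_set))) {
      if (query_set$segment_id[i] == subject_set$segment_id[j]) next
      aln <- local_align(query_set$seq[i], subject_set$seq[j], scoring,
                         query_id = query_set$segment_id[i],
                         subject_id = subject_set$segment_id[j])
      if (aln$score >= min_score && aln$n_columns > 0) {
        k <- k + 1L
        out[[k]] <- hit_metrics(aln)
      }
    }
  }
  if (k == 0L) return(.empty_hits())
  hits <- do.call(rbind, out[seq_len(k)])
  hits <- hits[order(hits$query, -hits$score, hits$subject), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write a hit table as TSV
#'
#' Stable column order: query, subject, identity, coverage, score, then the
#' query and subject spans (1-based inclusive).
#'
#' @param hits A hit data frame from [search_all()] or [hit_metrics()].
#' @param out_path Output path.
#' @export
write_hit_table <- function(hits, out_path) {
  cols <- c("query", "subject", "identity", "coverage", "score",
            "q_start", "q_end", "s_start", "s_end")
  write.table(hits[, cols, drop = FALSE], out_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(out_path)
}
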