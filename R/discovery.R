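#' Pipeline screening parameters
#'
#' The thresholds of the marker-discovery pipeline, with defaults matching
#' the standard screen: coding segments of at least 100 bp; a segment is
#' multi-copy when some other sequence in the same genome aligns to it with
#' more than 20% coverage and more than 40% identity (strict inequalities);
#' the intron must be at most 1,000 bp in at least one of the compared
#' species; flanking-exon identity averaged over the references must reach
#' one of the reporting tiers (0.65 / 0.80 / 0.85); qualifying introns within
#' 1,000 bp of each other are reported as one marker.
#'
#' @param min_cds_len Minimum CDS segment length in bp (inclusive).
#' @param copy_coverage_thresh,copy_identity_thresh Single-copy criterion:
#'   a segment is discarded iff some non-self hit has coverage strictly
#'   above `copy_coverage_thresh` AND identity strictly above
#'   `copy_identity_thresh`.
#' @param max_intron_len Intron-size screen: at most this many bp in at
#'   least one species (query included).
#' @param min_mean_identity Identity tier; the mean flanking-exon identity,
#'   rounded to 2 decimals, must be >= this value.
#' @param merge_window Maximum gap (bp) between qualifying intron regions of
#'   one gene merged into a single marker.
#' @param require_all_references If `TRUE` (default) a candidate must map to
#'   every reference; if `FALSE`, one mapped reference suffices.
#' @param marker_start_convention How the reported "Marker start (bp)" is
#'   chosen: `"upstream_exon"` (default; chromosomal start of the upstream
#'   flanking exon region) or `"intron"` (start of the first intron).
#' @return A `pipeline_params` object (validated list).
#' @export
pipeline_params <- function(min_cds_len = 100, copy_coverage_thresh = 0.20,
                            copy_identity_thresh = 0.40,
                            max_intron_len = 1000,
                            min_mean_identity = 0.85, merge_window = 1000,
                            require_all_references = TRUE,
                            marker_start_convention = c("upstream_exon", "intron")) {
  marker_start_convention <- match.arg(marker_start_convention)
  fr <- c(copy_coverage_thresh, copy_identity_thresh, min_mean_identity)
  stopifnot(all(fr >= 0 & fr <= 1), min_cds_len > 0, max_intron_len > 0,
            merge_window >= 0, is.logical(require_all_references))
  structure(list(min_cds_len = min_cds_len,
                 copy_coverage_thresh = copy_coverage_thresh,
                 copy_identity_thresh = copy_identity_thresh,
                 max_intron_len = max_intron_len,
                 min_mean_identity = min_mean_identity,
                 merge_window = merge_window,
                 require_all_references = require_all_references,
                 marker_start_convention = marker_start_convention),
            class = "pipeline_params")
}

#' Keep large CDS segments
#'
#' @param segments CDS segment data frame.
#' @param min_len Minimum length in bp, inclusive (>= keeps the boundary).
#' @return The qualifying rows, input order preserved.
#' @export
filter_large_cds <- function(segments, min_len = 100) {
  stopifnot(is.data.frame(segments), "length" %in% names(segments))
  out <- segments[segments$length >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Single-copy filter
#'
#' Removes every segment for which some non-self hit exceeds both the
#' coverage and the identity threshold (strict inequalities); all other
#' segments are kept. `self_hits` must come from an all-vs-all search of the
#' segments against themselves ([search_all()] already excludes self-pairs).
#'
#' @param segments CDS segment data frame.
#' @param self_hits Hit data frame with `query` matching segment ids.
#' @param params A [pipeline_params()].
#' @return The surviving segments.
#' @export
single_copy_filter <- function(segments, self_hits,
                               params = pipeline_params()) {
  stopifnot(is.data.frame(segments), is.data.frame(self_hits))
  if (nrow(self_hits) > 0) {
    unknown <- setdiff(unique(c(self_hits$query, self_hits$subject)),
                       segments$segment_id)
    if (length(unknown))
      stop("hits reference unknown segments: ",
           paste(utils::head(unknown, 3), collapse = ", "))
    bad <- self_hits$coverage > params$copy_coverage_thresh &
      self_hits$identity > params$copy_identity_thresh
    multi <- unique(self_hits$query[bad])
  } else multi <- character(0)
  out <- segments[!segments$segment_id %in% multi, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Best local alignment of `seq` against a whole genome (both strands).
# mode "seed": exact k-mer seeding + Smith-Waterman on merged candidate
# windows; "full": exhaustive tiled scan; "auto": seeded, falling back to the
# tiled scan when no seed fires anywhere. Subject coordinates are always on
# the forward strand of the reference chromosome.
.genome_search <- function(seq, genome, scoring = scoring_scheme(),
                           mode = c("auto", "seed", "full"), seed_k = 12) {
  mode <- match.arg(mode)
  seq <- .as_seq_string(seq)
  qlen <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  pad <- max(50L, qlen)

  seed_windows <- function(pattern, chrom_dna) {
    k <- min(seed_k, qlen)
    offs <- unique(c(seq(1L, qlen - k + 1L, by = k), qlen - k + 1L))
    starts <- integer(0); ends <- integer(0)
    for (off in offs) {
      kmer <- substr(pattern, off, off + k - 1L)
      if (grepl("N", kmer, fixed = TRUE)) next
      m <- Biostrings::matchPattern(kmer, chrom_dna)
      if (length(m) == 0) next
      s <- BiocGenerics::start(m) - off + 1L - pad
      starts <- c(starts, pmax(1L, s))
      ends <- c(ends, pmin(length(chrom_dna), s + qlen - 1L + 2L * pad))
    }
    if (!length(starts)) return(NULL)
    r <- IRanges::reduce(IRanges::IRanges(starts, ends))
    data.frame(start = BiocGenerics::start(r), end = BiocGenerics::end(r))
  }
  tile_windows <- function(chrom_dna) {
    len <- length(chrom_dna)
    size <- max(10000L, 4L * qlen)
    step <- size - 3L * qlen
    if (step <= 0) step <- size
    starts <- seq(1L, max(1L, len), by = step)
    data.frame(start = starts, end = pmin(len, starts + size - 1L))
  }

  best <- NULL
  scan <- function(use_tiles) {
    for (chrom in names(genome$chromosomes)) {
      chrom_dna <- genome$chromosomes[[chrom]]
      for (strand in c("+", "-")) {
        pattern <- if (strand == "+") seq else rc
        win <- if (use_tiles) tile_windows(chrom_dna)
               else seed_windows(pattern, chrom_dna)
        if (is.null(win)) next
        for (w in seq_len(nrow(win))) {
          subject <- as.character(Biostrings::subseq(chrom_dna, win$start[w],
                                                     win$end[w]))
          aln <- local_align(pattern, subject, scoring)
          if (aln$n_columns == 0) next
          if (is.null(best) || aln$score > best$score) {
            qs <- aln$q_start; qe <- aln$q_end
            if (strand == "-") { qs <- qlen - aln$q_end + 1L
                                 qe <- qlen - aln$q_start + 1L }
            best <<- list(score = aln$score, chromosome = chrom,
                          strand = strand,
                          q_start = qs, q_end = qe,
                          s_start = win$start[w] + aln$s_start - 1L,
                          s_end = win$start[w] + aln$s_end - 1L,
                          n_columns = aln$n_columns,
                          n_matches = aln$n_matches,
                          n_gap_columns = aln$n_gap_columns)
          }
        }
      }
    }
  }
  if (mode %in% c("auto", "seed")) scan(use_tiles = FALSE)
  if (mode == "full" || (mode == "auto" && is.null(best))) scan(use_tiles = TRUE)
  if (is.null(best)) return(NULL)
  best$identity <- best$n_matches / best$n_columns
  best$coverage <- (best$q_end - best$q_start + 1L) / qlen
  best
}

#' Map a query CDS segment onto an (annotation-free) reference genome
#'
#' Searches both strands of every reference chromosome for the best local
#' alignment of the segment and reports it as a homology hit, or `NULL` when
#' no alignment reaches `min_identity_floor`. The default engine seeds with
#' exact 12-mers and runs the Smith-Waterman engine on the candidate
#' windows; `mode = "full"` forces the exhaustive scan (the seeded path is
#' tested against it).
#'
#' @param query_segment One-row CDS segment data frame (or a bare sequence
#'   string).
#' @param reference A [genome_record()].
#' @param scoring A [scoring_scheme()].
#' @param min_identity_floor Qualifying-hit floor: a hit is reported only if
#'   both its identity and its query coverage reach this value (0 disables
#'   the floor). The joint requirement matters because any two sequences
#'   share some short, identity-rich local alignment; demanding that most of
#'   the segment aligns at the floor identity reproduces the "no qualifying
#'   hit" outcome a heuristic search engine gives for unrelated sequences.
#' @param mode Search strategy: `"auto"` (default), `"seed"`, `"full"`.
#' @return One-row data frame with `query`, `chromosome`, `strand`,
#'   `identity`, `coverage`, `score`, `q_start`, `q_end`, `s_start`,
#'   `s_end` (forward-strand reference coordinates), or `NULL`.
#' @export
map_to_reference <- function(query_segment, reference,
                             scoring = scoring_scheme(),
                             min_identity_floor = 0, mode = "auto") {
  stopifnot(inherits(reference, "genome_record"))
  if (is.data.frame(query_segment)) {
    stopifnot(nrow(query_segment) == 1)
    seq <- query_segment$seq
    qid <- query_segment$segment_id
  } else {
    seq <- query_segment
    qid <- NA_character_
  }
  hit <- .genome_search(seq, reference, scoring, mode = mode)
  if (is.null(hit) || hit$identity < min_identity_floor ||
      hit$coverage < min_identity_floor) return(NULL)
  data.frame(query = qid, chromosome = hit$chromosome, strand = hit$strand,
             identity = hit$identity, coverage = hit$coverage,
             score = hit$score, q_start = hit$q_start, q_end = hit$q_end,
             s_start = hit$s_start, s_end = hit$s_end,
             stringsAsFactors = FALSE)
}

.locus_digits <- function(gene_id) {
  d <- gsub("\\D", "", gene_id)
  if (nchar(d) >= 5) substr(d, nchar(d) - 4L, nchar(d)) else d
}

.locus_name <- function(gene_id, junction_index) {
  paste0(.locus_digits(gene_id), "E", junction_index)
}

#' Mean flanking-exon identity of a candidate
#'
#' The arithmetic mean, over the mapped references, of each reference's mean
#' identity across the two flanking-exon hits.
#'
#' @param candidate Either a one-row candidate data frame from
#'   [find_epic_candidates()] or a numeric vector of per-reference
#'   identities (`NA` = unmapped reference).
#' @return The mean identity as a fraction.
#' @export
mean_exon_identity <- function(candidate) {
  if (is.data.frame(candidate)) {
    stopifnot(nrow(candidate) == 1)
    v <- unlist(candidate[grep("^identity\\.", names(candidate))])
  } else v <- candidate
  v <- v[!is.na(v)]
  if (!length(v)) stop("candidate has no mapped references")
  mean(v)
}

#' Screen consecutive single-copy exon pairs for EPIC candidacy
#'
#' For every pair of consecutive surviving CDS segments of a gene
#' (consecutive in the gene's chromosomal segment order, both present in
#' `segments`), both flanks are mapped onto every reference genome. A
#' reference counts as mapped when both flanks hit the same chromosome and
#' strand with a positive gap between the hit intervals; that gap is the
#' reference's inferred intron length. A candidate is emitted when (a) the
#' mapping requirement of `params$require_all_references` holds, (b) the
#' intron is at most `params$max_intron_len` bp in at least one species
#' (query included), and (c) the mean flanking-exon identity (rounded to 2
#' decimals) reaches `params$min_mean_identity`.
#'
#' @param genome Query [genome_record()].
#' @param segments Surviving CDS segments (after [filter_large_cds()] and
#'   [single_copy_filter()]).
#' @param references Named list of reference [genome_record()] objects.
#' @param params A [pipeline_params()].
#' @param scoring A [scoring_scheme()].
#' @param mode Reference-search mode passed to [map_to_reference()].
#' @return Candidate data frame, one row per qualifying intron, with query
#'   coordinates, per-species intron lengths (`intron_len.<species>`),
#'   per-reference identities (`identity.<species>`) and hit spans, and
#'   `mean_identity`. Screening-stage counts are attached as the
#'   `stage_counts` attribute.
#' @export
find_epic_candidates <- function(genome, segments, references,
                                 params = pipeline_params(),
                                 scoring = scoring_scheme(), mode = "auto") {
  stopifnot(inherits(genome, "genome_record"), is.data.frame(segments))
  if (is.null(names(references)) || any(!nzchar(names(references))))
    names(references) <- vapply(references, function(r) r$genome_id, character(1))
  qlab <- genome$genome_id
  refs <- names(references)

  counts <- c(junctions = 0L, mapped = 0L, intron_size = 0L, identity = 0L)
  rows <- list()
  if (nrow(segments)) {
    # cache per-segment reference hits (a segment can flank two introns)
    hit_cache <- new.env(parent = emptyenv())
    get_hit <- function(seg_row, ref_name) {
      key <- paste0(seg_row$segment_id, "\r", ref_name)
      if (!is.null(hit_cache[[key]])) return(hit_cache[[key]])
      h <- map_to_reference(seg_row, references[[ref_name]], scoring,
                            mode = mode)
      hit_cache[[key]] <- if (is.null(h)) list(NULL) else h
      hit_cache[[key]]
    }
    for (g in split(segments, segments$gene_id)) {
      g <- g[order(g$segment_index), , drop = FALSE]
      if (nrow(g) < 2) next
      for (i in seq_len(nrow(g) - 1L)) {
        if (g$segment_index[i + 1L] != g$segment_index[i] + 1L) next
        up <- g[i, ]; down <- g[i + 1L, ]
        q_intron_len <- down$start - up$end - 1L
        if (q_intron_len < 1L) next
        counts["junctions"] <- counts["junctions"] + 1L

        intron_len <- setNames(rep(NA_real_, length(refs) + 1L), c(qlab, refs))
        intron_len[qlab] <- q_intron_len
        ident <- setNames(rep(NA_real_, length(refs)), refs)
        span <- list()
        for (rn in refs) {
          hu <- get_hit(up, rn); hd <- get_hit(down, rn)
          if (is.null(hu$chromosome) || is.null(hd$chromosome)) next
          if (hu$chromosome != hd$chromosome || hu$strand != hd$strand) next
          gap <- if (hu$s_end < hd$s_start) hd$s_start - hu$s_end - 1L
                 else if (hd$s_end < hu$s_start) hu$s_start - hd$s_end - 1L
                 else -1L
          if (gap < 1L) next
          intron_len[rn] <- gap
          ident[rn] <- (hu$identity + hd$identity) / 2
          span[[rn]] <- list(chromosome = hu$chromosome, strand = hu$strand,
                             start = min(hu$s_start, hd$s_start),
                             end = max(hu$s_end, hd$s_end))
        }
        n_mapped <- sum(!is.na(ident))
        ok_map <- if (params$require_all_references) n_mapped == length(refs)
                  else n_mapped >= 1L
        if (!ok_map) next
        counts["mapped"] <- counts["mapped"] + 1L
        if (!any(intron_len <= params$max_intron_len, na.rm = TRUE)) next
        counts["intron_size"] <- counts["intron_size"] + 1L
        mid <- mean(ident, na.rm = TRUE)
        if (round(mid, 2) < params$min_mean_identity) next
        counts["identity"] <- counts["identity"] + 1L

        row <- data.frame(
          gene_id = up$gene_id, chromosome = up$chromosome,
          strand = up$strand, gene_description = up$description,
          junction_index = up$segment_index,
          upstream_segment_id = up$segment_id,
          downstream_segment_id = down$segment_id,
          span_start = up$start, span_end = down$end,
          intron_start = up$end + 1L, intron_end = down$start - 1L,
          mean_identity = mid, stringsAsFactors = FALSE)
        for (sp in names(intron_len))
          row[[paste0("intron_len.", sp)]] <- unname(intron_len[sp])
        for (rn in refs) {
          row[[paste0("identity.", rn)]] <- unname(ident[rn])
          s <- span[[rn]]
          row[[paste0("hit_chrom.", rn)]] <- if (is.null(s)) NA_character_ else s$chromosome
          row[[paste0("hit_strand.", rn)]] <- if (is.null(s)) NA_character_ else s$strand
          row[[paste0("hit_start.", rn)]] <- if (is.null(s)) NA_integer_ else s$start
          row[[paste0("hit_end.", rn)]] <- if (is.null(s)) NA_integer_ else s$end
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  cand <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(cand)) {
    cand <- data.frame(gene_id = character(), chromosome = character(),
                       strand = character(), gene_description = character(),
                       junction_index = integer(),
                       upstream_segment_id = character(),
                       downstream_segment_id = character(),
                       span_start = integer(), span_end = integer(),
                       intron_start = integer(), intron_end = integer(),
                       mean_identity = numeric(), stringsAsFactors = FALSE)
    cand[[paste0("intron_len.", qlab)]] <- numeric(0)
    for (rn in refs) {
      cand[[paste0("intron_len.", rn)]] <- numeric(0)
      cand[[paste0("identity.", rn)]] <- numeric(0)
      cand[[paste0("hit_chrom.", rn)]] <- character(0)
      cand[[paste0("hit_strand.", rn)]] <- character(0)
      cand[[paste0("hit_start.", rn)]] <- integer(0)
      cand[[paste0("hit_end.", rn)]] <- integer(0)
    }
  }
  rownames(cand) <- NULL
  attr(cand, "query_label") <- qlab
  attr(cand, "reference_labels") <- refs
  attr(cand, "stage_counts") <- as.list(counts)
  cand
}

#' Merge nearby candidate introns into reported markers
#'
#' Candidates of the same gene whose query-genome spans lie within
#' `merge_window` bp of each other (transitively chained) are reported as a
#' single marker covering the union span. The merged mean identity is the
#' mean over constituents; per-species intron lengths are summed over
#' constituents (`NA` when any constituent lacks the species). Loci are
#' named from the last five digits of the gene id plus "E" and the
#' chromosomal-order index of the first constituent intron's upstream
#' segment. Output is sorted by chromosome then start; merging is
#' idempotent.
#'
#' @param candidates Candidate data frame from [find_epic_candidates()].
#' @param merge_window Maximum gap in bp between spans merged together.
#' @param marker_start_convention See [pipeline_params()].
#' @return Marker data frame (`locus`, `chromosome`, `strand`,
#'   `marker_start`, `span_start`, `span_end`, `gene_id`,
#'   `gene_description`, `mean_identity`, `n_introns_merged`, per-species
#'   `intron_len.*`), with a `species_spans` attribute used by
#'   [write_marker_fasta()].
#' @export
merge_nearby <- function(candidates, merge_window = 1000,
                         marker_start_convention = "upstream_exon") {
  qlab <- attr(candidates, "query_label")
  refs <- attr(candidates, "reference_labels")
  len_cols <- grep("^intron_len\\.", names(candidates), value = TRUE)
  species <- sub("^intron_len\\.", "", len_cols)

  mk_rows <- list(); span_rows <- list()
  for (g in split(candidates, candidates$gene_id)) {
    g <- g[order(g$span_start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(
      g$span_start[-1] - cummax(g$span_end)[-nrow(g)] - 1L > merge_window)))
    for (cl in split(g, grp)) {
      span_start <- min(cl$span_start); span_end <- max(cl$span_end)
      first <- cl[which.min(cl$span_start), ]
      locus <- .locus_name(first$gene_id, first$junction_index)
      row <- data.frame(
        locus = locus, chromosome = first$chromosome, strand = first$strand,
        marker_start = if (identical(marker_start_convention, "intron"))
          first$intron_start else span_start,
        span_start = span_start, span_end = span_end,
        gene_id = first$gene_id, gene_description = first$gene_description,
        mean_identity = mean(cl$mean_identity),
        n_introns_merged = nrow(cl), stringsAsFactors = FALSE)
      for (k in seq_along(len_cols)) {
        v <- cl[[len_cols[k]]]
        row[[len_cols[k]]] <- if (anyNA(v)) NA_real_ else sum(v)
      }
      mk_rows[[length(mk_rows) + 1L]] <- row
      # per-species marker spans, query first
      span_rows[[length(span_rows) + 1L]] <- data.frame(
        locus = locus, species = qlab, chromosome = first$chromosome,
        start = span_start, end = span_end, strand = first$strand,
        stringsAsFactors = FALSE)
      if (!is.null(refs)) for (rn in refs) {
        hs <- cl[[paste0("hit_start.", rn)]]
        if (is.null(hs) || anyNA(hs)) next
        if (length(unique(cl[[paste0("hit_chrom.", rn)]])) != 1L) next
        span_rows[[length(span_rows) + 1L]] <- data.frame(
          locus = locus, species = rn,
          chromosome = cl[[paste0("hit_chrom.", rn)]][1],
          start = min(hs), end = max(cl[[paste0("hit_end.", rn)]]),
          strand = cl[[paste0("hit_strand.", rn)]][1],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(mk_rows)) {
    out <- do.call(rbind, mk_rows)
    out <- out[order(out$chromosome, out$span_start), , drop = FALSE]
  } else {
    out <- data.frame(locus = character(), chromosome = character(),
                      strand = character(), marker_start = integer(),
                      span_start = integer(), span_end = integer(),
                      gene_id = character(), gene_description = character(),
                      mean_identity = numeric(), n_introns_merged = integer(),
                      stringsAsFactors = FALSE)
    for (lc in len_cols) out[[lc]] <- numeric(0)
  }
  rownames(out) <- NULL
  attr(out, "species_spans") <- if (length(span_rows))
    do.call(rbind, span_rows) else
    data.frame(locus = character(), species = character(),
               chromosome = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  attr(out, "query_label") <- qlab
  attr(out, "reference_labels") <- refs
  out
}

#' Run the whole marker-discovery pipeline
#'
#' End to end: read the annotated query genome, keep large CDS segments,
#' remove multi-copy segments by all-vs-all local alignment, map the
#' surviving exon flanks onto every reference genome, screen introns by
#' size and flanking identity, merge nearby qualifying introns, and name
#' the markers. Deterministic for fixed inputs and parameters. The run
#' report mirrors the per-stage counting of the screen (segments found,
#' large, single-copy, junctions, candidates after each screen, final
#' markers).
#'
#' @param query_fasta,query_annotation Paths to the query genome FASTA and
#'   its GFF3/GTF annotation.
#' @param reference_fastas Character vector of reference FASTA paths
#'   (names, if present, become the species labels).
#' @param params A [pipeline_params()].
#' @param scoring A [scoring_scheme()].
#' @param out_prefix Optional path prefix; when given, writes
#'   `<prefix>.markers.tsv`, `.markers.fasta`, `.markers.bed` and
#'   `.report.json`.
#' @param query_id Label for the query genome.
#' @param min_self_score Score floor for the all-vs-all self search. The
#'   default (40) plays the role of a heuristic search engine's noise
#'   cutoff: under +1/-1 scoring, chance local alignments between unrelated
#'   coding segments of a few hundred bp score well below it, while any
#'   biologically meaningful paralog hit (tens of bp at high identity)
#'   clears it easily.
#' @param mode Reference-search mode (see [map_to_reference()]).
#' @return List with `markers` (data frame) and `report` (list of stage
#'   counts, parameter echo, input checksums and timing).
#' @export
run_pipeline <- function(query_fasta, query_annotation, reference_fastas,
                         params = pipeline_params(),
                         scoring = scoring_scheme(), out_prefix = NULL,
                         query_id = sub("\\.[^.]*$", "", basename(query_fasta)),
                         min_self_score = 40, mode = "auto") {
  t0 <- Sys.time()
  q <- read_genome(query_fasta, query_annotation, genome_id = query_id)
  if (is.null(names(reference_fastas)))
    names(reference_fastas) <-
      sub("\\.[^.]*$", "", basename(reference_fastas))
  refs <- lapply(names(reference_fastas), function(nm)
    read_genome(reference_fastas[[nm]], NULL, genome_id = nm)$genome)
  names(refs) <- names(reference_fastas)

  large <- filter_large_cds(q$segments, params$min_cds_len)
  self_hits <- search_all(large, scoring = scoring, min_score = min_self_score)
  single <- single_copy_filter(large, self_hits, params)
  cand <- find_epic_candidates(q$genome, single, refs, params, scoring,
                               mode = mode)
  sc <- attr(cand, "stage_counts")
  markers <- merge_nearby(cand, params$merge_window,
                          params$marker_start_convention)

  inputs <- c(query_fasta = query_fasta, query_annotation = query_annotation,
              setNames(unlist(reference_fastas),
                       paste0("reference.", names(reference_fastas))))
  report <- list(
    counts = list(
      cds_segments = nrow(q$segments),
      large_cds = nrow(large),
      single_copy_cds = nrow(single),
      junctions_screened = sc$junctions,
      candidates_mapped = sc$mapped,
      candidates_intron_size = sc$intron_size,
      candidates_identity = sc$identity,
      markers = nrow(markers)),
    params = unclass(params),
    scoring = unclass(scoring),
    inputs = as.list(unname(Map(function(n, p) list(path = p,
                        md5 = unname(tools::md5sum(p))),
                      names(inputs), inputs))),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(out_prefix)) {
    write_marker_table(markers, paste0(out_prefix, ".markers.tsv"))
    genomes <- c(setNames(list(q$genome), query_id), refs)
    write_marker_fasta(markers, genomes, paste0(out_prefix, ".markers.fasta"))
    write_marker_bed(markers, paste0(out_prefix, ".markers.bed"))
    jsonlite::write_json(report, paste0(out_prefix, ".report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(markers = markers, report = report)
}
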