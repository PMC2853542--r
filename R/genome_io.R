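#' Construct a genome record
#'
#' A lightweight container for one genome: a short id plus its chromosome
#' sequences. Sequences are uppercased and any character outside A/C/G/T/N
#' is mapped to N, so downstream alignment sees a clean alphabet.
#'
#' @param genome_id Short label for the genome (e.g. a species tag).
#' @param seqs Named `DNAStringSet` or named character vector of chromosome
#'   sequences; names must be unique and sequences non-empty.
#' @return A `genome_record`: list with `genome_id` and `chromosomes`
#'   (a `DNAStringSet`).
#' @export
genome_record <- function(genome_id, seqs) {
  stopifnot(is.character(genome_id), length(genome_id) == 1, nzchar(genome_id))
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  stopifnot(methods::is(seqs, "DNAStringSet"))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all chromosomes must be named")
  if (anyDuplicated(names(seqs))) stop("chromosome ids must be unique")
  if (any(Biostrings::width(seqs) == 0)) stop("chromosome sequences must be non-empty")
  # collapse the alphabet: anything outside ACGTN becomes N
  chr <- toupper(as.character(seqs))
  chr <- vapply(chr, function(x) gsub("[^ACGTN]", "N", x), character(1),
                USE.NAMES = FALSE)
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(seqs)
  structure(list(genome_id = genome_id, chromosomes = out),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("genome_record '%s': %d chromosome(s), %s bp total\n",
              x$genome_id, length(x$chromosomes),
              format(sum(Biostrings::width(x$chromosomes)), big.mark = ",")))
  invisible(x)
}

.empty_segments <- function() {
  data.frame(gene_id = character(), chromosome = character(),
             strand = character(), description = character(),
             segment_index = integer(), segment_id = character(),
             start = integer(), end = integer(), length = integer(),
             seq = character(), stringsAsFactors = FALSE)
}

# Resolve CDS -> gene linkage for GFF3 (ID/Parent hierarchy) and GTF
# (gene_id/transcript_id attributes). Returns a data.frame with one row per
# CDS feature: gene_id, transcript_id, chromosome, start, end, strand.
.annotation_cds_table <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  is_gtf <- "gene_id" %in% names(mc) && !"Parent" %in% names(mc)
  type <- as.character(mc$type)
  cds <- gr[type == "CDS"]
  if (length(cds) == 0) stop("annotation contains no CDS features")
  if (is_gtf) {
    tab <- data.frame(
      gene_id = as.character(S4Vectors::mcols(cds)$gene_id),
      transcript_id = as.character(S4Vectors::mcols(cds)$transcript_id),
      chromosome = as.character(GenomicRanges::seqnames(cds)),
      start = GenomicRanges::start(cds), end = GenomicRanges::end(cds),
      strand = as.character(GenomicRanges::strand(cds)),
      stringsAsFactors = FALSE)
    gene_desc <- setNames(character(0), character(0))
  } else {
    # GFF3: CDS Parent is usually an mRNA/transcript whose Parent is the gene;
    # tolerate CDS parented directly to a gene.
    ids <- as.character(mc$ID)
    parents <- vapply(as.list(mc$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
    feat_parent <- setNames(parents, ids)
    gene_ids <- ids[type == "gene"]
    cds_parent <- vapply(as.list(S4Vectors::mcols(cds)$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
    if (anyNA(cds_parent)) stop("CDS features without Parent attribute")
    to_gene <- function(p) {
      seen <- character(0)
      while (!(p %in% gene_ids) && p %in% names(feat_parent) &&
             !is.na(feat_parent[[p]]) && !(p %in% seen)) {
        seen <- c(seen, p)
        p <- feat_parent[[p]]
      }
      p
    }
    tab <- data.frame(
      gene_id = vapply(cds_parent, to_gene, character(1), USE.NAMES = FALSE),
      transcript_id = cds_parent,
      chromosome = as.character(GenomicRanges::seqnames(cds)),
      start = GenomicRanges::start(cds), end = GenomicRanges::end(cds),
      strand = as.character(GenomicRanges::strand(cds)),
      stringsAsFactors = FALSE)
    desc_col <- intersect(c("description", "Note", "product"), names(mc))
    gene_desc <- character(0)
    if (length(desc_col)) {
      genes <- gr[type == "gene"]
      d <- S4Vectors::mcols(genes)[[desc_col[1]]]
      d <- vapply(as.list(d), function(x)
        if (length(x) && !is.na(x[[1]])) as.character(x[[1]]) else "", character(1))
      gene_desc <- setNames(d, as.character(S4Vectors::mcols(genes)$ID))
    }
  }
  attr(tab, "gene_desc") <- gene_desc
  tab
}

#' Read a genome and (optionally) its gene annotation
#'
#' Loads a FASTA genome and, when an annotation is supplied, builds gene
#' models from its CDS features: one segment per CDS feature line, ordered by
#' ascending chromosomal coordinate regardless of strand, with the segment
#' sequence extracted in transcription orientation (reverse-complemented for
#' minus-strand genes). When a gene has several transcripts, the transcript
#' with the largest total CDS length is used (ties broken by transcript id).
#' Genes without any CDS feature are dropped (a message reports the count);
#' genes whose CDS reference an unknown chromosome are skipped with a
#' warning. Reference genomes are typically read annotation-free.
#'
#' @param fasta_path Path to a (multi-)FASTA file.
#' @param annotation_path Optional path to a GFF3 or GTF annotation with CDS
#'   features; `NULL` for annotation-free genomes.
#' @param genome_id Genome label; defaults to the FASTA file name stem.
#' @return A list with `genome` (a [genome_record()]) and `segments`, a data
#'   frame of CDS segments with columns `gene_id`, `chromosome`, `strand`,
#'   `description`, `segment_index`, `segment_id`, `start`, `end`, `length`,
#'   `seq` (1-based inclusive coordinates). Annotation-free reads return an
#'   empty `segments` frame.
#' @export
read_genome <- function(fasta_path, annotation_path = NULL,
                        genome_id = sub("\\.[^.]*$", "", basename(fasta_path))) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome <- genome_record(genome_id, seqs)
  if (is.null(annotation_path))
    return(list(genome = genome, segments = .empty_segments()))
  if (!file.exists(annotation_path))
    stop("annotation file not found: ", annotation_path)
  gr <- rtracklayer::import(annotation_path)
  cds <- .annotation_cds_table(gr)
  gene_desc <- attr(cds, "gene_desc")

  # count genes present in the annotation but contributing no CDS
  type <- as.character(S4Vectors::mcols(gr)$type)
  if ("ID" %in% names(S4Vectors::mcols(gr))) {
    ann_genes <- as.character(S4Vectors::mcols(gr)$ID[type == "gene"])
    n_dropped <- sum(!ann_genes %in% cds$gene_id)
    if (n_dropped > 0)
      message(n_dropped, " gene(s) without CDS features dropped")
  }

  segs_list <- lapply(split(cds, cds$gene_id), function(g) {
    if (!all(g$chromosome[1] == g$chromosome) ||
        !all(g$strand[1] == g$strand)) {
      warning("gene ", g$gene_id[1],
              " has CDS on multiple chromosomes/strands; skipped")
      return(NULL)
    }
    if (!g$chromosome[1] %in% names(genome$chromosomes)) {
      warning("gene ", g$gene_id[1], " references unknown chromosome ",
              g$chromosome[1], "; skipped")
      return(NULL)
    }
    # longest-CDS transcript
    tx_len <- tapply(g$end - g$start + 1, g$transcript_id, sum)
    best_tx <- names(tx_len)[order(-tx_len, names(tx_len))][1]
    g <- g[g$transcript_id == best_tx, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (any(g$start[-1] <= g$end[-nrow(g)] & nrow(g) > 1))
      warning("gene ", g$gene_id[1], " has overlapping CDS segments")
    chrom_seq <- genome$chromosomes[[g$chromosome[1]]]
    seqs <- vapply(seq_len(nrow(g)), function(i) {
      s <- Biostrings::subseq(chrom_seq, g$start[i], g$end[i])
      if (g$strand[1] == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, character(1))
    desc <- if (g$gene_id[1] %in% names(gene_desc))
      gene_desc[[g$gene_id[1]]] else ""
    data.frame(
      gene_id = g$gene_id[1], chromosome = g$chromosome[1],
      strand = g$strand[1], description = desc,
      segment_index = seq_len(nrow(g)),
      segment_id = paste0(g$gene_id[1], ".", seq_len(nrow(g))),
      start = g$start, end = g$end, length = g$end - g$start + 1L,
      seq = seqs, stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, segs_list)
  if (is.null(segs)) segs <- .empty_segments()
  rownames(segs) <- NULL
  list(genome = genome, segments = segs)
}

#' Derive intron coordinates from a gene's CDS segments
#'
#' Introns are the gaps between consecutive CDS segments in chromosomal
#' order; a gene with k segments has at most k - 1 introns. Abutting
#' segments (zero-length gap) produce no intron and raise a warning;
#' single-segment genes return an empty frame.
#'
#' @param segments CDS segment data frame as returned by [read_genome()];
#'   may contain one or several genes.
#' @return Data frame with columns `gene_id`, `chromosome`,
#'   `upstream_segment_index` (chromosomal-order ordinal of the 5'-adjacent
#'   segment), `start`, `end`, `length` (1-based inclusive).
#' @examples
#' segs <- data.frame(gene_id = "g1", chromosome = "chr1", strand = "+",
#'                    description = "", segment_index = 1:2,
#'                    segment_id = c("g1.1", "g1.2"),
#'                    start = c(100L, 351L), end = c(250L, 500L),
#'                    length = c(151L, 150L), seq = c("A", "A"))
#' infer_introns(segs)  # one intron, [251..350], length 100
#' @export
infer_introns <- function(segments) {
  stopifnot(is.data.frame(segments))
  empty <- data.frame(gene_id = character(), chromosome = character(),
                      upstream_segment_index = integer(), start = integer(),
                      end = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(segments) == 0) return(empty)
  out <- lapply(split(segments, segments$gene_id), function(g) {
    g <- g[order(g$segment_index), , drop = FALSE]
    if (nrow(g) < 2) return(NULL)
    up_end <- g$end[-nrow(g)]
    down_start <- g$start[-1]
    len <- down_start - up_end - 1L
    if (any(len == 0))
      warning("gene ", g$gene_id[1], ": abutting CDS segments, intron omitted")
    if (any(len < 0))
      warning("gene ", g$gene_id[1], ": overlapping CDS segments, intron omitted")
    keep <- len >= 1L
    if (!any(keep)) return(NULL)
    data.frame(gene_id = g$gene_id[1], chromosome = g$chromosome[1],
               upstream_segment_index = g$segment_index[-nrow(g)][keep],
               start = up_end[keep] + 1L, end = down_start[keep] - 1L,
               length = len[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Write the marker catalogue as TSV
#'
#' One row per marker, ordered by chromosome then start, with the catalogue
#' schema: Locus, Chromosome, Marker start (bp), Gene description, mean exon
#' identity, number of merged introns, then one intron-length column per
#' species. An empty marker set writes a header-only file.
#'
#' @param markers Marker data frame from [merge_nearby()] or [run_pipeline()].
#' @param out_path Output path.
#' @export
write_marker_table <- function(markers, out_path) {
  len_cols <- grep("^intron_len\\.", names(markers), value = TRUE)
  species <- sub("^intron_len\\.", "", len_cols)
  tab <- data.frame(
    Locus = markers$locus, Chromosome = markers$chromosome,
    `Marker start (bp)` = markers$marker_start,
    `Gene description` = markers$gene_description,
    `Mean exon identity` = round(markers$mean_identity, 4),
    `Introns merged` = markers$n_introns_merged,
    check.names = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(species))
    tab[[paste0("Intron size ", species[i], " (bp)")]] <- markers[[len_cols[i]]]
  ord <- order(tab$Chromosome, tab$`Marker start (bp)`)
  write.table(tab[ord, , drop = FALSE], out_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(out_path)
}

#' Write marker regions as FASTA, one record per marker per species
#'
#' Each record spans the upstream flanking exon through the downstream
#' flanking exon, intron(s) included. The query-genome span comes from the
#' marker coordinates; reference spans come from the mapped flanking-hit
#' intervals stored with the marker set. Headers encode
#' `locus|species|chromosome:start-end(strand)`. Markers whose span falls
#' outside the chromosome are skipped with a warning.
#'
#' @param markers Marker data frame (with its `species_spans` attribute) from
#'   [merge_nearby()] or [run_pipeline()].
#' @param genomes Named list of [genome_record()] objects; names are species
#'   labels matching the span table (the query genome included).
#' @param out_path Output FASTA path.
#' @export
write_marker_fasta <- function(markers, genomes, out_path) {
  spans <- attr(markers, "species_spans")
  if (is.null(spans))
    stop("markers carry no species span table (attribute 'species_spans')")
  recs <- character(0)
  hdrs <- character(0)
  for (i in seq_len(nrow(spans))) {
    sp <- spans$species[i]
    if (!sp %in% names(genomes)) next
    g <- genomes[[sp]]
    if (!spans$chromosome[i] %in% names(g$chromosomes)) {
      warning("marker ", spans$locus[i], ": unknown chromosome in ", sp)
      next
    }
    chrom <- g$chromosomes[[spans$chromosome[i]]]
    if (spans$start[i] < 1 || spans$end[i] > length(chrom)) {
      warning("marker ", spans$locus[i], ": span out of bounds in ", sp,
              "; skipped")
      next
    }
    s <- Biostrings::subseq(chrom, spans$start[i], spans$end[i])
    if (spans$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    recs <- c(recs, as.character(s))
    hdrs <- c(hdrs, sprintf("%s|%s|%s:%d-%d(%s)", spans$locus[i], sp,
                            spans$chromosome[i], spans$start[i], spans$end[i],
                            spans$strand[i]))
  }
  out <- Biostrings::DNAStringSet(recs)
  names(out) <- hdrs
  Biostrings::writeXStringSet(out, out_path)
  invisible(out_path)
}

#' Write marker intervals as BED6 on the query genome
#'
#' Standard BED convention: 0-based half-open intervals; the score column
#' carries the mean exon identity scaled to 0-1000.
#'
#' @param markers Marker data frame.
#' @param out_path Output path.
#' @export
write_marker_bed <- function(markers, out_path) {
  if (nrow(markers) == 0) {
    writeLines(character(0), out_path)
    return(invisible(out_path))
  }
  bed <- data.frame(markers$chromosome, markers$span_start - 1L,
                    markers$span_end, markers$locus,
                    as.integer(round(markers$mean_identity * 1000)),
                    markers$strand)
  ord <- order(bed[[1]], bed[[2]])
  write.table(bed[ord, ], out_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(out_path)
}
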