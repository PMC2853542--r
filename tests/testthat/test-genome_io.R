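test_that("reading a genome with annotation builds clean gene models", {
  dir <- withr::local_tempdir()
  toy <- write_toy_genome(dir)
  expect_warning(
    expect_message(res <- read_genome(toy$fasta, toy$gff, genome_id = "toy"),
                   "without CDS"),
    "unknown chromosome")

  expect_s3_class(res$genome, "genome_record")
  expect_named(res$genome$chromosomes, c("chrA", "chrB"))
  expect_setequal(unique(res$segments$gene_id), c("gA", "gB", "gC", "gE"))

  gA <- res$segments[res$segments$gene_id == "gA", ]
  expect_equal(gA$start, c(101L, 351L, 801L))
  expect_equal(gA$length, c(150L, 150L, 150L))
  expect_equal(gA$description, rep("alpha-type toy gene", 3))
  expect_equal(gA$seq[1], substr(toy$chrA, 101, 250))
})

test_that("minus-strand segments are chromosomally ordered with reverse-complement sequences", {
  dir <- withr::local_tempdir()
  toy <- write_toy_genome(dir)
  res <- suppressWarnings(suppressMessages(
    read_genome(toy$fasta, toy$gff, genome_id = "toy")))
  gB <- res$segments[res$segments$gene_id == "gB", ]
  # ascending chromosomal order despite descending order in the file
  expect_equal(gB$start, c(1001L, 1151L, 1301L))
  expect_equal(gB$segment_index, 1:3)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(gB$seq[1], rc(substr(toy$chrA, 1001, 1100)))
  expect_equal(gB$seq[3], rc(substr(toy$chrA, 1301, 1400)))
})

test_that("annotation-free references yield an empty gene list", {
  dir <- withr::local_tempdir()
  toy <- write_toy_genome(dir)
  res <- read_genome(toy$fasta)
  expect_equal(nrow(res$segments), 0L)
  expect_length(res$genome$chromosomes, 2L)
  expect_error(read_genome(file.path(dir, "nope.fa")), "not found")
})

test_that("non-ACGTN characters collapse to N and alignment treats N as mismatch", {
  g <- genome_record("x", c(chr1 = "ACGTRYSWacgt"))
  expect_equal(as.character(g$chromosomes[[1]]), "ACGTNNNNACGT")
  # N never matches, not even N vs N
  expect_equal(local_align("ACGTACGT", "ACGTNCGT")$n_matches, 7L)
  expect_equal(local_align("NNNNN", "NNNNN")$score, 0)
})

test_that("intron inference reproduces hand-computed gaps on the toy annotation", {
  dir <- withr::local_tempdir()
  toy <- write_toy_genome(dir)
  res <- suppressWarnings(suppressMessages(
    read_genome(toy$fasta, toy$gff, genome_id = "toy")))
  introns <- infer_introns(res$segments)

  gA <- introns[introns$gene_id == "gA", ]
  expect_equal(gA$start, c(251L, 501L))
  expect_equal(gA$end, c(350L, 800L))
  expect_equal(gA$length, c(100L, 300L))
  expect_equal(gA$upstream_segment_index, c(1L, 2L))

  expect_equal(introns[introns$gene_id == "gB", "length"], c(50L, 50L))
  expect_equal(introns[introns$gene_id == "gE", "length"], 100L)
  # single-exon gene contributes no junction
  expect_false("gC" %in% introns$gene_id)

  # per-gene totals: sum of CDS + intron lengths equals the gene span
  for (gid in c("gA", "gB", "gE")) {
    segs <- res$segments[res$segments$gene_id == gid, ]
    ins <- introns[introns$gene_id == gid, ]
    expect_equal(sum(segs$length) + sum(ins$length),
                 max(segs$end) - min(segs$start) + 1L)
  }
})

test_that("abutting segments omit the intron with a warning", {
  segs <- data.frame(gene_id = "g", chromosome = "c", strand = "+",
                     description = "", segment_index = 1:2,
                     segment_id = c("g.1", "g.2"),
                     start = c(1L, 101L), end = c(100L, 200L),
                     length = c(100L, 100L), seq = c("A", "A"),
                     stringsAsFactors = FALSE)
  expect_warning(out <- infer_introns(segs), "abutting")
  expect_equal(nrow(out), 0L)
})

test_that("intron lengths are invariant under a whole-gene strand flip", {
  dir <- withr::local_tempdir()
  toy <- write_toy_genome(dir)
  res <- suppressWarnings(suppressMessages(
    read_genome(toy$fasta, toy$gff, genome_id = "toy")))
  chr_len <- nchar(toy$chrA)
  for (gid in c("gA", "gB")) {
    segs <- res$segments[res$segments$gene_id == gid, ]
    flipped <- segs
    flipped$start <- chr_len - segs$end + 1L
    flipped$end <- chr_len - segs$start + 1L
    flipped$strand <- ifelse(segs$strand == "+", "-", "+")
    flipped <- flipped[order(flipped$start), ]
    flipped$segment_index <- seq_len(nrow(flipped))
    expect_setequal(infer_introns(flipped)$length,
                    infer_introns(segs)$length)
  }
})

test_that("marker catalogue TSV has the documented schema and ordering", {
  cand <- rbind(make_candidates("ENSDARG00000059107",
                                cbind(5000L, 5400L), junction = 2L),
                make_candidates("gene00042", cbind(300L, 700L), junction = 1L))
  attr(cand, "query_label") <- "query"
  attr(cand, "reference_labels") <- character(0)
  mk <- merge_nearby(cand, 1000)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_marker_table(mk, path)
  lines <- readLines(path)
  expect_length(lines, 3L)  # header + 2 markers
  # locus names like 59107E2 are valid E-notation; force character
  tab <- read.delim(path, check.names = FALSE,
                    colClasses = c(Locus = "character"))
  expect_equal(names(tab)[1:4],
               c("Locus", "Chromosome", "Marker start (bp)",
                 "Gene description"))
  # naming rule: last five digits of the gene id + junction ordinal
  expect_true("59107E2" %in% tab$Locus)
  expect_true("00042E1" %in% tab$Locus)
  expect_equal(tab$`Marker start (bp)`, sort(tab$`Marker start (bp)`))

  # empty catalogue still writes the header
  e <- make_candidates("g", cbind(100L, 200L))[0, , drop = FALSE]
  attr(e, "query_label") <- "query"
  attr(e, "reference_labels") <- character(0)
  empty <- merge_nearby(e, 1000)
  write_marker_table(empty, path)
  expect_length(readLines(path), 1L)
})

test_that("marker FASTA spans flank-to-flank and round-trips intron lengths", {
  set.seed(99)
  chrom <- random_dna(1000)
  genome <- genome_record("query", c(chr1 = chrom))
  cand <- make_candidates("gene12345", cbind(100L, 500L))
  mk <- merge_nearby(cand, 1000)
  path <- withr::local_tempfile(fileext = ".fa")
  write_marker_fasta(mk, list(query = genome), path)
  recs <- Biostrings::readDNAStringSet(path)
  expect_length(recs, 1L)
  expect_equal(unname(Biostrings::width(recs)), 401L)
  expect_equal(as.character(recs[[1]]), substr(chrom, 100, 500))

  # out-of-bounds marker is skipped with a warning
  bad <- merge_nearby(make_candidates("gene9", cbind(900L, 1200L)), 1000)
  expect_warning(write_marker_fasta(bad, list(query = genome), path),
                 "out of bounds")
})

test_that("BED export is 0-based half-open", {
  mk <- merge_nearby(make_candidates("gene12345", cbind(100L, 500L)), 1000)
  path <- withr::local_tempfile(fileext = ".bed")
  write_marker_bed(mk, path)
  bed <- read.delim(path, header = FALSE,
                    colClasses = c(V4 = "character"))
  expect_equal(bed$V2, 99L)
  expect_equal(bed$V3, 500L)
  expect_equal(bed$V4, "12345E1")
})
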