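# Writes a small hand-specified genome + GFF3 annotation into `dir` and
# returns the paths together with the expectations the files encode.
# Layout (1-based inclusive):
#   chrA (2000 bp):
#     gA (+): CDS [101..250], [351..500], [801..950]
#             -> introns [251..350] (100 bp), [501..800] (300 bp)
#     gB (-): CDS [1001..1100], [1151..1250], [1301..1400], listed in
#             descending order in the file -> introns 50 bp, 50 bp
#     gC (+): single CDS [1501..1650] -> no introns
#     gD    : gene feature without any CDS (must be dropped)
#   chrB (600 bp):
#     gE (+): CDS [11..160], [261..410] -> intron [161..260] (100 bp)
#   gZ     : CDS on unknown chromosome chrZ (gene must be skipped)
write_toy_genome <- function(dir) {
  set.seed(424241)
  chrA <- random_dna(2000)
  chrB <- random_dna(600)
  fa <- file.path(dir, "toy.fa")
  writeLines(c(">chrA extra words in header", chrA, ">chrB", chrB), fa)

  gff <- file.path(dir, "toy.gff3")
  g <- function(chrom, src, type, start, end, strand, attrs)
    paste(chrom, src, type, start, end, ".", strand, ".", attrs, sep = "\t")
  lines <- c(
    "##gff-version 3",
    g("chrA", "toy", "gene", 101, 950, "+",
      "ID=gA;description=alpha-type toy gene"),
    g("chrA", "toy", "mRNA", 101, 950, "+", "ID=gA.t1;Parent=gA"),
    g("chrA", "toy", "CDS", 101, 250, "+", "ID=gA.c1;Parent=gA.t1"),
    g("chrA", "toy", "CDS", 351, 500, "+", "ID=gA.c2;Parent=gA.t1"),
    g("chrA", "toy", "CDS", 801, 950, "+", "ID=gA.c3;Parent=gA.t1"),
    g("chrA", "toy", "gene", 1001, 1400, "-", "ID=gB;description=beta toy"),
    g("chrA", "toy", "mRNA", 1001, 1400, "-", "ID=gB.t1;Parent=gB"),
    # deliberately listed in descending coordinate order
    g("chrA", "toy", "CDS", 1301, 1400, "-", "ID=gB.c3;Parent=gB.t1"),
    g("chrA", "toy", "CDS", 1151, 1250, "-", "ID=gB.c2;Parent=gB.t1"),
    g("chrA", "toy", "CDS", 1001, 1100, "-", "ID=gB.c1;Parent=gB.t1"),
    g("chrA", "toy", "gene", 1501, 1650, "+", "ID=gC"),
    g("chrA", "toy", "mRNA", 1501, 1650, "+", "ID=gC.t1;Parent=gC"),
    g("chrA", "toy", "CDS", 1501, 1650, "+", "ID=gC.c1;Parent=gC.t1"),
    g("chrA", "toy", "gene", 1700, 1800, "+", "ID=gD;description=no CDS here"),
    g("chrB", "toy", "gene", 11, 410, "+", "ID=gE"),
    g("chrB", "toy", "mRNA", 11, 410, "+", "ID=gE.t1;Parent=gE"),
    g("chrB", "toy", "CDS", 11, 160, "+", "ID=gE.c1;Parent=gE.t1"),
    g("chrB", "toy", "CDS", 261, 410, "+", "ID=gE.c2;Parent=gE.t1"),
    g("chrZ", "toy", "gene", 1, 200, "+", "ID=gZ"),
    g("chrZ", "toy", "mRNA", 1, 200, "+", "ID=gZ.t1;Parent=gZ"),
    g("chrZ", "toy", "CDS", 1, 200, "+", "ID=gZ.c1;Parent=gZ.t1"))
  writeLines(lines, gff)
  list(fasta = fa, gff = gff, chrA = chrA, chrB = chrB)
}

# Noise-free 5-species preset: exact exon copies and unperturbed intron
# lengths, so realized identities are all 1 and the truth set is exact.
noise_free_config <- function(seed, n_genes = 20, n_species = 5,
                              n_duplicated_genes = 2) {
  simulation_config(
    n_species = n_species, n_genes = n_genes,
    n_duplicated_genes = n_duplicated_genes,
    exon_substitution_rate = 0, intron_substitution_rate = 0,
    intron_indel_rate = 0, seed = seed)
}

# Minimal candidate table (the merge operation's input contract) for
# merge tests: one gene, arbitrary spans.
make_candidates <- function(gene_id, spans, junction = seq_len(nrow(spans)),
                            identity = 0.9, query_label = "query") {
  df <- data.frame(
    gene_id = gene_id, chromosome = "chr1", strand = "+",
    gene_description = "toy", junction_index = junction,
    upstream_segment_id = paste0(gene_id, ".", junction),
    downstream_segment_id = paste0(gene_id, ".", junction + 1L),
    span_start = spans[, 1], span_end = spans[, 2],
    intron_start = spans[, 1] + 10L, intron_end = spans[, 2] - 10L,
    mean_identity = identity, stringsAsFactors = FALSE)
  df[[paste0("intron_len.", query_label)]] <-
    as.numeric(spans[, 2] - spans[, 1] - 19L)
  attr(df, "query_label") <- query_label
  attr(df, "reference_labels") <- character(0)
  df
}
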