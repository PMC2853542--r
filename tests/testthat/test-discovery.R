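make_segs <- function(ids, seqs, lens = nchar(seqs)) {
  data.frame(segment_id = ids, seq = seqs, length = lens,
             stringsAsFactors = FALSE)
}

test_that("large-CDS filter keeps the >= 100 bp boundary inclusive", {
  segs <- data.frame(segment_id = c("a", "b", "c"),
                     length = c(99L, 100L, 101L))
  kept <- filter_large_cds(segs, 100)
  expect_equal(kept$segment_id, c("b", "c"))
  expect_equal(nrow(filter_large_cds(segs[0, ], 100)), 0L)
  set.seed(4)
  lens <- sample(50:300, 20)
  many <- data.frame(segment_id = paste0("s", 1:20), length = lens)
  expect_equal(nrow(filter_large_cds(many, 100)), sum(lens >= 100))
})

test_that("single-copy criterion uses strict > on both thresholds", {
  segs <- data.frame(segment_id = c("x", "y"), length = c(100L, 100L))
  hit <- function(cov, id) data.frame(query = "x", subject = "y",
                                      identity = id, coverage = cov,
                                      score = 50)
  # identity not above 0.40 -> kept
  expect_equal(single_copy_filter(segs, hit(0.25, 0.35))$segment_id,
               c("x", "y"))
  # boundary values are not "more than" -> kept
  expect_equal(single_copy_filter(segs, hit(0.20, 0.40))$segment_id,
               c("x", "y"))
  # both exceeded -> x removed, y (no hit as query) kept
  expect_equal(single_copy_filter(segs, hit(0.25, 0.45))$segment_id, "y")
  expect_error(
    single_copy_filter(segs, data.frame(query = "zz", subject = "y",
                                        identity = 1, coverage = 1,
                                        score = 9)),
    "unknown segments")
})

test_that("planted duplicates are removed and true singles survive", {
  cfg <- noise_free_config(seed = 1302, n_genes = 13, n_species = 2,
                           n_duplicated_genes = 3)
  sim <- simulate_genome_set(cfg)
  segs <- filter_large_cds(sim$query$segments, 100)
  hits <- search_all(segs, min_score = 40)
  single <- single_copy_filter(segs, hits)
  surviving_genes <- unique(single$gene_id)
  dup_genes <- sprintf("gene%05d", 100 + 1:3)
  singles <- sprintf("gene%05d", 100 + 4:13)
  expect_setequal(surviving_genes, setdiff(unique(segs$gene_id),
                                           c(dup_genes, paste0("dup", dup_genes))))
  expect_true(all(singles %in% surviving_genes))

  # perturbation: dropping a planted paralog restores its partner
  partner <- dup_genes[1]
  kept <- segs[segs$gene_id != paste0("dup", partner), ]
  hits2 <- search_all(kept, min_score = 40)
  single2 <- single_copy_filter(kept, hits2)
  expect_true(partner %in% unique(single2$gene_id))
})

test_that("reference mapping finds planted exons at the planted locus", {
  set.seed(21)
  exon <- random_dna(180)
  ref <- genome_record("ref", c(chr1 = paste0(random_dna(500), exon,
                                              random_dna(500))))
  hit <- map_to_reference(exon, ref)
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$s_start, 501L)
  expect_equal(hit$s_end, 680L)
  expect_equal(hit$strand, "+")

  # ~90% identical copy still maps to the same locus
  mut <- mutate_sequence(exon, 0.1)
  ref2 <- genome_record("ref2", c(chr1 = paste0(random_dna(500), mut,
                                                random_dna(500))))
  hit2 <- map_to_reference(exon, ref2)
  expect_true(hit2$identity >= 0.85 && hit2$identity <= 0.98)
  expect_true(hit2$s_start >= 450 && hit2$s_end <= 730)

  # a sequence absent from the reference does not clear an identity floor
  expect_null(map_to_reference(random_dna(180), ref,
                               min_identity_floor = 0.5))

  # minus-strand copies are found with forward-strand coordinates
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(exon)))
  ref3 <- genome_record("ref3", c(chr1 = paste0(random_dna(300), rc,
                                                random_dna(300))))
  hit3 <- map_to_reference(exon, ref3)
  expect_equal(hit3$strand, "-")
  expect_equal(hit3$s_start, 301L)
  expect_equal(hit3$identity, 1.0)
})

test_that("seeded reference search matches the exhaustive scan", {
  set.seed(33)
  exon <- random_dna(150)
  mut <- mutate_sequence(exon, 0.08)
  ref <- genome_record("r", c(c1 = paste0(random_dna(2000), mut,
                                          random_dna(2000)),
                              c2 = random_dna(1500)))
  fast <- map_to_reference(exon, ref, mode = "seed")
  full <- map_to_reference(exon, ref, mode = "full")
  expect_equal(fast$score, full$score)
  expect_equal(fast$s_start, full$s_start)
  expect_equal(fast$chromosome, full$chromosome)
})

test_that("candidate screening applies the intron-size and identity rules", {
  set.seed(8)
  up <- random_dna(150); down <- random_dna(150)
  mkref <- function(intron_len, id, rate = 0) {
    u <- if (rate > 0) mutate_sequence(up, rate) else up
    d <- if (rate > 0) mutate_sequence(down, rate) else down
    genome_record(id, c(chr1 = paste0(random_dna(200), u,
                                      random_dna(intron_len), d,
                                      random_dna(200))))
  }
  qchrom <- paste0(random_dna(100), up, random_dna(300), down, random_dna(100))
  query <- genome_record("query", c(chr1 = qchrom))
  segs <- data.frame(gene_id = "gene00007", chromosome = "chr1", strand = "+",
                     description = "toy", segment_index = 1:2,
                     segment_id = c("gene00007.1", "gene00007.2"),
                     start = c(101L, 551L), end = c(250L, 700L),
                     length = c(150L, 150L), seq = c(up, down),
                     stringsAsFactors = FALSE)

  # intron <= 1000 in at least one species (the query's 300 bp qualifies)
  refs <- list(r1 = mkref(1500, "r1"), r2 = mkref(1200, "r2"))
  cand <- find_epic_candidates(query, segs, refs, pipeline_params())
  expect_equal(nrow(cand), 1L)
  expect_equal(cand[["intron_len.query"]], 300)
  expect_equal(cand[["intron_len.r1"]], 1500)
  expect_equal(cand$mean_identity, 1.0)

  # no species at or under the cap -> no candidate
  long_q <- genome_record("query", c(chr1 = paste0(
    random_dna(100), up, random_dna(1100), down, random_dna(100))))
  segs2 <- segs
  segs2$start <- c(101L, 1351L); segs2$end <- c(250L, 1500L)
  cand2 <- find_epic_candidates(long_q, segs2, refs, pipeline_params())
  expect_equal(nrow(cand2), 0L)
  expect_equal(attr(cand2, "stage_counts")$mapped, 1)
  expect_equal(attr(cand2, "stage_counts")$intron_size, 0)

  # identity below the tier -> rejected by the identity screen
  refs_div <- list(r1 = mkref(400, "r1", rate = 0.35),
                   r2 = mkref(400, "r2", rate = 0.35))
  cand3 <- find_epic_candidates(query, segs, refs_div,
                                pipeline_params(min_mean_identity = 0.85))
  expect_equal(nrow(cand3), 0L)

  # ... but accepted when the tier is lowered below the planted divergence
  cand4 <- find_epic_candidates(query, segs, refs_div,
                                pipeline_params(min_mean_identity = 0.65))
  expect_lte(nrow(cand4), 1L)
})

test_that("mean exon identity averages mapped references only", {
  expect_equal(mean_exon_identity(c(0.9, 0.8, 0.9, 0.8)), 0.85)
  expect_equal(mean_exon_identity(c(1.0, NA)), 1.0)
  expect_error(mean_exon_identity(c(NA_real_, NA_real_)), "no mapped")
})

test_that("nearby candidates merge by the transitive 1 kb chain rule", {
  two <- make_candidates("gene00042", rbind(c(300L, 400L), c(700L, 800L)))
  mk <- merge_nearby(two, 1000)
  expect_equal(nrow(mk), 1L)
  expect_equal(mk$span_start, 300L)
  expect_equal(mk$span_end, 800L)
  expect_equal(mk$n_introns_merged, 2L)
  expect_equal(mk$locus, "00042E1")

  far <- make_candidates("gene00042", rbind(c(300L, 400L), c(5500L, 5600L)))
  expect_equal(nrow(merge_nearby(far, 1000)), 2L)

  # merged mean identity is the mean over constituents
  two$mean_identity <- c(0.8, 0.9)
  expect_equal(merge_nearby(two, 1000)$mean_identity, 0.85)
})

test_that("merged markers partition their candidates and never overlap", {
  set.seed(2024)
  for (trial in 1:50) {
    n <- sample(1:8, 1)
    starts <- sort(sample(1:20000, n))
    spans <- cbind(starts, starts + sample(100:400, n, replace = TRUE))
    cand <- make_candidates("gene00077", spans)
    mk <- merge_nearby(cand, 1000)
    # every candidate lies inside exactly one marker span
    covered <- vapply(seq_len(n), function(i)
      sum(spans[i, 1] >= mk$span_start & spans[i, 2] <= mk$span_end),
      integer(1))
    expect_true(all(covered == 1L))
    # markers of one gene never lie within the merge window of each other
    if (nrow(mk) > 1) {
      m <- mk[order(mk$span_start), ]
      gaps <- m$span_start[-1] - m$span_end[-nrow(m)] - 1L
      expect_true(all(gaps > 1000))
    }
    # idempotence: re-merging the merged spans changes nothing
    again <- make_candidates("gene00077",
                             cbind(mk$span_start, mk$span_end),
                             junction = mk$n_introns_merged)
    expect_equal(nrow(merge_nearby(again, 1000)), nrow(mk))
  }
})

test_that("full pipeline recovers exactly the planted markers (noise-free)", {
  cfg <- noise_free_config(seed = 5150, n_genes = 10, n_species = 3,
                           n_duplicated_genes = 2)
  sim <- simulate_genome_set(cfg)
  dir <- withr::local_tempdir()
  paths <- write_genome_set(sim, dir)
  res <- run_pipeline(paths$query_fasta, paths$query_gff,
                      paths$reference_fastas, query_id = "query")
  truth <- truth_marker_table(sim$truth)
  expect_setequal(res$markers$locus, truth$locus)
  expect_equal(res$report$counts$markers, nrow(truth))
  # spans agree with the truth geometry
  m <- res$markers[order(res$markers$locus), ]
  t2 <- truth[order(truth$locus), ]
  expect_equal(m$span_start, t2$span_start)
  expect_equal(m$span_end, t2$span_end)
})

test_that("pipeline recovery separates qualifying from planted disqualifying genes", {
  # 18 one-intron genes: 2 duplicated, 2 with strongly diverged exons,
  # 2 with long introns in every species -> 12 qualify
  overrides <- data.frame(
    gene = 3:6,
    exon_substitution_rate = c(0.30, 0.30, NA, NA),
    intron_len = c(NA, NA, 1500L, 1500L))
  cfg <- simulation_config(n_species = 3, n_genes = 18,
                           exons_per_gene = c(2, 2),
                           exon_substitution_rate = 0,
                           intron_substitution_rate = 0,
                           intron_indel_rate = 0,
                           n_duplicated_genes = 2, seed = 7447)
  sim <- simulate_genome_set(cfg, gene_overrides = overrides)
  truth <- truth_marker_table(sim$truth)
  expect_equal(nrow(truth), 12L)
  dir <- withr::local_tempdir()
  paths <- write_genome_set(sim, dir)
  res <- run_pipeline(paths$query_fasta, paths$query_gff,
                      paths$reference_fastas, query_id = "query")
  expect_setequal(res$markers$locus, truth$locus)
})

test_that("marker counts fall as the identity tier rises", {
  cfg <- simulation_config(n_species = 3, n_genes = 8, seed = 909,
                           exon_substitution_rate = 0.06,
                           intron_substitution_rate = 0.15,
                           intron_indel_rate = 0.02,
                           n_duplicated_genes = 1)
  sim <- simulate_genome_set(cfg)
  dir <- withr::local_tempdir()
  paths <- write_genome_set(sim, dir)
  q <- read_genome(paths$query_fasta, paths$query_gff, genome_id = "query")
  refs <- lapply(names(paths$reference_fastas), function(n)
    read_genome(paths$reference_fastas[[n]], NULL, genome_id = n)$genome)
  names(refs) <- names(paths$reference_fastas)
  segs <- single_copy_filter(filter_large_cds(q$segments),
                             search_all(filter_large_cds(q$segments),
                                        min_score = 40))
  cand <- find_epic_candidates(q$genome, segs, refs,
                               pipeline_params(min_mean_identity = 0))
  n_at <- vapply(c(0.65, 0.80, 0.85), function(tier) {
    keep <- cand[round(cand$mean_identity, 2) >= tier, , drop = FALSE]
    attr(keep, "query_label") <- attr(cand, "query_label")
    attr(keep, "reference_labels") <- attr(cand, "reference_labels")
    nrow(merge_nearby(keep, 1000))
  }, numeric(1))
  expect_true(all(diff(n_at) <= 0))
})
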