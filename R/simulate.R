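#' Configuration for the multi-species genome simulator
#'
#' Describes the statistical structure the marker pipeline assumes: genes
#' with exon/intron architecture shared across species, lineage-specific
#' substitution with exons evolving more slowly than introns (the premise
#' that makes exon-primed intron-crossing markers work), indel-driven
#' intron-length variation, and paralog duplications planted in the query
#' genome. Every species' copy of a gene is mutated independently from a
#' common ancestor (a star phylogeny with per-site substitution and no rate
#' heterogeneity — deliberately the simplest model that exercises the
#' identity and size screens).
#'
#' @param n_species Number of genomes (1 query + n - 1 references).
#' @param n_genes Number of ancestral genes.
#' @param exons_per_gene Length-2 integer range of exons per gene.
#' @param exon_len,intron_len Length-2 bp ranges for exon and intron sizes.
#' @param exon_substitution_rate,intron_substitution_rate Per-site
#'   substitution probability per lineage; introns must evolve at least as
#'   fast as exons.
#' @param intron_indel_rate Per-site probability that an indel event starts
#'   at an intron position.
#' @param mean_indel_len Mean indel length (geometric).
#' @param n_duplicated_genes How many genes receive a planted paralog copy
#'   in the query genome.
#' @param duplicate_identity Per-site identity of the planted copy to its
#'   original.
#' @param seed Mandatory RNG seed; the whole genome set is a deterministic
#'   function of the configuration.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_species = 5, n_genes = 20,
                              exons_per_gene = c(2, 4),
                              exon_len = c(120, 300),
                              intron_len = c(200, 900),
                              exon_substitution_rate = 0.05,
                              intron_substitution_rate = 0.15,
                              intron_indel_rate = 0.02,
                              mean_indel_len = 4,
                              n_duplicated_genes = 2,
                              duplicate_identity = 0.95,
                              seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  check_range <- function(r, nm) {
    if (length(r) != 2 || any(r <= 0) || r[2] < r[1])
      stop("infeasible range for ", nm)
  }
  check_range(exons_per_gene, "exons_per_gene")
  check_range(exon_len, "exon_len")
  check_range(intron_len, "intron_len")
  rates <- c(exon_substitution_rate, intron_substitution_rate,
             intron_indel_rate)
  stopifnot(all(rates >= 0 & rates <= 1),
            duplicate_identity >= 0, duplicate_identity <= 1,
            mean_indel_len >= 1, n_species >= 2, n_genes >= 1,
            n_duplicated_genes >= 0, n_duplicated_genes <= n_genes)
  if (intron_substitution_rate < exon_substitution_rate)
    stop("introns must evolve at least as fast as exons")
  structure(list(n_species = as.integer(n_species),
                 n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_len = as.integer(exon_len),
                 intron_len = as.integer(intron_len),
                 exon_substitution_rate = exon_substitution_rate,
                 intron_substitution_rate = intron_substitution_rate,
                 intron_indel_rate = intron_indel_rate,
                 mean_indel_len = mean_indel_len,
                 n_duplicated_genes = as.integer(n_duplicated_genes),
                 duplicate_identity = duplicate_identity,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.BASES <- c("A", "C", "G", "T")

# sample() treats a length-1 numeric as 1:n; this does not
.resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

.random_seq <- function(len) {
  paste(sample(.BASES, len, replace = TRUE), collapse = "")
}

#' Mutate a nucleotide sequence
#'
#' Each A/C/G/T site is substituted independently with probability
#' `substitution_rate` to a uniformly chosen *different* base (a
#' substitution never reproduces the original base). Indel events start at
#' each position with probability `indel_rate`; each event is an insertion
#' or a deletion with equal probability and has geometric length with mean
#' `mean_indel_len`.
#'
#' @param seq Input sequence (character or `DNAString`).
#' @param substitution_rate Per-site substitution probability.
#' @param indel_rate Per-site indel event probability.
#' @param mean_indel_len Mean indel length.
#' @param seed Optional seed (`set.seed` is called when given); by default
#'   the current RNG stream is used.
#' @return The mutated sequence as a character string.
#' @export
mutate_sequence <- function(seq, substitution_rate, indel_rate = 0,
                            mean_indel_len = 4, seed = NULL) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  x <- strsplit(.as_seq_string(seq), "")[[1]]
  if (substitution_rate > 0) {
    hit <- which(runif(length(x)) < substitution_rate & x %in% .BASES)
    if (length(hit))
      x[hit] <- vapply(x[hit],
                       function(b) sample(setdiff(.BASES, b), 1),
                       character(1), USE.NAMES = FALSE)
  }
  if (indel_rate > 0) {
    ev <- which(runif(length(x)) < indel_rate)
    for (pos in rev(ev)) {
      len <- rgeom(1, 1 / mean_indel_len) + 1L
      if (runif(1) < 0.5) {
        x <- append(x, sample(.BASES, len, replace = TRUE), after = pos)
      } else {
        x <- x[-(pos:min(length(x), pos + len - 1L))]
      }
    }
  }
  paste(x, collapse = "")
}

.flank_identity <- function(a, b) {
  ai <- strsplit(a, "")[[1]]; bi <- strsplit(b, "")[[1]]
  mean(ai == bi)
}

#' Simulate a multi-species genome set with known marker truth
#'
#' Generates ancestral genes (exons + introns), mutates each species' copy
#' independently (exons: substitution only; introns: substitution plus
#' indels, so intron lengths vary across species), assembles each genome on
#' two chromosomes with independent random intergenic spacers, plants
#' annotated paralog copies of the first `n_duplicated_genes` genes into the
#' query genome at `duplicate_identity`, and records the ground truth every
#' pipeline stage can be checked against. Only the query genome carries
#' annotation; references are plain sequence, exercising the
#' annotation-free mapping path. Deterministic for a fixed configuration.
#'
#' @param config A [simulation_config()].
#' @param gene_overrides Optional data frame planting per-gene deviations:
#'   column `gene` (1-based gene index) plus any of
#'   `exon_substitution_rate` (e.g. a high rate to plant a low-identity
#'   gene) and `intron_len` (fixed length for all of that gene's introns,
#'   e.g. > 1,000 bp to plant a disqualifying long intron).
#' @param duplicate_placement `"dispersed"` (paralog on the other
#'   chromosome, default) or `"tandem"` (immediately downstream of its
#'   original).
#' @return A `genome_set_sim` list: `query` (list with `genome` and
#'   `segments` as in [read_genome()]), `references` (named list of
#'   [genome_record()]), `truth` (one row per exon junction: per-species
#'   intron lengths `intron_len.*`, per-reference flanking identities
#'   `identity.*`, `mean_identity`, `single_copy`, `qualifies` under the
#'   default [pipeline_params()]), and `config`.
#' @export
simulate_genome_set <- function(config, gene_overrides = NULL,
                                duplicate_placement = c("dispersed", "tandem")) {
  stopifnot(inherits(config, "simulation_config"))
  duplicate_placement <- match.arg(duplicate_placement)
  set.seed(config$seed)
  species <- c("query", paste0("ref", seq_len(config$n_species - 1L)))
  refs <- species[-1]

  ov <- function(i, field, default) {
    if (is.null(gene_overrides) || !field %in% names(gene_overrides))
      return(default)
    hit <- which(gene_overrides$gene == i)
    if (!length(hit) || is.na(gene_overrides[[field]][hit[1]])) return(default)
    gene_overrides[[field]][hit[1]]
  }

  # --- per-gene structures -------------------------------------------------
  genes <- vector("list", config$n_genes)
  for (i in seq_len(config$n_genes)) {
    gene_id <- sprintf("gene%05d", 100L + i)
    n_ex <- .resample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1)
    ex_lens <- .resample(seq(config$exon_len[1], config$exon_len[2]), n_ex,
                         replace = TRUE)
    fixed_intron <- ov(i, "intron_len", NA)
    in_lens <- if (!is.na(fixed_intron)) rep(as.integer(fixed_intron), n_ex - 1L)
               else .resample(seq(config$intron_len[1], config$intron_len[2]),
                              max(0L, n_ex - 1L), replace = TRUE)
    ex_rate <- ov(i, "exon_substitution_rate", config$exon_substitution_rate)
    anc_ex <- lapply(ex_lens, .random_seq)
    anc_in <- lapply(in_lens, .random_seq)
    ex_sp <- list(); in_sp <- list()
    for (sp in species) {
      ex_sp[[sp]] <- lapply(anc_ex, mutate_sequence,
                            substitution_rate = ex_rate)
      in_sp[[sp]] <- lapply(anc_in, mutate_sequence,
                            substitution_rate = config$intron_substitution_rate,
                            indel_rate = config$intron_indel_rate,
                            mean_indel_len = config$mean_indel_len)
    }
    dup <- NULL
    if (i <= config$n_duplicated_genes) {
      drate <- 1 - config$duplicate_identity
      dup <- list(
        exons = lapply(ex_sp[["query"]], mutate_sequence,
                       substitution_rate = drate),
        introns = lapply(in_sp[["query"]], mutate_sequence,
                         substitution_rate = drate))
    }
    genes[[i]] <- list(id = gene_id, chrom = paste0("chr", (i %% 2L) + 1L),
                       n_ex = n_ex, exons = ex_sp, introns = in_sp, dup = dup)
  }

  # --- assemble genomes ----------------------------------------------------
  spacer <- function() .random_seq(sample(300:600, 1))
  seg_rows <- list()
  genomes <- list()
  for (sp in species) {
    chroms <- c(chr1 = "", chr2 = "")
    for (g in genes) {
      pieces <- list()
      emit_gene <- function(gid, exons, introns, annotate) {
        parts <- character(0)
        pos <- nchar(chroms[[g$chrom]]) + nchar(spc <- spacer()) + 1L
        parts <- c(parts, spc)
        for (k in seq_along(exons)) {
          ex <- exons[[k]]
          if (annotate) {
            seg_rows[[length(seg_rows) + 1L]] <<- data.frame(
              gene_id = gid, chromosome = g$chrom, strand = "+",
              description = paste("simulated gene", gid),
              segment_index = k, segment_id = paste0(gid, ".", k),
              start = pos, end = pos + nchar(ex) - 1L,
              length = nchar(ex), seq = ex, stringsAsFactors = FALSE)
          }
          parts <- c(parts, ex)
          pos <- pos + nchar(ex)
          if (k < length(exons)) {
            parts <- c(parts, introns[[k]])
            pos <- pos + nchar(introns[[k]])
          }
        }
        chroms[[g$chrom]] <<- paste0(chroms[[g$chrom]],
                                     paste(parts, collapse = ""))
      }
      emit_gene(g$id, g$exons[[sp]], g$introns[[sp]], annotate = sp == "query")
      if (sp == "query" && !is.null(g$dup) &&
          duplicate_placement == "tandem") {
        emit_gene(paste0("dup", g$id), g$dup$exons, g$dup$introns, TRUE)
      }
    }
    if (sp == "query" && duplicate_placement == "dispersed") {
      for (g in genes) {
        if (is.null(g$dup)) next
        # place the paralog on the other chromosome
        g2 <- g
        g2$chrom <- if (g$chrom == "chr1") "chr2" else "chr1"
        g <- g2
        emit <- function(gid, exons, introns) {
          spc <- spacer()
          pos <- nchar(chroms[[g$chrom]]) + nchar(spc) + 1L
          parts <- spc
          for (k in seq_along(exons)) {
            ex <- exons[[k]]
            seg_rows[[length(seg_rows) + 1L]] <<- data.frame(
              gene_id = gid, chromosome = g$chrom, strand = "+",
              description = paste("simulated paralog of", sub("^dup", "", gid)),
              segment_index = k, segment_id = paste0(gid, ".", k),
              start = pos, end = pos + nchar(ex) - 1L,
              length = nchar(ex), seq = ex, stringsAsFactors = FALSE)
            parts <- paste0(parts, ex)
            pos <- pos + nchar(ex)
            if (k < length(exons)) {
              parts <- paste0(parts, introns[[k]])
              pos <- pos + nchar(introns[[k]])
            }
          }
          chroms[[g$chrom]] <<- paste0(chroms[[g$chrom]], parts)
        }
        emit(paste0("dup", g$id), g$dup$exons, g$dup$introns)
      }
    }
    chroms <- vapply(chroms, function(x) paste0(x, spacer()), character(1))
    genomes[[sp]] <- genome_record(sp, chroms)
  }
  segments <- do.call(rbind, seg_rows)
  segments <- segments[order(segments$gene_id, segments$segment_index), ,
                       drop = FALSE]
  rownames(segments) <- NULL

  # --- ground truth per exon junction -------------------------------------
  truth_rows <- list()
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    if (g$n_ex < 2) next
    single <- i > config$n_duplicated_genes
    qsegs <- segments[segments$gene_id == g$id, , drop = FALSE]
    for (k in seq_len(g$n_ex - 1L)) {
      row <- data.frame(
        gene_id = g$id, chromosome = g$chrom, junction_index = k,
        single_copy = single,
        up_len = nchar(g$exons[["query"]][[k]]),
        down_len = nchar(g$exons[["query"]][[k + 1L]]),
        q_span_start = qsegs$start[k], q_span_end = qsegs$end[k + 1L],
        stringsAsFactors = FALSE)
      for (sp in species)
        row[[paste0("intron_len.", sp)]] <- nchar(g$introns[[sp]][[k]])
      idents <- numeric(0)
      for (rn in refs) {
        idu <- .flank_identity(g$exons[["query"]][[k]], g$exons[[rn]][[k]])
        idd <- .flank_identity(g$exons[["query"]][[k + 1L]],
                               g$exons[[rn]][[k + 1L]])
        row[[paste0("identity.", rn)]] <- (idu + idd) / 2
        idents <- c(idents, (idu + idd) / 2)
      }
      row$mean_identity <- mean(idents)
      truth_rows[[length(truth_rows) + 1L]] <- row
    }
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  truth$qualifies <- truth_qualifies(truth, pipeline_params())

  structure(list(
    species = species,
    query = list(genome = genomes[["query"]], segments = segments),
    references = genomes[refs],
    truth = truth,
    config = config), class = "genome_set_sim")
}

#' Recompute which truth junctions qualify as markers
#'
#' Applies the pipeline's screening rules directly to the simulator's
#' recorded ground truth (flank sizes, per-species intron lengths,
#' per-reference flanking identities, single-copy status) — an internal
#' consistency check for the stored `qualifies` flag and the reference for
#' recovery tests.
#'
#' @param truth Truth data frame from [simulate_genome_set()].
#' @param params A [pipeline_params()].
#' @return Logical vector, one element per truth row.
#' @export
truth_qualifies <- function(truth, params = pipeline_params()) {
  len_cols <- grep("^intron_len\\.", names(truth), value = TRUE)
  id_cols <- grep("^identity\\.", names(truth), value = TRUE)
  vapply(seq_len(nrow(truth)), function(i) {
    r <- truth[i, ]
    if (!r$single_copy) return(FALSE)
    if (r$up_len < params$min_cds_len || r$down_len < params$min_cds_len)
      return(FALSE)
    lens <- unlist(r[len_cols])
    if (!any(lens <= params$max_intron_len, na.rm = TRUE)) return(FALSE)
    mid <- mean(unlist(r[id_cols]), na.rm = TRUE)
    round(mid, 2) >= params$min_mean_identity
  }, logical(1))
}

#' Expected marker table from the simulation truth
#'
#' Applies the qualification screen and the nearby-marker merge rule to the
#' truth junctions, yielding the loci an ideal pipeline run should report.
#'
#' @param truth Truth data frame from [simulate_genome_set()].
#' @param params A [pipeline_params()].
#' @return Data frame with `locus`, `gene_id`, `span_start`, `span_end`,
#'   `n_introns_merged`, sorted by chromosome then start.
#' @export
truth_marker_table <- function(truth, params = pipeline_params()) {
  q <- truth[truth_qualifies(truth, params), , drop = FALSE]
  rows <- list()
  for (g in split(q, q$gene_id)) {
    g <- g[order(g$q_span_start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(
      g$q_span_start[-1] - cummax(g$q_span_end)[-nrow(g)] - 1L >
        params$merge_window)))
    for (cl in split(g, grp)) {
      rows[[length(rows) + 1L]] <- data.frame(
        locus = .locus_name(cl$gene_id[1], min(cl$junction_index)),
        gene_id = cl$gene_id[1], chromosome = cl$chromosome[1],
        span_start = min(cl$q_span_start), span_end = max(cl$q_span_end),
        n_introns_merged = nrow(cl), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus = character(), gene_id = character(),
               chromosome = character(), span_start = integer(),
               span_end = integer(), n_introns_merged = integer(),
               stringsAsFactors = FALSE)
  out <- out[order(out$chromosome, out$span_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a simulated genome set to disk
#'
#' Emits one FASTA per species, a GFF3 annotation for the query only
#' (gene/mRNA/CDS hierarchy with descriptions), the truth table as TSV and
#' the configuration as JSON — the on-disk shape the pipeline consumes.
#'
#' @param sim A `genome_set_sim` from [simulate_genome_set()].
#' @param out_dir Output directory (created if needed).
#' @return Named list of paths: `query_fasta`, `query_gff`,
#'   `reference_fastas` (named character vector), `truth`, `config`.
#' @export
write_genome_set <- function(sim, out_dir) {
  stopifnot(inherits(sim, "genome_set_sim"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  qf <- file.path(out_dir, "query.fa")
  Biostrings::writeXStringSet(sim$query$genome$chromosomes, qf)
  paths$query_fasta <- qf

  segs <- sim$query$segments
  gene_ids <- unique(segs$gene_id)
  feat <- list()
  for (gid in gene_ids) {
    s <- segs[segs$gene_id == gid, , drop = FALSE]
    feat[[length(feat) + 1L]] <- data.frame(
      chrom = s$chromosome[1], start = min(s$start), end = max(s$end),
      strand = s$strand[1], type = "gene", ID = gid, Parent = NA_character_,
      description = s$description[1], stringsAsFactors = FALSE)
    feat[[length(feat) + 1L]] <- data.frame(
      chrom = s$chromosome[1], start = min(s$start), end = max(s$end),
      strand = s$strand[1], type = "mRNA", ID = paste0(gid, ".t1"),
      Parent = gid, description = NA_character_, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(s)))
      feat[[length(feat) + 1L]] <- data.frame(
        chrom = s$chromosome[1], start = s$start[i], end = s$end[i],
        strand = s$strand[1], type = "CDS", ID = NA_character_,
        Parent = paste0(gid, ".t1"), description = NA_character_,
        stringsAsFactors = FALSE)
  }
  feat <- do.call(rbind, feat)
  gr <- GenomicRanges::GRanges(
    seqnames = feat$chrom,
    ranges = IRanges::IRanges(feat$start, feat$end),
    strand = feat$strand)
  S4Vectors::mcols(gr)$type <- feat$type
  S4Vectors::mcols(gr)$ID <- feat$ID
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(feat$Parent, function(p) if (is.na(p)) character(0) else p))
  S4Vectors::mcols(gr)$description <- feat$description
  S4Vectors::mcols(gr)$phase <- ifelse(feat$type == "CDS", 0L, NA_integer_)
  gff <- file.path(out_dir, "query.gff3")
  rtracklayer::export(gr, gff, format = "gff3")
  paths$query_gff <- gff

  ref_paths <- character(0)
  for (rn in names(sim$references)) {
    p <- file.path(out_dir, paste0(rn, ".fa"))
    Biostrings::writeXStringSet(sim$references[[rn]]$chromosomes, p)
    ref_paths[rn] <- p
  }
  paths$reference_fastas <- ref_paths

  tp <- file.path(out_dir, "truth.tsv")
  write.table(sim$truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$truth <- tp
  cp <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(sim$config), cp, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths$config <- cp
  paths
}
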