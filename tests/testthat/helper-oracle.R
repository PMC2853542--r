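# Naive score-only affine-gap local alignment: a direct transcription of the
# Gotoh recurrences in plain R, kept independent of the package's engine.
sw_score_oracle <- function(q, s, match = 1, mismatch = -1,
                            gap_open = 5, gap_extend = 2) {
  qv <- strsplit(toupper(q), "")[[1]]
  sv <- strsplit(toupper(s), "")[[1]]
  acgt <- c("A", "C", "G", "T")
  n <- length(qv); m <- length(sv)
  NEG <- -1e18
  Hprev <- numeric(m + 1)
  Fprev <- rep(NEG, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    H <- numeric(m + 1)
    E <- rep(NEG, m + 1)
    F <- rep(NEG, m + 1)
    for (j in seq_len(m)) {
      sub <- if (qv[i] == sv[j] && qv[i] %in% acgt) match else mismatch
      E[j + 1] <- max(H[j] - gap_open - gap_extend, E[j] - gap_extend)
      F[j + 1] <- max(Hprev[j + 1] - gap_open - gap_extend,
                      Fprev[j + 1] - gap_extend)
      H[j + 1] <- max(0, Hprev[j] + sub, E[j + 1], F[j + 1])
      if (H[j + 1] > best) best <- H[j + 1]
    }
    Hprev <- H
    Fprev <- F
  }
  best
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Recompute an alignment's score from its aligned strings under a scoring
# scheme: substitution columns plus affine costs for each gap run.
rescore_alignment <- function(q_aln, s_aln, scoring) {
  qv <- strsplit(q_aln, "")[[1]]
  sv <- strsplit(s_aln, "")[[1]]
  stopifnot(length(qv) == length(sv))
  acgt <- c("A", "C", "G", "T")
  score <- 0
  in_gap_q <- FALSE  # current run of gaps in the query string
  in_gap_s <- FALSE
  for (k in seq_along(qv)) {
    if (qv[k] == "-") {
      score <- score - (if (in_gap_q) 0 else scoring$gap_open) - scoring$gap_extend
      in_gap_q <- TRUE; in_gap_s <- FALSE
    } else if (sv[k] == "-") {
      score <- score - (if (in_gap_s) 0 else scoring$gap_open) - scoring$gap_extend
      in_gap_s <- TRUE; in_gap_q <- FALSE
    } else {
      score <- score +
        (if (qv[k] == sv[k] && qv[k] %in% acgt) scoring$match else scoring$mismatch)
      in_gap_q <- FALSE; in_gap_s <- FALSE
    }
  }
  score
}
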