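# Shared builders for synthetic test inputs.

# Advertisement-call spec for one clade, from the shipped call-parameter
# table (one Type I note + round(n_notes) - 1 Type II notes).
cladeCallSpec <- function(clade, ...) {
  calls <- referenceTable("calls")
  callSpecFromParams(calls[calls$clade == clade, ], ...)
}

# The three-note D. leucophyllatus advertisement structure (one Type I
# trill followed by two Type II notes; note count at the top of the
# published 2-3 range).
leucoThreeNoteSpec <- function() {
  calls <- referenceTable("calls")
  p <- calls[calls$clade == "B", ]
  nI <- round(p$typeI_pulses)
  nII <- round(p$typeII_pulses)
  callSpec(nPulses = c(nI, nII, nII),
           pulsePeriodS = c(p$typeI_duration_s / nI,
                            rep(p$typeII_duration_s / nII, 2)),
           interNoteGapS = p$inter_note_s,
           carrierHz = p$dominant_freq_hz,
           amplitudes = c(1, 0.8, 0.8))
}

# Random small gapped alignment for oracle comparisons.
randomAlignment <- function(nSeq, nSites, gapProb = 0.08) {
  chars <- c("A", "C", "G", "T", "-", "N")
  probs <- c(rep((1 - gapProb) / 4, 4), gapProb / 2, gapProb / 2)
  seqs <- vapply(seq_len(nSeq), function(i)
    paste(sample(chars, nSites, replace = TRUE, prob = probs),
          collapse = ""), character(1))
  names(seqs) <- paste0("s", seq_len(nSeq))
  Biostrings::DNAStringSet(seqs)
}

# Site-by-site counting oracle for the uncorrected p-distance with
# pairwise deletion; intentionally naive and independent of the
# vectorized implementation.
bruteForceP <- function(s1, s2) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  nComp <- 0L
  nMis <- 0L
  for (k in seq_along(a)) {
    if (a[k] %in% c("A", "C", "G", "T") && b[k] %in% c("A", "C", "G", "T")) {
      nComp <- nComp + 1L
      if (a[k] != b[k]) nMis <- nMis + 1L
    }
  }
  if (nComp == 0L) NA_real_ else nMis / nComp
}
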