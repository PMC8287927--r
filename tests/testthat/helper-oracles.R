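# Independent brute-force oracles. These deliberately share no code with the
# package scanners: reverse complements come from Biostrings, window
# comparison is a per-position loop, and trio runs are found by naive
# extension at every offset.

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

oracle_iupac <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  lapply(m, function(s) setdiff(strsplit(s, "")[[1]], "N"))
})

# Every window within Hamming distance max_mm of motif (0-based starts on the
# scanned strand). Sequence N never matches; motif IUPAC codes match their
# base set.
brute_box_hits <- function(sequence, motif, max_mm, strand = "+") {
  s <- if (strand == "-") oracle_revcomp(sequence) else toupper(sequence)
  L <- nchar(motif)
  n <- nchar(s)
  mch <- strsplit(toupper(motif), "")[[1]]
  out <- data.frame(start = integer(), mismatches = integer())
  if (n < L) return(out)
  for (i in seq_len(n - L + 1L)) {
    w <- strsplit(substr(s, i, i + L - 1L), "")[[1]]
    d <- 0L
    for (j in seq_len(L)) {
      if (!(w[j] %in% oracle_iupac[[mch[j]]])) d <- d + 1L
    }
    if (d <= max_mm)
      out <- rbind(out, data.frame(start = i - 1L, mismatches = d))
  }
  out
}

# All maximal N-A-N runs per phase (0-based starts on the scanned strand),
# found by testing each in-phase offset and extending greedily.
brute_trio_runs <- function(sequence, strand = "+") {
  s <- if (strand == "-") oracle_revcomp(sequence) else toupper(sequence)
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  is_trio <- function(i) {  # i = 1-based offset of the 3-mer
    i + 2L <= n &&
      all(ch[i:(i + 2L)] %in% c("A", "C", "G", "T")) &&
      ch[i + 1L] == "A"
  }
  out <- data.frame(start = integer(), phase = integer(), count = integer())
  for (i in seq_len(max(n - 2L, 0L))) {
    if (!is_trio(i)) next
    if (i - 3L >= 1L && is_trio(i - 3L)) next  # not run start
    k <- 0L
    while (is_trio(i + 3L * k)) k <- k + 1L
    out <- rbind(out, data.frame(start = i - 1L, phase = (i - 1L) %% 3L,
                                 count = k))
  }
  out[order(out$start, out$phase), , drop = FALSE]
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# A hand-built origin: left pad + box (with given substitutions applied at
# fixed positions) + spacer + trios + right pad. Pads are box-free and
# trio-free by construction (no adenines or thymines at all).
synth_origin <- function(box = "TTATCCACA", spacer = 13, trios = rep("TAG", 5),
                         pad_left = 30, pad_right = 30,
                         spacer_fill = "G") {
  paste0(strrep("C", pad_left), box, strrep(spacer_fill, spacer),
         paste(trios, collapse = ""), strrep("C", pad_right))
}

# Substitute characters at 1-based positions.
subst <- function(x, pos, repl) {
  ch <- strsplit(x, "")[[1]]
  ch[pos] <- repl
  paste(ch, collapse = "")
}
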