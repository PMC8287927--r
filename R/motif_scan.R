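# Low-level, strand-aware scanners. Coordinates are 0-based half-open on the
# scanned strand: for strand "-" the scan runs over the reverse complement of
# the input and `start` refers to that reverse-complemented string.

# Consensus DnaA-trio written 5'->3' on the scanned strand. The literature
# writes the consensus 3'-GAT-5'; read 5'->3' that is TAG.
TRIO_CONSENSUS <- "TAG"

check_motif <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) < 1L)
    abort("`motif` must be a single non-empty DNA string.")
  motif <- str_to_upper(motif)
  bad <- setdiff(seq_chars(motif), names(IUPAC_MATCH))
  if (length(bad) > 0L)
    abort(sprintf("Motif contains non-IUPAC character(s): %s",
                  paste(unique(bad), collapse = ", ")))
  motif
}

#' Find mismatch-bounded DnaA-box matches
#'
#' Slides a window of the motif's length along the scanned strand and reports
#' every window whose Hamming distance to the motif is at most `max_mm`.
#' There are no indels: a hit always has the motif's length. Motif positions
#' may carry IUPAC degeneracy codes, which match their base set; an `N` in
#' the *sequence* never matches any motif position (ambiguous data cannot
#' create hits), whereas an `N` in the *motif* is a wildcard over A/C/G/T.
#'
#' @param sequence DNA string over A,C,G,T,N (uppercased internally).
#' @param motif DNA string, IUPAC codes allowed.
#' @param max_mm maximum Hamming distance (>= 0).
#' @param strand `"+"` or `"-"`; for `"-"` the reverse complement of
#'   `sequence` is scanned and `start` is an offset on that strand.
#' @return a tibble with columns `start` (0-based), `strand`, `motif`,
#'   `observed` (the matched window, scanned strand), `mismatches`; sorted by
#'   `start`. Overlapping hits are all reported.
#' @examples
#' find_box_hits("TTATCCACA", "TTATCCACA", max_mm = 0)
#' @export
find_box_hits <- function(sequence, motif, max_mm, strand = "+") {
  stopifnot(strand %in% c("+", "-"))
  motif <- check_motif(motif)
  seq_s <- str_to_upper(sequence)
  if (strand == "-") seq_s <- revcomp(seq_s)
  h <- box_hits_core(seq_s, motif, max_mm)
  tibble(
    start = h$start,
    strand = rep(strand, length(h$start)),
    motif = rep(motif, length(h$start)),
    observed = h$observed,
    mismatches = h$mismatches
  )
}

# Plain-vector scanner over an already-oriented (scanned-strand) string.
box_hits_core <- function(seq_s, motif, max_mm) {
  L <- nchar(motif)
  n <- nchar(seq_s)
  nw <- n - L + 1L
  none <- list(start = integer(), observed = character(),
               mismatches = integer())
  if (nw < 1L) return(none)
  ch <- seq_chars(seq_s)
  mpos <- seq_chars(motif)
  mm <- integer(nw)
  for (j in seq_len(L)) {
    allowed <- IUPAC_MATCH[[mpos[j]]]
    mm <- mm + !(ch[j:(j + nw - 1L)] %in% allowed)
  }
  keep <- which(mm <= max_mm)
  if (length(keep) == 0L) return(none)
  list(start = keep - 1L,
       observed = substring(seq_s, keep, keep + L - 1L),
       mismatches = mm[keep])
}

#' Find maximal runs of DnaA-trio (N-A-N) trinucleotides
#'
#' A DnaA-trio is a trinucleotide with a conserved adenine in the middle; the
#' general pattern is `(.A.)`. For each of the three reading phases, all
#' maximal runs of consecutive N-A-N 3-mers on the scanned strand are
#' reported (runs in different phases may overlap). An `N` base in the
#' sequence fails the pattern at any of the three positions. Runs of length 1
#' and 2 are reported here; the >= 3 requirement for a BUS call is enforced
#' by the search layer.
#'
#' @inheritParams find_box_hits
#' @return a tibble with columns `start` (0-based offset of the first trio on
#'   the scanned strand), `strand`, `phase` (0..2), `count`, and `trios`
#'   (list-column of the 3-mers in run order); sorted by `start`, then
#'   `phase`.
#' @examples
#' find_trio_arrays("TAGTAGTAG")
#' @export
find_trio_arrays <- function(sequence, strand = "+") {
  stopifnot(strand %in% c("+", "-"))
  seq_s <- str_to_upper(sequence)
  if (strand == "-") seq_s <- revcomp(seq_s)
  r <- trio_runs_core(seq_s)
  ord <- order(r$start, r$phase)
  tibble(start = r$start[ord],
         strand = rep(strand, length(r$start)),
         phase = r$phase[ord],
         count = r$count[ord],
         trios = r$trios[ord])
}

# Plain-vector trio-run scanner over an already-oriented string.
trio_runs_core <- function(seq_s) {
  n <- nchar(seq_s)
  none <- list(start = integer(), phase = integer(), count = integer(),
               trios = list())
  if (n < 3L) return(none)
  ch <- seq_chars(seq_s)
  base_ok <- ch %in% c("A", "C", "G", "T")
  start <- integer(); phase_v <- integer(); count <- integer()
  trios <- list()
  for (phase in 0:2) {
    starts <- seq.int(phase + 1L, by = 3L, length.out = (n - phase) %/% 3L)
    if (length(starts) == 0L) next
    ok <- ch[starts + 1L] == "A" & base_ok[starts] & base_ok[starts + 2L]
    r <- rle(ok)
    ends_i <- cumsum(r$lengths)
    begs_i <- ends_i - r$lengths + 1L
    runs <- which(r$values)
    if (length(runs) == 0L) next
    s1 <- starts[begs_i[runs]]
    k <- r$lengths[runs]
    start <- c(start, s1 - 1L)
    phase_v <- c(phase_v, rep(phase, length(runs)))
    count <- c(count, k)
    trios <- c(trios, map2(s1, k, function(s, kk) {
      off <- s + 3L * (seq_len(kk) - 1L)
      substring(seq_s, off, off + 2L)
    }))
  }
  list(start = start, phase = phase_v, count = count, trios = trios)
}

#' Score a DnaA-trio run
#'
#' The default scheme (`"consensus_weighted"`) rewards both run length and
#' agreement with the consensus trio (3'-GAT-5', i.e. `TAG` written 5'->3' on
#' the scanned strand): each trio contributes `w_full` (default 3) if it
#' equals the consensus and `w_partial` (default 1) otherwise, and the score
#' is the sum. Two alternative schemes are selectable: `"count"` (score =
#' number of trios) and `"matrix"` (a user-supplied 4 x 3 per-position weight
#' matrix with rownames A,C,G,T; each trio contributes the sum of the weights
#' of its three bases).
#'
#' @param trios a character vector of 3-mers (e.g. the `trios` entry of a
#'   [find_trio_arrays()] row).
#' @param scoring a list with element `scheme` and scheme-specific weights;
#'   see [bus_params()].
#' @return a single non-negative number.
#' @examples
#' score_trios(c("TAG", "TAG", "TAG"))
#' score_trios(c("CAT", "GAC", "AAA"))
#' @export
score_trios <- function(trios,
                        scoring = list(scheme = "consensus_weighted",
                                       w_full = 3, w_partial = 1)) {
  if (length(trios) < 1L) abort("`trios` must contain at least one 3-mer.")
  scheme <- scoring$scheme %||% "consensus_weighted"
  if (scheme == "consensus_weighted") {
    w_full <- scoring$w_full %||% 3
    w_partial <- scoring$w_partial %||% 1
    sum(ifelse(trios == TRIO_CONSENSUS, w_full, w_partial))
  } else if (scheme == "count") {
    length(trios)
  } else if (scheme == "matrix") {
    w <- scoring$weights
    if (is.null(w) || !is.matrix(w) || nrow(w) != 4L || ncol(w) != 3L ||
        !setequal(rownames(w), c("A", "C", "G", "T")))
      abort("`matrix` scheme needs `weights`: a 4 x 3 matrix with rownames A,C,G,T.")
    sum(vapply(trios, function(tr) {
      b <- seq_chars(tr)
      sum(w[cbind(match(b, rownames(w)), 1:3)])
    }, numeric(1)))
  } else {
    abort(sprintf("Unknown trio scoring scheme: '%s'", scheme))
  }
}
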