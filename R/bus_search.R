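# The two-step search (enumerate candidates) and three-step screen (retain a
# single call) that together make one BUS call per origin.

candidate_cols <- function() {
  tibble(
    strand = character(), box_len = integer(),
    box1_start = integer(), box1_seq = character(), box1_mm = integer(),
    box2_start = integer(), box2_seq = character(), box2_mm = integer(),
    box2_side = character(), box2_gap = integer(),
    ref_box = character(), ref_start = integer(), spacer = integer(),
    trio_start = integer(), trio_phase = integer(), trio_count = integer(),
    trio_score = double(), trio_seqs = character(), primary_mm = integer()
  )
}

as_origin_row <- function(origin) {
  if (is.data.frame(origin)) {
    stopifnot(nrow(origin) == 1L)
    origin <- as.list(origin)
  }
  origin$sequence <- str_to_upper(origin$sequence)
  if (is.null(origin$box_motif) || is.na(origin$box_motif) ||
      origin$box_motif == "")
    origin$box_motif <- DEFAULT_BOX_MOTIF
  if (is.null(origin$searchable))
    origin$searchable <- nchar(origin$sequence) >= nchar(origin$box_motif) + 9L
  origin
}

#' Enumerate BUS candidate modules within one origin
#'
#' Step one of the search: on each scanned strand, every maximal DnaA-trio
#' run with at least `min_trios` trios is paired with every upstream DnaA-box
#' whose mismatch count is within the first-located cap (2 for a 9-bp motif,
#' `max_mm_long_motif` for longer motifs) and whose spacer (bases strictly
#' between the box 3' end and the first trio) is 0..`max_spacer`. Step two:
#' for each pair a secondary box with at most `max_mm_secondary` mismatches
#' is searched downstream of the first box inside the spacer and immediately
#' upstream of it (gap at most `max_interbox_gap`); the best-qualifying
#' secondary (fewest mismatches, then smallest gap, then leftmost) is
#' attached. When an upstream secondary has strictly fewer mismatches than
#' the first-located box it becomes the reference box and the spacer is
#' recounted from it — in that one case the spacer may exceed `max_spacer`.
#'
#' @param origin a one-row origin tibble (see [origin_tbl()]) or a named list
#'   with at least `sequence` and optionally `box_motif`.
#' @param params a [bus_params()] object.
#' @return a tibble of candidates, one row each, with 0-based scanned-strand
#'   coordinates; zero rows when the origin is unsearchable or nothing
#'   qualifies.
#' @export
enumerate_candidates <- function(origin, params = bus_params()) {
  origin <- as_origin_row(origin)
  out <- candidate_cols()
  if (!isTRUE(origin$searchable)) return(out)
  motif <- check_motif(origin$box_motif)
  L <- nchar(motif)
  cap1 <- cap_primary(L, params)
  strands <- if (params$strands == "plus") "+" else c("+", "-")
  seq_fwd <- origin$sequence

  rows <- list()
  for (strand in strands) {
    seq_s <- if (strand == "-") revcomp(seq_fwd) else seq_fwd
    sec <- box_hits_core(seq_s, motif, params$max_mm_secondary)
    b1_idx <- which(sec$mismatches <= cap1)
    if (length(b1_idx) == 0L) next
    tr <- trio_runs_core(seq_s)
    t_idx <- which(tr$count >= params$min_trios)
    if (length(t_idx) == 0L) next
    for (ti in t_idx) {
      t_start <- tr$start[ti]
      t_score <- score_trios(tr$trios[[ti]], params$trio_scoring)
      t_str <- paste(tr$trios[[ti]], collapse = ",")
      for (bi in b1_idx) {
        b_start <- sec$start[bi]
        b_mm <- sec$mismatches[bi]
        spacer0 <- t_start - (b_start + L)
        if (spacer0 < 0L || spacer0 > params$max_spacer) next
        # secondary search, two windows
        dn <- sec$start >= b_start + L & sec$start + L <= t_start
        gap_up <- b_start - (sec$start + L)
        up <- gap_up >= 0L & gap_up <= params$max_interbox_gap
        sel <- which((dn | up) & sec$start != b_start)
        has2 <- length(sel) > 0L
        if (has2) {
          gap2 <- ifelse(dn[sel], sec$start[sel] - (b_start + L), gap_up[sel])
          ord <- order(sec$mismatches[sel], gap2, sec$start[sel])
          k <- sel[ord[1L]]
          s2_gap <- gap2[ord[1L]]
          s2_side <- if (dn[k]) "downstream" else "upstream"
          s2_mm <- sec$mismatches[k]
        }
        takeover <- has2 && s2_side == "upstream" && s2_mm < b_mm
        ref_start <- if (takeover) sec$start[k] else b_start
        spacer <- t_start - (ref_start + L)
        rows[[length(rows) + 1L]] <- list(
          strand = strand, box_len = L,
          box1_start = b_start, box1_seq = sec$observed[bi], box1_mm = b_mm,
          box2_start = if (has2) sec$start[k] else NA_integer_,
          box2_seq = if (has2) sec$observed[k] else NA_character_,
          box2_mm = if (has2) as.integer(s2_mm) else NA_integer_,
          box2_side = if (has2) s2_side else NA_character_,
          box2_gap = if (has2) as.integer(s2_gap) else NA_integer_,
          ref_box = if (takeover) "box2" else "box1",
          ref_start = as.integer(ref_start), spacer = as.integer(spacer),
          trio_start = t_start, trio_phase = tr$phase[ti],
          trio_count = tr$count[ti],
          trio_score = t_score,
          trio_seqs = t_str,
          primary_mm = as.integer(if (has2) min(b_mm, s2_mm) else b_mm)
        )
      }
    }
  }
  if (length(rows) == 0L) return(out)
  cands <- as_tibble(do.call(
    rbind.data.frame, c(rows, list(stringsAsFactors = FALSE))))
  # A tandem pair can be enumerated twice with box1/box2 roles swapped when
  # both members pass the first-located cap; keep one row per physical
  # module, preferring the description whose box1 is the more conserved.
  cands <- arrange(cands, match(.data$strand, c("+", "-")), .data$ref_start,
                   .data$box1_mm)
  cands <- mutate(cands,
                  .lo = pmin(.data$box1_start, .data$box2_start, na.rm = TRUE),
                  .hi = pmax(.data$box1_start, .data$box2_start, na.rm = TRUE))
  cands <- distinct(cands, .data$strand, .data$ref_start, .data$trio_start,
                    .data$spacer, .data$.lo, .data$.hi, .keep_all = TRUE)
  select(cands, -".lo", -".hi")
}

#' Screen candidates down to a single retained BUS call
#'
#' Applies the three screening filters in their fixed order: (1) keep the
#' candidates with the highest DnaA-trio score; (2) of those, keep the ones
#' with the fewest mismatches in the sole (or more conserved) box; (3) of
#' those, keep the ones whose spacer is closest to the preferred length
#' (13 bp by default). Survivors of filter 3 are counted in `tie_count`; when
#' more than one survives, the retained candidate is the one with the
#' smallest reference-box start on the plus strand, then the minus strand.
#'
#' @param candidates a candidate tibble from [enumerate_candidates()].
#' @param params a [bus_params()] object.
#' @return a one-row tibble: `found`, the retained candidate's fields
#'   (`NA` when not found), `tie_count`, `candidates_considered`.
#' @export
screen_candidates <- function(candidates, params = bus_params()) {
  n_in <- nrow(candidates)
  if (n_in == 0L) {
    na_row <- candidate_cols()[NA_integer_, ]
    return(mutate(na_row, found = FALSE, tie_count = 0L,
                  candidates_considered = 0L))
  }
  s1 <- filter(candidates, .data$trio_score == max(.data$trio_score))
  s2 <- filter(s1, .data$primary_mm == min(.data$primary_mm))
  s3 <- filter(s2, abs(.data$spacer - params$preferred_spacer) ==
                 min(abs(.data$spacer - params$preferred_spacer)))
  s3 <- arrange(s3, match(.data$strand, c("+", "-")), .data$ref_start)
  mutate(s3[1L, ], found = TRUE, tie_count = nrow(s3),
         candidates_considered = n_in)
}

#' Search one origin for its BUS module
#'
#' Runs [enumerate_candidates()] then [screen_candidates()]; deterministic
#' for fixed input.
#'
#' @inheritParams enumerate_candidates
#' @return a one-row result tibble: origin metadata (`id`, `organism`,
#'   `lineage`, `seq_len`, `motif`), `found`, the retained candidate's fields
#'   and `tie_count` / `candidates_considered`. Coordinates are 0-based on
#'   the scanned strand; use [write_results()] for 1-based forward-strand
#'   reports.
#' @export
search_origin <- function(origin, params = bus_params()) {
  origin <- as_origin_row(origin)
  res <- screen_candidates(enumerate_candidates(origin, params), params)
  mutate(res,
         id = origin$id %||% NA_character_,
         organism = origin$organism %||% "",
         lineage = origin$lineage %||% "",
         seq_len = nchar(origin$sequence),
         motif = str_to_upper(origin$box_motif),
         box_len = nchar(origin$box_motif),
         .before = 1L)
}

#' Search a table of origins
#'
#' Vectorised driver over [search_origin()]: one call, and one result row,
#' per origin record.
#'
#' @param origins an origin tibble (see [origin_tbl()] / [read_origins()]).
#' @param params a [bus_params()] object.
#' @return a result tibble with one row per origin, in input order.
#' @examples
#' origins <- origin_tbl(
#'   id = "toy",
#'   sequence = paste0(strrep("C", 30), "TTATCCACA", strrep("G", 13),
#'                     strrep("TAG", 5), strrep("C", 30)))
#' search_origins(origins)[, c("id", "found", "spacer", "trio_count")]
#' @export
search_origins <- function(origins, params = bus_params()) {
  if (nrow(origins) == 0L) {
    empty <- search_origin(list(id = "x", sequence = strrep("A", 20)),
                           params)[0L, ]
    return(empty)
  }
  rows <- map(seq_len(nrow(origins)),
              function(i) search_origin(origins[i, ], params))
  list_rbind(rows)
}
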