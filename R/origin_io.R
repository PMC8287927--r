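# Reading origin sequences (FASTA or a DoriC-style table) and writing result
# tables. Internally everything is tabular: one row per origin.

# E. coli highest-affinity DnaA-box; the default standard motif.
DEFAULT_BOX_MOTIF <- "TTATCCACA"

# Columns of the on-disk result table (TSV and JSON mirror each other).
# Coordinates are 1-based inclusive on the forward (input) sequence.
RESULT_COLUMNS <- c(
  "id", "organism", "lineage", "found", "strand",
  "box1_start", "box1_end", "box1_seq", "box1_mm",
  "box2_start", "box2_end", "box2_seq", "box2_mm", "box2_side",
  "ref_box", "spacer", "trio_start", "trio_end", "trio_count",
  "trio_score", "trio_seq", "tie_count", "candidates_considered",
  "seq_len", "motif"
)

#' Assemble and normalise a table of origin records
#'
#' Uppercases sequences, fills in the default DnaA-box motif
#' (`TTATCCACA`, the E. coli highest-affinity box) where none is supplied,
#' rejects records whose sequence contains characters outside A,C,G,T,N
#' (with a message; the run continues), and flags records too short to ever
#' contain a BUS module (shorter than motif length + 9: a box, a zero-length
#' spacer and three trios) as unsearchable.
#'
#' @param id character vector of record identifiers.
#' @param sequence character vector of DNA sequences.
#' @param organism,lineage optional character vectors (lineage is a
#'   semicolon-separated taxon list, highest rank first).
#' @param box_motif optional character vector of species-specific standard
#'   motifs (IUPAC codes allowed); `NA` or `""` falls back to the default.
#' @return a tibble with columns `id`, `organism`, `lineage`, `sequence`,
#'   `box_motif`, `searchable`.
#' @export
origin_tbl <- function(id, sequence, organism = "", lineage = "",
                       box_motif = NA_character_) {
  n <- length(id)
  tb <- tibble(
    id = as.character(id),
    organism = rep_len(as.character(organism), n),
    lineage = rep_len(as.character(lineage), n),
    sequence = str_to_upper(as.character(sequence)),
    box_motif = rep_len(as.character(box_motif), n)
  )
  tb$organism[is.na(tb$organism)] <- ""
  tb$lineage[is.na(tb$lineage)] <- ""
  tb$box_motif[is.na(tb$box_motif) | tb$box_motif == ""] <- DEFAULT_BOX_MOTIF
  tb$box_motif <- str_to_upper(tb$box_motif)

  legal <- !str_detect(tb$sequence, "[^ACGTN]")
  if (any(!legal)) {
    for (bad_id in tb$id[!legal])
      inform(sprintf("[buscan] record '%s' rejected: illegal characters in sequence", bad_id))
    tb <- tb[legal, ]
  }
  mutate(tb, searchable = nchar(.data$sequence) >= nchar(.data$box_motif) + 9L)
}

#' Read origin records from FASTA or a DoriC-style table
#'
#' FASTA headers are split at the first whitespace: the first token is the
#' record id, the remainder (if any) the organism. The `doric_table` format
#' is tab-separated with a header row naming at least `id` and `sequence`;
#' optional columns `organism`, `lineage` (semicolon-separated) and
#' `box_motif` (a species-specific standard motif, IUPAC codes allowed) are
#' used when present. Records whose motif column is empty get the default
#' `TTATCCACA`.
#'
#' @param path path to the input file.
#' @param format `"fasta"` or `"doric_table"`.
#' @return a tibble as produced by [origin_tbl()], in file order.
#' @export
read_origins <- function(path, format = c("fasta", "doric_table")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("Input file not found: %s", path))
  if (format == "fasta") {
    recs <- Biostrings::readBStringSet(path)
    if (length(recs) == 0L) {
      warn(sprintf("[buscan] no records in FASTA file %s", path))
      return(origin_tbl(character(), character()))
    }
    headers <- names(recs)
    ids <- sub("\\s.*$", "", headers)
    orgs <- ifelse(grepl("\\s", headers),
                   sub("^\\S+\\s+", "", headers), "")
    origin_tbl(id = ids, sequence = as.character(recs), organism = orgs)
  } else {
    tb <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    missing_cols <- setdiff(c("id", "sequence"), names(tb))
    if (length(missing_cols) > 0L)
      abort(sprintf("doric_table is missing required column(s): %s",
                    paste(missing_cols, collapse = ", ")))
    origin_tbl(
      id = tb$id,
      sequence = tb$sequence,
      organism = if ("organism" %in% names(tb)) tb$organism else "",
      lineage = if ("lineage" %in% names(tb)) tb$lineage else "",
      box_motif = if ("box_motif" %in% names(tb)) tb$box_motif else NA_character_
    )
  }
}

# Convert an in-memory result tibble (0-based half-open, scanned strand) to
# the on-disk schema (1-based inclusive, forward strand). Sequence columns
# hold the forward-strand slice, so slicing the input at the reported
# coordinates reproduces them exactly; for strand "-" the motif matches the
# reverse complement of the reported slice.
results_to_disk <- function(results) {
  stopifnot(is.data.frame(results))
  fwd1 <- function(start, len, strand, n) {
    ifelse(is.na(start), NA_integer_,
           as.integer(scanned_to_forward(start, len, strand, n)) + 1L)
  }
  fwd_seq <- function(obs, strand) {
    ifelse(is.na(obs), NA_character_,
           ifelse(strand == "-", revcomp(ifelse(is.na(obs), "", obs)), obs))
  }
  n <- results$seq_len
  trio_len <- 3L * results$trio_count
  trio_scanned <- ifelse(is.na(results$trio_seqs), NA_character_,
                         gsub(",", "", results$trio_seqs, fixed = TRUE))
  out <- tibble(
    id = results$id,
    organism = results$organism,
    lineage = results$lineage,
    found = results$found,
    strand = ifelse(results$found, results$strand, NA_character_),
    box1_start = fwd1(results$box1_start, results$box_len, results$strand, n),
    box1_end = fwd1(results$box1_start, results$box_len, results$strand, n) +
      results$box_len - 1L,
    box1_seq = fwd_seq(results$box1_seq, results$strand),
    box1_mm = results$box1_mm,
    box2_start = fwd1(results$box2_start, results$box_len, results$strand, n),
    box2_end = fwd1(results$box2_start, results$box_len, results$strand, n) +
      results$box_len - 1L,
    box2_seq = fwd_seq(results$box2_seq, results$strand),
    box2_mm = results$box2_mm,
    box2_side = results$box2_side,
    ref_box = results$ref_box,
    spacer = results$spacer,
    trio_start = fwd1(results$trio_start, trio_len, results$strand, n),
    trio_end = fwd1(results$trio_start, trio_len, results$strand, n) +
      trio_len - 1L,
    trio_count = results$trio_count,
    trio_score = results$trio_score,
    trio_seq = fwd_seq(trio_scanned, results$strand),
    tie_count = results$tie_count,
    candidates_considered = results$candidates_considered,
    seq_len = results$seq_len,
    motif = results$motif
  )
  out[, RESULT_COLUMNS]
}

#' Write BUS search results to TSV or JSON
#'
#' One row per origin. Coordinates are 1-based inclusive on the forward
#' (input) sequence; `strand` records which strand the module was called on,
#' and for `-` calls the sequence columns are the forward-strand slice (the
#' motif matches their reverse complement). Origins without a BUS call get
#' `found = FALSE` and empty fields. The JSON format mirrors the TSV row
#' schema as an array of objects.
#'
#' @param results a result tibble from [search_origins()].
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  disk <- results_to_disk(results)
  if (format == "tsv") {
    readr::write_tsv(disk, path, na = "")
  } else {
    jsonlite::write_json(disk, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' Restores the in-memory representation (0-based half-open coordinates on
#' the scanned strand, scanned-strand trio strings) from the on-disk TSV, so
#' downstream steps such as [summarize_cohort()] can run from a saved table.
#'
#' @param path path to a TSV written by [write_results()].
#' @return a result tibble in the [search_origins()] layout.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort(sprintf("Results file not found: %s", path))
  disk <- readr::read_tsv(
    path, progress = FALSE,
    col_types = readr::cols(
      id = "c", organism = "c", lineage = "c", found = "l", strand = "c",
      box1_start = "i", box1_end = "i", box1_seq = "c", box1_mm = "i",
      box2_start = "i", box2_end = "i", box2_seq = "c", box2_mm = "i",
      box2_side = "c", ref_box = "c", spacer = "i",
      trio_start = "i", trio_end = "i", trio_count = "i",
      trio_score = "d", trio_seq = "c", tie_count = "i",
      candidates_considered = "i", seq_len = "i", motif = "c"
    ))
  disk$organism[is.na(disk$organism)] <- ""
  disk$lineage[is.na(disk$lineage)] <- ""
  box_len <- nchar(disk$motif)
  back <- function(start1, len, strand, n) {
    fwd0 <- start1 - 1L
    ifelse(is.na(start1), NA_integer_,
           as.integer(ifelse(strand == "+", fwd0, n - (fwd0 + len))))
  }
  scan_seq <- function(fwd, strand) {
    ifelse(is.na(fwd), NA_character_,
           ifelse(strand == "-", revcomp(ifelse(is.na(fwd), "", fwd)), fwd))
  }
  trio_scanned <- scan_seq(disk$trio_seq, disk$strand)
  trio_seqs <- vapply(trio_scanned, function(s) {
    if (is.na(s)) return(NA_character_)
    k <- nchar(s) %/% 3L
    paste(str_sub(s, 3L * (seq_len(k) - 1L) + 1L, 3L * seq_len(k)),
          collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  tibble(
    id = disk$id, organism = disk$organism, lineage = disk$lineage,
    found = disk$found, strand = disk$strand,
    ref_box = disk$ref_box,
    ref_start = ifelse(disk$ref_box %in% "box2",
                       back(disk$box2_start, box_len, disk$strand, disk$seq_len),
                       back(disk$box1_start, box_len, disk$strand, disk$seq_len)),
    box_len = box_len,
    box1_start = back(disk$box1_start, box_len, disk$strand, disk$seq_len),
    box1_seq = scan_seq(disk$box1_seq, disk$strand),
    box1_mm = disk$box1_mm,
    box2_start = back(disk$box2_start, box_len, disk$strand, disk$seq_len),
    box2_seq = scan_seq(disk$box2_seq, disk$strand),
    box2_mm = disk$box2_mm,
    box2_side = disk$box2_side,
    spacer = disk$spacer,
    primary_mm = as.integer(pmin(disk$box1_mm, disk$box2_mm, na.rm = TRUE)),
    trio_start = back(disk$trio_start, 3L * disk$trio_count, disk$strand,
                      disk$seq_len),
    trio_count = disk$trio_count,
    trio_score = disk$trio_score,
    trio_seqs = trio_seqs,
    tie_count = disk$tie_count,
    candidates_considered = disk$candidates_considered,
    seq_len = disk$seq_len,
    motif = disk$motif
  )
}

#' Write origin records as FASTA
#'
#' Convenience writer used by the simulator and CLI; the header is
#' `id organism` when an organism is present.
#'
#' @param origins an origin tibble ([origin_tbl()] layout).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_origins_fasta <- function(origins, path) {
  headers <- ifelse(origins$organism == "", origins$id,
                    paste(origins$id, origins$organism))
  xs <- Biostrings::DNAStringSet(origins$sequence)
  names(xs) <- headers
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}
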