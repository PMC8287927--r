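#' Search parameters for the BUS scanner
#'
#' Bundles every tunable threshold of the search and screening cascade. The
#' defaults are the rule set used for the published genome survey:
#'
#' * a sole 9-bp DnaA-box, or the more conserved member of a tandem pair,
#'   tolerates at most 2 mismatches (`max_mm_sole_9`,
#'   `max_mm_primary_tandem_9`);
#' * the less conserved member of a tandem pair tolerates at most 4
#'   (`max_mm_secondary`);
#' * a standard motif longer than 9 bp raises the sole/primary cap to 3
#'   (`max_mm_long_motif`);
#' * the spacer between the reference box and the first DnaA-trio is at most
#'   16 bp (`max_spacer`), with 13 bp the preferred length used as the final
#'   tie-breaker (`preferred_spacer`);
#' * at least 3 consecutive N-A-N trios are required (`min_trios`);
#' * two boxes of a tandem pair may be separated by at most 3 bp
#'   (`max_interbox_gap`).
#'
#' @param max_mm_sole_9 mismatch cap for a sole 9-bp box.
#' @param max_mm_primary_tandem_9 mismatch cap for the more conserved box of
#'   a tandem pair (9-bp motif).
#' @param max_mm_secondary mismatch cap for the less conserved (secondary)
#'   box.
#' @param max_mm_long_motif sole/primary mismatch cap when the standard motif
#'   is longer than 9 bp.
#' @param max_spacer maximum box-to-trios spacer, bp.
#' @param min_trios minimum number of consecutive N-A-N trios.
#' @param preferred_spacer spacer length preferred by the final screen, bp.
#' @param max_interbox_gap maximum gap between the two boxes of a tandem
#'   pair, bp.
#' @param trio_scoring a list describing the trio scoring scheme; see
#'   [score_trios()]. Default: consensus-weighted count with `w_full = 3`,
#'   `w_partial = 1`.
#' @param strands `"both"` to scan both strands (default) or `"plus"` to
#'   restrict to the forward strand.
#' @return an object of class `bus_params` (a validated named list).
#' @examples
#' p <- bus_params()
#' p$max_spacer
#' @export
bus_params <- function(max_mm_sole_9 = 2L,
                       max_mm_primary_tandem_9 = 2L,
                       max_mm_secondary = 4L,
                       max_mm_long_motif = 3L,
                       max_spacer = 16L,
                       min_trios = 3L,
                       preferred_spacer = 13L,
                       max_interbox_gap = 3L,
                       trio_scoring = list(scheme = "consensus_weighted",
                                           w_full = 3, w_partial = 1),
                       strands = c("both", "plus")) {
  strands <- match.arg(strands)
  p <- list(
    max_mm_sole_9 = as.integer(max_mm_sole_9),
    max_mm_primary_tandem_9 = as.integer(max_mm_primary_tandem_9),
    max_mm_secondary = as.integer(max_mm_secondary),
    max_mm_long_motif = as.integer(max_mm_long_motif),
    max_spacer = as.integer(max_spacer),
    min_trios = as.integer(min_trios),
    preferred_spacer = as.integer(preferred_spacer),
    max_interbox_gap = as.integer(max_interbox_gap),
    trio_scoring = trio_scoring,
    strands = strands
  )
  validate_bus_params(p)
  structure(p, class = "bus_params")
}

validate_bus_params <- function(p) {
  ints <- c("max_mm_sole_9", "max_mm_primary_tandem_9", "max_mm_secondary",
            "max_mm_long_motif", "max_spacer", "min_trios",
            "preferred_spacer", "max_interbox_gap")
  for (f in ints) {
    v <- p[[f]]
    if (length(v) != 1L || is.na(v) || v < 0L)
      abort(sprintf("`%s` must be a single non-negative integer.", f))
  }
  if (p$min_trios < 1L) abort("`min_trios` must be >= 1.")
  if (p$preferred_spacer > p$max_spacer)
    abort("`preferred_spacer` must not exceed `max_spacer`.")
  if (!is.list(p$trio_scoring) || is.null(p$trio_scoring$scheme))
    abort("`trio_scoring` must be a list with a `scheme` element.")
  invisible(p)
}

#' @export
print.bus_params <- function(x, ...) {
  cat("<bus_params>\n")
  for (f in setdiff(names(x), "trio_scoring"))
    cat(sprintf("  %-24s %s\n", f, as.character(x[[f]])))
  cat(sprintf("  %-24s %s\n", "trio_scoring", x$trio_scoring$scheme))
  invisible(x)
}

# Mismatch cap for a first-located / sole box, by motif length.
cap_primary <- function(motif_len, params) {
  if (motif_len > 9L) params$max_mm_long_motif else params$max_mm_sole_9
}

#' Read search parameters from a YAML file
#'
#' The file is a single mapping whose keys mirror the [bus_params()]
#' arguments; absent keys keep their defaults. `trio_scoring` may be given as
#' a nested mapping (`scheme`, `w_full`, `w_partial`, optional `weights`).
#'
#' @param path path to a YAML file.
#' @return a `bus_params` object.
#' @export
read_params_yaml <- function(path) {
  if (!file.exists(path)) abort(sprintf("Parameter file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(bus_params))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    abort(sprintf("Unknown parameter(s) in %s: %s",
                  path, paste(unknown, collapse = ", ")))
  if (!is.null(raw$trio_scoring)) {
    def <- list(scheme = "consensus_weighted", w_full = 3, w_partial = 1)
    raw$trio_scoring <- utils::modifyList(def, raw$trio_scoring)
  }
  do.call(bus_params, raw)
}
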