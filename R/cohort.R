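# Cohort-level survey statistics over many origins: prevalence of the BUS,
# tandem-box fraction, spacer distribution, per-position trio base
# frequencies, and per-phylum breakdowns.

phylum_of <- function(lineage) {
  first <- map_chr(str_split(lineage %||% "", ";"),
                   function(x) trimws(x[1]))
  ifelse(is.na(first) | first == "", "unclassified", first)
}

split_trios <- function(trio_seqs) str_split(trio_seqs, ",", simplify = FALSE)

cohort_counts <- function(results) {
  found <- filter(results, .data$found)
  list(
    n_origins = nrow(results),
    n_found = nrow(found),
    n_tandem = sum(!is.na(found$box2_start))
  )
}

#' Summarise BUS search results across a cohort of origins
#'
#' Aggregates a result table into the survey statistics: prevalence (fraction
#' of origins with a BUS call), tandem fraction (fraction of found origins
#' whose call includes a secondary box, computed over all found origins), the
#' spacer-length histogram, per-position base frequencies of the DnaA-trios
#' (trio index 1 is box-proximal), and the same core fields per phylum. The
#' phylum is the first rank of the semicolon-separated lineage
#' (`"unclassified"` when absent); per-phylum rows are reported only for
#' phyla with at least one found origin and at least `min_genomes` origins.
#'
#' @param results a result tibble from [search_origins()] or [read_results()].
#' @param min_genomes minimum number of origins for a phylum to be reported
#'   (default 15).
#' @return a `bus_cohort` object; see [tidy.bus_cohort()],
#'   [glance.bus_cohort()] and [autoplot.bus_cohort()].
#' @export
summarize_cohort <- function(results, min_genomes = 15L) {
  cc <- cohort_counts(results)
  found <- filter(results, .data$found)

  spacer_histogram <- count(found, spacer = .data$spacer, name = "n")

  trio_freqs <- tibble(trio_index = integer(), position = integer(),
                       base = character(), n = integer(), freq = double())
  if (nrow(found) > 0L) {
    per_trio <- list_rbind(map(seq_len(nrow(found)), function(i) {
      trios <- split_trios(found$trio_seqs[i])[[1]]
      tibble(trio_index = seq_along(trios), trio = trios)
    }))
    trio_freqs <- per_trio |>
      mutate(b1 = str_sub(.data$trio, 1, 1),
             b2 = str_sub(.data$trio, 2, 2),
             b3 = str_sub(.data$trio, 3, 3)) |>
      tidyr::pivot_longer(c("b1", "b2", "b3"), names_to = "position",
                          values_to = "base") |>
      mutate(position = as.integer(sub("b", "", .data$position))) |>
      count(.data$trio_index, .data$position, .data$base, name = "n") |>
      group_by(.data$trio_index, .data$position) |>
      mutate(freq = .data$n / sum(.data$n)) |>
      ungroup()
  }

  per_phylum <- results |>
    mutate(phylum = phylum_of(.data$lineage)) |>
    group_by(.data$phylum) |>
    summarise(n_origins = n(),
              n_found = sum(.data$found),
              n_tandem = sum(.data$found & !is.na(.data$box2_start)),
              .groups = "drop") |>
    filter(.data$n_found >= 1L, .data$n_origins >= min_genomes) |>
    mutate(prevalence = .data$n_found / .data$n_origins,
           tandem_fraction = ifelse(.data$n_found > 0,
                                    .data$n_tandem / .data$n_found, NA_real_))

  structure(list(
    n_origins = cc$n_origins,
    n_found = cc$n_found,
    prevalence = if (cc$n_origins > 0) cc$n_found / cc$n_origins else 0,
    prevalence_defined = cc$n_origins > 0,
    tandem_fraction = if (cc$n_found > 0) cc$n_tandem / cc$n_found else NA_real_,
    spacer_histogram = spacer_histogram,
    trio_position_freqs = trio_freqs,
    per_phylum = per_phylum,
    min_genomes = as.integer(min_genomes)
  ), class = "bus_cohort")
}

#' @export
print.bus_cohort <- function(x, ...) {
  cat("<bus_cohort>\n")
  cat(sprintf("  origins: %d, with BUS: %d (prevalence %.3f%s)\n",
              x$n_origins, x$n_found, x$prevalence,
              if (!x$prevalence_defined) ", undefined: empty cohort" else ""))
  cat(sprintf("  tandem fraction among found: %s\n",
              ifelse(is.na(x$tandem_fraction), "NA",
                     sprintf("%.3f", x$tandem_fraction))))
  cat(sprintf("  phyla reported (>= %d origins): %d\n",
              x$min_genomes, nrow(x$per_phylum)))
  invisible(x)
}

#' Glance at a cohort summary
#'
#' @param x a `bus_cohort` object.
#' @param ... unused.
#' @return a one-row tibble: `n_origins`, `n_found`, `prevalence`,
#'   `tandem_fraction`.
#' @method glance bus_cohort
#' @export
glance.bus_cohort <- function(x, ...) {
  tibble(n_origins = x$n_origins, n_found = x$n_found,
         prevalence = x$prevalence, tandem_fraction = x$tandem_fraction)
}

#' Tidy a cohort summary into one of its component tables
#'
#' @param x a `bus_cohort` object.
#' @param what `"phyla"` (per-phylum statistics), `"spacer"` (spacer-length
#'   histogram) or `"trios"` (per-position trio base frequencies).
#' @param ... unused.
#' @return a tibble.
#' @method tidy bus_cohort
#' @export
tidy.bus_cohort <- function(x, what = c("phyla", "spacer", "trios"), ...) {
  what <- match.arg(what)
  switch(what,
         phyla = x$per_phylum,
         spacer = x$spacer_histogram,
         trios = x$trio_position_freqs)
}

#' Plot a cohort summary
#'
#' `type = "spacer"` draws the spacer-length histogram; `type = "trios"`
#' draws per-position base frequencies faceted by trio index (index 1 is
#' box-proximal).
#'
#' @param object a `bus_cohort` object.
#' @param type which panel to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot bus_cohort
#' @export
autoplot.bus_cohort <- function(object, type = c("spacer", "trios"), ...) {
  type <- match.arg(type)
  if (type == "spacer") {
    ggplot(object$spacer_histogram, aes(x = .data$spacer, y = .data$n)) +
      geom_col(fill = "#e08214") +
      scale_x_continuous(breaks = function(lims) seq(0, ceiling(lims[2]), 2)) +
      labs(x = "spacer length (bp)", y = "origins",
           title = "Box-to-trios spacer distribution") +
      theme_minimal()
  } else {
    ggplot(object$trio_position_freqs,
           aes(x = factor(.data$position), y = .data$freq, fill = .data$base)) +
      geom_col() +
      facet_grid(. ~ .data$trio_index) +
      labs(x = "position within trio", y = "base frequency",
           title = "DnaA-trio composition by trio index (1 = box-proximal)") +
      theme_minimal()
  }
}

#' Export per-origin annotation tracks
#'
#' Writes the data behind the three origin-annotation rings: trio score,
#' spacer length, and box conservation class (mismatch count of the more
#' conserved box), plus a tandem flag. Origins without a BUS call get empty
#' track fields.
#'
#' @param results a result tibble from [search_origins()].
#' @param path output TSV path.
#' @return the track tibble, invisibly.
#' @export
export_tracks <- function(results, path) {
  tracks <- tibble(
    id = results$id,
    found = results$found,
    trio_score = ifelse(results$found, results$trio_score, NA_real_),
    spacer = ifelse(results$found, results$spacer, NA_integer_),
    box_conservation = ifelse(results$found, results$primary_mm, NA_integer_),
    tandem = ifelse(results$found, !is.na(results$box2_start), NA)
  )
  readr::write_tsv(tracks, path, na = "")
  invisible(tracks)
}
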