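# Build a small labelled cohort once: 8 planted origins (4 of them tandem)
# across two phyla, plus 2 background-only origins.
make_cohort <- function() {
  specs <- c(
    lapply(1:4, function(i) plant_spec(box_mm = i %% 3, spacer = 13,
                                       trio_count = 4 + i %% 3,
                                       trio_comp = "random",
                                       strand = c("+", "-")[1 + i %% 2])),
    lapply(1:4, function(i) plant_spec(
      box_mm = 0, box2 = list(mm = 2 + i %% 3, side = "downstream", gap = 2),
      spacer = 15, trio_count = 5, trio_comp = "consensus")),
    lapply(1:2, function(i) background_spec())
  )
  lineages <- c(rep("Bacillota;Bacillaceae", 5),
                rep("Pseudomonadota;Enterobacteriaceae", 5))
  out <- lapply(seq_along(specs), function(i) {
    generate_origin(specs[[i]], seed = 9000 + i, id = sprintf("c%02d", i),
                    lineage = lineages[i])
  })
  dplyr::bind_rows(lapply(out, function(x) x$origin))
}

cohort_origins <- make_cohort()
cohort_results <- search_origins(cohort_origins)

test_that("an empty cohort summarises to zeros with an undefined-prevalence flag", {
  cs <- summarize_cohort(cohort_results[0, ])
  expect_equal(cs$n_origins, 0L)
  expect_equal(cs$n_found, 0L)
  expect_equal(cs$prevalence, 0)
  expect_false(cs$prevalence_defined)
  expect_equal(nrow(cs$spacer_histogram), 0L)
})

test_that("prevalence and tandem fraction count planted modules exactly", {
  cs <- summarize_cohort(cohort_results, min_genomes = 1L)
  expect_equal(cs$n_origins, 10L)
  expect_equal(cs$n_found, 8L)
  expect_equal(cs$prevalence, 0.8)
  expect_equal(cs$tandem_fraction, 0.5)
  expect_true(cs$prevalence_defined)
  # spacer histogram sums to the number of found origins
  expect_equal(sum(cs$spacer_histogram$n), cs$n_found)
  # all sole modules were planted at 13, all tandem at 15
  expect_equal(sort(cs$spacer_histogram$spacer), c(13, 15))
  expect_equal(cs$spacer_histogram$n[cs$spacer_histogram$spacer == 13], 4L)
})

test_that("trio base frequencies are per index and position, box-proximal first", {
  # degenerate cohort: every planted run is the consensus
  g <- lapply(1:3, function(i) generate_origin(
    plant_spec(trio_count = 4, trio_comp = "consensus"),
    seed = 400 + i, id = paste0("t", i)))
  res <- search_origins(dplyr::bind_rows(lapply(g, `[[`, "origin")))
  cs <- summarize_cohort(res, min_genomes = 1L)
  tf <- cs$trio_position_freqs
  expect_equal(sort(unique(tf$trio_index)), 1:4)
  # every trio is TAG: frequency 1 at T/A/G for positions 1/2/3
  expect_true(all(tf$freq == 1))
  expect_equal(tf$base[tf$position == 1], rep("T", 4))
  expect_equal(tf$base[tf$position == 2], rep("A", 4))
  expect_equal(tf$base[tf$position == 3], rep("G", 4))
  # frequencies sum to one within each (index, position)
  cs2 <- summarize_cohort(cohort_results, min_genomes = 1L)
  sums <- tapply(cs2$trio_position_freqs$freq,
                 paste(cs2$trio_position_freqs$trio_index,
                       cs2$trio_position_freqs$position), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("per-phylum grouping uses the first lineage rank and the min-genomes filter", {
  cs <- summarize_cohort(cohort_results, min_genomes = 1L)
  expect_setequal(cs$per_phylum$phylum, c("Bacillota", "Pseudomonadota"))
  expect_equal(sum(cs$per_phylum$n_origins), 10L)
  expect_equal(sum(cs$per_phylum$n_found), 8L)
  # the default threshold of 15 genomes hides both 5-genome phyla
  cs15 <- summarize_cohort(cohort_results)
  expect_equal(nrow(cs15$per_phylum), 0L)
  # absent lineage groups as unclassified
  res2 <- cohort_results
  res2$lineage <- ""
  csu <- summarize_cohort(res2, min_genomes = 1L)
  expect_equal(csu$per_phylum$phylum, "unclassified")
})

test_that("summaries are permutation-invariant and merge additively", {
  cs <- summarize_cohort(cohort_results, min_genomes = 1L)
  perm <- cohort_results[sample(nrow(cohort_results)), ]
  csp <- summarize_cohort(perm, min_genomes = 1L)
  expect_equal(csp$prevalence, cs$prevalence)
  expect_equal(csp$tandem_fraction, cs$tandem_fraction)
  expect_equal(dplyr::arrange(csp$spacer_histogram, spacer),
               dplyr::arrange(cs$spacer_histogram, spacer))
  expect_equal(csp$per_phylum, cs$per_phylum)

  # two disjoint halves recombine to the whole
  a <- cohort_results[1:5, ]
  b <- cohort_results[6:10, ]
  ca <- summarize_cohort(a, min_genomes = 1L)
  cb <- summarize_cohort(b, min_genomes = 1L)
  expect_equal(ca$n_found + cb$n_found, cs$n_found)
  expect_equal((ca$prevalence * ca$n_origins + cb$prevalence * cb$n_origins) /
                 (ca$n_origins + cb$n_origins), cs$prevalence)
  merged_hist <- dplyr::count(
    dplyr::bind_rows(ca$spacer_histogram, cb$spacer_histogram),
    spacer, wt = n, name = "n")
  expect_equal(dplyr::arrange(merged_hist, spacer),
               dplyr::arrange(cs$spacer_histogram, spacer))
})

test_that("glance, tidy and autoplot expose the summary in broom/ggplot style", {
  cs <- summarize_cohort(cohort_results, min_genomes = 1L)
  g <- glance(cs)
  expect_s3_class(g, "tbl_df")
  expect_equal(nrow(g), 1L)
  expect_named(g, c("n_origins", "n_found", "prevalence", "tandem_fraction"))
  expect_s3_class(tidy(cs, "phyla"), "tbl_df")
  expect_s3_class(tidy(cs, "spacer"), "tbl_df")
  expect_s3_class(tidy(cs, "trios"), "tbl_df")
  expect_s3_class(autoplot(cs, "spacer"), "ggplot")
  expect_s3_class(autoplot(cs, "trios"), "ggplot")
  expect_output(print(cs), "origins: 10")
})

test_that("exported tracks carry the planted parameters and empty rows for misses", {
  g <- generate_origin(plant_spec(box_mm = 1, spacer = 12, trio_count = 6,
                                  trio_comp = "consensus"),
                       seed = 77, id = "trk")
  gn <- generate_origin(background_spec(), seed = 78, id = "none")
  res <- search_origins(dplyr::bind_rows(g$origin, gn$origin))
  path <- withr::local_tempfile(fileext = ".tsv")
  tracks <- export_tracks(res, path)
  expect_true(file.exists(path))
  expect_equal(tracks$trio_score[1], 6 * 3)   # 6 consensus trios, w_full = 3
  expect_equal(tracks$spacer[1], 12L)
  expect_equal(tracks$box_conservation[1], 1L)
  expect_false(tracks$tandem[1])
  expect_true(all(is.na(tracks[2, c("trio_score", "spacer",
                                    "box_conservation", "tandem")])))
})
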