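p_def <- bus_params()

test_that("a perfect sole-box module yields exactly one candidate at the planted locus", {
  s <- synth_origin(spacer = 13, trios = rep("TAG", 7))
  cands <- enumerate_candidates(list(id = "x", sequence = s), p_def)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$strand, "+")
  expect_equal(cands$box1_start, 30L)
  expect_equal(cands$ref_start, 30L)
  expect_equal(cands$spacer, 13L)
  expect_equal(cands$trio_count, 7L)
  expect_true(is.na(cands$box2_start))
})

test_that("a spacer beyond the maximum excludes the pairing", {
  s <- synth_origin(spacer = 17)
  expect_equal(nrow(enumerate_candidates(list(sequence = s), p_def)), 0L)
  expect_false(search_origin(list(id = "x", sequence = s), p_def)$found)
})

test_that("tandem spacer decomposes as gap + secondary box + second gap", {
  # perfect upstream box, 2 bp gap, secondary with 3 mismatches, 4 bp to trios
  box2 <- subst("TTATCCACA", c(1, 3, 5), c("G", "G", "G"))
  s <- paste0(strrep("C", 30), "TTATCCACA", "GG", box2, "GGGG",
              strrep("TAG", 5), strrep("C", 30))
  cands <- enumerate_candidates(list(sequence = s), p_def)
  main <- cands[cands$box1_start == 30L, ]
  expect_equal(nrow(main), 1L)
  expect_equal(main$ref_box, "box1")
  expect_equal(main$ref_start, 30L)
  expect_equal(main$spacer, 2L + 9L + 4L)
  expect_equal(main$box2_side, "downstream")
  expect_equal(main$box2_mm, 3L)
  res <- screen_candidates(cands, p_def)
  expect_true(res$found)
  expect_equal(res$spacer, 15L)
  expect_equal(res$box2_mm, 3L)
})

test_that("an upstream secondary with fewer mismatches re-anchors the spacer past 16 bp", {
  box1 <- subst("TTATCCACA", 5, "G")  # 1 mismatch, first located
  s <- paste0(strrep("C", 30), "TTATCCACA", "GG", box1, strrep("G", 14),
              strrep("TAG", 5), strrep("C", 30))
  res <- search_origin(list(id = "x", sequence = s), p_def)
  expect_true(res$found)
  expect_equal(res$ref_start, 30L)           # the perfect upstream copy
  expect_equal(res$spacer, 2L + 9L + 14L)    # recounted, exceeds max_spacer
  expect_gt(res$spacer, p_def$max_spacer)
})

test_that("screening filters apply in order: score, then mismatches, then spacer", {
  base <- enumerate_candidates(list(sequence = synth_origin()), p_def)
  stopifnot(nrow(base) == 1L)
  mk <- function(sc, mmv, sp, rs = 30L, st = "+") {
    dplyr::mutate(base, trio_score = sc, primary_mm = mmv, box1_mm = mmv,
                  spacer = sp, ref_start = rs, strand = st)
  }
  # higher trio score wins regardless of mismatches and spacer
  two <- dplyr::bind_rows(mk(9, 2, 16), mk(5, 0, 13, rs = 100L))
  r <- screen_candidates(two, p_def)
  expect_equal(r$trio_score, 9)
  expect_equal(r$tie_count, 1L)
  # equal score: fewer mismatches wins regardless of spacer
  two <- dplyr::bind_rows(mk(9, 2, 13), mk(9, 1, 16, rs = 100L))
  expect_equal(screen_candidates(two, p_def)$primary_mm, 1L)
  # equal score and mismatches: spacer closest to 13 wins
  two <- dplyr::bind_rows(mk(9, 1, 16), mk(9, 1, 13, rs = 100L))
  expect_equal(screen_candidates(two, p_def)$spacer, 13L)
  # empty candidate list: not found
  r0 <- screen_candidates(base[0, ], p_def)
  expect_false(r0$found)
  expect_equal(r0$candidates_considered, 0L)
})

test_that("screening is invariant under permutation of its input", {
  set.seed(501)
  sim <- simulate_origins(6, seed = 31)
  for (i in seq_len(nrow(sim$origins))) {
    cands <- enumerate_candidates(sim$origins[i, ], p_def)
    if (nrow(cands) < 2L) next
    ref <- screen_candidates(cands, p_def)
    for (rep in 1:5) {
      perm <- cands[sample(nrow(cands)), ]
      expect_equal(screen_candidates(perm, p_def), ref)
    }
  }
  # and on a constructed two-module origin
  s <- paste0(strrep("C", 20), "TTATCCACA", strrep("G", 13), strrep("TAG", 5),
              strrep("C", 40), "TTATCCACA", strrep("G", 8), strrep("TAG", 5),
              strrep("C", 20))
  cands <- enumerate_candidates(list(sequence = s), p_def)
  expect_gte(nrow(cands), 2L)
  ref <- screen_candidates(cands, p_def)
  expect_equal(screen_candidates(cands[rev(seq_len(nrow(cands))), ], p_def),
               ref)
})

test_that("each screening step never increases the surviving set", {
  # reimplement the cascade as the oracle and compare the retained call
  set.seed(502)
  sim <- simulate_origins(8, seed = 77)
  for (i in seq_len(nrow(sim$origins))) {
    cands <- enumerate_candidates(sim$origins[i, ], p_def)
    if (nrow(cands) == 0L) next
    s1 <- cands[cands$trio_score == max(cands$trio_score), ]
    s2 <- s1[s1$primary_mm == min(s1$primary_mm), ]
    d <- abs(s2$spacer - p_def$preferred_spacer)
    s3 <- s2[d == min(d), ]
    expect_lte(nrow(s1), nrow(cands))
    expect_lte(nrow(s2), nrow(s1))
    expect_lte(nrow(s3), nrow(s2))
    got <- screen_candidates(cands, p_def)
    expect_equal(got$tie_count, nrow(s3))
    s3 <- s3[order(match(s3$strand, c("+", "-")), s3$ref_start), ]
    expect_equal(got$ref_start, s3$ref_start[1])
    expect_equal(got$spacer, s3$spacer[1])
  }
})

test_that("co-equal candidates tie deterministically, leftmost plus-strand first", {
  s <- paste0(strrep("C", 20), "TTATCCACA", strrep("G", 13), strrep("TAG", 5),
              strrep("C", 40), "TTATCCACA", strrep("G", 13), strrep("TAG", 5),
              strrep("C", 20))
  res <- search_origin(list(id = "tie", sequence = s), p_def)
  expect_true(res$found)
  expect_equal(res$tie_count, 2L)
  expect_equal(res$candidates_considered, 2L)
  expect_equal(res$ref_start, 20L)
  expect_equal(res$strand, "+")
})

test_that("two co-equal modules differing only in spacer resolve to the 13 bp one", {
  s <- paste0(strrep("C", 20), "TTATCCACA", strrep("G", 7), strrep("TAG", 5),
              strrep("C", 40), "TTATCCACA", strrep("G", 13), strrep("TAG", 5),
              strrep("C", 20))
  res <- search_origin(list(id = "x", sequence = s), p_def)
  expect_true(res$found)
  expect_equal(res$spacer, 13L)
  expect_equal(res$tie_count, 1L)
})

test_that("detection is exact at every rule boundary (9 and 12 bp motifs)", {
  run1 <- function(seq, motif = "TTATCCACA") {
    search_origin(list(id = "b", sequence = seq, box_motif = motif), p_def)
  }
  # sole-box mismatches: cap 2 for the 9-bp motif
  expect_true(run1(synth_origin(box = subst("TTATCCACA", c(2, 4), "G")))$found)
  expect_false(run1(synth_origin(box = subst("TTATCCACA", c(2, 4, 6), "G")))$found)
  # spacer: cap 16
  expect_true(run1(synth_origin(spacer = 16))$found)
  expect_false(run1(synth_origin(spacer = 17))$found)
  # trio count: minimum 3
  expect_true(run1(synth_origin(trios = rep("TAG", 3)))$found)
  expect_false(run1(synth_origin(trios = rep("TAG", 2)))$found)
  # long motif: cap rises to 3
  m12 <- "TTATCCACAGGT"
  expect_true(run1(synth_origin(box = subst(m12, c(2, 4, 6), "G")), m12)$found)
  expect_false(run1(synth_origin(box = subst(m12, c(2, 4, 6, 8), "G")), m12)$found)
  # secondary box: cap 4 (largest mismatch count still reported as tandem)
  tandem <- function(mm2) {
    box2 <- if (mm2 > 0) subst("TTATCCACA", seq_len(mm2) * 2 - 1, "G")
            else "TTATCCACA"
    s <- paste0(strrep("C", 30), "TTATCCACA", "GG", box2, "GGGG",
                strrep("TAG", 5), strrep("C", 30))
    search_origin(list(id = "t", sequence = s), p_def)
  }
  r4 <- tandem(4)
  expect_true(r4$found)
  expect_equal(r4$box2_mm, 4L)
  r5 <- tandem(5)
  expect_true(r5$found)            # the sole-box module is still there
  expect_true(is.na(r5$box2_mm))   # but no secondary is attached
})

test_that("searching the reverse complement finds the same module on the minus strand", {
  set.seed(503)
  sim <- simulate_origins(5, seed = 19)
  for (i in seq_len(nrow(sim$origins))) {
    o <- sim$origins[i, ]
    res_f <- search_origin(o, p_def)
    o_rc <- o
    o_rc$sequence <- oracle_revcomp(o$sequence)
    res_r <- search_origin(o_rc, p_def)
    expect_true(res_r$found)
    expect_equal(res_r$strand, ifelse(res_f$strand == "+", "-", "+"))
    expect_equal(res_r$ref_start, res_f$ref_start)
    expect_equal(res_r$spacer, res_f$spacer)
    expect_equal(res_r$trio_count, res_f$trio_count)
    expect_equal(res_r$trio_seqs, res_f$trio_seqs)
  }
})

test_that("restricting to the plus strand hides minus-strand modules", {
  g <- generate_origin(plant_spec(strand = "-"), seed = 11, id = "m")
  expect_true(search_origin(g$origin, p_def)$found)
  p_plus <- bus_params(strands = "plus")
  expect_false(search_origin(g$origin, p_plus)$found)
})
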