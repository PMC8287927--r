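# Seeded synthetic-origin generator with planted BUS ground truth.
#
# A fixture is a random background with one BUS cassette inserted. The
# background is cleaned so that, outside the planted module, there is no
# DnaA-box hit within the secondary cap and no trio run long enough to seed a
# candidate, on either strand; cleaning is done by targeted single-base
# repair of each violating window (whole-sequence rejection sampling is
# hopeless: random DNA carries several qualifying trio runs per strand).
# Every fixture is verified at generation time by running the scanner and
# requiring that it reproduces the planted truth exactly; a failed
# verification redraws the background (bounded attempts).

DNA_BASES <- c("A", "C", "G", "T")

random_bases <- function(n, gc = 0.5) {
  if (n <= 0L) return(character(0))
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Plant `mm` substitutions at distinct random positions of a concrete motif.
mutate_motif <- function(motif, mm) {
  ch <- seq_chars(motif)
  if (any(!ch %in% DNA_BASES))
    abort("Planted motifs must be concrete (A/C/G/T only).")
  if (mm > length(ch)) abort("More mismatches requested than motif positions.")
  if (mm > 0L) {
    pos <- sample(length(ch), mm)
    for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

make_trios <- function(count, comp) {
  if (length(comp) > 1L || !comp %in% c("consensus", "random", "nonconsensus")) {
    trios <- str_to_upper(comp)
    if (length(trios) != count || any(nchar(trios) != 3L) ||
        any(str_sub(trios, 2, 2) != "A"))
      abort("Explicit trios must be `count` 3-mers with middle base A.")
    return(trios)
  }
  if (comp == "consensus") return(rep(TRIO_CONSENSUS, count))
  draw <- function() paste0(sample(DNA_BASES, 1), "A", sample(DNA_BASES, 1))
  trios <- vapply(seq_len(count), function(i) draw(), character(1))
  if (comp == "nonconsensus") {
    while (any(trios == TRIO_CONSENSUS))
      trios[trios == TRIO_CONSENSUS] <-
        vapply(seq_len(sum(trios == TRIO_CONSENSUS)),
               function(i) draw(), character(1))
  }
  trios
}

#' Specify a synthetic origin with (or without) a planted BUS module
#'
#' Describes one fixture: the planted DnaA-box (motif and number of planted
#' substitutions), an optional secondary box (side, inter-box gap and its own
#' substitutions), the spacer length, the trio run (count and composition),
#' the strand the module sits on, and the background (total length and GC
#' fraction). `plant = FALSE` gives a background-only negative control.
#'
#' For a downstream secondary box, `spacer` is the full distance from the
#' first box to the trios and must be at least `gap + nchar(motif)` (the
#' secondary box and both gaps sit inside it). For an upstream secondary,
#' `spacer` is the first-box-to-trios distance; when the upstream box carries
#' strictly fewer substitutions it anchors the module and the effective
#' spacer grows by `gap + nchar(motif)`.
#'
#' @param box_mm substitutions planted in the first box.
#' @param box2 `NULL`, or `list(mm =, side = "upstream"|"downstream", gap =)`.
#' @param spacer spacer length, bp.
#' @param trio_count number of planted trios.
#' @param trio_comp `"consensus"`, `"random"`, `"nonconsensus"`, or a
#'   character vector of `trio_count` explicit N-A-N 3-mers.
#' @param strand strand carrying the module.
#' @param offset 0-based insertion offset of the cassette (random if `NULL`).
#' @param bg_length total origin length, bp.
#' @param gc background GC fraction.
#' @param motif the standard box motif planted (concrete A/C/G/T).
#' @param plant `FALSE` for a background-only origin.
#' @return a `plant_spec` object.
#' @export
plant_spec <- function(box_mm = 0L, box2 = NULL, spacer = 13L,
                       trio_count = 5L, trio_comp = "consensus",
                       strand = "+", offset = NULL, bg_length = 300L,
                       gc = 0.5, motif = DEFAULT_BOX_MOTIF, plant = TRUE) {
  spec <- list(box_mm = as.integer(box_mm), box2 = box2,
               spacer = as.integer(spacer),
               trio_count = as.integer(trio_count), trio_comp = trio_comp,
               strand = strand, offset = offset,
               bg_length = as.integer(bg_length), gc = gc,
               motif = str_to_upper(motif), plant = isTRUE(plant))
  if (!strand %in% c("+", "-")) abort("`strand` must be '+' or '-'.")
  if (spec$plant) {
    if (spec$spacer < 0L) abort("`spacer` must be >= 0.")
    if (spec$trio_count < 1L) abort("`trio_count` must be >= 1.")
    if (length(trio_comp) > 1L ||
        !trio_comp %in% c("consensus", "random", "nonconsensus")) {
      trios <- str_to_upper(trio_comp)
      if (length(trios) != spec$trio_count || any(nchar(trios) != 3L) ||
          any(substr(trios, 2, 2) != "A"))
        abort("Explicit trios must be `trio_count` 3-mers with middle base A.")
      spec$trio_comp <- trios
    }
    if (!is.null(box2)) {
      if (!is.list(box2) || !all(c("mm", "side", "gap") %in% names(box2)))
        abort("`box2` must be list(mm =, side =, gap =).")
      if (!box2$side %in% c("upstream", "downstream"))
        abort("`box2$side` must be 'upstream' or 'downstream'.")
      if (box2$side == "downstream" &&
          spec$spacer < box2$gap + nchar(spec$motif))
        abort("Downstream secondary needs spacer >= gap + motif length.")
    }
  }
  structure(spec, class = "plant_spec")
}

#' Background-only negative-control spec
#'
#' @inheritParams plant_spec
#' @return a `plant_spec` with `plant = FALSE`.
#' @export
background_spec <- function(bg_length = 300L, gc = 0.5,
                            motif = DEFAULT_BOX_MOTIF) {
  plant_spec(bg_length = bg_length, gc = gc, motif = motif, plant = FALSE)
}

# ---- background cleaning ---------------------------------------------------

overlaps <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end & b_start < a_end
}

in_any_interval <- function(pos, intervals) {
  if (length(intervals) == 0L) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (iv in intervals) out <- out | (pos >= iv[1] & pos < iv[2])
  out
}

# Remove, by targeted single-base mutation, every box hit within `max_mm` and
# every trio run of >= min_trios on either strand whose window does not
# overlap a protected interval (0-based half-open, forward coordinates).
# Protected single bases (guards) are never mutated. Returns the repaired
# character vector or NULL when passes are exhausted.
clean_sequence <- function(ch, protect, motif, params, max_passes = 40L) {
  n <- length(ch)
  L <- nchar(motif)
  mpos <- seq_chars(motif)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (pass in seq_len(max_passes)) {
    dirty <- FALSE
    for (strand in c("+", "-")) {
      seq_str <- paste(ch, collapse = "")
      if (strand == "-") seq_str <- revcomp(seq_str)
      to_fwd <- function(s, len) {
        if (strand == "+") s else n - (s + len)
      }
      hits <- box_hits_core(seq_str, motif, params$max_mm_secondary)
      for (i in seq_along(hits$start)) {
        s <- hits$start[i]
        f0 <- to_fwd(s, L)
        if (any(vapply(protect, function(iv)
          overlaps(f0, f0 + L, iv[1], iv[2]), logical(1)))) next
        # mutate one currently-matching motif position to push the
        # distance past the cap
        obs <- seq_chars(hits$observed[i])
        match_j <- which(obs == mpos)
        fwd_pos <- if (strand == "+") s + match_j - 1L else n - (s + match_j)
        usable <- which(!in_any_interval(fwd_pos, protect))
        if (length(usable) == 0L) next
        j <- match_j[usable[sample.int(length(usable), 1L)]]
        new_scanned <- sample(setdiff(DNA_BASES, mpos[j]), 1L)
        p <- if (strand == "+") s + j else n - (s + j) + 1L  # 1-based
        ch[p] <- if (strand == "+") new_scanned else comp[[new_scanned]]
        dirty <- TRUE
      }
      runs <- trio_runs_core(if (dirty) {
        if (strand == "-") revcomp(paste(ch, collapse = "")) else
          paste(ch, collapse = "")
      } else seq_str)
      for (i in which(runs$count >= params$min_trios)) {
        s <- runs$start[i]
        len <- 3L * runs$count[i]
        f0 <- to_fwd(s, len)
        if (any(vapply(protect, function(iv)
          overlaps(f0, f0 + len, iv[1], iv[2]), logical(1)))) next
        # break every third trio's middle adenine
        mids <- s + 3L * (seq(3L, runs$count[i], by = 3L) - 1L) + 1L
        if (length(mids) == 0L) mids <- s + 1L
        fwd_mid <- if (strand == "+") mids else n - mids - 1L
        usable <- fwd_mid[!in_any_interval(fwd_mid, protect)]
        if (length(usable) == 0L) next
        for (p0 in usable) {
          new_scanned <- sample(c("C", "G"), 1L)
          ch[p0 + 1L] <- if (strand == "+") new_scanned else comp[[new_scanned]]
        }
        dirty <- TRUE
      }
    }
    if (!dirty) return(ch)
  }
  NULL
}

# ---- cassette assembly -----------------------------------------------------

# Assemble the planted cassette in scanned (module) orientation and record
# the within-cassette layout. Returns NULL when the drawn mutations make the
# plant inconsistent (the 3-mer preceding the trio run is forced N-A-N).
build_cassette <- function(spec) {
  L <- nchar(spec$motif)
  box1 <- mutate_motif(spec$motif, spec$box_mm)
  trios <- make_trios(spec$trio_count, spec$trio_comp)
  trio_str <- paste(trios, collapse = "")
  rand_region <- integer(0)  # cassette-local 0-based indices that are filler

  if (is.null(spec$box2)) {
    filler <- random_bases(spec$spacer, spec$gc)
    parts <- c(seq_chars(box1), filler, seq_chars(trio_str))
    box1_off <- 0L
    box2_off <- NA_integer_
    trio_off <- L + spec$spacer
    if (spec$spacer > 0L) rand_region <- L + seq_len(spec$spacer) - 1L
    box2_seq <- NA_character_
  } else if (spec$box2$side == "downstream") {
    box2_seq <- mutate_motif(spec$motif, spec$box2$mm)
    gap1 <- spec$box2$gap
    gap2 <- spec$spacer - gap1 - L
    parts <- c(seq_chars(box1), random_bases(gap1, spec$gc),
               seq_chars(box2_seq), random_bases(gap2, spec$gc),
               seq_chars(trio_str))
    box1_off <- 0L
    box2_off <- L + gap1
    trio_off <- L + spec$spacer
    rand_region <- c(if (gap1 > 0L) L + seq_len(gap1) - 1L,
                     if (gap2 > 0L) L + gap1 + L + seq_len(gap2) - 1L)
  } else {
    box2_seq <- mutate_motif(spec$motif, spec$box2$mm)
    gap <- spec$box2$gap
    parts <- c(seq_chars(box2_seq), random_bases(gap, spec$gc),
               seq_chars(box1), random_bases(spec$spacer, spec$gc),
               seq_chars(trio_str))
    box2_off <- 0L
    box1_off <- L + gap
    trio_off <- box1_off + L + spec$spacer
    rand_region <- c(if (gap > 0L) L + seq_len(gap) - 1L,
                     if (spec$spacer > 0L) box1_off + L + seq_len(spec$spacer) - 1L)
  }

  # guard: the 3-mer immediately preceding the trio run (same phase) must not
  # be N-A-N, or the maximal run swallows the upstream element
  guard <- integer(0)
  pre_mid <- trio_off - 2L
  if (pre_mid >= 0L) {
    if (pre_mid %in% rand_region) {
      parts[pre_mid + 1L] <- sample(c("C", "G"), 1L)
      guard <- pre_mid
    } else if (parts[pre_mid + 1L] == "A") {
      return(NULL)  # forced extension; this draw cannot represent the plant
    }
  }
  list(chars = parts, box1_off = box1_off, box2_off = box2_off,
       trio_off = trio_off, trios = trios, box1 = box1, box2 = box2_seq,
       guard = guard)
}

# Expected (truth) call for a spec, mirroring the documented search rules.
expected_truth <- function(spec, cass, offset, n, params) {
  L <- nchar(spec$motif)
  cap1 <- cap_primary(L, params)
  box1_start <- offset + cass$box1_off
  box2_start <- if (!is.null(spec$box2)) offset + cass$box2_off else NA_integer_
  trio_start <- offset + cass$trio_off
  box2_eff <- !is.null(spec$box2) && spec$box2$mm <= params$max_mm_secondary
  expect_found <- spec$plant && spec$box_mm <= cap1 &&
    spec$spacer <= params$max_spacer && spec$trio_count >= params$min_trios
  takeover <- box2_eff && !is.null(spec$box2) &&
    spec$box2$side == "upstream" && spec$box2$mm < spec$box_mm
  ref_start <- if (takeover) box2_start else box1_start
  spacer_eff <- trio_start - (ref_start + L)
  tibble(
    expect_found = expect_found,
    strand = spec$strand,
    ref_start = as.integer(ref_start),
    box1_start = as.integer(box1_start), box1_mm = spec$box_mm,
    box2_present = box2_eff,
    box2_start = as.integer(box2_start),
    box2_side = if (!is.null(spec$box2)) spec$box2$side else NA_character_,
    box2_mm = if (!is.null(spec$box2)) as.integer(spec$box2$mm) else NA_integer_,
    spacer = as.integer(spacer_eff),
    trio_start = as.integer(trio_start),
    trio_count = spec$trio_count,
    trio_score = score_trios(cass$trios, params$trio_scoring),
    seq_len = as.integer(n)
  )
}

verify_fixture <- function(res, truth) {
  if (!truth$expect_found) return(!res$found)
  res$found &&
    identical(res$strand, truth$strand) &&
    res$ref_start == truth$ref_start &&
    res$spacer == truth$spacer &&
    res$trio_count == truth$trio_count &&
    (!is.na(res$box2_start)) == truth$box2_present &&
    (!truth$box2_present ||
       res$box2_start %in% c(truth$box1_start, truth$box2_start))
}

#' Generate one synthetic origin from a plant specification
#'
#' Deterministic for a fixed `seed`. The background is drawn, cleaned (see
#' the package vignette), and the finished sequence is verified by running
#' [search_origin()] and requiring that it reproduces the planted truth
#' (or reports no BUS, for background-only and beyond-cap specs). A failed
#' verification redraws the background; after `max_attempts` failures the
#' generator stops with the seed in the message.
#'
#' @param spec a [plant_spec()].
#' @param seed integer seed (optional but recommended).
#' @param params the [bus_params()] the fixture must be consistent with.
#' @param id record id for the generated origin.
#' @param organism,lineage metadata for the generated record.
#' @param max_attempts background redraws before giving up.
#' @return a list with `origin` (a one-row [origin_tbl()]) and `truth` (a
#'   one-row tibble of planted coordinates on the scanned strand, mismatch
#'   counts, spacer, trio count and score).
#' @export
generate_origin <- function(spec, seed = NULL, params = bus_params(),
                            id = "sim_1", organism = "", lineage = "",
                            max_attempts = 30L) {
  run <- function() {
    for (attempt in seq_len(max_attempts)) {
      out <- generate_origin_once(spec, params, id, organism, lineage)
      if (!is.null(out)) return(out)
    }
    abort(sprintf(
      "generate_origin: no valid fixture after %d attempts (id=%s, seed=%s); the spec may be inconsistent with the search parameters",
      max_attempts, id, ifelse(is.null(seed), "NULL", seed)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

generate_origin_once <- function(spec, params, id, organism, lineage) {
  n <- spec$bg_length
  if (!spec$plant) {
    ch <- random_bases(n, spec$gc)
    ch <- clean_sequence(ch, list(), spec$motif, params)
    if (is.null(ch)) return(NULL)
    origin <- origin_tbl(id = id, sequence = paste(ch, collapse = ""),
                         organism = organism, lineage = lineage,
                         box_motif = spec$motif)
    res <- search_origin(origin, params)
    if (res$found) return(NULL)
    truth <- tibble(id = id, expect_found = FALSE, strand = NA_character_,
                    ref_start = NA_integer_, box1_start = NA_integer_,
                    box1_mm = NA_integer_, box2_present = FALSE,
                    box2_start = NA_integer_, box2_side = NA_character_,
                    box2_mm = NA_integer_, spacer = NA_integer_,
                    trio_start = NA_integer_, trio_count = NA_integer_,
                    trio_score = NA_real_, seq_len = as.integer(n))
    return(list(origin = origin, truth = truth))
  }

  cass <- build_cassette(spec)
  if (is.null(cass)) return(NULL)
  clen <- length(cass$chars)
  if (n < clen + 4L)
    abort("`bg_length` too short for the requested cassette.")
  offset <- spec$offset %||% sample(0:(n - clen), 1L)
  if (offset < 0L || offset + clen > n)
    abort("`offset` places the cassette outside the sequence.")

  # scanned-orientation assembly, then flip to the forward strand if needed
  sc <- c(random_bases(offset, spec$gc), cass$chars,
          random_bases(n - offset - clen, spec$gc))
  # guard after the run: the following 3-mer (same phase) must not be N-A-N
  post_mid <- offset + cass$trio_off + 3L * spec$trio_count + 1L
  if (post_mid < n) sc[post_mid + 1L] <- sample(c("C", "G"), 1L)

  ch <- if (spec$strand == "-") seq_chars(revcomp(paste(sc, collapse = "")))
        else sc

  # protected intervals (forward coordinates): planted boxes, trio run, guards
  L <- nchar(spec$motif)
  to_fwd <- function(s, len) {
    if (spec$strand == "+") c(s, s + len) else c(n - (s + len), n - s)
  }
  protect <- list(to_fwd(offset + cass$box1_off, L),
                  to_fwd(offset + cass$trio_off, 3L * spec$trio_count))
  if (!is.na(cass$box2_off))
    protect <- c(protect, list(to_fwd(offset + cass$box2_off, L)))
  for (g in cass$guard)
    protect <- c(protect, list(to_fwd(offset + g, 1L)))
  if (post_mid < n) protect <- c(protect, list(to_fwd(post_mid, 1L)))

  ch <- clean_sequence(ch, protect, spec$motif, params)
  if (is.null(ch)) return(NULL)

  origin <- origin_tbl(id = id, sequence = paste(ch, collapse = ""),
                       organism = organism, lineage = lineage,
                       box_motif = spec$motif)
  truth <- expected_truth(spec, cass, offset, n, params)
  res <- search_origin(origin, params)
  if (!verify_fixture(res, truth)) return(NULL)
  if (truth$expect_found) {
    # the planted candidate must be among the enumerated candidates
    cands <- enumerate_candidates(origin, params)
    hit <- filter(cands, .data$strand == truth$strand,
                  .data$ref_start == truth$ref_start,
                  .data$trio_start == truth$trio_start,
                  .data$spacer == truth$spacer)
    if (nrow(hit) == 0L) return(NULL)
  }
  list(origin = origin, truth = mutate(truth, id = id, .before = 1L))
}

# Draw one random spec spanning the legal parameter box. Upstream-secondary
# specs are drawn either as takeovers (box2 strictly more conserved) or with
# box2 beyond the first-located cap, so the planted anchoring is unambiguous.
sample_plant_spec <- function(params, bg_length = 300L, gc = 0.5,
                              motif = DEFAULT_BOX_MOTIF) {
  L <- nchar(motif)
  cap1 <- cap_primary(L, params)
  strand <- sample(c("+", "-"), 1L)
  arrangement <- sample(c("sole", "down", "up"), 1L, prob = c(.5, .25, .25))
  trio_count <- sample(params$min_trios:8L, 1L)
  trio_comp <- sample(c("consensus", "random"), 1L, prob = c(.4, .6))
  spacer_pool <- c(0L, 2L:params$max_spacer)  # spacer 1 forces run extension
  if (arrangement == "sole") {
    plant_spec(box_mm = sample(0:cap1, 1L), spacer = sample(spacer_pool, 1L),
               trio_count = trio_count, trio_comp = trio_comp,
               strand = strand, bg_length = bg_length, gc = gc, motif = motif)
  } else if (arrangement == "down") {
    gap <- sample(0:params$max_interbox_gap, 1L)
    gap2 <- sample(c(0L, 2L, 3L, 4L), 1L)
    plant_spec(box_mm = sample(0:cap1, 1L),
               box2 = list(mm = sample(0:params$max_mm_secondary, 1L),
                           side = "downstream", gap = gap),
               spacer = gap + L + gap2,
               trio_count = trio_count, trio_comp = trio_comp,
               strand = strand, bg_length = bg_length, gc = gc, motif = motif)
  } else {
    takeover <- sample(c(TRUE, FALSE), 1L)
    if (takeover) {
      box_mm <- sample(1:cap1, 1L)
      box2_mm <- sample(0:(box_mm - 1L), 1L)
    } else {
      box_mm <- sample(0:cap1, 1L)
      box2_mm <- sample((cap1 + 1L):params$max_mm_secondary, 1L)
    }
    plant_spec(box_mm = box_mm,
               box2 = list(mm = box2_mm, side = "upstream",
                           gap = sample(0:params$max_interbox_gap, 1L)),
               spacer = sample(spacer_pool, 1L),
               trio_count = trio_count, trio_comp = trio_comp,
               strand = strand, bg_length = bg_length, gc = gc, motif = motif)
  }
}

#' Simulate a cohort of synthetic origins
#'
#' Draws `n` independent fixtures: either planted single-BUS origins whose
#' specs span the legal parameter box (both strands; sole, tandem-downstream
#' and tandem-upstream arrangements; mismatches up to the caps; spacers up to
#' the maximum; 3-8 trios of mixed composition), or background-only negative
#' controls. Deterministic for fixed `seed`; per-origin seeds are derived
#' from it.
#'
#' @param n number of origins.
#' @param seed integer master seed.
#' @param kind `"planted"` or `"background"`.
#' @param params the [bus_params()] the fixtures target.
#' @param bg_length,gc background length (bp) and GC fraction.
#' @param motif standard motif to plant.
#' @param lineage optional lineage string(s) recycled over origins.
#' @return a list with `origins` (an [origin_tbl()] tibble) and `truth` (one
#'   row per origin of planted ground truth).
#' @export
simulate_origins <- function(n, seed, kind = c("planted", "background"),
                             params = bus_params(), bg_length = 300L,
                             gc = 0.5, motif = DEFAULT_BOX_MOTIF,
                             lineage = "") {
  kind <- match.arg(kind)
  lineage <- rep_len(lineage, n)
  out <- map(seq_len(n), function(i) {
    seed_i <- (as.numeric(seed) + i * 9973) %% 2147483647
    id <- sprintf("sim_%05d", i)
    spec <- if (kind == "background") {
      background_spec(bg_length = bg_length, gc = gc, motif = motif)
    } else {
      withr::with_seed(seed_i, sample_plant_spec(params, bg_length, gc, motif))
    }
    generate_origin(spec, seed = (seed_i * 31) %% 2147483647, params = params,
                    id = id, lineage = lineage[i])
  })
  list(origins = list_rbind(map(out, "origin")),
       truth = list_rbind(map(out, "truth")))
}
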