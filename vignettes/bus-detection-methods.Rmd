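---
title: "Detecting basal unwinding system (BUS) modules in bacterial origins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting basal unwinding system (BUS) modules in bacterial origins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(buscan)
library(dplyr)
```

## The biological model

Bacterial chromosome replication initiates at a single locus, *oriC*, where
the initiator protein DnaA both binds double-stranded DNA and melts it. Two
sequence elements cooperate in the basal unwinding system (BUS):

* **DnaA-boxes** — asymmetric ~9 bp double-stranded motifs bound by DnaA
  domain IV. The highest-affinity consensus is 5'-TTATCCACA-3'; some species
  use a longer or divergent standard motif. A module may carry one box or a
  tandem pair in which the more conserved member anchors the module and the
  less conserved one tolerates more degeneracy.
* **DnaA-trios** — a run of repeating trinucleotides on which a DnaA oligomer
  assembles along one DNA strand. Each trio has a conserved adenine in the
  middle (pattern N-A-N); the consensus trio is written 3'-GAT-5' in the
  literature, which read 5'→3' on the scanned strand is `TAG`. At least three
  consecutive trios are required for origin function.
* **The spacer** — the bases strictly between the anchoring box's 3' end and
  the first trio. Surveyed origins peak around 10–13 bp, and the search caps
  it at 16 bp: the sum of a ≤3 bp inter-box gap, a ~9 bp less-conserved box
  and a ~4 bp second gap.

`buscan` implements the rule-based scanner that finds this architecture in
predicted origin sequences (e.g. DoriC exports), screens the candidates down
to a single call per origin, and aggregates calls into cohort statistics.

## The search and screening cascade

For each scanned strand (`find_box_hits()` / `find_trio_arrays()` scan the
reverse complement for `-`):

1. **Enumerate** (`enumerate_candidates()`): every maximal N-A-N run with at
   least `min_trios` trios is paired with every upstream box hit within the
   first-located mismatch cap (2 for a 9 bp motif, 3 for longer motifs) at
   spacer 0..16 bp. For each pair a secondary box with up to 4 mismatches is
   searched in two windows: inside the spacer (downstream of the first box)
   and immediately upstream of it, separated by at most 3 bp. When an
   upstream secondary is strictly better conserved than the first-located
   box, it becomes the reference box and the spacer is recounted from it —
   the one case in which a reported spacer may exceed 16 bp.
2. **Screen** (`screen_candidates()`), three filters in a fixed order:
   highest trio score, then fewest mismatches in the sole/more-conserved box,
   then spacer closest to 13 bp. Survivors of the last filter are reported in
   `tie_count`; the retained call is the leftmost plus-strand survivor. Ties
   are warned about, not errors: a small residue of multi-candidate origins
   is expected.

Matching is pure Hamming distance — no indels. Two wildcard conventions
matter and are asymmetric by design: an `N` *in the sequence* never matches
any motif position (ambiguous data must not create hits), while IUPAC codes
*in a motif* match their base set (`N` in a user-supplied species-specific
motif is a deliberate wildcard).

## Trio scoring

The screening cascade needs a total order on trio runs. The run score is not
uniquely determined by the published rule set, so the package makes it an
explicit, pluggable choice (`trio_scoring` in `bus_params()`):

* `consensus_weighted` (default): each trio contributes `w_full = 3` if it
  equals the consensus `TAG`, else `w_partial = 1`. This rewards both run
  length and consensus agreement, the two properties the survey emphasises.
* `count`: score = number of trios (set `w_full = w_partial = 1` to get the
  same from the default scheme).
* `matrix`: a user-supplied 4 × 3 per-position weight matrix, for users who
  want frequency-derived weights.

Under the default weights a run of consensus trios always outscores an
equally long degenerate run, and extending a run never lowers its score.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `max_mm_sole_9` | 2 | mismatch cap, sole 9 bp box |
| `max_mm_primary_tandem_9` | 2 | cap for the more conserved tandem box |
| `max_mm_secondary` | 4 | cap for the less conserved (secondary) box |
| `max_mm_long_motif` | 3 | sole/primary cap when the motif exceeds 9 bp |
| `max_spacer` | 16 bp | largest box-to-trios spacer searched |
| `preferred_spacer` | 13 bp | spacer used by the final screen |
| `min_trios` | 3 | minimum consecutive N-A-N trios |
| `max_interbox_gap` | 3 bp | largest gap between tandem boxes |
| `strands` | both | set `"plus"` to fix the orientation |

All of them can be supplied as a YAML mapping (`read_params_yaml()`), so a
survey can be re-run under a different rule set without code changes.

## Coordinates

Internally every coordinate is 0-based, half-open, on the *scanned* strand.
Written reports (`write_results()`, TSV or JSON) use 1-based inclusive
coordinates on the *forward* (input) sequence, and the sequence columns hold
the forward-strand slice — so slicing the input at the reported coordinates
reproduces the reported strings exactly, for minus-strand calls too (there
the motif matches the reverse complement of the slice). `read_results()`
restores the internal representation from a saved table.

## Design choices in the open corners

Several behaviours are not pinned down by the published rule set; the package
fixes them as follows.

* **One candidate per (box, trio-run) pair.** The secondary-box search may
  find several qualifying boxes; the best one (fewest mismatches, then
  smallest gap, then leftmost) is attached rather than emitting one candidate
  per option. Otherwise a sole-box and a tandem description of the same
  physical module would tie through every screen and inflate `tie_count`.
  For the same reason, a tandem pair whose two members both pass the
  first-located cap (and so is enumerated twice with the roles swapped) is
  deduplicated, keeping the description whose first box is the more
  conserved.
* **Maximal runs only.** A trio run is used at its maximal extent; it is
  never trimmed to fit a pairing. A consequence worth knowing: with the
  default motif (ending ...ACA) a spacer of exactly 1 bp is degenerate — the
  3-mer preceding the trios is then forced to be N-A-N, the maximal run
  swallows the box tail, and the pairing fails the spacer ≥ 0 rule. This is
  the same behaviour a leftmost-longest `(.A.){3,}` regular-expression
  search would show. The simulator refuses to plant such modules.
* **Both strands are scanned** and reported; `strands = "plus"` restricts the
  scan when the input orientation is known.
* **Ties resolve deterministically** (leftmost reference box, plus strand
  first) and are counted, so results are reproducible and the residual
  multi-candidate rate is observable.

## What the simulator emulates — and what it does not

`plant_spec()` / `generate_origin()` / `simulate_origins()` build fixtures
with exact ground truth: a random-background origin (default 300 bp, GC 0.5,
matching the scale of DoriC origin records) carrying one planted module with
chosen box substitutions, spacer, trio count/composition, optional secondary
box and strand. Planted sampling spans the legal parameter box: both strands;
sole, tandem-downstream and tandem-upstream arrangements; mismatches up to
the caps; spacers up to the maximum; 3–8 trios of consensus or random
composition.

Random DNA is not naturally "background-clean": a 300 bp sequence carries
several qualifying trio runs per strand in expectation, so whole-sequence
rejection sampling would essentially never terminate. The generator instead
repairs the background: every box hit within the secondary cap (4
mismatches — stricter than the first-located cap, so a chance background box
can never masquerade as a secondary) and every trio run of ≥ 3 outside the
planted module is broken by a targeted single-base mutation, over bounded
passes. Guard bases adjacent to the planted run keep it maximal at exactly
the planted count. Finally every fixture is *verified*: the scanner must
reproduce the planted truth exactly (or stay silent, for background-only and
beyond-cap fixtures); a failed verification redraws the background, and
persistent failure stops with the seed reported.

What passing on these fixtures does **not** show: real origins are not
background-clean (they contain additional DnaA-boxes and chance trio runs, so
real tie rates and screening pressure are higher), their composition is not
i.i.d. with a global GC fraction, and species-specific motif choice is taken
from the input, not inferred. The simulator validates the *rules engine*, not
the biological prevalence figures; cohort-scale statistics (85% prevalence,
57% tandem fraction in the published survey) require the real DoriC cohort,
which this package consumes but does not ship.

## Numerical and scale choices

Everything is exact integer/string computation; there are no tolerances
beyond `==` on counts and coordinates. Deterministic seeds derive per-origin
streams from one master seed (kept below 2^31). The shipped test suite sizes
are: 1000 random sequences against brute-force oracles for the scanners, 500
planted fixtures for recovery (recovered 100%, with the >99% single-candidate
check), 200 background-only negatives (0 calls), and boundary sweeps for
every threshold (spacer 16/17, sole-box mismatches 2/3, secondary 4/5,
long-motif 3/4, trio count 3/2) — sizes chosen to exercise every rule corner
while keeping a full run in a couple of minutes.

## Known limitations

* One record = one origin; multi-chromosome genomes and plasmid origins are
  out of scope, as are DnaA-independent initiation systems (simply reported
  as not found).
* The trio score is a modelling choice (see above), not a published formula;
  rankings under alternative schemes can differ for mixed-composition runs.
* `oriC` prediction itself (Z-curve analysis etc.) is not performed — the
  scanner consumes predicted origins.
* Figure-style outputs are data tracks (`export_tracks()`); drawing an
  annotated phylogenetic tree from them is left to dedicated tools.
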