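---
title: "Scanning CRMs for the SFZE cis-regulatory syntax"
author: "sfzescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning CRMs for the SFZE cis-regulatory syntax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfzescan)
```

## The problem and the model

Notochord enhancers of chordate *brachyury* genes share little or no
alignable sequence, yet they share an arrangement of transcription-factor
binding sites — the SFZE syntax, named after Su(H), Foxh1, Zic and Ets.
The arrangement, not the surrounding sequence, appears to carry the
regulatory information, and versions of it occur at *brachyury* loci far
outside the chordates. `sfzescan` turns that observation into a testable,
reusable classifier: detect candidate sites in a cis-regulatory module
(CRM), evaluate the grammar rules, and assign a compliance tier.

The grammar has four rules:

1. **Order.** Reading 5′→3′, the classes appear as
   Su(H) – Foxh1 (one or two) – Zic – Ets, or the mirror image of that
   order (the reversed reading is equally grammatical; enhancers work in
   either genomic direction).
2. **Zic/Ets orientation.** The Zic and Ets sites face each other: the
   upstream one of the pair sits on the plus strand and the downstream one
   on the minus strand, so their 3′ ends point toward each other.
3. **Foxh1/Zic orientation.** The Foxh1 site adjacent to Zic lies on the
   same strand as Zic.
4. **Spacing.** The Foxh1–Zic–Ets core spans at most one nucleosome length,
   ~147 bp. The Su(H) site is the least constrained: it may sit on either
   flank of the core, at any distance by default.

Site detection uses two model kinds. Zic and Foxh1 are matrix motifs:
position frequency matrices (PFMs) in JASPAR format, converted to log-odds
weight matrices

$$ w_{b,i} \;=\; \log_2 \frac{(n_{b,i} + p\,q_b) / (N_i + p)}{q_b} $$

with counts $n_{b,i}$, column sums $N_i$, pseudocount $p$ and background
$q_b$; windows are accepted when the relative score
$(s - s_{\min})/(s_{\max} - s_{\min})$ reaches the class threshold. Ets and
Su(H) are degenerate IUPAC core consensi matched exactly: `MGGAW` for Ets
and `GTGTRGAR` for Su(H), with the suboptimal Su(H)-like 7-mers `NTGRGAR`
and `GTGRGAN` as a separate class. Sequence descriptions of the Su(H) core
vary between a 7-mer (`GTGRGAR`) and an 8-mer (`GTGTRGAR`) form; this
package uses the 8-mer for class S and the 7-mers for the S-like class, so
the stricter core defines the canonical site and the looser forms are
still reported, under their own class label.

## Tiers

Each combination of candidate sites (one Zic, one Ets, one or two Foxh1,
optionally one Su(H)/Su(H)-like) receives per-rule flags, and the flags map
to a tier with a fixed precedence:

| tier | meaning |
|---|---|
| `SFZE_FULL` | all rules pass, Su(H) present (direct or mirrored order) |
| `SFZE_LIKE_INVERTED` | orientation and spacing pass, but the linear order deviates (e.g. the S–E–Z–F "SEZF" permutation), or Su(H) is absent with the order intact |
| `SFZE_LIKE_SPAN` | orientation passes but the core exceeds one nucleosome length |
| `SFZE_LIKE_ORIENT` | Zic/Ets not face-to-face, or the adjacent Foxh1 on the wrong strand |
| `INCOMPLETE` | no complete Foxh1–Zic–Ets core |

An incomplete core is checked first, then orientation, then spacing, then
order/Su(H): an orientation violation is treated as a deeper departure
from the grammar than a spacing violation, which in turn is deeper than a
permuted order. The same ordering ranks tiers when the best of several
candidate combinations is chosen (`best_instance()`: tier, then number of
passing rules, then the tighter core, then total site score, then leftmost
position). A CRM's tier is its best instance's tier.

Mirror handling is explicit: `mirror_used` records whether an instance
reads in the reversed direction, operationalised as "the Ets site starts
upstream of the Zic site" for any complete core. Under reverse
complementation of a region the tier is invariant and `mirror_used`
toggles; for instances without a complete core the flag is `FALSE` on both
strands and only tier invariance is meaningful.

## Tunable parameters

* `scoring_params()`: pseudocount 0.8 (a common PFM convention; no value
  is canonical), uniform background (the package scans CRMs from many
  genomes, so no single genome composition is privileged), relative-score
  threshold 0.80 per matrix class. Consensus motifs are exact-match only —
  no mismatch allowance.
* `detect_sites()`: same-class calls overlapping by more than 0.5 of the
  shorter site are deduplicated, keeping the best score (ties: smaller
  start, then plus strand). Cross-class overlaps are kept — real CRMs have
  interleaved sites.
* `syntax_grammar()`: up to `max_f = 2` Foxh1 slots; `max_core_span = 147`
  bp; `s_max_distance = Inf` ("anywhere in the region") because the Su(H)
  position varies between real enhancers — it sits next to Foxh1 in the
  zebrafish enhancer but next to Ets in the hemichordate one;
  `enumeration_budget = 10000` combinations, beyond which the scan errors
  and asks for tighter thresholds rather than silently truncating.
* "Adjacent Foxh1" is operationalised as the Foxh1 site nearest Zic by
  interval distance, ties to the upstream site; no numeric definition of
  adjacency exists, and nearest-by-distance is the least arbitrary choice.
* One Su(H) site per instance suffices even where several exist; extras
  are reported in the site set but not required.

The Zic and Foxh1 matrices are configuration, not constants: vertebrate
Zic-family and FOXH1 JASPAR entries are the natural choices, supplied as
JASPAR files via `sfze_motif_set()`. The package bundles small
*synthetic* matrices (`synthetic_motif_set()`,
`inst/extdata/synthetic_motifs.jaspar`) for tests and simulation; they are
labelled synthetic and are not curated database entries.

## The synthetic benchmark

`generate_dataset()` emulates CRM-scale inputs: i.i.d. background of
configurable GC (default length 700 bp, the scale of real CRMs, which run
from a few hundred bp to ~1 kb) with one planted arrangement per sequence:

```{r arrangements, eval = FALSE}
simulation_config(seed = 1, n_sequences = 7, length = 700, gc_content = 0.4,
                  arrangement = c("FULL_DIRECT", "FULL_MIRROR",
                                  "PARTIAL_INVERTED", "ORIENT_VIOLATION",
                                  "SPAN_VIOLATION", "INCOMPLETE",
                                  "BACKGROUND_ONLY"))
```

Plants never overlap; inter-site gaps are drawn uniformly within a span
budget (core spans up to 147 bp for compliant tiers, above 147 for span
violations); matrix site realisations are rejection-sampled until their
relative score reaches `plant_score_floor` (default 0.9, above the 0.8
detection threshold, so every plant is detectable by construction). Each
sequence draws from a substream mixed deterministically from the global
seed and the sequence index, making datasets reproducible and
order-independent.

Two design points matter for interpreting benchmark results:

* **Truth is re-derived, not assumed.** The intended tier of every
  sequence is computed by running the same enumeration and classification
  the pipeline uses on the planted geometry. If a requested arrangement
  did not produce its tier, generation fails loudly, so the simulator and
  the classifier cannot drift apart.
* **The background is scrubbed.** Random background of realistic GC
  contains chance `MGGAW` matches roughly every few hundred bp, which
  would contaminate truth labels. After planting, any detectable site that
  is not a plant (or an intentional decoy) has its background positions
  resampled until none remain. With `decoy_density = 0` the detectable
  sites are therefore *exactly* the planted ones, which is what makes
  recall 1.0 and a diagonal tier confusion matrix the correct expectation
  rather than an approximation. Decoy sites — extra consensus words at
  `decoy_density` per kb — are exempt from scrubbing and drive the
  precision axis of the benchmark.

Span violations are planted with a single Foxh1 site: with two, the
enumeration could select the nearer Foxh1 and form a narrower, fully
compliant sub-arrangement, and the intended tier would not be well
defined. This mirrors how the classifier treats real CRMs: a region is
span-violating only if *no* choice of sites satisfies the spacing rule.

What the generator does not emulate: real CRMs have correlated base
composition, repeats, clustered low-affinity sites and phylogenetic
structure; background here is i.i.d. and plants are near-optimal words.
Passing the benchmark shows the machinery is exact on known ground truth —
it does not by itself validate threshold choices on real genomes, which is
why the matrix IDs and thresholds are configuration.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; BED output stays 0-based,
  GFF3 converts to 1-based inclusive.
* Windows containing non-ACGT letters are skipped on both model kinds
  (`N` in a draft genome should not match `N` in a consensus).
* A matrix whose maximum and minimum scores coincide cannot define a
  relative score and is rejected as degenerate.
* Empty sequences and empty site sets yield empty results, not errors;
  a CRM with no candidate instances reports tier `INCOMPLETE`.
* All tie-breaks (dedup, adjacent-Foxh1, best instance) are deterministic,
  so repeated runs produce byte-identical TSV/JSON output.

## Problem sizes used in the validation suite

The package's own checks run exhaustive oracles at small scale: all 1,024
5-mers and 65,536 8-mers for the consensus cores; brute-force rescoring of
50 random 300-bp sequences for the matrix scanner; exhaustive subset
enumeration for site sets of up to 15 sites; 100 synthetic regions for
strand-flip invariance; and a 200-sequence, 700-bp benchmark spanning all
seven arrangements for end-to-end recovery. These sizes were chosen so
each oracle remains exact (full enumeration) while the whole suite stays
fast enough to run routinely.

## Limitations

* The grammar encodes order, orientation and spacing — it does not model
  binding affinity trade-offs, cooperative energetics or chromatin
  context.
* Consensus classes are exact-match; a one-mismatch Ets core is invisible
  by design, matching how the cores were defined.
* Tier precedence is a modelling choice where several rules fail at once;
  the per-rule flags are always reported so alternative orderings can be
  applied downstream.
* The promoter-element annotator uses standard literature consensi and
  windows (TATA `TATAWAWR` at −40..−20, Inr `YYANWYY` spanning the TSS,
  BREd `RTDKKKK` immediately 3′ of a TATA call, DPE `RGWYV` at +25..+35,
  CCAAT and `GGGCGG` boxes within −250..−1). They are defaults, clearly
  overridable, not measured values.
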