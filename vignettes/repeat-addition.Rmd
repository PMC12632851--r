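---
title: "Modeling ncRNA-templated tandem-repeat cDNA synthesis"
author: "repeatweaver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ncRNA-templated tandem-repeat cDNA synthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatweaver)
```

## The model

DRT10-class reverse transcriptases synthesize single-stranded,
tandem-repeat cDNA from a short template inside a partner ncRNA. The
template region has a direct-repeat architecture we write as **A–B–A′**:
`A+B` is the template proper, and `A′` is a downstream copy of `A`.
Synthesis is protein-primed (modeled only as a boolean flag on the
product) and proceeds by a telomerase-like cycle:

1. reverse transcription copies `A+B` from the 3′ end of B to the 5′
   template boundary at the start of A, appending one repeat unit — the
   reverse complement of `A+B` — to the cDNA;
2. the cDNA dissociates from the template;
3. its 3′ end re-anneals at `A′` (whose sequence matches `A`, and hence
   pairs the fresh cDNA terminus), priming the next round.

`repeatweaver` implements this cycle as a stochastic simulation
(`simulate_product`) and, around it, the detection machinery that finds
A–B–A′ patterns in candidate ncRNAs and the read-level analyses that
recognize the resulting tandem repeats in sequencing data.

### Pattern detection

`find_aba_patterns` enumerates every (`a_start`, `a_len`, `b_len`) triple
with exact `A = A′` identity inside the search interval, subject to
configurable bounds (`aba_search_params`). Three choices were genuinely
open and are resolved as follows:

* **Exact identity.** Detection allows no mismatches between A and A′.
  Mismatch tolerance is a property of the *realignment rules* in the
  simulator, where position-specific effects (see below) make a flat
  Hamming allowance wrong. Exactness also keeps the brute-force test
  oracle trivial.
* **Ranking.** Patterns are ordered by `a_len` descending, then `b_len`
  ascending, then position. Longer A–A′ homology gives stronger primer
  capture, so it dominates; among equals, a shorter spacer means a more
  compact, more repeat-dense unit. Under this rule the native Eco3-like
  pattern (A = `CAAU`, B = `GAUUC`) ranks first in its loop.
* **Maximality.** A pattern whose A could be extended one base leftward at
  both sites (absorbing the last base of B) is suppressed: it is the same
  repeat described with a weaker A, and reporting it would inflate the
  output combinatorially. Patterns blocked from extension by the interval
  edge or the `max_a` bound are kept.

The search interval is the user-supplied `loop_interval` or, when only a
dot-bracket structure is available, the longest unpaired run — the
template loop of these ncRNAs is their dominant single-stranded region. De
novo RNA folding is out of scope.

Note one consequence of the ranking for round trips: on a long random
motif, `design_template` + `find_aba_patterns` always *recovers* the
designed pattern, but an accidental internal repeat with a longer A can
legitimately outrank it. Tests therefore assert membership in general and
top-rank recovery only on fixtures verified unambiguous by exhaustive
enumeration.

### Realignment rules

Candidate annealing sites are template positions from the start of B
through the end of A′ (annealing upstream of B, inside A, is disallowed —
the behavior there is unconstrained by available evidence, and forbidding
it is the conservative choice). At each site the primer's 3′-terminal
bases are compared with the template, counting depth from the 3′ end:

| depth (default) | rule |
|---|---|
| 1–2 (`strict_positions`) | any mismatch aborts the site |
| 3 (`purine_purine_block_depth`) | purine:purine mismatch aborts; pyrimidine:pyrimidine is tolerated |
| ≥ 4 (`free_depth`) | any mismatch tolerated |

This encodes the observed asymmetries of the system: repeat addition
survives mismatches at the fourth position, survives a pyrimidine
mismatch but not the sterically clashing purine:purine mismatch at the
third, and tolerates nothing at the terminal two.

A surviving site is scored by its contiguous 3′-terminal Watson–Crick
match length; the best-scoring site is chosen (ties: closest to the
canonical A′, then a seeded random draw). The success probability of the
cycle is

```
p_success_by_matchlen[score] * decay(a_len + b_len)
```

with defaults `2 → 0.05`, `3 → 0.5`, `≥4 → 0.95`, reflecting the finding
that three bases of A–A′ homology generally suffice while two only
marginally do. `decay` is a sigmoid in template length with midpoint
`template_len_midpoint = 14` nt and scale `template_len_scale = 2` nt.
The quantitative mapping from template length to reset efficiency is not
known; the sigmoid is a calibration choice anchored to three qualitative
facts — the native 9-nt template resets efficiently (decay(9) ≈ 0.92), a
10-mer spacer supports low-level repeat addition (decay(14) = 0.5), and a
20-mer spacer effectively none (decay(24) ≈ 0.007). Both parameters are
exposed in `sim_config` and should be treated as free.

Cycle counts follow a geometric law (`p_continue`, default 0.98, capped
at `max_cycles = 500`): the data constrain product lengths only as
kilobase-scale smears, so the law and its default are free parameters.
Initiation is at the 3′ end of B, so cycle 1 emits one full unit; the
exact initiating nucleotide is not established and the choice makes the
unit count interpretable. A realignment at a non-canonical (cryptic) site
copies from that site to the 5′ boundary, producing an aberrant-length
unit — with a strong cryptic site inside B the simulator reproduces the
irregular unit spacing seen in less precise homologs.

### The sequencing layer

`generate_dataset` emulates a miniprep-seq-like experiment: WT libraries
mix background reads (uniform random windows of a reference plasmid,
either strand) with windows of independently simulated repeat products;
RT-dead control libraries are background only. Reads are emitted in the
cDNA orientation with 50/50 strand randomization, then substitution
errors are applied per base (`seq_error_rate = 0.001`). Products shorter
than the 150-nt read length are emitted whole, as real short fragments
would be. Ground-truth origin labels and the background read count (the
CPM denominator) are recorded.

Defaults — 150-nt reads, 30% repeat-product reads in WT
(`background_fraction = 0.7`), error 0.001 — are the study conditions for
all tests and for the acceptance analysis.

What the generator does **not** emulate: second-strand synthesis (barely
detectable in the real system), adapters and quality-score structure,
PCR duplicates, coverage bias, host-genome contamination, and the
kilobase-scale product lengths — under default parameters simulated
products average ~7 units (~60 nt), so simulated run-length medians sit
well below the ≥15-repeat medians reported from real reads. Raising
`p_continue` and the success map toward 1 recovers read-saturating
products. Consequently, passing tests demonstrate correctness of the
algorithms under the stated generative model, not performance on real
libraries with their full artifact spectrum.

## The read pipeline

* `partition_unmapped` calls a read mapped iff it shares an exact
  ≥ `min_anchor` (default 30) nt substring with the reference or its
  reverse complement — a transparent stand-in for an aligner, adequate at
  the simulated error rate. Anchors below 10 nt warn about spurious
  matches.
* `discover_motifs` replaces black-box motif discovery with a
  transparent differential k-mer procedure: per-read containment counts
  of each k-mer (either strand) in both conditions; a one-sided
  two-proportion z-test per k-mer (computed on the log scale — the
  planted-motif contrasts underflow double precision); greedy clustering
  of shift-overlapping / reverse-complement k-mers around the most
  significant seed (exact ungapped overlap ≥ `min_overlap = 5`), plus
  absorption of every k-mer consistent with a tandem array of the
  consensus.
* **Consensus width.** Within a cluster the consensus is the largest
  width whose best member keeps read support within `support_tol = 5%`
  of the cluster maximum. For a tandem repeat this stops exactly at the
  unit length: sub-width k-mers and the full unit are carried by the same
  reads, but every longer k-mer wraps around the unit junction and is
  absent from single-unit products, which are a substantial read class
  (~14% of products under defaults). The 5% tolerance sits an order of
  magnitude above the support erosion from sequencing errors
  (≈ 0.1–0.3% across widths 6–12 at error 0.001) and well below that
  14% gap.
* **Orientation.** Libraries are strand-randomized, so a consensus and
  its reverse complement are equivalent; the package reports whichever
  orientation has more raw occurrences in the WT set. The *phase* of the
  repeat, by contrast, is identifiable (single-unit products anchor it),
  and the pipeline recovers it exactly.
* `position_graph` shifts each read's hit starts so its first hit is 0
  (read coordinates are 0-based throughout, while ncRNA coordinates are
  1-based to match mutation nomenclature) and sums counts across reads.
  `estimate_period` then takes the mode of spacings between successive
  nonzero positions, each weighted by the smaller flanking count —
  chosen over autocorrelation for interpretability and because it admits
  an exact brute-force oracle. Ties break toward the smaller period;
  fewer than two nonzero positions is an error, not a guess.
* Normalization is counts per million reference-mapping reads
  throughout; a zero denominator yields raw counts plus a message rather
  than an invented scale.

**Control comparator.** Under the generative model the control library
maps essentially completely, so "control unmapped reads" can be empty —
an empty comparator would make the enrichment test degenerate. When the
control unmapped set has fewer than `min_ctrl_unmapped = 100` reads,
`run_pipeline` and the acceptance analysis use the full control library
as the background comparator. This is conservative: it can only raise
the control containment fraction.

## Degenerate inputs and numerical notes

* Empty template collections return an empty prevalence table with the
  aggregate fraction reported as missing, not zero.
* Motif prediction requires only `A+B` inside the sequence; simulation
  additionally requires `A′`. Patterns are *geometry*, so mutational
  series run a fixed pattern on perturbed templates where `A ≠ A′`, and
  failure emerges from the pairing rules rather than from validation.
* All randomness flows through R's RNG; a `seed` in `sim_config` (or the
  pipeline config, where it is mandatory) makes read sets and artifacts
  byte-identical across runs.
* p-values at the planted-motif scale underflow to 0 by design; ranking
  uses log-scale values internally and `log10_p` is reported alongside.

## Problem sizes

Unit and property tests run on reduced instances chosen to keep the
statistical contrasts decisive: oracle equivalence on sequences ≤ 60 nt,
discovery recovery on 1,500-read libraries, truncation series at 20
seeds × 600 reads, and the headline analysis at the full study scale of
10,000 + 10,000 reads. The 20-mer-spacer contrast uses 3,000 simulated
products because the expected multi-repeat fraction there (~0.6%) must
be resolved against a 1% bound.

## Known limitations

* The A–B–A′ prevalence reported for curated homolog collections cannot
  be recomputed here without those collections; `batch_aba_prevalence`
  is validated against synthetic collections with known ground truth,
  and the search bounds that would tune real-collection prevalence are
  exposed rather than fixed.
* The anchor-based mapper is not an aligner; with higher error rates or
  repetitive references it will misclassify reads that BWA-class tools
  would place.
* Thermodynamics are reduced to match-length scoring; stacking, GU
  wobble and structure of the cDNA are not modeled.
* Second-strand synthesis, effector engagement and infection-dependent
  modulation of cDNA levels are out of scope.
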