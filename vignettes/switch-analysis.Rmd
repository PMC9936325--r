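---
title: "Profiling the miRNA-to-sdRNA expression switch: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the miRNA-to-sdRNA expression switch: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrnaswitch)
```

## The problem

Mature miRNAs are ~20 nt silencing RNAs whose canonical biogenesis runs
through DICER cleavage of a hairpin precursor. snoRNAs are 60–300 nt
nucleolar RNAs (C/D-box SNORDs and H/ACA-box SNORAs) that are frequently
processed further into miRNA-sized fragments — snoRNA-derived RNAs, sdRNAs —
by a DICER-independent, AGO2-driven route. In a DICER-knockout cell line the
two classes should therefore move in opposite directions: miRNAs collapse to
a few percent of wild type while sdRNAs rise severalfold. This package turns
that comparison into a reusable, fully tested pipeline: exact-match
alignment of two small RNA-seq libraries to a merged miRNA + snoRNA
precursor reference, coverage-based sdRNA locus calling, RPM quantification
with an expression floor, and three-way differential classification with
class-level summaries.

## The pipeline model, stage by stage

### Reference (`load_reference`, `build_index`)

Two FASTA inputs (miRNAs and snoRNAs) are merged into one validated
precursor set. Sequences are uppercased and U→T normalised so that all
matching happens in DNA space; duplicate ids across files are an error;
snoRNAs outside a 40–350 nt sanity band load with a warning. The miRNA input
may be mature sequences, or hairpins together with a TSV of mature-arm
intervals (0-based, half-open) — the second form is needed when arm-level
names such as `miR-192-5p` must be reported.

Exact matching is served by a 16-mer table: every 16-mer of every precursor
is indexed by sequence, a query of 16–32 nt retrieves the candidates sharing
its first 16-mer, and each candidate is verified by direct substring
comparison. Because any exact match of ≥ 16 nt contains its first 16-mer,
the lookup is exhaustive — and it trivially subsumes a seeded word search
with any word size ≤ 16. The index is property-tested against a naive
`gregexpr` scan on thousands of randomized queries.

### Alignment (`align_reads`, `align_library`)

A read is accepted only where the *entire* read matches a precursor exactly:
no mismatches, no indels, no partial local hits, and only for read lengths
of 16–32 nt. Post-trimming small RNA reads *are* the fragment of interest,
so a local sub-match of a longer read would inflate counts. An accepted read
is reported at every occurrence; `multiplicity` records the number of
placements so that downstream counting can split a read 1/multiplicity
(`fractional = TRUE`). Sense-strand placements only by default — mature
small RNAs are sense to their precursor — with `antisense = TRUE` adding
reverse-complement placements. No E-value filter exists: at 100% identity
over ≥ 16 nt against a reference of this size, any conventional E-value
threshold is a no-op.

### Coverage and locus calling (`build_profiles`, `call_loci`)

Per precursor, the profile holds read 5′-end counts `s(i)` and depth `d(i)`
(difference-array accumulation; exact interval-stab counts). Loci are called
per snoRNA host:

* anchor: `s(p)` is a local maximum (leftmost position of a plateau) with
  `s(p) ≥ peak_fraction · max(s)`;
* support: reads starting within ± `offset_tolerance` nt of `p` must number
  ≥ `min_reads`. Support is windowed because library preparation and
  trimming jitter read 5′ ends by a nucleotide or two; demanding the floor
  at the single anchor position would implicitly raise it severalfold;
* extent: the locus runs from `p` over the modal length of its supporting
  reads (ties to the shorter length), and must stay inside the 16–32 nt
  band and the host;
* conflict resolution: candidates are ranked by support and overlapping
  intervals keep the higher-count one, so loci on a host never overlap;
* side label: a locus starting within `end_tolerance` nt of the host 5′ end
  is `FIVE_PRIME`, ending within that distance of the 3′ end `THREE_PRIME`,
  otherwise `INTERNAL`.

Defaults: `min_reads = 10`, `peak_fraction = 0.25`, `offset_tolerance = 3`,
`end_tolerance = 5`. These are deliberate package-level concretisations of a
procedure that the field describes only loosely; all five are configuration,
and the caller is validated against simulated truth (planted fragments with
≥ 10 supporting reads are recovered within ± 3 nt in ≥ 99% of cases), not
against any published threshold set. No smoothing or wavelet decomposition
is applied — the caller works on raw 5′-end counts.

Locus counts are **fragment-species counts**: a read is attributed to a
locus when its 5′ end lies within `offset_tolerance` of the anchor, not
whenever it overlaps the interval, so a locus is not credited with reads
from a different fragment that merely overlaps it.

### Quantification and floor (`quantify`, `apply_floor`)

RPM = raw count × 10⁶ / denominator, computed per library. The denominator
is a genuine open choice for single-library small RNA data; both
conventions are implemented — `total_reads` (per million sequenced reads,
the default, matching the most common reading of "reads per million") and
`aligned_reads`. miRNA counting: for mature references, any full-read
alignment to the record; for hairpin references, an alignment is attributed
to each arm it overlaps by at least half the read length (with disjoint
arms separated by a loop, at most one arm can meet that bar for reads in
the accepted length band). Features below
30 RPM in *both* libraries are excluded; the floor, like the thresholds
below, is a parameter.

### Classification and summary (`classify_expression`, `summarize_switch`)

Percent-of-WT is `P = 100 · RPM_KO / RPM_WT`; UP means `P ≥ 150`, DOWN
`P ≤ 50`, UNCHANGED the open interval between. The comparison is done by
cross-multiplication (`100·RPM_KO` vs `threshold·RPM_WT`) with no
intermediate division or rounding, so boundary cases are decided exactly. A
feature with `RPM_WT = 0` has infinite percent and is UP; post-floor, a
0/0 feature cannot occur and is rejected as a contract violation. No
hypothesis test is run — with one library per condition there is nothing to
test; "significant" in this analysis *is* the threshold rule.

Class means (`mean_percent_of_wt_down`, `mean_percent_of_wt_up`) are
arithmetic means of per-feature percentages over the DOWN and UP sets
respectively. Infinite percentages cannot enter an arithmetic mean; they are
excluded from the UP mean and counted in `n_up_infinite`. Because
feature-mean versus ratio-of-sums is a genuine ambiguity for a summary like
"average percent of WT", the pooled alternative
(`100·Σ RPM_KO / Σ RPM_WT` over the same class set) is emitted alongside.
Top-10 lists are ranked by `|log2(P/100)|` descending with lexicographic
tie-breaks.

### Orchestration

`compare_libraries()` chains the stages in memory and returns an
`sdrna_switch` object with `tidy()`/`glance()`/`autoplot()` methods;
`run_pipeline(pipeline_config(...))` adds file I/O: the TSV/BED/JSON
artifact set plus an MD5 manifest, so identical configurations reproduce
identical hashes. sdRNA loci are called on the **pooled** WT + KO
alignments: an sdRNA absent in WT and strong in KO (the expected direction)
must still be quantified in both libraries over the same interval.

## The simulator: what it emulates, and what it does not

`simulate_reference()` draws random snoRNAs (lengths uniform on 60–300 nt)
and hairpins with 20–23 nt designated arms, and plants one fragment window
(optionally two, non-overlapping) of 20–24 nt per snoRNA. Hosts are
rejection-resampled until every planted fragment occurs exactly once in the
whole reference, so truth reads have multiplicity 1 by construction.

`simulate_libraries()` builds the two libraries as follows:

* wild-type relative abundances per feature: lognormal (σ = 1), normalised
  within type; miRNA arms receive 85% of aligned wild-type reads, sdRNA
  windows 15% — in wild-type small RNA libraries miRNAs dominate and sdRNAs
  are a minor species;
* each feature gets a KO/WT ratio: lognormal with arithmetic mean 0.064 for
  miRNAs and 6.793 for sdRNAs (σ = 0.35 — a coherent global shift of about
  half a log2 unit of spread around the type mean), except that an exact
  rounded count of features per type (fractions 29/288 and 8/103) is forced
  to ratio 1, representing the DICER-independent minority of miRNAs and the
  non-responsive minority of sdRNAs;
* knockout expected counts are wild-type expected counts times the ratio,
  and unalignable decoy background fills **both** libraries to exactly
  `reads_per_library`. With equal denominators the realised percent-of-WT
  of a feature is centred on its planted ratio. (Renormalising the knockout
  library multinomially to a fixed aligned mass would instead divide every
  realised ratio by the total mass shift, ≈ 7% here — a bias that would be
  invisible in class counts but visible in class means.) If the knockout
  aligned mass would exceed the library size, ratios are rescaled down with
  a warning;
* counts are multinomial given the library totals; read sequences are the
  planted fragment with ± 2 nt end jitter (unimodal, centred on 0, clamped
  to the host and to 16–32 nt); qualities are fixed `I` since the aligner
  is quality-blind.

Defaults are the validated study conditions: 288 miRNAs, 103 snoRNA
fragments, 10⁵ reads per library, 10% background. Under them the pipeline
recovers 259/288 miRNAs DOWN and ~95/103 sdRNAs UP with class means within
sampling error of 6.4% and 679.3% — the structure of a DICER-knockout
comparison.

The simulator does **not** emulate: sequencing errors (an error would simply
break a perfect match; an error-rate robustness knob would only depress
counts uniformly), adapter read-through (reads are born trimmed), true RNA
secondary structure (hairpin "arms" are positional, not thermodynamic),
multi-mapping families (paralogous precursors sharing fragments are
screened *out*, so fractional counting is exercised by dedicated fixtures
rather than by the simulator), or biological replicates. Passing tests on
simulated data therefore demonstrate the correctness of the counting,
calling and classification machinery under the stated statistical
structure — not robustness to the full messiness of real libraries.

## Numerical choices and degenerate inputs

* Classification at thresholds is exact by cross-multiplication; 150.0000
  is UP and 50.0000 is DOWN bit-exactly.
* Coverage uses difference arrays; in fractional mode weights 1/m are
  accumulated as doubles (m is a small integer; the worst-case accumulation
  error is orders of magnitude below any decision boundary).
* Plateau peaks take the leftmost position; modal-length ties take the
  shorter length; top-list ties break lexicographically — all tie-breaks
  are deterministic, making every stage idempotent and reruns bit-identical.
* Degenerate inputs: an all-zero profile calls nothing; an empty alignment
  set yields an empty profile map; an absurd floor empties the call table
  but the run still succeeds; a zero denominator (no reads in a library) is
  an error.
* Problem sizes in the test suite are chosen for tightness per case: oracle
  equivalence on 10⁴ random queries against a ten-precursor reference,
  parameter recovery on the full default configuration (2 × 10⁵ reads),
  locus recovery on 100 snoRNAs at 5 × 10⁴ reads per library.

## Known limitations

* Full-read matching is a dialect choice: a pipeline accepting internal
  perfect sub-matches of longer reads would count more, and the difference
  is not recoverable from a methods description alone. The choice is
  documented at the alignment stage and applies symmetrically to both
  libraries.
* With one library per condition there is no dispersion estimate, no
  p-value, and no multiple-testing correction — the classification is a
  fold-change rule, exactly as stated.
* The RPM denominator convention changes absolute RPM values (and hence the
  floor's bite) but cancels from percent-of-WT whenever both libraries use
  the same convention.
* Genome coordinates are out of scope: all positions are precursor-local,
  and fetching references or SRA libraries is left to the user.
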