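---
title: "Methods: multipartite mitogenome characterization and microDNA calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multipartite mitogenome characterization and microDNA calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitosplit)
```

This vignette is the package's own account of its models and the choices
behind them: what each statistic assumes, which knobs matter, what the
synthetic-data generator does and does not emulate, and where the methods
stop being trustworthy.

## Circular coordinates and the conservation identity

Everything uses 1-based inclusive coordinates on the heavy (H) strand, the
convention of GenBank flat files and published mitogenome tables. A feature
may wrap the origin (`wraps = TRUE`, start > end); its length is then
`L - start + 1 + end`. The gap "before" a gene is the number of unannotated
positions strictly between the previous gene's end and its start, modulo L;
the first gene's gap reaches back across the origin to the last gene.

Published annotation tables for genomes of this kind print a per-gene
"intergenic region (bp)" column without defining it. The preceding-gap
reading is an inference, adopted because it reproduces every printed value
we bundled — including the first gene's 223 bp gap, which only works if the
gap is computed across the circular origin. Reports that quote that column
should state this semantics, as our documentation does.

For a non-overlapping table the identity
`sum(feature lengths) + sum(gaps) = L` must hold exactly; `genome_summary`
checks it and the bundled 31,099 bp table satisfies it as
17,035 + 14,064 = 31,099. Overlapping features make "gap" ill-defined, so
`preceding_gaps` raises an error carrying a per-pair overlap report rather
than emitting negative numbers.

A note on headline fractions: the IGR fraction of the main chromosome is
14,064/31,099 = 45.2%, which the source literature elsewhere rounds to
"approximately 40%"; the arithmetic value is the one this package reports.

## Composition and strand skews

AT-skew = (A−T)/(A+T) and GC-skew = (G−C)/(G+C), always computed from raw
counts, never from rounded percentages. A zero denominator yields `NA` — an
explicit "undefined", deliberately distinct from 0, and aggregates skip it.
Ambiguity symbols (N) count toward length but are excluded from skew
numerators and denominators, which keeps skews in [−1, 1]. Reports print
percentages to 1 decimal and skews to 4 decimals, rounding half away from
zero (`round_half_up`), matching how such tables are typeset; R's default
half-to-even rounding would differ on boundary values.

`counts_from_percentages` inverts a printed percentage row back to integer
counts under the constraint that counts sum to the known length. Candidates
per base are integers within 0.15 percentage points of the printed value —
wide enough to absorb a printed percentage that is off by one rounding unit,
which occurs in real tables (the bundled 291 bp row prints T = 32.7% while
the only count consistent with the row sum, 95, gives 32.6%). The
combination minimizing total deviation must be unique, or the function
refuses. The inversion is effectively exact for short regions (the two
microDNA-sized rows invert uniquely and reproduce all four printed skew
values); above roughly 1 kb a 1-decimal percentage no longer pins the count,
so recomputed skews can drift in the 4th decimal — the per-region analysis
script reports agreement per row rather than pretending exactness.

A related bookkeeping trap: in a multipartite genome, per-class totals
depend on which chromosomes are pooled. The bundled main chromosome's 19
tRNAs total 1,366 bp; adding the microDNA-borne tRNA (73 bp) gives 1,439.
Published composition tables sometimes print the former while footnoting
the latter's inclusion — an inconsistency a reader cannot resolve from the
table alone. `genome_summary` therefore never pools across chromosomes:
each molecule is summarized separately, and any pooled total is the
caller's explicit sum.

## Translation, codon usage, position composition

Translation uses the mold/protozoan/coelenterate mitochondrial code
(NCBI table 4; UGA = tryptophan, stops UAA/UAG), loaded from Biostrings as
a data table so another code can be swapped in. A CDS must be a whole ORF:
length divisible by 3, terminal stop, no internal stops (the first
violation's codon index is reported). GUG (and AUA/UUG) initiation is
accepted when `allow_alt_start = TRUE`; the first residue is reported as
encoded, with no methionine override — hence the length law
`aa = nt/3 − 1` for every valid CDS, which the bundled tables satisfy for
all 14 protein rows.

Per-codon-position composition is averaged across genes unweighted (each
gene is one observation, mean ± sample sd), reproducing the "across genes"
framing of mitogenome reports; a codon-count-weighted pooling is available
via `weighted = TRUE` where a genome-wide rate is wanted instead.

## IGR size classes

The five classes (I: 1–20, II: 66–109, III: 198–426, IV: 592–1,108,
V: 1,496–1,791 bp) are the *observed* ranges of the motivating genome, and
they leave gaps. `classify_igr` returns `"unbinned"` for lengths falling
between or beyond classes rather than snapping to the nearest class: the
published per-class counts (11/5/7/6/4) stay exactly reproducible, and
novel data cannot be silently misbinned. Length 0 is its own category.

## Terminal repeat detection

`find_terminal_repeats` searches for arm pairs near the two termini:
direct (TDR) or reverse-complement (TIR) identity, arm ≥ 10 bp by default.
"Imperfect" means substitutions only, up to
`floor(max_mismatch_frac × arm length)` under Hamming distance
(default 10%). This is deliberately not an edit-distance or seed-heuristic
search: with substitutions only, the detector is deterministic and exactly
checkable against brute-force enumeration, which the test suite does on
hundreds of seeded sequences. The trade-off is that indel-containing
repeats are found only as their longest gap-free sub-arms.

Arms must start (5′ arm) or end (3′ arm) within `terminal_window` (default
25% of sequence length) of their terminus — the "terminal" in TDR/TIR; the
published counts come from a repeat finder whose windowing is not fully
documented, so ours is explicit and configurable. A hit is reported only if
its span is not contained in a longer valid arm pair on the same alignment
diagonal ("maximal extension"); with a length-dependent mismatch budget this
containment definition is the one a brute-force oracle can share exactly.
Ordering is deterministic: 5′ arm position, then longest first.

The published regression statistics for repeat counts versus IGR length
(R² ≈ 0.90 for TDRs, 0.83 for TIRs) depend on that tool's exact settings
and on accession sequences we do not bundle; they are treated as
qualitative context, not as targets. What the package owns is the
statistic itself: `regress_counts_on_length` is simple OLS with
F = MSreg/MSres on (1, n−2) df and an upper-tail p value, verified against
the closed-form normal equations. The analysis script demonstrates the
length effect on seeded Poisson counts with rate λ = length/30 — a rate
chosen once to match the order of magnitude of repeat counts reported for
real long IGRs (tens of repeats in a ~1.8 kb IGR) — and detection power
under those conditions exceeds 95%, as the acceptance suite checks.

MITE candidacy (terminal TIRs plus a 2–10 bp target-site duplication in
the flanking context) is a separate flag (`mite_candidates`) and never
counted among plain TDR/TIR hits.

## The microDNA evidence chain

The circularity argument for a small contig has four independent legs:

1. **Terminal overlap** (`trim_terminal_overlap`): de novo assemblers emit
   circles as linear contigs whose start reappears at the end; an exact
   prefix–suffix match ≥ 20 bp is trimmed (longest wins). 20 bp keeps the
   false-positive rate for random sequence near 4⁻²⁰ while staying below
   any realistic assembler k-mer.
2. **Junction support** (`junction_support`): reads crossing the artificial
   origin with ≥ `anchor` = 20 aligned bases on each side. For a circle
   sequenced at depth d with read length r, the expectation is
   d·(r−2·anchor)/r; at the 100× / 150 bp study conditions that is ≈ 73.
3. **Flank diversity** (`flank_diversity`): reads overhanging a terminus
   whose overhang does *not* continue with the wraparound sequence. A true
   circle has zero; a tandem array inside a longer molecule exposes its
   genomic flanks (typically two classes, one per side). Overhang
   comparison tolerates `max(1, ceiling(0.05·len))` substitutions — scaled
   with overhang length because a fixed budget of 1 lets ordinary 1%
   sequencing error masquerade as flanking diversity on overhangs beyond
   ~100 bp, while genuine flanks diverge from the wraparound expectation at
   the ~75% level and can never slip under a 5% budget.
4. **Verdict** (`call_circle`): circular iff junction support ≥ 3 and
   flank diversity = 0; support with diversity ⇒ tandem array; diversity
   without support ⇒ linear; neither ⇒ ambiguous (absence of evidence).
   `min_support = 3` and `anchor = 20` are the smallest values robust to 1%
   read error at 50× in our simulations; both are arguments.

The built-in mapper (`map_reads`) is an exact-seed (k = 15) +
Hamming-extension placement on the repeated sequence with coordinates
reported modulo L. It exists to serve the synthetic contract and small
circles — it handles substitutions only and is not a general read aligner;
SAM alignments from a real mapper can be imported instead
(`read_sam_alignments`).

NUMT discrimination (`numt_classify`) operates on externally computed hit
summaries: coverage < 0.95 of the gene or a frameshift/internal stop ⇒
nuclear pseudogene copy; full coverage, intact frame and ≥ 98% identity ⇒
organellar candidate; the grey zone (high coverage, intact frame,
intermediate identity) is left ambiguous rather than forced — a highly
divergent but intact copy deserves a human eye. The thresholds are not from
the literature; they are set so that the canonical published example (a
74 bp nuclear hit at 92% identity against a 291 bp gene) classifies as a
pseudogene, and all are configurable.

## The synthetic-data generator

`simulate_genome` emulates the study conditions: a 31,099 bp circular
chromosome with the published 34-feature layout (the bundled table, so the
gap multiset and all accounting statistics match by construction), microDNA
circles of 291 bp (a single ORF, AUG…UAG) and 140 bp (a 73 bp tRNA-like
gene plus 67 bp spacer), and 2×150 bp inward-facing paired-end reads with
insert 350 ± 35 bp at a default 400× depth with 1% substitution error —
several-hundred-fold coverage being what the motivating study reports for
its mitochondrial contigs. Tests and analyses scale depth down (25–100×)
because the statistics under test converge long before 400×; depth remains
a parameter.

Non-coding sequence is drawn per segment from base probabilities implied by
the target skews (AT −0.1677, GC 0.2362, GC% 38.2 — the main chromosome's
printed values) with rejection until the realized segment skews land within
±0.02, capped at 200 draws (the closest draw wins below the cap; only very
short segments ever hit it). Coding sequence fixes the annotated start/stop
codons and samples internal codons from the 60 non-stop codons weighted by
those same base probabilities — every generated CDS translates cleanly by
construction. Read fragments are drawn uniformly on the circle with
wraparound and may wrap repeatedly when the molecule is shorter than the
insert; errors are substitutions only, matching the Hamming-only mapper
contract (an indel error mode would require a gapped mapper and is out of
scope).

`plant_artifacts` adds ground truth: imperfect terminal repeat arms
(14 bp, 1 substitution by default) written at the termini of the largest
IGRs; a tandem-array decoy — a *fresh* composition-matched unit repeated
2–5 times inside a 10 kb host, deliberately not a copy of the genuine
microDNA so the negative control shares no reads with the positive case;
and a NUMT — a mutated internal fragment (25% of the gene at 8%
substitution) of the microDNA gene placed elsewhere in the host. An
internal fragment is used because a fragment containing the gene's
terminus would, at low mutation load, carry the junction anchor and
contaminate the flank-diversity signal of the genuine circle — precisely
the confusion NUMTs cause in real data; the generator keeps the two
signals separable so each detector can be scored on its own.

What the generator does **not** emulate: real Illumina quality-score and
error-profile structure (errors are uniform substitutions), GC-coverage
bias, chimeric fragments, the host microbiome background of a real
metagenome, and biologically structured IGRs (they are skew-matched random
sequence apart from planted elements). Passing tests therefore demonstrate
the pipeline's correctness on data satisfying its stated assumptions — not
robustness to every artifact of real libraries.

## Numerical and interface choices

* Coordinates are validated eagerly; `start > end` without a wrap flag is
  an error, not a guess.
* Sequence alphabet is uppercase DNA; U maps to T on input; codons are
  reported in the RNA alphabet to match how mitogenome tables print them.
* `canonical_rotation` (lexicographic minimum over both strands' rotations)
  makes circle assemblies comparable across arbitrary rotation and strand;
  it is quadratic and intended for microDNA-sized molecules.
* Gene names normalize through a bundled synonym map (nad4l/ND4L,
  cob/CYTB, …); breakpoint distance defaults to unsigned adjacencies
  because in the motivating genomes all genes lie on one strand, with
  signed and reflection-aware modes behind flags.
* The pipeline report (`run_pipeline`) contains no timestamps; identical
  inputs and seed give byte-identical JSON.
* Analysis problem sizes: the bundled drivers simulate the full 31,099 bp
  genome, read libraries at 25–100×, scan short (≤ 250 bp) IGRs
  exhaustively and long IGRs in a 5% terminal window, and run the decoy
  experiment at 100×; these sizes were chosen so the whole workflow
  re-runs in a few minutes on one core while leaving every statistic well
  inside its asymptotic regime.

## Known limitations

* The terminal-repeat detector's published counterpart values (e.g. "up to
  67 TDRs" in one IGR) are not reproducible without that tool's exact
  parameters; we reproduce the *phenomenon* (counts growing with IGR
  length) and verify our detector against enumeration instead.
* The mapper and error model are substitution-only; data with abundant
  indels need an external aligner via SAM import.
* `numt_classify` consumes hit summaries; it does not itself align a gene
  against a nuclear assembly.
* Gene-order comparison quantifies rearrangement with a breakpoint
  distance; it does not reconstruct rearrangement scenarios (no DCJ or
  inversion sorting).
* The GenBank reader covers the minimal subset that mitogenome records
  use (LOCUS, simple and complement locations, ORIGIN); joins and fuzzy
  ends are rejected loudly.
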