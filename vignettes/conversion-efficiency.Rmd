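---
title: "Conversion-efficiency analysis of Pol IV-derived siRNA precursors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conversion-efficiency analysis of Pol IV-derived siRNA precursors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p4ce)
```

## The biological question

In *Arabidopsis*, RNA-directed DNA methylation is guided by 24-nt
heterochromatic siRNAs. Their biogenesis starts with Pol IV transcribing a
30–40 nt single-stranded precursor (P4RNA), which RDR2 copies into a short
duplex and DCL3 dices into a 24-nt siRNA duplex; the guide strand is
retained by AGO4 or AGO6 in RISC. Not every precursor is converted into an
AGO-bound siRNA with equal efficiency: the 5′ nucleotide of the guide (g1)
and the thermodynamic stability of the duplex's 5′-terminal base pair
(proxied by the second nucleotide, g2: A/U pairs are weak, C/G strong)
both bias loading.

`p4ce` quantifies this with a per-precursor **conversion efficiency**

$$\mathrm{CE}_i \;=\; \frac{\text{AGO-bound siRNA reads anchored at precursor } i}{\text{precursor reads of } i},$$

computed as a raw ratio without depth normalization: CE is only ever
compared *between* precursors within one library pair, where the two
depths are common factors, and keeping the printed definition makes the
numbers directly comparable across re-analyses. Precursors are sorted by
CE and split into equal-size ascending bins (quartiles by default); the
analysis then asks how nucleotide composition at g1 and g2 changes from
the least- (bin 1) to the most-efficiently converted (bin 4) precursors.

## The pipeline

1. **seqio** — collapsed FASTA/FASTQ reading (`id_xN` headers carry read
   multiplicities), 3′ TruSeq-adapter trimming, and exact matching of
   reads to reference sequences.
2. **catalog** — precursor reads mapped fully within Pol IV cluster
   intervals are combined when they share a 5′ end (same cluster,
   position, strand); the representative sequence of a group is its
   longest member (ties broken lexicographically) and counts are summed.
   Species with length > 30 nt and > 50 reads survive (strict
   inequalities, exactly as the catalog definition states).
3. **ce** — siRNA reads count toward a precursor only when they are exact
   5′-anchored prefixes of its sequence; CE and equal-size ascending bins
   follow.
4. **composition** — per-bin g1 nucleotide frequencies and g2 weak/strong
   frequencies conditional on a fixed g1 (A by default, G as the
   secondary analysis), summarized by the scalar trend
   `freq(last bin) − freq(bin 1)`.

### Design choices made where the procedure was open

* **Exact matching only.** The original read mapping used a short-read
  aligner with unstated mismatch settings. We map by exact, ungapped,
  sense-strand identity: it is fully reproducible and conservative, at
  the cost of losing reads with sequencing errors. This is a documented
  divergence to keep in mind when replicating published counts from real
  libraries.
* **Representative of a 5′-group.** "Combined into one" does not name a
  representative; we keep the longest member so downstream g1/g2 analysis
  retains maximal sequence context.
* **Multi-mapping siRNAs** contribute their full count to every precursor
  they prefix (the stated counting rule); a fractional 1/k option exists
  for sensitivity analysis, off by default.
* **Species-level frequencies.** Composition panels report "number of
  P4RNAs per bin", implying each species counts once regardless of reads;
  that is our default, with a read-weighted option.
* **Ties and remainders in binning.** Records are sorted by (CE, id) —
  the id tie-break makes binning deterministic — and any remainder goes
  to the lowest-numbered bins, keeping the top bin maximally pure.
* **Untrimmed reads are retained** (flagged), since adapter-trimming
  options for the original libraries are unstated; trimmed reads shorter
  than 15 nt are discarded. Sense-strand mapping only: whether siRNAs
  were also matched against the RDR2 (antisense) strand is unstated, so
  the conservative sense-only rule is implemented.

## The generative simulator

The simulator exists so that every stage of the pipeline can be tested
against known ground truth at desk scale. It emulates:

* **Biogenesis**: `n_loci` precursor sequences with lengths uniform on
  31–40 nt; the +1 nucleotide drawn with a purine bias (defaults A 0.45,
  G 0.35, C 0.10, U 0.10 — Pol IV start sites prefer A/G, and most
  natural 24-nt siRNAs start with A); body positions i.i.d. from a
  mildly AT-rich composition (A/U 0.30 each, C/G 0.20 each).
* **Abundance**: heavy-tailed per-locus means (log-normal, log-sd 1.2)
  scaled to the target depth, negative-binomial counts (dispersion 0.3)
  around them, rescaled to exactly `precursor_depth` total reads by a
  multinomial draw. With the defaults, roughly a third of loci fall at or
  under the 50-read filter — so the catalog filters are exercised
  non-trivially rather than passing everything.
* **Dicing**: guides are 5′-anchored prefixes (19–25 nt) of their
  precursor, so guide g1 equals the precursor +1 base. The
  duplex/passenger strand is not represented; g2 identity on the guide is
  the terminal-pair stability proxy. DCL3's own end preference is
  absorbed into the loading weights by default.
* **Loading**: each guide's multinomial weight is
  `abundance × w5[g1] × (w_g2 if g2 ∈ {A,U}) × w_len[length]`, and
  `sirna_depth` reads are drawn. Two presets are provided:
  `loading_params_ago4()` uses 5′ weights (A 1, U 0.5, C 0.2, G 0.3) —
  fixed by the measured in vitro relative loading efficiencies of ~50%,
  ~20% and ~30% for 5′ U/C/G versus 5′ A — with a terminal-stability
  multiplier of 2 as an illustrative weak-pair preference;
  `loading_params_ago6()` is a strict-5′A caricature (A 1, others 0.05),
  labeled as uncalibrated because no quantitative AGO6 weight estimates
  exist.

Seed discipline: one top-level seed per stage; `derive_seeds()` spawns
independent substream seeds so stages never perturb each other. Identical
seeds give byte-identical output files.

What the simulator does **not** model: sequencing errors, RDR2's extra 3′
nucleotide, genome-scale positional structure, antisense reads, or
chemically modified constructs used as in vitro controls. Passing
parameter-recovery tests therefore shows the *pipeline* is correct and
sensitive at realistic depths, not that real libraries are free of those
complications.

## Parameter recovery at study scale

The study-scale conditions used throughout the tests are `n_loci = 2000`,
`precursor_depth = 5e5`, `sirna_depth = 1e5`:

```{r recovery}
bio <- biogenesis_params(n_loci = 2000, precursor_depth = 5e5, seed = 11)
ds <- make_dataset(bio, loading_params_ago6(sirna_depth = 1e5, seed = 12))
res <- analyze_dataset(ds$precursors, ds$sirnas, ds$clusters,
                       pipeline_config(log_level = "quiet"))
res$g1_composition
res$trends$g1_A
```

With a strict 5′A loading preference the bin-4 minus bin-1 g1-A trend is
strongly positive (at these depths CE separates the classes almost
completely, so the trend approaches 1); with all-neutral loading it stays
within the binomial sampling bound `trend_sampling_bound(n1, n4, p)`
(three standard errors of a between-bin frequency difference under
symbol-independent binning). The analogous check recovers a
`g2_stability_weight` of 2 as a positive weak-class trend among 5′A
precursors, and the recovered g1-A trend increases monotonically in the
5′A weight.

## In vitro quantification

Band intensities from RISC-assembly gels enter as plain numbers
(condition × replicate TSV; densitometry is out of scope).
`normalize_to_reference()` divides each replicate by its reference
condition (canonically 5′ A), so the reference is exactly 1 per replicate
and summaries are mean ± sample SD (n − 1), matching the three-replicate
convention of the assays. `total_normalized_distribution()` implements
the "total band intensity as 1" convention for length distributions.
`paired_t_bh()` runs two-sided paired t-tests and adjusts across the
declared comparisons with the Benjamini–Hochberg step-up; zero-variance
paired differences are flagged degenerate and excluded from the
adjustment rather than producing undefined statistics. The comparisons
are caller-declared because the published legend leaves the exact pairing
(between Argonautes per length, or between lengths within one Argonaute)
ambiguous. Published adjusted p-values from those assays depend on
unpublished replicate intensities and are not reproduction targets; the
procedure is the contract, and it is property-tested against a
brute-force step-up oracle.

## Numerical and degenerate-input conventions

* Coordinates are 0-based, half-open throughout; BED input is taken as
  standard BED.
* U and T are interchangeable on input; internal computation uses a
  single DNA alphabet and small-RNA tables report RNA.
* Frequencies per bin sum to 1 within 1e-9; bins emptied by a g1 filter
  are reported with `n = 0` and `NA` frequencies and excluded from
  trends, never raised as errors.
* Character ordering uses radix (C-locale) sorting everywhere a
  tie-break depends on string order, so results are locale-independent.
* Fewer records than bins, zero precursor read counts, all-zero loading
  weights, and missing input files raise immediate, named errors.

## Known limitations

Exact matching understates mapped reads for error-containing libraries;
CE is undefined for precursors that fail the read filter (they are simply
excluded); sense-strand-only mapping ignores possible antisense siRNAs;
and the simulator's independence assumptions (i.i.d. body composition,
locus-independent loading weights) are idealizations — real composition
trends can be confounded by dicing-end preferences, which can be explored
with the optional per-locus weighting but are not separately identified
by this analysis.
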