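# p4ce — conversion-efficiency analysis of Pol IV-derived siRNA precursors

In *Arabidopsis* RNA-directed DNA methylation, Pol IV transcribes 30–40 nt
precursors (P4RNAs) that are copied by RDR2, diced by DCL3 into 24-nt siRNA
duplexes, and loaded into AGO4 or AGO6. `p4ce` is for researchers asking
*which precursors make it into RISC and why*. Its core statistic is the
per-precursor **conversion efficiency**

```
CE_i = (AGO-bound siRNA reads whose 5' ends align exactly with precursor i)
       / (precursor reads of i)
```

Precursors are sorted by CE, split into equal-size ascending bins
(quartiles by default), and profiled for 5′-nucleotide (g1) composition and
for weak (A/U) versus strong (C/G) identity at the second position (g2, a
proxy for the thermodynamic stability of the duplex's 5′-terminal base
pair). A rising g1-A or weak-g2 frequency from bin 1 to bin 4 indicates
that 5′A / unstable-ended precursors are preferentially converted into
AGO-bound siRNAs.

The package provides:

* **Catalog construction** — collapsed FASTA/FASTQ reading, TruSeq 3′
  adapter trimming, exact sense-strand mapping to Pol IV cluster
  references, combining of reads that share a 5′ end, and the strict
  \>30 nt / >50 read species filters.
* **CE + binning** — 5′-anchored prefix counting of AGO-bound siRNAs,
  exact-ratio CE, deterministic equal-size binning.
* **Composition profiling** — per-bin g1 frequencies, g2 stability classes
  conditional on a chosen g1, and scalar bin-trend summaries with a
  binomial sampling bound.
* **A generative simulator** of biogenesis and AGO loading with known
  ground-truth weights (AGO4-like and AGO6-like presets), used for
  end-to-end parameter-recovery testing.
* **In vitro quantification** — reference normalization of gel band
  intensities, total-normalized length distributions, and paired t-tests
  with Benjamini–Hochberg correction.

## Worked example

Simulate a study-scale dataset (2000 loci, 5×10⁵ precursor reads, 10⁵
AGO-bound reads) with a strict 5′A loading preference, then run the full
analysis:

```r
library(p4ce)

bio <- biogenesis_params(n_loci = 2000, precursor_depth = 5e5, seed = 11)
ds  <- make_dataset(bio, loading_params_ago6(sirna_depth = 1e5, seed = 12))
res <- analyze_dataset(ds$precursors, ds$sirnas, ds$clusters,
                       pipeline_config(log_level = "quiet"))
res$g1_composition
#>   bin   n     A      U      C     G
#> 1   1 341 0.000 0.1525 0.1466 0.701
#> 2   2 341 0.000 0.1818 0.1906 0.628
#> 3   3 340 0.759 0.0588 0.0412 0.141
#> 4   4 340 1.000 0.0000 0.0000 0.000
res$trends$g1_A
#> [1] 1
```

Of the 1998 precursor species observed, 1362 survive the length/abundance
filters and are split into four CE bins of ~340 species. Bin 1 (lowest CE)
contains no 5′A precursors while bin 4 (highest CE) is entirely 5′A: the
simulated strict 5′A loading preference is recovered as a maximal g1-A
trend (bin 4 minus bin 1 frequency = 1). With a neutral loading model the
same trend stays within `trend_sampling_bound()` of zero.

File-based runs work the same way (`run_end_to_end()` writes catalog, CE,
composition TSVs and a JSON report), and a thin command-line wrapper with
`simulate` / `catalog` / `ce` / `composition` / `quant` / `all` subcommands
ships at `inst/cli/p4ce.R`.

In vitro band intensities are analyzed with the same conventions as the
sequencing side:

```r
gel <- data.frame(condition = c("A", "U", "C", "G"), replicate = 1,
                  intensity = c(1000, 500, 200, 300))
normalize_to_reference(gel, reference = "A")$summary
#>   condition mean sd n
#>           A  1.0 NA 1
#>           U  0.5 NA 1
#>           C  0.2 NA 1
#>           G  0.3 NA 1
```

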