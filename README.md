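# mcseq

Single-base resolution analysis of whole-genome bisulfite sequencing
(MethylC-seq) data, for epigenomics researchers who want the classic
vertebrate methylome workflow — methylcytosine calling, CpG islands,
differentially methylated regions, methylation–expression integration —
as composable, tested R functions with tidyverse ergonomics (tibbles in,
tibbles out, `tidy()`/`glance()` on fitted objects, `autoplot()` for each
result type).

## What it computes

Bisulfite conversion turns unmethylated C into T while 5-methylcytosine
stays C, so each reference cytosine yields counts *(m, n)*: *n*
informative reads and *m* supporting methylation, with methylation level
*m/n*. The core statistical machinery:

* **Methylcytosine calling.** The combined non-conversion + sequencing
  error rate *p* is estimated from an unmethylated mitochondrial contig;
  a site with depth *n* is tested against *X* ~ B(*n*, *p*). The default
  `tail_fdr` mode picks depth-stratified thresholds *m\*(n)* — the
  smallest *m* with tail probability P(*X* ≥ *m*) below a genome-wide
  cutoff chosen so that the expected number of false calls stays below
  1 % of all calls. A `literal` mode implements the alternative per-site
  inequality C(n,m) pᵐ(1−p)ⁿ⁻ᵐ < 0.01·m/(n−m), whose only
  consistent reading at m = n is a right-hand side of +∞.
* **CpG islands.** Takai–Jones-style scan with criteria GC > 55 %,
  observed/expected CpG = (#CpG·L)/(#C·#G) ≥ 0.65, length > 500 bp;
  islands are *methylated* when ≥ 70 % of their CpG dinucleotides carry a
  called methylcytosine on either strand.
* **DMRs.** Per-site two-sided Fisher's exact tests with
  Benjamini–Hochberg FDR (5 %) plus a two-fold level difference define
  differential mCGs; a 1 kb window stepped at 100 bp seeds on ≥ 4 such
  sites, extends while the trailing edge window still qualifies, and
  reported regions hold ≥ 5 differential mCGs over ≥ 1 kb, merged when
  overlapping. Each DMR carries the detected window span and a
  site-anchored core whose boundaries are refined by site-local evidence.
* **Integration.** Region metrics (mC/CG relative level, mC/Length
  absolute level, mean per-site degree), strand-aware promoters
  (−1.5 kb..+0.5 kb of the TSS), metagene and repeat/flank profiles,
  hyper-/hypo-methylated gene classes (≥ 70 % / ≤ 30 %), expression
  quintiles with Spearman promoter–expression correlation, Welch t-tests
  between gene groups, and per-gene χ² divergence between two lines.

A full synthetic-data module (`simulate_genome()`, `simulate_methylome()`,
`simulate_reads()`, `simulate_counts()`) generates genomes with planted
CpG islands, two-line methylomes with planted DMRs, bisulfite reads with
recorded truth alignments, and expression tables rank-coupled to promoter
methylation — so every stage is testable against known truth without any
download. A toy-scale three-letter aligner (`align_bisulfite_reads()`)
closes the loop from FASTQ to counts; genome-scale data enters as
per-cytosine count tables (`read_cytosine_report()`).

## Worked example

Simulate a two-line methylome, call methylcytosines, and find the planted
DMRs:

```r
library(mcseq)

cfg <- sim_config(seed = 42,
  genome    = list(n_contigs = 1L, contig_length_bp = 200000L, n_islands = 6L,
                   n_genes = 15L, n_repeats = 10L),
  methylome = list(n_dmrs = 4L))
sim   <- simulate_genome(cfg)
truth <- simulate_methylome(sim)

# two replicates per line at 14x, pooled to line level
counts_a <- pool_counts(
  simulate_counts(truth, 14, 0.007, seed = 1, level = "level_a"),
  simulate_counts(truth, 14, 0.007, seed = 2, level = "level_a"))
counts_b <- pool_counts(
  simulate_counts(truth, 14, 0.007, seed = 3, level = "level_b"),
  simulate_counts(truth, 14, 0.007, seed = 4, level = "level_b"))

err <- estimate_error_rate(counts_a, sim$genome)
#> <error_model> p = 0.0069 from chrM (184,491 bases)
```

The error model says: across 184,491 read bases at mitochondrial cytosine
positions, 0.69 % read as C — the combined non-conversion + sequencing
error, i.e. a conversion rate of 99.31 %.

```r
calls <- call_methylcytosines(counts_a, err)
glance(calls)
#> # A tibble: 1 x 7
#>   n_calls n_tested error_p mode     fdr_target   alpha expected_fp
#>     <int>    <int>   <dbl> <chr>         <dbl>   <dbl>       <dbl>
#> 1    6360    88420 0.00690 tail_fdr       0.01 0.00140        60.2

methylome_summary(calls)$context_fractions
#> # A tibble: 3 x 2
#>   context fraction
#> 1 CG       0.979
#> 2 CHG      0.00456
#> 3 CHH      0.0167
```

6360 of 88,420 covered cytosines are called methylated, with an expected
60.2 false calls (0.95 % of calls, inside the 1 % budget); 97.9 % of the
methylcytosines are in CG context, with only trace CHG/CHH — the
hallmark of a vertebrate methylome.

```r
dmrs <- find_dmrs(test_differential_sites(counts_a, counts_b))
dmrs
#> <dmr_set> 4 DMRs from 362 differential mCGs (11186 sites tested)
#>   contig  start    end length core_start core_end n_diff_sites direction
#> 1 chr1    66800  70400   3600      67688    69647          134 hyper_in_A
#> 2 chr1   124300 127900   3600     125128   126981           62 hyper_in_B
#> 3 chr1   162500 166300   3800     163362   165309          100 hyper_in_A
#> 4 chr1   172000 175600   3600     172831   174785           66 hyper_in_B
```

All four planted DMRs are recovered with the planted directions;
`core_start`/`core_end` track the outermost differential sites (the
sharp boundary estimate), while `start`/`end` is the ≥ 1 kb detection
span. `associate_dmrs_with_genes()` then links DMRs to genes within
±2 kb and `integrate_expression_differences()` flags two-fold expression
changes. `autoplot()` methods draw the level histogram, chromosome-scale
strand-signed mC density, metagene profiles, and per-quintile TSS
profiles.

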