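# sweeplines

Genome scans for **detecting and dating selective sweeps** in long-term
divergent selection experiments — two lines bred in opposite directions from
a common founder population, genotyped at several generations, with
"relaxed" sublines in which selection was discontinued at a known
generation. The motivating system is a pair of chicken lines divergently
selected for juvenile body weight for 50+ generations, genotyped on a 60K
SNP chip at generations 40, 50 and 53, plus relaxed lines split off at
generation 45 and sampled nine generations later.

The package is aimed at quantitative and population geneticists analysing
such experiments (or simulating them): it provides the scan statistics, the
drift calibration, the event-dating logic, and a forward simulator of the
whole breeding design so every stage can be verified against known truth.

## What it computes

* **Windowed expected heterozygosity.** Per marker,
  `Hz = 1 − (m² + (1−m)²) = 2m(1−m)` with `m` the major allele frequency;
  averaged over sliding windows of `W = 100` consecutive markers per
  chromosome (`window_profile()`, `het_profiles()`).
* **Empirically calibrated drift null.** The scan statistic is the change of
  the between-line profile difference over time,
  `Δ(w) = [Hz_H53 − Hz_L53](w) − [Hz_H40 − Hz_L40](w)`. A normal fit to the
  genome-wide window-wise distribution of `Δ` is cut two-sided at the
  family-wise 5% level, Bonferroni-corrected for `⌈M/W⌉` nonoverlapping
  windows (560 for 55,983 markers; per-tail quantile ≈ 4.5×10⁻⁵,
  `Φ⁻¹ ≈ −3.92`). Flagged windows merge into regions
  (`empirical_threshold()`, `call_regions()`).
* **Event dating.** Each region is classified fixed / reduced / polymorphic
  in all eight subgroups and a rule table over the design brackets onset and
  fixation — e.g. polymorphic at 40, fixed at 50 and 53, reduced in the
  relaxed line ⇒ onset in (40,45], fixation in (45,50]
  (`classify_timeline()`).
* **Fisher exact divergence scans** between relaxed and ancestral selected
  samples at every marker, against the Bonferroni cut `0.05/n_tests`
  (8.9×10⁻⁷ for 55,983 markers), plus the ordered −log₁₀ p regression
  comparing two pairs' global divergence (`scan_pair()`,
  `ordered_logp_regression()`).
* **Heterozygosity-loss summaries** with window-based standard errors
  (`mean_het_loss()`, `het_loss_table()`).
* **Haplotype blocks** from unphased genotypes via the D′
  confidence-interval definition: two-locus EM, likelihood-profile CIs,
  strong-LD spanning rule, pairs within 10 Mb, blocks > 5 Mb
  (`two_locus_em()`, `dprime_ci()`, `call_blocks()`,
  `filter_large_blocks()`).
* **A forward Wright–Fisher simulator** of the full design: structured
  founders, truncation selection on an additive polygenic trait
  (hermaphroditic or sex-structured sires/dams breeding), relaxed-line
  splits, scheduled sampling, and an optional injected beneficial mutation
  (`sim_config()`, `simulate_lines()`, `scenario_library()`).

I/O: PLINK ped/map and plain-text VCF in and out (`read_panel()`,
`write_panel()`), the published missingness QC (`qc_filter_missing()`,
markers with ≥10 missing genotypes dropped), TSV/BED/JSON exports, and
ggplot2 helpers (`plot_het_profiles()`, `plot_change_profile()`,
`autoplot()` on divergence scans).

## Worked example

Simulate the rapid-sweep scenario — a strongly beneficial mutation entering
the high line at generation 42 — and run the scan pipeline:

```r
library(sweeplines)

sim <- simulate_lines(scenario_library("B_novel_mutation", seed = 42))
res <- run_full_analysis(sim, stages = c("qc", "scan"))

attr(sim, "truth")$injected
#> $marker_id
#> [1] "c1_m2000"
#> $chrom
#> [1] "1"
#> $pos_bp
#> [1] 49987497

res$threshold
#> <sweep_threshold> cuts [-0.1343, 0.1252]  (q = 0.000125 per tail, 200 independent windows)

dplyr::select(res$regions, chrom, start_bp, end_bp, direction, n_windows, rule)
#> # A tibble: 1 × 6
#>   chrom start_bp   end_bp direction n_windows rule
#>   <chr>    <int>    <int> <chr>         <int> <chr>
#> 1 1     46036510 54413604 loss            175 e

res$regions$states[1]
#> HWS40=polymorphic; HWS50=reduced; HWS53=reduced; HWR9=polymorphic; ...
```

The one called region (heterozygosity **loss**, 175 flagged windows spanning
46.0-54.4 Mb) covers the injected locus at 50.0 Mb on chromosome 1: the scan
found the sweep. The per-subgroup states carry the dating evidence —
polymorphic at generation 40, strongly reduced at 50 and 53 — while the
relaxed subline, split off at generation 45 when the allele was still at
intermediate frequency, stayed polymorphic in this replicate (rule "e"; the
full (40,45]/(45,50] call, rule "c", additionally needs the region fixed at
50/53 and visibly reduced in the relaxed line — see the methods vignette for
when that is expected).
`plot_change_profile(res$change, res$threshold, res$regions)` draws the
genome-wide change profile with the cuts and the region.

The methods vignette (`vignettes/sweep-scan-methods.Rmd`) documents the
model, every threshold and default, the simulator's breeding structure, and
known limitations.

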