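---
title: "Detecting and dating selective sweeps in divergently selected lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating selective sweeps in divergently selected lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

sweeplines implements a genome-scan workflow for long-term divergent
selection experiments in which two lines are bred from a common founder
population, sampled with SNP chips at several generations, and accompanied
by "relaxed" sublines in which artificial selection was discontinued at a
known generation. The workflow detects genomic regions whose variability
changed more than genetic drift can explain, and then *dates* each event by
the pattern of fixation across the sampled subgroups. A forward Wright-Fisher
simulator reproducing this breeding design makes every stage testable
against known truth without any external data.

## The statistic: windowed expected heterozygosity

Within-population variability at a biallelic marker is measured by the
expected heterozygosity

$$Hz = 1 - \left(m^2 + (1-m)^2\right) = 2m(1-m),$$

where $m$ is the major allele frequency ($Hz = 0$ at fixation, maximal 0.5
at $m = 0.5$). Per-marker values are noisy — individual markers fix early by
drift wherever founder haplotypes carried uneven allele frequencies — so the
scan statistic is a moving average over windows of $W$ consecutive markers
(`window_profile()`). Windows never span a chromosome boundary, advance by
one marker (fully sliding), and renormalize over non-missing markers. The
default $W = 100$ markers matches the wavelength of heterozygosity
fluctuations along a dense (tens of thousands of markers) genome-wide panel;
on the real 60K chicken panel this corresponds to roughly 7 cM, commensurate
with the linkage drag expected around a locus selected for ~13 generations.
`scan_config()` exposes $W$ so the sensitivity range 20–500 markers can be
explored.

## Separating selection from drift: the empirical null

For a two-line design sampled at an early and a late generation (here 40 and
53), the scanned quantity is the *change* of the between-line profile
difference:

$$\Delta(w) = \left[Hz^{H53}(w) - Hz^{L53}(w)\right] -
              \left[Hz^{H40}(w) - Hz^{L40}(w)\right].$$

Most of the genome is assumed to be drifting, so the genome-wide window-wise
distribution of $\Delta$ estimates the drift null empirically — slightly
conservatively, because windows under true selection inflate its variance.
`empirical_threshold()` fits a normal distribution to the observed $\Delta$
(mean $\mu$, SD $\sigma$) and cuts at

$$\mu + \sigma\,\Phi^{-1}\!\left(\frac{\alpha/2}{n_\text{indep}}\right),
  \qquad n_\text{indep} = \lceil M / W \rceil,$$

two-sided at family-wise level $\alpha = 0.05$, Bonferroni-corrected for the
number of *nonoverlapping* $W$-marker windows needed to cover the $M$
markers. For $M = 55{,}983$ and $W = 100$ this gives $n_\text{indep} = 560$
and a per-tail quantile of $0.025/560 \approx 4.5\times10^{-5}$
($\Phi^{-1} \approx -3.92$). Note the two roles of windows are deliberately
different: profiles slide by one marker, but the multiplicity correction
counts nonoverlapping windows. Windows beyond a cut are flagged (ties at
exactly the cut are not, for determinism) and consecutive same-sign flagged
windows merge into regions spanning the first window's first marker to the
last window's last marker (`call_regions()`).

## Dating events: the subgroup fixation pattern

With selected lines sampled at generations 40, 50 and 53 and relaxed lines
split off at 45 and sampled nine generations later, the presence/absence of
a fixation across subgroups brackets when selection started and when
fixation completed. `classify_timeline()` reduces each region, per subgroup,
to one of three states from the mean windowed $Hz$ over the region's
*contributing* (flagged) windows:

* **fixed**: below `fixation_threshold` (default 0.03 — not zero, because a
  20-diploid sample showing a single stray heterozygote at a marker already
  reads $Hz \approx 0.05$ there, and flagged regions necessarily include
  partially swept shoulder windows);
* **reduced**: below `reduced_threshold`, default half that population's
  genome-wide median windowed $Hz$;
* **polymorphic**: otherwise.

The rule table over the design then brackets onset and fixation; e.g. a
region polymorphic at 40, fixed at 50 and 53, and reduced-but-not-fixed in
the relaxed line dates onset to (40, 45] and fixation to (45, 50] — the
signature of a strongly beneficial novel mutation arising shortly after
generation 40. The contributing-windows restriction matters: the merged
region's coordinate span is padded by up to $W$ markers on each side, and
averaging unflagged padding windows into the state call would dilute a fixed
core beyond recognition.

## Genome-wide divergence: Fisher exact scans

Divergence between a relaxed line and its ancestral selected sample is
tested marker-by-marker with the two-sided Fisher exact test on allele
counts (`scan_pair()`), against the Bonferroni cut $\alpha/n_\text{tests}$
($0.05/55{,}983 \approx 8.9\times10^{-7}$ on the real panel — conservative,
since linked markers are not independent tests). The p-value sums all
hypergeometric tables with the observed margins whose probability does not
exceed the observed table's (relative tie tolerance $10^{-7}$), the same
convention as `stats::fisher.test()`; the implementation is a vectorised
tail sum over `dhyper()` so a genome scan runs in seconds, computing each
distinct margin/count combination once.

Global divergence of two pairs is compared by re-ordering each scan's
$-\log_{10} p$ values from largest to smallest and regressing one on the
other rank-for-rank (`ordered_logp_regression()`, OLS with an intercept by
default; both the base and the intercept are options since neither is
canonical). A slope above 1 means the $y$ pair diverged more across the
whole distribution — the signature of purging selection acting genome-wide
in a relaxed line rather than at a few loci.

## Heterozygosity loss

`mean_het_loss()` summarises the genome-wide mean change of $Hz$ between two
samples (later minus earlier; negative is loss), over markers or over
nonoverlapping $W$-marker window means. The uncertainty is always the
standard error over nonoverlapping windows: markers in LD are far from
independent, and a marker-wise SE would be absurdly optimistic. Markers
undefined in either sample are excluded pairwise. Under pure drift the
expected loss over $t$ generations is $1 - (1 - 1/(2N_e))^t$ of the starting
heterozygosity, which anchors the simulator calibration below.

## Haplotype blocks

`call_blocks()` implements the confidence-interval block definition from
unphased genotypes. Two-locus haplotype frequencies come from an EM over
double-heterozygote phase (`two_locus_em()`; convergence when the largest
frequency change falls below $10^{-8}$, at most 1000 iterations; marginal
allele frequencies are reproduced exactly by construction). $|D'|$ and its
interval come from a likelihood profile on a $|D'|$ grid of step 0.001 with
allele frequencies held fixed, taking the 5th and 95th percentiles of the
normalized cumulative likelihood (`dprime_ci()`). Pairs are *strong LD* when
the interval is (0.70, 0.98] or tighter toward 1, *strong recombination*
when the upper bound is below 0.90, otherwise uninformative. A block is a
marker interval whose outermost pair is strong LD and in which at least 95%
of informative pairs are strong LD; overlaps resolve longest-span-first;
pairs farther apart than 10 Mb are never evaluated; markers below 5% minor
allele frequency are excluded. All thresholds are arguments. The pair matrix
is quadratic in markers per chromosome, so this stage is meant for targeted
panels, not the full sliding-window scan. `filter_large_blocks()` keeps
blocks strictly larger than 5 Mb, the scale at which blocks in these lines
are exceptional.

## The simulator and what it emulates

`simulate_lines()` is an individual-based forward Wright-Fisher simulator:
diploid individuals carry two haplotypes per chromosome over the marker
map; founders mix allele frequencies from several partially differentiated
founder sub-lines (Balding-Nichols draws around ancestral frequencies,
emulating a cross of partially inbred strains); the selected trait is
strictly additive over configured causal loci plus Gaussian environmental
noise (heritability sets the noise SD); gametes recombine as a Poisson
process on the cM map (Haldane, no interference; the compiled kernel copies
parental segments between crossover points). Scheduled line splits found
relaxed colonies, scheduled samplings emit genotype panels, and an optional
injected mutation places one allele copy in one breeding individual at a
stated generation. Everything is reproducible from one seed.

Two breeding modes are provided. Hermaphroditic truncation (select a
proportion, mate at random avoiding selfing) is the textbook model, but its
effective size is close to the selected-parent count, and with the
truncation intensities needed for a single new allele to fix within 5–10
generations the whole simulated genome fixes long before generation 40 —
nothing like a real selection line. Poultry lines are bred sex-structured:
a small number of top sires and a larger number of top dams, with family
sizes managed to limit inbreeding. The `list(direction, sires, dams)` mode
implements this (family sizes equalized within each sex), decoupling the
speed at which a beneficial allele spreads through the sire bottleneck from
the drift rate, which is governed by
$N_e \approx 4 N_s N_d / (N_s + N_d)$. The injected mutation enters a sire:
conditioned on observing a sweep fast enough to fix in well under ten
generations, the allele's early spread almost surely ran through the sire
side.

`scenario_library()` packages four study designs at desk scale (two lines
split at generation 45 into relaxed colonies, samples of 20 at generations
40/50/53 and relaxed generation 9; 5 chromosomes of 760 cM — the chicken
genetic-map scale — and $10^8$ bp):

* **A_drift_only** — no selection, census 50 per line, 10,000 markers. The
  null for calibration: with $N_e = 50$ the lines retain most of their
  founder heterozygosity through generation 53.
* **B_novel_mutation** — 20 sires / 80 dams from a census of 250 per line
  ($N_e \approx 75$, which reproduces per-13-generation heterozygosity
  losses of the observed ~0.02 magnitude), 20,000 markers so that a
  100-marker window (19 cM) matches the genetic extent of a young sweep
  core, 25 causal loci of large effect (standing-variation sweeps largely
  complete by generation 40, as observed), and an injected allele of effect
  far above the phenotypic SD at generation 42.
* **C_standing_sweeps** — the same design without the injection.
* **D_purging_relaxed** — as C, but relaxed colonies are weakly
  counter-selected (truncation 0.5 against the line's previous direction),
  emulating fitness costs of previously favored alleles.

### What passing simulations do and do not show

The injected-sweep scenario validates detection: the flagged region set
covers the injected locus in ≥90% of replicates, the allele is absent at
generation 40 and fixed by 50. Dating is validated structurally (the rule
table is exercised against constructed profiles with known states), but the
full narrative call — "reduced but not fixed" in the relaxed line — is a
*minority* outcome in simulation, and the package reports this honestly
rather than engineering around it. The reason is quantitative: the
reduced state requires the swept haplotype near frequency 0.9 at the
generation-45 split, i.e. a rise from one copy in three generations, which
caps the carrier's reproductive share at values only a handful of parents
can provide; a parent pool that small drives $N_e$ below ~30 and erases the
genome-wide diversity that detection (and the experiment itself) depends
on. A real event dated this way therefore carries information the desk
simulation cannot jointly reproduce — most plausibly the real mutation
preceded the earliest compatible generation, or the true breeding structure
had more reproductive skew than the managed scheme modeled here. Simulated
panels also idealize real data in other ways: evenly spaced markers, no
genotyping error, no missingness (QC is exercised on constructed fixtures),
and uniform recombination.

### Numerical and design choices

* Missing per-marker $Hz$ is renormalized out of window means (divisor
  reduced), rather than imputed or skipped.
* The empirical null is fit once, genome-wide, pooling all windows.
* Ties at exactly a cut are never flagged; regions of opposite sign never
  merge.
* The Bonferroni window count is marker-based, $\lceil M/W\rceil$,
  independent of the sliding step.
* Monomorphic markers are retained throughout (fixation *is* the signal),
  and markers monomorphic for the same allele in both populations of a
  divergence scan contribute $p = 1$ and count toward $n_\text{tests}$.
* The EM treats only double heterozygotes as phase-ambiguous; all other
  genotype pairs contribute haplotype counts deterministically.
* Test-suite and acceptance problem sizes: 50 replicates per calibration
  (binomial Monte-Carlo error ~0.03–0.07 on rates), drift-decay checks on
  single 300-marker chromosomes over 20 generations, block calling on
  60-marker planted panels. These are the package's chosen desk scales;
  all are arguments, not constants.

## Limitations

* The empirical-null normal fit is mildly anti-conservative when few
  independent segments underlie each window (small $N_e$, short maps); the
  family-wise flag rate under pure drift runs above the nominal 5% and is
  reported as measured by the acceptance checks.
* The timeline rule table assumes the eight-subgroup design; other
  sampling grids need their own table.
* Block calling is the published confidence-interval definition, not a
  byte-level reimplementation of any particular GUI tool; counts on real
  panels are comparable but not identical.
* The simulator ignores dominance, epistasis, overlapping generations and
  mutation (other than the single injected allele).
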