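---
title: "Methods and modelling choices in msatkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in msatkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatkit)
```

msatkit takes a microsatellite marker project from raw shotgun reads to a
per-locus characterization table. This vignette explains the model behind
each stage, the tunable parameters and their defaults, the numerical
conventions, and what the bundled simulators do and do not emulate. It is
the place where the package's genuinely open design choices are argued;
the reference manual documents the contracts.

## 1. Repeat discovery

A microsatellite (SSR) is a tandem repetition of a 2–6 bp motif; the motif
length is conventionally called the *kmer* (a dimer repeats 2 bp, a
tetramer 4 bp). `scan_read()` reports every **maximal perfect run**: a
stretch in which position $i$ equals position $i+k$ for a motif length
$k$, extendable by no further full repeat unit on either side. Three
conventions pin the output down:

* **Perfect repeats only.** Interrupted or compound repeats are not
  extended across mismatches; an `N` always breaks a run. Markers chosen
  for genotyping panels are typically perfect repeats, and perfect runs
  have an unambiguous unit count.
* **Left anchoring.** The reported footprint is the first
  $k \times \mathrm{units}$ bases of the run; a trailing partial unit is
  not part of the footprint, so `end - start = kmer * units` always
  holds.
* **Sub-period suppression.** A run whose motif is itself periodic (e.g.
  `ACAC` with period 2) is reported only at the shorter period. This
  prevents an $(AC)_8$ run from appearing a second time as a sham
  tetramer and, as a side effect, resolves equal-footprint ties in favour
  of the smallest kmer. Homopolymers (period 1) are never reported.

Motifs are summarized by their **canonical class**: the lexicographically
smallest string among all cyclic rotations of the motif and of its
reverse complement, so `TG`, `GT`, `CA` and `AC` are one class. This makes
counts strand-invariant, which matters because shotgun reads sample both
strands at random.

The per-kmer minimum repeat units that make a run worth reporting are a
screening policy, not a biological constant. The defaults,
`{2: 8, 3: 6, 4: 4, 5: 4, 6: 4}`, follow common practice for
read-based SSR mining — dimers need many units before they are usefully
polymorphic and reliably scorable, longer motifs fewer — and are exposed
in `msat_config(min_units = )` precisely because reasonable projects
differ here.

## 2. PAL screening

A repeat with a designable primer pair is a *potentially amplifiable
locus* (PAL). Whether it will behave as a single-copy marker is screened
from the read pool itself: `count_primer_occurrences()` counts exact
matches of each primer **or its reverse complement** across all reads,
overlapping matches included. The count acts as a crude copy-number
estimate:

* too few occurrences (default < 2) suggest the primer sequence contains
  a sequencing error and may not match the genome;
* more occurrences than the genome coverage suggest the primer site is
  repeated in the genome and would amplify several loci at once.

Exact matching (no mismatch tolerance) is deliberate: it is the only
reading that is exactly reproducible, and the screen is a coarse triage,
not an alignment. Both mates of a pair are searched as independent reads
and counting is over total matches, not reads-containing — both choices
are documented contracts rather than attempts to model library structure.

Coverage itself is estimated by `estimate_coverage()` from read depths
over a panel of single-copy gene fragments: the median depth per gene
(mean of the central pair for even counts), then the **grand median**
across genes, with the min and max of the per-gene medians reported for
context. Medians are used throughout because depth distributions from
shotgun data are heavy-tailed. The keep-rule upper bound defaults to the
grand median rounded half up; `filter_pals()` applies the inclusive band
and reports the first failing bound (`fwd_low`, `fwd_high`, `rev_low`,
`rev_high`) per locus, independently of every other locus.

## 3. Allele binning

Capillary electrophoresis reports fragment sizes on a continuous scale
(often fractional bp); alleles are integer labels on a ladder spaced by
the repeat unit. Historically bins were drawn by eye on a peak-size
histogram; `bin_alleles()` replaces that with an explicit, reproducible
rule:

1. sort the sizes and single-linkage cluster them — a new bin starts when
   the gap to the previous size exceeds `gap_factor * motif_len`
   (default `gap_factor = 0.5`, i.e. half a repeat unit);
2. label each bin with the round-half-up of its median size;
3. score the locus for ambiguity.

The ambiguity score counts, relative to the number of bins, (a) adjacent
bin pairs whose label spacing is not a positive whole multiple of the
repeat unit and (b) bins whose internal spread exceeds `motif_len - 1`
(a bin wider than a full unit minus one bp cannot be a single allele plus
measurement noise). A locus whose score exceeds `ambiguity_threshold`
(default 0.25) is flagged and excluded from characterization, mirroring
the practice of dropping loci whose histograms do not separate. The
threshold is a tool choice: 0.25 flags a locus as soon as more than a
quarter of its bins look wrong, which in our simulations separates clean
ladders (score 0) from bridged smears (score near 1) with a wide margin;
there is no published quantitative criterion to match here.

`assign_genotypes()` then maps each raw peak to the bin containing it. A
single present peak is recorded as a homozygote — the standard
fragment-analysis convention — which is worth stating because null
alleles produce exactly the same signal; the characterization stage's
null-allele estimate is the tool for noticing that. A peak outside every
bin voids the call (reported in the out-of-bin rate) rather than being
silently snapped to the nearest bin.

## 4. Locus characterization

`characterize_loci()` computes, per locus, the row a marker note
publishes: sample size, allele size range, allele count, observed and
expected heterozygosity, a Monte-Carlo Hardy–Weinberg test with
multiple-testing adjustment, rarefaction allelic richness, the Brookfield
null-allele frequency, and (when the whole panel was genotyped twice) the
replicate error rate.

**Heterozygosity.** $H_o$ is the fraction of complete genotypes with two
distinct alleles. $H_e$ uses Nei's unbiased estimator
$\frac{2n}{2n-1}\left(1-\sum_i p_i^2\right)$, which is exactly the
probability that two allele copies drawn *without replacement* differ
(the test suite verifies this identity against exhaustive pair
enumeration). The small-sample correction is the field's standard for
marker reports at $n \sim 30$; `expected_het(unbiased = FALSE)` gives the
plain gene diversity for comparison with software that omits it.

**Hardy–Weinberg test.** The statistic is the Pearson chi-square over all
genotype classes against expected counts $np_i^2$ and $2np_ip_j$. Its
null distribution is simulated by re-pairing: shuffle the pooled $2n$
allele copies and pair consecutive copies, which preserves the allele
counts exactly while randomizing genotypes. With $B$ permutations
(default 1999) the p-value is $(1 + \#\{T_b \ge T_{obs}\})/(B+1)$, never
zero and reproducible under a fixed seed. Each locus draws its seed from
a named sub-stream of the master seed, so adding or reordering loci never
changes another locus's p-value. Monomorphic loci get $p = 1$ by
convention and are excluded from the adjustment unless requested,
because a locus that cannot deviate only dilutes the correction.

**Adjustment.** Both Holm (step-down, family-wise error) and
Benjamini–Hochberg (step-up, false discovery rate) are provided via
`stats::p.adjust`; Holm is the default as the conservative choice for a
dozen-locus panel where a single false "out of HWE" verdict would
discard a usable marker. The method used is recorded in output headers.

**Null alleles.** The Brookfield estimator
$r = \max\!\left(0, \frac{H_e - H_o}{1 + H_e}\right)$ attributes a
heterozygote deficit to a non-amplifying allele. It is worth knowing its
behaviour under the dropout mechanism the simulator implements (null
homozygotes appear as missing and are excluded; null heterozygotes appear
as visible homozygotes): allele-frequency estimates stay unbiased,
$E[H_o] = H_e(1-r)/(1+r)$, and the estimate therefore converges to
$2rH_e/\big((1+r)(1+H_e)\big)$ — a modest underestimate that grows with
$r$ (about $-0.01$ at $r=0.1$ and $-0.08$ at $r=0.3$ for
$H_e \approx 0.9$; the test suite measures exactly this). The estimator
is kept in its standard form because it is what marker characterizations
report and compare; treat large estimates as conservative lower bounds.

**Allelic richness.** Allele counts grow with sample size, so loci (or
populations) with unequal $n$ are compared by rarefaction: the expected
number of distinct alleles in a subsample of $g$ allele copies,
$\sum_i \left[1 - \binom{N-N_i}{g}\big/\binom{N}{g}\right]$, computed
with log-binomials so large $N$ cannot overflow. The default
$g = 2 \times \min_\ell n_\ell$ (twice the smallest per-locus sample
size) is the usual convention that makes every locus comparable at the
size of the worst-sampled one; `msat_config(rarefaction_g = )` overrides
it. $g = N$ recovers the raw allele count and $g = 1$ gives exactly 1,
identities the tests assert.

**Error rate.** The unit is the genotype: the fraction of individuals
whose two replicate genotypes differ as unordered pairs, among
individuals complete in both replicates. A per-allele mode exists behind
a flag; published error rates in this range (0–7%) are consistent with
either unit, so the choice is stated rather than inferred.

## 5. Simulators and what they prove

The three simulators exist so every stage has a ground truth:

* `simulate_reads()` plants repeats and primer sites in uniform-ACGT
  background reads, **rejection-sampling the background** so no read
  accidentally contains a reportable repeat or a primer match. Planted
  composition is therefore exactly recoverable, and count assertions in
  the tests are equalities, not probabilistic bounds.
* `simulate_genotypes()` draws two allele copies per individual from
  Hardy–Weinberg proportions, with a null allele at a specified
  frequency implementing the dropout mechanism described above, optional
  extra missingness, and an optional second replicate with per-genotype
  miscalls (a miscall always changes the genotype, so the replicate
  discordance rate estimates the miscall rate directly).
* `simulate_peaks()` emits each allele label plus uniform jitter, with
  homozygotes producing a single peak.

One master seed drives a named stream per component
(`stream_seed(seed, name)`), so outputs are byte-identical across runs
and adding a new stream never perturbs an existing one.

What the simulators deliberately omit: sequencing-error and stutter
models, dye- and size-standard calibration artifacts, allele-frequency
structure from demography (no coalescent), and linkage between loci.
Passing the recovery tests therefore demonstrates the *algorithms* are
correct under their stated models, not that real electropherograms or
real read pools are this clean; on real data the binning ambiguity flag
and the out-of-bin rate are the early warnings.

## 6. Numerical conventions and problem sizes

* Coordinates are 0-based half-open everywhere; fragment sizes are
  fractional before binning and integer bp after.
* Rounding is half-up (`8.5 -> 9`) for bin labels and the coverage-derived
  count bound; reported tables print to 2 decimals by default, with full
  precision kept internally.
* Monte-Carlo ties count as "at least as extreme" (with a `1e-12`
  guard), which keeps the test valid (conservative) when statistics tie.
* Degenerate inputs error early and loudly: empty depth tables, empty
  size vectors, zero complete genotypes, rarefaction `g` outside
  `[1, N]`.

The test suite sizes its simulations to be decisive but quick: scanner
equivalence against an exhaustive oracle on 1,000 random reads of up to
200 bp; HWE p-value uniformity over 500 simulated loci at $B = 199$;
null-allele recovery over 200 replicate loci of 200 individuals at four
true frequencies; error-rate recovery at $n = 500$. These sizes give
Monte-Carlo standard errors comfortably below the asserted tolerances
while keeping the whole suite around half a minute.

## 7. Known limitations

* The PAL screen's exact-match counting undercounts when reads carry
  errors inside a primer site, and the coverage bound inherits any bias
  of the single-copy-gene panel; both are screening heuristics, not
  copy-number inference.
* Gap clustering assumes alleles are better separated than the
  within-allele size scatter; loci violating that (bridged clusters) are
  flagged ambiguous rather than force-binned, so a very noisy but real
  locus is lost rather than mis-scored.
* The Brookfield estimate is a lower-bound-flavoured summary under
  dropout (see above); it is not a substitute for a likelihood-based
  null-allele model when null frequencies are large.
* The HWE permutation test conditions on observed allele counts; it has
  low power at very small $n$ or with many rare alleles, which matches
  its field use as a flag rather than a verdict.
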