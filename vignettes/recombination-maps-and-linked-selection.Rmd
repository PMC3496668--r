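---
title: "Recombination maps, map comparison, and the footprint of linked selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recombination maps, map comparison, and the footprint of linked selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recmapsel)
```

## The scientific problem

In *Drosophila* and many other taxa, nucleotide diversity at putatively
neutral sites correlates positively with the local crossover rate. Two very
different mechanisms predict this pattern: recombination could be mutagenic
(in which case *divergence* between species should correlate with
recombination too), or recombination could modulate the loss of linked
neutral variation caused by selection — hitchhiking and background
selection — in which case diversity but not divergence should track the
local rate. Distinguishing the two requires (i) fine-scale recombination
maps measured directly from crosses, (ii) evidence that the rates are
comparable between the species whose divergence is being examined, and
(iii) models that relate diversity and divergence to recombination while
controlling for base composition, gene density and the local mutation rate.

`recmapsel` implements that full chain for backcross-based maps in the
*D. pseudoobscura* species group, together with a synthetic-data generator
that plays the role of the fly crosses and the resequenced genomes. Every
stage therefore has a recovery test against known ground truth, which is
how the package validates itself: no organism-scale genotyping or
resequencing dataset is shipped or required.

## Map construction from backcross genotypes

A backcross progeny is homozygous or heterozygous at each marker, and a
crossover in the F1 parent shows up as a switch between those two states
along the chromosome. `build_map()` chains the four steps:

1. **Error filtering** (`filter_double_crossovers()`). A single call whose
   nearest non-missing neighbours on both sides agree with each other and
   disagree with it would require two crossovers within one marker
   interval; crossover interference makes that vanishingly rare within a
   couple of megabases, so such calls are treated as genotyping errors and
   masked. The rule is applied in one simultaneous pass (no iteration), on
   runs of length one only, and regardless of physical distance — single
   discordant calls are removed wherever they occur.
2. **Crossover scoring** (`count_crossovers()`). A state change between
   consecutive non-missing calls is one event. When the flanking calls are
   adjacent markers the event belongs to that interval; when missing calls
   are skipped the event is attributed to the merged span and reported in a
   separate log, because assigning it to either constituent interval would
   be arbitrary. Each interval's denominator is the number of individuals
   with informative (non-missing) calls at both flanking markers.
3. **Kosambi scaling** (`kosambi_cm()`). Recombination fractions are
   converted to map distance with `cM = 25 ln((1 + 2r)/(1 - 2r))`, which
   corrects for interference, and divided by physical length to give cM/Mb
   (`rate_cm_per_mb()`). Intervals with no recombinant are reported as
   0 cM/Mb.
4. **Uncertainty** (`permutation_ci()`, `zero_event_upper_bound()`). The
   95% interval comes from resampling individuals' event indicators with
   replacement (10,000 replicates by default, percentile method, lower
   bound truncated at zero). "Permutation interval" is a loose term in this
   literature; the implementation here is an individual-level bootstrap,
   chosen because it matches common practice for cross-based maps and has
   verifiable coverage. For zero-event intervals the
   bootstrap degenerates, so the upper bound solves `(1 - x)^N = 0.05`,
   i.e. `x = 1 - 0.05^(1/N)`.

Rate heterogeneity among intervals is tested with a binomial GLM
(`heterogeneity_test()`): the interval-identity factor is compared by
likelihood ratio against a model with log interval size only, so the
degrees of freedom are the interval count minus two (minus one when all
intervals share one size and the size covariate is aliased).

Internally interval arithmetic is 0-based half-open; marker positions in
files are 1-based, and BED output converts accordingly.

## Comparing maps between crosses and species

Maps built from different crosses place markers at slightly different
positions, so `condense_intervals()` first restricts the comparison to
spans bounded by markers matched across all maps (greedy left-to-right,
default tolerance 10 kb — real matched markers differ by tens to hundreds
of base pairs; events in merged sub-intervals are summed and the
informative cohort of a merged span is conservatively the minimum of its
parts).

Crossovers are rare events: roughly one per individual per chromosome
spread over ~100 intervals. Ordinary logistic regression of event against
non-event is biased at such rates, so all comparisons use a Firth-type
penalized-likelihood logistic regression (`firth_logit()`), written
in-package: the Jeffreys-prior penalty removes the leading-order
small-sample bias and keeps estimates finite under near-separation. A
regression test asserts agreement with plain ML within 5% on non-rare
tables.

For each pair of maps, the additive model (map + interval) yields the
**global** odds ratio — e.g. a map-wide elevation of recombination in one
species — and its reciprocal is the multiplier that projects the elevated
map onto the reference scale (`apply_global_modifier()`). Per-interval
odds ratios come from interval-wise 2x2 Firth fits and are reported after
dividing out the global effect; the Wald test of that adjusted log-odds
against zero is the interaction test (the global estimate, supported by
~100 intervals, is treated as fixed relative to the single-interval
standard error). With three maps the package tests all pairs; a joint
three-way interaction test would be an alternative reading, but pairwise
tests are what the conservation rule below consumes.

Classification (`classify_intervals()`): an interval is **divergent** when
any pairwise q-value (Benjamini–Hochberg within the pair) is below 0.05;
**conserved** when every pairwise uncorrected p is at least 0.05 *and*
every adjusted odds ratio lies in [0.62, 1.615]; otherwise
**undetermined**. The asymmetric window is applied verbatim (note that
1/0.62 would be 1.6129, not 1.615); fidelity to the established rule was
preferred over imposing symmetry. No multiple-test correction enters the conserved rule, making it
deliberately conservative: an interval must look flat in every comparison.
Intervals with zero events in every map are excluded from per-interval
testing (no information) but kept in the global fit.

## Diversity, divergence and their covariates

Diversity and divergence are measured at third positions of 4-fold
degenerate codon families — sites where any base encodes the same amino
acid — and by default only in *unpreferred* codons, a stricter neutrality
proxy that avoids sites under translational selection. `classify_sites()`
derives degeneracy from the standard genetic code, strand- and
frame-aware; sites under overlapping reading frames are never eligible and
genes with internal stops are dropped. The shipped preference table marks
one C/G-ending major codon per amino acid, the typical *Drosophila*
pattern; no canonical machine-readable table exists for this species
group, so the shipped table is a documented, swappable default
(`default_preference_table()`), and a property test guarantees the
unpreferred and all-4-fold streams coincide when every codon is marked
unpreferred.

A site is **eligible** when every sample carries an unambiguous A/C/G/T
call (`eligible_mask()`); read-depth and base-quality filtering are
assumed to act upstream of this package, encoded as ambiguity or missing
characters in the alignment. `pairwise_diversity()` is the mean over eligible sites of the
fraction of sequence pairs differing (closed form `i(n-i)/C(n,2)` at a
biallelic site); `polymorphic_fraction()` returns the (SNP, eligible)
count pair that the GLMs bind as a two-column response — a count response,
distinct from the per-site average, and both are exposed.
`interval_summaries()` assembles the per-interval table: counts, GC,
coding density (union of CDS), and the neutral-mutation proxy (average
pairwise divergence of an outgroup species pair at the same site stream).

The interval model (`fit_quasibinomial_glm()`) is a quasibinomial GLM —
the counts are overdispersed — with sequential (type-I) deviance F-tests
in a fixed term order: gene density, mutation proxy, recombination, GC,
then the four two-way interactions. Sequential tests are order-dependent,
so the order is part of the model definition, and the same formula serves
the diversity and the divergence response so that the two streams are
directly comparable (interactions kept in both if significant in either).
Point estimates are identical to the binomial fit; the dispersion
(Pearson chi-square over residual df) only rescales the tests.

## Footprints of selection around substitutions

Around a substitution that fixed by positive selection, diversity should
dip and recover over a physical scale set by the local recombination rate.
`build_windows()` tiles 1,000 bp non-overlapping windows 60 kb on either
side of each substitution (anchored immediately adjacent to the site;
distance is window midpoint to substitution, so the innermost windows sit
at 500 bp; both sides are pooled by absolute distance). Windows with fewer
than 75 eligible 4-fold sites are dropped (`filter_windows()`), then
substitutions retaining fewer than 10 windows (`filter_substitutions()`);
both thresholds are strict (74 fails, 75 passes). Here all 4-fold sites
are used, not just unpreferred codons, because 1 kb windows would
otherwise often be empty. Narrower spans (5 or 15 kb) are just the `span`
argument. Covariates are standardized to mean zero, unit sd
(`standardize_covariates()`), with the (mean, sd) reference emitted for
interpretation.

The model (`fit_poisson_glmm_footprint()`) is a Poisson GLMM with a random
intercept per substitution and fixed effects for eligible sites, GC,
neutral proxy, proportion coding, proportion of nonsynonymous-substitution
bases, absolute distance, recombination rate, and the
distance-by-recombination interaction — the headline term: a negative
estimate means high recombination buys the same diversity recovery at
shorter distance. The control stream runs the identical model on windows
around synonymous substitutions. Mixed models use Laplace-approximate ML
(`lme4::glmer`), deterministic given the input table; fixed-effect
p-values use the normal reference for the Wald z. A companion per-gene
model (`fit_poisson_glmm_genes()`) relates nonsynonymous substitution
counts to recombination with synonymous counts, GC, flanking gene density
and the neutral proxy as covariates and a random intercept per map
interval.

## What the synthetic generator emulates — and what it does not

`simulate_backcross()` draws each individual's chromosome as a two-state
Markov chain over marker intervals: independent per-interval crossover
indicators with the scenario's true fractions, then per-call errors and
missingness. Real meiosis has crossover interference; the generator's
default deliberately omits it because the analysis side *removes*
apparent double crossovers as errors, and an interference-free generator
is the harder test of that filter. An optional mode suppresses double
crossovers within 2 Mb for users who want the interference-consistent
variant. Identical scenario and seed give identical fixtures.

`simulate_interval_table()` encodes the causal structure that motivates
the whole analysis: diversity responds to recombination
(logit-linear, default +0.10 per cM/Mb, i.e. about a 2.2-fold odds
difference across the simulated 0–8 cM/Mb range — of the order of the
severalfold diversity differences seen between low- and
high-recombination regions in *Drosophila*, and chosen so that the
27-interval design has decisive power), while divergence has its own
coefficients with the recombination term zero. Counts are beta-binomial
with the dispersion parameterized so that 1 is pure binomial (default 3,
matching the overdispersion that motivates the quasibinomial analysis).
Intervals default to eligible-site counts of 1,500–2,500, GC 0.35–0.55,
gene density 0.2–0.8 and a 2–8% neutral proxy — interval-scale values for
this genome.

`simulate_footprint_region()` uses an explicit stand-in kernel for the
sweep trough: expected polymorphic fraction
`pi0 (1 - c exp(-d / L(rho)))` with `L(rho) = L0 / max(rho, rho_min)`.
This is *not* a claim about how real troughs decay — no generative model
is published for them — but it has the three properties the analysis must
detect: depth `c` at the site, recovery to `pi0`, and width inversely
proportional to the local rate. Defaults: `pi0 = 0.25`, `c = 0.5`,
`L0 = 20 kb` at 1 cM/Mb, 200 eligible sites per kb window, synonymous
depth 0 (a flat control). Window counts are binomial around the kernel, so
the Poisson analysis model is slightly conservative on the null stream —
the same direction of approximation the real analysis makes when it
models bounded counts as Poisson.

What passing these tests shows is that the estimators recover the planted
structure at realistic sample sizes; what they cannot show is robustness
to features the generator lacks — linkage disequilibrium between sites,
demographic history, alignment error, or real trough shapes.

## Diffusion-theory checks

`fixation_probability()` implements the single-locus diffusion result
`u(p0) = (1 - e^{-4 Ne s p0}) / (1 - e^{-4 Ne s})` under genic selection
(`p' = p(1+s)/(1+ps)` before binomial sampling of `2 Ne` copies), with the
neutral limit taken analytically and log-space branches for extreme
`|Ne s|`. `wf_conditional_fixation_time()` is the matching discrete
simulator; it is the oracle for the facts that anchor the sweep
interpretation: a neutral mutation that fixes does so in 4 Ne generations
on average, with standard deviation 2.15 Ne, and conditional fixation
times are identical for +s and -s ("loser's luck": slightly deleterious
mutations that fix do so *quickly*, and can also dent diversity). These
quantities are in Ne units and scale-free, so the package verifies them at
Ne = N = 100 where a vectorized run takes seconds; the acceptance script
uses at least 3,000 fixed trajectories.

## Numerical choices and problem sizes

* Firth fits: Newton iterations with step-halving on the penalized
  likelihood, convergence at 1e-8; Wald CIs on the log-odds scale.
* GLMs: IRLS at epsilon 1e-8; all fits deterministic given the table.
* Bootstrap CIs: percentile method; type-7 quantiles; resampled fractions
  of 0.5 or more map to an infinite Kosambi distance and simply land in
  the upper tail.
* Simulation studies in the test suite and acceptance script use:
  1,000 bootstrap-coverage replicates at 1,200 individuals; 100 replicates
  of the 97-interval two-map design; 300–500 replicates of the 27-interval
  quasibinomial contrast; 30 + 60 replicates of the footprint GLMM; 3,000+
  Wright-Fisher fixations. These sizes keep every Monte-Carlo standard
  error a few times smaller than the margin being asserted.

## Known limitations

* The conserved/divergent classification tests map pairs; a joint
  multi-map interaction test is not implemented.
* Eligibility is a complete-unambiguous-call rule; upstream quality
  filtering must be encoded in the alignment.
* The per-interval Wald test treats the global map effect as known; for
  very few intervals that approximation weakens.
* The footprint kernel is a stand-in; inference about real trough shapes
  should not lean on its functional form.
* Marker order is taken as given (no linkage-group or ordering
  inference), and segregation distortion is not tested.
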