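---
title: "Methods: two-point linkage and exome variant filtering"
author: "linkexome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-point linkage and exome variant filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the statistical machinery it
implements: the two-locus pedigree likelihood and its peeling algorithm, the
LOD-score estimator of the recombination fraction, the exome filter cascade,
and the design of the synthetic-data generators that make the whole pipeline
testable without access to any family's real genotypes.

## The disease model

The pipeline targets a rare, fully ascertained autosomal dominant trait
segregating in a single large family.  The disease locus is modelled with
two alleles, D (disease) and d, and three parameters:

* the population disease-allele frequency $q$ (default $10^{-4}$, the
  conventional educated guess for a rare dominant disorder),
* the penetrance vector $(f_{DD}, f_{Dd}, f_{dd})$, the probability of
  being affected given each genotype (default $(0.9, 0.9, 0)$).

The defaults encode 90% penetrance for carriers — a deliberate hedge
against the genetic heterogeneity of hereditary hearing loss — with no
phenocopies ($f_{dd} = 0$) and homozygous carriers penetrant like
heterozygotes.  Both choices are configurable through `disease_model()`;
zero phenocopy is the simplest reading of a "penetrance 90%" specification
and the one used throughout the tests.

Individuals younger than the family's average age of onset are a modelling
hazard: an unaffected young carrier is expected under the model, not
evidence against linkage.  Rather than age-dependent liability classes, the
package takes the simpler mechanism of masking: the pedigree carries a
`below_onset_age` flag and `effective_phenotype()` scores flagged members
as *unknown* in every likelihood and in the co-segregation rule.  Liability
classes would add information only if onset-age distributions were known,
which they are not here.

## The two-locus likelihood and peeling

`two_locus_likelihood()` computes the exact joint likelihood of the
observed phenotypes and the genotypes at one marker, as a function of the
recombination fraction $\theta$ between marker and disease locus.

The state of an individual is an **ordered pair of haplotypes** (paternally
and maternally inherited), each haplotype coupling a disease allele with
one of the marker's $k$ alleles — $(2k)^2$ states per person.  Phase must
be represented because recombination acts on haplotypes; it is summed out
by the algorithm, never reported.  The factors are:

* **founder priors**: linkage equilibrium, $P(\text{hap}) = P(d)\,P(m)$,
  with Hardy–Weinberg sampling of the two haplotypes;
* **transmission**: a parent picks, independently at each locus, which of
  its two haplotypes contributes the allele; the picks agree with
  probability $1-\theta$ and disagree (a recombinant gamete) with
  probability $\theta$;
* **penetrance** of the effective phenotype given the disease genotype;
* **observation indicators** matching the unordered observed marker
  genotype (missing calls are always compatible).

The sum over all configurations is taken by Elston–Stewart peeling: the
pedigree is decomposed into nuclear families, each individual shared
between families acts as a separator, and messages (vectors over the
shared individual's states) are passed over the resulting bipartite tree.
The bipartite graph is a tree exactly when the pedigree has no marriage or
consanguinity loops; looped pedigrees are rejected at construction with a
clear error rather than loop-broken, since loop-breaking is not needed for
the loop-free families this pipeline targets.  Within a family the sum
over a child's states reduces to the matrix product
$\tau \Psi_c \tau^{\mathsf T}$ with $\tau$ the $(2k)^2 \times 2k$ gamete
matrix, so peeling a 53-member pedigree with an 8-allele marker takes
milliseconds.  Messages are rescaled to a unit maximum as they are formed,
with the log-scale factors accumulated separately, so underflow cannot
occur even on deep pedigrees; Mendelian-inconsistent data propagate an
all-zero message and return likelihood 0 (not an error).

The test suite certifies the engine against an independent oracle that
enumerates every state configuration explicitly (hundreds of random
pedigrees of up to 8 members, relative tolerance $10^{-9}$), and against
closed forms: a phase-known, fully penetrant pedigree with $m$
non-recombinant meioses must give $Z(0) = m\,\log_{10} 2$ (3.0103 for
$m = 10$), and $Z(\theta) = m \log_{10} 2(1-\theta)$ in between.

## LOD curves and estimating the recombination fraction

The two-point LOD score is
$Z(\theta) = \log_{10} L(\theta) - \log_{10} L(0.5)$.  `lod_curve()` is
the package's fitting function: it evaluates $Z$ on a reporting grid
(default $0, 0.1, \dots, 0.5$) and, unless `refine = FALSE`, maximises
$Z$ by golden-section search bracketed around the best grid point, to a
tolerance of $10^{-4}$ in $\theta$.  Grid-only mode exists to reproduce
published grid tabulations exactly.  Two tie-break conventions are fixed:
the grid argmax takes the first (smallest-$\theta$) maximum, and the
golden-section comparison prefers the left subinterval on ties, so a flat
curve reports $\theta_{\max}$ at the smallest grid value.  Published grid
rows with interior optima (e.g. a row whose tabulated $Z_{\max}$ of 0.29
at $\theta = 0.344$ exceeds every grid value) illustrate why refinement
needs the likelihood itself: from the grid alone the best that can be
reported is the grid argmax, and that is what
`lod_curve_from_values()` does.

LOD scores add across independent families on a shared grid
(`combine_families()`); the summed curve's maximum is recomputed from the
grid.  Sex-averaged recombination is assumed throughout — no sex-specific
map is modelled — and only two-point (single-marker) likelihoods are
computed; multipoint linkage and haplotype reconstruction are out of
scope.

Parameter recovery is verified by simulation: over 200 gene-dropped
replicates of the 53-member family fixture with a fully informative
8-allele marker at true $\theta = 0.1$, the mean of $\hat\theta$ falls in
$[0.05, 0.15]$ (the estimate from a single family is noisy — single-family
$\hat\theta$ has a standard deviation near 0.14 — but it is unbiased in
the mean).

## The linked interval

`define_interval()` turns the two markers flanking the disease haplotype
into a closed, 1-based physical interval, symmetric in argument order.
The span is reported as `end_bp - start_bp` (the distance between the
flanking markers); on the packaged 9q map the D9S1677–D9S1838 interval
spans 28,537,902 bp = 28.54 Mb.  BED export converts to 0-based
half-open coordinates; interval membership for variants
(`in_interval()`) is closed on both ends and insensitive to `chr`
prefixes.

## Variant QC

`apply_qc()` applies the four post-calling filters with boundary semantics
taken verbatim from their definitions: reject iff quality $< 20$, average
copy number at the site $\ge 2$, distance to the nearest other SNP
$< 5$ bp, or depth $< 4$ or $> 500$.  Thus quality exactly 20, distance
exactly 5 and depths 4 and 500 survive while copy number exactly 2 does
not.  Each rejected record is labelled with the *first* criterion it
fails, in that order.  The adjacency criterion is defined for SNPs, so
indels skip it.  Distances are consumed as a stored per-record field —
merging tables or interleaving indels therefore cannot silently change
the filter's meaning — with `recompute_snp_distance()` available to derive
the field from positions (as is done for VCF input).  How the upstream
caller computed "average copy number" is deliberately not modelled; the
value is consumed as given.

## The filter cascade

Candidate filtering proceeds in the canonical order for a dominant family
design:

1. **functional classes** — keep nonsynonymous, splice-site and indel
   variants (`functional_filter()`);
2. **public databases** — remove anything present in the configured
   known-variant sets (`subtract_known()`);
3. **control exome** — remove anything carried by the sequenced unaffected
   relative, treated as one more membership set.

At every stage and for every requested sample combination the ledger
records the count of variants shared by the combination (requiring a
non-reference call in each listed sample), exome-wide and inside the
linked interval.  Containment guarantees the ledger is monotone
non-increasing down stages and across added samples, and the final
candidates are the last stage's shared set for the largest combination
intersected with the interval.  Variant identity everywhere is the
(chromosome, position, ref, alt) 4-tuple with left-aligned indel anchors;
heterozygosity is *not* enforced during intersection — that is the
business of `cosegregation_check()`, which runs after candidates emerge,
mirroring the study workflow in which Sanger genotyping of the whole
family follows exome-level filtering.  One annotation quirk is handled
explicitly: codon-change strings (e.g. `GTG-aTG`) are treated as the
authoritative source for amino-acid annotation
(`translate_codon_change()`, standard genetic code, stops rendered `X`),
with no attempt to reconcile genomic strand against the ref/alt alleles.

The co-segregation rule: every typed affected member must be a
heterozygous carrier, every typed unaffected member at or past the onset
age must be a noncarrier, carriers below onset age are permitted, untyped
members are ignored.

## Synthetic data: what it emulates and what it does not

Two generators make every stage testable end to end.

`gene_drop()` emulates marker/disease co-transmission: founder haplotypes
from equilibrium frequencies, transmissions recombining with probability
$\theta$, phenotypes from the penetrances.  Because a $q = 10^{-4}$ allele
essentially never appears spontaneously among ten founders, an ascertained
disease family is emulated by forcing one founder to be a carrier
(`founder_carrier`), which is the simulation analogue of studying a family
*because* it segregates the disease.  Empirical checks recover the
configured $\theta$ (to $\pm 0.02$ over 10,000 meioses) and the 0.9
carrier penetrance (to $\pm 0.01$ over 10,000 carriers).

`simulate_exomes()` emulates the variant-table side: a background of
coding variants (default 18,000, each carried by a sample with probability
0.75, giving per-sample functional counts in the 7,000s — the scale a
whole-exome pipeline reports per individual), hierarchical database
membership (a variant is "known" with probability 0.93; known variants
join each public set with per-set probabilities, so roughly 7% of a
sample's functional variants survive database subtraction), and QC fields
drawn as quality $\sim$ round $\mathcal N(60, 20)$, depth $\sim$
NegBin(mean 50, echoing $\sim$50-fold mean coverage), copy number $\sim 1
+ \mathrm{Exp}(\text{mean } 0.1)$, nearest-SNP distance $\sim
\mathrm{Exp}(\text{mean } 500)$ — each filter then bites on the order of
1–3% of records, a light touch as post-calling QC should be.  The planted
causal variant obeys its specification (inside or outside the interval,
co-segregating or not, absent from all databases and the control,
heterozygous in every affected sample), and its QC fields are drawn
conditional on passing the filters: the causal variant a study reports is
by definition one that survived calling QC, so simulating QC failure for
it would emulate a *detection* failure mode this pipeline does not claim
to model.  A single seeded random stream with fixed draw order makes every
dataset byte-reproducible.

What the generators do **not** emulate — and hence what passing tests do
not show about real data: linkage disequilibrium among background
variants, sequence-context error modes (the background is positionally
uniform within chromosomes), relatedness-induced sharing structure beyond
the planted variant (per-sample carriage is independent), read-level
artefacts, and population stratification in the database sets.  The
end-to-end recovery property (planted variant recovered in $\ge 95\%$ of
100 seeded replicates over a 1,000-variant background) is therefore a
statement about the pipeline's internal consistency and power under its
own assumptions, not a re-derivation of any published yield.

## Numerical choices and problem sizes

* Log-domain accumulation with per-message rescaling; likelihood 0 is a
  value, not an error, except where even $L(0.5) = 0$ (then a structured
  `lx_impossible_data` error, since no LOD is defined).
* Golden-section tolerance $10^{-4}$ in $\theta$; grid ties toward
  smaller $\theta$.
* Marker allele frequencies default to equal ($1/k$), the convention for
  microsatellites of unknown frequency; per-marker frequencies are
  accepted everywhere.
* The exhaustive oracle used in tests is capped at $3\times 10^5$ state
  configurations per pedigree; random test pedigrees are drawn until they
  fit, which bounds oracle time without touching the engine under test.
* Test problem sizes — 200 oracle comparisons, 200 recovery replicates,
  100 end-to-end replicates over 1,000-variant backgrounds — were chosen
  as the smallest sizes at which the binomial/Monte-Carlo noise of each
  check is comfortably inside its assertion band.

## Known limitations

* Loop-free pedigrees only; no X-linked inheritance, no liability
  classes, no multiple phenotypes, no sex-specific maps.
* Two-point linkage only; the interval comes from flanking markers, not
  from multipoint support curves.
* The `n_alleles = 8`, equal-frequency annotation on the packaged marker
  map is a synthetic stand-in (the scan's allele counts were never
  published); LOD values computed from gene drops on these markers are
  exercise data, not reconstructions of the published table.
* The packaged family fixture reproduces the published census (53
  members, 11 affected, 5 below onset age) and named subject ids, but its
  topology is a construction; conclusions that depend on the true family
  structure cannot be drawn from it.
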