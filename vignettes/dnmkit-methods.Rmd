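---
title: "Methods: multigenerational de novo mutation analysis in dnmkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multigenerational de novo mutation analysis in dnmkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dnmkit implements a de novo mutation (DNM) analysis designed for large
three-generation pedigrees: multi-sibship families in which grandparents
(G1), parents (G2) and many children (G3) are all jointly genotyped. This
vignette is the package's own account of the methods: the generative and
statistical models, the filtering rules, the numerical choices, and what
the test suite does and does not establish.

## 1. The discovery model

A candidate DNM in a child is a biallelic site at which the child carries
an allele absent from both parents. The filters, applied in a fixed order
and recorded per candidate in a filter trail, are:

1. both parents genotyped in the cohort;
2. the child's genotype is heterozygous (on the X chromosome, males must
   be hemizygous for the alternate allele; heterozygous or
   homozygous-alternate calls there are treated as artifacts);
3. both parents homozygous reference;
4. aligned depth ≥ 12 in child, mother and father;
5. Phred-scaled genotype quality (GQ) ≥ 20 in all three;
6. zero reads supporting the de novo allele in either parent (allele
   depths, not genotype calls);
7. the site passes the joint caller's filters (`PASS`);
8. the site is outside low-complexity regions (LCR);
9. no *likely carriers* of the allele elsewhere in the cohort — samples
   genotyped with the allele at depth ≥ 12, allele balance ≥ 0.2 and GQ ≥
   20, outside the candidate's immediate family.

**Carrier-screen exemption.** The screen exempts the candidate's parents,
grandparents and siblings — and also their children and grandchildren.
Descendants must be exempt because a genuine, transmitted G2 DNM is carried
by the candidate's own children by construction; a literal
"siblings/parents/grandparents" reading would delete every validated G2
DNM. This is the one place where the package interprets rather than merely
applies the published recipe; the interpretation is forced by the
transmission design.

**Validation.** G2 candidates are validated by transmission: at least one
G3 child carries the allele at depth ≥ 12 and GQ ≥ 20, and the *median*
allele balance across such transmissions is ≥ 0.3. G3 candidates cannot be
transmission-validated, so they face stricter filters: own allele balance ≥
0.3, *zero possible carriers* (any genotyped carrier outside the family,
regardless of quality), and no high-quality grandparental genotype carrying
the allele. Candidates failing only the grandparental check are routed to
the missed-heterozygote tally rather than silently dropped.

A configuration knob (`min_g3_for_transmission`) can exclude G2 individuals
from sibships too small to yield confident transmissions; it is off by
default because the simulator controls sibship sizes directly.

**No allele-balance bound is applied to the G2 candidate's own genotype.**
Gonosomal (post-zygotic) mutations are expected at low allele balance, and
the classification step — not an AB filter — separates them from germline
events.

**Error rates.** The missed-heterozygote rate (MHR) is the fraction of G3
DNMs (validated + grandparental-supported) with grandparental support:
such variants were probably inherited from a parent mis-genotyped as
homozygous reference. The false-positive rate (FPR) uses the families whose
G1 grandparents were re-sequenced at high depth: a validated G2 DNM with ≥
2 reads supporting the allele in a deep parental alignment (mapping and
base quality ≥ 20) is counted false. The asymmetry — genotype calls for the
MHR, raw reads for the FPR — mirrors the different evidence each check has
available. The rate adjustment is

`adj_mu = mu * (1 - FPR) / (1 - MHR)` ,

with `mu = count / callable_bp / 2`. `callable_bp` is the number of
autosomal positions callable (depth ≥ 12, mapping quality ≥ 20) in child,
mother *and* father, outside LCRs; the expected number of mutations per
genome extrapolates `adj_mu` by a diploid genome size of 6.4 Gbp.

## 2. Phasing

**Informative sites** are variants heterozygous in the focal individual and
carried by exactly one of their two parents; the allele then tags one
parental haplotype.

*Transmission phasing* (G2 DNMs) searches ±200 kb for informative sites
additionally observed in every G3 child that inherited the DNM. For each
site the *transmission pattern* is the combination (G1 carrier parent, G2
child, exact set of G3 grandchildren co-inheriting marker and DNM); the DNM
is assigned the carrier parent of the modal pattern iff that pattern covers
≥ 75% of informative sites (the threshold is inclusive, so 3 of 4 sites
suffice). The 75% rule absorbs marker discordance from recombination or
genotyping error.

*Read tracing* (G2 and G3 DNMs) uses fragments co-observing the DNM site
and an informative site within ±500 bp (about one fragment length).
Observing the DNM allele with the single-parent allele places the DNM on
that parent's chromosome; observing it with the *other* allele places it on
the other parent's chromosome (phasing by exclusion). Fragment votes are
aggregated with the same ≥ 75% modal rule — the published method describes
only per-site logic, and symmetry with transmission phasing is the natural
multi-site generalization; the threshold is exposed as an argument.

*Consensus*: when both strategies phase a DNM and agree, the call stands as
consensus; a disagreement flags a conflict and the DNM is left unphased; a
DNM phased by one strategy only keeps that single-method call (threshold
support included — there is no second chance to overrule it).

*Shared mosaics* are phased by grandparental haplotype sharing: if every G3
carrier of a shared DNM carries one G2 parent's informative markers near
the site — with no marker splitting the carrier set — while the other
parent shows no such consistency, the DNM is assigned to the consistent
parent's germline. Two-carrier groups often share a haplotype from *both*
parents by chance; such DNMs stay unphased rather than guessed.

**Window boundaries are inclusive** (a marker exactly 200,000 bp away is
used); the choice is arbitrary and documented here.

## 3. Mosaicism classification

Three mutually exclusive mechanisms are distinguished for validated DNMs:

* **Shared post-PGCS germline mosaic** (G3): the same single-nucleotide DNM
  in ≥ 2 siblings of one family unit, absent from the blood genotypes *and*
  allele depths of both parents and all sequenced grandparents. Groups at
  which a parent nonetheless shows ≥ 2 raw aligned reads of support are
  removed — local reassembly by the joint caller can drop such reads from
  the emitted genotypes, masking a true carrier parent. Sibship membership
  is the family unit (same father *and* mother).
* **Gonosomal** (G2): incomplete linkage. A germline G2 DNM inherited on
  one gamete is in complete linkage with its background haplotype: every
  child carrying the linked informative alleles also carries the DNM. A
  post-zygotic mutation is carried by only a fraction of the germ cells
  with that haplotype, so some child inherits the informative alleles
  *without* the DNM. Classification requires ≥ 2 children carrying a
  linked marker (with one, incomplete linkage is undetectable and the DNM
  conservatively stays germline, flagged `low_power`), and the discordant
  child must lack the DNM at *every* linked marker — the conservative
  reading of an ambiguous rule, chosen to keep the classifier's false
  positive rate at zero in the zero-noise regime (a property the test
  suite asserts).
* **Post-zygotic in the child (three-haplotype test)**: fragments spanning
  a DNM and a nearby heterozygous site normally show two allele
  combinations; a third combination supported by ≥ 2 fragments implies the
  mutation arose after fertilization of the child and the DNM is removed
  from the germline callset. The threshold of 2 fragments is explicit in
  the published method and exposed as `min_reads`.

Per-child statistics divide each G3 child's shared (mosaic) DNM count by
their total DNM count (germline + shared); children with zero DNMs get an
`NA` fraction and a flag rather than a silent drop.

## 4. Statistical models

All age-effect models are Poisson regressions with the **identity link**:
`E[count] = slope * age + intercept`, so slopes read as additional DNMs per
year. Fitting goes through `stats::glm(family = poisson(link =
"identity"))` — the same route the study's own analysis used — initialized
from an ordinary-least-squares fit, with the start shifted toward the data
mean when OLS produces nonpositive fitted means. Non-convergence or a
nonpositive fitted mean is reported as an error; the link is never silently
switched. An independent brute-force likelihood grid search over a
two-parameter toy problem is kept in the test suite as an oracle for this
routine.

Confidence intervals are Wald intervals (estimate ± 1.96 SE); model
comparison is by analysis of deviance (`chi2 = deviance_null −
deviance_full`, chi-squared with the parameter-count difference as degrees
of freedom; identical models return `chi2 = 0, p = 1`). The family-aware
suite fits: the pooled paternal-age model; family intercepts; the
`dad_age * family_id` interaction (per-family slopes); a coverage-aware
no-intercept model `count ~ dad_age_scaled + callable_fraction + 0`, which
is the exact expansion of `E = (Bp*Ap + B0) * callable_fraction`; and a
parental model `dad_age + mom_age + family_id`. Because both parents age in
lockstep within a family, the parental model can be near-collinear; it is
reported as `NULL` rather than fitted degenerately when the design is rank
deficient. Per-family fits require ≥ 2 children and non-constant ages, and
are flagged as skipped otherwise.

Mutation spectra use eight classes — pyrimidine-normalized SNV classes,
with C>T at CpG separated, plus a pooled indel class. Purine-reference
records are folded through the reverse complement together with their
trinucleotide context. Spectrum comparisons run a per-class 2×2 chi-squared
test of independence **without continuity correction** (the published
analyses do not state a correction; the flag is exposed), with
Benjamini–Hochberg adjustment *within the class set compared* (per figure
panel, not across panels) at FDR 0.05.

Mosaic age models follow the pool model's predictions: an identity-link
Poisson regression of the shared count on paternal age (expected flat), a
linear model of the log shared fraction on age (expected negative, since
the germline denominator grows with age: fraction ≈ m/(m + Bp·Ap + B0)),
and correlation tests of the shared fraction and count against sibship
size (expected null under the pool model).

## 5. The synthetic cohort generator

The generator's defaults *are* the study conditions the pipeline targets:

* 33 families, sibships of 4–16 children drawn as `4 + Binomial(12, 1/3)`
  (median ≈ 8); parental ages at first birth uniform (fathers 18–28,
  mothers 16–24) with 1–3-year sibling gaps, recorded in whole years, as
  pedigree metadata usually is;
* paternal germline DNM counts per child Poisson with identity-link mean
  `1.44 * dad_age + 14.24` (≈ 56 at age 29) and maternal counts
  `0.38 * mom_age + 4.12` (≈ 14 at age 26), giving ≈ 80% paternal events
  overall; G2 individuals receive their own germline DNMs from G1 ages on
  the same model; all means are scaled by the trio callable fraction;
* per G2 individual, gonosomal mutations Poisson(7) — about 9% of their
  candidate DNMs — carried on a background haplotype (label paternal with
  probability 0.5, reflecting the sex balance of post-zygotic events) and
  transmitted to each background-haplotype child with conditional
  probability 0.5 (net 0.25 per child), with a Beta-skewed allele balance
  (mean 0.35) in the carrier's blood;
* per G2 parent, a post-PGCS mosaic pool of Poisson(6) mutations, each
  transmitted at net probability 0.25 per child independently of parental
  age. The per-gamete mosaic-fraction distribution is not published; this
  single-fraction pool is an assumption, chosen so that sibships of ~8
  usually share a pool mutation between ≥ 2 siblings, and it is the main
  caveat on the mosaic-detection sensitivity results;
* missed heterozygotes at rate 0.4% of G3 DNMs (a truly inherited variant;
  the carrier parent emitted as confident hom-ref with zero alternate
  reads while one grandparent keeps the het call) and false-positive G2
  candidates at 4.5% — modelled as G1-level missed heterozygotes, the one
  mechanism consistent with a "false" candidate that nonetheless validates
  by transmission; deep resequencing of the affected grandparent then
  reveals ≥ 2 supporting reads. Four G2 individuals per cohort have
  deep-sequenced parents, mirroring the study's re-sequencing subset;
* informative markers: Poisson(3) transmission-phasing markers within
  ±200 kb and Poisson(1.5) read-tracing markers within ±500 bp per DNM
  (per parent for shared-mosaic sites), each planted on a random
  haplotype of the focal individual and propagated consistently from its
  G1 founder; fragments co-observe alleles exactly as the true phase
  dictates, with third-haplotype fragments at gonosomal sites;
* a miniature genome of four 10-Mb autosomes plus one X-like chromosome;
  ~5% of each chromosome masked as LCR; per-sample callable masks with
  Poisson(15) gaps of mean 20 kb per chromosome. Mutations are placed only
  in territory callable across the whole family and outside the LCR —
  the same restriction the callable-genome rate denominator encodes.

Haplotype inheritance is drawn once per (child, parent, chromosome) with no
recombination, so marker–DNM co-segregation within a chromosome is perfect
by construction; a 200-kb window in this model never spans a recombination
breakpoint. Genotype evidence is noisy by default (Poisson depth around 30,
GQ levels {99, 60, 30}, binomial allele depths); `genotype_noise = FALSE`
makes evidence deterministic, the regime in which truth recovery is exact.

One master seed drives per-family substreams, so any family is reproducible
independently and two runs of the same configuration are identical.

**What the generator does not emulate** — and what passing tests therefore
do not establish about real data: alignment and calling artifacts beyond
the two error channels modelled (no stray parental alt reads at true DNM
sites, no mapping errors, no multiallelic complexity); recombination
between a DNM and its markers; population sharing of marker alleles
(markers are private to their founder); X-chromosome mutation (the X exists
in the genome model and the X calling rules are unit-tested on constructed
records, but the default generator places DNMs on autosomes, as the rate
and age analyses are autosomal); and somatic tissue structure (no mosaic
cell-fraction model beyond a skewed allele balance).

## 6. Numerical choices and degenerate inputs

* Interval arithmetic uses `GenomicRanges` (1-based, closed) with BED I/O
  through `rtracklayer`; multi-mask intersections go through coverage
  slicing, which is algebraically identical to chained pairwise
  intersection. A per-base brute-force oracle in the test suite pins the
  arithmetic.
* Allele-balance thresholds (0.2, 0.3) are compared exactly on integer
  allele depths (`100 * alt >= 100*thr * (ref+alt)`), avoiding float
  boundary flakiness; the transmission *median* is compared with a 1e-12
  guard (an even number of transmissions averages two exact fractions).
* Multi-allelic VCF records are dropped with a message on read; sites are
  biallelic thereafter.
* Children lacking a genotyped parent are skipped (counted, not rejected);
  missing grandparents are skipped by the MHR and shared-mosaic checks,
  which therefore lose sensitivity rather than fail.
* An empty transmission set, zero callable bp, an MHR denominator of zero,
  and an FPR subset with no DNMs all raise explicit errors.
* In `simulate_cohort`, positions are drawn uniformly within allowed
  territory with rejection on collisions; a bounded retry guard turns a
  too-small genome into an error instead of an endless loop.

## 7. Problem sizes used by the test suite

The tests exercise the pipeline at desk scale, chosen as the smallest
cohorts that leave every mechanism observable: zero-noise end-to-end
recovery uses 3 families of 4–6 children (≈ 850 truth events); error-rate
recovery uses 6 families of 6–10 children with all error channels on;
regression recovery uses 2,000 simulated children per model; coverage and
test-size calibrations use 1,000 seeded replicates. The acceptance script
regenerates the slope-recovery experiments at n = 2,000 under a
caller-supplied seed.

## 8. Known limitations

* Gonosomal detection is bounded by sibship informativeness: an event whose
  background-haplotype children all happen to carry the DNM is genuinely
  indistinguishable from a germline event, so cohort-level gonosomal counts
  are underestimates; the classifier reports `low_power` where only one
  marker-informative child exists.
* Shared-mosaic detection only sees pool mutations transmitted to ≥ 2
  siblings; singleton transmissions are (correctly) counted as ordinary
  germline DNMs.
* The consensus step trusts single-method phase calls at exactly threshold
  support; with both methods available, conflicts are never resolved by
  support weight — they unphase the DNM.
* The per-family interaction model is fitted unpenalized; families with
  few children yield wide intervals and occasionally fail to converge, and
  such fits are flagged, not imputed.
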