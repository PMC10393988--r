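---
title: "Models and methods behind paleokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paleokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(paleokin)
```

paleokin implements the analysis chain used to study kinship and
population structure in low-coverage ancient genomes: damage-aware
genotype calling, pairwise relatedness, rule-based pedigree
reconstruction, f-statistics with block jackknife, qpAdm-style admixture
modelling, and Y-haplogroup assignment — together with a synthetic-data
module that provides ground truth for all of it.  This vignette explains
the models, the tunable parameters, and the design decisions, in the
package's own terms.

## The synthetic cohort: what it emulates and what it does not

Ancient-DNA cohorts have three defining data pathologies: very low and
variable coverage (median well below 1x in typical studies), post-mortem
cytosine deamination producing C→T (and complementary G→A) miscalls
concentrated at fragment ends, and contamination from modern human DNA.
The simulator reproduces all three on top of genetic truth drawn from an
explicit population-history model:

* **Allele frequencies** evolve on an admixture graph.  Drift on a branch
  with parameter $F$ is a Balding–Nichols Beta draw with mean equal to
  the parent frequency $p$ and variance $F\,p(1-p)$; an admixed node is
  the $\alpha$-weighted average of its two sources before its own drift.
  This model was chosen because its first two moments propagate in closed
  form, so every expected f-statistic is available exactly
  (`graph_moments()`, `expected_f4()`), giving the estimators an
  independent oracle.  Ancestral frequencies are uniform on
  $[0.05, 0.95]$; all frequencies are clamped to $[10^{-6}, 1-10^{-6}]$
  so likelihoods stay finite (fixed sites carry no information).
* **Pedigrees** are gene-dropped site by site: autosomes receive one
  random allele from each parent, the X is hemizygous in males and
  transmitted mother-to-son, Y and mitochondrial lineage labels follow
  the uniparental paths.  Every founder allele carries a unique
  identity-by-descent tag, so realized $k$-coefficients (`realized_k()`)
  are exact ground truth, not a pedigree expectation.
* **Reads** are Poisson per site (`mean_depth` = $\lambda$), drawn from
  the individual's alleles or, with probability $\varepsilon$, from a
  contaminant population's frequency; each read is deaminated first
  (C→T/G→A with the profile rate at its distance to the nearer fragment
  end) and then miscalled with the base-error probability.  Damage is
  applied before sequencing error because deamination is a template
  property; at realistic rates the order is numerically negligible.

The simulator deliberately omits linkage (sites are exchangeable;
coordinates exist only so distance thinning and genomic-block jackknifing
operate as on real data), sequence-level reads (no FASTQ), and library
mixtures (one `sequencing_spec` per individual).  Consequently a passing
test shows that an estimator behaves correctly under the stated noise
model — it does not show robustness to LD, mapping bias, or reference
bias, which real data add.

## Damage-aware genotype calling

For each read with observed base $b$, true-allele hypothesis $a$, error
probability $e$ (from the base quality) and deamination probability $d$
(from the profile at the read's terminal distance; flat fallback when no
distance is available):

$$P(b \mid a) = (1-d)\,P_e(b \mid a) + d\,P_e(b \mid \mathrm{dam}(a)),$$

where $\mathrm{dam}(C)=T$, $\mathrm{dam}(G)=A$, and $P_e$ misreads to
each other base with probability $e/3$.  Genotype likelihoods are read
products (haploid genotypes for the male X and Y), and GQ is the
phred-scaled difference between the best and second-best genotype under
a flat prior — no population prior is defensible for single ancient
individuals.  Each concordant read separates homozygote from
heterozygote by $10\log_{10}2 \approx 3$ phred, so GQ grows slowly for
homozygotes; heterozygotes supported by both alleles become confident
almost immediately.  Hard diploid calls in the analysis scripts therefore
use a GQ threshold of 30, which in practice admits well-supported
heterozygotes and deep homozygotes only.

Pseudo-haploid calls draw one read uniformly per site, with an RNG stream
keyed by `(seed, individual)` so results do not depend on processing
order.  Genetic sex uses $R_y = n_Y/(n_X+n_Y)$ with an exact binomial
95% CI against thresholds 0.016 (female) and 0.075 (male) — standard
shotgun-ratio cutpoints, exposed as arguments.  The authenticity gate
fails individuals with contamination estimates above 0.2 or terminal
damage below 25%; missing fields are reported, never failed.

## Pairwise relatedness

Two independent routes, consolidated:

* **Mismatch route (READ-style).**  `read_p0()` computes the pseudo-
  haploid mismatch fraction over sites with reference-population MAF
  $\ge 0.1$, in 1 Mb windows (retained for spread estimates) and overall.
  `classify_read()` divides by the cohort median — assuming a mostly
  unrelated cohort; at least 10 pairs are required, otherwise an explicit
  normalization value must be supplied — and classifies by midpoints of
  the expectations $1-\phi$: below 0.625 identical, then first degree,
  second degree, and unrelated from 0.90625.
* **Likelihood route (NgsRelate-style).**  `ml_k_coefficients()` runs EM
  on $\sum_s \log \sum_{g_1,g_2} L_1(g_1) L_2(g_2) P(g_1,g_2 \mid f, k)$
  with the standard non-inbred nine-cell table, start $(1/3,1/3,1/3)$,
  tolerance $10^{-6}$ in log-likelihood, 200 iterations; the per-pair
  site set is distance-thinned at 2,500 bp.  $\theta = k_1/4 + k_2/2$.
  An identifiability caveat worth knowing: at per-site depth near 1 the
  data constrain only $\theta$, not the split into $k_1$ versus
  $k_0/k_2$; the reference studies therefore estimate $k$ at
  $\lambda = 4$ while the mismatch route runs at $\lambda = 1$.
* **IBS statistics.**  Operative definitions are frozen as:
  IBS0 = opposite homozygotes, $\theta_{KING} = (N_{\text{het,het}} -
  2\,\mathrm{IBS0})/(N_{\text{het},i}+N_{\text{het},j})$,
  $R_0 = \mathrm{IBS0}/N_{\text{het,het}}$, and
  $R_1 = N_{\text{het,het}}/(\mathrm{IBS0}+\mathrm{IBS1})$.  A third
  commonly plotted quantity, sometimes called R2, has no standard
  definition; this package reports $\theta_{KING}$ in that role and says
  so rather than guessing.

On conflict between the two routes the likelihood-based degree wins and
the conflict is flagged (`consolidate_degree()`).

**X-chromosome kinship** (`theta_x()`) is reported as the X kinship
coefficient: the probability that one random X allele from each
individual is IBD.  Male data are haploid; male–male and male–female
pairs use two-component sharing mixtures fitted by EM, female–female
pairs use the diploid k-model ($\theta$ is the X kinship directly).  On
this scale father–son is 0, brothers and mother–son are about 0.5, and
an identical male sampled twice is 1 — exactly the contrasts the
pedigree rules need.  A 1,000-site overlap gate withholds estimates on
thin data.

## Pedigree reconstruction

The engine is deliberately a rule system, not a likelihood search over
topologies, because the evidence types (uniparental markers, age
classes, k-coefficients, X kinship) are heterogeneous and the field's
practice is rule-based.  The fixed order is: gates (10,000 autosomal /
1,000 X overlapping SNPs; sub-gate evidence never enters), first-degree
typing (juvenile and mitochondrial rules before k-evidence, X kinship as
a male-male tiebreaker), triangulation to fixpoint, then X-kinship
pruning of what remains.  Triangulation implements the two classic
inferences — first degree to one member of a sibling pair plus second
degree to the other means child/niece–nephew; second degree to one
sibling with demonstrated unrelatedness to the other means grandchild —
plus their corollaries for orienting parent–offspring edges (a PO
partner of both members of a sibling pair is the parent; chains through
known grandparents; adults over juveniles).  When both members of a PO
pair are same-class adults and no triangulation applies, the edge stays
unoriented with an ambiguity flag rather than guessing.  Conflicting
rule firings are retained and flagged, never silently overridden, and a
cycle check runs on the parent-of relation.  Half-siblings are kept in
the second-degree candidate set alongside grandparental and avuncular
types for completeness, with the X-kinship pruning table
(male–male near 0 → paternal line; elevated → maternal line; thresholds
0.12 and 0.3, midpoints of the pedigree-expected values 0 and 0.25–0.5)
narrowing candidates where X data exist.

`pedigree_truth_evidence()` generates the complete error-free evidence
table for any scripted pedigree (class-exact $k$ vectors, recursive
pedigree $\phi$ and X kinship), which is how the four-generation
reconstruction test can demand exactness.

## f-statistics and their standard errors

`fstat_f3/f4/d` evaluate the textbook per-site forms on frequency
matrices whose columns may be populations (allele-count means — no
heterozygosity correction by default, the appropriate choice for
pseudo-haploid data where sample-size corrections assume diploid calls)
or single individuals (pseudo-haploid 0/1 codes).  Standard errors use
the weighted delete-one-block jackknife with 5 Mb genomic blocks and
weights proportional to block SNP counts; on equal blocks it reduces
exactly to the classical delete-one formula, which the tests verify.
Cohort hygiene before population-level statistics: singleton variants
and individuals under 85% genotyping are dropped, and each kin group
keeps only its highest-coverage member.

Within-group diversity is summarized as $1-f_3$ over pairs excluding
relatives of degree two or closer.  The autosome-versus-X contrast fits
a least-squares line of autosomal outgroup-$f_3$ on X outgroup-$f_3$
across partner populations and reports standardized residuals:
male-driven gene flow from a partner-like source elevates autosomal
affinity relative to X, a positive residual.  The per-individual
site-affinity D test removes the focal individual — and, by default, its
first/second-degree relatives — from the site population term before
computing $D(\text{outgroup}, \text{individual}; \text{cohort},
\text{site})$; excluding relatives is a deliberate design choice to
separate residence signal from direct kinship, and the switch is
exposed and test-covered both ways.  The per-sex rank test
(`wilcox.test`) is summary plumbing, not a reproduction of any published
statistic.

## qpAdm-style admixture modelling

A target's profile of $f_4(\text{target}, r_0; r_j, r_0)$ over the
non-base right populations is, under an admixture model, the
weight-combination of its sources' profiles.  `fit_weights()` solves
that system by feasible GLS: the residual covariance is estimated by
delete-one-block jackknife at an initial fit and the fit re-weighted
(two passes); the full-model p-value is the chi-square tail of the
weighted residual with $(|R|-1)-(k-1)$ degrees of freedom; weight SEs
re-fit on every block deletion.  Singular covariances are
ridge-regularized with $\varepsilon = 10^{-8}\,\mathrm{tr}(Q)/\dim$ and
a logged message.  The implementation follows the published description
of the method; exact numerical equivalence with the original ADMIXTOOLS
binaries is not claimed — the validated surface is parameter recovery on
simulated truth, which is what the acceptance checks measure.  Per-site
("allsnps"-style) overlap is the default, switchable to global
intersection; on complete data the two are identical.

The nested rule declares a model plausible only when every
source-dropped submodel is rejected (nested $p < 0.05$), the full model
fits ($p \ge 0.05$), and the weights are feasible — reported as three
separate conditions.  The rotating-outgroup screen fits every
$k$-subset of a candidate pool as sources with the complement as rights
(guarded against combinatorial explosion), flagging models with
single-individual sources.  Per-individual ancestry decomposition fits a
fixed three-source model and, when a nested model is not rejected, falls
back to the surviving two-way model; if that model lacks the focal
source the focal ancestry is 0, with the fallback provenance recorded.

## Y-haplogroup assignment

Markers live on the branches of a rooted haplogroup tree.  Before
assignment, calls are cleaned by the two ancient-DNA rules: transition
calls with GQ below 50 are kept only when the observed allele is C or G
(T/A observations there are indistinguishable from deamination), and at
transversion sites whose two alleles exclude T (resp. A) an observed T
is relabelled C (resp. A to G).  Assignment scores every root-to-node
lineage by cumulative derived calls, restricted to candidate tips whose
own branch carries derived support (an unsupported descendant is the
same lineage as its parent); the assigned label is the deepest supported
node on the winning lineage, and off-lineage derived calls are counted
but ignored.  The phrase "lowest level supported by the highest number
of derived mutations" admits two readings — deepest supported node
versus maximal-count node; the deepest-supported reading is implemented
because the maximal-count reading can never descend past the first
branch of a long lineage with sparse data.  Ties between lineages prefer
fewer conflicting ancestral calls, then stop at the deepest common
ancestor with a conflict flag, since the data genuinely cannot separate
them.

## Study conditions and problem sizes

The reference experiments fix the conditions every test and the
acceptance script share: a six-population calibration graph at 50,000
sites for f4 calibration; two-way mixtures with $\alpha = 0.3$ at
50,000 sites, 20 replicates, for weight recovery; the family cohort at
160,000 candidate sites and $\lambda = 1$ (over 50,000 overlapping
pseudo-haploid sites per dyad after the MAF filter) with terminal
deamination 0.2 for degree classification, plus a $\lambda = 4$ pass
for the k-model, 20 replicates; a 50-node marker tree with 20%
missingness for haplogroup recovery, 100 replicates; and 20 replicates
each of the sex-biased admixture ($\alpha_{auto} = 0.35$ versus
$\alpha_X = 0.1$) and patrilocal-site (three-generation patriline with
in-marrying females, 10-individual cohort) designs.  These sizes were
chosen so each experiment's sampling noise sits well inside the
decision margins being tested.

## Known limitations

No linkage or recombination model; no contamination-aware kinship; no
inbreeding-aware (nine-coefficient) estimation; mitochondrial haplogroup
labels are metadata inputs, not called from sequence; the qpAdm-style
fit validates against simulated truth, not against the reference
implementation's numerics; and pedigree reconstruction is rule-based,
so relationships outside its rule vocabulary (e.g. double cousins)
will be typed as their nearest expressible class or left ambiguous.
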