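---
title: "Recombination bin maps and joint linkage in NAM populations: models and methods"
author: "nambin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nambin methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Nested association mapping (NAM) panels cross one common parent to many
diverse founders and derive recombinant inbred line (RIL) families by
single seed descent (SSD), typically to F7. Genotyping-by-sequencing (GBS)
at low coverage yields on the order of $10^5$–$10^6$ SNPs per family but
with two defects that matter for linkage work: a large missing-call
fraction (a site is only observed if a read happened to cover it) and
allele-call errors, including heterozygotes reported as a random homozygote
because only one allele was sampled. Raw SNPs are therefore both too noisy
and too numerous for joint linkage analysis.

`nambin` implements the full path from such data to usable genetics:

1. quality screens for contaminated and excess-heterozygosity lines;
2. per-family inference of which observed allele came from the common
   parent (maximum parsimony plus a resampling stability score);
3. a two-state hidden Markov model (HMM) that decodes each RIL's parental
   origin along the chromosome and corrects isolated call errors;
4. reduction of SNPs to recombination bins — chromosome intervals within
   which no RIL in the family recombines — which retain all linkage
   information while shrinking the marker count by two orders of magnitude;
5. per-family and composite genetic maps (Haldane distances with a
   selfed-RIL correction, segregation-distortion screening);
6. multi-environment BLUPs and broad-sense heritability;
7. joint-linkage QTL scans with family-nested marker effects, permutation
   entry thresholds, LOD profiles and 2-LOD support intervals.

Because the package ships a simulator that produces panels with complete
ground truth (true breakpoints, true parental origins, true QTL effects),
every stage is verified against known answers rather than against
plausibility.

# The simulator and what it does (not) emulate

`simConfig()` fixes the study design: number of families, RILs per family
(the classic designs use ~180), chromosome lengths in bp and cM,
genome-wide SNP count, founder minor-allele-frequency spectrum,
generations of inbreeding (7 = F7), and the three GBS noise rates. One
master seed drives named sub-streams (founders, each family, noise,
phenotypes) so any part of a panel can be regenerated independently.

Meiosis has no crossover interference: crossover counts are Poisson with
mean equal to the map length in Morgans and positions uniform on the
genetic scale, mapped to bp through a uniform cM–bp relation per
chromosome. This matches the Haldane map function used downstream — the
simulator and the estimator share one model, deliberately. Selfing keeps
one offspring per generation (SSD). Residual heterozygosity falls as
$2^{-g}$ after $g$ selfings (≈1.6% at F7), and the simulator resolves
remaining heterozygous stretches by splitting them at their midpoint when
it writes the ground-truth segments.

Two useful closed forms anchor the tests: the marginal per-site
heterozygosity $2^{-6}$ at F7, and the density of detectable junctions in
the homozygous consensus, which an independent grid-based Monte-Carlo
oracle puts at 1.857 per Morgan at F7 (standard error 0.011). The popular
"2 per Morgan" figure is the fully inbred ($F_\infty$) asymptote; at F7 a
fraction of junctions is still hidden inside unresolved heterozygous
stretches, and the tests use the F7 value.

GBS noise is applied per call, independently: missing with probability
`missing_rate` (default 0.3), a surviving homozygote flipped with
probability `error_rate` (default 0.01), a surviving heterozygote reported
as a random homozygote with probability `het_undercall_rate` (default
0.5). The real per-call GBS rates of the maize panels are not published;
these defaults are plausible stand-ins and are fully configurable — any
conclusion that depends on them should be rechecked at other settings.
What the simulator does **not** emulate: read-depth-dependent error
structure, selection during SSD, segregation distortion with a biological
cause, population structure beyond the NAM design, or a non-uniform
recombination landscape (a piecewise cM–bp map can be supplied, but the
default is uniform). Passing tests therefore demonstrate correctness of
the algorithms under the stated model, not robustness to every real-data
pathology.

# Outlier screens

Both screens follow the two published definitions. Sites are first
filtered with strict inequalities (taxa coverage >10%, MAF >0.01, site
coverage >20%); heterozygotes contribute one count to each allele in the
MAF. The **excess-heterozygosity screen** refilters per family (site
coverage >66%, MAF >0.25) and flags lines whose ratio of H calls to
non-missing calls exceeds 10% (strict).

The **contamination screen** is built on identity-by-state (IBS): the
distance between two call vectors is the mean half-mismatch (heterozygote
vs homozygote counts one half) over shared non-missing sites.
Neighbor-joining trees per chromosome (via `ape::nj`) are produced for
manual review, and an automatic rule replaces the by-eye inspection of the
original protocol: a chromosome votes "foreign" when some other family's
diverse parent is closer to the line than its own family's diverse parent
by more than an IBS margin (default 0.05), votes "own" in the reverse
case, and abstains otherwise; a line is flagged when foreign votes
outnumber own votes. Two details matter and were set by simulation
evidence. First, the margin: a RIL chromosome that happens to be inherited
entirely from the common parent is equidistant from every diverse founder,
and without the margin such chromosomes vote at random. Second, abstention:
with few chromosomes, demanding a majority of *all* chromosomes lets
uninformative ones mask a clear foreign signal. A line whose genome is
essentially all common parent is undetectable in principle — it carries no
non-parental alleles and, by the published definition, is not an outlier.

# Parental-origin inference

Within a family, only sites with family MAF ≥ 0.05 are used, and among
sites closer than 64 bp (a proxy for "same sequencing tag") only the
best-covered one is kept. The inference then chooses, per site, which
allele came from the common parent so as to minimize the number of
parent-origin switches implied between consecutive sites, summed over
RILs (heterozygous calls are ignored; they are handled later by the HMM).
This is solved exactly by a two-state shortest path: the cost of giving
two adjacent sites the same (different) assignment parity is the number of
RILs whose calls disagree (agree) across the pair. Ties break toward
keeping the previous site's assignment, then toward "allele A is common".
The global sign is unidentifiable from RIL data alone; it is anchored to
known common-parent calls when available, otherwise to the majority allele
of the first informative site.

One screen precedes the path search. A site that carries no linkage
information — its agree/disagree margin with *both* neighbours is smaller
than $4\sqrt{n}$ — is excluded. Such sites are almost always monomorphic
sites that crossed the MAF threshold on call errors alone, and they are
not merely useless: a single one breaks the chain of pairwise evidence,
after which the shortest path can flip the assignment parity of the whole
remainder of the chromosome at essentially zero cost. In one simulated
family a single such site flipped 1,646 of 5,070 sites. The screen removes
the failure mode at its source; the excluded sites are reported as
unassigned.

Stability is then scored by resampling: RILs are drawn with replacement
(default 200 draws), the parsimony inference is rerun on overlapping
windows of 15 sites, each window's sign is aligned to the full-data
assignment, and $q_j$ is the fraction of runs reproducing site $j$'s
assignment. Sites with $q_j < 0.9$ are dropped. This score replaces the
Bayesian posterior of the method this step descends from, whose exact
formulation is not restated in the literature available here; it behaves
as intended (clean sites get $q = 1$, a pure-noise column centres near
0.5) but is a declared stand-in, and the window width, draw count and
threshold are all configurable. Note its limit: a *coherently* wrong
region agrees with itself under resampling, which is exactly why the
strong-linkage screen above is needed as well.

# Error-correcting HMM

Each RIL's origin-coded calls along a chromosome are decoded with a
two-state HMM (common / diverse origin; "heterozygote set to missing"
removes any need for a third state). The transition probability between
adjacent sites $d$ cM apart is $(1 - e^{-2\rho d})/2$, capped at 0.5, with
$\rho = 0.02$ per cM by default — two junctions per Morgan, the selfed-RIL
map expansion. Emissions show the true origin with probability
$1-\varepsilon$ (default $\varepsilon = 0.01$); missing sites emit
nothing. Decoding is by forward–backward posterior rather than Viterbi so
that a confidence threshold can act per site: only sites whose maximum
posterior reaches `p_min` (default 0.99) receive a state, the rest stay
missing and are treated as transition-region missing data downstream.
`fitEpsilon()` re-estimates $\varepsilon$ from the mismatch fraction
between confident decoded states and observed calls (kept only when at
least 1,000 usable calls exist).

Residual heterozygosity needs one extra step. Inside a heterozygous
stretch, half of the surviving calls are observed "H" (set missing), but
the other half are *undercalled random homozygotes*, and a run of five or
more same-direction random calls decodes as a confident false block —
posterior confidence cannot help, because the evidence really is
consistent within the run. `maskHetRegions()` uses the observed H calls as
the witness: any window of 7 observed calls containing ≥2 H calls is set
missing entirely. Without this mask the spurious-breakpoint rate on
default simulations is ~30% of the true breakpoint count; with it, ~2%.

# Blocks, breakpoints, bins

Maximal runs of identical decoded states form blocks (missing sites do not
interrupt a run); a breakpoint is placed at the midpoint between the last
site of one block and the first site of the next — the published
procedure says only "at the transition", and the midpoint is the natural
unbiased choice. A block is masked as missing when it is **both** shorter
than 1,500 kb **and** supported by fewer than five SNPs; the conjunction
reading (each condition alone is survivable) follows the wording and is
kept as the default, with both thresholds configurable. Flanking blocks of
equal genotype re-merge after masking.

The family bin map partitions each chromosome at the union of all RILs'
breakpoints; adjacent intervals with identical genotype columns (NA equal)
merge; bins extend to the chromosome ends so they tile it completely.
Per-RIL bin genotypes come from the covering block; bins inside a RIL's
transition gap stay NA. Bins narrower than 5 kb (strict) merge into the
next bin; where the constituents disagree the cell becomes NA. Finally
`imputeTransitionBins()` fills NA cells: agreeing flanks win directly,
disagreeing flanks are resolved by the same two-state HMM run over the
RIL's bin sequence at bin midpoints. The compression is lossless by
construction before the 5-kb merge: expanding bins back to SNP coordinates
reproduces every RIL's post-mask decoded genotype (the 5-kb merge is the
one deliberately lossy step, and the tests treat it as such).

# Genetic maps

The observed discordance $R$ between two bin columns understates the
meiotic recombination fraction $r$ in inbred lines, because recombinants
accumulate over generations. The classical Haldane–Waddington relation
$R = 2r/(1+2r)$ assumes complete inbreeding; `rfBetweenBins()` applies it
by default, and $d = -50\ln(1-2r)$ cM (Haldane) converts to map distance.
At F7, however, the relation is not yet at its asymptote, and using the
$F_\infty$ form deflates map lengths by a stable ≈7.5% on F7 panels.
`selfedDiscordance()` therefore computes the exact finite-generation
discordance by iterating the two-locus selfing Markov chain (it converges
to $2r/(1+2r)$ as $t \to \infty$, which the tests check), and the map
builders `buildFamilyMap()` and `assembleCompositeMap()` invert it at
`generations = 7` by default — the design this package targets. Set
`generations = Inf` to reproduce the classical behaviour.

The composite map takes markers polymorphic in strictly more than
`min_families` families (the published thresholds: more than two families
in an 11-family panel, more than four in a 25-family panel), encodes the
common-parent allele as 1, the diverse allele as 0, heterozygous and
family-monomorphic cells as NA, and merges consecutive identical columns
into joint bins (again merging <5 kb). In the full pipeline the joint-bin
genotypes used for distances are re-read from the families' *imputed* bin
maps rather than from the raw encoding: the HMM's confidence threshold
leaves NA exactly at transition bins, so raw-encoding discordance between
adjacent joint bins would miss most recombinations (observed: a composite
length of 45 cM where ~92 was expected). Structural NAs — whole families
in which a marker is monomorphic — are preserved.

Linkage groups form by single-linkage clustering at a pairwise two-point
LOD of 10 (full pairwise up to a size cap, adjacent chaining above it);
a group spanning two chromosomes is treated as evidence of upstream
contamination and raises an error. Markers with 1:1 segregation (1-df
chi-square, P ≥ 0.05) form the framework map in physical order; distorted
markers are inserted at their physical rank and excluded when their
distances to the flanking framework markers are inconsistent with the
framework interval (tolerance 5 cM). Ordering is by physical position
throughout — the marker coordinates are anchored to a reference genome,
so a likelihood-based reordering step would only be able to disagree with
the reference by error; likelihood enters through the distances only.

# Phenotypes: variance components and BLUP

Variance components come from the ANOVA expected mean squares of the
line × environment model with replicates (method of moments; negative
estimates truncate at zero), and broad-sense heritability on a line-mean
basis is $H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_{ge}/E +
\sigma^2_e/(ER))$. Line BLUPs use environments as fixed and lines as
random: each line's environment-adjusted mean shrinks toward the grand
mean by $\sigma^2_g / (\sigma^2_g + \sigma^2_{ge}/E_i + \sigma^2_e/n_i)$
with per-line counts handling unbalanced data. On balanced data this
closed form equals the REML mixed-model solution (checked against lme4 in
the test suite). The exact mixed-model specification behind the published
analysis (covariance structure, blocks, checks of the augmented design) is
not printed; this declared model is the substitute, and field-trial
spatial adjustment is out of scope.

# Joint-linkage QTL analysis

The response is the line BLUP; family main effects are always in the
model; a marker enters as one allele-substitution slope per family in
which it segregates (0/2 coding, so the slope *is* the additive allele
effect: the two homozygous classes differ by twice the effect). Because
every model column — family indicator or family-nested slope — is
supported on a single family, the design is block-diagonal by family;
residualizing against the current model acts within families and keeps
candidate columns for different families orthogonal, so the F-test of a
candidate marker decomposes into per-family projections. The scan exploits
this (the whole 500-marker scan is a few matrix products), and
`nestedMarkerTest()` is the direct QR implementation kept as the reference
the fast path is tested against.

Entry thresholds come from permutations: the response is shuffled within
families (preserving the forced family structure — the published
procedure does not say which; within-family is the choice that leaves the
forced terms' null distribution untouched), the minimum nested-marker P
over all markers is recorded per permutation, and the empirical
α-quantile of the minima is the entry threshold. Forward selection enters
the smallest-P marker while it beats the threshold; a backward pass after
each entry removes any marker whose drop-P exceeds the exit threshold
(set equal to the entry threshold — only entry thresholds are published
for this analysis); family terms are never removable. Mean imputation
within family fills residual NA marker cells for the regression.

Each selected QTL is profiled over its own marker and four flanking
markers per side: the QTL's term is swapped for the candidate's while all
other QTL stay as covariates, and $\mathrm{LOD} = (n/2)\log_{10}
(\mathrm{RSS}_\mathrm{without}/\mathrm{RSS}_\mathrm{with})$. The 2-LOD
support interval extends from the peak in both directions up to and
including the first marker at or below peak − 2, flagged as truncated
when the drop is not reached inside the window. Allele-effect significance
is an uncorrected t-test of each family's slope against the reference
(common-parent) effect of zero, as in the source analysis. For a combined
two-panel design the two common parents' panels are distinguished by a
forced reference covariate; with family main effects present this term is
collinear and changes labelling, not fit, which is the expected behaviour
of a nested design.

# Numerical choices and problem sizes

Posterior recursions are scaled per site (no underflow); LOD and F
computations guard RSS with a floor of $10^{-300}$; the parsimony DP and
the HMM are exact and are property-tested against exhaustive enumeration
up to 12 sites. Tie-breaks: parsimony prefers the previous assignment,
then allele A; bin-genotype conflicts in merges become NA; the
distortion test uses the two observed codes' counts directly.

The shipped experiments use panels scaled to run on a laptop: the bin-map
experiments use 2 families × 200 RILs on one 200 cM / 200 Mb chromosome
with ~5,000 segregating SNPs per family at 30% missingness and 1% call
error; QTL calibration and power use 5 families × 200 RILs × 500 bins with
200-permutation thresholds, and the combined-panel contrast merges two
3-family panels. These sizes were chosen so that Monte-Carlo standard
errors are small relative to the acceptance margins while a full run stays
in minutes; all of them are parameters, not constants.

# Known limitations

* The resampling stability score is a pragmatic replacement for the cited
  Bayesian refinement, not a reimplementation of it.
* The heterozygosity-region mask assumes observed H calls witness true
  heterozygosity; in data where H calls are themselves artifacts the
  window parameters need care.
* The contamination rule compares diverse founders only; a contaminant
  whose genome is almost entirely common-parent is undetectable (and
  arguably harmless).
* Composite ordering trusts the physical positions; misassembled
  reference regions would propagate into the map rather than being
  reordered away.
* Map distances assume no crossover interference (Haldane); on organisms
  with strong interference the cM scale will be compressed relative to a
  Kosambi-based one.
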