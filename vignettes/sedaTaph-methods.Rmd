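---
title: "Models and methods behind sedaTaph"
author: "sedaTaph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sedaTaph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Sedimentary ancient DNA (sedaDNA) profiles from sediment cores promise
taxon-level reconstruction of past landscapes, but the signal in any one
stratum is a mixture: DNA shed by the local contemporaneous environment,
DNA arriving with influxing and reworked sediment from elsewhere (and
elsewhen), and DNA moved after deposition by diffusion through the pore
water. `sedaTaph` implements a self-contained analysis stack for this
problem: read-count confidence scoring and contamination filtering,
co-occurrence "plant guild" construction, guild-profile distances,
stratification and diffusion tests, a Monte-Carlo-fitted sediment-influx
depositional model that classifies strata as secure or insecure, Simpson
diversity time series over secure dated samples, and a clade-support SNP
counter for placing an ancient sequence among reference genomes.  A
synthetic-landscape generator with full ground truth makes every stage
testable without any external data.

# Count confidence and filtering

Upstream taxonomic assignment (a phylogenetic-intersection filter over
BLAST hits) has a published accuracy of 0.96 on data of this kind, hence
a per-read false-positive rate fpr = 0.04.  Treating reads as
independent, the probability that a taxon's entire signal of $n$ reads
is spurious is

$$P = \mathrm{fpr}^n,$$

which `assignConfidence()` uses as the assignation's P value; the scope
filter (`subsetScope()`) retains taxa with $P < 10^{-4}$, an allowed
taxonomic rank, and native-to-Europe status.  The confidence is computed
on each taxon's total read count across samples, matching a per-taxon
(not per-sample) retention decision.  `filterNegativeControl()` removes
taxa exceeding 2% — strictly greater, and of the *control library's own*
total — in any control batch; pooling across batches is available via
`pool = TRUE`, with per-batch the conservative default since a
contaminant prominent in one extraction batch should not be diluted away
by clean batches.

# Plant guilds

Guilds are groups of taxa that tend to occur together across samples.
The similarity between two taxa is the Pearson correlation (pmcc) of
their per-sample relative frequencies (counts divided by sample totals —
raw counts would mostly correlate sequencing depth).  Correlations map
to distances by

$$d = 1 - \frac{\mathrm{pmcc} + 1}{2},$$

so perfect co-occurrence is 0 and perfect avoidance 1.  Classical
(Torgerson) multidimensional scaling embeds taxa in 10 dimensions, and
taxa are grouped by hypercube occupancy: each axis is divided into three
equal sections, a hypercube is a joint choice of section on the
considered dimensions, and grouping starts at three dimensions, adding
dimensions to a group until it is *stable* — the added dimension either
leaves no subgroup of two or more taxa outside the largest piece, or the
largest piece keeps at least 90% of the members (configurable).
Singleton groups are unassigned taxa, not guilds.

Two numerical choices matter here:

* **Axis sectioning uses a common coordinate scale across dimensions**
  (the hypercubes are true cubes in the embedding space), the way a
  plotted, equal-aspect MDS configuration would be sectioned.
  Sectioning each axis over its own observed range was tried and
  rejected: MDS dimensions beyond the informative ones have near-zero
  eigenvalues and near-zero spread, and sectioning that spread into
  thirds shreds tight clusters along pure noise axes (planted-block
  recovery collapsed from an adjusted Rand index of 1.0 to 0.33 on the
  default synthetic world).  The per-dimension variant remains available
  via `scale = "per-dimension"`.
* **Determinism**: eigenvector sign is fixed by making each axis's
  largest-magnitude loading positive; boundary coordinates fall in the
  lower section (half-open sections, closed at the top).

Guild quality is assessed on two levels.  Pairwise association P values
come from a one-sided permutation test on the pmcc (sample labels
permuted independently per taxon; $p = (1 + \#\{r^* \ge r\}) / (1 +
n_{perm})$) — an in-package substitute for an external
negative-binomial GLM, chosen so the whole stack runs with no external
fitting machinery.  On top of that, `guildEnrichment()` asks whether a
guild contains more significant pairs than the false-discovery rate
would produce: $P(X \ge x)$ with $X \sim \mathrm{Bin}(m, p_0)$, where
$m$ is the number of member pairs tested ($k(k-1)/2$ for $k$ members —
the counted events are pairwise correlations; the member-count reading
can be had by passing $m = k$).  Guilds whose member pairs are all
significant at 5% are *simple*; the rest are *complex* and carry an
anchor taxon, the member with the most significant pairings.

A sample's guild profile is the fraction of its reads belonging to each
guild's taxa, with an explicit `unassigned` bucket so the profile sums
to one; reads of taxa excluded from clustering (zero variance) count as
unassigned.  The distance between two profiles is

$$\partial = \sqrt{\sum_{i=1}^{N} (p_{1i} - p_{2i})^2}$$

over guild coordinates only.  For proportion vectors this is bounded by
$\sqrt 2$ (attained by disjoint unit profiles), which is the bound the
package asserts — the looser "0 to 2" sometimes quoted for such scores
is not attainable here.

# Stratification and diffusion

Whether two adjacent samples carry distinct compositions is tested per
taxon from the Beta posteriors of the underlying proportions:
$\mathrm{Beta}(1 + c,\; t - c + 1)$ for count $c$ of total $t$ (a
uniform prior).  The "same underlying proportion" probability is the
overlap coefficient $\int_0^1 \min(f_1, f_2)\,d\theta$, computed exactly
from incomplete-Beta differences after locating the at most two density
crossings (the log-density difference is $c_0 + c_1\log\theta +
c_2\log(1-\theta)$).  A pair with summed reads above 50 is *stratified*
when any taxon's overlap falls below $\alpha = 0.05$ — evidence that
post-depositional processes have not homogenised the record.  No
multiple-testing correction is applied across taxa within a pair by
default (a Bonferroni switch is not provided; the raw-$\alpha$ behaviour
is the modelled procedure), and the calibration of the whole rule is
tested empirically: under a shared multinomial at depth 500 the flag
rate stays below $1.5\alpha$.

Diffusion is bounded, not estimated: under a one-parameter unidirectional
decay, a taxon at donor proportion $p_2$ observed at $p_1$ a distance
$x$ cm away implies

$$\lambda = -\log(p_1/p_2)\,/\,x,$$

with the donor chosen as the larger proportion so $\lambda \ge 0$.
Per-taxon $\lambda$ values mix real environmental change with any shared
diffusion, so the *highest* cluster of the $\lambda$ distribution (1-D
k-means on $\log\lambda$, $k \le 5$ by best silhouette; both choices
configurable) gives the fastest decay consistent with the data — the
minimum possible universal $\lambda$.  Applying it,

$$C_{diff} = e^{-\lambda x} \cdot p_2 \cdot s1_{total}$$

per taxon, summed and expressed as a percentage of the receiving
sample's reads (capped at 100), is the maximum share of the signal
explicable by diffusion alone.

# The sediment-influx depositional model

For each sediment type, two observables summarise adjacent-pair guild
distances: $\partial 1$, the mean over pairs where the sediment type
does not change, and $\partial 2$, the mean over pairs where it does (a
type-change pair contributes to both flanking types).  The model
predicts both from five parameters — local compositional proportion
$cl$ (with $cs = 1 - cl$), local change $\partial x_{loc}$,
inter-sediment guild difference $id$, and rate modifiers $e_1, e_2 \in
[-1, 1]$:

$$\partial 1_i = \partial x_{loc} + \frac{\partial x_{loc}}{cl}\, cs\,(1 + e_1),
\qquad
\partial 2_i = \partial x_{loc} + id \cdot cs\,(1 + e_2).$$

The first equation is the *fraction* reading of the influx term:
$\partial 1 = \partial x_{loc}$ when $cl = 1$ and apparent change
inflates as the local fraction shrinks, diverging as $cl \to 0$ (the
grid therefore starts at $cl = 0.01$).  A plain product reading
$\partial x_{loc} \cdot cl \cdot cs (1 + e_1)$ is available via
`eq7 = "product"`; the fraction form is the default because it matches
the narrative that heavy influx inflates apparent change.  Fit quality
is

$$\mathrm{fit} = (\partial 1_i - \partial 1)^2 + (\partial 2_i - \partial 2)^2
  + \left(\frac{\partial 2_i}{\partial 1_i} - \frac{\partial 2}{\partial 1}\right)^2,$$

with the ratio term dropped (and flagged) when either denominator is
zero.  The search is the modelled procedure exactly: chains start at
random on-grid $(e_1, e_2)$; for each visited pair the full inner grid
over $cl \in (0, 1]$, $\partial x_{loc}, id \in [0, 2]$ at step 0.01 —
$100 \times 201 \times 201 = 4{,}040{,}100$ points — is searched
exhaustively (vectorised in C++; results memoised so chain revisits are
free); a chain moves $e_1$ or $e_2$ one step at a time, reflecting at
$\pm 1$, accepts improvements, and stops after 20 consecutive
non-improving proposals; 1,000 chains by default, deterministic given
the seed.  Ties keep the first grid point visited ($cl$, then $\partial
x_{loc}$, then $id$, ascending).

**Identifiability** is partial and worth stating plainly: five
parameters face two observations, so the zero-fit set is a surface, and
the returned parameter values — in particular $cl$ — are pinned only by
grid quantisation except where the observations actively constrain them
($cl$ is forced below 1 only when $\partial 1 > \partial 2$, since
$\partial x_{loc} \le \partial 1_i$ and $\partial 2_i \ge \partial
x_{loc}$).  The package's guaranteed surface is therefore reproduction
of the observations: on synthetic fixtures the fitted model reproduces
$(\partial 1, \partial 2)$ within grid resolution, and independent
searches from different seeds agree on the best fit score to $10^{-6}$.
Recovering the *true* mixing proportion from $(\partial 1, \partial 2)$
alone should not be expected, and the test suite documents this
honestly rather than asserting it works.

Security classification combines the fitted $cl$ with sedimentology: a
sample is *secure* when its sediment type's fitted $cl \ge 0.85$ or it
is laminated clay/silt (lamination marking undisturbed deposition), and
*insecure* when fitted $cl \le 0.5$ or the sediment is coarse sand.
The thresholds sit between the reported bands for fine sediments
(roughly 89–98% local) and coarse ones (up to ~70% influxed), and are
arguments, not constants.

# Biodiversity series

Simpson's index $\lambda_s = \sum_i p_i^2$ per sample, diversity
$1/\lambda_s$ (the effective taxon count).  Only secure samples with a
numeric age and more than 50 reads enter.  Windows are 1,000 years wide
on 500-year centres spanning the eligible ages (inclusive membership,
$|age - centre| \le 500$), averaged separately for marine and
terrestrial samples; a sample is marine when the marine guild (seagrass
in the motivating system) holds the strictly largest share of its guild
profile, with a metadata domain label taking precedence when present.

# Clade-support SNP counting

The ancient-sequence placement works on a gap-concatenated alignment:
one ancient row assembled from reads separated by runs of five or more
gaps (the read blocks), plus reference rows.  A SNP site is a column
where the ancient row is covered and at least two states occur among
covered rows; the site's sharing set is the reference taxa matching the
ancient state, and a taxon's clade support is the number of sites it
shares *exclusively* with the ancient row.  The damage-filter chain
masks, in order: `clip` bases at both ends of every read block (terminal
deamination), singleton sites (ancient state shared by no reference — a
candidate base modification, not phylogenetic signal), sites where the
ancient state differs from the plurality reference state by a
transition (C↔T / G↔A, the deamination-confounded changes; plurality
ties are masked conservatively), and optionally sites with any missing
reference data.  Masking writes N into the ancient row, so masked
columns simply stop being sites; each stage's counts are reportable via
`cladeSupportByStage()`.

# The synthetic landscape

`simulateLandscape()` states a world in which every pipeline stage has
known truth.  Taxa fall into disjoint guild blocks whose archetype
compositions are Dirichlet draws; each core's local environment is a
temporally autocorrelated random walk over guild weights ($w_t \sim
\mathrm{Dirichlet}(\kappa w_{t-1} + 0.1)$); observed composition mixes
local and influx signals as $cl \cdot \mathrm{local} + (1 - cl) \cdot
\mathrm{influx}$ with $cl$ set by the sample's sediment class; optional
diffusion averages adjacent samples with weight $e^{-\lambda x}$;
counts are multinomial at the configured depth.  Defaults: 4 guild
blocks over 40 taxa, 6 cores × 10 samples, depth 5,000 reads, silt
($cl = 0.95$) over coarse sand ($cl = 0.4$) sequences, a linear age
model (6,000 cal BP at the surface, 15 y/cm), per-core seed substreams.

Two generator choices deserve their rationale:

* **Influx is the local environment lagged by a per-sample reworking
  age** drawn from $[3, 24]$ samples, not a fixed offset.  Reworked
  sediment arrives from parcels of varying age, so the influx signal is
  erratic between adjacent samples; with a fixed offset the influx's
  adjacent-sample change has exactly the local step magnitude and
  mixing *reduces* apparent change in influx-dominated strata —
  backwards from the depositional story the model encodes.
* **Walk concentration $\kappa = 60$** keeps the one-step guild-weight
  change under ~10% of the simplex scale: the local environment is
  genuinely autocorrelated at the sampling interval (gradual vegetation
  change over the ~150 years between samples), while leaving enough
  within-core variation for co-occurrence to be estimable from 60
  samples.  Much faster walks destroy the local/influx contrast; much
  slower ones starve the correlation estimate of effective samples.

What a green test on this world does establish: the clustering recovers
block-structured co-occurrence (adjusted Rand ≥ 0.8), the
stratification test is calibrated under a shared multinomial, decay
rates round-trip exactly without noise and to ~20% under multinomial
noise at depth 10,000, and the depositional fit reproduces its own
forward predictions.  What it does not establish: recovery of the true
$cl$ per sediment class (see identifiability above), realistic damage
patterns beyond terminal C→T/G→A toggles, read-level sequencing error,
or taxonomic misassignment structure.

`simulateAlignment()` plants exclusively-shared, transversion-derived
SNPs in interior block positions for chosen taxa, so planted counts
survive the full filter chain by construction; optional end-deamination
noise (ancient C→T at 5′ ends, G→A at 3′ ends within the clip margin)
exercises the clipping stage, which restores the planted counts
exactly.

# Degenerate inputs and numerical notes

Zero-variance taxa are excluded from correlation (logged) and counted as
unassigned; empty negative controls warn and change nothing; samples
with zero filtered reads are an error for profiles; Beta-overlap is
exact to well below $10^{-6}$ via incomplete-Beta differences; MDS axes
with non-positive eigenvalues are zero-filled with a warning; the
depositional grid excludes $cl = 0$ where the fraction reading is
undefined; λ estimation drops zero proportions (logged) and attaches
zero-decay values to the lowest cluster.

# Worked example

```{r example}
library(sedaTaph)

sim <- simulateLandscape(simConfig(seed = 42))
guilds <- buildGuilds(sim$se, nPerm = 199, seed = 43)
guilds

profiles <- guildProfiles(sim$se, guilds)
strat <- stratifyCores(sim$se)
fits <- fitDepositionModel(profiles, sim$truth$metadata, seed = 44,
                           nChains = 10)
fits[["silt"]]

security <- classifySecurity(sim$truth$metadata, fits)
table(security)

diversitySeries(sim$se)[1:5, ]
```
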