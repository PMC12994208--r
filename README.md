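# sedaTaph

Taphonomy-aware analysis of sedimentary ancient DNA (sedaDNA) taxonomic
profiles.

Shotgun-sequenced sediment cores yield taxon read-count profiles of past
landscapes, but each stratum mixes three signals: DNA from the local
contemporaneous environment, DNA arriving with influxing/reworked
sediment, and DNA redistributed after deposition by pore-water
diffusion. `sedaTaph` is for palaeoecologists who need to ask, before
interpreting a profile: *is this stratum's signal local and in place?*
It implements:

- **Count confidence and filtering** — per-taxon assignation P values
  `P = fpr^n` from the upstream classifier's false-positive rate
  (default fpr = 0.04), strict >2% negative-control removal, and
  native/rank scope subsetting.
- **Plant guilds** — groups of co-occurring taxa, built from the Pearson
  correlation of per-sample frequencies via the distance
  `d = 1 − (pmcc + 1)/2`, classical MDS into 10 dimensions, and
  hypercube clustering with a stability rule; validated by permutation
  pair tests and binomial enrichment `P(X ≥ x), X ~ Bin(m, p0)`.
- **Guild profiles and distances** — per-sample guild read proportions
  and the profile distance `∂ = sqrt(Σ_i (p1i − p2i)²) ≤ √2`.
- **Stratification test** — per-taxon overlap of Beta(1+c, t−c+1)
  posteriors between adjacent samples; any overlap < α marks the pair
  stratified.
- **Diffusion bound** — per-taxon decay rates `λ = −log(p1/p2)/x`, a
  universal λ from the highest 1-D cluster, and the maximum percentage
  of reads attributable to diffusion via `C_diff = e^{−λx}·p2·s1_total`.
- **Sediment-influx depositional model** — predicts the mean adjacent
  pair distances `∂1 = ∂xloc + (∂xloc/cl)·cs·(1+e1)` and
  `∂2 = ∂xloc + id·cs·(1+e2)`; fitted by Monte-Carlo chains over
  (e1, e2), each evaluating an exhaustive 100×201×201 ≈ 4.04 million
  point grid over (cl, ∂xloc, id); samples classified secure/insecure
  from fitted cl plus sedimentology.
- **Biodiversity series** — Simpson's `λ_s = Σ p_i²`, diversity 1/λ_s,
  1000-year windows at 500-year steps over secure dated samples, split
  marine/terrestrial.
- **Clade-support SNP counting** — on a gap-concatenated alignment with
  one ancient row: SNP sites, a damage filter chain (end clipping,
  singleton and transition masking, completeness), and per-taxon
  exclusively-shared SNP counts.
- **Synthetic landscapes** — a seeded generator with planted guild
  blocks, known local/influx mixing per sediment class, optional
  diffusion and ages, so every stage above is testable against ground
  truth.

## Worked example

```r
library(sedaTaph)

sim    <- simulateLandscape(simConfig(seed = 1))      # 40 taxa, 6 cores x 10 samples
guilds <- buildGuilds(sim$se, nPerm = 199, seed = 2)
guilds
#> GuildSet with 4 guilds over 40 taxa
#>   assigned taxa: 40  unassigned: 0
#>   types: 4 simple / 0 complex

profiles <- guildProfiles(sim$se, guilds)
strat    <- stratifyCores(sim$se)
fits     <- fitDepositionModel(profiles, sim$truth$metadata,
                               seed = 3, nChains = 10)
fits[["silt"]]
#> DepositionFit [silt]
#>   cl = 0.94  dxloc = 0.09  id = 0.36  e1 = 0.84  e2 = 0.94
#>   fit = 1.294e-08  predicted (d1, d2) = ( 0.1006 , 0.1319 )  observed = ( 0.1005 , 0.1319 )
#>   chains: 10  grid evaluations: 359,568,900
```

The numbers to read: the four planted guild blocks are recovered exactly
(adjusted Rand index 1.0 against truth), 49 of 54 adjacent pairs are
flagged stratified (the simulated environment drifts between samples),
and the fitted model reproduces the observed pair distances
(0.1005, 0.1319) to within grid resolution at fit ≈ 1.3e-08. The fitted
`cl` itself should be read with the identifiability caveat above.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the whole pipeline from scratch on the seeded synthetic
landscape — simulation, contamination/scope filtering, guild building
(with recovery scored against the planted truth), guild profiles,
stratification and diffusion scans, the depositional-model fits with
security classification, the diversity series, and filtered
clade-support counts on a simulated alignment — logging each stage's
summary to stderr and writing the target report to `--out`.
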