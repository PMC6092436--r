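# rarescape

Most bacterioplankton taxa are rare: in a coastal 16S rRNA survey a few
dozen OTUs typically hold more than half the reads while tens of thousands
of OTUs sit in the long tail. Whether those two ends of the abundance
spectrum are assembled by the same ecological processes — environmental
selection (niche) versus dispersal and drift (neutral) — is a central
question in microbial biogeography. `rarescape` implements the full analysis
chain used to ask it, for anyone with an OTU table, station coordinates, and
water-chemistry measurements.

## What it computes

**Abundant / rare partitioning.** An OTU is *abundant* when its relative
abundance reaches ≥ 1% in at least one sample **and** its regional mean
(average of local relative abundances across all samples, zeros included) is
≥ 0.1%; it is *rare* when it falls below 0.01% in at least one sample
**and** its regional mean is below 0.001%; the regional cutoffs are the local
ones divided by 10. Everything else is *intermediate*.

**Diversity and structure.** Observed richness, Chao1
(S<sub>obs</sub> + F₁(F₁−1)/(2(F₂+1))), ACE, Shannon H′ = −Σ pᵢ ln pᵢ,
Simpson 1−D, Pielou H′/ln S, Good's coverage 1 − F₁/N, analytic
(hypergeometric) rarefaction and species-accumulation curves; Bray–Curtis
dissimilarity on square-root abundances, NMDS, ANOSIM, Mann–Whitney
comparisons.

**Space vs environment.** Great-circle distances, distance-decay
(Spearman Mantel r plus decay slope), PCNM spatial eigenfunctions from the
truncated geographic distance matrix, Euclidean environmental distance on
log(x+1)-transformed, z-scored variables, Mantel and partial Mantel tests,
DCA gradient-length gating of RDA vs CCA, VIF (> 20) elimination,
permutation forward selection (P < 0.05), and two-component variation
partitioning on adjusted R²:

    E|S = adjR²(E∪S) − adjR²(S),  S|E = adjR²(E∪S) − adjR²(E),
    S∩E = adjR²(E) + adjR²(S) − adjR²(E∪S),  residual = 1 − adjR²(E∪S)

**Neutrality.** Sloan's neutral community model: a taxon with regional mean
relative abundance *p* is detected in a local community of size *N* with
probability 1 − BetaCDF(d; *Nm·p*, *Nm*(1−*p*)); `fit_ncm()` estimates *Nm*
(hence immigration *m = Nm/N*) by least squares on the occurrence-frequency
spectrum and reports the fit R².

**Ground truth.** A synthetic metacommunity generator places samples in bay
clusters along a coastline arc with environmental gradients partially
confounded with space and independent dials for niche strength and dispersal
limitation, so every statistic above can be exercised against known drivers.

## Worked example

```r
library(rarescape)

sim <- simulate_metacommunity(simulation_config(
  n_otus = 5000, n_samples = 22, depth = 12000, seed = 42))
cm  <- rarefy_even_depth(sim$counts, depth = 10000, seed = 1, prune_empty = TRUE)
ra  <- relative_abundance(cm)

cls <- classify_otus(ra, threshold_config())
partition_summary(cls, cm)
#> # A tibble: 3 × 5
#>   label        otu_n otu_pct  seq_n seq_pct
#> 1 abundant        70    2.18 131116    59.6
#> 2 intermediate  2157   67.0   87561    39.8
#> 3 rare           990   30.8    1323     0.6
```

Seventy OTUs (2%) hold 60% of the reads; a thousand rare OTUs hold 0.6%.

```r
bc  <- bray_curtis(ra, transform = "sqrt")
geo <- haversine_matrix(sim$metadata)
distance_decay(bc, geo, method = "spearman", n_perm = 999, seed = 2)
#> Distance-decay: Mantel r = 0.769 (p = 0.001), slope = 0.000436 per km
anosim_test(bc, sim$metadata$bay, n_perm = 999, seed = 3)
#> ANOSIM: R = 0.801, p = 0.001 (999 permutations, 3 groups)
```

Communities grow apart with distance and the three bays separate strongly.

```r
comm <- transform_community(cm, "hellinger")
dca_gradient_length(comm)
#> DCA axis lengths: 2.71, 2.06, 0.99, 1.00 SD; longest 2.71 -> rda

env <- prepare_env_predictors(sim$metadata)
sel <- forward_select(comm, env, method = "rda", alpha = 0.05,
                      n_perm = 199, seed = 4)
pc  <- pcnm_basis(geo)
variation_partition(comm, env[, sel$selected, drop = FALSE], pc$vectors,
                    n_perm = 999, seed = 5)
#> Variation partitioning (rda, adjusted R2):
#>   pure env (E|S)       11.5%  (p = 0.001)
#>   pure spatial (S|E)   28.4%  (p = 0.001)
#>   shared (S n E)       27.2%
#>   residual             32.9%

fit_ncm(cm)
#> Sloan neutral community model fit:
#>   Nm = 4170.4  (m = 0.417, N = 10000.0)
#>   R2 = 0.791 on 3217 OTUs x 22 samples (detection limit 6.93e-05)
```

The partition says both selection (11.5% pure environmental) and spatial
processes (28.4% pure spatial, with 27.2% spatially structured environment)
shape this community — as they should, since the generator ran with both
dials on — and the occurrence-frequency spectrum is well described by the
neutral model (R² = 0.79) with an immigration estimate `m` of 0.42.

Every result object has `tidy()` / `glance()` methods and an `autoplot()`
(NMDS maps, distance-decay scatter, variation-partition bars, NCM frequency
spectrum). `run_full_analysis()` chains all stages — rarefy, classify, and
then diversity, ordination, distance-decay, forward selection, variation
partitioning, and Mantel tests for each of the all/abundant/rare levels,
plus one neutral-model fit — and writes every table as TSV.

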