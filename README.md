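# subcomm

Microbial communities are not monoliths: most OTUs (operational taxonomic
units) drift between rarity and abundance as conditions change, and these
*transient* taxa — not the handful of always-abundant ones — often carry the
community's response to environmental change. `subcomm` dissects soil (or any
amplicon-derived) OTU count tables into abundance-based subcommunities and
asks, for each of them, whether **deterministic** processes (environmental
filtering along soil gradients) or **stochastic** processes (dispersal and
drift) assemble it. It is written for microbial ecologists working with
rarefied OTU tables from multi-site surveys — bacteria, fungi, protists —
with matching site metadata (coordinates, land use, soil chemistry).

## What it computes

**Six-category classification.** With relative abundance cutoffs
*t<sub>r</sub>* (rare, default 0.01%) and *t<sub>a</sub>* (abundant, default
1%), an OTU's min/max relative abundance across samples puts it in exactly
one of: AAT (always abundant, min ≥ *t<sub>a</sub>*), RT (always rare,
max ≤ *t<sub>r</sub>*), MT (moderate, strictly between the cutoffs
everywhere), CRT (conditionally rare: rare somewhere, never abundant), CAT
(conditionally abundant: abundant somewhere, never rare), and CRAT (rare in
some samples, abundant in others).

**Distance decay.** Bray–Curtis dissimilarity
*d<sub>jk</sub>* = Σ|x<sub>j</sub> − x<sub>k</sub>| / Σ(x<sub>j</sub> + x<sub>k</sub>)
per subcommunity, regressed and Mantel-tested (Spearman, 999 permutations)
against standardized Euclidean environmental distance; ANOSIM across
land-use groups.

**Spatial structure and variation partitioning.** PCNM spatial eigenvectors
(principal coordinates of the MST-truncated geographic distance matrix),
forward selection of soil and spatial predictors with Blanchet's double
stopping rule, and redundancy analysis (RDA) on Hellinger-transformed
tables, partitioned into adjusted-R² fractions: *a* (environment only),
*b* (shared), *c* (space only), *d* (residual), with *a + b + c + d* = 1.

**Sloan's neutral community model.** For each OTU with mean relative
abundance *p*, the expected occurrence frequency across samples is

> F̂(p) = 1 − I<sub>d</sub>(Nm·p, Nm·(1 − p)),

the tail of a Beta distribution above the one-read detection limit
*d* = 1/N. The immigration rate *m* is fitted by bounded nonlinear least
squares; the fit quality is the generalized R² = 1 − SSE/SST (negative when
neutrality predicts worse than the mean), with a 95% Wilson envelope
classifying each OTU as above / within / below the neutral expectation.

**Simulators.** A beta-field neutral generator (each sample a census of N
individuals with Beta(Nm·p, Nm·(1−p)) local relative abundances, so
occupancy sits exactly on the Sloan curve of the generating Nm) and a
Gaussian-niche generator (OTU optima along spatially autocorrelated or
measured environmental gradients), plus a survey-design metadata generator
(46 sites, 7 land-use types with unequal replicates by default). These let
every stage be validated by parameter recovery.

## Worked example

```r
library(subcomm)

tab  <- simulate_neutral(n_samples = 46, n_otus = 2000, depth = 10000,
                         m = 0.1, seed = 1)
part <- classify_taxa(tab)
partition_summary(part, tab)
#>   category n_otus pct_otus n_reads pct_reads
#> 1      AAT      5     0.25  132348  28.77130
#> 2      CAT     30     1.50   97241  21.13935
#> 3       MT     58     2.90   76865  16.70978
#> 4      CRT   1511    75.55  152555  33.16413
#> 5     CRAT      1     0.05     958   0.20826
#> 6      RT     395    19.75      33   0.00717

crt <- subset_by_category(tab, part, "CRT")
fit_ncm(crt, require_even_depth = FALSE)
#> Sloan NCM fit: m = 0.103, Nm = 341.7, R2 = 0.964 (N = 3316, 1511 OTUs, 46 samples)
#>  above within  below
#>     34   1407     70
```

Conditionally rare taxa dominate the OTU pool (75.6% of OTUs, 33.2% of
reads), and their occupancy–abundance relation fits the neutral curve
(R² = 0.96): within the CRT subcommunity, presence/absence across sites is
what dispersal plus drift would produce at an immigration rate of about 0.10
(Nm ≈ 342 at the subcommunity's mean depth of 3,316 reads).

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on synthetic
three-domain data (a neutral "bacteria" domain, an environment-filtered
"fungi" domain, a weakly connected "protists" domain):

```sh
Rscript analysis/01_simulate_communities.R     # data -> scratch/sim_data/
Rscript analysis/02_classify_subcommunities.R  # -> results/partition_summary.tsv
Rscript analysis/03_distance_decay.R           # -> results/distance_decay.tsv
Rscript analysis/04_variation_partitioning.R   # -> results/vpa.tsv, selected_variables.tsv
Rscript analysis/05_neutral_model.R            # -> results/ncm.tsv
```

`run_pipeline()` wraps the same stages behind a single YAML-configurable
call with per-stage seeds and a JSON report.

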