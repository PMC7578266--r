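# kinomeSR

Reliability scoring, differential phosphorylation and surface similarity
for peptide-array kinome profiles.

## The problem

Tyrosine-kinase peptide microarrays (PamChip-style: 144 consensus peptide
substrates, three technical replicates, fluorescence read-out) profile the
kinase activity of cell lysates. A common application is ranking candidate
biomaterials — e.g. machined vs. surface-modified titanium implants — by
the kinome response of mesenchymal stem cells adhering to them. The raw
data are noisy: background subtraction can push weak spots below zero, and
replicate scatter varies strongly from spot to spot. `kinomeSR` implements
the full desk-side analysis chain for such experiments:

1. **Ingest** — read layout and replicate intensities, drop the internal
   control peptide, floor negative signals to zero.
2. **Spot reliability (SR)** — per spot and group, compute
   `P1 = sd/A` (coefficient of variation) and `P2 = A/M` (mean/median
   skew), where `A`, `M`, `sd` are the replicate mean, median and sample
   standard deviation. Band each parameter High (`P1 < 0.2`;
   `0.8 < P2 < 1.2`), Medium (`P1 < 0.5`; `0.7 < P2 < 1.4`) or Low, and
   combine the two levels into an integer score `SR ∈ {1..6}`
   (High/High → 6, Low/Low → 1, symmetric in its arguments).
3. **Differential phosphorylation** — for a test vs. control surface,
   keep the spots with the same SR level in both groups, quantile
   normalize their replicate columns jointly, then per spot a two-sided
   pooled-variance Student's *t*-test (default α = 0.05, raw p-values)
   and fold change `FC = mean(test)/mean(control)`.
4. **Surface similarity** — the χ statistic over the N common spots,

   χ² = (1/N) Σᵢ [ (I₀[i] − Iₜ[i]) / (1 − |σ₀[i] − σₜ[i]|) ]²,

   with I and σ the per-spot mean and sd of normalized intensities in the
   model (0) and test (t) group; χ = √χ² is reported (0 = identical
   response, larger = more dissimilar). Profiles are rescaled to [0, 1]
   by the pair's maximum so the denominator stays positive.
5. **Network comparison** — undirected protein–protein interaction
   networks built from edge lists (STRING-export style) plus
   kinase→substrate-site predictions (NetworKIN-output style): degree,
   betweenness and closeness centralities, top-decile node sets, and
   Venn-style cross-surface comparisons.

A synthetic chip generator (`generate_dataset()`) with known ground truth
(quality classes, fold effects, negative-background events) makes every
stage testable without any external download.

## Worked example

A small bundled synthetic fixture (three surfaces `Maq`, `DAA`, `nanoHA`;
40 spots; four spots down-regulated ×0.5 in `DAA`):

```r
library(kinomeSR)
lay <- read_layout(system.file("extdata", "synthetic_layout.tsv", package = "kinomeSR"))
ds  <- read_intensities(system.file("extdata", "synthetic_intensities.tsv",
                                    package = "kinomeSR"), lay)
ds  <- floor_negatives(exclude_control(ds, lay$spot_id[1]))

sr_histogram(score_dataset(ds, "Maq"))
#>  1  2  3  4  5  6
#>  0  2  1  0  2 34

rec <- differential_analysis(ds, test = "DAA", control = "Maq", sr_level = 6)
rec[rec$direction != "ns", c("spot_id", "p_value", "fold_change", "direction")]
#>           spot_id      p_value fold_change direction
#> 1  SYN002_402_414 0.0028343345   0.6260182      down
#> 2  SYN003_221_233 0.0002628231   0.5380705      down
#> 15 SYN021_691_703 0.0005436213   1.3452848      up
#> 24 SYN032_205_217 0.0047944679   1.1215285      up

volcano_table(rec)$counts
#>   up down
#>    2    2

pairwise_similarity(ds, sr_level = 6)
#> chi similarity at SR = 6
#>          DAA   Maq nanoHA
#> DAA    0.000 0.027  0.012
#> Maq    0.027 0.000  0.020
#> nanoHA 0.012 0.020  0.000
```

Reading the output: 34 of the 39 analyte spots are maximally reliable
(SR 6) on the control surface. Two of the four injected down-effects are
recovered at SR 6 (`SYN002`, `SYN003`, FC ≈ 0.5–0.6); one injected spot
was generated in a noisier quality class and is excluded by SR-6
selection, one falls short of significance. The two modest "up" calls are
compensation from forcing equal column distributions during joint
quantile normalization — see the methods vignette for when that matters.
The χ matrix says `DAA` and `nanoHA` respond more similarly to each other
(χ = 0.012) than either does to the control `Maq`.

One-command version, writing all report files plus a JSON manifest:

```r
cfg <- run_config(control_group = "Maq", test_groups = c("DAA", "nanoHA"),
                  sr_level = 6, alpha = 0.05,
                  control_peptide_id = lay$spot_id[1], output_dir = "report")
run_pipeline(cfg, dataset = ds)
```

A thin CLI wrapper lives at `inst/cli/kinomesr.R`
(`Rscript kinomesr.R synth|run ...`).

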