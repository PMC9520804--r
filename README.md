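# telarch

Three-dimensional nuclear telomere architecture profiling for chronic
myeloid leukemia (CML) phase discrimination.

In CML, progression from the chronic to the accelerated/blast phase is
accompanied by rising genomic instability. `telarch` implements three
quantitative readouts of that transformation, for researchers working
with 3D Q-FISH imaging and molecular markers of disease progression:

- **3D telomere architecture**: per-nucleus profiles of CD34+ interphase
  nuclei from multi-channel 3D image stacks (DAPI nucleus, Cy3 telomere
  probe, FITC CD34) — telomere signal counts, integrated intensities
  (telomere-length proxy), telomere aggregates (clusters too close to
  resolve optically), the a/c shape ratio of the telomere cloud, nuclear
  volume, and radial signal positions — plus cohort comparison by nested
  factorial ANOVA (phase fixed, patient random within phase, nuclei as
  replicates) and chi-square tests on intensity distributions.
- **Aurora kinase expression**: comparative-Ct relative quantification,
  `fold = 2^-ddCt` with `ddCt = dCt(patient) - mean dCt(healthy donors)`
  against a GAPDH reference, with one-way ANOVA and Bonferroni
  post-tests across healthy / chronic / blast groups.
- **Cytogenetics**: a simplified ISCN karyotype parser detecting the
  Philadelphia translocation t(9;22)(q34;q11.2) and counting additional
  chromosomal abnormalities acquired between phases.

Because no real image stacks are publicly available for this design, the
package ships a first-class synthetic-data generator that renders 3D
nuclei with known ground truth (spot positions, intensity mixture of
short/intermediate/long telomere populations, aggregate structure,
nuclear geometry) at the study's acquisition geometry (102 nm lateral /
200 nm axial sampling, 60 z-slices). The whole measurement chain is
validated against that ground truth and against independent statistical
oracles. See the methods vignette
(`vignettes/telomere-architecture.Rmd`) for the models and the reasoning
behind every tunable parameter.

## Worked example

A reduced end-to-end run (3 patients × 5 nuclei per phase; the study
conditions are 18 × 30):

```r
library(telarch)
demo <- run_study_demo(seed = 1, n_patients = 3, n_nuclei_per_sample = 5)
demo$telomere_comparison
#> Cohort comparison: chronic vs accelerated_blast
#>   n_telomeres              39.400 +/-   5.853  vs   41.533 +/-   4.838   p = 0.00132
#>   n_aggregates              3.400 +/-   1.121  vs    4.667 +/-   0.900   p = 0.00621
#>   total_intensity        4627.250 +/- 627.355  vs 6078.537 +/- 679.412   p = 0.00124
#>   mean_signal_intensity   117.858 +/-   7.116  vs  146.625 +/-   7.639   p = 0.00206
#>   ac_ratio                  2.563 +/-   0.309  vs    7.214 +/-   0.931   p = 0.000117
#>   nuclear_volume          196.510 +/-  43.991  vs  338.052 +/-  77.543   p = 0.00909
#>   signal intensity distribution: chi-square = 242.1 (df 9), p = 4.55e-47
#>   (no multiple-testing correction across parameters)
```

Each line is one of the six telomere parameters: the per-phase mean ± SD
across nuclei and the nested-ANOVA p-value for the phase effect (at this
reduced size the p-values are modest; at the full 18 × 30 design all six
parameters separate at p < 0.001). The aurora kinase module reports
group mean fold changes relative to healthy donors:

```r
glance(demo$qpcr$AURKA$result)
#> # A tibble: 3 × 5
#>   group             gene      n mean_fold sd_fold
#>   <chr>             <chr> <int>     <dbl>   <dbl>
#> 1 accelerated_blast AURKA     8      4.09   0.237
#> 2 chronic           AURKA     8      2.79   0.172
#> 3 healthy           AURKA     8      1.01   0.128
demo$cytogenetics$n_ph_negative_blast
#> [1] 3
```

so AURKA is ~2.8-fold over-expressed in chronic phase and ~4.1-fold in
blast phase relative to healthy donors, and 3 of the 18 blast-phase
karyotypes in the packaged cytogenetic table lack the Philadelphia
chromosome. `autoplot()` methods produce the matching figures for
comparisons, expression results and intensity partitions. A thin command
line wrapper for the pipeline stages
(`simulate | quantify | compare | qpcr | karyotype | demo`) is installed
at `inst/scripts/telarch`.

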