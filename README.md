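# ribotrace

Quantitative profiling of bacterial ribosome biogenesis from
cold-sensitivity screens and stable-isotope proteomics.

Defects in ribosome assembly make bacteria preferentially sick in the
cold, which turns cold sensitivity into a genome- and library-wide
enrichment strategy for assembly genes and assembly-targeting small
molecules. ribotrace implements, as tested reusable R functions, the
statistics such a campaign needs:

* **Screen statistics** — cold-sensitivity factors
  `CSF = mean OD600(37 °C) / mean OD600(15 °C)`, normalized to a
  collection mean of 1; top-fraction hit calling; the 3σ/2σ
  two-temperature compound gate; plate-median normalization;
  permutation tests for functional-class (COG) enrichment with the
  add-one p-value estimator `(1 + #[null ≥ obs]) / (1 + n_perm)`;
  MIC calling (>95 % inhibition) with explicit right-censoring; binding
  normalization to a baseline flow-through.
* **Isotopologue model** — CHNOS peptide compositions, isotope
  distributions at arbitrary ¹⁵N enrichment by element-wise
  convolution, m/z stick templates per charge state.
* **Spectral deconvolution** — non-negative least squares
  `argmin_{a ≥ 0} ‖I_obs − Σ_s a_s T_s‖²` matching observed peaks to
  template positions at ppm tolerance, with r²-based interference
  filtering.
* **Occupancy profiling** — reference-standard correction
  (light/heavy ratio minus the reference-only triplicate mean),
  occupancy `c/(c+1)`, loading correction, median-over-peptides
  protein × fraction matrices scaled to per-protein unit maximum, and
  spectral-count factor profiles with 3-tap Gaussian smoothing.
* **Pulse-labeling synthesis rates** — three-species (0 %/50 %/100 %
  ¹⁵N) ratios, OLS slopes of median post-pulse synthesis over the
  0/4/8/16 h time points, per-protein normalization to the DMSO
  control with log₂ transform, and notched box-plot summaries
  (notch = 1.57 × IQR/√n).
* **rRNA processing** — capillary-electrophoresis peak assignment to
  mature/+115 (16S) and mature/+3/+7 (23S) 5′ species, and
  immature-over-total proportions per primer.
* **Synthetic data** — generators for every input above with planted
  ground truth and one-seed determinism, so the whole pipeline is
  testable offline; with zero noise every estimator returns its
  planted parameters to machine precision.

The methods vignette (`vignettes/ribotrace-methods.Rmd`) documents the
models, defaults and design decisions in detail.

## Worked example

Simulate a 1000-strain deletion screen with 30 planted cold-sensitive
strains (15 °C growth reduced to 25 %), call the top 3.5 %, and test
enrichment of the translation class:

```r
library(ribotrace)

sim <- gen_screen_data(screen_sim_config(
  n_items = 1000, n_planted_coldsensitive = 30,
  planted_effect = 0.25, seed = 42))
csf <- select_top_fraction(compute_csf_table(sim$growth), 0.035)
head(csf, 3)
#>      item_id csf_raw csf_norm rank is_hit undefined_csf
#> 1 item_00712    6.63     4.84    1   TRUE         FALSE
#> 2 item_00332    6.56     4.79    2   TRUE         FALSE
#> 3 item_00420    6.32     4.62    3   TRUE         FALSE
```

The planted strains grow ~4-fold worse in the cold than the collection
(csf_norm ≈ 4.8 against a mean of 1), and all 30 land in the 35-strain
hit set (`round(0.035 × 1000) = 35`). With the planted strains assigned
to the translation class:

```r
map <- data.frame(gene_id = sim$growth$item_id,
                  cog_class = rep(c("translation", paste0("class_", 1:9)),
                                  length.out = 1000))
map$cog_class[map$gene_id %in% sim$truth$item_id] <- "translation"
cog_permutation_enrichment(csf$item_id[csf$is_hit], map, "translation",
                           n_perm = 1e5, seed = 42)
#>    class_name n_hits_in_class n_total_in_class proportion p_perm n_permutations
#> 1 translation              30              125       0.24  1e-05          1e+05
```

24 % of the translation class is cold-sensitive and no permutation
reaches the observed proportion, so p bottoms out at the estimator's
floor `1/(1 + n_perm) = 10⁻⁵`.

A noiseless two-species isotope envelope (10 pmol natural + 30 pmol
¹⁵N-labeled) deconvolves exactly:

```r
tmpl <- species_templates("ELVISLIVESK", 2, c(0, 0.99))
peaks <- data.frame(
  mz = c(tmpl[[1]]$mz, tmpl[[2]]$mz),
  intensity = c(10 * tmpl[[1]]$probability, 30 * tmpl[[2]]$probability))
fit_species_mixture(aggregate(intensity ~ mz, peaks, sum), tmpl)
#> Spectrum fit: ELVISLIVESK 2+ [ok]
#>   amplitudes: enr_0=10, enr_0.99=30
#>   r2 = 1.0000 over 25 matched isotopologues; filter passed
```

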