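---
title: "Methods: quantitative profiling of bacterial ribosome biogenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative profiling of bacterial ribosome biogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribotrace)
```

## Scope

ribotrace implements the statistics used to dissect bacterial ribosome
biogenesis by chemical-genetic means: two-temperature growth screens
that exploit the cold sensitivity of assembly defects, quantitative
stable-isotope mass spectrometry of ribosomal-protein (r-protein)
occupancy on gradient-separated particles, ¹⁵N pulse-labeling estimates
of per-protein synthesis rates, and 5′ primer-extension quantitation of
rRNA maturation. Each stage is a pure function over plain tables, and a
synthetic-data generator with planted ground truth exercises every stage
end to end.

## Cold-sensitivity screening

A strain's (or compound-treated culture's) **cold-sensitivity factor**
is the ratio of its mean growth (OD~600~) at 37 °C to its mean growth at
15 °C; replicates are combined by the arithmetic mean. Factors are
normalized so that their mean over the whole collection equals 1
(`compute_csf_table()`), making screens comparable regardless of
absolute growth; the normalization identity `mean(csf_norm) == 1` is an
exact invariant, tested to 10⁻¹². Items with zero 15 °C growth have an
undefined ratio; they are flagged, excluded from the normalization mean
and reported separately rather than silently dropped.

Hit selection takes the top fraction of the ranked table
(`select_top_fraction()`), with `k = round(fraction × N)` rounded half
away from zero (base R's `round()` rounds half to even, which would make
the cut size depend on parity). Boundary ties are resolved by the
stable input order.

For compound libraries, each OD is first divided by its plate median
(`normalize_plates()`), a robust, scale-free correction for
plate-to-plate variation. The hit gate (`compound_hit_gate()`) selects
compounds more than 3 population standard deviations below the screen
mean at 15 °C while staying within 2 standard deviations of the mean at
37 °C — cold-specific inhibition rather than general toxicity. The
means and deviations are computed once over all screened compounds, with
no iterative re-estimation after hit removal.

**Functional-class enrichment** among hits is assessed by permutation
(`cog_permutation_enrichment()`): the statistic is the proportion of a
functional class (e.g. a COG category) that are hits, and the null is
generated by permuting the class-label assignment over all items with
the hit set fixed. Under such a permutation the number of hits landing
in a class of size *k* is exactly hypergeometric, so the null is sampled
directly from that distribution; a test verifies the equivalence against
explicit exhaustive label enumeration on small instances. The p-value
uses the add-one estimator `(1 + #[null ≥ obs]) / (1 + n_perm)`, which
is never zero and super-uniform under the null; resolving p below a
given level requires `n_perm` beyond its reciprocal (e.g. ≥10⁶
permutations to report p < 10⁻⁶).

**MIC calling** (`mic_from_dose_response()`) returns the lowest tested
concentration inhibiting growth by more than 95 % of the untreated
control. When no tested concentration achieves that, the MIC is
right-censored at the highest concentration and carried symbolically;
fold shifts computed from a censored bound (`mic_fold_shift()`) are
flagged as lower bounds ("≥" semantics) rather than silently treated as
exact.

## Isotopologue model and spectral deconvolution

The quantitation chain rests on a forward model of the MS1 isotope
envelope. A peptide's elemental composition over C, H, N, O, S is the
sum of residue formulas plus one water (`peptide_composition()`); the
isotopologue distribution is the convolution of per-element single-atom
isotope distributions (`isotopologue_distribution()`), computed by
binary-exponentiation convolution powers and verified against naive
atom-by-atom polynomial expansion to 10⁻¹⁰. ¹⁵N labeling replaces the
natural nitrogen distribution with `(1 − p, p)` at enrichment *p*;
enrichment only redistributes probability toward higher neutron shifts,
and the mean shift is strictly increasing in *p*. Templates
(`isotope_template()`) place sticks at
`(M + k·Δ + z·m_p)/z` with Δ = 1.00286864 Da, an average ¹³C/¹⁵N
spacing adequate for matching at ppm tolerances; sticks in the smallest
10⁻¹⁰ of cumulative probability are pruned.

Numerical defaults worth knowing: natural abundances are the standard
IUPAC/NIST values, hard-coded; the "100 % ¹⁵N" species defaults to an
enrichment of 0.99 because labeled media are never fully enriched, and
the "50 %" species to exactly 0.50 (twofold dilution into labeled
media); both are configurable wherever they appear.

`fit_species_mixture()` decomposes an observed stick spectrum into
non-negative species amplitudes by least squares
(Lawson–Hanson active-set NNLS via `pracma::lsqnonneg`). Observed peaks
are assigned to the nearest predicted position within a 10 ppm tolerance
(ties to the lower m/z; co-assigned peaks are summed); predicted
positions with no matching peak enter the fit as zeros, so an absent
species is estimated as absent instead of being ignored. Fit quality is
the centered coefficient of determination over matched positions, and a
fit passes the interference filter when r² ≥ 0.9 with at least 3 matched
isotopologues (`filter_interference()`); all three thresholds are
configurable, documented defaults — the filter's existence is part of
the method, its exact cutoff is not prescribed. A co-eluting
contaminant must be sizable relative to the envelope to trip the 0.9
default: a stick carrying ~30 % of the total envelope intensity drives
r² to ≈0.7 and is rejected, whereas a 30 % distortion of a single minor
stick is within what the default tolerates.

Occupancy experiments fit two species (natural and ~100 % ¹⁵N); pulse
experiments fit three (0 %, 50 %, ~100 %).

## Occupancy matrices

Every gradient fraction receives a fixed spike of a mixed reference
standard: 10 pmol natural-abundance plus 30 pmol ¹⁵N-labeled 70S
ribosomes, so each peptide has a labeled partner regardless of its
abundance in the sample. Quantitation proceeds as:

1. per-spectrum normalization `r = A_light / A_heavy`;
2. subtraction of the reference's own light contribution, measured by
   running the reference alone in triplicate
   (`reference_ratios()`, `normalize_to_reference()`); negative
   corrected ratios — noise overshoot of the subtraction — are clipped
   to zero and counted;
3. occupancy per measurement `c / (c + 1)`, the light fraction of total
   material with the heavy reference as unit scale. Composing the
   occupancy definition (light over total) with the per-spectrum heavy
   normalization fixes the heavy species at 1; this composition is the
   single biggest interpretive decision in the package and is what
   makes a corrected ratio of 1 correspond to occupancy 0.5;
4. correction for the amount of sample analyzed, dividing by
   `loading / nominal` (nominal 20 pmol);
5. the median over peptide-charge measurements per protein and fraction
   (each charge state is an independent measurement), then per-protein
   scaling to its maximum across fractions
   (`protein_occupancy_matrix()`).

Fits from two instruments covering the same peptide/charge/fraction key
are merged keeping the higher-r² fit (`merge_datasets()`), with
provenance retained.

Non-ribosomal biogenesis factors are profiled label-free from spectral
counts (`factor_profile()`): counts are normalized to the fraction
total, scaled to unit maximum, and smoothed with a 3-tap discrete
Gaussian (0.25, 0.5, 0.25 — a σ ≈ 0.7-fraction kernel), renormalized
over available taps at the edges so the smoother preserves constants
everywhere. Fractions are indexed 1-based from the gradient top, so
"earlier in the gradient" always means a lower index.

## Pulse-labeling synthesis rates

Cultures are diluted twofold into ¹⁵N media at time zero, so material
synthesized after the pulse carries ~50 % ¹⁵N while pre-existing
material stays at natural abundance and the spiked reference is fully
labeled. After the three-species fit, each species is normalized to the
reference (`species_ratios()`): pre-pulse `A₀/A₁₀₀`, post-pulse
`A₅₀/A₁₀₀`, and total `(A₀+A₅₀)/A₁₀₀`, with `total = pre + post` an
algebraic identity that the tests assert. Measurements with zero
reference amplitude are excluded and logged.

The synthesis rate is the free-intercept ordinary-least-squares slope of
the median post-pulse ratio against time over the 0, 4, 8 and 16 h time
points (`synthesis_rate()`). The 1 h and 2.6 h samples are ingested but
deliberately excluded from the fit — they sit in the label-equilibration
regime; at least 3 of the four rate time points are required, otherwise
the protein is flagged instead of fitted. Treatment rates are divided
by the matching vehicle (DMSO) rate per protein and log₂-transformed
(`normalize_rates()`); non-positive treatment slopes cannot be
log-transformed and are reported as censored, never silently dropped or
transformed.

Box-plot summaries (`box_summary()`) use linear-interpolation (type 7)
quartiles, whiskers at the most extreme points within 1.5 × IQR of the
quartiles, outliers beyond the whiskers, and a notch half-width of
1.57 × IQR / √n.

## rRNA processing

5′ primer extension converts each rRNA 5′ state into a cDNA fragment
length: mature 16S at the primer's own distance, its precursor extended
by 115 nt (the only immature 16S 5′ end this assay observes — the
transient 49 nt RNase E intermediate is not detectable by primer
extension and is deliberately absent from the default table); mature
23S plus +3 and +7 precursors. `assign_species()` bins
capillary-electrophoresis peaks into ±1 nt windows (single-nucleotide
CE resolution) around each expected size; windows must not overlap, and
off-window peaks are reported rather than discarded silently.
`immature_proportion()` is immature over total fluorescence per primer;
16S and 23S come from separate reactions and are never pooled into one
proportion. The proportion is exactly invariant under rescaling of all
fluorescence values. The absolute fragment sizes in the default table
are nominal primer positions; only the extension offsets (+115, +3, +7)
identify species.

## The synthetic-data generator

The generators emulate the structure of each experiment with planted
ground truth:

* **Screens** (`gen_screen_data()`): items across plates with additive
  per-plate offsets (default SD 0.03 OD) and replicate noise (default
  SD 0.03 OD), baseline OD 0.9 at 37 °C and 0.7 at 15 °C — saturated
  growth in rich media, somewhat lower in the cold; planted
  cold-sensitive items have their true 15 °C growth multiplied by the
  planted effect.
* **Gradient spectra** (`gen_spectra()`): every tryptic peptide
  (cleave after K/R except before P, lengths 6–30 — the standard
  convention, as the quantified peptide set is not prescribed) at
  charges 2–3, as amplitude-weighted sums of species templates with
  multiplicative log-normal stick noise. Planted occupancies follow
  logistic curves over fraction index (early binders shifted left),
  capped at 0.95 since occupancy 1 would require unbounded experimental
  material. The generator plants the *final* occupancy value and
  inverts the quantitation chain to choose amplitudes, so with all
  noise at zero the full pipeline returns planted values to machine
  precision — the noise-free closure property.
* **Pulse series** (`gen_pulse_experiment()`): pre-pulse amplitude
  decaying as `exp(−δt)`, post-pulse accumulating as `σ·t` (early
  linear regime), reference constant. Noise is multiplicative
  log-normal on the reference-normalized pre/post amplitudes: the
  reference spike defines each spectrum's unit scale, and common-mode
  intensity variation (injection amount, ionization efficiency) cancels
  in the within-spectrum normalization, so placing independent noise on
  all three species would double-count ratio error. Six peptide
  measurements per protein is the default multiplicity, a typical count
  of quantifiable tryptic peptides for an r-protein and the level of
  averaging at which the median-then-fit estimator keeps every one of
  200 simulated proteins within 10 % of its planted rate at 5 % CV.
* **CE tables** (`gen_ce_tables()`): one peak per species at its
  assignment size with multiplicative fluorescence noise, and the
  planted per-primer immature proportion recorded. At 5 % CV a single
  two-peak run has a proportion SD near 0.017, so recovery is assessed
  on the typical (median-over-runs) error.

All randomness descends from one integer seed per configuration;
sub-generators derive independent child streams from the stage name, so
identical configurations are bit-reproducible and adding a stage never
perturbs another's draws. Multiplicative log-normal noise (unit mean,
given CV) reflects intensity-proportional instrument error.

What the generator does **not** emulate: chromatographic elution and
profile-mode peak shapes (stick spectra are the contract), retention-time
drift, detector saturation, peptide-specific ionization efficiency,
missing peptides, and real biological replicate structure. Passing
recovery tests therefore demonstrates the correctness of the estimators
under the stated noise model, not robustness to every artifact of real
instruments.

## Problem sizes and numerical choices

The shipped tests run the property suites at these sizes: polynomial-
expansion cross-checks on peptides up to ~165 atoms (tolerance 10⁻¹⁰);
exhaustive NNLS grid oracles on 2- and 3-species toys; 10⁴ null screens
for p-value super-uniformity; 200 proteins for synthesis-rate recovery;
3 proteins × 6 fractions × 2 charges for occupancy recovery; and ≥100
peptides at 1 % CV for the reference-standard benchmark, which recovers
the 10 pmol light component from the 10:30 pmol mixed standard within
2 % (the quantity `scripts/acceptance.R` recomputes). Degenerate inputs
are handled explicitly rather than by convention: zero 15 °C growth,
zero reference amplitudes, all-zero factor-count profiles, empty fit
tables and censored MICs each have a defined, flagged pathway.

## Known limitations

* Occupancy composition `c/(c+1)` assumes the heavy reference is the
  unit scale; if the spike amount varied across fractions beyond the
  declared loading values, occupancies would be bias-scaled.
* The permutation test treats items as exchangeable; genuine
  plate-level correlation among hits would make it anticonservative.
* The interference filter is a quality threshold, not a deconvolution:
  a contaminant that mimics the envelope shape passes.
* Censored MICs depend on the tested concentration grid; fold-shift
  bounds are only as tight as the highest tested dose.
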