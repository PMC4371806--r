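# Synthetic-data generators with planted ground truth. Every downstream
# stage of the pipeline can be exercised end to end on these outputs, and
# with all noise parameters at zero each estimator recovers its planted
# parameters exactly.
#
# Randomness: each generator derives a child seed from the config's global
# seed and its own stage name, so stages draw from independent streams and
# identical configs always reproduce identical tables. The caller's RNG
# state is saved and restored.

with_seed <- function(seed, stage, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(child_seed(seed, stage))
  expr
}

#' Configuration for a synthetic cold-sensitivity screen
#'
#' Emulates a duplicate two-temperature plate screen: items are laid out
#' across plates with additive plate effects; a chosen number of planted
#' cold-sensitive items have their true 15-degree growth multiplied by
#' `planted_effect` (< 1 = growth reduction; 1 = no effect).
#'
#' @param n_items Number of screened items (> 0).
#' @param n_plates Number of plates items are distributed over.
#' @param replicate_sd Additive replicate noise (OD600 units).
#' @param plate_effect_sd Additive per-plate offset scale (OD600 units).
#' @param n_planted_coldsensitive Number of planted cold-sensitive items
#'   (<= n_items).
#' @param planted_effect Multiplicative growth reduction at 15 degrees in
#'   (0, 1\].
#' @param baseline_od37,baseline_od15 Mean uninhibited OD600 at each
#'   temperature (defaults 0.9 and 0.7: saturated growth in rich media,
#'   somewhat lower in the cold).
#' @param seed Integer seed.
#' @return List of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_items, n_plates = 10, replicate_sd = 0.03,
                              plate_effect_sd = 0.03,
                              n_planted_coldsensitive = 0,
                              planted_effect = 0.3,
                              baseline_od37 = 0.9, baseline_od15 = 0.7,
                              seed = 1L) {
  assert_that(is.numeric(n_items) && length(n_items) == 1L && n_items >= 1,
              "n_items must be a positive count")
  assert_that(n_planted_coldsensitive <= n_items,
              "cannot plant more items than screened")
  assert_that(replicate_sd >= 0 && plate_effect_sd >= 0,
              "noise SDs must be non-negative")
  assert_that(planted_effect > 0 && planted_effect <= 1,
              "planted_effect must be in (0, 1]")
  structure(list(n_items = as.integer(n_items),
                 n_plates = as.integer(n_plates),
                 replicate_sd = replicate_sd,
                 plate_effect_sd = plate_effect_sd,
                 n_planted_coldsensitive = as.integer(n_planted_coldsensitive),
                 planted_effect = planted_effect,
                 baseline_od37 = baseline_od37,
                 baseline_od15 = baseline_od15,
                 seed = as.integer(seed)),
            class = "screen_sim_config")
}

#' Generate a synthetic screen growth table
#'
#' @param cfg A [screen_sim_config()].
#' @return List with `growth` (data.frame `item_id`, `plate_id`,
#'   `od37_rep1`, `od37_rep2`, `od15_rep1`, `od15_rep2`) and `truth`
#'   (data.frame `item_id`, `planted_value` = the multiplicative 15-degree
#'   effect of each planted item).
#' @export
gen_screen_data <- function(cfg) {
  assert_that(inherits(cfg, "screen_sim_config"),
              "cfg must be a screen_sim_config")
  with_seed(cfg$seed, "screen", {
    ids <- sprintf("item_%05d", seq_len(cfg$n_items))
    plates <- sprintf("plate_%02d",
                      rep_len(seq_len(cfg$n_plates), cfg$n_items))
    planted <- if (cfg$n_planted_coldsensitive > 0) {
      sample(ids, cfg$n_planted_coldsensitive)
    } else character(0)
    plate_off37 <- stats::rnorm(cfg$n_plates, 0, cfg$plate_effect_sd)
    plate_off15 <- stats::rnorm(cfg$n_plates, 0, cfg$plate_effect_sd)
    names(plate_off37) <- names(plate_off15) <-
      sprintf("plate_%02d", seq_len(cfg$n_plates))

    true37 <- cfg$baseline_od37 + plate_off37[plates]
    true15 <- cfg$baseline_od15 + plate_off15[plates]
    true15[ids %in% planted] <- true15[ids %in% planted] * cfg$planted_effect

    rep_noise <- function(mu) {
      pmax(mu + stats::rnorm(length(mu), 0, cfg$replicate_sd), 0)
    }
    growth <- data.frame(
      item_id = ids, plate_id = unname(plates),
      od37_rep1 = unname(rep_noise(true37)),
      od37_rep2 = unname(rep_noise(true37)),
      od15_rep1 = unname(rep_noise(true15)),
      od15_rep2 = unname(rep_noise(true15))
    )
    truth <- data.frame(item_id = sort(planted),
                        planted_value = rep(cfg$planted_effect,
                                            length(planted)))
    list(growth = growth, truth = truth)
  })
}

#' Logistic planted occupancy profiles
#'
#' Builds a protein-by-fraction matrix of planted occupancies following
#' logistic curves over the fraction index: early-binding proteins reach
#' their plateau in low-density fractions (small midpoint), late binders
#' only near the bottom of the gradient. Plateaus are capped below 1
#' because an occupancy of exactly 1 corresponds to an unbounded amount of
#' experimental material relative to the reference.
#'
#' @param proteins Character vector of protein names.
#' @param n_fractions Number of gradient fractions.
#' @param midpoints Per-protein logistic midpoint (fraction index);
#'   defaults to an even spread over the gradient.
#' @param steepness Logistic scale in fractions (default 1.5).
#' @param max_occupancy Plateau occupancy (default 0.95).
#' @return Matrix proteins x fractions with values in \[0, max_occupancy\].
#' @export
planted_occupancy_profiles <- function(proteins, n_fractions,
                                       midpoints = NULL, steepness = 1.5,
                                       max_occupancy = 0.95) {
  assert_that(max_occupancy > 0 && max_occupancy < 1,
              "max_occupancy must be in (0, 1)")
  if (is.null(midpoints)) {
    midpoints <- seq(2, n_fractions - 1, length.out = length(proteins))
  }
  assert_that(length(midpoints) == length(proteins),
              "one midpoint per protein required")
  f <- seq_len(n_fractions)
  m <- t(vapply(midpoints, function(mid) {
    max_occupancy / (1 + exp(-(f - mid) / steepness))
  }, numeric(n_fractions)))
  dimnames(m) <- list(proteins, f)
  m
}

#' Configuration for synthetic quantitative-MS gradient spectra
#'
#' Describes a sucrose-gradient labeling experiment: proteins digested into
#' tryptic peptides, observed as MS1 stick spectra that mix a
#' natural-abundance (light) species — experimental material plus the light
#' half of the mixed reference standard — with the 15N-labeled (heavy)
#' reference. Planted occupancies are expressed on the final pipeline
#' scale (reference-corrected light fraction of total), and the generator
#' inverts the quantitation chain so that noise-free analysis returns them
#' exactly.
#'
#' @param proteins Named character vector of protein sequences.
#' @param n_fractions Number of gradient fractions.
#' @param species_enrichments 15N enrichments of the species, strictly
#'   increasing; default `c(0, 0.99)`.
#' @param occupancy Planted protein x fraction occupancy matrix in
#'   \[0, 1); default from [planted_occupancy_profiles()].
#' @param reference_amounts Per-species reference-standard amounts (pmol);
#'   default `c(10, 30)` light:heavy.
#' @param loading_pmol Amount of experimental sample analyzed per fraction
#'   (scalar or per-fraction vector; default 20).
#' @param nominal_loading_pmol Loading to which the pipeline standardizes
#'   (default 20).
#' @param noise_cv Multiplicative log-normal noise CV per stick.
#' @param charges Charge states emitted per peptide (default 2:3).
#' @param min_length,max_length Tryptic peptide length window.
#' @param seed Integer seed.
#' @return List of class `qms_sim_config`.
#' @export
qms_sim_config <- function(proteins, n_fractions,
                           species_enrichments = c(0, 0.99),
                           occupancy = NULL,
                           reference_amounts = c(10, 30),
                           loading_pmol = 20, nominal_loading_pmol = 20,
                           noise_cv = 0, charges = 2:3,
                           min_length = 6, max_length = 30, seed = 1L) {
  assert_that(length(proteins) >= 1L && !is.null(names(proteins)),
              "proteins must be a named character vector of sequences")
  assert_that(!is.unsorted(species_enrichments, strictly = TRUE),
              "species enrichments must be strictly increasing")
  assert_that(length(reference_amounts) == length(species_enrichments),
              "one reference amount per species required")
  assert_that(all(reference_amounts >= 0), "reference amounts must be >= 0")
  assert_that(noise_cv >= 0, "noise_cv must be non-negative")
  loading_pmol <- rep_len(loading_pmol, n_fractions)
  assert_that(all(loading_pmol > 0), "loading_pmol must be positive")
  if (is.null(occupancy)) {
    occupancy <- planted_occupancy_profiles(names(proteins), n_fractions)
  }
  assert_that(nrow(occupancy) == length(proteins) &&
                ncol(occupancy) == n_fractions,
              "occupancy must be proteins x fractions")
  assert_that(all(occupancy >= 0 & occupancy < 1),
              "planted occupancies must be in [0, 1)")
  scaled <- sweep(occupancy, 2, loading_pmol / nominal_loading_pmol, `*`)
  assert_that(all(scaled < 1),
              "loading-scaled occupancy reaches 1; reduce occupancy or loading")
  structure(list(proteins = proteins, n_fractions = as.integer(n_fractions),
                 species_enrichments = species_enrichments,
                 occupancy = occupancy,
                 reference_amounts = reference_amounts,
                 loading_pmol = loading_pmol,
                 nominal_loading_pmol = nominal_loading_pmol,
                 noise_cv = noise_cv, charges = charges,
                 min_length = min_length, max_length = max_length,
                 seed = as.integer(seed)),
            class = "qms_sim_config")
}

#' Generate MS1 stick spectra for one gradient fraction
#'
#' Emits the isotopologue stick spectrum of every tryptic peptide (within
#' the configured length window) and charge state: the superposition of
#' each species' isotope template scaled by its amplitude, under
#' multiplicative log-normal noise. Experimental samples contain both the
#' gradient material and the mixed reference standard; reference-only
#' samples contain the standard alone.
#'
#' @param cfg A [qms_sim_config()].
#' @param fraction Fraction index (1-based from the gradient top).
#' @param sample_kind `"experimental"` or `"reference_only"`.
#' @param replicate Replicate number, folded into the sample id and the
#'   noise stream (default 1).
#' @return data.frame peak list: `sample_id`, `fraction_id`, `peptide`,
#'   `charge`, `mz`, `intensity`.
#' @export
gen_spectra <- function(cfg, fraction,
                        sample_kind = c("experimental", "reference_only"),
                        replicate = 1L) {
  assert_that(inherits(cfg, "qms_sim_config"), "cfg must be a qms_sim_config")
  sample_kind <- match.arg(sample_kind)
  assert_that(fraction >= 1 && fraction <= cfg$n_fractions,
              "fraction out of range")
  sample_id <- sprintf("%s_f%02d_r%d", sample_kind, fraction, replicate)

  with_seed(cfg$seed, paste0("spectra_", sample_id), {
    rows <- list()
    for (pi in seq_along(cfg$proteins)) {
      prot <- names(cfg$proteins)[pi]
      peptides <- tryptic_peptides(cfg$proteins[[pi]], cfg$min_length,
                                   cfg$max_length)
      for (pep in peptides) {
        for (z in cfg$charges) {
          tmpl <- species_templates(pep, z, cfg$species_enrichments)
          amps <- cfg$reference_amounts
          if (sample_kind == "experimental") {
            # invert the quantitation chain: planted occupancy p (after
            # loading correction) requires corrected ratio p/(1-p), hence
            # a light amplitude of ref_heavy * p/(1-p) on top of the
            # reference's own light pool
            q <- cfg$occupancy[pi, fraction] *
              cfg$loading_pmol[fraction] / cfg$nominal_loading_pmol
            heavy <- cfg$reference_amounts[length(cfg$reference_amounts)]
            amps[1] <- amps[1] + heavy * q / (1 - q)
          }
          mz <- unlist(lapply(tmpl, `[[`, "mz"))
          intensity <- unlist(mapply(function(t, a) a * t$probability,
                                     tmpl, amps, SIMPLIFY = FALSE))
          # superpose species on the shared stick grid
          agg <- tapply(intensity, round(mz, 6), sum)
          mz_u <- as.numeric(names(agg))
          int_u <- as.numeric(agg) * rlnorm_cv(length(agg), cfg$noise_cv)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sample_id, fraction_id = fraction,
            peptide = pep, charge = z, mz = mz_u, intensity = int_u)
        }
      }
    }
    assert_that(length(rows) > 0L,
                "no tryptic peptides in the configured length window")
    out <- do.call(rbind, rows)
    out <- out[order(out$peptide, out$charge, out$mz), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Configuration for a synthetic 15N pulse-labeling experiment
#'
#' Cultures growing on light media are diluted twofold into 15N media at
#' time zero, so protein made after the pulse carries ~50 percent 15N.
#' Pre-pulse material decays exponentially with the degradation rate;
#' post-pulse material accumulates linearly with the synthesis rate (early
#' linear regime); the fully labeled spiked reference is constant.
#'
#' @param proteins Character vector of protein names.
#' @param time_points Pulse durations in hours (non-negative, sorted);
#'   default `c(0, 1, 2.6, 4, 8, 16)`.
#' @param synthesis_rates Named per-protein synthesis rate
#'   (ratio units / hr).
#' @param degradation_rates Named per-protein degradation rate (/hr,
#'   default 0).
#' @param initial_pool Pre-pulse material per protein (ratio units,
#'   default 1).
#' @param ref_amount Spiked reference amplitude (default 1).
#' @param treatments Named numeric vector of synthesis-rate multipliers,
#'   one per treatment (default `c(DMSO = 1)`).
#' @param n_peptides Peptide measurements simulated per protein (default
#'   6, a typical count of quantifiable tryptic peptides for a ribosomal
#'   protein).
#' @param noise_cv Multiplicative log-normal noise CV on the
#'   reference-normalized pre- and post-pulse amplitudes. The reference
#'   spike defines the unit scale of each spectrum: common-mode intensity
#'   variation (injection amount, ionization efficiency) cancels in the
#'   within-spectrum normalization, so noise is placed on the normalized
#'   amplitudes rather than independently on all three species.
#' @param seed Integer seed.
#' @return List of class `pulse_sim_config`.
#' @export
pulse_sim_config <- function(proteins, time_points = c(0, 1, 2.6, 4, 8, 16),
                             synthesis_rates, degradation_rates = NULL,
                             initial_pool = 1, ref_amount = 1,
                             treatments = c(DMSO = 1), n_peptides = 6,
                             noise_cv = 0, seed = 1L) {
  assert_that(length(time_points) >= 1L, "time grid must be non-empty")
  assert_that(all(time_points >= 0) && !is.unsorted(time_points),
              "time points must be non-negative and sorted")
  assert_that(all(proteins %in% names(synthesis_rates)),
              "every protein needs a synthesis rate")
  if (is.null(degradation_rates)) {
    degradation_rates <- stats::setNames(rep(0, length(proteins)), proteins)
  }
  assert_that(all(proteins %in% names(degradation_rates)),
              "every protein needs a degradation rate")
  assert_that(all(synthesis_rates >= 0) && all(degradation_rates >= 0),
              "rates must be non-negative")
  assert_that(ref_amount > 0, "ref_amount must be positive")
  assert_that(!is.null(names(treatments)), "treatments must be named")
  structure(list(proteins = proteins, time_points = time_points,
                 synthesis_rates = synthesis_rates,
                 degradation_rates = degradation_rates,
                 initial_pool = initial_pool, ref_amount = ref_amount,
                 treatments = treatments,
                 n_peptides = as.integer(n_peptides),
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "pulse_sim_config")
}

#' Generate pulse-labeling species-amplitude tables
#'
#' @param cfg A [pulse_sim_config()].
#' @return List with `series` (data.frame `treatment`, `protein`,
#'   `peptide`, `time_hr`, `a_pre`, `a_post`, `a_ref`) and `truth`
#'   (data.frame `treatment`, `protein`, `synthesis_rate`,
#'   `degradation_rate`).
#' @export
gen_pulse_experiment <- function(cfg) {
  assert_that(inherits(cfg, "pulse_sim_config"),
              "cfg must be a pulse_sim_config")
  with_seed(cfg$seed, "pulse", {
    grid <- expand.grid(treatment = names(cfg$treatments),
                        protein = cfg$proteins,
                        pep_i = seq_len(cfg$n_peptides),
                        time_hr = cfg$time_points,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mult <- cfg$treatments[grid$treatment]
    synth <- cfg$synthesis_rates[grid$protein] * mult
    deg <- cfg$degradation_rates[grid$protein]
    n <- nrow(grid)
    series <- data.frame(
      treatment = grid$treatment, protein = grid$protein,
      peptide = sprintf("%s_pep%d", grid$protein, grid$pep_i),
      time_hr = grid$time_hr,
      a_pre = unname(cfg$initial_pool * exp(-deg * grid$time_hr)) *
        rlnorm_cv(n, cfg$noise_cv),
      a_post = unname(synth * grid$time_hr) * rlnorm_cv(n, cfg$noise_cv),
      a_ref = cfg$ref_amount
    )
    truth <- expand.grid(treatment = names(cfg$treatments),
                         protein = cfg$proteins,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    truth$synthesis_rate <- unname(cfg$synthesis_rates[truth$protein] *
                                     cfg$treatments[truth$treatment] /
                                     cfg$ref_amount)
    truth$degradation_rate <- unname(cfg$degradation_rates[truth$protein])
    list(series = series, truth = truth)
  })
}

#' Generate a capillary-electrophoresis peak table
#'
#' Places one peak per configured rRNA species at its assignment-table
#' fragment size, with multiplicative log-normal fluorescence noise, and
#' records the planted immature proportion per primer from the noise-free
#' intensities.
#'
#' @param species_intensities Named numeric vector of fluorescence per
#'   species; names must appear in `assignments$species`.
#' @param noise_cv Multiplicative noise CV.
#' @param seed Integer seed.
#' @param assignments Species assignment table (default
#'   [ce_species_table()]).
#' @param sample_id,fraction Labels carried into the peak table.
#' @return List with `peaks` (data.frame `sample_id`, `fraction`,
#'   `primer`, `size_nt`, `fluorescence`) and `truth` (data.frame
#'   `primer`, `planted_proportion`).
#' @export
gen_ce_tables <- function(species_intensities, noise_cv = 0, seed = 1L,
                          assignments = ce_species_table(),
                          sample_id = "sim", fraction = "70S") {
  assert_that(!is.null(names(species_intensities)),
              "species_intensities must be named")
  assert_that(all(species_intensities >= 0),
              "species intensities must be non-negative")
  unknown <- setdiff(names(species_intensities), assignments$species)
  assert_that(length(unknown) == 0L,
              "unknown species: ", paste(unknown, collapse = ", "))
  with_seed(seed, "ce", {
    idx <- match(names(species_intensities), assignments$species)
    peaks <- data.frame(
      sample_id = sample_id, fraction = fraction,
      primer = assignments$primer[idx],
      size_nt = assignments$size_nt[idx],
      fluorescence = unname(species_intensities) *
        rlnorm_cv(length(species_intensities), noise_cv)
    )
    truth <- do.call(rbind, lapply(unique(peaks$primer), function(p) {
      sel <- idx[peaks$primer == p]
      imm <- assignments$immature[sel]
      tot <- sum(species_intensities[peaks$primer == p])
      data.frame(primer = p,
                 planted_proportion = if (tot > 0) {
                   sum(species_intensities[peaks$primer == p][imm]) / tot
                 } else NA_real_)
    }))
    list(peaks = peaks, truth = truth)
  })
}
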