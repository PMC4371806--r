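# Reference correction, occupancy matrices, dataset merging, factor profiles.

fit_row <- function(sample_id, fraction_id, peptide, a1, a2, r2 = 1,
                    charge = 2) {
  data.frame(sample_id = sample_id, fraction_id = fraction_id,
             peptide = peptide, charge = charge, a1 = a1, a2 = a2,
             r_squared = r2, n_matched = 10L, passed_filter = TRUE,
             status = "ok")
}

test_that("reference correction subtracts the triplicate mean and clips at zero", {
  ref <- data.frame(peptide = "PEP", charge = 2L, ref_ratio = 0.1,
                    n_replicates = 3L)
  f <- fit_row("s", 1, "PEP", a1 = 0.5, a2 = 1)
  out <- normalize_to_reference(f, ref)
  expect_equal(out$corrected_ratio, 0.4)

  at_ref <- normalize_to_reference(fit_row("s", 1, "PEP", 0.1, 1), ref)
  expect_equal(at_ref$corrected_ratio, 0)

  below <- normalize_to_reference(fit_row("s", 1, "PEP", 0.05, 1), ref)
  expect_equal(below$corrected_ratio, 0)
  expect_identical(attr(below, "n_clipped"), 1L)

  no_ref <- normalize_to_reference(fit_row("s", 1, "OTHER", 0.5, 1), ref)
  expect_identical(nrow(no_ref), 0L)
  expect_identical(attr(no_ref, "dropped"), "OTHER/2")
})

test_that("reference ratios average light/heavy across replicate runs", {
  fits <- rbind(fit_row("r1", 1, "PEP", 1, 10),
                fit_row("r2", 1, "PEP", 2, 10),
                fit_row("r3", 1, "PEP", 3, 10))
  rr <- reference_ratios(fits)
  expect_equal(rr$ref_ratio, 0.2)
  expect_identical(rr$n_replicates, 3L)
})

test_that("a reference-only sample corrects to zero for every peptide", {
  # self-consistency: analyzing the reference against its own triplicate
  prot <- random_protein_sequences(2, 80, seed = 31)
  cfg <- qms_sim_config(prot, 1, noise_cv = 0, charges = 2L, seed = 8,
                        occupancy = matrix(0.5, 2, 1,
                                           dimnames = list(names(prot), NULL)))
  ref_fits <- do.call(rbind, lapply(1:3, function(r) {
    fit_peak_table(gen_spectra(cfg, 1, "reference_only", replicate = r),
                   c(0, 0.99))
  }))
  rr <- reference_ratios(ref_fits)
  again <- fit_peak_table(gen_spectra(cfg, 1, "reference_only", replicate = 4),
                          c(0, 0.99))
  corr <- normalize_to_reference(again, rr)
  expect_lt(max(corr$corrected_ratio), 1e-9)
})

test_that("occupancy is corrected ratio over corrected ratio plus one", {
  ref <- data.frame(peptide = "PEP", charge = 2L, ref_ratio = 1 / 3,
                    n_replicates = 3L)
  pmap <- data.frame(protein = "P1", peptide = "PEP")
  meta <- data.frame(fraction_id = 1, loading_pmol = 20)
  # corrected ratio 1 -> occupancy 0.5 (pre-normalization)
  f <- normalize_to_reference(fit_row("s", 1, "PEP", 1 + 1 / 3, 1), ref)
  m <- protein_occupancy_matrix(f, pmap, meta, normalize = "none")
  expect_equal(m$occupancy["P1", "1"], 0.5)
  # corrected ratio 0 -> occupancy 0
  f0 <- normalize_to_reference(fit_row("s", 1, "PEP", 1 / 3, 1), ref)
  m0 <- protein_occupancy_matrix(f0, pmap, meta, normalize = "none")
  expect_equal(m0$occupancy["P1", "1"], 0)
})

test_that("noise-free planted logistic profiles are recovered exactly", {
  prot <- random_protein_sequences(3, 100, seed = 5)
  occ_planted <- planted_occupancy_profiles(names(prot), 5)
  cfg <- qms_sim_config(prot, 5, occupancy = occ_planted, noise_cv = 0,
                        charges = 2L, seed = 3)
  fits <- do.call(rbind, lapply(1:5, function(f) {
    fit_peak_table(gen_spectra(cfg, f, "experimental"), c(0, 0.99))
  }))
  ref_fits <- do.call(rbind, lapply(1:3, function(r) {
    fit_peak_table(gen_spectra(cfg, 1, "reference_only", replicate = r),
                   c(0, 0.99))
  }))
  corr <- normalize_to_reference(filter_interference(fits)$retained,
                                 reference_ratios(ref_fits))
  m <- protein_occupancy_matrix(corr, peptide_protein_map(prot),
                                data.frame(fraction_id = 1:5,
                                           loading_pmol = 20))
  planted_norm <- occ_planted / apply(occ_planted, 1, max)
  expect_lt(max(abs(m$occupancy[rownames(planted_norm), ] - planted_norm)),
            1e-9)
})

test_that("planted profiles are recovered within 0.05 at 5% CV", {
  prot <- random_protein_sequences(3, 120, seed = 15)
  occ_planted <- planted_occupancy_profiles(names(prot), 6)
  cfg <- qms_sim_config(prot, 6, occupancy = occ_planted, noise_cv = 0.05,
                        charges = 2:3, seed = 9)
  fits <- do.call(rbind, lapply(1:6, function(f) {
    fit_peak_table(gen_spectra(cfg, f, "experimental"), c(0, 0.99))
  }))
  ref_fits <- do.call(rbind, lapply(1:3, function(r) {
    fit_peak_table(gen_spectra(cfg, 1, "reference_only", replicate = r),
                   c(0, 0.99))
  }))
  corr <- normalize_to_reference(filter_interference(fits)$retained,
                                 reference_ratios(ref_fits))
  m <- protein_occupancy_matrix(corr, peptide_protein_map(prot),
                                data.frame(fraction_id = 1:6,
                                           loading_pmol = 20))
  planted_norm <- occ_planted / apply(occ_planted, 1, max)
  expect_lt(max(abs(m$occupancy[rownames(planted_norm), ] - planted_norm)),
            0.05)
})

test_that("loading correction standardizes unequal fraction loadings", {
  prot <- random_protein_sequences(2, 80, seed = 44)
  occ_planted <- matrix(c(0.3, 0.6, 0.3, 0.6), 2, 2,
                        dimnames = list(names(prot), NULL))
  cfg <- qms_sim_config(prot, 2, occupancy = occ_planted, noise_cv = 0,
                        loading_pmol = c(20, 10), charges = 2L, seed = 2)
  fits <- do.call(rbind, lapply(1:2, function(f) {
    fit_peak_table(gen_spectra(cfg, f, "experimental"), c(0, 0.99))
  }))
  ref_fits <- fit_peak_table(gen_spectra(cfg, 1, "reference_only"), c(0, 0.99))
  corr <- normalize_to_reference(fits, reference_ratios(ref_fits))
  m <- protein_occupancy_matrix(corr, peptide_protein_map(prot),
                                data.frame(fraction_id = 1:2,
                                           loading_pmol = c(20, 10)),
                                normalize = "none")
  expect_equal(unname(m$occupancy), unname(occ_planted), tolerance = 1e-9)
})

test_that("stoichiometric 70S-like fractions give a uniform matrix column", {
  prot <- random_protein_sequences(4, 100, seed = 23)
  occ_planted <- matrix(0.8, 4, 3, dimnames = list(names(prot), NULL))
  occ_planted[, 1:2] <- 0.2
  cfg <- qms_sim_config(prot, 3, occupancy = occ_planted, noise_cv = 0.02,
                        charges = 2L, seed = 13)
  fits <- do.call(rbind, lapply(1:3, function(f) {
    fit_peak_table(gen_spectra(cfg, f, "experimental"), c(0, 0.99))
  }))
  ref_fits <- do.call(rbind, lapply(1:3, function(r) {
    fit_peak_table(gen_spectra(cfg, 1, "reference_only", replicate = r),
                   c(0, 0.99))
  }))
  corr <- normalize_to_reference(filter_interference(fits)$retained,
                                 reference_ratios(ref_fits))
  m <- protein_occupancy_matrix(corr, peptide_protein_map(prot),
                                data.frame(fraction_id = 1:3,
                                           loading_pmol = 20))
  col70 <- m$occupancy[, "3"]
  expect_lt(max(abs(col70 - mean(col70))), 0.05)
})

test_that("max-normalization is idempotent", {
  ref <- data.frame(peptide = c("PEP", "QEP"), charge = 2L,
                    ref_ratio = c(0.2, 0.2), n_replicates = 3L)
  pmap <- data.frame(protein = c("P1", "P1"), peptide = c("PEP", "QEP"))
  meta <- data.frame(fraction_id = 1:2, loading_pmol = 20)
  fits <- rbind(fit_row("s", 1, "PEP", 1, 1), fit_row("s", 2, "PEP", 3, 1),
                fit_row("s", 1, "QEP", 1.2, 1), fit_row("s", 2, "QEP", 2.8, 1))
  corr <- normalize_to_reference(fits, ref)
  m1 <- protein_occupancy_matrix(corr, pmap, meta)
  expect_equal(max(m1$occupancy, na.rm = TRUE), 1)
  # renormalizing the already-normalized matrix changes nothing
  renorm <- m1$occupancy / apply(m1$occupancy, 1, max, na.rm = TRUE)
  expect_equal(renorm, m1$occupancy)
})

test_that("linearity standards: dilution series fits a line through the origin", {
  # simulated standards with varying light amounts at fixed heavy spike
  tmpl <- ribotrace:::species_templates("ELVISLIVESK", 2, c(0, 0.99))
  amounts <- c(1, 2, 5, 10, 20, 40)
  set.seed(77)
  sdlog <- sqrt(log(1 + 0.02^2))
  fitted <- vapply(amounts, function(a) {
    peaks <- make_spectrum(tmpl, c(a, 30))
    peaks$intensity <- peaks$intensity *
      rlnorm(nrow(peaks), -sdlog^2 / 2, sdlog)
    fit_species_mixture(peaks, tmpl)$amplitudes[[1]]
  }, numeric(1))
  lmfit <- lm(fitted ~ amounts)
  expect_gt(summary(lmfit)$r.squared, 0.99)
  expect_lt(abs(coef(lmfit)[1]), 0.5)
})

test_that("merging keeps the higher-quality fit on key collisions", {
  a <- fit_row("s", 1, "PEP", 1, 1, r2 = 0.95)
  b <- fit_row("s", 1, "PEP", 2, 2, r2 = 0.80)
  merged <- merge_datasets(a, b)
  expect_identical(nrow(merged), 1L)
  expect_equal(merged$a1, 1)
  expect_identical(merged$provenance, "primary")

  flipped <- merge_datasets(b, a)
  expect_identical(flipped$provenance, "secondary")

  disjoint <- merge_datasets(fit_row("s", 1, "PEP", 1, 1),
                             fit_row("s", 2, "PEP", 2, 2))
  expect_identical(nrow(disjoint), 2L)

  unchanged <- merge_datasets(a, a[0, , drop = FALSE])
  expect_identical(nrow(unchanged), 1L)
})

test_that("merging disjoint keys is commutative in content", {
  a <- fit_row("s", 1, "PEP", 1, 1)
  b <- fit_row("s", 2, "QEP", 2, 2)
  ab <- merge_datasets(a, b)
  ba <- merge_datasets(b, a)
  key <- function(df) paste(df$sample_id, df$fraction_id, df$peptide)
  expect_setequal(key(ab), key(ba))
})

test_that("factor profiles normalize, scale to unit max, and smooth", {
  # delta profile convolved with the 3-tap kernel
  fp <- factor_profile(c(0, 0, 1, 0, 0), rep(1, 5))
  expect_equal(fp$normalized, c(0, 0, 1, 0, 0))
  expect_equal(fp$smoothed, c(0, 0.25, 0.5, 0.25, 0))

  # constant profiles are fixed points of the smoother
  fc <- factor_profile(c(3, 3, 3, 3), c(10, 10, 10, 10))
  expect_equal(fc$smoothed, rep(1, 4))

  # per-fraction totals enter before the max scaling
  fm <- factor_profile(c(2, 4, 2), c(10, 40, 10))
  expect_equal(fm$normalized, c(1, 0.5, 1))
  expect_equal(max(fm$normalized), 1)

  fz <- factor_profile(c(0, 0, 0), c(1, 1, 1))
  expect_true(fz$flat_zero)
  expect_equal(fz$smoothed, c(0, 0, 0))
  expect_error(factor_profile(c(1, 2), c(1, 2)),
               class = "ribotrace_input_error")
})
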