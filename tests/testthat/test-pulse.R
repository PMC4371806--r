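# Pulse-labeling ratios, synthesis rates, DMSO normalization, box summaries.

test_that("species ratios normalize each labeled pool to the reference", {
  r <- species_ratios(data.frame(peptide = "X", time_hr = 4,
                                 a_pre = 2, a_post = 0, a_ref = 4))
  expect_equal(r$pre_pulse, 0.5)
  expect_equal(r$post_pulse, 0)
  expect_equal(r$total, 0.5)

  zero <- species_ratios(data.frame(peptide = "X", time_hr = 0,
                                    a_pre = 0, a_post = 0, a_ref = 1))
  expect_equal(c(zero$pre_pulse, zero$post_pulse, zero$total), c(0, 0, 0))
})

test_that("total always equals pre plus post; zero reference is excluded", {
  set.seed(3)
  df <- data.frame(peptide = "X", time_hr = 1,
                   a_pre = runif(50), a_post = runif(50),
                   a_ref = runif(50, 0.1, 2))
  r <- species_ratios(df)
  expect_equal(r$total, r$pre_pulse + r$post_pulse, tolerance = 1e-12)

  df$a_ref[1] <- 0
  r2 <- species_ratios(df)
  expect_identical(nrow(r2), 49L)
  expect_identical(attr(r2, "n_excluded"), 1L)
})

test_that("collinear medians {0,1,2,4} over {0,4,8,16} hr give slope 0.25", {
  df <- data.frame(protein = "P", peptide = "P_pep1",
                   time_hr = c(0, 4, 8, 16),
                   post_pulse = c(0, 1, 2, 4))
  out <- synthesis_rate(df)
  expect_equal(out$slope, 0.25)
  expect_identical(out$n_timepoints, 4L)

  flat <- synthesis_rate(transform(df, post_pulse = 2))
  expect_equal(flat$slope, 0)
})

test_that("only the designated rate time points enter the fit", {
  # early points carry a deliberate distortion; the 0/4/8/16 fit ignores it
  df <- data.frame(protein = "P", peptide = "P_pep1",
                   time_hr = c(0, 1, 2.6, 4, 8, 16),
                   post_pulse = c(0, 99, 99, 1, 2, 4))
  out <- synthesis_rate(df)
  expect_equal(out$slope, 0.25)

  few <- synthesis_rate(df[df$time_hr %in% c(0, 4), , drop = FALSE])
  expect_true(few$flagged)
  expect_true(is.na(few$slope))
})

test_that("the median over peptides feeds the line fit", {
  df <- expand.grid(peptide = c("a", "b", "c"), time_hr = c(0, 4, 8, 16))
  df$protein <- "P"
  df$post_pulse <- 0.25 * df$time_hr
  df$post_pulse[df$peptide == "c"] <- 10  # one deviant peptide, overruled
  out <- synthesis_rate(df)
  expect_equal(out$slope, 0.25)
})

test_that("planted synthesis rates are recovered within 10% at 5% CV", {
  prot <- sprintf("rp%03d", 1:200)
  rates <- with(list(), {
    set.seed(10)
    setNames(runif(200, 0.05, 0.5), prot)
  })
  cfg <- pulse_sim_config(prot, synthesis_rates = rates, noise_cv = 0.05,
                          seed = 6)
  pe <- gen_pulse_experiment(cfg)
  sr <- synthesis_rate(species_ratios(pe$series))
  truth <- pe$truth[match(sr$protein, pe$truth$protein), ]
  rel_err <- abs(sr$slope - truth$synthesis_rate) / truth$synthesis_rate
  expect_lt(max(rel_err), 0.10)
  # estimator bias well under 2%
  expect_lt(abs(mean(sr$slope / truth$synthesis_rate - 1)), 0.02)
})

test_that("with zero degradation the pre-pulse ratio is constant in time", {
  cfg <- pulse_sim_config("p1", synthesis_rates = c(p1 = 0.2),
                          degradation_rates = c(p1 = 0), noise_cv = 0,
                          seed = 4)
  r <- species_ratios(gen_pulse_experiment(cfg)$series)
  expect_equal(diff(range(r$pre_pulse)), 0)

  decaying <- pulse_sim_config("p1", synthesis_rates = c(p1 = 0.2),
                               degradation_rates = c(p1 = 0.1),
                               noise_cv = 0, seed = 4)
  rd <- species_ratios(gen_pulse_experiment(decaying)$series)
  agg <- tapply(rd$pre_pulse, rd$time_hr, median)
  expect_true(all(diff(agg[order(as.numeric(names(agg)))]) < 0))
})

test_that("DMSO normalization gives log2 ratios and censors non-positive slopes", {
  t_rates <- data.frame(treatment = "drug", protein = c("a", "b", "c"),
                        slope = c(0.2, 0.1, -0.01), n_timepoints = 4L,
                        flagged = FALSE)
  d_rates <- data.frame(treatment = "DMSO", protein = c("a", "b", "c"),
                        slope = c(0.2, 0.2, 0.2), n_timepoints = 4L,
                        flagged = FALSE)
  out <- normalize_rates(t_rates, d_rates)
  expect_equal(out$slope_norm_log2[out$protein == "a"], 0)
  expect_equal(out$slope_norm_log2[out$protein == "b"], -1)
  expect_true(out$censored[out$protein == "c"])
  expect_true(is.na(out$slope_norm_log2[out$protein == "c"]))

  self <- normalize_rates(d_rates, d_rates)
  expect_equal(self$slope_norm_log2, c(0, 0, 0))

  missing <- normalize_rates(t_rates,
                             d_rates[d_rates$protein != "b", , drop = FALSE])
  expect_identical(attr(missing, "dropped"), "b")
})

test_that("a planted 0.3x inhibition centers normalized log2 rates at log2(0.3)", {
  prot <- sprintf("rp%02d", 1:30)
  rates <- with(list(), {
    set.seed(2)
    setNames(runif(30, 0.1, 0.4), prot)
  })
  cfg <- pulse_sim_config(prot, synthesis_rates = rates,
                          treatments = c(DMSO = 1, cam = 0.3),
                          noise_cv = 0.05, seed = 12)
  sr <- synthesis_rate(species_ratios(gen_pulse_experiment(cfg)$series))
  nr <- normalize_rates(sr[sr$treatment == "cam", , drop = FALSE],
                        sr[sr$treatment == "DMSO", , drop = FALSE])
  expect_equal(median(nr$slope_norm_log2), log2(0.3), tolerance = 0.1)
})

test_that("box summaries follow interpolated quartiles and the 1.57 notch rule", {
  b <- box_summary(1:9)
  expect_equal(b$median, 5)
  expect_equal(b$q1, 3)
  expect_equal(b$q3, 7)
  expect_equal(b$whisker_lo, 1)
  expect_equal(b$whisker_hi, 9)
  expect_identical(b$outliers, numeric(0))

  # IQR 2, n 16 -> notch 1.57 * 2 / 4 = 0.785
  iqr2 <- box_summary(c(1, 1, 3, 3), n = 16)
  expect_equal(iqr2$iqr, 2)
  expect_equal(iqr2$notch_halfwidth, 0.785)

  const <- box_summary(rep(4, 6))
  expect_equal(const$iqr, 0)
  expect_equal(const$whisker_lo, 4)
  expect_equal(const$whisker_hi, 4)
  expect_identical(const$outliers, numeric(0))

  far <- box_summary(c(1, 2, 2, 3, 3, 4, 50))
  expect_true(50 %in% far$outliers)
  expect_lt(far$whisker_hi, 50)

  expect_error(box_summary(1), class = "ribotrace_input_error")
})
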