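#' Species ratios from a 3-species pulse-labeling fit
#'
#' A pulse experiment fits three labeled species per spectrum: 0 percent
#' 15N (material made before the pulse), ~50 percent (made after twofold
#' dilution into labeled media) and ~100 percent (the spiked reference).
#' Each species is normalized to the reference, giving pre-pulse
#' (`a_pre / a_ref`), post-pulse synthesis (`a_post / a_ref`) and total
#' material (`(a_pre + a_post) / a_ref`) ratios.
#'
#' @param fits data.frame with columns `protein` (optional), `peptide`,
#'   `time_hr`, and amplitudes `a_pre`, `a_post`, `a_ref` (a 3-species fit
#'   table from [fit_peak_table()] may be renamed: a1 = pre, a2 = post,
#'   a3 = ref).
#' @return The input table with added `pre_pulse`, `post_pulse`, `total`
#'   columns; measurements with `a_ref == 0` are excluded and counted in
#'   attribute `"n_excluded"`.
#' @examples
#' species_ratios(data.frame(peptide = "X", time_hr = 4,
#'                           a_pre = 2, a_post = 0, a_ref = 4))
#' @export
species_ratios <- function(fits) {
  req <- c("peptide", "time_hr", "a_pre", "a_post", "a_ref")
  assert_that(is.data.frame(fits) && all(req %in% names(fits)),
              "fits must have columns ", paste(req, collapse = ", "))
  assert_that(all(fits$a_pre >= 0 & fits$a_post >= 0 & fits$a_ref >= 0),
              "amplitudes must be non-negative")
  bad <- fits$a_ref == 0
  out <- fits[!bad, , drop = FALSE]
  out$pre_pulse <- out$a_pre / out$a_ref
  out$post_pulse <- out$a_post / out$a_ref
  out$total <- (out$a_pre + out$a_post) / out$a_ref
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' Per-protein synthesis rates from pulse time courses
#'
#' For each protein, the median post-pulse synthesis ratio at each time
#' point is fit to a straight line (ordinary least squares, free
#' intercept) over the designated rate time points; the slope is the
#' synthesis rate in ratio units per hour. Other time points in the data
#' (e.g. very early samples) are ingested but excluded from the fit.
#'
#' @param ratios Output of [species_ratios()] with a `protein` column (and
#'   optionally `treatment`).
#' @param rate_timepoints Time points used in the line fit (default
#'   `c(0, 4, 8, 16)` hours); at least 3 must be present per protein.
#' @return data.frame with `treatment` (if present), `protein`, `slope`,
#'   `n_timepoints`, `flagged` (TRUE when too few time points; slope NA).
#' @export
synthesis_rate <- function(ratios, rate_timepoints = c(0, 4, 8, 16)) {
  assert_that(is.data.frame(ratios) &&
                all(c("protein", "time_hr", "post_pulse") %in% names(ratios)),
              "ratios must have protein, time_hr and post_pulse columns")
  assert_that(length(rate_timepoints) >= 3L,
              "need at least 3 rate time points")
  if (!"treatment" %in% names(ratios)) ratios$treatment <- "all"
  groups <- split(ratios, list(ratios$treatment, ratios$protein), drop = TRUE)
  rows <- lapply(groups, function(g) {
    g <- g[g$time_hr %in% rate_timepoints, , drop = FALSE]
    med <- tapply(g$post_pulse, g$time_hr, stats::median)
    t <- as.numeric(names(med))
    ok <- length(med) >= 3L
    slope <- NA_real_
    if (ok) {
      slope <- unname(stats::coef(stats::lm(as.numeric(med) ~ t))[2])
    }
    data.frame(treatment = g$treatment[1], protein = g$protein[1],
               slope = slope, n_timepoints = length(med), flagged = !ok)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$treatment, out$protein), , drop = FALSE]
}

#' Normalize treatment synthesis rates to the vehicle control
#'
#' Divides each protein's slope under treatment by its slope under the
#' control (DMSO) treatment and takes log2. Proteins whose treatment slope
#' is non-positive cannot be log-transformed and are reported as censored;
#' proteins lacking a control partner (or with non-positive control slope)
#' are dropped.
#'
#' @param rates_treatment,rates_dmso Rate tables from [synthesis_rate()].
#' @return data.frame with `protein`, `slope`, `slope_dmso`,
#'   `slope_norm_log2`, `censored`; attribute `"dropped"` lists proteins
#'   without a usable control.
#' @export
normalize_rates <- function(rates_treatment, rates_dmso) {
  assert_that(all(c("protein", "slope") %in% names(rates_treatment)) &&
                all(c("protein", "slope") %in% names(rates_dmso)),
              "rate tables must have protein and slope columns")
  ctrl <- rates_dmso[!rates_dmso$flagged %in% TRUE & !is.na(rates_dmso$slope) &
                       rates_dmso$slope > 0, , drop = FALSE]
  idx <- match(rates_treatment$protein, ctrl$protein)
  dropped <- rates_treatment$protein[is.na(idx)]
  out <- rates_treatment[!is.na(idx), , drop = FALSE]
  out$slope_dmso <- ctrl$slope[idx[!is.na(idx)]]
  out$censored <- is.na(out$slope) | out$slope <= 0
  out$slope_norm_log2 <- NA_real_
  ok <- !out$censored
  out$slope_norm_log2[ok] <- log2(out$slope[ok] / out$slope_dmso[ok])
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Notched box-plot summary statistics
#'
#' Quartiles use linear interpolation (quantile type 7). Whiskers extend to
#' the most extreme data points within 1.5 x IQR of the quartiles; points
#' beyond the whiskers are outliers. The notch half-width is
#' `1.57 x IQR / sqrt(n)`.
#'
#' @param values Numeric vector (length >= 2).
#' @param n Number of points used in the notch formula (defaults to
#'   `length(values)`).
#' @return Object of class `box_summary`: list with `median`, `q1`, `q3`,
#'   `iqr`, `whisker_lo`, `whisker_hi`, `notch_halfwidth`, `outliers`, `n`.
#' @examples
#' box_summary(1:9)
#' @export
box_summary <- function(values, n = length(values)) {
  assert_that(is.numeric(values) && length(values) >= 2L,
              "need at least 2 values")
  assert_that(!anyNA(values), "values must not contain NA")
  values <- as.numeric(values)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  structure(
    list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
         whisker_lo = min(inside), whisker_hi = max(inside),
         notch_halfwidth = 1.57 * iqr / sqrt(n),
         outliers = sort(values[values < lo_fence | values > hi_fence]),
         n = n),
    class = "box_summary"
  )
}

#' @export
print.box_summary <- function(x, ...) {
  cat(sprintf(
    "Box summary (n=%d): median %.4g [q1 %.4g, q3 %.4g], whiskers [%.4g, %.4g], notch +/- %.4g, %d outlier(s)\n",
    x$n, x$median, x$q1, x$q3, x$whisker_lo, x$whisker_hi,
    x$notch_halfwidth, length(x$outliers)))
  invisible(x)
}
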