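#' Decompose an MS1 isotope envelope into labeled-species abundances
#'
#' Fits an extracted stick spectrum as a non-negative linear combination of
#' the isotopologue templates of the candidate labeled species (e.g.
#' natural-abundance and 15N-labeled forms of one peptide). Observed peaks
#' are matched to the union of the template m/z ladders within a ppm
#' tolerance; predicted positions with no matching peak contribute zero
#' intensity, so a missing species is fit as absent rather than ignored.
#' Amplitudes solve `min || y - T a ||^2` subject to `a >= 0`
#' (Lawson-Hanson active-set NNLS).
#'
#' @param peaks data.frame with columns `mz` (ascending) and `intensity`
#'   (non-negative) for one peptide/charge in one sample.
#' @param templates List of `isotope_template` objects sharing the
#'   spectrum's peptide and charge, one per candidate species.
#' @param tol_ppm Peak-matching tolerance in parts per million (default 10).
#' @param r2_min Minimum coefficient of determination for
#'   `passed_filter` (default 0.9).
#' @param n_min Minimum number of matched isotopologue positions for
#'   `passed_filter` (default 3).
#' @return Object of class `spectrum_fit`: list with `amplitudes` (named by
#'   template enrichment), `residual_norm`, `r_squared`,
#'   `n_matched_isotopologues`, `passed_filter` and `status`
#'   (`"ok"` or `"unmatched"`; amplitudes are NA when unmatched).
#' @examples
#' tmpl <- species_templates("SAMPLER", 2, c(0, 0.99))
#' peaks <- data.frame(mz = tmpl[[1]]$mz,
#'                     intensity = 5 * tmpl[[1]]$probability)
#' fit_species_mixture(peaks, tmpl)
#' @export
fit_species_mixture <- function(peaks, templates, tol_ppm = 10,
                                r2_min = 0.9, n_min = 3) {
  assert_that(is.data.frame(peaks) && all(c("mz", "intensity") %in% names(peaks)),
              "peaks must have columns mz and intensity")
  assert_that(all(peaks$intensity >= 0), "intensities must be non-negative")
  assert_that(length(templates) >= 1L, "at least one template required")
  pep <- unique(vapply(templates, `[[`, "", "peptide"))
  chg <- unique(vapply(templates, `[[`, 1L, "charge"))
  assert_that(length(pep) == 1L && length(chg) == 1L,
              "all templates must share one peptide and charge")

  # Shared isotopologue grid: the union of neutron shifts over all species.
  # All species of one peptide/charge share stick positions, so the grid is
  # indexed by shift.
  shifts <- sort(unique(unlist(lapply(templates, `[[`, "shift"))))
  ref <- templates[[1]]
  comp_mass <- ref$mz[1] * ref$charge - ref$charge * PROTON_MASS -
    ref$shift[1] * ISOTOPOLOGUE_SPACING
  grid_mz <- (comp_mass + shifts * ISOTOPOLOGUE_SPACING +
                chg * PROTON_MASS) / chg

  # Template matrix over the grid.
  tmat <- vapply(templates, function(t) {
    v <- numeric(length(shifts))
    v[match(t$shift, shifts)] <- t$probability
    v
  }, numeric(length(shifts)))

  # Assign each observed peak to its nearest grid position within tol_ppm;
  # ties go to the lower m/z. Multiple peaks on one position are summed.
  y <- numeric(length(shifts))
  matched <- logical(length(shifts))
  if (nrow(peaks) > 0L) {
    for (i in seq_len(nrow(peaks))) {
      d <- abs(grid_mz - peaks$mz[i])
      j <- which(d == min(d))[1]                 # tie -> lower m/z
      if (d[j] / grid_mz[j] * 1e6 <= tol_ppm) {
        y[j] <- y[j] + peaks$intensity[i]
        matched[j] <- TRUE
      }
    }
  }

  labels <- sprintf("enr_%g", vapply(templates, `[[`, 0, "enrichment_15n"))
  if (!any(matched)) {
    return(structure(
      list(peptide = pep, charge = chg,
           amplitudes = stats::setNames(rep(NA_real_, length(templates)), labels),
           residual_norm = NA_real_, r_squared = NA_real_,
           n_matched_isotopologues = 0L, passed_filter = FALSE,
           status = "unmatched"),
      class = "spectrum_fit"))
  }

  nn <- pracma::lsqnonneg(tmat, y)
  a <- nn$x
  fitted <- as.vector(tmat %*% a)
  resid <- y - fitted

  # Fit quality on matched positions only: unmatched zeros quantify absent
  # species but should not inflate r-squared.
  ym <- y[matched]
  fm <- fitted[matched]
  ss_res <- sum((ym - fm)^2)
  ss_tot <- sum((ym - mean(ym))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else as.numeric(ss_res <= 1e-12)

  structure(
    list(peptide = pep, charge = chg,
         amplitudes = stats::setNames(a, labels),
         residual_norm = sqrt(sum(resid^2)),
         r_squared = r2,
         n_matched_isotopologues = sum(matched),
         passed_filter = (r2 >= r2_min) && (sum(matched) >= n_min),
         status = "ok"),
    class = "spectrum_fit"
  )
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf("Spectrum fit: %s %d+ [%s]\n", x$peptide, x$charge, x$status))
  if (x$status == "ok") {
    cat("  amplitudes:",
        paste(sprintf("%s=%.4g", names(x$amplitudes), x$amplitudes),
              collapse = ", "), "\n")
    cat(sprintf("  r2 = %.4f over %d matched isotopologues; filter %s\n",
                x$r_squared, x$n_matched_isotopologues,
                if (x$passed_filter) "passed" else "failed"))
  }
  invisible(x)
}

#' Fit every spectrum in a peak-list table
#'
#' Groups a long peak table by sample, fraction, peptide and charge, fits
#' each group with [fit_species_mixture()] against templates built at the
#' requested enrichments, and returns one row per fit.
#'
#' @param peak_table data.frame with columns `sample_id`, `fraction_id`,
#'   `peptide`, `charge`, `mz`, `intensity`.
#' @param enrichments 15N enrichments of the candidate species, strictly
#'   increasing (e.g. `c(0, 0.99)` for occupancy runs, `c(0, 0.5, 0.99)`
#'   for pulse runs).
#' @param tol_ppm,r2_min,n_min Passed to [fit_species_mixture()].
#' @return data.frame with one row per (sample, fraction, peptide, charge):
#'   amplitude columns `a1..ak` in enrichment order, `r_squared`,
#'   `n_matched`, `passed_filter`, `status`. Carries the enrichment vector
#'   as attribute `"enrichments"`.
#' @export
fit_peak_table <- function(peak_table, enrichments = c(0, 0.99),
                           tol_ppm = 10, r2_min = 0.9, n_min = 3) {
  req <- c("sample_id", "fraction_id", "peptide", "charge", "mz", "intensity")
  assert_that(is.data.frame(peak_table) && all(req %in% names(peak_table)),
              "peak_table must have columns ", paste(req, collapse = ", "))
  key <- interaction(peak_table$sample_id, peak_table$fraction_id,
                     peak_table$peptide, peak_table$charge, drop = TRUE)
  groups <- split(peak_table, key)

  # Template cache: identical peptide/charge groups across samples and
  # fractions reuse one template set.
  cache <- new.env(parent = emptyenv())
  get_templates <- function(peptide, charge) {
    id <- paste0(peptide, "/", charge)
    if (!is.null(cache[[id]])) return(cache[[id]])
    t <- species_templates(peptide, charge, enrichments)
    cache[[id]] <- t
    t
  }

  rows <- lapply(groups, function(g) {
    tmpl <- get_templates(g$peptide[1], g$charge[1])
    fit <- fit_species_mixture(g[order(g$mz), c("mz", "intensity")], tmpl,
                               tol_ppm = tol_ppm, r2_min = r2_min,
                               n_min = n_min)
    amp <- as.list(fit$amplitudes)
    names(amp) <- paste0("a", seq_along(amp))
    cbind(
      data.frame(sample_id = g$sample_id[1], fraction_id = g$fraction_id[1],
                 peptide = g$peptide[1], charge = g$charge[1]),
      as.data.frame(amp),
      data.frame(r_squared = fit$r_squared,
                 n_matched = fit$n_matched_isotopologues,
                 passed_filter = fit$passed_filter, status = fit$status)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "enrichments") <- enrichments
  out
}

#' Interference filtering of spectrum fits
#'
#' Retains fits whose quality filter passed (high r-squared over enough
#' matched isotopologues); co-eluting contaminant peptides distort the
#' envelope and depress r-squared, so they are rejected here.
#'
#' @param fits Fit table from [fit_peak_table()] (or any data.frame with
#'   `passed_filter`, `status`, `r_squared`, `n_matched` columns).
#' @return List with `retained` (filtered fit table) and `report`
#'   (data.frame of rejection counts by cause: `unmatched`, `low_r2`,
#'   `few_isotopologues`).
#' @export
filter_interference <- function(fits) {
  assert_that(is.data.frame(fits), "fits must be a data.frame")
  if (nrow(fits) == 0L) {
    return(list(retained = fits,
                report = data.frame(cause = character(0), n = integer(0))))
  }
  unmatched <- fits$status == "unmatched"
  few <- !unmatched & !fits$passed_filter &
    fits$n_matched < attr_or(fits, "n_min", 3)
  low_r2 <- !unmatched & !fits$passed_filter & !few
  report <- data.frame(
    cause = c("unmatched", "low_r2", "few_isotopologues"),
    n = c(sum(unmatched), sum(low_r2), sum(few))
  )
  retained <- fits[fits$passed_filter %in% TRUE, , drop = FALSE]
  rownames(retained) <- NULL
  attr(retained, "enrichments") <- attr(fits, "enrichments")
  list(retained = retained, report = report)
}

attr_or <- function(x, name, default) {
  v <- attr(x, name)
  if (is.null(v)) default else v
}
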