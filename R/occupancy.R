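#' Reference triplicate ratios from reference-only runs
#'
#' The mixed reference standard contains both a natural-abundance (light)
#' and a 15N-labeled (heavy) pool, so even a sample with no experimental
#' material shows a light/heavy ratio. Running the reference alone (in
#' triplicate) measures that baseline per peptide; it is subtracted from
#' experimental ratios by [normalize_to_reference()].
#'
#' @param ref_fits Fit table(s) from reference-only samples
#'   ([fit_peak_table()] output with 2 species, already
#'   interference-filtered); replicates are distinguished by `sample_id`.
#' @return data.frame with `peptide`, `charge`, `ref_ratio` (mean light /
#'   heavy over replicates) and `n_replicates`.
#' @export
reference_ratios <- function(ref_fits) {
  assert_that(is.data.frame(ref_fits) && all(c("a1", "a2") %in% names(ref_fits)),
              "ref_fits must be a 2-species fit table")
  assert_that(all(ref_fits$a2 > 0), "reference heavy amplitudes must be positive")
  r <- ref_fits$a1 / ref_fits$a2
  key <- paste(ref_fits$peptide, ref_fits$charge, sep = "/")
  agg <- tapply(r, key, mean)
  n <- tapply(r, key, length)
  parts <- strsplit(names(agg), "/", fixed = TRUE)
  data.frame(peptide = vapply(parts, `[[`, "", 1),
             charge = as.integer(vapply(parts, `[[`, "", 2)),
             ref_ratio = as.numeric(agg),
             n_replicates = as.integer(n))
}

#' Reference-corrected light-isotope ratio per fit
#'
#' Each spectrum is first normalized by its paired heavy (15N) abundance,
#' `r = light / heavy`; the reference standard's own light contribution
#' (mean of the reference-only triplicate for that peptide) is then
#' subtracted. Negative corrected ratios, which arise when noise pushes an
#' empty measurement below the reference baseline, are clipped to zero and
#' counted.
#'
#' @param fits 2-species fit table (light = `a1`, heavy = `a2`), filtered
#'   for interference.
#' @param reference Reference table from [reference_ratios()].
#' @return The fit table with added columns `ratio_raw` and
#'   `corrected_ratio`; rows whose peptide/charge lacks a reference pair
#'   are dropped and reported in attribute `"dropped"`; attribute
#'   `"n_clipped"` counts negative ratios clipped to 0.
#' @export
normalize_to_reference <- function(fits, reference) {
  assert_that(is.data.frame(fits) && all(c("a1", "a2") %in% names(fits)),
              "fits must be a 2-species fit table")
  assert_that(all(fits$a2 > 0), "heavy amplitude must be positive for correction")
  key <- paste(fits$peptide, fits$charge, sep = "/")
  rkey <- paste(reference$peptide, reference$charge, sep = "/")
  idx <- match(key, rkey)
  dropped <- unique(key[is.na(idx)])
  keep <- !is.na(idx)
  out <- fits[keep, , drop = FALSE]
  out$ratio_raw <- out$a1 / out$a2
  corrected <- out$ratio_raw - reference$ref_ratio[idx[keep]]
  n_clipped <- sum(corrected < 0)
  out$corrected_ratio <- pmax(corrected, 0)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Protein occupancy matrix across gradient fractions
#'
#' Converts corrected per-peptide ratios into occupancies
#' `c / (c + 1)` — the light fraction of total material when the heavy
#' reference is the unit scale — corrects each fraction for the amount of
#' sample analyzed relative to the nominal loading, takes the median over
#' peptide-charge measurements per protein and fraction, and finally scales
#' each protein to its maximum across fractions.
#'
#' @param corrected_fits Output of [normalize_to_reference()].
#' @param protein_map data.frame with `protein`, `peptide` columns (see
#'   [peptide_protein_map()]).
#' @param fraction_meta data.frame with `fraction_id` and `loading_pmol`.
#' @param nominal_loading_pmol Loading to which fractions are standardized
#'   (default 20).
#' @param normalize `"max"` (default, per-protein max = 1) or `"none"`.
#' @return Object of class `occupancy_matrix`: list with `occupancy`
#'   (protein x fraction matrix), `n_peptides` (measurement counts per
#'   cell) and `dropped_proteins` (no surviving measurements anywhere).
#' @export
protein_occupancy_matrix <- function(corrected_fits, protein_map,
                                     fraction_meta,
                                     nominal_loading_pmol = 20,
                                     normalize = c("max", "none")) {
  normalize <- match.arg(normalize)
  assert_that(all(c("protein", "peptide") %in% names(protein_map)),
              "protein_map must have protein and peptide columns")
  assert_that(all(c("fraction_id", "loading_pmol") %in% names(fraction_meta)),
              "fraction_meta must have fraction_id and loading_pmol columns")
  assert_that(all(fraction_meta$loading_pmol > 0), "loading_pmol must be positive")
  assert_that("corrected_ratio" %in% names(corrected_fits),
              "corrected_fits must come from normalize_to_reference()")

  df <- corrected_fits
  df$protein <- protein_map$protein[match(df$peptide, protein_map$peptide)]
  unmapped <- unique(df$peptide[is.na(df$protein)])
  df <- df[!is.na(df$protein), , drop = FALSE]

  df$occupancy <- df$corrected_ratio / (df$corrected_ratio + 1)
  load <- fraction_meta$loading_pmol[match(df$fraction_id,
                                           fraction_meta$fraction_id)]
  assert_that(!anyNA(load), "fits reference fractions missing from fraction_meta")
  df$occupancy <- df$occupancy / (load / nominal_loading_pmol)

  proteins <- sort(unique(protein_map$protein))
  fractions <- sort(unique(fraction_meta$fraction_id))
  occ <- matrix(NA_real_, length(proteins), length(fractions),
                dimnames = list(proteins, fractions))
  npep <- matrix(0L, length(proteins), length(fractions),
                 dimnames = list(proteins, fractions))
  if (nrow(df) > 0L) {
    med <- tapply(df$occupancy, list(factor(df$protein, proteins),
                                     factor(df$fraction_id, fractions)),
                  stats::median)
    cnt <- tapply(df$occupancy, list(factor(df$protein, proteins),
                                     factor(df$fraction_id, fractions)),
                  length)
    occ[] <- med
    npep[] <- ifelse(is.na(cnt), 0L, cnt)
  }

  empty <- rowSums(!is.na(occ)) == 0L
  dropped <- proteins[empty]
  occ <- occ[!empty, , drop = FALSE]
  npep <- npep[!empty, , drop = FALSE]

  if (normalize == "max" && nrow(occ) > 0L) {
    mx <- apply(occ, 1, max, na.rm = TRUE)
    mx[mx == 0] <- 1  # flat-zero proteins stay zero
    occ <- occ / mx
  }

  structure(list(occupancy = occ, n_peptides = npep,
                 normalization = normalize,
                 dropped_proteins = dropped,
                 unmapped_peptides = unmapped),
            class = "occupancy_matrix")
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat(sprintf("Occupancy matrix: %d proteins x %d fractions (%s-normalized)\n",
              nrow(x$occupancy), ncol(x$occupancy), x$normalization))
  if (length(x$dropped_proteins) > 0L) {
    cat("  dropped (no measurements):",
        paste(x$dropped_proteins, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Merge fit tables from two instruments
#'
#' Union of two fit tables keyed by (sample, fraction, peptide, charge);
#' when both instruments measured the same key the fit with the higher
#' r-squared is kept. A `provenance` column records the source of each
#' retained row.
#'
#' @param primary_fits,secondary_fits Fit tables with identical columns.
#' @param names Length-2 character vector labeling the sources.
#' @return Merged fit table with a `provenance` column.
#' @export
merge_datasets <- function(primary_fits, secondary_fits,
                           names = c("primary", "secondary")) {
  assert_that(is.data.frame(primary_fits) && is.data.frame(secondary_fits),
              "inputs must be data.frames")
  add_prov <- function(df, who) {
    if (nrow(df) > 0L) df$provenance <- who
    else df$provenance <- character(0)
    df
  }
  p <- add_prov(primary_fits, names[1])
  s <- add_prov(secondary_fits, names[2])
  if (nrow(s) == 0L) return(p)
  if (nrow(p) == 0L) return(s)
  keyof <- function(df) paste(df$sample_id, df$fraction_id, df$peptide,
                              df$charge, sep = "\r")
  kp <- keyof(p)
  ks <- keyof(s)
  both <- intersect(kp, ks)
  # collisions: keep the higher r-squared (primary wins exact ties)
  drop_p <- logical(nrow(p))
  drop_s <- logical(nrow(s))
  for (k in both) {
    i <- which(kp == k)[1]
    j <- which(ks == k)[1]
    if (s$r_squared[j] > p$r_squared[i]) drop_p[i] <- TRUE else drop_s[j] <- TRUE
  }
  out <- rbind(p[!drop_p, , drop = FALSE], s[!drop_s, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "enrichments") <- attr(primary_fits, "enrichments")
  out
}

#' Normalized, smoothed abundance profile of a biogenesis factor
#'
#' Spectral counts of a (non-ribosomal) protein across gradient fractions
#' are normalized to the total counts in each fraction, scaled so the
#' maximum fraction equals 1, and smoothed with a 3-tap Gaussian kernel
#' (0.25, 0.5, 0.25); at the edges the kernel is renormalized over the
#' available taps.
#'
#' @param counts Spectral counts of the protein per fraction (>= 3
#'   fractions).
#' @param fraction_totals Total spectral counts per fraction (all
#'   proteins), aligned with `counts`.
#' @return Object of class `factor_profile`: list with `normalized`
#'   (max = 1 before smoothing), `smoothed`, and `flat_zero` flag.
#' @export
factor_profile <- function(counts, fraction_totals) {
  assert_that(length(counts) >= 3L, "need at least 3 fractions")
  assert_that(length(fraction_totals) == length(counts),
              "fraction_totals must align with counts")
  assert_that(all(counts >= 0), "counts must be non-negative")
  assert_that(all(fraction_totals > 0), "fraction totals must be positive")
  rel <- counts / fraction_totals
  if (all(rel == 0)) {
    return(structure(list(normalized = rel, smoothed = rel,
                          flat_zero = TRUE), class = "factor_profile"))
  }
  normalized <- rel / max(rel)
  smoothed <- gaussian_smooth3(normalized)
  structure(list(normalized = normalized, smoothed = smoothed,
                 flat_zero = FALSE), class = "factor_profile")
}

# 3-tap Gaussian smoothing (kernel 0.25/0.5/0.25), edge-renormalized.
gaussian_smooth3 <- function(x) {
  k <- c(0.25, 0.5, 0.25)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - 1L)
    hi <- min(n, i + 1L)
    w <- k[(lo - i + 2L):(hi - i + 2L)]
    out[i] <- sum(x[lo:hi] * w) / sum(w)
  }
  out
}

#' Render an occupancy matrix as a heat map
#'
#' @param x An `occupancy_matrix`.
#' @param ... Passed to [graphics::image()].
#' @export
plot_occupancy <- function(x, ...) {
  assert_that(inherits(x, "occupancy_matrix"), "x must be an occupancy_matrix")
  m <- x$occupancy
  m[is.na(m)] <- 0
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
                  xlab = "Gradient fraction", ylab = "",
                  yaxt = "n", ...)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 2,
                 cex.axis = 0.6)
  invisible(x)
}
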