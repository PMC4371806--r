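#' Cold-sensitivity factors for a screened collection
#'
#' For each item (deletion strain or compound-treated culture) the raw
#' cold-sensitivity factor is the ratio of mean growth at 37 degrees C to
#' mean growth at 15 degrees C; factors are then normalized so that their
#' mean over the collection equals 1, and ranked in descending order (most
#' cold-sensitive first).
#'
#' Items whose mean 15 degree growth is zero have an undefined ratio: they
#' are flagged `undefined_csf`, excluded from the normalization mean, and
#' returned unranked with NA factors.
#'
#' @param records data.frame with columns `item_id`, optional `plate_id`,
#'   and one or more replicate columns per temperature named
#'   `od37_rep1, od37_rep2, ...` and `od15_rep1, od15_rep2, ...`.
#' @return data.frame with columns `item_id`, `csf_raw`, `csf_norm`,
#'   `rank` (1 = most cold-sensitive), `is_hit` (initialized FALSE; set by
#'   [select_top_fraction()]) and `undefined_csf`.
#' @examples
#' g <- data.frame(item_id = c("a", "b"),
#'                 od37_rep1 = c(1, 1), od37_rep2 = c(1, 1),
#'                 od15_rep1 = c(1, 0.25), od15_rep2 = c(1, 0.25))
#' compute_csf_table(g)
#' @export
compute_csf_table <- function(records) {
  assert_that(is.data.frame(records) && "item_id" %in% names(records),
              "records must be a data.frame with an item_id column")
  od37_cols <- grep("^od37_rep", names(records), value = TRUE)
  od15_cols <- grep("^od15_rep", names(records), value = TRUE)
  assert_that(length(od37_cols) >= 1L && length(od15_cols) >= 1L,
              "records need at least one od37_rep* and one od15_rep* column")
  od37 <- as.matrix(records[od37_cols])
  od15 <- as.matrix(records[od15_cols])
  assert_that(all(od37 >= 0, na.rm = TRUE) && all(od15 >= 0, na.rm = TRUE),
              "OD values must be non-negative")

  m37 <- rowMeans(od37)
  m15 <- rowMeans(od15)
  undefined <- m15 == 0
  csf_raw <- ifelse(undefined, NA_real_, m37 / m15)
  norm_mean <- mean(csf_raw[!undefined])
  csf_norm <- csf_raw / norm_mean

  out <- data.frame(item_id = records$item_id, csf_raw = csf_raw,
                    csf_norm = csf_norm, rank = NA_integer_,
                    is_hit = FALSE, undefined_csf = undefined)
  defined <- which(!undefined)
  # descending csf_norm; stable item order breaks ties
  ord <- defined[order(-csf_norm[defined], seq_along(defined))]
  out$rank[ord] <- seq_along(ord)
  out[order(out$rank, na.last = TRUE), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Select the top fraction of a ranked cold-sensitivity table
#'
#' Marks as hits the `k = round(fraction * N)` items with the highest
#' normalized cold-sensitivity factor, where rounding is half away from
#' zero and N counts items with a defined factor. Boundary ties are broken
#' by the stable rank order already present in the table.
#'
#' @param results Ranked table from [compute_csf_table()].
#' @param fraction Fraction of the collection to call, in (0, 1\].
#' @return The input table with `is_hit` set; attribute `"k"` records the
#'   cut size.
#' @export
select_top_fraction <- function(results, fraction) {
  assert_that(is.data.frame(results) && all(c("rank", "csf_norm") %in% names(results)),
              "results must come from compute_csf_table()")
  assert_that(is.numeric(fraction) && length(fraction) == 1L &&
                fraction > 0 && fraction <= 1,
              "fraction must be in (0, 1]")
  n <- sum(!is.na(results$rank))
  k <- as.integer(round_half_up(fraction * n))
  results$is_hit <- !is.na(results$rank) & results$rank <= k
  attr(results, "k") <- k
  results
}

#' Permutation test for functional-class enrichment among hits
#'
#' Tests whether screen hits are over-represented in one functional class
#' (e.g. a COG category). The observed statistic is the proportion of the
#' class that are hits. The null distribution is obtained by permuting the
#' class-label assignment over all items while the hit set stays fixed;
#' under permutation the number of hits landing in the class is
#' hypergeometric, which is sampled directly. The p-value uses the add-one
#' estimator `(1 + #(null >= observed)) / (1 + n_perm)`, so it is never
#' exactly zero.
#'
#' @param hits Character vector of hit item ids.
#' @param class_map data.frame with columns `gene_id` and `cog_class`
#'   covering every item in the screen (hits included).
#' @param target_class Class whose enrichment is tested.
#' @param n_perm Number of label permutations (default 1e5).
#' @param seed Integer seed for the permutation stream.
#' @return data.frame (one row) with `class_name`, `n_hits_in_class`,
#'   `n_total_in_class`, `proportion`, `p_perm`, `n_permutations`.
#' @export
cog_permutation_enrichment <- function(hits, class_map, target_class,
                                       n_perm = 1e5, seed = 1L) {
  assert_that(is.data.frame(class_map) &&
                all(c("gene_id", "cog_class") %in% names(class_map)),
              "class_map must have columns gene_id, cog_class")
  assert_that(!anyDuplicated(class_map$gene_id),
              "class_map has duplicated gene ids")
  missing <- setdiff(hits, class_map$gene_id)
  assert_that(length(missing) == 0L,
              "hits absent from class_map: ", paste(missing, collapse = ", "))
  n_class <- sum(class_map$cog_class == target_class)
  assert_that(n_class > 0L, "target class '", target_class, "' is empty")
  n_total <- nrow(class_map)
  n_hits <- length(unique(hits))

  in_class <- class_map$gene_id[class_map$cog_class == target_class]
  observed_count <- length(intersect(unique(hits), in_class))
  observed <- observed_count / n_class

  # Permuting class labels over ids fixes the class size and the hit set;
  # the null count of hits in the class is Hypergeometric(n_hits,
  # n_total - n_hits, n_class).
  withr_seed <- child_seed(seed, "cog_permutation")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(withr_seed)
  null_counts <- stats::rhyper(n_perm, m = n_hits, n = n_total - n_hits,
                               k = n_class)
  p_perm <- (1 + sum(null_counts / n_class >= observed)) / (1 + n_perm)

  data.frame(class_name = target_class,
             n_hits_in_class = observed_count,
             n_total_in_class = n_class,
             proportion = observed,
             p_perm = p_perm,
             n_permutations = n_perm)
}

# Save/restore the global RNG state so statistical functions with their own
# seed argument do not clobber the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Compound-screen hit gate
#'
#' A compound is a cold-specific growth inhibitor when its culture density
#' at 15 degrees C falls more than 3 standard deviations below the screen
#' mean while its density at 37 degrees C stays within 2 standard
#' deviations of the mean there (population standard deviations over all
#' screened compounds).
#'
#' @param od15,od37 Numeric vectors of (plate-normalized) OD600 per
#'   compound, aligned and named by compound id.
#' @return Character vector of hit compound ids (names of the input), with
#'   attribute `"criteria"` recording the two thresholds.
#' @export
compound_hit_gate <- function(od15, od37) {
  assert_that(length(od15) == length(od37),
              "od15 and od37 must have equal length")
  assert_that(length(od15) >= 3L, "need at least 3 compounds")
  assert_that(!is.null(names(od15)) || !is.null(names(od37)),
              "compound vectors must be named by compound id")
  ids <- if (!is.null(names(od15))) names(od15) else names(od37)
  lo15 <- mean(od15) - 3 * sd_pop(od15)
  lo37 <- mean(od37) - 2 * sd_pop(od37)
  hit <- od15 < lo15 & od37 > lo37
  structure(ids[hit], criteria = c(threshold_15 = lo15, threshold_37 = lo37))
}

#' Normalize plate OD values by plate median
#'
#' Divides each OD by the median OD of its plate (per measurement column),
#' removing plate-to-plate scale differences.
#'
#' @param od Numeric vector of OD values.
#' @param plate_id Plate label per value.
#' @return Normalized vector of the same length.
#' @export
normalize_plates <- function(od, plate_id) {
  assert_that(length(od) == length(plate_id),
              "od and plate_id must align")
  meds <- tapply(od, plate_id, stats::median)
  assert_that(all(meds > 0), "plate medians must be positive")
  od / as.numeric(meds[as.character(plate_id)])
}

#' Minimum inhibitory concentration from a dose-response series
#'
#' The MIC is the lowest tested concentration at which growth is inhibited
#' by more than 95 percent of the no-drug control, i.e. the first
#' concentration with OD <= 0.05 x control OD. When no concentration
#' achieves this the MIC is right-censored at the highest tested
#' concentration.
#'
#' @param concentrations Strictly increasing concentrations (uM).
#' @param od OD600 at each concentration.
#' @param od_control Positive OD600 of the untreated control.
#' @param inhibition Fractional inhibition defining the MIC (default 0.95).
#' @return Object of class `mic`: list with `value` (uM) and `censored`
#'   (TRUE when the value is a lower bound).
#' @examples
#' mic_from_dose_response(c(1, 2, 4, 8), c(0.9, 0.5, 0.04, 0.01), 1)
#' @export
mic_from_dose_response <- function(concentrations, od, od_control,
                                   inhibition = 0.95) {
  assert_that(length(concentrations) >= 1L, "empty dose series")
  assert_that(!is.unsorted(concentrations, strictly = TRUE),
              "concentrations must be strictly increasing")
  assert_that(length(od) == length(concentrations),
              "od must align with concentrations")
  assert_that(is.numeric(od_control) && od_control > 0,
              "od_control must be positive")
  below <- which(od <= (1 - inhibition) * od_control)
  if (length(below) == 0L) {
    structure(list(value = max(concentrations), censored = TRUE),
              class = "mic")
  } else {
    structure(list(value = concentrations[min(below)], censored = FALSE),
              class = "mic")
  }
}

#' @export
print.mic <- function(x, ...) {
  cat("MIC:", if (x$censored) paste0("> ", x$value) else x$value, "uM\n")
  invisible(x)
}

#' Fold shift between two MICs
#'
#' Ratio of the high-temperature to the low-temperature MIC. When the
#' numerator is right-censored (`> c`), the ratio computed from the bound
#' is itself a lower bound and the result is censored (">= fold"
#' semantics). A censored denominator makes the ratio an upper bound and is
#' flagged likewise.
#'
#' @param mic_hi,mic_lo `mic` objects (typically the permissive- and
#'   restrictive-condition MICs).
#' @return List with `fold` and `bound` in `c("exact", "lower", "upper")`.
#' @export
mic_fold_shift <- function(mic_hi, mic_lo) {
  assert_that(inherits(mic_hi, "mic") && inherits(mic_lo, "mic"),
              "arguments must be mic objects")
  fold <- mic_hi$value / mic_lo$value
  bound <- if (mic_hi$censored && !mic_lo$censored) "lower"
  else if (!mic_hi$censored && mic_lo$censored) "upper"
  else if (!mic_hi$censored && !mic_lo$censored) "exact"
  else "lower"  # both censored: bound direction dominated by numerator
  list(fold = fold, bound = bound)
}

#' Relative binding from scintillation counts
#'
#' Normalizes experimental counts-per-minute to the baseline flow-through
#' signal, giving relative association values (1 = baseline).
#'
#' @param cpm_samples Numeric vector (or named vector) of sample CPMs.
#' @param cpm_baseline Single positive baseline CPM.
#' @return Vector of `cpm_samples / cpm_baseline`, order and names
#'   preserved.
#' @export
relative_binding <- function(cpm_samples, cpm_baseline) {
  assert_that(is.numeric(cpm_baseline) && length(cpm_baseline) == 1L &&
                cpm_baseline > 0, "baseline CPM must be a single positive value")
  assert_that(all(cpm_samples >= 0), "sample CPMs must be non-negative")
  cpm_samples / cpm_baseline
}
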