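#' Default capillary-electrophoresis species assignment table
#'
#' Primer-extension products report the 5' processing state of an rRNA:
#' the mature 5' end gives the shortest cDNA, precursors extend it by a
#' characteristic number of nucleotides. The shipped table covers the
#' species quantified in 5' primer-extension assays of E. coli ribosome
#' assembly: mature 16S and its +115 nt precursor (the only immature 16S 5'
#' end observed; the transient 49 nt RNase E intermediate is not
#' detectable by this assay and is deliberately absent), and mature 23S
#' with its +3 and +7 nt precursors. Fragment sizes are nominal primer
#' positions; the 5' extension offsets are what identify each species.
#'
#' @param mature_size_16s,mature_size_23s cDNA fragment size (nt) of the
#'   mature species for each primer.
#' @return data.frame with columns `primer`, `species`, `size_nt`,
#'   `immature`.
#' @export
ce_species_table <- function(mature_size_16s = 50, mature_size_23s = 60) {
  data.frame(
    primer = c("16S", "16S", "23S", "23S", "23S"),
    species = c("16S_mature", "16S_p115", "23S_mature", "23S_p3", "23S_p7"),
    size_nt = c(mature_size_16s, mature_size_16s + 115,
                mature_size_23s, mature_size_23s + 3, mature_size_23s + 7),
    immature = c(FALSE, TRUE, FALSE, TRUE, TRUE)
  )
}

#' Assign CE peaks to rRNA species
#'
#' Each electrophoresis peak is assigned to the species whose size window
#' (`size_nt` +/- `window_nt`) contains it, per primer; windows must not
#' overlap. Peaks falling in no window are reported unassigned and excluded
#' from species totals.
#'
#' @param peaks data.frame with columns `primer`, `size_nt`,
#'   `fluorescence` (additional columns such as `sample_id`, `fraction`
#'   are carried through grouping if present).
#' @param assignments Assignment table, see [ce_species_table()].
#' @param window_nt Half-width of each size window (default 1 nt,
#'   single-nucleotide CE resolution).
#' @return List with `species` (data.frame `primer`, `species`,
#'   `immature`, `fluorescence` summed per species) and `unassigned`
#'   (rows of `peaks` not matching any window).
#' @export
assign_species <- function(peaks, assignments = ce_species_table(),
                           window_nt = 1) {
  req <- c("primer", "size_nt", "fluorescence")
  assert_that(is.data.frame(peaks) && all(req %in% names(peaks)),
              "peaks must have columns ", paste(req, collapse = ", "))
  assert_that(all(peaks$fluorescence >= 0), "fluorescence must be non-negative")
  assert_that(all(peaks$size_nt > 0), "fragment sizes must be positive")

  # windows within one primer must not overlap
  for (p in unique(assignments$primer)) {
    s <- sort(assignments$size_nt[assignments$primer == p])
    if (length(s) > 1L && any(diff(s) <= 2 * window_nt)) {
      stop_input("assignment windows overlap for primer ", p,
                 " at window half-width ", window_nt, " nt")
    }
  }

  hit_species <- rep(NA_character_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    cand <- assignments[assignments$primer == peaks$primer[i] &
                          abs(assignments$size_nt - peaks$size_nt[i]) <= window_nt, ]
    if (nrow(cand) == 1L) hit_species[i] <- cand$species
  }
  assigned <- peaks[!is.na(hit_species), , drop = FALSE]
  assigned$species <- hit_species[!is.na(hit_species)]
  totals <- assignments[c("primer", "species", "immature")]
  totals$fluorescence <- vapply(totals$species, function(sp) {
    sum(assigned$fluorescence[assigned$species == sp])
  }, numeric(1))
  list(species = totals,
       unassigned = peaks[is.na(hit_species), , drop = FALSE])
}

#' Proportion of immature rRNA for one primer
#'
#' Immature species fluorescence divided by total fluorescence over all
#' species of that primer (for 23S, immature = +3 plus +7). Each primer is
#' quantified from its own reaction, so 16S and 23S signals are never
#' combined into a single proportion.
#'
#' @param species data.frame from [assign_species()]`$species` (columns
#'   `primer`, `immature`, `fluorescence`).
#' @param primer `"16S"` or `"23S"`.
#' @return Proportion in \[0, 1\]; NA with a warning when the primer's
#'   total fluorescence is zero.
#' @examples
#' tab <- ce_species_table()
#' tab$fluorescence <- c(60, 40, 100, 0, 0)
#' immature_proportion(tab, "16S")
#' @export
immature_proportion <- function(species, primer) {
  assert_that(all(c("primer", "immature", "fluorescence") %in% names(species)),
              "species table must have primer, immature, fluorescence columns")
  sub <- species[species$primer == primer, , drop = FALSE]
  assert_that(nrow(sub) > 0L, "no species for primer ", primer)
  total <- sum(sub$fluorescence)
  if (total == 0) {
    warning("zero total fluorescence for primer ", primer,
            "; proportion undefined")
    return(NA_real_)
  }
  sum(sub$fluorescence[sub$immature]) / total
}
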