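#' Elemental composition of a peptide
#'
#' Sums the residue formulas of a peptide sequence over the CHNOS alphabet
#' and adds one water, returning atom counts and the monoisotopic mass of
#' the neutral molecule.
#'
#' @param sequence Single string over the 20 standard one-letter amino-acid
#'   codes (upper case).
#' @return An object of class `elemental_composition`: a list with `counts`
#'   (named integer vector over C, H, N, O, S) and `monoisotopic_mass` (Da).
#' @examples
#' peptide_composition("GASP")
#' @export
peptide_composition <- function(sequence) {
  assert_that(is.character(sequence) && length(sequence) == 1L,
              "sequence must be a single string")
  assert_that(nchar(sequence) > 0L, "sequence must be non-empty")
  residues <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(residues, rownames(AA_RESIDUE_COMPOSITION))
  if (length(unknown) > 0L) {
    stop_input("unknown residue(s) ", paste(unique(unknown), collapse = ", "),
               " in sequence '", sequence, "'")
  }
  counts <- colSums(AA_RESIDUE_COMPOSITION[residues, , drop = FALSE]) +
    WATER_COMPOSITION
  counts <- as.integer(counts)
  names(counts) <- colnames(AA_RESIDUE_COMPOSITION)
  structure(
    list(
      counts = counts,
      monoisotopic_mass = sum(counts * ELEMENT_MONO_MASS[names(counts)])
    ),
    class = "elemental_composition"
  )
}

#' @export
print.elemental_composition <- function(x, ...) {
  nz <- x$counts[x$counts > 0]
  cat("Elemental composition:",
      paste0(names(nz), nz, collapse = " "),
      sprintf("(monoisotopic %0.5f Da)\n", x$monoisotopic_mass))
  invisible(x)
}

# Linear convolution of two probability vectors.
conv_full <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# n-fold convolution power by binary exponentiation, trimming negligible
# tails (< 1e-18 cumulative) to keep vectors short for large atom counts.
conv_pow <- function(v, n) {
  result <- 1
  base <- v
  while (n > 0L) {
    if (n %% 2L == 1L) result <- conv_full(result, base)
    n <- n %/% 2L
    if (n > 0L) base <- conv_full(base, base)
    result <- trim_tail(result)
    base <- trim_tail(base)
  }
  result
}

trim_tail <- function(v, tol = 1e-18) {
  cs <- rev(cumsum(rev(v)))
  keep <- which(cs > tol)
  if (length(keep) == 0L) return(v[1])
  v[1:max(keep)]
}

#' Aggregate isotopologue distribution of a composition
#'
#' Convolves per-element single-atom isotope distributions into the
#' neutron-shift distribution of the whole molecule. Nitrogen may be
#' enriched in 15N: with enrichment p > 0 the single-atom nitrogen
#' distribution becomes (1 - p', p') with p' = max(p, natural 15N
#' abundance); with enrichment 0 the natural distribution is used.
#'
#' @param composition An `elemental_composition`.
#' @param enrichment_15n 15N enrichment in \[0, 1\].
#' @return Numeric vector of probabilities indexed by neutron shift
#'   (element 1 = all-lightest isotopologue); sums to 1 up to floating
#'   point rounding.
#' @export
isotopologue_distribution <- function(composition, enrichment_15n = 0) {
  assert_that(inherits(composition, "elemental_composition"),
              "composition must be an elemental_composition")
  assert_that(is.numeric(enrichment_15n) && length(enrichment_15n) == 1L &&
                enrichment_15n >= 0 && enrichment_15n <= 1,
              "enrichment_15n must be a single value in [0, 1]")
  counts <- composition$counts
  dist <- 1
  for (el in names(counts)) {
    n <- counts[[el]]
    if (n == 0L) next
    single <- NATURAL_ABUNDANCE[[el]]
    if (el == "N" && enrichment_15n > 0) {
      p <- max(enrichment_15n, NATURAL_15N)
      single <- c(1 - p, p)
    }
    dist <- conv_full(dist, conv_pow(single, n))
  }
  dist
}

#' Isotopologue m/z and probability template for a peptide species
#'
#' The forward model of the spectral fit: for one peptide, charge state and
#' 15N enrichment it predicts the stick spectrum (m/z ladder and
#' probabilities) of that labeled species. Isotopologues in the lowest tail
#' of the distribution are pruned: the smallest probabilities are dropped
#' while their cumulative sum stays below `prune_tol`.
#'
#' @param peptide Peptide sequence string.
#' @param charge Positive integer charge state.
#' @param enrichment_15n 15N enrichment in \[0, 1\].
#' @param prune_tol Maximum total probability mass that may be pruned
#'   (default 1e-10).
#' @return Object of class `isotope_template`: list with `peptide`,
#'   `charge`, `enrichment_15n`, `shift` (integer neutron shifts), `mz`
#'   (ascending) and `probability`.
#' @examples
#' tmpl <- isotope_template("SAMPLER", charge = 2, enrichment_15n = 0.5)
#' sum(tmpl$probability)
#' @export
isotope_template <- function(peptide, charge, enrichment_15n = 0,
                             prune_tol = 1e-10) {
  assert_that(is.numeric(charge) && length(charge) == 1L && charge >= 1 &&
                charge == floor(charge), "charge must be a positive integer")
  comp <- peptide_composition(peptide)
  probs <- isotopologue_distribution(comp, enrichment_15n)
  shift <- seq_along(probs) - 1L

  # prune the smallest sticks whose combined mass is below prune_tol
  ord <- order(probs)
  cum <- cumsum(probs[ord])
  drop <- ord[cum <= prune_tol]
  if (length(drop) > 0L) {
    keep <- setdiff(seq_along(probs), drop)
    probs <- probs[keep]
    shift <- shift[keep]
  }

  mz <- (comp$monoisotopic_mass + shift * ISOTOPOLOGUE_SPACING +
           charge * PROTON_MASS) / charge
  structure(
    list(peptide = peptide, charge = as.integer(charge),
         enrichment_15n = enrichment_15n,
         shift = as.integer(shift), mz = mz, probability = probs),
    class = "isotope_template"
  )
}

#' @export
print.isotope_template <- function(x, ...) {
  cat(sprintf(
    "Isotope template: %s %d+ at %.1f%% 15N; %d sticks, m/z %.4f-%.4f\n",
    x$peptide, x$charge, 100 * x$enrichment_15n, length(x$mz),
    min(x$mz), max(x$mz)))
  invisible(x)
}

#' Templates for a set of labeled species of one peptide
#'
#' @param peptide Peptide sequence.
#' @param charge Charge state.
#' @param enrichments Numeric vector of 15N enrichments, strictly
#'   increasing (e.g. `c(0, 0.99)` for natural vs fully labeled, or
#'   `c(0, 0.5, 0.99)` for a pulse experiment).
#' @param prune_tol Tail mass pruned per template.
#' @return List of `isotope_template`, named by enrichment.
#' @export
species_templates <- function(peptide, charge, enrichments,
                              prune_tol = 1e-10) {
  assert_that(length(enrichments) >= 1L && !is.unsorted(enrichments, strictly = TRUE),
              "enrichments must be strictly increasing")
  key <- paste(peptide, charge, paste(enrichments, collapse = ","),
               prune_tol, sep = "|")
  cached <- .template_cache[[key]]
  if (!is.null(cached)) return(cached)
  out <- lapply(enrichments, function(e) {
    isotope_template(peptide, charge, e, prune_tol)
  })
  names(out) <- sprintf("enr_%g", enrichments)
  .template_cache[[key]] <- out
  out
}

# memoization store for species_templates: template construction dominates
# simulation and fitting cost, and the same peptide/charge/enrichment sets
# recur across fractions and samples
.template_cache <- new.env(parent = emptyenv())

#' Dump templates as a long table
#'
#' @param templates List of `isotope_template` objects.
#' @return data.frame with columns peptide, charge, enrichment, mz,
#'   probability.
#' @export
templates_as_table <- function(templates) {
  do.call(rbind, lapply(templates, function(t) {
    data.frame(peptide = t$peptide, charge = t$charge,
               enrichment = t$enrichment_15n, mz = t$mz,
               probability = t$probability)
  }))
}
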