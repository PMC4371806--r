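#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence after every K or R except when the next
#' residue is P (the standard trypsin rule), with no missed cleavages.
#'
#' @param sequence Protein sequence over the 20 standard amino acids.
#' @param min_length,max_length Peptide length window retained
#'   (defaults 6 and 30); set `min_length = 1, max_length = Inf` for the
#'   raw digest.
#' @return Character vector of peptides in N- to C-terminal order.
#' @examples
#' tryptic_peptides("MKAILR", min_length = 1)
#' @export
tryptic_peptides <- function(sequence, min_length = 6, max_length = 30) {
  assert_that(is.character(sequence) && length(sequence) == 1L &&
                nchar(sequence) > 0L, "sequence must be a non-empty string")
  residues <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(residues, rownames(AA_RESIDUE_COMPOSITION))
  if (length(unknown) > 0L) {
    stop_input("unknown residue(s) ", paste(unique(unknown), collapse = ", "),
               " in sequence '", sequence, "'")
  }
  n <- length(residues)
  cut_after <- which(residues %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & residues[cut_after + 1L] != "P" |
                           cut_after == n]
  bounds <- c(0L, cut_after, n)
  bounds <- unique(bounds)
  peptides <- character(0)
  for (i in seq_len(length(bounds) - 1L)) {
    peptides <- c(peptides,
                  paste(residues[(bounds[i] + 1L):bounds[i + 1L]],
                        collapse = ""))
  }
  len <- nchar(peptides)
  peptides[len >= min_length & len <= max_length]
}

#' Map tryptic peptides back to their parent proteins
#'
#' @param sequences Named character vector of protein sequences.
#' @param min_length,max_length Length window passed to
#'   [tryptic_peptides()].
#' @return data.frame with columns `protein`, `peptide`.
#' @export
peptide_protein_map <- function(sequences, min_length = 6, max_length = 30) {
  assert_that(length(sequences) > 0L && !is.null(names(sequences)) &&
                all(nzchar(names(sequences))),
              "sequences must be a named character vector")
  rows <- lapply(names(sequences), function(p) {
    peps <- tryptic_peptides(sequences[[p]], min_length, max_length)
    if (length(peps) == 0L) return(NULL)
    data.frame(protein = p, peptide = peps)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(protein = character(0),
                                      peptide = character(0))
  rownames(out) <- NULL
  out
}
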