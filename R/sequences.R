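#' Deterministic random protein sequences
#'
#' Draws residues uniformly from the 20 standard amino acids. With K and R
#' together at 10 percent frequency, tryptic peptides average ~10 residues,
#' so a realistic share falls in the usual 6-30 length window.
#'
#' @param n Number of sequences.
#' @param length Residues per sequence (recycled).
#' @param seed Integer seed.
#' @param prefix Name prefix (default "prot").
#' @return Named character vector of sequences.
#' @export
random_protein_sequences <- function(n, length = 120, seed = 1L,
                                     prefix = "prot") {
  assert_that(n >= 1, "n must be positive")
  length <- rep_len(length, n)
  with_seed(seed, "sequences", {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(rownames(AA_RESIDUE_COMPOSITION), length[i],
                   replace = TRUE), collapse = "")
    }, "")
    names(seqs) <- sprintf("%s_%03d", prefix, seq_len(n))
    seqs
  })
}
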