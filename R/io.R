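# Tabular and sequence I/O. All pipeline tables are TSV with mandatory
# headers, decimal points and no thousands separators; every reader
# validates its schema and reports offending columns or lines by name.

#' Read and validate a TSV against a column schema
#'
#' @param path File path.
#' @param schema Named character vector mapping required column names to
#'   types (`"character"`, `"numeric"`, `"integer"`, `"logical"`).
#' @param optional Named character vector of optional columns, same form.
#' @return data.frame with columns coerced to the schema types; extra
#'   columns are kept as read.
#' @export
validate_and_load <- function(path, schema, optional = character(0)) {
  assert_that(file.exists(path), "file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  missing <- setdiff(names(schema), names(df))
  assert_that(length(missing) == 0L,
              "file ", path, " is missing required column(s): ",
              paste(missing, collapse = ", "))
  types <- c(schema, optional[names(optional) %in% names(df)])
  for (col in names(types)) {
    df[[col]] <- coerce_column(df[[col]], types[[col]], col, path)
  }
  df
}

coerce_column <- function(x, type, col, path) {
  if (type == "character") return(x)
  if (type == "logical") {
    out <- as.logical(x)
  } else {
    out <- suppressWarnings(as.numeric(x))
    if (type == "integer") out <- as.integer(out)
  }
  bad <- which(is.na(out) & !is.na(x) & x != "" & toupper(x) != "NA")
  if (length(bad) > 0L) {
    stop_input("malformed ", type, " in column '", col, "' of ", path,
               " at line ", bad[1] + 1L, ": '", x[bad[1]], "'")
  }
  out
}

growth_schema <- function(n_rep = 2) {
  reps <- c(paste0("od37_rep", seq_len(n_rep)),
            paste0("od15_rep", seq_len(n_rep)))
  c(item_id = "character",
    stats::setNames(rep("numeric", length(reps)), reps))
}

#' Read a two-temperature growth table
#' @param path TSV with columns `item_id`, optional `plate_id`, and
#'   replicate columns `od37_rep*`, `od15_rep*`.
#' @param n_replicates Replicates per temperature (default 2).
#' @return Validated data.frame.
#' @export
read_growth_table <- function(path, n_replicates = 2) {
  validate_and_load(path, growth_schema(n_replicates),
                    optional = c(plate_id = "character"))
}

#' Read a gene-to-functional-class map
#' @param path TSV with columns `gene_id`, `cog_class`.
#' @return Validated data.frame.
#' @export
read_class_map <- function(path) {
  validate_and_load(path, c(gene_id = "character", cog_class = "character"))
}

#' Read a dose-response table
#' @param path TSV with columns `conc_uM`, `od`.
#' @return Validated data.frame sorted by concentration.
#' @export
read_dose_response <- function(path) {
  df <- validate_and_load(path, c(conc_uM = "numeric", od = "numeric"))
  df[order(df$conc_uM), , drop = FALSE]
}

#' Read an MS1 peak-list table
#' @param path TSV with columns `sample_id`, `fraction_id`, `peptide`,
#'   `charge`, `mz`, `intensity`.
#' @return Validated data.frame.
#' @export
read_peak_table <- function(path) {
  validate_and_load(path, c(sample_id = "character",
                            fraction_id = "character",
                            peptide = "character", charge = "integer",
                            mz = "numeric", intensity = "numeric"))
}

#' Read a capillary-electrophoresis peak table
#' @param path TSV with columns `sample_id`, `fraction`, `primer`,
#'   `size_nt`, `fluorescence`.
#' @return Validated data.frame.
#' @export
read_ce_peak_table <- function(path) {
  validate_and_load(path, c(sample_id = "character", fraction = "character",
                            primer = "character", size_nt = "numeric",
                            fluorescence = "numeric"))
}

#' Read gradient fraction metadata
#' @param path TSV with columns `fraction_id`, `treatment`,
#'   `loading_pmol`.
#' @return Validated data.frame.
#' @export
read_fraction_meta <- function(path) {
  validate_and_load(path, c(fraction_id = "character",
                            treatment = "character",
                            loading_pmol = "numeric"))
}

#' Write a pipeline table as TSV
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta_proteins <- function(path) {
  assert_that(file.exists(path), "file not found: ", path)
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  ids <- names(seqs)
  dup <- unique(ids[duplicated(ids)])
  assert_that(length(dup) == 0L,
              "duplicate FASTA ids in ", path, ": ",
              paste(dup, collapse = ", "))
  out <- toupper(vapply(seqs, function(s) as.character(s)[1], ""))
  names(out) <- ids
  out
}
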