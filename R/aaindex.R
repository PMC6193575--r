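# Amino-acid property scales (AAindex) used by the property encoder.

# The 12 AAindex accessions of the default table.
AAINDEX12_IDS <- c("TSAJ990101", "MAXF760101", "NAKH920108", "BLAM930101",
                   "BIOV880101", "CEDJ970104", "NOZY710101", "KLEP840101",
                   "NAKH900109", "LIFS790101", "HUTJ700103", "MIYS990104")

#' Load an amino-acid property table
#'
#' The default table packages 12 physicochemical AAindex scales (volume,
#' secondary-structure propensity, membrane-protein composition,
#' hydrophobicity and contact-energy scales, among others), each covering
#' the 20 canonical residues. `NA` entries in the source scales are
#' replaced by 0. Any user table in the same layout (first column `aa`,
#' one named numeric column per scale) may be substituted.
#'
#' @param path Path to a property TSV; default = the packaged 12-scale table.
#' @return 20 x n_indices numeric matrix, rownames = amino-acid letters in
#'   [AA_ALPHABET] order, colnames = scale accessions.
#' @export
load_aaindex_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "aaindex12.tsv", package = "gpsuc",
                        mustWork = TRUE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (names(df)[1] != "aa") stop("property table must start with column 'aa'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$aa
  if (!setequal(rownames(m), AA_ALPHABET))
    stop("property table must cover exactly the 20 canonical residues")
  m <- m[AA_ALPHABET, , drop = FALSE]
  if (anyNA(m)) {
    warning("NA values in property table replaced by 0")
    m[is.na(m)] <- 0
  }
  storage.mode(m) <- "double"
  m
}
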