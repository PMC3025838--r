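# ---------------------------------------------------------------------------
# The regulatory-protein table: one row per modeled protein with its
# localization, quiescent (G0) level, ubiquitinators, transcriptional
# inducers, activators and inactivators.  The shipped table is the default
# model definition; interactions marked * or ** carry weaker literature
# support and are individually switchable.
# ---------------------------------------------------------------------------

#' Read the regulatory-protein specification table
#'
#' @param file TSV path; defaults to the table shipped with the package
#'   (33 proteins).
#' @return data.frame of class `ProteinSpecs` with character columns
#'   PROTEIN, LOC, G0, UBIQ, INDUCER, ACTIVATOR, INACTIVATOR, FUNCTION and
#'   list columns `ubiq`, `inducers`, `activators`, `inactivators` (parsed
#'   on `;`).
#' @export
protein_specs <- function(file = system.file("extdata", "protein_specs.tsv",
                                             package = "mitosim")) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, quote = "")
  need <- c("PROTEIN", "LOC", "G0", "UBIQ", "INDUCER", "ACTIVATOR",
            "INACTIVATOR", "FUNCTION")
  if (!all(need %in% names(df)))
    stop("protein spec table must have columns: ", paste(need, collapse = ", "))
  split_col <- function(x) lapply(strsplit(x, ";", fixed = TRUE),
                                  function(v) trimws(v[nzchar(trimws(v))]))
  df$ubiq <- split_col(df$UBIQ)
  df$inducers <- split_col(df$INDUCER)
  df$activators <- split_col(df$ACTIVATOR)
  df$inactivators <- split_col(df$INACTIVATOR)
  if (!all(df$LOC %in% c("C", "N", "CN")))
    stop("LOC must be one of C, N, CN")
  class(df) <- c("ProteinSpecs", "data.frame")
  df
}

#' Look up one protein's spec row
#' @param specs a `ProteinSpecs` table.
#' @param name protein name as in the PROTEIN column.
#' @return one-row data.frame.
#' @export
protein_spec <- function(specs, name) {
  i <- match(name, specs$PROTEIN)
  if (is.na(i)) stop(sprintf("no spec for protein '%s'", name))
  specs[i, ]
}

# internal: map table protein names to construct identifiers
cc_id <- function(name) {
  map <- c("p27" = "p27", "Rb" = "rb", "cycD" = "cycd", "Cdk2" = "cdk2",
           "cycE" = "cyce", "B-Myb" = "bmyb", "NF-Y" = "nfy", "E2F" = "e2f",
           "cycA" = "cyca", "SCF" = "scf", "Skp2" = "skp2", "Btrc" = "btrc",
           "Fbw7" = "fbw7", "TF-grow" = "tfg", "RC" = "rc",
           "DNApol" = "dnapol", "Wee1" = "wee1", "cycB" = "cycb",
           "Cdk1" = "cdk1", "Cdc25C" = "cdc25c", "Plk1" = "plk1",
           "Emi1" = "emi1", "APC" = "apc", "Cdh1" = "cdh1",
           "Cdc20" = "cdc20", "Cdc14" = "cdc14", "Cdc25A" = "cdc25a",
           "Cdc25B" = "cdc25b", "Securin" = "securin", "cycC" = "cycc",
           "KPC" = "kpc", "RNApol" = "rnapol", "eIF-4" = "eif4")
  out <- map[name]
  if (anyNA(out)) stop("unknown protein name: ",
                       paste(name[is.na(out)], collapse = ", "))
  unname(out)
}
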