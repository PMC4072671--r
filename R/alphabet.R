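#' @keywords internal
"_PACKAGE"

#' Canonical residue and class orderings
#'
#' All feature vectors, PSSM columns and model matrices use the fixed
#' alphabetical residue order `ACDEFGHIKLMNPQRSTVWY`. PSSM files written by
#' PSI-BLAST use a different column order; they are re-mapped to this one at
#' parse time.
#'
#' @format `aa_alphabet` is a character vector of the 20 standard residues;
#'   `transporter_classes` the eight dataset labels (seven substrate classes
#'   plus the non-transporter control) in the fixed tie-break order.
#' @export
aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @rdname aa_alphabet
#' @export
transporter_classes <- c("amino_acid", "anion", "cation", "electron",
                         "protein_mrna", "sugar", "other", "non_transporter")

# 400 dipeptides, row-major over the declared residue order (AA, AC, ..., YY)
dipeptide_names <- as.vector(t(outer(aa_alphabet, aa_alphabet, paste0)))

#' Construct a validated protein sequence
#'
#' @param id Sequence identifier, unique within a dataset.
#' @param residues Residue string over the 20-letter alphabet.
#' @param strict If `TRUE` (default), any letter outside the standard
#'   alphabet is an error naming the offending residue and position; if
#'   `FALSE`, such letters are dropped with a warning giving the count.
#' @return An object of class `protein_sequence` with fields `id` and
#'   `residues`.
#' @examples
#' protein_sequence("p1", "ACDE")
#' @export
protein_sequence <- function(id, residues, strict = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  letters_ <- strsplit(residues, "")[[1]]
  bad <- which(!letters_ %in% aa_alphabet)
  if (length(bad)) {
    if (strict) {
      stop(sprintf("sequence '%s': non-standard residue '%s' at position %d",
                   id, letters_[bad[1]], bad[1]), call. = FALSE)
    }
    warning(sprintf("sequence '%s': dropped %d non-standard residue(s) (%s)",
                    id, length(bad),
                    paste(unique(letters_[bad]), collapse = ",")),
            call. = FALSE)
    letters_ <- letters_[-bad]
    residues <- paste(letters_, collapse = "")
  }
  structure(list(id = id, residues = residues), class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s (%d aa)\n", x$id, nchar(x$residues)))
  invisible(x)
}

seq_length <- function(seq) nchar(seq$residues)

seq_letters <- function(seq) strsplit(seq$residues, "")[[1]]

as_protein_sequences <- function(x) {
  if (inherits(x, "protein_sequence")) return(list(x))
  stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "protein_sequence")))
  x
}
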