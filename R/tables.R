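# Configuration tables backing the AAI and PHC encoders.

the <- new.env(parent = emptyenv())

#' Load a biochemical property table
#'
#' The AAI encoder averages 49 residue-level physical, chemical, energetic
#' and conformational property scales over a sequence. The table is shipped
#' as configuration data, not code: a TSV with one row per property (first
#' column the property identifier, an AAindex accession) and 20 residue
#' columns holding 0-1 normalized values. The default table bundled with the
#' package is derived from the AAindex database (49 scales, each min-max
#' normalized); users can substitute their own subset.
#'
#' @param path Path to a property TSV; default is the bundled table.
#' @return A 49 x 20 numeric matrix, rows named by property, columns in
#'   [aa_alphabet] order.
#' @export
load_property_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aaindex49_synthetic.tsv",
                        package = "transpec", mustWork = TRUE)
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!identical(colnames(m), aa_alphabet)) {
    if (!setequal(colnames(m), aa_alphabet)) {
      stop("property table must have the 20 residue columns", call. = FALSE)
    }
    m <- m[, aa_alphabet, drop = FALSE]
  }
  if (nrow(m) != 49L) {
    stop("property table must have exactly 49 rows, found ", nrow(m),
         call. = FALSE)
  }
  if (!all(is.finite(m)) || any(m < 0) || any(m > 1)) {
    stop("property table entries must be finite and in [0, 1]", call. = FALSE)
  }
  m
}

#' Load the physico-chemical residue class table
#'
#' Eleven named, overlapping residue classes (charged, aliphatic, aromatic,
#' polar, neutral, hydrophobic, positively/negatively charged, tiny, small,
#' large) used by the PHC encoder. The bundled table reproduces the
#' published class memberships verbatim, under which the polar and neutral
#' sets coincide; a warning notes this once per session, and a corrected
#' table can be supplied instead.
#'
#' @param path Path to a YAML file mapping class names to residue vectors;
#'   default is the bundled table.
#' @return A named list of 11 character vectors of residues.
#' @export
load_residue_classes <- function(path = NULL) {
  default <- is.null(path)
  if (default) {
    path <- system.file("extdata", "residue_classes.yaml",
                        package = "transpec", mustWork = TRUE)
  }
  cls <- yaml::read_yaml(path)
  if (length(cls) != 11L) {
    stop("residue class table must define exactly 11 classes, found ",
         length(cls), call. = FALSE)
  }
  cls <- lapply(cls, as.character)
  bad <- unlist(cls)[!unlist(cls) %in% aa_alphabet]
  if (length(bad)) {
    stop("residue class table contains non-residue letters: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  if (default && is.null(the$warned_identical_classes)) {
    key <- vapply(cls, function(x) paste(sort(x), collapse = ""), "")
    if (anyDuplicated(key)) {
      dup <- names(cls)[duplicated(key) | duplicated(key, fromLast = TRUE)]
      message("note: residue classes ", paste(dup, collapse = " and "),
              " have identical membership under the default table")
      the$warned_identical_classes <- TRUE
    }
  }
  cls
}
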