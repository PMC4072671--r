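# Sequence, PSSM-profile and manifest input/output.

# PSI-BLAST writes profile columns in this order; parsed files are re-mapped
# to aa_alphabet order.
psiblast_order <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a (multi-record) FASTA file; wrapped or unwrapped
#'   lines are both accepted.
#' @param strict If `TRUE` (default) sequences containing letters outside the
#'   20-residue alphabet (B, J, O, U, X, Z, `*`, ...) are rejected with an
#'   error; if `FALSE` those letters are dropped and a warning reports the
#'   count per sequence.
#' @return A list of [protein_sequence()] objects in file order.
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(raw) != "")
  if (!length(nonblank)) stop("empty FASTA file: ", path, call. = FALSE)
  if (!startsWith(trimws(raw[nonblank[1]]), ">")) {
    stop(sprintf("malformed FASTA (%s): line %d is not a header line",
                 path, nonblank[1]), call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  mapply(protein_sequence, ids, as.character(set),
         MoreArgs = list(strict = strict),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs List of [protein_sequence()] objects.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_protein_sequences(seqs)
  set <- Biostrings::AAStringSet(vapply(seqs, `[[`, "", "residues"))
  names(set) <- vapply(seqs, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a PSI-BLAST ASCII PSSM profile
#'
#' Parses the standard `-out_ascii_pssm` layout: header lines, then one row
#' per query position holding the position index, the query residue, 20
#' log-odds columns, 20 weighted-percentage columns and trailing per-position
#' statistics. Only the log-odds block is kept; columns are re-mapped from
#' PSI-BLAST order to the package's alphabetical residue order.
#'
#' @param path Path to the ASCII PSSM file.
#' @param sequence_id Identifier to attach; defaults to the file base name.
#' @return A `pssm_profile`: list with `sequence_id`, `query_residues`
#'   (length-L string) and `scores` (integer L x 20 matrix, columns named by
#'   residue).
#' @export
read_pssm_ascii <- function(path, sequence_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sequence_id)) {
    sequence_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  is_row <- vapply(toks, function(tk) {
    length(tk) >= 3L && grepl("^[0-9]+$", tk[1]) && grepl("^[A-Za-z]$", tk[2])
  }, TRUE)
  if (!any(is_row)) stop("no PSSM rows found in ", path, call. = FALSE)
  rows <- toks[is_row]
  residues <- character(length(rows))
  scores <- matrix(0L, length(rows), 20L,
                   dimnames = list(NULL, psiblast_order))
  for (i in seq_along(rows)) {
    tk <- rows[[i]]
    res <- toupper(tk[2])
    if (!res %in% aa_alphabet) {
      stop(sprintf("PSSM %s row %d: residue column holds '%s'",
                   path, i, tk[2]), call. = FALSE)
    }
    num <- tk[-(1:2)]
    num <- num[grepl("^-?[0-9.]+$", num)]
    # 40 profile columns; per-position information/weight stats are floats
    ints <- num[grepl("^-?[0-9]+$", num)]
    if (length(ints) < 40L) {
      stop(sprintf("PSSM %s row %d: expected 40 numeric profile columns, found %d",
                   path, i, length(ints)), call. = FALSE)
    }
    residues[i] <- res
    scores[i, ] <- as.integer(ints[1:20])
  }
  scores <- scores[, aa_alphabet, drop = FALSE]
  structure(list(sequence_id = sequence_id,
                 query_residues = paste(residues, collapse = ""),
                 scores = scores),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("<pssm_profile> %s: %d positions x 20 residues\n",
              x$sequence_id, nrow(x$scores)))
  invisible(x)
}

#' Write a PSSM profile in the PSI-BLAST ASCII dialect
#'
#' Emits the full 40-column layout (log-odds block followed by a percentage
#' block derived from the scores) plus per-position statistics and the
#' K/Lambda footer, so that files are parseable by [read_pssm_ascii()] and
#' by other tools expecting the standard format.
#'
#' @param profile A `pssm_profile`.
#' @param path Output path.
#' @export
write_pssm_ascii <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"))
  sc <- profile$scores[, psiblast_order, drop = FALSE]
  res <- strsplit(profile$query_residues, "")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
    paste("Last position-specific scoring matrix computed, weighted observed",
          "percentages rounded down, information per position, and relative",
          "weight of gapless real matches to pseudocounts")), con)
  writeLines(paste0("           ",
                    paste(sprintf("%3s", psiblast_order), collapse = " "), "  ",
                    paste(sprintf("%3s", psiblast_order), collapse = " ")), con)
  for (i in seq_len(nrow(sc))) {
    w <- exp(sc[i, ] / 2)
    pct <- floor(100 * w / sum(w))
    writeLines(paste0(sprintf("%5d %s  ", i, res[i]),
                      paste(sprintf("%3d", sc[i, ]), collapse = " "), "  ",
                      paste(sprintf("%3d", pct), collapse = " "),
                      sprintf("  %4.2f %4.2f", 0.5, 0.1)), con)
  }
  writeLines(c("", "                      K         Lambda",
               "Standard Ungapped    0.1365     0.3176",
               "Standard Gapped      0.0410     0.2670"), con)
  invisible(path)
}

#' Read a labelled dataset manifest
#'
#' A manifest is a two-column tab-separated file mapping each sequence id to
#' one of the eight class labels.
#'
#' @param path Path to the TSV (no header).
#' @return A data frame with columns `sequence_id` and `class_label`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sequence_id", "class_label"),
                          colClasses = "character", quote = "")
  dup <- df$sequence_id[duplicated(df$sequence_id)]
  if (length(dup)) {
    stop("duplicate sequence id(s) in manifest: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$class_label), transporter_classes)
  if (length(bad)) {
    stop(sprintf("unknown class label(s) %s; valid labels: %s",
                 paste(bad, collapse = ", "),
                 paste(transporter_classes, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Write a dataset manifest
#'
#' @param manifest Data frame with `sequence_id` and `class_label` columns.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("sequence_id", "class_label") %in% names(manifest)))
  utils::write.table(manifest[, c("sequence_id", "class_label")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
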