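# Fixed-length sequence descriptors: amino acid composition (AAC, 20),
# dipeptide composition (DPC, 400), physico-chemical class composition
# (PHC, 11), averaged biochemical properties (AAI, 49) and the summed
# PSSM profile (PSSM, 400), plus their concatenated hybrids.

feature_vector <- function(values, encoder) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  structure(values, encoder = encoder, class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s (%d components)\n",
              attr(x, "encoder"), length(x)))
  invisible(x)
}

#' Encoder tag of a feature vector or matrix
#' @param x A `feature_vector` or a feature matrix.
#' @return The encoder tag string, e.g. `"AAC"` or `"AAI+PSSM"`.
#' @export
encoder_tag <- function(x) attr(x, "encoder")

#' Amino acid composition (AAC)
#'
#' The percentage of each of the 20 residues in the sequence: component
#' i = 100 * count(residue i) / L. Components sum to 100.
#'
#' @param seq A [protein_sequence()].
#' @return A `feature_vector` with 20 components in [aa_alphabet] order.
#' @examples
#' encode_aac(protein_sequence("p", "ACDE"))
#' @export
encode_aac <- function(seq) {
  stopifnot(inherits(seq, "protein_sequence"))
  L <- seq_length(seq)
  if (L < 1L) stop("cannot encode an empty sequence", call. = FALSE)
  counts <- table(factor(seq_letters(seq), levels = aa_alphabet))
  feature_vector(stats::setNames(100 * as.numeric(counts) / L, aa_alphabet),
                 "AAC")
}

#' Dipeptide composition (DPC)
#'
#' The percentage of each of the 400 ordered residue pairs among the L - 1
#' consecutive pairs of the sequence: component XY = 100 * count(XY) / (L-1).
#' Components sum to 100; ordering is row-major over the residue order
#' (AA, AC, ..., YY).
#'
#' @param seq A [protein_sequence()] of length >= 2.
#' @return A `feature_vector` with 400 components.
#' @export
encode_dpc <- function(seq) {
  stopifnot(inherits(seq, "protein_sequence"))
  L <- seq_length(seq)
  if (L < 2L) {
    stop("dipeptide composition requires length >= 2, got ", L, call. = FALSE)
  }
  lt <- seq_letters(seq)
  pairs <- paste0(lt[-L], lt[-1])
  counts <- table(factor(pairs, levels = dipeptide_names))
  feature_vector(stats::setNames(100 * as.numeric(counts) / (L - 1),
                                 dipeptide_names), "DPC")
}

#' Physico-chemical class composition (PHC)
#'
#' The percentage of residues falling in each of 11 overlapping
#' physico-chemical classes (charged, aliphatic, aromatic, polar, neutral,
#' hydrophobic, positively charged, negatively charged, tiny, small, large).
#' Because classes overlap, the components do not sum to a constant.
#'
#' @param seq A [protein_sequence()].
#' @param classes Residue class table, see [load_residue_classes()].
#' @return A `feature_vector` with 11 components.
#' @export
encode_phc <- function(seq, classes = load_residue_classes()) {
  stopifnot(inherits(seq, "protein_sequence"))
  L <- seq_length(seq)
  if (L < 1L) stop("cannot encode an empty sequence", call. = FALSE)
  lt <- seq_letters(seq)
  vals <- vapply(classes, function(members) 100 * sum(lt %in% members) / L,
                 0.0)
  feature_vector(vals, "PHC")
}

#' Averaged biochemical property composition (AAI)
#'
#' For each of 49 residue-level property scales (0-1 normalized AAindex
#' subset), the mean property value over the residues of the sequence;
#' each component therefore lies in [0, 1].
#'
#' @param seq A [protein_sequence()].
#' @param table 49 x 20 property matrix, see [load_property_table()].
#' @return A `feature_vector` with 49 components named by property.
#' @export
encode_aai <- function(seq, table = load_property_table()) {
  stopifnot(inherits(seq, "protein_sequence"))
  L <- seq_length(seq)
  if (L < 1L) stop("cannot encode an empty sequence", call. = FALSE)
  lt <- seq_letters(seq)
  missing_ <- setdiff(lt, colnames(table))
  if (length(missing_)) {
    stop("residue(s) absent from property table: ",
         paste(missing_, collapse = ", "), call. = FALSE)
  }
  feature_vector(rowMeans(table[, lt, drop = FALSE]), "AAI")
}

#' Summed PSSM profile descriptor
#'
#' Collapses an L x 20 PSSM into 400 components indexed by (query residue a,
#' profile column b): the sum of `scores[pos, b]` over all positions whose
#' query residue is `a`, divided by the sequence length L. The 400-vector is
#' then min-max scaled to [0, 1]; if all components are equal the degenerate
#' vector of 0.5s is returned.
#'
#' @param profile A `pssm_profile`, see [read_pssm_ascii()].
#' @param scale If `TRUE` (default) apply the per-vector min-max scaling;
#'   `FALSE` returns the length-normalized sums unscaled (useful when a
#'   caller wants dataset-level scaling instead).
#' @return A `feature_vector` with 400 components named row-major
#'   (query residue, profile residue).
#' @export
encode_pssm <- function(profile, scale = TRUE) {
  stopifnot(inherits(profile, "pssm_profile"))
  res <- strsplit(profile$query_residues, "")[[1]]
  L <- length(res)
  sums <- matrix(0, 20L, 20L, dimnames = list(aa_alphabet, aa_alphabet))
  for (a in unique(res)) {
    sums[a, ] <- colSums(profile$scores[res == a, , drop = FALSE])
  }
  v <- as.vector(t(sums)) / L
  names(v) <- dipeptide_names
  if (scale) {
    rng <- range(v)
    v <- if (rng[1] == rng[2]) {
      stats::setNames(rep(0.5, length(v)), names(v))
    } else {
      (v - rng[1]) / (rng[2] - rng[1])
    }
  }
  feature_vector(v, "PSSM")
}

#' Concatenate feature vectors into a hybrid descriptor
#'
#' Hybrid encoders (e.g. AAI+PSSM, 49 + 400 = 449 components) are the
#' concatenation of their parts in the given order, with component names
#' prefixed by the part's encoder tag.
#'
#' @param parts A list of `feature_vector`s computed from the same sequence.
#' @return A `feature_vector` whose encoder tag joins the part tags with
#'   `+`.
#' @export
encode_hybrid <- function(parts) {
  if (!length(parts)) stop("empty parts list", call. = FALSE)
  stopifnot(all(vapply(parts, inherits, TRUE, "feature_vector")))
  tags <- vapply(parts, encoder_tag, "")
  vals <- unlist(lapply(parts, function(p) {
    stats::setNames(as.numeric(p), paste0(encoder_tag(p), ".", names(p)))
  }))
  feature_vector(vals, paste(tags, collapse = "+"))
}

#' Encode a set of sequences into a feature matrix
#'
#' @param seqs List of [protein_sequence()] objects.
#' @param encoder One of `"AAC"`, `"DPC"`, `"PHC"`, `"AAI"`, `"PSSM"` or a
#'   `+`-joined hybrid such as `"AAI+PSSM"`.
#' @param pssms Named list of `pssm_profile`s (by sequence id); required by
#'   PSSM-using encoders.
#' @param property_table,classes Optional overrides for the AAI/PHC tables.
#' @return A numeric matrix, one row per sequence (rownames = ids), with an
#'   `encoder` attribute.
#' @export
encode_sequences <- function(seqs, encoder = "AAC", pssms = NULL,
                             property_table = NULL, classes = NULL) {
  seqs <- as_protein_sequences(seqs)
  parts_tags <- strsplit(encoder, "+", fixed = TRUE)[[1]]
  known <- c("AAC", "DPC", "PHC", "AAI", "PSSM")
  if (!length(parts_tags) || !all(parts_tags %in% known)) {
    stop("unknown encoder '", encoder, "'; parts must be among ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  if ("AAI" %in% parts_tags && is.null(property_table)) {
    property_table <- load_property_table()
  }
  if ("PHC" %in% parts_tags && is.null(classes)) {
    classes <- load_residue_classes()
  }
  ids <- vapply(seqs, `[[`, "", "id")
  if ("PSSM" %in% parts_tags) {
    missing_ <- setdiff(ids, names(pssms))
    if (length(missing_)) {
      stop("missing PSSM profile(s) for sequence id(s): ",
           paste(missing_, collapse = ", "), call. = FALSE)
    }
  }
  encode_one <- function(seq) {
    parts <- lapply(parts_tags, function(tag) {
      switch(tag,
             AAC  = encode_aac(seq),
             DPC  = encode_dpc(seq),
             PHC  = encode_phc(seq, classes),
             AAI  = encode_aai(seq, property_table),
             PSSM = encode_pssm(pssms[[seq$id]]))
    })
    if (length(parts) == 1L) parts[[1]] else encode_hybrid(parts)
  }
  rows <- lapply(seqs, encode_one)
  m <- do.call(rbind, lapply(rows, as.numeric))
  dimnames(m) <- list(ids, names(rows[[1]]))
  attr(m, "encoder") <- encoder
  m
}

#' Per-class composition means and across-class variance
#'
#' For each residue, the mean amino acid composition (percent) within each
#' class and the variance of those class means across classes. Residues with
#' a high across-class variance are the ones that discriminate transporter
#' classes compositionally.
#'
#' @param seqs List of [protein_sequence()] objects.
#' @param labels Class label per sequence (character, parallel to `seqs`).
#' @return A list with `class_means` (classes x 20 matrix) and `variance`
#'   (named length-20 vector).
#' @export
composition_summary <- function(seqs, labels) {
  seqs <- as_protein_sequences(seqs)
  labels <- as.character(labels)
  stopifnot(length(labels) == length(seqs))
  classes <- unique(labels)
  if (length(classes) < 2L) {
    stop("composition summary needs at least 2 classes", call. = FALSE)
  }
  empty <- classes[!classes %in% labels]
  if (length(empty)) stop("class with zero members: ", empty, call. = FALSE)
  aac <- t(vapply(seqs, function(s) as.numeric(encode_aac(s)),
                  numeric(20L)))
  colnames(aac) <- aa_alphabet
  means <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(aac[labels == cl, , drop = FALSE])
  }))
  rownames(means) <- classes
  list(class_means = means, variance = apply(means, 2, stats::var))
}

#' Write / read a feature matrix as TSV
#'
#' The encoder tag is stored on a leading comment line so that models and
#' feature files can be checked for consistency.
#'
#' @param x Feature matrix from [encode_sequences()].
#' @param path File path.
#' @return `read_feature_matrix` returns the matrix with its `encoder`
#'   attribute restored.
#' @export
write_feature_matrix <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# encoder: ", attr(x, "encoder")), con)
  writeLines(paste(c("sequence_id", colnames(x)), collapse = "\t"), con)
  utils::write.table(data.frame(sequence_id = rownames(x), x,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  encoder <- if (startsWith(first, "# encoder:")) {
    trimws(sub("^# encoder:", "", first))
  } else NA_character_
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, quote = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  attr(m, "encoder") <- encoder
  m
}
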