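# Seeded synthetic datasets. Real transporter classes differ in the
# composition of a handful of residues (notably D, E, K, F, G, I, L, S show
# the highest across-class variance); the generator reproduces that
# structure by perturbing class-specific triples of those residues around a
# common background, so that composition-based encoders are the
# discriminative channel. PSSM fixtures emulate conservation: the true
# residue's column scores high, the rest low.

# Swiss-Prot-like background residue frequencies (alphabetical order)
background_frequencies <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0672, F = 0.0386, G = 0.0708,
  H = 0.0227, I = 0.0593, K = 0.0581, L = 0.0965, M = 0.0241, N = 0.0406,
  P = 0.0472, Q = 0.0393, R = 0.0553, S = 0.0660, T = 0.0535, V = 0.0687,
  W = 0.0110, Y = 0.0292)
background_frequencies <- background_frequencies / sum(background_frequencies)

# residues with the highest across-class compositional variance in real
# transporter data; each synthetic class up-weights three of them
high_variance_residues <- c("D", "E", "K", "F", "G", "I", "L", "S")

#' Class-specific residue frequency profiles
#'
#' Starts from a common background frequency vector and, for each of the
#' eight classes, adds `separation / 3` to each of a class-specific triple
#' of high-variance residues (class k up-weights triples drawn cyclically
#' from D, E, K, F, G, I, L, S), then renormalizes. `separation = 0` gives
#' eight identical profiles; larger values move the profiles apart
#' monotonically in L1 distance.
#'
#' @param separation Non-negative scale of the class-specific frequency
#'   perturbation (probability mass added per class).
#' @param mean_length,length_dispersion Sequence length model: lengths are
#'   log-normal around `mean_length` with log-scale standard deviation
#'   `length_dispersion`, floored at 30 residues.
#' @return A named list of eight `class_profile` objects (fields
#'   `class_label`, `frequencies`, `mean_length`, `length_dispersion`,
#'   `signature`).
#' @export
make_class_profiles <- function(separation = 0.15, mean_length = 200,
                                length_dispersion = 0.25) {
  stopifnot(separation >= 0, mean_length >= 10)
  profiles <- lapply(seq_along(transporter_classes), function(k) {
    sig <- high_variance_residues[(k - 1 + 0:2) %% 8 + 1]
    freq <- background_frequencies
    freq[sig] <- freq[sig] + separation / 3
    floor_ <- 1e-4
    if (any(freq < floor_)) {
      freq <- pmax(freq, floor_)
      message("class profile ", transporter_classes[k],
              ": frequencies clipped at floor ", floor_)
    }
    freq <- freq / sum(freq)
    structure(list(class_label = transporter_classes[k], frequencies = freq,
                   mean_length = mean_length,
                   length_dispersion = length_dispersion, signature = sig),
              class = "class_profile")
  })
  names(profiles) <- transporter_classes
  profiles
}

#' Sample sequences from a class profile
#'
#' Residues are drawn i.i.d. from the profile's frequency vector; lengths
#' are log-normal around the profile's mean length (floored at 30).
#'
#' @param profile A `class_profile` from [make_class_profiles()].
#' @param n Number of sequences.
#' @param seed Integer seed; `NULL` uses the current RNG state (so callers
#'   such as [make_dataset()] can seed once globally).
#' @return A list of [protein_sequence()] objects with ids
#'   `<class>_<i>`.
#' @export
sample_sequences <- function(profile, n, seed = NULL) {
  stopifnot(inherits(profile, "class_profile"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  lens <- pmax(30L, round(stats::rlnorm(n, log(profile$mean_length),
                                        profile$length_dispersion)))
  lapply(seq_len(n), function(i) {
    protein_sequence(sprintf("%s_%03d", profile$class_label, i),
                     paste(sample(aa_alphabet, lens[i], replace = TRUE,
                                  prob = profile$frequencies),
                           collapse = ""))
  })
}

#' Sample a conservation-shaped PSSM for a sequence
#'
#' At every position the column matching the true residue scores around
#' `+conservation * s_max` and all other columns around
#' `-conservation * s_max`, plus Gaussian noise of standard deviation
#' `noise`; scores are rounded to integers, as in PSI-BLAST output.
#'
#' @param seq A [protein_sequence()].
#' @param conservation Conservation strength in (0, 1].
#' @param noise Additive score noise (standard deviation, score units).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param s_max Score ceiling (default 10, a typical log-odds magnitude).
#' @return A `pssm_profile` aligned to `seq`.
#' @export
sample_pssm <- function(seq, conservation = 0.9, noise = 2, seed = NULL,
                        s_max = 10) {
  stopifnot(inherits(seq, "protein_sequence"),
            conservation > 0, conservation <= 1, noise >= 0)
  if (!is.null(seed)) set.seed(seed)
  lt <- seq_letters(seq)
  L <- length(lt)
  m <- matrix(-conservation * s_max, L, 20L,
              dimnames = list(NULL, aa_alphabet))
  m[cbind(seq_len(L), match(lt, aa_alphabet))] <- conservation * s_max
  m <- m + stats::rnorm(L * 20L, 0, noise)
  structure(list(sequence_id = seq$id,
                 query_residues = seq$residues,
                 scores = matrix(as.integer(round(m)), L, 20L,
                                 dimnames = list(NULL, aa_alphabet))),
            class = "pssm_profile")
}

#' Generate a labelled synthetic dataset
#'
#' Draws `n_per_class` sequences for each of the eight classes from
#' [make_class_profiles()] and attaches a manifest; optionally samples a
#' conservation-shaped PSSM per sequence and, if `dir` is given, writes the
#' FASTA, manifest TSV and per-sequence ASCII PSSM files to disk in the
#' formats the readers of this package accept.
#'
#' @param n_per_class Sequences per class (>= 10 recommended for CV use).
#' @param separation Between-class compositional separation, see
#'   [make_class_profiles()].
#' @param seed Integer seed governing all sampling.
#' @param with_pssm Also sample PSSM profiles.
#' @param pssm_conservation,pssm_noise Passed to [sample_pssm()].
#' @param mean_length,length_dispersion Passed to [make_class_profiles()].
#' @param dir Optional output directory for fixture files.
#' @return A list with `sequences`, `manifest` (data frame), `pssms` (named
#'   list or `NULL`), `profiles` and, when `dir` is given, `paths`.
#' @export
make_dataset <- function(n_per_class = 30, separation = 0.15, seed = 1L,
                         with_pssm = FALSE, pssm_conservation = 0.9,
                         pssm_noise = 2, mean_length = 200,
                         length_dispersion = 0.25, dir = NULL) {
  stopifnot(n_per_class >= 1)
  profiles <- make_class_profiles(separation, mean_length, length_dispersion)
  set.seed(seed)
  sequences <- list()
  pssms <- if (with_pssm) list() else NULL
  for (pf in profiles) {
    cls_seqs <- sample_sequences(pf, n_per_class)
    sequences <- c(sequences, cls_seqs)
    if (with_pssm) {
      for (s in cls_seqs) {
        pssms[[s$id]] <- sample_pssm(s, pssm_conservation, pssm_noise)
      }
    }
  }
  manifest <- data.frame(
    sequence_id = vapply(sequences, `[[`, "", "id"),
    class_label = rep(transporter_classes, each = n_per_class))
  out <- list(sequences = sequences, manifest = manifest, pssms = pssms,
              profiles = profiles)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(fasta = file.path(dir, "sequences.fasta"),
                  manifest = file.path(dir, "manifest.tsv"))
    write_fasta(sequences, paths$fasta)
    write_manifest(manifest, paths$manifest)
    if (with_pssm) {
      pssm_dir <- file.path(dir, "pssm")
      dir.create(pssm_dir, showWarnings = FALSE)
      for (p in pssms) {
        write_pssm_ascii(p, file.path(pssm_dir, paste0(p$sequence_id, ".pssm")))
      }
      paths$pssm_dir <- pssm_dir
    }
    out$paths <- paths
  }
  out
}
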