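test_that("amino acid composition matches hand counts", {
  v <- encode_aac(protein_sequence("p", "AAAA"))
  expect_equal(v[["A"]], 100)
  expect_equal(sum(v), 100)
  v <- encode_aac(protein_sequence("p", "ACDE"))
  expect_equal(unname(as.numeric(v[c("A", "C", "D", "E")])), rep(25, 4))
  v <- encode_aac(protein_sequence("p", "AAC"))
  expect_equal(v[["A"]], 100 * 2 / 3)
  expect_equal(v[["C"]], 100 / 3)
  expect_length(v, 20)
  expect_equal(encoder_tag(v), "AAC")
})

test_that("dipeptide composition counts consecutive pairs over L-1", {
  v <- encode_dpc(protein_sequence("p", "AAA"))
  expect_equal(v[["AA"]], 100)
  v <- encode_dpc(protein_sequence("p", "ACAC"))  # pairs AC, CA, AC
  expect_equal(v[["AC"]], 100 * 2 / 3)
  expect_equal(v[["CA"]], 100 / 3)
  v <- encode_dpc(protein_sequence("p", "AC"))
  expect_equal(v[["AC"]], 100)
  expect_length(v, 400)
  expect_error(encode_dpc(protein_sequence("p", "A")), "length")
})

test_that("AAC and DPC sum to 100 for random sequences", {
  set.seed(7)
  for (i in 1:50) {
    s <- random_sequence(sample(2:400, 1))
    expect_equal(sum(encode_aac(s)), 100, tolerance = 1e-12)
    expect_equal(sum(encode_dpc(s)), 100, tolerance = 1e-12)
  }
})

test_that("AAC of a homopolymer is independent of its length", {
  base <- as.numeric(encode_aac(protein_sequence("p", "W")))
  for (k in c(2, 17, 240)) {
    s <- protein_sequence("p", strrep("W", k))
    expect_equal(as.numeric(encode_aac(s)), base)
  }
})

test_that("physico-chemical composition follows the printed class table", {
  v <- encode_phc(protein_sequence("p", "RRRR"))
  expect_length(v, 11)
  on <- c("charged", "polar", "neutral", "positively_charged", "large")
  expect_equal(unname(as.numeric(v[on])), rep(100, 5))
  expect_equal(unname(as.numeric(v[setdiff(names(v), on)])),
               rep(0, 6))
  v <- encode_phc(protein_sequence("p", "IIII"))
  expect_equal(unname(as.numeric(v[c("aliphatic", "hydrophobic", "small")])),
               rep(100, 3))
  # D and R: overlapping memberships hand-counted from the table
  v <- encode_phc(protein_sequence("p", "DR"))
  expect_equal(v[["charged"]], 100)
  expect_equal(v[["polar"]], 100)
  expect_equal(v[["neutral"]], 100)
  expect_equal(v[["negatively_charged"]], 50)
  expect_equal(v[["positively_charged"]], 50)
  expect_equal(v[["tiny"]], 50)
  expect_equal(v[["large"]], 50)
  expect_equal(v[["hydrophobic"]], 0)
})

test_that("polar and neutral classes coincide under the default table", {
  cls <- load_residue_classes()
  expect_setequal(cls$polar, cls$neutral)
})

test_that("biochemical property averaging obeys the homopolymer identity and column bounds", {
  tab <- load_property_table()
  expect_equal(dim(tab), c(49L, 20L))
  expect_true(all(tab >= 0 & tab <= 1))
  v <- encode_aai(protein_sequence("p", "GGGG"), tab)
  expect_equal(as.numeric(v), unname(tab[, "G"]))
  expect_length(v, 49)
  v <- encode_aai(protein_sequence("p", "AG"), tab)
  expect_equal(as.numeric(v), unname((tab[, "A"] + tab[, "G"]) / 2))
  set.seed(3)
  for (i in 1:20) {
    s <- random_sequence(sample(5:100, 1))
    v <- as.numeric(encode_aai(s, tab))
    lo <- apply(tab[, unique(strsplit(s$residues, "")[[1]]), drop = FALSE], 1, min)
    hi <- apply(tab[, unique(strsplit(s$residues, "")[[1]]), drop = FALSE], 1, max)
    expect_true(all(v >= lo - 1e-12 & v <= hi + 1e-12))
  }
})

test_that("PSSM descriptor sums rows per query residue, scales to [0,1]", {
  # one-position profile, query A, scores 1..20: before scaling the A-row
  # holds 1..20 and the other 380 cells 0; min-max lands on [0, 1]
  p <- structure(list(sequence_id = "x", query_residues = "A",
                      scores = matrix(1:20, 1, 20,
                                      dimnames = list(NULL, aa_alphabet))),
                 class = "pssm_profile")
  raw <- encode_pssm(p, scale = FALSE)
  expect_equal(unname(as.numeric(raw[paste0("A", aa_alphabet)])), 1:20)
  expect_equal(sum(as.numeric(raw)), sum(1:20))
  v <- encode_pssm(p)
  expect_equal(min(v), 0)
  expect_equal(max(v), 1)
  expect_equal(v[["AY"]], 1)   # largest score lands on column Y
  expect_length(v, 400)

  # an all-zero profile makes every component equal; the degenerate
  # min-max rule maps the whole vector to 0.5
  p$scores[] <- 0L
  expect_equal(unname(as.numeric(encode_pssm(p))), rep(0.5, 400))
})

test_that("PSSM descriptor is invariant to joint row/query permutation", {
  set.seed(21)
  s <- random_sequence(40)
  p <- sample_pssm(s, 0.8, 3)
  perm <- sample(40)
  letters_ <- strsplit(s$residues, "")[[1]]
  p2 <- structure(list(sequence_id = "x",
                       query_residues = paste(letters_[perm], collapse = ""),
                       scores = p$scores[perm, , drop = FALSE]),
                  class = "pssm_profile")
  expect_equal(as.numeric(encode_pssm(p2)), as.numeric(encode_pssm(p)))
})

test_that("hybrid encoders concatenate parts with prefixed names", {
  s <- protein_sequence("p", "ACDEFGHIKL")
  aai <- encode_aai(s)
  pssm <- encode_pssm(sample_pssm(s, 0.9, 1, seed = 2))
  hyb <- encode_hybrid(list(aai, pssm))
  expect_length(hyb, 449)
  expect_equal(encoder_tag(hyb), "AAI+PSSM")
  expect_true(all(startsWith(names(hyb)[1:49], "AAI.")))
  expect_true(all(startsWith(names(hyb)[50:449], "PSSM.")))
  expect_length(encode_hybrid(list(encode_aac(s), encode_dpc(s))), 420)
  single <- encode_hybrid(list(aai))
  expect_equal(as.numeric(single), as.numeric(aai))
  expect_error(encode_hybrid(list()), "empty")
})

test_that("encoders are deterministic", {
  s <- protein_sequence("p", "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")
  p <- sample_pssm(s, 0.9, 2, seed = 5)
  expect_identical(encode_aac(s), encode_aac(s))
  expect_identical(encode_dpc(s), encode_dpc(s))
  expect_identical(encode_phc(s), encode_phc(s))
  expect_identical(encode_aai(s), encode_aai(s))
  expect_identical(encode_pssm(p), encode_pssm(p))
})

test_that("composition summary gives per-class means and across-class variance", {
  a <- lapply(1:3, function(i) protein_sequence(paste0("a", i), "AAAA"))
  c_ <- lapply(1:3, function(i) protein_sequence(paste0("c", i), "CCCC"))
  lab <- rep(c("cation", "sugar"), each = 3)
  cs <- composition_summary(c(a, c_), lab)
  expect_equal(dim(cs$class_means), c(2L, 20L))
  expect_length(cs$variance, 20)
  # class means 100 vs 0 for A: two-point sample variance is 5000
  expect_equal(cs$variance[["A"]], stats::var(c(100, 0)))
  expect_equal(cs$variance[["W"]], 0)

  same <- composition_summary(c(a, a), lab)
  expect_equal(unname(same$variance), rep(0, 20))
  expect_error(composition_summary(a, rep("cation", 3)), "2 classes")
})

test_that("feature matrices carry encoder tags through file round-trips", {
  ds <- make_dataset(n_per_class = 3, separation = 0.2, seed = 4)
  x <- encode_sequences(ds$sequences, "AAC")
  expect_equal(dim(x), c(24L, 20L))
  expect_equal(attr(x, "encoder"), "AAC")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(x, f)
  back <- read_feature_matrix(f)
  expect_equal(attr(back, "encoder"), "AAC")
  expect_equal(unname(back), unname(x), tolerance = 1e-12)
  expect_equal(rownames(back), rownames(x))
})
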