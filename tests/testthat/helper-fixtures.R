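# Shared fixtures and independent oracles.

random_sequence <- function(len, id = "r") {
  protein_sequence(id, paste(sample(aa_alphabet, len, replace = TRUE),
                             collapse = ""))
}

# O(n^2) rank-statistic oracle for the AUC: P(score+ > score-) + 0.5 P(tie)
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# two well-separated Gaussian clouds in 2D, positive at the origin
separable_clouds <- function(n = 30, gap = 8, sd = 0.5, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n, 0, sd), ncol = 2),
             matrix(rnorm(2 * n, gap, sd), ncol = 2))
  colnames(x) <- c("f1", "f2")
  list(x = x, y = rep(c(TRUE, FALSE), each = n))
}

# minimal 4-position PSSM fixture with known integers, in transpec's
# alphabetical column order
fixture_pssm <- function(id = "fix") {
  set.seed(9)
  scores <- matrix(as.integer(sample(-8:12, 80, replace = TRUE)), 4, 20,
                   dimnames = list(NULL, aa_alphabet))
  structure(list(sequence_id = id, query_residues = "ACDE", scores = scores),
            class = "pssm_profile")
}
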