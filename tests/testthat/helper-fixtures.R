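# Shared fixtures and independent oracles for the test suite.

# Desk-scale model preset used by the end-to-end and acceptance tests: a
# small instance of the dual-pathway architecture plus a compact descriptor
# set, sized so repeated training runs stay cheap.
desk_descriptors <- function() {
  descriptor_config(enabled_groups = c("global_physchem", "aac",
                                       "structure_fractions", "length"))
}

desk_architecture <- function() {
  architecture_spec(conv1_filters = 8, conv2_filters = 16,
                    embedding_dim = 8, recurrent_hidden = 8,
                    max_sequence_length = 400)
}

desk_train <- function(seed = 0, epochs = 20) {
  train_config(learning_rate = 0.01, epochs = epochs, seed = seed)
}

tiny_records <- function() {
  tibble::tibble(
    id = c("p1", "p2", "p3", "p4"),
    sequence = c("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
                 "ACDEFGHIKLMNPQRSTVWY",
                 "LLLLLVVVVVIIIIIFFFFFKRAAAA",
                 "DEDEDEDEKRKRKKEELSSTT"))
}

write_tmp_fasta <- function(records, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "seqs.fasta")
  write_fasta(records, path)
  path
}

# Independent silhouette oracle: literal per-sample evaluation of
# (b - a) / max(a, b) with explicit loops over a precomputed distance matrix.
silhouette_oracle <- function(X, cl) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  scores <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(cl == cl[i]), i)
    if (length(same) == 0) { scores[i] <- 0; next }
    a <- mean(vapply(same, d, numeric(1), i = i))
    b <- Inf
    for (k in setdiff(unique(cl), cl[i])) {
      b <- min(b, mean(vapply(which(cl == k), d, numeric(1), i = i)))
    }
    scores[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(scores)
}

# Independent pseudo-amino-acid composition oracle: literal recursion with
# explicit double loops over the published formulas.
paac_oracle <- function(sequence, rank, weight) {
  aas <- strsplit(sequence, "")[[1]]
  norm <- function(h) (h - mean(h)) / sqrt(mean((h - mean(h))^2))
  h1 <- norm(secretrain:::PAAC_HYDROPHOBICITY[secretrain:::AA_ALPHABET])
  h2 <- norm(secretrain:::PAAC_HYDROPHILICITY[secretrain:::AA_ALPHABET])
  m <- norm(secretrain:::PAAC_SIDECHAIN_MASS[secretrain:::AA_ALPHABET])
  L <- length(aas)
  theta <- numeric(rank)
  for (k in seq_len(rank)) {
    acc <- 0
    for (i in seq_len(L - k)) {
      ri <- aas[i]; rj <- aas[i + k]
      acc <- acc + ((h1[rj] - h1[ri])^2 + (h2[rj] - h2[ri])^2 +
                      (m[rj] - m[ri])^2) / 3
    }
    theta[k] <- acc / (L - k)
  }
  f <- table(factor(aas, levels = secretrain:::AA_ALPHABET)) / L
  denom <- sum(f) + weight * sum(theta)
  c(as.numeric(f), weight * theta) / denom
}

# Brute-force confusion-matrix oracle.
confusion_oracle <- function(truth, predicted) {
  tab <- table(factor(truth, levels = c(0, 1)),
               factor(predicted, levels = c(0, 1)))
  list(tp = tab["1", "1"], tn = tab["0", "0"],
       fp = tab["0", "1"], fn = tab["1", "0"])
}
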