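# Dual-pathway classifier: configuration, encoding, parameter handling,
# supervised training (Adam on the weighted cross-entropy) and prediction.
# The numerical kernels (forward pass, BPTT) live in src/nn.cpp.

VOCABULARY_SIZE <- 21L  # 20 residues + unknown token; padding index is 0

#' Dual-pathway architecture specification
#'
#' The feature branch runs two valid 1-D convolution/ReLU/max-pool stages
#' over the selected descriptor vector; the sequence branch embeds residues
#' and runs a bidirectional LSTM whose two final states are concatenated; a
#' single affine layer over the fused representation yields the secretion
#' probability.
#'
#' @param conv1_filters,conv2_filters Filters in the two convolution stages.
#' @param conv_kernel Convolution kernel size.
#' @param pool_kernel Max-pooling kernel (and stride).
#' @param embedding_dim Residue embedding dimension.
#' @param recurrent_hidden LSTM hidden units per direction.
#' @param bidirectional Must be `TRUE`; kept explicit for clarity.
#' @param max_sequence_length Sequences longer than this are truncated at the
#'   carboxy end (amino-terminal signal peptides are the strongest known
#'   secretion cue, so the amino end is preserved).
#' @return A named list of class `architecture_spec`.
#' @export
architecture_spec <- function(conv1_filters = 64, conv_kernel = 3,
                              pool_kernel = 2, conv2_filters = 128,
                              embedding_dim = 128, recurrent_hidden = 128,
                              bidirectional = TRUE,
                              max_sequence_length = 2000) {
  check_number(conv1_filters, "conv1_filters", 1, integer = TRUE)
  check_number(conv2_filters, "conv2_filters", 1, integer = TRUE)
  check_number(conv_kernel, "conv_kernel", 1, integer = TRUE)
  check_number(pool_kernel, "pool_kernel", 2, 2, integer = TRUE)
  check_number(embedding_dim, "embedding_dim", 1, integer = TRUE)
  check_number(recurrent_hidden, "recurrent_hidden", 1, integer = TRUE)
  check_number(max_sequence_length, "max_sequence_length", 1,
               integer = TRUE)
  if (!isTRUE(bidirectional)) {
    stop_secretrain("the sequence branch is bidirectional by design",
                    "config_error")
  }
  structure(list(conv1_filters = as.integer(conv1_filters),
                 conv_kernel = as.integer(conv_kernel),
                 pool_kernel = as.integer(pool_kernel),
                 conv2_filters = as.integer(conv2_filters),
                 embedding_dim = as.integer(embedding_dim),
                 recurrent_hidden = as.integer(recurrent_hidden),
                 bidirectional = TRUE,
                 max_sequence_length = as.integer(max_sequence_length)),
            class = "architecture_spec")
}

#' Supervised training configuration
#'
#' @param learning_rate Adam learning rate (default 2e-5, the published
#'   setting).
#' @param epochs Optimization epochs for the initial supervised phase
#'   (default 100, the published setting).
#' @param batch_size Minibatch size; `NULL` (default) trains full-batch.
#' @param class_weights Named weights for `positive` and `negative`; `NULL`
#'   derives them from the class frequencies as `N / (2 * N_c)`.
#' @param seed Seed for parameter initialization and batch shuffling.
#' @return A named list of class `train_config`.
#' @export
train_config <- function(learning_rate = 2e-5, epochs = 100,
                         batch_size = NULL, class_weights = NULL,
                         seed = 42) {
  check_number(learning_rate, "learning_rate", lower = 1e-12)
  check_number(epochs, "epochs", lower = 0, integer = TRUE)
  if (!is.null(batch_size)) {
    check_number(batch_size, "batch_size", lower = 1, integer = TRUE)
  }
  if (!is.null(class_weights)) {
    stopifnot(all(c("positive", "negative") %in% names(class_weights)),
              all(is.finite(unlist(class_weights))),
              all(unlist(class_weights) > 0))
  }
  check_number(seed, "seed", integer = TRUE)
  structure(list(learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = batch_size,
                 class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Class weights inversely proportional to class frequencies
#'
#' `w_c = N / (2 * N_c)`, normalized so a balanced dataset gets unit weights.
#'
#' @param n_positive,n_negative Class counts.
#' @return Named list with `positive` and `negative` weights.
#' @export
class_weights_from_counts <- function(n_positive, n_negative) {
  n <- n_positive + n_negative
  list(positive = n / (2 * n_positive), negative = n / (2 * n_negative))
}

#' Encode a protein sequence as integer tokens
#'
#' Residues map alphabetically (A = 1 ... Y = 20); any other code (X after
#' normalization) maps to the unknown token 21. Sequences longer than
#' `max_sequence_length` keep their amino-terminal prefix; shorter ones are
#' right-padded with 0.
#'
#' @param sequence A normalized amino-acid sequence.
#' @param spec An [architecture_spec()].
#' @return Integer vector of length `spec$max_sequence_length`.
#' @export
encode_sequence <- function(sequence, spec = architecture_spec()) {
  codes <- seq_codes(sequence)
  codes[is.na(codes)] <- VOCABULARY_SIZE
  n <- min(length(codes), spec$max_sequence_length)
  out <- integer(spec$max_sequence_length)
  out[seq_len(n)] <- codes[seq_len(n)]
  out
}

# Token matrix (rows = records) trimmed to the longest sequence in the batch.
encode_batch <- function(sequences, spec) {
  lens <- pmin(nchar(sequences), spec$max_sequence_length)
  lmax <- max(1L, max(lens))
  toks <- matrix(0L, length(sequences), lmax)
  for (i in seq_along(sequences)) {
    codes <- seq_codes(sequences[i])
    codes[is.na(codes)] <- VOCABULARY_SIZE
    toks[i, seq_len(lens[i])] <- codes[seq_len(lens[i])]
  }
  list(tokens = toks, lengths = as.integer(lens))
}

conv_out_length <- function(n_feat, spec) {
  k <- spec$conv_kernel
  n1 <- n_feat - k + 1
  n2 <- n1 %/% 2
  n3 <- n2 - k + 1
  n4 <- n3 %/% 2
  if (n1 < 1 || n3 < 1 || n4 < 1) {
    stop_secretrain(sprintf(
      "feature branch needs more input features (%d) for two conv/pool stages",
      n_feat), "dimension_error")
  }
  n4
}

# Glorot-style uniform initialization; fully determined by the R RNG state.
init_params <- function(n_feat, spec) {
  H <- spec$recurrent_hidden
  E <- spec$embedding_dim
  F1 <- spec$conv1_filters
  F2 <- spec$conv2_filters
  K <- spec$conv_kernel
  n4 <- conv_out_length(n_feat, spec)
  d_head <- F2 * n4 + 2 * H
  u <- function(nr, nc) {
    r <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -r, r), nr, nc)
  }
  emb <- u(VOCABULARY_SIZE + 1L, E)
  emb[1, ] <- 0   # padding row
  list(emb = emb,
       lstm_f_Wx = u(E, 4 * H), lstm_f_Wh = u(H, 4 * H),
       lstm_f_b = numeric(4 * H),
       lstm_b_Wx = u(E, 4 * H), lstm_b_Wh = u(H, 4 * H),
       lstm_b_b = numeric(4 * H),
       conv1_W = u(F1, K), conv1_b = numeric(F1),
       conv2_W = u(F2, F1 * K), conv2_b = numeric(F2),
       head_w = as.numeric(u(d_head, 1)), head_b = 0)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

feature_matrix_for <- function(features, ids, feature_names) {
  rows <- match(ids, features$protein_id)
  if (anyNA(rows)) {
    stop_secretrain("feature matrix is missing rows for some records",
                    "missing_record")
  }
  missing_cols <- setdiff(feature_names, names(features))
  if (length(missing_cols) > 0) {
    stop_secretrain(sprintf(
      "feature matrix lacks fitted feature column(s): %s",
      paste(utils::head(missing_cols, 5), collapse = ", ")),
      "dimension_error")
  }
  as.matrix(features[rows, feature_names])
}

#' Weighted binary cross-entropy
#'
#' Mean over samples of the class-weighted log loss, with probabilities
#' clamped to `[1e-7, 1 - 1e-7]`. Unit weights recover the plain binary
#' cross-entropy.
#'
#' @param probabilities Predicted probabilities in (0, 1).
#' @param labels 0/1 labels.
#' @param weights Per-sample weights (e.g. the class weight of each label).
#' @return Non-negative scalar loss.
#' @export
weighted_bce <- function(probabilities, labels, weights = 1) {
  if (!all(labels %in% c(0, 1))) {
    stop_secretrain("labels must be 0 or 1", "value_error")
  }
  eps <- 1e-7
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  w <- rep_len(weights, length(p))
  -mean(w * (labels * log(p) + (1 - labels) * log(1 - p)))
}

# One Adam pass over the data. `penalty` is a list(coef, lo, hi, reg_ids) or
# NULL; reg rows enter the objective through the soft positive-proportion
# band only. Returns params, optimizer state and the per-epoch loss trace.
run_adam <- function(params, X, tokens, lengths, y, w, reg, penalty,
                     config, epochs, adam = NULL) {
  if (is.null(adam)) adam <- adam_init(params)
  coef <- if (is.null(penalty)) 0 else penalty$coef
  lo <- if (is.null(penalty)) 0 else penalty$lo
  hi <- if (is.null(penalty)) 1 else penalty$hi
  n <- length(y)
  bs <- config$batch_size %||% n
  trace <- numeric(0)
  for (ep in seq_len(epochs)) {
    idx_all <- if (bs >= n) list(seq_len(n)) else {
      sh <- sample.int(n)
      split(sh, ceiling(seq_along(sh) / bs))
    }
    ep_bce <- 0
    ep_pen <- 0
    nb <- 0
    for (idx in idx_all) {
      step <- nn_step_cpp(params, X[idx, , drop = FALSE],
                          tokens[idx, , drop = FALSE], lengths[idx],
                          y[idx], w[idx], reg[idx], lo, hi, coef)
      upd <- adam_update(params, step$grads, adam, config$learning_rate)
      params <- upd$params
      adam <- upd$state
      ep_bce <- ep_bce + step$loss_bce
      ep_pen <- ep_pen + step$penalty
      nb <- nb + 1
    }
    trace <- c(trace, ep_bce / nb + ep_pen / nb)
  }
  list(params = params, adam = adam, loss_history = trace)
}

#' Fit the dual-pathway classifier on labeled data
#'
#' Trains the convolutional-plus-bidirectional-LSTM network with Adam on the
#' class-weighted binary cross-entropy. Class weights default to
#' `N / (2 * N_c)`.
#'
#' @param features Standardized feature tibble (see [standardize_features()])
#'   whose non-id columns are the selected descriptors.
#' @param records Tibble with `id` and `sequence` for at least every labeled
#'   protein.
#' @param labels Tibble with `id` and `label` (`positive` / `negative` rows
#'   are used).
#' @param config A [train_config()].
#' @param spec An [architecture_spec()].
#' @return A `secretrain_model` object with elements `params`, `spec`,
#'   `feature_names`, `loss_history`.
#' @export
fit_supervised <- function(features, records, labels,
                           config = train_config(),
                           spec = architecture_spec()) {
  lab <- labels[labels$label %in% c("positive", "negative"), ]
  if (length(unique(lab$label)) < 2) {
    stop_secretrain("training labels must contain both classes",
                    "degenerate_training")
  }
  feature_names <- setdiff(names(features), "protein_id")
  X <- feature_matrix_for(features, lab$id, feature_names)
  seqs <- records$sequence[match(lab$id, records$id)]
  if (anyNA(seqs)) {
    stop_secretrain("labels refer to ids without sequence records",
                    "missing_record")
  }
  y <- as.numeric(lab$label == "positive")
  cw <- config$class_weights %||%
    class_weights_from_counts(sum(y == 1), sum(y == 0))
  w <- ifelse(y == 1, cw$positive, cw$negative)
  withr::with_seed(config$seed, {
    params <- init_params(ncol(X), spec)
    enc <- encode_batch(seqs, spec)
    fit <- run_adam(params, X, enc$tokens, enc$lengths, y, w,
                    reg = integer(length(y)), penalty = NULL,
                    config = config, epochs = config$epochs)
  })
  structure(list(params = fit$params, spec = spec,
                 feature_names = feature_names,
                 seed = config$seed,
                 loss_history = fit$loss_history),
            class = "secretrain_model")
}

# Shared prediction engine: encodes once, processes length-sorted chunks so
# padding work tracks the true sequence lengths, and evaluates one or many
# parameter sets on the same encodings.
predict_probabilities_multi <- function(param_list, spec, feature_names,
                                        features, records, chunk = 512L) {
  X <- feature_matrix_for(features, records$id, feature_names)
  n <- nrow(records)
  ord <- order(nchar(records$sequence))
  probs <- matrix(0, n, length(param_list))
  for (start in seq(1, n, by = chunk)) {
    idx <- ord[start:min(start + chunk - 1, n)]
    enc <- encode_batch(records$sequence[idx], spec)
    Xc <- X[idx, , drop = FALSE]
    for (m in seq_along(param_list)) {
      probs[idx, m] <- nn_forward_cpp(param_list[[m]], Xc, enc$tokens,
                                      enc$lengths)
    }
  }
  probs
}

predict_probabilities <- function(params, spec, feature_names, features,
                                  records, chunk = 512L) {
  probs <- predict_probabilities_multi(list(params), spec, feature_names,
                                       features, records, chunk)
  tibble::tibble(id = records$id, probability = probs[, 1])
}

#' Predict secretion probabilities
#'
#' @param object A fitted `secretrain_model`.
#' @param features Feature tibble covering all `records` (same scaling as at
#'   fit time).
#' @param records Tibble with `id` and `sequence`.
#' @param ... Unused.
#' @return A tibble with `id` and `probability`.
#' @export
predict.secretrain_model <- function(object, features, records, ...) {
  predict_probabilities(object$params, object$spec, object$feature_names,
                        features, records)
}

#' @export
print.secretrain_model <- function(x, ...) {
  cat("<secretrain_model>\n")
  cat(sprintf("  features: %d | embedding %d | LSTM %d/dir | conv %d>%d\n",
              length(x$feature_names), x$spec$embedding_dim,
              x$spec$recurrent_hidden, x$spec$conv1_filters,
              x$spec$conv2_filters))
  if (length(x$loss_history) > 0) {
    cat(sprintf("  trained %d epochs, final loss %.5f\n",
                length(x$loss_history), utils::tail(x$loss_history, 1)))
  }
  invisible(x)
}
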