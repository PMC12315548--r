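# Biologically constrained self-training: pseudo-label selection at the
# confidence extremes, a decaying penalty keeping the predicted secretory
# proportion inside a prior band, the combined objective, the fixed-iteration
# loop and the ensemble of identically structured members.

#' Self-training configuration
#'
#' Defaults follow the published settings: top/bottom 1% pseudo-labels, 60
#' iterations, penalty weight 20 decaying by 0.95 per iteration, prior band
#' 30-40% secretory, 3 ensemble members.
#'
#' @param pseudo_fraction Fraction of the unlabeled pool taken as
#'   pseudo-positives and (separately) pseudo-negatives each iteration.
#' @param max_iterations Fixed number of self-training iterations (no early
#'   stopping).
#' @param lambda_initial Initial penalty coefficient.
#' @param decay Per-iteration penalty decay factor (1 disables decay).
#' @param band_lower,band_upper Prior band for the positive proportion.
#' @param ensemble_size Number of ensemble members (identical architecture,
#'   member seeds `seed + 0 ... seed + size - 1`).
#' @param epochs_per_iteration Retraining epochs per iteration (warm start).
#' @param accumulate_pseudo Keep pseudo-labels across iterations instead of
#'   re-selecting from the full pool (default `FALSE`: fresh selection).
#' @param reg_subsample Size of the fixed unlabeled subsample entering the
#'   soft positive-proportion estimate.
#' @param seed Base seed.
#' @return A named list of class `selftrain_config`.
#' @export
selftrain_config <- function(pseudo_fraction = 0.01, max_iterations = 60,
                             lambda_initial = 20, decay = 0.95,
                             band_lower = 0.30, band_upper = 0.40,
                             ensemble_size = 3, epochs_per_iteration = 5,
                             accumulate_pseudo = FALSE,
                             reg_subsample = 500, seed = 42) {
  check_number(pseudo_fraction, "pseudo_fraction", lower = 0,
               upper = 0.5 - 1e-12)
  check_number(max_iterations, "max_iterations", lower = 0, integer = TRUE)
  check_number(lambda_initial, "lambda_initial", lower = 0)
  check_number(decay, "decay", lower = 1e-12, upper = 1)
  check_number(band_lower, "band_lower", lower = 1e-12, upper = 1 - 1e-12)
  check_number(band_upper, "band_upper", lower = band_lower,
               upper = 1 - 1e-12)
  if (band_lower >= band_upper) {
    stop_secretrain("band_lower must be below band_upper", "config_error")
  }
  check_number(ensemble_size, "ensemble_size", lower = 1, integer = TRUE)
  check_number(epochs_per_iteration, "epochs_per_iteration", lower = 1,
               integer = TRUE)
  check_number(reg_subsample, "reg_subsample", lower = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  structure(list(pseudo_fraction = pseudo_fraction,
                 max_iterations = as.integer(max_iterations),
                 lambda_initial = lambda_initial, decay = decay,
                 band_lower = band_lower, band_upper = band_upper,
                 ensemble_size = as.integer(ensemble_size),
                 epochs_per_iteration = as.integer(epochs_per_iteration),
                 accumulate_pseudo = isTRUE(accumulate_pseudo),
                 reg_subsample = as.integer(reg_subsample),
                 seed = as.integer(seed)),
            class = "selftrain_config")
}

#' Select pseudo-labels at the confidence extremes
#'
#' Takes the `floor(fraction * N)` lowest-probability pool members as
#' pseudo-negatives and the same number of highest-probability members as
#' pseudo-positives. Ties break by stable (probability, id) ordering; any
#' overlap between the two selections (tiny pools) is removed from both
#' sides.
#'
#' @param predictions Tibble with `id` and `probability`, restricted to the
#'   unlabeled pool.
#' @param fraction Selection fraction per side, in (0, 0.5).
#' @return A list with `pseudo_positive_ids`, `pseudo_negative_ids`,
#'   `theta_pos`, `theta_neg`.
#' @export
select_pseudo_labels <- function(predictions, fraction = 0.01) {
  if (fraction <= 0 || fraction >= 0.5) {
    stop_secretrain("pseudo fraction must lie in (0, 0.5)", "config_error")
  }
  n <- nrow(predictions)
  k <- floor(fraction * n)
  if (k == 0) {
    rlang::warn("pool too small for the pseudo-label fraction; selecting none")
    return(list(pseudo_positive_ids = character(0),
                pseudo_negative_ids = character(0),
                theta_pos = NA_real_, theta_neg = NA_real_))
  }
  ord <- order(predictions$probability, predictions$id)
  neg <- predictions$id[ord[seq_len(k)]]
  pos <- predictions$id[rev(ord)[seq_len(k)]]
  overlap <- intersect(neg, pos)
  neg <- setdiff(neg, overlap)
  pos <- setdiff(pos, overlap)
  probs <- predictions$probability
  list(pseudo_positive_ids = pos,
       pseudo_negative_ids = neg,
       theta_pos = if (length(pos)) min(probs[predictions$id %in% pos]) else NA_real_,
       theta_neg = if (length(neg)) max(probs[predictions$id %in% neg]) else NA_real_)
}

#' Prior-proportion penalty
#'
#' Zero while the positive proportion lies inside the prior band; outside it
#' the distance to the nearest bound is scaled by the decaying coefficient
#' `lambda_initial * decay^g`.
#'
#' @param p_positive Predicted positive proportion in `[0, 1]`.
#' @param g Self-training iteration (0-based in the decay exponent).
#' @param config A [selftrain_config()].
#' @return Non-negative penalty value.
#' @export
prior_penalty <- function(p_positive, g, config = selftrain_config()) {
  check_number(g, "g", lower = 0, integer = TRUE)
  coef <- config$lambda_initial * config$decay^g
  if (p_positive < config$band_lower) {
    coef * (config$band_lower - p_positive)
  } else if (p_positive > config$band_upper) {
    coef * (p_positive - config$band_upper)
  } else {
    0
  }
}

#' Combined self-training loss
#'
#' Weighted cross-entropy plus the prior-proportion penalty; both addends
#' are also reported separately.
#'
#' @param probabilities,labels,weights As for [weighted_bce()].
#' @param p_positive,g,config As for [prior_penalty()].
#' @return A list with `bce`, `penalty`, `total`.
#' @export
combined_loss <- function(probabilities, labels, weights = 1,
                          p_positive, g, config = selftrain_config()) {
  bce <- weighted_bce(probabilities, labels, weights)
  pen <- prior_penalty(p_positive, g, config)
  list(bce = bce, penalty = pen, total = bce + pen)
}

#' Average predictions over ensemble members
#'
#' @param fit A `selftrain_fit` object.
#' @param features,records As for [predict.secretrain_model()].
#' @return A tibble with `id` and `probability` (member mean).
#' @export
ensemble_predict <- function(fit, features, records) {
  if (length(fit$members) == 0) {
    stop_secretrain("no fitted ensemble members", "state_error")
  }
  probs <- predict_probabilities_multi(fit$members, fit$spec,
                                       fit$feature_names, features, records)
  tibble::tibble(id = records$id, probability = rowMeans(probs))
}

#' Run the biologically constrained self-training loop
#'
#' Starts from per-member supervised fits (member seeds derived from the
#' base seed), then for each iteration: averages member probabilities over
#' the unlabeled pool, selects pseudo-labels at the confidence extremes,
#' and retrains every member for a few epochs on the labeled-plus-pseudo
#' union under the combined loss, whose penalty term keeps a differentiable
#' soft positive proportion -- the mean probability over the labeled set,
#' the pseudo members and a fixed unlabeled subsample, a stand-in for the
#' positive-prediction census of the entire dataset -- inside the prior
#' band. A hard
#' census (fraction of probabilities >= 0.5 over all records) is logged per
#' iteration. No early stopping is applied.
#'
#' @param features Standardized feature tibble covering labeled and pool
#'   records.
#' @param records Tibble with `id`, `sequence` for all proteins.
#' @param labels Tibble with `id`, `label`; `unlabeled` rows form the pool.
#' @param config A [selftrain_config()].
#' @param train A [train_config()] for the initial supervised phase (its
#'   learning rate is reused during retraining).
#' @param spec An [architecture_spec()].
#' @return A `selftrain_fit` with `members`, `trace`, `pseudo`, `iteration`.
#' @export
run_self_training <- function(features, records, labels,
                              config = selftrain_config(),
                              train = train_config(),
                              spec = architecture_spec()) {
  lab <- labels[labels$label %in% c("positive", "negative"), ]
  pool_ids <- labels$id[labels$label == "unlabeled"]
  if (length(pool_ids) == 0) {
    rlang::warn("empty unlabeled pool: self-training degenerates to supervised training")
  }
  feature_names <- setdiff(names(features), "protein_id")
  y_lab <- as.numeric(lab$label == "positive")
  cw <- train$class_weights %||%
    class_weights_from_counts(sum(y_lab == 1), sum(y_lab == 0))

  members <- list()
  for (m in seq_len(config$ensemble_size)) {
    cfg_m <- train_config(learning_rate = train$learning_rate,
                          epochs = train$epochs,
                          batch_size = train$batch_size,
                          class_weights = cw,
                          seed = config$seed + (m - 1L))
    fit_m <- fit_supervised(features, records, labels, cfg_m, spec)
    members[[m]] <- fit_m$params
  }

  all_records <- records[records$id %in% c(lab$id, pool_ids), ]
  reg_unlab <- withr::with_seed(config$seed, {
    if (length(pool_ids) > config$reg_subsample) {
      sample(pool_ids, config$reg_subsample)
    } else {
      pool_ids
    }
  })

  state <- structure(list(members = members, spec = spec,
                          feature_names = feature_names,
                          iteration = 0L, seed = config$seed,
                          config = config,
                          pseudo = list(pseudo_positive_ids = character(0),
                                        pseudo_negative_ids = character(0)),
                          trace = NULL),
                     class = "selftrain_fit")

  trace_row <- function(g, bce, pen, p_soft, preds_all) {
    tibble::tibble(iteration = g, loss_bce = bce, penalty = pen,
                   loss_total = bce + pen,
                   p_positive_soft = p_soft,
                   p_positive_hard = mean(preds_all$probability >= 0.5),
                   n_pseudo_positive = length(state$pseudo$pseudo_positive_ids),
                   n_pseudo_negative = length(state$pseudo$pseudo_negative_ids))
  }

  # Iteration-0 row: supervised model, no pseudo-labels, penalty at g = 0.
  preds_all <- ensemble_predict(state, features, all_records)
  lab_probs <- preds_all$probability[match(lab$id, preds_all$id)]
  reg_ids0 <- unique(c(lab$id, reg_unlab))
  p_soft <- mean(preds_all$probability[match(reg_ids0, preds_all$id)])
  bce0 <- weighted_bce(lab_probs, y_lab,
                       ifelse(y_lab == 1, cw$positive, cw$negative))
  state$trace <- trace_row(0L, bce0, prior_penalty(p_soft, 0, config),
                           p_soft, preds_all)

  if (length(pool_ids) == 0 || config$max_iterations == 0) return(state)

  for (g in seq_len(config$max_iterations)) {
    # Pseudo-labels come from the current ensemble's pool predictions; the
    # pass computed at the end of the previous iteration is exactly that.
    pool_preds <- preds_all[match(pool_ids, preds_all$id), ]
    sel <- if (config$pseudo_fraction > 0) {
      select_pseudo_labels(pool_preds, config$pseudo_fraction)
    } else {
      list(pseudo_positive_ids = character(0),
           pseudo_negative_ids = character(0))
    }
    if (config$accumulate_pseudo) {
      sel$pseudo_positive_ids <- setdiff(
        union(state$pseudo$pseudo_positive_ids, sel$pseudo_positive_ids),
        sel$pseudo_negative_ids)
      sel$pseudo_negative_ids <- setdiff(
        union(state$pseudo$pseudo_negative_ids, sel$pseudo_negative_ids),
        sel$pseudo_positive_ids)
    }
    state$pseudo <- sel

    train_ids <- c(lab$id, sel$pseudo_positive_ids, sel$pseudo_negative_ids)
    y <- c(y_lab, rep(1, length(sel$pseudo_positive_ids)),
           rep(0, length(sel$pseudo_negative_ids)))
    w <- ifelse(y == 1, cw$positive, cw$negative)
    reg_ids <- unique(c(lab$id, sel$pseudo_positive_ids,
                        sel$pseudo_negative_ids, reg_unlab))
    reg_only <- setdiff(reg_ids, train_ids)
    step_ids <- c(train_ids, reg_only)
    yy <- c(y, rep(-1, length(reg_only)))
    ww <- c(w, rep(0, length(reg_only)))
    rr <- as.integer(step_ids %in% reg_ids)
    step_records <- records[match(step_ids, records$id), ]
    X <- feature_matrix_for(features, step_ids, feature_names)
    enc <- encode_batch(step_records$sequence, spec)
    coef <- config$lambda_initial * config$decay^g
    pen_cfg <- list(coef = coef, lo = config$band_lower,
                    hi = config$band_upper)
    bce_g <- NA_real_
    pen_g <- NA_real_
    for (m in seq_along(state$members)) {
      upd <- withr::with_seed(config$seed + 1000L * g + (m - 1L), {
        run_adam(state$members[[m]], X, enc$tokens, enc$lengths, yy, ww,
                 rr, pen_cfg,
                 train_config(learning_rate = train$learning_rate,
                              epochs = 1L,
                              batch_size = train$batch_size,
                              class_weights = cw, seed = 1L),
                 epochs = config$epochs_per_iteration,
                 adam = NULL)   # optimizer state reset between iterations
      })
      state$members[[m]] <- upd$params
    }
    state$iteration <- g

    preds_all <- ensemble_predict(state, features, all_records)
    p_soft <- mean(preds_all$probability[match(reg_ids, preds_all$id)])
    probs_train <- preds_all$probability[match(train_ids, preds_all$id)]
    bce_g <- weighted_bce(probs_train, y, w)
    pen_g <- prior_penalty(p_soft, g, config)
    state$trace <- dplyr::bind_rows(state$trace,
                                    trace_row(g, bce_g, pen_g, p_soft,
                                              preds_all))
  }
  state
}

#' @export
print.selftrain_fit <- function(x, ...) {
  cat("<selftrain_fit>\n")
  cat(sprintf("  %d ensemble member(s), %d iteration(s)\n",
              length(x$members), x$iteration))
  if (!is.null(x$trace) && nrow(x$trace) > 0) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  final loss %.5f (bce %.5f + penalty %.5f), hard p+ %.3f\n",
                last$loss_total, last$loss_bce, last$penalty,
                last$p_positive_hard))
  }
  invisible(x)
}
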