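test_that("pseudo-label selection takes the confidence extremes", {
  set.seed(8)
  n <- 300
  preds <- tibble::tibble(id = sprintf("u%03d", 1:n),
                          probability = runif(n))
  sel <- select_pseudo_labels(preds, 0.01)
  expect_length(sel$pseudo_positive_ids, 3)
  expect_length(sel$pseudo_negative_ids, 3)
  expect_length(intersect(sel$pseudo_positive_ids,
                          sel$pseudo_negative_ids), 0)
  ord <- order(preds$probability)
  expect_setequal(sel$pseudo_negative_ids, preds$id[ord[1:3]])
  expect_setequal(sel$pseudo_positive_ids, preds$id[rev(ord)[1:3]])
  expect_true(sel$theta_neg < sel$theta_pos)

  # floor rule: pool of 50 at 1% selects nothing, with a warning
  expect_warning(sel0 <- select_pseudo_labels(preds[1:50, ], 0.01),
                 "selecting none")
  expect_length(sel0$pseudo_positive_ids, 0)

  # order statistics on a deterministic grid
  grid <- tibble::tibble(id = letters[1:10], probability = 1:10 / 10)
  sel10 <- select_pseudo_labels(grid, 0.1)
  expect_equal(sel10$pseudo_negative_ids, "a")
  expect_equal(sel10$pseudo_positive_ids, "j")

  expect_error(select_pseudo_labels(grid, 0.6),
               class = "secretrain_config_error")
})

test_that("the prior penalty matches its closed form", {
  cfg <- selftrain_config()
  expect_equal(prior_penalty(0.35, 17, cfg), 0)
  expect_equal(prior_penalty(0.25, 0, cfg), 1.0, tolerance = 1e-12)
  expect_equal(prior_penalty(0.45, 2, cfg), 0.9025, tolerance = 1e-12)
  # geometric decay outside the band
  for (p in c(0.1, 0.9)) {
    r <- vapply(0:5, prior_penalty, numeric(1), p_positive = p,
                config = cfg)
    expect_equal(r[-1] / r[-6], rep(0.95, 5), tolerance = 1e-12)
  }
  # continuity at the bounds
  expect_lt(prior_penalty(0.3 - 1e-9, 0, cfg), 1e-7)
  expect_lt(prior_penalty(0.4 + 1e-9, 0, cfg), 1e-7)
  # no-decay variant
  cfg1 <- selftrain_config(decay = 1)
  expect_equal(prior_penalty(0.25, 50, cfg1), prior_penalty(0.25, 0, cfg1))
  # disabled penalty
  cfg0 <- selftrain_config(lambda_initial = 0)
  expect_equal(prior_penalty(0.1, 0, cfg0), 0)
})

test_that("combined loss is the sum of its reported parts", {
  cfg <- selftrain_config()
  cl <- combined_loss(0.5, 1, 1, p_positive = 0.25, g = 0, config = cfg)
  expect_equal(cl$total, log(2) + 1, tolerance = 1e-9)
  expect_equal(cl$total, cl$bce + cl$penalty)
  cl_in <- combined_loss(0.5, 1, 1, p_positive = 0.35, g = 0, config = cfg)
  expect_equal(cl_in$total, cl_in$bce)
})

test_that("ensemble prediction averages member probabilities", {
  recs <- tiny_records()
  fm <- standardize_features(featurize(recs, desk_descriptors()))
  spec <- architecture_spec(conv1_filters = 2, conv2_filters = 3,
                            embedding_dim = 4, recurrent_hidden = 3,
                            max_sequence_length = 50)
  params <- lapply(1:3, function(s) {
    withr::with_seed(s, secretrain:::init_params(ncol(fm) - 1, spec))
  })
  fit <- structure(list(members = params, spec = spec,
                        feature_names = setdiff(names(fm), "protein_id")),
                   class = "selftrain_fit")
  pm <- ensemble_predict(fit, fm, recs)
  single <- sapply(params, function(par) {
    secretrain:::predict_probabilities(par, spec, fit$feature_names, fm,
                                       recs)$probability
  })
  expect_equal(pm$probability, rowMeans(single), tolerance = 1e-12)
  expect_true(all(pm$probability > 0 & pm$probability < 1))

  fit$members <- list()
  expect_error(ensemble_predict(fit, fm, recs),
               class = "secretrain_state_error")
})

make_selftrain_fixture <- function(n_lab = 30, n_pool = 200, seed = 21) {
  syn <- simulate_proteins(synthesis_config(
    n_positive = n_lab, n_negative = n_lab, n_unlabeled = n_pool,
    length_min = 40, length_max = 120, seed = seed))
  fm <- standardize_features(
    featurize(syn$records, desk_descriptors()),
    fit_ids = syn$labels$id[syn$labels$label != "unlabeled"])
  list(syn = syn, fm = fm,
       spec = architecture_spec(conv1_filters = 4, conv2_filters = 8,
                                embedding_dim = 4, recurrent_hidden = 4,
                                max_sequence_length = 150))
}

test_that("the loop traces every iteration and respects the pool", {
  fx <- make_selftrain_fixture()
  st <- selftrain_config(pseudo_fraction = 0.02, max_iterations = 3,
                         ensemble_size = 2, epochs_per_iteration = 2,
                         reg_subsample = 50, seed = 1)
  fit <- run_self_training(fx$fm, fx$syn$records, fx$syn$labels, st,
                           desk_train(seed = 1, epochs = 5), fx$spec)
  expect_equal(nrow(fit$trace), 4)   # initial state + three iterations
  expect_equal(fit$iteration, 3)
  pool <- fx$syn$labels$id[fx$syn$labels$label == "unlabeled"]
  expect_true(all(fit$pseudo$pseudo_positive_ids %in% pool))
  expect_true(all(fit$pseudo$pseudo_negative_ids %in% pool))
  expect_equal(fit$trace$n_pseudo_positive[-1], rep(4, 3))

  # determinism of the whole loop
  fit2 <- run_self_training(fx$fm, fx$syn$records, fx$syn$labels, st,
                            desk_train(seed = 1, epochs = 5), fx$spec)
  expect_identical(fit$trace, fit2$trace)

  expect_s3_class(glance(fit), "tbl_df")
  expect_s3_class(autoplot(fit), "ggplot")

  # checkpoint round-trip for the full self-training state
  dir <- withr::local_tempdir()
  save_checkpoint(fit, file.path(dir, "st.json"))
  back <- load_checkpoint(file.path(dir, "st.json"))
  expect_equal(ensemble_predict(back, fx$fm, fx$syn$records)$probability,
               ensemble_predict(fit, fx$fm, fx$syn$records)$probability)
})

test_that("an empty pool degenerates to supervised training with a warning", {
  fx <- make_selftrain_fixture(n_lab = 15, n_pool = 0)
  st <- selftrain_config(max_iterations = 2, ensemble_size = 1,
                         reg_subsample = 10, seed = 2)
  expect_warning(
    fit <- run_self_training(fx$fm, fx$syn$records, fx$syn$labels, st,
                             desk_train(seed = 2, epochs = 3), fx$spec),
    "empty unlabeled pool")
  expect_equal(nrow(fit$trace), 1)
})

test_that("without pseudo-labels the loop reduces to scheduled supervised training", {
  fx <- make_selftrain_fixture(n_lab = 15, n_pool = 100)
  labels <- fx$syn$labels
  st <- selftrain_config(pseudo_fraction = 0, max_iterations = 2,
                         lambda_initial = 0, ensemble_size = 1,
                         epochs_per_iteration = 3, reg_subsample = 10,
                         seed = 3)
  tc <- desk_train(seed = 3, epochs = 4)
  fit <- run_self_training(fx$fm, fx$syn$records, labels, st, tc, fx$spec)

  # reference: supervised fit with the same schedule (4 epochs, then two
  # 3-epoch segments with a fresh optimizer each, matching the loop's
  # per-iteration optimizer reset)
  lab <- labels[labels$label != "unlabeled", ]
  ref <- fit_supervised(fx$fm, fx$syn$records, labels,
                        train_config(learning_rate = tc$learning_rate,
                                     epochs = 4, seed = 3), fx$spec)
  y <- as.numeric(lab$label == "positive")
  cw <- class_weights_from_counts(sum(y == 1), sum(y == 0))
  w <- ifelse(y == 1, cw$positive, cw$negative)
  X <- secretrain:::feature_matrix_for(fx$fm, lab$id, ref$feature_names)
  enc <- secretrain:::encode_batch(
    fx$syn$records$sequence[match(lab$id, fx$syn$records$id)], fx$spec)
  params <- ref$params
  for (g in 1:2) {
    params <- secretrain:::run_adam(
      params, X, enc$tokens, enc$lengths, y, w, integer(length(y)),
      NULL, tc, epochs = 3)$params
  }
  pool_rec <- fx$syn$records
  got <- ensemble_predict(fit, fx$fm, pool_rec)$probability
  want <- secretrain:::predict_probabilities(params, fx$spec,
                                             ref$feature_names, fx$fm,
                                             pool_rec)$probability
  expect_equal(got, want, tolerance = 1e-6)
})
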