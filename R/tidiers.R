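# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   theme_minimal
#' @export
ggplot2::autoplot

#' Tidy the per-generation trace of a DE feature selection
#'
#' @param x A `de_selection` from [de_evolve()].
#' @param ... Unused.
#' @return A tibble with `generation` and `best_fitness`.
#' @method tidy de_selection
#' @export
tidy.de_selection <- function(x, ...) {
  tibble::tibble(generation = seq_along(x$fitness_trace) - 1L,
                 best_fitness = x$fitness_trace)
}

#' @rdname tidy.de_selection
#' @method glance de_selection
#' @export
glance.de_selection <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected_indices),
                 best_fitness = x$best_fitness,
                 generations = length(x$fitness_trace) - 1L)
}

#' @rdname tidy.de_selection
#' @method autoplot de_selection
#' @export
autoplot.de_selection <- function(x, ...) {
  ggplot(tidy(x), aes(x = .data$generation, y = .data$best_fitness)) +
    geom_line() +
    labs(x = "Generation", y = "Best silhouette fitness",
         title = "Differential-evolution feature selection") +
    theme_minimal()
}

#' Tidy the per-epoch loss of a supervised fit
#'
#' @param x A `secretrain_model` from [fit_supervised()].
#' @param ... Unused.
#' @return A tibble with `epoch` and `loss`.
#' @method tidy secretrain_model
#' @export
tidy.secretrain_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history),
                 loss = x$loss_history)
}

#' @rdname tidy.secretrain_model
#' @method glance secretrain_model
#' @export
glance.secretrain_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$feature_names),
                 epochs = length(x$loss_history),
                 final_loss = if (length(x$loss_history)) {
                   utils::tail(x$loss_history, 1)
                 } else {
                   NA_real_
                 })
}

#' @rdname tidy.secretrain_model
#' @method autoplot secretrain_model
#' @export
autoplot.secretrain_model <- function(x, ...) {
  ggplot(tidy(x), aes(x = .data$epoch, y = .data$loss)) +
    geom_line() +
    labs(x = "Epoch", y = "Weighted cross-entropy",
         title = "Supervised training loss") +
    theme_minimal()
}

#' Tidy the per-iteration trace of a self-training run
#'
#' @param x A `selftrain_fit` from [run_self_training()].
#' @param ... Unused.
#' @return The trace tibble (one row per iteration, including iteration 0).
#' @method tidy selftrain_fit
#' @export
tidy.selftrain_fit <- function(x, ...) {
  x$trace
}

#' @rdname tidy.selftrain_fit
#' @method glance selftrain_fit
#' @export
glance.selftrain_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble::tibble(iterations = x$iteration,
                 members = length(x$members),
                 final_loss = last$loss_total,
                 final_p_positive_hard = last$p_positive_hard,
                 n_pseudo_positive = last$n_pseudo_positive,
                 n_pseudo_negative = last$n_pseudo_negative)
}

#' @rdname tidy.selftrain_fit
#' @method autoplot selftrain_fit
#' @export
autoplot.selftrain_fit <- function(x, ...) {
  long <- tidyr::pivot_longer(
    x$trace[, c("iteration", "loss_bce", "penalty", "loss_total")],
    -"iteration", names_to = "term", values_to = "value")
  ggplot(long, aes(x = .data$iteration, y = .data$value,
                   colour = .data$term)) +
    geom_line() +
    labs(x = "Self-training iteration", y = "Loss",
         title = "Self-training objective trace", colour = NULL) +
    theme_minimal()
}

#' Marker-proportion bar chart
#'
#' @param profiles Output of [build_marker_profiles()].
#' @return A ggplot object comparing marker proportions across groups.
#' @export
plot_marker_profiles <- function(profiles) {
  dat <- profiles[profiles$available, ]
  ggplot(dat, aes(x = .data$marker, y = .data$proportion,
                  fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    labs(x = NULL, y = "Proportion with marker", fill = NULL,
         title = "Secretion-marker prevalence by group") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
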