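# Unsupervised feature selection by differential evolution over continuous
# inclusion weights in [0,1]^n, with a k-means silhouette fitness and a
# threshold binarization of the best vector.

#' Differential-evolution configuration
#'
#' @param population_size Number of candidate vectors (>= 4; mutation draws
#'   three distinct partners besides the target).
#' @param generations Number of evolution generations.
#' @param scale_factor Mutation scale F in `[0.5, 1]` (0 allowed for the
#'   degenerate identity mutation used in testing).
#' @param crossover_rate Crossover probability CR in (0, 1].
#' @param k_clusters Number of k-means clusters for the fitness (default 2).
#' @param binarize_threshold Inclusion-weight threshold for the final mask.
#' @param fitness_subsample Optional row subsample size for the fitness;
#'   drawn once per run so all candidates see the same rows.
#' @param kmeans_restarts Restarts of the seeded k-means per evaluation.
#' @param seed Seed governing initialization, DE randomness and k-means.
#' @return A named list of class `de_config`.
#' @export
de_config <- function(population_size = 50, generations = 100,
                      scale_factor = 0.5, crossover_rate = 0.9,
                      k_clusters = 2, binarize_threshold = 0.5,
                      fitness_subsample = NULL, kmeans_restarts = 10,
                      seed = 42) {
  check_number(population_size, "population_size", lower = 4,
               integer = TRUE)
  check_number(generations, "generations", lower = 0, integer = TRUE)
  check_number(scale_factor, "scale_factor", lower = 0, upper = 1)
  check_number(crossover_rate, "crossover_rate", lower = 1e-12, upper = 1)
  check_number(k_clusters, "k_clusters", lower = 2, integer = TRUE)
  check_number(binarize_threshold, "binarize_threshold", lower = 1e-12,
               upper = 1 - 1e-12)
  if (!is.null(fitness_subsample)) {
    check_number(fitness_subsample, "fitness_subsample", lower = 3,
                 integer = TRUE)
  }
  check_number(kmeans_restarts, "kmeans_restarts", lower = 1,
               integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 scale_factor = scale_factor,
                 crossover_rate = crossover_rate,
                 k_clusters = as.integer(k_clusters),
                 binarize_threshold = binarize_threshold,
                 fitness_subsample = fitness_subsample,
                 kmeans_restarts = as.integer(kmeans_restarts),
                 seed = as.integer(seed)),
            class = "de_config")
}

#' Initialize a DE population
#'
#' Components are i.i.d. uniform on `[0, 1]`.
#'
#' @param n_features Length of each candidate vector (>= 2).
#' @param config A [de_config()].
#' @return A `population_size` x `n_features` matrix of inclusion weights.
#' @export
de_initialize_population <- function(n_features, config = de_config()) {
  check_number(n_features, "n_features", lower = 2, integer = TRUE)
  matrix(stats::runif(config$population_size * n_features),
         config$population_size, n_features)
}

#' DE mutation
#'
#' `v = x_r1 + F * (x_r2 - x_r3)` with r1, r2, r3 distinct from each other
#' and from the target index, clipped componentwise to `[0, 1]`.
#'
#' @param target_index Row index of the target vector.
#' @param population Population matrix.
#' @param config A [de_config()].
#' @param partners Optional integer triple overriding the random draw.
#' @return A mutant vector in `[0, 1]^n`.
#' @export
de_mutate <- function(target_index, population, config = de_config(),
                      partners = NULL) {
  if (nrow(population) < 4) {
    stop_secretrain("mutation needs a population of at least 4",
                    "index_error")
  }
  if (is.null(partners)) {
    partners <- sample(setdiff(seq_len(nrow(population)), target_index), 3)
  }
  v <- population[partners[1], ] +
    config$scale_factor * (population[partners[2], ] -
                             population[partners[3], ])
  pmin(pmax(v, 0), 1)
}

#' DE binomial crossover
#'
#' Component `j` takes the mutant value when `runif() <= CR` or `j` equals a
#' randomly forced coordinate, ensuring the trial differs from the target
#' whenever the mutant does.
#'
#' @param target,mutant Equal-length candidate vectors.
#' @param config A [de_config()].
#' @return The trial vector.
#' @export
de_crossover <- function(target, mutant, config = de_config()) {
  if (length(target) != length(mutant)) {
    stop_secretrain("target and mutant lengths differ", "dimension_error")
  }
  n <- length(target)
  j_rand <- sample.int(n, 1)
  take <- stats::runif(n) <= config$crossover_rate
  take[j_rand] <- TRUE
  ifelse(take, mutant, target)
}

#' Binarize a candidate vector into feature indices
#'
#' @param candidate Inclusion-weight vector.
#' @param threshold Weights `>= threshold` are selected.
#' @return Ascending integer indices of the selected features.
#' @export
de_binarize <- function(candidate, threshold = 0.5) {
  check_number(threshold, "threshold", lower = 1e-12, upper = 1 - 1e-12)
  idx <- which(candidate >= threshold)
  if (length(idx) == 0) {
    stop_secretrain("binarization selected no features", "empty_selection")
  }
  idx
}

# Mean silhouette of a clustering; per-sample (b - a) / max(a, b) with the
# usual degenerate conventions (singleton clusters and zero spread score 0).
silhouette_mean <- function(X, cl) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  ks <- sort(unique(cl))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl[i]
    same <- which(cl == own)
    if (length(same) <= 1) { s[i] <- 0; next }
    a <- sum(D[i, same]) / (length(same) - 1)
    b <- min(vapply(ks[ks != own], function(k) {
      mean(D[i, cl == k])
    }, numeric(1)))
    m <- max(a, b)
    s[i] <- if (m > 0) (b - a) / m else 0
  }
  mean(s)
}

#' Silhouette fitness of a candidate feature mask
#'
#' Binarizes the candidate, clusters the selected-column submatrix with
#' seeded k-means (k = `k_clusters`) and returns the mean per-sample
#' silhouette `(b - a) / max(a, b)`. A candidate with no surviving feature
#' scores the sentinel -1; clusterings with fewer distinct points than
#' clusters score 0.
#'
#' @param candidate Inclusion-weight vector (one entry per feature column).
#' @param X Numeric matrix of samples by features (standardized).
#' @param config A [de_config()].
#' @param rows Optional fixed row subset to evaluate on.
#' @return Scalar fitness in `[-1, 1]`.
#' @export
silhouette_fitness <- function(candidate, X, config = de_config(),
                               rows = NULL) {
  if (nrow(X) < 3) {
    stop_secretrain("fitness needs at least 3 samples", "insufficient_data")
  }
  idx <- which(candidate >= config$binarize_threshold)
  if (length(idx) == 0) return(-1)
  sub <- X[rows %||% seq_len(nrow(X)), idx, drop = FALSE]
  if (nrow(unique(sub)) < config$k_clusters) return(0)
  cl <- withr::with_seed(config$seed, {
    stats::kmeans(sub, centers = config$k_clusters,
                  nstart = config$kmeans_restarts)$cluster
  })
  silhouette_mean(sub, cl)
}

#' Evolve a feature-selection mask by differential evolution
#'
#' Runs the mutate/crossover/select loop with strict greedy replacement (a
#' trial replaces its target only on strictly higher silhouette), tracks the
#' per-generation best fitness and binarizes the final best vector.
#'
#' @param features Standardized feature tibble (first column `protein_id`)
#'   or a plain numeric matrix.
#' @param config A [de_config()].
#' @return A `de_selection` object with `best_vector`, `best_fitness`,
#'   `fitness_trace`, `selected_indices`, `selected_features`.
#' @export
de_evolve <- function(features, config = de_config()) {
  if (is.data.frame(features)) {
    if (is.null(attr(features, "scaling"))) {
      rlang::warn(paste("feature matrix carries no scaling state;",
                        "silhouette fitness is scale-sensitive"))
    }
    feature_names <- setdiff(names(features), "protein_id")
    X <- as.matrix(features[, feature_names])
  } else {
    X <- as.matrix(features)
    feature_names <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  }
  n_feat <- ncol(X)
  withr::with_seed(config$seed, {
    rows <- if (!is.null(config$fitness_subsample) &&
                config$fitness_subsample < nrow(X)) {
      sort(sample.int(nrow(X), config$fitness_subsample))
    } else {
      NULL
    }
    pop <- de_initialize_population(n_feat, config)
    fit <- apply(pop, 1, function(cand) {
      silhouette_fitness(cand, X, config, rows)
    })
    trace <- max(fit)
    for (g in seq_len(config$generations)) {
      for (i in seq_len(config$population_size)) {
        mutant <- de_mutate(i, pop, config)
        trial <- de_crossover(pop[i, ], mutant, config)
        f_trial <- silhouette_fitness(trial, X, config, rows)
        if (f_trial > fit[i]) {   # strict: ties keep the incumbent
          pop[i, ] <- trial
          fit[i] <- f_trial
        }
      }
      trace <- c(trace, max(fit))
    }
  })
  best <- which.max(fit)
  best_vec <- pop[best, ]
  idx <- de_binarize(best_vec, config$binarize_threshold)
  structure(list(best_vector = best_vec,
                 best_fitness = fit[best],
                 fitness_trace = trace,
                 selected_indices = idx,
                 selected_features = feature_names[idx],
                 config = config),
            class = "de_selection")
}

#' @export
print.de_selection <- function(x, ...) {
  cat("<de_selection>\n")
  cat(sprintf("  %d features selected | best silhouette %.4f | %d generations\n",
              length(x$selected_indices), x$best_fitness,
              length(x$fitness_trace) - 1))
  invisible(x)
}
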