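# Evaluation metrics, dataset splitting, negative-candidate filtering and
# annotation cross-checking, secretion-marker rule scanning, and the
# PCA-space class-separation diagnostic.

#' Confusion counts from labels and predicted classes
#'
#' @param truth 0/1 (or logical) true labels.
#' @param predicted 0/1 (or logical) predicted classes.
#' @return A list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  t <- as.integer(as.logical(truth))
  p <- as.integer(as.logical(predicted))
  list(tp = sum(t == 1 & p == 1), tn = sum(t == 0 & p == 0),
       fp = sum(t == 0 & p == 1), fn = sum(t == 1 & p == 0))
}

auc_rank <- function(probabilities, labels) {
  pos <- probabilities[labels == 1]
  neg <- probabilities[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) {
    stop_secretrain("AUC needs scores from both classes", "undefined_metric")
  }
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Classification metrics
#'
#' Computes accuracy, sensitivity (recall), specificity, the Matthews
#' correlation coefficient and two F1 variants from confusion counts, plus a
#' rank-based AUC (probability that a random positive outscores a random
#' negative, ties counted half) when scores are supplied. `f1` follows the
#' specificity/sensitivity form `2*SP*SN / (SP + SN)`;
#' `f1_precision_recall` is the conventional harmonic mean of precision and
#' recall. The two agree exactly when specificity equals precision. MCC is 0
#' by convention when any denominator marginal vanishes.
#'
#' @param counts A list with `tp`, `tn`, `fp`, `fn` (see
#'   [confusion_counts()]).
#' @param scores Optional tibble/data frame with columns `probability` and
#'   `label` (0/1) for the AUC.
#' @return A one-row tibble with `acc`, `sn`, `sp`, `mcc`, `auc`, `f1`,
#'   `f1_precision_recall`.
#' @export
compute_metrics <- function(counts, scores = NULL) {
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  total <- tp + tn + fp + fn
  if (total <= 0) {
    stop_secretrain("confusion counts sum to zero", "value_error")
  }
  acc <- (tp + tn) / total
  sn <- if (tp + fn > 0) tp / (tp + fn) else 0
  sp <- if (tn + fp > 0) tn / (tn + fp) else 0
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  f1 <- if (sp + sn > 0) 2 * sp * sn / (sp + sn) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1_pr <- if (prec + sn > 0) 2 * prec * sn / (prec + sn) else 0
  auc <- if (!is.null(scores)) {
    auc_rank(scores$probability, scores$label)
  } else {
    NA_real_
  }
  tibble::tibble(acc = acc, sn = sn, sp = sp, mcc = mcc, auc = auc,
                 f1 = f1, f1_precision_recall = f1_pr)
}

#' Split ids into training and validation partitions
#'
#' The validation partition holds `ceiling(fraction * N)` ids (the only
#' rounding convention consistent with an 8204/2052 split of 10256 at 20%);
#' shuffling is seeded.
#'
#' @param ids Character vector of ids.
#' @param validation_fraction Fraction held out, in (0, 1).
#' @param seed Shuffle seed (default 42, the published split seed).
#' @return A list with `training` and `validation` id vectors.
#' @export
split_dataset <- function(ids, validation_fraction = 0.2, seed = 42) {
  if (length(ids) < 2) {
    stop_secretrain("need at least 2 ids to split", "split_error")
  }
  check_number(validation_fraction, "validation_fraction", lower = 1e-12,
               upper = 1 - 1e-12)
  n_val <- ceiling(validation_fraction * length(ids))
  shuffled <- withr::with_seed(seed, sample(ids))
  list(training = shuffled[-seq_len(n_val)],
       validation = shuffled[seq_len(n_val)])
}

#' Negative-candidate filter configuration
#'
#' @param exclusion_keywords Lowercase substrings of the subcellular-location
#'   text that disqualify a protein as a negative (secretion/extracellular
#'   evidence). The default is the published in-text trio; the full list is
#'   user-extensible.
#' @param confidence_threshold Minimum localization confidence score.
#' @param keep_above Retain proteins with confidence `>=` threshold
#'   (flippable).
#' @return A named list of class `negative_filter_config`.
#' @export
negative_filter_config <- function(exclusion_keywords = c("extracellular",
                                                          "efflux",
                                                          "synapse"),
                                   confidence_threshold = 1.1,
                                   keep_above = TRUE) {
  if (length(exclusion_keywords) == 0) {
    stop_secretrain("need at least one exclusion keyword", "config_error")
  }
  structure(list(exclusion_keywords = tolower(exclusion_keywords),
                 confidence_threshold = confidence_threshold,
                 keep_above = isTRUE(keep_above)),
            class = "negative_filter_config")
}

#' Filter negative candidates by localization keywords and confidence
#'
#' Removes every id whose subcellular-location text contains an exclusion
#' keyword (case-insensitive substring) or whose localization confidence
#' falls below the threshold.
#'
#' @param annotations Annotation tibble (see [read_annotation_table()]).
#' @param scores Tibble with `id` and `confidence`.
#' @param config A [negative_filter_config()].
#' @return Character vector of retained ids.
#' @export
filter_negative_candidates <- function(annotations, scores,
                                       config = negative_filter_config()) {
  missing <- setdiff(scores$id, annotations$id)
  if (length(missing) > 0) {
    stop_secretrain(sprintf(
      "confidence scores given for unannotated id(s): %s",
      paste(utils::head(missing, 5), collapse = ", ")),
      "consistency_error")
  }
  loc <- tolower(annotations$subcellular_location)
  kw_hit <- Reduce(`|`, lapply(config$exclusion_keywords, function(k) {
    stringr::str_detect(loc, stringr::fixed(k))
  }))
  conf <- scores$confidence[match(annotations$id, scores$id)]
  conf_ok <- if (config$keep_above) {
    !is.na(conf) & conf >= config$confidence_threshold
  } else {
    !is.na(conf) & conf <= config$confidence_threshold
  }
  annotations$id[!kw_hit & conf_ok]
}

#' Cross-check candidate negatives against curated annotations
#'
#' Flags each candidate under four exclusion criteria: (A) the
#' subcellular-location text contains "Secreted"; (B) it contains
#' "Extracellular"; (C) the signal-peptide field is non-empty; (D) any of
#' A-C. Reports retained counts and percentages (two decimals, half-up).
#'
#' @param ids Candidate negative ids.
#' @param annotations Annotation tibble covering every id.
#' @return A tibble with one row per criterion: `criterion`, `excluded`,
#'   `retained`, `total`, `retained_pct`.
#' @export
cross_check_against_annotations <- function(ids, annotations) {
  rows <- match(ids, annotations$id)
  if (anyNA(rows)) {
    stop_secretrain(sprintf(
      "unannotated candidate id(s): %s",
      paste(utils::head(ids[is.na(rows)], 5), collapse = ", ")),
      "missing_annotation")
  }
  loc <- tolower(annotations$subcellular_location[rows])
  sp <- annotations$signal_peptide[rows]
  a <- stringr::str_detect(loc, stringr::fixed("secreted"))
  b <- stringr::str_detect(loc, stringr::fixed("extracellular"))
  cc <- nzchar(trimws(sp))
  d <- a | b | cc
  flags <- list(A = a, B = b, C = cc, D = d)
  purrr::map_dfr(names(flags), function(k) {
    excl <- sum(flags[[k]])
    tibble::tibble(criterion = k, excluded = excl,
                   retained = length(ids) - excl, total = length(ids),
                   retained_pct = round_half_up(
                     100 * (length(ids) - excl) / length(ids), 2))
  })
}

#' Detect a carboxy-terminal ER-retention motif
#'
#' `TRUE` iff the final four residues are exactly KDEL, HDEL, KEEL or QEEL.
#' Sequences shorter than four residues return `FALSE`.
#'
#' @param sequence Character vector of sequences (vectorized).
#' @return Logical vector.
#' @export
detect_er_retention <- function(sequence) {
  n <- nchar(sequence)
  tail4 <- substring(sequence, pmax(1, n - 3), n)
  n >= 4 & tail4 %in% ER_RETENTION_MOTIFS
}

#' Detect a dibasic cleavage motif near the carboxy terminus
#'
#' `TRUE` iff "KR" or "RR" occurs with its first residue inside the final
#' `min(20, length)` residues.
#'
#' @param sequence Character vector of sequences (vectorized).
#' @return Logical vector.
#' @export
detect_dibasic_cleavage <- function(sequence) {
  n <- nchar(sequence)
  start <- pmax(1, n - 20)  # window of starts: last 20 positions, plus the
                            # partner residue immediately before
  window <- substring(sequence, start, n)
  # motif must *start* within the last 20 residues
  hit <- function(s, full_n) {
    if (full_n < 2) return(FALSE)
    pos <- unlist(gregexpr("(?=KR|RR)", s, perl = TRUE))
    pos <- pos[pos > 0]
    if (length(pos) == 0) return(FALSE)
    offset <- max(1, full_n - 20)
    any((pos + offset - 1) >= full_n - 19)
  }
  mapply(hit, window, n, USE.NAMES = FALSE)
}

MARKER_SEQUENCE <- c("er_retention", "dibasic_cleavage")
MARKER_ANNOTATION <- c("signal_peptide", "tm_region", "n_glycosylation",
                       "disulfide", "gpi_anchor")

#' Per-group secretion-marker proportions
#'
#' For each group of proteins (e.g. pseudo-positives vs pseudo-negatives),
#' reports the fraction carrying each secretion-related marker and the
#' fraction carrying at least one (`any_marker`). ER-retention and dibasic
#' markers are computed from the sequences; signal peptide, transmembrane
#' region, N-glycosylation, disulfide and GPI-anchor flags come from the
#' annotation table and are reported as unavailable without one.
#'
#' @param records Tibble with `id`, `sequence`.
#' @param groups Tibble with `id` and `group`.
#' @param annotations Optional annotation tibble.
#' @return A long tibble with `group`, `marker`, `proportion`, `available`.
#' @export
build_marker_profiles <- function(records, groups, annotations = NULL) {
  dat <- dplyr::left_join(groups, records, by = "id")
  if (anyNA(dat$sequence)) {
    stop_secretrain("groups refer to ids without sequence records",
                    "missing_record")
  }
  dat$er_retention <- detect_er_retention(dat$sequence)
  dat$dibasic_cleavage <- detect_dibasic_cleavage(dat$sequence)
  have_ann <- !is.null(annotations)
  if (have_ann) {
    rows <- match(dat$id, annotations$id)
    dat$signal_peptide <- nzchar(trimws(
      annotations$signal_peptide[rows])) %in% TRUE
    for (fl in ANNOTATION_FLAGS) {
      dat[[fl]] <- annotations[[fl]][rows] %in% TRUE
    }
  } else {
    dat$signal_peptide <- NA
    for (fl in ANNOTATION_FLAGS) dat[[fl]] <- NA
  }
  markers <- c(MARKER_ANNOTATION, MARKER_SEQUENCE)
  av_flags <- dat[, markers]
  dat$any_marker <- apply(av_flags, 1, function(r) any(r %in% TRUE))
  out <- purrr::map_dfr(c(markers, "any_marker"), function(mk) {
    vals <- dat[[mk]]
    available <- !all(is.na(vals))
    dat %>%
      dplyr::group_by(.data$group) %>%
      dplyr::summarise(marker = mk,
                       proportion = if (available) {
                         mean(.data[[mk]] %in% TRUE)
                       } else {
                         NA_real_
                       },
                       available = available, .groups = "drop")
  })
  out[, c("group", "marker", "proportion", "available")]
}

#' Class separation in PCA space
#'
#' Projects the feature matrix onto its first two principal components
#' (fitted on all rows) and returns the Mahalanobis distance between the two
#' class means under the pooled within-class covariance of the projected
#' data. A singular pooled covariance is ridge-regularized (1e-8 on the
#' diagonal).
#'
#' @param features Feature tibble (first column `protein_id`) or numeric
#'   matrix.
#' @param labels 0/1 (or two-level) class vector aligned with the rows.
#' @return Non-negative scalar separation index.
#' @export
pca_class_separation <- function(features, labels) {
  X <- if (is.data.frame(features)) {
    as.matrix(features[, setdiff(names(features), "protein_id")])
  } else {
    as.matrix(features)
  }
  cls <- unique(labels)
  if (length(cls) != 2) {
    stop_secretrain("need exactly two classes", "value_error")
  }
  if (min(table(labels)) < 3) {
    stop_secretrain("need at least 3 samples per class",
                    "insufficient_data")
  }
  keep <- apply(X, 2, stats::sd) > 0
  pc <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE,
                      scale. = FALSE)$x[, 1:2, drop = FALSE]
  g1 <- pc[labels == cls[1], , drop = FALSE]
  g2 <- pc[labels == cls[2], , drop = FALSE]
  s_pooled <- ((nrow(g1) - 1) * stats::cov(g1) +
                 (nrow(g2) - 1) * stats::cov(g2)) /
    (nrow(g1) + nrow(g2) - 2)
  if (abs(det(s_pooled)) < 1e-12) {
    s_pooled <- s_pooled + diag(1e-8, 2)
  }
  delta <- colMeans(g1) - colMeans(g2)
  sqrt(drop(t(delta) %*% solve(s_pooled) %*% delta))
}
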