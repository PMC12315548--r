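# Synthetic protein benchmark generator: two separable sequence classes with
# planted secretion cues (amino-terminal hydrophobic stretch, carboxy-
# terminal dibasic motif vs ER-retention motif, composition shifts) plus an
# unlabeled pool with a configurable hidden positive fraction.

#' Synthetic dataset configuration
#'
#' @param n_positive,n_negative,n_unlabeled Record counts per partition.
#' @param unlabeled_positive_fraction Hidden positive fraction of the pool
#'   (default 0.35, inside the prior band of the secretory-proportion
#'   constraint).
#' @param length_min,length_max Sequence length range (uniform; minimum 30
#'   to leave room for the planted motifs).
#' @param signal_strength Probability in `[0, 1]` that each secretion cue is
#'   planted in a given record; 0 produces a null dataset with background
#'   statistics in both classes.
#' @param seed Generator seed.
#' @return A named list of class `synthesis_config`.
#' @export
synthesis_config <- function(n_positive = 100, n_negative = 100,
                             n_unlabeled = 2000,
                             unlabeled_positive_fraction = 0.35,
                             length_min = 80, length_max = 400,
                             signal_strength = 0.9, seed = 42) {
  check_number(n_positive, "n_positive", lower = 0, integer = TRUE)
  check_number(n_negative, "n_negative", lower = 0, integer = TRUE)
  check_number(n_unlabeled, "n_unlabeled", lower = 0, integer = TRUE)
  check_number(unlabeled_positive_fraction, "unlabeled_positive_fraction",
               lower = 0, upper = 1)
  check_number(length_min, "length_min", lower = 30, integer = TRUE)
  check_number(length_max, "length_max", lower = length_min, integer = TRUE)
  check_number(signal_strength, "signal_strength", lower = 0, upper = 1)
  check_number(seed, "seed", integer = TRUE)
  structure(list(n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 n_unlabeled = as.integer(n_unlabeled),
                 unlabeled_positive_fraction = unlabeled_positive_fraction,
                 length_min = as.integer(length_min),
                 length_max = as.integer(length_max),
                 signal_strength = signal_strength,
                 seed = as.integer(seed)),
            class = "synthesis_config")
}

# Composition tilts applied to the background frequencies when the
# corresponding cue fires.
tilt_composition <- function(base, residues, factor) {
  w <- base
  w[residues] <- w[residues] * factor
  w / sum(w)
}

sample_sequence <- function(len, comp) {
  paste(sample(AA_ALPHABET, len, replace = TRUE, prob = comp), collapse = "")
}

simulate_one <- function(positive, len, strength) {
  plant_stretch <- positive && stats::runif(1) < strength
  plant_dibasic <- positive && stats::runif(1) < strength
  plant_hydro <- positive && stats::runif(1) < strength
  plant_er <- !positive && stats::runif(1) < strength
  plant_polar <- !positive && stats::runif(1) < strength
  comp <- BACKGROUND_COMPOSITION
  if (plant_hydro) {
    comp <- tilt_composition(comp, c(HYDROPHOBIC_SET, "C"), 1.5)
  }
  if (plant_polar) {
    comp <- tilt_composition(comp, c("D", "E", "K", "R", "N", "Q", "S",
                                     "T", "H"), 1.5)
  }
  seq <- sample_sequence(len, comp)
  if (plant_stretch) {
    k <- sample(15:25, 1)
    stretch <- paste(sample(HYDROPHOBIC_SET, k, replace = TRUE),
                     collapse = "")
    seq <- paste0(stretch, substring(seq, k + 1))
  }
  if (plant_dibasic) {
    motif <- sample(c("KR", "RR"), 1)
    pos <- nchar(seq) - sample(2:18, 1)   # first residue in final 20
    substring(seq, pos, pos + 1) <- motif
  }
  if (plant_er) {
    motif <- sample(ER_RETENTION_MOTIFS, 1)
    substring(seq, nchar(seq) - 3, nchar(seq)) <- motif
  }
  list(sequence = seq, signal_peptide = plant_stretch)
}

#' Generate a synthetic secretion benchmark
#'
#' Positives carry, each independently with probability `signal_strength`,
#' an amino-terminal hydrophobic stretch of 15-25 residues (signal-peptide
#' surrogate), a dibasic KR/RR motif inside the final 20 residues, and an
#' elevated hydrophobic composition. Negatives carry, with the same
#' probability, a carboxy-terminal ER-retention tetrapeptide and a
#' polar/charged-enriched composition. Unlabeled records are hidden
#' positives with probability `unlabeled_positive_fraction`. Background
#' residues follow the average curated-proteome composition. The annotation
#' table is consistent with the planted cues: the signal-peptide field is
#' non-empty exactly when a stretch was planted, the location text reads
#' "Secreted" for true positives, and the binary marker flags fire at higher
#' rates in positives.
#'
#' @param config A [synthesis_config()].
#' @return A list of class `synthetic_dataset` with `records` (id,
#'   sequence), `labels` (visible labels), `truth` (hidden truth for every
#'   record) and `annotations`.
#' @export
simulate_proteins <- function(config = synthesis_config()) {
  n_total <- config$n_positive + config$n_negative + config$n_unlabeled
  if (n_total == 0) {
    stop_secretrain("all record counts are zero", "empty_dataset")
  }
  withr::with_seed(config$seed, {
    visible <- c(rep("positive", config$n_positive),
                 rep("negative", config$n_negative),
                 rep("unlabeled", config$n_unlabeled))
    hidden <- c(rep(TRUE, config$n_positive),
                rep(FALSE, config$n_negative),
                stats::runif(config$n_unlabeled) <
                  config$unlabeled_positive_fraction)
    ids <- sprintf("SYN%05d", seq_len(n_total))
    lens <- sample(config$length_min:config$length_max, n_total,
                   replace = TRUE)
    sims <- lapply(seq_len(n_total), function(i) {
      simulate_one(hidden[i], lens[i], config$signal_strength)
    })
    seqs <- vapply(sims, `[[`, character(1), "sequence")
    has_sp <- vapply(sims, `[[`, logical(1), "signal_peptide")

    flag_rate <- function(pos_rate, neg_rate) {
      r <- ifelse(hidden, pos_rate * config$signal_strength, neg_rate)
      stats::runif(n_total) < r
    }
    annotations <- tibble::tibble(
      id = ids,
      subcellular_location = ifelse(
        hidden, "Secreted",
        sample(c("Cytoplasm", "Nucleus", "Mitochondrion"), n_total,
               replace = TRUE)),
      signal_peptide = ifelse(has_sp, "SIGNAL 1..20", ""),
      tm_region = flag_rate(0.35, 0.05),
      n_glycosylation = flag_rate(0.55, 0.05),
      disulfide = flag_rate(0.45, 0.05),
      gpi_anchor = flag_rate(0.10, 0.01))
  })
  structure(list(
    records = tibble::tibble(id = ids, sequence = seqs),
    labels = tibble::tibble(id = ids, label = visible),
    truth = tibble::tibble(id = ids,
                           label = ifelse(hidden, "positive", "negative")),
    annotations = annotations), class = "synthetic_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Emits `sequences.fasta`, `labels.tsv` (visible labels only),
#' `truth.tsv` (hidden truth) and `annotations.tsv` into a directory, in
#' formats that round-trip through [read_fasta()], [read_label_table()] and
#' [read_annotation_table()].
#'
#' @param dataset A `synthetic_dataset` from [simulate_proteins()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "sequences.fasta"),
             labels = file.path(dir, "labels.tsv"),
             truth = file.path(dir, "truth.tsv"),
             annotations = file.path(dir, "annotations.tsv"))
  write_fasta(dataset$records, paths[["fasta"]])
  write_label_table(dataset$labels, paths[["labels"]])
  write_label_table(dataset$truth, paths[["truth"]])
  write_annotation_table(dataset$annotations, paths[["annotations"]])
  invisible(paths)
}
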