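# Readers and writers for the on-disk formats: FASTA sequences, tab-delimited
# label/annotation tables, feature matrices, YAML run configuration, and JSON
# model checkpoints. All tables are tab-delimited with a header line.

#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a tibble of protein records. Sequences are
#' upper-cased and wrapped lines are concatenated; the record id is the first
#' whitespace-delimited token of the header. Degenerate residue codes are
#' normalized by default (U to C, B to N, Z to Q, O to K); X is retained and
#' later excluded from physicochemical averages.
#'
#' @param path Path to a FASTA file.
#' @param normalize Substitute degenerate residue codes at parse time
#'   (default `TRUE`). Substitutions are reported via a message naming each
#'   affected record.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path, normalize = TRUE) {
  if (!file.exists(path)) {
    stop_secretrain(sprintf("FASTA file not found: %s", path), "io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0 || !startsWith(lines[[1]], ">")) {
    stop_secretrain(sprintf("not a FASTA file (no records): %s", path),
                    "format_error")
  }
  starts <- which(startsWith(lines, ">"))
  ids <- vapply(lines[starts], function(h) {
    strsplit(sub("^>", "", h), "\\s+")[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  ends <- c(starts[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(starts), function(i) {
    if (ends[i] < starts[i] + 1L) return("")
    toupper(paste0(lines[(starts[i] + 1L):ends[i]], collapse = ""))
  }, character(1))
  if (any(!nzchar(ids)) || anyNA(ids)) {
    stop_secretrain("FASTA header with empty identifier", "format_error")
  }
  if (anyDuplicated(ids)) {
    stop_secretrain(
      sprintf("duplicate FASTA identifier(s): %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", ")),
      "duplicate_identifier")
  }
  if (any(!nzchar(seqs))) {
    stop_secretrain(
      sprintf("empty sequence for record(s): %s",
              paste(ids[!nzchar(seqs)], collapse = ", ")),
      "format_error")
  }
  allowed <- c(AA_ALPHABET, AA_DEGENERATE)
  bad <- vapply(seqs, function(s) {
    any(!strsplit(s, "", fixed = TRUE)[[1]] %in% allowed)
  }, logical(1))
  if (any(bad)) {
    stop_secretrain(
      sprintf("invalid residue code(s) in record(s): %s",
              paste(ids[bad], collapse = ", ")),
      "invalid_residue")
  }
  records <- tibble::tibble(id = ids, sequence = seqs)
  if (normalize) records <- normalize_residues(records)
  records
}

#' Normalize degenerate residue codes
#'
#' Applies the fixed substitution map U->C, B->N, Z->Q, O->K; X is kept.
#' Records whose sequence changed are reported with a message.
#'
#' @param records Tibble with `id` and `sequence` columns.
#' @return The records tibble with normalized sequences.
#' @export
normalize_residues <- function(records) {
  seqs <- records$sequence
  out <- chartr(paste(names(AA_SUBSTITUTION), collapse = ""),
                paste(AA_SUBSTITUTION, collapse = ""), seqs)
  changed <- out != seqs
  if (any(changed)) {
    rlang::inform(sprintf(
      "substituted degenerate residue codes (U>C, B>N, Z>Q, O>K) in: %s",
      paste(records$id[changed], collapse = ", ")))
  }
  records$sequence <- out
  records
}

#' Write protein records to a FASTA file
#'
#' @param records Tibble with `id` and `sequence` columns.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$sequence[i]
    idx <- seq(1, nchar(s), by = width)
    writeLines(substring(s, idx, pmin(idx + width - 1, nchar(s))), con)
  }
  invisible(path)
}

LABEL_LEVELS <- c("positive", "negative", "unlabeled")

#' Read a protein label table
#'
#' Reads a tab-delimited table with header columns `id` and `label`, where
#' labels are one of `positive`, `negative`, `unlabeled`. Records absent from
#' the table default to `unlabeled`.
#'
#' @param path Path to the TSV file. An empty file yields all-unlabeled.
#' @param records Tibble of protein records the ids must refer to.
#' @return A tibble with columns `id` and `label` covering every record.
#' @export
read_label_table <- function(path, records) {
  if (!file.exists(path)) {
    stop_secretrain(sprintf("label table not found: %s", path), "io_error")
  }
  info <- file.info(path)
  if (info$size == 0) {
    tab <- tibble::tibble(id = character(), label = character())
  } else {
    tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    if (!all(c("id", "label") %in% names(tab))) {
      stop_secretrain("label table must have columns `id` and `label`",
                      "format_error")
    }
    tab <- tab[, c("id", "label")]
  }
  bad_label <- setdiff(unique(tab$label), LABEL_LEVELS)
  if (length(bad_label) > 0) {
    stop_secretrain(
      sprintf("unknown label value(s): %s (allowed: %s)",
              paste(bad_label, collapse = ", "),
              paste(LABEL_LEVELS, collapse = ", ")),
      "value_error")
  }
  missing <- setdiff(tab$id, records$id)
  if (length(missing) > 0) {
    stop_secretrain(
      sprintf("label table refers to id(s) without a sequence record: %s",
              paste(missing, collapse = ", ")),
      "missing_record")
  }
  if (anyDuplicated(tab$id)) {
    stop_secretrain("duplicate id(s) in label table", "duplicate_identifier")
  }
  out <- tibble::tibble(id = records$id)
  out$label <- tab$label[match(out$id, tab$id)]
  out$label[is.na(out$label)] <- "unlabeled"
  out
}

#' Write a label table
#' @param labels Tibble with `id` and `label` columns.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(labels, path) {
  readr::write_tsv(labels[, c("id", "label")], path, progress = FALSE)
  invisible(path)
}

ANNOTATION_FLAGS <- c("tm_region", "n_glycosylation", "disulfide",
                      "gpi_anchor")

#' Read an annotation table
#'
#' Reads a tab-delimited table with header columns `id`,
#' `subcellular_location`, `signal_peptide` and optional boolean marker flag
#' columns (`tm_region`, `n_glycosylation`, `disulfide`, `gpi_anchor`).
#' Missing text fields become empty strings; missing flags become `NA`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with one row per annotated protein.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) {
    stop_secretrain(sprintf("annotation table not found: %s", path),
                    "io_error")
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("id", "subcellular_location", "signal_peptide") %in% names(tab))) {
    stop_secretrain(paste("annotation table must have columns `id`,",
                          "`subcellular_location`, `signal_peptide`"),
                    "format_error")
  }
  if (anyDuplicated(tab$id)) {
    stop_secretrain("duplicate id(s) in annotation table",
                    "duplicate_identifier")
  }
  tab$subcellular_location[is.na(tab$subcellular_location)] <- ""
  tab$signal_peptide[is.na(tab$signal_peptide)] <- ""
  for (fl in ANNOTATION_FLAGS) {
    tab[[fl]] <- if (fl %in% names(tab)) {
      as.logical(tab[[fl]])
    } else {
      NA
    }
  }
  tab[, c("id", "subcellular_location", "signal_peptide", ANNOTATION_FLAGS)]
}

#' Write an annotation table
#' @param annotations Tibble as returned by [read_annotation_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  readr::write_tsv(annotations, path, progress = FALSE)
  invisible(path)
}

#' Write / read a feature matrix
#'
#' Feature matrices are stored as TSV with the protein id in the first column
#' and one named descriptor per remaining column. Standardization state, if
#' attached, is persisted as a `<path>.scaling.tsv` sidecar.
#'
#' @param features Feature tibble from [featurize()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  readr::write_tsv(features, path, progress = FALSE)
  scaling <- attr(features, "scaling")
  if (!is.null(scaling)) {
    readr::write_tsv(scaling, paste0(path, ".scaling.tsv"), progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = "c", .default = "d"), progress = FALSE)
  side <- paste0(path, ".scaling.tsv")
  if (file.exists(side)) {
    attr(tab, "scaling") <- readr::read_tsv(
      side, col_types = readr::cols(feature = "c", .default = "d"),
      progress = FALSE)
  }
  tab
}

#' Assemble the full run configuration
#'
#' Bundles the per-stage configuration constructors into one nested list;
#' every default mirrors the published study settings where those are stated.
#'
#' @param descriptors,de,architecture,training,self_training,negative_filter,synthesis
#'   Stage configurations built by the corresponding `*_config()` /
#'   [architecture_spec()] constructors.
#' @param seed Global random seed (default 42).
#' @return A named list of class `secretrain_config`.
#' @export
secretrain_config <- function(descriptors = descriptor_config(),
                              de = de_config(),
                              architecture = architecture_spec(),
                              training = train_config(),
                              self_training = selftrain_config(),
                              negative_filter = negative_filter_config(),
                              synthesis = synthesis_config(),
                              seed = 42) {
  check_number(seed, "seed", integer = TRUE)
  structure(list(descriptors = descriptors, de = de,
                 architecture = architecture, training = training,
                 self_training = self_training,
                 negative_filter = negative_filter,
                 synthesis = synthesis, seed = as.integer(seed)),
            class = "secretrain_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys at any level are rejected; values not present fall back to the
#' package defaults.
#'
#' @param path Path to a YAML file whose top-level keys are a subset of
#'   `descriptors`, `de`, `architecture`, `training`, `self_training`,
#'   `negative_filter`, `synthesis`, `seed`.
#' @return A `secretrain_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  groups <- c("descriptors", "de", "architecture", "training",
              "self_training", "negative_filter", "synthesis")
  check_known_keys(raw, c(groups, "seed"), "run config")
  ctors <- list(descriptors = descriptor_config, de = de_config,
                architecture = architecture_spec, training = train_config,
                self_training = selftrain_config,
                negative_filter = negative_filter_config,
                synthesis = synthesis_config)
  args <- lapply(groups, function(g) {
    do.call(ctors[[g]], as.list(raw[[g]]))
  })
  names(args) <- groups
  args$seed <- if (is.null(raw$seed)) 42 else raw$seed
  do.call(secretrain_config, args)
}

config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

# Doubles are written as 17-significant-digit strings so that reloading is
# bit-identical.
serialize_params <- function(params) {
  lapply(params, function(p) {
    list(dim = dim(p) %||% length(p), values = sprintf("%.17g", p))
  })
}

deserialize_params <- function(ser) {
  lapply(ser, function(p) {
    d <- unlist(p$dim)
    v <- as.numeric(unlist(p$values))
    if (length(d) == 2) matrix(v, d[1], d[2]) else v
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a model checkpoint
#'
#' Checkpoints are JSON documents carrying the architecture hash, iteration
#' counter, seeds and every parameter tensor at full double precision, so a
#' reloaded model reproduces predictions bit-identically.
#'
#' @param state A fitted `secretrain_model` or `selftrain_fit` object.
#' @param path Output path for the JSON checkpoint.
#' @return `path`, invisibly (for save); the restored object (for load).
#' @export
save_checkpoint <- function(state, path) {
  if (inherits(state, "secretrain_model")) {
    doc <- list(kind = "model",
                spec_hash = config_hash(unclass(state$spec)),
                spec = unclass(state$spec),
                feature_names = state$feature_names,
                seed = state$seed,
                loss_history = state$loss_history,
                params = serialize_params(state$params))
  } else if (inherits(state, "selftrain_fit")) {
    doc <- list(kind = "selftrain",
                spec_hash = config_hash(unclass(state$spec)),
                spec = unclass(state$spec),
                feature_names = state$feature_names,
                iteration = state$iteration,
                seed = state$seed,
                config = unclass(state$config),
                pseudo_positive = as.list(state$pseudo$pseudo_positive_ids),
                pseudo_negative = as.list(state$pseudo$pseudo_negative_ids),
                trace = state$trace,
                members = lapply(state$members, serialize_params))
  } else {
    stop_secretrain("unsupported state object for checkpointing",
                    "state_error")
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param spec Optional [architecture_spec()]; when given, loading a
#'   checkpoint written under a different architecture raises an
#'   incompatibility error.
#' @export
load_checkpoint <- function(path, spec = NULL) {
  if (!file.exists(path)) {
    stop_secretrain(sprintf("checkpoint not found: %s", path), "io_error")
  }
  doc <- jsonlite::read_json(path)
  restored_spec <- do.call(architecture_spec, doc$spec)
  if (!is.null(spec) &&
      !identical(config_hash(unclass(spec)), doc$spec_hash)) {
    stop_secretrain(
      "checkpoint was written under a different architecture configuration",
      "incompatibility_error")
  }
  feature_names <- as.character(unlist(doc$feature_names))
  if (identical(doc$kind, "model")) {
    structure(list(params = deserialize_params(doc$params),
                   spec = restored_spec,
                   feature_names = feature_names,
                   seed = doc$seed,
                   loss_history = as.numeric(unlist(doc$loss_history))),
              class = "secretrain_model")
  } else {
    trace <- dplyr::bind_rows(lapply(doc$trace, tibble::as_tibble))
    structure(list(members = lapply(doc$members, deserialize_params),
                   spec = restored_spec,
                   feature_names = feature_names,
                   iteration = doc$iteration,
                   seed = doc$seed,
                   config = do.call(selftrain_config, doc$config),
                   pseudo = list(
                     pseudo_positive_ids = as.character(unlist(doc$pseudo_positive)),
                     pseudo_negative_ids = as.character(unlist(doc$pseudo_negative))),
                   trace = trace),
              class = "selftrain_fit")
  }
}
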