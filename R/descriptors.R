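# Physicochemical and sequence-derived descriptor engine: the pre-constructed
# feature set consumed by the convolutional pathway and searched by the
# differential-evolution selector.

DESCRIPTOR_GROUPS <- c("global_physchem", "aac", "dipeptide", "tripeptide",
                       "paac", "apaac", "ctd", "structure_fractions",
                       "length", "window_profiles")

#' Descriptor configuration
#'
#' @param enabled_groups Character vector of descriptor groups to compute.
#'   The default enables `global_physchem` (9), `aac` (20), `dipeptide`
#'   (400), `paac` (25), `apaac` (30), `ctd` (147), `structure_fractions`
#'   (3), `length` (1) and `window_profiles` (4), i.e. 639 columns.
#'   Tripeptide composition (8000 columns) is implemented but disabled by
#'   default for dimensionality reasons.
#' @param paac_rank Sequence-order correlation depth for (amphiphilic)
#'   pseudo-amino-acid composition; must be smaller than the shortest
#'   sequence.
#' @param paac_weight Weight of the sequence-order terms, in (0, 1).
#' @param window_size Odd window length for the disorder/flexibility/
#'   aggregation profile descriptors.
#' @param aggregation_threshold Mean window hydropathy above which a window
#'   counts as aggregation-prone.
#' @return A named list of class `descriptor_config`.
#' @export
descriptor_config <- function(enabled_groups = setdiff(DESCRIPTOR_GROUPS,
                                                       "tripeptide"),
                              paac_rank = 5, paac_weight = 0.05,
                              window_size = 9,
                              aggregation_threshold = 1.0) {
  enabled_groups <- match.arg(enabled_groups, DESCRIPTOR_GROUPS,
                              several.ok = TRUE)
  if (length(enabled_groups) == 0) {
    stop_secretrain("at least one descriptor group must be enabled",
                    "config_error")
  }
  check_number(paac_rank, "paac_rank", lower = 1, integer = TRUE)
  check_number(paac_weight, "paac_weight", lower = 1e-12, upper = 1 - 1e-12)
  check_number(window_size, "window_size", lower = 1, integer = TRUE)
  if (window_size %% 2 == 0) {
    stop_secretrain("`window_size` must be odd", "config_error")
  }
  check_number(aggregation_threshold, "aggregation_threshold")
  structure(list(enabled_groups = enabled_groups,
                 paac_rank = as.integer(paac_rank),
                 paac_weight = paac_weight,
                 window_size = as.integer(window_size),
                 aggregation_threshold = aggregation_threshold),
            class = "descriptor_config")
}

# Codes with X as NA; physicochemical averages skip NA positions.
physchem_codes <- function(sequence) {
  codes <- seq_codes(sequence)
  if (length(codes) == 0 || all(is.na(codes))) {
    stop_secretrain("sequence contains no canonical residues", "undefined_descriptor")
  }
  codes
}

charge_at_ph <- function(sequence, ph) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  chars <- chars[chars %in% AA_ALPHABET]
  counts <- table(factor(chars, levels = AA_ALPHABET))
  pos <- PKA_POSITIVE
  neg <- PKA_NEGATIVE
  nterm <- chars[1]
  cterm <- chars[length(chars)]
  if (nterm %in% names(PKA_NTERMINAL)) pos[["Nterm"]] <- PKA_NTERMINAL[[nterm]]
  if (cterm %in% names(PKA_CTERMINAL)) neg[["Cterm"]] <- PKA_CTERMINAL[[cterm]]
  n_of <- function(aa) if (aa %in% c("Nterm", "Cterm")) 1 else counts[[aa]]
  positive <- sum(vapply(names(pos), function(aa) {
    n_of(aa) / (10^(ph - pos[[aa]]) + 1)
  }, numeric(1)))
  negative <- sum(vapply(names(neg), function(aa) {
    n_of(aa) / (10^(neg[[aa]] - ph) + 1)
  }, numeric(1)))
  positive - negative
}

isoelectric_point <- function(sequence) {
  # Interval bisection on the Bjellqvist charge model, matching the de-facto
  # standard toolkit (start 7.775, bracket [4.05, 12], width < 1e-4).
  lo <- 4.05
  hi <- 12
  ph <- 7.775
  while (hi - lo > 1e-4) {
    if (charge_at_ph(sequence, ph) > 0) lo <- ph else hi <- ph
    ph <- (lo + hi) / 2
  }
  ph
}

#' Global physicochemical descriptors
#'
#' Computes the nine whole-sequence physicochemical descriptors: average
#' molecular weight, aromaticity (F/Y/W frequency), Guruprasad instability
#' index, isoelectric point, Kyte-Doolittle GRAVY, net charge at pH 7,
#' Boman binding index, aliphatic index and mean helical hydrophobic moment
#' (amphipathicity, 11-residue window, 100 degrees per residue). Positions
#' holding the unknown code X are excluded from every average.
#'
#' @param sequence A single normalized amino-acid sequence.
#' @return A named numeric vector of length 9.
#' @export
compute_global_physchem <- function(sequence) {
  codes <- physchem_codes(sequence)
  known <- codes[!is.na(codes)]
  n <- length(known)
  freqs <- tabulate(known, nbins = 20) / n
  names(freqs) <- AA_ALPHABET

  mw <- sum(AA_MASS[known]) - (n - 1) * WATER_MASS
  aromaticity <- sum(freqs[AROMATIC])

  # Instability: dipeptide weights over adjacent canonical pairs.
  pairs_ok <- !is.na(codes[-length(codes)]) & !is.na(codes[-1])
  ii <- codes[-length(codes)][pairs_ok]
  jj <- codes[-1][pairs_ok]
  instability <- if (n > 1) 10 / n * sum(DIWV[cbind(ii, jj)]) else 0

  gravy <- mean(KYTE_DOOLITTLE[known])
  boman <- -mean(BOMAN_TFE[known])
  aliphatic <- 100 * (freqs[["A"]] + 2.9 * freqs[["V"]] +
                        3.9 * (freqs[["I"]] + freqs[["L"]]))

  # Mean helical hydrophobic moment over sliding 11-residue windows
  # (whole sequence if shorter), Eisenberg scale, delta = 100 degrees.
  h <- EISENBERG[known]
  win <- min(11L, n)
  angles <- (seq_len(n)) * 100 * pi / 180
  hs <- h * sin(angles)
  hc <- h * cos(angles)
  starts <- seq_len(n - win + 1L)
  css <- c(0, cumsum(hs))
  csc <- c(0, cumsum(hc))
  mu <- sqrt((css[starts + win] - css[starts])^2 +
               (csc[starts + win] - csc[starts])^2) / win
  amphipathicity <- mean(mu)

  c(molecular_weight = mw,
    aromaticity = aromaticity,
    instability_index = instability,
    isoelectric_point = isoelectric_point(sequence),
    gravy = gravy,
    net_charge_ph7 = charge_at_ph(sequence, 7),
    boman_index = boman,
    aliphatic_index = unname(aliphatic),
    amphipathicity = amphipathicity)
}

kmer_levels <- function(order) {
  if (order == 1) return(AA_ALPHABET)
  grids <- rev(rep(list(AA_ALPHABET), order))
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

#' Amino-acid and k-mer composition
#'
#' Relative frequencies of residues (`order = 1`), dipeptides (`order = 2`)
#' or tripeptides (`order = 3`), indexed in fixed alphabetical order. K-mers
#' containing the unknown code X are excluded from both numerator and
#' denominator; the returned vector sums to 1.
#'
#' @param sequence A normalized amino-acid sequence.
#' @param order K-mer order (1, 2 or 3).
#' @return Named frequency vector of length `20^order`.
#' @export
compute_composition <- function(sequence, order = 1) {
  check_number(order, "order", lower = 1, upper = 3, integer = TRUE)
  codes <- seq_codes(sequence)
  if (length(codes) < order) {
    stop_secretrain(sprintf("sequence shorter than k-mer order %d", order),
                    "short_sequence")
  }
  n <- length(codes) - order + 1L
  idx0 <- rep(0, n)
  valid <- rep(TRUE, n)
  for (k in seq_len(order)) {
    part <- codes[k:(k + n - 1L)]
    valid <- valid & !is.na(part)
    idx0 <- idx0 * 20 + (ifelse(is.na(part), 1L, part) - 1L)
  }
  idx <- idx0[valid] + 1L
  if (length(idx) == 0) {
    stop_secretrain("no fully canonical k-mers in sequence",
                    "undefined_descriptor")
  }
  counts <- tabulate(idx, nbins = 20^order)
  out <- counts / sum(counts)
  names(out) <- paste0(c("aac_", "dpc_", "tpc_")[order], kmer_levels(order))
  out
}

paac_scales <- function() {
  norm <- function(h) {
    (h - mean(h)) / sqrt(mean((h - mean(h))^2))
  }
  list(h1 = norm(PAAC_HYDROPHOBICITY[AA_ALPHABET]),
       h2 = norm(PAAC_HYDROPHILICITY[AA_ALPHABET]),
       m = norm(PAAC_SIDECHAIN_MASS[AA_ALPHABET]))
}

#' Pseudo-amino-acid composition
#'
#' Chou-type pseudo-amino-acid composition: the 20 residue frequencies plus
#' `paac_rank` sequence-order correlation factors built from normalized
#' hydrophobicity, hydrophilicity and side-chain mass scales. The amphiphilic
#' variant emits two correlation factors per lag (hydrophobicity and
#' hydrophilicity cross-products). The full vector sums to 1. Positions
#' holding X are skipped; a lag with no canonical pair contributes 0.
#'
#' @param sequence A normalized amino-acid sequence.
#' @param config A [descriptor_config()] providing `paac_rank` and
#'   `paac_weight`.
#' @param amphiphilic Compute the amphiphilic variant.
#' @return Named numeric vector of length `20 + rank` (or `20 + 2 * rank`).
#' @export
compute_paac <- function(sequence, config = descriptor_config(),
                         amphiphilic = FALSE) {
  rank <- config$paac_rank
  w <- config$paac_weight
  codes <- seq_codes(sequence)
  L <- length(codes)
  if (L <= rank) {
    stop_secretrain(sprintf(
      "sequence length %d must exceed paac_rank %d", L, rank),
      "short_sequence")
  }
  sc <- paac_scales()
  known <- codes[!is.na(codes)]
  freqs <- tabulate(known, nbins = 20) / length(known)

  if (!amphiphilic) {
    theta <- vapply(seq_len(rank), function(k) {
      i <- codes[seq_len(L - k)]
      j <- codes[seq_len(L - k) + k]
      ok <- !is.na(i) & !is.na(j)
      if (!any(ok)) return(0)
      mean(((sc$h1[j[ok]] - sc$h1[i[ok]])^2 +
              (sc$h2[j[ok]] - sc$h2[i[ok]])^2 +
              (sc$m[j[ok]] - sc$m[i[ok]])^2) / 3)
    }, numeric(1))
    denom <- sum(freqs) + w * sum(theta)
    out <- c(freqs, w * theta) / denom
    names(out) <- c(paste0("paac_", AA_ALPHABET),
                    paste0("paac_lambda", seq_len(rank)))
  } else {
    tau <- unlist(lapply(seq_len(rank), function(k) {
      i <- codes[seq_len(L - k)]
      j <- codes[seq_len(L - k) + k]
      ok <- !is.na(i) & !is.na(j)
      if (!any(ok)) return(c(0, 0))
      c(mean(sc$h1[i[ok]] * sc$h1[j[ok]]),
        mean(sc$h2[i[ok]] * sc$h2[j[ok]]))
    }))
    denom <- sum(freqs) + w * sum(tau)
    out <- c(freqs, w * tau) / denom
    names(out) <- c(paste0("apaac_", AA_ALPHABET),
                    paste0("apaac_", rep(c("hb", "hl"), rank),
                           rep(seq_len(rank), each = 2)))
  }
  out
}

#' Composition/transition/distribution descriptors
#'
#' Maps residues into three classes for each of seven physicochemical
#' property groupings (hydrophobicity, normalized van der Waals volume,
#' polarity, polarizability, charge, secondary-structure propensity, solvent
#' accessibility) and emits, per grouping: class composition (3), class
#' transitions (3) and the positional distribution of the first, 25th, 50th,
#' 75th and 100th percentile occurrence of each class (15), i.e. 147 values.
#' Distribution entries of an absent class are 0. X positions are skipped.
#'
#' @param sequence A normalized amino-acid sequence.
#' @return Named numeric vector of length 147.
#' @export
compute_ctd <- function(sequence) {
  codes <- seq_codes(sequence)
  known <- AA_ALPHABET[codes[!is.na(codes)]]
  n <- length(known)
  if (n < 2) {
    stop_secretrain("CTD needs at least two canonical residues",
                    "short_sequence")
  }
  out <- numeric(0)
  for (prop in names(CTD_GROUPS)) {
    classes <- CTD_GROUPS[[prop]]
    cls <- integer(n)
    for (g in 1:3) cls[known %in% classes[[g]]] <- g
    comp <- tabulate(cls, nbins = 3) / n
    a <- cls[-n]
    b <- cls[-1]
    trans <- c(sum((a == 1 & b == 2) | (a == 2 & b == 1)),
               sum((a == 1 & b == 3) | (a == 3 & b == 1)),
               sum((a == 2 & b == 3) | (a == 3 & b == 2))) / (n - 1)
    distr <- numeric(15)
    for (g in 1:3) {
      pos <- which(cls == g)
      if (length(pos) > 0) {
        qs <- pos[pmax(1, ceiling(length(pos) * c(0.0001, 0.25, 0.5, 0.75, 1)))]
        distr[(g - 1) * 5 + 1:5] <- 100 * qs / n
      }
    }
    vals <- c(comp, trans, distr)
    names(vals) <- paste0("ctd_", prop, "_",
                          c(paste0("comp", 1:3), paste0("tran", 1:3),
                            paste0("dist", rep(1:3, each = 5), "_",
                                   rep(c("first", "p25", "p50", "p75",
                                         "p100"), 3))))
    out <- c(out, vals)
  }
  out
}

#' Secondary-structure fractions
#'
#' Residue-propensity fractions under the classic single-residue convention:
#' helix \{V,I,Y,F,W,L\}, sheet \{E,M,A,L\}, coil/turn \{N,P,G,S\}.
#'
#' @param sequence A normalized amino-acid sequence.
#' @return Named numeric vector `frac_helix`, `frac_sheet`, `frac_coil`.
#' @export
compute_structure_fractions <- function(sequence) {
  codes <- physchem_codes(sequence)
  known <- AA_ALPHABET[codes[!is.na(codes)]]
  c(frac_helix = mean(known %in% SS_HELIX),
    frac_sheet = mean(known %in% SS_SHEET),
    frac_coil = mean(known %in% SS_COIL))
}

window_means <- function(vals, win) {
  n <- length(vals)
  if (n <= win) return(mean(vals, na.rm = TRUE))
  cs <- c(0, cumsum(ifelse(is.na(vals), 0, vals)))
  cn <- c(0, cumsum(!is.na(vals)))
  starts <- seq_len(n - win + 1L)
  tot <- cs[starts + win] - cs[starts]
  cnt <- cn[starts + win] - cn[starts]
  ifelse(cnt > 0, tot / cnt, NA_real_)
}

#' Window-profile descriptors
#'
#' Sliding-window proxies for structural disorder (TOP-IDP scale), backbone
#' flexibility (Vihinen scale, fixed 9-residue windows), aggregation
#' propensity (fraction of windows whose mean Kyte-Doolittle hydropathy
#' exceeds a threshold) and the number of tryptic cleavage sites (K or R not
#' followed by P). Sequences shorter than the window are scored as a single
#' whole-sequence window.
#'
#' @param sequence A normalized amino-acid sequence.
#' @param config A [descriptor_config()].
#' @return Named numeric vector `disorder_score`, `flexibility_score`,
#'   `aggregation_propensity`, `cleavage_site_count`.
#' @export
compute_window_profiles <- function(sequence,
                                    config = descriptor_config()) {
  codes <- physchem_codes(sequence)
  win <- config$window_size
  disorder <- mean(window_means(TOP_IDP[codes], win), na.rm = TRUE)
  flexibility <- mean(window_means(FLEX_VIHINEN[codes], 9L), na.rm = TRUE)
  hyd <- window_means(KYTE_DOOLITTLE[codes], win)
  aggregation <- mean(hyd > config$aggregation_threshold, na.rm = TRUE)
  chars <- AA_ALPHABET[codes]
  kr <- which(!is.na(chars) & chars %in% c("K", "R"))
  nxt <- chars[pmin(kr + 1L, length(chars))]
  cleave <- sum(kr == length(chars) | is.na(nxt) | nxt != "P")
  c(disorder_score = disorder, flexibility_score = flexibility,
    aggregation_propensity = aggregation,
    cleavage_site_count = as.numeric(cleave))
}

sequence_descriptors <- function(sequence, config) {
  parts <- list()
  g <- config$enabled_groups
  if ("global_physchem" %in% g) parts$gp <- compute_global_physchem(sequence)
  if ("aac" %in% g) parts$aac <- compute_composition(sequence, 1)
  if ("dipeptide" %in% g) parts$dpc <- compute_composition(sequence, 2)
  if ("tripeptide" %in% g) parts$tpc <- compute_composition(sequence, 3)
  if ("paac" %in% g) parts$paac <- compute_paac(sequence, config, FALSE)
  if ("apaac" %in% g) parts$apaac <- compute_paac(sequence, config, TRUE)
  if ("ctd" %in% g) parts$ctd <- compute_ctd(sequence)
  if ("structure_fractions" %in% g) {
    parts$ss <- compute_structure_fractions(sequence)
  }
  if ("length" %in% g) parts$len <- c(seq_length = nchar(sequence))
  if ("window_profiles" %in% g) {
    parts$wp <- compute_window_profiles(sequence, config)
  }
  unlist(unname(parts))
}

#' Compute the pre-constructed feature matrix
#'
#' Applies every enabled descriptor group to each record and assembles a
#' proteins-by-descriptors tibble (first column `protein_id`). Column order
#' is fixed: global physicochemical, AAC, dipeptide, (tripeptide), PAAC,
#' amphiphilic PAAC, CTD, structure fractions, length, window profiles.
#'
#' @param records Tibble with `id` and `sequence` columns (normalized).
#' @param config A [descriptor_config()].
#' @return A tibble with one row per record and one column per descriptor.
#' @export
featurize <- function(records, config = descriptor_config()) {
  if (nrow(records) == 0) {
    stop_secretrain("no records to featurize", "config_error")
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    tryCatch(sequence_descriptors(records$sequence[i], config),
             error = function(e) {
               stop_secretrain(sprintf("featurize failed for record %s: %s",
                                       records$id[i], conditionMessage(e)),
                               "featurize_error")
             })
  })
  mat <- do.call(rbind, rows)
  out <- tibble::as_tibble(as.data.frame(mat))
  stopifnot(!anyDuplicated(names(out)))
  dplyr::bind_cols(tibble::tibble(protein_id = records$id), out)
}

#' Standardize feature columns
#'
#' Z-scores every descriptor column using means and standard deviations
#' fitted on a designated subset of rows (by default all rows), and attaches
#' the fitted scaling as the `scaling` attribute so it can be re-applied to
#' new data. Zero-variance columns are centred only.
#'
#' @param features Feature tibble from [featurize()].
#' @param fit_ids Protein ids of the rows used to fit means/sds (default all).
#' @param scaling A previously fitted scaling tibble (`feature`, `mean`,
#'   `sd`); overrides `fit_ids`.
#' @return The standardized feature tibble with a `scaling` attribute.
#' @export
standardize_features <- function(features, fit_ids = NULL, scaling = NULL) {
  cols <- setdiff(names(features), "protein_id")
  if (is.null(scaling)) {
    fit_rows <- if (is.null(fit_ids)) {
      seq_len(nrow(features))
    } else {
      match(fit_ids, features$protein_id)
    }
    if (anyNA(fit_rows)) {
      stop_secretrain("fit_ids contain ids absent from the feature matrix",
                      "missing_record")
    }
    sub <- as.matrix(features[fit_rows, cols])
    mu <- colMeans(sub)
    sdv <- apply(sub, 2, stats::sd)
    scaling <- tibble::tibble(feature = cols, mean = unname(mu),
                              sd = unname(sdv))
  }
  if (!identical(scaling$feature, cols)) {
    stop_secretrain("scaling state does not match feature columns",
                    "dimension_error")
  }
  sdv <- ifelse(scaling$sd > 0, scaling$sd, 1)
  mat <- as.matrix(features[, cols])
  mat <- sweep(mat, 2, scaling$mean, "-")
  mat <- sweep(mat, 2, sdv, "/")
  out <- dplyr::bind_cols(tibble::tibble(protein_id = features$protein_id),
                          tibble::as_tibble(as.data.frame(mat)))
  attr(out, "scaling") <- scaling
  out
}
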