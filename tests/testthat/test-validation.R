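test_that("metrics follow the printed formulas on a worked example", {
  m <- compute_metrics(list(tp = 2, tn = 2, fp = 1, fn = 1))
  expect_equal(m$acc, 2 / 3, tolerance = 1e-12)
  expect_equal(m$sn, 2 / 3, tolerance = 1e-12)
  expect_equal(m$sp, 2 / 3, tolerance = 1e-12)
  expect_equal(m$mcc, 1 / 3, tolerance = 1e-12)
  expect_equal(m$f1, 2 / 3, tolerance = 1e-12)

  perfect <- compute_metrics(list(tp = 5, tn = 5, fp = 0, fn = 0),
                             tibble::tibble(probability = c(.9, .8, .1, .2),
                                            label = c(1, 1, 0, 0)))
  expect_equal(unlist(perfect[c("acc", "sn", "sp", "mcc", "auc", "f1")]),
               c(acc = 1, sn = 1, sp = 1, mcc = 1, auc = 1, f1 = 1))

  # zero-denominator MCC convention
  expect_equal(compute_metrics(list(tp = 3, tn = 0, fp = 0, fn = 2))$mcc, 0)
  expect_error(compute_metrics(list(tp = 0, tn = 0, fp = 0, fn = 0)),
               class = "secretrain_value_error")
  expect_error(
    compute_metrics(list(tp = 1, tn = 0, fp = 0, fn = 0),
                    tibble::tibble(probability = 0.5, label = 1)),
    class = "secretrain_undefined_metric")
})

test_that("metrics match a brute-force confusion oracle on random data", {
  set.seed(14)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    truth <- rbinom(n, 1, 0.5)
    if (length(unique(truth)) < 2) next
    pred <- rbinom(n, 1, 0.5)
    counts <- confusion_counts(truth, pred)
    oracle <- confusion_oracle(truth, pred)
    expect_identical(counts[order(names(counts))],
                     lapply(oracle[order(names(oracle))], as.integer))
    m <- compute_metrics(counts)
    expect_equal(m$acc, mean(truth == pred), tolerance = 1e-12)
  }
})

test_that("metric arithmetic stays exact for large integer counts", {
  counts <- list(tp = 50000L, tn = 48000L, fp = 2500L, fn = 1800L)
  m <- compute_metrics(counts)
  tp <- 50000; tn <- 48000; fp <- 2500; fn <- 1800
  expect_equal(m$mcc, (tp * tn - fp * fn) /
                 sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)),
               tolerance = 1e-12)
})

test_that("rank AUC equals the normalized Mann-Whitney statistic", {
  set.seed(15)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    label <- c(rep(1, 3), rbinom(n - 6, 1, 0.5), rep(0, 3))
    prob <- round(runif(n), 2)   # force ties
    auc <- compute_metrics(confusion_counts(label, prob >= 0.5),
                           tibble::tibble(probability = prob,
                                          label = label))$auc
    w <- wilcox.test(prob[label == 1], prob[label == 0],
                     exact = FALSE)$statistic
    expect_equal(auc, unname(w) / (sum(label == 1) * sum(label == 0)),
                 tolerance = 1e-12)
  }
})

test_that("the F1 variants coincide exactly when SP equals precision", {
  # balanced symmetric errors: SP == precision
  m <- compute_metrics(list(tp = 40, tn = 40, fp = 10, fn = 10))
  expect_equal(m$f1, m$f1_precision_recall, tolerance = 1e-12)
  # imbalanced: the two definitions part ways, both reported
  m2 <- compute_metrics(list(tp = 40, tn = 10, fp = 40, fn = 2))
  expect_false(isTRUE(all.equal(m2$f1, m2$f1_precision_recall)))
})

test_that("splitting uses the ceiling convention and a fixed seed", {
  ids <- sprintf("id%05d", 1:10256)
  spl <- split_dataset(ids, 0.2, seed = 42)
  expect_length(spl$training, 8204)
  expect_length(spl$validation, 2052)
  expect_setequal(c(spl$training, spl$validation), ids)

  spl2 <- split_dataset(ids, 0.2, seed = 42)
  expect_identical(spl, spl2)

  small <- split_dataset(sprintf("x%02d", 1:10), 0.2, seed = 1)
  expect_length(small$training, 8)
  expect_length(small$validation, 2)
  expect_error(split_dataset("one", 0.2), class = "secretrain_split_error")
})

test_that("negative-candidate filtering applies keywords and confidence", {
  ann <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    subcellular_location = c("Extracellular matrix", "nucleus", "nucleus",
                             "Synapse junction"),
    signal_peptide = "",
    tm_region = NA, n_glycosylation = NA, disulfide = NA, gpi_anchor = NA)
  scores <- tibble::tibble(id = c("a", "b", "c", "d"),
                           confidence = c(5, 2, 0.9, 2))
  kept <- filter_negative_candidates(ann, scores)
  expect_equal(kept, "b")   # a: keyword, c: low confidence, d: keyword

  flipped <- filter_negative_candidates(
    ann, scores, negative_filter_config(keep_above = FALSE,
                                        confidence_threshold = 1.1))
  expect_equal(flipped, "c")

  expect_error(
    filter_negative_candidates(ann[1:2, ], scores),
    class = "secretrain_consistency_error")
})

test_that("annotation cross-check reproduces the retention arithmetic", {
  # cohort of 2038 candidates of which 20 carry secretion evidence
  n <- 2038
  ann <- tibble::tibble(
    id = sprintf("n%04d", 1:n),
    subcellular_location = c(rep("Secreted", 8),
                             rep("Extracellular space", 6),
                             rep("Cytoplasm", n - 14)),
    signal_peptide = c(rep("", 14), rep("SIGNAL 1..22", 6),
                       rep("", n - 20)),
    tm_region = NA, n_glycosylation = NA, disulfide = NA, gpi_anchor = NA)
  rep_ <- cross_check_against_annotations(ann$id, ann)
  expect_equal(rep_$retained[rep_$criterion == "D"], 2018)
  expect_equal(rep_$retained_pct[rep_$criterion == "D"], 99.02)
  expect_equal(rep_$retained[rep_$criterion == "A"], n - 8)
  expect_equal(rep_$retained[rep_$criterion == "C"], n - 6)
  # percentages recompute from the report's own counts
  expect_equal(rep_$retained_pct,
               floor(100 * rep_$retained / rep_$total * 100 + 0.5) / 100)

  # single-criterion case: SP field only
  one <- tibble::tibble(id = "p", subcellular_location = "",
                        signal_peptide = "SIGNAL 1..22", tm_region = NA,
                        n_glycosylation = NA, disulfide = NA,
                        gpi_anchor = NA)
  r1 <- cross_check_against_annotations("p", one)
  expect_equal(r1$excluded, c(0, 0, 1, 1))

  # fully cytoplasmic protein is retained under every criterion
  cyt <- tibble::tibble(id = "q", subcellular_location = "Cytoplasm",
                        signal_peptide = "", tm_region = NA,
                        n_glycosylation = NA, disulfide = NA,
                        gpi_anchor = NA)
  expect_equal(cross_check_against_annotations("q", cyt)$retained,
               rep(1, 4))
  expect_error(cross_check_against_annotations("ghost", cyt),
               class = "secretrain_missing_annotation")
})

test_that("motif detectors follow the terminal-window rules", {
  expect_true(detect_er_retention("MKTAAAKDEL"))
  expect_true(detect_er_retention("AAAAQEEL"))
  expect_false(detect_er_retention("MKTKDELA"))
  expect_false(detect_er_retention("DEL"))
  expect_true(all(detect_er_retention(paste0("AAAA", c("KDEL", "HDEL",
                                                       "KEEL", "QEEL")))))

  expect_true(detect_dibasic_cleavage(paste0(strrep("A", 30), "KR",
                                             strrep("A", 5))))
  expect_false(detect_dibasic_cleavage(paste0("KR", strrep("A", 30))))
  expect_true(detect_dibasic_cleavage(paste0(strrep("A", 10), "RR")))
  expect_true(detect_dibasic_cleavage("RR"))
  expect_false(detect_dibasic_cleavage("R"))
  # boundary: motif starting exactly 20 residues from the end counts,
  # one residue earlier does not
  exactly20 <- paste0(strrep("A", 10), "KR", strrep("A", 18))
  expect_true(detect_dibasic_cleavage(exactly20))
  at21 <- paste0(strrep("A", 10), "KR", strrep("A", 19))
  expect_false(detect_dibasic_cleavage(at21))
})

test_that("marker profiles aggregate by group with availability flags", {
  recs <- tibble::tibble(id = c("a", "b", "c", "d"),
                         sequence = c("MAAAKDEL", "MAAAAAAA",
                                      paste0(strrep("A", 10), "KRAA"),
                                      "MWWWWWWW"))
  groups <- tibble::tibble(id = recs$id,
                           group = c("pseudo_negative", "pseudo_negative",
                                     "pseudo_positive", "pseudo_positive"))
  prof <- build_marker_profiles(recs, groups)
  er_neg <- prof$proportion[prof$group == "pseudo_negative" &
                              prof$marker == "er_retention"]
  expect_equal(er_neg, 0.5)
  # annotation-derived markers unavailable without a table
  expect_false(any(prof$available[prof$marker == "signal_peptide"]))
  expect_true(all(is.na(prof$proportion[prof$marker == "tm_region"])))
  # any_marker dominates every individual marker within a group
  for (g in unique(prof$group)) {
    any_p <- prof$proportion[prof$group == g & prof$marker == "any_marker"]
    singles <- prof$proportion[prof$group == g &
                                 prof$marker != "any_marker"]
    expect_true(all(singles[!is.na(singles)] <= any_p))
  }

  ann <- tibble::tibble(id = recs$id,
                        subcellular_location = "",
                        signal_peptide = c("", "", "SIGNAL 1..20", ""),
                        tm_region = c(FALSE, FALSE, TRUE, FALSE),
                        n_glycosylation = FALSE, disulfide = FALSE,
                        gpi_anchor = FALSE)
  prof2 <- build_marker_profiles(recs, groups, ann)
  sp_pos <- prof2$proportion[prof2$group == "pseudo_positive" &
                               prof2$marker == "signal_peptide"]
  expect_equal(sp_pos, 0.5)
})

test_that("PCA-space class separation behaves like a Mahalanobis distance", {
  set.seed(33)
  n <- 500
  g1 <- cbind(rnorm(n, 0), rnorm(n, 0), rnorm(n, 0))
  g2 <- cbind(rnorm(n, 3), rnorm(n, 0), rnorm(n, 0))
  X <- rbind(g1, g2)
  labels <- rep(c(0, 1), each = n)
  d <- pca_class_separation(X, labels)
  expect_equal(d, 3, tolerance = 0.1)

  # shuffled labels on a shared cloud: no separation
  d0 <- pca_class_separation(X, sample(labels))
  expect_lt(d0, 0.2)

  # rotation invariance of the retained subspace
  theta <- 0.7
  R <- diag(3)
  R[1:2, 1:2] <- matrix(c(cos(theta), sin(theta), -sin(theta),
                          cos(theta)), 2)
  expect_equal(pca_class_separation(X %*% R, labels), d, tolerance = 1e-6)

  expect_error(pca_class_separation(X, rep(1, 2 * n)),
               class = "secretrain_value_error")
})
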