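test_that("global physicochemical descriptors match the reference toolkit", {
  ref <- readr::read_tsv(test_path("physchem-reference.tsv"),
                         col_types = readr::cols(sequence = "c",
                                                 .default = "d"),
                         progress = FALSE)
  for (i in seq_len(nrow(ref))) {
    g <- compute_global_physchem(ref$sequence[i])
    expect_equal(g[["molecular_weight"]], ref$molecular_weight[i],
                 tolerance = 1e-6)
    expect_equal(g[["aromaticity"]], ref$aromaticity[i], tolerance = 1e-9)
    expect_equal(g[["instability_index"]], ref$instability_index[i],
                 tolerance = 1e-9)
    expect_equal(g[["isoelectric_point"]], ref$isoelectric_point[i],
                 tolerance = 1e-6)
    expect_equal(g[["gravy"]], ref$gravy[i], tolerance = 1e-9)
    expect_equal(g[["net_charge_ph7"]], ref$net_charge_ph7[i],
                 tolerance = 1e-9)
  }
})

test_that("worked physicochemical examples hold", {
  expect_equal(compute_global_physchem("FYWA")[["aromaticity"]], 0.75)
  expect_equal(compute_global_physchem("AA")[["gravy"]], 1.8)
  # an instability index above 40 marks an unstable protein
  idx <- compute_global_physchem("MWCW")[["instability_index"]]
  expect_gt(idx, 40)
  # aliphatic index closed form
  g <- compute_global_physchem("AVIL")
  expect_equal(g[["aliphatic_index"]],
               100 * (0.25 + 2.9 * 0.25 + 3.9 * 0.5))
  # Boman index is minus the mean transfer free energy
  expect_equal(compute_global_physchem("LK")[["boman_index"]],
               -(4.92 - 5.55) / 2)
})

test_that("composition vectors are exact frequency counts", {
  aac <- compute_composition("AAAA", 1)
  expect_equal(aac[["aac_A"]], 1)
  expect_equal(sum(aac), 1)

  dpc <- compute_composition("ACAC", 2)
  expect_equal(dpc[["dpc_AC"]], 2 / 3)
  expect_equal(dpc[["dpc_CA"]], 1 / 3)
  expect_equal(sum(dpc), 1)

  expect_error(compute_composition("A", 2),
               class = "secretrain_short_sequence")
  # X-containing k-mers drop from numerator and denominator
  expect_equal(compute_composition("AXA", 1)[["aac_A"]], 1)
  expect_equal(compute_composition("AXAC", 2)[["dpc_AC"]], 1)
})

test_that("pseudo-amino-acid composition matches a brute-force recursion", {
  cfg <- descriptor_config(paac_rank = 2, paac_weight = 0.05)
  got <- compute_paac("ACDEFG", cfg)
  expect_equal(unname(got), paac_oracle("ACDEFG", 2, 0.05),
               tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-9)

  set.seed(42)
  for (i in 1:5) {
    s <- paste(sample(secretrain:::AA_ALPHABET, 40, TRUE), collapse = "")
    expect_equal(unname(compute_paac(s, descriptor_config())),
                 paac_oracle(s, 5, 0.05), tolerance = 1e-12)
  }

  # homopolymer: zero sequence-order variance, pure composition
  hp <- compute_paac("AAAAAA", cfg)
  expect_equal(hp[["paac_A"]], 1)
  expect_equal(unname(hp[21:22]), c(0, 0))

  ap <- compute_paac("ACDEFGHIK", descriptor_config(paac_rank = 3), TRUE)
  expect_length(ap, 26)
  expect_equal(sum(ap), 1, tolerance = 1e-9)
  expect_error(compute_paac("ACD", descriptor_config(paac_rank = 5)),
               class = "secretrain_short_sequence")
})

test_that("CTD blocks follow the class mapping conventions", {
  ctd <- compute_ctd("RKRK")
  # R and K share the positive charge class: no charge transitions
  expect_equal(ctd[["ctd_charge_comp1"]], 1)
  expect_equal(unname(ctd[grep("ctd_charge_tran", names(ctd))]),
               c(0, 0, 0))
  # distribution of an absent class is zero by convention
  expect_equal(unname(ctd[grep("ctd_charge_dist3", names(ctd))]), rep(0, 5))
  # composition triple sums to one for every property
  for (p in names(secretrain:::CTD_GROUPS)) {
    expect_equal(sum(ctd[paste0("ctd_", p, "_comp", 1:3)]), 1,
                 tolerance = 1e-9)
  }
  # brute-force check of hydrophobicity composition for a mixed sequence
  s <- "RGCLAV"
  got <- compute_ctd(s)
  expect_equal(got[["ctd_hydrophobicity_comp1"]], 1 / 6)  # R
  expect_equal(got[["ctd_hydrophobicity_comp2"]], 2 / 6)  # G, A
  expect_equal(got[["ctd_hydrophobicity_comp3"]], 3 / 6)  # C, L, V
  expect_error(compute_ctd("A"), class = "secretrain_short_sequence")
})

test_that("structure fractions use the classic residue sets", {
  expect_equal(compute_structure_fractions("VVVV")[["frac_helix"]], 1)
  ss <- compute_structure_fractions("NPGS")
  expect_equal(unname(ss), c(0, 0, 1))
  # L belongs to both helix and sheet sets
  ss2 <- compute_structure_fractions("LE")
  expect_equal(ss2[["frac_helix"]], 0.5)
  expect_equal(ss2[["frac_sheet"]], 1)
})

test_that("window profiles count cleavage sites and average scales", {
  expect_equal(compute_window_profiles("AKAA")[["cleavage_site_count"]], 1)
  expect_equal(compute_window_profiles("AKPA")[["cleavage_site_count"]], 0)
  wp <- compute_window_profiles(strrep("A", 30))
  expect_equal(wp[["flexibility_score"]], 0.984)   # homopolymer = scale value
  expect_equal(wp[["disorder_score"]], 0.06, tolerance = 1e-12)
})

test_that("featurize assembles the documented column layout", {
  recs <- tiny_records()
  fm <- featurize(recs)
  expect_equal(dim(fm), c(4, 640))
  expect_false(anyNA(fm))
  expect_true(all(vapply(fm[-1], is.finite, logical(nrow(fm)))))

  fm_aac <- featurize(recs, descriptor_config(enabled_groups = "aac"))
  expect_equal(ncol(fm_aac), 21)

  # permutation equivariance
  perm <- c(3, 1, 4, 2)
  fm_perm <- featurize(recs[perm, ])
  expect_equal(fm_perm, fm[perm, ], ignore_attr = TRUE)

  # failures carry the offending id
  bad <- tibble::tibble(id = "weird", sequence = "XXX")
  expect_error(featurize(bad), "weird")
})

test_that("standardization is a fitted, re-applicable z-score", {
  recs <- tiny_records()
  fm <- featurize(recs, desk_descriptors())
  std <- standardize_features(fm)
  vals <- as.matrix(std[, -1])
  mu <- colMeans(vals)
  sdv <- apply(vals, 2, sd)
  expect_true(all(abs(mu) < 1e-8))
  expect_true(all(abs(sdv[sdv > 0] - 1) < 1e-8))

  # re-application with the stored scaling reproduces the transform
  again <- standardize_features(fm, scaling = attr(std, "scaling"))
  expect_equal(again, std)
})

test_that("frequency blocks sum to one for generator output", {
  syn <- simulate_proteins(synthesis_config(n_positive = 5, n_negative = 5,
                                            n_unlabeled = 5, seed = 3))
  for (s in syn$records$sequence) {
    expect_equal(sum(compute_composition(s, 1)), 1, tolerance = 1e-9)
    expect_equal(sum(compute_composition(s, 2)), 1, tolerance = 1e-9)
    expect_equal(sum(compute_paac(s, descriptor_config())), 1,
                 tolerance = 1e-9)
    expect_equal(sum(compute_paac(s, descriptor_config(), TRUE)), 1,
                 tolerance = 1e-9)
  }
})
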