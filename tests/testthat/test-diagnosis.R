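# diagnosis: metrics arithmetic, cross-validated evaluation protocol,
# single-scan diagnosis and model persistence

test_that("metrics reproduce the reference confusion arithmetic", {
  perfect <- metrics(tp = 65, fp = 0, tn = 19, fn = 0)
  expect_equal(unlist(perfect), c(acc_pct = 100, spec_pct = 100,
                                  sens_pct = 100))
  # printed values in the source tables are truncated; +-0.02 tolerance
  cell <- metrics(tp = 65, fp = 10, tn = 9, fn = 0)
  expect_equal(cell$acc_pct, 88.09, tolerance = 0.02)
  expect_equal(cell$spec_pct, 47.36, tolerance = 0.02)
  expect_equal(cell$sens_pct, 100)
  # degenerate always-MCI predictor on a 19 NC / 65 MCI cohort
  degen <- metrics(tp = 65, fp = 19, tn = 0, fn = 0)
  expect_equal(degen$acc_pct, 77.38)
  expect_equal(degen$spec_pct, 0)
  expect_equal(degen$sens_pct, 100)
  expect_error(metrics(0, 0, 0, 0), "undefined metric")
  expect_error(metrics(0, 1, 1, 0), "sensitivity")
  expect_error(metrics(1, 0, 0, 1), "specificity")
})

test_that("LOSO on the strong-effect phantom is perfect and audited", {
  feat <- small_features()
  ev <- evaluate_features(feat, eval_scheme("LOSO"))
  expect_equal(c(ev$acc_pct, ev$spec_pct, ev$sens_pct), c(100, 100, 100))
  # every subject predicted exactly once
  expect_equal(sum(ev$counts), length(unique(feat$subject_id)))
  expect_identical(sort(ev$predictions$subject_id),
                   sort(unique(feat$subject_id)))
  # selection recovered exactly the planted regions
  expect_identical(ev$selected_per_fold[["1"]],
                   planted_region_ids(small_sim()$registry))
})

test_that("stratified K-fold evaluates every subject once, deterministically", {
  feat <- small_features()
  for (k in c(2L, 4L)) {
    ev <- evaluate_features(feat, eval_scheme("KFOLD", k = k,
                                              shuffle_seed = 9L))
    expect_equal(sum(ev$counts), 14)
    ev2 <- evaluate_features(feat, eval_scheme("KFOLD", k = k,
                                               shuffle_seed = 9L))
    expect_identical(ev$predictions, ev2$predictions)
  }
})

test_that("nested selection uses only training subjects per fold", {
  feat <- small_features()
  ids <- unique(feat$subject_id)
  labels <- feat$group[match(ids, feat$subject_id)]
  mt <- petcad:::mean_table_from_features(feat, ids)
  ev <- evaluate_features(feat, eval_scheme("LOSO",
                                            selection_scope = "nested"))
  # audit: each fold's selection must equal a from-scratch selection on
  # that fold's training rows (the held-out subject cannot influence it)
  for (f in names(ev$selected_per_fold)) {
    tr <- setdiff(seq_along(ids), as.integer(f))
    ref <- select_regions(mt[tr, , drop = FALSE], labels[tr])$selected
    expect_identical(ev$selected_per_fold[[f]], ref)
  }
})

test_that("label permutation destroys the signal (null control)", {
  # run on the full-size strong-effect cohort (the stated world for this
  # property); its 65/84 base rate is what a signal-free classifier
  # collapses to
  feat <- acceptance_features()
  ids <- unique(feat$subject_id)
  labels <- as.character(feat$group[match(ids, feat$subject_id)])
  planted <- planted_region_ids(acceptance_sim()$registry)
  base_rate <- 100 * mean(labels == "MCI")
  accs <- sapply(1:20, function(s) {
    perm <- petcad:::with_seed(3000 + s, sample(labels))
    pf <- feat
    pf$group <- perm[match(pf$subject_id, ids)]
    evaluate_features(pf, eval_scheme("LOSO"),
                      region_subset = planted)$acc_pct
  })
  expect_lt(abs(mean(accs) - base_rate), 10)
})

test_that("ablations: excluding the planted regions hurts performance", {
  feat <- small_features()
  planted <- planted_region_ids(small_sim()$registry)
  ev_all <- evaluate_features(feat, eval_scheme("LOSO"),
                              region_subset = 1:116)
  ev_excl <- evaluate_features(feat, eval_scheme("LOSO"),
                               region_subset = setdiff(1:116, planted))
  ev_sig <- evaluate_features(feat, eval_scheme("LOSO"))
  expect_gte(ev_sig$acc_pct, ev_excl$acc_pct)
  expect_gte(ev_all$acc_pct, ev_excl$acc_pct)
})

test_that("diagnose produces per-region probabilities and a global call", {
  sim <- small_sim()
  feat <- small_features()
  model <- fit_pipeline_model(sim$cohort, sim$atlas, sim$registry,
                              ladder = small_ladder(), feat_df = feat)
  prof <- small_profile()
  mci <- simulate_subject(sim$atlas, sim$registry, prof, "MCI",
                          seed = 777L)
  nc <- simulate_subject(sim$atlas, sim$registry, prof, "NC",
                         seed = 778L)
  rep_mci <- diagnose(mci, sim$atlas, sim$registry, model, overlay = TRUE)
  rep_nc <- diagnose(nc, sim$atlas, sim$registry, model)
  expect_equal(rep_mci$global_label, "MCI")
  expect_equal(rep_nc$global_label, "NC")
  expect_true(all(rep_mci$region_probs > 0 & rep_mci$region_probs < 1))
  # overlay: probabilities painted into selected-region masks only
  ov <- rep_mci$overlay$values
  expect_gte(min(ov), 0); expect_lte(max(ov), 1)
  outside <- !(sim$atlas$labels %in% model$selection$selected)
  expect_true(all(ov[outside] == 0))
  expect_true(any(ov > 0))
  # the overlay survives a NIfTI round trip within float precision
  p <- file.path(withr::local_tempdir(), "overlay.nii.gz")
  write_volume(rep_mci$overlay, p)
  back <- read_volume(p)
  expect_gte(min(back$values), 0)
  expect_lte(max(back$values), 1)
})

test_that("models persist losslessly and refuse tampered configs", {
  sim <- small_sim()
  model <- fit_pipeline_model(sim$cohort, sim$atlas, sim$registry,
                              ladder = small_ladder(),
                              feat_df = small_features())
  p <- file.path(withr::local_tempdir(), "model.json")
  write_model(model, p)
  back <- read_model(p)
  expect_identical(back$selection$selected, model$selection$selected)
  expect_identical(back$config_hash, model$config_hash)
  # identical predictions after the round trip
  prof <- small_profile()
  scan <- simulate_subject(sim$atlas, sim$registry, prof, "MCI",
                           seed = 55L)
  r1 <- diagnose(scan, sim$atlas, sim$registry, model)
  r2 <- diagnose(scan, sim$atlas, sim$registry, back)
  expect_equal(r1$region_probs, r2$region_probs, tolerance = 1e-10)
  expect_equal(r1$global_score, r2$global_score, tolerance = 1e-10)
  # tamper with the embedded config
  txt <- readLines(p, warn = FALSE)
  txt <- sub("\"alpha_family\":0.05", "\"alpha_family\":0.5", txt)
  writeLines(txt, p)
  expect_error(read_model(p), "hash mismatch")
})

test_that("untrainable folds are refused with a clear error", {
  feat <- small_features()
  # keep only one NC subject: LOSO training folds lack the NC class
  ids <- unique(feat$subject_id)
  keep <- c(ids[1], ids[7:14])
  sub <- feat[feat$subject_id %in% keep, ]
  expect_error(evaluate_features(sub, eval_scheme("LOSO")),
               "at least 2 subjects|single class")
})
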