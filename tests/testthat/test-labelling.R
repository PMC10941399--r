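# Constructs small complexes with exact distances to exercise the labelling
# rules, then the bootstrap/training/prediction machinery on synthetic data.

test_that("contact, ambiguity and burial rules label residues as specified", {
  # residues along x; leader ligand atom at x = 0, member ligand at x = 30
  s <- ca_structure(rbind(c(4.9, 0, 0), c(10, 0, 0), c(25.1, 0, 0),
                          c(40, 0, 0), c(60, 0, 0)))
  leader <- list(ligand_instance("LIG", "L", 1, rbind(c(0, 0, 0))))
  member <- list(ligand_instance("MEM", "M", 1, rbind(c(30, 0, 0))))
  rsa <- setNames(c(0.5, 0.5, 0.5, 0.5, 0.01), s$residue_keys)

  lab <- label_from_complexes(s, leader, rsa, member_ligands = member)
  expect_identical(unname(lab),
                   c("binding",             # 4.9 A from leader ligand
                     "non_binding",         # 10 A from everything
                     "excluded_ambiguous",  # 4.9 A from member ligand only
                     "non_binding",
                     "excluded_buried"))    # RSA 0.01 <= 0.02

  # burial overrides even a leader contact
  rsa2 <- setNames(c(0.01, 0.5, 0.5, 0.5, 0.5), s$residue_keys)
  lab2 <- label_from_complexes(s, leader, rsa2, member_ligands = member)
  expect_identical(lab2[[1]], "excluded_buried")

  # boundary: exactly 5.0 A is a contact (rule is inclusive)
  s5 <- ca_structure(rbind(c(5, 0, 0), c(5.001, 0, 0), c(20, 0, 0)))
  rsa5 <- setNames(rep(0.5, 3), s5$residue_keys)
  lab5 <- label_from_complexes(s5, leader, rsa5)
  expect_identical(unname(lab5[1:2]), c("binding", "non_binding"))

  # every residue gets exactly one label
  expect_length(lab, n_residues(s))
  expect_true(all(lab %in% c("binding", "non_binding", "excluded_ambiguous",
                             "excluded_buried")))
})

test_that("training sets are balanced bootstrap draws with derived sub-seeds", {
  set.seed(99)
  n_pos <- 100; n_neg <- 1000
  keys <- c(sprintf("P%d", 1:n_pos), sprintf("N%d", 1:n_neg))
  emb <- matrix(rnorm((n_pos + n_neg) * 8), ncol = 8,
                dimnames = list(keys, NULL))
  labels <- setNames(rep(c("binding", "non_binding"), c(n_pos, n_neg)), keys)

  sets <- build_training_sets(emb, labels, n_sets = 40, seed = 3)
  expect_length(sets, 40)
  for (ts in sets[c(1, 20, 40)]) {
    expect_equal(sum(ts$y == 1), 80)          # floor(0.8 * 100)
    expect_equal(sum(ts$y == 0), 80)          # balanced
    expect_true(all(grepl("^P", ts$keys[ts$y == 1])))
    expect_true(all(grepl("^N", ts$keys[ts$y == 0])))
  }
  expect_false(identical(sets[[1]]$keys, sets[[2]]$keys))

  again <- build_training_sets(emb, labels, n_sets = 40, seed = 3)
  expect_identical(lapply(sets, `[[`, "keys"), lapply(again, `[[`, "keys"))

  # excluded classes are never sampled
  labels2 <- labels
  labels2[sample(names(labels2), 200)] <- "excluded_buried"
  sets2 <- build_training_sets(emb, labels2, n_sets = 2, seed = 1)
  expect_true(all(labels2[unlist(lapply(sets2, `[[`, "keys"))] %in%
                    c("binding", "non_binding")))

  expect_error(build_training_sets(emb, setNames(rep("non_binding",
                                                     length(keys)), keys)),
               "at least one binding")
})

test_that("balanced sets hold for any pool composition (property)", {
  for (seed in 1:5) {
    set.seed(seed)
    n_pos <- sample(3:50, 1); n_neg <- sample(3:200, 1)
    keys <- c(sprintf("p%d", seq_len(n_pos)), sprintf("n%d", seq_len(n_neg)))
    emb <- matrix(rnorm((n_pos + n_neg) * 4), ncol = 4,
                  dimnames = list(keys, NULL))
    labels <- setNames(rep(c("binding", "non_binding"), c(n_pos, n_neg)),
                       keys)
    for (ts in build_training_sets(emb, labels, n_sets = 3, seed = seed))
      expect_equal(sum(ts$y == 1), sum(ts$y == 0))
  }
})

test_that("each trained member runs exactly the configured boosting rounds", {
  set.seed(7)
  emb <- matrix(rnorm(60 * 6), ncol = 6,
                dimnames = list(sprintf("r%d", 1:60), NULL))
  labels <- setNames(rep(c("binding", "non_binding"), each = 30),
                     rownames(emb))
  sets <- build_training_sets(emb, labels, n_sets = 2, seed = 1)
  ens <- train_ensemble(sets, classifier_config(n_iterations = 200,
                                                base_seed = 1))
  expect_length(ens$models, 2)
  dump <- xgboost::xgb.dump(pocketvote:::member_booster(ens$models[[1]]))
  expect_equal(sum(grepl("^booster\\[", dump)), 200)
  # the 10% holdout is recorded for reporting
  expect_equal(ens$validation[[1]]$n, floor(0.1 * length(sets[[1]]$y)))
  expect_true(is.finite(ens$validation[[1]]$logloss))
})

test_that("training on separable synthetic rows reaches high holdout accuracy", {
  u <- planted_direction(32, 4)
  emb <- NULL; lab <- character()
  for (i in 1:3) {
    fx <- make_fixture(fixture_spec(seed = 600 + i * 101))
    e <- synthetic_embeddings(fx$structure, fx$true_binding, dim = 32,
                              effect_size = 5, seed = 11 + i, direction = u)
    l <- label_from_complexes(fx$structure, list(fx$ligand), fx$rsa)
    rownames(e) <- paste0("p", i, "|", rownames(e))
    names(l) <- paste0("p", i, "|", names(l))
    emb <- rbind(emb, e); lab <- c(lab, l)
  }
  sets <- build_training_sets(emb, lab, n_sets = 5, seed = 2)
  ens <- train_ensemble(sets, classifier_config(base_seed = 2))
  acc <- vapply(ens$validation, `[[`, numeric(1), "accuracy")
  expect_true(all(acc > 0.95))
})

test_that("unanimity requires every model and the 0.5 threshold is inclusive", {
  probs <- rbind(all_pass = rep(0.73, 40),
                 one_dissent = c(rep(0.99, 39), 0.49),
                 at_threshold = rep(0.5, 40),
                 below = rep(0.499, 40))
  dec <- unanimous_positive(probs, 0.5)
  expect_identical(dec$positive, c("all_pass", "at_threshold"))
})

test_that("adding a model can only shrink the positive set (monotonicity)", {
  set.seed(12)
  for (rep in 1:5) {
    probs <- matrix(runif(30 * 6), 30, 6,
                    dimnames = list(sprintf("r%d", 1:30), NULL))
    for (m in 1:5) {
      before <- unanimous_positive(probs[, 1:m, drop = FALSE])$positive
      after <- unanimous_positive(probs[, 1:(m + 1), drop = FALSE])$positive
      expect_true(all(after %in% before))
    }
  }
})

test_that("ensemble prediction equals the intersection of per-model positives", {
  fx <- small_fixture(seed = 22)
  u <- planted_direction(16, 8)
  emb <- synthetic_embeddings(fx$structure, fx$true_binding, dim = 16,
                              effect_size = 2, seed = 3, direction = u)
  lab <- label_from_complexes(fx$structure, list(fx$ligand), fx$rsa)
  sets <- build_training_sets(emb, lab, n_sets = 4, seed = 5)
  ens <- train_ensemble(sets, classifier_config(base_seed = 5))
  pred <- predict_binding_residues(emb, ens)
  per_model <- lapply(seq_along(ens$models), function(m)
    predict_binding_residues(emb, ens, model_index = m)$positive)
  expect_setequal(pred$positive, Reduce(intersect, per_model))
  expect_error(predict_binding_residues(emb[, 1:8], ens), "dim")
})

test_that("ensembles serialise to disk and reload with identical predictions", {
  fx <- small_fixture(seed = 23)
  u <- planted_direction(16, 2)
  emb <- synthetic_embeddings(fx$structure, fx$true_binding, dim = 16,
                              effect_size = 3, seed = 4, direction = u)
  lab <- label_from_complexes(fx$structure, list(fx$ligand), fx$rsa)
  sets <- build_training_sets(emb, lab, n_sets = 3, seed = 6)
  ens <- train_ensemble(sets, classifier_config(base_seed = 6))

  dir <- withr::local_tempdir()
  save_ensemble(ens, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_ensemble(dir)
  expect_equal(back$dim, ens$dim)
  expect_equal(length(back$models), length(ens$models))
  expect_equal(ensemble_probabilities(back, emb),
               ensemble_probabilities(ens, emb), tolerance = 1e-6)
})

test_that("the unskilled baseline respects strata, counts and seeds", {
  rsa <- setNames(c(runif(20, 0.011, 0.05),    # sub-surface
                    runif(50, 0.051, 1.0),     # surface
                    runif(10, 0, 0.01)),       # ineligible
                  sprintf("r%d", 1:80))
  picked <- baseline_predict(rsa, c(3, 7), seed = 4)
  expect_length(picked, 10)
  expect_equal(sum(rsa[picked] > 0.01 & rsa[picked] <= 0.05), 3)
  expect_equal(sum(rsa[picked] > 0.05), 7)
  expect_identical(picked, baseline_predict(rsa, c(3, 7), seed = 4))
  expect_length(baseline_predict(rsa, c(0, 0), seed = 1), 0)
  expect_error(baseline_predict(rsa, c(21, 7), seed = 1), "exceeds")
})
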