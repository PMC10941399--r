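# Ground-truth residue labelling, balanced bootstrap training sets, the
# gradient-boosted ensemble, unanimous-vote prediction and the unskilled
# baseline predictor.

LABEL_LEVELS <- c("binding", "non_binding", "excluded_ambiguous",
                  "excluded_buried")

# Minimum heavy-atom distance from every residue of `structure` to any atom
# of any ligand in `ligands` (Inf if no ligands).
residue_ligand_min_dist <- function(structure, ligands) {
  n <- n_residues(structure)
  if (!length(ligands)) return(setNames(rep(Inf, n), structure$residue_keys))
  lig_atoms <- do.call(rbind, lapply(ligands, atom_coords))
  d_atom <- cpp_min_dist(atom_coords(structure), lig_atoms)
  setNames(as.numeric(tapply(d_atom, structure$residue_index, min)),
           structure$residue_keys)
}

#' Label residues from a leader complex (and aligned member ligands)
#'
#' Residues within `contact_cutoff` of any leader ligand heavy atom are
#' `binding`; remaining residues within the cutoff of any member-structure
#' ligand are `excluded_ambiguous` (possible false negatives, never
#' trained on); the rest are `non_binding`. Any residue with RSA at or below
#' `rsa_min` is overridden to `excluded_buried`, including buried
#' leader-ligand contacts.
#'
#' @param leader_structure the cluster-leader `protein_structure`
#' @param leader_ligands list of `ligand_instance` of the leader complex
#' @param rsa_map named RSA vector from [relative_surface_accessibility()]
#' @param member_ligands ligands of aligned member structures (same frame)
#' @param contact_cutoff heavy-atom contact distance, Angstrom (default 5)
#' @param rsa_min buried-residue RSA threshold (default 0.02, exclusive:
#'   residues must have RSA strictly above it to be kept)
#' @return named character vector over all residue keys with values in
#'   `binding`, `non_binding`, `excluded_ambiguous`, `excluded_buried`
#' @export
label_from_complexes <- function(leader_structure, leader_ligands, rsa_map,
                                 member_ligands = list(),
                                 contact_cutoff = 5.0, rsa_min = 0.02) {
  for (l in c(leader_ligands, member_ligands))
    if (nrow(atom_coords(l)) < 1) stop("ligand with zero atoms")
  keys <- leader_structure$residue_keys
  if (!all(keys %in% names(rsa_map))) stop("missing RSA entry for residue(s)")
  d_lead <- residue_ligand_min_dist(leader_structure, leader_ligands)
  d_memb <- residue_ligand_min_dist(leader_structure, member_ligands)
  lab <- ifelse(d_lead <= contact_cutoff, "binding",
                ifelse(d_memb <= contact_cutoff, "excluded_ambiguous",
                       "non_binding"))
  lab[rsa_map[keys] <= rsa_min] <- "excluded_buried"
  setNames(lab, keys)
}

#' Balanced bootstrap training sets
#'
#' Each set draws `k = floor(positive_fraction * P)` binding residues and an
#' equal number of non-binding residues, both sampled with replacement
#' (standard bagging; `replace_positives = FALSE` switches the positive draw
#' to a without-replacement subsample). Excluded residues are never sampled.
#' Set `i` uses sub-seed `seed + i`.
#'
#' @param embeddings embedding matrix over the labelled pool (rownames keys)
#' @param labels named label vector from [label_from_complexes()]
#' @param n_sets number of sets (default 40)
#' @param positive_fraction fraction of the positive pool drawn per set
#' @param seed base integer seed
#' @param replace_positives sample positives with replacement (default TRUE)
#' @return list of `training_set` objects: fields `x` (matrix), `y` (0/1),
#'   `keys` (sampled residue keys) and `seed`
#' @export
build_training_sets <- function(embeddings, labels, n_sets = 40,
                                positive_fraction = 0.8, seed = 1,
                                replace_positives = TRUE) {
  pos_keys <- names(labels)[labels == "binding"]
  neg_keys <- names(labels)[labels == "non_binding"]
  if (!length(pos_keys) || !length(neg_keys))
    stop("need at least one binding and one non-binding residue")
  stopifnot(all(c(pos_keys, neg_keys) %in% rownames(embeddings)))
  k <- max(1L, floor(positive_fraction * length(pos_keys)))
  lapply(seq_len(n_sets), function(i) {
    drawn <- withr_seed(seed + i, {
      p <- sample(pos_keys, k, replace = replace_positives)
      n <- sample(neg_keys, k, replace = TRUE)
      list(p = p, n = n)
    })
    keys <- c(drawn$p, drawn$n)
    structure(list(x = embeddings[keys, , drop = FALSE],
                   y = rep(c(1L, 0L), each = k),
                   keys = keys, seed = seed + i),
              class = "training_set")
  })
}

#' Classifier configuration
#'
#' Fixed gradient-boosted decision-tree configuration: binary objective with
#' log-loss metric, 200 leaves, 200 boosting iterations, no feature
#' pre-filtering and no early stopping; a 10% random holdout per model is
#' recorded for reporting but never used to stop training.
#'
#' @param n_leaves maximum leaves per tree (default 200)
#' @param n_iterations boosting rounds (default 200)
#' @param learning_rate shrinkage (default 0.1)
#' @param validation_fraction per-model holdout fraction (default 0.10)
#' @param base_seed integer; model `i` trains with seed `base_seed + i`
#' @return list of class `classifier_config`
#' @export
classifier_config <- function(n_leaves = 200, n_iterations = 200,
                              learning_rate = 0.1,
                              validation_fraction = 0.10, base_seed = 1) {
  stopifnot(n_leaves >= 1, n_iterations >= 1,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(n_leaves = n_leaves, n_iterations = n_iterations,
                 learning_rate = learning_rate,
                 validation_fraction = validation_fraction,
                 base_seed = base_seed),
            class = "classifier_config")
}

# Train one leaf-wise GBDT member on a training set, holding out a fraction
# for reporting. Returns the booster plus holdout metrics.
train_member <- function(ts, config, model_seed) {
  n <- length(ts$y)
  n_val <- floor(config$validation_fraction * n)
  idx_val <- withr_seed(model_seed, sample.int(n, n_val))
  idx_tr <- setdiff(seq_len(n), idx_val)
  if (length(unique(ts$y[idx_tr])) < 2)
    stop("degenerate training set: single class after holdout split")
  params <- list(objective = "binary:logistic", eval_metric = "logloss",
                 tree_method = "hist", grow_policy = "lossguide",
                 max_leaves = config$n_leaves, max_depth = 0,
                 eta = config$learning_rate, nthread = 1,
                 seed = model_seed)
  booster <- xgboost::xgb.train(
    params = params,
    data = xgboost::xgb.DMatrix(ts$x[idx_tr, , drop = FALSE],
                                label = ts$y[idx_tr]),
    nrounds = config$n_iterations, verbose = 0)
  val <- list(n = n_val, logloss = NA_real_, accuracy = NA_real_)
  if (n_val > 0 && length(unique(ts$y[idx_val])) >= 1) {
    p <- predict(booster, xgboost::xgb.DMatrix(ts$x[idx_val, , drop = FALSE]))
    eps <- 1e-15
    y <- ts$y[idx_val]
    val$logloss <- -mean(y * log(pmax(p, eps)) +
                           (1 - y) * log(pmax(1 - p, eps)))
    val$accuracy <- mean((p >= 0.5) == (y == 1))
  }
  # members are kept as serialized model bytes: a live booster handle pins
  # its training caches (~100s of MB each), which 40 members cannot afford
  raw <- xgboost::xgb.save.raw(booster)
  rm(booster)
  gc(verbose = FALSE)
  list(model = raw, validation = val, seed = model_seed)
}

# Transient booster handle for a serialized member.
member_booster <- function(raw) xgboost::xgb.load.raw(raw)

#' Train the classifier ensemble
#'
#' One gradient-boosted decision-tree model per training set, each trained
#' on 90% of its rows with the 10% holdout's log-loss and accuracy recorded.
#' Early stopping is off: every member runs exactly
#' `config$n_iterations` rounds.
#'
#' @param training_sets list from [build_training_sets()]
#' @param config a [classifier_config()]
#' @return object of class `classifier_ensemble`: fields `models`,
#'   `validation` (per-model holdout metrics), `threshold` (0.5, inclusive),
#'   `dim`, `config`
#' @export
train_ensemble <- function(training_sets, config = classifier_config()) {
  stopifnot(length(training_sets) >= 1)
  dims <- vapply(training_sets, function(ts) ncol(ts$x), integer(1))
  if (length(unique(dims)) != 1) stop("training sets disagree on dim")
  members <- lapply(seq_along(training_sets), function(i)
    train_member(training_sets[[i]], config, config$base_seed + i))
  structure(
    list(models = lapply(members, `[[`, "model"),
         validation = lapply(members, `[[`, "validation"),
         threshold = 0.5, dim = dims[1], config = config),
    class = "classifier_ensemble")
}

#' @export
print.classifier_ensemble <- function(x, ...) {
  cat(sprintf("classifier_ensemble: %d models, dim %d, threshold %.2f (unanimous)\n",
              length(x$models), x$dim, x$threshold))
  invisible(x)
}

#' Per-model probabilities for an embedding matrix
#' @param ensemble a `classifier_ensemble`
#' @param embeddings embedding matrix (rownames = residue keys)
#' @return n_residues x M probability matrix
#' @export
ensemble_probabilities <- function(ensemble, embeddings) {
  if (ncol(embeddings) != ensemble$dim)
    stop("embedding dim ", ncol(embeddings), " != training dim ",
         ensemble$dim)
  dm <- xgboost::xgb.DMatrix(embeddings)
  probs <- vapply(ensemble$models,
                  function(m) predict(member_booster(m), dm),
                  numeric(nrow(embeddings)))
  probs <- matrix(probs, nrow = nrow(embeddings))
  rownames(probs) <- rownames(embeddings)
  probs
}

#' Unanimous-vote decision rule
#'
#' Applies the positive-labelling rule to a probability matrix: a row is
#' positive iff every column's probability is at or above the threshold
#' ("minimum predicted probability of 0.5" read inclusively).
#'
#' @param probs n x M probability matrix (rownames = residue keys)
#' @param threshold positive-label probability (default 0.5, inclusive)
#' @return list with `positive` (rownames of unanimous rows) and `votes`
#'   (logical matrix)
#' @export
unanimous_positive <- function(probs, threshold = 0.5) {
  votes <- probs >= threshold
  list(positive = rownames(probs)[rowSums(votes) == ncol(votes)],
       votes = votes)
}

#' Predict binding residues by unanimous vote
#'
#' A residue is positive only if every ensemble member assigns probability
#' at or above the threshold (0.5, inclusive): the positive set is the
#' intersection of the per-model positive sets.
#'
#' @param embeddings embedding matrix (rownames = residue keys)
#' @param ensemble a `classifier_ensemble`
#' @param model_index optional single member to use instead of the full
#'   ensemble (the single-model pathways)
#' @return list with `positive` (residue keys), `votes` (logical
#'   n_residues x M matrix) and `probabilities`
#' @export
predict_binding_residues <- function(embeddings, ensemble,
                                     model_index = NULL) {
  probs <- ensemble_probabilities(ensemble, embeddings)
  if (!is.null(model_index)) {
    stopifnot(model_index >= 1, model_index <= ncol(probs))
    probs <- probs[, model_index, drop = FALSE]
  }
  dec <- unanimous_positive(probs, ensemble$threshold)
  list(positive = dec$positive, votes = dec$votes, probabilities = probs)
}

#' Unskilled baseline residue prediction
#'
#' Randomly annotates the same number of surface residues as a real
#' prediction, preserving its split between sub-surface (RSA in
#' (0.01, 0.05]) and surface (RSA > 0.05) residues; sampling is uniform
#' without replacement within each stratum.
#'
#' @param rsa_map named RSA vector
#' @param stratum_counts integer vector `c(n_subsurface, n_surface)` taken
#'   from a real prediction
#' @param seed integer seed
#' @return character vector of selected residue keys
#' @export
baseline_predict <- function(rsa_map, stratum_counts, seed = 1) {
  stopifnot(length(stratum_counts) == 2, all(stratum_counts >= 0))
  sub <- names(rsa_map)[rsa_map > 0.01 & rsa_map <= 0.05]
  surf <- names(rsa_map)[rsa_map > 0.05]
  if (stratum_counts[1] > length(sub) || stratum_counts[2] > length(surf))
    stop("stratum demand exceeds eligible residues")
  withr_seed(seed, c(
    if (stratum_counts[1] > 0) sample(sub, stratum_counts[1]) else character(),
    if (stratum_counts[2] > 0) sample(surf, stratum_counts[2]) else character()))
}

#' Serialise / load an ensemble
#'
#' One model file per member (xgboost JSON) plus a JSON manifest recording
#' the configuration, seeds, embedding dimension and holdout metrics.
#'
#' @param ensemble a `classifier_ensemble`
#' @param dir target directory (created if needed)
#' @return `dir` (save) or the restored ensemble (load)
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ensemble$models))
    xgboost::xgb.save(member_booster(ensemble$models[[i]]),
                      file.path(dir, sprintf("model_%03d.json", i)))
  manifest <- list(n_models = length(ensemble$models),
                   dim = ensemble$dim, threshold = ensemble$threshold,
                   config = unclass(ensemble$config),
                   validation = ensemble$validation)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  files <- file.path(dir, sprintf("model_%03d.json",
                                  seq_len(manifest$n_models)))
  structure(
    list(models = lapply(files, function(f)
      xgboost::xgb.save.raw(xgboost::xgb.load(f))),
         validation = manifest$validation,
         threshold = manifest$threshold, dim = manifest$dim,
         config = do.call(classifier_config,
                          manifest$config[names(manifest$config) %in%
                                            names(formals(classifier_config))])),
    class = "classifier_ensemble")
}
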