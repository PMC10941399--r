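# Shared builders and independent oracles for the test suite. Everything is
# generated in code; nothing is read from disk.

# -- tiny hand-built structures -------------------------------------------

# A structure from an explicit CA-only atom table (one atom per residue).
ca_structure <- function(coords, chain = "A", resid = "ALA") {
  coords <- as.matrix(coords)
  protein_structure(data.frame(
    chain = chain, resno = seq_len(nrow(coords)), icode = "",
    resid = resid, elety = "CA", elesy = "C",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE), source = "test")
}

# A quick small fixture for unit tests (smaller chain than the default).
small_fixture <- function(seed = 1, n_residues = 60)
  make_fixture(fixture_spec(n_residues = n_residues, seed = seed))

# -- independent oracles ---------------------------------------------------

# Textbook DBSCAN on a point multiset (points duplicated by multiplicity),
# O(n^2), index-ordered scans; returns cluster labels per unique point
# (0 = noise). Written to mirror the published pseudocode, independent of
# the package's weighted implementation.
brute_dbscan <- function(points, multiplicity, eps, min_samples) {
  idx <- rep(seq_len(nrow(points)), multiplicity)   # duplicate expansion
  pts <- points[idx, , drop = FALSE]
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  neigh <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))  # incl self
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    if (length(neigh[[i]]) < min_samples) next      # not core (may join later)
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(neigh[[i]], i)
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (length(neigh[[j]]) >= min_samples)
          queue <- c(queue, neigh[[j]][labels[neigh[[j]]] == 0L])
      }
    }
  }
  # collapse duplicates back to unique points (all copies share a label)
  vapply(seq_len(nrow(points)), function(k) {
    lab <- unique(labels[idx == k])
    stopifnot(length(lab) == 1)
    lab
  }, integer(1))
}

# Exhaustive 4-counter confusion tally.
brute_confusion <- function(predicted, truth, universe) {
  tp <- fp <- fn <- tn <- 0L
  for (u in universe) {
    p <- u %in% predicted; t <- u %in% truth
    if (p && t) tp <- tp + 1L
    else if (p) fp <- fp + 1L
    else if (t) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Random proper rotation matrix from a seed.
random_rotation <- function(seed) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Empirical AUC of scores for a binary truth vector (rank statistic).
rank_auc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# -- shared heavyweight state for the acceptance tests ---------------------

.pv_test_env <- new.env(parent = emptyenv())

# The trained 40-model ensemble used by the parameter-recovery and
# consensus acceptance tests: 25-fixture training pool (~3000 residues),
# 512-dim embeddings with a planted effect size of 3. Built once per
# session.
acceptance_state <- function() {
  if (!is.null(.pv_test_env$state)) return(.pv_test_env$state)
  dim <- 512
  u <- planted_direction(dim, 42)
  pool_emb <- NULL
  pool_lab <- character()
  for (i in 1:25) {
    fx <- make_fixture(fixture_spec(seed = 1000 + i * 101))
    lab <- label_from_complexes(fx$structure, list(fx$ligand), fx$rsa)
    emb <- synthetic_embeddings(fx$structure, fx$true_binding, dim = dim,
                                effect_size = 3, seed = 50 + i,
                                direction = u)
    rownames(emb) <- paste0("p", i, "|", rownames(emb))
    names(lab) <- paste0("p", i, "|", names(lab))
    pool_emb <- rbind(pool_emb, emb)
    pool_lab <- c(pool_lab, lab)
  }
  sets <- build_training_sets(pool_emb, pool_lab, n_sets = 40, seed = 7)
  ens <- train_ensemble(sets, classifier_config(base_seed = 7))
  .pv_test_env$state <- list(dim = dim, u = u, ensemble = ens,
                             n_pool = length(pool_lab),
                             n_pool_binding = sum(pool_lab == "binding"))
  .pv_test_env$state
}
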