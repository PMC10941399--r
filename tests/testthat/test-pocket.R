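# Geometric stages: shell lattice, multiplicity annotation, weighted
# density clustering, and the composed site predictor.

single_atom <- function() ca_structure(rbind(c(0, 0, 0)))

test_that("the shell band is inclusive at both 3.0 and 6.0 A", {
  cloud <- generate_grid_cloud(single_atom(), spacing = 1.5, anchor = c(0, 0, 0))
  has_point <- function(p)
    any(rowSums(abs(sweep(cloud$points, 2, p))) < 1e-9)
  expect_true(has_point(c(3, 0, 0)))     # distance exactly 3.0: kept
  expect_true(has_point(c(6, 0, 0)))     # distance exactly 6.0: kept
  expect_false(has_point(c(1.5, 0, 0)))  # 1.5 < 3: rejected
  expect_false(has_point(c(7.5, 0, 0)))  # 7.5 > 6: rejected
})

test_that("the single-atom cloud equals exhaustive lattice enumeration", {
  cloud <- generate_grid_cloud(single_atom(), spacing = 1.5, anchor = c(0, 0, 0))
  # oracle: all integer triples scaled by 1.5 within the bounding range
  g <- as.matrix(expand.grid(i = -5:5, j = -5:5, k = -5:5)) * 1.5
  d <- sqrt(rowSums(g^2))
  oracle <- g[d >= 3 & d <= 6, , drop = FALSE]
  expect_equal(nrow(cloud$points), 230)
  expect_equal(nrow(oracle), 230)
  ord <- function(m) m[order(m[, 1], m[, 2], m[, 3]), ]
  expect_equal(ord(cloud$points), ord(oracle), ignore_attr = TRUE)
})

test_that("every retained point's nearest-atom distance lies in the band", {
  fx <- small_fixture(seed = 8)
  cloud <- generate_grid_cloud(fx$structure)
  d <- apply(cloud$points, 1, function(p)
    min(sqrt(rowSums(sweep(atom_coords(fx$structure), 2, p)^2))))
  expect_true(all(d >= 3 - 1e-9 & d <= 6 + 1e-9))
})

test_that("translating the structure by a lattice multiple translates the cloud", {
  fx <- small_fixture(seed = 10)
  cloud0 <- generate_grid_cloud(fx$structure)
  shift <- c(3, -4.5, 6)                     # multiples of 1.5
  moved <- transform_structure(fx$structure, diag(3), shift)
  cloud1 <- generate_grid_cloud(moved)
  ord <- function(m) m[order(m[, 1], m[, 2], m[, 3]), ]
  expect_equal(ord(cloud1$points), ord(sweep(cloud0$points, 2, shift, "+")),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("multiplicity counts distinct residues and the >=3 cutoff drops m=2", {
  # three residues 4.4 A from origin, two residues 4.4 A from (20,0,0)
  s <- ca_structure(rbind(c(4.4, 0, 0), c(0, 4.4, 0), c(0, 0, 4.4),
                          c(24.4, 0, 0), c(20, 4.4, 0),
                          c(50, 50, 50)))
  cloud <- list(points = rbind(c(0, 0, 0), c(20, 0, 0)), spacing = 1.5)
  ann <- annotate_cloud(cloud, s, s$residue_keys[1:5],
                        radius = 4.5, min_count = 3)
  expect_equal(nrow(ann$points), 1)          # m=3 point kept
  expect_equal(ann$multiplicity, 3L)
  expect_equal(ann$points[1, ], c(0, 0, 0))  # the m=2 point dropped

  # boundary: exactly 4.5 A counts
  ann45 <- annotate_cloud(list(points = rbind(c(0, 0, 0))),
                          ca_structure(rbind(c(4.5, 0, 0), c(0, 4.5, 0),
                                             c(0, 0, 4.5))),
                          residue_key("A", 1:3), radius = 4.5, min_count = 3)
  expect_equal(nrow(ann45$points), 1)

  empty <- annotate_cloud(cloud, s, character())
  expect_equal(nrow(empty$points), 0)
})

test_that("weighted clustering matches the hand example", {
  ann <- list(points = rbind(c(0, 0, 0), c(1.5, 0, 0)),
              multiplicity = c(3L, 4L))
  sites <- cluster_sites(ann, eps = 1.7, min_samples = 1)
  expect_length(sites, 1)
  expect_equal(sites[[1]]$weight, 7)
  expect_equal(sites[[1]]$n_points, 2)
  expect_equal(sites[[1]]$centre, c(6 / 7, 0, 0))

  # two well-separated groups rank by weight
  ann2 <- list(points = rbind(c(0, 0, 0), c(1.5, 0, 0),
                              c(30, 0, 0), c(31.5, 0, 0)),
               multiplicity = c(3L, 4L, 5L, 5L))
  sites2 <- cluster_sites(ann2, eps = 1.7, min_samples = 1)
  expect_length(sites2, 2)
  expect_equal(sites2[[1]]$weight, 10)       # heavier group first
  expect_gt(sites2[[1]]$centre[1], 20)

  # isolated unit-weight points below min_samples are all noise
  ann3 <- list(points = rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0),
                              c(30, 0, 0)),
               multiplicity = rep(1L, 4))
  expect_length(cluster_sites(ann3, eps = 1.7, min_samples = 5), 0)

  # a single point whose multiplicity reaches min_samples is core alone
  ann4 <- list(points = rbind(c(0, 0, 0)), multiplicity = 5L)
  expect_length(cluster_sites(ann4, eps = 1.7, min_samples = 5), 1)
})

test_that("weighted clustering equals brute-force DBSCAN on duplicated points", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(20:60, 1)
    pts <- matrix(runif(n * 3, 0, 12), n, 3)
    pts <- unique(round(pts / 1.5) * 1.5)    # lattice-like, unique
    m <- sample(1:6, nrow(pts), replace = TRUE)
    eps <- runif(1, 1.2, 3)
    ms <- sample(2:8, 1)

    mine <- pocketvote:::weighted_dbscan(pts, m, eps, ms)
    oracle <- brute_dbscan(pts, m, eps, ms)
    # identical partitions: noise agrees, cluster relabelling allowed
    expect_identical(mine == 0, oracle == 0)
    split_mine <- split(seq_along(mine), mine)
    split_mine <- unname(split_mine[names(split_mine) != "0"])
    split_orac <- split(seq_along(oracle), oracle)
    split_orac <- unname(split_orac[names(split_orac) != "0"])
    expect_setequal(split_mine, split_orac)
  }
})

test_that("cluster weights conserve total multiplicity and partition the points", {
  fx <- small_fixture(seed = 12)
  cloud <- generate_grid_cloud(fx$structure)
  ann <- annotate_cloud(cloud, fx$structure, fx$true_binding)
  sites <- cluster_sites(ann)
  labels <- pocketvote:::weighted_dbscan(ann$points, ann$multiplicity,
                                         1.7, 5)
  expect_equal(sum(vapply(sites, `[[`, numeric(1), "weight")),
               sum(ann$multiplicity[labels != 0]))
  expect_equal(sum(vapply(sites, `[[`, numeric(1), "n_points")),
               sum(labels != 0))
  # centre inside the members' bounding box; ranks strictly ordered
  for (s in sites) {
    expect_true(all(s$centre >= apply(s$members, 2, min) - 1e-9))
    expect_true(all(s$centre <= apply(s$members, 2, max) + 1e-9))
  }
  w <- vapply(sites, `[[`, numeric(1), "weight")
  expect_true(all(diff(w) <= 0))
})

test_that("site centres and ranking are invariant to input point order", {
  fx <- small_fixture(seed = 14)
  cloud <- generate_grid_cloud(fx$structure)
  ann <- annotate_cloud(cloud, fx$structure, fx$true_binding)
  set.seed(1)
  perm <- sample(nrow(ann$points))
  ann_p <- list(points = ann$points[perm, , drop = FALSE],
                multiplicity = ann$multiplicity[perm])
  s1 <- cluster_sites(ann)
  s2 <- cluster_sites(ann_p)
  expect_equal(lapply(s1, `[[`, "centre"), lapply(s2, `[[`, "centre"),
               tolerance = 1e-9)
  expect_equal(vapply(s1, `[[`, numeric(1), "weight"),
               vapply(s2, `[[`, numeric(1), "weight"))
})

test_that("predict_sites composes the stages, propagates empties, and is deterministic", {
  fx <- small_fixture(seed = 16)
  sp <- predict_sites_from_residues(fx$structure, fx$true_binding)
  expect_s3_class(sp, "site_prediction")
  expect_gt(length(sp$sites), 0)
  expect_lte(length(sp$top3), 3)
  d <- dca(sp$sites[[1]]$centre, fx$ligand)
  expect_true(d$success)                     # perfect labels find the pocket

  sp2 <- predict_sites_from_residues(fx$structure, fx$true_binding)
  expect_equal(sp, sp2)

  empty <- predict_sites_from_residues(fx$structure, character())
  expect_length(empty$sites, 0)
  expect_length(empty$binding_residues, 0)
})

test_that("site predictions serialise to readable reports", {
  fx <- small_fixture(seed = 18)
  sp <- predict_sites_from_residues(fx$structure, fx$true_binding)
  dir <- withr::local_tempdir()
  write_site_prediction(sp, dir)
  sites <- read.table(file.path(dir, "sites.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(sites), length(sp$sites))
  expect_named(sites, c("rank", "x", "y", "z", "weight", "n_points"))
  res <- read.table(file.path(dir, "residues.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(res), length(sp$binding_residues))
})

test_that("degenerate parameters are rejected", {
  fx <- small_fixture(seed = 20)
  expect_error(generate_grid_cloud(fx$structure, spacing = 0), "spacing")
  expect_error(generate_grid_cloud(fx$structure, dmin = 6, dmax = 3), "dmin")
  expect_error(annotate_cloud(list(points = matrix(0, 1, 3)), fx$structure,
                              fx$true_binding, radius = -1), "radius")
  expect_error(site_params(nonsense = 1), "unknown parameter")
})
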