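# Geometric post-processing: shell lattice generation around the chain,
# multiplicity annotation against predicted binding residues, and
# multiplicity-weighted density clustering into ranked site centres.

#' Pipeline parameter set
#'
#' All distance thresholds of the site-prediction pipeline with their
#' default values: 1.5 A lattice spacing, 3-6 A shell band (inclusive),
#' 4.5 A point-to-residue radius, multiplicity cutoff 3, DBSCAN eps 1.7 A
#' with weighted min_samples 5, probability threshold 0.5, 4 A DCA cutoff,
#' 5 A site-to-residue re-annotation, 3-of-10 consensus voting.
#'
#' @param ... overrides of the named defaults
#' @return list of class `site_params`
#' @export
site_params <- function(...) {
  p <- list(spacing = 1.5, dmin = 3.0, dmax = 6.0,
            residue_radius = 4.5, min_count = 3L,
            eps = 1.7, min_samples = 5L,
            prob_threshold = 0.5, contact_cutoff = 5.0, rsa_min = 0.02,
            dca_cutoff = 4.0, reannotate_radius = 5.0,
            min_votes = 3L, n_structures = 10L, n_models = 40L,
            weighted_centre = TRUE, top_n = 3L)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  structure(modifyList(p, over), class = "site_params")
}

#' Shell lattice around a protein chain
#'
#' Axis-aligned lattice with the given spacing, anchored at the chain
#' bounding-box minimum corner minus `dmax` (so the kept cloud is
#' translation-consistent: translating the structure by a lattice multiple
#' translates the cloud identically). A point is kept iff its distance to
#' the nearest protein heavy atom lies in `[dmin, dmax]`, both ends
#' inclusive.
#'
#' @param structure single-chain `protein_structure`
#' @param spacing lattice spacing, Angstrom (default 1.5)
#' @param dmin,dmax shell band in Angstrom (defaults 3 and 6)
#' @param anchor optional lattice origin override (length-3), used by tests
#' @return list of class `grid_cloud`: `points` (n x 3 matrix), `spacing`,
#'   `anchor`, `band`
#' @export
generate_grid_cloud <- function(structure, spacing = 1.5, dmin = 3.0,
                                dmax = 6.0, anchor = NULL) {
  stopifnot(spacing > 0, dmin < dmax)
  atoms <- atom_coords(structure)
  if (nrow(atoms) < 1) stop("empty structure")
  lo <- apply(atoms, 2, min) - dmax
  hi <- apply(atoms, 2, max) + dmax
  if (is.null(anchor)) anchor <- lo
  ax <- lapply(1:3, function(k) {
    i0 <- ceiling((lo[k] - anchor[k]) / spacing - 1e-9)
    i1 <- floor((hi[k] - anchor[k]) / spacing + 1e-9)
    anchor[k] + spacing * (i0:i1)
  })
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  dimnames(pts) <- NULL
  keep <- cpp_band_filter(pts, atoms, dmin, dmax)
  base::structure(list(points = pts[keep, , drop = FALSE], spacing = spacing,
                 anchor = as.numeric(anchor), band = c(dmin, dmax)),
            class = "grid_cloud")
}

#' Annotate cloud points with binding-residue multiplicity
#'
#' A point's multiplicity m is the number of predicted binding residues
#' with at least one heavy atom within `radius`; only points with
#' `m >= min_count` are retained ("saved three or more times").
#'
#' @param cloud a [generate_grid_cloud()] result
#' @param structure the same single-chain `protein_structure`
#' @param binding_residues character vector of predicted residue keys
#' @param radius point-to-residue distance, Angstrom (default 4.5)
#' @param min_count minimum multiplicity (default 3)
#' @return list of class `annotated_cloud`: `points` (unique, n x 3),
#'   `multiplicity` (integer), `radius`, `min_count`
#' @export
annotate_cloud <- function(cloud, structure, binding_residues,
                           radius = 4.5, min_count = 3) {
  stopifnot(radius > 0, min_count >= 1)
  unknown <- setdiff(binding_residues, structure$residue_keys)
  if (length(unknown)) stop("binding residue(s) not in structure: ",
                            paste(head(unknown, 3), collapse = ", "))
  empty <- base::structure(list(points = matrix(numeric(), 0, 3),
                          multiplicity = integer(),
                          radius = radius, min_count = as.integer(min_count)),
                     class = "annotated_cloud")
  if (!length(binding_residues) || nrow(cloud$points) == 0) return(empty)
  sel <- structure$residue_keys[structure$residue_index] %in% binding_residues
  atoms <- atom_coords(structure)[sel, , drop = FALSE]
  grp <- match(structure$residue_keys[structure$residue_index][sel],
               binding_residues)
  m <- cpp_count_groups_within(cloud$points, atoms, grp,
                               length(binding_residues), radius)
  keep <- m >= min_count
  base::structure(list(points = cloud$points[keep, , drop = FALSE],
                 multiplicity = as.integer(m[keep]),
                 radius = radius, min_count = as.integer(min_count)),
            class = "annotated_cloud")
}

# Multiplicity-weighted DBSCAN. Points are unique lattice points carrying
# integer weights; a point is core when the weights in its eps-ball
# (itself included) sum to at least min_samples. This reproduces exactly the
# standard algorithm run on the multiset in which each point appears m times
# (all duplicates land in the same cluster; border duplicates too).
weighted_dbscan <- function(points, weights, eps, min_samples) {
  n <- nrow(points)
  if (n == 0) return(integer())
  nb <- cpp_radius_neighbors(points, eps)
  wsum <- vapply(seq_len(n), function(i) weights[i] + sum(weights[nb[[i]]]),
                 numeric(1))
  core <- wsum >= min_samples
  labels <- integer(n)              # 0 = unassigned/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}

#' Cluster annotated points into ranked binding sites
#'
#' Density clustering (DBSCAN, Euclidean, eps 1.7 A) over the unique
#' annotated points, counting each point with its multiplicity for the
#' core-point test and for ranking: cluster weight is the summed
#' multiplicity of its members ("including repetitions of the same point"),
#' and the centre is the multiplicity-weighted mean of member coordinates
#' (`weighted_centre = FALSE` gives the unweighted mean). Noise points are
#' discarded. Clusters are sorted by weight, then unique point count, then
#' lexicographic centre.
#'
#' @param annotated a [annotate_cloud()] result
#' @param eps neighbourhood radius, Angstrom (default 1.7)
#' @param min_samples weighted core-point threshold (default 5)
#' @param weighted_centre weight the centre by multiplicity (default TRUE)
#' @return list of `pocket_site` objects: `rank`, `centre`, `weight`,
#'   `n_points`, `members`, `multiplicity`
#' @export
cluster_sites <- function(annotated, eps = 1.7, min_samples = 5,
                          weighted_centre = TRUE) {
  stopifnot(eps > 0, min_samples >= 1)
  pts <- annotated$points
  m <- annotated$multiplicity
  if (nrow(pts) == 0) return(list())
  labels <- weighted_dbscan(pts, m, eps, min_samples)
  ids <- setdiff(unique(labels), 0L)
  sites <- lapply(ids, function(cl) {
    sel <- labels == cl
    w <- if (weighted_centre) m[sel] else rep(1, sum(sel))
    centre <- as.numeric(colSums(pts[sel, , drop = FALSE] * w) / sum(w))
    list(centre = centre, weight = sum(m[sel]), n_points = sum(sel),
         members = pts[sel, , drop = FALSE], multiplicity = m[sel])
  })
  ord <- order(-vapply(sites, `[[`, numeric(1), "weight"),
               -vapply(sites, `[[`, numeric(1), "n_points"),
               vapply(sites, function(s) s$centre[1], numeric(1)),
               vapply(sites, function(s) s$centre[2], numeric(1)),
               vapply(sites, function(s) s$centre[3], numeric(1)))
  sites <- sites[ord]
  for (i in seq_along(sites)) {
    sites[[i]]$rank <- i
    class(sites[[i]]) <- "pocket_site"
  }
  sites
}

#' Predicted-residue set to ranked site centres
#'
#' The geometric half of the pipeline: shell lattice, multiplicity
#' annotation and clustering, starting from an already-known set of binding
#' residues (predicted or ground truth).
#'
#' @param structure single-chain `protein_structure`
#' @param binding_residues character vector of residue keys
#' @param params a [site_params()]
#' @return object of class `site_prediction`: `sites` (ranked), `top3`,
#'   `binding_residues`, `params`
#' @export
predict_sites_from_residues <- function(structure, binding_residues,
                                        params = site_params()) {
  cloud <- generate_grid_cloud(structure, params$spacing, params$dmin,
                               params$dmax)
  ann <- annotate_cloud(cloud, structure, binding_residues,
                        params$residue_radius, params$min_count)
  sites <- cluster_sites(ann, params$eps, params$min_samples,
                         params$weighted_centre)
  base::structure(list(sites = sites,
                 top3 = head(sites, params$top_n),
                 binding_residues = binding_residues,
                 params = params),
            class = "site_prediction")
}

#' Full site prediction from embeddings
#'
#' Composition of the classification and geometric stages: unanimous-vote
#' residue prediction, shell lattice, multiplicity annotation, clustering
#' and ranking.
#'
#' @param structure single-chain `protein_structure`
#' @param embeddings embedding matrix for the structure
#' @param ensemble a trained `classifier_ensemble`
#' @param params a [site_params()]
#' @param model_index optional single ensemble member (single-model mode)
#' @return a `site_prediction` (empty `sites` when no residue passes)
#' @export
predict_sites <- function(structure, embeddings, ensemble,
                          params = site_params(), model_index = NULL) {
  pred <- predict_binding_residues(embeddings, ensemble, model_index)
  predict_sites_from_residues(structure, pred$positive, params)
}

#' @export
print.site_prediction <- function(x, ...) {
  cat(sprintf("site_prediction: %d site(s), %d predicted residue(s)\n",
              length(x$sites), length(x$binding_residues)))
  for (s in head(x$sites, 3))
    cat(sprintf("  rank %d: centre (%.2f, %.2f, %.2f)  weight %d  points %d\n",
                s$rank, s$centre[1], s$centre[2], s$centre[3],
                s$weight, s$n_points))
  invisible(x)
}

#' Write a site prediction as text reports
#'
#' `sites.tsv` holds one row per site (rank, centre, weight, point count);
#' `residues.tsv` the predicted residue keys (chain and residue number
#' columns); optionally `cloud.pdb` with cluster points as pseudo-atoms.
#'
#' @param prediction a `site_prediction`
#' @param dir output directory
#' @param write_cloud also write cluster points as a PDB of pseudo-atoms
#' @return `dir`, invisibly
#' @export
write_site_prediction <- function(prediction, dir, write_cloud = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sites <- prediction$sites
  df <- if (length(sites))
    data.frame(rank = vapply(sites, `[[`, numeric(1), "rank"),
               x = vapply(sites, function(s) s$centre[1], numeric(1)),
               y = vapply(sites, function(s) s$centre[2], numeric(1)),
               z = vapply(sites, function(s) s$centre[3], numeric(1)),
               weight = vapply(sites, `[[`, numeric(1), "weight"),
               n_points = vapply(sites, `[[`, numeric(1), "n_points"))
  else data.frame(rank = numeric(), x = numeric(), y = numeric(),
                  z = numeric(), weight = numeric(), n_points = numeric())
  write.table(df, file.path(dir, "sites.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  keys <- strsplit(prediction$binding_residues, ":", fixed = TRUE)
  rdf <- data.frame(chain = vapply(keys, `[[`, character(1), 1),
                    resno = vapply(keys, `[[`, character(1), 2))
  write.table(rdf, file.path(dir, "residues.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (write_cloud && length(sites)) {
    pts <- do.call(rbind, lapply(sites, `[[`, "members"))
    bio3d::write.pdb(file = file.path(dir, "cloud.pdb"),
                     xyz = as.numeric(t(pts)),
                     type = rep("HETATM", nrow(pts)),
                     resno = rep(seq_along(sites),
                                 vapply(sites, `[[`, numeric(1), "n_points")),
                     resid = rep("PNT", nrow(pts)),
                     eleno = seq_len(nrow(pts)),
                     elety = rep("C", nrow(pts)),
                     chain = rep("X", nrow(pts)))
  }
  invisible(dir)
}
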