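# Multi-model / multi-structure combination: site-to-residue re-annotation,
# k-of-n voting across conformers, and the four comparison pathways.

PATHWAYS <- c("single-model/single-structure", "multi-model/single-structure",
              "single-model/multi-structure", "multi-model/multi-structure")

#' Re-annotate residues from top-ranked sites
#'
#' Residues with any heavy atom within `radius` (inclusive) of any member
#' point of the supplied sites are labelled ligand-binding; the 5 A default
#' is the conventional intermolecular-interaction distance.
#'
#' @param structure single-chain `protein_structure`
#' @param sites_top3 list of up to 3 `pocket_site` objects (a
#'   `site_prediction` is accepted and its top-3 taken)
#' @param radius re-annotation distance, Angstrom (default 5)
#' @return character vector of residue keys
#' @export
sites_to_residues <- function(structure, sites_top3, radius = 5.0) {
  if (inherits(sites_top3, "site_prediction")) sites_top3 <- sites_top3$top3
  if (!length(sites_top3)) return(character())
  sites_top3 <- head(sites_top3, 3)
  for (s in sites_top3)
    if (is.null(s$members) || nrow(s$members) == 0)
      stop("site with no member points")
  pts <- do.call(rbind, lapply(sites_top3, `[[`, "members"))
  d_atom <- cpp_min_dist(atom_coords(structure), pts)
  d_res <- tapply(d_atom, structure$residue_index, min)
  structure$residue_keys[as.numeric(d_res) <= radius]
}

#' Combine per-conformer residue predictions by voting
#'
#' Votes are membership counts across conformer predictions over a common
#' residue-key universe; the final set keeps residues with at least
#' `min_votes` votes (3 of 10 by default).
#'
#' @param residue_sets list of character vectors, one per conformer
#' @param min_votes acceptance threshold (default 3); capped at the number
#'   of sets, so voting over fewer conformers than the threshold reduces to
#'   requiring all of them
#' @param universe residue-key universe; defaults to the union of the sets
#' @return list with `final` (residue keys) and `votes` (a `vote_table`:
#'   named integer vector `votes`, `n_structures`)
#' @export
combine_structures <- function(residue_sets, min_votes = 3,
                               universe = NULL) {
  stopifnot(length(residue_sets) >= 1)
  min_votes <- min(min_votes, length(residue_sets))
  if (is.null(universe)) universe <- unique(unlist(residue_sets))
  for (s in residue_sets)
    if (length(setdiff(s, universe)))
      stop("residue set contains keys outside the shared universe")
  votes <- setNames(integer(length(universe)), universe)
  for (s in residue_sets) votes[unique(s)] <- votes[unique(s)] + 1L
  vt <- base::structure(list(votes = votes,
                             n_structures = length(residue_sets)),
                        class = "vote_table")
  list(final = universe[votes >= min_votes], votes = vt)
}

#' Run one of the four prediction pathways
#'
#' Pathways cross single vs multiple classifier models with single vs
#' multiple conformer structures. Per conformer: residue classification
#' (one designated ensemble member, or the full unanimous-vote ensemble),
#' geometric site prediction, then top-3 site-to-residue re-annotation.
#' Multi-structure pathways finish with k-of-n voting across conformers.
#'
#' @param pathway_id one of `single-model/single-structure`,
#'   `multi-model/single-structure`, `single-model/multi-structure`,
#'   `multi-model/multi-structure`
#' @param conformers list of `protein_structure` conformers of one protein
#'   (single-structure pathways may pass one; each is scored separately)
#' @param embeddings_per_conformer list of embedding matrices, same length
#' @param ensemble trained `classifier_ensemble`
#' @param truth character vector of reference binding-residue keys
#' @param params a [site_params()]
#' @param single_model_index ensemble member used by single-model pathways
#' @return object of class `pathway_result`: `pathway`, `per_structure`
#'   (list of final residue sets), `final` (consensus set, or the
#'   per-structure sets for single-structure pathways), `votes`
#'   (multi-structure only), `f1` (per-structure for single-structure
#'   pathways; single consensus value otherwise), `mean_f1`
#' @export
run_pathway <- function(pathway_id, conformers, embeddings_per_conformer,
                        ensemble, truth, params = site_params(),
                        single_model_index = 1) {
  pathway_id <- match.arg(pathway_id, PATHWAYS)
  if (length(conformers) != length(embeddings_per_conformer))
    stop("conformer/embedding count mismatch")
  multi_model <- startsWith(pathway_id, "multi-model")
  multi_structure <- endsWith(pathway_id, "multi-structure")
  model_index <- if (multi_model) NULL else single_model_index
  universe <- conformers[[1]]$residue_keys
  per_structure <- lapply(seq_along(conformers), function(i) {
    sp <- predict_sites(conformers[[i]], embeddings_per_conformer[[i]],
                        ensemble, params, model_index = model_index)
    sites_to_residues(conformers[[i]], sp, params$reannotate_radius)
  })
  if (multi_structure) {
    comb <- combine_structures(per_structure, params$min_votes,
                               universe = universe)
    f1 <- residue_confusion(comb$final, truth, universe)$f1
    res <- list(pathway = pathway_id, per_structure = per_structure,
                final = comb$final, votes = comb$votes, f1 = f1,
                mean_f1 = f1)
  } else {
    f1 <- vapply(per_structure, function(s)
      residue_confusion(s, truth, universe)$f1, numeric(1))
    res <- list(pathway = pathway_id, per_structure = per_structure,
                final = per_structure, votes = NULL, f1 = f1,
                mean_f1 = mean(f1))
  }
  base::structure(res, class = "pathway_result")
}

#' Write a vote table and final consensus set as a delimited table
#' @param vote_table a `vote_table`
#' @param final final residue key set
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_vote_table <- function(vote_table, final, path) {
  df <- data.frame(key = names(vote_table$votes),
                   votes = as.integer(vote_table$votes),
                   final = names(vote_table$votes) %in% final)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
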