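# Evaluation metrics: DCA/DCC distances, top-n success rates, residue-level
# confusion statistics, and vote-frequency precision-recall curves.

#' Distance from site centre to nearest ligand heavy atom (DCA)
#'
#' Success is declared when the predicted site centre lies within `cutoff`
#' (inclusive) of any heavy atom of any ligand.
#'
#' @param site_centre length-3 coordinate vector (Angstrom)
#' @param ligands a `ligand_instance` or list of them
#' @param cutoff success distance, Angstrom (default 4)
#' @return list with `distance` (Angstrom) and `success` (logical)
#' @export
dca <- function(site_centre, ligands, cutoff = 4.0) {
  if (inherits(ligands, "ligand_instance")) ligands <- list(ligands)
  if (!length(ligands)) stop("no ligands")
  atoms <- do.call(rbind, lapply(ligands, atom_coords))
  if (nrow(atoms) < 1) stop("no ligand atoms")
  d <- min(cpp_min_dist(matrix(site_centre, 1, 3), atoms))
  list(distance = d, success = d <= cutoff)
}

#' Distance from site centre to ligand centroid (DCC)
#'
#' @param site_centre length-3 coordinate vector
#' @param ligand a `ligand_instance`
#' @return distance in Angstrom to the unweighted heavy-atom centroid
#' @export
dcc <- function(site_centre, ligand) {
  atoms <- atom_coords(ligand)
  if (nrow(atoms) < 1) stop("empty ligand")
  sqrt(sum((site_centre - colMeans(atoms))^2))
}

#' Top-n DCA success rate over a set of proteins
#'
#' A protein counts as a success when any of its `n` best-ranked sites has
#' a DCA success against any of its ligands; proteins with fewer than `n`
#' sites use those available, and empty predictions count as failures.
#'
#' @param predictions_by_protein named list of `site_prediction` objects
#'   (or plain lists of `pocket_site`)
#' @param ligands_by_protein named list (same names) of ligand lists
#' @param n number of top-ranked sites considered
#' @param cutoff DCA cutoff, Angstrom
#' @return list with `rate` and per-protein logical `success`
#' @export
topn_success <- function(predictions_by_protein, ligands_by_protein, n,
                         cutoff = 4.0) {
  stopifnot(n >= 1)
  keys <- names(predictions_by_protein)
  if (!setequal(keys, names(ligands_by_protein)))
    stop("protein keys of predictions and ligands disagree")
  success <- vapply(keys, function(k) {
    p <- predictions_by_protein[[k]]
    sites <- if (inherits(p, "site_prediction")) p$sites else p
    sites <- head(sites, n)
    if (!length(sites)) return(FALSE)
    any(vapply(sites, function(s)
      dca(s$centre, ligands_by_protein[[k]], cutoff)$success, logical(1)))
  }, logical(1))
  list(rate = mean(success), success = success)
}

#' Residue-level confusion statistics
#'
#' Precision, recall, F1 and the Matthews correlation coefficient of a
#' predicted residue set against the true set over a fixed universe, with
#' the 0/0 -> 0 convention throughout (so an empty prediction against a
#' non-empty truth scores 0, matching the all-negative degenerate case).
#'
#' @param predicted_set,true_set character vectors (subsets of `universe`)
#' @param universe all residue keys under consideration
#' @return list with `tp`, `fp`, `fn`, `tn`, `precision`, `recall`, `f1`,
#'   `mcc`
#' @export
residue_confusion <- function(predicted_set, true_set, universe) {
  if (length(setdiff(predicted_set, universe)) ||
      length(setdiff(true_set, universe)))
    stop("predicted/true sets must be subsets of the universe")
  pred <- universe %in% predicted_set
  truth <- universe %in% true_set
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = precision, recall = recall, f1 = f1, mcc = mcc)
}

#' Precision-recall curve from conformer vote frequencies
#'
#' Each residue's score is its vote fraction `votes / n_structures`. One
#' curve point is computed per distinct achievable threshold (descending;
#' predict positive iff score >= threshold), and average precision is the
#' step-curve sum `AP = sum (R_k - R_{k-1}) * P_k`.
#'
#' @param vote_table a `vote_table` from [combine_structures()], or a named
#'   integer vector of votes with attribute-free counts
#' @param true_set character vector of true binding residues
#' @param universe residue-key universe (defaults to the vote table's keys)
#' @param n_structures total conformers (defaults to the table's)
#' @return list with `curve` (data.frame: threshold, precision, recall) and
#'   `average_precision`
#' @export
pr_curve_from_votes <- function(vote_table, true_set, universe = NULL,
                                n_structures = NULL) {
  if (inherits(vote_table, "vote_table")) {
    votes <- vote_table$votes
    if (is.null(n_structures)) n_structures <- vote_table$n_structures
  } else votes <- vote_table
  if (is.null(n_structures)) n_structures <- max(votes, 1)
  if (any(votes > n_structures)) stop("vote count exceeds n_structures")
  if (is.null(universe)) universe <- names(votes)
  votes <- votes[universe]
  votes[is.na(votes)] <- 0L
  names(votes) <- universe
  truth <- universe %in% true_set
  thresholds <- sort(unique(votes[votes > 0]), decreasing = TRUE) /
    n_structures
  score <- votes / n_structures
  prev_recall <- 0
  rows <- lapply(thresholds, function(th) {
    pred <- score >= th
    tp <- sum(pred & truth)
    precision <- if (sum(pred) == 0) 0 else tp / sum(pred)
    recall <- if (sum(truth) == 0) 0 else tp / sum(truth)
    c(threshold = th, precision = precision, recall = recall)
  })
  curve <- as.data.frame(do.call(rbind, rows))
  if (!nrow(curve))
    curve <- data.frame(threshold = numeric(), precision = numeric(),
                        recall = numeric())
  ap <- 0
  if (nrow(curve)) {
    r_prev <- 0
    for (k in seq_len(nrow(curve))) {
      ap <- ap + (curve$recall[k] - r_prev) * curve$precision[k]
      r_prev <- curve$recall[k]
    }
  }
  list(curve = curve, average_precision = ap)
}

#' Evaluate a batch of predictions against reference complexes
#'
#' Convenience report: per-protein top-1/top-3 DCA flags and distances plus
#' aggregate success rates.
#'
#' @param predictions_by_protein named list of `site_prediction`s
#' @param ligands_by_protein named list of ligand lists
#' @param cutoff DCA cutoff (default 4)
#' @return list with `per_protein` data.frame and `rates`
#' @export
evaluation_report <- function(predictions_by_protein, ligands_by_protein,
                              cutoff = 4.0) {
  keys <- names(predictions_by_protein)
  per <- do.call(rbind, lapply(keys, function(k) {
    p <- predictions_by_protein[[k]]
    sites <- if (inherits(p, "site_prediction")) p$sites else p
    d1 <- if (length(sites))
      dca(sites[[1]]$centre, ligands_by_protein[[k]], cutoff)$distance
    else NA_real_
    top1 <- isTRUE(!is.na(d1) && d1 <= cutoff)
    top3 <- any(vapply(head(sites, 3), function(s)
      dca(s$centre, ligands_by_protein[[k]], cutoff)$success, logical(1)))
    data.frame(protein = k, n_sites = length(sites), dca_top1 = d1,
               top1 = top1, top3 = isTRUE(top3))
  }))
  list(per_protein = per,
       rates = c(top1 = mean(per$top1), top3 = mean(per$top3)))
}
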