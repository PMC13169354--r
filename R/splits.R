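# Leakage-safe retrospective holdout construction: Bemis-Murcko scaffold
# grouping followed by sphere-exclusion filtering, with a from-scratch audit
# of the separation guarantee.

#' Scaffold-based preliminary split
#'
#' Groups actives by Bemis-Murcko scaffold, shuffles the groups under the
#' seed and fills the holdout greedily until the requested fraction is
#' reached; whole scaffold groups are always assigned to one side, so no
#' scaffold appears on both.
#'
#' @param scaffolds character vector: scaffold SMILES per molecule.
#' @param holdout_fraction requested holdout fraction.
#' @param seed RNG seed.
#' @return list(train, holdout): index vectors.
#' @export
scaffold_split <- function(scaffolds, holdout_fraction = 0.2, seed = 1) {
  n <- length(scaffolds)
  groups <- split(seq_len(n), scaffolds)
  if (length(groups) < 2)
    stop("unsplittable: a single scaffold covers all molecules")
  set.seed(seed)
  groups <- groups[sample.int(length(groups))]
  target <- holdout_fraction * n
  hold <- integer(0)
  for (g in groups) {
    if (length(hold) >= target) break
    hold <- c(hold, g)
  }
  # never swallow the whole set
  if (length(hold) == n) hold <- setdiff(hold, groups[[length(groups)]])
  list(train = sort(setdiff(seq_len(n), hold)), holdout = sort(hold))
}

#' Sphere-exclusion filtering of a preliminary holdout
#'
#' Removes every preliminary-holdout molecule whose Tanimoto similarity to
#' any training molecule is >= \code{threshold} (inclusive). The survivors
#' have maximum cross-set similarity strictly below the threshold.
#'
#' @param holdout_fps,train_fps lists of fingerprints.
#' @param threshold similarity threshold (default 0.6).
#' @return list(keep, removed): indices into the holdout list, and
#'   \code{max_sim}: per-holdout-molecule maximum similarity to train.
#' @export
sphere_exclusion <- function(holdout_fps, train_fps, threshold = 0.6) {
  if (length(train_fps) == 0)
    return(list(keep = seq_along(holdout_fps), removed = integer(0),
                max_sim = rep(0, length(holdout_fps))))
  mx <- vapply(holdout_fps, function(h)
    max(vapply(train_fps, function(t) tanimoto(h, t), numeric(1))),
    numeric(1))
  list(keep = which(mx < threshold), removed = which(mx >= threshold),
       max_sim = mx)
}

#' Leakage-safe two-step split
#'
#' Scaffold split followed by sphere exclusion, returning the final
#' partition together with a from-scratch audit (max cross-set Tanimoto,
#' shared-scaffold count, achieved sizes). The audit re-derives both
#' quantities from the molecule list, independent of the construction path,
#' and errors if either invariant is violated.
#'
#' @param smiles character vector of curated canonical SMILES.
#' @param holdout_fraction requested preliminary holdout fraction.
#' @param threshold sphere-exclusion similarity threshold (default 0.6).
#' @param seed RNG seed.
#' @return object of class \code{mf_split}: list(train, holdout, removed,
#'   audit).
#' @export
leakage_safe_split <- function(smiles, holdout_fraction = 0.2, threshold = 0.6,
                               seed = 1) {
  mols <- lapply(smiles, standardize)
  bad <- vapply(mols, inherits, logical(1), "mol_rejection")
  if (any(bad)) stop("unstandardizable input at row(s) ",
                     paste(which(bad), collapse = ", "))
  scaf <- vapply(mols, `[[`, character(1), "scaffold_smiles")
  fps <- lapply(mols, `[[`, "fingerprint")
  prelim <- scaffold_split(scaf, holdout_fraction, seed)
  se <- sphere_exclusion(fps[prelim$holdout], fps[prelim$train], threshold)
  holdout <- prelim$holdout[se$keep]
  removed <- prelim$holdout[se$removed]
  out <- structure(list(train = prelim$train, holdout = holdout,
                        removed = removed, threshold = threshold,
                        prelim_holdout_size = length(prelim$holdout)),
                   class = "mf_split")
  out$audit <- audit_split(out, smiles)
  out
}

#' Audit a split from scratch
#'
#' Recomputes the maximum train-holdout Tanimoto similarity and the number
#' of shared scaffolds directly from the molecules (an O(N*M) pass
#' independent of how the split was built) and fails loudly when the
#' leakage-safety invariants are violated.
#'
#' @param split an \code{mf_split} (or list with train/holdout indices and
#'   a \code{threshold}).
#' @param smiles the molecule list the indices refer to.
#' @return list(max_cross_tanimoto, shared_scaffold_count, n_train,
#'   n_holdout, n_removed, achieved_fraction).
#' @export
audit_split <- function(split, smiles) {
  mols <- lapply(smiles, standardize)
  fps <- lapply(mols, `[[`, "fingerprint")
  scaf <- vapply(mols, `[[`, character(1), "scaffold_smiles")
  mx <- 0
  for (h in split$holdout) for (t in split$train)
    mx <- max(mx, tanimoto(fps[[h]], fps[[t]]))
  shared <- length(intersect(scaf[split$holdout], scaf[split$train]))
  thr <- if (!is.null(split$threshold)) split$threshold else 0.6
  if (length(split$holdout) > 0) {
    if (mx >= thr) stop("leakage_detected: max cross similarity ", round(mx, 3))
    if (shared > 0) stop("leakage_detected: ", shared, " shared scaffolds")
  }
  list(max_cross_tanimoto = mx, shared_scaffold_count = shared,
       n_train = length(split$train), n_holdout = length(split$holdout),
       n_removed = length(split$removed),
       achieved_fraction = length(split$holdout) / length(smiles))
}

#' @export
print.mf_split <- function(x, ...) {
  cat("<leakage-safe split>", x$audit$n_train, "train /", x$audit$n_holdout,
      "holdout (", x$audit$n_removed, "removed by sphere exclusion)\n")
  cat("  max cross Tanimoto", round(x$audit$max_cross_tanimoto, 3),
      "| shared scaffolds", x$audit$shared_scaffold_count, "\n")
  invisible(x)
}

#' Write split artifacts (train/holdout/removed CSVs + audit JSON)
#' @param split an \code{mf_split}.
#' @param smiles the molecule list the indices refer to.
#' @param dir output directory.
#' @export
write_split <- function(split, smiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(smiles = smiles[split$train]),
                   file.path(dir, "train.csv"), row.names = FALSE)
  utils::write.csv(data.frame(smiles = smiles[split$holdout]),
                   file.path(dir, "holdout.csv"), row.names = FALSE)
  utils::write.csv(data.frame(smiles = smiles[split$removed]),
                   file.path(dir, "removed.csv"), row.names = FALSE)
  jsonlite::write_json(split$audit, file.path(dir, "audit.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
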