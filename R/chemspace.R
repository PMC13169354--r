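# UMAP chemical-space projection over Morgan fingerprints, following the
# fit/transform protocol: the manifold is learned on the combined training
# and generated sets only; holdout molecules are projected into it
# afterwards. The UMAP computation runs in the pre-installed Python
# umap-learn backend through a subprocess with CSV interchange.

#' Project chemical space with UMAP
#'
#' Encodes molecules as 2048-bit Morgan fingerprints (passed as boolean
#' vectors so the Jaccard metric is well-defined), fits a 2-D UMAP embedding
#' on train + generated, and transforms holdout into the fitted manifold.
#' Defaults follow the reference protocol: Jaccard metric, n_neighbors 30,
#' min_dist 0.1, generated sample capped at 10,000.
#'
#' @param train,generated,holdout character vectors of canonical SMILES
#'   (holdout may be empty).
#' @param n_neighbors,min_dist,metric UMAP parameters.
#' @param max_generated cap on the generated sample (default 10000).
#' @param seed random state passed to UMAP.
#' @param python python executable with umap-learn (default "python").
#' @return object of class \code{mf_embedding_map}: data.frame (id, set, x,
#'   y) plus a \code{params} attribute.
#' @export
embed_chemical_space <- function(train, generated, holdout = character(0),
                                 n_neighbors = 30, min_dist = 0.1,
                                 metric = "jaccard", max_generated = 10000,
                                 seed = 42, python = "python") {
  if (length(generated) > max_generated)
    generated <- generated[seq_len(max_generated)]
  n_fit <- length(train) + length(generated)
  if (n_fit <= n_neighbors)
    stop("fewer fit points (", n_fit, ") than n_neighbors (", n_neighbors,
         "); lower n_neighbors")
  all_smiles <- c(train, generated, holdout)
  sets <- c(rep("train", length(train)), rep("generated", length(generated)),
            rep("holdout", length(holdout)))
  fps <- lapply(all_smiles, ecfp4)
  nb <- attr(fps[[1]], "n_bits")
  M <- matrix(0L, length(fps), nb)
  for (i in seq_along(fps)) M[i, fps[[i]]] <- 1L
  td <- tempfile("umap")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  utils::write.table(M, file.path(td, "fps.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  writeLines(sets, file.path(td, "sets.txt"))
  script <- file.path(td, "run_umap.py")
  writeLines(c(
    "import sys, warnings",
    "warnings.filterwarnings('ignore')",
    "import numpy as np",
    "import umap",
    "d = sys.argv[1]",
    sprintf("nn, md, metric, seed = %d, %s, '%s', %d",
            as.integer(n_neighbors), format(min_dist), metric,
            as.integer(seed)),
    "X = np.loadtxt(d + '/fps.csv', delimiter=',').astype(bool)",
    "sets = open(d + '/sets.txt').read().split()",
    "fit_mask = np.array([s != 'holdout' for s in sets])",
    "m = umap.UMAP(n_neighbors=nn, min_dist=md, metric=metric,",
    "              random_state=seed, n_components=2)",
    "emb_fit = m.fit_transform(X[fit_mask])",
    "out = np.zeros((X.shape[0], 2))",
    "out[fit_mask] = emb_fit",
    "if (~fit_mask).sum() > 0:",
    "    out[~fit_mask] = m.transform(X[~fit_mask])",
    "np.savetxt(d + '/coords.csv', out, delimiter=',')"),
    script)
  status <- system2(python, c(script, td), stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(file.path(td, "coords.csv")))
    stop("UMAP backend failed (python umap-learn not available?)")
  xy <- utils::read.table(file.path(td, "coords.csv"), sep = ",")
  out <- data.frame(id = seq_along(all_smiles), set = sets,
                    x = xy[[1]], y = xy[[2]], stringsAsFactors = FALSE)
  structure(out,
            params = list(metric = metric, n_neighbors = n_neighbors,
                          min_dist = min_dist, seed = seed),
            class = c("mf_embedding_map", "data.frame"))
}

#' Write embedding coordinates to CSV
#' @param map an \code{mf_embedding_map}.
#' @param path output CSV.
#' @export
write_embedding <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}
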