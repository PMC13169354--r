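# Generative, distributional and target-focused evaluation: validity /
# uniqueness / novelty, KS and KL distribution distances, Frechet distance
# over molecular embeddings with the repeated size-matched subsampling
# protocol, and the rediscovery metrics (RR_T, RS_T, RS_H, SNN, IntDiv).

#' Validity, uniqueness and novelty of a generated batch
#'
#' validity = valid / total; uniqueness = unique canonical SMILES / valid;
#' novelty = unique canonical SMILES not present in the training set /
#' unique. All returned as percentages.
#'
#' @param batch an \code{mf_generation}, or character vector of raw SMILES.
#' @param training_set character vector of training canonical SMILES.
#' @return named numeric c(validity=, uniqueness=, novelty=) in percent.
#' @export
generative_metrics <- function(batch, training_set = character(0)) {
  if (inherits(batch, "mf_generation")) {
    recs <- batch$records
    if (nrow(recs) == 0) stop("empty batch")
    n <- nrow(recs)
    canon <- recs$canonical_smiles[recs$valid]
  } else {
    if (length(batch) == 0) stop("empty batch")
    n <- length(batch)
    canon <- character(0)
    for (s in batch) {
      cs <- tryCatch(smi_canonical(smi_parse(s)), error = function(e) NULL)
      if (!is.null(cs)) canon <- c(canon, cs)
    }
  }
  n_valid <- length(canon)
  uniq <- unique(canon)
  n_unique <- length(uniq)
  novel <- setdiff(uniq, training_set)
  c(validity = 100 * n_valid / n,
    uniqueness = if (n_valid == 0) NA_real_ else 100 * n_unique / n_valid,
    novelty = if (n_unique == 0) NA_real_ else 100 * length(novel) / n_unique)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Supremum of the absolute difference between the empirical CDFs.
#'
#' @param a,b numeric samples (nonempty).
#' @return statistic in [0, 1].
#' @export
ks_statistic <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  unname(suppressWarnings(stats::ks.test(a, b)$statistic))
}

#' Histogram Kullback-Leibler divergence
#'
#' KL(P || Q) over a shared equal-width binning of the pooled range, with
#' additive smoothing \code{eps} so empty bins are defined. Nonnegative;
#' ~0 for identical samples.
#'
#' @param a,b numeric samples (a is P, b is Q).
#' @param bins number of shared bins (default 20).
#' @param eps additive smoothing (default 1e-10).
#' @return divergence in nats.
#' @export
kl_divergence <- function(a, b, bins = 20, eps = 1e-10) {
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  rng <- range(c(a, b))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  p <- tabulate(findInterval(a, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), bins)
  q <- tabulate(findInterval(b, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), bins)
  p <- p / sum(p) + eps; p <- p / sum(p)
  q <- q / sum(q) + eps; q <- q / sum(q)
  sum(p * log(p / q))
}

#' Deterministic fingerprint-projection embedding
#'
#' Projects 2048-bit Morgan fingerprints into a fixed low-dimensional real
#' space through a frozen Gaussian random matrix (fixed internal seed), the
#' pluggable embedding backend for Frechet-distance comparisons when a
#' chemistry-trained network embedding is not available. Internally
#' consistent across runs but not comparable with values computed under
#' other embedding backends.
#'
#' @param smiles character vector, or a list of fingerprints.
#' @param dim embedding dimension (default 32).
#' @return n x dim numeric matrix.
#' @export
fingerprint_embedding <- function(smiles, dim = 32) {
  fps <- if (is.list(smiles)) smiles else lapply(smiles, ecfp4)
  nb <- attr(fps[[1]], "n_bits")
  proj <- local({
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    rs <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", rs, envir = globalenv()))
    set.seed(20231115L)             # frozen projection: embedding is a constant
    matrix(stats::rnorm(nb * dim), nb, dim) / sqrt(dim)
  })
  out <- matrix(0, length(fps), dim)
  for (i in seq_along(fps)) out[i, ] <- colSums(proj[fps[[i]], , drop = FALSE])
  out
}

#' Frechet distance between two embedded sets
#'
#' \code{||mu_a - mu_b||^2 + tr(S_a + S_b - 2 (S_a S_b)^{1/2})} on the
#' Gaussian summaries of two embedding matrices; the matrix square root uses
#' a symmetric eigendecomposition, and small negative eigenvalues (numerical
#' noise, tolerance 1e-8) are clipped to zero.
#'
#' @param emb_a,emb_b n x d embedding matrices (n >= 2 each).
#' @return nonnegative distance.
#' @export
frechet_distance <- function(emb_a, emb_b) {
  if (nrow(emb_a) < 2 || nrow(emb_b) < 2) stop("need at least 2 points per set")
  mua <- colMeans(emb_a); mub <- colMeans(emb_b)
  Sa <- stats::cov(emb_a); Sb <- stats::cov(emb_b)
  # tr((Sa Sb)^1/2) via symmetric form: eigenvalues of Sa^1/2 Sb Sa^1/2
  ea <- eigen(Sa, symmetric = TRUE)
  va <- pmax(ea$values, 0)
  Sa_half <- ea$vectors %*% (sqrt(va) * t(ea$vectors))
  M <- Sa_half %*% Sb %*% Sa_half
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0 & ev > -1e-8] <- 0
  ev <- pmax(ev, 0)
  d2 <- sum((mua - mub)^2) + sum(diag(Sa)) + sum(diag(Sb)) - 2 * sum(sqrt(ev))
  max(d2, 0)
}

#' Repeated size-matched subsampling of a distributional metric
#'
#' Computes \code{metric(sub_a, sub_b)} on \code{n_reps} independent random
#' subsets of size \code{subsample_size} drawn from each set, reporting
#' mean and standard deviation. This is the protocol used both for
#' generated-vs-training comparisons and for the baseline reference against
#' size-matched samples of the pretraining distribution.
#'
#' @param set_a,set_b lists/vectors the metric understands (e.g. embedding
#'   row indices are drawn from matrices; vectors are subset directly).
#' @param metric function(a, b) -> scalar.
#' @param subsample_size subset size (each set must be at least this big).
#' @param n_reps repetitions (default 20).
#' @param seed RNG seed.
#' @return c(mean=, sd=) with attribute \code{"values"}.
#' @export
subsampled_comparison <- function(set_a, set_b, metric, subsample_size,
                                  n_reps = 20, seed = 1) {
  size <- function(x) if (is.matrix(x)) nrow(x) else length(x)
  take <- function(x, idx) if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx]
  if (size(set_a) < subsample_size || size(set_b) < subsample_size)
    stop("subsample_size exceeds a set size")
  set.seed(seed)
  vals <- vapply(seq_len(n_reps), function(r) {
    ia <- sample.int(size(set_a), subsample_size)
    ib <- sample.int(size(set_b), subsample_size)
    metric(take(set_a, ia), take(set_b, ib))
  }, numeric(1))
  structure(c(mean = mean(vals), sd = stats::sd(vals)), values = vals)
}

#' Target-focused rediscovery metrics
#'
#' \itemize{
#'   \item RR_T (training recovery): percent of training actives with at
#'     least one generated molecule at Tanimoto >= \code{threshold}.
#'   \item RS_T / RS_H (scaffold recovery): percent of training / holdout
#'     Bemis-Murcko scaffolds present among the generated molecules'
#'     scaffolds (exact canonical-SMILES match).
#'   \item SNN: mean over generated molecules of the maximum Tanimoto
#'     similarity to the training set.
#'   \item IntDiv: 1 - mean pairwise Tanimoto within the generated set.
#' }
#'
#' @param generated character vector of valid generated canonical SMILES.
#' @param train_actives character vector of training-active canonical SMILES.
#' @param holdout_actives character vector (may be empty: RS_H is NA).
#' @param threshold rediscovery similarity threshold (default 0.6).
#' @return list(rr_t, rs_t, rs_h, snn, intdiv).
#' @export
target_metrics <- function(generated, train_actives,
                           holdout_actives = character(0), threshold = 0.6) {
  if (length(train_actives) == 0) stop("empty reference set")
  if (length(generated) == 0) stop("empty generated set")
  gen_fp <- lapply(generated, ecfp4)
  trn_fp <- lapply(train_actives, ecfp4)
  sim <- matrix(0, length(train_actives), length(generated))
  for (i in seq_along(trn_fp))
    for (j in seq_along(gen_fp))
      sim[i, j] <- tanimoto(trn_fp[[i]], gen_fp[[j]])
  rr_t <- 100 * mean(apply(sim, 1, max) >= threshold)
  snn <- mean(apply(sim, 2, max))
  gen_scaf <- unique(vapply(generated, murcko_scaffold, character(1)))
  scaf_recovery <- function(ref) {
    rs <- unique(vapply(ref, murcko_scaffold, character(1)))
    if (length(rs) == 0) return(NA_real_)
    100 * mean(rs %in% gen_scaf)
  }
  rs_t <- scaf_recovery(train_actives)
  rs_h <- if (length(holdout_actives) > 0) scaf_recovery(holdout_actives) else NA_real_
  n <- length(gen_fp)
  intdiv <- if (n < 2) 0 else {
    s <- 0; cnt <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      s <- s + tanimoto(gen_fp[[i]], gen_fp[[j]]); cnt <- cnt + 1
    }
    1 - s / cnt
  }
  list(rr_t = rr_t, rs_t = rs_t, rs_h = rs_h, snn = snn, intdiv = intdiv)
}

#' Full evaluation report for a generated batch
#'
#' Bundles the generative metrics, the physicochemical summary, per-property
#' distributional distances against a reference set (KS and KL on MW, logP,
#' ring count, HBD, HBA, rotatable bonds), the subsampled Frechet distance
#' under the fingerprint-projection embedding, and (when active sets are
#' supplied) the target-focused metrics.
#'
#' @param batch an \code{mf_generation}.
#' @param training_set character vector of training canonical SMILES.
#' @param holdout_set optional holdout canonical SMILES.
#' @param n_reps subsampling repetitions (default 20).
#' @param subsample_size defaults to \code{min(|valid|, |training|)}.
#' @param seed RNG seed for subsampling.
#' @return object of class \code{mf_metric_report} (a nested list); the
#'   \code{embedding_backend} field records that the fingerprint projection
#'   (not a chemistry-trained network) produced the Frechet values.
#' @export
metric_report <- function(batch, training_set, holdout_set = character(0),
                          n_reps = 20, subsample_size = NULL, seed = 1) {
  gen <- generative_metrics(batch, training_set)
  valid <- batch$records$canonical_smiles[batch$records$valid]
  valid <- valid[!is.na(valid)]
  if (length(valid) < 2) stop("need at least 2 valid molecules for a report")
  prof_gen <- physchem_profile(valid)
  prof_ref <- physchem_profile(training_set)
  props <- c("mw", "logp", "ring_count", "hbd", "hba", "rotatable_bonds")
  dist <- lapply(props, function(p) {
    a <- prof_gen$table[[p]]; b <- prof_ref$table[[p]]
    c(ks = ks_statistic(a, b), kl = kl_divergence(a, b))
  })
  names(dist) <- props
  emb_gen <- fingerprint_embedding(valid)
  emb_ref <- fingerprint_embedding(training_set)
  if (is.null(subsample_size))
    subsample_size <- min(nrow(emb_gen), nrow(emb_ref))
  fcd <- subsampled_comparison(emb_gen, emb_ref, frechet_distance,
                               subsample_size = subsample_size,
                               n_reps = n_reps, seed = seed)
  tgt <- if (length(training_set) > 0)
    target_metrics(valid, training_set, holdout_set) else NULL
  structure(list(generative = gen,
                 physchem = prof_gen$summary,
                 distributional = dist,
                 frechet = fcd,
                 target = tgt,
                 embedding_backend = "fingerprint-projection",
                 provenance = list(n = nrow(batch$records),
                                   n_valid = length(valid),
                                   n_reps = n_reps,
                                   subsample_size = subsample_size,
                                   seed = seed)),
            class = "mf_metric_report")
}

#' @export
print.mf_metric_report <- function(x, ...) {
  cat("<metric report>\n")
  cat(sprintf("  validity %.1f%%  uniqueness %.1f%%  novelty %.1f%%\n",
              x$generative["validity"], x$generative["uniqueness"],
              x$generative["novelty"]))
  cat(sprintf("  Frechet (fingerprint projection) %.3f +/- %.3f over %d reps\n",
              x$frechet["mean"], x$frechet["sd"], x$provenance$n_reps))
  if (!is.null(x$target))
    cat(sprintf("  RR_T %.1f%%  RS_T %.1f%%  SNN %.3f  IntDiv %.3f\n",
                x$target$rr_t, x$target$rs_t, x$target$snn, x$target$intdiv))
  invisible(x)
}

#' Write a metric report to JSON
#' @param report an \code{mf_metric_report}.
#' @param path output JSON path.
#' @export
write_metric_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
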