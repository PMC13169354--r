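# Conditional training sequences: assembly of [context + SEP + target]
# records in the three experimental modes, the [5, 140] token length filter,
# curriculum ordering by topological complexity, and on-the-fly randomized-
# SMILES augmentation.

SEQUENCE_MODES <- c("unconditional", "smarts_only", "hybrid")

#' Assemble a conditional training sequence
#'
#' Layouts (ids are bracketed specials):
#' \itemize{
#'   \item unconditional: \code{[START] Target [END]}
#'   \item smarts_only: \code{[START] SMARTS [SEP] Target [END]}
#'   \item hybrid: \code{[START] SMARTS [SEP] Scaffold [SEP] Target [END]}
#' }
#' Descriptor tokens are emitted in ontology (= vocabulary) order, a stable
#' canonical order so prompts are reproducible. For acyclic molecules in
#' hybrid mode the scaffold span is empty but both \code{[SEP]}s are kept, so
#' the layout stays parseable. The total length \code{l_tot} counts the three
#' component spans only (descriptors + scaffold tokens + target tokens),
#' excluding specials.
#'
#' @param mol a \code{standard_mol}; its \code{descriptor_ids} field (set by
#'   \code{\link{curate_smiles}} with an ontology) supplies the SMARTS span.
#' @param mode one of \code{"unconditional"}, \code{"smarts_only"},
#'   \code{"hybrid"}.
#' @param vocab an \code{mf_vocab}.
#' @return object of class \code{training_sequence}: list with \code{mode},
#'   \code{descriptor_tokens}, \code{scaffold_tokens}, \code{target_tokens},
#'   \code{assembled_ids}, \code{l_tot}, \code{ring_count},
#'   \code{branch_count}, \code{canonical_smiles}, \code{mol}.
#' @export
build_sequence <- function(mol, mode = c("hybrid", "smarts_only", "unconditional"),
                           vocab) {
  mode <- match.arg(mode)
  stopifnot(inherits(mol, "standard_mol"))
  desc <- mol$descriptor_ids
  if (is.null(desc)) desc <- character(0)
  desc <- desc[order(match(desc, vocab$descriptor_tokens))]
  scaf_tok <- if (mode == "hybrid" && nzchar(mol$scaffold_smiles))
    tokenize_smiles(mol$scaffold_smiles) else character(0)
  tgt_tok <- tokenize_smiles(mol$canonical_smiles)
  START <- special_id(vocab, "START"); SEP <- special_id(vocab, "SEP")
  END <- special_id(vocab, "END")
  ids <- switch(mode,
    unconditional = c(START, encode(tgt_tok, vocab), END),
    smarts_only   = c(START, encode(desc, vocab), SEP, encode(tgt_tok, vocab), END),
    hybrid        = c(START, encode(desc, vocab), SEP, encode(scaf_tok, vocab),
                      SEP, encode(tgt_tok, vocab), END))
  structure(list(
    mode = mode,
    descriptor_tokens = desc,
    scaffold_tokens = scaf_tok,
    target_tokens = tgt_tok,
    assembled_ids = as.integer(ids),
    l_tot = length(desc) + length(scaf_tok) + length(tgt_tok),
    ring_count = mol$ring_count,
    branch_count = mol$branch_count,
    canonical_smiles = mol$canonical_smiles,
    mol = mol
  ), class = "training_sequence")
}

#' Decompose an assembled sequence back into its component spans
#'
#' Inverse of \code{\link{build_sequence}}: splits on the \code{[SEP]}
#' positions. The number of \code{[SEP]}s identifies the mode.
#'
#' @param ids assembled id vector (with \code{[START]}/\code{[END]}).
#' @param vocab an \code{mf_vocab}.
#' @return list(mode, descriptor_tokens, scaffold_tokens, target_tokens).
#' @export
decompose_sequence <- function(ids, vocab) {
  START <- special_id(vocab, "START"); SEP <- special_id(vocab, "SEP")
  END <- special_id(vocab, "END")
  if (length(ids) < 2 || ids[1] != START || ids[length(ids)] != END)
    stop("sequence must be framed by [START]...[END]")
  body <- ids[-c(1, length(ids))]
  seps <- which(body == SEP)
  if (length(seps) == 0) {
    return(list(mode = "unconditional", descriptor_tokens = character(0),
                scaffold_tokens = character(0),
                target_tokens = decode(body, vocab)))
  }
  if (length(seps) == 1) {
    return(list(mode = "smarts_only",
                descriptor_tokens = decode(body[seq_len(seps[1] - 1)], vocab),
                scaffold_tokens = character(0),
                target_tokens = decode(body[-seq_len(seps[1])], vocab)))
  }
  if (length(seps) == 2) {
    d <- if (seps[1] > 1) decode(body[seq_len(seps[1] - 1)], vocab) else character(0)
    s <- if (seps[2] > seps[1] + 1) decode(body[(seps[1] + 1):(seps[2] - 1)], vocab) else character(0)
    t <- if (seps[2] < length(body)) decode(body[(seps[2] + 1):length(body)], vocab) else character(0)
    return(list(mode = "hybrid", descriptor_tokens = d, scaffold_tokens = s,
                target_tokens = t))
  }
  stop("malformed sequence: more than two [SEP] delimiters")
}

#' Sequence length filter
#'
#' Keeps sequences whose component token count \code{l_tot} lies in the
#' inclusive band \code{[min_len, max_len]} (defaults [5, 140]).
#'
#' @param seq a \code{training_sequence}, or a numeric \code{l_tot}.
#' @param min_len,max_len inclusive bounds.
#' @return logical.
#' @export
length_filter <- function(seq, min_len = 5, max_len = 140) {
  l <- if (inherits(seq, "training_sequence")) seq$l_tot else seq
  l >= min_len & l <= max_len
}

#' Curriculum ordering by topological complexity
#'
#' Stable ascending sort by (ring_count, branch_count, l_tot), returning the
#' permutation of indices and quantile-bin stage boundaries. Training starts
#' on the simplest stage and unlocks the next when validation improvement
#' plateaus.
#'
#' @param seqs list of \code{training_sequence}.
#' @param n_stages number of quantile bins (default 4).
#' @return list(order = integer permutation, stage = integer stage label per
#'   *sorted* position, boundaries = last sorted index of each stage).
#' @export
curriculum_order <- function(seqs, n_stages = 4) {
  n <- length(seqs)
  rc <- vapply(seqs, `[[`, numeric(1), "ring_count")
  bc <- vapply(seqs, `[[`, numeric(1), "branch_count")
  lt <- vapply(seqs, `[[`, numeric(1), "l_tot")
  ord <- order(rc, bc, lt)                      # radix sort: stable
  n_stages <- max(1L, min(n_stages, n))
  sizes <- diff(floor(seq(0, n, length.out = n_stages + 1)))
  stage <- rep(seq_len(n_stages), times = sizes)
  list(order = ord, stage = stage, boundaries = cumsum(sizes))
}

#' On-the-fly randomized-SMILES augmentation
#'
#' With probability \code{p} the target span is replaced by a randomized
#' rendering of the same molecule (re-tokenized and re-encoded); the
#' conditioning context is never altered and molecule identity is preserved.
#'
#' @param seq a \code{training_sequence}.
#' @param p replacement probability (default 0.1).
#' @param vocab an \code{mf_vocab}.
#' @return a \code{training_sequence} (possibly unchanged).
#' @export
augment <- function(seq, p = 0.1, vocab) {
  if (p <= 0 || stats::runif(1) >= p) return(seq)
  rand <- randomize_smiles(seq$mol)
  tgt_tok <- tokenize_smiles(rand)
  ok <- tryCatch({ encode(tgt_tok, vocab); TRUE }, error = function(e) FALSE)
  if (!ok) return(seq)                          # rendering used an unseen token
  START <- special_id(vocab, "START"); SEP <- special_id(vocab, "SEP")
  END <- special_id(vocab, "END")
  ids <- switch(seq$mode,
    unconditional = c(START, encode(tgt_tok, vocab), END),
    smarts_only   = c(START, encode(seq$descriptor_tokens, vocab), SEP,
                      encode(tgt_tok, vocab), END),
    hybrid        = c(START, encode(seq$descriptor_tokens, vocab), SEP,
                      encode(seq$scaffold_tokens, vocab), SEP,
                      encode(tgt_tok, vocab), END))
  seq$target_tokens <- tgt_tok
  seq$assembled_ids <- as.integer(ids)
  seq$l_tot <- length(seq$descriptor_tokens) + length(seq$scaffold_tokens) +
    length(tgt_tok)
  seq
}

#' Cosine similarity of corpus fingerprint centroids
#'
#' Cosine of the mean Morgan fingerprint bit-vectors (as real vectors) of two
#' corpora; used to audit that length filtering preserves the global chemical
#' space distribution.
#'
#' @param fps_a,fps_b lists of fingerprints (from \code{\link{ecfp4}}).
#' @return cosine similarity in \code{[0, 1]}.
#' @export
centroid_similarity <- function(fps_a, fps_b) {
  if (length(fps_a) == 0 || length(fps_b) == 0) stop("empty corpus")
  nb <- attr(fps_a[[1]], "n_bits")
  if (is.null(nb)) nb <- 2048L
  centroid <- function(fps) {
    v <- numeric(nb)
    for (f in fps) v[f] <- v[f] + 1
    v / length(fps)
  }
  a <- centroid(fps_a); b <- centroid(fps_b)
  den <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

#' Build a curated training corpus end to end
#'
#' Standardizes and deduplicates the raw SMILES, profiles them against the
#' ontology, assembles sequences in the requested mode, applies the length
#' filter and builds the vocabulary from the retained sequences. The counts
#' reconcile: kept + rejected + duplicate + dropped_by_length = input size.
#'
#' @param smiles character vector of raw SMILES.
#' @param ontology a \code{smartsrx_ontology}.
#' @param mode sequence mode (default \code{"hybrid"}).
#' @param min_len,max_len inclusive length-filter bounds.
#' @param vocab optional pre-built vocabulary (e.g. from a pretrained
#'   checkpoint); sequences with out-of-vocabulary tokens are then an error.
#' @param seed recorded in the manifest (curation itself is deterministic).
#' @return object of class \code{mf_corpus}: list(sequences, vocab, counts,
#'   manifest, curation).
#' @export
build_training_corpus <- function(smiles, ontology,
                                  mode = c("hybrid", "smarts_only", "unconditional"),
                                  min_len = 5, max_len = 140,
                                  vocab = NULL, seed = NA) {
  mode <- match.arg(mode)
  cur <- curate_smiles(smiles, ontology)
  if (is.null(vocab)) {
    tok_lists <- lapply(cur$molecules, function(m) {
      c(tokenize_smiles(m$canonical_smiles),
        if (mode == "hybrid" && nzchar(m$scaffold_smiles))
          tokenize_smiles(m$scaffold_smiles))
    })
    if (length(tok_lists) == 0) stop("empty corpus after curation")
    vocab <- build_vocabulary(tok_lists, ontology)
  }
  seqs <- lapply(cur$molecules, build_sequence, mode = mode, vocab = vocab)
  keep <- vapply(seqs, length_filter, logical(1), min_len = min_len, max_len = max_len)
  counts <- c(input = unname(cur$counts["input"]),
              kept = sum(keep),
              rejected = unname(cur$counts["rejected"]),
              duplicate = unname(cur$counts["duplicate"]),
              dropped_by_length = sum(!keep))
  manifest <- list(mode = mode, counts = as.list(counts),
                   vocab_hash = vocab$hash,
                   length_filter = c(min_len, max_len), seed = seed)
  structure(list(sequences = seqs[keep], vocab = vocab, counts = counts,
                 manifest = manifest, curation = cur),
            class = "mf_corpus")
}

#' @export
print.mf_corpus <- function(x, ...) {
  cat("<training corpus>", length(x$sequences), "sequences, mode",
      x$manifest$mode, "\n")
  print(x$counts)
  invisible(x)
}

#' Write the curated-corpus CSV and manifest JSON
#'
#' @param corpus an \code{mf_corpus}.
#' @param dir output directory (created if missing).
#' @return paths invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "corpus.csv")
  utils::write.csv(corpus$curation$table, csv, row.names = FALSE)
  man <- file.path(dir, "manifest.json")
  jsonlite::write_json(corpus$manifest, man, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, manifest = man))
}
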