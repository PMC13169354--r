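# Prompt construction, temperature-scaled autoregressive decoding and batch
# generation with per-record bookkeeping.

#' Conditioning context
#'
#' The tuple steering generation: an ordered set of functional-group
#' descriptor tokens and an optional scaffold SMILES template. Both may be
#' empty (unconstrained generation).
#'
#' @param descriptors character vector of descriptor tokens (may be empty).
#' @param scaffold scaffold SMILES string or \code{NULL}/\code{""}.
#' @return object of class \code{mf_context}.
#' @export
conditioning_context <- function(descriptors = character(0), scaffold = NULL) {
  if (!is.null(scaffold) && !nzchar(scaffold)) scaffold <- NULL
  structure(list(descriptors = as.character(descriptors), scaffold = scaffold),
            class = "mf_context")
}

#' Extract a conditioning context from a molecule
#'
#' Convenience wrapper: standardizes the molecule, profiles it against the
#' ontology and extracts its Bemis-Murcko scaffold on the fly, yielding the
#' (descriptors, scaffold) context that would regenerate molecules sharing
#' its functional environments and core.
#'
#' @param smiles a SMILES string.
#' @param ontology a \code{smartsrx_ontology}.
#' @param use_scaffold include the scaffold (hybrid conditioning)?
#' @return an \code{mf_context}.
#' @export
context_from_molecule <- function(smiles, ontology, use_scaffold = TRUE) {
  sm <- standardize(smiles, fingerprint = FALSE)
  if (inherits(sm, "mol_rejection")) stop("invalid_molecule: ", sm$reason)
  conditioning_context(profile(sm, ontology),
                       if (use_scaffold && nzchar(sm$scaffold_smiles))
                         sm$scaffold_smiles else NULL)
}

#' Build the decoding prompt for a conditioning context
#'
#' \code{[START] + X_SMARTS + [SEP] + X_Scaffold + [SEP]} when both spans are
#' present; \code{[START] + X_SMARTS + [SEP]} for semantic-only conditioning;
#' bare \code{[START]} when unconstrained. Descriptor tokens are ordered by
#' their vocabulary (ontology) position; unknown descriptor or scaffold
#' tokens are a hard error.
#'
#' @param context an \code{mf_context}.
#' @param vocab an \code{mf_vocab}.
#' @return integer vector of prompt ids.
#' @export
build_prompt <- function(context, vocab) {
  START <- special_id(vocab, "START"); SEP <- special_id(vocab, "SEP")
  desc <- context$descriptors
  unknown <- setdiff(desc, vocab$descriptor_tokens)
  if (length(unknown) > 0)
    stop("oov_token: ", paste(unknown, collapse = ", "))
  desc <- desc[order(match(desc, vocab$descriptor_tokens))]
  ids <- START
  if (is.null(context$scaffold)) {
    if (length(desc) > 0) ids <- c(ids, encode(desc, vocab), SEP)
  } else {
    scaf_tok <- tokenize_smiles(context$scaffold)
    ids <- c(ids, encode(desc, vocab), SEP, encode(scaf_tok, vocab), SEP)
  }
  as.integer(ids)
}

#' Temperature-scaled sampling from a logit vector
#'
#' Draws from \code{softmax(z / T)}. \code{T = 0} is greedy decoding
#' (argmax, lowest-id tie-break); \code{T < 0} is an error.
#'
#' @param z numeric logit vector.
#' @param temperature positive sampling temperature, or 0 for greedy.
#' @return 0-based sampled token id.
#' @export
temperature_sample <- function(z, temperature = 1) {
  if (temperature < 0) stop("temperature must be >= 0")
  if (temperature == 0) return(which.max(z) - 1L)
  p <- .softmax_rows(matrix(z / temperature, 1))[1, ]
  sample.int(length(p), 1, prob = p) - 1L
}

#' Generate molecules by conditional autoregressive decoding
#'
#' Starts every record from the prompt of \code{context} and extends it
#' token-by-token, sampling from the temperature-scaled next-token
#' distribution until \code{[END]} or \code{max_len} generated tokens. The
#' decoded SMILES is the target span only (prompt stripped); validity is
#' judged by the chemical parser (valence + aromaticity checks). A record
#' whose target span contains a special token is invalid. Fixed seed gives
#' byte-identical batches.
#'
#' @param state an \code{mf_model}.
#' @param context an \code{mf_context} (default: unconstrained).
#' @param n number of molecules.
#' @param temperature sampling temperature (0 = greedy).
#' @param max_len maximum generated target length (default: what fits in
#'   \code{max_positions}).
#' @param seed RNG seed.
#' @param forbid_specials disallow sampling PAD/START/SEP inside the target
#'   span by masking their logits (default FALSE: the raw distribution is
#'   used and such records are marked invalid at decode).
#' @return object of class \code{mf_generation}: list with \code{records}
#'   (data.frame: raw_smiles, valid, canonical_smiles, stop_reason),
#'   \code{context}, \code{temperature}, \code{seed},
#'   \code{step_entropies} (mean per-step sampling entropy, nats).
#' @export
generate <- function(state, context = conditioning_context(), n = 100,
                     temperature = 1, max_len = NULL, seed = 1,
                     forbid_specials = FALSE) {
  vocab <- state$vocab
  prompt <- build_prompt(context, vocab)
  if (is.null(max_len)) max_len <- state$config$max_positions - length(prompt)
  max_len <- min(max_len, state$config$max_positions - length(prompt))
  END <- special_id(vocab, "END")
  specials <- vapply(c("PAD", "START", "SEP"), function(w) special_id(vocab, w),
                     integer(1))
  set.seed(seed)
  if (n == 0) {
    return(structure(list(records = data.frame(raw_smiles = character(0),
                                               valid = logical(0),
                                               canonical_smiles = character(0),
                                               stop_reason = character(0),
                                               stringsAsFactors = FALSE),
                          context = context, temperature = temperature,
                          seed = seed, step_entropies = numeric(0)),
                     class = "mf_generation"))
  }
  seqs <- lapply(seq_len(n), function(i) prompt)
  done <- rep(FALSE, n)
  stop_reason <- rep("max_len", n)
  ent_sum <- 0; ent_n <- 0
  for (step in seq_len(max_len)) {
    open <- which(!done)
    if (length(open) == 0) break
    ids <- .pad_batch(seqs[open])
    fwd <- .forward(state$params, state$config, ids, train = FALSE)
    L <- ncol(ids)
    for (j in seq_along(open)) {
      i <- open[j]
      pos <- length(seqs[[i]])
      z <- fwd$logits[(j - 1) * L + pos, ]
      if (forbid_specials) z[specials + 1L] <- -Inf
      if (temperature > 0) {
        p <- .softmax_rows(matrix(z / temperature, 1))[1, ]
        ent_sum <- ent_sum - sum(ifelse(p > 0, p * log(p), 0)); ent_n <- ent_n + 1
        tok <- sample.int(length(p), 1, prob = p) - 1L
      } else {
        tok <- which.max(z) - 1L
      }
      if (tok == END) { done[i] <- TRUE; stop_reason[i] <- "END" }
      else seqs[[i]] <- c(seqs[[i]], tok)
    }
  }
  raw <- vapply(seqs, function(s) {
    body <- s[-seq_along(prompt)]
    paste(decode(pmin(pmax(body, 0L), vocab_size(vocab) - 1L), vocab),
          collapse = "")
  }, character(1))
  has_special <- vapply(seqs, function(s) any(s[-seq_along(prompt)] %in% specials),
                        logical(1))
  canon <- character(n); valid <- logical(n)
  for (i in seq_len(n)) {
    if (has_special[i]) { valid[i] <- FALSE; canon[i] <- NA_character_; next }
    sm <- tryCatch(smi_canonical(smi_parse(raw[i])), error = function(e) NULL)
    valid[i] <- !is.null(sm)
    canon[i] <- if (valid[i]) sm else NA_character_
  }
  structure(list(records = data.frame(raw_smiles = raw, valid = valid,
                                      canonical_smiles = canon,
                                      stop_reason = stop_reason,
                                      stringsAsFactors = FALSE),
                 context = context, temperature = temperature, seed = seed,
                 step_entropies = if (ent_n > 0) ent_sum / ent_n else NA_real_),
            class = "mf_generation")
}

#' @export
print.mf_generation <- function(x, ...) {
  cat("<generation batch>", nrow(x$records), "records at T =", x$temperature,
      "|", sum(x$records$valid), "valid\n")
  invisible(x)
}

#' Constraint adherence of a generated batch
#'
#' Measures how faithfully generation honored its conditioning context:
#' scaffold retention (percentage of valid molecules whose Bemis-Murcko
#' scaffold equals the conditioning scaffold, canonical-SMILES equality by
#' default, substructure containment optionally), descriptor satisfaction
#' (percentage of valid molecules whose functional-group profile contains
#' every requested descriptor) and the mean aromatic-ring count of the valid
#' molecules.
#'
#' @param batch an \code{mf_generation} (or data.frame of its records).
#' @param context the \code{mf_context} used (default: the batch's own).
#' @param ontology ontology for descriptor profiling (required when
#'   descriptors were requested).
#' @param scaffold_mode \code{"exact"} (default) or \code{"substructure"}.
#' @return list(scaffold_retention, descriptor_satisfaction,
#'   aromatic_ring_mean, n_valid); percentage fields are \code{NA} (with a
#'   warning) when no molecule is valid.
#' @export
constraint_adherence <- function(batch, context = NULL, ontology = NULL,
                                 scaffold_mode = c("exact", "substructure")) {
  scaffold_mode <- match.arg(scaffold_mode)
  recs <- if (inherits(batch, "mf_generation")) batch$records else batch
  if (is.null(context) && inherits(batch, "mf_generation")) context <- batch$context
  valid <- recs[recs$valid & !is.na(recs$canonical_smiles), , drop = FALSE]
  if (nrow(valid) == 0) {
    warning("no valid molecules in batch; adherence metrics are NA")
    return(list(scaffold_retention = NA_real_,
                descriptor_satisfaction = NA_real_,
                aromatic_ring_mean = NA_real_, n_valid = 0L))
  }
  mols <- lapply(valid$canonical_smiles, smi_parse)
  scaffold_retention <- NA_real_
  if (!is.null(context$scaffold)) {
    want <- smi_canonical(smi_parse(context$scaffold))
    got <- vapply(mols, murcko_scaffold, character(1))
    if (scaffold_mode == "exact") {
      scaffold_retention <- 100 * mean(got == want)
    } else {
      ob_want <- context$scaffold
      scaffold_retention <- 100 * mean(vapply(valid$canonical_smiles, function(s)
        tryCatch(ChemmineOB::smartsSearch_OB(.obmol(s), ob_want) > 0,
                 error = function(e) FALSE), logical(1)))
    }
  }
  descriptor_satisfaction <- NA_real_
  if (length(context$descriptors) > 0) {
    if (is.null(ontology)) stop("ontology required to check descriptor satisfaction")
    sub <- ontology[ontology$id %in% context$descriptors, , drop = FALSE]
    descriptor_satisfaction <- 100 * mean(vapply(valid$canonical_smiles,
      function(s) length(profile(s, sub)) == nrow(sub), logical(1)))
  }
  n_arom <- vapply(mols, function(m) {
    rings <- .sssr(m)
    sum(vapply(rings, function(r) all(m$arom[r]), logical(1)))
  }, numeric(1))
  list(scaffold_retention = scaffold_retention,
       descriptor_satisfaction = descriptor_satisfaction,
       aromatic_ring_mean = mean(n_arom), n_valid = nrow(valid))
}

#' Greedy reconstruction rate over a training corpus
#'
#' For each training sequence, rebuilds its conditioning prompt and decodes
#' greedily (T = 0); reports the fraction of molecules whose decoded
#' canonical SMILES equals the training target. Used as the memorization
#' sanity check for a deliberately overfit tiny model.
#'
#' @param state an \code{mf_model}.
#' @param corpus an \code{mf_corpus} (hybrid or smarts_only mode).
#' @param indices subset of sequences to test (default: all).
#' @return list(rate, hits (logical), decoded (character)).
#' @export
memorization_rate <- function(state, corpus, indices = NULL) {
  seqs <- corpus$sequences
  if (is.null(indices)) indices <- seq_along(seqs)
  decoded <- character(length(indices))
  hits <- logical(length(indices))
  for (j in seq_along(indices)) {
    s <- seqs[[indices[j]]]
    ctx <- switch(s$mode,
      unconditional = conditioning_context(),
      smarts_only = conditioning_context(s$descriptor_tokens),
      hybrid = conditioning_context(s$descriptor_tokens,
                                    if (length(s$scaffold_tokens) > 0)
                                      paste(s$scaffold_tokens, collapse = "") else NULL))
    g <- generate(state, ctx, n = 1, temperature = 0, seed = 1)
    decoded[j] <- g$records$raw_smiles[1]
    can <- g$records$canonical_smiles[1]
    hits[j] <- g$records$valid[1] && !is.na(can) && can == s$canonical_smiles
  }
  list(rate = mean(hits), hits = hits, decoded = decoded)
}
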