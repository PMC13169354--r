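# Decoder-only Transformer for conditional autoregressive SMILES generation,
# implemented directly on R matrices with hand-written backpropagation so the
# whole training stack is self-contained and exactly reproducible. A pre-norm
# residual layout (LayerNorm -> sublayer -> residual add) is used; per-step
# next-token logits are produced for every position under a causal mask.

#' Transformer model configuration
#'
#' Defaults are the reference architecture (6 layers, 6 heads, embedding
#' dimension 512, FFN hidden size 2048, dropout 0.1); every size is
#' configurable so a tiny desk-scale instance is first-class.
#'
#' @param n_layers number of masked self-attention layers.
#' @param n_heads attention heads per layer (must divide \code{d_model}).
#' @param d_model embedding dimension.
#' @param d_ffn FFN hidden size.
#' @param dropout dropout rate in \code{[0, 1)}.
#' @param max_positions maximum assembled sequence length.
#' @return object of class \code{mf_model_config}.
#' @export
model_config <- function(n_layers = 6, n_heads = 6, d_model = 512,
                         d_ffn = 2048, dropout = 0.1, max_positions = 160) {
  stopifnot(d_model %% n_heads == 0, dropout >= 0, dropout < 1,
            d_model %% 2 == 0)
  structure(list(n_layers = n_layers, n_heads = n_heads, d_model = d_model,
                 d_ffn = d_ffn, dropout = dropout,
                 max_positions = max_positions),
            class = "mf_model_config")
}

#' Training configuration
#'
#' @param max_epochs epoch budget (reference protocol: 100).
#' @param batch_size minibatch size (reference fine-tuning: 32).
#' @param warmup_steps warmup steps of the inverse square-root schedule
#'   (default 4000, the standard setting; scale down for tiny corpora).
#' @param learning_rate constant learning rate; \code{NA} (default) selects
#'   the inverse square-root warmup schedule. Fine-tuning uses 5e-5.
#' @param augment_p randomized-SMILES augmentation probability (default 0.1).
#' @param val_fraction validation fraction (default 0.1; split 90/10).
#' @param patience early-stopping patience in epochs (default 5; \code{Inf}
#'   disables early stopping).
#' @param curriculum logical; order training molecules by topological
#'   complexity and unlock stages as validation improvement plateaus.
#' @param n_stages curriculum quantile stages (default 4).
#' @param stage_patience epochs without >= \code{stage_tol} validation
#'   improvement before the next curriculum stage is unlocked (default 2).
#' @param stage_max_epochs hard cap on epochs spent in one curriculum stage
#'   before the next is unlocked regardless of progress (default 10), so a
#'   steadily improving run still sees the whole corpus.
#' @param stage_tol minimum validation-loss improvement counted as progress
#'   (default 1e-3).
#' @param loss_span \code{"all"} (cross-entropy over all non-PAD positions,
#'   the default) or \code{"target"} (target span only).
#' @param seed RNG seed controlling init, split, shuffling, augmentation and
#'   dropout.
#' @return object of class \code{mf_train_config}.
#' @export
train_config <- function(max_epochs = 100, batch_size = 32, warmup_steps = 4000,
                         learning_rate = NA, augment_p = 0.1,
                         val_fraction = 0.1, patience = 5, curriculum = TRUE,
                         n_stages = 4, stage_patience = 2, stage_tol = 1e-3,
                         stage_max_epochs = 10,
                         loss_span = c("all", "target"), seed = 1) {
  stopifnot(val_fraction > 0, val_fraction < 1)
  structure(list(max_epochs = max_epochs, batch_size = batch_size,
                 warmup_steps = warmup_steps, learning_rate = learning_rate,
                 augment_p = augment_p, val_fraction = val_fraction,
                 patience = patience, curriculum = curriculum,
                 n_stages = n_stages, stage_patience = stage_patience,
                 stage_tol = stage_tol, stage_max_epochs = stage_max_epochs,
                 loss_span = match.arg(loss_span),
                 seed = seed),
            class = "mf_train_config")
}

#' Sinusoidal positional encodings
#'
#' \code{PE[pos, 2i] = sin(pos / 10000^(2i/d))},
#' \code{PE[pos, 2i+1] = cos(pos / 10000^(2i/d))} with \code{pos} starting
#' at 0.
#'
#' @param max_positions number of positions.
#' @param d_model embedding dimension (must be even).
#' @return \code{max_positions x d_model} matrix.
#' @export
positional_encoding <- function(max_positions, d_model) {
  if (d_model %% 2 != 0) stop("d_model must be even")
  pos <- 0:(max_positions - 1)
  i <- 0:(d_model / 2 - 1)
  ang <- outer(pos, 1 / 10000^(2 * i / d_model))
  pe <- matrix(0, max_positions, d_model)
  pe[, seq(1, d_model, by = 2)] <- sin(ang)
  pe[, seq(2, d_model, by = 2)] <- cos(ang)
  pe
}

#' Inverse square-root warmup learning-rate schedule
#'
#' \code{lr(step) = d_model^-0.5 * min(step^-0.5, step * warmup^-1.5)}:
#' linear warmup to the peak at \code{step == warmup_steps}, then inverse
#' square-root decay.
#'
#' @param step training step (>= 1).
#' @param d_model embedding dimension.
#' @param warmup_steps warmup length.
#' @return learning rate.
#' @export
lr_schedule <- function(step, d_model, warmup_steps) {
  if (any(step < 1)) stop("step must be >= 1")
  d_model^(-0.5) * pmin(step^(-0.5), step * warmup_steps^(-1.5))
}

# --- parameters ------------------------------------------------------------

.randmat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

.init_params <- function(cfg, vocab_n) {
  d <- cfg$d_model
  layers <- lapply(seq_len(cfg$n_layers), function(i) list(
    Wq = .randmat(d, d), bq = numeric(d),
    Wk = .randmat(d, d), bk = numeric(d),
    Wv = .randmat(d, d), bv = numeric(d),
    Wo = .randmat(d, d), bo = numeric(d),
    ln1_g = rep(1, d), ln1_b = numeric(d),
    W1 = .randmat(d, cfg$d_ffn), b1 = numeric(cfg$d_ffn),
    W2 = .randmat(cfg$d_ffn, d), b2 = numeric(d),
    ln2_g = rep(1, d), ln2_b = numeric(d)
  ))
  list(E = .randmat(vocab_n, d), layers = layers,
       lnf_g = rep(1, d), lnf_b = numeric(d),
       Wout = .randmat(d, vocab_n), bout = numeric(vocab_n))
}

#' Number of learnable parameters of a model state
#' @param state an \code{mf_model} state.
#' @return integer count.
#' @export
n_parameters <- function(state) {
  cnt <- function(x) if (is.list(x)) sum(vapply(x, cnt, numeric(1))) else length(x)
  cnt(state$params)
}

# --- forward / backward ----------------------------------------------------

.layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  inv <- 1 / sqrt(v + eps)
  Xhat <- Xc * inv
  list(Y = sweep(Xhat, 2, g, `*`) + matrix(b, nrow(X), length(b), byrow = TRUE),
       Xhat = Xhat, inv = inv)
}

.layernorm_bwd <- function(dY, cache, g) {
  Xhat <- cache$Xhat; inv <- cache$inv
  d <- ncol(Xhat)
  dXhat <- sweep(dY, 2, g, `*`)
  rs1 <- rowSums(dXhat)
  rs2 <- rowSums(dXhat * Xhat)
  dX <- inv * (dXhat - rs1 / d - Xhat * rs2 / d)
  list(dX = dX, dg = colSums(dY * Xhat), db = colSums(dY))
}

.softmax_rows <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

# forward pass over a padded batch.
# ids: B x L matrix of 0-based ids (PAD = 0 right-padding)
# returns logits (B*L x V, row-major by sequence) and caches for backward
.forward <- function(params, cfg, ids, train = FALSE, keep_cache = FALSE) {
  B <- nrow(ids); L <- ncol(ids); d <- cfg$d_model
  nh <- cfg$n_heads; dh <- d / nh
  rows_of <- function(b) ((b - 1) * L + 1):(b * L)
  flat <- as.integer(t(ids)) + 1L            # row (b-1)*L+t  <- ids[b, t]
  X <- params$E[flat, , drop = FALSE]
  pe <- positional_encoding(L, d)
  X <- X + pe[rep(seq_len(L), times = B), , drop = FALSE]
  p_drop <- if (train) cfg$dropout else 0
  caches <- vector("list", cfg$n_layers)
  neg <- -1e30
  for (li in seq_len(cfg$n_layers)) {
    lp <- params$layers[[li]]
    ln1 <- .layernorm_fwd(X, lp$ln1_g, lp$ln1_b)
    H <- ln1$Y
    Q <- H %*% lp$Wq; Q <- sweep(Q, 2, lp$bq, `+`)
    K <- H %*% lp$Wk; K <- sweep(K, 2, lp$bk, `+`)
    V <- H %*% lp$Wv; V <- sweep(V, 2, lp$bv, `+`)
    O <- matrix(0, B * L, d)
    att <- if (keep_cache) vector("list", B) else NULL
    for (b in seq_len(B)) {
      rb <- rows_of(b)
      ab <- if (keep_cache) vector("list", nh) else NULL
      for (h in seq_len(nh)) {
        cols <- ((h - 1) * dh + 1):(h * dh)
        Qh <- Q[rb, cols, drop = FALSE]; Kh <- K[rb, cols, drop = FALSE]
        S <- tcrossprod(Qh, Kh) / sqrt(dh)
        S[upper.tri(S)] <- neg                # causal mask
        A <- .softmax_rows(S)
        O[rb, cols] <- A %*% V[rb, cols, drop = FALSE]
        if (keep_cache) ab[[h]] <- A
      }
      if (keep_cache) att[[b]] <- ab
    }
    AO <- O %*% lp$Wo; AO <- sweep(AO, 2, lp$bo, `+`)
    drop1 <- NULL
    if (p_drop > 0) {
      drop1 <- matrix(stats::rbinom(length(AO), 1, 1 - p_drop), nrow(AO)) / (1 - p_drop)
      AO <- AO * drop1
    }
    X1 <- X + AO
    ln2 <- .layernorm_fwd(X1, lp$ln2_g, lp$ln2_b)
    F1pre <- ln2$Y %*% lp$W1; F1pre <- sweep(F1pre, 2, lp$b1, `+`)
    F1 <- pmax(F1pre, 0)
    F2 <- F1 %*% lp$W2; F2 <- sweep(F2, 2, lp$b2, `+`)
    drop2 <- NULL
    if (p_drop > 0) {
      drop2 <- matrix(stats::rbinom(length(F2), 1, 1 - p_drop), nrow(F2)) / (1 - p_drop)
      F2 <- F2 * drop2
    }
    Xout <- X1 + F2
    if (keep_cache)
      caches[[li]] <- list(Xin = X, ln1 = ln1, H = H, Q = Q, K = K, V = V,
                           O = O, att = att, drop1 = drop1, X1 = X1,
                           ln2 = ln2, F1 = F1, drop2 = drop2)
    X <- Xout
  }
  lnf <- .layernorm_fwd(X, params$lnf_g, params$lnf_b)
  logits <- lnf$Y %*% params$Wout
  logits <- sweep(logits, 2, params$bout, `+`)
  list(logits = logits, caches = caches, lnf = lnf, Xfinal = X, flat = flat,
       B = B, L = L)
}

# backward pass; dlogits: (B*L x V). returns gradient tree matching params.
.backward <- function(params, cfg, fwd, dlogits) {
  B <- fwd$B; L <- fwd$L; d <- cfg$d_model
  nh <- cfg$n_heads; dh <- d / nh
  rows_of <- function(b) ((b - 1) * L + 1):(b * L)
  g <- list(layers = vector("list", cfg$n_layers))
  g$Wout <- crossprod(fwd$lnf$Y, dlogits)
  g$bout <- colSums(dlogits)
  dlnfY <- tcrossprod(dlogits, params$Wout)
  lb <- .layernorm_bwd(dlnfY, fwd$lnf, params$lnf_g)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dX <- lb$dX
  for (li in rev(seq_len(cfg$n_layers))) {
    lp <- params$layers[[li]]
    ca <- fwd$caches[[li]]
    gl <- list()
    dF2 <- dX
    if (!is.null(ca$drop2)) dF2 <- dF2 * ca$drop2
    gl$W2 <- crossprod(ca$F1, dF2)
    gl$b2 <- colSums(dF2)
    dF1 <- tcrossprod(dF2, lp$W2)
    dF1[ca$F1 <= 0] <- 0
    gl$W1 <- crossprod(ca$ln2$Y, dF1)
    gl$b1 <- colSums(dF1)
    dln2Y <- tcrossprod(dF1, lp$W1)
    lb2 <- .layernorm_bwd(dln2Y, ca$ln2, lp$ln2_g)
    gl$ln2_g <- lb2$dg; gl$ln2_b <- lb2$db
    dX1 <- dX + lb2$dX
    dAO <- dX1
    if (!is.null(ca$drop1)) dAO <- dAO * ca$drop1
    gl$Wo <- crossprod(ca$O, dAO)
    gl$bo <- colSums(dAO)
    dO <- tcrossprod(dAO, lp$Wo)
    dQ <- matrix(0, B * L, d); dK <- matrix(0, B * L, d); dV <- matrix(0, B * L, d)
    for (b in seq_len(B)) {
      rb <- rows_of(b)
      for (h in seq_len(nh)) {
        cols <- ((h - 1) * dh + 1):(h * dh)
        A <- ca$att[[b]][[h]]
        dOh <- dO[rb, cols, drop = FALSE]
        Vh <- ca$V[rb, cols, drop = FALSE]
        dA <- tcrossprod(dOh, Vh)
        dV[rb, cols] <- crossprod(A, dOh)
        dS <- A * (dA - rowSums(dA * A))
        dS <- dS / sqrt(dh)
        Qh <- ca$Q[rb, cols, drop = FALSE]
        Kh <- ca$K[rb, cols, drop = FALSE]
        dQ[rb, cols] <- dS %*% Kh
        dK[rb, cols] <- crossprod(dS, Qh)
      }
    }
    gl$Wq <- crossprod(ca$H, dQ); gl$bq <- colSums(dQ)
    gl$Wk <- crossprod(ca$H, dK); gl$bk <- colSums(dK)
    gl$Wv <- crossprod(ca$H, dV); gl$bv <- colSums(dV)
    dH <- tcrossprod(dQ, lp$Wq) + tcrossprod(dK, lp$Wk) +
      tcrossprod(dV, lp$Wv)
    lb1 <- .layernorm_bwd(dH, ca$ln1, lp$ln1_g)
    gl$ln1_g <- lb1$dg; gl$ln1_b <- lb1$db
    dX <- dX1 + lb1$dX
    g$layers[[li]] <- gl
  }
  g$E <- matrix(0, nrow(params$E), d)
  # scatter-add embedding gradients
  agg <- rowsum(dX, group = fwd$flat)
  g$E[as.integer(rownames(agg)), ] <- agg
  g
}

#' Per-position next-token logits under the causal mask
#'
#' Evaluation-mode forward pass for a single id sequence; position t's logits
#' depend only on ids at positions <= t.
#'
#' @param state an \code{mf_model}.
#' @param ids integer vector of 0-based token ids.
#' @return \code{length(ids) x vocab} logit matrix.
#' @export
causal_forward <- function(state, ids) {
  if (any(ids < 0 | ids >= nrow(state$params$E)))
    stop("id out of range")
  fwd <- .forward(state$params, state$config,
                  matrix(as.integer(ids), nrow = 1), train = FALSE)
  fwd$logits
}

#' Masked sparse categorical cross-entropy
#'
#' Mean negative log-likelihood of the targets under
#' \code{softmax(logits)}, computed over non-PAD target positions only; PAD
#' positions are excluded from both the mean and (during training) the
#' gradient.
#'
#' @param logits \code{N x V} matrix.
#' @param targets integer vector (0-based ids) of length N.
#' @param pad_id id excluded from the loss (default 0).
#' @param mask optional logical vector overriding the PAD rule.
#' @return scalar loss.
#' @export
masked_ce_loss <- function(logits, targets, pad_id = 0L, mask = NULL) {
  if (is.null(mask)) mask <- targets != pad_id
  if (!any(mask)) stop("empty_loss: all positions are PAD")
  keep <- which(mask)
  lse <- apply(logits[keep, , drop = FALSE], 1, function(r) {
    m <- max(r); m + log(sum(exp(r - m)))
  })
  picked <- logits[cbind(keep, targets[keep] + 1L)]
  mean(lse - picked)
}

# batch loss + gradient wrt logits for training
.loss_and_dlogits <- function(logits, targets_flat, mask_flat) {
  keep <- which(mask_flat)
  P <- .softmax_rows(logits[keep, , drop = FALSE])
  idx <- cbind(seq_along(keep), targets_flat[keep] + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-300)))
  dP <- P
  dP[idx] <- dP[idx] - 1
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  dlogits[keep, ] <- dP / length(keep)
  list(loss = loss, dlogits = dlogits)
}

# --- optimizer -------------------------------------------------------------

.adam_new <- function(params) {
  zero_like <- function(x) if (is.list(x)) lapply(x, zero_like) else x * 0
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

.adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.98,
                       eps = 1e-9) {
  opt$t <- opt$t + 1L
  t <- opt$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      keys <- if (!is.null(names(p))) names(p) else seq_along(p)
      for (k in keys) {
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m2 <- beta1 * m + (1 - beta1) * g
    v2 <- beta2 * v + (1 - beta2) * g^2
    mhat <- m2 / (1 - beta1^t)
    vhat <- v2 / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
  }
  r <- walk(params, grads, opt$m, opt$v)
  list(params = r$p, opt = list(m = r$m, v = r$v, t = t))
}

# --- training --------------------------------------------------------------

.pad_batch <- function(id_list, pad_id = 0L) {
  L <- max(vapply(id_list, length, integer(1)))
  ids <- matrix(pad_id, length(id_list), L)
  for (i in seq_along(id_list))
    ids[i, seq_along(id_list[[i]])] <- id_list[[i]]
  ids
}

# loss mask per sequence position (for the shifted targets)
.target_mask <- function(seq, vocab, loss_span) {
  ids <- seq$assembled_ids
  n <- length(ids)
  m <- rep(TRUE, n - 1)            # mask over targets ids[2..n]
  if (loss_span == "target") {
    SEP <- special_id(vocab, "SEP")
    seps <- which(ids == SEP)
    first_target <- if (length(seps) > 0) max(seps) + 1L else 2L
    m[seq_len(n - 1) < (first_target - 1L)] <- FALSE
  }
  m
}

.epoch_pass <- function(params, cfg, batches, vocab, train, opt = NULL,
                        tcfg = NULL, d_model = NULL, base_step = 0L) {
  total <- 0; ntok <- 0
  step <- base_step
  for (batch in batches) {
    inp <- .pad_batch(lapply(batch, function(s) s$ids_in))
    tgt <- .pad_batch(lapply(batch, function(s) s$ids_tgt), pad_id = -1L)
    msk <- .pad_batch(lapply(batch, function(s) as.integer(s$mask)), pad_id = 0L)
    tgt_flat <- as.integer(t(tgt))
    msk_flat <- as.logical(as.integer(t(msk))) & tgt_flat >= 0L
    fwd <- .forward(params, cfg, inp, train = train, keep_cache = train)
    ld <- .loss_and_dlogits(fwd$logits, pmax(tgt_flat, 0L), msk_flat)
    nt <- sum(msk_flat)
    total <- total + ld$loss * nt; ntok <- ntok + nt
    if (train) {
      grads <- .backward(params, cfg, fwd, ld$dlogits)
      step <- step + 1L
      lr <- if (!is.na(tcfg$learning_rate)) tcfg$learning_rate
            else lr_schedule(step, d_model, tcfg$warmup_steps)
      st <- .adam_step(params, grads, opt, lr)
      params <- st$params; opt <- st$opt
    }
  }
  list(params = params, opt = opt, loss = total / max(ntok, 1), step = step)
}

.prep_record <- function(seq, vocab, loss_span) {
  ids <- seq$assembled_ids
  list(ids_in = ids[-length(ids)], ids_tgt = ids[-1],
       mask = .target_mask(seq, vocab, loss_span))
}

#' Pretrain the conditional Transformer
#'
#' Trains on the corpus with the masked cross-entropy objective, 90/10
#' train/validation split, inverse square-root warmup schedule (or constant
#' learning rate), topological-complexity curriculum (stages unlock when
#' validation improvement plateaus) and on-the-fly randomized-SMILES
#' augmentation. Fully deterministic under a fixed seed and single-threaded
#' BLAS.
#'
#' @param corpus an \code{mf_corpus}.
#' @param config an \code{mf_model_config}.
#' @param tcfg an \code{mf_train_config}.
#' @param verbose print per-epoch losses.
#' @return object of class \code{mf_model}: list(params, config, tcfg, vocab,
#'   history, best_val_loss).
#' @export
pretrain <- function(corpus, config, tcfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(corpus, "mf_corpus"))
  set.seed(tcfg$seed)
  params <- .init_params(config, vocab_size(corpus$vocab))
  .fit(params, corpus, config, tcfg, verbose = verbose, reseed = FALSE)
}

.fit <- function(params, corpus, config, tcfg, verbose = FALSE, reseed = TRUE) {
  vocab <- corpus$vocab
  seqs <- corpus$sequences
  maxlen <- max(vapply(seqs, function(s) length(s$assembled_ids), integer(1)))
  if (maxlen > config$max_positions)
    stop("max_positions (", config$max_positions, ") < longest assembled sequence (", maxlen, ")")
  if (reseed) set.seed(tcfg$seed)
  n <- length(seqs)
  n_val <- max(1L, round(tcfg$val_fraction * n))
  val_idx <- sample.int(n, n_val)
  train_idx <- setdiff(seq_len(n), val_idx)
  cur <- curriculum_order(seqs[train_idx], n_stages = tcfg$n_stages)
  train_sorted <- train_idx[cur$order]
  stage_of <- cur$stage
  n_stages_eff <- max(cur$stage)
  active_stage <- if (tcfg$curriculum) 1L else n_stages_eff
  val_recs <- lapply(seqs[val_idx], .prep_record, vocab = vocab,
                     loss_span = tcfg$loss_span)
  opt <- .adam_new(params)
  history <- list()
  best_val <- Inf; best_params <- params
  plateau <- 0L; no_improve <- 0L; step <- 0L; stage_epochs <- 0L
  for (epoch in seq_len(tcfg$max_epochs)) {
    act <- train_sorted[stage_of <= active_stage]
    act <- act[sample.int(length(act))]
    recs <- lapply(seqs[act], function(s) {
      s2 <- augment(s, p = tcfg$augment_p, vocab = vocab)
      .prep_record(s2, vocab, tcfg$loss_span)
    })
    nb <- ceiling(length(recs) / tcfg$batch_size)
    batches <- split(recs, rep(seq_len(nb), each = tcfg$batch_size,
                               length.out = length(recs)))
    tr <- .epoch_pass(params, config, batches, vocab, train = TRUE, opt = opt,
                      tcfg = tcfg, d_model = config$d_model, base_step = step)
    params <- tr$params; opt <- tr$opt; step <- tr$step
    vl <- .epoch_pass(params, config, list(val_recs), vocab, train = FALSE)
    history[[epoch]] <- data.frame(epoch = epoch, train_loss = tr$loss,
                                   val_loss = vl$loss, stage = active_stage)
    if (verbose)
      message(sprintf("epoch %3d stage %d train %.4f val %.4f", epoch,
                      active_stage, tr$loss, vl$loss))
    improved <- vl$loss < best_val - tcfg$stage_tol
    if (vl$loss < best_val) { best_val <- vl$loss; best_params <- params; no_improve <- 0L }
    else no_improve <- no_improve + 1L
    if (!improved) plateau <- plateau + 1L else plateau <- 0L
    stage_epochs <- stage_epochs + 1L
    if (active_stage < n_stages_eff &&
        (plateau >= tcfg$stage_patience || stage_epochs >= tcfg$stage_max_epochs)) {
      active_stage <- active_stage + 1L
      plateau <- 0L; stage_epochs <- 0L
    }
    if (is.finite(tcfg$patience) && active_stage >= n_stages_eff &&
        no_improve >= tcfg$patience) break
  }
  structure(list(params = params, best_params = best_params,
                 config = config, tcfg = tcfg, vocab = vocab,
                 history = do.call(rbind, history), best_val_loss = best_val,
                 train_idx = sort(train_idx), val_idx = sort(val_idx)),
            class = "mf_model")
}

#' Fine-tune a pretrained model on a target corpus
#'
#' Continues training with a constant reduced learning rate (default 5e-5)
#' and batch size 32, early-stopped on validation loss; the vocabulary is
#' frozen at pretraining (out-of-vocabulary target tokens are an error,
#' raised when the target corpus is built against the frozen vocabulary).
#' The returned state carries the best-validation-loss parameters.
#'
#' @param state a pretrained \code{mf_model}.
#' @param corpus an \code{mf_corpus} built with \code{vocab = state$vocab}.
#' @param tcfg an \code{mf_train_config}; defaults to the fine-tuning
#'   protocol (lr 5e-5, batch 32, no curriculum).
#' @return an \code{mf_model} with updated parameters and history.
#' @export
finetune <- function(state, corpus,
                     tcfg = train_config(learning_rate = 5e-5, batch_size = 32,
                                         curriculum = FALSE)) {
  stopifnot(inherits(state, "mf_model"), inherits(corpus, "mf_corpus"))
  if (!identical(corpus$vocab$hash, state$vocab$hash))
    stop("vocabulary mismatch: fine-tuning corpus must use the pretraining vocabulary")
  out <- .fit(state$params, corpus, state$config, tcfg)
  out$params <- out$best_params   # best-validation-loss checkpoint retained
  out
}

#' @export
print.mf_model <- function(x, ...) {
  cat("<transformer>", x$config$n_layers, "layers,", x$config$n_heads,
      "heads, d_model", x$config$d_model, "|", n_parameters(x), "parameters\n")
  if (!is.null(x$history))
    cat("  trained", nrow(x$history), "epochs; best val loss",
        signif(x$best_val_loss, 4), "\n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a directory holding the weights, the model and training
#' configurations (JSON), the vocabulary (JSON) and the epoch history (CSV).
#' Loading a checkpoint without its vocabulary file is an error.
#'
#' @param state an \code{mf_model}.
#' @param dir checkpoint directory.
#' @export
save_checkpoint <- function(state, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(state$params, file.path(dir, "weights.rds"))
  jsonlite::write_json(unclass(state$config), file.path(dir, "model_config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(state$tcfg), file.path(dir, "train_config.json"),
                       auto_unbox = TRUE, digits = NA)
  write_vocabulary(state$vocab, file.path(dir, "vocabulary.json"))
  if (!is.null(state$history))
    utils::write.csv(state$history, file.path(dir, "history.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @param dir checkpoint directory.
#' @export
load_checkpoint <- function(dir) {
  vp <- file.path(dir, "vocabulary.json")
  if (!file.exists(vp)) stop("checkpoint has no vocabulary.json")
  cfg <- jsonlite::read_json(file.path(dir, "model_config.json"), simplifyVector = TRUE)
  config <- do.call(model_config, cfg[c("n_layers", "n_heads", "d_model",
                                        "d_ffn", "dropout", "max_positions")])
  hist_path <- file.path(dir, "history.csv")
  structure(list(params = readRDS(file.path(dir, "weights.rds")),
                 config = config,
                 tcfg = jsonlite::read_json(file.path(dir, "train_config.json"),
                                            simplifyVector = TRUE),
                 vocab = read_vocabulary(vp),
                 history = if (file.exists(hist_path)) utils::read.csv(hist_path) else NULL,
                 best_val_loss = NA),
            class = "mf_model")
}
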