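# Transformer components: positional encodings, schedule, masked loss,
# causality, gradient correctness, determinism and the autoregressive
# factorization.

test_that("sinusoidal positional encodings match their closed form", {
  pe <- positional_encoding(16, 8)
  expect_equal(pe[1, seq(1, 8, 2)], rep(0, 4))   # sin(0)
  expect_equal(pe[1, seq(2, 8, 2)], rep(1, 4))   # cos(0)
  expect_true(all(pe >= -1 & pe <= 1))
  expect_equal(pe[2, 1], sin(1), tolerance = 1e-12)
  expect_equal(pe[2, 2], cos(1), tolerance = 1e-12)
  expect_equal(pe[5, 3], sin(4 / 10000^(2 / 8)), tolerance = 1e-12)
  expect_error(positional_encoding(4, 7), "even")
})

test_that("warmup schedule is continuous, rising then decaying", {
  d <- 512; w <- 4000
  steps <- 1:8000
  lr <- lr_schedule(steps, d, w)
  expect_true(all(diff(lr[1:w]) >= 0))
  expect_true(all(diff(lr[w:8000]) <= 0))
  # both branches agree at the warmup point
  expect_equal(lr_schedule(w, d, w), d^-0.5 * w^-0.5, tolerance = 1e-12)
  # plug-in arithmetic
  expect_equal(lr_schedule(100, d, w), 512^-0.5 * 100 * 4000^-1.5,
               tolerance = 1e-12)
  expect_error(lr_schedule(0, d, w))
})

test_that("masked cross-entropy has the right closed forms", {
  V <- 7; N <- 5
  uniform <- matrix(0, N, V)
  targets <- c(1L, 2L, 3L, 4L, 5L)
  expect_equal(masked_ce_loss(uniform, targets), log(V), tolerance = 1e-9)
  # near-one-hot logits -> loss ~ 0
  hot <- matrix(-1e4, N, V)
  hot[cbind(1:N, targets + 1L)] <- 1e4
  expect_equal(masked_ce_loss(hot, targets), 0, tolerance = 1e-9)
  # appending PAD positions leaves the loss unchanged
  with_pad <- rbind(uniform, matrix(rnorm(10 * V), 10, V))
  expect_equal(masked_ce_loss(with_pad, c(targets, rep(0L, 10))),
               masked_ce_loss(uniform, targets), tolerance = 1e-9)
  expect_error(masked_ce_loss(uniform, rep(0L, N)), "empty_loss")
})

test_that("causal masking: future tokens never change past logits", {
  st <- overfit_model()
  ids <- recon_corpus()$sequences[[1]]$assembled_ids
  base <- causal_forward(st, ids)
  set.seed(17)
  for (k in 1:25) {
    t <- sample(2:(length(ids) - 1), 1)
    ids2 <- ids
    ids2[(t + 1):length(ids2)] <- sample(0:(vocab_size(st$vocab) - 1),
                                         length(ids2) - t, replace = TRUE)
    pert <- causal_forward(st, ids2)
    expect_identical(pert[1:t, ], base[1:t, ])
  }
})

test_that("next-token distributions are normalized", {
  st <- overfit_model()
  ids <- recon_corpus()$sequences[[2]]$assembled_ids
  logits <- causal_forward(st, ids)
  p <- exp(logits - apply(logits, 1, max))
  p <- p / rowSums(p)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
})

test_that("analytic gradients agree with finite differences", {
  set.seed(99)
  cfg <- model_config(n_layers = 1, n_heads = 2, d_model = 8, d_ffn = 12,
                      dropout = 0, max_positions = 8)
  V <- 9
  params <- molforge:::.init_params(cfg, V)
  ids <- matrix(c(1L, 4L, 5L, 6L, 2L, 0L), nrow = 1)
  tgt <- as.integer(c(ids[-1], 0L))
  msk <- tgt != 0L
  lossfun <- function(p) {
    fwd <- molforge:::.forward(p, cfg, ids)
    molforge:::.loss_and_dlogits(fwd$logits, tgt, msk)$loss
  }
  fwd <- molforge:::.forward(params, cfg, ids, keep_cache = TRUE)
  ld <- molforge:::.loss_and_dlogits(fwd$logits, tgt, msk)
  g <- molforge:::.backward(params, cfg, fwd, ld$dlogits)
  eps <- 1e-5
  for (nm in c("Wq", "Wo", "W1", "W2", "ln1_g")) {
    x <- params$layers[[1]][[nm]]
    for (ii in sample(length(x), 3)) {
      p2 <- params; p2$layers[[1]][[nm]][ii] <- x[ii] + eps
      p3 <- params; p3$layers[[1]][[nm]][ii] <- x[ii] - eps
      num <- (lossfun(p2) - lossfun(p3)) / (2 * eps)
      expect_equal(g$layers[[1]][[nm]][ii], num, tolerance = 1e-3,
                   label = paste("grad", nm, ii))
    }
  }
  for (ii in sample(length(params$Wout), 3)) {
    p2 <- params; p2$Wout[ii] <- params$Wout[ii] + eps
    p3 <- params; p3$Wout[ii] <- params$Wout[ii] - eps
    expect_equal(g$Wout[ii], (lossfun(p2) - lossfun(p3)) / (2 * eps),
                 tolerance = 1e-3)
  }
})

test_that("sequence log-probability factorizes autoregressively", {
  st <- overfit_model()
  v <- st$vocab
  for (s in recon_corpus()$sequences[1:10]) {
    ids <- s$assembled_ids
    logits <- causal_forward(st, ids[-length(ids)])
    tgt <- ids[-1]
    lp <- 0
    for (t in seq_along(tgt)) {
      z <- logits[t, ]
      lp <- lp + (z[tgt[t] + 1] - (max(z) + log(sum(exp(z - max(z))))))
    }
    loss <- masked_ce_loss(logits, tgt, mask = rep(TRUE, length(tgt)))
    expect_equal(-lp, loss * length(tgt), tolerance = 1e-8)
  }
})

test_that("training runs are reproducible and the tiny model fits on CPU", {
  corpus <- recon_corpus()
  cfg <- tiny_config()
  tcfg <- train_config(max_epochs = 3, batch_size = 16, warmup_steps = 200,
                       augment_p = 0.1, patience = Inf, seed = 9)
  t0 <- Sys.time()
  a <- pretrain(corpus, cfg, tcfg)
  b <- pretrain(corpus, cfg, tcfg)
  expect_identical(a$history$train_loss, b$history$train_loss)
  expect_identical(a$history$val_loss, b$history$val_loss)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 300)
  # validation is a held-out 10%
  expect_length(a$val_idx, 5)
  expect_length(intersect(a$train_idx, a$val_idx), 0)
  expect_gt(n_parameters(a), 0)
})

test_that("fine-tuning warm-starts and keeps the frozen vocabulary", {
  st <- overfit_model()
  corpus <- recon_corpus()
  ft <- finetune(st, corpus,
                 train_config(learning_rate = 5e-5, batch_size = 32,
                              max_epochs = 4, patience = 2,
                              curriculum = FALSE, augment_p = 0, seed = 3,
                              loss_span = "target"))
  # fine-tuning the memorized model on its own corpus: low loss throughout,
  # and no runaway growth across epochs
  expect_lt(min(ft$history$val_loss), 1)
  expect_lte(min(ft$history$val_loss), ft$history$val_loss[1] + 0.05)
  # vocabulary mismatch is rejected
  other <- build_training_corpus(recon_raw()$smiles[1:20], make_toy_ontology(5),
                                 mode = "hybrid")
  expect_error(finetune(st, other), "vocabulary mismatch")
})

test_that("checkpoints round-trip through disk", {
  st <- overfit_model()
  d <- tempfile()
  save_checkpoint(st, d)
  st2 <- load_checkpoint(d)
  expect_identical(st2$vocab$tokens, st$vocab$tokens)
  expect_equal(st2$params$E, st$params$E)
  ids <- recon_corpus()$sequences[[1]]$assembled_ids
  expect_equal(causal_forward(st2, ids), causal_forward(st, ids))
  # vocabulary file is mandatory
  file.remove(file.path(d, "vocabulary.json"))
  expect_error(load_checkpoint(d), "vocabulary")
})
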