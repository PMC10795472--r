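mk_event_with_extrema <- function(extrema_t, extrema_c, rel = 10) {
  opm <- structure(list(I0 = 100, sigma0 = 1, fit = list()),
                   class = "open_pore_model")
  e <- porePTM:::blockade_event(0L, 100L, rep(rel, 100), 1e4)
  e <- compute_features(e, opm)
  e$extrema <- cbind(t_s = extrema_t, rel_current_pct = extrema_c,
                     kind = rep_len(c(-1, 1), length(extrema_t)))
  e
}

test_that("sequence preparation rescales, truncates tail and pads sentinels", {
  e <- mk_event_with_extrema(0.001, 9.0)
  s <- prepare_sequences(list(e), rescale = c(f_t = 1000, f_c = 0.01))
  expect_equal(s[[1]], matrix(c(1.0, 0.09), 1, 2,
                              dimnames = list(NULL, c("t", "c"))))

  # identity rescale
  s1 <- prepare_sequences(list(e), rescale = c(f_t = 1, f_c = 1))
  expect_equal(unname(s1[[1]]), cbind(0.001, 9.0))

  # empty extrema -> sentinel (0, rel_current_pct), rescaled
  e0 <- mk_event_with_extrema(numeric(0), numeric(0), rel = 12)
  s0 <- prepare_sequences(list(e0), rescale = c(f_t = 1000, f_c = 0.01))
  expect_equal(unname(s0[[1]]), cbind(0, 0.12))
  expect_false(attr(s0, "truncated"))

  # tail truncation keeps the head and flags the sequence
  elong <- mk_event_with_extrema(seq(1e-4, 5e-3, by = 1e-4),
                                 rep(c(8, 12), 25))
  sl <- prepare_sequences(list(elong), max_len = 10)
  expect_equal(nrow(sl[[1]]), 10)
  expect_true(attr(sl, "truncated"))
  expect_equal(unname(sl[[1]][1, 1]), 1e-4 * 1000)  # head retained

  # round trip through the inverse factors recovers the originals
  set.seed(40)
  evs <- lapply(1:20, function(i) {
    k <- sample(1:8, 1)
    mk_event_with_extrema(sort(runif(k, 0, 0.01)), runif(k, 5, 35))
  })
  ss <- prepare_sequences(evs, rescale = c(f_t = 1e3, f_c = 1e-2))
  for (i in seq_along(evs)) {
    back <- cbind(ss[[i]][, 1] / 1e3, ss[[i]][, 2] / 1e-2)
    expect_equal(back, evs[[i]]$extrema[, 1:2, drop = FALSE],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("the 3-part loss matches analytic values and the scalar oracle", {
  # perfect one-hot prediction with full confidence: all parts vanish
  probs <- diag(3)[c(1, 2, 3), ]
  lp <- three_part_loss(probs, c(1, 1, 1), 1:3)
  expect_equal(lp$L_cls, 0, tolerance = 1e-10)
  expect_equal(lp$L_assess, 0, tolerance = 1e-10)
  expect_equal(lp$L_reinforce, 0, tolerance = 1e-10)

  # uniform probabilities over 8 classes: L_cls = ln 8
  u <- matrix(1 / 8, 5, 8)
  expect_equal(three_part_loss(u, runif(5), sample(1:8, 5, TRUE))$L_cls,
               log(8), tolerance = 1e-12)

  # random batches agree with the independent per-sample computation
  set.seed(50)
  for (r in 1:5) {
    n <- 16; K <- sample(2:8, 1)
    p <- matrix(rgamma(n * K, 1), n, K); p <- p / rowSums(p)
    a <- runif(n); y <- sample(1:K, n, TRUE)
    got <- three_part_loss(p, a, y)
    want <- oracle_three_part_loss(p, a, y)
    expect_equal(got$L_cls, want$L_cls, tolerance = 1e-9)
    expect_equal(got$L_assess, want$L_assess, tolerance = 1e-9)
    expect_equal(got$L_reinforce, want$L_reinforce, tolerance = 1e-9)
    expect_equal(got$L_total,
                 got$L_cls + got$L_assess + got$L_reinforce)
  }

  # zero probability on the true class is clamped with a warning
  p <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_warning(lp <- three_part_loss(p, c(0.5, 0.5), c(2L, 1L)), "clamped")
  expect_true(is.finite(lp$L_total))
})

test_that("network gradients agree with finite differences", {
  # tiny networks so the check is cheap; exercises LSTM + both MLP heads
  set.seed(60)
  B <- 5; Tn <- 4
  X <- array(rnorm(B * Tn * 2), c(B, Tn, 2))
  mask <- matrix(1, B, Tn); mask[1, 3:4] <- 0; mask[2, 4] <- 0
  y <- sample(1:3, B, TRUE)
  net <- list(lstm = porePTM:::nn_init_lstm(2L, 5L),
              mlp = porePTM:::nn_init_mlp(5L, c(6L, 6L), 3L), act = "relu")
  loss_of <- function(net) {
    out <- porePTM:::nn_net_forward(net, X, mask)$out
    p <- porePTM:::softmax_rows(out)
    -mean(log(p[cbind(seq_len(B), y)]))
  }
  fwd <- porePTM:::nn_net_forward(net, X, mask, cache = TRUE)
  p <- porePTM:::softmax_rows(fwd$out)
  Y <- matrix(0, B, 3); Y[cbind(seq_len(B), y)] <- 1
  g <- porePTM:::nn_net_backward(net, fwd, (p - Y) / B)
  flat <- porePTM:::nn_flatten(net)
  eps <- 1e-6
  for (k in seq_along(flat)) {
    for (i in sample(seq_along(flat[[k]]), min(5, length(flat[[k]])))) {
      f2 <- flat
      f2[[k]][i] <- f2[[k]][i] + eps
      up <- loss_of(porePTM:::nn_unflatten(net, f2))
      f2[[k]][i] <- f2[[k]][i] - 2 * eps
      dn <- loss_of(porePTM:::nn_unflatten(net, f2))
      expect_equal(g[[k]][i], (up - dn) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("prediction is deterministic, normalized and padding-invariant", {
  set.seed(70)
  le <- make_labeled_events(sim_config(duration_s = 30, capture_rate_Hz = 5,
                                       seed = 71), separable_signatures())
  seqs <- prepare_sequences(le$events)
  cfg <- classifier_config(state_size = 16L, hidden = c(32L, 32L),
                           ass_state_size = 8L, ass_hidden = c(16L),
                           epochs = 3, batch_size = 64, seed = 7)
  fit <- pore_classifier(seqs, le$labels, cfg, min_class_train = 20)

  p1 <- predict(fit, seqs)
  p2 <- predict(fit, seqs)
  expect_identical(p1, p2)
  pm <- as.matrix(p1[, grep("^prob_", names(p1))])
  expect_true(all(abs(rowSums(pm) - 1) < 1e-6))
  expect_true(all(p1$assessment_score >= 0 & p1$assessment_score <= 1))

  # padding invariance: predicting alone vs inside a batch of longer
  # sequences gives the same probabilities
  lens <- vapply(seqs, nrow, integer(1))
  short <- which.min(lens); long <- which.max(lens)
  solo <- predict(fit, seqs[short])
  pair <- predict(fit, seqs[c(short, long)])
  expect_equal(as.numeric(solo[1, -1]), as.numeric(pair[1, -1]),
               tolerance = 1e-10)

  expect_error(predict(fit, list(matrix(0, 2, 3))), "2 feature columns")
  s_other <- prepare_sequences(le$events, rescale = c(f_t = 1, f_c = 1))
  expect_error(predict(fit, s_other), "rescale")
})

test_that("joint training separates threshold-separable classes", {
  # ~600 events of two classes with disjoint relative-current ranges;
  # a rel-current threshold rule is a perfect oracle on these data
  le <- make_labeled_events(sim_config(duration_s = 130, capture_rate_Hz = 5,
                                       seed = 80), separable_signatures())
  seqs <- prepare_sequences(le$events)
  fit <- pore_classifier(seqs, le$labels,
                         classifier_config(state_size = 32L,
                                           hidden = rep(64L, 3),
                                           batch_size = 64L,
                                           epochs = 30, seed = 81),
                         min_class_train = 50)
  # training loss decreased
  expect_lt(fit$log$L_total[nrow(fit$log)], fit$log$L_total[1])
  # validation accuracy at 100% selection
  va <- chronological_split(seq_along(seqs))$validation
  pred <- predict(fit, seqs[va])
  acc <- mean(as.character(pred$prediction) == le$labels[va])
  expect_gte(acc, 0.95)
  # agreement with the threshold oracle
  rc <- vapply(le$events[va], `[[`, numeric(1), "rel_current_pct")
  oracle <- ifelse(rc < 18, "A", "B")
  expect_gte(mean(as.character(pred$prediction) == oracle), 0.95)
  # assessment scores rank correctness better than chance on training data
  pall <- predict(fit, seqs)
  correct <- as.character(pall$prediction) == le$labels
  if (any(!correct)) {
    expect_gt(oracle_auroc(pall$assessment_score, correct), 0.5)
  }
})

test_that("training guards reject degenerate inputs", {
  le <- make_labeled_events(sim_config(duration_s = 10, capture_rate_Hz = 4,
                                       seed = 90), separable_signatures())
  seqs <- prepare_sequences(le$events)
  expect_error(pore_classifier(seqs, rep("A", length(seqs))), "2 classes")
  expect_error(pore_classifier(seqs, le$labels,
                               classifier_config(epochs = 1),
                               min_class_train = 1e6), "fewer than")
})

test_that("confidence selection keeps the top-scored events, stably", {
  pr <- data.frame(prediction = factor(rep("A", 10)),
                   assessment_score = c(0.9, 0.5, 0.5, 0.8, 0.1,
                                        0.95, 0.5, 0.3, 0.7, 0.2))
  sel <- select_by_confidence(pr, 100)
  expect_equal(nrow(sel$selected), 10)  # identity at 100%

  sel <- select_by_confidence(pr, 50)
  expect_equal(sel$selected$index, c(1, 2, 4, 6, 9))  # tie at 0.5 -> earliest
  expect_equal(sel$threshold, 0.5)

  # selected size is exactly ceiling(p * N / 100)
  for (p in c(1, 10, 33, 75)) {
    expect_equal(nrow(select_by_confidence(pr, p)$selected),
                 ceiling(p / 100 * 10))
  }
  expect_error(select_by_confidence(pr[0, ], 50), "empty")
  expect_error(select_by_confidence(pr, 0), "0, 100")
})
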