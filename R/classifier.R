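# Event classification with a rejection option: a recurrent reader over each
# event's local-extrema sequence feeds a feed-forward classifier (softmax over
# peptide classes), while a second, smaller recurrent network — the assessment
# network — predicts whether the classifier's call is correct. Both are
# trained jointly on a 3-part loss; the assessment score later gates which
# events are kept (the selection percentage).

#' Prepare extrema sequences for the classifier
#'
#' Converts events' local-extrema lists into rescaled (time, relative
#' current) sequences. Features are rescaled by fixed factors so both input
#' channels are of order one, which shortens training: times (s) by `f_t`
#' and relative currents (percent) by `f_c`. Sequences longer than `max_len`
#' are truncated at the tail (the head of the sequence is always kept) and
#' flagged; events with no extrema receive a single sentinel pair
#' `(0, rel_current_pct)` so every event remains classifiable.
#'
#' @param events List of `blockade_event`s with extrema computed, or a list
#'   of bare extrema matrices with columns `t_s` and `rel_current_pct`.
#' @param rescale Named vector `c(f_t = ..., f_c = ...)`; defaults
#'   `f_t = 1e3` (seconds to millisecond scale) and `f_c = 1e-2` (percent to
#'   unit scale).
#' @param max_len Maximum sequence length (default 32).
#' @return List of L x 2 matrices (class `extrema_sequences`) with
#'   attributes `rescale`, `max_len` and logical `truncated` per sequence.
#' @export
prepare_sequences <- function(events, rescale = c(f_t = 1e3, f_c = 1e-2),
                              max_len = 32L) {
  stopifnot(is.list(events), all(c("f_t", "f_c") %in% names(rescale)),
            max_len >= 1L)
  truncated <- logical(length(events))
  seqs <- vector("list", length(events))
  for (i in seq_along(events)) {
    e <- events[[i]]
    if (inherits(e, "blockade_event")) {
      if (is.null(e$extrema)) {
        stop("event ", i, " has no extrema; run extract_local_extrema() first")
      }
      ex <- e$extrema
      fallback_c <- e$rel_current_pct
    } else {
      ex <- e
      fallback_c <- if (nrow(ex)) ex[1, "rel_current_pct"] else 0
    }
    if (nrow(ex) == 0L) {
      m <- matrix(c(0, fallback_c), 1, 2)
    } else {
      m <- cbind(as.numeric(ex[, "t_s"]), as.numeric(ex[, "rel_current_pct"]))
      if (nrow(m) > max_len) {
        m <- m[seq_len(max_len), , drop = FALSE]
        truncated[i] <- TRUE
      }
    }
    m[, 1] <- m[, 1] * rescale[["f_t"]]
    m[, 2] <- m[, 2] * rescale[["f_c"]]
    dimnames(m) <- list(NULL, c("t", "c"))
    seqs[[i]] <- m
  }
  structure(seqs, rescale = rescale, max_len = as.integer(max_len),
            truncated = truncated, class = c("extrema_sequences", "list"))
}

#' @export
`[.extrema_sequences` <- function(x, i) {
  structure(unclass(x)[i], rescale = attr(x, "rescale"),
            max_len = attr(x, "max_len"),
            truncated = attr(x, "truncated")[i],
            class = c("extrema_sequences", "list"))
}

#' The 3-part training loss
#'
#' The joint objective of the classifier and the assessment network:
#' \describe{
#'   \item{`L_cls`}{full classification cross-entropy, mean of
#'     `-log p_true` over the batch;}
#'   \item{`L_assess`}{binary cross-entropy between the assessment score and
#'     the actual prediction validity (1 if the classifier's argmax equals
#'     the true label, else 0);}
#'   \item{`L_reinforce`}{the classification cross-entropy of each event
#'     scaled by its assessment score — events the assessor trusts weigh
#'     more;}
#' }
#' with `L_total` their sum. Probabilities are clamped at `eps` before
#' taking logs.
#'
#' @param probs N x K matrix of class probabilities (rows sum to 1).
#' @param assessment_scores Numeric vector in `[0, 1]`, length N.
#' @param true_labels Integer class indices (1..K) or factor, length N.
#' @param eps Probability clamp (default 1e-12).
#' @return Object of class `loss_parts`: list with `L_cls`, `L_assess`,
#'   `L_reinforce`, `L_total`.
#' @examples
#' p <- matrix(1 / 8, 2, 8)
#' three_part_loss(p, c(0.5, 0.5), c(1L, 2L))$L_cls  # log(8)
#' @export
three_part_loss <- function(probs, assessment_scores, true_labels,
                            eps = 1e-12) {
  probs <- as.matrix(probs)
  n <- nrow(probs)
  if (is.factor(true_labels)) true_labels <- as.integer(true_labels)
  stopifnot(length(assessment_scores) == n, length(true_labels) == n,
            all(true_labels >= 1), all(true_labels <= ncol(probs)))
  p_true <- probs[cbind(seq_len(n), true_labels)]
  if (any(p_true < eps)) {
    warning("true-class probabilities below ", eps, " were clamped")
    p_true <- pmax(p_true, eps)
  }
  nll <- -log(p_true)
  v <- as.numeric(max.col(probs, ties.method = "first") == true_labels)
  a <- pmin(pmax(assessment_scores, eps), 1 - eps)
  L_cls <- mean(nll)
  L_assess <- mean(-(v * log(a) + (1 - v) * log(1 - a)))
  L_reinforce <- mean(assessment_scores * nll)
  structure(list(L_cls = L_cls, L_assess = L_assess,
                 L_reinforce = L_reinforce,
                 L_total = L_cls + L_assess + L_reinforce),
            class = "loss_parts")
}

#' @export
print.loss_parts <- function(x, ...) {
  cat(sprintf("loss: total %.4f = cls %.4f + assess %.4f + reinforce %.4f\n",
              x$L_total, x$L_cls, x$L_assess, x$L_reinforce))
  invisible(x)
}

#' Classifier configuration
#'
#' Architecture defaults: the classifier reads each sequence with an LSTM of
#' state size 128 (no activation on the readout) followed by 6 fully
#' connected hidden layers of width 256 with ReLU and a softmax output over
#' the classes; the assessment network is a scaled-down copy with LSTM state
#' 32, 3 hidden layers of width 64 with tanh, and a single sigmoid output.
#' Training defaults (adaptive-moment optimizer, learning rate 1e-3, batch
#' 256, up to 50 epochs with early stopping on validation loss) are the
#' package's own choices.
#'
#' @param state_size,hidden Classifier LSTM state size and hidden widths.
#' @param ass_state_size,ass_hidden Assessment-network sizes.
#' @param lr Learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement); `Inf` disables early stopping.
#' @param seed Integer seed controlling initialization and batch order.
#' @param detach_assessment If `TRUE` (default) the reinforcement loss
#'   treats the assessment score as a constant scale; if `FALSE` it also
#'   back-propagates into the assessment network.
#' @param class_weights Optional named per-class weights on the
#'   classification loss (default: unweighted).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(state_size = 128L, hidden = rep(256L, 6),
                              ass_state_size = 32L, ass_hidden = rep(64L, 3),
                              lr = 1e-3, batch_size = 256L, epochs = 50L,
                              patience = 10L, seed = 1L,
                              detach_assessment = TRUE, class_weights = NULL) {
  structure(list(state_size = state_size, hidden = hidden,
                 ass_state_size = ass_state_size, ass_hidden = ass_hidden,
                 lr = lr, batch_size = batch_size, epochs = epochs,
                 patience = patience, seed = seed,
                 detach_assessment = detach_assessment,
                 class_weights = class_weights),
            class = "classifier_config")
}

pad_batch <- function(seqs) {
  B <- length(seqs)
  Tn <- max(vapply(seqs, nrow, integer(1)))
  X <- array(0, c(B, Tn, 2))
  mask <- matrix(0, B, Tn)
  for (i in seq_len(B)) {
    L <- nrow(seqs[[i]])
    X[i, seq_len(L), ] <- seqs[[i]]
    mask[i, seq_len(L)] <- 1
  }
  list(X = X, mask = mask)
}

#' Train the joint classifier + assessment model
#'
#' Fits the event classifier and its assessment network jointly on the
#' 3-part loss (see [three_part_loss()]). The validity targets for the
#' assessment network are recomputed from the classifier's current argmax at
#' every step. Events are split chronologically — the first `split` fraction
#' (in acquisition order) trains, the rest validates — mirroring how
#' single-channel measurements are benchmarked. With a fixed seed the
#' training log is reproducible.
#'
#' @param sequences An `extrema_sequences` object (see
#'   [prepare_sequences()]), in acquisition order.
#' @param labels Factor (or coercible) of true classes, one per sequence;
#'   at least 2 classes.
#' @param config A [classifier_config()].
#' @param split Fraction of events used for training (default 0.75,
#'   chronological).
#' @param min_class_train Minimum training events required per class
#'   (default 100; lower it for toy runs).
#' @param verbose Print per-epoch progress.
#' @return An object of class `pore_classifier` with the trained networks,
#'   class labels, rescale factors and a per-epoch training `log`
#'   (data frame: losses and validation accuracy).
#' @seealso [predict.pore_classifier()], [select_by_confidence()]
#' @export
pore_classifier <- function(sequences, labels, config = classifier_config(),
                            split = 0.75, min_class_train = 100L,
                            verbose = FALSE) {
  stopifnot(inherits(sequences, "extrema_sequences"))
  labels <- factor(labels)
  n <- length(sequences)
  stopifnot(length(labels) == n, n >= 4L)
  K <- nlevels(labels)
  if (K < 2L) stop("need at least 2 classes, got ", K)
  y <- as.integer(labels)

  sp <- chronological_split(seq_len(n), frac = split)
  tr_idx <- sp$train; va_idx <- sp$validation
  tr_counts <- table(labels[tr_idx])
  if (any(tr_counts < min_class_train)) {
    stop("class(es) with fewer than ", min_class_train, " training events: ",
         paste(names(tr_counts)[tr_counts < min_class_train], collapse = ", "))
  }

  w_cls <- rep(1, K)
  if (!is.null(config$class_weights)) {
    w_cls <- config$class_weights[levels(labels)]
    if (anyNA(w_cls)) stop("class_weights must name every class")
  }

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)

  cls <- list(lstm = nn_init_lstm(2L, config$state_size),
              mlp = nn_init_mlp(config$state_size, config$hidden, K),
              act = "relu")
  ass <- list(lstm = nn_init_lstm(2L, config$ass_state_size),
              mlp = nn_init_mlp(config$ass_state_size, config$ass_hidden, 1L),
              act = "tanh")
  opt_c <- adam_init(nn_flatten(cls))
  opt_a <- adam_init(nn_flatten(ass))

  log_rows <- list()
  best <- list(val_loss = Inf, cls = cls, ass = ass, epoch = 0L)
  stale <- 0L
  for (epoch in seq_len(config$epochs)) {
    perm <- sample(tr_idx)
    nb <- ceiling(length(perm) / config$batch_size)
    acc_parts <- c(L_cls = 0, L_assess = 0, L_reinforce = 0, L_total = 0)
    for (b in seq_len(nb)) {
      bi <- perm[((b - 1L) * config$batch_size + 1L):
                   min(b * config$batch_size, length(perm))]
      batch <- pad_batch(unclass(sequences)[bi])
      yb <- y[bi]; B <- length(bi)

      fc <- nn_net_forward(cls, batch$X, batch$mask, cache = TRUE)
      fa <- nn_net_forward(ass, batch$X, batch$mask, cache = TRUE)
      p <- softmax_rows(fc$out)
      a <- sigmoid(fa$out[, 1])

      lp <- suppressWarnings(three_part_loss(p, a, yb))  # clamp is routine here
      acc_parts <- acc_parts + unlist(lp) * B
      if (!is.finite(lp$L_total)) {
        stop("non-finite training loss at epoch ", epoch, ", batch ", b,
             " (L_cls = ", lp$L_cls, ", L_assess = ", lp$L_assess, ")")
      }

      Y <- matrix(0, B, K); Y[cbind(seq_len(B), yb)] <- 1
      wrow <- w_cls[yb]
      # classifier gradient: (1 + a) * CE  (reinforcement scales CE by a)
      dlogit_c <- ((1 + a) * wrow / B) * (p - Y)
      # assessor gradient: BCE against current validity
      v <- as.numeric(max.col(p, ties.method = "first") == yb)
      dlogit_a <- matrix((a - v) / B, B, 1)
      if (!config$detach_assessment) {
        nll <- -log(pmax(p[cbind(seq_len(B), yb)], 1e-12))
        dlogit_a <- dlogit_a + matrix(a * (1 - a) * nll / B, B, 1)
      }
      gc_ <- nn_net_backward(cls, fc, dlogit_c)
      ga_ <- nn_net_backward(ass, fa, dlogit_a)
      up <- adam_step(opt_c, nn_flatten(cls), gc_, lr = config$lr)
      opt_c <- up$state; cls <- nn_unflatten(cls, up$flat)
      up <- adam_step(opt_a, nn_flatten(ass), ga_, lr = config$lr)
      opt_a <- up$state; ass <- nn_unflatten(ass, up$flat)
    }
    acc_parts <- acc_parts / length(tr_idx)

    val <- classifier_forward(cls, ass, unclass(sequences)[va_idx])
    vl <- suppressWarnings(three_part_loss(val$probs, val$assessment, y[va_idx]))
    val_acc <- mean(val$pred == y[va_idx])
    log_rows[[epoch]] <- data.frame(epoch = epoch, t(acc_parts),
                                    val_loss = vl$L_total,
                                    val_accuracy = val_acc)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  val acc %.3f",
                      epoch, acc_parts["L_total"], vl$L_total, val_acc))
    }
    if (vl$L_total < best$val_loss - 1e-6) {
      best <- list(val_loss = vl$L_total, cls = cls, ass = ass, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }

  structure(list(cls = best$cls, ass = best$ass, classes = levels(labels),
                 rescale = attr(sequences, "rescale"),
                 max_len = attr(sequences, "max_len"),
                 config = config, best_epoch = best$epoch,
                 log = do.call(rbind, log_rows),
                 n_train = length(tr_idx), n_validation = length(va_idx)),
            class = "pore_classifier")
}

# chunked forward pass over a plain list of sequences
classifier_forward <- function(cls, ass, seqs, chunk = 512L) {
  n <- length(seqs)
  K <- ncol(cls$mlp[[length(cls$mlp)]]$W)
  probs <- matrix(NA_real_, n, K)
  a <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    ii <- s:min(s + chunk - 1L, n)
    batch <- pad_batch(seqs[ii])
    probs[ii, ] <- softmax_rows(nn_net_forward(cls, batch$X, batch$mask)$out)
    a[ii] <- sigmoid(nn_net_forward(ass, batch$X, batch$mask)$out[, 1])
  }
  list(probs = probs, assessment = a,
       pred = max.col(probs, ties.method = "first"))
}

#' Predict classes and assessment scores for events
#'
#' Deterministic given fixed weights: class probabilities (softmax),
#' predicted class (argmax) and the assessment score in `[0, 1]` per event.
#'
#' @param object A trained [pore_classifier()].
#' @param sequences An `extrema_sequences` object prepared with the same
#'   rescale factors the model was trained with.
#' @param ... Unused.
#' @return A data frame of class `pore_predictions`: `prediction` (factor),
#'   `assessment_score`, and one `prob_<class>` column per class.
#' @export
predict.pore_classifier <- function(object, sequences, ...) {
  stopifnot(inherits(sequences, "extrema_sequences") || is.list(sequences))
  if (inherits(sequences, "extrema_sequences")) {
    rs <- attr(sequences, "rescale")
    if (!isTRUE(all.equal(rs, object$rescale))) {
      stop("sequences were prepared with different rescale factors ",
           "than the model was trained with")
    }
  }
  bad <- which(vapply(sequences, function(m) ncol(m) != 2L, logical(1)))
  if (length(bad)) stop("sequence ", bad[1], " does not have 2 feature columns")
  fw <- classifier_forward(object$cls, object$ass, unclass(sequences))
  out <- data.frame(prediction = factor(object$classes[fw$pred],
                                        levels = object$classes),
                    assessment_score = fw$assessment)
  pm <- as.data.frame(fw$probs)
  names(pm) <- paste0("prob_", object$classes)
  out <- cbind(out, pm)
  class(out) <- c("pore_predictions", "data.frame")
  out
}

#' @export
print.pore_classifier <- function(x, ...) {
  cat(sprintf("<pore_classifier> %d classes: %s\n", length(x$classes),
              paste(x$classes, collapse = ", ")))
  cat(sprintf("  trained %d epochs (best %d), %d train / %d validation events\n",
              nrow(x$log), x$best_epoch, x$n_train, x$n_validation))
  cat(sprintf("  final validation accuracy %.3f (100%% selection)\n",
              x$log$val_accuracy[x$best_epoch]))
  invisible(x)
}

#' @export
summary.pore_classifier <- function(object, ...) {
  npar <- function(net) sum(vapply(nn_flatten(net), length, numeric(1)))
  cat(sprintf("Joint classifier + assessment model (%d + %d parameters)\n",
              npar(object$cls), npar(object$ass)))
  print(object)
  cat("\nTraining log (last 5 epochs):\n")
  print(utils::tail(object$log, 5), row.names = FALSE)
  invisible(object)
}

#' @export
plot.pore_classifier <- function(x, ...) {
  lg <- x$log
  graphics::par(mfrow = c(1, 2))
  graphics::plot(lg$epoch, lg$L_total, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "3-part loss", ...)
  graphics::lines(lg$epoch, lg$val_loss, lty = 2)
  graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  graphics::plot(lg$epoch, lg$val_accuracy, type = "l", xlab = "epoch",
                 ylab = "validation accuracy", ylim = c(0, 1),
                 main = "accuracy (100% selection)", ...)
  invisible(x)
}

#' Select events by prediction confidence
#'
#' Implements the selection percentage: the `ceiling(selection_pct / 100 *
#' N)` events with the highest assessment scores are kept, ties broken by
#' event order (stable). Trades coverage for accuracy.
#'
#' @param predictions A `pore_predictions` data frame (or any data frame
#'   with an `assessment_score` column).
#' @param selection_pct Percentage in (0, 100].
#' @return List with `selected` (the retained rows, original order, with an
#'   `index` column), `threshold` (lowest retained score) and `n_total`.
#' @export
select_by_confidence <- function(predictions, selection_pct) {
  stopifnot(is.data.frame(predictions))
  n <- nrow(predictions)
  if (n == 0L) stop("empty prediction set")
  if (selection_pct <= 0 || selection_pct > 100) {
    stop("selection_pct must lie in (0, 100]")
  }
  k <- ceiling(selection_pct / 100 * n)
  sc <- predictions$assessment_score
  ord <- order(-sc, seq_len(n))  # stable: ties by event order
  keep <- sort(ord[seq_len(k)])
  sel <- predictions[keep, , drop = FALSE]
  sel$index <- keep
  list(selected = sel, threshold = min(sc[keep]), n_total = n)
}
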