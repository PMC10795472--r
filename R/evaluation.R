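# Evaluation protocols: normalized confusion matrices, accuracy versus
# selection percentage, mixture assignment, and the chronological
# train/validation split.

#' Chronological train/validation split
#'
#' Splits by acquisition order, never randomly: the first `frac` of the
#' events (floor) trains, the remainder validates.
#'
#' @param events A vector, list or data frame of events in acquisition
#'   order; at least 4 elements/rows.
#' @param frac Training fraction (default 0.75).
#' @return List with `train` and `validation` holding the corresponding
#'   subsets (indices if `events` is `seq_len(n)`).
#' @examples
#' chronological_split(1:4)        # 3 train, 1 validation
#' lengths(chronological_split(seq_len(519000)))
#' @export
chronological_split <- function(events, frac = 0.75) {
  n <- if (is.data.frame(events)) nrow(events) else length(events)
  if (n < 4L) stop("need at least 4 events to split, got ", n)
  stopifnot(frac > 0, frac < 1)
  n_train <- floor(frac * n)
  take <- function(i) if (is.data.frame(events)) events[i, , drop = FALSE] else events[i]
  list(train = take(seq_len(n_train)),
       validation = take((n_train + 1L):n))
}

as_label_vector <- function(predictions) {
  if (is.data.frame(predictions)) {
    if (!"prediction" %in% names(predictions)) {
      stop("predictions data frame must have a `prediction` column")
    }
    predictions$prediction
  } else predictions
}

#' Normalized confusion matrix
#'
#' Counts are tallied and normalized per actual class: columns are the
#' actual classes, rows the assigned classes, and each column of the
#' normalized matrix sums to 100 percent.
#'
#' @param predictions A `pore_predictions` data frame or a vector of
#'   assigned labels.
#' @param true_labels Vector of actual labels, aligned with `predictions`.
#' @param classes Class labels defining the matrix order; defaults to the
#'   prediction factor levels. True labels outside this set are an error.
#' @return Object of class `confusion_matrix`: list with `counts` and
#'   `percent` matrices (rows = assigned, columns = actual) and `accuracy`.
#' @export
confusion_matrix <- function(predictions, true_labels, classes = NULL) {
  pred <- as_label_vector(predictions)
  stopifnot(length(pred) == length(true_labels))
  if (is.null(classes)) {
    classes <- if (is.factor(pred)) levels(pred) else sort(unique(c(as.character(pred))))
  }
  bad <- setdiff(unique(as.character(true_labels)), classes)
  if (length(bad)) {
    stop("true label(s) outside the model's classes: ",
         paste(bad, collapse = ", "))
  }
  pred <- factor(as.character(pred), levels = classes)
  truth <- factor(as.character(true_labels), levels = classes)
  counts <- table(assigned = pred, actual = truth)
  colsum <- colSums(counts)
  percent <- sweep(counts, 2, pmax(colsum, 1L), "/") * 100
  structure(list(classes = classes, counts = unclass(counts),
                 percent = unclass(percent),
                 accuracy = sum(diag(counts)) / max(sum(counts), 1L)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 1, ...) {
  cat("Confusion matrix (% of actual class; columns = actual, rows = assigned)\n")
  print(round(x$percent, digits))
  cat(sprintf("overall accuracy: %.1f%%\n", 100 * x$accuracy))
  invisible(x)
}

#' Accuracy versus selection percentage
#'
#' For each selection percentage on the grid, the accuracy is computed on
#' the subset retained by [select_by_confidence()]; with several
#' (predictions, truth) repeats the accuracies are averaged and their SE
#' reported. Lower selection percentages keep only high-confidence events,
#' trading coverage for accuracy.
#'
#' @param predictions A `pore_predictions` data frame, or a list of them
#'   (independent repeats).
#' @param true_labels Labels aligned with `predictions` (a list if
#'   `predictions` is a list).
#' @param grid Selection percentages in (0, 100], default
#'   `c(100, 75, 50, 25)`.
#' @return Object of class `selection_curve`: data frame with
#'   `selection_pct`, `accuracy`, `se`, `n_selected`, plus attribute
#'   `n_repeats`.
#' @export
accuracy_vs_selection <- function(predictions, true_labels,
                                  grid = c(100, 75, 50, 25)) {
  if (any(grid <= 0 | grid > 100)) stop("selection grid must lie in (0, 100]")
  if (is.data.frame(predictions)) {
    predictions <- list(predictions); true_labels <- list(true_labels)
  }
  stopifnot(length(predictions) == length(true_labels))
  grid <- sort(grid, decreasing = TRUE)
  acc <- matrix(NA_real_, length(predictions), length(grid))
  nsel <- integer(length(grid))
  for (r in seq_along(predictions)) {
    pr <- predictions[[r]]
    tl <- as.character(true_labels[[r]])
    if (!"assessment_score" %in% names(pr)) {
      stop("predictions must carry assessment scores")
    }
    for (j in seq_along(grid)) {
      sel <- select_by_confidence(pr, grid[j])
      acc[r, j] <- mean(as.character(sel$selected$prediction) ==
                          tl[sel$selected$index])
      nsel[j] <- nrow(sel$selected)
    }
  }
  out <- data.frame(selection_pct = grid,
                    accuracy = colMeans(acc),
                    se = apply(acc, 2, function(v) {
                      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
                    }),
                    n_selected = nsel)
  structure(out, n_repeats = length(predictions),
            class = c("selection_curve", "data.frame"))
}

#' @export
print.selection_curve <- function(x, ...) {
  cat(sprintf("Selection curve (averaged over %d repeat(s))\n",
              attr(x, "n_repeats")))
  df <- as.data.frame(x)
  df$accuracy <- sprintf("%.3f", df$accuracy)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.selection_curve <- function(x, ...) {
  graphics::plot(x$selection_pct, x$accuracy, type = "b",
                 xlab = "selection percentage", ylab = "averaged accuracy",
                 xlim = rev(range(x$selection_pct)), ylim = c(0, 1), ...)
  invisible(x)
}

#' Mixture assignment percentages
#'
#' For a mixture sample classified with a model trained on pure classes
#' (holdout protocol: the mixture never enters training), reports the
#' percentage of all events assigned to each class among those passing the
#' confidence selection, plus the unassigned percentage (events dropped by
#' the selection), so the percentages sum to 100. With repeats, means and
#' SEs over repeats are reported.
#'
#' @param predictions A `pore_predictions` data frame or a list of them
#'   (independent repeats).
#' @param selection_pct Selection percentage (default 100: no rejection).
#' @param classes Classes to report; defaults to the prediction levels.
#' @return Object of class `mixture_result`: data frame with `class`,
#'   `percent`, `se`.
#' @export
assign_mixture <- function(predictions, selection_pct = 100, classes = NULL) {
  if (is.data.frame(predictions)) predictions <- list(predictions)
  if (is.null(classes)) {
    p1 <- predictions[[1]]$prediction
    classes <- if (is.factor(p1)) levels(p1) else sort(unique(as.character(p1)))
  }
  rows <- matrix(NA_real_, length(predictions), length(classes) + 1L)
  for (r in seq_along(predictions)) {
    pr <- predictions[[r]]
    n <- nrow(pr)
    sel <- select_by_confidence(pr, selection_pct)
    tallies <- table(factor(as.character(sel$selected$prediction),
                            levels = classes))
    rows[r, ] <- c(100 * as.numeric(tallies) / n,
                   100 * (n - nrow(sel$selected)) / n)
  }
  out <- data.frame(
    class = c(classes, "(unassigned)"),
    percent = colMeans(rows),
    se = apply(rows, 2, function(v) {
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    })
  )
  structure(out, n_repeats = length(predictions),
            class = c("mixture_result", "data.frame"))
}

#' @export
print.mixture_result <- function(x, ...) {
  cat(sprintf("Mixture assignment (%d repeat(s))\n", attr(x, "n_repeats")))
  df <- as.data.frame(x)
  df$percent <- sprintf("%.1f", df$percent)
  df$se <- ifelse(is.na(df$se), "-", sprintf("%.2f", df$se))
  print(df, row.names = FALSE)
  invisible(x)
}
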