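# Evaluation metrics for tile-risk prediction.

#' Root-mean-square error
#'
#' `sqrt(mean((a - f)^2))` between actual and predicted vectors.
#'
#' @param a Actual values.
#' @param f Predicted values (same nonzero length).
#' @return A nonnegative scalar.
#' @export
#' @examples
#' rmse(c(0, 0), c(3, 4)) # sqrt(12.5)
rmse <- function(a, f) {
  stop_if(length(a) == 0, "empty vectors")
  stop_if(length(a) != length(f), "length mismatch")
  sqrt(mean((a - f)^2))
}

#' Recall in percent
#'
#' `100 * tp / (tp + fn)`: the share of true positive visit evidence among all
#' positive case evidence.
#'
#' @param tp_tweets True-positive count (check-ins in truly risky tiles that
#'   the model flags).
#' @param fn_cases False-negative count.
#' @return Percent in `[0, 100]`.
#' @export
#' @examples
#' recall(7, 3) # 70
recall <- function(tp_tweets, fn_cases) {
  stop_if(tp_tweets < 0 || fn_cases < 0, "counts must be nonnegative")
  stop_if(tp_tweets + fn_cases == 0, "tp + fn must be positive")
  100 * tp_tweets / (tp_tweets + fn_cases)
}

#' Evaluate a fitted model on held-out tiles
#'
#' Computes tile-level accuracy at the given threshold, check-in-weighted
#' recall (each matched check-in in a truly risky tile counts as a true
#' positive if its tile is flagged, else a false negative), and the RMSE
#' between predicted sigmoid scores and the planted true tile scores.
#'
#' @param object A fitted [glstm()] model.
#' @param tiles Tile ids to evaluate (default: the model's test split).
#' @param threshold Decision threshold on the score.
#' @return A list of class `glstm_eval`: `accuracy`, `recall`, `rmse`,
#'   `predictions` (data.frame `tile`, `score`, `label`, `truth`,
#'   `true_score`, `n_checkins`).
#' @export
evaluate <- function(object, tiles = NULL, threshold = 0.5) {
  stopifnot(inherits(object, "glstm"))
  tiles <- tiles %||% object$split$test
  stop_if(length(tiles) == 0, "empty evaluation set")
  pr <- predict(object, newdata = tiles, threshold = threshold)
  all_ids <- vapply(object$prepared$tiles, function(t) t$tile, character(1))
  idx <- match(pr$tile, all_ids)
  truth <- vapply(object$prepared$tiles, function(t) t$label, numeric(1))[idx]
  true_score <- vapply(object$prepared$tiles, function(t) t$score, numeric(1))[idx]
  n_ck <- vapply(object$prepared$tiles, function(t) t$n_checkins, numeric(1))[idx]
  stop_if(anyNA(truth), "evaluation requires true labels")

  accuracy <- 100 * mean(pr$label == truth)
  pos <- truth == 1
  tp <- sum(n_ck[pos & pr$label == 1])
  fn <- sum(n_ck[pos & pr$label == 0])
  rec <- if (tp + fn > 0) recall(tp, fn) else NA_real_
  preds <- data.frame(tile = pr$tile, score = pr$score, label = pr$label,
                      truth = as.integer(truth), true_score = true_score,
                      n_checkins = as.integer(n_ck), stringsAsFactors = FALSE)
  structure(list(accuracy = accuracy, recall = rec,
                 rmse = rmse(true_score, pr$score), predictions = preds,
                 threshold = threshold),
            class = "glstm_eval")
}

#' @export
print.glstm_eval <- function(x, ...) {
  cat("Tile-risk evaluation\n")
  cat(sprintf("  tiles: %d   accuracy: %.2f%%   recall: %s   rmse: %.4f\n",
              nrow(x$predictions), x$accuracy,
              ifelse(is.na(x$recall), "NA", sprintf("%.2f%%", x$recall)),
              x$rmse))
  invisible(x)
}

#' Write per-tile predictions to CSV
#'
#' @param eval A `glstm_eval` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_predictions_csv <- function(eval, path) {
  p <- eval$predictions
  lines <- c("tile,score,label,truth,true_score,n_checkins",
             sprintf("%s,%s,%d,%d,%s,%d", p$tile, fmt_num(p$score), p$label,
                     p$truth, fmt_num(p$true_score), p$n_checkins))
  writeLines(lines, path)
  invisible(path)
}
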