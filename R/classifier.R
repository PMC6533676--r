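## Supervised behavior classification from burst features.
##
## The classifier is pluggable: anything honoring the predict contract
## (a function from a feature data frame to fine labels + class
## probabilities) can stand in. The default is a random forest, trained
## on labeled bursts; a hold-out split reports accuracy so users can
## judge whether their annotation vocabulary is separable.

feature_columns <- function(df) {
  setdiff(names(df), c("bird_id", "t", "label", "fine", "class"))
}

#' Train the burst behavior classifier
#'
#' Fits a random forest on labeled burst features, with a stratified
#' hold-out split to report accuracy on unseen bursts.
#'
#' @param features Data frame of burst features (see
#'   [extract_features_table()]); non-feature key columns are ignored.
#' @param labels Character vector of fine behavior labels, one per row.
#' @param seed Integer seed; fixes both the hold-out split and the
#'   forest.
#' @param holdout Fraction of bursts held out for accuracy estimation
#'   (default 0.3).
#' @param num_trees Number of trees (default 500).
#' @return A `behavior_classifier`: list with `model`, `levels`,
#'   `feature_names`, `holdout_accuracy`, `confusion` (hold-out
#'   confusion matrix) and a `predict_fun(features)` returning a data
#'   frame with `fine` and a probability matrix `prob`.
#' @export
train_classifier <- function(features, labels, seed = 1L, holdout = 0.3,
                             num_trees = 500) {
  labels <- as.character(labels)
  if (length(labels) != nrow(features)) {
    stop("`labels` must match rows of `features`", call. = FALSE)
  }
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 behavior labels", call. = FALSE)
  if (any(tab < 5)) {
    stop("need >= 5 examples per label; short: ",
         paste(names(tab)[tab < 5], collapse = ", "), call. = FALSE)
  }
  fcols <- feature_columns(features)
  x <- features[, fcols, drop = FALSE]
  lev <- sort(unique(labels))
  y <- factor(labels, levels = lev)

  idx_test <- with_seed(seed, {
    unlist(lapply(split(seq_along(y), y), function(i) {
      sample(i, max(1, round(length(i) * holdout)))
    }), use.names = FALSE)
  })
  train_df <- cbind(x[-idx_test, , drop = FALSE],
                    .label = y[-idx_test])
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = train_df,
    num.trees = num_trees, probability = TRUE,
    seed = seed, num.threads = 1
  )
  predict_fun <- function(newdata) {
    prob <- predict(fit, data = newdata[, fcols, drop = FALSE],
                    num.threads = 1)$predictions
    fine <- colnames(prob)[max.col(prob, ties.method = "first")]
    list(fine = fine, prob = prob)
  }
  pred_test <- predict_fun(x[idx_test, , drop = FALSE])$fine
  acc <- mean(pred_test == as.character(y[idx_test]))
  out <- list(
    model = fit, levels = lev, feature_names = fcols,
    holdout_accuracy = acc,
    confusion = table(truth = as.character(y[idx_test]), pred = pred_test),
    predict_fun = predict_fun
  )
  class(out) <- "behavior_classifier"
  out
}

#' @export
print.behavior_classifier <- function(x, ...) {
  cat(sprintf("Behavior classifier: %d labels, hold-out accuracy %.3f\n",
              length(x$levels), x$holdout_accuracy))
  invisible(x)
}

#' Classify bursts and aggregate to behavior classes
#'
#' Predicts a fine behavior for every burst and maps it to one of the
#' four energetic classes. Fixes in `fix_keys` without a burst are
#' labeled `"unannotated"`.
#'
#' @param features Burst feature table with `bird_id`, `t` key columns.
#' @param classifier A [train_classifier()] result (or any list with a
#'   `predict_fun`).
#' @param scheme A [behavior_scheme()]; the classifier's labels must lie
#'   inside it.
#' @param fix_keys Optional data frame `bird_id`, `t` of all fixes; rows
#'   without a matching burst get fine = NA, class = "unannotated".
#' @return Data frame `bird_id`, `t`, `fine`, `class`, `prob` (winning
#'   class probability; NA when unannotated).
#' @export
classify_and_aggregate <- function(features, classifier,
                                   scheme = behavior_scheme(),
                                   fix_keys = NULL) {
  stopifnot(inherits(scheme, "behavior_scheme"))
  pred <- classifier$predict_fun(features)
  bad <- setdiff(unique(pred$fine), scheme$fine_labels)
  if (length(bad)) {
    stop("classifier produced label(s) outside the scheme: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ann <- data.frame(
    bird_id = features$bird_id, t = features$t,
    fine = pred$fine,
    class = aggregate_behavior(pred$fine, scheme),
    prob = apply(pred$prob, 1, max)
  )
  if (is.null(fix_keys)) return(ann)
  key_fix <- paste(fix_keys$bird_id, fix_keys$t)
  key_ann <- paste(ann$bird_id, ann$t)
  m <- match(key_fix, key_ann)
  out <- data.frame(
    bird_id = fix_keys$bird_id, t = fix_keys$t,
    fine = ann$fine[m],
    class = ifelse(is.na(m), "unannotated", ann$class[m]),
    prob = ann$prob[m]
  )
  out
}
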