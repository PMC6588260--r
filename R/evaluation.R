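#' Prediction metrics: mean negative log-probability and percent correct
#'
#' `nlp()` is the per-trial mean of the negative log-probability the trace
#' assigns to the actions actually taken (lower is better; a uniform
#' predictor scores `log 2`). `percent_correct()` is the percentage of
#' trials on which the most probable action matches the taken action; exact
#' ties between the two actions count as incorrect.
#'
#' @param trace a policy trace (data frame with `p_L`, `p_R`) aligned to
#'   `session`.
#' @param session the subject's trials.
#' @return `nlp()`: non-negative scalar; `percent_correct()`: percentage in
#'   \[0, 100\].
#' @export
nlp <- function(trace, session) {
  if (nrow(trace) != nrow(session)) stop("trace/session length mismatch")
  a <- action_to_int(session$action)
  p_taken <- ifelse(a == 1L, trace$p_L, trace$p_R)
  -mean(log_floor(p_taken))
}

#' @rdname nlp
#' @export
percent_correct <- function(trace, session) {
  if (nrow(trace) != nrow(session)) stop("trace/session length mismatch")
  a <- action_to_int(session$action)
  pred <- ifelse(trace$p_L > trace$p_R, 1L, ifelse(trace$p_R > trace$p_L,
                                                   2L, 0L))
  100 * mean(pred == a)
}

#' Cohort-level mean negative log-probability
#'
#' The cohort NLL divided by the total number of trials across subjects.
#'
#' @param model a `bandit_model`.
#' @param sessions cohort data frame.
#' @return non-negative scalar.
#' @export
cohort_nlp <- function(model, sessions) {
  cohort_negative_log_likelihood(model, sessions) / nrow(sessions)
}

# Evaluate a fitted model on a held-out subject (nlp + percent correct),
# optionally at every stored checkpoint.
eval_heldout <- function(fit, session, checkpoints = FALSE) {
  if (!checkpoints || length(fit$checkpoints) == 0) {
    trace <- policy_trace(fit$model, session)
    return(data.frame(iteration = NA_integer_, nlp = nlp(trace, session),
                      percent_correct = percent_correct(trace, session)))
  }
  iters <- names(fit$checkpoints)
  do.call(rbind, lapply(iters, function(key) {
    model <- fit_at_iteration(fit, key)
    trace <- policy_trace(model, session)
    data.frame(iteration = as.integer(key), nlp = nlp(trace, session),
               percent_correct = percent_correct(trace, session))
  }))
}

#' Leave-one-out cross-validation of a model family
#'
#' For every subject: fit one model to all remaining subjects, freeze it,
#' and record the mean negative log-probability and percent-correct of its
#' causal predictions on the withheld subject. The fold count equals the
#' cohort size. A fold whose fit fails is recorded with `NA` metrics rather
#' than aborting the run.
#'
#' @param family model family tag.
#' @param sessions cohort data frame (>= 2 subjects).
#' @param config a [fit_config()].
#' @param eval_checkpoints if `TRUE`, evaluate the held-out subject at every
#'   stored training checkpoint (the early-stopping grid), yielding one row
#'   per (subject, iteration).
#' @param ... family hyperparameters passed to [fit_ml()] (`d`, `J`,
#'   `n_cells`).
#' @return data frame with columns `subject_id`, `iteration`, `nlp`,
#'   `percent_correct`.
#' @export
loo_cv <- function(family, sessions, config = fit_config(),
                   eval_checkpoints = FALSE, ...) {
  sessions <- validate_sessions(sessions)
  ids <- unique(sessions$subject_id)
  if (length(ids) < 2) stop("leave-one-out needs at least 2 subjects")
  res <- lapply(ids, function(sid) {
    train <- sessions[sessions$subject_id != sid, , drop = FALSE]
    test <- sessions[sessions$subject_id == sid, , drop = FALSE]
    out <- tryCatch({
      fit <- fit_ml(family, train, config = config, ...)
      eval_heldout(fit, test, checkpoints = eval_checkpoints)
    }, error = function(e) {
      warning(sprintf("fold %s failed: %s", sid, conditionMessage(e)))
      data.frame(iteration = NA_integer_, nlp = NA_real_,
                 percent_correct = NA_real_)
    })
    cbind(subject_id = sid, out)
  })
  do.call(rbind, res)
}

#' Select model hyperparameters by cross-validated prediction accuracy
#'
#' Evaluates every grid point by leave-one-out cross-validation and returns
#' the setting with the lowest mean held-out nlp. For the network the grid
#' is over the cell count, and the training-iteration dimension comes for
#' free from the stored checkpoints (early stopping); for LIN the grid is
#' over the lag depth `J`; for GQL over `d`. With `mode = "other_groups"`
#' the cross-validation runs on the pooled sessions of the *other* groups
#' and the chosen setting is applied to the target group, an alternative to
#' the default in-sample selection.
#'
#' @param family model family tag.
#' @param sessions the target group's sessions.
#' @param grid named list: `list(n_cells = c(5, 10, 20))`,
#'   `list(J = ...)` or `list(d = ...)`.
#' @param config a [fit_config()].
#' @param mode `"in_sample"` (default) or `"other_groups"`.
#' @param other_groups list of the other groups' session data frames
#'   (required for `mode = "other_groups"`).
#' @return list with `best` (named list of chosen settings, including
#'   `iteration` for the network, and the attained `mean_nlp`) and `table`
#'   (mean nlp for every evaluated setting).
#' @export
select_hyperparams <- function(family, sessions, grid,
                               config = fit_config(),
                               mode = c("in_sample", "other_groups"),
                               other_groups = NULL) {
  mode <- match.arg(mode)
  if (length(grid) == 0 || any(lengths(grid) == 0)) stop("empty grid")
  cv_data <- if (mode == "in_sample") sessions else {
    if (is.null(other_groups)) stop("other_groups required for this mode")
    do.call(rbind, other_groups)
  }
  key <- names(grid)[1]
  rows <- list()
  for (val in grid[[1]]) {
    args <- list(family = family, sessions = cv_data, config = config,
                 eval_checkpoints = (family == "rnn"))
    args[[key]] <- val
    cv <- do.call(loo_cv, args)
    agg <- stats::aggregate(nlp ~ iteration, data = cv, FUN = mean,
                            na.action = stats::na.pass)
    if (all(is.na(cv$iteration))) {
      agg <- data.frame(iteration = NA_integer_,
                        nlp = mean(cv$nlp, na.rm = TRUE))
    }
    agg[[key]] <- val
    rows[[length(rows) + 1]] <- agg
  }
  table <- do.call(rbind, rows)
  best_row <- table[which.min(table$nlp), ]
  best <- stats::setNames(list(best_row[[key]]), key)
  if (!is.na(best_row$iteration)) best$iteration <- best_row$iteration
  best$mean_nlp <- best_row$nlp
  list(best = best, table = table)
}

#' Predict a subject's diagnostic label from group-level models
#'
#' Assigns the label of the group model that best fits the subject's
#' choices (lowest per-trial mean negative log-probability). Ties are
#' broken deterministically by the order of `group_models`.
#'
#' @param session one subject's trials.
#' @param group_models named list mapping labels to `bandit_model` or
#'   `bandit_fit` objects.
#' @return the predicted label (character), with the per-label nlp values
#'   attached as attribute `"nlp"`.
#' @export
classify_subject <- function(session, group_models) {
  if (length(group_models) < 2) stop("need at least 2 group models")
  scores <- vapply(group_models, function(m) {
    if (inherits(m, "bandit_fit")) m <- m$model
    nlp(policy_trace(m, session), session)
  }, numeric(1))
  label <- names(scores)[which.min(scores)] # which.min: first minimum wins
  structure(label, nlp = scores)
}

#' Leave-one-out diagnostic-label prediction
#'
#' For every subject: refit their own group's model without them, fit the
#' other groups' models on those groups' full data, and predict the label
#' via [classify_subject()]. Returns the true-by-predicted confusion
#' matrix with row percentages.
#'
#' @param groups named list mapping group labels to session data frames.
#' @param family model family used for the group models.
#' @param config a [fit_config()].
#' @param ... hyperparameters for [fit_ml()].
#' @return a `confusion_matrix`: list with integer `counts`, `percent`
#'   (row percentages) and `accuracy` (overall percent correct).
#' @export
diagnostic_cv <- function(groups, family, config = fit_config(), ...) {
  labels <- names(groups)
  full_fits <- lapply(groups, function(g) fit_ml(family, g, config = config,
                                                 ...))
  counts <- matrix(0L, length(labels), length(labels),
                   dimnames = list(true = labels, predicted = labels))
  for (g in labels) {
    for (sid in unique(groups[[g]]$subject_id)) {
      ses <- groups[[g]]
      train <- ses[ses$subject_id != sid, , drop = FALSE]
      test <- ses[ses$subject_id == sid, , drop = FALSE]
      models <- lapply(full_fits, `[[`, "model")
      models[[g]] <- fit_ml(family, train, config = config, ...)$model
      pred <- as.character(classify_subject(test, models))
      counts[g, pred] <- counts[g, pred] + 1L
    }
  }
  structure(list(counts = counts,
                 percent = 100 * counts / rowSums(counts),
                 accuracy = 100 * sum(diag(counts)) / sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Diagnostic-label confusion matrix (counts, row % in parentheses):\n")
  m <- matrix(sprintf("%d (%.0f%%)", x$counts, x$percent),
              nrow(x$counts), dimnames = dimnames(x$counts))
  print(m, quote = FALSE)
  cat(sprintf("Overall correct: %.0f%%\n", x$accuracy))
  invisible(x)
}
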