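#' Leave-one-out response prediction
#'
#' For each cell line the full model chain — standardization, PCA with
#' Kaiser (or fixed) retention, singleton pooling, LDA segmentation — is
#' refit on the remaining lines only; the held-out line is then projected
#' into that fold's frozen PC space and classified. A prediction is
#' correct when the line lands in its own (pooled) response region.
#'
#' Folds whose training labels collapse to a single class after pooling
#' are marked unpredictable and, by default, counted as incorrect.
#'
#' @param fg FG matrix (rows = cell lines, >= 4).
#' @param labels Factor of per-line response classes, level order from
#'   most to least responsive.
#' @param fixed_k Retained PC count per fold; `NULL` (default) recomputes
#'   the Kaiser criterion within each fold. `fixed_k = 4` mirrors the
#'   4D-PC-space setting used throughout the original study design.
#' @param ridge,priors Passed to [fit_class_regions()].
#' @param skip_degenerate If `TRUE`, unpredictable folds are excluded from
#'   the accuracy denominator instead of counting as incorrect.
#' @param return_models If `TRUE`, the per-fold fitted `pc_model` and
#'   `class_region_model` are attached as attribute `"fold_models"` (a
#'   list, one entry per held-out line) so folds can be audited.
#' @return An object of class `loocv_result`: data.frame with per-line
#'   `cell_line`, `observed` (pooled within the fold), `predicted`, `k`,
#'   `correct`, plus attribute `"accuracy"`.
#' @export
loocv_predict <- function(fg, labels, fixed_k = NULL, ridge = NULL,
                          priors = "uniform", skip_degenerate = FALSE,
                          return_models = FALSE) {
  X <- as.matrix(fg)
  n <- nrow(X)
  if (n < 4L) stop("need >= 4 cell lines for LOOCV", call. = FALSE)
  if (length(labels) != n) stop("labels length != number of lines",
                                call. = FALSE)
  f <- as.factor(labels)
  lines <- rownames(X)
  if (is.null(lines)) lines <- paste0("line", seq_len(n))
  obs <- pred <- character(n)
  kk <- integer(n)
  ok <- pred_ok <- logical(n)
  fold_models <- if (return_models) vector("list", n) else NULL
  for (i in seq_len(n)) {
    tr <- X[-i, , drop = FALSE]
    trlab <- droplevels(f[-i])
    pooled <- tryCatch(pool_singleton_classes(trlab),
                       error = function(e) NULL)
    held_label <- as.character(f[i])
    if (is.null(pooled) || nlevels(pooled) < 2L) {
      obs[i] <- held_label
      pred[i] <- NA_character_
      kk[i] <- NA_integer_
      ok[i] <- FALSE
      pred_ok[i] <- FALSE
      next
    }
    mapping <- attr(pooled, "mapping")
    if (held_label %in% names(mapping)) {
      held_label <- unname(mapping[held_label])
    }
    if (!held_label %in% levels(pooled)) {
      # the held-out line's class is absent from the fold: map it like the
      # pooling rule would, toward the nearest less responsive class
      lv <- levels(f)
      i0 <- match(held_label, lv)
      present <- which(lv %in% levels(pooled))
      later <- present[present > i0]
      held_label <- lv[if (length(later)) later[1L]
                       else max(present[present < i0])]
    }
    pc <- fit_pc_model(tr, n_components = fixed_k)
    coords <- project(pc, tr)
    lda <- fit_class_regions(coords, pooled, ridge = ridge,
                             priors = priors)
    if (return_models) fold_models[[i]] <- list(pc = pc, lda = lda)
    p <- as.character(classify(lda, project(pc, X[i, ])))
    obs[i] <- held_label
    pred[i] <- p
    kk[i] <- pc$k
    ok[i] <- identical(p, held_label)
    pred_ok[i] <- TRUE
  }
  res <- data.frame(cell_line = lines, observed = obs, predicted = pred,
                    k = kk, correct = ok, stringsAsFactors = FALSE)
  acc <- if (skip_degenerate) mean(ok[pred_ok]) else mean(ok)
  structure(res, accuracy = acc, fold_models = fold_models,
            class = c("loocv_result", "data.frame"))
}

#' Accuracy of a LOOCV run
#' @param result A `loocv_result`.
#' @return Fraction of correctly placed lines.
#' @export
loocv_accuracy <- function(result) attr(result, "accuracy")

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("LOOCV: %d/%d correct (accuracy %.2f)\n",
              sum(x$correct), nrow(x), attr(x, "accuracy")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Recommend the treatment arm with higher predicted responsiveness
#'
#' The optimal treatment is the one predicted to induce more cell death;
#' equal predicted classes yield `"either"`.
#'
#' @param pred_tmz,pred_trail Predicted response classes (factor or
#'   character using [response_levels()], or any shared ordered level
#'   set); `NA` marks a missing arm prediction.
#' @param levels Level order from most to least responsive.
#' @return Character vector over `{"TMZ", "TRAIL", "either",
#'   "unavailable"}`.
#' @export
recommend_treatment <- function(pred_tmz, pred_trail,
                                levels = response_levels()) {
  a <- match(as.character(pred_tmz), levels)
  b <- match(as.character(pred_trail), levels)
  out <- ifelse(is.na(a) | is.na(b), "unavailable",
                ifelse(a < b, "TMZ", ifelse(b < a, "TRAIL", "either")))
  out
}

#' Score treatment recommendations against observed survival
#'
#' A recommendation is correct when the recommended arm's observed
#' survival is at most the alternative's, or when the two arms differ by
#' no more than `similar_tol` (similar amounts of cell death make either
#' suggestion acceptable). An `"either"` recommendation is therefore
#' always scored correct: whichever arm is taken, one of the two
#' single-arm readings holds. `"unavailable"` counts as incorrect.
#'
#' @param recommendations Character vector from [recommend_treatment()].
#' @param survival_tmz,survival_trail Observed survival fractions per
#'   line.
#' @param similar_tol Absolute survival difference treated as "similar";
#'   default 0.10.
#' @return List with `correct` (logical vector) and `accuracy` (fraction).
#' @export
evaluate_recommendations <- function(recommendations, survival_tmz,
                                     survival_trail, similar_tol = 0.10) {
  stopifnot(length(recommendations) == length(survival_tmz),
            length(survival_tmz) == length(survival_trail))
  similar <- abs(survival_tmz - survival_trail) <= similar_tol
  s_rec <- ifelse(recommendations == "TMZ", survival_tmz,
                  ifelse(recommendations == "TRAIL", survival_trail,
                         pmin(survival_tmz, survival_trail)))
  s_alt <- ifelse(recommendations == "TMZ", survival_trail,
                  ifelse(recommendations == "TRAIL", survival_tmz,
                         pmax(survival_tmz, survival_trail)))
  correct <- recommendations != "unavailable" &
    (similar | s_rec <= s_alt)
  list(correct = correct, accuracy = mean(correct))
}
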