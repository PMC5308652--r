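#' Webb fractional-product combination index
#'
#' Under Bliss/Webb independence the expected survival of a combination is
#' the product of the monotherapy survivals. The combination index is the
#' observed combination survival divided by that product:
#' `CI = s_ab / (s_a * s_b)`. `CI < 1` indicates synergy (more death than
#' independence predicts), `CI ~ 1` additivity, `CI > 1` antagonism.
#'
#' Survival values above 1 (assay noise beyond the untreated control) are
#' clipped to 1 for the CI computation only, with a warning.
#'
#' @param s_a,s_b Monotherapy survival fractions (> 0).
#' @param s_ab Combination survival fraction (>= 0).
#' @return Numeric CI values.
#' @export
webb_ci <- function(s_a, s_b, s_ab) {
  if (any(s_ab < 0)) stop("negative combination survival", call. = FALSE)
  if (any(s_a <= 0) || any(s_b <= 0)) {
    stop(paste("monotherapy survival of 0: combination index undefined",
               "(monotherapy already fully effective)"), call. = FALSE)
  }
  if (any(s_a > 1) || any(s_b > 1) || any(s_ab > 1)) {
    warning("survival > 1 clipped to 1 for CI computation")
    s_a <- pmin(s_a, 1)
    s_b <- pmin(s_b, 1)
    s_ab <- pmin(s_ab, 1)
  }
  s_ab / (s_a * s_b)
}

#' Default synergy class labels
#' @param n_classes Number of classes (bin edges + 1).
#' @return Character vector, most synergistic first.
#' @export
synergy_levels <- function(n_classes = 3L) {
  if (n_classes == 3L) c("SYNERGY_HIGH", "SYNERGY_MODERATE",
                         "NON_SYNERGISTIC")
  else paste0("SYNERGY_BIN", seq_len(n_classes))
}

#' Bin combination indices into ordinal synergy classes
#'
#' Half-open binning (lower edge exclusive, upper inclusive); the most
#' synergistic class (lowest CI) comes first. The default edges
#' `c(0.5, 0.9)` are a working convention for synthetic studies, not
#' values taken from any published grouping.
#'
#' @param ci Positive CI values.
#' @param bins Strictly increasing positive bin edges.
#' @param labels Class labels, most synergistic first; default
#'   [synergy_levels()].
#' @return Factor of synergy classes, levels most synergistic first.
#' @export
assign_synergy_class <- function(ci, bins = c(0.5, 0.9), labels = NULL) {
  if (any(ci <= 0)) stop("CI must be positive", call. = FALSE)
  if (is.unsorted(bins, strictly = TRUE)) {
    stop("bins must be strictly increasing", call. = FALSE)
  }
  if (is.null(labels)) labels <- synergy_levels(length(bins) + 1L)
  if (length(labels) != length(bins) + 1L) {
    stop("need one more label than bin edges", call. = FALSE)
  }
  idx <- findInterval(ci, bins, left.open = FALSE) + 1L
  # findInterval is lower-inclusive; shift exact edge hits down one bin
  # to get (lower, upper] semantics
  on_edge <- ci %in% bins
  idx[on_edge] <- match(ci[on_edge], bins)
  factor(labels[idx], levels = labels)
}

#' Leave-one-out prediction of combination-treatment synergy classes
#'
#' Identical mechanics to [loocv_predict()] with labels derived from CI
#' bins rather than survival bins; singleton pooling applies to the
#' synergy classes in the same way.
#'
#' @param fg FG matrix.
#' @param synergy_labels Factor of per-line synergy classes (levels most
#'   synergistic first), e.g. from [assign_synergy_class()].
#' @inheritParams loocv_predict
#' @return A `loocv_result`.
#' @export
synergy_loocv <- function(fg, synergy_labels, fixed_k = NULL, ridge = NULL,
                          priors = "uniform", skip_degenerate = FALSE) {
  loocv_predict(fg, synergy_labels, fixed_k = fixed_k, ridge = ridge,
                priors = priors, skip_degenerate = skip_degenerate)
}

#' Combination-index table for a response table
#'
#' Joins the two monotherapy arms with the combination arm per cell line
#' and computes the Webb CI and its synergy class.
#'
#' @param responses A `response_table` containing `TMZ`, `TRAIL` and
#'   `TMZ+TRAIL` rows.
#' @param bins,labels Passed to [assign_synergy_class()].
#' @param mono_floor Detection floor applied to the survival values
#'   before the CI is formed (viability assays cannot read exactly zero;
#'   a zero monotherapy survival leaves the CI undefined and a zero
#'   combination survival a zero CI, outside the valid class range).
#'   Default 0.01; set to 0 for strict behavior.
#' @return data.frame with `cell_line`, `s_tmz`, `s_trail`, `s_combo`,
#'   `ci`, `synergy_class`.
#' @export
combination_index_table <- function(responses, bins = c(0.5, 0.9),
                                    labels = NULL, mono_floor = 0.01) {
  s_t <- pmax(arm_survival(responses, "TMZ"), mono_floor)
  s_r <- pmax(arm_survival(responses, "TRAIL", cell_lines = names(s_t)),
              mono_floor)
  s_c <- pmax(arm_survival(responses, "TMZ+TRAIL",
                           cell_lines = names(s_t)), mono_floor)
  ci <- webb_ci(s_t, s_r, s_c)
  data.frame(cell_line = names(s_t), s_tmz = unname(s_t),
             s_trail = unname(s_r), s_combo = unname(s_c),
             ci = unname(ci),
             synergy_class = assign_synergy_class(unname(ci), bins, labels),
             stringsAsFactors = FALSE)
}
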