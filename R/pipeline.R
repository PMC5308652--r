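#' Run the full prediction pipeline
#'
#' Orchestrates the end-to-end analysis on a protein panel and a viability
#' table: replicate aggregation, FG encoding, PC-space construction,
#' response-class assignment with singleton pooling, LDA segmentation with
#' resubstitution accuracy, leave-one-out prediction per arm, treatment
#' recommendation, Webb-CI synergy scoring with synergy LOOCV (when a
#' combination arm is present), and in-silico target-depletion
#' sensitization predictions. Entirely deterministic given the inputs and
#' configuration.
#'
#' @param panel A `protein_panel`.
#' @param viability A `response_table`.
#' @param config Named list of options: `fg_defs` (FG definitions),
#'   `ratio_policy`, `thresholds` (default `c(0.30, 0.80)`), `fixed_k`
#'   (default 4; `NULL` for per-fold Kaiser), `ridge`, `priors`,
#'   `similar_tol` (default 0.10), `ci_bins` (default `c(0.5, 0.9)`),
#'   `sensitization_targets` (default Bcl-2/Bcl-xL; `NULL` disables the
#'   stage), `seed` (recorded in metadata only; the pipeline itself is
#'   deterministic).
#' @param out_dir Optional directory; when given, every intermediate
#'   artifact (FG table, PC model, class tables, LOOCV results,
#'   recommendations, CI table, sensitization table, JSON summary) is
#'   persisted with run metadata.
#' @return List of class `apopto_run` with components `fg`, `pc_model`,
#'   `arms` (per-arm classes, region model, resubstitution and LOOCV
#'   results), `recommendations`, `synergy`, `sensitization`, `summary`,
#'   `config`.
#' @export
run_full_analysis <- function(panel, viability, config = list(),
                              out_dir = NULL) {
  cfg <- utils::modifyList(list(
    fg_defs = default_fg_definitions(), ratio_policy = "strict",
    thresholds = c(0.30, 0.80), fixed_k = 4L, ridge = NULL,
    priors = "uniform", similar_tol = 0.10, ci_bins = c(0.5, 0.9),
    sensitization_targets = c("Bcl-2", "Bcl-xL"), seed = NULL
  ), config)
  panel <- aggregate_replicates(panel)
  fg <- compute_fg_matrix(panel, cfg$fg_defs,
                          ratio_policy = cfg$ratio_policy)
  pc <- fit_pc_model(fg, n_components = cfg$fixed_k)
  coords <- project(pc, fg)

  run_arm <- function(arm) {
    s <- tryCatch(arm_survival(viability, arm,
                               cell_lines = rownames(fg)),
                  error = function(e) {
                    stop("classification stage failed for arm ", arm, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
    cls <- assign_response_class(s, cfg$thresholds)
    pooled <- pool_singleton_classes(cls)
    lda <- fit_class_regions(coords, pooled, ridge = cfg$ridge,
                             priors = cfg$priors)
    loocv <- loocv_predict(fg, cls, fixed_k = cfg$fixed_k,
                           ridge = cfg$ridge, priors = cfg$priors)
    list(survival = s,
         classes = data.frame(cell_line = rownames(fg),
                              survival = unname(s),
                              class = as.character(cls),
                              pooled_class = as.character(pooled),
                              stringsAsFactors = FALSE),
         region_model = lda,
         resubstitution = resubstitution_accuracy(lda, coords, pooled),
         loocv = loocv)
  }

  present <- unique(viability$treatment)
  arms <- list()
  for (arm in intersect(c("TMZ", "TRAIL"), present)) {
    arms[[arm]] <- run_arm(arm)
  }

  recommendations <- NULL
  if (all(c("TMZ", "TRAIL") %in% names(arms))) {
    rec <- recommend_treatment(arms$TMZ$loocv$predicted,
                               arms$TRAIL$loocv$predicted)
    ev <- evaluate_recommendations(rec, arms$TMZ$survival,
                                   arms$TRAIL$survival,
                                   similar_tol = cfg$similar_tol)
    recommendations <- list(
      table = data.frame(cell_line = rownames(fg), recommended = rec,
                         pred_tmz = arms$TMZ$loocv$predicted,
                         pred_trail = arms$TRAIL$loocv$predicted,
                         survival_tmz = unname(arms$TMZ$survival),
                         survival_trail = unname(arms$TRAIL$survival),
                         correct = ev$correct, stringsAsFactors = FALSE),
      accuracy = ev$accuracy)
  }

  synergy <- NULL
  if (all(c("TMZ", "TRAIL", "TMZ+TRAIL") %in% present)) {
    ci_tab <- combination_index_table(viability, bins = cfg$ci_bins)
    ci_tab <- ci_tab[match(rownames(fg), ci_tab$cell_line), ]
    sloocv <- synergy_loocv(fg, ci_tab$synergy_class,
                            fixed_k = cfg$fixed_k, ridge = cfg$ridge,
                            priors = cfg$priors)
    synergy <- list(table = ci_tab, loocv = sloocv)
  }

  sensitization <- NULL
  if (!is.null(cfg$sensitization_targets) && length(arms)) {
    sensitization <- do.call(rbind, lapply(names(arms), function(arm) {
      sensitization_table(pc, arms[[arm]]$region_model, panel,
                          targets = cfg$sensitization_targets,
                          defs = cfg$fg_defs, arm = arm)
    }))
  }

  summary <- list(
    n_lines = nrow(fg), n_fgs = ncol(fg), k = pc$k,
    explained_fraction = pc$explained_fraction,
    resubstitution = lapply(arms, `[[`, "resubstitution"),
    loocv_accuracy = lapply(arms, function(a) loocv_accuracy(a$loocv)),
    recommendation_accuracy = if (!is.null(recommendations))
      recommendations$accuracy else NULL,
    synergy_loocv_accuracy = if (!is.null(synergy))
      loocv_accuracy(synergy$loocv) else NULL,
    n_sensitized = if (!is.null(sensitization))
      sum(sensitization$verdict == "SENSITIZED") else NULL
  )

  run <- structure(list(fg = fg, pc_model = pc, arms = arms,
                        recommendations = recommendations,
                        synergy = synergy, sensitization = sensitization,
                        summary = summary, config = cfg),
                   class = "apopto_run")
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

#' @export
print.apopto_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("apopto_run: %d lines, %d FGs, k = %d (%.1f%% variance)\n",
              s$n_lines, s$n_fgs, s$k, 100 * s$explained_fraction))
  for (arm in names(s$loocv_accuracy)) {
    cat(sprintf("  %s: resubstitution %.2f, LOOCV %.2f\n", arm,
                s$resubstitution[[arm]], s$loocv_accuracy[[arm]]))
  }
  if (!is.null(s$recommendation_accuracy)) {
    cat(sprintf("  recommendation accuracy: %.2f\n",
                s$recommendation_accuracy))
  }
  if (!is.null(s$synergy_loocv_accuracy)) {
    cat(sprintf("  synergy LOOCV accuracy: %.2f\n",
                s$synergy_loocv_accuracy))
  }
  invisible(x)
}

# serializable view of the run configuration
.config_plain <- function(cfg) {
  out <- cfg
  out$fg_defs <- lapply(cfg$fg_defs, function(d) unclass(d))
  out
}

#' Persist every artifact of a pipeline run
#'
#' @param run An `apopto_run`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_artifacts <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  meta <- list(seed = run$config$seed, config = .config_plain(run$config))
  fg_df <- data.frame(cell_line = rownames(run$fg), run$fg,
                      check.names = FALSE)
  write_report(fg_df, file.path(out_dir, "fg_matrix.csv"), meta)
  write_pc_model(run$pc_model, file.path(out_dir, "pc_model.json"))
  for (arm in names(run$arms)) {
    a <- run$arms[[arm]]
    write_report(a$classes,
                 file.path(out_dir, paste0("classes_", arm, ".csv")), meta)
    write_report(as.data.frame(a$loocv),
                 file.path(out_dir, paste0("loocv_", arm, ".csv")), meta)
  }
  if (!is.null(run$recommendations)) {
    write_report(run$recommendations$table,
                 file.path(out_dir, "recommendations.csv"), meta)
  }
  if (!is.null(run$synergy)) {
    write_report(run$synergy$table,
                 file.path(out_dir, "combination_index.csv"), meta)
    write_report(as.data.frame(run$synergy$loocv),
                 file.path(out_dir, "loocv_synergy.csv"), meta)
  }
  if (!is.null(run$sensitization)) {
    write_report(run$sensitization,
                 file.path(out_dir, "sensitization.csv"), meta)
  }
  write_report(run$summary, file.path(out_dir, "summary.json"), meta)
  invisible(out_dir)
}
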