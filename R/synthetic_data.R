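#' Default log-normal location parameters for protein abundance
#'
#' Plausible per-protein median abundances spanning roughly 0.1-500 nM
#' (the two death receptors are in relative surface-expression units).
#'
#' @return Named numeric vector of medians on the natural scale.
#' @export
default_protein_medians <- function() {
  c("Apaf-1" = 200, "Bak" = 80, "Bax" = 100, "Bcl-2" = 40,
    "Bcl-xL" = 60, "Bid" = 50, "Bim" = 10, "caspase-3" = 100,
    "caspase-8" = 30, "caspase-9" = 20, "cFLIP" = 8, "FADD" = 12,
    "Mcl-1" = 20, "Noxa" = 5, "Puma" = 15, "SMAC" = 120, "XIAP" = 40,
    "DR4" = 0.5, "DR5" = 1.5)
}

# signed pro/anti-apoptotic direction per protein: +1 promotes death
.protein_direction <- function() {
  d <- stats::setNames(rep(1, 19L), canonical_proteins())
  d[c("Bcl-2", "Bcl-xL", "Mcl-1", "cFLIP", "XIAP")] <- -1
  d
}

#' Default latent-responsiveness coefficients per treatment arm
#'
#' Coefficients over the 11 default FGs defining each arm's latent
#' responsiveness as a linear combination of standardized FG values. TMZ
#' (intrinsic pathway) weights the mitochondrial groups; TRAIL (extrinsic)
#' weights the DISC and caspase-8 axis; the anti-apoptotic Bcl-2 group
#' counts against both.
#'
#' @return Named list with numeric coefficient vectors `TMZ` and `TRAIL`.
#' @export
default_arm_coefficients <- function() {
  fg <- vapply(default_fg_definitions(), `[[`, character(1L), "name")
  tmz <- stats::setNames(c(-1, 1, 0.5, 0.5, 1, 0.5, 1, 0, 0, 1, 0.5), fg)
  trail <- stats::setNames(c(-1, 0.5, 1, 0, 0, 0, 0.5, 1, 1, 1, 0.5), fg)
  list(TMZ = tmz, TRAIL = trail)
}

#' Simulation configuration for synthetic panels and responses
#'
#' The generator emulates the statistical structure of a quantified
#' apoptosis-protein panel: log-normal protein abundances sharing a
#' line-level co-regulation factor (so the FG matrix has a dominant
#' variance direction, as real panels do), replicate measurement noise at
#' a fixed coefficient of variation, and per-arm survival produced by a
#' logistic link on a latent responsiveness that is a linear combination
#' of standardized FG values.
#'
#' @param n_lines Number of cell lines (default 11).
#' @param seed Integer seed; fully determines all generated data.
#' @param replicates Replicate measurements per (line, protein), default 3.
#' @param replicate_cv Replicate coefficient of variation, default 0.15.
#' @param protein_medians Named medians, see [default_protein_medians()].
#' @param protein_sdlog Between-line log-scale SD, default 0.5.
#' @param factor_loading Strength (0-1) of the shared line-level
#'   co-regulation factor, signed by pro/anti-apoptotic direction;
#'   default 0.7. Set to 0 for independent proteins.
#' @param class_means Optional numeric vector of component means (in
#'   line-factor SD units, most apoptosis-competent first) planting a
#'   Gaussian-mixture class structure in the line factor; lines are
#'   assigned to components in balanced rotation and the panel carries the
#'   planted labels as attribute `"class_true"`. `NULL` (default) draws a
#'   unimodal factor.
#' @param arms Named list of FG coefficient vectors, see
#'   [default_arm_coefficients()].
#' @param separation Class separation: SD of the latent responsiveness in
#'   logit units (default 3).
#' @param intercept Latent intercept per arm (recycled), default 0 (median
#'   survival 0.5).
#' @param noise_sd Additive Gaussian noise SD on observed survival,
#'   default 0.05.
#' @param thresholds Survival thresholds defining ground-truth classes.
#' @param true_ci True combination index: scalar, per-line vector, or a
#'   function of the standardized FG matrix returning one CI per line
#'   (default 0.8).
#' @param ci_noise_sd Additive noise SD on combination survival,
#'   default 0.02.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_lines = 11L, seed = 1L, replicates = 3L,
                              replicate_cv = 0.15,
                              protein_medians = default_protein_medians(),
                              protein_sdlog = 0.5, factor_loading = 0.7,
                              class_means = NULL,
                              arms = default_arm_coefficients(),
                              separation = 3, intercept = 0,
                              noise_sd = 0.05,
                              thresholds = c(0.30, 0.80),
                              true_ci = 0.8, ci_noise_sd = 0.02) {
  stopifnot(n_lines >= 2L, replicates >= 1L, replicate_cv >= 0,
            protein_sdlog >= 0, factor_loading >= 0, factor_loading <= 1,
            separation >= 0, noise_sd >= 0, ci_noise_sd >= 0)
  structure(list(n_lines = as.integer(n_lines), seed = as.integer(seed),
                 replicates = as.integer(replicates),
                 replicate_cv = replicate_cv,
                 protein_medians = protein_medians,
                 protein_sdlog = protein_sdlog,
                 factor_loading = factor_loading,
                 class_means = class_means, arms = arms,
                 separation = separation, intercept = intercept,
                 noise_sd = noise_sd, thresholds = thresholds,
                 true_ci = true_ci, ci_noise_sd = ci_noise_sd),
            class = "simulation_config")
}

#' Generate a synthetic protein panel
#'
#' Per-line true abundances are log-normal around the configured medians;
#' a shared line-level factor (strength `factor_loading`, signed by
#' pro/anti-apoptotic direction) induces realistic co-regulation.
#' Replicates scatter around the true value with the configured CV.
#' Deterministic given `cfg$seed`.
#'
#' When `cfg$class_means` is set, the line factor is drawn from a
#' Gaussian mixture (unit component SD) with those means, most
#' apoptosis-competent component first; the planted component labels are
#' attached as attribute `"class_true"` (levels [response_levels()] when
#' there are three components).
#'
#' @param cfg A `simulation_config`.
#' @return A `protein_panel` with `n_lines x 19 x replicates`
#'   measurements.
#' @export
generate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  prots <- canonical_proteins()
  med <- cfg$protein_medians[prots]
  if (anyNA(med)) stop("protein_medians must cover all 19 proteins",
                       call. = FALSE)
  n <- cfg$n_lines
  lam <- cfg$factor_loading * .protein_direction()[prots]
  g <- stats::rnorm(n)                     # line-level competence factor
  class_true <- NULL
  if (!is.null(cfg$class_means)) {
    comp <- rep_len(seq_along(cfg$class_means), n)
    g <- g + cfg$class_means[comp]
    lev <- if (length(cfg$class_means) == 3L) response_levels()
           else paste0("C", seq_along(cfg$class_means))
    class_true <- factor(lev[comp], levels = lev)
  }
  eps <- matrix(stats::rnorm(n * 19L), n, 19L)
  logv <- sweep(outer(g, lam) + sweep(eps, 2L, sqrt(1 - lam^2), `*`),
                2L, cfg$protein_sdlog, `*`)
  true_val <- sweep(exp(logv), 2L, med, `*`)
  dimnames(true_val) <- list(sprintf("SL%02d", seq_len(n)), prots)
  sdlog_rep <- sqrt(log(1 + cfg$replicate_cv^2))
  rows <- expand.grid(replicate = seq_len(cfg$replicates),
                      protein = prots,
                      cell_line = rownames(true_val),
                      stringsAsFactors = FALSE)
  mult <- if (cfg$replicate_cv > 0) {
    stats::rlnorm(nrow(rows), meanlog = -sdlog_rep^2 / 2,
                  sdlog = sdlog_rep)
  } else rep(1, nrow(rows))
  rows$value <- true_val[cbind(rows$cell_line, rows$protein)] * mult
  panel <- protein_panel(rows[c("cell_line", "protein", "replicate",
                                "value")])
  if (!is.null(class_true)) {
    attr(panel, "class_true") <- stats::setNames(class_true,
                                                 rownames(true_val))
  }
  panel
}

# standardized FG matrix of an aggregated panel
.fg_z <- function(panel, defs = default_fg_definitions()) {
  fg <- compute_fg_matrix(panel, defs)
  scale(fg)
}

#' Generate per-arm responses with known ground truth
#'
#' Latent responsiveness per arm is the configured linear combination of
#' standardized FG values, rescaled to SD `separation` across lines (plus
#' the intercept). True survival is `plogis(intercept - latent)` so more
#' responsive lines survive less; the ground-truth class comes from the
#' noiseless survival via the configured thresholds; observed survival
#' adds Gaussian noise and is clipped to `[0, 1.1]` (assays can read
#' slightly above the untreated control). Deterministic given
#' `cfg$seed` (offset by 1 from panel generation).
#'
#' @param panel A `protein_panel`.
#' @param cfg A `simulation_config`.
#' @param defs FG definitions; default [default_fg_definitions()].
#' @return List: `responses` (a `response_table` over the configured
#'   arms) and `truth` (data.frame of `cell_line`, `treatment`, `latent`,
#'   `survival_true`, `class_true`).
#' @export
generate_responses <- function(panel, cfg,
                               defs = default_fg_definitions()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 1L)
  Z <- .fg_z(panel, defs)
  arms <- cfg$arms
  intercept <- rep(cfg$intercept, length.out = length(arms))
  resp <- truth <- list()
  for (j in seq_along(arms)) {
    beta <- arms[[j]][colnames(Z)]
    if (anyNA(beta)) stop("arm coefficients must cover all FGs",
                          call. = FALSE)
    raw <- drop(Z %*% beta)
    s_raw <- stats::sd(raw)
    latent <- if (cfg$separation == 0 || s_raw == 0) {
      rep(0, length(raw))
    } else {
      cfg$separation * (raw - mean(raw)) / s_raw
    }
    survival_true <- stats::plogis(intercept[j] - latent)
    class_true <- assign_response_class(survival_true, cfg$thresholds)
    observed <- pmin(pmax(survival_true +
                            stats::rnorm(length(latent), 0, cfg$noise_sd),
                          0), 1.1)
    arm <- names(arms)[j]
    resp[[arm]] <- data.frame(cell_line = rownames(Z), treatment = arm,
                              survival = observed,
                              stringsAsFactors = FALSE)
    truth[[arm]] <- data.frame(cell_line = rownames(Z), treatment = arm,
                               latent = latent,
                               survival_true = survival_true,
                               class_true = as.character(class_true),
                               stringsAsFactors = FALSE)
  }
  list(responses = response_table(do.call(rbind, c(resp,
                                                   make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Generate combination-arm survival with known combination index
#'
#' Combination survival is `true_CI * s_tmz * s_trail` plus Gaussian
#' noise, clipped to `[0, 1.1]`; the true CI per line is stored as ground
#' truth so the Webb estimator can be validated by round trip.
#' Deterministic given `cfg$seed` (offset by 2).
#'
#' @param responses A `response_table` with the two monotherapy arms
#'   (`TMZ`, `TRAIL`).
#' @param cfg A `simulation_config`; `cfg$true_ci` may be a scalar, a
#'   per-line vector, or a function of the standardized FG matrix.
#' @param panel Required when `cfg$true_ci` is a function.
#' @param defs FG definitions for the function form of `true_ci`.
#' @return List: `responses` (input table with `TMZ+TRAIL` rows appended)
#'   and `truth` (data.frame of `cell_line`, `true_ci`).
#' @export
generate_combination <- function(responses, cfg, panel = NULL,
                                 defs = default_fg_definitions()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 2L)
  s_t <- arm_survival(responses, "TMZ")
  s_r <- arm_survival(responses, "TRAIL", cell_lines = names(s_t))
  ci <- cfg$true_ci
  if (is.function(ci)) {
    if (is.null(panel)) stop("panel required for a CI-generating function",
                             call. = FALSE)
    ci <- ci(.fg_z(panel, defs))
  }
  ci <- rep(ci, length.out = length(s_t))
  s_c <- pmin(pmax(ci * s_t * s_r +
                     stats::rnorm(length(s_t), 0, cfg$ci_noise_sd), 0),
              1.1)
  combo <- data.frame(cell_line = names(s_t), treatment = "TMZ+TRAIL",
                      survival = unname(s_c), stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(responses), combo)
  list(responses = response_table(out),
       truth = data.frame(cell_line = names(s_t), true_ci = unname(ci),
                          stringsAsFactors = FALSE))
}
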