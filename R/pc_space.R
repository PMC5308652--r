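#' Fit the principal-component space of a functional-group matrix
#'
#' FG values are z-scored over the training cell lines and the resulting
#' correlation structure is eigendecomposed (correlation-scale PCA). The
#' number of retained components follows the Kaiser criterion: components
#' with eigenvalue above 1, with a floor of one component. Loading signs
#' are fixed deterministically (the largest-magnitude coefficient of each
#' component is made positive) so projections are reproducible across
#' platforms.
#'
#' Correlation-scale PCA is used because the Kaiser rule is defined on that
#' scale and the FG units are heterogeneous (nM sums, dimensionless
#' ratios, nM-squared products).
#'
#' @param fg Numeric matrix of FG values, rows = cell lines (>= 3),
#'   columns = FGs; no constant column.
#' @param n_components Optional override of the Kaiser-retained dimension.
#' @param log10_transform If `TRUE`, FG values are log10-transformed
#'   before standardization (all values must be positive).
#' @return An object of class `pc_model`: `loadings` (FG x PC, all
#'   components), `eigenvalues`, `k`, `explained_fraction`, `center`,
#'   `scale`, `fg_names`, `training_lines`, `log10_transform`.
#' @export
fit_pc_model <- function(fg, n_components = NULL, log10_transform = FALSE) {
  X <- as.matrix(fg)
  if (nrow(X) < 3L) stop("need >= 3 cell lines to fit a PC model",
                         call. = FALSE)
  if (is.null(colnames(X))) {
    stop("FG matrix must have column names", call. = FALSE)
  }
  if (log10_transform) {
    if (any(X <= 0)) stop("log10 transform requires positive FG values",
                          call. = FALSE)
    X <- log10(X)
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  const <- scl < 1e-12 * pmax(1, abs(ctr))
  if (any(const)) {
    stop("constant FG column(s): ",
         paste(colnames(X)[const], collapse = ", "), call. = FALSE)
  }
  Z <- scale(X, center = ctr, scale = scl)
  R <- stats::cor(X)
  e <- eigen(R, symmetric = TRUE)
  V <- e$vectors
  # deterministic sign: largest-|coefficient| entry positive per PC
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(colnames(X), paste0("PC", seq_len(ncol(V))))
  ev <- pmax(e$values, 0)
  k <- if (!is.null(n_components)) {
    k <- as.integer(n_components)
    if (k < 1L || k > ncol(X)) stop("n_components out of range",
                                    call. = FALSE)
    k
  } else {
    max(1L, sum(ev > 1))
  }
  structure(list(
    loadings = V,
    eigenvalues = ev,
    k = k,
    explained_fraction = sum(ev[seq_len(k)]) / sum(ev),
    center = ctr,
    scale = scl,
    fg_names = colnames(X),
    training_lines = rownames(X),
    log10_transform = log10_transform
  ), class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf(paste0("pc_model: %d FGs, %d training lines, k = %d ",
                     "(%.1f%% of variance)\n"),
              length(x$fg_names), length(x$training_lines), x$k,
              100 * x$explained_fraction))
  invisible(x)
}

#' Project FG values into a fitted PC space
#'
#' Uses the model's frozen standardization; never refits. Accepts a named
#' FG vector (one cell line) or an FG matrix (rows projected
#' independently).
#'
#' @param model A `pc_model`.
#' @param fg_row Named numeric vector covering all model FGs, or a matrix
#'   with FG columns.
#' @return Length-`k` coordinate vector, or an n x k coordinate matrix.
#' @export
project <- function(model, fg_row) {
  if (is.matrix(fg_row) || is.data.frame(fg_row)) {
    X <- as.matrix(fg_row)
    miss <- setdiff(model$fg_names, colnames(X))
    if (length(miss)) stop("missing FG(s): ", paste(miss, collapse = ", "),
                           call. = FALSE)
    out <- t(apply(X[, model$fg_names, drop = FALSE], 1L,
                   function(r) project(model, r)))
    colnames(out) <- paste0("PC", seq_len(model$k))
    return(out)
  }
  x <- fg_row
  if (!is.null(names(x))) {
    miss <- setdiff(model$fg_names, names(x))
    if (length(miss)) stop("missing FG(s): ", paste(miss, collapse = ", "),
                           call. = FALSE)
    x <- x[model$fg_names]
  } else if (length(x) != length(model$fg_names)) {
    stop("fg_row must supply all ", length(model$fg_names), " FGs",
         call. = FALSE)
  }
  if (model$log10_transform) {
    if (any(x <= 0)) stop("log10 transform requires positive FG values",
                          call. = FALSE)
    x <- log10(x)
  }
  z <- (x - model$center) / model$scale
  drop(crossprod(model$loadings[, seq_len(model$k), drop = FALSE], z))
}

#' Cumulative explained variance of the first m components
#'
#' @param model A `pc_model`.
#' @param m Component count, `1 <= m <=` number of FGs.
#' @return Fraction of total variance in `[0, 1]`.
#' @export
explained_variance <- function(model, m) {
  p <- length(model$eigenvalues)
  if (m < 1L || m > p) stop("m out of range [1, ", p, "]", call. = FALSE)
  sum(model$eigenvalues[seq_len(m)]) / sum(model$eigenvalues)
}

#' Serialize a PC model to a structured text artifact
#'
#' @param model A `pc_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_pc_model <- function(model, path) {
  obj <- list(
    fg_names = model$fg_names,
    training_lines = model$training_lines,
    k = model$k,
    eigenvalues = model$eigenvalues,
    explained_fraction = model$explained_fraction,
    center = as.list(model$center),
    scale = as.list(model$scale),
    loadings = unname(model$loadings),
    log10_transform = model$log10_transform
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a PC model written by [write_pc_model()]
#'
#' @param path JSON path.
#' @return A `pc_model`.
#' @export
read_pc_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- as.matrix(obj$loadings)
  dimnames(L) <- list(obj$fg_names, paste0("PC", seq_len(ncol(L))))
  structure(list(
    loadings = L,
    eigenvalues = as.numeric(obj$eigenvalues),
    k = as.integer(obj$k),
    explained_fraction = as.numeric(obj$explained_fraction),
    center = unlist(obj$center),
    scale = unlist(obj$scale),
    fg_names = obj$fg_names,
    training_lines = obj$training_lines,
    log10_transform = isTRUE(obj$log10_transform)
  ), class = "pc_model")
}
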