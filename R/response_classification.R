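#' Response-class levels in responsiveness order
#'
#' Most responsive first: `HIGH` (survival up to 30% of control), `LOW`
#' (30-80%), `RESISTANT` (above 80%).
#'
#' @return Character vector of the three class labels.
#' @export
response_levels <- function() c("HIGH", "LOW", "RESISTANT")

#' Assign ordinal response classes from survival fractions
#'
#' Boundaries are upper-inclusive: survival <= `t_high` is `HIGH`,
#' survival in (`t_high`, `t_resistant`] is `LOW`, above `t_resistant` is
#' `RESISTANT` ("up to 30%" is read as inclusive; one consistent
#' convention throughout).
#'
#' @param survival Numeric vector of survival fractions (>= 0).
#' @param thresholds Length-2 numeric `c(t_high, t_resistant)`, strictly
#'   increasing in (0, 1); default `c(0.30, 0.80)`.
#' @return Factor with levels [response_levels()].
#' @export
assign_response_class <- function(survival, thresholds = c(0.30, 0.80)) {
  if (any(survival < 0)) stop("negative survival", call. = FALSE)
  if (length(thresholds) != 2L || diff(thresholds) <= 0 ||
      thresholds[1L] <= 0 || thresholds[2L] >= 1) {
    stop("thresholds must be strictly increasing within (0, 1)",
         call. = FALSE)
  }
  cls <- ifelse(survival <= thresholds[1L], "HIGH",
                ifelse(survival <= thresholds[2L], "LOW", "RESISTANT"))
  factor(cls, levels = response_levels())
}

#' Merge singleton response classes into a neighbor
#'
#' Any class with exactly one member is merged into the adjacent class in
#' the direction of lower responsiveness (a singleton `HIGH` joins `LOW`;
#' a singleton `RESISTANT`, having no less-responsive neighbor, joins
#' `LOW`), repeating until no singleton remains or a single class is left.
#' Works for any ordered label set (e.g. synergy classes), with "less
#' responsive" meaning later factor levels.
#'
#' @param labels Factor of class labels whose level order runs from most
#'   to least responsive.
#' @return Factor of pooled labels (unused levels dropped) with attribute
#'   `"mapping"`: a named character vector from every original level to
#'   its final pooled level.
#' @export
pool_singleton_classes <- function(labels) {
  if (length(labels) < 2L) stop("need >= 2 lines to pool", call. = FALSE)
  f <- droplevels(as.factor(labels))
  orig_levels <- levels(f)
  mapping <- stats::setNames(orig_levels, orig_levels)
  counts <- table(f)
  if (length(counts) > 1L && all(counts == 1L)) {
    stop("every class is a singleton; use coarser response bins",
         call. = FALSE)
  }
  repeat {
    counts <- table(f)
    present <- names(counts)[counts > 0L]
    if (length(present) <= 1L) break
    singles <- names(counts)[counts == 1L]
    singles <- singles[singles %in% present]
    if (!length(singles)) break
    # most responsive singleton first (earliest level)
    s <- present[present %in% singles][1L]
    si <- match(s, present)
    target <- if (si < length(present)) present[si + 1L]
              else present[si - 1L]
    f[f == s] <- target
    mapping[mapping == s] <- target
    f <- droplevels(f)
  }
  structure(f, mapping = mapping)
}

#' Fit linear-discriminant response regions in PC space
#'
#' Linear discriminant analysis with a pooled within-class covariance
#' stabilized by a ridge term; decision regions are convex polyhedra
#' bounded by hyperplanes. Priors are uniform by default (set
#' `priors = "empirical"` for class-frequency priors).
#'
#' @param coords n x k matrix of PC coordinates (rows = cell lines).
#' @param labels Factor of pooled class labels, level order from most to
#'   least responsive; every class needs >= 2 members.
#' @param ridge Ridge coefficient added to the covariance diagonal;
#'   default `1e-6 * trace(S)/k`.
#' @param priors `"uniform"` or `"empirical"`.
#' @return An object of class `class_region_model`: `means`, `cov`,
#'   `cov_inv`, `log_priors`, `classes`, `k`, `ridge`.
#' @export
fit_class_regions <- function(coords, labels, ridge = NULL,
                              priors = c("uniform", "empirical")) {
  priors <- match.arg(priors)
  X <- as.matrix(coords)
  f <- droplevels(as.factor(labels))
  if (nlevels(f) < 2L) stop("need >= 2 classes to fit regions",
                            call. = FALSE)
  counts <- table(f)
  if (any(counts < 2L)) {
    stop("class(es) with a single member: ",
         paste(names(counts)[counts < 2L], collapse = ", "),
         "; pool singleton classes first", call. = FALSE)
  }
  k <- ncol(X)
  n <- nrow(X)
  g <- nlevels(f)
  mu <- t(vapply(levels(f),
                 function(cl) colMeans(X[f == cl, , drop = FALSE]),
                 numeric(k)))
  Sw <- matrix(0, k, k)
  for (cl in levels(f)) {
    Xi <- X[f == cl, , drop = FALSE]
    Sw <- Sw + crossprod(sweep(Xi, 2L, colMeans(Xi)))
  }
  Sw <- Sw / (n - g)
  if (is.null(ridge)) ridge <- 1e-6 * sum(diag(Sw)) / k
  S <- Sw + diag(ridge, k)
  Sinv <- tryCatch(chol2inv(chol(S)), error = function(e) NULL)
  if (is.null(Sinv)) {
    stop("regularized covariance is singular; increase the ridge term",
         call. = FALSE)
  }
  pr <- if (priors == "uniform") rep(1 / g, g)
        else as.numeric(counts) / n
  structure(list(means = mu, cov = S, cov_inv = Sinv,
                 log_priors = stats::setNames(log(pr), levels(f)),
                 classes = levels(f), k = k, ridge = ridge),
            class = "class_region_model")
}

#' Discriminant scores for points in PC space
#'
#' @param model A `class_region_model`.
#' @param coords Length-`k` vector or n x k matrix.
#' @return n x classes matrix of linear discriminant scores.
#' @export
discriminant_scores <- function(model, coords) {
  X <- if (is.matrix(coords)) coords else matrix(coords, nrow = 1L)
  if (ncol(X) != model$k) {
    stop("coordinate dimension ", ncol(X), " != model k = ", model$k,
         call. = FALSE)
  }
  A <- model$cov_inv %*% t(model$means)            # k x g
  const <- -0.5 * colSums(t(model$means) * A) + model$log_priors
  sweep(X %*% A, 2L, const, `+`) |>
    `colnames<-`(model$classes)
}

#' Classify points into response regions
#'
#' Assigns the class with the maximal discriminant score; exact ties are
#' broken toward the less responsive class (conservative for treatment
#' decisions).
#'
#' @param model A `class_region_model`.
#' @param coords Length-`k` vector or n x k matrix of PC coordinates.
#' @return Factor of predicted classes (levels = model classes).
#' @export
classify <- function(model, coords) {
  sc <- discriminant_scores(model, coords)
  idx <- apply(sc, 1L, function(r) max(which(r == max(r))))
  factor(model$classes[idx], levels = model$classes)
}

#' Resubstitution accuracy of a fitted region model
#'
#' @param model A `class_region_model`.
#' @param coords Training coordinates.
#' @param labels Training labels.
#' @return Fraction in `[0, 1]` of training points classified into their
#'   own class.
#' @export
resubstitution_accuracy <- function(model, coords, labels) {
  pred <- classify(model, coords)
  mean(as.character(pred) == as.character(labels))
}
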