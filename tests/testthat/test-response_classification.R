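test_that("survival bins into ordinal classes with inclusive upper bounds", {
  expect_equal(as.character(assign_response_class(
    c(0.25, 0.30, 0.31, 0.80, 0.81, 0.85, 1.05))),
    c("HIGH", "HIGH", "LOW", "LOW", "RESISTANT", "RESISTANT", "RESISTANT"))
  expect_error(assign_response_class(-0.1), "negative")
  expect_error(assign_response_class(0.5, thresholds = c(0.8, 0.3)),
               "strictly increasing")

  # monotone: lower survival is never a less responsive class
  s <- sort(stats::runif(50, 0, 1.1))
  cls <- as.integer(assign_response_class(s))
  expect_true(all(diff(cls) >= 0))
})

test_that("singleton classes pool toward the less responsive neighbor", {
  lv <- response_levels()
  lab <- factor(rep(lv, c(1, 5, 5)), levels = lv)
  pooled <- pool_singleton_classes(lab)
  expect_equal(as.vector(table(pooled)[c("LOW", "RESISTANT")]), c(6L, 5L))
  expect_equal(attr(pooled, "mapping")[["HIGH"]], "LOW")

  lab <- factor(rep(lv, c(3, 4, 4)), levels = lv)
  expect_equal(as.character(pool_singleton_classes(lab)),
               as.character(lab))

  lab <- factor(rep(lv, c(1, 1, 9)), levels = lv)
  pooled <- pool_singleton_classes(lab)
  expect_equal(as.vector(table(pooled)[c("LOW", "RESISTANT")]), c(2L, 9L))

  # a singleton RESISTANT has no less responsive neighbor: joins LOW
  lab <- factor(rep(lv, c(0, 5, 1)), levels = lv)
  pooled <- pool_singleton_classes(lab)
  expect_equal(levels(droplevels(pooled)), "LOW")

  expect_error(pool_singleton_classes(factor(lv, levels = lv)),
               "coarser")
})

test_that("two-class LDA matches the closed-form discriminant", {
  set.seed(5)
  k <- 4
  n <- 30
  whiten <- function(E) {
    E <- scale(E, scale = FALSE)
    E %*% solve(chol(crossprod(E) / (nrow(E) - 1)))
  }
  mu1 <- c(-3, 0, 0, 0); mu2 <- c(3, 0, 0, 0)
  X <- rbind(sweep(whiten(matrix(stats::rnorm(n * k), n)), 2, mu1, `+`),
             sweep(whiten(matrix(stats::rnorm(n * k), n)), 2, mu2, `+`))
  lab <- factor(rep(c("HIGH", "RESISTANT"), each = n),
                levels = c("HIGH", "RESISTANT"))
  m <- fit_class_regions(X, lab, ridge = 0)

  # pooled covariance is the identity by construction, so the closed-form
  # score difference is (mu1-mu2).x - (|mu1|^2 - |mu2|^2)/2 (equal priors)
  pts <- matrix(stats::rnorm(50 * k), 50)
  sc <- discriminant_scores(m, pts)
  closed <- drop(pts %*% (mu1 - mu2)) - 0.5 * (sum(mu1^2) - sum(mu2^2))
  expect_equal(unname(sc[, 1] - sc[, 2]), closed, tolerance = 1e-6)

  # the boundary is the hyperplane x1 = 0
  expect_equal(as.character(classify(m, c(-0.01, 1, 1, 1))), "HIGH")
  expect_equal(as.character(classify(m, c(0.01, 1, 1, 1))), "RESISTANT")
})

test_that("LDA agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(6)
  X <- rbind(matrix(stats::rnorm(40, -1), 20, 2),
             matrix(stats::rnorm(40, 1), 20, 2))
  lab <- factor(rep(c("LOW", "RESISTANT"), each = 20),
                levels = c("LOW", "RESISTANT"))
  m <- fit_class_regions(X, lab, ridge = 0)
  ref <- MASS::lda(X, lab, prior = c(0.5, 0.5))
  expect_equal(as.character(classify(m, X)),
               as.character(stats::predict(ref, X)$class))
})

test_that("classification honors class means, ties and degenerate input", {
  set.seed(7)
  X <- rbind(matrix(stats::rnorm(20, -4), 10, 2),
             matrix(stats::rnorm(20, 4), 10, 2))
  lab <- factor(rep(c("HIGH", "LOW"), each = 10), levels = c("HIGH", "LOW"))
  m <- fit_class_regions(X, lab)
  expect_equal(as.character(classify(m, m$means["HIGH", ])), "HIGH")
  expect_equal(resubstitution_accuracy(m, X, lab), 1.0)

  # exact score tie breaks toward the less responsive class
  mid <- colMeans(m$means)
  sc <- discriminant_scores(m, mid)
  if (abs(sc[1] - sc[2]) < 1e-12) {
    expect_equal(as.character(classify(m, mid)), "LOW")
  }
  tie <- structure(list(
    means = rbind(HIGH = c(0, 0), LOW = c(0, 0)), cov = diag(2),
    cov_inv = diag(2), log_priors = c(HIGH = log(0.5), LOW = log(0.5)),
    classes = c("HIGH", "LOW"), k = 2L, ridge = 0),
    class = "class_region_model")
  expect_equal(as.character(classify(tie, c(1, 1))), "LOW")

  # identical coordinates cannot be segmented
  X0 <- matrix(1, 8, 2)
  expect_error(fit_class_regions(X0, factor(rep(c("a", "b"), 4)),
                                 ridge = 0))
  expect_error(classify(m, c(1, 2, 3)), "dimension")
})

test_that("decisions are invariant under invertible affine maps", {
  set.seed(8)
  X <- rbind(matrix(stats::rnorm(30, -2), 15, 2),
             matrix(stats::rnorm(30, 2), 15, 2))
  lab <- factor(rep(c("HIGH", "LOW"), each = 15), levels = c("HIGH", "LOW"))
  pts <- matrix(stats::rnorm(60), 30, 2)
  base <- classify(fit_class_regions(X, lab, ridge = 0), pts)
  for (s in 1:5) {
    set.seed(200 + s)
    A <- matrix(stats::rnorm(4), 2)
    while (abs(det(A)) < 0.1) A <- matrix(stats::rnorm(4), 2)
    b <- stats::rnorm(2)
    tX <- sweep(X %*% A, 2, b, `+`)
    tpts <- sweep(pts %*% A, 2, b, `+`)
    expect_equal(as.character(classify(
      fit_class_regions(tX, lab, ridge = 0), tpts)),
      as.character(base))
  }
})

test_that("accuracy approaches the analytic Bayes rate for known Gaussians", {
  set.seed(9)
  n <- 4000
  delta <- 2  # mean separation, unit spherical covariance
  X <- rbind(matrix(stats::rnorm(n, -delta / 2), n / 2, 2),
             matrix(stats::rnorm(n, delta / 2), n / 2, 2))
  X[, 2] <- stats::rnorm(n)
  lab <- factor(rep(c("HIGH", "LOW"), each = n / 2),
                levels = c("HIGH", "LOW"))
  m <- fit_class_regions(X, lab)
  bayes <- stats::pnorm(delta / 2)
  expect_equal(resubstitution_accuracy(m, X, lab), bayes,
               tolerance = 0.03)
})

test_that("resubstitution on permuted labels concentrates near chance", {
  set.seed(10)
  X <- matrix(stats::rnorm(400), 200, 2)
  lab <- factor(rep(c("HIGH", "LOW"), each = 100),
                levels = c("HIGH", "LOW"))
  accs <- replicate(50, {
    pl <- sample(lab)
    resubstitution_accuracy(fit_class_regions(X, pl), X, pl)
  })
  expect_lte(abs(mean(accs) - 0.5), 0.05)
})
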