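# Feature selection and model primitives for the functional-vs-oedema tissue
# classifier: information gain over equal-frequency bins, pooled-variance
# t screening, k-means profiling and L2-penalised logistic regression.

#' Information gain of a feature for a binary label
#'
#' `IG = H(Y) - sum_b p(b) H(Y | b)` in bits, with bins equal-frequency on the
#' pooled feature. Invariant to strictly monotone transforms of the feature;
#' bounded by `0 <= IG <= H(Y)`.
#'
#' @param feature_values numeric vector.
#' @param binary_labels vector with exactly 2 levels, >= 2 samples per class.
#' @param n_bins number of equal-frequency bins (default 10).
#' @return Information gain in bits.
#' @export
information_gain <- function(feature_values, binary_labels, n_bins = 10) {
  y <- as.integer(factor(binary_labels))
  if (length(unique(y)) != 2) stop_domain("labels must contain exactly 2 classes")
  if (min(table(y)) < 2) stop_domain("need >= 2 samples per class")
  if (n_bins < 2) stop_domain("n_bins must be >= 2")
  br <- unique(quantile(feature_values, probs = seq(0, 1, length.out = n_bins + 1),
                        type = 7, names = FALSE))
  b <- if (length(br) < 2) rep(1L, length(feature_values)) else
    cut(feature_values, breaks = br, include.lowest = TRUE, labels = FALSE)
  ent <- function(v) {
    p <- tabulate(v) / length(v)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  hy <- ent(y)
  cond <- vapply(split(y, b), function(yy) length(yy) / length(y) * ent(yy), numeric(1))
  max(0, hy - sum(cond))
}

#' Pooled-variance two-sample t screening per feature
#'
#' Student t with `df = n1 + n2 - 2` and two-sided p, computed column-wise.
#' Zero pooled variance yields `t = 0, p = 1` when the group means are equal
#' and a signed infinite-t sentinel (`p = 0`) otherwise.
#'
#' @param matrix numeric matrix, columns = features.
#' @param labels binary labels, >= 2 per group.
#' @return data.frame with `feature`, `t`, `p`.
#' @export
screen_ttest <- function(matrix, labels) {
  y <- as.integer(factor(labels))
  if (length(unique(y)) != 2 || min(table(y)) < 2)
    stop_domain("need two groups with >= 2 samples each")
  g1 <- matrix[y == 1, , drop = FALSE]
  g2 <- matrix[y == 2, , drop = FALSE]
  n1 <- nrow(g1); n2 <- nrow(g2)
  m1 <- colMeans(g1); m2 <- colMeans(g2)
  v1 <- apply(g1, 2, var); v2 <- apply(g2, 2, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- ifelse(se > 0, (m1 - m2) / se,
               ifelse(m1 == m2, 0, sign(m1 - m2) * Inf))
  df <- n1 + n2 - 2
  p <- ifelse(is.finite(tt), 2 * pt(-abs(tt), df), ifelse(tt == 0, 1, 0))
  data.frame(feature = colnames(matrix) %||% paste0("V", seq_along(tt)),
             t = unname(tt), p = unname(p), stringsAsFactors = FALSE)
}

# k-means++ style seeding: first centre uniform, then proportional to squared
# distance to the nearest chosen centre
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    pick <- if (sum(d2) > 0) sample.int(n, 1, prob = d2) else sample.int(n, 1)
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' k-means subgrouping of feature profiles
#'
#' Lloyd iterations from k-means++ style seeding, best of `n_init` restarts
#' by inertia (total within-cluster sum of squares); deterministic given the
#' seed.
#'
#' @param matrix standardised numeric matrix.
#' @param k number of clusters, `k <= nrow(matrix)`.
#' @param seed integer seed.
#' @param n_init number of restarts.
#' @param max_iter Lloyd iteration cap per restart.
#' @return List with `assignments`, `centroids`, `inertia`.
#' @export
kmeans_profiles <- function(matrix, k, seed = 1L, n_init = 10, max_iter = 100) {
  matrix <- as.matrix(matrix)
  if (k > nrow(matrix)) stop_domain("k must not exceed the number of rows")
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_init)) {
      init <- kmeanspp_init(matrix, k)
      km <- suppressWarnings(
        kmeans(matrix, centers = init, iter.max = max_iter, algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    list(assignments = unname(best$cluster), centroids = unname(best$centers),
         inertia = best$tot.withinss)
  })
}

#' Fit an L2-penalised logistic regression
#'
#' Maximises the penalised Bernoulli log-likelihood
#' `sum(y log p + (1 - y) log(1 - p)) - l2/2 * sum(beta^2)` (intercept
#' unpenalised) by Newton iterations; declares convergence when the gradient
#' max-norm falls below 1e-6.
#'
#' @param matrix_selected standardised feature matrix (named columns).
#' @param labels binary labels; the second factor level (or value 1) is the
#'   positive class.
#' @param l2_strength ridge penalty on the standardised coefficients
#'   (default 1).
#' @param seed kept for interface symmetry; the fit is deterministic.
#' @param max_iter Newton iteration cap.
#' @return Object of class `logistic_model`: list with `intercept`,
#'   `coefficients` (named), `threshold`, `l2_strength`, `converged`,
#'   `n_iter`, `seed`.
#' @export
fit_logistic <- function(matrix_selected, labels, l2_strength = 1, seed = 1L,
                         max_iter = 100) {
  X <- cbind(`(Intercept)` = 1, as.matrix(matrix_selected))
  y <- if (is.numeric(labels)) as.numeric(labels != 0) else
    as.numeric(factor(labels)) - 1
  if (length(unique(y)) != 2) stop_domain("both classes must be present")
  p <- ncol(X)
  pen <- c(0, rep(l2_strength, p - 1))
  beta <- rep(0, p)
  g <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    g <- drop(crossprod(X, y - mu)) - pen * beta
    if (max(abs(g)) < 1e-6) break
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X) + diag(pen, p)
    beta <- beta + solve(H, g)
  }
  if (max(abs(g)) >= 1e-6)
    stop_domain("logistic fit failed to converge after %d iterations (|g| = %.3g)",
                max_iter, max(abs(g)))
  structure(list(intercept = unname(beta[1]),
                 coefficients = setNames(beta[-1], colnames(matrix_selected)),
                 threshold = 0.5, l2_strength = l2_strength,
                 converged = TRUE, n_iter = it, seed = seed,
                 standardization = NULL, catalogue_version = CATALOGUE_VERSION),
            class = "logistic_model")
}

#' Predicted functional probability from a logistic model
#'
#' @param model a `logistic_model`.
#' @param matrix feature matrix on the model's (standardised) scale.
#' @return Probabilities strictly inside (0, 1).
#' @export
predict_logistic <- function(model, matrix) {
  eta <- model$intercept +
    drop(as.matrix(matrix[, names(model$coefficients), drop = FALSE]) %*%
           model$coefficients)
  pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
}

# unadjusted Rand index between two partitions (exploratory cluster report)
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  ut <- upper.tri(same_a)
  mean(same_a[ut] == same_b[ut])
}
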