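#' Centroid size of a landmark configuration
#'
#' The standard size measure of geometric morphometrics: the square root of
#' the summed squared distances between each landmark and the configuration
#' centroid. Invariant to rotation and translation; scales linearly with
#' isotropic scaling.
#'
#' @param config k x 2 coordinate matrix.
#' @return Positive scalar.
#' @export
centroid_size <- function(config) {
  if (!is.matrix(config) || ncol(config) != 2L || nrow(config) < 2L)
    stop("config must be a k x 2 matrix with k >= 2")
  centered <- sweep(config, 2, colMeans(config))
  cs <- sqrt(sum(centered^2))
  if (cs == 0) stop("degenerate configuration: all landmarks coincident")
  cs
}

# optimal rotation (no reflection) taking X onto Y, both centered:
# R = U diag(1, det(UV')) V' with svd(X'Y) = U D V'
.opt_rotation <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

.center_scale <- function(config) {
  centered <- sweep(config, 2, colMeans(config))
  centered / sqrt(sum(centered^2))
}

#' Generalized Procrustes analysis (full superimposition)
#'
#' Iteratively superimposes landmark configurations onto a common mean
#' shape so that only shape differences remain: each configuration is
#' centered, scaled to unit centroid size (full Procrustes), and rotated to
#' the current mean by the optimal orthogonal rotation; the mean is then
#' recomputed and renormalized, until its change (root summed squared
#' difference) falls below `tol`. Reflections are never allowed in the
#' rotation fit (determinant +1 enforced) -- specimens digitized on the
#' other body side must be mirrored explicitly on input.
#'
#' @param coords n x k x 2 array of landmark coordinates (or a list of
#'   k x 2 matrices).
#' @param tol Convergence tolerance on the mean-shape change (default
#'   1e-10).
#' @param max_iter Iteration cap (default 1000); exceeding it returns the
#'   current state with `converged = FALSE` and a warning.
#' @return List of class `gpa`: `aligned` (n x k x 2, unit centroid size),
#'   `mean_shape` (k x 2, centered, unit centroid size),
#'   `centroid_sizes` (original sizes, named), `iterations`, `converged`.
#' @export
gpa <- function(coords, tol = 1e-10, max_iter = 1000L) {
  if (is.list(coords)) {
    coords <- array(unlist(lapply(coords, t)), # nolint
                    dim = c(2, nrow(coords[[1]]), length(coords)))
    coords <- aperm(coords, c(3, 2, 1))
  }
  n <- dim(coords)[1]; k <- dim(coords)[2]
  if (n < 2L) stop("need at least 2 specimens")
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  sizes <- vapply(seq_len(n), function(i) centroid_size(coords[i, , ]),
                  numeric(1))
  names(sizes) <- dimnames(coords)[[1]]
  aligned <- array(NA_real_, dim = dim(coords), dimnames = dimnames(coords))
  for (i in seq_len(n)) aligned[i, , ] <- .center_scale(coords[i, , ])
  mean_shape <- aligned[1, , ]
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n))
      aligned[i, , ] <- aligned[i, , ] %*%
        .opt_rotation(aligned[i, , ], mean_shape)
    new_mean <- .center_scale(apply(aligned, c(2, 3), mean))
    # the mean is defined up to rotation; compare after aligning to the old
    new_mean <- new_mean %*% .opt_rotation(new_mean, mean_shape)
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations")
  for (i in seq_len(n))
    aligned[i, , ] <- aligned[i, , ] %*%
      .opt_rotation(aligned[i, , ], mean_shape)
  structure(list(aligned = aligned, mean_shape = mean_shape,
                 centroid_sizes = sizes, iterations = iter,
                 converged = converged),
            class = "gpa")
}

#' @export
print.gpa <- function(x, ...) {
  cat("gpa:", dim(x$aligned)[1], "specimens,", dim(x$aligned)[2],
      "landmarks;", x$iterations, "iterations;",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' Principal component analysis of Procrustes shape coordinates
#'
#' Flattens the aligned configurations to specimens x 2k variables, forms
#' one covariance matrix for the data set and eigendecomposes it. Component
#' signs are fixed by making each component's largest-magnitude loading
#' positive, so plots are reproducible across runs and platforms.
#'
#' @param fit A [gpa()] result.
#' @return List of class `shape_pca`: `eigenvalues` (descending),
#'   `loadings` (2k x m), `scores` (n x m, zero-mean columns),
#'   `variance_fraction`, `center` (mean vector of the flattened data).
#' @export
shape_pca <- function(fit) {
  stopifnot(inherits(fit, "gpa"))
  n <- dim(fit$aligned)[1]; k <- dim(fit$aligned)[2]
  if (n < 3L) stop("need at least 3 specimens")
  X <- matrix(fit$aligned, nrow = n)   # columns: all x then all y
  colnames(X) <- c(paste0("x", seq_len(k)), paste0("y", seq_len(k)))
  rownames(X) <- if (!is.null(dimnames(fit$aligned)[[1]]))
    dimnames(fit$aligned)[[1]] else sprintf("spec_%03d", seq_len(n))
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  loadings <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")
  ev <- pc$sdev^2
  structure(list(eigenvalues = ev, loadings = loadings, scores = scores,
                 variance_fraction = ev / sum(ev), center = pc$center),
            class = "shape_pca")
}

#' Mean shape difference between two groups
#'
#' Per-landmark displacement from the mean aligned shape of one group to
#' another, the quantity drawn as wire-frame deformation graphs.
#'
#' @param fit A [gpa()] result.
#' @param groups Factor or character vector, one label per specimen.
#' @param group_a,group_b The two groups to compare (direction a -> b).
#' @param pca Optional [shape_pca()] result; with `pcs`, the displacement
#'   is projected onto the subspace of those components.
#' @param pcs Optional integer vector of component indices.
#' @return List: `mean_a`, `mean_b` (k x 2), `displacement` (k x 2,
#'   b minus a), `procrustes_distance` between the group means.
#' @export
group_shape_difference <- function(fit, groups, group_a, group_b,
                                   pca = NULL, pcs = NULL) {
  stopifnot(inherits(fit, "gpa"))
  groups <- as.character(groups)
  for (g in c(group_a, group_b))
    if (!any(groups == g)) stop("empty group: ", g)
  mean_a <- apply(fit$aligned[groups == group_a, , , drop = FALSE],
                  c(2, 3), mean)
  mean_b <- apply(fit$aligned[groups == group_b, , , drop = FALSE],
                  c(2, 3), mean)
  disp <- mean_b - mean_a
  if (!is.null(pcs)) {
    if (is.null(pca)) stop("pcs given without pca")
    v <- as.vector(disp)
    basis <- pca$loadings[, pcs, drop = FALSE]
    disp <- matrix(basis %*% crossprod(basis, v), ncol = 2)
  }
  list(mean_a = mean_a, mean_b = mean_b, displacement = disp,
       procrustes_distance = sqrt(sum((mean_b - mean_a)^2)))
}

#' Centroid size summaries and group location tests
#'
#' Box-plot-ready per-group summaries of centroid size plus pairwise
#' two-sided rank-based location tests (Wilcoxon) with multiple-testing
#' correction.
#'
#' @param coords n x k x 2 landmark array (raw, pre-superimposition:
#'   centroid size is a property of the digitized configuration).
#' @param groups Factor or character vector, one label per specimen.
#' @param p_adjust Correction method passed to [stats::p.adjust()].
#' @return List of class `centroid_size_report`: `sizes` (named vector),
#'   `summary` (per group: n, median, q1, q3, whiskers, outliers), `tests`
#'   (pairwise data frame with raw and adjusted p-values).
#' @export
centroid_size_report <- function(coords, groups, p_adjust = "holm") {
  n <- dim(coords)[1]
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  sizes <- vapply(seq_len(n), function(i) centroid_size(coords[i, , ]),
                  numeric(1))
  names(sizes) <- dimnames(coords)[[1]]
  summ <- do.call(rbind, lapply(split(sizes, groups), function(s) {
    q <- quantile(s, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(n = length(s), median = q[2], q1 = q[1], q3 = q[3],
               lower_whisker = min(s[s >= q[1] - 1.5 * iqr]),
               upper_whisker = max(s[s <= q[3] + 1.5 * iqr]),
               n_outliers = sum(s < q[1] - 1.5 * iqr | s > q[3] + 1.5 * iqr))
  }))
  testable <- names(which(table(groups) >= 2))
  small <- setdiff(unique(groups), testable)
  if (length(small))
    warning("group(s) with < 2 specimens excluded from tests: ",
            paste(small, collapse = ", "))
  tests <- NULL
  if (length(testable) >= 2) {
    pairs <- utils::combn(sort(testable), 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      p <- suppressWarnings(
        wilcox.test(sizes[groups == a], sizes[groups == b],
                    alternative = "two.sided", exact = FALSE))$p.value
      data.frame(group_a = a, group_b = b, p_value = p,
                 stringsAsFactors = FALSE)
    }))
    tests$p_adjusted <- p.adjust(tests$p_value, method = p_adjust)
  }
  structure(list(sizes = sizes, summary = summ, tests = tests),
            class = "centroid_size_report")
}
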