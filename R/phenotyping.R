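#' Permutational multivariate analysis of variance (one-way, Euclidean)
#'
#' Partitions the total sum of squared Euclidean distances among samples into
#' among- and within-group components and tests the pseudo-F statistic by
#' random relabeling. With a single response column the pseudo-F equals the
#' classical one-way ANOVA F.
#'
#' Definitions (distances `d_ij`, `n` samples, `g` groups of size `n_k`):
#' `SS_total = (1/n) sum_{i<j} d_ij^2`,
#' `SS_within = sum_k (1/n_k) sum_{i<j in k} d_ij^2`,
#' `SS_among = SS_total - SS_within`,
#' `F = [SS_among/(g-1)] / [SS_within/(n-g)]`,
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_permutations)`.
#'
#' @param x Samples x variables numeric matrix (Euclidean distances are
#'   computed), a `spectra_set`, or a `dist` object.
#' @param groups Group labels, one per sample; at least 2 groups with at
#'   least 2 samples each.
#' @param n_permutations Number of random relabelings.
#' @param seed Optional RNG seed (local; the caller's stream is untouched).
#' @return A list of class `permanova_result`: `pseudo_f`, `p_value`,
#'   `ss_total`, `ss_among`, `ss_within`, `df_among`, `df_within`,
#'   `n_permutations`, `group_sizes`.
#' @export
permanova <- function(x, groups, n_permutations = 10000L, seed = NULL) {
  if (inherits(x, "spectra_set")) x <- x$reflectance
  D2 <- if (inherits(x, "dist")) as.matrix(x)^2 else
    as.matrix(stats::dist(as.matrix(x)))^2
  n <- nrow(D2)
  groups <- factor(groups)
  if (length(groups) != n) stop("one group label per sample required")
  sizes <- table(groups)
  g <- length(sizes)
  if (g < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L)) stop("singleton group(s): ",
                            paste(names(sizes)[sizes < 2L], collapse = ", "))

  ss_total <- sum(D2) / (2 * n)
  ss_within_of <- function(lab) {
    s <- 0
    for (k in levels(lab)) {
      idx <- which(lab == k)
      s <- s + sum(D2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  ss_within <- ss_within_of(groups)
  ss_among <- ss_total - ss_within
  f_of <- function(ssw) (( ss_total - ssw) / (g - 1)) / (ssw / (n - g))
  f_obs <- f_of(ss_within)

  n_perm <- as.integer(n_permutations)
  p <- NA_real_
  if (n_perm > 0L) {
    exceed <- with_seed(seed, {
      count <- 0L
      for (b in seq_len(n_perm)) {
        lab <- groups[sample.int(n)]
        if (f_of(ss_within_of(lab)) >= f_obs) count <- count + 1L
      }
      count
    })
    p <- (1 + exceed) / (1 + n_perm)
  }
  structure(list(pseudo_f = f_obs, p_value = p,
                 ss_total = ss_total, ss_among = ss_among,
                 ss_within = ss_within,
                 df_among = g - 1L, df_within = n - g,
                 n_permutations = n_perm,
                 group_sizes = as.integer(sizes),
                 groups = names(sizes)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (Euclidean, one-way): pseudo-F = %.4g, p = %.4g (%d permutations)\n",
              x$pseudo_f, x$p_value, x$n_permutations))
  cat(sprintf("  SS among = %.4g (df %d), SS within = %.4g (df %d)\n",
              x$ss_among, x$df_among, x$ss_within, x$df_within))
  invisible(x)
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Gower double-centering of the squared distance matrix,
#' `B = -1/2 J D^2 J`, followed by an eigendecomposition; scores are
#' eigenvectors scaled by the square roots of the (non-negative) eigenvalues.
#' For Euclidean distances the embedding reproduces centered-data PCA scores
#' up to per-axis sign.
#'
#' @param x Data matrix (Euclidean distances computed), `spectra_set`, `dist`
#'   object, or symmetric distance matrix with a zero diagonal.
#' @param eps Eigenvalues below `eps * max(eigenvalue)` in absolute value are
#'   treated as zero.
#' @return A list of class `pcoa_result`: `eigenvalues` (descending),
#'   `scores` (n x k, columns for positive eigenvalues), `proportion`
#'   (variance share per retained axis).
#' @export
pcoa <- function(x, eps = 1e-9) {
  if (inherits(x, "spectra_set")) x <- x$reflectance
  if (inherits(x, "dist")) {
    D <- as.matrix(x)
  } else {
    x <- as.matrix(x)
    is_dist <- nrow(x) == ncol(x) && all(abs(diag(x)) < 1e-12) &&
      all(x >= -1e-12)
    if (is_dist) {
      if (max(abs(x - t(x))) > 1e-8) stop("distance matrix is not symmetric")
      D <- x
    } else {
      D <- as.matrix(stats::dist(x))
    }
  }
  n <- nrow(D)
  A <- -0.5 * D^2
  B <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- e$values
  tol <- eps * max(abs(lam), 1e-300)
  keep <- which(lam > tol)
  scores <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(lam[keep]),
                                                    length(keep))
  if (length(keep) > 0L) colnames(scores) <- paste0("PCo", seq_along(keep))
  pos_sum <- sum(lam[lam > tol])
  structure(list(eigenvalues = lam, scores = scores,
                 proportion = lam[keep] / pos_sum),
            class = "pcoa_result")
}

# ---- PLS-DA ----------------------------------------------------------------

# Multivariate-response (PLS2) NIPALS on centered data; returns enough to
# build coefficient matrices for any truncation a <= A.
pls2_fit <- function(X, Y, A, tol = 1e-10, max_iter = 500L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  Xd <- sweep(X, 2, x_mean); Yd <- sweep(Y, 2, y_mean)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Q <- matrix(0, m, A); Tm <- matrix(0, n, A)
  a_used <- 0L
  for (a in seq_len(A)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    if (sum(u^2) < 1e-12) break
    t_old <- rep(Inf, n)
    w <- NULL; tvec <- NULL; q <- NULL
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)
      wn <- sqrt(sum(w^2))
      if (wn < 1e-12) break
      w <- w / wn
      tvec <- Xd %*% w
      tt <- sum(tvec^2)
      if (tt < 1e-12) break
      q <- crossprod(Yd, tvec) / tt
      u <- Yd %*% q / sum(q^2)
      if (sqrt(sum((tvec - t_old)^2)) < tol * max(1, sqrt(tt))) break
      t_old <- tvec
    }
    if (is.null(tvec) || sum(tvec^2) < 1e-12 || sqrt(sum(w^2)) < 0.5) break
    tt <- sum(tvec^2)
    pl <- crossprod(Xd, tvec) / tt
    W[, a] <- w; P[, a] <- pl; Q[, a] <- q; Tm[, a] <- tvec
    Xd <- Xd - tcrossprod(tvec, pl)
    Yd <- Yd - tcrossprod(tvec, q)
    a_used <- a
  }
  if (a_used == 0L) stop("PLS-DA: no usable component")
  list(W = W[, 1:a_used, drop = FALSE], P = P[, 1:a_used, drop = FALSE],
       Q = Q[, 1:a_used, drop = FALSE], T = Tm[, 1:a_used, drop = FALSE],
       x_mean = x_mean, y_mean = y_mean, n_components = a_used)
}

pls2_predict <- function(fit, X_new, a) {
  a <- min(a, fit$n_components)
  Wa <- fit$W[, 1:a, drop = FALSE]
  Pa <- fit$P[, 1:a, drop = FALSE]
  Qa <- fit$Q[, 1:a, drop = FALSE]
  B <- Wa %*% solve(crossprod(Pa, Wa), t(Qa))
  sweep(sweep(as.matrix(X_new), 2, fit$x_mean) %*% B, 2, fit$y_mean, "+")
}

one_hot <- function(labels) {
  labels <- factor(labels)
  Y <- matrix(0, length(labels), nlevels(labels),
              dimnames = list(NULL, levels(labels)))
  Y[cbind(seq_along(labels), as.integer(labels))] <- 1
  Y
}

#' PLS discriminant analysis: fit on calibration data, predict labels
#'
#' Class labels are encoded as a one-hot indicator matrix, a multivariate
#' (PLS2) NIPALS model is fitted on centered data, and a new sample is
#' assigned to the class whose indicator column has the largest predicted
#' value (ties go to the lexicographically first class label).
#'
#' @param X_cal,labels_cal Calibration spectra matrix and class labels (at
#'   least 2 classes).
#' @param X_val Matrix of samples to classify (same columns as `X_cal`).
#' @param n_components Number of PLS components.
#' @return Character vector of predicted labels for the rows of `X_val`.
#' @export
plsda_fit_predict <- function(X_cal, labels_cal, X_val, n_components) {
  labels_cal <- factor(labels_cal)
  labels_cal <- droplevels(labels_cal)
  if (nlevels(labels_cal) < 2L) stop("need at least 2 classes in calibration")
  classes <- sort(levels(labels_cal))
  Y <- one_hot(factor(labels_cal, levels = classes))
  fit <- pls2_fit(as.matrix(X_cal), Y, n_components)
  Yhat <- pls2_predict(fit, X_val, n_components)
  classes[max.col(Yhat, ties.method = "first")]
}

#' Cohen's kappa from a confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = trace/total` and chance agreement
#' `p_e = sum(row_total * col_total) / total^2`. The degenerate case
#' `p_e = 1` (all mass in one cell) is defined as 0 with a warning.
#'
#' @param cm Square nonnegative confusion matrix (rows = reference,
#'   columns = predicted), total > 0.
#' @return Numeric kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("confusion matrix must be nonnegative")
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix total must be positive")
  p_o <- sum(diag(cm)) / total
  p_e <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - p_e) < 1e-12) {
    warning("degenerate confusion matrix (chance agreement = 1); kappa set to 0")
    return(0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' PLS-DA grid search over split ratios and component counts
#'
#' For every combination of calibration:validation ratio and component
#' count, runs `n_iter` stratified random splits (every class is represented
#' in each calibration set), classifies the validation split, and records
#' accuracy and Cohen's kappa. The best configuration is the highest mean
#' validation kappa; ties break to fewer components, then to the larger
#' calibration fraction. Component counts are capped at (calibration size -
#' 2); capped-out cells are skipped with a warning.
#'
#' @param X Samples x wavelengths matrix or `spectra_set`.
#' @param labels Class labels, at least 2 per class.
#' @param ratios Calibration fractions (0.5, 0.7, 0.8 correspond to 50:50,
#'   70:30, 80:20 calibration:validation splits).
#' @param component_grid Candidate component counts.
#' @param n_iter Random splits per grid cell.
#' @param seed Optional RNG seed (local).
#' @return A list of class `plsda_result`: `grid` (data frame: ratio, ncomp,
#'   acc_mean, acc_sd, kappa_mean, kappa_sd), `best` (row of `grid`),
#'   `best_confusion` (summed over the `n_iter` validation splits of the best
#'   cell), `classes`, `n_iter`.
#' @export
plsda_grid <- function(X, labels, ratios = c(0.5, 0.7, 0.8),
                       component_grid = 1:10, n_iter = 500L, seed = NULL) {
  if (inherits(X, "spectra_set")) X <- X$reflectance
  X <- as.matrix(X)
  labels <- factor(labels)
  classes <- sort(levels(labels))
  labels <- factor(labels, levels = classes)
  if (any(table(labels) < 2L)) stop("every class needs at least 2 samples")
  n <- nrow(X)
  component_grid <- sort(unique(as.integer(component_grid)))
  idx_by_class <- split(seq_len(n), labels)

  with_seed(seed, {
    grid_rows <- list()
    conf_by_cell <- list()
    for (ratio in ratios) {
      cal_counts <- vapply(idx_by_class, function(ix) {
        k <- as.integer(round(ratio * length(ix)))
        min(max(k, 1L), length(ix) - 1L)
      }, integer(1))
      cal_n <- sum(cal_counts)
      cap <- min(cal_n - 2L, ncol(X))
      comps <- component_grid[component_grid <= cap]
      if (length(comps) < length(component_grid)) {
        warning(sprintf(
          "ratio %.2f: component count capped at %d (calibration size %d)",
          ratio, cap, cal_n))
      }
      if (length(comps) == 0L) next
      A_max <- max(comps)
      acc <- matrix(NA_real_, n_iter, length(comps))
      kap <- matrix(NA_real_, n_iter, length(comps))
      conf <- rep(list(matrix(0, length(classes), length(classes),
                              dimnames = list(classes, classes))),
                  length(comps))
      for (b in seq_len(n_iter)) {
        cal_idx <- unlist(lapply(seq_along(idx_by_class), function(k) {
          ix <- idx_by_class[[k]]
          ix[sample.int(length(ix), cal_counts[k])]
        }), use.names = FALSE)
        val_idx <- setdiff(seq_len(n), cal_idx)
        fit <- pls2_fit(X[cal_idx, , drop = FALSE],
                        one_hot(labels[cal_idx]), A_max)
        for (j in seq_along(comps)) {
          Yhat <- pls2_predict(fit, X[val_idx, , drop = FALSE], comps[j])
          pred <- classes[max.col(Yhat, ties.method = "first")]
          cm <- table(factor(labels[val_idx], levels = classes),
                      factor(pred, levels = classes))
          acc[b, j] <- sum(diag(cm)) / sum(cm)
          kap[b, j] <- suppressWarnings(cohen_kappa(cm))
          conf[[j]] <- conf[[j]] + cm
        }
      }
      for (j in seq_along(comps)) {
        key <- sprintf("%.3f_%d", ratio, comps[j])
        grid_rows[[key]] <- data.frame(
          ratio = ratio, ncomp = comps[j],
          acc_mean = mean(acc[, j]), acc_sd = stats::sd(acc[, j]),
          kappa_mean = mean(kap[, j]), kappa_sd = stats::sd(kap[, j]))
        conf_by_cell[[key]] <- conf[[j]]
      }
    }
    if (length(grid_rows) == 0L) stop("no feasible grid cell")
    grid <- do.call(rbind, grid_rows)
    rownames(grid) <- NULL
    ord <- order(-grid$kappa_mean, grid$ncomp, -grid$ratio)
    best <- grid[ord[1L], , drop = FALSE]
    best_key <- sprintf("%.3f_%d", best$ratio, best$ncomp)
    structure(list(grid = grid, best = best,
                   best_confusion = conf_by_cell[[best_key]],
                   classes = classes, n_iter = as.integer(n_iter)),
              class = "plsda_result")
  })
}

#' @export
print.plsda_result <- function(x, ...) {
  cat(sprintf("PLS-DA grid (%d iterations/cell): best ratio %.0f:%.0f, %d component(s)\n",
              x$n_iter, 100 * x$best$ratio, 100 * (1 - x$best$ratio),
              x$best$ncomp))
  cat(sprintf("  validation accuracy %.3f +/- %.3f, kappa %.3f +/- %.3f\n",
              x$best$acc_mean, x$best$acc_sd, x$best$kappa_mean,
              x$best$kappa_sd))
  invisible(x)
}
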