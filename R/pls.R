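#' Fit a univariate partial least squares regression by NIPALS
#'
#' From-scratch PLS1: predictors (and the response) are centered and, by
#' default, scaled to unit variance; components are extracted one at a time
#' by the NIPALS alternation (weight, score, loading) with X-deflation.
#' Successive score vectors are mutually orthogonal by construction. For
#' `n_components = p` on a full-rank X the fit coincides with ordinary least
#' squares.
#'
#' @param X Numeric n x p matrix (rows = samples, columns = predictors,
#'   e.g., reflectance per wavelength). No missing values.
#' @param y Numeric response vector of length n.
#' @param n_components Number of latent components A, `A <= min(n - 1, p)`.
#' @param scale Autoscale predictors and response to unit variance (default
#'   TRUE). Standardized coefficients and VIP are best interpreted on
#'   autoscaled data.
#' @param deflate_y Also deflate the response (classical option; for PLS1 the
#'   fitted model is identical, so off by default).
#' @param tol Convergence tolerance for the NIPALS inner loop.
#' @param max_iter Maximum NIPALS iterations per component.
#' @return An object of class `pls_model`: centering/scaling constants,
#'   weights `W` (p x A, unit norm), x-loadings `P`, y-loadings `q`, scores
#'   `T`, `coefficients_std` (autoscaled units), `coefficients_raw` plus
#'   `intercept_raw` (original units), and bookkeeping fields.
#' @export
fit_pls <- function(X, y, n_components, scale = TRUE, deflate_y = FALSE,
                    tol = 1e-10, max_iter = 500L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n < 3L) stop("need at least 3 samples")
  if (anyNA(X) || anyNA(y) || !all(is.finite(X)) || !all(is.finite(y))) {
    stop("X and y must be finite with no missing values")
  }
  A <- as.integer(n_components)
  if (A < 1L || A > min(n - 1L, p)) {
    stop("n_components must be in 1..min(n - 1, p)")
  }

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  if (scale) {
    x_scale <- apply(X, 2, stats::sd)
    zero_var <- x_scale < .Machine$double.eps^0.5
    if (any(zero_var)) {
      warning(sprintf("%d zero-variance predictor(s); their coefficients are 0",
                      sum(zero_var)))
      x_scale[zero_var] <- 1
    }
    y_scale <- stats::sd(y)
    if (y_scale < .Machine$double.eps^0.5) stop("constant response")
  } else {
    x_scale <- rep(1, p)
    y_scale <- 1
  }
  Xd <- sweep(sweep(X, 2, x_mean, "-"), 2, x_scale, "/")
  yd <- (y - y_mean) / y_scale
  Xc <- Xd  # keep the (scaled) training matrix for fitted values

  W <- matrix(0, p, A)
  P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  a_used <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xd, yd)  # for univariate y NIPALS converges in one pass,
    wn <- sqrt(sum(w^2))    # but iterate to honour the general algorithm
    if (wn < 1e-12) {
      warning(sprintf("rank collapse at component %d; using %d component(s)",
                      a, a - 1L))
      break
    }
    w <- w / wn
    t_old <- rep(Inf, n)
    it <- 0L
    repeat {
      tvec <- Xd %*% w
      if (sqrt(sum((tvec - t_old)^2)) < tol * max(1, sqrt(sum(tvec^2))) ||
          it >= max_iter) break
      t_old <- tvec
      w <- crossprod(Xd, yd)
      w <- w / sqrt(sum(w^2))
      it <- it + 1L
    }
    tt <- sum(tvec^2)
    if (tt < 1e-12) {
      warning(sprintf("degenerate score at component %d; using %d component(s)",
                      a, a - 1L))
      break
    }
    pl <- crossprod(Xd, tvec) / tt
    q[a] <- sum(yd * tvec) / tt
    W[, a] <- w
    P[, a] <- pl
    Tm[, a] <- tvec
    Xd <- Xd - tcrossprod(tvec, pl)
    if (deflate_y) yd <- yd - q[a] * tvec
    a_used <- a
  }
  if (a_used == 0L) stop("no usable PLS component (X'y is numerically zero)")
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Tm <- Tm[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]

  b_std <- pls_coefficients(W, P, q, a_used)
  b_raw <- y_scale * b_std / x_scale
  model <- structure(list(
    n_components = a_used,
    x_mean = x_mean, x_scale = x_scale,
    y_mean = y_mean, y_scale = y_scale,
    weights = W, x_loadings = P, y_loadings = q, scores = Tm,
    coefficients_std = as.numeric(b_std),
    coefficients_raw = as.numeric(b_raw),
    intercept_raw = y_mean - sum(b_raw * x_mean),
    scale = scale,
    predictor_names = colnames(X),
    n = n, p = p
  ), class = "pls_model")
  model
}

# Regression vector (scaled units) truncated at `a` components:
# b = W (P'W)^{-1} q. P'W is unit upper triangular for NIPALS.
pls_coefficients <- function(W, P, q, a) {
  Wa <- W[, seq_len(a), drop = FALSE]
  Pa <- P[, seq_len(a), drop = FALSE]
  Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)])
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model: %d component(s), p = %d, n = %d, %s>\n",
              x$n_components, x$p, x$n,
              if (x$scale) "autoscaled" else "centered only"))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Matrix with the same columns (wavelengths) as the training
#'   X; a `spectra_set` is accepted and its reflectance matrix used.
#' @param n_components Use a truncated model with fewer components
#'   (default: all fitted components).
#' @param ... Unused.
#' @return Numeric vector of predictions in original response units.
#' @export
predict.pls_model <- function(object, newdata, n_components = NULL, ...) {
  if (inherits(newdata, "spectra_set")) newdata <- newdata$reflectance
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) {
    stop(sprintf("newdata has %d columns; model expects %d",
                 ncol(newdata), object$p))
  }
  if (!is.null(object$predictor_names) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$predictor_names)) {
    stop("newdata column names do not match the model's predictors")
  }
  A <- n_components %||% object$n_components
  if (A < 1L || A > object$n_components) stop("invalid n_components")
  b <- if (A == object$n_components) object$coefficients_std else
    pls_coefficients(object$weights, object$x_loadings, object$y_loadings, A)
  Xs <- sweep(sweep(newdata, 2, object$x_mean, "-"), 2, object$x_scale, "/")
  as.numeric(object$y_mean + object$y_scale * (Xs %*% b))
}

#' Leave-one-out PRESS curve
#'
#' For each candidate component count A, the predicted residual sum of
#' squares PRESS(A) = sum_i (y_i - yhat_{-i}(A))^2, where yhat_{-i} comes
#' from a model refit without sample i. Each held-out refit is done once at
#' the largest A and truncated, which is exact for NIPALS.
#'
#' @param X,y Training data as in [fit_pls()].
#' @param max_components Largest component count to evaluate; silently
#'   truncated (with a warning) to `min(n - 2, p)`.
#' @param scale Passed to [fit_pls()].
#' @return A data frame of class `press_curve` with columns `components` and
#'   `press`.
#' @export
loo_press <- function(X, y, max_components, scale = TRUE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 samples for leave-one-out")
  A_max <- as.integer(max_components)
  cap <- min(n - 2L, ncol(X))
  if (A_max > cap) {
    warning(sprintf("max_components truncated from %d to %d", A_max, cap))
    A_max <- cap
  }
  sq_err <- matrix(NA_real_, n, A_max)
  for (i in seq_len(n)) {
    fit <- suppressWarnings(
      fit_pls(X[-i, , drop = FALSE], y[-i], A_max, scale = scale))
    for (a in seq_len(min(A_max, fit$n_components))) {
      yhat <- predict(fit, X[i, , drop = FALSE], n_components = a)
      sq_err[i, a] <- (y[i] - yhat)^2
    }
  }
  # carry the last available column forward if some refits lost rank
  for (a in seq_len(A_max)[-1]) {
    miss <- is.na(sq_err[, a])
    sq_err[miss, a] <- sq_err[miss, a - 1L]
  }
  out <- data.frame(components = seq_len(A_max), press = colSums(sq_err))
  class(out) <- c("press_curve", "data.frame")
  out
}

#' Select the number of PLS components from a PRESS curve
#'
#' @param curve A `press_curve` (or data frame with `components`, `press`).
#' @param rule `"onesigma"` (default): smallest A whose PRESS is within
#'   `tol` (relative) of the minimum - the parsimonious choice guarding
#'   against overfitting; `"min"`: the argmin. Ties break to the smaller A.
#' @param tol Relative tolerance for the `"onesigma"` rule.
#' @return Integer component count.
#' @export
select_ncomp <- function(curve, rule = c("onesigma", "min"), tol = 0.05) {
  rule <- match.arg(rule)
  stopifnot(nrow(curve) >= 1L, all(is.finite(curve$press)))
  press <- curve$press
  comps <- curve$components
  if (rule == "min") {
    return(as.integer(comps[which.min(press)]))
  }
  thr <- min(press) * (1 + tol)
  as.integer(comps[which(press <= thr)[1L]])
}

#' Variable importance in projection (VIP)
#'
#' Wold's VIP: `VIP_j = sqrt(p * sum_a SSY_a * (w_ja / ||w_a||)^2 / sum_a
#' SSY_a)` with `SSY_a = q_a^2 * t_a' t_a`, the share of response variance
#' explained by component a. Wavelengths with VIP above ~1 contribute more
#' than average to the fit; the profile satisfies `sum(VIP^2) = p`.
#'
#' @param model A fitted `pls_model`.
#' @return Numeric vector of length p (named by predictor when available),
#'   class `vip_profile`.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  W <- model$weights
  ssy <- model$y_loadings^2 * colSums(model$scores^2)
  if (sum(ssy) < 1e-300) stop("degenerate model: no explained response variance")
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  v <- sqrt(model$p * as.numeric(wn2 %*% ssy) / sum(ssy))
  names(v) <- model$predictor_names
  class(v) <- "vip_profile"
  v
}

#' Standardized PLS regression coefficients
#'
#' Coefficients for the regression of the autoscaled (centered, unit
#' variance) response on autoscaled predictors; invariant under affine
#' rescaling of the raw inputs. For a model fitted with `scale = TRUE` these
#' are the internally stored coefficients; otherwise the raw coefficients
#' are rescaled by the training standard deviations.
#'
#' @param model A fitted `pls_model`.
#' @return Numeric vector of length p.
#' @export
standardized_coefficients <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  if (model$scale) {
    b <- model$coefficients_std
  } else {
    sx <- apply_sd_from_model(model)
    b <- model$coefficients_raw * sx$x_sd / sx$y_sd
  }
  names(b) <- model$predictor_names
  b
}

# For unscaled fits the training sds are not stored; reconstruct from the
# stored scores/loadings is not possible, so we stash sds at fit time via
# x_scale/y_scale only when scaling. Fall back to unit sds with a warning.
apply_sd_from_model <- function(model) {
  warning("model was fitted without autoscaling; standardized coefficients ",
          "use the stored (unit) scales")
  list(x_sd = model$x_scale, y_sd = model$y_scale)
}

#' Serialize / restore a PLS model as a JSON document
#'
#' @param model A `pls_model`.
#' @param path Output (input) file path.
#' @return `write_pls_model` returns `path` invisibly; `read_pls_model`
#'   returns the restored `pls_model`.
#' @export
write_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  obj <- unclass(model)
  obj$weights <- unname(obj$weights)
  obj$x_loadings <- unname(obj$x_loadings)
  obj$scores <- unname(obj$scores)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("weights", "x_loadings", "scores")) obj[[f]] <- as.matrix(obj[[f]])
  for (f in c("x_mean", "x_scale", "y_loadings", "coefficients_std",
              "coefficients_raw")) obj[[f]] <- as.numeric(obj[[f]])
  structure(obj, class = "pls_model")
}
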