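#' Spatial neighbour weights
#'
#' Builds the neighbour-weight matrix W used by the spatially explicit
#' models. Weights are inverse distance by default; `"knn"` links each unit
#' to its k nearest neighbours; `"gabriel"` links pairs whose diametral
#' circle contains no third unit. Row standardization (default) rescales
#' each row to sum to 1 (isolated units keep all-zero rows).
#'
#' @param coords numeric matrix (n x 2) of planar coordinates; duplicate
#'   coordinates are rejected.
#' @param scheme `"inverse_distance"` (default), `"knn"` or `"gabriel"`.
#' @param row_standardize logical, default TRUE.
#' @param k neighbours for `"knn"` (default 4).
#' @return object of class `spatial_weights`: list with `W`, `scheme`,
#'   `row_standardized`.
#' @export
spatial_weights <- function(coords, scheme = c("inverse_distance", "knn", "gabriel"),
                            row_standardize = TRUE, k = 4) {
  scheme <- match.arg(scheme)
  coords <- as.matrix(coords)
  stop_if_not(is.numeric(coords) && ncol(coords) == 2 && all(is.finite(coords)),
              "`coords` must be a finite n x 2 numeric matrix")
  n <- nrow(coords)
  stop_if_not(n >= 2, "need at least 2 spatial units")
  d <- as.matrix(dist(coords))
  if (any(d[upper.tri(d)] == 0)) stop("duplicate coordinates: distances of 0", call. = FALSE)
  W <- switch(scheme,
    inverse_distance = {
      w <- 1 / d
      diag(w) <- 0
      w
    },
    knn = {
      stop_if_not(k >= 1 && k < n, "`k` must be in [1, n - 1]")
      w <- matrix(0, n, n)
      for (i in seq_len(n)) {
        nb <- order(d[i, -i])[seq_len(k)]
        w[i, setdiff(seq_len(n), i)[nb]] <- 1
      }
      w
    },
    gabriel = {
      w <- matrix(0, n, n)
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          others <- setdiff(seq_len(n), c(i, j))
          ok <- all(d[i, others]^2 + d[j, others]^2 >= d[i, j]^2)
          if (ok) w[i, j] <- w[j, i] <- 1
        }
      }
      w
    })
  if (row_standardize) {
    rs <- rowSums(W)
    W <- W / ifelse(rs == 0, 1, rs)
  }
  dimnames(W) <- list(rownames(coords), rownames(coords))
  structure(list(W = W, scheme = scheme, row_standardized = row_standardize),
            class = "spatial_weights")
}

#' Residualize a metric on a covariate
#'
#' Ordinary least squares residuals of `metric` on `covariate` with an
#' intercept; used to strip pollinator abundance/richness effects from
#' network metrics before relating them to performance (e.g. connectance
#' residualized on pollinator abundance, clustering on richness).
#'
#' @param metric,covariate numeric vectors of equal length (n >= 3).
#' @return residual vector (mean 0).
#' @export
residualize <- function(metric, covariate) {
  stop_if_not(length(metric) == length(covariate) && length(metric) >= 3,
              "need equal-length vectors with n >= 3")
  stop_if_not(all(is.finite(metric)) && all(is.finite(covariate)),
              "NaN/Inf values are not allowed")
  as.numeric(stats::lm.fit(cbind(1, covariate), metric)$residuals)
}

as_weight_matrix <- function(W) {
  if (inherits(W, "spatial_weights")) W$W else as.matrix(W)
}

# Central-difference Hessian of scalar function f at x.
num_hessian <- function(f, x, h = NULL) {
  p <- length(x)
  if (is.null(h)) h <- 1e-4 * (abs(x) + 1)
  H <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- ej <- numeric(p); ei[i] <- h[i]; ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' Fit a lagged-predictor spatial autoregressive model (SAR_mix)
#'
#' Fits `y = rho W y + X beta + W X gamma + epsilon` by maximum likelihood:
#' the autoregression parameter rho is profiled over its feasible interval
#' (bounded by the reciprocal extreme eigenvalues of W, which enter the
#' log-Jacobian `log |I - rho W|`), and beta/gamma follow by least squares on
#' the spatially filtered response. Standard errors come from the inverse
#' observed information (numeric Hessian of the full log-likelihood); with
#' `rho` fixed (e.g. `rho = 0`) the fit collapses to OLS on `[X, WX]` with
#' classical standard errors.
#'
#' @param y numeric response vector (one value per spatial unit).
#' @param X predictor matrix or data.frame (without intercept).
#' @param W a [spatial_weights()] object or weight matrix.
#' @param lag_predictors include the `W X gamma` term (default TRUE).
#' @param rho NULL to estimate by ML, or a fixed value.
#' @param perms if > 0, additionally compute permutation p-values for the
#'   slopes by refitting on row-permuted responses.
#' @param seed seed for the permutation test.
#' @return object of class `sar_fit`: list with `rho`, `rho_se`,
#'   `coefficients`, `se`, `z`, `p_value`, `perm_p` (or NULL), `sigma2`,
#'   `loglik`, `feasible`, `n`.
#' @export
fit_sar_mix <- function(y, X, W, lag_predictors = TRUE, rho = NULL,
                        perms = 0, seed = NULL) {
  Wm <- as_weight_matrix(W)
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  stop_if_not(nrow(X) == n && nrow(Wm) == n && ncol(Wm) == n,
              "dimensions of y, X and W must agree")
  stop_if_not(all(is.finite(y)) && all(is.finite(X)), "NaN/Inf in y or X")
  Z <- cbind(`(Intercept)` = 1, X)
  if (lag_predictors) {
    WX <- Wm %*% X
    colnames(WX) <- paste0("lag_", colnames(X))
    Z <- cbind(Z, WX)
  }
  k <- ncol(Z)
  stop_if_not(n > k + 1, "more parameters than observations")
  if (n <= 10) warning("n <= 10 spatial units: SAR estimates are fragile; ",
                       "interpret structurally, not inferentially")
  qrz <- qr(Z)
  if (qrz$rank < k) {
    bad <- colnames(Z)[qrz$pivot[(qrz$rank + 1):k]]
    stop("collinear design columns: ", paste(bad, collapse = ", "), call. = FALSE)
  }

  Wy <- as.numeric(Wm %*% y)
  b0 <- qr.coef(qrz, y);  e0 <- y - Z %*% b0
  bd <- qr.coef(qrz, Wy); ed <- Wy - Z %*% bd
  sse <- function(r) sum((e0 - r * ed)^2)

  ev <- eigen(Wm, only.values = TRUE)$values
  if (is.complex(ev)) ev <- Re(ev[abs(Im(ev)) < 1e-8])
  lo <- if (min(ev) < 0) 1 / min(ev) else -Inf
  hi <- if (max(ev) > 0) 1 / max(ev) else Inf
  lo <- max(lo, -5); hi <- min(hi, 5)

  loglik_at <- function(r, s2 = NULL, coefs = NULL) {
    e <- if (is.null(coefs)) sqrt(sse(r)) else
      sqrt(sum((y - r * Wy - Z %*% coefs)^2))
    s2 <- s2 %||% (e^2 / n)
    -n / 2 * log(2 * pi * s2) + sum(log(abs(1 - r * ev))) - e^2 / (2 * s2)
  }

  if (is.null(rho)) {
    eps <- 1e-6 * (hi - lo)
    opt <- optimize(function(r) -(-n / 2 * log(sse(r) / n) + sum(log(abs(1 - r * ev)))),
                    lower = lo + eps, upper = hi - eps, tol = 1e-9)
    rho_hat <- opt$minimum
    coefs <- as.numeric(b0 - rho_hat * bd)
    sigma2 <- sse(rho_hat) / n
    theta <- c(rho_hat, coefs, log(sigma2))
    negll <- function(th) {
      -(-n / 2 * log(2 * pi) - n / 2 * th[length(th)] +
          sum(log(abs(1 - th[1] * ev))) -
          sum((y - th[1] * Wy - Z %*% th[2:(k + 1)])^2) / (2 * exp(th[length(th)])))
    }
    H <- num_hessian(negll, theta)
    cov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, k + 2, k + 2))
    ses <- sqrt(pmax(diag(cov), 0))
    rho_se <- ses[1]
    se <- ses[2:(k + 1)]
  } else {
    rho_hat <- rho
    coefs <- as.numeric(b0 - rho_hat * bd)
    resid <- y - rho_hat * Wy - Z %*% coefs
    sigma2 <- sum(resid^2) / (n - k)
    ZtZinv <- chol2inv(qr.R(qrz))
    se <- sqrt(diag(ZtZinv) * sigma2)
    rho_se <- NA_real_
  }
  names(coefs) <- names(se) <- colnames(Z)
  z <- coefs / se
  pv <- 2 * pnorm(-abs(z))
  ll <- loglik_at(rho_hat, sigma2, coefs)

  perm_p <- NULL
  if (perms > 0) {
    obs <- abs(coefs[-1])
    hits <- numeric(length(obs))
    with_seed(seed, {
      for (b in seq_len(perms)) {
        yp <- y[sample.int(n)]
        fp <- fit_sar_mix(yp, X, Wm, lag_predictors = lag_predictors,
                          rho = if (is.null(rho)) NULL else rho, perms = 0)
        hits <- hits + (abs(fp$coefficients[-1]) >= obs)
      }
    })
    perm_p <- (1 + hits) / (perms + 1)
  }

  structure(list(rho = rho_hat, rho_se = rho_se, coefficients = coefs, se = se,
                 z = z, p_value = pv, perm_p = perm_p, sigma2 = sigma2,
                 loglik = ll, feasible = c(lower = lo, upper = hi), n = n,
                 fixed_rho = !is.null(rho)),
            class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf("<sar_fit> n=%d rho=%.4f%s logLik=%.3f\n", x$n, x$rho,
              if (is.na(x$rho_se)) " (fixed)" else sprintf(" (se %.4f)", x$rho_se),
              x$loglik))
  print(data.frame(estimate = x$coefficients, se = x$se, z = x$z, p = x$p_value))
  invisible(x)
}
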