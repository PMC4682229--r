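#' Lasso regularization path (least-angle implementation)
#'
#' Computes the full piecewise-linear lasso coefficient path in the
#' penalty \eqn{\lambda}, recording every knot at which a predictor
#' enters or leaves the active set. The solution satisfies the lasso
#' KKT conditions at every knot: inactive predictors have
#' \eqn{|x_j^T r| \le \lambda}, active predictors have
#' \eqn{x_j^T r = \lambda \, \mathrm{sign}(\beta_j)}. Predictors are
#' standardized to zero mean and unit variance and the response centered
#' before the path is traced (the model carries no intercept beyond this
#' centering).
#'
#' @param X Numeric matrix, samples x predictors (column names used as
#'   predictor identifiers).
#' @param y Numeric response vector.
#' @param standardize Standardize columns of `X` (default `TRUE`). Set
#'   `FALSE` when `X` is already scaled (e.g. orthonormal designs).
#' @param max_steps Maximum number of entry events to trace (default:
#'   the full path down to \eqn{\lambda = 0}).
#' @return An object of class `astro_lasso_path`: list with `knots`
#'   (decreasing penalty values, last one 0 when the path completed),
#'   `beta` (predictors x knots coefficient matrix, standardized
#'   coordinates), `events` (tibble: `step`, `lambda`, `predictor`,
#'   `action` enter/drop, `sign`), `X` (standardized design), `y`
#'   (centered response), `predictors`, `completed` (logical).
#' @export
lasso_path <- function(X, y, standardize = TRUE, max_steps = Inf) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (n < 2) abort_astro("need at least two samples", "astronet_config_error")
  mu <- colMeans(X)
  sds <- sqrt(colSums((X - rep(mu, each = n))^2) / (n - 1))
  if (any(sds == 0)) {
    abort_astro(paste0("constant predictor(s): ",
                       paste(colnames(X)[sds == 0], collapse = ", ")),
                "astronet_config_error")
  }
  if (standardize) {
    X <- (X - rep(mu, each = n)) / rep(sds, each = n)
  }
  yc <- y - mean(y)
  core <- lar_core(X, yc, max_steps = max_steps)
  ev <- tibble::tibble(
    step = seq_along(core$ev_lambda),
    lambda = unname(core$ev_lambda),
    predictor = colnames(X)[core$ev_pred],
    action = ifelse(core$ev_enter, "enter", "drop"),
    sign = unname(core$ev_sign)
  )
  beta <- core$beta
  rownames(beta) <- colnames(X)
  structure(list(knots = core$knots, beta = beta, events = ev, X = X,
                 y = yc, predictors = colnames(X),
                 completed = core$completed),
            class = "astro_lasso_path")
}

# Core least-angle lasso path on a pre-standardized design and centered
# response. Plain vectors only (called in tight Monte-Carlo loops).
# Stops early once lambda reaches lambda_min (recording the exact
# solution there) or after max_steps entry events.
lar_core <- function(X, yc, max_steps = Inf, lambda_min = 0) {
  n <- nrow(X); p <- ncol(X)
  tol <- 1e-12
  max_active <- min(n - 1, p)
  beta <- numeric(p)
  active <- integer(0)
  s <- numeric(0)
  ev_lambda <- numeric(0); ev_pred <- integer(0)
  ev_enter <- logical(0); ev_sign <- numeric(0)
  knots <- numeric(0); betas <- list()
  completed <- FALSE

  c_all <- drop(crossprod(X, yc))
  lambda <- max(abs(c_all))
  if (lambda < tol || lambda <= lambda_min) {
    return(list(knots = numeric(0),
                beta = matrix(0, p, 0), ev_lambda = numeric(0),
                ev_pred = integer(0), ev_enter = logical(0),
                ev_sign = numeric(0), completed = TRUE))
  }
  j <- which.max(abs(c_all))
  active <- j; s <- sign(c_all[j])
  ev_lambda <- lambda; ev_pred <- j; ev_enter <- TRUE; ev_sign <- s
  knots <- lambda; betas[[1]] <- beta
  n_entries <- 1L

  repeat {
    XA <- X[, active, drop = FALSE]
    G <- crossprod(XA)
    w <- tryCatch(drop(solve(G, s)), error = function(e) NULL)
    if (is.null(w)) break
    u <- drop(XA %*% w)
    a <- drop(crossprod(X, u))
    r <- yc - drop(XA %*% beta[active])
    cj <- drop(crossprod(X, r))

    gamma_enter <- Inf; j_enter <- NA_integer_
    if (length(active) < max_active && n_entries < max_steps) {
      inact <- setdiff(seq_len(p), active)
      if (length(inact) > 0) {
        g1 <- (lambda - cj[inact]) / (1 - a[inact])
        g2 <- (lambda + cj[inact]) / (1 + a[inact])
        g1[g1 <= tol | !is.finite(g1)] <- Inf
        g2[g2 <= tol | !is.finite(g2)] <- Inf
        gmin <- pmin(g1, g2)
        k <- which.min(gmin)
        gamma_enter <- gmin[k]; j_enter <- inact[k]
      }
    }
    gamma_drop <- Inf; j_drop <- NA_integer_
    gd <- -beta[active] / w
    gd[gd <= tol | !is.finite(gd)] <- Inf
    kd <- which.min(gd)
    if (is.finite(gd[kd])) { gamma_drop <- gd[kd]; j_drop <- active[kd] }

    gamma_stop <- lambda - lambda_min     # reach lambda_min
    gamma <- min(gamma_enter, gamma_drop, gamma_stop)
    beta[active] <- beta[active] + gamma * w
    lambda <- lambda - gamma

    if (gamma == gamma_stop || lambda < tol) {
      lambda <- max(lambda_min, 0)
      knots <- c(knots, lambda)
      betas[[length(betas) + 1L]] <- beta
      completed <- TRUE
      break
    }
    if (gamma == gamma_drop) {
      beta[j_drop] <- 0
      keep <- active != j_drop
      active <- active[keep]; s <- s[keep]
      ev_lambda <- c(ev_lambda, lambda); ev_pred <- c(ev_pred, j_drop)
      ev_enter <- c(ev_enter, FALSE); ev_sign <- c(ev_sign, 0)
    } else {
      r <- yc - drop(X[, active, drop = FALSE] %*% beta[active])
      sgn <- sign(sum(X[, j_enter] * r))
      active <- c(active, j_enter); s <- c(s, sgn)
      n_entries <- n_entries + 1L
      ev_lambda <- c(ev_lambda, lambda); ev_pred <- c(ev_pred, j_enter)
      ev_enter <- c(ev_enter, TRUE); ev_sign <- c(ev_sign, sgn)
    }
    knots <- c(knots, lambda)
    betas[[length(betas) + 1L]] <- beta

    if (n_entries >= max_steps) break
    if (length(active) == 0) break
  }

  list(knots = knots, beta = do.call(cbind, betas), ev_lambda = ev_lambda,
       ev_pred = ev_pred, ev_enter = ev_enter, ev_sign = ev_sign,
       completed = completed)
}

# Interpolate a core path at penalty lambda (standardized coordinates).
core_coef_at <- function(knots, beta, lambda) {
  K <- length(knots)
  if (K == 0 || lambda >= knots[1]) return(numeric(nrow(beta) %||% 0))
  if (lambda <= knots[K]) return(beta[, K])
  k <- max(which(knots >= lambda))
  l1 <- knots[k]; l2 <- knots[k + 1]
  f <- (l1 - lambda) / (l1 - l2)
  beta[, k] + f * (beta[, k + 1] - beta[, k])
}

#' Lasso coefficients at an arbitrary penalty value
#'
#' Interpolates the piecewise-linear path. Above the first knot all
#' coefficients are zero; below the last computed knot of a truncated
#' path the last coefficients are held.
#'
#' @param path An `astro_lasso_path`.
#' @param lambda Penalty value (>= 0).
#' @return Named numeric vector of coefficients (standardized
#'   coordinates).
#' @export
coef_at <- function(path, lambda) {
  p <- length(path$predictors)
  if (length(path$knots) == 0) {
    return(stats::setNames(numeric(p), path$predictors))
  }
  b <- core_coef_at(path$knots, path$beta, lambda)
  if (length(b) == 0) b <- numeric(p)
  stats::setNames(b, path$predictors)
}

#' Covariance significance test along a lasso path
#'
#' For the k-th predictor entry at knot \eqn{\lambda_k}, the statistic is
#' \deqn{T_k = (\langle y, X\beta(\lambda_{k+1})\rangle -
#'       \langle y, X_A \tilde\beta_A(\lambda_{k+1})\rangle)/\sigma^2,}
#' where \eqn{A} is the active set just before the entry and
#' \eqn{\tilde\beta_A} is the lasso solution using only those
#' predictors. Under the null that all signal predictors are already in
#' \eqn{A}, \eqn{T_k} is asymptotically standard exponential, so
#' \eqn{p = \exp(-T_k)}. Each predictor is scored at its first entry;
#' re-entries after a drop are not re-scored. On a truncated path
#' (finite `max_steps`) entries without a following knot are skipped.
#'
#' @param path An `astro_lasso_path` (must carry its design and
#'   response, as returned by [lasso_path()]).
#' @param sigma2 Noise variance \eqn{\sigma^2 > 0} (see
#'   [estimate_noise_variance()]).
#' @return Tibble with one row per first entry: `predictor`, `lambda`,
#'   `lambda_next`, `statistic`, `p`.
#' @export
covariance_test <- function(path, sigma2) {
  if (sigma2 <= 0) abort_astro("sigma2 must be positive",
                               "astronet_config_error")
  ev <- path$events
  entries <- which(ev$action == "enter" & !duplicated(ev$predictor))
  X <- path$X; yc <- path$y
  m <- length(entries)
  predictor <- character(m); lambda <- numeric(m)
  lambda_next <- numeric(m); statistic <- numeric(m)
  keep <- logical(m)
  for (q in seq_len(m)) {
    i <- entries[q]
    lam <- ev$lambda[i]
    later <- which(path$knots < lam - 1e-15)
    if (length(later) == 0) {
      if (!path$completed) next
      lam_next <- 0
    } else {
      lam_next <- path$knots[later[1]]
    }
    beta_full <- core_coef_at(path$knots, path$beta, lam_next)
    fit_full <- drop(X %*% beta_full)
    prior <- seq_len(i - 1)
    act <- integer(0)
    idx <- match(ev$predictor, path$predictors)
    for (k in prior) {
      act <- if (ev$action[k] == "enter") union(act, idx[k]) else
        setdiff(act, idx[k])
    }
    fit_red <- if (length(act) == 0) 0 else {
      Xa <- X[, act, drop = FALSE]
      sub <- lar_core(Xa, yc, lambda_min = lam_next)
      drop(Xa %*% core_coef_at(sub$knots, sub$beta, lam_next))
    }
    predictor[q] <- ev$predictor[i]
    lambda[q] <- lam
    lambda_next[q] <- lam_next
    statistic[q] <- (sum(yc * fit_full) - sum(yc * fit_red)) / sigma2
    keep[q] <- TRUE
  }
  tibble::tibble(predictor = predictor[keep], lambda = lambda[keep],
                 lambda_next = lambda_next[keep],
                 statistic = statistic[keep],
                 p = exp(-pmax(statistic[keep], 0)))
}

#' Estimate the noise variance of a sparse linear model
#'
#' When the sample size exceeds the number of predictors plus one, the
#' residual variance of the full least-squares fit (intercept included,
#' degrees of freedom `n - p - 1`) is used. Otherwise the support
#' selected at a cross-validated penalty is refit by least squares and
#' its df-corrected residual variance returned. Numerically exact fits
#' are floored at `1e-8` with a warning so noiseless toys stay testable.
#'
#' @param X Numeric design matrix, samples x predictors.
#' @param y Numeric response.
#' @param seed Seed for the cross-validation fold assignment (only used
#'   in the high-dimensional branch).
#' @return The estimated variance (scalar).
#' @export
estimate_noise_variance <- function(X, y, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 3) abort_astro("need at least three samples",
                         "astronet_config_error")
  if (n > p + 1) {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
    dfres <- n - fit$rank
    if (dfres <= 0) abort_astro("degenerate design: no residual degrees of freedom",
                                "astronet_config_error")
    sigma2 <- sum(fit$residuals^2) / dfres
  } else {
    set.seed(seed)
    foldid <- sample(rep(seq_len(10), length.out = n))
    cv <- glmnet::cv.glmnet(X, y, foldid = foldid, intercept = TRUE)
    b <- as.numeric(stats::coef(cv, s = "lambda.1se"))[-1]
    sel <- which(b != 0)
    if (length(sel) >= n - 1) sel <- sel[seq_len(max(0, n - 2))]
    fit <- stats::lm.fit(cbind(1, X[, sel, drop = FALSE]), y)
    dfres <- n - fit$rank
    sigma2 <- sum(fit$residuals^2) / max(dfres, 1)
  }
  if (sigma2 < 1e-8) {
    warning("numerically exact fit: flooring noise variance at 1e-8")
    sigma2 <- 1e-8
  }
  sigma2
}
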