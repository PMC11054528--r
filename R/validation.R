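#' Coefficient of determination and root-mean-square error
#'
#' \code{r2 = 1 - SS_res / SS_tot} about the observed mean and
#' \code{rmse = sqrt(SS_res / n)}. The n-denominator RMSE matches the
#' RMSE_tr / RMSE_P convention of QSAR model reporting; set
#' \code{df_adjust = TRUE} for the residual-degrees-of-freedom variant
#' \code{sqrt(SS_res / (n - p - 1))}.
#'
#' @param observed,predicted equal-length numeric vectors, n >= 2.
#' @param df_adjust use \code{n - p - 1} in the RMSE denominator.
#' @param p number of predictors (needed only when \code{df_adjust}).
#' @return List with \code{r2} and \code{rmse}.
#' @export
r2_rmse <- function(observed, predicted, df_adjust = FALSE, p = NULL) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed values have zero variance; R2 undefined")
  denom <- if (df_adjust) {
    if (is.null(p)) stop("df_adjust = TRUE requires p")
    length(observed) - p - 1
  } else length(observed)
  list(r2 = 1 - ss_res / ss_tot, rmse = sqrt(ss_res / denom))
}

#' Leave-one-out cross-validated Q2
#'
#' Each compound is predicted by the model refit without it;
#' \code{q2 = 1 - PRESS / SS_tot}. Two routes are implemented: literal
#' refitting, and the exact hat-matrix shortcut for OLS
#' (\code{press residual = residual / (1 - leverage)}). They agree to
#' machine precision; the shortcut is the default because the genetic
#' algorithm evaluates Q2 thousands of times.
#'
#' @param X numeric matrix of predictors (no intercept column).
#' @param y response vector.
#' @param method \code{"hat"} (default) or \code{"refit"}.
#' @return Q2_LOO value (at most 1; negative when the model predicts worse
#'   than the training mean).
#' @export
q2_loo <- function(X, y, method = c("hat", "refit")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n == length(y), n > ncol(X) + 2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("response has zero variance; Q2 undefined")
  press <- if (method == "hat") press_hat(X, y) else press_refit(X, y)
  1 - press / ss_tot
}

press_hat <- function(X, y) {
  Xi <- cbind(1, X)
  qr_fit <- qr(Xi)
  if (qr_fit$rank < ncol(Xi)) stop("singular design in leave-one-out fit")
  res <- qr.resid(qr_fit, y)
  h <- rowSums(qr.Q(qr_fit)[, seq_len(qr_fit$rank), drop = FALSE]^2)
  if (any(h >= 1 - 1e-12))
    stop("a leverage of 1: some leave-one-out fit is singular")
  sum((res / (1 - h))^2)
}

press_refit <- function(X, y) {
  n <- nrow(X)
  press <- 0
  for (i in seq_len(n)) {
    fit <- stats::lm.fit(cbind(1, X[-i, , drop = FALSE]), y[-i])
    if (any(is.na(fit$coefficients)))
      stop("singular design when leaving out observation ", i)
    pred <- sum(c(1, X[i, ]) * fit$coefficients)
    press <- press + (y[i] - pred)^2
  }
  press
}

#' Lin's concordance correlation coefficient
#'
#' \code{ccc = 2 cov(o, p) / (var(o) + var(p) + (mean(o) - mean(p))^2)}
#' with sample (n-denominator) moments -- the standard Lin definition.
#' Unlike Pearson's r, the CCC penalizes location and scale shift between
#' observed and predicted values, so it is 1 only for exact agreement.
#'
#' @param observed,predicted equal-length numeric vectors, n >= 2.
#' @return CCC in [-1, 1].
#' @export
#' @examples
#' ccc(c(1, 2, 3), c(2, 3, 4))  # 4/7
ccc <- function(observed, predicted) {
  n <- length(observed)
  stopifnot(n == length(predicted), n >= 2)
  mo <- mean(observed); mp <- mean(predicted)
  vo <- mean((observed - mo)^2)
  vp <- mean((predicted - mp)^2)
  cv <- mean((observed - mo) * (predicted - mp))
  denom <- vo + vp + (mo - mp)^2
  if (denom == 0) stop("both vectors constant and equal; CCC undefined")
  2 * cv / denom
}

#' Williams-plot applicability domain
#'
#' Leverage of a point x is \code{h = x' (X'X)^-1 x} with the intercept
#' column included, computed against the training design. The critical
#' leverage is \code{h* = 3 (p + 1) / n_train} and residuals are
#' standardized by the training RMSE; a compound is outside the domain when
#' \code{h > h*} or \code{|standardized residual| > 3}.
#'
#' @param X_train training descriptor matrix (selected descriptors only).
#' @param y_train training response.
#' @param X_query matrix of points to assess (defaults to the training set).
#' @param y_query observed responses for the query points (optional; without
#'   them residual flags are NA and only leverage is assessed).
#' @param fit optional list with \code{coefficients} (intercept first) to
#'   use for predictions; by default OLS is refit on the training data.
#' @return A data frame with columns \code{leverage}, \code{std_residual},
#'   \code{outside} and \code{reason}; attributes \code{h_star} and
#'   \code{rmse_train}.
#' @export
williams_ad <- function(X_train, y_train, X_query = X_train,
                        y_query = NULL, fit = NULL) {
  X_train <- as.matrix(X_train); X_query <- as.matrix(X_query)
  n <- nrow(X_train); p <- ncol(X_train)
  Xi <- cbind(1, X_train)
  xtx <- crossprod(Xi)
  xtx_inv <- tryCatch(solve(xtx), error = function(e)
    stop("singular training design; cannot compute leverages"))
  if (is.null(fit)) {
    beta <- drop(xtx_inv %*% crossprod(Xi, y_train))
  } else beta <- fit$coefficients
  rmse_tr <- sqrt(mean((y_train - drop(Xi %*% beta))^2))
  Qi <- cbind(1, X_query)
  h <- rowSums((Qi %*% xtx_inv) * Qi)
  std_res <- if (!is.null(y_query)) {
    (y_query - drop(Qi %*% beta)) / rmse_tr
  } else rep(NA_real_, nrow(Qi))
  h_star <- 3 * (p + 1) / n
  high_lev <- h > h_star
  big_res <- !is.na(std_res) & abs(std_res) > 3
  out <- data.frame(leverage = h, std_residual = std_res,
                    outside = high_lev | big_res,
                    reason = ifelse(high_lev & big_res, "leverage+residual",
                             ifelse(high_lev, "leverage",
                             ifelse(big_res, "residual", ""))))
  attr(out, "h_star") <- h_star
  attr(out, "rmse_train") <- rmse_tr
  out
}
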