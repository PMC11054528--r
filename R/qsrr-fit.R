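#' Fit a QSRR model by GA descriptor selection and MLR
#'
#' The one-stop model-building routine: splits the compounds into training
#' and validation groups, runs genetic-algorithm descriptor selection on
#' the training group only, fits the final OLS model on the selected
#' subset, and attaches the full validation battery (training R2 and RMSE,
#' leave-one-out Q2, external R2, external RMSE, Lin's concordance
#' correlation coefficient on the validation group) plus a Williams-plot
#' applicability-domain assessment of every compound.
#'
#' @param X pruned descriptor matrix (all compounds in rows, named
#'   columns); run [filter_constant()] and [filter_correlated()] first.
#' @param y response vector (a chromatographic index such as CHI at pH
#'   7.4, CHI_IAM or logK_HSA).
#' @param model_size number of descriptors in the model (Table-style QSRR
#'   models typically use 3).
#' @param split a list with integer vectors \code{train} and
#'   \code{validation}, as returned by [split_train_validation()]; by
#'   default the systematic 19/7-style split scaled to \code{length(y)}.
#' @param control GA settings from [ga_control()].
#' @param seed integer seed governing the GA (and a random split, if
#'   requested).
#' @param response_name label used when printing the model equation.
#' @return An object of class \code{"qsrr"}: list with \code{model} (the
#'   final \code{"mlr_fit"}), \code{ga} (the \code{"ga_result"}),
#'   \code{split}, \code{stats} (named vector: r2_train, rmse_train,
#'   q2_loo, r2_ext, rmse_p, ccc_ext), \code{ad} (Williams
#'   applicability-domain table for all compounds, with a \code{set}
#'   column), \code{data} (the selected columns and response, retained for
#'   plotting).
#' @seealso [ga_select()], [williams_ad()], [ccc()]
#' @export
#' @examples
#' sim <- gen_descriptor_matrix(synthetic_spec(n_descriptors = 30, seed = 7))
#' fit <- qsrr(sim$matrix, sim$response, model_size = 2,
#'             control = ga_control(generations = 50), seed = 7)
#' fit$stats
qsrr <- function(X, y, model_size = 3, split = NULL,
                 control = ga_control(), seed = NULL,
                 response_name = deparse(substitute(y))) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(split)) {
    n_val <- max(1L, round(length(y) * 7 / 26))
    split <- split_train_validation(y, n_train = length(y) - n_val,
                                    n_validation = n_val)
  }
  tr <- split$train; va <- split$validation
  if (length(intersect(tr, va)) || length(union(tr, va)) != length(y))
    stop("split must be a disjoint, exhaustive partition of the compounds")

  ga <- ga_select(X[tr, , drop = FALSE], y[tr], model_size = model_size,
                  control = control, seed = seed)
  sel <- ga$best_subset
  model <- ga$best

  Xtr <- X[tr, sel, drop = FALSE]
  Xva <- X[va, sel, drop = FALSE]
  pred_va <- predict(model, Xva)
  ext <- r2_rmse(y[va], pred_va)
  stats <- c(r2_train = model$r2,
             rmse_train = model$rmse,
             q2_loo = q2_loo(Xtr, y[tr]),
             r2_ext = ext$r2,
             rmse_p = ext$rmse,
             ccc_ext = ccc(y[va], pred_va))

  ad <- williams_ad(Xtr, y[tr], X_query = X[, sel, drop = FALSE],
                    y_query = y, fit = list(coefficients =
                      c(model$intercept, model$coefficients)))
  ad$set <- ifelse(seq_len(length(y)) %in% tr, "training", "validation")

  structure(list(model = model, ga = ga, split = split, stats = stats,
                 ad = ad, response_name = response_name,
                 data = list(X = X[, sel, drop = FALSE], y = y)),
            class = "qsrr")
}

#' @export
print.qsrr <- function(x, digits = 3, ...) {
  cat("QSRR model (GA-selected descriptors, OLS fit)\n")
  cat(" ", format_equation(x$model, response = x$response_name,
                           digits = digits), "\n")
  s <- x$stats
  cat(sprintf("  training  (n = %d): R2 = %.3f  RMSE_tr = %.3f  Q2_LOO = %.3f\n",
              length(x$split$train), s["r2_train"], s["rmse_train"],
              s["q2_loo"]))
  cat(sprintf("  validation(n = %d): R2_ext = %.3f  RMSE_P = %.3f  CCC_ext = %.3f\n",
              length(x$split$validation), s["r2_ext"], s["rmse_p"],
              s["ccc_ext"]))
  invisible(x)
}

#' @export
summary.qsrr <- function(object, ...) {
  print(object)
  outside <- object$ad[object$ad$outside, , drop = FALSE]
  if (nrow(outside)) {
    cat("  outside applicability domain:",
        paste(rownames(outside), collapse = ", "), "\n")
  } else cat("  all compounds inside the applicability domain\n")
  cat(sprintf("  critical leverage h* = %.3f\n", attr(object$ad, "h_star")))
  invisible(object)
}

#' @export
coef.qsrr <- function(object, ...) {
  c(object$model$coefficients, `(Intercept)` = object$model$intercept)
}

#' @export
predict.qsrr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data$X
  predict(object$model, newdata)
}

#' @export
residuals.qsrr <- function(object, ...) {
  object$data$y - predict(object)
}

#' Williams plot for a QSRR model
#'
#' Leverage against standardized residual for every compound, training and
#' validation distinguished, with the critical leverage \code{h*} and the
#' plus/minus 3 residual cut-offs drawn.
#'
#' @param x a \code{"qsrr"} object.
#' @param ... passed to \code{plot}.
#' @export
plot.qsrr <- function(x, ...) {
  ad <- x$ad
  col <- ifelse(ad$set == "training", "forestgreen", "purple")
  graphics::plot(ad$leverage, ad$std_residual, col = col, pch = 19,
                 xlab = "leverage", ylab = "standardized residual",
                 main = paste("Williams plot:", x$response_name),
                 ylim = range(c(ad$std_residual, -3.5, 3.5)), ...)
  graphics::abline(h = c(-3, 3), lty = 2)
  graphics::abline(v = attr(ad, "h_star"), lty = 2)
  graphics::legend("topright", legend = c("training", "validation"),
                   col = c("forestgreen", "purple"), pch = 19, bty = "n")
  invisible(x)
}
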