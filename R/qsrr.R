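#' Split compounds into training and validation groups
#'
#' The default strategy sorts compounds by response rank and sends evenly
#' spaced ranks to the validation group, so both groups span the full
#' response range -- a reconstruction of the usual QSAR practice, since the
#' actual group membership used for the shipped fixture study is
#' unpublished. A seeded random strategy is also available.
#'
#' @param y response vector (used for ranking under the systematic
#'   strategy).
#' @param n_train,n_validation group sizes; must sum to \code{length(y)}.
#'   Defaults 19 and 7 for a 26-compound library.
#' @param strategy \code{"systematic"} (every k-th compound by response
#'   rank to validation) or \code{"random"}.
#' @param seed integer seed for the random strategy.
#' @return List with integer index vectors \code{train} and
#'   \code{validation}: disjoint, exhaustive, in increasing index order.
#' @export
split_train_validation <- function(y, n_train = 19, n_validation = 7,
                                   strategy = c("systematic", "random"),
                                   seed = NULL) {
  strategy <- match.arg(strategy)
  n <- length(y)
  if (n_train + n_validation != n)
    stop("n_train + n_validation must equal the number of compounds (", n, ")")
  stopifnot(n_train >= 1, n_validation >= 1)
  if (strategy == "systematic") {
    ord <- order(y)   # rank 1 = smallest response
    pos <- unique(round(seq(n / n_validation, n, length.out = n_validation)))
    if (length(pos) < n_validation)
      stop("systematic split degenerate: too few distinct validation ranks")
    val <- sort(ord[pos])
  } else {
    if (!is.null(seed)) set.seed(seed)
    val <- sort(sample.int(n, n_validation))
  }
  list(train = setdiff(seq_len(n), val), validation = val)
}

#' Ordinary-least-squares multiple linear regression
#'
#' Fits \code{y = b0 + sum(b_j x_j)} by OLS and reports coefficient
#' standard errors (the plus/minus values quoted alongside QSRR model
#' equations). Rank-deficient designs are rejected, naming the aliased
#' columns.
#'
#' @param X numeric matrix or data frame of selected descriptors
#'   (compounds in rows); must have more rows than columns + 1.
#' @param y response vector.
#' @return An object of class \code{"mlr_fit"}: list with
#'   \code{descriptor_names}, \code{coefficients} (per descriptor),
#'   \code{intercept}, \code{se} (standard errors, intercept last, matching
#'   the equation layout), \code{fitted}, \code{residuals}, \code{r2},
#'   \code{rmse} (n-denominator), \code{n}, \code{p}.
#' @export
fit_mlr <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n == length(y))
  if (n <= p + 1)
    stop("need more compounds than descriptors + 1 (n = ", n, ", p = ", p, ")")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(Xi, y)
  if (fit$rank < ncol(Xi)) {
    aliased <- colnames(Xi)[is.na(fit$coefficients)]
    stop("singular design: collinear column(s) ",
         paste(aliased, collapse = ", "))
  }
  res <- fit$residuals
  sigma2 <- sum(res^2) / (n - p - 1)
  xtx_inv <- chol2inv(qr.R(fit$qr)[seq_len(fit$rank), , drop = FALSE])
  se <- sqrt(diag(xtx_inv) * sigma2)
  names(se) <- colnames(Xi)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(descriptor_names = colnames(X),
                 coefficients = fit$coefficients[-1],
                 intercept = unname(fit$coefficients[1]),
                 se = c(se[-1], intercept = unname(se[1])),
                 fitted = drop(Xi %*% fit$coefficients),
                 residuals = res,
                 r2 = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_,
                 rmse = sqrt(mean(res^2)),
                 n = n, p = p),
            class = "mlr_fit")
}

#' @export
print.mlr_fit <- function(x, digits = 3, ...) {
  cat("MLR model:", format_equation(x, digits = digits), "\n")
  cat(sprintf("  n = %d, R2 = %.3f, RMSE = %.3f\n", x$n, x$r2, x$rmse))
  invisible(x)
}

#' Format an MLR model as a flat equation string
#'
#' @param fit an \code{"mlr_fit"} (or \code{"qsrr"}) object.
#' @param response name to print on the left-hand side.
#' @param digits digits for coefficients and standard errors.
#' @return A single string like
#'   \code{"y = 3.375(+-1.761) d1 + 3.262(+-0.456) d2 + 90.055(+-20.430)"}.
#' @export
format_equation <- function(fit, response = "y", digits = 3) {
  if (inherits(fit, "qsrr")) fit <- fit$model
  co <- fit$coefficients
  se <- fit$se
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  terms <- sprintf("%s(±%s) %s", fmt(co), fmt(se[seq_along(co)]),
                   fit$descriptor_names)
  terms <- c(terms, sprintf("%s(±%s)", fmt(fit$intercept),
                            fmt(se[["intercept"]])))
  eq <- paste(terms, collapse = " + ")
  paste(response, "=", gsub("\\+ -", "− ", eq))
}

#' Predict from an MLR model
#'
#' @param object an \code{"mlr_fit"} object.
#' @param newdata matrix or data frame containing at least the model's
#'   descriptor columns (matched by name when named).
#' @param ... unused.
#' @return Predicted response vector.
#' @export
predict.mlr_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(X))) {
    missing <- setdiff(object$descriptor_names, colnames(X))
    if (length(missing))
      stop("newdata lacks descriptor column(s): ",
           paste(missing, collapse = ", "))
    X <- X[, object$descriptor_names, drop = FALSE]
  } else if (ncol(X) != object$p) {
    stop("newdata must have ", object$p, " columns when unnamed")
  }
  drop(object$intercept + X %*% object$coefficients)
}

#' Genetic-algorithm settings for descriptor selection
#'
#' Defaults follow the QSARINS-style protocol: population 10, per-gene
#' mutation probability 0.20 (a "mutation rate of 20" on the percent
#' scale), 500 generations per model size, elitism on.
#'
#' @param population_size number of chromosomes, >= 2.
#' @param mutation_rate per-gene mutation probability in [0, 1].
#' @param generations generations evolved per model size.
#' @param fitness \code{"q2"} (leave-one-out Q2 on the training set, the
#'   default selection criterion) or \code{"r2"}.
#' @param elitism carry the best chromosome into the next generation
#'   unchanged, making best-fitness monotone across generations.
#' @param tournament_size chromosomes drawn per tournament.
#' @return A list of class \code{"ga_control"}.
#' @export
ga_control <- function(population_size = 10, mutation_rate = 0.20,
                       generations = 500, fitness = c("q2", "r2"),
                       elitism = TRUE, tournament_size = 2) {
  stopifnot(population_size >= 2, mutation_rate >= 0, mutation_rate <= 1,
            generations >= 1, tournament_size >= 1)
  structure(list(population_size = population_size,
                 mutation_rate = mutation_rate,
                 generations = generations,
                 fitness = match.arg(fitness),
                 elitism = elitism,
                 tournament_size = tournament_size),
            class = "ga_control")
}

subset_fitness <- function(X, y, criterion) {
  cache <- new.env(parent = emptyenv())
  function(idx) {
    key <- paste(idx, collapse = ",")
    if (!is.null(val <- cache[[key]])) return(val)
    val <- tryCatch({
      Xs <- X[, idx, drop = FALSE]
      if (criterion == "q2") q2_loo(Xs, y) else {
        fit <- stats::lm.fit(cbind(1, Xs), y)
        if (any(is.na(fit$coefficients))) stop("singular")
        1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
      }
    }, error = function(e) -Inf)
    cache[[key]] <- val
    val
  }
}

#' Genetic-algorithm descriptor selection for MLR
#'
#' Evolves fixed-size descriptor subsets. Chromosomes are subsets of
#' exactly \code{model_size} descriptor indices; parents are picked by
#' tournament, combined by uniform crossover (the union is sampled back
#' down to size), and each gene is replaced by a random non-member with
#' probability \code{mutation_rate}. Fitness is leave-one-out Q2 (or R2)
#' of the OLS fit on the supplied data, which should be the training split
#' only. With elitism the best fitness is non-decreasing across
#' generations. Fully reproducible given \code{seed}.
#'
#' @param X pruned, finite descriptor matrix (training compounds in rows).
#' @param y training response.
#' @param model_size number of descriptors per model; must satisfy
#'   \code{model_size < nrow(X) - 2} so the LOO fits are determined.
#' @param control a [ga_control()] list.
#' @param seed integer seed; set for reproducibility.
#' @param n_keep how many top distinct subsets to report.
#' @return List of class \code{"ga_result"}: \code{best} (an
#'   \code{"mlr_fit"} on the best subset), \code{ranked} (data frame of the
#'   top distinct subsets with fitness), \code{trace} (best fitness per
#'   generation), \code{control}, \code{fitness_name}.
#' @export
ga_select <- function(X, y, model_size, control = ga_control(),
                      seed = NULL, n_keep = 10) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (model_size >= n - 2)
    stop("infeasible model size ", model_size, " for ", n, " compounds")
  stopifnot(model_size >= 1, d >= model_size)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(d))
  if (!is.null(seed)) set.seed(seed)
  fitness_of <- subset_fitness(X, y, control$fitness)

  new_chrom <- function() sort(sample.int(d, model_size))
  pop <- replicate(control$population_size, new_chrom(), simplify = FALSE)
  fit <- vapply(pop, fitness_of, numeric(1))

  archive <- new.env(parent = emptyenv())
  note <- function(chrom, f) {
    key <- paste(chrom, collapse = ",")
    if (is.null(archive[[key]]) || archive[[key]]$fitness < f)
      archive[[key]] <- list(subset = chrom, fitness = f)
  }
  mapply(note, pop, fit)

  tournament <- function() {
    cand <- sample.int(length(pop), min(control$tournament_size, length(pop)))
    pop[[cand[which.max(fit[cand])]]]
  }
  trace <- numeric(control$generations)
  for (gen in seq_len(control$generations)) {
    offspring <- vector("list", control$population_size)
    start <- 1L
    if (control$elitism) {
      offspring[[1]] <- pop[[which.max(fit)]]
      start <- 2L
    }
    for (k in seq(start, control$population_size)) {
      p1 <- tournament(); p2 <- tournament()
      pool <- union(p1, p2)             # uniform crossover, repaired to size
      child <- sort(sample(pool, model_size))
      mutate <- stats::runif(model_size) < control$mutation_rate
      if (any(mutate)) {
        outside <- setdiff(seq_len(d), child)
        for (g in which(mutate)) {
          if (!length(outside)) break
          pick <- outside[sample.int(length(outside), 1)]
          outside <- c(outside[outside != pick], child[g])
          child[g] <- pick
        }
        child <- sort(child)
      }
      offspring[[k]] <- child
    }
    pop <- offspring
    fit <- vapply(pop, fitness_of, numeric(1))
    mapply(note, pop, fit)
    trace[gen] <- max(fit)
  }

  entries <- as.list(archive)
  ord <- order(vapply(entries, `[[`, numeric(1), "fitness"), decreasing = TRUE)
  top <- entries[ord][seq_len(min(n_keep, length(entries)))]
  ranked <- data.frame(
    descriptors = vapply(top, function(e)
      paste(colnames(X)[e$subset], collapse = " + "), character(1)),
    fitness = vapply(top, `[[`, numeric(1), "fitness"))
  best_idx <- top[[1]]$subset
  structure(list(best = fit_mlr(X[, best_idx, drop = FALSE], y),
                 best_subset = colnames(X)[best_idx],
                 ranked = ranked,
                 trace = trace,
                 control = control,
                 fitness_name = control$fitness),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat("GA descriptor selection (", x$fitness_name, " fitness)\n", sep = "")
  cat("  best subset:", paste(x$best_subset, collapse = " + "),
      sprintf(" [fitness %.4f]\n", x$ranked$fitness[1]))
  invisible(x)
}
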