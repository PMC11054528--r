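test_that("train/validation split is disjoint, exhaustive and reproducible", {
  y <- ipsapirone_chromatography()$`CHI_pH7.4`
  sp <- split_train_validation(y, 19, 7)
  expect_length(sp$train, 19)
  expect_length(sp$validation, 7)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), 1:26)

  # systematic rule on 4 compounds: response ranks 2 and 4 go to validation
  y4 <- c(10, 40, 20, 30)   # ranks: 1, 4, 2, 3
  sp4 <- split_train_validation(y4, 2, 2)
  expect_setequal(sp4$validation, c(3, 2))   # rank-2 is y=20 (id 3), rank-4 y=40 (id 2)

  r1 <- split_train_validation(y, 19, 7, strategy = "random", seed = 9)
  r2 <- split_train_validation(y, 19, 7, strategy = "random", seed = 9)
  expect_identical(r1, r2)

  expect_error(split_train_validation(y, 18, 7), "must equal")
})

test_that("OLS fit recovers exact data and matches the normal-equations oracle", {
  x1 <- c(0, 1, 2, 3, 4)
  exact <- fit_mlr(cbind(x1 = x1), 2 * x1 + 1)
  expect_equal(unname(exact$coefficients), 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$residuals, rep(0, 5), tolerance = 1e-12)
  expect_equal(exact$r2, 1)

  set.seed(11)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("x1", "x2")))
  y <- 3 * X[, 1] - 1 * X[, 2] + 0.5 + rnorm(30, sd = 0.1)
  fit <- fit_mlr(X, y)
  oracle <- ols_oracle(X, y)
  expect_equal(unname(fit$coefficients), unname(oracle$coefficients),
               tolerance = 1e-8)
  expect_equal(fit$intercept, unname(oracle$intercept), tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(c(oracle$se[-1], oracle$se[1])),
               tolerance = 1e-8)
  # estimates within 3 SE of the generating truth
  expect_lt(abs(fit$coefficients["x1"] - 3), 3 * oracle$se[2])
  expect_lt(abs(fit$coefficients["x2"] + 1), 3 * oracle$se[3])
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  x <- rnorm(10)
  expect_error(fit_mlr(cbind(a = x, b = x), rnorm(10)), "collinear.*b")
})

test_that("prediction is the affine map and checks descriptor availability", {
  fit <- fit_mlr(cbind(x1 = c(0, 1, 2, 3, 4)), 2 * c(0, 1, 2, 3, 4) + 1)
  expect_equal(predict(fit, cbind(x1 = 3)), 7)
  expect_equal(predict(fit, cbind(x1 = 0)), 1)
  expect_error(predict(fit, cbind(z = 3)), "lacks descriptor")

  # hand evaluation of a three-descriptor equation with quoted coefficients
  hsa_like <- list(descriptor_names = c("CHI_IAM", "GATS2e", "RDF155u"),
                   coefficients = c(CHI_IAM = 0.114, GATS2e = -0.857,
                                    RDF155u = -0.050),
                   intercept = -2.751, p = 3)
  class(hsa_like) <- "mlr_fit"
  expect_equal(predict(hsa_like, cbind(CHI_IAM = 40, GATS2e = 1,
                                       RDF155u = 10)),
               0.114 * 40 - 0.857 * 1 - 0.050 * 10 - 2.751)
})

test_that("GA equals exhaustive search on an enumerable descriptor pool", {
  sim <- gen_descriptor_matrix(synthetic_spec(
    n_compounds = 20, n_descriptors = 8,
    informative = c(`2` = 1, `5` = -1.5), noise_sd = 1, seed = 21))
  X <- sim$matrix; y <- sim$response
  g <- ga_select(X, y, model_size = 2, seed = 21)
  oracle <- exhaustive_best(8, 2, function(idx) q2_loo(X[, idx], y))
  expect_equal(g$ranked$fitness[1], oracle$fitness, tolerance = 1e-10)
  expect_setequal(g$best_subset, paste0("d", oracle$subset))
})

test_that("GA respects cardinality, monotone elitist fitness and seed determinism", {
  sim <- gen_descriptor_matrix(synthetic_spec(
    n_compounds = 26, n_descriptors = 40, noise_sd = 0.5, seed = 5))
  g <- ga_select(sim$matrix, sim$response, model_size = 3,
                 control = ga_control(generations = 60), seed = 5)
  expect_length(g$best_subset, 3)
  expect_true(all(diff(g$trace) >= 0))      # elitism: never loses the best
  expect_false(any(duplicated(g$ranked$descriptors)))

  g2 <- ga_select(sim$matrix, sim$response, model_size = 3,
                  control = ga_control(generations = 60), seed = 5)
  expect_identical(g$best_subset, g2$best_subset)
  expect_identical(g$trace, g2$trace)
})

test_that("a descriptor collinear with the response is found immediately", {
  set.seed(31)
  X <- matrix(rnorm(26 * 10), 26, 10,
              dimnames = list(NULL, paste0("d", 1:10)))
  y <- 2 * X[, 4]                      # perfect one-descriptor model
  g <- ga_select(X, y, model_size = 1,
                 control = ga_control(generations = 30, fitness = "r2"),
                 seed = 31)
  expect_equal(g$best_subset, "d4")
  expect_equal(g$ranked$fitness[1], 1, tolerance = 1e-12)
})

test_that("infeasible model sizes are rejected", {
  X <- matrix(rnorm(5 * 6), 5, 6)
  expect_error(ga_select(X, rnorm(5), model_size = 4), "infeasible")
})

test_that("the qsrr wrapper assembles model, statistics and domain flags", {
  sim <- gen_descriptor_matrix(synthetic_spec(
    n_descriptors = 60, noise_sd = 0.5, seed = 13))
  fit <- qsrr(sim$matrix, sim$response, model_size = 2,
              control = ga_control(generations = 120), seed = 13,
              response_name = "y")
  expect_s3_class(fit, "qsrr")
  expect_setequal(fit$ga$best_subset, c("d3", "d7"))
  s <- fit$stats
  expect_true(all(c("r2_train", "rmse_train", "q2_loo", "r2_ext",
                    "rmse_p", "ccc_ext") %in% names(s)))
  expect_lte(s["q2_loo"], s["r2_train"])
  expect_gt(s["r2_train"], 0.9)

  expect_equal(nrow(fit$ad), 26)
  expect_equal(sum(fit$ad$set == "training"), 19)
  # coef/predict/residuals methods are consistent
  expect_length(coef(fit), 3)
  expect_equal(predict(fit), fit$model$intercept +
                 drop(fit$data$X %*% fit$model$coefficients),
               tolerance = 1e-12)
  expect_equal(residuals(fit), sim$response - predict(fit),
               tolerance = 1e-12)
  eq <- format_equation(fit, response = "y")
  expect_match(eq, "^y = ")
  expect_match(eq, "d3")
})
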