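test_that("predict_ga computes intercept + weighted beta sum", {
  beta <- tiny_beta(c(0.5, 0.25, 0.1, 0.9), c("A", "B"), c("cg1", "cg2"))
  # all-zero model: predictions equal the intercept
  m0 <- clock_model("flat", 38, setNames(numeric(0), character(0)))
  expect_equal(unname(predict_ga(m0, beta)), c(38, 38))
  # single-probe arithmetic
  m1 <- clock_model("one", 10, c(cg1 = 20))
  expect_equal(unname(predict_ga(m1, beta)["A"]), 10 + 20 * 0.5)
  expect_equal(unname(predict(m1, beta)["B"]), 10 + 20 * 0.25)
})

test_that("predict_ga missing-probe policies work", {
  beta <- tiny_beta(c(0.5, 0.25), c("A", "B"), "cg1")
  m <- clock_model("m", 0, c(cg1 = 2, cg9 = 4))
  expect_error(predict_ga(m, beta), "cg9")
  got <- predict_ga(m, beta, on_missing_probe = "impute_value",
                    missing_value = 0.5)
  expect_equal(unname(got["A"]), 2 * 0.5 + 4 * 0.5)
})

test_that("packaged RPC prediction matches an independent summation oracle", {
  rpc <- read_clock(clock_file("rpc"))
  beta <- tiny_beta(rep(0.5, 558), "S1", names(rpc$coefficients))
  got <- unname(predict_ga(rpc, beta))
  # oracle: plain scalar loop over the coefficient table
  acc <- rpc$intercept
  for (p in names(rpc$coefficients)) acc <- acc + 0.5 * rpc$coefficients[[p]]
  expect_equal(got, acc, tolerance = 1e-12)
})

test_that("predict_ga is linear in the beta matrix", {
  sim <- small_clock_sim(n = 30, p = 100, k = 10)
  m <- clock_model("lin", 5, setNames(rnorm(20), colnames(sim$beta)[1:20]))
  b1 <- sim$beta[1:15, ]
  b2 <- sim$beta[16:30, ]
  dimnames(b2) <- dimnames(b1)
  for (a in c(0, 0.3, 1)) {
    mix <- a * b1 + (1 - a) * b2
    expect_equal(predict_ga(m, mix),
                 a * predict_ga(m, b1) + (1 - a) * predict_ga(m, b2),
                 tolerance = 1e-10)
  }
})

test_that("training is deterministic given the fold seed", {
  sim <- small_clock_sim()
  m1 <- train_clock(sim$beta, sim$sheet, fold_seed = 9)
  m2 <- train_clock(sim$beta, sim$sheet, fold_seed = 9)
  expect_identical(m1$lambda, m2$lambda)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$intercept, m2$intercept)
})

test_that("unpenalized fit reproduces OLS on well-conditioned data", {
  set.seed(5)
  n <- 60
  x <- matrix(runif(n * 3, 0.2, 0.8), n, 3,
              dimnames = list(sprintf("s%02d", 1:n), c("cg1", "cg2", "cg3")))
  y <- 20 + 8 * x[, 1] - 5 * x[, 2] + rnorm(n, 0, 0.1)
  sheet <- sheet_for(x, y)
  m <- train_clock(x, sheet, lambda = 0)
  ols <- coef(lm(y ~ x))
  expect_equal(m$intercept, unname(ols[1]), tolerance = 1e-6)
  expect_equal(unname(coef(m)[c("cg1", "cg2", "cg3")]), unname(ols[-1]),
               tolerance = 1e-6)
})

test_that("probe subsets confine the model and refined clocks nest in parents", {
  sim <- simulate_dataset(sim_config(n_samples = 200, n_probes = 400,
                                     n_clock_probes = 25, ga_range = c(20, 42),
                                     seed = 77L))
  parent <- train_clock(sim$beta, sim$sheet, fold_seed = 3, name = "parent")
  expect_gt(parent$n_features, 0)
  refined <- train_clock(sim$beta, sim$sheet, fold_seed = 3,
                         sample_filter = filter_uncomplicated_term,
                         probe_subset = names(parent$coefficients),
                         name = "refined")
  expect_true(all(names(refined$coefficients) %in% names(parent$coefficients)))
  expect_lte(refined$n_features, parent$n_features)
  expect_error(train_clock(sim$beta, sim$sheet, probe_subset = "cg_nope"),
               "cg_nope")
})

test_that("training rejects degenerate inputs", {
  sim <- small_clock_sim(n = 20, p = 50, k = 5)
  expect_error(train_clock(sim$beta[1:6, ], sim$sheet, n_folds = 10),
               "fewer samples")
  sheet <- sim$sheet
  sheet$ga_weeks <- 30
  expect_error(train_clock(sim$beta, sheet), "constant gestational age")
  sheet2 <- sim$sheet
  sheet2$ga_weeks[1] <- NA
  expect_error(train_clock(sim$beta, sheet2), "missing ga_weeks")
})

test_that("GA acceleration is the OLS residual of predicted on observed", {
  obs <- c(30, 32, 35, 38, 40, 41)
  # predicted == observed: all residuals zero
  acc <- ga_acceleration(obs, obs)
  expect_equal(unname(acc$raw_residuals), rep(0, 6), tolerance = 1e-12)
  # a constant shift is absorbed by the intercept
  acc2 <- ga_acceleration(obs + 2, obs)
  expect_equal(unname(acc2$raw_residuals), rep(0, 6), tolerance = 1e-12)
  expect_equal(acc2$intercept, 2)
  expect_equal(acc2$slope, 1)
  expect_error(ga_acceleration(obs, rep(30, 6)), "constant observed")
})

test_that("acceleration residuals are orthogonal to observed GA", {
  set.seed(19)
  for (rep_i in 1:5) {
    obs <- runif(50, 8, 42)
    pred <- 0.9 * obs + rnorm(50, 0, 2)
    acc <- ga_acceleration(pred, obs)
    expect_lt(abs(cor(acc$raw_residuals, obs)), 1e-10)
    expect_equal(sd(acc$standardized_residuals), 1, tolerance = 1e-12)
    expect_equal(residuals(acc), acc$raw_residuals)
  }
})

test_that("sex classifier training and prediction behave at the contracts", {
  # zero-coefficient classifier: probability 0.5, tie resolved to negative
  clf0 <- structure(list(intercept = 0, coefficients = c(cg1 = 0),
                         positive_class = "female", alpha = 0.5, lambda = 1,
                         n_features = 0L),
                    class = "sex_classifier")
  beta <- tiny_beta(c(0.2, 0.8), c("A", "B"), "cg1")
  out <- predict_sex(clf0, beta)
  expect_equal(out$probability, c(0.5, 0.5))
  expect_equal(out$sex, c("male", "male"))
  # strong positive intercept: everything positive class
  clf0$intercept <- 10
  expect_equal(predict_sex(clf0, beta)$sex, c("female", "female"))
  # missing probes are an error
  clf0$coefficients <- c(cgX = 1)
  expect_error(predict_sex(clf0, beta), "cgX")
})

test_that("separable sexes are classified perfectly out of sample", {
  sim <- simulate_dataset(sim_config(n_samples = 150, n_probes = 400,
                                     n_clock_probes = 10, n_sex_probes = 25,
                                     sex_effect = 0.2, seed = 88L))
  tr <- 1:100
  te <- 101:150
  clf <- train_sex_classifier(sim$beta[tr, ], sim$sheet, fold_seed = 2)
  clf_again <- train_sex_classifier(sim$beta[tr, ], sim$sheet, fold_seed = 2)
  expect_identical(clf$coefficients, clf_again$coefficients)
  pred <- predict_sex(clf, sim$beta[te, ])
  expect_equal(pred$sex, sim$sheet$sex[te])
  expect_error(train_sex_classifier(sim$beta[sim$sheet$sex == "male", ],
                                    sim$sheet),
               "both sexes")
})

test_that("label-permuted sex training carries no held-out signal", {
  sim <- simulate_dataset(sim_config(n_samples = 120, n_probes = 300,
                                     n_clock_probes = 0, n_sex_probes = 20,
                                     sex_effect = 0.2, seed = 99L))
  sheet <- sim$sheet
  set.seed(123)
  sheet$sex <- sample(sheet$sex)
  clf <- train_sex_classifier(sim$beta[1:80, ], sheet, fold_seed = 4)
  pred <- predict_sex(clf, sim$beta[81:120, ])
  acc <- mean(pred$sex == sheet$sex[81:120])
  expect_lt(abs(acc - 0.5), 0.25)
})

test_that("autosome manifests restrict sex-classifier features", {
  sim <- simulate_dataset(sim_config(n_samples = 100, n_probes = 200,
                                     n_sex_probes = 20, sex_effect = 0.25,
                                     seed = 55L))
  manifest <- data.frame(probe_id = colnames(sim$beta),
                         chromosome = rep(c("1", "X"),
                                          length.out = ncol(sim$beta)),
                         stringsAsFactors = FALSE)
  clf <- train_sex_classifier(sim$beta, sim$sheet, fold_seed = 6,
                              manifest = manifest)
  auto <- manifest$probe_id[manifest$chromosome == "1"]
  expect_true(all(names(clf$coefficients) %in% auto))
})
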