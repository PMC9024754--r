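test_that("splits have the planned sizes and are seed-reproducible", {
  lib <- data.frame(record_id = sprintf("r%03d", 1:100))
  plan <- split_plan(20, 0.75, rng_seed = 1)
  s1 <- make_splits(lib, plan)
  expect_length(s1, 20)
  for (sp in s1) {
    expect_length(sp$train_ids, 75)
    expect_length(sp$test_ids, 25)
    expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  }
  expect_identical(s1, make_splits(lib, plan))
  expect_false(identical(s1[[1]], make_splits(lib, split_plan(20, 0.75, 2))[[1]]))
  expect_error(make_splits(data.frame(record_id = letters[1:5]), plan),
               "too small")
})

test_that("20 splits of a large library test almost every record", {
  lib <- data.frame(record_id = sprintf("r%04d", 1:1000))
  splits <- make_splits(lib, split_plan(20, 0.75, 5))
  tested <- unique(unlist(lapply(splits, `[[`, "test_ids")))
  expect_gte(length(tested) / 1000, 0.99)
})

test_that("mean baseline predicts the training mean in original units", {
  x <- matrix(rbinom(40, 1, 0.5), nrow = 4)
  fit <- ri_model(x, c(1000, 2000, 1400, 1600), backend = "mean_baseline")
  expect_equal(predict(fit, x), rep(1500, 4))
  expect_equal(predict(fit, x[0, , drop = FALSE]), numeric(0))
})

test_that("svm_linear nearly interpolates a noise-free linear target", {
  set.seed(21)
  x <- matrix(rbinom(120 * 50, 1, 0.3), nrow = 120)
  w <- runif(50, 0, 20)
  ri <- 800 + as.numeric(x %*% w)
  fit <- ri_model(x, ri, backend = "svm_linear")
  res <- prediction_results(seq_len(120), predict(fit, x), ri)
  expect_lt(error_summary(res)$mdape, 0.5)
})

test_that("x10 target scaling is undone on the way out", {
  x <- matrix(rbinom(60, 1, 0.5), nrow = 6)
  ri <- c(900, 1100, 1000, 950, 1050, 1020)
  mb <- ri_model(x, ri, backend = "mean_baseline")
  expect_equal(mb$fit$mean, mean(ri) * 10)      # fitted on scaled targets
  expect_equal(predict(mb, x), rep(mean(ri), 6))  # returned in RI units
  set.seed(2)
  x2 <- matrix(rbinom(300, 1, 0.4), nrow = 30)
  ri2 <- 1000 + 30 * x2[, 1] + 15 * x2[, 2]
  f1 <- ri_model(x2, ri2, backend = "svm_linear")
  f2 <- ri_model(x2, ri2, backend = "svm_linear")
  expect_equal(predict(f1, x2), predict(f2, x2), tolerance = 1e-9)
})

test_that("unknown and unplugged backends are rejected distinctly", {
  x <- matrix(1L, 4, 2)
  expect_error(ri_model(x, 1:4, backend = "gradient_cascade"),
               "unknown backend")
  expect_error(ri_model(x, 1:4, backend = "dnn"), "plugin")
  expect_error(ri_model(x, 1:3, backend = "mean_baseline"), "nrow")
  fit <- ri_model(x, 1:4, backend = "mean_baseline")
  expect_error(predict(fit, matrix(1L, 2, 5)), "dimension mismatch")
})

test_that("registered plugin backends slot into the protocol", {
  register_ri_backend("dnn",
    fit = function(x, y, hp) list(w = rep(mean(y), 1)),
    predict = function(handle, x) rep(handle$w, nrow(x)))
  on.exit(rm("dnn", envir = tmsri:::.backends))
  x <- matrix(rbinom(40, 1, 0.5), 4)
  fit <- ri_model(x, c(10, 20, 30, 40), backend = "dnn")
  expect_equal(predict(fit, x), rep(25, 4))
})

test_that("error summaries match their definitions and a sort oracle", {
  res <- prediction_results(1:3, c(1010, 1020, 1060), rep(1000, 3))
  s <- error_summary(res)
  expect_equal(s$mae, 30)
  expect_equal(s$mdae, 20)
  expect_equal(s$mape, 3)
  expect_equal(s$mdape, 2)

  perfect <- error_summary(prediction_results(1:2, c(5, 7), c(5, 7)))
  expect_equal(unlist(perfect[c("mae", "mdae", "mape", "mdape")]),
               c(mae = 0, mdae = 0, mape = 0, mdape = 0))

  set.seed(8)
  e <- runif(31, 0, 50)
  r <- prediction_results(seq_along(e), 1000 + e, rep(1000, length(e)))
  srt <- sort(e)
  expect_equal(error_summary(r)$mdae, srt[16])  # odd-length sort oracle
  expect_error(error_summary(r[0, ]), "no prediction")
})

test_that("paired Wilcoxon comparison behaves at its edges", {
  a <- runif(30, 1, 5)
  expect_equal(compare_models(a, a), 1)
  b <- a + 5
  expect_lt(compare_models(a, b), 0.001)
  expect_equal(compare_models(a, b), compare_models(b, a))
  expect_error(compare_models(a, b[-1]), "equal length")
})

test_that("the repeated-split protocol pools and pairs across backends", {
  gen <- fixture_gen()
  lib <- gen$library
  proto <- run_protocol(lib, fingerprint_config(),
                        specs = list("mean_baseline",
                                     backend_spec("svm_linear")),
                        plan = split_plan(4, 0.75, rng_seed = 9),
                        with_similarity = TRUE)
  n_test <- nrow(lib) - round(0.75 * nrow(lib))
  mb <- proto$results$mean_baseline
  sv <- proto$results$svm_linear
  expect_equal(nrow(mb), 4 * n_test)
  # identical split sequences consumed by both backends
  expect_identical(mb$record_id, sv$record_id)
  expect_identical(mb$split_index, sv$split_index)
  expect_true(all(sv$max_train_similarity >= 0 &
                  sv$max_train_similarity <= 1))
  # structured data: the learner beats the constant predictor
  expect_lt(error_summary(sv)$mdape, error_summary(mb)$mdape)
})
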