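# Synthetic feature matrices (Gaussian blobs with subject structure) let
# the protocol be exercised without the signal pipeline.
make_blob_data <- function(seed, shift = 0, n_per_group = 6, reps = 10,
                           p = 20, informative = 5) {
  set.seed(seed)
  subj <- c(sprintf("H%02d", 1:n_per_group), sprintf("A%02d", 1:n_per_group))
  coh <- rep(c("healthy", "acl"), each = n_per_group)
  rows <- list()
  for (i in seq_along(subj)) {
    centre <- rnorm(p, 0, 0.5)
    mu <- centre + if (coh[i] == "acl") c(rep(shift, informative),
                                          rep(0, p - informative)) else 0
    X <- matrix(rnorm(reps * p, 0, 1), reps, p, byrow = FALSE)
    X <- sweep(X, 2, mu, "+")
    rows[[i]] <- data.frame(subject = subj[i], cohort = coh[i],
                            X, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out)[-(1:2)] <- sprintf("f%02d", seq_len(p))
  out
}

test_that("stratified splits honour the 6/2/4 design and determinism", {
  subjects <- data.frame(subject = c(sprintf("H%d", 1:6), sprintf("A%d", 1:6)),
                         cohort = rep(c("healthy", "acl"), each = 6))
  plan <- stratified_split(subjects, seed = 5)
  tab <- table(plan$role, plan$cohort)
  expect_equal(unname(tab["train", ]), c(3L, 3L))
  expect_equal(unname(tab["validation", ]), c(1L, 1L))
  expect_equal(unname(tab["test", ]), c(2L, 2L))
  expect_identical(plan, stratified_split(subjects, seed = 5))
  for (s in 1:10) {
    pl <- stratified_split(subjects, seed = s)
    expect_setequal(pl$subject, subjects$subject)
    expect_equal(sort(as.integer(table(pl$role))), c(2L, 4L, 6L))
    t2 <- table(pl$role, pl$cohort)
    expect_true(all(t2[, 1] == t2[, 2]))
  }
  expect_error(stratified_split(data.frame(subject = letters[1:5],
                                           cohort = c("healthy", "healthy",
                                                      "acl", "acl", "acl")),
                                seed = 1), "equal sizes")
})

test_that("confusion metrics match their closed forms and bounds", {
  m <- metrics_from_confusion(confusion_matrix(10, 0, 0, 10))
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)
  expect_equal(m$f1, 100)
  expect_equal(m$kappa, 1)
  # marginally independent predictions: kappa exactly zero
  m0 <- metrics_from_confusion(confusion_matrix(6, 6, 2, 2))
  expect_equal(m0$kappa, 0, tolerance = 1e-12)
  # degenerate margins flag undefined metrics
  mna <- metrics_from_confusion(confusion_matrix(0, 0, 5, 5))
  expect_true(is.na(mna$sensitivity))
  expect_true(!is.na(mna$specificity))
  expect_error(metrics_from_confusion(confusion_matrix(0, 0, 0, 0)), "empty")
  expect_error(confusion_matrix(-1, 0, 0, 2), "non-negative")
})

test_that("a single grid point is returned as the optimum", {
  d <- make_blob_data(1, shift = 1)
  grid <- model_grid("knn", k_best = 5,
                     params = list(knn = list(list(k = 3))))
  gs <- loso_grid_search(d, grid, seed = 2)
  expect_equal(gs$best$family, "knn")
  expect_equal(gs$best$params$k, 3)
  expect_equal(gs$best$k, 5L)
  expect_length(gs$features, 5L)
  expect_error(loso_grid_search(d, structure(list(), class = "model_grid")),
               "empty")
  expect_error(model_grid("knn", k_best = 12), "<= 10")
})

test_that("strongly separated cohorts reach high LOSO accuracy", {
  d <- make_blob_data(3, shift = 3)
  grid <- model_grid("knn", k_best = c(5, 10),
                     params = list(knn = list(list(k = 3), list(k = 5))))
  gs <- loso_grid_search(d, grid, seed = 4)
  expect_gt(gs$accuracy, 90)
})

test_that("label-permuted data stays inside the binomial chance band", {
  d <- make_blob_data(5, shift = 2)
  set.seed(11)
  # permute cohort labels at the subject level
  subs <- unique(d[c("subject", "cohort")])
  newlab <- sample(subs$cohort)
  d$cohort <- newlab[match(d$subject, subs$subject)]
  grid <- model_grid("knn", k_best = 5,
                     params = list(knn = list(list(k = 3))))
  gs <- loso_grid_search(d, grid, seed = 6)
  # chance band over subjects: repetitions of one subject are correlated,
  # so the subject is the exchangeable unit
  n_sub <- length(gs$per_subject)
  expect_lt(abs(gs$accuracy - 50), 100 * 1.96 * sqrt(0.25 / n_sub))
  rep <- evaluate_protocol(d, grid, n_permutations = 3, seed = 8)
  n_scores <- nrow(rep$per_subject)
  expect_lt(abs(rep$test_accuracy - 50),
            100 * 1.96 * sqrt(0.25 / n_scores))
})

test_that("the protocol report is reproducible and internally consistent", {
  d <- make_blob_data(7, shift = 1.5)
  grid <- model_grid("knn", k_best = c(3, 5),
                     params = list(knn = list(list(k = 3))))
  r1 <- evaluate_protocol(d, grid, n_permutations = 1, seed = 9)
  r2 <- evaluate_protocol(d, grid, n_permutations = 1, seed = 9)
  expect_identical(r1, r2)
  # pooled confusion total equals the number of scored test repetitions
  n_scored <- with(r1$confusion, tp + fn + fp + tn)
  expect_equal(n_scored, 4L * 10L)   # 4 test subjects x 10 repetitions
  expect_equal(nrow(r1$per_subject), 4L)
  expect_equal(r1$test_se,
               sd(r1$per_subject$accuracy) / sqrt(nrow(r1$per_subject)))
  # different seed gives a different split
  r3 <- evaluate_protocol(d, grid, n_permutations = 1, seed = 10)
  expect_false(identical(r1$permutations[[1]]$plan,
                         r3$permutations[[1]]$plan))
})

test_that("deleting unseen subjects does not change the fitted model", {
  d <- make_blob_data(9, shift = 1)
  subs <- unique(d$subject)
  train_sub <- subs[1:8]
  test_sub <- setdiff(subs, train_sub)
  d_train <- d[d$subject %in% train_sub, ]
  d_test <- d[d$subject %in% test_sub, ]
  f1 <- train_classifier(d_train, "knn", list(k = 3), 5)
  # retrain after deleting the test subjects from the surrounding frame:
  # the training rows are all the fit may depend on
  d_reduced <- d[d$subject %in% train_sub, ]
  f2 <- train_classifier(d_reduced, "knn", list(k = 3), 5)
  expect_identical(f1$scaler, f2$scaler)
  expect_identical(f1$sel, f2$sel)
  expect_identical(predict(f1, d_test), predict(f2, d_test))
})

test_that("non-finite features are rejected by name", {
  d <- make_blob_data(2, shift = 1)
  d$f03[5] <- NA
  grid <- model_grid("knn", k_best = 3,
                     params = list(knn = list(list(k = 3))))
  expect_error(loso_grid_search(d, grid), "f03")
  expect_equal(ncol(drop_undefined_features(d)), ncol(d) - 1L)
})

test_that("every model family trains and predicts through the pipeline", {
  d <- make_blob_data(13, shift = 2, reps = 5, p = 8, informative = 4)
  for (fam in c("knn", "nb", "svm", "xgb", "mlp", "stacking")) {
    params <- switch(fam, knn = list(k = 3), nb = list(laplace = 0),
                     svm = list(cost = 1, gamma = "scale"),
                     xgb = list(max_depth = 2, nrounds = 20, eta = 0.3),
                     mlp = list(size = 4, decay = 1e-3), list())
    set.seed(21)
    fit <- train_classifier(d, fam, params, 4)
    pred <- predict(fit, d)
    expect_s3_class(pred, "factor")
    expect_identical(levels(pred), c("healthy", "acl"))
    # in-sample accuracy on well-separated blobs is far above chance
    expect_gt(mean(pred == d$cohort), 0.8)
    pr <- predict(fit, d, type = "prob")
    expect_true(all(pr >= 0 & pr <= 1))
  }
})
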