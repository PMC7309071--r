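# Subject-stratified machine-learning evaluation protocol:
# 6/2/4 train/validation/test splits, leave-one-subject-out (LOSO) grid
# search with select-K-best feature selection (K <= 10), retraining on
# the merged 8 subjects, per-player accuracies, pooled confusion matrices
# and derived metrics, repeated over random subject assignments.
#
# The positive class throughout is the post-ACL cohort ("acl").

META_COLS <- c("subject", "cohort", "direction", "trial")
COHORT_LEVELS <- c("healthy", "acl")

# ---- data handling ---------------------------------------------------------

split_feature_data <- function(data) {
  meta <- intersect(META_COLS, names(data))
  if (!all(c("subject", "cohort") %in% meta))
    stop("data must have 'subject' and 'cohort' columns")
  fcols <- setdiff(names(data), meta)
  X <- as.matrix(data[fcols])
  storage.mode(X) <- "double"
  bad <- colnames(X)[!vapply(seq_len(ncol(X)),
                             function(j) all(is.finite(X[, j])), logical(1))]
  if (length(bad))
    stop(sprintf("non-finite feature value(s) in: %s",
                 paste(head(bad, 5), collapse = ", ")))
  list(X = X, y = factor(data$cohort, levels = COHORT_LEVELS),
       subject = as.character(data$subject))
}

#' Drop feature columns with undefined values
#'
#' Removes feature columns containing any `NA`/non-finite entry (the
#' explicit flags produced by feature extraction) before model fitting.
#'
#' @param data feature data.frame with metadata columns.
#' @return the data.frame without offending columns.
#' @export
drop_undefined_features <- function(data) {
  meta <- intersect(META_COLS, names(data))
  fcols <- setdiff(names(data), meta)
  ok <- vapply(fcols, function(cn) all(is.finite(data[[cn]])), logical(1))
  data[c(meta, fcols[ok])]
}

# ---- split plan ------------------------------------------------------------

#' Subject-stratified train/validation/test split
#'
#' Randomly assigns subjects to training, validation and test partitions
#' with equal cohort counts in each (at the study sizes 6+6 this is the
#' 6/2/4 split: 3+3 train, 1+1 validation, 2+2 test).
#'
#' @param subjects data.frame with `subject` and `cohort`.
#' @param seed integer seed; the plan is deterministic given it.
#' @return A `split_plan` data.frame (`subject`, `cohort`, `role`).
#' @export
stratified_split <- function(subjects, seed) {
  tab <- table(subjects$cohort)
  if (length(tab) != 2L || tab[1] != tab[2])
    stop("cohorts must have equal sizes to stratify")
  n <- tab[[1]]
  n_train <- round(n / 2); n_val <- max(1L, round(n / 6))
  n_test <- n - n_train - n_val
  if (n_test < 1L) stop("too few subjects per cohort to stratify")
  plan <- with_seed(seed, {
    roles <- character(nrow(subjects))
    for (coh in unique(subjects$cohort)) {
      s <- sample(subjects$subject[subjects$cohort == coh])
      role <- rep(c("train", "validation", "test"), c(n_train, n_val, n_test))
      roles[match(s, subjects$subject)] <- role
    }
    roles
  })
  out <- data.frame(subject = subjects$subject, cohort = subjects$cohort,
                    role = plan, stringsAsFactors = FALSE)
  class(out) <- c("split_plan", "data.frame")
  attr(out, "seed") <- seed
  out
}

# ---- feature selection and scaling ----------------------------------------

# One-way F statistic of each feature for a two-level label.
feature_f_scores <- function(X, y) {
  g <- split(seq_along(y), y)
  n1 <- length(g[[1]]); n2 <- length(g[[2]])
  m1 <- colMeans(X[g[[1]], , drop = FALSE])
  m2 <- colMeans(X[g[[2]], , drop = FALSE])
  v1 <- apply(X[g[[1]], , drop = FALSE], 2, var)
  v2 <- apply(X[g[[2]], , drop = FALSE], 2, var)
  grand <- colMeans(X)
  msb <- n1 * (m1 - grand)^2 + n2 * (m2 - grand)^2
  msw <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  f
}

select_k_best <- function(X, y, k) {
  f <- feature_f_scores(X, y)
  k <- min(k, ncol(X))
  order(-f)[seq_len(k)]   # ties broken by column order (stable)
}

fit_scaler <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s < 1e-12] <- 1
  list(mu = mu, s = s)
}
apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$mu), 2, scaler$s, "/")
}

# ---- model backends --------------------------------------------------------

#' Default hyper-parameter grids per model family
#'
#' @param family one of `"knn"`, `"nb"`, `"svm"`, `"xgb"`, `"mlp"`,
#'   `"stacking"`.
#' @return list of named parameter lists (lexicographic order).
#' @export
default_param_grid <- function(family) {
  switch(family,
    knn = lapply(c(1, 3, 5, 7, 9), function(k) list(k = k)),
    nb = list(list(laplace = 0)),
    svm = {
      out <- list()
      for (C in c(0.1, 1, 10)) for (g in list("scale", 0.01, 0.1))
        out[[length(out) + 1L]] <- list(cost = C, gamma = g)
      out
    },
    xgb = {
      out <- list()
      for (d in c(2, 3, 4)) for (nr in c(50, 100, 200))
        for (eta in c(0.05, 0.1, 0.3))
          out[[length(out) + 1L]] <-
            list(max_depth = d, nrounds = nr, eta = eta)
      out
    },
    mlp = {
      out <- list()
      for (sz in c(8, 16, 32)) for (dec in c(1e-4, 1e-3))
        out[[length(out) + 1L]] <- list(size = sz, decay = dec)
      out
    },
    stacking = list(list()),
    stop(sprintf("unknown model family '%s'", family)))
}

#' Model/selection grid
#'
#' Expands model families, their hyper-parameter lists and the
#' select-K-best grid into an ordered list of grid points (ordered by K,
#' then lexicographic parameter order — also the deterministic tie-break
#' order of the grid search).
#'
#' @param families model families to include.
#' @param k_best K values (all must be <= 10).
#' @param params optional named list overriding [default_param_grid()]
#'   per family.
#' @return object of class `model_grid` (list of
#'   `list(family, params, k)`).
#' @export
model_grid <- function(families = "knn", k_best = 1:10, params = NULL) {
  if (any(k_best > 10L)) stop("K must be <= 10 to avoid overfitting")
  if (any(k_best < 1L)) stop("K must be >= 1")
  out <- list()
  for (k in sort(unique(as.integer(k_best))))
    for (fam in families) {
      pl <- params[[fam]] %||% default_param_grid(fam)
      for (p in pl)
        out[[length(out) + 1L]] <- list(family = fam, params = p, k = k)
    }
  structure(out, class = "model_grid")
}

resolve_gamma <- function(gamma, X) {
  if (identical(gamma, "scale")) 1 / (ncol(X) * max(var(as.vector(X)), 1e-12))
  else as.numeric(gamma)
}

fit_base_model <- function(family, params, X, y) {
  fit <- switch(family,
    knn = list(X = X, y = y, k = params$k),
    nb = e1071::naiveBayes(X, y, laplace = params$laplace %||% 0),
    svm = e1071::svm(X, y, kernel = "radial",
                     cost = params$cost %||% 1,
                     gamma = resolve_gamma(params$gamma %||% "scale", X),
                     probability = TRUE),
    xgb = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth %||% 3,
                    eta = params$eta %||% 0.1, nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = as.numeric(y == "acl"),
                                  nthread = 1),
      nrounds = params$nrounds %||% 100, verbose = 0),
    mlp = nnet::nnet(X, as.numeric(y == "acl"), size = params$size %||% 16,
                     decay = params$decay %||% 1e-3, maxit = 300,
                     entropy = TRUE, trace = FALSE),
    stop(sprintf("unknown model family '%s'", family)))
  list(family = family, params = params, fit = fit)
}

predict_base_prob <- function(model, X) {
  fit <- model$fit
  switch(model$family,
    knn = {
      pr <- class::knn(fit$X, X, fit$y, k = fit$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "acl", p, 1 - p)
    },
    nb = predict(fit, X, type = "raw")[, "acl"],
    svm = {
      pr <- predict(fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "acl"]
    },
    xgb = predict(fit, xgboost::xgb.DMatrix(X, nthread = 1)),
    mlp = as.numeric(predict(fit, X)))
}

predict_base_class <- function(model, X) {
  p <- predict_base_prob(model, X)
  factor(ifelse(p > 0.5, "acl", "healthy"), levels = COHORT_LEVELS)
}

# Stacking: five base learners with fixed configurations; LOSO
# out-of-fold probabilities on the training set feed a logistic
# regression meta-learner.
STACK_BASE <- list(
  knn = list(k = 5), nb = list(laplace = 0),
  svm = list(cost = 1, gamma = "scale"),
  xgb = list(max_depth = 3, nrounds = 100, eta = 0.1),
  mlp = list(size = 16, decay = 1e-3))

fit_stacking <- function(X, y, subject) {
  meta_X <- matrix(NA_real_, nrow(X), length(STACK_BASE),
                   dimnames = list(NULL, names(STACK_BASE)))
  for (s in unique(subject)) {
    hold <- subject == s
    for (fam in names(STACK_BASE)) {
      m <- fit_base_model(fam, STACK_BASE[[fam]],
                          X[!hold, , drop = FALSE], y[!hold])
      meta_X[hold, fam] <- predict_base_prob(m, X[hold, , drop = FALSE])
    }
  }
  base <- lapply(names(STACK_BASE), function(fam)
    fit_base_model(fam, STACK_BASE[[fam]], X, y))
  names(base) <- names(STACK_BASE)
  md <- data.frame(.y = as.numeric(y == "acl"), meta_X)
  meta <- suppressWarnings(glm(.y ~ ., data = md, family = binomial()))
  list(family = "stacking", base = base, meta = meta)
}

predict_stacking_prob <- function(model, X) {
  meta_X <- vapply(model$base, function(m) predict_base_prob(m, X),
                   numeric(nrow(X)))
  if (is.null(dim(meta_X))) meta_X <- matrix(meta_X, nrow = 1)
  nd <- as.data.frame(meta_X)
  names(nd) <- names(model$base)
  as.numeric(predict(model$meta, newdata = nd, type = "response"))
}

# ---- classifier = scaler + K-best + model ----------------------------------

#' Train a classifier on a feature data set
#'
#' Fits the full pipeline on the given rows only: z-scoring, K-best
#' selection by one-way F score, and the model — nothing outside `data`
#' is touched, which is the leakage guard of the evaluation protocol.
#'
#' @param data feature data.frame (rows = repetitions).
#' @param family model family.
#' @param params hyper-parameter list.
#' @param k number of features kept.
#' @return object of class `acl_classifier`.
#' @export
train_classifier <- function(data, family, params, k) {
  d <- split_feature_data(data)
  scaler <- fit_scaler(d$X)
  Xs <- apply_scaler(scaler, d$X)
  sel <- select_k_best(Xs, d$y, k)
  Xk <- Xs[, sel, drop = FALSE]
  model <- if (family == "stacking") fit_stacking(Xk, d$y, d$subject)
           else fit_base_model(family, params, Xk, d$y)
  structure(list(scaler = scaler, sel = sel,
                 features = colnames(d$X)[sel], model = model,
                 family = family, params = params, k = k),
            class = "acl_classifier")
}

#' Predict cohort labels with a trained classifier
#' @param object an `acl_classifier`.
#' @param newdata feature data.frame.
#' @param type `"class"` or `"prob"` (probability of the post-ACL class).
#' @param ... unused.
#' @return factor of labels or numeric probabilities.
#' @export
predict.acl_classifier <- function(object, newdata, type = "class", ...) {
  d <- split_feature_data(newdata)
  Xk <- apply_scaler(object$scaler, d$X)[, object$sel, drop = FALSE]
  p <- if (object$family == "stacking")
    predict_stacking_prob(object$model, Xk)
  else predict_base_prob(object$model, Xk)
  if (type == "prob") return(p)
  factor(ifelse(p > 0.5, "acl", "healthy"), levels = COHORT_LEVELS)
}

# ---- LOSO grid search ------------------------------------------------------

#' Leave-one-subject-out grid search
#'
#' For every grid point, holds out each subject in turn, fits scaling,
#' K-best selection and the model on the remaining subjects only, and
#' scores the held-out repetitions.  The grid point with the highest mean
#' per-subject accuracy wins; ties resolve to the smallest K, then the
#' first parameter combination in lexicographic grid order.
#'
#' @param data feature data.frame (>= 2 subjects).
#' @param grid a [model_grid()].
#' @param seed seed for the stochastic learners.
#' @return list: `best` (grid point), `accuracy` / `se` (training
#'   LOSO mean per-subject accuracy, percent), `per_subject`, `features`
#'   (K-best names refit on all rows at the optimum), `grid_results`.
#' @export
loso_grid_search <- function(data, grid, seed = 1L) {
  if (length(grid) == 0L) stop("grid is empty")
  d <- split_feature_data(data)
  subs <- unique(d$subject)
  if (length(subs) < 2L) stop("need at least 2 training subjects")
  res <- with_seed(seed, {
    lapply(grid, function(gp) {
      acc <- vapply(subs, function(s) {
        hold <- d$subject == s
        fit <- train_classifier(data[!hold, , drop = FALSE],
                                gp$family, gp$params, gp$k)
        pred <- predict(fit, data[hold, , drop = FALSE])
        mean(pred == d$y[hold])
      }, numeric(1))
      list(gp = gp, mean = mean(acc), per_subject = acc)
    })
  })
  means <- vapply(res, `[[`, numeric(1), "mean")
  best_i <- which.max(means)   # first max: smallest K, lexicographic params
  best <- res[[best_i]]
  final <- with_seed(child_seed(seed, 1L), {
    train_classifier(data, best$gp$family, best$gp$params, best$gp$k)
  })
  list(best = best$gp,
       accuracy = 100 * best$mean,
       se = 100 * sd(best$per_subject) / sqrt(length(subs)),
       per_subject = 100 * best$per_subject,
       features = final$features,
       classifier = final,
       grid_results = data.frame(
         index = seq_along(res),
         family = vapply(res, function(r) r$gp$family, character(1)),
         k = vapply(res, function(r) r$gp$k, numeric(1)),
         mean_accuracy = 100 * means))
}

# ---- confusion matrices and metrics ----------------------------------------

#' Confusion matrix constructor
#'
#' Pooled counts with the post-ACL cohort as the positive class.
#'
#' @param tp,fn,fp,tn non-negative integer counts.
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  v <- c(tp = unname(tp), fn = unname(fn), fp = unname(fp),
         tn = unname(tn))
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(as.list(round(v)), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (positive = post-ACL)\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("true acl", "true healthy"),
                              c("pred acl", "pred healthy")))
  print(m)
  invisible(x)
}

#' Metrics derived from a confusion matrix
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP)
#' and F1 2TP/(2TP+FP+FN) as percentages; Cohen's kappa (chance-corrected
#' agreement from the marginals, unitless) and pooled accuracy (%).
#' Zero-denominator metrics are `NA`.
#'
#' @param cm a [confusion_matrix()] or a list/vector with `tp`, `fn`,
#'   `fp`, `tn`.
#' @return named list of metrics.
#' @export
metrics_from_confusion <- function(cm) {
  tp <- cm$tp %||% cm["tp"]; fn <- cm$fn %||% cm["fn"]
  fp <- cm$fp %||% cm["fp"]; tn <- cm$tn %||% cm["tn"]
  n <- tp + fn + fp + tn
  if (n <= 0) stop("confusion matrix is empty")
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  list(sensitivity = rate(tp, tp + fn),
       specificity = rate(tn, tn + fp),
       precision = rate(tp, tp + fp),
       f1 = rate(2 * tp, 2 * tp + fp + fn),
       kappa = kappa,
       accuracy = 100 * po)
}

# ---- full evaluation protocol ---------------------------------------------

#' Run the full subject-stratified evaluation protocol
#'
#' For each of `n_permutations` random subject assignments: split the
#' subjects 6/2/4 (stratified), grid-search hyper-parameters and K by
#' LOSO on the 6 training subjects, confirm the optimum on the 2
#' validation subjects, merge into 8 subjects and re-tune by LOSO, then
#' score the 4 held-out test subjects.  Per-player accuracies and pooled
#' confusion counts accumulate across permutations.
#'
#' @param data feature data.frame (rows = repetitions, with `subject`
#'   and `cohort`).
#' @param grid a [model_grid()].
#' @param n_permutations number of random assignments.
#' @param seed master seed; expands to one seed per permutation.
#' @return object of class `metrics_report`.
#' @export
evaluate_protocol <- function(data, grid, n_permutations = 10, seed = 1L) {
  subjects <- unique(data[c("subject", "cohort")])
  perm_seeds <- with_seed(seed,
                          sample.int(2147483646L, n_permutations))
  counts <- c(tp = 0L, fn = 0L, fp = 0L, tn = 0L)
  test_rows <- train_rows <- val_rows <- list()
  perms <- list()
  for (p in seq_len(n_permutations)) {
    sp <- perm_seeds[p]
    plan <- stratified_split(subjects, sp)
    role_of <- stats::setNames(plan$role, plan$subject)
    rows_for <- function(role) data[role_of[data$subject] == role, , drop = FALSE]
    d_train <- rows_for("train")
    d_val <- rows_for("validation")
    d_merged <- rbind(d_train, d_val)
    gs1 <- loso_grid_search(d_train, grid, seed = child_seed(sp, 1L))
    val_fit <- with_seed(child_seed(sp, 2L), {
      train_classifier(d_train, gs1$best$family, gs1$best$params, gs1$best$k)
    })
    val_acc <- per_subject_accuracy(val_fit, d_val)
    gs2 <- loso_grid_search(d_merged, grid, seed = child_seed(sp, 3L))
    test_acc <- per_subject_accuracy(gs2$classifier, rows_for("test"))
    pred <- predict(gs2$classifier, rows_for("test"))
    truth <- factor(rows_for("test")$cohort, levels = COHORT_LEVELS)
    counts <- counts + c(
      tp = sum(pred == "acl" & truth == "acl"),
      fn = sum(pred == "healthy" & truth == "acl"),
      fp = sum(pred == "acl" & truth == "healthy"),
      tn = sum(pred == "healthy" & truth == "healthy"))
    train_rows[[p]] <- data.frame(perm = p, subject = names(gs2$per_subject),
                                  accuracy = unname(gs2$per_subject))
    val_rows[[p]] <- data.frame(perm = p, subject = names(val_acc),
                                accuracy = unname(val_acc))
    test_rows[[p]] <- data.frame(perm = p, subject = names(test_acc),
                                 accuracy = unname(test_acc))
    perms[[p]] <- list(seed = sp, plan = plan, best_train = gs1$best,
                       best_final = gs2$best, features = gs2$features)
  }
  test_df <- do.call(rbind, test_rows)
  train_df <- do.call(rbind, train_rows)
  cm <- confusion_matrix(counts["tp"], counts["fn"], counts["fp"],
                         counts["tn"])
  structure(list(
    test_accuracy = mean(test_df$accuracy),
    test_se = sd(test_df$accuracy) / sqrt(nrow(test_df)),
    train_accuracy = mean(train_df$accuracy),
    train_se = sd(train_df$accuracy) / sqrt(nrow(train_df)),
    per_subject = test_df,
    per_subject_train = train_df,
    per_subject_validation = do.call(rbind, val_rows),
    confusion = cm,
    metrics = metrics_from_confusion(cm),
    permutations = perms,
    n_permutations = n_permutations,
    seed = seed), class = "metrics_report")
}

per_subject_accuracy <- function(fit, data) {
  pred <- predict(fit, data)
  y <- factor(data$cohort, levels = COHORT_LEVELS)
  acc <- tapply(pred == y, data$subject, mean)
  100 * stats::setNames(as.numeric(acc), names(acc))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d permutation(s)\n", x$n_permutations))
  cat(sprintf("  test accuracy  %.2f%% (SE %.2f%%) over %d player scores\n",
              x$test_accuracy, x$test_se, nrow(x$per_subject)))
  cat(sprintf("  train accuracy %.2f%% (SE %.2f%%)\n",
              x$train_accuracy, x$train_se))
  m <- x$metrics
  cat(sprintf(
    "  pooled: acc %.2f%%  sens %.2f%%  spec %.2f%%  prec %.2f%%  F1 %.2f%%  kappa %.3f\n",
    m$accuracy, m$sensitivity, m$specificity, m$precision, m$f1, m$kappa))
  print(x$confusion)
  invisible(x)
}
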