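#' Stratified train/test split
#'
#' Splits samples into train and test partitions at the given ratio,
#' stratified by class with largest-remainder allocation (so the train size
#' is `round(ratio * n)` overall and class balance is preserved as closely
#' as integers allow).
#'
#' @param labels Binary labels (0/1), one per sample; both classes must be
#'   present with at least 2 samples each.
#' @param ratio Train fraction (default 0.7).
#' @param seed Integer seed; the same seed reproduces the same split.
#' @param stratify Stratify by class (default TRUE).
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   covering all samples).
#' @export
split_samples <- function(labels, ratio = 0.7, seed = 1L, stratify = TRUE) {
  labels <- as.integer(labels)
  if (ratio <= 0 || ratio >= 1) stop("'ratio' must be in (0, 1)",
                                     call. = FALSE)
  tab <- table(factor(labels, levels = c(0L, 1L)))
  if (any(tab == 0))
    stop("class absent: both classes must be present", call. = FALSE)
  if (any(tab < 2))
    stop("each class needs at least 2 samples", call. = FALSE)
  n <- length(labels)
  n_train <- round(ratio * n)
  with_seed(seed, {
    if (!stratify) {
      train <- sort(sample.int(n, n_train))
    } else {
      classes <- sort(unique(labels))
      quota <- ratio * as.numeric(tab[as.character(classes)])
      base <- floor(quota)
      rem <- quota - base
      extra <- n_train - sum(base)
      if (extra > 0) {
        give <- order(rem, decreasing = TRUE)[seq_len(extra)]
        base[give] <- base[give] + 1
      }
      train <- sort(unlist(lapply(seq_along(classes), function(i) {
        idx <- which(labels == classes[i])
        sample(idx, base[i])
      })))
    }
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney AUC with midrank tie handling: the probability that a random
#' positive outscores a random negative, plus half the tie mass.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 = positive); both classes required.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute an AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# ---- model grid -----------------------------------------------------------

selector_names <- function() c("none", "lasso", "elastic-net",
                               "stepwise-forward", "stepwise-backward",
                               "stepwise-both", "univariate-filter")

classifier_names <- function() c("logistic", "ridge-logistic",
                                 "lasso-logistic", "lda", "naive-bayes",
                                 "knn", "random-forest", "linear-svm",
                                 "gradient-boosting")

# Pairs where the selector would re-run the identical penalized fit the
# classifier performs; kept out of the grid.
incoherent_pairs <- function() list(c("lasso", "lasso-logistic"))

#' Enumerate feature-selector x classifier model combinations
#'
#' Builds the model grid of the integration framework: every classifier on
#' its own (selector `none`), plus every two-stage selector-classifier pair
#' except incoherent ones (a selector feeding a classifier that repeats the
#' identical penalized fit). The order is deterministic.
#'
#' @param selectors Selector names (default: the full registry, `none`
#'   first).
#' @param classifiers Classifier names (default: the full registry).
#' @param allow_two_stage Include selector-classifier pairs (default TRUE);
#'   when FALSE only the bare classifiers are returned.
#' @return List of `model_spec` objects (`selector`, `classifier`, `name`).
#' @export
enumerate_combinations <- function(selectors = selector_names(),
                                   classifiers = classifier_names(),
                                   allow_two_stage = TRUE) {
  if (length(classifiers) == 0) stop("no classifiers given", call. = FALSE)
  bad <- incoherent_pairs()
  specs <- list()
  for (sel in selectors) {
    if (sel != "none" && !allow_two_stage) next
    for (cls in classifiers) {
      if (sel != "none" &&
          any(vapply(bad, function(p) p[1] == sel && p[2] == cls,
                     logical(1)))) next
      name <- if (sel == "none") cls else paste(sel, "+", cls)
      specs[[length(specs) + 1L]] <-
        structure(list(selector = sel, classifier = cls, name = name),
                  class = "model_spec")
    }
  }
  names <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(names))
    stop("duplicate model spec names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "),
         call. = FALSE)
  specs
}

# ---- selectors ------------------------------------------------------------

# Per-gene Welch t-test p-values (vectorized).
univariate_p <- function(x, y) {
  a <- x[y == 1L, , drop = FALSE]
  b <- x[y == 0L, , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  va <- apply(a, 2, stats::var) / na
  vb <- apply(b, 2, stats::var) / nb
  se <- sqrt(va + vb)
  tt <- (colMeans(a) - colMeans(b)) / se
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df = df)
  p[!is.finite(p)] <- 1
  p
}

glmnet_foldid <- function(y, nfolds = 5) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  fold
}

select_glmnet <- function(x, y, alpha) {
  cv <- suppressWarnings(
    glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                      nfolds = 5, foldid = glmnet_foldid(y)))
  cf <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, 1]
  names(cf)[cf != 0]
}

# Stepwise logistic selection by AIC; features are pre-screened to the top
# univariate candidates so the underlying glm stays identifiable at small n.
select_stepwise <- function(x, y, direction) {
  n_keep <- min(ncol(x), max(2L, floor(nrow(x) / 3)))
  keep <- colnames(x)[order(univariate_p(x, y))[seq_len(n_keep)]]
  df <- data.frame(x[, keep, drop = FALSE], check.names = FALSE)
  df$.y <- y
  full <- stats::as.formula(paste(".y ~",
                                  paste(sprintf("`%s`", keep),
                                        collapse = " + ")))
  start <- suppressWarnings(
    if (direction == "backward")
      stats::glm(full, data = df, family = stats::binomial())
    else
      stats::glm(.y ~ 1, data = df, family = stats::binomial()))
  fit <- suppressWarnings(
    stats::step(start, scope = list(lower = .y ~ 1, upper = full),
                direction = direction, trace = 0))
  gsub("`", "", names(stats::coef(fit))[-1])
}

run_selector <- function(selector, x, y, alpha_filter = 0.05) {
  switch(selector,
    "none" = colnames(x),
    "lasso" = select_glmnet(x, y, alpha = 1),
    "elastic-net" = select_glmnet(x, y, alpha = 0.5),
    "stepwise-forward" = select_stepwise(x, y, "forward"),
    "stepwise-backward" = select_stepwise(x, y, "backward"),
    "stepwise-both" = select_stepwise(x, y, "both"),
    "univariate-filter" = colnames(x)[univariate_p(x, y) < alpha_filter],
    stop("unknown selector '", selector, "'", call. = FALSE))
}

# ---- classifiers ----------------------------------------------------------

# Each fitter returns list(predict = function(newx) scores,
#                          coefficients = named numeric or NULL).
fit_classifier <- function(classifier, x, y) {
  yf <- factor(y, levels = c(0L, 1L))
  switch(classifier,
    "logistic" = {
      df <- data.frame(x, check.names = FALSE); df$.y <- y
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                         family = stats::binomial()))
      cf <- stats::coef(fit)[-1]
      list(predict = function(newx) {
             nd <- data.frame(newx, check.names = FALSE)
             suppressWarnings(stats::predict(fit, nd, type = "link"))
           },
           coefficients = cf[!is.na(cf)])
    },
    "ridge-logistic" = ,
    "lasso-logistic" = {
      alpha <- if (classifier == "ridge-logistic") 0 else 1
      xx <- x
      if (ncol(xx) == 1) xx <- cbind(xx, .const = 0)  # glmnet needs >= 2
      cv <- suppressWarnings(
        glmnet::cv.glmnet(xx, y, family = "binomial", alpha = alpha,
                          nfolds = 5, foldid = glmnet_foldid(y)))
      cf <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, 1]
      list(predict = function(newx) {
             if (ncol(newx) == 1) newx <- cbind(newx, .const = 0)
             as.numeric(stats::predict(cv, newx, s = "lambda.min",
                                       type = "link"))
           },
           coefficients = cf[cf != 0 & names(cf) != ".const"])
    },
    "lda" = {
      sds <- apply(x, 2, stats::sd)
      keep <- sds > 0
      if (!any(keep)) stop("all features constant", call. = FALSE)
      xx <- x[, keep, drop = FALSE]
      fit <- suppressWarnings(MASS::lda(xx, grouping = yf))
      list(predict = function(newx)
             stats::predict(fit, newx[, keep, drop = FALSE])$posterior[, "1"],
           coefficients = stats::setNames(fit$scaling[, 1],
                                          colnames(xx)))
    },
    "naive-bayes" = {
      fit <- e1071::naiveBayes(x, yf)
      list(predict = function(newx)
             stats::predict(fit, newx, type = "raw")[, "1"],
           coefficients = NULL)
    },
    "knn" = {
      ks <- c(3, 5, 7, 9, 11)
      ks <- ks[ks < nrow(x)]
      if (length(ks) == 0) ks <- 1
      acc <- vapply(ks, function(k)
        mean(class::knn.cv(x, yf, k = k) == yf), numeric(1))
      k_best <- ks[which.max(acc)]
      list(predict = function(newx) {
             pr <- class::knn(x, newx, yf, k = k_best, prob = TRUE)
             p <- attr(pr, "prob")
             ifelse(pr == "1", p, 1 - p)
           },
           coefficients = NULL)
    },
    "random-forest" = {
      fit <- randomForest::randomForest(x, yf, ntree = 300)
      list(predict = function(newx)
             stats::predict(fit, newx, type = "prob")[, "1"],
           coefficients = NULL)
    },
    "linear-svm" = {
      fit <- e1071::svm(x, yf, kernel = "linear", scale = FALSE)
      dv <- function(newx)
        as.numeric(attr(stats::predict(fit, newx, decision.values = TRUE),
                        "decision.values"))
      flip <- if (auc(dv(x), y) < 0.5) -1 else 1    # orient using train only
      w <- flip * drop(crossprod(fit$coefs, fit$SV))
      list(predict = function(newx) flip * dv(newx),
           coefficients = stats::setNames(w, colnames(x)))
    },
    "gradient-boosting" = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y)
      params <- list(objective = "binary:logistic", max_depth = 2,
                     eta = 0.3, nthread = 1)
      cv <- xgboost::xgb.cv(params, dtrain, nrounds = 60, nfold = 4,
                            early_stopping_rounds = 10, verbose = 0,
                            stratified = TRUE)
      best <- cv$early_stop$best_iteration
      if (is.null(best)) best <- cv$niter
      fit <- xgboost::xgb.train(params, dtrain, nrounds = best)
      list(predict = function(newx)
             stats::predict(fit, xgboost::xgb.DMatrix(newx)),
           coefficients = NULL)
    },
    stop("unknown classifier '", classifier, "'", call. = FALSE))
}

#' Fit one selector-classifier combination and evaluate it on all partitions
#'
#' The selector is fitted on the training partition only; the classifier is
#' then fitted on the training partition restricted to the selected genes.
#' Internal tuning (penalty paths, k for knn, boosting rounds) uses
#' cross-validation within the training partition. AUCs are computed on
#' train, test, and validation; the selection criterion `mean_auc` averages
#' the test and validation AUCs only.
#'
#' A selector that returns zero genes yields a flagged result with all AUCs
#' 0.5 and an empty gene set.
#'
#' @param spec A `model_spec` from [enumerate_combinations()].
#' @param train,test,valid Lists with `x` (samples x genes matrix, shared
#'   columns) and `y` (binary labels).
#' @param seed Integer seed controlling all internal randomness.
#' @return A `model_result` list: `spec`, `genes_used`, `coefficients`,
#'   `auc_train`, `auc_test`, `auc_valid`, `mean_auc`, `flagged`.
#' @export
fit_evaluate <- function(spec, train, test, valid, seed = 1L) {
  stopifnot(inherits(spec, "model_spec") ||
              all(c("selector", "classifier", "name") %in% names(spec)))
  for (part in list(train, test, valid))
    stopifnot(is.matrix(part$x), length(part$y) == nrow(part$x))
  with_seed(seed, {
    genes <- run_selector(spec$selector, train$x, train$y)
    if (length(genes) == 0) {
      res <- list(spec = spec, genes_used = character(0),
                  coefficients = NULL, auc_train = 0.5, auc_test = 0.5,
                  auc_valid = 0.5, mean_auc = 0.5, flagged = TRUE)
      class(res) <- "model_result"
      return(res)
    }
    model <- fit_classifier(spec$classifier,
                            train$x[, genes, drop = FALSE], train$y)
    sc <- function(part)
      auc(model$predict(part$x[, genes, drop = FALSE]), part$y)
    auc_train <- sc(train)
    auc_test <- sc(test)
    auc_valid <- sc(valid)
    res <- list(spec = spec, genes_used = genes,
                coefficients = model$coefficients,
                auc_train = auc_train, auc_test = auc_test,
                auc_valid = auc_valid,
                mean_auc = (auc_test + auc_valid) / 2, flagged = FALSE)
    class(res) <- "model_result"
    res
  })
}

#' Fit and evaluate every model of a grid
#'
#' @param specs List of `model_spec`s (default: the full grid).
#' @param train,test,valid Partitions as in [fit_evaluate()].
#' @param seed Base seed; model i uses `seed + i`.
#' @return List of `model_result`s in grid order.
#' @export
evaluate_models <- function(specs = enumerate_combinations(), train, test,
                            valid, seed = 1L) {
  lapply(seq_along(specs), function(i)
    fit_evaluate(specs[[i]], train, test, valid, seed = seed + i))
}

#' Rank model results by mean test/validation AUC
#'
#' Descending `mean_auc`; ties broken by fewer genes used, then by name.
#'
#' @param results List of `model_result`s.
#' @return The same list, reordered (best first).
#' @export
rank_models <- function(results) {
  if (length(results) == 0) stop("no results to rank", call. = FALSE)
  mean_auc <- vapply(results, `[[`, numeric(1), "mean_auc")
  n_genes <- vapply(results, function(r) length(r$genes_used), integer(1))
  nm <- vapply(results, function(r) r$spec$name, character(1))
  results[order(-mean_auc, n_genes, nm)]
}

#' Per-gene model membership counts
#'
#' For each gene, the number of models whose final selected gene set
#' contains it.
#'
#' @param results List of `model_result`s.
#' @param genes Optional gene universe for zero counts of never-selected
#'   genes; default is the union of all `genes_used`.
#' @return Named integer vector, decreasing.
#' @export
gene_frequency <- function(results, genes = NULL) {
  if (length(results) == 0) stop("no results", call. = FALSE)
  used <- unlist(lapply(results, `[[`, "genes_used"))
  if (is.null(genes)) genes <- sort(unique(used))
  counts <- vapply(genes, function(g) sum(vapply(results, function(r)
    g %in% r$genes_used, logical(1))), integer(1))
  sort(counts, decreasing = TRUE)
}

#' Summarize a list of model results as a data frame
#'
#' @param results List of `model_result`s.
#' @return Data frame with one row per model: name, selector, classifier,
#'   n_genes, the three AUCs, mean_auc, flagged.
#' @export
model_summary <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(name = r$spec$name, selector = r$spec$selector,
               classifier = r$spec$classifier,
               n_genes = length(r$genes_used),
               auc_train = r$auc_train, auc_test = r$auc_test,
               auc_valid = r$auc_valid, mean_auc = r$mean_auc,
               flagged = r$flagged, stringsAsFactors = FALSE)))
}
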