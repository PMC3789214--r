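#' Fit the logistic diagnostic index
#'
#' Maximum-likelihood logistic regression of the binary outcome
#' (AD-converter = 1, MCI-stable = 0) on a set of biomarker features:
#' z = beta0 + sum_i beta_i x_i, with f(z) = 1 / (1 + exp(-z)) read as the
#' probability of conversion. On (quasi-)separated data the unpenalized
#' likelihood diverges; the fit is then redone with a tiny ridge penalty
#' (1e-6) and flagged `separated`.
#'
#' @param features data.frame or matrix of numeric features (subjects in
#'   rows); column names become the biomarker names of the model.
#' @param labels binary vector (0/1 or logical); both classes required.
#' @param threshold classification probability cutoff (default 0.5,
#'   boundary inclusive: f >= threshold predicts class 1).
#' @return A `logistic_index_model`: list with `beta0`, `betas` (named),
#'   `biomarker_names`, `threshold`, `separated`.
#' @export
fit_logistic <- function(features, labels, threshold = 0.5) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  if (length(y) != nrow(X)) stop("features and labels length mismatch")
  if (anyNA(X)) stop("missing feature values are not allowed in the fit")
  if (min(table(y)) < 2) stop("need at least 2 subjects per class")
  fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                         family = stats::binomial()))
  co <- fit$coefficients
  separated <- !fit$converged || any(!is.finite(co)) ||
    any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  if (separated || anyNA(co)) {
    co <- .ridge_logistic(X, y, lambda = 1e-6)
    separated <- TRUE
  }
  structure(list(beta0 = unname(co[1L]),
                 betas = stats::setNames(co[-1L], colnames(X)),
                 biomarker_names = colnames(X), threshold = threshold,
                 separated = separated),
            class = "logistic_index_model")
}

# penalized ML with a small L2 term; keeps coefficients finite under
# complete separation
.ridge_logistic <- function(X, y, lambda = 1e-6) {
  Xb <- cbind(1, X)
  nll <- function(b) {
    eta <- drop(Xb %*% b)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      lambda * sum(b[-1L]^2)
  }
  grad <- function(b) {
    p <- 1 / (1 + exp(-drop(Xb %*% b)))
    drop(crossprod(Xb, p - y)) + 2 * lambda * c(0, b[-1L])
  }
  opt <- stats::optim(rep(0, ncol(X) + 1L), nll, grad, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  stats::setNames(opt$par, c("(Intercept)", colnames(X)))
}

#' @export
print.logistic_index_model <- function(x, ...) {
  cat(sprintf("<logistic_index_model> %d biomarkers%s\n",
              length(x$betas), if (x$separated) " [separated: ridge-capped]" else ""))
  cat(sprintf("  beta0 = %.3g\n", x$beta0))
  for (nm in names(x$betas)) cat(sprintf("  %-40s %8.3g\n", nm, x$betas[nm]))
  invisible(x)
}

#' Predict conversion probability and class from a logistic index
#'
#' @param object a `logistic_index_model`.
#' @param newdata data.frame/matrix containing at least the model's
#'   biomarker columns.
#' @param ... unused.
#' @return data.frame with `probability` and `class` (1 = AD-converter when
#'   probability >= threshold, boundary inclusive).
#' @export
predict.logistic_index_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$biomarker_names, drop = FALSE]
  if (anyNA(X)) stop("missing feature value(s) for prediction")
  z <- object$beta0 + drop(X %*% object$betas)
  p <- 1 / (1 + exp(-z))
  data.frame(probability = p, class = as.integer(p >= object$threshold))
}

#' Classification outcome metrics
#'
#' Sensitivity, specificity, positive predictive value, positive likelihood
#' ratio and the Matthews correlation coefficient, plus the confusion
#' counts. Degenerate denominators: SP = 1 yields `PLR = Inf` (an ordered
#' sentinel above every finite PLR); an MCC denominator of 0 yields MCC 0;
#' PPV with no positive prediction is `NA`.
#'
#' @param predicted predicted classes (0/1).
#' @param truth true classes (0/1); both classes must be present.
#' @return An `outcome_metrics` list: `sensitivity`, `specificity`, `ppv`,
#'   `plr`, `mcc`, `tp`, `fp`, `tn`, `fn`.
#' @export
outcome_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  if (length(unique(truth)) < 2) stop("truth must contain both classes")
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  tn <- sum(predicted == 0 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  metrics_from_counts(tp, fp, tn, fn)
}

#' Outcome metrics from confusion counts
#' @param tp,fp,tn,fn confusion-matrix counts.
#' @return see [outcome_metrics()].
#' @export
metrics_from_counts <- function(tp, fp, tn, fn) {
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  plr <- if (sp == 1) Inf else se / (1 - sp)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else min(1, max(-1, (tp * tn - fp * fn) / den))
  structure(list(sensitivity = se, specificity = sp, ppv = ppv, plr = plr,
                 mcc = mcc, tp = tp, fp = fp, tn = tn, fn = fn),
            class = "outcome_metrics")
}

#' @export
print.outcome_metrics <- function(x, ...) {
  cat(sprintf("SE %.0f%%  SP %.0f%%  PPV %s  MCC %.2f  PLR %s  (TP %d FP %d TN %d FN %d)\n",
              100 * x$sensitivity, 100 * x$specificity,
              if (is.na(x$ppv)) "NA" else sprintf("%.0f%%", 100 * x$ppv),
              x$mcc,
              if (is.infinite(x$plr)) "Inf" else sprintf("%.1f", x$plr),
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Rank biomarkers by single-biomarker classification power
#'
#' Fits one logistic model per biomarker and ranks by the training Matthews
#' correlation coefficient (the seeding criterion of the genetic search).
#'
#' @param features subject x biomarker data.
#' @param labels binary outcome.
#' @return data.frame sorted by decreasing MCC: `biomarker`, `mcc`.
#' @export
rank_single_biomarkers <- function(features, labels) {
  X <- as.data.frame(features)
  mcc <- vapply(names(X), function(nm) {
    m <- fit_logistic(X[, nm, drop = FALSE], labels)
    outcome_metrics(predict(m, X[, nm, drop = FALSE])$class, labels)$mcc
  }, numeric(1))
  out <- data.frame(biomarker = names(X), mcc = mcc, row.names = NULL)
  out[order(-out$mcc), ]
}

#' Genetic-search configuration
#' @param n_generations generations to run (default 100).
#' @param rule_applications_per_rule offspring per mutation rule per
#'   generation (default 5, i.e., 20 offspring from the four rules).
#' @param seed_set_size size of the MCC-ranked seed set (default 5).
#' @param survival_criterion metric maximized across generations
#'   (default `"plr"`).
#' @param seed RNG seed.
#' @return a `genetic_search_config` list.
#' @export
genetic_search_config <- function(n_generations = 100,
                                  rule_applications_per_rule = 5,
                                  seed_set_size = 5,
                                  survival_criterion = "plr", seed = 1L) {
  stopifnot(n_generations >= 0, rule_applications_per_rule >= 1,
            seed_set_size >= 1)
  structure(list(n_generations = n_generations,
                 rule_applications_per_rule = rule_applications_per_rule,
                 seed_set_size = seed_set_size,
                 survival_criterion = survival_criterion, seed = seed),
            class = "genetic_search_config")
}

# survival ordering: criterion, then MCC, then smaller set (earlier
# candidate wins ties by strict >)
.survival_key <- function(metrics, set_size, criterion) {
  c(metrics[[criterion]], metrics$mcc, -set_size)
}

.key_greater <- function(k1, k2) {
  for (i in seq_along(k1)) {
    a <- k1[i]; b <- k2[i]
    if (is.infinite(a) && is.infinite(b) && a == b) next
    if (a > b) return(TRUE)
    if (a < b) return(FALSE)
  }
  FALSE
}

#' Genetic search for an optimal biomarker set
#'
#' Evolutionary wrapper selection around the logistic index: the current
#' set is mutated each generation by four rules (add a random biomarker,
#' remove one, draw a fresh random set of four, substitute one), each
#' applied `rule_applications_per_rule` times; every offspring is fitted by
#' logistic regression and scored on the training data by the survival
#' criterion (positive likelihood ratio by default), and only the best of
#' current-plus-offspring survives (elitism: the criterion trace is
#' non-decreasing). The search starts from the `seed_set_size` biomarkers
#' with the highest single-biomarker MCC. Set size is unconstrained.
#'
#' @param features training subject x biomarker data (no NAs).
#' @param labels binary outcome.
#' @param config a [genetic_search_config()].
#' @return list: `biomarkers` (selected set), `model` (fitted
#'   `logistic_index_model`), `criterion_trace` (best criterion per
#'   generation), `train_metrics`.
#' @export
genetic_search <- function(features, labels,
                           config = genetic_search_config()) {
  X <- as.data.frame(features)
  pool <- names(X)
  if (length(pool) < config$seed_set_size)
    stop("fewer candidate biomarkers than the seed set size")
  set.seed(config$seed)
  evaluate <- function(set) {
    m <- fit_logistic(X[, set, drop = FALSE], labels)
    mt <- outcome_metrics(predict(m, X[, set, drop = FALSE])$class, labels)
    list(model = m, metrics = mt,
         key = .survival_key(mt, length(set), config$survival_criterion))
  }
  ranking <- rank_single_biomarkers(X, labels)
  current_set <- ranking$biomarker[seq_len(config$seed_set_size)]
  current <- evaluate(current_set)
  trace <- numeric(config$n_generations)
  mutate <- function(set, rule) {
    switch(rule,
      add = unique(c(set, sample(setdiff(pool, set), 1))),
      remove = if (length(set) > 1) set[-sample.int(length(set), 1)] else set,
      fresh = sample(pool, min(4, length(pool))),
      substitute = {
        out <- set
        out[sample.int(length(set), 1)] <- sample(setdiff(pool, set), 1)
        unique(out)
      })
  }
  for (gen in seq_len(config$n_generations)) {
    for (rule in c("add", "remove", "fresh", "substitute")) {
      for (k in seq_len(config$rule_applications_per_rule)) {
        if (rule %in% c("add", "substitute") &&
            length(setdiff(pool, current_set)) == 0) next
        cand_set <- mutate(current_set, rule)
        cand <- evaluate(cand_set)
        if (.key_greater(cand$key, current$key)) {
          current <- cand
          current_set <- cand_set
        }
      }
    }
    trace[gen] <- current$metrics[[config$survival_criterion]]
  }
  list(biomarkers = current_set, model = current$model,
       criterion_trace = trace, train_metrics = current$metrics)
}

#' Elastic-net configuration
#'
#' `alpha` follows the L2-fraction convention alpha = lambda2 /
#' (lambda1 + lambda2): alpha = 1 is pure ridge, alpha = 0 pure lasso.
#' (This is the complement of glmnet's mixing parameter; the mapping is
#' handled internally.)
#'
#' @param alpha L2-fraction mixing parameter in \[0, 1\] (default 0.8).
#' @param n_cv_splits cross-validation folds for the lambda path
#'   (default 5).
#' @param seed RNG seed (fold assignment).
#' @return an `elastic_net_config` list.
#' @export
elastic_net_config <- function(alpha = 0.8, n_cv_splits = 5, seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1, n_cv_splits >= 3)
  structure(list(alpha = alpha, n_cv_splits = n_cv_splits, seed = seed),
            class = "elastic_net_config")
}

#' Elastic-net penalized logistic index
#'
#' Penalized logistic regression over a lambda path at the configured L1/L2
#' mix; lambda is chosen by `n_cv_splits`-fold cross-validated deviance
#' (lambda.min). Features are z-scored internally using their own
#' (training) statistics; returned coefficients are on the standardized
#' scale. Selected biomarkers are those with nonzero coefficients at the
#' chosen lambda. Zero-variance features are dropped with a warning.
#'
#' @param features training subject x biomarker data.
#' @param labels binary outcome.
#' @param config an [elastic_net_config()].
#' @return list: `biomarkers` (nonzero-coefficient set), `model` (a
#'   `logistic_index_model` holding the penalized coefficients plus the
#'   standardization to apply to new data), `lambda`, `glmnet_alpha`.
#' @export
fit_elastic_net <- function(features, labels, config = elastic_net_config()) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  mus <- colMeans(X)
  Z <- sweep(sweep(X, 2L, mus), 2L, sds, "/")
  glmnet_alpha <- 1 - config$alpha          # L1 fraction
  set.seed(config$seed)
  cv <- glmnet::cv.glmnet(Z, y, family = "binomial", alpha = glmnet_alpha,
                          nfolds = config$n_cv_splits,
                          type.measure = "deviance", standardize = FALSE)
  co <- as.numeric(stats::coef(cv, s = "lambda.min"))
  names(co) <- c("(Intercept)", colnames(Z))
  nz <- names(co)[-1L][co[-1L] != 0]
  model <- structure(
    list(beta0 = co[[1L]], betas = co[-1L][co[-1L] != 0],
         biomarker_names = nz, threshold = 0.5, separated = FALSE,
         standardize = list(mean = mus[nz], sd = sds[nz])),
    class = c("elastic_net_model", "logistic_index_model"))
  list(biomarkers = nz, model = model, lambda = cv$lambda.min,
       glmnet_alpha = glmnet_alpha)
}

#' @export
predict.elastic_net_model <- function(object, newdata, ...) {
  if (!length(object$biomarker_names)) {
    p <- rep(1 / (1 + exp(-object$beta0)), nrow(as.matrix(newdata)))
    return(data.frame(probability = p,
                      class = as.integer(p >= object$threshold)))
  }
  X <- as.matrix(newdata)[, object$biomarker_names, drop = FALSE]
  Z <- sweep(sweep(X, 2L, object$standardize$mean), 2L,
             object$standardize$sd, "/")
  z <- object$beta0 + drop(Z %*% object$betas)
  p <- 1 / (1 + exp(-z))
  data.frame(probability = p, class = as.integer(p >= object$threshold))
}

#' Monte-Carlo significance thresholds for outcome metrics
#'
#' Null model: a random classifier that labels each subject positive with
#' probability 0.5, independent of the fixed true labels. For each of
#' `n_iterations` draws all five outcome metrics are computed; the
#' `level`-quantiles of the null distributions are the critical values
#' (a classification beating them differs significantly from random).
#'
#' @param n_subjects total number of subjects.
#' @param n_positive number of true positives among them.
#' @param n_iterations Monte-Carlo draws (default 5000).
#' @param level quantile level (default 0.95).
#' @param seed RNG seed.
#' @return named numeric vector: critical values for `mcc`, `sensitivity`,
#'   `specificity`, `ppv`, `plr`.
#' @export
monte_carlo_thresholds <- function(n_subjects, n_positive,
                                   n_iterations = 5000, level = 0.95,
                                   seed = 1L) {
  stopifnot(n_positive > 0, n_positive < n_subjects)
  set.seed(seed)
  n_neg <- n_subjects - n_positive
  tp <- stats::rbinom(n_iterations, n_positive, 0.5)
  fp <- stats::rbinom(n_iterations, n_neg, 0.5)
  fn <- n_positive - tp
  tn <- n_neg - fp
  se <- tp / n_positive
  sp <- tn / n_neg
  ppv <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  plr <- ifelse(sp == 1, Inf, se / (1 - sp))
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- ifelse(den == 0, 0, (tp * tn - fp * fn) / den)
  q <- function(v) unname(stats::quantile(v, level, na.rm = TRUE))
  c(mcc = q(mcc), sensitivity = q(se), specificity = q(sp), ppv = q(ppv),
    plr = q(plr))
}

#' Half-split cross-validation of the diagnostic index
#'
#' Repeatedly splits the subjects randomly in half (stratified by class),
#' trains on the first half and evaluates on the second, reporting the
#' median of each outcome metric across iterations. By default the
#' biomarker set is fixed and only the logistic fit is redone per split;
#' with `reselect`, the supplied selection procedure is rerun inside every
#' split.
#'
#' @param features subject x biomarker data.
#' @param labels binary outcome.
#' @param n_iterations number of random half-splits (default 1000).
#' @param seed RNG seed.
#' @param reselect optional function(features, labels) returning a
#'   character vector of biomarker names, applied per split.
#' @return named numeric vector of median `sensitivity`, `specificity`,
#'   `ppv`, `mcc`, `plr`.
#' @export
half_split_cv <- function(features, labels, n_iterations = 1000, seed = 1L,
                          reselect = NULL) {
  X <- as.data.frame(features)
  y <- as.integer(labels)
  if (min(table(y)) < 4) stop("need at least 4 subjects per class")
  set.seed(seed)
  ipos <- which(y == 1); ineg <- which(y == 0)
  res <- matrix(NA_real_, n_iterations, 5,
                dimnames = list(NULL, c("sensitivity", "specificity", "ppv",
                                        "mcc", "plr")))
  it <- 1L
  while (it <= n_iterations) {
    tr <- c(sample(ipos, floor(length(ipos) / 2)),
            sample(ineg, floor(length(ineg) / 2)))
    te <- setdiff(seq_along(y), tr)
    if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) next
    sel <- if (is.null(reselect)) names(X)
           else reselect(X[tr, , drop = FALSE], y[tr])
    m <- tryCatch(fit_logistic(X[tr, sel, drop = FALSE], y[tr]),
                  error = function(e) NULL)
    if (is.null(m)) next
    mt <- outcome_metrics(predict(m, X[te, sel, drop = FALSE])$class, y[te])
    res[it, ] <- c(mt$sensitivity, mt$specificity, mt$ppv, mt$mcc, mt$plr)
    it <- it + 1L
  }
  apply(res, 2L, stats::median, na.rm = TRUE)
}
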