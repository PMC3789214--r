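#' Channel-wise two-sample t-test
#'
#' Classical equal-variance Student t-test (Welch available via
#' `var_equal = FALSE`) on one biomarker at one channel.
#'
#' @param a,b numeric vectors of per-subject biomarker values for the two
#'   groups (NAs dropped).
#' @param var_equal pool variances (default TRUE).
#' @return two-sided p-value, or `NA` when either group has fewer than two
#'   non-missing values.
#' @export
channelwise_ttest <- function(a, b, var_equal = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  stats::t.test(a, b, var.equal = var_equal)$p.value
}

#' Binomial multiple-comparison correction over channels
#'
#' Declares a biomarker significant when at least `k_min` channels reach
#' `p < alpha` individually, and reports the binomial tail probability
#' P(X >= count) for X ~ Binomial(n valid channels, alpha) for
#' transparency (at 21 channels and alpha = 0.05 the tail for k = 3 is
#' slightly above 0.05; the k_min = 3 rule is applied as stated).
#'
#' @param p_values per-channel p-values (NAs excluded from the count and n).
#' @param alpha per-channel significance level.
#' @param k_min minimum number of significant channels.
#' @return list: `corrected_significant`, `n_significant`, `n_valid`,
#'   `binomial_tail_p`.
#' @export
binomial_channel_correction <- function(p_values, alpha = 0.05, k_min = 3) {
  valid <- p_values[is.finite(p_values)]
  if (!length(valid)) stop("need at least one valid channel p-value")
  k <- sum(valid < alpha)
  list(corrected_significant = k >= k_min,
       n_significant = k, n_valid = length(valid),
       binomial_tail_p = stats::pbinom(k - 1, length(valid), alpha,
                                       lower.tail = FALSE))
}

#' Group difference map over a cohort of biomarker tensors
#'
#' For every biomarker and channel, a two-sample Student t-test between the
#' two groups, followed by the binomial channel-count correction per
#' biomarker. Group medians per channel are recorded alongside.
#'
#' @param tensors list of `biomarker_tensor`s (one recording each), all with
#'   the same registry and montage.
#' @param group_a,group_b the two group labels to contrast.
#' @param alpha,k_min see [binomial_channel_correction()].
#' @param var_equal see [channelwise_ttest()].
#' @return A `difference_map`: list with `p_values` (biomarker x channel),
#'   `median_a`, `median_b`, `significance_mask`, `corrected_significant`
#'   (named logical), `significant_channels` (named list), `alpha`, `k_min`.
#' @export
difference_map <- function(tensors, group_a = "MCI-stable",
                           group_b = "AD-converter", alpha = 0.05,
                           k_min = 3, var_equal = TRUE) {
  grp <- vapply(tensors, function(t) t$group, character(1))
  ia <- which(grp == group_a); ib <- which(grp == group_b)
  if (!length(ia) || !length(ib)) stop("both groups must be present")
  v0 <- tensors[[1L]]$values
  P <- matrix(NA_real_, nrow(v0), ncol(v0), dimnames = dimnames(v0))
  A <- vapply(tensors[ia], function(t) t$values, v0)
  B <- vapply(tensors[ib], function(t) t$values, v0)
  for (i in seq_len(nrow(v0))) for (j in seq_len(ncol(v0)))
    P[i, j] <- channelwise_ttest(A[i, j, ], B[i, j, ], var_equal = var_equal)
  mask <- is.finite(P) & P < alpha
  corr <- logical(nrow(P)); names(corr) <- rownames(P)
  tail_p <- numeric(nrow(P)); names(tail_p) <- rownames(P)
  sig_ch <- stats::setNames(vector("list", nrow(P)), rownames(P))
  for (i in seq_len(nrow(P))) {
    if (!any(is.finite(P[i, ]))) { corr[i] <- FALSE; tail_p[i] <- NA; next }
    bc <- binomial_channel_correction(P[i, ], alpha, k_min)
    corr[i] <- bc$corrected_significant
    tail_p[i] <- bc$binomial_tail_p
    sig_ch[[i]] <- colnames(P)[mask[i, ]]
  }
  structure(list(p_values = P,
                 median_a = apply(A, c(1, 2), stats::median, na.rm = TRUE),
                 median_b = apply(B, c(1, 2), stats::median, na.rm = TRUE),
                 significance_mask = mask, corrected_significant = corr,
                 binomial_tail_p = tail_p, significant_channels = sig_ch,
                 alpha = alpha, k_min = k_min,
                 groups = c(group_a, group_b)),
            class = "difference_map")
}

#' @export
print.difference_map <- function(x, ...) {
  cat(sprintf("<difference_map> %d biomarkers x %d channels (%s vs %s)\n",
              nrow(x$p_values), ncol(x$p_values), x$groups[1L], x$groups[2L]))
  cat(sprintf("  %d biomarkers pass the binomial channel correction (>=%d channels p<%g)\n",
              sum(x$corrected_significant), x$k_min, x$alpha))
  invisible(x)
}

#' Reduce tensors to a subject-by-biomarker feature table
#'
#' For each biomarker passing the binomial correction in the (training)
#' difference map, each subject's feature is the median of that biomarker
#' over the map's significant channels. The channel sets are frozen in the
#' map and reused verbatim for any cohort (in particular for test-visit
#' data), so no test information leaks into the feature definition.
#'
#' @param tensors list of `biomarker_tensor`s to reduce.
#' @param dmap a [difference_map()] computed on the training visit.
#' @return A data.frame with columns `subject_id`, `group`, `visit` and one
#'   column per selected biomarker (medians over significant channels;
#'   missing channel values are dropped from the median).
#' @export
reduce_to_features <- function(tensors, dmap) {
  sel <- names(dmap$corrected_significant)[dmap$corrected_significant]
  sel <- sel[vapply(dmap$significant_channels[sel], length, integer(1)) > 0]
  if (!length(sel)) stop("no biomarker passes the binomial correction")
  rows <- lapply(tensors, function(t) {
    feats <- vapply(sel, function(bm) {
      ch <- intersect(dmap$significant_channels[[bm]], colnames(t$values))
      stats::median(t$values[bm, ch], na.rm = TRUE)
    }, numeric(1))
    cbind(data.frame(subject_id = t$subject_id, group = t$group,
                     visit = t$visit, stringsAsFactors = FALSE),
          as.data.frame(as.list(feats), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation test for a difference in medians
#'
#' Two-sided test of the absolute difference in group medians under random
#' relabeling. When the number of distinct splits is small enough the
#' permutation distribution is enumerated exactly; otherwise `n_perm` random
#' permutations are drawn and the +1-corrected Monte-Carlo p-value is
#' returned.
#'
#' @param a,b numeric samples.
#' @param n_perm number of random permutations (default 5000).
#' @param seed integer seed for the sampled variant.
#' @return list: `p_value`, `observed` (median(a) - median(b)), `exact`.
#' @export
permutation_test_median <- function(a, b, n_perm = 5000, seed = 1L) {
  stopifnot(length(a) > 0, length(b) > 0)
  pooled <- c(a, b)
  if (stats::sd(pooled) == 0)
    return(list(p_value = 1, observed = 0, exact = TRUE))
  na <- length(a)
  obs <- stats::median(a) - stats::median(b)
  stat <- function(idx) stats::median(pooled[idx]) - stats::median(pooled[-idx])
  n_splits <- choose(length(pooled), na)
  if (n_splits <= n_perm) {
    splits <- utils::combn(length(pooled), na)
    d <- apply(splits, 2L, stat)
    list(p_value = mean(abs(d) >= abs(obs) - 1e-12), observed = obs,
         exact = TRUE)
  } else {
    set.seed(seed)
    d <- replicate(n_perm, stat(sample.int(length(pooled), na)))
    list(p_value = (sum(abs(d) >= abs(obs) - 1e-12) + 1) / (n_perm + 1),
         observed = obs, exact = FALSE)
  }
}

#' Bias-corrected and accelerated bootstrap confidence interval
#'
#' BCa interval for a statistic (default: the median) via the `boot`
#' package; degenerate all-equal samples return a zero-width interval.
#'
#' @param x numeric sample (n >= 8).
#' @param statistic function of a numeric vector (default `median`).
#' @param n_boot bootstrap replicates (default 5000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return numeric `c(low, high)`.
#' @export
bca_bootstrap_ci <- function(x, statistic = stats::median, n_boot = 5000,
                             level = 0.95, seed = 1L) {
  if (length(x) < 8) stop("need at least 8 observations")
  if (stats::sd(x) == 0) return(c(statistic(x), statistic(x)))
  set.seed(seed)
  bt <- boot::boot(x, function(d, i) statistic(d[i]), R = n_boot)
  ci <- boot::boot.ci(bt, conf = level, type = "bca")
  unname(ci$bca[1L, 4:5])
}

#' Barnard's unconditional exact test for a 2x2 table
#'
#' Two-sided unconditional exact test ordered by the pooled score (Wald)
#' statistic, maximizing the tail probability over the nuisance success
#' probability on an equally spaced grid in (0, 1).
#'
#' @param tab 2x2 matrix of non-negative integer counts; rows are groups,
#'   columns outcomes.
#' @param n_grid number of nuisance-parameter grid points (default 1000).
#' @return list: `p_value`, `statistic` (observed score statistic).
#' @export
barnard_exact_test <- function(tab, n_grid = 1000) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0), all(tab == round(tab)))
  n1 <- sum(tab[1L, ]); n2 <- sum(tab[2L, ])
  if (n1 == 0 || n2 == 0 || any(colSums(tab) == 0))
    stop("all table margins must be positive")
  score <- function(x1, x2) {
    p1 <- x1 / n1; p2 <- x2 / n2
    pp <- (x1 + x2) / (n1 + n2)
    den <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    ifelse(den == 0, 0, (p1 - p2) / den)
  }
  obs <- score(tab[1L, 1L], tab[2L, 1L])
  g <- expand.grid(x1 = 0:n1, x2 = 0:n2)
  s <- abs(score(g$x1, g$x2))
  extreme <- s >= abs(obs) - 1e-12
  pis <- seq(1 / (n_grid + 1), n_grid / (n_grid + 1), length.out = n_grid)
  pmax_val <- 0
  lx1 <- lchoose(n1, g$x1); lx2 <- lchoose(n2, g$x2)
  xs <- g$x1 + g$x2; nn <- n1 + n2
  le <- which(extreme)
  for (pi in pis) {
    lp <- lx1[le] + lx2[le] + xs[le] * log(pi) + (nn - xs[le]) * log1p(-pi)
    pmax_val <- max(pmax_val, sum(exp(lp)))
  }
  list(p_value = min(1, pmax_val), statistic = obs)
}
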