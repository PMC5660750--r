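# Cross-validated evaluation: stratified folds, ROC/AUC, stringency-level
# confusion metrics and top-percentile retrieval.

#' Seeded stratified fold assignment
#'
#' Splits positives and negatives separately so every fold's positive count
#' differs by at most one from any other.
#'
#' @param labels Binary 0/1 vector.
#' @param k Number of folds (default 10).
#' @param seed Integer seed; the assignment is deterministic given the seed
#'   and does not disturb the caller's RNG state.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  if (k < 2) abort("need at least 2 folds", class = "kinsub_argument_error")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos < k || n_neg < k) {
    warn(sprintf(
      "only %d positives / %d negatives for %d folds; some test folds will be single-class",
      n_pos, n_neg, k))
  }
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in c(1, 0)) {
      idx <- sample(which(labels == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the fraction of
#' (positive, negative) pairs where the positive scores higher, ties
#' counting one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 vector aligned with `scores`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC undefined: need both classes", class = "kinsub_argument_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return Tibble with `threshold`, `fpr`, `tpr`, one row per distinct
#'   score plus the two trivial endpoints, ordered by increasing FPR.
#' @export
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each tied block
  tp <- cumsum(l)[keep]; fp <- cumsum(1 - l)[keep]
  tibble(threshold = c(Inf, s[keep]),
         fpr = c(0, fp / max(sum(1 - l), 1)),
         tpr = c(0, tp / max(sum(l), 1)))
}

#' Classification metrics from a confusion table
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, F1 `2*Pre*Sn/(Pre+Sn)` and the Matthews correlation
#' coefficient.  A zero denominator in Pre, F1 or MCC yields 0 with
#' `degenerate = TRUE` so batch tables never carry undefined entries.
#'
#' @param tp,fp,tn,fn Nonnegative confusion counts.
#' @return One-row tibble with the counts, the five metrics and a
#'   `degenerate` flag.
#' @export
metrics_from_confusion <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sn <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  pre <- safe_div(tp, tp + fp)
  f1 <- if (is.na(pre) || is.na(sn) || pre + sn == 0) NA_real_
        else 2 * pre * sn / (pre + sn)
  mcc_den <- sqrt(tn + fn) * sqrt(tn + fp) * sqrt(tp + fn) * sqrt(tp + fp)
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  degenerate <- anyNA(c(sn, sp, pre, f1, mcc))
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         sn = sn %|0|% 0, sp = sp %|0|% 0, pre = pre %|0|% 0,
         f1 = f1 %|0|% 0, mcc = mcc %|0|% 0, degenerate = degenerate)
}

`%|0|%` <- function(x, y) if (is.na(x)) y else x

#' Operating point at a target specificity
#'
#' Scans the achievable thresholds (predicted positive means
#' `score >= threshold`) and picks the one that maximizes sensitivity
#' subject to specificity at or above the target; no ROC interpolation is
#' performed, and the realized specificity is returned alongside.
#'
#' @inheritParams roc_auc
#' @param sp_target Target specificity in (0, 1\].
#' @return One-row tibble: `sp_target`, `threshold`, confusion counts and
#'   metrics at the chosen threshold.
#' @export
metrics_at_specificity <- function(scores, labels, sp_target = 0.9) {
  if (sp_target <= 0 || sp_target > 1) {
    abort("sp_target must be in (0, 1]", class = "kinsub_argument_error")
  }
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("need both classes", class = "kinsub_argument_error")
  }
  thresholds <- c(sort(unique(scores), decreasing = TRUE), Inf)
  best <- NULL
  for (t in thresholds) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    sp <- (n_neg - fp) / n_neg
    if (sp >= sp_target) {
      # ties in Sn resolve to the lowest feasible threshold, so the
      # realized specificity sits as close to the target as achievable
      cand <- list(t = t, tp = tp, fp = fp)
      if (is.null(best) || cand$tp >= best$tp) best <- cand
    }
  }
  m <- metrics_from_confusion(best$tp, best$fp, n_neg - best$fp,
                              n_pos - best$tp)
  dplyr::bind_cols(tibble(sp_target = sp_target, threshold = best$t), m)
}

#' True positives among the top-ranked percentiles
#'
#' Ranks by descending score (ties broken by the stable input order) and,
#' for each percentile `p`, counts the known-positive items among the top
#' `floor(p/100 * n)` predictions, together with the recall fraction.
#'
#' @inheritParams roc_auc
#' @param percentiles Percentile values in (0, 100\] (default
#'   `c(1, 2, 5, 10, 15)`).
#' @return Tibble with `percentile`, `n_top`, `n_true`, `recall`.
#' @export
top_percentile_retrieval <- function(scores, labels,
                                     percentiles = c(1, 2, 5, 10, 15)) {
  if (any(percentiles <= 0 | percentiles > 100)) {
    abort("percentiles must lie in (0, 100]", class = "kinsub_argument_error")
  }
  ord <- order(-scores, seq_along(scores))
  l <- labels[ord]
  total <- sum(labels == 1)
  purrr::map_dfr(percentiles, function(p) {
    n_top <- floor(p / 100 * length(scores))
    n_true <- sum(l[seq_len(n_top)] == 1)
    tibble(percentile = p, n_top = n_top, n_true = n_true,
           recall = if (total > 0) n_true / total else 0)
  })
}

weight_of <- function(config, name) {
  v <- unname(config$kernel_weights[name])
  if (length(v) == 0 || is.na(v)) 1 else v
}

# per-fold kernel construction + fit + test scoring for one kinase
cv_fold_scores <- function(bundle, kinase, config, ablation, folds,
                           labels, seq_raw, ppi_full) {
  k <- max(folds)
  sites <- bundle$sites
  Y <- bundle$adjacency
  scores <- numeric(nrow(sites))
  for (f in seq_len(k)) {
    test <- folds == f
    train <- !test
    parts_tr <- list(); parts_te <- list(); wts <- c()
    if ("seq" %in% ablation) {
      rng <- range(seq_raw[train, train])
      parts_tr <- c(parts_tr, list(normalize_seq(seq_raw[train, train,
                                                         drop = FALSE], rng)))
      parts_te <- c(parts_te, list(normalize_seq(seq_raw[test, train,
                                                         drop = FALSE], rng)))
      wts <- c(wts, weight_of(config, "seq"))
    }
    if ("ppi" %in% ablation) {
      parts_tr <- c(parts_tr, list(ppi_full[train, train, drop = FALSE]))
      parts_te <- c(parts_te, list(ppi_full[test, train, drop = FALSE]))
      wts <- c(wts, weight_of(config, "ppi"))
    }
    if ("net" %in% ablation) {
      Ym <- mask_profiles(Y, config$mask_policy, kinase,
                          test_sites = sites$site_id[test])
      g <- pskn_bandwidth(Ym[train, , drop = FALSE], config$gamma_prime)
      parts_tr <- c(parts_tr, list(
        gaussian_profile_kernel(Ym[train, , drop = FALSE],
                                Ym[train, , drop = FALSE], g)))
      parts_te <- c(parts_te, list(
        gaussian_profile_kernel(Ym[test, , drop = FALSE],
                                Ym[train, , drop = FALSE], g)))
      wts <- c(wts, weight_of(config, "net"))
    }
    wts <- wts / sum(wts)
    K_tr <- Reduce(`+`, Map(`*`, parts_tr, wts))
    K_te <- Reduce(`+`, Map(`*`, parts_te, wts))
    alpha <- ridge_solve(K_tr, labels[train], config$lambda)
    scores[test] <- drop(K_te %*% alpha)
  }
  scores
}

#' Cross-validated evaluation of one kinase model
#'
#' Runs seeded stratified k-fold cross-validation for a single kinase with
#' the requested kernel ablation.  Within each fold every kernel is built
#' from training-fold information only: the sequence min/max comes from the
#' training submatrix, the network-profile bandwidth from the training rows
#' of the masked adjacency; the PPI kernel is static.  The report carries
#' per-fold AUCs and their mean, the pooled-prediction AUC, ROC points, and
#' confusion metrics at the requested stringency (target specificity)
#' levels computed on the pooled predictions.
#'
#' @param bundle A `ksr_bundle`.
#' @param kinase Kinase to evaluate (a column of the adjacency).
#' @param config A [ksr_config()].
#' @param ablation Character subset of `c("seq", "ppi", "net")` naming the
#'   kernels to combine (default all three).
#' @param k Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @param sp_targets Stringency levels (default medium 0.90 and high 0.95).
#' @param labels Optional explicit 0/1 label vector overriding
#'   [label_vector()] — used for permutation nulls.
#' @return A `ksr_eval` object.
#' @export
cross_validate <- function(bundle, kinase, config = ksr_config(),
                           ablation = c("seq", "ppi", "net"), k = 10L,
                           seed = 1L, sp_targets = c(0.90, 0.95),
                           labels = NULL) {
  stopifnot(all(ablation %in% c("seq", "ppi", "net")), length(ablation) >= 1)
  labels <- labels %||% label_vector(bundle$adjacency, kinase)
  folds <- stratified_folds(labels, k = k, seed = seed)
  seq_raw <- if ("seq" %in% ablation)
    blosum_raw_matrix(setNames(bundle$sites$window, bundle$sites$site_id),
                      pad = config$pad)
  ppi_full <- if ("ppi" %in% ablation)
    unclass(ppi_kernel(bundle$sites, bundle$ppi))
  scores <- cv_fold_scores(bundle, kinase, config, ablation, folds,
                           labels, seq_raw, ppi_full)
  fold_auc <- vapply(seq_len(k), function(f) {
    l <- labels[folds == f]
    if (length(unique(l)) < 2) {
      warn(sprintf("fold %d has a single-class test set; AUC skipped", f))
      return(NA_real_)
    }
    roc_auc(scores[folds == f], l)
  }, numeric(1))
  stringency <- purrr::map_dfr(sp_targets, function(sp)
    metrics_at_specificity(scores, labels, sp))
  structure(list(
    kinase = kinase, ablation = sort(ablation), k = k, seed = seed,
    scores = tibble(site_id = bundle$sites$site_id, label = labels,
                    fold = folds, score = scores),
    fold_auc = fold_auc,
    mean_fold_auc = mean(fold_auc, na.rm = TRUE),
    pooled_auc = roc_auc(scores, labels),
    stringency = stringency,
    roc = roc_points(scores, labels),
    config = config), class = "ksr_eval")
}

#' @export
print.ksr_eval <- function(x, ...) {
  cat(sprintf(
    "<ksr_eval> %s [%s] %d-fold: pooled AUC %.3f (fold mean %.3f)\n",
    x$kinase, paste(x$ablation, collapse = "+"), x$k, x$pooled_auc,
    x$mean_fold_auc))
  invisible(x)
}

#' @export
tidy.ksr_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble(kinase = x$kinase, ablation = paste(x$ablation, collapse = "+")),
    x$stringency)
}

#' @export
glance.ksr_eval <- function(x, ...) {
  tibble(kinase = x$kinase, ablation = paste(x$ablation, collapse = "+"),
         k = x$k, seed = x$seed,
         n_pos = sum(x$scores$label == 1), n_neg = sum(x$scores$label == 0),
         pooled_auc = x$pooled_auc, mean_fold_auc = x$mean_fold_auc)
}

#' Evaluate every eligible kinase under several ablations
#'
#' @param bundle A `ksr_bundle`.
#' @param config A [ksr_config()].
#' @param ablations Named list of kernel subsets (default the three
#'   headline configurations: sequence only, sequence + network profiles,
#'   and the full three-kernel model).
#' @inheritParams cross_validate
#' @return A list with `report` (tibble: one row per kinase x ablation x
#'   stringency level) and `summaries` (tibble of pooled/fold-mean AUCs),
#'   plus all `ksr_eval` objects in `evals`.
#' @export
evaluate_kinases <- function(bundle, config = ksr_config(),
                             ablations = list(seq = "seq",
                                              seq_pskn = c("seq", "net"),
                                              full = c("seq", "ppi", "net")),
                             k = 10L, seed = 1L,
                             sp_targets = c(0.90, 0.95)) {
  kinases <- select_model_kinases(bundle$adjacency, config$min_positives)
  evals <- list()
  for (kin in kinases) {
    for (ab_name in names(ablations)) {
      evals[[paste(kin, ab_name, sep = ".")]] <-
        cross_validate(bundle, kin, config, ablation = ablations[[ab_name]],
                       k = k, seed = seed, sp_targets = sp_targets)
    }
  }
  report <- purrr::map_dfr(evals, tidy)
  summaries <- purrr::map_dfr(evals, glance)
  list(report = report, summaries = summaries, evals = evals)
}

#' ROC curve plot for a cross-validation result
#'
#' @param object A `ksr_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ksr_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s (%s), pooled AUC %.3f", object$kinase,
                      paste(object$ablation, collapse = "+"),
                      object$pooled_auc),
      x = "False positive rate (1 - Sp)", y = "True positive rate (Sn)") +
    ggplot2::theme_minimal()
}

#' Stringency-level metric bars across kinases and ablations
#'
#' @param report Report tibble from [evaluate_kinases()].
#' @param sp_target Which stringency level to show (default 0.9).
#' @return A ggplot object: Sn/MCC/F1/Pre bars per kinase, filled by
#'   ablation.
#' @export
plot_stringency_bars <- function(report, sp_target = 0.9) {
  df <- report[abs(report$sp_target - sp_target) < 1e-9, , drop = FALSE] |>
    tidyr::pivot_longer(cols = c("sn", "mcc", "f1", "pre"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value,
                                   fill = .data$ablation)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~kinase) +
    ggplot2::labs(title = sprintf("Metrics at Sp >= %.0f%%", 100 * sp_target),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
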