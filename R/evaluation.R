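#' Ranking quality: ROC summary with mid-rank AUC
#'
#' AUC is computed from mid-ranks (equivalent to the Mann-Whitney U statistic
#' divided by `n_pos * n_neg`), so tied scores contribute half. The ROC curve
#' is traced over all distinct score thresholds, and confusion metrics are
#' reported at a fixed score threshold (default: score > 0 predicts the
#' interest class, the neutral point of a +/-1 voting scheme).
#'
#' @param scores numeric scores, larger meaning more interest-like.
#' @param labels logical (or 0/1) true class, `TRUE` = interest.
#' @param threshold score threshold for the confusion metrics; a sample is
#'   called positive when `score > threshold`.
#' @return List of class `ssir_roc`: `auc`, `curve` (data frame `fpr`,
#'   `tpr`), `accuracy`, `sensitivity`, `specificity`, `precision`, `mcc`,
#'   and the confusion counts. `precision` is `NA` when nothing is called
#'   positive; `mcc` is 0 when its denominator vanishes.
#' @examples
#' ssir_auroc(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE))$auc  # 1
#' @export
ssir_auroc <- function(scores, labels, threshold = 0) {
  y <- as.logical(labels)
  stopifnot(length(scores) == length(y), !anyNA(y), !anyNA(scores))
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute a ROC", call. = FALSE)
  r <- rank(scores)                       # mid-ranks for ties
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !y) / n0, numeric(1))
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  tp <- sum(scores > threshold & y); fp <- sum(scores > threshold & !y)
  fn <- n1 - tp; tn <- n0 - fp
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  structure(list(
    auc = auc, curve = curve,
    accuracy = (tp + tn) / (n1 + n0),
    sensitivity = tp / n1,
    specificity = tn / n0,
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den,
    tp = tp, fp = fp, tn = tn, fn = fn, threshold = threshold),
    class = "ssir_roc")
}

#' @export
print.ssir_roc <- function(x, ...) {
  cat(sprintf(
    "AU-ROC = %.3f | acc = %.1f%% sens = %.1f%% spec = %.1f%% prec = %s mcc = %.1f%%\n",
    x$auc, 100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity,
    if (is.na(x$precision)) "NA" else sprintf("%.1f%%", 100 * x$precision),
    100 * x$mcc))
  invisible(x)
}

#' Exact leave-one-out cross-validation
#'
#' For every sample the entire model is rebuilt on the remaining `a - 1`
#' samples — `b` and every rule's coverage, tails and votes are recomputed —
#' and the held-out sample is scored by that fold's model. The
#' `"incremental"` method caches each rule's full-data coverage (coverage
#' does not depend on which sample is held out beyond removing its own
#' contribution) and keeps a rule for fold reuse only if some single-sample
#' removal could drive one of its tails under `p_c`, checked exactly over the
#' reachable count states; it is bit-identical to `"naive"` from-scratch
#' retraining, which re-enumerates everything per fold.
#'
#' @param lib training [ssir_library]; needs `a >= 3` and at least two
#'   samples of each class so no fold loses a class.
#' @inheritParams ssir_train
#' @param method `"incremental"` (cached, default) or `"naive"`.
#' @return List of class `ssir_loo`: `scores` (held-out score per sample),
#'   `roc` (an [ssir_auroc()] summary of the held-out scores),
#'   `n_rules` (selected-rule count per fold), `method`.
#' @export
ssir_loo <- function(lib, p_c, orders = 2L,
                     method = c("incremental", "naive"),
                     positive_only = FALSE, max_rules = 2e6) {
  stopifnot(inherits(lib, "ssir_library"))
  method <- match.arg(method)
  a <- n_samples(lib); b <- n_interest(lib)
  if (a < 3) stop("leave-one-out needs a >= 3", call. = FALSE)
  if (b < 2 || a - b < 2) {
    lone <- if (b < 2) which(lib$y) else which(!lib$y)
    stop("removing sample '", names(lib$y)[lone[1]],
         "' would leave a fold without its class; each class needs >= 2 members",
         call. = FALSE)
  }
  orders <- sort(unique(as.integer(orders)))
  scores <- integer(a)
  nrules <- integer(a)
  if (method == "naive") {
    for (i in seq_len(a)) {
      sub <- subset_samples(lib, -i)
      m <- suppressWarnings(ssir_train(sub, p_c, orders,
                                       positive_only = positive_only,
                                       max_rules = max_rules))
      scores[i] <- ssir_score(m, lib$x[i, , drop = FALSE])$scores
      nrules[i] <- nrow(m$rules)
    }
  } else {
    core <- .eval_core(lib, orders, max_rules = max_rules)
    y <- lib$y
    for (bi in seq_along(core)) {
      bl <- core[[bi]]
      cfull <- bl$c
      dfull <- colSums(bl$M[y, , drop = FALSE])
      # reachable fold states (a-1; b or b-1; c or c-1; d or d-1): keep the
      # rule if any state could pass the cutoff
      keep <- rep(FALSE, length(cfull))
      for (st in list(c(0, 0, 0), c(0, 1, 0), c(1, 1, 1), c(1, 0, 0))) {
        bf <- b - st[1]; cf <- cfull - st[2]; df <- dfull - st[3]
        ok <- cf >= 1 & df >= 0 & df <= pmin(bf, cf) &
              df >= pmax(0, cf + bf - (a - 1))
        if (!any(ok)) next
        t <- .tails_cd(a - 1, bf, cf[ok], df[ok])
        keep[ok] <- keep[ok] | t$p_plus <= p_c |
          (!positive_only & t$p_minus <= p_c)
      }
      core[[bi]]$M <- bl$M[, keep, drop = FALSE]
      core[[bi]]$c <- cfull[keep]
      core[[bi]]$d <- dfull[keep]
    }
    for (i in seq_len(a)) {
      yi <- y[i]; bf <- b - yi
      tot <- 0L; cnt <- 0L
      for (bl in core) {
        if (!ncol(bl$M)) next
        mi <- bl$M[i, ]
        cf <- bl$c - mi
        df <- bl$d - (mi & yi)
        live <- cf >= 1
        if (!any(live)) next
        t <- .tails_cd(a - 1, bf, cf[live], df[live])
        plus <- t$p_plus <= p_c
        minus <- !positive_only & t$p_minus <= p_c
        vote <- ifelse(plus, 1L, ifelse(minus, -1L, 0L))
        tot <- tot + sum(vote * mi[live])
        cnt <- cnt + sum(vote != 0)
      }
      scores[i] <- tot
      nrules[i] <- cnt
    }
  }
  names(scores) <- rownames(lib$x)
  structure(list(scores = scores, roc = ssir_auroc(scores, lib$y),
                 n_rules = nrules, method = method, p_c = p_c,
                 orders = orders),
            class = "ssir_loo")
}

#' @export
print.ssir_loo <- function(x, ...) {
  cat(sprintf("leave-one-out (%s), p_c = %g, orders = %s\nheld-out ",
              x$method, x$p_c, paste(x$orders, collapse = ",")))
  print(x$roc)
  invisible(x)
}

#' Label-randomization (Y-scrambling) test
#'
#' Shuffles the training labels (a permutation, so class counts are
#' preserved), retrains the full model from the shuffled labels, and records
#' the training AUC (against the shuffled labels) and the external AUC
#' (against the untouched external labels) of every false model. A Gaussian
#' is fitted to the external values; the true model's external AUC is
#' reported as a z-score and upper-tail normal p-value against that null.
#'
#' Rule coverage does not depend on labels, so each shuffle re-derives every
#' rule's counts, tails and votes from the cached coverage — exactly the
#' from-scratch result.
#'
#' @param train_lib,external_lib training and external [ssir_library]s over
#'   the same descriptor schema; external labels are never shuffled.
#' @inheritParams ssir_train
#' @param n_shuffles number of label permutations.
#' @param seed master seed; per-shuffle substreams are derived from it.
#' @param include_identity if `TRUE` the first "shuffle" is the identity
#'   permutation (useful to check the true point is reproduced).
#' @return List of class `ssir_randomization`: `true_point` (train/external
#'   AUC of the real model), `shuffles` (data frame per shuffle),
#'   `mean`, `sd` (Gaussian fit to shuffled external AUCs), `z`, `p`.
#' @export
ssir_randomization <- function(train_lib, external_lib, p_c, orders = 2L,
                               n_shuffles = 200, seed,
                               positive_only = FALSE, max_rules = 2e6,
                               include_identity = FALSE) {
  stopifnot(inherits(train_lib, "ssir_library"),
            inherits(external_lib, "ssir_library"))
  if (n_shuffles < 1) stop("'n_shuffles' must be >= 1", call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (ncol(external_lib$x) != ncol(train_lib$x))
    stop("descriptor count mismatch between training and external sets",
         call. = FALSE)
  orders <- sort(unique(as.integer(orders)))
  core <- .eval_core(train_lib, orders, max_rules = max_rules)
  Mx <- lapply(core, function(bl) .match_matrix(bl$ruleset, external_lib$x))
  y <- train_lib$y
  run <- function(ylab) {
    tr_scores <- integer(length(ylab))
    ex_scores <- integer(nrow(external_lib$x))
    n_sel <- 0L
    for (bi in seq_along(core)) {
      s <- .select_block(core[[bi]], ylab, p_c, positive_only)
      if (!length(s$rule)) next
      n_sel <- n_sel + length(s$rule)
      tr_scores <- tr_scores +
        as.integer(core[[bi]]$M[, s$rule, drop = FALSE] %*% s$vote)
      ex_scores <- ex_scores +
        as.integer(Mx[[bi]][, s$rule, drop = FALSE] %*% s$vote)
    }
    c(train = ssir_auroc(tr_scores, ylab)$auc,
      external = ssir_auroc(ex_scores, external_lib$y)$auc,
      n_rules = n_sel)
  }
  true_pt <- run(y)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1, n_shuffles)
  sh <- matrix(NA_real_, n_shuffles, 3)
  for (s in seq_len(n_shuffles)) {
    set.seed(sub_seeds[s])
    yp <- if (include_identity && s == 1) y else sample(y)
    sh[s, ] <- run(yp)
  }
  shuffles <- data.frame(shuffle = seq_len(n_shuffles),
                         train_auc = sh[, 1], external_auc = sh[, 2],
                         n_rules = as.integer(sh[, 3]))
  mu <- mean(shuffles$external_auc)
  sdv <- stats::sd(shuffles$external_auc)
  z <- (true_pt[["external"]] - mu) / sdv
  structure(list(true_point = list(train_auc = true_pt[["train"]],
                                   external_auc = true_pt[["external"]],
                                   n_rules = as.integer(true_pt[["n_rules"]])),
                 shuffles = shuffles, mean = mu, sd = sdv, z = z,
                 p = stats::pnorm(z, lower.tail = FALSE),
                 n_shuffles = n_shuffles, seed = seed, p_c = p_c,
                 orders = orders),
            class = "ssir_randomization")
}

#' @export
print.ssir_randomization <- function(x, ...) {
  cat(sprintf(
    paste0("randomization test: %d shuffles\n",
           "true point: train AUC %.3f, external AUC %.3f\n",
           "shuffled external AUC ~ N(%.3f, %.3f^2); z = %.2f, p = %.3g\n"),
    x$n_shuffles, x$true_point$train_auc, x$true_point$external_auc,
    x$mean, x$sd, x$z, x$p))
  invisible(x)
}
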