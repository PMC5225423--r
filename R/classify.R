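#' Cross-validation configuration for the RBF-SVM evaluator
#'
#' Hyperparameters follow common SVM practice: cost 1 and
#' `kernel_width = "auto"`, which sets the RBF gamma to
#' `1 / (n_features * mean training-fold feature variance)` (features
#' are standardized on training-fold statistics, so this is ~`1/d`).
#'
#' @param n_folds number of stratified folds (default 5; must not
#'   exceed the smaller group size).
#' @param seed integer seed controlling fold assignment.
#' @param kernel_width RBF gamma, or `"auto"`.
#' @param regularization SVM cost parameter (> 0).
#' @return list of class `cv_config`.
#' @export
cv_config <- function(n_folds = 5, seed = 1, kernel_width = "auto",
                      regularization = 1) {
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (!identical(kernel_width, "auto") &&
      (!is.numeric(kernel_width) || kernel_width <= 0))
    stop("kernel_width must be 'auto' or a positive number")
  if (regularization <= 0) stop("regularization must be > 0")
  structure(list(n_folds = as.integer(n_folds), seed = as.integer(seed),
                 kernel_width = kernel_width,
                 regularization = regularization),
            class = "cv_config")
}

#' Cross-validated RBF-SVM decision scores
#'
#' Folds are stratified by class; every sample is scored exactly once by
#' a model whose training fold excluded it.  Features are standardized
#' using training-fold means/SDs only (zero-SD features pass through
#' unscaled).  Scores are oriented so that larger values favour the
#' case class.  Output is deterministic given the seed in `cv`.
#'
#' @param x `mirna_expr` with groups set, no missing values among the
#'   selected features.
#' @param feature_ids miRNA ids used as features.
#' @param cv `cv_config`.
#' @return named numeric vector of decision scores, one per sample of
#'   `x` (names = sample ids).
#' @export
cross_validated_scores <- function(x, feature_ids, cv = cv_config()) {
  stopifnot(inherits(x, "mirna_expr"), inherits(cv, "cv_config"))
  if (is.null(x$groups)) stop("groups must be set")
  feature_ids <- unique(as.character(feature_ids))
  absent <- setdiff(feature_ids, rownames(x$values))
  if (length(absent))
    stop("feature(s) not in matrix: ", paste(absent, collapse = ", "))
  feat <- t(x$values[feature_ids, , drop = FALSE])  # samples x features
  if (anyNA(feat)) stop("missing values among selected features")
  y <- factor(x$groups, levels = c("case", "control"))
  n_min <- min(table(y))
  if (cv$n_folds > n_min)
    stop("a fold would contain a single class; use n_folds <= ", n_min)

  set.seed(cv$seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(cv$n_folds), length(idx)))
  }

  scores <- setNames(numeric(length(y)), rownames(feat))
  for (f in seq_len(cv$n_folds)) {
    tr <- fold != f
    mu <- colMeans(feat[tr, , drop = FALSE])
    sg <- apply(feat[tr, , drop = FALSE], 2, sd)
    sg[sg == 0] <- 1
    z_tr <- sweep(sweep(feat[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    z_te <- sweep(sweep(feat[!tr, , drop = FALSE], 2, mu), 2, sg, "/")
    gamma <- if (identical(cv$kernel_width, "auto")) {
      v <- mean(apply(z_tr, 2, var))
      if (!is.finite(v) || v <= 0) v <- 1
      1 / (ncol(z_tr) * v)
    } else cv$kernel_width
    fit <- e1071::svm(z_tr, y[tr], kernel = "radial", gamma = gamma,
                      cost = cv$regularization, scale = FALSE)
    pred <- predict(fit, z_te, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    s <- dv[, 1]
    # libsvm orients decision values toward the first class named in
    # the column label; flip if that class is "control"
    if (startsWith(colnames(dv)[1], "control")) s <- -s
    scores[!tr] <- s
  }
  scores
}

#' ROC curve and AUC from scores and labels
#'
#' AUC is the Mann-Whitney probability that a random case outscores a
#' random control, with half credit for ties:
#' `(#concordant + 0.5 * #tied) / (n_case * n_control)`.  The curve is
#' obtained by sweeping a threshold over the unique scores and always
#' runs from (0, 0) to (1, 1).
#'
#' @param scores numeric vector (larger = more case-like).
#' @param labels character/factor vector of `"case"`/`"control"`, same
#'   length as `scores`.
#' @return list of class `roc_result` with elements `thresholds`,
#'   `tpr`, `fpr`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  is_case <- labels == "case"
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)                       # average ranks give tie credit
  auc <- (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & is_case) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !is_case) / n0, 0)
  structure(list(thresholds = c(Inf, thr), tpr = c(0, tpr),
                 fpr = c(0, fpr), auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d thresholds)\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' Evaluate named feature sets by cross-validated AUC
#'
#' For each named set, computes pooled cross-validated decision scores
#' (all folds' held-out scores in one vector) and a single ROC/AUC —
#' one curve per feature set.  Per-fold AUC averaging is available via
#' `pool_folds = FALSE`.
#'
#' @param x `mirna_expr` with groups set.
#' @param feature_sets named list of miRNA-id vectors (singletons,
#'   pairs, strata or larger panels).
#' @param cv `cv_config`.
#' @param pool_folds pool held-out scores into one ROC (default) or
#'   average per-fold AUCs.
#' @return data.frame with columns `set_name`, `n_features`, `auc`;
#'   pooled ROC objects in attribute `"roc"` (named list).
#' @export
evaluate_feature_sets <- function(x, feature_sets, cv = cv_config(),
                                  pool_folds = TRUE) {
  if (!length(feature_sets) || is.null(names(feature_sets)))
    stop("feature_sets must be a non-empty named list")
  rocs <- list()
  auc <- n_feat <- numeric(length(feature_sets))
  for (i in seq_along(feature_sets)) {
    ids <- feature_sets[[i]]
    s <- cross_validated_scores(x, ids, cv)
    n_feat[i] <- length(unique(ids))
    if (pool_folds) {
      r <- roc_auc(s, x$groups[names(s)])
      rocs[[names(feature_sets)[i]]] <- r
      auc[i] <- r$auc
    } else {
      # recompute fold assignment to group held-out scores by fold
      set.seed(cv$seed)
      y <- factor(x$groups, levels = c("case", "control"))
      fold <- integer(length(y))
      for (cl in levels(y)) {
        idx <- which(y == cl)
        fold[idx] <- sample(rep_len(seq_len(cv$n_folds), length(idx)))
      }
      auc[i] <- mean(vapply(seq_len(cv$n_folds), function(f)
        roc_auc(s[fold == f], as.character(y)[fold == f])$auc, 0))
    }
  }
  out <- data.frame(set_name = names(feature_sets), n_features = n_feat,
                    auc = auc, stringsAsFactors = FALSE)
  attr(out, "roc") <- rocs
  out
}

#' Write ROC curve points as TSV
#' @param roc `roc_result`.
#' @param path output path.
#' @export
write_roc <- function(roc, path) {
  write.table(data.frame(threshold = roc$thresholds, fpr = roc$fpr,
                         tpr = roc$tpr),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
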