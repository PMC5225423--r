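#' Missing-value screening and row-median imputation
#'
#' Rows whose missing fraction exceeds `max_missing_frac` are removed;
#' remaining missing cells are imputed by the row median so no missing
#' values reach the test stage.
#'
#' @param x `mirna_expr`.
#' @param max_missing_frac maximum tolerated per-row missing fraction,
#'   in [0, 1).
#' @return `mirna_expr` without missing values.
#' @export
preprocess_expression <- function(x, max_missing_frac = 0.2) {
  stopifnot(inherits(x, "mirna_expr"))
  if (max_missing_frac < 0 || max_missing_frac >= 1)
    stop("max_missing_frac must be in [0, 1)")
  v <- x$values
  frac <- rowMeans(is.na(v))
  keep <- frac <= max_missing_frac
  if (!any(keep)) stop("missing-value screening removed every miRNA")
  v <- v[keep, , drop = FALSE]
  na_rows <- which(rowSums(is.na(v)) > 0)
  for (i in na_rows) {
    med <- median(v[i, ], na.rm = TRUE)
    v[i, is.na(v[i, ])] <- med
  }
  mirna_expr(v, x$groups)
}

#' Two-group differential test per miRNA
#'
#' `log2fc` is the case-mean minus control-mean of the (already log2)
#' intensities.  `moderated_t` (the default) fits the two-group linear
#' model with limma and applies its empirical-Bayes variance shrinkage:
#' per-row variances are squeezed toward a pooled prior with the
#' prior degrees of freedom estimated from the data (limma's
#' `lmFit`/`eBayes`).  `welch_t` is the unequal-variance two-sample t
#' statistic with Welch-Satterthwaite degrees of freedom.  P-values are
#' two-sided.  Rows that are constant within both groups with equal
#' group means return `log2fc = 0`, `p = 1` (degenerate contract).
#'
#' FDR is the Benjamini-Hochberg adjustment across all tested rows
#' (see [bh_adjust()]).
#'
#' @param x `mirna_expr` with groups set and no missing values (run
#'   [preprocess_expression()] first).
#' @param method `"moderated_t"` or `"welch_t"`.
#' @return data.frame with columns `mirna_id`, `log2fc`, `p_value`,
#'   `fdr`, `direction` (`"up"` iff log2fc >= 0), `passes` (all `FALSE`
#'   until [filter_demirs()] is applied).
#' @export
differential_test <- function(x, method = c("moderated_t", "welch_t")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "mirna_expr"))
  if (is.null(x$groups)) stop("groups must be set")
  if (anyNA(x$values))
    stop("missing values present; run preprocess_expression() first")
  case <- x$values[, x$groups == "case", drop = FALSE]
  ctrl <- x$values[, x$groups == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group")
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- apply(case, 1, var); v2 <- apply(ctrl, 1, var)
  lfc <- m1 - m2

  if (method == "welch_t") {
    se2 <- v1 / n1 + v2 / n2
    tstat <- ifelse(se2 > 0, lfc / sqrt(se2), ifelse(lfc == 0, 0, Inf * sign(lfc)))
    df <- ifelse(se2 > 0,
                 se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
                 1)
    p <- 2 * pt(-abs(tstat), df)
    p[se2 == 0 & lfc == 0] <- 1
    p[se2 == 0 & lfc != 0] <- 0
  } else {
    design <- cbind(Intercept = 1, case = as.numeric(x$groups == "case"))
    fit <- limma::eBayes(limma::lmFit(x$values, design))
    lfc <- fit$coefficients[, "case"]
    p <- fit$p.value[, "case"]
    degen <- v1 == 0 & v2 == 0 & m1 == m2
    lfc[degen] <- 0
    p[degen] <- 1
    p[is.na(p)] <- 1
  }
  data.frame(mirna_id = rownames(x$values),
             log2fc = unname(lfc),
             p_value = unname(p),
             fdr = bh_adjust(unname(p)),
             direction = ifelse(lfc >= 0, "up", "down"),
             passes = FALSE,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1, returned in the
#' input order.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return numeric vector of BH-adjusted values (same order).
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Select differential miRNAs by the joint screening thresholds
#'
#' A miRNA passes iff `p_value < p_thr` AND `|log2fc| >= lfc_thr` AND
#' `fdr < fdr_thr` (strict `<` on both p and FDR, `>=` on the fold
#' change, matching the usual reporting convention).
#'
#' @param results data.frame from [differential_test()].
#' @param p_thr,lfc_thr,fdr_thr thresholds (defaults 0.05, 0.8, 0.05).
#' @return `results` with `passes` filled in; attributes `"n_up"` and
#'   `"n_down"` count passing rows by direction.
#' @export
filter_demirs <- function(results, p_thr = 0.05, lfc_thr = 0.8,
                          fdr_thr = 0.05) {
  if (!nrow(results)) stop("empty results table")
  results$passes <- results$p_value < p_thr &
    abs(results$log2fc) >= lfc_thr &
    results$fdr < fdr_thr
  attr(results, "n_up") <- sum(results$passes & results$direction == "up")
  attr(results, "n_down") <- sum(results$passes & results$direction == "down")
  results
}

#' Write a differential-result table as TSV
#' @param results data.frame from [differential_test()]/[filter_demirs()].
#' @param path output path.
#' @export
write_differential <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
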