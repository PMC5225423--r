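#' Pearson correlation (CE) for all unordered miRNA pairs
#'
#' Computes the Pearson correlation coefficient over all samples (cases
#' and controls pooled) for every unordered pair among `feature_ids`,
#' using pairwise-complete observations when values are missing.  Pairs
#' are reported with `mirna_a < mirna_b` lexicographically.
#' `sign_class` is `"positive"` for CE > 0 and `"negative"` for CE < 0;
#' a CE of exactly 0 belongs to neither class (`NA`).  Zero-variance
#' features yield undefined correlations: their pairs are dropped with a
#' warning naming the feature.
#'
#' @param x `mirna_expr`.
#' @param feature_ids miRNA ids to correlate (>= 2, present in `x`).
#' @return data.frame with columns `mirna_a`, `mirna_b`, `ce`,
#'   `sign_class`.
#' @export
pairwise_ce <- function(x, feature_ids) {
  stopifnot(inherits(x, "mirna_expr"))
  feature_ids <- unique(as.character(feature_ids))
  absent <- setdiff(feature_ids, rownames(x$values))
  if (length(absent))
    stop("feature(s) not in matrix: ", paste(absent, collapse = ", "))
  if (length(feature_ids) < 2)
    stop("need at least two features")
  if (ncol(x$values) < 3) stop("need at least three samples")
  v <- x$values[feature_ids, , drop = FALSE]
  sds <- apply(v, 1, sd, na.rm = TRUE)
  degenerate <- feature_ids[is.na(sds) | sds == 0]
  if (length(degenerate)) {
    warning("zero-variance feature(s), pairs excluded: ",
            paste(degenerate, collapse = ", "))
    feature_ids <- setdiff(feature_ids, degenerate)
    if (length(feature_ids) < 2)
      return(data.frame(mirna_a = character(), mirna_b = character(),
                        ce = numeric(), sign_class = character(),
                        stringsAsFactors = FALSE))
    v <- v[feature_ids, , drop = FALSE]
  }
  cm <- suppressWarnings(cor(t(v), use = "pairwise.complete.obs"))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  a <- feature_ids[idx[, 1]]; b <- feature_ids[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  ce <- cm[idx]
  keep <- !is.na(ce)
  data.frame(mirna_a = a[keep], mirna_b = b[keep], ce = ce[keep],
             sign_class = ifelse(ce[keep] > 0, "positive",
                                 ifelse(ce[keep] < 0, "negative",
                                        NA_character_)),
             stringsAsFactors = FALSE)
}

#' Stratify miRNA pairs by |CE| within each sign class
#'
#' With the default edges `c(0.6, 0.7, 0.8)` pairs fall into the strata
#' (0.6, 0.7], (0.7, 0.8] and (0.8, 1] per sign class, mirroring the
#' panels commonly used to compare classifier feature sets across
#' correlation strength.  Pairs with |CE| at or below the lowest edge,
#' and pairs with CE exactly 0, are left unassigned.
#'
#' @param pairs data.frame from [pairwise_ce()].
#' @param bin_edges increasing numeric vector inside [0, 1].
#' @return named list of pair data.frames, keyed
#'   `"<sign>_(lo,hi]"`; empty strata are present with zero rows.
#' @export
stratify_pairs <- function(pairs, bin_edges = c(0.6, 0.7, 0.8)) {
  if (is.unsorted(bin_edges, strictly = TRUE) ||
      any(bin_edges < 0 | bin_edges > 1))
    stop("bin_edges must be strictly increasing within [0, 1]")
  lo <- bin_edges
  hi <- c(bin_edges[-1], 1)
  labels <- sprintf("(%g,%g]", lo, hi)
  strata <- list()
  for (sgn in c("positive", "negative")) {
    sub <- pairs[!is.na(pairs$sign_class) & pairs$sign_class == sgn, ,
                 drop = FALSE]
    for (bi in seq_along(lo)) {
      key <- paste0(sgn, "_", labels[bi])
      inbin <- abs(sub$ce) > lo[bi] & abs(sub$ce) <= hi[bi]
      strata[[key]] <- sub[inbin, , drop = FALSE]
    }
  }
  strata
}

#' Unique miRNAs appearing in a set of pairs
#' @param pairs data.frame with columns `mirna_a`, `mirna_b`.
#' @return character vector, sorted.
#' @export
pair_members <- function(pairs) {
  sort(unique(c(pairs$mirna_a, pairs$mirna_b)))
}
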