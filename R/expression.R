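#' miRNA expression matrix with group labels
#'
#' Container for a miRNAs x samples matrix of log2 intensities.  Missing
#' values are stored as `NA` (the missing-value mask).  Each sample
#' carries a group label, `"case"` or `"control"`; labels may be left
#' unset (e.g. straight after parsing a GEO series matrix) but are
#' required by the differential and classification stages.
#'
#' @param values numeric matrix, rows = miRNAs, columns = samples; both
#'   dimnames must be set, unique and non-empty.
#' @param groups named character vector mapping every sample id to
#'   `"case"` or `"control"`, or `NULL` if labels are not yet assigned.
#' @return An object of class `mirna_expr`: a list with elements
#'   `values` (the matrix) and `groups` (named character or `NULL`).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("mir-", 1:3), paste0("s", 1:4)))
#' g <- setNames(rep(c("case", "control"), each = 2), colnames(m))
#' x <- mirna_expr(m, g)
#' dim(x)
#' @export
mirna_expr <- function(values, groups = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have row (miRNA) and column (sample) names")
  dup_r <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_r))
    stop("duplicate miRNA id(s): ", paste(dup_r, collapse = ", "))
  dup_c <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_c))
    stop("duplicate sample id(s): ", paste(dup_c, collapse = ", "))
  if (!is.null(groups)) {
    groups <- groups[colnames(values)]
    missing_lab <- colnames(values)[is.na(names(groups)) | is.na(groups)]
    if (length(missing_lab))
      stop("sample(s) without group label: ",
           paste(missing_lab, collapse = ", "))
    if (!all(groups %in% c("case", "control")))
      stop("group labels must be 'case' or 'control'")
    names(groups) <- colnames(values)
  }
  structure(list(values = values, groups = groups), class = "mirna_expr")
}

#' @export
dim.mirna_expr <- function(x) dim(x$values)

#' @export
print.mirna_expr <- function(x, ...) {
  cat("mirna_expr:", nrow(x$values), "miRNAs x", ncol(x$values), "samples\n")
  if (is.null(x$groups)) {
    cat("  groups: <unset>\n")
  } else {
    tb <- table(x$groups)
    cat("  groups:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  n_na <- sum(is.na(x$values))
  cat("  missing:", n_na,
      sprintf("(%.2f%%)", 100 * n_na / length(x$values)), "\n")
  invisible(x)
}

#' Subset an expression object by miRNA and/or sample ids
#'
#' @param x `mirna_expr`.
#' @param i,j miRNA / sample selectors (names or indices).
#' @param ... ignored.
#' @export
`[.mirna_expr` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  v <- x$values[i, j, drop = FALSE]
  g <- if (is.null(x$groups)) NULL else x$groups[colnames(v)]
  mirna_expr(v, g)
}

#' Attach group labels to an expression object
#'
#' @param x `mirna_expr` (groups may be unset).
#' @param groups named character vector (sample -> "case"/"control")
#'   covering every sample of `x`.
#' @return `mirna_expr` with groups set.
#' @export
set_groups <- function(x, groups) {
  stopifnot(inherits(x, "mirna_expr"))
  mirna_expr(x$values, groups)
}
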