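#' Read an expression matrix and its group labels from TSV files
#'
#' The matrix file is tab-separated, UTF-8, first header row = sample
#' ids, first column = miRNA ids.  Empty cells, `NA` and `NaN` enter the
#' missing mask.  The labels file has two columns (sample, group) with
#' groups `case`/`control`.
#'
#' @param path path to the expression TSV.
#' @param labels_path path to the two-column labels TSV, or `NULL` to
#'   leave groups unset.
#' @return `mirna_expr`.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path, labels_path = NULL) {
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    na.strings = c("NA", "NaN", ""), colClasses = "character",
                    stringsAsFactors = FALSE)
  ids <- tab[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate miRNA id(s) in ", path, ": ", paste(dup, collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  groups <- NULL
  if (!is.null(labels_path)) {
    lab <- read.delim(labels_path, sep = "\t", header = TRUE,
                      check.names = FALSE, stringsAsFactors = FALSE)
    groups <- setNames(as.character(lab[[2]]), as.character(lab[[1]]))
    absent <- setdiff(colnames(m), names(groups))
    if (length(absent))
      stop("sample(s) in matrix absent from labels file: ",
           paste(absent, collapse = ", "))
    groups <- groups[colnames(m)]
  }
  mirna_expr(m, groups)
}

#' Write an expression matrix (and optionally its labels) as TSV
#'
#' Finite values are printed with 17 significant digits so that
#' write/read round-trips bit-exactly; missing entries are written as
#' `NA`.
#'
#' @param x `mirna_expr`.
#' @param path output path for the matrix TSV.
#' @param labels_path optional output path for the two-column labels TSV
#'   (requires groups to be set).
#' @export
write_expression <- function(x, path, labels_path = NULL) {
  stopifnot(inherits(x, "mirna_expr"))
  v <- x$values
  chr <- matrix(sprintf("%.17g", v), nrow(v), ncol(v))
  chr[is.na(v)] <- "NA"
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("mirna_id", colnames(v)), collapse = "\t"), con)
  writeLines(paste(rownames(v), apply(chr, 1, paste, collapse = "\t"),
                   sep = "\t"), con)
  if (!is.null(labels_path)) {
    if (is.null(x$groups))
      stop("cannot write labels: groups are unset")
    lab <- data.frame(sample = names(x$groups), group = unname(x$groups))
    write.table(lab, labels_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Parse a GEO series-matrix file into an expression object
#'
#' Reads the probe x sample table between the
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers.
#' Quoted ids/values are unquoted.  Group labels are left unset; sample
#' titles (the `!Sample_title` header line, when present) are returned
#' in attribute `"sample_titles"` to support label assignment.
#'
#' @param path path to a series-matrix text file.
#' @return `mirna_expr` with `groups = NULL`.
#' @export
read_geo_series_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop("malformed series matrix: need one table_begin/table_end pair ",
         "enclosing a non-empty table")
  unquote <- function(s) gsub('^"|"$', "", s)
  split_row <- function(ln) unquote(strsplit(ln, "\t", fixed = TRUE)[[1]])
  header <- split_row(lines[beg + 1L])
  body <- lines[(beg + 2L):(end - 1L)]
  cells <- lapply(body, split_row)
  n_col <- length(header)
  if (any(vapply(cells, length, 1L) != n_col))
    stop("malformed series matrix: ragged table rows")
  ids <- vapply(cells, `[`, "", 1L)
  m <- matrix(NA_real_, length(ids), n_col - 1L,
              dimnames = list(ids, header[-1L]))
  for (i in seq_along(cells)) {
    vals <- cells[[i]][-1L]
    vals[vals %in% c("", "NA", "NaN", "null")] <- NA
    m[i, ] <- suppressWarnings(as.numeric(vals))
  }
  x <- mirna_expr(m, NULL)
  title_line <- grep("^!Sample_title\t", lines, value = TRUE)
  if (length(title_line) == 1L) {
    titles <- split_row(title_line)[-1L]
    if (length(titles) == ncol(m))
      attr(x, "sample_titles") <- setNames(titles, colnames(m))
  }
  x
}

# ---- target maps -----------------------------------------------------------

#' Construct a miRNA -> target-gene map
#'
#' @param sets named list; each element a character vector of target
#'   gene ids for one miRNA.
#' @return object of class `target_map` (the named list, with the gene
#'   universe in attribute `"universe"`).
#' @export
target_map <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("'sets' must be a fully named list")
  sets <- lapply(sets, function(g) sort(unique(as.character(g))))
  structure(sets, class = "target_map",
            universe = sort(unique(unlist(sets, use.names = FALSE))))
}

#' @export
print.target_map <- function(x, ...) {
  cat("target_map:", length(x), "miRNAs,",
      length(attr(x, "universe")), "genes in universe\n")
  invisible(x)
}

#' Read a two-column (miRNA, gene) TSV as a target map
#'
#' @param path path to a TSV with a header row and columns miRNA, gene.
#' @return `target_map`.
#' @export
read_target_map <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  target_map(split(as.character(tab[[2]]), as.character(tab[[1]])))
}

#' Write a target map as a two-column TSV
#' @param tm `target_map`.
#' @param path output path.
#' @export
write_target_map <- function(tm, path) {
  stopifnot(inherits(tm, "target_map"))
  df <- data.frame(mirna = rep(names(tm), lengths(tm)),
                   gene = unlist(tm, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble consensus targets from several prediction databases
#'
#' Each input file is a normalized two-column (miRNA, gene) TSV exported
#' from one target-prediction database.  A (miRNA, gene) link is kept if
#' and only if it occurs in at least `min_db` distinct sources; the
#' default 4 corresponds to requiring support from more than three of
#' the usual seven prediction databases.
#'
#' @param db_paths character vector of TSV paths, one per database.
#' @param min_db minimum number of distinct supporting databases (>= 1).
#' @return `target_map` of the consensus links.  An empty consensus
#'   yields a warning (not an error).
#' @export
read_consensus_targets <- function(db_paths, min_db = 4) {
  stopifnot(length(db_paths) >= 1, min_db >= 1)
  links <- lapply(db_paths, function(p) {
    tab <- read.delim(p, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    unique(paste(tab[[1]], tab[[2]], sep = "\r"))
  })
  counts <- table(unlist(links))
  keep <- names(counts)[counts >= min_db]
  if (!length(keep)) {
    warning("no (miRNA, gene) link supported by >= ", min_db, " databases")
    return(target_map(setNames(list(), character(0))))
  }
  parts <- strsplit(keep, "\r", fixed = TRUE)
  target_map(split(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L)))
}

# ---- pathway gene sets (GMT) ----------------------------------------------

#' Read pathway gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member genes.  Files written without the
#' description field are supported via `has_desc = FALSE`.
#'
#' @param path path to the GMT file.
#' @param has_desc whether the second field is a description.
#' @return named list of character vectors (class `pathway_sets`), with
#'   descriptions in attribute `"description"`.
#' @export
read_gmt <- function(path, has_desc = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[`, "", 1L)
  first_gene <- if (has_desc) 3L else 2L
  sets <- lapply(fields, function(f)
    unique(f[seq.int(first_gene, length(f))]))
  desc <- if (has_desc) vapply(fields, `[`, "", 2L) else rep("", length(nm))
  if (any(!lengths(sets)))
    stop("GMT contains an empty gene set")
  structure(setNames(sets, nm), class = "pathway_sets",
            description = setNames(desc, nm))
}

#' Write pathway gene sets in GMT format
#' @param sets named list of gene vectors (descriptions taken from the
#'   `"description"` attribute when present).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("", length(sets)), names(sets))
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}

# ---- network export --------------------------------------------------------

#' Export a synergy network for graph viewers
#'
#' `"sif"` writes Cytoscape simple-interaction lines with relation
#' labels `pos`/`neg` by the sign of the edge's Pearson CE.
#' `"graphml"` writes GraphML with `ce` and `n_sig_pathways` edge
#' attributes.
#'
#' @param network `synergy_network` (see [build_network()]) or an igraph
#'   graph with edge attributes `ce` and `n_sig_pathways`.
#' @param path output path.
#' @param format `"sif"` or `"graphml"`.
#' @export
write_network <- function(network, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  g <- if (inherits(network, "synergy_network")) network$graph else network
  if (!igraph::is_igraph(g)) stop("'network' must be a synergy_network or igraph")
  if (igraph::ecount(g) == 0L) stop("cannot export an empty network")
  if (format == "sif") {
    el <- igraph::as_edgelist(g)
    rel <- ifelse(igraph::E(g)$ce > 0, "pos", "neg")
    writeLines(paste(el[, 1], rel, el[, 2], sep = "\t"), path)
  } else {
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
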