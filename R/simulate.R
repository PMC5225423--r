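#' Configuration for the two-group expression simulator
#'
#' Defaults emulate the whole-blood microarray study design the package
#' targets: 38 cases vs 38 controls, 900 miRNA probes, 20 planted
#' differential miRNAs with |log2 fold change| 1.5, two tightly
#' correlated four-member families (loading 0.95, nominal pairwise
#' CE = 0.95^2 ~ 0.9), 2% values missing completely at random, and unit
#' residual standard deviation on the log2 scale.
#'
#' @param n_case,n_control samples per group.
#' @param n_mirnas number of miRNA probes.
#' @param n_de number of planted differential miRNAs (<= n_mirnas).
#' @param effect_log2 absolute group-mean difference of planted rows,
#'   log2 units (>= 0).  Half the planted rows go up, half down; rows in
#'   the same correlation block share a direction.
#' @param corr_blocks list of `c(size, loading)` pairs: each block of
#'   `size` rows (>= 2) shares a per-sample latent factor with the given
#'   loading in [0, 1].  Within a block the residual of each row is
#'   `loading * F + sqrt(1 - loading^2) * eps`, so the nominal pairwise
#'   Pearson correlation is `loading^2` whatever `noise_sd` is.
#' @param missing_frac fraction of cells masked missing, in [0, 1).
#' @param noise_sd residual standard deviation (log2 units, > 0).
#' @param baseline_range range of per-miRNA baseline log2 intensities.
#' @param seed integer seed; identical configs give identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_case = 38, n_control = 38, n_mirnas = 900,
                       n_de = 20, effect_log2 = 1.5,
                       corr_blocks = list(c(4, 0.95), c(4, 0.95)),
                       missing_frac = 0.02, noise_sd = 1,
                       baseline_range = c(6, 12), seed = 1) {
  if (n_case < 1 || n_control < 1 || n_mirnas < 1)
    stop("dimensions must be positive")
  if (n_de < 0 || n_de > n_mirnas) stop("need 0 <= n_de <= n_mirnas")
  if (effect_log2 < 0) stop("effect_log2 must be >= 0")
  if (missing_frac < 0 || missing_frac >= 1)
    stop("missing_frac must be in [0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  for (b in corr_blocks) {
    if (length(b) != 2 || b[1] < 2) stop("every block needs size >= 2")
    if (b[2] < 0 || b[2] > 1) stop("block loading must be in [0, 1]")
  }
  if (length(corr_blocks) && sum(vapply(corr_blocks, `[`, 0, 1)) > n_mirnas)
    stop("sum of block sizes exceeds n_mirnas")
  structure(list(n_case = n_case, n_control = n_control,
                 n_mirnas = n_mirnas, n_de = n_de,
                 effect_log2 = effect_log2, corr_blocks = corr_blocks,
                 missing_frac = missing_frac, noise_sd = noise_sd,
                 baseline_range = baseline_range, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a two-group miRNA expression matrix with ground truth
#'
#' Generates log2-scale intensities `mu_i + effect_i * 1(case) +
#' noise_sd * resid_ij` with Gaussian residuals.  Rows inside a
#' correlation block share a per-sample latent factor (see
#' [sim_config()]); correlation blocks are carved from the planted
#' differential rows first (correlated miRNA families in real arrays
#' are typically co-regulated and jointly differential), overflowing
#' into null rows if the blocks outnumber the differential set.
#' Missingness is completely at random.
#'
#' @param config `sim_config`.
#' @return list with elements
#'   \describe{
#'     \item{expr}{`mirna_expr` (missing cells are `NA`).}
#'     \item{truth}{list with `de` (data.frame mirna_id, effect),
#'       `block_pairs` (data.frame mirna_a, mirna_b, nominal_ce) and
#'       `blocks` (list of member id vectors).}
#'   }
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_mirnas
  ns <- config$n_case + config$n_control
  ids <- sprintf("mir-%04d", seq_len(n))
  samples <- c(sprintf("case_%02d", seq_len(config$n_case)),
               sprintf("ctrl_%02d", seq_len(config$n_control)))
  groups <- setNames(rep(c("case", "control"),
                         c(config$n_case, config$n_control)), samples)
  is_case <- groups == "case"

  ord <- sample.int(n)                      # random placement of structure
  de_rows <- ord[seq_len(config$n_de)]
  # blocks take differential rows first, then null rows
  block_rows <- list()
  used <- 0L
  for (b in config$corr_blocks) {
    sz <- b[1]
    block_rows[[length(block_rows) + 1L]] <- ord[used + seq_len(sz)]
    used <- used + sz
  }
  # signed effects: same sign within a block, alternating across blocks
  # and remaining DE rows so roughly half go each way
  effect <- numeric(n)
  if (config$n_de > 0) {
    sgn <- numeric(config$n_de)
    pos <- 1L
    dir <- 1
    for (br in block_rows) {
      in_de <- sum(br %in% de_rows)
      if (in_de > 0) { sgn[pos:(pos + in_de - 1L)] <- dir; pos <- pos + in_de
                       dir <- -dir }
    }
    while (pos <= config$n_de) { sgn[pos] <- dir; dir <- -dir; pos <- pos + 1L }
    effect[de_rows] <- sgn * config$effect_log2
  }

  mu <- runif(n, config$baseline_range[1], config$baseline_range[2])
  resid <- matrix(rnorm(n * ns), n, ns)
  for (bi in seq_along(block_rows)) {
    rows <- block_rows[[bi]]
    lam <- config$corr_blocks[[bi]][2]
    f <- rnorm(ns)
    resid[rows, ] <- lam * matrix(f, length(rows), ns, byrow = TRUE) +
      sqrt(1 - lam^2) * resid[rows, , drop = FALSE]
  }
  vals <- mu + outer(effect, as.numeric(is_case)) + config$noise_sd * resid
  dimnames(vals) <- list(ids, samples)
  if (config$missing_frac > 0)
    vals[runif(n * ns) < config$missing_frac] <- NA

  blocks <- lapply(block_rows, function(r) ids[sort(r)])
  bp <- do.call(rbind, lapply(seq_along(blocks), function(bi) {
    mem <- blocks[[bi]]
    if (length(mem) < 2) return(NULL)
    cmb <- combn(mem, 2)
    data.frame(mirna_a = pmin(cmb[1, ], cmb[2, ]),
               mirna_b = pmax(cmb[1, ], cmb[2, ]),
               nominal_ce = config$corr_blocks[[bi]][2]^2,
               stringsAsFactors = FALSE)
  }))
  if (is.null(bp))
    bp <- data.frame(mirna_a = character(), mirna_b = character(),
                     nominal_ce = numeric(), stringsAsFactors = FALSE)
  truth <- list(
    de = data.frame(mirna_id = ids[sort(de_rows)],
                    effect = effect[sort(de_rows)],
                    stringsAsFactors = FALSE),
    block_pairs = bp,
    blocks = blocks)
  list(expr = mirna_expr(vals, groups), truth = truth)
}

#' Configuration for the synthetic target/pathway annotation
#'
#' @param n_genes size of the target-gene universe.
#' @param targets_per_mirna number of target genes per miRNA.
#' @param n_pathways number of pathway gene sets.
#' @param pathway_size genes per pathway.
#' @param planted_synergy_pairs list of length-2 character vectors of
#'   miRNA ids; each pair will share exactly `co_target_overlap` target
#'   genes, all placed inside one designated pathway.  Pairs must be
#'   node-disjoint.
#' @param co_target_overlap shared-target count per planted pair
#'   (<= `targets_per_mirna` and <= `pathway_size`).
#' @param seed integer seed.
#' @return list of class `annotation_config`.
#' @export
annotation_config <- function(n_genes = 5000, targets_per_mirna = 50,
                              n_pathways = 50, pathway_size = 20,
                              planted_synergy_pairs = list(),
                              co_target_overlap = 10, seed = 1) {
  if (pathway_size > n_genes) stop("pathway_size must be <= n_genes")
  if (co_target_overlap > targets_per_mirna)
    stop("co_target_overlap must be <= targets_per_mirna")
  if (co_target_overlap > pathway_size)
    stop("co_target_overlap must be <= pathway_size")
  if (length(planted_synergy_pairs) > n_pathways)
    stop("need one designated pathway per planted pair")
  members <- unlist(planted_synergy_pairs)
  if (anyDuplicated(members))
    stop("planted synergy pairs must be node-disjoint")
  structure(list(n_genes = n_genes, targets_per_mirna = targets_per_mirna,
                 n_pathways = n_pathways, pathway_size = pathway_size,
                 planted_synergy_pairs = planted_synergy_pairs,
                 co_target_overlap = co_target_overlap,
                 seed = as.integer(seed)),
            class = "annotation_config")
}

#' Simulate target-gene and pathway annotations with planted synergy
#'
#' Every miRNA in `mirna_ids` receives `targets_per_mirna` target genes.
#' For each planted pair the two miRNAs share exactly
#' `co_target_overlap` genes, all members of that pair's designated
#' pathway, and their remaining targets are drawn disjointly so the
#' overlap is exact; all other miRNAs draw targets uniformly from the
#' universe, so non-planted pairs share co-targets only by chance.
#'
#' @param config `annotation_config`.
#' @param mirna_ids character vector of miRNA ids to annotate (must
#'   include every planted-pair member).
#' @return list with `targets` (`target_map`), `pathways`
#'   (`pathway_sets`) and `truth` (data.frame of planted pairs with
#'   their designated pathway).
#' @export
generate_annotation <- function(config, mirna_ids) {
  stopifnot(inherits(config, "annotation_config"))
  members <- unlist(config$planted_synergy_pairs)
  absent <- setdiff(members, mirna_ids)
  if (length(absent))
    stop("planted miRNA(s) not in mirna_ids: ", paste(absent, collapse = ", "))
  set.seed(config$seed)
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  pathways <- lapply(seq_len(config$n_pathways), function(i)
    sample(genes, config$pathway_size))
  names(pathways) <- sprintf("pw%03d", seq_len(config$n_pathways))

  sets <- vector("list", length(mirna_ids))
  names(sets) <- mirna_ids
  planted <- data.frame(mirna_a = character(), mirna_b = character(),
                        pathway = character(), stringsAsFactors = FALSE)
  for (pi in seq_along(config$planted_synergy_pairs)) {
    pr <- sort(config$planted_synergy_pairs[[pi]])
    pw <- names(pathways)[pi]
    shared <- if (config$co_target_overlap > 0)
      sample(pathways[[pw]], config$co_target_overlap) else character(0)
    n_fill <- config$targets_per_mirna - config$co_target_overlap
    pool <- setdiff(genes, shared)
    fill <- sample(pool, 2 * n_fill)
    sets[[pr[1]]] <- c(shared, fill[seq_len(n_fill)])
    sets[[pr[2]]] <- c(shared, fill[n_fill + seq_len(n_fill)])
    planted <- rbind(planted, data.frame(mirna_a = pr[1], mirna_b = pr[2],
                                         pathway = pw,
                                         stringsAsFactors = FALSE))
  }
  for (id in setdiff(mirna_ids, members))
    sets[[id]] <- sample(genes, config$targets_per_mirna)
  list(targets = target_map(sets),
       pathways = structure(pathways, class = "pathway_sets",
                            description = setNames(rep("", length(pathways)),
                                                   names(pathways))),
       truth = planted)
}

#' Simulate an additive two-feature panel with weak marginals
#'
#' A constructed design in which each feature alone is a mediocre
#' classifier but the two together separate the groups almost
#' perfectly: both features shift by `delta` in cases, while their
#' within-group residuals correlate at `rho` (strongly negative by
#' default), so the sum has variance `2(1 + rho)` and a Bayes AUC of
#' `pnorm(2 * delta / sqrt(2 * 2 * (1 + rho)))` against marginal Bayes
#' AUCs of `pnorm(delta / sqrt(2))`.
#'
#' @param n_case,n_control samples per group.
#' @param delta per-feature group-mean shift (units of residual SD).
#' @param rho within-group correlation of the two features, in (-1, 1).
#' @param seed integer seed.
#' @return `mirna_expr` with two rows, `panel_1` and `panel_2`.
#' @export
simulate_additive_panel <- function(n_case = 100, n_control = 100,
                                    delta = 0.7, rho = -0.9, seed = 1) {
  stopifnot(rho > -1, rho < 1)
  set.seed(as.integer(seed))
  ns <- n_case + n_control
  e1 <- rnorm(ns)
  e2 <- rho * e1 + sqrt(1 - rho^2) * rnorm(ns)
  is_case <- rep(c(1, 0), c(n_case, n_control))
  vals <- rbind(panel_1 = delta * is_case + e1,
                panel_2 = delta * is_case + e2)
  samples <- c(sprintf("case_%03d", seq_len(n_case)),
               sprintf("ctrl_%03d", seq_len(n_control)))
  colnames(vals) <- samples
  mirna_expr(vals, setNames(rep(c("case", "control"),
                                c(n_case, n_control)), samples))
}
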