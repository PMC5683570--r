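#' Candidate inverse-change miRNA-mRNA pairs
#'
#' Enumerates every (miRNA, gene) pair such that both members are
#' differentially expressed, the gene is a validated target of the miRNA in
#' the network, and the two directions are opposite (the signature of
#' miRNA-mediated repression: an up-regulated miRNA with a down-regulated
#' target, or vice versa). Output order is deterministic:
#' (`mirna_id`, `gene_id`) ascending. Correlation columns are left `NA`
#' until [score_pairs()].
#'
#' @param de_mirna Classified miRNA [de_table()].
#' @param de_mrna Classified mRNA [de_table()].
#' @param network A [build_network()] result.
#' @return data.frame of class `pair_table`: `mirna_id`, `gene_id`,
#'   `mirna_dir`, `gene_dir`, `r`, `p_param`, `p_perm`, `significant`.
#' @export
candidate_pairs <- function(de_mirna, de_mrna, network) {
  stopifnot(inherits(de_mirna, "de_table"), inherits(de_mrna, "de_table"),
            inherits(network, "regulatory_network"))
  mdir <- setNames(de_mirna$direction, de_mirna$feature_id)
  gdir <- setNames(de_mrna$direction, de_mrna$feature_id)
  de_m <- names(mdir)[mdir %in% c("up", "down")]
  rows <- list()
  for (m in sort(intersect(de_m, names(network$targets)))) {
    tg <- sort(intersect(network$targets[[m]], names(gdir)))
    tg <- tg[gdir[tg] %in% c("up", "down") & gdir[tg] != mdir[m]]
    if (length(tg) > 0)
      rows[[m]] <- data.frame(mirna_id = m, gene_id = tg,
                              mirna_dir = unname(mdir[m]),
                              gene_dir = unname(gdir[tg]),
                              stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows)
         else data.frame(mirna_id = character(0), gene_id = character(0),
                         mirna_dir = character(0), gene_dir = character(0),
                         stringsAsFactors = FALSE)
  out$r <- rep(NA_real_, nrow(out))
  out$p_param <- rep(NA_real_, nrow(out))
  out$p_perm <- rep(NA_real_, nrow(out))
  out$significant <- rep(NA, nrow(out))
  rownames(out) <- NULL
  class(out) <- c("pair_table", "data.frame")
  out
}

#' Pearson correlation with parametric p-value
#'
#' Sample Pearson correlation with the two-sided p-value from
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r` and `p_param`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (var(x) == 0 || var(y) == 0) stop("zero variance input")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p_param = p)
}

# log2(CPM + 1) over the shared, sorted sample IDs of both assays; each
# matrix is first restricted to the intersection so unmatched samples do
# not leak into the normalization factors
shared_log_expr <- function(mirna_expr, mrna_expr, samples = NULL) {
  shared <- sort(intersect(colnames(mirna_expr$counts),
                           colnames(mrna_expr$counts)))
  if (!is.null(samples)) shared <- intersect(shared, samples)
  if (length(shared) < 3)
    stop("need at least 3 shared samples between the two assays")
  xm <- count_matrix(mirna_expr$counts[, shared, drop = FALSE], "mirna")
  xg <- count_matrix(mrna_expr$counts[, shared, drop = FALSE], "mrna")
  lx <- log2(cpm_matrix(xm, norm_factors(xm)) + 1)
  ly <- log2(cpm_matrix(xg, norm_factors(xg)) + 1)
  list(mirna = lx, mrna = ly, samples = shared)
}

#' Score candidate pairs by expression correlation
#'
#' Computes each pair's Pearson correlation and parametric p-value on
#' `log2(CPM + 1)` values (per-assay TMM normalization) over the sorted
#' intersection of the two matrices' sample IDs. Pairs whose miRNA or gene
#' is constant across the shared samples, or absent from a matrix, are
#' dropped with a message.
#'
#' @param pairs A [candidate_pairs()] table.
#' @param mirna_expr,mrna_expr The two [count_matrix()] objects.
#' @param samples Optional sample-ID subset (e.g. tumours only); default is
#'   every shared sample.
#' @return The pair table with `r` and `p_param` filled in.
#' @export
score_pairs <- function(pairs, mirna_expr, mrna_expr, samples = NULL) {
  stopifnot(inherits(pairs, "pair_table"))
  if (nrow(pairs) == 0) return(pairs)
  ex <- shared_log_expr(mirna_expr, mrna_expr, samples)
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    m <- pairs$mirna_id[i]; g <- pairs$gene_id[i]
    if (!m %in% rownames(ex$mirna) || !g %in% rownames(ex$mrna)) {
      message("dropping pair (", m, ", ", g, "): missing from expression data")
      next
    }
    xv <- ex$mirna[m, ]; yv <- ex$mrna[g, ]
    if (var(xv) == 0 || var(yv) == 0) {
      message("dropping pair (", m, ", ", g,
              "): constant expression across shared samples")
      next
    }
    pc <- pearson_cor(xv, yv)
    pairs$r[i] <- pc$r
    pairs$p_param[i] <- pc$p_param
    keep[i] <- TRUE
  }
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pair_table", "data.frame")
  out
}

#' Joint sample-shuffling permutation test for miRNA-mRNA pairs
#'
#' For each of `B` permutations the sample alignment of the miRNA matrix is
#' shuffled relative to the mRNA matrix (one shared shuffle per permutation,
#' so inter-pair dependence is preserved), and every pair's correlation is
#' recomputed. The per-pair permutation p-value is left-tailed,
#' `p_perm = (1 + #[r_b <= r_obs]) / (1 + B)`; a pair is significant when
#' `p_perm < alpha` and `r_obs < 0`. The global p-value compares the
#' observed number of significant pairs `K_obs` with the per-permutation
#' count of pairs meeting the same criterion against their own null
#' distribution: `global_p = (1 + #[K_b >= K_obs]) / (1 + B)`.
#'
#' @param pairs A scored [score_pairs()] table.
#' @param mirna_expr,mrna_expr The two [count_matrix()] objects.
#' @param B Number of permutations (default 10000).
#' @param alpha Per-pair significance level (default 0.05).
#' @param seed RNG seed; fixed seed gives identical results.
#' @param samples Optional sample-ID subset, as in [score_pairs()]; use the
#'   same subset the pairs were scored on.
#' @return List of class `pair_test`: `pairs` (with `p_perm` and
#'   `significant` filled), `k_obs`, `global_p`, `B`, `alpha`,
#'   `n_samples`.
#' @export
permutation_test <- function(pairs, mirna_expr, mrna_expr, B = 10000,
                             alpha = 0.05, seed = NULL, samples = NULL) {
  stopifnot(inherits(pairs, "pair_table"))
  if (B < 1) stop("B must be at least 1")
  if (nrow(pairs) == 0) {
    return(structure(list(pairs = pairs, k_obs = 0L, global_p = 1,
                          B = B, alpha = alpha, n_samples = NA_integer_),
                     class = "pair_test"))
  }
  if (any(is.na(pairs$r))) stop("pairs must be scored first (r is NA)")
  ex <- shared_log_expr(mirna_expr, mrna_expr, samples)
  n <- length(ex$samples)
  std <- function(m) {
    c_m <- m - rowMeans(m)
    c_m / sqrt(rowSums(c_m^2))
  }
  zx <- std(ex$mirna[pairs$mirna_id, , drop = FALSE])
  zy <- std(ex$mrna[pairs$gene_id, , drop = FALSE])
  r_obs <- rowSums(zx * zy)
  if (!is.null(seed)) set.seed(seed)
  null_r <- matrix(NA_real_, nrow(pairs), B)
  for (b in seq_len(B)) {
    perm <- sample.int(n)
    null_r[, b] <- rowSums(zx[, perm, drop = FALSE] * zy)
  }
  p_perm <- (1 + rowSums(null_r <= r_obs)) / (1 + B)
  pairs$p_perm <- p_perm
  pairs$significant <- p_perm < alpha & r_obs < 0
  k_obs <- sum(pairs$significant)
  # per-permutation analogue of the per-pair criterion: rank of each null r
  # within its own pair's null distribution
  null_p <- t(apply(null_r, 1, rank, ties.method = "max")) / (1 + B)
  sig_b <- null_p < alpha & null_r < 0
  k_b <- colSums(sig_b)
  global_p <- (1 + sum(k_b >= k_obs)) / (1 + B)
  structure(list(pairs = pairs, k_obs = k_obs, global_p = global_p,
                 B = B, alpha = alpha, n_samples = n),
            class = "pair_test")
}

#' @export
print.pair_test <- function(x, ...) {
  cat(sprintf(
    "<pair_test> %d pairs, %d significant (alpha %.3g), global p = %.4g (B = %d)\n",
    nrow(x$pairs), x$k_obs, x$alpha, x$global_p, x$B))
  invisible(x)
}

#' Write a pair table to TSV
#'
#' @param x A `pair_table` (or the `pairs` element of a `pair_test`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
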