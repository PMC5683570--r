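#' Build a typed miRNA/TF regulatory network
#'
#' Node classes are inferred from edge roles: sources of `mirna_target`
#' edges are miRNAs; sources of `tf_gene` edges and all edge targets are
#' genes. An identifier appearing in both classes is an error. Propagation
#' runs on the gene-level subgraph, which contains only `tf_gene` edges;
#' genes touched only by miRNA-target edges remain as isolated nodes of that
#' subgraph.
#'
#' @param edges An [edge_list()].
#' @return A list of class `regulatory_network` with elements `mirnas`,
#'   `genes`, `targets` (named list: miRNA -> gene targets), `tf_edges`
#'   (data.frame) and `adjacency` (sparse column-normalized gene-by-gene
#'   walk matrix; dangling columns are all-zero).
#' @export
build_network <- function(edges) {
  stopifnot(inherits(edges, "edge_list"))
  if (nrow(edges) == 0) {
    warning("empty edge list: network has no nodes")
    return(structure(list(mirnas = character(0), genes = character(0),
                          targets = list(),
                          tf_edges = edges[0, , drop = FALSE],
                          adjacency = Matrix::sparseMatrix(
                            i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(0, 0))),
                     class = "regulatory_network"))
  }
  mt <- edges[edges$edge_type == "mirna_target", , drop = FALSE]
  tf <- edges[edges$edge_type == "tf_gene", , drop = FALSE]
  mirnas <- sort(unique(mt$source))
  genes <- sort(unique(c(mt$target, tf$source, tf$target)))
  both <- intersect(mirnas, genes)
  if (length(both) > 0)
    stop("identifier used as both miRNA and gene: ",
         paste(both, collapse = ", "))
  targets <- lapply(split(mt$target, mt$source), unique)
  n <- length(genes)
  w <- Matrix::sparseMatrix(i = match(tf$target, genes),
                            j = match(tf$source, genes),
                            x = rep(1, nrow(tf)), dims = c(n, n),
                            dimnames = list(genes, genes))
  cs <- Matrix::colSums(w)
  nz <- cs > 0
  if (any(nz)) w[, nz] <- sweep(w[, nz, drop = FALSE], 2, cs[nz], "/")
  structure(list(mirnas = mirnas, genes = genes, targets = targets,
                 tf_edges = tf, adjacency = w),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %d miRNAs, %d genes, %d tf_gene edges\n",
              length(x$mirnas), length(x$genes), nrow(x$tf_edges)))
  invisible(x)
}

#' Random walk with restart over the gene subgraph
#'
#' Power iteration on `p <- (1 - restart) * (W p + m p0) + restart * p0`,
#' where `W` is the column-normalized `tf_gene` adjacency, `p0` is uniform
#' over the seed genes and `m` is the walk mass sitting on dangling
#' (out-degree zero) genes, which is redistributed to the restart vector.
#' Iteration stops when the L1 change falls below `tol`; the result is the
#' stationary influence distribution and sums to 1.
#'
#' @param network A [build_network()] result.
#' @param seeds Character vector of seed genes (all must be network genes).
#' @param restart Restart probability in (0, 1] (default 0.5).
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 1000).
#' @return Named influence vector over all network genes.
#' @export
rwr <- function(network, seeds, restart = 0.5, tol = 1e-10,
                max_iter = 1000) {
  stopifnot(inherits(network, "regulatory_network"))
  if (restart <= 0 || restart > 1) stop("restart must be in (0, 1]")
  genes <- network$genes
  seeds <- unique(seeds)
  if (length(seeds) == 0 || !all(seeds %in% genes))
    stop("seeds must be a non-empty subset of the network's genes")
  n <- length(genes)
  p0 <- numeric(n)
  p0[match(seeds, genes)] <- 1 / length(seeds)
  if (restart == 1) return(setNames(p0, genes))
  w <- network$adjacency
  dangling <- Matrix::colSums(w) == 0
  p <- p0
  for (i in seq_len(max_iter)) {
    m <- sum(p[dangling])
    p_new <- as.numeric((1 - restart) * (w %*% p + m * p0) + restart * p0)
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) return(setNames(p, genes))
  }
  stop(sprintf("random walk did not converge in %d iterations (L1 residual %.3e)",
               max_iter, delta))
}

# Resolvent kernel K = (I - (1-restart) W)^{-1}. The RWR fixed point for any
# seed profile p0 is K p0 renormalized to sum 1 (the dangling-mass term only
# rescales p0), so batches of seed sets reduce to column sums of K.
rwr_kernel <- function(network, restart = 0.5) {
  n <- length(network$genes)
  k <- solve(diag(n) - (1 - restart) * as.matrix(network$adjacency))
  dimnames(k) <- list(network$genes, network$genes)
  k
}

rwr_from_kernel <- function(kernel, seeds) {
  v <- rowSums(kernel[, seeds, drop = FALSE])
  v / sum(v)
}

#' Rank genes by differential-expression strength
#'
#' Builds the ranked gene list the propagation score walks over. The default
#' statistic is the unsigned significance `-log10(p_raw)`, so strongly
#' dysregulated genes sit at the top regardless of direction; `signed = TRUE`
#' multiplies by `sign(log2fc)` instead. Ties are broken by feature ID so
#' the order is strict and deterministic.
#'
#' @param de A [de_table()] covering every tested gene.
#' @param signed Use the signed statistic? Default `FALSE`.
#' @return A data.frame (`gene_id`, `stat`) in descending rank order, class
#'   `ranked_de_list`.
#' @export
ranked_de_list <- function(de, signed = FALSE) {
  stopifnot(inherits(de, "de_table"))
  stat <- -log10(pmax(de$p_raw, 1e-300))
  if (signed) stat <- stat * sign(de$log2fc)
  ord <- order(-stat, de$feature_id)
  structure(data.frame(gene_id = de$feature_id[ord], stat = stat[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_de_list", "data.frame"))
}

#' Weighted running-sum propagation score
#'
#' Walks the ranked gene list from top to bottom. At a hit gene (influence
#' above `eps`) the running sum rises by that gene's share of the total hit
#' influence; elsewhere it falls by `1 / (N - |H|)`. The raw score is the
#' signed maximal deviation and the leading edge is the set of hits at or
#' before the extremum when the extremum is positive, or strictly after it
#' when negative.
#'
#' @param influence Named influence vector (e.g. from [rwr()]); genes absent
#'   from the ranking are ignored.
#' @param ranked A [ranked_de_list()].
#' @param eps Hit-membership threshold; default `1 / (10 * N)` where N is
#'   the ranking length.
#' @return List with `raw_score`, `leading_edge` (character) and
#'   `extremum_pos`.
#' @export
propagation_score <- function(influence, ranked, eps = NULL) {
  stopifnot(inherits(ranked, "ranked_de_list"))
  n <- nrow(ranked)
  if (is.null(eps)) eps <- 1 / (10 * n)
  infl <- setNames(numeric(n), ranked$gene_id)
  shared <- intersect(names(influence), ranked$gene_id)
  infl[shared] <- influence[shared]
  hit <- infl > eps
  h <- sum(hit)
  if (h == 0 || h == n)
    stop("hit set must be a proper non-empty subset of the ranked genes")
  inc <- ifelse(hit, infl / sum(infl[hit]), -1 / (n - h))
  cs <- cumsum(inc)
  pos <- which.max(abs(cs))
  raw <- cs[pos]
  le <- if (raw >= 0) names(infl)[seq_len(pos)][hit[seq_len(pos)]]
        else names(infl)[seq(pos + 1, n)][hit[seq(pos + 1, n)]]
  list(raw_score = unname(raw), leading_edge = le, extremum_pos = unname(pos))
}

mirna_perm_seed <- function(seed, mirna_id) {
  h <- sum(utf8ToInt(mirna_id) * seq_along(utf8ToInt(mirna_id)))
  as.integer((as.numeric(seed) * 131 + h) %% 2147483647)
}

#' Network perturbation effect score for one miRNA
#'
#' Diffuses influence from the miRNA's target set through the TF-gene
#' network by random walk with restart, scores the influence profile against
#' the ranked DE list with the running-sum statistic, and normalizes by `B`
#' size-matched random seed sets drawn without replacement from the
#' network's genes: `npes = (S - mean(S_b)) / sd(S_b)` and
#' `p_emp = (1 + #[S_b >= S]) / (1 + B)`.
#'
#' @param network A [build_network()] result.
#' @param ranked A [ranked_de_list()].
#' @param mirna_id miRNA whose target set seeds the walk.
#' @param restart Restart probability (default 0.5).
#' @param B Number of seed-set permutations (default 1000).
#' @param seed RNG seed; fixed seed gives identical results.
#' @param eps Hit threshold forwarded to [propagation_score()].
#' @param kernel Optional precomputed [rwr_kernel()] (reused across miRNAs).
#' @return List of class `npes_record`: `mirna_id`, `n_targets`,
#'   `raw_score`, `null_mean`, `null_sd`, `npes`, `p_emp`, `leading_edge`,
#'   `degenerate`.
#' @export
npes <- function(network, ranked, mirna_id, restart = 0.5, B = 1000,
                 seed = NULL, eps = NULL, kernel = NULL) {
  stopifnot(inherits(network, "regulatory_network"))
  tgt <- intersect(network$targets[[mirna_id]], network$genes)
  if (length(tgt) == 0)
    stop("miRNA '", mirna_id, "' has no targets in the gene subgraph")
  if (is.null(kernel)) kernel <- rwr_kernel(network, restart)
  obs <- propagation_score(rwr_from_kernel(kernel, tgt), ranked, eps)
  if (!is.null(seed)) set.seed(seed)
  n_genes <- length(network$genes)
  null_scores <- vapply(seq_len(B), function(b) {
    rs <- network$genes[sample.int(n_genes, length(tgt))]
    propagation_score(rwr_from_kernel(kernel, rs), ranked, eps)$raw_score
  }, numeric(1))
  mu <- mean(null_scores)
  sdev <- sd(null_scores)
  degenerate <- !is.finite(sdev) || sdev == 0
  structure(list(mirna_id = mirna_id, n_targets = length(tgt),
                 raw_score = obs$raw_score, null_mean = mu, null_sd = sdev,
                 npes = if (degenerate) NA_real_
                        else (obs$raw_score - mu) / sdev,
                 p_emp = (1 + sum(null_scores >= obs$raw_score)) / (1 + B),
                 leading_edge = obs$leading_edge, degenerate = degenerate),
            class = "npes_record")
}

#' Screen every miRNA by network perturbation effect score
#'
#' Runs [npes()] for each miRNA with at least `min_targets` targets mapped
#' into the gene subgraph, BH-adjusts the empirical p-values across
#' non-degenerate miRNAs, and flags a miRNA as enriched when
#' `npes > npes_min` and its adjusted p passes both the `alpha` and
#' `fdr_max` cut-offs. Each miRNA's permutation stream is seeded from the
#' global seed and the miRNA's identifier, so results do not depend on
#' screen order.
#'
#' @param network A [build_network()] result.
#' @param ranked A [ranked_de_list()].
#' @param restart Restart probability (default 0.5).
#' @param B Seed-set permutations per miRNA (default 1000).
#' @param seed Global RNG seed.
#' @param min_targets Minimum mapped targets (default 3).
#' @param eps Hit threshold forwarded to [propagation_score()].
#' @param npes_min NPES threshold for the enriched flag (default 2).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param fdr_max Additional FDR threshold on the same adjusted value
#'   (default 0.1).
#' @param family_map Optional named character vector mapping miRNA IDs to
#'   family labels; member target sets are unioned and each family is
#'   scored as one unit (unmapped miRNAs keep their own identity).
#' @return data.frame sorted by decreasing NPES: `mirna_id`, `n_targets`,
#'   `raw_score`, `npes`, `p_emp`, `p_adj`, `enriched`, `leading_edge`
#'   (semicolon-joined).
#' @export
npes_screen <- function(network, ranked, restart = 0.5, B = 1000,
                        seed = NULL, min_targets = 3, eps = NULL,
                        npes_min = 2, alpha = 0.05, fdr_max = 0.1,
                        family_map = NULL) {
  if (!is.null(family_map)) {
    grp <- family_map[names(network$targets)]
    missing_map <- is.na(grp)
    grp[missing_map] <- names(network$targets)[missing_map]
    network$targets <- lapply(split(unname(network$targets), unname(grp)),
                              function(sets) sort(unique(unlist(sets))))
  }
  eligible <- names(network$targets)[vapply(network$targets, function(t)
    length(intersect(t, network$genes)) >= min_targets, logical(1))]
  eligible <- sort(eligible)
  if (length(eligible) == 0)
    return(data.frame(mirna_id = character(0), n_targets = integer(0),
                      raw_score = numeric(0), npes = numeric(0),
                      p_emp = numeric(0), p_adj = numeric(0),
                      enriched = logical(0), leading_edge = character(0),
                      stringsAsFactors = FALSE))
  kernel <- rwr_kernel(network, restart)
  base_seed <- if (is.null(seed)) 0L else seed
  recs <- lapply(eligible, function(m)
    npes(network, ranked, m, restart = restart, B = B,
         seed = mirna_perm_seed(base_seed, m), eps = eps, kernel = kernel))
  tab <- data.frame(
    mirna_id = vapply(recs, `[[`, character(1), "mirna_id"),
    n_targets = vapply(recs, `[[`, integer(1), "n_targets"),
    raw_score = vapply(recs, `[[`, numeric(1), "raw_score"),
    npes = vapply(recs, `[[`, numeric(1), "npes"),
    p_emp = vapply(recs, `[[`, numeric(1), "p_emp"),
    leading_edge = vapply(recs, function(r)
      paste(r$leading_edge, collapse = ";"), character(1)),
    degenerate = vapply(recs, `[[`, logical(1), "degenerate"),
    stringsAsFactors = FALSE)
  tab$p_adj <- NA_real_
  ok <- !tab$degenerate
  tab$p_adj[ok] <- bh_adjust(tab$p_emp[ok])
  tab$enriched <- ok & tab$npes > npes_min & tab$p_adj < alpha &
    tab$p_adj < fdr_max
  tab <- tab[order(-ifelse(is.na(tab$npes), -Inf, tab$npes),
                   tab$mirna_id), ]
  rownames(tab) <- NULL
  tab[, c("mirna_id", "n_targets", "raw_score", "npes", "p_emp", "p_adj",
          "enriched", "degenerate", "leading_edge")]
}
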