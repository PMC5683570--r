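# Shared fixture builders: everything is generated in code at test time.

random_count_matrix <- function(nf = 50, ns = 10, class = "mrna",
                                max_count = 1000, seed = 1) {
  set.seed(seed)
  m <- matrix(sample.int(max_count + 1, nf * ns, replace = TRUE) - 1L,
              nrow = nf,
              dimnames = list(sprintf("f%03d", seq_len(nf)),
                              sprintf("s%02d", seq_len(ns))))
  count_matrix(m, class)
}

two_group_sheet <- function(x, n_tumor = NULL) {
  ids <- colnames(x$counts)
  if (is.null(n_tumor)) n_tumor <- length(ids) %/% 2
  as_sample_sheet(data.frame(
    sample_id = ids,
    group = rep(c("tumor", "normal"),
                c(n_tumor, length(ids) - n_tumor)),
    stringsAsFactors = FALSE))
}

# NB counts with planted log2 fold changes; equal group sizes by default
nb_dataset <- function(nf = 500, n_per_group = 8, phi = 0.2, lfc = NULL,
                       mean_log = log(100), seed = 1) {
  set.seed(seed)
  if (is.null(lfc)) lfc <- rep(0, nf)
  mu <- exp(rnorm(nf, mean_log, 1))
  ns <- 2 * n_per_group
  grp <- rep(c(1, 0), each = n_per_group)
  mumat <- outer(mu, rep(1, ns)) * 2^outer(lfc, grp)
  y <- if (phi == 0) matrix(rpois(nf * ns, mumat), nrow = nf)
       else matrix(rnbinom(nf * ns, size = 1 / phi, mu = mumat), nrow = nf)
  dimnames(y) <- list(sprintf("g%04d", seq_len(nf)),
                      sprintf("s%02d", seq_len(ns)))
  x <- count_matrix(y, "mrna")
  list(x = x, sheet = two_group_sheet(x, n_per_group), lfc = lfc)
}

# independent brute-force BH step-up, straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- seq(i, m)
    q[ord[i]] <- min(1, min(m / js * p[ord[js]]))
  }
  q
}

# dense linear-algebra RWR oracle: direct fixed-point solve
rwr_oracle <- function(network, seeds, restart) {
  genes <- network$genes
  n <- length(genes)
  w <- as.matrix(network$adjacency)
  p0 <- numeric(n)
  p0[match(seeds, genes)] <- 1 / length(seeds)
  d <- as.numeric(colSums(w) == 0)
  # p = (1-r) W p + [(1-r) d.p + r] p0  ->  (I - (1-r)W - (1-r) p0 d') p = r p0
  a <- diag(n) - (1 - restart) * w - (1 - restart) * outer(p0, d)
  setNames(solve(a, restart * p0), genes)
}

random_network <- function(n_genes = 30, n_edges = 60, n_mirnas = 3,
                           targets = 4, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  tf <- unique(data.frame(
    source = sample(genes, n_edges, replace = TRUE),
    target = sample(genes, n_edges, replace = TRUE),
    stringsAsFactors = FALSE))
  tf <- tf[tf$source != tf$target, , drop = FALSE]
  tf$edge_type <- "tf_gene"
  mt <- do.call(rbind, lapply(seq_len(n_mirnas), function(i)
    data.frame(source = sprintf("m%02d", i),
               target = sample(genes, targets), edge_type = "mirna_target",
               stringsAsFactors = FALSE)))
  build_network(edge_list(rbind(mt, tf)))
}

random_ranking <- function(gene_ids, seed = 1) {
  set.seed(seed)
  ranked_de_list(de_table(data.frame(
    feature_id = gene_ids,
    log2fc = rnorm(length(gene_ids)),
    p_raw = runif(length(gene_ids)),
    p_adj = runif(length(gene_ids)),
    stringsAsFactors = FALSE)))
}

# ungated pair table (one row per miRNA-target edge), ready for score_pairs
target_pair_table <- function(pairs_df) {
  pairs_df$mirna_dir <- "up"
  pairs_df$gene_dir <- "down"
  pairs_df$r <- NA_real_
  pairs_df$p_param <- NA_real_
  pairs_df$p_perm <- NA_real_
  pairs_df$significant <- NA
  rownames(pairs_df) <- NULL
  class(pairs_df) <- c("pair_table", "data.frame")
  pairs_df
}

network_pair_table <- function(network) {
  target_pair_table(do.call(rbind, lapply(sort(names(network$targets)),
    function(m) data.frame(mirna_id = m,
                           gene_id = sort(network$targets[[m]]),
                           stringsAsFactors = FALSE))))
}
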