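test_that("network construction infers node classes and degrees", {
  el <- edge_list(data.frame(
    source = c("miR-1", "TF1", "TF1"),
    target = c("G1", "G1", "G2"),
    edge_type = c("mirna_target", "tf_gene", "tf_gene"),
    stringsAsFactors = FALSE))
  net <- build_network(el)
  expect_identical(net$mirnas, "miR-1")
  expect_setequal(net$genes, c("G1", "G2", "TF1"))
  expect_equal(Matrix::colSums(net$adjacency)[["TF1"]], 1)  # normalized
  expect_identical(net$targets[["miR-1"]], "G1")

  expect_warning(empty <- build_network(edge_list(
    data.frame(source = character(0), target = character(0),
               edge_type = character(0)))), "empty")
  expect_length(empty$genes, 0)

  dual <- edge_list(data.frame(
    source = c("X", "TF1"), target = c("G1", "X"),
    edge_type = c("mirna_target", "tf_gene"), stringsAsFactors = FALSE))
  expect_error(build_network(dual), "both miRNA and gene: X")
})

test_that("network node and edge tallies match brute-force counts", {
  set.seed(41)
  df <- unique(data.frame(
    source = sample(c(sprintf("m%02d", 1:20), sprintf("t%02d", 1:30)),
                    1200, replace = TRUE),
    target = sample(sprintf("g%03d", 1:150), 1200, replace = TRUE),
    stringsAsFactors = FALSE))
  df$edge_type <- ifelse(startsWith(df$source, "m"), "mirna_target",
                         "tf_gene")
  df <- head(df, 1000)
  net <- build_network(edge_list(df))
  mt <- df[df$edge_type == "mirna_target", ]
  tf <- df[df$edge_type == "tf_gene", ]
  expect_setequal(net$mirnas, unique(mt$source))
  expect_setequal(net$genes, unique(c(mt$target, tf$source, tf$target)))
  expect_identical(nrow(net$tf_edges), nrow(tf))
  expect_identical(sum(lengths(net$targets)), nrow(mt))
})

test_that("random walk matches closed forms and the dense solve oracle", {
  cyc <- build_network(edge_list(data.frame(
    source = c("A", "B", "miR-1"), target = c("B", "A", "A"),
    edge_type = c("tf_gene", "tf_gene", "mirna_target"),
    stringsAsFactors = FALSE)))
  # restart 1 returns the seed profile itself
  expect_equal(rwr(cyc, "A", restart = 1)[["A"]], 1)
  # two-node cycle, seed {A}, restart 0.5: p_A = 2/3, p_B = 1/3
  p <- rwr(cyc, "A", restart = 0.5)
  expect_equal(p[["A"]], 2 / 3, tolerance = 1e-9)
  expect_equal(p[["B"]], 1 / 3, tolerance = 1e-9)

  for (s in 1:10) {
    net <- random_network(n_genes = 30, n_edges = 70, seed = s)
    seeds <- sample(net$genes, 3)
    r <- runif(1, 0.2, 0.9)
    got <- rwr(net, seeds, restart = r)
    expect_equal(sum(got), 1, tolerance = 1e-8)
    expect_lt(sum(abs(got - rwr_oracle(net, seeds, r))), 1e-8)
    # seed order is irrelevant
    expect_equal(got, rwr(net, rev(seeds), restart = r))
  }
  expect_error(rwr(random_network(seed = 1), "absent-gene"), "seeds")
})

test_that("influence approaches the restart profile as restart grows", {
  net <- random_network(n_genes = 25, n_edges = 60, seed = 6)
  seeds <- net$genes[1:4]
  p0 <- setNames(numeric(length(net$genes)), net$genes)
  p0[seeds] <- 1 / 4
  l1 <- vapply(c(0.3, 0.6, 0.9, 0.99), function(r)
    sum(abs(rwr(net, seeds, restart = r) - p0)), numeric(1))
  expect_true(all(diff(l1) < 0))
  expect_lt(l1[4], 0.05)
})

test_that("the kernel shortcut reproduces iterative propagation exactly", {
  net <- random_network(n_genes = 40, n_edges = 90, seed = 13)
  k <- mirmint:::rwr_kernel(net, restart = 0.5)
  for (s in 1:5) {
    set.seed(s)
    seeds <- sample(net$genes, sample(2:6, 1))
    expect_lt(sum(abs(mirmint:::rwr_from_kernel(k, seeds) -
                        rwr(net, seeds, restart = 0.5))), 1e-9)
  }
})

test_that("running-sum score handles extreme and random configurations", {
  rk <- structure(data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                             stat = c(3, 2, 1, 0)),
                  class = c("ranked_de_list", "data.frame"))
  top <- propagation_score(c(g1 = 1), rk)
  expect_equal(top$raw_score, 1)
  expect_identical(top$leading_edge, "g1")
  bottom <- propagation_score(c(g4 = 1), rk)
  expect_lt(bottom$raw_score, 0)
  expect_identical(bottom$leading_edge, "g4")

  # oracle: plain loop over the definition
  score_oracle <- function(infl, rk, eps) {
    v <- setNames(numeric(nrow(rk)), rk$gene_id)
    v[intersect(names(infl), names(v))] <-
      infl[intersect(names(infl), names(v))]
    hit <- v > eps
    run <- 0; best <- 0
    for (i in seq_along(v)) {
      run <- run + if (hit[i]) v[i] / sum(v[hit]) else -1 / sum(!hit)
      if (abs(run) > abs(best)) best <- run
    }
    unname(best)
  }
  for (s in 1:10) {
    set.seed(s)
    genes <- sprintf("g%03d", 1:60)
    rk2 <- random_ranking(genes, seed = s)
    infl <- setNames(runif(60)^4, sample(genes))
    infl <- infl / sum(infl)
    eps <- 1 / 600
    expect_equal(propagation_score(infl, rk2, eps)$raw_score,
                 score_oracle(infl, rk2, eps), tolerance = 1e-12)
  }
  expect_error(propagation_score(setNames(rep(1, 4), rk$gene_id), rk,
                                 eps = 0), "proper non-empty subset")
})

test_that("NPES finds a miRNA targeting the top of a strong signal", {
  net <- random_network(n_genes = 50, n_edges = 100, n_mirnas = 1,
                        targets = 5, seed = 77)
  # ranking where the miRNA's targets are exactly the strongest genes
  tg <- net$targets[["m01"]]
  stats <- data.frame(feature_id = net$genes,
                      log2fc = 0,
                      p_raw = ifelse(net$genes %in% tg, 1e-8, runif(50)),
                      p_adj = 1, stringsAsFactors = FALSE)
  rk <- ranked_de_list(de_table(stats))
  rec <- npes(net, rk, "m01", B = 200, seed = 5)
  expect_gt(rec$npes, 2)
  expect_lte(rec$p_emp, 0.05)
  expect_gte(rec$p_emp, 1 / 201)
  # determinism for a fixed seed
  rec2 <- npes(net, rk, "m01", B = 200, seed = 5)
  expect_identical(rec$npes, rec2$npes)
})

test_that("empirical NPES p-values are calibrated under random rankings", {
  net <- random_network(n_genes = 40, n_edges = 80, n_mirnas = 1,
                        targets = 5, seed = 3)
  k <- mirmint:::rwr_kernel(net, 0.5)
  p_emps <- vapply(1:200, function(s) {
    rk <- random_ranking(net$genes, seed = 1000 + s)
    npes(net, rk, "m01", B = 99, seed = s, kernel = k)$p_emp
  }, numeric(1))
  expect_lt(abs(mean(p_emps < 0.05) - 0.05), 0.04)
  ks <- suppressWarnings(stats::ks.test(p_emps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the screen is order-independent and BH-adjusts across miRNAs", {
  net <- random_network(n_genes = 50, n_edges = 100, n_mirnas = 6,
                        targets = 4, seed = 9)
  rk <- random_ranking(net$genes, seed = 2)
  scr <- npes_screen(net, rk, B = 99, seed = 17)
  expect_identical(nrow(scr), 6L)
  # each miRNA's record equals a standalone npes() with its derived seed
  for (m in scr$mirna_id[1:3]) {
    solo <- npes(net, rk, m, B = 99,
                 seed = mirmint:::mirna_perm_seed(17, m))
    expect_equal(scr$npes[scr$mirna_id == m], solo$npes)
  }
  ok <- !scr$degenerate
  expect_equal(sort(scr$p_adj[ok]), sort(bh_adjust(scr$p_emp[ok])))

  # a single eligible miRNA gets p_adj = p_emp
  net1 <- random_network(n_genes = 30, n_edges = 60, n_mirnas = 1,
                         targets = 4, seed = 10)
  scr1 <- npes_screen(net1, random_ranking(net1$genes, 3), B = 99, seed = 1)
  expect_equal(scr1$p_adj, scr1$p_emp)
})

test_that("NPES ignores genes outside the network", {
  net <- random_network(n_genes = 30, n_edges = 60, n_mirnas = 1,
                        targets = 4, seed = 12)
  rk <- random_ranking(c(net$genes, sprintf("extra%02d", 1:10)), seed = 4)
  rk_renamed <- rk
  rk_renamed$gene_id <- sub("^extra", "renamed", rk_renamed$gene_id)
  a <- npes(net, rk, "m01", B = 49, seed = 2)
  b <- npes(net, rk_renamed, "m01", B = 49, seed = 2)
  expect_equal(a$npes, b$npes)
  expect_equal(a$raw_score, b$raw_score)
})

test_that("family collapse unions member target sets before scoring", {
  net <- random_network(n_genes = 40, n_edges = 80, n_mirnas = 4,
                        targets = 3, seed = 21)
  rk <- random_ranking(net$genes, seed = 5)
  fam <- c(m01 = "famA", m02 = "famA")
  scr <- npes_screen(net, rk, B = 49, seed = 3, family_map = fam)
  expect_true("famA" %in% scr$mirna_id)
  expect_false(any(c("m01", "m02") %in% scr$mirna_id))
  expect_identical(
    scr$n_targets[scr$mirna_id == "famA"],
    length(unique(unlist(net$targets[c("m01", "m02")]))))
})
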