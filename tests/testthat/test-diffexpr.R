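test_that("cpm matches its definition and conserves column totals", {
  m <- rbind(f1 = c(10, 5), f2 = c(999990, 15))
  colnames(m) <- c("s1", "s2")
  x <- count_matrix(m, "mrna")
  cp <- cpm_matrix(x)
  expect_equal(cp["f1", "s1"], 10)  # 10 reads in a library of 1e6
  zeros <- count_matrix(rbind(m, f3 = c(0, 0)), "mrna")
  expect_equal(unname(cpm_matrix(zeros)["f3", ]), c(0, 0))

  r <- random_count_matrix(20, 6, seed = 5)
  expect_equal(unname(colSums(cpm_matrix(r))), rep(1e6, 6))

  empty_lib <- count_matrix(matrix(c(1, 0), 1,
                            dimnames = list("f", c("s1", "s2"))), "mrna")
  expect_error(cpm_matrix(empty_lib), "zero library size.*'s2'")
})

test_that("low-expression filter keeps exactly the qualifying features", {
  # counts with library size 1e7, so CPM = count / 10 exactly
  m <- rbind(f1 = c(120, 110, 0, 0),        # CPM 12, 11, 0, 0
             f2 = c(99, 99, 99, 99))        # CPM 9.9 everywhere
  mm <- rbind(m, filler = 1e7 - colSums(m))
  colnames(mm) <- sprintf("s%d", 1:4)
  x <- count_matrix(mm, "mirna")
  kept <- filter_low_expression(x, de_config())
  expect_true("f1" %in% rownames(kept$counts))   # 2 of 4 reach 10 CPM
  expect_false("f2" %in% rownames(kept$counts))

  r <- random_count_matrix(200, 6, max_count = 50, seed = 11)
  cfg <- de_config(cpm_min = 10, cpm_frac = 0.5)
  kept2 <- filter_low_expression(r, cfg)
  cp <- cpm_matrix(r)
  brute <- rownames(r$counts)[vapply(seq_len(200), function(f)
    sum(cp[f, ] >= 10) >= ceiling(0.5 * 6), logical(1))]
  expect_identical(rownames(kept2$counts), brute)
  # idempotence
  expect_identical(filter_low_expression(kept2, cfg)$counts, kept2$counts)
})

test_that("normalization factors absorb pure depth differences", {
  base <- random_count_matrix(100, 1, max_count = 500, seed = 2)$counts[, 1]
  m <- outer(base, c(1, 2, 5, 10))
  dimnames(m) <- list(names(base), sprintf("s%d", 1:4))
  f <- norm_factors(count_matrix(m, "mrna"))
  expect_equal(unname(unclass(f)), rep(1, 4), tolerance = 1e-9)

  single <- count_matrix(matrix(c(5, 10), 1,
                         dimnames = list("f", c("s1", "s2"))), "mrna")
  expect_equal(unname(unclass(norm_factors(single))), c(1, 1))
})

test_that("normalization factors track the true composition correction", {
  # 5% planted DE shifts tumour library composition; the trimmed-mean
  # factors must match the oracle correction (which makes every null
  # feature's effective CPM equal across samples) within 5%
  set.seed(31)
  nf <- 500; npg <- 4
  mu <- exp(rnorm(nf, log(100), 1))
  lfc <- c(rep(c(3, -3), length.out = 25), rep(0, 475))
  grp <- rep(c(1, 0), each = npg)
  mumat <- outer(mu, rep(1, 2 * npg)) * 2^outer(lfc, grp)
  y <- matrix(rnbinom(nf * 2 * npg, size = 10, mu = mumat), nrow = nf,
              dimnames = list(sprintf("g%03d", seq_len(nf)),
                              sprintf("s%d", seq_len(2 * npg))))
  f <- norm_factors(count_matrix(y, "mrna"))
  # equal effective depth for null features: factor proportional to the
  # inverse realized library size
  oracle <- 1 / colSums(y)
  oracle <- oracle / exp(mean(log(oracle)))
  expect_true(all(abs(unclass(f) / oracle - 1) < 0.05))
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(0.01), 0.01)
  # hand evaluation: q_(i) = min_{j>=i} (4/j) p_(j) = 0.04 for all
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  for (s in 1:20) {
    set.seed(s)
    p <- runif(sample(1:300, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))
    # monotone: adjusted values preserve the order of the raw p-values
    expect_true(all(diff(q[order(p)]) >= 0))
  }
})

test_that("dispersion estimates recover the truth and shrink sensibly", {
  d0 <- nb_dataset(nf = 1000, n_per_group = 20, phi = 0, seed = 7)
  disp0 <- estimate_dispersions(d0$x, d0$sheet)
  expect_lt(median(disp0), 0.05)

  d2 <- nb_dataset(nf = 2000, n_per_group = 10, phi = 0.2, seed = 8)
  disp2 <- estimate_dispersions(d2$x, d2$sheet)
  expect_gt(median(disp2), 0.1)
  expect_lt(median(disp2), 0.3)

  # identical counts within each group -> zero raw dispersion
  m <- matrix(rep(c(10, 10, 40, 40), each = 3), nrow = 3, byrow = FALSE,
              dimnames = list(sprintf("f%d", 1:3), sprintf("s%d", 1:4)))
  x <- count_matrix(m, "mrna")
  sheet <- two_group_sheet(x, 2)
  raw <- attr(estimate_dispersions(x, sheet), "raw")
  expect_true(all(raw == 0))
})

test_that("the NB test is calibrated under the null", {
  d <- nb_dataset(nf = 2000, n_per_group = 8, phi = 0.1, seed = 12)
  de <- nb_test(d$x, d$sheet, norm_factors(d$x))
  alpha_hat <- mean(de$p_raw < 0.01)
  expect_gt(alpha_hat, 0.003)
  expect_lt(alpha_hat, 0.025)
  ks <- suppressWarnings(stats::ks.test(de$p_raw, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the NB test recovers planted fold changes with correct signs", {
  lfc <- rep(0, 1000); idx <- 1:100
  lfc[idx] <- rep(c(3, -3), 50)
  d <- nb_dataset(nf = 1000, n_per_group = 8, phi = 0.2, lfc = lfc,
                  seed = 13)
  de <- run_de(d$x, d$sheet, filter = FALSE)
  expect_gte(mean(de$direction[idx] != "ns"), 0.9)
  called <- de$direction[idx] != "ns"
  expect_true(all((de$direction[idx] == "up")[called] ==
                    (lfc[idx] > 0)[called]))
})

test_that("all-zero features give log2fc 0 and p 1", {
  d <- nb_dataset(nf = 50, n_per_group = 4, phi = 0.1, seed = 14)
  d$x$counts[1, ] <- 0
  de <- nb_test(d$x, d$sheet)
  expect_equal(de$log2fc[1], 0)
  expect_equal(de$p_raw[1], 1)
})

test_that("swapping group labels negates fold changes, preserves p-values", {
  d <- nb_dataset(nf = 300, n_per_group = 5, phi = 0.15,
                  lfc = rnorm(300, sd = 0.5), seed = 15)
  de1 <- nb_test(d$x, d$sheet)
  flipped <- d$sheet
  flipped$group <- ifelse(flipped$group == "tumor", "normal", "tumor")
  de2 <- nb_test(d$x, flipped)
  expect_equal(de1$log2fc, -de2$log2fc, tolerance = 1e-9)
  expect_equal(de1$p_raw, de2$p_raw, tolerance = 1e-9)
})

test_that("NB test p-values track an independent exact-test implementation", {
  d <- nb_dataset(nf = 400, n_per_group = 6, phi = 0.2,
                  lfc = c(rep(2, 40), rep(0, 360)), seed = 16)
  de <- nb_test(d$x, d$sheet, norm_factors(d$x))
  dge <- edgeR::DGEList(counts = d$x$counts,
                        group = d$sheet$group)
  dge <- edgeR::calcNormFactors(dge)
  dge <- edgeR::estimateDisp(dge)
  et <- edgeR::exactTest(dge, pair = c("normal", "tumor"))$table
  expect_gt(cor(-log10(de$p_raw), -log10(et$PValue), method = "spearman"),
            0.9)
  expect_gt(cor(de$log2fc, et$logFC), 0.98)
})

test_that("classification applies all three thresholds jointly", {
  tab <- de_table(data.frame(feature_id = "f1", log2fc = 1.5,
                             p_raw = 1e-6, p_adj = 1e-5))
  expect_identical(classify_de(tab)$direction, "ns")

  set.seed(17)
  rnd <- de_table(data.frame(
    feature_id = sprintf("f%03d", 1:100),
    log2fc = rnorm(100, sd = 3),
    p_raw = runif(100)^3, p_adj = NA, stringsAsFactors = FALSE))
  rnd$p_adj <- pmin(1, rnd$p_raw * 2)
  got <- classify_de(rnd, de_config())
  brute <- ifelse(rnd$log2fc > 2 & rnd$p_raw < 0.01 & rnd$p_adj < 0.01, "up",
           ifelse(rnd$log2fc < -2 & rnd$p_raw < 0.01 & rnd$p_adj < 0.01,
                  "down", "ns"))
  expect_identical(got$direction, brute)
  expect_identical(attr(got, "n_up"), sum(brute == "up"))
  expect_identical(attr(got, "n_down"), sum(brute == "down"))
})

test_that("latent factor count is near zero for pure noise", {
  hits <- vapply(1:10, function(s) {
    d <- nb_dataset(nf = 300, n_per_group = 6, phi = 0.1, seed = 100 + s)
    ncol(estimate_latent_factors(d$x, d$sheet, seed = s)) == 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("a planted batch is detected and tracked by factor 1", {
  d <- nb_dataset(nf = 500, n_per_group = 6, phi = 0.05, seed = 21)
  batch <- rep(c(0, 1), length.out = 12)  # alternates across both groups
  set.seed(22)
  affected <- sample(500, 150)
  y <- d$x$counts
  y[affected, batch == 1] <- round(y[affected, batch == 1] * 2)
  x <- count_matrix(y, "mrna")
  v <- estimate_latent_factors(x, d$sheet, seed = 23)
  expect_gte(ncol(v), 1)
  expect_gt(abs(cor(v[, 1], batch)), 0.8)
  # explicit k = 0 leaves downstream DE untouched
  v0 <- estimate_latent_factors(x, d$sheet, k = 0)
  expect_identical(ncol(v0), 0L)
  expect_equal(nb_test(x, d$sheet)$p_raw,
               nb_test(x, d$sheet, latent = NULL)$p_raw)
  expect_error(estimate_latent_factors(x, d$sheet, k = 11), "smaller than")
})
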