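#' Differential-expression configuration
#'
#' Thresholds and tuning constants for the two-group negative-binomial test.
#' The defaults reproduce the stringent decision surface used for both assay
#' arms of the tumour-vs-normal comparison: a feature is called up (down)
#' when log2FC > 2 (< -2) with raw p < 0.01 and BH-adjusted p < 0.01, and
#' miRNAs are pre-filtered to those with at least 10 counts per million in at
#' least half of the samples.
#'
#' @param t_lfc Absolute log2 fold-change threshold (default 2).
#' @param t_p Raw p-value threshold (default 0.01).
#' @param t_fdr BH-adjusted p-value threshold (default 0.01).
#' @param cpm_min CPM cut-off for the low-expression filter (default 10).
#' @param cpm_frac Fraction of samples that must reach `cpm_min`
#'   (default 0.5).
#' @param prior_count Pseudo-count added to group-mean CPM in the
#'   fold-change ratio only, never inside the likelihood (default 0.5).
#' @param n_latent Number of latent factors to include as covariates:
#'   `NULL` to skip, `"auto"` for permutation-based selection, or a
#'   non-negative integer.
#' @return A list of class `de_config`.
#' @export
de_config <- function(t_lfc = 2, t_p = 0.01, t_fdr = 0.01,
                      cpm_min = 10, cpm_frac = 0.5, prior_count = 0.5,
                      n_latent = NULL) {
  stopifnot(t_lfc > 0, t_p > 0, t_fdr > 0, cpm_min > 0,
            cpm_frac > 0, cpm_frac <= 1, prior_count >= 0)
  structure(list(t_lfc = t_lfc, t_p = t_p, t_fdr = t_fdr, cpm_min = cpm_min,
                 cpm_frac = cpm_frac, prior_count = prior_count,
                 n_latent = n_latent),
            class = "de_config")
}

#' Counts per million
#'
#' `cpm_matrix(x)[f, s] = counts[f, s] / effective_library_size[s] * 1e6`,
#' where the effective library size is the raw column sum times the sample's
#' normalization factor (1 when `norm` is omitted).
#'
#' @param x A [count_matrix()].
#' @param norm Optional [norm_factors()] result.
#' @return Real matrix with the same dimnames as the counts.
#' @export
cpm_matrix <- function(x, norm = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  lib <- colSums(x$counts)
  if (any(lib == 0))
    stop("zero library size for sample '",
         colnames(x$counts)[which(lib == 0)[1]], "'")
  if (!is.null(norm)) {
    stopifnot(all(colnames(x$counts) %in% names(norm)))
    lib <- lib * norm[colnames(x$counts)]
  }
  sweep(x$counts, 2, lib, "/") * 1e6
}

#' Remove features expressed below a CPM floor
#'
#' Keeps feature `f` iff at least `ceil(cpm_frac * n_samples)` samples have
#' `cpm[f, s] >= cpm_min`. The sample set is unchanged and the operation is
#' idempotent. CPM here uses raw library sizes (the filter precedes
#' normalization).
#'
#' @param x A [count_matrix()].
#' @param cfg A [de_config()].
#' @return A [count_matrix()] restricted to the surviving features.
#' @export
filter_low_expression <- function(x, cfg = de_config()) {
  cp <- cpm_matrix(x)
  need <- ceiling(cfg$cpm_frac * ncol(cp))
  keep <- rowSums(cp >= cfg$cpm_min) >= need
  count_matrix(x$counts[keep, , drop = FALSE], x$feature_class)
}

#' Trimmed-mean normalization factors
#'
#' Per-sample scale factors computed by the trimmed mean of M-values against
#' the sample whose upper quartile is closest to the mean upper quartile
#' (30% trim on log-ratios, 5% on average abundance), rescaled to geometric
#' mean 1. The effective library size of a sample is its raw library size
#' times its factor. Degenerate inputs (fewer than two features, or a sample
#' sharing no positive feature with the reference) fall back to factor 1
#' with a warning.
#'
#' @param x A [count_matrix()].
#' @return Named positive numeric vector of factors (one per sample) with
#'   class `norm_factors`.
#' @export
norm_factors <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  n <- ncol(x$counts)
  if (n < 2) stop("normalization needs at least 2 samples")
  if (nrow(x$counts) < 2) {
    f <- rep(1, n)
  } else {
    f <- tryCatch(
      edgeR::calcNormFactors(x$counts, method = "TMM"),
      error = function(e) {
        warning("TMM normalization failed (", conditionMessage(e),
                "); using unit factors")
        rep(1, n)
      })
    if (any(!is.finite(f))) {
      warning("non-finite TMM factor; replaced by 1")
      f[!is.finite(f)] <- 1
    }
  }
  f <- f / exp(mean(log(f)))
  structure(setNames(f, colnames(x$counts)), class = "norm_factors")
}

effective_lib_sizes <- function(x, norm = NULL) {
  lib <- colSums(x$counts)
  if (!is.null(norm)) lib <- lib * norm[colnames(x$counts)]
  lib
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} (m / j) p_(j)` clipped at 1
#' and returned in input order, with ties resolved stably by input index.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, elementwise `>= p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Moment-based shrunken negative-binomial dispersions
#'
#' For each feature the dispersion `phi` (variance = mu + phi * mu^2) is
#' estimated by the method of moments from within-group residuals of
#' depth-normalized counts, floored at zero, and then shrunk toward the
#' median raw dispersion with weight `w = prior_df / (prior_df + group_df)`,
#' where `group_df = n_samples - n_groups`.
#'
#' @param x A [count_matrix()].
#' @param sheet Sample sheet covering the matrix's samples.
#' @param norm Optional [norm_factors()].
#' @param prior_df Prior degrees of freedom for shrinkage (default 10).
#' @return Named numeric vector of shrunken dispersions; the raw
#'   (unshrunken) estimates are in `attr(, "raw")` and the common value in
#'   `attr(, "common")`.
#' @export
estimate_dispersions <- function(x, sheet, norm = NULL, prior_df = 10) {
  check_sheet_matches(x, sheet)
  counts <- x$counts[, sheet$sample_id, drop = FALSE]
  groups <- split(seq_len(nrow(sheet)), sheet$group)
  if (any(lengths(groups) < 2))
    stop("each group needs at least 2 samples")
  lib <- effective_lib_sizes(x, norm)[sheet$sample_id]
  rel <- lib / mean(lib)
  z <- sweep(counts, 2, rel, "/")   # counts rescaled to the mean depth
  num <- 0; den <- 0
  for (idx in groups) {
    m <- rowMeans(z[, idx, drop = FALSE])
    v <- apply(z[, idx, drop = FALSE], 1, var)
    # E var(z) ~ mu * mean(1/rel) + phi * mu^2 within a group
    pois <- m * mean(1 / rel[idx])
    df <- length(idx) - 1
    num <- num + (v - pois) * df
    den <- den + df
  }
  m_all <- rowMeans(z)
  raw <- ifelse(m_all > 0, (num / den) / pmax(m_all, 1e-300)^2, 0)
  raw <- pmax(raw, 0)
  common <- median(raw[m_all > 0])
  if (!is.finite(common)) common <- 0
  group_df <- nrow(sheet) - length(groups)
  w <- prior_df / (prior_df + group_df)
  phi <- w * common + (1 - w) * raw
  structure(setNames(phi, rownames(counts)), raw = setNames(raw,
            rownames(counts)), common = common)
}

# Profile MLE of the per-unit-depth NB mean, jointly over all features.
# Model: y[f, s] ~ NB(mu_f * N[f, s], phi_f); solves the score equation
# sum_s y = mu * sum_s (phi*y + 1) * N / (1 + phi*mu*N) by fixed point.
fit_nb_mean <- function(y, offs, phi, iter = 200, tol = 1e-12) {
  tot <- rowSums(y)
  mu <- tot / rowSums(offs)
  phi <- pmax(phi, 0)
  active <- tot > 0 & phi > 0
  if (any(active)) {
    ya <- y[active, , drop = FALSE]
    oa <- offs[active, , drop = FALSE]
    pa <- phi[active]
    mua <- mu[active]
    ta <- tot[active]
    wa <- pa * ya + 1
    for (i in seq_len(iter)) {
      den <- 1 + pa * mua * oa
      mu_new <- ta / rowSums(wa * oa / den)
      delta <- max(abs(mu_new - mua) / pmax(mua, 1e-300))
      mua <- mu_new
      if (delta < tol) break
    }
    mu[active] <- mua
  }
  mu
}

nb_loglik <- function(y, mu_mat, phi) {
  ll <- numeric(nrow(y))
  pois <- phi < 1e-8
  if (any(pois)) {
    # Poisson limit; dpois handles lambda = 0 with y = 0 exactly
    ll[pois] <- rowSums(dpois(y[pois, , drop = FALSE],
                              lambda = mu_mat[pois, , drop = FALSE],
                              log = TRUE))
  }
  if (any(!pois)) {
    ll[!pois] <- rowSums(dnbinom(y[!pois, , drop = FALSE],
                                 size = 1 / phi[!pois],
                                 mu = mu_mat[!pois, , drop = FALSE],
                                 log = TRUE))
  }
  ll
}

#' Two-group negative-binomial likelihood-ratio test
#'
#' For each feature, the per-unit-depth mean is fitted by profile maximum
#' likelihood at the feature's fixed dispersion, once pooled and once per
#' group; twice the log-likelihood difference is referred to chi-squared with
#' 1 df. The reported `log2fc` is
#' `log2((mean tumour CPM + prior) / (mean normal CPM + prior))`, with the
#' prior count applied only in this ratio. `p_adj` is Benjamini-Hochberg
#' over tested features and directions follow [classify_de()].
#'
#' @param x A [count_matrix()].
#' @param sheet Sample sheet (exactly two groups, each with >= 2 samples).
#' @param norm Optional [norm_factors()].
#' @param dispersions Per-feature dispersions from [estimate_dispersions()]
#'   (recomputed when omitted).
#' @param cfg A [de_config()].
#' @param latent Optional sample-by-factor matrix from
#'   [estimate_latent_factors()]; its fitted per-feature contribution is
#'   absorbed into the log-mean offsets.
#' @return A [de_table()] with one row per feature, in matrix row order.
#' @export
nb_test <- function(x, sheet, norm = NULL, dispersions = NULL,
                    cfg = de_config(), latent = NULL) {
  check_sheet_matches(x, sheet)
  if (length(unique(sheet$group)) != 2)
    stop("exactly two groups are required")
  if (any(table(sheet$group) < 2))
    stop("each group needs at least 2 samples")
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(x, sheet, norm)
  y <- x$counts[, sheet$sample_id, drop = FALSE]
  lib <- effective_lib_sizes(x, norm)[sheet$sample_id]
  offs <- matrix(lib, nrow = nrow(y), ncol = ncol(y), byrow = TRUE)
  if (!is.null(latent) && NCOL(latent) > 0) {
    offs <- offs * 2^latent_log2_contribution(x, sheet, latent, norm)
  }
  phi <- as.numeric(dispersions[rownames(y)])
  tum <- which(sheet$group == "tumor")
  nor <- which(sheet$group == "normal")

  mu0 <- fit_nb_mean(y, offs, phi)
  mu1 <- fit_nb_mean(y[, tum, drop = FALSE], offs[, tum, drop = FALSE], phi)
  mu2 <- fit_nb_mean(y[, nor, drop = FALSE], offs[, nor, drop = FALSE], phi)
  ll0 <- nb_loglik(y, mu0 * offs, phi)
  ll1 <- nb_loglik(y[, tum, drop = FALSE],
                   mu1 * offs[, tum, drop = FALSE], phi)
  ll2 <- nb_loglik(y[, nor, drop = FALSE],
                   mu2 * offs[, nor, drop = FALSE], phi)
  stat <- pmax(0, 2 * (ll1 + ll2 - ll0))
  p_raw <- pchisq(stat, df = 1, lower.tail = FALSE)
  allzero <- rowSums(y) == 0
  p_raw[allzero] <- 1

  cp <- sweep(y, 2, lib, "/") * 1e6
  mt <- rowMeans(cp[, tum, drop = FALSE])
  mn <- rowMeans(cp[, nor, drop = FALSE])
  log2fc <- log2((mt + cfg$prior_count) / (mn + cfg$prior_count))
  tab <- de_table(data.frame(feature_id = rownames(y), log2fc = log2fc,
                             p_raw = p_raw, p_adj = bh_adjust(p_raw),
                             stringsAsFactors = FALSE))
  classify_de(tab, cfg)
}

#' Classify DE records into up / down / not-significant
#'
#' `up` iff `log2fc > t_lfc`, `p_raw < t_p` and `p_adj < t_fdr`; `down`
#' symmetric with `log2fc < -t_lfc`; otherwise `ns`. The returned table
#' carries `n_up` and `n_down` attributes.
#'
#' @param tab A [de_table()].
#' @param cfg A [de_config()].
#' @return The table with `direction` recomputed.
#' @export
classify_de <- function(tab, cfg = de_config()) {
  stopifnot(inherits(tab, "de_table"))
  sig <- tab$p_raw < cfg$t_p & tab$p_adj < cfg$t_fdr
  dir <- ifelse(sig & tab$log2fc > cfg$t_lfc, "up",
                ifelse(sig & tab$log2fc < -cfg$t_lfc, "down", "ns"))
  tab$direction <- dir
  attr(tab, "n_up") <- sum(dir == "up")
  attr(tab, "n_down") <- sum(dir == "down")
  tab
}

latent_log2_contribution <- function(x, sheet, latent, norm = NULL) {
  v <- as.matrix(latent)
  stopifnot(nrow(v) == nrow(sheet))
  lc <- log2(cpm_matrix(x, norm)[, sheet$sample_id, drop = FALSE] + 1)
  for (g in unique(sheet$group)) {
    idx <- which(sheet$group == g)
    lc[, idx] <- lc[, idx] - rowMeans(lc[, idx, drop = FALSE])
  }
  beta <- lc %*% v %*% solve(crossprod(v))
  beta %*% t(v)
}

#' Latent expression factors by residual SVD
#'
#' Estimates hidden sample-level factors (batch, processing artefacts) from
#' the SVD of group-mean-centred `log2(CPM + 1)`, preserving the group
#' contrast of interest. When `k` is `NULL`, the number of factors is chosen
#' by parallel analysis: each residual row is permuted independently
#' `n_perm` times and a leading singular value is kept while it exceeds the
#' 95th percentile of its permuted counterparts.
#'
#' @param x A [count_matrix()] with at least 4 samples.
#' @param sheet Sample sheet for the matrix.
#' @param k Number of factors; `NULL` for automatic selection.
#' @param n_perm Number of row-wise permutations for the automatic choice.
#' @param seed Optional RNG seed for the permutations.
#' @return A samples-by-k matrix of factor scores (0 columns when `k = 0`),
#'   rows ordered as `sheet$sample_id`.
#' @export
estimate_latent_factors <- function(x, sheet, k = NULL, n_perm = 20,
                                    seed = NULL) {
  check_sheet_matches(x, sheet)
  n <- nrow(sheet)
  if (n < 4) stop("latent factor estimation needs at least 4 samples")
  if (!is.null(k) && k >= n - 2)
    stop("k must be smaller than n_samples - 2")
  # group-mean centring removes the contrast of interest; column centring
  # removes per-sample depth offsets, which the NB model already absorbs
  # through its library-size offsets and which would otherwise always
  # surface as a spurious leading factor
  center <- function(m) {
    for (g in unique(sheet$group)) {
      idx <- which(sheet$group == g)
      m[, idx] <- m[, idx] - rowMeans(m[, idx, drop = FALSE])
    }
    sweep(m, 2, colMeans(m))
  }
  lc <- center(log2(cpm_matrix(x)[, sheet$sample_id, drop = FALSE] + 1))
  sv <- svd(lc)
  if (is.null(k)) {
    if (!is.null(seed)) set.seed(seed)
    nd <- length(sv$d)
    # compare variance proportions, not raw singular values: row-wise
    # shuffling plus re-centring changes total variance slightly, and
    # proportions are invariant to that
    obs <- sv$d^2 / sum(sv$d^2)
    perm_d <- matrix(0, n_perm, nd)
    for (b in seq_len(n_perm)) {
      shuf <- center(t(apply(lc, 1, sample)))
      d2 <- svd(shuf, nu = 0, nv = 0)$d^2
      perm_d[b, ] <- d2 / sum(d2)
    }
    thresh <- apply(perm_d, 2, quantile, probs = 0.95)
    exceeds <- obs > thresh
    k <- if (exceeds[1]) rle(exceeds)$lengths[1] else 0
    k <- min(k, n - 3)
  }
  if (k == 0)
    return(matrix(numeric(0), nrow = n, ncol = 0,
                  dimnames = list(sheet$sample_id, NULL)))
  out <- sv$v[, seq_len(k), drop = FALSE]
  rownames(out) <- sheet$sample_id
  out
}

#' Run the full differential-expression stage
#'
#' Convenience wrapper: low-expression filtering (by default only for miRNA
#' matrices, matching the usual small-RNA practice), TMM normalization,
#' optional latent factors, dispersion estimation, the NB likelihood-ratio
#' test and threshold classification.
#'
#' @param x A [count_matrix()].
#' @param sheet Sample sheet.
#' @param cfg A [de_config()].
#' @param filter Apply the CPM filter? Default: `TRUE` for miRNA matrices,
#'   `FALSE` for mRNA.
#' @param seed Seed forwarded to the latent-factor permutations.
#' @return A classified [de_table()].
#' @export
run_de <- function(x, sheet, cfg = de_config(),
                   filter = x$feature_class == "mirna", seed = NULL) {
  sheet <- as_sample_sheet(as.data.frame(sheet))
  sheet <- sheet[sheet$sample_id %in% colnames(x$counts), , drop = FALSE]
  if (filter) x <- filter_low_expression(x, cfg)
  if (nrow(x$counts) == 0)
    return(classify_de(de_table(data.frame(feature_id = character(0),
                                           log2fc = numeric(0),
                                           p_raw = numeric(0),
                                           p_adj = numeric(0))), cfg))
  nf <- norm_factors(x)
  latent <- NULL
  if (!is.null(cfg$n_latent)) {
    k <- if (identical(cfg$n_latent, "auto")) NULL else as.integer(cfg$n_latent)
    latent <- estimate_latent_factors(x, sheet, k = k, seed = seed)
    if (ncol(latent) == 0) latent <- NULL
  }
  disp <- estimate_dispersions(x, sheet, nf)
  nb_test(x, sheet, nf, disp, cfg, latent = latent)
}
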