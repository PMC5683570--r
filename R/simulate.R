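#' Simulation configuration
#'
#' Defines the study conditions for the coupled miRNA/mRNA count simulator:
#' a two-group negative-binomial design mirroring a small-RNA arm of 17
#' tumours vs 4 normals (the mRNA arm of the emulated design, 28 vs 5, is
#' available via `preset = "mrna_arm"`), planted up-regulated driver miRNAs
#' whose validated targets are repressed in tumours, independently planted
#' DE genes and down-regulated miRNAs at |log2FC| = 3, and an optional batch
#' factor.
#'
#' @param n_genes,n_tfs,n_mirnas Network sizes (TFs are drawn from the
#'   genes).
#' @param targets_per_mirna,genes_per_tf Out-degrees of miRNA and TF nodes.
#' @param n_tumor,n_normal Group sizes (defaults 17 and 4).
#' @param n_drivers Number of up-regulated driver miRNAs (default 5).
#' @param n_down_mirnas Number of planted down-regulated miRNAs (default 5).
#' @param lfc_mirna Planted miRNA |log2FC| (default 3).
#' @param repression_lfc Per-driver log2 knockdown of each target in
#'   tumours (default -1.5); summed over a gene's up-regulated drivers and
#'   capped at `repression_cap`.
#' @param repression_cap Most extreme total repression (default -4).
#' @param frac_de_genes Fraction of genes planted as independently DE
#'   (default 0.1) at `lfc_gene`.
#' @param lfc_gene Planted |log2FC| of independent DE genes (default 3).
#' @param dispersion NB dispersion phi (default 0.2); 0 gives Poisson.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline expression
#'   (natural-log scale).
#' @param activity_sd SD of the unitless per-sample driver-activity
#'   deviation (default 0.3). Each driver's effective activity in sample `s`
#'   is `is_tumor(s) + z[d, s]` with `z ~ N(0, activity_sd)`; the driver's
#'   own log2 shift is `lfc_mirna` times this activity and each target's is
#'   its (capped) total repression times the mean activity of its drivers,
#'   so the coupling magnitude is tied to `repression_lfc` and planted pairs
#'   anti-correlate within groups as well as across them.
#' @param batch_shift Optional log2 batch shift applied to a random 30% of
#'   features in half of the samples; `NULL` for no batch.
#' @param lib_mirna,lib_mrna Nominal library sizes of the two assays.
#' @param lib_sdlog Log-normal spread of library sizes.
#' @param preset `"mirna_arm"` (17 vs 4, default) or `"mrna_arm"`
#'   (28 vs 5).
#' @param seed RNG seed; the whole simulation is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 300, n_tfs = 30, n_mirnas = 30,
                       targets_per_mirna = 8, genes_per_tf = 8,
                       n_tumor = 17, n_normal = 4,
                       n_drivers = 5, n_down_mirnas = 5,
                       lfc_mirna = 3, repression_lfc = -1.5,
                       repression_cap = -4, frac_de_genes = 0.1,
                       lfc_gene = 3, dispersion = 0.2,
                       baseline_meanlog = log(50), baseline_sdlog = 1.5,
                       activity_sd = 0.3, batch_shift = NULL,
                       lib_mirna = 1e6, lib_mrna = 2e7, lib_sdlog = 0.3,
                       preset = c("mirna_arm", "mrna_arm"), seed = 1) {
  preset <- match.arg(preset)
  if (preset == "mrna_arm") { n_tumor <- 28; n_normal <- 5 }
  stopifnot(n_tumor >= 2, n_normal >= 2,
            targets_per_mirna <= n_genes, genes_per_tf <= n_genes - 1,
            n_drivers + n_down_mirnas <= n_mirnas,
            dispersion >= 0, frac_de_genes >= 0, frac_de_genes <= 1)
  seed <- as.integer(seed)
  stopifnot(seed >= 0, seed < 2^31 - 10)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a miRNA/TF regulatory network
#'
#' Each miRNA receives `targets_per_mirna` distinct gene targets drawn
#' uniformly at random; each TF (a gene) receives `genes_per_tf` out-edges
#' to distinct other genes. Deterministic for a fixed config seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `edges` (an [edge_list()]), `genes`, `tfs`, `mirnas`.
#' @export
simulate_network <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  mirnas <- sprintf("miR-%03d", seq_len(cfg$n_mirnas))
  tfs <- sort(sample(genes, cfg$n_tfs))
  mt <- do.call(rbind, lapply(mirnas, function(m)
    data.frame(source = m, target = sample(genes, cfg$targets_per_mirna),
               edge_type = "mirna_target", stringsAsFactors = FALSE)))
  tf <- do.call(rbind, lapply(tfs, function(f)
    data.frame(source = f,
               target = sample(setdiff(genes, f), cfg$genes_per_tf),
               edge_type = "tf_gene", stringsAsFactors = FALSE)))
  list(edges = edge_list(rbind(mt, tf)), genes = genes, tfs = tfs,
       mirnas = mirnas)
}

#' Simulate coupled miRNA and mRNA count matrices
#'
#' Baseline per-feature means are log-normal. Driver miRNAs are up-regulated
#' by `lfc_mirna` log2 units in tumours and their targets knocked down by
#' the (capped) sum of `repression_lfc` over the gene's drivers; a latent
#' per-sample driver-activity variable scales each driver up and its targets
#' down within every sample, so planted pairs are negatively correlated
#' across samples, not merely across groups. Independent DE genes and
#' down-regulated miRNAs are planted on top, counts are drawn from a
#' negative binomial at each assay's log-normal library depth, and an
#' optional batch shifts a random 30% of features in half of the samples.
#' Fully reproducible from the config seed.
#'
#' @param cfg A [sim_config()].
#' @param network Optional [simulate_network()] result (re-simulated from
#'   `cfg` when omitted).
#' @return List with `mirna` and `mrna` [count_matrix()] objects, `sheet`
#'   (sample sheet shared by both assays), `truth` (ground truth, class
#'   `sim_truth`) and `network`.
#' @export
simulate_counts <- function(cfg, network = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(network)) network <- simulate_network(cfg)
  set.seed(cfg$seed + 1L)
  genes <- network$genes
  mirnas <- network$mirnas
  n_s <- cfg$n_tumor + cfg$n_normal
  samples <- c(sprintf("T%02d", seq_len(cfg$n_tumor)),
               sprintf("N%02d", seq_len(cfg$n_normal)))
  is_tumor <- c(rep(1, cfg$n_tumor), rep(0, cfg$n_normal))

  drivers <- sort(sample(mirnas, cfg$n_drivers))
  down_mirnas <- sort(sample(setdiff(mirnas, drivers), cfg$n_down_mirnas))
  target_map <- lapply(split(
    network$edges$target[network$edges$edge_type == "mirna_target"],
    network$edges$source[network$edges$edge_type == "mirna_target"]),
    unique)
  driver_targets <- sort(unique(unlist(target_map[drivers])))
  n_de <- round(cfg$frac_de_genes * cfg$n_genes)
  de_pool <- setdiff(genes, driver_targets)
  de_genes <- sort(sample(de_pool, min(n_de, length(de_pool))))
  de_sign <- sample(c(-1, 1), length(de_genes), replace = TRUE)

  # planted log2FC per feature
  lfc_m <- setNames(numeric(length(mirnas)), mirnas)
  lfc_m[drivers] <- cfg$lfc_mirna
  lfc_m[down_mirnas] <- -cfg$lfc_mirna
  lfc_g <- setNames(numeric(length(genes)), genes)
  lfc_g[de_genes] <- de_sign * cfg$lfc_gene
  rep_g <- setNames(numeric(length(genes)), genes)
  for (d in drivers)
    rep_g[target_map[[d]]] <- rep_g[target_map[[d]]] + cfg$repression_lfc
  rep_g <- pmax(rep_g, cfg$repression_cap)

  # per-sample driver activity couples each driver to its targets: activity
  # is is_tumor + z, so the coupling magnitude scales with the planted lfc's
  z <- matrix(rnorm(length(drivers) * n_s, sd = cfg$activity_sd),
              nrow = length(drivers), ncol = n_s,
              dimnames = list(drivers, samples))
  shift_m <- outer(unname(lfc_m), is_tumor)
  dimnames(shift_m) <- list(mirnas, samples)
  if (length(drivers) > 0)
    shift_m[drivers, ] <- cfg$lfc_mirna *
      (matrix(is_tumor, length(drivers), n_s, byrow = TRUE) + z)
  shift_g <- outer(unname(lfc_g), is_tumor)
  dimnames(shift_g) <- list(genes, samples)
  for (g in driver_targets) {
    dg <- drivers[vapply(drivers, function(d) g %in% target_map[[d]],
                         logical(1))]
    zbar <- colMeans(z[dg, , drop = FALSE])
    shift_g[g, ] <- shift_g[g, ] + rep_g[g] * (is_tumor + zbar)
  }
  lfc_g <- lfc_g + rep_g   # group-level total, recorded as ground truth

  base_m <- exp(rnorm(length(mirnas), cfg$baseline_meanlog,
                      cfg$baseline_sdlog))
  base_g <- exp(rnorm(length(genes), cfg$baseline_meanlog,
                      cfg$baseline_sdlog))
  mu_m <- base_m * 2^shift_m
  mu_g <- base_g * 2^shift_g

  batch <- rep(NA_character_, n_s)
  batch_feat <- list(mirna = character(0), mrna = character(0))
  if (!is.null(cfg$batch_shift)) {
    batch <- ifelse(seq_len(n_s) %% 2 == 1, "A", "B")
    bm <- sample(mirnas, round(0.3 * length(mirnas)))
    bg <- sample(genes, round(0.3 * length(genes)))
    shift <- 2^cfg$batch_shift
    mu_m[bm, batch == "B"] <- mu_m[bm, batch == "B", drop = FALSE] * shift
    mu_g[bg, batch == "B"] <- mu_g[bg, batch == "B", drop = FALSE] * shift
    batch_feat <- list(mirna = sort(bm), mrna = sort(bg))
  }

  lib_m <- exp(rnorm(n_s, log(cfg$lib_mirna), cfg$lib_sdlog))
  lib_g <- exp(rnorm(n_s, log(cfg$lib_mrna), cfg$lib_sdlog))
  depth_m <- lib_m / cfg$lib_mirna
  depth_g <- lib_g / cfg$lib_mrna

  draw <- function(mu, phi) {
    n <- length(mu)
    if (phi == 0) matrix(rpois(n, mu), nrow = nrow(mu),
                         dimnames = dimnames(mu))
    else matrix(rnbinom(n, size = 1 / phi, mu = mu), nrow = nrow(mu),
                dimnames = dimnames(mu))
  }
  counts_m <- draw(sweep(mu_m, 2, depth_m, "*"), cfg$dispersion)
  counts_g <- draw(sweep(mu_g, 2, depth_g, "*"), cfg$dispersion)

  sheet <- as_sample_sheet(data.frame(
    sample_id = samples,
    group = ifelse(is_tumor == 1, "tumor", "normal"),
    batch = batch, stringsAsFactors = FALSE))
  pairs <- do.call(rbind, lapply(drivers, function(d)
    data.frame(mirna_id = d, gene_id = sort(target_map[[d]]),
               stringsAsFactors = FALSE)))
  if (is.null(pairs))
    pairs <- data.frame(mirna_id = character(0), gene_id = character(0),
                        stringsAsFactors = FALSE)
  truth <- structure(list(
    mirnas = data.frame(mirna_id = mirnas, log2fc = unname(lfc_m),
                        driver = mirnas %in% drivers,
                        stringsAsFactors = FALSE),
    genes = data.frame(gene_id = genes, log2fc = unname(lfc_g),
                       stringsAsFactors = FALSE),
    pairs = pairs,
    batch = data.frame(sample_id = samples, batch = batch,
                       stringsAsFactors = FALSE)), class = "sim_truth")
  list(mirna = count_matrix(counts_m, "mirna"),
       mrna = count_matrix(counts_g, "mrna"),
       sheet = sheet, truth = truth, network = network)
}

#' Write or read simulation ground truth
#'
#' Serialized as a single long-format TSV with columns `record_type`
#' (`mirna`, `gene`, `pair`, `batch`), `id1`, `id2` and `value`;
#' `write_truth()` then `read_truth()` reproduces the object.
#'
#' @param truth A `sim_truth` object.
#' @param path TSV path.
#' @return `path` invisibly (write); a `sim_truth` (read).
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  rec <- function(type, id1, id2, value)
    data.frame(record_type = rep(type, length(id1)), id1 = id1,
               id2 = id2, value = value, stringsAsFactors = FALSE)
  rows <- rbind(
    rec("mirna", truth$mirnas$mirna_id,
        ifelse(truth$mirnas$driver, "driver", ""), truth$mirnas$log2fc),
    rec("gene", truth$genes$gene_id, rep("", nrow(truth$genes)),
        truth$genes$log2fc),
    rec("pair", truth$pairs$mirna_id, truth$pairs$gene_id,
        rep(NA_real_, nrow(truth$pairs))),
    rec("batch", truth$batch$sample_id,
        ifelse(is.na(truth$batch$batch), "", truth$batch$batch),
        rep(NA_real_, nrow(truth$batch))))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   na.strings = "NA")
  df$id2[is.na(df$id2)] <- ""
  pick <- function(type) df[df$record_type == type, , drop = FALSE]
  m <- pick("mirna"); g <- pick("gene"); p <- pick("pair"); b <- pick("batch")
  structure(list(
    mirnas = data.frame(mirna_id = m$id1, log2fc = m$value,
                        driver = m$id2 == "driver", stringsAsFactors = FALSE),
    genes = data.frame(gene_id = g$id1, log2fc = g$value,
                       stringsAsFactors = FALSE),
    pairs = data.frame(mirna_id = p$id1, gene_id = p$id2,
                       stringsAsFactors = FALSE),
    batch = data.frame(sample_id = b$id1,
                       batch = ifelse(b$id2 == "", NA_character_, b$id2),
                       stringsAsFactors = FALSE)), class = "sim_truth")
}
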