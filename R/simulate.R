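## Synthetic two-channel BeadArray intensity generator with ground truth.
##
## Each SNP's three genotype clusters are placed by (contrast, total
## intensity) geometry: a genotype with contrast y and total intensity T
## has channel means r = T (1 + y) / 2, g = T (1 - y) / 2. Per-channel
## Gaussian noise is added and intensities are truncated at zero. A small
## fraction of samples is replaced by uniform draws over the intensity
## bounding box, emulating abnormal ("null-component") measurements that
## the posterior-rate no-call rule must reject.

#' Specification of one simulated SNP
#'
#' @param maf minor allele frequency in \[0, 0.5\]; genotypes are drawn
#'   from the HWE frequencies `((1-q)^2, 2q(1-q), q^2)`.
#' @param n number of samples.
#' @param contrasts per-genotype mean contrast (AA, AB, BB).
#' @param total_intensity cluster total intensity (r + g scale).
#' @param noise_sd per-channel Gaussian noise standard deviation; the
#'   default 188 puts adjacent genotype clusters about six channel
#'   standard deviations apart under the default geometry.
#' @param outlier_frac expected fraction of samples replaced by abnormal
#'   uniform intensities.
#' @param counts optional explicit genotype counts `c(AA, AB, BB)` summing
#'   to `n`; overrides HWE sampling (used to pin rare-SNP regimes).
#' @return list of class `snp_sim_spec`.
#' @export
snp_sim_spec <- function(maf = 0.3, n = 300L,
                         contrasts = c(AA = 0.8, AB = 0, BB = -0.8),
                         total_intensity = 2000, noise_sd = 188,
                         outlier_frac = 0.01, counts = NULL) {
  stopifnot(maf >= 0, maf <= 0.5, n >= 1,
            length(contrasts) == 3, total_intensity > 0, noise_sd >= 0,
            outlier_frac >= 0, outlier_frac < 1)
  if (!is.null(counts)) {
    stopifnot(length(counts) == 3, sum(counts) == n, all(counts >= 0))
    counts <- as.integer(counts)
  }
  structure(list(maf = maf, n = as.integer(n), contrasts = contrasts,
                 total_intensity = total_intensity, noise_sd = noise_sd,
                 outlier_frac = outlier_frac, counts = counts),
            class = "snp_sim_spec")
}

#' Simulate one SNP's intensities with truth
#'
#' Genotypes are drawn multinomially from HWE frequencies at the spec's
#' MAF (or fixed at the spec's explicit counts); intensities are the
#' genotype cluster mean plus bivariate per-channel Gaussian noise,
#' truncated at zero; a binomial `outlier_frac` subset is replaced by
#' uniform draws over `[0, 1.2 * total_intensity]` per channel and
#' flagged.
#'
#' @param spec a [snp_sim_spec()].
#' @param seed integer seed.
#' @return list with `x` (n x 2 matrix, columns r, g), `truth` (data.frame
#'   `sample`, `genotype`, `outlier`), `spec`.
#' @export
simulate_snp <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "snp_sim_spec"))
  set.seed(seed)
  q <- spec$maf
  n <- spec$n
  if (is.null(spec$counts)) {
    geno <- sample(c("AA", "AB", "BB"), n, replace = TRUE,
                   prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
  } else {
    geno <- sample(rep(c("AA", "AB", "BB"), times = spec$counts))
  }
  y <- spec$contrasts[match(geno, c("AA", "AB", "BB"))]
  mu_r <- spec$total_intensity * (1 + y) / 2
  mu_g <- spec$total_intensity * (1 - y) / 2
  r <- stats::rnorm(n, mu_r, spec$noise_sd)
  g <- stats::rnorm(n, mu_g, spec$noise_sd)
  outlier <- stats::runif(n) < spec$outlier_frac
  if (any(outlier)) {
    box <- 1.2 * spec$total_intensity
    r[outlier] <- stats::runif(sum(outlier), 0, box)
    g[outlier] <- stats::runif(sum(outlier), 0, box)
  }
  x <- cbind(r = pmax(r, 0), g = pmax(g, 0))
  samples <- sprintf("S%04d", seq_len(n))
  rownames(x) <- samples
  list(x = x,
       truth = data.frame(sample = samples, genotype = unname(geno),
                          outlier = outlier, stringsAsFactors = FALSE),
       spec = spec)
}

#' Simulate a multi-SNP panel
#'
#' SNP order equals spec order, which defines the "before the T-SNP"
#' structure of the reference search; place common SNPs ahead of rare ones
#' so extremely rare SNPs have reference candidates. All specs must share
#' the same `n`.
#'
#' @param specs named list of [snp_sim_spec()] (names become SNP ids;
#'   unnamed specs get `SNP0001`...).
#' @param populations optional named character vector sample -> population,
#'   or a single integer to split samples evenly into that many
#'   populations.
#' @param seed integer seed; per-SNP seeds are derived from it.
#' @return list with `dataset` (an [intensity_dataset()]) and `truth`
#'   (data.frame `snp`, `sample`, `genotype`, `outlier`).
#' @export
simulate_panel <- function(specs, populations = NULL, seed = 1L) {
  stopifnot(length(specs) >= 1)
  ns <- vapply(specs, `[[`, integer(1), "n")
  if (length(unique(ns)) != 1L)
    stop("all specs must share the same sample count n")
  n <- ns[[1]]
  ids <- names(specs)
  if (is.null(ids)) ids <- sprintf("SNP%04d", seq_along(specs))
  ids[ids == ""] <- sprintf("SNP%04d", which(ids == ""))
  samples <- sprintf("S%04d", seq_len(n))
  pops <- NULL
  if (!is.null(populations)) {
    if (length(populations) == 1L && is.numeric(populations)) {
      k <- as.integer(populations)
      pops <- stats::setNames(sprintf("POP%d", ((seq_len(n) - 1L) %% k) + 1L),
                              samples)
    } else pops <- populations
  }
  rows <- vector("list", length(specs))
  truths <- vector("list", length(specs))
  for (j in seq_along(specs)) {
    sim <- simulate_snp(specs[[j]], seed = derive_seed(seed, j, 9L))
    rows[[j]] <- data.frame(snp = ids[j], sample = samples,
                            r = sim$x[, 1], g = sim$x[, 2],
                            stringsAsFactors = FALSE)
    truths[[j]] <- data.frame(snp = ids[j], sample = samples,
                              genotype = sim$truth$genotype,
                              outlier = sim$truth$outlier,
                              stringsAsFactors = FALSE)
  }
  ds <- intensity_dataset(do.call(rbind, rows), populations = pops,
                          snp_order = ids)
  list(dataset = ds, truth = rownames_reset(do.call(rbind, truths)))
}

#' Rare-SNP fixtures by routing regime
#'
#' Builds one SNP pinned to a rare-variant regime: `g2-like` draws a minor
#' homozygote cluster of size in \[3, 10), `g3-like` of size in \[0, 3)
#' (with about ten heterozygotes so the SNP still routes to g3), and
#' `monomorphic` a single cluster. Truth carries the realized counts.
#'
#' @param kind `"g2-like"`, `"g3-like"` or `"monomorphic"`.
#' @param seed integer seed.
#' @param n number of samples.
#' @param minor_count optional fixed minor-homozygote cluster size.
#' @param het_count optional fixed heterozygote cluster size.
#' @param outlier_frac abnormal-sample fraction, default 0 for fixtures.
#' @param noise_sd per-channel noise sd.
#' @return as [simulate_snp()].
#' @export
make_rare_snp_fixture <- function(kind = c("g2-like", "g3-like", "monomorphic"),
                                  seed = 1L, n = 300L, minor_count = NULL,
                                  het_count = NULL, outlier_frac = 0,
                                  noise_sd = 188) {
  kind <- match.arg(kind)
  set.seed(seed + 1e6)
  if (kind == "monomorphic") {
    counts <- c(n, 0L, 0L)
  } else if (kind == "g2-like") {
    m <- if (is.null(minor_count)) sample(3:9, 1) else minor_count
    h <- if (is.null(het_count))
      sample(0:max(0, min(11, floor(0.1 * n) - 2 * m - 1)), 1) else het_count
    counts <- c(n - m - h, h, m)
  } else {
    m <- if (is.null(minor_count)) sample(0:2, 1) else minor_count
    h <- if (is.null(het_count)) sample(10:12, 1) else het_count
    counts <- c(n - m - h, h, m)
  }
  maf <- (2 * counts[3] + counts[2]) / (2 * n)
  spec <- snp_sim_spec(maf = maf, n = n, counts = counts,
                       outlier_frac = outlier_frac, noise_sd = noise_sd)
  simulate_snp(spec, seed = seed)
}

#' Write a simulated panel to TSV files
#'
#' Emits the standard long-form intensity TSV (with a `Population` column
#' when labels exist), a truth TSV, and returns the paths.
#'
#' @param panel a [simulate_panel()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- panel$dataset
  df <- data.frame(SNP = ds$data$snp, Sample = ds$data$sample,
                   r = ds$data$r, g = ds$data$g, stringsAsFactors = FALSE)
  if (!is.null(ds$populations))
    df$Population <- unname(ds$populations[df$Sample])
  ipath <- file.path(dir, "intensities.tsv")
  utils::write.table(df, ipath, sep = "\t", quote = FALSE, row.names = FALSE)
  tpath <- file.path(dir, "truth.tsv")
  utils::write.table(
    data.frame(SNP = panel$truth$snp, Sample = panel$truth$sample,
               Genotype = panel$truth$genotype, Outlier = panel$truth$outlier),
    tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  c(intensities = ipath, truth = tpath)
}

#' Read a truth TSV written by [write_panel()]
#'
#' @param path file path.
#' @return data.frame with `snp`, `sample`, `genotype`, `outlier`.
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  data.frame(snp = df$SNP, sample = df$Sample, genotype = df$Genotype,
             outlier = as.logical(df$Outlier), stringsAsFactors = FALSE)
}

#' Spec list for a mixed-MAF study panel
#'
#' Convenience builder for the validation panel used throughout the
#' package: `n_common` common SNPs (MAF drawn uniformly in
#' `common_maf_range`) placed first, then `n_g2` rare SNPs pinned to the
#' g2 regime and `n_g3` extremely rare SNPs pinned to the g3 regime.
#'
#' @param n_common,n_g2,n_g3 SNP counts per regime.
#' @param n samples per SNP.
#' @param common_maf_range range of common-SNP MAFs.
#' @param outlier_frac abnormal-sample fraction.
#' @param noise_sd per-channel noise sd.
#' @param seed integer seed (for the MAF draw and regime counts).
#' @return named list of [snp_sim_spec()] suitable for [simulate_panel()].
#' @export
study_panel_specs <- function(n_common = 70L, n_g2 = 20L, n_g3 = 10L,
                              n = 300L, common_maf_range = c(0.2, 0.4),
                              outlier_frac = 0.01, noise_sd = 188,
                              seed = 1L) {
  set.seed(seed)
  specs <- list()
  for (j in seq_len(n_common)) {
    maf <- stats::runif(1, common_maf_range[1], common_maf_range[2])
    specs[[sprintf("COMMON%03d", j)]] <-
      snp_sim_spec(maf = maf, n = n, outlier_frac = outlier_frac,
                   noise_sd = noise_sd)
  }
  for (j in seq_len(n_g2)) {
    m <- sample(3:9, 1)
    h <- sample(0:5, 1)
    specs[[sprintf("RARE_G2_%03d", j)]] <-
      snp_sim_spec(maf = (2 * m + h) / (2 * n), n = n,
                   counts = c(n - m - h, h, m),
                   outlier_frac = outlier_frac, noise_sd = noise_sd)
  }
  for (j in seq_len(n_g3)) {
    m <- sample(0:2, 1)
    h <- sample(10:12, 1)
    specs[[sprintf("RARE_G3_%03d", j)]] <-
      snp_sim_spec(maf = (2 * m + h) / (2 * n), n = n,
                   counts = c(n - m - h, h, m),
                   outlier_frac = outlier_frac, noise_sd = noise_sd)
  }
  specs
}
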