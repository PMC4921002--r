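## Model III: reference-SNP selection for extremely rare SNPs.
##
## A hard-to-call rare SNP (the T-SNP) borrows strength from a good-quality
## common SNP (the R-SNP) chosen in three steps: (I) predecessors with
## MAF > 0.15; (II) of those, SNPs whose rough contrast clustering puts at
## least 10% of observations in each genotype cluster; (III) the candidate
## minimizing a pooled-covariance Mahalanobis cluster distance to the
## T-SNP. The T-SNP's intensities are then stacked with the R-SNP's and the
## DP mixture is fitted to the augmented data, so the reference's
## well-populated clusters anchor the T-SNP's sparse ones.

#' Rough clustering by contrast cutoffs
#'
#' Assigns each sample a provisional genotype from its contrast alone:
#' `y >= 0.5 -> AA`, `-0.5 <= y < 0.5 -> AB`, `y < -0.5 -> BB`. Per-cluster
#' means and (ridge-regularized) covariances are attached; singleton or
#' empty clusters get a small isotropic covariance at the data scale.
#' Points with zero total intensity have no contrast and are excluded.
#'
#' @param x n x 2 intensity matrix.
#' @return object of class `rough_clustering`: `labels` (per retained
#'   sample), `keep` (logical, contrast computable), `stats` (per-genotype
#'   list of `x` member rows, `mu`, `sigma`, `count`), `prop` (cluster
#'   proportions over labeled samples).
#' @export
rough_cluster_by_contrast <- function(x) {
  x <- as.matrix(x)
  y <- contrast_or_na(x[, 1], x[, 2])
  keep <- !is.na(y)
  xk <- x[keep, , drop = FALSE]
  yk <- y[keep]
  labels <- ifelse(yk >= 0.5, "AA", ifelse(yk < -0.5, "BB", "AB"))
  scale_var <- max(stats::var(as.numeric(xk)), 1e-8)
  stats_ <- lapply(c(AA = "AA", AB = "AB", BB = "BB"), function(g) {
    rows <- xk[labels == g, , drop = FALSE]
    nG <- nrow(rows)
    mu <- if (nG > 0) colMeans(rows) else c(NA_real_, NA_real_)
    sigma <- if (nG > 1) regularize_cov(stats::cov(rows), 1e-6)
             else diag(1e-6 * scale_var, 2)
    list(x = rows, mu = mu, sigma = sigma, count = nG)
  })
  n_lab <- length(yk)
  prop <- if (n_lab > 0)
    vapply(stats_, function(s) s$count / n_lab, numeric(1)) else
    stats::setNames(rep(NA_real_, 3), c("AA", "AB", "BB"))
  structure(list(labels = labels, keep = keep, stats = stats_, prop = prop),
            class = "rough_clustering")
}

#' Step I: high-MAF predecessor candidates
#'
#' SNPs strictly before the T-SNP in dataset order with MAF above the
#' threshold (exclusive, `maf > ref_maf`), capped at the `max_candidates`
#' nearest predecessors.
#'
#' @param ds an [intensity_dataset()].
#' @param t_index position of the T-SNP in `ds$snp_ids`.
#' @param maf named numeric vector of per-SNP MAF estimates (from the
#'   initial EM pass).
#' @param ref_maf MAF threshold, default 0.15.
#' @param max_candidates cap, default 200.
#' @return character vector of candidate SNP ids, nearest first; empty if
#'   no predecessor qualifies (reference unavailable).
#' @export
select_r1 <- function(ds, t_index, maf, ref_maf = 0.15, max_candidates = 200L) {
  stopifnot(inherits(ds, "intensity_dataset"),
            t_index >= 1, t_index <= length(ds$snp_ids))
  before <- ds$snp_ids[seq_len(t_index - 1L)]
  if (length(before) == 0L) return(character(0))
  ok <- before[!is.na(maf[before]) & maf[before] > ref_maf]
  utils::head(rev(ok), max_candidates)  # nearest predecessors first
}

#' Step II: well-clustered candidates
#'
#' Keeps candidates whose rough contrast clustering places at least
#' `min_prop` (inclusive) of labeled observations in *each* of the three
#' genotype clusters.
#'
#' @param r1 character vector of step-I candidate ids.
#' @param ds an [intensity_dataset()].
#' @param min_prop per-cluster proportion floor, default 0.10.
#' @return named list (by SNP id) of `rough_clustering` objects for the
#'   retained candidates; empty list if none qualify.
#' @export
select_r2 <- function(r1, ds, min_prop = 0.10) {
  out <- list()
  for (id in r1) {
    rc <- rough_cluster_by_contrast(snp_intensities(ds, id))
    if (all(!is.na(rc$prop)) && all(rc$prop >= min_prop)) out[[id]] <- rc
  }
  out
}

#' Cluster distance between a T-SNP and a reference candidate
#'
#' For each genotype cluster k, every member row of the T-SNP's rough
#' cluster is centered at the candidate's cluster mean and the quadratic
#' form under the pooled covariance `(Sigma_kt + Sigma_kd) / 2` is summed
#' (the trace of the stacked quadratic form). Clusters empty in the T-SNP
#' contribute zero, so rare SNPs missing clusters are still ranked by the
#' clusters they have.
#'
#' @param t_clust `rough_clustering` of the T-SNP.
#' @param cand `rough_clustering` of the candidate.
#' @return non-negative scalar distance.
#' @export
cluster_distance <- function(t_clust, cand) {
  stopifnot(inherits(t_clust, "rough_clustering"),
            inherits(cand, "rough_clustering"))
  d <- 0
  for (g in c("AA", "AB", "BB")) {
    st <- t_clust$stats[[g]]
    sd_ <- cand$stats[[g]]
    if (st$count == 0L) next
    if (sd_$count == 0L || anyNA(sd_$mu))
      stop("candidate lacks cluster ", g, "; apply select_r2 first")
    pooled <- (st$sigma + sd_$sigma) / 2
    pinv <- tryCatch(solve(pooled), error = function(e)
      solve(regularize_cov(pooled, 1e-6)))
    dx <- sweep(st$x, 2, sd_$mu)
    d <- d + sum(rowSums((dx %*% pinv) * dx))
  }
  d
}

#' Step III: pick the reference SNP
#'
#' Returns the candidate with the minimum [cluster_distance()] to the
#' T-SNP; ties are broken by nearest dataset position, then lexicographic
#' id.
#'
#' @param t_clust `rough_clustering` of the T-SNP.
#' @param r2 named list of candidate clusterings from [select_r2()].
#' @param ds an [intensity_dataset()] (for tie-breaking by position).
#' @param t_index the T-SNP's position in dataset order.
#' @return list with `snp` (winner id) and `distance` (named vector of all
#'   candidate distances).
#' @export
select_reference <- function(t_clust, r2, ds = NULL, t_index = NULL) {
  if (length(r2) == 0L) stop("no reference candidates")
  dist <- vapply(r2, function(cand) cluster_distance(t_clust, cand), numeric(1))
  ids <- names(r2)
  pos_gap <- if (!is.null(ds) && !is.null(t_index))
    abs(match(ids, ds$snp_ids) - t_index) else rep(0L, length(ids))
  ord <- order(dist, pos_gap, ids)
  list(snp = ids[ord[1L]], distance = dist)
}

#' Call a rare SNP with reference augmentation
#'
#' Stacks the T-SNP's intensity rows on top of the reference SNP's and fits
#' the DP Gaussian mixture to the augmented data; the reference's
#' well-populated clusters attract the T-SNP's sparse minor-cluster points
#' so they are not absorbed into the major cluster. Only the T-SNP rows'
#' calls are returned. If the DP fit fails the T-SNP is reported all-NC
#' with a warning.
#'
#' @param t_data n_t x 2 intensity matrix of the T-SNP.
#' @param r_data n_r x 2 intensity matrix of the selected reference.
#' @param hyper optional [dp_hyper()]; default: empirical from the stacked
#'   data.
#' @param pr_threshold no-call threshold.
#' @param n_iter,burn_in Gibbs settings.
#' @param seed integer seed.
#' @return data.frame with `sample`, `genotype`, `pr` for the T-SNP rows.
#' @export
call_with_reference <- function(t_data, r_data, hyper = NULL,
                                pr_threshold = 0.85,
                                n_iter = 2000L, burn_in = 500L, seed = 1L) {
  t_data <- as.matrix(t_data)
  r_data <- as.matrix(r_data)
  n_t <- nrow(t_data)
  stacked <- rbind(t_data, r_data)
  rownames(stacked) <- c(
    rownames(t_data) %||% as.character(seq_len(n_t)),
    paste0(".ref", seq_len(nrow(r_data))))
  calls <- tryCatch({
    fit <- fit_dp_gmm(stacked, hyper = hyper, n_iter = n_iter,
                      burn_in = burn_in, seed = seed)
    dp_calls_to_genotypes(fit, pr_threshold)
  }, error = function(e) {
    warning("reference-augmented DP fit failed (", conditionMessage(e),
            "); T-SNP reported as all no-call")
    data.frame(sample = rownames(stacked), genotype = "NC", pr = NA_real_,
               stringsAsFactors = FALSE)
  })
  calls[seq_len(n_t), , drop = FALSE]
}
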