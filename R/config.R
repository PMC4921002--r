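#' Calling-procedure configuration
#'
#' Collects every tunable of the M-D procedure in one validated list.
#' Defaults follow the published calibration: SNPs with MAF >= 0.05 are
#' common (group g1, Gaussian mixture); among rare SNPs those with at least
#' one genotype cluster of size in \[b1, b2) = \[3, 10) go to g2 (DP
#' mixture); the rest go to g3 (reference-assisted DP). Calls with posterior
#' rate below `pr_threshold` = 0.85 are withheld as NC. Reference candidates
#' need MAF > 0.15 and every genotype cluster to hold at least 10% of
#' observations.
#'
#' @param pr_threshold no-call threshold on the per-call posterior rate.
#' @param maf_threshold MAF cut separating common (g1) from rare SNPs.
#' @param b1,b2 cluster-size window \[b1, b2) routing rare SNPs to g2.
#' @param ref_maf minimum MAF (exclusive) for reference candidates (step I).
#' @param ref_min_prop minimum per-cluster proportion (inclusive) for
#'   reference candidates (step II).
#' @param max_candidates cap on reference candidates; the nearest
#'   predecessors are kept.
#' @param hwe_alpha significance level for the Hardy-Weinberg test.
#' @param hwe_method `"chisq"` (1-df goodness of fit) or `"exact"`.
#' @param gmm_tol relative log-likelihood convergence tolerance of the EM.
#' @param gmm_max_iter EM iteration cap.
#' @param dp_n_iter,dp_burn_in Gibbs sweeps and burn-in for the DP fits.
#' @param seed master seed; all per-SNP seeds are derived from it.
#' @return a list of class `md_config`.
#' @export
md_config <- function(pr_threshold = 0.85, maf_threshold = 0.05,
                      b1 = 3, b2 = 10,
                      ref_maf = 0.15, ref_min_prop = 0.10,
                      max_candidates = 200,
                      hwe_alpha = 1e-4, hwe_method = c("chisq", "exact"),
                      gmm_tol = 1e-8, gmm_max_iter = 500,
                      dp_n_iter = 2000, dp_burn_in = 500,
                      seed = 1L) {
  hwe_method <- match.arg(hwe_method)
  stopifnot(pr_threshold >= 0, pr_threshold <= 1,
            maf_threshold > 0, maf_threshold <= 0.5,
            b1 >= 1, b2 > b1, ref_maf > 0, ref_maf < 0.5,
            ref_min_prop > 0, ref_min_prop < 1/3 + 1e-12,
            max_candidates >= 1, hwe_alpha > 0, hwe_alpha < 1,
            gmm_tol >= 0, gmm_max_iter >= 1,
            dp_n_iter > dp_burn_in, dp_burn_in >= 0)
  structure(list(
    pr_threshold = pr_threshold, maf_threshold = maf_threshold,
    b1 = as.integer(b1), b2 = as.integer(b2),
    ref_maf = ref_maf, ref_min_prop = ref_min_prop,
    max_candidates = as.integer(max_candidates),
    hwe_alpha = hwe_alpha, hwe_method = hwe_method,
    gmm_tol = gmm_tol, gmm_max_iter = as.integer(gmm_max_iter),
    dp_n_iter = as.integer(dp_n_iter), dp_burn_in = as.integer(dp_burn_in),
    seed = as.integer(seed)
  ), class = "md_config")
}

#' Read configuration from a YAML file
#'
#' Keys match the arguments of [md_config()]; absent keys keep their
#' defaults, unknown keys are an error.
#'
#' @param path YAML file path.
#' @return a validated `md_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(md_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  do.call(md_config, vals)
}

#' @export
print.md_config <- function(x, ...) {
  cat("M-D calling configuration\n")
  for (k in names(x)) cat(sprintf("  %-14s %s\n", k, format(x[[k]])))
  invisible(x)
}
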