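## The M-D orchestrator: an initial EM pass over every SNP estimates MAF
## and per-cluster sample sizes; SNPs are partitioned into g1 (common),
## g2 (rare, moderately populated clusters) and g3 (extremely rare), and
## each group is called by its model: g1 -> GMM, g2 -> DP-GMM,
## g3 -> reference-assisted DP-GMM.

#' Allele-counting MAF estimate from genotype calls
#'
#' `maf = (2 n_minor_hom + n_AB) / (2 n_called)`, with the minor allele
#' chosen so the estimate is at most 0.5. No-calls are excluded; with zero
#' called samples the MAF is undefined (NA) and the SNP falls through to
#' group g3.
#'
#' @param genotypes character vector of calls in `{AA, AB, BB, NC}`.
#' @return MAF in \[0, 0.5\], or NA.
#' @export
estimate_maf <- function(genotypes) {
  called <- genotypes[genotypes %in% c("AA", "AB", "BB")]
  n <- length(called)
  if (n == 0L) return(NA_real_)
  nb <- 2 * sum(called == "BB") + sum(called == "AB")
  q <- nb / (2 * n)
  min(q, 1 - q)
}

#' Partition SNPs into calling groups
#'
#' The routing rule: a SNP is `g1` if its MAF is at least `maf_threshold`;
#' otherwise `g2` if at least one genotype cluster's size `n_k` satisfies
#' `b1 <= n_k < b2` (clusters with zero observations never qualify);
#' otherwise `g3`. A SNP with undefined MAF goes to `g3`. Exactly one
#' branch fires for every SNP.
#'
#' @param maf per-SNP MAF vector (NA allowed).
#' @param n_ks matrix (SNPs x 3) or length-3 vector of per-genotype cluster
#'   sizes.
#' @param b1,b2 the cluster-size window, defaults 3 and 10.
#' @param maf_threshold the common-SNP cut, default 0.05.
#' @return character vector of groups in `{g1, g2, g3}`.
#' @export
partition_snps <- function(maf, n_ks, b1 = 3, b2 = 10, maf_threshold = 0.05) {
  if (is.null(dim(n_ks))) n_ks <- matrix(n_ks, nrow = length(maf), ncol = 3,
                                         byrow = length(maf) == 1L)
  stopifnot(nrow(n_ks) == length(maf), ncol(n_ks) == 3)
  in_window <- n_ks >= b1 & n_ks < b2 & n_ks > 0
  ifelse(!is.na(maf) & maf >= maf_threshold, "g1",
         ifelse(rowSums(in_window) > 0, "g2", "g3"))
}

## Per-SNP seed streams derived from the master seed (kept below 2^31).
derive_seed <- function(seed, i, stream = 0L) {
  (as.double(seed) * 7919 + i * 131 + stream * 17) %% 2147483629 + 1
}

#' Run the full M-D calling procedure
#'
#' Pass 1 fits the three-component EM mixture to every SNP, calls at the
#' posterior-rate threshold, and estimates MAF and cluster sizes; SNPs are
#' then partitioned by [partition_snps()]. Pass 2 keeps the EM calls for
#' g1, refits g2 SNPs with the DP mixture, and refits g3 SNPs with
#' reference augmentation ([call_with_reference()]); a g3 SNP with no
#' qualifying predecessor searches after itself, and falls back to the
#' plain DP fit (flagged) if still empty. Per-SNP failures yield all-NC
#' calls for that SNP and never abort the run. Fully deterministic given
#' `config$seed`.
#'
#' @param ds an [intensity_dataset()].
#' @param config an [md_config()] list.
#' @param verbose print per-stage progress?
#' @return object of class `md_fit` with elements `calls` (data.frame:
#'   `snp`, `sample`, `genotype`, `pr`, `model`), `snp_summary` (per-SNP
#'   `apr`, `maf`, `group`, `model`, cluster sizes), `config`, and `notes`
#'   (per-SNP log of fallbacks/failures).
#' @export
run_md <- function(ds, config = md_config(), verbose = FALSE) {
  stopifnot(inherits(ds, "intensity_dataset"), inherits(config, "md_config"))
  S <- length(ds$snp_ids)
  thr <- config$pr_threshold
  notes <- character(0)

  ## ---- pass 1: EM everywhere, MAF + cluster sizes -> partition ----
  pass1 <- vector("list", S)
  maf <- stats::setNames(rep(NA_real_, S), ds$snp_ids)
  n_ks <- matrix(0L, S, 3, dimnames = list(ds$snp_ids, c("AA", "AB", "BB")))
  for (i in seq_len(S)) {
    id <- ds$snp_ids[i]
    x <- snp_intensities(ds, id)
    ok <- rowSums(x) > 0
    res <- tryCatch(suppressWarnings({
      fit <- fit_gmm(x[ok, , drop = FALSE], tol = config$gmm_tol,
                     max_iter = config$gmm_max_iter,
                     seed = derive_seed(config$seed, i, 1L))
      list(fit = fit, calls = call_genotypes(fit, thr), ok = ok)
    }), error = function(e) {
      notes <<- c(notes, sprintf("%s: pass-1 EM failed (%s)", id,
                                 conditionMessage(e)))
      NULL
    })
    pass1[[i]] <- res
    if (!is.null(res)) {
      maf[i] <- estimate_maf(res$calls$genotype)
      tab <- table(factor(res$calls$genotype, levels = c("AA", "AB", "BB")))
      n_ks[i, ] <- as.integer(tab)
    }
  }
  group <- partition_snps(maf, n_ks, config$b1, config$b2, config$maf_threshold)
  names(group) <- ds$snp_ids
  if (verbose)
    message(sprintf("pass 1 done: %d g1, %d g2, %d g3",
                    sum(group == "g1"), sum(group == "g2"), sum(group == "g3")))

  ## ---- pass 2: model per group ----
  all_calls <- vector("list", S)
  summ <- data.frame(snp = ds$snp_ids, apr = NA_real_, maf = unname(maf),
                     group = unname(group), model = NA_character_,
                     n_AA = 0L, n_AB = 0L, n_BB = 0L, n_NC = 0L,
                     stringsAsFactors = FALSE)
  for (i in seq_len(S)) {
    id <- ds$snp_ids[i]
    x <- snp_intensities(ds, id)
    ok <- rowSums(x) > 0
    model <- switch(group[i], g1 = "GMM", g2 = "DP-GMM", g3 = "DP-Ref")
    calls <- NULL
    apr <- NA_real_
    if (group[i] == "g1" && !is.null(pass1[[i]])) {
      calls <- pass1[[i]]$calls
      apr <- pass1[[i]]$fit$apr
    } else if (group[i] == "g2") {
      res <- tryCatch({
        fit <- fit_dp_gmm(x[ok, , drop = FALSE],
                          n_iter = config$dp_n_iter, burn_in = config$dp_burn_in,
                          seed = derive_seed(config$seed, i, 2L))
        list(calls = dp_calls_to_genotypes(fit, thr), apr = fit$apr)
      }, error = function(e) {
        notes <<- c(notes, sprintf("%s: DP-GMM failed (%s)", id,
                                   conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) { calls <- res$calls; apr <- res$apr }
    } else if (group[i] == "g3") {
      t_clust <- rough_cluster_by_contrast(x[ok, , drop = FALSE])
      r1 <- select_r1(ds, i, maf, config$ref_maf, config$max_candidates)
      r2 <- select_r2(r1, ds, config$ref_min_prop)
      if (length(r2) == 0L) {
        ## fallback: search after the T-SNP
        after <- ds$snp_ids[seq_len(S) > i]
        ok_after <- after[!is.na(maf[after]) & maf[after] > config$ref_maf]
        r1b <- utils::head(ok_after, config$max_candidates)
        r2 <- select_r2(r1b, ds, config$ref_min_prop)
        if (length(r2) > 0L)
          notes <- c(notes, sprintf("%s: reference found after the T-SNP", id))
      }
      if (length(r2) > 0L) {
        ref <- select_reference(t_clust, r2, ds, i)
        r_data <- snp_intensities(ds, ref$snp)
        r_ok <- rowSums(r_data) > 0
        calls <- call_with_reference(
          x[ok, , drop = FALSE], r_data[r_ok, , drop = FALSE],
          pr_threshold = thr, n_iter = config$dp_n_iter,
          burn_in = config$dp_burn_in, seed = derive_seed(config$seed, i, 3L))
        apr <- average_posterior_rate(calls$pr, calls$genotype != "NC")
      } else {
        notes <- c(notes, sprintf("%s: no reference candidate; plain DP fallback", id))
        model <- "DP-GMM"
        res <- tryCatch({
          fit <- fit_dp_gmm(x[ok, , drop = FALSE],
                            n_iter = config$dp_n_iter, burn_in = config$dp_burn_in,
                            seed = derive_seed(config$seed, i, 2L))
          list(calls = dp_calls_to_genotypes(fit, thr), apr = fit$apr)
        }, error = function(e) NULL)
        if (!is.null(res)) { calls <- res$calls; apr <- res$apr }
      }
    }
    samples <- rownames(x)
    geno <- stats::setNames(rep("NC", nrow(x)), samples)
    pr <- stats::setNames(rep(NA_real_, nrow(x)), samples)
    if (!is.null(calls)) {
      geno[calls$sample] <- calls$genotype
      pr[calls$sample] <- calls$pr
    }
    geno[!ok] <- "NC"  # degenerate (0,0) intensity pairs are never called
    all_calls[[i]] <- data.frame(snp = id, sample = samples,
                                 genotype = unname(geno), pr = unname(pr),
                                 model = model, stringsAsFactors = FALSE)
    tab <- table(factor(geno, levels = c("AA", "AB", "BB", "NC")))
    summ$apr[i] <- apr
    summ$model[i] <- model
    summ$n_AA[i] <- tab[["AA"]]; summ$n_AB[i] <- tab[["AB"]]
    summ$n_BB[i] <- tab[["BB"]]; summ$n_NC[i] <- tab[["NC"]]
    if (verbose && i %% 25L == 0L) message("pass 2: ", i, "/", S, " SNPs")
  }
  calls <- do.call(rbind, all_calls)
  structure(list(calls = calls, snp_summary = summ, config = config,
                 populations = ds$populations, notes = notes),
            class = "md_fit")
}

#' @export
print.md_fit <- function(x, ...) {
  cat("M-D genotype calls\n")
  tab <- table(factor(x$snp_summary$group, levels = c("g1", "g2", "g3")))
  cat(sprintf("  %d SNPs (g1=%d, g2=%d, g3=%d), %d calls\n",
              nrow(x$snp_summary), tab[["g1"]], tab[["g2"]], tab[["g3"]],
              nrow(x$calls)))
  cat(sprintf("  call rate %.2f%%, mean APR %.4f\n",
              call_rate(x), mean(x$snp_summary$apr, na.rm = TRUE)))
  if (length(x$notes)) cat("  notes:", length(x$notes), "(see $notes)\n")
  invisible(x)
}

#' @export
summary.md_fit <- function(object, ...) {
  s <- object$snp_summary
  out <- list(
    n_snps = nrow(s),
    n_calls = nrow(object$calls),
    call_rate = call_rate(object),
    groups = table(factor(s$group, levels = c("g1", "g2", "g3"))),
    models = table(s$model),
    apr = stats::quantile(s$apr, c(0, .25, .5, .75, 1), na.rm = TRUE),
    maf = stats::quantile(s$maf, c(0, .25, .5, .75, 1), na.rm = TRUE)
  )
  class(out) <- "summary.md_fit"
  out
}

#' @export
print.summary.md_fit <- function(x, ...) {
  cat("M-D calling summary\n")
  cat(sprintf("  SNPs: %d  calls: %d  call rate: %.2f%%\n",
              x$n_snps, x$n_calls, x$call_rate))
  cat("  groups: ", paste(sprintf("%s=%d", names(x$groups), x$groups),
                          collapse = " "), "\n")
  cat("  models: ", paste(sprintf("%s=%d", names(x$models), x$models),
                          collapse = " "), "\n")
  cat("  APR quartiles:", paste(sprintf("%.3f", x$apr), collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.md_fit <- function(x, ...) {
  s <- x$snp_summary
  cols <- c(g1 = "#0072B2", g2 = "#D55E00", g3 = "#009E73")
  graphics::plot(s$maf, s$apr, col = cols[s$group], pch = 19,
                 xlab = "MAF", ylab = "APR",
                 main = "Per-SNP quality by routing group", ...)
  graphics::legend("bottomright", legend = names(cols), col = cols, pch = 19)
  invisible(x)
}
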