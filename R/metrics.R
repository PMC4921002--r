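## Evaluation metrics: call rate, concordance between call sets, accuracy
## against truth, and per-population Hardy-Weinberg equilibrium tests.

#' Call rate
#'
#' Percentage of observed cells with a non-NC genotype:
#' `100 * (# called) / (# cells supposed to be genotyped)`.
#'
#' @param calls a call table (see [write_calls()] for the columns) or an
#'   object with `$calls` such as [run_md()] output.
#' @return percentage in \[0, 100\].
#' @export
call_rate <- function(calls) {
  calls <- as_call_table(calls)
  if (nrow(calls) == 0L) stop("empty call set")
  100 * mean(calls$genotype != "NC")
}

#' Concordance between two call sets
#'
#' Percentage of agreeing genotypes over the cells called (non-NC) by
#' *both* sets, matched on (SNP, sample). Undefined (NA, with a warning)
#' when no cell is jointly called.
#'
#' @param a,b call tables or objects with `$calls`.
#' @return percentage in \[0, 100\], or NA.
#' @export
concordance <- function(a, b) {
  a <- as_call_table(a)
  b <- as_call_table(b)
  key_a <- paste(a$snp, a$sample, sep = "\r")
  key_b <- paste(b$snp, b$sample, sep = "\r")
  idx <- match(key_a, key_b)
  ok <- !is.na(idx) & a$genotype != "NC" & b$genotype[idx] != "NC"
  if (!any(ok)) {
    warning("no jointly called cells; concordance undefined")
    return(NA_real_)
  }
  100 * mean(a$genotype[ok] == b$genotype[idx][ok])
}

#' Accuracy against truth genotypes
#'
#' Concordance of calls against a truth table over truth-covered, called
#' cells: `100 * (# calls equal to truth) / (# called cells with truth)`.
#'
#' @param calls call table or object with `$calls`.
#' @param truth data.frame with columns `snp`, `sample`, `genotype` (the
#'   gold-standard genotypes; may cover only a subset of samples).
#' @return percentage in \[0, 100\], or NA when no overlap.
#' @export
accuracy <- function(calls, truth) {
  calls <- as_call_table(calls)
  stopifnot(all(c("snp", "sample", "genotype") %in% names(truth)))
  idx <- match(paste(calls$snp, calls$sample, sep = "\r"),
               paste(truth$snp, truth$sample, sep = "\r"))
  ok <- !is.na(idx) & calls$genotype != "NC" &
    truth$genotype[idx] %in% c("AA", "AB", "BB")
  if (!any(ok)) {
    warning("no called cells with truth coverage; accuracy undefined")
    return(NA_real_)
  }
  100 * mean(calls$genotype[ok] == truth$genotype[idx][ok])
}

## 1-df chi-square goodness of fit of genotype counts (nAA, nAB, nBB)
## against HWE expectations at the estimated allele frequency.
hwe_chisq <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  p <- (2 * nAA + nAB) / (2 * n)
  if (p == 0 || p == 1) return(list(statistic = 0, p.value = 1))
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((c(nAA, nAB, nBB) - e)^2 / e)
  list(statistic = stat, p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

## Exact HWE test (heterozygote-count enumeration conditional on the
## allele counts), two-sided by summing configurations no more probable
## than the observed one.
hwe_exact <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  n_minor <- 2 * min(nAA, nBB) + nAB
  ## possible heterozygote counts share parity with the minor-allele count
  het <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  logp <- lgamma(n + 1) - lgamma((n_minor - het) / 2 + 1) - lgamma(het + 1) -
    lgamma(n - (n_minor + het) / 2 + 1) + het * log(2) +
    lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(het == nAB)
  list(statistic = NA_real_, p.value = min(1, sum(p[p <= p[obs] + 1e-12])))
}

#' Hardy-Weinberg equilibrium test per population
#'
#' Tests each population's called genotype counts at one SNP against HWE
#' expectations at the estimated allele frequency. Default is the 1-df
#' chi-square goodness-of-fit test; monomorphic SNPs pass by definition
#' (statistic 0, p = 1). Populations with fewer than `min_n` called
#' samples are skipped with a warning. A population fails iff
#' `p < alpha`.
#'
#' @param genotypes character vector of calls for one SNP.
#' @param populations population label per call (same length); a single
#'   label may be given to test one pooled population.
#' @param alpha significance level, default 1e-4.
#' @param method `"chisq"` or `"exact"`.
#' @param min_n minimum called samples per population, default 5.
#' @return data.frame with one row per tested population: `population`,
#'   `n`, `statistic`, `p.value`, `fail`.
#' @export
hwe_test <- function(genotypes, populations = NULL, alpha = 1e-4,
                     method = c("chisq", "exact"), min_n = 5L) {
  method <- match.arg(method)
  if (is.null(populations)) populations <- rep("all", length(genotypes))
  if (length(populations) == 1L)
    populations <- rep(populations, length(genotypes))
  stopifnot(length(populations) == length(genotypes))
  out <- list()
  for (pop in unique(populations[!is.na(populations)])) {
    g <- genotypes[populations == pop & genotypes %in% c("AA", "AB", "BB")]
    if (length(g) < min_n) {
      warning("population ", pop, " has fewer than ", min_n,
              " called samples; skipped")
      next
    }
    cnt <- table(factor(g, levels = c("AA", "AB", "BB")))
    res <- if (method == "chisq")
      hwe_chisq(cnt[["AA"]], cnt[["AB"]], cnt[["BB"]])
    else hwe_exact(cnt[["AA"]], cnt[["AB"]], cnt[["BB"]])
    out[[pop]] <- data.frame(population = pop, n = length(g),
                             statistic = res$statistic, p.value = res$p.value,
                             fail = res$p.value < alpha,
                             stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(population = character(0), n = integer(0),
                      statistic = numeric(0), p.value = numeric(0),
                      fail = logical(0)))
  rownames_reset(do.call(rbind, out))
}

rownames_reset <- function(df) { rownames(df) <- NULL; df }

#' HWE failure counts across a call set
#'
#' Applies [hwe_test()] to every SNP of a call set, per population, and
#' counts failing SNPs.
#'
#' @param calls call table or object with `$calls`.
#' @param populations named character vector mapping sample -> population;
#'   defaults to the populations attached to a [run_md()] result, else one
#'   pooled population.
#' @param alpha significance level.
#' @param method `"chisq"` or `"exact"`.
#' @return data.frame with `population`, `n_tested`, `n_fail`.
#' @export
hwe_failures <- function(calls, populations = NULL, alpha = 1e-4,
                         method = c("chisq", "exact")) {
  method <- match.arg(method)
  if (is.null(populations) && !is.data.frame(calls))
    populations <- calls$populations
  tab <- as_call_table(calls)
  if (is.null(populations)) {
    populations <- stats::setNames(rep("all", length(unique(tab$sample))),
                                   unique(tab$sample))
    message("no population labels; pooling all samples for the HWE test")
  }
  pop_of <- unname(populations[tab$sample])
  res <- list()
  for (id in unique(tab$snp)) {
    sel <- tab$snp == id
    ht <- suppressWarnings(
      hwe_test(tab$genotype[sel], pop_of[sel], alpha, method))
    if (nrow(ht)) { ht$snp <- id; res[[id]] <- ht }
  }
  if (!length(res))
    return(data.frame(population = character(0), n_tested = integer(0),
                      n_fail = integer(0)))
  all <- do.call(rbind, res)
  agg <- stats::aggregate(cbind(n_tested = !is.na(all$p.value),
                                n_fail = all$fail) ~ population, data = all, FUN = sum)
  agg
}
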