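## Model I: per-SNP three-component bivariate Gaussian mixture fitted by EM.
##
## Each observed sample at a SNP contributes an intensity pair x = (r, g);
## the three genotype clusters AA/AB/BB are modelled as bivariate normals
## with free means and covariances. Abnormal points are not given their own
## mixture component; they are rejected downstream by the posterior-rate
## no-call rule.

## log-density of rows of x under a bivariate normal, closed form for 2x2.
dmvnorm2_log <- function(x, mu, sigma) {
  a <- sigma[1, 1]; b <- sigma[1, 2]; d <- sigma[2, 2]
  det <- a * d - b * b
  if (det <= 0) stop("non-positive-definite covariance")
  dx <- x[, 1] - mu[1]; dy <- x[, 2] - mu[2]
  q <- (d * dx * dx - 2 * b * dx * dy + a * dy * dy) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

## Conditional ridge: lift the smallest eigenvalue of a 2x2 covariance to
## eps * mean(diag) if it sits below that floor (tight/degenerate clusters);
## healthy covariances are returned untouched so EM stays an exact ascent.
regularize_cov <- function(sigma, eps = 1e-6) {
  sigma <- (sigma + t(sigma)) / 2
  floor_val <- eps * max(mean(diag(sigma)), .Machine$double.eps)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < floor_val) sigma <- sigma + diag(floor_val - min(ev) + floor_val, 2)
  sigma
}

#' Initialize the three-component mixture
#'
#' Samples are split along the contrast \eqn{y = (r-g)/(r+g)} at the fixed
#' cutoffs +0.5 / -0.5 (AA / AB / BB); empty groups fall back to a contrast
#' tercile split. The split is refined by k-means started at the group
#' means. Mixing proportions start uniform and all components share the
#' pooled within-group covariance (ridge-regularized).
#'
#' @param x numeric matrix (n x 2) of (r, g) intensities, n >= 3.
#' @param seed integer seed; initialization is deterministic given it.
#' @return list with `pi` (3), `mu` (3 x 2), `sigma` (2 x 2 x 3); components
#'   ordered by descending mean contrast (AA, AB, BB).
#' @export
init_gmm <- function(x, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 samples to initialize a 3-component mixture")
  if (all(abs(x[, 1] - x[1, 1]) < 1e-12) && all(abs(x[, 2] - x[1, 2]) < 1e-12))
    stop("degenerate data: all intensity pairs identical")
  set.seed(seed)
  y <- contrast_or_na(x[, 1], x[, 2])
  y[is.na(y)] <- 0
  lab <- ifelse(y >= 0.5, 1L, ifelse(y < -0.5, 3L, 2L))
  ## an empty contrast group gets a synthetic center at the canonical
  ## contrast position (scaled by the data's mean total intensity); with no
  ## data nearby the component is starved in the E-step and freezes, so a
  ## SNP with a missing genotype cluster degrades to a 2- or 1-component
  ## fit instead of splitting a real cluster
  tot <- mean(rowSums(x))
  canon <- c(0.75, 0, -0.75)
  centers <- do.call(rbind, lapply(1:3, function(k) {
    if (any(lab == k)) colMeans(x[lab == k, , drop = FALSE])
    else tot * c(1 + canon[k], 1 - canon[k]) / 2
  }))
  if (all(tabulate(lab, 3L) > 0L)) {
    km <- tryCatch(stats::kmeans(x, centers = centers, iter.max = 25L),
                   error = function(e) NULL)
    ## accept the refinement only if every refined center stays in its
    ## contrast region; with very unbalanced clusters k-means prefers to
    ## split the major cluster and merge the sparse ones, which must not
    ## override the cutoff grouping
    if (!is.null(km) && all(km$size > 0L)) {
      yc <- contrast_or_na(km$centers[, 1], km$centers[, 2])
      if (!anyNA(yc) && yc[1] >= 0.5 && yc[2] >= -0.5 && yc[2] < 0.5 &&
          yc[3] < -0.5)
        lab <- km$cluster
    }
  }
  mu <- do.call(rbind, lapply(1:3, function(k) {
    if (any(lab == k)) colMeans(x[lab == k, , drop = FALSE]) else centers[k, ]
  }))
  pooled <- matrix(0, 2, 2)
  for (k in 1:3) {
    xi <- x[lab == k, , drop = FALSE]
    if (nrow(xi) > 1L) {
      c_ <- sweep(xi, 2, colMeans(xi))
      pooled <- pooled + crossprod(c_)
    }
  }
  denom <- max(n - length(unique(lab)), 1L)
  pooled <- pooled / denom
  if (mean(diag(pooled)) <= 0) pooled <- diag(mean(x^2) * 1e-4 + 1e-8, 2)
  pooled <- regularize_cov(pooled)
  ord <- order(contrast_or_na(mu[, 1], mu[, 2]), decreasing = TRUE)
  mu <- mu[ord, , drop = FALSE]
  sigma <- array(rep(pooled, 3), dim = c(2, 2, 3))
  list(pi = rep(1/3, 3), mu = mu, sigma = sigma)
}

#' E-step: posterior responsibilities
#'
#' For each sample, the probability it belongs to each of the three
#' components given the current parameters:
#' \eqn{f_k(x_i) = \pi_k \Psi(x_i; \mu_k, \Sigma_k) / \sum_u \pi_u \Psi(x_i; \mu_u, \Sigma_u)}.
#' Computed in log space, so far-out points never produce NaN rows.
#'
#' @param x n x 2 intensity matrix.
#' @param params list with `pi`, `mu`, `sigma` as from [init_gmm()].
#' @return list with `resp` (n x 3 row-stochastic matrix) and `loglik` (the
#'   observed-data log-likelihood at `params`).
#' @export
e_step <- function(x, params) {
  x <- as.matrix(x)
  n <- nrow(x)
  lp <- matrix(0, n, 3)
  logpi <- log(pmax(params$pi, 1e-300))
  for (k in 1:3)
    lp[, k] <- logpi[k] + dmvnorm2_log(x, params$mu[k, ], params$sigma[, , k])
  m <- apply(lp, 1, max)
  w <- exp(lp - m)
  rs <- rowSums(w)
  list(resp = w / rs, loglik = sum(m + log(rs)))
}

#' M-step: weighted parameter updates
#'
#' Responsibility-weighted mean and scatter-about-the-new-mean updates; the
#' mixing proportion is the responsibility column mean. A component whose
#' responsibility mass vanishes is frozen at its previous parameters with
#' its proportion floored at 1e-10 (such SNPs are then routed to the DP
#' models by the partition rule).
#'
#' @param x n x 2 intensity matrix.
#' @param resp n x 3 responsibility matrix (rows sum to 1).
#' @param prev previous parameter list (needed only to freeze empty
#'   components).
#' @param eps ridge scale passed to the covariance regularizer; `eps = 0`
#'   disables regularization (used by exactness tests).
#' @return updated parameter list (`pi`, `mu`, `sigma`, `frozen` logical).
#' @export
m_step <- function(x, resp, prev = NULL, eps = 1e-6) {
  x <- as.matrix(x)
  n <- nrow(x)
  nk <- colSums(resp)
  pi_ <- nk / n
  mu <- matrix(0, 3, 2)
  sigma <- array(0, dim = c(2, 2, 3))
  frozen <- nk < 1e-10
  for (k in 1:3) {
    if (frozen[k]) {
      if (is.null(prev)) stop("empty component with no previous parameters")
      mu[k, ] <- prev$mu[k, ]
      sigma[, , k] <- prev$sigma[, , k]
      pi_[k] <- 1e-10
      next
    }
    mu[k, ] <- colSums(resp[, k] * x) / nk[k]
    cx <- sweep(x, 2, mu[k, ])
    s <- crossprod(cx, resp[, k] * cx) / nk[k]
    sigma[, , k] <- if (eps > 0) regularize_cov(s, eps) else (s + t(s)) / 2
  }
  pi_ <- pi_ / sum(pi_)
  list(pi = pi_, mu = mu, sigma = sigma, frozen = frozen)
}

#' Fit the per-SNP Gaussian mixture by EM
#'
#' Alternates [e_step()] and [m_step()] from the contrast-based
#' initialization until the relative log-likelihood change drops below
#' `tol` or `max_iter` is reached. At convergence the components are
#' relabeled by descending mean contrast: highest contrast -> AA, middle ->
#' AB, lowest -> BB (the `r` channel measures allele A).
#'
#' @param x n x 2 matrix of (r, g) intensities (rownames = sample ids).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param seed integer seed (initialization determinism).
#' @return object of class `snp_gmm`: `pi`, `mu`, `sigma`, `labels`
#'   (genotype per component), `resp`, `assignment` (hard component index),
#'   `pr` (posterior rate per sample), `apr`, `loglik_trace`, `converged`,
#'   `n`.
#' @export
fit_gmm <- function(x, tol = 1e-8, max_iter = 500L, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 observed samples")
  params <- init_gmm(x, seed = seed)
  params$frozen <- rep(FALSE, 3)
  trace <- numeric(0)
  converged <- FALSE
  resp <- NULL
  for (it in seq_len(max_iter)) {
    es <- e_step(x, params)
    resp <- es$resp
    trace <- c(trace, es$loglik)
    if (it > 1L) {
      delta <- trace[it] - trace[it - 1L]
      if (abs(delta) / max(abs(trace[it]), 1e-12) < tol) {
        converged <- TRUE
        break
      }
    }
    params <- m_step(x, resp, prev = params)
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations")
  ## order components by descending mean contrast and map to genotypes:
  ## highest y -> AA, middle -> AB, lowest -> BB when the three means fall
  ## in distinct contrast regions (the typical three-cluster SNP); when two
  ## components share a region (e.g. a missing het cluster let one real
  ## cluster be covered by two components) both take that region's
  ## genotype, so a split major cluster is not miscalled heterozygous
  yc <- contrast_or_na(params$mu[, 1], params$mu[, 2])
  yc[is.na(yc)] <- 0
  ord <- order(yc, decreasing = TRUE)
  params$pi <- params$pi[ord]
  params$mu <- params$mu[ord, , drop = FALSE]
  params$sigma <- params$sigma[, , ord, drop = FALSE]
  params$frozen <- params$frozen[ord]
  resp <- resp[, ord, drop = FALSE]
  yc <- yc[ord]
  region <- ifelse(yc >= 0.5, "AA", ifelse(yc < -0.5, "BB", "AB"))
  labels <- if (length(unique(region)) == 3L) c("AA", "AB", "BB") else region
  assignment <- max.col(resp, ties.method = "first")
  pr <- resp[cbind(seq_len(n), assignment)]
  structure(list(
    pi = params$pi, mu = params$mu, sigma = params$sigma,
    labels = labels, frozen = params$frozen,
    resp = resp, assignment = assignment, pr = pr,
    apr = mean(pr), loglik_trace = trace, converged = converged,
    n = n, sample_ids = rownames(x)
  ), class = "snp_gmm")
}

#' Per-sample posterior rate of a fitted mixture
#'
#' PR is the converged responsibility of each sample's assigned component —
#' the posterior probability of its called genotype cluster.
#'
#' @param fit a [fit_gmm()] result.
#' @return numeric vector in \[0, 1\], one value per sample.
#' @export
posterior_rate <- function(fit) {
  stopifnot(inherits(fit, c("snp_gmm", "snp_dpgmm")))
  fit$pr
}

#' Average posterior rate over assigned samples
#'
#' The per-SNP quality score: the mean PR over samples counted in the
#' genotype clusters (non-NC). Undefined (NA) when no sample is assigned.
#'
#' @param pr per-sample posterior rates.
#' @param assigned logical vector, TRUE for samples counted in a cluster.
#' @return scalar APR in \[0, 1\], or NA.
#' @export
average_posterior_rate <- function(pr, assigned = rep(TRUE, length(pr))) {
  if (!any(assigned)) return(NA_real_)
  mean(pr[assigned])
}

#' Threshold-based genotype calling from a fitted mixture
#'
#' Each sample is called to the genotype of its maximum-responsibility
#' component when its posterior rate reaches the threshold (inclusive:
#' PR >= threshold), and NC otherwise.
#'
#' @param fit a [fit_gmm()] (or [fit_dp_gmm()]) result.
#' @param pr_threshold no-call threshold, default 0.85.
#' @return data.frame with columns `sample`, `genotype`, `pr`.
#' @export
call_genotypes <- function(fit, pr_threshold = 0.85) {
  UseMethod("call_genotypes")
}

#' @export
call_genotypes.snp_gmm <- function(fit, pr_threshold = 0.85) {
  geno <- fit$labels[fit$assignment]
  geno[fit$pr < pr_threshold] <- "NC"
  data.frame(sample = fit$sample_ids %||% as.character(seq_len(fit$n)),
             genotype = geno, pr = fit$pr, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.snp_gmm <- function(x, ...) {
  cat("Three-component bivariate Gaussian mixture (EM)\n")
  cat(sprintf("  n = %d, converged = %s, iterations = %d, APR = %.4f\n",
              x$n, x$converged, length(x$loglik_trace), x$apr))
  tab <- table(factor(x$labels[x$assignment], levels = c("AA", "AB", "BB")))
  cat("  cluster sizes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.snp_gmm <- function(object, ...) {
  list(pi = stats::setNames(object$pi, object$labels),
       mu = structure(object$mu, dimnames = list(object$labels, c("r", "g"))),
       sigma = object$sigma)
}

#' @export
predict.snp_gmm <- function(object, newdata = NULL, pr_threshold = 0.85, ...) {
  if (is.null(newdata)) return(call_genotypes(object, pr_threshold))
  es <- e_step(as.matrix(newdata), object)
  a <- max.col(es$resp, ties.method = "first")
  pr <- es$resp[cbind(seq_len(nrow(es$resp)), a)]
  geno <- object$labels[a]
  geno[pr < pr_threshold] <- "NC"
  data.frame(genotype = geno, pr = pr, stringsAsFactors = FALSE)
}

#' @export
plot.snp_gmm <- function(x, data = NULL, ...) {
  cols <- c(AA = "#D55E00", AB = "#009E73", BB = "#0072B2", NC = "grey60")
  geno <- x$labels[x$assignment]
  if (!is.null(data)) {
    data <- as.matrix(data)
    graphics::plot(data[, 1], data[, 2], col = cols[geno], pch = 19,
                   xlab = "r (allele A)", ylab = "g (allele B)", ...)
  }
  graphics::points(x$mu[, 1], x$mu[, 2], pch = 3, cex = 2, lwd = 2,
                   col = cols[x$labels])
  invisible(x)
}
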