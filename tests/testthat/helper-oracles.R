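# Independent oracles used across the suite: plain-loop implementations of
# the mixture updates, enumeration of the indicator conditional, and
# counting versions of the evaluation metrics. Deliberately written with
# scalar loops and base density algebra so they share no code path with the
# package internals they check.

# bivariate normal density via explicit 2x2 algebra (covariance form)
oracle_dmvnorm <- function(x, mu, sigma) {
  d <- x - mu
  det <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2] * sigma[2, 1]
  q <- (sigma[2, 2] * d[1]^2 - 2 * sigma[1, 2] * d[1] * d[2] +
          sigma[1, 1] * d[2]^2) / det
  exp(-q / 2) / (2 * pi * sqrt(det))
}

# responsibilities by direct evaluation of the ratio of weighted densities
oracle_e_step <- function(x, params) {
  n <- nrow(x)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    f <- numeric(3)
    for (k in 1:3)
      f[k] <- params$pi[k] *
        oracle_dmvnorm(x[i, ], params$mu[k, ], params$sigma[, , k])
    out[i, ] <- f / sum(f)
  }
  out
}

# weighted-moment updates with scalar accumulation; eps = 0 disables the
# ridge so results are the raw weighted moments
oracle_m_step <- function(x, resp) {
  n <- nrow(x)
  pi_ <- colSums(resp) / n
  mu <- matrix(0, 3, 2)
  sigma <- array(0, dim = c(2, 2, 3))
  for (k in 1:3) {
    sw <- sum(resp[, k])
    for (j in 1:2) mu[k, j] <- sum(resp[, k] * x[, j]) / sw
    acc <- matrix(0, 2, 2)
    for (i in seq_len(n)) {
      d <- x[i, ] - mu[k, ]
      acc <- acc + resp[i, k] * (d %o% d)
    }
    sigma[, , k] <- acc / sw
  }
  list(pi = pi_, mu = mu, sigma = sigma)
}

# direct term-by-term evaluation of the indicator conditional for one
# sample: existing clusters weighted by counts times the normal density at
# the instantiated (mu, precision R) parameters, the new-cluster slot by
# alpha times the Normal-Wishart prior predictive evaluated by the
# closed-form Student-t with an independently coded density
oracle_crp_conditional <- function(i, z, clusters, alpha, x, hyper) {
  counts <- sapply(clusters, function(cl) cl$count)
  k0 <- z[i]
  counts[k0] <- counts[k0] - 1
  if (counts[k0] == 0) {
    clusters <- clusters[-k0]
    counts <- counts[-k0]
  }
  K <- length(clusters)
  w <- numeric(K + 1)
  for (u in seq_len(K)) {
    R <- clusters[[u]]$R
    w[u] <- counts[u] * oracle_dmvnorm(x[i, ], clusters[[u]]$mu, solve(R))
  }
  w[K + 1] <- alpha * oracle_t_predictive(x[i, ], hyper)
  w / sum(w)
}

# bivariate Student-t density of the Normal-Wishart prior predictive,
# coded from the generic multivariate-t formula
oracle_t_predictive <- function(x, hyper) {
  df <- hyper$nu - 1
  Sig <- hyper$S * (hyper$r + 1) / (hyper$r * df)
  d <- x - hyper$m
  det <- Sig[1, 1] * Sig[2, 2] - Sig[1, 2] * Sig[2, 1]
  q <- (Sig[2, 2] * d[1]^2 - 2 * Sig[1, 2] * d[1] * d[2] +
          Sig[1, 1] * d[2]^2) / det
  gamma((df + 2) / 2) / (gamma(df / 2) * df * pi * sqrt(det)) *
    (1 + q / df)^(-(df + 2) / 2)
}

# counting oracles for the evaluation metrics
oracle_call_rate <- function(genotypes) {
  n_called <- 0L
  for (g in genotypes) if (g != "NC") n_called <- n_called + 1L
  100 * n_called / length(genotypes)
}

oracle_concordance <- function(ga, gb) {
  joint <- 0L; agree <- 0L
  for (i in seq_along(ga)) {
    if (ga[i] != "NC" && gb[i] != "NC") {
      joint <- joint + 1L
      if (ga[i] == gb[i]) agree <- agree + 1L
    }
  }
  if (joint == 0L) NA_real_ else 100 * agree / joint
}

# quick fixtures -------------------------------------------------------

# three well-separated bivariate Gaussian clusters in intensity space
make_three_cluster_data <- function(n_per = c(50, 50, 50), sd = 60,
                                    seed = 1) {
  set.seed(seed)
  mus <- rbind(c(1800, 200), c(1000, 1000), c(200, 1800))
  x <- do.call(rbind, lapply(1:3, function(k)
    cbind(rnorm(n_per[k], mus[k, 1], sd), rnorm(n_per[k], mus[k, 2], sd))))
  list(x = pmax(x, 0), labels = rep(1:3, times = n_per), mu = mus)
}

random_params <- function(seed = 1) {
  set.seed(seed)
  sig <- function() {
    a <- matrix(rnorm(4, sd = 0.5), 2)
    crossprod(a) + diag(0.5, 2)
  }
  p <- runif(3) + 0.2
  list(pi = p / sum(p),
       mu = matrix(rnorm(6, sd = 2), 3, 2),
       sigma = array(c(sig(), sig(), sig()), dim = c(2, 2, 3)))
}
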