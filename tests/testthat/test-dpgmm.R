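toy_hyper <- function() {
  dp_hyper(m = c(0, 0), r = 2, nu = 5, S = diag(2) * 3)
}

test_that("hyperparameters are validated", {
  expect_error(dp_hyper(m = c(0, 0), S = matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")
  expect_error(dp_hyper(m = c(0, 0), S = diag(2), r = -1), "r must be")
  expect_error(dp_hyper(m = c(0, 0), S = diag(2), nu = 1), "nu must")
  expect_error(dp_hyper(), "supply data")
  h <- dp_hyper(matrix(rnorm(20), 10, 2))
  expect_s3_class(h, "dp_hyper")
})

test_that("initial state is a single cluster and is seed-reproducible", {
  x <- matrix(rnorm(10), 5, 2)
  st <- init_dp_state(x, toy_hyper(), seed = 3)
  expect_equal(st$z, rep(1L, 5))
  expect_equal(st$clusters[[1]]$count, 5L)
  expect_equal(st$alpha, 1)
  st2 <- init_dp_state(x, toy_hyper(), seed = 3)
  expect_identical(st, st2)
})

test_that("new-cluster predictive is a proper, symmetric density", {
  h <- toy_hyper()
  # symmetry about m for isotropic S
  d <- c(1.3, -0.4)
  expect_equal(new_cluster_predictive(h$m + d, h),
               new_cluster_predictive(h$m - d, h), tolerance = 1e-12)
  # agrees with the independently coded Student-t formula
  for (pt in list(c(0, 0), c(2, 1), c(-3, 4)))
    expect_equal(new_cluster_predictive(pt, h), oracle_t_predictive(pt, h),
                 tolerance = 1e-12)
  # integrates to 1 over a wide grid
  gr <- seq(-60, 60, length.out = 601)
  hstep <- diff(gr[1:2])
  vals <- outer(gr, gr, function(a, b)
    new_cluster_predictive(cbind(a, b), h))
  expect_equal(sum(vals) * hstep^2, 1, tolerance = 1e-3)
})

test_that("new-cluster predictive matches Monte-Carlo prior integration", {
  # ~1e5 draws here keep the unit suite quick; the acceptance suite runs 1e6
  h <- toy_hyper()
  set.seed(77)
  nmc <- 1e5
  Rs <- stats::rWishart(nmc, h$nu, solve(h$S))
  r11 <- Rs[1, 1, ]; r12 <- Rs[1, 2, ]; r22 <- Rs[2, 2, ]
  detR <- r11 * r22 - r12^2
  # mu | R ~ N(m, (r R)^-1): draw via the 2x2 precision Cholesky
  z1 <- rnorm(nmc); z2 <- rnorm(nmc)
  # inverse covariance = r*R; covariance = (1/r) R^-1
  c11 <- r22 / detR / h$r; c12 <- -r12 / detR / h$r; c22 <- r11 / detR / h$r
  l11 <- sqrt(c11); l21 <- c12 / l11; l22 <- sqrt(c22 - l21^2)
  mu1 <- h$m[1] + l11 * z1
  mu2 <- h$m[2] + l21 * z1 + l22 * z2
  for (pt in list(c(0, 0), c(2, 1), c(-3, 4))) {
    d1 <- pt[1] - mu1; d2 <- pt[2] - mu2
    q <- r11 * d1^2 + 2 * r12 * d1 * d2 + r22 * d2^2
    dens <- sqrt(detR) / (2 * pi) * exp(-q / 2)
    mc <- mean(dens)
    se <- sd(dens) / sqrt(nmc)
    expect_lt(abs(new_cluster_predictive(pt, h) - mc), 3 * se)
  }
})

test_that("indicator conditional matches direct enumeration for n <= 6", {
  h <- toy_hyper()
  set.seed(5)
  for (n in c(3, 5, 6)) {
    x <- matrix(rnorm(2 * n, sd = 2), n, 2)
    z <- c(1L, rep(c(1L, 2L), length.out = n - 1))
    clusters <- lapply(1:2, function(k) {
      A <- matrix(rnorm(4, sd = 0.3), 2)
      list(mu = rnorm(2), R = crossprod(A) + diag(2),
           count = sum(z == k))
    })
    st <- structure(list(z = z, clusters = clusters, alpha = 0.8),
                    class = "dp_state")
    for (i in seq_len(n)) {
      got <- crp_indicator_conditional(i, st, x, h)
      ref <- oracle_crp_conditional(i, z, clusters, 0.8, x, h)
      expect_equal(got$prob, ref, tolerance = 1e-12)
      expect_equal(sum(got$prob), 1, tolerance = 1e-12)
    }
  }
})

test_that("indicator conditional has the CRP limits and structure", {
  h <- toy_hyper()
  x <- matrix(rnorm(10), 5, 2)
  one <- structure(list(z = rep(1L, 5),
                        clusters = list(list(mu = c(0, 0), R = diag(2),
                                             count = 5L)),
                        alpha = 1e-12), class = "dp_state")
  p <- crp_indicator_conditional(1, one, x, h)$prob
  expect_lt(p[2], 1e-8)  # alpha -> 0 kills the new-cluster slot

  # removing a singleton deletes its cluster before evaluation
  st <- structure(list(z = c(1L, 1L, 1L, 1L, 2L),
                       clusters = list(list(mu = c(0, 0), R = diag(2), count = 4L),
                                       list(mu = c(3, 3), R = diag(2), count = 1L))),
                  class = "dp_state")
  st$alpha <- 0.8
  res <- crp_indicator_conditional(5, st, x, h)
  expect_length(res$prob, 2L)       # one remaining cluster + new slot
  expect_length(res$clusters, 1L)

  # density monotonicity: the cluster at the point's location wins
  st2 <- structure(list(z = rep(c(1L, 2L), c(3, 2)),
                        clusters = list(list(mu = c(0, 0), R = diag(2), count = 3L),
                                        list(mu = c(40, 40), R = diag(2), count = 2L)),
                        alpha = 0.5), class = "dp_state")
  x2 <- rbind(c(0, 0), x[-1, ])
  p2 <- crp_indicator_conditional(1, st2, x2, h)$prob
  expect_gt(p2[1], p2[2])
})

test_that("rich-gets-richer: constant likelihood reduces to CRP weights", {
  h <- toy_hyper()
  # identical cluster parameters make every density equal, so the
  # conditional must be proportional to (n_{-i,1}, n_{-i,2}, alpha)
  x <- matrix(0, 6, 2)
  shared <- list(mu = c(0, 0), R = diag(2))
  st <- structure(list(z = rep(c(1L, 2L), c(4, 2)),
                       clusters = list(c(shared, count = 4L),
                                       c(shared, count = 2L)),
                       alpha = 1.5), class = "dp_state")
  p <- crp_indicator_conditional(6, st, x, h)$prob
  dens <- oracle_dmvnorm(c(0, 0), c(0, 0), diag(2))
  w <- c(4 * dens, 1 * dens, 1.5 * oracle_t_predictive(c(0, 0), h))
  expect_equal(p, w / sum(w), tolerance = 1e-12)
  expect_gt(p[1], p[2])  # larger cluster attracts more
})

test_that("cluster parameter draws concentrate on the conjugate posterior", {
  h <- toy_hyper()
  set.seed(123)
  x <- cbind(rnorm(1e4, 5, 1), rnorm(1e4, -2, 1))
  st <- init_dp_state(x, h, seed = 1)
  mus <- t(replicate(50, sample_cluster_params(st, x, h)$clusters[[1]]$mu))
  # posterior sd of mu ~ sigma/sqrt(n); allow 4 posterior sds
  expect_lt(abs(mean(mus[, 1]) - mean(x[, 1])), 4 / sqrt(1e4))
  expect_lt(abs(mean(mus[, 2]) - mean(x[, 2])), 4 / sqrt(1e4))

  # r -> Inf pins the mean draws at m
  h_inf <- dp_hyper(m = c(1, 1), r = 1e12, nu = 5, S = diag(2))
  st2 <- init_dp_state(x[1:50, ], h_inf, seed = 2)
  mu2 <- sample_cluster_params(st2, x[1:50, ], h_inf)$clusters[[1]]$mu
  expect_equal(mu2, c(1, 1), tolerance = 1e-3)

  set.seed(9); d1 <- sample_cluster_params(st, x, h)
  set.seed(9); d2 <- sample_cluster_params(st, x, h)
  expect_identical(d1, d2)
})

test_that("alpha updates follow the MH contract and recover the prior", {
  st <- structure(list(z = rep(1L, 10),
                       clusters = list(list(mu = c(0, 0), R = diag(2),
                                            count = 10L)),
                       alpha = 1), class = "dp_state")
  # sd = 0 proposes the current value: alpha unchanged
  set.seed(4)
  expect_equal(sample_alpha(st, n = 10, sd = 0)$alpha, 1)

  # with the likelihood removed, long-run samples follow the prior
  # 1/alpha ~ Exp(1), so 1/alpha has mean 1
  set.seed(11)
  cur <- st
  inv_draws <- numeric(4000)
  for (it in seq_len(4000)) {
    cur <- sample_alpha(cur, n = 10, likelihood = FALSE)
    inv_draws[it] <- 1 / cur$alpha
  }
  expect_lt(abs(mean(inv_draws[-(1:500)]) - 1), 0.15)

  # more occupied clusters push alpha up stochastically
  many <- structure(list(z = 1:10, alpha = 1,
                         clusters = lapply(1:10, function(k)
                           list(mu = c(0, 0), R = diag(2), count = 1L))),
                    class = "dp_state")
  a_hi <- a_lo <- numeric(500)
  set.seed(21)
  cur <- many
  for (it in seq_len(500)) { cur <- sample_alpha(cur, n = 10); a_hi[it] <- cur$alpha }
  cur <- st
  for (it in seq_len(500)) { cur <- sample_alpha(cur, n = 10); a_lo[it] <- cur$alpha }
  expect_gt(mean(a_hi), mean(a_lo))
})

test_that("DP fit keeps counts consistent and is reproducible", {
  sim <- simulate_snp(snp_sim_spec(maf = 0.2, n = 60, outlier_frac = 0),
                      seed = 31)
  f <- fit_dp_gmm(sim$x, n_iter = 400, burn_in = 100, seed = 5)
  expect_equal(length(f$consensus_z), 60L)
  expect_equal(sum(tabulate(f$consensus_z)), 60L)
  expect_true(all(tabulate(f$consensus_z, f$n_occupied) >= 1L))
  expect_equal(rowSums(f$resp), rep(1, 60), tolerance = 1e-9)
  f2 <- fit_dp_gmm(sim$x, n_iter = 400, burn_in = 100, seed = 5)
  expect_identical(f$consensus_z, f2$consensus_z)
  expect_identical(f$alpha_trace, f2$alpha_trace)
  expect_error(fit_dp_gmm(sim$x, n_iter = 100, burn_in = 100), "n_iter")

  one <- fit_dp_gmm(matrix(c(10, 20), 1, 2), hyper = toy_hyper(),
                    n_iter = 50, burn_in = 10, seed = 1)
  expect_equal(one$n_occupied, 1L)
})

test_that("consensus recovers two well-separated clusters", {
  sim <- simulate_snp(snp_sim_spec(maf = 0.35, n = 200,
                                   counts = c(130, 70, 0), outlier_frac = 0),
                      seed = 41)
  f <- fit_dp_gmm(sim$x, seed = 9)
  expect_equal(f$n_occupied, 2L)
  agree <- table(f$consensus_z, sim$truth$genotype)
  expect_gte(sum(apply(agree, 1, max)), 198)
})

test_that("a 5-member minor cluster is recovered in the consensus", {
  k3 <- 0L
  coassigned <- 0L
  for (s in 1:10) {
    sim <- simulate_snp(snp_sim_spec(maf = 0.1, n = 120,
                                     counts = c(100, 15, 5), outlier_frac = 0),
                        seed = 51 + s)
    f <- fit_dp_gmm(sim$x, seed = 13 + s)
    k3 <- k3 + (f$n_occupied == 3L)
    minor <- which(sim$truth$genotype == "BB")
    coassigned <- coassigned + (max(table(f$consensus_z[minor])) >= 4L)
  }
  expect_gte(k3, 8L)           # three clusters found in most replicates
  expect_gte(coassigned, 9L)   # the 5 minor points travel together
})

test_that("DP genotype mapping follows the contrast regions", {
  # single cluster at high contrast -> all AA
  sim <- simulate_snp(snp_sim_spec(maf = 0, n = 80, outlier_frac = 0),
                      seed = 61)
  f <- fit_dp_gmm(sim$x, seed = 3)
  calls <- dp_calls_to_genotypes(f, 0.85)
  expect_true(all(calls$genotype == "AA"))

  # two clusters at y ~ {0.8, 0} -> AA and AB
  sim2 <- simulate_snp(snp_sim_spec(maf = 0.3, n = 150,
                                    counts = c(100, 50, 0), outlier_frac = 0),
                       seed = 62)
  f2 <- fit_dp_gmm(sim2$x, seed = 4)
  calls2 <- dp_calls_to_genotypes(f2, 0.85)
  expect_setequal(unique(calls2$genotype[calls2$genotype != "NC"]),
                  c("AA", "AB"))
  tab <- table(calls2$genotype, sim2$truth$genotype)
  expect_gte(tab["AA", "AA"], 95)
  expect_gte(tab["AB", "AB"], 45)

  # more than three occupied clusters: extra-cluster members are NC
  f4 <- f2
  f4$n_occupied <- 4L
  f4$assignment <- f4$consensus_z <- rep(1:4, length.out = 150)
  f4$mu <- rbind(c(1800, 200), c(1400, 600), c(1000, 1000), c(600, 1400))
  f4$pr <- rep(1, 150)
  calls4 <- dp_calls_to_genotypes(f4, 0.85)
  counts <- tabulate(f4$assignment, 4)
  unlabeled <- setdiff(1:4, utils::head(order(counts, decreasing = TRUE), 3))
  expect_true(all(calls4$genotype[f4$assignment == unlabeled] == "NC"))
  expect_true(all(calls4$genotype[f4$assignment != unlabeled] != "NC"))
})
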