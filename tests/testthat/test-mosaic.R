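mk_sites <- function(n = 4, dp = 100L, ad_alt = 50L, pos = NULL) {
  data.frame(site_id = sprintf("s%03d", seq_len(n)),
             sample_id = "T0001", gene = sprintf("g%02d", seq_len(n)),
             chrom = "1",
             pos = if (is.null(pos)) seq(1000, by = 10000, length.out = n)
                   else pos,
             dp = dp, ad_alt = ad_alt, ad_ref = dp - ad_alt,
             adf_alt = ad_alt %/% 2L, adr_alt = ad_alt - ad_alt %/% 2L,
             adf_ref = (dp - ad_alt) %/% 2L,
             adr_ref = (dp - ad_alt) - (dp - ad_alt) %/% 2L,
             parental_alt = 0L, pop_af = 0, cohort_ac = 1L,
             mismatch_support = 0L, flags = "", stringsAsFactors = FALSE)
}

test_that("preprocessing filters remove depth, cluster and frequency failures", {
  s <- mk_sites(5)
  s$dp[1] <- 501L; s$ad_alt[1] <- 200L; s$ad_ref[1] <- 301L
  s$pos[2] <- 5000L; s$pos[3] <- 5009L       # 9 bp apart, same sample
  s$pop_af[4] <- 1e-3
  out <- cumc_prefilter(s)
  expect_equal(unname(out$tally["depth_cap"]), 1L)
  expect_equal(unname(out$tally["complex_cluster"]), 2L)
  expect_equal(unname(out$tally["pop_af"]), 1L)
  expect_equal(out$retained$site_id, "s005")

  clean <- mk_sites(3)
  out2 <- cumc_prefilter(clean)
  expect_equal(nrow(out2$retained), 3)
  expect_true(all(out2$tally == 0))

  # cohort-frequency and outlier-sample rules
  s3 <- mk_sites(10, pos = seq(1e4, by = 1e6, length.out = 10))
  s3$cohort_ac <- c(10L, rep(1L, 9))
  out3 <- cumc_prefilter(s3, n_cohort = 465)
  expect_equal(unname(out3$tally["cohort_freq"]), 1L)
  expect_equal(unname(out3$tally["outlier_sample"]), 9L)  # 9 SNVs left in T0001
})

test_that("strand-bias rule flags one-sided and skewed tables only", {
  expect_true(strand_bias_flag(50, 50, 0, 10))
  expect_false(strand_bias_flag(50, 50, 25, 25))
  # [[90,10],[5,45]]: OR = 81, Fisher p << 1e-3
  expect_true(strand_bias_flag(90, 10, 5, 45))
  # strong p but OR inside (1/3, 3) must not flag
  expect_false(strand_bias_flag(1000, 1000, 500, 520))
})

test_that("PHET matches the exact binomial oracle", {
  expect_equal(phet(50, 100), 1)
  expect_equal(phet(0, 10), 2 * 2^-10, tolerance = 1e-15)
  expect_lt(phet(5, 100), 1e-15)
  set.seed(8)
  for (i in 1:40) {
    n <- sample(500, 1)
    k <- sample(0:n, 1)
    expect_equal(phet(k, n), binom.test(k, n, 0.5)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("Clopper-Pearson upper bound matches closed form and a root-finding oracle", {
  for (n in c(5, 20, 100)) {
    expect_equal(vaf_ci_upper(0, n), 1 - 0.05^(1 / n), tolerance = 1e-12)
  }
  expect_equal(vaf_ci_upper(10, 10), 1)
  expect_equal(vaf_ci_upper(10, 100), 0.1637176, tolerance = 1e-6)
  # oracle: upper limit solves P(X <= k; p) = 0.05
  for (case in list(c(10, 100), c(3, 40), c(120, 480))) {
    k <- case[1]; n <- case[2]
    u <- uniroot(function(p) pbinom(k, n, p) - 0.05, c(1e-9, 1 - 1e-9),
                 tol = 1e-12)$root
    expect_equal(vaf_ci_upper(k, n), u, tolerance = 1e-8)
  }
})

test_that("filter-branch classification applies candidate and mosaic rules", {
  s <- mk_sites(5, dp = 100L, ad_alt = c(4L, 12L, 45L, 12L, 12L))
  s$parental_alt[4] <- 5L
  s$flags[5] <- "segdup"
  out <- ohsu_classify(s)
  expect_equal(out$label, c("filtered", "mosaic", "germline",
                            "filtered", "filtered"))
  expect_false(out$candidate[1])  # only 4 alt reads
  expect_equal(out$phet[2], phet(12, 100))
  expect_lt(out$ci90_upper[2], 0.4)
  expect_gt(out$phet[3], 0.001)
  # externally supplied classifier scores can veto calls
  out2 <- ohsu_classify(s, scores = c(1, 0.1, 1, 1, 1))
  expect_equal(out2$label[2], "germline")
})

test_that("overdispersion estimation recovers the generating rho", {
  set.seed(14)
  n <- 10000
  dp <- pmin(rnbinom(n, mu = 80, size = 10) + 1L, 500L)
  # binomial limit
  th0 <- estimate_theta(dp, rbinom(n, dp, 0.5))
  expect_lte(th0$theta_hat, 0.005)
  # rho = 0.05 recovery
  th <- estimate_theta(dp, rbetabinom(n, dp, 0.5, 0.05))
  expect_gte(th$theta_hat, 0.04)
  expect_lte(th$theta_hat, 0.06)
  # per-bin MLE agrees with a grid-search oracle on one bin
  b <- th$theta_per_bin$bin[which.max(th$theta_per_bin$n)]
  idx <- (dp - 1L) %/% 10L == b
  grid <- seq(0.001, 0.2, by = 0.001)
  ad <- rbetabinom(sum(idx), dp[idx], 0.5, 0.05)
  ll <- vapply(grid, function(r) sum(dbetabinom(ad, dp[idx], 0.5, r,
                                                log = TRUE)), numeric(1))
  opt <- optimize(function(r) -sum(dbetabinom(ad, dp[idx], 0.5, r,
                                              log = TRUE)), c(0, 0.99))
  expect_lt(abs(grid[which.max(ll)] - opt$minimum), 0.002)
  # single bin: global equals the bin estimate
  th1 <- estimate_theta(rep(80L, 500), rbetabinom(500, 80, 0.5, 0.05))
  expect_equal(th1$theta_hat, th1$theta_per_bin$theta[1])
})

test_that("EM mixture drives the mosaic fraction to zero on pure germline data", {
  s <- mk_sites(200, dp = 400L, ad_alt = 200L)
  em <- em_mosaic(s, 0.01)
  expect_lt(em$pi_m, 1e-3)
  expect_true(all(em$calls$posterior_odds < 1))
  expect_true(all(diff(em$loglik) > -1e-8))
})

test_that("EM estimates are order-invariant and match direct likelihood maximization", {
  set.seed(19)
  n <- 2000
  dp <- pmin(rnbinom(n, mu = 80, size = 10) + 1L, 500L)
  mos <- runif(n) < 0.10
  ad <- rbetabinom(n, dp, ifelse(mos, runif(n, 0.03, 0.35), 0.5), 0.03)
  s <- data.frame(site_id = sprintf("s%04d", 1:n), dp = dp, ad_alt = ad)
  grid <- seq(0.03, 0.35, length.out = 50)
  em <- em_mosaic(s, 0.03, vaf_grid = grid)
  # permuting the input leaves the estimate unchanged
  perm <- sample(n)
  em_p <- em_mosaic(s[perm, ], 0.03, vaf_grid = grid)
  expect_equal(em_p$pi_m, em$pi_m, tolerance = 1e-9)
  # direct numerical maximization of the observed-data likelihood over pi
  lg <- dbetabinom(ad, dp, 0.5, 0.03, log = TRUE)
  lmm <- sapply(grid, function(f) dbetabinom(ad, dp, f, 0.03, log = TRUE))
  lmos <- apply(lmm, 1, function(x) max(x) + log(mean(exp(x - max(x)))))
  nll <- function(p) {
    a <- log(p) + lmos; b <- log(1 - p) + lg
    m <- pmax(a, b)
    -sum(m + log(exp(a - m) + exp(b - m)))
  }
  opt <- optimize(nll, c(1e-6, 0.5))
  expect_equal(em$pi_m, opt$minimum, tolerance = 1e-4)
  expect_equal(tail(em$loglik, 1), -opt$objective, tolerance = 1e-6)
  # responsibilities separate true labels at the Bayes-achievable level
  expect_gt(cor(em$calls$responsibility, as.numeric(mos),
                method = "spearman"), 0.4)
  # posterior odds decrease with distance from the heterozygous mean at fixed N
  fix <- data.frame(site_id = sprintf("f%02d", 1:5), dp = 200L,
                    ad_alt = c(100L, 80L, 60L, 40L, 20L))
  emf <- em_mosaic(fix, 0.03, vaf_grid = grid)
  expect_true(all(diff(emf$calls$posterior_odds) > 0))
})

test_that("q-values bound the realized false-mosaic fraction on synthetic data", {
  set.seed(23)
  n_seeds <- 10
  false_called <- 0; called <- 0
  for (r in seq_len(n_seeds)) {
    n <- 3000
    dp <- pmin(rnbinom(n, mu = 80, size = 10) + 1L, 500L)
    mos <- runif(n) < 0.10
    ad <- rbetabinom(n, dp, ifelse(mos, runif(n, 0.03, 0.35), 0.5), 0.05)
    s <- data.frame(site_id = as.character(1:n), dp = dp, ad_alt = ad)
    em <- em_mosaic(s, 0.05, vaf_grid = seq(0.03, 0.35, length.out = 50))
    sel <- em$calls$q_value <= 0.1
    called <- called + sum(sel)
    false_called <- false_called + sum(sel & !mos)
  }
  expect_gt(called, 100)
  expect_lte(false_called / called,
             0.1 + 3 * sqrt(0.1 * 0.9 / called))
})

test_that("union call set applies the posterior-odds retention rule", {
  oh <- data.frame(site_id = c("a", "b", "c", "d"),
                   label = c("mosaic", "mosaic", "mosaic", "germline"))
  cu <- data.frame(site_id = c("a", "b", "c", "d"),
                   label = c("mosaic", "germline", "germline", "mosaic"),
                   posterior_odds = c(50, 0.8, 1.2, 30))
  un <- union_mosaic_callset(oh, cu)
  expect_setequal(un$site_id, c("a", "c", "d"))
  expect_equal(un$branch[un$site_id == "a"], "ohsu,cumc")
  expect_equal(un$branch[un$site_id == "c"], "ohsu")
  expect_equal(un$branch[un$site_id == "d"], "cumc")
})
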