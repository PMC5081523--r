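test_that("ICE leaves balanced matrices alone and balances toy marginals", {
  # all off-diagonal entries equal: already balanced
  m <- dense_to_contact_matrix(matrix(1, 4, 4) - diag(4))
  res <- ice_normalize(m)
  expect_true(all(abs(res$bias - 1) < 1e-6))

  # unequal marginals (6, 4, 4) on a balanceable support
  toy <- dense_to_contact_matrix(matrix(c(0, 3, 3, 3, 0, 1, 3, 1, 0), 3))
  res <- ice_normalize(toy)
  W <- as_dense(res$corrected)
  rs <- rowSums(W)
  expect_lt(diff(range(rs)), 1e-6 * mean(rs))
})

test_that("zero-marginal bins are masked and excluded", {
  W <- matrix(c(0, 5, 0, 5, 0, 0, 0, 0, 0), 3)
  res <- ice_normalize(dense_to_contact_matrix(W))
  expect_equal(res$mask, c(FALSE, FALSE, TRUE))
  expect_true(is.na(res$bias[3]))
  bd <- collect_by_distance(res$corrected, 1, res$mask)
  expect_false("2" %in% names(bd))  # (0,2) masked out

  expect_error(ice_normalize(dense_to_contact_matrix(matrix(0, 3, 3))),
               "all-zero")
})

test_that("ICE converges to tiny marginal coefficient of variation", {
  for (s in 1:3) {
    m <- toy_matrix(25, seed = s)
    res <- ice_normalize(m)
    W <- as_dense(res$corrected)
    rs <- rowSums(W)[!res$mask]
    expect_lt(sd(rs) / mean(rs), 1e-4)
    # biases multiply back to the raw counts (up to the global rescale)
    raw <- as_dense(m)
    back <- W * outer(res$bias, res$bias)
    ratio <- back[raw > 0] / raw[raw > 0]
    expect_lt(diff(range(ratio)), 1e-6 * mean(ratio))
  }
})

test_that("distance collection counts pairs exactly and sums match brute force", {
  m <- toy_matrix(5)
  bd <- collect_by_distance(m)
  expect_equal(length(bd[["4"]]), 1)
  W <- as_dense(m)
  for (d in 1:4) {
    i <- seq_len(5 - d)
    expect_equal(sum(bd[[as.character(d)]]), sum(W[cbind(i, i + d)]))
  }
  m2 <- contact_matrix("c", 1e5, 100, data.frame(i = 0, j = 1, value = 1))
  expect_equal(length(collect_by_distance(m2)[["1"]]), 99)
})

test_that("sparse distances are pooled until thresholds are met", {
  obs <- list("1" = rep(c(0, 3), 30), "2" = rep(0, 40), "3" = rep(0, 40),
              "4" = c(rep(0, 50), rep(2, 10)))
  names(obs) <- 1:4
  g <- chromsteer:::pool_deltas(obs, min_n = 50, min_nonzero = 10)
  expect_equal(g[[1]], 1L)             # already satisfies both thresholds
  expect_equal(g[[2]], 2:4)            # grown until nonzeros arrive
})

test_that("ZiNB MLE recovers parameters and degenerates gracefully", {
  expect_equal(fit_zinb(rep(0, 100))$status, "degenerate")
  expect_equal(fit_zinb(integer(0))$status, "degenerate")

  set.seed(11)
  x <- rzinb(10000, 0.3, 2, 5)
  f <- fit_zinb(x)
  expect_equal(f$status, "ok")
  expect_lt(abs(f$pi - 0.3), 3 * f$se_pi)
  expect_lt(abs(f$theta - 2), 3 * f$se_theta)
  expect_lt(abs(f$mu - 5), 3 * f$se_mu)
  expect_equal(f$p, f$theta / (f$theta + f$mu))

  # order invariance
  f2 <- fit_zinb(sample(x))
  expect_equal(f2$pi, f$pi, tolerance = 1e-6)
  expect_equal(f2$loglik, f$loglik, tolerance = 1e-8)

  # log-likelihood at the optimum beats the moment start
  start_nll <- chromsteer:::zinb_nll(
    c(stats::qlogis(0.3), log(2), log(5)), x)
  expect_gte(f$loglik, -start_nll - 1e-6)
})

test_that("nested pure-NB data is recovered with vanishing zero inflation", {
  set.seed(12)
  x <- rnbinom(10000, size = 5, mu = 10)
  f <- fit_zinb(x)
  expect_lt(f$pi, 0.05)
  expect_lt(abs(f$theta - 5) / 5, 0.1)
  expect_lt(abs(f$mu - 10) / 10, 0.1)
})

test_that("censored fitting stays consistent on clean data", {
  set.seed(13)
  x <- rzinb(8000, 0.3, 2, 5)
  f <- fit_zinb(x, censor_q = 0.15)
  expect_equal(f$status, "ok")
  expect_lt(abs(f$pi - 0.3), 4 * f$se_pi)
  expect_lt(abs(f$mu - 5) / 5, 0.1)
})

test_that("ZiNB tail p-values are exact and monotone", {
  fit <- list(pi = 0.5, theta = 1, mu = 2, status = "ok")
  expect_identical(zinb_pvalue(0, fit), 1)
  expect_equal(zinb_pvalue(1, fit),
               (1 - 0.5) * (1 - dnbinom(0, size = 1, mu = 2)),
               tolerance = 1e-15)
  p <- zinb_pvalue(0:50, fit)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p > 0 & p <= 1))
  expect_error(zinb_pvalue(-1, fit), "non-negative")
  expect_error(zinb_pvalue(1, list(status = "degenerate")), "degenerate")
})

test_that("p-values agree with brute-force pmf tail sums to 1e-12", {
  grid <- expand.grid(pi = c(0, 0.2, 0.6), theta = c(0.5, 2, 10),
                      mu = c(0.5, 5, 40))
  xs <- c(1, 3, 10, 100, 1000)
  for (r in seq_len(nrow(grid))) {
    fit <- list(pi = grid$pi[r], theta = grid$theta[r], mu = grid$mu[r],
                status = "ok")
    for (x in xs) {
      # independent oracle: explicit pmf summation over the tail
      kmax <- 50000
      tail <- (1 - fit$pi) *
        sum(dnbinom(x:kmax, size = fit$theta, mu = fit$mu))
      expect_lt(abs(zinb_pvalue(x, fit) - tail), 1e-12)
    }
  }
})

test_that("BH selection follows the step-up rule per distance group", {
  tab <- data.frame(chrom = "c", i = 1:4, j = 3:6, delta = 1,
                    p = c(0.001, 0.004, 0.03, 0.5))
  sel <- bh_select(tab, alpha = 0.01)
  expect_equal(nrow(sel), 2)
  expect_equal(sort(sel$p), c(0.001, 0.004))

  expect_equal(nrow(bh_select(tab[0, ], alpha = 0.01)), 0)
  tab$p <- 1
  expect_equal(nrow(bh_select(tab, alpha = 0.01)), 0)

  # groups corrected independently: same p-values, different m per group
  tab2 <- data.frame(chrom = "c", i = c(1, 1:8), j = c(3, 5:12),
                     delta = c(1, rep(2, 8)),
                     p = c(0.009, 0.009, rep(0.9, 7)))
  sel2 <- bh_select(tab2, alpha = 0.01)
  expect_equal(sel2$delta, 1)  # singleton group passes, diluted group fails
})

test_that("the full caller returns coherent tables on a planted matrix", {
  set.seed(21)
  tr <- synthetic_truth(80, planted = sample_planted(20, 80, fold = 50))
  m <- gen_hic_matrix(tr, seed = 5)
  res <- call_contacts(m)
  cc <- res$contacts
  expect_true(all(cc$q <= 0.01))
  expect_true(all(cc$p > 0 & cc$p <= 1))
  expect_true(all(cc$j > cc$i))
  expect_equal(cc$delta, cc$j - cc$i)
  expect_true(all(diff(order(cc$i, cc$j)) > 0))
  # most selections are planted pairs on this easy instance (the remainder
  # are the false discoveries a 1% FDR procedure is allowed)
  key_t <- paste(tr$planted$i, tr$planted$j)
  expect_gt(mean(paste(cc$i, cc$j) %in% key_t), 0.7)
  expect_gt(mean(key_t %in% paste(cc$i, cc$j)), 0.7)
  # params table covers the distance range with ok/pooled fits
  expect_true(all(res$params$status %in% c("ok", "pooled", "degenerate")))
  f <- withr::local_tempfile()
  write_contacts(cc, f)
  expect_equal(nrow(read_contacts(f)), nrow(cc))
})
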