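test_that("satisfaction matches the brute-force oracle and is monotone", {
  set.seed(31)
  coords <- matrix(rnorm(300, sd = 400), 100, 3)
  tab <- data.frame(chain = 1, a0 = seq(0, 40, 10), a1 = seq(5, 45, 10),
                    b0 = seq(50, 90, 10), b1 = seq(55, 95, 10),
                    s = 50, k_init = 0, k_max = 0)
  rs <- chromsteer:::new_restraint_set(tab, "steering", NA, 1,
                                       data.frame(tau = 0, d0 = 0))
  sc <- satisfaction(list(coords), rs, cutoffs = c(120, 240, 480))
  for (crit in c("com", "closest")) for (cut in c(120, 240, 480)) {
    got <- sc$fraction[sc$criterion == crit & sc$cutoff == cut]
    expect_equal(got, mean(oracle_satisfaction(coords, tab, cut, crit)))
  }
  # monotone in cutoff; closest-bead >= COM at equal cutoff
  for (crit in c("com", "closest")) {
    fr <- sc$fraction[sc$criterion == crit][order(c(120, 240, 480))]
    expect_true(all(diff(fr) >= 0))
  }
  for (cut in c(120, 240, 480)) {
    expect_gte(sc$fraction[sc$criterion == "closest" & sc$cutoff == cut],
               sc$fraction[sc$criterion == "com" & sc$cutoff == cut])
  }
})

test_that("satisfaction hits the trivial extremes", {
  A <- matrix(rep(c(0, 0, 0), each = 66), 66, 3)
  tab <- data.frame(chain = 1, a0 = 0, a1 = 33, b0 = 33, b1 = 66, s = 33,
                    k_init = 0, k_max = 0)
  rs <- chromsteer:::new_restraint_set(tab, "steering", NA, 1,
                                       data.frame(tau = 0, d0 = 0))
  sc <- satisfaction(list(A), rs)
  expect_true(all(sc$fraction == 1))
  A[34:66, 1] <- 10000
  sc <- satisfaction(list(A), rs)
  expect_true(all(sc$fraction == 0))
})

test_that("distance matrices average bins and match brute force", {
  coords <- cbind(seq_len(66) * 10, 0, 0)  # collinear, 2 bins of 33
  D <- distance_matrix(coords, 33)
  expect_equal(dim(D), c(2, 2))
  expect_equal(D[1, 2], 330)
  expect_equal(diag(D), c(0, 0))

  set.seed(32)
  coords <- matrix(rnorm(99 * 3), 99, 3)
  D <- distance_matrix(coords, 33)
  means <- t(sapply(0:2, function(b) colMeans(coords[b * 33 + 1:33, ])))
  expect_equal(D, unname(as.matrix(dist(means))), ignore_attr = TRUE)
  expect_equal(D, t(D))
})

test_that("Kendall association recovers perfect orderings and matches counting", {
  n <- 12
  set.seed(33)
  H <- matrix(0, n, n)
  H[upper.tri(H)] <- sample(100, sum(upper.tri(H)))
  H <- H + t(H)
  Dm <- 1 / (H + 1)  # strictly decreasing transform
  out <- kendall_vs_hic(Dm, H, thresholds = 1)
  expect_equal(out$tau, -1)
  out2 <- kendall_vs_hic(H, H, thresholds = 1)
  expect_equal(out2$tau, 1)

  # brute-force concordant/discordant counting on a 6x6 toy
  n <- 6
  H <- matrix(0, n, n); H[upper.tri(H)] <- sample(50, 15); H <- H + t(H)
  Dm <- matrix(0, n, n); Dm[upper.tri(Dm)] <- rnorm(15); Dm <- Dm + t(Dm)
  got <- kendall_vs_hic(Dm, H, thresholds = 1)$tau
  x <- Dm[upper.tri(Dm)]; y <- H[upper.tri(H)]
  nc <- 0; nd <- 0
  for (a in 1:14) for (b in (a + 1):15) {
    s <- sign(x[a] - x[b]) * sign(y[a] - y[b])
    if (s > 0) nc <- nc + 1 else if (s < 0) nd <- nd + 1
  }
  n0 <- choose(15, 2)
  tx <- sum(sapply(table(x), choose, 2)); ty <- sum(sapply(table(y), choose, 2))
  tau_b <- (nc - nd) / sqrt((n0 - tx) * (n0 - ty))
  expect_equal(got, tau_b, tolerance = 1e-12)

  # thresholds with too few pairs are flagged
  out3 <- kendall_vs_hic(Dm, H, thresholds = 5)
  expect_true(out3$omitted)
})

test_that("radial profiles bin beads into shells correctly", {
  sys <- coil_system(1, 990, r_nuc = 4800, seed = 5)
  sys$track_flags <- list(genes = rep(c(TRUE, FALSE), length.out = 990))
  # all beads near the centre: feature only in inner shells
  sys$coords <- sys$coords / max(1, max(sqrt(rowSums(sys$coords^2))) / 300)
  rp <- radial_profiles(list(sys$coords), sys, n_shells = 15)
  inner <- rp$profile[rp$profile$feature == "genes" & rp$profile$shell == 1, ]
  expect_equal(inner$r_hi, 320)
  occupied <- rp$profile$n_beads > 0
  expect_true(all(is.na(rp$profile$percent[!occupied])))
  expect_true(all(rp$profile$percent[occupied] >= 0 &
                  rp$profile$percent[occupied] <= 100))
  # feature on every bead: 100% in every occupied shell
  sys$track_flags <- list(all = rep(TRUE, 990))
  rp <- radial_profiles(list(sys$coords), sys)
  expect_true(all(rp$profile$percent[rp$profile$n_beads > 0] == 100))
  # brute-force check of one shell
  sys$track_flags <- list(genes = rep(c(TRUE, FALSE), length.out = 990))
  rp <- radial_profiles(list(sys$coords), sys)
  r <- sqrt(rowSums(sys$coords^2))
  sh <- pmin(15, pmax(1, findInterval(r, seq(0, 4800, length.out = 16),
                                      rightmost.closed = TRUE)))
  k <- sh[1]
  expect_equal(rp$profile$percent[rp$profile$feature == "genes" &
                                    rp$profile$shell == k],
               100 * sum(sys$track_flags$genes & sh == k) / sum(sh == k))
  # per-bin radial statistics across replicates
  reps <- list(sys$coords, sys$coords + 10)
  rp2 <- radial_profiles(reps, sys)
  expect_equal(nrow(rp2$bins), 990 %/% 33)
  expect_true(all(rp2$bins$sd_r >= 0))
})

test_that("macrodomain partition equals the exhaustive optimum", {
  set.seed(34)
  for (trial in 1:6) {
    m <- sample(6:12, 1); K <- sample(2:4, 1)
    P <- matrix(runif(m * 3, 0, 1200), m, 3)
    D <- chromsteer:::capped_dissimilarity(as.matrix(dist(P)))
    part <- macrodomain_partition(as.matrix(dist(P)), list(1:m), K)
    expect_equal(partition_cost(D, part$domain), oracle_partition_cost(D, K),
                 tolerance = 1e-9)
    expect_equal(length(unique(part$domain)), K)
    expect_true(all(diff(part$domain) %in% 0:1))  # contiguous, ordered
  }
})

test_that("two-block structure and edge cases are recovered", {
  D <- matrix(1500, 10, 10)
  D[1:4, 1:4] <- 100; D[5:10, 5:10] <- 100; diag(D) <- 0
  part <- macrodomain_partition(D, list(1:10), 2)
  expect_equal(part$domain, rep(1:2, c(4, 6)))

  expect_equal(unique(macrodomain_partition(D, list(1:10), 1)$domain), 1)
  expect_error(macrodomain_partition(D, list(1:10), 11), "more domains")

  # the dissimilarity rule: below 750 kept, above set to 1000
  Dm <- matrix(c(0, 600, 900, 600, 0, 1400, 900, 1400, 0), 3)
  Delta <- chromsteer:::capped_dissimilarity(Dm)
  expect_equal(Delta[1, 2], 600)
  expect_equal(Delta[1, 3], 1000)
  expect_equal(Delta[2, 3], 1000)
})

test_that("partition overlap counts label agreement with exclusions", {
  expect_equal(partition_overlap(c(1, 1, 1, 2, 2), c(1, 1, 2, 2, 2)), 0.8)
  p <- macrodomain_partition(matrix(0, 6, 6) + 100 - diag(100, 6),
                             list(1:6), 2)
  expect_equal(partition_overlap(p, p), 1)
  expect_equal(partition_overlap(c(1, 1, 2, 2), c(1, 2, 2, 2), exclude = 2),
               1)
  expect_error(partition_overlap(c(1, 1), c(1, 1, 2)), "different")
})

test_that("overlap significance separates identical from random partitions", {
  set.seed(35)
  a <- rep(1:4, c(5, 7, 6, 7))
  pa <- data.frame(arm = 1, segment = 1:25, domain = a)
  res <- overlap_significance(pa, pa, n_random = 1000, seed = 2)
  expect_equal(res$q, 1)
  expect_lte(res$p_value, 0.05)
  expect_length(res$q_random, 1000)
})

test_that("Procrustes RMSD is zero under rigid motion and matches vegan", {
  set.seed(36)
  A <- matrix(rnorm(12), 4, 3)
  expect_equal(procrustes_rmsd(A, A), 0, tolerance = 1e-12)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  B <- A %*% R + matrix(rep(c(5, -3, 2), each = 4), 4, 3)
  expect_lt(procrustes_rmsd(A, B), 1e-9)

  # independent oracle: vegan's Procrustes superposition (no scaling)
  skip_if_not_installed("vegan")
  B2 <- A + matrix(rnorm(12, sd = 0.3), 4, 3)
  pv <- vegan::procrustes(A, B2, scale = FALSE, symmetric = FALSE)
  expect_equal(procrustes_rmsd(A, B2), sqrt(mean(residuals(pv)^2)),
               tolerance = 1e-9)
  expect_error(procrustes_rmsd(A[1:2, ], B2[1:2, ]), "3 points")
})

test_that("MDS reconstruction is self-consistent and metric-completing", {
  # contacts derived exactly from inverse distances of collinear points
  x <- cbind(seq(0, 9) * 2, 0, 0)
  D0 <- as.matrix(dist(x))
  H <- ifelse(D0 > 0, 1 / D0, 0)
  rec <- mds_reconstruct(H, alpha = 1)
  expect_lt(procrustes_rmsd(x, rec$coords), 1e-6)
  # completed metric satisfies the triangle inequality
  SP <- rec$dist
  n <- nrow(SP)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(SP[i, j], SP[i, k] + SP[k, j] + 1e-9)

  # complete uniform matrix -> regular simplex (n = 4)
  H4 <- matrix(1, 4, 4) - diag(4)
  rec4 <- mds_reconstruct(H4)
  pd <- dist(rec4$coords)
  expect_lt(diff(range(pd)), 1e-6)

  # disconnected graph errors
  H2 <- matrix(0, 4, 4); H2[1, 2] <- H2[2, 1] <- 1; H2[3, 4] <- H2[4, 3] <- 1
  expect_error(mds_reconstruct(H2), "disconnected")
})
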