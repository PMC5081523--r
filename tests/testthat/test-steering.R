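test_that("restraints duplicate per homolog copy and map bins to beads", {
  spec <- toy_spec(1, 2e6, copy_number = 2L)
  sys <- build_system(spec, rosette = list(n_loop = 15, n_petals = 4))
  contacts <- data.frame(chrom = "chr1", i = 3, j = 10)
  rs <- build_restraints(contacts, sys)
  expect_equal(nrow(rs$table), 2)
  # first copy: global offset 0
  expect_equal(rs$table$a0[1], 99)
  expect_equal(rs$table$a1[1], 132)
  expect_equal(rs$table$b0[1], 330)
  expect_equal(rs$table$b1[1], 363)
  # second copy shifted by one chain length
  off <- sys$chains$first[2] - 1
  expect_equal(rs$table$a0[2], off + 99)
  # ranges stay within one chain
  expect_true(all(rs$table$b1 <= sys$chains$first + sys$chains$n_beads - 1 +
                    1)[1])

  spec1 <- toy_spec(1, 2e6, copy_number = 1L)
  spec1$chroms$chrom <- "chrX"
  sysX <- build_system(spec1, rosette = list(n_loop = 15, n_petals = 4))
  rsX <- build_restraints(data.frame(chrom = "chrX", i = 0, j = 5), sysX)
  expect_equal(nrow(rsX$table), 1)

  expect_error(build_restraints(data.frame(chrom = "chr1", i = 0, j = 500),
                                sys), "outside")
  expect_error(build_restraints(data.frame(chrom = "chrZ", i = 0, j = 1),
                                sys), "not in the system")
})

test_that("entropy-matched spring constants follow the WLC recoil formula", {
  expect_equal(init_spring_constant(1000), 3 / (2 * 150 * 30000))
  expect_equal(init_spring_constant(1000), 3.333e-7, tolerance = 1e-3)
  expect_equal(init_spring_constant(2000), init_spring_constant(1000) / 2)
  s <- c(66, 100, 500, 2000)
  expect_true(all(diff(init_spring_constant(s)) < 0))
  expect_warning(k <- init_spring_constant(10), "clamping")
  expect_equal(k, init_spring_constant(66))
})

test_that("restraint forces are equal and opposite to machine precision", {
  set.seed(41)
  sys <- coil_system(1, 300, r_nuc = 2000, seed = 5)
  tab <- data.frame(chain = 1, a0 = c(0, 100), a1 = c(33, 133),
                    b0 = c(200, 250), b1 = c(233, 283), s = 200,
                    k_init = 1e-4, k_max = 0.1)
  rs <- chromsteer:::new_restraint_set(tab, "steering", NA, 1,
                                       data.frame(tau = 0, d0 = 0))
  f <- restraint_forces(sys, rs, ramp_frac = 0.5, d0 = 0)
  FA <- colSums(f$forces[1:33, ]) + colSums(f$forces[101:133, ])
  FB <- colSums(f$forces[201:233, ]) + colSums(f$forces[251:283, ])
  expect_equal(FA, -FB, tolerance = 1e-12)
  expect_lt(max(abs(colSums(f$forces))), 1e-10)
  # beads outside the restrained ranges feel nothing
  expect_equal(max(abs(f$forces[34:100, ])), 0)
})

test_that("the recondensation schedule lands exactly on the bead size", {
  sch <- recondensation_schedule()
  expect_equal(sch$d0, c(200, 170, 140, 110, 80, 50, 30))
  expect_equal(sch$tau, seq(0, 3.6, by = 0.6))
  expect_equal(sch$d0[nrow(sch)], 30)
})

test_that("loop anchors are spaced at 66 beads with end coverage", {
  sys <- coil_system(1, 66, r_nuc = 2000, seed = 2)
  rs <- loop_anchor_restraints(sys)
  expect_equal(nrow(rs$table), 1)
  expect_equal(c(rs$table$a0, rs$table$b0), c(0, 65))
  # all anchors are single beads
  expect_true(all(rs$table$a1 - rs$table$a0 == 1))

  sys2 <- coil_system(1, 150, r_nuc = 2000, seed = 2)
  rs2 <- loop_anchor_restraints(sys2)
  expect_equal(nrow(rs2$table), 2)  # anchors at 0, 66, 149 (end absorbed)
  expect_equal(rs2$table$b0[2], 149)

  sys3 <- coil_system(1, 30, r_nuc = 2000, seed = 2)
  expect_warning(rs3 <- loop_anchor_restraints(sys3), "shorter")
  expect_equal(nrow(rs3$table), 0)
})

test_that("steering pulls target regions together", {
  dists <- sapply(1:6, function(seed) {
    sys <- coil_system(1, 500, r_nuc = 3000, seed = seed)
    eq <- langevin_run(sys, duration_tau = 20, seed = seed,
                       soft_start_tau = 4, snapshot_every_tau = 0)
    sys <- eq$system
    tab <- data.frame(chain = 1, a0 = 100, a1 = 133, b0 = 400, b1 = 433,
                      s = 300, k_init = init_spring_constant(300),
                      k_max = 0.1)
    rs <- chromsteer:::new_restraint_set(tab, "steering", NA, 1,
                                         data.frame(tau = 0, d0 = 0))
    comd <- function(x) sqrt(sum((colMeans(x[101:133, ]) -
                                    colMeans(x[401:433, ]))^2))
    st <- steer(sys, rs, duration_tau = 120, seed = seed + 50,
                snapshot_every_tau = 0)
    c(before = comd(sys$coords), after = comd(st$system$coords))
  })
  expect_gte(sum(dists["after", ] < dists["before", ]), 5)
  expect_lt(median(dists["after", ]), 480)
})

test_that("steering with no restraints reduces to plain dynamics", {
  sys <- coil_system(1, 200, r_nuc = 2000, seed = 9)
  sys <- langevin_run(sys, duration_tau = 10, seed = 9, soft_start_tau = 4,
                      snapshot_every_tau = 0)$system
  rs <- chromsteer:::new_restraint_set(
    data.frame(chain = integer(), a0 = integer(), a1 = integer(),
               b0 = integer(), b1 = integer(), s = integer(),
               k_init = numeric(), k_max = numeric()),
    "steering", NA, 1, data.frame(tau = 0, d0 = 0))
  st <- steer(sys, rs, duration_tau = 10, seed = 10, snapshot_every_tau = 0)
  ref <- langevin_run(sys, duration_tau = 10, seed = 10,
                      snapshot_every_tau = 0)
  expect_equal(st$system$coords, ref$system$coords)
})

test_that("added restraints keep the old set and report both fractions", {
  sys <- coil_system(1, 400, r_nuc = 1200, seed = 21)
  eq <- langevin_run(sys, duration_tau = 20, seed = 21, soft_start_tau = 4,
                     snapshot_every_tau = 0)
  sys <- eq$system
  mk <- function(a0, b0) data.frame(chain = 1, a0 = a0, a1 = a0 + 33,
                                    b0 = b0, b1 = b0 + 33, s = b0 - a0,
                                    k_init = 1e-5, k_max = 0.1)
  old <- chromsteer:::new_restraint_set(mk(0, 200), "steering", NA, 1,
                                        data.frame(tau = 0, d0 = 0))
  st <- steer(sys, old, duration_tau = 100, seed = 22,
              snapshot_every_tau = 0)
  extra <- chromsteer:::new_restraint_set(mk(100, 300), "steering", NA, 1,
                                          data.frame(tau = 0, d0 = 0))
  out <- add_restraints_and_continue(st$system, old, extra,
                                     duration_tau = 100, seed = 23,
                                     snapshot_every_tau = 25)
  expect_s3_class(out$satisfaction_old, "satisfaction_curve")
  expect_equal(nrow(out$maintained), 3)   # one row per cutoff
  expect_equal(nrow(out$established), 3)
  expect_true(all(out$maintained$fraction >= 0 &
                  out$maintained$fraction <= 1))

  # identical extra set: established fraction equals maintained fraction
  out2 <- add_restraints_and_continue(st$system, old, old,
                                      duration_tau = 30, seed = 24,
                                      snapshot_every_tau = 10)
  expect_equal(out2$maintained$fraction, out2$established$fraction)
})

test_that("recondensation compacts chains and reports satisfaction", {
  sys <- coil_system(2, 200, r_nuc = 1500, seed = 31)
  eq <- langevin_run(sys, duration_tau = 20, seed = 31, soft_start_tau = 4,
                     snapshot_every_tau = 0)
  rec <- recondense(eq$system, spacing = 66, hold_tau = 60, seed = 32,
                    snapshot_every_tau = 10)
  expect_equal(nrow(rec$restraints$table), 6)  # anchors 0,66,132,199 per chain
  sc <- rec$satisfaction
  first <- sc[sc$time_tau == min(sc$time_tau) & sc$criterion == "com" &
                sc$cutoff == 120, "fraction"]
  last <- sc[sc$time_tau == max(sc$time_tau) & sc$criterion == "com" &
               sc$cutoff == 120, "fraction"]
  expect_gte(last, first)
  expect_gte(last, 0.5)
  # d0 schedule reached its terminal 30 nm value
  expect_equal(rec$traj$d0[length(rec$traj$d0)], 30)
})
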