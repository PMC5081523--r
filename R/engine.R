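#' Force-field parameters for the bead-spring chromatin model
#'
#' Kremer-Grest defaults in reduced units (energies in kT, lengths in nm):
#' FENE bonds with K = 30 eps/sigma^2 and R0 = 1.5 sigma, WCA excluded
#' volume with unit eps, Kratky-Porod bending constant kappa = 5 eps
#' (targeting a persistence length of 5 sigma = 150 nm), a confining
#' harmonic wall with capped force, and an attractive cut-shifted LJ between
#' centromeric beads of the same chain (depth 1 eps, cutoff 1.5 sigma).
#' Timestep 0.012 tau_LJ and friction 0.5 / tau_LJ are stable standard
#' choices for this force field.
#'
#' @param sigma bead diameter (nm).
#' @param r_nuc nucleus radius (nm); `Inf` disables the wall.
#' @param overrides named list overriding any parameter: `fene_k` (eps/nm^2),
#'   `fene_r0` (nm), `kappa` (eps), `wall_k` (eps/nm^2), `wall_fcap`
#'   (eps/nm), `cen_eps` (eps), `cen_cut` (nm), `dt` (tau_LJ), `gamma`
#'   (1/tau_LJ), `temp` (kT).
#' @return named list of parameters in internal units (nm, eps, time with
#'   tau_LJ = sigma).
#' @export
forcefield_params <- function(sigma = .sigma_default, r_nuc = .rnuc_default,
                              overrides = list()) {
  tau <- sigma  # tau_LJ = sigma * sqrt(m/eps), m = eps = 1
  p <- list(sigma = sigma,
            fene_k = 30 / sigma^2,
            fene_r0 = 1.5 * sigma,
            kappa = 5,
            r_nuc = r_nuc,
            wall_k = 1,
            wall_fcap = 1,
            cen_eps = 1,
            cen_cut = 1.5 * sigma,
            dt = 0.012,
            gamma = 0.5,
            temp = 1,
            pair_fcap = 0,
            max_step = 0)
  p <- utils::modifyList(p, overrides)
  if (p$dt > 0.012 + 1e-12)
    stop("dt must be <= 0.012 tau_LJ for integrator stability")
  # convert tau-denominated quantities to internal time units
  p$dt <- p$dt * tau
  p$gamma <- p$gamma / tau
  p
}

#' Forces and energy of the conformational force field
#'
#' Exact negative gradient of the bonded (FENE), excluded-volume (WCA),
#' bending (Kratky-Porod), wall and centromere-attraction energies at the
#' current coordinates. Restraint forces are not included; see
#' [restraint_forces()].
#'
#' @param system a `bead_system`.
#' @param params force-field overrides (see [forcefield_params()]).
#' @return list with `forces` (n x 3, eps/nm) and `energy` (eps).
#' @export
compute_forces <- function(system, params = list()) {
  p <- forcefield_params(system$sigma, system$r_nuc, params)
  cpp_forces(system$coords, system$chain_of_bead, system$cen, p)
}

#' Run Langevin dynamics
#'
#' Underdamped Langevin dynamics (BAOAB splitting of velocity-Verlet with
#' friction and fluctuation-dissipation-consistent Gaussian noise),
#' deterministic given the seed. With `gamma = 0` and `temp = 0` the
#' integrator is plain velocity Verlet (NVE).
#'
#' @param system a `bead_system`.
#' @param duration_tau run length in tau_LJ.
#' @param seed RNG seed.
#' @param params force-field overrides (see [forcefield_params()]).
#' @param restraints a `restraint_set` or `NULL`.
#' @param snapshot_every_tau snapshot interval in tau_LJ (0 = endpoints only).
#' @param vel0 optional n x 3 initial velocities (default Maxwell-Boltzmann).
#' @param soft_start_tau length of a preliminary push-off phase with capped
#'   pair forces (resolves steric overlaps of dense prepared conformations
#'   before the exact force field takes over; 0 = none).
#' @return list with `system` (coordinates updated), `traj` (a `trajectory`:
#'   `snaps` list of coordinate matrices, `time_tau`, `pe`, `ke`, `d0`,
#'   `ramp_frac`), and `vel` (final velocities).
#' @export
langevin_run <- function(system, duration_tau, seed = 1, params = list(),
                         restraints = NULL, snapshot_every_tau = NULL,
                         vel0 = NULL, soft_start_tau = 0) {
  if (soft_start_tau > 0) {
    # quasi-overdamped push-off with a ramped force cap: overlaps drain
    # gradually (small steps, high friction, displacement clamp) until the
    # exact excluded volume is safe at the production timestep
    for (cap in c(2, 5, 10, 20)) {
      soft <- langevin_run(system,
                           duration_tau = soft_start_tau / 4,
                           seed = seed + 77773 + round(cap),
                           params = utils::modifyList(params,
                                                      list(pair_fcap = cap,
                                                           dt = 0.002,
                                                           gamma = 20,
                                                           max_step = 0.5)),
                           snapshot_every_tau = 0)
      system <- soft$system
    }
    vel0 <- NULL  # velocities re-thermalized at the production friction
  }
  p <- forcefield_params(system$sigma, system$r_nuc, params)
  dt_tau <- p$dt / system$sigma
  nsteps <- max(0L, as.integer(round(duration_tau / dt_tau)))
  if (is.null(snapshot_every_tau)) snapshot_every_tau <- max(duration_tau / 50, dt_tau)
  snap_every <- if (snapshot_every_tau <= 0) 0L else
    max(1L, as.integer(round(snapshot_every_tau / dt_tau)))
  restr <- if (is.null(restraints)) list() else
    restraints_to_cpp(restraints, dt_tau)
  if (nsteps == 0) {
    traj <- structure(list(snaps = list(system$coords), time_tau = 0,
                           pe = NA_real_, ke = NA_real_, d0 = 0, ramp_frac = 0,
                           restraints = restraints),
                      class = "trajectory")
    return(list(system = system, traj = traj, vel = vel0))
  }
  out <- cpp_run(system$coords, system$chain_of_bead, system$cen, p, restr,
                 nsteps, snap_every, as.integer(seed),
                 if (is.null(vel0)) NULL else vel0)
  system$coords <- out$coords
  traj <- structure(list(snaps = out$snaps,
                         time_tau = out$snap_step * dt_tau,
                         pe = out$pe, ke = out$ke, d0 = out$d0,
                         ramp_frac = out$ramp_frac,
                         restraints = restraints),
                    class = "trajectory")
  list(system = system, traj = traj, vel = out$vel)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$snaps), "snapshot(s) over",
      round(max(x$time_tau), 1), "tau_LJ\n")
  invisible(x)
}

#' Relaxation phase
#'
#' Evolves the compressed system with stochastic dynamics: centromeres are
#' compacted by their attractive interaction while chromosome arms relax
#' from the rod-like start and expand inside the nucleus. The production
#' duration is 120,000 tau_LJ; desk-scale runs shorten it through
#' `time_scale`.
#'
#' @param system a compressed `bead_system`.
#' @param duration_tau nominal duration in tau_LJ.
#' @param time_scale multiplier applied to `duration_tau` (desk-scale < 1).
#' @param seed RNG seed.
#' @param params force-field overrides.
#' @param snapshot_every_tau snapshot interval in tau_LJ.
#' @param soft_start_tau capped-force push-off length (tau_LJ); rosette
#'   starts are dense and need it.
#' @return list with `system` and `traj` as in [langevin_run()].
#' @export
relax <- function(system, duration_tau = 120000, time_scale = 1, seed = 1,
                  params = list(), snapshot_every_tau = NULL,
                  soft_start_tau = 5) {
  langevin_run(system, duration_tau = duration_tau * time_scale, seed = seed,
               params = params, snapshot_every_tau = snapshot_every_tau,
               soft_start_tau = soft_start_tau)
}

#' Build a single free chain system (no confinement)
#'
#' Convenience constructor for property checks on an unconfined chain: one
#' chain of `n_beads`, wall disabled. The `"kp"` start draws bond angles
#' from the equilibrium discrete Kratky-Porod distribution
#' p(cos theta) proportional to exp(kappa cos theta), so orientational
#' statistics start at equilibrium and only excluded-volume swelling
#' remains to relax.
#'
#' @param n_beads chain length.
#' @param sigma bead diameter (nm).
#' @param start `"kp"`, `"straight"` or `"rosette"`.
#' @param kappa bending constant used by the `"kp"` start (kT).
#' @param seed RNG seed for the stochastic starts.
#' @return a `bead_system`.
#' @export
free_chain <- function(n_beads, sigma = .sigma_default,
                       start = c("kp", "straight", "rosette"), kappa = 5,
                       seed = 1) {
  start <- match.arg(start)
  coords <- switch(start,
    straight = cbind(0, 0, (seq_len(n_beads) - (n_beads + 1) / 2) * sigma),
    rosette = build_rosette(n_beads, sigma = sigma, seed = seed),
    kp = kp_chain(n_beads, sigma = sigma, kappa = kappa, seed = seed))
  structure(list(coords = coords,
                 chains = data.frame(chain = 1L, chrom = "chrF", copy = 1L,
                                     n_beads = as.integer(n_beads), first = 1L),
                 chain_of_bead = rep(1L, n_beads),
                 cen = rep(FALSE, n_beads),
                 track_flags = list(),
                 bead_bp = .bead_bp_default, resolution = 100000,
                 beads_per_bin = 33L, sigma = sigma, r_nuc = Inf,
                 placed = TRUE, radial = NULL),
            class = "bead_system")
}

#' Build a multi-chain system of equilibrium coils in a nucleus
#'
#' Chains are drawn as equilibrium discrete Kratky-Porod coils and placed
#' at random non-clashing midpoints inside the nuclear sphere: a desk-scale
#' stand-in for the long production relaxation phase, useful wherever a
#' "relaxed" starting state is needed. Residual excluded-volume overlaps
#' should be removed with a short capped-force push-off
#' (`soft_start_tau`) before production dynamics.
#'
#' @param n_chains number of chains (one chromosome each, single copy).
#' @param n_beads beads per chain (recycled).
#' @param r_nuc nucleus radius (nm).
#' @param sigma bead diameter (nm).
#' @param kappa bending constant (kT).
#' @param seed RNG seed.
#' @return a `bead_system`.
#' @export
coil_system <- function(n_chains, n_beads, r_nuc = .rnuc_default,
                        sigma = .sigma_default, kappa = 5, seed = 1) {
  set.seed(seed)
  n_beads <- rep_len(as.integer(n_beads), n_chains)
  coords <- vector("list", n_chains)
  for (k in seq_len(n_chains)) {
    mid <- sample_shell_point(0, 0.5 * r_nuc)
    coords[[k]] <- kp_chain(n_beads[k], sigma = sigma, kappa = kappa,
                            seed = seed * 1000 + k, center = mid,
                            r_conf = r_nuc - sigma)
  }
  chains <- data.frame(chain = seq_len(n_chains),
                       chrom = paste0("chr", seq_len(n_chains)),
                       copy = 1L, n_beads = n_beads,
                       first = cumsum(c(1L, utils::head(n_beads, -1))))
  structure(list(coords = do.call(rbind, coords),
                 chains = chains,
                 chain_of_bead = rep(seq_len(n_chains), n_beads),
                 cen = rep(FALSE, sum(n_beads)),
                 track_flags = list(),
                 bead_bp = .bead_bp_default, resolution = 100000,
                 beads_per_bin = 33L, sigma = sigma, r_nuc = r_nuc,
                 placed = TRUE, radial = NULL),
            class = "bead_system")
}

# sample a discrete Kratky-Porod chain at equilibrium: successive bond
# angles have p(cos) ~ exp(kappa cos) (inverse-CDF), azimuths uniform
kp_chain <- function(n_beads, sigma = .sigma_default, kappa = 5, seed = 1,
                     center = c(0, 0, 0), r_conf = Inf) {
  set.seed(seed)
  t_cur <- c(0, 0, 1)
  coords <- matrix(0, n_beads, 3)
  coords[1, ] <- center
  step_dir <- function(t_cur) {
    u <- stats::runif(1)
    cosb <- log(exp(-kappa) + u * (exp(kappa) - exp(-kappa))) / kappa
    sinb <- sqrt(max(0, 1 - cosb^2))
    phi <- stats::runif(1, 0, 2 * pi)
    # orthonormal frame around the current tangent
    a <- if (abs(t_cur[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- a - sum(a * t_cur) * t_cur; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(t_cur[2] * e1[3] - t_cur[3] * e1[2],
            t_cur[3] * e1[1] - t_cur[1] * e1[3],
            t_cur[1] * e1[2] - t_cur[2] * e1[1])
    t_new <- cosb * t_cur + sinb * (cos(phi) * e1 + sin(phi) * e2)
    t_new / sqrt(sum(t_new^2))
  }
  for (i in seq_len(n_beads - 1)) {
    t_new <- step_dir(t_cur)
    if (is.finite(r_conf)) {
      tries <- 0
      while (sqrt(sum((coords[i, ] + sigma * t_new)^2)) > r_conf &&
             tries < 50) {
        t_new <- step_dir(t_cur)
        tries <- tries + 1
      }
      if (tries == 50) {  # point back toward the centre, jittered
        inward <- -coords[i, ] / sqrt(sum(coords[i, ]^2))
        t_new <- inward + 0.3 * stats::rnorm(3)
        t_new <- t_new / sqrt(sum(t_new^2))
      }
    }
    t_cur <- t_new
    coords[i + 1, ] <- coords[i, ] + sigma * t_cur
  }
  if (is.finite(r_conf)) coords else sweep(coords, 2, colMeans(coords))
}

#' Persistence length from tangent-tangent correlations
#'
#' Fits log <t_i . t_{i+s}> against contour distance s * sigma by least
#' squares over `s_max` bond separations, averaging the correlation over all
#' bonds and all supplied snapshots; l_p is the negative inverse slope.
#'
#' @param snaps list of coordinate matrices of one chain.
#' @param sigma bond length (nm).
#' @param s_max maximum bond separation used in the fit.
#' @return fitted persistence length (nm).
#' @export
persistence_length <- function(snaps, sigma = .sigma_default, s_max = 20) {
  corr <- numeric(s_max)
  cnt <- numeric(s_max)
  for (x in snaps) {
    b <- diff(x)
    b <- b / sqrt(rowSums(b^2))
    nb <- nrow(b)
    for (s in seq_len(min(s_max, nb - 1))) {
      corr[s] <- corr[s] + sum(b[1:(nb - s), ] * b[(1 + s):nb, ])
      cnt[s] <- cnt[s] + (nb - s)
    }
  }
  cs <- corr / cnt
  keep <- cs > 0
  s <- seq_len(s_max)[keep]
  fit <- stats::lm(log(cs[keep]) ~ 0 + s)
  -sigma / unname(stats::coef(fit)[1])
}
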