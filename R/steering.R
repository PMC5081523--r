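#' Entropy-matched initial spring constant
#'
#' Initial restraint stiffness chosen to just counteract the entropic recoil
#' of the chain segment separating the two targets, using the worm-like
#' chain entropic spring constant k = 3 kT / (2 l_p L) with contour length
#' L = s * sigma. Monotone decreasing in the sequence separation s.
#' Separations below `s_min` (66 beads, the 200 kb region scale under which
#' centre-of-mass steering is meaningless) are clamped with a warning.
#'
#' @param s sequence separation of the target pair, in beads (vectorized).
#' @param sigma bead diameter (nm).
#' @param lp persistence length (nm).
#' @param s_min minimum separation (beads).
#' @return spring constant(s) in kT/nm^2.
#' @export
init_spring_constant <- function(s, sigma = .sigma_default, lp = 150,
                                 s_min = 66) {
  if (any(s < s_min)) {
    warning("sequence separation below ", s_min,
            " beads; clamping spring constant")
    s <- pmax(s, s_min)
  }
  3 / (2 * lp * s * sigma)
}

new_restraint_set <- function(table, mode, ramp_tau, fcap, sched) {
  structure(list(table = table, mode = mode, ramp_tau = ramp_tau,
                 fcap = fcap, sched = sched),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat("restraint_set:", nrow(x$table), "restraint(s), mode =", x$mode, "\n")
  invisible(x)
}

#' Build COM restraints from significant contacts
#'
#' Each cis contact (100 kb bin pair) becomes one centre-of-mass harmonic
#' restraint between the two 33-bead target regions, duplicated per homolog
#' copy (a contact on a two-copy chromosome yields one restraint in each
#' copy, never across homologs). Initial spring constants are
#' entropy-matched via [init_spring_constant()]; the steering equilibrium
#' distance is 0 (pure attraction), satisfaction being judged by the
#' analysis cutoffs.
#'
#' @param contacts data.frame with columns `chrom`, `i`, `j` (0-based bins).
#' @param system a `bead_system`.
#' @param k_max spring constant at the end of the ramp (kT/nm^2).
#' @param fcap cap on the restraint force magnitude per COM pair (kT/nm).
#' @param lp persistence length used for the entropic matching (nm).
#' @return a `restraint_set` in steering mode (global 0-based bead ranges).
#' @export
build_restraints <- function(contacts, system, k_max = 0.1, fcap = 1,
                             lp = 150) {
  bpb <- system$beads_per_bin
  rows <- list()
  for (r in seq_len(nrow(contacts))) {
    chains <- system$chains[system$chains$chrom == contacts$chrom[r], ,
                            drop = FALSE]
    if (nrow(chains) == 0)
      stop("contact chromosome ", contacts$chrom[r], " not in the system")
    i <- contacts$i[r]; j <- contacts$j[r]
    for (q in seq_len(nrow(chains))) {
      nb <- chains$n_beads[q]
      off <- chains$first[q] - 1L  # global 0-based offset of the chain
      a <- bin_to_beads(i, bpb); b <- bin_to_beads(j, bpb)
      if (b[, "end"] > nb || a[, "start"] < 0)
        stop("contact bin outside chromosome ", contacts$chrom[r])
      s <- abs(j - i) * bpb
      rows[[length(rows) + 1]] <- data.frame(
        chain = chains$chain[q],
        a0 = off + a[, "start"], a1 = off + a[, "end"],
        b0 = off + b[, "start"], b1 = off + b[, "end"],
        s = s)
    }
  }
  tab <- do.call(rbind, rows)
  tab$k_init <- init_spring_constant(tab$s, sigma = system$sigma, lp = lp)
  tab$k_max <- k_max
  new_restraint_set(tab, mode = "steering", ramp_tau = NA_real_, fcap = fcap,
                    sched = data.frame(tau = 0, d0 = 0))
}

# translate a restraint_set into the flat list the C++ engine consumes
restraints_to_cpp <- function(rs, dt_tau) {
  tab <- rs$table
  list(a0 = as.integer(tab$a0), a1 = as.integer(tab$a1),
       b0 = as.integer(tab$b0), b1 = as.integer(tab$b1),
       k_init = tab$k_init, k_max = tab$k_max,
       fcap = rs$fcap,
       ramp_steps = if (is.na(rs$ramp_tau)) 0 else round(rs$ramp_tau / dt_tau),
       sched_step = as.integer(round(rs$sched$tau / dt_tau)),
       sched_d0 = rs$sched$d0)
}

#' Restraint forces at a given ramp fraction
#'
#' Forces exerted by a restraint set alone (no conformational force field),
#' exposed for verification: the total force on the two COM groups of every
#' restraint is equal and opposite.
#'
#' @param system a `bead_system`.
#' @param restraints a `restraint_set`.
#' @param ramp_frac ramp fraction in `[0, 1]`.
#' @param d0 equilibrium distance (nm).
#' @return list with `forces` (n x 3) and `energy`.
#' @export
restraint_forces <- function(system, restraints, ramp_frac = 1, d0 = 0) {
  p <- forcefield_params(system$sigma, system$r_nuc)
  cpp_restraint_forces(system$coords, system$chain_of_bead, system$cen, p,
                       restraints_to_cpp(restraints, p$dt / system$sigma),
                       ramp_frac, d0)
}

#' Steering phase
#'
#' Runs Langevin dynamics with the restraint spring constants ramped
#' linearly from their entropy-matched initial values to `k_max` over the
#' run (maximum 6,000 tau_LJ at production scale). The restraint force acts
#' on the centres of mass of the two target regions and is distributed
#' equally over their member beads. Per-snapshot satisfaction statistics
#' are attached.
#'
#' @param system a relaxed `bead_system`.
#' @param restraints a `restraint_set` from [build_restraints()].
#' @param duration_tau steering duration in tau_LJ.
#' @param time_scale desk-scale multiplier on the duration.
#' @param seed RNG seed.
#' @param params force-field overrides.
#' @param snapshot_every_tau snapshot interval.
#' @param cutoffs satisfaction cutoffs (nm).
#' @return list with `system`, `traj`, and `satisfaction` (a
#'   `satisfaction_curve`).
#' @export
steer <- function(system, restraints, duration_tau = 6000, time_scale = 1,
                  seed = 1, params = list(), snapshot_every_tau = NULL,
                  cutoffs = c(120, 240, 480)) {
  dur <- duration_tau * time_scale
  restraints$ramp_tau <- dur
  out <- langevin_run(system, duration_tau = dur, seed = seed,
                      params = params, restraints = restraints,
                      snapshot_every_tau = snapshot_every_tau)
  out$satisfaction <- satisfaction(out$traj, restraints, cutoffs = cutoffs)
  out
}

#' Add a second restraint set and continue steering
#'
#' Keeps the previous restraints active at their final stiffness and ramps
#' the new set from its own entropy-matched initial values (maximum
#' 600 tau_LJ at production scale). Reports the maintained fraction of the
#' old set and the established fraction of the new set at the end of the
#' run (closest-bead criterion at each cutoff).
#'
#' @param system a post-steering `bead_system`.
#' @param old the already-established `restraint_set`.
#' @param extra the new `restraint_set`.
#' @param duration_tau continuation duration in tau_LJ.
#' @param time_scale desk-scale multiplier.
#' @param seed RNG seed.
#' @param params force-field overrides.
#' @param snapshot_every_tau snapshot interval.
#' @param cutoffs satisfaction cutoffs (nm).
#' @return list with `system`, `traj`, `satisfaction_old`,
#'   `satisfaction_new`, `maintained`, `established` (the last two are
#'   per-cutoff closest-bead fractions at the end of the run).
#' @export
add_restraints_and_continue <- function(system, old, extra,
                                        duration_tau = 600, time_scale = 1,
                                        seed = 1, params = list(),
                                        snapshot_every_tau = NULL,
                                        cutoffs = c(120, 240, 480)) {
  dur <- duration_tau * time_scale
  held <- old$table
  held$k_init <- held$k_max  # held at full stiffness, no ramp
  comb <- new_restraint_set(rbind(held, extra$table), mode = "steering",
                            ramp_tau = dur, fcap = max(old$fcap, extra$fcap),
                            sched = data.frame(tau = 0, d0 = 0))
  out <- langevin_run(system, duration_tau = dur, seed = seed,
                      params = params, restraints = comb,
                      snapshot_every_tau = snapshot_every_tau)
  n_old <- nrow(old$table)
  sat_old <- satisfaction(out$traj, old, cutoffs = cutoffs)
  sat_new <- if (nrow(extra$table))
    satisfaction(out$traj, extra, cutoffs = cutoffs) else NULL
  last <- function(sc) if (is.null(sc)) NULL else
    sc[sc$time_tau == max(sc$time_tau) & sc$criterion == "closest", ]
  list(system = out$system, traj = out$traj,
       satisfaction_old = sat_old, satisfaction_new = sat_new,
       maintained = last(sat_old), established = last(sat_new))
}

#' Equilibrium-distance schedule of the recondensation protocol
#'
#' Step sequence 200, 170, 140, 110, 80, 50, 30 nm, one step every 0.6
#' tau_LJ (the stated 30 nm decrement does not divide the 200-to-30 nm span
#' evenly; the last step is 20 nm so the schedule lands exactly on the
#' 30 nm bead size).
#'
#' @param step_tau time between steps (tau_LJ).
#' @return data.frame with columns `tau`, `d0`.
#' @export
recondensation_schedule <- function(step_tau = 0.6) {
  d0 <- c(200, 170, 140, 110, 80, 50, 30)
  data.frame(tau = (seq_along(d0) - 1) * step_tau, d0 = d0)
}

#' Build regular loop-anchor restraints
#'
#' Single-bead anchor pairs every `spacing` beads (66 beads = 200 kb) along
#' each chain; the final bead is always an anchor so every chain segment is
#' covered. Chains shorter than the spacing get no anchors (with a warning).
#'
#' @param system a `bead_system`.
#' @param spacing anchor spacing in beads.
#' @param k spring constant (kT/nm^2), equal for all pairs.
#' @param fcap force cap (kT/nm).
#' @return a `restraint_set` in recondensation mode.
#' @export
loop_anchor_restraints <- function(system, spacing = 66, k = 1, fcap = 1) {
  rows <- list()
  for (r in seq_len(nrow(system$chains))) {
    nb <- system$chains$n_beads[r]
    off <- system$chains$first[r] - 1L
    if (nb < spacing) {
      warning("chain ", system$chains$chain[r], " shorter than the anchor ",
              "spacing; no anchors placed")
      next
    }
    anchors <- seq(0L, nb - 1L, by = spacing)
    last <- anchors[length(anchors)]
    if (last < nb - 1L) {
      # cover the chain end: extend the final anchor if the leftover is
      # shorter than half a spacing, otherwise add one more anchor
      if (nb - 1L - last < spacing / 2) {
        anchors[length(anchors)] <- nb - 1L
      } else {
        anchors <- c(anchors, nb - 1L)
      }
    }
    if (length(anchors) < 2) next
    a <- anchors[-length(anchors)]; b <- anchors[-1]
    rows[[length(rows) + 1]] <- data.frame(
      chain = system$chains$chain[r],
      a0 = off + a, a1 = off + a + 1L, b0 = off + b, b1 = off + b + 1L,
      s = b - a, k_init = k, k_max = k)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = integer(), a0 = integer(), a1 = integer(),
               b0 = integer(), b1 = integer(), s = integer(),
               k_init = numeric(), k_max = numeric())
  new_restraint_set(tab, mode = "recondensation", ramp_tau = NA_real_,
                    fcap = fcap, sched = recondensation_schedule())
}

#' Pre-mitotic recondensation protocol
#'
#' Removes all steering restraints and couples loci at a regular 200 kb
#' (66-bead) sequence spacing with equal, constant spring constants; the
#' equilibrium distances follow the stepped schedule from 200 nm (the
#' maximum extension of a 200 kb model strand) down to 30 nm (one bead),
#' then the run is extended to `hold_tau` at the final distance.
#'
#' @param system a steered or relaxed `bead_system`.
#' @param spacing anchor spacing in beads.
#' @param k spring constant (kT/nm^2).
#' @param hold_tau total run length in tau_LJ (schedule plus hold).
#' @param time_scale desk-scale multiplier on `hold_tau` (the schedule
#'   itself is never rescaled: its step times are part of the protocol).
#' @param seed RNG seed.
#' @param params force-field overrides.
#' @param snapshot_every_tau snapshot interval.
#' @param cutoffs satisfaction cutoffs (nm).
#' @return list with `system`, `traj`, `restraints`, `satisfaction`.
#' @export
recondense <- function(system, spacing = 66, k = 1, hold_tau = 300,
                       time_scale = 1, seed = 1, params = list(),
                       snapshot_every_tau = NULL, cutoffs = c(120, 240, 480)) {
  rs <- loop_anchor_restraints(system, spacing = spacing, k = k)
  dur <- max(hold_tau * time_scale, max(rs$sched$tau) + 0.6)
  out <- langevin_run(system, duration_tau = dur, seed = seed,
                      params = params, restraints = rs,
                      snapshot_every_tau = snapshot_every_tau)
  list(system = out$system, traj = out$traj, restraints = rs,
       satisfaction = satisfaction(out$traj, rs, cutoffs = cutoffs))
}
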