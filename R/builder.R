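#' Discretize a genome specification into beads
#'
#' Chromosomes are cut into beads of `bead_bp` (3,030 bp, a 30 nm fiber
#' stretch), so a 100 kb matrix bin spans 33 beads. Annotation intervals are
#' mapped to per-bead flags by a majority rule: a bead carries a feature when
#' the union of the track's intervals covers at least half of the bead.
#'
#' @param spec a `genome_spec`.
#' @param bead_bp bp per bead.
#' @param resolution Hi-C bin size in bp.
#' @return list with `n_beads` (named per chromosome), `beads_per_bin`,
#'   `cen_flags` and `track_flags` (per chromosome logical vectors over
#'   beads; `track_flags` is a list per track).
#' @export
discretize_genome <- function(spec, bead_bp = .bead_bp_default,
                              resolution = 100000) {
  ch <- spec$chroms
  n_beads <- stats::setNames(as.integer(ceiling(ch$length_bp / bead_bp)),
                             ch$chrom)
  flags_from_intervals <- function(iv, L, nb) {
    cov <- numeric(nb)
    if (nrow(iv)) {
      iv <- merge_intervals(iv)
      for (r in seq_len(nrow(iv))) {
        b0 <- floor(iv$start[r] / bead_bp)
        b1 <- min(nb - 1, floor((iv$end[r] - 1) / bead_bp))
        for (b in b0:b1) {
          lo <- b * bead_bp; hi <- min(L, lo + bead_bp)
          cov[b + 1] <- cov[b + 1] +
            max(0, min(hi, iv$end[r]) - max(lo, iv$start[r]))
        }
      }
    }
    cov >= 0.5 * bead_bp
  }
  cen_flags <- lapply(seq_len(nrow(ch)), function(k) {
    flags_from_intervals(data.frame(start = ch$cen_start[k], end = ch$cen_end[k]),
                         ch$length_bp[k], n_beads[k])
  })
  names(cen_flags) <- ch$chrom
  track_flags <- lapply(spec$tracks, function(track) {
    out <- lapply(seq_len(nrow(ch)), function(k) {
      iv <- track[track$chrom == ch$chrom[k], , drop = FALSE]
      flags_from_intervals(iv, ch$length_bp[k], n_beads[k])
    })
    names(out) <- ch$chrom
    out
  })
  list(n_beads = n_beads,
       beads_per_bin = as.integer(round(resolution / bead_bp)),
       cen_flags = cen_flags, track_flags = track_flags)
}

merge_intervals <- function(iv) {
  iv <- iv[order(iv$start), , drop = FALSE]
  if (nrow(iv) < 2) return(iv)
  out <- iv[1, c("start", "end"), drop = FALSE]
  for (r in 2:nrow(iv)) {
    last <- nrow(out)
    if (iv$start[r] <= out$end[last]) {
      out$end[last] <- max(out$end[last], iv$end[r])
    } else {
      out <- rbind(out, iv[r, c("start", "end")])
    }
  }
  out
}

#' Bead index range of a matrix bin
#'
#' Converts a 0-based 100 kb bin index into the half-open 0-based bead index
#' range it spans within its chain (33 beads per bin at the defaults).
#'
#' @param bin 0-based bin index (vectorized).
#' @param beads_per_bin beads per bin.
#' @return two-column matrix `start`, `end` (half-open, 0-based).
#' @export
bin_to_beads <- function(bin, beads_per_bin = 33L) {
  cbind(start = bin * beads_per_bin, end = (bin + 1L) * beads_per_bin)
}

#' Build a rod-like stacked-rosette conformation
#'
#' Beads are laid with exact spacing `sigma` along a rosette curve: planar
#' petals of roughly `n_loop` beads each, `n_petals` petals per turn, the
#' turn advancing `pitch` along the rod axis. Long chains therefore form
#' lengthwise-compact rods whose length grows linearly with bead number.
#'
#' @param n_beads number of beads.
#' @param sigma bead diameter (nm); also the bond length.
#' @param n_loop target beads per petal.
#' @param n_petals petals per rosette turn.
#' @param pitch axial advance per turn (nm).
#' @param seed seed for the random azimuthal phase.
#' @return `n_beads` x 3 coordinate matrix (nm), rod axis along z, centred
#'   at the origin.
#' @export
build_rosette <- function(n_beads, sigma = .sigma_default, n_loop = 100,
                          n_petals = 12, pitch = 2 * .sigma_default, seed = 1) {
  stopifnot(n_beads >= 1)
  set.seed(seed)
  phase <- stats::runif(1, 0, 2 * pi)
  r0 <- 2 * sigma
  rp <- n_loop * sigma / pi  # petal radius: half-circumference ~ n_loop bonds
  curve <- function(t) {
    r <- r0 + rp * abs(sin(n_petals * t / 2))
    cbind(r * cos(t + phase), r * sin(t + phase), pitch * t / (2 * pi))
  }
  # dense polyline, then chord-step exactly sigma from bead to bead
  step_t <- 2 * pi / (n_petals * n_loop * 25)
  coords <- matrix(NA_real_, n_beads, 3)
  t_cur <- 0
  coords[1, ] <- curve(0)
  if (n_beads > 1) {
    buf_t <- t_cur
    buf_p <- coords[1, , drop = FALSE]
    k <- 1
    last <- coords[1, ]
    bead <- 2
    while (bead <= n_beads) {
      if (k >= nrow(buf_p)) {  # extend the polyline buffer
        tt <- buf_t[length(buf_t)] + step_t * seq_len(4096)
        buf_t <- c(buf_t, tt)
        buf_p <- rbind(buf_p, curve(tt))
      }
      a <- buf_p[k, ]; b <- buf_p[k + 1, ]
      # farthest point of this segment from the last bead
      if (sum((b - last)^2) < sigma^2) { k <- k + 1; next }
      # solve |a + s(b-a) - last| = sigma for s in (0, 1]
      d <- b - a; m <- a - last
      A <- sum(d * d); B <- 2 * sum(m * d); C <- sum(m * m) - sigma^2
      s <- (-B + sqrt(max(0, B^2 - 4 * A * C))) / (2 * A)
      s <- min(1, max(0, s))
      last <- a + s * d
      coords[bead, ] <- last
      bead <- bead + 1
      # keep walking from the same segment (next bead may land further on)
      buf_p[k, ] <- last
    }
  }
  sweep(coords, 2, colMeans(coords))
}

#' Assemble a bead system from a genome specification
#'
#' Creates one chain per chromosome copy (diploid autosomes give two chains,
#' a single-copy X one), builds each chain as a stacked-rosette rod, and
#' returns the unplaced system; use [place_chromosomes()] next.
#'
#' @param spec a `genome_spec`.
#' @param bead_bp bp per bead.
#' @param resolution Hi-C bin size (bp).
#' @param sigma bead diameter (nm).
#' @param r_nuc nucleus radius (nm).
#' @param rosette list of rosette parameters (`n_loop`, `n_petals`, `pitch`).
#' @param seed RNG seed.
#' @return an object of class `bead_system`.
#' @export
build_system <- function(spec, bead_bp = .bead_bp_default,
                         resolution = 100000, sigma = .sigma_default,
                         r_nuc = spec$r_nuc %||% .rnuc_default,
                         rosette = list(), seed = 1) {
  disc <- discretize_genome(spec, bead_bp = bead_bp, resolution = resolution)
  ros <- utils::modifyList(list(n_loop = 100, n_petals = 12,
                                pitch = 2 * sigma), rosette)
  ch <- spec$chroms
  chains <- list(); coords <- list(); cen <- list(); chain_of <- list()
  id <- 0L
  for (k in seq_len(nrow(ch))) {
    for (cp in seq_len(ch$copy_number[k])) {
      id <- id + 1L
      nb <- disc$n_beads[[ch$chrom[k]]]
      chains[[id]] <- data.frame(chain = id, chrom = ch$chrom[k], copy = cp,
                                 n_beads = nb)
      coords[[id]] <- build_rosette(nb, sigma = sigma, n_loop = ros$n_loop,
                                    n_petals = ros$n_petals, pitch = ros$pitch,
                                    seed = seed + id)
      cen[[id]] <- disc$cen_flags[[ch$chrom[k]]]
      chain_of[[id]] <- rep(id, nb)
    }
  }
  chains <- do.call(rbind, chains)
  chains$first <- cumsum(c(1L, utils::head(chains$n_beads, -1)))
  track_flags <- lapply(disc$track_flags, function(tf) {
    unlist(lapply(seq_len(nrow(chains)),
                  function(r) tf[[chains$chrom[r]]]), use.names = FALSE)
  })
  structure(list(coords = do.call(rbind, coords),
                 chains = chains,
                 chain_of_bead = unlist(chain_of, use.names = FALSE),
                 cen = unlist(cen, use.names = FALSE),
                 track_flags = track_flags,
                 bead_bp = bead_bp, resolution = resolution,
                 beads_per_bin = disc$beads_per_bin,
                 sigma = sigma, r_nuc = r_nuc, placed = FALSE,
                 radial = spec$radial),
            class = "bead_system")
}

#' @export
print.bead_system <- function(x, ...) {
  cat("bead_system:", nrow(x$coords), "beads,", nrow(x$chains), "chain(s),",
      "R_nuc =", x$r_nuc, "nm, sigma =", x$sigma, "nm",
      if (x$placed) "(placed)" else "(unplaced)", "\n")
  invisible(x)
}

random_rotation <- function() {
  # uniform rotation from a random quaternion
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# sample a point uniformly over the volume between radii [r_lo, r_hi]
sample_shell_point <- function(r_lo, r_hi) {
  r <- (stats::runif(1, r_lo^3, r_hi^3))^(1 / 3)
  v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
  r * v
}

#' Place chromosome rods inside the nucleus
#'
#' Chromosomes are placed longest-first with random orientation. In
#' `random` mode the midpoint is uniform in the nuclear volume and the first
#' placement free of trans steric clashes (any inter-rod bead pair closer
#' than `sigma`) is kept. In `phenomenological` mode the midpoint is drawn
#' inside the equal-volume radial shell (of six) containing the chromosome's
#' target mean radial position, and among up to `trials` non-clashing
#' candidates the one minimizing |mean bead radius - target| is kept; the
#' achieved residual is reported.
#'
#' @param system an unplaced `bead_system`.
#' @param mode `"random"` or `"phenomenological"`.
#' @param trials candidate placements per chromosome.
#' @param seed RNG seed.
#' @param max_redraws clash-rejection budget per chromosome.
#' @return the placed `bead_system`, with a `placement` data.frame attached
#'   (chain, mode, mean radius, target, residual).
#' @export
place_chromosomes <- function(system, mode = c("random", "phenomenological"),
                              trials = 10000, seed = 1, max_redraws = 10000) {
  mode <- match.arg(mode)
  set.seed(seed)
  rn <- system$r_nuc
  shells <- rn * (0:6 / 6)^(1 / 3)  # six equal-volume shells
  targets <- NULL
  if (mode == "phenomenological") {
    if (is.null(system$radial))
      stop("phenomenological placement needs radial targets in the genome spec")
    targets <- stats::setNames(system$radial$target_r, system$radial$chrom)
  }
  ord <- order(-system$chains$n_beads)
  placed <- matrix(numeric(0), 0, 3)
  new_coords <- system$coords
  report <- list()
  for (r in ord) {
    first <- system$chains$first[r]
    nb <- system$chains$n_beads[r]
    rod <- system$coords[first:(first + nb - 1), , drop = FALSE]
    best <- NULL; best_resid <- Inf
    tgt <- NA_real_
    lo <- 0; hi <- rn
    if (mode == "phenomenological") {
      tgt <- targets[[system$chains$chrom[r]]]
      s <- max(1, min(6, findInterval(tgt, shells, rightmost.closed = TRUE)))
      lo <- shells[s]; hi <- shells[s + 1]
    }
    n_try <- 0
    budget <- if (mode == "random") max_redraws else max(trials, 1)
    while (n_try < budget) {
      n_try <- n_try + 1
      R <- random_rotation()
      mid <- if (mode == "random") sample_shell_point(0, rn) else
        sample_shell_point(lo, hi)
      cand <- sweep(rod %*% t(R), 2, -mid)
      if (nrow(placed) && cpp_has_clash(placed, cand, system$sigma)) next
      if (mode == "random") { best <- cand; break }
      resid <- abs(mean(sqrt(rowSums(cand^2))) - tgt)
      if (resid < best_resid) { best_resid <- resid; best <- cand }
    }
    if (is.null(best))
      stop("could not place chain ", system$chains$chain[r], " without trans ",
           "steric clashes after ", budget, " redraws; lower the genome ",
           "density or enlarge the nucleus")
    new_coords[first:(first + nb - 1), ] <- best
    placed <- rbind(placed, best)
    report[[length(report) + 1]] <- data.frame(
      chain = system$chains$chain[r], chrom = system$chains$chrom[r],
      mode = mode, mean_r = mean(sqrt(rowSums(best^2))), target_r = tgt,
      residual = if (mode == "phenomenological") best_resid else NA_real_)
  }
  system$coords <- new_coords
  system$placed <- TRUE
  system$placement <- do.call(rbind, report)
  system
}

#' Resolve protrusions by compressive Langevin dynamics
#'
#' Briefly evolves the placed system under the confining-wall force (whose
#' capped branch acts as a constant radial compressive force on protruding
#' beads) until every bead is inside the nuclear sphere. The nominal duration
#' is 1,200 tau_LJ; if beads remain outside, the run is extended with a
#' warning.
#'
#' @param system a placed `bead_system`.
#' @param duration_tau compression duration in tau_LJ.
#' @param seed RNG seed.
#' @param params force-field overrides, see [forcefield_params()].
#' @param max_extensions extra runs of the same duration if protrusions remain.
#' @return the compressed `bead_system`.
#' @export
compress_protrusions <- function(system, duration_tau = 1200, seed = 1,
                                 params = list(), max_extensions = 3) {
  inside <- function(s) all(sqrt(rowSums(s$coords^2)) < s$r_nuc)
  if (inside(system)) return(system)
  # strongly damped descent: beads falling from far outside must not pick
  # up supra-thermal kinetic energy before entering the crowded interior
  comp_params <- utils::modifyList(list(gamma = 5, dt = 0.006, max_step = 2),
                                   params)
  for (round in 0:max_extensions) {
    if (round > 0)
      warning("beads still outside the nucleus after compression; extending")
    system <- langevin_run(system, duration_tau = duration_tau,
                           seed = seed + round, params = comp_params,
                           snapshot_every_tau = 0,
                           soft_start_tau = if (round == 0) 5 else 0)$system
    if (inside(system)) return(system)
  }
  warning("protrusions remain after ", max_extensions, " extensions")
  system
}

#' Gyration-tensor asphericity of a point set
#'
#' Normalized asphericity in `[0, 1]`: 0 for a sphere, 1 for a thin rod.
#'
#' @param coords n x 3 matrix.
#' @return scalar asphericity.
#' @export
asphericity <- function(coords) {
  c0 <- sweep(coords, 2, colMeans(coords))
  ev <- eigen(crossprod(c0) / nrow(c0), symmetric = TRUE)$values
  1.5 * sum(ev^2) / sum(ev)^2 - 0.5
}
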