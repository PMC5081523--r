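#' Restraint satisfaction along a trajectory
#'
#' For every snapshot and restraint, a target pair is satisfied under the
#' COM criterion when the distance between the centres of mass of the two
#' regions is at most the cutoff, and under the closest-bead criterion when
#' the minimum distance over all bead pairs is. Fractions are reported per
#' criterion and per cutoff (120, 240, 480 nm by default).
#'
#' @param traj a `trajectory` (or a list of coordinate matrices).
#' @param restraints a `restraint_set`.
#' @param criteria subset of `c("com", "closest")`.
#' @param cutoffs distance cutoffs in nm.
#' @return a `satisfaction_curve` data.frame with columns `time_tau`,
#'   `criterion`, `cutoff`, `fraction`.
#' @export
satisfaction <- function(traj, restraints, criteria = c("com", "closest"),
                         cutoffs = c(120, 240, 480)) {
  snaps <- if (inherits(traj, "trajectory")) traj$snaps else traj
  times <- if (inherits(traj, "trajectory")) traj$time_tau else
    seq_along(snaps) - 1
  tab <- restraints$table
  rows <- list()
  for (s in seq_along(snaps)) {
    x <- snaps[[s]]
    com_d <- numeric(nrow(tab)); min_d <- numeric(nrow(tab))
    for (r in seq_len(nrow(tab))) {
      A <- x[(tab$a0[r] + 1):tab$a1[r], , drop = FALSE]
      B <- x[(tab$b0[r] + 1):tab$b1[r], , drop = FALSE]
      com_d[r] <- sqrt(sum((colMeans(A) - colMeans(B))^2))
      d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
        outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
      min_d[r] <- sqrt(max(0, min(d2)))
    }
    for (crit in criteria) {
      d <- if (crit == "com") com_d else min_d
      for (cut in cutoffs)
        rows[[length(rows) + 1]] <- data.frame(
          time_tau = times[s], criterion = crit, cutoff = cut,
          fraction = mean(d <= cut))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("satisfaction_curve", class(out))
  out
}

#' Coarse-grained mean-position distance matrix
#'
#' Averages bead positions within each 100 kb bin (33 beads) of a single
#' chain and returns the Euclidean distance matrix between bin means.
#'
#' @param coords coordinate matrix of one chain (n_beads x 3).
#' @param beads_per_bin beads per bin.
#' @return symmetric distance matrix (nm), zero diagonal; the bin mean
#'   positions are attached as attribute `"bin_means"`.
#' @export
distance_matrix <- function(coords, beads_per_bin = 33L) {
  nb <- nrow(coords) %/% beads_per_bin
  if (nb < 1) stop("fewer beads than one bin")
  means <- t(vapply(seq_len(nb), function(b) {
    colMeans(coords[((b - 1) * beads_per_bin + 1):(b * beads_per_bin), ,
                    drop = FALSE])
  }, numeric(3)))
  D <- as.matrix(stats::dist(means))
  dimnames(D) <- NULL
  attr(D, "bin_means") <- means
  D
}

#' Kendall association between model distances and Hi-C counts
#'
#' Kendall tau-b (tie-corrected) between corresponding upper-triangle
#' entries of the model distance matrix and the Hi-C count matrix,
#' restricted to pairs with genomic separation at least each threshold in
#' the sweep (shorter spatial distances reflect higher read counts, so the
#' expected association is negative). Thresholds with fewer than 10 pairs
#' are omitted and flagged.
#'
#' @param distmat model distance matrix (bins x bins).
#' @param hic a `contact_matrix` or dense count matrix of matching size.
#' @param thresholds genomic-separation thresholds in bins.
#' @return data.frame with columns `threshold`, `n_pairs`, `tau`, `p`,
#'   `omitted`.
#' @export
kendall_vs_hic <- function(distmat, hic, thresholds = NULL) {
  H <- if (inherits(hic, "contact_matrix")) as_dense(hic) else hic
  n <- nrow(distmat)
  if (!all(dim(H) == n)) stop("matrix sizes do not match")
  if (is.null(thresholds)) thresholds <- seq(10, floor(n / 2), by = 10)
  idx <- which(upper.tri(distmat), arr.ind = TRUE)
  sep <- idx[, 2] - idx[, 1]
  rows <- lapply(thresholds, function(t) {
    keep <- sep >= t
    if (sum(keep) < 10)
      return(data.frame(threshold = t, n_pairs = sum(keep), tau = NA_real_,
                        p = NA_real_, omitted = TRUE))
    ct <- suppressWarnings(
      stats::cor.test(distmat[idx[keep, , drop = FALSE]],
                      H[idx[keep, , drop = FALSE]], method = "kendall"))
    data.frame(threshold = t, n_pairs = sum(keep),
               tau = unname(ct$estimate), p = ct$p.value, omitted = FALSE)
  })
  do.call(rbind, rows)
}

#' Radial-shell enrichment profiles
#'
#' Subdivides the nucleus into `n_shells` radial shells of equal thickness
#' (15 shells of ~320 nm at the defaults) and reports, per shell and
#' feature, the percentage of shell beads carrying the feature, aggregated
#' over replicate conformations. Also returns the per-bin mean and standard
#' deviation of the radial position across replicates.
#'
#' @param conformations list of coordinate matrices (replicates; full
#'   system).
#' @param system the `bead_system` supplying the feature flags.
#' @param n_shells number of shells.
#' @return list with `profile` (shell, r_lo, r_hi, feature, percent,
#'   n_beads; empty shells have `percent = NA`) and `bins` (chain, bin,
#'   mean_r, sd_r).
#' @export
radial_profiles <- function(conformations, system, n_shells = 15) {
  rn <- system$r_nuc
  edges <- seq(0, rn, length.out = n_shells + 1)
  feats <- system$track_flags
  if (!length(feats)) stop("system carries no annotation flags")
  counts <- matrix(0, n_shells, length(feats),
                   dimnames = list(NULL, names(feats)))
  totals <- numeric(n_shells)
  for (x in conformations) {
    r <- sqrt(rowSums(x^2))
    shell <- pmin(n_shells, pmax(1L, findInterval(r, edges,
                                                  rightmost.closed = TRUE)))
    totals <- totals + tabulate(shell, n_shells)
    for (f in seq_along(feats))
      counts[, f] <- counts[, f] + tabulate(shell[feats[[f]]], n_shells)
  }
  profile <- do.call(rbind, lapply(names(feats), function(f) {
    data.frame(shell = seq_len(n_shells), r_lo = edges[-(n_shells + 1)],
               r_hi = edges[-1], feature = f,
               percent = ifelse(totals > 0, 100 * counts[, f] / totals,
                                NA_real_),
               n_beads = totals)
  }))
  # per-100kb-bin radial statistics across replicates
  bpb <- system$beads_per_bin
  bins <- list()
  for (k in seq_len(nrow(system$chains))) {
    first <- system$chains$first[k]; nbd <- system$chains$n_beads[k]
    nb <- nbd %/% bpb
    if (nb < 1) next
    rmat <- vapply(conformations, function(x) {
      r <- sqrt(rowSums(x[first:(first + nbd - 1), , drop = FALSE]^2))
      vapply(seq_len(nb),
             function(b) mean(r[((b - 1) * bpb + 1):(b * bpb)]), numeric(1))
    }, numeric(nb))
    rmat <- matrix(rmat, nrow = nb)
    bins[[k]] <- data.frame(chain = system$chains$chain[k],
                            bin = seq_len(nb) - 1L,
                            mean_r = rowMeans(rmat),
                            sd_r = apply(rmat, 1, stats::sd))
  }
  list(profile = profile, bins = do.call(rbind, bins))
}

# capped dissimilarity per the macrodomain rule: <d> below d_cap is kept,
# more distant pairs are set to d_fill
capped_dissimilarity <- function(D, d_cap = 750, d_fill = 1000) {
  out <- ifelse(D < d_cap, D, d_fill)
  diag(out) <- 0
  out
}

# exact optimal contiguous K-medoids partition of one arm by dynamic
# programming; returns integer labels 1..K
contiguous_kmedoids <- function(D, K) {
  m <- nrow(D)
  if (K > m) stop("more domains requested than segments")
  if (K == m) return(seq_len(m))
  csum <- apply(D, 2, cumsum)
  block_cost <- matrix(Inf, m, m)
  for (i in seq_len(m)) {
    base <- if (i > 1) csum[i - 1, ] else rep(0, m)
    for (j in i:m) {
      colsums <- csum[j, ] - base
      block_cost[i, j] <- min(colsums[i:j])
    }
  }
  best <- matrix(Inf, K, m)
  cut <- matrix(NA_integer_, K, m)
  best[1, ] <- block_cost[1, ]
  if (K > 1) {
    for (k in 2:K) {
      for (j in k:m) {
        cand <- best[k - 1, (k - 1):(j - 1)] + block_cost[k:j, j]
        pick <- which.min(cand)  # first minimum: smallest boundary wins ties
        best[k, j] <- cand[pick]
        cut[k, j] <- (k:j)[pick]
      }
    }
  }
  labels <- integer(m)
  j <- m
  for (k in K:1) {
    i <- if (k == 1) 1L else cut[k, j]
    labels[i:j] <- k
    j <- i - 1L
  }
  labels
}

#' Sequence-continuous K-medoids macrodomain partition
#'
#' Builds the capped dissimilarity matrix (entries below 750 nm keep their
#' mean distance, more distant pairs are set to 1,000 nm) from the
#' replicate-averaged 100 kb distance matrix, then partitions each arm
#' separately into the requested number of sequence-contiguous domains
#' minimizing the total within-domain dissimilarity to the best medoid
#' segment. The optimum is found exactly by dynamic programming; ties are
#' broken toward the smallest boundary, so the result is deterministic.
#'
#' @param distmat replicate-averaged distance matrix over 100 kb segments.
#' @param arms list of integer vectors: the segment indices (1-based) of
#'   each arm.
#' @param n_domains domains per arm (recycled).
#' @param d_cap dissimilarity cap (nm).
#' @param d_fill dissimilarity assigned beyond the cap (nm).
#' @return a `partition`: data.frame with columns `arm`, `segment`,
#'   `domain`.
#' @export
macrodomain_partition <- function(distmat, arms, n_domains, d_cap = 750,
                                  d_fill = 1000) {
  n_domains <- rep_len(n_domains, length(arms))
  Delta <- capped_dissimilarity(distmat, d_cap, d_fill)
  rows <- lapply(seq_along(arms), function(a) {
    seg <- arms[[a]]
    lab <- contiguous_kmedoids(Delta[seg, seg, drop = FALSE], n_domains[a])
    data.frame(arm = a, segment = seg, domain = lab)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("partition", class(out))
  out
}

part_labels <- function(p) {
  if (inherits(p, "partition") || is.data.frame(p)) {
    p <- p[order(p$arm, p$segment), ]
    list(labels = p$domain, arm = p$arm, segment = p$segment)
  } else {
    list(labels = as.integer(p), arm = rep(1L, length(p)),
         segment = seq_along(p))
  }
}

#' Overlap of two sequence-continuous partitions
#'
#' Fraction of segments whose sequentially numbered domain label agrees
#' between the two partitions, optionally excluding centromeric segments.
#'
#' @param a,b partitions (from [macrodomain_partition()]) or plain label
#'   vectors over the same segments.
#' @param exclude segment indices to exclude (e.g. centromeric).
#' @return overlap q in `[0, 1]`.
#' @export
partition_overlap <- function(a, b, exclude = NULL) {
  la <- part_labels(a); lb <- part_labels(b)
  if (length(la$labels) != length(lb$labels))
    stop("partitions cover different numbers of segments")
  keep <- !(la$segment %in% exclude)
  mean(la$labels[keep] == lb$labels[keep])
}

random_contiguous_labels <- function(m, K) {
  if (K == 1) return(rep(1L, m))
  bounds <- sort(sample(m - 1, K - 1))
  findInterval(seq_len(m) - 1, c(0, bounds)) |> as.integer()
}

#' Permutation significance of a partition overlap
#'
#' Compares the observed overlap against `n_random` random
#' sequence-continuous subdivisions of the same arms into the same numbers
#' of domains (boundaries uniform over placements), replacing the second
#' partition: p = (1 + #\{q_rand >= q\}) / (n_random + 1).
#'
#' @param a,b partitions over the same segments.
#' @param n_random number of random subdivisions.
#' @param seed RNG seed.
#' @param exclude segment indices to exclude from q.
#' @return list with `q`, `p_value`, `q_random` (the null sample).
#' @export
overlap_significance <- function(a, b, n_random = 1000, seed = 1,
                                 exclude = NULL) {
  set.seed(seed)
  q_obs <- partition_overlap(a, b, exclude = exclude)
  lb <- part_labels(b)
  arms <- split(seq_along(lb$labels), lb$arm)
  Ks <- vapply(arms, function(ix) length(unique(lb$labels[ix])), integer(1))
  q_rand <- vapply(seq_len(n_random), function(t) {
    lab <- integer(length(lb$labels))
    for (g in seq_along(arms))
      lab[arms[[g]]] <- random_contiguous_labels(length(arms[[g]]), Ks[g])
    rb <- data.frame(arm = lb$arm, segment = lb$segment, domain = lab)
    partition_overlap(a, rb, exclude = exclude)
  }, numeric(1))
  list(q = q_obs, p_value = (1 + sum(q_rand >= q_obs)) / (n_random + 1),
       q_random = q_rand)
}

#' Procrustes RMSD of two point sets
#'
#' Root-mean-square deviation after optimal rigid superimposition
#' (translation plus rotation via the Kabsch/SVD solution; uniform scaling
#' optional and off by default).
#'
#' @param a,b n x 3 matrices, matched point order (n >= 3).
#' @param scale allow uniform scaling of `b`.
#' @return minimized RMSD in the units of the input.
#' @export
procrustes_rmsd <- function(a, b, scale = FALSE) {
  if (nrow(a) != nrow(b)) stop("point counts differ")
  if (nrow(a) < 3) stop("need at least 3 points")
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  M <- crossprod(bc, ac)               # rotate b onto a
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  s <- if (scale) sum(sv$d * c(1, 1, d)) / sum(bc^2) else 1
  sqrt(mean(rowSums((ac - s * (bc %*% R))^2)))
}

#' MDS reconstruction of a chromosome from a contact matrix
#'
#' Converts contacts to distances d_ij = x_ij^(-alpha) for x_ij > 0,
#' completes missing entries to the shortest-path metric (Floyd-Warshall,
#' via graph distances), and embeds with classical MDS (top three
#' eigenvectors of the double-centred squared-distance matrix).
#'
#' @param hic a `contact_matrix` or dense non-negative matrix.
#' @param alpha counts-to-distance exponent.
#' @return list with `coords` (n x 3) and `dist` (the completed metric).
#' @export
mds_reconstruct <- function(hic, alpha = 1) {
  X <- if (inherits(hic, "contact_matrix")) as_dense(hic) else hic
  if (any(X < 0)) stop("contact matrix must be non-negative")
  n <- nrow(X)
  D <- ifelse(X > 0, X^(-alpha), 0)
  diag(D) <- 0
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  SP <- igraph::distances(g)
  if (any(!is.finite(SP)))
    stop("contact graph is disconnected; cannot complete the metric")
  dimnames(SP) <- NULL
  xy <- suppressWarnings(stats::cmdscale(SP, k = min(3, n - 1)))
  coords <- matrix(0, n, 3)
  coords[, seq_len(ncol(xy))] <- xy
  list(coords = coords, dist = SP)
}
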