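#' Synthetic-truth model for Hi-C matrix generation
#'
#' Defines the ZiNB background at every genomic distance and the list of
#' planted enriched pairs against which contact calling can be scored. The
#' background at distance `delta` (in bins) is
#' ZiNB(`pi`, `theta`, `mu_delta`) with a power-law distance decay
#' `mu_delta = mu_c / delta^decay` — the standard null for chromatin contact
#' frequency; the exponent and scale are configurable.
#'
#' @param n_bins number of bins of the target matrix.
#' @param resolution bin size in bp.
#' @param planted data.frame with columns `i`, `j` (0-based bins) and `fold`
#'   (> 1 enrichment of the mean); may have zero rows.
#' @param pi zero-inflation probability in `[0, 1)` (scalar or length
#'   `n_bins - 1` vector over delta).
#' @param theta NB dispersion (> 0; scalar or per-delta vector).
#' @param mu_c decay scale: mean at delta = 1.
#' @param decay power-law exponent of the distance decay.
#' @param chrom chromosome name.
#' @return an object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(n_bins, resolution = 100000,
                            planted = data.frame(i = integer(), j = integer(),
                                                 fold = numeric()),
                            pi = 0.3, theta = 2, mu_c = 100, decay = 1,
                            chrom = "chrS") {
  deltas <- seq_len(n_bins - 1)
  expand <- function(v) if (length(v) == 1) rep(v, length(deltas)) else v
  pi_d <- expand(pi); theta_d <- expand(theta)
  stopifnot(length(pi_d) == length(deltas), length(theta_d) == length(deltas))
  if (any(pi_d < 0 | pi_d >= 1)) stop("pi must be in [0, 1)")
  if (any(theta_d <= 0)) stop("theta must be > 0")
  mu_d <- mu_c / deltas^decay
  if (any(mu_d <= 0)) stop("mu must be > 0")
  if (nrow(planted)) {
    stopifnot(all(c("i", "j", "fold") %in% names(planted)))
    ii <- pmin(planted$i, planted$j); jj <- pmax(planted$i, planted$j)
    planted <- data.frame(i = ii, j = jj, fold = planted$fold)
    if (any(planted$j - planted$i < 1)) stop("planted pairs must be cis with |i-j| >= 1")
    if (any(planted$fold <= 1)) stop("planted fold enrichment must exceed 1")
    if (any(planted$i < 0 | planted$j >= n_bins))
      stop("planted pair outside matrix")
  }
  structure(list(chrom = chrom, n_bins = as.integer(n_bins),
                 resolution = resolution, planted = planted,
                 pi = pi_d, theta = theta_d, mu = mu_d),
            class = "synthetic_truth")
}

#' Sample planted enriched pairs
#'
#' Draws `n` distinct cis pairs with sequence separations spanning the range
#' from a minimum separation up to half the chromosome length, mimicking a
#' mixture of local (TAD-boundary-like, ~200 kb) and non-local (tens of Mb)
#' constraint sets.
#'
#' @param n number of pairs.
#' @param n_bins matrix size in bins.
#' @param fold enrichment factor applied to the background mean.
#' @param min_sep minimum separation in bins (default 2 = 200 kb at 100 kb).
#' @return data.frame with columns `i`, `j`, `fold`.
#' @export
sample_planted <- function(n, n_bins, fold = 50, min_sep = 2) {
  max_sep <- max(min_sep, floor(n_bins / 2))
  pairs <- matrix(NA_integer_, 0, 2)
  guard <- 0
  while (nrow(pairs) < n && guard < 100) {
    sep <- sample(seq(min_sep, max_sep), n, replace = TRUE)
    i <- vapply(sep, function(s) sample(n_bins - s, 1) - 1L, integer(1))
    cand <- unique(rbind(pairs, cbind(i, i + sep)))
    pairs <- cand[seq_len(min(nrow(cand), n)), , drop = FALSE]
    guard <- guard + 1
  }
  if (nrow(pairs) < n) stop("could not sample ", n, " distinct pairs")
  data.frame(i = pairs[, 1], j = pairs[, 2], fold = fold)
}

#' Generate a synthetic genome specification
#'
#' Builds chromosome records with centromeres at a configurable fractional
#' position and annotation tracks with a controllable spatial gradient:
#' gene density decays (or grows) along each chromosome and LAD blocks are
#' placed complementary to the gene-rich blocks.
#'
#' @param n_chrom number of chromosomes.
#' @param lengths_bp chromosome lengths (recycled); each >= 1 Mb.
#' @param seed RNG seed; the returned genome_spec is deterministic given
#'   the seed.
#' @param cen_frac fractional centromere midpoint position.
#' @param cen_width_bp centromere width in bp.
#' @param gene_gradient sign of the gene-density gradient along the
#'   chromosome: negative means gene-rich near the start.
#' @param track_bin_bp granularity of generated annotation blocks.
#' @param radial optional vector of radial targets (nm, recycled) to attach.
#' @param r_nuc nucleus radius (nm).
#' @return a `genome_spec` with tracks `genes` and `LADs`.
#' @export
gen_genome_spec <- function(n_chrom, lengths_bp, seed = 1, cen_frac = 0.4,
                            cen_width_bp = 3e5, gene_gradient = -1,
                            track_bin_bp = 1e5, radial = NULL,
                            r_nuc = .rnuc_default) {
  if (n_chrom < 1) stop("n_chrom must be >= 1")
  lengths_bp <- rep_len(lengths_bp, n_chrom)
  if (any(lengths_bp < 1e6)) stop("chromosome lengths must be >= 1 Mb")
  set.seed(seed)
  names <- paste0("chr", seq_len(n_chrom))
  cen_mid <- round(lengths_bp * cen_frac)
  chroms <- data.frame(chrom = names, length_bp = lengths_bp,
                       cen_start = pmax(0, cen_mid - cen_width_bp / 2),
                       cen_end = pmin(lengths_bp, cen_mid + cen_width_bp / 2),
                       copy_number = 2L)
  genes <- list(); lads <- list()
  for (k in seq_len(n_chrom)) {
    nb <- floor(lengths_bp[k] / track_bin_bp)
    pos <- (seq_len(nb) - 0.5) / nb
    # monotone gene-density probability along the chromosome
    p_gene <- if (gene_gradient < 0) 0.85 - 0.7 * pos else 0.15 + 0.7 * pos
    is_gene <- stats::runif(nb) < p_gene
    starts <- (seq_len(nb) - 1) * track_bin_bp
    if (any(is_gene))
      genes[[k]] <- data.frame(chrom = names[k], start = starts[is_gene],
                               end = starts[is_gene] + track_bin_bp,
                               name = "gene")
    if (any(!is_gene))
      lads[[k]] <- data.frame(chrom = names[k], start = starts[!is_gene],
                              end = starts[!is_gene] + track_bin_bp,
                              name = "LAD")
  }
  tracks <- list(genes = do.call(rbind, genes), LADs = do.call(rbind, lads))
  tracks <- Filter(Negate(is.null), tracks)
  rad <- if (!is.null(radial))
    data.frame(chrom = names, target_r = rep_len(radial, n_chrom)) else NULL
  genome_spec(chroms, tracks, rad, r_nuc = r_nuc)
}

#' Sample from a zero-inflated negative binomial
#'
#' Mixture sampler: with probability `pi` emit 0, otherwise draw from
#' NB(size = `theta`, mean = `mu`) — the same parametrization used by the
#' contact caller, so selection is testable against planted truth.
#'
#' @param n number of draws.
#' @param pi zero-inflation probability.
#' @param theta NB dispersion.
#' @param mu NB mean.
#' @return integer vector of counts.
#' @export
rzinb <- function(n, pi, theta, mu) {
  extra0 <- stats::rbinom(n, 1, pi) == 1
  x <- stats::rnbinom(n, size = theta, mu = mu)
  x[extra0] <- 0L
  x
}

#' Generate a synthetic cis Hi-C contact matrix
#'
#' Every background pair at separation `delta` is drawn from the truth's
#' ZiNB(pi, theta, mu_delta); planted pairs are drawn from the same NB family
#' with the mean multiplied by their fold enrichment and zero-inflation
#' suppressed. Zeros are omitted, giving a sparse matrix.
#'
#' @param truth a `synthetic_truth`.
#' @param seed RNG seed.
#' @return a `contact_matrix`.
#' @export
gen_hic_matrix <- function(truth, seed = 1) {
  set.seed(seed)
  nb <- truth$n_bins
  rows <- vector("list", nb - 1)
  planted_key <- paste(truth$planted$i, truth$planted$j)
  for (d in seq_len(nb - 1)) {
    i <- 0:(nb - 1 - d)
    x <- rzinb(length(i), truth$pi[d], truth$theta[d], truth$mu[d])
    keep <- x > 0
    if (any(keep))
      rows[[d]] <- data.frame(i = i[keep], j = i[keep] + d, value = x[keep])
  }
  entries <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(entries))
    entries <- data.frame(i = integer(), j = integer(), value = numeric())
  # overwrite planted pairs: NB with boosted mean, no zero inflation
  if (nrow(truth$planted)) {
    d <- truth$planted$j - truth$planted$i
    xp <- stats::rnbinom(nrow(truth$planted), size = truth$theta[d],
                         mu = truth$mu[d] * truth$planted$fold)
    entries <- entries[!(paste(entries$i, entries$j) %in% planted_key), ,
                       drop = FALSE]
    keep <- xp > 0
    if (any(keep))
      entries <- rbind(entries,
                       data.frame(i = truth$planted$i[keep],
                                  j = truth$planted$j[keep], value = xp[keep]))
  }
  contact_matrix(truth$chrom, truth$resolution, nb, entries)
}

#' Write planted truth pairs as TSV
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @export
export_truth <- function(truth, path) {
  utils::write.table(truth$planted, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read planted truth pairs written by [export_truth()]
#' @param path file path.
#' @return data.frame with columns `i`, `j`, `fold`.
#' @export
read_truth <- function(path) {
  utils::read.table(path, header = TRUE,
                    colClasses = c("integer", "integer", "numeric"))
}
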