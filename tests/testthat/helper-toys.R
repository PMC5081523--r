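# shared fixture builders (all generated in code; nothing on disk)

toy_spec <- function(n_chrom = 1, length_bp = 2e6, copy_number = 2L,
                     radial = NULL) {
  chroms <- data.frame(chrom = paste0("chr", seq_len(n_chrom)),
                       length_bp = length_bp,
                       cen_start = round(length_bp * 0.4),
                       cen_end = pmin(length_bp,
                                      round(length_bp * 0.4) + 1e5),
                       copy_number = copy_number)
  rad <- if (!is.null(radial))
    data.frame(chrom = chroms$chrom, target_r = rep_len(radial, n_chrom))
  genome_spec(chroms, radial = rad)
}

toy_matrix <- function(n_bins = 6, chrom = "chrT", seed = 1) {
  set.seed(seed)
  idx <- which(upper.tri(diag(n_bins)), arr.ind = TRUE)
  contact_matrix(chrom, 100000, n_bins,
                 data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                            value = rpois(nrow(idx), 8) + 1))
}

# brute-force closest/COM satisfaction for one snapshot
oracle_satisfaction <- function(coords, tab, cutoff, criterion) {
  sapply(seq_len(nrow(tab)), function(r) {
    A <- coords[(tab$a0[r] + 1):tab$a1[r], , drop = FALSE]
    B <- coords[(tab$b0[r] + 1):tab$b1[r], , drop = FALSE]
    if (criterion == "com") {
      sqrt(sum((colMeans(A) - colMeans(B))^2)) <= cutoff
    } else {
      dmin <- Inf
      for (p in seq_len(nrow(A))) for (q in seq_len(nrow(B)))
        dmin <- min(dmin, sqrt(sum((A[p, ] - B[q, ])^2)))
      dmin <= cutoff
    }
  })
}

# exhaustive optimal contiguous K-medoids objective by boundary enumeration
oracle_partition_cost <- function(D, K) {
  m <- nrow(D)
  block_cost <- function(i, j)
    min(vapply(i:j, function(med) sum(D[i:j, med]), numeric(1)))
  if (K == 1) return(block_cost(1, m))
  best <- Inf
  for (bnd in utils::combn(m - 1, K - 1, simplify = FALSE)) {
    cuts <- c(0, bnd, m)
    cost <- sum(vapply(seq_len(K), function(k)
      block_cost(cuts[k] + 1, cuts[k + 1]), numeric(1)))
    best <- min(best, cost)
  }
  best
}

partition_cost <- function(D, labels) {
  sum(vapply(unique(labels), function(l) {
    ix <- which(labels == l)
    min(vapply(ix, function(med) sum(D[ix, med]), numeric(1)))
  }, numeric(1)))
}
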