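#' Construct a genome specification
#'
#' A `genome_spec` bundles everything the builder needs: chromosome records
#' (length, centromere interval, copy number), annotation tracks as 0-based
#' half-open intervals, and an optional table of phenomenological radial
#' placement targets (mean distance from the nuclear centre, nm).
#'
#' @param chroms data.frame with columns `chrom`, `length_bp`, `cen_start`,
#'   `cen_end`, `copy_number` (1 or 2).
#' @param tracks named list of annotation tracks; each a data.frame with
#'   columns `chrom`, `start`, `end` and optionally `name`.
#' @param radial optional data.frame with columns `chrom`, `target_r` (nm).
#' @param r_nuc nucleus radius in nm, used to validate radial targets.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(chroms, tracks = list(), radial = NULL,
                        r_nuc = .rnuc_default) {
  stopifnot(is.data.frame(chroms),
            all(c("chrom", "length_bp", "cen_start", "cen_end",
                  "copy_number") %in% names(chroms)))
  if (any(chroms$length_bp <= 0))
    stop("chromosome lengths must be positive")
  if (any(chroms$cen_start < 0 | chroms$cen_end > chroms$length_bp |
          chroms$cen_start >= chroms$cen_end))
    stop("centromere interval must lie within [0, length)")
  if (!all(chroms$copy_number %in% c(1L, 2L)))
    stop("copy_number must be 1 or 2")
  for (nm in names(tracks)) tracks[[nm]] <- validate_track(tracks[[nm]], chroms)
  if (!is.null(radial)) {
    stopifnot(all(c("chrom", "target_r") %in% names(radial)))
    if (any(radial$target_r < 0 | radial$target_r > r_nuc))
      stop("radial targets must lie in [0, R_nuc]")
  }
  structure(list(chroms = chroms, tracks = tracks, radial = radial,
                 r_nuc = r_nuc),
            class = "genome_spec")
}

validate_track <- function(track, chroms) {
  stopifnot(is.data.frame(track), all(c("chrom", "start", "end") %in% names(track)))
  if (any(track$start >= track$end))
    stop("annotation intervals must satisfy start < end (0-based half-open)")
  if (any(track$start < 0)) stop("annotation intervals must start at >= 0")
  len <- stats::setNames(chroms$length_bp, chroms$chrom)
  bad <- !(track$chrom %in% chroms$chrom) | track$end > len[track$chrom]
  if (any(bad)) stop("annotation interval outside chromosome bounds")
  if (is.null(track$name)) track$name <- "feature"
  track
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", nrow(x$chroms), "chromosome(s),",
      sum(x$chroms$length_bp), "bp total\n")
  cat("  tracks:", if (length(x$tracks)) paste(names(x$tracks), collapse = ", ")
      else "(none)", "\n")
  cat("  radial targets:", if (is.null(x$radial)) "(none)" else
      paste0(nrow(x$radial), " chromosome(s)"), "\n")
  invisible(x)
}

#' Construct a cis contact matrix
#'
#' Symmetric sparse matrix of Hi-C counts for one chromosome, stored as the
#' upper triangle (`i <= j`, 0-based bins). Duplicate entries are summed and
#' the (i, j) ordering canonicalized.
#'
#' @param chrom chromosome name.
#' @param resolution bin size in bp.
#' @param n_bins number of bins.
#' @param entries data.frame with columns `i`, `j`, `value`.
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(chrom, resolution, n_bins, entries) {
  stopifnot(all(c("i", "j", "value") %in% names(entries)))
  if (nrow(entries)) {
    if (any(!is.finite(entries$value)) || any(entries$value < 0))
      stop("contact values must be finite and non-negative")
    if (any(entries$i < 0 | entries$j < 0))
      stop("bin indices must be non-negative")
    if (any(entries$i >= n_bins | entries$j >= n_bins))
      stop("bin index beyond n_bins")
    ii <- pmin(entries$i, entries$j)
    jj <- pmax(entries$i, entries$j)
    agg <- stats::aggregate(entries$value, by = list(i = ii, j = jj), FUN = sum)
    entries <- data.frame(i = agg$i, j = agg$j, value = agg$x)
    entries <- entries[order(entries$i, entries$j), , drop = FALSE]
    rownames(entries) <- NULL
  } else {
    entries <- data.frame(i = integer(), j = integer(), value = numeric())
  }
  structure(list(chrom = chrom, resolution = resolution, n_bins = as.integer(n_bins),
                 entries = entries),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", x$chrom, "-", x$n_bins, "bins @", x$resolution, "bp,",
      nrow(x$entries), "nonzero upper-triangle entries\n")
  invisible(x)
}

#' Convert a contact matrix to a dense symmetric matrix
#' @param mat a `contact_matrix`.
#' @return dense numeric `n_bins x n_bins` matrix.
#' @export
as_dense <- function(mat) {
  m <- matrix(0, mat$n_bins, mat$n_bins)
  e <- mat$entries
  if (nrow(e)) {
    m[cbind(e$i + 1L, e$j + 1L)] <- e$value
    m[cbind(e$j + 1L, e$i + 1L)] <- e$value
  }
  m
}

#' Build a contact matrix from a dense symmetric matrix
#' @param m dense numeric matrix.
#' @param chrom chromosome name.
#' @param resolution bin size in bp.
#' @return a `contact_matrix`.
#' @export
dense_to_contact_matrix <- function(m, chrom = "chr", resolution = 100000) {
  idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  contact_matrix(chrom, resolution, nrow(m),
                 data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                            value = m[idx]))
}

#' Read a sparse triplet contact matrix
#'
#' Parses whitespace-separated triplet lines `chrom bin_i bin_j value` (or
#' `chrom start1 start2 value` with genomic coordinates, detected when indices
#' are multiples of the resolution and large). One chromosome per file;
#' duplicate and transposed entries are summed into the upper triangle.
#'
#' @param path file path.
#' @param resolution bin size in bp.
#' @param n_bins number of bins; inferred from the largest index if `NULL`.
#' @return a `contact_matrix`.
#' @export
read_contact_matrix <- function(path, resolution = 100000, n_bins = NULL) {
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, col.names = c("chrom", "i", "j", "value"),
                      colClasses = c("character", "numeric", "numeric", "numeric")),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(data.frame(chrom = character(), i = numeric(), j = numeric(),
                          value = numeric()))
      stop("malformed contact matrix file: ", conditionMessage(e))
    })
  if (nrow(tab) == 0)
    return(contact_matrix("chr", resolution, n_bins %||% 0L,
                          data.frame(i = integer(), j = integer(), value = numeric())))
  if (length(unique(tab$chrom)) > 1)
    stop("one chromosome per matrix file; found: ",
         paste(unique(tab$chrom), collapse = ", "))
  if (any(tab$value < 0)) stop("negative contact value in ", path)
  # genomic-coordinate convention: indices are bin starts in bp
  if (all(tab$i %% resolution == 0) && all(tab$j %% resolution == 0) &&
      max(tab$i, tab$j) >= resolution) {
    tab$i <- tab$i / resolution
    tab$j <- tab$j / resolution
  }
  if (any(tab$i != floor(tab$i) | tab$j != floor(tab$j)))
    stop("bin indices must be integers (or bin-start coordinates)")
  nb <- n_bins %||% as.integer(max(tab$i, tab$j) + 1)
  if (max(tab$i, tab$j) >= nb)
    stop("bin index beyond n_bins in ", path)
  contact_matrix(tab$chrom[1], resolution, nb,
                 data.frame(i = as.integer(tab$i), j = as.integer(tab$j),
                            value = tab$value))
}

#' Write a contact matrix as triplet text
#' @param mat a `contact_matrix`.
#' @param path output path.
#' @export
write_contact_matrix <- function(mat, path) {
  e <- mat$entries
  out <- data.frame(chrom = rep(mat$chrom, nrow(e)), i = e$i, j = e$j,
                    value = e$value)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a dense whitespace-separated square matrix (toy inputs)
#' @param path file path.
#' @param chrom chromosome name to attach.
#' @param resolution bin size in bp.
#' @return a `contact_matrix`.
#' @export
read_dense_matrix <- function(path, chrom = "chr", resolution = 100000) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) stop("dense matrix must be square")
  if (any(m < 0)) stop("negative contact value in ", path)
  if (any(abs(m - t(m)) > 1e-9)) stop("dense matrix must be symmetric")
  dense_to_contact_matrix(m, chrom, resolution)
}

#' Read a BED3+ annotation track
#'
#' Returns the intervals exactly as stored (BED is natively 0-based
#' half-open, the package-wide convention). Overlapping intervals are
#' permitted and preserved.
#'
#' @param path BED file path.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "", fill = TRUE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("BED file needs at least 3 columns")
  out <- data.frame(chrom = as.character(tab[[1]]),
                    start = as.numeric(tab[[2]]),
                    end = as.numeric(tab[[3]]),
                    name = if (ncol(tab) >= 4) as.character(tab[[4]]) else "feature",
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$start)) || any(!is.finite(out$end)))
    stop("malformed BED coordinates in ", path)
  if (any(out$start >= out$end))
    stop("BED intervals must satisfy start < end")
  out
}

#' Write a BED track
#' @param track data.frame with columns `chrom`, `start`, `end` and optionally `name`.
#' @param path output path.
#' @export
write_bed <- function(track, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(track))
  utils::write.table(track[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chrom.sizes table
#' @param path file path.
#' @return data.frame with columns `chrom`, `length_bp`.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("chrom", "length_bp"),
                           colClasses = c("character", "numeric"))
  if (any(tab$length_bp <= 0)) stop("chromosome lengths must be positive")
  tab
}

#' Write a two-column chrom.sizes table
#' @param chroms data.frame with columns `chrom`, `length_bp`.
#' @param path output path.
#' @export
write_chrom_sizes <- function(chroms, path) {
  utils::write.table(chroms[, c("chrom", "length_bp")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a bead conformation as plain text
#'
#' One record per bead: chain id, bead index within the chain (0-based),
#' genomic start of the bead (bp), and x, y, z in nm at 3 decimal places
#' (sub-Angstrom precision is meaningless at the 30 nm bead scale).
#'
#' @param system a `bead_system`.
#' @param path output path.
#' @export
write_conformation <- function(system, path) {
  if (any(!is.finite(system$coords)))
    stop("conformation contains non-finite coordinates")
  per_chain_index <- sequence(system$chains$n_beads) - 1L
  gstart <- per_chain_index * system$bead_bp
  out <- data.frame(chain = system$chain_of_bead,
                    bead = per_chain_index,
                    gstart = gstart,
                    x = sprintf("%.3f", system$coords[, 1]),
                    y = sprintf("%.3f", system$coords[, 2]),
                    z = sprintf("%.3f", system$coords[, 3]))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bead conformation written by [write_conformation()]
#' @param path file path.
#' @return list with `coords` (n x 3 matrix, nm), `chain` (integer vector),
#'   `bead` (within-chain 0-based index), `gstart` (bp).
#' @export
read_conformation <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("chain", "bead", "gstart", "x", "y", "z"))
  if (any(!is.finite(as.matrix(tab[, c("x", "y", "z")]))))
    stop("conformation file contains non-finite coordinates")
  list(coords = as.matrix(tab[, c("x", "y", "z")]),
       chain = as.integer(tab$chain), bead = as.integer(tab$bead),
       gstart = tab$gstart)
}

#' Read a YAML run configuration
#'
#' Reads a nested key/value configuration, fills in package defaults for
#' missing keys and validates the few numeric invariants the pipeline relies
#' on. The resolved configuration (defaults merged in) is returned so callers
#' can log it alongside their RNG seeds.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    resolution = 100000,
    bead_bp = .bead_bp_default,
    sigma = .sigma_default,
    r_nuc = .rnuc_default,
    persistence_length = 150,
    alpha = 0.01,
    min_delta = 1L,
    pool_min_n = 50L,
    pool_min_nonzero = 10L,
    dt = 0.012,
    gamma = 0.5,
    kappa = 5,
    steer_k_max = 0.1,
    recondense_k = 1,
    time_scale = 1
  )
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  out <- utils::modifyList(defaults, cfg)
  if (out$dt > 0.012 + 1e-12)
    stop("config: dt must be <= 0.012 tau_LJ for integrator stability")
  if (out$alpha <= 0 || out$alpha >= 1) stop("config: alpha must be in (0,1)")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
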