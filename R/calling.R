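#' ICE iterative bias correction
#'
#' Iterative correction of a cis contact matrix: per-bin multiplicative bias
#' factors are estimated by repeatedly dividing each entry by the product of
#' its row and column marginal factors until the marginals over unmasked bins
#' are equal. Bins with zero raw marginal are masked and excluded from
#' balancing (and from all downstream testing). The corrected matrix is
#' rescaled so its total equals the raw total, keeping corrected values on
#' the count scale.
#'
#' Bias estimation is robust to focal signal: entries above their
#' genomic-distance's `1 - high_frac` quantile are clipped to that quantile
#' while the bias factors are iterated (strongly enriched contacts otherwise
#' masquerade as per-bin visibility bias and corrupt the balancing); the
#' final factors are applied to the full, unclipped matrix.
#'
#' @param mat a `contact_matrix` of raw counts.
#' @param max_iter maximum number of iterations.
#' @param tol convergence tolerance on the maximum relative change of the
#'   marginal factors.
#' @param high_frac per-distance fraction of highest entries clipped during
#'   bias estimation (0 disables clipping).
#' @return list with `corrected` (a `contact_matrix`, real-valued),
#'   `bias` (per-bin multiplicative factors, NA for masked bins),
#'   `mask` (logical, TRUE = masked), `converged`, `n_iter`.
#' @export
ice_normalize <- function(mat, max_iter = 200, tol = 1e-8, high_frac = 0) {
  W0 <- as_dense(mat)
  n <- nrow(W0)
  if (n == 0 || sum(W0) == 0) stop("cannot balance an all-zero matrix")
  W <- W0
  if (high_frac > 0 && n > 2) {
    for (d in seq_len(n - 1)) {
      i <- seq_len(n - d)
      v <- W[cbind(i, i + d)]
      cap <- as.numeric(stats::quantile(v, 1 - high_frac, type = 1))
      v <- pmin(v, cap)
      W[cbind(i, i + d)] <- v
      W[cbind(i + d, i)] <- v
    }
  }
  marg <- rowSums(W0)
  mask <- marg == 0
  bias <- rep(1, n)
  converged <- FALSE
  it <- 0
  idx <- which(!mask)
  while (it < max_iter) {
    it <- it + 1
    s <- rowSums(W)
    db <- s / mean(s[idx])
    db[mask] <- 1
    W <- W / outer(db, db)
    W[mask, ] <- 0; W[, mask] <- 0
    bias <- bias * db
    if (max(abs(db[idx] - 1)) < tol) { converged <- TRUE; break }
  }
  # apply the (robustly estimated) biases to the unclipped matrix
  W <- W0 / outer(bias, bias)
  W[mask, ] <- 0; W[, mask] <- 0
  if (!converged)
    warning("ICE did not converge in ", max_iter,
            " iterations; returning partial result")
  # preserve the total count scale
  tot_raw <- sum(as_dense(mat)[idx, idx])
  tot_cor <- sum(W[idx, idx])
  W <- W * tot_raw / tot_cor
  corrected <- dense_to_contact_matrix(W, mat$chrom, mat$resolution)
  corrected$n_bins <- mat$n_bins
  bias[mask] <- NA_real_
  list(corrected = corrected, bias = bias, mask = mask,
       converged = converged, n_iter = it)
}

#' Collect corrected counts by genomic distance
#'
#' For each separation `delta >= min_delta` (in bins), returns the vector of
#' all matrix entries at that separation between unmasked bins. Structural
#' zeros between unmasked bins are included: a zero is an observation, not
#' missing data.
#'
#' @param mat a `contact_matrix` (typically ICE-corrected).
#' @param min_delta smallest separation collected (self-pairs, delta = 0,
#'   are never collected).
#' @param mask logical per-bin mask (TRUE = excluded).
#' @return named list mapping `delta` to its observation vector.
#' @export
collect_by_distance <- function(mat, min_delta = 1, mask = NULL) {
  n <- mat$n_bins
  if (is.null(mask)) mask <- rep(FALSE, n)
  W <- as_dense(mat)
  out <- list()
  for (d in seq.int(max(1, min_delta), n - 1)) {
    i <- seq_len(n - d)
    keep <- !mask[i] & !mask[i + d]
    if (any(keep))
      out[[as.character(d)]] <- W[cbind(i[keep], i[keep] + d)]
  }
  out
}

# group deltas so every group has >= min_n observations and >= min_nonzero
# nonzero values, widening geometrically at sparse separations
pool_deltas <- function(by_delta, min_n = 50, min_nonzero = 10) {
  deltas <- as.integer(names(by_delta))
  groups <- list()
  cur <- integer()
  cur_n <- 0; cur_nz <- 0
  for (k in seq_along(deltas)) {
    cur <- c(cur, deltas[k])
    obs <- by_delta[[k]]
    cur_n <- cur_n + length(obs)
    cur_nz <- cur_nz + sum(obs > 0)
    if (cur_n >= min_n && cur_nz >= min_nonzero) {
      groups[[length(groups) + 1]] <- cur
      cur <- integer(); cur_n <- 0; cur_nz <- 0
    }
  }
  if (length(cur)) {
    if (length(groups)) {
      groups[[length(groups)]] <- c(groups[[length(groups)]], cur)
    } else {
      groups[[1]] <- cur
    }
  }
  groups
}

# negative ZiNB log-likelihood; observations above `cval` are treated as
# right-censored and contribute P(X > cval) (cval = Inf means no censoring)
zinb_nll <- function(eta, x, cval = Inf) {
  if (any(!is.finite(eta)) || abs(eta[1]) > 20 || abs(eta[2]) > 12 ||
      abs(eta[3]) > 20)
    return(1e10 + sum(pmin(eta^2, 1e8)))  # sloped penalty keeps BFGS sane
  pi <- stats::plogis(eta[1]); theta <- exp(eta[2]); mu <- exp(eta[3])
  lo <- x[x <= cval]
  n_hi <- length(x) - length(lo)
  p0 <- stats::dnbinom(0, size = theta, mu = mu)
  is0 <- lo == 0
  ll <- sum(is0) * log(pi + (1 - pi) * p0) +
    sum(log1p(-pi) +
          stats::dnbinom(lo[!is0], size = theta, mu = mu, log = TRUE))
  if (n_hi > 0)
    ll <- ll + n_hi * (log1p(-pi) +
                         stats::pnbinom(cval, size = theta, mu = mu,
                                        lower.tail = FALSE, log.p = TRUE))
  if (!is.finite(ll)) return(1e12)
  -ll
}

#' Maximum-likelihood fit of the zero-inflated negative binomial
#'
#' Fits the mixture P(0) = pi + (1 - pi) NB(0; theta, mu),
#' P(k > 0) = (1 - pi) NB(k; theta, mu) by direct numerical optimization of
#' the log-likelihood (BFGS on logit/log-transformed parameters) from a
#' moment-based start, with additional starts if the first fails. The NB
#' failure probability of the classic parametrization is reported as
#' p = theta / (theta + mu).
#'
#' With `censor_q > 0` the top `censor_q` fraction of observations is
#' right-censored: those points contribute P(X > c) to the likelihood rather
#' than their pmf (c = the empirical `1 - censor_q` quantile). The censored
#' estimator stays consistent under the model while remaining robust to a
#' small fraction of strongly enriched contacts contaminating the background
#' — the situation every background fit on real Hi-C faces. Censoring is
#' disabled automatically when the cutoff would fall below 2 counts.
#'
#' @param x integer observation vector (zeros included).
#' @param min_nonzero below this many nonzero values the fit is declared
#'   degenerate.
#' @param censor_q upper fraction of observations to right-censor
#'   (0 = plain MLE).
#' @return list with `pi`, `theta`, `mu`, `p`, standard errors (`se_pi`,
#'   `se_theta`, `se_mu`), `loglik`, `n`, `n_nonzero`, `status`
#'   (`"ok"` or `"degenerate"`).
#' @export
fit_zinb <- function(x, min_nonzero = 5, censor_q = 0) {
  x <- as.numeric(x)
  n <- length(x)
  nz <- sum(x > 0)
  deg <- list(pi = NA_real_, theta = NA_real_, mu = NA_real_, p = NA_real_,
              se_pi = NA_real_, se_theta = NA_real_, se_mu = NA_real_,
              loglik = NA_real_, n = n, n_nonzero = nz, status = "degenerate")
  if (n == 0 || nz < min_nonzero) return(deg)
  cval <- Inf
  if (censor_q > 0) {
    cval <- as.numeric(stats::quantile(x, 1 - censor_q, type = 1))
    if (cval < 2 || sum(x <= cval) < 20) cval <- Inf
  }
  mbar <- mean(x); v <- stats::var(x); p0 <- mean(x == 0)
  pi0 <- min(0.9, max(0.02, 0.5 * p0))
  mu0 <- mbar / (1 - pi0)
  denom <- v / ((1 - pi0) * mu0) - 1 - pi0 * mu0
  theta0 <- if (is.finite(denom) && denom > 1e-3) mu0 / denom else 10
  theta0 <- min(1e3, max(0.05, theta0))
  starts <- list(c(stats::qlogis(pi0), log(theta0), log(mu0)),
                 c(stats::qlogis(0.05), log(1), log(max(mbar, 0.1))),
                 c(stats::qlogis(min(0.9, max(0.05, p0 * 0.9))), log(5),
                   log(max(mean(x[x > 0]), 0.5))))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      suppressWarnings(
        stats::optim(s, zinb_nll, x = x, cval = cval, method = "BFGS",
                     hessian = TRUE,
                     control = list(maxit = 500, reltol = 1e-10))),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(deg)
  eta <- best$par
  pi <- stats::plogis(eta[1]); theta <- exp(eta[2]); mu <- exp(eta[3])
  se <- rep(NA_real_, 3)
  vc <- tryCatch(solve(best$hessian), error = function(e) NULL)
  if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) >= 0))
    se <- sqrt(diag(vc))
  list(pi = pi, theta = theta, mu = mu, p = theta / (theta + mu),
       se_pi = se[1] * pi * (1 - pi), se_theta = se[2] * theta,
       se_mu = se[3] * mu,
       loglik = -best$value, n = n, n_nonzero = nz, status = "ok")
}

#' Upper-tail p-value under a fitted ZiNB
#'
#' Returns P(X >= x) under the fitted mixture: 1 for x = 0, and
#' (1 - pi) * (1 - F_NB(x - 1)) for x >= 1, where F_NB is the negative
#' binomial CDF. Monotone non-increasing in x and always in (0, 1].
#'
#' @param x integer count(s), >= 0.
#' @param fit a fit returned by [fit_zinb()] with status `"ok"`.
#' @return numeric vector of p-values.
#' @export
zinb_pvalue <- function(x, fit) {
  if (!identical(fit$status, "ok"))
    stop("cannot compute p-values from a degenerate ZiNB fit")
  if (any(x < 0) || any(x != floor(x))) stop("x must be a non-negative integer")
  p <- ifelse(x == 0, 1,
              (1 - fit$pi) *
                stats::pnbinom(x - 1, size = fit$theta, mu = fit$mu,
                               lower.tail = FALSE))
  pmin(1, pmax(p, .Machine$double.xmin))
}

#' Benjamini-Hochberg selection grouped by genomic distance
#'
#' Applies the BH step-up procedure separately within each `delta` group
#' (each genomic distance is corrected independently) and returns the rows
#' whose adjusted p-value (q-value) is at most `alpha`, sorted by
#' (chrom, i, j).
#'
#' @param tab data.frame with at least columns `delta` and `p` (plus any
#'   bookkeeping columns, carried through).
#' @param alpha FDR level (default 1%).
#' @return data.frame of selected rows with a `q` column appended; class
#'   `significant_contacts`, attribute `alpha`.
#' @export
bh_select <- function(tab, alpha = 0.01) {
  if (nrow(tab) == 0) {
    out <- cbind(tab, q = numeric(0))
  } else {
    q <- rep(NA_real_, nrow(tab))
    for (d in unique(tab$delta)) {
      sel <- tab$delta == d
      q[sel] <- stats::p.adjust(tab$p[sel], method = "BH")
    }
    out <- tab
    out$q <- q
    out <- out[q <= alpha, , drop = FALSE]
    ord <- do.call(order, out[intersect(c("chrom", "i", "j"), names(out))])
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "alpha") <- alpha
  class(out) <- c("significant_contacts", class(out))
  out
}

#' Call significant cis contacts from a raw count matrix
#'
#' The full caller: ICE bias correction, per-distance collection (structural
#' zeros included), pooling of sparse distances, censored ZiNB
#' maximum-likelihood fits, upper-tail p-values, and per-distance
#' Benjamini-Hochberg selection at level `alpha`.
#'
#' By default the fit and test operate on raw counts (`test_on = "raw"`):
#' with a separate fit at every genomic distance, multiplicative visibility
#' bias enters the per-pair mean and is absorbed by the per-distance
#' dispersion, while on matrices of desk-scale bin counts the ICE bias
#' factors are too noisy to divide by without mis-calibrating the discrete
#' test. ICE still runs: zero-marginal bins are masked everywhere, and the
#' bias vector and corrected matrix are reported (and used by downstream
#' analyses). `test_on = "corrected"` tests rounded corrected counts
#' instead (corrected values are non-integer while the ZiNB is discrete, so
#' they are rounded to the nearest integer, preserving the model's
#' support); appropriate when bins are numerous enough for precise bias
#' estimates.
#'
#' @param mat a `contact_matrix` of raw counts.
#' @param alpha FDR level.
#' @param min_delta smallest tested separation in bins (self-interactions
#'   are never tested).
#' @param pool_min_n,pool_min_nonzero pooling thresholds per distance group.
#' @param censor_q upper-censoring fraction of the background fit (see
#'   [fit_zinb()]); keeps the fitted null robust to the very contacts being
#'   tested.
#' @param ice_high_frac per-distance clipping fraction for robust ICE bias
#'   estimation (see [ice_normalize()]).
#' @param ice_max_iter,ice_tol ICE controls.
#' @return list with `contacts` (a `significant_contacts` data.frame:
#'   chrom, i, j, raw, corrected, delta, p, q), `params` (per-group ZiNB
#'   fits as a data.frame), `corrected`, `bias`, `mask`.
#' @export
call_contacts <- function(mat, alpha = 0.01, min_delta = 1,
                          pool_min_n = 50, pool_min_nonzero = 10,
                          censor_q = 0.15, ice_high_frac = 0.15,
                          test_on = c("raw", "corrected"),
                          ice_max_iter = 200, ice_tol = 1e-8) {
  test_on <- match.arg(test_on)
  ice <- ice_normalize(mat, max_iter = ice_max_iter, tol = ice_tol,
                       high_frac = ice_high_frac)
  Wraw <- as_dense(mat)
  Wcor <- as_dense(ice$corrected)
  W <- if (test_on == "raw") Wraw else Wcor
  n <- mat$n_bins
  by_delta <- collect_by_distance(
    if (test_on == "raw") mat else ice$corrected,
    min_delta = min_delta, mask = ice$mask)
  groups <- pool_deltas(by_delta, min_n = pool_min_n,
                        min_nonzero = pool_min_nonzero)
  fits <- list(); rows <- list()
  for (g in seq_along(groups)) {
    deltas <- groups[[g]]
    obs <- round(unlist(by_delta[as.character(deltas)], use.names = FALSE))
    fit <- fit_zinb(obs, censor_q = censor_q)
    status <- if (!identical(fit$status, "ok")) "degenerate"
              else if (length(deltas) > 1) "pooled" else "ok"
    fits[[g]] <- data.frame(delta_lo = min(deltas), delta_hi = max(deltas),
                            pi = fit$pi, theta = fit$theta, mu = fit$mu,
                            p = fit$p, n_obs = fit$n,
                            n_nonzero = fit$n_nonzero, status = status)
    if (identical(fit$status, "ok")) {
      for (d in deltas) {
        i <- seq_len(n - d)
        keep <- !ice$mask[i] & !ice$mask[i + d]
        i <- i[keep]
        if (!length(i)) next
        xt <- W[cbind(i, i + d)]
        rows[[length(rows) + 1]] <- data.frame(
          chrom = mat$chrom, i = i - 1L, j = i + d - 1L,
          raw = Wraw[cbind(i, i + d)], corrected = Wcor[cbind(i, i + d)],
          delta = d, p = zinb_pvalue(round(xt), fit))
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), i = integer(), j = integer(),
               raw = numeric(), corrected = numeric(), delta = integer(),
               p = numeric())
  list(contacts = bh_select(tab, alpha = alpha),
       params = do.call(rbind, fits),
       corrected = ice$corrected, bias = ice$bias, mask = ice$mask)
}

#' Write a significant-contact table as TSV
#' @param contacts a `significant_contacts` data.frame.
#' @param path output path.
#' @export
write_contacts <- function(contacts, path) {
  utils::write.table(as.data.frame(contacts), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a significant-contact table written by [write_contacts()]
#' @param path file path.
#' @return data.frame.
#' @export
read_contacts <- function(path) {
  utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
}
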