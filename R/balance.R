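# Matrix balancing (ICE and KR) and observed/expected transformation.

default_mask <- function(counts, mask, low_quantile = 0.02) {
  totals <- rowSums(counts)
  m <- mask | totals == 0
  if (any(!m)) {
    thr <- stats::quantile(totals[!m], low_quantile, names = FALSE)
    # low-coverage filter: lowest-2% (or zero) total-count bins are excluded
    m <- m | totals < thr
  }
  m
}

#' Iterative correction (ICE) balancing
#'
#' Iteratively rescales the contact matrix so that all unmasked bins have
#' equal row sums. Bins with zero counts or a total count in the lowest
#' `low_quantile` of the chromosome are masked before balancing and their
#' rows/columns set to zero.
#'
#' @param m a `ContactMatrix` (raw or real-valued).
#' @param tol convergence tolerance on the relative row-sum deviation.
#' @param max_iter maximum number of iterations.
#' @param low_quantile low-coverage mask quantile (default 0.02).
#' @return A `BalancedMatrix`: list with elements `matrix` (ContactMatrix of
#'   balanced values), `bias` (per-bin bias, NA on masked bins), `method`,
#'   `converged`, `iterations`, `residual`.
#' @export
ice_balance <- function(m, tol = 1e-8, max_iter = 1000, low_quantile = 0.02) {
  stopifnot(inherits(m, "ContactMatrix"))
  mask <- default_mask(m$counts, m$mask, low_quantile)
  if (sum(!mask) < 2) stop("fewer than 2 unmasked bins")
  w <- m$counts
  w[mask, ] <- 0
  w[, mask] <- 0
  n <- nrow(w)
  bias <- rep(1, n)
  keep <- !mask
  converged <- FALSE
  res <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    s <- rowSums(w)
    sm <- s[keep] / mean(s[keep])
    res <- max(abs(sm - 1))
    if (res < tol) { converged <- TRUE; break }
    f <- rep(1, n)
    f[keep] <- sqrt(sm)  # damped correction: same fixed point, stable on
    w <- w / outer(f, f) # weakly-connected (near-reducible) support
    bias <- bias * f
  }
  if (!converged && it >= max_iter) {
    warning("ICE did not converge within max_iter; partial result returned")
  }
  bias[mask] <- NA_real_
  bal <- contact_matrix(w, m$bin_size, m$chrom, mask = mask)
  structure(list(matrix = bal, bias = bias, method = "ICE",
                 converged = converged, iterations = it, residual = res),
            class = "BalancedMatrix")
}

#' @export
print.BalancedMatrix <- function(x, ...) {
  cat(sprintf("BalancedMatrix (%s): %d bins, %d masked, %d iterations, residual %.3g\n",
              x$method, x$matrix$n_bins, sum(x$matrix$mask),
              x$iterations, x$residual))
  invisible(x)
}

# Connected components of the non-zero support graph over unmasked bins.
support_components <- function(w, keep) {
  idx <- which(keep)
  comp <- rep(NA_integer_, length(idx))
  cid <- 0L
  adj <- (w[idx, idx, drop = FALSE] > 0)
  diag(adj) <- FALSE
  for (s in seq_along(idx)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  cid
}

#' Knight-Ruiz (KR) balancing
#'
#' Computes the symmetric diagonal scaling `diag(b) M diag(b)` with equal
#' (unit) row sums on unmasked bins, via a damped fixed-point iteration on
#' the doubly-stochastic scaling problem. On strictly positive matrices the
#' result is proportional to the ICE result (the doubly stochastic scaling
#' of a symmetric non-negative matrix is unique up to scale). If the
#' unmasked support graph is reducible (disconnected blocks) the scaling is
#' not unique and the function falls back to ICE with a warning.
#'
#' @inheritParams ice_balance
#' @return A `BalancedMatrix` with method tag `"KR"` (or `"ICE"` after the
#'   documented fallback).
#' @export
kr_balance <- function(m, tol = 1e-8, max_iter = 3000, low_quantile = 0.02) {
  stopifnot(inherits(m, "ContactMatrix"))
  mask <- default_mask(m$counts, m$mask, low_quantile)
  if (sum(!mask) < 2) stop("fewer than 2 unmasked bins")
  keep <- !mask
  if (support_components(m$counts, keep) > 1L) {
    warning("KR: reducible support (disconnected blocks); falling back to ICE")
    return(ice_balance(m, tol = tol, low_quantile = low_quantile))
  }
  a <- m$counts[keep, keep, drop = FALSE]
  k <- nrow(a)
  x <- rep(1 / sqrt(mean(a)), k)
  converged <- FALSE
  res <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ax <- as.vector(a %*% x)
    r <- x * ax
    res <- max(abs(r - 1))
    if (res < tol) { converged <- TRUE; break }
    if (any(ax <= 0)) break # row with no support against current x
    x <- sqrt(x / ax)       # geometric-mean damped Sinkhorn step
  }
  if (!converged) {
    warning("KR iteration failed to converge; falling back to ICE")
    return(ice_balance(m, tol = tol, low_quantile = low_quantile))
  }
  n <- m$n_bins
  bias <- rep(NA_real_, n)
  bias[keep] <- x
  w <- matrix(0, n, n)
  w[keep, keep] <- a * outer(x, x)
  bal <- contact_matrix(w, m$bin_size, m$chrom, mask = mask)
  structure(list(matrix = bal, bias = bias, method = "KR",
                 converged = TRUE, iterations = it, residual = res),
            class = "BalancedMatrix")
}

#' Observed/expected transformation
#'
#' Divides every cell by the mean of unmasked cells at the same diagonal
#' distance. Cells on all-masked diagonals, or at distances where the
#' expected value is zero, are undefined (NA).
#'
#' @param b a `BalancedMatrix` or `ContactMatrix`.
#' @return A real matrix of O/E ratios with NA for undefined cells.
#' @export
observed_expected <- function(b) {
  m <- if (inherits(b, "BalancedMatrix")) b$matrix else b
  stopifnot(inherits(m, "ContactMatrix"))
  w <- m$counts
  n <- nrow(w)
  keep <- !m$mask
  oe <- matrix(NA_real_, n, n)
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    j <- i + d
    ok <- keep[i] & keep[j]
    if (!any(ok)) next
    vals <- w[cbind(i[ok], j[ok])]
    e <- mean(vals)
    if (!is.finite(e) || e == 0) next
    oe[cbind(i[ok], j[ok])] <- vals / e
    oe[cbind(j[ok], i[ok])] <- vals / e
  }
  oe
}
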