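# TAD-scale structure: insulation score, boundary calling, arrowhead
# transform with a simplified corner-score domain caller, and the
# directionality index.

#' Insulation score track
#'
#' Slides a `span` x `span` square along the matrix diagonal: for bin `i`
#' the square covers rows `i-s..i-1` by columns `i+1..i+s` (the off-diagonal
#' region immediately flanking the bin; `s = span / bin_size`). The mean
#' signal over defined cells in the square is the raw insulation of bin `i`;
#' bins within `span` of either chromosome end are skipped. Normalized
#' insulation is the log2 ratio of the raw score to the chromosome mean of
#' defined raw scores.
#'
#' @param b a `BalancedMatrix` at structural (25 kb) resolution.
#' @param span insulation span in bp (default 500 kb = 20 bins).
#' @param accession identifier stored in the track.
#' @return An `InsulationTrack`: list with per-bin `raw`, `norm`, plus
#'   `bin_size`, `span_bins`, `chrom`, `accession`.
#' @export
insulation_score <- function(b, span = 5e5, accession = "ref") {
  m <- if (inherits(b, "BalancedMatrix")) b$matrix else b
  stopifnot(inherits(m, "ContactMatrix"))
  s <- as.integer(round(span / m$bin_size))
  n <- m$n_bins
  raw <- rep(NA_real_, n)
  if (n < 2 * s + 1) {
    warning("chromosome shorter than twice the insulation span; all-undefined track")
  } else {
    w <- m$counts
    w[m$mask, ] <- NA
    w[, m$mask] <- NA
    for (i in (s + 1):(n - s)) {
      sq <- w[(i - s):(i - 1), (i + 1):(i + s), drop = FALSE]
      if (all(is.na(sq))) next
      raw[i] <- mean(sq, na.rm = TRUE)
    }
  }
  mu <- mean(raw, na.rm = TRUE)
  norm <- if (is.finite(mu) && mu > 0) log2(raw / mu) else rep(NA_real_, n)
  norm[!is.finite(norm)] <- NA_real_
  structure(list(accession = accession, chrom = m$chrom,
                 bin_size = m$bin_size, span_bins = s,
                 raw = raw, norm = norm),
            class = "InsulationTrack")
}

#' @export
print.InsulationTrack <- function(x, ...) {
  cat(sprintf("InsulationTrack %s/%s: %d bins (%d defined), span %d bins\n",
              x$accession, x$chrom, length(x$norm),
              sum(!is.na(x$norm)), x$span_bins))
  invisible(x)
}

# Delta vector: mean normalized insulation over the delta_bins to the left
# minus the mean over the delta_bins to the right of each bin.
insulation_delta <- function(norm, delta_bins) {
  n <- length(norm)
  delta <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    l <- norm[max(1, i - delta_bins):max(1, i - 1)]
    r <- norm[min(n, i + 1):min(n, i + delta_bins)]
    if (i == 1 || i == n) next
    l <- l[!is.na(l)]; r <- r[!is.na(r)]
    if (!length(l) || !length(r)) next
    delta[i] <- mean(l) - mean(r)
  }
  delta
}

# Walk from bin i to the local minimum of the normalized insulation (the
# valley the delta crossing marks), at most max_steps bins away.
descend_to_valley <- function(norm, i, max_steps = 3L) {
  n <- length(norm)
  for (s in seq_len(max_steps)) {
    lo <- if (i > 1 && !is.na(norm[i - 1]) && !is.na(norm[i]) &&
                norm[i - 1] < norm[i]) i - 1L else i
    hi <- if (i < n && !is.na(norm[i + 1]) && !is.na(norm[i]) &&
                norm[i + 1] < norm[i]) i + 1L else i
    nxt <- if (lo != i && (hi == i || norm[lo] <= norm[hi])) lo else hi
    if (nxt == i) break
    i <- nxt
  }
  i
}

# Nearest local maximum of delta at or left of i (indices with defined delta).
local_extremum <- function(delta, i, dir, type) {
  n <- length(delta)
  j <- i
  repeat {
    nxt <- j + dir
    if (nxt < 1 || nxt > n || is.na(delta[nxt])) break
    better <- if (type == "max") delta[nxt] >= delta[j] else delta[nxt] <= delta[j]
    if (!better) break
    j <- nxt
  }
  j
}

#' Call TAD boundaries from an insulation track
#'
#' Candidate boundaries are downward zero-crossings of the insulation delta
#' vector (crossings at insulation valleys; crossings at peaks are upward
#' and are discarded). Boundary strength is the delta at the nearest local
#' maximum to the left of the candidate minus the delta at the nearest
#' local minimum to the right; candidates with strength below
#' `min_strength` are removed. TADs are the regions between consecutive
#' boundaries; the chromosome-end flanks are returned as open intervals.
#'
#' @param track an `InsulationTrack`.
#' @param delta_span total delta span in bp (default 250 kb, i.e. 125 kb =
#'   5 bins on each side of the central bin).
#' @param min_strength minimum boundary strength (default 0.1).
#' @return list with `boundaries` (data.frame: bin, start, end, strength,
#'   region_start, region_end; coordinates bp, half-open; region = bin +/- 1
#'   flanking bin) and `tads` (data.frame: start, end, open flag).
#' @export
call_boundaries <- function(track, delta_span = 2.5e5, min_strength = 0.1) {
  stopifnot(inherits(track, "InsulationTrack"))
  bs <- track$bin_size
  db <- as.integer(round(delta_span / bs / 2))
  norm <- track$norm
  n <- length(norm)
  empty <- list(
    boundaries = data.frame(bin = integer(0), start = numeric(0),
                            end = numeric(0), strength = numeric(0),
                            region_start = numeric(0), region_end = numeric(0)),
    tads = data.frame(start = numeric(0), end = numeric(0), open = logical(0)))
  if (!any(!is.na(norm))) return(empty)
  delta <- insulation_delta(norm, db)
  def <- which(!is.na(delta))
  if (length(def) < 2) return(empty)
  cand <- integer(0)
  for (k in seq_len(length(def) - 1)) {
    i <- def[k]; j <- def[k + 1]
    if (j != i + 1) next
    di <- delta[i]; dj <- delta[j]
    # downward crossing (+ -> -) marks an insulation valley
    if (di > 0 && dj < 0) {
      # boundary bin = the deeper insulation valley of the two; tie -> left
      ni <- norm[i]; nj <- norm[j]
      pick <- if (!is.na(ni) && !is.na(nj)) {
        if (nj < ni) j else i
      } else if (abs(di) <= abs(dj)) i else j
      cand <- c(cand, descend_to_valley(norm, pick))
    } else if (di == 0 && dj < 0) {
      if (k == 1 || delta[def[k - 1]] > 0) cand <- c(cand, i) # exact zero -> left bin
    }
  }
  cand <- unique(cand)
  if (!length(cand)) return(empty)
  strength <- vapply(cand, function(i) {
    lm <- local_extremum(delta, i, -1L, "max")
    rm_ <- local_extremum(delta, i, +1L, "min")
    delta[lm] - delta[rm_]
  }, numeric(1))
  keepb <- strength >= min_strength
  cand <- cand[keepb]; strength <- strength[keepb]
  o <- order(cand)
  cand <- cand[o]; strength <- strength[o]
  boundaries <- data.frame(
    bin = cand,
    start = (cand - 1) * bs,
    end = cand * bs,
    strength = strength,
    region_start = pmax(0, (cand - 2) * bs),
    region_end = pmin(n * bs, (cand + 1) * bs))
  tads <- if (length(cand)) {
    starts <- c(0, cand * bs)
    ends <- c((cand - 1) * bs, n * bs)
    data.frame(start = starts, end = ends,
               open = c(TRUE, rep(FALSE, max(0, length(cand) - 1)), TRUE))
  } else {
    data.frame(start = numeric(0), end = numeric(0), open = logical(0))
  }
  list(boundaries = boundaries, tads = tads)
}

#' Arrowhead transformation
#'
#' `A[i, i+d] = (M[i, i-d] - M[i, i+d]) / (M[i, i-d] + M[i, i+d])`, defined
#' where both cells exist and the denominator is positive; other cells are
#' NA (never NaN/Inf).
#'
#' @param b a `BalancedMatrix` or `ContactMatrix`.
#' @return Matrix with `A[i, j]` for `j > i` (NA elsewhere).
#' @export
arrowhead_transform <- function(b) {
  m <- if (inherits(b, "BalancedMatrix")) b$matrix else b
  w <- m$counts
  n <- nrow(w)
  a <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    dmax <- min(i - 1, n - i)
    if (dmax < 1) next
    d <- seq_len(dmax)
    up <- w[cbind(i, i - d)]
    dn <- w[cbind(i, i + d)]
    den <- up + dn
    ok <- is.finite(den) & den > 0
    a[cbind(i, (i + d))[ok, , drop = FALSE]] <- (up[ok] - dn[ok]) / den[ok]
  }
  a
}

# Corner score of candidate domain [a, b] (bins, inclusive): the arrowhead
# matrix summed over the wedge of cells whose upstream mirror falls inside
# the domain and whose downstream partner falls beyond it:
# { (i, j) : a <= i <= b, b < j <= 2 i - a }. Returns the wedge sum and
# cell count; the normalized score is sum / count.
corner_score <- function(A, a, b) {
  n <- nrow(A)
  tot <- 0; cnt <- 0L
  for (i in a:b) {
    jmax <- min(2 * i - a, n)
    if (jmax <= b) next
    v <- A[i, (b + 1):jmax]
    v <- v[!is.na(v)]
    tot <- tot + sum(v); cnt <- cnt + length(v)
  }
  c(sum = tot, count = cnt)
}

#' Contact domains from the arrowhead matrix (simplified corner-score DP)
#'
#' Scores every candidate interval by the mean arrowhead value over its
#' corner wedge; candidates reaching `threshold` enter a dynamic program
#' that selects the best non-overlapping set, maximizing total net wedge
#' evidence (wedge sum minus half the threshold per wedge cell). The net
#' form makes one full domain beat both any split of it into sub-intervals
#' and any dilution by extending into featureless background. This is a
#' deliberately simplified corner-score caller (no variance or
#' sign-consistency terms).
#'
#' @param A arrowhead matrix from [arrowhead_transform()].
#' @param bin_size bin width in bp used for output coordinates.
#' @param min_size minimum domain size in bins (default 2).
#' @param max_size maximum domain size in bins (default 80).
#' @param threshold minimum corner score (default 0.2).
#' @return data.frame of non-overlapping sorted domains: start_bin, end_bin
#'   (1-based inclusive), start, end (bp, half-open), score.
#' @export
call_domains_arrowhead <- function(A, bin_size = 25e3, min_size = 2,
                                   max_size = 80, threshold = 0.2) {
  n <- nrow(A)
  empty <- data.frame(start_bin = integer(0), end_bin = integer(0),
                      start = numeric(0), end = numeric(0), score = numeric(0))
  if (n < min_size || !any(!is.na(A))) return(empty)
  cands <- list()
  for (a in seq_len(n - min_size + 1)) {
    for (b in (a + min_size - 1):min(n, a + max_size - 1)) {
      sc <- corner_score(A, a, b)
      if (sc[["count"]] > 0 && sc[["sum"]] / sc[["count"]] >= threshold) {
        net <- sc[["sum"]] - 0.5 * threshold * sc[["count"]]
        cands[[length(cands) + 1L]] <- c(a, b, net,
                                         sc[["sum"]] / sc[["count"]])
      }
    }
  }
  if (!length(cands)) return(empty)
  cd <- do.call(rbind, cands)
  cd <- cd[order(cd[, 2]), , drop = FALSE]
  # weighted interval scheduling on end-sorted candidates
  k <- nrow(cd)
  best <- numeric(k + 1)
  prev <- vapply(seq_len(k), function(r) {
    p <- which(cd[, 2] < cd[r, 1])
    if (length(p)) max(p) else 0L
  }, integer(1))
  for (r in seq_len(k)) {
    best[r + 1] <- max(best[r], cd[r, 3] + best[prev[r] + 1])
  }
  sel <- integer(0)
  r <- k
  while (r > 0) {
    if (best[r + 1] == best[r]) {
      r <- r - 1L
    } else {
      sel <- c(r, sel)
      r <- prev[r]
    }
  }
  out <- cd[sel, , drop = FALSE]
  out <- out[order(out[, 1]), , drop = FALSE]
  data.frame(start_bin = as.integer(out[, 1]), end_bin = as.integer(out[, 2]),
             start = (out[, 1] - 1) * bin_size, end = out[, 2] * bin_size,
             score = out[, 4], evidence = out[, 3])
}

#' Directionality index
#'
#' For each bin, `A` is the total contact count to the upstream `window`
#' and `B` to the downstream `window`;
#' `DI = sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)` with
#' `E = (A + B) / 2`. When `A == B` (including `A == B == 0`) the formula's
#' sign is undefined and DI is reported as 0 with a flag. Bins whose window
#' is truncated by a chromosome end are flagged.
#'
#' @param b a `BalancedMatrix` or `ContactMatrix` at 25-kb resolution.
#' @param window one-sided window in bp (default 2 Mb).
#' @return data.frame: bin, A, B, DI, truncated, tied.
#' @export
directionality_index <- function(b, window = 2e6) {
  m <- if (inherits(b, "BalancedMatrix")) b$matrix else b
  w <- m$counts
  n <- nrow(w)
  wb <- as.integer(round(window / m$bin_size))
  A <- B <- DI <- numeric(n)
  truncated <- tied <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - wb); hi <- min(n, i + wb)
    truncated[i] <- (i - wb < 1) || (i + wb > n)
    A[i] <- if (lo <= i - 1) sum(w[i, lo:(i - 1)]) else 0
    B[i] <- if (i + 1 <= hi) sum(w[i, (i + 1):hi]) else 0
    DI[i] <- di_value(A[i], B[i])
    tied[i] <- A[i] == B[i]
  }
  data.frame(bin = seq_len(n), A = A, B = B, DI = DI,
             truncated = truncated, tied = tied)
}

#' Directionality index of a single (A, B) pair
#'
#' @param A,B upstream and downstream contact totals.
#' @export
di_value <- function(A, B) {
  if (A == B) return(0)
  E <- (A + B) / 2
  sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
}
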