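# Shared internal helpers: interval arithmetic and seed sub-streams.

# Derive a reproducible sub-seed from a global seed and a stream name, so
# that adding one generator never perturbs another's draws. Kept < 2^31.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483629 + 1)
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(substream_seed(seed, stream))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# Merge overlapping/adjacent half-open intervals given as a 2-column matrix
# or data.frame with columns start, end. Returns a data.frame sorted by start.
merge_intervals <- function(start, end, gap = 0L) {
  if (length(start) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (k in seq_along(start)[-1]) {
    if (start[k] <= me + gap) {
      me <- max(me, end[k])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[k]; me <- end[k]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

# Total length of the union of half-open intervals.
union_length <- function(start, end) {
  m <- merge_intervals(start, end)
  sum(m$end - m$start)
}

# Length of overlap of [s1,e1) with [s2,e2), vectorised.
overlap_length <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
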