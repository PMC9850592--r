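# Cross-accession pan-classification of compartments and TAD boundaries.

#' Classify pan-compartment bins
#'
#' Per bin across the panel: conservative bins show the same status (A, B,
#' or NA) in every accession; variable bins show at least two distinct
#' statuses. Variable bins split into only-A (A and NA, no B), only-B
#' (B and NA, no A), and AB (both A and B present). The coefficient of
#' compartment variation CCV = ln(#B / #A) is defined only for variable-AB
#' bins.
#'
#' @param status character matrix, accessions x bins, entries "A"/"B"/NA.
#' @return data.frame per bin: `bin`, `nA`, `nB`, `nNA`, `class` (one of
#'   conservative-A/B/NA, variable-onlyA/onlyB/AB), `ccv`.
#' @export
classify_pan_compartments <- function(status) {
  stopifnot(is.matrix(status))
  nb <- ncol(status)
  nA <- colSums(status == "A", na.rm = TRUE)
  nB <- colSums(status == "B", na.rm = TRUE)
  nNA <- colSums(is.na(status))
  n <- nrow(status)
  cls <- character(nb)
  cls[nA == n] <- "conservative-A"
  cls[nB == n] <- "conservative-B"
  cls[nNA == n] <- "conservative-NA"
  variable <- nA < n & nB < n & nNA < n
  cls[variable & nA > 0 & nB == 0] <- "variable-onlyA"
  cls[variable & nB > 0 & nA == 0] <- "variable-onlyB"
  cls[variable & nA > 0 & nB > 0] <- "variable-AB"
  ccv_v <- rep(NA_real_, nb)
  ab <- cls == "variable-AB"
  ccv_v[ab] <- log(nB[ab] / nA[ab])
  data.frame(bin = seq_len(nb), nA = nA, nB = nB, nNA = nNA,
             class = cls, ccv = ccv_v)
}

#' Coefficient of compartment variation
#'
#' `CCV = ln(#B / #A)`: positive values lean toward B, negative toward A.
#' Defined only when both counts are positive.
#'
#' @param nA,nB numbers of accessions with A and with B status at the bin.
#' @export
ccv <- function(nA, nB) {
  ifelse(nA > 0 & nB > 0, log(nB / nA), NA_real_)
}

#' Pan-compartment saturation curve
#'
#' For each panel size k = 1..N, draws `n_rand` random accession orderings
#' and classifies the first k accessions of each ordering, so that per
#' randomization the conservative count is non-increasing and the variable
#' count non-decreasing in k. At k = N every randomization equals the full
#' panel classification.
#'
#' @param status character matrix, accessions x bins.
#' @param n_rand number of randomizations (default 100).
#' @param seed RNG seed.
#' @return data.frame: k, conservative_mean, conservative_sd,
#'   variable_mean, variable_sd.
#' @export
pan_saturation_curve <- function(status, n_rand = 100, seed = 1) {
  n <- nrow(status)
  cons <- vars <- matrix(0, n_rand, n)
  with_stream(seed, "saturation", {
    for (r in seq_len(n_rand)) {
      perm <- sample(n)
      for (k in seq_len(n)) {
        cl <- classify_pan_compartments(status[perm[seq_len(k)], , drop = FALSE])
        cons[r, k] <- sum(startsWith(cl$class, "conservative"))
        vars[r, k] <- sum(startsWith(cl$class, "variable"))
      }
    }
  })
  data.frame(k = seq_len(n),
             conservative_mean = colMeans(cons),
             conservative_sd = apply(cons, 2, stats::sd),
             variable_mean = colMeans(vars),
             variable_sd = apply(vars, 2, stats::sd))
}

#' Map an interval through a coordinate map
#'
#' The map is a table of colinear segments
#' (`ref_chrom, ref_start, ref_end, query_chrom, query_start, query_end,
#' strand`), non-overlapping on both genomes, 0-based half-open. The
#' interval is mapped from the `from` side to the other side segment by
#' segment; colinear mapped pieces on one target chromosome are unioned
#' into a span. Mapping fails when less than `min_frac` of the interval is
#' covered by map segments.
#'
#' @param map coordinate-map data.frame.
#' @param chrom,start,end interval on the `from` genome (0-based half-open).
#' @param from `"query"` (default) or `"ref"`: which side the interval is on.
#' @param min_frac minimum mapped fraction for success (default 0.5).
#' @return list: `ok`, `chrom`, `start`, `end` (the spanning mapped
#'   interval), `fraction` (mapped fraction), `pieces` (data.frame of
#'   mapped sub-intervals).
#' @export
liftover_interval <- function(map, chrom, start, end, from = "query",
                              min_frac = 0.5) {
  stopifnot(end > start)
  if (from == "query") {
    sc <- map$query_chrom; ss <- map$query_start; se <- map$query_end
    tc <- map$ref_chrom; ts <- map$ref_start; te <- map$ref_end
  } else {
    sc <- map$ref_chrom; ss <- map$ref_start; se <- map$ref_end
    tc <- map$query_chrom; ts <- map$query_start; te <- map$query_end
  }
  hit <- which(sc == chrom & ss < end & se > start)
  fail <- list(ok = FALSE, chrom = NA_character_, start = NA_real_,
               end = NA_real_, fraction = 0,
               pieces = data.frame(chrom = character(0), start = numeric(0),
                                   end = numeric(0)))
  if (!length(hit)) return(fail)
  pc <- character(0); ps <- pe <- numeric(0)
  for (k in hit) {
    a <- max(start, ss[k]); b <- min(end, se[k])
    if (map$strand[k] == "-") {
      ms <- ts[k] + (se[k] - b); me <- ts[k] + (se[k] - a)
    } else {
      ms <- ts[k] + (a - ss[k]); me <- ts[k] + (b - ss[k])
    }
    pc <- c(pc, tc[k]); ps <- c(ps, ms); pe <- c(pe, me)
  }
  frac <- union_length(pmax(ss[hit], start), pmin(se[hit], end)) / (end - start)
  pieces <- data.frame(chrom = pc, start = ps, end = pe)
  if (frac < min_frac) { fail$fraction <- frac; fail$pieces <- pieces; return(fail) }
  # spanning interval on the majority target chromosome
  cov <- tapply(pe - ps, pc, sum)
  main <- names(cov)[which.max(cov)]
  on <- pc == main
  list(ok = TRUE, chrom = main, start = min(ps[on]), end = max(pe[on]),
       fraction = frac, pieces = pieces)
}

#' Pairwise comparative classification of TAD boundaries
#'
#' Query boundary regions (the 75-kb boundary bin plus one flank each side)
#' are lifted to reference coordinates and compared with reference
#' boundary regions. Two regions match when they overlap by at least half
#' the (shorter) region length -- for exact 3-bin regions this is
#' precisely a boundary shift of at most 1 bin in either flank: a 1-bin
#' shift leaves 2 bins (50 kb) of overlap, a 2-bin shift only 1 bin.
#' Matched boundaries are labeled common, the rest specific; query
#' boundaries whose regions fail coordinate conversion are query-specific.
#'
#' @param ref_bounds data.frame with `chrom`, `region_start`, `region_end`
#'   on reference coordinates.
#' @param query_bounds same columns on the query genome.
#' @param map coordinate map (query -> ref) as in [liftover_interval()];
#'   `NULL` means identity.
#' @param min_frac liftover success fraction (default 0.5).
#' @return list: `ref` and `query` data.frames with a `label` column
#'   (reference-common/-specific, query-common/-specific), and `summary`
#'   with common percentages in both directions.
#' @export
match_boundaries_pairwise <- function(ref_bounds, query_bounds, map = NULL,
                                      min_frac = 0.5) {
  nq <- nrow(query_bounds)
  q_chrom <- character(nq); q_start <- q_end <- rep(NA_real_, nq)
  for (k in seq_len(nq)) {
    if (is.null(map)) {
      q_chrom[k] <- query_bounds$chrom[k]
      q_start[k] <- query_bounds$region_start[k]
      q_end[k] <- query_bounds$region_end[k]
    } else {
      lv <- liftover_interval(map, query_bounds$chrom[k],
                              query_bounds$region_start[k],
                              query_bounds$region_end[k],
                              from = "query", min_frac = min_frac)
      if (lv$ok) { q_chrom[k] <- lv$chrom; q_start[k] <- lv$start; q_end[k] <- lv$end }
    }
  }
  nr <- nrow(ref_bounds)
  ref_match <- rep(FALSE, nr)
  query_match <- rep(FALSE, nq)
  for (r in seq_len(nr)) {
    for (q in seq_len(nq)) {
      if (is.na(q_start[q])) next
      if (ref_bounds$chrom[r] != q_chrom[q]) next
      ov <- overlap_length(ref_bounds$region_start[r], ref_bounds$region_end[r],
                           q_start[q], q_end[q])
      need <- 0.5 * min(ref_bounds$region_end[r] - ref_bounds$region_start[r],
                        q_end[q] - q_start[q])
      if (ov >= need && ov > 0) {
        ref_match[r] <- TRUE
        query_match[q] <- TRUE
      }
    }
  }
  ref <- ref_bounds
  ref$label <- ifelse(ref_match, "reference-common", "reference-specific")
  query <- query_bounds
  query$label <- ifelse(query_match, "query-common", "query-specific")
  list(ref = ref, query = query,
       summary = data.frame(
         ref_common_pct = if (nr) 100 * mean(ref_match) else NA_real_,
         query_common_pct = if (nq) 100 * mean(query_match) else NA_real_))
}

#' Similarity of a boundary-region pair from mapped-segment evidence
#'
#' Similarity is the fraction of the boundary region covered by mapped
#' (aligned) segments: overlapping evidence segments are merged before
#' summing.
#'
#' @param region_start,region_end the boundary region (must span 3 bins).
#' @param seg_start,seg_end mapped-segment evidence intervals on the same
#'   coordinates.
#' @param bin_size bin width (default 25 kb).
#' @return Fraction in \[0, 1\].
#' @export
boundary_region_similarity <- function(region_start, region_end,
                                       seg_start, seg_end, bin_size = 25e3) {
  len <- region_end - region_start
  if (abs(len - 3 * bin_size) > 1e-6) {
    stop("boundary region must span exactly 3 bins")
  }
  if (!length(seg_start)) return(0)
  s <- pmax(seg_start, region_start)
  e <- pmin(seg_end, region_end)
  keep <- e > s
  if (!any(keep)) return(0)
  union_length(s[keep], e[keep]) / len
}

#' Cluster boundary regions across accessions
#'
#' Builds a match graph over boundary regions with an edge wherever the
#' directed similarity reaches `cutoff` in either direction, and takes
#' connected components (single linkage) as clusters. A cluster is core
#' when its members span every panel accession, private when they come
#' from exactly one accession, and dispensable otherwise.
#'
#' @param regions data.frame: `region_id`, `accession` (one row per
#'   boundary region).
#' @param edges data.frame of directed similarities: `from`, `to`
#'   (region ids), `similarity`.
#' @param accessions character vector of all panel accession ids.
#' @param cutoff similarity cutoff (default 0.5).
#' @return list: `membership` (regions with `cluster` column), `clusters`
#'   (data.frame: cluster, n_regions, n_accessions, class), `summary`
#'   (counts of core/dispensable/private clusters and the directed
#'   comparison count N^2).
#' @export
cluster_boundary_regions <- function(regions, edges, accessions,
                                     cutoff = 0.5) {
  ids <- regions$region_id
  idx <- stats::setNames(seq_along(ids), ids)
  parent <- seq_along(ids)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(edges)) {
    keep <- edges$similarity >= cutoff &
      edges$from %in% ids & edges$to %in% ids
    for (k in which(keep)) {
      a <- find(idx[[edges$from[k]]]); b <- find(idx[[edges$to[k]]])
      if (a != b) parent[b] <- a
    }
  }
  comp <- vapply(seq_along(ids), find, integer(1))
  comp <- match(comp, unique(comp))
  regions$cluster <- comp
  n_panel <- length(accessions)
  cl <- do.call(rbind, lapply(split(seq_along(ids), comp), function(rows) {
    nacc <- length(unique(regions$accession[rows]))
    data.frame(n_regions = length(rows), n_accessions = nacc,
               class = if (nacc == n_panel) "core"
                       else if (nacc == 1L) "private" else "dispensable")
  }))
  cl$cluster <- as.integer(rownames(cl))
  cl <- cl[order(cl$cluster), c("cluster", "n_regions", "n_accessions", "class")]
  rownames(cl) <- NULL
  list(membership = regions, clusters = cl,
       summary = data.frame(
         n_clusters = nrow(cl),
         core = sum(cl$class == "core"),
         dispensable = sum(cl$class == "dispensable"),
         private = sum(cl$class == "private"),
         directed_comparisons = n_panel^2))
}
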