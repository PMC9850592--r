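# SV-vs-3D association, genomic feature tracks, repeat/DEG meta-profiles,
# nonVariation genes, and the windowed Weir-Cockerham F_ST selection scan.

#' Classify an SV against TAD boundaries
#'
#' ABA (absolute boundary-affecting) SVs span the whole 25-kb boundary bin;
#' PBA (partial boundary-affecting) SVs overlap a boundary bin partially;
#' NBA (non-boundary-affecting) SVs lie strictly inside a TAD. SVs touching
#' no annotated territory are "none". The boundary unit is the boundary
#' bin, not the 75-kb boundary region (switchable via `unit`).
#'
#' @param sv data.frame: `chrom`, `start`, `end` (0-based half-open
#'   reference intervals), plus any other columns (kept).
#' @param boundaries data.frame: `chrom`, `start`, `end` of boundary bins
#'   (set `unit = "region"` to pass 75-kb regions instead).
#' @param tads data.frame: `chrom`, `start`, `end` of TAD intervals.
#' @param unit "bin" (default) or "region"; documentation of which
#'   boundary extent ABA/PBA is judged against.
#' @return `sv` with an added `boundary_class` column.
#' @export
classify_sv_vs_boundary <- function(sv, boundaries, tads, unit = c("bin", "region")) {
  unit <- match.arg(unit)
  cls <- character(nrow(sv))
  for (k in seq_len(nrow(sv))) {
    b <- boundaries[boundaries$chrom == sv$chrom[k] &
                      boundaries$start < sv$end[k] &
                      boundaries$end > sv$start[k], , drop = FALSE]
    if (nrow(b)) {
      covers <- any(sv$start[k] <= b$start & sv$end[k] >= b$end)
      cls[k] <- if (covers) "ABA" else "PBA"
      next
    }
    t <- tads[tads$chrom == sv$chrom[k] &
                tads$start <= sv$start[k] &
                tads$end >= sv$end[k], , drop = FALSE]
    cls[k] <- if (nrow(t)) "NBA" else "none"
  }
  sv$boundary_class <- cls
  sv
}

#' Bootstrap enrichment of SVs in compartment segments
#'
#' Counts SVs overlapping the observed segments (e.g. A compartments or I
#' regions), then builds a null distribution by re-placing length-matched,
#' non-overlapping segments uniformly within each chromosome `n_boot`
#' times. Reports the z score against the null and the empirical P with
#' the +1 correction, plus a normal-approximation P.
#'
#' @param sv data.frame: `chrom`, `start`, `end`.
#' @param segments data.frame: `chrom`, `start`, `end` observed segments.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed RNG seed.
#' @return list: observed, null_mean, null_sd, z, p_empirical, p_normal,
#'   null (the replicate counts).
#' @export
sv_compartment_enrichment <- function(sv, segments, chrom_lengths,
                                      n_boot = 10000, seed = 1) {
  for (ch in unique(segments$chrom)) {
    if (any(segments$end[segments$chrom == ch] -
              segments$start[segments$chrom == ch] > chrom_lengths[[ch]])) {
      stop("segment longer than its chromosome")
    }
  }
  count_in <- function(seg) {
    hit <- 0L
    for (k in seq_len(nrow(sv))) {
      s <- seg[seg$chrom == sv$chrom[k], , drop = FALSE]
      if (any(s$start < sv$end[k] & s$end > sv$start[k])) hit <- hit + 1L
    }
    hit
  }
  obs <- count_in(segments)
  null <- integer(n_boot)
  with_stream(seed, "sv_bootstrap", {
    for (r in seq_len(n_boot)) {
      plc <- place_random_segments(segments, chrom_lengths)
      null[r] <- count_in(plc)
    }
  })
  mu <- mean(null); sdv <- stats::sd(null)
  z <- if (sdv > 0) (obs - mu) / sdv else NA_real_
  list(observed = obs, null_mean = mu, null_sd = sdv, z = z,
       p_empirical = (1 + sum(null >= obs)) / (n_boot + 1),
       p_normal = if (is.na(z)) NA_real_ else stats::pnorm(z, lower.tail = FALSE),
       null = null)
}

# Place the per-chromosome segment length multiset uniformly at random,
# non-overlapping: rejection sampling with a cap, then sequential gap
# placement as fallback.
place_random_segments <- function(segments, chrom_lengths, max_reject = 50L) {
  out <- NULL
  for (ch in unique(segments$chrom)) {
    lens <- segments$end[segments$chrom == ch] - segments$start[segments$chrom == ch]
    L <- chrom_lengths[[ch]]
    placed_s <- placed_e <- numeric(0)
    for (l in sort(lens, decreasing = TRUE)) {
      ok <- FALSE
      for (tr in seq_len(max_reject)) {
        s <- floor(stats::runif(1, 0, L - l + 1))
        if (!any(s < placed_e & s + l > placed_s)) {
          placed_s <- c(placed_s, s); placed_e <- c(placed_e, s + l)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        # fallback: drop into the first random free gap large enough
        gaps <- merge_intervals(placed_s, placed_e)
        free_s <- c(0, gaps$end); free_e <- c(gaps$start, L)
        fit <- which(free_e - free_s >= l)
        if (!length(fit)) stop("cannot place segment: chromosome too full")
        g <- fit[sample.int(length(fit), 1)]
        s <- floor(stats::runif(1, free_s[g], free_e[g] - l + 1))
        placed_s <- c(placed_s, s); placed_e <- c(placed_e, s + l)
      }
    }
    out <- rbind(out, data.frame(chrom = ch, start = placed_s, end = placed_e))
  }
  out
}

#' Effect and contribution of SV types on boundary variation
#'
#' For each of the 8 SV classes ({ABA, PBA} x {PAV, CNV, INV, TRANS}):
#' contribution = #(specific boundaries with the SV) / #specific;
#' effect = #(specific with SV) / #(boundaries with SV); one-sided
#' Fisher's exact P (enrichment of the SV in specific boundaries) from the
#' 2x2 table (specific/common) x (SV/no SV).
#'
#' @param boundary_label character vector, "specific" or "common", one per
#'   boundary.
#' @param sv_presence logical matrix, boundaries x SV classes (column names
#'   name the classes, e.g. "ABA-PAV").
#' @return data.frame per SV class: n_with_sv, n_specific_with_sv,
#'   contribution_pct, effect_pct (NA when the denominator is zero),
#'   p_fisher.
#' @export
sv_effect_contribution <- function(boundary_label, sv_presence) {
  stopifnot(length(boundary_label) == nrow(sv_presence))
  spec <- boundary_label == "specific"
  n_spec <- sum(spec)
  out <- lapply(colnames(sv_presence), function(cl) {
    has <- sv_presence[, cl]
    a <- sum(spec & has)          # specific with SV
    tab <- matrix(c(a, sum(!spec & has), sum(spec & !has), sum(!spec & !has)),
                  nrow = 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(sv_class = cl,
               n_with_sv = sum(has),
               n_specific_with_sv = a,
               contribution_pct = if (n_spec > 0) 100 * a / n_spec else NA_real_,
               effect_pct = if (sum(has) > 0) 100 * a / sum(has) else NA_real_,
               p_fisher = p)
  })
  do.call(rbind, out)
}

#' Windowed genomic feature track
#'
#' Computes per-window GC fraction, deduplicated TSS count (raw and per
#' Mb), and merged repeat coverage fraction. GC is taken from per-window
#' values when `gc` is numeric, or computed over non-N bases when `seq` is
#' a character string of bases.
#'
#' @param chrom_length chromosome length in bp.
#' @param window window size in bp.
#' @param tss numeric vector of TSS positions (bp).
#' @param repeats data.frame with `start`, `end` repeat fragments.
#' @param gc optional per-window GC fractions.
#' @param seq optional base-level sequence (single string, A/C/G/T/N).
#' @return data.frame per window: start, end, gc, tss_count, tss_per_mb,
#'   repeat_frac, partial (flag for a final truncated window).
#' @export
feature_tracks <- function(chrom_length, window, tss = numeric(0),
                           repeats = NULL, gc = NULL, seq = NULL) {
  n <- ceiling(chrom_length / window)
  starts <- (seq_len(n) - 1) * window
  ends <- pmin(starts + window, chrom_length)
  gc_out <- rep(NA_real_, n)
  if (!is.null(seq)) {
    bases <- strsplit(toupper(seq), "")[[1]]
    for (w in seq_len(n)) {
      b <- bases[(starts[w] + 1):min(ends[w], length(bases))]
      b <- b[b != "N"]
      gc_out[w] <- if (length(b)) mean(b %in% c("G", "C")) else NA_real_
    }
  } else if (!is.null(gc)) {
    gc_out[seq_along(gc)] <- gc
  }
  tss <- unique(tss)
  tss_count <- vapply(seq_len(n), function(w) {
    sum(tss >= starts[w] & tss < ends[w])
  }, numeric(1))
  rep_frac <- rep(0, n)
  if (!is.null(repeats) && nrow(repeats)) {
    for (w in seq_len(n)) {
      s <- pmax(repeats$start, starts[w]); e <- pmin(repeats$end, ends[w])
      keep <- e > s
      if (any(keep)) {
        rep_frac[w] <- union_length(s[keep], e[keep]) / (ends[w] - starts[w])
      }
    }
  }
  data.frame(start = starts, end = ends, gc = gc_out,
             tss_count = tss_count, tss_per_mb = tss_count * 1e6 / (ends - starts),
             repeat_frac = rep_frac,
             partial = ends - starts < window)
}

#' Repeat meta-profile around anchors
#'
#' Aggregates repeat fragments around a set of anchor positions into
#' offset bins spanning `[-flank, +flank)`. Coverage percentage per offset
#' bin uses merged fragment coverage; fragment counts and mean lengths
#' assign each fragment to the offset bin containing its midpoint
#' (`floor((start + end) / 2)`; a midpoint on a bin edge belongs to the
#' right-open bin starting there). Anchor sides truncated by a chromosome
#' end are excluded from that bin's denominator.
#'
#' @param anchors numeric vector of anchor positions (bp).
#' @param repeats data.frame: `start`, `end`, optional `subtype`.
#' @param flank one-sided flank in bp.
#' @param bin offset bin width in bp.
#' @param chrom_length chromosome length for truncation handling.
#' @return data.frame per offset bin (and per subtype when present):
#'   offset (bin start relative to anchor), coverage_pct, n_fragments,
#'   mean_length, n_anchors (denominator).
#' @export
repeat_metaprofile <- function(anchors, repeats, flank, bin,
                               chrom_length = Inf) {
  nb <- as.integer(2 * flank / bin)
  offs <- -flank + (seq_len(nb) - 1) * bin
  subtypes <- if (!is.null(repeats$subtype)) unique(repeats$subtype) else "all"
  out <- list()
  for (st in subtypes) {
    rp <- if (identical(st, "all")) repeats else repeats[repeats$subtype == st, , drop = FALSE]
    mid <- floor((rp$start + rp$end) / 2)
    cov <- cnt <- lensum <- nanch <- numeric(nb)
    for (bi in seq_len(nb)) {
      for (a in anchors) {
        ws <- a + offs[bi]; we <- ws + bin
        if (ws < 0 || we > chrom_length) next
        nanch[bi] <- nanch[bi] + 1
        s <- pmax(rp$start, ws); e <- pmin(rp$end, we)
        keep <- e > s
        if (any(keep)) cov[bi] <- cov[bi] + union_length(s[keep], e[keep])
        inbin <- mid >= ws & mid < we
        cnt[bi] <- cnt[bi] + sum(inbin)
        lensum[bi] <- lensum[bi] + sum((rp$end - rp$start)[inbin])
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      subtype = st, offset = offs,
      coverage_pct = ifelse(nanch > 0, 100 * cov / (nanch * bin), NA_real_),
      n_fragments = cnt,
      mean_length = ifelse(cnt > 0, lensum / cnt, NA_real_),
      n_anchors = nanch)
  }
  do.call(rbind, out)
}

#' DEG density profile around boundary classes
#'
#' Average number of DEGs (positioned at their TSS on reference
#' coordinates) per offset bin around boundaries of each class, averaged
#' across accessions.
#'
#' @param boundaries data.frame: `position` (bp), `class`.
#' @param degs data.frame: `accession`, `tss` (bp).
#' @param flank one-sided flank in bp.
#' @param bin offset bin width in bp.
#' @return data.frame: class, offset, mean_degs (mean count per boundary,
#'   averaged over accessions).
#' @export
deg_density_profile <- function(boundaries, degs, flank, bin) {
  nb <- as.integer(2 * flank / bin)
  offs <- -flank + (seq_len(nb) - 1) * bin
  accs <- unique(degs$accession)
  if (!length(accs)) accs <- NA_character_  # empty DEG table -> zero profile
  out <- list()
  for (cl in unique(boundaries$class)) {
    pos <- boundaries$position[boundaries$class == cl]
    prof_acc <- matrix(0, length(accs), nb)
    for (ai in seq_along(accs)) {
      tss <- degs$tss[degs$accession == accs[ai]]
      for (bi in seq_len(nb)) {
        cnt <- vapply(pos, function(p) {
          sum(tss >= p + offs[bi] & tss < p + offs[bi] + bin)
        }, numeric(1))
        prof_acc[ai, bi] <- if (length(pos)) mean(cnt) else NA_real_
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      class = cl, offset = offs, mean_degs = colMeans(prof_acc))
  }
  do.call(rbind, out)
}

#' Flag nonVariation genes
#'
#' A gene is a nonVariation gene for an accession pair iff its genic
#' interval (0-based half-open) overlaps no variant (SNV position, InDel,
#' or SV interval) between the two accessions.
#'
#' @param genes data.frame: `gene_id`, `chrom`, `start`, `end`.
#' @param variants data.frame: `chrom`, `start`, `end` (a SNV at position p
#'   is the interval `[p, p+1)`).
#' @return `genes` with a logical `nonvariation` column.
#' @export
nonvariation_genes <- function(genes, variants) {
  hit <- vapply(seq_len(nrow(genes)), function(k) {
    v <- variants[variants$chrom == genes$chrom[k], , drop = FALSE]
    any(v$start < genes$end[k] & v$end > genes$start[k])
  }, logical(1))
  genes$nonvariation <- !hit
  genes
}

# Per-site Weir-Cockerham variance components from allele counts of two
# populations (allele-count form: MSP/MSG mean squares over allele copies).
wc_site_components <- function(n1, x1, n2, x2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  nsum <- n1 + n2
  pbar <- (x1 + x2) / nsum
  if (pbar <= 0 || pbar >= 1) return(c(a = NA_real_, tot = NA_real_))
  r <- 2
  msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nsum - r)
  nc <- (nsum - (n1^2 + n2^2) / nsum) / (r - 1)
  c(a = msp - msg, tot = msp + (nc - 1) * msg)
}

# Hudson's estimator components for the optional alternative.
hudson_site_components <- function(n1, x1, n2, x2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pbar <- (x1 + x2) / (n1 + n2)
  if (pbar <= 0 || pbar >= 1) return(c(a = NA_real_, tot = NA_real_))
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  c(a = num, tot = den)
}

#' Windowed F_ST and top-5% selected regions
#'
#' Per-site Weir-Cockerham variance components are combined over each
#' window as a ratio of sums. Monomorphic sites contribute nothing;
#' windows with fewer than `min_sites` polymorphic sites are undefined and
#' excluded from ranking. Selected regions are the windows whose F_ST
#' falls in the top `top` fraction of defined windows, merged when
#' adjacent.
#'
#' @param sites data.frame: `chrom`, `pos` (bp), `n1`, `x1`, `n2`, `x2`
#'   (total and alternate allele counts per population).
#' @param chrom_lengths named numeric vector.
#' @param window window size in bp (default 25 kb).
#' @param min_sites minimum polymorphic sites per window (default 5).
#' @param top selected fraction (default 0.05).
#' @param estimator "wc" (Weir-Cockerham, default) or "hudson".
#' @return list: `windows` (chrom, start, end, n_sites, fst), `selected`
#'   (merged BED-like data.frame of selected regions), `threshold`.
#' @export
windowed_fst <- function(sites, chrom_lengths, window = 25e3, min_sites = 5,
                         top = 0.05, estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  compfun <- if (estimator == "wc") wc_site_components else hudson_site_components
  if (any(sites$n1 < 2 | sites$n2 < 2)) stop("population allele count < 2")
  comp <- t(mapply(compfun, sites$n1, sites$x1, sites$n2, sites$x2))
  wins <- NULL
  for (ch in names(chrom_lengths)) {
    n <- ceiling(chrom_lengths[[ch]] / window)
    starts <- (seq_len(n) - 1) * window
    idx_ch <- which(sites$chrom == ch)
    wbin <- sites$pos[idx_ch] %/% window + 1
    a_sum <- tot_sum <- nsite <- numeric(n)
    for (k in seq_along(idx_ch)) {
      w <- wbin[k]
      if (w < 1 || w > n || is.na(comp[idx_ch[k], 1])) next
      a_sum[w] <- a_sum[w] + comp[idx_ch[k], 1]
      tot_sum[w] <- tot_sum[w] + comp[idx_ch[k], 2]
      nsite[w] <- nsite[w] + 1
    }
    fst <- ifelse(nsite >= min_sites & tot_sum > 0, a_sum / tot_sum, NA_real_)
    wins <- rbind(wins, data.frame(chrom = ch, start = starts,
                                   end = pmin(starts + window, chrom_lengths[[ch]]),
                                   n_sites = nsite, fst = fst))
  }
  def <- wins[!is.na(wins$fst), , drop = FALSE]
  if (!nrow(def)) {
    return(list(windows = wins,
                selected = data.frame(chrom = character(0), start = numeric(0),
                                      end = numeric(0)),
                threshold = NA_real_))
  }
  thr <- stats::quantile(def$fst, 1 - top, names = FALSE)
  sel <- def[def$fst >= thr, , drop = FALSE]
  merged <- NULL
  for (ch in unique(sel$chrom)) {
    m <- merge_intervals(sel$start[sel$chrom == ch], sel$end[sel$chrom == ch])
    merged <- rbind(merged, data.frame(chrom = ch, m))
  }
  list(windows = wins, selected = merged, threshold = thr)
}
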