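# Synthetic multi-accession panel generator with planted ground truth.
#
# A reference genome model (compartment blocks, TAD tiling, TSS/GC/repeat
# features) is perturbed per accession by structural variants applied
# left-to-right in reference coordinates; every accession carries its exact
# coordinate map back to the reference plus truth labels (lost boundaries,
# flipped compartment bins) so downstream calls can be scored.

REPEAT_SUBTYPES <- c(
  "hAT", "CACTA", "Mutator", "PIF/Harbinger", "Tc1/Mariner",
  "Tourist-like MITE", "Stowaway-like MITE", "Helitron", "unclassified DNA",
  "Gypsy", "Copia", "unclassified LTR", "LINE", "SINE",
  "simple", "low-complexity", "satellite")

default_reference_config <- function() {
  list(
    n_chrom = 2,
    chrom_length = 2e7,
    comp_bin = 1e5,
    struct_bin = 25e3,
    mean_block_bins = 15,     # mean A/B block length, 100-kb bins
    tad_median = 475e3,       # bp; matches the soybean TAD-size scale
    tad_sdlog = 0.35,
    tad_min = 150e3,
    tad_max = 1.5e6,
    tss_a = 8, tss_b = 3,     # mean TSS per 100-kb bin in A vs B
    gc_a = 0.32, gc_b = 0.38, # B compartments are GC/repeat rich
    gc_sd = 0.01,
    rep_a = 0.30, rep_b = 0.60, # target repeat coverage fraction
    rep_frag_mean = 3e3)
}

#' Simulate a reference genome model
#'
#' Builds chromosome-length, compartment, TAD, TSS, GC, and repeat tracks
#' with the configured A/B contrasts. Feature means are mixed smoothly
#' across compartment transitions (a 5-bin window average of the A
#' fraction), so intersection zones carry intermediate genomic features.
#'
#' @param config list of generator parameters; see
#'   `pan3d:::default_reference_config()` for fields and defaults.
#' @param seed RNG seed; the model is deterministic given (config, seed).
#' @return A `ReferenceModel`: chrom_lengths, comp_bin, struct_bin,
#'   comp_labels / gc / tss / repeats / tads per chromosome, config.
#' @export
simulate_reference <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(default_reference_config(), config)
  if (cfg$chrom_length <= 0 || cfg$n_chrom <= 0 ||
      cfg$tss_a < 0 || cfg$tss_b < 0 || cfg$rep_a < 0 || cfg$rep_b < 0) {
    stop("non-positive lengths or densities in configuration")
  }
  if (cfg$chrom_length %% cfg$comp_bin != 0) {
    stop("chromosome length must be a multiple of the compartment bin")
  }
  chroms <- sprintf("chr%d", seq_len(cfg$n_chrom))
  lens <- stats::setNames(rep(cfg$chrom_length, cfg$n_chrom), chroms)
  model <- list(chrom_lengths = lens, comp_bin = cfg$comp_bin,
                struct_bin = cfg$struct_bin, config = cfg,
                comp_labels = list(), gc = list(), tss = list(),
                repeats = list(), tads = list())
  nb <- cfg$chrom_length / cfg$comp_bin
  for (ch in chroms) {
    model$comp_labels[[ch]] <- with_stream(seed, paste0("labels_", ch), {
      lab <- character(0)
      cur <- sample(c("A", "B"), 1)
      while (length(lab) < nb) {
        blk <- 1 + stats::rgeom(1, 1 / cfg$mean_block_bins)
        lab <- c(lab, rep(cur, blk))
        cur <- if (cur == "A") "B" else "A"
      }
      lab[seq_len(nb)]
    })
    lab <- model$comp_labels[[ch]]
    # A fraction of the 5-bin window centred on each bin: 1 deep inside A
    # blocks, 0 deep inside B, intermediate at transitions
    amix <- vapply(seq_len(nb), function(i) {
      w <- lab[max(1, i - 2):min(nb, i + 2)]
      mean(w == "A")
    }, numeric(1))
    model$gc[[ch]] <- with_stream(seed, paste0("gc_", ch), {
      pmin(1, pmax(0, stats::rnorm(nb, cfg$gc_b + amix * (cfg$gc_a - cfg$gc_b),
                                   cfg$gc_sd)))
    })
    model$tss[[ch]] <- with_stream(seed, paste0("tss_", ch), {
      mu <- cfg$tss_b + amix * (cfg$tss_a - cfg$tss_b)
      counts <- stats::rpois(nb, mu)
      unlist(lapply(seq_len(nb), function(i) {
        if (counts[i] == 0) return(numeric(0))
        sort(floor(stats::runif(counts[i], (i - 1) * cfg$comp_bin,
                                i * cfg$comp_bin)))
      }))
    })
    model$repeats[[ch]] <- with_stream(seed, paste0("repeats_", ch), {
      frac <- cfg$rep_b + amix * (cfg$rep_a - cfg$rep_b)
      frags <- lapply(seq_len(nb), function(i) {
        target <- frac[i] * cfg$comp_bin
        got <- 0; s <- e <- numeric(0)
        while (got < target) {
          l <- max(200, round(stats::rexp(1, 1 / cfg$rep_frag_mean)))
          p <- floor(stats::runif(1, (i - 1) * cfg$comp_bin,
                                  i * cfg$comp_bin - l))
          if (p < (i - 1) * cfg$comp_bin) break
          s <- c(s, p); e <- c(e, p + l); got <- got + l
        }
        if (!length(s)) return(NULL)
        data.frame(start = s, end = e,
                   subtype = sample(REPEAT_SUBTYPES, length(s), replace = TRUE,
                                    prob = repeat_weights(lab[i])))
      })
      out <- do.call(rbind, frags)
      out[order(out$start), ]
    })
    model$tads[[ch]] <- with_stream(seed, paste0("tads_", ch), {
      bs <- cfg$struct_bin
      pos <- 0; starts <- numeric(0)
      while (pos < cfg$chrom_length) {
        starts <- c(starts, pos)
        size <- round(stats::rlnorm(1, log(cfg$tad_median), cfg$tad_sdlog) / bs) * bs
        size <- min(max(size, cfg$tad_min), cfg$tad_max)
        pos <- pos + size
      }
      ends <- c(starts[-1], cfg$chrom_length)
      keep <- ends > starts
      # avoid a runt final TAD: merge it into its neighbour
      if (sum(keep) > 1 && (ends[sum(keep)] - starts[sum(keep)]) < cfg$tad_min) {
        starts <- starts[-sum(keep)]
        ends <- c(starts[-1], cfg$chrom_length)
      }
      data.frame(start = starts, end = c(starts[-1], cfg$chrom_length))
    })
  }
  structure(model, class = "ReferenceModel")
}

# Repeat subtype sampling weights: LTRs dominate, heavier in B.
repeat_weights <- function(label) {
  w <- stats::setNames(rep(1, length(REPEAT_SUBTYPES)), REPEAT_SUBTYPES)
  w["Gypsy"] <- if (label == "B") 12 else 6
  w["Copia"] <- 6
  w["unclassified LTR"] <- 3
  w["LINE"] <- if (label == "A") 2 else 1
  w["satellite"] <- if (label == "B") 3 else 1
  w / sum(w)
}

#' @export
print.ReferenceModel <- function(x, ...) {
  cat(sprintf("ReferenceModel: %d chromosomes x %g Mb, %d TADs, %d TSS\n",
              length(x$chrom_lengths), x$chrom_lengths[[1]] / 1e6,
              sum(vapply(x$tads, nrow, integer(1))),
              sum(vapply(x$tss, length, integer(1)))))
  invisible(x)
}

# Reference TAD boundary positions (internal junctions) per chromosome.
reference_boundaries <- function(tads) tads$start[-1]

# Per-bin TSS density on the compartment grid (gene-density covariate for
# compartment orientation).
gene_density_track <- function(model, chrom, bin_size = NULL) {
  bs <- bin_size %||% model$comp_bin
  n <- ceiling(model$chrom_lengths[[chrom]] / bs)
  tabulate(model$tss[[chrom]] %/% bs + 1, nbins = n)
}

#' Simulate a Hi-C contact matrix from planted structure
#'
#' Expected counts follow a power-law distance decay modulated by plaid
#' compartment structure and block-diagonal TAD enrichment:
#' `lambda(i, j) = scale * max(|i - j|, 1)^(-alpha) * comp_factor^[same
#' compartment] * tad_factor^[same TAD]`. Counts are Poisson draws (or a
#' negative binomial when `noise = "nb"`, or `round(lambda)` when
#' `noise = "none"`).
#'
#' @param labels per-bin compartment labels (character, NA allowed).
#' @param tad_id per-bin TAD identifier (integer, NA allowed).
#' @param bin_size bin width in bp.
#' @param chrom chromosome id for the output matrix.
#' @param scale count scale (> 0).
#' @param alpha distance-decay exponent (> 0).
#' @param comp_factor same-compartment contact multiplier (>= 1).
#' @param tad_factor same-TAD contact multiplier (>= 1).
#' @param noise "poisson" (default), "nb", or "none".
#' @param nb_size negative-binomial size when `noise = "nb"`.
#' @param depleted optional per-bin coverage multiplier in \[0,1\]
#'   (emulates reference-mapped accessions with deleted sequence).
#' @param seed RNG seed.
#' @return A `ContactMatrix`.
#' @export
simulate_contact_matrix <- function(labels, tad_id, bin_size, chrom = "chr1",
                                    scale = 150, alpha = 1, comp_factor = 1.6,
                                    tad_factor = 2, noise = "poisson",
                                    nb_size = 10, depleted = NULL, seed = 1) {
  if (alpha <= 0 || scale <= 0) stop("alpha and scale must be positive")
  n <- length(labels)
  stopifnot(length(tad_id) == n)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  lam <- scale * pmax(d, 1)^(-alpha)
  same_comp <- outer(labels, labels, function(a, b) !is.na(a) & !is.na(b) & a == b)
  same_tad <- outer(tad_id, tad_id, function(a, b) !is.na(a) & !is.na(b) & a == b)
  lam <- lam * ifelse(same_comp, comp_factor, 1) * ifelse(same_tad, tad_factor, 1)
  if (!is.null(depleted)) lam <- lam * outer(depleted, depleted)
  counts <- with_stream(seed, paste0("contacts_", chrom), {
    if (noise == "none") {
      round(lam)
    } else {
      up <- upper.tri(lam, diag = TRUE)
      v <- if (noise == "nb") {
        stats::rnbinom(sum(up), mu = lam[up], size = nb_size)
      } else {
        stats::rpois(sum(up), lam[up])
      }
      m <- matrix(0, n, n)
      m[up] <- v
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      m
    }
  })
  contact_matrix(counts, bin_size, chrom = chrom)
}

default_panel_config <- function() {
  list(
    sv_rates = c(PAV = 30, CNV = 12, INV = 6, TRANS = 1), # expected per accession
    aba_frac = 0.10,  # fraction of PAVs planted to delete a boundary bin
    pba_frac = 0.10,  # fraction of PAVs planted to clip part of a boundary bin
    pav_size = c(25e3, 100e3),
    cnv_size = c(25e3, 75e3),
    inv_size = c(100e3, 400e3),
    trans_size = 500e3,
    flip_rate = 0.03) # per-accession flip probability of border-adjacent bins
}

#' Simulate a multi-accession panel from a reference model
#'
#' The first accession is the reference itself (identity coordinate map).
#' Every other accession receives a random, non-overlapping SV edit list
#' (PAV deletions, tandem-duplication CNV gains, inversions, reciprocal
#' translocations) applied left-to-right in reference coordinates. A
#' configurable fraction of PAVs is planted directly on TAD boundary bins,
#' deleting them entirely (ABA) or partially (PBA); boundary-adjacent
#' compartment bins are flipped A<->B at the configured rate. Each
#' accession records its exact coordinate map and truth labels.
#'
#' @param reference a `ReferenceModel`.
#' @param n_accessions panel size including the reference (default 27).
#' @param config list overriding `pan3d:::default_panel_config()`.
#' @param seed RNG seed.
#' @return An `AccessionPanel`: list with `reference`, `accessions` (each
#'   with id, svs, pieces, map, chrom_lengths, labels_ref, tads_ref,
#'   truth), `config`, `seed`.
#' @export
simulate_accession_panel <- function(reference, n_accessions = 27,
                                     config = list(), seed = 1) {
  cfg <- utils::modifyList(default_panel_config(), config)
  stopifnot(inherits(reference, "ReferenceModel"))
  accs <- vector("list", n_accessions)
  ids <- c("ref", sprintf("q%02d", seq_len(max(0, n_accessions - 1))))
  accs[[1]] <- make_accession(reference, ids[1],
                              svs = empty_sv(), cfg, seed)
  for (k in seq_len(n_accessions - 1) + 1) {
    svs <- with_stream(seed, paste0("svs_", ids[k]), {
      draw_accession_svs(reference, cfg)
    })
    accs[[k]] <- make_accession(reference, ids[k], svs, cfg, seed)
  }
  structure(list(reference = reference, accessions = stats::setNames(accs, ids),
                 config = cfg, seed = seed),
            class = "AccessionPanel")
}

#' @export
print.AccessionPanel <- function(x, ...) {
  nsv <- vapply(x$accessions, function(a) nrow(a$svs), integer(1))
  cat(sprintf("AccessionPanel: %d accessions, %d-%d SVs per query accession\n",
              length(x$accessions),
              if (length(nsv) > 1) min(nsv[-1]) else 0,
              if (length(nsv) > 1) max(nsv[-1]) else 0))
  invisible(x)
}

empty_sv <- function() {
  data.frame(type = character(0), chrom = character(0), start = numeric(0),
             end = numeric(0), chrom2 = character(0), start2 = numeric(0),
             end2 = numeric(0), planted = character(0))
}

# Draw one accession's SV catalog; intervals are non-overlapping per
# chromosome (rejection-resampled; a message is emitted if the rejection
# rate exceeds 50%).
draw_accession_svs <- function(reference, cfg) {
  lens <- reference$chrom_lengths
  chroms <- names(lens)
  bs <- reference$struct_bin
  svs <- empty_sv()
  attempts <- 0L; rejects <- 0L
  occupied <- stats::setNames(
    lapply(chroms, function(ch) data.frame(start = numeric(0), end = numeric(0))),
    chroms)
  claim <- function(ch, s, e) {
    occ <- occupied[[ch]]
    if (any(occ$start < e & occ$end > s)) return(FALSE)
    occupied[[ch]] <<- rbind(occ, data.frame(start = s, end = e))
    TRUE
  }
  add <- function(type, ch, s, e, ch2 = NA, s2 = NA, e2 = NA, planted = "random") {
    svs <<- rbind(svs, data.frame(type = type, chrom = ch, start = s, end = e,
                                  chrom2 = ch2, start2 = s2, end2 = e2,
                                  planted = planted))
  }
  n_pav <- stats::rpois(1, cfg$sv_rates[["PAV"]])
  n_aba <- round(cfg$aba_frac * n_pav)
  n_pba <- round(cfg$pba_frac * n_pav)
  # planted boundary-deleting PAVs
  bounds <- do.call(rbind, lapply(chroms, function(ch) {
    b <- reference_boundaries(reference$tads[[ch]])
    if (length(b)) data.frame(chrom = ch, pos = b) else NULL
  }))
  if (nrow(bounds)) {
    pick <- bounds[sample.int(nrow(bounds), min(n_aba + n_pba, nrow(bounds))), ,
                   drop = FALSE]
    for (r in seq_len(nrow(pick))) {
      ch <- pick$chrom[r]; p <- pick$pos[r]
      if (r <= n_aba) {
        s <- p - bs; e <- p + 2 * bs      # covers the whole boundary bin
        planted <- "ABA"
      } else {
        s <- p + bs / 2; e <- p + 2 * bs  # clips the right half of the bin
        planted <- "PBA"
      }
      s <- max(0, s); e <- min(lens[[ch]], e)
      if (claim(ch, s, e)) add("PAV", ch, s, e, planted = planted)
    }
  }
  place <- function(type, ch, size) {
    for (tr in 1:40) {
      attempts <<- attempts + 1L
      s <- floor(stats::runif(1, 0, lens[[ch]] - size)) %/% 1e3 * 1e3
      if (claim(ch, s, s + size)) return(s)
      rejects <<- rejects + 1L
    }
    NA_real_
  }
  sizes <- function(range, n) {
    if (n == 0) return(numeric(0))
    round(stats::runif(n, range[1], range[2]) / 1e3) * 1e3
  }
  for (sz in sizes(cfg$pav_size, max(0, n_pav - n_aba - n_pba))) {
    ch <- sample(chroms, 1)
    s <- place("PAV", ch, sz)
    if (!is.na(s)) add("PAV", ch, s, s + sz)
  }
  for (sz in sizes(cfg$cnv_size, stats::rpois(1, cfg$sv_rates[["CNV"]]))) {
    ch <- sample(chroms, 1)
    s <- place("CNV", ch, sz)
    if (!is.na(s)) add("CNV", ch, s, s + sz)
  }
  for (sz in sizes(cfg$inv_size, stats::rpois(1, cfg$sv_rates[["INV"]]))) {
    ch <- sample(chroms, 1)
    s <- place("INV", ch, sz)
    if (!is.na(s)) add("INV", ch, s, s + sz)
  }
  n_trans <- stats::rpois(1, cfg$sv_rates[["TRANS"]])
  if (length(chroms) >= 2 && n_trans > 0) {
    for (t in seq_len(n_trans)) {
      pair <- sample(chroms, 2)
      sz <- cfg$trans_size
      s1 <- place("TRANS", pair[1], sz)
      s2 <- place("TRANS", pair[2], sz)
      if (!is.na(s1) && !is.na(s2)) {
        add("TRANS", pair[1], s1, s1 + sz, pair[2], s2, s2 + sz)
      }
    }
  }
  if (attempts > 0 && rejects / attempts > 0.5) {
    message(sprintf("SV placement rejection rate %.0f%% (genome crowded)",
                    100 * rejects / attempts))
  }
  svs
}

# Build an accession: apply the edit list to piece lists, derive the
# coordinate map, per-accession truth labels and reference-coordinate
# compartment/TAD tracks.
make_accession <- function(reference, id, svs, cfg, seed) {
  chroms <- names(reference$chrom_lengths)
  pieces <- apply_edits(reference, svs)
  map <- pieces_to_map(pieces)
  qlens <- vapply(pieces, function(p) sum(p$ref_end - p$ref_start), numeric(1))
  # lost boundaries: reference boundary bins fully covered by a PAV
  lost <- NULL
  bs <- reference$struct_bin
  for (ch in chroms) {
    b <- reference_boundaries(reference$tads[[ch]])
    if (!length(b)) next
    pav <- svs[svs$type == "PAV" & svs$chrom == ch, , drop = FALSE]
    if (!nrow(pav)) next
    gone <- vapply(b, function(p) {
      any(pav$start <= p & pav$end >= p + bs)
    }, logical(1))
    if (any(gone)) lost <- rbind(lost, data.frame(chrom = ch, pos = b[gone]))
  }
  lost <- lost %||% data.frame(chrom = character(0), pos = numeric(0))
  # merged TAD partition in reference coordinates (lost boundaries removed)
  tads_ref <- stats::setNames(lapply(chroms, function(ch) {
    b <- reference_boundaries(reference$tads[[ch]])
    b <- setdiff(b, lost$pos[lost$chrom == ch])
    data.frame(start = c(0, b), end = c(b, reference$chrom_lengths[[ch]]))
  }), chroms)
  # compartment flips near borders (reference 100-kb grid)
  flips <- stats::setNames(lapply(chroms, function(ch) integer(0)), chroms)
  labels_ref <- reference$comp_labels
  if (id != "ref" && cfg$flip_rate > 0) {
    for (ch in chroms) {
      lab <- reference$comp_labels[[ch]]
      border <- compartment_borders(lab)
      eligible <- sort(unique(pmin(pmax(c(border - 1, border, border + 1), 1),
                                   length(lab))))
      flip <- with_stream(seed, paste0("flips_", id, "_", ch), {
        eligible[stats::runif(length(eligible)) < cfg$flip_rate]
      })
      flips[[ch]] <- flip
      if (length(flip)) {
        lab[flip] <- ifelse(lab[flip] == "A", "B", "A")
        labels_ref[[ch]] <- lab
      }
    }
  }
  list(id = id, svs = svs, pieces = pieces, map = map,
       chrom_lengths = stats::setNames(qlens, chroms),
       labels_ref = labels_ref, tads_ref = tads_ref,
       truth = list(lost_boundaries = lost, flipped_bins = flips))
}

# Apply an SV edit list to the reference, returning per-chromosome piece
# lists (ref_chrom, ref_start, ref_end, strand, dup) in query order.
apply_edits <- function(reference, svs) {
  chroms <- names(reference$chrom_lengths)
  cuts <- stats::setNames(lapply(chroms, function(ch) {
    c(0, reference$chrom_lengths[[ch]],
      svs$start[svs$chrom == ch], svs$end[svs$chrom == ch],
      svs$start2[!is.na(svs$chrom2) & svs$chrom2 == ch],
      svs$end2[!is.na(svs$chrom2) & svs$chrom2 == ch])
  }), chroms)
  pieces <- stats::setNames(lapply(chroms, function(ch) {
    b <- sort(unique(cuts[[ch]]))
    data.frame(ref_chrom = ch, ref_start = b[-length(b)], ref_end = b[-1],
               strand = "+", dup = FALSE, stringsAsFactors = FALSE)
  }), chroms)
  range_idx <- function(p, ch, s, e) {
    which(p$ref_chrom == ch & p$ref_start >= s & p$ref_end <= e & !p$dup)
  }
  # apply per chromosome left-to-right; TRANS handled as reciprocal block swap
  ord <- order(svs$chrom, svs$start)
  for (k in ord) {
    tp <- svs$type[k]; ch <- svs$chrom[k]
    s <- svs$start[k]; e <- svs$end[k]
    p <- pieces[[ch]]
    idx <- range_idx(p, ch, s, e)
    if (tp == "PAV") {
      if (length(idx)) pieces[[ch]] <- p[-idx, , drop = FALSE]
    } else if (tp == "CNV") {
      if (length(idx)) {
        dupblk <- p[idx, , drop = FALSE]
        dupblk$dup <- TRUE
        pieces[[ch]] <- rbind(p[seq_len(max(idx)), , drop = FALSE], dupblk,
                              if (max(idx) < nrow(p))
                                p[(max(idx) + 1):nrow(p), , drop = FALSE])
      }
    } else if (tp == "INV") {
      if (length(idx)) {
        blk <- p[rev(idx), , drop = FALSE]
        blk$strand <- ifelse(blk$strand == "+", "-", "+")
        p[idx, ] <- blk
        pieces[[ch]] <- p
      }
    } else if (tp == "TRANS") {
      ch2 <- svs$chrom2[k]; s2 <- svs$start2[k]; e2 <- svs$end2[k]
      p1 <- pieces[[ch]]; p2 <- pieces[[ch2]]
      i1 <- range_idx(p1, ch, s, e)
      i2 <- range_idx(p2, ch2, s2, e2)
      if (length(i1) && length(i2)) {
        blk1 <- p1[i1, , drop = FALSE]; blk2 <- p2[i2, , drop = FALSE]
        pieces[[ch]] <- rbind(
          p1[seq_len(min(i1) - 1), , drop = FALSE], blk2,
          if (max(i1) < nrow(p1)) p1[(max(i1) + 1):nrow(p1), , drop = FALSE])
        pieces[[ch2]] <- rbind(
          p2[seq_len(min(i2) - 1), , drop = FALSE], blk1,
          if (max(i2) < nrow(p2)) p2[(max(i2) + 1):nrow(p2), , drop = FALSE])
      }
    }
  }
  pieces
}

# Coordinate map (non-dup pieces) with query coordinates from cumulated
# piece lengths.
pieces_to_map <- function(pieces) {
  out <- NULL
  for (qch in names(pieces)) {
    p <- pieces[[qch]]
    if (!nrow(p)) next
    lens <- p$ref_end - p$ref_start
    qend <- cumsum(lens)
    qstart <- qend - lens
    keep <- !p$dup
    out <- rbind(out, data.frame(
      ref_chrom = p$ref_chrom[keep], ref_start = p$ref_start[keep],
      ref_end = p$ref_end[keep], query_chrom = qch,
      query_start = qstart[keep], query_end = qend[keep],
      strand = p$strand[keep], stringsAsFactors = FALSE))
  }
  out
}

# Merge runs shorter than min_run into the preceding run (the first run
# merges forward). NA runs are left untouched.
merge_micro_runs <- function(x, min_run) {
  repeat {
    rl <- rle(x)
    short <- which(rl$lengths < min_run & !is.na(rl$values))
    if (!length(short)) return(x)
    k <- short[1]
    rl$values[k] <- if (k > 1) rl$values[k - 1] else rl$values[k + 1]
    x <- inverse.rle(rl)
  }
}

# Source reference position of a query position (dup pieces included, so
# every query base has structural ancestry even when unmapped).
query_source <- function(pieces, qch, qpos) {
  p <- pieces[[qch]]
  lens <- p$ref_end - p$ref_start
  qend <- cumsum(lens)
  qstart <- qend - lens
  k <- which(qpos >= qstart & qpos < qend)
  if (!length(k)) return(NULL)
  k <- k[1]
  off <- qpos - qstart[k]
  rp <- if (p$strand[k] == "+") p$ref_start[k] + off else p$ref_end[k] - 1 - off
  list(chrom = p$ref_chrom[k], pos = rp)
}

# Per-bin compartment label and TAD id tracks for an accession, in either
# reference space (reference grid; PAV-deleted bins flagged depleted) or
# self space (query grid; structure looked up at each bin midpoint's
# reference source).
accession_tracks <- function(panel, acc_id, chrom, bin_size,
                             space = c("reference", "self")) {
  space <- match.arg(space)
  acc <- panel$accessions[[acc_id]]
  ref <- panel$reference
  lookup_ref <- function(rch, rpos) {
    lab <- ref$comp_labels[[rch]]
    li <- pmin(length(lab), rpos %/% ref$comp_bin + 1)
    l <- acc$labels_ref[[rch]][li]
    tads <- acc$tads_ref[[rch]]
    ti <- findInterval(rpos, tads$start)
    list(label = l, tad = ti)
  }
  if (space == "reference") {
    n <- ceiling(ref$chrom_lengths[[chrom]] / bin_size)
    mids <- (seq_len(n) - 0.5) * bin_size
    lk <- lookup_ref(chrom, mids)
    # coverage retained per bin after PAV deletion (reference mapping)
    depleted <- rep(1, n)
    pav <- acc$svs[acc$svs$type == "PAV" & acc$svs$chrom == chrom, , drop = FALSE]
    if (nrow(pav)) {
      for (i in seq_len(n)) {
        bs0 <- (i - 1) * bin_size; be0 <- i * bin_size
        del <- sum(overlap_length(pav$start, pav$end, bs0, be0))
        depleted[i] <- 1 - del / bin_size
      }
    }
    list(labels = lk$label, tad = lk$tad, depleted = depleted, n = n)
  } else {
    n <- floor(acc$chrom_lengths[[chrom]] / bin_size)
    mids <- (seq_len(n) - 0.5) * bin_size
    labs <- character(n); tid <- integer(n)
    for (i in seq_len(n)) {
      src <- query_source(acc$pieces, chrom, mids[i])
      if (is.null(src)) { labs[i] <- NA; tid[i] <- NA; next }
      lk <- lookup_ref(src$chrom, src$pos)
      # TAD ids from other chromosomes (translocations) get a distinct block
      labs[i] <- lk$label
      tid[i] <- lk$tad + 10000L * match(src$chrom, names(ref$chrom_lengths))
    }
    # SV edits can slice TADs into sub-minimum slivers (inversion and
    # translocation edges); chromatin fragments below the minimum TAD size
    # do not form stable insulated domains, so merge them into the
    # preceding domain
    min_run <- max(1L, as.integer(ref$config$tad_min / bin_size))
    tid <- merge_micro_runs(tid, min_run)
    list(labels = labs, tad = tid, depleted = NULL, n = n)
  }
}

#' Planted TAD boundaries of an accession in its own coordinates
#'
#' Returns the junction bins of the accession's structural (TAD) track in
#' self space -- the exact partition its self-mapped contact matrix is
#' simulated from, with boundary-deleting PAVs merged and SV coordinate
#' effects (including inversions relocating junctions) applied. These are
#' the ground-truth positions that boundary callers are scored against.
#'
#' @param panel an `AccessionPanel`.
#' @param acc_id accession id.
#' @param chrom chromosome.
#' @param bin_size structural bin size (default: the reference's).
#' @return data.frame: `bin` (1-based first bin of the downstream TAD),
#'   `start` (bp in query coordinates).
#' @export
planted_boundaries <- function(panel, acc_id, chrom, bin_size = NULL) {
  bs <- bin_size %||% panel$reference$struct_bin
  tr <- accession_tracks(panel, acc_id, chrom, bs, space = "self")
  rl <- rle(tr$tad)
  j <- cumsum(rl$lengths)
  j <- j[-length(j)] + 1L
  data.frame(bin = j, start = (j - 1) * bs)
}

#' Simulate one accession contact matrix
#'
#' Reference space emulates reference-mapped Hi-C (reference grid, deleted
#' sequence depletes coverage); self space emulates self-mapped Hi-C on
#' the accession's own genome.
#'
#' @param panel an `AccessionPanel`.
#' @param acc_id accession id.
#' @param chrom chromosome.
#' @param bin_size bin width in bp.
#' @param space "reference" or "self".
#' @param ... passed to [simulate_contact_matrix()].
#' @param seed RNG seed (the accession/chromosome name is folded in).
#' @return A `ContactMatrix`.
#' @export
simulate_accession_matrix <- function(panel, acc_id, chrom, bin_size,
                                      space = c("reference", "self"), ...,
                                      seed = NULL) {
  space <- match.arg(space)
  seed <- seed %||% panel$seed
  tr <- accession_tracks(panel, acc_id, chrom, bin_size, space)
  simulate_contact_matrix(tr$labels, tr$tad, bin_size,
                          chrom = paste(acc_id, chrom, space, sep = "_"),
                          depleted = tr$depleted,
                          seed = substream_seed(seed, paste0(acc_id, chrom, space,
                                                             bin_size)), ...)
}

default_expression_config <- function() {
  list(fpkm_meanlog_a = log(20), fpkm_meanlog_b = log(4), fpkm_sdlog = 0.6,
       acc_sdlog = 0.2, shift_factor = 4, shift_flank = 1e5, fc_cutoff = 2)
}

#' Simulate expression and DEG tables for a panel
#'
#' Gene FPKM is log-normal with a higher mean in A than in B compartments.
#' Genes within `shift_flank` of a boundary lost in an accession receive a
#' `shift_factor` expression shift (direction fixed per gene) in that
#' accession. The DEG table lists genes exceeding the fold-change cutoff
#' between each query accession and the reference (the usual
#' FDR < 0.05, |fold change| > 2 convention is recorded in metadata; the
#' generator plants fold changes directly).
#'
#' @param panel an `AccessionPanel`.
#' @param config overrides of `pan3d:::default_expression_config()`.
#' @param seed RNG seed.
#' @return list: `genes` (gene_id, chrom, tss, label), `fpkm` (genes x
#'   accessions), `degs` (gene_id, accession, direction, log2fc),
#'   `planted` (gene/accession pairs with planted shifts), `metadata`.
#' @export
simulate_expression <- function(panel, config = list(), seed = 1) {
  cfg <- utils::modifyList(default_expression_config(), config)
  ref <- panel$reference
  genes <- do.call(rbind, lapply(names(ref$chrom_lengths), function(ch) {
    tss <- ref$tss[[ch]]
    if (!length(tss)) return(NULL)
    lab <- ref$comp_labels[[ch]][tss %/% ref$comp_bin + 1]
    data.frame(chrom = ch, tss = tss, label = lab)
  }))
  genes$gene_id <- sprintf("G%05d", seq_len(nrow(genes)))
  base <- with_stream(seed, "expression_base", {
    stats::rlnorm(nrow(genes),
                  ifelse(genes$label == "A", cfg$fpkm_meanlog_a, cfg$fpkm_meanlog_b),
                  cfg$fpkm_sdlog)
  })
  accs <- names(panel$accessions)
  fpkm <- matrix(0, nrow(genes), length(accs),
                 dimnames = list(genes$gene_id, accs))
  planted <- NULL
  shift_dir <- with_stream(seed, "expression_dir", {
    sample(c(-1, 1), nrow(genes), replace = TRUE)
  })
  for (a in accs) {
    noise <- with_stream(seed, paste0("expression_", a), {
      stats::rlnorm(nrow(genes), 0, cfg$acc_sdlog)
    })
    v <- base * noise
    lost <- panel$accessions[[a]]$truth$lost_boundaries
    if (nrow(lost) && cfg$shift_factor != 1) {
      near <- rep(FALSE, nrow(genes))
      for (r in seq_len(nrow(lost))) {
        near <- near | (genes$chrom == lost$chrom[r] &
                          abs(genes$tss - lost$pos[r]) <= cfg$shift_flank)
      }
      if (any(near)) {
        v[near] <- v[near] * cfg$shift_factor^shift_dir[near]
        planted <- rbind(planted, data.frame(gene_id = genes$gene_id[near],
                                             accession = a))
      }
    }
    fpkm[, a] <- v
  }
  eps <- 1e-3
  degs <- NULL
  for (a in setdiff(accs, "ref")) {
    l2 <- log2((fpkm[, a] + eps) / (fpkm[, "ref"] + eps))
    hit <- abs(l2) > log2(cfg$fc_cutoff)
    if (any(hit)) {
      degs <- rbind(degs, data.frame(
        gene_id = genes$gene_id[hit], accession = a,
        direction = ifelse(l2[hit] > 0, "up", "down"), log2fc = l2[hit]))
    }
  }
  list(genes = genes, fpkm = fpkm,
       degs = degs %||% data.frame(gene_id = character(0),
                                   accession = character(0),
                                   direction = character(0),
                                   log2fc = numeric(0)),
       planted = planted %||% data.frame(gene_id = character(0),
                                         accession = character(0)),
       metadata = list(deg_convention = "FDR < 0.05 and |fold change| > 2",
                       fc_cutoff = cfg$fc_cutoff))
}

default_genotype_config <- function() {
  list(n1 = 60, n2 = 60, sites_per_window = 10,
       fst_neutral = 0.02, fst_selected = 0.6, selected_frac = 0.05)
}

#' Simulate two-population allele counts with planted selected windows
#'
#' Per-site population allele frequencies follow a Balding-Nichols model:
#' an ancestral frequency drawn uniformly, then population frequencies
#' drawn from Beta distributions whose divergence parameter is
#' `fst_neutral` genome wide and `fst_selected` inside the designated
#' selected windows (a random `selected_frac` of 25-kb windows unless
#' given).
#'
#' @param chrom_lengths named numeric vector.
#' @param window window size in bp (default 25 kb).
#' @param selected optional data.frame (`chrom`, `start`, `end`) of
#'   selected windows.
#' @param config overrides of `pan3d:::default_genotype_config()`.
#' @param seed RNG seed.
#' @return list: `sites` (chrom, pos, n1, x1, n2, x2), `selected` (the
#'   planted windows).
#' @export
simulate_genotypes <- function(chrom_lengths, window = 25e3, selected = NULL,
                               config = list(), seed = 1) {
  cfg <- utils::modifyList(default_genotype_config(), config)
  if (cfg$n1 < 2 || cfg$n2 < 2) stop("population size must be >= 2")
  sites <- list()
  sel_out <- NULL
  with_stream(seed, "genotypes", {
    for (ch in names(chrom_lengths)) {
      nwin <- floor(chrom_lengths[[ch]] / window)
      if (is.null(selected)) {
        nsel <- max(1, round(cfg$selected_frac * nwin))
        selw <- sort(sample.int(nwin, nsel))
      } else {
        selw <- selected$start[selected$chrom == ch] %/% window + 1
      }
      sel_out <- rbind(sel_out, data.frame(chrom = ch,
                                           start = (selw - 1) * window,
                                           end = selw * window))
      spw <- cfg$sites_per_window
      win_of <- rep(seq_len(nwin), each = spw)
      ns <- nwin * spw
      pos <- floor((win_of - 1) * window + stats::runif(ns, 0, window))
      fst <- ifelse(win_of %in% selw, cfg$fst_selected, cfg$fst_neutral)
      anc <- stats::runif(ns, 0.1, 0.9)
      bn <- function(p, fst) {
        # Balding-Nichols: Beta around the ancestral frequency
        out <- p
        pos_f <- fst > 0
        out[pos_f] <- stats::rbeta(sum(pos_f),
                                   p[pos_f] * (1 - fst[pos_f]) / fst[pos_f],
                                   (1 - p[pos_f]) * (1 - fst[pos_f]) / fst[pos_f])
        out
      }
      p1 <- bn(anc, fst); p2 <- bn(anc, fst)
      sites[[ch]] <- data.frame(
        chrom = ch, pos = pos, n1 = cfg$n1,
        x1 = stats::rbinom(ns, cfg$n1, p1),
        n2 = cfg$n2, x2 = stats::rbinom(ns, cfg$n2, p2))
    }
  })
  sites <- do.call(rbind, sites)
  sites <- sites[order(sites$chrom, sites$pos), ]
  rownames(sites) <- NULL
  list(sites = sites, selected = sel_out)
}
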