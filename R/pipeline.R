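# Panel-level pipeline: per-accession structure calling on simulated
# matrices, pan-compartment status assembly, and pan-boundary clustering.

#' Call compartments for one accession (reference space)
#'
#' Simulates (or accepts) the reference-mapped 100-kb matrix per
#' chromosome, ICE-balances it, computes eigenvectors, and calls A/B
#' against the reference gene-density track.
#'
#' @param panel an `AccessionPanel`.
#' @param acc_id accession id.
#' @param low_quantile low-coverage mask quantile for balancing. At 100-kb
#'   compartment resolution only zero-coverage (fully deleted) bins are
#'   masked by default: a relative-quantile filter would mask a different
#'   random 2% of bins in every accession and manufacture spurious
#'   pan-compartment variability.
#' @param ... passed to [simulate_accession_matrix()].
#' @return Named list of `CompartmentTrack` per chromosome.
#' @export
call_compartments_accession <- function(panel, acc_id, low_quantile = 0, ...) {
  ref <- panel$reference
  out <- list()
  for (ch in names(ref$chrom_lengths)) {
    m <- simulate_accession_matrix(panel, acc_id, ch, ref$comp_bin,
                                   space = "reference", ...)
    bal <- ice_balance(m, low_quantile = low_quantile)
    eigs <- compute_eigs(bal)
    gd <- gene_density_track(ref, ch)
    out[[ch]] <- call_ab(eigs, gd, accession = acc_id, chrom = ch,
                         bin_size = ref$comp_bin)
  }
  out
}

#' Call TAD boundaries for one accession (self space)
#'
#' Simulates the self-mapped 25-kb matrix per chromosome, balances it,
#' computes the insulation track and calls boundaries.
#'
#' @param panel an `AccessionPanel`.
#' @param acc_id accession id.
#' @param min_strength boundary strength filter (default 0.1).
#' @param ... passed to [simulate_accession_matrix()].
#' @return Named list per chromosome: list(track, boundaries, tads).
#' @export
call_boundaries_accession <- function(panel, acc_id, min_strength = 0.1, ...) {
  ref <- panel$reference
  acc <- panel$accessions[[acc_id]]
  out <- list()
  for (ch in names(ref$chrom_lengths)) {
    m <- simulate_accession_matrix(panel, acc_id, ch, ref$struct_bin,
                                   space = "self", ...)
    bal <- ice_balance(m)
    tr <- insulation_score(bal, accession = acc_id)
    cb <- call_boundaries(tr, min_strength = min_strength)
    out[[ch]] <- list(track = tr, boundaries = cb$boundaries, tads = cb$tads)
  }
  out
}

#' Assemble the panel-wide compartment status matrix
#'
#' @param panel an `AccessionPanel`.
#' @param ... passed to [call_compartments_accession()].
#' @return list: `status` (accessions x bins character matrix over all
#'   chromosomes), `bins` (chrom/start per column), `tracks` (per
#'   accession per chromosome).
#' @export
pan_compartment_status <- function(panel, ...) {
  ref <- panel$reference
  accs <- names(panel$accessions)
  tracks <- lapply(accs, function(a) call_compartments_accession(panel, a, ...))
  names(tracks) <- accs
  bins <- do.call(rbind, lapply(names(ref$chrom_lengths), function(ch) {
    n <- ref$chrom_lengths[[ch]] / ref$comp_bin
    data.frame(chrom = ch, start = (seq_len(n) - 1) * ref$comp_bin)
  }))
  status <- matrix(NA_character_, length(accs), nrow(bins),
                   dimnames = list(accs, NULL))
  for (a in accs) {
    status[a, ] <- unlist(lapply(names(ref$chrom_lengths), function(ch) {
      tracks[[a]][[ch]]$labels
    }))
  }
  list(status = status, bins = bins, tracks = tracks)
}

#' Lift called boundary regions to reference coordinates
#'
#' @param panel an `AccessionPanel`.
#' @param bounds_by_acc named list (per accession) of per-chromosome
#'   boundary call results from [call_boundaries_accession()].
#' @param min_frac liftover success fraction.
#' @return data.frame of regions: region_id, accession, chrom (reference),
#'   start, end, lifted (FALSE when coordinate conversion failed).
#' @export
lift_boundary_regions <- function(panel, bounds_by_acc, min_frac = 0.5) {
  out <- list()
  for (a in names(bounds_by_acc)) {
    map <- panel$accessions[[a]]$map
    for (ch in names(bounds_by_acc[[a]])) {
      b <- bounds_by_acc[[a]][[ch]]$boundaries
      if (!nrow(b)) next
      for (r in seq_len(nrow(b))) {
        qch <- ch # self matrices are named by accession; regions live on query chrom
        lv <- liftover_interval(map, qch, b$region_start[r], b$region_end[r],
                                from = "query", min_frac = min_frac)
        out[[length(out) + 1L]] <- data.frame(
          region_id = sprintf("%s_%s_%d", a, ch, r), accession = a,
          chrom = if (lv$ok) lv$chrom else NA_character_,
          start = if (lv$ok) lv$start else NA_real_,
          end = if (lv$ok) lv$end else NA_real_,
          lifted = lv$ok)
      }
    }
  }
  do.call(rbind, out) %||%
    data.frame(region_id = character(0), accession = character(0),
               chrom = character(0), start = numeric(0), end = numeric(0),
               lifted = logical(0))
}

#' Directed similarity edges between lifted boundary regions
#'
#' Similarity of an ordered region pair is the fraction of the source
#' region covered by the target region on reference coordinates (the
#' mapped-segment evidence of the synthetic panel is exact, so reference
#' overlap is the mapped length). Only pairs with positive overlap are
#' returned.
#'
#' @param regions lifted regions from [lift_boundary_regions()].
#' @return data.frame: from, to, similarity (directed, both directions).
#' @export
boundary_similarity_edges <- function(regions) {
  reg <- regions[regions$lifted, , drop = FALSE]
  out <- list()
  for (ch in unique(reg$chrom)) {
    r <- reg[reg$chrom == ch, , drop = FALSE]
    if (nrow(r) < 2) next
    o <- order(r$start)
    r <- r[o, , drop = FALSE]
    for (i in seq_len(nrow(r) - 1)) {
      j <- i + 1
      while (j <= nrow(r) && r$start[j] < r$end[i]) {
        ov <- overlap_length(r$start[i], r$end[i], r$start[j], r$end[j])
        if (ov > 0) {
          out[[length(out) + 1L]] <- data.frame(
            from = c(r$region_id[i], r$region_id[j]),
            to = c(r$region_id[j], r$region_id[i]),
            similarity = c(ov / (r$end[i] - r$start[i]),
                           ov / (r$end[j] - r$start[j])))
        }
        j <- j + 1
      }
    }
  }
  do.call(rbind, out) %||%
    data.frame(from = character(0), to = character(0), similarity = numeric(0))
}

#' Pan-boundary clustering over a panel
#'
#' Lifts every accession's called boundary regions to the reference,
#' builds the similarity match graph, and clusters by single-linkage
#' connected components into core/dispensable/private clusters. Regions
#' that fail coordinate conversion become singleton (private-leaning)
#' clusters for their accession.
#'
#' @param panel an `AccessionPanel`.
#' @param bounds_by_acc boundary calls per accession.
#' @param cutoff similarity cutoff (default 0.5).
#' @param min_frac liftover fraction (default 0.5).
#' @return As [cluster_boundary_regions()], plus `regions`.
#' @export
pan_boundary_clusters <- function(panel, bounds_by_acc, cutoff = 0.5,
                                  min_frac = 0.5) {
  regions <- lift_boundary_regions(panel, bounds_by_acc, min_frac = min_frac)
  edges <- boundary_similarity_edges(regions)
  res <- cluster_boundary_regions(regions, edges,
                                  accessions = names(panel$accessions),
                                  cutoff = cutoff)
  res$regions <- regions
  res
}

#' Comparative boundary matching of every query accession against the
#' reference accession
#'
#' @param panel an `AccessionPanel`.
#' @param bounds_by_acc boundary calls per accession.
#' @param min_frac liftover fraction.
#' @return list: `per_query` (data.frame per accession with common
#'   percentages both directions), `mean_ref_common_pct`,
#'   `mean_query_common_pct`.
#' @export
comparative_boundaries <- function(panel, bounds_by_acc, min_frac = 0.5) {
  ref_b <- do.call(rbind, lapply(names(bounds_by_acc[["ref"]]), function(ch) {
    b <- bounds_by_acc[["ref"]][[ch]]$boundaries
    if (!nrow(b)) return(NULL)
    data.frame(chrom = ch, region_start = b$region_start,
               region_end = b$region_end)
  }))
  per <- list()
  for (a in setdiff(names(bounds_by_acc), "ref")) {
    q_b <- do.call(rbind, lapply(names(bounds_by_acc[[a]]), function(ch) {
      b <- bounds_by_acc[[a]][[ch]]$boundaries
      if (!nrow(b)) return(NULL)
      data.frame(chrom = ch, region_start = b$region_start,
                 region_end = b$region_end)
    }))
    if (is.null(q_b) || is.null(ref_b)) next
    mm <- match_boundaries_pairwise(ref_b, q_b,
                                    map = panel$accessions[[a]]$map,
                                    min_frac = min_frac)
    per[[a]] <- data.frame(accession = a, mm$summary)
  }
  per <- do.call(rbind, per)
  list(per_query = per,
       mean_ref_common_pct = mean(per$ref_common_pct),
       mean_query_common_pct = mean(per$query_common_pct))
}

# ---- plain-text writers for the standard interchange formats ----

#' Write intervals as BED (0-based half-open)
#' @param df data.frame with chrom, start, end and optional name, score.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  cols <- df[, intersect(c("chrom", "start", "end", "name", "score"),
                         names(df)), drop = FALSE]
  utils::write.table(format(cols, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a per-bin value track as BEDGraph
#' @param chrom chromosome id.
#' @param values per-bin values (NA bins skipped).
#' @param bin_size bin width in bp.
#' @param path output file.
#' @export
write_bedgraph <- function(chrom, values, bin_size, path) {
  keep <- !is.na(values)
  df <- data.frame(chrom = chrom,
                   start = format((which(keep) - 1) * bin_size, scientific = FALSE, trim = TRUE),
                   end = format(which(keep) * bin_size, scientific = FALSE, trim = TRUE),
                   value = values[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene TSS records as GFF3 (1-based, inclusive)
#' @param genes data.frame: gene_id, chrom, tss.
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tpan3d\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                     genes$chrom, genes$tss + 1, genes$tss + 1,
                     genes$gene_id), con)
  invisible(path)
}

#' Write a coordinate map as TSV
#' @param map coordinate-map data.frame.
#' @param path output file.
#' @export
write_map_tsv <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated panel to a directory of plain-text files
#'
#' Emits, per accession: the SV catalog and coordinate map as TSV, plus
#' contact matrices as COO TSV for the requested chromosomes/spaces.
#' Reference annotations (TSS GFF3, repeats BED, compartment labels BED)
#' are written once.
#'
#' @param panel an `AccessionPanel`.
#' @param dir output directory (created).
#' @param matrices logical: also write contact matrices (default FALSE;
#'   they are the bulky part).
#' @export
write_panel <- function(panel, dir, matrices = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- panel$reference
  genes <- do.call(rbind, lapply(names(ref$chrom_lengths), function(ch) {
    if (!length(ref$tss[[ch]])) return(NULL)
    data.frame(chrom = ch, tss = ref$tss[[ch]])
  }))
  genes$gene_id <- sprintf("G%05d", seq_len(nrow(genes)))
  write_gff3(genes, file.path(dir, "reference_tss.gff3"))
  for (ch in names(ref$chrom_lengths)) {
    rp <- ref$repeats[[ch]]
    write_bed(data.frame(chrom = ch, start = rp$start, end = rp$end,
                         name = rp$subtype),
              file.path(dir, paste0("reference_repeats_", ch, ".bed")))
    lab <- ref$comp_labels[[ch]]
    write_bed(data.frame(chrom = ch,
                         start = (seq_along(lab) - 1) * ref$comp_bin,
                         end = seq_along(lab) * ref$comp_bin, name = lab),
              file.path(dir, paste0("reference_compartments_", ch, ".bed")))
  }
  for (a in names(panel$accessions)) {
    acc <- panel$accessions[[a]]
    utils::write.table(acc$svs, file.path(dir, paste0(a, "_svs.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_map_tsv(acc$map, file.path(dir, paste0(a, "_map.tsv")))
    if (matrices) {
      for (ch in names(ref$chrom_lengths)) {
        m <- simulate_accession_matrix(panel, a, ch, ref$struct_bin,
                                       space = "self")
        write_contacts(m, file.path(dir, paste0(a, "_", ch, "_25kb.coo.tsv")))
      }
    }
  }
  invisible(dir)
}
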