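# A/B compartment calling: eigenvectors of the O/E correlation matrix,
# gene-density orientation, borders, A percentage, and I regions.

#' First three compartment eigenvectors
#'
#' Computes the Pearson correlation matrix of the observed/expected matrix
#' over unmasked bins, eigendecomposes it, and returns the top three
#' eigenvectors by eigenvalue magnitude as full-length tracks (NA on masked
#' bins). Eigenvectors are unit-norm; their global sign is arbitrary until
#' oriented downstream.
#'
#' @param b a `BalancedMatrix` at compartment (100 kb) resolution.
#' @return list with `e` (n x 3 matrix of eigen-tracks), `values`
#'   (eigenvalues), `mask`, `degenerate` (TRUE when the leading eigenvalue
#'   is numerically zero).
#' @export
compute_eigs <- function(b) {
  m <- if (inherits(b, "BalancedMatrix")) b$matrix else b
  oe <- observed_expected(b)
  keep <- !m$mask & apply(oe, 1, function(r) sum(!is.na(r)) >= 2)
  if (sum(keep) < 10) stop("fewer than 10 unmasked bins: track too short")
  sub <- oe[keep, keep, drop = FALSE]
  cc <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
  cc[!is.finite(cc)] <- 0
  ed <- eigen(cc, symmetric = TRUE)
  o <- order(abs(ed$values), decreasing = TRUE)[1:3]
  n <- m$n_bins
  e <- matrix(NA_real_, n, 3)
  for (k in 1:3) {
    v <- ed$vectors[, o[k]]
    e[keep, k] <- v / sqrt(sum(v^2))
  }
  list(e = e, values = ed$values[o], mask = !keep,
       degenerate = abs(ed$values[o[1]]) < 1e-10 * nrow(sub))
}

#' Call A/B compartments from eigen-tracks and gene density
#'
#' Among the first three eigenvectors, the one with maximal absolute Pearson
#' correlation to gene density is selected (automating the usual manual
#' adjudication of E1/E2/E3 against gene density), oriented so the
#' correlation is positive, and thresholded at zero: positive bins are A,
#' negative bins B, masked bins NA. If no eigenvector reaches the
#' correlation floor the chromosome is flagged uncallable and all labels
#' are NA.
#'
#' @param eigs result of [compute_eigs()].
#' @param gene_density per-bin gene (TSS) density on the same grid.
#' @param accession,chrom identifiers stored in the track.
#' @param bin_size bin width in bp (default 1e5).
#' @param cor_floor minimum |correlation| to call the chromosome (0.2).
#' @return A `CompartmentTrack`: list with `labels` (character A/B/NA),
#'   `e1` (the chosen, oriented eigenvector), `e` (all three raw tracks),
#'   `eig_index`, `orientation`, `callable`.
#' @export
call_ab <- function(eigs, gene_density, accession = "ref", chrom = "chr1",
                    bin_size = 1e5, cor_floor = 0.2) {
  stopifnot(length(gene_density) == nrow(eigs$e))
  cors <- vapply(1:3, function(k) {
    suppressWarnings(stats::cor(eigs$e[, k], gene_density,
                                use = "complete.obs"))
  }, numeric(1))
  cors[is.na(cors)] <- 0
  n <- nrow(eigs$e)
  track <- structure(
    list(accession = accession, chrom = chrom, bin_size = bin_size,
         labels = rep(NA_character_, n), e1 = rep(NA_real_, n),
         e = eigs$e, eig_index = NA_integer_, orientation = NA_real_,
         callable = FALSE, cors = cors),
    class = "CompartmentTrack")
  if (max(abs(cors)) < cor_floor) {
    warning(sprintf("%s/%s: no eigenvector correlates with gene density (max |r| = %.2f); uncallable",
                    accession, chrom, max(abs(cors))))
    return(track)
  }
  k <- which.max(abs(cors))
  s <- sign(cors[k])
  e1 <- eigs$e[, k] * s
  labels <- ifelse(is.na(e1), NA_character_, ifelse(e1 > 0, "A", "B"))
  track$labels <- labels
  track$e1 <- e1
  track$eig_index <- k
  track$orientation <- s
  track$callable <- TRUE
  track
}

#' @export
print.CompartmentTrack <- function(x, ...) {
  cat(sprintf("CompartmentTrack %s/%s: %d bins (%d A, %d B, %d NA), E%s\n",
              x$accession, x$chrom, length(x$labels),
              sum(x$labels == "A", na.rm = TRUE),
              sum(x$labels == "B", na.rm = TRUE),
              sum(is.na(x$labels)),
              ifelse(is.na(x$eig_index), "?", x$eig_index)))
  invisible(x)
}

#' Compartment border bins
#'
#' A bin is a border iff it is labeled A or B and an adjacent bin carries
#' the opposite label; NA bins break adjacency.
#'
#' @param track a `CompartmentTrack` (or bare label vector).
#' @return Integer vector of border bin indices (1-based).
#' @export
compartment_borders <- function(track) {
  lab <- if (inherits(track, "CompartmentTrack")) track$labels else track
  n <- length(lab)
  if (n < 2) return(integer(0))
  border <- rep(FALSE, n)
  for (i in seq_len(n - 1)) {
    a <- lab[i]; b <- lab[i + 1]
    if (!is.na(a) && !is.na(b) && a != b) border[c(i, i + 1)] <- TRUE
  }
  which(border)
}

#' A-compartment percentage of a chromosome
#'
#' (Number of A bins x bin size) / chromosome length, as a percentage.
#'
#' @param track a `CompartmentTrack`.
#' @param chrom_length chromosome length in bp; defaults to bins x bin size.
#' @export
a_percentage <- function(track, chrom_length = NULL) {
  lab <- track$labels
  len <- chrom_length %||% (length(lab) * track$bin_size)
  100 * sum(lab == "A", na.rm = TRUE) * track$bin_size / len
}

#' I regions and the A/B/I partition
#'
#' A bin belongs to an I region iff the sliding window consisting of the
#' bin and the following `window - 1` bins contains both A and B labels.
#' Windows truncated by the chromosome end are evaluated when at least two
#' labeled bins remain, otherwise skipped. NA bins inside a window neither
#' create nor veto I status.
#'
#' @param track a `CompartmentTrack` or label vector.
#' @param window window size in bins (default 5, i.e. 500 kb at 100 kb).
#' @return list of 1-based index vectors: `I` (all I bins), `A_regions`
#'   (A bins outside I), `B_regions`, `I_A` (A bins inside I), `I_B`.
#'   The four sets `A_regions`, `B_regions`, `I_A`, `I_B` partition all
#'   labeled bins; `I = I_A + I_B`.
#' @export
find_i_regions <- function(track, window = 5) {
  lab <- if (inherits(track, "CompartmentTrack")) track$labels else track
  n <- length(lab)
  is_i <- rep(FALSE, n)
  for (i in seq_len(n)) {
    w <- lab[i:min(n, i + window - 1)]
    w <- w[!is.na(w)]
    if (length(w) < 2 && i + window - 1 > n) next # truncated, too short
    if (any(w == "A") && any(w == "B")) is_i[i] <- TRUE
  }
  labeled <- !is.na(lab)
  list(I = which(is_i & labeled),
       A_regions = which(labeled & lab == "A" & !is_i),
       B_regions = which(labeled & lab == "B" & !is_i),
       I_A = which(labeled & lab == "A" & is_i),
       I_B = which(labeled & lab == "B" & is_i))
}
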