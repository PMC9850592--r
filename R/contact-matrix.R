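#' Binned intra-chromosomal Hi-C contact matrix
#'
#' A `ContactMatrix` holds symmetric, binned contact counts for one
#' chromosome at a fixed bin size, together with a mask of excluded bins.
#' Counts are stored dense; bin `i` covers the half-open interval
#' `[(i-1) * bin_size, i * bin_size)` in 0-based genomic coordinates.
#'
#' @param counts symmetric numeric matrix of non-negative counts.
#' @param bin_size bin width in bp (> 0).
#' @param chrom chromosome identifier.
#' @param mask optional logical vector marking excluded bins.
#' @return An object of class `ContactMatrix`.
#' @export
contact_matrix <- function(counts, bin_size, chrom = "chr1", mask = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (max(abs(counts - t(counts)), na.rm = TRUE) > 1e-8) {
    stop("counts must be symmetric")
  }
  if (!is.numeric(bin_size) || bin_size <= 0) stop("bin_size must be > 0")
  n <- nrow(counts)
  if (is.null(mask)) mask <- rep(FALSE, n)
  stopifnot(length(mask) == n)
  structure(
    list(counts = counts, bin_size = as.numeric(bin_size),
         chrom = as.character(chrom), n_bins = n, mask = as.logical(mask)),
    class = "ContactMatrix"
  )
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix %s: %d bins @ %g bp (%d masked), total %g\n",
              x$chrom, x$n_bins, x$bin_size, sum(x$mask), sum(x$counts)))
  invisible(x)
}

#' @export
dim.ContactMatrix <- function(x) dim(x$counts)

#' Read a COO contact file into a ContactMatrix
#'
#' The COO dialect is a headerless TSV with columns
#' `chrom, bin1_start, bin2_start, count` where bin starts are 0-based
#' multiples of the bin size. Duplicate records for one cell, in either
#' orientation, are summed (so `(0,1,3)` plus `(1,0,2)` yields
#' `M[1,2] = 5`): symmetrization by summation is the documented dialect.
#'
#' @param path file to read.
#' @param bin_size bin width in bp.
#' @param chrom_length chromosome length in bp (defines the bin count).
#' @param chrom chromosome to keep (default: first seen).
#' @return A `ContactMatrix`.
#' @export
read_contacts <- function(path, bin_size, chrom_length, chrom = NULL) {
  n <- ceiling(chrom_length / bin_size)
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = c("character", "numeric", "numeric", "numeric")),
    error = function(e) NULL
  )
  if (is.null(raw) || nrow(raw) == 0L) {
    return(contact_matrix(matrix(0, n, n), bin_size,
                          chrom = chrom %||% "chr1"))
  }
  names(raw) <- c("chrom", "bin1_start", "bin2_start", "count")
  if (is.null(chrom)) chrom <- raw$chrom[1]
  raw <- raw[raw$chrom == chrom, , drop = FALSE]
  bad <- which(raw$count < 0)
  if (length(bad)) stop(sprintf("negative count at line %d", bad[1]))
  off <- which(raw$bin1_start %% bin_size != 0 | raw$bin2_start %% bin_size != 0)
  if (length(off)) {
    stop(sprintf("bin start not a multiple of bin size at line %d", off[1]))
  }
  i <- raw$bin1_start %/% bin_size + 1L
  j <- raw$bin2_start %/% bin_size + 1L
  oob <- which(i < 1L | i > n | j < 1L | j > n)
  if (length(oob)) stop(sprintf("bin start out of bounds at line %d", oob[1]))
  m <- matrix(0, n, n)
  for (k in seq_along(i)) {
    a <- min(i[k], j[k]); b <- max(i[k], j[k])
    m[a, b] <- m[a, b] + raw$count[k]
  }
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  contact_matrix(m, bin_size, chrom = chrom)
}

#' Write a ContactMatrix as canonical COO TSV
#'
#' Writes the upper triangle (including the diagonal) of non-zero cells with
#' 0-based bin starts, sorted by (bin1, bin2), so that
#' `read_contacts(write_contacts(m))` is the identity.
#'
#' @param m a `ContactMatrix`.
#' @param path output file.
#' @export
write_contacts <- function(m, path) {
  stopifnot(inherits(m, "ContactMatrix"))
  idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(chrom = m$chrom,
                   bin1_start = (idx[, 1] - 1L) * m$bin_size,
                   bin2_start = (idx[, 2] - 1L) * m$bin_size,
                   count = m$counts[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Estimate map resolution from per-bin contact totals
#'
#' Map resolution is the smallest candidate bin size at which at least a
#' given fraction of loci (bins) carry at least `min_contacts` contacts.
#'
#' @param totals named list: one numeric vector of per-bin contact totals per
#'   candidate bin size; names are the bin sizes in bp, ascending.
#' @param fraction required fraction of qualifying loci (default 0.80).
#' @param min_contacts minimum contacts per locus (default 1000).
#' @return The smallest qualifying bin size (bp), or `NA` if none qualifies.
#' @export
estimate_map_resolution <- function(totals, fraction = 0.80, min_contacts = 1000) {
  if (length(totals) == 0L) stop("no candidate bin sizes supplied")
  sizes <- as.numeric(names(totals))
  if (any(is.na(sizes))) stop("totals must be named by bin size")
  o <- order(sizes)
  for (k in o) {
    v <- totals[[k]]
    if (mean(v >= min_contacts) >= fraction) return(sizes[k])
  }
  NA_real_
}
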