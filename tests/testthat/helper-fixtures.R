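# Shared fixtures: small random matrices and label tracks, built in code.

random_contact_matrix <- function(n, seed, positive = FALSE, bin_size = 25e3) {
  set.seed(seed)
  m <- matrix(0, n, n)
  up <- upper.tri(m, diag = TRUE)
  m[up] <- if (positive) runif(sum(up), 1, 10) else rpois(sum(up), 5)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  contact_matrix(m, bin_size)
}

random_labels <- function(n, seed, p_na = 0.1) {
  set.seed(seed)
  lab <- sample(c("A", "B"), n, replace = TRUE)
  lab[runif(n) < p_na] <- NA
  lab
}

# A deterministic block matrix: background level 1, TAD blocks elevated.
block_matrix <- function(n, blocks, level = 3, bin_size = 25e3) {
  m <- matrix(1, n, n)
  for (b in blocks) m[b[1]:b[2], b[1]:b[2]] <- level
  contact_matrix(m, bin_size)
}

# Shared synthetic panel, built once per test session (used by the
# synthetic-module tests and the acceptance suite).
.panel_cache <- new.env()

shared_panel <- function() {
  if (is.null(.panel_cache$panel)) {
    ref <- simulate_reference(list(n_chrom = 2, chrom_length = 1e7), seed = 5)
    .panel_cache$panel <- suppressMessages(
      simulate_accession_panel(ref, n_accessions = 6, seed = 5))
  }
  .panel_cache$panel
}

shared_boundary_calls <- function() {
  if (is.null(.panel_cache$bounds)) {
    panel <- shared_panel()
    b <- lapply(names(panel$accessions), function(a)
      call_boundaries_accession(panel, a))
    names(b) <- names(panel$accessions)
    .panel_cache$bounds <- b
  }
  .panel_cache$bounds
}

shared_compartment_calls <- function() {
  if (is.null(.panel_cache$comps)) {
    panel <- shared_panel()
    .panel_cache$comps <- pan_compartment_status(panel)
  }
  .panel_cache$comps
}

# Callable-region edge: insulation span (20 bins) + delta span (5 bins).
INS_EDGE_BINS <- 26
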