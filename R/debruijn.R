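# One assembly iteration at a fixed k: seeding from above-valley k-mers,
# the three-filter extension cascade, bidirectional verification, collision
# healing and end trimming.  The heavy lifting lives in C++ (asm_iterate);
# the filter rules are also exposed as small R functions for direct testing.

#' Candidate extension bases at a contig end
#'
#' For the last k-mer of a contig end, the per-base plus/minus counts of the
#' four k-mers obtained by shifting in one more base.  Absent k-mers (and,
#' by default, k-mers already claimed by a contig) report zero.
#'
#' @param tbl A `conskex_kmers` table.
#' @param kmer The oriented k-mer at the contig end.
#' @param include_used Report counts for claimed k-mers too?
#' @return List with integer vectors `plus`, `minus` (named A,C,G,T) and
#'   logical `used`.
#' @export
candidate_bases <- function(tbl, kmer, include_used = FALSE) {
  candidate_bases_cpp(tbl$ptr, toupper(kmer), include_used)
}

#' Count filter for extension candidates
#'
#' Candidates whose total count falls below `ext_frac` of the maximum
#' candidate count are noise and are dropped; the boundary is kept
#' (`>=`).  A single candidate always survives.
#'
#' @param totals Named numeric vector of per-base total counts (zero or
#'   absent bases excluded by the caller).
#' @param ext_frac Extension threshold (default 0.1).
#' @return Names of the surviving bases.
#' @export
filter_by_count <- function(totals, ext_frac = 0.1) {
  totals <- totals[totals > 0]
  if (length(totals) == 0L) return(character(0))
  names(totals)[totals >= ext_frac * max(totals) - 1e-9]
}

#' Strand-balance filter for extension candidates
#'
#' Illumina systematic errors are strand-specific: a candidate seen almost
#' exclusively on one strand is distrusted when a strand-balanced candidate
#' exists.  A candidate is balanced when its minor-strand share reaches
#' `balance_frac`; if at least one candidate is balanced, unbalanced ones
#' are dropped, otherwise all are kept.
#'
#' @param plus,minus Named numeric vectors of per-strand counts for the
#'   surviving candidates.
#' @param balance_frac Minor-strand share defining "balanced" (default 0.25:
#'   a 3:1 skew is still balanced, 4:1 is not).
#' @return Names of the surviving bases.
#' @export
filter_by_strand <- function(plus, minus, balance_frac = 0.25) {
  tot <- plus + minus
  keep <- tot > 0
  plus <- plus[keep]; minus <- minus[keep]; tot <- tot[keep]
  if (length(tot) == 0L) return(character(0))
  balanced <- pmin(plus, minus) >= balance_frac * tot - 1e-9
  if (any(balanced)) names(tot)[balanced] else names(tot)
}

#' Run the extension cascade from an oriented k-mer
#'
#' Diagnostic access to the full decision: count filter, strand filter,
#' bounded path exploration over `max(100, k)` steps, and (optionally) the
#' bidirectional check that the unique backward extension of the chosen
#' k-mer reproduces the current one.
#'
#' @param tbl A `conskex_kmers` table.
#' @param kmer Oriented k-mer to extend rightward.
#' @param ext_frac,balance_frac Filter thresholds.
#' @param bidirectional Apply the backward verification?
#' @return List with `outcome` (`"dead_end"`, `"unique"` or `"break"`) and
#'   `base` (the chosen base for `"unique"`).
#' @export
extension_decision <- function(tbl, kmer, ext_frac = 0.1, balance_frac = 0.25,
                               bidirectional = TRUE) {
  r <- cascade_cpp(tbl$ptr, toupper(kmer), ext_frac, balance_frac, bidirectional)
  list(outcome = c("dead_end", "unique", "break")[r$status + 1L], base = r$base)
}

#' One De Bruijn assembly iteration
#'
#' Contigs carried over from the previous iteration claim their k-mers and
#' are extended at both ends; fresh contigs are then seeded from every
#' unclaimed k-mer with count above the valley, in ascending canonical
#' order (or interleaved across `partitions`, which must not change the
#' result), and extended in both directions.  Extensions that run into a
#' k-mer already claimed by another contig stop and are healed afterwards by
#' a connector pass that merges contigs end-to-end and recognizes circular
#' closures.  Each terminal dead-end/break end is trimmed by k-1 bases
#' (carried-over contigs lose at most what they gained); fresh contigs
#' shorter than k are dropped.  No k-mer ends up in two contigs.
#'
#' @param tbl A `conskex_kmers` table for this k (freshly built; its used
#'   flags are consumed by the iteration).
#' @param valley Count valley for seeding (0 when no coverage peak).
#' @param prior Data frame of prior contigs (`seq`, `circular`) or `NULL`.
#' @param ext_frac,balance_frac Filter thresholds.
#' @param partitions Seed-partition count (parallel-schedule emulation).
#' @return Data frame with columns `seq` and `circular` (canonicalized,
#'   sorted).
#' @export
assemble_iteration <- function(tbl, valley = 0, prior = NULL, ext_frac = 0.1,
                               balance_frac = 0.25, partitions = 1L) {
  pseq <- if (is.null(prior)) character(0) else as.character(prior$seq)
  pcirc <- if (is.null(prior)) logical(0) else as.logical(prior$circular)
  res <- asm_iterate(tbl$ptr, as.integer(valley), ext_frac, balance_frac,
                     pseq, pcirc, as.integer(partitions))
  canonicalize_contigs(data.frame(seq = res$seq,
                                  circular = as.logical(res$circular),
                                  stringsAsFactors = FALSE),
                       k_orient = tbl$k)
}

# byte-wise (locale-independent) string comparison: is a < b?
str_less <- function(a, b) {
  if (a == b) return(FALSE)
  order(c(a, b), method = "radix")[1] == 1L
}

# Canonical orientation/rotation and alphabetical order without ordinals.
canonicalize_contigs <- function(contigs, k_orient = 21L) {
  if (nrow(contigs) == 0L) return(contigs)
  seqs <- contigs$seq
  circ <- contigs$circular
  k <- as.integer(k_orient)
  for (i in seq_along(seqs)) {
    if (circ[i]) {
      kk <- min(k, nchar(seqs[i]))
      seqs[i] <- cpp_canonical_rotation(seqs[i], kk)
    } else {
      rc <- cpp_revcomp(seqs[i])
      kk <- min(k, nchar(seqs[i]))
      a <- substr(seqs[i], 1L, kk)
      b <- substr(rc, 1L, kk)
      if (str_less(b, a) || (a == b && str_less(rc, seqs[i]))) seqs[i] <- rc
    }
  }
  ord <- order(seqs, method = "radix")
  data.frame(seq = seqs[ord], circular = circ[ord], stringsAsFactors = FALSE)
}
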