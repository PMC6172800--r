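# Strand-aware canonical k-mer counting and the k-mer spectrum.

#' Count canonical k-mers with strand attribution
#'
#' Every window of every sequence (windows containing N are skipped) is
#' reduced to its canonical form, the lexicographic minimum of the window and
#' its reverse complement; a window equal to its canonical form increments
#' the plus count, otherwise the minus count (a self-reverse-complementary
#' window counts as plus).  Counting uses the sorted-array method; with
#' `batches > 1` windows are processed in disjoint hash partitions to cap
#' memory, with identical results.
#'
#' @param x A `conskex_reads` store (available, trimmed reads are used) or a
#'   character vector of sequences.
#' @param k K-mer length.
#' @param c_min Minimum total count; k-mers below it are discarded.
#' @param batches Number of hash partitions for counting.
#' @return An object of class `conskex_kmers` (an external pointer to the
#'   sorted count table plus metadata).
#' @examples
#' tb <- kmer_table("ACGT", k = 3)
#' kmer_counts(tb)   # ACG observed once forward, once as reverse complement
#' @export
kmer_table <- function(x, k, c_min = 1L, batches = 1L) {
  seqs <- if (inherits(x, "conskex_reads")) active_seqs(x) else as.character(x)
  k <- as.integer(k)
  if (k < 1L) stop("k must be positive")
  if (length(seqs) == 0L || all(nchar(seqs) < k)) {
    if (length(seqs) > 0L)
      warning("k = ", k, " exceeds every read length; empty k-mer table")
    seqs <- character(0)
  }
  ptr <- kt_build(seqs, k, as.integer(c_min), as.integer(batches))
  structure(list(ptr = ptr, k = k, c_min = as.integer(c_min)),
            class = "conskex_kmers")
}

#' @export
print.conskex_kmers <- function(x, ...) {
  info <- kt_info(x$ptr)
  cat("<conskex_kmers> k = ", info$k, ", ", format(info$n, big.mark = ","),
      " distinct canonical k-mers (c_min = ", x$c_min, ")\n", sep = "")
  invisible(x)
}

#' Extract k-mer counts as a data frame
#'
#' @param tbl A `conskex_kmers` table.
#' @param n Maximum rows to return (in sorted canonical order); `Inf` for all.
#' @return Data frame with columns `kmer`, `plus`, `minus`.
#' @export
kmer_counts <- function(tbl, n = Inf) {
  kt_dump(tbl$ptr, if (is.infinite(n)) -1 else as.double(n))
}

#' Number of distinct k-mers in a table
#' @param tbl A `conskex_kmers` table.
#' @export
kmer_table_size <- function(tbl) kt_info(tbl$ptr)$n

#' K-mer spectrum with main peak, valley and genome-size estimate
#'
#' Builds the count histogram (count versus number of distinct k-mers with
#' that count) and runs [detect_peak()] on it.
#'
#' @param tbl A `conskex_kmers` table.
#' @return An object of class `conskex_spectrum`: list with `k`, `bins` (data
#'   frame `count`, `n_kmers`), `main_peak`, `valley`, `genome_size`.
#' @export
kmer_histogram <- function(tbl) {
  bins <- kt_histogram_cpp(tbl$ptr)
  pk <- detect_peak(bins)
  structure(list(k = tbl$k, bins = bins, main_peak = pk$main_peak,
                 valley = pk$valley, genome_size = pk$genome_size),
            class = "conskex_spectrum")
}

#' @export
print.conskex_spectrum <- function(x, ...) {
  cat("<conskex_spectrum> k = ", x$k, ", ", sum(x$bins$n_kmers),
      " distinct k-mers\n", sep = "")
  if (is.na(x$main_peak)) {
    cat("  no coverage peak detected; genome size fallback = ",
        round(x$genome_size), " (80% of distinct k-mers)\n", sep = "")
  } else {
    cat("  main peak at count ", x$main_peak, ", valley at ", x$valley,
        ", genome size ~ ", round(x$genome_size), " k-mers\n", sep = "")
  }
  invisible(x)
}

#' Detect the coverage peak, valley and genome size of a k-mer histogram
#'
#' The multiplicities of the counts present in the histogram are scanned
#' upward; the first rise marks the end of the low-count noise slope and the
#' main peak is the count with the largest multiplicity beyond it (raw, not
#' smoothed: smoothing smears the noise slope into a shoulder that can
#' out-weigh a sparse genuine mode).  Secondary high-count peaks from
#' repeats or plasmids have few distinct k-mers and are never selected.
#' The valley is the left low end of the distribution around the main
#' peak: the largest count below the peak achieving the minimal window-5
#' moving-average multiplicity on the dense count grid, so that any
#' low-count mode sits entirely below it.
#' Low-level contamination forms its own low-count mode,
#' and placing the valley at the trough between that mode and the genomic
#' mode keeps contaminant k-mers from seeding contigs.  The genome size is
#' the number of distinct k-mers with count above the valley.  When the
#' multiplicities never rise (no coverage mode is distinguishable) the peak
#' is absent, the valley is zero and 80% of the distinct k-mers is used as
#' the genome-size estimate.
#'
#' @param bins Data frame with columns `count` and `n_kmers`.
#' @return List with `main_peak` (count or `NA`), `valley` (count, 0 when no
#'   peak) and `genome_size` (distinct k-mers).
#' @examples
#' bins <- data.frame(count = c(1, 2, 3, 28, 30, 32),
#'                    n_kmers = c(1000, 400, 50, 90, 120, 80))
#' detect_peak(bins)   # peak 30, valley between the modes, genome size 290
#' @export
detect_peak <- function(bins) {
  stopifnot(nrow(bins) > 0L)
  bins <- bins[order(bins$count), , drop = FALSE]
  cnt <- as.numeric(bins$count)
  mult <- as.numeric(bins$n_kmers)
  total <- sum(mult)
  n <- length(cnt)

  # first rise of the raw multiplicities over present counts: the noise
  # slope has ended and a coverage mode lies above
  rise_i <- NA_integer_
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      if (mult[i + 1L] > mult[i]) { rise_i <- i; break }
    }
  }
  if (is.na(rise_i)) {
    return(list(main_peak = NA_real_, valley = 0, genome_size = 0.8 * total))
  }

  # window-5 moving average on the dense count grid
  grid_max <- max(cnt)
  dense <- numeric(grid_max)
  dense[cnt] <- mult
  if (grid_max >= 5L) {
    sm <- as.numeric(stats::filter(dense, rep(1 / 5, 5), sides = 2))
    sm[is.na(sm)] <- dense[is.na(sm)]            # grid edges: raw values
  } else {
    sm <- dense
  }
  # peak from the raw multiplicities: smoothing smears the noise slope's
  # shoulder above genuine modes when the modes are sparse
  above <- which(seq_len(grid_max) > cnt[rise_i])
  main_peak <- above[which.max(dense[above])]

  # valley: the left low end of the main distribution -- the largest count
  # below the peak at the minimal smoothed multiplicity, i.e. the trough
  # between the genomic mode and whatever lies below it (noise or a
  # contaminant mode)
  lo <- cnt[1]
  if (lo >= main_peak) {
    valley <- max(lo - 1, 0)
  } else {
    rng <- lo:(main_peak - 1L)
    mn <- min(sm[rng])
    valley <- max(rng[sm[rng] <= mn + 1e-9])
  }

  list(main_peak = as.numeric(main_peak), valley = as.numeric(valley),
       genome_size = sum(mult[cnt > valley]))
}

#' Write a k-mer histogram as TSV
#'
#' Two columns, count and multiplicity, for spectrum diagnostics.
#'
#' @param x A `conskex_spectrum` or the `bins` data frame.
#' @param path Output file.
#' @export
write_histogram <- function(x, path) {
  bins <- if (inherits(x, "conskex_spectrum")) x$bins else x
  utils::write.table(bins, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Conservation helper: total windows and N-containing windows of sequences.
count_windows <- function(seqs, k) count_windows_cpp(as.character(seqs), as.integer(k))

#' Reverse complement
#' @param x Character vector of DNA sequences.
#' @export
revcomp <- function(x) cpp_revcomp(as.character(x))
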