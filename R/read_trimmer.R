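# Suspect-19-mer read trimming: adapter and vector sequence shows up as
# 19-mers present in an implausibly large fraction of reads; every read is
# clipped at its first suspect 19-mer.

TRIM_K <- 19L

#' Find suspect 19-mers
#'
#' A 19-mer is *suspect* when the number of mates containing it at least
#' once, in either orientation, reaches `v_f` times the number of mates
#' (per-read presence, not per-occurrence: adapter contamination is a
#' per-read phenomenon).  Genomic 19-mers cannot reach the default 5%
#' presence threshold in any realistic library, so suspects are adapter,
#' vector, or extreme-homopolymer signal.
#'
#' @param store A `conskex_reads` store (untrimmed).
#' @param v_f Suspect threshold as a fraction of mates (default 0.05).
#' @return An object of class `conskex_suspects`: list with `suspects`
#'   (canonical 19-mer strings), `report` (data frame `kmer`, `n_reads`,
#'   `fraction`), `most_frequent` and `n_mates`.
#' @export
find_suspect_kmers <- function(store, v_f = 0.05) {
  stopifnot(inherits(store, "conskex_reads"))
  if (v_f <= 0 || v_f > 1) stop("v_f must be in (0, 1]")
  seqs <- store$seq
  n_mates <- length(seqs)
  if (n_mates == 0L) stop("empty read store")
  if (all(nchar(seqs) < TRIM_K)) {
    warning("all reads shorter than ", TRIM_K, " bases; no suspect k-mers")
    census <- data.frame(kmer = character(0), n_reads = numeric(0))
  } else {
    census <- cpp_kmer_read_census(seqs, TRIM_K, v_f * n_mates)
  }
  report <- census
  report$fraction <- if (nrow(report)) report$n_reads / n_mates else numeric(0)
  report <- report[order(-report$n_reads, report$kmer), , drop = FALSE]
  structure(list(
    suspects = report$kmer,
    report = report,
    most_frequent = if (nrow(report)) report$kmer[1] else NA_character_,
    n_mates = n_mates
  ), class = "conskex_suspects")
}

#' @export
print.conskex_suspects <- function(x, ...) {
  cat("<conskex_suspects> ", length(x$suspects), " suspect ", TRIM_K,
      "-mers over ", x$n_mates, " mates\n", sep = "")
  if (length(x$suspects)) {
    cat("  most frequent: ", x$most_frequent, " (",
        sprintf("%.1f%%", 100 * x$report$fraction[1]), " of reads)\n", sep = "")
  }
  invisible(x)
}

#' Trim reads at their first suspect 19-mer
#'
#' Each mate is scanned from position 1; at the first window whose canonical
#' form is suspect, the suspect 19-mer and everything after it are removed
#' (`trimmed_len` becomes the 0-based window start).  A suspect at the very
#' start removes the read entirely.  Trimming is idempotent for a fixed
#' suspect set.
#'
#' @param store A `conskex_reads` store.
#' @param suspects A `conskex_suspects` object or character vector of
#'   19-mers.
#' @return The updated store; the attribute `"trim_report"` holds a data
#'   frame of clip positions (0-based) for the reads that were trimmed.
#' @export
trim_reads <- function(store, suspects) {
  stopifnot(inherits(store, "conskex_reads"))
  sus <- if (inherits(suspects, "conskex_suspects")) suspects$suspects else
    as.character(suspects)
  if (length(sus) == 0L) {
    attr(store, "trim_report") <- data.frame(read = integer(0), clip_pos = integer(0))
    return(store)
  }
  eff <- effective_seq(store, seq_along(store$seq))
  pos <- cpp_first_suspect_pos(eff, sus, TRIM_K)
  hit <- pos >= 0L
  store$trimmed_len[hit] <- pos[hit]
  attr(store, "trim_report") <- data.frame(read = which(hit), clip_pos = pos[hit])
  store
}

#' Run the full trimming stage
#'
#' Convenience wrapper: census, then clip.  Serializes the suspect report as
#' TSV when `report_path` is given.
#'
#' @inheritParams find_suspect_kmers
#' @param report_path Optional path for a TSV of (kmer, n_reads, fraction).
#' @return The trimmed store; attributes `"suspects"` and `"trim_report"`
#'   carry the census and the clip positions.
#' @export
trim_store <- function(store, v_f = 0.05, report_path = NULL) {
  sus <- find_suspect_kmers(store, v_f)
  if (!is.null(report_path))
    utils::write.table(sus$report, report_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  store <- trim_reads(store, sus)
  attr(store, "suspects") <- sus
  store
}
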