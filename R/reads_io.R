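# Read store: in-memory collection of (possibly trimmed) mates with pairing
# information, plus FASTA/FASTQ input and contig FASTA output.

#' Construct a read store from sequence vectors
#'
#' The read store holds one entry per mate: its identifier, sequence, pairing
#' slot, trim state and a used flag (set once a read has been absorbed into a
#' contig and retired from later iterations).  Reads keep their input order,
#' which anchors deterministic output.
#'
#' @param seq Character vector of read sequences (first mates in paired mode).
#' @param seq2 Optional character vector of second mates, same length as
#'   `seq`; pairs are linked by position.
#' @param id,id2 Optional identifiers; defaults are generated.
#' @return An object of class `conskex_reads`.
#' @examples
#' rs <- read_store(c("ACGTACGT", "TTTTACGT"))
#' rs
#' @export
read_store <- function(seq, seq2 = NULL, id = NULL, id2 = NULL) {
  seq <- toupper(as.character(seq))
  if (is.null(id)) id <- sprintf("read_%d", seq_along(seq))
  if (!is.null(seq2)) {
    seq2 <- toupper(as.character(seq2))
    if (length(seq2) != length(seq))
      stop("paired input has mismatched mate counts: ", length(seq), " vs ",
           length(seq2))
    if (is.null(id2)) id2 <- sprintf("%s/2", sub("/1$", "", id))
    n <- length(seq)
    # interleave so mates of a pair are adjacent, preserving pair order
    allseq <- c(rbind(seq, seq2))
    allid <- c(rbind(id, id2))
    store <- list(
      id = allid,
      seq = allseq,
      pair_slot = rep(c("first", "second"), n),
      mate_index = rep(seq_len(n), each = 2L),
      trimmed_len = nchar(allseq),
      used = rep(FALSE, 2L * n),
      paired = TRUE
    )
  } else {
    store <- list(
      id = id,
      seq = seq,
      pair_slot = rep("unpaired", length(seq)),
      mate_index = rep(NA_integer_, length(seq)),
      trimmed_len = nchar(seq),
      used = rep(FALSE, length(seq)),
      paired = FALSE
    )
  }
  class(store) <- "conskex_reads"
  store
}

detect_format <- function(path) {
  con <- gzfile(path, "rb")                      # transparent for plain files
  on.exit(close(con))
  first <- rawToChar(readBin(con, "raw", 1L))
  if (identical(first, ">")) return("fasta")
  if (identical(first, "@")) return("fastq")
  stop("cannot detect FASTA/FASTQ format of '", path,
       "' (first character '", first, "')")
}

read_seq_file <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  fmt <- detect_format(path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = fmt),
    error = function(e) stop("malformed ", fmt, " record in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  list(seq = as.character(x), id = sub("\\s.*$", "", names(x)))
}

#' Load reads from FASTA/FASTQ files
#'
#' Input format (FASTA or FASTQ, plain or gzip-compressed) is auto-detected
#' from the first record character; gzip is detected by the stream itself,
#' not the file extension.  Base qualities, if present, are parsed and
#' discarded.  Reads containing N are kept: k-mer windows containing N are
#' simply never generated downstream.
#'
#' @param paths One file (unpaired or interleaved paired) or two files
#'   (paired, mates matched by record index).
#' @param paired Logical; are reads paired?
#' @param interleaved Logical; with one file, are mates interleaved
#'   first/second?
#' @return A `conskex_reads` store.
#' @export
load_reads <- function(paths, paired = FALSE, interleaved = FALSE) {
  paths <- as.character(paths)
  if (paired && !interleaved) {
    if (length(paths) != 2L)
      stop("paired non-interleaved input requires exactly two files")
    a <- read_seq_file(paths[1])
    b <- read_seq_file(paths[2])
    if (length(a$seq) != length(b$seq))
      stop("mate files have mismatched record counts: ", length(a$seq),
           " vs ", length(b$seq))
    read_store(a$seq, b$seq, id = a$id, id2 = b$id)
  } else if (paired && interleaved) {
    if (length(paths) != 1L)
      stop("interleaved input must be a single file")
    a <- read_seq_file(paths[1])
    if (length(a$seq) %% 2L != 0L)
      stop("interleaved file has an odd number of records")
    odd <- seq(1L, length(a$seq), by = 2L)
    read_store(a$seq[odd], a$seq[odd + 1L], id = a$id[odd], id2 = a$id[odd + 1L])
  } else {
    if (length(paths) != 1L) {
      parts <- lapply(paths, read_seq_file)
      read_store(unlist(lapply(parts, `[[`, "seq")),
                 id = unlist(lapply(parts, `[[`, "id")))
    } else {
      a <- read_seq_file(paths[1])
      read_store(a$seq, id = a$id)
    }
  }
}

# Effective (trimmed) sequences of reads still available for assembly.
active_seqs <- function(store, min_len = 1L) {
  keep <- !store$used & store$trimmed_len >= min_len
  s <- store$seq[keep]
  tl <- store$trimmed_len[keep]
  clip <- tl < nchar(s)
  s[clip] <- substr(s[clip], 1L, tl[clip])
  s
}

# Total trimmed bases T over available reads.
store_total_bases <- function(store) {
  sum(as.numeric(store$trimmed_len[!store$used]))
}

# Average trimmed mate length A_read.
store_avg_mate <- function(store) {
  mean(store$trimmed_len[!store$used])
}

# Available (both mates unused) pairs as index pairs into the store.
available_pairs <- function(store, min_len = 1L) {
  if (!store$paired) return(cbind(integer(0), integer(0)))
  i1 <- which(store$pair_slot == "first")
  i2 <- which(store$pair_slot == "second")
  i2 <- i2[match(store$mate_index[i1], store$mate_index[i2])]
  ok <- !store$used[i1] & !store$used[i2] &
    store$trimmed_len[i1] >= min_len & store$trimmed_len[i2] >= min_len
  cbind(i1[ok], i2[ok])
}

effective_seq <- function(store, idx) {
  s <- store$seq[idx]
  tl <- store$trimmed_len[idx]
  clip <- tl < nchar(s)
  s[clip] <- substr(s[clip], 1L, tl[clip])
  s
}

#' @export
print.conskex_reads <- function(x, ...) {
  n <- length(x$seq)
  avail <- sum(!x$used)
  cat("<conskex_reads> ", n, if (x$paired) " paired mates (" else " unpaired reads (",
      avail, " available)\n", sep = "")
  cat("  total trimmed bases: ", format(store_total_bases(x), big.mark = ","),
      "; mean mate length: ", round(store_avg_mate(x), 1), "\n", sep = "")
  trimmed <- sum(x$trimmed_len < nchar(x$seq))
  if (trimmed > 0) cat("  reads trimmed: ", trimmed, "\n", sep = "")
  invisible(x)
}

#' Write contigs as FASTA
#'
#' Contigs are written in their final sorted order with headers
#' `Contig_N_C`, where `N` is the 1-based ordinal after alphabetical sorting
#' and `C` the mean count of the contig's K_min-mers in the trimmed read set
#' (one decimal place); circular contigs carry the suffix `_Circ`.  Sequences
#' are wrapped at 80 columns.
#'
#' @param contigs A `conskex_assembly`, or a data frame with columns `seq`,
#'   `circular`, `mean_kmin_count` (already canonicalized and sorted).
#' @param path Output file.
#' @return Invisibly, the header names written.
#' @export
write_contigs <- function(contigs, path) {
  if (inherits(contigs, "conskex_assembly")) contigs <- contigs$contigs
  if (nrow(contigs) == 0L) {
    warning("no contigs to write; producing an empty FASTA file")
    file.create(path)
    return(invisible(character(0)))
  }
  nm <- sprintf("Contig_%d_%.1f", seq_len(nrow(contigs)), contigs$mean_kmin_count)
  nm[contigs$circular] <- paste0(nm[contigs$circular], "_Circ")
  x <- Biostrings::DNAStringSet(contigs$seq)
  names(x) <- nm
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(nm)
}
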