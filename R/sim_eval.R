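# Simulated test sets (substrings and contamination) and a seed-and-chain
# assembly evaluator: N50, mismatches per 100 kb, misassemblies, and the
# length-deviation statistic L_R + L_A - 2*C_RA.

#' Generate a random genome
#'
#' @param length Genome length in bases.
#' @param seed RNG seed.
#' @param gc GC content (default 0.5).
#' @return A single DNA string.
#' @export
random_genome <- function(length, seed = 1L, gc = 0.5) {
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

#' Substrings read set
#'
#' One error-free read per genome position: every length-`K` window (with
#' wraparound for circular genomes, so per-base coverage is exactly `K`);
#' windows starting at even 0-based positions are reverse complemented so
#' both strands are represented.  This set varies read length and coverage
#' together without introducing errors.
#'
#' @param genome DNA string.
#' @param K Substring (read) length.
#' @param circular Treat the genome as circular (default)?
#' @return An unpaired `conskex_reads` store.
#' @examples
#' st <- gen_substrings("ACGTAC", 3)
#' st$seq   # position 0 read is revcomp("ACG") = "CGT"
#' @export
gen_substrings <- function(genome, K, circular = TRUE) {
  L <- nchar(genome)
  stopifnot(K <= L)
  if (circular) {
    doubled <- paste0(genome, substr(genome, 1L, K - 1L))
    starts <- seq_len(L)                       # 1-based; 0-based = starts - 1
  } else {
    doubled <- genome
    starts <- seq_len(L - K + 1L)
  }
  reads <- substring(doubled, starts, starts + K - 1L)
  even0 <- (starts - 1L) %% 2L == 0L
  reads[even0] <- cpp_revcomp(reads[even0])
  read_store(reads, id = sprintf("sub_%d", starts - 1L))
}

#' Contamination read set
#'
#' Error-free paired reads covering the genome uniformly at `coverage`, plus
#' reads from a copy of the same genome mutated at a fraction
#' `mutation_rate` of its positions (each mutated base substituted by a
#' uniformly chosen different base), added at `contaminant_coverage`.  This
#' emulates low-level carryover contamination from a previous sequencing
#' run: almost identical sequence at a few percent of the main coverage.
#' Mates are `mate_len` bases, fragments exactly `insert` long, second mates
#' reverse complemented.  The mutated genome depends only on `seed` and
#' `mutation_rate`, so a coverage sweep at fixed seed uses one contaminant.
#'
#' @param genome DNA string.
#' @param coverage Clean fold coverage (default 60).
#' @param contaminant_coverage Contaminant fold coverage (default 0).
#' @param mate_len Mate length (default 150).
#' @param insert Insert (fragment) size (default 300).
#' @param mutation_rate Per-position substitution probability of the
#'   contaminant copy (default 0.001).
#' @param circular Treat the genome as circular (default)?
#' @param seed RNG seed.
#' @return List with `store` (paired `conskex_reads`), `truth` (mutated
#'   positions, 1-based, and the mutant genome) and the pair counts.
#' @export
gen_contamination <- function(genome, coverage = 60, contaminant_coverage = 0,
                              mate_len = 150L, insert = 300L,
                              mutation_rate = 0.001, circular = TRUE,
                              seed = 1L) {
  L <- nchar(genome)
  stopifnot(L >= insert, mate_len <= insert)
  set.seed(seed)

  # contaminant genome: fixed given seed and rate, independent of coverages
  bases <- c("A", "C", "G", "T")
  mut_pos <- which(stats::runif(L) < mutation_rate)
  mutant <- genome
  if (length(mut_pos) > 0L) {
    cur <- substring(mutant, mut_pos, mut_pos)
    repl <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), character(1))
    for (i in seq_along(mut_pos))
      substr(mutant, mut_pos[i], mut_pos[i]) <- repl[i]
  }

  draw_pairs <- function(g, n) {
    if (n == 0L) return(list(m1 = character(0), m2 = character(0)))
    if (circular) {
      gd <- paste0(g, substr(g, 1L, insert - 1L))
      starts <- sample.int(L, n, replace = TRUE)
    } else {
      gd <- g
      starts <- sample.int(L - insert + 1L, n, replace = TRUE)
    }
    frag_end <- starts + insert - 1L
    m1 <- substring(gd, starts, starts + mate_len - 1L)
    m2 <- cpp_revcomp(substring(gd, frag_end - mate_len + 1L, frag_end))
    list(m1 = m1, m2 = m2)
  }

  n_clean <- round(L * coverage / (2 * mate_len))
  n_cont <- round(L * contaminant_coverage / (2 * mate_len))
  cl <- draw_pairs(genome, n_clean)
  co <- draw_pairs(mutant, n_cont)
  store <- read_store(c(cl$m1, co$m1), c(cl$m2, co$m2),
                      id = c(sprintf("clean_%d/1", seq_len(n_clean)),
                             sprintf("cont_%d/1", seq_len(n_cont))))
  list(store = store,
       truth = list(mutated_positions = mut_pos, mutant_genome = mutant),
       n_clean_pairs = n_clean, n_contaminant_pairs = n_cont)
}

#' Write a simulated read set to FASTQ/FASTA
#'
#' @param store A `conskex_reads` store.
#' @param path Output file (paired stores are written interleaved); `.gz`
#'   paths are compressed.
#' @param format `"fastq"` (dummy qualities) or `"fasta"`.
#' @export
write_reads <- function(store, path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  x <- Biostrings::DNAStringSet(store$seq)
  names(x) <- store$id
  if (format == "fastq") {
    q <- Biostrings::BStringSet(vapply(nchar(store$seq),
                                       function(n) strrep("I", n), character(1)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                                compress = grepl("\\.gz$", path))
  } else {
    Biostrings::writeXStringSet(x, path, width = 80L,
                                compress = grepl("\\.gz$", path))
  }
  invisible(path)
}

# chain blocks of one contig; returns aligned query length, mismatches and
# misassembly events
chain_blocks <- function(bl, contig_len, seed_len, max_ref_gap) {
  if (nrow(bl) == 0L)
    return(list(aligned = 0, mismatches = 0, events = 0L))
  # convert reverse-strand oriented coordinates to forward contig coordinates
  fq <- bl
  neg <- bl$strand < 0
  fq$qstart[neg] <- contig_len - bl$qend[neg] + 1L
  fq$qend[neg] <- contig_len - bl$qstart[neg] + 1L
  fq$len <- fq$qend - fq$qstart + 1L
  # doubled circular references give duplicate diagonals: drop repeats of the
  # same query span, keep the smaller reference start
  fq <- fq[order(fq$qstart, fq$qend, fq$rstart), , drop = FALSE]
  dup <- duplicated(fq[, c("strand", "qstart", "qend")])
  fq <- fq[!dup, , drop = FALSE]
  # greedy cover: longest blocks first, accept if mostly new query territory
  fq <- fq[order(-fq$len, fq$qstart), , drop = FALSE]
  acc <- integer(0)
  covered <- logical(contig_len)
  for (i in seq_len(nrow(fq))) {
    span <- fq$qstart[i]:fq$qend[i]
    if (sum(covered[span]) < 0.5 * fq$len[i]) {
      acc <- c(acc, i)
      covered[span] <- TRUE
    }
  }
  ch <- fq[acc, , drop = FALSE]
  ch <- ch[order(ch$qstart), , drop = FALSE]
  events <- 0L
  if (nrow(ch) > 1L) {
    slack <- 2L * seed_len
    for (i in seq_len(nrow(ch) - 1L)) {
      a <- ch[i, ]; b <- ch[i + 1L, ]
      if (a$strand != b$strand) { events <- events + 1L; next }
      gap <- if (a$strand > 0) b$rstart - a$rend else a$rstart - b$rend
      if (gap < -slack || gap > max_ref_gap) events <- events + 1L
    }
  }
  list(aligned = sum(covered), mismatches = sum(ch$mismatches),
       events = events)
}

#' Evaluate an assembly against a reference
#'
#' A simplified, deterministic scorer in the spirit of standard assembly
#' evaluators.  Each contig is aligned to the reference by exact seed
#' matches grouped per strand and diagonal into gapless blocks (the
#' simulated sets are indel-free), extended end-gap free; the best chain of
#' blocks covers the contig.  A contig contributes a misassembly event at
#' every junction between chained blocks with inconsistent strand,
#' inconsistent reference order, or a reference gap larger than
#' `max_ref_gap` (default 1 kb, the conventional threshold for an extensive
#' misassembly).  Mismatches are substitutions inside aligned blocks;
#' `mismatches_per_100kb` is normalized by the aligned length C_RA.  The
#' deviation statistic is `L_R + L_A - 2 * C_RA`.  Circular references are
#' doubled so wraparound alignments stay contiguous.
#'
#' @param contigs A `conskex_assembly`, contig data frame, or character
#'   vector of contig sequences.
#' @param reference Reference genome string.
#' @param circular Is the reference circular (default TRUE)?
#' @param seed_len Seed length for exact matching (default 21).
#' @param max_ref_gap Reference gap defining a misassembly (default 1000).
#' @param max_occ Seeds occurring more often than this in the reference are
#'   skipped (repeat shielding).
#' @param min_contig Contigs shorter than this are excluded from all metrics
#'   (default 500, the conventional evaluator floor).
#' @return An object of class `conskex_eval`: list with `n50`, `total_len`,
#'   `aligned_len`, `mismatches`, `mismatches_per_100kb`, `misassemblies`,
#'   `deviation`, `n_contigs`, `n_unaligned`.
#' @export
evaluate_assembly <- function(contigs, reference, circular = TRUE,
                              seed_len = 21L, max_ref_gap = 1000L,
                              max_occ = 50L, min_contig = 500L) {
  if (inherits(contigs, "conskex_assembly")) contigs <- contigs$contigs
  seqs <- if (is.data.frame(contigs)) contigs$seq else as.character(contigs)
  seqs <- seqs[nchar(seqs) >= min_contig]
  stopifnot(nchar(reference) > 0)
  l_r <- nchar(reference)
  ref2 <- if (circular) paste0(reference, reference) else reference
  l_a <- sum(nchar(seqs))
  aligned <- 0
  mism <- 0
  events <- 0L
  unal <- 0L
  for (s in seqs) {
    if (nchar(s) < seed_len) { unal <- unal + 1L; next }
    bl <- cpp_align_blocks(ref2, s, as.integer(seed_len), as.integer(max_occ))
    ch <- chain_blocks(bl, nchar(s), seed_len, max_ref_gap)
    if (ch$aligned == 0) unal <- unal + 1L
    aligned <- aligned + min(ch$aligned, nchar(s))
    mism <- mism + ch$mismatches
    events <- events + ch$events
  }
  aligned <- min(aligned, max(l_r, l_a))
  structure(list(
    n_contigs = length(seqs),
    n50 = n50(nchar(seqs)),
    total_len = l_a,
    aligned_len = aligned,
    mismatches = mism,
    mismatches_per_100kb = if (aligned > 0) 1e5 * mism / aligned else 0,
    misassemblies = events,
    deviation = l_r + l_a - 2 * aligned,
    n_unaligned = unal
  ), class = "conskex_eval")
}

#' @export
print.conskex_eval <- function(x, ...) {
  cat("<conskex_eval>\n")
  cat(sprintf("  contigs: %d (N50 %s bp, total %s bp, %d unaligned)\n",
              x$n_contigs, format(x$n50, big.mark = ","),
              format(x$total_len, big.mark = ","), x$n_unaligned))
  cat(sprintf("  aligned: %s bp; mismatches/100kb: %.3f; misassemblies: %d\n",
              format(x$aligned_len, big.mark = ","),
              x$mismatches_per_100kb, x$misassemblies))
  cat(sprintf("  length deviation (L_R + L_A - 2 C_RA): %s\n",
              format(x$deviation, big.mark = ",")))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' @param x A `conskex_eval` object.
#' @param path Output path; `.json` writes JSON, anything else TSV.
#' @export
write_eval <- function(x, path) {
  stopifnot(inherits(x, "conskex_eval"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- as.data.frame(unclass(x))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
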