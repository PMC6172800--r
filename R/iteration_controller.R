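# Full multi-k pipeline: trim -> detect parameters -> mate-length k ladder
# with read retirement -> pair connection -> long-k iterations -> canonical
# output.

#' Assemble reads into contigs
#'
#' Runs the complete conservative assembly pipeline.  Reads are clipped at
#' overrepresented 19-mers; all constants (count thresholds, k-mer ladder,
#' insert size) are detected from the data unless overridden; the ladder of
#' De Bruijn iterations ascends from `k_min` to the tuned `K_max`, retiring
#' reads that fall deeper than the buffer zone inside a contig; for paired
#' input, still-available pairs are connected into insert-sized fragments
#' that drive three final iterations at k-mer sizes beyond the mate length.
#' Output contigs are canonically oriented (circular contigs canonically
#' rotated) and alphabetically sorted, making repeated runs byte-identical
#' regardless of `partitions`.
#'
#' @param x A `conskex_reads` store, or file path(s) handed to
#'   [load_reads()].
#' @param paired,interleaved Passed to [load_reads()] when `x` is a path;
#'   ignored for stores (the store knows its pairing).
#' @param k_min Minimal k-mer size (default 21).
#' @param steps Ladder size S (default 11).
#' @param v_f Suspect-19-mer read fraction for trimming (default 0.05).
#' @param ext_frac Extension noise threshold (default 0.1).
#' @param balance_frac Strand-balance threshold (default 0.25).
#' @param insert_size Insert-size override; estimated when `NULL`.
#' @param partitions Seed-partition count; emulates parallel scheduling and
#'   must not change the output.
#' @param batches Hash-partition count for k-mer counting (memory cap).
#' @param seed Seed for the insert-sample RNG (the only randomness).
#' @param trim Run the read-trimming stage?
#' @param long_k Run the pair-connection and long-k-mer stage?
#' @param min_contig Minimum contig length written to the final assembly
#'   (default 200); shorter contigs, typically unresolvable scraps, are
#'   dropped at output.
#' @param verbose Log per-stage progress to stderr.
#' @return An object of class `conskex_assembly`: list with `contigs` (data
#'   frame `name`, `seq`, `length`, `circular`, `mean_kmin_count`),
#'   `params`, `log` (per-iteration summaries) and `store_summary`.
#' @examples
#' g <- random_genome(3000, seed = 4)
#' asm <- assemble(gen_substrings(g, 60), k_min = 21)
#' asm
#' @export
assemble <- function(x, paired = FALSE, interleaved = FALSE, k_min = 21L,
                     steps = 11L, v_f = 0.05, ext_frac = 0.1,
                     balance_frac = 0.25, insert_size = NULL, partitions = 1L,
                     batches = 1L, seed = 17L, trim = TRUE, long_k = TRUE,
                     min_contig = 200L, verbose = FALSE) {
  store <- if (inherits(x, "conskex_reads")) x
           else load_reads(x, paired = paired, interleaved = interleaved)
  if (length(store$seq) == 0L) stop("empty read store")
  say <- function(...) if (verbose) message("[conskex] ", ...)

  if (trim) {
    store <- trim_store(store, v_f = v_f)
    tr <- attr(store, "trim_report")
    say("trimming: ", nrow(tr), " reads clipped")
  }
  if (store_total_bases(store) <= 0) stop("all reads trimmed away")

  params <- detect_params(store, k_min = k_min, steps = steps, v_f = v_f,
                          ext_frac = ext_frac, balance_frac = balance_frac,
                          insert_size = insert_size, seed = seed,
                          batches = batches)
  say("params: ", jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = 4))

  contigs <- data.frame(seq = character(0), circular = logical(0),
                        stringsAsFactors = FALSE)
  log <- list()
  run_iter <- function(k, seqs, contigs, valley_from_hist = TRUE) {
    tb <- kmer_table(seqs, k, c_min = params$c_min, batches = batches)
    if (kmer_table_size(tb) == 0) return(list(contigs = contigs, skipped = TRUE))
    valley <- 0
    if (valley_from_hist) {
      sp <- kmer_histogram(tb)
      valley <- sp$valley
    }
    out <- assemble_iteration(tb, valley = valley, prior = contigs,
                              ext_frac = params$ext_frac,
                              balance_frac = params$balance_frac,
                              partitions = partitions)
    list(contigs = out, skipped = FALSE, valley = valley)
  }

  for (k in params$ladder) {
    seqs <- active_seqs(store, k)
    if (length(seqs) == 0L) {
      say("k = ", k, ": no available reads; carrying contigs forward")
      next
    }
    it <- run_iter(k, seqs, contigs)
    if (it$skipped) next
    contigs <- it$contigs
    store <- mark_used(store, contigs, k, params$buffer_m)
    log[[length(log) + 1L]] <- data.frame(
      stage = "mate", k = k, valley = it$valley, n_contigs = nrow(contigs),
      total_len = sum(nchar(contigs$seq)), n50 = n50(nchar(contigs$seq)),
      reads_available = sum(!store$used))
    say("k = ", k, ": ", nrow(contigs), " contigs, ",
        sum(nchar(contigs$seq)), " bp, N50 ", n50(nchar(contigs$seq)))
  }

  if (store$paired && long_k && length(params$long_ladder) > 0L) {
    frags <- harvest_long_kmers(store, contigs, params)
    say("pair connection: ", length(frags), " fragments")
    if (length(frags) > 0L) {
      for (k in params$long_ladder) {
        if (k > max(nchar(frags))) next
        it <- run_iter(k, frags, contigs)
        if (it$skipped) next
        contigs <- it$contigs
        log[[length(log) + 1L]] <- data.frame(
          stage = "long", k = k, valley = it$valley, n_contigs = nrow(contigs),
          total_len = sum(nchar(contigs$seq)), n50 = n50(nchar(contigs$seq)),
          reads_available = sum(!store$used))
        say("long k = ", k, ": ", nrow(contigs), " contigs, N50 ",
            n50(nchar(contigs$seq)))
      }
    }
  }

  contigs <- contigs[nchar(contigs$seq) >= min_contig, , drop = FALSE]
  out <- canonicalize_assembly(contigs, store, params)
  structure(list(
    contigs = out, params = params,
    log = if (length(log)) do.call(rbind, log) else NULL,
    store_summary = list(n_reads = length(store$seq),
                         n_used = sum(store$used),
                         n_trimmed = sum(store$trimmed_len < nchar(store$seq)),
                         paired = store$paired)
  ), class = "conskex_assembly")
}

#' Retire reads buried inside contigs
#'
#' A read is marked used when one of its k-mers maps inside a contig at a
#' distance greater than `m` from both contig ends; such a read can add no
#' new information.  Circular contigs retire every read sharing a k-mer with
#' them.  Used reads are excluded from all later graphs.
#'
#' @param store A `conskex_reads` store.
#' @param contigs Contig data frame (`seq`, `circular`).
#' @param k K-mer size of the iteration just finished.
#' @param m Buffer zone M from [buffer_zone()].
#' @return The updated store.
#' @export
mark_used <- function(store, contigs, k, m) {
  if (nrow(contigs) == 0L) return(store)
  idx <- which(!store$used & store$trimmed_len >= k)
  if (length(idx) == 0L) return(store)
  hit <- cpp_mark_used_reads(contigs$seq, contigs$circular,
                             effective_seq(store, idx), as.integer(k),
                             as.double(m))
  store$used[idx[hit]] <- TRUE
  store
}

#' Connect one or more mate pairs through the graph
#'
#' All paths from the last k-mer of the first mate to the first k-mer of the
#' (reverse-complemented) second mate, up to the maximal insert size, are
#' enumerated; the same search is repeated from the reverse complement.  The
#' connection succeeds only when both directions yield exactly one path and
#' the two agree; the result is the full fragment (mate, gap fill, mate).
#' Mates overlapping by at least k are handled by direct overlap placement.
#' Ambiguity, absent anchors, or exceeding the exploration budget give
#' failure (`NA`), never a guess.
#'
#' @param tbl A `conskex_kmers` table (count floor `C_min` only; no valley
#'   or strand filtering, conservatism comes from the uniqueness
#'   requirement).
#' @param m1,m2 Character vectors of first/second mates.
#' @param max_insert Maximal fragment length (3I).
#' @param path_cap Exploration budget multiplier; the search aborts (fails)
#'   after `path_cap * max_insert` steps.
#' @return Character vector of fragments, `NA` where connection failed.
#' @export
connect_pairs <- function(tbl, m1, m2, max_insert, path_cap = 200) {
  cpp_connect_pairs(tbl$ptr, toupper(as.character(m1)),
                    toupper(as.character(m2)), as.integer(max_insert),
                    as.double(path_cap))
}

#' Build the long-k-mer fragment store
#'
#' Still-available pairs are mapped onto the contigs with K_min-mers; a pair
#' whose mates land on one contig within the maximal insert is replaced by
#' the contig substring spanning it (the contig already resolves it), and
#' the remaining pairs are connected through the K_min graph of all trimmed
#' reads.  The returned fragments are the read-equivalents from which k-mers
#' longer than the mate length are counted.
#'
#' @param store A `conskex_reads` store after the mate-length ladder.
#' @param contigs Current contig data frame.
#' @param params A `conskex_params` object.
#' @return Character vector of fragments.
#' @export
harvest_long_kmers <- function(store, contigs, params) {
  pr <- available_pairs(store, min_len = params$k_min)
  if (nrow(pr) == 0L) return(character(0))
  m1 <- effective_seq(store, pr[, 1])
  m2 <- effective_seq(store, pr[, 2])

  sub_frag <- character(0)
  need <- rep(TRUE, length(m1))
  if (nrow(contigs) > 0L) {
    mp <- cpp_map_pairs(contigs$seq, contigs$circular, m1, m2,
                        as.integer(params$k_min))
    span <- mp[, 3] - mp[, 2] + 1L
    inb <- mp[, 1] > 0L & !is.na(span) & span <= params$max_insert
    if (any(inb)) {
      cseq <- contigs$seq
      doubled <- ifelse(contigs$circular, paste0(cseq, cseq), cseq)
      sub_frag <- substr(doubled[mp[inb, 1]], mp[inb, 2], mp[inb, 3])
      need[inb] <- FALSE
    }
  }
  conn <- character(0)
  if (any(need)) {
    tb <- kmer_table(active_seqs(store, params$k_min), params$k_min,
                     c_min = params$c_min)
    fr <- connect_pairs(tb, m1[need], m2[need], params$max_insert)
    conn <- fr[!is.na(fr)]
  }
  c(sub_frag, conn)
}

#' Canonicalize, sort and name the final assembly
#'
#' Linear contigs keep the orientation whose leading K_min-mer is
#' lexicographically smaller; circular contigs are rotated to start at the
#' smallest K_min-mer over both strands and all rotations.  Contigs are then
#' sorted alphabetically by sequence and numbered; the mean K_min-mer count
#' of each contig is computed over the full trimmed read set.
#'
#' @param contigs Contig data frame (`seq`, `circular`).
#' @param store The read store (all trimmed reads, including used ones).
#' @param params A `conskex_params` object.
#' @return Data frame `name`, `seq`, `length`, `circular`,
#'   `mean_kmin_count`.
#' @export
canonicalize_assembly <- function(contigs, store, params) {
  contigs <- canonicalize_contigs(contigs, k_orient = params$k_min)
  if (nrow(contigs) == 0L) {
    return(data.frame(name = character(0), seq = character(0),
                      length = integer(0), circular = logical(0),
                      mean_kmin_count = numeric(0), stringsAsFactors = FALSE))
  }
  all_trimmed <- store$seq
  tl <- store$trimmed_len
  clip <- tl < nchar(all_trimmed)
  all_trimmed[clip] <- substr(all_trimmed[clip], 1L, tl[clip])
  tb <- kmer_table(all_trimmed[tl >= params$k_min], params$k_min, c_min = 1L)
  mc <- vapply(seq_len(nrow(contigs)), function(i)
    cpp_mean_window_count(tb$ptr, contigs$seq[i], contigs$circular[i]),
    numeric(1))
  nm <- sprintf("Contig_%d_%.1f", seq_len(nrow(contigs)), mc)
  nm[contigs$circular] <- paste0(nm[contigs$circular], "_Circ")
  data.frame(name = nm, seq = contigs$seq, length = nchar(contigs$seq),
             circular = contigs$circular, mean_kmin_count = mc,
             stringsAsFactors = FALSE)
}

#' N50 of a set of contig lengths
#'
#' The largest length L such that contigs of length at least L hold at least
#' half the total assembled bases.
#'
#' @param lengths Integer vector of contig lengths.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) return(0L)
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' @export
print.conskex_assembly <- function(x, ...) {
  ct <- x$contigs
  cat("<conskex_assembly> ", nrow(ct), " contigs, ",
      format(sum(ct$length), big.mark = ","), " bp\n", sep = "")
  if (nrow(ct) > 0L) {
    cat("  N50 ", format(n50(ct$length), big.mark = ","), " bp; ",
        sum(ct$circular), " circular\n", sep = "")
    show <- utils::head(ct, 5L)
    for (i in seq_len(nrow(show)))
      cat("  ", show$name[i], "  ", show$length[i], " bp\n", sep = "")
    if (nrow(ct) > 5L) cat("  ... and ", nrow(ct) - 5L, " more\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.conskex_assembly <- function(object, ...) {
  ct <- object$contigs
  out <- list(
    n_contigs = nrow(ct),
    total_length = sum(ct$length),
    n50 = n50(ct$length),
    longest = if (nrow(ct)) max(ct$length) else 0L,
    n_circular = sum(ct$circular),
    k_ladder = object$params$ladder,
    long_ladder = object$params$long_ladder,
    c_min = object$params$c_min,
    insert = object$params$insert,
    reads_used = object$store_summary$n_used,
    reads_total = object$store_summary$n_reads
  )
  class(out) <- "summary.conskex_assembly"
  out
}

#' @export
print.summary.conskex_assembly <- function(x, ...) {
  cat("conskex assembly summary\n")
  cat("  contigs:       ", x$n_contigs, " (", x$n_circular, " circular)\n", sep = "")
  cat("  total length:  ", format(x$total_length, big.mark = ","), " bp\n", sep = "")
  cat("  N50 / longest: ", format(x$n50, big.mark = ","), " / ",
      format(x$longest, big.mark = ","), " bp\n", sep = "")
  cat("  k ladder:      ", paste(x$k_ladder, collapse = " "), "\n", sep = "")
  if (length(x$long_ladder))
    cat("  long k sizes:  ", paste(x$long_ladder, collapse = " "), "\n", sep = "")
  cat("  C_min: ", x$c_min, "; insert: ", x$insert, "\n", sep = "")
  cat("  reads retired: ", x$reads_used, " of ", x$reads_total, "\n", sep = "")
  invisible(x)
}

#' @export
plot.conskex_assembly <- function(x, ...) {
  ct <- x$contigs
  if (nrow(ct) == 0L) {
    warning("no contigs to plot")
    return(invisible(NULL))
  }
  len <- sort(ct$length, decreasing = TRUE)
  graphics::plot(seq_along(len), cumsum(len) / sum(len), type = "s",
                 xlab = "contigs (longest first)",
                 ylab = "cumulative fraction of assembly",
                 main = "conskex assembly contiguity", ...)
  graphics::abline(h = 0.5, lty = 2, col = "grey50")
  invisible(x)
}
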