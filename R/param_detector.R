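# Automatic detection of the assembly constants: count thresholds, the k-mer
# ladder, insert size, and the buffer zone for retiring reads.

round_half_up <- function(x) floor(x + 0.5)

# nearest odd integer, ties toward the lower odd
round_odd <- function(x) {
  lo <- 2 * floor((x + 1) / 2) - 1
  hi <- lo + 2
  ifelse(x - lo <= hi - x, lo, hi)
}

#' Minimum k-mer count C_min
#'
#' `max(2, floor(T / (G * 50)))`: in high-coverage read sets more noise
#' k-mers clear any fixed floor, so the floor scales with coverage `T/G`.
#' K-mers below `C_min` are ignored entirely.
#'
#' @param t_bases Total length of (trimmed) reads, T.
#' @param g_kmers Estimated genome size in distinct k-mers, G.
#' @export
compute_cmin <- function(t_bases, g_kmers) {
  if (g_kmers <= 0) stop("genome size estimate must be positive")
  max(2, floor(t_bases / (g_kmers * 50)))
}

#' Desired average k-mer count C_max
#'
#' `max(10, floor(T / (G * 10)))`; the largest usable k-mer size is the one
#' that still achieves this average count.
#'
#' @inheritParams compute_cmin
#' @export
compute_cmax <- function(t_bases, g_kmers) {
  if (g_kmers <= 0) stop("genome size estimate must be positive")
  max(10, floor(t_bases / (g_kmers * 10)))
}

#' Tune the maximal k-mer length K_max
#'
#' Starts at the average mate length and, while the mean count of (above
#' `c_min`) k-mers at the current size falls short of `c_max`, steps down by
#' `A_read/25` bases.  Returns the first size meeting the requirement, or
#' `k_min` (with a warning) if none does.
#'
#' @param store A `conskex_reads` store, used by the default `counts_at`.
#' @param c_min,c_max Count thresholds from [compute_cmin()]/[compute_cmax()].
#' @param k_min Minimal k-mer length.
#' @param a_read Average mate length; defaults to the store's.
#' @param counts_at Function `k -> mean count of k-mers with count >= c_min`;
#'   injectable for testing.
#' @return Integer K_max.
#' @export
tune_kmax <- function(store = NULL, c_min, c_max, k_min = 21L,
                      a_read = NULL, counts_at = NULL) {
  if (is.null(a_read)) a_read <- store_avg_mate(store)
  if (a_read < k_min) stop("average mate length below k_min")
  if (is.null(counts_at)) {
    counts_at <- function(k) {
      seqs <- active_seqs(store, k)
      if (length(seqs) == 0L) return(0)
      tb <- kmer_table(seqs, k, c_min = c_min)
      kt_mean_count(tb$ptr)
    }
  }
  kmax <- as.integer(round_half_up(a_read))
  step <- max(1L, as.integer(floor(a_read / 25)))
  while (kmax >= k_min) {
    if (counts_at(kmax) >= c_max) return(kmax)
    kmax <- kmax - step
  }
  warning("no k-mer size reaches the desired average count; using K_max = k_min")
  as.integer(k_min)
}

#' Choose the k-mer ladder
#'
#' When `k_max` exceeds 1.5 times `k_min`, `steps` sizes are spread evenly
#' from `k_min` to `k_max`, interior values rounded to the nearest odd
#' integer (ties to the lower odd), deduplicated.  Otherwise only `k_min` is
#' used and iterations are disabled (warning).
#'
#' @param k_min,k_max Ladder endpoints.
#' @param steps Number of sizes, S.
#' @return Increasing integer vector of k-mer sizes.
#' @export
choose_ladder <- function(k_min, k_max, steps = 11L) {
  stopifnot(k_min <= k_max, steps >= 2L)
  if (k_max <= 1.5 * k_min) {
    if (k_max > k_min)
      warning("K_max <= 1.5 * K_min; iterations are disabled")
    return(as.integer(k_min))
  }
  i <- seq_len(steps) - 1L
  v <- k_min + round_half_up(i * (k_max - k_min) / (steps - 1L))
  interior <- i > 0L & i < steps - 1L
  v[interior] <- round_odd(v[interior])
  as.integer(sort(unique(v)))
}

#' Estimate the insert size from a read sample
#'
#' A sample of pairs is connected through the `k_min` graph
#' ([connect_pairs()] semantics: unambiguous path between the mate anchor
#' k-mers, verified in both directions); the insert estimate is the median
#' length of the connected fragments, robust to occasional chimeric
#' connections.
#'
#' @param store Paired `conskex_reads` store (trimmed).
#' @param k_min K-mer length for the mini-assemblies.
#' @param c_min Count floor for the graph.
#' @param sample_n Number of pairs to sample (default 10000).
#' @param seed Seed for the pair sample; fixed by default so repeated runs
#'   are identical.
#' @param search_limit Maximal fragment length explored.
#' @param path_cap Path-exploration budget multiplier.
#' @param min_connected Minimum number of connected pairs required.
#' @return Integer insert size I.
#' @export
estimate_insert <- function(store, k_min = 21L, c_min = 2L, sample_n = 10000L,
                            seed = 17L, search_limit = 1200L, path_cap = 100,
                            min_connected = 100L) {
  if (!store$paired) stop("insert size requires paired reads")
  pr <- available_pairs(store, min_len = k_min)
  if (nrow(pr) == 0L) stop("no available pairs with both mates >= k_min")
  set.seed(seed)
  take <- sample.int(nrow(pr), min(sample_n, nrow(pr)))
  m1 <- effective_seq(store, pr[take, 1])
  m2 <- effective_seq(store, pr[take, 2])
  tb <- kmer_table(active_seqs(store, k_min), k_min, c_min = c_min)
  fr <- cpp_connect_pairs(tb$ptr, m1, m2, as.integer(search_limit), path_cap)
  ok <- !is.na(fr)
  if (sum(ok) < min_connected)
    stop("only ", sum(ok), " pairs connected unambiguously; ",
         "provide insert_size explicitly")
  as.integer(round_half_up(stats::median(nchar(fr[ok]))))
}

#' Buffer zone M for retiring reads
#'
#' `M = I + 50 + F`, with flank `F = K_max` when input reads are being
#' retired and `F = 0` for pair-assembled fragments.  Reads whose k-mers all
#' fall within `M` of a contig end stay available: they can still inform
#' junctions and extensions.
#'
#' @param insert Insert size I (0 for unpaired runs).
#' @param flank Flank F.
#' @export
buffer_zone <- function(insert, flank) {
  stopifnot(insert >= 0, flank >= 0)
  insert + 50 + flank
}

# The three post-mate-ladder k sizes: 1.25*K_max, the midpoint of that and I,
# and I itself; odd-rounded, capped at I, deduplicated, and restricted to
# sizes beyond the mate ladder.
long_k_ladder <- function(k_max, insert) {
  v <- c(1.25 * k_max, (1.25 * k_max + insert) / 2, insert)
  v <- round_odd(v)
  v <- pmin(v, insert)
  v <- sort(unique(v[v > k_max]))
  as.integer(v)
}

#' Detect all assembly parameters
#'
#' Runs the full parameter-detection stage on a trimmed read store: the
#' K_min spectrum gives the genome size G (80% of distinct k-mers when no
#' coverage peak stands out), coverage `T/G` gives the count thresholds,
#' k-mer averages tune K_max, and, for paired input, a 10000-pair sample
#' gives the insert size.
#'
#' @param store A trimmed `conskex_reads` store.
#' @param k_min Minimal k-mer length (default 21).
#' @param steps Ladder size S (default 11).
#' @param v_f Suspect-19-mer threshold carried in the parameter set.
#' @param ext_frac Extension noise threshold (default 0.1).
#' @param balance_frac Strand-balance threshold (default 0.25).
#' @param insert_size Insert override; estimated when `NULL` and paired.
#' @param seed Seed for the insert-sample RNG.
#' @param batches Hash partitions for counting.
#' @return An object of class `conskex_params`.
#' @export
detect_params <- function(store, k_min = 21L, steps = 11L, v_f = 0.05,
                          ext_frac = 0.1, balance_frac = 0.25,
                          insert_size = NULL, seed = 17L, batches = 1L) {
  t_bases <- store_total_bases(store)
  a_read <- store_avg_mate(store)
  if (t_bases <= 0) stop("all reads trimmed away; nothing to assemble")

  tb <- kmer_table(store, k_min, c_min = 1L, batches = batches)
  if (kmer_table_size(tb) == 0) stop("no k-mers at k_min; reads too short?")
  spectrum <- kmer_histogram(tb)
  g <- spectrum$genome_size
  c_min <- compute_cmin(t_bases, g)
  c_max <- compute_cmax(t_bases, g)
  k_max <- tune_kmax(store, c_min = c_min, c_max = c_max, k_min = k_min,
                     a_read = a_read)
  ladder <- choose_ladder(k_min, k_max, steps)

  if (store$paired) {
    i_ins <- if (is.null(insert_size))
      estimate_insert(store, k_min = k_min, c_min = c_min, seed = seed)
    else as.integer(insert_size)
    long_k <- long_k_ladder(k_max, i_ins)
    max_insert <- 3L * i_ins
  } else {
    i_ins <- 0L
    long_k <- integer(0)
    max_insert <- 0L
  }

  structure(list(
    k_min = as.integer(k_min), steps = as.integer(steps),
    k_max = as.integer(k_max), ladder = ladder,
    c_min = as.integer(c_min), c_max = as.integer(c_max),
    v_f = v_f, ext_frac = ext_frac, balance_frac = balance_frac,
    insert = i_ins, max_insert = max_insert, long_ladder = long_k,
    buffer_m = buffer_zone(i_ins, k_max),
    genome_size = g, main_peak = spectrum$main_peak,
    t_bases = t_bases, a_read = a_read, seed = as.integer(seed)
  ), class = "conskex_params")
}

#' @export
print.conskex_params <- function(x, ...) {
  cat("<conskex_params> ", jsonlite::toJSON(unclass(x), auto_unbox = TRUE,
                                            digits = 4), "\n", sep = "")
  invisible(x)
}
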