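# Independent oracles and fixture builders.  Everything here is deliberately
# naive (string dictionaries, exhaustive enumeration) and stays independent
# of the package's C++ paths it is used to check.

oracle_revcomp <- function(s) {
  vapply(s, function(x)
    chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = "")),
    character(1), USE.NAMES = FALSE)
}

# naive dictionary k-mer counter with strand attribution
oracle_kmer_counts <- function(seqs, k, c_min = 1) {
  plus <- new.env(parent = emptyenv())
  minus <- new.env(parent = emptyenv())
  bump <- function(e, key) assign(key, (if (exists(key, e)) get(key, e) else 0) + 1, e)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      rc <- oracle_revcomp(w)
      if (w <= rc) bump(plus, w) else bump(minus, rc)
    }
  }
  keys <- sort(unique(c(ls(plus), ls(minus))))
  df <- data.frame(
    kmer = keys,
    plus = vapply(keys, function(k2) if (exists(k2, plus)) get(k2, plus) else 0, numeric(1)),
    minus = vapply(keys, function(k2) if (exists(k2, minus)) get(k2, minus) else 0, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  df[df$plus + df$minus >= c_min, , drop = FALSE]
}

# adjacency of the naive De Bruijn graph: k-mers reachable by one base shift
oracle_successors <- function(kmers_df, kmer) {
  suffix <- substr(kmer, 2, nchar(kmer))
  cand <- paste0(suffix, c("A", "C", "G", "T"))
  canon <- ifelse(cand <= oracle_revcomp(cand), cand, oracle_revcomp(cand))
  present <- canon %in% kmers_df$kmer
  cand[present]
}

# exhaustive path walk: does any path from `start` survive `steps` shifts
# without hitting a dead end?  (forks explored in full)
oracle_walk_survives <- function(kmers_df, start, steps) {
  if (steps == 0) return(TRUE)
  succ <- oracle_successors(kmers_df, start)
  if (length(succ) == 0) return(FALSE)
  any(vapply(succ, function(s) oracle_walk_survives(kmers_df, s, steps - 1),
             logical(1)))
}

# vectorized flavor of the dictionary oracle (same semantics, pure R string
# ops) for larger equivalence runs
oracle_revcomp_vec <- function(x) {
  if (length(x) == 0) return(character(0))
  k <- nchar(x[1])
  m <- matrix(chartr("ACGT", "TGCA", unlist(strsplit(x, ""), use.names = FALSE)),
              nrow = k)
  do.call(paste0, as.data.frame(t(m[k:1, , drop = FALSE]),
                                stringsAsFactors = FALSE))
}

oracle_kmer_counts_fast <- function(seqs, k, c_min = 1) {
  wins <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }))
  wins <- wins[!grepl("[^ACGT]", wins)]
  rc <- oracle_revcomp_vec(wins)
  plus_t <- table(wins[wins <= rc])
  minus_t <- table(rc[wins > rc])
  keys <- sort(unique(c(names(plus_t), names(minus_t))), method = "radix")
  p <- as.integer(plus_t[keys]); p[is.na(p)] <- 0L
  m <- as.integer(minus_t[keys]); m[is.na(m)] <- 0L
  keep <- p + m >= c_min
  data.frame(kmer = keys[keep], plus = p[keep], minus = m[keep],
             stringsAsFactors = FALSE)
}

rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# linear toy genome X-R-Y-R-Z with an exact interior repeat R; Y and Z are
# built to start with different bases so the repeat exit is a genuine fork
toy_repeat_genome <- function(seed = 33, seg = 1200, rep_len = 200) {
  set.seed(seed)
  piece <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  x <- piece(seg); y <- piece(seg); z <- piece(seg); r <- piece(rep_len)
  while (substr(z, 1, 1) == substr(y, 1, 1)) z <- piece(seg)
  list(genome = paste0(x, r, y, r, z), x = x, y = y, z = z, r = r)
}

# error-free paired reads at uniform random positions (FR orientation)
sim_pairs <- function(genome, coverage, mate_len = 150L, insert = 300L,
                      seed = 1L, circular = FALSE) {
  sim <- gen_contamination(genome, coverage = coverage,
                           contaminant_coverage = 0, mate_len = mate_len,
                           insert = insert, circular = circular, seed = seed)
  sim$store
}

# read set with per-window error-free shotgun coverage (single-end)
sim_single <- function(genome, coverage, read_len = 150L, seed = 1L,
                       circular = TRUE) {
  set.seed(seed)
  L <- nchar(genome)
  n <- round(L * coverage / read_len)
  if (circular) {
    gd <- paste0(genome, substr(genome, 1L, read_len - 1L))
    starts <- sample.int(L, n, replace = TRUE)
  } else {
    gd <- genome
    starts <- sample.int(L - read_len + 1L, n, replace = TRUE)
  }
  read_store(substring(gd, starts, starts + read_len - 1L))
}
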