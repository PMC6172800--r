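# Pair connection, read retirement, canonicalization, and full-pipeline
# behavior on small fixtures.

test_that("error-free pairs connect into the exact genomic fragment", {
  g <- rand_seq(6000, 51)
  set.seed(9)
  starts <- sample.int(6000 - 300, 200, TRUE)
  m1 <- substring(g, starts, starts + 149)
  m2 <- revcomp(substring(g, starts + 150, starts + 299))
  tb <- kmer_table(c(m1, m2), 21, c_min = 1)
  fr <- connect_pairs(tb, m1, m2, max_insert = 900)
  expect_true(all(!is.na(fr)))
  expect_equal(fr, substring(g, starts, starts + 299))
})

test_that("a repeat with two genomic resolutions fails connection", {
  toy <- toy_repeat_genome(seed = 21, seg = 500, rep_len = 120)
  st <- gen_substrings(toy$genome, 80, circular = FALSE)
  tb <- kmer_table(st, 21)
  # mate1 ends just before the first repeat copy; mate2 starts inside R,
  # whose k-mers occur at both copies: two valid paths reach the target
  m1 <- substr(toy$genome, 401, 500)                 # inside X
  m2 <- revcomp(substr(toy$r, 21, 120))              # inside R
  fr <- connect_pairs(tb, m1, m2, max_insert = 900)
  expect_true(is.na(fr))
  # a mate pair bridging the repeat into unique sequence connects fine
  m2u <- revcomp(substr(toy$genome, 626, 725))       # inside Y
  fr2 <- connect_pairs(tb, m1, m2u, max_insert = 900)
  expect_false(is.na(fr2))
  expect_equal(fr2, substr(toy$genome, 401, 725))
})

test_that("absent anchors give failure, not an error", {
  tb <- kmer_table(rand_seq(500, 3), 21)
  m1 <- rand_seq(100, 4)     # foreign sequence: anchors not in graph
  m2 <- rand_seq(100, 5)
  expect_true(is.na(connect_pairs(tb, m1, m2, max_insert = 900)))
})

test_that("mark_used retires only reads buried deeper than M", {
  ctg <- rand_seq(4000, 61)
  contigs <- data.frame(seq = ctg, circular = FALSE)
  mid <- substr(ctg, 1800, 1949)        # read deep inside
  edge <- substr(ctg, 50, 199)          # read within M of the left end
  out <- rand_seq(150, 62)              # read not in the contig
  st <- read_store(c(mid, edge, out))
  st2 <- mark_used(st, contigs, k = 21, m = 300)
  expect_equal(st2$used, c(TRUE, FALSE, FALSE))
})

test_that("circular contigs retire any matching read", {
  ctg <- rand_seq(2000, 63)
  contigs <- data.frame(seq = ctg, circular = TRUE)
  edge <- substr(ctg, 1, 150)
  wrap <- paste0(substr(ctg, 1951, 2000), substr(ctg, 1, 100))
  st <- read_store(c(edge, wrap, rand_seq(150, 64)))
  st2 <- mark_used(st, contigs, k = 21, m = 300)
  expect_equal(st2$used, c(TRUE, TRUE, FALSE))
})

test_that("canonical orientation picks the lexicographically smaller start", {
  s <- paste0("TTGA", rand_seq(100, 71))        # revcomp starts with ...
  out <- conskex:::canonicalize_contigs(
    data.frame(seq = s, circular = FALSE), k_orient = 4)
  rc <- revcomp(s)
  keep <- if (substr(rc, 1, 4) < substr(s, 1, 4)) rc else s
  expect_equal(out$seq, keep)
  # idempotent
  expect_identical(conskex:::canonicalize_contigs(out, k_orient = 4), out)
})

test_that("circular canonical rotation is unique across rotations and strands", {
  g <- rand_seq(500, 81)
  rots <- c(13L, 257L, 499L)
  forms <- vapply(rots, function(r) {
    s <- paste0(substr(g, r + 1, 500), substr(g, 1, r))
    if (r %% 2 == 0) s <- revcomp(s)
    conskex:::cpp_canonical_rotation(s, 21L)
  }, character(1))
  expect_equal(length(unique(forms)), 1L)
  expect_identical(conskex:::cpp_canonical_rotation(forms[1], 21L), forms[1])
})

test_that("N50 follows the cumulative-half definition", {
  expect_equal(n50(c(5, 4, 3, 2, 1) * 1000), 4000)
  # brute-force check on random length sets
  set.seed(5)
  for (i in 1:20) {
    lens <- sample.int(5000, sample(1:12, 1))
    tot <- sum(lens)
    cand <- sort(unique(lens), decreasing = TRUE)
    want <- max(cand[vapply(cand, function(L) sum(lens[lens >= L]) >= tot / 2,
                            logical(1))])
    expect_equal(n50(lens), want)
  }
  expect_equal(n50(integer(0)), 0L)
})

test_that("repeats between mate and insert length are resolved by long k-mers", {
  toy <- toy_repeat_genome(seed = 33, seg = 3000, rep_len = 200)
  st <- sim_pairs(toy$genome, coverage = 60, mate_len = 150L, insert = 300L,
                  seed = 14, circular = FALSE)
  full <- assemble(st, min_contig = 300)
  trunc <- assemble(st, long_k = FALSE, min_contig = 300)
  expect_lt(nrow(full$contigs), nrow(trunc$contigs))
  ev <- evaluate_assembly(full, toy$genome, circular = FALSE)
  expect_equal(ev$mismatches, 0)
  expect_equal(ev$misassemblies, 0L)
  # the full pipeline spans a repeat copy: some contig is longer than any
  # single unique segment plus one repeat
  expect_gt(max(full$contigs$length), 3000 + 200)
})

test_that("unpaired input skips the pair-connection stage", {
  g <- rand_seq(3000, 15)
  st <- gen_substrings(g, 60)
  asm <- assemble(st)
  expect_equal(asm$params$insert, 0L)
  expect_length(asm$params$long_ladder, 0L)
  expect_equal(nrow(asm$contigs), 1L)
  expect_true(asm$contigs$circular[1])
})

test_that("assembly output is identical across runs and partition counts", {
  g <- rand_seq(8000, 25)
  sim <- gen_contamination(g, coverage = 50, contaminant_coverage = 9,
                           seed = 5)
  fa <- vapply(list(c(1L, 1L), c(1L, 2L), c(4L, 1L)), function(cfg) {
    asm <- assemble(sim$store, partitions = cfg[1])
    p <- tempfile(fileext = ".fa")
    write_contigs(asm, p)
    paste(readLines(p), collapse = "\n")
  }, character(1))
  expect_identical(fa[1], fa[2])
  expect_identical(fa[1], fa[3])
})

test_that("empty and fully-trimmed stores are hard errors", {
  expect_error(assemble(read_store(character(0))), "empty")
  st <- read_store(rep("ACGTACGTAC", 5))        # shorter than 19: no trim,
  suppressWarnings(
    expect_error(assemble(st), "k_min|k-mers")  # but also no 21-mers
  )
})
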