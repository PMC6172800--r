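# Extension filters, fork resolution against exhaustive enumeration,
# bidirectional verification, and single-iteration assembly invariants.

test_that("count filter keeps the >= boundary and single candidates", {
  expect_equal(filter_by_count(c(A = 100, C = 8)), "A")
  expect_equal(filter_by_count(c(A = 100, C = 10)), c("A", "C"))
  expect_equal(filter_by_count(c(A = 7)), "A")
})

test_that("strand filter drops unbalanced candidates only when a balanced one exists", {
  expect_equal(filter_by_strand(c(A = 30, C = 40), c(A = 28, C = 0)), "A")
  both <- filter_by_strand(c(A = 40, C = 0), c(A = 0, C = 35))
  expect_setequal(both, c("A", "C"))
  both2 <- filter_by_strand(c(A = 30, C = 31), c(A = 28, C = 29))
  expect_setequal(both2, c("A", "C"))
  # 3:1 skew is balanced at balance_frac 0.25; 4:1 is not
  expect_equal(filter_by_strand(c(A = 30, C = 40), c(A = 10, C = 9)), "A")
})

test_that("candidate bases report per-base strand counts and hide used k-mers", {
  # linear graph: one successor
  g <- rand_seq(300, 7)
  st <- gen_substrings(g, 40, circular = FALSE)
  tb <- kmer_table(st, 21)
  kmer <- substr(g, 10, 30)
  cb <- candidate_bases(tb, kmer)
  nxt <- substr(g, 31, 31)
  expect_equal(sum(cb$plus + cb$minus > 0), 1L)
  expect_gt(cb$plus[nxt] + cb$minus[nxt], 0)
  # terminal k-mer: dead end
  tail_k <- substr(g, 280, 300)
  cbt <- candidate_bases(tb, tail_k)
  expect_true(all(cbt$plus + cbt$minus == 0))
  # marking the successor used hides it unless include_used = TRUE
  nxt_kmer <- substr(g, 11, 31)
  conskex:::kt_set_used(tb$ptr, nxt_kmer, TRUE)
  expect_true(all(candidate_bases(tb, kmer)$plus + candidate_bases(tb, kmer)$minus == 0))
  cb2 <- candidate_bases(tb, kmer, include_used = TRUE)
  expect_gt(cb2$plus[nxt] + cb2$minus[nxt], 0)
})

test_that("repeat branch points expose two candidates (X-R-Y-R-Z toy)", {
  toy <- toy_repeat_genome(seed = 12, seg = 400, rep_len = 120)
  st <- gen_substrings(toy$genome, 60, circular = FALSE)
  tb <- kmer_table(st, 21)
  # last k-mer of R: successors are the first bases of Y and Z
  r_end <- substr(toy$r, nchar(toy$r) - 20, nchar(toy$r))
  cb <- candidate_bases(tb, r_end)
  expect_equal(sum(cb$plus + cb$minus > 0), 2L)
  expect_setequal(names(which(cb$plus + cb$minus > 0)),
                  unique(c(substr(toy$y, 1, 1), substr(toy$z, 1, 1))))
})

test_that("fork resolution removes a short error tip, matching enumeration", {
  set.seed(31)
  g <- rand_seq(600, 31)
  # erroneous branch: diverges mid-genome then dead-ends after 5 bases
  fork_at <- 300L
  tip_base <- setdiff(c("A", "C", "G", "T"), substr(g, fork_at + 1, fork_at + 1))[1]
  tip <- paste0(substr(g, fork_at - 20, fork_at), tip_base, rand_seq(4, 99))
  main_reads <- gen_substrings(g, 80, circular = FALSE)$seq
  reads <- c(main_reads, rep(c(tip, oracle_revcomp(tip)), 10))
  tb <- kmer_table(reads, 21)
  before <- substr(g, fork_at - 20, fork_at)
  dec <- extension_decision(tb, before)
  expect_equal(dec$outcome, "unique")
  expect_equal(dec$base, substr(g, fork_at + 1, fork_at + 1))
  # oracle: exhaustively enumerate both branches' survival over 100 steps
  km <- oracle_kmer_counts(reads, 21)
  succ <- oracle_successors(km, before)
  surv <- vapply(succ, oracle_walk_survives, logical(1),
                 kmers_df = km, steps = 100)
  expect_equal(sum(surv), 1L)
  expect_equal(substr(names(which(surv)), 21, 21), dec$base)
})

test_that("two genuine branches of a repeat produce a break", {
  toy <- toy_repeat_genome(seed = 13, seg = 400, rep_len = 120)
  st <- gen_substrings(toy$genome, 60, circular = FALSE)
  tb <- kmer_table(st, 21)
  r_end <- substr(toy$r, nchar(toy$r) - 20, nchar(toy$r))
  dec <- extension_decision(tb, r_end)
  expect_equal(dec$outcome, "break")
  # enumeration agrees: both branches survive the walk
  km <- oracle_kmer_counts(st$seq, 21)
  succ <- oracle_successors(km, r_end)
  surv <- vapply(succ, oracle_walk_survives, logical(1),
                 kmers_df = km, steps = 100)
  expect_equal(sum(surv), 2L)
})

test_that("bidirectional verification stops extension at convergence points", {
  set.seed(41)
  s1 <- rand_seq(200, 42)
  s2 <- rand_seq(200, 43)
  while (substr(s2, 200, 200) == substr(s1, 200, 200))
    s2 <- paste0(substr(s2, 1, 199), sample(c("A", "C", "G", "T"), 1))
  common <- rand_seq(200, 44)
  reads <- c(gen_substrings(paste0(s1, common), 50, circular = FALSE)$seq,
             gen_substrings(paste0(s2, common), 50, circular = FALSE)$seq)
  tb <- kmer_table(reads, 21)
  # the step into the first k-mer fully inside `common`: forward it is
  # unique, but that k-mer has two balanced in-edges (from s1 and s2)
  x <- paste0(substr(s1, 200, 200), substr(common, 1, 20))
  fwd <- extension_decision(tb, x, bidirectional = FALSE)
  expect_equal(fwd$outcome, "unique")
  bid <- extension_decision(tb, x, bidirectional = TRUE)
  expect_equal(bid$outcome, "break")
  # one step earlier the backward extension is still unambiguous
  deep <- substr(s1, 180, 200)
  expect_equal(extension_decision(tb, deep, bidirectional = TRUE)$outcome,
               "unique")
})

test_that("an error-free substrings graph reassembles the genome at one k", {
  g <- rand_seq(4000, 17)
  st <- gen_substrings(g, 60)                  # circular
  tb <- kmer_table(st, 21)
  out <- assemble_iteration(tb, valley = 0)
  expect_equal(nrow(out), 1L)
  expect_true(out$circular[1])
  expect_equal(nchar(out$seq[1]), 4000L)
  ev <- evaluate_assembly(out$seq, g, circular = TRUE)
  expect_equal(ev$mismatches, 0)
  expect_equal(ev$misassemblies, 0L)
})

test_that("no canonical k-mer appears in two contigs of one iteration", {
  toy <- toy_repeat_genome(seed = 77, seg = 500, rep_len = 150)
  st <- gen_substrings(toy$genome, 60, circular = FALSE)
  tb <- kmer_table(st, 21)
  out <- assemble_iteration(tb, valley = 0)
  expect_gt(nrow(out), 1L)
  kmers <- unlist(lapply(out$seq, function(s) {
    df <- oracle_kmer_counts(s, 21)
    df$kmer
  }))
  expect_equal(anyDuplicated(kmers), 0L)
})

test_that("assembling the reverse-complemented read set gives identical output", {
  g <- rand_seq(3000, 23)
  st <- gen_substrings(g, 50, circular = FALSE)
  a <- assemble_iteration(kmer_table(st$seq, 21), valley = 0)
  b <- assemble_iteration(kmer_table(revcomp(st$seq), 21), valley = 0)
  expect_identical(a, b)
})

test_that("the extension threshold separates noise from genuine branches", {
  # two long branches after a shared stem, minority branch at ~8% of the
  # majority: dropped as noise at the default threshold, kept (and hence a
  # break) when the threshold is lowered below its share
  set.seed(67)
  stem <- rand_seq(300, 68)
  a <- rand_seq(300, 69)
  b <- rand_seq(300, 70)
  while (substr(b, 1, 1) == substr(a, 1, 1))
    b <- paste0(sample(c("A", "C", "G", "T"), 1), substr(b, 2, 300))
  # replicate branch-b reads at ~8% of branch-a coverage
  reads_a <- gen_substrings(paste0(stem, a), 60, circular = FALSE)$seq
  reads_b <- gen_substrings(paste0(stem, b), 60, circular = FALSE)$seq
  reads <- c(rep(reads_a, 12), rep(reads_b, 1))
  tb <- kmer_table(reads, 21)
  end_stem <- substr(stem, 280, 300)
  hi <- extension_decision(tb, end_stem, ext_frac = 0.1)
  expect_equal(hi$outcome, "unique")
  expect_equal(hi$base, substr(a, 1, 1))
  tb2 <- kmer_table(reads, 21)
  lo <- extension_decision(tb2, end_stem, ext_frac = 0.05)
  expect_equal(lo$outcome, "break")
})

test_that("a single isolated seed k-mer is dropped after end trimming", {
  reads <- rep("ACGTACGTACGTACGTACGTA", 5)    # one 21-mer, no extension
  tb <- kmer_table(reads, 21)
  out <- assemble_iteration(tb, valley = 0)
  expect_equal(nrow(out), 0L)
})

test_that("seed partitioning does not change the canonical output", {
  toy <- toy_repeat_genome(seed = 3, seg = 600, rep_len = 150)
  st <- gen_substrings(toy$genome, 60, circular = FALSE)
  outs <- lapply(c(1L, 3L, 7L), function(p) {
    tb <- kmer_table(st$seq, 21)
    assemble_iteration(tb, valley = 0, partitions = p)
  })
  expect_identical(outs[[1]], outs[[2]])
  expect_identical(outs[[1]], outs[[3]])
})
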