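# Read-set generators and the seed-and-chain evaluator.

test_that("substrings set alternates strand by start-position parity", {
  st <- gen_substrings("ACGTAC", 3)
  expect_length(st$seq, 6L)               # circular: one read per position
  expect_equal(st$seq[2], "CGT")          # 0-based position 1, forward
  expect_equal(st$seq[1], "CGT")          # position 0: revcomp("ACG")
  stl <- gen_substrings(rand_seq(10, 1), 4, circular = FALSE)
  expect_length(stl$seq, 7L)
})

test_that("circular substrings cover every base exactly K times", {
  g <- rand_seq(200, 6)
  K <- 25L
  st <- gen_substrings(g, K)
  cov <- integer(200)
  for (s in seq_len(200)) {
    idx <- ((s - 1) + 0:(K - 1)) %% 200 + 1
    cov[idx] <- cov[idx] + 1L
  }
  expect_true(all(cov == K))
  expect_equal(sum(nchar(st$seq)), 200L * K)
})

test_that("contamination mates are opposite-strand, insert apart, error-free", {
  g <- rand_seq(3000, 10)
  sim <- gen_contamination(g, coverage = 10, contaminant_coverage = 0,
                           mate_len = 100, insert = 250, circular = FALSE,
                           seed = 2)
  st <- sim$store
  m1 <- st$seq[st$pair_slot == "first"]
  m2 <- st$seq[st$pair_slot == "second"]
  frag <- paste0(m1, "")                     # locate m1 in the genome
  for (i in seq_len(min(20, length(m1)))) {
    p <- regexpr(m1[i], g, fixed = TRUE)[1]
    expect_gt(p, 0)
    expect_equal(revcomp(m2[i]), substr(g, p + 250 - 100, p + 249))
  }
})

test_that("mutation count is binomial around rate * length", {
  g <- rand_seq(100000, 20)
  sim <- gen_contamination(g, coverage = 0.2, contaminant_coverage = 0.2,
                           mutation_rate = 0.001, seed = 8)
  nmut <- length(sim$truth$mutated_positions)
  expect_gt(nmut, 60)
  expect_lt(nmut, 140)
  # mutant genome differs from the reference exactly at the recorded sites
  diff <- which(strsplit(g, "")[[1]] != strsplit(sim$truth$mutant_genome, "")[[1]])
  expect_equal(diff, sim$truth$mutated_positions)
})

test_that("the contaminant genome depends only on seed and rate", {
  g <- rand_seq(20000, 30)
  a <- gen_contamination(g, coverage = 1, contaminant_coverage = 3, seed = 4)
  b <- gen_contamination(g, coverage = 1, contaminant_coverage = 12, seed = 4)
  expect_identical(a$truth$mutant_genome, b$truth$mutant_genome)
})

test_that("evaluating a reference against itself is the zero report", {
  g <- rand_seq(5000, 40)
  ev <- evaluate_assembly(g, g, circular = FALSE)
  expect_equal(ev$mismatches, 0)
  expect_equal(ev$misassemblies, 0L)
  expect_equal(ev$deviation, 0)
  expect_equal(ev$aligned_len, 5000)
})

test_that("deviation follows L_R + L_A - 2 C_RA", {
  g <- rand_seq(10000, 41)
  contig <- substr(g, 1, 9000)
  ev <- evaluate_assembly(contig, g, circular = FALSE)
  expect_equal(ev$deviation, 10000 + 9000 - 2 * 9000)
})

test_that("substitutions are counted and normalized per 100 kb", {
  g <- rand_seq(20000, 42)
  contig <- g
  substr(contig, 5000, 5000) <- if (substr(g, 5000, 5000) == "A") "C" else "A"
  substr(contig, 15000, 15000) <- if (substr(g, 15000, 15000) == "G") "T" else "G"
  ev <- evaluate_assembly(contig, g, circular = FALSE)
  expect_equal(ev$mismatches, 2)
  expect_equal(ev$mismatches_per_100kb, 1e5 * 2 / ev$aligned_len)
  expect_equal(ev$misassemblies, 0L)
})

test_that("large reference gaps and inversions are misassemblies", {
  g <- rand_seq(20000, 43)
  chimera <- paste0(substr(g, 1, 2000), substr(g, 8000, 10000))
  ev <- evaluate_assembly(chimera, g, circular = FALSE)
  expect_gte(ev$misassemblies, 1L)
  inv <- paste0(substr(g, 1, 2000), revcomp(substr(g, 2001, 4000)))
  ev2 <- evaluate_assembly(inv, g, circular = FALSE)
  expect_gte(ev2$misassemblies, 1L)
  # an adjacent, consistent junction is not a misassembly
  ok <- paste0(substr(g, 1, 2000), substr(g, 2001, 4000))
  expect_equal(evaluate_assembly(ok, g, circular = FALSE)$misassemblies, 0L)
})

test_that("wraparound contigs align contiguously on circular references", {
  g <- rand_seq(8000, 44)
  rot <- paste0(substr(g, 4001, 8000), substr(g, 1, 4000))
  ev <- evaluate_assembly(rot, g, circular = TRUE)
  expect_equal(ev$misassemblies, 0L)
  expect_equal(ev$mismatches, 0)
  expect_equal(ev$deviation, 0)
})

test_that("contigs below the evaluator floor are ignored", {
  g <- rand_seq(10000, 45)
  ct <- c(substr(g, 1, 6000), rand_seq(300, 46))   # 300 bp of junk
  ev <- evaluate_assembly(ct, g, circular = FALSE, min_contig = 500)
  expect_equal(ev$mismatches, 0)
  expect_equal(ev$total_len, 6000)
})

test_that("reads and evaluation reports serialize to standard formats", {
  g <- rand_seq(400, 47)
  st <- gen_substrings(g, 50)
  fq <- tempfile(fileext = ".fastq")
  write_reads(st, fq, format = "fastq")
  expect_equal(load_reads(fq)$seq, st$seq)
  ev <- evaluate_assembly(g, g, circular = FALSE)
  j <- tempfile(fileext = ".json")
  write_eval(ev, j)
  expect_equal(jsonlite::read_json(j)$mismatches, 0)
})
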