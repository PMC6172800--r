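# Parameter-detection formulas, ladder construction, K_max tuning and the
# insert-size estimator.

test_that("C_min and C_max follow the coverage-scaled formulas", {
  expect_equal(compute_cmin(1e9, 4e6), 5)
  expect_equal(compute_cmin(1e8, 4e6), 2)     # floor below 1 -> floor of 2
  expect_equal(compute_cmin(4.8e8, 4.8e6), 2)
  expect_equal(compute_cmax(1e9, 4e6), 25)
  expect_equal(compute_cmax(1e7, 4e6), 10)
  expect_equal(compute_cmax(0, 4e6), 10)
  expect_error(compute_cmin(1e9, 0), "positive")
})

test_that("C_min/C_max are monotone in T and G", {
  ts <- c(1e7, 1e8, 1e9)
  gs <- c(1e6, 4e6, 2e7)
  for (g in gs) {
    expect_true(!is.unsorted(vapply(ts, compute_cmin, numeric(1), g_kmers = g)))
    expect_true(!is.unsorted(vapply(ts, compute_cmax, numeric(1), g_kmers = g)))
  }
  for (t in ts) {
    expect_true(!is.unsorted(rev(vapply(gs, function(g) compute_cmin(t, g), numeric(1)))))
  }
})

test_that("choose_ladder spreads odd interior values evenly (golden case)", {
  lad <- choose_ladder(21, 127, 11)
  expect_equal(lad, c(21L, 31L, 41L, 53L, 63L, 73L, 85L, 95L, 105L, 115L, 127L))
  expect_length(lad, 11L)
  expect_true(all(lad[2:10] %% 2 == 1))
  gaps <- diff(lad)
  expect_true(all(abs(gaps - (127 - 21) / 10) <= 2))
})

test_that("ladder collapses to K_min when K_max <= 1.5 K_min", {
  expect_warning(lad <- choose_ladder(21, 31, 11), "disabled")
  expect_equal(lad, 21L)
  expect_equal(choose_ladder(21, 21, 11), 21L)
})

test_that("K_max tuning steps down by A_read/25 until C_max is reached", {
  # injected count function: mean count rises as k shrinks (coverage-like)
  counts_at <- function(k) 75 * (151 - k) / 150
  km <- tune_kmax(c_min = 2, c_max = 10, k_min = 21, a_read = 150,
                  counts_at = counts_at)
  # steps of 6 from 150: means 0.5, 3.5, 6.5, 9.5, 12.5 -> stops at k = 126
  expect_equal(km, 126L)
  # immediate success keeps A_read
  expect_equal(tune_kmax(c_min = 2, c_max = 10, k_min = 21, a_read = 150,
                         counts_at = function(k) 100), 150L)
  # exhaustion falls back to K_min with a warning
  expect_warning(
    km0 <- tune_kmax(c_min = 2, c_max = 10, k_min = 21, a_read = 150,
                     counts_at = function(k) 1),
    "K_max = k_min")
  expect_equal(km0, 21L)
})

test_that("higher coverage gives a larger (or equal) K_max", {
  g <- rand_seq(8000, 55)
  st_hi <- sim_single(g, coverage = 60, seed = 3)
  st_lo <- sim_single(g, coverage = 15, seed = 3)
  km_hi <- tune_kmax(st_hi, c_min = 2, c_max = 10)
  km_lo <- tune_kmax(st_lo, c_min = 2, c_max = 10)
  expect_gte(km_hi, km_lo)
})

test_that("insert estimator recovers the truth within 2% across inserts", {
  g <- rand_seq(20000, 91)
  for (ins in c(200L, 300L, 500L)) {
    st <- sim_pairs(g, coverage = 30, mate_len = 100L, insert = ins,
                    seed = ins, circular = TRUE)
    est <- estimate_insert(st, k_min = 21, c_min = 2, sample_n = 500,
                           seed = 1)
    expect_lt(abs(est - ins) / ins, 0.02, label = paste("insert", ins))
  }
})

test_that("fully-overlapping mates give insert = mate length", {
  g <- rand_seq(8000, 13)
  set.seed(2)
  starts <- sample.int(8000 - 150, 400, TRUE)
  m1 <- substring(g, starts, starts + 149)
  st <- read_store(m1, revcomp(m1))
  est <- estimate_insert(st, sample_n = 400, seed = 1)
  expect_equal(est, 150L)
})

test_that("insert estimation is deterministic for a fixed seed", {
  g <- rand_seq(10000, 19)
  st <- sim_pairs(g, coverage = 30, insert = 300L, seed = 4)
  e1 <- estimate_insert(st, sample_n = 300, seed = 9)
  e2 <- estimate_insert(st, sample_n = 300, seed = 9)
  expect_identical(e1, e2)
})

test_that("estimator demands paired input and enough connections", {
  st <- read_store(c("ACGTACGTACGTACGTACGTACGTA"))
  expect_error(estimate_insert(st), "paired")
  g <- rand_seq(5000, 77)
  stp <- sim_pairs(g, coverage = 2, insert = 300L, seed = 6)
  expect_error(estimate_insert(stp, min_connected = 1e6), "insert_size")
})

test_that("buffer zone is I + 50 + F", {
  expect_equal(buffer_zone(300, 127), 477)
  expect_equal(buffer_zone(300, 0), 350)
  expect_equal(buffer_zone(0, 127), 177)
})

test_that("long k sizes are the three odd-rounded values capped at I", {
  lad <- conskex:::long_k_ladder(126, 300)
  expect_equal(lad, c(157L, 229L, 299L))
  expect_true(all(lad %% 2 == 1))
  expect_true(all(lad <= 300))
  expect_true(all(lad > 126))
})
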