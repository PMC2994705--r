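test_that("random tables are seed-reproducible and seed-distinct", {
  t1 <- random_transition_table("H4", 1)
  t2 <- random_transition_table("H4", 1)
  t3 <- random_transition_table("H4", 2)
  expect_identical(t1$p, t2$p)
  expect_false(identical(t1$p, t3$p))
  expect_true(all(t1$p >= 0 & t1$p <= 1))
  # the ten-dataset protocol yields ten distinct tables
  tabs <- lapply(1:10, function(s) random_transition_table("H4", s)$p)
  expect_identical(length(unique(tabs)), 10L)
  # generation must not disturb the caller's RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(random_transition_table("H2A", 5)); after <- runif(3)
  expect_identical(before, after)
})

test_that("table text round-trip preserves probabilities and validates input", {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  tab <- random_transition_table("H2A", 3)
  write_transition_table(tab, f)
  back <- read_transition_table(f, "H2A")
  expect_equal(back$p, tab$p)

  df <- read.delim(f)
  df$prob[1] <- 1.7
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_transition_table(f, "H2A"), "\\[0, 1\\]")

  df$prob[1] <- 0.5
  write.table(df[-2, ], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_transition_table(f, "H2A"), "missing")
})

test_that("methylation modulation matches the closed forms and clamps", {
  h4 <- enumerate_states("H4")
  tab <- random_transition_table("H4", 1)
  # from all-zero: acetyl-gaining move 00100, methyl-gaining 02000,
  # phospho moves are balance-neutral
  nb <- neighbor_states(h4, "00000")
  tab$p[] <- 0.3
  w0 <- modulate_shift_probabilities(tab, "00000", D = 0)
  expect_equal(unname(w0["00100"]), 0.6)
  expect_equal(unname(w0["02000"]), 0)
  expect_equal(unname(w0["30000"]), 0.3)
  tab$p[] <- 0.6
  w1 <- modulate_shift_probabilities(tab, "00000", D = 1)
  expect_equal(unname(w1["00100"]), 0)       # 0.6 * (2 - 2)
  expect_equal(unname(w1["02000"]), 1)       # clamp(0.6 * 2)
  # removing a methyl mark is an acetyl-directed move
  w2 <- modulate_shift_probabilities(tab, "02000", D = 0)
  expect_equal(unname(w2["00000"]), 1)       # clamp(0.6 * 2)
  expect_error(modulate_shift_probabilities(tab, "00000", D = -0.1), "\\[0, 1\\]")
})

test_that("modulation is the identity at D = k for every H4 state", {
  h4 <- enumerate_states("H4")
  tab <- random_transition_table("H4", 8)
  for (i in seq_len(h4$n)) {
    w <- modulate_shift_probabilities(tab, i, D = 0.5, k = 0.5)
    expect_equal(unname(w), tab$p[(h4$ptr[i] + 1):h4$ptr[i + 1]])
  }
})

test_that("modulated weights stay in [0,1] and are monotone in D", {
  h4 <- enumerate_states("H4")
  tab <- random_transition_table("H4", 13)
  grid <- seq(0, 1, by = 0.1)
  set.seed(4)
  for (i in sample.int(h4$n, 10L)) {
    nb <- h4$adj[[i]]
    d <- h4$bal[nb] - h4$bal[i]
    ws <- sapply(grid, function(D) modulate_shift_probabilities(tab, i, D))
    expect_true(all(ws >= 0 & ws <= 1))
    for (j in seq_along(nb)) {
      diffs <- diff(ws[j, ])
      if (d[j] > 0) expect_true(all(diffs <= 1e-12))      # acetyl-directed
      else if (d[j] < 0) expect_true(all(diffs >= -1e-12)) # methyl-directed
      else expect_true(all(abs(diffs) < 1e-12))
    }
  }
})

test_that("modulation is a no-op for histone types unaffected by methylation", {
  h2a <- enumerate_states("H2A")
  tab <- random_transition_table("H2A", 2)
  w <- modulate_shift_probabilities(tab, "0000", D = 0.05)
  expect_equal(unname(w), tab$p[(h2a$ptr[1] + 1):h2a$ptr[2]])
})

test_that("categorical sampling honours weights, stalls, and rejects negatives", {
  h4 <- enumerate_states("H4")
  nb <- neighbor_states(h4, "00000", codes = FALSE)
  w <- rep(0, length(nb)); w[3] <- 1
  set.seed(1)
  expect_identical(sample_next_state(h4, "00000", weights = w), nb[3])
  expect_identical(sample_next_state(h4, "00000", weights = rep(0, 6)),
                   state_index(h4, "00000"))
  expect_error(sample_next_state(h4, "00000", weights = c(-1, rep(1, 5))),
               "nonnegative")
  expect_error(sample_next_state(h4, "00000", weights = rep(1, 3)), "align")
})

test_that("equal-weight sampling matches the uniform law at 60000 draws", {
  h4 <- enumerate_states("H4")
  nb <- neighbor_states(h4, "00000", codes = FALSE)
  set.seed(2024)
  draws <- replicate(60000, sample_next_state(h4, 1L, weights = rep(1, 6)))
  counts <- tabulate(match(draws, nb), nbins = 6)
  expect_identical(sum(counts), 60000L)
  p <- chisq.test(counts, p = rep(1 / 6, 6))$p.value
  expect_gt(p, 0.001)
})

test_that("sampled transition sequences are reproducible under a fixed seed", {
  h4 <- enumerate_states("H4")
  tab <- random_transition_table("H4", 5)
  walk <- function() {
    s <- 1L
    vapply(1:200, function(i) {
      s <<- sample_next_state(h4, s, table = tab, D = 0.3)
      s
    }, integer(1))
  }
  set.seed(31); w1 <- walk()
  set.seed(31); w2 <- walk()
  expect_identical(w1, w2)
})

test_that("most probable path equals exhaustive search on toy subgraphs", {
  # 8-state subgraph of the H2A hypercube, several random weightings
  h2a <- enumerate_states("H2A")
  keep <- vapply(c("0000", "3000", "0200", "0010", "3200", "3010", "0210",
                   "3210"), function(cd) state_index(h2a, cd), integer(1))
  for (seed in 1:5) {
    tab <- toy_table("H2A", keep, seed = seed)
    src <- keep[[1]]; dst <- keep[[8]]
    got <- most_probable_path(tab, src, dst)
    want <- bf_best_path("H2A", tab, src, dst)
    expect_equal(got$prob, want$prob, tolerance = 1e-12)
    expect_identical(got$path, want$path)
  }
  # 4-state chain with hand-set probabilities: direct hop loses to detour
  chain <- vapply(c("0000", "0010", "3000", "3010"),
                  function(cd) state_index(h2a, cd), integer(1))
  tab <- toy_table("H2A", chain, seed = 1)
  tab$p[] <- 0
  edge <- function(a, b) which(
    rep(seq_len(h2a$n), diff(h2a$ptr)) == chain[[a]] & h2a$nbr == chain[[b]])
  tab$p[edge(1, 2)] <- 0.1          # 0000 -> 0010 direct
  tab$p[edge(1, 3)] <- 0.9          # 0000 -> 3000
  tab$p[edge(3, 4)] <- 0.9          # 3000 -> 3010
  tab$p[edge(4, 2)] <- 0.9          # 3010 -> 0010
  got <- most_probable_path(tab, "0000", "0010")
  expect_equal(got$codes, c("0000", "3000", "3010", "0010"))
  expect_equal(got$prob, 0.9^3)
})

test_that("path queries handle identity and unreachable targets", {
  tab <- random_transition_table("H2A", 9)
  same <- most_probable_path(tab, "0000", "0000")
  expect_true(same$found)
  expect_identical(same$codes, "0000")
  expect_equal(same$prob, 1)
  tab$p[] <- 0
  none <- most_probable_path(tab, "0000", "3210")
  expect_false(none$found)
  expect_equal(none$prob, 0)
})
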