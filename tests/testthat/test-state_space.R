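test_that("state-space sizes match the catalogue for all five types", {
  expected <- c(H1 = 1L, H2A = 16L, H2B = 1536L, H3 = 6300L, H4 = 48L)
  for (type in names(expected)) {
    expect_identical(enumerate_states(type)$n, expected[[type]],
                     label = paste(type, "count"))
  }
  # the compressed H3 space factorises as 5*5*3*3 free positions times the
  # number of (met, ace) lysine pairs with met + ace <= 6
  pairs <- sum(outer(0:6, 0:6, `+`) <= 6L)
  expect_identical(pairs, 28L)
  expect_identical(5L * 5L * 3L * 3L * pairs, 6300L)
  expect_error(enumerate_states("H5"))
})

test_that("adjacency is symmetric and every state is reachable from all-zero", {
  for (type in c("H2A", "H2B", "H3", "H4")) {
    sp <- enumerate_states(type)
    from <- rep(seq_len(sp$n), diff(sp$ptr))
    key <- paste(from, sp$nbr)
    rev_key <- paste(sp$nbr, from)
    expect_true(all(rev_key %in% key), label = paste(type, "symmetry"))
    expect_false(any(from == sp$nbr), label = paste(type, "no self-loops"))
    expect_true(all(bfs_reachable(sp)), label = paste(type, "connectivity"))
  }
})

test_that("index/code round-trips are the identity", {
  for (type in c("H2A", "H4")) {
    sp <- enumerate_states(type)
    idx <- vapply(seq_len(sp$n), function(i) state_index(sp, state_code(sp, i)),
                  integer(1))
    expect_identical(idx, seq_len(sp$n))
  }
  for (type in c("H2B", "H3")) {
    sp <- enumerate_states(type)
    set.seed(7)
    pick <- sample.int(sp$n, 300L)
    idx <- vapply(pick, function(i) state_index(sp, state_code(sp, i)),
                  integer(1))
    expect_identical(idx, pick)
  }
})

test_that("neighbour sets follow the one-change rule", {
  h4 <- enumerate_states("H4")
  expect_setequal(neighbor_states(h4, "00000"),
                  c("30000", "02000", "00100", "00010", "00001", "00002"))
  h2a <- enumerate_states("H2A")
  expect_length(neighbor_states(h2a, "0000"), 4L)
  h3 <- enumerate_states("H3")
  # pos5 at its joint maximum blocks the pos6 increment
  expect_setequal(neighbor_states(h3, "000060"),
                  c("100060", "010060", "001060", "000160", "000050"))
  expect_error(neighbor_states(h4, "00003"), "invalid")
})

test_that("every neighbour differs by exactly one legal move", {
  one_move <- function(sp, i, j, compressed) {
    d <- sp$codes[i, ] - sp$codes[j, ]
    nz <- which(d != 0L)
    if (length(nz) != 1L) return(FALSE)
    if (compressed) abs(d[nz]) == 1L
    else sp$codes[i, nz] == 0L || sp$codes[j, nz] == 0L
  }
  for (type in c("H2A", "H4")) {
    sp <- enumerate_states(type)
    for (i in seq_len(sp$n)) {
      for (j in sp$adj[[i]]) expect_true(one_move(sp, i, j, FALSE))
    }
  }
  set.seed(11)
  for (type in c("H2B", "H3")) {
    sp <- enumerate_states(type)
    compressed <- sp$kind == "compressed"
    for (i in sample.int(sp$n, 50L)) {
      for (j in sp$adj[[i]]) expect_true(one_move(sp, i, j, compressed))
    }
  }
})

test_that("balance classification takes a strict acetyl/methyl majority", {
  h4 <- enumerate_states("H4")
  expect_identical(classify_balance(h4, "00000"), "neutral")
  expect_identical(classify_balance(h4, "00111"), "acetyl")
  expect_identical(classify_balance(h4, "02002"), "methyl")
  expect_identical(classify_balance(h4, "02001"), "neutral")  # 1 vs 1 tie
  h3 <- enumerate_states("H3")
  expect_identical(classify_balance(h3, "000006"), "acetyl")
  expect_identical(classify_balance(h3, "400000"), "methyl")
  expect_identical(classify_balance(h3, "042000"), "neutral") # phospho only
})

test_that("modification counts respect kind and multiplicity", {
  h4 <- enumerate_states("H4")
  expect_identical(modification_counts(h4, "00000"),
                   c(ace = 0L, met = 0L, ph = 0L))
  expect_identical(modification_counts(h4, "30000"),
                   c(ace = 0L, met = 0L, ph = 1L))
  # tri-acetylation of K12 counts three marks without changing identity
  expect_identical(modification_counts(h4, "00001",
                                       multiplicity = c(1, 1, 1, 1, 3)),
                   c(ace = 3L, met = 0L, ph = 0L))
  expect_error(modification_counts(h4, "00001",
                                   multiplicity = c(1, 1, 1, 1, 4)))
  h3 <- enumerate_states("H3")
  expect_identical(modification_counts(h3, "210242"),
                   c(ace = 2L, met = 8L, ph = 1L))
})

test_that("state-space dump writes one validated row per state", {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  write_state_space(enumerate_states("H4"), f)
  df <- read.delim(f, colClasses = c(code = "character"))
  expect_identical(nrow(df), 48L)
  expect_identical(df$code[11], "00111")
  expect_true(all(df$ace + df$met + df$ph <= 5L))
})
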