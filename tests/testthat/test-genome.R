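test_that("the default genome wires 64 blocks under 16 promoters", {
  cfg <- simulation_config()
  g <- build_genome(cfg)
  expect_identical(nrow(g$blocks), 64L)
  expect_identical(sum(g$blocks$type == "promoter"), 16L)
  # every gene points at the promoter immediately controlling it
  genes <- g$blocks$type == "gene"
  expect_true(all(g$blocks$promoter[genes] > 0))
  expect_true(all(g$blocks$type[g$blocks$promoter[genes]] == "promoter"))
  # one nucleosome carries the nine-histone complement
  expect_identical(length(g$slots), 9L)
  counts <- table(g$slot_type)
  expect_identical(as.integer(counts[c("H1", "H2A", "H2B", "H3", "H4")]),
                   c(1L, 2L, 2L, 2L, 2L))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(iterations = 0), "positive")
  expect_error(simulation_config(iterations = 100, record_every = 33),
               "divide")
  expect_error(simulation_config(layout = c("gene", "promoter")), "before")
  expect_error(simulation_config(layout = "nonsense"), "layout")
  expect_error(simulation_config(D0 = 1.3), "\\[0, 1\\]")
  expect_error(simulation_config(pinned = TRUE), "D0")
  expect_error(simulation_config(tables = list(H4.1 = random_transition_table(
    "H2A", 1))), "type")
})

test_that("one time-step makes at most one change per histone", {
  set.seed(5)
  g <- build_genome(tiny_config())
  g1 <- step_genome(g, 1)
  for (s in seq_along(g1$slots)) {
    sp <- enumerate_states(g1$slot_type[s])
    for (b in seq_len(nrow(g1$blocks))) {
      nmods <- sum(sp$codes[g1$state[s, b], ] != 0)
      expect_lte(nmods, 1L)
    }
  }
  expect_identical(g1$steps_done, 1L)
})

test_that("H1 never leaves its single empty state", {
  set.seed(6)
  g <- step_genome(build_genome(tiny_config()), 200)
  h1 <- which(g$slot_type == "H1")
  expect_true(all(g$state[h1, ] == 1L))
  expect_identical(sum(g$visits[[h1]]), 200L * nrow(g$blocks))
})

test_that("visit counts are conserved and runs are schedule-shaped", {
  cfg <- tiny_config(iterations = 500, record_every = 25, seed = 9)
  sim <- run_simulation(cfg)
  expect_identical(nrow(sim$D_trace), 20L)    # 500 / 25 records
  expect_identical(nrow(sim$T_trace), 20L)
  for (s in seq_along(sim$slots)) {
    expect_true(all(colSums(sim$visits[[s]]) == 500L))
  }
  expect_true(all(sim$D_trace >= 0 & sim$D_trace <= 1))
  expect_true(all(sim$T_trace >= 0 & sim$T_trace <= 1))
})

test_that("fixed-seed runs are byte-identical", {
  cfg <- tiny_config(iterations = 300, record_every = 25, seed = 77)
  expect_identical(run_simulation(cfg), run_simulation(cfg))
})

test_that("pinned methylation never moves", {
  cfg <- tiny_config(iterations = 200, record_every = 25, seed = 3,
                     D0 = c(0.1, 0.9, 0.5, 0.5), pinned = TRUE)
  sim <- run_simulation(cfg)
  expect_true(all(sim$D_trace[, 1] == 0.1))
  expect_true(all(sim$D_trace[, 2] == 0.9))
  expect_identical(sim$final_D, c(0.1, 0.9, 0.5, 0.5))
})

test_that("user tables are honoured and flagged in the run seeds", {
  tab <- random_transition_table("H4", 123)
  cfg <- tiny_config(iterations = 100, record_every = 25, seed = 2,
                     tables = list(H4.1 = tab))
  sim <- run_simulation(cfg)
  expect_identical(sim$table_seeds[["H4.1"]], 123L)
  expect_false(sim$table_seeds[["H4.2"]] == 123L)
})

test_that("equal-weight H2A occupancy is near uniform on the hypercube", {
  h2a <- enumerate_states("H2A")
  tab <- random_transition_table("H2A", 1)
  tab$p[] <- 0.5
  cfg <- simulation_config(layout = "promoter", iterations = 20000,
                           record_every = 20000, seed = 10,
                           tables = list(H2A.1 = tab, H2A.2 = tab))
  sim <- run_simulation(cfg)
  occ <- occupancy_statistics(sim, "H2A", blocks = "promoter")
  expect_equal(sum(occ$mean_pct), 100)
  # equal weights on a regular bipartite graph give a uniform stationary law
  expect_true(all(occ$mean_pct > 3 & occ$mean_pct < 11))
})

test_that("run records serialise to a complete text directory", {
  dir <- tempfile("runrec")
  on.exit(unlink(dir, recursive = TRUE))
  sim <- run_simulation(tiny_config(iterations = 100, record_every = 25))
  write_run_record(sim, dir)
  files <- list.files(dir)
  expect_true(all(c("methylation.tsv", "transcription.tsv",
                    "global_levels.tsv", "visits_H4.tsv",
                    "manifest.yaml") %in% files))
  meth <- read.delim(file.path(dir, "methylation.tsv"))
  expect_identical(nrow(meth), 4L * nrow(sim$blocks))
  vis <- read.delim(file.path(dir, "visits_H4.tsv"))
  expect_identical(nrow(vis), 48L)
  expect_equal(sum(vis[, -(1:2)]), 100 * 2 * nrow(sim$blocks))
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_identical(man$iterations, 100L)
})
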