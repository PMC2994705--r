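# shared fixtures: tiny configs, toy tables, and independent oracles

tiny_config <- function(iterations = 100, record_every = 25, seed = 42, ...) {
  simulation_config(layout = default_layout(2, 1), iterations = iterations,
                    record_every = record_every, seed = seed, ...)
}

# restrict a table to a subgraph: zero every edge not inside `keep`
toy_table <- function(type, keep, seed = 1) {
  space <- enumerate_states(type)
  tab <- random_transition_table(type, seed)
  from <- rep(seq_len(space$n), diff(space$ptr))
  tab$p[!(from %in% keep & space$nbr %in% keep)] <- 0
  tab
}

# independent oracle: exhaustive max-product search over all simple paths
bf_best_path <- function(type, tab, src, dst) {
  space <- enumerate_states(type)
  best <- list(prob = 0, path = integer(0))
  if (src == dst) return(list(prob = 1, path = src))
  rec <- function(path, prob) {
    u <- path[length(path)]
    nb <- space$adj[[u]]
    p <- tab$p[(space$ptr[u] + 1L):space$ptr[u + 1L]]
    for (j in seq_along(nb)) {
      v <- nb[j]
      if (p[j] <= 0 || v %in% path) next
      pr <- prob * p[j]
      if (v == dst) {
        if (pr > best$prob) best <<- list(prob = pr, path = c(path, v))
      } else {
        rec(c(path, v), pr)
      }
    }
  }
  rec(src, 1)
  best
}

# minimal run-record stand-in carrying only what occupancy summaries read
fake_sim <- function(visits_by_slot, slot_type, block_types) {
  structure(list(
    blocks = data.frame(id = seq_along(block_types), type = block_types,
                        stringsAsFactors = FALSE),
    slot_type = slot_type, visits = visits_by_slot
  ), class = "chromatin_sim")
}

# breadth-first reachability over a state space's neighbour graph
bfs_reachable <- function(space, from = 1L) {
  seen <- logical(space$n)
  seen[from] <- TRUE
  queue <- from
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    nb <- space$adj[[u]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  seen
}
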