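## Shift-probability tables and neighbour-shift dynamics
##
## A transition table stores, for every ordered pair of neighbouring states
## (a, b), the base probability of a shift a -> b in one time-step.  For H3
## and H4 the block's DNA-methylation level modulates these weights each step
## before one move is sampled.

## run code with a private, seeded RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.new_transition_table <- function(space, p, provenance, seed = NA_integer_) {
  stopifnot(length(p) == length(space$nbr))
  if (any(p < 0 | p > 1 | is.na(p)))
    stop("shift probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(type = space$type, p = p, provenance = provenance,
                 seed = seed, n = space$n),
            class = "transition_table")
}

#' Generate a seeded random shift-probability table
#'
#' Draws one independent uniform \[0, 1\] probability for every ordered pair
#' of neighbouring states of the given histone type.  The draw is fully
#' reproducible from the seed (R's default Mersenne-Twister stream) and does
#' not disturb the caller's RNG state.
#'
#' @param type Histone type name.
#' @param seed Integer seed.
#' @return A `transition_table`.
#' @examples
#' tab <- random_transition_table("H4", seed = 1)
#' identical(tab$p, random_transition_table("H4", 1)$p)  # TRUE
#' @export
random_transition_table <- function(type, seed) {
  space <- enumerate_states(type)
  p <- .with_seed(seed, stats::runif(length(space$nbr)))
  .new_transition_table(space, p, "random", as.integer(seed))
}

#' Transition-table text serialisation
#'
#' Tables are exchanged as delimited text with one row per directed edge:
#' source state index, neighbour state index, probability.  Loading validates
#' that every probability lies in \[0, 1\] and that every row names an
#' adjacent pair; every adjacent pair must be present.
#'
#' @param table A `transition_table`.
#' @param file Path.
#' @param type Histone type the stored table refers to.
#' @return `write_transition_table()`: the path, invisibly;
#'   `read_transition_table()`: a `transition_table`.
#' @export
write_transition_table <- function(table, file) {
  space <- enumerate_states(table$type)
  from <- rep(seq_len(space$n), diff(space$ptr))
  df <- data.frame(from = from, to = space$nbr, prob = table$p)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_transition_table
#' @export
read_transition_table <- function(file, type) {
  space <- enumerate_states(type)
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("from", "to", "prob")
  if (!all(need %in% names(df)))
    stop("transition table file must have columns from, to, prob", call. = FALSE)
  if (any(df$prob < 0 | df$prob > 1 | is.na(df$prob)))
    stop("shift probabilities must lie in [0, 1]", call. = FALSE)
  key <- paste(rep(seq_len(space$n), diff(space$ptr)), space$nbr)
  got <- paste(df$from, df$to)
  if (anyDuplicated(got)) stop("duplicate edges in transition table", call. = FALSE)
  pos <- match(key, got)
  if (anyNA(pos))
    stop("transition table is missing entries for some adjacent pairs", call. = FALSE)
  if (length(got) != length(key))
    stop("transition table contains non-adjacent pairs", call. = FALSE)
  .new_transition_table(space, df$prob[pos], "user")
}

## per-edge base probabilities out of state i
.edge_probs <- function(space, table, i) {
  if (space$ptr[i] == space$ptr[i + 1L]) return(numeric(0))
  table$p[(space$ptr[i] + 1L):space$ptr[i + 1L]]
}

#' Methylation-modulated shift weights
#'
#' Modulates the base shift probabilities out of `state` by the block's
#' DNA-methylation level `D`.  Each candidate move is classified by the
#' change in the acetyl-minus-methyl balance between the current state and
#' the neighbour: moves that raise the balance (gain acetylation / shed
#' methylation) are scaled by `2 - D/k`, moves that lower it by `D/k`, and
#' balance-neutral moves are untouched; results are clamped to \[0, 1\].  At
#' `D = k` the modulation is the identity.  Only H3 and H4 respond to
#' methylation; for other types the base probabilities are returned
#' unchanged (a documented no-op).
#'
#' @param table A `transition_table`.
#' @param state Current state (index, code string or code vector).
#' @param D DNA-methylation level in \[0, 1\].
#' @param k Mean-methylation scaling factor in (0, 1], default 0.5.
#' @return Numeric vector of weights in \[0, 1\], named by neighbour code,
#'   aligned with `neighbor_states()`.
#' @export
modulate_shift_probabilities <- function(table, state, D, k = 0.5) {
  if (!is.numeric(D) || length(D) != 1L || is.na(D) || D < 0 || D > 1)
    stop("D must be a single value in [0, 1]", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k > 1)
    stop("k must lie in (0, 1]", call. = FALSE)
  space <- enumerate_states(table$type)
  i <- .resolve_state(space, state)
  nb <- space$adj[[i]]
  p <- .edge_probs(space, table, i)
  if (table$type %in% c("H3", "H4")) {
    d <- space$bal[nb] - space$bal[i]
    fac <- ifelse(d > 0L, 2 - D / k, ifelse(d < 0L, D / k, 1))
    p <- pmin(pmax(p * fac, 0), 1)
  }
  names(p) <- space$code[nb]
  p
}

#' Sample the next state of a one-change-per-step shift
#'
#' Draws one neighbour with probability proportional to its weight
#' (categorical draw over the weight vector).  If every weight is zero the
#' chain stalls and the input state is returned unchanged.
#'
#' @param space A `histone_space`.
#' @param state Current state.
#' @param weights Nonnegative weights aligned with `neighbor_states()`; by
#'   default taken from `table`, modulated by `D` when given.
#' @param table Optional `transition_table` used when `weights` is missing.
#' @param D,k Optional methylation level and scaling factor for modulation.
#' @return The next state's integer index.
#' @export
sample_next_state <- function(space, state, weights = NULL, table = NULL,
                              D = NULL, k = 0.5) {
  i <- .resolve_state(space, state)
  nb <- space$adj[[i]]
  if (is.null(weights)) {
    if (is.null(table)) stop("supply weights or a transition table", call. = FALSE)
    weights <- if (is.null(D)) .edge_probs(space, table, i)
               else unname(modulate_shift_probabilities(table, i, D, k))
  }
  if (length(weights) != length(nb))
    stop("weights must align with the neighbour list", call. = FALSE)
  if (any(weights < 0 | is.na(weights)))
    stop("weights must be nonnegative", call. = FALSE)
  tot <- sum(weights)
  if (tot == 0) return(i)
  nb[sample.int(length(nb), 1L, prob = weights)]
}

#' Most probable path between two histone states
#'
#' Finds the path from `source` to `target` maximising the product of base
#' shift probabilities along its edges, by Dijkstra shortest path under edge
#' weight `-log(p)`.  Zero-probability edges are excluded; when the target is
#' unreachable through positive-probability edges the result flags "no
#' path".  Distance ties resolve toward lexicographically smaller state
#' indices.
#'
#' @param table A `transition_table`.
#' @param source,target States (index, code string or code vector).
#' @return A list of class `chromsim_path`: `found`, `path` (state indices),
#'   `codes`, `prob` (product of edge probabilities; 1 when source equals
#'   target, 0 when no path exists).
#' @export
most_probable_path <- function(table, source, target) {
  space <- enumerate_states(table$type)
  src <- .resolve_state(space, source)
  dst <- .resolve_state(space, target)
  if (src == dst) {
    return(structure(list(found = TRUE, path = src,
                          codes = space$code[src], prob = 1),
                     class = "chromsim_path"))
  }
  n <- space$n
  dist <- rep(Inf, n); dist[src] <- 0
  prev <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  repeat {
    dist_active <- ifelse(done, Inf, dist)
    u <- which.min(dist_active)           # ties -> smallest index
    if (!is.finite(dist_active[u])) break
    done[u] <- TRUE
    if (u == dst) break
    nb <- space$adj[[u]]
    p <- .edge_probs(space, table, u)
    keep <- p > 0 & !done[nb]
    for (j in which(keep)) {
      alt <- dist[u] - log(p[j])
      v <- nb[j]
      if (alt < dist[v]) { dist[v] <- alt; prev[v] <- u }
    }
  }
  if (!is.finite(dist[dst])) {
    return(structure(list(found = FALSE, path = integer(0),
                          codes = character(0), prob = 0),
                     class = "chromsim_path"))
  }
  path <- dst
  while (!is.na(prev[path[1L]])) path <- c(prev[path[1L]], path)
  structure(list(found = TRUE, path = path, codes = space$code[path],
                 prob = exp(-dist[dst])),
            class = "chromsim_path")
}

#' @export
print.chromsim_path <- function(x, ...) {
  if (!x$found) {
    cat("No positive-probability path.\n")
  } else {
    cat("Most probable path (", length(x$path), " states, probability ",
        format(x$prob, digits = 6), "):\n  ", paste(x$codes, collapse = " -> "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.transition_table <- function(x, ...) {
  cat("Shift-probability table:", x$type, "-", length(x$p), "directed edges\n")
  cat("  provenance:", x$provenance,
      if (!is.na(x$seed)) paste0("(seed ", x$seed, ")"), "\n")
  invisible(x)
}
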