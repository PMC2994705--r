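## Genome assembly and the simulation loop
##
## A genome is a chain of blocks (promoter / gene / intron / isolator /
## silencer); every block holds nucleosomes of nine histones (2 x H2A, 2 x
## H2B, 2 x H3, 2 x H4, 1 x H1), a DNA-methylation level and a transcription
## trace.  Each histone copy (H4.1, H4.2, ...) has its own shift-probability
## table, shared across blocks.

.block_types <- c("promoter", "gene", "intron", "isolator", "silencer")
.copy_names <- c("H2A.1", "H2A.2", "H2B.1", "H2B.2", "H3.1", "H3.2",
                 "H4.1", "H4.2", "H1")
.copy_types <- c("H2A", "H2A", "H2B", "H2B", "H3", "H3", "H4", "H4", "H1")

#' Default promoter/gene block layout
#'
#' @param n_promoters Number of promoters (default 16).
#' @param genes_per_promoter Gene blocks following each promoter (default 3,
#'   giving the default 64-block genome).
#' @return Character vector of block types.
#' @export
default_layout <- function(n_promoters = 16, genes_per_promoter = 3) {
  rep(c("promoter", rep("gene", genes_per_promoter)), n_promoters)
}

#' Simulation configuration
#'
#' Collects and validates everything a run needs: the block layout,
#' nucleosome count, iteration and recording schedule, transcription and
#' methylation parameters, shift-probability tables (or the seed they are
#' generated from) and the optional pinned-methylation mode used for regime
#' experiments.
#'
#' @param layout Block-type vector (default `default_layout()`: 16 promoters
#'   each followed by 3 genes, 64 blocks).
#' @param nucleosomes Nucleosomes per block (default 1).
#' @param iterations Total time-steps (default 5000).
#' @param record_every Recording interval for methylation and global levels
#'   (default 25; must divide `iterations`).
#' @param interval Time-steps per transcription interval (1, 5, 25 or 100).
#' @param P_T,kappa,blocking_threshold See [transcription_params()].
#' @param k Mean-methylation scaling factor of the shift modulation.
#' @param gate_fraction Methylation-update gate fraction (default 0.05).
#' @param D0 Optional initial DNA-methylation: a single value or one per
#'   block; when `NULL` each block starts at the histone-derived anchor.
#' @param pinned If `TRUE`, methylation levels are held fixed at `D0`
#'   (the conditional update is skipped) - the regime-experiment mode.
#' @param tables Optional named list of `transition_table`s keyed by histone
#'   copy (`"H2A.1"`, ..., `"H4.2"`); missing entries are generated from
#'   seeds derived from `seed`.
#' @param seed Master seed for table generation and the run (default 1).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(layout = default_layout(), nucleosomes = 1,
                              iterations = 5000, record_every = 25,
                              interval = 25, P_T = 0.5, kappa = log(2),
                              blocking_threshold = 0.75, k = 0.5,
                              gate_fraction = 0.05, D0 = NULL, pinned = FALSE,
                              tables = NULL, seed = 1) {
  if (length(layout) == 0L || !all(layout %in% .block_types))
    stop("layout entries must be one of: ",
         paste(.block_types, collapse = ", "), call. = FALSE)
  if (iterations < 1) stop("iterations must be positive", call. = FALSE)
  if (record_every < 1 || iterations %% record_every != 0)
    stop("record_every must divide iterations", call. = FALSE)
  tp <- transcription_params(P_T, interval, kappa, blocking_threshold)
  if (k <= 0 || k > 1) stop("k must lie in (0, 1]", call. = FALSE)
  if (gate_fraction < 0 || gate_fraction > 1)
    stop("gate_fraction must lie in [0, 1]", call. = FALSE)
  if (nucleosomes < 1) stop("nucleosomes must be positive", call. = FALSE)
  B <- length(layout)
  if (!is.null(D0)) {
    if (!length(D0) %in% c(1L, B))
      stop("D0 must be a single value or one per block", call. = FALSE)
    if (any(D0 < 0 | D0 > 1))
      stop("initial methylation values must lie in [0, 1]", call. = FALSE)
    D0 <- rep_len(as.numeric(D0), B)
  }
  if (isTRUE(pinned) && is.null(D0))
    stop("pinned mode needs user methylation values D0", call. = FALSE)
  ## every gene needs a controlling promoter upstream
  promoter_of <- integer(B)
  last_prom <- 0L
  for (b in seq_len(B)) {
    if (layout[b] == "promoter") last_prom <- b
    if (layout[b] == "gene") {
      if (last_prom == 0L)
        stop("layout places a gene before any promoter", call. = FALSE)
      promoter_of[b] <- last_prom
    }
  }
  if (!is.null(tables)) {
    bad <- setdiff(names(tables), .copy_names)
    if (length(bad)) stop("unknown table keys: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    for (nm in names(tables)) {
      if (!inherits(tables[[nm]], "transition_table") ||
          tables[[nm]]$type != .copy_types[match(nm, .copy_names)])
        stop("table ", nm, " must be a transition_table of type ",
             .copy_types[match(nm, .copy_names)], call. = FALSE)
    }
  }
  structure(list(layout = layout, promoter_of = promoter_of,
                 nucleosomes = as.integer(nucleosomes),
                 iterations = as.integer(iterations),
                 record_every = as.integer(record_every),
                 params = tp, k = k, gate_fraction = gate_fraction,
                 D0 = D0, pinned = isTRUE(pinned), tables = tables,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat("  blocks:     ", length(x$layout), " (",
      sum(x$layout == "promoter"), " promoters, ",
      sum(x$layout == "gene"), " genes)\n", sep = "")
  cat("  nucleosomes:", x$nucleosomes, "per block\n")
  cat("  iterations: ", x$iterations, " (record every ", x$record_every,
      ", transcription interval ", x$params$interval, ")\n", sep = "")
  cat("  methylation:", if (x$pinned) "pinned at user values" else "dynamic",
      "\n")
  cat("  seed:       ", x$seed, "\n")
  invisible(x)
}

## derive independent sub-seeds from the master seed
.derive_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(2147483646L, n))
}

## materialise the nine per-copy tables (user-supplied or seeded random)
.resolve_tables <- function(config) {
  tseeds <- .derive_seeds(config$seed, length(.copy_names) + 1L)
  tables <- stats::setNames(vector("list", length(.copy_names)), .copy_names)
  for (i in seq_along(.copy_names)) {
    nm <- .copy_names[i]
    if (!is.null(config$tables[[nm]])) {
      tables[[nm]] <- config$tables[[nm]]
    } else {
      tables[[nm]] <- random_transition_table(.copy_types[i], tseeds[i])
    }
  }
  list(tables = tables, sim_seed = tseeds[length(tseeds)])
}

## flat space description handed to the compiled core
.space_payload <- function(type) {
  sp <- enumerate_states(type)
  list(n = sp$n, ptr = sp$ptr, nbr = sp$nbr, bal = sp$bal,
       ace = sp$ace, met = sp$met, ph = sp$ph,
       modulated = type %in% c("H3", "H4"))
}

#' Build the block/nucleosome/histone hierarchy
#'
#' Wires the object hierarchy for a configuration: blocks in layout order,
#' each with `nucleosomes` nucleosomes of nine histones, every histone
#' initialised to the all-unmodified state, methylation initialised from the
#' user values or the histone-derived anchor, and one shift-probability table
#' per histone copy.
#'
#' @param config A `simulation_config`.
#' @return An object of class `chromatin_genome` holding the current state
#'   matrix (histone slots x blocks), methylation levels, ledgers, visit
#'   counts and tables; advance it with [step_genome()] or run a full
#'   schedule with [run_simulation()].
#' @export
build_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  B <- length(config$layout)
  slots <- rep(.copy_names, config$nucleosomes)
  slot_type <- rep(.copy_types, config$nucleosomes)
  types <- unique(slot_type)
  spaces <- lapply(types, .space_payload)
  names(spaces) <- types
  rt <- .resolve_tables(config)
  state <- matrix(1L, nrow = length(slots), ncol = B)
  D <- if (is.null(config$D0)) {
    rep(initial_methylation(NULL, 0, 0), B)
  } else {
    vapply(config$D0, initial_methylation, numeric(1))
  }
  mx <- .nucleosome_maxima() * config$nucleosomes
  visits <- lapply(slot_type, function(t) {
    matrix(0L, nrow = enumerate_states(t)$n, ncol = B)
  })
  structure(list(
    config = config, blocks = data.frame(
      id = seq_len(B), type = config$layout,
      promoter = config$promoter_of, stringsAsFactors = FALSE),
    slots = slots, slot_type = slot_type, spaces = spaces,
    tables = rt$tables, sim_seed = rt$sim_seed,
    state = state, D = D,
    max_ace = unname(mx["ace"]), max_met = unname(mx["met"]),
    visits = visits, steps_done = 0L
  ), class = "chromatin_genome")
}

## shared driver for step_genome()/run_simulation()
.advance <- function(genome, iterations, record_every = 0L, interval = 0L) {
  cfg <- genome$config
  bt <- match(cfg$layout, c("promoter", "gene")) - 1L
  bt[is.na(bt)] <- 2L
  probs <- lapply(seq_along(genome$slots), function(s) {
    genome$tables[[genome$slots[s]]]$p
  })
  res <- .sim_core(bt, cfg$promoter_of,
                   unname(genome$spaces), match(genome$slot_type,
                                                names(genome$spaces)),
                   probs, genome$state, genome$D,
                   rep_len(cfg$pinned, length(cfg$layout)),
                   genome$max_ace, genome$max_met,
                   cfg$k, cfg$params$P_T, cfg$params$kappa,
                   as.integer(interval),
                   cfg$gate_fraction, cfg$params$blocking_threshold,
                   as.integer(iterations), as.integer(record_every), TRUE)
  genome$state <- res$state
  genome$D <- res$D
  genome$visits <- mapply(`+`, genome$visits, res$visits, SIMPLIFY = FALSE)
  genome$steps_done <- genome$steps_done + as.integer(iterations)
  list(genome = genome, core = res)
}

#' Advance a genome by a number of time-steps
#'
#' One time-step applies at most one modification change to every histone of
#' every block (H3/H4 weights modulated by the block's current methylation),
#' updates the ledgers and visit counters, and then applies the conditional
#' methylation update per block (unless the configuration pins methylation).
#' Uses the current R RNG stream; seed with `set.seed()` for reproducibility.
#'
#' @param genome A `chromatin_genome`.
#' @param steps Number of time-steps (default 1).
#' @return The updated genome.
#' @export
step_genome <- function(genome, steps = 1) {
  stopifnot(inherits(genome, "chromatin_genome"))
  .advance(genome, steps)$genome
}

#' Run a full simulation
#'
#' Builds the genome for `config`, seeds the RNG from the configuration,
#' iterates the time-step loop for the configured number of iterations,
#' computes transcription every interval (with promoter gating of downstream
#' genes) and records methylation and global modification levels every
#' recording step.
#'
#' @param config A `simulation_config`.
#' @return An object of class `chromatin_sim` - the run record: `D_trace`
#'   (recording steps x blocks), `T_trace` (intervals x blocks), global
#'   `ace`/`met`/`ph` traces, per-copy per-state visit counts, final states
#'   and the seeds used.
#' @examples
#' \donttest{
#' cfg <- simulation_config(layout = default_layout(2, 1), iterations = 200,
#'                          record_every = 25, seed = 7)
#' sim <- run_simulation(cfg)
#' summary(sim)
#' }
#' @export
run_simulation <- function(config) {
  genome <- build_genome(config)
  out <- .with_seed(genome$sim_seed,
                    .advance(genome, config$iterations,
                             record_every = config$record_every,
                             interval = config$params$interval))
  core <- out$core
  genome <- out$genome
  rec_steps <- seq(config$record_every, config$iterations,
                   by = config$record_every)
  int_steps <- seq(config$params$interval, config$iterations,
                   by = config$params$interval)
  dimnames(core$D_trace) <- list(rec_steps, NULL)
  dimnames(core$T_trace) <- list(int_steps, NULL)
  structure(list(
    config = config, blocks = genome$blocks,
    slots = genome$slots, slot_type = genome$slot_type,
    D_trace = core$D_trace, T_trace = core$T_trace,
    ace_trace = core$ace_trace, met_trace = core$met_trace,
    ph_trace = core$ph_trace,
    max_ace = genome$max_ace, max_met = genome$max_met,
    visits = stats::setNames(genome$visits, genome$slots),
    final_state = genome$state, final_D = genome$D,
    table_seeds = vapply(genome$tables, function(t) {
      if (is.na(t$seed)) NA_integer_ else t$seed
    }, integer(1)),
    sim_seed = genome$sim_seed, iterations = config$iterations
  ), class = "chromatin_sim")
}

#' @export
print.chromatin_sim <- function(x, ...) {
  cat("Chromatin simulation run\n")
  cat("  blocks:     ", nrow(x$blocks), " (",
      sum(x$blocks$type == "promoter"), " promoters)\n", sep = "")
  cat("  iterations: ", x$iterations, "\n", sep = "")
  cat("  records:    ", nrow(x$D_trace), " methylation, ",
      nrow(x$T_trace), " transcription intervals\n", sep = "")
  cat("  methylation:", if (x$config$pinned) "pinned" else "dynamic", "\n")
  invisible(x)
}

#' @export
summary.chromatin_sim <- function(object, ...) {
  prom <- object$blocks$type == "promoter"
  gene <- object$blocks$type == "gene"
  cat("Chromatin simulation run:", nrow(object$blocks), "blocks,",
      object$iterations, "iterations\n")
  cat(sprintf("  promoter methylation: start %.3f, end %.3f (mean)\n",
              mean(object$D_trace[1L, prom]), mean(object$final_D[prom])))
  cat(sprintf("  mean promoter transcription: %.3f\n",
              mean(object$T_trace[, prom])))
  if (any(gene))
    cat(sprintf("  mean gene transcription:     %.3f\n",
                mean(object$T_trace[, gene])))
  r_ace <- mean(object$ace_trace[nrow(object$ace_trace), ]) / object$max_ace
  r_met <- mean(object$met_trace[nrow(object$met_trace), ]) / object$max_met
  cat(sprintf("  final balance ratios: r_ace %.3f, r_met %.3f\n", r_ace, r_met))
  invisible(object)
}

#' @export
plot.chromatin_sim <- function(x, which = c("transcription", "methylation"),
                               ...) {
  which <- match.arg(which)
  prom <- which(x$blocks$type == "promoter")
  if (which == "methylation") {
    graphics::matplot(as.integer(rownames(x$D_trace)),
                      x$D_trace[, prom, drop = FALSE], type = "l", lty = 1,
                      xlab = "iteration", ylab = "DNA methylation (D)",
                      main = "Promoter methylation", ylim = c(0, 1), ...)
  } else {
    graphics::matplot(as.integer(rownames(x$T_trace)),
                      x$T_trace[, prom, drop = FALSE], type = "l", lty = 1,
                      xlab = "iteration", ylab = "transcription (T)",
                      main = "Promoter transcription", ylim = c(0, 1), ...)
  }
  invisible(x)
}

#' Write a run record as a directory of delimited text tables
#'
#' Writes `methylation.tsv`, `transcription.tsv`, `global_levels.tsv`, one
#' `visits_<TYPE>.tsv` per histone type (copies summed) and a
#' `manifest.yaml` with the seeds and parameters needed to reproduce the run.
#'
#' @param sim A `chromatin_sim`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_run_record <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  B <- nrow(sim$blocks)
  rec <- as.integer(rownames(sim$D_trace))
  long <- function(m, value, steps) {
    data.frame(step = rep(steps, times = B),
               block = rep(sim$blocks$id, each = length(steps)),
               type = rep(sim$blocks$type, each = length(steps)),
               value = as.vector(m), check.names = FALSE) |>
      stats::setNames(c("step", "block", "type", value))
  }
  utils::write.table(long(sim$D_trace, "D", rec),
                     file.path(dir, "methylation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(long(sim$T_trace, "T", as.integer(rownames(sim$T_trace))),
                     file.path(dir, "transcription.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gl <- long(sim$ace_trace, "ace", rec)
  gl$met <- as.vector(sim$met_trace)
  gl$ph <- as.vector(sim$ph_trace)
  utils::write.table(gl, file.path(dir, "global_levels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (type in unique(sim$slot_type)) {
    sel <- sim$slot_type == type
    v <- Reduce(`+`, sim$visits[sel])
    df <- data.frame(state = seq_len(nrow(v)),
                     code = enumerate_states(type)$code, v)
    names(df)[-(1:2)] <- paste0("block", sim$blocks$id)
    utils::write.table(df, file.path(dir, paste0("visits_", type, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package = "chromsim",
    version = as.character(utils::packageVersion("chromsim")),
    seed = sim$config$seed, sim_seed = sim$sim_seed,
    table_seeds = as.list(sim$table_seeds),
    blocks = B, nucleosomes = sim$config$nucleosomes,
    iterations = sim$iterations, record_every = sim$config$record_every,
    interval = sim$config$params$interval,
    pinned = sim$config$pinned,
    D0 = if (is.null(sim$config$D0)) "anchor" else sim$config$D0)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
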