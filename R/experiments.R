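## Scripted regime experiments and occupancy summaries
##
## The reference protocol: the default 64-block genome (16 promoters x 3
## genes), 5000 iterations, 10 independently seeded random shift-probability
## datasets, methylation pinned low (< 0.15) or high (> 0.85), and per-state
## visitation percentages aggregated over the 16 promoters and both copies of
## the histone under study.

.experiment_names <- c("h4_low_D", "h4_high_D", "h3_low_D", "h3_high_D",
                       "h4_compare", "transcription_vs_methylation")

#' Per-state occupancy statistics
#'
#' Percentage visitation of every state of one histone type, aggregated over
#' the selected blocks and both histone copies, with the mean and standard
#' deviation taken across replicate runs.
#'
#' @param sims A `chromatin_sim` or a list of replicate `chromatin_sim`s.
#' @param type Histone type (default `"H4"`).
#' @param blocks Which blocks to aggregate: a block-type name (default
#'   `"promoter"`) or a vector of block ids.
#' @return A data frame: `state`, `code`, `mean_pct`, `sd_pct` (across
#'   replicates; 0 when there is a single replicate).
#' @export
occupancy_statistics <- function(sims, type = "H4", blocks = "promoter") {
  if (inherits(sims, "chromatin_sim")) sims <- list(sims)
  if (!length(sims)) stop("no replicate runs supplied", call. = FALSE)
  space <- enumerate_states(type)
  pct <- vapply(sims, function(sim) {
    sel_b <- if (is.character(blocks)) which(sim$blocks$type %in% blocks)
             else as.integer(blocks)
    if (!length(sel_b)) stop("empty block selection", call. = FALSE)
    sel_s <- sim$slot_type == type
    if (!any(sel_s)) stop("no histone copies of type ", type, call. = FALSE)
    v <- Reduce(`+`, sim$visits[sel_s])
    tot <- rowSums(v[, sel_b, drop = FALSE])
    100 * tot / sum(tot)
  }, numeric(space$n))
  pct <- matrix(pct, nrow = space$n)
  data.frame(state = seq_len(space$n), code = space$code,
             mean_pct = rowMeans(pct),
             sd_pct = if (ncol(pct) > 1L) apply(pct, 1L, stats::sd) else 0,
             stringsAsFactors = FALSE)
}

#' Signature H4 state sets of the two methylation regimes
#'
#' Low methylation favours the fully lysine-acetylated H4 states (K5, K8 and
#' K12 all acetylated); high methylation favours the K12-methylated states.
#'
#' @param regime `"low"` or `"high"`.
#' @return Integer state indices into the H4 state space.
#' @export
h4_target_states <- function(regime = c("low", "high")) {
  regime <- match.arg(regime)
  sp <- enumerate_states("H4")
  if (regime == "low") {
    which(sp$codes[, "K5"] == 1L & sp$codes[, "K8"] == 1L &
          sp$codes[, "K12"] == 1L)
  } else {
    which(sp$codes[, "K12"] == 2L)
  }
}

## dominance verdict: at least 2 of the 3 top-visited states belong to the
## regime's signature set (the operational reading of "these states
## predominated")
.dominates <- function(occ, target, n_top = 3L) {
  top <- order(occ$mean_pct, decreasing = TRUE)[seq_len(n_top)]
  sum(top %in% target) >= 2L
}

## one pinned-methylation replicate of the reference protocol
.regime_config <- function(D, dataset_seed, iterations = 5000,
                           layout = default_layout()) {
  simulation_config(layout = layout, iterations = iterations,
                    record_every = if (iterations %% 25L == 0L) 25L
                                   else iterations,
                    D0 = D, pinned = TRUE, seed = dataset_seed)
}

#' Run a named regime experiment
#'
#' Replicates the model's reference experiments: `n_datasets` independently
#' seeded random shift-probability datasets, each run on the default
#' 64-block genome for `iterations` time-steps with DNA methylation pinned in
#' the requested regime, then aggregated over the 16 promoters.
#'
#' * `h4_low_D` / `h4_high_D`: per-dataset H4 occupancy, top-visited states
#'   and the dominance verdict against the regime's signature set.
#' * `h4_compare`: both regimes on the same datasets plus the top-3
#'   disjointness check across regimes.
#' * `h3_low_D` / `h3_high_D`: per-position H3 modification report within the
#'   regime's dominant-state subset.
#' * `transcription_vs_methylation`: mean promoter transcription across a
#'   pinned methylation grid (see [transcription_vs_methylation()]).
#'
#' @param name Experiment name.
#' @param n_datasets Number of random probability datasets (default 10).
#' @param seed Master seed; dataset seeds are derived from it.
#' @param iterations Time-steps per run (default 5000).
#' @param D_low,D_high Pinned methylation levels of the two regimes
#'   (defaults 0.10 and 0.90, inside the < 0.15 / > 0.85 regime bounds).
#' @return An object of class `chromsim_experiment` with per-dataset tables,
#'   verdicts and the aggregate summary.
#' @export
run_experiment <- function(name, n_datasets = 10, seed = 1, iterations = 5000,
                           D_low = 0.10, D_high = 0.90) {
  name <- match.arg(name, .experiment_names)
  if (name == "transcription_vs_methylation")
    return(transcription_vs_methylation(seed = seed, n_runs = n_datasets,
                                        iterations = iterations))
  if (D_low < 0 || D_low >= 0.15 || D_high <= 0.85 || D_high > 1)
    stop("regime levels must satisfy D_low < 0.15 and D_high > 0.85",
         call. = FALSE)
  ds_seeds <- .derive_seeds(seed, n_datasets)
  regimes <- switch(name,
                    h4_low_D = , h3_low_D = "low",
                    h4_high_D = , h3_high_D = "high",
                    h4_compare = c("low", "high"))
  type <- if (startsWith(name, "h3")) "H3" else "H4"
  occ <- list(low = vector("list", n_datasets),
              high = vector("list", n_datasets))
  sims <- list(low = vector("list", n_datasets),
               high = vector("list", n_datasets))
  for (i in seq_len(n_datasets)) {
    for (rg in regimes) {
      D <- if (rg == "low") D_low else D_high
      sim <- run_simulation(.regime_config(D, ds_seeds[i], iterations))
      occ[[rg]][[i]] <- occupancy_statistics(sim, type = type,
                                             blocks = "promoter")
      sims[[rg]][[i]] <- sim
    }
  }
  out <- list(name = name, type = type, n_datasets = n_datasets,
              seed = seed, dataset_seeds = ds_seeds,
              iterations = iterations, D_low = D_low, D_high = D_high,
              occupancy = occ[regimes])
  if (type == "H4") {
    verdicts <- lapply(regimes, function(rg) {
      target <- h4_target_states(rg)
      vapply(occ[[rg]], .dominates, logical(1), target = target)
    })
    names(verdicts) <- regimes
    out$verdicts <- verdicts
    out$dominance_count <- vapply(verdicts, sum, integer(1))
    out$dominance_pct <- 100 * out$dominance_count / n_datasets
    out$top_states <- lapply(regimes, function(rg) {
      t(vapply(occ[[rg]], function(o) {
        order(o$mean_pct, decreasing = TRUE)[1:3]
      }, integer(3)))
    })
    names(out$top_states) <- regimes
    if (name == "h4_compare") {
      out$disjoint <- vapply(seq_len(n_datasets), function(i) {
        !any(out$top_states$low[i, ] %in% out$top_states$high[i, ])
      }, logical(1))
      ## Fig. 9 style mean +/- SD occupancy across datasets, per regime
      out$summary <- lapply(regimes, function(rg) {
        m <- vapply(occ[[rg]], function(o) o$mean_pct,
                    numeric(nrow(occ[[rg]][[1L]])))
        data.frame(state = occ[[rg]][[1L]]$state,
                   code = occ[[rg]][[1L]]$code,
                   mean_pct = rowMeans(m), sd_pct = apply(m, 1L, stats::sd))
      })
      names(out$summary) <- regimes
    }
  } else {
    subset <- if (regimes == "low") "lys_ace" else "lys_met"
    out$report <- h3_modification_report(sims[[regimes]], subset = subset)
  }
  structure(out, class = "chromsim_experiment")
}

#' @export
print.chromsim_experiment <- function(x, ...) {
  cat("Regime experiment:", x$name, "\n")
  cat("  datasets:", x$n_datasets, " iterations:", x$iterations,
      " seed:", x$seed, "\n")
  if (!is.null(x$dominance_count)) {
    for (rg in names(x$dominance_count)) {
      cat(sprintf("  %s-methylation dominance: %d / %d datasets (%.0f%%)\n",
                  rg, x$dominance_count[[rg]], x$n_datasets,
                  100 * x$dominance_count[[rg]] / x$n_datasets))
    }
  }
  if (!is.null(x$disjoint))
    cat("  disjoint top-3 across regimes:", sum(x$disjoint), "/",
        x$n_datasets, "datasets\n")
  if (!is.null(x$curve)) {
    cat("  mean promoter transcription by pinned methylation:\n")
    print(x$curve, row.names = FALSE)
  }
  invisible(x)
}

#' Transcription versus pinned DNA methylation
#'
#' Runs the default genome over a grid of pinned methylation levels with
#' several seeds per level and reports the mean promoter transcription -- the
#' model's inverse transcription-methylation relation.  Gene-block
#' transcription downstream of promoters above the blocking threshold is
#' gated to zero.
#'
#' @param D_grid Pinned methylation levels.
#' @param n_runs Seeded replicate runs per level (default 3).
#' @param seed Master seed.
#' @param iterations Time-steps per run.
#' @return A `chromsim_experiment` whose `curve` element tabulates, per
#'   methylation level, the mean promoter and gene transcription across runs;
#'   `by_run` holds the per-run means.
#' @export
transcription_vs_methylation <- function(D_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                         n_runs = 3, seed = 1,
                                         iterations = 5000) {
  run_seeds <- .derive_seeds(seed, n_runs)
  by_run <- expand.grid(D = D_grid, run = seq_len(n_runs),
                        KEEP.OUT.ATTRS = FALSE)
  by_run$T_promoter <- NA_real_
  by_run$T_gene <- NA_real_
  for (r in seq_len(nrow(by_run))) {
    sim <- run_simulation(.regime_config(by_run$D[r],
                                         run_seeds[by_run$run[r]],
                                         iterations))
    prom <- sim$blocks$type == "promoter"
    by_run$T_promoter[r] <- mean(sim$T_trace[, prom])
    by_run$T_gene[r] <- mean(sim$T_trace[, !prom])
  }
  curve <- stats::aggregate(cbind(T_promoter, T_gene) ~ D, data = by_run,
                            FUN = mean)
  structure(list(name = "transcription_vs_methylation",
                 n_datasets = n_runs, seed = seed, iterations = iterations,
                 D_grid = D_grid, by_run = by_run, curve = curve),
            class = "chromsim_experiment")
}

#' Per-position H3 modification visitation report
#'
#' For each of the six compressed H3 positions and each admissible count, the
#' percentage of (promoter) H3 visits that landed on states carrying that
#' count, optionally restricted to a regime's dominant-state subset: states
#' containing lysine acetylation (`"lys_ace"`, position 6 > 0 - the low
#' methylation subset) or lysine methylation (`"lys_met"`, position 5 > 0 -
#' the high-methylation subset).  Percentages sum to 100 within each
#' position.
#'
#' @param sims A `chromatin_sim` or list of replicates.
#' @param subset `"all"`, `"lys_ace"` or `"lys_met"`.
#' @param blocks Block selection as in [occupancy_statistics()].
#' @return A data frame: `position`, `modification`, `residues`, `count`,
#'   `pct` (mean across replicates).
#' @export
h3_modification_report <- function(sims, subset = c("all", "lys_ace",
                                                    "lys_met"),
                                   blocks = "promoter") {
  subset <- match.arg(subset)
  occ <- occupancy_statistics(sims, type = "H3", blocks = blocks)
  sp <- enumerate_states("H3")
  keep <- switch(subset,
                 all = rep(TRUE, sp$n),
                 lys_ace = sp$codes[, 6L] > 0L,
                 lys_met = sp$codes[, 5L] > 0L)
  w <- occ$mean_pct * keep
  if (sum(w) == 0) stop("no visits in the selected state subset", call. = FALSE)
  pos <- sp$spec$positions
  out <- do.call(rbind, lapply(1:6, function(j) {
    vals <- 0:pos$max[j]
    pct <- vapply(vals, function(v) sum(w[sp$codes[, j] == v]), numeric(1))
    data.frame(position = j, modification = pos$modification[j],
               residues = pos$residues[j], count = vals,
               pct = 100 * pct / sum(pct), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
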