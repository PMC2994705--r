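## Block-level transcription and DNA-methylation rules
##
## Transcription is a clamped exponential of the interval-mean
## acetyl-minus-methyl balance of the block's histones; DNA methylation is
## pulled toward a histone-derived anchor through a rare conditional update.

#' Block modification ledger
#'
#' Tracks a block's current multiplicity-weighted acetyl/methyl/phospho
#' totals across all histones of all its nucleosomes, together with the
#' maximum attainable acetyl and methyl totals for that histone complement.
#'
#' @param ace,met,ph Current totals.
#' @param max_ace,max_met Maximum attainable totals (must be positive).
#' @return An object of class `modification_ledger`.
#' @export
modification_ledger <- function(ace = 0, met = 0, ph = 0, max_ace, max_met) {
  if (max_ace <= 0 || max_met <= 0)
    stop("ledger maxima must be positive (empty block?)", call. = FALSE)
  if (ace < 0 || met < 0 || ph < 0 || ace > max_ace || met > max_met)
    stop("ledger totals must lie between 0 and their maxima", call. = FALSE)
  structure(list(ace = ace, met = met, ph = ph,
                 max_ace = max_ace, max_met = max_met),
            class = "modification_ledger")
}

## per-nucleosome maxima for the standard 9-histone complement
.nucleosome_maxima <- function() {
  types <- c("H2A", "H2A", "H2B", "H2B", "H3", "H3", "H4", "H4", "H1")
  m <- vapply(types, function(t) .space_maxima(enumerate_states(t)), numeric(2))
  c(ace = sum(m["ace", ]), met = sum(m["met", ]))
}

#' Acetylation and methylation balance ratios of a block
#'
#' Ratios of the current acetyl and methyl totals to the maximum attainable
#' totals for the block's histone complement.
#'
#' @param ledger A `modification_ledger`.
#' @return Named numeric `c(r_ace, r_met)`, each in \[0, 1\].
#' @export
balance_ratios <- function(ledger) {
  if (!inherits(ledger, "modification_ledger"))
    stop("ledger must be a modification_ledger", call. = FALSE)
  c(r_ace = ledger$ace / ledger$max_ace, r_met = ledger$met / ledger$max_met)
}

#' Transcription parameters
#'
#' @param P_T Base transcription probability (default 0.5, the unbiased
#'   neutral point).
#' @param interval Time-steps per transcription interval; one of 1, 5, 25
#'   or 100.
#' @param kappa Exponential gain on the interval-mean balance (default
#'   `log(2)`, so a full acetyl excess doubles `P_T`).
#' @param blocking_threshold Promoter methylation level above which
#'   downstream gene transcription is blocked (default 0.75).
#' @return An object of class `transcription_params`.
#' @export
transcription_params <- function(P_T = 0.5, interval = 25, kappa = log(2),
                                 blocking_threshold = 0.75) {
  if (P_T < 0 || P_T > 1) stop("P_T must lie in [0, 1]", call. = FALSE)
  if (!interval %in% c(1L, 5L, 25L, 100L))
    stop("interval must be one of 1, 5, 25, 100", call. = FALSE)
  if (kappa <= 0) stop("kappa must be positive", call. = FALSE)
  if (blocking_threshold < 0 || blocking_threshold > 1)
    stop("blocking_threshold must lie in [0, 1]", call. = FALSE)
  structure(list(P_T = P_T, interval = as.integer(interval), kappa = kappa,
                 blocking_threshold = blocking_threshold),
            class = "transcription_params")
}

#' Transcription over one time-interval
#'
#' Computes the interval transcription value from the per-step balance
#' ratios: with mean balance `b = mean(r_ace - r_met)` over the interval's
#' steps, `T = min(1, P_T * exp(kappa * b))`.  At a neutral balance the
#' result equals `P_T`.
#'
#' @param balances An `m x 2` matrix (or data frame) of per-step
#'   `(r_ace, r_met)` pairs, one row per time-step of the interval; `m`
#'   must equal `params$interval`.
#' @param params A `transcription_params`.
#' @return Transcription value in \[0, 1\].
#' @examples
#' p <- transcription_params(interval = 5)
#' compute_transcription(matrix(0, 5, 2), p)   # 0.5
#' @export
compute_transcription <- function(balances, params = transcription_params()) {
  balances <- as.matrix(balances)
  if (ncol(balances) != 2L || nrow(balances) != params$interval)
    stop("balances must supply exactly ", params$interval,
         " (r_ace, r_met) pairs", call. = FALSE)
  b <- mean(balances[, 1L] - balances[, 2L])
  min(1, params$P_T * exp(params$kappa * b))
}

#' Promoter gating of downstream transcription
#'
#' When a promoter's DNA-methylation level exceeds the blocking threshold,
#' transcription of the gene blocks it controls is forced to zero for the
#' interval; otherwise the gene values pass through untouched.
#'
#' @param promoter_D Promoter methylation level.
#' @param T_genes Transcription values of the downstream gene blocks.
#' @param threshold Blocking threshold (default 0.75).
#' @return `T_genes`, zeroed when the promoter is blocked.
#' @export
gate_downstream <- function(promoter_D, T_genes, threshold = 0.75) {
  if (promoter_D > threshold) rep(0, length(T_genes)) else T_genes
}

## histone-derived methylation anchor: high methyl and low acetyl pull D up
.methylation_anchor <- function(r_ace, r_met) (r_met + (1 - r_ace)) / 2

#' One conditional DNA-methylation update
#'
#' Implements the rare, methylation-gated update: draw `u ~ U[0,1]`; only if
#' `u < gate_fraction * D` does the level move, to `D' = D + R * (A - D)`
#' with `R ~ U[0,1]` and anchor `A = (r_met + (1 - r_ace)) / 2`.  The update
#' is a convex combination, so `D` stays in \[0, 1\]; `D = 0` is absorbing
#' under the gate.
#'
#' @param D Current methylation level in \[0, 1\].
#' @param r_ace,r_met Current balance ratios of the block.
#' @param gate_fraction Gate fraction (default 0.05, i.e. fire with
#'   probability 5% of the current level).
#' @return The updated methylation level.
#' @export
update_dna_methylation <- function(D, r_ace, r_met, gate_fraction = 0.05) {
  if (D < 0 || D > 1) stop("D must lie in [0, 1]", call. = FALSE)
  if (stats::runif(1L) < gate_fraction * D) {
    A <- .methylation_anchor(r_ace, r_met)
    R <- stats::runif(1L)
    D <- D + R * (A - D)
  }
  min(max(D, 0), 1)
}

#' Initial DNA-methylation level of a block
#'
#' The user-supplied value when given (validated to \[0, 1\]); otherwise the
#' histone-derived anchor `A = (r_met + (1 - r_ace)) / 2` computed from the
#' initial histone states (0.5 for the all-unmodified start).
#'
#' @param user Optional user value in \[0, 1\].
#' @param r_ace,r_met Initial balance ratios.
#' @return The initial methylation level.
#' @export
initial_methylation <- function(user = NULL, r_ace = 0, r_met = 0) {
  if (!is.null(user)) {
    if (!is.numeric(user) || length(user) != 1L || is.na(user) ||
        user < 0 || user > 1)
      stop("user methylation value must lie in [0, 1]", call. = FALSE)
    return(as.numeric(user))
  }
  .methylation_anchor(r_ace, r_met)
}
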