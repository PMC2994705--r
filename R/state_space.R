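## Histone modification state spaces
##
## Each histone type carries a catalogue of modifiable amino-acid sites.
## Modifications are encoded as digits: 0 none, 1 acetylation (Ace),
## 2 methylation (Met), 3 phosphorylation (Ph).  A histone *state* is one
## combination of site codes; H3 uses a compressed 6-position counts
## representation instead of per-residue codes.

.mod_codes <- c(none = 0L, Ace = 1L, Met = 2L, Ph = 3L)

## Allowed nonzero codes for a site, by modification label.
.allowed_codes <- function(mod) {
  switch(mod,
    "Ace"     = 1L,
    "Met"     = 2L,
    "Ph"      = 3L,
    "Ace/Met" = c(1L, 2L),
    stop("unknown modification label: ", mod, call. = FALSE)
  )
}

## Site catalogues per histone type. H3 is compressed: six positions, each a
## count of modified residues of one kind, with positions 5 and 6 sharing the
## same six lysines (joint constraint count5 + count6 <= 6).
.histone_catalogue <- list(
  H1 = list(kind = "code", sites = data.frame(
    site = character(0), modification = character(0),
    stringsAsFactors = FALSE)),
  H2A = list(kind = "code", sites = data.frame(
    site = c("S1", "R3", "K5", "K9"),
    modification = c("Ph", "Met", "Ace", "Ace"),
    stringsAsFactors = FALSE)),
  H2B = list(kind = "code", sites = data.frame(
    site = c("K5", "S10", "K11", "K12", "S14", "K15", "K16", "K20",
             "K23", "K24"),
    modification = c("Ace/Met", "Ph", "Ace", "Ace", "Ph", "Ace", "Ace",
                     "Ace", "Met", "Ace"),
    stringsAsFactors = FALSE)),
  H4 = list(kind = "code", sites = data.frame(
    site = c("S1", "R3", "K5", "K8", "K12"),
    modification = c("Ph", "Met", "Ace", "Ace", "Ace/Met"),
    stringsAsFactors = FALSE)),
  H3 = list(kind = "compressed", positions = data.frame(
    position = 1:6,
    modification = c("Met", "Ph", "Ph", "Met", "Met", "Ace"),
    max = c(4L, 4L, 2L, 2L, 6L, 6L),
    residues = c("R2,R8,R17,R26", "T3,T11,T22,T32", "S10,S28", "K4,K37",
                 "K9,K14,K18,K23,K27,K36", "K9,K14,K18,K23,K27,K36"),
    stringsAsFactors = FALSE))
)

#' Histone types known to the model
#'
#' @return Character vector of the five core histone type names.
#' @export
histone_types <- function() c("H1", "H2A", "H2B", "H3", "H4")

#' Site catalogue for a histone type
#'
#' Returns the modifiable-site catalogue that defines the modification state
#' space of one histone type: for H1, H2A, H2B and H4 a table of amino-acid
#' sites with their admissible modification (acetylation, methylation,
#' phosphorylation, or acetylation/methylation); for H3 the compressed
#' six-position representation, each position a count of modified residues of
#' one modification kind, with positions 5 and 6 drawing on the same six
#' lysines (so their counts jointly never exceed 6).
#'
#' @param type Histone type name, one of `histone_types()`.
#' @return A list with elements `name`, `kind` (`"code"` or `"compressed"`)
#'   and the site/position table.
#' @export
histone_spec <- function(type) {
  type <- match.arg(toupper(type), histone_types())
  spec <- .histone_catalogue[[type]]
  c(list(name = type), spec)
}

## package-local cache: enumeration is deterministic, do it once per session
.space_cache <- new.env(parent = emptyenv())

#' Enumerate the modification state space of a histone type
#'
#' Builds the complete state space for one histone type together with its
#' neighbour graph: two states are neighbours when they differ by exactly one
#' modification event (one site going unmodified -> modified or back; for H3,
#' one compressed position changing by one count).  States are indexed
#' lexicographically on the code vector so that indices are stable across
#' runs.
#'
#' @param type Histone type name.
#' @return An object of class `histone_space`: the code matrix, code strings,
#'   flattened adjacency (`ptr`/`nbr`), per-state acetyl/methyl/phospho counts
#'   and acetyl-methyl balance, and the site catalogue.
#' @examples
#' sp <- enumerate_states("H4")
#' sp$n            # 48 states
#' state_code(sp, 1)
#' @export
enumerate_states <- function(type) {
  type <- match.arg(toupper(type), histone_types())
  if (!is.null(.space_cache[[type]])) return(.space_cache[[type]])
  spec <- histone_spec(type)

  if (spec$kind == "code") {
    allowed <- lapply(spec$sites$modification, function(m) c(0L, .allowed_codes(m)))
    if (length(allowed) == 0L) {
      codes <- matrix(integer(0), nrow = 1L, ncol = 0L)
    } else {
      codes <- as.matrix(expand.grid(allowed, KEEP.OUT.ATTRS = FALSE))
      codes <- codes[do.call(order, as.data.frame(codes)), , drop = FALSE]
    }
    colnames(codes) <- spec$sites$site
    ace <- as.integer(rowSums(codes == 1L))
    met <- as.integer(rowSums(codes == 2L))
    ph  <- as.integer(rowSums(codes == 3L))
  } else {
    mx <- spec$positions$max
    codes <- as.matrix(expand.grid(lapply(mx, function(m) 0:m),
                                   KEEP.OUT.ATTRS = FALSE))
    codes <- codes[codes[, 5L] + codes[, 6L] <= 6L, , drop = FALSE]
    codes <- codes[do.call(order, as.data.frame(codes)), , drop = FALSE]
    colnames(codes) <- paste0("pos", 1:6)
    ace <- as.integer(codes[, 6L])
    met <- as.integer(codes[, 1L] + codes[, 4L] + codes[, 5L])
    ph  <- as.integer(codes[, 2L] + codes[, 3L])
  }
  storage.mode(codes) <- "integer"
  rownames(codes) <- NULL
  code_str <- apply(codes, 1L, paste0, collapse = "")
  if (ncol(codes) == 0L) code_str <- ""
  lookup <- seq_along(code_str)
  names(lookup) <- code_str

  adj <- .build_adjacency(spec, codes, lookup)
  lens <- lengths(adj)
  space <- structure(list(
    type = type, kind = spec$kind, n = nrow(codes),
    codes = codes, code = code_str, lookup = lookup,
    adj = adj,
    ptr = c(0L, cumsum(lens)),
    nbr = if (sum(lens)) unlist(adj, use.names = FALSE) else integer(0),
    ace = ace, met = met, ph = ph, bal = ace - met,
    spec = spec
  ), class = "histone_space")
  .space_cache[[type]] <- space
  space
}

## neighbour lists: one modification change per move
.build_adjacency <- function(spec, codes, lookup) {
  n <- nrow(codes)
  if (ncol(codes) == 0L) return(list(integer(0)))
  adj <- vector("list", n)
  if (spec$kind == "code") {
    allowed_nz <- lapply(spec$sites$modification, .allowed_codes)
    for (i in seq_len(n)) {
      s <- codes[i, ]
      out <- integer(0)
      for (j in seq_along(s)) {
        t <- s
        if (s[j] == 0L) {
          for (v in allowed_nz[[j]]) {
            t[j] <- v
            out <- c(out, lookup[[paste0(t, collapse = "")]])
          }
        } else {
          t[j] <- 0L
          out <- c(out, lookup[[paste0(t, collapse = "")]])
        }
      }
      adj[[i]] <- sort(out)
    }
  } else {
    mx <- spec$positions$max
    for (i in seq_len(n)) {
      s <- codes[i, ]
      out <- integer(0)
      for (j in seq_along(s)) {
        for (d in c(-1L, 1L)) {
          t <- s
          t[j] <- s[j] + d
          if (t[j] < 0L || t[j] > mx[j]) next
          if (t[5L] + t[6L] > 6L) next
          out <- c(out, lookup[[paste0(t, collapse = "")]])
        }
      }
      adj[[i]] <- sort(out)
    }
  }
  adj
}

#' @rdname enumerate_states
#' @export
histone_space <- enumerate_states

## resolve a state given as index, code string, or integer code vector
.resolve_state <- function(space, state) {
  if (is.character(state)) {
    i <- space$lookup[state]
    if (anyNA(i)) stop("invalid ", space$type, " state code: ", state, call. = FALSE)
    return(unname(i))
  }
  state <- as.integer(state)
  if (length(state) == ncol(space$codes) && ncol(space$codes) > 1L) {
    i <- space$lookup[paste0(state, collapse = "")]
    if (is.na(i)) stop("invalid ", space$type, " state vector", call. = FALSE)
    return(unname(i))
  }
  if (length(state) != 1L || is.na(state) || state < 1L || state > space$n)
    stop("state index out of range for ", space$type, call. = FALSE)
  state
}

#' State index and code conversions
#'
#' `state_index()` maps a code string (or integer code vector) to its stable
#' lexicographic index; `state_code()` is the inverse.  Round-tripping is the
#' identity for every enumerated state.
#'
#' @param space A `histone_space`.
#' @param state A state: index, code string, or integer code vector.
#' @param index State index (vectorised).
#' @return `state_index()`: integer index; `state_code()`: character code.
#' @export
state_index <- function(space, state) .resolve_state(space, state)

#' @rdname state_index
#' @export
state_code <- function(space, index) {
  index <- as.integer(index)
  if (any(is.na(index) | index < 1L | index > space$n))
    stop("state index out of range for ", space$type, call. = FALSE)
  space$code[index]
}

#' Neighbouring states
#'
#' States reachable from `state` by exactly one modification event: a site
#' going 0 -> x or x -> 0 for code-type histones, or one H3 compressed
#' position changing by 1 subject to its range and the shared-lysine
#' constraint.  The input state is never its own neighbour.
#'
#' @inheritParams state_index
#' @param codes If `TRUE` (default) return code strings, else integer indices.
#' @return Character vector of neighbour codes (or integer indices).
#' @examples
#' sp <- enumerate_states("H4")
#' neighbor_states(sp, "00000")
#' @export
neighbor_states <- function(space, state, codes = TRUE) {
  i <- .resolve_state(space, state)
  nb <- space$adj[[i]]
  if (codes) space$code[nb] else nb
}

#' Acetyl/methyl balance class of a state
#'
#' Compares the state's acetylated site count against its methylated site
#' count (for H3: position 6 versus positions 1 + 4 + 5).  A strict majority
#' decides; ties are neutral.
#'
#' @inheritParams state_index
#' @return One of `"acetyl"`, `"methyl"`, `"neutral"`.
#' @examples
#' sp <- enumerate_states("H4")
#' classify_balance(sp, "00111")   # "acetyl"
#' classify_balance(sp, "02002")   # "methyl"
#' @export
classify_balance <- function(space, state) {
  i <- .resolve_state(space, state)
  b <- space$bal[i]
  if (b > 0L) "acetyl" else if (b < 0L) "methyl" else "neutral"
}

#' Modification counts of a state
#'
#' Counts of acetylation, methylation and phosphorylation marks carried by a
#' state, optionally weighted by per-site multiplicity (mono/di/tri marks:
#' repeated deposition of the same mark at one site, which raises the global
#' modification level without changing state identity).
#'
#' @inheritParams state_index
#' @param multiplicity Optional integer vector (one entry per site/position)
#'   of mark multiplicities in 1..3; entries at unmodified sites are ignored.
#' @return Named integer vector `c(ace, met, ph)`.
#' @export
modification_counts <- function(space, state, multiplicity = NULL) {
  i <- .resolve_state(space, state)
  s <- space$codes[i, ]
  k <- length(s)
  if (is.null(multiplicity)) multiplicity <- rep(1L, k)
  if (length(multiplicity) != k)
    stop("multiplicity must have one entry per site", call. = FALSE)
  multiplicity <- as.integer(multiplicity)
  if (any(multiplicity[s != 0L] < 1L | multiplicity[s != 0L] > 3L))
    stop("multiplicity entries must be in 1..3", call. = FALSE)
  if (space$kind == "code") {
    out <- c(ace = sum(multiplicity[s == 1L]),
             met = sum(multiplicity[s == 2L]),
             ph  = sum(multiplicity[s == 3L]))
  } else {
    w <- s * multiplicity
    out <- c(ace = w[6L], met = w[1L] + w[4L] + w[5L], ph = w[2L] + w[3L])
  }
  as.integer(out) -> v; names(v) <- c("ace", "met", "ph"); v
}

## maximum attainable (unit-multiplicity) ace/met totals for one histone
.space_maxima <- function(space) {
  c(ace = max(space$ace), met = max(space$met))
}

#' Dump a state space as delimited text
#'
#' Writes one row per state: index, code string, acetyl/methyl/phospho counts
#' and the balance class.
#'
#' @param space A `histone_space`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_state_space <- function(space, file) {
  df <- data.frame(index = seq_len(space$n), code = space$code,
                   ace = space$ace, met = space$met, ph = space$ph,
                   balance = ifelse(space$bal > 0L, "acetyl",
                                    ifelse(space$bal < 0L, "methyl", "neutral")),
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @export
print.histone_space <- function(x, ...) {
  cat("Histone state space:", x$type, "\n")
  cat("  states:    ", x$n, "\n", sep = "")
  cat("  edges:     ", length(x$nbr) / 2L, " (undirected)\n", sep = "")
  cat("  encoding:  ",
      if (x$kind == "code") "per-site codes (0 none, 1 Ace, 2 Met, 3 Ph)"
      else "compressed counts over 6 positions", "\n", sep = "")
  invisible(x)
}

#' @export
summary.histone_space <- function(object, ...) {
  deg <- diff(object$ptr)
  cat("Histone state space:", object$type, "-", object$n, "states\n")
  cat("  degree range:", min(deg), "-", max(deg), "\n")
  cat("  balance classes: acetyl", sum(object$bal > 0L),
      "/ methyl", sum(object$bal < 0L),
      "/ neutral", sum(object$bal == 0L), "\n")
  invisible(object)
}
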