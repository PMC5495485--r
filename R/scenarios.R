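## Stage 3: parsimonious sequential inversion scenarios over signed block
## permutations, optionally restricted to inversions whose endpoints are
## the two copies of a repeat pair. The constrained search tracks repeat
## copies as "markers" interleaved with the blocks: an inversion bounded by
## a pair reverses (and sign-flips) everything strictly between its two
## markers, leaves the bounding markers untouched (the crossover falls at
## the core midpoint, so both junctions retain a full core in the original
## orientation), and flips the strand of any other marker with exactly one
## copy inside the span. A pair is a legal substrate only while its two
## copies are in inverted relative orientation (opposite strands).

#' Apply inversion events to a signed permutation
#'
#' Each event reverses a contiguous slice and flips its signs.
#'
#' @param perm signed integer vector.
#' @param events two-column matrix or data.frame of 1-based slice bounds
#'   `(from, to)`, applied sequentially.
#' @return the transformed permutation.
#' @examples
#' apply_inversions(c(1L, 2L, 3L), cbind(2, 2)) # +1 -2 +3
#' @export
apply_inversions <- function(perm, events) {
  events <- as.matrix(events)
  for (e in seq_len(nrow(events))) {
    i <- events[e, 1]; j <- events[e, 2]
    if (i < 1L || j > length(perm) || i > j)
      stop("inversion slice out of range", call. = FALSE)
    perm[i:j] <- -rev(perm[i:j])
  }
  perm
}

## ---- marker-state machinery (internal) ----------------------------------

## A state is a list with $kind ("B" block / "M" marker), $id, $sign (+1/-1).
## Encoded as an integer vector for hashing: blocks as +-id, markers as
## +-(1000 + id) (block counts here are far below 1000).
state_encode <- function(kind, id, sign) {
  v <- ifelse(kind == "B", id, 1000L + id) * sign
  paste(v, collapse = ",")
}

make_state <- function(kind, id, sign) list(kind = kind, id = id, sign = sign)

#' Build the ancestral marker state for constrained scenario search
#'
#' @param n_blocks number of synteny blocks (ancestral arrangement is
#'   `+1..+n`).
#' @param pairs data.frame with one row per repeat pair: `pair` (integer
#'   id), `pos_a`, `pos_b` (adjacency indices 0..n: a marker at adjacency
#'   `i` lies between block `i` and block `i+1` of the ancestral
#'   arrangement), `strand_a`, `strand_b` (`+`/`-`; a pair is in inverted
#'   orientation when the strands differ).
#' @return an opaque state object used by [min_inversion_distance()] and
#'   [enumerate_minimal_scenarios()].
#' @export
marker_state <- function(n_blocks, pairs) {
  stopifnot(all(c("pair", "pos_a", "pos_b", "strand_a", "strand_b") %in%
                names(pairs)))
  kind <- rep("B", n_blocks); id <- seq_len(n_blocks)
  sign <- rep(1L, n_blocks)
  ins <- rbind(
    data.frame(pair = pairs$pair, pos = pairs$pos_a,
               strand = ifelse(pairs$strand_a == "+", 1L, -1L)),
    data.frame(pair = pairs$pair, pos = pairs$pos_b,
               strand = ifelse(pairs$strand_b == "+", 1L, -1L)))
  ins <- ins[order(ins$pos, ins$pair), , drop = FALSE]
  for (r in rev(seq_len(nrow(ins)))) {   # insert right-to-left to keep pos
    p <- ins$pos[r]
    kind <- append(kind, "M", after = p)
    id <- append(id, ins$pair[r], after = p)
    sign <- append(sign, ins$strand[r], after = p)
  }
  make_state(kind, id, sign)
}

## legal pair moves: pairs whose two markers have opposite signs and are
## not adjacent (adjacent markers invert nothing at block scale)
state_moves <- function(st) {
  mpos <- which(st$kind == "M")
  if (length(mpos) == 0L) return(integer(0))
  out <- integer(0)
  for (p in unique(st$id[mpos])) {
    at <- mpos[st$id[mpos] == p]
    if (length(at) != 2L) next
    if (st$sign[at[1]] != st$sign[at[2]] && at[2] - at[1] > 1L)
      out <- c(out, p)
  }
  out
}

state_apply <- function(st, pair) {
  mpos <- which(st$kind == "M" & st$id == pair)
  i <- mpos[1]; j <- mpos[2]
  idx <- (i + 1L):(j - 1L)
  st$kind[idx] <- rev(st$kind[idx])
  st$id[idx] <- rev(st$id[idx])
  st$sign[idx] <- -rev(st$sign[idx])
  st
}

state_blocks <- function(st) {
  b <- st$kind == "B"
  st$id[b] * st$sign[b]
}

state_key <- function(st) state_encode(st$kind, st$id, st$sign)

## ---- distance and enumeration -------------------------------------------

#' Minimal number of inversions between two signed permutations
#'
#' Breadth-first search over permutation states. Unconstrained, every
#' contiguous slice reversal is a legal move; with `pairs` given, only
#' inversions bounded by a repeat pair currently in inverted orientation
#' are legal (see [marker_state()]).
#'
#' @param ancestral,derived signed integer vectors over the same block ids.
#'   `ancestral` is typically `1:n`.
#' @param pairs optional repeat-pair table (see [marker_state()]) enabling
#'   the endpoint-constrained search.
#' @param max_n exhaustive-search guard on the number of blocks (default
#'   12).
#' @param max_depth search-depth guard (default `length(ancestral) + 2`).
#' @return integer distance, or `Inf` when `derived` is unreachable under
#'   the constraints (within `max_depth`).
#' @export
min_inversion_distance <- function(ancestral, derived, pairs = NULL,
                                   max_n = 12L, max_depth = NULL) {
  n <- length(ancestral)
  if (n != length(derived) ||
      !setequal(abs(ancestral), abs(derived)) ||
      anyDuplicated(abs(ancestral)))
    stop("permutations must be over the same block universe", call. = FALSE)
  if (n > max_n)
    stop("n > max_n: exhaustive search refused; use an unconstrained ",
         "lower bound (e.g. breakpoint count / 2) instead", call. = FALSE)
  max_depth <- max_depth %||% (n + 2L)
  res <- scenario_search(ancestral, derived, pairs, max_depth,
                         enumerate = FALSE, max_scenarios = 1L)
  res$distance
}

#' Enumerate all minimal inversion scenarios
#'
#' All distinct orderings of minimal-length event sequences transforming
#' `ancestral` into `derived`; each scenario is verified by re-application.
#' Output is canonically ordered (lexicographic on the event sequence) and
#' capped at `max_scenarios` with a `truncated` flag.
#'
#' @inheritParams min_inversion_distance
#' @param max_scenarios cap on the number of scenarios returned (default
#'   1000).
#' @return list with `distance`, `scenarios` (list of event sequences; with
#'   `pairs` each event is a pair id, otherwise a `c(from, to)` slice) and
#'   `truncated` (logical). Unreachable targets give `distance = Inf` and
#'   an empty scenario list.
#' @export
enumerate_minimal_scenarios <- function(ancestral, derived, pairs = NULL,
                                        max_n = 12L, max_depth = NULL,
                                        max_scenarios = 1000L) {
  n <- length(ancestral)
  if (n > max_n) stop("n > max_n: exhaustive search refused", call. = FALSE)
  max_depth <- max_depth %||% (n + 2L)
  res <- scenario_search(ancestral, derived, pairs, max_depth,
                         enumerate = TRUE, max_scenarios = max_scenarios)
  ## verify every scenario by re-application
  for (sc in res$scenarios) {
    final <- if (is.null(pairs)) {
      apply_inversions(ancestral, do.call(rbind, sc))
    } else {
      st <- marker_state_from(ancestral, pairs)
      for (p in sc) st <- state_apply(st, p)
      state_blocks(st)
    }
    stopifnot(identical(as.integer(final), as.integer(derived)))
  }
  res
}

marker_state_from <- function(ancestral, pairs) {
  if (!identical(as.integer(ancestral), seq_along(ancestral)))
    stop("the endpoint-constrained search requires the ancestral ",
         "arrangement to be the identity (+1..+n)", call. = FALSE)
  marker_state(length(ancestral), pairs)
}

scenario_search <- function(ancestral, derived, pairs, max_depth,
                            enumerate, max_scenarios) {
  target <- as.integer(derived)
  if (is.null(pairs)) {
    n <- length(ancestral)
    slices <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
    slices <- slices[, c("row", "col"), drop = FALSE]
    init <- as.integer(ancestral)
    key <- function(s) paste(s, collapse = ",")
    blocks <- identity
    moves <- function(s) seq_len(nrow(slices))
    apply_move <- function(s, m) {
      i <- slices[m, 1]; j <- slices[m, 2]
      s[i:j] <- -rev(s[i:j]); s
    }
    move_label <- function(m) unname(c(slices[m, 1], slices[m, 2]))
  } else {
    init <- marker_state_from(ancestral, pairs)
    key <- state_key
    blocks <- state_blocks
    moves <- state_moves
    apply_move <- state_apply
    move_label <- identity
  }

  if (identical(as.integer(blocks(init)), target))
    return(list(distance = 0L, scenarios = list(), truncated = FALSE))

  ## BFS for the distance
  frontier <- list(init)
  visited <- new.env(hash = TRUE, parent = emptyenv())
  assign(key(init), 0L, envir = visited)
  distance <- Inf
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (s in frontier) {
      for (m in moves(s)) {
        s2 <- apply_move(s, m)
        k2 <- key(s2)
        if (!is.null(visited[[k2]])) next
        assign(k2, depth, envir = visited)
        if (identical(as.integer(blocks(s2)), target)) distance <- depth
        nxt[[length(nxt) + 1L]] <- s2
      }
    }
    if (is.finite(distance)) break
    frontier <- nxt
    if (length(frontier) == 0L) break
  }
  if (!enumerate || !is.finite(distance))
    return(list(distance = distance, scenarios = list(),
                truncated = FALSE))

  ## DFS to the exact depth, collecting event sequences
  found <- list(); truncated <- FALSE
  dfs <- function(s, path, remaining) {
    if (truncated) return()
    if (remaining == 0L) {
      if (identical(as.integer(blocks(s)), target)) {
        if (length(found) >= max_scenarios) { truncated <<- TRUE; return() }
        found[[length(found) + 1L]] <<- path
      }
      return()
    }
    for (m in moves(s)) {
      dfs(apply_move(s, m), c(path, list(move_label(m))), remaining - 1L)
    }
  }
  dfs(init, list(), distance)
  ## canonical order
  lab <- vapply(found, function(p)
    paste(vapply(p, paste, "", collapse = "-"), collapse = ";"), "")
  found <- found[order(lab)]
  list(distance = distance, scenarios = found, truncated = truncated)
}

## ---- sequence-level application -----------------------------------------

#' Invert a genomic segment in place
#'
#' Reverse-complements `[start, end)` of the sequence (0-based,
#' half-open).
#'
#' @param g a [genome_record()].
#' @param start,end segment bounds.
#' @return the modified `genome_record`.
#' @export
invert_segment <- function(g, start, end) {
  stopifnot(inherits(g, "genome_record"))
  if (start < 0L || end > g$length || start >= end)
    stop("segment out of range", call. = FALSE)
  seq <- paste0(subseq0(g$seq, 0L, start),
                reverse_complement(subseq0(g$seq, start, end)),
                subseq0(g$seq, end, g$length))
  genome_record(g$id, seq, circular = g$circular,
                origin_offset = g$origin_offset)
}

#' Apply a repeat-pair-bounded inversion at sequence level
#'
#' Reverse-complements the half-open interval between the core midpoints
#' of the two copies of a repeat pair, updates the coordinates and strands
#' of all tracked copies, and returns the new genome and pair table. The
#' pair must currently be in inverted orientation (opposite strands).
#'
#' @param g a [genome_record()].
#' @param pairs data.frame with columns `pair`, `a_start`, `a_end`,
#'   `a_strand`, `b_start`, `b_end`, `b_strand` (0-based half-open).
#' @param pair_id id of the pair to recombine.
#' @return list with `genome`, `pairs` (updated), `m1`, `m2` (the inverted
#'   interval).
#' @export
invert_between_pair <- function(g, pairs, pair_id) {
  upd <- pair_inversion_coords(pairs, pair_id)
  g2 <- invert_segment(g, upd$m1, upd$m2)
  list(genome = g2, pairs = upd$pairs, m1 = upd$m1, m2 = upd$m2)
}

## coordinate-level part of invert_between_pair: returns the inverted
## interval and the updated pair table without touching any sequence
pair_inversion_coords <- function(pairs, pair_id) {
  row <- which(pairs$pair == pair_id)
  if (length(row) != 1L) stop("unknown pair id ", pair_id, call. = FALSE)
  p <- pairs[row, ]
  if (p$a_strand == p$b_strand)
    stop("pair ", pair_id, " is in direct orientation: not a legal ",
         "inversion substrate", call. = FALSE)
  if (p$a_start <= p$b_start) {
    ls <- p$a_start; le <- p$a_end; rs <- p$b_start; re <- p$b_end
  } else {
    ls <- p$b_start; le <- p$b_end; rs <- p$a_start; re <- p$a_end
  }
  m1 <- ls + (le - ls) %/% 2L
  m2 <- rs + (re - rs) %/% 2L
  ## remap every other copy lying fully inside [m1, m2)
  remap <- function(s, e, strand) {
    if (s >= m1 && e <= m2) {
      c(m1 + m2 - e, m1 + m2 - s, if (strand == "+") "-" else "+")
    } else c(s, e, strand)
  }
  for (r in seq_len(nrow(pairs))) {
    if (r == row) next   # the bounding pair's copies straddle the cuts
    a <- remap(pairs$a_start[r], pairs$a_end[r], pairs$a_strand[r])
    b <- remap(pairs$b_start[r], pairs$b_end[r], pairs$b_strand[r])
    pairs$a_start[r] <- as.integer(a[1]); pairs$a_end[r] <- as.integer(a[2])
    pairs$a_strand[r] <- a[3]
    pairs$b_start[r] <- as.integer(b[1]); pairs$b_end[r] <- as.integer(b[2])
    pairs$b_strand[r] <- b[3]
  }
  list(pairs = pairs, m1 = m1, m2 = m2)
}

#' Orientation of every repeat pair along a scenario
#'
#' Applies a scenario (an ordered vector of pair ids) at sequence level and
#' reports, after each event, whether each tracked pair is in direct or
#' inverted orientation. A pair with exactly one copy inside an event's
#' span flips; a pair with both copies inside, or both outside, keeps its
#' orientation.
#'
#' @param g ancestral [genome_record()].
#' @param pairs repeat-pair table as for [invert_between_pair()].
#' @param scenario integer vector of pair ids, applied in order.
#' @return list with `timeline` (data.frame: `step`, `event_pair`, one
#'   orientation column per pair) and `genome` (the final sequence).
#' @export
repeat_orientation_timeline <- function(g, pairs, scenario) {
  orient <- function(ps) ifelse(ps$a_strand == ps$b_strand,
                                "direct", "inverted")
  snap <- function(step, ev, ps) {
    d <- data.frame(step = step, event_pair = ev)
    o <- orient(ps)
    for (i in seq_len(nrow(ps))) d[[paste0("pair_", ps$pair[i])]] <- o[i]
    d
  }
  out <- snap(0L, NA_integer_, pairs)
  for (s in seq_along(scenario)) {
    res <- invert_between_pair(g, pairs, scenario[s])
    g <- res$genome; pairs <- res$pairs
    out <- rbind(out, snap(s, scenario[s], pairs))
  }
  list(timeline = out, genome = g, pairs = pairs)
}
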