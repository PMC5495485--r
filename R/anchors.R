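#' Exact-match anchors between two genomes
#'
#' Computes all maximal exact matches (MUM-style anchors) of length `>=
#' min_len` between `g1` and `g2`, in both orientations of `g2`. Seeding uses
#' shared k-mers; k-mers occurring more than `max_kmer_freq` times in either
#' genome are masked from seeding (repeat families are recovered later by the
#' breakpoint forensics stage). Seeds on a common diagonal are merged into
#' runs and extended base-by-base to maximality; `N` never matches. If `g2`
#' is circular it is doubled internally and wrapped hits are de-duplicated
#' modulo its length.
#'
#' @param g1,g2 [genome_record()] objects.
#' @param k k-mer size for seeding (>= 8, default 16).
#' @param min_len minimum anchor length to report (>= k, default 24).
#' @param max_kmer_freq seeding mask threshold (default 10).
#' @return data.frame of anchors sorted by `q_start` with 0-based half-open
#'   columns `q_start`, `q_end`, `s_start`, `s_end`, `orientation` (`+`/`-`)
#'   and `length`. `s_end` may exceed `g2$length` for matches wrapping the
#'   origin of a circular `g2`.
#' @export
find_anchors <- function(g1, g2, k = 16L, min_len = 24L,
                         max_kmer_freq = 10L) {
  stopifnot(inherits(g1, "genome_record"), inherits(g2, "genome_record"))
  k <- as.integer(k); min_len <- as.integer(min_len)
  if (k < 8L) stop("k must be >= 8", call. = FALSE)
  if (min_len < k) stop("min_len must be >= k", call. = FALSE)
  if (k > g1$length || k > g2$length)
    stop("k larger than a genome", call. = FALSE)

  qseq <- g1$seq
  len2 <- g2$length
  sseq <- if (g2$circular) paste0(g2$seq, g2$seq) else g2$seq
  slen <- nchar(sseq)

  qk <- kmers_of(qseq, k)
  masked_q <- kmer_mask(qk, max_kmer_freq)

  collect <- function(target, orientation) {
    sk <- kmers_of(target, k)
    masked_s <- kmer_mask(sk, max_kmer_freq)
    dtq <- data.table(kmer = qk, qpos = seq_along(qk) - 1L)[!masked_q]
    dts <- data.table(kmer = sk, spos = seq_along(sk) - 1L)[!masked_s]
    hits <- dtq[dts, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
    if (nrow(hits) == 0L) return(NULL)
    hits[, diag := spos - qpos]
    data.table::setorder(hits, diag, qpos)
    hits[, run := seed_run_id(diag, qpos)]
    runs <- hits[, list(qpos = qpos[1L], spos = spos[1L],
                        len = .N + k - 1L), by = run]
    extend_maximal(runs, qseq, target, orientation)
  }

  fwd <- collect(sseq, "+")
  rev <- collect(reverse_complement(sseq), "-")
  if (!is.null(rev)) {
    ## map coordinates on the reverse complement back to the target strand
    rs <- slen - (rev$spos + rev$len)
    rev$spos <- rs
  }
  anch <- data.table::rbindlist(list(fwd, rev))
  if (is.null(anch) || nrow(anch) == 0L) return(empty_anchors())
  anch <- unique(anch, by = c("qpos", "spos", "len", "orientation"))
  anch <- anch[len >= min_len]
  if (g2$circular) {
    ## de-duplicate hits from the doubled sequence: map starts mod length,
    ## then drop anchors contained in a longer anchor on the same
    ## (mod-length) diagonal class — these are copies truncated at the
    ## doubled-string boundary
    anch[, s_mod := spos %% len2]
    anch <- unique(anch, by = c("qpos", "s_mod", "len", "orientation"))
    anch[, spos := s_mod][, s_mod := NULL]
    anch[, dclass := fifelse(orientation == "+",
                             (spos - qpos) %% len2,
                             (spos + qpos + len) %% len2)]
    data.table::setorder(anch, dclass, orientation, -len)
    keep <- rep(TRUE, nrow(anch))
    for (i in seq_len(nrow(anch))) {
      if (!keep[i]) next
      j <- i + 1L
      while (j <= nrow(anch) && anch$dclass[j] == anch$dclass[i] &&
             anch$orientation[j] == anch$orientation[i]) {
        if (anch$qpos[j] >= anch$qpos[i] &&
            anch$qpos[j] + anch$len[j] <= anch$qpos[i] + anch$len[i])
          keep[j] <- FALSE
        j <- j + 1L
      }
    }
    anch <- anch[keep][, dclass := NULL]
  }
  out <- data.frame(q_start = anch$qpos, q_end = anch$qpos + anch$len,
                    s_start = anch$spos, s_end = anch$spos + anch$len,
                    orientation = anch$orientation, length = anch$len)
  out <- out[order(out$q_start, out$s_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## run ids over (diagonal, consecutive qpos) seed chains
seed_run_id <- function(diag, qpos) {
  n <- length(diag)
  if (n == 0L) return(integer(0))
  same <- c(FALSE, diag[-1] == diag[-n] & qpos[-1] == qpos[-n] + 1L)
  cumsum(!same)
}

kmer_mask <- function(kmers, max_freq) {
  cnt <- data.table(kmer = kmers)[, list(n = .N), by = kmer]
  bad <- cnt$kmer[cnt$n > max_freq]
  data.table::`%chin%`(kmers, bad) | grepl("N", kmers, fixed = TRUE)
}

empty_anchors <- function() {
  data.frame(q_start = integer(0), q_end = integer(0), s_start = integer(0),
             s_end = integer(0), orientation = character(0),
             length = integer(0))
}

## Extend seed runs to maximal exact matches and drop duplicates. Works in
## the frame of (qseq, oriented target); N is encoded so it never matches.
extend_maximal <- function(runs, qseq, target, orientation) {
  qv <- seq_ints(qseq); sv <- seq_ints(target)
  qv[qv == 78L] <- -1L; sv[sv == 78L] <- -2L   # 78 == 'N'
  nq <- length(qv); ns <- length(sv)
  n <- nrow(runs)
  qs <- runs$qpos; ss <- runs$spos; ln <- runs$len
  for (i in seq_len(n)) {
    a <- qs[i]; b <- ss[i]; l <- ln[i]
    while (a > 0L && b > 0L && qv[a] == sv[b]) {
      a <- a - 1L; b <- b - 1L; l <- l + 1L
    }
    while (a + l < nq && b + l < ns && qv[a + l + 1L] == sv[b + l + 1L]) {
      l <- l + 1L
    }
    qs[i] <- a; ss[i] <- b; ln[i] <- l
  }
  unique(data.table(qpos = qs, spos = ss, len = ln,
                    orientation = orientation))
}

#' Chain anchors into synteny blocks
#'
#' Greedy single-linkage chaining of q-sorted anchors: an anchor joins the
#' current chain when it has the same orientation and both its q-gap and its
#' orientation-respecting s-gap to the previous anchor are within
#' `[-slack, max_gap]`. Chains spanning less than `min_block` on genome 1
#' are discarded; surviving blocks are renumbered 1..n along genome 1.
#' Leftmost-first and deterministic given sorted input.
#'
#' @param anchors data.frame from [find_anchors()].
#' @param max_gap maximum within-block gap in bp (default 20000).
#' @param min_block minimum block span in bp (default 5000).
#' @param slack tolerated overlap between chained anchors in bp (default
#'   1000); anchors at inversion borders can overlap by up to the repeat
#'   core length.
#' @param min_anchor_frac minimum fraction of a block's genome-1 span
#'   covered by exact matches (default 0.25). Guards against phantom
#'   blocks: the two mirror cross-matches of an inverted repeat pair lie
#'   on one anti-diagonal and would otherwise chain across the unrelated
#'   sequence between them.
#' @return data.frame with columns `id`, `q_start`, `q_end`, `s_start`,
#'   `s_end`, `orientation`, `n_anchors`, `anchor_bp` (0-based half-open).
#' @export
chain_to_blocks <- function(anchors, max_gap = 20000L, min_block = 5000L,
                            slack = 1000L, min_anchor_frac = 0.25) {
  if (nrow(anchors) == 0L) {
    return(data.frame(id = integer(0), q_start = integer(0),
                      q_end = integer(0), s_start = integer(0),
                      s_end = integer(0), orientation = character(0),
                      n_anchors = integer(0), anchor_bp = integer(0)))
  }
  ## MUM-style uniqueness: an anchor whose footprint on either genome is
  ## contained in a much longer anchor's footprint is a repeat-induced
  ## cross-match (e.g. a paralogous core matching its partner copy), not
  ## collinear backbone; such repeats are characterized later by the
  ## breakpoint forensics stage
  keep <- rep(TRUE, nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    li <- anchors$length[i]
    contained <- (anchors$q_start <= anchors$q_start[i] &
                    anchors$q_end >= anchors$q_end[i] |
                  anchors$s_start <= anchors$s_start[i] &
                    anchors$s_end >= anchors$s_end[i]) &
      anchors$length >= 2L * li
    if (any(contained)) keep[i] <- FALSE
  }
  anchors <- anchors[keep, , drop = FALSE]
  a <- anchors[order(anchors$q_start, anchors$s_start), , drop = FALSE]
  n <- nrow(a)
  chain <- integer(n); chain[1] <- 1L; cur <- 1L
  for (i in seq_len(n)[-1]) {
    p <- i - 1L
    q_gap <- a$q_start[i] - a$q_end[p]
    s_gap <- if (a$orientation[i] == "+") a$s_start[i] - a$s_end[p]
             else a$s_start[p] - a$s_end[i]
    ok <- a$orientation[i] == a$orientation[p] &&
      q_gap >= -slack && q_gap <= max_gap &&
      s_gap >= -slack && s_gap <= max_gap
    if (!ok) cur <- cur + 1L
    chain[i] <- cur
  }
  dt <- data.table(a, chain = chain)
  blocks <- dt[, list(q_start = min(q_start), q_end = max(q_end),
                      s_start = min(s_start), s_end = max(s_end),
                      orientation = orientation[1L], n_anchors = .N,
                      anchor_bp = sum(length)), by = chain]
  blocks <- blocks[(q_end - q_start) >= min_block &
                     anchor_bp >= min_anchor_frac * (q_end - q_start)]
  data.table::setorder(blocks, q_start)
  blocks[, id := seq_len(.N)][, chain := NULL]
  as.data.frame(blocks[, list(id, q_start, q_end, s_start, s_end,
                              orientation, n_anchors, anchor_bp)])
}

#' Signed permutation, breakpoints and inversion segments from blocks
#'
#' Lists the blocks in genome-2 order with signs encoding orientation,
#' reports every genome-2 adjacency that is not adjacent-and-co-oriented on
#' genome 1 as a breakpoint, and reports maximal runs of minus-oriented
#' blocks as inversion segments with their bp spans on both genomes.
#'
#' A breakpoint's junction joins two genome-1 locations that may be far
#' apart (one recombination-substrate copy sits at each); both
#' junction-facing endpoints are reported (`q_end_left`, `q_end_right`)
#' together with the junction's genome-2 gap.
#'
#' @param blocks data.frame from [chain_to_blocks()].
#' @param overlap_slack maximum tolerated overlap between blocks on either
#'   genome (default 1000 bp); larger overlaps raise an error suggesting
#'   re-chaining with a larger `min_block`.
#' @return list with elements `permutation` (signed integer vector),
#'   `breakpoints` (data.frame: `left_block`, `right_block`, `q_end_left`,
#'   `q_end_right`, `s_gap_start`, `s_gap_end`) and `inversions`
#'   (data.frame: `blocks`, `q_start`, `q_end`, `q_span`, `s_start`,
#'   `s_end`, `s_span`).
#' @export
blocks_to_permutation <- function(blocks, overlap_slack = 1000L) {
  n <- nrow(blocks)
  if (n == 0L)
    return(list(permutation = integer(0), breakpoints = empty_breakpoints(),
                inversions = empty_inversions()))
  check_disjoint <- function(start, end, axis) {
    o <- order(start)
    if (n > 1L && any(start[o][-1] - end[o][-n] < -overlap_slack))
      stop("blocks overlap on ", axis, " beyond slack; re-chain with a ",
           "larger min_block", call. = FALSE)
  }
  check_disjoint(blocks$q_start, blocks$q_end, "genome 1")
  check_disjoint(blocks$s_start, blocks$s_end, "genome 2")

  so <- order(blocks$s_start)
  b2 <- blocks[so, , drop = FALSE]
  perm <- ifelse(b2$orientation == "+", b2$id, -b2$id)

  bps <- empty_breakpoints()
  if (n > 1L) {
    for (p in seq_len(n - 1L)) {
      i <- p; j <- p + 1L
      conserved <- (b2$orientation[i] == "+" && b2$orientation[j] == "+" &&
                    b2$id[j] == b2$id[i] + 1L) ||
                   (b2$orientation[i] == "-" && b2$orientation[j] == "-" &&
                    b2$id[j] == b2$id[i] - 1L)
      if (conserved) next
      ## junction-facing q coordinates of the two blocks
      p1 <- if (b2$orientation[i] == "+") b2$q_end[i] else b2$q_start[i]
      p2 <- if (b2$orientation[j] == "+") b2$q_start[j] else b2$q_end[j]
      bps <- rbind(bps, data.frame(
        left_block = b2$id[i], right_block = b2$id[j],
        q_end_left = p1, q_end_right = p2,
        s_gap_start = b2$s_end[i], s_gap_end = max(b2$s_end[i],
                                                   b2$s_start[j])))
    }
  }

  inv <- empty_inversions()
  is_neg <- b2$orientation == "-"
  if (any(is_neg)) {
    r <- rle(is_neg)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (w in which(r$values)) {
      idx <- starts[w]:ends[w]
      inv <- rbind(inv, data.frame(
        blocks = paste(b2$id[idx], collapse = ","),
        q_start = min(b2$q_start[idx]), q_end = max(b2$q_end[idx]),
        q_span = max(b2$q_end[idx]) - min(b2$q_start[idx]),
        s_start = min(b2$s_start[idx]), s_end = max(b2$s_end[idx]),
        s_span = max(b2$s_end[idx]) - min(b2$s_start[idx])))
    }
  }
  list(permutation = as.integer(perm), breakpoints = bps, inversions = inv)
}

empty_breakpoints <- function() {
  data.frame(left_block = integer(0), right_block = integer(0),
             q_end_left = integer(0), q_end_right = integer(0),
             s_gap_start = integer(0), s_gap_end = integer(0))
}

empty_inversions <- function() {
  data.frame(blocks = character(0), q_start = integer(0), q_end = integer(0),
             q_span = integer(0), s_start = integer(0), s_end = integer(0),
             s_span = integer(0))
}

#' One-stop genome comparison
#'
#' Runs [find_anchors()], [chain_to_blocks()] and [blocks_to_permutation()]
#' with shared defaults.
#'
#' @inheritParams find_anchors
#' @inheritParams chain_to_blocks
#' @return list with `anchors`, `blocks`, `permutation`, `breakpoints`,
#'   `inversions`.
#' @export
compare_genomes <- function(g1, g2, k = 16L, min_len = 24L,
                            max_kmer_freq = 10L, max_gap = 20000L,
                            min_block = 5000L, slack = 1000L) {
  anchors <- find_anchors(g1, g2, k = k, min_len = min_len,
                          max_kmer_freq = max_kmer_freq)
  blocks <- chain_to_blocks(anchors, max_gap = max_gap,
                            min_block = min_block, slack = slack)
  res <- blocks_to_permutation(blocks, overlap_slack = slack)
  c(list(anchors = anchors, blocks = blocks), res)
}
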