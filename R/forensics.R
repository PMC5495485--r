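## Stage 2: characterize the recombination substrates at breakpoints —
## maximal perfectly conserved shared segments (direct or inverted), global
## percent identity of breakpoint flanks, and crossover localization
## between informative mismatches.

## All maximal exact shared segments between two plain strings, seeded with
## unmasked k-mers and extended to maximality. Exact for all shared
## segments of length >= k. Columns: a_start, b_start, len (0-based).
shared_exact_matches <- function(sa, sb, k = 20L) {
  k <- as.integer(min(k, nchar(sa), nchar(sb)))
  ka <- kmers_of(sa, k); kb <- kmers_of(sb, k)
  keep_a <- !grepl("N", ka, fixed = TRUE)
  keep_b <- !grepl("N", kb, fixed = TRUE)
  dta <- data.table(kmer = ka, qpos = seq_along(ka) - 1L)[keep_a]
  dtb <- data.table(kmer = kb, spos = seq_along(kb) - 1L)[keep_b]
  hits <- dta[dtb, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(hits) == 0L)
    return(data.frame(a_start = integer(0), b_start = integer(0),
                      len = integer(0)))
  hits[, diag := spos - qpos]
  data.table::setorder(hits, diag, qpos)
  hits[, run := seed_run_id(diag, qpos)]
  runs <- hits[, list(qpos = qpos[1L], spos = spos[1L], len = .N + k - 1L),
               by = run]
  m <- extend_maximal(runs, sa, sb, "+")
  data.frame(a_start = m$qpos, b_start = m$spos, len = m$len)
}

## Exhaustive diagonal scan for the longest common substring; exact for any
## length, O(n*m). Used when no shared k-mer exists (true LCS below seed
## size). Returns list(len, a_start, b_start).
lcs_scan <- function(sa, sb) {
  av <- seq_ints(sa); bv <- seq_ints(sb)
  av[av == 78L] <- -1L; bv[bv == 78L] <- -2L
  na <- length(av); nb <- length(bv)
  best <- list(len = 0L, a_start = 0L, b_start = 0L)
  for (d in (-(na - 1L)):(nb - 1L)) {
    ai <- max(1L, 1L - d); bi <- ai + d
    n <- min(na - ai, nb - bi) + 1L
    if (n < 1L || n <= best$len) next
    eq <- av[ai:(ai + n - 1L)] == bv[bi:(bi + n - 1L)]
    r <- rle(eq)
    if (!any(r$values)) next
    lens <- r$lengths[r$values]
    if (max(lens) <= best$len) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    w <- which(r$values)[which.max(lens)]
    best <- list(len = max(lens),
                 a_start = ai + starts[w] - 2L,    # 0-based
                 b_start = bi + starts[w] - 2L)
  }
  best
}

#' Longest perfectly shared segment between two sequences
#'
#' Finds the longest common substring of `seqA` and `seqB` (orientation
#' `"direct"`) or of `seqA` and the reverse complement of `seqB`
#' (orientation `"inverted"`). Exact; `N` never matches; ties broken by
#' smallest position in A, then in B. Positions reported on the input
#' strands (for `"inverted"`, `b_start`/`b_end` delimit the segment on
#' `seqB` as given, whose reverse complement equals the A segment).
#'
#' @param seqA,seqB nucleotide strings.
#' @param orientation `"direct"` or `"inverted"`.
#' @return list with `core_len`, `a_start`, `a_end`, `b_start`, `b_end`
#'   (0-based half-open); `core_len = 0` when nothing is shared.
#' @export
longest_shared_segment <- function(seqA, seqB,
                                   orientation = c("direct", "inverted")) {
  orientation <- match.arg(orientation)
  seqA <- toupper(seqA); seqB <- toupper(seqB)
  check_dna(seqA, "seqA"); check_dna(seqB, "seqB")
  if (!nzchar(seqA) || !nzchar(seqB)) stop("empty sequence", call. = FALSE)
  sb <- if (orientation == "inverted") reverse_complement(seqB) else seqB
  k <- 20L
  cand <- shared_exact_matches(seqA, sb, k = k)
  if (nrow(cand) > 0L && max(cand$len) >= min(k, nchar(seqA), nchar(sb))) {
    best_len <- max(cand$len)
    cand <- cand[cand$len == best_len, , drop = FALSE]
    cand <- cand[order(cand$a_start, cand$b_start), , drop = FALSE]
    hit <- list(len = best_len, a_start = cand$a_start[1],
                b_start = cand$b_start[1])
  } else {
    hit <- lcs_scan(seqA, sb)
  }
  b_start <- hit$b_start; b_end <- hit$b_start + hit$len
  if (orientation == "inverted" && hit$len > 0L) {
    nb <- nchar(seqB)
    b_start <- nb - hit$b_start - hit$len
    b_end <- nb - hit$b_start
  }
  list(core_len = hit$len, a_start = hit$a_start,
       a_end = hit$a_start + hit$len, b_start = b_start, b_end = b_end,
       orientation = orientation)
}

#' Global percent identity of two sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1, gap open
#' -2, gap extend -1; identity is matches over alignment columns, as a
#' percentage rounded to 0.1.
#'
#' @param seqA,seqB nucleotide strings.
#' @return numeric percentage in `[0, 100]`.
#' @export
percent_identity <- function(seqA, seqB) {
  seqA <- toupper(seqA); seqB <- toupper(seqB)
  check_dna(seqA, "seqA"); check_dna(seqB, "seqB")
  if (!nzchar(seqA) || !nzchar(seqB)) stop("empty sequence", call. = FALSE)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(seqA, seqB, substitutionMatrix = mat,
                                      gapOpening = 2, gapExtension = 1,
                                      type = "global")
  round(100 * Biostrings::nmatch(pa) / Biostrings::nchar(pa), 1)
}

#' Localize a recombination crossover between informative positions
#'
#' Parents must be alignable without gaps over the analyzed window (equal
#' lengths); informative positions are columns where the parents differ.
#' The call is the maximal interval `(l, r]` such that the recombinant
#' matches parent A at all informative positions `<= l` and parent B at all
#' informative positions `>= r`.
#'
#' @param parentA,parentB,recombinant nucleotide strings of equal length.
#' @return list with `status` (`"crossover"`, `"no_crossover"`),
#'   `left_informative`, `right_informative` (0-based positions; the
#'   crossover lies in `(left_informative, right_informative]`), and
#'   `n_informative`. Chimeric patterns needing more than one crossover, or
#'   a recombinant matching neither parent at an informative position,
#'   raise an error.
#' @export
localize_crossover <- function(parentA, parentB, recombinant) {
  a <- toupper(parentA); b <- toupper(parentB); r <- toupper(recombinant)
  if (nchar(a) != nchar(b) || nchar(a) != nchar(r))
    stop("parents and recombinant must have equal length ",
         "(gapped case not supported)", call. = FALSE)
  av <- seq_ints(a); bv <- seq_ints(b); rv <- seq_ints(r)
  inf <- which(av != bv)
  if (length(inf) == 0L)
    return(list(status = "no_crossover", left_informative = NA_integer_,
                right_informative = NA_integer_, n_informative = 0L))
  mA <- rv[inf] == av[inf]; mB <- rv[inf] == bv[inf]
  if (any(!mA & !mB))
    stop("recombinant matches neither parent at informative position ",
         inf[which(!mA & !mB)[1]] - 1L, call. = FALSE)
  if (all(mA) || all(mB))
    return(list(status = "no_crossover", left_informative = NA_integer_,
                right_informative = NA_integer_,
                n_informative = length(inf)))
  state <- ifelse(mA, "A", "B")
  switches <- sum(state[-1] != state[-length(state)])
  if (switches > 1L || state[1] != "A")
    stop("multiple crossovers required to explain the recombinant",
         call. = FALSE)
  l <- inf[max(which(state == "A"))] - 1L
  r_pos <- inf[min(which(state == "B"))] - 1L
  list(status = "crossover", left_informative = l,
       right_informative = r_pos, n_informative = length(inf))
}

#' Characterize repeat substrates at synteny breakpoints
#'
#' Collects the genome-1 junction endpoints of all breakpoints (the two
#' `q_end_*` coordinates of each), clusters endpoints closer than
#' `merge_dist` (duplicate references to the same junction can differ by
#' up to the repeat core length because anchors extend through the core),
#' extracts `window` bp of flank around each endpoint cluster, and finds,
#' for every pair of endpoint windows, the maximal perfectly shared
#' segment in inverted and direct orientation. Endpoints are then paired
#' greedily by descending core length (each endpoint used once), which
#' recovers the true repeat-pair pairing even under nested or overlapping
#' inversion histories where the two junctions of one inverted run belong
#' to different pairs. Cores shorter than `min_core` are not reported.
#' Global percent identity of the two paired windows is computed for
#' reported pairs, and cores from different pairs are checked for shared
#' segments `>= inter_pair_min` bp (attribute `inter_pair_shared`).
#'
#' @param g1 ancestral [genome_record()].
#' @param breakpoints data.frame from [blocks_to_permutation()].
#' @param window flank window in bp around each endpoint (default 2000).
#' @param min_core smallest core to report (default 20 bp).
#' @param merge_dist endpoint clustering distance (default 2000 bp).
#' @param inter_pair_min threshold for the cross-pair similarity check
#'   (default 20 bp).
#' @return data.frame of repeat pairs: `endpoint_a`, `endpoint_b`
#'   (endpoint cluster indices along the genome), `a_start`, `a_end`,
#'   `b_start`, `b_end` (genome coordinates of the shared core, 0-based
#'   half-open), `orientation` (`direct`/`inverted`), `core_len`,
#'   `identity_pct`; attribute `inter_pair_shared` (logical) and
#'   attribute `endpoints` (the clustered endpoint coordinates).
#' @export
characterize_breakpoints <- function(g1, breakpoints, window = 2000L,
                                     min_core = 20L, merge_dist = 2000L,
                                     inter_pair_min = 20L) {
  stopifnot(inherits(g1, "genome_record"))
  empty <- data.frame(endpoint_a = integer(0), endpoint_b = integer(0),
                      a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      orientation = character(0), core_len = integer(0),
                      identity_pct = numeric(0))
  attr(empty, "inter_pair_shared") <- FALSE
  attr(empty, "endpoints") <- numeric(0)
  if (nrow(breakpoints) == 0L) return(empty)
  window <- as.integer(window)
  if (window < 200L) stop("window must be >= 200 bp", call. = FALSE)

  ## cluster junction endpoints
  ep <- sort(c(breakpoints$q_end_left, breakpoints$q_end_right))
  grp <- cumsum(c(TRUE, diff(ep) > merge_dist))
  centers <- as.integer(round(tapply(ep, grp, function(x)
    (min(x) + max(x)) / 2)))
  lo <- as.integer(tapply(ep, grp, min))
  hi <- as.integer(tapply(ep, grp, max))
  nb <- length(centers)

  ext <- function(from, to) {           # clipped/wrapped window extraction
    if (g1$circular) {
      from2 <- from %% g1$length; span <- to - from
      subseq0(paste0(g1$seq, g1$seq), from2, from2 + span)
    } else {
      if (from < 0L || to > g1$length)
        warning("breakpoint window truncated at genome bounds")
      subseq0(g1$seq, max(0L, from), min(g1$length, to))
    }
  }
  win_from <- lo - window
  win_to <- hi + window
  wins <- mapply(ext, win_from, win_to)
  win0 <- if (g1$circular) win_from else pmax(0L, win_from)

  if (nb < 2L) return(empty)
  k_seed <- min(20L, max(12L, as.integer(min_core)))
  cand <- list()
  for (i in seq_len(nb - 1L)) for (j in (i + 1L):nb) {
    for (orient in c("inverted", "direct")) {
      wb <- if (orient == "inverted") reverse_complement(wins[j]) else wins[j]
      m <- shared_exact_matches(wins[i], wb, k = k_seed)
      if (nrow(m) == 0L) next
      best <- m[which.max(m$len), , drop = FALSE]
      if (best$len < min_core) next
      cand[[length(cand) + 1L]] <- data.frame(
        ep_a = i, ep_b = j, orientation = orient, core_len = best$len,
        wa = best$a_start, wb = best$b_start)
    }
  }
  if (length(cand) == 0L) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$core_len, cand$ep_a, cand$ep_b), , drop = FALSE]

  used <- logical(nb); out <- NULL
  for (r in seq_len(nrow(cand))) {
    i <- cand$ep_a[r]; j <- cand$ep_b[r]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    L <- cand$core_len[r]
    a_start <- win0[i] + cand$wa[r]
    wlen_j <- nchar(wins[j])
    b_start <- if (cand$orientation[r] == "inverted")
      win0[j] + (wlen_j - cand$wb[r] - L) else win0[j] + cand$wb[r]
    if (g1$circular) { a_start <- a_start %% g1$length
                       b_start <- b_start %% g1$length }
    idp <- percent_identity(wins[i],
                            if (cand$orientation[r] == "inverted")
                              reverse_complement(wins[j]) else wins[j])
    out <- rbind(out, data.frame(
      endpoint_a = i, endpoint_b = j, a_start = a_start,
      a_end = a_start + L, b_start = b_start, b_end = b_start + L,
      orientation = cand$orientation[r], core_len = L, identity_pct = idp))
  }
  if (is.null(out)) return(empty)
  rownames(out) <- NULL

  inter <- FALSE
  if (nrow(out) > 1L) {
    cores <- vapply(seq_len(nrow(out)), function(r) {
      s <- extract_circular(g1, out$a_start[r], out$a_end[r]); s
    }, "")
    for (i in seq_len(nrow(out) - 1L)) for (j in (i + 1L):nrow(out)) {
      for (sj in c(cores[j], reverse_complement(cores[j]))) {
        m <- shared_exact_matches(cores[i], sj, k = inter_pair_min)
        if (nrow(m) > 0L && max(m$len) >= inter_pair_min) inter <- TRUE
      }
    }
  }
  attr(out, "inter_pair_shared") <- inter
  attr(out, "endpoints") <- centers
  out
}

#' Marker table for the endpoint-constrained scenario search
#'
#' Converts recovered repeat pairs into the adjacency/strand table
#' consumed by [marker_state()]: each copy's core midpoint is assigned the
#' adjacency index of the block gap it falls into (ancestral block order),
#' copy `a` is taken as `+` strand and copy `b` as `+`/`-` according to
#' the pair orientation.
#'
#' @param blocks data.frame from [chain_to_blocks()].
#' @param repeat_pairs data.frame from [characterize_breakpoints()].
#' @return data.frame with columns `pair`, `pos_a`, `pos_b`, `strand_a`,
#'   `strand_b`.
#' @export
ancestral_marker_table <- function(blocks, repeat_pairs) {
  ## block centers, not edges: anchors extend through repeat cores, so
  ## block edges overlap the junction by up to the core length
  ctr <- sort((blocks$q_start + blocks$q_end) / 2)
  adj_of <- function(m) sum(ctr < m)
  out <- NULL
  for (r in seq_len(nrow(repeat_pairs))) {
    ma <- (repeat_pairs$a_start[r] + repeat_pairs$a_end[r]) %/% 2L
    mb <- (repeat_pairs$b_start[r] + repeat_pairs$b_end[r]) %/% 2L
    sa <- "+"
    sb <- if (repeat_pairs$orientation[r] == "inverted") "-" else "+"
    pa <- adj_of(ma); pb <- adj_of(mb)
    if (ma > mb) { tmp <- pa; pa <- pb; pb <- tmp
                   tmp <- sa; sa <- sb; sb <- tmp }
    out <- rbind(out, data.frame(pair = r, pos_a = pa, pos_b = pb,
                                 strand_a = sa, strand_b = sb))
  }
  out
}

## Extract [start, end) from a genome, wrapping if circular.
extract_circular <- function(g, start, end) {
  if (!g$circular || (start >= 0L && end <= g$length))
    return(subseq0(g$seq, max(0L, start), min(g$length, end)))
  start <- start %% g$length
  subseq0(paste0(g$seq, g$seq), start, start + (end - start))
}
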