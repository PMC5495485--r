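# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately use different algorithms from the package code
# paths they check.

# Longest common substring by binary search over length with exact
# substring-set intersection (no hashing, no diagonal scan).
oracle_lcs_len <- function(sa, sb) {
  n <- min(nchar(sa), nchar(sb))
  if (n == 0) return(0L)
  has_shared <- function(L) {
    if (L == 0L) return(TRUE)
    subs_a <- unique(substring(sa, 1:(nchar(sa) - L + 1L),
                               L:nchar(sa)))
    subs_b <- unique(substring(sb, 1:(nchar(sb) - L + 1L),
                               L:nchar(sb)))
    subs_a <- subs_a[!grepl("N", subs_a, fixed = TRUE)]
    any(subs_a %in% subs_b)
  }
  lo <- 0L; hi <- n
  while (lo < hi) {
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (has_shared(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

# All maximal exact matches >= min_len between two sequences by full
# per-diagonal scan (both orientations), for small inputs only.
oracle_anchors <- function(sa, sb, min_len) {
  scan_orient <- function(sb_o, orientation) {
    av <- utf8ToInt(sa); bv <- utf8ToInt(sb_o)
    av[av == 78L] <- -1L; bv[bv == 78L] <- -2L
    na <- length(av); nb <- length(bv)
    out <- NULL
    for (d in (-(na - 1L)):(nb - 1L)) {
      ai <- max(1L, 1L - d); bi <- ai + d
      n <- min(na - ai, nb - bi) + 1L
      if (n < min_len) next
      r <- rle(av[ai:(ai + n - 1L)] == bv[bi:(bi + n - 1L)])
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (w in which(r$values & r$lengths >= min_len)) {
        q0 <- ai + starts[w] - 2L; s0 <- bi + starts[w] - 2L
        len <- r$lengths[w]
        s_start <- if (orientation == "-") nb - s0 - len else s0
        out <- rbind(out, data.frame(q_start = q0, s_start = s_start,
                                     length = len,
                                     orientation = orientation))
      }
    }
    out
  }
  res <- rbind(scan_orient(sb, "+"),
               scan_orient(reverse_complement(sb), "-"))
  if (is.null(res)) return(res)
  res[order(res$q_start, res$s_start, res$orientation), , drop = FALSE]
}

# Minimal inversion count by iterative-deepening enumeration of all slice
# sequences (unconstrained moves), up to max_d.
oracle_inv_distance <- function(anc, der, max_d = 3L) {
  if (identical(as.integer(anc), as.integer(der))) return(0L)
  n <- length(anc)
  slices <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  states <- list(as.integer(anc))
  for (d in seq_len(max_d)) {
    nxt <- list()
    for (s in states) {
      for (m in seq_len(nrow(slices))) {
        i <- slices[m, 1]; j <- slices[m, 2]
        s2 <- s; s2[i:j] <- -rev(s2[i:j])
        if (identical(s2, as.integer(der))) return(d)
        nxt[[length(nxt) + 1L]] <- s2
      }
    }
    states <- nxt
  }
  Inf
}

# Brute-force read placement: Hamming distance at every position on both
# strands (circular-aware), returning best mismatch count, its
# multiplicity, and one best position.
oracle_map_read <- function(read, refseq, circular = FALSE) {
  L <- nchar(read)
  ext <- if (circular) paste0(refseq, substr(refseq, 1, L)) else refseq
  rv <- utf8ToInt(ext); rv[rv == 78L] <- -1L
  npos <- if (circular) nchar(refseq) else nchar(refseq) - L + 1L
  W <- t(sapply(seq_len(npos), function(p) rv[p:(p + L - 1L)]))
  best <- Inf; n_best <- 0L; bpos <- NA; bstrand <- NA
  for (s in c("+", "-")) {
    rd <- if (s == "+") read else reverse_complement(read)
    ri <- utf8ToInt(rd); ri[ri == 78L] <- -2L
    mm <- rowSums(W != matrix(ri, nrow = npos, ncol = L, byrow = TRUE))
    mn <- min(mm)
    if (mn < best) {
      best <- mn; n_best <- sum(mm == mn)
      bpos <- which.min(mm) - 1L; bstrand <- s
    } else if (mn == best) n_best <- n_best + sum(mm == mn)
  }
  list(best = best, n_best = n_best, pos = bpos, strand = bstrand)
}

# Parse the truth metadata that simulate_reads() embeds in read names.
read_meta <- function(ids, field) {
  vapply(strsplit(ids, "|", fixed = TRUE), function(x) {
    hit <- grep(paste0("^", field, "="), x, value = TRUE)
    sub(paste0("^", field, "="), "", hit[1])
  }, "")
}

random_test_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A genome pair differing by one planted inversion between inverted
# repeat copies, built by hand (not via the generator under test).
planted_inversion_pair <- function(len = 60000L, inv_from = 20000L,
                                   inv_to = 30000L, seed = 1L) {
  set.seed(seed)
  base <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                collapse = "")
  derived <- paste0(substr(base, 1, inv_from),
                    reverse_complement(substr(base, inv_from + 1, inv_to)),
                    substr(base, inv_to + 1, len))
  list(g1 = genome_record("anc", base),
       g2 = genome_record("der", derived))
}
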