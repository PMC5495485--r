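## Stage 5: read-based genotyping of inversion alleles and plasmid copy
## number. A bespoke seed-and-extend mapper keeps the pipeline
## self-contained and desk-testable: exact k-mer seeds at max_mismatch+1
## disjoint offsets (pigeonhole: a read with <= max_mismatch substitutions
## always has one clean seed), ungapped extension, unique-best placement.

#' Map reads to a reference by seed-and-extend
#'
#' Ungapped, deterministic mapping: exact seeds of length `seed_k` at
#' `max_mismatch + 1` disjoint offsets per strand, candidate positions
#' scored by Hamming distance, and a read is placed iff it has a unique
#' best position with `<= max_mismatch` mismatches. Reads tying over
#' several best positions (e.g. inside a two-copy exact repeat) are
#' `ambiguous`; all reads must share one length.
#'
#' @param reads data.frame with columns `id`, `seq` (as from
#'   [simulate_reads()] or [load_fastq()]).
#' @param ref [genome_record()] (circular references are handled with
#'   wrap-around).
#' @param seed_k seed length (default 21).
#' @param max_mismatch maximum mismatches for placement (default 3).
#' @return data.frame: `read_id`, `pos` (0-based leftmost reference
#'   coordinate, NA unless mapped), `strand` (alignment strand: `-` means
#'   the reverse complement of the read matches the reference),
#'   `mismatches`, `status` (`mapped`/`ambiguous`/`unmapped`).
#' @export
map_reads <- function(reads, ref, seed_k = 21L, max_mismatch = 3L) {
  stopifnot(inherits(ref, "genome_record"))
  n <- nrow(reads)
  if (n == 0L)
    return(data.frame(read_id = character(0), pos = integer(0),
                      strand = character(0), mismatches = integer(0),
                      status = character(0)))
  out <- data.frame(read_id = reads$id, pos = NA_integer_,
                    strand = NA_character_, mismatches = NA_integer_,
                    status = rep("unmapped", n))
  L <- unique(nchar(reads$seq))
  if (length(L) != 1L)
    stop("all reads must have equal length (v1 mapper)", call. = FALSE)
  if (L < 2L * seed_k)
    stop("reads must be at least 2*seed_k long", call. = FALSE)
  seed_k <- as.integer(seed_k)

  ext <- if (ref$circular) paste0(ref$seq, subseq0(ref$seq, 0L, L)) else
    ref$seq
  ref_int <- seq_ints(ext)
  ref_int[ref_int == 78L] <- -1L              # N never matches
  idx_k <- kmers_of(ext, seed_k)                    # doubled extension so
  index <- data.table(kmer = idx_k,                 # wrapping seeds hit
                      rpos = seq_along(idx_k) - 1L)
  max_pos <- if (ref$circular) ref$length - 1L else ref$length - L

  n_seeds <- max_mismatch + 1L
  offs <- unique(pmin((seq_len(n_seeds) - 1L) * seed_k, L - seed_k))

  fwd <- reads$seq
  rvc <- reverse_complement(fwd)
  read_int <- function(v) {
    m <- matrix(utf8ToInt(paste(v, collapse = "")), nrow = L)
    m[m == 78L] <- -2L
    m
  }
  RI <- list("+" = read_int(fwd), "-" = read_int(rvc))

  seeds <- data.table::rbindlist(lapply(c("+", "-"), function(s) {
    v <- if (s == "+") fwd else rvc
    data.table::rbindlist(lapply(offs, function(o) {
      data.table(read = seq_len(n), strand = s,
                 kmer = substring(v, o + 1L, o + seed_k), off = o)
    }))
  }))
  cand <- index[seeds, on = "kmer", allow.cartesian = TRUE,
                nomatch = NULL]
  if (nrow(cand) == 0L) return(out)
  cand[, pos := rpos - off]
  if (ref$circular) cand[, pos := pos %% ref$length]
  cand <- unique(cand[pos >= 0L & pos <= max_pos,
                      list(read, strand, pos)])
  if (nrow(cand) == 0L) return(out)

  ## Hamming distance in batches
  cand[, mm := 0L]
  bs <- 200000L
  for (from in seq(1L, nrow(cand), by = bs)) {
    to <- min(from + bs - 1L, nrow(cand))
    rows <- from:to
    posm <- outer(0:(L - 1L), cand$pos[rows], "+") + 1L
    refm <- matrix(ref_int[posm], nrow = L)
    rd <- matrix(0L, nrow = L, ncol = length(rows))
    plus <- cand$strand[rows] == "+"
    if (any(plus)) rd[, plus] <- RI[["+"]][, cand$read[rows][plus]]
    if (any(!plus)) rd[, !plus] <- RI[["-"]][, cand$read[rows][!plus]]
    cand$mm[rows] <- colSums(refm != rd)
  }

  best <- cand[, {
    b <- min(mm)
    w <- which(mm == b)
    list(best = b, n_best = length(w), pos = pos[w[1L]],
         strand = strand[w[1L]])
  }, by = read]
  mapped <- best[best <= max_mismatch & n_best == 1L]
  amb <- best[best <= max_mismatch & n_best > 1L]
  out$pos[mapped$read] <- mapped$pos
  out$strand[mapped$read] <- mapped$strand
  out$mismatches[mapped$read] <- mapped$best
  out$status[mapped$read] <- "mapped"
  out$status[amb$read] <- "ambiguous"
  out
}

#' Two-pass read assignment against ancestral and derived references
#'
#' Pass 1 maps all reads to the ancestral reference; the pool of unmapped
#' reads is then mapped to the derived reference. Ambiguous reads are not
#' re-mapped.
#'
#' @param reads data.frame (`id`, `seq`).
#' @param ancestral_ref,derived_ref [genome_record()] objects.
#' @inheritParams map_reads
#' @return list with `pass1`, `pass2` (alignment tables as from
#'   [map_reads()]; `pass2` covers only the pass-1 unmapped pool) and
#'   `summary` (named counts: total, mapped_ancestral,
#'   ambiguous_ancestral, mapped_derived, ambiguous_derived, unmapped).
#' @export
two_pass_assign <- function(reads, ancestral_ref, derived_ref,
                            seed_k = 21L, max_mismatch = 3L) {
  p1 <- map_reads(reads, ancestral_ref, seed_k, max_mismatch)
  pool <- reads[p1$status == "unmapped", , drop = FALSE]
  p2 <- map_reads(pool, derived_ref, seed_k, max_mismatch)
  s <- c(total = nrow(reads),
         mapped_ancestral = sum(p1$status == "mapped"),
         ambiguous_ancestral = sum(p1$status == "ambiguous"),
         mapped_derived = sum(p2$status == "mapped"),
         ambiguous_derived = sum(p2$status == "ambiguous"),
         unmapped = sum(p2$status == "unmapped"))
  list(pass1 = p1, pass2 = p2, summary = s)
}

#' Choose diagnostic positions at inversion junctions
#'
#' Recombination between two perfectly conserved repeat copies creates no
#' locally novel sequence: around each junction the derived genome reads,
#' through the entire shared core, exactly like the ancestral genome
#' around one copy or the other. A read is informative about the junction
#' allele only if it spans the whole core plus discriminating flank bases
#' on both sides. Accordingly, for each junction this function anchors a
#' coordinate just *outside* the core on the non-inverted side and picks
#' `n_positions` reference coordinates just beyond the core's far edge at
#' which the ancestral and derived references differ in base composition
#' (the references share one coordinate frame because inversions are
#' in-place). [classify_breakpoint_reads()] counts a read only if its
#' alignment covers both the anchor and a diagnostic position; alignments
#' of derived-interior reads (which map perfectly, reverse-complemented,
#' to the mirrored ancestral locus) lie entirely within the inverted span
#' and can never cover the anchor, so they are excluded exactly.
#'
#' @param ancestral,derived [genome_record()] objects of equal length.
#' @param junctions data.frame with one row per junction: `junction` (the
#'   crossover coordinate, e.g. truth `m1`/`m2`), `side` (`"left"` if the
#'   inverted span lies to the right of the junction, `"right"`
#'   otherwise) and `core_half` (half-width of the conserved core
#'   centred on the junction). See [truth_junction_table()].
#' @param read_len read length the diagnostics must fit within; reads
#'   must be able to span `2*core_half + anchor_margin + ~20` bp.
#' @param n_positions diagnostics per junction (default 2).
#' @param min_offset closest allowed distance from the core edge (default
#'   5 bp; nearer positions are reachable by reads overhanging the core
#'   by fewer novel bases than the mapper's mismatch allowance).
#' @param anchor_margin distance of the anchor outside the core edge
#'   (default 12 bp). Derived reads overhanging the *partner* junction by
#'   a few bases mirror-map onto this junction's locus within the
#'   mismatch allowance; pushing the anchor outward forces them to carry
#'   `anchor_margin` foreign flank bases, and the flank-identity check
#'   (`check_bases`, verified by the classifier) rejects the remainder.
#' @param check_len flank-identity check width at the anchor (default 4
#'   bp; the reference bases there are shared by both references).
#' @return data.frame: `breakpoint_id`, `junction`, `side`, `anchor`,
#'   `check_start`, `check_bases`, `pos`, `base_anc`, `base_der`.
#' @export
make_site_diagnostics <- function(ancestral, derived, junctions,
                                  read_len = 250L, n_positions = 2L,
                                  min_offset = 5L, anchor_margin = 12L,
                                  check_len = 4L) {
  stopifnot(ancestral$length == derived$length)
  av <- strsplit(ancestral$seq, "")[[1]]
  dv <- strsplit(derived$seq, "")[[1]]
  diffs <- which(av != dv) - 1L                 # 0-based
  out <- NULL
  for (r in seq_len(nrow(junctions))) {
    j <- junctions$junction[r]
    ch <- junctions$core_half[r]
    side <- junctions$side[r]
    if (side == "left") {
      anchor <- j - ch - anchor_margin
      check_start <- anchor
      lo <- j + ch + min_offset
      hi <- anchor + read_len - 15L
      cand <- diffs[diffs >= lo & diffs <= hi]
    } else {
      anchor <- j + ch + anchor_margin - 1L
      check_start <- anchor - check_len + 1L
      hi <- j - ch - min_offset
      lo <- anchor - read_len + 15L
      cand <- diffs[diffs >= lo & diffs <= hi]
    }
    check_bases <- paste(av[check_start + seq_len(check_len)],
                         collapse = "")
    if (!identical(check_bases,
                   paste(dv[check_start + seq_len(check_len)],
                         collapse = "")))
      stop("anchor flank differs between references at junction ", j,
           call. = FALSE)
    if (length(cand) < n_positions)
      stop("too few discriminating positions near junction at ", j,
           " (core too long for the read length?)", call. = FALSE)
    ord <- order(abs(cand - j))
    pos <- sort(cand[ord[seq_len(n_positions)]])
    out <- rbind(out, data.frame(
      breakpoint_id = r, junction = j, side = side, anchor = anchor,
      check_start = check_start, check_bases = check_bases,
      pos = pos, base_anc = av[pos + 1L], base_der = dv[pos + 1L]))
  }
  out
}

#' Junction table from a generator truth history
#'
#' Builds the [make_site_diagnostics()] input from the events of
#' [apply_truth_history()] (one `left` and one `right` junction per
#' event, with core half-widths from the bounding pair).
#'
#' @param truth truth object with `events` and `pairs`.
#' @return data.frame with columns `junction`, `side`, `core_half`,
#'   `event`, `pair`.
#' @export
truth_junction_table <- function(truth) {
  ev <- truth$events
  out <- NULL
  for (i in seq_len(nrow(ev))) {
    ch <- truth$pairs$core_len[truth$pairs$pair == ev$pair[i]] %/% 2L
    out <- rbind(out,
                 data.frame(junction = c(ev$m1[i], ev$m2[i]),
                            side = c("left", "right"),
                            core_half = ch, event = i, pair = ev$pair[i]))
  }
  out
}

#' Estimate inversion-allele fractions at breakpoints
#'
#' Pools the mapped alignments of both passes, classifies each
#' junction-informative read (alignment covering the junction anchor and
#' at least one diagnostic position) as ancestral, derived, or other
#' (bases matching neither expectation, e.g. sequencing errors), and
#' returns the derived-allele fraction per breakpoint with a 95% Wilson
#' interval computed on the number of distinct informative reads.
#' Per-position base counts are attached as attribute `position_counts`.
#'
#' @param assignment list from [two_pass_assign()].
#' @param reads the read table given to [two_pass_assign()].
#' @param diagnostics data.frame from [make_site_diagnostics()].
#' @return data.frame: `breakpoint_id`, `junction`, `n_ancestral`,
#'   `n_derived`, `n_other`, `n_informative`, `derived_fraction` (NA when
#'   uncovered), `ci_lo`, `ci_hi`.
#' @export
classify_breakpoint_reads <- function(assignment, reads, diagnostics) {
  p1 <- assignment$pass1[assignment$pass1$status == "mapped", ,
                         drop = FALSE]
  p2 <- assignment$pass2[assignment$pass2$status == "mapped", ,
                         drop = FALSE]
  aln <- rbind(p1, p2)
  seq_by_id <- stats::setNames(reads$seq, reads$id)
  aseq <- seq_by_id[aln$read_id]
  neg <- aln$strand == "-"
  if (any(neg)) aseq[neg] <- reverse_complement(aseq[neg])
  L <- if (nrow(aln) > 0L) nchar(aseq[1]) else 0L

  out <- NULL; pos_counts <- NULL; read_calls <- NULL
  for (b in unique(diagnostics$breakpoint_id)) {
    d <- diagnostics[diagnostics$breakpoint_id == b, , drop = FALSE]
    anchor <- d$anchor[1]
    cover_anchor <- aln$pos <= anchor & aln$pos + L > anchor
    ## flank-identity check: the read must reproduce the shared reference
    ## bases just outside the core (mirror-mapped partner-junction reads
    ## carry foreign flank there)
    cs <- d$check_start[1]; cb <- d$check_bases[1]; cl <- nchar(cb)
    cover_check <- aln$pos <= cs & aln$pos + L >= cs + cl
    flank_ok <- cover_check &
      substr(aseq, cs - aln$pos + 1L, cs - aln$pos + cl) == cb
    cover_anchor <- cover_anchor & flank_ok
    votes_anc <- integer(nrow(aln)); votes_der <- integer(nrow(aln))
    votes_oth <- integer(nrow(aln)); covered <- logical(nrow(aln))
    for (r in seq_len(nrow(d))) {
      p <- d$pos[r]
      cov <- cover_anchor & aln$pos <= p & aln$pos + L > p
      base <- substr(aseq, p - aln$pos + 1L, p - aln$pos + 1L)
      is_anc <- cov & base == d$base_anc[r]
      is_der <- cov & base == d$base_der[r]
      is_oth <- cov & !is_anc & !is_der
      votes_anc <- votes_anc + is_anc
      votes_der <- votes_der + is_der
      votes_oth <- votes_oth + is_oth
      covered <- covered | cov
      pos_counts <- rbind(pos_counts, data.frame(
        breakpoint_id = b, pos = p, ancestral = sum(is_anc),
        derived = sum(is_der), other = sum(is_oth)))
    }
    call <- ifelse(!covered, "uncovered",
                   ifelse(votes_anc > 0L & votes_der == 0L &
                            votes_oth == 0L, "ancestral",
                   ifelse(votes_der > 0L & votes_anc == 0L &
                            votes_oth == 0L, "derived", "other")))
    inf_rows <- which(call != "uncovered")
    if (length(inf_rows) > 0L)
      read_calls <- rbind(read_calls, data.frame(
        breakpoint_id = b, read_id = aln$read_id[inf_rows],
        call = call[inf_rows]))
    n_anc <- sum(call == "ancestral"); n_der <- sum(call == "derived")
    n_oth <- sum(call == "other")
    n_inf <- n_anc + n_der
    frac <- if (n_inf > 0L) n_der / n_inf else NA_real_
    ci <- wilson_ci(n_der, n_inf)
    out <- rbind(out, data.frame(
      breakpoint_id = b, junction = d$junction[1], n_ancestral = n_anc,
      n_derived = n_der, n_other = n_oth, n_informative = n_inf,
      derived_fraction = frac, ci_lo = ci[1], ci_hi = ci[2]))
  }
  attr(out, "position_counts") <- pos_counts
  attr(out, "read_calls") <- read_calls
  out
}

#' Read-depth ratio of a target region against the chromosomal baseline
#'
#' Computes per-base depth from an alignment table, averages it over the
#' target region and over the chromosome excluding masked regions, and
#' reports the ratio as copies per chromosome. When the target is an
#' integrated locus also present once on the chromosome, set
#' `target_baseline_copies = 1` to subtract the resident copy.
#'
#' @param alignments data.frame from [map_reads()] (mapped rows used).
#' @param ref [genome_record()] the alignments refer to.
#' @param read_len read length.
#' @param target c(start, end): target interval, 0-based half-open.
#' @param mask optional data.frame (`start`, `end`) of regions excluded
#'   from the baseline (the target itself is always excluded).
#' @param target_baseline_copies chromosomal copies resident in the
#'   target (default 0).
#' @return list: `mean_target`, `mean_baseline`, `ratio`,
#'   `copies_per_chromosome`.
#' @export
depth_ratio <- function(alignments, ref, read_len, target, mask = NULL,
                        target_baseline_copies = 0) {
  L <- ref$length
  d <- numeric(L + 1L)
  mapped <- alignments[alignments$status == "mapped", , drop = FALSE]
  for (i in seq_len(nrow(mapped))) {
    s <- mapped$pos[i]; e <- s + read_len
    if (e <= L) {
      d[s + 1L] <- d[s + 1L] + 1; d[e + 1L] <- d[e + 1L] - 1
    } else {                       # circular wrap
      d[s + 1L] <- d[s + 1L] + 1
      d[1L] <- d[1L] + 1; d[e - L + 1L] <- d[e - L + 1L] - 1
      d[L + 1L] <- d[L + 1L] - 1
    }
  }
  depth <- cumsum(d[seq_len(L)])
  in_target <- logical(L)
  in_target[(target[1] + 1L):target[2]] <- TRUE
  excluded <- logical(L)
  if (!is.null(mask)) for (i in seq_len(nrow(mask)))
    excluded[(mask$start[i] + 1L):mask$end[i]] <- TRUE
  if (!any(!excluded)) stop("empty baseline", call. = FALSE)
  mb <- mean(depth[!excluded])
  if (mb == 0) stop("zero baseline depth", call. = FALSE)
  mt <- mean(depth[in_target])
  list(mean_target = mt, mean_baseline = mb, ratio = mt / mb,
       copies_per_chromosome = mt / mb - target_baseline_copies)
}
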