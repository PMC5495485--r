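## Synthetic-data generator: genomes with planted paralogous repeat pairs,
## derived genomes via sampled inversion histories, mixed-population short
## reads, recombination-engine construct maps, and a serial-passage
## population simulator. Every generator is deterministic given its seed
## and returns a truth object sufficient to regenerate its output.

#' Generate a genome with planted repeat pairs
#'
#' Background sequence is i.i.d. at the requested GC content; each pair is
#' one random core copied (reverse-complemented for inverted pairs) to a
#' second locus. Cores of different pairs share no 20-mer, and the bases
#' immediately flanking each copy are forced to differ between the two
#' copies so that the maximal perfectly shared segment equals the planted
#' core length exactly. All copies (and the genome ends of the linear
#' frame) are separated by at least `min_separation`.
#'
#' @param length genome length in bp.
#' @param gc GC fraction of the background (default 0.5).
#' @param pair_specs data.frame with columns `core_len` and `orientation`
#'   (`"direct"`/`"inverted"`); defaults to the four sizes observed at
#'   natural inversion breakpoints (104, 176, 284, 620 bp, all inverted).
#' @param min_separation minimum distance between any two planted copies
#'   and from the origin (default 12000 bp).
#' @param seed integer RNG seed.
#' @param id record id (default "sim").
#' @param circular logical (default TRUE).
#' @return list with `genome` ([genome_record()]) and `truth` (list with
#'   `seed`, `params` and `pairs`: `pair`, `core_len`, `orientation`,
#'   `a_start`, `a_end`, `a_strand`, `b_start`, `b_end`, `b_strand`).
#' @export
make_genome_with_repeats <- function(length, gc = 0.5, pair_specs = NULL,
                                     min_separation = 12000L, seed = 1L,
                                     id = "sim", circular = TRUE) {
  set.seed(seed)
  length <- as.integer(length)
  if (is.null(pair_specs))
    pair_specs <- data.frame(core_len = c(104L, 176L, 284L, 620L),
                             orientation = "inverted")
  np <- nrow(pair_specs)
  if (sum(pair_specs$core_len) * 4L > length)
    stop("planted repeats too large for the genome", call. = FALSE)

  chars <- strsplit(random_dna(length, gc), "")[[1]]

  if (np == 0L) {
    g <- genome_record(id, random_dna(length, gc), circular = circular)
    return(list(genome = g,
                truth = list(seed = seed,
                             params = list(length = length, gc = gc,
                                           min_separation = min_separation),
                             pairs = pair_specs_empty())))
  }
  ## sample 2*np loci with pairwise distance >= min_separation + max_core
  ## (uniform over valid configurations via the spacing construction)
  max_core <- max(pair_specs$core_len)
  d <- min_separation + max_core
  nl <- 2L * np
  free <- length - nl * d - min_separation
  if (free <= nl)
    stop("infeasible packing: cannot place repeat copies with the ",
         "requested separation", call. = FALSE)
  u <- sort(as.integer(floor(stats::runif(nl, 0, free))))
  loci <- u + (seq_len(nl) - 1L) * d + min_separation %/% 2L
  ## assign consecutive locus pairs to repeat pairs at random
  assign_pair <- sample(rep(seq_len(np), 2L))

  cores <- character(np)
  for (p in seq_len(np)) {
    repeat {
      core <- random_dna(pair_specs$core_len[p], gc)
      clash <- FALSE
      for (q in seq_len(p - 1L)) {
        for (s in c(cores[q], reverse_complement(cores[q]))) {
          m <- shared_exact_matches(core, s, k = 20L)
          if (nrow(m) > 0L && max(m$len) >= 20L) clash <- TRUE
        }
      }
      if (!clash) break
    }
    cores[p] <- core
  }

  pairs <- data.frame(pair = seq_len(np),
                      core_len = as.integer(pair_specs$core_len),
                      orientation = pair_specs$orientation,
                      a_start = NA_integer_, a_end = NA_integer_,
                      a_strand = "+", b_start = NA_integer_,
                      b_end = NA_integer_, b_strand = "+")
  for (p in seq_len(np)) {
    at <- loci[assign_pair == p]
    cl <- pairs$core_len[p]
    a <- at[1]; b <- at[2]
    inverted <- pairs$orientation[p] == "inverted"
    chars[(a + 1):(a + cl)] <- strsplit(cores[p], "")[[1]]
    bseq <- if (inverted) reverse_complement(cores[p]) else cores[p]
    chars[(b + 1):(b + cl)] <- strsplit(bseq, "")[[1]]
    ## force flanking mismatches so the shared core is exactly core_len:
    ## for direct pairs the homologous flank positions are (a-1,b-1) and
    ## (a_end,b_end); for inverted pairs they are (a-1, b_end) and
    ## (a_end, b-1) with a complement relation
    chars[a] <- "C"; chars[a + cl + 1L] <- "C"
    if (inverted) {
      chars[b + cl + 1L] <- "A"   # comp = T != C
      chars[b] <- "A"             # comp = T != C
    } else {
      chars[b] <- "A"; chars[b + cl + 1L] <- "A"
    }
    pairs$a_start[p] <- a; pairs$a_end[p] <- a + cl
    pairs$b_start[p] <- b; pairs$b_end[p] <- b + cl
    pairs$b_strand[p] <- if (inverted) "-" else "+"
  }

  g <- genome_record(id, paste(chars, collapse = ""), circular = circular)
  truth <- list(seed = seed,
                params = list(length = length, gc = gc,
                              min_separation = min_separation),
                pairs = pairs)
  list(genome = g, truth = truth)
}

#' Apply a sampled inversion history
#'
#' Samples `n_events` sequential inversions by randomized backtracking,
#' each bounded by a repeat pair that is currently in inverted orientation
#' (orientation is re-evaluated after every event, so a pair planted in
#' direct orientation can become a substrate after an overlapping
#' inversion). Events use distinct pairs. A candidate sequence is accepted
#' only if (i) the endpoint-constrained minimal inversion distance between
#' ancestral and derived block arrangements equals `n_events` (the
#' divergence is genuinely `n_events` deep) and (ii) every junction
#' created by the history is still a synteny breakpoint in the final
#' arrangement. Some repeat-pair geometries admit no such history, in
#' which case an error invites re-drawing the genome.
#'
#' @param genome ancestral [genome_record()].
#' @param truth truth object from [make_genome_with_repeats()].
#' @param n_events number of inversions to apply.
#' @param seed integer RNG seed.
#' @param max_candidates budget of complete candidate sequences to test
#'   (default 200).
#' @return list with `genome` (derived [genome_record()]), `truth`
#'   (augmented with `events`: data.frame `step`, `pair`, `m1`, `m2`;
#'   `pairs_final`; `perm_derived`; `marker_pairs` for the constrained
#'   search; `distance`).
#' @export
apply_truth_history <- function(genome, truth, n_events, seed = 1L,
                                max_candidates = 200L) {
  set.seed(seed)
  ## randomized backtracking over event sequences at coordinate level
  ## (sequence mutation deferred until a sequence is accepted)
  tried <- 0L
  found <- NULL
  dfs <- function(pairs, path, used) {
    if (!is.null(found) || tried >= max_candidates) return()
    if (length(path) == n_events) {
      tried <<- tried + 1L
      chk <- history_checks(truth, path)
      if (chk$ok) found <<- list(path = path, checks = chk)
      return()
    }
    cand <- setdiff(pairs$pair[pairs$a_strand != pairs$b_strand], used)
    if (length(cand) == 0L) return()
    for (pick in (if (length(cand) == 1L) cand else sample(cand))) {
      upd <- pair_inversion_coords(pairs, pick)
      dfs(upd$pairs, c(path, pick), c(used, pick))
      if (!is.null(found)) return()
    }
  }
  dfs(truth$pairs, integer(0), integer(0))
  if (is.null(found))
    stop("no acceptable ", n_events, "-event history exists for this ",
         "repeat-pair geometry", call. = FALSE)

  ## apply the accepted sequence at sequence level
  g <- genome; pairs <- truth$pairs; events <- NULL
  for (step in seq_along(found$path)) {
    r <- invert_between_pair(g, pairs, found$path[step])
    g <- r$genome; pairs <- r$pairs
    events <- rbind(events, data.frame(step = step,
                                       pair = found$path[step],
                                       m1 = r$m1, m2 = r$m2))
  }
  list(genome = genome_record(paste0(genome$id, "_derived"), g$seq,
                              circular = g$circular),
       truth = c(truth, list(
         events = events, pairs_final = pairs,
         perm_derived = found$checks$perm,
         marker_pairs = found$checks$mk,
         used_pairs = sort(found$path),
         distance = found$checks$distance)))
}

pair_specs_empty <- function() {
  data.frame(pair = integer(0), core_len = integer(0),
             orientation = character(0), a_start = integer(0),
             a_end = integer(0), a_strand = character(0),
             b_start = integer(0), b_end = integer(0),
             b_strand = character(0))
}

## block-level acceptance checks for a candidate event sequence: the
## constrained minimal distance must equal the event count and every
## junction must remain a breakpoint of the final arrangement
history_checks <- function(truth, path) {
  used <- sort(path)
  anc_pairs <- truth$pairs[truth$pairs$pair %in% used, , drop = FALSE]
  mk <- marker_pair_table(anc_pairs)
  st <- marker_state(2L * nrow(anc_pairs) + 1L, mk)
  for (p in path) st <- state_apply(st, match(p, used))
  perm <- state_blocks(st)
  dist <- min_inversion_distance(seq_len(2L * nrow(anc_pairs) + 1L),
                                 perm, pairs = mk)
  list(ok = is.finite(dist) && dist == length(path) &&
         all_junctions_active(st),
       perm = perm, mk = mk, distance = dist)
}

## adjacency table for marker_state(): the 2u markers of the used pairs in
## ancestral coordinate order sit at adjacencies 1..2u between the 2u+1
## segments they delimit; pair ids are re-labelled 1..u in sorted order
marker_pair_table <- function(anc_pairs) {
  u <- nrow(anc_pairs)
  copies <- rbind(
    data.frame(pair = anc_pairs$pair, start = anc_pairs$a_start,
               strand = anc_pairs$a_strand),
    data.frame(pair = anc_pairs$pair, start = anc_pairs$b_start,
               strand = anc_pairs$b_strand))
  copies <- copies[order(copies$start), , drop = FALSE]
  copies$adj <- seq_len(2L * u)
  out <- NULL
  for (i in seq_len(u)) {
    p <- sort(anc_pairs$pair)[i]
    cc <- copies[copies$pair == p, , drop = FALSE]
    out <- rbind(out, data.frame(pair = i, pos_a = cc$adj[1],
                                 pos_b = cc$adj[2],
                                 strand_a = cc$strand[1],
                                 strand_b = cc$strand[2]))
  }
  out
}

## every marker must sit at a non-conserved adjacency of the final state
all_junctions_active <- function(st) {
  n <- length(st$kind)
  for (t in which(st$kind == "M")) {
    lb <- max(which(st$kind[seq_len(t - 1L)] == "B"))
    rb <- t + min(which(st$kind[(t + 1L):n] == "B"))
    bl <- st$id[lb] * st$sign[lb]; br <- st$id[rb] * st$sign[rb]
    conserved <- (bl > 0L && br > 0L && br == bl + 1L) ||
                 (bl < 0L && br < 0L && abs(bl) == abs(br) + 1L)
    if (conserved) return(FALSE)
  }
  TRUE
}

#' Simulate single-end short reads from a genome mixture
#'
#' Read positions are uniform (circular-aware); strands are random;
#' substitutions occur independently at rate `err`; quality is a constant
#' Phred 40. Read names encode the truth after a reserved `|` delimiter
#' (`src`, `pos`, `strand`), which all consumers ignore.
#'
#' @param genomes list of [genome_record()] objects.
#' @param fractions read fractions per genome (sum to 1); exactly one of
#'   `fractions`/`copies` must be given.
#' @param copies per-genome copy numbers: read counts become proportional
#'   to `length * copies` (for plasmid/chromosome mixtures).
#' @param coverage fold coverage (of each genome at `copies = 1`, or of
#'   the pool under `fractions`).
#' @param read_len read length in bp (default 100).
#' @param err per-base substitution rate (default 0.01).
#' @param seed integer RNG seed.
#' @return list with `reads` (data.frame `id`, `seq`, `qual`) and `truth`.
#' @export
simulate_reads <- function(genomes, fractions = NULL, copies = NULL,
                           coverage = 100, read_len = 100L, err = 0.01,
                           seed = 1L) {
  set.seed(seed)
  read_len <- as.integer(read_len)
  if (is.null(fractions) == is.null(copies))
    stop("give exactly one of fractions or copies", call. = FALSE)
  lens <- vapply(genomes, `[[`, 0L, "length")
  if (any(read_len > lens))
    stop("read_len exceeds a genome length", call. = FALSE)
  n_reads <- if (!is.null(fractions)) {
    stopifnot(abs(sum(fractions) - 1) < 1e-8)
    round(coverage * lens / read_len * fractions)
  } else {
    round(coverage * lens * copies / read_len)
  }
  all_reads <- NULL
  idx0 <- 0L
  for (gi in seq_along(genomes)) {
    g <- genomes[[gi]]; n <- n_reads[gi]
    if (n == 0L) next
    ext <- if (g$circular) paste0(g$seq, subseq0(g$seq, 0L, read_len)) else
      g$seq
    pos <- if (g$circular) sample.int(g$length, n, replace = TRUE) - 1L
           else sample.int(g$length - read_len + 1L, n, replace = TRUE) - 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- subseq0_many(ext, pos, pos + read_len)
    neg <- strand == "-"
    if (any(neg)) seqs[neg] <- reverse_complement(seqs[neg])
    if (err > 0) seqs <- add_substitutions(seqs, err)
    ids <- sprintf("r%07d|src=%s|pos=%d|strand=%s", idx0 + seq_len(n),
                   g$id, pos, strand)
    all_reads <- rbind(all_reads,
                       data.frame(id = ids, seq = seqs,
                                  qual = strrep("I", read_len)))
    idx0 <- idx0 + n
  }
  truth <- list(seed = seed, coverage = coverage, read_len = read_len,
                err = err, fractions = fractions, copies = copies,
                n_reads = n_reads,
                sources = vapply(genomes, `[[`, "", "id"))
  list(reads = all_reads %||% data.frame(id = character(0),
                                         seq = character(0),
                                         qual = character(0)),
       truth = truth)
}

## independent per-base substitutions; each error becomes one of the three
## other bases uniformly
add_substitutions <- function(seqs, err) {
  n_err <- stats::rbinom(length(seqs), nchar(seqs), err)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    ch <- strsplit(seqs[i], "")[[1]]
    at <- sample.int(length(ch), n_err[i])
    for (j in at) ch[j] <- sample(setdiff(bases, ch[j]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Build recombination-engine construct maps
#'
#' Emits concrete [molecule()] maps with random filler sequence satisfying
#' exact length constraints, mimicking the in vitro substrates:
#'
#' * `"pMC479"`: circular plasmid carrying, in order, an 87-bp att site
#'   (core = its first 43 bp), a 762-bp spacer, and a 43-bp minimal att
#'   site in direct orientation; excision releases a circle of spacer +
#'   one full-length hybrid site (849 bp). Restriction sites are placed so
#'   the intact plasmid digests to `pre_digest`.
#' * `"pMC477"`: same sites in inverted orientation separated by a 892-bp
#'   spacer; enzyme sites are solved by exact integer search so that the
#'   intact plasmid digests to `pre_digest` and the inversion product to
#'   `post_digest`.
#' * `"TKV4"`: a linear host fragment carrying an integrated element
#'   flanked by att sites sharing a 43-bp core, with outward-facing
#'   primers that yield a product (of `amplicon` bp) only after excision
#'   and circularization.
#'
#' Filler is scrubbed of accidental enzyme sites and core-sequence copies.
#' The maps are reconstructions constrained to the printed fragment
#' sizes, not the (unpublished) true construct sequences.
#'
#' @param template one of `"pMC479"`, `"pMC477"`, `"TKV4"`.
#' @param seed integer RNG seed.
#' @param total total plasmid length (default 4573 bp for both plasmid
#'   templates).
#' @param enzyme recognition sequence (default `"CATATG"`, NdeI).
#' @param pre_digest,post_digest target fragment multisets (defaults:
#'   pMC479 `{3207, 1366}`; pMC477 `{2796, 1777}` / `{2358, 2215}`).
#' @param host_len,element_len,amplicon TKV4 template geometry (defaults
#'   12000, 5000, 1710 bp).
#' @return list with `mol` ([molecule()]) and template-specific extras
#'   (`enzyme`, `primers`, `truth`).
#' @export
build_construct_map <- function(template = c("pMC479", "pMC477", "TKV4"),
                                seed = 1L, total = 4573L,
                                enzyme = "CATATG",
                                pre_digest = NULL, post_digest = NULL,
                                host_len = 12000L, element_len = 5000L,
                                amplicon = 1710L) {
  template <- match.arg(template)
  set.seed(seed)
  switch(template,
         pMC479 = construct_pmc479(total, enzyme,
                                   pre_digest %||% c(3207L, 1366L)),
         pMC477 = construct_pmc477(total, enzyme,
                                   pre_digest %||% c(2796L, 1777L),
                                   post_digest %||% c(2358L, 2215L)),
         TKV4 = construct_tkv4(host_len, element_len, amplicon))
}

## random filler free of the enzyme site (both strands) and of any 16-mer
## of the supplied motifs
clean_filler <- function(n, forbidden) {
  repeat {
    s <- random_dna(n)
    ok <- TRUE
    for (f in forbidden) {
      if (grepl(f, s, fixed = TRUE) ||
          grepl(reverse_complement(f), s, fixed = TRUE)) ok <- FALSE
    }
    if (ok) return(s)
  }
}

## assemble a plasmid from segments, then verify no stray enzyme site
assemble_plasmid <- function(id, segments, features, enzyme,
                             expected_cuts) {
  seq <- paste(segments, collapse = "")
  mol <- molecule(id, seq, circular = TRUE, features = features)
  dg <- digest(mol, enzyme)
  if (!identical(sort(attr(dg, "cuts")), sort(as.integer(expected_cuts))))
    stop("stray or missing enzyme site in assembled construct",
         call. = FALSE)
  mol
}

construct_pmc479 <- function(total, enzyme, pre_digest) {
  core <- clean_filler(43L, enzyme)
  site1_extra <- clean_filler(44L, c(enzyme, core))
  spacer <- clean_filler(762L, c(enzyme, core))
  ## layout: site1 [0,87) core [0,43); spacer [87,849); site2 [849,892);
  ## backbone [892,total) carrying the two enzyme sites
  if (sum(pre_digest) != total)
    stop("pre_digest must sum to the plasmid length", call. = FALSE)
  p1 <- 1000L; p2 <- p1 + min(pre_digest)
  if (p1 < 892L + 8L || p2 + nchar(enzyme) > total - 8L)
    stop("unsatisfiable digest constraint: ", paste(pre_digest,
                                                    collapse = "/"),
         call. = FALSE)
  bb1 <- clean_filler(p1 - 892L, c(enzyme, core))
  bb2 <- clean_filler(p2 - (p1 + nchar(enzyme)), c(enzyme, core))
  bb3 <- clean_filler(total - (p2 + nchar(enzyme)), c(enzyme, core))
  feats <- rbind(att_feature("attL88", 0L, 87L, "+", 0L, 43L),
                 att_feature("attB44", 849L, 892L, "+", 849L, 892L))
  mol <- assemble_plasmid("pMC479_like",
                          c(core, site1_extra, spacer, core, bb1, enzyme,
                            bb2, enzyme, bb3),
                          feats, enzyme, c(p1, p2))
  stopifnot(identical(as.integer(digest(mol, enzyme)),
                      sort(as.integer(pre_digest), decreasing = TRUE)))
  list(mol = mol, enzyme = enzyme,
       truth = list(sites = c("attL88", "attB44"), core_len = 43L,
                    spacer = 762L, pre_digest = sort(pre_digest)))
}

construct_pmc477 <- function(total, enzyme, pre_digest, post_digest) {
  if (sum(pre_digest) != total || sum(post_digest) != total)
    stop("digest targets must sum to the plasmid length", call. = FALSE)
  core <- clean_filler(43L, enzyme)
  site1_extra <- clean_filler(44L, c(enzyme, core))
  spacer_len <- 892L
  ## layout: site1 [0,87) core [0,43) "+"; spacer [87,979); site2
  ## [979,1022) "-" (content = revcomp core); backbone [1022,total).
  ## crossover at core midpoint (offset 21): inversion span [21, 1001).
  m1 <- 21L; m2 <- 1022L - 21L
  el <- nchar(enzyme)
  sol <- NULL
  for (d in unique(pre_digest)) {
    for (p1 in (87L + 2L):(979L - el - 2L)) {     # one site in the spacer
      if (p1 < m1 || p1 + el > m2) next           # must lie in the span
      p2 <- p1 + d
      if (p2 <= 1022L + 2L || p2 + el > total - 2L) next  # in backbone
      p1_post <- m1 + m2 - (p1 + el)
      d_post <- p2 - p1_post
      if (setequal(c(d_post, total - d_post), post_digest)) {
        sol <- c(p1, p2); break
      }
    }
    if (!is.null(sol)) break
  }
  if (is.null(sol))
    stop("unsatisfiable digest constraints: no enzyme placement gives ",
         "pre {", paste(pre_digest, collapse = ","), "} and post {",
         paste(post_digest, collapse = ","), "}", call. = FALSE)
  p1 <- sol[1]; p2 <- sol[2]
  sp1 <- clean_filler(p1 - 87L, c(enzyme, core))
  sp2 <- clean_filler(979L - (p1 + el), c(enzyme, core))
  bb1 <- clean_filler(p2 - 1022L, c(enzyme, core))
  bb2 <- clean_filler(total - (p2 + el), c(enzyme, core))
  feats <- rbind(att_feature("attL88", 0L, 87L, "+", 0L, 43L),
                 att_feature("attB44", 979L, 1022L, "-", 979L, 1022L))
  mol <- assemble_plasmid("pMC477_like",
                          c(core, site1_extra, sp1, enzyme, sp2,
                            reverse_complement(core), bb1, enzyme, bb2),
                          feats, enzyme, c(p1, p2))
  stopifnot(identical(as.integer(digest(mol, enzyme)),
                      sort(as.integer(pre_digest), decreasing = TRUE)))
  list(mol = mol, enzyme = enzyme,
       truth = list(sites = c("attL88", "attB44"), core_len = 43L,
                    spacer = spacer_len, enzyme_at = c(p1, p2),
                    pre_digest = sort(pre_digest),
                    post_digest = sort(post_digest)))
}

construct_tkv4 <- function(host_len, element_len, amplicon) {
  core_len <- 43L; plen <- 20L
  circle_len <- element_len - core_len
  if (amplicon >= circle_len - 2L * plen || amplicon < 2L * plen + 10L)
    stop("unsatisfiable amplicon length for this element size",
         call. = FALSE)
  ## excised circle = [cut_in_attL, cut_in_attR) of the host; primers are
  ## outward-facing on the integrated element: fwd at distance tail from
  ## the right cut, rev-binding ending head after the left cut, with
  ## tail + head == amplicon
  tail <- amplicon %/% 2L
  head <- amplicon - tail
  a <- host_len %/% 3L                       # element start in the host
  core <- clean_filler(core_len, character(0))
  interior_len <- element_len - 2L * core_len
  fwd <- clean_filler(plen, core)
  rev <- clean_filler(plen, c(core, fwd))
  ## element interior coordinates (relative to element start):
  ## rev-binding region (revcomp of rev) ends at core_len - 21 + head
  off <- core_len %/% 2L                     # crossover offset 21
  cutL <- a + off
  cutR <- a + element_len - core_len + off
  rev_end_rel <- (cutL - a) + head           # element-relative
  fwd_start_rel <- (cutR - a) - tail
  int0 <- core_len                           # interior begins after attL core
  seg1 <- clean_filler(rev_end_rel - plen - int0, c(core, fwd, rev))
  seg2 <- clean_filler(fwd_start_rel - rev_end_rel, c(core, fwd, rev))
  seg3 <- clean_filler((element_len - core_len) - (fwd_start_rel + plen),
                       c(core, fwd, rev))
  element <- paste0(core, seg1, reverse_complement(rev), seg2, fwd, seg3,
                    core)
  stopifnot(nchar(element) == element_len)
  left <- clean_filler(a, c(core, fwd, rev))
  right <- clean_filler(host_len - a - element_len, c(core, fwd, rev))
  host <- paste0(left, element, right)
  feats <- rbind(att_feature("attL", a, a + core_len, "+"),
                 att_feature("attR", a + element_len - core_len,
                             a + element_len, "+"))
  mol <- molecule("TKV4_host", host, circular = FALSE, features = feats)
  list(mol = mol, primers = list(fwd = fwd, rev = rev),
       truth = list(element_start = a, element_len = element_len,
                    circle_len = circle_len, amplicon = amplicon))
}

#' Neutral serial-passage population simulator
#'
#' Wright-Fisher-style model of a culture of lineages whose genomes are
#' repeat-pair orientation states: each generation, each lineage fires an
#' inversion at each currently-inverted pair with probability `inv_rate`,
#' then the population is resampled multinomially at constant size; every
#' `generations_per_passage` generations a dilution bottleneck subsamples
#' `pop_size / dilution` lineages before regrowth. The dynamics model is
#' illustrative scaffolding: rates are not calibrated to any organism.
#'
#' @param pairs repeat-pair table (as in [make_genome_with_repeats()]
#'   truth).
#' @param inv_rate inversion probability per invertible pair per lineage
#'   per generation.
#' @param generations total generations (default 60).
#' @param dilution bottleneck fold (default 50).
#' @param generations_per_passage growth phase length (default 6,
#'   approximately log2(50)).
#' @param pop_size modelled population size (default 1000).
#' @param seed integer RNG seed.
#' @return list with `trajectory` (data.frame `generation`, `state`,
#'   `count`, `freq`), `states` (list of pair tables keyed by state id)
#'   and `n_events` (total inversions fired).
#' @export
simulate_passaging <- function(pairs, inv_rate, generations = 60L,
                               dilution = 50L,
                               generations_per_passage = 6L,
                               pop_size = 1000L, seed = 1L) {
  set.seed(seed)
  state_id <- function(ps) paste(ps$a_strand, ps$b_strand, ps$a_start,
                                 ps$b_start, collapse = ";")
  states <- list(); counts <- integer(0)
  k0 <- state_id(pairs)
  states[[k0]] <- pairs; counts[k0] <- pop_size
  n_events <- 0L
  traj <- NULL
  record <- function(gen) {
    rbind(traj, data.frame(generation = gen, state = names(counts),
                           count = as.integer(counts),
                           freq = as.numeric(counts) / sum(counts)))
  }
  traj <- record(0L)
  for (gen in seq_len(generations)) {
    ## mutation: per state, per invertible pair, binomial movers
    new_counts <- counts
    for (key in names(counts)) {
      ps <- states[[key]]
      n_here <- counts[key]
      if (n_here == 0L) next
      inv_pairs <- ps$pair[ps$a_strand != ps$b_strand]
      for (p in inv_pairs) {
        movers <- stats::rbinom(1L, n_here, inv_rate)
        if (movers == 0L) next
        upd <- pair_inversion_coords(ps, p)
        k2 <- state_id(upd$pairs)
        if (is.null(states[[k2]])) states[[k2]] <- upd$pairs
        if (is.na(new_counts[k2])) new_counts[k2] <- 0L
        new_counts[k2] <- new_counts[k2] + movers
        new_counts[key] <- new_counts[key] - movers
        n_events <- n_events + movers
      }
    }
    counts <- new_counts[new_counts > 0L]
    ## drift (and bottleneck at passage boundaries)
    resample <- function(cnt, size) {
      stats::setNames(stats::rmultinom(1L, size,
                                       prob = as.numeric(cnt))[, 1],
                      names(cnt))
    }
    if (gen %% generations_per_passage == 0L) {
      counts <- resample(counts, max(2L, pop_size %/% dilution))
      counts <- counts[counts > 0L]
      counts <- resample(counts, pop_size)      # regrow after dilution
    } else {
      counts <- resample(counts, pop_size)
    }
    counts <- counts[counts > 0L]
    traj <- record(gen)
  }
  list(trajectory = traj, states = states, n_events = n_events)
}
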