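## Stage 4: in-silico model of integrase-mediated reactions on DNA maps.
## Site-specific integration, excision and inversion follow the Campbell
## model: recombination is legal only between att sites whose core
## sequences are identical (up to reverse complement for inverted
## geometry); the crossover falls at a configurable offset inside the
## core (default: midpoint); hybrid product sites are composed as the
## upstream partner's prefix up to the crossover plus the downstream
## partner's suffix. Low-sequence-specificity ("homology-mimicking")
## recombination treats every maximal perfectly shared segment above a
## length threshold as a generic att site pair.

#' Construct an annotated DNA molecule
#'
#' @param id character label.
#' @param seq nucleotide string.
#' @param circular logical (default `TRUE`; most substrates are plasmids).
#' @param features data.frame with columns `name`, `type` (`"att"`,
#'   `"misc"`, ...), `start`, `end`, `strand` (`+`/`-`) and, for att sites,
#'   `core_start`, `core_end` (absolute molecule coordinates of the shared
#'   core). All coordinates 0-based, half-open.
#' @return object of class `dna_molecule`.
#' @export
molecule <- function(id, seq, circular = TRUE, features = NULL) {
  seq <- toupper(seq)
  check_dna(seq, paste0("molecule '", id, "'"))
  len <- nchar(seq)
  if (is.null(features)) features <- empty_features()
  features$core_start <- features$core_start %||% rep(NA_integer_,
                                                      nrow(features))
  stopifnot(all(features$start >= 0L), all(features$start < features$end))
  if (any(features$end > len & !circular))
    stop("feature beyond the end of a linear molecule", call. = FALSE)
  structure(list(id = as.character(id), seq = seq,
                 circular = isTRUE(circular), length = len,
                 features = features),
            class = "dna_molecule")
}

empty_features <- function() {
  data.frame(name = character(0), type = character(0), start = integer(0),
             end = integer(0), strand = character(0),
             core_start = integer(0), core_end = integer(0))
}

#' Describe an att site feature row
#'
#' @param name site name (`attP`, `attB`, `attL`, `attR` or any label).
#' @param start,end site interval (0-based, half-open).
#' @param strand `+` or `-`.
#' @param core_start,core_end core interval shared identically by
#'   recombining partners; defaults to the whole site.
#' @return one-row feature data.frame.
#' @export
att_feature <- function(name, start, end, strand = "+",
                        core_start = start, core_end = end) {
  stopifnot(core_start >= start, core_end <= end, core_start < core_end)
  data.frame(name = name, type = "att", start = as.integer(start),
             end = as.integer(end), strand = strand,
             core_start = as.integer(core_start),
             core_end = as.integer(core_end))
}

#' @export
print.dna_molecule <- function(x, ...) {
  cat(sprintf("<dna_molecule> %s: %d bp, %s, %d feature(s)\n", x$id,
              x$length, if (x$circular) "circular" else "linear",
              nrow(x$features)))
  invisible(x)
}

get_feature <- function(mol, site) {
  if (is.character(site)) {
    idx <- which(mol$features$name == site)
    if (length(idx) != 1L)
      stop("site '", site, "' matches ", length(idx), " features of ",
           mol$id, call. = FALSE)
  } else idx <- as.integer(site)
  mol$features[idx, , drop = FALSE]
}

## core sequence in the site's 5'->3' orientation
core_seq <- function(mol, f) {
  s <- subseq0(mol$seq, f$core_start, f$core_end)
  if (f$strand == "-") reverse_complement(s) else s
}

## molecule coordinate of the crossover cut for a site, given the offset
## within the oriented core
cut_pos <- function(f, offset) {
  if (f$strand == "+") f$core_start + offset else f$core_end - offset
}

#' Site-specific recombination (Campbell model)
#'
#' Performs one of the three canonical reactions, chosen by the geometry of
#' the substrates: two circular molecules give a co-integrate
#' (integration); one circular molecule with co-oriented sites gives two
#' circles (excision; the deletion circle carries the spacer plus one
#' hybrid site); one molecule with inverted sites returns the molecule
#' with the inter-core segment reverse-complemented (inversion).
#' Recombination is refused when the site cores are not identical in the
#' oriented frame — mirroring, e.g., the failure of tRNA-Leu x tRNA-Thr
#' substrates.
#'
#' @param molA [molecule()]; the substrate carrying `siteA`.
#' @param siteA,siteB feature names (or row indices) of the recombining
#'   sites; `siteB` is on `molB` when given, else on `molA`.
#' @param molB optional second substrate (integration).
#' @param crossover_offset integer offset of the crossover within the
#'   shared core (0..core length); default: core midpoint.
#' @return object of class `reaction_result`: list with `products` (list of
#'   [molecule()]), `reaction`, `crossover` (the offset used) and `cuts`.
#' @examples
#' # a direct-repeat excision releasing spacer + one hybrid site
#' @export
site_recombine <- function(molA, siteA, siteB, molB = NULL,
                           crossover_offset = NULL) {
  fA <- get_feature(molA, siteA)
  fB <- get_feature(molB %||% molA, siteB)
  cA <- core_seq(molA, fA); cB <- core_seq(molB %||% molA, fB)
  if (nchar(cA) != nchar(cB) || cA != cB)
    stop("incompatible sites: core sequences are not identical ",
         "(no recombination)", call. = FALSE)
  core_len <- nchar(cA)
  off <- as.integer(crossover_offset %||% (core_len %/% 2L))
  if (off < 0L || off > core_len)
    stop("crossover_offset outside the shared core", call. = FALSE)

  if (!is.null(molB)) {
    res <- react_integration(molA, fA, molB, fB, off)
  } else if (fA$strand == fB$strand) {
    res <- react_excision(molA, fA, fB, off)
  } else {
    res <- react_inversion(molA, fA, fB, off)
  }
  res$crossover <- off
  class(res) <- "reaction_result"
  res
}

#' @export
print.reaction_result <- function(x, ...) {
  cat(sprintf("<reaction_result> %s: %d product(s) of %s bp\n", x$reaction,
              length(x$products),
              paste(vapply(x$products, `[[`, 0L, "length"),
                    collapse = " + ")))
  invisible(x)
}

hybrid_name <- function(a, b) {
  if (setequal(c(a, b), c("attP", "attB"))) "attL"
  else if (setequal(c(a, b), c("attL", "attR")))
    if (a == "attL") "attP" else "attB"
  else paste0(a, "x", b)
}

## features of `mol` remapped into a product window [from, to) of the
## (possibly virtually rotated) source; drops att sites consumed by the
## reaction (listed in drop_rows), splits other features at the window
## edges with :5p/:3p suffixes.
window_features <- function(feats, from, to, shift, drop_rows = integer(0)) {
  keep <- setdiff(seq_len(nrow(feats)), drop_rows)
  out <- NULL
  for (r in keep) {
    s <- feats$start[r]; e <- feats$end[r]
    if (e <= from || s >= to) next
    nm <- feats$name[r]
    cs <- s; ce <- e
    if (s < from) { cs <- from; nm <- paste0(nm, ":3p") }
    if (e > to)   { ce <- to;   nm <- paste0(nm, ":5p") }
    row <- feats[r, , drop = FALSE]
    row$name <- nm; row$start <- cs + shift; row$end <- ce + shift
    if (!is.na(row$core_start)) {
      row$core_start <- max(row$core_start, cs) + shift
      row$core_end <- min(row$core_end, ce) + shift
      if (row$core_start >= row$core_end) {
        row$core_start <- NA_integer_; row$core_end <- NA_integer_
        row$type <- "misc"
      }
    }
    out <- rbind(out, row)
  }
  out %||% empty_features()
}

react_excision <- function(mol, f1, f2, off) {
  rows <- c(which(mol$features$name == f1$name &
                  mol$features$start == f1$start),
            which(mol$features$name == f2$name &
                  mol$features$start == f2$start))
  c1 <- cut_pos(f1, off); c2 <- cut_pos(f2, off)
  if (c1 > c2) { tmp <- f1; f1 <- f2; f2 <- tmp; tmp <- c1; c1 <- c2
                 c2 <- tmp }
  ## deletion circle: [c1, c2); carries the spacer plus one hybrid site
  ## composed of site-1 suffix + site-2 prefix across its junction
  seq1 <- subseq0(mol$seq, c1, c2)
  feats1 <- window_features(mol$features, c1, c2, -c1, rows)
  hyb1_len_suffix <- f1$end - c1        # site-1 suffix at circle start
  hyb1_start <- f2$start - c1           # site-2 prefix at circle end
  feats1 <- rbind(feats1, data.frame(
    name = hybrid_name(f2$name, f1$name), type = "att",
    start = hyb1_start, end = (c2 - c1) + hyb1_len_suffix,
    strand = f1$strand,
    core_start = f2$core_start - c1,
    core_end = (c2 - c1) + (f1$core_end - c1)))
  circle <- molecule(paste0(mol$id, "_excised"), seq1, circular = TRUE,
                     features = feats1)
  if (mol$circular) {
    ## remaining circle: [c2, L) + [0, c1), with the complementary hybrid
    seq2 <- paste0(subseq0(mol$seq, c2, mol$length),
                   subseq0(mol$seq, 0L, c1))
    tail_len <- mol$length - c2
    rem_len <- tail_len + c1
    feats2 <- rbind(window_features(mol$features, c2, mol$length, -c2,
                                    rows),
                    window_features(mol$features, 0L, c1, tail_len, rows))
    ## hybrid wraps the remainder's junction: site-1 prefix (near its
    ## end) then site-2 suffix (at its start)
    feats2 <- rbind(feats2, data.frame(
      name = hybrid_name(f1$name, f2$name), type = "att",
      start = tail_len + f1$start, end = rem_len + (f2$end - c2),
      strand = f1$strand,
      core_start = tail_len + f1$core_start,
      core_end = rem_len + (f2$core_end - c2)))
  } else {
    ## linear substrate: deletion leaves a linear molecule with the
    ## hybrid at the fusion point c1
    seq2 <- paste0(subseq0(mol$seq, 0L, c1),
                   subseq0(mol$seq, c2, mol$length))
    feats2 <- rbind(window_features(mol$features, 0L, c1, 0L, rows),
                    window_features(mol$features, c2, mol$length,
                                    c1 - c2, rows))
    feats2 <- rbind(feats2, data.frame(
      name = hybrid_name(f1$name, f2$name), type = "att",
      start = f1$start, end = c1 + (f2$end - c2),
      strand = f1$strand,
      core_start = f1$core_start, core_end = c1 + (f2$core_end - c2)))
  }
  remainder <- molecule(paste0(mol$id, "_backbone"), seq2,
                        circular = mol$circular, features = feats2)
  list(products = list(circle, remainder), reaction = "excision",
       cuts = c(c1, c2))
}

react_inversion <- function(mol, f1, f2, off) {
  c1 <- cut_pos(f1, off); c2 <- cut_pos(f2, off)
  if (c1 > c2) { tmp <- c1; c1 <- c2; c2 <- tmp }
  if (c1 == c2) stop("degenerate inversion: coincident cuts", call. = FALSE)
  seq <- paste0(subseq0(mol$seq, 0L, c1),
                reverse_complement(subseq0(mol$seq, c1, c2)),
                subseq0(mol$seq, c2, mol$length))
  feats <- mol$features
  for (r in seq_len(nrow(feats))) {
    s <- feats$start[r]; e <- feats$end[r]
    if (s >= c1 && e <= c2) {
      feats$start[r] <- c1 + c2 - e; feats$end[r] <- c1 + c2 - s
      if (!is.na(feats$core_start[r])) {
        cs <- feats$core_start[r]; ce <- feats$core_end[r]
        feats$core_start[r] <- c1 + c2 - ce
        feats$core_end[r] <- c1 + c2 - cs
      }
      feats$strand[r] <- if (feats$strand[r] == "+") "-" else "+"
    }
    ## sites straddling a cut (the recombining pair) keep their
    ## coordinates: the crossover reconstitutes a full core at each
    ## junction in the original orientation
  }
  prod <- molecule(mol$id, seq, circular = mol$circular, features = feats)
  list(products = list(prod), reaction = "inversion", cuts = c(c1, c2))
}

react_integration <- function(molA, fA, molB, fB, off) {
  if (!molA$circular || !molB$circular)
    stop("integration requires two circular substrates", call. = FALSE)
  if (fA$strand != fB$strand)
    stop("inverted intermolecular geometry not supported: flip one ",
         "molecule first", call. = FALSE)
  cA <- cut_pos(fA, off); cB <- cut_pos(fB, off)
  rowsA <- which(molA$features$name == fA$name &
                 molA$features$start == fA$start)
  rowsB <- which(molB$features$name == fB$name &
                 molB$features$start == fB$start)
  seq <- paste0(subseq0(molA$seq, 0L, cA),
                subseq0(molB$seq, cB, molB$length),
                subseq0(molB$seq, 0L, cB),
                subseq0(molA$seq, cA, molA$length))
  lenB <- molB$length
  feats <- rbind(
    window_features(molA$features, 0L, cA, 0L, rowsA),
    window_features(molB$features, cB, lenB, cA - cB, rowsB),
    window_features(molB$features, 0L, cB, cA + (lenB - cB), rowsB),
    window_features(molA$features, cA, molA$length, lenB, rowsA))
  ## hybrid sites at the two junctions: A-prefix + B-suffix at coordinate
  ## cA, and B-prefix + A-suffix at coordinate cA + lenB
  h1 <- data.frame(name = hybrid_name(fA$name, fB$name), type = "att",
                   start = fA$start, end = cA + (fB$end - cB),
                   strand = fA$strand,
                   core_start = fA$core_start,
                   core_end = cA + (fB$core_end - cB))
  h2 <- data.frame(name = hybrid_name(fB$name, fA$name), type = "att",
                   start = cA + (lenB - cB) + fB$start,
                   end = lenB + fA$end,
                   strand = fA$strand,
                   core_start = cA + (lenB - cB) + fB$core_start,
                   core_end = lenB + fA$core_end)
  feats <- rbind(feats, h1, h2)
  prod <- molecule(paste0(molA$id, "::", molB$id), seq, circular = TRUE,
                   features = feats)
  list(products = list(prod), reaction = "integration", cuts = c(cA, cB))
}

#' Low-sequence-specificity recombination between shared segments
#'
#' Finds every maximal perfectly shared segment of at least `min_core` bp
#' between (or within) the substrates, synthesises a generic att-site pair
#' at each, and returns the corresponding [site_recombine()] result,
#' flagged with the core length (a qualitative proxy for the reaction's
#' efficiency gradient). Within one molecule, direct repeats give excision
#' (circular substrates) and inverted repeats give inversion; between two
#' molecules, shared segments give integration.
#'
#' @param molA [molecule()].
#' @param molB optional second substrate; omitted for intramolecular
#'   reactions.
#' @param min_core minimum shared-segment length in bp (default 100, the
#'   smallest substrate active in vitro).
#' @return list of `reaction_result` objects, each with elements
#'   `core_len`, `a_start`, `b_start`, `orientation` describing the
#'   substrate segment; empty list when nothing is shared.
#' @export
homologous_recombine <- function(molA, molB = NULL, min_core = 100L) {
  min_core <- as.integer(min_core)
  if (min_core < 1L) stop("min_core must be >= 1", call. = FALSE)
  k <- min(min_core, 20L)
  out <- list()
  add <- function(res, m, orient) {
    res$core_len <- m$len; res$a_start <- m$a_start
    res$b_start <- m$b_start; res$orientation <- orient
    out[[length(out) + 1L]] <<- res
  }
  generic_site <- function(prefix, i, start, len, strand) {
    att_feature(paste0(prefix, i), start, start + len, strand = strand)
  }

  if (is.null(molB)) {
    for (orient in c("direct", "inverted")) {
      sb <- if (orient == "inverted") reverse_complement(molA$seq) else
        molA$seq
      m <- shared_exact_matches(molA$seq, sb, k = k)
      if (orient == "direct") {
        m <- m[m$len < molA$length, , drop = FALSE]      # drop self-match
      } else {
        m$b_start <- molA$length - m$b_start - m$len      # map to + strand
      }
      m <- m[m$len >= min_core & m$b_start > m$a_start, , drop = FALSE]
      ## no overlapping copies (palindrome-like self hits)
      m <- m[m$b_start >= m$a_start + m$len, , drop = FALSE]
      for (r in seq_len(nrow(m))) {
        if (orient == "direct" && !molA$circular) next
        mol2 <- molA
        mol2$features <- rbind(mol2$features,
          generic_site("hr_a", r, m$a_start[r], m$len[r], "+"),
          generic_site("hr_b", r, m$b_start[r], m$len[r],
                       if (orient == "inverted") "-" else "+"))
        res <- site_recombine(mol2, paste0("hr_a", r), paste0("hr_b", r))
        add(res, m[r, ], orient)
      }
    }
  } else {
    m <- shared_exact_matches(molA$seq, molB$seq, k = k)
    m <- m[m$len >= min_core, , drop = FALSE]
    for (r in seq_len(nrow(m))) {
      a2 <- molA; b2 <- molB
      a2$features <- rbind(a2$features,
        generic_site("hr_a", r, m$a_start[r], m$len[r], "+"))
      b2$features <- rbind(b2$features,
        generic_site("hr_b", r, m$b_start[r], m$len[r], "+"))
      res <- site_recombine(a2, paste0("hr_a", r), paste0("hr_b", r),
                            molB = b2)
      add(res, m[r, ], "direct")
    }
  }
  out
}

#' In-silico restriction digest
#'
#' Scans both strands for exact occurrences of the recognition sequence
#' and returns fragment lengths. Cuts are placed at the start of each
#' recognition site; fragment sizes are unaffected by the within-site cut
#' offset.
#'
#' @param mol [molecule()].
#' @param recognition recognition sequence (>= 4 bp).
#' @return integer vector of fragment lengths (decreasing); attribute
#'   `status` is `"cut"` or, for a circular molecule without sites,
#'   `"uncut_circular"` (empty vector); attribute `cuts` holds cut
#'   positions.
#' @export
digest <- function(mol, recognition) {
  recognition <- toupper(recognition)
  if (nchar(recognition) < 4L)
    stop("recognition sequence must be >= 4 bp", call. = FALSE)
  rl <- nchar(recognition)
  scan_seq <- if (mol$circular)
    paste0(mol$seq, subseq0(mol$seq, 0L, rl - 1L)) else mol$seq
  hit_starts <- function(pat) {
    h <- gregexpr(pat, scan_seq, fixed = TRUE)[[1]]
    if (h[1] == -1L) integer(0) else as.integer(h) - 1L
  }
  cuts <- sort(unique(c(hit_starts(recognition),
                        hit_starts(reverse_complement(recognition)))))
  cuts <- cuts[cuts < mol$length]
  if (length(cuts) == 0L) {
    frags <- if (mol$circular) integer(0) else mol$length
    out <- frags
    attr(out, "status") <- if (mol$circular) "uncut_circular" else "cut"
    attr(out, "cuts") <- integer(0)
    return(out)
  }
  if (mol$circular) {
    frags <- diff(c(cuts, cuts[1] + mol$length))
  } else {
    frags <- diff(c(0L, cuts, mol$length))
    frags <- frags[frags > 0L]
  }
  out <- sort(as.integer(frags), decreasing = TRUE)
  attr(out, "status") <- "cut"
  attr(out, "cuts") <- cuts
  out
}

#' Predict PCR amplicons
#'
#' Exact-match primer binding; amplicons are reported for convergent
#' primer pairs within `max_len`, including across the origin of circular
#' molecules — so outward-facing primers on an integrated element yield a
#' product only after excision and circularization.
#'
#' @param mol [molecule()].
#' @param fwd,rev primer sequences (>= 15 nt), written 5'->3'.
#' @param max_len maximum amplicon length (default 10000).
#' @return sorted integer vector of amplicon lengths (may be empty); warns
#'   when a primer binds at more than 5 loci.
#' @export
pcr_predict <- function(mol, fwd, rev, max_len = 10000L) {
  fwd <- toupper(fwd); rev <- toupper(rev)
  if (nchar(fwd) < 15L || nchar(rev) < 15L)
    stop("primers must be >= 15 nt", call. = FALSE)
  scan_seq <- if (mol$circular)
    paste0(mol$seq, subseq0(mol$seq, 0L, min(mol$length,
                                             max(nchar(fwd), nchar(rev)))))
  else mol$seq
  starts_of <- function(pat) {
    h <- gregexpr(pat, scan_seq, fixed = TRUE)[[1]]
    p <- if (h[1] == -1L) integer(0) else as.integer(h) - 1L
    unique(p %% if (mol$circular) mol$length else .Machine$integer.max)
  }
  amp <- integer(0)
  pair_products <- function(p_fwd, p_rev_seq, rev_len) {
    fpos <- starts_of(p_fwd)
    rpos <- starts_of(p_rev_seq)       # revcomp of reverse primer, + strand
    if (length(fpos) > 5L || length(rpos) > 5L)
      warning("primer binds at more than 5 loci; products may be ambiguous")
    for (f in fpos) for (r in rpos) {
      rend <- r + rev_len
      len <- if (mol$circular) ((rend - f - 1L) %% mol$length) + 1L
             else rend - f
      if (!is.na(len) && len >= nchar(p_fwd) + rev_len && len <= max_len)
        amp <- c(amp, len)
    }
    amp
  }
  amp <- pair_products(fwd, reverse_complement(rev), nchar(rev))
  sort(unique(as.integer(amp)))
}

#' Are two sequences equal as circles?
#'
#' True when `b` is a rotation of `a` (or of its reverse complement, with
#' `allow_flip`).
#'
#' @param a,b nucleotide strings.
#' @param allow_flip also accept the reverse complement (default TRUE).
#' @return logical.
#' @export
circular_equal <- function(a, b, allow_flip = TRUE) {
  if (nchar(a) != nchar(b)) return(FALSE)
  if (grepl(b, paste0(a, a), fixed = TRUE)) return(TRUE)
  allow_flip && grepl(reverse_complement(b), paste0(a, a), fixed = TRUE)
}

#' Read / write molecule maps as JSON
#'
#' The JSON object has fields `id`, `circular`, `seq` and `features`
#' (array of objects with `name`, `type`, `start`, `end`, `strand`,
#' `core_start`, `core_end`; coordinates 0-based half-open).
#'
#' @param mol [molecule()].
#' @param path file path.
#' @return `read_molecule` returns a [molecule()]; `write_molecule`
#'   returns `path` invisibly.
#' @export
write_molecule <- function(mol, path) {
  jsonlite::write_json(list(id = mol$id, circular = mol$circular,
                            seq = mol$seq, features = mol$features),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_molecule
#' @export
read_molecule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- if (length(x$features) == 0L) empty_features() else
    as.data.frame(x$features)
  if (nrow(feats) > 0L) {
    feats$start <- as.integer(feats$start)
    feats$end <- as.integer(feats$end)
    feats$core_start <- as.integer(feats$core_start)
    feats$core_end <- as.integer(feats$core_end)
  }
  molecule(x$id, x$seq, circular = isTRUE(x$circular), features = feats)
}
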