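#' Genome records and sequence primitives
#'
#' A `genome_record` is a named nucleotide sequence over `{A,C,G,T,N}` with a
#' circularity flag and an origin offset recording any rotation applied so
#' that position 0 is the chosen origin (e.g. a predicted origin of
#' replication). All coordinates in this package are 0-based, half-open.
#'
#' @param id character label.
#' @param seq nucleotide string; lowercase accepted, stored uppercase.
#' @param circular logical, is the molecule circular?
#' @param origin_offset integer rotation (bp) already applied; `0 <=
#'   origin_offset < length`.
#' @return An object of class `genome_record` with fields `id`, `seq`,
#'   `circular`, `origin_offset` and `length`.
#' @examples
#' g <- genome_record("g1", "acgtACGT")
#' g$seq
#' @export
genome_record <- function(id, seq, circular = FALSE, origin_offset = 0L) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty sequence for record '", id, "'", call. = FALSE)
  check_dna(seq, paste0("record '", id, "'"))
  len <- nchar(seq)
  origin_offset <- as.integer(origin_offset)
  if (origin_offset < 0L || origin_offset >= len)
    stop("origin_offset must be in [0, length)", call. = FALSE)
  structure(list(id = as.character(id), seq = seq,
                 circular = isTRUE(circular),
                 origin_offset = origin_offset, length = len),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp, %s, origin offset %d\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear", x$origin_offset))
  invisible(x)
}

#' Load genomes from a FASTA file
#'
#' Reads one `genome_record` per FASTA record. Sequences are upper-cased;
#' characters outside `{A,C,G,T,N}` are rejected; the id is the header up to
#' the first whitespace.
#'
#' @param path FASTA file.
#' @param circular logical flag applied to every record.
#' @return A list of [genome_record()] objects (length 1 for single-record
#'   files).
#' @export
load_genome <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a valid FASTA file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    genome_record(ids[i], as.character(set[[i]]), circular = circular)
  })
}

#' Write genome records to FASTA
#'
#' Output is wrapped at 70 columns and always uppercase.
#'
#' @param records a `genome_record` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome <- function(records, path) {
  if (inherits(records, "genome_record")) records <- list(records)
  set <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "seq"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Reverse complement
#'
#' Length-preserving involution over `{A,C,G,T,N}`; `N` maps to `N`.
#'
#' @param seq nucleotide string (vectorised over multiple strings).
#' @return reverse-complemented string(s).
#' @examples
#' reverse_complement("AAAC") # "GTTT"
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  check_dna(seq)
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), "",
         USE.NAMES = FALSE)
}

#' Rotate a circular genome to a new origin
#'
#' Returns the record with sequence `seq[new_origin:] + seq[:new_origin]`
#' (0-based) and the cumulative rotation recorded in `origin_offset`.
#'
#' @param g a circular [genome_record()].
#' @param new_origin integer in `[0, length)`.
#' @return the rotated `genome_record`.
#' @export
rotate_circular <- function(g, new_origin) {
  stopifnot(inherits(g, "genome_record"))
  if (!g$circular) stop("cannot rotate a linear record", call. = FALSE)
  new_origin <- as.integer(new_origin)
  if (new_origin < 0L || new_origin >= g$length)
    stop("new_origin must be in [0, length)", call. = FALSE)
  if (new_origin == 0L) return(g)
  seq <- paste0(subseq0(g$seq, new_origin, g$length),
                subseq0(g$seq, 0L, new_origin))
  genome_record(g$id, seq, circular = TRUE,
                origin_offset = (g$origin_offset + new_origin) %% g$length)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ file.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
load_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0)))
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: line count not a multiple of 4", call. = FALSE)
  ids <- sub("^@", "", lines[seq(1, length(lines), 4)])
  data.frame(id = ids,
             seq = toupper(lines[seq(2, length(lines), 4)]),
             qual = lines[seq(4, length(lines), 4)],
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads data.frame with columns `id`, `seq` and optionally `qual`
#'   (defaults to constant quality "I", Q40).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual
  if (is.null(qual)) qual <- strrep("I", nchar(reads$seq))
  out <- character(4L * nrow(reads))
  out[seq(1, length(out), 4)] <- paste0("@", reads$id)
  out[seq(2, length(out), 4)] <- reads$seq
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- qual
  writeLines(out, path)
  invisible(path)
}
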