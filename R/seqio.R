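#' Read nucleotide sequences from a FASTA file
#'
#' Sequences are upper-cased on read and validated against the nucleotide
#' alphabet `{A,C,G,T,N}`. Record ids (the header token before the first
#' whitespace) must be unique within a file.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences; full header descriptions
#'   are kept in the `"desc"` attribute.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  desc <- names(x)
  ids <- sub("\\s.*$", "", desc)
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(x))
  if (any(nchar(seqs) == 0L)) stop("empty sequence in ", path)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-nucleotide characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  names(seqs) <- ids
  attr(seqs, "desc") <- desc
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  x <- Biostrings::BStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read reads from a FASTQ file (qualities ignored)
#'
#' @param path Path to a FASTQ file.
#' @return A list with elements `reads` (named, upper-cased character vector)
#'   and `read_length` (the common read length; an error if reads differ in
#'   length).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  if (length(x) == 0L) stop("empty FASTQ file: ", path)
  reads <- toupper(as.character(x))
  names(reads) <- sub("\\s.*$", "", names(x))
  len <- unique(nchar(reads))
  if (length(len) != 1L)
    stop("reads of differing length in ", path)
  list(reads = reads, read_length = len)
}

#' Write reads to a FASTQ file with placeholder qualities
#'
#' Quality strings are constant `'I'` (Phred 40); the toolkit works on
#' post-trimming reads and never consumes qualities.
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.character(reads), !is.null(names(reads)))
  qual <- vapply(nchar(reads), function(n) strrep("I", n), "")
  lines <- as.vector(rbind(paste0("@", names(reads)), unname(reads),
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Write a HybPiper-style target reference FASTA
#'
#' One record per (source species, locus), with headers formatted
#' `"<Species>-<locusID>"`. The dash is the reserved separator of that
#' dialect, so neither species nor locus ids may contain one.
#'
#' @param panel_loci Named list (by locus id); each element is a named
#'   character vector of reference sequences keyed by source species.
#' @param path Output path.
#' @export
write_target_file <- function(panel_loci, path) {
  if (length(panel_loci) == 0L) {
    warning("no loci to write; emitting empty target file")
    file.create(path)
    return(invisible(path))
  }
  stopifnot(!is.null(names(panel_loci)))
  ids <- character(0)
  seqs <- character(0)
  for (locus in names(panel_loci)) {
    refs <- panel_loci[[locus]]
    stopifnot(length(refs) >= 1L, !is.null(names(refs)))
    if (grepl("-", locus, fixed = TRUE))
      stop("locus id contains reserved separator '-': ", locus)
    if (any(grepl("-", names(refs), fixed = TRUE)))
      stop("species name contains reserved separator '-': ",
           paste(grep("-", names(refs), fixed = TRUE, value = TRUE),
                 collapse = ", "))
    ids <- c(ids, paste0(names(refs), "-", locus))
    seqs <- c(seqs, unname(refs))
  }
  names(seqs) <- ids
  write_fasta(seqs, path)
}

#' Parse a HybPiper-style target FASTA into (species, locus) records
#'
#' @param path Path to a target FASTA whose headers follow
#'   `"<Species>-<locusID>"`.
#' @return A data.frame with columns `ref` (full header), `species`, `locus`,
#'   `seq`, `len`.
#' @export
read_target_file <- function(path) {
  seqs <- read_fasta(path)
  ids <- names(seqs)
  if (any(!grepl("-", ids, fixed = TRUE)))
    stop("target headers must be '<Species>-<locus>': ",
         paste(ids[!grepl("-", ids, fixed = TRUE)], collapse = ", "))
  species <- sub("-[^-]*$", "", ids)
  locus <- sub("^.*-", "", ids)
  data.frame(ref = ids, species = species, locus = locus,
             seq = unname(seqs), len = nchar(unname(seqs)),
             stringsAsFactors = FALSE)
}

#' Construct and validate an exon map
#'
#' Intervals are 0-based half-open transcript coordinates and must be sorted,
#' non-overlapping and, together, cover the transcript end to end.
#'
#' @param start,end Integer vectors of interval starts/ends.
#' @param transcript_len Transcript length the map must cover exactly.
#' @return A data.frame with columns `start`, `end` of class `"exon_map"`.
#' @export
exon_map <- function(start, end, transcript_len) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == length(end), length(start) >= 1L)
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (any(end <= start)) stop("exon interval with end <= start")
  if (start[1L] != 0L || end[length(end)] != transcript_len)
    stop("exon map does not cover the transcript end-to-end")
  if (length(start) > 1L && any(start[-1L] != end[-length(end)]))
    stop("exon intervals overlap or leave gaps")
  structure(data.frame(start = start, end = end),
            class = c("exon_map", "data.frame"))
}

#' Read per-transcript exon maps from a BED-like file
#'
#' Three whitespace-separated columns (transcript id, start, end), 0-based
#' half-open. Each transcript's intervals must satisfy the [exon_map()]
#' invariants against the supplied transcript lengths.
#'
#' @param path Path to the BED-like file.
#' @param transcripts Named character vector of the transcripts the map
#'   annotates (used for length validation and id checks).
#' @return A named list of exon maps keyed by transcript id.
#' @export
read_exon_bed <- function(path, transcripts) {
  bed <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("id", "start", "end"))
  unknown <- setdiff(unique(bed$id), names(transcripts))
  if (length(unknown))
    stop("exon map for unknown transcript(s): ",
         paste(unknown, collapse = ", "))
  maps <- lapply(split(bed, bed$id), function(d) {
    exon_map(d$start, d$end, nchar(transcripts[[d$id[1L]]]))
  })
  maps[unique(bed$id)]
}

#' Write per-transcript exon maps to a BED-like file
#'
#' @param maps Named list of exon maps.
#' @param path Output path.
#' @export
write_exon_bed <- function(maps, path) {
  rows <- do.call(rbind, lapply(names(maps), function(id) {
    data.frame(id = id, start = maps[[id]]$start, end = maps[[id]]$end)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate a gapped multiple alignment
#'
#' @param rows Named character vector of gapped sequences (gap character
#'   `'-'`), at least two rows, all the same length.
#' @return The rows, invisibly classed as `"multi_alignment"`.
#' @export
multi_alignment <- function(rows) {
  stopifnot(is.character(rows), !is.null(names(rows)), length(rows) >= 2L)
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows differ in length")
  structure(rows, class = "multi_alignment")
}

#' Number of columns of an alignment
#' @param aln A gapped alignment (named character vector).
#' @export
aln_ncol <- function(aln) nchar(aln[[1L]])

#' Reverse-complement of nucleotide strings
#' @param seqs Character vector over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seqs) {
  vapply(seqs, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}
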