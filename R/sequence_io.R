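#' Genome sequence container
#'
#' An in-memory genome: an ordered set of named nucleotide records plus a
#' genome label. Records are stored uppercase; IUPAC ambiguity codes other
#' than A/C/G/T/N are collapsed to N so downstream repeat detection and
#' flank alignment operate on a five-letter alphabet.
#'
#' @param records named character vector of nucleotide sequences.
#' @param genome_label label identifying the assembly (e.g. a cultivar name).
#' @return An object of class `GenomeSequence` with elements `genome_label`,
#'   `records` (named uppercase character vector) and `total_length` (bp).
#' @examples
#' g <- genome_sequence(c(chr1 = "ACGTacgt"), "demo")
#' g$total_length
#' @export
genome_sequence <- function(records, genome_label = "genome") {
  if (length(records) == 0L) stop("genome has no records")
  ids <- names(records)
  if (is.null(ids) || any(!nzchar(ids))) stop("all records must be named")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  recs <- toupper(as.character(records))
  bad <- grepl("[^A-Z]", recs)
  if (any(bad)) stop("non-letter characters in record(s): ",
                     paste(ids[bad], collapse = ", "))
  # collapse IUPAC ambiguity codes to N; reject non-IUPAC letters
  if (any(grepl("[EFIJLOPQXZ]", recs))) {
    stop("non-IUPAC nucleotide letters in record(s): ",
         paste(ids[grepl("[EFIJLOPQXZ]", recs)], collapse = ", "))
  }
  recs <- gsub("[^ACGTN]", "N", recs)
  names(recs) <- ids
  structure(
    list(genome_label = genome_label, records = recs,
         total_length = sum(nchar(recs))),
    class = "GenomeSequence"
  )
}

#' @export
print.GenomeSequence <- function(x, ...) {
  cat(sprintf("GenomeSequence '%s': %d record(s), %d bp total\n",
              x$genome_label, length(x$records), x$total_length))
  invisible(x)
}

#' Read a FASTA file into a GenomeSequence
#'
#' Parsing is delegated to [Biostrings::readDNAStringSet()]; wrapped lines
#' are concatenated, lowercase is folded to uppercase, and record ids must
#' be unique. Plain and gzip-compressed FASTA are accepted.
#'
#' @param path path to a FASTA file.
#' @param genome_label label for the genome; defaults to the file base name.
#' @return A [genome_sequence()] object.
#' @export
read_fasta <- function(path, genome_label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("not valid FASTA (", conditionMessage(e),
                             "): ", path, call. = FALSE)
  )
  if (length(set) == 0L) stop("no FASTA records in: ", path)
  recs <- as.character(set)
  # FASTA description lines: id = first whitespace-delimited token
  names(recs) <- sub("\\s.*$", "", names(set))
  if (is.null(genome_label)) {
    genome_label <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
                        basename(path), ignore.case = TRUE)
  }
  genome_sequence(recs, genome_label)
}

#' Write a GenomeSequence to FASTA
#'
#' @param genome a [genome_sequence()] object.
#' @param path output file path; `.gz` suffix triggers gzip compression.
#' @param width line-wrap width in bp.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "GenomeSequence"))
  set <- Biostrings::DNAStringSet(genome$records)
  Biostrings::writeXStringSet(set, path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Extract a subsequence
#'
#' Coordinates are 0-based half-open `[start, end)`, the package's internal
#' convention; exported locus tables use 1-based inclusive positions.
#'
#' @param genome a [genome_sequence()] object.
#' @param seq_id record identifier.
#' @param start,end 0-based half-open interval bounds.
#' @return Character scalar of length `end - start`.
#' @export
subsequence <- function(genome, seq_id, start, end) {
  stopifnot(inherits(genome, "GenomeSequence"))
  if (!seq_id %in% names(genome$records)) {
    stop("unknown seq_id: ", seq_id)
  }
  rec <- genome$records[[seq_id]]
  n <- nchar(rec)
  if (start < 0 || end < start || end > n) {
    stop(sprintf("interval [%d,%d) out of range for '%s' (length %d)",
                 start, end, seq_id, n))
  }
  if (end == start) return("")
  substr(rec, start + 1L, end)
}

#' Reverse complement of a nucleotide string
#'
#' Handles the full IUPAC alphabet (N maps to N) and is an involution.
#'
#' @param s nucleotide string.
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(s) {
  if (nchar(s) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Write a locus table as TSV
#'
#' Positions are exported 1-based inclusive (GFF3 convention); the header
#' comment states this explicitly.
#'
#' @param loci data.frame of SSR loci as returned by [detect_ssrs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_locus_table <- function(loci, path) {
  out <- loci
  out$start <- out$start + 1L  # 0-based half-open -> 1-based inclusive
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates are 1-based inclusive", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a locus table written by [write_locus_table()]
#' @param path TSV path.
#' @return data.frame with internal 0-based half-open coordinates.
#' @export
read_locus_table <- function(path) {
  loci <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
  loci$start <- loci$start - 1L
  loci
}

#' Export loci as GFF3 microsatellite features
#' @param loci data.frame of SSR loci ([detect_ssrs()] output).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loci_gff3 <- function(loci, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(loci)) {
    lines <- sprintf(
      "%s\tmgbssr\tmicrosatellite\t%d\t%d\t.\t+\t.\tID=ssr%04d;motif=%s;repeat_count=%d",
      loci$seq_id, loci$start + 1L, loci$end, seq_len(nrow(loci)),
      loci$motif, loci$repeat_count)
    writeLines(lines, con)
  }
  invisible(path)
}
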