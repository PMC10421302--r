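#' Detect perfect simple sequence repeats
#'
#' Scans every record of a genome for maximal perfect tandem repeats of
#' primitive motifs (motifs that are not themselves a repetition of a
#' shorter motif, so e.g. "ATAT" is never reported as a 4-mer). For each
#' motif length the scan is left-to-right: the leftmost maximal run is
#' reported and scanning resumes after it, so reported loci of the same
#' motif length never overlap and rotated sub-runs of an already reported
#' array are not reported again. Runs are maximal in whole motif units;
#' partial trailing copies are excluded. Runs containing N are split at
#' the N.
#'
#' @param genome a [genome_sequence()] object.
#' @param motif_lengths integer vector of motif lengths to scan,
#'   within 1..6 (defaults to the tri- to hexanucleotide range).
#' @param min_repeats minimum number of whole motif copies, either a single
#'   integer applied to every motif length or a vector named by motif
#'   length. Must be >= 2.
#' @return data.frame with columns `genome`, `seq_id`, `start` (0-based),
#'   `end` (half-open), `motif`, `repeat_count`, `core_seq`, sorted by
#'   `(seq_id, start)`.
#' @examples
#' g <- genome_sequence(c(s = paste0("TT", strrep("GCA", 7), "TT")), "demo")
#' detect_ssrs(g)
#' @export
detect_ssrs <- function(genome, motif_lengths = 3:6, min_repeats = 4L) {
  stopifnot(inherits(genome, "GenomeSequence"))
  motif_lengths <- sort(unique(as.integer(motif_lengths)))
  if (any(motif_lengths < 1L | motif_lengths > 6L)) {
    stop("motif_lengths must be within 1..6")
  }
  minrep <- .expand_min_repeats(min_repeats, motif_lengths)
  out <- list()
  for (sid in names(genome$records)) {
    s <- genome$records[[sid]]
    for (k in motif_lengths) {
      m <- minrep[[as.character(k)]]
      hits <- .scan_motif_length(s, k, m)
      if (nrow(hits)) {
        hits$seq_id <- sid
        out[[length(out) + 1L]] <- hits
      }
    }
  }
  if (!length(out)) {
    return(data.frame(genome = character(), seq_id = character(),
                      start = integer(), end = integer(),
                      motif = character(), repeat_count = integer(),
                      core_seq = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$genome <- genome$genome_label
  res <- res[order(res$seq_id, res$start), c("genome", "seq_id", "start",
                                             "end", "motif", "repeat_count",
                                             "core_seq")]
  rownames(res) <- NULL
  res
}

.expand_min_repeats <- function(min_repeats, motif_lengths) {
  if (any(min_repeats < 2L)) stop("min_repeats must be >= 2")
  if (length(min_repeats) == 1L && is.null(names(min_repeats))) {
    minrep <- stats::setNames(rep(as.integer(min_repeats),
                                  length(motif_lengths)),
                              as.character(motif_lengths))
  } else {
    if (is.null(names(min_repeats))) {
      stop("vector min_repeats must be named by motif length")
    }
    miss <- setdiff(as.character(motif_lengths), names(min_repeats))
    if (length(miss)) stop("min_repeats missing for motif length(s): ",
                           paste(miss, collapse = ", "))
    minrep <- as.integer(min_repeats)
    names(minrep) <- names(min_repeats)
  }
  as.list(minrep)
}

# One motif length: a perl regex with a backreference matches the leftmost
# maximal run of whole motif copies; [ACGT] in the captured unit keeps N
# out of cores (runs split at N for free). Negative lookaheads reject
# non-primitive motifs (any proper-divisor period) at the match start so a
# shorter-period array never consumes sequence at this motif length.
# Scanning resumes k-1 characters before the end of each match: a
# distinct maximal run may share up to k-1 boundary characters with the
# previous one and must still be reported, while the same run can never
# re-match (fewer than min_rep whole copies remain past the resume point).
.scan_motif_length <- function(s, k, min_rep) {
  divs <- seq_len(k - 1L)
  divs <- divs[k %% divs == 0L]
  look <- ""
  grp <- 0L
  for (d in divs) {
    grp <- grp + 1L
    look <- paste0(look,
                   sprintf("(?!([ACGT]{%d})\\%d{%d})", d, grp, k %/% d - 1L))
  }
  grp <- grp + 1L
  pat <- sprintf("%s([ACGT]{%d})\\%d{%d,}", look, k, grp, min_rep - 1L)
  n <- nchar(s)
  starts <- integer(0); lens <- integer(0)
  pos <- 1L
  while (pos + k * min_rep - 1L <= n) {
    m <- regexpr(pat, substr(s, pos, n), perl = TRUE)
    if (m == -1L) break
    st <- pos + as.integer(m) - 1L
    ln <- attr(m, "match.length")
    starts <- c(starts, st)
    lens <- c(lens, ln)
    pos <- st + ln - k + 1L
  }
  empty <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      repeat_count = integer(), core_seq = character(),
                      stringsAsFactors = FALSE)
  if (!length(starts)) return(empty)
  motifs <- substr(rep(s, length(starts)), starts, starts + k - 1L)
  reps <- lens %/% k
  data.frame(seq_id = NA_character_, start = starts - 1L,
             end = starts - 1L + lens, motif = motifs,
             repeat_count = reps,
             core_seq = substr(rep(s, length(starts)), starts,
                               starts + lens - 1L),
             stringsAsFactors = FALSE)
}

# A motif is primitive if it is not a whole-number repetition of any
# shorter motif (checked over all proper divisors of its length).
.is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        strrep(substr(motif, 1L, d), k %/% d) == motif) {
      return(FALSE)
    }
  }
  TRUE
}

#' Canonical motif key
#'
#' The lexicographically smallest string among all cyclic rotations of the
#' motif and of its reverse complement. Loci are always reported with the
#' motif as spelled in the genome; this key is an optional aid for
#' deduplicating motif classes across strands and phases.
#'
#' @param motif nucleotide motif.
#' @return Character scalar canonical key.
#' @export
canonical_motif <- function(motif) {
  k <- nchar(motif)
  rots <- function(x) {
    vapply(seq_len(k) - 1L, function(i) {
      paste0(substr(x, i + 1L, k), substr(x, 1L, i))
    }, character(1))
  }
  min(c(rots(motif), rots(reverse_complement(motif))))
}

#' Summarize SSR loci by motif length
#'
#' @param loci data.frame from [detect_ssrs()].
#' @param motif_lengths motif lengths to tabulate (zero counts included).
#' @return data.frame with columns `motif_length`, `count`, `percent`,
#'   plus an attribute `total`; percentages are of the total count and are
#'   0 when no loci are present.
#' @export
summarize_ssrs <- function(loci, motif_lengths = 3:6) {
  lens <- nchar(loci$motif)
  counts <- vapply(motif_lengths, function(k) sum(lens == k), integer(1))
  total <- sum(counts)
  pct <- if (total > 0) 100 * counts / total else rep(0, length(counts))
  res <- data.frame(motif_length = motif_lengths, count = counts,
                    percent = pct)
  attr(res, "total") <- total
  res
}

#' Print a motif-length summary block
#' @param summary output of [summarize_ssrs()].
#' @param label optional genome label for the header.
#' @return `summary`, invisibly.
#' @export
print_ssr_summary <- function(summary, label = NULL) {
  if (!is.null(label)) cat(sprintf("Genome: %s\n", label))
  cat(sprintf("%-14s %10s %10s\n", "motif length", "count", "percent"))
  for (i in seq_len(nrow(summary))) {
    cat(sprintf("%-14d %10d %9.2f%%\n", summary$motif_length[i],
                summary$count[i], summary$percent[i]))
  }
  cat(sprintf("%-14s %10d %9.2f%%\n", "total", attr(summary, "total"),
              if (attr(summary, "total") > 0) 100 else 0))
  invisible(summary)
}
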