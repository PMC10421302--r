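#' Attach flanking sequence to SSR loci
#'
#' Extracts the repeat core together with up to `flank_len` bp of genomic
#' sequence on each side (default 300 bp, the conserved-flank window used
#' for cross-genome matching and primer design). Flanks are truncated at
#' contig ends and such loci are flagged.
#'
#' @param loci data.frame from [detect_ssrs()].
#' @param genome the [genome_sequence()] the loci were detected in.
#' @param flank_len flank length in bp (>= 0).
#' @return `loci` with added columns `left_flank`, `right_flank`,
#'   `full_seq` (left + core + right, an exact genome substring),
#'   `truncated` (logical) and `locus_id`.
#' @export
extract_flanked <- function(loci, genome, flank_len = 300L) {
  stopifnot(inherits(genome, "GenomeSequence"), flank_len >= 0L)
  n <- nrow(loci)
  left <- character(n); right <- character(n); trunc <- logical(n)
  for (i in seq_len(n)) {
    if (!loci$seq_id[i] %in% names(genome$records)) {
      stop("locus seq_id not in genome: ", loci$seq_id[i])
    }
    rec <- genome$records[[loci$seq_id[i]]]
    len <- nchar(rec)
    if (loci$end[i] > len) stop("locus outside genome record: row ", i)
    ls <- max(0L, loci$start[i] - flank_len)
    re <- min(len, loci$end[i] + flank_len)
    left[i] <- subsequence(genome, loci$seq_id[i], ls, loci$start[i])
    right[i] <- subsequence(genome, loci$seq_id[i], loci$end[i], re)
    trunc[i] <- nchar(left[i]) < flank_len || nchar(right[i]) < flank_len
  }
  loci$left_flank <- left
  loci$right_flank <- right
  loci$full_seq <- paste0(left, loci$core_seq, right)
  loci$truncated <- trunc
  loci$locus_id <- sprintf("%s:%s:%d", loci$genome, loci$seq_id,
                           loci$start)
  loci
}

# Seed index: every overlapping seed_len-mer of every record, hashed to
# global positions. Built once per genome and reused across queries.
.seed_index <- function(genome, seed_len = 15L) {
  km <- character(0); seqidx <- integer(0); pos <- integer(0)
  for (si in seq_along(genome$records)) {
    s <- genome$records[[si]]
    n <- nchar(s)
    if (n < seed_len) next
    starts <- seq_len(n - seed_len + 1L)
    k <- substring(s, starts, starts + seed_len - 1L)
    km <- c(km, k)
    seqidx <- c(seqidx, rep.int(si, length(starts)))
    pos <- c(pos, starts)
  }
  env <- list2env(split(seq_along(km), km), hash = TRUE,
                  parent = emptyenv())
  list(env = env, seqidx = seqidx, pos = pos, seed_len = seed_len,
       genome = genome)
}

# Gapless flank placement: compare `flank` against the target record at
# 1-based position `at`, trying small diagonal shifts; returns the best
# (matches, shift). Columns are the flank length clipped to the record.
.place_flank <- function(rec, flank, at, max_shift = 3L) {
  fl <- nchar(flank)
  n <- nchar(rec)
  fchars <- strsplit(flank, "", fixed = TRUE)[[1]]
  best <- list(matches = -1L, shift = 0L, start = at, cols = 0L,
               mism_at = integer(0))
  for (sh in c(0L, seq_len(max_shift), -seq_len(max_shift))) {
    s0 <- at + sh
    lo <- max(1L, s0); hi <- min(n, s0 + fl - 1L)
    if (hi < lo) next
    tch <- strsplit(substr(rec, lo, hi), "", fixed = TRUE)[[1]]
    qoff <- lo - s0  # flank chars skipped at the left edge
    qch <- fchars[(qoff + 1L):(qoff + length(tch))]
    eq <- qch == tch
    matches <- sum(eq)
    if (matches > best$matches) {
      best <- list(matches = matches, shift = sh, start = s0,
                   cols = length(tch),
                   mism_at = (qoff + which(!eq)))  # 1-based flank offsets
    }
    if (best$matches == fl) break
  }
  best
}

#' Search a flanked query against a genome
#'
#' Seed-and-extend search for the orthologous site of an SSR query
#' (left flank + core + right flank). Non-overlapping seeds tiled along
#' each flank locate candidate placements; each flank is then aligned
#' gaplessly (best over small diagonal shifts) and left/right placements
#' are paired across a target core gap. Identity is computed over flank
#' columns only — the repeat core is excised before comparison, so
#' repeat-count differences between genomes do not depress identity.
#' Both strands are searched (the query is reverse-complemented and
#' re-searched; minus-strand hits are reported in forward target
#' coordinates with `strand == "-"`).
#'
#' @param query full query sequence (flanks + core).
#' @param target a [genome_sequence()] to search, or a prebuilt index from
#'   the internal seed indexer.
#' @param min_identity minimum flank identity (matches / flank columns).
#' @param core 0-based half-open `(start, end)` of the repeat core within
#'   `query`, or `NULL` to treat the whole query as a single flank.
#' @param motif repeat motif of the query core (required when `core` is
#'   given; used to recount repeats at the matched site).
#' @param min_coverage minimum fraction of flank columns that must be
#'   placed on the target.
#' @param seed_len exact-seed length; the query flanks must each be at
#'   least this long (error otherwise).
#' @param max_shift maximum diagonal shift tried during gapless placement.
#' @param window width (bp) of the core-adjacent flank windows in which
#'   mismatches are counted for the mutation filter.
#' @param both_strands search the minus strand as well.
#' @return data.frame of hits sorted by descending `flank_identity`:
#'   `seq_id`, `strand`, `start`, `end` (0-based half-open span in forward
#'   target coordinates), `flank_identity`, `window_mismatches`,
#'   `core_gap` (bp between the placed flanks) and `target_repeat_count`
#'   (0 if no run of the query motif is present at the matched site).
#' @export
search_genome <- function(query, target, min_identity = 0.90,
                          core = NULL, motif = NULL,
                          min_coverage = 0.9, seed_len = 15L,
                          max_shift = 3L, window = 50L,
                          both_strands = TRUE) {
  idx <- if (inherits(target, "GenomeSequence")) {
    .seed_index(target, seed_len)
  } else target
  hits <- .search_one_strand(query, idx, min_identity, core, motif,
                             min_coverage, max_shift, window, "+")
  if (both_strands) {
    qlen <- nchar(query)
    rcq <- reverse_complement(query)
    rcc <- if (is.null(core)) NULL else c(qlen - core[2], qlen - core[1])
    rcm <- if (is.null(motif)) NULL else reverse_complement(motif)
    hits <- rbind(hits, .search_one_strand(rcq, idx, min_identity, rcc,
                                           rcm, min_coverage, max_shift,
                                           window, "-"))
  }
  hits <- hits[order(-hits$flank_identity, hits$seq_id, hits$start), ]
  rownames(hits) <- NULL
  hits
}

.empty_hits <- function() {
  data.frame(seq_id = character(), strand = character(),
             start = integer(), end = integer(),
             flank_identity = numeric(), window_mismatches = integer(),
             core_gap = integer(), target_repeat_count = integer(),
             stringsAsFactors = FALSE)
}

.tile_seeds <- function(flank, seed_len) {
  fl <- nchar(flank)
  if (fl < seed_len) stop("query flank (", fl,
                          " bp) shorter than seed length (", seed_len, ")")
  starts <- unique(c(seq(1L, fl - seed_len + 1L, by = seed_len),
                     fl - seed_len + 1L))
  seeds <- substring(flank, starts, starts + seed_len - 1L)
  ok <- !grepl("N", seeds, fixed = TRUE)
  list(starts = starts[ok], seeds = seeds[ok])
}

# Candidate flank placements from seed lookups: (seq index, flank start).
.flank_candidates <- function(flank, idx) {
  td <- .tile_seeds(flank, idx$seed_len)
  cand_seq <- integer(0); cand_at <- integer(0)
  for (j in seq_along(td$starts)) {
    g <- idx$env[[td$seeds[j]]]
    if (is.null(g)) next
    cand_seq <- c(cand_seq, idx$seqidx[g])
    cand_at <- c(cand_at, idx$pos[g] - td$starts[j] + 1L)
  }
  if (!length(cand_at)) return(NULL)
  # cluster near-identical diagonals (within max shift) to one candidate
  o <- order(cand_seq, cand_at)
  cand_seq <- cand_seq[o]; cand_at <- cand_at[o]
  keep <- c(TRUE, diff(cand_at) > 3L | diff(cand_seq) != 0L)
  list(seq = cand_seq[keep], at = cand_at[keep])
}

.search_one_strand <- function(query, idx, min_identity, core, motif,
                               min_coverage, max_shift, window, strand) {
  qlen <- nchar(query)
  if (is.null(core)) core <- c(qlen, qlen)  # single-flank query
  left <- substr(query, 1L, core[1])
  right <- if (core[2] < qlen) substr(query, core[2] + 1L, qlen) else ""
  core_len <- core[2] - core[1]
  k <- if (!is.null(motif)) nchar(motif) else 0L
  max_gap <- max(200L, 4L * core_len)

  lc <- if (nzchar(left)) .flank_candidates(left, idx) else NULL
  rc <- if (nzchar(right)) .flank_candidates(right, idx) else NULL
  out <- .empty_hits()
  genome <- idx$genome
  nl <- nchar(left); nr <- nchar(right)
  tot_cols <- nl + nr

  if (nzchar(left) && nzchar(right)) {
    if (is.null(lc) || is.null(rc)) return(out)
    for (i in seq_along(lc$at)) {
      rec_i <- lc$seq[i]
      rec <- genome$records[[rec_i]]
      pl <- .place_flank(rec, left, lc$at[i], max_shift)
      # expected right-flank start if target core length were unchanged
      cand_j <- which(rc$seq == rec_i &
                        rc$at >= lc$at[i] + nl - max_shift &
                        rc$at <= lc$at[i] + nl + core_len + max_gap)
      if (!length(cand_j)) next
      for (j in cand_j) {
        pr <- .place_flank(rec, right, rc$at[j], max_shift)
        matches <- pl$matches + pr$matches
        cols <- pl$cols + pr$cols
        if (cols / tot_cols < min_coverage) next
        identity <- matches / cols
        if (identity < min_identity) next
        gap_lo <- pl$start + nl       # 1-based start of target core
        gap_hi <- pr$start - 1L       # 1-based end of target core
        core_gap <- gap_hi - gap_lo + 1L
        if (core_gap < 0L) next
        wm <- sum(pl$mism_at > nl - window) + sum(pr$mism_at <= window)
        trc <- 0L
        if (k > 0L) {
          wlo <- max(1L, gap_lo - k)
          whi <- min(nchar(rec), gap_hi + k)
          trc <- .count_motif_repeats(substr(rec, wlo, whi), motif)
        }
        out <- rbind(out, data.frame(
          seq_id = names(genome$records)[rec_i], strand = strand,
          start = pl$start - 1L, end = pr$start + pr$cols - 1L,
          flank_identity = identity, window_mismatches = wm,
          core_gap = core_gap, target_repeat_count = trc,
          stringsAsFactors = FALSE))
      }
    }
  } else {
    # single-flank query (plain sequence search)
    flank <- if (nzchar(left)) left else right
    cand <- if (nzchar(left)) lc else rc
    if (is.null(cand)) return(out)
    for (i in seq_along(cand$at)) {
      rec <- genome$records[[cand$seq[i]]]
      pl <- .place_flank(rec, flank, cand$at[i], max_shift)
      if (pl$cols / nchar(flank) < min_coverage) next
      identity <- pl$matches / pl$cols
      if (identity < min_identity) next
      out <- rbind(out, data.frame(
        seq_id = names(genome$records)[cand$seq[i]], strand = strand,
        start = pl$start - 1L, end = pl$start + pl$cols - 1L,
        flank_identity = identity, window_mismatches = 0L,
        core_gap = 0L, target_repeat_count = 0L,
        stringsAsFactors = FALSE))
    }
  }
  out
}

# Repeat count of `motif` (or a cyclic rotation, to absorb boundary phase)
# in a small window; maximal run in whole motif units, min 2 copies.
.count_motif_repeats <- function(window_seq, motif) {
  k <- nchar(motif)
  runs <- .scan_motif_length(window_seq, k, 2L)
  if (!nrow(runs)) return(0L)
  rots <- vapply(seq_len(k) - 1L, function(i) {
    paste0(substr(motif, i + 1L, k), substr(motif, 1L, i))
  }, character(1))
  runs <- runs[runs$motif %in% rots, , drop = FALSE]
  if (!nrow(runs)) return(0L)
  max(runs$repeat_count)
}

#' Cross-genome polymorphic SSR screen
#'
#' Runs the five-stage comparative screen over two or more related genome
#' assemblies. SSRs are detected in the anchor genome, extracted with
#' conserved flanks, and each candidate passes through, in order:
#' self-uniqueness in the anchor (multi-hit candidates dropped), ortholog
#' matching in every other genome at the flank-identity threshold
#' (ambiguous multi-hits dropped as non-unique; absent or low-identity
#' matches dropped), repeat-count comparison (all genomes equal dropped as
#' monomorphic), a flank-mutation filter on the core-adjacent primer
#' windows, and the all-genomes requirement (loci differing between only
#' two genomes dropped; retained loci have pairwise-distinct repeat counts
#' in every genome). With exactly two genomes the last stage is a no-op
#' and any repeat-count difference is retained.
#'
#' @param genomes list of [genome_sequence()] objects (>= 2, unique labels).
#' @param anchor label of the anchor genome (default: first).
#' @param motif_lengths,min_repeats detection parameters, see
#'   [detect_ssrs()].
#' @param flank_len conserved-flank length (bp).
#' @param min_identity minimum cross-genome flank identity.
#' @param min_coverage minimum placed fraction of flank columns.
#' @param seed_len exact-seed length for the search.
#' @param window core-adjacent window width (bp) for the mutation filter.
#' @param max_window_mutations mutations tolerated inside the windows
#'   (default 0: any substitution/indel at the likely primer sites drops
#'   the candidate).
#' @param near_best a secondary hit counts against uniqueness only if its
#'   identity is within this margin of the best hit.
#' @return list with `loci` (one row per anchor candidate: position, motif,
#'   per-genome repeat counts `rc_<label>`, per-genome flank identities
#'   `id_<label>`, `status`), `retained` (the surviving subset) and
#'   `funnel` (named candidate counts after each stage).
#' @export
screen_polymorphic <- function(genomes, anchor = NULL,
                               motif_lengths = 3:6, min_repeats = 4L,
                               flank_len = 300L, min_identity = 0.90,
                               min_coverage = 0.9, seed_len = 15L,
                               window = 50L, max_window_mutations = 0L,
                               near_best = 0.05) {
  if (length(genomes) < 2L) stop("need at least 2 genomes")
  labels <- vapply(genomes, function(g) g$genome_label, character(1))
  if (anyDuplicated(labels)) stop("genome labels must be unique")
  names(genomes) <- labels
  if (is.null(anchor)) anchor <- labels[1]
  if (!anchor %in% labels) stop("anchor label not found: ", anchor)
  others <- setdiff(labels, anchor)

  ag <- genomes[[anchor]]
  loci <- detect_ssrs(ag, motif_lengths, min_repeats)
  fl <- extract_flanked(loci, ag, flank_len)
  n <- nrow(fl)

  idx <- lapply(genomes, .seed_index, seed_len = seed_len)

  status <- rep(NA_character_, n)
  rc <- matrix(NA_integer_, n, length(labels),
               dimnames = list(NULL, labels))
  idm <- matrix(NA_real_, n, length(labels),
                dimnames = list(NULL, labels))
  wmut <- integer(n)
  rc[, anchor] <- fl$repeat_count
  idm[, anchor] <- 1

  for (i in seq_len(n)) {
    core <- c(nchar(fl$left_flank[i]),
              nchar(fl$left_flank[i]) + nchar(fl$core_seq[i]))
    # (a) self-uniqueness in the anchor
    selfhits <- search_genome(fl$full_seq[i], idx[[anchor]],
                              min_identity = min_identity, core = core,
                              motif = fl$motif[i],
                              min_coverage = min_coverage,
                              seed_len = seed_len, window = window)
    nq <- if (nrow(selfhits)) {
      sum(selfhits$flank_identity >=
            max(selfhits$flank_identity) - near_best)
    } else 0L
    if (nq != 1L) {
      status[i] <- "dropped_nonunique"
      next
    }
    # (b) ortholog matching in every other genome
    ok <- TRUE
    for (lab in others) {
      hits <- search_genome(fl$full_seq[i], idx[[lab]],
                            min_identity = min_identity, core = core,
                            motif = fl$motif[i],
                            min_coverage = min_coverage,
                            seed_len = seed_len, window = window)
      if (nrow(hits) == 0L) {
        status[i] <- "dropped_low_identity"; ok <- FALSE; break
      }
      nq <- sum(hits$flank_identity >=
                  max(hits$flank_identity) - near_best)
      if (nq > 1L) {
        status[i] <- "dropped_nonunique"; ok <- FALSE; break
      }
      rc[i, lab] <- hits$target_repeat_count[1]
      idm[i, lab] <- hits$flank_identity[1]
      wmut[i] <- wmut[i] + hits$window_mismatches[1]
    }
    if (!ok) next
    counts <- rc[i, ]
    # (c) repeat-count comparison
    if (length(unique(counts)) == 1L) {
      status[i] <- "dropped_monomorphic"
      next
    }
    # (d) flank-mutation filter at the primer windows
    if (wmut[i] > max_window_mutations) {
      status[i] <- "dropped_flank_mutation"
      next
    }
    # (e) all-genomes requirement (no-op for 2 genomes)
    if (length(counts) > 2L && anyDuplicated(counts)) {
      status[i] <- "dropped_two_way_only"
      next
    }
    status[i] <- "retained"
  }

  res <- fl[, c("locus_id", "seq_id", "start", "end", "motif",
                "repeat_count")]
  for (lab in labels) res[[paste0("rc_", lab)]] <- rc[, lab]
  for (lab in others) res[[paste0("id_", lab)]] <- idm[, lab]
  res$window_mutations <- wmut
  res$status <- status

  funnel <- c(
    detected = n,
    unique_in_anchor = sum(status != "dropped_nonunique"),
    matched_all_genomes = sum(!status %in%
      c("dropped_nonunique", "dropped_low_identity")),
    polymorphic = sum(!status %in%
      c("dropped_nonunique", "dropped_low_identity",
        "dropped_monomorphic")),
    flanks_clean = sum(!status %in%
      c("dropped_nonunique", "dropped_low_identity",
        "dropped_monomorphic", "dropped_flank_mutation")),
    retained = sum(status == "retained")
  )
  list(loci = res, retained = res[res$status == "retained", ],
       funnel = funnel)
}
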