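# SantaLucia unified nearest-neighbor parameters (dH kcal/mol, dS eu),
# duplex initiation split into terminal A/T vs G/C contributions and a
# symmetry term for self-complementary duplexes.
.NN_DH <- c("AA" = -7.9, "TT" = -7.9, "AT" = -7.2, "TA" = -7.2,
            "CA" = -8.5, "TG" = -8.5, "GT" = -8.4, "AC" = -8.4,
            "CT" = -7.8, "AG" = -7.8, "GA" = -8.2, "TC" = -8.2,
            "CG" = -10.6, "GC" = -9.8, "GG" = -8.0, "CC" = -8.0)
.NN_DS <- c("AA" = -22.2, "TT" = -22.2, "AT" = -20.4, "TA" = -21.3,
            "CA" = -22.7, "TG" = -22.7, "GT" = -22.4, "AC" = -22.4,
            "CT" = -21.0, "AG" = -21.0, "GA" = -22.2, "TC" = -22.2,
            "CG" = -27.2, "GC" = -24.4, "GG" = -19.9, "CC" = -19.9)

#' Nearest-neighbor melting temperature
#'
#' Duplex Tm from the SantaLucia unified nearest-neighbor parameter set
#' with terminal A/T and G/C initiation terms, a symmetry correction for
#' self-complementary oligos, and an entropy-based monovalent-salt
#' correction (0.368 (N-1) ln\[Na+\]). Defaults model a typical PCR mix:
#' 50 mM monovalent salt, 250 nM primer in excess over template.
#'
#' @param seq primer sequence, ACGT only.
#' @param Na monovalent cation concentration (mM).
#' @param primer_conc primer concentration (nM).
#' @return Tm in degrees Celsius.
#' @export
tm_nn <- function(seq, Na = 50, primer_conc = 250) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stop("primer must contain only A/C/G/T")
  n <- nchar(seq)
  if (n < 2L) stop("primer too short for nearest-neighbor Tm")
  steps <- substring(seq, 1:(n - 1L), 2:n)
  dh <- sum(.NN_DH[steps])
  ds <- sum(.NN_DS[steps])
  ends <- c(substr(seq, 1L, 1L), substr(seq, n, n))
  n_at <- sum(ends %in% c("A", "T"))
  n_gc <- 2L - n_at
  dh <- dh + 2.3 * n_at + 0.1 * n_gc
  ds <- ds + 4.1 * n_at - 2.8 * n_gc
  # primer in excess over template: the duplex CT term is the primer conc
  ct <- primer_conc * 1e-9
  if (identical(seq, reverse_complement(seq))) ds <- ds - 1.4
  ds <- ds + 0.368 * (n - 1L) * log(Na / 1000)
  r_gas <- 1.987
  1000 * dh / (ds + r_gas * log(ct)) - 273.15
}

#' M13(-21) universal primer sequence (18 nt)
#'
#' Default 5' tail prepended to the forward primer so a dye-labelled
#' universal primer labels every amplicon.
#' @export
M13_TAIL <- "TGTAAAACGACGGCCAGT"

#' Construct a primer pair record
#'
#' @param marker_id marker name.
#' @param forward_seq,reverse_seq primer sequences, 5'->3'.
#' @param expected_amplicon_len expected product size (bp), untailed.
#' @param dye fluorescent dye label (opaque string).
#' @param m13_tail tail prepended to the forward primer.
#' @return list of class `PrimerPair` with computed `tm_forward`,
#'   `tm_reverse` and `m13_tagged_forward`.
#' @export
primer_pair <- function(marker_id, forward_seq, reverse_seq,
                        expected_amplicon_len, dye = NA_character_,
                        m13_tail = M13_TAIL) {
  forward_seq <- toupper(forward_seq)
  reverse_seq <- toupper(reverse_seq)
  if (!nzchar(forward_seq) || !nzchar(reverse_seq)) {
    stop("primer sequences must be non-empty")
  }
  if (grepl("[^ACGT]", paste0(forward_seq, reverse_seq))) {
    stop("primer sequences must be ACGT only")
  }
  structure(list(
    marker_id = marker_id,
    forward_seq = forward_seq,
    reverse_seq = reverse_seq,
    expected_amplicon_len = as.integer(expected_amplicon_len),
    tm_forward = tm_nn(forward_seq),
    tm_reverse = tm_nn(reverse_seq),
    m13_tagged_forward = paste0(m13_tail, forward_seq),
    dye = dye
  ), class = "PrimerPair")
}

# Longest common substring length between two short strings (dynamic
# programming; primers are ~20 nt so quadratic cost is negligible).
.longest_common_substring <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L || nb == 0L) return(0L)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  prev <- integer(nb)
  best <- 0L
  for (i in seq_len(na)) {
    cur <- integer(nb)
    eq <- av[i] == bv
    cur[eq] <- c(1L, prev[-nb] + 1L)[eq]
    best <- max(best, cur)
    prev <- cur
  }
  best
}

# Longest suffix of `a` occurring as a substring of `b`.
.longest_anchored_suffix <- function(a, b) {
  na <- nchar(a)
  for (l in rev(seq_len(na))) {
    if (grepl(substr(a, na - l + 1L, na), b, fixed = TRUE)) return(l)
  }
  0L
}

#' Inter-primer dimer check
#'
#' Longest perfect complementary run between the two primers (all
#' antiparallel offsets), plus the longest run anchored at either primer's
#' 3' end — 3'-anchored duplexes prime extension and are held to a
#' stricter limit.
#'
#' @param forward_seq,reverse_seq primer sequences, 5'->3'.
#' @return list with `max_run` and `max_run_3prime`.
#' @export
primer_dimer_runs <- function(forward_seq, reverse_seq) {
  rcr <- reverse_complement(reverse_seq)
  rcf <- reverse_complement(forward_seq)
  list(
    max_run = .longest_common_substring(forward_seq, rcr),
    max_run_3prime = max(.longest_anchored_suffix(forward_seq, rcr),
                         .longest_anchored_suffix(reverse_seq, rcf))
  )
}

# Amplifiable sites of a convergent primer pair in one genome: forward
# matches one strand and the reverse-complemented reverse primer matches
# downstream within max_product bp (exact matching, both orientations).
.amplicon_sites <- function(pair, genome, max_product = 2000L) {
  count <- 0L
  for (rec in genome$records) {
    for (or in 1:2) {
      p1 <- if (or == 1L) pair$forward_seq else pair$reverse_seq
      p2 <- if (or == 1L) pair$reverse_seq else pair$forward_seq
      s1 <- gregexpr(p1, rec, fixed = TRUE)[[1]]
      if (s1[1] == -1L) next
      s2 <- gregexpr(reverse_complement(p2), rec, fixed = TRUE)[[1]]
      if (s2[1] == -1L) next
      for (a in as.integer(s1)) {
        prod <- as.integer(s2) + nchar(p2) - a
        count <- count + sum(prod >= nchar(p1) + nchar(p2) &
                               prod <= max_product)
      }
    }
  }
  count
}

#' Evaluate a primer pair against the six acceptance criteria
#'
#' The criteria: (1) both primers lie wholly within the conserved flanks
#' of the locus; (2) the amplicon is 50-300 bp; (3) forward/reverse
#' melting temperatures are within `tm_tolerance`; (4) no inter-primer
#' complementary run at or above the dimer limits; (5) exactly one
#' amplifiable site per screened genome; (6) the M13 tail is correctly
#' prepended to the forward primer.
#'
#' @param pair a [primer_pair()].
#' @param flanked one row of an [extract_flanked()] data.frame for the
#'   target locus (or `NULL` to skip criterion 1, reported `NA`).
#' @param genomes list of [genome_sequence()] objects for the specificity
#'   check (or `NULL` to skip criterion 5, reported `NA`).
#' @param tm_tolerance maximum |delta Tm| (deg C).
#' @param dimer_run any complementary run of this length fails.
#' @param dimer_run_3prime any 3'-anchored run of this length fails.
#' @param amplicon_range acceptable product-size range (bp).
#' @param m13_tail expected tail sequence.
#' @param max_product maximum product size scanned for spurious amplicons.
#' @return list of per-criterion logicals (`in_flanks`, `amplicon_size`,
#'   `tm_match`, `no_dimer`, `specific`, `m13_tagged`) plus `pass` (all
#'   non-NA criteria true) and supporting numbers.
#' @export
evaluate_primer_pair <- function(pair, flanked = NULL, genomes = NULL,
                                 tm_tolerance = 5, dimer_run = 8L,
                                 dimer_run_3prime = 5L,
                                 amplicon_range = c(50L, 300L),
                                 m13_tail = M13_TAIL,
                                 max_product = 2000L) {
  stopifnot(inherits(pair, "PrimerPair"))

  in_flanks <- NA
  amp_len <- pair$expected_amplicon_len
  if (!is.null(flanked)) {
    lf <- flanked$left_flank; rf <- flanked$right_flank
    f_in_left <- regexpr(pair$forward_seq, lf, fixed = TRUE)
    r_in_right <- regexpr(reverse_complement(pair$reverse_seq), rf,
                          fixed = TRUE)
    in_flanks <- f_in_left > 0L && r_in_right > 0L
    if (in_flanks) {
      # product spans from the forward 5' end to the reverse 5' end
      amp_len <- (nchar(lf) - as.integer(f_in_left) + 1L) +
        nchar(flanked$core_seq) +
        (as.integer(r_in_right) - 1L) + nchar(pair$reverse_seq)
    }
  }

  amplicon_ok <- amp_len >= amplicon_range[1] && amp_len <= amplicon_range[2]
  tm_ok <- abs(pair$tm_forward - pair$tm_reverse) <= tm_tolerance
  runs <- primer_dimer_runs(pair$forward_seq, pair$reverse_seq)
  dimer_ok <- runs$max_run < dimer_run &&
    runs$max_run_3prime < dimer_run_3prime

  specific <- NA
  sites <- NA_integer_
  if (!is.null(genomes)) {
    sites <- vapply(genomes, .amplicon_sites, integer(1), pair = pair,
                    max_product = max_product)
    specific <- all(sites == 1L)
  }

  m13_ok <- identical(pair$m13_tagged_forward,
                      paste0(m13_tail, pair$forward_seq)) &&
    nchar(m13_tail) == 18L

  crit <- c(in_flanks = in_flanks, amplicon_size = amplicon_ok,
            tm_match = tm_ok, no_dimer = dimer_ok, specific = specific,
            m13_tagged = m13_ok)
  list(criteria = crit, pass = all(crit, na.rm = TRUE),
       amplicon_len = amp_len,
       delta_tm = abs(pair$tm_forward - pair$tm_reverse),
       dimer_runs = runs, amplicon_sites = sites)
}

#' Assign accepted primer pairs to fluorescent dye panels
#'
#' Deterministic greedy packing: pairs are taken in descending expected
#' amplicon length and placed on the first dye whose current members all
#' differ from the pair by at least `min_separation` bp (so capillary
#' peaks sharing a dye stay distinguishable) and which is below capacity.
#'
#' @param pairs list of [primer_pair()] objects.
#' @param dyes ordered dye labels.
#' @param per_panel maximum pairs per dye.
#' @param min_separation minimum expected-size separation (bp) within a dye.
#' @return data.frame `marker_id`, `expected_amplicon_len`, `dye`.
#' @export
assign_panels <- function(pairs, dyes = c("FAM", "HEX", "ROX", "TAMRA"),
                          per_panel = 3L, min_separation = 20L) {
  n <- length(pairs)
  if (n > length(dyes) * per_panel) {
    stop("more pairs (", n, ") than panel capacity (",
         length(dyes) * per_panel, ")")
  }
  lens <- vapply(pairs, function(p) p$expected_amplicon_len, integer(1))
  ids <- vapply(pairs, function(p) p$marker_id, character(1))
  ord <- order(-lens, ids)
  assigned <- rep(NA_character_, n)
  members <- stats::setNames(vector("list", length(dyes)), dyes)
  conflicts <- character(0)
  for (i in ord) {
    placed <- FALSE
    for (d in dyes) {
      if (length(members[[d]]) >= per_panel) next
      if (all(abs(members[[d]] - lens[i]) >= min_separation)) {
        members[[d]] <- c(members[[d]], lens[i])
        assigned[i] <- d
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      conflicts <- c(conflicts,
                     sprintf("%s (%d bp)", ids[i], lens[i]))
    }
  }
  if (length(conflicts)) {
    stop("cannot pack pairs into dye panels (size separation < ",
         min_separation, " bp on every dye): ",
         paste(conflicts, collapse = "; "))
  }
  data.frame(marker_id = ids, expected_amplicon_len = lens,
             dye = assigned, stringsAsFactors = FALSE)
}
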