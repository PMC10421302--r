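# Independent brute-force SSR oracle based on the periodicity array:
# eq[i] <- s[i] == s[i + k]; each maximal TRUE-run of length L is a
# k-periodic region of length L + k holding floor((L + k) / k) whole
# motif copies at its leftmost position. Mechanically unrelated to the
# package's regex scanner.
oracle_detect_ssrs <- function(s, motif_lengths = 3:6, min_repeats = 4L) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  valid <- ch %in% c("A", "C", "G", "T")
  rows <- list()
  for (k in motif_lengths) {
    if (n < 2L * k) next
    i <- seq_len(n - k)
    eq <- ch[i] == ch[i + k] & valid[i] & valid[i + k]
    r <- rle(eq)
    run_start <- cumsum(c(1L, r$lengths))
    for (j in seq_along(r$lengths)) {
      if (!r$values[j]) next
      a <- run_start[j]
      m_len <- r$lengths[j] + k
      copies <- m_len %/% k
      if (copies < min_repeats) next
      motif <- substr(s, a, a + k - 1L)
      if (!oracle_is_primitive(motif)) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = a - 1L, end = a - 1L + k * copies, motif = motif,
        repeat_count = copies, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), repeat_count = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, nchar(out$motif)), ]
  rownames(out) <- NULL
  out
}

# primitivity via explicit rotation test (different mechanism from the
# package's divisor check): a motif is non-primitive iff it equals one of
# its proper rotations at an offset dividing its length
oracle_is_primitive <- function(motif) {
  k <- nchar(motif)
  doubled <- paste0(motif, motif)
  for (d in seq_len(k - 1L)) {
    if (substr(doubled, d + 1L, d + k) == motif && k %% d == 0L) {
      return(FALSE)
    }
  }
  TRUE
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

detected_as_oracle <- function(genome_df) {
  df <- genome_df[order(genome_df$start, nchar(genome_df$motif)),
                  c("start", "end", "motif", "repeat_count")]
  rownames(df) <- NULL
  df
}

# expected screen status for each planted polymorphism class
expected_status <- c(
  three_way_polymorphic = "retained",
  two_way_only = "dropped_two_way_only",
  monomorphic = "dropped_monomorphic",
  nonunique_decoy = "dropped_nonunique",
  low_identity_flank = "dropped_low_identity",
  flank_mutation = "dropped_flank_mutation"
)
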