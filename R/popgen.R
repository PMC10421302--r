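#' Ploidy-aware genotype table
#'
#' Samples by markers; each cell is a multiset of integer allele fragment
#' sizes (bp) with up to `ploidy` entries, or empty when typing failed.
#' Diploid and triploid samples can be mixed.
#'
#' @param cells list-matrix (samples x markers) of integer vectors; a
#'   zero-length vector is a missing cell. Row names are sample ids,
#'   column names marker ids.
#' @param ploidy integer vector (2 or 3) per sample; defaults to 2.
#' @return object of class `GenotypeTable` with elements `samples`,
#'   `markers`, `cells`, `ploidy`.
#' @export
genotype_table <- function(cells, ploidy = NULL) {
  stopifnot(is.matrix(cells), is.list(cells))
  samples <- rownames(cells); markers <- colnames(cells)
  if (is.null(samples) || is.null(markers)) {
    stop("cells must have sample row names and marker column names")
  }
  if (is.null(ploidy)) ploidy <- rep(2L, length(samples))
  ploidy <- as.integer(ploidy)
  if (length(ploidy) != length(samples)) {
    stop("ploidy must have one entry per sample")
  }
  if (any(!ploidy %in% 2:3)) stop("ploidy must be 2 or 3")
  for (i in seq_along(samples)) {
    for (j in seq_along(markers)) {
      a <- cells[[i, j]]
      if (length(a) > ploidy[i]) {
        stop(sprintf("cell %s/%s has %d alleles but ploidy %d",
                     samples[i], markers[j], length(a), ploidy[i]))
      }
      if (length(a) && any(a <= 0)) stop("allele sizes must be positive")
      cells[[i, j]] <- sort(as.integer(a))
    }
  }
  structure(list(samples = samples, markers = markers, cells = cells,
                 ploidy = stats::setNames(ploidy, samples)),
            class = "GenotypeTable")
}

#' @export
print.GenotypeTable <- function(x, ...) {
  cat(sprintf("GenotypeTable: %d samples x %d markers (%d triploid)\n",
              length(x$samples), length(x$markers),
              sum(x$ploidy == 3L)))
  invisible(x)
}

#' Read a genotype table from delimited text
#'
#' One row per sample, one column per marker; a cell is "/"-joined allele
#' sizes ("245/251", "245/245/251"); empty, "00" or NA means missing.
#' An optional `ploidy` column gives per-sample ploidy, otherwise ploidy
#' is inferred as max(2, largest observed allele count per sample).
#'
#' @param path TSV/CSV path (delimiter sniffed from the extension).
#' @param sample_col name of the sample-id column.
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(path, sample_col = "sample") {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (!sample_col %in% names(df)) {
    stop("no '", sample_col, "' column in ", path)
  }
  samples <- df[[sample_col]]
  ploidy <- NULL
  if ("ploidy" %in% names(df)) ploidy <- as.integer(df$ploidy)
  markers <- setdiff(names(df), c(sample_col, "ploidy"))
  cells <- matrix(vector("list", length(samples) * length(markers)),
                  nrow = length(samples),
                  dimnames = list(samples, markers))
  for (j in markers) {
    for (i in seq_along(samples)) {
      v <- df[[j]][i]
      cells[[i, j]] <- if (is.na(v) || v == "" || v == "00") {
        integer(0)
      } else as.integer(strsplit(v, "/", fixed = TRUE)[[1]])
    }
  }
  if (is.null(ploidy)) {
    ploidy <- pmax(2L, apply(cells, 1L, function(r) {
      max(c(0L, lengths(r)))
    }))
  }
  genotype_table(cells, ploidy)
}

#' Write a genotype table as TSV
#' @param table a [genotype_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(table, path) {
  df <- data.frame(sample = table$samples,
                   ploidy = as.integer(table$ploidy),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (j in table$markers) {
    df[[j]] <- vapply(seq_along(table$samples), function(i) {
      a <- table$cells[[i, j]]
      if (!length(a)) "00" else paste(a, collapse = "/")
    }, character(1))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Allele frequencies at one marker
#'
#' Each typed sample contributes its observed allele copies (with
#' multiplicity, up to its ploidy); missing cells are excluded.
#'
#' @param table a [genotype_table()].
#' @param marker marker id.
#' @param exclude_nondiploid drop samples with ploidy != 2.
#' @return named numeric vector of frequencies (names = allele sizes,
#'   ascending), summing to 1.
#' @export
allele_frequencies <- function(table, marker, exclude_nondiploid = FALSE) {
  stopifnot(inherits(table, "GenotypeTable"))
  if (!marker %in% table$markers) stop("unknown marker: ", marker)
  keep <- if (exclude_nondiploid) table$ploidy == 2L else
    rep(TRUE, length(table$samples))
  alleles <- unlist(table$cells[keep, marker])
  if (!length(alleles)) stop("marker '", marker, "' has no typed samples")
  tab <- table(alleles)
  freqs <- as.numeric(tab) / sum(tab)
  names(freqs) <- names(tab)
  freqs[order(as.integer(names(freqs)))]
}

#' Per-marker diversity statistics
#'
#' Computes, from the allele frequencies p_i and the typed samples:
#' Na (observed alleles), Ne = 1 / sum(p_i^2) (effective alleles),
#' He = 1 - sum(p_i^2) (Nei's gene diversity; optionally the unbiased
#' C/(C-1)-corrected variant over C allele copies), Ho (fraction of typed
#' samples carrying >= 2 distinct alleles; a triploid is heterozygous
#' unless all three alleles are identical) and the polymorphism
#' information content PIC = 1 - sum(p_i^2) - sum_\{i<j\} 2 p_i^2 p_j^2.
#'
#' @param table a [genotype_table()].
#' @param marker marker id.
#' @param unbiased apply the small-sample correction to He.
#' @param exclude_nondiploid restrict to diploid samples.
#' @return list (`MarkerStats`): `marker_id`, `allele_freqs`, `Na`, `Ne`,
#'   `Ho`, `He`, `PIC`, `n_typed`.
#' @export
marker_stats <- function(table, marker, unbiased = FALSE,
                         exclude_nondiploid = FALSE) {
  p <- allele_frequencies(table, marker, exclude_nondiploid)
  keep <- if (exclude_nondiploid) table$ploidy == 2L else
    rep(TRUE, length(table$samples))
  cells <- table$cells[keep, marker]
  typed <- lengths(cells) > 0L
  n_typed <- sum(typed)
  copies <- sum(lengths(cells))
  sp2 <- sum(p^2)
  he <- 1 - sp2
  if (unbiased && copies > 1L) he <- he * copies / (copies - 1L)
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  pic <- 1 - sp2 - (sp2^2 - sum(p^4))
  ho <- mean(vapply(cells[typed], function(a) {
    length(unique(a)) >= 2L
  }, logical(1)))
  structure(list(marker_id = marker, allele_freqs = p,
                 Na = length(p), Ne = 1 / sp2, Ho = ho, He = he,
                 PIC = pic, n_typed = n_typed),
            class = "MarkerStats")
}

#' Diversity statistics for every marker
#'
#' @inheritParams marker_stats
#' @return data.frame with one row per marker: `marker`, `na`, `ne`,
#'   `ho`, `he`, `pic`, `n_typed`.
#' @export
marker_stats_table <- function(table, unbiased = FALSE,
                               exclude_nondiploid = FALSE) {
  rows <- lapply(table$markers, function(m) {
    s <- marker_stats(table, m, unbiased, exclude_nondiploid)
    data.frame(marker = m, na = s$Na, ne = s$Ne, ho = s$Ho, he = s$He,
               pic = s$PIC, n_typed = s$n_typed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Panel-level summary of marker statistics
#'
#' @param stats data.frame with columns `marker`, `na`, `ne`, `ho`, `he`,
#'   `pic` (as from [marker_stats_table()], or any published per-marker
#'   table read from disk).
#' @return list: `n_markers`, `total_alleles` (sum of Na), unweighted
#'   `mean_*` for each statistic, and per-statistic ranges with the
#'   markers attaining them.
#' @export
panel_summary <- function(stats) {
  stopifnot(nrow(stats) >= 1L,
            all(c("marker", "na", "ne", "ho", "he", "pic") %in%
                  names(stats)))
  rng <- function(col) {
    i <- which.min(stats[[col]]); j <- which.max(stats[[col]])
    list(min = stats[[col]][i], min_marker = stats$marker[i],
         max = stats[[col]][j], max_marker = stats$marker[j])
  }
  list(n_markers = nrow(stats),
       total_alleles = sum(stats$na),
       mean_na = mean(stats$na),
       mean_ne = mean(stats$ne),
       mean_ho = mean(stats$ho),
       mean_he = mean(stats$he),
       mean_pic = mean(stats$pic),
       range_na = rng("na"), range_ne = rng("ne"), range_ho = rng("ho"),
       range_he = rng("he"), range_pic = rng("pic"))
}
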