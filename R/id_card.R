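# Sort key for a genotype pattern: fixed-width allele sizes joined by "/",
# so plain string order equals numeric-lexicographic order on the sorted
# tuple, with a shorter tuple sorting before its extensions ("/" < "0").
.pattern_key <- function(alleles) {
  paste(sprintf("%09d", sort(alleles)), collapse = "/")
}

.pattern_label <- function(alleles) {
  paste(sort(alleles), collapse = "/")
}

#' Build a genotype codebook
#'
#' For each marker, every distinct genotype pattern (the sorted multiset
#' of allele sizes) observed in the table gets a 2-character code "01"
#' through "99", assigned in ascending order of the pattern sort key;
#' "00" is reserved for missing typing. Deterministic: the same table
#' always yields the same codebook.
#'
#' @param table a [genotype_table()].
#' @param marker_order marker ids defining the digit order of the ID
#'   (default: the table's marker order).
#' @param sort_by "genotype" (lexicographic on the sorted allele tuple,
#'   the default) or "frequency" (descending pattern frequency, ties by
#'   genotype order).
#' @return object of class `Codebook`: `marker_order` plus per-marker
#'   named code maps (pattern label -> code).
#' @export
build_codebook <- function(table, marker_order = NULL,
                           sort_by = c("genotype", "frequency")) {
  stopifnot(inherits(table, "GenotypeTable"))
  sort_by <- match.arg(sort_by)
  if (is.null(marker_order)) marker_order <- table$markers
  miss <- setdiff(marker_order, table$markers)
  if (length(miss)) stop("marker(s) not in table: ",
                         paste(miss, collapse = ", "))
  codes <- list()
  for (m in marker_order) {
    cells <- table$cells[, m]
    cells <- cells[lengths(cells) > 0L]
    labs <- vapply(cells, .pattern_label, character(1))
    keys <- vapply(cells, .pattern_key, character(1))
    if (sort_by == "genotype") {
      uk <- sort(unique(keys))
    } else {
      freq <- sort(table(keys), decreasing = TRUE)
      uk <- names(freq)[order(-as.integer(freq), names(freq))]
    }
    if (length(uk) > 99L) {
      stop("marker '", m, "' has ", length(uk),
           " genotype patterns; codes 01-99 cannot hold more than 99")
    }
    lab_of <- labs[match(uk, keys)]
    codes[[m]] <- stats::setNames(sprintf("%02d", seq_along(uk)), lab_of)
  }
  structure(list(marker_order = marker_order, codes = codes),
            class = "Codebook")
}

#' Encode digital molecular IDs
#'
#' Concatenates the per-marker 2-digit genotype codes in codebook marker
#' order; a 12-marker panel therefore yields a 24-digit ID. Missing
#' typing encodes as "00".
#'
#' @param table a [genotype_table()].
#' @param codebook a [build_codebook()] result covering the table.
#' @return named character vector, one ID per sample.
#' @export
encode_ids <- function(table, codebook) {
  stopifnot(inherits(table, "GenotypeTable"),
            inherits(codebook, "Codebook"))
  ids <- vapply(seq_along(table$samples), function(i) {
    parts <- vapply(codebook$marker_order, function(m) {
      a <- table$cells[[i, m]]
      if (!length(a)) return("00")
      code <- unname(codebook$codes[[m]][.pattern_label(a)])
      if (is.na(code)) {
        stop(sprintf("pattern %s at sample '%s', marker '%s' absent from codebook",
                     .pattern_label(a), table$samples[i], m))
      }
      code
    }, character(1))
    paste(parts, collapse = "")
  }, character(1))
  stats::setNames(ids, table$samples)
}

#' Decode an ID back to genotype patterns
#'
#' @param id ID string from [encode_ids()].
#' @param codebook the codebook used to encode it.
#' @return named list (by marker) of integer allele vectors; `NULL` for
#'   markers coded "00".
#' @export
decode_id <- function(id, codebook) {
  stopifnot(inherits(codebook, "Codebook"))
  m <- codebook$marker_order
  if (nchar(id) != 2L * length(m)) {
    stop("ID length ", nchar(id), " does not match ", length(m),
         " markers")
  }
  out <- stats::setNames(vector("list", length(m)), m)
  for (j in seq_along(m)) {
    code <- substr(id, 2L * j - 1L, 2L * j)
    if (code == "00") next
    map <- codebook$codes[[m[j]]]
    lab <- names(map)[map == code]
    if (!length(lab)) stop("code ", code, " unknown at marker ", m[j])
    out[[j]] <- as.integer(strsplit(lab, "/", fixed = TRUE)[[1]])
  }
  out
}

#' Check ID uniqueness
#'
#' @param ids named character vector from [encode_ids()].
#' @return list of colliding sample groups (character vectors); empty
#'   when all IDs are distinct.
#' @export
check_uniqueness <- function(ids) {
  if (!length(ids)) return(list())
  groups <- split(names(ids), ids)
  unname(groups[lengths(groups) > 1L])
}

#' Export a codebook as JSON
#' @param codebook a [build_codebook()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(codebook, path) {
  jsonlite::write_json(
    list(marker_order = codebook$marker_order,
         codes = lapply(codebook$codes, as.list)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
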