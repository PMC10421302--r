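#' Specification for planting SSR loci in synthetic genomes
#'
#' Describes a set of related genomes carrying SSR loci of controlled
#' polymorphism classes, the ground truth used to validate the
#' cross-genome screen:
#' \describe{
#'   \item{three_way_polymorphic}{pairwise-distinct repeat counts in every
#'     genome; the class the screen must retain.}
#'   \item{two_way_only}{repeat counts differing between only two genomes.}
#'   \item{monomorphic}{identical repeat counts everywhere.}
#'   \item{nonunique_decoy}{distinct counts, but the flank block is
#'     duplicated elsewhere in the anchor genome (repeat core replaced by
#'     neutral filler so the duplicate is not itself an SSR locus).}
#'   \item{low_identity_flank}{distinct counts, but one non-anchor
#'     genome's flanks carry heavy substitution noise (default 15%),
#'     below the 90% identity threshold.}
#'   \item{flank_mutation}{distinct counts and near-identical flanks, but
#'     substitutions planted inside the core-adjacent primer windows.}
#' }
#' Motif lengths are drawn from a tri- to hexanucleotide distribution
#' matching the composition reported for jujube genomes (71/20/5.5/3.25%).
#'
#' @param n_per_class named integer vector of loci per class (any subset
#'   of the six class names).
#' @param motif_probs sampling probabilities for motif lengths 3-6.
#' @param repeat_range inclusive range of repeat counts.
#' @param flank_len planted conserved-flank length (bp).
#' @param spacer_len neutral spacer length between loci (bp).
#' @param min_repeats detection threshold the spacers are screened
#'   against (spacers and flanks are rejection-sampled free of qualifying
#'   runs so planted truth is the only truth).
#' @param low_identity_divergence substitution rate for the
#'   low_identity_flank class.
#' @param window core-adjacent window width (bp) targeted by the
#'   flank_mutation class.
#' @param window_mutations substitutions planted per mutated window pair.
#' @return list of class `PlantSpec`.
#' @export
plant_spec <- function(n_per_class = c(three_way_polymorphic = 10L,
                                       two_way_only = 10L,
                                       monomorphic = 10L,
                                       nonunique_decoy = 10L,
                                       low_identity_flank = 10L,
                                       flank_mutation = 10L),
                       motif_probs = c(`3` = 0.7112, `4` = 0.2009,
                                       `5` = 0.0553, `6` = 0.0325),
                       repeat_range = c(4L, 12L),
                       flank_len = 300L, spacer_len = 1000L,
                       min_repeats = 4L,
                       low_identity_divergence = 0.15,
                       window = 50L, window_mutations = 2L) {
  classes <- c("three_way_polymorphic", "two_way_only", "monomorphic",
               "nonunique_decoy", "low_identity_flank", "flank_mutation")
  bad <- setdiff(names(n_per_class), classes)
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "))
  if (repeat_range[1] < max(2L, min_repeats)) {
    stop("repeat_range must start at min_repeats or above")
  }
  structure(list(n_per_class = n_per_class, motif_probs = motif_probs,
                 repeat_range = repeat_range, flank_len = flank_len,
                 spacer_len = spacer_len, min_repeats = min_repeats,
                 low_identity_divergence = low_identity_divergence,
                 window = window, window_mutations = window_mutations),
            class = "PlantSpec")
}

.random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random sequence free of any primitive 3-6-mer run of >= min_rep copies.
.suppressed_seq <- function(n, min_rep) {
  repeat {
    s <- .random_bases(n)
    hit <- FALSE
    for (k in 3:6) if (nrow(.scan_motif_length(s, k, min_rep))) {
      hit <- TRUE; break
    }
    if (!hit) return(s)
  }
}

.random_primitive_motif <- function(motif_probs) {
  k <- as.integer(sample(names(motif_probs), 1L, prob = motif_probs))
  repeat {
    m <- .random_bases(k)
    # reject non-primitive motifs and homopolymer-like ends that would
    # complicate junction handling
    if (.is_primitive_motif(m)) return(m)
  }
}

.mutate_positions <- function(s, positions) {
  ch <- strsplit(s, "")[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

.mutate_rate <- function(s, rate) {
  n <- nchar(s)
  k <- max(1L, round(rate * n))
  .mutate_positions(s, sample.int(n, k))
}

#' Generate related genomes with planted SSR loci
#'
#' Builds `n_genomes` single-contig genome assemblies sharing flank and
#' spacer sequence but differing in planted repeat counts (and, for the
#' noise classes, in flank mutations) according to `spec`. Spacers and
#' flanks are rejection-sampled free of qualifying SSR runs, and flanks
#' never begin/end with a motif boundary base, so the planted loci are
#' exactly the detectable loci; the generator verifies this by running
#' the detector on every assembled genome and re-derives its randomness
#' deterministically if a pathological draw slips through. The same seed
#' always produces identical genomes.
#'
#' @param spec a [plant_spec()].
#' @param n_genomes number of genomes (>= 2; the first is the anchor).
#' @param seed integer random seed.
#' @param labels genome labels.
#' @return list: `genomes` (list of [genome_sequence()]), `truth`
#'   (data.frame: `locus_id`, `class`, `seq_id`, `motif`, per-genome
#'   `start_<label>` and `rc_<label>`, `mutated_genome`).
#' @export
generate_genomes <- function(spec, n_genomes = 3L, seed = 1L,
                             labels = paste0("G", seq_len(n_genomes))) {
  stopifnot(inherits(spec, "PlantSpec"), n_genomes >= 2L)
  for (attempt in 0:19) {
    set.seed((seed + attempt * 1000003L) %% .Machine$integer.max)
    res <- .generate_genomes_once(spec, n_genomes, labels)
    if (!is.null(res)) return(res)
  }
  stop("could not assemble verified genomes; relax the spec")
}

.generate_genomes_once <- function(spec, n_genomes, labels) {
  classes <- rep(names(spec$n_per_class), spec$n_per_class)
  if (length(classes) == 0L) stop("spec plants no loci")
  classes <- sample(classes)  # spread classes along the contig
  nl <- length(classes)
  rr <- spec$repeat_range
  fl <- spec$flank_len
  anchor <- 1L

  loci <- vector("list", nl)
  for (i in seq_len(nl)) {
    motif <- .random_primitive_motif(spec$motif_probs)
    k <- nchar(motif)
    counts <- switch(classes[i],
      monomorphic = rep(sample(rr[1]:rr[2], 1L), n_genomes),
      two_way_only = {
        if (n_genomes == 2L) {
          sample(rr[1]:rr[2], 2L)  # degenerates to retainable (documented)
        } else {
          # one duplicated value on a random genome pair, all others
          # distinct from it and from each other
          vals <- sample(rr[1]:rr[2], n_genomes - 1L)
          cnt <- integer(n_genomes)
          pair <- sample.int(n_genomes, 2L)
          cnt[pair] <- vals[1]
          cnt[-pair] <- vals[-1]
          cnt
        }
      },
      sample(rr[1]:rr[2], n_genomes)  # all pairwise-distinct classes
    )
    # flanks: SSR-suppressed, and boundary bases never continue the motif
    left <- .suppressed_seq(fl, spec$min_repeats)
    while (substr(left, fl, fl) == substr(motif, k, k)) {
      left <- paste0(substr(left, 1L, fl - 1L),
                     sample(c("A", "C", "G", "T"), 1L))
    }
    right <- .suppressed_seq(fl, spec$min_repeats)
    while (substr(right, 1L, 1L) == substr(motif, 1L, 1L)) {
      right <- paste0(sample(c("A", "C", "G", "T"), 1L),
                      substr(right, 2L, fl))
    }
    mutated_genome <- NA_integer_
    left_g <- rep(left, n_genomes)
    right_g <- rep(right, n_genomes)
    if (classes[i] == "low_identity_flank") {
      mutated_genome <- sample(2:n_genomes, 1L)
      left_g[mutated_genome] <- .mutate_rate(left,
                                             spec$low_identity_divergence)
      right_g[mutated_genome] <- .mutate_rate(right,
                                              spec$low_identity_divergence)
    } else if (classes[i] == "flank_mutation") {
      mutated_genome <- sample(2:n_genomes, 1L)
      w <- spec$window
      nm <- spec$window_mutations
      # substitutions inside the core-adjacent primer windows
      left_g[mutated_genome] <-
        .mutate_positions(left, sample((fl - w + 1L):fl, nm))
      right_g[mutated_genome] <-
        .mutate_positions(right, sample(seq_len(w), nm))
    }
    loci[[i]] <- list(class = classes[i], motif = motif, counts = counts,
                      left = left_g, right = right_g,
                      mutated_genome = mutated_genome)
  }

  spacers <- replicate(nl + 1L,
                       .suppressed_seq(spec$spacer_len, spec$min_repeats))
  decoys <- which(classes == "nonunique_decoy")
  decoy_fill <- lapply(decoys, function(i) {
    .suppressed_seq(30L, spec$min_repeats)
  })
  decoy_spacers <- replicate(length(decoys),
                             .suppressed_seq(spec$spacer_len,
                                             spec$min_repeats))

  genomes <- vector("list", n_genomes)
  starts <- matrix(NA_integer_, nl, n_genomes)
  for (g in seq_len(n_genomes)) {
    parts <- character(0)
    off <- 0L
    for (i in seq_len(nl)) {
      parts <- c(parts, spacers[i], loci[[i]]$left[g])
      off <- off + nchar(spacers[i]) + nchar(loci[[i]]$left[g])
      starts[i, g] <- off  # 0-based core start
      core <- strrep(loci[[i]]$motif, loci[[i]]$counts[g])
      parts <- c(parts, core, loci[[i]]$right[g])
      off <- off + nchar(core) + nchar(loci[[i]]$right[g])
    }
    parts <- c(parts, spacers[nl + 1L])
    if (g == anchor && length(decoys)) {
      for (j in seq_along(decoys)) {
        i <- decoys[j]
        parts <- c(parts, loci[[i]]$left[g], decoy_fill[[j]],
                   loci[[i]]$right[g], decoy_spacers[j])
      }
    }
    genomes[[g]] <- genome_sequence(
      c(chr1 = paste(parts, collapse = "")), labels[g])
  }

  # verify: detected loci in every genome are exactly the planted ones
  for (g in seq_len(n_genomes)) {
    det <- detect_ssrs(genomes[[g]], 3:6, spec$min_repeats)
    counts_g <- vapply(loci, function(l) l$counts[g], integer(1))
    motifs <- vapply(loci, function(l) l$motif, character(1))
    o <- order(starts[, g])  # det is sorted by start already
    ok <- nrow(det) == nl &&
      all(det$start == starts[o, g]) &&
      all(det$motif == motifs[o]) &&
      all(det$repeat_count == counts_g[o])
    if (!ok) return(NULL)
  }

  truth <- data.frame(
    locus_id = sprintf("L%03d", seq_len(nl)),
    class = classes,
    seq_id = "chr1",
    motif = vapply(loci, function(l) l$motif, character(1)),
    stringsAsFactors = FALSE)
  for (g in seq_len(n_genomes)) {
    truth[[paste0("start_", labels[g])]] <- starts[, g]
    truth[[paste0("rc_", labels[g])]] <-
      vapply(loci, function(l) l$counts[g], integer(1))
  }
  truth$mutated_genome <- vapply(loci, function(l) {
    if (is.na(l$mutated_genome)) NA_character_ else
      labels[l$mutated_genome]
  }, character(1))
  names(genomes) <- labels
  list(genomes = genomes, truth = truth)
}

#' Random per-marker allele frequency maps
#'
#' @param n_markers number of markers.
#' @param n_alleles_range inclusive range of allele counts per marker.
#' @param base_size,step smallest fragment size and allele spacing (bp).
#' @param seed integer seed.
#' @return named list of named frequency vectors summing to 1.
#' @export
random_marker_freqs <- function(n_markers = 12L,
                                n_alleles_range = c(5L, 15L),
                                base_size = 100L, step = 3L, seed = 1L) {
  set.seed(seed)
  out <- list()
  for (m in seq_len(n_markers)) {
    na <- sample(n_alleles_range[1]:n_alleles_range[2], 1L)
    sizes <- base_size + step * (seq_len(na) - 1L) + 10L * m
    w <- stats::rgamma(na, shape = 1)
    out[[sprintf("M%02d", m)]] <- stats::setNames(w / sum(w),
                                                  as.character(sizes))
  }
  out
}

#' Simulate a genotype table from known allele frequencies
#'
#' Alleles are drawn independently per chromosome copy (Hardy-Weinberg
#' sampling) from the supplied per-marker frequencies; missing cells are
#' inserted at `missing_rate`. The default ploidy plan emulates a mixed
#' panel of 26 diploid accessions plus 4 triploid cultivars.
#'
#' @param freqs named list: per marker, a named numeric vector of allele
#'   frequencies (names = fragment sizes in bp) summing to 1.
#' @param n_samples number of samples.
#' @param ploidy per-sample ploidy vector (recycled/truncated to
#'   `n_samples`).
#' @param missing_rate per-cell probability of missing typing.
#' @param distinct resample colliding samples until all multi-marker
#'   genotypes are pairwise distinct.
#' @param seed integer seed.
#' @return list: `table` (a [genotype_table()]) and `truth` (the input
#'   frequencies).
#' @export
generate_genotypes <- function(freqs, n_samples = 30L,
                               ploidy = c(rep(2L, 26L), rep(3L, 4L)),
                               missing_rate = 0, distinct = FALSE,
                               seed = 1L) {
  stopifnot(is.list(freqs), length(freqs) >= 1L)
  for (m in names(freqs)) {
    if (abs(sum(freqs[[m]]) - 1) > 1e-8 || any(freqs[[m]] < 0)) {
      stop("frequencies for marker '", m, "' must be >= 0 and sum to 1")
    }
  }
  set.seed(seed)
  ploidy <- rep_len(ploidy, n_samples)
  markers <- names(freqs)
  samples <- sprintf("S%03d", seq_len(n_samples))
  draw_cell <- function(m, pl) {
    if (missing_rate > 0 && stats::runif(1) < missing_rate) {
      return(integer(0))
    }
    sizes <- as.integer(names(freqs[[m]]))
    sort(sample(sizes, pl, replace = TRUE, prob = freqs[[m]]))
  }
  cells <- matrix(vector("list", n_samples * length(markers)),
                  nrow = n_samples, dimnames = list(samples, markers))
  for (i in seq_len(n_samples)) {
    for (m in markers) cells[[i, m]] <- draw_cell(m, ploidy[i])
  }
  if (distinct) {
    key <- function(i) paste(vapply(markers, function(m) {
      paste(cells[[i, m]], collapse = "/")
    }, character(1)), collapse = "|")
    repeat {
      keys <- vapply(seq_len(n_samples), key, character(1))
      dup <- which(duplicated(keys))
      if (!length(dup)) break
      for (i in dup) {
        for (m in markers) cells[[i, m]] <- draw_cell(m, ploidy[i])
      }
    }
  }
  list(table = genotype_table(cells, ploidy), truth = freqs)
}
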