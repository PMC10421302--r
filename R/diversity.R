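#' Genotypes to 0/1 allele-presence matrix
#'
#' One column per (marker, allele) pair observed anywhere in the table,
#' ordered by marker (table order) then ascending allele size; entry 1
#' iff the sample carries that allele (presence, not dosage — a triploid
#' 100/100/120 scores (1, 1)). Missing cells are all-zero across that
#' marker's columns.
#'
#' @param table a [genotype_table()].
#' @return integer matrix, rows = samples, columns named
#'   `"<marker>:<allele>"`.
#' @export
to_binary_matrix <- function(table) {
  stopifnot(inherits(table, "GenotypeTable"))
  cols <- list()
  for (m in table$markers) {
    alleles <- sort(unique(unlist(table$cells[, m])))
    for (a in alleles) cols[[paste0(m, ":", a)]] <- c(m, a)
  }
  mat <- matrix(0L, nrow = length(table$samples), ncol = length(cols),
                dimnames = list(table$samples, names(cols)))
  for (j in seq_along(cols)) {
    m <- cols[[j]][1]; a <- as.integer(cols[[j]][2])
    mat[, j] <- vapply(seq_along(table$samples), function(i) {
      as.integer(a %in% table$cells[[i, m]])
    }, integer(1))
  }
  mat
}

#' Binary dissimilarity matrix
#'
#' Standard dissimilarities for 0/1 band data. For rows with no scored
#' bands at all: distance 0 to another all-zero row, 1 to any other row
#' (jaccard/dice; simple matching handles them natively).
#'
#' @param mat 0/1 matrix from [to_binary_matrix()].
#' @param metric one of "jaccard", "dice", "simple_matching".
#' @return a [stats::dist] object.
#' @export
binary_distance <- function(mat,
                            metric = c("jaccard", "dice",
                                       "simple_matching")) {
  metric <- match.arg(metric)
  if (nrow(mat) < 2L) stop("need at least 2 samples")
  m <- as.matrix(mat)
  storage.mode(m) <- "double"
  inter <- tcrossprod(m)            # shared bands
  rs <- rowSums(m)
  tot <- outer(rs, rs, "+")
  d <- switch(metric,
    jaccard = {
      un <- tot - inter
      r <- 1 - inter / un
      r[un == 0] <- 0               # two all-zero rows
      r
    },
    dice = {
      r <- 1 - 2 * inter / tot
      r[tot == 0] <- 0
      r
    },
    simple_matching = {
      mism <- outer(rs, rs, "+") - 2 * inter
      mism / ncol(m)
    })
  diag(d) <- 0
  stats::as.dist(d)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix (via [ape::nj()]).
#' Negative branch lengths, which NJ can produce on non-additive input,
#' are clamped to zero with the deficit moved to the adjacent branch so
#' the total tree length is preserved.
#'
#' @param d a [stats::dist] or symmetric matrix (>= 3 samples).
#' @param digits significant digits for the newick string.
#' @return list: `tree` (an [ape] `phylo`), `newick` (character).
#' @export
nj_tree <- function(d, digits = 6L) {
  dm <- as.matrix(d)
  if (nrow(dm) < 3L) stop("need at least 3 samples for a tree")
  tree <- ape::nj(stats::as.dist(dm))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1]
    up <- which(tree$edge[, 2] == parent)
    adj <- if (length(up)) up else {
      setdiff(which(tree$edge[, 1] == parent), e)[1]
    }
    tree$edge.length[adj] <- tree$edge.length[adj] + deficit
  }
  list(tree = tree, newick = ape::write.tree(tree, digits = digits))
}

#' Principal coordinates analysis
#'
#' Classical (metric) scaling: Gower double-centering of -d^2/2,
#' eigendecomposition, coordinates scaled by sqrt(eigenvalue). Axes are
#' ordered by descending eigenvalue; negative eigenvalues are reported
#' but their axes omitted, and axis signs are canonicalized (the
#' largest-magnitude loading on each axis is positive) so output is
#' deterministic.
#'
#' @param d a [stats::dist] or symmetric matrix.
#' @param k number of axes requested (>= 1).
#' @return list: `points` (samples x k', k' <= k with a warning when the
#'   positive spectrum is smaller), `eigenvalues` (all, descending),
#'   `rel_eig` (share of the positive inertia per returned axis).
#' @export
pcoa <- function(d, k = 2L) {
  stopifnot(k >= 1L)
  dm <- as.matrix(d)
  n <- nrow(dm)
  # Gower double-centering: sequential row then column centering of
  # -d^2/2 equals B = (I - J/n) A (I - J/n)
  b <- -0.5 * dm^2
  b <- sweep(b, 1L, rowMeans(b))
  b <- sweep(b, 2L, colMeans(b))
  eg <- eigen((b + t(b)) / 2, symmetric = TRUE)
  vals <- eg$values
  pos <- which(vals > max(vals[1], 0) * 1e-9)
  if (length(pos) < k) {
    warning("only ", length(pos), " positive eigenvalue(s); returning ",
            length(pos), " axes")
  }
  k_eff <- min(k, length(pos))
  pts <- matrix(0, n, k_eff,
                dimnames = list(rownames(dm),
                                paste0("Axis", seq_len(k_eff))))
  for (j in seq_len(k_eff)) {
    v <- eg$vectors[, j] * sqrt(vals[j])
    i_max <- which.max(abs(v))
    if (v[i_max] < 0) v <- -v
    pts[, j] <- v
  }
  list(points = pts, eigenvalues = vals,
       rel_eig = if (k_eff) vals[seq_len(k_eff)] / sum(vals[pos]) else
         numeric(0))
}

#' Cut a tree into k groups
#'
#' Presentation utility: partitions the samples into `k` groups by
#' cutting the `k - 1` longest internal branches of the NJ tree.
#'
#' @param tree a `phylo` object from [nj_tree()].
#' @param k number of groups.
#' @return named integer vector of group memberships per tip.
#' @export
cut_tree_groups <- function(tree, k) {
  stopifnot(k >= 1L)
  ntip <- length(tree$tip.label)
  internal <- which(tree$edge[, 2] > ntip)
  cut <- internal[order(-tree$edge.length[internal])]
  cut <- cut[seq_len(min(k - 1L, length(cut)))]
  keep <- setdiff(seq_len(nrow(tree$edge)), cut)
  # union-find over the uncut edges
  parent <- seq_len(max(tree$edge))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in keep) {
    a <- find(tree$edge[e, 1]); b <- find(tree$edge[e, 2])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(ntip), find, integer(1))
  stats::setNames(as.integer(factor(roots)), tree$tip.label)
}

#' Write a distance matrix as square TSV
#' @param d a [stats::dist] or matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  utils::write.table(data.frame(sample = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
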