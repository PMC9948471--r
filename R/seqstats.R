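#' Composition profile of a sequence
#'
#' GC fraction (counted over unambiguous bases only) and a normalised k-mer
#' frequency vector. Windows containing ambiguity codes are skipped. With
#' `canonical = TRUE` each k-mer is merged with its reverse complement, so a
#' sequence and its reverse complement give identical profiles — the default
#' for read/contig profiles, since reads come from both strands. The
#' strand-naive mode is retained for strict reproduction of wordfreq-style
#' counting.
#'
#' @param seq a `seq_record` or single (named) character sequence.
#' @param k word size, 3 or 4.
#' @param canonical merge each k-mer with its reverse complement.
#' @return list of class `composition_profile`: `seq_id`, `length`, `gc`,
#'   `kmer_freq` (entries sum to 1 when length >= k, all-zero otherwise).
#' @examples
#' composition_profile("AAAA", k = 4)$kmer_freq
#' @export
composition_profile <- function(seq, k = 4L, canonical = TRUE) {
  s <- as_seq(seq)
  if (nchar(s$seq) == 0L) stop("empty sequence")
  if (!k %in% c(3L, 4L)) stop("k must be 3 or 4")
  m <- composition_matrix(structure(s$seq, names = s$id), k = k,
                          canonical = canonical)
  structure(list(seq_id = s$id, length = nchar(s$seq),
                 gc = unname(gc_fraction(s$seq)), kmer_freq = m[1L, ]),
            class = "composition_profile")
}

#' k-mer frequency matrix for a sequence set
#'
#' @param seqs named character vector (or list of `seq_record`s).
#' @inheritParams composition_profile
#' @return numeric matrix, one row per sequence over the (canonical) k-mer
#'   alphabet; rows sum to 1 (or are all zero for sequences shorter than k).
#'   GC fractions are attached as `attr(, "gc")`.
#' @export
composition_matrix <- function(seqs, k = 4L, canonical = TRUE) {
  seqs <- as_seqs(seqs)
  counts <- composition_counts(seqs, k, canonical)
  tot <- rowSums(counts)
  freq <- counts / ifelse(tot > 0, tot, 1)
  freq[tot == 0, ] <- 0
  rownames(freq) <- names(seqs)
  attr(freq, "gc") <- setNames(gc_fraction(unname(seqs)), names(seqs))
  freq
}

# raw (canonical) k-mer count matrix; windows with ambiguity codes are not
# counted in any column
composition_counts <- function(seqs, k, canonical) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  counts <- Biostrings::oligonucleotideFrequency(x, width = k)
  if (canonical) {
    kmers <- colnames(counts)
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
    canon <- pmin(kmers, rc)
    counts <- t(rowsum(t(counts), group = canon))
    counts <- counts[, sort(unique(canon)), drop = FALSE]
  }
  rownames(counts) <- names(seqs)
  counts
}

#' Principal component analysis of k-mer frequency rows
#'
#' Eigendecomposition of the covariance of the centred rows, components
#' ordered by explained variance. The sign of each component is fixed
#' (largest-magnitude loading positive) for run-to-run determinism.
#'
#' @param x numeric matrix, one composition row per sequence.
#' @param dims number of components to keep (default all).
#' @return object of class `ordination`: `coordinates` (n x d, centred),
#'   `explained_fraction` (non-increasing, sums to <= 1), `loadings`,
#'   `method = "pca"`.
#' @export
kmer_pca <- function(x, dims = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows")
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  totvar <- sum(apply(x, 2, function(col) stats::var(col)))
  d <- if (is.null(dims)) ncol(p$x) else min(dims, ncol(p$x))
  coords <- p$x[, seq_len(d), drop = FALSE]
  load <- p$rotation[, seq_len(d), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(d)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; coords[, j] <- -coords[, j] }
  }
  expl <- if (totvar > 0) (p$sdev[seq_len(d)]^2) / totvar else rep(0, d)
  if (totvar == 0) coords[] <- 0
  structure(list(coordinates = coords, explained_fraction = expl,
                 loadings = load, method = "pca"), class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination:%s> %d points x %d axes; explained: %s\n",
              x$method, nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * x$explained_fraction),
                    collapse = ", ")))
  invisible(x)
}

#' Bray-Curtis dissimilarity
#'
#' `BC = sum(|p_i - q_i|) / sum(p_i + q_i)` between non-negative abundance
#' vectors; 0 for identical vectors, 1 for disjoint support.
#'
#' @param p,q non-negative numeric vectors of equal length, not both all-zero.
#' @return dissimilarity in \[0, 1\].
#' @examples
#' bray_curtis(c(2, 2), c(1, 3))  # 0.25
#' @export
bray_curtis <- function(p, q) {
  if (length(p) != length(q)) stop("vectors must have equal length")
  if (any(p < 0) || any(q < 0)) stop("negative entries are not allowed")
  tot <- sum(p + q)
  if (tot == 0) stop("both vectors are all-zero")
  sum(abs(p - q)) / tot
}

#' Bray-Curtis dissimilarity matrix
#'
#' @param x numeric matrix, one non-negative profile per row.
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
bray_curtis_matrix <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d[i, j] <- d[j, i] <- bray_curtis(x[i, ], x[j, ])
  }
  d
}

#' Principal coordinates analysis
#'
#' Classic metric scaling: double-centering of `-D^2/2`, coordinates from
#' the non-negative eigenpairs. Negative eigenvalues (non-Euclidean input)
#' are dropped and reported in `attr(, "negative_eigenvalues")`.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @param dims maximum number of axes to return.
#' @return object of class `ordination` with `method = "pcoa"`.
#' @export
pcoa <- function(d, dims = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d) || any(abs(d - t(d)) > 1e-8))
    stop("dissimilarity matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d * d) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  if (length(pos) == 0L) {
    coords <- matrix(0, n, 1L, dimnames = list(rownames(d), "Axis1"))
    out <- structure(list(coordinates = coords, explained_fraction = 0,
                          method = "pcoa"), class = "ordination")
    attr(out, "negative_eigenvalues") <- numeric(0)
    return(out)
  }
  if (!is.null(dims)) pos <- pos[seq_len(min(dims, length(pos)))]
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), nrow = length(pos))
  for (jx in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, jx]))
    if (coords[i, jx] < 0) coords[, jx] <- -coords[, jx]
  }
  dimnames(coords) <- list(rownames(d), paste0("Axis", seq_along(pos)))
  expl <- e$values[pos] / sum(e$values[e$values > tol])
  out <- structure(list(coordinates = coords, explained_fraction = expl,
                        method = "pcoa"), class = "ordination")
  attr(out, "negative_eigenvalues") <- e$values[e$values < -tol]
  out
}

#' Pooled k-mer profile of a read set
#'
#' Pools k-mer counts over the first `max_reads` reads (a deterministic
#' prefix, mirroring fixed-size metagenome subsets) and normalises. Used to
#' compare whole metagenomes by Bray-Curtis + PCoA.
#'
#' @param reads named character vector of reads.
#' @param k word size.
#' @param max_reads number of reads from the head of the set to use
#'   (clamped to the set size).
#' @param canonical merge strands.
#' @return named frequency vector over the (canonical) k-mer alphabet.
#' @export
metagenome_kmer_profile <- function(reads, k = 4L, max_reads = Inf,
                                    canonical = TRUE) {
  reads <- as_seqs(reads, prefix = "read")
  if (length(reads) == 0L) stop("empty read set")
  n <- min(length(reads), max_reads)
  pooled <- colSums(composition_counts(reads[seq_len(n)], k, canonical))
  tot <- sum(pooled)
  if (tot == 0) stop("no countable k-mer windows in the read prefix")
  pooled / tot
}
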