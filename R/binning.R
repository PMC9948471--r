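#' Taxonomy-consensus classification of contigs
#'
#' A contig at least `min_len` long is assigned to a phylum when at least
#' `min_fraction` of its genes share that best-hit taxonomy; genes without a
#' label count in the denominator. A two-way tie at the threshold cannot
#' name one phylum and yields `"unclassified"`. Contigs below the length
#' gate, or with no genes, are unclassified.
#'
#' @param gene_labels character vector of per-gene best-hit labels for one
#'   contig (`NA` = no label).
#' @param contig_length contig length in bases.
#' @param min_len length gate (default 5000).
#' @param min_fraction consensus fraction (default 0.5).
#' @param count_unlabelled should unlabelled genes count in the denominator
#'   (default TRUE: "fraction of the genes" reads as all genes).
#' @return a single label or `"unclassified"`.
#' @export
classify_contig <- function(gene_labels, contig_length, min_len = 5000,
                            min_fraction = 0.5, count_unlabelled = TRUE) {
  if (contig_length < min_len) return("unclassified")
  labs <- gene_labels[!is.na(gene_labels)]
  denom <- if (count_unlabelled) length(gene_labels) else length(labs)
  if (denom == 0L || length(labs) == 0L) return("unclassified")
  tab <- table(labs)
  qualifying <- names(tab)[as.numeric(tab) / denom >= min_fraction]
  if (length(qualifying) == 1L) qualifying else "unclassified"
}

#' @rdname classify_contig
#' @param gene_table data.frame with columns contig_id and taxon.
#' @param contig_lengths named numeric vector of contig lengths.
#' @return `classify_contigs()`: named character vector of labels over all
#'   contigs in `contig_lengths` (contigs absent from the gene table are
#'   unclassified).
#' @export
classify_contigs <- function(gene_table, contig_lengths, min_len = 5000,
                             min_fraction = 0.5, count_unlabelled = TRUE) {
  by_contig <- split(gene_table$taxon, gene_table$contig_id)
  out <- vapply(names(contig_lengths), function(id) {
    classify_contig(if (id %in% names(by_contig)) by_contig[[id]]
                    else character(0),
                    contig_lengths[[id]], min_len, min_fraction,
                    count_unlabelled)
  }, character(1))
  setNames(out, names(contig_lengths))
}

#' Differential coverage of contigs across metagenomes
#'
#' Best-hit read mapping at the coverage thresholds (99% identity over at
#' least 50 bp by default), on a deterministic prefix subsample of each
#' metagenome, normalised to RPKG: mapped reads per contig-kilobase per
#' gigabase of (subsampled) metagenome.
#'
#' @param contigs named character vector.
#' @param metagenomes named list of read sets (named character vectors).
#' @param min_identity,min_aln mapping thresholds.
#' @param subsample reads taken from the head of each metagenome.
#' @return numeric matrix `contigs x metagenomes` of RPKG values.
#' @export
contig_coverage <- function(contigs, metagenomes, min_identity = 99,
                            min_aln = 50, subsample = 20e6) {
  contigs <- as_seqs(contigs, prefix = "contig")
  if (any(nchar(contigs) == 0L)) stop("zero-length contig")
  if (length(metagenomes) == 0L) stop("at least one metagenome required")
  if (is.null(names(metagenomes)))
    names(metagenomes) <- paste0("mg", seq_along(metagenomes))
  out <- matrix(0, length(contigs), length(metagenomes),
                dimnames = list(names(contigs), names(metagenomes)))
  for (m in names(metagenomes)) {
    reads <- as_seqs(metagenomes[[m]], prefix = "read")
    reads <- reads[seq_len(min(length(reads), subsample))]
    gb <- sum(nchar(reads)) / 1e9
    hits <- map_reads(reads, contigs, min_identity, min_aln,
                      mode = "best_hit")
    counts <- table(hits$subject_id)
    n <- setNames(rep(0, length(contigs)), names(contigs))
    n[names(counts)] <- as.numeric(counts)
    out[, m] <- n / ((nchar(contigs) / 1e3) * gb)
  }
  out
}

# z-score columns; constant columns become 0
zscore_cols <- function(x) {
  apply(x, 2, function(col) {
    s <- sd(col)
    if (!is.finite(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
}

# centre columns and scale the whole block by its largest column sd, so the
# block's internal variance structure is preserved while blocks stay
# commensurate (per-column z-scoring would inflate pure-noise dimensions)
block_scale <- function(x) {
  x <- as.matrix(x)
  x <- sweep(x, 2, colMeans(x))
  s <- suppressWarnings(max(apply(x, 2, sd), na.rm = TRUE))
  if (!is.finite(s) || s == 0) return(x * 0)
  x / s
}

# single-linkage components of the eps-neighbourhood graph
radius_clusters <- function(d, eps) {
  n <- nrow(d)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(d[i, ] <= eps)
      m <- min(comp[nb])
      if (any(comp[nb] != m)) { comp[nb] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

#' Bin contigs by taxonomy, composition, GC and differential coverage
#'
#' The feature vector per contig is (top `pca_dims` tetranucleotide
#' principal components, GC, log10(RPKG + 0.1) per metagenome); each block
#' is centred and scaled by its leading column's spread so the blocks are
#' commensurate without inflating noise dimensions. Within each taxonomy
#' stratum
#' contigs are clustered by a neighbourhood-radius (density) rule:
#' single-linkage components of the graph joining contigs closer than
#' `eps_mult` times the stratum's median nearest-neighbour distance.
#' Unclassified contigs are then attached to the nearest cluster whose
#' centroid distance is below that cluster's `attach_quantile` internal
#' radius, else left `"unbinned"`. Deterministic.
#'
#' @param kmer_freq tetranucleotide frequency matrix (rows = contigs), as
#'   from [composition_matrix()].
#' @param gc numeric vector of GC fractions (parallel to rows).
#' @param coverage RPKG matrix from [contig_coverage()] (all-zero metagenome
#'   columns are dropped with a warning).
#' @param taxonomy character vector of per-contig labels
#'   (`"unclassified"` allowed), parallel to rows.
#' @param pca_dims number of composition PCs (default 3).
#' @param eps_mult neighbourhood radius multiplier (default 2.5).
#' @param attach_quantile internal-radius quantile for attaching
#'   unclassified contigs (default 0.95).
#' @return object of class `bin_assignment`: `assignments` (data.frame id,
#'   bin), `features`, and the call parameters.
#' @export
bin_contigs <- function(kmer_freq, gc, coverage, taxonomy, pca_dims = 3L,
                        eps_mult = 2.5, attach_quantile = 0.95) {
  ids <- rownames(kmer_freq)
  stopifnot(!is.null(ids), length(gc) == nrow(kmer_freq),
            nrow(coverage) == nrow(kmer_freq),
            length(taxonomy) == nrow(kmer_freq))
  zero_cols <- colSums(coverage) == 0
  if (any(zero_cols)) {
    warning("dropping all-zero coverage column(s): ",
            paste(colnames(coverage)[zero_cols], collapse = ", "))
    coverage <- coverage[, !zero_cols, drop = FALSE]
  }
  pcs <- kmer_pca(kmer_freq, dims = pca_dims)$coordinates
  feats <- cbind(block_scale(pcs), gc = as.vector(scale(gc)),
                 block_scale(log10(coverage + 0.1)))
  feats[is.na(feats)] <- 0
  rownames(feats) <- ids
  bins <- setNames(rep("unbinned", length(ids)), ids)
  d_all <- as.matrix(stats::dist(feats))
  bin_no <- 0L
  centroids <- list()
  radii <- numeric(0)
  for (stratum in setdiff(unique(taxonomy), "unclassified")) {
    members <- ids[taxonomy == stratum]
    if (length(members) == 1L) {
      cl <- 1L
    } else {
      d <- d_all[members, members, drop = FALSE]
      nn <- apply(d + diag(Inf, length(members)), 1, min)
      eps <- eps_mult * median(nn)
      cl <- radius_clusters(d, eps)
    }
    for (g in unique(cl)) {
      bin_no <- bin_no + 1L
      lab <- sprintf("bin%02d", bin_no)
      mem <- members[cl == g]
      bins[mem] <- lab
      cen <- colMeans(feats[mem, , drop = FALSE])
      centroids[[lab]] <- cen
      rad <- sqrt(colSums((t(feats[mem, , drop = FALSE]) - cen)^2))
      radii[lab] <- if (length(mem) > 1L)
        as.numeric(quantile(rad, attach_quantile)) else 0
    }
  }
  # attach unclassified contigs to the nearest admissible cluster
  glob_nn <- if (nrow(feats) > 1L)
    median(apply(d_all + diag(Inf, nrow(feats)), 1, min)) else 0
  for (id in ids[taxonomy == "unclassified"]) {
    if (length(centroids) == 0L) break
    dd <- vapply(centroids, function(cen)
      sqrt(sum((feats[id, ] - cen)^2)), numeric(1))
    j <- which.min(dd)
    gate <- max(radii[names(dd)[j]], eps_mult * glob_nn)
    if (dd[j] <= gate) bins[id] <- names(dd)[j]
  }
  structure(list(assignments = data.frame(id = ids, bin = unname(bins[ids]),
                                          stringsAsFactors = FALSE),
                 features = feats,
                 params = list(pca_dims = pca_dims, eps_mult = eps_mult,
                               attach_quantile = attach_quantile)),
            class = "bin_assignment")
}

#' @export
print.bin_assignment <- function(x, ...) {
  tab <- table(x$assignments$bin)
  cat(sprintf("<bin_assignment> %d members in %d bins\n",
              nrow(x$assignments), sum(names(tab) != "unbinned")))
  print(tab)
  invisible(x)
}

#' Seeded binning of long reads
#'
#' Reconstructs unassembled populations around marker-bearing seed reads:
#' (1) reads aligning to known genomes at `remove_identity` percent over
#' at least `remove_cov` of their length are discarded; (2) each remaining read
#' gets a feature vector of trinucleotide-composition principal components
#' plus (optionally) a log-coverage term; (3) reads are assigned to the
#' nearest seed group within a distance gate, else left unbinned. Seeds
#' closer than the gate to each other merge into a single bin.
#'
#' @param reads named character vector of long reads.
#' @param seed_read_ids ids of reads carrying validated markers (non-empty,
#'   subset of `names(reads)`).
#' @param known_genomes optional named character vector of already-binned
#'   genomes used for the removal step.
#' @param remove_identity percent identity of the removal rule (default 97).
#' @param remove_cov fraction of the read that must align for removal.
#' @param dims number of composition PCs (default 3).
#' @param coverage optional per-read depth estimate; `NULL` derives one from
#'   median 15-mer multiplicity across the read set; `NA` disables the
#'   coverage feature.
#' @param gate assignment distance gate in z-scored feature space
#'   (calibrated on synthetic communities; default 3).
#' @return `bin_assignment` over reads; bins are named `rbin01`, ... and
#'   `attr(, "seeds")` maps bins to their seed reads. Removed reads get bin
#'   `"removed"`.
#' @export
seeded_read_binning <- function(reads, seed_read_ids, known_genomes = NULL,
                                remove_identity = 97, remove_cov = 0.5,
                                dims = 3L, coverage = NULL, gate = 0.8) {
  reads <- as_seqs(reads, prefix = "read")
  if (length(seed_read_ids) == 0L) stop("at least one seed read is required")
  if (!all(seed_read_ids %in% names(reads)))
    stop("seed_read_ids must be a subset of the read ids")
  bins <- setNames(rep("unbinned", length(reads)), names(reads))
  keep <- names(reads)
  if (!is.null(known_genomes) && length(known_genomes) > 0L) {
    hits <- map_reads(reads, known_genomes, remove_identity, 50,
                      mode = "best_hit")
    rm_ids <- hits$query_id[(hits$qend - hits$qstart) >=
                              remove_cov * nchar(reads)[hits$query_id]]
    bins[rm_ids] <- "removed"
    keep <- setdiff(keep, rm_ids)
  }
  seed_read_ids <- intersect(seed_read_ids, keep)
  if (length(seed_read_ids) == 0L)
    stop("all seed reads were removed by the known-genome filter")
  freq <- composition_matrix(reads[keep], k = 3L, canonical = TRUE)
  pcs <- kmer_pca(freq, dims = dims)$coordinates
  feats <- block_scale(pcs)
  # depth enters in dex units (centred, not rescaled): a 10-fold coverage
  # difference weighs like the full composition spread, a small one little
  if (is.null(coverage)) {
    depth <- cpp_kmer_depth(unname(reads[keep]), 15L)
    feats <- cbind(feats, cov = log10(depth + 0.1) -
                     mean(log10(depth + 0.1)))
  } else if (!all(is.na(coverage))) {
    lc <- log10(coverage[keep] + 0.1)
    feats <- cbind(feats, cov = lc - mean(lc))
  }
  feats[is.na(feats)] <- 0
  rownames(feats) <- keep
  # merge seeds within the gate into seed groups (single linkage)
  sfe <- feats[seed_read_ids, , drop = FALSE]
  sd_ <- as.matrix(stats::dist(sfe))
  sgrp <- radius_clusters(sd_, gate)
  labs <- sprintf("rbin%02d", sgrp)
  # nearest-seed assignment with the distance gate
  for (id in keep) {
    dd <- sqrt(rowSums((t(t(sfe) - feats[id, ]))^2))
    j <- which.min(dd)
    if (dd[j] <= gate) bins[id] <- labs[j]
  }
  seeds_by_bin <- split(seed_read_ids, labs)
  out <- structure(list(assignments = data.frame(id = names(reads),
                                                 bin = unname(bins),
                                                 stringsAsFactors = FALSE),
                        features = feats,
                        params = list(dims = dims, gate = gate,
                                      remove_identity = remove_identity)),
                   class = "bin_assignment")
  attr(out, "seeds") <- seeds_by_bin
  out
}

#' Remove redundant reads (cd-hit semantics)
#'
#' Greedy longest-first clustering matching `-G 0 -aS 0.9 -c 0.99 -g 1`:
#' a read is redundant when it aligns to an already-kept read at >=
#' `identity` with the local alignment covering >= `short_cov` of the
#' shorter sequence; with `-g 1` semantics each redundant read is assigned
#' to the best-matching kept read, not the first. Idempotent.
#'
#' @param reads named character vector.
#' @param identity identity threshold as a fraction (0.99) or percent (99).
#' @param short_cov minimum aligned fraction of the shorter sequence.
#' @return list: `kept` (names), `membership` (data.frame read,
#'   representative; representatives map to themselves).
#' @export
remove_redundancy <- function(reads, identity = 0.99, short_cov = 0.90) {
  reads <- as_seqs(reads, prefix = "read")
  if (identity <= 1) identity <- 100 * identity
  if (length(reads) == 0L)
    return(list(kept = character(0),
                membership = data.frame(read = character(0),
                                        representative = character(0),
                                        stringsAsFactors = FALSE)))
  o <- order(-nchar(reads), names(reads))
  reads <- reads[o]
  hits <- engine_map(reads, reads, min_identity = identity,
                     min_aln_len = 20L)
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  lens <- nchar(reads)
  shorter <- pmin(lens[hits$query_id], lens[hits$subject_id])
  span_q <- hits$qend - hits$qstart
  span_s <- hits$send - hits$sstart
  onshort <- ifelse(lens[hits$query_id] <= lens[hits$subject_id], span_q,
                    span_s)
  hits$qualifies <- onshort >= short_cov * shorter
  hits <- hits[hits$qualifies, , drop = FALSE]
  kept <- character(0)
  rep_of <- setNames(names(reads), names(reads))
  for (id in names(reads)) {
    h <- hits[hits$query_id == id & hits$subject_id %in% kept, ,
              drop = FALSE]
    if (nrow(h) > 0L) {
      best <- h[order(-h$pident, -(h$qend - h$qstart), h$subject_id), ,
                drop = FALSE][1L, ]
      rep_of[id] <- best$subject_id
    } else {
      kept <- c(kept, id)
    }
  }
  list(kept = kept,
       membership = data.frame(read = names(reads),
                               representative = unname(rep_of),
                               stringsAsFactors = FALSE))
}

#' Merge reads in a bin through unambiguous dovetail overlaps
#'
#' Builds an overlap graph from end-to-end alignments (>= `min_identity`
#' over > `min_overlap` columns) and stitches unambiguous simple paths —
#' read ends involved in more than one qualifying overlap (forks between
#' incompatible extensions) are never merged through. At disagreeing
#' columns the earlier read's base wins (coordinate stitching).
#'
#' @param reads named character vector (redundancy already removed).
#' @param min_identity overlap identity floor (default 99).
#' @param min_overlap overlap length floor (default 1000).
#' @return list: `fragments` (named character vector of merged sequences,
#'   singletons returned unchanged), `members` (list of read ids per
#'   fragment).
#' @export
scaffold_bin <- function(reads, min_identity = 99, min_overlap = 1000) {
  reads <- as_seqs(reads, prefix = "read")
  n <- length(reads)
  if (n <= 1L)
    return(list(fragments = reads, members = as.list(names(reads))))
  # qualifying dovetails from one all-vs-all alignment pass
  ov <- 20L
  hits <- engine_map(reads, reads, min_identity, min_overlap)
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  links <- list()   # each: list(a, b, type)
  if (nrow(hits) > 0L) {
    la <- nchar(reads)[hits$query_id]
    lb <- nchar(reads)[hits$subject_id]
    q_at_start <- hits$qstart <= ov
    q_at_end <- hits$qend >= la - ov
    s_at_start <- hits$sstart <= ov
    s_at_end <- hits$send >= lb - ov
    contained <- (q_at_start & q_at_end) | (s_at_start & s_at_end)
    type <- rep(NA_character_, nrow(hits))
    plus <- hits$strand == "+"
    type[plus & q_at_end & s_at_start] <- "a_suffix_b_prefix"
    type[plus & q_at_start & s_at_end] <- "a_prefix_b_suffix"
    type[!plus & q_at_end & s_at_end] <- "a_suffix_b_suffix"
    type[!plus & q_at_start & s_at_start] <- "a_prefix_b_prefix"
    type[contained] <- NA_character_   # containments are not dovetails
    keep <- which(!is.na(type))
    # normalise to unordered pairs (a < b), flip asymmetric types
    seen <- character(0)
    flip <- c(a_suffix_b_prefix = "a_prefix_b_suffix",
              a_prefix_b_suffix = "a_suffix_b_prefix",
              a_suffix_b_suffix = "a_suffix_b_suffix",
              a_prefix_b_prefix = "a_prefix_b_prefix")
    keep <- keep[order(-hits$score[keep])]
    for (i in keep) {
      a <- hits$query_id[i]; b <- hits$subject_id[i]; ty <- type[i]
      if (a > b) { tmp <- a; a <- b; b <- tmp; ty <- flip[[ty]] }
      key <- paste(a, b)
      if (key %in% seen) next   # best-scoring dovetail per pair
      seen <- c(seen, key)
      links[[length(links) + 1L]] <- list(a = a, b = b, type = ty)
    }
  }
  # end-usage bookkeeping: ends are "<read>:L" / "<read>:R"
  end_of <- function(l) {
    switch(l$type,
           a_suffix_b_prefix = c(paste0(l$a, ":R"), paste0(l$b, ":L")),
           a_prefix_b_suffix = c(paste0(l$a, ":L"), paste0(l$b, ":R")),
           a_suffix_b_suffix = c(paste0(l$a, ":R"), paste0(l$b, ":R")),
           a_prefix_b_prefix = c(paste0(l$a, ":L"), paste0(l$b, ":L")))
  }
  ends <- unlist(lapply(links, end_of))
  usage <- table(ends)
  ok <- vapply(links, function(l) all(usage[end_of(l)] == 1L), logical(1))
  links <- links[ok]
  # adjacency over simple links
  adj <- list()
  for (l in links) {
    e <- end_of(l)
    adj[[e[1]]] <- e[2]
    adj[[e[2]]] <- e[1]
  }
  visited <- setNames(rep(FALSE, n), names(reads))
  fragments <- character(0)
  members <- list()
  frag_no <- 0L
  oriented <- function(id, orient) {
    if (orient == "+") reads[[id]] else revcomp(reads[[id]])
  }
  for (start_id in names(reads)) {
    if (visited[start_id]) next
    # walk left to the chain start
    id <- start_id; orient <- "+"
    guard <- 0L
    repeat {
      backend <- paste0(id, if (orient == "+") ":L" else ":R")
      prev <- adj[[backend]]
      if (is.null(prev)) break
      pid <- sub(":[LR]$", "", prev)
      if (visited[pid] || pid == start_id) break   # cycle guard
      porient <- if (grepl(":R$", prev)) "+" else "-"
      id <- pid; orient <- porient
      guard <- guard + 1L
      if (guard > n) break
    }
    # walk right, stitching
    chain <- character(0)
    seqs <- oriented(id, orient)
    chain <- id; visited[id] <- TRUE
    repeat {
      fwd <- paste0(id, if (orient == "+") ":R" else ":L")
      nxt <- adj[[fwd]]
      if (is.null(nxt)) break
      nid <- sub(":[LR]$", "", nxt)
      if (visited[nid]) break
      norient <- if (grepl(":L$", nxt)) "+" else "-"
      nseq <- oriented(nid, norient)
      # recompute the suffix-prefix overlap on the oriented pair
      ov <- align_pair(seqs, nseq, min_identity, min_overlap)
      ov <- ov[ov$strand == "+" & ov$qend >= nchar(seqs) - 20 &
                 ov$sstart <= 20, , drop = FALSE]
      if (nrow(ov) == 0L) break
      best <- ov[which.max(ov$score), ]
      if (best$send < nchar(nseq))
        seqs <- paste0(seqs, substr(nseq, best$send + 1L, nchar(nseq)))
      visited[nid] <- TRUE
      chain <- c(chain, nid)
      id <- nid; orient <- norient
    }
    frag_no <- frag_no + 1L
    fname <- if (length(chain) > 1L) sprintf("fragment%02d", frag_no)
             else chain
    fragments[fname] <- seqs
    members[[fname]] <- chain
  }
  list(fragments = fragments, members = members)
}

#' Per-bin summary statistics
#'
#' Total size, GC mean and standard deviation across members
#' (length-unweighted, reported in percent), gene count and mean gene size,
#' plus any per-metagenome RPKG columns supplied.
#'
#' @param seqs named character vector: the bin's member sequences
#'   (non-empty).
#' @param genes optional gene table rows for the members (data.frame with
#'   contig_id, start, end).
#' @param rpkg optional named numeric vector of per-metagenome RPKG values
#'   for the bin.
#' @return one-row data.frame: total_size, gc_mean, gc_sd, n_genes,
#'   mean_gene_size (NA when no genes), and one `rpkg_*` column per entry.
#' @export
bin_summary <- function(seqs, genes = NULL, rpkg = NULL) {
  seqs <- as_seqs(seqs)
  if (length(seqs) == 0L) stop("empty bin")
  gcs <- 100 * gc_fraction(seqs)
  g <- if (!is.null(genes))
    genes[genes$contig_id %in% names(seqs), , drop = FALSE] else NULL
  n_genes <- if (is.null(g)) 0L else nrow(g)
  out <- data.frame(total_size = sum(nchar(seqs)),
                    gc_mean = mean(gcs),
                    gc_sd = if (length(seqs) > 1L) sd(gcs) else NA_real_,
                    n_genes = n_genes,
                    mean_gene_size = if (n_genes > 0L)
                      mean(g$end - g$start) else NA_real_)
  if (!is.null(rpkg))
    for (m in names(rpkg)) out[[paste0("rpkg_", m)]] <- rpkg[[m]]
  out
}
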