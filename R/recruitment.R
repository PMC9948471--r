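#' Fragment recruitment of metagenomic reads to a genome
#'
#' Best-hit mapping at the species-level gates (95% identity over >= 50
#' columns by default), normalised to RPKG (reads per genome-kilobase per
#' metagenome-gigabase). Breadth is the fraction of (unmasked) genome
#' positions covered by at least one best-hit alignment. A genome is called
#' present when RPKG >= `min_rpkg` AND breadth >= `min_breadth` ("less than
#' three RPKG" and "70% of the genome covered" rules). rRNA intervals can
#' be masked: masked positions are excluded from mapping and from the
#' genome length used in both RPKG and breadth.
#'
#' @param genome `seq_record` or single (named) character sequence.
#' @param reads named character vector of metagenomic reads.
#' @param min_identity,min_aln recruitment gates (95 / 50).
#' @param mask optional data.frame of 0-based half-open intervals
#'   (columns start, end) to exclude (e.g. the rRNA operon).
#' @param metagenome_gb metagenome size in Gb; defaults to the total bases
#'   of `reads` / 1e9.
#' @param metagenome_id label recorded in the profile.
#' @param min_rpkg,min_breadth presence thresholds (3 RPKG, 0.7 breadth;
#'   boundary values count as present).
#' @return one-row data.frame of class `recruitment_profile`: genome_id,
#'   metagenome_id, n_reads, rpkg, breadth, present.
#' @export
recruit <- function(genome, reads, min_identity = 95, min_aln = 50,
                    mask = NULL, metagenome_gb = NULL,
                    metagenome_id = "metagenome", min_rpkg = 3,
                    min_breadth = 0.7) {
  g <- as_seq(genome, "genome")
  if (nchar(g$seq) == 0L) stop("empty genome")
  seq <- g$seq
  masked <- 0L
  if (!is.null(mask) && nrow(mask) > 0L) {
    for (i in seq_len(nrow(mask))) {
      s <- mask$start[i]; e <- mask$end[i]
      substr(seq, s + 1L, e) <- strrep("N", e - s)
    }
    masked <- covered_length(mask$start, mask$end)
  }
  unmasked <- nchar(seq) - masked
  if (unmasked <= 0L) stop("genome is fully masked")
  reads <- as_seqs(reads, prefix = "read")
  if (is.null(metagenome_gb)) metagenome_gb <- sum(nchar(reads)) / 1e9
  hits <- if (length(reads) > 0L)
    map_reads(reads, setNames(seq, g$id), min_identity, min_aln,
              mode = "best_hit")
  else data.frame(sstart = integer(0), send = integer(0))
  n <- nrow(hits)
  rpkg <- n / ((unmasked / 1e3) * metagenome_gb)
  breadth <- covered_length(hits$sstart, hits$send) / unmasked
  structure(data.frame(genome_id = g$id, metagenome_id = metagenome_id,
                       n_reads = n, rpkg = rpkg, breadth = breadth,
                       present = rpkg >= min_rpkg & breadth >= min_breadth,
                       stringsAsFactors = FALSE),
            class = c("recruitment_profile", "data.frame"))
}

#' Read-based average nucleotide identity (ANIr)
#'
#' Unweighted mean percent identity of best-hit read alignments passing the
#' permissive population gate (80% identity over >= 50 bp by default) — a
#' direct readout of intra-population microdiversity: highly diverse
#' populations pull ANIr well below 100%.
#'
#' @inheritParams recruit
#' @param gate_identity,gate_aln the ANIr gate (80 / 50).
#' @param length_weighted weight read identities by alignment length
#'   (off by default: the read-averaged convention).
#' @return mean percent identity, or `NA` when no read passes the gate.
#' @export
anir <- function(genome, reads, gate_identity = 80, gate_aln = 50,
                 mask = NULL, length_weighted = FALSE) {
  g <- as_seq(genome, "genome")
  seq <- g$seq
  if (!is.null(mask) && nrow(mask) > 0L) {
    for (i in seq_len(nrow(mask))) {
      s <- mask$start[i]; e <- mask$end[i]
      substr(seq, s + 1L, e) <- strrep("N", e - s)
    }
  }
  hits <- map_reads(as_seqs(reads, prefix = "read"), setNames(seq, g$id),
                    gate_identity, gate_aln, mode = "best_hit")
  if (nrow(hits) == 0L) return(NA_real_)
  if (length_weighted) sum(hits$pident * hits$aln_len) / sum(hits$aln_len)
  else mean(hits$pident)
}

#' Fragment-based average nucleotide identity between two genomes
#'
#' JSpecies-style: `a` is cut into consecutive fragments (1020 bases by
#' default), each fragment best-hit aligned to `b`; fragments aligning over
#' at least `min_frag_cov` of their length (and above `min_frag_identity`)
#' are retained, and ANI is their mean identity. The symmetric variant
#' averages both directions.
#'
#' @param a,b genomes (`seq_record` or single character).
#' @param fragment fragment size in bases (1020).
#' @param min_frag_identity identity floor for retaining a fragment. Note
#'   the practical detection floor of a seeded nucleotide aligner is well
#'   above this nominal 30%: distant pairs simply return no fragments.
#' @param min_frag_cov minimum aligned fraction of the fragment (0.7).
#' @param symmetric average the two directions.
#' @return list: `ani` (percent, `NA` when no fragment is retained),
#'   `aligned_fraction`, `n_fragments`, `n_retained`.
#' @export
ani <- function(a, b, fragment = 1020L, min_frag_identity = 30,
                min_frag_cov = 0.7, symmetric = TRUE) {
  one_way <- function(x, y) {
    sx <- as_seq(x, "a"); sy <- as_seq(y, "b")
    L <- nchar(sx$seq)
    starts <- seq(1L, L, by = fragment)
    frags <- substring(sx$seq, starts, pmin(L, starts + fragment - 1L))
    keep <- nchar(frags) >= min(fragment, L) * 0.5
    frags <- frags[keep]
    names(frags) <- sprintf("frag%05d", seq_along(frags))
    hits <- map_reads(frags, setNames(sy$seq, sy$id),
                      min_identity = min_frag_identity, min_aln = 50,
                      mode = "best_hit", seed_k = 11L)
    flen <- nchar(frags)[hits$query_id]
    retained <- hits[(hits$qend - hits$qstart) >= min_frag_cov * flen, ,
                     drop = FALSE]
    list(ani = if (nrow(retained) > 0L) mean(retained$pident) else NA_real_,
         n_fragments = length(frags), n_retained = nrow(retained),
         aligned_fraction = nrow(retained) / max(1L, length(frags)))
  }
  f <- one_way(a, b)
  if (!symmetric)
    return(list(ani = f$ani, aligned_fraction = f$aligned_fraction,
                n_fragments = f$n_fragments, n_retained = f$n_retained))
  r <- one_way(b, a)
  anis <- c(f$ani, r$ani)
  list(ani = if (all(is.na(anis))) NA_real_ else mean(anis, na.rm = TRUE),
       aligned_fraction = mean(c(f$aligned_fraction, r$aligned_fraction)),
       n_fragments = f$n_fragments + r$n_fragments,
       n_retained = f$n_retained + r$n_retained)
}

#' Dereplicate genomes at the species boundary
#'
#' Greedy clustering by decreasing genome length on the ANI graph: a genome
#' joins the first kept representative with symmetric ANI >=
#' `species_ani` and aligned fraction >= `min_align_frac`; otherwise it
#' founds a cluster. The longest member represents each cluster.
#'
#' @param genomes named character vector (or list of `seq_record`s).
#' @param species_ani species-boundary ANI in percent (default 95).
#' @param min_align_frac minimum aligned fraction for an edge (default 0.5).
#' @param fragment ANI fragment size.
#' @return list: `representatives` (names), `membership` (data.frame
#'   genome, representative).
#' @export
dereplicate_genomes <- function(genomes, species_ani = 95,
                                min_align_frac = 0.5, fragment = 1020L) {
  genomes <- as_seqs(genomes, prefix = "genome")
  if (length(genomes) == 0L) stop("at least one genome required")
  o <- order(-nchar(genomes), names(genomes))
  genomes <- genomes[o]
  reps <- character(0)
  rep_of <- setNames(names(genomes), names(genomes))
  for (id in names(genomes)) {
    assigned <- FALSE
    for (r in reps) {
      res <- ani(genomes[id], genomes[r], fragment = fragment)
      if (!is.na(res$ani) && res$ani >= species_ani &&
          res$aligned_fraction >= min_align_frac) {
        rep_of[id] <- r
        assigned <- TRUE
        break
      }
    }
    if (!assigned) reps <- c(reps, id)
  }
  list(representatives = reps,
       membership = data.frame(genome = names(genomes),
                               representative = unname(rep_of),
                               stringsAsFactors = FALSE))
}

#' AAI / shared-protein network between proteomes
#'
#' All-vs-all Smith-Waterman (BLOSUM62, affine gaps 11/1) within each genome
#' pair; reciprocal best hits whose alignment covers at least `min_cov` of
#' the shorter peptide define orthologue pairs (the coverage gate keeps
#' short chance alignments between unrelated peptides out). AAI is the mean
#' percent identity over RBH pairs and the orthologous fraction (OF) is
#' `n_rbh / min(proteome sizes)`. Edges failing either floor (25% OF, 30%
#' AAI by default) are dropped; the unfiltered pair table is kept in
#' `attr(, "all_pairs")`.
#'
#' @param proteomes named list of named character vectors of peptides.
#' @param min_of orthologous-fraction floor (0.25).
#' @param min_aai AAI floor in percent (30).
#' @param min_cov minimum aligned fraction of the shorter peptide for an
#'   RBH pair to count (0.7).
#' @return data.frame of edges: genome_a, genome_b, n_rbh, aai, of.
#' @export
aai_network <- function(proteomes, min_of = 0.25, min_aai = 30,
                        min_cov = 0.7) {
  sizes <- vapply(proteomes, length, integer(1))
  if (any(sizes == 0L)) {
    warning("excluding empty proteome(s): ",
            paste(names(proteomes)[sizes == 0L], collapse = ", "))
    proteomes <- proteomes[sizes > 0L]
  }
  ids <- names(proteomes)
  rows <- list()
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) for (j in seq.int(i + 1L, length(ids))) {
      pa <- proteomes[[ids[i]]]; pb <- proteomes[[ids[j]]]
      m <- cpp_protein_matrix(unname(pa), unname(pb))
      sc <- m$score
      best_ab <- apply(sc, 1, which.max)
      best_ba <- apply(sc, 2, which.max)
      shorter <- outer(nchar(pa), nchar(pb), pmin)
      covered <- m$aln_len >= min_cov * shorter
      rbh <- which(best_ba[best_ab] == seq_along(best_ab) &
                     sc[cbind(seq_along(best_ab), best_ab)] > 0 &
                     covered[cbind(seq_along(best_ab), best_ab)])
      n_rbh <- length(rbh)
      aai_v <- if (n_rbh > 0L)
        mean(m$pident[cbind(rbh, best_ab[rbh])]) else NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(genome_a = ids[i], genome_b = ids[j], n_rbh = n_rbh,
                   aai = aai_v, of = n_rbh / min(length(pa), length(pb)),
                   stringsAsFactors = FALSE)
    }
  }
  all_pairs <- if (length(rows)) do.call(rbind, rows)
               else data.frame(genome_a = character(0),
                               genome_b = character(0), n_rbh = integer(0),
                               aai = numeric(0), of = numeric(0),
                               stringsAsFactors = FALSE)
  edges <- all_pairs[!is.na(all_pairs$aai) & all_pairs$of >= min_of &
                       all_pairs$aai >= min_aai, , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "all_pairs") <- all_pairs
  edges
}

#' Recruitment matrix across genomes, metagenomes and identity levels
#'
#' One recruitment profile per (genome, metagenome, identity level) — the
#' species-level (95%) and genus-level (70%) sweeps of the depth-profile
#' figures.
#'
#' @param genomes named character vector (or list of `seq_record`s).
#' @param metagenomes named list of read sets.
#' @param identity_levels identity gates to sweep (default `c(95, 70)`).
#' @param min_aln alignment-length gate.
#' @param masks optional named list of mask data.frames per genome.
#' @return long-format data.frame: genome_id, metagenome_id, identity,
#'   n_reads, rpkg, breadth, present.
#' @export
recruitment_matrix <- function(genomes, metagenomes,
                               identity_levels = c(95, 70), min_aln = 50,
                               masks = NULL) {
  genomes <- as_seqs(genomes, prefix = "genome")
  if (is.null(names(metagenomes)))
    names(metagenomes) <- paste0("mg", seq_along(metagenomes))
  rows <- list()
  for (idl in identity_levels) for (m in names(metagenomes)) {
    reads <- as_seqs(metagenomes[[m]], prefix = "read")
    gb <- sum(nchar(reads)) / 1e9
    for (g in names(genomes)) {
      p <- recruit(setNames(genomes[g], g), reads, min_identity = idl,
                   min_aln = min_aln,
                   mask = if (!is.null(masks)) masks[[g]] else NULL,
                   metagenome_gb = gb, metagenome_id = m)
      p$identity <- idl
      rows[[length(rows) + 1L]] <- p
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("genome_id", "metagenome_id", "identity", "n_reads", "rpkg",
          "breadth", "present")]
}
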