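#' Specify a synthetic genome
#'
#' A genome is sampled from an order-3 Markov background whose transition
#' table is drawn from `signature_seed` and then rescaled so that the chain's
#' stationary GC matches `gc_target`. Each `signature_seed` therefore yields
#' a distinct, stable tetranucleotide signature, which the composition-based
#' binning steps rely on. An optional marker gene (e.g. a 16S-like reference
#' sequence) can be embedded exactly once, at a recorded position and strand,
#' after per-site divergence from the template.
#'
#' @param name genome label.
#' @param length genome length in bases (> 0).
#' @param gc_target target GC fraction, in \[0.25, 0.75\].
#' @param signature_seed integer seed for the background composition model.
#' @param circular logical; circular replicons allow reads to span the origin.
#' @param marker_template optional marker sequence to embed.
#' @param marker_divergence per-site substitution rate applied to the embedded
#'   marker, in \[0, 0.3\].
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(name, length, gc_target = 0.5, signature_seed = 1L,
                        circular = FALSE, marker_template = NULL,
                        marker_divergence = 0) {
  if (!is.numeric(length) || length(length) != 1L || length <= 0)
    stop("genome length must be a positive integer")
  if (gc_target < 0.25 || gc_target > 0.75)
    stop("gc_target must lie in [0.25, 0.75]")
  if (marker_divergence < 0 || marker_divergence > 0.3)
    stop("marker_divergence must lie in [0, 0.3]")
  if (!is.null(marker_template) && nchar(marker_template) >= length)
    stop("marker_template longer than the genome")
  structure(list(name = as.character(name), length = as.integer(length),
                 gc_target = gc_target,
                 signature_seed = as.integer(signature_seed),
                 circular = isTRUE(circular),
                 marker_template = marker_template,
                 marker_divergence = marker_divergence),
            class = "genome_spec")
}

# order-3 transition table for a signature seed, rescaled to hit gc_target
# (GC columns reweighted by w, solved so the stationary GC equals the target)
signature_transitions <- function(signature_seed, gc_target) {
  t0 <- with_seed(signature_seed, {
    m <- matrix(rgamma(64L * 4L, shape = 1), nrow = 64L, ncol = 4L)
    m / rowSums(m)
  })
  ns <- outer(0:63, 0:3, function(s, b) bitwAnd(s * 4L + b, 63L)) + 1L
  stat_gc <- function(w) {
    tw <- t0 * rep(c(1, w, w, 1), each = 64L)
    tw <- tw / rowSums(tw)
    p <- matrix(0, 64L, 64L)
    for (b in 1:4) p[cbind(1:64, ns[, b])] <- p[cbind(1:64, ns[, b])] + tw[, b]
    pi0 <- rep(1 / 64, 64L)
    for (i in 1:200) pi0 <- as.vector(pi0 %*% p)
    list(gc = sum(pi0 * (tw[, 2] + tw[, 3])), trans = tw)
  }
  f <- function(lw) stat_gc(exp(lw))$gc - gc_target
  lw <- uniroot(f, interval = c(-8, 8), tol = 1e-10)$root
  stat_gc(exp(lw))$trans
}

#' Generate a synthetic genome
#'
#' @param spec a [genome_spec()].
#' @param rng_seed integer seed for the sequence draw; `NULL` uses the current
#'   RNG stream (used internally when a whole community is generated under a
#'   single seed).
#' @return an object of class `seq_record`: a list with `id`, `seq`,
#'   `circular`, and (when a marker is embedded) `marker` holding the 0-based
#'   half-open interval and strand of the embedded copy.
#' @examples
#' g <- generate_genome(genome_spec("g1", 10000, gc_target = 0.5), rng_seed = 1)
#' nchar(g$seq)
#' @export
generate_genome <- function(spec, rng_seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  trans <- signature_transitions(spec$signature_seed, spec$gc_target)
  build <- function() {
    marker <- NULL
    mlen <- if (is.null(spec$marker_template)) 0L else nchar(spec$marker_template)
    bg <- cpp_markov_gen(spec$length - mlen, trans)
    if (mlen > 0L) {
      m <- spec$marker_template
      if (spec$marker_divergence > 0) {
        nmut <- rbinom(1L, mlen, spec$marker_divergence)
        m <- mutate_sites(m, sample.int(mlen, nmut))
      }
      strand <- if (runif(1) < 0.5) "+" else "-"
      ins <- if (strand == "-") revcomp(m) else m
      p <- sample.int(nchar(bg) + 1L, 1L) - 1L  # 0-based insertion point
      bg <- paste0(substr(bg, 1L, p), ins, substr(bg, p + 1L, nchar(bg)))
      marker <- list(start = p, end = p + mlen, strand = strand)
    }
    list(seq = bg, marker = marker)
  }
  out <- if (is.null(rng_seed)) build() else with_seed(rng_seed, build())
  structure(list(id = spec$name, seq = out$seq, circular = spec$circular,
                 gc_target = spec$gc_target, marker = out$marker),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s: %d bp, %s, GC %.3f%s\n", x$id, nchar(x$seq),
              if (isTRUE(x$circular)) "circular" else "linear",
              gc_fraction(x$seq),
              if (!is.null(x$marker))
                sprintf(", marker at [%d,%d) strand %s", x$marker$start,
                        x$marker$end, x$marker$strand) else ""))
  invisible(x)
}

#' Derive strains of a population by independent substitution
#'
#' Emulates intra-population microdiversity: each strain differs from the
#' parent at a Binomial(length, divergence) number of sites. Substitutions
#' only, so all strains stay length-aligned to the parent.
#'
#' @param genome a `seq_record` (or single character sequence).
#' @param n_strains number of strains (>= 1).
#' @param divergence per-site substitution rate, in \[0, 0.05\].
#' @param rng_seed seed; `NULL` uses the current stream.
#' @return list of `seq_record`s, ids suffixed `_s1`, `_s2`, ...
#' @export
diversify_population <- function(genome, n_strains, divergence,
                                 rng_seed = 1L) {
  if (n_strains < 1L) stop("n_strains must be >= 1")
  if (divergence < 0 || divergence > 0.05)
    stop("divergence must lie in [0, 0.05]")
  g <- as_seq(genome)
  circ <- if (inherits(genome, "seq_record")) isTRUE(genome$circular) else FALSE
  L <- nchar(g$seq)
  build <- function() {
    lapply(seq_len(n_strains), function(i) {
      s <- g$seq
      if (divergence > 0) {
        nmut <- rbinom(1L, L, divergence)
        s <- mutate_sites(s, sample.int(L, nmut))
      }
      structure(list(id = sprintf("%s_s%d", g$id, i), seq = s,
                     circular = circ, marker = NULL), class = "seq_record")
    })
  }
  if (is.null(rng_seed)) build() else with_seed(rng_seed, build())
}

#' Specify a synthetic community
#'
#' @param members list of members built by [community_member()].
#' @param rng_seed seed governing genome and strain generation.
#' @return object of class `community_spec`.
#' @export
community_spec <- function(members, rng_seed = 1L) {
  ab <- vapply(members, `[[`, numeric(1), "abundance")
  if (abs(sum(ab) - 1) > 1e-9)
    stop("relative abundances must sum to 1 (within 1e-9)")
  structure(list(members = members, rng_seed = as.integer(rng_seed)),
            class = "community_spec")
}

#' @rdname community_spec
#' @param spec a [genome_spec()].
#' @param abundance relative abundance (fractions must sum to 1 over members).
#' @param population_divergence per-site strain substitution rate in
#'   \[0, 0.05\]; with `n_strains = 1` it is a no-op.
#' @param n_strains number of strains drawn from the member (>= 1).
#' @export
community_member <- function(spec, abundance, population_divergence = 0,
                             n_strains = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  if (n_strains < 1L) stop("n_strains must be >= 1")
  if (population_divergence < 0 || population_divergence > 0.05)
    stop("population_divergence must lie in [0, 0.05]")
  list(spec = spec, abundance = abundance,
       population_divergence = population_divergence,
       n_strains = as.integer(n_strains))
}

#' Specify a read simulation
#'
#' Long reads follow a truncated normal length law (mean 14.3 kb by default,
#' the CCS-like regime) with a per-base error rate split 80/20 between
#' substitutions and length-preserving small indels. Short mode emits 150 bp
#' pairs from fragments with a normal insert-size law.
#'
#' @param mode `"long"` or `"short"`.
#' @param mean_length mean read length (long mode) in bases.
#' @param length_sd read-length standard deviation (long mode).
#' @param min_length lower truncation of the length law (long mode).
#' @param read_length fixed read length for short mode.
#' @param insert_mean,insert_sd insert-size law for short mode.
#' @param error_rate per-base substitution+indel rate, in \[0, 0.05\].
#' @param depth mean fold coverage (used when `n_reads` is `NULL`).
#' @param n_reads total number of reads to draw (pairs count as two).
#' @param rng_seed seed governing read sampling.
#' @return object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(mode = c("long", "short"), mean_length = NULL,
                          length_sd = NULL, min_length = NULL,
                          read_length = 150L, insert_mean = 350,
                          insert_sd = 35, error_rate = NULL, depth = NULL,
                          n_reads = NULL, rng_seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "long") {
    if (is.null(mean_length)) mean_length <- 14300
    if (is.null(length_sd)) length_sd <- 5000
    if (is.null(min_length)) min_length <- 3000
    if (is.null(error_rate)) error_rate <- 0.005
  } else {
    if (is.null(mean_length)) mean_length <- read_length
    if (is.null(length_sd)) length_sd <- 0
    if (is.null(min_length)) min_length <- read_length
    if (is.null(error_rate)) error_rate <- 0.001
  }
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must lie in [0, 0.05]")
  if (is.null(n_reads) && (is.null(depth) || depth <= 0))
    stop("either n_reads or a positive depth is required")
  if (!is.null(n_reads) && n_reads <= 0) stop("n_reads must be positive")
  structure(list(mode = mode, mean_length = mean_length,
                 length_sd = length_sd, min_length = min_length,
                 read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate, depth = depth, n_reads = n_reads,
                 rng_seed = as.integer(rng_seed)),
            class = "read_sim_spec")
}

# truncated normal lengths (resampling below the truncation point)
rtrunc_lengths <- function(n, mean, sd, min) {
  if (n == 0L) return(integer(0))
  x <- round(rnorm(n, mean, sd))
  bad <- which(x < min)
  guard <- 0L
  while (length(bad) > 0L && guard < 100L) {
    x[bad] <- round(rnorm(length(bad), mean, sd))
    bad <- bad[x[bad] < min]
    guard <- guard + 1L
  }
  x[x < min] <- min
  as.integer(x)
}

# apply substitution (80%) and length-preserving indel (20%) errors
apply_read_errors <- function(seq, rate, sub_frac = 0.8) {
  L <- nchar(seq)
  if (rate <= 0 || L == 0L) return(seq)
  n <- rbinom(1L, L, rate)
  if (n == 0L) return(seq)
  nsub <- rbinom(1L, n, sub_frac)
  if (nsub > 0L) seq <- mutate_sites(seq, sample.int(L, min(nsub, L)))
  nind <- n - nsub
  if (nind > 0L) {
    r <- charToRaw(seq)
    bases <- charToRaw("ACGT")
    nind <- min(nind, length(r) - 1L)
    r <- r[-sample.int(length(r), nind)]                  # deletions
    ins_pos <- sort(sample.int(length(r) + 1L, nind, replace = TRUE))
    out <- raw(length(r) + nind)
    out[seq_along(r) + findInterval(seq_along(r), ins_pos)] <- r
    out[ins_pos + seq_len(nind) - 1L] <- bases[sample.int(4L, nind,
                                                          replace = TRUE)]
    seq <- rawToChar(out)
  }
  seq
}

# extract [start, start+len) from a genome, wrapping the origin if circular
extract_read <- function(seq, start, len, circular) {
  L <- nchar(seq)
  truncated <- FALSE
  if (len > L && !circular) { len <- L; start <- 0L; truncated <- TRUE }
  if (start + len <= L) {
    out <- substr(seq, start + 1L, start + len)
  } else if (circular) {
    out <- paste0(substr(seq, start + 1L, L),
                  substr(seq, 1L, (start + len) - L))
  } else {
    out <- substr(seq, start + 1L, L)
    truncated <- TRUE
  }
  list(seq = out, end = start + len, truncated = truncated)
}

#' Simulate a read set from a community
#'
#' Read counts per genome are multinomial in abundance x genome length;
#' strains are drawn uniformly within a member. Long mode draws start
#' positions uniformly (reads from circular genomes may wrap through the
#' origin; truth intervals are then recorded modulo the genome length, with
#' `end` > genome length marking the wrap). Short mode emits read pairs.
#' The error process is applied after extraction. Every read is recorded in
#' a truth table.
#'
#' @param community a [community_spec()].
#' @param readspec a [read_sim_spec()].
#' @return object of class `read_sim`: list with `reads` (named character
#'   vector), `truth` (data.frame: read_id, genome, strain, start, end,
#'   strand, truncated) and `genomes` (the strain sequences used).
#' @export
simulate_reads <- function(community, readspec) {
  stopifnot(inherits(community, "community_spec"),
            inherits(readspec, "read_sim_spec"))
  members <- community$members
  # genomes and strains under the community seed
  strains <- with_seed(community$rng_seed, {
    lapply(members, function(m) {
      g <- generate_genome(m$spec, rng_seed = NULL)
      list(genome = g,
           strains = diversify_population(g, m$n_strains,
                                          m$population_divergence,
                                          rng_seed = NULL))
    })
  })
  glens <- vapply(strains, function(s) nchar(s$genome$seq), numeric(1))
  ab <- vapply(members, `[[`, numeric(1), "abundance")
  w <- ab * glens
  w <- w / sum(w)
  n_reads <- readspec$n_reads
  if (is.null(n_reads))
    n_reads <- max(1L, round(readspec$depth * sum(glens) /
                               readspec$mean_length))
  if (readspec$mode == "short" && n_reads %% 2L == 1L)
    n_reads <- n_reads + 1L
  n_units <- if (readspec$mode == "short") n_reads %/% 2L else n_reads

  with_seed(readspec$rng_seed, {
    counts <- as.vector(rmultinom(1L, n_units, w))
    reads <- character(0)
    truth <- vector("list", length(members))
    unit <- 0L
    for (gi in seq_along(members)) {
      cnt <- counts[gi]
      if (cnt == 0L) { truth[[gi]] <- NULL; next }
      st <- strains[[gi]]
      L <- glens[gi]
      circ <- isTRUE(st$genome$circular)
      sidx <- sample.int(length(st$strains), cnt, replace = TRUE)
      rows <- vector("list", cnt)
      gseqs <- character(if (readspec$mode == "short") 2L * cnt else cnt)
      gids <- character(length(gseqs))
      for (i in seq_len(cnt)) {
        unit <- unit + 1L
        sseq <- st$strains[[sidx[i]]]$seq
        if (readspec$mode == "long") {
          len <- rtrunc_lengths(1L, readspec$mean_length, readspec$length_sd,
                                readspec$min_length)
          start <- if (circ) sample.int(L, 1L) - 1L
                   else sample.int(max(1L, L - min(len, L) + 1L), 1L) - 1L
          ex <- extract_read(sseq, start, len, circ)
          strand <- if (runif(1) < 0.5) "+" else "-"
          rseq <- if (strand == "-") revcomp(ex$seq) else ex$seq
          rseq <- apply_read_errors(rseq, readspec$error_rate)
          id <- sprintf("read%07d", unit)
          gseqs[i] <- rseq
          gids[i] <- id
          rows[[i]] <- data.frame(read_id = id, genome = st$genome$id,
                                  strain = sidx[i], start = start,
                                  end = ex$end, strand = strand,
                                  truncated = ex$truncated,
                                  stringsAsFactors = FALSE)
        } else {
          rl <- readspec$read_length
          frag <- max(2L * rl, round(rnorm(1L, readspec$insert_mean,
                                           readspec$insert_sd)))
          start <- if (circ) sample.int(L, 1L) - 1L
                   else sample.int(max(1L, L - min(frag, L) + 1L), 1L) - 1L
          ex <- extract_read(sseq, start, frag, circ)
          fl <- nchar(ex$seq)
          r1 <- substr(ex$seq, 1L, rl)
          r2 <- revcomp(substr(ex$seq, fl - rl + 1L, fl))
          r1 <- apply_read_errors(r1, readspec$error_rate)
          r2 <- apply_read_errors(r2, readspec$error_rate)
          id1 <- sprintf("read%07d/1", unit)
          id2 <- sprintf("read%07d/2", unit)
          gseqs[2L * i - 1L] <- r1
          gseqs[2L * i] <- r2
          gids[2L * i - 1L] <- id1
          gids[2L * i] <- id2
          rows[[i]] <- data.frame(
            read_id = c(id1, id2), genome = st$genome$id,
            strain = sidx[i],
            start = c(start, (start + fl - rl) %% max(L, 1L)),
            end = c(start + rl, ((start + fl - rl) %% max(L, 1L)) + rl),
            strand = c("+", "-"), truncated = ex$truncated,
            stringsAsFactors = FALSE)
        }
      }
      names(gseqs) <- gids
      reads <- c(reads, gseqs)
      truth[[gi]] <- do.call(rbind, rows)
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    structure(list(reads = reads, truth = truth,
                   genomes = lapply(strains, `[[`, "genome"),
                   strains = lapply(strains, `[[`, "strains")),
              class = "read_sim")
  })
}

#' @export
print.read_sim <- function(x, ...) {
  cat(sprintf("<read_sim> %d reads from %d genomes (%.2f Mb total)\n",
              length(x$reads), length(x$genomes),
              sum(nchar(x$reads)) / 1e6))
  invisible(x)
}

#' Cut a genome into contigs
#'
#' Convenience for building contig sets from synthetic genomes: consecutive
#' pieces with lengths drawn uniformly from `[min_len, max_len]`. A trailing
#' piece shorter than `min_len` is merged into its predecessor.
#'
#' @param genome `seq_record` or single character sequence.
#' @param min_len,max_len contig length bounds in bases.
#' @param rng_seed seed; `NULL` uses the current stream.
#' @return named character vector of contigs (`<id>_c1`, ...), with the
#'   source intervals in `attr(, "intervals")`.
#' @export
fragment_genome <- function(genome, min_len = 5000, max_len = 50000,
                            rng_seed = 1L) {
  g <- as_seq(genome)
  L <- nchar(g$seq)
  build <- function() {
    cuts <- integer(0)
    p <- 0L
    while (p < L) {
      len <- sample.int(max_len - min_len + 1L, 1L) + min_len - 1L
      p <- min(L, p + len)
      cuts <- c(cuts, p)
    }
    starts <- c(0L, cuts[-length(cuts)])
    ends <- cuts
    if (length(starts) > 1L && (ends[length(ends)] - starts[length(starts)]) < min_len) {
      starts <- starts[-length(starts)]
      ends[length(ends) - 1L] <- L
      ends <- ends[-length(ends)]
    }
    out <- substring(g$seq, starts + 1L, ends)
    names(out) <- sprintf("%s_c%d", g$id, seq_along(out))
    attr(out, "intervals") <- data.frame(contig_id = names(out),
                                         genome = g$id,
                                         start = as.integer(starts),
                                         end = as.integer(ends),
                                         stringsAsFactors = FALSE)
    out
  }
  if (is.null(rng_seed)) build() else with_seed(rng_seed, build())
}

#' Simulate a gene table for a contig set
#'
#' Emits non-overlapping gene calls tiling ~85% of each contig, with a
#' best-hit taxonomy label that equals the contig's true phylum with
#' probability `label_accuracy` (otherwise a decoy label or no label).
#' Optionally assigns single-copy marker labels to a subset of genes.
#'
#' @param contigs named character vector of contigs.
#' @param taxa named character vector: true phylum per contig.
#' @param mean_gene_len,gene_len_sd gene length law (bases).
#' @param label_accuracy probability a gene is labelled with the true phylum.
#' @param decoy_taxa labels used for mislabelled genes.
#' @param unlabelled_frac fraction of genes with no best-hit label.
#' @param markers optional character vector of marker labels to sprinkle
#'   (one gene per marker, chosen at random across the contig set).
#' @param rng_seed seed; `NULL` uses the current stream.
#' @return data.frame: contig_id, start, end, strand, taxon, marker.
#' @export
simulate_gene_table <- function(contigs, taxa, mean_gene_len = 900,
                                gene_len_sd = 200, label_accuracy = 0.9,
                                decoy_taxa = c("DecoyPhylumA", "DecoyPhylumB"),
                                unlabelled_frac = 0.05, markers = NULL,
                                rng_seed = 1L) {
  contigs <- as_seqs(contigs, prefix = "contig")
  build <- function() {
    rows <- lapply(names(contigs), function(id) {
      L <- nchar(contigs[[id]])
      truth <- taxa[[id]]
      starts <- integer(0); ends <- integer(0)
      p <- round(runif(1, 0, 200))
      while (p < L - 200) {
        len <- max(90L, round(rnorm(1, mean_gene_len, gene_len_sd)))
        e <- min(L, p + len)
        starts <- c(starts, p); ends <- c(ends, e)
        p <- e + round(runif(1, 10, 250))
      }
      n <- length(starts)
      if (n == 0L)
        return(data.frame(contig_id = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          taxon = character(0), stringsAsFactors = FALSE))
      u <- runif(n)
      taxon <- ifelse(u < label_accuracy, truth,
                      ifelse(u < label_accuracy + unlabelled_frac,
                             NA_character_,
                             sample(decoy_taxa, n, replace = TRUE)))
      data.frame(contig_id = id, start = starts, end = ends,
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 taxon = taxon, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$marker <- NA_character_
    if (!is.null(markers) && nrow(tab) > 0L) {
      idx <- sample.int(nrow(tab), min(length(markers), nrow(tab)))
      tab$marker[idx] <- markers[seq_along(idx)]
    }
    tab
  }
  if (is.null(rng_seed)) build() else with_seed(rng_seed, build())
}
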