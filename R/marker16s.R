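#' Build a marker reference set
#'
#' A marker reference set couples reference sequences (e.g. full-length
#' 16S-like genes) with semicolon-delimited taxonomy strings
#' (`Domain;Phylum;Class;...`).
#'
#' @param seqs named character vector of reference marker sequences.
#' @param taxonomy character vector of semicolon-delimited rank strings,
#'   parallel to `seqs`.
#' @return object of class `marker_refs`.
#' @export
marker_ref_set <- function(seqs, taxonomy) {
  seqs <- as_seqs(seqs, prefix = "marker")
  if (length(seqs) == 0L) stop("empty marker reference set")
  stopifnot(length(taxonomy) == length(seqs))
  structure(list(seqs = seqs, taxonomy = setNames(taxonomy, names(seqs))),
            class = "marker_refs")
}

#' Read a marker reference FASTA with taxonomy headers
#'
#' Headers are `>id Domain;Phylum;Class;...` — the first whitespace-separated
#' token is the id, the remainder the taxonomy string.
#'
#' @param path FASTA path.
#' @return a [marker_ref_set()].
#' @export
read_marker_refs <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  full <- names(x)
  ids <- sub("\\s.*$", "", full)
  tax <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  marker_ref_set(setNames(as.character(x), ids), tax)
}

# Karlin-Altschul lambda for the +1/-2 scheme at uniform base composition:
# solves (1/4) e^lambda + (3/4) e^(-2 lambda) = 1
ka_lambda <- function() {
  v <- get0("lambda", envir = .metalag_cache)
  if (!is.null(v)) return(v)
  f <- function(l) 0.25 * exp(l) + 0.75 * exp(-2 * l) - 1
  v <- uniroot(f, c(0.1, 3), tol = 1e-12)$root
  assign("lambda", v, envir = .metalag_cache)
  v
}
.metalag_cache <- new.env(parent = emptyenv())
# K for the ungapped +1/-2 scheme (standard tabulated value); the 1e-5
# candidate gate is permissive, so modest approximation error is immaterial
KA_K <- 0.46

#' Find marker-gene candidates in sequences
#'
#' Local alignment of each sequence against a marker reference set; hits are
#' screened by a Karlin-Altschul expectation value,
#' `E = K * m * n * exp(-lambda * S)` with `m` the query length and `n` the
#' total reference length, using the engine's +1/-2 (gap 5/2) scheme. The
#' best hit per sequence with `E < max_evalue` is emitted with the aligned
#' segment extracted (reverse-complemented to reference orientation for
#' minus-strand hits).
#'
#' @param seqs named character vector of reads or contigs.
#' @param marker_refs a [marker_ref_set()].
#' @param max_evalue expectation-value ceiling (default `1e-5`).
#' @return data.frame of class `marker_hits`: source_id, best_ref, start,
#'   end, strand (segment interval on the source, 0-based half-open),
#'   pident, aln_len, score, evalue, ref_start, ref_end, segment.
#' @export
find_marker_candidates <- function(seqs, marker_refs, max_evalue = 1e-5) {
  stopifnot(inherits(marker_refs, "marker_refs"))
  seqs <- as_seqs(seqs, prefix = "seq")
  hits <- engine_map(seqs, marker_refs$seqs, min_identity = 55,
                     min_aln_len = 30, seed_k = 11L)
  empty <- data.frame(source_id = character(0), best_ref = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), pident = numeric(0),
                      aln_len = numeric(0), score = numeric(0),
                      evalue = numeric(0), ref_start = integer(0),
                      ref_end = integer(0), segment = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(structure(empty, class = c("marker_hits",
                                                          "data.frame")))
  n_db <- sum(nchar(marker_refs$seqs))
  m_q <- nchar(seqs)[hits$query_id]
  hits$evalue <- KA_K * m_q * n_db * exp(-ka_lambda() * hits$score)
  hits <- hits[order(hits$query_id, hits$evalue, -hits$score), , drop = FALSE]
  hits <- hits[!duplicated(hits$query_id), , drop = FALSE]
  hits <- hits[hits$evalue < max_evalue, , drop = FALSE]
  if (nrow(hits) == 0L) return(structure(empty, class = c("marker_hits",
                                                          "data.frame")))
  seg <- substring(seqs[hits$query_id], hits$qstart + 1L, hits$qend)
  seg[hits$strand == "-"] <- revcomp(seg[hits$strand == "-"])
  out <- data.frame(source_id = hits$query_id, best_ref = hits$subject_id,
                    start = hits$qstart, end = hits$qend,
                    strand = hits$strand, pident = hits$pident,
                    aln_len = hits$aln_len, score = hits$score,
                    evalue = hits$evalue, ref_start = hits$sstart,
                    ref_end = hits$send, segment = unname(seg),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("marker_hits", "data.frame"))
}

#' Validate marker candidates by reference-model coverage
#'
#' A candidate is bona fide when its alignment covers at least
#' `min_model_fraction` of the best reference's length — a lightweight
#' surrogate for profile-model validation that rejects spurious short
#' matches.
#'
#' @param hits a `marker_hits` data.frame.
#' @param marker_refs the [marker_ref_set()] the hits were found against.
#' @param min_model_fraction minimum covered fraction of the reference
#'   (default 0.5; 0 accepts every candidate).
#' @return logical vector, one entry per hit.
#' @export
validate_marker <- function(hits, marker_refs, min_model_fraction = 0.5) {
  stopifnot(inherits(marker_refs, "marker_refs"))
  if (nrow(hits) == 0L) return(logical(0))
  rlen <- nchar(marker_refs$seqs)[hits$best_ref]
  (hits$ref_end - hits$ref_start) >= min_model_fraction * rlen
}

#' Classify marker hits by best-reference taxonomy
#'
#' Short-read class: classified when identity is at least 80% and alignment
#' length at least 90 bases. Long class: classified when the segment is at
#' least 1000 bases (and identity >= 80%). Hits failing the gates are
#' returned as `"unclassified"`.
#'
#' @param hits a `marker_hits` data.frame (validated candidates).
#' @param marker_refs the [marker_ref_set()] carrying taxonomy strings.
#' @param read_class `"short"` or `"long"`.
#' @param min_identity identity floor applied to both classes.
#' @param min_aln_short alignment-length floor for the short class.
#' @param min_segment_long segment-length floor for the long class.
#' @return character vector of taxonomy strings (or `"unclassified"`).
#' @export
classify_marker <- function(hits, marker_refs,
                            read_class = c("short", "long"),
                            min_identity = 80, min_aln_short = 90,
                            min_segment_long = 1000) {
  read_class <- match.arg(read_class)
  stopifnot(inherits(marker_refs, "marker_refs"))
  if (nrow(hits) == 0L) return(character(0))
  ok <- if (read_class == "short") {
    hits$pident >= min_identity & hits$aln_len >= min_aln_short
  } else {
    hits$pident >= min_identity & nchar(hits$segment) >= min_segment_long
  }
  out <- rep("unclassified", nrow(hits))
  out[ok] <- unname(marker_refs$taxonomy[hits$best_ref[ok]])
  out
}

#' Dereplicate marker segments by identity clustering
#'
#' Greedy longest-first clustering (cd-hit convention): segments are visited
#' by decreasing length; a segment joins the first existing representative
#' it matches at >= `identity` percent over >= `min_self_cov` of its own
#' length, otherwise it founds a new cluster. Deterministic.
#'
#' @param segments named character vector of marker segments (each >= 1000
#'   bases, the long-read gate).
#' @param identity percent identity threshold (default 97).
#' @param min_self_cov fraction of the member's own length that must align.
#' @return list: `representatives` (names), `membership` (data.frame
#'   segment, representative).
#' @export
dereplicate_markers <- function(segments, identity = 97,
                                min_self_cov = 0.9) {
  segments <- as_seqs(segments, prefix = "seg")
  if (length(segments) == 0L)
    return(list(representatives = character(0),
                membership = data.frame(segment = character(0),
                                        representative = character(0),
                                        stringsAsFactors = FALSE)))
  o <- order(-nchar(segments), names(segments))
  segments <- segments[o]
  reps <- character(0)
  member_of <- character(length(segments))
  hits <- engine_map(segments, segments, min_identity = identity,
                     min_aln_len = 100L)
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  for (i in seq_along(segments)) {
    id <- names(segments)[i]
    own <- nchar(segments[[i]])
    h <- hits[hits$query_id == id & hits$subject_id %in% reps &
                (hits$qend - hits$qstart) >= min_self_cov * own, ,
              drop = FALSE]
    if (nrow(h) > 0L) {
      # first representative in founding order
      member_of[i] <- reps[min(match(h$subject_id, reps))]
    } else {
      reps <- c(reps, id)
      member_of[i] <- id
    }
  }
  list(representatives = reps,
       membership = data.frame(segment = names(segments),
                               representative = member_of,
                               stringsAsFactors = FALSE))
}

#' Aggregate classified hits into a taxon profile
#'
#' Counts and fractions at a taxonomy rank over classified sequences.
#' Groups at or below `min_display_fraction` are pooled into `"other"` in
#' the display table ("larger than" is strict); the full counts are always
#' retained in `data`.
#'
#' @param taxon_paths character vector of semicolon-delimited taxonomy
#'   strings (entries equal to `"unclassified"` are excluded).
#' @param level rank to aggregate at: index into the path or one of
#'   `"domain"`, `"phylum"`, `"class"`, `"order"`, `"family"`, `"genus"`.
#' @param min_display_fraction display floor (default 0.01).
#' @return object of class `taxon_profile`: `level`, `n_total`, `data`
#'   (taxon, count, fraction) and `display` (with pooling).
#' @export
taxon_profile <- function(taxon_paths, level = "phylum",
                          min_display_fraction = 0.01) {
  ranks <- c(domain = 1L, phylum = 2L, class = 3L, order = 4L, family = 5L,
             genus = 6L)
  lvl <- if (is.character(level)) ranks[[match.arg(level, names(ranks))]]
         else as.integer(level)
  paths <- taxon_paths[taxon_paths != "unclassified" & !is.na(taxon_paths)]
  if (length(paths) == 0L) {
    empty <- data.frame(taxon = character(0), count = integer(0),
                        fraction = numeric(0), stringsAsFactors = FALSE)
    return(structure(list(level = level, n_total = 0L, data = empty,
                          display = empty), class = "taxon_profile"))
  }
  taxa <- vapply(strsplit(paths, ";", fixed = TRUE), function(p) {
    if (length(p) >= lvl) trimws(p[[lvl]]) else "unresolved"
  }, character(1))
  tab <- sort(table(taxa), decreasing = TRUE)
  dat <- data.frame(taxon = names(tab), count = as.integer(tab),
                    fraction = as.numeric(tab) / length(taxa),
                    stringsAsFactors = FALSE)
  keep <- dat$fraction > min_display_fraction
  disp <- dat[keep, , drop = FALSE]
  if (any(!keep)) {
    disp <- rbind(disp, data.frame(taxon = "other",
                                   count = sum(dat$count[!keep]),
                                   fraction = sum(dat$fraction[!keep]),
                                   stringsAsFactors = FALSE))
  }
  rownames(disp) <- NULL
  structure(list(level = level, n_total = length(taxa), data = dat,
                 display = disp), class = "taxon_profile")
}

#' @export
print.taxon_profile <- function(x, ...) {
  cat(sprintf("<taxon_profile> rank %s, %d classified sequences\n",
              as.character(x$level), x$n_total))
  if (nrow(x$display) > 0L) {
    for (i in seq_len(nrow(x$display)))
      cat(sprintf("  %-24s %6d  %5.1f%%\n", x$display$taxon[i],
                  x$display$count[i], 100 * x$display$fraction[i]))
  }
  invisible(x)
}
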