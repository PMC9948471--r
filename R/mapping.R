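# R surface of the seed-and-extend alignment engine. All identity/length
# thresholds across the package funnel through these three functions.

# seed size: k=15 for high-identity contracts (>=90%), k=11 below
default_seed_k <- function(min_identity) if (min_identity >= 90) 15L else 11L

engine_map <- function(queries, references, min_identity, min_aln_len,
                       seed_k = NULL, max_occ = 128L, min_anchors = NULL,
                       both_strands = TRUE) {
  queries <- as_seqs(queries, prefix = "q")
  references <- as_seqs(references, prefix = "ref")
  if (length(references) == 0L) stop("empty reference set")
  if (is.null(seed_k)) seed_k <- default_seed_k(min_identity)
  if (is.null(min_anchors)) min_anchors <- if (seed_k <= 12L) 2L else 1L
  raw <- cpp_map(unname(queries), unname(references), as.integer(seed_k),
                 as.numeric(min_identity), as.integer(min_aln_len),
                 as.integer(max_occ), as.integer(min_anchors),
                 isTRUE(both_strands))
  hits <- data.frame(query_id = names(queries)[raw$query],
                     subject_id = names(references)[raw$subject],
                     qstart = raw$qstart, qend = raw$qend,
                     sstart = raw$sstart, send = raw$send,
                     strand = raw$strand, matches = raw$matches,
                     aln_len = raw$aln_len, score = raw$score,
                     stringsAsFactors = FALSE)
  hits$pident <- ifelse(hits$aln_len > 0, 100 * hits$matches / hits$aln_len, 0)
  hits
}

# deterministic best-hit selection: highest score, then higher identity,
# then lexicographically smallest subject id, then smallest subject start
select_best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$query_id, -hits$score, -hits$pident, hits$subject_id,
             hits$sstart)
  hits <- hits[o, , drop = FALSE]
  hits <- hits[!duplicated(hits$query_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Map reads against a reference set
#'
#' k-mer seeded local alignment with explicit identity/length contracts:
#' every returned alignment satisfies both `min_identity` (percent,
#' matches / alignment columns with gaps counted as columns) and
#' `min_aln_len` (alignment columns). Both strands are searched. In
#' `best_hit` mode one alignment is kept per read — highest score, ties
#' broken by higher identity, then lexicographically smallest subject id,
#' then smallest subject start — so downstream RPKG values are reproducible
#' run-to-run.
#'
#' @param reads named character vector of query sequences.
#' @param references named character vector of subject sequences (non-empty).
#' @param min_identity percent identity floor.
#' @param min_aln_len alignment-length floor in columns (thresholds are
#'   inclusive: `>=` the stated value).
#' @param mode `"best_hit"` (one alignment per read) or `"all_hits"`.
#' @param seed_k seed k-mer size; defaults to 15 for `min_identity >= 90`,
#'   11 below (seed survival > 0.999 over the stated minimum lengths).
#' @return data.frame of alignments (`query_id`, `subject_id`, `qstart`,
#'   `qend`, `sstart`, `send` 0-based half-open on the forward strands,
#'   `strand`, `matches`, `aln_len`, `score`, `pident`). Reads shorter than
#'   `min_aln_len` or without qualifying alignments are listed in
#'   `attr(, "unmapped")`.
#' @export
map_reads <- function(reads, references, min_identity = 95,
                      min_aln_len = 50, mode = c("best_hit", "all_hits"),
                      seed_k = NULL) {
  mode <- match.arg(mode)
  if (min_identity <= 0 || min_aln_len <= 0)
    stop("thresholds must be positive")
  reads <- as_seqs(reads, prefix = "read")
  references <- as_seqs(references, prefix = "ref")
  if (length(references) == 0L) stop("empty reference set")
  long_enough <- nchar(reads) >= min_aln_len
  hits <- engine_map(reads[long_enough], references, min_identity,
                     min_aln_len, seed_k = seed_k)
  if (mode == "best_hit") hits <- select_best_hits(hits)
  attr(hits, "unmapped") <- setdiff(names(reads), unique(hits$query_id))
  hits
}

#' All maximal local alignments between two sequences
#'
#' Returns every alignment meeting the thresholds, on either strand,
#' non-redundant (no alignment whose query and subject intervals are both
#' contained in another's).
#'
#' @param a,b sequences (`seq_record` or single character).
#' @param min_identity percent identity floor.
#' @param min_len alignment-length floor.
#' @param seed_k optional seed size override.
#' @return alignment data.frame as in [map_reads()] (possibly empty).
#' @export
align_pair <- function(a, b, min_identity = 95, min_len = 50,
                       seed_k = NULL) {
  sa <- as_seq(a, "a"); sb <- as_seq(b, "b")
  if (nchar(sa$seq) == 0L || nchar(sb$seq) == 0L) stop("empty sequence")
  hits <- engine_map(setNames(sa$seq, sa$id), setNames(sb$seq, sb$id),
                     min_identity, min_len, seed_k = seed_k)
  if (nrow(hits) <= 1L) return(hits)
  o <- order(-hits$score, -hits$aln_len)
  hits <- hits[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1L]) {
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if (hits$qstart[i] >= hits$qstart[j] && hits$qend[i] <= hits$qend[j] &&
          hits$sstart[i] >= hits$sstart[j] && hits$send[i] <= hits$send[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  hits <- hits[keep, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Dovetail overlap between two sequences
#'
#' Reports a suffix-onto-prefix overlap (either strand) meeting the identity
#' and length thresholds, tolerating at most `max_overhang` unaligned bases
#' at the joined ends; `NULL` when no qualifying overlap exists (absence is
#' a value, not an error).
#'
#' @param a,b sequences, each at least `min_len` long.
#' @param min_identity percent identity floor.
#' @param min_len minimum overlap length in alignment columns.
#' @param max_overhang unaligned bases tolerated at the joined ends.
#' @return `NULL`, or a list with `type` (one of `"a_suffix_b_prefix"`,
#'   `"a_prefix_b_suffix"`, `"a_suffix_b_suffix"`, `"a_prefix_b_prefix"`;
#'   the last two imply the partner must be flipped when merging),
#'   `strand`, and `alignment` (one-row data.frame).
#' @export
end_overlap <- function(a, b, min_identity = 99, min_len = 1000,
                        max_overhang = 20L) {
  sa <- as_seq(a, "a"); sb <- as_seq(b, "b")
  la <- nchar(sa$seq); lb <- nchar(sb$seq)
  if (la < min_len || lb < min_len) return(NULL)
  hits <- align_pair(sa$seq, sb$seq, min_identity, min_len)
  if (nrow(hits) == 0L) return(NULL)
  ov <- max_overhang
  type <- rep(NA_character_, nrow(hits))
  plus <- hits$strand == "+"
  type[plus & hits$qend >= la - ov & hits$sstart <= ov &
         hits$qstart > ov] <- "a_suffix_b_prefix"
  type[plus & hits$qstart <= ov & hits$send >= lb - ov &
         hits$qend < la - ov] <- "a_prefix_b_suffix"
  # full containment counts as an overlap from either end; classify by size
  full <- plus & hits$qstart <= ov & hits$qend >= la - ov
  type[full] <- "a_suffix_b_prefix"
  minus <- hits$strand == "-"
  type[minus & hits$qend >= la - ov & hits$send >= lb - ov] <-
    "a_suffix_b_suffix"
  type[minus & hits$qstart <= ov & hits$sstart <= ov] <- "a_prefix_b_prefix"
  cand <- which(!is.na(type))
  if (length(cand) == 0L) return(NULL)
  best <- cand[which.max(hits$score[cand])]
  list(type = type[best], strand = hits$strand[best],
       alignment = hits[best, , drop = FALSE])
}
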