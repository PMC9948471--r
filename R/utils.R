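# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of sequences (A/C/G/T/N, case preserved as
#'   upper case in the output).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    r <- chartr("ACGTNacgtn", "TGCANTGCAN", s)
    paste(rev(strsplit(r, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# substitute a different random base at each 1-based position in `pos`
mutate_sites <- function(seq, pos) {
  if (length(pos) == 0L) return(seq)
  r <- charToRaw(seq)
  bases <- charToRaw("ACGT")
  cur <- match(r[pos], bases)
  shift <- sample.int(3L, length(pos), replace = TRUE)
  repl <- bases[((cur - 1L + shift) %% 4L) + 1L]
  # positions holding ambiguity codes are left untouched
  ok <- !is.na(cur)
  r[pos[ok]] <- repl[ok]
  rawToChar(r)
}

# coerce seq_record / named character scalar to list(id=, seq=)
as_seq <- function(x, default_id = "seq") {
  if (inherits(x, "seq_record")) return(list(id = x$id, seq = x$seq))
  if (is.character(x) && length(x) == 1L) {
    id <- if (!is.null(names(x))) names(x) else default_id
    return(list(id = id, seq = unname(x)))
  }
  stop("expected a seq_record or a single character sequence")
}

# coerce a collection of sequences to a named character vector
as_seqs <- function(x, prefix = "seq") {
  if (length(x) == 0L) return(setNames(character(0), character(0)))
  if (inherits(x, "seq_record")) x <- list(x)
  if (is.list(x)) {
    seqs <- vapply(x, function(e) {
      if (inherits(e, "seq_record")) e$seq else as.character(e)
    }, character(1))
    ids <- vapply(seq_along(x), function(i) {
      e <- x[[i]]
      if (inherits(e, "seq_record")) e$id
      else if (!is.null(names(x)) && nzchar(names(x)[i])) names(x)[i]
      else paste0(prefix, i)
    }, character(1))
    names(seqs) <- ids
    return(seqs)
  }
  stopifnot(is.character(x))
  if (is.null(names(x))) names(x) <- paste0(prefix, seq_along(x))
  x
}

gc_fraction <- function(seq) {
  s <- Biostrings::DNAStringSet(seq)
  f <- Biostrings::letterFrequency(s, letters = c("A", "C", "G", "T"))
  tot <- rowSums(f)
  ifelse(tot > 0, (f[, "C"] + f[, "G"]) / tot, NA_real_)
}

# merge 0-based half-open intervals; returns total covered length
covered_length <- function(start, end) {
  if (length(start) == 0L) return(0L)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  tot <- 0L; cs <- start[1L]; ce <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= ce) ce <- max(ce, end[i])
    else { tot <- tot + (ce - cs); cs <- start[i]; ce <- end[i] }
  }
  tot + (ce - cs)
}
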