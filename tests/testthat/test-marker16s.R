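make_refs <- function() metalag:::demo_marker_refs()

test_that("marker candidates are gated by expectation value", {
  refs <- make_refs()
  host <- random_dna(8000, seed = 21)
  read_plus <- paste0(substr(host, 1, 3000), refs$seqs[[1]],
                      substr(host, 3001, 6000))
  cand <- find_marker_candidates(c(rp = read_plus), refs)
  expect_identical(nrow(cand), 1L)
  expect_lt(cand$evalue, 1e-50)
  expect_identical(cand$best_ref, names(refs$seqs)[1])
  expect_identical(cand$segment, unname(refs$seqs[[1]]))
  # minus strand: segment is reverse-complemented to reference orientation
  read_minus <- paste0(substr(host, 1, 3000), revcomp(refs$seqs[[2]]),
                       substr(host, 3001, 6000))
  cm <- find_marker_candidates(c(rm = read_minus), refs)
  expect_identical(cm$strand, "-")
  expect_identical(cm$segment, unname(refs$seqs[[2]]))
  # random short reads yield no candidate at E < 1e-5
  rnd <- setNames(vapply(1:100, function(i) random_dna(150), ""),
                  paste0("r", 1:100))
  expect_identical(nrow(metalag:::with_seed(5,
    find_marker_candidates(rnd, refs))), 0L)
  expect_error(find_marker_candidates(c(a = host), "not refs"))
})

test_that("diverged markers are still detected", {
  refs <- make_refs()
  g <- generate_genome(genome_spec("g", 30000, 0.5, 41,
                                   marker_template = refs$seqs[[3]],
                                   marker_divergence = 0.1),
                       rng_seed = 6)
  cand <- find_marker_candidates(c(g = g$seq), refs)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$best_ref, names(refs$seqs)[3])
  expect_gt(cand$pident, 85)
})

test_that("validation requires reference-model coverage", {
  refs <- make_refs()
  full <- paste0(random_dna(500, seed = 31), refs$seqs[[1]],
                 random_dna(500, seed = 32))
  frag <- paste0(random_dna(500, seed = 33),
                 substr(refs$seqs[[1]], 1, 90),
                 random_dna(500, seed = 34))
  cand <- find_marker_candidates(c(full = full, frag = frag), refs)
  v <- validate_marker(cand, refs, 0.5)
  expect_identical(setNames(v, cand$source_id),
                   c(frag = FALSE, full = TRUE)[cand$source_id])
  expect_true(all(validate_marker(cand, refs, 0)))
})

test_that("classification gates follow read class and are monotone", {
  refs <- make_refs()
  mk <- function(pident, aln_len, seg_len) {
    data.frame(source_id = "s", best_ref = names(refs$seqs)[1],
               start = 0L, end = seg_len, strand = "+", pident = pident,
               aln_len = aln_len, score = 100, evalue = 1e-30,
               ref_start = 0L, ref_end = aln_len,
               segment = strrep("A", seg_len), stringsAsFactors = FALSE)
  }
  tax1 <- unname(refs$taxonomy[1])
  expect_identical(classify_marker(mk(85, 120, 120), refs, "short"), tax1)
  expect_identical(classify_marker(mk(85, 60, 60), refs, "short"),
                   "unclassified")
  expect_identical(classify_marker(mk(79, 120, 120), refs, "short"),
                   "unclassified")
  expect_identical(classify_marker(mk(85, 800, 800), refs, "long"),
                   "unclassified")
  expect_identical(classify_marker(mk(85, 1200, 1200), refs, "long"), tax1)
  # monotone in identity: raising identity never declassifies
  for (pid in seq(80, 100, by = 5)) {
    cur <- classify_marker(mk(pid, 120, 120), refs, "short")
    expect_identical(cur, tax1)
  }
})

test_that("greedy dereplication matches a brute-force membership check", {
  g <- generate_genome(genome_spec("m", 1500, 0.5, 2), rng_seed = 1)
  copies <- diversify_population(g, 5, 0.005, rng_seed = 2)
  segs <- setNames(vapply(copies, `[[`, character(1), "seq"),
                   vapply(copies, `[[`, character(1), "id"))
  dr <- dereplicate_markers(segs)
  expect_identical(length(dr$representatives), 1L)
  expect_identical(nrow(dr$membership), 5L)
  # two markers at ~90% identity stay apart
  far <- metalag:::with_seed(5, metalag:::mutate_sites(g$seq,
                                                       sample(1500, 150)))
  dr2 <- dereplicate_markers(c(a = unname(segs[1]), b = far))
  expect_identical(length(dr2$representatives), 2L)
  # brute force: every member is >= 97% identical to its representative
  for (i in seq_len(nrow(dr$membership))) {
    m <- dr$membership[i, ]
    if (m$segment == m$representative) next
    hit <- align_pair(segs[[m$segment]], segs[[m$representative]], 97, 100)
    expect_gt(nrow(hit), 0)
    expect_gte(max(hit$pident), 97)
  }
  # empty input
  empty <- dereplicate_markers(character(0))
  expect_identical(length(empty$representatives), 0L)
})

test_that("taxon profiles tally, pool and respect the strict display floor", {
  paths <- c(rep("Bacteria;PhyA;c", 60), rep("Bacteria;PhyB;c", 40))
  tp <- taxon_profile(paths, "phylum")
  expect_identical(tp$n_total, 100L)
  expect_identical(tp$data$fraction[tp$data$taxon == "PhyA"], 0.6)
  expect_identical(tp$data$fraction[tp$data$taxon == "PhyB"], 0.4)
  # boundary: exactly 1% is NOT larger than 1% -> pooled in display
  paths2 <- c(rep("Bacteria;PhyA;c", 99), "Bacteria;PhyB;c")
  tp2 <- taxon_profile(paths2, "phylum", min_display_fraction = 0.01)
  expect_false("PhyB" %in% tp2$display$taxon)
  expect_true("other" %in% tp2$display$taxon)
  expect_true("PhyB" %in% tp2$data$taxon)
  # no classified hits
  tp3 <- taxon_profile(rep("unclassified", 5))
  expect_identical(tp3$n_total, 0L)
  expect_identical(nrow(tp3$data), 0L)
})

test_that("a planted community is recovered within multinomial error", {
  refs <- make_refs()
  n <- c(120, 60, 20)
  reads <- character(0)
  for (i in 1:3) {
    host <- generate_genome(genome_spec(paste0("h", i), 4000, 0.5, 60 + i),
                            rng_seed = i)
    r <- metalag:::with_seed(70 + i, vapply(seq_len(n[i]), function(j) {
      m <- metalag:::mutate_sites(refs$seqs[[i]],
                                  sample(1500, rbinom(1, 1500, 0.02)))
      paste0(substr(host$seq, 1, 1000), m, substr(host$seq, 1001, 2000))
    }, character(1)))
    names(r) <- sprintf("p%d_%03d", i, seq_len(n[i]))
    reads <- c(reads, r)
  }
  cand <- find_marker_candidates(reads, refs)
  valid <- cand[validate_marker(cand, refs), , drop = FALSE]
  tax <- classify_marker(valid, refs, "long")
  tp <- taxon_profile(tax, "phylum")
  truth <- n / sum(n)
  for (i in 1:3) {
    phy <- sub(";.*$", "", sub("^Bacteria;", "", refs$taxonomy[i]))
    got <- tp$data$fraction[tp$data$taxon == phy]
    expect_lt(abs(got - truth[i]),
              3 * sqrt(truth[i] * (1 - truth[i]) / sum(n)) + 1e-9)
  }
})
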