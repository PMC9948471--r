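test_that("contig taxonomy consensus matches a brute-force oracle", {
  # exhaustive over all multisets of {A, B, unlabelled} up to 12 genes
  oracle <- function(a, b, u, len) {
    n <- a + b + u
    if (len < 5000 || n == 0) return("unclassified")
    winners <- character(0)
    if (a / n >= 0.5) winners <- c(winners, "A")
    if (b / n >= 0.5) winners <- c(winners, "B")
    if (length(winners) == 1) winners else "unclassified"
  }
  for (n in 0:12) for (a in 0:n) for (b in 0:(n - a)) {
    u <- n - a - b
    labels <- c(rep("A", a), rep("B", b), rep(NA_character_, u))
    expect_identical(classify_contig(labels, 10000),
                     oracle(a, b, u, 10000),
                     info = sprintf("a=%d b=%d u=%d", a, b, u))
  }
  # length gate and flagged degenerate cases
  expect_identical(classify_contig(rep("A", 10), 4000), "unclassified")
  expect_identical(classify_contig(c(rep("A", 5), rep("B", 5)), 10000),
                   "unclassified")
  expect_identical(classify_contig(character(0), 10000), "unclassified")
  # unlabelled genes can be excluded from the denominator on request
  expect_identical(classify_contig(c("A", NA, NA), 10000,
                                   count_unlabelled = FALSE), "A")
})

test_that("coverage RPKG normalisation scales with contig length", {
  g <- generate_genome(genome_spec("g", 20000, 0.5, 13), rng_seed = 1)
  reads <- metalag:::with_seed(2, {
    starts <- sample(20000 - 150, 400, replace = TRUE)
    setNames(substring(g$seq, starts + 1, starts + 150),
             sprintf("r%03d", 1:400))
  })
  whole <- c(gc = g$seq)
  halves <- c(h1 = substr(g$seq, 1, 10000), h2 = substr(g$seq, 10001, 20000))
  cov_w <- contig_coverage(whole, list(m = reads))
  cov_h <- contig_coverage(halves, list(m = reads))
  # same mapped reads over double the length -> RPKG halves
  n_w <- cov_w["gc", "m"] * 20 * (sum(nchar(reads)) / 1e9)
  n_h <- sum(cov_h[, "m"] * 10 * (sum(nchar(reads)) / 1e9))
  expect_equal(n_w, n_h, tolerance = 0.02)
  expect_equal(cov_w["gc", "m"],
               mean(cov_h[, "m"]), tolerance = 0.05 * cov_w["gc", "m"])
  expect_error(contig_coverage(c(z = ""), list(m = reads)), "zero-length")
  expect_error(contig_coverage(whole, list()), "metagenome")
})

test_that("contig binning recovers the 5-genome benchmark", {
  bench <- make_contig_benchmark(seed = 1, genome_length = 120000,
                                 reads_per_mg = 9000)
  freq <- composition_matrix(bench$contigs, k = 4)
  gc <- attr(freq, "gc")
  cov <- contig_coverage(bench$contigs, bench$metagenomes)
  tax <- classify_contigs(bench$gene_table, nchar(bench$contigs))
  bins <- bin_contigs(freq, gc, cov, tax)
  expect_gte(ari(bins$assignments$bin, bench$truth), 0.90)
  # single genome's contigs collapse to one bin
  one <- bench$truth == "g01"
  b1 <- bin_contigs(freq[one, , drop = FALSE], gc[one],
                    cov[one, , drop = FALSE], rep("P1", sum(one)))
  expect_identical(length(unique(b1$assignments$bin)), 1L)
  expect_identical(ari(b1$assignments$bin, bench$truth[one]), NaN)
})

test_that("indistinguishable genomes merge into one bin (documented mode)", {
  # same signature seed, same GC, same coverage: nothing separates them
  sp <- function(nm) genome_spec(nm, 60000, 0.5, signature_seed = 5)
  sim <- simulate_reads(
    community_spec(list(community_member(sp("t1"), 0.5),
                        community_member(sp("t2"), 0.5)), rng_seed = 3),
    read_sim_spec("short", error_rate = 0, n_reads = 4000, rng_seed = 4))
  cs <- c(fragment_genome(sim$genomes[[1]], 5000, 15000, rng_seed = 5),
          fragment_genome(sim$genomes[[2]], 5000, 15000, rng_seed = 6))
  names(cs) <- sprintf("c%02d", seq_along(cs))
  freq <- composition_matrix(cs, k = 4)
  cov <- contig_coverage(cs, list(m = sim$reads))
  bins <- bin_contigs(freq, attr(freq, "gc"), cov,
                      rep("P", length(cs)))
  expect_identical(length(unique(bins$assignments$bin)), 1L)
})

test_that("seeded read binning recovers marker-seeded populations", {
  bench <- make_read_bin_benchmark(seed = 5, n_reads = 300)
  sim <- bench$sim
  tr <- sim$truth
  rownames(tr) <- tr$read_id
  cand <- find_marker_candidates(sim$reads, bench$refs)
  valid <- cand[validate_marker(cand, bench$refs), , drop = FALSE]
  valid$taxon <- classify_marker(valid, bench$refs, "long")
  seeds <- valid$source_id[valid$taxon != "unclassified"]
  expect_gte(length(seeds), 3)
  seed_pick <- seeds[!duplicated(tr[seeds, "genome"])]
  expect_identical(length(seed_pick), 3L)
  rb <- seeded_read_binning(sim$reads, seed_pick)
  asn <- rb$assignments
  tab <- table(asn$bin, tr[asn$id, "genome"])
  rb_bins <- grep("^rbin", rownames(tab), value = TRUE)
  expect_identical(length(rb_bins), 3L)
  purity <- apply(tab[rb_bins, , drop = FALSE], 1,
                  function(r) max(r) / sum(r))
  expect_true(all(purity >= 0.80))
  # seeds from the same population merge into a single bin
  same_pop <- seeds[tr[seeds, "genome"] == tr[seeds[1], "genome"]][1:2]
  rb2 <- seeded_read_binning(sim$reads, same_pop)
  expect_identical(
    length(setdiff(unique(rb2$assignments$bin), c("unbinned", "removed"))),
    1L)
  expect_error(seeded_read_binning(sim$reads, character(0)), "seed")
})

test_that("reads matching known genomes are removed before binning", {
  bench <- make_read_bin_benchmark(seed = 7, n_reads = 200)
  sim <- bench$sim
  tr <- sim$truth
  rownames(tr) <- tr$read_id
  known <- c(p1 = sim$genomes[[1]]$seq)
  other_seed <- tr$read_id[match(c("p2", "p3"), tr$genome)]
  rb <- seeded_read_binning(sim$reads, other_seed, known_genomes = known)
  asn <- rb$assignments
  rownames(asn) <- asn$id
  p1_reads <- tr$read_id[tr$genome == "p1"]
  expect_gte(mean(asn[p1_reads, "bin"] == "removed"), 0.9)
  expect_true(all(asn[tr$read_id[tr$genome != "p1"], "bin"] != "removed"))
})

test_that("redundancy removal follows cd-hit -G 0 -aS 0.9 -c 0.99 -g 1", {
  s <- random_dna(40000, seed = 41)
  base <- substr(s, 1, 10000)
  dup <- c(a = base, b = base, c = base, d = substr(s, 25001, 35000))
  rr <- remove_redundancy(dup)
  expect_setequal(rr$kept, c("a", "d"))
  expect_identical(
    rr$membership$representative[rr$membership$read == "b"], "a")
  # two reads at ~95% identity both survive the 99% threshold
  p95 <- metalag:::with_seed(42,
    metalag:::mutate_sites(base, sample(10000, 500)))
  expect_identical(length(remove_redundancy(c(a = base, e = p95))$kept), 2L)
  # nested exact substring (50% of the longer) is removed: -aS applies to
  # the shorter sequence
  nested <- c(long = base, short = substr(base, 2001, 7000))
  rrn <- remove_redundancy(nested)
  expect_identical(rrn$kept, "long")
  # idempotence
  again <- remove_redundancy(dup[rr$kept])
  expect_setequal(again$kept, rr$kept)
})

test_that("scaffolding merges unambiguous tilings and stops at forks", {
  g <- generate_genome(genome_spec("g", 40000, 0.5, 8), rng_seed = 3)
  s <- g$seq
  tiling <- c(r1 = substr(s, 1, 8000), r2 = substr(s, 6001, 14000),
              r3 = substr(s, 12001, 20000))
  sc <- scaffold_bin(tiling)
  expect_identical(length(sc$fragments), 1L)
  # expected length = span of the union of the truth intervals
  expect_identical(nchar(sc$fragments[[1]]), 20000L)
  expect_identical(unname(sc$fragments[[1]]), substr(s, 1, 20000))
  expect_setequal(sc$members[[1]], c("r1", "r2", "r3"))
  # orientation handling: a reverse-complemented middle read still merges
  tiling_rc <- tiling
  tiling_rc["r2"] <- revcomp(tiling["r2"])
  sc_rc <- scaffold_bin(tiling_rc)
  expect_identical(nchar(sc_rc$fragments[[1]]), 20000L)
  # fork between incompatible extensions: no merge across the fork
  fork <- c(a = substr(s, 1, 8000), b = substr(s, 6001, 14000),
            b2 = paste0(substr(s, 6001, 13000),
                        revcomp(substr(s, 30001, 31000))))
  expect_identical(length(scaffold_bin(fork)$fragments), 3L)
  # reads with no qualifying overlaps are returned unchanged
  lone <- c(x = substr(s, 1, 5000), y = substr(s, 20001, 25000))
  expect_identical(scaffold_bin(lone)$fragments, lone)
})

test_that("bin summaries reproduce the worked statistics", {
  m1 <- strrep(c("AT", "GC"), c(1500, 1000))   # 5 kb at GC 0.40
  m2 <- strrep(c("AT", "GC"), c(1250, 1250))   # 5 kb at GC 0.50
  seqs <- c(c1 = paste0(m1[1], m1[2]), c2 = paste0(m2[1], m2[2]))
  genes <- data.frame(contig_id = c("c1", "c1"), start = c(0L, 1000L),
                      end = c(500L, 1600L), marker = NA)
  bs <- bin_summary(seqs, genes)
  expect_identical(bs$total_size, 10000L)
  expect_equal(bs$gc_mean, 45)
  expect_equal(bs$gc_sd, sd(c(40, 50)), tolerance = 1e-9)  # 7.071
  expect_identical(bs$n_genes, 2L)
  expect_equal(bs$mean_gene_size, 550)
  # zero genes: count 0, undefined mean size reported as missing
  bs0 <- bin_summary(seqs, genes[0, ])
  expect_identical(bs0$n_genes, 0L)
  expect_true(is.na(bs0$mean_gene_size))
  expect_error(bin_summary(character(0)), "empty bin")
})
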