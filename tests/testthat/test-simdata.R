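test_that("generated genomes hit the requested length and GC", {
  for (gc in c(0.30, 0.50, 0.70)) {
    g <- generate_genome(genome_spec("g", 100000, gc_target = gc,
                                     signature_seed = round(100 * gc)),
                         rng_seed = 1)
    expect_identical(nchar(g$seq), 100000L)
    realized <- metalag:::gc_fraction(g$seq)
    expect_lt(abs(realized - gc), 0.01)
    expect_true(grepl("^[ACGT]+$", g$seq))
  }
})

test_that("genome generation is deterministic and validates its inputs", {
  sp <- genome_spec("g", 2000, gc_target = 0.5, signature_seed = 7)
  a <- generate_genome(sp, rng_seed = 3)
  b <- generate_genome(sp, rng_seed = 3)
  expect_identical(a$seq, b$seq)
  expect_false(identical(a$seq, generate_genome(sp, rng_seed = 4)$seq))
  expect_error(genome_spec("g", 0), "positive")
  expect_error(genome_spec("g", 1000, gc_target = 0.9), "gc_target")
  expect_error(genome_spec("g", 1000, marker_divergence = 0.5),
               "marker_divergence")
})

test_that("embedded markers occur once at the recorded position and strand", {
  marker <- random_dna(1500, seed = 11)
  for (seed in 1:5) {
    g <- generate_genome(genome_spec("g", 60000, signature_seed = seed,
                                     marker_template = marker,
                                     marker_divergence = 0),
                         rng_seed = seed)
    expect_identical(nchar(g$seq), 60000L)
    emb <- substr(g$seq, g$marker$start + 1, g$marker$end)
    if (g$marker$strand == "-") emb <- revcomp(emb)
    expect_identical(emb, marker)
  }
})

test_that("population divergence follows the binomial substitution model", {
  g <- generate_genome(genome_spec("g", 100000, signature_seed = 2),
                       rng_seed = 2)
  # zero rate: identical copies
  same <- diversify_population(g, 3, 0, rng_seed = 1)
  for (s in same) expect_identical(s$seq, g$seq)
  # 2% rate: per-strain identity 98% within 3 binomial SDs
  st <- diversify_population(g, 4, 0.02, rng_seed = 1)
  se3 <- 3 * sqrt(0.02 * 0.98 / 100000)
  pr <- charToRaw(g$seq)
  divs <- vapply(st, function(s) mean(charToRaw(s$seq) != pr), numeric(1))
  expect_true(all(abs(divs - 0.02) < se3))
  # strain-vs-strain divergence ~ 2d (independent mutations rarely collide)
  d12 <- mean(charToRaw(st[[1]]$seq) != charToRaw(st[[2]]$seq))
  expect_lt(abs(d12 - 2 * 0.02), 6 * sqrt(0.04 * 0.96 / 100000))
  expect_error(diversify_population(g, 0, 0.01), "n_strains")
  expect_error(diversify_population(g, 2, 0.2), "divergence")
})

test_that("read counts recover abundance x length weighting", {
  specs <- list(genome_spec("gA", 80000, 0.45, 11),
                genome_spec("gB", 80000, 0.55, 22))
  comm <- community_spec(list(community_member(specs[[1]], 0.8),
                              community_member(specs[[2]], 0.2)),
                         rng_seed = 5)
  sim <- simulate_reads(comm, read_sim_spec("long", mean_length = 6000,
                                            length_sd = 1500,
                                            min_length = 2000,
                                            error_rate = 0, n_reads = 4000,
                                            rng_seed = 9))
  frac <- mean(sim$truth$genome == "gA")
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / 4000))
})

test_that("error-free reads are exact substrings of their source strain", {
  comm <- community_spec(list(
    community_member(genome_spec("gA", 50000, 0.5, 3), 0.6,
                     population_divergence = 0.02, n_strains = 3),
    community_member(genome_spec("gB", 50000, 0.5, 4), 0.4)), rng_seed = 2)
  sim <- simulate_reads(comm, read_sim_spec("long", mean_length = 4000,
                                            length_sd = 800,
                                            min_length = 1500,
                                            error_rate = 0, n_reads = 60,
                                            rng_seed = 3))
  ids <- vapply(sim$genomes, `[[`, character(1), "id")
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    strain <- sim$strains[[match(tr$genome, ids)]][[tr$strain]]$seq
    sub <- substr(strain, tr$start + 1, tr$end)
    if (tr$strand == "-") sub <- revcomp(sub)
    expect_identical(unname(sim$reads[tr$read_id]), sub)
  }
})

test_that("reads from circular genomes wrap through the origin", {
  comm <- community_spec(list(community_member(
    genome_spec("gc", 8000, 0.5, 6, circular = TRUE), 1)), rng_seed = 7)
  sim <- simulate_reads(comm, read_sim_spec("long", mean_length = 3000,
                                            length_sd = 500,
                                            min_length = 1500,
                                            error_rate = 0, n_reads = 200,
                                            rng_seed = 8))
  gseq <- sim$strains[[1]][[1]]$seq
  wrapped <- sim$truth[sim$truth$end > nchar(gseq), ]
  expect_gt(nrow(wrapped), 0)
  for (i in seq_len(nrow(wrapped))) {
    tr <- wrapped[i, ]
    sub <- paste0(substr(gseq, tr$start + 1, nchar(gseq)),
                  substr(gseq, 1, tr$end - nchar(gseq)))
    if (tr$strand == "-") sub <- revcomp(sub)
    expect_identical(unname(sim$reads[tr$read_id]), sub)
  }
})

test_that("short mode emits pairs and the truth table is complete", {
  comm <- community_spec(list(community_member(
    genome_spec("g", 30000, 0.5, 5), 1)), rng_seed = 1)
  sim <- simulate_reads(comm, read_sim_spec("short", error_rate = 0,
                                            n_reads = 500, rng_seed = 2))
  expect_identical(length(sim$reads), 500L)
  expect_identical(sort(names(sim$reads)), sort(sim$truth$read_id))
  expect_identical(anyDuplicated(sim$truth$read_id), 0L)
  expect_true(all(nchar(sim$reads) == 150L))
  # mates point in opposite directions
  expect_setequal(unique(sim$truth$strand), c("+", "-"))
  expect_error(read_sim_spec("long", depth = 0), "depth")
})

test_that("identical specs and seeds give byte-identical FASTA output", {
  comm <- community_spec(list(community_member(
    genome_spec("g", 20000, 0.5, 9), 1)), rng_seed = 4)
  rs <- read_sim_spec("long", mean_length = 3000, length_sd = 500,
                      min_length = 1000, error_rate = 0.01, n_reads = 50,
                      rng_seed = 5)
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  write_fasta(simulate_reads(comm, rs)$reads, f1)
  write_fasta(simulate_reads(comm, rs)$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("fragment_genome tiles the genome exactly", {
  g <- generate_genome(genome_spec("g", 40000, 0.5, 2), rng_seed = 1)
  cs <- fragment_genome(g, 5000, 15000, rng_seed = 2)
  iv <- attr(cs, "intervals")
  expect_identical(paste(cs, collapse = ""), g$seq)
  expect_true(all(nchar(cs) >= 5000))
  expect_identical(iv$end[nrow(iv)], 40000L)
})
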