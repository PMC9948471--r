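# construct a read set whose best-hit count and covered span are known
tiled_reads <- function(genome, from, to, n, len = 150) {
  starts <- floor(seq(from, to - len, length.out = n))
  setNames(substring(genome, starts + 1, starts + len),
           sprintf("t%04d", seq_len(n)))
}

test_that("RPKG follows its formula exactly", {
  g <- generate_genome(genome_spec("g", 10000, 0.5, 1), rng_seed = 1)
  reads <- tiled_reads(g$seq, 0, 10000, 100)
  # 100 best-hit reads, 10 kb genome, 1 Gb metagenome -> RPKG 10 exactly
  p <- recruit(g, reads, 95, 50, metagenome_gb = 1)
  expect_identical(p$n_reads, 100L)
  expect_identical(p$rpkg, 10)
  # doubling genome length halves RPKG at the same mapped count
  g2 <- paste0(g$seq, generate_genome(genome_spec("pad", 10000, 0.5, 99),
                                      rng_seed = 2)$seq)
  p2 <- recruit(c(g2 = g2), reads, 95, 50, metagenome_gb = 1)
  expect_identical(p2$n_reads, 100L)
  expect_identical(p2$rpkg, 5)
  # no reads mapped -> 0
  p0 <- recruit(g, setNames(random_dna(150, seed = 3), "x"), 95, 50,
                metagenome_gb = 1)
  expect_identical(p0$rpkg, 0)
})

test_that("presence needs both the RPKG floor and the breadth floor", {
  g <- generate_genome(genome_spec("g", 10000, 0.5, 4), rng_seed = 1)
  # breadth is set by the tiled span, rpkg by the metagenome size
  cases <- expand.grid(rpkg = c(2.9, 3.0), breadth = c(0.69, 0.70))
  for (i in seq_len(nrow(cases))) {
    want_rpkg <- cases$rpkg[i]
    want_breadth <- cases$breadth[i]
    n <- 300
    reads <- tiled_reads(g$seq, 0, 10000 * want_breadth, n)
    gb <- n / (10 * want_rpkg)
    p <- recruit(g, reads, 95, 50, metagenome_gb = gb)
    expect_equal(p$rpkg, want_rpkg, tolerance = 1e-9)
    expect_equal(p$breadth, want_breadth, tolerance = 2e-3)
    expect_identical(p$present, want_rpkg >= 3 && p$breadth >= 0.7)
  }
  # high RPKG but reads piled on one half -> absent
  half <- recruit(g, tiled_reads(g$seq, 0, 5000, 500), 95, 50,
                  metagenome_gb = 1)
  expect_gt(half$rpkg, 3)
  expect_lt(half$breadth, 0.7)
  expect_false(half$present)
})

test_that("rRNA masking excludes intervals from length and breadth", {
  g <- generate_genome(genome_spec("g", 20000, 0.5, 5), rng_seed = 2)
  mask <- data.frame(start = 5000L, end = 10000L)
  reads <- tiled_reads(g$seq, 10000, 20000, 200)
  p <- recruit(g, reads, 95, 50, mask = mask, metagenome_gb = 1)
  # unmasked length is 15 kb; reads cover 10 of those 15 kb
  expect_identical(p$rpkg, 200 / 15)
  expect_equal(p$breadth, 10000 / 15000, tolerance = 2e-3)
  # reads inside the mask no longer map
  masked_reads <- tiled_reads(g$seq, 5000, 10000, 50)
  pm <- recruit(g, masked_reads, 95, 50, mask = mask, metagenome_gb = 1)
  expect_identical(pm$n_reads, 0L)
  expect_error(recruit(g, reads, mask = data.frame(start = 0, end = 20000)),
               "masked")
})

test_that("ANIr averages read identities at the 80/50 gate", {
  g <- generate_genome(genome_spec("g", 30000, 0.5, 6), rng_seed = 3)
  # error-free reads from the reference itself
  exact <- tiled_reads(g$seq, 0, 30000, 100, len = 1000)
  expect_identical(anir(g, exact), 100)
  # mixed 50/50 at 100% and ~96%: mean ~98
  mut <- metalag:::with_seed(7, vapply(seq(0, 14000, by = 1000), function(s) {
    r <- substr(g$seq, s + 1, s + 1000)
    metalag:::mutate_sites(r, sample(1000, 40))
  }, character(1)))
  names(mut) <- sprintf("m%02d", seq_along(mut))
  mixed <- c(exact[1:15], mut[1:15])
  a <- anir(g, mixed)
  expect_lt(abs(a - 98), 0.3)
  # no passing reads -> missing value, not an error
  expect_true(is.na(anir(g, setNames(random_dna(500, seed = 8), "x"))))
})

test_that("fragment ANI is exact on self and tracks known divergence", {
  g <- generate_genome(genome_spec("g", 60000, 0.5, 3), rng_seed = 1)
  self <- ani(g, g)
  expect_identical(self$ani, 100)
  expect_identical(self$aligned_fraction, 1)
  m5 <- metalag:::with_seed(4,
    metalag:::mutate_sites(g$seq, sample(60000, rbinom(1, 60000, 0.05))))
  a5 <- ani(g$seq, m5)
  expect_lt(abs(a5$ani - 95), 0.3)
  # symmetric within 0.3 points
  f <- ani(g$seq, m5, symmetric = FALSE)
  r <- ani(m5, g$seq, symmetric = FALSE)
  expect_lt(abs(f$ani - r$ani), 0.3)
  # unrelated genomes: missing, no fragments retained
  u <- generate_genome(genome_spec("u", 60000, 0.5, 77), rng_seed = 2)
  au <- ani(g, u)
  expect_true(is.na(au$ani))
  expect_identical(au$n_retained, 0L)
})

test_that("genome dereplication clusters at the species boundary", {
  g <- generate_genome(genome_spec("g", 50000, 0.5, 9), rng_seed = 1)
  strains <- diversify_population(g, 3, 0.01, rng_seed = 2)
  gen <- setNames(vapply(strains, `[[`, character(1), "seq"),
                  vapply(strains, `[[`, character(1), "id"))
  far <- metalag:::with_seed(3,
    metalag:::mutate_sites(g$seq, sample(50000, 5000)))   # ~90% ANI
  dr <- dereplicate_genomes(c(gen, far = far))
  expect_identical(length(dr$representatives), 2L)
  expect_true("far" %in% dr$representatives)
  single <- dereplicate_genomes(c(g = g$seq))
  expect_identical(single$representatives, "g")
})

test_that("AAI network computes RBH statistics and drops weak edges", {
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  mkpep <- function(n, len = 150) vapply(seq_len(n), function(i)
    paste(sample(aas, len, replace = TRUE), collapse = ""), character(1))
  peps <- metalag:::with_seed(9, {
    shared <- mkpep(10)
    list(A = setNames(c(shared, mkpep(10)), paste0("a", 1:20)),
         B = setNames(c(shared, mkpep(10)), paste0("b", 1:20)),
         C = setNames(mkpep(20), paste0("c", 1:20)))
  })
  # identical proteomes: AAI 100, OF 1
  selfnet <- aai_network(list(X = peps$A, Y = peps$A))
  expect_identical(selfnet$aai, 100)
  expect_identical(selfnet$of, 1)
  net <- aai_network(peps)
  # half-shared proteomes: OF ~ 0.5, AAI ~ 100 over the shared set
  ab <- net[net$genome_a == "A" & net$genome_b == "B", ]
  expect_identical(nrow(ab), 1L)
  expect_equal(ab$of, 0.5, tolerance = 0.1)
  expect_gt(ab$aai, 95)
  # unrelated random peptides: no edge
  expect_false(any(net$genome_b == "C" | net$genome_a == "C"))
  # deterministic
  expect_identical(net, aai_network(peps))
  expect_warning(aai_network(list(A = peps$A, E = character(0),
                                  B = peps$B)), "empty proteome")
})

test_that("the recruitment matrix sweeps identities and metagenomes", {
  gA <- genome_spec("gA", 30000, 0.45, 12)
  gB <- genome_spec("gB", 30000, 0.55, 13)
  mk <- function(ab, seed) simulate_reads(
    community_spec(list(community_member(gA, ab),
                        community_member(gB, 1 - ab)), rng_seed = 1),
    read_sim_spec("short", error_rate = 0, n_reads = 3000,
                  rng_seed = seed))$reads
  sim0 <- simulate_reads(
    community_spec(list(community_member(gA, .5), community_member(gB, .5)),
                   rng_seed = 1),
    read_sim_spec("long", n_reads = 1, rng_seed = 9))
  genomes <- metalag:::as_seqs(sim0$genomes)
  mgs <- list(m1 = mk(0.999, 2), m2 = mk(0.001, 3))
  rec <- recruitment_matrix(genomes, mgs, identity_levels = c(95, 70))
  expect_identical(nrow(rec), 8L)
  r95 <- rec[rec$identity == 95, ]
  expect_true(r95$present[r95$genome_id == "gA" & r95$metagenome_id == "m1"])
  expect_false(r95$present[r95$genome_id == "gA" & r95$metagenome_id == "m2"])
  # lowering the identity gate never decreases the mapped-read count
  for (g in names(genomes)) for (m in names(mgs)) {
    n95 <- rec$n_reads[rec$genome_id == g & rec$metagenome_id == m &
                         rec$identity == 95]
    n70 <- rec$n_reads[rec$genome_id == g & rec$metagenome_id == m &
                         rec$identity == 70]
    expect_gte(n70, n95)
  }
  # an (effectively) empty metagenome recruits nothing
  rec0 <- recruitment_matrix(genomes,
                             list(z = setNames(random_dna(150, seed = 5),
                                               "x")))
  expect_true(all(rec0$n_reads == 0))
})
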