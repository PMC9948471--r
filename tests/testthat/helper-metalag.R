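# shared test helpers: all fixtures are generated in code

# adjusted Rand index between two labelings
ari <- function(a, b) {
  ct <- table(a, b)
  n <- sum(ct)
  si <- sum(choose(rowSums(ct), 2))
  sj <- sum(choose(colSums(ct), 2))
  sij <- sum(choose(ct, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

random_dna <- function(n, seed = NULL) {
  f <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                        collapse = "")
  if (is.null(seed)) f() else metalag:::with_seed(seed, f())
}

# five-genome differential-coverage benchmark (shared by binning tests and
# the acceptance suite): distinct signatures, GC 35-65%, three metagenomes
make_contig_benchmark <- function(seed = 1, genome_length = 150000,
                                  reads_per_mg = 12000) {
  gcs <- c(0.35, 0.45, 0.50, 0.58, 0.65)
  gspecs <- lapply(1:5, function(i)
    genome_spec(sprintf("g%02d", i), genome_length, gc_target = gcs[i],
                signature_seed = 100 + i))
  abunds <- list(c(.4, .3, .15, .1, .05), c(.05, .1, .15, .3, .4),
                 c(.2, .2, .2, .2, .2))
  mgs <- lapply(1:3, function(m) {
    mem <- lapply(1:5, function(i) community_member(gspecs[[i]],
                                                    abunds[[m]][i]))
    simulate_reads(community_spec(mem, rng_seed = seed),
                   read_sim_spec("short", error_rate = 0.001,
                                 n_reads = reads_per_mg,
                                 rng_seed = seed * 10 + m))$reads
  })
  names(mgs) <- paste0("mg", 1:3)
  sim0 <- simulate_reads(
    community_spec(lapply(1:5, function(i) community_member(gspecs[[i]], .2)),
                   rng_seed = seed),
    read_sim_spec("long", n_reads = 1, rng_seed = 99))
  genomes <- sim0$genomes
  contig_sets <- lapply(1:5, function(i)
    fragment_genome(genomes[[i]], 5000, 50000, rng_seed = seed + 20 + i))
  contigs <- do.call(c, lapply(contig_sets, function(x) {
    attr(x, "intervals") <- NULL
    x
  }))
  truth <- rep(vapply(genomes, `[[`, character(1), "id"),
               vapply(contig_sets, length, integer(1)))
  phyla <- c("P1", "P1", "P2", "P3", "P4")
  gt <- do.call(rbind, lapply(1:5, function(i)
    simulate_gene_table(contig_sets[[i]],
                        setNames(rep(phyla[i], length(contig_sets[[i]])),
                                 names(contig_sets[[i]])),
                        rng_seed = seed + 40 + i)))
  list(genomes = genomes, metagenomes = mgs, contigs = contigs,
       contig_sets = contig_sets, truth = truth, gene_table = gt)
}

# three marker-seeded populations at 2% internal divergence
make_read_bin_benchmark <- function(seed = 5, n_reads = 400) {
  refs <- metalag:::demo_marker_refs()
  gspecs <- lapply(1:3, function(i)
    genome_spec(sprintf("p%d", i), 120000,
                gc_target = c(0.42, 0.5, 0.58)[i],
                signature_seed = 300 + i, marker_template = refs$seqs[[i]],
                marker_divergence = 0.02))
  mem <- lapply(1:3, function(i)
    community_member(gspecs[[i]], c(.4, .35, .25)[i],
                     population_divergence = 0.02, n_strains = 3))
  sim <- simulate_reads(community_spec(mem, rng_seed = seed),
                        read_sim_spec("long", mean_length = 8000,
                                      length_sd = 2000, min_length = 3000,
                                      error_rate = 0.005, n_reads = n_reads,
                                      rng_seed = seed + 1))
  list(refs = refs, sim = sim)
}
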