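#' Build a pipeline run configuration
#'
#' Every threshold used by the analysis modules is a config key, with the
#' published decision-rule values as defaults. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed below.
#' @param seed master RNG seed for the run.
#' @return object of class `run_config`.
#' @export
run_config <- function(..., seed = 1L) {
  defaults <- list(
    seed = as.integer(seed),
    # community simulation
    n_genomes = 5L, genome_length = 150000L,
    gc_targets = c(0.35, 0.45, 0.50, 0.58, 0.65),
    circular_genomes = c(TRUE, FALSE, TRUE, FALSE, FALSE),
    abundances = c(0.35, 0.25, 0.2, 0.12, 0.08),
    population_divergence = 0.02, n_strains = 3L,
    long_reads = 500L, long_mean = 8000, long_sd = 2000, long_min = 3000,
    long_error = 0.005,
    short_reads_per_mg = 10000L, short_error = 0.001, n_metagenomes = 3L,
    # contig handling
    contig_min = 5000L, contig_max = 50000L,
    consensus_min_len = 5000L, consensus_min_fraction = 0.5,
    coverage_identity = 99, coverage_min_aln = 50, coverage_subsample = 20e6,
    pca_dims = 3L,
    # markers
    marker_max_evalue = 1e-5, marker_model_fraction = 0.5,
    classify_min_identity = 80, classify_min_aln_short = 90,
    classify_min_segment_long = 1000, derep_marker_identity = 97,
    display_min_fraction = 0.01,
    # read binning
    remove_identity = 97, read_bin_gate = 0.8,
    redundancy_identity = 0.99, redundancy_short_cov = 0.90,
    scaffold_identity = 99, scaffold_overlap = 1000,
    # recruitment
    recruit_identity = 95, recruit_min_aln = 50, recruit_levels = c(95, 70),
    min_rpkg = 3, min_breadth = 0.7, anir_identity = 80, anir_min_aln = 50,
    # qc
    circ_identity = 95, circ_end_aln = 250,
    qc_min_completeness = 40, qc_max_contamination = 5,
    n_markers = 43L,
    # aai network
    aai_min_of = 0.25, aai_min_aai = 30)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(over)) defaults[[k]] <- over[[k]]
  if (any(unlist(defaults[c("coverage_identity", "recruit_identity",
                            "anir_identity", "circ_identity")]) <= 0))
    stop("identity thresholds must be positive")
  if (abs(sum(defaults$abundances) - 1) > 1e-9)
    stop("abundances must sum to 1")
  structure(defaults, class = "run_config")
}

# deterministic synthetic marker reference set with taxonomy strings
demo_marker_refs <- function(n = 6L, len = 1500L, seed = 424242L) {
  phyla <- c("PhylumA", "PhylumB", "PhylumC", "PhylumD", "PhylumE",
             "PhylumF")[seq_len(n)]
  seqs <- with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1)))
  names(seqs) <- sprintf("ref16S_%02d", seq_len(n))
  marker_ref_set(seqs, paste0("Bacteria;", phyla, ";ClassX;OrderY"))
}

#' Run the full analysis pipeline on a simulated community
#'
#' Stages, in dependency order: simulate (genomes, strains, short-read
#' metagenomes with differential abundance, long reads), profile
#' (contig fragmentation + composition), classify-contigs (gene-taxonomy
#' consensus), bin-contigs, markers (candidates, validation,
#' classification, dereplication, taxon profile), bin-reads (seeded),
#' scaffold (redundancy removal + overlap merging), recruit (RPKG matrix +
#' ANIr), qc (circularity, marker completeness, filtering), aai network,
#' report. Each stage's tables are written to `out_dir` along with the
#' resolved config; reruns with the same config are byte-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created; tables written as TSV).
#' @return object of class `run_report` aggregating all sections.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  seed <- config$seed
  tsv <- function(x, name) {
    write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  ## -- simulate ------------------------------------------------------------
  refs <- demo_marker_refs()
  phyla <- sub("^Bacteria;", "", refs$taxonomy)
  phyla <- vapply(strsplit(phyla, ";"), `[[`, character(1), 1L)
  gspecs <- lapply(seq_len(config$n_genomes), function(i)
    genome_spec(sprintf("genome%02d", i), config$genome_length,
                gc_target = config$gc_targets[i],
                signature_seed = seed * 100L + i,
                circular = config$circular_genomes[i],
                marker_template = refs$seqs[[i]],
                marker_divergence = 0.02))
  members <- lapply(seq_len(config$n_genomes), function(i)
    community_member(gspecs[[i]], config$abundances[i],
                     population_divergence = config$population_divergence,
                     n_strains = config$n_strains))
  comm <- community_spec(members, rng_seed = seed)
  long <- simulate_reads(comm, read_sim_spec(
    "long", mean_length = config$long_mean, length_sd = config$long_sd,
    min_length = config$long_min, error_rate = config$long_error,
    n_reads = config$long_reads, rng_seed = seed + 1L))
  mg_abund <- with_seed(seed + 2L, lapply(seq_len(config$n_metagenomes),
    function(m) {
      w <- rgamma(config$n_genomes, shape = 1)
      w / sum(w)
    }))
  metagenomes <- lapply(seq_len(config$n_metagenomes), function(m) {
    mem <- lapply(seq_len(config$n_genomes), function(i)
      community_member(gspecs[[i]], mg_abund[[m]][i],
                       population_divergence = config$population_divergence,
                       n_strains = config$n_strains))
    sim <- simulate_reads(community_spec(mem, rng_seed = seed),
                          read_sim_spec("short",
                                        error_rate = config$short_error,
                                        n_reads = config$short_reads_per_mg,
                                        rng_seed = seed + 10L + m))
    sim$reads
  })
  names(metagenomes) <- sprintf("mg%d", seq_len(config$n_metagenomes))
  genomes <- as_seqs(long$genomes)
  genome_phyla <- setNames(phyla[seq_len(config$n_genomes)], names(genomes))

  ## -- profile: contigs + composition -------------------------------------
  contig_sets <- lapply(seq_along(genomes), function(i)
    fragment_genome(setNames(genomes[i], names(genomes)[i]),
                    config$contig_min, config$contig_max,
                    rng_seed = seed + 20L + i))
  contigs <- do.call(c, lapply(contig_sets, function(x) {
    a <- attr(x, "intervals"); attr(x, "intervals") <- NULL; x
  }))
  contig_truth <- setNames(rep(names(genomes),
                               vapply(contig_sets, length, integer(1))),
                           names(contigs))
  freq <- composition_matrix(contigs, k = 4L)
  gc <- attr(freq, "gc")

  ## -- gene tables + contig classification --------------------------------
  marker_labels <- sprintf("scg%03d", seq_len(config$n_markers))
  gene_tables <- lapply(seq_along(genomes), function(i) {
    cs <- contig_sets[[i]]
    simulate_gene_table(cs, setNames(rep(genome_phyla[i], length(cs)),
                                     names(cs)),
                        markers = marker_labels,
                        rng_seed = seed + 40L + i)
  })
  gene_table <- do.call(rbind, gene_tables)
  taxonomy <- classify_contigs(gene_table, nchar(contigs),
                               min_len = config$consensus_min_len,
                               min_fraction = config$consensus_min_fraction)
  tsv(gene_table, "gene_table.tsv")
  tsv(data.frame(contig_id = names(taxonomy), taxon = unname(taxonomy)),
      "contig_taxonomy.tsv")

  ## -- coverage + contig binning -------------------------------------------
  coverage <- contig_coverage(contigs, metagenomes,
                              min_identity = config$coverage_identity,
                              min_aln = config$coverage_min_aln,
                              subsample = config$coverage_subsample)
  bins <- bin_contigs(freq, gc, coverage, taxonomy,
                      pca_dims = config$pca_dims)
  tsv(bins$assignments, "contig_bins.tsv")
  bin_ids <- setdiff(unique(bins$assignments$bin), "unbinned")
  bin_rows <- lapply(bin_ids, function(b) {
    mem <- bins$assignments$id[bins$assignments$bin == b]
    rpkg <- colMeans(coverage[mem, , drop = FALSE])
    cbind(bin = b, bin_summary(contigs[mem], gene_table, rpkg))
  })
  bin_table <- do.call(rbind, bin_rows)
  tsv(bin_table, "bin_summary.tsv")

  ## -- markers on long reads ------------------------------------------------
  cand <- find_marker_candidates(long$reads, refs,
                                 max_evalue = config$marker_max_evalue)
  valid <- cand[validate_marker(cand, refs,
                                config$marker_model_fraction), ,
                drop = FALSE]
  valid$taxon_path <- classify_marker(
    valid, refs, "long", min_identity = config$classify_min_identity,
    min_segment_long = config$classify_min_segment_long)
  profile <- taxon_profile(valid$taxon_path, "phylum",
                           config$display_min_fraction)
  segs <- setNames(valid$segment, valid$source_id)
  segs <- segs[nchar(segs) >= config$classify_min_segment_long]
  derep <- dereplicate_markers(segs, config$derep_marker_identity)
  tsv(valid[, setdiff(names(valid), "segment")], "marker_hits.tsv")
  tsv(profile$data, "taxon_profile.tsv")

  ## -- seeded read binning --------------------------------------------------
  seeds <- valid$source_id[valid$taxon_path != "unclassified"]
  read_bins <- NULL
  scaffolds <- NULL
  if (length(seeds) > 0L) {
    read_bins <- seeded_read_binning(long$reads, seeds,
                                     remove_identity = config$remove_identity,
                                     dims = config$pca_dims,
                                     gate = config$read_bin_gate)
    tsv(read_bins$assignments, "read_bins.tsv")
    first_bin <- names(sort(table(read_bins$assignments$bin[
      read_bins$assignments$bin != "unbinned"]), decreasing = TRUE))[1]
    mem <- read_bins$assignments$id[read_bins$assignments$bin == first_bin]
    nr <- remove_redundancy(long$reads[mem], config$redundancy_identity,
                            config$redundancy_short_cov)
    scaffolds <- scaffold_bin(long$reads[nr$kept],
                              config$scaffold_identity,
                              config$scaffold_overlap)
  }

  ## -- recruitment ----------------------------------------------------------
  rec <- recruitment_matrix(genomes, metagenomes,
                            identity_levels = config$recruit_levels,
                            min_aln = config$recruit_min_aln)
  anir_vals <- vapply(names(genomes), function(g)
    anir(setNames(genomes[g], g), long$reads,
         gate_identity = config$anir_identity,
         gate_aln = config$anir_min_aln), numeric(1))
  tsv(rec, "recruitment.tsv")
  tsv(data.frame(genome = names(anir_vals), anir = unname(anir_vals)),
      "anir.tsv")

  ## -- qc -------------------------------------------------------------------
  circ <- lapply(seq_along(genomes), function(i) {
    jf <- with_seed(seed + 60L + i, {
      L <- nchar(genomes[i])
      if (config$circular_genomes[i]) {
        # fragment spanning the origin (junction evidence)
        s <- L - 1500L
        setNames(paste0(substr(genomes[i], s + 1L, L),
                        substr(genomes[i], 1L, 1500L)), "junction")
      } else {
        setNames(substr(genomes[i], 5000L, 8000L), "internal")
      }
    })
    check_circular(setNames(genomes[i], names(genomes)[i]), jf,
                   config$circ_identity, config$circ_end_aln)
  })
  circ_tab <- data.frame(
    genome = names(genomes),
    verdict = vapply(circ, `[[`, character(1), "verdict"),
    truth = ifelse(config$circular_genomes[seq_along(genomes)], "circular",
                   "linear"),
    stringsAsFactors = FALSE)
  tsv(circ_tab, "circularity.tsv")
  mk <- lapply(seq_along(genomes), function(i)
    marker_completeness(gene_tables[[i]], marker_labels))
  names(mk) <- names(genomes)
  kept <- filter_genomes(mk, config$qc_min_completeness,
                         config$qc_max_contamination)
  qc_tab <- data.frame(
    genome = names(mk),
    completeness = vapply(mk, `[[`, numeric(1), "completeness"),
    contamination = vapply(mk, `[[`, numeric(1), "contamination"),
    kept = names(mk) %in% kept, stringsAsFactors = FALSE)
  tsv(qc_tab, "genome_qc.tsv")

  ## -- aai network (proteomes translated from gene calls) -------------------
  proteomes <- lapply(seq_along(genomes), function(i) {
    gt <- gene_tables[[i]]
    gt <- gt[(gt$end - gt$start) >= 300, , drop = FALSE]
    gt <- gt[seq_len(min(nrow(gt), 30L)), , drop = FALSE]
    contig_seq <- contig_sets[[i]]
    peps <- vapply(seq_len(nrow(gt)), function(r) {
      s <- substr(contig_seq[[gt$contig_id[r]]], gt$start[r] + 1L, gt$end[r])
      s <- substr(s, 1L, 3L * (nchar(s) %/% 3L))
      as.character(Biostrings::translate(Biostrings::DNAString(s),
                                         if.fuzzy.codon = "solve"))
    }, character(1))
    names(peps) <- sprintf("%s_p%03d", names(genomes)[i], seq_along(peps))
    peps
  })
  names(proteomes) <- names(genomes)
  network <- aai_network(proteomes, config$aai_min_of, config$aai_min_aai)
  tsv(attr(network, "all_pairs"), "aai_pairs.tsv")

  report <- structure(list(
    out_dir = out_dir, config = config,
    bins = bin_table, contig_bins = bins, read_bins = read_bins,
    scaffolds = scaffolds, recruitment = rec, anir = anir_vals,
    taxon_profile = profile, marker_derep = derep,
    aai_network = network, circularity = circ_tab, qc = qc_tab,
    contig_truth = contig_truth, truth = long$truth),
    class = "run_report")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  contig bins: %d (%d contigs)\n",
              length(setdiff(unique(x$contig_bins$assignments$bin),
                             "unbinned")),
              nrow(x$contig_bins$assignments)))
  if (!is.null(x$read_bins))
    cat(sprintf("  read bins: %d\n",
                length(setdiff(unique(x$read_bins$assignments$bin),
                               c("unbinned", "removed")))))
  cat(sprintf("  recruitment rows: %d; present calls: %d\n",
              nrow(x$recruitment), sum(x$recruitment$present)))
  cat(sprintf("  taxon profile: %d taxa over %d classified markers\n",
              nrow(x$taxon_profile$data), x$taxon_profile$n_total))
  cat(sprintf("  circularity: %d/%d verdicts match truth\n",
              sum(x$circularity$verdict == x$circularity$truth),
              nrow(x$circularity)))
  cat(sprintf("  outputs: %s\n", x$out_dir))
  invisible(x)
}
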