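#' End-to-end demonstration pipeline on a simulated trio
#'
#' Chains every stage of the package on one generated fixture: trio
#' simulation, k-mer counting, solid k-mer and hap-mer derivation, read
#' binning with truth-based accuracy, phasing QC of each haplotype, telomere
#' scanning (on telomere-flanked copies of the haplotypes, so the scan has
#' signal to find), diagnostic-SNP calling and hybrid read assignment,
#' allelic counting, allele pairing on a gene subset, and the expression
#' analyses (species DE, MPV additivity, mode classification, both ASE
#' methods, pathway report). Results are written as TSV/VCF/BED/FASTA files
#' plus a run manifest of checksums; rerunning with the same configuration
#' reproduces every checksum.
#'
#' @param out_dir Output directory (created; must be empty unless
#'   \code{overwrite}).
#' @param seed Top-level seed; per-stage streams derive from it.
#' @param config Optional [sim_config()] (defaults to the standard study
#'   conditions at a reduced 50 kb / 100-gene scale so the demo stays fast).
#' @param n_pair_genes Number of genes run through the built-in aligner for
#'   allele pairing (alignment is quadratic; default 20).
#' @param overwrite Overwrite an existing non-empty directory?
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_demo <- function(out_dir, seed = 1, config = NULL, n_pair_genes = 20,
                     overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("output directory exists and is non-empty; use overwrite = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config))
    config <- sim_config(genome_length = 50000, n_genes = 100, seed = seed)

  message("[1/6] simulating trio fixture")
  sim <- simulate_trio(config)
  write_fixture_bundle(sim, file.path(out_dir, "fixture"), overwrite = TRUE)

  message("[2/6] k-mer binning and phasing QC")
  k <- config$k
  solid <- lapply(list(mat = sim$maternal_reads$reads,
                       pat = sim$paternal_reads$reads,
                       hyb = sim$hybrid_reads$reads),
                  function(r) solid_kmers(count_kmers(r, k), low = 2))
  hapmers <- derive_hapmers(solid$mat, solid$pat, solid$hyb)
  bins <- bin_reads(sim$hybrid_reads$reads, hapmers)
  truth_hap <- ifelse(sim$hybrid_reads$truth$hap == "hybmat",
                      "maternal", "paternal")
  informative <- bins$labels != "ambiguous"
  bin_accuracy <- mean(bins$labels[informative] ==
                         truth_hap[match(names(bins$labels),
                                         sim$hybrid_reads$truth$read_id)][informative])
  write_tsv(bins$summary, file.path(out_dir, "binning_summary.tsv"))
  qc <- lapply(c(maternal = "maternal", paternal = "paternal"), function(h) {
    phasing_qc(sim$haplotypes[[h]], hapmers, solid$hyb, k, haplotype = h)
  })
  qc_df <- do.call(rbind, lapply(names(qc), function(h)
    data.frame(haplotype = h, recovery = qc[[h]]$hapmer_recovery,
               contamination = qc[[h]]$hapmer_contamination,
               completeness = qc[[h]]$kmer_completeness, qv = qc[[h]]$qv)))
  write_tsv(qc_df, file.path(out_dir, "phasing_qc.tsv"))

  message("[3/6] telomere scan")
  telo_seqs <- c(Hmat = paste0(strrep("TTTAGGG", 40), sim$haplotypes$maternal,
                               strrep("CCCTAAA", 40)),
                 Hpat = paste0(strrep("TTTAGGG", 40), sim$haplotypes$paternal,
                               strrep("CCCTAAA", 40)))
  telo <- find_telomere_repeats(telo_seqs)
  telo$name <- "TTTAGGG"
  telo$score <- telo$n_repeats
  write_bed6(telo, file.path(out_dir, "telomeres.bed"))

  message("[4/6] diagnostic SNPs and allelic assignment")
  vars <- sim$haplotypes$variants
  pile_mat <- simulate_pileup(sim$haplotypes$maternal, vars$pos, depth = 20)
  pile_pat <- simulate_pileup(sim$haplotypes$paternal, vars$pos, depth = 20)
  snps <- call_diagnostic_snps(pile_mat, pile_pat)
  write_vcf_minimal(snps, file.path(out_dir, "diagnostic_snps.vcf"))
  hr <- sim$hybrid_reads
  obs <- read_site_alleles(hr$reads, hr$truth, snps$pos)
  assignments <- assign_reads(obs, snps, read_ids = hr$truth$read_id)
  assignments$replicate <- rep_len(paste0("rep", seq_len(config$replicates)),
                                   nrow(assignments))
  overlaps <- read_gene_overlaps(hr$truth, sim$gene_models)
  allelic <- allelic_counts(assignments, overlaps, sim$gene_models)
  write_tsv(allelic$counts, file.path(out_dir, "allelic_counts.tsv"))
  write_tsv(allelic$summary, file.path(out_dir, "assignment_summary.tsv"))

  message("[5/6] allele pairing on a gene subset")
  sub <- head(sim$gene_models, n_pair_genes)
  gseq <- function(hap) setNames(substring(hap, sub$start + 1L, sub$end),
                                 sub$gene_id)
  seq_m <- gseq(sim$haplotypes$maternal)
  seq_p <- gseq(sim$haplotypes$paternal)
  names(seq_m) <- paste0("Hmat:", names(seq_m))
  names(seq_p) <- paste0("Hpat:", names(seq_p))
  hits <- homology_hits(seq_m, seq_p)
  models2 <- rbind(
    data.frame(gene_id = names(seq_m), haplotype = "maternal",
               rank = sub$rank, stringsAsFactors = FALSE),
    data.frame(gene_id = names(seq_p), haplotype = "paternal",
               rank = sub$rank, stringsAsFactors = FALSE))
  blocks <- collinear_blocks(hits, models2)
  og <- orthogroups(hits, models2$gene_id)
  pairs <- allele_pairs(blocks, og,
                        setNames(models2$haplotype, models2$gene_id))
  write_tsv(pairs, file.path(out_dir, "allele_pairs.tsv"))

  message("[6/6] expression analyses")
  rna <- sim$rnaseq
  sf <- size_factors(cbind(rna$parent1_counts, rna$parent2_counts,
                           rna$hybrid_counts))
  reps <- config$replicates
  de_12 <- nb_two_group_test(rna$parent1_counts, rna$parent2_counts,
                             sf[1:reps], sf[reps + 1:reps])
  de_h1 <- nb_two_group_test(rna$parent1_counts, rna$hybrid_counts,
                             sf[1:reps], sf[2 * reps + 1:reps])
  de_h2 <- nb_two_group_test(rna$parent2_counts, rna$hybrid_counts,
                             sf[reps + 1:reps], sf[2 * reps + 1:reps])
  mpv <- mpv_comparison(rna$parent1_counts, rna$parent2_counts,
                        rna$hybrid_counts, sf = sf)
  modes <- classify_mode(de_12, de_h1, de_h2)
  allelic_df <- data.frame(
    gene_id = rep(rownames(rna$hybrid_maternal), reps),
    replicate = rep(paste0("rep", seq_len(reps)),
                    each = nrow(rna$hybrid_maternal)),
    maternal_count = as.vector(rna$hybrid_maternal),
    paternal_count = as.vector(rna$hybrid_paternal),
    stringsAsFactors = FALSE)
  ase_model <- ase_model_test(allelic_df)
  tot <- colSums(rna$hybrid_maternal) + colSums(rna$hybrid_paternal)
  ase_ratio <- ase_ratio_call(
    fpkm(rna$hybrid_maternal, rna$gene_lengths, tot),
    fpkm(rna$hybrid_paternal, rna$gene_lengths, tot))
  pathways <- split(rna$truth$gene_id,
                    rep_len(c("pathway_A", "pathway_B", "pathway_C"),
                            nrow(rna$truth)))
  report <- pathway_report(modes, ase_ratio, pathways)
  write_tsv(de_12, file.path(out_dir, "de_parent1_vs_parent2.tsv"))
  write_tsv(mpv, file.path(out_dir, "mpv_additivity.tsv"))
  write_tsv(modes, file.path(out_dir, "expression_modes.tsv"))
  write_tsv(ase_model, file.path(out_dir, "ase_model_test.tsv"))
  write_tsv(ase_ratio, file.path(out_dir, "ase_ratio_call.tsv"))
  write_tsv(report$summary, file.path(out_dir, "pathway_summary.tsv"))
  write_tsv(report$categories, file.path(out_dir, "pathway_categories.tsv"))

  manifest <- run_manifest(out_dir, config)
  write_tsv(manifest, file.path(out_dir, "run_manifest.tsv"))
  invisible(list(config = config, sim = sim, hapmers = hapmers, bins = bins,
                 bin_accuracy = bin_accuracy, phasing_qc = qc,
                 telomeres = telo, snps = snps, assignments = assignments,
                 allelic = allelic, pairs = pairs, de_parent = de_12,
                 mpv = mpv, modes = modes, ase_model = ase_model,
                 ase_ratio = ase_ratio, pathway_report = report,
                 manifest = manifest))
}

#' Checksum manifest of a pipeline run
#'
#' Lists every file under a run directory with its MD5 checksum and size,
#' plus a hash of the configuration; identical configuration and inputs
#' reproduce identical manifests.
#'
#' @param dir Run directory.
#' @param config The [sim_config()] (or any serializable configuration).
#' @return data.frame: \code{file}, \code{md5}, \code{bytes}; the
#'   configuration hash is stored in attribute \code{"config_hash"} and as a
#'   pseudo-row \code{<config>}.
#' @export
run_manifest <- function(dir, config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config)), tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  files <- sort(setdiff(list.files(dir, recursive = TRUE),
                        "run_manifest.tsv"))
  out <- data.frame(file = c("<config>", files),
                    md5 = c(cfg_hash,
                            unname(tools::md5sum(file.path(dir, files)))),
                    bytes = c(NA_integer_,
                              file.size(file.path(dir, files))),
                    stringsAsFactors = FALSE)
  attr(out, "config_hash") <- cfg_hash
  out
}
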