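#' Simulation configuration for a parent-parent-hybrid trio
#'
#' Bundles every tunable of the synthetic-data generator: the two parental
#' haploid genomes (length and per-base divergence), genomic short reads
#' (coverage, length, substitution error rate), single-exon gene models, and
#' the replicated RNA-seq design with planted expression modes and allelic
#' fractions.
#'
#' The defaults describe the study conditions the package is validated under:
#' 100 kb haplotypes diverged at 4.6% (the heterozygosity regime of a highly
#' heterozygous interspecific hybrid), 21-mers, 30-fold error-free 150 bp
#' reads, and a 3-replicate RNA-seq design per group with negative-binomial
#' dispersion 0.05 and 4-fold planted expression effects.
#'
#' @param genome_length Haplotype length in bp.
#' @param divergence Per-base substitution probability between the two
#'   parental haplotypes (default 0.046).
#' @param k K-mer length, odd, >= 11 (default 21).
#' @param coverage Fold sequencing coverage per genome.
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution error rate of simulated reads.
#' @param n_genes Number of single-exon gene models.
#' @param gene_length Gene length in bp, default 400 (genes are placed non-overlapping at
#'   identical coordinates on both haplotypes).
#' @param replicates Biological replicates per expression group (default 3).
#' @param dispersion Negative-binomial dispersion phi, variance
#'   \eqn{\mu + \phi \mu^2} (default 0.05).
#' @param effect_fold Fold change used when planting parental differences and
#'   over-/underdominant deviations (default 4).
#' @param mode_proportions Named numeric vector over the expression-mode
#'   categories \code{conserved}, \code{additive}, \code{high_parent_dominance},
#'   \code{low_parent_dominance}, \code{overdominance}, \code{underdominance};
#'   must sum to 1.
#' @param ase_ratio_grid Planted maternal allelic fractions, recycled across
#'   genes in order.
#' @param seed Integer seed; every generator call derives its stream from it.
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(genome_length = 100000,
                       divergence = 0.046,
                       k = 21,
                       coverage = 30,
                       read_length = 150,
                       error_rate = 0,
                       n_genes = 200,
                       gene_length = 400,
                       replicates = 3,
                       dispersion = 0.05,
                       effect_fold = 4,
                       mode_proportions = c(conserved = 0.35,
                                            additive = 0.25,
                                            high_parent_dominance = 0.10,
                                            low_parent_dominance = 0.10,
                                            overdominance = 0.10,
                                            underdominance = 0.10),
                       ase_ratio_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                       seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              divergence = divergence, k = as.integer(k),
              coverage = coverage, read_length = as.integer(read_length),
              error_rate = error_rate, n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              replicates = as.integer(replicates),
              dispersion = dispersion, effect_fold = effect_fold,
              mode_proportions = mode_proportions,
              ase_ratio_grid = ase_ratio_grid, seed = as.integer(seed))
  if (cfg$divergence < 0 || cfg$divergence > 1)
    stop("divergence must be in [0, 1]")
  if (cfg$error_rate < 0 || cfg$error_rate > 1)
    stop("error_rate must be in [0, 1]")
  if (cfg$k %% 2L == 0L || cfg$k < 11L)
    stop("k must be odd and >= 11")
  if (cfg$genome_length < cfg$k) stop("genome too short for k")
  if (any(c(cfg$genome_length, cfg$coverage, cfg$read_length, cfg$n_genes,
            cfg$gene_length, cfg$replicates) <= 0))
    stop("all counts must be positive")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  modes <- c("conserved", "additive", "high_parent_dominance",
             "low_parent_dominance", "overdominance", "underdominance")
  if (!setequal(names(cfg$mode_proportions), modes))
    stop("mode_proportions must be named over the six expression modes")
  if (abs(sum(cfg$mode_proportions) - 1) > 1e-9)
    stop("mode_proportions must sum to 1")
  if (any(cfg$ase_ratio_grid < 0 | cfg$ase_ratio_grid > 1))
    stop("ase_ratio_grid values must be in [0, 1]")
  structure(cfg, class = "sim_config")
}

# stage-specific substream so that stages are independently reproducible
stage_seed <- function(config, stage) {
  (config$seed + sum(utf8ToInt(stage)) * 1009L) %% .Machine$integer.max
}

DNA_BASES <- c("A", "C", "G", "T")

#' Simulate two parental haplotypes from a common ancestor
#'
#' Draws a random ancestral sequence and substitutes bases independently at
#' the configured divergence; at each variant site one parent (chosen at
#' random) carries a derived allele and the other the ancestral one, so the
#' realized maternal-paternal divergence equals \code{config$divergence} up to
#' binomial sampling error. Substitution-only divergence keeps coordinates
#' shared across haplotypes, so the variant table doubles as diagnostic-SNP
#' truth.
#'
#' @param config A [sim_config()].
#' @return List with \code{maternal}, \code{paternal} (character sequences)
#'   and \code{variants}, a data.frame with 1-based \code{pos},
#'   \code{maternal} and \code{paternal} alleles.
#' @export
simulate_parental_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(stage_seed(config, "haplotypes"))
  L <- config$genome_length
  anc <- sample(DNA_BASES, L, replace = TRUE)
  mat <- pat <- anc
  is_var <- runif(L) < config$divergence
  pos <- which(is_var)
  if (length(pos)) {
    # derived allele differs from ancestral; carrier parent chosen at random
    shift <- sample(1:3, length(pos), replace = TRUE)
    derived <- DNA_BASES[(match(anc[pos], DNA_BASES) - 1L + shift) %% 4L + 1L]
    to_mat <- runif(length(pos)) < 0.5
    mat[pos[to_mat]] <- derived[to_mat]
    pat[pos[!to_mat]] <- derived[!to_mat]
  }
  variants <- data.frame(pos = pos,
                         maternal = mat[pos],
                         paternal = pat[pos],
                         stringsAsFactors = FALSE)
  list(maternal = paste(mat, collapse = ""),
       paternal = paste(pat, collapse = ""),
       variants = variants)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate labeled shotgun reads from one haplotype
#'
#' Uniform start positions on both strands at the requested fold coverage,
#' with independent per-base substitution errors. The truth table records,
#' per read, the source haplotype, 0-based half-open coordinates, strand and
#' the introduced errors (read position and original base), so a read can be
#' reconstructed exactly from the haplotype.
#'
#' @param sequence Source haplotype (character scalar).
#' @param config A [sim_config()].
#' @param label Haplotype label encoded in read identifiers (e.g. "mat").
#' @param seed Optional seed override; defaults to a label-specific stream
#'   derived from \code{config$seed}.
#' @return List with \code{reads} (named character vector, names = read ids)
#'   and \code{truth} (data.frame: read_id, hap, start, end, strand,
#'   n_errors, errors).
#' @export
simulate_reads <- function(sequence, config, label = "hap", seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$coverage <= 0) stop("coverage must be positive")
  L <- nchar(sequence)
  rl <- config$read_length
  if (L < rl) stop("sequence shorter than read_length")
  withr::local_seed(seed %||% stage_seed(config, paste0("reads:", label)))
  n <- as.integer(round(config$coverage * L / rl))
  start1 <- sample.int(L - rl + 1L, n, replace = TRUE)   # 1-based
  strand <- sample(c("+", "-"), n, replace = TRUE)
  reads <- substring(sequence, start1, start1 + rl - 1L)
  neg <- strand == "-"
  if (any(neg)) reads[neg] <- revcomp(reads[neg])
  n_err <- if (config$error_rate > 0) rbinom(n, rl, config$error_rate) else integer(n)
  err_str <- character(n)
  if (any(n_err > 0)) {
    for (i in which(n_err > 0)) {
      p <- sample.int(rl, n_err[i])
      chars <- strsplit(reads[i], "")[[1]]
      orig <- chars[p]
      chars[p] <- DNA_BASES[(match(orig, DNA_BASES) - 1L +
                               sample(1:3, n_err[i], replace = TRUE)) %% 4L + 1L]
      reads[i] <- paste(chars, collapse = "")
      err_str[i] <- paste0(p, orig, collapse = ",")
    }
  }
  ids <- sprintf("%s_read%06d", label, seq_len(n))
  names(reads) <- ids
  truth <- data.frame(read_id = ids, hap = label,
                      start = start1 - 1L, end = start1 - 1L + rl,
                      strand = strand, n_errors = n_err, errors = err_str,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Revert the simulated sequencing errors of a read
#'
#' Replaces each errored position with the original base recorded in the
#' truth table. The reverted read must equal the labeled interval of the
#' source haplotype (reverse-complemented for minus-strand reads) — the
#' round-trip consistency contract of the generator.
#' @param read The emitted read sequence.
#' @param truth_row One row of a [simulate_reads()] truth table.
#' @return Character scalar, the error-free read.
#' @export
revert_read_errors <- function(read, truth_row) {
  if (truth_row$n_errors == 0) return(read)
  chars <- strsplit(read, "")[[1]]
  for (tok in strsplit(truth_row$errors, ",")[[1]]) {
    p <- as.integer(sub("[ACGT]$", "", tok))
    chars[p] <- sub("^[0-9]+", "", tok)
  }
  paste(chars, collapse = "")
}

#' Place non-overlapping single-exon gene models
#'
#' Genes are laid out left to right with uniform spacing, on the forward
#' strand, at identical coordinates on both haplotypes (the design assumes
#' one-to-one allele pairs). Coordinates are 0-based half-open.
#'
#' @param config A [sim_config()].
#' @return data.frame: gene_id, seqid, start, end, strand, rank.
#' @export
simulate_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  gl <- config$gene_length
  pitch <- config$genome_length %/% n
  if (pitch < gl) stop("genome too short for n_genes non-overlapping genes")
  start <- (seq_len(n) - 1L) * pitch
  data.frame(gene_id = sprintf("gene%04d", seq_len(n)),
             seqid = "chr1", start = start, end = start + gl,
             strand = "+", rank = seq_len(n), stringsAsFactors = FALSE)
}

#' Simulate a replicated trio RNA-seq design with planted expression modes
#'
#' Each gene gets a planted expression-mode category (drawn from
#' \code{mode_proportions}), parental means derived from a log-normal
#' baseline, and a hybrid mean dictated by the mode: conserved and additive
#' genes sit at the mid-parent value, dominant genes at one parent's level,
#' over-/underdominant genes \code{effect_fold}-fold outside the parental
#' range. Counts are negative-binomial with variance \eqn{\mu + \phi\mu^2};
#' hybrid maternal counts are binomially thinned from the hybrid total at the
#' gene's planted maternal fraction.
#'
#' @param config A [sim_config()].
#' @param variant_aware Unused placeholder kept for interface stability;
#'   allelic truth is always planted.
#' @return List with matrices \code{parent1_counts} (maternal species),
#'   \code{parent2_counts}, \code{hybrid_counts} (totals),
#'   \code{hybrid_maternal}, \code{hybrid_paternal}, numeric
#'   \code{gene_lengths}, and \code{truth} (per-gene data.frame: mode,
#'   mu_parent1, mu_parent2, mu_hybrid, maternal_fraction).
#' @export
simulate_rnaseq_counts <- function(config, variant_aware = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (config$dispersion < 0) stop("dispersion must be >= 0")
  withr::local_seed(stage_seed(config, "rnaseq"))
  n <- config$n_genes
  reps <- config$replicates
  fold <- config$effect_fold
  modes <- sample(names(config$mode_proportions), n, replace = TRUE,
                  prob = config$mode_proportions)
  base <- rlnorm(n, meanlog = log(150), sdlog = 0.6)
  hi_is_p2 <- runif(n) < 0.5
  mu1 <- mu2 <- base
  differs <- modes != "conserved"
  mu_hi <- base * fold
  mu1[differs & !hi_is_p2] <- mu_hi[differs & !hi_is_p2]
  mu2[differs & hi_is_p2]  <- mu_hi[differs & hi_is_p2]
  mpv <- (mu1 + mu2) / 2
  muH <- mpv
  muH[modes == "conserved"] <- base[modes == "conserved"]
  muH[modes == "high_parent_dominance"] <- pmax(mu1, mu2)[modes == "high_parent_dominance"]
  muH[modes == "low_parent_dominance"]  <- pmin(mu1, mu2)[modes == "low_parent_dominance"]
  muH[modes == "overdominance"]  <- (pmax(mu1, mu2) * fold)[modes == "overdominance"]
  muH[modes == "underdominance"] <- (pmin(mu1, mu2) / fold)[modes == "underdominance"]
  frac <- rep_len(config$ase_ratio_grid, n)

  rnb <- function(mu) {
    m <- matrix(0L, n, reps)
    for (j in seq_len(reps)) {
      m[, j] <- if (config$dispersion == 0) stats::rpois(n, mu)
                else rnbinom(n, mu = mu, size = 1 / config$dispersion)
    }
    rownames(m) <- sprintf("gene%04d", seq_len(n))
    colnames(m) <- paste0("rep", seq_len(reps))
    m
  }
  p1 <- rnb(mu1)
  p2 <- rnb(mu2)
  hy <- rnb(muH)
  hm <- matrix(rbinom(n * reps, as.vector(hy), rep(frac, reps)), n, reps,
               dimnames = dimnames(hy))
  truth <- data.frame(gene_id = rownames(hy), mode = modes,
                      mu_parent1 = mu1, mu_parent2 = mu2, mu_hybrid = muH,
                      maternal_fraction = frac, stringsAsFactors = FALSE)
  list(parent1_counts = p1, parent2_counts = p2, hybrid_counts = hy,
       hybrid_maternal = hm, hybrid_paternal = hy - hm,
       gene_lengths = setNames(rep(config$gene_length, n), rownames(hy)),
       truth = truth)
}

#' Simulate a complete trio fixture
#'
#' Convenience wrapper chaining [simulate_parental_haplotypes()],
#' [simulate_reads()] for each parent and for the hybrid (which carries one
#' copy of each haplotype, so its coverage is split evenly between them),
#' [simulate_gene_models()] and [simulate_rnaseq_counts()].
#'
#' @param config A [sim_config()].
#' @return List: haplotypes (+variants), parental and hybrid genomic reads
#'   with truth, gene models, and the RNA-seq count bundle.
#' @export
simulate_trio <- function(config) {
  hap <- simulate_parental_haplotypes(config)
  half <- config
  half$coverage <- config$coverage / 2
  hyb_mat <- simulate_reads(hap$maternal, half, label = "hybmat")
  hyb_pat <- simulate_reads(hap$paternal, half, label = "hybpat")
  list(haplotypes = hap,
       maternal_reads = simulate_reads(hap$maternal, config, label = "mat"),
       paternal_reads = simulate_reads(hap$paternal, config, label = "pat"),
       hybrid_reads = list(reads = c(hyb_mat$reads, hyb_pat$reads),
                           truth = rbind(hyb_mat$truth, hyb_pat$truth)),
       gene_models = simulate_gene_models(config),
       rnaseq = simulate_rnaseq_counts(config))
}

#' Write a simulated trio to disk as a plain-text fixture bundle
#'
#' Writes FASTA haplotypes, FASTQ reads (constant quality), a GFF3 of the
#' gene models, TSV count/truth tables and a manifest of MD5 checksums.
#'
#' @param sim Result of [simulate_trio()].
#' @param dir Output directory.
#' @param overwrite Overwrite an existing non-empty directory?
#' @return data.frame manifest (file, md5, bytes), invisibly also written to
#'   \code{manifest.tsv}.
#' @export
write_fixture_bundle <- function(sim, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0 && !overwrite)
    stop("directory exists and is non-empty; use overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(c(Hmat = sim$haplotypes$maternal,
                Hpat = sim$haplotypes$paternal),
              file.path(dir, "haplotypes.fasta"))
  write_fastq(sim$maternal_reads$reads, file.path(dir, "reads_mat.fastq"))
  write_fastq(sim$paternal_reads$reads, file.path(dir, "reads_pat.fastq"))
  write_fastq(sim$hybrid_reads$reads, file.path(dir, "reads_hybrid.fastq"))
  write_gff3(sim$gene_models, file.path(dir, "genes.gff3"))
  write_tsv(sim$haplotypes$variants, file.path(dir, "variants.tsv"))
  for (nm in c("parent1_counts", "parent2_counts", "hybrid_counts",
               "hybrid_maternal", "hybrid_paternal")) {
    df <- data.frame(gene_id = rownames(sim$rnaseq[[nm]]),
                     sim$rnaseq[[nm]], check.names = FALSE)
    write_tsv(df, file.path(dir, paste0(nm, ".tsv")))
  }
  write_tsv(sim$rnaseq$truth, file.path(dir, "truth_genes.tsv"))
  write_tsv(rbind(sim$maternal_reads$truth, sim$paternal_reads$truth,
                  sim$hybrid_reads$truth),
            file.path(dir, "truth_reads.tsv"))
  files <- sort(setdiff(dir(dir), "manifest.tsv"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))),
                         bytes = file.size(file.path(dir, files)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(dir, "manifest.tsv"))
  manifest
}
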