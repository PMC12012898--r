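#' Simulate a pileup table from a known sequence
#'
#' Builds per-position base counts as an aligner + pileup step would produce
#' for a homozygous sample sequenced to the given depth: at every requested
#' position the sample's own base receives \code{depth} observations, minus
#' occasional miscalls redistributed uniformly to the other three bases at
#' \code{error_rate}.
#'
#' @param sequence Character scalar (the sample's haplotype).
#' @param positions 1-based positions to tabulate.
#' @param depth Read depth per position (scalar or vector).
#' @param error_rate Per-observation miscall probability.
#' @param seqid Sequence name for the pileup.
#' @return Pileup data.frame: \code{seqid}, \code{pos} (1-based), counts
#'   \code{A}, \code{C}, \code{G}, \code{T}, and \code{depth}.
#' @export
simulate_pileup <- function(sequence, positions, depth = 20, error_rate = 0,
                            seqid = "chr1") {
  n <- length(positions)
  depth <- rep_len(depth, n)
  base <- substring(sequence, positions, positions)
  m <- matrix(0L, n, 4, dimnames = list(NULL, DNA_BASES))
  err <- if (error_rate > 0) rbinom(n, depth, error_rate) else integer(n)
  m[cbind(seq_len(n), match(base, DNA_BASES))] <- depth - err
  if (any(err > 0)) {
    for (i in which(err > 0)) {
      alt <- sample(setdiff(DNA_BASES, base[i]), err[i], replace = TRUE)
      for (b in alt) m[i, b] <- m[i, b] + 1L
    }
  }
  data.frame(seqid = seqid, pos = positions, m, depth = depth,
             stringsAsFactors = FALSE)
}

#' Call diagnostic SNPs from two parental pileups
#'
#' A position is diagnostic when both parents are covered at
#' \code{min_cov} or more, each parent's major allele accounts for at least
#' \code{1 - max_minor_fraction} of its observations (near-fixed), and the
#' two major alleles differ. Such fixed inter-parental differences are what
#' allow hybrid RNA-seq reads to be attributed to a parental allele.
#'
#' @param parent1_pileup,parent2_pileup Pileup data.frames (see
#'   [simulate_pileup()] for the layout); parent1 is taken as maternal.
#' @param min_cov Minimum depth per parent (default 10).
#' @param max_minor_fraction Maximum tolerated minor-allele fraction per
#'   parent (default 0.1).
#' @return data.frame: \code{seqid}, \code{pos}, \code{maternal},
#'   \code{paternal} alleles, \code{maternal_depth}, \code{paternal_depth}.
#' @export
call_diagnostic_snps <- function(parent1_pileup, parent2_pileup,
                                 min_cov = 10, max_minor_fraction = 0.1) {
  key1 <- paste(parent1_pileup$seqid, parent1_pileup$pos)
  key2 <- paste(parent2_pileup$seqid, parent2_pileup$pos)
  shared <- intersect(key1, key2)
  empty <- data.frame(seqid = character(), pos = integer(),
                      maternal = character(), paternal = character(),
                      maternal_depth = integer(), paternal_depth = integer(),
                      stringsAsFactors = FALSE)
  if (length(shared) == 0) {
    warning("parental pileups share no positions")
    return(empty)
  }
  p1 <- parent1_pileup[match(shared, key1), , drop = FALSE]
  p2 <- parent2_pileup[match(shared, key2), , drop = FALSE]
  major <- function(p) {
    m <- as.matrix(p[, DNA_BASES])
    depth <- rowSums(m)
    i <- max.col(m, ties.method = "first")
    list(allele = DNA_BASES[i], freq = m[cbind(seq_len(nrow(m)), i)] /
           pmax(depth, 1), depth = depth)
  }
  a1 <- major(p1)
  a2 <- major(p2)
  ok <- a1$depth >= min_cov & a2$depth >= min_cov &
    a1$freq >= 1 - max_minor_fraction & a2$freq >= 1 - max_minor_fraction &
    a1$allele != a2$allele
  if (!any(ok)) return(empty)
  out <- data.frame(seqid = p1$seqid[ok], pos = p1$pos[ok],
                    maternal = a1$allele[ok], paternal = a2$allele[ok],
                    maternal_depth = a1$depth[ok],
                    paternal_depth = a2$depth[ok],
                    stringsAsFactors = FALSE)
  out[order(out$seqid, out$pos), , drop = FALSE]
}

COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Observed alleles of simulated reads at diagnostic sites
#'
#' Bridges the read simulator's truth coordinates to allelic assignment:
#' for every read, reports the base it carries (on the reference strand) at
#' each diagnostic position falling inside the read's interval.
#'
#' @param reads Named character vector of read sequences.
#' @param truth Truth table from [simulate_reads()] (coordinates on the
#'   shared parental coordinate system).
#' @param positions Sorted 1-based diagnostic positions.
#' @param seqid Sequence name attached to the observations.
#' @return data.frame: \code{read_id}, \code{seqid}, \code{pos},
#'   \code{allele}.
#' @export
read_site_alleles <- function(reads, truth, positions, seqid = "chr1") {
  positions <- sort(positions)
  out_id <- character(0); out_pos <- integer(0); out_allele <- character(0)
  rl <- nchar(reads[1])
  for (i in seq_len(nrow(truth))) {
    lo <- truth$start[i] + 1L        # first covered 1-based position
    hi <- truth$end[i]
    j1 <- findInterval(lo - 1L, positions) + 1L
    j2 <- findInterval(hi, positions)
    if (j1 > j2) next
    pos <- positions[j1:j2]
    off <- pos - truth$start[i]      # 1-based offset in forward fragment
    read <- reads[[truth$read_id[i]]]
    allele <- if (truth$strand[i] == "+") {
      substring(read, off, off)
    } else {
      unname(COMP[substring(read, rl - off + 1L, rl - off + 1L)])
    }
    out_id <- c(out_id, rep(truth$read_id[i], length(pos)))
    out_pos <- c(out_pos, pos)
    out_allele <- c(out_allele, allele)
  }
  data.frame(read_id = out_id, seqid = rep(seqid, length(out_id)),
             pos = out_pos, allele = out_allele, stringsAsFactors = FALSE)
}

#' Assign hybrid reads to parental alleles at diagnostic SNPs
#'
#' Tallies, per read, the diagnostic sites supporting the maternal and the
#' paternal allele. In \code{strict} (consensus) mode a read is assigned only
#' when every informative site supports the same parent; any conflict leaves
#' it unassigned. In \code{majority} mode the parent supported by more than
#' half of the informative sites wins, with ties unassigned. Reads covering
#' no diagnostic site are unassigned with reason \code{no_sites}; observed
#' bases outside A/C/G/T are skipped, and bases matching neither parental
#' allele support neither side.
#'
#' @param observations data.frame of per-read observed alleles
#'   (\code{read_id}, \code{seqid}, \code{pos}, \code{allele}), e.g. from
#'   [read_site_alleles()].
#' @param snps Diagnostic-SNP table from [call_diagnostic_snps()].
#' @param read_ids All read identifiers; reads absent from
#'   \code{observations} are reported as \code{no_sites}. Defaults to the
#'   reads present in \code{observations}.
#' @param mode \code{"strict"} or \code{"majority"}.
#' @return data.frame: \code{read_id}, \code{label} (\code{maternal} /
#'   \code{paternal} / \code{unassigned}), \code{n_mat}, \code{n_pat},
#'   \code{reason} (\code{consistent} / \code{conflict} / \code{no_sites}).
#' @export
assign_reads <- function(observations, snps, read_ids = NULL,
                         mode = c("strict", "majority")) {
  mode <- match.arg(mode)
  if (is.null(read_ids)) read_ids <- unique(observations$read_id)
  obs <- observations[observations$allele %in% DNA_BASES, , drop = FALSE]
  skey <- paste(snps$seqid, snps$pos)
  okey <- paste(obs$seqid, obs$pos)
  idx <- match(okey, skey)
  keep <- !is.na(idx)
  obs <- obs[keep, , drop = FALSE]
  idx <- idx[keep]
  sup_mat <- obs$allele == snps$maternal[idx]
  sup_pat <- obs$allele == snps$paternal[idx]
  f <- factor(obs$read_id, levels = read_ids)
  n_mat <- as.integer(tapply(sup_mat, f, sum, default = 0))
  n_pat <- as.integer(tapply(sup_pat, f, sum, default = 0))
  n_mat[is.na(n_mat)] <- 0L
  n_pat[is.na(n_pat)] <- 0L
  if (mode == "strict") {
    label <- ifelse(n_mat > 0 & n_pat == 0, "maternal",
                    ifelse(n_pat > 0 & n_mat == 0, "paternal", "unassigned"))
  } else {
    tot <- n_mat + n_pat
    label <- ifelse(tot > 0 & n_mat > tot / 2, "maternal",
                    ifelse(tot > 0 & n_pat > tot / 2, "paternal",
                           "unassigned"))
  }
  reason <- ifelse(n_mat + n_pat == 0, "no_sites",
                   ifelse(label == "unassigned", "conflict", "consistent"))
  data.frame(read_id = read_ids, label = label, n_mat = n_mat,
             n_pat = n_pat, reason = reason, stringsAsFactors = FALSE)
}

#' Assign a single read from its observed alleles
#'
#' Single-read convenience wrapper around [assign_reads()].
#' @inheritParams assign_reads
#' @param read_alleles data.frame with \code{seqid}, \code{pos},
#'   \code{allele} for one read.
#' @return One-row assignment data.frame.
#' @export
assign_read <- function(read_alleles, snps, mode = c("strict", "majority")) {
  read_alleles$read_id <- rep("read", nrow(read_alleles))
  assign_reads(read_alleles, snps, read_ids = "read", mode = mode)
}

#' Build a per-gene allelic count matrix from read assignments
#'
#' Each assigned read increments exactly one gene — the gene with the largest
#' overlap, ties broken by the lexicographically smallest gene id — in its
#' parent's column for its replicate. Unassigned reads contribute to the
#' summary fractions only.
#'
#' @param assignments Assignment data.frame from [assign_reads()] with an
#'   additional \code{replicate} column.
#' @param read_to_gene_overlaps data.frame: \code{read_id}, \code{gene_id},
#'   \code{overlap} (bp).
#' @param gene_models Gene-model data.frame (validates gene ids).
#' @return List with \code{counts} (data.frame \code{gene_id},
#'   \code{replicate}, \code{maternal_count}, \code{paternal_count}; complete
#'   over genes x replicates) and \code{summary} (percent maternal /
#'   paternal / unassigned of all reads).
#' @export
allelic_counts <- function(assignments, read_to_gene_overlaps, gene_models) {
  ov <- read_to_gene_overlaps
  unknown <- setdiff(ov$gene_id, gene_models$gene_id)
  if (length(unknown))
    stop("unknown gene id(s) in overlaps: ", paste(unknown, collapse = ", "))
  stopifnot("replicate" %in% names(assignments))
  # largest overlap wins; ties to the smallest gene id
  ov <- ov[order(ov$read_id, -ov$overlap, ov$gene_id), , drop = FALSE]
  ov <- ov[!duplicated(ov$read_id), , drop = FALSE]
  asg <- assignments[assignments$label %in% c("maternal", "paternal"), ,
                     drop = FALSE]
  asg$gene_id <- ov$gene_id[match(asg$read_id, ov$read_id)]
  asg <- asg[!is.na(asg$gene_id), , drop = FALSE]
  reps <- sort(unique(assignments$replicate))
  grid <- expand.grid(gene_id = gene_models$gene_id, replicate = reps,
                      stringsAsFactors = FALSE)
  tab <- function(lbl) {
    sub <- asg[asg$label == lbl, , drop = FALSE]
    key <- paste(grid$gene_id, grid$replicate)
    cnt <- table(paste(sub$gene_id, sub$replicate))
    as.integer(ifelse(key %in% names(cnt), cnt[key], 0L))
  }
  grid$maternal_count <- tab("maternal")
  grid$paternal_count <- tab("paternal")
  n_all <- nrow(assignments)
  summary <- data.frame(
    class = c("maternal", "paternal", "unassigned"),
    n = c(sum(assignments$label == "maternal"),
          sum(assignments$label == "paternal"),
          sum(assignments$label == "unassigned")))
  summary$percent <- round_half_up(100 * summary$n / max(n_all, 1))
  list(counts = grid, summary = summary)
}

#' Overlap widths between simulated reads and gene models
#'
#' Computes, from the simulator's truth coordinates, how many bases of each
#' read fall inside each gene model — the read-to-gene overlap input of
#' [allelic_counts()].
#'
#' @param truth Read truth table ([simulate_reads()]).
#' @param gene_models Gene-model data.frame (0-based half-open).
#' @return data.frame: \code{read_id}, \code{gene_id}, \code{overlap} (bp).
#' @export
read_gene_overlaps <- function(truth, gene_models) {
  reads <- IRanges::IRanges(start = truth$start + 1L, end = truth$end)
  genes <- IRanges::IRanges(start = gene_models$start + 1L,
                            end = gene_models$end)
  ov <- IRanges::findOverlaps(reads, genes)
  w <- IRanges::width(IRanges::pintersect(
    reads[S4Vectors::queryHits(ov)], genes[S4Vectors::subjectHits(ov)]))
  data.frame(read_id = truth$read_id[S4Vectors::queryHits(ov)],
             gene_id = gene_models$gene_id[S4Vectors::subjectHits(ov)],
             overlap = w, stringsAsFactors = FALSE)
}
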