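#' Pairwise homology hits between two gene sets
#'
#' Either passes through a precomputed 12-column tabular hit file (the
#' standard protein-search output: query, subject, identity, length,
#' mismatches, gap opens, qstart, qend, sstart, send, evalue, bitscore) or
#' scores all query-subject pairs with the built-in affine-gap
#' Smith-Waterman local aligner — intended for fixture-scale inputs. Hits
#' below the score or aligned-fraction thresholds are dropped.
#'
#' @param genes_a,genes_b Named character vectors of gene (protein or CDS)
#'   sequences; ignored when \code{hit_file} is given.
#' @param hit_file Optional path to a 12-column tabular hit file.
#' @param match,mismatch,gap_open,gap_extend Alignment scoring (match reward,
#'   mismatch score, positive gap-open and gap-extend costs); defaults follow
#'   standard nucleotide-search practice (2/-3, gap 5/2), stringent enough
#'   that random sequence does not reach the score threshold.
#' @param min_score Minimum hit score (default 50).
#' @param min_fraction Minimum aligned fraction of the shorter sequence
#'   (default 0.5; not evaluable for file input, where it is ignored).
#' @return data.frame: \code{query}, \code{subject}, \code{score},
#'   \code{fraction}.
#' @export
homology_hits <- function(genes_a = NULL, genes_b = NULL, hit_file = NULL,
                          match = 2, mismatch = -3,
                          gap_open = 5, gap_extend = 2,
                          min_score = 50, min_fraction = 0.5) {
  if (!is.null(hit_file)) {
    tab <- read.delim(hit_file, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 12) stop("hit file must have 12 columns")
    hits <- data.frame(query = tab[[1]], subject = tab[[2]],
                       score = tab[[12]], fraction = NA_real_,
                       stringsAsFactors = FALSE)
    return(hits[hits$score >= min_score, , drop = FALSE])
  }
  if (is.null(genes_a) || is.null(genes_b))
    stop("supply either sequences for both gene sets or a hit file")
  if (length(genes_a) == 0 || length(genes_b) == 0)
    return(data.frame(query = character(), subject = character(),
                      score = numeric(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  grid <- expand.grid(query = names(genes_a), subject = names(genes_b),
                      stringsAsFactors = FALSE)
  res <- t(mapply(function(q, s) {
    .sw_align_cpp(genes_a[[q]], genes_b[[s]], match, mismatch,
                  gap_open, gap_extend)
  }, grid$query, grid$subject))
  grid$score <- res[, 1]
  shorter <- pmin(nchar(genes_a)[grid$query], nchar(genes_b)[grid$subject])
  grid$fraction <- res[, 2] / shorter
  rownames(grid) <- NULL
  grid[grid$score >= min_score & grid$fraction >= min_fraction, ,
       drop = FALSE]
}

#' Local alignment score of two sequences
#'
#' The package's built-in affine-gap Smith-Waterman aligner, exposed for
#' direct use and verification.
#' @inheritParams homology_hits
#' @param a,b Sequences (any alphabet; scoring is match/mismatch).
#' @return List with \code{score} and \code{query_aln_len}.
#' @export
sw_align <- function(a, b, match = 2, mismatch = -3,
                     gap_open = 5, gap_extend = 2) {
  r <- .sw_align_cpp(a, b, match, mismatch, gap_open, gap_extend)
  list(score = unname(r[1]), query_aln_len = unname(r[2]))
}

# best monotone chain by DP over anchors sorted by rank_a; direction -1
# chains against decreasing rank_b (inverted blocks)
chain_anchors <- function(anch, max_gap, gap_penalty, direction = 1) {
  n <- nrow(anch)
  rb <- direction * anch$rank_b
  ord <- order(anch$rank_a, rb)
  anch <- anch[ord, , drop = FALSE]
  rb <- rb[ord]
  dp <- anch$score
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ga <- anch$rank_a[i] - anch$rank_a[j]
      gb <- rb[i] - rb[j]
      if (ga >= 1 && gb >= 1 && ga <= max_gap && gb <= max_gap) {
        cand <- dp[j] + anch$score[i] - gap_penalty * ((ga - 1) + (gb - 1))
        if (cand > dp[i] ||
            (cand == dp[i] && !is.na(prev[i]) &&
             anch$rank_a[j] < anch$rank_a[prev[i]])) {
          dp[i] <- cand
          prev[i] <- j
        }
      }
    }
  }
  end <- which.max(dp)
  chain <- integer(0)
  i <- end
  while (!is.na(i)) {
    chain <- c(i, chain)
    i <- prev[i]
  }
  list(score = dp[end], members = anch$idx[chain])
}

#' Chain homology hits into collinear gene blocks
#'
#' Dynamic-programming chaining of hit anchors by gene order: a chain extends
#' from one anchor to the next when both rank gaps are at most
#' \code{max_gap}, scoring the sum of hit scores minus a linear penalty per
#' skipped rank. Maximal-scoring non-overlapping chains with at least
#' \code{min_block} anchor pairs are reported; inverted blocks are found by
#' chaining against the reversed rank order of the second haplotype.
#'
#' @param hits Hit data.frame from [homology_hits()] (query genes from
#'   haplotype A, subjects from haplotype B).
#' @param gene_models Gene models of both haplotypes: data.frame with
#'   \code{gene_id}, \code{haplotype}, \code{rank}.
#' @param min_block Minimum anchors per reported block (default 5).
#' @param max_gap Maximum rank gap between consecutive anchors (default 25).
#' @param gap_penalty Score units per skipped rank (default 1).
#' @return data.frame, one row per anchor pair in a block: \code{block_id},
#'   \code{gene_a}, \code{gene_b}, \code{orientation} (\code{same} /
#'   \code{inverted}), \code{block_score}, \code{block_length}.
#' @export
collinear_blocks <- function(hits, gene_models, min_block = 5, max_gap = 25,
                             gap_penalty = 1) {
  empty <- data.frame(block_id = integer(), gene_a = character(),
                      gene_b = character(), orientation = character(),
                      block_score = numeric(), block_length = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(empty)
  rank_of <- setNames(gene_models$rank, gene_models$gene_id)
  anch <- data.frame(gene_a = hits$query, gene_b = hits$subject,
                     score = hits$score,
                     rank_a = rank_of[hits$query],
                     rank_b = rank_of[hits$subject],
                     stringsAsFactors = FALSE)
  if (anyNA(anch$rank_a) || anyNA(anch$rank_b))
    stop("hits reference genes without assigned ranks")
  anch$idx <- seq_len(nrow(anch))
  out <- list()
  block_id <- 0L
  active <- rep(TRUE, nrow(anch))
  repeat {
    sub <- anch[active, , drop = FALSE]
    if (nrow(sub) < min_block) break
    fwd <- chain_anchors(sub, max_gap, gap_penalty, direction = 1)
    rev <- chain_anchors(sub, max_gap, gap_penalty, direction = -1)
    pick <- if (fwd$score >= rev$score) c(fwd, orientation = "same")
            else c(rev, orientation = "inverted")
    if (length(pick$members) < min_block || pick$score <= 0) break
    block_id <- block_id + 1L
    sel <- anch[pick$members, , drop = FALSE]
    out[[block_id]] <- data.frame(block_id = block_id,
                                  gene_a = sel$gene_a, gene_b = sel$gene_b,
                                  orientation = pick$orientation,
                                  block_score = pick$score,
                                  block_length = nrow(sel),
                                  stringsAsFactors = FALSE)
    active[pick$members] <- FALSE
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cluster genes into orthogroups by single-linkage over homology hits
#'
#' Connected components of the hit graph (hits are treated as undirected).
#' A lightweight stand-in for full orthogroup inference, adequate for
#' two-haplotype gene sets where homology is essentially one-to-one.
#'
#' @param hits Hit data.frame from [homology_hits()].
#' @param gene_ids Optional full gene universe; genes without hits become
#'   singleton groups.
#' @return Named character vector mapping gene id to orthogroup id.
#' @export
orthogroups <- function(hits, gene_ids = NULL) {
  verts <- unique(c(hits$query, hits$subject, gene_ids))
  if (length(verts) == 0) return(setNames(character(0), character(0)))
  g <- igraph::graph_from_data_frame(
    hits[, c("query", "subject"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = verts))
  comp <- igraph::components(g)$membership
  setNames(sprintf("OG%05d", comp), names(comp))
}

#' Define one-to-one allele pairs between the hybrid's haplotypes
#'
#' A maternal-paternal gene pair is an allele pair when (i) it occurs as an
#' anchor in a collinear block and (ii) its orthogroup contains exactly one
#' gene from each haplotype — excluding tandem duplicates and ambiguous
#' homology. Each gene appears in at most one pair.
#'
#' @param blocks Block table from [collinear_blocks()] (gene_a maternal,
#'   gene_b paternal).
#' @param orthogroup_map Mapping from [orthogroups()].
#' @param haplotype_of Named vector mapping gene id to \code{"maternal"} or
#'   \code{"paternal"}.
#' @return data.frame: \code{maternal_gene}, \code{paternal_gene},
#'   \code{block_id}, \code{orthogroup}.
#' @export
allele_pairs <- function(blocks, orthogroup_map, haplotype_of) {
  empty <- data.frame(maternal_gene = character(),
                      paternal_gene = character(),
                      block_id = integer(), orthogroup = character(),
                      stringsAsFactors = FALSE)
  if (nrow(blocks) == 0) return(empty)
  og_sizes <- table(orthogroup_map, haplotype_of[names(orthogroup_map)])
  one_to_one <- rownames(og_sizes)[
    rowSums(og_sizes) == 2 &
      og_sizes[, "maternal", drop = TRUE] == 1 &
      og_sizes[, "paternal", drop = TRUE] == 1]
  og_a <- orthogroup_map[blocks$gene_a]
  og_b <- orthogroup_map[blocks$gene_b]
  keep <- !is.na(og_a) & !is.na(og_b) & og_a == og_b & og_a %in% one_to_one
  res <- data.frame(maternal_gene = blocks$gene_a[keep],
                    paternal_gene = blocks$gene_b[keep],
                    block_id = blocks$block_id[keep],
                    orthogroup = unname(og_a[keep]),
                    stringsAsFactors = FALSE)
  res <- res[!duplicated(res$maternal_gene) & !duplicated(res$paternal_gene), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Allelic count matrix from combined-gene-set (metagenome) counts
#'
#' In the haplotype-resolved route, hybrid RNA-seq reads are quantified
#' against the combined gene set of both haplotypes, so each haplotype copy
#' of a gene accumulates its own counts. This reshapes those per-copy counts
#' into the maternal/paternal allelic matrix over allele pairs; counts on
#' genes outside any pair are returned separately as unpaired.
#'
#' @param counts Matrix of counts, rows named by haplotype-qualified gene
#'   ids, columns = replicates.
#' @param pairs Allele-pair table from [allele_pairs()].
#' @param known_gene_ids Optional gene universe for validation; count rows
#'   outside it raise an error.
#' @return List with \code{counts} (data.frame \code{gene_id} = maternal
#'   member, \code{replicate}, \code{maternal_count}, \code{paternal_count})
#'   and \code{unpaired} (count matrix of genes outside pairs).
#' @export
allelic_matrix_from_metagenome_counts <- function(counts, pairs,
                                                  known_gene_ids = NULL) {
  ids <- rownames(counts)
  if (!is.null(known_gene_ids)) {
    unknown <- setdiff(ids, known_gene_ids)
    if (length(unknown))
      stop("count table references unknown gene id(s): ",
           paste(head(unknown, 5), collapse = ", "))
  }
  missing <- setdiff(c(pairs$maternal_gene, pairs$paternal_gene), ids)
  if (length(missing))
    stop("allele pairs reference genes absent from the count table: ",
         paste(head(missing, 5), collapse = ", "))
  reps <- colnames(counts) %||% paste0("rep", seq_len(ncol(counts)))
  long <- expand.grid(i = seq_len(nrow(pairs)), replicate = reps,
                      stringsAsFactors = FALSE)
  out <- data.frame(gene_id = pairs$maternal_gene[long$i],
                    replicate = long$replicate,
                    maternal_count = counts[cbind(
                      match(pairs$maternal_gene[long$i], ids),
                      match(long$replicate, reps))],
                    paternal_count = counts[cbind(
                      match(pairs$paternal_gene[long$i], ids),
                      match(long$replicate, reps))],
                    stringsAsFactors = FALSE)
  paired_ids <- c(pairs$maternal_gene, pairs$paternal_gene)
  list(counts = out,
       unpaired = counts[setdiff(ids, paired_ids), , drop = FALSE])
}
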