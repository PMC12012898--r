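#' FPKM from raw counts
#'
#' \eqn{FPKM_{gs} = 10^9 c_{gs} / (L_g N_s)} with \eqn{L_g} the gene length
#' in bp and \eqn{N_s} the total assigned counts of sample s.
#'
#' @param counts Gene x sample matrix of non-negative integer counts.
#' @param gene_lengths Gene lengths in bp, named or in row order.
#' @param totals Per-sample library sizes; defaults to column sums.
#' @return Matrix of FPKM values, same dimensions as \code{counts}.
#' @export
fpkm <- function(counts, gene_lengths, totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts)))
    gene_lengths <- gene_lengths[rownames(counts)]
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  if (any(totals <= 0)) stop("zero library size")
  1e9 * sweep(counts / gene_lengths, 2, totals, "/")
}

#' Median-of-ratios size factors
#'
#' The per-sample normalization of count-based differential expression: the
#' reference expression of a gene is its geometric mean across samples
#' (genes with any zero excluded), and a sample's size factor is the median
#' across genes of its counts over that reference.
#'
#' @param counts Gene x sample count matrix.
#' @return Named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use))
    stop("no gene has nonzero counts in every sample; consider pseudo-counts")
  apply(counts[use, , drop = FALSE], 2, function(cnt)
    median(exp(log(cnt) - log_geo[use])))
}

row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(NA_real_, nrow(m)))
  rowSums((m - rowMeans(m))^2) / (n - 1)
}

# parametric mean-dispersion trend phi(mu) = a0 + a1/mu fitted to per-gene
# method-of-moments estimates (gamma GLM as in count-based DE practice),
# with a median-based fallback when the fit degenerates
fit_dispersion_trend <- function(mu, phi) {
  use <- is.finite(mu) & is.finite(phi) & mu > 1 & phi > 1e-6
  fallback <- function() {
    a0 <- median(phi[use & mu > median(mu[use], na.rm = TRUE)], na.rm = TRUE)
    c(a0 = max(a0, 1e-6, na.rm = TRUE), a1 = 0)
  }
  if (sum(use) < 10) return(fallback())
  fit <- try(suppressWarnings(
    stats::glm(phi[use] ~ I(1 / mu[use]),
               family = stats::Gamma(link = "identity"),
               start = c(0.05, 1))), silent = TRUE)
  if (inherits(fit, "try-error") || any(!is.finite(coef(fit))) ||
      coef(fit)[1] <= 0)
    return(fallback())
  c(a0 = unname(coef(fit)[1]), a1 = max(0, unname(coef(fit)[2])))
}

#' Negative-binomial two-group Wald test
#'
#' Per-gene NB test of group B against group A on size-factor normalized
#' counts. Gene-wise dispersions are estimated by method of moments, a
#' parametric mean-dispersion trend \eqn{\phi(\mu) = a_0 + a_1/\mu} is
#' fitted across genes, and each gene's working dispersion shrinks the
#' gene-wise estimate toward the trend in log space (weight
#' \eqn{df/(df + df_{prior})} — few-replicate designs lean mostly on the
#' trend). The Wald-type statistic is the log2 fold change of the group
#' means (pseudo-count 0.5) over its delta-method standard error, referred
#' to a moderated t distribution with \eqn{df + df_{prior}} degrees of
#' freedom (borrowing strength across genes widens the effective degrees of
#' freedom while keeping few-replicate tests honest); BH-adjusted p-values
#' are reported alongside raw ones.
#'
#' @param counts_a,counts_b Gene x replicate count matrices for the two
#'   groups (same genes, same order).
#' @param sf_a,sf_b Size factors per replicate (default 1, i.e. counts
#'   already normalized).
#' @param prior_df Prior degrees of freedom of the trend (default 40).
#' @return data.frame: \code{gene_id}, \code{base_mean_a},
#'   \code{base_mean_b}, \code{log2fc} (B over A), \code{se}, \code{stat},
#'   \code{pvalue}, \code{padj}, \code{dispersion}, \code{untestable}.
#' @export
nb_two_group_test <- function(counts_a, counts_b,
                              sf_a = rep(1, ncol(counts_a)),
                              sf_b = rep(1, ncol(counts_b)),
                              prior_df = 40) {
  counts_a <- as.matrix(counts_a)
  counts_b <- as.matrix(counts_b)
  stopifnot(nrow(counts_a) == nrow(counts_b))
  qa <- sweep(counts_a, 2, sf_a, "/")
  qb <- sweep(counts_b, 2, sf_b, "/")
  na <- ncol(qa); nb <- ncol(qb)
  mu_a <- rowMeans(qa); mu_b <- rowMeans(qb)
  xim_a <- mean(1 / sf_a); xim_b <- mean(1 / sf_b)
  # pooled within-group method-of-moments dispersion
  df <- (na - 1) + (nb - 1)
  v_pool <- ((na - 1) * row_vars(qa) + (nb - 1) * row_vars(qb)) / df
  mu_pool <- (na * mu_a + nb * mu_b) / (na + nb)
  xim <- (na * xim_a + nb * xim_b) / (na + nb)
  phi_mom <- (v_pool - xim * mu_pool) / mu_pool^2
  trend <- fit_dispersion_trend(mu_pool, phi_mom)
  phi_tr <- pmax(trend["a0"] + trend["a1"] / pmax(mu_pool, 1e-8), 1e-8)
  w <- df / (df + prior_df)
  phi <- exp(w * log(pmax(phi_mom, 1e-8)) + (1 - w) * log(phi_tr))
  lfc <- log2((mu_b + 0.5) / (mu_a + 0.5))
  # delta method on log2 of the (pseudo-counted) group means
  var_log_a <- (xim_a * mu_a + phi * mu_a^2) / (na * (mu_a + 0.5)^2)
  var_log_b <- (xim_b * mu_b + phi * mu_b^2) / (nb * (mu_b + 0.5)^2)
  se <- sqrt(var_log_a + var_log_b) / log(2)
  stat <- ifelse(se > 0, lfc / se, 0)
  pvalue <- 2 * stats::pt(-abs(stat), df = df + prior_df)
  untestable <- mu_a == 0 & mu_b == 0
  pvalue[untestable] <- NA_real_
  data.frame(gene_id = rownames(counts_a) %||% seq_len(nrow(counts_a)),
             base_mean_a = mu_a, base_mean_b = mu_b, log2fc = lfc, se = se,
             stat = stat, pvalue = pvalue,
             padj = p.adjust(pvalue, "BH"),
             dispersion = phi, untestable = untestable,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter to genes expressed in both parental species
#'
#' A gene is retained when its summed raw counts reach \code{min_total} in
#' parent 1 and in parent 2 — guarding against false negatives where zero
#' expression merely reflects failure to map reads across divergent genomes.
#'
#' @param counts_parent1,counts_parent2 Gene x replicate count matrices.
#' @param min_total Minimum summed raw counts per species (default 10).
#' @return Character vector of retained gene ids (row names).
#' @export
expressed_filter <- function(counts_parent1, counts_parent2, min_total = 10) {
  keep <- rowSums(as.matrix(counts_parent1)) >= min_total &
    rowSums(as.matrix(counts_parent2)) >= min_total
  rownames(counts_parent1)[keep]
}

#' Test hybrid expression against the mid-parent value
#'
#' Builds MPV pseudo-replicates — the per-replicate-index average of the two
#' parents' normalized counts, rounded to integers on the normalized scale —
#' and tests the (normalized) hybrid counts against them with
#' [nb_two_group_test()]. Genes passing \code{|log2FC| > lfc_threshold} and
#' \code{p < p_threshold} express nonadditively (up or down by fold-change
#' sign); the rest follow the additive model.
#'
#' @param parent1_counts,parent2_counts,hybrid_counts Gene x replicate raw
#'   count matrices with equal replicate numbers, replicates paired by index.
#' @param sf Optional size factors for the combined 3-group matrix; computed
#'   by [size_factors()] when omitted.
#' @param lfc_threshold,p_threshold Call thresholds (defaults 1 and 0.01,
#'   raw p).
#' @return data.frame: test columns from [nb_two_group_test()] (hybrid over
#'   MPV) plus \code{additivity} (\code{additive} / \code{nonadditive_up} /
#'   \code{nonadditive_down}).
#' @export
mpv_comparison <- function(parent1_counts, parent2_counts, hybrid_counts,
                           sf = NULL, lfc_threshold = 1, p_threshold = 0.01) {
  p1 <- as.matrix(parent1_counts); p2 <- as.matrix(parent2_counts)
  hy <- as.matrix(hybrid_counts)
  if (ncol(p1) != ncol(p2) || ncol(p1) != ncol(hy))
    stop("groups must have equal replicate numbers (pair or subsample first)")
  if (is.null(sf)) sf <- size_factors(cbind(p1, p2, hy))
  n <- ncol(p1)
  idx <- function(g) seq_len(n) + (g - 1L) * n
  q1 <- sweep(p1, 2, sf[idx(1)], "/")
  q2 <- sweep(p2, 2, sf[idx(2)], "/")
  qh <- round(sweep(hy, 2, sf[idx(3)], "/"))
  mpv <- round((q1 + q2) / 2)
  res <- nb_two_group_test(mpv, qh)  # B = hybrid, lfc = hybrid over MPV
  sig <- !res$untestable & !is.na(res$pvalue) &
    res$pvalue < p_threshold & abs(res$log2fc) > lfc_threshold
  res$additivity <- ifelse(!sig, "additive",
                           ifelse(res$log2fc > 0, "nonadditive_up",
                                  "nonadditive_down"))
  res
}

#' Classify per-gene heterosis expression modes from three pairwise tests
#'
#' Combines the parent-vs-parent test and the two hybrid-vs-parent tests
#' into one of the heterosis expression categories. With significance
#' defined as \code{p < p_threshold} and \code{|log2FC| > lfc_threshold}:
#' \itemize{
#'   \item hybrid significantly above both parents: overdominance; below
#'     both: underdominance;
#'   \item parents not different, hybrid different from neither: conserved;
#'   \item parents different, hybrid different from neither: additive
#'     (intermediate);
#'   \item parents different, hybrid indistinguishable from the higher
#'     parent but above the lower: high-parent dominance; mirrored:
#'     low-parent dominance;
#'   \item every remaining pattern (including missing or untestable tests):
#'     ambiguous.
#' }
#' The table is exhaustive: every combination of test outcomes maps to
#' exactly one category.
#'
#' @param test_p1p2 [nb_two_group_test()] result of parent2 over parent1.
#' @param test_h_p1,test_h_p2 Results of hybrid over parent1 / parent2.
#' @param lfc_threshold,p_threshold Shared thresholds (defaults 1, 0.01).
#' @return data.frame: \code{gene_id}, \code{category},
#'   \code{higher_parent} (\code{parent1} / \code{parent2} / \code{none}).
#' @export
classify_mode <- function(test_p1p2, test_h_p1, test_h_p2,
                          lfc_threshold = 1, p_threshold = 0.01) {
  stopifnot(nrow(test_p1p2) == nrow(test_h_p1),
            nrow(test_p1p2) == nrow(test_h_p2))
  sig <- function(tt) !is.na(tt$pvalue) & !tt$untestable &
    tt$pvalue < p_threshold & abs(tt$log2fc) > lfc_threshold
  s12 <- sig(test_p1p2); s1 <- sig(test_h_p1); s2 <- sig(test_h_p2)
  l12 <- test_p1p2$log2fc; l1 <- test_h_p1$log2fc; l2 <- test_h_p2$log2fc
  missing_any <- is.na(test_p1p2$pvalue) | is.na(test_h_p1$pvalue) |
    is.na(test_h_p2$pvalue)
  p2_higher <- l12 > 0
  sig_vs_higher <- ifelse(p2_higher, s2, s1)
  sig_vs_lower <- ifelse(p2_higher, s1, s2)
  lfc_vs_higher <- ifelse(p2_higher, l2, l1)
  lfc_vs_lower <- ifelse(p2_higher, l1, l2)
  category <- rep("ambiguous", nrow(test_p1p2))
  category[s1 & s2 & l1 > 0 & l2 > 0] <- "overdominance"
  category[s1 & s2 & l1 < 0 & l2 < 0] <- "underdominance"
  category[!s12 & !s1 & !s2] <- "conserved"
  category[s12 & !s1 & !s2] <- "additive"
  hpd <- s12 & !sig_vs_higher & sig_vs_lower & lfc_vs_lower > 0
  lpd <- s12 & !sig_vs_lower & sig_vs_higher & lfc_vs_higher < 0
  category[hpd & !(s1 & s2)] <- "high_parent_dominance"
  category[lpd & !(s1 & s2)] <- "low_parent_dominance"
  category[missing_any] <- "ambiguous"
  data.frame(gene_id = test_p1p2$gene_id, category = category,
             higher_parent = ifelse(!s12, "none",
                                    ifelse(p2_higher, "parent2", "parent1")),
             stringsAsFactors = FALSE)
}

#' Model-based allele-specific expression test
#'
#' Tests maternal against paternal allelic counts per gene with the NB Wald
#' test, normalizing each replicate by its total assigned allelic counts
#' (the combined maternal + paternal library of that replicate, scaled to
#' geometric mean 1, shared by the replicate's two allelic columns so the
#' within-replicate allelic ratio is preserved). A gene is an ASEG at
#' \code{p < p_threshold} and \code{|log2FC| > lfc_threshold}, labeled by
#' the higher allele; others are balanced.
#'
#' @param allelic Allelic count data.frame (\code{gene_id},
#'   \code{replicate}, \code{maternal_count}, \code{paternal_count}).
#' @param lfc_threshold,p_threshold Call thresholds (defaults 1, 0.01).
#' @return data.frame: \code{gene_id}, \code{log2fc} (maternal over
#'   paternal), \code{pvalue}, \code{padj}, \code{label} (\code{maternal} /
#'   \code{paternal} / \code{balanced}), \code{untestable},
#'   \code{method = "model_test"}.
#' @export
ase_model_test <- function(allelic, lfc_threshold = 1, p_threshold = 0.01) {
  reps <- sort(unique(allelic$replicate))
  if (length(reps) < 2) stop("ase_model_test needs >= 2 replicates")
  genes <- unique(allelic$gene_id)
  shape <- function(col) {
    m <- matrix(0, length(genes), length(reps),
                dimnames = list(genes, as.character(reps)))
    m[cbind(match(allelic$gene_id, genes),
            match(allelic$replicate, reps))] <- allelic[[col]]
    m
  }
  mat <- shape("maternal_count")
  pat <- shape("paternal_count")
  totals <- colSums(mat) + colSums(pat)
  if (any(totals == 0)) stop("replicate with zero assigned allelic counts")
  sf <- totals / exp(mean(log(totals)))
  res <- nb_two_group_test(pat, mat, sf_a = sf, sf_b = sf)
  aseg <- !res$untestable & !is.na(res$pvalue) &
    res$pvalue < p_threshold & abs(res$log2fc) > lfc_threshold
  data.frame(gene_id = genes, log2fc = res$log2fc, pvalue = res$pvalue,
             padj = res$padj,
             label = ifelse(!aseg, "balanced",
                            ifelse(res$log2fc > 0, "maternal", "paternal")),
             untestable = res$untestable, method = "model_test",
             stringsAsFactors = FALSE)
}

#' Replicate-thresholded allele-specific expression call
#'
#' Computes the per-replicate ASE ratio \eqn{r = } maternal FPKM / (maternal
#' + paternal FPKM) and calls a gene maternal-dominant when \eqn{r >} hi in
#' at least \code{min_reps} replicates, paternal-dominant when \eqn{r <} lo
#' in at least \code{min_reps} replicates, and balanced otherwise.
#' Replicates with zero combined allelic signal are excluded and flagged; a
#' gene with fewer than \code{min_reps} usable replicates is balanced with
#' an insufficient-data flag.
#'
#' @param maternal_fpkm,paternal_fpkm Gene x replicate matrices of allelic
#'   FPKM (or any expression measure on a shared scale).
#' @param hi,lo Ratio thresholds (defaults 0.7 and 0.3).
#' @param min_reps Minimum qualifying replicates (default 2).
#' @return data.frame: \code{gene_id}, \code{label}, \code{n_hi},
#'   \code{n_lo}, \code{n_usable}, \code{insufficient_data},
#'   \code{method = "ratio_threshold"}; the ratio matrix is attached as
#'   attribute \code{"ratios"}.
#' @export
ase_ratio_call <- function(maternal_fpkm, paternal_fpkm, hi = 0.7, lo = 0.3,
                           min_reps = 2) {
  if (lo >= hi) stop("need lo < hi")
  m <- as.matrix(maternal_fpkm); p <- as.matrix(paternal_fpkm)
  stopifnot(all(dim(m) == dim(p)))
  if (min_reps > ncol(m)) stop("min_reps exceeds the number of replicates")
  tot <- m + p
  r <- ifelse(tot > 0, m / tot, NA_real_)
  n_usable <- rowSums(!is.na(r))
  n_hi <- rowSums(r > hi, na.rm = TRUE)
  n_lo <- rowSums(r < lo, na.rm = TRUE)
  insufficient <- n_usable < min_reps
  label <- ifelse(insufficient, "balanced",
                  ifelse(n_hi >= min_reps, "maternal",
                         ifelse(n_lo >= min_reps, "paternal", "balanced")))
  out <- data.frame(gene_id = rownames(m) %||% seq_len(nrow(m)),
                    label = label, n_hi = n_hi, n_lo = n_lo,
                    n_usable = n_usable, insufficient_data = insufficient,
                    method = "ratio_threshold", stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "ratios") <- r
  out
}

#' Average FPKM across two reference genomes
#'
#' When expression is quantified once per parental reference, ortholog-
#' matched FPKM values are averaged per gene and sample; genes quantified
#' under only one reference are carried through and flagged.
#'
#' @param fpkm_ref_a,fpkm_ref_b Gene x sample FPKM matrices.
#' @param ortholog_map Named character vector mapping reference-A gene ids
#'   to reference-B ids (one-to-one); defaults to identity on shared row
#'   names.
#' @return List with \code{fpkm} (averaged matrix, rows = A ids then
#'   unmatched B ids) and \code{single_source} (logical flag per row).
#' @export
average_across_references <- function(fpkm_ref_a, fpkm_ref_b,
                                      ortholog_map = NULL) {
  a <- as.matrix(fpkm_ref_a); b <- as.matrix(fpkm_ref_b)
  if (is.null(ortholog_map)) {
    shared <- intersect(rownames(a), rownames(b))
    ortholog_map <- setNames(shared, shared)
  }
  if (anyDuplicated(ortholog_map) || anyDuplicated(names(ortholog_map)))
    stop("ortholog_map must be one-to-one")
  map <- ortholog_map[names(ortholog_map) %in% rownames(a) &
                        ortholog_map %in% rownames(b)]
  avg <- (a[names(map), , drop = FALSE] + b[map, , drop = FALSE]) / 2
  rownames(avg) <- names(map)
  only_a <- a[setdiff(rownames(a), names(map)), , drop = FALSE]
  only_b <- b[setdiff(rownames(b), map), , drop = FALSE]
  out <- rbind(avg, only_a, only_b)
  list(fpkm = out,
       single_source = setNames(c(rep(FALSE, nrow(avg)),
                                  rep(TRUE, nrow(only_a) + nrow(only_b))),
                                rownames(out)))
}

#' Sum expression of gene copies into per-family values
#'
#' Consolidates multi-copy genes: the expression of a functional gene
#' (family) is the sum of its copies' FPKM per sample.
#'
#' @param fpkm Copy x sample expression matrix.
#' @param copy_map data.frame with \code{copy} and \code{family} (each copy
#'   in exactly one family) or a named vector copy -> family.
#' @return Family x sample matrix; families with no quantified copy are 0
#'   with a warning.
#' @export
sum_gene_copies <- function(fpkm, copy_map) {
  if (is.data.frame(copy_map)) {
    if (anyDuplicated(copy_map$copy))
      stop("a gene copy is assigned to two families")
    copy_map <- setNames(copy_map$family, copy_map$copy)
  }
  fpkm <- as.matrix(fpkm)
  copies <- intersect(rownames(fpkm), names(copy_map))
  fams <- unique(unname(copy_map))
  out <- rowsum(fpkm[copies, , drop = FALSE], copy_map[copies])
  missing <- setdiff(fams, rownames(out))
  if (length(missing)) {
    warning("families with no quantified copies set to 0: ",
            paste(missing, collapse = ", "))
    zero <- matrix(0, length(missing), ncol(out),
                   dimnames = list(missing, colnames(out)))
    out <- rbind(out, zero)
  }
  out[fams, , drop = FALSE]
}

#' Pathway-level report of expression modes and allelic bias
#'
#' Cross-tabulates expression-mode categories and ASE calls over gene sets
#' (pathways). Percentages are 100 x count / pathway size, rounded half-up
#' to 2 decimals, and always recompute exactly from the printed counts.
#'
#' @param mode_calls data.frame with \code{gene_id} and \code{category}.
#' @param ase_calls data.frame with \code{gene_id} and \code{label}.
#' @param pathway_gene_sets Named list of gene-id vectors.
#' @return List with \code{summary} (one row per pathway: size, ASEG counts
#'   by bias, ASEG percentage) and \code{categories} (long table: pathway,
#'   category, n, percent). Empty pathways carry \code{NA} percentages.
#' @export
pathway_report <- function(mode_calls, ase_calls, pathway_gene_sets) {
  cat_of <- setNames(mode_calls$category, mode_calls$gene_id)
  ase_of <- setNames(ase_calls$label, ase_calls$gene_id)
  cats <- list(); rows <- list()
  for (pw in names(pathway_gene_sets)) {
    genes <- pathway_gene_sets[[pw]]
    size <- length(genes)
    cc <- cat_of[genes]
    cc[is.na(cc)] <- "missing"
    tab <- table(cc)
    if (length(tab))
      cats[[pw]] <- data.frame(pathway = pw, category = names(tab),
                               n = as.integer(tab),
                               percent = round_half_up(
                                 100 * as.integer(tab) / size),
                               stringsAsFactors = FALSE)
    aa <- ase_of[genes]
    n_mat <- sum(aa == "maternal", na.rm = TRUE)
    n_pat <- sum(aa == "paternal", na.rm = TRUE)
    rows[[pw]] <- data.frame(
      pathway = pw, size = size, n_aseg_maternal = n_mat,
      n_aseg_paternal = n_pat, n_aseg = n_mat + n_pat,
      percent_aseg = if (size) round_half_up(100 * (n_mat + n_pat) / size)
                     else NA_real_,
      stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       categories = do.call(rbind, c(cats, list(make.row.names = FALSE))))
}
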