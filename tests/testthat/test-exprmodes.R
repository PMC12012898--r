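nb_mat <- function(n, mu, reps = 3, phi = 0.05) {
  m <- sapply(seq_len(reps), function(i) rnbinom(n, mu = mu, size = 1 / phi))
  rownames(m) <- sprintf("g%04d", seq_len(n))
  m
}

test_that("FPKM follows its defining formula", {
  counts <- matrix(c(100, 0), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  f <- fpkm(counts, gene_lengths = c(g1 = 1000, g2 = 500), totals = 1e6)
  expect_equal(f["g1", 1], 100)
  expect_equal(f["g2", 1], 0)
  # doubling the library size halves FPKM
  f2 <- fpkm(counts, c(g1 = 1000, g2 = 500), totals = 2e6)
  expect_equal(f2, f / 2)
  expect_error(fpkm(counts, c(g1 = 1000, g2 = 500), totals = 0), "library")
})

test_that("median-of-ratios size factors reproduce exact scaling", {
  set.seed(61)
  base <- rnbinom(500, mu = 100, size = 20) + 1
  counts <- cbind(s1 = base, s2 = 2 * base)
  sf <- size_factors(counts)
  # oracle: with exact doubling, the geometric-mean reference makes the
  # factors (1/sqrt(2), sqrt(2))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
  expect_equal(prod(sf), 1, tolerance = 1e-10)
  same <- cbind(base, base, base)
  expect_equal(unname(size_factors(same)), c(1, 1, 1))
  expect_error(size_factors(cbind(c(0, 5), c(5, 0))), "pseudo")
})

test_that("identical groups give zero fold change and p near 1", {
  set.seed(62)
  a <- nb_mat(200, 100)
  res <- nb_two_group_test(a, a)
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$pvalue[!res$untestable] > 0.99))
  zero <- matrix(0, 2, 3)
  rz <- nb_two_group_test(zero, zero)
  expect_true(all(rz$untestable))
  expect_true(all(is.na(rz$pvalue)))
})

test_that("the NB test is calibrated under the null and powered at 8-fold", {
  set.seed(63)
  mu <- rlnorm(2000, log(150), 0.6)
  res <- nb_two_group_test(nb_mat(2000, mu), nb_mat(2000, mu))
  for (alpha in c(0.05, 0.01)) {
    frac <- mean(res$pvalue < alpha)
    expect_lt(abs(frac - alpha), 3 * sqrt(alpha * (1 - alpha) / 2000))
  }
  pow <- nb_two_group_test(nb_mat(2000, 50), nb_mat(2000, 400))
  expect_gte(mean(pow$pvalue < 0.01 & abs(pow$log2fc) > 2), 0.95)
})

test_that("the expression filter keeps genes expressed in both species", {
  p1 <- matrix(c(4, 4, 4, 4, 4, 4, 0, 0, 0), 3, 3, byrow = TRUE,
               dimnames = list(c("g1", "g2", "g3"), NULL))
  p2 <- matrix(c(5, 5, 5, 1, 1, 2, 9, 9, 9), 3, 3, byrow = TRUE,
               dimnames = list(c("g1", "g2", "g3"), NULL))
  expect_equal(expressed_filter(p1, p2), "g1")   # sums 12/15, 12/4, 0/27
  expect_setequal(expressed_filter(p1, p2, min_total = 0),
                  c("g1", "g2", "g3"))
})

test_that("MPV comparison separates additive from nonadditive genes", {
  set.seed(64)
  mu1 <- rep(100, 400); mu2 <- rep(300, 400)
  p1 <- nb_mat(400, mu1); p2 <- nb_mat(400, mu2)
  hy_add <- nb_mat(400, (mu1 + mu2) / 2)
  res <- mpv_comparison(p1, p2, hy_add)
  expect_gt(mean(res$additivity == "additive"), 0.97)
  # plant 30% of genes at a 4-fold deviation above the MPV (a global shift
  # would be absorbed by normalization, as in any count-based DE analysis)
  up <- seq_len(120)
  mu_h <- (mu1 + mu2) / 2
  mu_h[up] <- 4 * mu_h[up]
  res_up <- mpv_comparison(p1, p2, nb_mat(400, mu_h))
  recovered <- mean(res_up$additivity == "nonadditive_up")
  expect_lt(abs(recovered - 0.30), 0.05)
  expect_gt(mean(res_up$additivity[-up] == "additive"), 0.95)
  expect_error(mpv_comparison(p1[, 1:2], p2, hy_add), "equal replicate")
})

fake_test <- function(lfc, p) {
  data.frame(gene_id = paste0("g", seq_along(lfc)), log2fc = lfc,
             pvalue = p, untestable = FALSE, stringsAsFactors = FALSE)
}

test_that("the mode decision table matches its defining patterns", {
  # worked examples: P1=100, P2=400 (parents differ, lfc 2)
  sig <- 1e-6; ns <- 0.5
  # hybrid at the higher parent: != lower (lfc 2), == higher
  hpd <- classify_mode(fake_test(2, sig), fake_test(2, sig),
                       fake_test(0, ns))
  expect_equal(hpd$category, "high_parent_dominance")
  expect_equal(hpd$higher_parent, "parent2")
  # hybrid above both parents
  over <- classify_mode(fake_test(2, sig), fake_test(4, sig),
                        fake_test(2, sig))
  expect_equal(over$category, "overdominance")
  # no significant differences anywhere
  expect_equal(classify_mode(fake_test(0, ns), fake_test(0, ns),
                             fake_test(0, ns))$category, "conserved")
  # parents differ, hybrid between them and distinguishable from neither
  expect_equal(classify_mode(fake_test(1.5, sig), fake_test(0.7, ns),
                             fake_test(-0.8, ns))$category, "additive")
  # mirrored dominance
  lpd <- classify_mode(fake_test(2, sig), fake_test(0, ns),
                       fake_test(-2, sig))
  expect_equal(lpd$category, "low_parent_dominance")
  # hybrid below both
  expect_equal(classify_mode(fake_test(2, sig), fake_test(-2, sig),
                             fake_test(-4, sig))$category, "underdominance")
  # discordant pattern: hybrid above one parent and below the other
  expect_equal(classify_mode(fake_test(0.2, ns), fake_test(2, sig),
                             fake_test(-2, sig))$category, "ambiguous")
  # missing test: ambiguous
  na_test <- fake_test(0, NA)
  expect_equal(classify_mode(na_test, fake_test(2, sig),
                             fake_test(2, sig))$category, "ambiguous")
})

test_that("the decision table is total over all test-outcome combinations", {
  outcomes <- list(c(0, 0.5), c(1.5, 1e-6), c(-1.5, 1e-6),
                   c(0.5, 1e-6), c(3, 0.5))  # ns, sig+, sig-, sub-threshold
  cats <- c("conserved", "additive", "high_parent_dominance",
            "low_parent_dominance", "overdominance", "underdominance",
            "ambiguous")
  for (o12 in outcomes) for (o1 in outcomes) for (o2 in outcomes) {
    res <- classify_mode(fake_test(o12[1], o12[2]),
                         fake_test(o1[1], o1[2]),
                         fake_test(o2[1], o2[2]))
    expect_equal(length(res$category), 1)
    expect_true(res$category %in% cats)
  }
})

test_that("the model-based ASE test labels planted imbalance and respects symmetry", {
  set.seed(65)
  n <- 300
  tot <- sapply(1:3, function(i) rnbinom(n, mu = 500, size = 20))
  mat <- matrix(rbinom(3 * n, as.vector(tot), 0.8), n, 3)
  allelic <- data.frame(gene_id = rep(sprintf("g%03d", 1:n), 3),
                        replicate = rep(1:3, each = n),
                        maternal_count = as.vector(mat),
                        paternal_count = as.vector(tot - mat))
  res <- ase_model_test(allelic)
  expect_gte(mean(res$label == "maternal"), 0.95)
  # symmetric counts: balanced
  bal <- allelic
  bal$maternal_count <- bal$paternal_count
  expect_true(all(ase_model_test(bal)$label == "balanced"))
  # swapping the allelic columns swaps every label
  sw <- allelic
  sw[c("maternal_count", "paternal_count")] <-
    sw[c("paternal_count", "maternal_count")]
  res_sw <- ase_model_test(sw)
  flip <- c(maternal = "paternal", paternal = "maternal",
            balanced = "balanced")
  expect_identical(unname(flip[res$label]), res_sw$label)
})

test_that("the ASE ratio rule reproduces the worked replicate thresholds", {
  m <- matrix(c(0.80, 0.75, 0.50,   # maternal in 2 of 3
                0.20, 0.25, 0.80,   # paternal in 2 of 3
                0.50, 0.55, 0.45),  # balanced
              3, 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), NULL))
  res <- ase_ratio_call(m, 1 - m)
  expect_equal(res$label, c("maternal", "paternal", "balanced"))
  # ratio symmetry: r(m, p) = 1 - r(p, m) wherever defined
  r1 <- attr(ase_ratio_call(m, 1 - m), "ratios")
  r2 <- attr(ase_ratio_call(1 - m, m), "ratios")
  expect_equal(r1, 1 - r2)
  # zero-signal replicates are excluded; too few usable -> flagged balanced
  mz <- matrix(c(10, 0, 0), 1, 3)
  pz <- matrix(c(0, 0, 0), 1, 3)
  rz <- ase_ratio_call(mz, pz)
  expect_equal(rz$n_usable, 1)
  expect_true(rz$insufficient_data)
  expect_equal(rz$label, "balanced")
  expect_error(ase_ratio_call(m, 1 - m, hi = 0.3, lo = 0.7), "lo < hi")
  expect_error(ase_ratio_call(m, 1 - m, min_reps = 4), "min_reps")
})

test_that("reference averaging and copy summation are linear and flag gaps", {
  a <- matrix(10, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  b <- matrix(20, 2, 2, dimnames = list(c("g1", "g3"), c("s1", "s2")))
  avg <- average_across_references(a, b)
  expect_equal(avg$fpkm["g1", "s1"], 15)
  expect_true(avg$single_source[["g2"]])   # only under reference A
  expect_true(avg$single_source[["g3"]])
  # averaging commutes
  avg2 <- average_across_references(b, a)
  expect_equal(avg$fpkm["g1", ], avg2$fpkm["g1", ])
  expect_error(average_across_references(a, b,
                                         c(g1 = "g1", g2 = "g1")),
               "one-to-one")
  # copy summation
  f <- matrix(c(10, 5, 2), 3, 1, dimnames = list(c("c1", "c2", "c3"), "s1"))
  fam <- sum_gene_copies(f, c(c1 = "F1", c2 = "F1", c3 = "F2"))
  expect_equal(fam["F1", 1], 15)
  expect_warning(sum_gene_copies(f[1:2, , drop = FALSE],
                                 c(c1 = "F1", c2 = "F1", c9 = "F9")),
                 "no quantified")
  expect_error(sum_gene_copies(f, data.frame(copy = c("c1", "c1"),
                                             family = c("F1", "F2"))),
               "two families")
  # summing after averaging equals averaging after summing
  cmap <- c(g1 = "F1")
  s1 <- sum_gene_copies(average_across_references(a, b)$fpkm["g1", ,
                                                             drop = FALSE],
                        cmap)
  s2 <- (sum_gene_copies(a["g1", , drop = FALSE], cmap) +
           sum_gene_copies(b["g1", , drop = FALSE], cmap)) / 2
  expect_equal(s1, s2)
})

test_that("pathway percentages recompute exactly from their counts", {
  # 13 of 58 high-parent dominant and a 17-of-27 ASEG pathway
  genes58 <- sprintf("c%02d", 1:58)
  genes27 <- sprintf("a%02d", 1:27)
  modes <- data.frame(gene_id = c(genes58, genes27),
                      category = c(rep("high_parent_dominance", 13),
                                   rep("conserved", 45),
                                   rep("additive", 27)),
                      stringsAsFactors = FALSE)
  ase <- data.frame(gene_id = c(genes58, genes27),
                    label = c(rep("balanced", 58), rep("maternal", 10),
                              rep("paternal", 7), rep("balanced", 10)),
                    stringsAsFactors = FALSE)
  rep <- pathway_report(modes, ase,
                        list(chlorophyll = genes58, anthocyanin = genes27))
  cats <- rep$categories
  expect_equal(cats$percent[cats$pathway == "chlorophyll" &
                              cats$category == "high_parent_dominance"],
               22.41)
  s <- rep$summary
  expect_equal(s$percent_aseg[s$pathway == "anthocyanin"], 62.96)
  expect_equal(s$n_aseg[s$pathway == "anthocyanin"], 17)
  # percentages recompute from printed counts
  expect_equal(cats$percent,
               trioase:::round_half_up(100 * cats$n /
                                         s$size[match(cats$pathway,
                                                      s$pathway)]))
  # empty pathway: size 0, undefined percentage
  e <- pathway_report(modes, ase, list(empty = character(0)))
  expect_equal(e$summary$size, 0)
  expect_true(is.na(e$summary$percent_aseg))
})

test_that("NB test calls agree with an established count-based DE package", {
  skip_if_not_installed("DESeq2")
  set.seed(66)
  n <- 300
  mu_a <- rep(100, n)
  mu_b <- mu_a
  de_idx <- 1:100
  mu_b[de_idx] <- mu_a[de_idx] * 8
  a <- nb_mat(n, mu_a)
  b <- nb_mat(n, mu_b)
  mine <- nb_two_group_test(a, b)
  cts <- cbind(a, b)
  colnames(cts) <- paste0("s", 1:6)
  coldata <- data.frame(group = factor(rep(c("A", "B"), each = 3)))
  dds <- DESeq2::DESeqDataSetFromMatrix(cts, coldata, ~group)
  ref <- as.data.frame(DESeq2::results(suppressMessages(DESeq2::DESeq(dds,
                                                                      quiet = TRUE))))
  call_mine <- !is.na(mine$pvalue) & mine$pvalue < 0.01 & abs(mine$log2fc) > 2
  call_ref <- !is.na(ref$pvalue) & ref$pvalue < 0.01 &
    abs(ref$log2FoldChange) > 2
  # both routes detect nearly all planted 8-fold genes and almost no nulls
  expect_gte(mean(call_mine[de_idx]), 0.95)
  expect_gte(mean(call_ref[de_idx]), 0.95)
  expect_lte(mean(call_mine[-de_idx]), 0.05)
  expect_lte(mean(call_ref[-de_idx]), 0.05)
  # fold-change estimates track each other
  expect_gt(cor(mine$log2fc, ref$log2FoldChange), 0.95)
})
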