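test_that("canonical k-mer counting matches a plain enumeration oracle", {
  set.seed(1)
  for (k in c(11, 15, 21)) {
    s <- random_dna(300)
    got <- count_kmers(s, k)
    exp <- oracle_kmer_counts(s, k)
    expect_setequal(got$kmer, names(exp))
    expect_equal(got$count[order(got$kmer)],
                 as.integer(exp[sort(got$kmer)]), ignore_attr = TRUE)
    # canonicalization symmetry: reverse complement counts identically
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    got_rc <- count_kmers(rc, k)
    expect_equal(sort(got$kmer), sort(got_rc$kmer))
  }
})

test_that("degenerate k-mer inputs are handled", {
  expect_equal(length(count_kmers("ACGTA", 11)), 0)   # shorter than k
  expect_error(count_kmers("ACGT", 12), "odd")
  expect_error(count_kmers("ACGT", 9), "between")
  # windows containing non-ACGT symbols are skipped
  s <- random_dna(50)
  s_n <- paste0(substr(s, 1, 25), "N", substr(s, 26, 50))
  expect_lt(length(count_kmers(s_n, 11)), length(count_kmers(s, 11)) + 1)
})

test_that("solid k-mer window selection follows the histogram valley", {
  # dense histogram: error peak at 1, valley at 4, coverage peak at 30
  n_kmers <- c(1000, 120, 15, 4, 9, 12, 20, 35, 60, 90, 130, 170, 210, 250,
               280, 310, 330, 350, 365, 375, 385, 390, 394, 396, 397, 398,
               399, 399, 399, 400)
  expect_equal(trioase:::histogram_valley(n_kmers), 4)
  counts <- rep(seq_along(n_kmers), n_kmers)
  ks <- trioase:::kmer_set(sprintf("km%06d", seq_along(counts)), 21,
                           count = counts)
  solid <- solid_kmers(ks)
  # auto window = [4, 4 * 30]; multiplicities 1-3 are excluded
  expect_setequal(solid$kmer, ks$kmer[counts >= 4])
  expect_null(solid$count)
})

test_that("solid k-mer extraction validates thresholds", {
  ks <- trioase:::kmer_set(c("x", "y", "z"), 21, count = c(1, 5, 40))
  expect_setequal(solid_kmers(ks, 3, 10)$kmer, "y")
  expect_error(solid_kmers(ks, 10, 3), "low")
  mono <- trioase:::kmer_set(sprintf("k%03d", 1:60), 21,
                             count = rep(c(1, 2, 3), each = 20))
  expect_error(solid_kmers(mono), "interior minimum")
})

test_that("hap-mer derivation is the hybrid intersection minus the other parent", {
  ks <- function(x) trioase:::kmer_set(x, 21)
  hp <- derive_hapmers(ks(c("a", "b", "c")), ks(c("b", "d")),
                       ks(c("a", "b", "d", "e")))
  expect_setequal(hp$maternal$kmer, "a")
  expect_setequal(hp$paternal$kmer, "d")
  # identical parents share everything: no haplotype-specific sequence
  same <- derive_hapmers(ks(c("a", "b")), ks(c("a", "b")), ks(c("a", "b")))
  expect_equal(length(same$maternal), 0)
  expect_equal(length(same$paternal), 0)
  # hybrid disjoint from both parents
  disj <- derive_hapmers(ks("a"), ks("b"), ks("c"))
  expect_equal(length(disj$maternal) + length(disj$paternal), 0)
  expect_error(derive_hapmers(ks("a"), trioase:::kmer_set("b", 23), ks("c")),
               "mismatched k")
})

test_that("read classification follows the exclusive-evidence rule", {
  set.seed(2)
  mat_src <- random_dna(60)
  pat_src <- random_dna(60)
  hapmers <- structure(list(maternal = count_kmers(mat_src, 11),
                            paternal = count_kmers(pat_src, 11)),
                       class = "hapmer_pair")
  hapmers$maternal$count <- hapmers$paternal$count <- NULL
  read_m <- substring(mat_src, 10, 39)  # 30 bp, hits maternal only
  res <- classify_read(read_m, hapmers)
  # oracle: hand k-mer lookup
  exp_hits <- sum(names(oracle_kmer_counts(read_m, 11)) %in%
                    hapmers$maternal$kmer)
  expect_equal(res$n_mat, exp_hits)
  expect_gt(res$n_mat, 0)
  expect_equal(res$n_pat, 0)
  expect_equal(res$label, "maternal")
  # chimeric read hits both sets: ambiguous
  chim <- paste0(substring(mat_src, 1, 30), substring(pat_src, 1, 30))
  expect_equal(classify_read(chim, hapmers)$label, "ambiguous")
  # read matching neither set: ambiguous
  expect_equal(classify_read(random_dna(30), hapmers)$label, "ambiguous")
  # read shorter than k: ambiguous with zero evidence
  short <- classify_read("ACGTACGT", hapmers)
  expect_equal(short$label, "ambiguous")
  expect_equal(short$n_mat + short$n_pat, 0)
})

test_that("classify_read agrees with a brute-force implementation", {
  cfg <- sim_config(genome_length = 5000, n_genes = 5, coverage = 5,
                    read_length = 100, seed = 13)
  hap <- simulate_parental_haplotypes(cfg)
  k <- cfg$k
  sets <- lapply(list(m = hap$maternal, p = hap$paternal,
                      h = c(hap$maternal, hap$paternal)),
                 function(s) {
                   x <- count_kmers(s, k); x$count <- NULL; x
                 })
  hp <- derive_hapmers(sets$m, sets$p, sets$h)
  rd <- simulate_reads(hap$maternal, cfg, "mat")
  brute <- function(read) {
    km <- names(oracle_kmer_counts(read, k))
    nm <- sum(km %in% hp$maternal$kmer)
    np <- sum(km %in% hp$paternal$kmer)
    if (nm > 0 && np == 0) "maternal"
    else if (np > 0 && nm == 0) "paternal" else "ambiguous"
  }
  for (r in rd$reads[1:40])
    expect_equal(classify_read(r, hp)$label, brute(r))
})

test_that("binning conserves reads and flags unreadable records", {
  cfg <- tiny_config(seed = 21)
  hap <- simulate_parental_haplotypes(cfg)
  sets <- lapply(list(hap$maternal, hap$paternal,
                      c(hap$maternal, hap$paternal)),
                 function(s) solid_kmers(count_kmers(s, cfg$k), 1, Inf))
  hp <- derive_hapmers(sets[[1]], sets[[2]], sets[[3]])
  rd <- simulate_reads(hap$maternal, cfg, "mat")
  reads <- rd$reads[1:100]
  reads[5] <- NA
  reads[17] <- ""
  res <- suppressMessages(bin_reads(reads, hp))
  expect_equal(sum(res$summary$n), 100)
  expect_equal(res$summary$n[res$summary$bin == "skipped"], 2)
  empty <- bin_reads(character(0), hp)
  expect_equal(sum(empty$summary$n), 0)
})

test_that("identical parents make every read ambiguous", {
  cfg <- tiny_config(divergence = 0, seed = 22)
  hap <- simulate_parental_haplotypes(cfg)
  sets <- lapply(list(hap$maternal, hap$paternal,
                      c(hap$maternal, hap$paternal)),
                 function(s) solid_kmers(count_kmers(s, cfg$k), 1, Inf))
  hp <- derive_hapmers(sets[[1]], sets[[2]], sets[[3]])
  rd <- simulate_reads(hap$maternal, cfg, "mat")
  res <- bin_reads(rd$reads[1:300], hp)
  expect_true(all(res$labels == "ambiguous"))
})

test_that("binning accuracy does not increase with read error rate", {
  acc <- sapply(c(0, 0.05, 0.15), function(e) {
    cfg <- tiny_config(error_rate = e, seed = 23)
    hap <- simulate_parental_haplotypes(cfg)
    sets <- lapply(list(hap$maternal, hap$paternal,
                        c(hap$maternal, hap$paternal)),
                   function(s) solid_kmers(count_kmers(s, cfg$k), 1, Inf))
    hp <- derive_hapmers(sets[[1]], sets[[2]], sets[[3]])
    rd <- simulate_reads(hap$maternal, cfg, "mat")
    res <- bin_reads(rd$reads[1:500], hp)
    assigned <- res$labels != "ambiguous"
    if (!any(assigned)) return(0)
    mean(res$labels[assigned] == "maternal")
  })
  expect_true(all(diff(acc) <= 0.02))  # small slack for sampling noise
  expect_gt(acc[1], 0.99)
})

test_that("hap-mer sets are disjoint across random simulations", {
  for (seed in 1:3) {
    cfg <- sim_config(genome_length = 5000, n_genes = 5, seed = seed,
                      divergence = 0.1)
    hap <- simulate_parental_haplotypes(cfg)
    sets <- lapply(list(hap$maternal, hap$paternal,
                        c(hap$maternal, hap$paternal)),
                   function(s) solid_kmers(count_kmers(s, cfg$k), 1, Inf))
    hp <- derive_hapmers(sets[[1]], sets[[2]], sets[[3]])
    expect_equal(length(intersect(hp$maternal$kmer, hp$paternal$kmer)), 0)
  }
})

test_that("phasing QC metrics are exact on constructed sets", {
  k <- 21
  set.seed(31)
  genome <- random_dna(3000)
  asm_kmers <- count_kmers(genome, k)
  own <- trioase:::kmer_set(asm_kmers$kmer[1:100], k)
  other <- trioase:::kmer_set(setdiff(sprintf("%s", replicate(50, random_dna(k))),
                                      asm_kmers$kmer), k)
  hp <- structure(list(maternal = own, paternal = other),
                  class = "hapmer_pair")
  read_solid <- trioase:::kmer_set(asm_kmers$kmer, k)
  qc <- phasing_qc(genome, hp, read_solid, k, "maternal")
  expect_equal(qc$hapmer_recovery, 100)
  expect_equal(qc$hapmer_contamination, 0)
  expect_equal(qc$kmer_completeness, 100)
  # perfect assembly vs its own read k-mers: zero error, QV capped
  expect_equal(qc$e_error, 0)
  expect_equal(qc$qv, 99)
  # opposite hap-mers present in the assembly count as contamination
  hp2 <- structure(list(maternal = trioase:::kmer_set(asm_kmers$kmer[1:80], k),
                        paternal = trioase:::kmer_set(asm_kmers$kmer[81:100], k)),
                   class = "hapmer_pair")
  qc2 <- phasing_qc(genome, hp2, read_solid, k, "maternal")
  expect_equal(qc2$hapmer_contamination, 100 * 20 / 100)
  # degenerate empty assembly
  qc3 <- phasing_qc(character(0), hp, read_solid, k, "maternal")
  expect_true(qc3$degenerate)
  expect_equal(qc3$qv, 0)
})

test_that("QV follows the shared-fraction formula and responds to damage", {
  # worked value: shared fraction 0.99 at k = 21
  expect_equal(qv_from_shared(0.99, 21)$qv, -10 * log10(1 - 0.99^(1 / 21)))
  expect_equal(round(qv_from_shared(0.99, 21)$qv, 1), 33.2)
  expect_equal(qv_from_shared(1, 21)$qv, 99)
  # QV strictly decreases as error k-mers are injected into the assembly
  k <- 21
  set.seed(32)
  genome <- random_dna(5000)
  read_solid <- count_kmers(genome, k)
  read_solid$count <- NULL
  qvs <- sapply(c(0, 200, 600), function(n_err) {
    asm <- c(genome, if (n_err > 0) random_dna(n_err + k - 1))
    phasing_qc(asm, structure(list(maternal = trioase:::kmer_set(character(0), k),
                                   paternal = trioase:::kmer_set(character(0), k)),
                              class = "hapmer_pair"),
               read_solid, k, "maternal")$qv
  })
  expect_true(all(diff(qvs) < 0))
  # completeness decreases as assembly sequence is deleted
  comp <- sapply(c(5000, 3000, 1000), function(len) {
    phasing_qc(substring(genome, 1, len),
               structure(list(maternal = trioase:::kmer_set(character(0), k),
                              paternal = trioase:::kmer_set(character(0), k)),
                         class = "hapmer_pair"),
               read_solid, k, "maternal")$kmer_completeness
  })
  expect_true(all(diff(comp) < 0))
})

test_that("telomere scanning finds terminal tandem repeat runs", {
  set.seed(33)
  body <- gsub("TTTAGGG|CCCTAAA", "ATATATA", random_dna(10000))
  seq1 <- paste0(strrep("TTTAGGG", 15), body)
  res <- find_telomere_repeats(c(chrA = seq1))
  expect_equal(nrow(res), 1)
  expect_equal(res$n_repeats, 15)
  expect_equal(res$strand, "+")
  expect_equal(res$start, 0)
  expect_true(res$terminal)
  # motif-free sequence: empty result
  expect_equal(nrow(find_telomere_repeats(c(x = body))), 0)
  # reverse-strand copies at the 3' end
  seq2 <- paste0(body, strrep("CCCTAAA", 20))
  res2 <- find_telomere_repeats(c(chrB = seq2))
  expect_equal(nrow(res2), 1)
  expect_equal(res2$strand, "-")
  expect_equal(res2$n_repeats, 20)
  expect_equal(res2$end, nchar(seq2))
  # runs below min_repeats are not reported
  seq3 <- paste0(strrep("TTTAGGG", 5), body)
  expect_equal(nrow(find_telomere_repeats(c(chrC = seq3))), 0)
  expect_error(find_telomere_repeats(c(x = body), motif = "TTN"), "motif")
})
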