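# small shared simulation configs used across module tests
tiny_config <- function(...) {
  sim_config(genome_length = 20000, n_genes = 20, coverage = 20, ...)
}

# R-side oracle for canonical k-mer counting: plain substring enumeration
# plus per-k-mer reverse complement, independent of the package's engine
oracle_kmer_counts <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(table(character(0)))
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  ok <- !grepl("[^ACGT]", kmers)
  kmers <- kmers[ok]
  rc <- vapply(kmers, function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }, character(1))
  table(pmin(kmers, rc))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
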