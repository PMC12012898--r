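#' Count canonical k-mers
#'
#' Slides a window of length \code{k} over every input sequence and counts
#' canonical k-mers — each k-mer is represented by the lexicographic minimum
#' of itself and its reverse complement, so a sequence and its reverse
#' complement yield identical counts. Windows containing non-ACGT symbols are
#' skipped.
#'
#' @param x Character vector of sequences/reads (or a DNAStringSet).
#' @param k Odd k-mer length between 11 and 31 (default 21).
#' @return Object of class \code{"kmer_set"}: list with \code{k},
#'   \code{kmer} (character) and \code{count} (integer multiplicities;
#'   \code{NULL} for pure sets).
#' @export
count_kmers <- function(x, k = 21) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd (even k makes canonicalization ambiguous)")
  if (k < 11L || k > 31L) stop("k must be between 11 and 31")
  x <- as.character(x)
  res <- .count_kmers_cpp(x, k)
  kmer_set(res$kmer, k, count = res$count)
}

kmer_set <- function(kmer, k, count = NULL) {
  structure(list(k = as.integer(k), kmer = kmer, count = count),
            class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("kmer_set: %d canonical %d-mers%s\n", length(x$kmer), x$k,
              if (is.null(x$count)) "" else " (with multiplicities)"))
  invisible(x)
}

#' @export
length.kmer_set <- function(x) length(x$kmer)

#' Multiplicity histogram of a counted k-mer set
#'
#' @param ks A \code{kmer_set} with multiplicities.
#' @return data.frame with \code{multiplicity} and \code{n_kmers}, dense from
#'   1 to the maximum observed multiplicity.
#' @export
kmer_histogram <- function(ks) {
  stopifnot(inherits(ks, "kmer_set"))
  if (is.null(ks$count)) stop("kmer_set has no multiplicities")
  if (length(ks$count) == 0)
    return(data.frame(multiplicity = integer(), n_kmers = integer()))
  h <- tabulate(ks$count, nbins = max(ks$count))
  data.frame(multiplicity = seq_along(h), n_kmers = h)
}

# first interior minimum of a dense histogram (error valley), scanning up
# from multiplicity 1; NULL when the histogram is monotone
histogram_valley <- function(n_kmers) {
  m <- length(n_kmers)
  if (m < 3) return(NULL)
  for (i in 2:(m - 1)) {
    if (n_kmers[i] <= n_kmers[i - 1] && n_kmers[i] < n_kmers[i + 1]) return(i)
  }
  NULL
}

#' Extract solid k-mers from a counted set
#'
#' Solid k-mers are canonical k-mers whose multiplicity falls inside a
#' coverage window consistent with single-copy genomic sequence — above the
#' sequencing-error peak at low multiplicity and below the high-copy repeat
#' tail. When thresholds are omitted they are derived from the multiplicity
#' histogram: \code{low} is the first interior minimum between the error peak
#' and the main coverage peak, \code{high} is 4x the main peak multiplicity.
#'
#' @param ks A counted \code{kmer_set}.
#' @param low,high Multiplicity window (inclusive); \code{NULL} for automatic.
#' @return A pure \code{kmer_set} (no multiplicities).
#' @export
solid_kmers <- function(ks, low = NULL, high = NULL) {
  stopifnot(inherits(ks, "kmer_set"))
  if (is.null(ks$count)) stop("solid_kmers needs a counted kmer_set")
  if (is.null(low) || is.null(high)) {
    h <- kmer_histogram(ks)
    if (is.null(low)) {
      low <- histogram_valley(h$n_kmers)
      if (is.null(low))
        stop("histogram has no interior minimum; supply explicit low/high thresholds")
    }
    if (is.null(high)) {
      peak <- which.max(replace(h$n_kmers, seq_len(min(low - 1L,
                                                       nrow(h))), -1L))
      high <- 4L * peak
    }
  }
  if (low < 1 || low > high) stop("need 1 <= low <= high")
  keep <- ks$count >= low & ks$count <= high
  kmer_set(ks$kmer[keep], ks$k)
}

#' Derive haplotype-diagnostic hap-mers from the trio's solid k-mer sets
#'
#' Maternal hap-mers are solid k-mers shared by the maternal parent and the
#' hybrid but absent from the paternal parent's solid set (and symmetrically
#' for paternal hap-mers). Subtracting the other parent makes the two sets
#' disjoint, so a read carrying hap-mers of only one type gives unambiguous
#' evidence for that haplotype.
#'
#' @param solid_maternal,solid_paternal,solid_hybrid Pure \code{kmer_set}s of
#'   identical k.
#' @return Object of class \code{"hapmer_pair"}: list with disjoint
#'   \code{maternal} and \code{paternal} \code{kmer_set}s.
#' @export
derive_hapmers <- function(solid_maternal, solid_paternal, solid_hybrid) {
  ks <- list(solid_maternal, solid_paternal, solid_hybrid)
  stopifnot(all(vapply(ks, inherits, logical(1), "kmer_set")))
  kk <- vapply(ks, `[[`, integer(1), "k")
  if (length(unique(kk)) != 1) stop("mismatched k across solid k-mer sets")
  mat <- setdiff(intersect(solid_maternal$kmer, solid_hybrid$kmer),
                 solid_paternal$kmer)
  pat <- setdiff(intersect(solid_paternal$kmer, solid_hybrid$kmer),
                 solid_maternal$kmer)
  stopifnot(length(intersect(mat, pat)) == 0)
  structure(list(maternal = kmer_set(mat, kk[1]),
                 paternal = kmer_set(pat, kk[1])),
            class = "hapmer_pair")
}

#' @export
print.hapmer_pair <- function(x, ...) {
  cat(sprintf("hapmer_pair (k=%d): %d maternal, %d paternal hap-mers\n",
              x$maternal$k, length(x$maternal), length(x$paternal)))
  invisible(x)
}

hapmer_hits <- function(reads, hapmers) {
  stopifnot(inherits(hapmers, "hapmer_pair"))
  hits <- .kmer_hits_cpp(as.character(reads), hapmers$maternal$k,
                         hapmers$maternal$kmer, hapmers$paternal$kmer)
  colnames(hits) <- c("n_mat", "n_pat")
  hits
}

bin_label <- function(n_mat, n_pat) {
  ifelse(n_mat > 0 & n_pat == 0, "maternal",
         ifelse(n_pat > 0 & n_mat == 0, "paternal", "ambiguous"))
}

#' Classify one read against a hap-mer pair
#'
#' Counts the read's canonical k-mers found in each hap-mer set and applies
#' the exclusive-evidence rule: a read is maternal (paternal) only when it
#' contains hap-mers of that type and none of the other; reads hitting both
#' sets or neither — including reads shorter than k — are ambiguous.
#'
#' @param read_sequence Character scalar.
#' @param hapmers A \code{hapmer_pair}.
#' @return List with \code{label} (\code{"maternal"}, \code{"paternal"} or
#'   \code{"ambiguous"}), \code{n_mat}, \code{n_pat}.
#' @export
classify_read <- function(read_sequence, hapmers) {
  hits <- hapmer_hits(read_sequence, hapmers)
  list(label = unname(bin_label(hits[1, 1], hits[1, 2])),
       n_mat = unname(hits[1, 1]), n_pat = unname(hits[1, 2]))
}

#' Trio-bin a read set into maternal, paternal and ambiguous groups
#'
#' Applies [classify_read()] to every read. Records that are missing or empty
#' are counted as skipped; every other read lands in exactly one bin, so
#' maternal + paternal + ambiguous + skipped equals the input size.
#'
#' @param reads Named character vector of read sequences.
#' @param hapmers A \code{hapmer_pair}.
#' @param out_dir Optional directory; when given, three FASTQ files
#'   (\code{maternal.fastq}, \code{paternal.fastq}, \code{ambiguous.fastq})
#'   are written.
#' @return List with \code{labels} (named character), \code{hits} (integer
#'   matrix n_mat/n_pat) and \code{summary} (data.frame bin/n/fraction,
#'   including skipped).
#' @export
bin_reads <- function(reads, hapmers, out_dir = NULL) {
  n_in <- length(reads)
  bad <- is.na(reads) | !nzchar(reads)
  if (any(bad)) message(sum(bad), " unreadable read record(s) skipped")
  ok <- reads[!bad]
  labels <- character(0)
  hits <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("n_mat", "n_pat")))
  if (length(ok)) {
    hits <- hapmer_hits(ok, hapmers)
    labels <- setNames(bin_label(hits[, 1], hits[, 2]), names(ok))
  }
  bins <- c("maternal", "paternal", "ambiguous")
  n <- c(vapply(bins, function(b) sum(labels == b), integer(1)), sum(bad))
  summary <- data.frame(bin = c(bins, "skipped"), n = n,
                        fraction = if (n_in) n / n_in else rep(0, 4))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (b in bins) {
      sel <- ok[labels == b]
      if (length(sel)) write_fastq(sel, file.path(out_dir, paste0(b, ".fastq")))
    }
  }
  list(labels = labels, hits = hits, summary = summary)
}

#' Phred-scaled assembly QV from a shared k-mer fraction
#'
#' Under the model that each assembly base is correct independently with
#' probability \eqn{P}, a k-mer is error-free with probability \eqn{P^k};
#' equating \eqn{P^k} with the observed fraction of assembly k-mers supported
#' by the read set gives \eqn{P = f^{1/k}}, error rate \eqn{E = 1 - P}, and
#' \eqn{QV = -10 \log_{10} E}. A zero error rate is capped at QV 99.
#'
#' @param shared_fraction Fraction of assembly k-mers found in the read set.
#' @param k K-mer length.
#' @return List with \code{p_correct}, \code{e_error}, \code{qv}.
#' @export
qv_from_shared <- function(shared_fraction, k) {
  p <- shared_fraction^(1 / k)
  e <- 1 - p
  qv <- if (e <= 0) 99 else min(99, -10 * log10(e))
  list(p_correct = p, e_error = e, qv = qv)
}

#' Phasing and consensus quality control of a haplotype assembly
#'
#' Computes the hap-mer based phasing metrics and the k-mer based consensus
#' QV for one haplotype assembly:
#' \describe{
#'   \item{hapmer_recovery}{percent of the assembly's own hap-mers present in
#'     the assembly.}
#'   \item{hapmer_contamination}{percent of hap-mers present in the assembly
#'     that belong to the opposite haplotype (denominator: hap-mers of either
#'     type present, so the two per-assembly percentages sum to 100).}
#'   \item{kmer_completeness}{percent of the solid read k-mers represented in
#'     the assembly.}
#'   \item{qv}{Phred-scaled per-base correctness from the fraction of
#'     distinct assembly k-mers supported by the read set
#'     (see [qv_from_shared()]).}
#' }
#'
#' @param assembly_sequence Character vector of assembly sequences.
#' @param hapmers A \code{hapmer_pair}.
#' @param read_solid Pure \code{kmer_set} of solid read k-mers.
#' @param k K-mer length (must match the sets).
#' @param haplotype Which haplotype the assembly represents
#'   (\code{"maternal"} or \code{"paternal"}).
#' @return Object of class \code{"phasing_qc"}: list with the four metrics,
#'   \code{p_correct}, \code{e_error} and a \code{degenerate} flag for empty
#'   input.
#' @export
phasing_qc <- function(assembly_sequence, hapmers, read_solid, k,
                       haplotype = c("maternal", "paternal")) {
  haplotype <- match.arg(haplotype)
  stopifnot(inherits(hapmers, "hapmer_pair"), inherits(read_solid, "kmer_set"))
  if (k != hapmers$maternal$k || k != read_solid$k)
    stop("inconsistent k across inputs")
  asm_len <- sum(nchar(assembly_sequence))
  if (length(assembly_sequence) == 0 || asm_len < k) {
    out <- list(hapmer_recovery = 0, hapmer_contamination = 0,
                kmer_completeness = 0, qv = 0, p_correct = 0, e_error = 1,
                degenerate = TRUE)
    return(structure(out, class = "phasing_qc"))
  }
  asm <- count_kmers(assembly_sequence, k)$kmer
  own <- hapmers[[haplotype]]$kmer
  other <- hapmers[[setdiff(c("maternal", "paternal"), haplotype)]]$kmer
  own_in <- sum(own %in% asm)
  other_in <- sum(other %in% asm)
  either <- own_in + other_in
  recovery <- if (length(own)) 100 * own_in / length(own) else 0
  contamination <- if (either) 100 * other_in / either else 0
  completeness <- if (length(read_solid$kmer))
    100 * sum(read_solid$kmer %in% asm) / length(read_solid$kmer) else 0
  shared <- sum(asm %in% read_solid$kmer) / length(asm)
  qv <- qv_from_shared(shared, k)
  structure(list(hapmer_recovery = recovery,
                 hapmer_contamination = contamination,
                 kmer_completeness = completeness,
                 qv = qv$qv, p_correct = qv$p_correct, e_error = qv$e_error,
                 degenerate = FALSE),
            class = "phasing_qc")
}

#' @export
print.phasing_qc <- function(x, ...) {
  cat(sprintf(paste0("phasing QC%s\n  hap-mer recovery:      %6.2f%%\n",
                     "  hap-mer contamination: %6.2f%%\n",
                     "  k-mer completeness:    %6.2f%%\n",
                     "  consensus QV:          %6.2f\n"),
              if (x$degenerate) " [degenerate input]" else "",
              x$hapmer_recovery, x$hapmer_contamination,
              x$kmer_completeness, x$qv))
  invisible(x)
}

scan_motif_runs <- function(sequence, motif, max_gap) {
  starts <- gregexpr(motif, sequence, fixed = TRUE)[[1]]
  if (starts[1] == -1) return(NULL)
  w <- nchar(motif)
  gap_before <- c(Inf, starts[-1] - (starts[-length(starts)] + w))
  run <- cumsum(gap_before > max_gap)
  data.frame(start = tapply(starts, run, min) - 1L,       # 0-based
             end = tapply(starts, run, max) + w - 1L,     # half-open
             n_repeats = as.integer(table(run)))
}

#' Scan sequences for tandem telomere motif repeats
#'
#' Finds maximal runs of the telomere motif (forward strand) and of its
#' reverse complement (reverse strand) in which consecutive copies are
#' separated by at most \code{max_gap} bases. Runs with at least
#' \code{min_repeats} copies are reported, with a terminal flag when the run
#' starts or ends within \code{terminal_window} of a sequence end —
#' the signature of a telomere-to-telomere chromosome.
#'
#' @param sequences Named character vector of sequences.
#' @param motif Telomere repeat motif (default the plant motif TTTAGGG).
#' @param min_repeats Minimum copies per reported region (default 10).
#' @param max_gap Maximum gap between consecutive copies in bp (default 100).
#' @param terminal_window Distance from a sequence end within which a region
#'   counts as terminal (default 10 kb).
#' @return data.frame with \code{seqid}, 0-based half-open \code{start} and
#'   \code{end}, \code{strand}, \code{n_repeats}, \code{terminal}.
#' @export
find_telomere_repeats <- function(sequences, motif = "TTTAGGG",
                                  min_repeats = 10, max_gap = 100,
                                  terminal_window = 10000) {
  if (!nzchar(motif) || grepl("[^ACGT]", motif))
    stop("motif must be a non-empty string over A/C/G/T")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  out <- list()
  for (id in names(sequences)) {
    seq <- sequences[[id]]
    for (strand in c("+", "-")) {
      m <- if (strand == "+") motif else revcomp(motif)
      runs <- scan_motif_runs(seq, m, max_gap)
      if (is.null(runs)) next
      runs <- runs[runs$n_repeats >= min_repeats, , drop = FALSE]
      if (!nrow(runs)) next
      runs$seqid <- id
      runs$strand <- strand
      runs$terminal <- runs$start < terminal_window |
        (nchar(seq) - runs$end) < terminal_window
      out[[length(out) + 1]] <- runs
    }
  }
  if (!length(out)) {
    return(data.frame(seqid = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_repeats = integer(), terminal = logical()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$seqid, res$start),
             c("seqid", "start", "end", "strand", "n_repeats", "terminal")]
  rownames(res) <- NULL
  res
}
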