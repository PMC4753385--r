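#' Read-level filter configuration
#'
#' Thresholds for the three read filters applied before window counting:
#' mean base quality, sequence complexity, and mapping uniqueness. The
#' defaults are toolkit choices exposed for tuning, not values taken from
#' any particular study.
#'
#' @param min_mean_quality Minimum arithmetic mean Phred score (default 20).
#' @param complexity_method `"entropy"` (Shannon entropy of mononucleotide
#'   frequencies, bits) or `"dust"` (triplet over-representation score).
#' @param min_entropy_bits Entropy pass threshold in bits, in \[0, 2\]
#'   (default 1.0).
#' @param max_dust_score DUST pass threshold on the 0–100 scale (default 7).
#' @param uniqueness_rule `"tag_based"` (alignment count from the `NH` tag /
#'   secondary flags) or `"mapq_threshold"` (MAPQ proxy).
#' @param min_mapq MAPQ cutoff for the proxy rule (default 30).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_mean_quality = 20,
                          complexity_method = c("entropy", "dust"),
                          min_entropy_bits = 1.0,
                          max_dust_score = 7,
                          uniqueness_rule = c("tag_based", "mapq_threshold"),
                          min_mapq = 30L) {
  complexity_method <- match.arg(complexity_method)
  uniqueness_rule <- match.arg(uniqueness_rule)
  stopifnot(min_entropy_bits >= 0, min_entropy_bits <= 2,
            max_dust_score >= 0, min_mapq >= 0)
  structure(list(min_mean_quality = min_mean_quality,
                 complexity_method = complexity_method,
                 min_entropy_bits = min_entropy_bits,
                 max_dust_score = max_dust_score,
                 uniqueness_rule = uniqueness_rule,
                 min_mapq = as.integer(min_mapq)),
            class = "filter_config")
}

#' Mean-quality filter
#'
#' A read passes iff the arithmetic mean of its per-base Phred scores is at
#' least the threshold (the boundary is inclusive).
#'
#' @param qualities A list/[IRanges::IntegerList] of per-base Phred scores, a
#'   numeric vector of precomputed means, or a
#'   [Biostrings::QualityScaledDNAStringSet].
#' @param min_mean_quality Threshold on the Phred scale.
#' @return Logical vector: `TRUE` = pass.
#' @export
mean_quality_filter <- function(qualities, min_mean_quality = 20) {
  if (methods::is(qualities, "QualityScaledDNAStringSet")) {
    qualities <- methods::as(Biostrings::quality(qualities), "IntegerList")
  }
  if (is.list(qualities) || methods::is(qualities, "IntegerList")) {
    means <- vapply(qualities, function(q) mean(as.numeric(q)), numeric(1))
  } else if (is.numeric(qualities)) {
    means <- qualities
  } else {
    stop("per-base Phred scores are required for the quality filter; ",
         "supply qualities or disable the filter")
  }
  if (anyNA(means)) {
    stop("missing quality scores with the quality filter enabled")
  }
  means >= min_mean_quality
}

#' Shannon entropy of mononucleotide frequencies
#'
#' Entropy in bits over the symbols actually present; `N` counts as a fifth
#' symbol. A homopolymer scores 0; a sequence with equal A/C/G/T counts
#' scores 2 bits.
#'
#' @param seqs Character vector or [Biostrings::DNAStringSet].
#' @return Numeric vector of entropies (bits).
#' @export
shannon_entropy <- function(seqs) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  freq <- Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T", "N"))
  tot <- rowSums(freq)
  p <- freq / ifelse(tot == 0, 1, tot)
  ent <- -rowSums(ifelse(p > 0, p * log2(p), 0))
  as.numeric(ent)
}

#' DUST-style low-complexity score
#'
#' Over-representation of overlapping trinucleotides, normalised to 0–100:
#' `100 * sum(c_t * (c_t - 1) / 2) / (m * (m - 1) / 2)` where `c_t` are the
#' counts of each distinct triplet and `m` the number of counted triplets.
#' Triplets containing `N` are skipped. A homopolymer scores 100; random
#' sequence scores near 0. Sequences yielding fewer than 2 countable
#' triplets score 0.
#'
#' @param seqs Character vector or [Biostrings::DNAStringSet].
#' @return Numeric vector of scores in \[0, 100\].
#' @export
dust_score <- function(seqs) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  tri <- Biostrings::oligonucleotideFrequency(seqs, width = 3L)
  m <- rowSums(tri)
  num <- rowSums(tri * (tri - 1) / 2)
  den <- m * (m - 1) / 2
  score <- ifelse(den > 0, 100 * num / den, 0)
  as.numeric(score)
}

#' Sequence-complexity filter
#'
#' Dispatches on the configured method: entropy (pass iff entropy >=
#' `min_entropy_bits`) or DUST (pass iff score <= `max_dust_score`). The
#' entropy score is invariant to permuting the bases of a read; the DUST
#' score is not (it sees local triplet structure).
#'
#' @param seqs Character vector or [Biostrings::DNAStringSet] over
#'   `{A,C,G,T,N}`.
#' @param config A [filter_config()].
#' @return Logical vector: `TRUE` = pass.
#' @export
complexity_filter <- function(seqs, config = filter_config()) {
  if (config$complexity_method == "entropy") {
    shannon_entropy(seqs) >= config$min_entropy_bits
  } else {
    dust_score(seqs) <= config$max_dust_score
  }
}

#' Unique-mapper filter
#'
#' Extracts reads that map exactly once. `tag_based` keeps reads whose
#' reported alignment count is 1: `NH == 1` when the tag is present,
#' otherwise a single record per read name with no secondary/supplementary
#' flag. `mapq_threshold` keeps primary records with MAPQ at or above
#' `min_mapq`, a common proxy when the aligner does not report counts.
#'
#' @param aln Alignment data frame from [load_alignments()].
#' @param config A [filter_config()].
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @return A mapped-read data frame of the retained reads.
#' @export
unique_mapper_filter <- function(aln, config = filter_config(), genome) {
  stopifnot(methods::is(genome, "Seqinfo"))
  primary <- !bitwAnd(aln$flag, 0x100L) & !bitwAnd(aln$flag, 0x800L)
  if (config$uniqueness_rule == "tag_based") {
    has_info <- !all(is.na(aln$nh)) || any(duplicated(aln$qname)) ||
      any(bitwAnd(aln$flag, 0x100L) > 0L) || any(bitwAnd(aln$flag, 0x800L) > 0L)
    if (nrow(aln) > 0L && !has_info) {
      stop("no multiplicity information (NH tag or secondary records) in ",
           "the alignments; use uniqueness_rule = \"mapq_threshold\"")
    }
    keep <- primary & aln$is_unique
  } else {
    keep <- primary & !is.na(aln$mapq) & aln$mapq >= config$min_mapq
  }
  mapped_reads(aln$chrom[keep], aln$start[keep], is_unique = TRUE,
               read_id = aln$qname[keep], genome = genome)
}

#' Filter report: where did each read go?
#'
#' Partition of the input reads over the three filters, applied in the fixed
#' order quality -> complexity -> uniqueness; a read is counted once, at its
#' first failure, so the four failure/pass counts always sum to the input.
#'
#' @param n_input,n_fail_quality,n_fail_complexity,n_fail_uniqueness,n_pass
#'   Non-negative counts.
#' @return A list of class `filter_report`.
#' @export
filter_report <- function(n_input, n_fail_quality = 0L, n_fail_complexity = 0L,
                          n_fail_uniqueness = 0L, n_pass) {
  counts <- c(n_input, n_fail_quality, n_fail_complexity, n_fail_uniqueness,
              n_pass)
  if (any(counts < 0)) stop("filter counts must be non-negative")
  if (n_input != n_fail_quality + n_fail_complexity + n_fail_uniqueness + n_pass) {
    stop("filter report does not partition the input: ", n_input, " != ",
         n_fail_quality, " + ", n_fail_complexity, " + ",
         n_fail_uniqueness, " + ", n_pass)
  }
  structure(list(n_input = n_input, n_fail_quality = n_fail_quality,
                 n_fail_complexity = n_fail_complexity,
                 n_fail_uniqueness = n_fail_uniqueness, n_pass = n_pass),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Read filter report\n")
  cat(sprintf("  input             %10d\n", x$n_input))
  cat(sprintf("  failed quality    %10d\n", x$n_fail_quality))
  cat(sprintf("  failed complexity %10d\n", x$n_fail_complexity))
  cat(sprintf("  failed uniqueness %10d\n", x$n_fail_uniqueness))
  cat(sprintf("  passed            %10d\n", x$n_pass))
  invisible(x)
}

#' Serialise a filter report as JSON
#'
#' @param report A [filter_report()].
#' @param path Optional output path; omitted, the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
filter_report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Run the quality and complexity filters over a FASTQ file
#'
#' Applies the sequence-level stages (quality, then complexity) in the fixed
#' report order and returns the passing reads plus the partial report
#' (uniqueness is an alignment-level stage and is reported separately by
#' [unique_mapper_filter()]).
#'
#' @param path FASTQ path.
#' @param config A [filter_config()].
#' @return List with `seqs` (passing [Biostrings::QualityScaledDNAStringSet])
#'   and `report` (a [filter_report()] with `n_fail_uniqueness = 0`).
#' @export
filter_fastq_reads <- function(path, config = filter_config()) {
  reads <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      # Biostrings warns when it drops FASTQ mcols during construction;
      # nothing the filter uses is lost
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  n <- length(reads)
  pass_q <- mean_quality_filter(reads, config$min_mean_quality)
  after_q <- reads[pass_q]
  pass_c <- complexity_filter(after_q, config)  # QSDNAStringSet is a DNAStringSet
  report <- filter_report(n_input = n,
                          n_fail_quality = sum(!pass_q),
                          n_fail_complexity = sum(!pass_c),
                          n_fail_uniqueness = 0L,
                          n_pass = sum(pass_c))
  list(seqs = after_q[pass_c], report = report)
}
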