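#' Build a genome index from chromosome names and lengths
#'
#' The genome index is the coordinate universe for every downstream step:
#' window grids, integrity scores and ideograms all iterate chromosomes in
#' index order. It is represented as a [GenomeInfoDb::Seqinfo] object.
#'
#' @param chrom Character vector of chromosome names (must be unique).
#' @param length Integer vector of chromosome lengths in bp (all >= 1).
#' @return A [GenomeInfoDb::Seqinfo] with one entry per chromosome, in the
#'   order given.
#' @examples
#' genome_index(c("chr1", "chr2"), c(500L, 250L))
#' @export
genome_index <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) {
    stop("genome index is empty: no sequences supplied")
  }
  dup <- chrom[duplicated(chrom)]
  if (length(dup) > 0L) {
    stop("duplicate sequence name(s) in genome index: ",
         paste(unique(dup), collapse = ", "))
  }
  if (any(is.na(length)) || any(length < 1)) {
    stop("all chromosome lengths must be >= 1")
  }
  GenomeInfoDb::Seqinfo(seqnames = chrom, seqlengths = as.integer(length))
}

#' Load a genome index from FASTA or a two-column chrom/length table
#'
#' For FASTA input only the sequence lengths are extracted (via
#' [Biostrings::fasta.seqlengths]); the sequences themselves are not kept in
#' memory. A tab-separated two-column table (name, length; no header) is
#' accepted as a lighter alternative. Entry order follows file order.
#'
#' @param path Path to a FASTA file (`.fa`, `.fasta`, `.fna`, or content
#'   starting with `>`) or a 2-column TSV.
#' @return A [GenomeInfoDb::Seqinfo].
#' @export
load_genome_index <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty genome source: ", path)
  if (is_fasta_file(path)) {
    lens <- Biostrings::fasta.seqlengths(path)
    names(lens) <- sub("\\s.*$", "", names(lens))
    if (length(lens) == 0L) stop("no sequences found in FASTA: ", path)
    genome_index(names(lens), lens)
  } else {
    tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                             colClasses = c("character", "numeric"))
    if (ncol(tab) < 2L) stop("chrom/length table must have two columns: ", path)
    genome_index(tab[[1L]], tab[[2L]])
  }
}

is_fasta_file <- function(path) {
  if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE)) return(TRUE)
  first <- readLines(path, n = 1L, warn = FALSE)
  length(first) == 1L && startsWith(first, ">")
}

#' Write a genome index as a two-column chrom/length table
#'
#' Round-trips exactly through [load_genome_index()].
#'
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @param path Output path (TSV, no header).
#' @return `path`, invisibly.
#' @export
write_genome_index <- function(genome, path) {
  stopifnot(methods::is(genome, "Seqinfo"))
  utils::write.table(
    data.frame(chrom = GenomeInfoDb::seqnames(genome),
               length = GenomeInfoDb::seqlengths(genome)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load genome sequences from FASTA
#'
#' Needed by the in-silico sampler and the pool simulator; names are
#' truncated at the first whitespace to match index names.
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
load_genome_sequences <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup) > 0L) {
    stop("duplicate sequence name(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  }
  seqs
}

.known_stains <- c("gneg", "gpos25", "gpos50", "gpos75", "gpos100",
                   "acen", "gvar", "stalk")

#' Load a UCSC-style cytoband table
#'
#' Reads the 5-column `cytoBand.txt` dialect (chrom, chromStart, chromEnd,
#' name, gieStain; 0-based half-open coordinates, tab-separated, no header).
#' Bands on chromosomes absent from the genome index are dropped with a
#' warning; overlapping or inverted bands are hard errors.
#'
#' @param path Path to the band table. An empty file yields an empty result
#'   (ideograms are then drawn band-less).
#' @param genome A [GenomeInfoDb::Seqinfo] defining the coordinate universe.
#' @return A [GenomicRanges::GRanges] sorted by chromosome (index order) and
#'   start, with metadata columns `band` and `stain`.
#' @export
load_cytobands <- function(path, genome) {
  stopifnot(methods::is(genome, "Seqinfo"))
  if (!file.exists(path)) stop("no such file: ", path)
  empty <- GenomicRanges::GRanges(seqinfo = genome)
  empty$band <- character(0)
  empty$stain <- character(0)
  if (file.size(path) == 0L) return(empty)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = c("character", "numeric", "numeric",
                                          "character", "character"))
  if (ncol(tab) < 5L) stop("cytoband table must have 5 columns: ", path)
  names(tab) <- c("chrom", "start", "end", "band", "stain")
  cytobands(tab, genome)
}

#' Validate and build a cytoband set from a data frame
#'
#' @param tab Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `band`, `stain`.
#' @inheritParams load_cytobands
#' @return See [load_cytobands()].
#' @export
cytobands <- function(tab, genome) {
  stopifnot(methods::is(genome, "Seqinfo"))
  bad_stain <- setdiff(unique(tab$stain), .known_stains)
  if (length(bad_stain) > 0L) {
    stop("unknown gieStain value(s): ", paste(bad_stain, collapse = ", "),
         " (allowed: ", paste(.known_stains, collapse = ", "), ")")
  }
  if (any(tab$end <= tab$start)) {
    i <- which(tab$end <= tab$start)[1L]
    stop(sprintf("cytoband with end <= start: %s:%d-%d (%s)",
                 tab$chrom[i], tab$start[i], tab$end[i], tab$band[i]))
  }
  known <- tab$chrom %in% GenomeInfoDb::seqnames(genome)
  if (any(!known)) {
    warning(sum(!known), " band(s) on chromosomes absent from the genome index dropped: ",
            paste(unique(tab$chrom[!known]), collapse = ", "))
    tab <- tab[known, , drop = FALSE]
  }
  lens <- GenomeInfoDb::seqlengths(genome)[tab$chrom]
  if (any(tab$start < 0) || any(tab$end > lens)) {
    i <- which(tab$start < 0 | tab$end > lens)[1L]
    stop(sprintf("cytoband outside chromosome bounds: %s:%d-%d (%s)",
                 tab$chrom[i], tab$start[i], tab$end[i], tab$band[i]))
  }
  # per-chromosome overlap check on sorted bands
  ord <- order(match(tab$chrom, GenomeInfoDb::seqnames(genome)), tab$start)
  tab <- tab[ord, , drop = FALSE]
  for (ch in unique(tab$chrom)) {
    sub <- tab[tab$chrom == ch, , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)])) {
      stop("overlapping cytobands on ", ch)
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(tab$chrom, levels = GenomeInfoDb::seqnames(genome)),
    ranges = IRanges::IRanges(start = tab$start + 1L, end = tab$end),
    seqinfo = genome)
  gr$band <- tab$band
  gr$stain <- tab$stain
  gr
}

#' Write a cytoband set back to the UCSC 5-column dialect
#'
#' @param bands A `GRanges` as returned by [load_cytobands()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytobands <- function(bands, path) {
  utils::write.table(
    data.frame(chrom = as.character(GenomicRanges::seqnames(bands)),
               start = GenomicRanges::start(bands) - 1L,
               end = GenomicRanges::end(bands),
               band = bands$band,
               stain = bands$stain),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a mapped-read table
#'
#' The internal read representation is a plain data frame with 0-based start
#' coordinates (`chrom`, `start`, `is_unique`, `read_id`); every constructor
#' validates reads against the genome index.
#'
#' @param chrom Chromosome names.
#' @param start 0-based start positions.
#' @param is_unique Logical: does the read map uniquely?
#' @param read_id Read identifiers.
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @return A `data.frame` of mapped reads.
#' @export
mapped_reads <- function(chrom, start, is_unique = TRUE, read_id = NULL,
                         genome) {
  stopifnot(methods::is(genome, "Seqinfo"))
  chrom <- as.character(chrom)
  start <- as.integer(start)
  n <- length(chrom)
  if (is.null(read_id)) read_id <- sprintf("read_%d", seq_len(n))
  reads <- data.frame(chrom = chrom, start = start,
                      is_unique = rep_len(as.logical(is_unique), n),
                      read_id = as.character(read_id))
  unknown <- !(reads$chrom %in% GenomeInfoDb::seqnames(genome))
  if (any(unknown)) {
    stop("reads on chromosome(s) absent from the genome index: ",
         paste(unique(reads$chrom[unknown]), collapse = ", "))
  }
  lens <- GenomeInfoDb::seqlengths(genome)[reads$chrom]
  if (any(reads$start < 0L | reads$start >= lens)) {
    stop("read start outside chromosome bounds")
  }
  reads
}

#' Load mapped reads from BED3 or SAM/BAM
#'
#' BED records are taken at face value (each treated as a unique mapper; the
#' quality/complexity filters cannot run without sequence). SAM/BAM goes
#' through [load_alignments()]: unmapped records are skipped, 1-based `POS`
#' is converted to the 0-based internal convention, and uniqueness is
#' decided from the `NH` tag when present, otherwise from the absence of
#' secondary/supplementary records for the read name. Reads on chromosomes
#' absent from the index are skipped; their number is reported as a warning
#' and attached as `attr(, "n_skipped_unknown")`.
#'
#' @param path A `.bed`, `.sam` or `.bam` file.
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @return A mapped-read `data.frame` (see [mapped_reads()]).
#' @export
load_mapped_reads <- function(path, genome) {
  stopifnot(methods::is(genome, "Seqinfo"))
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    load_bed_reads(path, genome)
  } else if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE)) {
    aln <- load_alignments(path, genome)
    keep_primary <- !bitwAnd(aln$flag, 0x100L) & !bitwAnd(aln$flag, 0x800L)
    reads <- mapped_reads(aln$chrom[keep_primary], aln$start[keep_primary],
                          is_unique = aln$is_unique[keep_primary],
                          read_id = aln$qname[keep_primary], genome = genome)
    attr(reads, "n_skipped_unknown") <- attr(aln, "n_skipped_unknown")
    reads
  } else {
    stop("unrecognised alignment format (expect .bed, .sam or .bam): ", path)
  }
}

load_bed_reads <- function(path, genome) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(mapped_reads(character(0), integer(0), genome = genome))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED record at line ", which(nf < 3L)[1L],
         ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | end <= start
  if (any(bad)) {
    stop("malformed BED record at line ", which(bad)[1L],
         ": non-numeric or inverted interval")
  }
  known <- chrom %in% GenomeInfoDb::seqnames(genome)
  n_skipped <- sum(!known)
  if (n_skipped == length(chrom)) {
    stop("no BED record matches any genome-index chromosome; ",
         "check for a naming-scheme mismatch (e.g. 'chr1' vs '1') ",
         "and supply a rename mapping if needed")
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " BED record(s) on unknown chromosomes skipped")
  }
  reads <- mapped_reads(chrom[known], start[known],
                        read_id = sprintf("bed_%d", which(known)),
                        genome = genome)
  attr(reads, "n_skipped_unknown") <- n_skipped
  reads
}

#' Load alignment records from SAM/BAM
#'
#' Plain SAM text is converted through [Rsamtools::asBam] (a header with
#' `@SQ` lines is required), then records are read with [Rsamtools::scanBam]
#' including the `NH` (number of reported alignments) tag. Unmapped records
#' are dropped. Per-record uniqueness (`is_unique`) is `NH == 1` when the
#' tag is present; otherwise a read is unique iff its name has a single
#' record and no secondary/supplementary flag anywhere.
#'
#' @param path `.sam` or `.bam` file.
#' @param genome A [GenomeInfoDb::Seqinfo].
#' @return Data frame with columns `qname`, `flag`, `chrom`, `start`
#'   (0-based), `mapq`, `nh`, `is_unique`; attribute `n_skipped_unknown`
#'   counts mapped records on chromosomes absent from the index.
#' @export
load_alignments <- function(path, genome) {
  stopifnot(methods::is(genome, "Seqinfo"))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq"), tag = "NH")
  rec <- Rsamtools::scanBam(bam, param = param)[[1L]]
  nh <- rec$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, length(rec$qname))
  aln <- data.frame(qname = rec$qname, flag = rec$flag,
                    chrom = as.character(rec$rname),
                    start = rec$pos - 1L, mapq = rec$mapq, nh = nh)
  mapped <- !bitwAnd(aln$flag, 0x4L) & !is.na(aln$chrom) & !is.na(aln$start)
  aln <- aln[mapped, , drop = FALSE]
  known <- aln$chrom %in% GenomeInfoDb::seqnames(genome)
  n_skipped <- sum(!known)
  if (nrow(aln) > 0L && n_skipped == nrow(aln)) {
    stop("no alignment matches any genome-index chromosome; ",
         "check for a naming-scheme mismatch (e.g. 'chr1' vs '1') ",
         "and supply a rename mapping if needed")
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " alignment(s) on unknown chromosomes skipped")
  }
  aln <- aln[known, , drop = FALSE]
  if (all(is.na(aln$nh))) {
    multi <- names(which(table(aln$qname) > 1L))
    second <- unique(aln$qname[bitwAnd(aln$flag, 0x100L) > 0L |
                               bitwAnd(aln$flag, 0x800L) > 0L])
    aln$is_unique <- !(aln$qname %in% c(multi, second))
  } else {
    aln$is_unique <- !is.na(aln$nh) & aln$nh == 1L
  }
  rownames(aln) <- NULL
  attr(aln, "n_skipped_unknown") <- n_skipped
  aln
}

#' Write mapped reads as BED3
#'
#' @param reads Mapped-read data frame.
#' @param path Output path.
#' @param read_length Read length in bp used for the BED `end` column.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path, read_length = 75L) {
  utils::write.table(
    data.frame(reads$chrom, reads$start, reads$start + as.integer(read_length)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
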