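#' Generate a toy genome with cytobands
#'
#' Fixture generator for end-to-end testing without any external data:
#' random A/C/G/T chromosome sequences plus a structurally valid cytoband
#' table. Each chromosome gets 4–8 contiguous bands tiling it exactly — an
#' acen pair (`p11`/`q11`) flanking a centromere placed at 40–60% of the
#' length, with the remaining bands split over the two arms, named outward
#' from the centromere (`p12`, `p13`, ... toward the p telomere; `q12`, ...
#' toward the q telomere) and stains cycling the Giemsa palette. Output is
#' deterministic under the seed.
#'
#' @param lengths Chromosome lengths in bp.
#' @param seed Integer seed.
#' @param names Chromosome names (default `chr1`, `chr2`, ...).
#' @param dir Optional directory: when given, writes `genome.fa` and
#'   `cytobands.tsv` there.
#' @return List with `seqs` ([Biostrings::DNAStringSet]), `genome`
#'   ([GenomeInfoDb::Seqinfo]), `bands` (cytoband `GRanges`) and, when `dir`
#'   is given, `fasta` and `cytoband_path`.
#' @examples
#' toy <- make_toy_genome(c(200000, 120000), seed = 1)
#' toy$genome
#' @export
make_toy_genome <- function(lengths, seed = 1L,
                            names = paste0("chr", seq_along(lengths)),
                            dir = NULL) {
  stopifnot(all(lengths >= 1), length(names) == length(lengths))
  set.seed(as.integer(seed))
  seqs <- Biostrings::DNAStringSet(vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, ""))
  names(seqs) <- names
  genome <- genome_index(names, lengths)
  band_tab <- do.call(rbind, lapply(seq_along(lengths), function(i) {
    toy_bands_one(names[i], lengths[i])
  }))
  bands <- cytobands(band_tab, genome)
  out <- list(seqs = seqs, genome = genome, bands = bands)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$fasta <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(seqs, out$fasta)
    out$cytoband_path <- file.path(dir, "cytobands.tsv")
    write_cytobands(bands, out$cytoband_path)
  }
  out
}

.stain_cycle <- c("gneg", "gpos25", "gpos50", "gpos75", "gpos100")

# one chromosome's bands: acen pair around a centromere, arms subdivided
toy_bands_one <- function(chrom, L) {
  n_bands <- sample(4:8, 1L)
  cen <- round(L * stats::runif(1, 0.4, 0.6))
  half_acen <- max(1L, round(L * 0.02))
  acen_lo <- max(1L, cen - half_acen)
  acen_hi <- min(L - 1L, cen + half_acen)
  n_extra <- n_bands - 2L
  n_p <- sample(0:n_extra, 1L)
  n_q <- n_extra - n_p
  cuts_in <- function(a, b, k) {
    # k internal cut points strictly inside (a, b), distinct
    if (k <= 0L || b - a < k + 1L) return(numeric(0))
    sort(sample(seq(a + 1L, b - 1L), k))
  }
  p_cuts <- cuts_in(0L, acen_lo, n_p)
  q_cuts <- cuts_in(acen_hi, L, n_q)
  p_bounds <- c(0, p_cuts, acen_lo)         # p arm: telomere -> centromere
  q_bounds <- c(acen_hi, q_cuts, L)
  n_p_eff <- length(p_bounds) - 1L
  n_q_eff <- length(q_bounds) - 1L
  # p bands named outward from centromere: nearest gets p12, farthest p1<n+1>
  p_names <- if (n_p_eff > 0) paste0("p1", (n_p_eff + 1L):2L) else character(0)
  q_names <- if (n_q_eff > 0) paste0("q1", seq_len(n_q_eff) + 1L) else character(0)
  stains <- function(k, phase) .stain_cycle[(seq_len(k) + phase) %% length(.stain_cycle) + 1L]
  rbind(
    if (n_p_eff > 0) data.frame(chrom = chrom, start = p_bounds[-length(p_bounds)],
                                end = p_bounds[-1L], band = p_names,
                                stain = stains(n_p_eff, 0L)),
    data.frame(chrom = chrom, start = c(acen_lo, cen), end = c(cen, acen_hi),
               band = c("p11", "q11"), stain = "acen"),
    if (n_q_eff > 0) data.frame(chrom = chrom, start = q_bounds[-length(q_bounds)],
                                end = q_bounds[-1L], band = q_names,
                                stain = stains(n_q_eff, 2L)))
}

#' Specify an engineered copy-number variant
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param copies_per_cell Copy number inside the interval for carriers
#'   (2 = neutral, 1 = hemizygous deletion, 0 = homozygous deletion, up to
#'   8).
#' @param carriers Integer vector of pool-member indices carrying the event.
#' @return A list of class `cnv_spec`.
#' @export
cnv_spec <- function(chrom, start, end, copies_per_cell, carriers) {
  stopifnot(end > start, start >= 0, copies_per_cell >= 0, copies_per_cell <= 8,
            length(carriers) >= 1, all(carriers >= 1))
  structure(list(chrom = chrom, start = as.numeric(start),
                 end = as.numeric(end),
                 copies_per_cell = as.integer(copies_per_cell),
                 carriers = as.integer(carriers)),
            class = "cnv_spec")
}

#' Simulate a pooled tumor read set with engineered CNVs
#'
#' Emulates DNA pooled from several patients: each pool member contributes
#' `per_member_reads` reads whose start positions are sampled with local
#' rate proportional to that member's copy number — 2 everywhere except
#' inside CNV intervals the member carries. A read's dosage is decided by
#' the copy number at its start position. The pooled window dosage is
#' therefore the carrier-averaged copy number: a hemizygous deletion in all
#' members halves expected coverage (log2 ratio −1 against a neutral
#' reference); in 2 of 4 members it gives 0.75 dosage (log2 ≈ −0.415). The
#' model is piecewise-constant sampling with multinomial noise only — no
#' breakpoint reads, sequencing errors or GC bias.
#'
#' @param seqs Genome [Biostrings::DNAStringSet].
#' @param pool_size Number of pool members (the pools this emulates held 4
#'   or 5 patients).
#' @param per_member_reads Reads contributed by each member.
#' @param read_length Read length in bp (default 75).
#' @param seed Integer seed; output is deterministic under it.
#' @param cnvs List of [cnv_spec()] objects (default none = neutral pool).
#' @return A mapped-read data frame (see [mapped_reads()]) with attributes
#'   `read_length` and `pool_size`; `read_id` encodes the member.
#' @export
simulate_pool_reads <- function(seqs, pool_size = 4L, per_member_reads,
                                read_length = 75L, seed = NULL,
                                cnvs = list()) {
  stopifnot(methods::is(seqs, "DNAStringSet"), pool_size >= 1,
            per_member_reads >= 1)
  if (inherits(cnvs, "cnv_spec")) cnvs <- list(cnvs)
  genome <- genome_index(names(seqs), Biostrings::width(seqs))
  lens <- stats::setNames(as.numeric(Biostrings::width(seqs)), names(seqs))
  valid <- lens - as.integer(read_length) + 1
  if (any(valid <= 0)) {
    stop("read_length ", read_length, " exceeds chromosome(s): ",
         paste(names(seqs)[valid <= 0], collapse = ", "))
  }
  for (cv in cnvs) {
    stopifnot(inherits(cv, "cnv_spec"))
    if (!(cv$chrom %in% names(seqs))) {
      stop("CNV on unknown chromosome: ", cv$chrom)
    }
    if (cv$end > lens[cv$chrom]) stop("CNV beyond chromosome end: ", cv$chrom)
    if (any(cv$carriers > pool_size)) {
      stop("CNV carrier index exceeds pool_size")
    }
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  members <- lapply(seq_len(pool_size), function(m) {
    mine <- Filter(function(cv) m %in% cv$carriers, cnvs)
    iv <- member_intervals(names(seqs), valid, mine)
    k <- stats::rmultinom(1L, per_member_reads, iv$w)[, 1L]
    pos <- unlist(lapply(seq_along(k), function(j) {
      if (k[j] == 0L) return(integer(0))
      iv$a[j] + as.integer(floor(stats::runif(k[j]) * (iv$b[j] - iv$a[j])))
    }))
    chrom <- rep(iv$chrom, k)
    data.frame(chrom = chrom, start = pos, member = m)
  })
  pooled <- do.call(rbind, members)
  reads <- mapped_reads(pooled$chrom, pooled$start,
                        read_id = sprintf("pool_m%d_%07d", pooled$member,
                                          seq_len(nrow(pooled))),
                        genome = genome)
  attr(reads, "read_length") <- as.integer(read_length)
  attr(reads, "pool_size") <- as.integer(pool_size)
  reads
}

# piecewise-constant copy-number intervals over valid start positions
# [0, valid) for one pool member; errors on overlapping CNVs
member_intervals <- function(chroms, valid, cnvs) {
  out <- list()
  for (ch in chroms) {
    v <- valid[[ch]]
    mine <- Filter(function(cv) cv$chrom == ch, cnvs)
    mine <- mine[order(vapply(mine, `[[`, 0, "start"))]
    if (length(mine) > 1L) {
      s <- vapply(mine, `[[`, 0, "start")
      e <- vapply(mine, `[[`, 0, "end")
      if (any(s[-1L] < e[-length(e)])) {
        stop("overlapping CNV intervals for one pool member on ", ch)
      }
    }
    cursor <- 0
    for (cv in mine) {
      a <- min(cv$start, v); b <- min(cv$end, v)
      if (cursor < a) {
        out[[length(out) + 1L]] <- data.frame(chrom = ch, a = cursor, b = a,
                                              copies = 2L)
      }
      if (b > a) {
        out[[length(out) + 1L]] <- data.frame(chrom = ch, a = a, b = b,
                                              copies = cv$copies_per_cell)
      }
      cursor <- max(cursor, b)
    }
    if (cursor < v) {
      out[[length(out) + 1L]] <- data.frame(chrom = ch, a = cursor, b = v,
                                            copies = 2L)
    }
  }
  df <- do.call(rbind, out)
  df$w <- df$copies * (df$b - df$a)
  if (sum(df$w) <= 0) stop("pool member has zero total sampling weight")
  df
}
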