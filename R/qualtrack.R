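#' Integer-preserving median of Phred scores
#'
#' Median rule used throughout the package: for an odd count the middle
#' value, for an even count the lower of the two middle values. This keeps
#' the track integral and deterministic.
#'
#' @param values integer vector (non-empty).
#' @return integer median; `NA` for an empty input (no data).
#' @examples
#' median_rule(c(30, 34, 38))  # 34
#' median_rule(c(30, 38))      # 30, lower-middle rule
#' @export
median_rule <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) return(NA_integer_)
  as.integer(sort.int(values, method = "quick")[ceiling(n / 2)])
}

#' Build strand-specific median quality tracks from aligned reads
#'
#' Reads a coordinate-sorted SAM or BAM file and computes, per contig and
#' strand, the median Phred score of all aligned bases at every covered
#' reference position. Read strand comes from FLAG bit 0x10 only; secondary
#' (0x100), supplementary (0x800) and unmapped (0x4) records are dropped, as
#' are records without quality strings. Only aligned (match/mismatch) bases
#' contribute; soft-clipped, inserted and deleted positions contribute
#' nothing. Loci with depth below `d_min` are masked as no-data
#' (`median_q = NA`).
#'
#' @param alignments path to a SAM or BAM file (SAM is converted on the fly).
#' @param contig optional contig to restrict to.
#' @param range optional 0-based half-open `c(start, end)` restriction
#'   (requires `contig`).
#' @param d_min minimum depth for a locus to carry a defined median.
#' @param mapq_min minimum mapping quality for a read to contribute.
#' @return tibble of class `quad_tracks` with columns `contig`, `strand`,
#'   `pos` (0-based), `depth`, `median_q` (NA where masked), plus attributes
#'   `d_min` and `contig_lengths` (from the SAM header).
#' @export
build_tracks <- function(alignments, contig = NULL, range = NULL,
                         d_min = 10L, mapq_min = 0L) {
  aln <- read_alignments(alignments, contig = contig, range = range,
                         mapq_min = mapq_min)
  base_tbl <- expand_aligned_bases(aln$records)
  if (!is.null(range)) {
    base_tbl <- base_tbl[base_tbl$pos >= range[1] & base_tbl$pos < range[2], ]
  }
  tracks_from_bases(base_tbl, d_min = d_min, contig_lengths = aln$contig_lengths)
}

# internal: shared finalization so simulated base tables can skip SAM I/O
tracks_from_bases <- function(base_tbl, d_min, contig_lengths) {
  if (!nrow(base_tbl)) {
    out <- tibble(contig = character(), strand = character(), pos = integer(),
                  depth = integer(), median_q = integer())
  } else {
    dt <- data.table::as.data.table(base_tbl)
    agg <- dt[, list(depth = .N,
                     median_q = sort.int(qual,
                                         method = "quick")[ceiling(.N / 2)]),
              by = c("contig", "strand", "pos")]
    data.table::setorder(agg, contig, strand, pos)
    out <- as_tibble(agg)
    out$median_q[out$depth < d_min] <- NA_integer_
  }
  structure(out, d_min = d_min, contig_lengths = contig_lengths,
            class = c("quad_tracks", class(out)))
}

#' @export
print.quad_tracks <- function(x, ...) {
  cat(sprintf("<quad_tracks> %d loci, d_min = %d\n",
              nrow(x), attr(x, "d_min")))
  NextMethod()
}

# read SAM/BAM via Rsamtools; returns list(records = tibble, contig_lengths)
read_alignments <- function(path, contig = NULL, range = NULL, mapq_min = 0L,
                            keep_seq = FALSE) {
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE))
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  clen <- hdr$targets
  what <- c("rname", "flag", "pos", "mapq", "cigar", "qual")
  if (keep_seq) what <- c(what, "seq")
  param <- Rsamtools::ScanBamParam(what = what)
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(res$pos) &
    !bitwAnd(res$flag, 0x4) & !bitwAnd(res$flag, 0x100) &
    !bitwAnd(res$flag, 0x800) & res$mapq >= mapq_min
  qual_chr <- as.character(res$qual)
  noqual <- qual_chr == "*" | !nzchar(qual_chr)
  if (any(noqual & keep)) {
    warn(sprintf("%d record(s) without quality strings dropped",
                 sum(noqual & keep)))
  }
  keep <- keep & !noqual
  rec <- tibble(
    contig = as.character(res$rname)[keep],
    flag = res$flag[keep],
    pos = res$pos[keep] - 1L,                 # to 0-based
    cigar = res$cigar[keep],
    qual = qual_chr[keep]
  )
  if (keep_seq) rec$seq <- as.character(res$seq)[keep]
  if (!is.null(contig)) rec <- rec[rec$contig == contig, ]
  # coordinate-sortedness within contig is a precondition of the pipeline
  unsorted <- rec |>
    group_by(.data$contig) |>
    summarise(bad = is.unsorted(.data$pos), .groups = "drop")
  if (any(unsorted$bad)) abort("alignments are not coordinate-sorted")
  rec$strand <- ifelse(bitwAnd(rec$flag, 0x10) > 0L, "-", "+")
  list(records = rec, contig_lengths = clen)
}

# expand records into one row per aligned base: contig, strand, pos, qual
# (and base if seq present).  CIGAR M/=/X consume both; I/S consume query
# only; D/N consume reference only; H/P consume neither.
expand_aligned_bases <- function(rec) {
  if (!nrow(rec)) {
    return(tibble(contig = character(), strand = character(),
                  pos = integer(), qual = integer()))
  }
  cig <- rec$cigar
  ref_rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, ops = c("M", "=", "X"), pos = rec$pos + 1L)
  qry_rl <- GenomicAlignments::cigarRangesAlongQuerySpace(
    cig, ops = c("M", "=", "X"))
  nseg <- S4Vectors::elementNROWS(ref_rl)
  ref_ir <- unlist(ref_rl, use.names = FALSE)
  qry_ir <- unlist(qry_rl, use.names = FALSE)
  seg_read <- rep(seq_len(nrow(rec)), nseg)
  w <- IRanges::width(ref_ir)
  stopifnot(all(w == IRanges::width(qry_ir)))
  base_read <- rep(seg_read, w)
  refpos <- rep(IRanges::start(ref_ir), w) + sequence(w) - 1L
  qrypos <- rep(IRanges::start(qry_ir), w) + sequence(w) - 1L
  # per-read quality integer vectors, indexed by query position
  qual_int <- lapply(rec$qual, function(q) utf8ToInt(q) - 33L)
  quals <- unlist(qual_int, use.names = FALSE)
  offs <- cumsum(c(0L, vapply(qual_int, length, integer(1))))[base_read]
  out <- tibble(
    contig = rec$contig[base_read],
    strand = rec$strand[base_read],
    pos = refpos - 1L,
    qual = quals[offs + qrypos]
  )
  if ("seq" %in% names(rec)) {
    seq_chars <- strsplit(rec$seq, "", fixed = TRUE)
    bases <- unlist(seq_chars, use.names = FALSE)
    out$base <- bases[offs + qrypos]
    out$read_id <- base_read
  }
  out
}

#' Materialize one strand of a track as a dense median vector
#'
#' @param tracks a `quad_tracks` tibble.
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param len contig length; defaults to the header length recorded on the
#'   track.
#' @return numeric vector of length `len`; `NA` at no-data loci. Element `i`
#'   is reference position `i - 1`.
#' @export
track_vector <- function(tracks, contig, strand, len = NULL) {
  if (is.null(len)) {
    clen <- attr(tracks, "contig_lengths")
    if (is.null(clen) || !contig %in% names(clen)) {
      abort(paste0("unknown contig length for ", contig))
    }
    len <- clen[[contig]]
  }
  v <- rep(NA_real_, len)
  sel <- tracks$contig == contig & tracks$strand == strand
  v[tracks$pos[sel] + 1L] <- tracks$median_q[sel]
  v
}

#' Write / read a track as TSV (debugging and fixtures)
#' @param tracks a `quad_tracks` tibble.
#' @param path file path.
#' @return `write_track_tsv` the path, invisibly; `read_track_tsv` a
#'   `quad_tracks` tibble.
#' @export
write_track_tsv <- function(tracks, path) {
  utils::write.table(as.data.frame(tracks), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param d_min minimum depth recorded with the track.
#' @param contig_lengths named integer vector of contig lengths.
#' @rdname write_track_tsv
#' @export
read_track_tsv <- function(path, d_min = 10L, contig_lengths = NULL) {
  df <- as_tibble(utils::read.table(
    path, sep = "\t", header = TRUE,
    colClasses = c("character", "character", "integer", "integer", "integer")))
  structure(df, d_min = d_min, contig_lengths = contig_lengths,
            class = c("quad_tracks", class(df)))
}
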