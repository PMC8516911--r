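# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately naive (enumeration, quadratic loops,
# direct text parsing) so it cannot share a bug with the implementation.

# brute force canonical-motif finder: tests the full-match grammar on every
# substring up to max_span (vectorized per length, PCRE engine), then merges
# overlapping candidate intervals.  Returns 0-based half-open tibble.
oracle_canonical_plus <- function(s, max_span = 75L) {
  L <- nchar(s)
  pat <- "^(G{3,}[ATCG]{1,7}){3}G{3,}$"
  iv_start <- integer(0); iv_end <- integer(0)
  for (len in 15:min(max_span, L)) {
    starts <- seq_len(L - len + 1L)
    subs <- substring(s, starts, starts + len - 1L)
    hit <- grepl(pat, subs, perl = TRUE)
    iv_start <- c(iv_start, starts[hit] - 1L)
    iv_end <- c(iv_end, starts[hit] - 1L + len)
  }
  if (!length(iv_start)) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  o <- order(iv_start, iv_end)
  iv_start <- iv_start[o]; iv_end <- iv_end[o]
  ms <- iv_start[1]; me <- iv_end[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(iv_start)[-1]) {
    if (iv_start[i] <= me) {
      me <- max(me, iv_end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- iv_start[i]; me <- iv_end[i]
    }
  }
  tibble::tibble(start = c(out_s, ms), end = c(out_e, me))
}

oracle_canonical <- function(s, max_span = 75L) {
  L <- nchar(s)
  plus <- oracle_canonical_plus(s, max_span)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  minus <- oracle_canonical_plus(rc, max_span)
  dplyr::bind_rows(
    dplyr::mutate(plus, strand = "+"),
    tibble::tibble(start = L - minus$end, end = L - minus$start,
                   strand = rep("-", nrow(minus))))
}

# quadratic >=1bp same-strand overlap oracle
oracle_overlaps <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$contig == a$contig[i] & b$strand == a$strand[i] &
          b$start < a$end[i] & a$start[i] < b$end)
  }, logical(1))
}

# naive interval merge oracle (single contig+strand)
oracle_merge <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]; out <- NULL
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i]) else {
      out <- rbind(out, c(ms, me)); ms <- start[i]; me <- end[i]
    }
  }
  rbind(out, c(ms, me))
}

# direct SAM-text median-track oracle; assumes the simulator's all-match
# CIGARs.  Returns tibble(contig, strand, pos, depth, median_q).
oracle_tracks_from_sam <- function(path, d_min = 10L) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  rows <- list()
  for (l in ln) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2]); pos <- as.integer(f[4]) - 1L
    qual <- utf8ToInt(f[11]) - 33L
    strand <- if (bitwAnd(flag, 16L)) "-" else "+"
    rows[[length(rows) + 1L]] <-
      data.frame(contig = f[3], strand = strand,
                 pos = pos + seq_along(qual) - 1L, qual = qual)
  }
  df <- do.call(rbind, rows)
  agg <- aggregate(qual ~ contig + strand + pos, df, function(v) {
    sv <- sort(v)
    n <- length(sv)
    c(n = n, med = if (n %% 2 == 1) sv[(n + 1) / 2] else
      min(sv[n / 2], sv[n / 2 + 1]))
  })
  out <- tibble::tibble(contig = agg$contig, strand = agg$strand,
                        pos = agg$pos, depth = as.integer(agg$qual[, "n"]),
                        median_q = as.integer(agg$qual[, "med"]))
  out$median_q[out$depth < d_min] <- NA_integer_
  out[order(out$contig, out$strand, out$pos), ]
}

# construct a quad_tracks object directly from dense per-strand vectors
make_track <- function(q_plus = NULL, q_minus = NULL, contig = "c",
                       depth = 30L, d_min = 10L, len = NULL) {
  mk <- function(q, std) {
    if (is.null(q)) return(NULL)
    tibble::tibble(contig = contig, strand = std,
                   pos = seq_along(q) - 1L, depth = depth,
                   median_q = as.integer(q))
  }
  df <- dplyr::bind_rows(mk(q_plus, "+"), mk(q_minus, "-"))
  if (is.null(len)) len <- max(length(q_plus), length(q_minus))
  structure(df, d_min = d_min, contig_lengths = setNames(len, contig),
            class = c("quad_tracks", class(df)))
}

# mirror a simulator SAM: reverse-complement world.  Read positions are
# reflected, strands flipped, SEQ reverse-complemented, QUAL reversed.
mirror_sam <- function(path, out, L) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "@")]
  body <- ln[!startsWith(ln, "@")]
  rec <- lapply(body, function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  mirrored <- lapply(rec, function(f) {
    pos <- as.integer(f[4]) - 1L
    rl <- nchar(f[10])
    f[4] <- as.character(L - (pos + rl) + 1L)
    f[2] <- as.character(bitwXor(as.integer(f[2]), 16L))
    f[10] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(f[10])))
    f[11] <- paste(rev(strsplit(f[11], "")[[1]]), collapse = "")
    f
  })
  ord <- order(vapply(mirrored, function(f) as.integer(f[4]), integer(1)))
  writeLines(c(hdr, vapply(mirrored[ord], paste, character(1),
                           collapse = "\t")), out)
  invisible(out)
}

# small, fast simulation shared by several test files
quick_sim <- function(seed = 7, genome_length = 30000,
                      features = c(canonical = 10), p_fold = 1,
                      delta = 6, depth = 30, ...) {
  cfg <- sim_config(genome_length = genome_length, features = features,
                    p_fold = p_fold, delta = delta, depth = depth,
                    seed = seed, ...)
  sim <- sim_genome(cfg)
  sam <- tempfile(fileext = ".sam")
  sim_reads(sim, cfg, sam)
  list(cfg = cfg, sim = sim, sam = sam)
}

random_dna <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}
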