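#' Scanner parameters
#'
#' Bundles all tuning of the low-quality-region scanner and the region
#' caller. `M` is the quality-drop magnitude (Phred units) that defines a
#' flag site, `N` the minimum number of low-quality loci within the window
#' for a hit. The 75-nt window is half the read length and longer than
#' almost all canonical motifs; the 35-nt upstream extension is the longest
#' canonical G4 length; `g_min` is the guanine-content floor applied to
#' called regions.
#'
#' @param M integer drop magnitude, 1-12 Phred units.
#' @param N integer low-quality locus count, 1 to `window`.
#' @param window window length in nt.
#' @param extension upstream extension in nt applied when hits become
#'   regions.
#' @param g_min minimum guanine fraction of a called region, on the scanned
#'   strand.
#' @param g_mode `"G"` to count guanine only on the scanned strand, `"GC"`
#'   to count G+C.
#' @return a `scanner_params` list.
#' @examples
#' scanner_params(M = 4, N = 15)
#' @export
scanner_params <- function(M, N, window = 75L, extension = 35L,
                           g_min = 0.28, g_mode = c("G", "GC")) {
  g_mode <- match.arg(g_mode)
  M <- as.integer(M); N <- as.integer(N)
  window <- as.integer(window); extension <- as.integer(extension)
  stopifnot(length(M) == 1L, length(N) == 1L, window > 0L,
            M >= 1L, M <= 12L, N >= 1L, N <= window,
            extension >= 0L, g_min >= 0, g_min <= 1)
  structure(list(M = M, N = N, window = window, extension = extension,
                 g_min = g_min, g_mode = g_mode),
            class = "scanner_params")
}

#' @export
print.scanner_params <- function(x, ...) {
  cat(sprintf(
    "<scanner_params> M=%d N=%d window=%d extension=%d g_min=%.2f (%s)\n",
    x$M, x$N, x$window, x$extension, x$g_min, x$g_mode))
  invisible(x)
}

# Core oriented scan of a dense median vector. q[i] is oriented position
# i-1; the scan runs left to right (the strand's 5'->3' direction).  For
# every adjacent defined pair with |diff| >= M the lower base is the start
# site and the higher the flag site; a window locus j is low-quality iff
# flag - q[j] >= M.  No-data loci neither trigger transitions nor count.
# Returns all start sites with their n_low (unfiltered by N).
scan_vector <- function(q, M, window = 75L) {
  L <- length(q)
  if (L < 2L) {
    return(tibble(idx = integer(), flag_value = integer(), n_low = integer()))
  }
  a <- q[-L]; b <- q[-1L]
  d <- b - a
  tr <- which(!is.na(d) & abs(d) >= M)
  if (!length(tr)) {
    return(tibble(idx = integer(), flag_value = integer(), n_low = integer()))
  }
  start <- ifelse(d[tr] < 0, tr + 1L, tr)       # 1-based index of lower base
  flag <- pmax(a[tr], b[tr])
  n_low <- integer(length(start))
  off <- 0:(window - 1L)
  blk <- 20000L
  for (i0 in seq(1L, length(start), by = blk)) {
    i1 <- min(i0 + blk - 1L, length(start))
    idxm <- outer(start[i0:i1], off, "+")
    ok <- idxm <= L
    qs <- q[pmin(idxm, L)]
    low <- !is.na(qs) & ok & (flag[i0:i1] - qs >= M)
    n_low[i0:i1] <- as.integer(rowSums(low))
  }
  tibble(idx = start, flag_value = as.integer(flag), n_low = n_low)
}

# scan one contig+strand of a track; returns genome-coordinate start sites
scan_contig_strand <- function(tracks, contig, strand, M, window, len) {
  q <- track_vector(tracks, contig, strand, len)
  if (strand == "-") q <- rev(q)
  h <- scan_vector(q, M, window)
  if (!nrow(h)) {
    return(tibble(contig = character(), strand = character(),
                  start_site = integer(), flag_value = integer(),
                  n_low = integer()))
  }
  pos0 <- if (strand == "+") h$idx - 1L else len - h$idx
  tibble(contig = contig, strand = strand, start_site = pos0,
         flag_value = h$flag_value, n_low = h$n_low)
}

#' Scan quality tracks for low-quality hits
#'
#' Runs the two-threshold low-quality-region scanner over every contig and
#' strand of a track set. Scanning proceeds in each strand's 5'->3'
#' direction (increasing coordinates on `+`, decreasing on `-`); windows
#' truncated by a contig end are counted over the available loci and still
#' require `N` low-quality loci.
#'
#' @param tracks a `quad_tracks` tibble (see [build_tracks()]).
#' @param params a [scanner_params()] object.
#' @param contig_lens named integer vector of contig lengths; defaults to
#'   the lengths recorded on the track.
#' @param min_n if `TRUE` (default) only start sites with
#'   `n_low >= params$N` are returned.
#' @return tibble with `contig`, `strand`, `start_site` (0-based reference
#'   position of the low-quality start site), `flag_value`, `n_low`.
#' @export
scan_tracks <- function(tracks, params, contig_lens = NULL, min_n = TRUE) {
  stopifnot(inherits(params, "scanner_params"))
  if (is.null(contig_lens)) contig_lens <- attr(tracks, "contig_lengths")
  if (is.null(contig_lens)) abort("contig lengths unavailable")
  combos <- unique(tibble(contig = tracks$contig, strand = tracks$strand))
  out <- purrr::pmap_dfr(combos, function(contig, strand) {
    if (!contig %in% names(contig_lens)) {
      abort(paste0("no length for contig ", contig))
    }
    scan_contig_strand(tracks, contig, strand, params$M, params$window,
                       contig_lens[[contig]])
  })
  if (!nrow(out)) {
    out <- tibble(contig = character(), strand = character(),
                  start_site = integer(), flag_value = integer(),
                  n_low = integer())
  }
  if (min_n) out <- filter(out, .data$n_low >= params$N)
  arrange(out, .data$contig, .data$strand, .data$start_site)
}

#' Turn scanner hits into merged stranded regions
#'
#' Each hit's window is extended by `params$extension` nt upstream (in
#' strand orientation) of the start site; overlapping regions on the same
#' contig and strand are merged. On the minus strand the window runs toward
#' decreasing reference coordinates, and reported intervals follow
#' plus-coordinate BED convention.
#'
#' @param hits tibble from [scan_tracks()].
#' @param params a [scanner_params()] object.
#' @param contig_lens named integer vector of contig lengths used to clip
#'   regions at contig bounds.
#' @return tibble with `contig`, `start`, `end`, `strand`, `n_low` (max over
#'   merged hits), `flag_value` (max), `n_hits`; sorted and disjoint within
#'   a strand.
#' @export
hit_regions <- function(hits, params, contig_lens = NULL) {
  stopifnot(inherits(params, "scanner_params"))
  if (!nrow(hits)) {
    return(merge_stranded(tibble(contig = character(), start = integer(),
                                 end = integer(), strand = character(),
                                 n_low = integer(), flag_value = integer())))
  }
  w <- params$window; ext <- params$extension
  raw <- hits |>
    mutate(
      start = ifelse(.data$strand == "+",
                     .data$start_site - ext,
                     .data$start_site - w + 1L),
      end = ifelse(.data$strand == "+",
                   .data$start_site + w,
                   .data$start_site + ext + 1L)
    ) |>
    mutate(start = pmax(.data$start, 0L))
  if (!is.null(contig_lens)) {
    raw$end <- pmin(raw$end, unname(contig_lens[raw$contig]))
  }
  merge_stranded(raw |>
                   transmute(.data$contig, start = as.integer(.data$start),
                             end = as.integer(.data$end), .data$strand,
                             .data$n_low, .data$flag_value))
}
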