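#' Build PG4-positive and negative calibration regions
#'
#' A positive region starts 12 nt upstream (the approximate DNA-polymerase
#' footprint) of a predicted canonical motif start and spans 75 nt in strand
#' orientation. After removing positive regions plus `exclusion` nt on both
#' sides, the remainder of each strand is tiled (5'->3') into 75-nt negative
#' windows. Every region is annotated with its guanine fraction on the
#' scanned strand.
#'
#' @param genome named character vector / DNAStringSet.
#' @param pg4s tibble from [predict_pg4()] (columns `contig`, `start`,
#'   `end`, `strand`).
#' @param upstream nt upstream of the motif start where the positive region
#'   begins.
#' @param window region width (nt).
#' @param exclusion buffer around positive regions excluded from negatives.
#' @param g_mode `"G"` (guanine on the scanned strand) or `"GC"`.
#' @return tibble: `contig`, `strand`, `start`, `end`, `label`
#'   (`positive`/`negative`), `g_fraction`, `clipped` (positive region
#'   truncated at a contig bound).
#' @export
calibration_regions <- function(genome, pg4s, upstream = 12L, window = 75L,
                                exclusion = 300L, g_mode = c("G", "GC")) {
  g_mode <- match.arg(g_mode)
  genome <- as_genome(genome)
  lens <- contig_lengths(genome)
  combos <- tidyr::expand_grid(contig = names(genome), strand = STRANDS)
  out <- purrr::pmap_dfr(combos, function(contig, strand) {
    L <- lens[[contig]]
    p <- pg4s[pg4s$contig == contig & pg4s$strand == strand, , drop = FALSE]
    if (nrow(p)) {
      if (strand == "+") {
        ps <- p$start - upstream
        pe <- ps + window
      } else {
        pe <- p$end + upstream
        ps <- pe - window
      }
      clipped <- ps < 0L | pe > L
      pos <- tibble(start = pmax(ps, 0L), end = pmin(pe, L),
                    label = "positive", clipped = clipped)
    } else {
      pos <- tibble(start = integer(), end = integer(),
                    label = character(), clipped = logical())
    }
    # excluded zone = positives +/- exclusion; tile the complement
    if (nrow(pos)) {
      excl <- IRanges::reduce(IRanges::IRanges(
        pmax(pos$start - exclusion, 0L) + 1L, pmin(pos$end + exclusion, L)))
      gaps <- IRanges::setdiff(IRanges::IRanges(1L, L), excl)
    } else {
      gaps <- IRanges::IRanges(1L, L)
    }
    gs <- IRanges::start(gaps) - 1L
    ge <- IRanges::end(gaps)
    neg <- purrr::map_dfr(seq_along(gs), function(i) {
      k <- (ge[i] - gs[i]) %/% window
      if (k == 0L) return(tibble())
      if (strand == "+") {
        st <- gs[i] + (seq_len(k) - 1L) * window
      } else {          # tile from the 5' end of the minus strand
        st <- ge[i] - seq_len(k) * window
      }
      tibble(start = st, end = st + window, label = "negative",
             clipped = FALSE)
    })
    reg <- bind_rows(pos, neg)
    if (!nrow(reg)) return(tibble())
    reg |>
      mutate(contig = contig, strand = strand,
             g_fraction = g_fraction_of(genome, contig, .data$start,
                                        .data$end, strand, g_mode)) |>
      select("contig", "strand", "start", "end", "label", "g_fraction",
             "clipped")
  })
  arrange(out, .data$contig, .data$strand, .data$start)
}

#' Per-genome guanine-content threshold
#'
#' The guanine filter threshold is the value exceeded by 99% of
#' PG4-positive regions: the nearest-rank 1st percentile of their guanine
#' fractions. With fewer than `min_regions` positives the percentile is
#' unstable and the conventional default of 0.28 is returned with a
#' warning.
#'
#' @param regions tibble from [calibration_regions()] (or any tibble with
#'   `label` and `g_fraction`), or a bare numeric vector of g fractions.
#' @param default fallback threshold.
#' @param min_regions minimum number of positive regions for a stable
#'   percentile.
#' @return a single guanine fraction.
#' @export
g_threshold <- function(regions, default = 0.28, min_regions = 100L) {
  g <- if (is.numeric(regions)) regions else
    regions$g_fraction[regions$label == "positive"]
  g <- g[!is.na(g)]
  n <- length(g)
  if (n < min_regions) {
    warn(sprintf(
      "only %d positive regions (< %d); using default g threshold %.2f",
      n, min_regions, default))
    return(default)
  }
  sort(g)[max(1L, ceiling(0.01 * n))]
}

#' Calibrate scanner thresholds by grid search
#'
#' For each strand, scans the tracks under every `M` in `M_range`, tallies
#' for each calibration region the best (largest) low-quality count of any
#' start site falling inside the region, and derives the full
#' `M x N` grid of positive rate (fraction of positive regions hit) and
#' false-positive rate (fraction of guanine-filtered negative regions hit).
#' The chosen cell maximizes the positive rate subject to
#' `fpr < fpr_max`; ties break toward lower fpr, then higher `M`, then
#' higher `N`.
#'
#' @param tracks a `quad_tracks` tibble.
#' @param regions tibble from [calibration_regions()].
#' @param M_range,N_range integer grids.
#' @param fpr_max false-positive-rate bound.
#' @param g_min guanine filter applied to negatives before the FPR is
#'   computed; `NULL` derives the per-genome threshold with [g_threshold()]
#'   from the pooled positive regions of both strands.
#' @param window scan window (nt).
#' @param extension,g_mode carried into the chosen [scanner_params()].
#' @param contig_lens named contig lengths (defaults to the track's).
#' @return object of class `quad_calibration`: list with `chosen` (tibble,
#'   one row per strand), `grid` (full grid per strand), `params` (named
#'   list of [scanner_params()] per strand), `g_min` (named per strand),
#'   `fpr_max`, `n_pos`, `n_neg`.
#' @export
calibrate_scanner <- function(tracks, regions, M_range = 1:12,
                              N_range = 1:20, fpr_max = 0.01, g_min = NULL,
                              window = 75L, extension = 35L,
                              g_mode = c("G", "GC"), contig_lens = NULL) {
  g_mode <- match.arg(g_mode)
  if (is.null(contig_lens)) contig_lens <- attr(tracks, "contig_lengths")
  if (is.null(contig_lens)) abort("contig lengths unavailable")
  # guanine threshold is a per-genome quantity: pool positives of both strands
  g_genome <- if (is.null(g_min)) g_threshold(regions) else g_min
  res <- purrr::map(STRANDS, function(std) {
    reg <- regions[regions$strand == std, , drop = FALSE]
    gmin_s <- g_genome
    pos_idx <- which(reg$label == "positive")
    neg_idx <- which(reg$label == "negative" & reg$g_fraction >= gmin_s)
    if (!length(pos_idx)) abort(paste0("no positive regions on strand ", std))
    if (!length(neg_idx)) abort(paste0("no usable negative regions on strand ",
                                       std))
    best <- matrix(0L, nrow(reg), length(M_range))
    ctgs <- intersect(unique(tracks$contig[tracks$strand == std]),
                      unique(reg$contig))
    greg <- GenomicRanges::GRanges(reg$contig,
                                   IRanges::IRanges(reg$start + 1L, reg$end))
    for (mi in seq_along(M_range)) {
      hits <- purrr::map_dfr(ctgs, function(ctg)
        scan_contig_strand(tracks, ctg, std, M_range[mi], window,
                           contig_lens[[ctg]]))
      if (!nrow(hits)) next
      gh <- GenomicRanges::GRanges(hits$contig,
                                   IRanges::IRanges(hits$start_site + 1L,
                                                    width = 1L))
      ov <- GenomicRanges::findOverlaps(gh, greg)
      if (!length(ov)) next
      agg <- tapply(hits$n_low[S4Vectors::queryHits(ov)],
                    S4Vectors::subjectHits(ov), max)
      best[as.integer(names(agg)), mi] <- as.integer(agg)
    }
    grid <- tidyr::expand_grid(M = M_range, N = N_range) |>
      rowwise() |>
      mutate(
        positive_rate = mean(best[pos_idx, match(.data$M, M_range)] >= .data$N),
        fpr = mean(best[neg_idx, match(.data$M, M_range)] >= .data$N)
      ) |>
      ungroup() |>
      mutate(strand = std, .before = 1)
    list(grid = grid, g_min = gmin_s,
         n_pos = length(pos_idx), n_neg = length(neg_idx))
  })
  grid <- bind_rows(purrr::map(res, "grid"))
  chosen <- grid |>
    group_by(.data$strand) |>
    filter(.data$fpr < fpr_max) |>
    arrange(desc(.data$positive_rate), .data$fpr, desc(.data$M),
            desc(.data$N)) |>
    slice(1) |>
    ungroup()
  if (nrow(chosen) < length(STRANDS) || all(chosen$positive_rate == 0)) {
    missing <- setdiff(STRANDS, chosen$strand)
    if (length(missing)) {
      abort(paste0("calibration failure: no (M, N) cell satisfies fpr < ",
                   fpr_max, " on strand ", paste(missing, collapse = ",")))
    }
    if (all(chosen$positive_rate == 0)) {
      abort("calibration failure: no parameter set detects any positive region")
    }
  }
  gmins <- setNames(purrr::map_dbl(res, "g_min"), STRANDS)
  params <- setNames(purrr::map(seq_along(STRANDS), function(i) {
    ch <- chosen[chosen$strand == STRANDS[i], ]
    scanner_params(ch$M, ch$N, window = window, extension = extension,
                   g_min = gmins[[i]], g_mode = g_mode)
  }), STRANDS)
  structure(list(chosen = chosen, grid = grid, params = params,
                 g_min = gmins, fpr_max = fpr_max,
                 n_pos = setNames(purrr::map_int(res, "n_pos"), STRANDS),
                 n_neg = setNames(purrr::map_int(res, "n_neg"), STRANDS)),
            class = "quad_calibration")
}

#' @export
print.quad_calibration <- function(x, ...) {
  cat("<quad_calibration>\n")
  for (std in names(x$params)) {
    ch <- x$chosen[x$chosen$strand == std, ]
    cat(sprintf(
      "  strand %s: M=%d N=%d  positive_rate=%.3f fpr=%.4f  g_min=%.3f (n_pos=%d, n_neg=%d)\n",
      std, ch$M, ch$N, ch$positive_rate, ch$fpr, x$g_min[[std]],
      x$n_pos[[std]], x$n_neg[[std]]))
  }
  invisible(x)
}

#' @rdname calibrate_scanner
#' @param x a `quad_calibration` object.
#' @param ... unused.
#' @export
tidy.quad_calibration <- function(x, ...) x$grid

#' @rdname calibrate_scanner
#' @export
glance.quad_calibration <- function(x, ...) {
  x$chosen |>
    mutate(g_min = unname(x$g_min[.data$strand]),
           fpr_max = x$fpr_max,
           n_pos = unname(x$n_pos[.data$strand]),
           n_neg = unname(x$n_neg[.data$strand]))
}
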