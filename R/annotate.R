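#' Build labeled genomic region models from a gene table
#'
#' Derives the eight region classes used for density statistics from a
#' refGene-like gene table: 3'-UTR, 5'-UTR, exon, intron, CDS, TSS-up (the
#' 1-kb promoter upstream of the transcription start site), TSS-up-down
#' (1 kb on both sides of the TSS) and splice-50 (50 nt on both sides of
#' every internal splice site). Upstream/downstream arithmetic is
#' strand-aware; all coordinates are 0-based half-open.
#'
#' @param gene_table tibble with columns `name`, `contig`, `strand`,
#'   `tx_start`, `tx_end`, `cds_start`, `cds_end`, `exon_starts`,
#'   `exon_ends` (comma-separated strings or list columns of integers),
#'   i.e. UCSC refGene columns under tidy names.
#' @param tss_flank promoter / TSS flank size (nt).
#' @param splice_flank flank around splice sites (nt).
#' @return tibble: `label`, `contig`, `start`, `end`, `strand`, `gene`.
#' @export
build_region_models <- function(gene_table, tss_flank = 1000L,
                                splice_flank = 50L) {
  parse_ints <- function(x) {
    if (is.list(x)) return(purrr::map(x, as.integer))
    purrr::map(strsplit(as.character(x), ","), as.integer)
  }
  gt <- as_tibble(gene_table)
  need <- c("name", "contig", "strand", "tx_start", "tx_end",
            "cds_start", "cds_end", "exon_starts", "exon_ends")
  if (!all(need %in% names(gt))) {
    abort(paste0("gene table must have columns: ", paste(need, collapse = ", ")))
  }
  es <- parse_ints(gt$exon_starts)
  ee <- parse_ints(gt$exon_ends)
  rows <- purrr::map_dfr(seq_len(nrow(gt)), function(i) {
    g <- gt[i, ]
    s <- es[[i]]; e <- ee[[i]]
    if (length(s) != length(e) || any(e <= s) ||
        is.na(g$tx_start) || is.na(g$tx_end) || !g$strand %in% STRANDS) {
      inform(paste0("skipping malformed gene row: ", g$name))
      return(tibble())
    }
    plus <- g$strand == "+"
    tss <- if (plus) g$tx_start else g$tx_end        # 0-based TSS locus edge
    add <- function(label, start, end) {
      keep <- end > start
      tibble(label = label, start = as.integer(start[keep]),
             end = as.integer(end[keep]))
    }
    exons <- add("exon", s, e)
    introns <- if (length(s) > 1L) add("intron", e[-length(e)], s[-1]) else
      tibble()
    cds <- add("CDS", pmax(s, g$cds_start), pmin(e, g$cds_end))
    # UTRs: exonic sequence outside the CDS span, 5' vs 3' by strand
    left <- add("left", s, pmin(e, g$cds_start))
    right <- add("right", pmax(s, g$cds_end), e)
    utr5 <- if (plus) left else right
    utr3 <- if (plus) right else left
    if (nrow(utr5)) utr5$label <- "5'-UTR"
    if (nrow(utr3)) utr3$label <- "3'-UTR"
    prom <- if (plus) add("TSS-up", tss - tss_flank, tss) else
      add("TSS-up", tss, tss + tss_flank)
    updown <- add("TSS-up-down", tss - tss_flank, tss + tss_flank)
    splice_sites <- c(e[-length(e)], s[-1])          # internal boundaries
    splice <- if (length(splice_sites)) {
      add("splice-50", splice_sites - splice_flank,
          splice_sites + splice_flank)
    } else tibble()
    bind_rows(exons, introns, cds, utr5, utr3, prom, updown, splice) |>
      mutate(contig = g$contig, strand = g$strand, gene = g$name)
  })
  if (!nrow(rows)) {
    return(tibble(label = character(), contig = character(),
                  start = integer(), end = integer(), strand = character(),
                  gene = character()))
  }
  rows |>
    mutate(start = pmax(.data$start, 0L)) |>
    select("label", "contig", "start", "end", "strand", "gene") |>
    arrange(.data$label, .data$contig, .data$start)
}

#' Feature density per labeled genomic region class
#'
#' For every region label, counts the features that overlap (>= 1 bp) any
#' region of that label — a feature overlapping several same-label regions
#' counts once — and derives the density per kilobase of the label's total
#' (non-deduplicated) size. Strand is ignored by default because mined
#' regions of both strands are tallied against gene-stranded annotation.
#'
#' @param features tibble of intervals (`contig`, `start`, `end`, and
#'   `strand` if `stranded`).
#' @param regions labeled tibble from [build_region_models()] (or any
#'   tibble with `label`, `contig`, `start`, `end`).
#' @param stranded require same-strand overlap.
#' @return tibble: `label`, `n_regions`, `total_size_mb`, `count`,
#'   `density_per_kb` (features per kb; `NA` when the label has zero total
#'   size).
#' @export
region_density <- function(features, regions, stranded = FALSE) {
  labels <- unique(regions$label)
  purrr::map_dfr(labels, function(lb) {
    reg <- regions[regions$label == lb, , drop = FALSE]
    total_bp <- sum(reg$end - reg$start)
    cnt <- if (nrow(features)) {
      sum(overlaps_any(features, reg, stranded = stranded))
    } else 0L
    tibble(label = lb, n_regions = nrow(reg),
           total_size_mb = total_bp / 1e6, count = as.integer(cnt),
           density_per_kb = if (total_bp > 0) cnt / (total_bp / 1000)
                            else NA_real_)
  })
}

#' Compare two stranded interval sets
#'
#' Symmetric >= 1 bp same-strand overlap report, e.g. for benchmarking
#' mined regions against published polymerase-stalling interval sets.
#'
#' @param a,b tibbles of stranded intervals.
#' @param stranded require same-strand overlap (default `TRUE`).
#' @return one-row tibble: `n_a`, `n_b`, `n_a_in_b`, `n_b_in_a`,
#'   `fraction_a_in_b`, `fraction_b_in_a`.
#' @export
compare_sets <- function(a, b, stranded = TRUE) {
  na_in_b <- sum(overlaps_any(a, b, stranded = stranded))
  nb_in_a <- sum(overlaps_any(b, a, stranded = stranded))
  tibble(n_a = nrow(a), n_b = nrow(b),
         n_a_in_b = na_in_b, n_b_in_a = nb_in_a,
         fraction_a_in_b = if (nrow(a)) na_in_b / nrow(a) else NA_real_,
         fraction_b_in_a = if (nrow(b)) nb_in_a / nrow(b) else NA_real_)
}
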