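#' Call mined G4 regions (MG4s) genome-wide
#'
#' Scans both strands with (per-strand) calibrated parameters, extends each
#' hit 35 nt upstream, merges overlapping low-quality regions, removes
#' regions whose strand-sequence guanine fraction falls below `g_min`, and
#' classifies the surviving regions into structural families from the full
#' merged-region sequence. An MG4 found in strand-S reads is reported on
#' strand S with its guanine content evaluated on the strand-S sequence.
#'
#' @param tracks a `quad_tracks` tibble (see [build_tracks()]).
#' @param params a [scanner_params()], a named list of them (`"+"`, `"-"`),
#'   or a `quad_calibration` object.
#' @param genome named character vector / DNAStringSet (same reference the
#'   reads were aligned to).
#' @param replicate optional replicate id stored with each record.
#' @return tibble of MG4 records: `contig`, `start`, `end` (plus-strand BED
#'   coordinates), `strand`, `family`, `n_low`, `flag_value`, `n_hits`,
#'   `g_fraction`, `replicate`.
#' @export
call_mg4 <- function(tracks, params, genome, replicate = NA_character_) {
  genome <- as_genome(genome)
  lens <- contig_lengths(genome)
  miss <- setdiff(unique(tracks$contig), names(genome))
  if (length(miss)) {
    abort(paste0("contig(s) absent from reference: ",
                 paste(miss, collapse = ", ")))
  }
  par_list <- if (inherits(params, "quad_calibration")) params$params
    else if (inherits(params, "scanner_params")) list("+" = params,
                                                      "-" = params)
    else params
  stopifnot(all(STRANDS %in% names(par_list)))
  out <- purrr::map_dfr(STRANDS, function(std) {
    p <- par_list[[std]]
    stopifnot(inherits(p, "scanner_params"))
    hits <- scan_tracks(tracks[tracks$strand == std, ], p,
                        contig_lens = lens)
    reg <- hit_regions(hits, p, contig_lens = lens)
    if (!nrow(reg)) return(tibble())
    reg$g_fraction <- g_fraction_of(genome, reg$contig, reg$start, reg$end,
                                    reg$strand, p$g_mode)
    reg <- reg[reg$g_fraction >= p$g_min, , drop = FALSE]
    if (!nrow(reg)) return(tibble())
    reg$family <- classify_family(
      oriented_sequence(genome, reg$contig, reg$start, reg$end, reg$strand))
    reg
  })
  if (!nrow(out)) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  strand = character(), family = character(),
                  n_low = integer(), flag_value = integer(),
                  n_hits = integer(), g_fraction = double(),
                  replicate = character()))
  }
  out$replicate <- replicate
  # post-call invariants: disjoint within contig+strand
  chk <- out |>
    group_by(.data$contig, .data$strand) |>
    summarise(ok = all(diff(.data$start) > 0) &&
                all(head(.data$end, -1) <= tail(.data$start, -1)),
              .groups = "drop")
  stopifnot(all(chk$ok))
  select(out, "contig", "start", "end", "strand", "family", "n_low",
         "flag_value", "n_hits", "g_fraction", "replicate")
}

#' Intersect MG4 calls from two replicates
#'
#' Returns the records of `a` that overlap (>= 1 bp, same strand) at least
#' one record of `b`. Run it both ways for a reciprocal report.
#'
#' @param a,b MG4 tibbles from [call_mg4()].
#' @return subset of `a`.
#' @export
intersect_replicates <- function(a, b) {
  a[overlaps_any(a, b, stranded = TRUE), , drop = FALSE]
}

#' Fraction of predicted motifs recovered by mined regions
#'
#' A PG4 counts as detected iff it overlaps (>= 1 bp) an MG4 on the same
#' strand.
#'
#' @param pg4s tibble from [predict_pg4()].
#' @param mg4s tibble from [call_mg4()].
#' @return one-row tibble: `n_pg4`, `n_detected`, `fraction` (percent;
#'   `NA` when there are no PG4s).
#' @export
pg4_recovery <- function(pg4s, mg4s) {
  n <- nrow(pg4s)
  nd <- sum(overlaps_any(pg4s, mg4s, stranded = TRUE))
  tibble(n_pg4 = n, n_detected = nd,
         fraction = if (n == 0L) NA_real_ else 100 * nd / n)
}
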