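#' Structural family grammar
#'
#' Regular expressions for the hierarchical G4 structural families. The
#' hierarchy reflects predicted thermodynamic stability: canonical > long
#' loops > bulges > two tracts > others; a sequence matching several family
#' patterns is assigned the most stable one.
#'
#' * `canonical`: four runs of >= 3 guanines joined by 1-7 nt loops.
#' * `long_loops`: canonical-like with one, two or three loops stretched to
#'   8-12 nt (the five printed loop arrangements).
#' * `bulges`: four G-tracts with 1-7 nt loops where either exactly one tract
#'   carries a 1-7 nt non-G bulge (`GH{1,7}GG`, H = A/T/C) or two or more
#'   tracts carry short bulges (`GH{1,2}GG`).
#' * `two_tracts`: four runs of just 2 guanines with loops up to 12 nt.
#'
#' @return named character vector of regular expressions.
#' @export
family_patterns <- function() {
  n <- "[ATCG]"
  long_loops <- c(
    "G{3,}[ATCG]{8,12}(G{3}[ATCG]{1,7}){2}G{3,}",
    "G{3,}[ATCG]{1,7}G{3,}[ATCG]{8,12}G{3,}[ATCG]{1,7}G{3,}",
    "(G{3,}[ATCG]{8,12}){2}G{3}[ATCG]{1,7}G{3,}",
    "G{3,}[ATCG]{8,12}G{3,}[ATCG]{1,7}G{3,}[ATCG]{8,12}G{3,}",
    "(G{3,}[ATCG]{8,12}){3}G{3,}"
  )
  # bulged quadruplex: alternation over tract combinations
  plain <- "G{3,}"
  b1 <- "G[ATC]{1,7}GG"   # single bulged tract
  b2 <- "G[ATC]{1,2}GG"   # short bulge, two or more tracts
  loop <- "[ATCG]{1,7}"
  combos <- list()
  for (k in 1:4) {          # exactly one tract GH{1,7}GG
    tr <- rep(plain, 4); tr[k] <- b1
    combos[[length(combos) + 1L]] <- tr
  }
  for (m in utils::combn(4, 2, simplify = FALSE)) {
    tr <- rep(plain, 4); tr[m] <- b2
    combos[[length(combos) + 1L]] <- tr
  }
  for (m in utils::combn(4, 3, simplify = FALSE)) {
    tr <- rep(plain, 4); tr[m] <- b2
    combos[[length(combos) + 1L]] <- tr
  }
  combos[[length(combos) + 1L]] <- rep(b2, 4)
  bulges <- paste0("(", vapply(combos, function(tr)
    paste0(tr[1], loop, tr[2], loop, tr[3], loop, tr[4]), character(1)),
    ")", collapse = "|")
  c(
    canonical  = "(G{3,}[ATCG]{1,7}){3}G{3,}",
    long_loops = paste0("(", paste0("(", long_loops, ")", collapse = "|"), ")"),
    bulges     = bulges,
    two_tracts = "(G{2}[ATCG]{1,12}){3}G{2}"
  )
}

FAMILY_LEVELS <- c("canonical", "long_loops", "bulges", "two_tracts", "other")

#' Classify sequences into G4 structural families
#'
#' Assigns each sequence the first family in the stability hierarchy
#' (canonical > long loops > bulges > two tracts > other) whose pattern
#' matches anywhere in the sequence. Mined regions are longer than the
#' motifs they contain, so matching is unanchored.
#'
#' @param sequence character vector of DNA sequences (A/C/G/T/N; `N` never
#'   matches a pattern position).
#' @return character vector of family labels, one per sequence.
#' @examples
#' classify_family(c("GGGAGGGAGGGAGGG", "GGAGGAGGAGG"))
#' @export
classify_family <- function(sequence) {
  stopifnot(is.character(sequence))
  if (any(!nzchar(sequence))) abort("empty sequence")
  sequence <- toupper(sequence)
  pats <- family_patterns()
  out <- rep("other", length(sequence))
  todo <- rep(TRUE, length(sequence))
  for (fam in names(pats)) {
    if (!any(todo)) break
    hit <- todo & grepl(pats[[fam]], sequence)
    out[hit] <- fam
    todo <- todo & !hit
  }
  out
}

#' Classify "other" sequences into non-G4 secondary-structure subcategories
#'
#' Sequences that fall outside the G4 families often harbor other structures
#' that can also perturb sequencing: i-motifs (C-rich quadruplex analogues),
#' hairpins, and poly-A/T runs. The first matching subcategory wins, in the
#' order i-motif > hairpin > poly-A/T > unassigned.
#'
#' A hairpin is any >= 7 nt substring whose reverse complement occurs
#' downstream with a gap (loop) of at most `max_loop` nt; only exact
#' reverse-complement stems are considered and the leftmost stem wins.
#'
#' @param sequence character vector of DNA sequences, normally ones already
#'   classified as family `"other"`.
#' @param min_stem minimum hairpin stem length (nt).
#' @param max_loop maximum hairpin loop length (nt).
#' @param min_at minimum poly-A/T run length (nt).
#' @return tibble with one row per sequence: `kind` and 0-based half-open
#'   offsets `start`, `end` of the matched element (`NA` for unassigned).
#' @examples
#' classify_subfeature("CCCACCCACCCACCC")
#' @export
classify_subfeature <- function(sequence, min_stem = 7L, max_loop = 30L,
                                min_at = 10L) {
  stopifnot(is.character(sequence), all(nzchar(sequence)))
  sequence <- toupper(sequence)
  one <- function(s) {
    m <- regexpr("(C{3,}[ATCG]{1,7}){3}C{3,}", s)
    if (m > 0) {
      return(tibble(kind = "i_motif", start = as.integer(m) - 1L,
                    end = as.integer(m) + attr(m, "match.length") - 1L))
    }
    hp <- find_hairpin(s, min_stem, max_loop)
    if (!is.null(hp)) {
      return(tibble(kind = "hairpin", start = hp[1], end = hp[2]))
    }
    m <- regexpr(sprintf("[AT]{%d,}", min_at), s)
    if (m > 0) {
      return(tibble(kind = "poly_at", start = as.integer(m) - 1L,
                    end = as.integer(m) + attr(m, "match.length") - 1L))
    }
    tibble(kind = "unassigned", start = NA_integer_, end = NA_integer_)
  }
  purrr::map_dfr(sequence, one)
}

# leftmost exact reverse-complement stem of length `stem`; returns 0-based
# half-open [stem_start, stem2_end) or NULL.  A stem longer than `stem`
# always contains a length-`stem` suffix stem with the same loop, so fixed
# width search is exhaustive for the existence question.
find_hairpin <- function(s, stem = 7L, max_loop = 30L) {
  L <- nchar(s)
  if (L < 2L * stem + 0L) return(NULL)
  for (i in seq_len(L - 2L * stem + 1L)) {
    arm <- substr(s, i, i + stem - 1L)
    if (grepl("N", arm, fixed = TRUE)) next
    rc <- revcomp(arm)
    lo <- i + stem
    hi <- min(L - stem + 1L, i + stem + max_loop)
    if (hi < lo) next
    window <- substr(s, lo, hi + stem - 1L)
    hit <- regexpr(rc, window, fixed = TRUE)
    if (hit > 0) {
      j <- lo + as.integer(hit) - 1L          # 1-based start of second arm
      return(c(i - 1L, j + stem - 1L))
    }
  }
  NULL
}

#' Predict canonical G4 motifs (PG4s)
#'
#' Scans sequences for the canonical quadruplex pattern
#' `(G{3,}[ATCG]{1,7}){3}G{3,}`. For every candidate start the maximal match
#' (POSIX leftmost-longest, capped at `max_span` nt) is taken and overlapping
#' candidate matches are merged into one reported motif, so the output is a
#' set of maximal, non-overlapping motifs per strand. Minus-strand motifs are
#' found on the reverse complement and reported in plus-strand coordinates
#' with `strand = "-"`. `N` bases never match.
#'
#' @param genome named character vector, single string or
#'   [Biostrings::DNAStringSet].
#' @param strand_mode `"both"` (default) or `"plus"` to scan only the given
#'   strand.
#' @param max_span maximum motif span considered for a single candidate
#'   match (nt).
#' @return tibble with columns `contig`, `start`, `end` (0-based half-open,
#'   plus-strand coordinates), `strand`, `family` (always `"canonical"`),
#'   `sequence` (strand-oriented motif sequence).
#' @examples
#' predict_pg4("GGGAGGGAGGGAGGG", strand_mode = "plus")
#' @export
predict_pg4 <- function(genome, strand_mode = c("both", "plus"),
                        max_span = 75L) {
  strand_mode <- match.arg(strand_mode)
  genome <- as_genome(genome)
  strands <- if (strand_mode == "both") STRANDS else "+"
  out <- purrr::map_dfr(names(genome), function(ctg) {
    s <- genome[[ctg]]
    L <- nchar(s)
    purrr::map_dfr(strands, function(std) {
      scan_seq <- if (std == "+") s else revcomp(s)
      iv <- canonical_intervals(scan_seq, max_span)   # 0-based half-open
      if (!nrow(iv)) return(tibble())
      if (std == "-") {
        iv <- tibble(start = L - iv$end, end = L - iv$start) |>
          arrange(.data$start)
      }
      tibble(contig = ctg, start = iv$start, end = iv$end, strand = std,
             family = "canonical",
             sequence = oriented_sequence(setNames(s, ctg), ctg,
                                          iv$start, iv$end, std))
    })
  })
  if (!nrow(out)) {
    out <- tibble(contig = character(), start = integer(), end = integer(),
                  strand = character(), family = character(),
                  sequence = character())
  }
  arrange(out, .data$contig, .data$start, .data$strand)
}

# merged union of maximal canonical matches anchored at every candidate
# start (a match must begin with GGG).  TRE (perl = FALSE) gives POSIX
# longest matches for the anchored pattern.
canonical_intervals <- function(s, max_span = 75L) {
  L <- nchar(s)
  starts <- unlist(gregexpr("(?=GGG)", s, perl = TRUE))
  if (length(starts) == 1L && starts[1] == -1L) {
    return(tibble(start = integer(), end = integer()))
  }
  pat <- "^(G{3,}[ATCG]{1,7}){3}G{3,}"
  windows <- substr(rep(s, length(starts)), starts,
                    pmin(starts + max_span - 1L, L))
  m <- regexpr(pat, windows)
  len <- attr(m, "match.length")
  ok <- m == 1L
  if (!any(ok)) return(tibble(start = integer(), end = integer()))
  iv <- IRanges::reduce(IRanges::IRanges(start = starts[ok],
                                         width = len[ok]))
  tibble(start = IRanges::start(iv) - 1L, end = IRanges::end(iv))
}

#' Motif density per megabase of double-stranded genome
#'
#' Both strands are scanned, so the density denominator is twice the genome
#' size: `count / (genome_size_mb * 2)`.
#'
#' @param count number of motifs (non-negative).
#' @param genome_size_mb genome size in megabases (positive).
#' @return motifs per Mb (unrounded; round at presentation).
#' @examples
#' round(pg4_density(38, 12.2), 2)   # yeast-scale example
#' @export
pg4_density <- function(count, genome_size_mb) {
  stopifnot(all(count >= 0))
  if (any(genome_size_mb <= 0)) abort("genome size must be positive")
  count / (genome_size_mb * 2)
}
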