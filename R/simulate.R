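#' Simulation configuration
#'
#' Bundles every knob of the synthetic data generator: a random genome with
#' implanted structural features, and error-free 150-bp-style reads whose
#' per-base qualities follow an Illumina-like binned distribution, with
#' stochastic per-read quality drops of magnitude `delta` starting at the
#' start (in read orientation) of drop-bearing features on the feature
#' strand.
#'
#' The default quality model (`qual_model = "binned"`) draws each base
#' quality from `q_baseline + {0, -1, -4}` with probabilities
#' `qual_probs`; instrument quality tables are binned and skewed downward,
#' and a downward-skewed background keeps the median track free of spurious
#' upward steps, which the scanner's flag-site rule would otherwise turn
#' into hits. `qual_model = "normal"` uses `round(Normal(q_baseline,
#' jitter_sd))` instead.
#'
#' @param genome_length total contig length (nt).
#' @param features named integer vector of implant counts per family:
#'   `canonical`, `long_loops`, `bulges`, `two_tracts`, `i_motif`,
#'   `poly_at`, `gc_matched_null`.
#' @param drop_families families whose implants bear quality drops. The
#'   default is `"canonical"`: threshold calibration assumes negative
#'   windows are structure-free, so the calibration genome carries drops
#'   only at motifs the canonical predictor can label as positives.
#' @param read_length read length (nt).
#' @param depth target per-strand coverage.
#' @param q_baseline modal Phred quality.
#' @param qual_model `"binned"` or `"normal"`.
#' @param qual_probs probabilities of the `{0, -1, -4}` quality offsets
#'   (binned model).
#' @param jitter_sd standard deviation of the normal quality model.
#' @param delta per-read quality-drop magnitude (Phred units).
#' @param p_fold probability that a read of the feature strand spanning a
#'   drop-bearing feature start carries the drop.
#' @param drop_span `Inf` (default) drops the remainder of the read;
#'   a finite value limits the dropped stretch to that many bases.
#' @param gc background GC content (i.i.d. bases).
#' @param min_spacing minimum gap between implanted features (nt).
#' @param n_het number of heterozygous motif loci: the reference carries a
#'   broken canonical motif (one tract guanine replaced) and the alternate
#'   allele restores it.
#' @param het_alt_fraction expected fraction of alternate-allele reads.
#' @param het_p_fold drop probability for alternate-allele (motif-forming)
#'   reads at heterozygous loci.
#' @param seed integer seed; every random draw of the generator derives
#'   from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genome_length = 200000L,
                       features = c(canonical = 180L, long_loops = 5L,
                                    bulges = 5L, two_tracts = 5L,
                                    i_motif = 0L, poly_at = 3L,
                                    gc_matched_null = 6L),
                       drop_families = "canonical",
                       read_length = 150L, depth = 30,
                       q_baseline = 37L,
                       qual_model = c("binned", "normal"),
                       qual_probs = c(0.75, 0.20, 0.05),
                       jitter_sd = 0.5,
                       delta = 6L, p_fold = 0.3, drop_span = Inf,
                       gc = 0.5, min_spacing = 500L,
                       n_het = 0L, het_alt_fraction = 0.5,
                       het_p_fold = 1.0, seed = 1L) {
  qual_model <- match.arg(qual_model)
  feat_names <- c("canonical", "long_loops", "bulges", "two_tracts",
                  "i_motif", "poly_at", "gc_matched_null")
  f <- setNames(rep(0L, length(feat_names)), feat_names)
  f[names(features)] <- as.integer(features)
  stopifnot(genome_length > 0, read_length > 0, depth >= 0,
            p_fold >= 0, p_fold <= 1, gc > 0, gc < 1,
            het_alt_fraction >= 0, het_alt_fraction <= 1,
            het_p_fold >= 0, het_p_fold <= 1,
            abs(sum(qual_probs) - 1) < 1e-8)
  structure(list(genome_length = as.integer(genome_length), features = f,
                 drop_families = drop_families,
                 read_length = as.integer(read_length), depth = depth,
                 q_baseline = as.integer(q_baseline),
                 qual_model = qual_model, qual_probs = qual_probs,
                 jitter_sd = jitter_sd, delta = as.integer(delta),
                 p_fold = p_fold, drop_span = drop_span, gc = gc,
                 min_spacing = as.integer(min_spacing),
                 n_het = as.integer(n_het),
                 het_alt_fraction = het_alt_fraction,
                 het_p_fold = het_p_fold, seed = as.integer(seed)),
            class = "sim_config")
}

# ---- family sequence generators (alphabet choices avoid accidental
#      matches of a more stable family; long-loop arrangements follow the
#      five printed loop patterns) ----

rand_chars <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

gen_family_seq <- function(family) {
  loops <- function(k, lens, alphabet = c("A", "C", "T")) {
    vapply(seq_len(k), function(i)
      rand_chars(sample(lens, 1), alphabet), character(1))
  }
  tract <- function(len) strrep("G", len)
  switch(family,
    canonical = {
      t <- vapply(sample(3:4, 4, replace = TRUE), tract, character(1))
      l <- loops(3, 1:7)
      paste0(t[1], l[1], t[2], l[2], t[3], l[3], t[4])
    },
    long_loops = {
      pattern <- sample(list(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
                             c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE),
                             c(TRUE, TRUE, TRUE)), 1)[[1]]
      t <- vapply(rep(3L, 4), tract, character(1))
      l <- ifelse(pattern, loops(3, 8:12), loops(3, 1:7))
      paste0(t[1], l[1], t[2], l[2], t[3], l[3], t[4])
    },
    bulges = {
      bulged <- function(h) paste0("G", rand_chars(h, c("A", "T", "C")), "GG")
      if (runif(1) < 0.5) {
        tr <- vapply(rep(3L, 4), tract, character(1))
        tr[sample(4, 1)] <- bulged(sample(1:7, 1))
      } else {
        tr <- vapply(rep(3L, 4), tract, character(1))
        for (k in sample(4, sample(2:3, 1))) tr[k] <- bulged(sample(1:2, 1))
      }
      l <- loops(3, 1:7)
      paste0(tr[1], l[1], tr[2], l[2], tr[3], l[3], tr[4])
    },
    two_tracts = {
      l <- loops(3, 1:12)
      paste0("GG", l[1], "GG", l[2], "GG", l[3], "GG")
    },
    i_motif = {
      t <- vapply(sample(3:4, 4, replace = TRUE), function(n)
        strrep("C", n), character(1))
      l <- loops(3, 1:7, alphabet = c("A", "T"))
      paste0(t[1], l[1], t[2], l[2], t[3], l[3], t[4])
    },
    poly_at = rand_chars(sample(10:14, 1),
                         alphabet = c(sample(c("A", "T"), 1))),
    gc_matched_null = {
      repeat {
        s <- rand_chars(sample(20:30, 1),
                        alphabet = c("G", "G", "A", "C", "T"))
        if (!grepl("GGG", s, fixed = TRUE)) return(s)
      }
    },
    abort(paste0("unknown family: ", family))
  )
}

#' Generate a synthetic genome with implanted features
#'
#' Draws an i.i.d. background at the configured GC content, implants the
#' configured features (minus-strand implants are reverse-complemented) at
#' loci spaced at least `min_spacing` apart, adds heterozygous motif loci
#' (reference allele breaks one guanine tract of a canonical motif), and
#' resamples any background stretch that spawns a spurious canonical motif
#' so the canonical truth set is exactly the implanted one.
#'
#' @param config a [sim_config()].
#' @param contig contig name.
#' @return list with `genome` (named character vector), `truth` (tibble:
#'   `contig`, `start`, `end`, `strand`, `family`, `drop_bearing`, `name`),
#'   `het` (tibble: `contig`, `pos`, `ref`, `alt`, `strand`,
#'   `motif_start`, `motif_end`).
#' @export
sim_genome <- function(config, contig = "sim1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  probs <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
             G = config$gc / 2, T = (1 - config$gc) / 2)
  chars <- sample(names(probs), L, replace = TRUE, prob = probs)

  fams <- rep(names(config$features), config$features)
  n_feat <- length(fams) + config$n_het
  feat_seqs <- lapply(fams, gen_family_seq)
  het_items <- if (config$n_het > 0) {
    lapply(seq_len(config$n_het), function(i) {
      m <- gen_family_seq("canonical")
      gpos <- which(strsplit(m, "")[[1]] == "G")
      j <- sample(gpos, 1)                    # oriented offset (1-based)
      broken <- m
      substr(broken, j, j) <- "A"
      list(motif = m, broken = broken, offset = j)
    })
  } else list()
  lens <- c(vapply(feat_seqs, nchar, integer(1)),
            vapply(het_items, function(h) nchar(h$broken), integer(1)))
  if (n_feat > 0) {
    margin <- 300L
    slot <- (L - 2L * margin) %/% n_feat
    if (slot < config$min_spacing + max(lens) + 1L) {
      abort("features do not fit at the requested spacing")
    }
    order_idx <- sample(n_feat)               # shuffle families over slots
    starts <- integer(n_feat)
    for (k in seq_len(n_feat)) {
      i <- order_idx[k]
      room <- slot - lens[i] - config$min_spacing
      starts[i] <- margin + (k - 1L) * slot + sample.int(room + 1L, 1) - 1L
    }
  } else starts <- integer(0)

  strands <- sample(STRANDS, n_feat, replace = TRUE)
  truth <- tibble(contig = character(), start = integer(), end = integer(),
                  strand = character(), family = character(),
                  drop_bearing = logical(), name = character())
  het <- tibble(contig = character(), pos = integer(), ref = character(),
                alt = character(), strand = character(),
                motif_start = integer(), motif_end = integer())
  for (i in seq_along(fams)) {
    s <- feat_seqs[[i]]
    if (strands[i] == "-") s <- revcomp(s)
    idx <- starts[i] + seq_len(nchar(s))
    chars[idx] <- strsplit(s, "")[[1]]
    truth <- bind_rows(truth, tibble(
      contig = contig, start = starts[i], end = starts[i] + nchar(s),
      strand = strands[i], family = fams[i],
      drop_bearing = fams[i] %in% config$drop_families,
      name = sprintf("%s_%03d", fams[i], i)))
  }
  for (j in seq_along(het_items)) {
    h <- het_items[[j]]
    i <- length(fams) + j
    s <- h$broken
    std <- strands[i]
    if (std == "-") s <- revcomp(s)
    idx <- starts[i] + seq_len(nchar(s))
    chars[idx] <- strsplit(s, "")[[1]]
    if (std == "+") {
      pos <- starts[i] + h$offset - 1L
      ref <- "A"; alt <- "G"
    } else {
      pos <- starts[i] + nchar(s) - h$offset
      ref <- "T"; alt <- "C"
    }
    het <- bind_rows(het, tibble(
      contig = contig, pos = pos, ref = ref, alt = alt, strand = std,
      motif_start = starts[i], motif_end = starts[i] + nchar(s)))
  }
  genome <- setNames(paste(chars, collapse = ""), contig)

  # scrub spurious canonical motifs arising from the background, so the
  # canonical truth (and therefore the calibration positive set) is exact
  in_zone <- function(d, zones) {
    if (!nrow(zones)) rep(FALSE, nrow(d)) else
      overlaps_any(mutate(d, strand = "*"),
                   mutate(zones, strand = "*"), stranded = FALSE)
  }
  zones <- bind_rows(
    if (nrow(truth)) select(truth, "contig", "start", "end"),
    if (nrow(het)) transmute(het, .data$contig, start = .data$motif_start,
                             end = .data$motif_end))
  zones <- zones %||% tibble(contig = character(), start = integer(),
                             end = integer())
  for (iter in 1:50) {
    pg <- predict_pg4(genome)
    spurious <- pg[!in_zone(pg, zones), , drop = FALSE]
    if (!nrow(spurious)) break
    chars <- strsplit(genome[[contig]], "")[[1]]
    for (r in seq_len(nrow(spurious))) {
      span <- (spurious$start[r] + 1L):spurious$end[r]
      # only touch background bases, never implanted features
      bg <- span[!span %in% unlist(purrr::map2(zones$start, zones$end,
                                               function(a, b) (a + 1L):b))]
      chars[bg] <- sample(names(probs), length(bg), replace = TRUE,
                          prob = probs)
    }
    genome[[contig]] <- paste(chars, collapse = "")
  }
  list(genome = genome, truth = truth, het = het)
}

# per-base quality draw
draw_quals <- function(n, config) {
  q <- if (config$qual_model == "binned") {
    config$q_baseline + sample(c(0L, -1L, -4L), n, replace = TRUE,
                               prob = config$qual_probs)
  } else {
    as.integer(round(rnorm(n, config$q_baseline, config$jitter_sd)))
  }
  pmin(pmax(q, 2L), 41L)
}

#' Simulate reads with the per-read quality-drop model and write SAM
#'
#' Error-free single-end reads (CIGAR all-match) with uniform start
#' positions on both strands at the configured per-strand depth. A read on
#' a drop-bearing feature's strand whose span includes the feature's
#' oriented start carries, with probability `p_fold`, a quality drop of
#' `delta` from the feature start onward (in read orientation). Reads
#' covering a heterozygous locus carry the alternate allele with
#' probability `het_alt_fraction`; alternate (motif-restoring) reads on the
#' motif strand spanning the motif start drop with probability
#' `het_p_fold`. Output is coordinate-sorted SAM with a proper header;
#' deterministic given `config$seed`.
#'
#' @param sim result of [sim_genome()].
#' @param config the same [sim_config()].
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
sim_reads <- function(sim, config, path) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  contig <- names(sim$genome)[1]
  gseq <- sim$genome[[contig]]
  L <- nchar(gseq)
  rl <- config$read_length
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", contig, L))
  n_per_strand <- round(config$depth * L / rl)
  recs <- purrr::map_dfr(STRANDS, function(std) {
    n <- n_per_strand
    if (n == 0L) return(tibble())
    starts <- sample.int(L - rl + 1L, n, replace = TRUE) - 1L
    qual <- matrix(draw_quals(n * rl, config), nrow = n)   # plus orientation
    seqs <- substring(gseq, starts + 1L, starts + rl)

    # heterozygous allele assignment and substitution
    drop_extra <- vector("list", 0)
    if (nrow(sim$het)) {
      for (h in seq_len(nrow(sim$het))) {
        hv <- sim$het[h, ]
        cov <- which(starts <= hv$pos & starts + rl > hv$pos)
        if (!length(cov)) next
        is_alt <- runif(length(cov)) < config$het_alt_fraction
        for (k in which(is_alt)) {
          r <- cov[k]
          off <- hv$pos - starts[r] + 1L
          substr(seqs[r], off, off) <- hv$alt
        }
        if (hv$strand == std) {
          ostart <- if (std == "+") hv$motif_start else hv$motif_end - 1L
          span <- cov[is_alt]
          span <- span[starts[span] <= ostart & starts[span] + rl > ostart]
          folded <- span[runif(length(span)) < config$het_p_fold]
          if (length(folded)) {
            drop_extra[[length(drop_extra) + 1L]] <-
              tibble(read = folded, ostart = ostart)
          }
        }
      }
    }

    # feature drops
    feats <- sim$truth[sim$truth$drop_bearing & sim$truth$strand == std, ]
    drops <- purrr::map_dfr(seq_len(nrow(feats)), function(i) {
      f <- feats[i, ]
      ostart <- if (std == "+") f$start else f$end - 1L
      cov <- which(starts <= ostart & starts + rl > ostart)
      folded <- cov[runif(length(cov)) < config$p_fold]
      if (!length(folded)) return(tibble())
      tibble(read = folded, ostart = ostart)
    })
    drops <- bind_rows(drops, drop_extra)
    if (nrow(drops)) {
      for (i in seq_len(nrow(drops))) {
        r <- drops$read[i]
        off <- drops$ostart[i] - starts[r] + 1L    # column of feature start
        cols <- if (std == "+") off:rl else 1L:off
        if (is.finite(config$drop_span)) {
          cols <- if (std == "+") {
            off:min(rl, off + config$drop_span - 1L)
          } else max(1L, off - config$drop_span + 1L):off
        }
        qual[r, cols] <- pmax(qual[r, cols] - config$delta, 2L)
      }
    }
    tibble(start = starts, flag = if (std == "+") 0L else 16L,
           seq = seqs,
           qual = vapply(seq_len(n), function(i)
             intToUtf8(qual[i, ] + 33L), character(1)))
  })
  if (nrow(recs)) {
    recs <- arrange(recs, .data$start)
    body <- sprintf("r%06d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                    seq_len(nrow(recs)), recs$flag, contig, recs$start + 1L,
                    rl, recs$seq, recs$qual)
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Score MG4 calls against simulation truth
#'
#' A truth feature is recovered iff it overlaps (>= 1 bp, same strand) at
#' least one call; a call is true iff it overlaps a drop-bearing truth
#' feature. Recall is computed over drop-bearing features.
#'
#' @param calls MG4 tibble from [call_mg4()].
#' @param truth truth tibble from [sim_genome()].
#' @return list: `recall`, `precision`, `n_truth`, `n_calls`,
#'   `per_family` (tibble of per-family recall over drop-bearing features).
#' @export
sim_evaluate <- function(calls, truth) {
  tr <- truth[truth$drop_bearing, , drop = FALSE]
  rec <- if (nrow(tr)) mean(overlaps_any(tr, calls)) else NA_real_
  prec <- if (nrow(calls)) mean(overlaps_any(calls, tr)) else NA_real_
  per_family <- tr |>
    mutate(hit = overlaps_any(tr, calls)) |>
    group_by(.data$family) |>
    summarise(n = dplyr::n(), recall = mean(.data$hit), .groups = "drop")
  list(recall = rec, precision = prec, n_truth = nrow(tr),
       n_calls = nrow(calls), per_family = per_family)
}

#' Write simulated heterozygous loci as a VCF
#'
#' @param het tibble from [sim_genome()] (`contig`, `pos`, `ref`, `alt`).
#' @param path output path.
#' @param genotype genotype string written for the single sample.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(het, path, genotype = "0/1") {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  "sample1"))
  body <- if (nrow(het)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
            het$contig, het$pos + 1L, het$ref, het$alt, genotype)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
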