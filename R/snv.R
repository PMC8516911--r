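#' Pre-read an alignment file for repeated allele-split calls
#'
#' Expands a SAM/BAM once into per-base records with read identity and
#' called base, so [allele_split_call()] can be applied to many SNVs
#' without re-reading the file.
#'
#' @param path SAM/BAM file.
#' @return list with `bases` (per-aligned-base tibble) and
#'   `contig_lengths`.
#' @export
read_alignments_for_snv <- function(path) {
  aln <- read_alignments(path, keep_seq = TRUE)
  list(bases = expand_aligned_bases(aln$records),
       contig_lengths = aln$contig_lengths)
}

#' Read biallelic SNVs from a VCF
#'
#' @param path VCF file (plain text or bgzipped).
#' @return tibble: `contig`, `pos` (0-based), `ref`, `alt`, `zygosity`
#'   (`hom`/`het` from the first sample's GT; `hom` when no genotype
#'   column is present). Indels and multiallelic records are skipped with a
#'   message.
#' @export
read_snvs <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    return(tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), zygosity = character()))
  }
  snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !grepl(",", fix$ALT)
  if (any(!snv)) {
    inform(sprintf("skipping %d non-SNV/multiallelic record(s)", sum(!snv)))
  }
  zyg <- rep("hom", nrow(fix))
  if (ncol(v@gt) >= 2L) {
    gt <- vcfR::extract.gt(v, element = "GT")[, 1]
    zyg <- ifelse(grepl("^(0[/|]1|1[/|]0)$", gt), "het", "hom")
  }
  tibble(contig = fix$CHROM[snv], pos = as.integer(fix$POS[snv]) - 1L,
         ref = toupper(fix$REF[snv]), alt = toupper(fix$ALT[snv]),
         zygosity = zyg[snv])
}

#' Apply homozygous SNVs to a reference genome
#'
#' Substitutes the alternate allele at every homozygous SNV position;
#' sequence lengths are preserved. Records whose stated reference allele
#' does not match the genome are rejected with a message; non-SNV records
#' are skipped.
#'
#' @param genome named character vector / DNAStringSet.
#' @param variants tibble from [read_snvs()] (columns `contig`, `pos`,
#'   `ref`, `alt`, optionally `zygosity` — only `hom` rows are applied).
#' @return modified genome (named character vector).
#' @export
apply_homozygous <- function(genome, variants) {
  genome <- as_genome(genome)
  v <- as_tibble(variants)
  if ("zygosity" %in% names(v)) v <- v[v$zygosity == "hom", , drop = FALSE]
  keep <- nchar(v$ref) == 1L & nchar(v$alt) == 1L
  if (any(!keep)) inform(sprintf("skipping %d indel record(s)", sum(!keep)))
  v <- v[keep, , drop = FALSE]
  for (ctg in unique(v$contig)) {
    if (!ctg %in% names(genome)) {
      abort(paste0("contig absent from reference: ", ctg))
    }
    vv <- v[v$contig == ctg, ]
    have <- substr(rep(genome[[ctg]], nrow(vv)), vv$pos + 1L, vv$pos + 1L)
    bad <- have != vv$ref
    if (any(bad)) {
      inform(sprintf(
        "rejecting %d record(s) on %s with reference-allele mismatch",
        sum(bad), ctg))
      vv <- vv[!bad, , drop = FALSE]
    }
    s <- strsplit(genome[[ctg]], "", fixed = TRUE)[[1]]
    s[vv$pos + 1L] <- vv$alt
    genome[[ctg]] <- paste(s, collapse = "")
  }
  genome
}

#' Gained and lost canonical motifs between two genomes
#'
#' Predicts canonical motifs on both genomes and reports motifs of the
#' modified genome with no identical-interval, same-strand counterpart in
#' the reference (`gained`) and vice versa (`lost`). Exact interval
#' matching (shift tolerance 0) avoids calling a shifted motif both gained
#' and lost.
#'
#' @param reference,modified genomes with identical contigs and lengths.
#' @return list of tibbles `gained` and `lost` (motif tibbles as from
#'   [predict_pg4()]).
#' @export
pg4_delta <- function(reference, modified) {
  reference <- as_genome(reference); modified <- as_genome(modified)
  stopifnot(identical(names(reference), names(modified)),
            identical(nchar(reference), nchar(modified)))
  pr <- predict_pg4(reference)
  pm <- predict_pg4(modified)
  key <- c("contig", "start", "end", "strand")
  list(gained = anti_join(pm, pr, by = key),
       lost = anti_join(pr, pm, by = key))
}

#' Allele-split MG4 calling at a heterozygous SNV
#'
#' Partitions the reads that have an aligned base at the SNV position into
#' reference- and alternate-allele groups (other bases are discarded),
#' builds per-group strand-specific quality tracks over a local window of
#' `window + extension` nt on each side of the SNV, calls MG4s per group
#' with shared scanner parameters, and classifies the SNV by the two
#' per-allele outcomes: `plus_plus` (MG4 in both groups), `plus_minus`
#' (reference group only), `minus_plus` (alternate group only),
#' `minus_minus` (neither), or `insufficient` when either group has fewer
#' than `r_min` reads.
#'
#' @param alignments path to SAM/BAM, or the result of a previous
#'   [read_alignments_for_snv()] call when classifying many SNVs against
#'   the same file.
#' @param snv one-row tibble (or list) with `contig`, `pos` (0-based),
#'   `ref`, `alt`.
#' @param params [scanner_params()], named list per strand, or
#'   `quad_calibration`.
#' @param genome reference genome.
#' @param r_min minimum reads per allele group.
#' @param d_min track depth mask within the allele groups.
#' @return one-row tibble: `contig`, `pos`, `ref`, `alt`, `n_ref`, `n_alt`,
#'   `mg4_ref`, `mg4_alt` (`"yes"`/`"no"`/`"insufficient"`), `class`.
#' @export
allele_split_call <- function(alignments, snv, params, genome, r_min = 10L,
                              d_min = 10L) {
  genome <- as_genome(genome)
  snv <- as_tibble(as.list(snv))
  stopifnot(nrow(snv) == 1L)
  p1 <- if (inherits(params, "quad_calibration")) params$params[["+"]] else
    if (inherits(params, "scanner_params")) params else params[["+"]]
  span <- p1$window + p1$extension
  L <- nchar(genome[[snv$contig]])
  lo <- max(0L, snv$pos - span); hi <- min(L, snv$pos + span + 1L)
  if (is.character(alignments)) {
    alignments <- read_alignments_for_snv(alignments)
  }
  bases <- alignments$bases
  at <- bases[bases$pos == snv$pos & bases$contig == snv$contig, ]
  groups <- list(ref = unique(at$read_id[at$base == snv$ref]),
                 alt = unique(at$read_id[at$base == snv$alt]))
  n_other <- length(setdiff(unique(at$read_id),
                            unlist(groups, use.names = FALSE)))
  if (n_other > 0) {
    inform(sprintf("discarding %d read(s) with a third allele", n_other))
  }
  outcome <- purrr::map_chr(groups, function(ids) {
    if (length(ids) < r_min) return("insufficient")
    sub <- bases[bases$read_id %in% ids &
                   bases$pos >= lo & bases$pos < hi, ]
    trk <- tracks_from_bases(
      sub[, c("contig", "strand", "pos", "qual")],
      d_min = d_min, contig_lengths = alignments$contig_lengths)
    mg4 <- call_mg4(trk, params, genome)
    if (nrow(mg4)) "yes" else "no"
  })
  cls <- if (any(outcome == "insufficient")) "insufficient" else
    c(yes.yes = "plus_plus", yes.no = "plus_minus",
      no.yes = "minus_plus", no.no = "minus_minus")[
        paste(outcome[["ref"]], outcome[["alt"]], sep = ".")]
  tibble(contig = snv$contig, pos = snv$pos, ref = snv$ref, alt = snv$alt,
         n_ref = length(groups$ref), n_alt = length(groups$alt),
         mg4_ref = outcome[["ref"]], mg4_alt = outcome[["alt"]],
         class = unname(cls))
}
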