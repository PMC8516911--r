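gene_row <- function(name = "g1", contig = "c", strand = "+",
                     tx_start = 10000L, tx_end = 20000L,
                     cds_start = 11000L, cds_end = 19000L,
                     exon_starts = "10000,15000", exon_ends = "12000,20000") {
  tibble::tibble(name = name, contig = contig, strand = strand,
                 tx_start = tx_start, tx_end = tx_end,
                 cds_start = cds_start, cds_end = cds_end,
                 exon_starts = exon_starts, exon_ends = exon_ends)
}

test_that("gene models produce strand-aware promoter and TSS regions", {
  reg <- build_region_models(gene_row())
  prom <- reg[reg$label == "TSS-up", ]
  expect_equal(c(prom$start, prom$end), c(9000L, 10000L))
  updown <- reg[reg$label == "TSS-up-down", ]
  expect_equal(c(updown$start, updown$end), c(9000L, 11000L))
  # minus-strand gene with TSS at tx_end = 10000 reflects the promoter
  m <- build_region_models(gene_row(strand = "-", tx_start = 5000L,
                                    tx_end = 10000L, cds_start = 6000L,
                                    cds_end = 9000L,
                                    exon_starts = "5000", exon_ends = "10000"))
  promm <- m[m$label == "TSS-up", ]
  expect_equal(c(promm$start, promm$end), c(10000L, 11000L))
  expect_equal(c(m[m$label == "TSS-up-down", ]$start,
                 m[m$label == "TSS-up-down", ]$end), c(9000L, 11000L))
})

test_that("a two-exon gene yields two splice sites with four 50-nt flanks", {
  reg <- build_region_models(gene_row())
  spl <- reg[reg$label == "splice-50", ]
  # hand-enumerated: exon1 end 12000 and exon2 start 15000, +/- 50 each,
  # emitted as one 100-nt window per splice site
  expect_equal(sort(spl$start), c(11950L, 14950L))
  expect_equal(sort(spl$end), c(12050L, 15050L))
  expect_equal(sum(spl$end - spl$start), 200L)
  intr <- reg[reg$label == "intron", ]
  expect_equal(c(intr$start, intr$end), c(12000L, 15000L))
  utr5 <- reg[reg$label == "5'-UTR", ]
  expect_equal(c(utr5$start, utr5$end), c(10000L, 11000L))
  utr3 <- reg[reg$label == "3'-UTR", ]
  expect_equal(c(utr3$start, utr3$end), c(19000L, 20000L))
  cds <- reg[reg$label == "CDS", ]
  expect_equal(cds$start, c(11000L, 15000L))
  expect_equal(cds$end, c(12000L, 19000L))
})

test_that("minus-strand gene models equal the reflected plus-strand construction", {
  L <- 30000L
  plus <- gene_row()
  minus <- gene_row(strand = "-",
                    tx_start = L - 20000L, tx_end = L - 10000L,
                    cds_start = L - 19000L, cds_end = L - 11000L,
                    exon_starts = paste(L - 20000L, L - 12000L, sep = ","),
                    exon_ends = paste(L - 15000L, L - 10000L, sep = ","))
  rp <- build_region_models(plus)
  rm <- build_region_models(minus)
  key <- function(d) {
    d |>
      dplyr::mutate(s = pmin(d$start, d$end)) |>
      dplyr::arrange(label, s) |>
      dplyr::transmute(label, w = end - start)
  }
  reflected <- rp |>
    dplyr::mutate(start2 = L - rp$end, end2 = L - rp$start) |>
    dplyr::transmute(label, start = start2, end = end2)
  expect_equal(
    dplyr::arrange(reflected, label, start) |> as.data.frame(),
    dplyr::arrange(rm[, c("label", "start", "end")], label, start) |>
      as.data.frame(),
    ignore_attr = TRUE)
})

test_that("region densities count features once per label and scale per kb", {
  regions <- tibble::tibble(
    label = c("A", "A", "B"),
    contig = "c", strand = "+",
    start = c(0L, 1000L, 5000L), end = c(500L, 1500L, 15000L))
  feats <- tibble::tibble(contig = "c",
                          start = c(100L, 450L, 1200L, 20000L),
                          end = c(150L, 1100L, 1300L, 20050L),
                          strand = "+")
  out <- region_density(feats, regions)
  a <- out[out$label == "A", ]
  # feature 2 overlaps both A windows but counts once
  expect_equal(a$count, 3L)
  expect_equal(a$density_per_kb, 3 / 1)       # 1000 bp total
  b <- out[out$label == "B", ]
  expect_equal(b$count, 0L)
  expect_equal(b$density_per_kb, 0)
  # empty features
  empty <- region_density(feats[0, ], regions)
  expect_true(all(empty$count == 0L))
  # doubling region sizes at fixed count halves the density
  doubled <- dplyr::mutate(regions, end = start + 2L * (end - start))
  out2 <- region_density(feats, doubled)
  expect_equal(out2$density_per_kb[out2$label == "A"], a$count / 2)
})

test_that("published-table arithmetic: density = count / (size_mb * 1000)", {
  expect_equal(round(10361 / (15.6e6 / 1000), 2), 0.66)
  expect_equal(round(10181 / (38.5e6 / 1000), 2), 0.26)
  regions <- tibble::tibble(label = "5'-UTR", contig = "c", start = 0L,
                            end = 15.6e6)
  feats <- tibble::tibble(contig = "c", start = 1L, end = 2L, strand = "+")
  out <- region_density(feats, regions)
  expect_equal(out$total_size_mb, 15.6)
})

test_that("interval-set comparison is symmetric and matches the all-pairs oracle", {
  a <- tibble::tibble(contig = "c", start = c(0L, 100L), end = c(50L, 150L),
                      strand = "+")
  b <- dplyr::bind_rows(a, tibble::tibble(contig = "c", start = 500L,
                                          end = 600L, strand = "+"))
  out <- compare_sets(a, b)
  expect_equal(out$fraction_a_in_b, 1)
  expect_equal(out$fraction_b_in_a, 2 / 3)
  disj <- tibble::tibble(contig = "c", start = 9000L, end = 9100L,
                         strand = "+")
  expect_equal(compare_sets(a, disj)$fraction_a_in_b, 0)
  set.seed(41)
  for (i in 1:25) {
    mk <- function(n) tibble::tibble(
      contig = "c", start = sample(0:400, n, replace = TRUE)) |>
      dplyr::mutate(end = start + sample(5:60, n, replace = TRUE),
                    strand = sample(c("+", "-"), n, replace = TRUE))
    x <- mk(sample(1:20, 1)); y <- mk(sample(1:20, 1))
    got <- compare_sets(x, y)
    expect_equal(got$n_a_in_b, sum(oracle_overlaps(x, y)))
    expect_equal(got$n_b_in_a, sum(oracle_overlaps(y, x)))
  }
})
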