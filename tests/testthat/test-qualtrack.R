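write_sam <- function(path, records, contig = "c1", len = 500L) {
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", contig, len),
               records), path)
}
sam_rec <- function(pos, qual, flag = 0L, cigar = NULL, contig = "c1",
                    seq = NULL) {
  n <- nchar(qual)
  if (is.null(cigar)) cigar <- paste0(n, "M")
  if (is.null(seq)) seq <- strrep("A", n)
  sprintf("r%d\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
          sample.int(1e6, 1), flag, contig, pos, cigar, seq, qual)
}

test_that("median rule is the lower-middle order statistic", {
  expect_equal(median_rule(c(30, 34, 38)), 34L)
  expect_equal(median_rule(c(30, 38)), 30L)
  expect_equal(median_rule(41L), 41L)
  expect_true(is.na(median_rule(integer(0))))
  set.seed(2)
  for (i in 1:50) {
    v <- sample(2:41, sample(1:30, 1), replace = TRUE)
    sv <- sort(v); n <- length(sv)
    exp <- if (n %% 2 == 1) sv[(n + 1) / 2] else min(sv[n / 2], sv[n / 2 + 1])
    expect_equal(median_rule(v), as.integer(exp))
  }
})

test_that("a single read yields its own qualities as the track", {
  q <- strrep(rawToChar(as.raw(30 + 33)), 150)
  f <- tempfile(fileext = ".sam")
  write_sam(f, sam_rec(11, q))
  tr <- build_tracks(f, d_min = 1L)
  expect_equal(nrow(tr), 150L)
  expect_true(all(tr$strand == "+"))
  expect_true(all(tr$median_q == 30L))
  expect_true(all(tr$depth == 1L))
  expect_equal(range(tr$pos), c(10L, 159L))
})

test_that("odd-count medians and strand separation behave per locus", {
  qc <- function(q, n = 10) strrep(rawToChar(as.raw(q + 33)), n)
  f <- tempfile(fileext = ".sam")
  write_sam(f, c(sam_rec(1, qc(30)), sam_rec(1, qc(34)),
                 sam_rec(1, qc(38)), sam_rec(1, qc(20), flag = 16L)))
  tr <- build_tracks(f, d_min = 1L)
  plus <- tr[tr$strand == "+", ]
  minus <- tr[tr$strand == "-", ]
  expect_true(all(plus$median_q == 34L))
  expect_true(all(plus$depth == 3L))
  # minus-strand reads never leak into the plus track
  expect_true(all(minus$median_q == 20L))
  expect_true(all(minus$depth == 1L))
})

test_that("soft clips, insertions and deletions contribute nothing", {
  f <- tempfile(fileext = ".sam")
  # 5S10M: only 10 aligned bases from query offset 6
  q1 <- paste0(strrep("#", 5), strrep("I", 10))          # clip Q2, aligned Q40
  # 5M2D5M: deletion advances reference without consuming quality
  q2 <- strrep("5", 10)                                  # Q20
  # 4M2I4M: insertion consumes query only
  q3 <- strrep("?", 10)                                  # Q30
  write_sam(f, c(sam_rec(1, q1, cigar = "5S10M", seq = strrep("A", 15)),
                 sam_rec(101, q2, cigar = "5M2D5M"),
                 sam_rec(201, q3, cigar = "4M2I4M")))
  tr <- build_tracks(f, d_min = 1L)
  expect_equal(tr$pos[tr$median_q == 40L], 0:9)
  d_read <- tr[tr$pos >= 100 & tr$pos < 112, ]
  expect_equal(d_read$pos, c(100:104, 107:111))          # 105,106 deleted
  expect_true(all(d_read$median_q == 20L))
  i_read <- tr[tr$pos >= 200, ]
  expect_equal(i_read$pos, 200:207)                      # 8 ref positions
  expect_true(all(i_read$median_q == 30L))
})

test_that("unsorted input is rejected and secondary records are dropped", {
  qc <- strrep("I", 10)
  f <- tempfile(fileext = ".sam")
  write_sam(f, c(sam_rec(100, qc), sam_rec(1, qc)))
  expect_error(build_tracks(f), "sorted")
  f2 <- tempfile(fileext = ".sam")
  write_sam(f2, c(sam_rec(1, qc), sam_rec(1, qc, flag = 256L),
                  sam_rec(1, qc, flag = 2048L)))
  tr <- build_tracks(f2, d_min = 1L)
  expect_true(all(tr$depth == 1L))
})

test_that("tracks equal a per-locus sort-and-pick oracle on simulated reads", {
  qs <- quick_sim(seed = 13, genome_length = 3000,
                  features = c(canonical = 2), depth = 12)
  got <- build_tracks(qs$sam, d_min = 10L)
  exp <- oracle_tracks_from_sam(qs$sam, d_min = 10L)
  expect_equal(as.data.frame(got[, c("contig", "strand", "pos", "depth",
                                     "median_q")]),
               as.data.frame(exp), ignore_attr = TRUE)
  # depth splits exactly across strands
  both <- merge(as.data.frame(got[got$strand == "+", c("pos", "depth")]),
                as.data.frame(got[got$strand == "-", c("pos", "depth")]),
                by = "pos")
  tot <- with(both, depth.x + depth.y)
  raw <- table(factor(unlist(lapply(
    grep("^@", readLines(qs$sam), value = TRUE, invert = TRUE),
    function(l) {
      f <- strsplit(l, "\t")[[1]]
      as.integer(f[4]) - 1L + seq_len(nchar(f[11])) - 1L
    })), levels = both$pos))
  expect_equal(unname(tot), as.integer(raw))
})

test_that("track construction is independent of read input order", {
  qs <- quick_sim(seed = 21, genome_length = 2000,
                  features = c(canonical = 1), depth = 8)
  ln <- readLines(qs$sam)
  hdr <- ln[startsWith(ln, "@")]
  body <- ln[!startsWith(ln, "@")]
  # re-sort by position with ties shuffled
  set.seed(1)
  body2 <- body[sample(length(body))]
  pos <- as.integer(vapply(body2, function(l) strsplit(l, "\t")[[1]][4], ""))
  f2 <- tempfile(fileext = ".sam")
  writeLines(c(hdr, body2[order(pos)]), f2)
  t1 <- build_tracks(qs$sam, d_min = 1L)
  t2 <- build_tracks(f2, d_min = 1L)
  expect_equal(as.data.frame(t1), as.data.frame(t2), ignore_attr = TRUE)
})
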