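test_that("genome generation is reproducible and respects spacing", {
  cfg <- sim_config(genome_length = 50000,
                    features = c(canonical = 10, long_loops = 3, bulges = 3,
                                 two_tracts = 2, poly_at = 2,
                                 gc_matched_null = 2),
                    seed = 7)
  a <- sim_genome(cfg)
  b <- sim_genome(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$truth), 22L)
  gaps <- with(dplyr::arrange(a$truth, start),
               start[-1] - head(end, -1))
  expect_true(all(gaps >= 500L))
  # every implanted feature sequence classifies as its family or better
  rank <- function(f) match(f, c("canonical", "long_loops", "bulges",
                                 "two_tracts", "other"))
  g4 <- a$truth[a$truth$family %in% c("canonical", "long_loops", "bulges",
                                      "two_tracts"), ]
  seqs <- quadmine:::oriented_sequence(a$genome, g4$contig, g4$start,
                                       g4$end, g4$strand)
  expect_true(all(rank(classify_family(seqs)) <= rank(g4$family)))
  # implanted canonical motifs are recovered by prediction at their loci
  can <- a$truth[a$truth$family == "canonical", ]
  pg4 <- predict_pg4(a$genome)
  expect_true(all(oracle_overlaps(can, pg4)))
  # ... and the canonical truth is exact: no spurious background motifs
  expect_false(any(!oracle_overlaps(pg4, a$truth)))
})

test_that("different seeds give different genomes", {
  cfg1 <- sim_config(genome_length = 10000, features = c(canonical = 2),
                     seed = 1)
  cfg2 <- sim_config(genome_length = 10000, features = c(canonical = 2),
                     seed = 2)
  expect_false(identical(sim_genome(cfg1)$genome, sim_genome(cfg2)$genome))
})

test_that("read simulation is deterministic, sorted, and SAM-conformant", {
  qs <- quick_sim(seed = 44, genome_length = 5000,
                  features = c(canonical = 2), depth = 5)
  sam2 <- tempfile(fileext = ".sam")
  sim_reads(qs$sim, qs$cfg, sam2)
  expect_identical(readLines(qs$sam), readLines(sam2))
  ln <- readLines(qs$sam)
  expect_equal(ln[1], "@HD\tVN:1.6\tSO:coordinate")
  body <- ln[!startsWith(ln, "@")]
  f <- do.call(rbind, strsplit(body, "\t"))
  expect_true(!is.unsorted(as.integer(f[, 4])))
  expect_true(all(f[, 6] == "150M"))
  expect_true(all(f[, 2] %in% c("0", "16")))
  expect_true(all(nchar(f[, 10]) == 150L, nchar(f[, 11]) == 150L))
  # error-free reads: sequences equal the reference substrings
  g <- qs$sim$genome[[1]]
  pos <- as.integer(f[, 4])
  expect_true(all(substring(g, pos, pos + 149L) == f[, 10]))
})

test_that("depth zero yields a header-only SAM", {
  cfg <- sim_config(genome_length = 2000, features = c(canonical = 1),
                    depth = 0, seed = 3)
  sim <- sim_genome(cfg)
  f <- tempfile(fileext = ".sam")
  sim_reads(sim, cfg, f)
  expect_equal(length(readLines(f)), 2L)
})

test_that("p_fold = 0 leaves the tracks hit-free at the features", {
  qs <- quick_sim(seed = 61, genome_length = 20000,
                  features = c(canonical = 5), p_fold = 0)
  tracks <- build_tracks(qs$sam)
  hits <- scan_tracks(tracks, scanner_params(4, 15))
  expect_equal(nrow(hits), 0L)
})

test_that("p_fold = 1 with a deep drop gives full scanner recall", {
  qs <- quick_sim(seed = 62, genome_length = 20000,
                  features = c(canonical = 5), p_fold = 1, delta = 10)
  tracks <- build_tracks(qs$sam)
  for (M in c(4, 10)) {
    mg4 <- call_mg4(tracks, scanner_params(M, 15), qs$sim$genome)
    ev <- sim_evaluate(mg4, qs$sim$truth)
    expect_equal(ev$recall, 1)
  }
  # median at feature starts dropped by at least delta relative baseline
  tru <- qs$sim$truth
  for (i in seq_len(nrow(tru))) {
    v <- track_vector(tracks, "sim1", tru$strand[i])
    ostart <- if (tru$strand[i] == "+") tru$start[i] else tru$end[i] - 1L
    expect_lte(v[ostart + 1L], 37 - 4)
  }
})

test_that("away from features the median track sits at the baseline", {
  qs <- quick_sim(seed = 63, genome_length = 20000,
                  features = c(canonical = 2), p_fold = 1)
  tracks <- build_tracks(qs$sam)
  tru <- qs$sim$truth
  near <- tibble::tibble(contig = "sim1", start = tru$start - 200L,
                         end = tru$end + 200L, strand = tru$strand)
  for (std in c("+", "-")) {
    v <- track_vector(tracks, "sim1", std)
    # exclude feature neighborhoods and masked loci
    excl <- unlist(purrr::map2(near$start, near$end, function(a, b) a:b))
    keep <- setdiff(which(!is.na(v)) - 1L, excl)
    expect_true(all(abs(v[keep + 1L] - 37) <= 2))
  }
})

test_that("evaluation scores identity and empty call sets correctly", {
  tru <- tibble::tibble(contig = "c", start = c(0L, 100L),
                        end = c(30L, 130L), strand = c("+", "-"),
                        family = "canonical", drop_bearing = TRUE,
                        name = c("a", "b"))
  id <- dplyr::select(tru, contig, start, end, strand)
  ev <- sim_evaluate(id, tru)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  ev0 <- sim_evaluate(id[0, ], tru)
  expect_equal(ev0$recall, 0)
  # calls overlapping nothing drop precision
  off <- tibble::tibble(contig = "c", start = 500L, end = 600L, strand = "+")
  expect_equal(sim_evaluate(dplyr::bind_rows(id, off), tru)$precision, 2 / 3)
})
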