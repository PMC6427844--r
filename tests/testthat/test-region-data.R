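test_that("call reader binarises by read ratio and drops hemi-methylated sites", {
  f <- write_tsv_lines(c(
    "chr1\t100\t3\t3",   # fully methylated -> 1
    "chr1\t200\t1\t2",   # 50% level -> dropped
    "chr1\t300\t0\t5",   # unmethylated -> 0
    "chr1\t400\t2\t6"    # 1/3 -> 0
  ))
  calls <- read_cell_calls(f, "counts")
  expect_equal(calls$position, c(100L, 300L, 400L))
  expect_equal(calls$state, c(1L, 0L, 0L))
})

test_that("duplicate count records are pooled before binarisation", {
  f <- write_tsv_lines(c(
    "chr1\t100\t1\t4",
    "chr1\t100\t3\t4",  # pooled: 4/8 = 0.5 -> dropped
    "chr1\t200\t2\t3",
    "chr1\t200\t2\t2"   # pooled: 4/5 -> 1
  ))
  calls <- read_cell_calls(f, "counts")
  expect_equal(calls$position, 200L)
  expect_equal(calls$state, 1L)
})

test_that("rates and binary dialects parse and validate", {
  f <- write_tsv_lines(c("chr1\t10\t0.9", "chr1\t20\t0.2", "chr2\t5\t0.5"))
  calls <- read_cell_calls(f, "rates")
  expect_equal(calls$state, c(1L, 0L))

  f2 <- write_tsv_lines(c("chr1\t10\t1", "chr1\t20\t0"))
  expect_equal(read_cell_calls(f2, "binary")$state, c(1L, 0L))

  bad <- write_tsv_lines(c("chr1\t10\t5\t3"))
  expect_error(read_cell_calls(bad, "counts"), "met_reads")
  malformed <- write_tsv_lines(c("chr1\t10\t1\t2", "chr1\tnot_a_number\t1\t2"))
  expect_error(read_cell_calls(malformed, "counts"), "line 2")
})

test_that("region mapping scales and orients relative coordinates", {
  ann <- tibble::tibble(
    region_id = c("plus", "minus"), chromosome = "chr1",
    start = c(7500, 47500), end = c(12500, 52500),
    strand = c("+", "-"), anchor = c(10000, 50000), window = 2500
  )
  calls <- tibble::tibble(
    cell = "c1", chromosome = "chr1",
    position = c(10000, 7500, 51250, 99999), # anchor, -window, anchor+1250(-), outside
    state = c(1L, 0L, 1L, 1L)
  )
  ds <- build_regions(calls, ann)
  plus <- ds[ds$region == "plus", ]
  expect_equal(sort(plus$pos), c(-1, 0))
  minus <- ds[ds$region == "minus", ]
  expect_equal(minus$pos, -0.5) # scaling then strand negation
  expect_equal(nrow(ds), 3) # CpG outside all regions discarded
})

test_that("interval regions map affinely and minus strand reverses order", {
  ann <- tibble::tibble(region_id = "iv", chromosome = "chr1",
                        start = 100, end = 300, strand = "+",
                        anchor = 200, window = NA_real_)
  calls <- tibble::tibble(cell = "c1", chromosome = "chr1",
                          position = c(100, 150, 300), state = c(1L, 0L, 1L))
  ds <- build_regions(calls, ann)
  expect_equal(ds$pos, c(-1, -0.5, 1))
  ann$strand <- "-"
  ds2 <- build_regions(calls, ann)
  # order-reversing on the minus strand
  expect_equal(ds2$pos, sort(-c(-1, -0.5, 1)))
})

test_that("BED annotations convert 0-based half-open coordinates", {
  bed <- write_tsv_lines("chr1\t99\t300\tr1\t0\t+")
  ann <- read_region_annotations(bed, "bed")
  expect_equal(ann$start, 100)
  expect_equal(ann$end, 300)
  expect_equal(ann$anchor, 200)
  tss <- write_tsv_lines("chr1\t5000\t-\tg1")
  ann2 <- read_region_annotations(tss, "tss", window = 2500)
  expect_equal(c(ann2$start, ann2$end), c(2500, 7500))
  expect_error(read_region_annotations(tss, "tss"), "window")
})

test_that("region filter enforces coverage, CpG minimum and variability", {
  mk <- function(cell, region, n, rate) {
    tibble::tibble(cell = cell, region = region,
                   pos = seq(-0.9, 0.9, length.out = n),
                   state = rep(c(1L, 0L), c(round(rate * n),
                                            n - round(rate * n))))
  }
  # 10 cells; region A covered (>=10 CpGs) by 4 cells only -> removed at 50%
  # region B has 9 CpGs everywhere -> removed; region C fine and variable;
  # region D covered but all means equal -> removed under variability
  d <- dplyr::bind_rows(
    purrr::map_dfr(1:4, ~mk(sprintf("c%02d", .x), "A", 12, 0.5)),
    purrr::map_dfr(1:10, ~mk(sprintf("c%02d", .x), "B", 9, 0.5)),
    purrr::map_dfr(1:10, ~mk(sprintf("c%02d", .x), "C", 12,
                             ifelse(.x <= 5, 0.25, 0.75))),
    purrr::map_dfr(1:10, ~mk(sprintf("c%02d", .x), "D", 12, 1))
  )
  d <- as_meth_dataset(d)
  kept <- filter_regions(d, min_cell_frac = 0.5, min_cpgs = 10)
  expect_equal(unique(kept$region), "C")
  # without the variability requirement D is retained
  kept2 <- filter_regions(d, min_cell_frac = 0.5, min_cpgs = 10,
                          require_variability = FALSE)
  expect_setequal(unique(kept2$region), c("C", "D"))
  # idempotence
  expect_equal(filter_regions(kept, 0.5, 10), kept)
  expect_error(filter_regions(d, min_cell_frac = 1, min_cpgs = 50),
               "removed")
})

test_that("train/test split partitions each block exactly and reproducibly", {
  sim <- tiny_sim()
  parts <- split_train_test(sim$data, 0.5, seed = 9)
  # union reconstructs the input, intersection empty
  key <- function(d) paste(d$cell, d$region, d$pos)
  expect_setequal(c(key(parts$train), key(parts$test)), key(sim$data))
  expect_length(intersect(key(parts$train), key(parts$test)), 0)
  # per-block counts: round(f * I), at least 1
  n_tr <- dplyr::count(parts$train, cell, region)
  n_all <- dplyr::count(sim$data, cell, region)
  j <- dplyr::left_join(n_all, n_tr, by = c("cell", "region"),
                        suffix = c("_all", "_tr"))
  expect_true(all(j$n_tr == pmax(1, round(0.5 * j$n_all))))
  # determinism
  parts2 <- split_train_test(sim$data, 0.5, seed = 9)
  expect_identical(parts$train, parts2$train)
  # fraction 1 -> empty test side
  all_train <- split_train_test(sim$data, 1, seed = 1)
  expect_equal(nrow(all_train$test), 0)
  expect_equal(nrow(all_train$train), nrow(sim$data))
})

test_that("dataset round-trips through the on-disk layout", {
  sim <- tiny_sim(n_cells = 5, n_regions = 3)
  dir <- tempfile()
  write_meth_dataset(sim$data, dir, extra = list(note = "roundtrip"))
  back <- read_meth_dataset(dir)
  expect_equal(as.data.frame(back), as.data.frame(sim$data))
  expect_equal(attr(back, "cells"), attr(sim$data, "cells"))
  expect_equal(attr(back, "regions"), attr(sim$data, "regions"))
})
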