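write_gem_text <- function(lines, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".gem.gz" else ".gem")
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  writeLines(lines, con)
  close(con)
  path
}

test_that("read_gem accumulates duplicate records per pixel", {
  path <- write_gem_text(c(
    "#comment line",
    "geneID\tx\ty\tMIDCount",
    "Ttr\t0\t0\t1",
    "Ttr\t0\t0\t1",
    "Ttr\t0\t1\t2"
  ))
  grid <- read_gem(path, binsize = 1)
  m <- as.matrix(grid$counts[["Ttr"]])
  # record at (x=0, y=1) lands in row 2 (row = y), both (0,0) records in (1,1)
  expect_identical(dim(grid), c(2L, 1L))
  expect_equal(m[1, 1], 2)
  expect_equal(m[2, 1], 2)
})

test_that("read_gem handles single records, headerless files and gzip", {
  path <- write_gem_text("g1\t5\t7\t3")
  grid <- read_gem(path, binsize = 1)
  expect_identical(dim(grid), c(1L, 1L))
  expect_equal(as.matrix(grid$counts[["g1"]])[1, 1], 3)

  pathgz <- write_gem_text(c("geneID\tx\ty\tMIDCount", "a\t0\t0\t1", "b\t1\t2\t4"),
                           gz = TRUE)
  grid <- read_gem(pathgz, binsize = 1)
  expect_setequal(grid$genes, c("a", "b"))
  expect_equal(sum(gene_totals(grid)), 5)
})

test_that("read_gem rejects malformed rows with the offending line number", {
  path <- write_gem_text(c("#h", "geneID\tx\ty\tMIDCount", "g\t1\t1\t1",
                           "g\t2.5\t1\t1"))
  expect_error(read_gem(path), "line 4")
  path <- write_gem_text(c("g\t1\t1\t1", "g\tfoo\t1\t1"))
  expect_error(read_gem(path), "line 2")
  path <- write_gem_text(c("g\t1\t1\t-2"))
  expect_error(read_gem(path), "count at line 1")
  expect_error(read_gem(write_gem_text(character(0))), "empty")
  expect_error(read_gem(write_gem_text("#only a comment")), "empty")
})

test_that("binning matches brute-force accumulation on a random lattice", {
  set.seed(11)
  n <- 10000
  recs <- data.frame(
    gene = sample(c("a", "b", "c"), n, replace = TRUE),
    x = sample(0:99, n, replace = TRUE),
    y = sample(0:99, n, replace = TRUE),
    count = sample(1:3, n, replace = TRUE)
  )
  # ensure the full extent is observed
  recs$x[1:2] <- c(0, 99); recs$y[1:2] <- c(0, 99)
  grid <- from_records(recs, binsize = 2)
  expect_identical(dim(grid), c(50L, 50L))
  expect_equal(sum(gene_totals(grid)), sum(recs$count))
  # brute-force per-pixel accumulation for one gene
  ref <- matrix(0, 50, 50)
  sub <- recs[recs$gene == "a", ]
  for (i in seq_len(nrow(sub)))
    ref[floor(sub$y[i] / 2) + 1, floor(sub$x[i] / 2) + 1] <-
      ref[floor(sub$y[i] / 2) + 1, floor(sub$x[i] / 2) + 1] + sub$count[i]
  expect_equal(as.matrix(grid$counts[["a"]]), ref, ignore_attr = TRUE)
})

test_that("from_records uses the floor convention and default count 1", {
  recs <- data.frame(gene = "g", x = c(0, 2, 0, 2), y = c(0, 0, 2, 2))
  grid <- from_records(recs, binsize = 2)
  expect_equal(as.matrix(grid$counts[["g"]]), matrix(1, 2, 2), ignore_attr = TRUE)
  # 0.4999 vs 0.5001 binsize both floor to bin 0 with binsize 1
  recs <- data.frame(gene = "g", x = c(0.4999, 0.5001), y = c(0, 0))
  grid <- from_records(recs, binsize = 1)
  expect_identical(dim(grid), c(1L, 1L))
  expect_equal(sum(gene_totals(grid)), 2)
  expect_error(from_records(recs[0, ], 1), "non-empty")
})

test_that("binning at b then aggregating 2x2 blocks equals binning at 2b", {
  set.seed(3)
  recs <- data.frame(
    gene = sample(c("a", "b"), 500, replace = TRUE),
    x = c(0, 19, sample(0:19, 498, replace = TRUE)),
    y = c(0, 19, sample(0:19, 498, replace = TRUE))
  )
  fine <- from_records(recs, binsize = 1)
  coarse <- from_records(recs, binsize = 2)
  block_sum <- function(m) {
    m <- as.matrix(m)
    m[seq(1, nrow(m), 2), seq(1, ncol(m), 2)] +
      m[seq(2, nrow(m), 2), seq(1, ncol(m), 2)] +
      m[seq(1, nrow(m), 2), seq(2, ncol(m), 2)] +
      m[seq(2, nrow(m), 2), seq(2, ncol(m), 2)]
  }
  for (g in fine$genes)
    expect_equal(block_sum(fine$counts[[g]]),
                 as.matrix(coarse$counts[[g]]), ignore_attr = TRUE)
})

test_that("filter_genes keeps exactly the genes above threshold and is idempotent", {
  set.seed(5)
  grid <- random_grid(10, 10, 6)
  totals <- gene_totals(grid)
  expect_identical(filter_genes(grid, 0)$genes, grid$genes)
  thr <- unname(sort(totals)[3])
  filt <- filter_genes(grid, thr)
  expect_setequal(filt$genes, names(totals)[totals >= thr])
  expect_identical(filter_genes(filt, thr)$genes, filt$genes)
  expect_identical(dim(filt), dim(grid))
})

test_that("crop slices all genes identically and composes", {
  set.seed(6)
  grid <- random_grid(12, 15, 3)
  expect_equal(crop(grid, 1:12, 1:15)$counts, grid$counts)
  w <- crop(grid, 3:9, 2:11)
  for (g in grid$genes)
    expect_equal(as.matrix(w$counts[[g]]),
                 as.matrix(grid$counts[[g]])[3:9, 2:11], ignore_attr = TRUE)
  expect_equal(crop(crop(grid, 3:9, 2:11), 2:4, 3:5)$counts,
               crop(grid, 4:6, 4:6)$counts)
  expect_error(crop(grid, 0:5, 1:5), "bounds")
  expect_error(crop(grid, integer(0), 1:5), "empty")
})

test_that("total_counts equals per-pixel loop summation", {
  set.seed(7)
  grid <- random_grid(8, 9, 5)
  ref <- matrix(0, 8, 9)
  for (g in grid$genes) ref <- ref + as.matrix(grid$counts[[g]])
  expect_equal(total_counts(grid), ref, ignore_attr = TRUE)
  one <- crop(grid, 1:8, 1:9); one$counts <- one$counts[1]; one$genes <- one$genes[1]
  expect_equal(total_counts(one), as.matrix(grid$counts[[1]]), ignore_attr = TRUE)
  empty <- filter_genes(grid, Inf)
  expect_error(total_counts(empty), "no genes")
})

test_that("write_gem/read_gem round-trips a collection", {
  set.seed(8)
  grid <- random_grid(15, 11, 4)
  # anchor the corners so the data-driven origin reproduces the full extent
  m <- as.matrix(grid$counts[[1]]); m[1, 1] <- 1; m[15, 11] <- 1
  grid$counts[[1]] <- Matrix::Matrix(m, sparse = TRUE)
  for (gz in c(FALSE, TRUE)) {
    path <- tempfile(fileext = if (gz) ".gem.gz" else ".gem")
    write_gem(grid, path)
    back <- read_gem(path, binsize = 1, resolution_nm = grid$resolution)
    expect_setequal(back$genes, grid$genes)
    for (g in grid$genes)
      expect_equal(as.matrix(back$counts[[g]]), as.matrix(grid$counts[[g]]),
                   ignore_attr = TRUE)
  }
})
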