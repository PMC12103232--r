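test_that("cosine similarity matches direct evaluation", {
  expect_equal(cosine_similarity(c(2, 3, 1), c(2, 3, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 0)), 0.70711,
               tolerance = 1e-5)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero-norm")
  expect_error(cosine_similarity(1:2, 1:3), "equal length")
})

test_that("the score upper bound equals the clipped difference norm", {
  expect_equal(assignment_upper_bound(c(1, 0), c(0, 1)), 1)
  expect_equal(assignment_upper_bound(c(1, 0), c(1, 1) / sqrt(2)), 1 - 1 / sqrt(2))
  expect_error(assignment_upper_bound(c(1, 0), c(1, 0)), "identical")
  # the bound dominates the gap for random non-negative vectors, with equality
  # at the clipped difference direction
  set.seed(41)
  for (i in 1:500) {
    n <- sample(3:8, 1)
    a <- runif(n); b <- runif(n); x <- runif(n)
    ah <- a / sqrt(sum(a^2)); bh <- b / sqrt(sum(b^2))
    bound <- assignment_upper_bound(a, b)
    gap <- cosine_similarity(x, a) - cosine_similarity(x, b)
    expect_lte(gap, bound + 1e-12)
    xstar <- pmax(ah - bh, 0)
    if (sum(xstar) > 0) {
      gap_star <- cosine_similarity(xstar, a) - cosine_similarity(xstar, b)
      expect_equal(gap_star, bound, tolerance = 1e-9)
    }
  }
})

test_that("assignment_score normalizes the cosine gap and breaks ties first", {
  a <- c(3, 1, 0); b <- c(0, 1, 3)
  sig <- signature_matrix(cbind(A = a, B = b),
                          gene_names = paste0("g", 1:3))
  ah <- a / sqrt(sum(a^2)); bh <- b / sqrt(sum(b^2))
  res <- assignment_score(pmax(ah - bh, 0), sig)
  expect_identical(res$label, "A")
  expect_equal(res$score, 1, tolerance = 1e-12)
  # equidistant pixel: zero score, tie broken toward the first signature
  res <- assignment_score(c(1, 1, 1), sig)
  expect_identical(res$label, "A")
  expect_equal(res$score, 0)
  expect_error(assignment_score(c(0, 0, 0), sig), "zero expression")
  solo <- signature_matrix(cbind(A = a), gene_names = paste0("g", 1:3))
  expect_error(assignment_score(c(1, 0, 0), solo), "two signatures")
})

test_that("assignment_score agrees with a term-by-term reimplementation", {
  set.seed(42)
  for (i in 1:50) {
    n <- 7
    sig <- random_signatures(n, 5)
    p <- runif(n)
    res <- assignment_score(p, sig)
    cs <- apply(unclass(sig), 2, naive_cosine, u = p)
    best <- which(cs == max(cs))[1]
    rest <- cs; rest[best] <- -Inf
    second <- which(rest == max(rest))[1]
    sn <- apply(unclass(sig), 2, function(s) s / sqrt(sum(s^2)))
    bound <- sqrt(sum(pmax(sn[, best] - sn[, second], 0)^2))
    expect_identical(res$label, colnames(sig)[best])
    expect_equal(res$cosine, cs[best], tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(res$score, (cs[best] - cs[second]) / bound, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("single-type data is labeled with cosine 1 and empty regions stay background", {
  set.seed(43)
  sig <- signature_matrix(
    cbind(A = c(2, 1, 0, 0), B = c(0, 0, 3, 1)),
    gene_names = paste0("g", 1:4)
  )
  # one isolated cell expressing exactly signature A's profile
  nr <- 40
  counts <- lapply(setNames(rownames(sig), rownames(sig)), function(g) {
    m <- matrix(0, nr, nr)
    m[18:22, 18:22] <- unclass(sig)[g, "A"] * 2
    Matrix::Matrix(m, sparse = TRUE)
  })
  grid <- gene_grid(counts)
  map <- assign_celltypes(grid, sig, gaussian_kernel(2), chunk_size = 500)
  assigned <- map$labels >= 0
  expect_true(all(map$labels[assigned] == 0))
  expect_equal(max(abs(map$cosine[assigned] - 1)), 0, tolerance = 1e-9)
  # pixels beyond the kernel radius of any molecule are background
  expect_identical(map$labels[1, 1], -1L)
  expect_true(is.na(map$score[1, 1]) && is.na(map$cosine[1, 1]))
  expect_true(all(map$score[assigned] >= 0 & map$score[assigned] <= 1))
})

test_that("the label map is invariant to chunk size and count scaling", {
  set.seed(44)
  grid <- random_grid(23, 31, 4, density = 0.07)
  sig <- random_signatures(4, 3)
  k <- epanechnikov_kernel(2.2)
  full <- assign_celltypes(grid, sig, k, chunk_size = 500)
  for (cs in c(7, 10, 23)) {
    chunked <- assign_celltypes(grid, sig, k, chunk_size = cs)
    expect_identical(chunked$labels, full$labels)
    expect_equal(chunked$score, full$score, tolerance = 1e-12)
    expect_equal(chunked$cosine, full$cosine, tolerance = 1e-12)
    expect_equal(chunked$total_kde, full$total_kde, tolerance = 1e-12)
  }
  # multiplying all counts by a positive integer changes nothing
  scaled <- grid
  scaled$counts <- lapply(grid$counts, function(m) m * 7)
  s <- assign_celltypes(scaled, sig, k, chunk_size = 500)
  expect_identical(s$labels, full$labels)
  expect_equal(s$score, full$score, tolerance = 1e-9)
  expect_equal(s$cosine, full$cosine, tolerance = 1e-9)
})

test_that("signature genes absent from the data are dropped with a warning", {
  set.seed(45)
  grid <- random_grid(10, 10, 3)
  vals <- matrix(runif(10), 5, 2,
                 dimnames = list(c("g1", "g2", "g3", "absent1", "absent2"),
                                 c("A", "B")))
  sig <- signature_matrix(vals)
  expect_warning(assign_celltypes(grid, sig, gaussian_kernel(1)), "absent")
  off <- signature_matrix(matrix(runif(4), 2, 2,
         dimnames = list(c("nope1", "nope2"), c("A", "B"))))
  expect_error(assign_celltypes(grid, off, gaussian_kernel(1)), "no genes shared")
})

test_that("background filtering applies global and per-type thresholds", {
  set.seed(46)
  grid <- random_grid(20, 20, 4, density = 0.1)
  sig <- random_signatures(4, 3)
  map <- assign_celltypes(grid, sig, gaussian_kernel(1.5))
  expect_identical(filter_background(map, 0)$labels, map$labels)
  allbg <- filter_background(map, max(map$total_kde) * 1.01)
  expect_true(all(allbg$labels == -1L))
  expect_true(all(is.na(allbg$score)))
  # mixed thresholds match a per-pixel predicate oracle
  thr <- c(ct2 = unname(quantile(map$total_kde, 0.6)))
  filt <- filter_background(map, quantile(map$total_kde, 0.2), thr)
  for (px in sample(400, 50)) {
    lab <- map$labels[px]
    expected_bg <- map$total_kde[px] < quantile(map$total_kde, 0.2) ||
      (lab == 1L && map$total_kde[px] < thr[["ct2"]])
    expect_identical(filt$labels[px] == -1L, expected_bg || lab == -1L)
  }
  expect_error(filter_background(map, 0, c(bogus = 1)), "unknown cell type")
})

test_that("labeled_regions finds 8-connected components above the area cutoff", {
  labels <- matrix(-1L, 30, 30)
  labels[5:14, 5:14] <- 0L           # 10x10 block, area 100
  labels[20:24, 20:24] <- 0L         # 5x5 block, area 25
  labels[1:3, 25:28] <- 1L
  map <- structure(list(labels = labels, cosine = labels * NA_real_,
                        score = labels * NA_real_,
                        total_kde = matrix(1, 30, 30),
                        celltype_names = c("A", "B")),
                   class = "celltype_map")
  regs <- labeled_regions(map, "A", min_area = 60)
  expect_identical(nrow(regs), 1L)
  expect_equal(regs$centroid_row, 9.5)
  expect_equal(regs$centroid_col, 9.5)
  expect_identical(regs$area, 100L)
  expect_identical(nrow(labeled_regions(map, "A", min_area = 101)), 0L)
  both <- labeled_regions(map, "A", min_area = 1)
  expect_identical(nrow(both), 2L)
  expect_error(labeled_regions(map, "C"), "unknown cell type")

  # random mask against an independent flood fill
  set.seed(47)
  labels <- matrix(ifelse(runif(400) < 0.3, 0L, -1L), 20, 20)
  map$labels <- labels
  map$total_kde <- matrix(1, 20, 20)
  regs <- labeled_regions(map, "A", min_area = 1)
  ref <- flood_fill_regions(labels == 0L)
  expect_identical(nrow(regs), length(ref))
  got <- regs[order(regs$centroid_row, regs$centroid_col), ]
  want <- do.call(rbind, lapply(ref, function(r)
    data.frame(centroid_row = mean(r[, 1]), centroid_col = mean(r[, 2]),
               area = nrow(r))))
  want <- want[order(want$centroid_row, want$centroid_col), ]
  expect_equal(got$centroid_row, want$centroid_row)
  expect_equal(got$centroid_col, want$centroid_col)
  expect_equal(got$area, want$area)
})
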