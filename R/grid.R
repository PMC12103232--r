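#' Sparse per-gene count grids
#'
#' A `gene_grid` holds one sparse 2D count matrix per gene, all of identical
#' shape, plus the physical pixel size. It is the central data model of the
#' package: transcript positions are binned onto a shared pixel raster and
#' every downstream step (density estimation, classification) operates on
#' these per-gene matrices.
#'
#' Pixel row corresponds to the y coordinate and pixel column to the x
#' coordinate; bin index is `floor((y - y_min)/binsize)` so the grid origin is
#' the minimum observed coordinate. Matrices are indexed 1-based as usual in R.
#'
#' @param counts named list of sparse matrices (`Matrix::dgCMatrix`), one per
#'   gene, all with identical dimensions and non-negative integer entries.
#' @param resolution physical edge length of one pixel in nanometres.
#' @return An object of class `gene_grid` with fields `counts` (named list of
#'   `dgCMatrix`), `genes` (character vector in storage order), `dim`
#'   (rows, cols) and `resolution`.
#' @export
gene_grid <- function(counts, resolution = 1) {
  if (!is.list(counts) || length(counts) == 0L)
    stop("'counts' must be a non-empty named list of sparse matrices")
  genes <- names(counts)
  if (is.null(genes) || anyDuplicated(genes) || any(!nzchar(genes)))
    stop("'counts' must have unique non-empty gene names")
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("'resolution' must be a single positive number")
  counts <- lapply(counts, function(m) as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix"))
  d <- dim(counts[[1L]])
  for (g in genes) {
    m <- counts[[g]]
    if (!identical(dim(m), d))
      stop("all gene matrices must share the same shape; '", g, "' differs")
    x <- m@x
    if (length(x) && (any(x < 0) || any(x != floor(x))))
      stop("counts for gene '", g, "' must be non-negative integers")
  }
  structure(
    list(counts = counts, genes = genes, dim = d, resolution = resolution),
    class = "gene_grid"
  )
}

#' @export
print.gene_grid <- function(x, ...) {
  cat(sprintf(
    "gene_grid: %d genes on a %d x %d pixel grid (%.0f nm/px), %s molecules\n",
    length(x$genes), x$dim[1L], x$dim[2L], x$resolution,
    format(sum(vapply(x$counts, function(m) sum(m@x), numeric(1L))), big.mark = ",")
  ))
  invisible(x)
}

#' @export
dim.gene_grid <- function(x) x$dim

# shared binning: records -> gene_grid
bin_records <- function(gene, x, y, count, binsize, resolution) {
  r <- floor((y - min(y)) / binsize)
  c <- floor((x - min(x)) / binsize)
  nrow <- max(r) + 1L
  ncol <- max(c) + 1L
  gene <- factor(gene)
  counts <- lapply(split(seq_along(gene), gene), function(idx) {
    Matrix::sparseMatrix(
      i = r[idx] + 1L, j = c[idx] + 1L, x = count[idx],
      dims = c(nrow, ncol)
    )
  })
  gene_grid(counts, resolution = resolution)
}

#' Read a GEM transcript table into a gene grid
#'
#' Parses the tab-separated molecule tables exported by Stereo-seq-like
#' platforms: one record per line with a gene identifier, integer x and y bead
#' coordinates and a molecule count. Lines starting with `#` are skipped and a
#' first non-comment line of recognised column names (`geneID`, `x`, `y`,
#' `MIDCount`/`UMICount`/`MIDCounts`) is treated as a header. Gzip-compressed
#' files are read transparently.
#'
#' @param path path to the (optionally gzipped) GEM file.
#' @param binsize positive integer; bead coordinates are floor-divided by this
#'   after subtracting the observed minimum, so `binsize = 1` keeps native
#'   resolution.
#' @param resolution_nm physical size of one *input* coordinate unit in
#'   nanometres (500 for Stereo-seq bead pitch); the grid resolution is
#'   `binsize * resolution_nm`.
#' @return A [gene_grid].
#' @export
read_gem <- function(path, binsize = 1L, resolution_nm = 500) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.numeric(binsize) || length(binsize) != 1L || binsize < 1 || binsize != floor(binsize))
    stop("'binsize' must be a positive integer")
  if (grepl("\\.gz$", path)) {
    # decompress through a connection; fread's own gz support needs R.utils
    tmp <- tempfile(fileext = ".gem")
    con <- gzfile(path, "r")
    writeLines(readLines(con), tmp)
    close(con)
    on.exit(unlink(tmp), add = TRUE)
    path <- tmp
  }
  n_read <- 100L
  repeat {
    head_lines <- readLines(path, n = n_read)
    n_comment <- 0L
    while (n_comment < length(head_lines) && startsWith(head_lines[n_comment + 1L], "#"))
      n_comment <- n_comment + 1L
    if (n_comment < length(head_lines) || length(head_lines) < n_read) break
    n_read <- n_read * 4L
  }
  if (n_comment >= length(head_lines)) stop("empty GEM file: ", path)
  first <- head_lines[n_comment + 1L]
  fields <- strsplit(first, "\t", fixed = TRUE)[[1L]]
  known <- c("geneid", "genename", "gene", "x", "y", "midcount", "midcounts",
             "umicount", "umicounts", "count", "counts", "expcount")
  has_header <- all(tolower(fields) %in% known)
  dt <- data.table::fread(
    path, sep = "\t", header = has_header, skip = n_comment,
    colClasses = list(character = 1L), showProgress = FALSE
  )
  if (nrow(dt) == 0L) stop("empty GEM file: ", path)
  if (ncol(dt) < 3L) stop("GEM file must have at least gene, x, y columns: ", path)
  gene <- as.character(dt[[1L]])
  x <- dt[[2L]]
  y <- dt[[3L]]
  count <- if (ncol(dt) >= 4L) dt[[4L]] else rep(1, nrow(dt))
  # line number in the file for error reporting
  line_of <- function(i) i + n_comment + as.integer(has_header)
  bad <- which(!is.finite(suppressWarnings(as.numeric(x))) |
               !is.finite(suppressWarnings(as.numeric(y))))
  if (length(bad))
    stop("malformed coordinate at line ", line_of(bad[1L]), " of ", path)
  x <- as.numeric(x); y <- as.numeric(y); count <- as.numeric(count)
  bad <- which(x != floor(x) | y != floor(y))
  if (length(bad))
    stop("non-integer coordinate at line ", line_of(bad[1L]), " of ", path)
  bad <- which(!is.finite(count) | count < 1 | count != floor(count))
  if (length(bad))
    stop("invalid count at line ", line_of(bad[1L]), " of ", path)
  bin_records(gene, x, y, count, binsize, resolution = binsize * resolution_nm)
}

#' Build a gene grid from generic transcript records
#'
#' Ingests molecule tables from imaging-based platforms (or any source) as a
#' data frame of gene names and physical coordinates, binning them to pixels
#' with the same floor-division convention as [read_gem()].
#'
#' @param records data frame with columns `gene`, `x`, `y` and optionally
#'   `count` (defaults to 1 per record).
#' @param binsize positive physical length of one pixel edge, in the units of
#'   `x` and `y`.
#' @param resolution_nm physical size of one coordinate unit in nanometres;
#'   grid resolution is `binsize * resolution_nm`.
#' @return A [gene_grid].
#' @export
from_records <- function(records, binsize, resolution_nm = 1) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must be a non-empty data frame")
  need <- c("gene", "x", "y")
  if (!all(need %in% names(records)))
    stop("'records' must have columns gene, x, y")
  if (!is.numeric(binsize) || length(binsize) != 1L || binsize <= 0)
    stop("'binsize' must be a positive number")
  count <- if ("count" %in% names(records)) as.numeric(records$count) else rep(1, nrow(records))
  if (any(!is.finite(count) | count < 1 | count != floor(count)))
    stop("'count' must be positive integers")
  bin_records(as.character(records$gene), as.numeric(records$x),
              as.numeric(records$y), count, binsize,
              resolution = binsize * resolution_nm)
}

#' Total molecule count per gene
#'
#' @param grid a [gene_grid].
#' @return Named numeric vector of summed counts per gene.
#' @export
gene_totals <- function(grid) {
  stopifnot(inherits(grid, "gene_grid"))
  vapply(grid$counts, function(m) sum(m@x), numeric(1L))
}

#' Drop low-count genes
#'
#' Retains exactly the genes whose total molecule count is at least
#' `min_count`; shape and resolution are unchanged. May return a collection
#' with zero genes (downstream operations reject it).
#'
#' @param grid a [gene_grid].
#' @param min_count non-negative total-count threshold.
#' @return A filtered [gene_grid] (possibly with no genes).
#' @export
filter_genes <- function(grid, min_count) {
  stopifnot(inherits(grid, "gene_grid"))
  if (!is.numeric(min_count) || length(min_count) != 1L || min_count < 0)
    stop("'min_count' must be a single non-negative number")
  keep <- gene_totals(grid) >= min_count
  out <- grid
  out$counts <- grid$counts[keep]
  out$genes <- grid$genes[keep]
  out
}

#' Crop a gene grid to a pixel window
#'
#' Slices every gene matrix to the same rectangular region of interest.
#' Ranges are 1-based and inclusive, as with ordinary R matrix indexing.
#'
#' @param grid a [gene_grid].
#' @param rows,cols integer ranges (e.g. `101:300`) within the grid bounds.
#' @return The cropped [gene_grid].
#' @export
crop <- function(grid, rows, cols) {
  stopifnot(inherits(grid, "gene_grid"))
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (length(rows) == 0L || length(cols) == 0L)
    stop("empty crop range")
  if (any(diff(rows) != 1L) || any(diff(cols) != 1L))
    stop("crop ranges must be contiguous")
  if (min(rows) < 1L || max(rows) > grid$dim[1L] ||
      min(cols) < 1L || max(cols) > grid$dim[2L])
    stop("crop range out of grid bounds")
  out <- grid
  out$counts <- lapply(grid$counts, function(m) m[rows, cols, drop = FALSE])
  out$dim <- c(length(rows), length(cols))
  out
}

#' Dense grid of total counts over all (or selected) genes
#'
#' @param grid a [gene_grid].
#' @param genes optional character vector of gene names to sum over.
#' @return Dense numeric matrix of per-pixel summed counts.
#' @export
total_counts <- function(grid, genes = NULL) {
  stopifnot(inherits(grid, "gene_grid"))
  genes <- check_genes(grid, genes)
  acc <- grid$counts[[genes[1L]]]
  for (g in genes[-1L]) acc <- acc + grid$counts[[g]]
  as.matrix(acc)
}

check_genes <- function(grid, genes) {
  if (length(grid$genes) == 0L) stop("gene grid contains no genes")
  if (is.null(genes)) return(grid$genes)
  missing <- setdiff(genes, grid$genes)
  if (length(missing))
    stop("unknown gene(s): ", paste(missing, collapse = ", "))
  genes
}

#' Write a gene grid as a GEM-style table
#'
#' Serialises the grid as a tab-separated molecule table (gene, x, y, count at
#' pixel resolution) with `#`-prefixed metadata lines, so that
#' `read_gem(path, binsize = 1)` round-trips the collection. Paths ending in
#' `.gz` are gzip-compressed.
#'
#' @param grid a [gene_grid].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gem <- function(grid, path) {
  stopifnot(inherits(grid, "gene_grid"))
  if (length(grid$genes) == 0L) stop("gene grid contains no genes")
  parts <- lapply(grid$genes, function(g) {
    m <- grid$counts[[g]]
    s <- Matrix::summary(m)
    if (nrow(s) == 0L) return(NULL)
    data.table::data.table(geneID = g, x = s$j - 1L, y = s$i - 1L,
                           MIDCount = as.integer(s$x))
  })
  dt <- data.table::rbindlist(parts)
  if (nrow(dt) == 0L) stop("gene grid contains no molecules")
  gz <- grepl("\\.gz$", path)
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  writeLines(c(
    sprintf("#resolution_nm=%g", grid$resolution),
    sprintf("#dim=%d,%d", grid$dim[1L], grid$dim[2L]),
    paste(names(dt), collapse = "\t")
  ), con)
  close(con)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = FALSE,
                     compress = if (gz) "gzip" else "none")
  invisible(path)
}
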