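#' Write a cell-type map as images plus a legend table
#'
#' Writes, under `outdir`:
#' * `labels.tif` — 16-bit grayscale TIFF storing `label + 1` per pixel
#'   (background -1 becomes 0), a lossless encoding of the label grid;
#' * `labels_rgb.png` — the same map rendered with the palette colors,
#'   background black;
#' * `legend.tsv` — pixel value, cell-type name, hex color (records the +1
#'   shift; image formats have no negative indices);
#' * `score.tif`, `cosine.tif` — 32-bit float TIFFs, background written as 0;
#' * `total_kde.tif` — 32-bit float TIFF of `total_kde / max`, with the
#'   scaling maximum stored in `total_kde_max.tsv`.
#'
#' @param map a `celltype_map`.
#' @param palette named character vector of colors covering every cell type
#'   present in the map; defaults to `grDevices::hcl.colors` over all types.
#' @param outdir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_map_images <- function(map, palette = NULL, outdir) {
  stopifnot(inherits(map, "celltype_map"))
  if (length(map$celltype_names) > 65535L) stop("too many cell types for 16-bit labels")
  if (is.null(palette)) {
    palette <- grDevices::hcl.colors(max(3L, length(map$celltype_names)), "Dark 3")
    palette <- stats::setNames(palette[seq_along(map$celltype_names)],
                               map$celltype_names)
  }
  present <- map$celltype_names[sort(unique(map$labels[map$labels >= 0L])) + 1L]
  missing <- setdiff(present, names(palette))
  if (length(missing))
    stop("palette missing color(s) for: ", paste(missing, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    labels = file.path(outdir, "labels.tif"),
    labels_rgb = file.path(outdir, "labels_rgb.png"),
    legend = file.path(outdir, "legend.tsv"),
    score = file.path(outdir, "score.tif"),
    cosine = file.path(outdir, "cosine.tif"),
    total_kde = file.path(outdir, "total_kde.tif"),
    total_kde_max = file.path(outdir, "total_kde_max.tsv")
  )
  tiff::writeTIFF((map$labels + 1L) / 65535, paths[["labels"]],
                  bits.per.sample = 16L)
  rgb <- array(0, c(dim(map$labels), 3L))
  for (code in sort(unique(map$labels[map$labels >= 0L]))) {
    ct <- map$celltype_names[code + 1L]
    col <- grDevices::col2rgb(palette[[ct]]) / 255
    m <- map$labels == code
    for (ch in 1:3) {
      plane <- rgb[, , ch]; plane[m] <- col[ch]; rgb[, , ch] <- plane
    }
  }
  png::writePNG(rgb, paths[["labels_rgb"]])
  legend <- data.frame(
    pixel_value = c(0L, seq_along(map$celltype_names)),
    celltype = c("background", map$celltype_names),
    color = c("#000000", unname(vapply(
      map$celltype_names,
      function(ct) if (ct %in% names(palette)) palette[[ct]] else NA_character_,
      character(1L)
    )))
  )
  legend <- legend[legend$celltype %in% c("background", present), , drop = FALSE]
  data.table::fwrite(legend, paths[["legend"]], sep = "\t")
  zero_na <- function(x) { x[is.na(x)] <- 0; x }
  tiff::writeTIFF(zero_na(map$score), paths[["score"]], bits.per.sample = 32L)
  tiff::writeTIFF(zero_na(map$cosine), paths[["cosine"]], bits.per.sample = 32L)
  kmax <- max(map$total_kde)
  tiff::writeTIFF(if (kmax > 0) map$total_kde / kmax else map$total_kde,
                  paths[["total_kde"]], bits.per.sample = 32L)
  data.table::fwrite(data.frame(total_kde_max = kmax), paths[["total_kde_max"]],
                     sep = "\t")
  invisible(paths)
}

#' Read back a label grid written by [write_map_images()]
#'
#' @param path path to `labels.tif`.
#' @return Integer label matrix with -1 background sentinel.
#' @export
read_label_image <- function(path) {
  img <- tiff::readTIFF(path)
  matrix(as.integer(round(img * 65535)) - 1L, nrow(img), ncol(img))
}

#' Export local-maxima expression as MTX with TSV sidecars
#'
#' Writes the pseudo-cell (maxima) x genes expression matrix in the standard
#' single-cell exchange layout readable by AnnData/Seurat alike:
#' `matrix.mtx` (genes x cells MatrixMarket, full double precision),
#' `features.tsv` (gene names) and `observations.tsv` (maximum id plus its
#' 1-based row/col pixel coordinates).
#'
#' @param expression maxima x genes matrix from [extract_expression()] (its
#'   `coords` attribute provides the coordinates, or pass `coords`).
#' @param outdir output directory (created if needed).
#' @param coords optional two-column coordinate matrix overriding the
#'   attribute.
#' @return Named character vector of written paths, invisibly.
#' @export
export_maxima_matrix <- function(expression, outdir, coords = NULL) {
  expression <- as.matrix(expression)
  if (nrow(expression) == 0L) stop("no maxima to export")
  if (is.null(coords)) coords <- attr(expression, "coords")
  if (is.null(coords) || nrow(coords) != nrow(expression))
    stop("need one (row, col) coordinate per maximum")
  if (is.null(colnames(expression))) stop("expression must have gene names")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(outdir, "matrix.mtx"),
             features = file.path(outdir, "features.tsv"),
             observations = file.path(outdir, "observations.tsv"))
  write_mtx(t(expression), paths[["matrix"]])
  writeLines(colnames(expression), paths[["features"]], useBytes = FALSE)
  data.table::fwrite(
    data.frame(id = sprintf("maximum_%d", seq_len(nrow(coords))),
               row = coords[, 1L], col = coords[, 2L]),
    paths[["observations"]], sep = "\t"
  )
  invisible(paths)
}

# MatrixMarket writer with full double precision (%.17g); Matrix::writeMM
# prints too few digits for a bitwise round-trip
write_mtx <- function(m, path) {
  m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  s <- Matrix::summary(m)
  con <- file(path, "w")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               sprintf("%d %d %d", nrow(m), ncol(m), nrow(s))), con)
  if (nrow(s))
    writeLines(sprintf("%d %d %.17g", s$i, s$j, s$x), con)
  close(con)
  invisible(path)
}
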