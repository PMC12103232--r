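#' Cell-type signature matrices
#'
#' A signature matrix holds the reference mean expression of each cell type
#' (genes in rows, cell types in columns, non-negative values). Signatures can
#' come from annotated single-cell RNA-seq data ([load_signatures()]) or be
#' derived de novo from the spatial data itself via local-maxima sampling and
#' external clustering ([find_local_maxima()], [extract_expression()],
#' [signatures_from_clusters()]).
#'
#' @param values non-negative numeric matrix, genes x cell types.
#' @param gene_names,celltype_names optional dimnames overrides.
#' @return A validated numeric matrix of class `signature_matrix`.
#' @export
signature_matrix <- function(values, gene_names = rownames(values),
                             celltype_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_names) || is.null(celltype_names))
    stop("signature matrix requires gene and cell-type names")
  if (anyDuplicated(gene_names)) stop("duplicated gene names in signatures")
  if (anyDuplicated(celltype_names)) stop("duplicated cell-type names in signatures")
  if (length(gene_names) != nrow(values) || length(celltype_names) != ncol(values))
    stop("dimnames do not match signature dimensions")
  if (any(!is.finite(values)) || any(values < 0))
    stop("signature values must be finite and non-negative")
  zero <- colSums(values) == 0
  if (any(zero))
    stop("all-zero signature column(s): ", paste(celltype_names[zero], collapse = ", "))
  dimnames(values) <- list(gene_names, celltype_names)
  class(values) <- c("signature_matrix", class(values))
  values
}

#' Load a signature matrix from delimited text
#'
#' Expects a header row of cell-type names and gene names in the first column;
#' the separator is sniffed from the header (tab or comma).
#'
#' @param path path to the TSV/CSV file.
#' @return A [signature_matrix].
#' @export
load_signatures <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, colClasses = list(character = 1L),
                          showProgress = FALSE)
  if (ncol(dt) < 2L) stop("signature file needs gene names plus >= 1 cell type")
  genes <- dt[[1L]]
  vals <- as.matrix(dt[, -1L])
  if (!is.numeric(vals)) stop("non-numeric signature values in ", path)
  rownames(vals) <- genes
  signature_matrix(vals)
}

#' Write a signature matrix to tab-separated text
#'
#' Values are written with full double precision so that
#' [load_signatures()] round-trips bitwise.
#'
#' @param signatures a [signature_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(signatures, path) {
  stopifnot(inherits(signatures, "signature_matrix"))
  dt <- data.table::data.table(gene = rownames(signatures))
  for (ct in colnames(signatures)) dt[[ct]] <- signatures[, ct]
  con <- file(path, "w")
  writeLines(paste(names(dt), collapse = "\t"), con)
  body <- apply(signatures, 1L, function(v) paste(sprintf("%.17g", v), collapse = "\t"))
  writeLines(paste(rownames(signatures), body, sep = "\t"), con)
  close(con)
  invisible(path)
}

#' Find local maxima of a density field
#'
#' Detects peaks of the total-mRNA KDE as candidate cell positions: a pixel is
#' returned when its value is maximal within a Chebyshev (square) neighborhood
#' of radius `min_dist`, it is nonzero, its connected (8-neighbor) above-zero
#' region has at least `min_area` pixels, and it is at least `min_dist` away
#' (Chebyshev) from every stronger retained maximum. A flat plateau of equal
#' values contributes one representative, the pixel with the lowest row then
#' column.
#'
#' @param field dense non-negative matrix (typically [total_mrna_kde()]).
#' @param min_dist minimum Chebyshev distance between maxima (default 4).
#' @param min_area minimum pixel area of the above-zero connected region
#'   containing a maximum (default 60).
#' @return Integer matrix with columns `row`, `col` (1-based pixel
#'   coordinates), ordered by decreasing field value.
#' @export
find_local_maxima <- function(field, min_dist = 4L, min_area = 60L) {
  field <- as.matrix(field)
  if (any(field < 0)) stop("'field' must be non-negative")
  min_dist <- as.integer(min_dist); min_area <- as.integer(min_area)
  if (min_dist < 1L || min_area < 1L) stop("'min_dist' and 'min_area' must be positive")
  dil <- chebyshev_max_filter(field, min_dist)
  cand <- field > 0 & field == dil
  empty <- matrix(integer(0L), 0L, 2L, dimnames = list(NULL, c("row", "col")))
  if (!any(cand)) return(empty)
  # adjacent candidates necessarily share the same value (each dominates the
  # other's window), so 8-connected components of the candidate mask are flat
  # plateaus; keep the lowest (row, col) pixel of each as representative
  plab <- label_components8(cand)
  idx <- which(cand)
  rows <- (idx - 1L) %% nrow(field) + 1L
  cols <- (idx - 1L) %/% nrow(field) + 1L
  comp <- plab[idx]
  ord <- order(comp, rows, cols)
  first <- ord[!duplicated(comp[ord])]
  rows <- rows[first]; cols <- cols[first]
  vals <- field[cbind(rows, cols)]
  # greedy separation filter, strongest first (ties by position)
  ord <- order(-vals, rows, cols)
  rows <- rows[ord]; cols <- cols[ord]
  keep <- logical(length(rows))
  for (i in seq_along(rows)) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    k <- which(keep[seq_len(i - 1L)])
    keep[i] <- all(pmax(abs(rows[k] - rows[i]), abs(cols[k] - cols[i])) >= min_dist)
  }
  rows <- rows[keep]; cols <- cols[keep]
  # area filter on the above-zero connected component of each maximum
  if (min_area > 1L) {
    comp0 <- label_components8(field > 0)
    areas <- tabulate(comp0[comp0 > 0L])
    ok <- areas[comp0[cbind(rows, cols)]] >= min_area
    rows <- rows[ok]; cols <- cols[ok]
  }
  if (length(rows) == 0L) return(empty)
  cbind(row = rows, col = cols)
}

#' Kernel-weighted expression profiles at selected pixels
#'
#' Extracts, for each coordinate, the per-gene KDE value at that pixel —
#' i.e. the kernel-weighted local expression profile, exportable as a
#' cells x genes matrix for standard single-cell clustering. Setting
#' `use_kde = FALSE` returns the raw binned counts at the pixels instead.
#'
#' @param grid a [gene_grid].
#' @param coords two-column matrix of 1-based (row, col) pixel coordinates,
#'   e.g. from [find_local_maxima()].
#' @param kernel a [kernel_mask]; ignored when `use_kde = FALSE`.
#' @param use_kde extract from the smoothed field (default) or raw counts.
#' @return Numeric matrix of shape `nrow(coords)` x n_genes with gene column
#'   names and a `coords` attribute.
#' @export
extract_expression <- function(grid, coords, kernel = NULL, use_kde = TRUE) {
  stopifnot(inherits(grid, "gene_grid"))
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L || nrow(coords) == 0L)
    stop("'coords' must be a non-empty two-column (row, col) matrix")
  if (min(coords) < 1L || max(coords[, 1L]) > grid$dim[1L] ||
      max(coords[, 2L]) > grid$dim[2L])
    stop("coordinate out of grid bounds")
  if (length(grid$genes) == 0L) stop("gene grid contains no genes")
  out <- matrix(0, nrow(coords), length(grid$genes),
                dimnames = list(NULL, grid$genes))
  for (g in grid$genes) {
    out[, g] <- if (use_kde) {
      stopifnot(inherits(kernel, "kernel_mask"))
      kde_gene(grid$counts[[g]], kernel)[coords]
    } else {
      as.matrix(grid$counts[[g]])[coords]
    }
  }
  attr(out, "coords") <- coords
  out
}

#' Average clustered pseudo-cell profiles into signatures
#'
#' Given the expression matrix of sampled local maxima and one cluster label
#' per maximum (e.g. from Leiden community detection run in an external
#' single-cell framework), returns the per-cluster arithmetic mean profile as
#' a signature matrix. Column order follows the order of first appearance for
#' character/integer labels, or the factor level order.
#'
#' @param expression maxima x genes matrix from [extract_expression()].
#' @param labels vector of cluster labels, one per row of `expression`.
#' @return A [signature_matrix] (genes x clusters).
#' @export
signatures_from_clusters <- function(expression, labels) {
  expression <- as.matrix(expression)
  if (length(labels) != nrow(expression))
    stop("need exactly one cluster label per expression row")
  if (!is.factor(labels)) labels <- factor(labels, levels = unique(labels))
  labels <- droplevels(labels)
  means <- vapply(levels(labels), function(l) {
    colMeans(expression[labels == l, , drop = FALSE])
  }, numeric(ncol(expression)))
  signature_matrix(means, gene_names = colnames(expression),
                   celltype_names = levels(labels))
}
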