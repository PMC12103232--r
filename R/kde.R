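#' Kernel density estimate of one gene's expression
#'
#' Smooths a sparse count matrix into a dense expression field by adding the
#' precomputed kernel mask, scaled by the pixel's count, around every nonzero
#' pixel. Pixels outside the grid contribute nothing (zero padding), so mass
#' is conserved for counts lying at least one kernel radius from every border.
#'
#' @param counts sparse (or dense) 2D non-negative count matrix.
#' @param kernel a [kernel_mask].
#' @return Dense numeric matrix of the same shape.
#' @export
kde_gene <- function(counts, kernel) {
  stopifnot(inherits(kernel, "kernel_mask"))
  m <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  s <- Matrix::summary(m)
  kde_accumulate(s$i - 1L, s$j - 1L, as.numeric(s$x),
                 nrow(m), ncol(m), kernel$weights)
}

#' Total-mRNA kernel density estimate
#'
#' The smoothed density of total gene expression over the tissue, used for
#' region-of-interest QC, background thresholds and local-maxima sampling.
#' By linearity it equals the KDE of the per-pixel total counts.
#'
#' @param grid a [gene_grid].
#' @param kernel a [kernel_mask].
#' @param genes optional subset of gene names to include.
#' @return Dense numeric matrix of the same shape as the grid.
#' @export
total_mrna_kde <- function(grid, kernel, genes = NULL) {
  stopifnot(inherits(grid, "gene_grid"), inherits(kernel, "kernel_mask"))
  genes <- check_genes(grid, genes)
  kde_gene(Reduce(`+`, grid$counts[genes]), kernel)
}
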