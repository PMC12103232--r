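#' Cosine similarity of two non-negative vectors
#'
#' `u . v / (||u|| ||v||)`; for non-negative expression vectors the result
#' lies in [0, 1]. The measure is scale-free, which is what makes pixel-level
#' classification robust to local differences in capture efficiency.
#'
#' @param u,v numeric vectors of equal length with positive norm.
#' @return Cosine similarity in [0, 1].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("'u' and 'v' must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-norm vector; treat such pixels as background")
  sum(u * v) / (nu * nv)
}

#' Upper bound of the cosine-similarity gap between two signatures
#'
#' For unit-norm non-negative signatures a and b, the difference
#' `Sc(x, a) - Sc(x, b)` over non-negative x equals `x/||x|| . (a - b)` and is
#' maximised by the colinear direction with negative coordinates clipped to
#' zero (the expression vector cannot be negative). The maximum is therefore
#' `||max(a - b, 0)||`. This bound is the denominator that turns the raw
#' cosine gap into the assignment score: it rescales the gap by how
#' distinguishable the two best signatures are at all.
#'
#' @param a,b non-negative unit-norm signature vectors, `a != b`.
#' @return The maximal cosine gap, a positive real.
#' @export
assignment_upper_bound <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  if (any(a < 0) || any(b < 0)) stop("signatures must be non-negative")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-norm signature")
  bound <- sqrt(sum(pmax(a / na - b / nb, 0)^2))
  if (bound == 0) stop("identical signatures: the bound is 0 and the score undefined")
  bound
}

# L2-normalize signature columns over a gene subset; errors on all-zero columns
normalize_signatures <- function(signatures, genes = rownames(signatures)) {
  s <- unclass(signatures)[genes, , drop = FALSE]
  norms <- sqrt(colSums(s^2))
  if (any(norms == 0))
    stop("signature(s) with zero norm on the shared gene set: ",
         paste(colnames(s)[norms == 0], collapse = ", "))
  sweep(s, 2L, norms, "/")
}

# pairwise bound matrix D[a, b] = ||(a_hat - b_hat)+||, ordered pairs
pairwise_bounds <- function(snorm) {
  k <- ncol(snorm)
  D <- matrix(0, k, k)
  for (a in seq_len(k)) {
    d <- pmax(snorm[, a] - snorm, 0)
    D[a, ] <- sqrt(colSums(d^2))
  }
  D
}

#' Classify one expression vector against a signature matrix
#'
#' Computes the cosine similarity of `p` to every signature, assigns the most
#' similar cell type, and normalises the gap to the runner-up by its analytic
#' maximum ([assignment_upper_bound()]) to give the assignment score, a
#' per-pixel confidence in [0, 1]. A score of 0 means the two best signatures
#' explain the pixel equally well; 1 means the pixel is as far from the
#' runner-up as any non-negative expression vector could be. Ties in the
#' argmax are broken toward the earlier signature column.
#'
#' @param p non-negative expression vector, named by gene or aligned to
#'   `rownames(signatures)`, with positive norm.
#' @param signatures a [signature_matrix] with at least two cell types.
#' @return List with `label` (cell-type name), `cosine` (similarity to the
#'   assigned type) and `score` (assignment score in [0, 1]).
#' @export
assignment_score <- function(p, signatures) {
  stopifnot(inherits(signatures, "signature_matrix"))
  if (ncol(signatures) < 2L) stop("need at least two signatures")
  if (length(p) != nrow(signatures)) stop("'p' must have one value per signature gene")
  if (any(p < 0)) stop("'p' must be non-negative")
  np <- sqrt(sum(p^2))
  if (np == 0) stop("zero expression vector; treat as background")
  snorm <- normalize_signatures(signatures)
  cos <- as.vector(p %*% snorm) / np
  best <- which.max(cos)
  second <- which.max(replace(cos, best, -Inf))
  gap <- cos[best] - cos[second]
  score <- if (gap == 0) 0 else {
    gap / assignment_upper_bound(snorm[, best], snorm[, second])
  }
  list(label = colnames(signatures)[best],
       cosine = min(max(cos[best], 0), 1),
       score = min(max(score, 0), 1))
}

#' Pixel-wise cell-type assignment over the whole grid
#'
#' The central operation of the package: for every pixel, the per-gene KDE
#' vector over the genes shared between data and signatures is classified by
#' cosine similarity, producing a cell-type label map with companion cosine,
#' assignment-score and total-KDE grids. The grid is processed in square
#' windows (default 500 x 500) padded by the kernel radius, so every window
#' pixel sees its full kernel support and the result is independent of
#' `chunk_size`.
#'
#' Pixels with no expression within the kernel radius cannot be classified:
#' they receive the background sentinel -1 and `NA` cosine/score.
#'
#' @param grid a [gene_grid].
#' @param signatures a [signature_matrix]; genes absent from the data are
#'   dropped with a warning.
#' @param kernel a [kernel_mask].
#' @param chunk_size side length of the processing windows (default 500).
#' @return An object of class `celltype_map`: list with `labels` (integer
#'   matrix, codes `0 .. k-1` in `celltype_names` order, -1 for background),
#'   `cosine`, `score` (numeric matrices, `NA` on background), `total_kde`,
#'   and `celltype_names` (code i maps to `celltype_names[i + 1]`).
#' @export
assign_celltypes <- function(grid, signatures, kernel, chunk_size = 500L) {
  stopifnot(inherits(grid, "gene_grid"), inherits(signatures, "signature_matrix"),
            inherits(kernel, "kernel_mask"))
  chunk_size <- as.integer(chunk_size)
  if (chunk_size < 1L) stop("'chunk_size' must be positive")
  if (ncol(signatures) < 2L) stop("need at least two signatures")
  shared <- intersect(grid$genes, rownames(signatures))
  if (length(shared) == 0L)
    stop("no genes shared between the data and the signature matrix")
  missing <- setdiff(rownames(signatures), grid$genes)
  if (length(missing))
    warning(length(missing), " signature gene(s) absent from the data dropped: ",
            paste(head(missing, 10L), collapse = ", "),
            if (length(missing) > 10L) ", ...")
  snorm <- normalize_signatures(signatures, shared)
  bounds <- pairwise_bounds(snorm)
  nr <- grid$dim[1L]; nc <- grid$dim[2L]
  R <- kernel$radius_px
  labels <- matrix(-1L, nr, nc)
  cosg <- matrix(NA_real_, nr, nc)
  scoreg <- matrix(NA_real_, nr, nc)
  totalg <- matrix(0, nr, nc)
  # per-gene triplets once (0-based), in dgCMatrix column-major order so the
  # accumulation order inside every window matches the whole-grid order
  trip <- lapply(grid$counts[shared], function(m) {
    s <- Matrix::summary(m)
    list(i = s$i - 1L, j = s$j - 1L, x = as.numeric(s$x))
  })
  row_starts <- seq(1L, nr, by = chunk_size)
  col_starts <- seq(1L, nc, by = chunk_size)
  for (r0 in row_starts) {
    r1 <- min(r0 + chunk_size - 1L, nr)
    pr0 <- max(1L, r0 - R); pr1 <- min(nr, r1 + R)
    for (c0 in col_starts) {
      c1 <- min(c0 + chunk_size - 1L, nc)
      pc0 <- max(1L, c0 - R); pc1 <- min(nc, c1 + R)
      core_r <- (r0 - pr0 + 1L):(r1 - pr0 + 1L)
      core_c <- (c0 - pc0 + 1L):(c1 - pc0 + 1L)
      npix <- length(core_r) * length(core_c)
      P <- matrix(0, npix, length(shared))
      total <- matrix(0, length(core_r), length(core_c))
      for (gi in seq_along(shared)) {
        tr <- trip[[gi]]
        sel <- tr$i >= (pr0 - 1L) & tr$i <= (pr1 - 1L) &
               tr$j >= (pc0 - 1L) & tr$j <= (pc1 - 1L)
        dk <- kde_accumulate(tr$i[sel] - (pr0 - 1L), tr$j[sel] - (pc0 - 1L),
                             tr$x[sel], pr1 - pr0 + 1L, pc1 - pc0 + 1L,
                             kernel$weights)[core_r, core_c, drop = FALSE]
        P[, gi] <- dk
        total <- total + dk
      }
      norms <- sqrt(rowSums(P^2))
      assigned <- norms > 0
      lab <- rep(-1L, npix)
      cosv <- rep(NA_real_, npix)
      scv <- rep(NA_real_, npix)
      if (any(assigned)) {
        C <- (P[assigned, , drop = FALSE] / norms[assigned]) %*% snorm
        best <- max.col(C, ties.method = "first")
        c1v <- C[cbind(seq_len(nrow(C)), best)]
        C[cbind(seq_len(nrow(C)), best)] <- -Inf
        second <- max.col(C, ties.method = "first")
        c2v <- C[cbind(seq_len(nrow(C)), second)]
        gap <- c1v - c2v
        sc <- ifelse(gap == 0, 0, gap / bounds[cbind(best, second)])
        lab[assigned] <- best - 1L
        cosv[assigned] <- pmin(pmax(c1v, 0), 1)
        scv[assigned] <- pmin(pmax(sc, 0), 1)
      }
      labels[r0:r1, c0:c1] <- matrix(lab, length(core_r), length(core_c))
      cosg[r0:r1, c0:c1] <- matrix(cosv, length(core_r), length(core_c))
      scoreg[r0:r1, c0:c1] <- matrix(scv, length(core_r), length(core_c))
      totalg[r0:r1, c0:c1] <- total
    }
  }
  structure(
    list(labels = labels, cosine = cosg, score = scoreg, total_kde = totalg,
         celltype_names = colnames(signatures)),
    class = "celltype_map"
  )
}

#' @export
print.celltype_map <- function(x, ...) {
  assigned <- sum(x$labels >= 0L)
  cat(sprintf(
    "celltype_map: %d x %d pixels, %d cell types, %.1f%% assigned\n",
    nrow(x$labels), ncol(x$labels), length(x$celltype_names),
    100 * assigned / length(x$labels)
  ))
  if (assigned > 0L)
    cat(sprintf("  median assignment score %.3f, median cosine %.3f\n",
                stats::median(x$score[x$labels >= 0L]),
                stats::median(x$cosine[x$labels >= 0L])))
  invisible(x)
}

#' Background filtering by total-mRNA density
#'
#' Relabels as background (-1) every pixel whose total-mRNA KDE falls below
#' the global threshold, or below its assigned cell type's threshold where
#' one is given. Cosine and score become `NA` on newly masked pixels; all
#' other pixels are unchanged.
#'
#' @param map a `celltype_map` from [assign_celltypes()].
#' @param global_threshold non-negative total-KDE threshold applied everywhere.
#' @param celltype_thresholds optional named numeric vector of per-type
#'   thresholds (names must be cell types of the map).
#' @return The filtered `celltype_map`.
#' @export
filter_background <- function(map, global_threshold = 0,
                              celltype_thresholds = NULL) {
  stopifnot(inherits(map, "celltype_map"))
  if (!is.numeric(global_threshold) || global_threshold < 0)
    stop("'global_threshold' must be non-negative")
  mask <- map$total_kde < global_threshold
  if (!is.null(celltype_thresholds)) {
    unknown <- setdiff(names(celltype_thresholds), map$celltype_names)
    if (length(unknown))
      stop("unknown cell type(s) in thresholds: ", paste(unknown, collapse = ", "))
    if (any(celltype_thresholds < 0)) stop("thresholds must be non-negative")
    for (ct in names(celltype_thresholds)) {
      code <- match(ct, map$celltype_names) - 1L
      mask <- mask | (map$labels == code &
                        map$total_kde < celltype_thresholds[[ct]])
    }
  }
  map$labels[mask] <- -1L
  map$cosine[mask] <- NA_real_
  map$score[mask] <- NA_real_
  map
}

#' Connected regions of one cell type
#'
#' Labels the 8-connected components of the binary mask `labels == celltype`
#' and returns those with at least `min_area` pixels, e.g. to detect
#' individual cells of a sparse population from the pixel map.
#'
#' @param map a `celltype_map`.
#' @param celltype cell-type name present in the map.
#' @param min_area minimum component area in pixels.
#' @return Data frame with `centroid_row`, `centroid_col` (1-based, possibly
#'   fractional) and `area`, one row per retained region.
#' @export
labeled_regions <- function(map, celltype, min_area = 60L) {
  stopifnot(inherits(map, "celltype_map"))
  code <- match(celltype, map$celltype_names) - 1L
  if (is.na(code)) stop("unknown cell type: ", celltype)
  comp <- label_components8(map$labels == code)
  if (max(comp) == 0L)
    return(data.frame(centroid_row = numeric(0L), centroid_col = numeric(0L),
                      area = integer(0L)))
  idx <- which(comp > 0L)
  rows <- (idx - 1L) %% nrow(comp) + 1L
  cols <- (idx - 1L) %/% nrow(comp) + 1L
  lab <- comp[idx]
  areas <- tabulate(lab)
  out <- data.frame(
    centroid_row = tapply(rows, lab, mean),
    centroid_col = tapply(cols, lab, mean),
    area = areas
  )
  out <- out[out$area >= min_area, , drop = FALSE]
  rownames(out) <- NULL
  out
}
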