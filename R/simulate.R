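#' Synthetic mean expression profiles with controlled separation
#'
#' Default profile maker for the tissue simulator: each gene is a marker of
#' one cell type with a log-normal mean, all other types express it at a
#' small `leak` fraction, and each column is rescaled so that every type has
#' the same expected total expression per spot. With the default leak the
#' pairwise cosine similarity between types is well below 0.2, matching the
#' near-orthogonal reference profiles used in validation.
#'
#' @param n_genes number of genes (default 100).
#' @param n_types number of cell types (default 9).
#' @param leak cross-type expression as a fraction of the marker mean
#'   (default 0.02); larger values make types harder to distinguish.
#' @param mean_total expected total transcripts per spot for every type
#'   (default 1.0, typical of sub-micron in situ capture pixels).
#' @param meanlog,sdlog log-normal parameters of the marker means.
#' @param seed optional integer seed (RNG state is restored on exit).
#' @return A [signature_matrix] of per-spot mean expression, genes x types.
#' @export
make_type_profiles <- function(n_genes = 100L, n_types = 9L, leak = 0.02,
                               mean_total = 1.0, meanlog = 0, sdlog = 1,
                               seed = NULL) {
  if (n_genes < n_types) stop("need at least one gene per type")
  if (leak < 0 || leak >= 1) stop("'leak' must be in [0, 1)")
  build <- function() {
    marker_of <- rep_len(seq_len(n_types), n_genes)
    m <- rlnorm(n_genes, meanlog, sdlog)
    prof <- matrix(leak, n_genes, n_types) * m
    prof[cbind(seq_len(n_genes), marker_of)] <- m
    prof <- sweep(prof, 2L, colSums(prof), "/") * mean_total
    dimnames(prof) <- list(sprintf("gene%03d", seq_len(n_genes)),
                           sprintf("type%02d", seq_len(n_types)))
    signature_matrix(prof)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

# evaluate code under a fixed seed, restoring the global RNG state afterwards
with_seed <- function(seed, code) {
  genv <- globalenv()
  has <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

#' Simulate a synthetic tissue with known per-pixel cell identity
#'
#' Emulates the validation design used for segmentation-free classifiers:
#' `n_cells` cell centers are placed uniformly at random on a square pixel
#' grid and cell outlines are their Voronoi diagram (every pixel belongs to
#' its nearest center); each cell draws a type from `type_abundances`; each
#' spot's count for gene g is Poisson with the cell type's mean profile; and
#' a uniformly random fraction `zero_inflation` of spots (exactly
#' `round(zero_inflation * n_spots)` of them) has all counts set to zero to
#' model capture dropout.
#'
#' @param grid_size side length of the square grid in pixels (default 500).
#' @param n_cells number of cell centers (default 625).
#' @param mean_profiles per-spot mean expression per type, a
#'   [signature_matrix] (default [make_type_profiles()] drawn from the
#'   simulation's RNG stream).
#' @param type_abundances probability vector over types (default uniform).
#' @param zero_inflation fraction of spots zeroed out, in [0, 1)
#'   (default 0.2).
#' @param seed integer seed; the whole tissue is reproducible from it.
#' @return An object of class `simulated_tissue`: list with `truth` (integer
#'   matrix of type indices 1..k per pixel), `cell_centers` (n_cells x 2),
#'   `cell_types` (type index per cell), `zeroed` (logical matrix of dropout
#'   spots), `grid` (a [gene_grid] of the generated counts), `profiles` and
#'   `params`.
#' @export
simulate_tissue <- function(grid_size = 500L, n_cells = 625L,
                            mean_profiles = NULL, type_abundances = NULL,
                            zero_inflation = 0.2, seed = 1L) {
  grid_size <- as.integer(grid_size); n_cells <- as.integer(n_cells)
  if (grid_size < 2L || n_cells < 1L) stop("grid_size and n_cells must be positive")
  if (zero_inflation < 0 || zero_inflation >= 1)
    stop("'zero_inflation' must be in [0, 1)")
  with_seed(seed, {
  if (is.null(mean_profiles)) mean_profiles <- make_type_profiles()
  stopifnot(inherits(mean_profiles, "signature_matrix"))
  k <- ncol(mean_profiles)
  if (is.null(type_abundances)) type_abundances <- rep(1 / k, k)
  if (length(type_abundances) != k || any(type_abundances < 0) ||
      abs(sum(type_abundances) - 1) > 1e-8)
    stop("'type_abundances' must be a probability vector over the types")
  # uniform continuous centers in pixel coordinate space [0, grid_size)
  centers <- cbind(row = runif(n_cells) * grid_size,
                   col = runif(n_cells) * grid_size)
  cell_types <- sample.int(k, n_cells, replace = TRUE, prob = type_abundances)
  # Voronoi partition: nearest center per pixel (pixel i at coordinate i - 0.5)
  cell_of <- nearest_center(grid_size, grid_size,
                            centers[, "row"] - 0.5, centers[, "col"] - 0.5)
  truth <- matrix(cell_types[cell_of], grid_size, grid_size)
  n_spots <- grid_size^2
  n_zero <- round(zero_inflation * n_spots)
  zero_idx <- sample.int(n_spots, n_zero)
  zeroed <- matrix(FALSE, grid_size, grid_size)
  zeroed[zero_idx] <- TRUE
  type_vec <- as.vector(truth)
  keep <- !as.vector(zeroed)
  counts <- vector("list", nrow(mean_profiles))
  names(counts) <- rownames(mean_profiles)
  for (g in seq_len(nrow(mean_profiles))) {
    lambda <- unclass(mean_profiles)[g, type_vec]
    cnt <- rpois(n_spots, lambda)
    nz <- which(cnt > 0L & keep)
    counts[[g]] <- Matrix::sparseMatrix(
      i = (nz - 1L) %% grid_size + 1L, j = (nz - 1L) %/% grid_size + 1L,
      x = cnt[nz], dims = c(grid_size, grid_size)
    )
  }
  structure(
    list(truth = truth, cell_centers = centers, cell_types = cell_types,
         zeroed = zeroed, grid = gene_grid(counts),
         profiles = mean_profiles,
         params = list(grid_size = grid_size, n_cells = n_cells,
                       zero_inflation = zero_inflation, seed = seed,
                       type_abundances = type_abundances)),
    class = "simulated_tissue"
  )
  })
}

#' @export
print.simulated_tissue <- function(x, ...) {
  cat(sprintf(
    "simulated_tissue: %d x %d px, %d cells of %d types, %.0f%% zero inflation, seed %d\n",
    x$params$grid_size, x$params$grid_size, x$params$n_cells,
    ncol(x$profiles), 100 * x$params$zero_inflation, x$params$seed
  ))
  invisible(x)
}

#' Classification accuracy stratified by assignment score
#'
#' Compares a cell-type map against simulated ground truth on the assigned
#' pixels whose assignment score is at or above the given quantile of
#' assigned-pixel scores (`score_quantile = 0` keeps all assigned pixels).
#' Map labels are matched to truth types by name through the map's
#' `celltype_names`.
#'
#' @param map a `celltype_map` from [assign_celltypes()].
#' @param truth a `simulated_tissue` (or an integer truth matrix plus
#'   `truth_names`).
#' @param score_quantile quantile of assigned-pixel scores used as the
#'   inclusion threshold, in [0, 1].
#' @param truth_names cell-type names for integer truth codes; defaults to
#'   the simulation's profile column names.
#' @return Data frame with one row per true cell type (`celltype`, `n`,
#'   `correct`, `accuracy`) and attributes `overall` (overall accuracy on the
#'   selected pixels) and `n_selected`.
#' @export
evaluate_accuracy <- function(map, truth, score_quantile = 0,
                              truth_names = NULL) {
  stopifnot(inherits(map, "celltype_map"))
  if (inherits(truth, "simulated_tissue")) {
    truth_names <- colnames(truth$profiles)
    truth <- truth$truth
  }
  if (is.null(truth_names)) stop("'truth_names' required for a bare truth matrix")
  if (!all(dim(truth) == dim(map$labels))) stop("shape mismatch between map and truth")
  if (score_quantile < 0 || score_quantile > 1)
    stop("'score_quantile' must be in [0, 1]")
  assigned <- map$labels >= 0L
  if (!any(assigned)) stop("no assigned pixels to evaluate")
  thr <- quantile(map$score[assigned], score_quantile, names = FALSE)
  sel <- assigned & !is.na(map$score) & map$score >= thr
  pred <- map$celltype_names[map$labels[sel] + 1L]
  true <- truth_names[truth[sel]]
  per_type <- lapply(sort(unique(true)), function(ct) {
    m <- true == ct
    data.frame(celltype = ct, n = sum(m), correct = sum(pred[m] == ct))
  })
  out <- do.call(rbind, per_type)
  out$accuracy <- out$correct / out$n
  attr(out, "overall") <- mean(pred == true)
  attr(out, "n_selected") <- length(true)
  out
}
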