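# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package: plain loops, direct
# evaluation of the kernel formulas and of the cosine/score definitions.

# kernel weights evaluated directly from the analytic form
naive_kernel_weights <- function(family, h, truncation = 2) {
  r <- if (family == "gaussian") floor(truncation * h) else floor(h)
  side <- 2 * r + 1
  w <- matrix(0, side, side)
  for (dr in -r:r) {
    for (dc in -r:r) {
      d2 <- dr^2 + dc^2
      w[dr + r + 1, dc + r + 1] <- if (family == "gaussian") {
        exp(-d2 / (2 * h^2))
      } else {
        max(0, 1 - d2 / h^2)
      }
    }
  }
  w / sum(w)
}

# dense convolution by direct summation over all molecule pixels
naive_kde_field <- function(dense, weights) {
  r <- (nrow(weights) - 1) / 2
  nr <- nrow(dense); nc <- ncol(dense)
  out <- matrix(0, nr, nc)
  nz <- which(dense != 0, arr.ind = TRUE)
  for (p in seq_len(nrow(nz))) {
    i <- nz[p, 1]; j <- nz[p, 2]; v <- dense[i, j]
    for (rr in seq_len(nr)) {
      for (cc in seq_len(nc)) {
        dr <- rr - i; dc <- cc - j
        if (abs(dr) <= r && abs(dc) <= r)
          out[rr, cc] <- out[rr, cc] + v * weights[dr + r + 1, dc + r + 1]
      }
    }
  }
  out
}

naive_cosine <- function(u, v) {
  s <- 0; nu <- 0; nv <- 0
  for (i in seq_along(u)) {
    s <- s + u[i] * v[i]; nu <- nu + u[i]^2; nv <- nv + v[i]^2
  }
  s / sqrt(nu) / sqrt(nv)
}

# full pixel-classification reference: dense KDE per gene, then per-pixel
# cosine to every signature, argmax with first-tie, score via the clipped
# difference-vector norm of the two best (unit-normalized) signatures
naive_assign <- function(dense_list, signatures, family, h, truncation = 2) {
  w <- naive_kernel_weights(family, h, truncation)
  fields <- lapply(dense_list, naive_kde_field, weights = w)
  nr <- nrow(dense_list[[1]]); nc <- ncol(dense_list[[1]])
  k <- ncol(signatures)
  snorm <- apply(signatures, 2, function(s) s / sqrt(sum(s^2)))
  labels <- matrix(-1L, nr, nc)
  cosine <- matrix(NA_real_, nr, nc)
  score <- matrix(NA_real_, nr, nc)
  for (rr in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      p <- vapply(fields, function(f) f[rr, cc], numeric(1))
      if (sum(p^2) == 0) next
      cs <- vapply(seq_len(k), function(t) naive_cosine(p, signatures[, t]),
                   numeric(1))
      best <- which(cs == max(cs))[1]
      rest <- cs; rest[best] <- -Inf
      second <- which(rest == max(rest))[1]
      bound <- sqrt(sum(pmax(snorm[, best] - snorm[, second], 0)^2))
      gap <- cs[best] - cs[second]
      labels[rr, cc] <- best - 1L
      cosine[rr, cc] <- cs[best]
      score[rr, cc] <- if (gap == 0) 0 else min(max(gap / bound, 0), 1)
    }
  }
  list(labels = labels, cosine = cosine, score = score)
}

# random sparse gene_grid for property tests
random_grid <- function(nr, nc, n_genes, density = 0.1, max_count = 5) {
  counts <- lapply(seq_len(n_genes), function(g) {
    m <- matrix(0, nr, nc)
    nnz <- max(1, round(density * nr * nc))
    idx <- sample.int(nr * nc, nnz)
    m[idx] <- sample.int(max_count, nnz, replace = TRUE)
    Matrix::Matrix(m, sparse = TRUE)
  })
  names(counts) <- paste0("g", seq_len(n_genes))
  gene_grid(counts)
}

random_signatures <- function(n_genes, k) {
  m <- matrix(runif(n_genes * k), n_genes, k)
  dimnames(m) <- list(paste0("g", seq_len(n_genes)), paste0("ct", seq_len(k)))
  signature_matrix(m)
}

dense_list <- function(grid) lapply(grid$counts, as.matrix)

# independent 8-connected flood fill; returns a list of (row, col) matrices
flood_fill_regions <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  out <- list()
  for (j in seq_len(ncol(mask))) {
    for (i in seq_len(nrow(mask))) {
      if (!mask[i, j] || seen[i, j]) next
      stack <- list(c(i, j))
      seen[i, j] <- TRUE
      px <- NULL
      while (length(stack)) {
        cur <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        px <- rbind(px, cur)
        for (dr in -1:1) for (dc in -1:1) {
          r <- cur[1] + dr; c <- cur[2] + dc
          if (r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) &&
              mask[r, c] && !seen[r, c]) {
            seen[r, c] <- TRUE
            stack[[length(stack) + 1]] <- c(r, c)
          }
        }
      }
      out[[length(out) + 1]] <- px
    }
  }
  out
}
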