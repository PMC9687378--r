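# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Adjusted Rand index between two label vectors (Hubert & Arabie).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Brute-force ABC boundary placement: sort by descending value, evaluate the
# distance-to-(0,1) objective at every candidate A|B cut and the slope rule
# at every candidate B|C cut, by explicit loops.
abc_oracle <- function(values) {
  ord <- order(-values, seq_along(values))
  v <- values[ord]
  n <- length(v)
  total <- sum(v)
  best_ab <- NA_integer_
  best_d <- Inf
  y_prev <- 0
  y <- numeric(n)
  for (i in seq_len(n)) {
    y[i] <- y_prev + v[i] / total
    y_prev <- y[i]
  }
  for (i in seq_len(n)) {
    d <- (i / n)^2 + (1 - y[i])^2
    if (d < best_d - 1e-12) {   # ties (within rounding) keep the earlier index
      best_d <- d
      best_ab <- i
    }
  }
  best_bc <- 0L
  for (i in seq_len(n)) {
    # slope of segment i equals v[i] / (total / n); compare via products
    if (v[i] * n > total) best_bc <- i
  }
  best_bc <- max(best_bc, best_ab)
  list(ab = best_ab, bc = best_bc,
       A = sort(ord[seq_len(best_ab)]),
       B = if (best_bc > best_ab) sort(ord[(best_ab + 1L):best_bc]) else integer(0))
}

# All multisets of length 1..max_len drawn from a value grid (order is
# irrelevant to the ABC curve up to its deterministic tie-breaking).
value_grid_vectors <- function(grid, max_len) {
  out <- list()
  for (len in seq_len(max_len)) {
    combos <- utils::combn(length(grid) + len - 1L, len)
    for (j in seq_len(ncol(combos))) {
      idx <- combos[, j] - seq_len(len) + 1L
      out[[length(out) + 1L]] <- grid[idx]
    }
  }
  out
}

# Tiny deterministic expression fixture written to a temp file.
write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Map discovered clusters onto the majority annotation label of their members.
majority_map <- function(cluster_labels, annotations) {
  ann <- annotations$label[match(names(cluster_labels), annotations$sample_id)]
  tab <- table(cluster_labels, ann)
  vapply(rownames(tab), function(r) colnames(tab)[which.max(tab[r, ])],
         character(1L))
}
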