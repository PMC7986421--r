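# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with R/.

# Exhaustive grid search for the M1 least-squares fit: evaluates the exact
# SSE at every (a, b) grid point (the quadratic-in-a expansion is algebra,
# not optimisation) and returns the minimum.
grid_sse_oracle_m1 <- function(day, tpm, a_range, b_range, step = 1e-3) {
  b_grid <- seq(b_range[1], b_range[2], by = step)
  a_grid <- seq(a_range[1], a_range[2], by = step)
  syy <- sum(tpm^2)
  best <- Inf
  for (b in b_grid) {
    e <- exp(b * day)
    sxy <- sum(tpm * e)
    sxx <- sum(e * e)
    sse <- syy - 2 * a_grid * sxy + a_grid^2 * sxx
    m <- min(sse)
    if (m < best) best <- m
  }
  best
}

# Naive agglomerative clustering (single / complete / average linkage) by
# repeated scan of the full distance matrix; lowest-index pair on ties.
hclust_oracle <- function(d, linkage = "average") {
  D <- as.matrix(d)
  n <- nrow(D)
  active <- seq_len(n)
  sizes <- rep(1, n)
  members <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        dij <- D[active[ii], active[jj]]
        if (dij < best_d) { best_d <- dij; best <- c(ii, jj) }
      }
    }
    i <- active[best[1]]; j <- active[best[2]]
    heights <- c(heights, best_d)
    # update distances from the merged cluster to the rest
    for (k in setdiff(active, c(i, j))) {
      dik <- D[i, k]; djk <- D[j, k]
      D[i, k] <- D[k, i] <- switch(linkage,
        single = min(dik, djk),
        complete = max(dik, djk),
        average = (sizes[i] * dik + sizes[j] * djk) / (sizes[i] + sizes[j]))
    }
    sizes[i] <- sizes[i] + sizes[j]
    members[[i]] <- c(members[[i]], members[[j]])
    active <- setdiff(active, j)
  }
  sort(heights)
}

# Full-matrix Smith-Waterman with linear gap penalty (gap per gapped base).
sw_oracle_linear <- function(read, ref, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(read, "")[[1]]; b <- strsplit(ref, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j] && a[i] != "N") match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + s, H[i, j + 1] + gap,
                             H[i + 1, j] + gap)
    }
  }
  max(H)
}

# Full-matrix global Needleman-Wunsch with affine gaps in the
# opening + L * extension convention (score only).
nw_oracle_affine <- function(a, b, submat, open, ext) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # match/mismatch state
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (vertical)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (horizontal)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -open - ext * i
  for (j in seq_len(m)) Y[1, j + 1] <- -open - ext * j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[a[i], b[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Adjusted Rand index from the contingency table.
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Are the clusters of `fine` nested within the clusters of `coarse`?
is_nested_partition <- function(fine, coarse) {
  all(apply(table(fine, coarse) > 0, 1, sum) == 1)
}

# Count of mismatching characters between two equal-length strings.
str_mismatches <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Small deterministic day grid used across decay tests.
default_days <- function(reps = 3) rep(c(0, 7, 14, 21, 28, 42, 56, 84), each = reps)

# Lognormal-noise series from the generative decay model.
sim_decay_series <- function(day, a = 300, b = -0.05, c = 0, sigma = 0.2) {
  (a * exp(b * day) + c) * exp(rnorm(length(day), 0, sigma))
}

# Tiny two-paralogue panel built by hand for I/O tests.
toy_panel <- function() {
  records <- expand.grid(accession = c("acc1", "acc2"),
                         paralogue = c("p1", "p2"),
                         day = c(0, 7, 14),
                         replicate = c("r1", "r2"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  records$tpm <- seq_len(nrow(records))
  meta <- data.frame(accession = c("acc1", "acc2"),
                     crop_type = c("spring", "winter"))
  expression_panel(records, meta, roster = c("p1", "p2"))
}
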