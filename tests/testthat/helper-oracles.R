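# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Naive Ward agglomeration: at each step merge the two clusters whose union
# minimizes the increase in total within-cluster sum of squared Euclidean
# distances to the centroid. Returns the partition at every k.
oracle_ward_partitions <- function(m) {
  sse <- function(idx) {
    if (length(idx) == 1L) return(0)
    ctr <- colMeans(m[idx, , drop = FALSE])
    sum(sweep(m[idx, , drop = FALSE], 2, ctr)^2)
  }
  clusters <- as.list(seq_len(nrow(m)))
  partitions <- list()
  partitions[[length(clusters)]] <- lapply(clusters, function(i) rownames(m)[i])
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      d <- sse(c(clusters[[i]], clusters[[j]])) -
        sse(clusters[[i]]) - sse(clusters[[j]])
      if (d < best[1]) best <- c(d, i, j)
    }
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1L]] <- merged
    partitions[[length(clusters)]] <-
      lapply(clusters, function(idx) sort(rownames(m)[idx]))
  }
  partitions
}

# canonical form of a partition (list of member vectors) for set comparison
canon_partition <- function(p) {
  p <- lapply(p, function(x) sort(as.character(x)))
  p[order(vapply(p, `[`, "", 1L))]
}

# Shoelace area of a convex point set, ordered by angle around the centroid
# (valid for convex hull vertices; independent of grDevices::chull).
oracle_convex_area <- function(pts) {
  ctr <- colMeans(pts)
  ord <- order(atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1]))
  p <- pts[ord, , drop = FALSE]
  n <- nrow(p)
  i2 <- c(2:n, 1L)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

# Brute-force zone frequencies from raw axial fractions.
oracle_zone_freq <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  c(b = mean(t < 1 / 3), m = mean(t >= 1 / 3 & t < 2 / 3), a = mean(t >= 2 / 3))
}

# Small synthetic scene shortcut for imaging tests.
tiny_scene <- function(cells_per_case = 6, seed = 42, noise = TRUE,
                       n_cases = 1) {
  cfg <- preset_from_tables(n_cases = n_cases, cells_per_case = cells_per_case,
                            seed = seed)
  cfg$fractions <- "raw"
  pop <- generate_population(cfg, seed = seed)
  render_images(pop, seed = seed + 1, noise = noise)
}
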