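# Independent oracles used across tests. These deliberately re-derive results
# by brute force and stay independent of the package implementation paths.

# O(n^2) DBSCAN from the textbook definition: full distance matrix, core =
# >= min_pts neighbours within eps (self included), clusters = BFS over core
# points, border points take the lowest reachable cluster id.
dbscan_brute <- function(x, y, eps, min_pts) {
  n <- length(x)
  if (n == 0) return(integer(0))
  d <- as.matrix(stats::dist(cbind(x, y))) <= eps
  diag(d) <- TRUE
  core <- rowSums(d) >= min_pts
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      nb <- which(d[j, ] & core & labels == -1L)
      labels[nb] <- cl
      queue <- c(queue, nb)
    }
  }
  for (i in which(!core)) {
    cls <- labels[d[i, ] & core]
    cls <- cls[cls > 0]
    if (length(cls)) labels[i] <- min(cls)
  }
  labels
}

# partition equality up to cluster-id permutation (noise must coincide)
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == -1L, b == -1L)) return(FALSE)
  m <- a != -1L
  if (!any(m)) return(TRUE)
  tab <- table(a[m], b[m])
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# minimal distance from each true centre to a detected structure centroid
centroid_match_dist <- function(mask, centers) {
  s <- mask$structures
  vapply(seq_len(nrow(centers)), function(i) {
    if (nrow(s) == 0) return(Inf)
    min(sqrt((s$centroid_row - centers$row[i])^2 +
               (s$centroid_col - centers$col[i])^2))
  }, numeric(1))
}

# detection matching with a time tolerance; returns sensitivity and the
# number of detections not matching any truth
match_spikes <- function(detected, truth, tol_s) {
  hit <- vapply(truth, function(t) any(abs(detected - t) <= tol_s), logical(1))
  fp <- vapply(detected, function(t) !any(abs(truth - t) <= tol_s), logical(1))
  list(sensitivity = if (length(truth)) mean(hit) else NA_real_,
       n_false_positive = sum(fp))
}

# structure mask built directly from a logical matrix, bypassing detection
mask_from_logical <- function(mask, image = NULL, pixel_size_nm = 100) {
  as_structure_mask(mask, image, pixel_size_nm)
}
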