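# Independent ray/triangle oracle: solves the 3x3 linear system
# o + t d = a + u (b - a) + v (c - a) directly, rather than the
# cross-product formulation used by the package kernel.
oracle_ray_triangle <- function(orig, dir, a, b, c) {
  M <- cbind(-dir, b - a, c - a)
  if (abs(det(M)) < 1e-12) return(NULL)
  s <- solve(M, orig - a)
  t <- s[1]; u <- s[2]; v <- s[3]
  if (u < 0 || u > 1 || v < 0 || u + v > 1 || t <= 1e-9) return(NULL)
  list(t = t, point = orig + t * dir)
}

# Exhaustive all-triangle cast with the oracle intersector.
oracle_cast_ray <- function(mesh, orig, dir) {
  v <- mesh$vertices
  f <- mesh$triangles
  best <- NULL
  for (i in seq_len(nrow(f))) {
    h <- oracle_ray_triangle(orig, dir, v[f[i, 1], ], v[f[i, 2], ],
                             v[f[i, 3], ])
    if (!is.null(h) && (is.null(best) || h$t < best$t)) {
      best <- h
      best$triangle <- i
    }
  }
  best
}

# Independent GPA loop whose pairwise rigid alignments go through
# vegan::procrustes (no scaling, mean re-estimated each sweep).
oracle_gpa_distances <- function(samples, n_sweeps = 50, tol = 1e-10) {
  scaled <- lapply(samples, function(s) {
    s <- as.matrix(s)
    ctr <- colMeans(s)
    cs <- sqrt(sum(sweep(s, 2, ctr)^2))
    sweep(s, 2, ctr) / cs
  })
  mn <- scaled[[1]]
  aligned <- scaled
  for (i in seq_len(n_sweeps)) {
    aligned <- lapply(scaled, function(s) {
      pr <- vegan::procrustes(mn, s, scale = FALSE, symmetric = FALSE)
      s %*% pr$rotation + matrix(pr$translation, nrow(s), 3, byrow = TRUE)
    })
    new_mn <- Reduce(`+`, aligned) / length(aligned)
    if (sqrt(sum((new_mn - mn)^2)) < tol) { mn <- new_mn; break }
    mn <- new_mn
  }
  vapply(aligned, function(a) sqrt(sum((a - mn)^2)), 0)
}
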