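# Independent oracles and small fixture builders shared across tests.

# Floyd-Warshall all-pairs hop counts (vectorized over the pivot), NA when
# unreachable. Independent of the BFS pathway used by the package.
fw_hops <- function(graph) {
  n <- graph$n_nodes
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  e <- graph$edges
  if (nrow(e)) {
    D[e] <- 1
    D[e[, 2:1, drop = FALSE]] <- 1
  }
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D[is.infinite(D)] <- NA
  D
}

# closeness from the Floyd-Warshall distances, Wasserman-Faust scaled
fw_closeness <- function(graph) {
  D <- fw_hops(graph)
  n <- nrow(D)
  reach <- rowSums(!is.na(D))
  dsum <- rowSums(D, na.rm = TRUE)
  ifelse(reach > 1, ((reach - 1) / (n - 1)) * ((reach - 1) / dsum), 0)
}

# Horn's quaternion method for minimal RMSD under proper rotation +
# translation: largest eigenvalue of the 4x4 quaternion matrix. An
# algorithmically independent check on the SVD-based Kabsch pathway.
horn_rmsd <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  S <- crossprod(yc, xc)  # S[a,b] = sum_i y_ia * x_ib
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  err <- sum(xc^2) + sum(yc^2) - 2 * lam
  sqrt(max(0, err) / nrow(x))
}

# random proper rotation matrix (QR of a Gaussian matrix, det corrected)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# mean silhouette width of labelled 2-d coordinates
silhouette_mean <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  n <- nrow(d)
  labs <- unique(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    a <- mean(d[i, labels == own & seq_len(n) != i])
    b <- min(vapply(labs[labs != own],
                    function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# accuracy of a logistic (linear) classifier on 2-d coordinates
linear_accuracy <- function(coords, labels) {
  y <- as.integer(labels == labels[1])
  df <- data.frame(y = y, x1 = coords[, 1], x2 = coords[, 2])
  fit <- suppressWarnings(stats::glm(y ~ x1 + x2, df, family = stats::binomial))
  mean((stats::predict(fit, type = "response") > 0.5) == (y == 1))
}

# topology with one CA atom per residue (the standard toy-chain fixture)
single_atom_topology <- function(n, chain = "A") {
  molecular_topology(atom_res = seq_len(n), atom_names = rep("CA", n),
                     chain = chain)
}

# frame from an n x 3 (or n x 2, z = 0) coordinate table
toy_frame <- function(xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) == 2) xy <- cbind(xy, 0)
  unname(xy)
}

edge_set <- function(graph) {
  if (nrow(graph$edges) == 0) character(0) else
    paste(graph$edges[, 1], graph$edges[, 2], sep = "-")
}
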