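# Shared fixtures, built in code at test time.

# canonical water monomer already posed in its oxygen frame
canonical_molecule <- function(cluster = 1L, molecule = 1L, atom_offset = 0L) {
  water_molecule_tbl(o = c(0, 0, 0), h1 = c(0.96, 0, 0), h2 = c(-0.24, 0.93, 0),
                     cluster = cluster, molecule = molecule, atom_offset = atom_offset)
}

# cluster with a canonical central molecule and neighbours at given O positions;
# neighbour hydrogens use a fixed internal geometry (orientation irrelevant for
# ordering tests)
fixture_cluster <- function(o_positions, cluster = 1L) {
  mols <- list(canonical_molecule(cluster))
  for (k in seq_along(o_positions)) {
    o <- o_positions[[k]]
    mols[[k + 1L]] <- water_molecule_tbl(
      o = o, h1 = o + c(0.96, 0, 0), h2 = o + c(-0.24, 0.93, 0),
      cluster = cluster, molecule = k + 1L, atom_offset = 3L * k)
  }
  dplyr::bind_rows(mols)
}

random_rotation_matrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# apply a rigid motion to an atom tibble
rigid_motion <- function(atoms, rotation, translation) {
  p <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rotation) +
    matrix(translation, nrow(atoms), 3, byrow = TRUE)
  atoms$x <- p[, 1]; atoms$y <- p[, 2]; atoms$z <- p[, 3]
  atoms
}

# relabel the non-central molecules of a single-cluster tibble by `perm`
# (a permutation of 2..n_mol), renumbering atoms to match the new order
shuffle_molecules <- function(atoms, perm) {
  stopifnot(sort(perm) == 2:max(atoms$molecule))
  new_order <- c(1L, perm)
  out <- atoms[order(match(atoms$molecule, new_order), atoms$atom), ]
  out$molecule <- rep(seq_along(new_order), each = 3L)
  out$atom <- seq_len(nrow(out))
  out
}

# dense-arithmetic oracle for the concentrated log-likelihood, weights and
# predictions, written with solve()/det() only (independent of the package's
# Cholesky path)
dense_krig_oracle <- function(X, y, theta, nugget = 1e-10, Xq = NULL) {
  n <- nrow(X)
  R <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    R[i, j] <- exp(-sum(theta * (X[i, ] - X[j, ])^2))
  }
  R <- R + diag(nugget, n)
  Ri <- solve(R)
  ones <- rep(1, n)
  mu <- c(ones %*% Ri %*% y) / c(ones %*% Ri %*% ones)
  r <- y - mu
  sigma2 <- c(t(r) %*% Ri %*% r) / n
  s2f <- max(sigma2, 1e-14)
  L <- -n / 2 * log(s2f) - log(det(R)) / 2 - c(t(r) %*% Ri %*% r) / (2 * s2f)
  a <- c(Ri %*% r)
  pred <- NULL
  if (!is.null(Xq)) {
    pred <- apply(Xq, 1, function(xq) {
      mu + sum(a * apply(X, 1, function(xi) exp(-sum(theta * (xq - xi)^2))))
    })
  }
  list(L = L, mu_hat = mu, sigma2_hat = sigma2, weights = a, pred = pred)
}

# the large shared benchmark used by the acceptance suite: 5000 decamers with
# surrogate labels and the feature matrices of the three headline schemes.
# Built once per test run and memoized.
.bench_env <- new.env(parent = emptyenv())
bench_dataset <- function() {
  if (is.null(.bench_env$data)) {
    ds <- generate_dataset(5000, seed = 2026)
    .bench_env$data <- list(
      ds = ds,
      standard = featurize(ds$atoms, "standard"),
      distance = featurize(ds$atoms, "distance"),
      structured_2a = featurize(ds$atoms, "structured_2a"))
  }
  .bench_env$data
}

# a smaller memoized set for property-style tests
small_decamers <- function(n = 500) {
  key <- paste0("small", n)
  if (is.null(.bench_env[[key]])) {
    .bench_env[[key]] <- generate_decamers(n, seed = 515)
  }
  .bench_env[[key]]
}
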