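test_that("node sets match the structured-scheme definitions", {
  n4 <- water_nodes("first-shell")
  n8 <- water_nodes("two-shell")
  expect_equal(nrow(n4), 4L)
  expect_equal(nrow(n8), 8L)
  expect_equal(n8[1:4, ], n4)
  expect_equal(unique(n4$r), 2.65)
  expect_equal(unique(n8$r[5:8]), 3.18)
  # node 1 lies on the +x axis of the local frame
  expect_equal(as.numeric(.spherical_to_cart(n4$r[1], n4$theta[1], n4$phi[1])),
               c(2.65, 0, 0), tolerance = 1e-12)
})

test_that("central features return internal coordinates, frame-free", {
  right <- water_molecule_tbl(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  cl <- dplyr::bind_rows(right, water_molecule_tbl(c(0, 0, 3), c(0.96, 0, 3),
                                                   c(-0.24, 0.93, 3),
                                                   molecule = 2, atom_offset = 3))
  cf <- central_features(cl)
  expect_equal(c(cf$R_OH1, cf$R_OH2, cf$theta_HOH), c(1, 1, 90))

  fo <- featurize(cl, "standard", "oxygen")
  fh <- featurize(cl, "standard", "hydrogen")
  expect_equal(as.numeric(fo[1, c("R_OH1", "R_OH2", "theta_HOH")]),
               as.numeric(fh[1, c("R_OH1", "R_OH2", "theta_HOH")]))
})

test_that("molecule ordering follows each scheme's rule", {
  # three neighbours at central-O distances 3.0, 2.7, 4.0 in input order
  cl <- fixture_cluster(list(c(3, 0, 0), c(0, 2.7, 0), c(0, 0, -4)))
  ord <- order_molecules(cl, "distance")
  expect_equal(ord$molecule, c(3L, 2L, 4L))
  expect_equal(ord$provenance, sprintf("distance rank %d", 1:3))

  ord_std <- order_molecules(cl, "standard")
  expect_equal(ord_std$molecule, 2:4)
  expect_equal(unique(ord_std$provenance), "atomic index")
})

test_that("greedy node allocation puts a zero-distance molecule on its node", {
  # one first-shell oxygen exactly at node 1's position (identity frame)
  opos <- list(c(2.65, 0, 0),              # node 1 exactly
               c(-0.69, 2.56, 0),          # near node 2
               c(-0.48, -0.61, 2.53),      # near node 3
               c(-0.48, -0.61, -2.53))     # near node 4
  cl <- fixture_cluster(opos)
  ord <- order_molecules(cl, "structured_1a")
  expect_equal(ord$molecule[1], 2L)
  expect_equal(ord$provenance[1], "node 1")
})

test_that("removing the nearest-four restriction lets an outer molecule take a node", {
  # four nearest molecules sit near nodes 1, 3, 4 and one anti-node direction;
  # the fifth-nearest sits exactly on the node-2 ray at 3.0 A
  node2_dir <- c(cos(.deg2rad(105)), sin(.deg2rad(105)), 0)
  opos <- list(c(2.6, 0, 0),
               c(0, -2.6, 0),
               2.6 * c(-0.477, -0.611, 2.534) / 2.65,
               2.6 * c(-0.477, -0.611, -2.534) / 2.65,
               3.0 * node2_dir)
  cl <- fixture_cluster(opos)

  ord2a <- order_molecules(cl, "structured_2a")
  # brute-force oracle: sequential greedy over plain Euclidean distances
  nodes <- water_nodes("first-shell")
  node_cart <- .spherical_to_cart(nodes$r, nodes$theta, nodes$phi)
  omat <- do.call(rbind, opos)
  taken <- integer(0)
  for (nd in 1:4) {
    cand <- setdiff(1:5, taken)
    d <- sqrt(rowSums(sweep(omat[cand, , drop = FALSE], 2, node_cart[nd, ])^2))
    taken <- c(taken, cand[which.min(d)])
  }
  expect_equal(ord2a$molecule[1:4], taken + 1L)
  expect_equal(ord2a$molecule[2], 6L)  # the outer molecule captures node 2

  # impossible under the restricted scheme: slots 1-4 are the four nearest
  ord1a <- order_molecules(cl, "structured_1a")
  expect_setequal(ord1a$molecule[1:4], 2:5)
  expect_equal(ord1a$molecule[5], 6L)
})

test_that("restricted structured ordering reuses the distance-ranked molecules", {
  atoms <- small_decamers(50)
  for (id in c(1, 17, 42)) {
    one <- atoms[atoms$cluster == id, ]
    d14 <- order_molecules(one, "distance")$molecule[1:4]
    s14 <- order_molecules(one, "structured_1a")$molecule[1:4]
    expect_setequal(s14, d14)
    d58 <- order_molecules(one, "distance")$molecule[5:8]
    s58 <- order_molecules(one, "structured_1b")$molecule[5:8]
    expect_setequal(s58, d58)
  }
})

test_that("feature vectors have 3N-6 entries", {
  dimer <- fixture_cluster(list(c(0, 0, 3)))
  expect_equal(ncol(featurize(dimer, "standard")) - 1L, 12L)
  trimer <- fixture_cluster(list(c(0, 0, 3), c(3, 0, 0)))
  expect_equal(ncol(featurize(trimer, "distance")) - 1L, 21L)
  atoms <- small_decamers(20)
  f <- featurize(atoms[atoms$cluster <= 3, ], "structured_2b")
  expect_equal(ncol(f) - 1L, 84L)
  expect_equal(names(f)[2:4], c("R_OH1", "R_OH2", "theta_HOH"))
  # structured schemes refuse clusters with too few molecules
  expect_error(featurize(dimer, "structured_1a"),
               class = "waterkrig_insufficient_molecules")
})

test_that("all twelve schemes are invariant under rigid motion", {
  atoms <- small_decamers(20)
  one <- atoms[atoms$cluster == 11, ]
  grid <- all_feature_schemes()
  withr::with_seed(31, {
    Q <- random_rotation_matrix(); tr <- rnorm(3, sd = 5)
    moved <- rigid_motion(one, Q, tr)
    for (i in seq_len(nrow(grid))) {
      f0 <- featurize(one, grid$scheme[i], grid$center[i])
      f1 <- featurize(moved, grid$scheme[i], grid$center[i])
      expect_lt(max(abs(as.matrix(f0[, -1]) - as.matrix(f1[, -1]))), 1e-9)
    }
  })
})

test_that("geometric schemes ignore input order; the standard scheme permutes with it", {
  atoms <- small_decamers(20)
  one <- atoms[atoms$cluster == 5, ]
  perm <- withr::with_seed(8, sample(2:10))
  shuffled <- shuffle_molecules(one, perm)

  for (s in c("distance", "structured_1a", "structured_1b",
              "structured_2a", "structured_2b")) {
    f0 <- as.matrix(featurize(one, s)[, -1])
    f1 <- as.matrix(featurize(shuffled, s)[, -1])
    expect_equal(f1, f0, tolerance = 1e-12)
  }

  f0 <- as.numeric(featurize(one, "standard")[1, -1])
  f1 <- as.numeric(featurize(shuffled, "standard")[1, -1])
  expect_false(isTRUE(all.equal(f0, f1)))
  # block j of the shuffled vector is the block of original molecule perm[j]
  block <- function(v, j) v[3 + (j - 1) * 9 + 1:9]
  for (j in 1:9) {
    expect_equal(block(f1, j), block(f0, perm[j] - 1L), tolerance = 1e-12)
  }
})

test_that("distance ordering contracts slot variance; structured contracts angles", {
  atoms <- small_decamers(500)
  ps <- spatial_projection(atoms, "standard")
  pd <- spatial_projection(atoms, "distance")
  p2a <- spatial_projection(atoms, "structured_2a")

  v_std <- var(ps$r[ps$slot == 1])
  v_dist <- var(pd$r[pd$slot == 1])
  expect_lt(v_dist, v_std)

  for (sl in 1:4) {
    expect_lte(var(p2a$theta[p2a$slot == sl]), var(pd$theta[pd$slot == sl]))
    expect_lte(var(p2a$phi[p2a$slot == sl]), var(pd$phi[pd$slot == sl]))
  }
  # sorted distances are monotone across slots
  expect_lt(mean(pd$r[pd$slot == 1]), mean(pd$r[pd$slot == 4]))
})

test_that("spatial projection emits one row per cluster and slot", {
  atoms <- small_decamers(20)
  pr <- spatial_projection(atoms, "distance", slots = 1:4)
  expect_equal(nrow(pr), 20L * 4L)
  pr1 <- spatial_projection(atoms[atoms$cluster == 1, ], "distance", slots = 1)
  expect_equal(nrow(pr1), 1L)
  empty <- spatial_projection(atoms[atoms$cluster == 0, ], "distance")
  expect_equal(nrow(empty), 0L)
})

test_that("density factor counts first-shell slot combinations", {
  expect_identical(density_factor(9, 4), 126L)
  expect_identical(density_factor(7, 0), 1L)
  # enumeration oracle
  expect_identical(density_factor(5, 2), ncol(utils::combn(5, 2)))
  expect_error(density_factor(4, 5), class = "waterkrig_domain_error")
  expect_error(density_factor(-1, 0), class = "waterkrig_domain_error")
})

test_that("feature matrices round-trip through CSV", {
  atoms <- small_decamers(20)
  f <- featurize(atoms[atoms$cluster <= 4, ], "distance")
  p <- withr::local_tempfile(fileext = ".csv")
  write_features(f, p)
  back <- read_features(p)
  expect_equal(as.matrix(back[, -1]), as.matrix(f[, -1]), tolerance = 1e-12,
               ignore_attr = TRUE)
  writeLines(c("cluster,R_OH1", "1,abc"), p)
  expect_error(read_features(p), class = "waterkrig_parse_error")
})
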