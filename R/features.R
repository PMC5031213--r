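#' Order the non-central molecules of each cluster into feature slots
#'
#' The heart of every feature-definition scheme: the rule that decides which
#' non-central water molecule fills which block of the feature vector.
#'
#' * `standard` - ascending atomic index of the molecules' oxygens (input
#'   file order; carries no geometric information).
#' * `distance` - ascending distance from the central oxygen to each
#'   molecule's oxygen.
#' * `structured_1a` - slots 1-4 assigned greedily to nodes 1-4 (each node,
#'   in node order, takes the unassigned molecule whose oxygen lies nearest
#'   to it), drawing only from the four distance-nearest molecules; slots
#'   5+ by distance rank.
#' * `structured_1b` - as `structured_1a`, then nodes 5-8 assigned greedily
#'   from the distance ranks 5-8; the last molecule fills the final slot.
#' * `structured_2a` - greedy node 1-4 assignment from *all* non-central
#'   molecules; the remainder by distance.
#' * `structured_2b` - greedy node 1-8 assignment from all non-central
#'   molecules; the remaining molecule last.
#'
#' Ties (equal distances) are broken by lower atomic index. Node-to-molecule
#' distance is the Euclidean distance from the node's position to the
#' molecule's oxygen, both expressed in the local frame implied by `center`.
#'
#' @param atoms Atom tibble (one or more clusters).
#' @param scheme,center Scheme id and frame center (see [feature_scheme()]),
#'   or pass a ready-made `feature_scheme` object as `scheme`.
#' @param central Index of the central molecule (default 1).
#' @param nodes Node tibble (see [water_nodes()]); defaults to the node set
#'   the scheme requires.
#' @return A tibble with columns `cluster`, `slot`, `molecule` and
#'   `provenance` (`"node k"`, `"distance rank m"` or `"atomic index"`).
#' @export
order_molecules <- function(atoms, scheme = "standard", center = "oxygen",
                            central = 1L, nodes = NULL) {
  spec <- if (inherits(scheme, "feature_scheme")) scheme else feature_scheme(scheme, center)
  nodes_cart <- .nodes_cart(spec, nodes)
  cl <- .cluster_list(atoms)
  purrr::map_dfr(cl, function(c1) {
    ord <- .order_one(c1, central, spec, nodes_cart)
    tibble::tibble(cluster = c1$id, slot = seq_along(ord$perm),
                   molecule = ord$perm, provenance = ord$provenance)
  })
}

.nodes_cart <- function(spec, nodes) {
  if (spec$n_nodes == 0L) return(NULL)
  nodes <- nodes %||% water_nodes(if (spec$n_nodes == 4L) "first-shell" else "two-shell")
  if (nrow(nodes) < spec$n_nodes) {
    abort(sprintf("scheme '%s' needs %d nodes, got %d", spec$scheme, spec$n_nodes, nrow(nodes)),
          class = "waterkrig_domain_error")
  }
  .spherical_to_cart(nodes$r, nodes$theta, nodes$phi)[seq_len(spec$n_nodes), , drop = FALSE]
}

# ordering for one cluster; returns list(perm = molecule ids, provenance = chr)
.order_one <- function(c1, central, spec, nodes_cart) {
  n_mol <- length(c1$mols)
  others <- setdiff(seq_len(n_mol), central)
  if (!length(others)) {
    abort("cluster has no non-central molecules", class = "waterkrig_insufficient_molecules")
  }
  o_rows <- vapply(c1$mols[others], `[[`, 0L, "O")
  opos <- c1$pos[o_rows, , drop = FALSE]
  oidx <- c1$atom[o_rows]
  central_o <- c1$pos[c1$mols[[central]]["O"], ]
  d_c <- sqrt(rowSums(sweep(opos, 2, central_o)^2))

  if (spec$scheme == "standard") {
    ord <- order(oidx)
    return(list(perm = others[ord], provenance = rep("atomic index", length(ord))))
  }
  rank_order <- order(d_c, oidx)  # distance ranks with atomic-index tie-break
  if (spec$scheme == "distance") {
    return(list(perm = others[rank_order],
                provenance = sprintf("distance rank %d", seq_along(rank_order))))
  }

  # structured schemes: greedy node allocation over O positions in the local frame
  need <- spec$n_nodes
  if (length(others) < need) {
    abort(sprintf("scheme '%s' needs at least %d non-central molecules, cluster %s has %d",
                  spec$scheme, need, c1$id, length(others)),
          class = "waterkrig_insufficient_molecules")
  }
  idx_mc <- c1$mols[[central]]
  frame <- .frame_from_points(c1$pos[idx_mc["O"], ], c1$pos[idx_mc["H1"], ],
                              c1$pos[idx_mc["H2"], ], spec$center)
  local_o <- (opos - matrix(frame$origin, nrow(opos), 3, byrow = TRUE)) %*% t(frame$rotation)

  greedy <- function(node_rows, pool) {
    # pool: positions into `others`; returns assignment vector (same length as node_rows)
    taken <- integer(0)
    for (nd in node_rows) {
      cand <- setdiff(pool, taken)
      dn <- sqrt(rowSums(sweep(local_o[cand, , drop = FALSE], 2, nodes_cart[nd, ])^2))
      pick <- cand[order(dn, oidx[cand])[1]]
      taken <- c(taken, pick)
    }
    taken
  }

  restricted <- grepl("^structured_1", spec$scheme)
  if (restricted) {
    first4 <- greedy(1:4, rank_order[1:4])
    if (spec$n_nodes == 4L) {
      rest <- rank_order[-(1:4)]
      perm_pos <- c(first4, rest)
      prov <- c(sprintf("node %d", 1:4),
                sprintf("distance rank %d", seq_along(rest) + 4L))
    } else {
      next4 <- greedy(5:8, rank_order[5:8])
      rest <- rank_order[-(1:8)]
      perm_pos <- c(first4, next4, rest)
      prov <- c(sprintf("node %d", 1:8),
                sprintf("distance rank %d", seq_along(rest) + 8L))
    }
  } else {
    alloc <- greedy(seq_len(need), seq_along(others))
    rest <- setdiff(rank_order, alloc)
    perm_pos <- c(alloc, rest)
    prov <- c(sprintf("node %d", seq_len(need)),
              sprintf("distance rank %d", match(rest, rank_order)))
  }
  list(perm = others[perm_pos], provenance = prov)
}

#' Build kriging feature vectors for water clusters
#'
#' Produces the 3N-6 internal-coordinate descriptor of each cluster: the two
#' central O-H bond lengths and the central H-O-H angle, followed by
#' (R, theta, phi) for every atom of every non-central molecule, measured in
#' the oxygen- or hydrogen-centered frame of [build_frame()] and ordered into
#' slots by [order_molecules()]. Within each molecule's block the oxygen comes
#' first, then the two hydrogens (nearer to the frame origin first, ties by
#' atomic index). Distances are in Angstrom, angles in degrees.
#'
#' @inheritParams order_molecules
#' @return A tibble with one row per cluster: a `cluster` column and 3N-6
#'   named feature columns (`R_OH1`, `R_OH2`, `theta_HOH`, then
#'   `R_O1, theta_O1, phi_O1, R_H1a, ...` per slot).
#' @examples
#' atoms <- generate_decamers(2, seed = 1)
#' featurize(atoms, "distance")
#' @export
featurize <- function(atoms, scheme = "standard", center = "oxygen",
                      central = 1L, nodes = NULL) {
  spec <- if (inherits(scheme, "feature_scheme")) scheme else feature_scheme(scheme, center)
  nodes_cart <- .nodes_cart(spec, nodes)
  cl <- .cluster_list(atoms)
  rows <- lapply(cl, function(c1) .featurize_one(c1, central, spec, nodes_cart))
  n_feat <- vapply(rows, length, 0L)
  if (length(unique(n_feat)) != 1L) {
    abort("clusters have differing atom counts; featurize them separately",
          class = "waterkrig_domain_error")
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- .feature_names((ncol(mat) - 3L) / 9L)
  out <- tibble::as_tibble(as.data.frame(mat))
  dplyr::bind_cols(tibble::tibble(cluster = unlist(lapply(cl, `[[`, "id"))), out)
}

.featurize_one <- function(c1, central, spec, nodes_cart) {
  idx_mc <- c1$mols[[central]]
  o <- c1$pos[idx_mc["O"], ]; h1 <- c1$pos[idx_mc["H1"], ]; h2 <- c1$pos[idx_mc["H2"], ]
  frame <- .frame_from_points(o, h1, h2, spec$center)
  v1 <- h1 - o; v2 <- h2 - o
  r1 <- sqrt(sum(v1^2)); r2 <- sqrt(sum(v2^2))
  ang <- .rad2deg(acos(max(-1, min(1, sum(v1 * v2) / (r1 * r2)))))
  ord <- .order_one(c1, central, spec, nodes_cart)

  vals <- c(r1, r2, ang)
  for (k in seq_along(ord$perm)) {
    idx <- c1$mols[[ord$perm[k]]]
    hpair <- c(idx["H1"], idx["H2"])
    dh <- sqrt(rowSums((c1$pos[hpair, , drop = FALSE] -
                          matrix(frame$origin, 2, 3, byrow = TRUE))^2))
    hpair <- hpair[order(dh, c1$atom[hpair])]
    p <- c1$pos[c(idx["O"], hpair), , drop = FALSE]
    sph <- .cart_to_sph_mat(
      (p - matrix(frame$origin, 3, 3, byrow = TRUE)) %*% t(frame$rotation))
    vals <- c(vals, t(sph))
  }
  vals
}

.feature_names <- function(n_slots) {
  c("R_OH1", "R_OH2", "theta_HOH",
    unlist(lapply(seq_len(n_slots), function(k) {
      c(paste0(c("R_", "theta_", "phi_"), "O", k),
        paste0(c("R_", "theta_", "phi_"), "H", k, "a"),
        paste0(c("R_", "theta_", "phi_"), "H", k, "b"))
    })))
}

#' Central-molecule internal coordinates
#'
#' The first three features of every scheme: the frame-defining O-H1 bond
#' length, the other O-H bond length, and the H-O-H angle. These are internal
#' coordinates, identical under the oxygen- and hydrogen-centered frames.
#'
#' @param atoms Atom tibble (one or more clusters).
#' @param central Index of the central molecule.
#' @return A tibble with columns `cluster`, `R_OH1`, `R_OH2` (Angstrom) and
#'   `theta_HOH` (degrees).
#' @export
central_features <- function(atoms, central = 1L) {
  cl <- .cluster_list(atoms)
  purrr::map_dfr(cl, function(c1) {
    idx <- c1$mols[[central]]
    o <- c1$pos[idx["O"], ]
    v1 <- c1$pos[idx["H1"], ] - o; v2 <- c1$pos[idx["H2"], ] - o
    r1 <- sqrt(sum(v1^2)); r2 <- sqrt(sum(v2^2))
    tibble::tibble(cluster = c1$id, R_OH1 = r1, R_OH2 = r2,
                   theta_HOH = .rad2deg(acos(max(-1, min(1, sum(v1 * v2) / (r1 * r2))))))
  })
}

#' Sampling-density ratio between index- and distance-defined slots
#'
#' The number of ways `k_shell` of `n_outer` surrounding molecules can land in
#' the first `k_shell` feature slots when slots are assigned by atomic index:
#' the binomial coefficient C(n_outer, k_shell). A distance-defined training
#' set collapses all of these onto one arrangement, so it samples that region
#' of feature space at a density C(n_outer, k_shell) times higher. For nine
#' neighbours and a four-molecule first shell the factor is C(9, 4) = 126.
#'
#' @param n_outer Number of non-central molecules.
#' @param k_shell Number of first-shell slots.
#' @return An integer count.
#' @export
density_factor <- function(n_outer, k_shell) {
  if (!is.numeric(n_outer) || !is.numeric(k_shell) || n_outer < 0 || k_shell < 0 ||
      k_shell > n_outer) {
    abort("need 0 <= k_shell <= n_outer", class = "waterkrig_domain_error")
  }
  as.integer(round(choose(n_outer, k_shell)))
}

#' Local spherical coordinates of slot oxygens across clusters
#'
#' Collects, for each cluster and each requested feature slot, the slot
#' oxygen's local spherical coordinates - the raw material of the
#' theta/phi-space projection plots that visualize how tightly a scheme
#' confines each slot.
#'
#' @inheritParams order_molecules
#' @param slots Which slots to project (default 1:4, the first shell).
#' @return A tibble with columns `cluster`, `slot`, `r`, `theta`, `phi`.
#' @seealso [plot_projection()]
#' @export
spatial_projection <- function(atoms, scheme = "standard", center = "oxygen",
                               slots = 1:4, central = 1L, nodes = NULL) {
  spec <- if (inherits(scheme, "feature_scheme")) scheme else feature_scheme(scheme, center)
  nodes_cart <- .nodes_cart(spec, nodes)
  cl <- .cluster_list(atoms)
  if (!length(cl)) {
    return(tibble::tibble(cluster = integer(), slot = integer(),
                          r = double(), theta = double(), phi = double()))
  }
  purrr::map_dfr(cl, function(c1) {
    idx_mc <- c1$mols[[central]]
    frame <- .frame_from_points(c1$pos[idx_mc["O"], ], c1$pos[idx_mc["H1"], ],
                                c1$pos[idx_mc["H2"], ], spec$center)
    ord <- .order_one(c1, central, spec, nodes_cart)
    sl <- slots[slots <= length(ord$perm)]
    o_rows <- vapply(c1$mols[ord$perm[sl]], `[[`, 0L, "O")
    sph <- .cart_to_spherical(
      (c1$pos[o_rows, , drop = FALSE] -
         matrix(frame$origin, length(o_rows), 3, byrow = TRUE)) %*% t(frame$rotation))
    dplyr::bind_cols(tibble::tibble(cluster = c1$id, slot = sl), sph)
  })
}

#' Write / read a feature matrix as headered CSV
#'
#' @param features Feature tibble from [featurize()] (or any tibble whose
#'   first column identifies the cluster).
#' @param path File path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns the feature tibble.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) abort(paste0("cannot parse feature file: ",
                                                  conditionMessage(e)),
                                           class = "waterkrig_parse_error"))
  num <- df[setdiff(names(df), "cluster")]
  if (!all(vapply(num, is.numeric, TRUE))) {
    bad <- names(num)[!vapply(num, is.numeric, TRUE)][1]
    abort(sprintf("feature file column '%s' is not numeric", bad),
          class = "waterkrig_parse_error")
  }
  tibble::as_tibble(df)
}
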