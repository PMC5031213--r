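#' Build the atom-centered coordinate frame of a cluster's central molecule
#'
#' Constructs the right-handed local frame every feature scheme measures its
#' spherical-polar coordinates in. With `center = "oxygen"` the origin is the
#' central oxygen, +x points along the O->H1 bond (H1 being the central
#' molecule's lower-index hydrogen) and the xy-plane contains the other
#' hydrogen at positive y. With `center = "hydrogen"` the origin is H1 itself
#' and +x points from H1 towards the oxygen, again with the other hydrogen
#' fixing the xy-plane at positive y. z completes the right-handed set.
#'
#' @param atoms Atom tibble holding exactly one cluster.
#' @param center `"oxygen"` or `"hydrogen"`.
#' @param central Index of the central molecule (default 1).
#' @return An object of class `atomic_frame`: list with `origin` (length-3,
#'   Angstrom), `rotation` (3 x 3 orthonormal, rows are the local axes so that
#'   local = rotation %*% (p - origin)) and `center` (`"oxygen"`/`"hydrogen"`).
#' @examples
#' mol <- water_molecule_tbl(o = c(0, 0, 0), h1 = c(0.96, 0, 0), h2 = c(-0.24, 0.93, 0))
#' dimer <- dplyr::bind_rows(mol, dplyr::mutate(mol, molecule = 2, atom = atom + 3, z = z + 3))
#' build_frame(dimer)
#' @export
build_frame <- function(atoms, center = c("oxygen", "hydrogen"), central = 1L) {
  center <- match.arg(center)
  c1 <- .single_cluster(atoms)
  if (central < 1L || central > length(c1$mols)) {
    abort("`central` is not a molecule of this cluster", class = "waterkrig_domain_error")
  }
  idx <- c1$mols[[central]]
  .frame_from_points(c1$pos[idx["O"], ], c1$pos[idx["H1"], ], c1$pos[idx["H2"], ], center)
}

# core frame construction from the three central-molecule atom positions
.frame_from_points <- function(o, h1, h2, center) {
  if (center == "oxygen") {
    origin <- o
    ex <- h1 - o
    ref <- h2 - o
  } else {
    origin <- h1
    ex <- o - h1
    ref <- h2 - h1
  }
  nx <- sqrt(sum(ex^2))
  if (nx < 1e-9) abort("frame-defining atoms coincide", class = "waterkrig_degenerate_frame")
  ex <- ex / nx
  ref_perp <- ref - sum(ref * ex) * ex
  ny <- sqrt(sum(ref_perp^2))
  if (ny < 1e-6) {
    abort("frame-defining atoms are collinear; xy-plane undefined",
          class = "waterkrig_degenerate_frame")
  }
  ey <- ref_perp / ny                     # plane hydrogen lands at positive y
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],  # x cross y: right-handed
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  structure(list(origin = origin, rotation = rbind(ex, ey, ez, deparse.level = 0),
                 center = center),
            class = "atomic_frame")
}

#' @export
print.atomic_frame <- function(x, ...) {
  cat(sprintf("<atomic_frame> %s-centered\n  origin : %s\n", x$center,
              paste(sprintf("%.4f", x$origin), collapse = ", ")))
  cat("  axes (rows):\n")
  print(round(x$rotation, 6))
  invisible(x)
}

#' Convert Cartesian positions to local spherical-polar coordinates
#'
#' Expresses positions in a frame from [build_frame()] as (R, theta, phi):
#' R the distance to the frame origin in Angstrom, theta the polar angle from
#' the local z-axis in degrees (0-180), phi the azimuth from the local x-axis
#' in degrees, in (-180, 180]. A position exactly at the origin maps to
#' (0, 0, 0) by convention.
#'
#' @param frame An `atomic_frame`.
#' @param position A length-3 vector, an n x 3 matrix, or a data frame with
#'   `x`, `y`, `z` columns (Angstrom, world coordinates).
#' @return A tibble with columns `r`, `theta`, `phi`.
#' @export
to_local_spherical <- function(frame, position) {
  p <- .as_xyz_matrix(position)
  local <- (p - matrix(frame$origin, nrow(p), 3, byrow = TRUE)) %*% t(frame$rotation)
  .cart_to_spherical(local)
}

.as_xyz_matrix <- function(position) {
  if (is.data.frame(position)) {
    p <- as.matrix(position[, c("x", "y", "z")])
  } else if (is.matrix(position)) {
    p <- position
  } else {
    p <- matrix(position, nrow = 1)
  }
  if (ncol(p) != 3 || !all(is.finite(p))) {
    abort("positions must be finite Cartesian triples", class = "waterkrig_domain_error")
  }
  p
}

# matrix workhorse: columns r, theta, phi
.cart_to_sph_mat <- function(local) {
  r <- sqrt(rowSums(local^2))
  theta <- ifelse(r < 1e-300, 0, .rad2deg(acos(pmax(-1, pmin(1, local[, 3] / pmax(r, 1e-300))))))
  phi <- ifelse(r < 1e-300, 0, .rad2deg(atan2(local[, 2], local[, 1])))
  phi[phi <= -180] <- 180  # azimuth convention: (-180, 180]
  cbind(r = r, theta = theta, phi = phi)
}

.cart_to_spherical <- function(local) {
  m <- .cart_to_sph_mat(local)
  tibble::tibble(r = m[, 1], theta = m[, 2], phi = m[, 3])
}

#' Convert local spherical-polar coordinates back to Cartesian positions
#'
#' Inverse of [to_local_spherical()]: maps (R, theta, phi) in a local frame to
#' world Cartesian coordinates.
#'
#' @param frame An `atomic_frame`.
#' @param r,theta,phi Numeric vectors (Angstrom / degrees / degrees).
#' @return An n x 3 matrix of world Cartesian positions.
#' @export
from_local_spherical <- function(frame, r, theta, phi) {
  local <- .spherical_to_cart(r, theta, phi)
  local %*% frame$rotation + matrix(frame$origin, length(r), 3, byrow = TRUE)
}

.spherical_to_cart <- function(r, theta, phi) {
  th <- .deg2rad(theta); ph <- .deg2rad(phi)
  cbind(r * sin(th) * cos(ph), r * sin(th) * sin(ph), r * cos(th))
}

#' Construct a single water molecule as an atom tibble
#'
#' Convenience constructor for examples and tests: one molecule with the
#' oxygen listed first, then the two hydrogens in atom-index order.
#'
#' @param o,h1,h2 Length-3 Cartesian positions (Angstrom).
#' @param cluster,molecule Identifiers for the emitted rows.
#' @param atom_offset Added to the 1..3 atom indices.
#' @return A three-row atom tibble.
#' @export
water_molecule_tbl <- function(o, h1, h2, cluster = 1L, molecule = 1L, atom_offset = 0L) {
  p <- rbind(o, h1, h2)
  tibble::tibble(
    cluster = cluster, molecule = molecule, atom = atom_offset + 1:3,
    element = c("O", "H", "H"), x = p[, 1], y = p[, 2], z = p[, 3]
  )
}
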