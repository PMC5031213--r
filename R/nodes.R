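#' Tetrahedral node positions for the structured feature schemes
#'
#' The structured schemes anchor feature slots to fixed "nodes": points in the
#' central molecule's local frame where the first and second solvation-shell
#' oxygens of liquid-like water concentrate. Nodes 1-4 sit on the vertices of
#' a tetrahedron at 2.65 Angstrom (the first peak of the water O-O radial
#' distribution); nodes 5-8 sit tetrahedrally at 3.18 Angstrom, where the
#' fifth-nearest molecule is expected.
#'
#' @param set `"first-shell"` (nodes 1-4, used by the `*a` schemes) or
#'   `"two-shell"` (nodes 1-8, used by the `*b` schemes).
#' @return A tibble with columns `node`, `r` (Angstrom), `theta`, `phi`
#'   (degrees, polar/azimuth in the local frame).
#' @export
water_nodes <- function(set = c("first-shell", "two-shell")) {
  set <- match.arg(set)
  nodes <- tibble::tibble(
    node  = 1:8,
    r     = c(2.65, 2.65, 2.65, 2.65, 3.18, 3.18, 3.18, 3.18),
    theta = c(90, 90, 17, 163, 90, 90, 30, 150),
    phi   = c(0, 105, -128, -128, 172, -68, 53, 53)
  )
  if (set == "first-shell") nodes[1:4, ] else nodes
}

#' Read a node set from a delimited text file
#'
#' Node files are headered delimited text with columns `node`, `r`, `theta`,
#' `phi` (Angstrom / degrees), as written by e.g. `readr`/`write.csv`.
#'
#' @param path File path (comma- or whitespace-delimited, with header).
#' @return A node tibble as from [water_nodes()].
#' @export
read_nodes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = if (grepl("\\.csv$", path)) "," else "")
  need <- c("node", "r", "theta", "phi")
  if (!all(need %in% names(df))) {
    abort("node file must have columns node, r, theta, phi", class = "waterkrig_parse_error")
  }
  tibble::as_tibble(df[need])
}

# the 12 scheme x frame combinations
.schemes <- c("standard", "distance", "structured_1a", "structured_1b",
              "structured_2a", "structured_2b")
.centers <- c("oxygen", "hydrogen")

#' Validate and normalize a feature-scheme specification
#'
#' A feature scheme is one of six molecule-ordering rules combined with an
#' oxygen- or hydrogen-centered coordinate frame, giving the twelve model
#' variants: `standard` (slots by atomic index), `distance` (slots by
#' central-O to O distance), `structured_1a`/`structured_1b` (greedy node
#' allocation restricted to the four nearest molecules; 4 or 8 nodes) and
#' `structured_2a`/`structured_2b` (unrestricted greedy node allocation;
#' 4 or 8 nodes).
#'
#' @param scheme Scheme id (see above).
#' @param center Frame center, `"oxygen"` or `"hydrogen"`.
#' @return A list of class `feature_scheme` with elements `scheme`, `center`,
#'   `n_nodes` (0, 4 or 8) and `label` (e.g. `"Structured 2aH"`).
#' @export
feature_scheme <- function(scheme = .schemes, center = c("oxygen", "hydrogen")) {
  if (is.character(scheme) && length(scheme) == 1 && !scheme %in% .schemes) {
    abort(sprintf("unknown scheme '%s'; valid ids: %s", scheme,
                  paste(.schemes, collapse = ", ")),
          class = "waterkrig_usage_error")
  }
  scheme <- match.arg(scheme)
  center <- match.arg(center)
  n_nodes <- if (grepl("a$", scheme)) 4L else if (grepl("b$", scheme)) 8L else 0L
  label <- switch(scheme,
    standard = "Standard", distance = "Distance",
    structured_1a = "Structured 1a", structured_1b = "Structured 1b",
    structured_2a = "Structured 2a", structured_2b = "Structured 2b")
  if (center == "hydrogen") label <- paste0(label, if (grepl("Structured", label)) "H" else " H")
  structure(list(scheme = scheme, center = center, n_nodes = n_nodes, label = label),
            class = "feature_scheme")
}

#' @export
print.feature_scheme <- function(x, ...) {
  cat(sprintf("<feature_scheme> %s (%s, %s-centered frame)\n", x$label, x$scheme, x$center))
  invisible(x)
}

#' All twelve scheme/frame combinations
#'
#' @return A tibble with columns `scheme`, `center`, `label`, one row per
#'   model variant.
#' @export
all_feature_schemes <- function() {
  grid <- expand.grid(scheme = .schemes, center = .centers,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$label <- vapply(seq_len(nrow(grid)),
                       function(i) feature_scheme(grid$scheme[i], grid$center[i])$label, "")
  tibble::as_tibble(grid)
}
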