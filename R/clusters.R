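#' Read water-cluster geometries from an XYZ file
#'
#' Parses a standard (possibly multi-frame) XYZ file and groups atoms into
#' water molecules. Each frame becomes one cluster. Hydrogens are assigned to
#' their nearest oxygen (`group = "nearest"`, robust to arbitrary atom order)
#' or taken as consecutive O,H,H triplets (`group = "triplets"`).
#'
#' Molecule numbering follows the first-appearance order of the oxygens in the
#' file; by convention the central molecule of a cluster is molecule 1 unless
#' a different `central` index is passed to downstream functions.
#'
#' @param path Path to an XYZ file (element symbol then x, y, z in Angstrom;
#'   one or more concatenated frames).
#' @param group Hydrogen-to-oxygen assignment rule, `"nearest"` (default) or
#'   `"triplets"`.
#' @return A tibble with one row per atom: `cluster` (frame number),
#'   `molecule` (within-cluster molecule id), `atom` (1-based input order
#'   within the frame), `element` (`"O"` or `"H"`), `x`, `y`, `z` (Angstrom).
#' @seealso [write_xyz()], [validate_clusters()]
#' @export
read_xyz <- function(path, group = c("nearest", "triplets")) {
  group <- match.arg(group)
  lines <- readLines(path)
  out <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) {
      abort(sprintf("line %d: expected an atom count, got '%s'", i, lines[i]),
            class = "waterkrig_parse_error")
    }
    if (i + 1L + n > length(lines)) {
      abort(sprintf("line %d: frame declares %d atoms but file ends early", i, n),
            class = "waterkrig_parse_error")
    }
    frame <- frame + 1L
    rec <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(rec), "\\s+")
    bad <- which(lengths(tok) < 4L)
    if (length(bad)) {
      abort(sprintf("line %d: malformed atom record '%s'", i + 1L + bad[1], rec[bad[1]]),
            class = "waterkrig_parse_error")
    }
    el <- vapply(tok, `[[`, "", 1L)
    xyz <- suppressWarnings(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    if (anyNA(xyz)) {
      j <- which(apply(is.na(xyz), 2, any))[1]
      abort(sprintf("line %d: non-numeric coordinate in '%s'", i + 1L + j, rec[j]),
            class = "waterkrig_parse_error")
    }
    if (!all(el %in% c("O", "H"))) {
      abort(sprintf("line %d: unsupported element '%s' (only O and H)",
                    i + 1L + which(!el %in% c("O", "H"))[1],
                    setdiff(el, c("O", "H"))[1]),
            class = "waterkrig_unsupported_element")
    }
    pos <- t(xyz)
    mol <- .group_molecules(el, pos, group, frame)
    out[[frame]] <- tibble::tibble(
      cluster = frame, molecule = mol, atom = seq_len(n),
      element = el, x = pos[, 1], y = pos[, 2], z = pos[, 3]
    )
    i <- i + 2L + n
  }
  if (!frame) abort("no frames found in file", class = "waterkrig_parse_error")
  dplyr::bind_rows(out)
}

# assign each H to a molecule; returns integer molecule ids in O first-appearance order
.group_molecules <- function(el, pos, group, frame) {
  o_idx <- which(el == "O")
  h_idx <- which(el == "H")
  if (length(h_idx) != 2L * length(o_idx)) {
    abort(sprintf("frame %d: %d O and %d H atoms cannot form intact water molecules",
                  frame, length(o_idx), length(h_idx)),
          class = "waterkrig_grouping_error")
  }
  mol <- integer(length(el))
  mol[o_idx] <- seq_along(o_idx)
  if (group == "triplets") {
    for (k in seq_along(o_idx)) {
      oi <- o_idx[k]
      if (oi + 2L > length(el) || any(el[(oi + 1L):(oi + 2L)] != "H")) {
        abort(sprintf("frame %d: atoms %d-%d are not an O,H,H triplet", frame, oi, oi + 2L),
              class = "waterkrig_grouping_error")
      }
      mol[(oi + 1L):(oi + 2L)] <- k
    }
  } else {
    opos <- pos[o_idx, , drop = FALSE]
    for (hi in h_idx) {
      d2 <- rowSums(sweep(opos, 2, pos[hi, ])^2)
      mol[hi] <- which.min(d2)
    }
    counts <- tabulate(mol[h_idx], nbins = length(o_idx))
    if (any(counts != 2L)) {
      k <- which(counts != 2L)[1]
      abort(sprintf("frame %d: oxygen (molecule %d) has %d nearest-assigned hydrogens, expected 2",
                    frame, k, counts[k]),
            class = "waterkrig_grouping_error")
    }
  }
  mol
}

#' Write water clusters to a (multi-frame) XYZ file
#'
#' @param atoms An atom tibble as returned by [read_xyz()] or
#'   [generate_decamers()].
#' @param path Output file path.
#' @param comment Comment line(s), recycled across frames.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(atoms, path, comment = "") {
  cl <- unique(atoms$cluster)
  comment <- rep_len(comment, length(cl))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(cl)) {
    fr <- atoms[atoms$cluster == cl[k], ]
    fr <- fr[order(fr$atom), ]
    writeLines(as.character(nrow(fr)), con)
    writeLines(comment[k], con)
    writeLines(sprintf("%s %.10f %.10f %.10f", fr$element, fr$x, fr$y, fr$z), con)
  }
  invisible(path)
}

# internal: atoms tibble -> list of per-cluster structures used by the hot paths.
# Each element: list(id, pos (n x 3), element, atom, molecule, mols) where mols
# is a list per molecule of c(O = row, H1 = row, H2 = row), H1 the lower atom index.
.cluster_list <- function(atoms) {
  need <- c("cluster", "molecule", "atom", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) {
    abort(paste0("atom table is missing column(s): ", paste(miss, collapse = ", ")),
          class = "waterkrig_domain_error")
  }
  ids <- unique(atoms$cluster)
  row_groups <- split(seq_len(nrow(atoms)), factor(atoms$cluster, levels = ids))
  cx <- atoms$x; cy <- atoms$y; cz <- atoms$z
  cel <- atoms$element; cat_ <- atoms$atom; cmol <- atoms$molecule
  lapply(seq_along(ids), function(k) {
    rows <- row_groups[[k]]
    rows <- rows[order(cat_[rows])]
    id <- ids[k]
    pos <- cbind(cx[rows], cy[rows], cz[rows])
    el <- cel[rows]; mol <- cmol[rows]; atm <- cat_[rows]
    mol_rows <- split(seq_along(rows), mol)
    mols <- lapply(seq_along(mol_rows), function(m) {
      r <- mol_rows[[m]]
      o <- r[el[r] == "O"]
      h <- r[el[r] == "H"]
      if (length(o) != 1L || length(h) != 2L) {
        abort(sprintf("cluster %s molecule %s is not one O with two H",
                      id, names(mol_rows)[m]),
              class = "waterkrig_grouping_error")
      }
      h <- h[order(atm[h])]
      c(O = o, H1 = h[1], H2 = h[2])
    })
    list(id = id, pos = pos, element = el, atom = atm, molecule = mol, mols = mols)
  })
}

.single_cluster <- function(atoms) {
  cl <- .cluster_list(atoms)
  if (length(cl) != 1L) {
    abort("expected a single cluster; filter the atom table first",
          class = "waterkrig_domain_error")
  }
  cl[[1]]
}

#' Diagnose geometric invariant violations in water clusters
#'
#' Checks every cluster in the table against the water-cluster invariants:
#' each molecule has both O-H bonds shorter than 1.2 Angstrom and an H-O-H
#' angle strictly inside (60, 180) degrees; a cluster has at least two
#' molecules; no two atoms sit closer than 0.5 Angstrom.
#'
#' @param atoms An atom tibble (see [read_xyz()]).
#' @return A tibble of violations (`cluster`, `molecule`, `rule`, `detail`);
#'   zero rows when every invariant holds.
#' @export
validate_clusters <- function(atoms) {
  cl <- .cluster_list(atoms)
  rows <- list()
  add <- function(cluster, molecule, rule, detail) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      cluster = cluster, molecule = molecule, rule = rule, detail = detail)
  }
  for (c1 in cl) {
    if (!all(is.finite(c1$pos))) {
      add(c1$id, NA_integer_, "finite_positions", "non-finite coordinate")
      next
    }
    if (length(c1$mols) < 2L) {
      add(c1$id, NA_integer_, "min_molecules", "fewer than 2 molecules")
    }
    for (m in seq_along(c1$mols)) {
      idx <- c1$mols[[m]]
      o <- c1$pos[idx["O"], ]
      for (h in c("H1", "H2")) {
        d <- sqrt(sum((c1$pos[idx[h], ] - o)^2))
        if (d >= 1.2) {
          add(c1$id, m, "oh_bond_length",
              sprintf("O-%s distance %.3f A >= 1.2 A", h, d))
        }
      }
      v1 <- c1$pos[idx["H1"], ] - o
      v2 <- c1$pos[idx["H2"], ] - o
      ang <- .rad2deg(acos(max(-1, min(1, sum(v1 * v2) /
                                         (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))))
      if (!(ang > 60 && ang < 180)) {
        add(c1$id, m, "hoh_angle", sprintf("H-O-H angle %.2f deg outside (60, 180)", ang))
      }
    }
    d <- as.matrix(stats::dist(c1$pos))
    diag(d) <- Inf
    clash <- which(d <= 0.5, arr.ind = TRUE)
    clash <- clash[clash[, 1] < clash[, 2], , drop = FALSE]
    for (k in seq_len(nrow(clash))) {
      add(c1$id, NA_integer_, "atom_clash",
          sprintf("atoms %d and %d are %.3f A apart (<= 0.5 A)",
                  c1$atom[clash[k, 1]], c1$atom[clash[k, 2]], d[clash[k, 1], clash[k, 2]]))
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(cluster = integer(), molecule = integer(),
                          rule = character(), detail = character()))
  }
  dplyr::bind_rows(rows)
}
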