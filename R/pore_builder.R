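# Construction of carbonyl-functionalized graphene nanopore models.
#
# A pore layer is carved from a honeycomb lattice by removing the 16 atoms
# inside a fixed elliptic stencil centred on a hexagon; the 8 rim atoms
# closest to the pore centre are the carbonyl candidate sites, indexed 0..7
# counterclockwise from the +x axis. Four of the eight sites carry a C=O
# group with the oxygen pointing at the pore axis; the functionalized set is
# the base set {0,2,5,7} rotated by an integral twist (+1 modulo 8 per step,
# the clockwise convention viewed down +z).

# stencil semi-axes (Angstrom) at the reference bond length of 1.42 A; the
# unique mirror-symmetric compact 16-atom removal
.pore_stencil <- c(rx = 3.76, ry = 3.68)
.base_carbonyl_set <- c(0L, 2L, 5L, 7L)

# honeycomb lattice with a hexagon centre at the origin, bond length `bond`,
# covering |x|,|y| <= extent
graphene_sheet <- function(bond = 1.42, extent = 14) {
  a <- bond * sqrt(3)
  nmax <- ceiling(extent / a) + 3
  ij <- expand.grid(i = -nmax:nmax, j = -nmax:nmax)
  ox <- ij$i * a + ij$j * a / 2
  oy <- ij$j * a * sqrt(3) / 2 - bond  # shift: hexagon centre -> origin
  pts <- rbind(cbind(ox, oy), cbind(ox + a / 2, oy + bond / 2))
  pts[abs(pts[, 1]) <= extent & abs(pts[, 2]) <= extent, , drop = FALSE]
}

# TRUE unless the index set contains >= 2 adjacent (consecutive mod 8) pairs;
# configurations with two or more adjacent carbonyl groups are dismissed
valid_carbonyl_set <- function(positions) {
  stopifnot(all(positions %in% 0:7), length(positions) == 4)
  p <- sort(unique(positions))
  n_adj <- sum(outer(p, p, function(a, b) (a - b) %% 8L == 1L))
  n_adj < 2L
}

#' Build one carbonyl-functionalized graphene pore layer
#'
#' Carves a 16-atom pore from a graphene sheet and attaches four carbonyl
#' groups at the candidate edge sites selected by `twist_index`: the base set
#' \{0, 2, 5, 7\} rotated by `twist_index` steps modulo 8 (the clockwise
#' twist convention). Twists 0..4 are the five single-layer elements A0..A4.
#'
#' @param twist_index integer in 0..4.
#' @param lattice_bond_length graphene C-C bond length in Angstrom.
#' @param extent half-width of the generated sheet in Angstrom.
#' @return an object of class `pore_layer` with fields `atoms` (data.frame
#'   `element,x,y,z`), `carbonyl_positions` (0-based site indices),
#'   `site_xy` (coordinates of the eight candidate sites), `pore_center`,
#'   `twist_index`, `n_removed` and `footprint` (van der Waals footprint of
#'   the carved hole, Angstrom).
#' @examples
#' a0 <- build_layer(0)
#' sort(a0$carbonyl_positions)  # 0 2 5 7
#' @export
build_layer <- function(twist_index, lattice_bond_length = 1.42, extent = 14) {
  if (!is.numeric(twist_index) || length(twist_index) != 1 ||
      twist_index != round(twist_index) || twist_index < 0 || twist_index > 4)
    stop("invalid configuration: twist_index must be an integer in 0..4")
  if (lattice_bond_length <= 0) stop("lattice_bond_length must be positive")
  scale <- lattice_bond_length / 1.42
  pts <- graphene_sheet(lattice_bond_length, extent)
  rx <- .pore_stencil["rx"] * scale
  ry <- .pore_stencil["ry"] * scale
  inside <- (pts[, 1] / rx)^2 + (pts[, 2] / ry)^2 < 1
  removed <- pts[inside, , drop = FALSE]
  if (nrow(removed) != 16)
    stop("pore stencil did not remove 16 atoms; enlarge `extent`")
  kept <- pts[!inside, , drop = FALSE]

  # rim atoms: kept atoms bonded to a removed atom
  bond_cut2 <- (1.1 * lattice_bond_length)^2
  has_removed_nbr <- vapply(seq_len(nrow(kept)), function(i) {
    any((removed[, 1] - kept[i, 1])^2 + (removed[, 2] - kept[i, 2])^2 < bond_cut2)
  }, logical(1))
  rim <- kept[has_removed_nbr, , drop = FALSE]
  r <- sqrt(rowSums(rim^2))
  cand <- rim[order(r)[1:8], , drop = FALSE]
  ang <- atan2(cand[, 2], cand[, 1]) %% (2 * pi)
  cand <- cand[order(ang), , drop = FALSE]          # site index 0..7, ccw from +x

  positions <- sort((.base_carbonyl_set + as.integer(twist_index)) %% 8L)
  if (!valid_carbonyl_set(positions))
    stop("invalid configuration: two or more adjacent carbonyl groups")

  oxy <- t(vapply(positions + 1L, function(i) {
    u <- -cand[i, ] / sqrt(sum(cand[i, ]^2))        # toward the pore axis
    cand[i, ] + kpore_constants$co_bond * scale * u
  }, numeric(2)))

  atoms <- rbind(
    data.frame(element = "C", x = kept[, 1], y = kept[, 2], z = 0),
    data.frame(element = "O", x = oxy[, 1], y = oxy[, 2], z = 0)
  )
  footprint <- c(diff(range(removed[, 1])), diff(range(removed[, 2]))) + 2 * 1.7
  structure(list(
    twist_index = as.integer(twist_index),
    carbonyl_positions = positions,
    atoms = atoms,
    site_xy = cand,
    pore_center = c(0, 0),
    n_removed = nrow(removed),
    footprint = footprint,
    bond_length = lattice_bond_length
  ), class = "pore_layer")
}

#' @export
print.pore_layer <- function(x, ...) {
  cat(sprintf("A%d pore layer: %d atoms (%d carbonyl O), sites {%s}, footprint %.1f x %.1f A\n",
              x$twist_index, nrow(x$atoms), sum(x$atoms$element == "O"),
              paste(x$carbonyl_positions, collapse = ","),
              x$footprint[1], x$footprint[2]))
  invisible(x)
}

#' Stack two pore layers into a bilayer channel model
#'
#' @param m,n twist indices of the first and second layer (0..4).
#' @param d interlayer distance in Angstrom; 3.35 A (pristine graphite) by
#'   default.
#' @param ... passed to [build_layer()].
#' @return an object of class `bilayer_pore` with the two coaxial layers at
#'   z = 0 and z = d and the label `"AmAn"`.
#' @examples
#' build_bilayer(0, 1)$label  # "A0A1"
#' @export
build_bilayer <- function(m, n, d = 3.35, ...) {
  if (!is.numeric(d) || length(d) != 1 || d <= 0)
    stop("geometry error: interlayer distance d must be > 0")
  layer1 <- build_layer(m, ...)
  layer2 <- build_layer(n, ...)
  layer2$atoms$z <- d
  structure(list(
    layer1 = layer1, layer2 = layer2, d = d,
    label = sprintf("A%dA%d", layer1$twist_index, layer2$twist_index)
  ), class = "bilayer_pore")
}

#' @export
print.bilayer_pore <- function(x, ...) {
  cat(sprintf("%s bilayer pore, d = %.2f A, %d atoms\n",
              x$label, x$d, nrow(x$layer1$atoms) + nrow(x$layer2$atoms)))
  invisible(x)
}

#' Are two bilayer configurations equivalent under a layer swap?
#'
#' Compares carbonyl position sets after exchanging the layers, i.e. AmAn is
#' equivalent to AnAm.
#' @param a,b `bilayer_pore` objects.
#' @export
layers_swap_equivalent <- function(a, b) {
  identical(a$layer1$carbonyl_positions, b$layer2$carbonyl_positions) &&
    identical(a$layer2$carbonyl_positions, b$layer1$carbonyl_positions)
}

#' Enumerate bilayer pore configurations
#'
#' The five single-layer elements combine into 25 ordered bilayer
#' configurations; deduplication under the exchange of the two layers leaves
#' 15 representatives.
#'
#' @param equivalence `"none"` for all ordered pairs, `"layer_swap"` (default)
#'   for one representative per unordered pair, or `"custom"` with a
#'   `predicate(m1, n1, m2, n2)` returning TRUE when the two labelled
#'   configurations are equivalent.
#' @param predicate equivalence predicate, used when `equivalence = "custom"`.
#' @return character vector of labels `"AmAn"`.
#' @examples
#' length(enumerate_configs("none"))       # 25
#' length(enumerate_configs("layer_swap")) # 15
#' @export
enumerate_configs <- function(equivalence = c("layer_swap", "none", "custom"),
                              predicate = NULL) {
  equivalence <- match.arg(equivalence)
  pairs <- expand.grid(n = 0:4, m = 0:4)[, c("m", "n")]
  labels <- sprintf("A%dA%d", pairs$m, pairs$n)
  if (equivalence == "none") return(labels)
  eq <- if (equivalence == "layer_swap") {
    function(m1, n1, m2, n2) (m1 == m2 && n1 == n2) || (m1 == n2 && n1 == m2)
  } else {
    if (!is.function(predicate)) stop("custom equivalence needs a predicate")
    predicate
  }
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    dup <- FALSE
    for (j in seq_len(i - 1)) {
      if (keep[j] && eq(pairs$m[j], pairs$n[j], pairs$m[i], pairs$n[i])) {
        dup <- TRUE; break
      }
    }
    keep[i] <- !dup
  }
  labels[keep]
}

# covalent radius lookup for the area probe
.atom_radius <- function(element) {
  r <- c(C = kpore_constants$r_cov_C, O = kpore_constants$r_cov_O)
  out <- r[element]
  out[is.na(out)] <- 0.77
  unname(out)
}

#' Effective open cross-sectional area of a pore
#'
#' Grid-samples the pore plane and counts the points whose distance to every
#' pore atom (projected on the plane) exceeds that atom's radius plus
#' `probe_radius`. Atom radii are covalent radii; the default probe of
#' 0.35 A is calibrated so that a carbonyl-functionalized layer yields the
#' ~32 A^2 open area of the twisted-carbonyl channel design.
#'
#' @param model a `pore_layer` or `bilayer_pore` (both layers projected), or
#'   NULL for an empty window.
#' @param probe_radius probe radius in Angstrom (>= 0).
#' @param grid_step grid spacing in Angstrom.
#' @param window either NULL (default: disc around the pore centre bounded by
#'   the candidate-site ring) or `c(xmin, xmax, ymin, ymax)`.
#' @return area in Angstrom^2.
#' @export
effective_pore_area <- function(model, probe_radius = 0.35, grid_step = 0.05,
                                window = NULL) {
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (grid_step <= 0) stop("grid_step must be > 0")
  atoms <- if (is.null(model)) {
    data.frame(element = character(), x = numeric(), y = numeric())
  } else if (inherits(model, "pore_layer")) {
    model$atoms
  } else if (inherits(model, "bilayer_pore")) {
    rbind(model$layer1$atoms, model$layer2$atoms)
  } else stop("model must be a pore_layer, bilayer_pore or NULL")

  if (is.null(window)) {
    if (is.null(model)) stop("an explicit window is required without a model")
    lay <- if (inherits(model, "bilayer_pore")) model$layer1 else model
    rmax <- max(sqrt(rowSums(lay$site_xy^2))) + 1.4
    window <- c(-rmax, rmax, -rmax, rmax)
    disc <- TRUE
  } else disc <- FALSE
  if (diff(window[1:2]) < 2 * grid_step || diff(window[3:4]) < 2 * grid_step)
    stop("resolution error: grid coarser than the pore window")

  # cell-centred sampling so an unobstructed window integrates to its area
  gx <- seq(window[1] + grid_step / 2, window[2], by = grid_step)
  gy <- seq(window[3] + grid_step / 2, window[4], by = grid_step)
  g <- expand.grid(x = gx, y = gy)
  open <- rep(TRUE, nrow(g))
  if (nrow(atoms) > 0) {
    rr <- .atom_radius(atoms$element) + probe_radius
    for (k in seq_len(nrow(atoms))) {
      if (!any(open)) break
      d2 <- (g$x - atoms$x[k])^2 + (g$y - atoms$y[k])^2
      open <- open & d2 > rr[k]^2
    }
  }
  if (disc) {
    rmax2 <- (max(abs(window)))^2
    open <- open & (g$x^2 + g$y^2) < rmax2
  }
  sum(open) * grid_step^2
}
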