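# Tagged-particle trajectory container and multi-frame XYZ IO.
#
# A trajectory stores per-frame coordinates for a small set of tagged atoms
# (ions, water oxygens/hydrogens grouped per molecule) together with the
# box, the two graphene layer planes and a role tag per atom. The pore axis
# is z through (x, y) = (0, 0).

#' Create a trajectory object
#'
#' @param atoms data.frame with columns `id` (integer), `element`, `role`
#'   (one of `"ionK"`, `"ionNa"`, `"waterO"`, `"waterH"`) and `mol` (water
#'   molecule id, NA for ions).
#' @param coords numeric array `n_atoms x 3 x n_frames`, Angstrom.
#' @param timestep_ps frame spacing in ps.
#' @param box `c(Lx, Ly, Lz)` in Angstrom.
#' @param layer_z `c(z1, z2)` positions of the two layer planes.
#' @param periodic logical `c(x, y, z)` periodicity flags.
#' @param times optional frame times (default `0:(n-1) * timestep_ps`).
#' @return object of class `md_trajectory`.
#' @export
md_trajectory <- function(atoms, coords, timestep_ps, box, layer_z,
                          periodic = c(FALSE, FALSE, TRUE), times = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("id", "element", "role", "mol") %in% names(atoms)),
            length(dim(coords)) == 3, dim(coords)[1] == nrow(atoms),
            dim(coords)[2] == 3, timestep_ps > 0,
            length(box) == 3, all(box > 0), length(layer_z) == 2)
  if (diff(layer_z) <= 0) stop("layer planes must satisfy z1 < z2")
  nf <- dim(coords)[3]
  if (is.null(times)) times <- (seq_len(nf) - 1) * timestep_ps
  structure(list(atoms = atoms, coords = coords, timestep_ps = timestep_ps,
                 box = as.numeric(box), layer_z = as.numeric(layer_z),
                 periodic = as.logical(periodic), times = times),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d atoms x %d frames, dt = %g ps, layers z = %.2f/%.2f A\n",
              nrow(x$atoms), dim(x$coords)[3], x$timestep_ps,
              x$layer_z[1], x$layer_z[2]))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3]

#' Write a trajectory as multi-frame XYZ with a metadata sidecar
#'
#' Each XYZ frame carries the frame time on its comment line (`t= <ps>`);
#' the YAML sidecar records timestep, box, periodicity, layer planes and the
#' id -> role map.
#'
#' @param traj an `md_trajectory`.
#' @param xyz_path,meta_path output paths.
#' @export
write_trajectory_xyz <- function(traj, xyz_path, meta_path) {
  n <- nrow(traj$atoms)
  con <- file(xyz_path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(c(as.character(n), sprintf("t= %.6f", traj$times[f]),
                 sprintf("%-2s %12.6f %12.6f %12.6f", traj$atoms$element,
                         traj$coords[, 1, f], traj$coords[, 2, f],
                         traj$coords[, 3, f])), con)
  }
  meta <- list(
    timestep_ps = traj$timestep_ps,
    box = as.list(traj$box),
    periodic = as.list(traj$periodic),
    layer_z1 = traj$layer_z[1], layer_z2 = traj$layer_z[2],
    atoms = lapply(seq_len(n), function(i) list(
      id = traj$atoms$id[i], element = traj$atoms$element[i],
      role = traj$atoms$role[i],
      mol = if (is.na(traj$atoms$mol[i])) NULL else traj$atoms$mol[i]))
  )
  yaml::write_yaml(meta, meta_path)
  invisible(xyz_path)
}

#' Read a multi-frame XYZ trajectory with its metadata sidecar
#'
#' @param xyz_path,meta_path input paths.
#' @return an `md_trajectory`.
#' @export
read_trajectory_xyz <- function(xyz_path, meta_path) {
  meta <- yaml::read_yaml(meta_path)
  lines <- readLines(xyz_path)
  n <- as.integer(lines[1])
  if (is.na(n)) stop("malformed XYZ trajectory")
  frame_len <- n + 2
  nf <- length(lines) %/% frame_len
  coords <- array(NA_real_, c(n, 3, nf))
  times <- numeric(nf)
  for (f in seq_len(nf)) {
    off <- (f - 1) * frame_len
    times[f] <- as.numeric(sub("^t=\\s*", "", lines[off + 2]))
    rec <- strsplit(trimws(lines[(off + 3):(off + n + 2)]), "\\s+")
    coords[, , f] <- cbind(as.numeric(vapply(rec, `[`, "", 2)),
                           as.numeric(vapply(rec, `[`, "", 3)),
                           as.numeric(vapply(rec, `[`, "", 4)))
  }
  atoms <- do.call(rbind, lapply(meta$atoms, function(a)
    data.frame(id = a$id, element = a$element, role = a$role,
               mol = if (is.null(a$mol)) NA_integer_ else a$mol)))
  md_trajectory(atoms, coords, meta$timestep_ps, unlist(meta$box),
                c(meta$layer_z1, meta$layer_z2), unlist(meta$periodic),
                times = times)
}
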