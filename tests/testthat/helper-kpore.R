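# shared fixtures built in code

kB300 <- 0.0019872 * 300

# tiny hand-built trajectory: coordinates supplied as a list of frames,
# each a matrix n_atoms x 3
tiny_traj <- function(frames, atoms, timestep_ps = 1, box = c(30, 30, 30),
                      layer_z = c(0, 3.35), periodic = c(FALSE, FALSE, FALSE)) {
  co <- array(NA_real_, c(nrow(atoms), 3, length(frames)))
  for (f in seq_along(frames)) co[, , f] <- frames[[f]]
  md_trajectory(atoms, co, timestep_ps, box, layer_z, periodic)
}

ion_atoms <- function(n = 1, species = "K") {
  data.frame(id = seq_len(n), element = species,
             role = paste0("ion", species), mol = NA_integer_)
}

# random 3D rotation matrix from a seed
random_rotation <- function() {
  repeat {
    m <- matrix(stats::rnorm(9), 3)
    q <- qr(m)
    R <- qr.Q(q)
    if (det(R) > 0) return(R)
  }
}

# apply a rigid rotation + translation to every frame of a trajectory
transform_traj <- function(traj, R, shift = c(0, 0, 0)) {
  out <- traj
  for (f in seq_len(dim(traj$coords)[3]))
    out$coords[, , f] <- traj$coords[, , f] %*% t(R) +
      matrix(shift, nrow(traj$atoms), 3, byrow = TRUE)
  out
}

# frames belonging to the generator's episodes, concatenated
episode_frames <- function(traj, which_ep = NULL) {
  gt <- attr(traj, "ground_truth")
  if (is.null(which_ep)) which_ep <- seq_len(nrow(gt))
  unlist(lapply(which_ep, function(e) gt$start_frame[e]:gt$end_frame[e]))
}
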