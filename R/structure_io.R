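# Structure export: XYZ and PDB writers for pore models.

model_atoms <- function(model) {
  if (inherits(model, "pore_layer")) {
    cbind(model$atoms, layer = 1L)
  } else if (inherits(model, "bilayer_pore")) {
    rbind(cbind(model$layer1$atoms, layer = 1L),
          cbind(model$layer2$atoms, layer = 2L))
  } else stop("model must be a pore_layer or bilayer_pore")
}

#' Write a pore model to an XYZ or PDB file
#'
#' XYZ files carry `element x y z` records in Angstrom; PDB files use HETATM
#' records with one residue and chain per layer (written through bio3d, so
#' they parse with standard readers).
#'
#' @param model `pore_layer` or `bilayer_pore`.
#' @param path output file path.
#' @param format `"xyz"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("xyz", "pdb")) {
  format <- match.arg(format)
  atoms <- model_atoms(model)
  label <- if (inherits(model, "bilayer_pore")) model$label
           else sprintf("A%d", model$twist_index)
  if (format == "xyz") {
    lines <- c(
      as.character(nrow(atoms)),
      sprintf("%s graphene nanopore model", label),
      sprintf("%-2s %12.6f %12.6f %12.6f",
              atoms$element, atoms$x, atoms$y, atoms$z)
    )
    writeLines(lines, path)
  } else {
    pdb <- bio3d::as.pdb(
      xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
      type = rep("HETATM", nrow(atoms)),
      resno = atoms$layer,
      resid = rep("POR", nrow(atoms)),
      eleno = seq_len(nrow(atoms)),
      elety = atoms$element,
      chain = c("A", "B")[atoms$layer],
      verbose = FALSE
    )
    bio3d::write.pdb(pdb, file = path)
  }
  invisible(path)
}

#' Read a single-frame XYZ file
#'
#' @param path XYZ file path.
#' @return data.frame with columns `element, x, y, z`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  if (is.na(n) || length(lines) < n + 2) stop("malformed XYZ file")
  rec <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  data.frame(
    element = vapply(rec, `[`, "", 1),
    x = as.numeric(vapply(rec, `[`, "", 2)),
    y = as.numeric(vapply(rec, `[`, "", 3)),
    z = as.numeric(vapply(rec, `[`, "", 4))
  )
}
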