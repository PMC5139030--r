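# Programmatic fixtures shared by the tests.

# Minimal PDB text writer so parser tests control their input bytes.
pdbLine <- function(eleno, elety, resid, resno, x, y, z, occ = 1, alt = "") {
  name <- if (nchar(elety) < 4) sprintf(" %-3s", elety) else elety
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          eleno, name, alt, resid, "A", resno, x, y, z, occ, 0)
}

writePdbText <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# Gly-Ala-Gly CA-only toy model text.
gagPdb <- function() {
  writePdbText(c(
    pdbLine(1, "CA", "GLY", 1, 0, 0, 0),
    pdbLine(2, "CA", "ALA", 2, 3.8, 0, 0),
    pdbLine(3, "CA", "GLY", 3, 7.6, 0, 0)))
}

# CA-only ProteinModel from a coordinate matrix.
caModel <- function(coords, id = "m", seqs = NULL) {
  L <- nrow(coords)
  if (is.null(seqs)) seqs <- paste(rep("A", L), collapse = "")
  proteinModel(id, seqs,
               data.frame(resno = seq_len(L), elety = "CA",
                          x = coords[, 1], y = coords[, 2], z = coords[, 3]))
}

randomRotationMatrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Rigidly transformed copy of a model (random rotation + translation).
rigidCopy <- function(model) {
  at <- atomTable(model)
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% randomRotationMatrix()
  xyz <- sweep(xyz, 2, runif(3, -50, 50), "+")
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  proteinModel(modelId(model), modelSequence(model), at, resno = model@resno)
}

# Small noisy decoy of a native built by the simulator.
simDecoy <- function(L, noise, template = "mixed", seed = 1) {
  nat <- generateNative(simConfig(L = L, template = template, seed = seed))
  pool <- generateDecoys(nat, simConfig(L = L, nDecoys = 1,
                                        noiseLevels = noise,
                                        seed = seed + 1000))
  list(native = nat, decoy = poolModels(pool)[[1]], pool = pool)
}
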