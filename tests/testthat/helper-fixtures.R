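# Fixture molecules built in code (no binary fixtures).

# planar benzene: aromatic hexagon of radius 1.39 A centred at `center`
make_benzene <- function(center = c(1, 2, 3)) {
  ang <- (0:5) * pi / 3
  xyz <- cbind(center[1] + 1.39 * cos(ang), center[2] + 1.39 * sin(ang),
               center[3])
  molecule("benzene", rep("C", 6),
           data.frame(a1 = 1:6, a2 = c(2:6, 1), order = 4L),
           list(xyz))
}

# dimethyl ether CH3-O-CH3 (implicit hydrogens)
make_dimethyl_ether <- function() {
  xyz <- rbind(c(-1.2, 0.3, 0), c(0, 0, 0), c(1.2, 0.3, 0))
  molecule("dme", c("C", "O", "C"),
           data.frame(a1 = c(1, 2), a2 = c(2, 3), order = 1L), list(xyz))
}

# trimethylamine N(CH3)3: no N-H, but the aliphatic amine rule protonates it
make_trimethylamine <- function() {
  xyz <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(-0.7, 1.2, 0), c(-0.7, -1.2, 0))
  molecule("tma", c("N", "C", "C", "C"),
           data.frame(a1 = c(1, 1, 1), a2 = c(2, 3, 4), order = 1L),
           list(xyz))
}

# butane chain: one aliphatic hydrophobic patch of 4 carbons
make_butane <- function() {
  xyz <- cbind(seq(0, 4.5, length.out = 4), 0, 0)
  molecule("butane", rep("C", 4),
           data.frame(a1 = 1:3, a2 = 2:4, order = 1L), list(xyz))
}

# apply an atom-order permutation to a molecule (bonds remapped)
permute_molecule <- function(mol, perm) {
  inv <- order(perm)
  molecule(mol$id, mol$atoms[perm, , drop = FALSE],
           data.frame(a1 = inv[mol$bonds$a1], a2 = inv[mol$bonds$a2],
                      order = mol$bonds$order),
           lapply(mol$conformers, function(x) x[perm, , drop = FALSE]),
           mol$properties)
}

# rigidly transform every conformer of a molecule
transform_molecule <- function(mol, rotation, translation) {
  mol$conformers <- lapply(mol$conformers, function(x)
    sweep(x %*% t(rotation), 2, translation, "+"))
  mol
}

rotation_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

# feature data frame from raw kinds + coordinates
make_features <- function(kinds, xyz) {
  data.frame(kind = kinds, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             conformer_index = 1L)
}

# synthetic fingerprint object
make_fp <- function(id, set_bits, n_bits = 64L) {
  bits <- logical(n_bits)
  bits[set_bits] <- TRUE
  structure(list(id = id, bits = bits), class = "fingerprint")
}

# cluster partition as a canonical sorted vector of member-id-set keys
partition_sets <- function(assignment) {
  unname(sort(vapply(split(names(assignment$labels), assignment$labels),
                     function(m) paste(sort(m), collapse = ","), "")))
}
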