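# Toy molecules built in code, used across the suite.

benzene <- function() {
  ang <- (0:5) * pi / 3
  atoms <- tibble::tibble(
    element = c(rep("C", 6), rep("H", 6)),
    x = c(1.396 * cos(ang), 2.483 * cos(ang)),
    y = c(1.396 * sin(ang), 2.483 * sin(ang)),
    z = 0)
  bonds <- tibble::tibble(
    a1 = c(1:6, 1:6),
    a2 = c(2:6, 1, 7:12),
    order = c(rep(c(2L, 1L), 3), rep(1L, 6)))
  molecule("benzene", atoms, bonds)
}

methane <- function() {
  molecule("methane",
           atoms = tibble::tibble(
             element = c("C", "H", "H", "H", "H"),
             x = c(0, .63, -.63, -.63, .63),
             y = c(0, .63, -.63, .63, -.63),
             z = c(0, .63, .63, -.63, -.63)),
           bonds = tibble::tibble(a1 = 1L, a2 = 2:5, order = 1L))
}

acetate <- function() {
  molecule("acetate",
           atoms = tibble::tibble(
             element = c("C", "C", "O", "O", "H", "H", "H"),
             x = c(0, 1.52, 2.15, 2.15, -.5, -.5, -.5),
             y = c(0, 0, 1.08, -1.08, .95, -.47, -.47),
             z = c(0, 0, 0, 0, 0, .82, -.82),
             charge = c(0L, 0L, 0L, -1L, 0L, 0L, 0L)),
           bonds = tibble::tibble(a1 = c(1, 2, 2, 1, 1, 1),
                                  a2 = c(2, 3, 4, 5, 6, 7),
                                  order = c(1L, 2L, 1L, 1L, 1L, 1L)))
}

# bare carbon chains for shape toys (bonded so they can carry a hydrophobe
# feature)
carbon_toy <- function(xyz, name = "toy") {
  xyz <- rbind(xyz)
  n <- nrow(xyz)
  bonds <- if (n > 1)
    tibble::tibble(a1 = seq_len(n - 1), a2 = 2:n, order = 1L)
  else NULL
  molecule(name,
           tibble::tibble(element = "C", x = xyz[, 1], y = xyz[, 2],
                          z = xyz[, 3]),
           bonds)
}

move_molecule <- function(mol, tf) {
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  xyz <- apply_transform(xyz, tf)
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}

random_rigid <- function(seed) {
  set.seed(seed)
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  rigid_transform(R, runif(3, -4, 4))
}
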