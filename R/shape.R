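#' Gaussian shape overlap and Tanimoto scoring
#'
#' Shape similarity follows the first-order Gaussian sphere model: each heavy
#' atom is a spherical Gaussian `p * exp(-alpha * r^2)` whose amplitude
#' `p = 2.7` and width `alpha` are chosen so the Gaussian integrates to the
#' atom's van der Waals sphere volume. By default all heavy atoms share one
#' radius of 1.70 Angstrom ("radii off" mode); per-element radii can be
#' enabled. The overlap volume of two molecules is the sum of pairwise
#' Gaussian product integrals, and the shape Tanimoto is
#' `V_AB / (V_AA + V_BB - V_AB)`.
#'
#' @name shape-scoring
NULL

.GAUSS_P <- 2.7
.SHARED_RADIUS <- 1.70
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92,
                Si = 2.10, Se = 1.90)

gauss_alpha <- function(radius, p = .GAUSS_P) {
  pi * (3 * p / (4 * pi * radius^3))^(2 / 3)
}

# Sum of pairwise Gaussian product integrals between two point sets with
# per-point alphas and amplitude p. Contributions below 1e-12 of the peak
# pair term are dropped (documented truncation).
gauss_overlap_sum <- function(xyzA, xyzB, alphaA, alphaB, p = .GAUSS_P) {
  if (nrow(xyzA) == 0 || nrow(xyzB) == 0) return(0)
  d2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), "+") -
    2 * xyzA %*% t(xyzB)
  d2[d2 < 0] <- 0
  asum <- outer(alphaA, alphaB, "+")
  aprod <- outer(alphaA, alphaB, "*")
  expo <- exp(-aprod / asum * d2)
  expo[expo < 1e-12] <- 0
  sum(p * p * (pi / asum)^1.5 * expo)
}

mol_gauss <- function(mol, radii = NULL) {
  xyz <- atom_coords(mol, heavy = TRUE)
  if (nrow(xyz) == 0) abort("molecule has no heavy atoms")
  el <- mol$atoms$element[mol$atoms$element != "H"]
  r <- if (is.null(radii)) rep(.SHARED_RADIUS, nrow(xyz)) else {
    rr <- radii[el]
    rr[is.na(rr)] <- .SHARED_RADIUS
    rr
  }
  list(xyz = xyz, alpha = gauss_alpha(r))
}

#' Gaussian overlap volume of two molecules
#'
#' @param a,b `lf_molecule` objects; hydrogens are excluded from shape.
#' @param transform `lf_transform` applied to `b` before the overlap.
#' @param radii Optional named per-element vdW radii (Angstrom); default is a
#'   single shared 1.70 Angstrom radius for all heavy atoms.
#' @return Overlap volume in cubic Angstrom.
#' @export
gaussian_overlap_volume <- function(a, b, transform = rigid_transform(),
                                    radii = NULL) {
  ga <- mol_gauss(a, radii)
  gb <- mol_gauss(b, radii)
  gauss_overlap_sum(ga$xyz, apply_transform(gb$xyz, transform),
                    ga$alpha, gb$alpha)
}

#' Shape Tanimoto of two molecules
#'
#' `V_AB / (V_AA + V_BB - V_AB)`, in (0, 1]; equals 1 for identical,
#' aligned shapes.
#'
#' @inheritParams gaussian_overlap_volume
#' @return Unitless shape Tanimoto.
#' @export
shape_tanimoto <- function(a, b, transform = rigid_transform(),
                           radii = NULL) {
  ga <- mol_gauss(a, radii)
  gb <- mol_gauss(b, radii)
  xyzB <- apply_transform(gb$xyz, transform)
  vab <- gauss_overlap_sum(ga$xyz, xyzB, ga$alpha, gb$alpha)
  vaa <- gauss_overlap_sum(ga$xyz, ga$xyz, ga$alpha, ga$alpha)
  vbb <- gauss_overlap_sum(xyzB, xyzB, gb$alpha, gb$alpha)
  vab / (vaa + vbb - vab)
}

feat_gauss <- function(feats) {
  list(xyz = as.matrix(feats[, c("x", "y", "z")]),
       alpha = gauss_alpha(feats$radius),
       kind = feats$kind)
}

#' Pharmacophore color Tanimoto of two feature sets
#'
#' Gaussian-overlap Tanimoto computed only between features of the same
#' kind; in `[0, 1]`. By convention it is 0 when either feature set is empty
#' (so a featureless molecule's self-similarity is 1, not 2).
#'
#' @param featsA,featsB Feature tibbles from [assign_features()].
#' @param transform `lf_transform` applied to `featsB`.
#' @return Unitless color Tanimoto.
#' @export
color_tanimoto <- function(featsA, featsB, transform = rigid_transform()) {
  if (nrow(featsA) == 0 || nrow(featsB) == 0) return(0)
  ga <- feat_gauss(featsA)
  gb <- feat_gauss(featsB)
  gb$xyz <- apply_transform(gb$xyz, transform)
  kinds <- union(ga$kind, gb$kind)
  vab <- vaa <- vbb <- 0
  for (k in kinds) {
    ia <- ga$kind == k; ib <- gb$kind == k
    if (any(ia) && any(ib))
      vab <- vab + gauss_overlap_sum(ga$xyz[ia, , drop = FALSE],
                                     gb$xyz[ib, , drop = FALSE],
                                     ga$alpha[ia], gb$alpha[ib])
    if (any(ia))
      vaa <- vaa + gauss_overlap_sum(ga$xyz[ia, , drop = FALSE],
                                     ga$xyz[ia, , drop = FALSE],
                                     ga$alpha[ia], ga$alpha[ia])
    if (any(ib))
      vbb <- vbb + gauss_overlap_sum(gb$xyz[ib, , drop = FALSE],
                                     gb$xyz[ib, , drop = FALSE],
                                     gb$alpha[ib], gb$alpha[ib])
  }
  if (vaa + vbb - vab <= 0) return(0)
  vab / (vaa + vbb - vab)
}

# combo score of a posed query vs reference (shape + color)
combo_score <- function(query, ref, featsQ, featsR, transform,
                        radii = NULL) {
  st <- shape_tanimoto(ref, query, transform, radii)
  ct <- color_tanimoto(featsR, featsQ, transform)
  c(shape = st, color = ct, combo = st + ct)
}
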