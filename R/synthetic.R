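#' Seeded synthetic-data generators
#'
#' Each generator emulates the statistical structure one pipeline stage
#' assumes (dose-response plates, MST serial dilutions, melting scans, pH
#' titrations, diffusion trajectories, PMF profiles, calibration sets), is
#' byte-deterministic under a fixed seed, and records its planted truths in
#' a `manifest` attribute so recovery tests read truths only from there.
#'
#' @name synthetic-data
NULL

manifest <- function(x) attr(x, "manifest")

#' Write a generator manifest as JSON
#' @param x A generated object carrying a `manifest` attribute.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  jsonlite::write_json(attr(x, "manifest"), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Toy screening template molecule
#'
#' A synthetic benzodioxole-carboxylate toy compound built from idealized
#' geometry: a benzene ring fused to a methylenedioxy five-ring, with a
#' two-carbon arm ending in a carboxylate. It carries ring, hydrophobe,
#' acceptor and anion features and serves as the screening template in
#' examples and synthetic libraries. It is a geometric stand-in, not any
#' published structure.
#'
#' @return An `lf_molecule`.
#' @export
toy_template <- function() {
  # benzene ring in the xy-plane
  ang <- (0:5) * pi / 3
  ring <- cbind(1.396 * cos(ang), 1.396 * sin(ang), 0)
  # methylenedioxy five-ring fused on the C1-C2 edge (regular pentagon)
  p1 <- ring[1, ]; p2 <- ring[2, ]
  mid <- (p1 + p2) / 2
  v <- mid / sqrt(sum(mid^2))
  s <- sqrt(sum((p2 - p1)^2))
  Rp <- s / (2 * sin(pi / 5))
  ctr <- mid + v * Rp * cos(pi / 5)
  u <- (p2 - p1) / s
  base_ang <- atan2(sum((p1 - ctr) * v), sum((p1 - ctr) * u))
  pent <- t(vapply(0:4, function(k) {
    a <- base_ang - 2 * pi * k / 5
    ctr + Rp * (cos(a) * u + sin(a) * v)
  }, numeric(3)))
  o1 <- pent[5, ]; ch2 <- pent[4, ]; o2 <- pent[3, ]
  # carboxylate arm on C4 (para edge), pointing away from the dioxole
  c4 <- ring[4, ]
  w <- c4 / sqrt(sum(c4^2))
  c7 <- c4 + 1.50 * w
  c8 <- c7 + 1.52 * w
  perp <- c(-w[2], w[1], 0)
  o3 <- c8 + 1.26 * (cos(pi / 3) * w + sin(pi / 3) * perp)
  o4 <- c8 + 1.26 * (cos(pi / 3) * w - sin(pi / 3) * perp)
  hpos <- function(cidx, scale = 1.09) {
    ring[cidx, ] * (1 + scale / 1.396)
  }
  atoms <- tibble(
    element = c(rep("C", 6), "O", "C", "O", "C", "C", "O", "O",
                "H", "H", "H", "H", "H", "H", "H"),
    x = c(ring[, 1], o1[1], ch2[1], o2[1], c7[1], c8[1], o3[1], o4[1],
          hpos(3)[1], hpos(5)[1], hpos(6)[1], ch2[1], ch2[1],
          c7[1] + 0.5, c7[1] - 0.5),
    y = c(ring[, 2], o1[2], ch2[2], o2[2], c7[2], c8[2], o3[2], o4[2],
          hpos(3)[2], hpos(5)[2], hpos(6)[2], ch2[2], ch2[2],
          c7[2], c7[2]),
    z = c(rep(0, 13), 0, 0, 0, 0.9, -0.9, 0.89, 0.89),
    charge = c(rep(0L, 12), -1L, rep(0L, 7)))
  bonds <- tibble(
    a1 = c(1, 2, 3, 4, 5, 6, 1, 7, 8, 2, 4, 10, 11, 11, 3, 5, 6, 8, 8,
           10, 10),
    a2 = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 9, 10, 11, 12, 13, 14, 15, 16, 17,
           18, 19, 20),
    order = c(2, 1, 2, 1, 2, 1, 1, 1, 1, 1, 1, 1, 2, 1, 1, 1, 1, 1, 1,
              1, 1))
  molecule("toy_template", atoms, bonds)
}

#' Generate a synthetic screening library
#'
#' Builds `n` perturbed copies of a template: seeded coordinate jitter with
#' per-member noise magnitude cycling through `noise_levels`, plus a random
#' rigid motion per member (which overlay optimization must undo). Optional
#' decoys are random apolar atom clouds with no template resemblance.
#' Expected Tanimoto-Combo against the template decreases with noise;
#' members at noise 0 score an exact 2.
#'
#' @param template An `lf_molecule`.
#' @param n Number of perturbed members (>= 1).
#' @param noise_levels Coordinate jitter SDs in Angstrom, recycled over
#'   members.
#' @param n_decoys Number of decoy molecules appended (default 0).
#' @param seed RNG seed.
#' @return List of `lf_molecule` with a `manifest` attribute recording each
#'   member's perturbation magnitude.
#' @export
gen_molecule_library <- function(template, n, noise_levels = c(0, 0.1, 0.3),
                                 n_decoys = 0, seed = 1) {
  if (n < 1) abort("`n` must be >= 1")
  with_seed(seed, {
    levels <- rep_len(noise_levels, n)
    mols <- vector("list", n + n_decoys)
    man <- list()
    for (i in seq_len(n)) {
      m <- template
      m$name <- sprintf("analog_%03d", i)
      xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, levels[i]),
                          ncol = 3)
      tf <- rigid_transform(random_rotation(),
                            stats::runif(3, -5, 5))
      xyz <- apply_transform(xyz, tf)
      m$atoms$x <- xyz[, 1]; m$atoms$y <- xyz[, 2]; m$atoms$z <- xyz[, 3]
      mols[[i]] <- m
      man[[m$name]] <- list(noise = levels[i], decoy = FALSE)
    }
    for (j in seq_len(n_decoys)) {
      nm <- sprintf("decoy_%03d", j)
      k <- sample(6:12, 1)
      atoms <- tibble(element = "C",
                      x = stats::rnorm(k, 0, 2), y = stats::rnorm(k, 0, 2),
                      z = stats::rnorm(k, 0, 2), charge = 0L)
      bonds <- tibble(a1 = seq_len(k - 1), a2 = 2:k, order = 1L)
      mols[[n + j]] <- molecule(nm, atoms, bonds)
      man[[nm]] <- list(noise = NA, decoy = TRUE)
    }
    attr(mols, "manifest") <- list(seed = seed, template = template$name,
                                   members = man)
    mols
  })
}

#' Generate a synthetic dose-response plate
#'
#' Four-parameter logistic viability curve plus Gaussian noise. The default
#' design is the screening plate layout: 8 log-spaced concentrations on
#' [1, 450] uM in triplicate.
#'
#' @param ic50,hill,top,bottom Planted 4PL parameters (ic50 in uM).
#' @param concentrations Concentration grid in uM.
#' @param replicates Number of replicates.
#' @param noise_sd Gaussian noise SD on the response fraction.
#' @param seed RNG seed.
#' @return A `titration_series` with a `manifest` attribute.
#' @export
gen_dose_response <- function(ic50 = 33, hill = 1.2, top = 1,
                              bottom = 0.05,
                              concentrations = 10^seq(log10(1), log10(450),
                                                      length.out = 8),
                              replicates = 3, noise_sd = 0.03, seed = 1) {
  stopifnot(all(concentrations > 0))
  with_seed(seed, {
    mu <- bottom + (top - bottom) / (1 + (concentrations / ic50)^hill)
    y <- matrix(rep(mu, replicates), ncol = replicates) +
      matrix(stats::rnorm(length(mu) * replicates, 0, noise_sd),
             ncol = replicates)
    s <- titration_series(concentrations, y, assay = "dose_response",
                          units = list(x = "uM", y = "fraction"))
    attr(s, "manifest") <- list(kind = "dose_response", ic50 = ic50,
                                hill = hill, top = top, bottom = bottom,
                                noise_sd = noise_sd, seed = seed)
    s
  })
}

#' Generate a synthetic MST titration
#'
#' Exact quadratic 1:1 isotherm sampled on a 1:1 serial dilution (default
#' 16 points from 1 mM) with a fixed labeled-target concentration (default
#' 100 nM), plus Gaussian noise on Fnorm.
#'
#' @param kd Planted dissociation constant in uM.
#' @param target_conc_nM Labeled target concentration in nM.
#' @param top_conc Highest ligand concentration in uM (default 1000 = 1 mM).
#' @param n_points Number of 1:1 dilution points (default 16).
#' @param f_free,f_bound Fnorm plateaus.
#' @param noise_sd Gaussian noise SD in Fnorm units.
#' @param replicates Measured replicates per dilution (default 3,
#'   triplicates of the same dilution series).
#' @param seed RNG seed.
#' @return A `titration_series` with a `manifest` attribute.
#' @export
gen_mst_titration <- function(kd = 39, target_conc_nM = 100,
                              top_conc = 1000, n_points = 16,
                              f_free = 0, f_bound = 10, noise_sd = 0.2,
                              replicates = 3, seed = 1) {
  if (n_points < 8) abort("`n_points` must be >= 8")
  with_seed(seed, {
    L <- top_conc / 2^(seq_len(n_points) - 1)
    fb <- bound_fraction(L, target_conc_nM / 1000, kd)
    mu <- f_free + (f_bound - f_free) * fb
    y <- matrix(rep(mu, replicates), ncol = replicates) +
      matrix(stats::rnorm(n_points * replicates, 0, noise_sd),
             ncol = replicates)
    s <- titration_series(L, y, assay = "mst",
                          units = list(x = "uM", y = "Fnorm"))
    attr(s, "manifest") <- list(kind = "mst", kd = kd,
                                target_conc_nM = target_conc_nM,
                                top_conc = top_conc, f_free = f_free,
                                f_bound = f_bound, noise_sd = noise_sd,
                                replicates = replicates, seed = seed)
    s
  })
}

#' Generate a synthetic nanoDSF melting scan
#'
#' Two-state melting transition in the F350/F330 ratio with linear channel
#' baselines and multiplicative channel noise. Default ramp 20-95 degC.
#'
#' @param tm Planted midpoint in degC.
#' @param width Transition width in degC (10-90% over ~4.4 widths).
#' @param t_range Temperature range, length 2.
#' @param step Ramp step in degC.
#' @param ratio_lo,ratio_hi Pre-/post-transition ratio levels.
#' @param baseline_slope Linear baseline slope per channel (ratio units per
#'   degC).
#' @param noise_frac Multiplicative noise SD (fraction of signal).
#' @param seed RNG seed.
#' @return Tibble with columns `temperature`, `f330`, `f350` and a
#'   `manifest` attribute.
#' @export
gen_melting_curve <- function(tm = 74.5, width = 2, t_range = c(20, 95),
                              step = 0.5, ratio_lo = 0.8, ratio_hi = 1.0,
                              baseline_slope = 5e-4, noise_frac = 0.005,
                              seed = 1) {
  with_seed(seed, {
    temp <- seq(t_range[1], t_range[2], by = step)
    frac <- 1 / (1 + exp(-(temp - tm) / width))
    ratio <- ratio_lo + (ratio_hi - ratio_lo) * frac +
      baseline_slope * (temp - t_range[1])
    f330 <- 20000 * (1 - 0.002 * (temp - t_range[1]))
    f350 <- ratio * f330
    f330 <- f330 * (1 + stats::rnorm(length(temp), 0, noise_frac))
    f350 <- f350 * (1 + stats::rnorm(length(temp), 0, noise_frac))
    out <- tibble(temperature = temp, f330 = f330, f350 = f350)
    attr(out, "manifest") <- list(kind = "melting_curve", tm = tm,
                                  width = width, ratio_lo = ratio_lo,
                                  ratio_hi = ratio_hi,
                                  baseline_slope = baseline_slope,
                                  noise_frac = noise_frac, seed = seed)
    out
  })
}

#' Generate a synthetic pH titration of a reporter proton
#'
#' Henderson-Hasselbalch chemical-shift curve on a pH grid (default 2-13 in
#' 0.5 steps) plus Gaussian noise.
#'
#' @param pka Planted pKa.
#' @param delta_acid,delta_base Shift limits in ppm.
#' @param ph_grid pH values.
#' @param noise_sd Gaussian noise SD in ppm.
#' @param seed RNG seed.
#' @return A `titration_series` with a `manifest` attribute.
#' @export
gen_ph_titration <- function(pka = 6.69, delta_acid = 1.20,
                             delta_base = 0.95,
                             ph_grid = seq(2, 13, by = 0.5),
                             noise_sd = 0.005, seed = 1) {
  with_seed(seed, {
    mu <- delta_base + (delta_acid - delta_base) /
      (1 + 10^(ph_grid - pka))
    y <- mu + stats::rnorm(length(ph_grid), 0, noise_sd)
    s <- titration_series(ph_grid, y, assay = "ph_titration",
                          units = list(x = "pH", y = "ppm"))
    attr(s, "manifest") <- list(kind = "ph_titration", pka = pka,
                                delta_acid = delta_acid,
                                delta_base = delta_base,
                                noise_sd = noise_sd, seed = seed)
    s
  })
}

#' Generate synthetic STD intensity records
#'
#' Per-proton on-/off-resonance intensity pairs with planted effects.
#'
#' @param effects Named numeric vector of planted `i_sat/i_0` effects.
#' @param i0 Off-resonance intensity scale.
#' @param noise_frac Multiplicative noise on intensities.
#' @param seed RNG seed.
#' @return Tibble with columns `label`, `i_sat`, `i_0` and a `manifest`
#'   attribute.
#' @export
gen_std_intensities <- function(effects = c(H1 = 0.41, H2 = 0.66,
                                            H3 = 0.91),
                                i0 = 1000, noise_frac = 0, seed = 1) {
  with_seed(seed, {
    n <- length(effects)
    i_0 <- i0 * (1 + stats::rnorm(n, 0, noise_frac))
    i_sat <- unname(effects) * i_0 * (1 + stats::rnorm(n, 0, noise_frac))
    out <- tibble(label = names(effects), i_sat = unname(i_sat),
                  i_0 = unname(i_0))
    attr(out, "manifest") <- list(kind = "std", effects = as.list(effects),
                                  seed = seed)
    out
  })
}

#' Parametric mock helical bundle
#'
#' A four-helix bundle (CA plus a pseudo side-chain CB per residue) with
#' exact 2-fold symmetry about the bundle (z) axis: chains C and D are the
#' 180-degree images of chains A and B. Adequate for contact geometry; no
#' physical realism intended.
#'
#' @param n_res Residues per helix (default 17).
#' @param helix_dist Helix axis distance from the bundle axis (Angstrom).
#' @return Tibble with columns `chain`, `resid`, `resname`, `name`,
#'   `element`, `x`, `y`, `z`.
#' @export
make_mock_bundle <- function(n_res = 17, helix_dist = 8) {
  helix <- function(phase) {
    i <- seq_len(n_res)
    ca_r <- 2.3
    a <- (i - 1) * 100 * pi / 180 + phase
    tibble(resid = i,
           ca = cbind(ca_r * cos(a), ca_r * sin(a), (i - 1) * 1.5),
           cb = cbind(3.9 * cos(a), 3.9 * sin(a), (i - 1) * 1.5))
  }
  place <- function(df, cx, cy, chain) {
    purrr::map_dfr(seq_len(nrow(df)), function(k) {
      tibble(chain = chain, resid = df$resid[k], resname = "ALA",
             name = c("CA", "CB"), element = "C",
             x = c(df$ca[k, 1], df$cb[k, 1]) + cx,
             y = c(df$ca[k, 2], df$cb[k, 2]) + cy,
             z = c(df$ca[k, 3], df$cb[k, 3]))
    })
  }
  h <- helix(0)
  ab <- dplyr::bind_rows(place(h, helix_dist, 0, "A"),
                         place(helix(pi / 2), 0, helix_dist, "B"))
  cd <- ab |>
    dplyr::mutate(chain = dplyr::recode(.data$chain, A = "C", B = "D"),
                  x = -.data$x, y = -.data$y)
  dplyr::bind_rows(ab, cd)
}

#' Generate a synthetic free-ligand-diffusion trajectory
#'
#' Places a rigid 5-atom ligand so that it contacts each planted epitope's
#' residue set (< 4 Angstrom to >= 5 distinct residues) in exactly
#' `round(fraction * n_frames)` frames; remaining frames are unbound (the
#' ligand floats far from the protein). Bound frames are assigned by a
#' seeded shuffle. The protein is the 2-fold symmetric mock bundle.
#'
#' @param n_frames Number of frames.
#' @param epitope_specs List of `list(residues = c("A:5", ...),
#'   fraction = 0.132)`; residue sets must be disjoint and have >= 5
#'   members; fractions must sum to <= 1.
#' @param bundle Protein atom tibble (default [make_mock_bundle()]).
#' @param jitter Coordinate jitter SD (Angstrom) on bound ligand poses.
#' @param seed RNG seed.
#' @return An `lf_trajectory` with a `manifest` attribute (planted epitope
#'   sets, per-epitope frame indices and counts).
#' @export
gen_trajectory <- function(n_frames = 1000,
                           epitope_specs = list(
                             list(residues = paste0("A:", 5:10),
                                  fraction = 0.132),
                             list(residues = paste0("B:", 8:13),
                                  fraction = 0.101)),
                           bundle = make_mock_bundle(), jitter = 0.15,
                           seed = 1) {
  fracs <- vapply(epitope_specs, `[[`, numeric(1), "fraction")
  if (sum(fracs) > 1) abort("epitope fractions must sum to <= 1")
  sets <- lapply(epitope_specs, `[[`, "residues")
  if (any(lengths(sets) < 5))
    abort("each epitope residue set needs >= 5 residues")
  for (i in seq_along(sets)) {
    for (j in seq_len(i - 1)) {
      if (length(intersect(sets[[i]], sets[[j]])) > 0)
        abort("epitope residue sets must be disjoint")
    }
  }
  prot_key <- paste0(bundle$chain, ":", bundle$resid)
  missing <- setdiff(unlist(sets), prot_key)
  if (length(missing) > 0)
    abort(paste0("epitope residues absent from protein: ",
                 paste(missing, collapse = ", ")))
  n_lig <- 5
  with_seed(seed, {
    counts <- round(fracs * n_frames)
    labels <- rep(0L, n_frames) # 0 = unbound
    pool <- sample.int(n_frames)
    off <- 0
    for (e in seq_along(counts)) {
      labels[pool[off + seq_len(counts[e])]] <- e
      off <- off + counts[e]
    }
    atoms <- dplyr::bind_rows(
      dplyr::mutate(bundle[, c("chain", "resid", "resname", "name",
                               "element")], is_ligand = FALSE),
      tibble(chain = "L", resid = 1, resname = "LIG",
             name = paste0("C", seq_len(n_lig)), element = "C",
             is_ligand = TRUE))
    nat <- nrow(atoms)
    coords <- array(NA_real_, c(n_frames, nat, 3))
    prot_xyz <- as.matrix(bundle[, c("x", "y", "z")])
    nprot <- nrow(prot_xyz)
    center <- colMeans(prot_xyz)
    for (f in seq_len(n_frames)) {
      coords[f, seq_len(nprot), ] <- prot_xyz
      e <- labels[f]
      if (e == 0) {
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        pos <- center + dir * 40
        lig <- sweep(matrix(stats::rnorm(n_lig * 3, 0, 1), ncol = 3), 2,
                     pos, "+")
      } else {
        res <- sets[[e]][seq_len(n_lig)]
        anchor <- t(vapply(res, function(r) {
          sel <- prot_key == r & bundle$name == "CB"
          if (!any(sel)) sel <- prot_key == r
          colMeans(prot_xyz[sel, , drop = FALSE])
        }, numeric(3)))
        pull <- sweep(-anchor, 2, center, "+") # toward protein center
        pull <- pull / sqrt(rowSums(pull^2))
        lig <- anchor + 1.2 * pull +
          matrix(stats::rnorm(n_lig * 3, 0, jitter), ncol = 3)
      }
      coords[f, nprot + seq_len(n_lig), ] <- lig
    }
    traj <- lf_trajectory(atoms, coords)
    attr(traj, "manifest") <- list(
      kind = "trajectory", n_frames = n_frames, seed = seed,
      epitopes = purrr::imap(epitope_specs, function(sp, i)
        list(residues = sp$residues, fraction = sp$fraction,
             n_bound = counts[[i]],
             frames = which(labels == i))))
    traj
  })
}

#' Generate a parametric PMF profile
#'
#' Sum of a Gaussian barrier at the bilayer center and symmetric Gaussian
#' interfacial wells, pinned to zero in the water phase.
#'
#' @param barrier_height Barrier at z = 0 in kcal/mol (>= 0: barrier;
#'   negative: central well).
#' @param well_depth Depth of the interfacial wells in kcal/mol (>= 0).
#' @param barrier_width,well_width Gaussian widths in Angstrom.
#' @param well_pos Well center distance from the bilayer center.
#' @param z_range Symmetric z range (Angstrom), length 2.
#' @param step Grid spacing in Angstrom.
#' @param temperature Temperature in K.
#' @return An `lf_pmf` with a `manifest` attribute.
#' @export
gen_pmf_profile <- function(barrier_height = 5, well_depth = 1,
                            barrier_width = 6, well_width = 4,
                            well_pos = 15, z_range = c(-40, 40),
                            step = 0.5, temperature = 300) {
  z <- seq(z_range[1], z_range[2], by = step)
  dG <- barrier_height * exp(-z^2 / (2 * barrier_width^2)) -
    well_depth * (exp(-(z - well_pos)^2 / (2 * well_width^2)) +
                    exp(-(z + well_pos)^2 / (2 * well_width^2)))
  # pin the water phase exactly to zero via the end values
  dG <- dG - mean(dG[c(1, length(dG))])
  dG[abs(dG) < 1e-3] <- 0
  out <- pmf_profile(z, dG, temperature)
  attr(out, "manifest") <- list(kind = "pmf_profile",
                                barrier_height = barrier_height,
                                well_depth = well_depth,
                                barrier_width = barrier_width,
                                well_width = well_width,
                                well_pos = well_pos)
  out
}

#' Generate a synthetic calibration set
#'
#' Reference pairs on a planted line `y = slope * x + intercept` plus
#' Gaussian scatter; default 9 reference compounds.
#'
#' @param true_slope,true_intercept Planted line.
#' @param n Number of reference pairs (default 9).
#' @param x_range Range of `log_peff_pmf` values.
#' @param scatter_sd Gaussian scatter SD in log10 units.
#' @param seed RNG seed.
#' @return Tibble with columns `compound`, `log_peff_pmf`,
#'   `log_peff_pampa` and a `manifest` attribute.
#' @export
gen_calibration_set <- function(true_slope = 0.27, true_intercept = -5.3,
                                n = 9, x_range = c(-5, 1),
                                scatter_sd = 0.05, seed = 1) {
  with_seed(seed, {
    x <- seq(x_range[1], x_range[2], length.out = n)
    y <- true_intercept + true_slope * x +
      stats::rnorm(n, 0, scatter_sd)
    out <- tibble(compound = sprintf("ref_%02d", seq_len(n)),
                  log_peff_pmf = x, log_peff_pampa = y)
    attr(out, "manifest") <- list(kind = "calibration_set",
                                  true_slope = true_slope,
                                  true_intercept = true_intercept,
                                  scatter_sd = scatter_sd, seed = seed)
    out
  })
}

#' Write a PMF profile to CSV (columns z_angstrom, dG_kcal_mol)
#' @param profile An `lf_pmf`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pmf_csv <- function(profile, path) {
  readr::write_csv(tibble(z_angstrom = profile$z,
                          dG_kcal_mol = profile$dG), path)
  invisible(path)
}
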