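#' Default pharmacophore feature-typing rules
#'
#' Loads the ruleset shipped with the package (a YAML file under
#' `inst/extdata/feature_rules.yaml`). Rules are data: copy the file, edit
#' it, and pass the edited version to [assign_features()].
#'
#' @param path Optional path to an alternative YAML ruleset.
#' @return A named list of rules.
#' @export
default_feature_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "feature_rules.yaml",
                                package = "ligandflow")
  yaml::read_yaml(path)
}

#' Assign pharmacophore features to a molecule
#'
#' Types the six standard color features (donor, acceptor, anion, cation,
#' hydrophobe, ring) on an explicit-hydrogen structure with connectivity.
#' Ring features sit at ring centroids (smallest set of smallest rings),
#' hydrophobes at centroids of connected apolar-carbon clusters, charged
#' features at charged-group centroids. The assignment is deterministic and
#' invariant to atom reordering.
#'
#' @param mol An `lf_molecule` with a non-empty bond list (feature perception
#'   needs connectivity; read SDF, not XYZ).
#' @param rules Ruleset, see [default_feature_rules()].
#' @return A tibble with columns `kind`, `x`, `y`, `z`, `radius`, one row
#'   per feature, ordered by kind then coordinates.
#' @export
assign_features <- function(mol, rules = default_feature_rules()) {
  stopifnot(inherits(mol, "lf_molecule"))
  if (nrow(mol$bonds) == 0)
    abort(paste0("molecule '", mol$name, "' has no bonds; feature ",
                 "perception needs connectivity - supply SDF/MOL input"))
  a <- mol$atoms
  n <- nrow(a)
  if (!any(a$element == "H") && any(a$element %in% c("N", "O")))
    warn("no explicit hydrogens found; donor features may be missed")
  nbrs <- neighbor_list(mol)
  el <- a$element
  radius <- rules$radii$default %||% 1.0

  feats <- list()
  add <- function(kind, centroid) {
    feats[[length(feats) + 1]] <<- tibble(
      kind = kind, x = centroid[1], y = centroid[2], z = centroid[3],
      radius = radius)
  }
  coords <- as.matrix(a[, c("x", "y", "z")])
  at <- function(i) colMeans(coords[i, , drop = FALSE])

  h_count <- vapply(seq_len(n), function(i) sum(el[nbrs[[i]]] == "H"),
                    integer(1))
  heavy_nbrs <- lapply(seq_len(n), function(i) {
    nb <- nbrs[[i]]
    nb[el[nb] != "H"]
  })

  # --- anion: formally negative atoms, grouped over equivalent O/S on the
  # same central atom (carboxylate -> one feature at the COO centroid);
  # optionally neutral COOH
  anion_atoms <- which(a$charge < 0)
  if (isTRUE(rules$anion$include_carboxylic_acid)) {
    cooh_o <- which(el == "O" & a$charge == 0 & h_count > 0 &
                      vapply(seq_len(n), function(i) {
                        hn <- heavy_nbrs[[i]]
                        length(hn) == 1 && el[hn] == "C" &&
                          has_carbonyl(hn, mol, nbrs)
                      }, logical(1)))
    anion_atoms <- union(anion_atoms, cooh_o)
  }
  for (grp in charged_groups(anion_atoms, mol, heavy_nbrs)) {
    add("anion", at(grp))
  }

  # --- cation: formally positive atoms; optionally neutral aliphatic amines
  cation_atoms <- which(a$charge > 0)
  if (isTRUE(rules$cation$include_aliphatic_amine)) {
    amine_n <- which(el == "N" & a$charge == 0 & h_count >= 2 &
                       vapply(seq_len(n), function(i) {
                         hn <- heavy_nbrs[[i]]
                         length(hn) >= 1 && all(el[hn] == "C") &&
                           all(bond_orders_of(i, mol) == 1)
                       }, logical(1)))
    cation_atoms <- union(cation_atoms, amine_n)
  }
  for (grp in charged_groups(cation_atoms, mol, heavy_nbrs)) {
    add("cation", at(grp))
  }

  # --- donor: N/O with explicit H (charged anion oxygens excluded)
  donors <- which(el %in% (rules$donor$elements %||% c("N", "O")) &
                    h_count > 0 & a$charge >= 0)
  for (i in donors) add("donor", coords[i, ])

  # --- acceptor: N/O with a lone pair (charge <= 0); positively charged
  # excluded
  acceptors <- which(el %in% (rules$acceptor$elements %||% c("N", "O")) &
                       a$charge <= 0)
  for (i in acceptors) add("acceptor", coords[i, ])

  # --- rings
  rings <- sssr(mol, max_size = rules$ring$max_ring_size %||% 8)
  for (r in rings) add("ring", at(r))

  # --- hydrophobes: clusters of carbons with no N/O/charged neighbours
  polar <- which(el %in% c("N", "O") | a$charge != 0)
  hydro <- which(el == "C" &
                   vapply(seq_len(n), function(i)
                     !any(nbrs[[i]] %in% polar), logical(1)))
  min_sz <- rules$hydrophobe$min_cluster_size %||% 2
  if (length(hydro) > 0) {
    sub <- subgraph_components(hydro, mol)
    for (comp in sub) {
      if (length(comp) >= min_sz) add("hydrophobe", at(comp))
    }
  }

  out <- if (length(feats) > 0) dplyr::bind_rows(feats) else
    tibble(kind = character(), x = numeric(), y = numeric(), z = numeric(),
           radius = numeric())
  dplyr::arrange(out, .data$kind, .data$x, .data$y, .data$z)
}

neighbor_list <- function(mol) {
  n <- nrow(mol$atoms)
  nbrs <- rep(list(integer()), n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    nbrs[[b$a1[k]]] <- c(nbrs[[b$a1[k]]], b$a2[k])
    nbrs[[b$a2[k]]] <- c(nbrs[[b$a2[k]]], b$a1[k])
  }
  nbrs
}

bond_orders_of <- function(i, mol) {
  b <- mol$bonds
  b$order[b$a1 == i | b$a2 == i]
}

has_carbonyl <- function(c_idx, mol, nbrs) {
  b <- mol$bonds
  any((b$a1 == c_idx | b$a2 == c_idx) & b$order == 2 &
        mol$atoms$element[ifelse(b$a1 == c_idx, b$a2, b$a1)] == "O")
}

# Expand charged atoms to groups: a charged atom with exactly one heavy
# neighbour (carboxylate O, etc.) is merged with that neighbour and the
# neighbour's equivalent terminal O/S atoms; the feature sits at the group
# centroid. Other charged atoms stand alone.
charged_groups <- function(atoms, mol, heavy_nbrs) {
  if (length(atoms) == 0) return(list())
  el <- mol$atoms$element
  groups <- list()
  used <- integer()
  for (i in atoms) {
    if (i %in% used) next
    hn <- heavy_nbrs[[i]]
    if (el[i] %in% c("O", "S") && length(hn) == 1) {
      center <- hn[1]
      sibs <- heavy_nbrs[[center]]
      term <- sibs[el[sibs] %in% c("O", "S") &
                     vapply(sibs, function(s)
                       length(heavy_nbrs[[s]]) == 1, logical(1))]
      grp <- sort(unique(c(i, center, term)))
    } else {
      grp <- i
    }
    used <- c(used, grp)
    groups[[length(groups) + 1]] <- grp
  }
  groups
}

# Smallest set of smallest rings via per-edge shortest cycles (igraph),
# greedily selected to an independent basis over GF(2).
sssr <- function(mol, max_size = 8) {
  b <- mol$bonds
  n <- nrow(mol$atoms)
  if (nrow(b) == 0) return(list())
  g <- igraph::graph_from_edgelist(cbind(b$a1, b$a2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  n_cycles <- igraph::ecount(g) - igraph::vcount(g) +
    igraph::components(g)$no
  if (n_cycles <= 0) return(list())
  cand <- list() # each: ordered vertex cycle (path a1..a2, closed by edge)
  for (k in seq_len(nrow(b))) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(b$a1[k], b$a2[k])))
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = b$a1[k], to = b$a2[k])$vpath[[1]])
    if (length(sp) >= 3 && length(sp) <= max_size)
      cand[[length(cand) + 1]] <- as.integer(sp)
  }
  if (length(cand) == 0) return(list())
  ring_edges <- function(cyc) {
    pairs <- cbind(cyc, c(cyc[-1], cyc[1]))
    sort(apply(cbind(pmin(pairs[, 1], pairs[, 2]),
                     pmax(pairs[, 1], pairs[, 2])), 1,
               paste, collapse = "-"))
  }
  keys <- vapply(cand, function(cyc) paste(ring_edges(cyc), collapse = ";"),
                 character(1))
  cand <- cand[!duplicated(keys)]
  cand <- cand[order(lengths(cand),
                     vapply(cand, function(v) paste(sort(v), collapse = ","),
                            character(1)))]
  # independence over GF(2) on edge incidence vectors
  all_edges <- apply(cbind(pmin(b$a1, b$a2), pmax(b$a1, b$a2)), 1,
                     paste, collapse = "-")
  basis <- matrix(0L, nrow = 0, ncol = length(all_edges))
  chosen <- list()
  for (ring in cand) {
    if (length(chosen) >= n_cycles) break
    red <- as.integer(all_edges %in% ring_edges(ring))
    for (r in seq_len(nrow(basis))) {
      piv <- which(basis[r, ] == 1L)[1]
      if (red[piv] == 1L) red <- (red + basis[r, ]) %% 2L
    }
    if (any(red == 1L)) {
      basis <- rbind(basis, red)
      chosen[[length(chosen) + 1]] <- sort(ring)
    }
  }
  chosen
}

# connected components of the bond graph restricted to `atoms`
subgraph_components <- function(atoms, mol) {
  b <- mol$bonds
  keep <- b$a1 %in% atoms & b$a2 %in% atoms
  g <- igraph::make_empty_graph(n = length(atoms), directed = FALSE)
  idx <- stats::setNames(seq_along(atoms), atoms)
  if (any(keep)) {
    g <- igraph::add_edges(g, rbind(idx[as.character(b$a1[keep])],
                                    idx[as.character(b$a2[keep])]))
  }
  comp <- igraph::components(g)$membership
  lapply(split(atoms, comp), sort)
}
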