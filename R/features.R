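# Pharmacophore feature perception.
#
# Three feature kinds are perceived from a 3D molecule:
#   A  hydrogen-bond acceptor, placed on the acceptor heteroatom nucleus
#      (carbonyl, ether/ester, hydroxyl oxygens; lone-pair nitrogens);
#      donors are deliberately not emitted — a donor hydroxyl is already
#      an acceptor, so acceptors subsume them
#   H  hydrophobe, at the heavy-atom centroid of a connected group of
#      non-polar carbons (no bond to any heteroatom, non-aromatic);
#      isolated terminal methyls (e.g. the acetate methyl) also count
#   R  aromatic ring, at the ring centroid with its unit plane normal
# The perception rules ship as an editable data file
# (extdata/feature_rules.csv); individual rules can be disabled.

#' Feature perception rule table
#'
#' @return Tibble of perception rules (`kind`, `rule`, `enabled`,
#'   `description`).
#' @export
feature_rules <- function() {
  readr::read_csv(pkg_file("extdata", "feature_rules.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

adjacency_list <- function(n_atoms, bonds) {
  adj <- vector("list", n_atoms)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$a1[i]; b <- bonds$a2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# Smallest ring through every bond: BFS from one endpoint to the other
# in the graph with that bond removed. Unique rings of size 3..6.
small_rings <- function(n_atoms, bonds) {
  adj <- adjacency_list(n_atoms, bonds)
  rings <- list()
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$a1[i]; b <- bonds$a2[i]
    # BFS a -> b avoiding the direct edge
    prev <- rep(NA_integer_, n_atoms)
    seen <- rep(FALSE, n_atoms)
    seen[a] <- TRUE
    queue <- a
    found <- FALSE
    while (length(queue) > 0 && !found) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (v == a && w == b) next
        if (!seen[w]) {
          seen[w] <- TRUE
          prev[w] <- v
          if (w == b) { found <- TRUE; break }
          queue <- c(queue, w)
        }
      }
    }
    if (!found) next
    path <- b
    while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
    if (length(path) >= 3 && length(path) <= 6) {
      rings[[length(rings) + 1L]] <- sort(path)
    }
  }
  unique(rings)
}

ring_is_aromatic <- function(ring, mol) {
  if (!length(ring) %in% c(5L, 6L)) return(FALSE)
  el <- mol$atoms$element[ring]
  if (!all(el %in% c("C", "N", "O", "S"))) return(FALSE)
  # conjugation: every ring carbon carries a double/aromatic bond
  b <- mol$bonds
  for (a in ring[el == "C"]) {
    orders <- b$order[(b$a1 == a | b$a2 == a)]
    if (!any(orders >= 2L)) return(FALSE)
  }
  # planarity of the ring atoms
  xyz <- mol$coords[ring, , drop = FALSE]
  centred <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(centred)
  max(abs(centred %*% sv$v[, 3])) < 0.15
}

ring_normal <- function(ring, coords) {
  xyz <- coords[ring, , drop = FALSE]
  centred <- sweep(xyz, 2, colMeans(xyz))
  n <- svd(centred)$v[, 3]
  n / sqrt(sum(n^2))
}

heteroatoms <- c("O", "N", "S", "P", "F", "Cl", "Br", "I")

perceive_sources <- function(mol, aromatic_as_hydrophobic = FALSE,
                             rules = feature_rules()) {
  atoms <- mol$atoms
  bonds <- mol$bonds
  n <- nrow(atoms)
  adj <- adjacency_list(n, bonds)
  heavy <- atoms$element != "H"
  heavy_deg <- vapply(seq_len(n), function(i) {
    sum(atoms$element[adj[[i]]] != "H")
  }, integer(1))
  enabled <- function(r) {
    row <- rules[rules$rule == r, , drop = FALSE]
    nrow(row) > 0 && isTRUE(row$enabled[1])
  }

  rings <- small_rings(n, bonds)
  aromatic <- Filter(function(r) ring_is_aromatic(r, mol), rings)
  aromatic_atoms <- unique(unlist(aromatic))

  feats <- list()
  add <- function(kind, source, rule) {
    feats[[length(feats) + 1L]] <<- list(kind = kind, source = source,
                                         rule = rule)
  }

  bond_order_to <- function(i, j) {
    hit <- (bonds$a1 == i & bonds$a2 == j) | (bonds$a1 == j & bonds$a2 == i)
    bonds$order[hit][1]
  }

  for (i in which(atoms$element == "O")) {
    nb <- adj[[i]]
    nb_heavy <- nb[atoms$element[nb] != "H"]
    if (i %in% aromatic_atoms) next  # aromatic O (furan) is a poor acceptor
    dbl <- any(vapply(nb_heavy, function(j) bond_order_to(i, j) == 2L,
                      logical(1)))
    if (dbl) {
      if (enabled("carbonyl_oxygen")) add("A", i, "carbonyl_oxygen")
    } else if (length(nb_heavy) >= 2) {
      if (enabled("ether_ester_oxygen")) add("A", i, "ether_ester_oxygen")
    } else {
      if (enabled("hydroxyl_oxygen")) add("A", i, "hydroxyl_oxygen")
    }
  }
  for (i in which(atoms$element == "N")) {
    if (!enabled("nitrogen_acceptor")) next
    nb <- adj[[i]]
    nb_heavy <- nb[atoms$element[nb] != "H"]
    if (length(nb_heavy) > 3) next
    n_oxy <- sum(atoms$element[nb_heavy] == "O")
    if (n_oxy >= 2) next  # nitro-like
    amide <- any(vapply(nb_heavy, function(j) {
      if (atoms$element[j] != "C") return(FALSE)
      any(vapply(adj[[j]], function(k) {
        atoms$element[k] == "O" && bond_order_to(j, k) == 2L
      }, logical(1)))
    }, logical(1)))
    if (amide) next
    add("A", i, "nitrogen_acceptor")
  }

  nonpolar <- atoms$element == "C" & !(seq_len(n) %in% aromatic_atoms) &
    vapply(seq_len(n), function(i) {
      !any(atoms$element[adj[[i]]] %in% heteroatoms)
    }, logical(1))
  # connected components of the non-polar carbon subgraph
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in which(nonpolar)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (nonpolar[w] && is.na(comp[w])) { comp[w] <- cid; queue <- c(queue, w) }
      }
    }
  }
  if (cid > 0) {
    for (g in seq_len(cid)) {
      members <- which(comp == g)
      if (length(members) >= 2) {
        if (enabled("carbon_group")) add("H", members, "carbon_group")
      } else if (heavy_deg[members] == 1L) {
        if (enabled("terminal_methyl")) add("H", members, "terminal_methyl")
      }
    }
  }

  if (enabled("aromatic_ring")) {
    for (r in aromatic) {
      add(if (aromatic_as_hydrophobic) "H" else "R", r, "aromatic_ring")
    }
  }

  if (length(feats) == 0) return(feats)
  kind_rank <- c(A = 1L, H = 2L, R = 3L)
  ord <- order(kind_rank[vapply(feats, `[[`, character(1), "kind")],
               vapply(feats, function(f) min(f$source), integer(1)))
  feats[ord]
}

feature_positions <- function(sources, coords) {
  t(vapply(sources, function(f) colMeans(coords[f$source, , drop = FALSE]),
           numeric(3)))
}

#' Perceive pharmacophore features of a 3D molecule
#'
#' @param mol A `molecule_3d` (see [molecule_3d()]).
#' @param aromatic_as_hydrophobic Re-type aromatic rings as hydrophobes
#'   (R -> H), mirroring protocols that treat rings as hydrophobic
#'   groups. Default FALSE: R stays a distinct kind.
#' @param rules Perception rule table (default [feature_rules()]).
#' @return A `feature_set` tibble: `label` ("A1", "H3", ... numbered
#'   across the whole set, acceptors first), `kind`, `x`, `y`, `z`,
#'   `source_atoms` (list), `normal` (list; ring features only). An
#'   empty tibble (with a message) when the molecule has no features.
#' @export
perceive_features <- function(mol, aromatic_as_hydrophobic = FALSE,
                              rules = feature_rules()) {
  stopifnot(inherits(mol, "molecule_3d"))
  sources <- perceive_sources(mol, aromatic_as_hydrophobic, rules)
  if (length(sources) == 0) {
    inform(paste0("No pharmacophore features perceived for ",
                  mol$molecule_id, "."))
    return(tibble::new_tibble(
      tibble::tibble(label = character(), kind = character(),
                     x = numeric(), y = numeric(), z = numeric(),
                     source_atoms = list(), normal = list()),
      class = "feature_set"
    ))
  }
  pos <- feature_positions(sources, mol$coords)
  kinds <- vapply(sources, `[[`, character(1), "kind")
  normals <- purrr::map2(sources, kinds, function(f, k) {
    if (k == "R") ring_normal(f$source, mol$coords) else NULL
  })
  tibble::new_tibble(
    tibble::tibble(
      label = paste0(kinds, seq_along(kinds)),
      kind = kinds,
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      source_atoms = purrr::map(sources, "source"),
      normal = normals
    ),
    class = "feature_set"
  )
}
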