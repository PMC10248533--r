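# Solvent-accessible surface area, interface burial, contact
# detection, hydrophobicity mapping and cavity volume.

# deterministic, nearly uniform points on the unit sphere
# (golden-spiral / Fibonacci lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(elements, default_radius = 1.70) {
  r <- VDW_RADII[elements]
  if (anyNA(r)) {
    warning("unknown element(s) ",
            paste(unique(elements[is.na(r)]), collapse = ", "),
            "; using default radius ", default_radius, " A")
    r[is.na(r)] <- default_radius
  }
  unname(r)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom accessible area from sphere-point sampling: `n_points`
#' points on each atom's solvent-accessible sphere (vdW radius +
#' probe) are tested against all neighbouring atoms; the unoccluded
#' fraction times the sphere area is the atom's SASA.
#'
#' @param s a [StructureModel-class] (hydrogens, if present, are used
#'   as-is)
#' @param probe probe radius in Angstrom (default 1.4, a water)
#' @param n_points sample points per atom (default 960)
#' @param default_radius fallback vdW radius for unknown elements
#' @return numeric vector of per-atom areas (Angstrom^2); total SASA is
#'   `sum()` of it
#' @export
shrakeRupleySasa <- function(s, probe = 1.4, n_points = 960,
                             default_radius = 1.70) {
  a <- atomTable(s)
  n <- nrow(a)
  xyz <- as.matrix(a[c("x", "y", "z")])
  r <- atom_radii(a$element, default_radius) + probe
  pts <- sphere_points(n_points)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r + r[i])^2 & seq_len(n) != i)
    p <- pts * r[i] + matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (p[free, 1] - xyz[j, 1])^2 + (p[free, 2] - xyz[j, 2])^2 +
        (p[free, 3] - xyz[j, 3])^2
      free[free] <- dj2 >= r[j]^2
    }
    out[i] <- 4 * pi * r[i]^2 * mean(free)
  }
  out
}

select_part <- function(atoms, part) {
  # part: chain ids, or a list(chains=..., resno=...) residue selection
  if (is.list(part)) {
    sel <- atoms$chain %in% part$chains
    if (!is.null(part$resno)) sel <- sel & atoms$resno %in% part$resno
    sel
  } else {
    atoms$chain %in% part
  }
}

#' Buried interface area between two parts of a structure
#'
#' Computes delta-SASA = SASA(A alone) + SASA(B alone) - SASA(A+B)
#' and reports both the total and the half convention, together with
#' cross-interface residue contacts (salt bridges, hydrogen-bond
#' candidates, hydrophobic contacts).
#'
#' @param s a [StructureModel-class]
#' @param partA,partB disjoint chain identifiers (or
#'   list(chains=, resno=) selections)
#' @inheritParams shrakeRupleySasa
#' @return an [InterfaceReport-class]
#' @export
buriedInterfaceArea <- function(s, partA, partB, probe = 1.4,
                                n_points = 960) {
  atoms <- atomTable(s)
  selA <- select_part(atoms, partA)
  selB <- select_part(atoms, partB)
  if (!any(selA) || !any(selB)) stop("both parts must be nonempty")
  if (any(selA & selB)) stop("parts overlap")
  mk <- function(sel) new("StructureModel", atoms = atoms[sel, ])
  sasaA <- sum(shrakeRupleySasa(mk(selA), probe, n_points))
  sasaB <- sum(shrakeRupleySasa(mk(selB), probe, n_points))
  sasaAB <- sum(shrakeRupleySasa(mk(selA | selB), probe, n_points))
  total <- max(sasaA + sasaB - sasaAB, 0)
  contacts <- interface_contacts(atoms, selA, selB)
  new("InterfaceReport",
      partA = as.character(unique(atoms$chain[selA])),
      partB = as.character(unique(atoms$chain[selB])),
      deltaSasaTotal = total, deltaSasaHalf = total / 2,
      contacts = contacts)
}

res_key <- function(a) paste0(a$chain, a$resno, a$insert)

interface_contacts <- function(atoms, selA, selB,
                               hb_cutoff = 3.5, hp_cutoff = 4.5) {
  sb <- salt_bridge_pairs(atoms, selA, selB, 4.0)
  out <- sb
  # hydrogen-bond candidates: N/O pairs across the interface
  don <- atoms[selA & atoms$element %in% c("N", "O"), ]
  acc <- atoms[selB & atoms$element %in% c("N", "O"), ]
  hb <- cross_pairs(don, acc, hb_cutoff)
  hb <- hb[!paste(hb$resA, hb$resB) %in% paste(sb$resA, sb$resB), ,
           drop = FALSE]
  if (nrow(hb)) hb$type <- "hydrogen bond candidate"
  # hydrophobic: carbon-carbon contacts on hydrophobic residues
  hydrophobic <- names(kyteDoolittleScale)[kyteDoolittleScale > 0]
  ca <- atoms[selA & atoms$element == "C" &
                atoms$resid %in% hydrophobic, ]
  cb <- atoms[selB & atoms$element == "C" &
                atoms$resid %in% hydrophobic, ]
  hp <- cross_pairs(ca, cb, hp_cutoff)
  if (nrow(hp)) hp$type <- "hydrophobic"
  out <- rbind(out, hb, hp)
  out[!duplicated(paste(out$resA, out$resB, out$type)), ,
      drop = FALSE]
}

cross_pairs <- function(a, b, cutoff) {
  empty <- data.frame(resA = character(), resB = character(),
                      distance = numeric(), type = character(),
                      stringsAsFactors = FALSE)
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)
  xa <- as.matrix(a[c("x", "y", "z")])
  xb <- as.matrix(b[c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rep(1, nrow(xb))) +
    outer(rep(1, nrow(xa)), rowSums(xb^2)) - 2 * xa %*% t(xb)
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  df <- data.frame(resA = res_key(a[hit[, 1], ]),
                   resB = res_key(b[hit[, 2], ]),
                   distance = sqrt(pmax(d2[hit], 0)),
                   type = "", stringsAsFactors = FALSE)
  df <- df[order(df$distance), ]
  df[!duplicated(paste(df$resA, df$resB)), , drop = FALSE]
}

salt_bridge_pairs <- function(atoms, selA, selB, cutoff) {
  basic_sel <- function(sel) {
    keep <- rep(FALSE, nrow(atoms))
    for (rn in names(SB_BASIC))
      keep <- keep | (atoms$resid == rn & atoms$atom %in% SB_BASIC[[rn]])
    atoms[sel & keep, , drop = FALSE]
  }
  acidic_sel <- function(sel) {
    keep <- rep(FALSE, nrow(atoms))
    for (rn in names(SB_ACIDIC))
      keep <- keep | (atoms$resid == rn & atoms$atom %in% SB_ACIDIC[[rn]])
    atoms[sel & keep, , drop = FALSE]
  }
  out <- rbind(cross_pairs(basic_sel(selA), acidic_sel(selB), cutoff),
               cross_pairs(acidic_sel(selA), basic_sel(selB), cutoff))
  if (nrow(out)) out$type <- "salt bridge"
  out
}

#' Detect salt bridges across a partition
#'
#' A pair is reported when a side-chain nitrogen of Arg/Lys/His in one
#' part lies within `cutoff` of a side-chain carboxylate oxygen of
#' Asp/Glu in the other.
#'
#' @param s a [StructureModel-class]
#' @param partA,partB chain identifiers (or residue selections)
#' @param cutoff distance cutoff in Angstrom (default 4.0)
#' @return data.frame: resA, resB, distance, type
#' @export
detectSaltBridges <- function(s, partA, partB, cutoff = 4.0) {
  atoms <- atomTable(s)
  salt_bridge_pairs(atoms, select_part(atoms, partA),
                    select_part(atoms, partB), cutoff)
}

dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Detect cis peptide bonds
#'
#' Computes the omega dihedral (CA_i, C_i, N_i+1, CA_i+1) for every
#' consecutive residue pair; a bond is cis iff |omega| <= `threshold`
#' degrees.  Chain breaks (C-N distance > 2.5 A) are skipped.
#'
#' @param s a [StructureModel-class]
#' @param threshold cis threshold in degrees (default 30)
#' @return data.frame: chain, resno (of residue i+1), resid, omega
#' @export
detectCisPeptides <- function(s, threshold = 30) {
  atoms <- atomTable(s)
  out <- data.frame(chain = character(), resno = integer(),
                    resid = character(), omega = numeric(),
                    stringsAsFactors = FALSE)
  for (ch in unique(atoms$chain)) {
    res <- chain_residues(atoms, ch)
    if (length(res) < 2L) next
    for (i in seq_len(length(res) - 1L)) {
      r1 <- res[[i]]; r2 <- res[[i + 1L]]
      g <- function(r, at) {
        k <- match(at, r$atom)
        if (is.na(k)) return(NULL)
        as.numeric(r[k, c("x", "y", "z")])
      }
      ca1 <- g(r1, "CA"); c1 <- g(r1, "C")
      n2 <- g(r2, "N"); ca2 <- g(r2, "CA")
      if (is.null(ca1) || is.null(c1) || is.null(n2) || is.null(ca2))
        next
      if (sqrt(sum((c1 - n2)^2)) > 2.5) next   # chain break
      om <- dihedral(ca1, c1, n2, ca2)
      if (abs(om) <= threshold)
        out <- rbind(out, data.frame(
          chain = ch, resno = r2$resno[1], resid = r2$resid[1],
          omega = om, stringsAsFactors = FALSE))
    }
  }
  out
}

#' Kyte-Doolittle hydrophobicity per residue
#'
#' @param s a [StructureModel-class]
#' @param scale named per-residue values (default the bundled
#'   Kyte-Doolittle table); unknown residues map to 0 with a warning
#' @return data.frame: chain, resno, resid, hydropathy
#' @export
hydrophobicityMap <- function(s, scale = kyteDoolittleScale) {
  atoms <- atomTable(s)
  res <- atoms[!duplicated(paste(atoms$chain, atoms$resno,
                                 atoms$insert)), ]
  val <- scale[res$resid]
  if (anyNA(val)) {
    warning("unknown residue(s) ",
            paste(unique(res$resid[is.na(val)]), collapse = ", "),
            " mapped to 0")
    val[is.na(val)] <- 0
  }
  data.frame(chain = res$chain, resno = res$resno, resid = res$resid,
             hydropathy = unname(val), stringsAsFactors = FALSE)
}

#' Interior cavity volume by grid flood fill
#'
#' Grid cells outside every probe-inflated atom are classified by a
#' flood fill from the bounding-box boundary; open cells unreachable
#' from outside form interior voids.  The helical-residue capacity uses
#' a documented 170 A^3-per-residue estimate.
#'
#' @param s a [StructureModel-class]
#' @param grid grid spacing in Angstrom (default 0.5)
#' @param probe probe radius (default 1.4)
#' @param volume_per_residue A^3 per helical residue for the capacity
#'   estimate (default 170)
#' @return list: `volume` (A^3), `capacity_residues`, `n_cavity_cells`
#' @export
cavityVolume <- function(s, grid = 0.5, probe = 1.4,
                         volume_per_residue = 170) {
  atoms <- atomTable(s)
  if (nrow(atoms) == 0L) stop("empty structure")
  xyz <- as.matrix(atoms[c("x", "y", "z")])
  r <- atom_radii(atoms$element) + probe
  lo <- apply(xyz, 2, min) - max(r) - grid
  hi <- apply(xyz, 2, max) + max(r) + grid
  dims <- pmax(ceiling((hi - lo) / grid) + 1L, 2L)
  ax <- lapply(1:3, function(k) lo[k] + (seq_len(dims[k]) - 1) * grid)
  blocked <- array(FALSE, dim = dims)
  for (i in seq_len(nrow(xyz))) {
    rng <- lapply(1:3, function(k) {
      which(abs(ax[[k]] - xyz[i, k]) <= r[i])
    })
    if (any(lengths(rng) == 0L)) next
    sub <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    d2 <- (ax[[1]][sub[, 1]] - xyz[i, 1])^2 +
      (ax[[2]][sub[, 2]] - xyz[i, 2])^2 +
      (ax[[3]][sub[, 3]] - xyz[i, 3])^2
    inside <- sub[d2 <= r[i]^2, , drop = FALSE]
    blocked[inside] <- TRUE
  }
  outside <- flood_from_boundary(blocked)
  cavity <- !blocked & !outside
  n_cav <- sum(cavity)
  vol <- n_cav * grid^3
  list(volume = vol,
       capacity_residues = vol / volume_per_residue,
       n_cavity_cells = n_cav)
}

# 6-neighbour flood fill from all boundary cells through open space
flood_from_boundary <- function(blocked) {
  d <- dim(blocked)
  visited <- array(FALSE, dim = d)
  # seed: open boundary cells
  idx <- function(i, j, k) cbind(i, j, k)
  seeds <- rbind(
    as.matrix(expand.grid(c(1, d[1]), seq_len(d[2]), seq_len(d[3]))),
    as.matrix(expand.grid(seq_len(d[1]), c(1, d[2]), seq_len(d[3]))),
    as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), c(1, d[3]))))
  open_seed <- !blocked[seeds]
  frontier <- unique(seeds[open_seed, , drop = FALSE])
  visited[frontier] <- TRUE
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  while (nrow(frontier) > 0L) {
    nxt <- NULL
    for (sft in seq_len(6)) {
      cand <- sweep(frontier, 2, shifts[sft, ], `+`)
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) == 0L) next
      new_cells <- !visited[cand] & !blocked[cand]
      cand <- cand[new_cells, , drop = FALSE]
      if (nrow(cand) == 0L) next
      visited[cand] <- TRUE
      nxt <- rbind(nxt, cand)
    }
    frontier <- if (is.null(nxt)) matrix(0, 0, 3) else nxt
  }
  visited
}
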