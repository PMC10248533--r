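# Rigid-body superposition and backbone RMSD.

#' Kabsch least-squares superposition
#'
#' Optimal rigid superposition (rotation + translation, reflection
#' excluded) of paired coordinate sets by SVD of the covariance matrix.
#' The returned transform maps `mobile` onto `fixed`:
#' x' = x R + t (row vectors).
#'
#' @param fixed,mobile n x 3 coordinate matrices with matched rows,
#'   n >= 3, not collinear
#' @return a [Superposition-class]
#' @export
kabschSuperpose <- function(fixed, mobile) {
  fixed <- as.matrix(fixed); mobile <- as.matrix(mobile)
  if (nrow(fixed) != nrow(mobile))
    stop("coordinate sets must be paired")
  if (nrow(fixed) < 3L) stop("need at least 3 points")
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  X <- sweep(mobile, 2, cm)
  Y <- sweep(fixed, 2, cf)
  if (min(svd(X)$d[2], svd(Y)$d[2]) < 1e-8)
    stop("points are collinear")
  H <- crossprod(X, Y)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  Rm <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  tv <- cf - cm %*% Rm
  moved <- mobile %*% Rm + matrix(tv, nrow(mobile), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  new("Superposition", rotation = Rm, translation = as.numeric(tv),
      rmsd = rmsd, n = nrow(fixed))
}

#' Apply a superposition to coordinates
#'
#' @param sp a [Superposition-class]
#' @param xyz n x 3 matrix
#' @return transformed n x 3 matrix
#' @export
applySuperposition <- function(sp, xyz) {
  xyz <- as.matrix(xyz)
  xyz %*% sp@rotation +
    matrix(sp@translation, nrow(xyz), 3, byrow = TRUE)
}

# residues of one chain, enumerated exactly like chainSequence()
chain_residues <- function(atoms, chain) {
  a <- atoms[atoms$chain == chain, ]
  split(a, factor(paste(a$resno, a$insert),
                  levels = unique(paste(a$resno, a$insert))))
}

#' Backbone RMSD between two structures
#'
#' Chains are paired greedily by best sequence identity; residue
#' correspondence within each chain pair comes from a global sequence
#' alignment; backbone atoms (N, CA, C, O) of aligned residue pairs
#' with all four atoms present on both sides enter a single rigid
#' Kabsch superposition over all chain pairs jointly.
#'
#' @param a,b [StructureModel-class] objects
#' @return list: `rmsd` (Angstrom), `n_atoms`, `n_residues`,
#'   `chain_pairs`, `superposition`
#' @export
backboneRmsd <- function(a, b) {
  ta <- atomTable(a); tb <- atomTable(b)
  cha <- unique(ta$chain); chb <- unique(tb$chain)
  # greedy best-identity chain pairing
  pairs <- list()
  avail <- chb
  for (ca in cha) {
    if (length(avail) == 0L) break
    ids <- vapply(avail, function(cb)
      pairwiseIdentity(chainSequence(a, ca), chainSequence(b, cb)),
      numeric(1))
    cb <- avail[which.max(ids)]
    pairs[[length(pairs) + 1L]] <- c(ca, cb)
    avail <- setdiff(avail, cb)
  }
  Pf <- NULL; Pm <- NULL; n_res <- 0L
  for (pr in pairs) {
    sa <- chainSequence(a, pr[1]); sb <- chainSequence(b, pr[2])
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(sa), Biostrings::AAString(sb),
      type = "global", substitutionMatrix = blosum62(),
      gapOpening = 11, gapExtension = 1)
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)),
                   "")[[1]]
    pb <- strsplit(as.character(Biostrings::alignedSubject(al)),
                   "")[[1]]
    ra <- chain_residues(ta, pr[1])
    rb <- chain_residues(tb, pr[2])
    bb <- c("N", "CA", "C", "O")
    ia <- 0L; ib <- 0L
    for (col in seq_along(pa)) {
      if (pa[col] != "-") ia <- ia + 1L
      if (pb[col] != "-") ib <- ib + 1L
      if (pa[col] == "-" || pb[col] == "-") next
      qa <- ra[[ia]][match(bb, ra[[ia]]$atom), ]
      qb <- rb[[ib]][match(bb, rb[[ib]]$atom), ]
      if (!anyNA(qa$x) && !anyNA(qb$x)) {
        Pf <- rbind(Pf, as.matrix(qa[c("x", "y", "z")]))
        Pm <- rbind(Pm, as.matrix(qb[c("x", "y", "z")]))
        n_res <- n_res + 1L
      }
    }
  }
  if (is.null(Pf) || nrow(Pf) < 3L)
    stop("no aligned residues with complete backbone")
  sp <- kabschSuperpose(Pf, Pm)
  list(rmsd = sp@rmsd, n_atoms = nrow(Pf), n_residues = n_res,
       chain_pairs = pairs, superposition = sp)
}
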