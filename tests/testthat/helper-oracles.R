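# Independent oracles used across the suite.  These deliberately share
# no code with the package internals they check.

AA <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

random_aa <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA, n, replace = TRUE), collapse = "")
}

# exhaustive affine-gap global alignment (Gotoh), returning the optimal
# score and one optimal aligned pair; O(nm), fine for short sequences
oracle_global_align <- function(a, b, submat, open = 11, extend = 1) {
  # Biostrings convention: a gap of length k costs open + k * extend,
  # i.e. open + extend to start and extend per further position
  open <- open + extend
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - (i - 2) * extend
  for (j in 2:(m + 1)) Y[1, j] <- -open - (j - 2) * extend
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1],
                   Y[i - 1, j - 1]) + submat[A[i - 1], B[j - 1]]
    X[i, j] <- max(M[i - 1, j] - open, X[i - 1, j] - extend,
                   Y[i - 1, j] - open)
    Y[i, j] <- max(M[i, j - 1] - open, Y[i, j - 1] - extend,
                   X[i, j - 1] - open)
  }
  sc <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  # traceback for one optimal alignment
  st <- which.max(c(M[n + 1, m + 1], X[n + 1, m + 1],
                    Y[n + 1, m + 1]))
  i <- n + 1; j <- m + 1
  pa <- character(); pb <- character()
  while (i > 1 || j > 1) {
    if (st == 1) {
      pa <- c(A[i - 1], pa); pb <- c(B[j - 1], pb)
      st <- which.max(c(M[i - 1, j - 1], X[i - 1, j - 1],
                        Y[i - 1, j - 1]))
      i <- i - 1; j <- j - 1
    } else if (st == 2) {
      pa <- c(A[i - 1], pa); pb <- c("-", pb)
      st <- which.max(c(M[i - 1, j] - open, X[i - 1, j] - extend,
                        Y[i - 1, j] - open))
      i <- i - 1
    } else {
      pa <- c("-", pa); pb <- c(B[j - 1], pb)
      st <- which.max(c(M[i, j - 1] - open, X[i, j - 1] - open,
                        Y[i, j - 1] - extend))
      st <- c(1L, 2L, 3L)[st]
      j <- j - 1
    }
  }
  list(score = sc, a = paste(pa, collapse = ""),
       b = paste(pb, collapse = ""))
}

oracle_identity <- function(a, b, submat) {
  al <- oracle_global_align(a, b, submat)
  pa <- strsplit(al$a, "")[[1]]; pb <- strsplit(al$b, "")[[1]]
  keep <- !(pa == "-" & pb == "-")
  sum(pa[keep] == pb[keep] & pa[keep] != "-") / sum(keep)
}

# quaternion (Horn 1987) closed-form superposition RMSD oracle
oracle_quaternion_rmsd <- function(fixed, mobile) {
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(fixed, 2, colMeans(fixed))
  S <- crossprod(X, Y)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(X^2) + sum(Y^2) - 2 * lam) / nrow(X)
  sqrt(max(msd, 0))
}

# random unrooted binary tree with branch lengths
random_tree <- function(n, seed = NULL, scale = 0.3) {
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rtree(n)
  phy$edge.length <- pmax(phy$edge.length * scale, 0.02)
  ape::unroot(phy)
}

# rigid-body transform of an n x 3 matrix (random rotation+shift)
random_rigid <- function(xyz, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t <- rnorm(3, sd = 5)
  sweep(xyz %*% R, 2, t, `+`)
}

b62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
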