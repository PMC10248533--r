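# Reversible amino-acid substitution models.
#
# LG (Le & Gascuel 2008) and VT (Mueller & Vingron 2000)
# exchangeabilities and frequencies are bundled as plain-text files
# under inst/extdata/models/.  TOY3 is a deliberately small 3-state
# model whose likelihoods can be checked by exhaustive enumeration.

read_model_file <- function(name) {
  path <- system.file("extdata", "models",
                      paste0(tolower(name), ".txt"),
                      package = "Get3Atlas", mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  iex <- which(lines == "exchangeabilities:")
  ifr <- which(lines == "frequencies:")
  ex <- as.numeric(lines[(iex + 1):(ifr - 1)])
  fr <- as.numeric(lines[(ifr + 1):length(lines)])
  R <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  R[lower.tri(R)] <- ex
  R <- R + t(R)
  list(R = R, freqs = setNames(fr, AA20))
}

#' Construct a substitution model
#'
#' Builds the normalised reversible rate matrix Q with
#' \eqn{Q_{ij} = r_{ij} \pi_j} (i != j), rows summing to zero, scaled so
#' the expected equilibrium rate is one substitution per site.  The
#' eigendecomposition used for fast \eqn{P(t) = e^{Qt}} is cached on the
#' object.
#'
#' @param name "LG", "VT" or "TOY3"
#' @param freqs "model" (the published frequencies; for TOY3 its fixed
#'   frequencies) or "empirical" with `alignment` supplied, in which
#'   case frequencies are counted from the alignment (add-one smoothed)
#' @param alignment optional [AlignmentBlock-class] for empirical
#'   frequencies
#' @return a [SubstitutionModel-class]
#' @export
substitutionModel <- function(name = c("LG", "VT", "TOY3"),
                              freqs = c("model", "empirical"),
                              alignment = NULL) {
  name <- match.arg(name)
  freqs <- match.arg(freqs)
  if (name == "TOY3") {
    states <- c("A", "B", "C")
    R <- matrix(c(0, 1, 2,
                  1, 0, 3,
                  2, 3, 0), 3, 3,
                dimnames = list(states, states))
    pf <- setNames(c(0.5, 0.3, 0.2), states)
  } else {
    mf <- read_model_file(name)
    R <- mf$R
    pf <- mf$freqs
    states <- AA20
  }
  if (freqs == "empirical") {
    if (is.null(alignment))
      stop("empirical frequencies need an alignment")
    m <- as.matrix(alignment)
    cnt <- tabulate(match(m, states), length(states))
    pf <- setNames((cnt + 1) / (sum(cnt) + length(states)), states)
  }
  pf <- pf / sum(pf)
  Q <- R * rep(pf, each = length(pf))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pf * diag(Q))
  Q <- Q / scale
  # symmetrise for a stable eigendecomposition:
  # B = diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric
  sp <- sqrt(pf)
  B <- (sp * Q) %*% diag(1 / sp)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  vectors <- diag(1 / sp) %*% e$vectors
  inverse <- t(e$vectors) %*% diag(sp)
  new("SubstitutionModel", name = name, states = states,
      exchangeabilities = R, freqs = pf, Q = Q,
      eig = list(values = e$values, vectors = vectors,
                 inverse = inverse))
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a [SubstitutionModel-class]
#' @param t branch length (expected substitutions per site), >= 0
#' @return stochastic matrix (rows sum to 1)
#' @export
transitionProbability <- function(model, t) {
  if (t < 0) stop("branch length must be >= 0")
  e <- model@eig
  P <- e$vectors %*% (exp(e$values * t) * e$inverse)
  # clip tiny negative round-off
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Model equilibrium frequencies
#' @param model a [SubstitutionModel-class]
#' @export
modelFrequencies <- function(model) model@freqs

#' Model state alphabet
#' @param model a [SubstitutionModel-class]
#' @export
modelStates <- function(model) model@states
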