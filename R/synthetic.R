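#' Specification of a synthetic two-class expression cohort
#'
#' Describes a Gaussian cohort with block-equicorrelated features and a
#' small planted set of informative features whose class means differ by
#' an additive shift. Defaults mirror the geometry of a balanced
#' 86-sample, 213-feature miRNA training cohort. The generator emulates
#' log-scale expression after upstream array preprocessing; it makes no
#' attempt to imitate array-specific noise such as spot background or dye
#' effects.
#'
#' @param m1,m2 Positive / negative class sizes.
#' @param n Number of features.
#' @param k_true Number of informative features (`<= n`). They are placed
#'   round-robin across correlation blocks, so with enough blocks each
#'   informative feature sits in its own block of correlated nulls.
#' @param effect Between-class mean shift per informative feature, in
#'   within-class standard-deviation units (>= 0).
#' @param rho Equicorrelation among features within a block, in \[0, 1).
#' @param block_size Features per correlation block.
#' @param seed Integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(m1 = 43L, m2 = 43L, n = 213L, k_true = 10L,
                           effect = 0.8, rho = 0.3, block_size = 10L,
                           seed = 1L) {
  if (k_true > n) stop("k_true cannot exceed n")
  if (rho < 0 || rho >= 1)
    stop("rho must lie in [0, 1) for a positive-definite correlation")
  if (effect < 0) stop("effect must be nonnegative")
  if (block_size < 1) stop("block_size must be positive")
  structure(list(m1 = as.integer(m1), m2 = as.integer(m2), n = as.integer(n),
                 k_true = as.integer(k_true), effect = effect, rho = rho,
                 block_size = as.integer(block_size), seed = as.integer(seed)),
            class = "synthetic_spec")
}

block_index <- function(spec) {
  rep(seq_len(ceiling(spec$n / spec$block_size)),
      each = spec$block_size)[seq_len(spec$n)]
}

informative_positions <- function(spec) {
  if (spec$k_true == 0) return(integer(0))
  nb <- max(block_index(spec))
  j <- 0:(spec$k_true - 1)
  pos <- (j %% nb) * spec$block_size + (j %/% nb) + 1L
  pos[pos <= spec$n][seq_len(spec$k_true)]
}

#' Generate a synthetic labeled cohort with known ground truth
#'
#' Draws features from a block-equicorrelated standard Gaussian (common
#' block factor plus independent noise), then shifts each informative
#' feature's mean by `+effect/2 * sign` in the positive class and
#' `-effect/2 * sign` in the negative class, with random signs. Class
#' sizes are exact and the draw is deterministic given the seed.
#'
#' The planted support and its signs are functions of `spec$seed` alone,
#' while the Gaussian noise is drawn under `seed`; drawing a second cohort
#' from the same spec with a different `seed` therefore yields an
#' independent cohort governed by the *same* ground truth, suitable as a
#' held-out test set.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Seed for the noise draw; defaults to `spec$seed`.
#' @param m1,m2 Optional class-size overrides (e.g. a larger held-out
#'   cohort from the same population).
#' @return List with `dataset` (a [labeled_dataset()]) and `truth`
#'   (list `features`, `positions`, `signs` of the planted support).
#' @export
simulate_cohort <- function(spec, seed = spec$seed, m1 = spec$m1,
                            m2 = spec$m2) {
  stopifnot(inherits(spec, "synthetic_spec"))
  m <- m1 + m2
  blocks <- block_index(spec)
  nb <- max(blocks)
  signs <- with_seed(spec$seed, sample(c(-1, 1), spec$k_true, replace = TRUE))
  pos <- informative_positions(spec)
  with_seed(derive_seed(seed, 1L), {
    G <- matrix(rnorm(m * nb), m, nb)                 # shared block factors
    E <- matrix(rnorm(m * spec$n), m, spec$n)
    X <- sqrt(spec$rho) * G[, blocks, drop = FALSE] + sqrt(1 - spec$rho) * E
    y <- c(rep(1, m1), rep(-1, m2))
    for (j in seq_along(pos))
      X[, pos[j]] <- X[, pos[j]] + y * (spec$effect / 2) * signs[j]
    features <- sprintf("F%04d", seq_len(spec$n))
    ds <- labeled_dataset(X, y,
                          samples = sprintf("S%03d", seq_len(m)),
                          features = features)
    list(dataset = ds,
         truth = list(features = features[pos], positions = pos,
                      signs = signs))
  })
}

#' Optimal (Bayes) accuracy of a synthetic specification
#'
#' Closed form `Phi(Delta / 2)` for equal class priors, where `Delta` is
#' the Mahalanobis distance between the two class means under the spec's
#' block covariance. Used to calibrate effect sizes.
#'
#' @param spec A [synthetic_spec()].
#' @return Fraction in \[0.5, 1\].
#' @export
bayes_accuracy <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$effect == 0 || spec$k_true == 0) return(0.5)
  blocks <- block_index(spec)
  pos <- informative_positions(spec)
  # first draw under the seed, identical to the one in simulate_cohort()
  signs <- with_seed(spec$seed, sample(c(-1, 1), spec$k_true, replace = TRUE))
  delta <- numeric(spec$n)
  delta[pos] <- spec$effect * signs
  d2 <- 0
  for (b in unique(blocks[pos])) {
    idx <- which(blocks == b)
    db <- delta[idx]
    sz <- length(idx)
    Sigma <- matrix(spec$rho, sz, sz); diag(Sigma) <- 1
    d2 <- d2 + drop(crossprod(db, solve(Sigma, db)))
  }
  pnorm(sqrt(d2) / 2)
}

#' Calibrate the effect size to a target Bayes accuracy
#'
#' Solves `bayes_accuracy(spec with effect e) = target` for `e` by root
#' finding, holding every other field of the spec fixed.
#'
#' @param spec A [synthetic_spec()] (its `effect` is ignored).
#' @param target Desired Bayes accuracy in (0.5, 1).
#' @return The calibrated effect size.
#' @export
calibrate_effect <- function(spec, target = 0.95) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (target <= 0.5 || target >= 1) stop("target must lie in (0.5, 1)")
  f <- function(e) {
    s <- spec; s$effect <- e
    bayes_accuracy(s) - target
  }
  uniroot(f, c(1e-9, 100), tol = 1e-10)$root
}
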