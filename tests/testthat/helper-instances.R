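# Small random problem instances and independent solvers used to
# cross-check the ADMM path.

# A tiny separable-ish two-class instance: k samples, s features.
random_svm_instance <- function(seed, kmax = 10, smax = 6) {
  set.seed(seed)
  k <- sample(4:kmax, 1)
  s <- sample(2:smax, 1)
  y <- c(rep(1, ceiling(k / 2)), rep(-1, floor(k / 2)))
  X <- matrix(rnorm(k * s), k) + outer(y, rnorm(s)) * 0.8
  list(X = X, y = y,
       lambda = runif(1, 0.02, 0.4),
       alpha = runif(1, 0.3, 0.7),
       gamma = runif(1, 0, 1))
}

# Independent oracle: minimize the (unconstrained, nonsmooth) objective by
# BFGS on a smoothed surrogate with a continuation schedule. Shares no code
# or algorithmic structure with the ADMM implementation.
oracle_bfgs_objective <- function(X, y, lambda, alpha, gamma) {
  k <- nrow(X); s <- ncol(X)
  cw <- (1 - lambda) * ifelse(y > 0, alpha, 1 - alpha)
  fn <- function(par, eps) {
    w <- par[1:s]; th <- par[s + 1]
    t <- 1 - y * (drop(X %*% w) - th)
    hub <- ifelse(t <= 0, 0, ifelse(t < eps, t^2 / (2 * eps), t - eps / 2))
    sum(cw * hub) + lambda * (gamma * sum(sqrt(w^2 + eps^2)) +
                                (1 - gamma) * sqrt(sum(w^2) + eps^2))
  }
  par <- rep(0, s + 1)
  for (eps in 10^seq(-1, -9, by = -1)) {
    o <- optim(par, fn, eps = eps, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    par <- o$par
  }
  svm_objective(par[1:s], par[s + 1], X, y, lambda, alpha, gamma)
}

# Independent oracle through the system `python` + scipy: generic
# nonlinear-programming solve of the cone formulation (SLSQP), and for
# gamma = 1 a linear program (HiGHS). Returns a data.frame of objective
# values, one row per instance.
oracle_python_objectives <- function(instances, mode = c("slsqp", "lp")) {
  mode <- match.arg(mode)
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(lapply(instances, function(z)
    list(X = z$X, y = z$y, lambda = z$lambda, alpha = z$alpha,
         gamma = z$gamma)),
    infile, digits = NA, auto_unbox = TRUE)
  status <- system2("python", c(test_path("oracle_socp.py"), mode,
                                infile, outfile),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(outfile))
    stop("python oracle failed: ", paste(status, collapse = "\n"))
  jsonlite::read_json(outfile, simplifyVector = TRUE)
}

# A tiny labeled dataset for plumbing tests.
tiny_dataset <- function(seed = 1, m1 = 6, m2 = 6, n = 10) {
  set.seed(seed)
  y <- c(rep(1, m1), rep(-1, m2))
  X <- matrix(rnorm((m1 + m2) * n), m1 + m2, n) +
    outer(y, c(rep(0.9, 2), rep(0, n - 2)))
  labeled_dataset(X, y)
}
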