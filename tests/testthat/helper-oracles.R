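# Independent oracles and small fixture builders shared across test files.

# Profiled REML criterion for the random-intercept model, computed from
# first principles (dense V, no lme4): used as a brute-force grid oracle.
reml_loglik <- function(y, X, subject, var_s, var_e) {
  Z <- stats::model.matrix(~ 0 + factor(subject))
  V <- var_s * tcrossprod(Z) + diag(var_e, length(y))
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  XtViX <- XtVi %*% X
  beta <- solve(XtViX, XtVi %*% y)
  r <- y - X %*% beta
  -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
            t(r) %*% Vi %*% r)[1]
}

reml_grid_betas <- function(y, X, subject, vs_grid, ve_grid) {
  best <- -Inf; best_vs <- NA; best_ve <- NA
  for (vs in vs_grid) for (ve in ve_grid) {
    ll <- reml_loglik(y, X, subject, vs, ve)
    if (ll > best) { best <- ll; best_vs <- vs; best_ve <- ve }
  }
  Z <- stats::model.matrix(~ 0 + factor(subject))
  V <- best_vs * tcrossprod(Z) + diag(best_ve, length(y))
  Vi <- solve(V)
  beta <- solve(crossprod(X, Vi) %*% X, crossprod(X, Vi) %*% y)
  list(beta = as.numeric(beta), var_s = best_vs, var_e = best_ve)
}

# balanced two-sex longitudinal layout used in several LMM simulations
balanced_lmm_data <- function(n_subjects = 20, ages = c(90, 120, 150),
                              var_s = 4, var_e = 1, seed = 1) {
  set.seed(seed)
  d <- expand.grid(subject = seq_len(n_subjects), age_days = ages)
  d$sex <- ifelse(d$subject <= n_subjects / 2, "F", "M")
  b <- stats::rnorm(n_subjects, 0, sqrt(var_s))
  d$resid <- b[d$subject] + stats::rnorm(nrow(d), 0, sqrt(var_e))
  d
}

# a small open planar grid mesh (for boundary/flat checks)
flat_grid_mesh <- function(n = 15, spacing = 1) {
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  v <- cbind(g$x * spacing, g$y * spacing, 0)
  id <- function(i, j) (j - 1) * n + i
  f <- list()
  for (i in 1:(n - 1)) for (j in 1:(n - 1)) {
    f[[length(f) + 1]] <- c(id(i, j), id(i + 1, j), id(i + 1, j + 1))
    f[[length(f) + 1]] <- c(id(i, j), id(i + 1, j + 1), id(i, j + 1))
  }
  cortical_mesh(v, do.call(rbind, f))
}

ages_7 <- c(85, 97, 110, 122, 135, 147, 155)
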