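# Independent oracles used to cross-check the implementation.

# brute-force least squares: numerically minimize the sum of squared
# residuals over (intercept, slope) without touching lm()
ols_oracle_predict <- function(t, y, target) {
  sse <- function(par) sum((y - par[1] - par[2] * t)^2)
  fit <- optim(c(mean(y), 0), sse, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  fit <- optim(fit$par, sse, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  fit$par[1] + fit$par[2] * target
}

# exact two-sided paired signed-rank p by full enumeration of sign vectors;
# requires non-zero differences with untied absolute values
wilcoxon_enumeration_p <- function(d) {
  stopifnot(all(d != 0), !any(duplicated(abs(d))))
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}
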