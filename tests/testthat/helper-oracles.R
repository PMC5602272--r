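# Independent oracles used across the DEA tests.

# all lambda vectors on the unit simplex with the given grid step
grid_simplex <- function(n, step) {
  k <- round(1 / step)
  if (n == 1) return(matrix(1, 1, 1))
  g <- as.matrix(do.call(expand.grid, rep(list(0:k), n - 1)))
  g <- g[rowSums(g) <= k, , drop = FALSE]
  unname(cbind(g, k - rowSums(g)) / k)
}

# best radial expansion supported by a fixed set of candidate lambdas
phi_over_lambdas <- function(L, X, Y, i) {
  xin <- L %*% X
  yout <- L %*% Y
  feas <- rowSums(xin <= matrix(X[i, ] + 1e-9, nrow(L), ncol(X),
                                byrow = TRUE)) == ncol(X)
  pos <- which(Y[i, ] > 0)
  phi <- yout[, pos[1]] / Y[i, pos[1]]
  for (j in pos[-1]) phi <- pmin(phi, yout[, j] / Y[i, j])
  if (!any(feas)) return(list(phi = -Inf, lambda = NULL))
  best <- which.max(ifelse(feas, phi, -Inf))
  list(phi = phi[best], lambda = L[best, ])
}

# brute-force output-oriented BCC expansion factor: scan every lambda on a
# simplex grid, keep those using no more of any input than DMU i, take the
# best radial expansion they support; then rescan a 10x finer grid in the
# one-step neighbourhood of the coarse optimum (pure enumeration, no LP)
phi_grid_oracle <- function(X, Y, i, step = 0.01, refine = TRUE) {
  n <- nrow(X)
  coarse <- phi_over_lambdas(grid_simplex(n, step), X, Y, i)
  if (!refine || n == 1) return(coarse$phi)
  fine <- step / 10
  offsets <- as.matrix(do.call(
    expand.grid, rep(list(seq(-step, step, by = fine)), n - 1)))
  lead <- sweep(offsets, 2, coarse$lambda[-n], "+")
  keep <- rowSums(lead < -1e-12) == 0 & rowSums(lead) <= 1 + 1e-12
  L <- cbind(lead[keep, , drop = FALSE],
             1 - rowSums(lead[keep, , drop = FALSE]))
  max(coarse$phi, phi_over_lambdas(L, X, Y, i)$phi)
}

# random small DEA instance with O(1) entries
random_instance <- function(n, m, s) {
  list(X = matrix(stats::runif(n * m, 0.2, 1), n, m),
       Y = matrix(stats::runif(n * s, 0.2, 1), n, s))
}

# phase-1 expansion factors for every DMU via scipy linprog (HiGHS),
# an LP backend entirely independent of the package's simplex
scipy_bcc_phi <- function(X, Y) {
  payload <- jsonlite::toJSON(list(X = X, Y = Y), digits = NA)
  script <- '
import sys, json
import numpy as np
from scipy.optimize import linprog
d = json.load(sys.stdin)
X = np.asarray(d["X"], float); Y = np.asarray(d["Y"], float)
n, m = X.shape; s = Y.shape[1]
phis = []
for i in range(n):
    c = np.zeros(n + 1); c[-1] = -1.0
    A_ub = np.zeros((m + s, n + 1)); b_ub = np.zeros(m + s)
    A_ub[:m, :n] = X.T; b_ub[:m] = X[i]
    A_ub[m:, :n] = -Y.T; A_ub[m:, n] = Y[i]
    A_eq = np.zeros((1, n + 1)); A_eq[0, :n] = 1.0
    r = linprog(c, A_ub=A_ub, b_ub=b_ub, A_eq=A_eq, b_eq=[1.0],
                bounds=[(0, None)] * (n + 1), method="highs")
    assert r.status == 0, r.message
    phis.append(float(r.x[n]))
print(json.dumps(phis))
'
  out <- system2("python", c("-c", shQuote(script)),
                 input = as.character(payload), stdout = TRUE)
  unlist(jsonlite::fromJSON(paste(out, collapse = "")))
}

make_stratum <- function(X, Y, stratum = 1L) {
  stratum_data(stratum, sprintf("D%03d", seq_len(nrow(X))), X, Y)
}
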