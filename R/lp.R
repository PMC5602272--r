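#' Solve a small dense linear program by the two-phase simplex method
#'
#' Maximizes (or minimizes) `obj %*% x` subject to `A %*% x (dir) rhs` and
#' `x >= 0`, where `dir` is a vector of `"<="`, `">="`, `"="`. Intended for
#' the small, dense envelopment programs that arise in DEA (tens of rows,
#' up to a few hundred columns); uses a full tableau with Bland's rule, so
#' it is immune to cycling on the degenerate bases these programs produce.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n).
#' @param dir character vector of constraint directions, one of
#'   `"<="`, `">="`, `"="` per row.
#' @param rhs numeric right-hand sides (length m).
#' @param maximize logical; minimize when `FALSE`.
#' @param tol pivot / feasibility tolerance.
#' @param max_iter iteration cap across both phases.
#'
#' @return A list with elements `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"` or `"iteration_limit"`), `solution` (primal vector, only
#'   for `"optimal"`), and `objval`.
#' @keywords internal
lp_solve <- function(obj, A, dir, rhs, maximize = TRUE, tol = 1e-9,
                     max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(dir) == m, length(rhs) == m,
            all(dir %in% c("<=", ">=", "=")))
  if (!maximize) obj <- -obj

  # canonical form: rhs >= 0
  flip <- rhs < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    rhs[flip] <- -rhs[flip]
    dir[flip] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[flip]]
  }

  slack_rows <- which(dir == "<=")
  surp_rows  <- which(dir == ">=")
  art_rows   <- which(dir != "<=")   # >= and = rows need artificials
  n_slack <- length(slack_rows)
  n_surp  <- length(surp_rows)
  n_art   <- length(art_rows)

  ncol_tot <- n + n_slack + n_surp + n_art
  M <- matrix(0, m, ncol_tot)
  M[, seq_len(n)] <- A
  if (n_slack) M[cbind(slack_rows, n + seq_len(n_slack))] <- 1
  if (n_surp)  M[cbind(surp_rows, n + n_slack + seq_len(n_surp))] <- -1
  if (n_art)   M[cbind(art_rows, n + n_slack + n_surp + seq_len(n_art))] <- 1
  art_cols <- if (n_art) n + n_slack + n_surp + seq_len(n_art) else integer(0)

  basis <- integer(m)
  basis[slack_rows] <- n + seq_len(n_slack)
  basis[art_rows] <- art_cols

  # tableau: m constraint rows + 1 objective row; last column = rhs
  tab <- rbind(cbind(M, rhs), 0)

  run_simplex <- function(tab, basis, iter_left) {
    m <- nrow(tab) - 1L
    nc <- ncol(tab) - 1L
    it <- 0L
    repeat {
      if (it >= iter_left) return(list(tab = tab, basis = basis,
                                       status = "iteration_limit", iter = it))
      red <- tab[m + 1L, seq_len(nc)]
      cand <- which(red > tol)
      if (!length(cand)) return(list(tab = tab, basis = basis,
                                     status = "optimal", iter = it))
      j <- cand[1L]                         # Bland: lowest eligible index
      col <- tab[seq_len(m), j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(tab = tab, basis = basis,
                                    status = "unbounded", iter = it))
      ratio <- tab[pos, nc + 1L] / col[pos]
      r <- pos[ratio <= min(ratio) + tol]
      r <- r[which.min(basis[r])]           # Bland tie-break on leaving index
      piv <- tab[r, ] / tab[r, j]
      tab <- tab - outer(tab[, j], piv)
      tab[r, ] <- piv
      basis[r] <- j
      it <- it + 1L
    }
  }

  set_objective <- function(tab, basis, cost) {
    nc <- ncol(tab) - 1L
    zrow <- c(cost, rep(0, nc - length(cost)), 0)
    for (i in seq_along(basis)) {
      cb <- zrow[basis[i]]
      if (abs(cb) > 0) zrow <- zrow - cb * tab[i, ]
    }
    tab[nrow(tab), ] <- zrow
    tab
  }

  iters_used <- 0L
  if (n_art) {
    phase1_cost <- rep(0, ncol_tot)
    phase1_cost[art_cols] <- -1
    tab <- set_objective(tab, basis, phase1_cost)
    res <- run_simplex(tab, basis, max_iter)
    iters_used <- res$iter
    if (res$status != "optimal") {
      return(list(status = res$status, solution = NULL, objval = NA_real_))
    }
    tab <- res$tab
    basis <- res$basis
    if (-tab[m + 1L, ncol(tab)] < -1e-7) {
      # phase-1 objective is -sum(artificials); nonzero => infeasible
    }
    if (abs(tab[m + 1L, ncol(tab)]) > 1e-7) {
      return(list(status = "infeasible", solution = NULL, objval = NA_real_))
    }
    # pivot remaining artificials out of the basis where possible
    for (i in which(basis %in% art_cols)) {
      row <- tab[i, seq_len(n + n_slack + n_surp)]
      j <- which(abs(row) > tol)
      if (length(j)) {
        j <- j[1L]
        piv <- tab[i, ] / tab[i, j]
        tab <- tab - outer(tab[, j], piv)
        tab[i, ] <- piv
        basis[i] <- j
      }
    }
    # freeze artificial columns at zero for phase 2
    tab[, art_cols] <- 0
  }

  phase2_cost <- rep(0, ncol_tot)
  phase2_cost[seq_len(n)] <- obj
  tab <- set_objective(tab, basis, phase2_cost)
  res <- run_simplex(tab, basis, max_iter - iters_used)
  if (res$status != "optimal") {
    return(list(status = res$status, solution = NULL, objval = NA_real_))
  }
  tab <- res$tab
  basis <- res$basis
  x <- numeric(ncol_tot)
  x[basis] <- tab[seq_len(m), ncol(tab)]
  sol <- x[seq_len(n)]
  objval <- sum(obj * sol)
  list(status = "optimal", solution = sol,
       objval = if (maximize) objval else -objval)
}
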