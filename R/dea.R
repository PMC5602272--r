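#' Solve the output-oriented BCC envelopment problem for one DMU
#'
#' Phase 1 maximizes the radial expansion factor phi subject to
#' \deqn{\sum_j \lambda_j x_{ij} \le x_{i0},\quad
#'       \sum_j \lambda_j y_{rj} \ge \phi\, y_{r0},\quad
#'       \sum_j \lambda_j = 1,\quad \lambda_j \ge 0,}
#' i.e. the largest equiproportional expansion of the evaluated DMU's
#' outputs attainable by a convex combination of observed DMUs using no
#' more of any input. Phase 2 fixes phi at its optimum and maximizes the
#' sum of input and output slacks, so the reported intensity weights come
#' from a maximal-slack optimum: reference sets are then deterministic
#' under the degenerate alternative optima that envelopment problems
#' routinely have. Columns are scaled to unit maximum before solving and
#' slacks unscaled afterwards, guarding against the ill-conditioning of
#' mixing raw counts (~1e5) with rates (~0.5).
#'
#' @param data a [stratum_data()] object.
#' @param dmu_index row index of the DMU to evaluate.
#' @param eps_eff tolerance on phi for calling a DMU efficient.
#' @param lambda_tol threshold on intensity weights for reference-set
#'   membership.
#' @return A list of class `dea_result`: `dmu_id`, `phi`,
#'   `score` (= 1/phi), `lambdas`, `reference_set`, `input_slacks`,
#'   `output_slacks`, `projected_outputs` (= phi * y0 + output slacks),
#'   `is_efficient`, `pareto_efficient` (radially efficient with zero
#'   slacks).
#' @export
solve_bcc_output <- function(data, dmu_index, eps_eff = 1e-6,
                             lambda_tol = 1e-6) {
  stopifnot(inherits(data, "stratum_data"))
  n <- nrow(data$X)
  stopifnot(dmu_index >= 1, dmu_index <= n)
  m <- ncol(data$X)
  s <- ncol(data$Y)

  sx <- apply(data$X, 2, max); sx[sx <= 0] <- 1
  sy <- apply(data$Y, 2, max); sy[sy <= 0] <- 1
  X <- sweep(data$X, 2, sx, "/")
  Y <- sweep(data$Y, 2, sy, "/")
  x0 <- X[dmu_index, ]
  y0 <- Y[dmu_index, ]

  # phase 1: variables (lambda_1..lambda_n, phi)
  A1 <- rbind(cbind(t(X), 0),        # inputs:  X'lambda <= x0
              cbind(t(Y), -y0),      # outputs: Y'lambda - phi y0 >= 0
              c(rep(1, n), 0))       # convexity
  r1 <- lp_solve(obj = c(rep(0, n), 1), A = A1,
                 dir = c(rep("<=", m), rep(">=", s), "="),
                 rhs = c(x0, rep(0, s), 1))
  if (r1$status != "optimal") {
    stop("phase-1 LP ", r1$status, " for DMU ", data$dmu_ids[dmu_index],
         call. = FALSE)
  }
  phi <- r1$solution[n + 1L]

  # phase 2: fix phi, maximize total slack; variables (lambda, s-, s+)
  A2 <- rbind(cbind(t(X), diag(m), matrix(0, m, s)),
              cbind(t(Y), matrix(0, s, m), -diag(s)),
              c(rep(1, n), rep(0, m + s)))
  r2 <- lp_solve(obj = c(rep(0, n), rep(1, m + s)), A = A2,
                 dir = rep("=", m + s + 1L),
                 rhs = c(x0, phi * y0, 1))
  if (r2$status != "optimal") {
    stop("phase-2 LP ", r2$status, " for DMU ", data$dmu_ids[dmu_index],
         call. = FALSE)
  }
  lambda <- r2$solution[seq_len(n)]
  lambda[lambda < 0] <- 0
  s_in <- r2$solution[n + seq_len(m)] * sx
  s_out <- r2$solution[n + m + seq_len(s)] * sy
  s_in[s_in < 0] <- 0
  s_out[s_out < 0] <- 0

  is_eff <- phi <= 1 + eps_eff
  ref <- which(lambda > lambda_tol)
  if (is_eff && !(dmu_index %in% ref)) ref <- sort(c(ref, dmu_index))
  y_obs <- data$Y[dmu_index, ]

  structure(list(
    dmu_id = data$dmu_ids[dmu_index],
    phi = phi,
    score = 1 / phi,
    lambdas = stats::setNames(lambda, data$dmu_ids),
    reference_set = data$dmu_ids[ref],
    input_slacks = stats::setNames(s_in, colnames(data$X)),
    output_slacks = stats::setNames(s_out, colnames(data$Y)),
    projected_outputs = stats::setNames(phi * y_obs + s_out,
                                        colnames(data$Y)),
    is_efficient = is_eff,
    pareto_efficient = is_eff && all(c(s_in, s_out) <= 1e-6 * c(sx, sy)),
    observed_outputs = y_obs), class = "dea_result")
}

#' Radial projection of observed outputs onto the frontier
#'
#' The headline efficiency target: every output expanded by the same
#' factor phi. Slacks are reported separately by [solve_bcc_output()] and
#' not folded into this equiproportional target.
#'
#' @param result a `dea_result`.
#' @param observed_outputs output vector of the evaluated DMU.
#' @return `phi * observed_outputs`.
#' @export
projection <- function(result, observed_outputs) {
  stopifnot(inherits(result, "dea_result"),
            length(observed_outputs) == length(result$output_slacks))
  result$phi * observed_outputs
}

#' Estimate the efficiency frontier of one stratum
#'
#' Solves the output-oriented BCC problem for every DMU against the same
#' input/output matrices, then counts, for each DMU, how many DMUs
#' (including itself) carry it in their maximal-slack reference set.
#'
#' @param data a [stratum_data()] object.
#' @param eps_eff,lambda_tol tolerances passed to [solve_bcc_output()].
#' @return An object of class `dea_frontier`: the per-DMU results, the
#'   reference counts, and the stratum data.
#' @examples
#' d <- stratum_data(1, c("A", "B"), X = matrix(c(1, 1)),
#'                   Y = matrix(c(1, 2)))
#' fr <- dea_frontier(d)
#' tidy(fr)
#' @export
dea_frontier <- function(data, eps_eff = 1e-6, lambda_tol = 1e-6) {
  stopifnot(inherits(data, "stratum_data"))
  results <- purrr::map(seq_along(data$dmu_ids), function(i) {
    tryCatch(solve_bcc_output(data, i, eps_eff, lambda_tol),
             error = function(e) {
               stop("DMU ", data$dmu_ids[i], ": ", conditionMessage(e),
                    call. = FALSE)
             })
  })
  names(results) <- data$dmu_ids
  counts <- stats::setNames(integer(length(results)), data$dmu_ids)
  for (r in results) {
    counts[r$reference_set] <- counts[r$reference_set] + 1L
  }
  structure(list(stratum = data$stratum, results = results,
                 reference_counts = counts, data = data,
                 eps_eff = eps_eff, lambda_tol = lambda_tol),
            class = "dea_frontier")
}

#' @export
print.dea_frontier <- function(x, ...) {
  n <- length(x$results)
  eff <- sum(purrr::map_lgl(x$results, "is_efficient"))
  cat("<dea_frontier> stratum ", x$stratum, ": ", n, " DMUs, ", eff,
      " efficient (", sprintf("%.1f", 100 * eff / n), "%)\n", sep = "")
  invisible(x)
}

#' Tidy a DEA frontier into one row per DMU
#'
#' @param x a `dea_frontier`.
#' @param ... unused.
#' @return Tibble with `dmu_id`, `stratum`, `phi`, `score`,
#'   `is_efficient`, `pareto_efficient`, `reference_count`, and a
#'   list-column `reference_set`.
#' @export
tidy.dea_frontier <- function(x, ...) {
  tibble(
    dmu_id = purrr::map_chr(x$results, "dmu_id"),
    stratum = x$stratum,
    phi = purrr::map_dbl(x$results, "phi"),
    score = purrr::map_dbl(x$results, "score"),
    is_efficient = purrr::map_lgl(x$results, "is_efficient"),
    pareto_efficient = purrr::map_lgl(x$results, "pareto_efficient"),
    reference_count = as.integer(x$reference_counts),
    reference_set = unname(purrr::map(x$results, "reference_set")))
}

#' One-row summary of a DEA frontier
#'
#' @param x a `dea_frontier`.
#' @param ... unused.
#' @return Tibble with stratum, n, counts of efficient DMUs, the
#'   inefficient percentage, and mean/min score.
#' @export
glance.dea_frontier <- function(x, ...) {
  td <- tidy(x)
  tibble(stratum = x$stratum, n = nrow(td),
         n_efficient = sum(td$is_efficient),
         n_inefficient = sum(!td$is_efficient),
         pct_inefficient = round_half_up(
           100 * mean(!td$is_efficient), 1),
         mean_score = mean(td$score), min_score = min(td$score))
}

#' Score histogram for a DEA frontier
#'
#' @param object a `dea_frontier`.
#' @param bins histogram bin count.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.dea_frontier <- function(object, bins = 20, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$score,
                                   fill = .data$is_efficient)) +
    ggplot2::geom_histogram(bins = bins, boundary = 1) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey60"),
      name = "efficient") +
    ggplot2::labs(x = "efficiency score (1/phi)", y = "municipalities",
                  title = paste0("Stratum ", object$stratum,
                                 " efficiency scores")) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
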