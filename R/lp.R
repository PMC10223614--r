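# Linear and quadratic programming core.
#
# All flux problems in the package reduce to
#     optimize   c'v  (+ 1/2 v'Dv for the trade-off stage)
#     subject to S v = beq,  A v >= bineq,  lb <= v <= ub
# and are solved through quadprog's dual active-set method. Pure LPs are
# handled by proximal-point iteration on a ridge-regularized QP: for a
# polyhedral objective the iteration reaches the exact LP optimum in a
# finite number of steps, so LP objectives agree with a vertex-enumeration
# oracle to ~1e-9. Redundant equality rows (ubiquitous in stoichiometric
# matrices) are dropped by QR before each solve; quadprog occasionally
# reports spuriously inconsistent constraints on degenerate instances, in
# which case the ridge is escalated and the solve retried.

.BIG_BOUND <- 1e6

#' Solve a bounded linear program
#'
#' Maximizes (or minimizes) \code{c'v} subject to equality constraints
#' \code{Seq v = beq}, optional inequality constraints \code{Aineq v >=
#' bineq}, and variable bounds \code{lb <= v <= ub}. This is the flux
#' balance analysis workhorse: rows of \code{Seq} are metabolite
#' steady-state balances, columns are reactions.
#'
#' @param obj numeric objective coefficients, one per variable.
#' @param Seq equality constraint matrix (may have redundant rows).
#' @param beq equality right-hand side (default all zero).
#' @param Aineq optional inequality constraint matrix (\code{Aineq v >= bineq}).
#' @param bineq inequality right-hand side.
#' @param lb,ub variable bounds; infinite entries are clamped to +/- 1e6
#'   and a solution pinned at the clamp is reported as \code{"unbounded"}.
#' @param maximize logical; maximize (default) or minimize.
#' @param ridge proximal regularization weight.
#' @return list with \code{solution} (numeric vector), \code{objective},
#'   and \code{status} (\code{"optimal"}, \code{"infeasible"} or
#'   \code{"unbounded"}).
#' @examples
#' # max v s.t. v <= 10
#' solve_lp(1, Seq = matrix(0, 0, 1), lb = 0, ub = 10)$objective
#' @export
solve_lp <- function(obj, Seq, beq = NULL, Aineq = NULL, bineq = NULL,
                     lb, ub, maximize = TRUE, ridge = 1e-6) {
  n <- length(obj)
  stopifnot(ncol(Seq) == n, length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) stop("lb must not exceed ub", call. = FALSE)
  lbc <- pmax(lb, -.BIG_BOUND)
  ubc <- pmin(ub, .BIG_BOUND)
  cc <- if (maximize) obj else -obj
  if (is.null(beq)) beq <- rep(0, nrow(Seq))

  red <- .reduce_rows(Seq, beq)
  if (is.character(red)) {
    return(list(solution = NULL, objective = NA_real_, status = "infeasible"))
  }
  Seq <- red$A; beq <- red$b
  m <- nrow(Seq)

  Amat <- t(rbind(Seq, diag(n), -diag(n),
                  if (!is.null(Aineq)) Aineq))
  bvec <- c(beq, lbc, -ubc, bineq)

  # proximal iteration v <- argmax c'v - (rd/2) ||v - v_prev||^2, posed
  # with unit Dmat (well-conditioned for quadprog) and the linear term
  # scaled by 1/rd; converges to the exact LP optimum in a few steps.
  # On heavily degenerate vertices quadprog's dual active-set method can
  # stall ("constraints inconsistent"); relaxing every inequality by a
  # deterministic ~1e-9 offset splits the vertex and perturbs the
  # optimum only within that offset.
  pert <- c(rep(0, m), .degeneracy_offsets(length(bvec) - m))
  v <- rep(0, n)
  rd <- ridge
  status <- "infeasible"
  for (it in 1:50) {
    ans <- tryCatch(
      quadprog::solve.QP(Dmat = diag(n), dvec = cc / rd + v,
                         Amat = Amat, bvec = bvec, meq = m),
      error = function(e) NULL)
    if (is.null(ans)) {
      ans <- tryCatch(
        quadprog::solve.QP(Dmat = diag(n), dvec = cc / rd + v,
                           Amat = Amat, bvec = bvec - pert, meq = m),
        error = function(e) NULL)
    }
    if (is.null(ans)) {
      rd <- rd * 100
      if (rd > 1e6) break
      next
    }
    vn <- ans$solution
    converged <- max(abs(vn - v)) < 1e-9
    v <- vn
    status <- "optimal"
    if (converged && rd <= ridge * 1.01) break
    if (converged) rd <- max(ridge, rd / 100)
  }
  if (status != "optimal") {
    return(list(solution = NULL, objective = NA_real_, status = "infeasible"))
  }
  # clamp tiny bound violations from the interior refinement
  v <- pmin(pmax(v, lbc), ubc)
  free_hit <- (is.infinite(ub) & v > .BIG_BOUND - 1e-3) |
              (is.infinite(lb) & v < -.BIG_BOUND + 1e-3)
  if (any(free_hit)) {
    return(list(solution = v, objective = sum(obj * v), status = "unbounded"))
  }
  list(solution = v, objective = sum(obj * v), status = "optimal")
}

# Solve 1/2 v'Dv - d'v (minimization) under the same constraint structure.
# D must be positive definite after the caller's ridge on null directions.
solve_qp <- function(Dmat, dvec, Seq, beq = NULL, Aineq = NULL, bineq = NULL,
                     lb, ub) {
  n <- length(dvec)
  lbc <- pmax(lb, -.BIG_BOUND)
  ubc <- pmin(ub, .BIG_BOUND)
  if (is.null(beq)) beq <- rep(0, nrow(Seq))
  red <- .reduce_rows(Seq, beq)
  if (is.character(red)) {
    return(list(solution = NULL, objective = NA_real_, status = "infeasible"))
  }
  Seq <- red$A; beq <- red$b
  m <- nrow(Seq)
  Amat <- t(rbind(Seq, diag(n), -diag(n),
                  if (!is.null(Aineq)) Aineq))
  bvec <- c(beq, lbc, -ubc, bineq)
  pert <- c(rep(0, m), .degeneracy_offsets(length(bvec) - m))
  jitter <- 0
  for (it in 1:6) {
    ans <- tryCatch(
      quadprog::solve.QP(Dmat = Dmat + diag(jitter, n), dvec = dvec,
                         Amat = Amat, bvec = bvec, meq = m),
      error = function(e) NULL)
    if (is.null(ans)) {
      ans <- tryCatch(
        quadprog::solve.QP(Dmat = Dmat + diag(jitter, n), dvec = dvec,
                           Amat = Amat, bvec = bvec - pert, meq = m),
        error = function(e) NULL)
    }
    if (!is.null(ans)) {
      v <- pmin(pmax(ans$solution, lbc), ubc)
      return(list(solution = v,
                  objective = 0.5 * drop(v %*% Dmat %*% v) - sum(dvec * v),
                  status = "optimal"))
    }
    # spurious inconsistency: improve conditioning and retry
    jitter <- if (jitter == 0) 1e-6 else jitter * 100
  }
  list(solution = NULL, objective = NA_real_, status = "infeasible")
}

# Deterministic sub-1e-9 offsets used to split degenerate vertices;
# hash-based so no RNG state is consumed.
.degeneracy_offsets <- function(k) {
  if (k == 0) return(numeric(0))
  1e-9 * (((seq_len(k) * 2654435761) %% 1000003) / 1000003)
}

# Drop linearly dependent equality rows; returns reduced system or the
# string "inconsistent" if a dependent row has an inconsistent rhs.
.reduce_rows <- function(A, b, tol = 1e-9) {
  if (nrow(A) == 0) return(list(A = A, b = b))
  qrA <- qr(t(A))
  r <- qrA$rank
  if (r == nrow(A)) return(list(A = A, b = b))
  keep <- qrA$pivot[seq_len(r)]
  drop_idx <- qrA$pivot[-seq_len(r)]
  if (r > 0 && length(drop_idx)) {
    # dependent rows must have rhs implied by kept rows
    coefs <- tryCatch(qr.solve(t(A[keep, , drop = FALSE]),
                               t(A[drop_idx, , drop = FALSE])),
                      error = function(e) NULL)
    if (!is.null(coefs)) {
      implied <- drop(crossprod(coefs, b[keep]))
      if (any(abs(implied - b[drop_idx]) > tol)) return("inconsistent")
    }
  }
  list(A = A[keep, , drop = FALSE], b = b[keep])
}
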