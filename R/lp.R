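#' Solve a bounded-variable linear program
#'
#' Deterministic dense two-phase primal simplex for problems of the form
#' maximize (or minimize) `c'x` subject to `A x = b` and `lb <= x <= ub`.
#' This is the single LP backend behind [fba()], [fva()], [pfba()] and the
#' valve reference solve; one backend with a fixed pivoting rule keeps flux
#' vectors reproducible run to run.
#'
#' Bland's smallest-index rule is used for both entering and leaving
#' variables, which prevents cycling at the cost of some speed; the models
#' this package targets are small enough that this does not matter.
#' Equality-constraint duals (shadow prices) and reduced costs are returned
#' in the orientation of the *stated* problem: for a maximization,
#' `y = duals of A x = b` and `w = c - A'y`.
#'
#' @param obj Numeric objective coefficients, length `n`.
#' @param A Constraint matrix (`m x n`), dense or sparse.
#' @param b Right-hand side, length `m` (default all zero).
#' @param lb,ub Finite variable bounds, length `n`.
#' @param maximize Logical; `FALSE` minimizes.
#' @param tol Pivoting tolerance on reduced costs.
#' @param max_iter Iteration cap; exceeding it is reported as an error status.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"` or
#'   `"iteration_limit"`), `objective`, `x`, `y` (shadow prices), `w`
#'   (reduced costs).  Non-optimal statuses carry `NA` numerics.
#' @export
solve_lp <- function(obj, A, b = NULL, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = 50000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n0 <- ncol(A)
  obj <- as.numeric(obj)
  lb <- as.numeric(lb)
  ub <- as.numeric(ub)
  if (is.null(b)) b <- numeric(m)
  b <- as.numeric(b)
  stopifnot(length(obj) == n0, length(lb) == n0, length(ub) == n0,
            length(b) == m)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp requires finite variable bounds; cap infinities first",
         call. = FALSE)
  if (any(lb > ub)) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n0), y = rep(NA_real_, m),
                w = rep(NA_real_, n0)))
  }

  sense <- if (maximize) 1 else -1
  c2 <- sense * obj

  # augment with one artificial per row; its sign makes the start feasible
  x0 <- ifelse(abs(lb) <= abs(ub), lb, ub)
  r <- b - as.numeric(A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, nrow = m))
  n <- n0 + m
  lbf <- c(lb, numeric(m))
  ubf <- c(ub, abs(r) + 1)     # artificials never need to exceed their start
  costs1 <- c(numeric(n0), rep(-1, m))
  costs2 <- c(c2, numeric(m))

  stat <- c(ifelse(abs(lb) <= abs(ub), "L", "U"), rep("B", m))
  val <- c(x0, abs(r))         # tracked value for nonbasic variables
  B <- (n0 + 1L):n

  iter <- 0L
  run_phase <- function(costs) {
    repeat {
      iter <<- iter + 1L
      if (iter > max_iter) return("iteration_limit")
      AB <- Afull[, B, drop = FALSE]
      nb <- which(stat != "B")
      rhs <- b - if (length(nb)) as.numeric(Afull[, nb, drop = FALSE] %*% val[nb]) else numeric(m)
      xB <- tryCatch(solve(AB, rhs), error = function(e) NULL)
      if (is.null(xB)) return("numerical_failure")
      y <- solve(t(AB), costs[B])
      d <- costs - as.numeric(crossprod(Afull, y))
      free <- nb[lbf[nb] < ubf[nb]]
      enter_ok <- free[(stat[free] == "L" & d[free] > tol) |
                       (stat[free] == "U" & d[free] < -tol)]
      if (length(enter_ok) == 0L) {
        val[B] <<- xB
        return("optimal")
      }
      q <- min(enter_ok)                       # Bland: smallest index enters
      dir <- if (stat[q] == "L") 1 else -1
      w <- solve(AB, Afull[, q])
      # candidate step limits: own bound flip, then each basic variable
      cand_t <- ubf[q] - lbf[q]
      cand_var <- q
      cand_pos <- 0L
      delta <- -dir * w                        # change in xB per unit step
      for (i in seq_len(m)) {
        di <- delta[i]
        if (di < -tol) {
          lim <- (xB[i] - lbf[B[i]]) / (-di)
        } else if (di > tol) {
          lim <- (ubf[B[i]] - xB[i]) / di
        } else next
        lim <- max(lim, 0)
        if (lim < cand_t - 1e-12 ||
            (lim < cand_t + 1e-12 && B[i] < cand_var)) {
          cand_t <- lim
          cand_var <- B[i]
          cand_pos <- i
        }
      }
      if (!is.finite(cand_t)) return("unbounded")
      if (cand_pos == 0L) {
        # bound flip: q moves to its opposite bound, basis unchanged
        stat[q] <<- if (stat[q] == "L") "U" else "L"
        val[q] <<- if (stat[q] == "L") lbf[q] else ubf[q]
      } else {
        p <- B[cand_pos]
        hit_lower <- delta[cand_pos] < 0
        stat[p] <<- if (hit_lower) "L" else "U"
        val[p] <<- if (hit_lower) lbf[p] else ubf[p]
        val[q] <<- val[q] + dir * cand_t
        stat[q] <<- "B"
        B[cand_pos] <<- q
      }
    }
  }

  st1 <- run_phase(costs1)
  if (st1 != "optimal") {
    return(list(status = if (st1 == "unbounded") "infeasible" else st1,
                objective = NA_real_, x = rep(NA_real_, n0),
                y = rep(NA_real_, m), w = rep(NA_real_, n0)))
  }
  art <- (n0 + 1L):n
  art_sum <- sum(val[art])
  if (art_sum > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n0), y = rep(NA_real_, m),
                w = rep(NA_real_, n0)))
  }
  # pin artificials at zero for phase 2
  ubf[art] <- 0
  val[art][stat[art] != "B"] <- 0

  st2 <- run_phase(costs2)
  if (st2 != "optimal") {
    return(list(status = st2, objective = NA_real_, x = rep(NA_real_, n0),
                y = rep(NA_real_, m), w = rep(NA_real_, n0)))
  }

  x <- val[seq_len(n0)]
  AB <- Afull[, B, drop = FALSE]
  y <- as.numeric(solve(t(AB), costs2[B]))
  w <- as.numeric(c2 - crossprod(A, y))
  list(status = "optimal",
       objective = sum(obj * x),
       x = x,
       y = sense * y,
       w = sense * w)
}
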