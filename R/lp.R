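#' Solve a bounded-variable linear program
#'
#' Dense two-phase revised simplex for problems of the form
#' maximize (or minimize) \eqn{c'x} subject to \eqn{Ax = b} and
#' \eqn{l \le x \le u}. This is the optimisation core behind every flux
#' balance computation in the package; it is written for the small, often
#' highly degenerate LPs that arise from reduced metabolic networks (many
#' reactions pinned to zero by transcript bounds), where generic tableau
#' implementations tend to fail on zero right-hand sides.
#'
#' @param obj numeric objective coefficients, length n.
#' @param A constraint matrix (m x n), dense or sparse (coerced to dense).
#' @param b right-hand side, length m.
#' @param lb,ub finite variable bounds, length n.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol numeric tolerance on reduced costs and pivots.
#' @param max_iter iteration cap across both phases.
#'
#' @return list with elements `status` ("optimal", "infeasible", "unbounded"
#'   or "iteration_limit"), `x` (solution, length n) and `objective`.
#' @export
#' @examples
#' # max x3 over a 3-reaction chain with capacity 10 on the first step
#' A <- rbind(c(1, -1, 0), c(0, 1, -1))
#' lp_solve(c(0, 0, 1), A, c(0, 0), lb = rep(0, 3), ub = c(10, 100, 100))
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE, tol = 1e-9,
                     max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_solve requires finite variable bounds", call. = FALSE)
  if (any(ub < lb - 1e-12))
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  ub <- pmax(ub, lb)
  cc <- if (maximize) as.numeric(obj) else -as.numeric(obj)

  ## augment with m artificial variables forming the phase-1 basis
  x0 <- lb
  r <- b - drop(A %*% x0)
  Aa <- cbind(A, diag(ifelse(r >= 0, 1, -1), m))
  lba <- c(lb, rep(0, m))
  uba <- c(ub, abs(r) + 1)      # room for the initial artificial values
  nt <- n + m
  art <- seq.int(n + 1L, nt)

  basis <- art
  at_upper <- rep(FALSE, nt)    # status of nonbasic variables
  xx <- c(x0, abs(r))

  run_phase <- function(cvec, basis, at_upper, xx, iter_left, fixed_zero) {
    bland_after <- 500L
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > iter_left) return(list(status = "iteration_limit", basis = basis,
                                      at_upper = at_upper, xx = xx, iters = it))
      Bmat <- Aa[, basis, drop = FALSE]
      nonbasic <- setdiff(seq_len(nt), basis)
      Nmat <- Aa[, nonbasic, drop = FALSE]
      xN <- xx[nonbasic]
      xB <- tryCatch(solve(Bmat, b - drop(Nmat %*% xN)),
                     error = function(e) NULL)
      if (is.null(xB)) return(list(status = "singular", basis = basis,
                                   at_upper = at_upper, xx = xx, iters = it))
      xx[basis] <- xB
      y <- tryCatch(solve(t(Bmat), cvec[basis]), error = function(e) NULL)
      if (is.null(y)) return(list(status = "singular", basis = basis,
                                  at_upper = at_upper, xx = xx, iters = it))
      d <- cvec[nonbasic] - drop(crossprod(Nmat, y))
      ## entering candidates: improve objective moving off the current bound;
      ## variables with zero range (fixed) can never move
      range_ok <- (uba[nonbasic] - lba[nonbasic]) > tol
      if (!is.null(fixed_zero)) range_ok <- range_ok & !(nonbasic %in% fixed_zero)
      cand <- which(range_ok &
                      ((!at_upper[nonbasic] & d > tol) |
                         (at_upper[nonbasic] & d < -tol)))
      if (!length(cand)) {
        return(list(status = "optimal", basis = basis, at_upper = at_upper,
                    xx = xx, iters = it))
      }
      if (it > bland_after) {
        q_loc <- cand[which.min(nonbasic[cand])]          # Bland's rule
      } else {
        q_loc <- cand[which.max(abs(d[cand]))]            # Dantzig rule
      }
      q <- nonbasic[q_loc]
      sigma <- if (at_upper[q]) -1 else 1                 # direction of x_q
      w <- solve(Bmat, Aa[, q]) * sigma                   # x_B moves by -w * t
      ## ratio test (vectorized over the basis)
      t_flip <- uba[q] - lba[q]
      xb <- xx[basis]
      ti <- rep(Inf, m)
      dn <- w > tol
      up <- w < -tol
      ti[dn] <- (xb[dn] - lba[basis[dn]]) / w[dn]
      ti[up] <- (uba[basis[up]] - xb[up]) / (-w[up])
      i_min <- if (any(is.finite(ti))) which.min(ti) else 0L
      if (i_min > 0L && ti[i_min] < t_flip - 1e-15) {
        t_best <- ti[i_min]; leave <- i_min; leave_to_upper <- up[i_min]
      } else {
        t_best <- t_flip; leave <- 0L; leave_to_upper <- FALSE
      }
      if (is.infinite(t_best)) return(list(status = "unbounded", basis = basis,
                                           at_upper = at_upper, xx = xx, iters = it))
      t_best <- max(t_best, 0)
      xx[q] <- xx[q] + sigma * t_best
      xx[basis] <- xx[basis] - w * t_best
      if (leave == 0L) {
        at_upper[q] <- !at_upper[q]                       # bound flip, basis unchanged
      } else {
        p <- basis[leave]
        xx[p] <- if (leave_to_upper) uba[p] else lba[p]
        at_upper[p] <- leave_to_upper
        basis[leave] <- q
      }
      iter_left_local <- iter_left   # cap enforced via it
    }
  }

  ## Phase 1: minimize sum of artificials (maximize the negative)
  c1 <- c(rep(0, n), rep(-1, m))
  ph1 <- run_phase(c1, basis, at_upper, xx, max_iter, fixed_zero = NULL)
  if (ph1$status %in% c("singular", "iteration_limit"))
    return(list(status = ph1$status, x = rep(NA_real_, n), objective = NA_real_))
  art_sum <- sum(ph1$xx[art])
  if (art_sum > 1e-7)
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  ## pin artificials to zero for phase 2
  uba[art] <- 0
  xx <- ph1$xx; xx[art] <- 0
  c2 <- c(cc, rep(0, m))
  ph2 <- run_phase(c2, ph1$basis, ph1$at_upper, xx, max_iter, fixed_zero = art)
  if (ph2$status %in% c("singular", "iteration_limit"))
    return(list(status = ph2$status, x = rep(NA_real_, n), objective = NA_real_))
  if (ph2$status == "unbounded")
    return(list(status = "unbounded", x = rep(NA_real_, n), objective = NA_real_))
  x <- ph2$xx[seq_len(n)]
  x <- pmin(pmax(x, lb), ub)
  val <- sum(as.numeric(obj) * x)
  list(status = "optimal", x = x, objective = val, iterations = ph2$iters)
}
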