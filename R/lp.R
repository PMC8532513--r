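#' Linear programming by bounded-variable simplex
#'
#' Solves \deqn{\max\ c'x \quad s.t.\ A x \{\le,=,\ge\} b,\ l \le x \le u}
#' with a two-phase primal simplex supporting variable bounds directly
#' (nonbasic variables rest at either bound), Bland-style lowest-index
#' pivoting and periodic refactorisation of the basis inverse.  Sized for
#' the small stoichiometric systems this package works with (hundreds of
#' variables); slack augmentation and the artificial-variable start are
#' internal.
#'
#' @param obj objective coefficients, length n.
#' @param A dense constraint matrix, m x n.
#' @param rhs right-hand sides, length m.
#' @param sense character vector of "<=", "=", ">=" per row.
#' @param lower,upper variable bounds (may be -Inf/Inf), length n.
#' @param maximize maximize (default) or minimize.
#' @param tol pivot/feasibility tolerance.
#' @return list with `status` ("optimal", "infeasible", "unbounded"),
#'   `objective`, and `x` (length n primal solution; NA unless optimal).
#' @export
lp_solve <- function(obj, A, rhs, sense, lower, upper,
                     maximize = TRUE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(sense) == m,
            length(lower) == n, length(upper) == n)
  if (any(lower > upper + 1e-12))
    stop("lp_solve: lower bound exceeds upper bound for variable(s) ",
         paste(which(lower > upper + 1e-12), collapse = ", "))
  if (!all(sense %in% c("<=", "=", ">=")))
    stop("lp_solve: sense entries must be '<=', '=' or '>='")

  c0 <- if (maximize) as.numeric(obj) else -as.numeric(obj)

  ## slack augmentation: every row becomes an equality
  n_slack <- sum(sense != "=")
  Aeq <- cbind(A, matrix(0, m, n_slack))
  k <- n
  sl_lo <- numeric(0); sl_hi <- numeric(0)
  for (i in seq_len(m)) {
    if (sense[i] == "=") next
    k <- k + 1
    Aeq[i, k] <- if (sense[i] == "<=") 1 else -1
    sl_lo <- c(sl_lo, 0); sl_hi <- c(sl_hi, Inf)
  }
  lo <- c(lower, sl_lo); hi <- c(upper, sl_hi)
  cc <- c(c0, rep(0, n_slack))
  nt <- n + n_slack

  ## initial nonbasic values: nearest finite bound, else 0
  start_val <- ifelse(is.finite(lo), lo, ifelse(is.finite(hi), hi, 0))

  ## artificials, one per row, signed to absorb the residual
  resid <- as.numeric(rhs) - as.numeric(Aeq %*% start_val)
  art_sign <- ifelse(resid >= 0, 1, -1)
  Afull <- cbind(Aeq, diag(art_sign, m, m))
  lo_f <- c(lo, rep(0, m)); hi_f <- c(hi, rep(Inf, m))
  ntot <- nt + m
  art_idx <- (nt + 1L):ntot

  st <- list(A = Afull, b = as.numeric(rhs), lo = lo_f, hi = hi_f,
             basis = art_idx,
             Binv = diag(art_sign, m, m),   # inverse of the diagonal basis
             x = c(start_val, abs(resid)),
             status = "optimal")

  ## phase 1: minimise sum of artificials (maximise the negative)
  c1 <- c(rep(0, nt), rep(-1, m))
  st <- .simplex_iterate(st, c1, tol)
  if (st$status != "optimal" || sum(st$x[art_idx]) > 1e-7)
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  ## freeze artificials at zero for phase 2
  st$lo[art_idx] <- 0; st$hi[art_idx] <- 0
  st$x[art_idx] <- 0

  c2 <- c(cc, rep(0, m))
  st <- .simplex_iterate(st, c2, tol)
  if (st$status == "unbounded")
    return(list(status = "unbounded", objective = NA_real_,
                x = rep(NA_real_, n)))
  if (st$status != "optimal")
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  x <- st$x[seq_len(n)]
  objective <- sum(c0 * x)
  list(status = "optimal",
       objective = if (maximize) objective else -objective,
       x = x)
}

## Core pivoting loop maximising cc'x over the equality system held in `st`.
.simplex_iterate <- function(st, cc, tol) {
  A <- st$A; b <- st$b; lo <- st$lo; hi <- st$hi
  m <- nrow(A); ntot <- ncol(A)
  basis <- st$basis; Binv <- st$Binv; x <- st$x
  in_basis <- logical(ntot); in_basis[basis] <- TRUE
  freev <- !is.finite(lo) & !is.finite(hi)

  refresh <- function() {
    nb <- which(!in_basis)
    rhsv <- b - A[, nb, drop = FALSE] %*% x[nb]
    x[basis] <<- as.numeric(Binv %*% rhsv)
  }
  refresh()

  max_iter <- 200L * (m + ntot) + 2000L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter)
      stop("lp_solve: simplex iteration limit reached")
    if (iter %% 64L == 0L) {
      Binv2 <- tryCatch(solve(A[, basis, drop = FALSE]),
                        error = function(e) NULL)
      if (is.null(Binv2)) { st$status <- "infeasible"; break }
      Binv <- Binv2
      refresh()
    }
    y <- as.numeric(crossprod(Binv, cc[basis]))          # duals
    d <- cc - as.numeric(crossprod(A, y))                # reduced costs
    d[basis] <- 0
    movable <- !in_basis & (hi - lo > tol)
    at_lo <- is.finite(lo) & abs(x - lo) <= 1e-7 * (1 + abs(lo))
    at_hi <- is.finite(hi) & abs(x - hi) <= 1e-7 * (1 + abs(hi))
    up_ok <- movable & (at_lo | freev) & d >  tol
    dn_ok <- movable & ((at_hi & !at_lo) | freev) & d < -tol
    cand <- which(up_ok | dn_ok)
    if (!length(cand)) { st$status <- "optimal"; break }
    j <- cand[1L]                                        # lowest index rule
    dir <- if (up_ok[j]) 1 else -1
    w <- as.numeric(Binv %*% A[, j])

    ## ratio test (delta = change of basic values per unit entering step)
    t_best <- if (is.finite(hi[j]) && is.finite(lo[j])) hi[j] - lo[j] else Inf
    leave_pos <- 0L; leave_to <- NA_character_
    delta <- dir * w
    xb <- x[basis]
    for (i in seq_len(m)) {
      if (delta[i] > tol) {
        if (!is.finite(lo[basis[i]])) next
        ti <- (xb[i] - lo[basis[i]]) / delta[i]
        if (ti < t_best - 1e-10 ||
            (ti < t_best + 1e-10 && leave_pos > 0L &&
             basis[i] < basis[leave_pos])) {
          t_best <- ti; leave_pos <- i; leave_to <- "lo"
        }
      } else if (delta[i] < -tol) {
        if (!is.finite(hi[basis[i]])) next
        ti <- (hi[basis[i]] - xb[i]) / (-delta[i])
        if (ti < t_best - 1e-10 ||
            (ti < t_best + 1e-10 && leave_pos > 0L &&
             basis[i] < basis[leave_pos])) {
          t_best <- ti; leave_pos <- i; leave_to <- "hi"
        }
      }
    }
    if (!is.finite(t_best)) { st$status <- "unbounded"; break }
    t_best <- max(t_best, 0)

    x[basis] <- xb - delta * t_best
    if (leave_pos == 0L) {
      ## entering variable flips to its opposite bound
      x[j] <- if (dir > 0) hi[j] else lo[j]
      next
    }
    x[j] <- x[j] + dir * t_best
    lv <- basis[leave_pos]
    x[lv] <- if (leave_to == "lo") lo[lv] else hi[lv]
    basis[leave_pos] <- j
    in_basis[lv] <- FALSE; in_basis[j] <- TRUE
    piv <- w[leave_pos]
    Binv[leave_pos, ] <- Binv[leave_pos, ] / piv
    other <- setdiff(seq_len(m), leave_pos)
    Binv[other, ] <- Binv[other, ] - outer(w[other], Binv[leave_pos, ])
  }
  st$basis <- basis; st$Binv <- Binv; st$x <- x
  st
}
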