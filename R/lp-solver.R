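# Internal canonical LP:
#   min  obj' x
#   s.t. Aeq x  = beq
#        Ale x <= ble
#        lb <= x <= ub     (entries may be -Inf / +Inf)
#
# Two interchangeable backends solve this form:
#   "simplex" - the package's own bounded-variable two-phase tableau simplex
#               (Bland's rule, dense; intended for the small LPs of DFBA
#               toy/community models and for full control of statuses),
#   "boot"    - boot::simplex applied to the same standardized problem, used
#               as an independent cross-check backend.
# Both must agree on optimal objective values within solver tolerance; this
# is asserted in the test suite.

.lp_stats <- new.env(parent = emptyenv())
.lp_stats$count <- 0L

#' Reset and read the global LP solve counter
#'
#' Every call to the canonical LP solver increments a package-level counter.
#' The counter supports the linear-scaling diagnostics for community
#' simulations (LP solves per right-hand-side evaluation grow linearly in
#' the number of species models).
#'
#' @return `lp_solve_count()` returns the number of LP solves since the last
#'   reset; `reset_lp_solve_count()` resets it to zero (invisibly).
#' @export
lp_solve_count <- function() .lp_stats$count

#' @rdname lp_solve_count
#' @export
reset_lp_solve_count <- function() {
  .lp_stats$count <- 0L
  invisible(0L)
}

# Convert the canonical form to pure standard form:
#   min c' t,  A t = b (b >= 0),  t >= 0
# recording the affine map back to the original variables.
lp_standardize <- function(obj, Aeq, beq, Ale, ble, lb, ub) {
  n <- length(obj)
  A <- rbind(Aeq, Ale)
  b <- c(beq, ble)
  m_eq <- length(beq)
  m_le <- length(ble)
  m <- m_eq + m_le

  # slack columns for the inequality rows
  if (m_le > 0L) {
    slack <- rbind(
      matrix(0, m_eq, m_le),
      diag(1, m_le)
    )
  } else {
    slack <- matrix(0, m, 0L)
  }

  if (any(lb > ub)) {
    return(list(empty_box = TRUE))
  }

  # Per original variable: substitution t >= 0 with x = shift + sign * t,
  # fixed variables eliminated, free variables split.
  cols <- list()   # columns of the standardized matrix (over original rows)
  cost <- numeric(0)
  map <- list()    # per original var: how to reconstruct
  ub_rows <- list()  # rows t_j <= d appended later
  const_shift <- numeric(n)  # x = const_shift + (linear part)

  for (j in seq_len(n)) {
    aj <- A[, j, drop = TRUE]
    if (is.finite(lb[j]) && is.finite(ub[j]) && lb[j] == ub[j]) {
      map[[j]] <- list(kind = "fixed", value = lb[j])
      const_shift[j] <- lb[j]
      b <- b - aj * lb[j]
    } else if (is.finite(lb[j])) {
      k <- length(cost) + 1L
      cols[[k]] <- aj
      cost <- c(cost, obj[j])
      b <- b - aj * lb[j]
      d <- if (is.finite(ub[j])) ub[j] - lb[j] else Inf
      if (is.finite(d)) ub_rows[[length(ub_rows) + 1L]] <- c(k, d)
      map[[j]] <- list(kind = "shift", col = k, shift = lb[j], sign = 1)
    } else if (is.finite(ub[j])) {
      k <- length(cost) + 1L
      cols[[k]] <- -aj
      cost <- c(cost, -obj[j])
      b <- b - aj * ub[j]
      map[[j]] <- list(kind = "shift", col = k, shift = ub[j], sign = -1)
    } else {
      k <- length(cost) + 1L
      cols[[k]] <- aj
      cols[[k + 1L]] <- -aj
      cost <- c(cost, obj[j], -obj[j])
      map[[j]] <- list(kind = "split", col = k)
    }
  }

  n_std <- length(cost)
  As <- if (n_std > 0L) do.call(cbind, cols) else matrix(0, m, 0L)
  As <- cbind(As, slack)
  cost <- c(cost, rep(0, m_le))
  n_std <- ncol(As)

  # upper-bound rows t_k + r = d
  n_ub <- length(ub_rows)
  if (n_ub > 0L) {
    Ub <- matrix(0, n_ub, n_std)
    dub <- numeric(n_ub)
    for (i in seq_len(n_ub)) {
      Ub[i, ub_rows[[i]][1L]] <- 1
      dub[i] <- ub_rows[[i]][2L]
    }
    As <- rbind(As, cbind(Ub))
    # bound-row slacks
    As <- cbind(As, rbind(matrix(0, m, n_ub), diag(1, n_ub)))
    cost <- c(cost, rep(0, n_ub))
    b <- c(b, dub)
  }

  neg <- b < 0
  if (any(neg)) {
    As[neg, ] <- -As[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }

  # all-zero rows: inconsistent if their rhs is nonzero, redundant otherwise
  if (nrow(As) > 0L) {
    zero_row <- apply(abs(As), 1L, max) == 0
    if (any(zero_row & b > 1e-11)) {
      return(list(empty_box = FALSE, trivially_infeasible = TRUE))
    }
    if (any(zero_row)) {
      As <- As[!zero_row, , drop = FALSE]
      b <- b[!zero_row]
    }
  }

  list(
    empty_box = FALSE, trivially_infeasible = FALSE,
    A = As, b = b, cost = cost, map = map,
    n_orig = n
  )
}

# Bland's-rule tableau simplex on  min cost' t, T t = b, t >= 0 with the
# given starting basis (columns of T at `basis` must form an identity).
# Returns list(status, tab, basis, obj).
simplex_iterate <- function(tab, basis, cost, blocked = integer(0),
                            tol = 1e-9, max_iter = 10000L) {
  m <- nrow(tab)
  n <- ncol(tab) - 1L
  for (iter in seq_len(max_iter)) {
    cb <- cost[basis]
    # reduced costs
    r <- cost - as.vector(cb %*% tab[, seq_len(n), drop = FALSE])
    r[basis] <- 0
    cand <- which(r < -tol)
    if (length(blocked)) cand <- setdiff(cand, blocked)
    if (!length(cand)) {
      return(list(status = "optimal", tab = tab, basis = basis,
                  obj = sum(cb * tab[, n + 1L])))
    }
    j <- min(cand)                      # Bland: smallest entering index
    col <- tab[, j]
    pos <- which(col > tol)
    if (!length(pos)) {
      return(list(status = "unbounded", tab = tab, basis = basis,
                  obj = -Inf))
    }
    ratio <- tab[pos, n + 1L] / col[pos]
    rmin <- min(ratio)
    ties <- pos[ratio <= rmin + tol * max(1, rmin)]
    i <- ties[which.min(basis[ties])]   # Bland: smallest leaving basis index
    # pivot on (i, j)
    piv <- tab[i, j]
    tab[i, ] <- tab[i, ] / piv
    other <- setdiff(seq_len(m), i)
    tab[other, ] <- tab[other, ] - outer(tab[other, j], tab[i, ])
    basis[i] <- j
  }
  list(status = "maxiter", tab = tab, basis = basis, obj = NA_real_)
}

solve_standard_form <- function(A, b, cost, tol = 1e-9, feastol = 1e-7) {
  m <- nrow(A)
  n <- ncol(A)
  if (m == 0L) {
    # nothing but t >= 0: unbounded iff any negative cost
    t <- rep(0, n)
    if (any(cost < -tol)) return(list(status = "unbounded"))
    return(list(status = "optimal", x = t, obj = 0))
  }
  # Phase 1: artificial basis
  tab <- cbind(A, diag(1, m), b)
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(1, m))
  p1 <- simplex_iterate(tab, basis, cost1, tol = tol)
  if (p1$status != "optimal") {
    return(list(status = "numerical_failure"))
  }
  if (p1$obj > feastol) {
    return(list(status = "infeasible", phase1 = p1$obj))
  }
  tab <- p1$tab
  basis <- p1$basis
  # drive artificials out of the basis or drop redundant rows
  art <- which(basis > n)
  drop_rows <- integer(0)
  for (i in art) {
    row <- tab[i, seq_len(n)]
    piv_j <- which(abs(row) > tol)
    if (length(piv_j)) {
      j <- piv_j[1L]
      piv <- tab[i, j]
      tab[i, ] <- tab[i, ] / piv
      other <- setdiff(seq_len(nrow(tab)), i)
      tab[other, ] <- tab[other, ] - outer(tab[other, j], tab[i, ])
      basis[i] <- j
    } else {
      drop_rows <- c(drop_rows, i)
    }
  }
  if (length(drop_rows)) {
    tab <- tab[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  tab <- tab[, c(seq_len(n), n + m + 1L), drop = FALSE]
  p2 <- simplex_iterate(tab, basis, cost, tol = tol)
  if (p2$status == "unbounded") return(list(status = "unbounded"))
  if (p2$status != "optimal") return(list(status = "numerical_failure"))
  t <- rep(0, n)
  t[p2$basis] <- p2$tab[, n + 1L]
  list(status = "optimal", x = t, obj = sum(cost * t))
}

# Map a standard-form solution back to original variables.
lp_unstandardize <- function(std, t) {
  x <- numeric(std$n_orig)
  for (j in seq_along(std$map)) {
    mj <- std$map[[j]]
    x[j] <- switch(mj$kind,
      fixed = mj$value,
      shift = mj$shift + mj$sign * t[mj$col],
      split = t[mj$col] - t[mj$col + 1L]
    )
  }
  x
}

solve_canonical_simplex <- function(obj, Aeq, beq, Ale, ble, lb, ub) {
  std <- lp_standardize(obj, Aeq, beq, Ale, ble, lb, ub)
  if (std$empty_box) return(list(status = "infeasible_bounds"))
  if (std$trivially_infeasible) return(list(status = "infeasible"))
  res <- solve_standard_form(std$A, std$b, std$cost)
  if (res$status != "optimal") return(list(status = res$status))
  x <- lp_unstandardize(std, res$x)
  list(status = "optimal", objective = sum(obj * x), x = x)
}

solve_canonical_boot <- function(obj, Aeq, beq, Ale, ble, lb, ub) {
  if (!requireNamespace("boot", quietly = TRUE)) {
    stop("backend 'boot' requires the 'boot' package")
  }
  std <- lp_standardize(obj, Aeq, beq, Ale, ble, lb, ub)
  if (std$empty_box) return(list(status = "infeasible_bounds"))
  if (std$trivially_infeasible) return(list(status = "infeasible"))
  A <- std$A
  b <- std$b
  # boot::simplex mishandles linearly dependent equality rows; eliminate
  # them after checking the dependent rows are consistent with b
  if (nrow(A) > 1L) {
    qA <- qr(t(A))
    if (qA$rank < nrow(A)) {
      if (qr(t(cbind(A, b)))$rank > qA$rank) {
        return(list(status = "infeasible"))
      }
      keep <- sort(qA$pivot[seq_len(qA$rank)])
      A <- A[keep, , drop = FALSE]
      b <- b[keep]
    }
  }
  if (nrow(A) == 0L) {
    if (any(std$cost < -1e-9)) return(list(status = "unbounded"))
    x <- lp_unstandardize(std, rep(0, ncol(A)))
    return(list(status = "optimal", objective = sum(obj * x), x = x))
  }
  ans <- tryCatch(
    boot::simplex(a = std$cost, A3 = A, b3 = b, maxi = FALSE,
                  n.iter = 50L * (nrow(A) + ncol(A))),
    error = function(e) NULL
  )
  if (is.null(ans)) return(list(status = "numerical_failure"))
  if (ans$solved == -1L) return(list(status = "infeasible"))
  if (ans$solved != 1L) return(list(status = "numerical_failure"))
  x <- lp_unstandardize(std, as.numeric(ans$soln))
  list(status = "optimal", objective = sum(obj * x), x = x)
}

solve_canonical <- function(obj, Aeq, beq, Ale = NULL, ble = NULL,
                            lb, ub, backend = "simplex") {
  if (is.null(Ale)) {
    Ale <- matrix(0, 0L, length(obj))
    ble <- numeric(0)
  }
  .lp_stats$count <- .lp_stats$count + 1L
  switch(backend,
    simplex = solve_canonical_simplex(obj, Aeq, beq, Ale, ble, lb, ub),
    boot = solve_canonical_boot(obj, Aeq, beq, Ale, ble, lb, ub),
    stop("unknown LP backend: ", backend)
  )
}
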