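# LASSO path via the LARS algorithm (lasso modification) and the
# covariance test along the path. Written for the small trigonometric
# designs used here (p <= 5): the path is computed from the closed-form
# piecewise-linear solution between knots, recording the active set and
# sign vector on every interval.

# X: n x p matrix (columns expected centered; scaling handled by caller)
lars_path <- function(X, y, tol = 1e-10) {
  p <- ncol(X)
  events <- list() # each: type, var, lambda, A (active set after), s (signs after)
  lambda <- Inf
  A <- integer(0)
  s <- numeric(0)
  c_full <- drop(crossprod(X, y))
  repeat {
    if (length(A) == 0L) {
      nxt <- max(abs(c_full))
      if (nxt <= tol) break
      j <- which.max(abs(c_full))
      A <- j
      s <- sign(c_full[j])
      lambda <- nxt
      events[[length(events) + 1L]] <- list(
        type = "enter", var = j, lambda = nxt, A = A, s = s
      )
      next
    }
    XA <- X[, A, drop = FALSE]
    G <- crossprod(XA)
    w <- solve(G, drop(crossprod(XA, y)))
    q <- solve(G, s)
    cand <- numeric(0)
    cand_var <- integer(0)
    cand_type <- character(0)
    inact <- setdiff(seq_len(p), A)
    if (length(inact) > 0) {
      bj <- drop(crossprod(X[, inact, drop = FALSE], y - XA %*% w))
      aj <- drop(crossprod(X[, inact, drop = FALSE], XA %*% q))
      l1 <- bj / (1 - aj) # c_j(lam) = +lam
      l2 <- -bj / (1 + aj) # c_j(lam) = -lam
      for (ii in seq_along(inact)) {
        for (lv in c(l1[ii], l2[ii])) {
          if (is.finite(lv) && lv > tol && lv < lambda - tol) {
            cand <- c(cand, lv)
            cand_var <- c(cand_var, inact[ii])
            cand_type <- c(cand_type, "enter")
          }
        }
      }
    }
    ld <- w / q # beta_j(lam) = w_j - lam q_j = 0
    for (ii in seq_along(A)) {
      lv <- ld[ii]
      if (is.finite(lv) && lv > tol && lv < lambda - tol) {
        cand <- c(cand, lv)
        cand_var <- c(cand_var, A[ii])
        cand_type <- c(cand_type, "drop")
      }
    }
    if (length(cand) == 0L) break
    # take the largest-lambda candidate whose entry keeps the active
    # Gram matrix invertible (rank-deficient designs, e.g. 5 phases with
    # subject intercepts, cannot support a full active set)
    ord <- order(cand, decreasing = TRUE)
    k <- 0L
    for (kk in ord) {
      if (cand_type[kk] == "enter") {
        Gtry <- crossprod(X[, c(A, cand_var[kk]), drop = FALSE])
        if (rcond(Gtry) < 1e-10) next
      }
      k <- kk
      break
    }
    if (k == 0L) break
    lambda <- cand[k]
    if (cand_type[k] == "enter") {
      beta_A <- w - lambda * q
      cj <- drop(crossprod(X[, cand_var[k], drop = FALSE], y - XA %*% beta_A))
      A <- c(A, cand_var[k])
      s <- c(s, if (cj >= 0) 1 else -1)
    } else {
      keep <- A != cand_var[k]
      A <- A[keep]
      s <- s[keep]
    }
    events[[length(events) + 1L]] <- list(
      type = cand_type[k], var = cand_var[k], lambda = lambda, A = A, s = s
    )
  }
  structure(list(X = X, y = y, events = events, p = p, tol = tol),
    class = "envt_lars_path"
  )
}

lambda_max <- function(path) {
  if (length(path$events) == 0L) 0 else path$events[[1L]]$lambda
}

# lasso solution at a given lambda, replaying the recorded states
lars_solution <- function(path, lambda) {
  beta <- numeric(path$p)
  ev <- path$events
  if (length(ev) == 0L || lambda >= ev[[1L]]$lambda) {
    return(beta)
  }
  state <- NULL
  for (e in ev) {
    if (e$lambda >= lambda) state <- e else break
  }
  A <- state$A
  s <- state$s
  if (length(A) == 0L) {
    return(beta)
  }
  XA <- path$X[, A, drop = FALSE]
  G <- crossprod(XA)
  beta[A] <- solve(G, drop(crossprod(XA, path$y)) - lambda * s)
  beta
}

# covariance-test statistics at each entering event of the path;
# sigma2 normalizes. One row per entry event, in path order.
covariance_tests <- function(path, sigma2) {
  X <- path$X
  y <- path$y
  ev <- path$events
  entry_rows <- which(vapply(ev, function(e) e$type == "enter", logical(1)))
  out <- vector("list", length(entry_rows))
  for (i in seq_along(entry_rows)) {
    k <- entry_rows[i]
    lam_next <- if (k < length(ev)) ev[[k + 1L]]$lambda else 0
    beta_full <- lars_solution(path, lam_next)
    fit_full <- sum(y * (X %*% beta_full))
    A_prev <- if (k > 1L) ev[[k - 1L]]$A else integer(0)
    fit_prev <- 0
    if (length(A_prev) > 0L) {
      sub <- lars_path(X[, A_prev, drop = FALSE], y, tol = path$tol)
      beta_sub <- lars_solution(sub, lam_next)
      fit_prev <- sum(y * (X[, A_prev, drop = FALSE] %*% beta_sub))
    }
    out[[i]] <- tibble::tibble(
      entry_order = i, var = ev[[k]]$var, lambda = ev[[k]]$lambda,
      statistic = (fit_full - fit_prev) / sigma2
    )
  }
  dplyr::bind_rows(out)
}

# Monte-Carlo null table for the entry statistics under the global null
# on a given design: null_tab[b, r] = statistic of the r-th entry event
# in null draw b (sigma = 1). Closed form when the columns are
# orthonormal (sorted |X^T y| gives the knots), full LARS otherwise.
mc_null_table <- function(X, n_draws = 2000, seed = 1) {
  p <- ncol(X)
  G <- crossprod(X)
  ortho <- max(abs(G - diag(p))) < 1e-8
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  if (ortho) {
    Z <- matrix(abs(stats::rnorm(n_draws * p)), nrow = n_draws)
    Zs <- t(apply(Z, 1, sort, decreasing = TRUE))
    Znext <- cbind(Zs[, -1, drop = FALSE], 0)
    return(Zs * (Zs - Znext))
  }
  n <- nrow(X)
  tab <- matrix(NA_real_, nrow = n_draws, ncol = p)
  for (b in seq_len(n_draws)) {
    yb <- stats::rnorm(n)
    yb <- yb - mean(yb)
    pb <- lars_path(X, yb)
    ct <- covariance_tests(pb, sigma2 = 1)
    m <- min(nrow(ct), p)
    if (m > 0) tab[b, seq_len(m)] <- ct$statistic[seq_len(m)]
  }
  tab
}

# p-value of an observed entry statistic against the rank-r column of
# the Monte-Carlo null table
mc_null_p <- function(null_tab, r, stat) {
  r <- min(max(r, 1L), ncol(null_tab))
  col <- null_tab[, r]
  col <- col[is.finite(col)]
  (1 + sum(col >= stat)) / (length(col) + 1)
}
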