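# ---- elementary-symmetric-function helpers for CML -------------------------

# log-space convolution of two log-coefficient vectors
log_conv <- function(lgA, lgB) {
  nA <- length(lgA); nB <- length(lgB)
  M <- matrix(-Inf, nA + nB - 1L, nB)
  for (x in seq_len(nB)) M[x:(x + nA - 1L), x] <- lgA + lgB[x]
  row_logsumexp(M)
}

# log gamma vectors with one item left out, via prefix/suffix products
log_esf_leave_one_out <- function(le_list) {
  I <- length(le_list)
  pref <- vector("list", I + 1L); pref[[1L]] <- 0
  for (i in seq_len(I)) pref[[i + 1L]] <- log_conv(pref[[i]], le_list[[i]])
  suf <- vector("list", I + 2L); suf[[I + 1L]] <- 0
  for (i in rev(seq_len(I))) suf[[i]] <- log_conv(suf[[i + 1L]], le_list[[i]])
  lapply(seq_len(I), function(i) log_conv(pref[[i]], suf[[i + 1L]]))
}

# ---- conditional maximum likelihood fit ------------------------------------

#' Fit the partial credit model by conditional maximum likelihood
#'
#' Estimates the item thresholds of a polytomous partial credit model by
#' maximizing the likelihood of the response patterns conditional on the
#' person total scores, which eliminates the person parameters entirely.
#' The conditional likelihood is evaluated through polytomous elementary
#' symmetric functions (summation algorithm, carried in log space) and
#' maximized by Newton-Raphson with step halving, using the exact conditional
#' information matrix. Because the totals are sufficient for the person
#' locations, the resulting item estimates do not depend on the person
#' distribution -- the defining invariance property of Rasch models.
#'
#' Identifiability: the conditional likelihood is invariant to a common shift
#' of all thresholds, so the fit is normalized by centering the item
#' locations (threshold means) to zero; within an item, centered thresholds
#' tau sum to zero by construction.
#'
#' @param resp a \code{\link{response_matrix}}.
#' @param max_iter maximum Newton-Raphson iterations.
#' @param tol convergence tolerance on the gradient infinity-norm.
#' @return an object of class \code{pcm_fit}: list with \code{item_ids},
#'   \code{max_score}, \code{beta} (list of uncentered thresholds
#'   \code{delta + tau}), \code{delta} (item locations, mean 0),
#'   \code{tau} (list of centered thresholds, each summing to 0),
#'   \code{se_beta}, \code{se_delta}, \code{logLik}, \code{iterations},
#'   \code{grad_norm}, \code{n_persons}, \code{subscale_map}.
#' @export
fit_pcm <- function(resp, max_iter = 200L, tol = 1e-8) {
  stopifnot(inherits(resp, "response_matrix"))
  I <- length(resp$item_ids)
  if (I < 2L) stop("conditional estimation needs at least 2 items")
  check_null_categories(resp)
  m <- as.integer(resp$max_score)
  P <- sum(m)
  idx <- rep(seq_len(I), m)              # item index of each stacked threshold
  kk  <- unlist(lapply(m, seq_len))      # threshold index within item

  X <- resp$scores
  n <- nrow(X)
  R <- sum(m)
  totals <- rowSums(X)
  n_r <- tabulate(totals + 1L, nbins = R + 1L)
  # sufficient statistics N_ik = #{persons with x_vi >= k}
  N <- unlist(lapply(seq_len(I), function(i)
    vapply(seq_len(m[i]), function(k) sum(X[, i] >= k), 0)))

  split_beta <- function(b) split(b, idx)

  loglik <- function(b) {
    le <- lapply(split_beta(b), log_eps)
    lg <- log_esf(le)
    -sum(N * b) - sum(n_r * lg)
  }

  # gradient and Hessian of the conditional log-likelihood at b
  grad_hess <- function(b) {
    beta <- split_beta(b)
    le <- lapply(beta, log_eps)
    lg <- log_esf(le)
    lg_mi <- log_esf_leave_one_out(le)
    # per-item conditional distributions P(X_i = x | r) and tails S_i[k, r]
    S <- vector("list", I)
    for (i in seq_len(I)) {
      Pm <- matrix(-Inf, m[i] + 1L, R + 1L)
      lmi <- lg_mi[[i]]                 # defined for totals 0..R - m_i
      for (x in 0:m[i]) {
        rr <- x:(x + length(lmi) - 1L)
        Pm[x + 1L, rr + 1L] <- le[[i]][x + 1L] + lmi - lg[rr + 1L]
      }
      Pm <- exp(Pm)
      Si <- Pm[rev(seq_len(m[i] + 1L)), , drop = FALSE]
      Si <- apply(Si, 2, cumsum)[rev(seq_len(m[i] + 1L)), , drop = FALSE]
      S[[i]] <- Si[-1L, , drop = FALSE] # rows k = 1..m_i: P(X_i >= k | r)
    }
    g <- numeric(P)
    H <- matrix(0, P, P)
    off <- c(0L, cumsum(m))
    for (i in seq_len(I)) {
      a <- drop(S[[i]] %*% n_r)
      rows <- off[i] + seq_len(m[i])
      g[rows] <- -N[rows] + a
      cross <- S[[i]] %*% (n_r * t(S[[i]]))
      t1 <- outer(seq_len(m[i]), seq_len(m[i]), function(k, l) a[pmax(k, l)])
      H[rows, rows] <- -(t1 - cross)
    }
    # off-diagonal blocks need pairwise leave-two-out gammas
    for (i in seq_len(I - 1L)) {
      red <- le[-i]
      pref <- vector("list", I); pref[[1L]] <- 0
      for (q in seq_len(I - 1L)) pref[[q + 1L]] <- log_conv(pref[[q]], red[[q]])
      suf <- vector("list", I + 1L); suf[[I]] <- 0
      for (q in rev(seq_len(I - 1L))) suf[[q]] <- log_conv(suf[[q + 1L]], red[[q]])
      for (j in (i + 1L):I) {
        pos <- j - 1L                   # index of item j within `red`
        lmij <- log_conv(pref[[pos]], suf[[pos + 1L]])
        # C[s] = sum_r n_r exp(lgam_mij[r - s] - lgam[r]), s = 0..m_i + m_j
        s_max <- m[i] + m[j]
        C <- numeric(s_max + 1L)
        for (s in 0:s_max) {
          rr <- s:(s + length(lmij) - 1L)
          C[s + 1L] <- sum(n_r[rr + 1L] * exp(lmij - lg[rr + 1L]))
        }
        W <- exp(outer(le[[i]], le[[j]], `+`)) *
          matrix(C[outer(0:m[i], 0:m[j], `+`) + 1L], m[i] + 1L, m[j] + 1L)
        # T[k, l] = sum over x >= k, y >= l of W (reverse double cumsum)
        Tm <- W[rev(seq_len(m[i] + 1L)), rev(seq_len(m[j] + 1L)), drop = FALSE]
        Tm <- apply(Tm, 2, cumsum)
        Tm <- t(apply(Tm, 1, cumsum))
        Tm <- Tm[rev(seq_len(m[i] + 1L)), rev(seq_len(m[j] + 1L)), drop = FALSE]
        Tm <- Tm[-1L, -1L, drop = FALSE]
        crossij <- S[[i]] %*% (n_r * t(S[[j]]))
        blk <- -(Tm - crossij)
        ri <- off[i] + seq_len(m[i]); rj <- off[j] + seq_len(m[j])
        H[ri, rj] <- blk
        H[rj, ri] <- t(blk)
      }
    }
    list(g = g, H = H)
  }

  # free parameterization enforcing sum(b) = 0: b = c(u, -sum(u))
  to_b <- function(u) c(u, -sum(u))
  u <- numeric(P - 1L)
  ll <- loglik(to_b(u))
  iter <- 0L
  gnorm <- Inf
  repeat {
    iter <- iter + 1L
    gh <- grad_hess(to_b(u))
    g_u <- gh$g[-P] - gh$g[P]
    gnorm <- max(abs(g_u))
    if (gnorm < tol) { iter <- iter - 1L; break }
    if (iter > max_iter)
      stop(sprintf("CML did not converge after %d iterations (gradient norm %.3g)",
                   max_iter, gnorm))
    H_u <- gh$H[-P, -P, drop = FALSE] -
      outer(gh$H[-P, P], rep(1, P - 1L)) -
      outer(rep(1, P - 1L), gh$H[P, -P]) + gh$H[P, P]
    step <- tryCatch(solve(-H_u, g_u),
                     error = function(e) g_u / max(abs(diag(H_u)), 1))
    smax <- max(abs(step))
    if (smax > 5) step <- step * 5 / smax   # trust-region style cap
    sc <- 1
    repeat {
      ll_new <- loglik(to_b(u + sc * step))
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      sc <- sc / 2
      if (sc < 1e-10)
        stop(sprintf("step halving failed at iteration %d (gradient norm %.3g)",
                     iter, gnorm))
    }
    u <- u + sc * step
    ll <- ll_new
  }

  b <- to_b(u)
  gh <- grad_hess(b)
  H_u <- gh$H[-P, -P, drop = FALSE] -
    outer(gh$H[-P, P], rep(1, P - 1L)) -
    outer(rep(1, P - 1L), gh$H[P, -P]) + gh$H[P, P]
  V_u <- tryCatch(solve(-H_u), error = function(e) matrix(NA_real_, P - 1L, P - 1L))
  # map to the full stacked vector: b = M u with M = [I; -1']
  M_map <- rbind(diag(P - 1L), -1)
  Vb <- M_map %*% V_u %*% t(M_map)
  # re-center so item locations (threshold means) average zero; the
  # centering shift c(b) = mean_i mean_k b_ik is linear in b
  w <- (1 / I) / m[idx]
  b <- b - sum(w * b)
  Amat <- diag(P) - outer(rep(1, P), w)
  Vb <- Amat %*% Vb %*% t(Amat)

  beta <- split_beta(b)
  names(beta) <- resp$item_ids
  delta <- vapply(beta, mean, 0)
  tau <- lapply(seq_len(I), function(i) beta[[i]] - delta[i])
  names(tau) <- resp$item_ids
  se_beta <- split(sqrt(pmax(diag(Vb), 0)), idx)
  names(se_beta) <- resp$item_ids
  se_delta <- vapply(seq_len(I), function(i) {
    rows <- which(idx == i)
    sqrt(max(mean(Vb[rows, rows]), 0))
  }, 0)
  names(se_delta) <- resp$item_ids

  structure(list(
    item_ids = resp$item_ids, max_score = stats::setNames(m, resp$item_ids),
    beta = beta, delta = delta, tau = tau,
    se_beta = se_beta, se_delta = se_delta,
    logLik = ll, iterations = iter, grad_norm = gnorm,
    n_persons = n, subscale_map = resp$subscale_map),
    class = "pcm_fit")
}

#' @export
print.pcm_fit <- function(x, ...) {
  cat("Partial credit model (CML),", length(x$item_ids), "items,",
      x$n_persons, "persons\n")
  cat(sprintf("Converged in %d iterations (gradient norm %.2g)\n",
              x$iterations, x$grad_norm))
  print(data.frame(item = x$item_ids, location = round(x$delta, 3),
                   se = round(x$se_delta, 3), max_score = x$max_score,
                   row.names = NULL))
  invisible(x)
}

# restrict a fit to a subset of items (anchored parameters)
subset_fit <- function(fit, items) {
  stopifnot(inherits(fit, "pcm_fit"))
  missing_items <- setdiff(items, fit$item_ids)
  if (length(missing_items))
    stop("unknown item(s): ", paste(missing_items, collapse = ", "))
  out <- fit
  out$item_ids <- items
  out$max_score <- fit$max_score[items]
  out$beta <- fit$beta[items]
  out$delta <- fit$delta[items]
  out$tau <- fit$tau[items]
  out$se_beta <- fit$se_beta[items]
  out$se_delta <- fit$se_delta[items]
  out$subscale_map <- if (!is.null(fit$subscale_map)) fit$subscale_map[items]
  out
}
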