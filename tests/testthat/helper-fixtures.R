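# Shared fixtures and independent oracles. Everything here is rebuilt from
# code at test time; the expensive null-model fit is computed once and
# reused across test files.

# brute-force conditional-likelihood maximizer: enumerates every response
# pattern compatible with each observed total. Only usable for tiny
# instruments; serves as the independent oracle for the CML fitter.
cml_oracle <- function(resp) {
  m <- as.integer(resp$max_score)
  I <- length(m)
  pats <- as.matrix(expand.grid(lapply(m, function(mi) 0:mi)))
  totals_p <- rowSums(pats)
  log_eps_at <- function(beta_i, x) c(0, -cumsum(beta_i))[x + 1]
  negll <- function(u) {
    b <- c(u, -sum(u))
    bl <- split(b, rep(seq_len(I), m))
    lw <- vapply(seq_len(nrow(pats)), function(p)
      sum(vapply(seq_len(I), function(i) log_eps_at(bl[[i]], pats[p, i]), 0)), 0)
    ll <- 0
    for (v in seq_len(nrow(resp$scores))) {
      x <- resp$scores[v, ]
      lnum <- sum(vapply(seq_len(I), function(i) log_eps_at(bl[[i]], x[i]), 0))
      ll <- ll + lnum - log(sum(exp(lw[totals_p == sum(x)])))
    }
    -ll
  }
  o <- stats::optim(rep(0, sum(m) - 1), negll, method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-15))
  b <- c(o$par, -sum(o$par))
  bl <- split(b, rep(seq_len(I), m))
  b <- b - mean(vapply(bl, mean, 0))   # same normalization as fit_pcm
  split(b, rep(seq_len(I), m))
}

# grid-search person oracle: maximize the unconditional log-likelihood of a
# pattern over a fine theta grid
person_oracle <- function(beta_list, pattern, grid = seq(-8, 8, by = 1e-3)) {
  ll <- rowSums(vapply(seq_along(beta_list), function(i)
    log(pcm_probs(grid, beta_list[[i]])[, pattern[i] + 1]), numeric(length(grid))))
  grid[which.max(ll)]
}

# one correctly specified unidimensional dataset shared across files
fx <- local({
  resp <- sim_pcm(800, item_bank(), seed = 11)
  fit <- fit_pcm(resp)
  pe <- person_estimates(resp, fit)
  z <- standardized_residuals(resp, fit, pe)
  list(resp = resp, fit = fit, pe = pe, z = z)
})

# memoized multi-seed null calibration: simulate from a correctly specified
# unidimensional model, refit, and collect the summary indicators
.calib_env <- new.env()
null_calibration <- function(n_seeds = 10) {
  key <- paste0("s", n_seeds)
  if (!is.null(.calib_env[[key]])) return(.calib_env[[key]])
  out <- lapply(seq_len(n_seeds), function(s) {
    resp <- sim_pcm(800, item_bank(), seed = 1000 + s)
    fit <- fit_pcm(resp)
    pe <- person_estimates(resp, fit)
    z <- standardized_residuals(resp, fit, pe)
    chi <- item_trait_chisq(resp, fit, pe)
    fr <- item_fit_residuals(z)
    rc <- residual_correlations(z)
    list(chisq_ratio = chi$total$chisq / chi$total$df,
         fr_mean = mean(fr), fr_sd = stats::sd(fr),
         n_chisq_flagged = sum(chi$items$significant),
         rc_avg = rc$average, rc_critical = rc$critical,
         ordered = check_threshold_ordering(fit),
         psi = person_separation_index(pe)$psi)
  })
  .calib_env[[key]] <- out
  out
}
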