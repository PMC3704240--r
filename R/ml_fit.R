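#' Two-log-unit support interval from a profile-likelihood curve
#'
#' Returns the parameter range within `drop` log-likelihood units of the
#' profile maximum. Crossings between grid points are located by linear
#' interpolation of the profile; an endpoint that reaches the edge of the
#' profiled grid without crossing is flagged open.
#'
#' @param theta parameter grid (increasing).
#' @param loglik profile log likelihood at each grid point.
#' @param drop log-likelihood drop defining the interval (default 2).
#' @return list with `lower`, `upper`, `open_lower`, `open_upper`,
#'   `theta_hat` (grid argmax), `flat` (profile range < `drop`/100).
#' @export
support_interval <- function(theta, loglik, drop = 2) {
  keep <- is.finite(loglik)
  theta <- theta[keep]; loglik <- loglik[keep]
  if (!length(theta)) stop("profile has no finite values")
  imax <- which.max(loglik)
  lmax <- loglik[imax]
  thr <- lmax - drop
  flat <- diff(range(loglik)) < drop / 100
  if (flat)
    warning("profile is essentially flat; both interval ends open")
  cross <- function(i1, i2) {  # interpolate crossing between grid points
    w <- (thr - loglik[i1]) / (loglik[i2] - loglik[i1])
    theta[i1] + w * (theta[i2] - theta[i1])
  }
  # walk left
  lower <- theta[1]; open_lower <- TRUE
  if (imax > 1) {
    below <- which(loglik[1:(imax - 1)] < thr)
    if (length(below)) {
      i <- max(below)
      lower <- cross(i, i + 1); open_lower <- FALSE
    }
  } else if (loglik[1] < thr) { # degenerate: max at first point
    open_lower <- FALSE
  }
  # walk right
  n <- length(theta)
  upper <- theta[n]; open_upper <- TRUE
  if (imax < n) {
    above <- which(loglik[(imax + 1):n] < thr)
    if (length(above)) {
      i <- imax + min(above)
      upper <- cross(i, i - 1); open_upper <- FALSE
    }
  }
  if (flat) { open_lower <- TRUE; open_upper <- TRUE }
  list(lower = lower, upper = upper, open_lower = open_lower,
       open_upper = open_upper, theta_hat = theta[imax], flat = flat)
}

# moment-based starting values for (M, Ea) given beta, P
ml_start_values <- function(ancestor, lines, beta, P) {
  dM <- mean(ancestor) - mean(lines)
  dV <- max(var(lines) - var(ancestor), 1e-6)
  Ea2 <- function(Ea) Ea^2 * (beta + 1) / beta      # E[a^2] given E(a)
  Ea0 <- max(abs(dV / max(abs(dM), 1e-3)), 0.02)
  M_from_var <- dV / Ea2(Ea0)
  M0 <- if (abs(1 - 2 * P) > 0.05 && dM > 0)
    dM / ((1 - 2 * P) * Ea0) else M_from_var
  M0 <- max(min(M0, 500), 0.05)
  list(M = M0, Ea = min(max(Ea0, 1e-3), 1.5))
}

# maximize joint loglik over (log M, log alpha, log sigma) at fixed beta, P
ml_optimize_cell <- function(ancestor, lines, G, beta, P, settings) {
  s_anc <- max(sd(ancestor), settings$sigma_min * 2)
  st <- ml_start_values(ancestor, lines, beta, P)
  starts <- list(
    c(log(st$M), log(beta / st$Ea), log(s_anc)),
    c(log(st$M * 3), log(beta / (st$Ea / 3)), log(s_anc)),
    c(log(max(st$M / 3, 0.02)), log(beta / min(st$Ea * 3, 1.9)), log(s_anc)))
  starts <- starts[seq_len(min(settings$n_starts, length(starts)))]
  Mr <- settings$U_range * G
  negll <- function(th) {
    M <- exp(th[1]); alpha <- exp(th[2]); sig <- exp(th[3])
    Ea <- beta / alpha
    if (M < Mr[1] || M > Mr[2] * 1.0001 ||
        Ea < settings$Ea_range[1] / 2 || Ea > settings$Ea_range[2] * 2 ||
        sig < settings$sigma_min || sig > 2) return(1e10)
    par <- ma_params(U = M / G, G = G, P = P, alpha = alpha, beta = beta,
                     sigma_env = sig)
    ll <- ma_joint_loglik(ancestor, lines, par, settings)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      optim(th0, negll, method = "Nelder-Mead",
            control = settings$optim_control),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(NULL)
  th <- best$par
  list(beta = beta, P = P, M = exp(th[1]), U = exp(th[1]) / G,
       alpha = exp(th[2]), Ea = beta / exp(th[2]), sigma_env = exp(th[3]),
       loglik = -best$value, convergence = best$convergence)
}

# profile the joint loglik over one of U or Ea at fixed (beta, P)
ml_profile <- function(ancestor, lines, G, beta, P, settings,
                       which = c("U", "Ea"), at = NULL) {
  which <- match.arg(which)
  rng <- if (which == "U") settings$U_range else settings$Ea_range
  grid <- exp(seq(log(rng[1]), log(rng[2]),
                  length.out = settings$profile_points))
  if (!is.null(at)) {
    # a finer local grid around the point estimate sharpens the crossing
    local <- at * 10^seq(-1, 1, length.out = 13)
    grid <- sort(unique(c(grid, at,
                          local[local >= rng[1] & local <= rng[2]])))
  }
  s_anc <- max(sd(ancestor), settings$sigma_min * 2)
  dM <- mean(ancestor) - mean(lines)
  dV <- max(var(lines) - var(ancestor), 1e-6)
  clampE <- function(e) min(max(e, settings$Ea_range[1]), settings$Ea_range[2])
  clampM <- function(m) min(max(m, settings$U_range[1] * G),
                            settings$U_range[2] * G)
  prof <- rep(NA_real_, length(grid))
  warm <- NULL
  eval_point <- function(g, warm) {
    negll <- function(th) {
      if (which == "U") {
        M <- g * G; alpha <- exp(th[1]); sig <- exp(th[2])
        Ea <- beta / alpha
        if (Ea < settings$Ea_range[1] / 2 || Ea > settings$Ea_range[2] * 2)
          return(1e10)
      } else {
        alpha <- beta / g; M <- exp(th[1]); sig <- exp(th[2])
        if (M < settings$U_range[1] * G / 2 || M > settings$U_range[2] * G * 2)
          return(1e10)
      }
      if (sig < settings$sigma_min || sig > 2) return(1e10)
      par <- ma_params(U = M / G, G = G, P = P, alpha = alpha, beta = beta,
                       sigma_env = sig)
      ll <- ma_joint_loglik(ancestor, lines, par, settings)
      if (!is.finite(ll)) return(1e10)
      -ll
    }
    # moment-matched starts consistent with the fixed parameter value
    starts <- if (which == "U") {
      M_fix <- g * G
      e_mean <- if (abs(1 - 2 * P) > 0.05 && dM > 0)
        clampE(dM / ((1 - 2 * P) * M_fix)) else NULL
      e_var <- clampE(sqrt(dV / (M_fix * (beta + 1) / beta)))
      lapply(unique(c(e_mean, e_var)),
             function(e) c(log(beta / e), log(s_anc)))
    } else {
      m_mean <- if (abs(1 - 2 * P) > 0.05 && dM > 0)
        clampM(dM / ((1 - 2 * P) * g)) else NULL
      m_var <- clampM(dV / (g^2 * (beta + 1) / beta))
      lapply(unique(c(m_mean, m_var)),
             function(m) c(log(m), log(s_anc)))
    }
    if (!is.null(warm)) starts <- c(list(warm), starts)
    best <- NULL
    for (th0 in starts) {
      fit <- tryCatch(
        optim(th0, negll, method = "Nelder-Mead",
              control = settings$optim_control),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
    best
  }
  # sweep outward from the point estimate, warm-starting each optimisation
  # from its neighbour's optimum to keep the profile smooth
  i0 <- if (is.null(at)) which.max(grid > median(grid))
        else which.min(abs(grid - at))
  res0 <- eval_point(grid[i0], NULL)
  prof[i0] <- if (is.null(res0)) -Inf else -res0$value
  for (side in list(i0:length(grid), rev(seq_len(i0)))) {
    warm <- if (is.null(res0)) NULL else res0$par
    for (i in side) {
      if (!is.na(prof[i])) next
      res <- eval_point(grid[i], warm)
      if (is.null(res)) { prof[i] <- -Inf; next }
      prof[i] <- -res$value
      warm <- res$par
    }
  }
  list(theta = grid, loglik = prof)
}

#' Maximum-likelihood fit of mutational parameters
#'
#' Fits the compound-Poisson reflected-gamma model (see [line_loglik()]) to
#' ancestor replicate values and MA line means, both on the relative-fitness
#' scale. Following the grid-profile search strategy, the likelihood is
#' maximised over `(U, alpha, sigma_env)` at every combination of fixed
#' gamma shape `beta` and beneficial fraction `P` on the settings grids (60
#' cells at the defaults), the grid is then refined around the best cell,
#' and 2-log-unit support intervals for `U` and `E(a)` are obtained from
#' profile likelihoods at the best `(beta, P)`. Profile endpoints that run
#' into the search bounds are flagged open (a flat high-`U`/small-effect
#' ridge is the classic case, reported as an open upper `U` bound).
#'
#' @param ancestor numeric vector of ancestor replicate relative fitness
#'   (>= 5 values).
#' @param lines numeric vector of MA line mean relative fitness (>= 10).
#' @param G generations of accumulation.
#' @param settings an [ml_settings()].
#' @return object of class `ml_fit`: `params_hat` ([ma_params()]), `loglik`,
#'   `profile` (data frame over grid cells), `support` (per-parameter
#'   intervals with open-endedness flags), `profiles` (curves), `ridge`
#'   (TRUE when the upper `U` end is open while the lower `E(a)` end is
#'   open/boundary), `equal_effects = FALSE`.
#' @export
fit_ml <- function(ancestor, lines, G = 994, settings = ml_settings()) {
  if (length(ancestor) < 5) stop("need >= 5 ancestor replicates")
  if (length(lines) < 10) stop("need >= 10 MA lines")
  cells <- expand.grid(beta = settings$beta_grid, P = settings$P_grid)
  fits <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    fits[[i]] <- ml_optimize_cell(ancestor, lines, G,
                                  cells$beta[i], cells$P[i], settings)
    if (is.null(fits[[i]]))
      warning(sprintf("cell (beta=%g, P=%g) failed to converge; excluded",
                      cells$beta[i], cells$P[i]))
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) stop("no grid cell converged")
  prof_df <- do.call(rbind, lapply(fits, function(f)
    data.frame(beta = f$beta, P = f$P, U = f$U, Ea = f$Ea,
               sigma_env = f$sigma_env, loglik = f$loglik)))
  best <- fits[[which.max(prof_df$loglik)]]

  if (isTRUE(settings$refine)) {
    bg <- sort(settings$beta_grid); pg <- sort(settings$P_grid)
    bi <- match(best$beta, bg); pi_ <- match(best$P, pg)
    beta_cand <- unique(c(
      if (bi > 1) sqrt(bg[bi - 1] * bg[bi]),
      if (bi < length(bg)) sqrt(bg[bi] * bg[bi + 1])))
    P_cand <- unique(pmin(pmax(c(best$P - 0.05, best$P + 0.05), 0), 1))
    extra <- expand.grid(beta = unique(c(best$beta, beta_cand)),
                         P = unique(c(best$P, P_cand)))
    extra <- extra[!(extra$beta == best$beta & extra$P == best$P), ]
    for (i in seq_len(nrow(extra))) {
      f <- ml_optimize_cell(ancestor, lines, G, extra$beta[i], extra$P[i],
                            settings)
      if (is.null(f)) next
      prof_df <- rbind(prof_df,
                       data.frame(beta = f$beta, P = f$P, U = f$U, Ea = f$Ea,
                                  sigma_env = f$sigma_env, loglik = f$loglik))
      if (f$loglik > best$loglik) best <- f
    }
  }

  # profile over every (beta, P) cell that can reach within the 2-log-unit
  # band of the maximum (cells further below can never contribute), taking
  # the pointwise maximum across cells
  contrib <- prof_df[prof_df$loglik >= best$loglik - 2.5, c("beta", "P")]
  contrib <- unique(contrib)
  if (nrow(contrib) > 6) {
    ord <- order(-prof_df$loglik)
    contrib <- unique(prof_df[ord, c("beta", "P")])[1:6, ]
  }
  combine_profiles <- function(which, at) {
    curves <- lapply(seq_len(nrow(contrib)), function(i)
      ml_profile(ancestor, lines, G, contrib$beta[i], contrib$P[i],
                 settings, which = which, at = at))
    theta <- sort(unique(unlist(lapply(curves, `[[`, "theta"))))
    ll <- apply(do.call(cbind, lapply(curves, function(cv)
      approx(cv$theta, cv$loglik, xout = theta, rule = 2)$y)), 1, max)
    list(theta = theta, loglik = ll)
  }
  pu <- combine_profiles("U", best$U)
  pe <- combine_profiles("Ea", best$Ea)
  # anchor the profiles at the joint maximum
  si_u <- support_interval(pu$theta, pmin(pu$loglik, best$loglik))
  si_e <- support_interval(pe$theta, pmin(pe$loglik, best$loglik))

  params_hat <- ma_params(U = best$U, G = G, P = best$P, alpha = best$alpha,
                          beta = best$beta, sigma_env = best$sigma_env)
  structure(list(params_hat = params_hat, loglik = best$loglik,
                 profile = prof_df,
                 support = list(
                   U = list(lower = si_u$lower, upper = si_u$upper,
                            open_lower = si_u$open_lower,
                            open_upper = si_u$open_upper, flat = si_u$flat),
                   Ea = list(lower = si_e$lower, upper = si_e$upper,
                             open_lower = si_e$open_lower,
                             open_upper = si_e$open_upper, flat = si_e$flat)),
                 profiles = list(U = pu, Ea = pe),
                 ridge = si_u$open_upper,
                 equal_effects = FALSE,
                 n_lines = length(lines), n_ancestor = length(ancestor)),
            class = "ml_fit")
}

#' @export
print.ml_fit <- function(x, ...) {
  p <- x$params_hat
  fmt_int <- function(s)
    sprintf("(%s-%s)",
            if (s$open_lower) "0" else sprintf("%.4g", s$lower),
            if (s$open_upper) "Inf" else sprintf("%.4g", s$upper))
  cat(sprintf("ml_fit%s: loglik = %.3f\n",
              if (x$equal_effects) " (equal effects)" else "", x$loglik))
  cat(sprintf("  U = %.4g %s  E(a) = %.4g %s  P = %.2f  beta = %s  sigma = %.4g\n",
              p$U, fmt_int(x$support$U), p$E_a, fmt_int(x$support$Ea), p$P,
              if (x$equal_effects) "point mass" else sprintf("%.3g", p$beta),
              p$sigma_env))
  if (x$ridge)
    cat("  note: flat high-U/small-effect ridge; upper U bound open\n")
  invisible(x)
}

# explicit truncated-sum density for the equal-effects model
equal_effects_loglik <- function(z, M, a, P, sigma, settings) {
  k_max <- which(ppois(0:settings$k_max, M, lower.tail = FALSE) <
                 settings$k_tail)[1] - 1
  if (is.na(k_max)) {
    warning("mutation-count truncation cap reached")
    k_max <- settings$k_max
  }
  dens <- rep(0, length(z))
  for (k in 0:k_max) {
    pk <- dpois(k, M)
    if (pk == 0) next
    for (j in 0:k) {
      w <- pk * dbinom(j, k, P)
      if (w < 1e-14) next
      dens <- dens + w * dnorm(z - 1 - (2 * j - k) * a, 0, sigma)
    }
  }
  log(pmax(dens, 1e-300))
}

#' Maximum-likelihood fit under the equal-effects model
#'
#' Variant of [fit_ml()] in which every mutation has the same absolute
#' effect `a` (gamma shape to infinity): the line-mean density is the
#' explicit truncated Poisson-binomial mixture of normals
#' `sum_k Pois(k; M) sum_j Binom(j; k, P) N(z - 1 - (2j - k) a, sigma^2)`.
#' The likelihood is maximised over `(U, a, sigma_env)` for each `P` on the
#' settings grid.
#'
#' @inheritParams fit_ml
#' @return `ml_fit` object with `equal_effects = TRUE`; the fitted effect
#'   size is reported as `E_a` (with `beta = Inf` convention left implicit).
#' @export
fit_equal_effects <- function(ancestor, lines, G = 994,
                              settings = ml_settings()) {
  if (length(ancestor) < 5) stop("need >= 5 ancestor replicates")
  if (length(lines) < 10) stop("need >= 10 MA lines")
  s_anc <- max(sd(ancestor), settings$sigma_min * 2)
  Mr <- settings$U_range * G
  fits <- list()
  for (P in settings$P_grid) {
    st <- ml_start_values(ancestor, lines, beta = 4, P = P)
    negll <- function(th) {
      M <- exp(th[1]); a <- exp(th[2]); sig <- exp(th[3])
      if (M < Mr[1] || M > Mr[2] * 1.0001 || a < settings$Ea_range[1] / 2 ||
          a > settings$Ea_range[2] * 2 || sig < settings$sigma_min ||
          sig > 2) return(1e10)
      ll <- sum(dnorm(ancestor, 1, sig, log = TRUE)) +
        sum(equal_effects_loglik(lines, M, a, P, sig, settings))
      if (!is.finite(ll)) return(1e10)
      -ll
    }
    best <- NULL
    for (f0 in c(1, 3, 1/3)) {
      th0 <- c(log(st$M * f0), log(st$Ea), log(s_anc))
      fit <- tryCatch(optim(th0, negll, method = "Nelder-Mead",
                            control = settings$optim_control),
                      error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
    if (is.null(best)) next
    th <- best$par
    fits[[length(fits) + 1]] <-
      list(P = P, M = exp(th[1]), U = exp(th[1]) / G, a = exp(th[2]),
           sigma_env = exp(th[3]), loglik = -best$value)
  }
  if (!length(fits)) stop("no P cell converged")
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  best <- fits[[which.max(ll)]]
  prof_df <- do.call(rbind, lapply(fits, function(f)
    data.frame(beta = Inf, P = f$P, U = f$U, Ea = f$a,
               sigma_env = f$sigma_env, loglik = f$loglik)))
  # large-shape gamma as the internal representation of a point mass
  params_hat <- ma_params(U = best$U, G = G, P = best$P,
                          alpha = 1e4 / best$a, beta = 1e4,
                          sigma_env = best$sigma_env)
  structure(list(params_hat = params_hat, loglik = best$loglik,
                 profile = prof_df, support = NULL, profiles = NULL,
                 ridge = FALSE, equal_effects = TRUE,
                 n_lines = length(lines), n_ancestor = length(ancestor)),
            class = "ml_fit")
}
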