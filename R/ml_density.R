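#' Numerical settings for the likelihood machinery
#'
#' @param n_nodes number of grid nodes for density inversion (power of 2).
#' @param halfwidth_sds half-width of the density grid in SDs of the summed
#'   mutational effect (plus assay noise).
#' @param k_tail Poisson tail-mass threshold for truncating the explicit
#'   mutation-count sum used by the equal-effects model.
#' @param k_max hard cap on the truncation point.
#' @param beta_grid gamma shape values of the search grid.
#' @param P_grid beneficial-fraction values of the search grid.
#' @param U_range,Ea_range search/profile bounds for the mutation rate and
#'   mean effect (endpoints hitting these bounds are flagged open).
#' @param sigma_min lower bound on the assay SD (relative-fitness scale).
#' @param profile_points points per profile-likelihood curve.
#' @param n_starts deterministic optimiser starts per grid cell.
#' @param refine refine the (beta, P) grid around the best cell.
#' @param optim_control control list passed to [stats::optim()].
#' @return list of class `ml_settings`.
#' @export
ml_settings <- function(n_nodes = 4096, halfwidth_sds = 12,
                        k_tail = 1e-10, k_max = 60,
                        beta_grid = c(0.1, 0.5, 1, 2, 3, 4, 6, 8, 10, 50),
                        P_grid = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                        U_range = c(1e-6, 1), Ea_range = c(1e-5, 2),
                        sigma_min = 1e-4, profile_points = 41,
                        n_starts = 3, refine = TRUE,
                        optim_control = list(maxit = 400, reltol = 1e-8)) {
  stopifnot(n_nodes >= 256, length(beta_grid) > 0, length(P_grid) > 0,
            U_range[1] > 0, Ea_range[1] > 0)
  structure(list(n_nodes = n_nodes, halfwidth_sds = halfwidth_sds,
                 k_tail = k_tail, k_max = k_max, beta_grid = beta_grid,
                 P_grid = P_grid, U_range = U_range, Ea_range = Ea_range,
                 sigma_min = sigma_min, profile_points = profile_points,
                 n_starts = n_starts, refine = refine,
                 optim_control = optim_control),
            class = "ml_settings")
}

# characteristic function of Gamma(shape, rate) at t
phi_gamma <- function(t, shape, rate) (1 - 1i * t / rate)^(-shape)

# invert a characteristic function on the symmetric grid [-L, L) with N nodes
cf_invert <- function(phi, L, N) {
  dx <- 2 * L / N
  m <- 0:(N - 1)
  t <- 2 * pi * ifelse(m <= N / 2, m, m - N) / (N * dx)
  f <- Re(fft(phi(t) * exp(1i * t * L))) / (N * dx)
  list(x = -L + m * dx, f = pmax(f, 0), dx = dx)
}

# moments of the summed mutational effect S under ma_params
shift_moments <- function(par) {
  Ea <- par$beta / par$alpha
  Ea2 <- par$beta * (par$beta + 1) / par$alpha^2
  list(mean = par$M * (2 * par$P - 1) * Ea,
       sd = sqrt(par$M * Ea2))
}

#' Density of the summed effect of k mutations, j of them beneficial
#'
#' The sum is `X - Y` with `X ~ Gamma(j*beta, alpha)` and
#' `Y ~ Gamma((k-j)*beta, alpha)` (a shape-0 gamma being a point mass at 0),
#' evaluated on a symmetric grid by discrete convolution of the two gamma
#' densities.
#'
#' @param k number of mutations (>= 1).
#' @param j number of beneficial mutations, `0 <= j <= k`.
#' @param alpha,beta gamma rate and shape of a single effect magnitude.
#' @param L grid half-width; defaults to cover the sum comfortably.
#' @param n_nodes grid size.
#' @return list with `x` (grid), `f` (density values), `dx`.
#' @export
effect_sum_density <- function(k, j, alpha, beta, L = NULL, n_nodes = 4096) {
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be > 0")
  if (k < 1 || j < 0 || j > k) stop("need k >= 1 and 0 <= j <= k")
  if (is.null(L))
    L <- (k * beta / alpha) + 10 * sqrt(k * beta) / alpha + 1 / alpha
  N <- n_nodes
  dx <- 2 * L / N
  x <- -L + (0:(N - 1)) * dx
  # discretise by exact cell masses (handles the shape < 1 singularity and
  # the discontinuity at 0 without losing probability mass)
  cell_gamma <- function(shape, reflected = FALSE) {
    if (!reflected) {
      pgamma(x + dx / 2, shape, alpha) - pgamma(x - dx / 2, shape, alpha)
    } else {
      pgamma(-(x - dx / 2), shape, alpha) - pgamma(-(x + dx / 2), shape, alpha)
    }
  }
  if (j == 0) return(list(x = x, f = cell_gamma((k - j) * beta, TRUE) / dx,
                          dx = dx))
  if (j == k) return(list(x = x, f = cell_gamma(j * beta) / dx, dx = dx))
  px <- cell_gamma(j * beta)                   # positive part masses
  py <- cell_gamma((k - j) * beta, TRUE)       # reflected negative part
  co <- Re(fft(fft(px) * fft(py), inverse = TRUE)) / N
  # circular convolution of sequences centred at index N/2 each leaves the
  # sum centred at index 0 (mod N); rotate back to the grid centre
  f <- pmax(co[((0:(N - 1)) + N / 2) %% N + 1], 0) / dx
  list(x = x, f = f, dx = dx)
}

# density grid of (line mean - 1) = S + noise under par; covers obs_x
line_mean_density <- function(par, settings = ml_settings(), obs_x = 0) {
  mom <- shift_moments(par)
  sig <- par$sigma_env
  L <- max(abs(mom$mean) + settings$halfwidth_sds * (mom$sd + sig),
           max(abs(obs_x)) * 1.2 + 8 * sig,
           0.25)
  phi <- function(t) {
    phi_e <- par$P * phi_gamma(t, par$beta, par$alpha) +
      (1 - par$P) * phi_gamma(-t, par$beta, par$alpha)
    exp(par$M * (phi_e - 1) - 0.5 * sig^2 * t^2)
  }
  cf_invert(phi, L, settings$n_nodes)
}

#' Log density of observed MA line means
#'
#' Computes the log likelihood contribution of line-mean relative fitness
#' values `z` under the compound-Poisson reflected-gamma model: the number
#' of mutations per line is Poisson with mean `U*G`, each mutation's effect
#' is a reflected-gamma draw (beneficial with probability `P`), effects add
#' on the relative scale, and assay error is `Normal(0, sigma_env)`. The
#' mixture density (including the mutation-free atom smoothed by the assay
#' error) is evaluated by inverting its closed-form characteristic function
#' `exp(M*(phi_e(t) - 1) - sigma^2 t^2/2)` on a fine grid; no truncation of
#' the mutation-count sum is involved.
#'
#' @param z numeric vector of line means (relative-fitness scale).
#' @param params an [ma_params()].
#' @param settings an [ml_settings()].
#' @return vector of log densities, same length as `z`.
#' @export
line_loglik <- function(z, params, settings = ml_settings()) {
  if (any(!is.finite(z))) stop("line means must be finite")
  g <- line_mean_density(params, settings, obs_x = z - 1)
  fz <- approx(g$x, g$f, xout = z - 1, rule = 2)$y
  log(pmax(fz, 1e-300))
}

# joint log likelihood: ancestor replicates ~ N(1, sigma), lines ~ model
ma_joint_loglik <- function(ancestor, lines, par, settings) {
  sum(dnorm(ancestor, 1, par$sigma_env, log = TRUE)) +
    sum(line_loglik(lines, par, settings))
}
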