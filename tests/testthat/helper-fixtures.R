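# Shared fixtures and independent oracles. Renders are cached per session so
# several test files can reuse the same monolayer without re-rendering.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

small_flow_mono <- function() {
  cached("flow_mono", render_monolayer(monolayer_spec(
    image_px = 320, n_cells = 100, kappa_axial = 3, elongation = 2.5,
    kappa_pol = 2, seed = 42, condition = "flow")))
}

small_static_mono <- function() {
  cached("static_mono", render_monolayer(monolayer_spec(
    image_px = 320, n_cells = 100, kappa_axial = 0, kappa_pol = 0,
    elongation = 1.4, marker_mean = 4000, seed = 43, condition = "static")))
}

clean_mono_50 <- function() {
  cached("clean_50", render_monolayer(monolayer_spec(
    image_px = 300, n_cells = 50, noise_sd = 0, shot_noise = FALSE,
    seed = 7)))
}

# circular absolute error between axial angles (period 180)
axial_abs_err <- function(a, b) {
  abs(((a - b + 90) %% 180) - 90)
}

# brute-force minimum-cost one-to-one matching (independent oracle for the
# Hungarian assignment); enumerates all injections of the smaller side
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

brute_force_min_cost <- function(cost) {
  transposed <- nrow(cost) > ncol(cost)
  if (transposed) cost <- t(cost)
  n <- nrow(cost); m <- ncol(cost)
  best <- Inf
  for (cols in utils::combn(m, n, simplify = FALSE)) {
    for (p in all_perms(cols)) {
      tot <- sum(cost[cbind(seq_len(n), p)])
      if (tot < best) best <- tot
    }
  }
  best
}

# Monte-Carlo null distribution of the mean resultant length under circular
# uniformity (oracle for the Rayleigh p-value)
mc_rayleigh_p <- function(theta_deg, n_sim = 1e5, seed = 99) {
  n <- length(theta_deg)
  r_obs <- circular_mean_resultant(theta_deg)$r
  withr::with_seed(seed, {
    th <- matrix(stats::runif(n * n_sim, 0, 2 * pi), n, n_sim)
    r_sim <- sqrt(colMeans(cos(th))^2 + colMeans(sin(th))^2)
    mean(r_sim >= r_obs)
  })
}
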