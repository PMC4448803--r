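#' Simulator configuration
#'
#' Parameters of the lattice exclusion-process simulator. Agents are square
#' `s` by `s` blocks (s odd, so a block is centred exactly on a lattice
#' site) living on a `4X` by `4X` lattice with reflecting (no-flux)
#' boundaries; only the centred `X` by `X` window is observed, so the window
#' edges are not physical boundaries — mirroring how a microscope field sits
#' inside a much larger dish.
#'
#' @param X observation window side in pixels (even positive integer).
#' @param s agent side length in pixels (odd, >= 1); default 5.
#' @param rho0 target initial agent density in the window,
#'   `rho0 = n s^2 / X^2`, in (0, 1].
#' @param R proliferation probability per selection, in \[0, 1\]; default 0
#'   (pure random placement).
#' @param tau time-step duration in minutes; default 1.
#' @param T termination time in minutes; `T/tau` must be a nonnegative
#'   integer number of steps. Default 0 (no proliferation steps).
#' @param N number of replicate realizations; default 1.
#' @param seed optional RNG seed for reproducible ensembles.
#' @return A `"simulation_config"` object.
#' @examples
#' simulation_config(X = 100, s = 5, rho0 = 0.5, N = 20, seed = 1)
#' @export
simulation_config <- function(X, s = 5L, rho0, R = 0, tau = 1, T = 0,
                              N = 1L, seed = NULL) {
  X <- check_lattice_side(X)
  if (length(s) != 1L || s < 1 || s != round(s) || s %% 2 == 0) {
    stop("'s' must be an odd positive integer", call. = FALSE)
  }
  if (length(rho0) != 1L || !is.finite(rho0) || rho0 <= 0 || rho0 > 1) {
    stop("'rho0' must lie in (0, 1]", call. = FALSE)
  }
  if (length(R) != 1L || !is.finite(R) || R < 0 || R > 1) {
    stop("'R' must lie in [0, 1]", call. = FALSE)
  }
  if (tau <= 0) stop("'tau' must be positive", call. = FALSE)
  if (T < 0) stop("'T' must be nonnegative", call. = FALSE)
  steps <- T / tau
  if (abs(steps - round(steps)) > 1e-8) {
    stop("'T/tau' must be a whole number of steps", call. = FALSE)
  }
  if (N < 1 || N != round(N)) stop("'N' must be a positive integer",
                                   call. = FALSE)
  structure(
    list(X = X, s = as.integer(s), rho0 = rho0, R = R, tau = tau, T = T,
         steps = as.integer(round(steps)), N = as.integer(N),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Exclusion-process simulation config\n",
      "  window X = ", x$X, " (lattice ", 4L * x$X, "), agent s = ", x$s,
      "\n  rho0 = ", x$rho0, ", R = ", x$R, ", tau = ", x$tau,
      ", T = ", x$T, " (", x$steps, " steps)",
      "\n  N = ", x$N, " realizations",
      if (!is.null(x$seed)) paste0(", seed = ", x$seed), "\n", sep = "")
  invisible(x)
}

new_agent_state <- function(centres, L, s) {
  structure(list(centres = centres, L = as.integer(L), s = as.integer(s)),
            class = "agent_state")
}

#' @export
print.agent_state <- function(x, ...) {
  cat("Agent state:", nrow(x$centres), "agents (s =", x$s,
      ") on a", x$L, "x", x$L, "lattice\n")
  invisible(x)
}

#' Random non-overlapping placement of agents
#'
#' Places `round(rho0 * (4X)^2 / s^2)` agents uniformly at random on the
#' full `4X` by `4X` lattice by rejection sampling of centre positions, so
#' the expected density in the observation window equals `rho0`. Placement
#' near the jamming density of aligned squares may fail; in that case an
#' error suggests lowering `rho0`.
#'
#' @param cfg a [simulation_config()].
#' @return An `"agent_state"`: agent centre coordinates on the full lattice.
#' @export
random_placement <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  L <- 4L * cfg$X
  n_target <- as.integer(round(cfg$rho0 * as.numeric(L)^2 / cfg$s^2))
  max_attempts <- max(100000, 3000 * n_target)
  centres <- cpp_place_agents(L, cfg$s, n_target, max_attempts)
  new_agent_state(centres, L, cfg$s)
}

#' Run proliferation steps of the exclusion process
#'
#' Advances the agent state by `T/tau` steps of the random sequential
#' update: in each step, `n` agents (with `n` the population at the start of
#' the step) are selected uniformly with replacement, and each selected
#' agent divides with probability `R`, placing its daughter's centre exactly
#' `s` sites away along one of the four lattice directions chosen uniformly.
#' Division attempts whose daughter would overlap another agent's footprint
#' or cross the reflecting lattice boundary are aborted.
#'
#' @param state an `"agent_state"` from [random_placement()].
#' @param cfg the [simulation_config()] (supplies `R` and the step count).
#' @return The evolved `"agent_state"`.
#' @export
proliferate <- function(state, cfg) {
  stopifnot(inherits(state, "agent_state"),
            inherits(cfg, "simulation_config"))
  if (cfg$steps == 0L || cfg$R == 0) return(state)
  centres <- cpp_proliferate(state$centres, state$L, state$s, cfg$R,
                             cfg$steps)
  new_agent_state(centres, state$L, state$s)
}

#' Observe the centred window of a simulation
#'
#' Keeps the agents whose centres fall in the centred `X` by `X` window of
#' the `4X` by `4X` lattice (full-lattice rows/columns `3X/2 + 1` to
#' `5X/2`) and remaps their coordinates to `1:X`.
#'
#' @param state an `"agent_state"`.
#' @param cfg the [simulation_config()].
#' @param label optional sample label.
#' @return A [point_pattern()] of agent centres in window coordinates.
#' @export
observe_window <- function(state, cfg, label = NULL) {
  stopifnot(inherits(state, "agent_state"),
            inherits(cfg, "simulation_config"))
  X <- cfg$X
  lo <- 3L * X %/% 2L
  keep <- state$centres[, 1L] > lo & state$centres[, 1L] <= lo + X &
          state$centres[, 2L] > lo & state$centres[, 2L] <= lo + X
  point_pattern(state$centres[keep, 1L] - lo, state$centres[keep, 2L] - lo,
                X = X, label = label)
}

#' Simulate an ensemble of identically prepared patterns
#'
#' Runs `N` independent realizations (random placement followed by `T/tau`
#' proliferation steps) and returns their observation windows. When the
#' config carries a seed, per-realization sub-seeds are drawn from it so the
#' ensemble is fully reproducible.
#'
#' @param cfg a [simulation_config()].
#' @return A [sample_set()] of `N` patterns.
#' @examples
#' cfg <- simulation_config(X = 40, s = 3, rho0 = 0.2, N = 3, seed = 7)
#' ss <- simulate_ensemble(cfg)
#' ss$N
#' @export
simulate_ensemble <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, cfg$N)
  samples <- vector("list", cfg$N)
  for (i in seq_len(cfg$N)) {
    set.seed(subseeds[i])
    state <- random_placement(cfg)
    state <- proliferate(state, cfg)
    samples[[i]] <- observe_window(state, cfg,
                                   label = sprintf("realization_%d", i))
  }
  sample_set(samples, label = "simulated ensemble")
}
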