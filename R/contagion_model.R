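#' Parameters of the contact-inhibition ("contagion") division-timing model
#'
#' The model describes mitotic-wave propagation along a row of G2-arrested
#' sensory organ progenitors (SOPs). Each undivided cell accumulates a
#' pro-mitotic factor A at rate `r`, repressed by an inhibitor I that
#' undivided immediate neighbours produce at rate `mu` per neighbour:
#'
#' \deqn{dA_i/dt = r/(1 + I_i) - A_i/\rho, \quad
#'       dI_i/dt = \mu m_i(t) - I_i/\delta}
#'
#' where \eqn{m_i(t)} counts the undivided immediate neighbours of cell *i*.
#' A cell divides the first time \eqn{A_i} reaches the threshold `theta`;
#' dividing switches its inhibitory effect off, which is what propagates the
#' wave outward from the first divider.
#'
#' By default the model is non-dimensionalised: `r`, `delta` and `theta` are
#' fixed at 1, leaving `rho` (degradation time of A) and `mu` (inhibition
#' strength) as the two free parameters; a separate time-scale factor maps
#' model time to minutes (see [fit_params()]).
#'
#' @param rho Degradation time of the pro-mitotic factor A (> 0).
#' @param mu Production rate of the inhibitor I per undivided neighbour
#'   (>= 0). `mu = 0` decouples the cells completely.
#' @param r Production rate of A (> 0).
#' @param delta Degradation time of I (> 0).
#' @param theta Division threshold on A (> 0). Unless
#'   `allow_nondividing = TRUE`, `theta < r * rho` is required, otherwise an
#'   isolated cell can never divide.
#' @param dt Integration step, in model time units (> 0).
#' @param t_max Simulation horizon, in model time units (> 0).
#' @param allow_nondividing Permit parameter sets with `theta >= r * rho`.
#'
#' @return An object of class `contagion_params` (a validated list).
#' @examples
#' p <- contagion_params(rho = 20, mu = 0.65)
#' uninhibited_division_time(p)
#' @export
contagion_params <- function(rho, mu, r = 1, delta = 1, theta = 1,
                             dt = 0.01, t_max = 200,
                             allow_nondividing = FALSE) {
  stopifnot(is.numeric(rho), length(rho) == 1L, is.finite(rho),
            is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(r), is.numeric(delta), is.numeric(theta),
            is.numeric(dt), is.numeric(t_max))
  if (rho <= 0) stop("`rho` must be > 0", call. = FALSE)
  if (mu < 0) stop("`mu` must be >= 0", call. = FALSE)
  if (r <= 0) stop("`r` must be > 0", call. = FALSE)
  if (delta <= 0) stop("`delta` must be > 0", call. = FALSE)
  if (theta <= 0) stop("`theta` must be > 0", call. = FALSE)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (t_max <= 0) stop("`t_max` must be > 0", call. = FALSE)
  if (!allow_nondividing && theta >= r * rho)
    stop("`theta` >= r * rho: an isolated cell would never divide ",
         "(set allow_nondividing = TRUE to permit)", call. = FALSE)
  structure(list(rho = rho, mu = mu, r = r, delta = delta, theta = theta,
                 dt = dt, t_max = t_max),
            class = "contagion_params")
}

#' @export
print.contagion_params <- function(x, ...) {
  cat("<contagion_params>\n")
  cat(sprintf("  rho = %g, mu = %g, r = %g, delta = %g, theta = %g\n",
              x$rho, x$mu, x$r, x$delta, x$theta))
  cat(sprintf("  dt = %g, t_max = %g\n", x$dt, x$t_max))
  invisible(x)
}

#' Steady-state inhibitor level under a fixed neighbour count
#'
#' Fixed point of \eqn{dI/dt = \mu m - I/\delta}, i.e. \eqn{\mu \delta m}.
#' Used for the model's initial condition, where every cell is still
#' undivided.
#'
#' @param params A [contagion_params()] object.
#' @param m Number of undivided immediate neighbours (0, 1 or 2).
#' @return The steady-state inhibitor concentration.
#' @export
steady_state_inhibition <- function(params, m) {
  stopifnot(inherits(params, "contagion_params"))
  if (!all(m %in% 0:2))
    stop("`m` must be 0, 1 or 2 (a row cell has at most two neighbours)",
         call. = FALSE)
  params$mu * params$delta * m
}

#' Division time of an uninhibited cell (closed form)
#'
#' With no inhibition (I = 0 throughout), A follows
#' \eqn{A(t) = r\rho(1 - e^{-t/\rho})} from A(0) = 0, so the threshold
#' `theta` is reached at \eqn{t^* = -\rho \log(1 - \theta/(r\rho))}.
#' This is the exact division time of every non-seed cell when `mu = 0`,
#' and serves as the closed-form oracle for the numerical integrator.
#'
#' @inheritParams steady_state_inhibition
#' @return The threshold-crossing time, in model time units.
#' @export
uninhibited_division_time <- function(params) {
  stopifnot(inherits(params, "contagion_params"))
  if (params$theta >= params$r * params$rho)
    stop("cell never divides: theta >= r * rho", call. = FALSE)
  -params$rho * log(1 - params$theta / (params$r * params$rho))
}

#' Simulate one arm of the mitotic wave
#'
#' Integrates the contagion model for `n_cells` cells on one side of the
#' seed (the first divider, SOP0). The seed occupies index 0, is treated as
#' divided at t = 0, and is not simulated; its division releases the
#' inhibition on cell 1. Integration is fixed-step explicit Euler with the
#' division instant located by linear interpolation within the step in which
#' A crosses the threshold.
#'
#' @inheritParams steady_state_inhibition
#' @param n_cells Number of cells in the arm, excluding the seed (>= 1).
#' @param boundary Distal boundary condition. `"infinite"` (default): the
#'   distal cell behaves as if the row continued with a permanently
#'   undivided neighbour, so the arm is the head of an infinite row and the
#'   wave can never be overtaken from the far end. `"open"`: the distal
#'   cell has a single neighbour; being less inhibited it can divide before
#'   the wave reaches it, seeding a backward wave from the row end.
#' @param record_trajectories Keep sampled A and I trajectories.
#' @param record_every Sampling stride (in integration steps) for
#'   trajectories.
#' @return An object of class `simulation_result`: a list with
#'   `division_time` (named numeric, seed first at rank "0" with time 0;
#'   `NA` marks cells that did not divide within `t_max`), `params`, and,
#'   if requested, `trajectories` (list of `time`, `A`, `I`; matrices are
#'   samples x cells).
#' @examples
#' p <- contagion_params(rho = 20, mu = 0.65)
#' simulate_arm(p, n_cells = 5)$division_time
#' @export
simulate_arm <- function(params, n_cells, boundary = c("infinite", "open"),
                         record_trajectories = FALSE, record_every = 10L) {
  stopifnot(inherits(params, "contagion_params"))
  boundary <- match.arg(boundary)
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 1L)
    stop("`n_cells` must be a positive integer", call. = FALSE)
  raw <- simulate_arm_cpp(n_cells, params$r, params$mu, params$rho,
                          params$delta, params$theta, params$dt,
                          params$t_max, identical(boundary, "open"),
                          isTRUE(record_trajectories),
                          as.integer(record_every))
  div <- c(0, raw$division_time)
  names(div) <- as.character(0:n_cells)
  n_never <- sum(is.na(div))
  if (n_never > 0L)
    warning(sprintf("%d cell(s) did not divide within t_max = %g",
                    n_never, params$t_max), call. = FALSE)
  res <- list(division_time = div, params = params, n_never = n_never,
              trajectories = NULL)
  if (isTRUE(record_trajectories))
    res$trajectories <- list(time = raw$time, A = raw$A, I = raw$I)
  structure(res, class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>\n")
  cat(sprintf("  %d cell(s) + seed; %d never divided\n",
              length(x$division_time) - 1L, x$n_never))
  print(round(x$division_time, 4))
  invisible(x)
}

#' Simulate a full row: anterior and posterior arms around the seed
#'
#' The two arms of the wave are independent once the seed has divided (the
#' seed is the only shared neighbour and is divided from t = 0 on), so the
#' row is simulated as two independent [simulate_arm()] calls and assembled
#' into a rank series with signed ranks `-n_ant .. n_post` (anterior
#' negative), metric ranks `rank * spacing_um`, and times scaled by
#' `time_scale` (minutes per model time unit).
#'
#' @inheritParams simulate_arm
#' @param n_ant,n_post Number of cells anterior / posterior to the seed
#'   (each >= 0, together >= 1).
#' @param ... Passed on to [simulate_arm()] (e.g. `boundary`).
#' @param spacing_um Mean inter-SOP distance used for the metric-rank
#'   conversion (µm, > 0).
#' @param time_scale Minutes per model time unit (> 0); 1 leaves times in
#'   model units.
#' @return A [rank_series] tibble with columns `rank`, `metric_rank_um`,
#'   `time_min`.
#' @export
simulate_row <- function(params, n_ant, n_post, spacing_um = 30,
                         time_scale = 1, ...) {
  stopifnot(inherits(params, "contagion_params"))
  n_ant <- as.integer(n_ant); n_post <- as.integer(n_post)
  if (n_ant < 0L || n_post < 0L || n_ant + n_post < 1L)
    stop("need n_ant >= 0, n_post >= 0 and at least one non-seed cell",
         call. = FALSE)
  if (spacing_um <= 0) stop("`spacing_um` must be > 0", call. = FALSE)
  if (time_scale <= 0) stop("`time_scale` must be > 0", call. = FALSE)
  t_ant <- if (n_ant > 0L)
    unname(simulate_arm(params, n_ant, ...)$division_time[-1]) else numeric(0)
  t_post <- if (n_post > 0L)
    unname(simulate_arm(params, n_post, ...)$division_time[-1]) else numeric(0)
  rank <- c(-rev(seq_len(n_ant)), 0L, seq_len(n_post))
  time <- c(rev(t_ant), 0, t_post) * time_scale
  new_rank_series(rank = rank, time_min = time, spacing_um = spacing_um)
}
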