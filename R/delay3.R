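#' Third-order exponential (Erlang-3) material delay
#'
#' A cascade of three first-order stages, each with time constant
#' `tau = duration / 3`. The continuous-time step response is the Erlang-3
#' CDF; the simulator advances the cascade with explicit Euler steps. With
#' the input held constant the cascade is at a fixed point and the output
#' equals the input exactly.
#'
#' @param input0 Input level the cascade is matched to at initialization.
#' @param duration Total delay duration in days (`> 0`).
#' @param mode `"matched"` sets every stage to `input0 * duration / 3` so
#'   the initial output equals `input0`; `"zero"` starts all stages empty
#'   (output 0 regardless of `input0`).
#' @return A `delay3` state object with stage stocks `s1, s2, s3` and
#'   `tau`.
#' @examples
#' st <- delay3_init(2, 365)
#' delay3_output(st)  # 2
#' @export
delay3_init <- function(input0, duration, mode = c("matched", "zero")) {
  mode <- match.arg(mode)
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  tau <- duration / 3
  s <- if (mode == "matched") rep(input0 * tau, 3) else rep(0, 3)
  structure(list(s1 = s[1], s2 = s[2], s3 = s[3], tau = tau),
            class = "delay3")
}

#' @rdname delay3_init
#' @param state A `delay3` state.
#' @param input Current input level.
#' @param dt Euler step in days.
#' @export
delay3_step <- function(state, input, dt = 1) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  tau <- state$tau
  s1 <- state$s1 + dt * (input - state$s1 / tau)
  s2 <- state$s2 + dt * (state$s1 / tau - state$s2 / tau)
  s3 <- state$s3 + dt * (state$s2 / tau - state$s3 / tau)
  state$s1 <- s1; state$s2 <- s2; state$s3 <- s3
  state
}

#' @rdname delay3_init
#' @export
delay3_output <- function(state) state$s3 / state$tau
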