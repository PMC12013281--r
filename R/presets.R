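#' Named cohort presets for the four experimental groups
#'
#' Ships four generative scenarios — one per cell of the 2 (material:
#' probabilistic vs. mixed-deterministic) x 2 (instructions: concealed vs.
#' revealed) design — whose parameter trajectories reproduce the qualitative
#' empirical signatures of the task:
#' * probabilistic groups: a growing starting-point bias toward the regular
#'   response, growing drift-rate advantage for regular trials, declining
#'   response caution under deadline pressure, flat nondecision time, and a
#'   growing positive response-competition offset;
#' * mixed-deterministic groups: strong starting-point anticipation and a
#'   steep nondecision-time drop in deterministic blocks, higher caution
#'   maintained in deterministic blocks, no drift-rate difference between
#'   deterministic and random blocks, and a response-competition offset only
#'   when the sequence was concealed.
#'
#' All numbers are illustrative generator defaults chosen to produce
#' plausible RT and error-rate magnitudes under a 500 ms deadline; they are
#' not empirical estimates.
#'
#' @param n_participants Participants per group.
#' @return A named list of four [cohort_scenario()] objects.
#' @examples
#' presets <- preset_scenarios(n_participants = 2)
#' names(presets)
#' @export
preset_scenarios <- function(n_participants = 25L) {
  prob_base <- function(instructions, delta_reg_end, beta_end, know) {
    cohort_scenario(
      material = "probabilistic", instructions = instructions,
      n_participants = n_participants,
      alpha = trajectory(1.05, 0.92, "linear"),
      beta = trajectory(0.50, beta_end, "linear"),
      delta = list(regular = trajectory(2.6, delta_reg_end, "exponential"),
                   nonregular = trajectory(-2.6, -2.2, "linear")),
      theta = trajectory(0.21, 0.21, "constant"),
      xi = trajectory(0.0, 0.05, "linear"),
      interview_knowledge = know
    )
  }
  mixed_base <- function(instructions, beta_det, theta_det, xi_end, know) {
    cohort_scenario(
      material = "mixed_deterministic", instructions = instructions,
      n_participants = n_participants,
      alpha = list(random = trajectory(1.05, 0.92, "linear"),
                   deterministic = trajectory(1.08, 1.05, "linear")),
      beta = list(regular = trajectory(0.50, 0.54, "linear"),
                  nonregular = trajectory(0.50, 0.54, "linear"),
                  deterministic = beta_det),
      delta = list(regular = trajectory(2.6, 2.9, "linear"),
                   nonregular = trajectory(-2.6, -2.4, "linear"),
                   deterministic = trajectory(2.6, 2.9, "linear")),
      theta = list(regular = trajectory(0.21, 0.21, "constant"),
                   nonregular = trajectory(0.21, 0.21, "constant"),
                   deterministic = theta_det),
      xi = trajectory(0.0, xi_end, "linear"),
      interview_knowledge = know
    )
  }
  list(
    probabilistic_concealed =
      prob_base("concealed", delta_reg_end = 3.2, beta_end = 0.58,
                know = 0.15),
    probabilistic_revealed =
      prob_base("revealed", delta_reg_end = 3.4, beta_end = 0.55,
                know = 0.35),
    mixed_deterministic_concealed =
      mixed_base("concealed",
                 beta_det = trajectory(0.50, 0.72, "exponential"),
                 theta_det = trajectory(0.21, 0.15, "exponential"),
                 xi_end = 0.03, know = 0.65),
    mixed_deterministic_revealed =
      mixed_base("revealed",
                 beta_det = trajectory(0.62, 0.80, "exponential"),
                 theta_det = trajectory(0.18, 0.13, "exponential"),
                 xi_end = 0.0, know = 0.9)
  )
}
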