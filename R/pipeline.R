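#' Estimate lower-body kinematics from seven IMU streams
#'
#' The full pipeline: assemble the factor graph ([build_graph()]), anchor
#' the gauge freedoms ([add_gauge_priors()]), initialize from zero /
#' identity / nominal alignment ([initialize_values()]), and run on-manifold
#' Levenberg-Marquardt ([optimize_graph()]). Knee angles are derived
#' afterwards with [derive_knee_angles()].
#'
#' @param streams list of 7 IMU streams (see [read_imu_table()] /
#'   [synthesize_imu()]).
#' @param noise a [noise_spec()].
#' @param priors anthropometric priors ([default_anthro_priors()]).
#' @param config a [solver_config()].
#' @param decimation samples per keyframe interval.
#' @param nominal initial skeleton alignment ([nominal_skeleton()]).
#' @param verbose print solver progress.
#' @return an `"imu_solution"`.
#' @export
estimate_lower_body <- function(streams, noise = noise_spec(),
                                priors = default_anthro_priors(),
                                config = solver_config(),
                                decimation = noise$decimation,
                                nominal = nominal_skeleton(),
                                verbose = FALSE) {
  graph <- build_graph(streams, noise = noise, priors = priors,
                       decimation = decimation)
  graph <- add_gauge_priors(graph)
  init <- initialize_values(graph, nominal)
  optimize_graph(graph, init, config, verbose = verbose)
}
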