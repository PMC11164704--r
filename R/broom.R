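# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.soaring_eval <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.soaring_eval <- function(x, ...) {
  tibble::tibble(
    n_runs = nrow(x),
    mean_eta = mean(x$eta), sd_eta = stats::sd(x$eta),
    mean_vz = mean(x$mean_vz),
    mean_frac_in_thermal = mean(x$frac_in_thermal),
    mean_return = mean(x$return),
    crash_rate = mean(x$status == "crash"),
    instability_rate = mean(x$status == "instability")
  )
}

#' @export
tidy.activation_clusters <- function(x, ...) {
  x$sse
}

#' @export
glance.activation_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$labels),
                 sse_at_k = x$sse$sse[match(x$k, x$sse$k)])
}

#' @export
tidy.curriculum_result <- function(x, ...) {
  x$log
}

#' @export
glance.curriculum_result <- function(x, ...) {
  tibble::tibble(
    n_episodes = nrow(x$log),
    sim_time = x$agent$sim_time,
    n_checkpoints = length(x$checkpoints),
    final_stable_frac = mean(utils::tail(x$log$stable_frac, 10)),
    final_frac_in_thermal = mean(utils::tail(x$log$frac_in_thermal, 10)),
    final_mean_vz = mean(utils::tail(x$log$mean_vz, 10))
  )
}
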