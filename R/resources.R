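# Resource accounting ----------------------------------------------------------
#
# Training compute is expressed in "A100 days": the equivalent of one day on a
# single reference datacentre GPU. Other GPUs enter via a relative-throughput
# factor (e.g. a consumer card benchmarked at 0.82 of an A100). Monetary cost
# assumes an 8-GPU cloud machine billed hourly.

#' Compute specification
#' @param gpu_hours Wall-clock hours per GPU.
#' @param n_gpus Number of GPUs used.
#' @param relative_throughput Throughput of the GPU used relative to the
#'   reference A100 (default 1.0).
#' @return An object of class `compute_spec`.
#' @export
compute_spec <- function(gpu_hours, n_gpus = 1L, relative_throughput = 1.0) {
  stopifnot(gpu_hours >= 0, n_gpus >= 0, relative_throughput >= 0)
  structure(list(gpu_hours = gpu_hours, n_gpus = as.integer(n_gpus),
                 relative_throughput = relative_throughput),
            class = "compute_spec")
}

#' Cost specification
#' @param hourly_machine_price Price of one machine per hour (default 30).
#' @param gpus_per_machine GPUs per machine (default 8).
#' @return An object of class `cost_spec`.
#' @export
cost_spec <- function(hourly_machine_price = 30, gpus_per_machine = 8L) {
  stopifnot(hourly_machine_price > 0, gpus_per_machine > 0)
  structure(list(hourly_machine_price = hourly_machine_price,
                 gpus_per_machine = as.integer(gpus_per_machine)),
            class = "cost_spec")
}

#' A100-day equivalent of a compute spec
#'
#' `(gpu_hours / 24) * n_gpus * relative_throughput`, rounded to two decimals
#' for reporting. Eight hours on one GPU at factor 0.82 gives 0.27; fourteen
#' days on eight GPUs gives 112.
#'
#' @param spec A [compute_spec()].
#' @return Days (2-decimal).
#' @export
a100_day_equivalent <- function(spec) {
  stopifnot(inherits(spec, "compute_spec"))
  round(spec$gpu_hours / 24 * spec$n_gpus * spec$relative_throughput, 2)
}

#' Sum of per-stage A100 days
#' @param stage_days Nonnegative numeric vector (empty gives 0).
#' @return Total days.
#' @export
stage_sum <- function(stage_days) {
  if (length(stage_days) == 0) return(0)
  stopifnot(all(stage_days >= 0))
  sum(stage_days)
}

#' Monetary training cost from A100 days
#'
#' `(a100_days / gpus_per_machine) * 24 * hourly_machine_price`: 112 days at
#' the default $30/hour 8-GPU machine gives $10,080. Reported to whole dollars
#' above $100 and to cents below.
#'
#' @param a100_days Nonnegative days.
#' @param cost A [cost_spec()].
#' @return Currency amount.
#' @export
training_cost <- function(a100_days, cost = cost_spec()) {
  stopifnot(a100_days >= 0, inherits(cost, "cost_spec"))
  x <- a100_days / cost$gpus_per_machine * 24 * cost$hourly_machine_price
  if (x > 100) round(x) else round(x, 2)
}

#' Energy-to-emissions hook
#'
#' Converts kWh to kg CO2-equivalent with a user-supplied grid factor. No
#' factor is shipped: emission factors depend on provider, region and time,
#' so the caller must provide one.
#'
#' @param kwh Energy in kilowatt hours.
#' @param kg_co2_per_kwh User-supplied emission factor.
#' @return kg CO2-equivalent.
#' @export
co2_equivalent <- function(kwh, kg_co2_per_kwh) {
  stopifnot(kwh >= 0, kg_co2_per_kwh >= 0)
  kwh * kg_co2_per_kwh
}
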