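#' Simulate single-cell flow-cytometry fluorescence events
#'
#' Draws ungated single-cell fluorescence intensities from a log-normal
#' mixture.  One component gives the unimodal samples of a homogeneous
#' colony; two well-separated components give the bimodal samples of a
#' heterogeneous culture.  The conventional acquisition depth is 10,000
#' events per sample.
#'
#' @param components Data frame (or list coercible to one) with columns
#'   `log_mean`, `log_sd`, `weight`; weights must be non-negative and sum
#'   to 1.
#' @param n_events Number of events (> 0), default 10,000.
#' @param seed Optional RNG seed.
#' @return An object of class `event_sample`: list with `events` (numeric
#'   vector), `gate` (threshold, `NA` until set) and `positive_fraction`
#'   (`NA` until gated).
#' @export
simulate_flow_events <- function(components, n_events = 10000L,
                                 seed = NULL) {
  components <- as.data.frame(components)
  stopifnot(all(c("log_mean", "log_sd", "weight") %in% names(components)),
            n_events > 0)
  w <- components$weight
  if (any(w < 0)) stop("component weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-8) stop("component weights must sum to 1")
  draw <- function() {
    comp <- sample.int(nrow(components), n_events, replace = TRUE, prob = w)
    stats::rlnorm(n_events, components$log_mean[comp],
                  components$log_sd[comp])
  }
  ev <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(list(events = ev, gate = NA_real_,
                 positive_fraction = NA_real_),
            class = "event_sample")
}

#' Fraction of events above a gate threshold
#'
#' @param events An `event_sample` or a numeric vector of intensities
#'   (non-empty).
#' @param threshold Gate threshold (a.u.); events with intensity greater
#'   than or equal to the threshold count as positive.
#' @return For a numeric input, the positive fraction.  For an
#'   `event_sample`, the sample with `gate` and `positive_fraction` set.
#' @export
gate_fraction <- function(events, threshold) {
  v <- if (inherits(events, "event_sample")) events$events else events
  stopifnot(length(v) > 0, is.finite(threshold))
  frac <- mean(v >= threshold)
  if (inherits(events, "event_sample")) {
    events$gate <- threshold
    events$positive_fraction <- frac
    events
  } else {
    frac
  }
}

#' Estimate the number of generations in a colony from flow-cytometry counts
#'
#' A colony founded by a single cell that has grown to `X` cells has
#' undergone `n = log(X)/log(2)` generations.  The total cell count is
#' scaled up from the analyzed volume: events are counted in
#' `analyzed_volume` out of the `total_volume` in which the colony was
#' resuspended (conventionally 120 out of 400 microlitres), so
#' `X = events_counted * total_volume / analyzed_volume`, rounded to the
#' nearest cell.
#'
#' @param events_counted Number of cell events counted (> 0).
#' @param analyzed_volume Volume analyzed (microlitres).
#' @param total_volume Total resuspension volume (microlitres), at least
#'   `analyzed_volume`.
#' @return An object of class `generation_estimate`: list with
#'   `events_counted`, `analyzed_volume`, `total_volume`, `X` (total
#'   cells) and `n` (generations).
#' @export
#' @examples
#' estimate_generations(300, analyzed_volume = 120, total_volume = 400)
estimate_generations <- function(events_counted, analyzed_volume = 120,
                                 total_volume = 400) {
  stopifnot(analyzed_volume > 0, total_volume > 0,
            analyzed_volume <= total_volume)
  if (events_counted <= 0) {
    stop("no events counted: cannot estimate a generation number")
  }
  X <- round(events_counted * total_volume / analyzed_volume)
  structure(list(events_counted = events_counted,
                 analyzed_volume = analyzed_volume,
                 total_volume = total_volume,
                 X = X, n = log(X) / log(2)),
            class = "generation_estimate")
}

#' @export
print.generation_estimate <- function(x, ...) {
  cat(sprintf(
    "%g events in %g of %g uL -> X = %g cells -> n = %.3f generations\n",
    x$events_counted, x$analyzed_volume, x$total_volume, x$X, x$n))
  invisible(x)
}
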