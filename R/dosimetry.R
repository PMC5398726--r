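#' Per-worm secretion rate
#'
#' Converts a bulk venom-collection measurement (total protein from a counted
#' pool of worms over a collection window) into a per-worm rate in ng.
#'
#' @param total_protein_ug Total protein collected, micrograms.
#' @param n_worms Number of worms in the pool.
#' @param duration_h Collection window, hours.
#' @return List of class `secretion_rate`: `rate_ng` (ng per worm per window)
#'   and `duration_h`.
#' @examples
#' per_worm_rate(100, 2e6, 3)   # 0.05 ng per worm per 3 h
#' @export
per_worm_rate <- function(total_protein_ug, n_worms, duration_h) {
  if (n_worms <= 0) stop("n_worms must be positive")
  if (total_protein_ug <= 0 || duration_h <= 0)
    stop("total_protein_ug and duration_h must be positive")
  structure(list(rate_ng = total_protein_ug * 1000 / n_worms,
                 duration_h = duration_h),
            class = "secretion_rate")
}

#' Linear time extrapolation of a secretion rate
#'
#' Scales a per-worm amount measured over `duration_h` hours to a target
#' window, assuming secretion continues at a constant rate. Reported values
#' are rounded half-up to 2 decimals; set `digits = NULL` for the raw value.
#'
#' @param rate_ng ng secreted per worm over `duration_h`.
#' @param duration_h Measured window, hours (> 0).
#' @param target_h Target window, hours.
#' @param digits Decimals for reporting (default 2), or NULL for no rounding.
#' @return ng per worm per `target_h` hours.
#' @examples
#' extrapolate_rate(0.061, 3, 24)   # 0.49 ng per worm per 24 h
#' @export
extrapolate_rate <- function(rate_ng, duration_h, target_h, digits = 2) {
  if (duration_h <= 0) stop("duration_h must be positive")
  out <- rate_ng * target_h / duration_h
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Worm-equivalents of a dose
#'
#' How many worms are needed to secrete a given dose over the rate's window —
#' e.g. worms per minimum lethal dose.
#'
#' @param dose_ng Dose in ng.
#' @param per_worm_ng ng secreted per worm over the reference window (> 0).
#' @return Nearest-integer number of worms.
#' @examples
#' worm_equivalents(10, 0.49)   # ~20 worms
#' @export
worm_equivalents <- function(dose_ng, per_worm_ng) {
  if (per_worm_ng <= 0) stop("per_worm_ng must be positive")
  as.integer(round_half_up(dose_ng / per_worm_ng))
}

#' Activation-rate time-course summary
#'
#' From per-replicate counts of non-activated, partially activated and fully
#' activated worms at each time point, computes mean proportions and standard
#' errors across replicates (sd with n-1 denominator over per-replicate
#' proportions, divided by sqrt(n); 0 by convention for a single replicate).
#' Total activation is partial + full.
#'
#' @param counts data.frame `time_h`, `replicate`, `n_non`, `n_partial`,
#'   `n_full`; every replicate must have a positive worm total.
#' @return data.frame with one row per time point: mean and SE of the
#'   partial, full and total-activated proportions, plus `n_replicates`.
#' @export
activation_proportions <- function(counts) {
  need <- c("time_h", "replicate", "n_non", "n_partial", "n_full")
  if (!all(need %in% names(counts)))
    stop("counts must have columns: ", paste(need, collapse = ", "))
  tot <- counts$n_non + counts$n_partial + counts$n_full
  if (any(tot <= 0)) stop("replicate with zero total worms")
  prop <- data.frame(time_h = counts$time_h,
                     partial = counts$n_partial / tot,
                     full = counts$n_full / tot)
  prop$total <- prop$partial + prop$full
  se <- function(x) if (length(x) < 2L) 0 else stats::sd(x) / sqrt(length(x))
  agg <- function(f) as.numeric(tapply(seq_len(nrow(prop)), prop$time_h,
                                       function(i) f(i)))
  times <- sort(unique(prop$time_h))
  out <- data.frame(
    time_h = times,
    n_replicates = as.integer(table(factor(prop$time_h, levels = times))),
    mean_partial = agg(function(i) mean(prop$partial[i])),
    se_partial = agg(function(i) se(prop$partial[i])),
    mean_full = agg(function(i) mean(prop$full[i])),
    se_full = agg(function(i) se(prop$full[i])),
    mean_total = agg(function(i) mean(prop$total[i])),
    se_total = agg(function(i) se(prop$total[i])))
  rownames(out) <- NULL
  out
}
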