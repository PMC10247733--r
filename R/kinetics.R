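## Growth kinetics: doubling times from proliferation curves, stage-duration
## allocation from phase proportions, and growth-competition fitness.

#' Doubling time from a proliferation curve
#'
#' Least-squares fit of log2(count) against time per replicate; the
#' doubling time is 1/slope. Group means are reported alongside.
#'
#' @param curve Data.frame with columns `group`, `replicate`, `time_h`,
#'   `count` (counts > 0, >= 3 time points per replicate).
#' @return List: `per_replicate` (group, replicate, doubling_time_h),
#'   `group_means` (group, mean_doubling_time_h).
#' @export
doubling_time <- function(curve) {
  if (any(curve$count <= 0)) stop("fit error: non-positive counts")
  key <- interaction(curve$group, curve$replicate, drop = TRUE)
  per <- do.call(rbind, lapply(split(curve, key), function(d) {
    if (nrow(d) < 3) stop("fit error: need >= 3 time points per replicate")
    if (any(duplicated(d$time_h))) stop("fit error: duplicated time points")
    sl <- coef(lm(log2(count) ~ time_h, data = d))[["time_h"]]
    if (sl <= 0) stop("fit error: non-growing replicate (slope <= 0)")
    data.frame(group = d$group[1], replicate = d$replicate[1],
               doubling_time_h = 1 / sl, stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  gm <- aggregate(doubling_time_h ~ group, per, mean)
  names(gm)[2] <- "mean_doubling_time_h"
  list(per_replicate = per, group_means = gm)
}

#' Allocate cell-cycle stage durations from phase proportions
#'
#' Proportional mode (default): duration_s = proportion_s x doubling time,
#' so durations sum exactly to the doubling time. The age-structured mode
#' corrects for the over-representation of young cells in an asynchronous
#' exponential culture (steady-state age density 2^(1 - t/Td) * log(2)/Td):
#' stage boundaries a_s solve 2^(-a_s/Td) = 2^(-a_{s-1}/Td) - p_s/2 in the
#' supplied stage order. The correction is never applied silently.
#'
#' @param proportions Named numeric vector of phase proportions (must sum
#'   to 1 within 0.01), in cycle order for the age-structured mode.
#' @param doubling_time_h Doubling time in hours.
#' @param mode "proportional" (default) or "age_structured".
#' @return Named numeric vector of stage durations (hours).
#' @export
stage_durations <- function(proportions, doubling_time_h,
                            mode = c("proportional", "age_structured")) {
  mode <- match.arg(mode)
  if (abs(sum(proportions) - 1) > 0.01)
    stop("input error: proportions sum to ", signif(sum(proportions), 4),
         ", not 1")
  p <- proportions / sum(proportions)
  if (mode == "proportional") return(p * doubling_time_h)
  # invert the exponential steady-state age distribution
  s <- 1
  bounds <- numeric(length(p))
  for (i in seq_along(p)) {
    s_next <- s - p[i] / 2
    if (s_next <= 0) stop("input error: proportions incompatible with ",
                          "exponential age structure")
    bounds[i] <- -doubling_time_h * log2(s_next)
    s <- s_next
  }
  setNames(diff(c(0, bounds)), names(p))
}

#' Growth-competition enrichment curve and per-doubling fitness difference
#'
#' Converts percent-marked measurements to marked:unmarked ratios,
#' normalizes to the first time point, and fits log2(normalized ratio)
#' against time; the slope divided by the population doubling rate is the
#' fitness difference per doubling (-1 means the marked population halves
#' in relative abundance every doubling).
#'
#' @param time Time points (any unit, strictly increasing).
#' @param percent_marked Percent of marked cells at each time (0-100,
#'   exclusive).
#' @param doublings_per_time Population doublings per unit of `time`
#'   (default 1, i.e. `time` is measured in doublings).
#' @return List: `normalized_ratio` (series normalized to the first point),
#'   `fitness_per_doubling`.
#' @export
competition_curve <- function(time, percent_marked,
                              doublings_per_time = 1) {
  stopifnot(length(time) == length(percent_marked),
            all(diff(time) > 0))
  if (any(percent_marked <= 0 | percent_marked >= 100))
    stop("percent_marked must be strictly inside (0, 100)")
  ratio <- percent_marked / (100 - percent_marked)
  norm <- ratio / ratio[1]
  slope <- coef(lm(log2(norm) ~ time))[["time"]]
  list(normalized_ratio = norm,
       fitness_per_doubling = slope / doublings_per_time)
}
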