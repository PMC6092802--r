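#' Construct disease-specific survival records
#'
#' Disease-specific survival runs from diagnosis to death from the studied
#' cancer; deaths from other causes are censored at the death date, as are
#' patients alive at last contact.
#'
#' @param case_id Character vector.
#' @param time Non-negative follow-up times (days).
#' @param event 0/1 (or logical): 1 = death from the specific cancer.
#' @param group Optional `"Above"`/`"Below"` expression-group labels.
#' @return Data frame of class `survival_records`.
#' @export
survival_records <- function(case_id, time, event, group = NA_character_) {
  if (any(!is.finite(time)) || any(time < 0))
    stop("survival times must be finite and non-negative")
  event <- as.integer(event)
  if (any(!event %in% c(0L, 1L)))
    stop("event indicators must be 0/1")
  out <- data.frame(case_id = case_id, time = as.numeric(time),
                    event = event, group = group, stringsAsFactors = FALSE)
  class(out) <- c("survival_records", "data.frame")
  out
}

#' Read a clinical survival table
#'
#' Dialect: `case_id<TAB>time_days<TAB>dss_event`, header optional, `#`
#' comments ignored.
#'
#' @param path File path.
#' @return A [survival_records()] data frame.
#' @export
read_clinical <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (suppressWarnings(is.na(as.numeric(fields[[1]][2]))))
    fields <- fields[-1]
  survival_records(
    case_id = vapply(fields, `[[`, character(1), 1),
    time = vapply(fields, function(f) as.numeric(f[[2]]), numeric(1)),
    event = vapply(fields, function(f) as.integer(f[[3]]), integer(1)))
}

#' Write a clinical survival table
#' @param records A [survival_records()] data frame.
#' @param path Output path.
#' @export
write_clinical <- function(records, path) {
  writeLines(c("case_id\ttime_days\tdss_event",
               paste(records$case_id, records$time, records$event,
                     sep = "\t")),
             path)
  invisible(path)
}

#' Kaplan–Meier product-limit curve
#'
#' Fitted through [survival::survfit()]; ties between an event and a
#' censoring at the same time follow the standard convention (events
#' first).
#'
#' @param records A [survival_records()] data frame (`time`, `event`).
#' @return List of class `km_curve`: `event_times` (times with at least
#'   one event), `survival` (estimate after each event time), `at_risk`
#'   (numbers at risk just before each event time), `n_events`,
#'   `censor_times`, and `median` (smallest time with survival <= 0.5, or
#'   `NA` if never reached).
#' @export
km_curve <- function(records) {
  if (nrow(records) < 1) stop("no survival records")
  if (any(records$time < 0)) stop("negative survival time")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  ev <- fit$n.event > 0
  med <- unname(stats::quantile(fit, probs = 0.5)$quantile)
  structure(list(event_times = fit$time[ev],
                 survival = fit$surv[ev],
                 at_risk = fit$n.risk[ev],
                 n_events = fit$n.event[ev],
                 censor_times = rep(fit$time[fit$n.censor > 0],
                                    fit$n.censor[fit$n.censor > 0]),
                 median = med),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: %d event times, %d censorings, median %s\n",
              length(x$event_times), length(x$censor_times),
              ifelse(is.na(x$median), "not reached", format(x$median))))
  invisible(x)
}

#' Write a Kaplan–Meier curve as TSV
#' @param curve A `km_curve`.
#' @param path Output path.
#' @export
write_km_curve <- function(curve, path) {
  writeLines(c("time\tsurvival\tat_risk\tn_events",
               paste(curve$event_times, sprintf("%.6g", curve$survival),
                     curve$at_risk, curve$n_events, sep = "\t")),
             path)
  invisible(path)
}

group_surv_data <- function(groupA, groupB) {
  if (nrow(groupA) < 1 || nrow(groupB) < 1)
    stop("both survival groups must be non-empty")
  dat <- rbind(
    data.frame(time = groupA$time, event = groupA$event, g = "A"),
    data.frame(time = groupB$time, event = groupB$event, g = "B"))
  if (sum(dat$event) < 1)
    stop("log-rank test undefined with zero events")
  dat
}

#' Log-rank (Mantel–Cox) test between two survival groups
#'
#' Observed-minus-expected event counts over the pooled event times
#' (survdiff with rho = 0); symmetric in group order.
#'
#' @param groupA,groupB [survival_records()] data frames.
#' @return An `assoc_test` with `method = "logrank"`, the chi-square
#'   statistic, df = 1 and the upper-tail P.
#' @export
logrank_test <- function(groupA, groupB) {
  dat <- group_surv_data(groupA, groupB)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = dat,
                           rho = 0)
  assoc_test("logrank",
             stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
             statistic = unname(sd$chisq), df = 1L)
}

#' Hazard ratio by the log-rank (O/E) method
#'
#' `HR = (O_A/E_A) / (O_B/E_B)` from the log-rank observed and expected
#' event counts — the method of the mainstream survival-plot software this
#' pipeline mirrors (Cox regression is deliberately out of scope). The
#' confidence interval uses the normal approximation on the log scale with
#' `SE(log HR) = sqrt(1/E_A + 1/E_B)`.
#'
#' @param groupA,groupB [survival_records()] data frames.
#' @param conf_level Confidence level, default 0.95.
#' @return List of class `hazard_ratio`: `hr`, `conf_low`, `conf_high`,
#'   `observed`, `expected` (2-vectors, A then B).
#' @export
hazard_ratio <- function(groupA, groupB, conf_level = 0.95) {
  dat <- group_surv_data(groupA, groupB)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = dat,
                           rho = 0)
  O <- unname(sd$obs); E <- unname(sd$exp)
  if (any(E <= 0))
    stop("zero expected events in a group; hazard ratio undefined")
  hr <- (O[1] / E[1]) / (O[2] / E[2])
  se <- sqrt(1 / E[1] + 1 / E[2])
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(hr = hr,
                 conf_low = exp(log(hr) - zq * se),
                 conf_high = exp(log(hr) + zq * se),
                 observed = O, expected = E),
            class = "hazard_ratio")
}

#' @export
print.hazard_ratio <- function(x, ...) {
  cat(sprintf("hazard ratio %.3g (%.3g-%.3g); O/E %g/%.3g vs %g/%.3g\n",
              x$hr, x$conf_low, x$conf_high,
              x$observed[1], x$expected[1], x$observed[2], x$expected[2]))
  invisible(x)
}
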