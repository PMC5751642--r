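# Estimated blood alcohol concentration (eBAC) from hourly drink reports,
# using the Matthews-Miller formula:
#   eBAC = (c / 2) * (GC / weight) - beta60 * t
# with c = standard drinks, GC = 9.0 (female) / 7.5 (male), weight in pounds,
# beta60 = 0.017 g/dL per hour of metabolism, t = hours spent drinking.

#' Hourly alcohol metabolism rate (g/dL per hour)
#'
#' The fixed clearance constant used by the Matthews-Miller eBAC formula.
#' @export
EBAC_METABOLISM_RATE <- 0.017

#' Create a subject profile
#'
#' A subject profile carries the two person-level quantities the
#' Matthews-Miller formula needs: body weight in pounds and the sex-derived
#' gender constant (9.0 for females, 7.5 for males), which absorbs sex
#' differences in body water content.
#'
#' @param subject_id Identifier (coerced to character).
#' @param sex Either `"female"` or `"male"`.
#' @param weight Body weight in pounds; must be positive.
#' @return An object of class `subject_profile` with fields `subject_id`,
#'   `sex`, `weight` and `gender_constant`.
#' @examples
#' subject_profile("s1", "female", 140)
#' @export
subject_profile <- function(subject_id, sex = c("female", "male"), weight) {
  sex <- match.arg(sex)
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) ||
      weight <= 0) {
    stop("invalid profile: 'weight' must be a single positive number",
         call. = FALSE)
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      sex = sex,
      weight = as.numeric(weight),
      gender_constant = if (sex == "female") 9.0 else 7.5
    ),
    class = "subject_profile"
  )
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> %s: %s, %.0f lb (GC = %.1f)\n",
              x$subject_id, x$sex, x$weight, x$gender_constant))
  invisible(x)
}

#' Compute estimated blood alcohol concentration
#'
#' Applies the Matthews-Miller formula
#' \deqn{eBAC = \frac{c}{2}\,\frac{GC}{weight} - 0.017\, t}
#' where `c` is the number of standard drinks, `GC` the gender constant and
#' `t` hours spent drinking. Negative values (fully metabolized) are clamped
#' to zero.
#'
#' @param profile A [subject_profile()].
#' @param total_drinks Number of standard drinks (>= 0); may be a vector.
#' @param hours_drinking Hours spent drinking (>= 0); recycled against
#'   `total_drinks`.
#' @return Estimated blood alcohol concentration in g/dL (never negative).
#' @examples
#' p <- subject_profile("s1", "male", 179)
#' compute_ebac(p, total_drinks = 4, hours_drinking = 2)
#' @export
compute_ebac <- function(profile, total_drinks, hours_drinking) {
  stopifnot(inherits(profile, "subject_profile"))
  if (any(total_drinks < 0) || any(hours_drinking < 0)) {
    stop("'total_drinks' and 'hours_drinking' must be non-negative",
         call. = FALSE)
  }
  pmax(0, (total_drinks / 2) * (profile$gender_constant / profile$weight) -
         EBAC_METABOLISM_RATE * hours_drinking)
}

#' Create an hourly drink-report series
#'
#' One evening of ecological momentary assessment (EMA) drink reports:
#' at each hourly slot the subject reports drinks consumed in the past hour
#' (menu 0-30), or the slot is missing (`NA`) when the EMA was not completed.
#'
#' @param subject_id,evening_id Identifiers.
#' @param hour_index Integer vector, strictly increasing (0 = 8 p.m. slot,
#'   4 = midnight slot).
#' @param drinks Integer vector of drinks per slot in `[0, 30]`, `NA` for a
#'   missed report.
#' @return An object of class `drink_report_series`.
#' @export
drink_report_series <- function(subject_id, evening_id, hour_index, drinks) {
  hour_index <- as.integer(hour_index)
  if (length(hour_index) != length(drinks)) {
    stop("'hour_index' and 'drinks' must have equal length", call. = FALSE)
  }
  if (length(hour_index) > 1L && any(diff(hour_index) <= 0L)) {
    stop("'hour_index' must be strictly increasing", call. = FALSE)
  }
  ok <- is.na(drinks) | (drinks >= 0 & drinks <= 30)
  if (!all(ok)) {
    stop("'drinks' must lie in [0, 30] or be NA", call. = FALSE)
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      evening_id = as.character(evening_id),
      hour_index = hour_index,
      drinks = as.integer(drinks)
    ),
    class = "drink_report_series"
  )
}

#' Compute an eBAC trajectory for one evening of drink reports
#'
#' Missing reports are treated as zero drinks consumed (the convention used
#' when the self-report for an hour is absent). Within a drinking episode,
#' eBAC at each report hour is computed from the cumulative drinks reported
#' since the episode's first (nonzero) report and the hours elapsed since
#' that report, so alcohol clearance is taken into account. An episode ends
#' when eBAC returns to zero, after which the elapsed-time clock resets.
#'
#' Each hour is labelled with the limb of the blood-alcohol curve it sits
#' on: `"ascending"` when eBAC rose relative to the previous hour,
#' `"descending"` when it fell, `"none"` otherwise (including evenings with
#' no drinking at all).
#'
#' @param profile A [subject_profile()].
#' @param reports A [drink_report_series()].
#' @return A data frame with columns `hour_index`, `ebac` (g/dL) and `limb`.
#'   An empty report list yields a zero-row trajectory.
#' @export
ebac_trajectory <- function(profile, reports) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(reports, "drink_report_series"))
  n <- length(reports$hour_index)
  if (n == 0L) {
    return(data.frame(hour_index = integer(), ebac = numeric(),
                      limb = character(), stringsAsFactors = FALSE))
  }
  drinks <- reports$drinks
  drinks[is.na(drinks)] <- 0L
  hours <- reports$hour_index

  ebac <- numeric(n)
  cum_drinks <- 0L
  episode_start <- NA_integer_  # hour of the episode's first drink report
  for (k in seq_len(n)) {
    if (is.na(episode_start) && drinks[k] > 0L) {
      episode_start <- hours[k]
    }
    cum_drinks <- cum_drinks + drinks[k]
    if (is.na(episode_start)) {
      ebac[k] <- 0
    } else {
      t_elapsed <- hours[k] - episode_start
      ebac[k] <- compute_ebac(profile, cum_drinks, t_elapsed)
      if (ebac[k] == 0) {
        # fully metabolized: episode over, clock resets
        cum_drinks <- 0L
        episode_start <- NA_integer_
      }
    }
  }

  prev <- c(0, ebac[-n])
  limb <- ifelse(ebac > prev, "ascending",
                 ifelse(ebac < prev, "descending", "none"))
  data.frame(hour_index = hours, ebac = ebac, limb = limb,
             stringsAsFactors = FALSE)
}

#' Read drink reports from CSV
#'
#' Expects columns `subject_id`, `evening_id`, `hour_index`, `drinks`;
#' empty `drinks` cells mark missed reports.
#'
#' @param path Path to a CSV file.
#' @return A list of [drink_report_series()], one per
#'   (subject, evening) pair, in file order.
#' @export
read_drink_reports <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "evening_id", "hour_index", "drinks")
  if (!all(needed %in% names(df))) {
    stop("drink report CSV must have columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  key <- paste(df$subject_id, df$evening_id, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(d) {
    d <- d[order(d$hour_index), ]
    drink_report_series(d$subject_id[1], d$evening_id[1],
                        d$hour_index, d$drinks)
  })
}

#' Write eBAC trajectories to CSV
#'
#' @param trajectories Named list of trajectory data frames from
#'   [ebac_trajectory()]; names or list elements must identify subject and
#'   evening via attributes, or supply `keys`.
#' @param keys Data frame with one row per trajectory holding `subject_id`
#'   and `evening_id`.
#' @param path Output CSV path.
#' @return Invisibly, the combined data frame written.
#' @export
write_ebac_trajectories <- function(trajectories, keys, path) {
  stopifnot(nrow(keys) == length(trajectories))
  out <- do.call(rbind, lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    if (nrow(tr) == 0L) return(NULL)
    cbind(subject_id = keys$subject_id[i], evening_id = keys$evening_id[i],
          tr, stringsAsFactors = FALSE)
  }))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
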