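#' Construct / read / write a survival table
#'
#' A survival table has one row per sample with the right-censored
#' follow-up `time` (study time units), the `event` indicator (1 =
#' progression or death, 0 = censored) and a `group` label.
#'
#' @param sample,time,event,group Component vectors.
#' @return A data frame of class `survival_table`.
#' @export
survival_table <- function(sample, time, event, group) {
  if (any(time < 0)) stop("negative follow-up times")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  structure(data.frame(sample = as.character(sample), time = time,
                       event = as.integer(event),
                       group = as.character(group),
                       stringsAsFactors = FALSE),
            class = c("survival_table", "data.frame"))
}

#' @rdname survival_table
#' @param path TSV file with columns `sample`, `time`, `event`,
#'   `group`.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("survival file not found: ", path)
  df <- utils::read.delim(path)
  survival_table(df$sample, df$time, df$event, df$group)
}

#' @rdname survival_table
#' @param x A `survival_table`.
#' @export
write_survival <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate
#' \eqn{S(t) = \prod_{t_i \le t} (1 - d_i/n_i)} over the distinct event
#' times, with right censoring handled through the risk set.
#'
#' @param x A [survival_table()].
#' @param group Optional single group label to restrict to.
#' @return A data frame with columns `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (the stepwise survival function evaluated just
#'   after each listed time).
#' @export
km_curve <- function(x, group = NULL) {
  if (!is.null(group)) x <- x[x$group == group, , drop = FALSE]
  if (nrow(x) == 0) stop("no subjects in the requested group")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = x)
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, n_censor = fit$n.censor,
             surv = fit$surv)
}

#' Two-group log-rank test
#'
#' The standard log-rank statistic: at each distinct event time the
#' observed events in the first group are compared with their
#' hypergeometric expectation given the risk sets, and
#' \eqn{\chi^2 = (O - E)^2 / V} is referred to a chi-square with 1 df.
#'
#' @param x A [survival_table()].
#' @param groups Optional length-2 character vector selecting the two
#'   groups to compare; by default the table must contain exactly two
#'   groups.
#' @return A list with `chi2` and `p`.
#' @export
logrank_test <- function(x, groups = NULL) {
  if (!is.null(groups)) x <- x[x$group %in% groups, , drop = FALSE]
  if (length(unique(x$group)) != 2) {
    stop("exactly two nonempty groups are required")
  }
  if (sum(x$event) == 0) stop("undefined test: no events at all")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = x)
  list(chi2 = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}
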