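#' Two-group log-rank test for lifespan tables
#'
#' Compares the survival distributions of two groups (e.g. fly lifespan
#' cohorts) with the standard log-rank statistic: at each distinct event time
#' the observed number of deaths in group A is compared with its expectation
#' under the pooled risk set, with the hypergeometric variance accounting for
#' ties; censored individuals contribute to risk sets only. The p-value comes
#' from a chi-square distribution with 1 df.
#'
#' @param table data frame with columns \code{time} (positive), \code{event}
#'   (logical or 0/1; TRUE = death observed) and \code{group}.
#' @param groupA,groupB the two group labels to compare; by default the two
#'   groups present in \code{table}.
#' @return list with \code{chi_square} and \code{p_value}.
#' @export
logrank_test <- function(table, groupA = NULL, groupB = NULL) {
  assert_that(is.data.frame(table) &&
                all(c("time", "event", "group") %in% names(table)),
              "table must have columns time, event, group")
  assert_that(all(table$time > 0), "times must be positive")
  if (is.null(groupA) || is.null(groupB)) {
    gs <- unique(as.character(table$group))
    assert_that(length(gs) == 2L,
                "specify groupA/groupB when more than two groups present")
    groupA <- gs[1]; groupB <- gs[2]
  }
  keep <- table$group %in% c(groupA, groupB)
  tab <- table[keep, , drop = FALSE]
  assert_that(any(tab$group == groupA) && any(tab$group == groupB),
              "both groups must be non-empty")
  assert_that(any(as.logical(tab$event)), "at least one event is required")

  fit <- survival::survdiff(
    survival::Surv(time, as.logical(event)) ~ factor(group),
    data = tab)
  chisq <- unname(fit$chisq)
  list(chi_square = chisq,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Median lifespan from the Kaplan-Meier estimator
#'
#' The median lifespan of a group is the smallest time at which the
#' Kaplan-Meier (product-limit) survival estimate drops to 0.5 or below.
#' If the estimate never reaches 0.5 (e.g. heavy censoring), the median is
#' undefined and \code{NA_real_} is returned (a signal, not an error).
#'
#' @param table data frame with columns \code{time}, \code{event},
#'   \code{group}.
#' @param group group label to estimate; may be omitted if only one group.
#' @return median lifespan (same time units as input) or \code{NA_real_}.
#' @export
median_lifespan <- function(table, group = NULL) {
  assert_that(is.data.frame(table) &&
                all(c("time", "event", "group") %in% names(table)),
              "table must have columns time, event, group")
  if (!is.null(group)) table <- table[table$group == group, , drop = FALSE]
  assert_that(nrow(table) > 0, "no records for the requested group")
  fit <- survival::survfit(survival::Surv(time, as.logical(event)) ~ 1,
                           data = table)
  cross <- which(fit$surv <= 0.5)
  if (length(cross) == 0L) return(NA_real_)
  fit$time[cross[1]]
}
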