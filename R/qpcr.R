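#' Relative expression by the delta-delta-Ct method
#'
#' Livak relative quantification with reference-gene normalization and
#' 100 percent amplification efficiency (factor 2 per cycle). Technical
#' replicate Cts are averaged on the Ct scale; per condition,
#' \eqn{\Delta Ct = \bar{Ct}_{target} - \bar{Ct}_{reference}}, then
#' \eqn{\Delta\Delta Ct = \Delta Ct_{condition} - \Delta Ct_{control}} and
#' \eqn{fold = 2^{-\Delta\Delta Ct}}. The log2-fold standard error is
#' propagated in quadrature from the four technical-replicate standard
#' errors entering the double difference.
#'
#' @param target data frame of target-gene Cts with columns
#'   \code{condition} and \code{ct} (one row per technical replicate).
#' @param reference same layout for the reference gene.
#' @param control_condition condition used as the fold-change baseline
#'   (its fold is exactly 1).
#' @return data frame with \code{condition}, \code{delta_ct},
#'   \code{delta_delta_ct}, \code{fold}, \code{log2_fold}, \code{se_log2};
#'   one row per condition.
#' @examples
#' target <- data.frame(condition = rep(c("treated", "control"), each = 3),
#'                      ct = c(25.0, 25.1, 24.9, 27.0, 27.1, 26.9))
#' reference <- data.frame(condition = rep(c("treated", "control"), each = 3),
#'                         ct = c(20.0, 20.0, 20.0, 20.0, 20.1, 19.9))
#' delta_delta_ct(target, reference, "control")
#' @export
delta_delta_ct <- function(target, reference, control_condition) {
  for (nm in list(target = target, reference = reference)) {
    assert_that(is.data.frame(nm) &&
                  all(c("condition", "ct") %in% names(nm)),
                "target/reference need columns condition, ct")
  }
  conds <- unique(as.character(target$condition))
  assert_that(control_condition %in% conds,
              "control condition absent from target data")
  assert_that(all(conds %in% reference$condition),
              "missing reference Cts for some condition")

  summ <- function(df, cond) {
    ct <- df$ct[df$condition == cond]
    ct <- ct[is.finite(ct)]
    assert_that(length(ct) >= 1, "no finite Ct for condition ", cond)
    list(mean = mean(ct),
         se = if (length(ct) >= 2) stats::sd(ct) / sqrt(length(ct)) else 0)
  }

  stats_per <- lapply(conds, function(cond) {
    tg <- summ(target, cond)
    rf <- summ(reference, cond)
    list(delta_ct = tg$mean - rf$mean,
         var = tg$se^2 + rf$se^2)
  })
  names(stats_per) <- conds
  ctrl <- stats_per[[control_condition]]

  out <- do.call(rbind, lapply(conds, function(cond) {
    st <- stats_per[[cond]]
    ddct <- st$delta_ct - ctrl$delta_ct
    se <- if (cond == control_condition) sqrt(st$var) else
      sqrt(st$var + ctrl$var)
    data.frame(condition = cond,
               delta_ct = st$delta_ct,
               delta_delta_ct = ddct,
               fold = 2^(-ddct),
               log2_fold = -ddct,
               se_log2 = se)
  }))
  rownames(out) <- NULL
  out
}
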