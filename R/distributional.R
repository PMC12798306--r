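#' Distributional summary of a reform
#'
#' Person-weighted inequality and poverty statistics plus cash winners and
#' losers for a set of household income results: the weighted Gini
#' coefficient of equivalised income (baseline and reform), mean cash and
#' percentage changes by baseline quintile, weighted counts of households by
#' gain/loss band, relative poverty headcounts (share of persons, and of
#' children, below 60% of the weighted median equivalised income, medians
#' fixed at baseline and recomputed under reform), and the annual net
#' exchequer cost.
#'
#' @param results An `income_result` table from [apply_scheme()] (>= 2
#'   households, positive weights).
#' @param gain_bands Breakpoints (GBP/month, household, unequivalised) for
#'   the winners/losers classification.
#' @return List of class `distributional_report`.
#' @export
distributional_summary <- function(results,
                                   gain_bands = c(-Inf, -10, 10, 50, 100,
                                                  200, Inf)) {
  if (nrow(results) < 2) stop("need at least 2 households", call. = FALSE)
  if (any(results$weight_hh <= 0)) stop("nonpositive weights", call. = FALSE)
  wp <- results$weight_hh * results$n_persons   # persons represented
  wc <- results$weight_hh * results$n_children  # children represented

  gini_base <- weighted_gini(results$net_equiv_base, wp)
  gini_reform <- weighted_gini(results$net_equiv_reform, wp)

  # baseline person-weighted quintiles of equivalised income
  o <- order(results$net_equiv_base)
  cw <- cumsum(wp[o]) / sum(wp)
  q <- integer(nrow(results))
  q[o] <- pmin(5L, findInterval(cw, seq(0.2, 0.8, 0.2)) + 1L)
  change <- results$net_income_reform - results$net_income_base
  quintiles <- do.call(rbind, lapply(1:5, function(k) {
    i <- q == k
    data.frame(
      quintile = k,
      mean_equiv_base = stats::weighted.mean(results$net_equiv_base[i], wp[i]),
      mean_change_cash = stats::weighted.mean(change[i], wp[i]),
      mean_change_pct = 100 * stats::weighted.mean(change[i], wp[i]) /
        stats::weighted.mean(results$net_income_base[i], wp[i])
    )
  }))

  band <- cut(change, breaks = gain_bands, include.lowest = TRUE)
  winners_losers <- data.frame(
    band = levels(band),
    households = as.vector(tapply(results$weight_hh, band, sum,
                                  default = 0)),
    stringsAsFactors = FALSE
  )

  med_base <- weighted_median(results$net_equiv_base, wp)
  med_reform <- weighted_median(results$net_equiv_reform, wp)
  pov <- function(x, w, med) sum(w[x < 0.6 * med]) / sum(w)
  poverty <- data.frame(
    measure = c("persons", "children"),
    base = c(pov(results$net_equiv_base, wp, med_base),
             pov(results$net_equiv_base, wc, med_base)),
    reform = c(pov(results$net_equiv_reform, wp, med_reform),
               pov(results$net_equiv_reform, wc, med_reform))
  )

  structure(
    list(gini_base = gini_base,
         gini_reform = gini_reform,
         quintiles = quintiles,
         winners_losers = winners_losers,
         poverty = poverty,
         exchequer_cost_annual = 12 * sum(results$weight_hh * change),
         scheme = attr(results, "scheme")),
    class = "distributional_report"
  )
}

#' @export
print.distributional_report <- function(x, ...) {
  cat("<distributional_report>", x$scheme %||% "", "\n")
  cat(sprintf("  Gini: %.4f -> %.4f\n", x$gini_base, x$gini_reform))
  cat(sprintf("  Poverty (persons): %.1f%% -> %.1f%%\n",
              100 * x$poverty$base[1], 100 * x$poverty$reform[1]))
  cat(sprintf("  Net exchequer cost: GBP %.2f bn/year\n",
              x$exchequer_cost_annual / 1e9))
  invisible(x)
}
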