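#' Chi-square goodness of fit against the adjusted Kaplan--Meier curve
#'
#' Compares the parametric survival with the offset-adjusted Kaplan--Meier
#' estimate at the observed event ages,
#' \deqn{X^2 = \sum_i \frac{(S_{\mathrm{model}}(t_i) - S_{\mathrm{adj}}(t_i))^2}
#'   {\widehat{\mathrm{Var}}(S_{\mathrm{adj}}(t_i))},}
#' using only the Kaplan--Meier (Greenwood) variance — not the fit's — which
#' makes the screen deliberately strict.  The p-value uses df = number of
#' evaluation points, uncorrected for estimated parameters: conservative
#' (under-rejects a true model); subtract the parameter count from `df`
#' yourself if you prefer.  Zero-variance points are skipped and counted.
#'
#' @param model fitted `multistage_model`.
#' @param adj_km an `adjusted_km` from [adjust_km()].
#' @param x covariate profile (default baseline).
#' @return A `gof_result`: `statistic`, `df`, `p_value`, `n_skipped`.
#' @export
chisq_gof <- function(model, adj_km, x = NULL) {
  stopifnot(inherits(adj_km, "adjusted_km"))
  S_model <- model_survival(model, adj_km$time, x)
  v <- adj_km$var_adj
  use <- v > 0
  n_skipped <- sum(!use)
  if (n_skipped > 0)
    message(n_skipped, " zero-variance point(s) skipped in GOF")
  if (sum(use) < 2L) stop("need >= 2 event ages with positive variance")
  stat <- sum((S_model[use] - adj_km$surv_adj[use])^2 / v[use])
  df <- sum(use)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 n_skipped = n_skipped),
            class = "gof_result")
}

#' Benjamini--Hochberg false-discovery-rate adjustment
#'
#' Step-up q-values across the disease ensemble; monotone in p-rank.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return q-values, same order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0L) stop("empty p-value vector")
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Inclusion rule for downstream analysis
#'
#' A disease is excluded when the goodness-of-fit screen rejects after FDR
#' adjustment (`q < fdr_level`) or when the fitted effective number of steps
#' falls below the threshold (`m < 0.8` by default, where the multistage
#' interpretation breaks down).
#'
#' @param m_hat fitted effective number of steps.
#' @param q FDR-adjusted GOF q-value.
#' @param m_threshold exclusion threshold on `m` (default 0.8).
#' @param fdr_level FDR significance level (default 0.05).
#' @return list `included` (logical) and `reason` (`"none"`, `"gof"`,
#'   `"m_below_threshold"`, or `"gof+m_below_threshold"`).
#' @export
inclusion_filter <- function(m_hat, q, m_threshold = 0.8, fdr_level = 0.05) {
  stopifnot(is.finite(m_hat), is.finite(q))
  reasons <- c(if (q < fdr_level) "gof",
               if (m_hat < m_threshold) "m_below_threshold")
  list(included = length(reasons) == 0L,
       reason = if (length(reasons)) paste(reasons, collapse = "+") else "none")
}
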