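#' Incremental cost-effectiveness ratio with dominance handling
#'
#' `compute_icer()` classifies the incremental pair (ΔC, ΔE): a positive
#' ratio ΔC/ΔE when both are positive (the standard north-east quadrant);
#' `"dominant"` when the intervention is no more expensive and more effective
#' (ΔC ≤ 0, ΔE > 0); `"dominated"` when it is no cheaper and less effective
#' (ΔC ≥ 0, ΔE < 0, not both zero); `"undefined"` when |ΔE| < 1e-9 (the
#' ratio blows up; ΔC is still reported). In the remaining south-west
#' quadrant (cheaper and less effective) the ratio is reported with label
#' `"ratio"` and interpreted against the threshold in [is_cost_effective()].
#'
#' `icer()` is the four-argument convenience wrapper taking per-arm costs and
#' effects (intervention first).
#'
#' @param d_cost Incremental cost (intervention minus control), USD.
#' @param d_eff Incremental effectiveness (QALYs).
#' @return A list with `icer` (numeric, `NA` for dominance/undefined cases),
#'   `label` (one of `"ratio"`, `"dominant"`, `"dominated"`, `"undefined"`),
#'   `d_cost`, `d_eff`.
#' @examples
#' icer(1578.37, 1114.01, 0.7497, 0.7095)
#' @export
compute_icer <- function(d_cost, d_eff) {
  if (!is.finite(d_cost) || !is.finite(d_eff)) {
    rlang::abort("incremental cost and effect must be finite")
  }
  out <- list(icer = NA_real_, label = "undefined",
              d_cost = d_cost, d_eff = d_eff)
  if (abs(d_eff) < 1e-9) {
    return(out)
  }
  if (d_cost <= 0 && d_eff > 0) {
    out$label <- "dominant"
  } else if (d_cost >= 0 && d_eff < 0) {
    out$label <- "dominated"
  } else {
    out$label <- "ratio"
    out$icer <- d_cost / d_eff
  }
  out
}

#' @rdname compute_icer
#' @param cost_i,cost_c Per-participant cost, intervention and control.
#' @param eff_i,eff_c Per-participant effectiveness (QALYs), intervention and
#'   control.
#' @export
icer <- function(cost_i, cost_c, eff_i, eff_c) {
  compute_icer(cost_i - cost_c, eff_i - eff_c)
}

#' Net monetary benefit
#'
#' `eff * wtp - cost`; on incremental values, a positive NMB at a
#' willingness-to-pay threshold is equivalent to ICER < threshold when the
#' incremental effect is positive.
#'
#' @param cost Cost (USD).
#' @param eff Effectiveness (QALYs).
#' @param wtp Willingness-to-pay threshold (USD/QALY), non-negative.
#' @export
nmb <- function(cost, eff, wtp = 150000) {
  if (any(wtp < 0)) rlang::abort("wtp must be non-negative")
  eff * wtp - cost
}

#' Cost-effectiveness decision at a willingness-to-pay threshold
#'
#' `TRUE` iff the intervention is dominant, or the ICER is a ratio below the
#' threshold with a positive incremental effect (strict inequality at the
#' boundary). A south-west ratio (cheaper, less effective) is cost-effective
#' when the ratio exceeds the threshold (QALYs are given up at an acceptable
#' saving); dominated and undefined-ratio cases are `FALSE`.
#'
#' @param icer_result A list from [compute_icer()].
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @export
is_cost_effective <- function(icer_result, wtp = 150000) {
  switch(icer_result$label,
    dominant = TRUE,
    dominated = FALSE,
    undefined = FALSE,
    ratio = if (icer_result$d_eff > 0) {
      icer_result$icer < wtp
    } else {
      icer_result$icer > wtp
    }
  )
}

#' Pairwise cost-effectiveness comparison of two arms
#'
#' Combines per-arm accumulated costs and QALYs (both measures) into
#' incremental differences, ICERs, incremental net monetary benefit and a
#' cost-effectiveness decision per measure.
#'
#' @param per_arm A data frame with columns `arm`, `cost`, `qaly_htvas`,
#'   `qaly_sf36` and exactly two rows.
#' @param intervention,control Arm labels identifying the two rows.
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @return A `cea_result` object; see [tidy.cea_result()] and
#'   [glance.cea_result()].
#' @export
cea_compare <- function(per_arm, intervention = "individual_coaching",
                        control = "education_control", wtp = 150000) {
  need <- c("arm", "cost", "qaly_htvas", "qaly_sf36")
  if (!all(need %in% names(per_arm))) {
    rlang::abort(paste("per_arm needs columns:", paste(need, collapse = ", ")))
  }
  gi <- per_arm[per_arm$arm == intervention, ]
  gc <- per_arm[per_arm$arm == control, ]
  if (nrow(gi) != 1L || nrow(gc) != 1L) {
    rlang::abort("per_arm must contain exactly one row per compared arm")
  }
  d_cost <- gi$cost - gc$cost
  measures <- c("htvas", "sf36")
  per_measure <- purrr::map(rlang::set_names(measures), function(m) {
    d_eff <- gi[[paste0("qaly_", m)]] - gc[[paste0("qaly_", m)]]
    ic <- compute_icer(d_cost, d_eff)
    list(
      d_qaly = d_eff, icer = ic$icer, label = ic$label,
      inmb = nmb(d_cost, d_eff, wtp),
      cost_effective = is_cost_effective(ic, wtp)
    )
  })
  structure(
    list(
      per_arm = tibble::as_tibble(per_arm),
      intervention = intervention, control = control,
      d_cost = d_cost, per_measure = per_measure, wtp = wtp
    ),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<CEA: %s vs %s, WTP $%s/QALY>\n", x$intervention, x$control,
              format(x$wtp, big.mark = ",")))
  cat(sprintf("  incremental cost: $%.2f\n", x$d_cost))
  for (m in names(x$per_measure)) {
    pm <- x$per_measure[[m]]
    lab <- if (pm$label == "ratio") sprintf("$%.2f/QALY", pm$icer) else pm$label
    cat(sprintf("  %-5s dQALY %.4f, ICER %s, cost-effective: %s\n",
                m, pm$d_qaly, lab, pm$cost_effective))
  }
  invisible(x)
}

#' Tidy a CEA result
#'
#' One row per QALY measure with the incremental cost, incremental QALYs,
#' ICER (NA under dominance), dominance label, incremental net monetary
#' benefit and the decision at the stored threshold.
#'
#' @param x A `cea_result`.
#' @param ... Unused.
#' @method tidy cea_result
#' @export
tidy.cea_result <- function(x, ...) {
  purrr::imap_dfr(x$per_measure, function(pm, m) {
    tibble::tibble(
      measure = m, d_cost = x$d_cost, d_qaly = pm$d_qaly,
      icer = pm$icer, label = pm$label, inmb = pm$inmb,
      cost_effective = pm$cost_effective
    )
  })
}

#' Glance at a CEA result
#'
#' @param x A `cea_result`.
#' @param ... Unused.
#' @method glance cea_result
#' @export
glance.cea_result <- function(x, ...) {
  tibble::tibble(
    intervention = x$intervention, control = x$control, wtp = x$wtp,
    d_cost = x$d_cost,
    icer_htvas = x$per_measure$htvas$icer,
    icer_sf36 = x$per_measure$sf36$icer,
    cost_effective = x$per_measure$htvas$cost_effective &&
      x$per_measure$sf36$cost_effective
  )
}
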