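#' Persist a pipeline report to a directory
#'
#' Writes `assignments.csv` (`player,context_cluster,behavior_subcluster`),
#' `summary.csv` (`treatment,cluster,n,n_subclusters,silhouette`),
#' `conditional_cooperation.csv` (per sub-cluster and context: counts,
#' cooperation probability and binomial standard error),
#' `archetype_calls.csv`, and per sub-cluster `hmm_<id>.json` plus
#' `hmm_<id>.dot` (display-pruned rendering).
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     quote = FALSE)
  }
  w(report$assignments, "assignments.csv")
  w(report$summary, "summary.csv")
  w(report$conditional_cooperation, "conditional_cooperation.csv")
  w(report$archetype_calls, "archetype_calls.csv")
  for (id in names(report$hmms)) {
    write_hmm_json(report$hmms[[id]],
                   file.path(dir, sprintf("hmm_%s.json", id)))
    writeLines(hmm_to_dot(report$display_hmms[[id]]),
               file.path(dir, sprintf("hmm_%s.dot", id)))
  }
  invisible(dir)
}

#' Plot conditional cooperation per sub-cluster
#'
#' Bar chart of the probability of a cooperative response per context, one
#' facet per behavioral sub-cluster, with binomial standard-error bars
#' `sqrt(p(1-p)/n)`.
#'
#' @param report A `pipeline_report`.
#' @return A ggplot object.
#' @export
plot_conditional_cooperation <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_conditional_cooperation requires the ggplot2 package",
         call. = FALSE)
  }
  d <- report$conditional_cooperation
  d <- d[d$n > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$context, y = .data$p)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$p - .data$se),
                   ymax = pmin(1, .data$p + .data$se)), width = 0.25) +
    ggplot2::facet_wrap(~subcluster) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "context (previous round, player-opponent)",
                  y = "P(cooperate | context)",
                  title = sprintf("Conditional cooperation, %s (%s)",
                                  report$treatment, report$window))
}
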