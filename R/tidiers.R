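# broom-style tidiers and ggplot2 autoplot methods for the fitted objects
# and result tables.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted codon branch model
#'
#' @param x A `codon_model_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `type` (`kappa`,
#'   `omega`, or `branch_length`), `estimate`, `fixed`.
#' @method tidy codon_model_fit
#' @export
tidy.codon_model_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "kappa", type = "kappa", estimate = x$kappa,
                   fixed = FALSE),
    tibble::tibble(term = paste0("omega_", names(x$omega)), type = "omega",
                   estimate = unname(x$omega),
                   fixed = names(x$omega) %in% names(x$fixed_omega)),
    tibble::tibble(term = paste0("bl_", names(x$branch_lengths)),
                   type = "branch_length",
                   estimate = unname(x$branch_lengths), fixed = FALSE)
  )
}

#' Glance at a fitted codon branch model
#'
#' @param x A `codon_model_fit`.
#' @param ... Unused.
#' @return One-row tibble: `model`, `logLik`, `np`, `AIC`, `n_tips`,
#'   `n_sites`, `converged`.
#' @method glance codon_model_fit
#' @export
glance.codon_model_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model_label, logLik = x$lnL, np = x$np,
    AIC = 2 * x$np - 2 * x$lnL,
    n_tips = x$n_tips, n_sites = x$n_sites, converged = x$converged
  )
}

#' Tidy a relaxation-K fit
#'
#' @param x A `relax_fit`.
#' @param ... Unused.
#' @return Tibble of the omega categories with proportions, on reference and
#'   test branches.
#' @method tidy relax_fit
#' @export
tidy.relax_fit <- function(x, ...) {
  x$omega_categories
}

#' Glance at a relaxation-K fit
#'
#' @param x A `relax_fit`.
#' @param ... Unused.
#' @return One-row tibble: `K`, `lnL_null`, `lnL_alt`, `stat`, `p_value`,
#'   `converged`.
#' @method glance relax_fit
#' @export
glance.relax_fit <- function(x, ...) {
  tibble::tibble(
    K = x$K, lnL_null = x$lnL_null, lnL_alt = x$lnL_alt,
    stat = x$lrt$stat, p_value = x$lrt$p_value, converged = x$converged
  )
}

#' Plot per-branch omega estimates of a fitted model
#'
#' Dot plot of branch omegas (log scale) with the neutral omega = 1 line;
#' most useful for free-ratio fits.
#'
#' @param object A `codon_model_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot codon_model_fit
#' @export
autoplot.codon_model_fit <- function(object, ...) {
  df <- tibble::tibble(
    branch = names(object$branch_lengths),
    omega = unname(object$omega[object$branch_classes[names(object$branch_lengths)]])
  )
  df$branch <- factor(df$branch, levels = df$branch[order(df$omega)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$omega, y = .data$branch)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(omega ~ "(dN/dS)"), y = NULL,
                  title = paste("Per-branch dN/dS, model", object$model_label)) +
    ggplot2::theme_minimal()
}

#' Plot lesion counts per species
#'
#' Stacked bar chart of mutation events by type, coloured by class, with
#' gene status on the axis label.
#'
#' @param statuses Status tibble from [scan_all()].
#' @return A ggplot object.
#' @export
plot_lesion_summary <- function(statuses) {
  ev <- all_events(statuses)
  if (nrow(ev) == 0) {
    stop("no events to plot", call. = FALSE)
  }
  lab <- stats::setNames(
    paste0(statuses$species_id, " [", substr(statuses$status, 1, 5), "]"),
    statuses$species_id
  )
  ev$species <- lab[ev$species_id]
  ggplot2::ggplot(ev, ggplot2::aes(y = .data$species, fill = .data$event_type)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "lesions", y = NULL, fill = "type",
                  title = "Inactivating and in-frame lesions per species") +
    ggplot2::theme_minimal()
}

#' Plot a dating table
#'
#' Interval plot of inactivation-time estimates per branch (Ma before the
#' recent end of the branch).
#'
#' @param dating Tibble from [assemble_dating()].
#' @return A ggplot object.
#' @export
plot_dating <- function(dating) {
  ggplot2::ggplot(dating, ggplot2::aes(y = .data$branch)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$tn_lower, xend = .data$tn_upper,
                                       yend = .data$branch), linewidth = 2,
                          colour = "steelblue") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$t_lower, xend = .data$t_upper,
                                       yend = .data$branch), alpha = 0.3) +
    ggplot2::labs(x = "Ma before the recent end of the branch", y = NULL,
                  subtitle = "thick bar: inactivation window; thin bar: full branch window") +
    ggplot2::theme_minimal()
}
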