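# Two-period inactivation dating. A pseudogene branch of duration T is split
# into a functional period (selection at omega_s) followed by a neutral
# period (omega_n = 1). The branch-average omega_a then satisfies
#   omega_a = omega_s * Ts / T + 1 * Tn / T,   Ts = T - Tn
# so the neutral period is Tn = T * (omega_a - omega_s) / (1 - omega_s),
# measured back from the recent end of the branch.

#' Date gene inactivation on one branch
#'
#' Solves the two-period model for the neutral period `Tn` and propagates a
#' divergence-time interval linearly through it. `omega_a` is clamped into
#' `[omega_s, 1]` before solving: estimates below `omega_s` (sampling noise)
#' date to Tn = 0, estimates above 1 to Tn = T (with a warning).
#'
#' @param omega_a Branch-average omega of the whole branch (e.g. its
#'   free-ratio estimate).
#' @param omega_s Functional-period omega (background estimate), in `[0, 1)`.
#' @param t_lower,t_upper Bounds (Ma) of the branch duration `T`.
#' @return One-row tibble: `omega_a`, `omega_a_used`, `omega_s`, `ratio`
#'   (`Tn / T`), `t_lower`, `t_upper`, `tn_lower`, `tn_upper`, `clamped`.
#' @export
date_inactivation <- function(omega_a, omega_s, t_lower, t_upper = t_lower) {
  if (omega_s < 0 || omega_s >= 1) {
    stop("omega_s must be in [0, 1); the model is undefined at omega_s >= 1",
         call. = FALSE)
  }
  if (t_lower <= 0 || t_lower > t_upper) {
    stop("need 0 < t_lower <= t_upper", call. = FALSE)
  }
  clamped <- FALSE
  used <- omega_a
  if (used > 1) {
    warning("omega_a = ", formatC(omega_a, digits = 4), " > 1; clamped to 1")
    used <- 1
    clamped <- TRUE
  }
  if (used < omega_s) {
    used <- omega_s
    clamped <- TRUE
  }
  ratio <- (used - omega_s) / (1 - omega_s)
  tibble::tibble(
    omega_a = omega_a, omega_a_used = used, omega_s = omega_s,
    ratio = ratio,
    t_lower = t_lower, t_upper = t_upper,
    tn_lower = ratio * t_lower, tn_upper = ratio * t_upper,
    clamped = clamped
  )
}

#' Date inactivation across pseudogenized branches
#'
#' Takes branch-average omegas from a free-ratio fit, the background
#' (functional-period) omega from a one-ratio fit over intact species, and a
#' divergence-time table, and dates each pseudogenized branch. Branches
#' lacking a time interval are skipped with a warning; duplicated branch
#' labels (e.g. several tips sharing one ancestral event that has already
#' been mapped to their stem branch) are dated once.
#'
#' @param model_E_fit Free-ratio `codon_model_fit` (one omega per branch).
#' @param background_fit One-ratio `codon_model_fit` over intact background
#'   species, or a single numeric omega_s.
#' @param time_table Tibble from [read_time_table()] keyed by branch label.
#' @param pseudogenized_branches Branch labels to date.
#' @return A tibble with one row per dated branch: branch label plus the
#'   columns of [date_inactivation()].
#' @export
assemble_dating <- function(model_E_fit, background_fit, time_table,
                            pseudogenized_branches) {
  omega_s <- if (is.numeric(background_fit)) {
    background_fit
  } else {
    stopifnot(inherits(background_fit, "codon_model_fit"))
    unname(background_fit$omega[[1]])
  }
  branches <- unique(pseudogenized_branches)
  rows <- lapply(branches, function(br) {
    om <- model_E_fit$omega[br]
    if (is.na(om)) {
      warning("branch '", br, "' has no free-ratio omega; skipped")
      return(NULL)
    }
    j <- match(br, time_table$label)
    if (is.na(j)) {
      warning("no time interval for branch '", br, "'; skipped")
      return(NULL)
    }
    out <- date_inactivation(unname(om), omega_s,
                             time_table$t_lower[j], time_table$t_upper[j])
    dplyr::bind_cols(tibble::tibble(branch = br), out)
  })
  dplyr::bind_rows(rows)
}
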