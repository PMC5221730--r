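#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a group comparison
#'
#' @param x An `af_group_comparison`.
#' @param ... Unused.
#' @return A plain tibble, one row per compared factor.
#' @export
tidy.af_group_comparison <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "af_group_comparison")
  out
}

#' @export
glance.af_group_comparison <- function(x, ...) {
  tibble(outcome = attr(x, "outcome"), n_true = attr(x, "n_true"),
         n_false = attr(x, "n_false"), alpha = attr(x, "alpha"),
         n_significant = sum(x$significant))
}

#' Tidy a partial-correlation result
#'
#' @param x An `af_pcr`.
#' @param ... Unused.
#' @return Tibble with `term`, `pcr`, `outcome`.
#' @export
tidy.af_pcr <- function(x, ...) {
  dplyr::mutate(as_tibble(x), outcome = attr(x, "outcome"))
}

#' @export
glance.af_pcr <- function(x, ...) {
  tibble(outcome = attr(x, "outcome"), n = attr(x, "n"),
         strongest = x$term[which.max(abs(x$pcr))],
         max_abs_pcr = max(abs(x$pcr)))
}

#' @export
tidy.af_maintenance <- function(x, ...) x$reentry

#' @export
glance.af_maintenance <- function(x, ...) {
  tibble(n_candidates = nrow(x$population),
         n_accepted = sum(x$population$accepted),
         n_simulated = nrow(x$reentry),
         n_sustained = sum(x$reentry$sustained),
         sustained_rate = mean(x$reentry$sustained),
         r2_df_rm = x$r2_df_rm)
}

#' @export
tidy.af_block_result <- function(x, ...) x$effects

#' @export
glance.af_block_result <- function(x, ...) {
  still <- x$effects[!x$effects$terminated, , drop = FALSE]
  tibble(n_blocked = nrow(x$effects),
         n_terminated = sum(x$effects$terminated),
         termination_rate = mean(x$effects$terminated),
         mean_d_rm = mean(still$d_rm, na.rm = TRUE),
         sd_d_rm = sd(still$d_rm, na.rm = TRUE),
         mean_d_df = mean(still$d_df, na.rm = TRUE),
         r2_d_df_d_rm = x$r2_d_df_d_rm)
}
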