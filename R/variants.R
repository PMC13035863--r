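# Model variants for the two-tumor experiment and parameter sharing masks for
# the metastasis model.

#' Two-tumor model variant
#'
#' A fit variant is the combination of growth law (Gompertz or logistic),
#' capacity structure (one shared capacity, individual and equal, or
#' individual and unequal), rate structure (equal or unequal intrinsic
#' rates), and, per parameter, whether it is population-level (one value for
#' the cohort) or subject-level (one value per mouse).
#'
#' @param law `"gompertz"`, `"logistic"` or `"exponential"`.
#' @param capacity_mode `"shared"`, `"individual_equal"`,
#'   `"individual_unequal"`; ignored for the exponential law.
#' @param rate_mode `"equal"` or `"unequal"`.
#' @param pooling named list with entries `r` and `K`, each `"population"`
#'   or `"subject"`.
#' @return object of class `model_variant`.
#' @export
model_variant <- function(law = "gompertz",
                          capacity_mode = c("shared", "individual_equal",
                                            "individual_unequal"),
                          rate_mode = c("equal", "unequal"),
                          pooling = list(r = "subject", K = "subject")) {
  law <- match.arg(law, c("gompertz", "logistic", "exponential"))
  capacity_mode <- match.arg(capacity_mode)
  rate_mode <- match.arg(rate_mode)
  pooling <- modifyList(list(r = "subject", K = "subject"), as.list(pooling))
  stopifnot(pooling$r %in% c("population", "subject"),
            pooling$K %in% c("population", "subject"))
  structure(list(law = law, capacity_mode = capacity_mode,
                 rate_mode = rate_mode, pooling = pooling),
            class = "model_variant")
}

#' @export
format.model_variant <- function(x, ...) {
  sprintf("%s/%s/r_%s/pool(r=%s,K=%s)", x$law, x$capacity_mode, x$rate_mode,
          x$pooling$r, x$pooling$K)
}

#' @export
print.model_variant <- function(x, ...) {
  cat("<model_variant>", format(x), "\n"); invisible(x)
}

.met_par_names <- c("a_PT", "a_m", "K", "mu", "chi", "vartheta")

#' Parameter sharing mask for the metastasis model
#'
#' Flags each of the six model parameters as group-level (one value for the
#' cohort) or subject-level (one value per mouse). The parsimonious
#' configuration identified for the experimental cohorts -- group-level
#' primary growth rate, seeding coefficient and inoculation survival;
#' subject-level metastatic growth rate, fractal dimension and shared
#' capacity -- is the default.
#'
#' @param group character vector of parameter names fitted at group level.
#' @param subject character vector fitted at subject level; together with
#'   `group` this must partition `a_PT, a_m, K, mu, chi, vartheta`.
#' @return object of class `sharing_mask`.
#' @export
sharing_mask <- function(group = c("a_PT", "mu", "vartheta"),
                         subject = c("a_m", "chi", "K")) {
  all_names <- sort(c(group, subject))
  if (!identical(all_names, sort(.met_par_names)))
    stop("`group` and `subject` must partition: ",
         paste(.met_par_names, collapse = ", "))
  structure(list(group = group, subject = subject), class = "sharing_mask")
}
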