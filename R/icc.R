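#' Inter/intra-technician variance components and ICC from a mixed model
#'
#' Fits, by REML, a linear mixed model of the per-replicate population
#' value (percent of parent) on the control samples as fixed effects with
#' a random technician intercept:
#' `value ~ 0 + control + (1 | technician)`. The conditional intraclass
#' correlation is the proportion of total (non-control) variance that lies
#' between technicians,
#' `ICC = var_inter / (var_inter + var_intra)`, where `var_inter` is the
#' technician variance component and `var_intra` the residual. A low ICC
#' indicates little technician batch effect. Variance estimates are floored
#' at zero (REML can return boundary fits for null components).
#'
#' @param design data.frame with columns `control_id`, `technician_id`,
#'   `replicate`, `population`, `value` (see
#'   [generateTechnicianStudy()] for the synthetic version of the
#'   repeated-controls design).
#' @param population optional population name to filter on.
#' @return Named numeric `c(icc, var_inter, var_intra)`.
#' @examples
#' des <- generateTechnicianStudy(varInter = 0.5, varIntra = 0.5, seed = 1)
#' iccMixedModel(des)
#' @export
iccMixedModel <- function(design, population = NULL) {
  need <- c("control_id", "technician_id", "value")
  if (!all(need %in% names(design)))
    preconditionError(paste("design must have columns",
                            paste(need, collapse = ", ")))
  if (!is.null(population) && "population" %in% names(design))
    design <- design[design$population == population, , drop = FALSE]
  design$control_id <- factor(design$control_id)
  design$technician_id <- factor(design$technician_id)
  if (nlevels(design$technician_id) < 2)
    preconditionError("ICC is not identifiable with a single technician")
  if (nrow(design) <= nlevels(design$control_id) + 1)
    preconditionError("too few replicates to estimate variance components")
  fit <- suppressMessages(lme4::lmer(
    value ~ 0 + control_id + (1 | technician_id), data = design, REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  varInter <- max(vc$vcov[vc$grp == "technician_id"], 0)
  varIntra <- max(vc$vcov[vc$grp == "Residual"], 0)
  icc <- if (varInter + varIntra > 0) varInter / (varInter + varIntra) else 0
  c(icc = icc, var_inter = varInter, var_intra = varIntra)
}
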