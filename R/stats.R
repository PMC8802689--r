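# Group-comparison layer: linear mixed-effects models with animal as a
# random intercept, estimated-marginal-mean pairwise contrasts, and the
# two-way ANOVA with Tukey post hoc used for morphology.

#' Significance tier labels
#'
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.0001.
#' @param p numeric p-values.
#' @return character vector of stars ("" when not significant).
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 1e-4, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}

#' Fit the cohort mixed-effects model
#'
#' Restricted-maximum-likelihood linear mixed model with sex, genotype,
#' litter and the condition factor (wave, ITD or frequency) as fixed
#' effects and a per-animal random intercept:
#' `response ~ sex * genotype * condition + litter + (1 | animal)`.
#' Inference on fixed effects uses Satterthwaite degrees of freedom (via
#' lmerTest).  Factors with a single observed level are dropped from the
#' formula; a rank-deficient design caused by empty sex-by-genotype cells
#' is tolerated (the aliased columns are dropped and recorded), and
#' singular random-effect fits are flagged, not hidden.
#'
#' @param table long-format data frame with columns `animal`, `sex`,
#'   `genotype`, `litter`, the condition column and the response column;
#'   rows with missing responses (absent waves) are dropped, never imputed.
#' @param response name of the response column.
#' @param condition name of the condition column (`NULL` for none).
#' @return object of class `abr_mixed`: list with the `lmerTest` fit,
#'   `singular` flag, dropped-row count and the formula used.
#' @export
fit_mixed_model <- function(table, response, condition = "wave") {
  needed <- c("animal", "sex", "genotype", response)
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols)) {
    stop("table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tab <- as.data.frame(table)
  keep <- !is.na(tab[[response]])
  n_dropped <- sum(!keep)
  tab <- tab[keep, , drop = FALSE]
  for (f in c("sex", "genotype", "litter", condition)) {
    if (!is.null(f) && f %in% names(tab)) tab[[f]] <- factor(tab[[f]])
  }
  if (any(table(tab$sex, tab$genotype)[table(tab$sex, tab$genotype) > 0] < 1)) {
    stop("empty factor levels in the design", call. = FALSE)
  }
  terms <- "sex * genotype"
  if (!is.null(condition) && condition %in% names(tab) &&
      nlevels(tab[[condition]]) > 1) {
    terms <- paste0("sex * genotype * ", condition)
  }
  if ("litter" %in% names(tab) && nlevels(tab$litter) > 1) {
    terms <- paste(terms, "+ litter")
  }
  fml <- stats::as.formula(paste(response, "~", terms, "+ (1 | animal)"))
  fit <- withCallingHandlers(
    lmerTest::lmer(fml, data = tab, REML = TRUE),
    message = function(m) {
      if (grepl("rank deficient", conditionMessage(m))) {
        invokeRestart("muffleMessage")
      }
    }
  )
  structure(
    list(fit = fit,
         formula = fml,
         response = response,
         condition = condition,
         singular = lme4::isSingular(fit),
         n_dropped = n_dropped,
         data = tab),
    class = "abr_mixed"
  )
}

#' @export
print.abr_mixed <- function(x, ...) {
  cat("<abr_mixed> ", deparse(x$formula), "\n", sep = "")
  if (x$singular) cat("  NOTE: singular random-effect fit\n")
  if (x$n_dropped) cat("  ", x$n_dropped, "rows with missing response dropped\n")
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  cat(sprintf("  animal SD = %.4g, residual SD = %.4g\n",
              vc$sdcor[vc$grp == "animal"], vc$sdcor[vc$grp == "Residual"]))
  invisible(x)
}

#' @export
summary.abr_mixed <- function(object, ...) summary(object$fit, ...)

#' @export
coef.abr_mixed <- function(object, ...) lme4::fixef(object$fit)

#' Pairwise estimated-marginal-mean contrasts
#'
#' All pairwise genotype contrasts within sex (`by = "sex"`) or sex
#' contrasts within genotype (`by = "genotype"`), optionally at fixed
#' levels of the condition factor, with Tukey multiplicity adjustment
#' within each contrast family.  Both raw and adjusted p-values are kept,
#' along with the adjustment method and the significance tier.
#'
#' @param model an [fit_mixed_model()] result.
#' @param by `"sex"` or `"genotype"`: the factor held fixed.
#' @param at optional named list restricting the condition factor, e.g.
#'   `list(wave = "IV")`.
#' @param adjust multiplicity adjustment (default `"tukey"`).
#' @return data frame of class `abr_contrasts`: `contrast`, the `by`
#'   column(s), `estimate`, `SE`, `df`, `t`, `p_raw`, `p_adj`, `adjust`,
#'   `stars`.  Non-estimable contrasts (empty design cells) are removed.
#' @export
pairwise_emmeans <- function(model, by = c("sex", "genotype"), at = NULL,
                             adjust = "tukey") {
  by <- match.arg(by)
  stopifnot(inherits(model, "abr_mixed"))
  vary <- if (by == "sex") "genotype" else "sex"
  group_vars <- by
  if (!is.null(model$condition) && model$condition %in% names(model$data) &&
      nlevels(model$data[[model$condition]]) > 1 &&
      (is.null(at) || !model$condition %in% names(at) ||
       length(at[[model$condition]]) > 1)) {
    group_vars <- c(by, model$condition)
  }
  spec <- stats::as.formula(paste("~", vary, "|",
                                  paste(group_vars, collapse = " + ")))
  em <- suppressMessages(emmeans::emmeans(
    model$fit, spec, at = at, lmer.df = "satterthwaite"))
  adj <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                         adjust = adjust))
  raw <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                         adjust = "none"))
  out <- adj
  names(out)[names(out) == "p.value"] <- "p_adj"
  out$p_raw <- raw$p.value
  out$adjust <- adjust
  out$stars <- significance_stars(out$p_adj)
  out <- out[!is.na(out$estimate), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("abr_contrasts", "data.frame")
  out
}

#' Two-way ANOVA with Tukey post hoc
#'
#' Sex-by-genotype analysis of a morphological response: main effects and
#' interaction, with Tukey honest-significant-difference pairwise
#' comparisons for all three terms.
#'
#' @param morphology per-animal data frame with `sex`, `genotype` and the
#'   response column.
#' @param response name of the response column.
#' @return object of class `abr_anova`: list with the `aov` fit, the ANOVA
#'   `table`, and `tukey` contrasts.
#' @export
anova_two_way <- function(morphology, response) {
  stopifnot(response %in% names(morphology))
  tab <- as.data.frame(morphology)
  tab$sex <- factor(tab$sex)
  tab$genotype <- factor(tab$genotype)
  cells <- table(tab$sex, tab$genotype)
  if (any(cells == 0)) {
    # tolerate structurally missing cells (e.g. no heterozygous males) but
    # refuse cells that are merely empty of data within the crossed design
    present <- cells[cells > 0]
    if (any(present < 2)) {
      stop("need at least 2 observations per non-empty sex x genotype cell",
           call. = FALSE)
    }
  } else if (any(cells < 2)) {
    stop("need at least 2 observations per sex x genotype cell",
         call. = FALSE)
  }
  fml <- stats::as.formula(paste(response, "~ sex * genotype"))
  fit <- stats::aov(fml, data = tab)
  structure(
    list(fit = fit,
         table = summary(fit)[[1]],
         tukey = stats::TukeyHSD(fit),
         response = response),
    class = "abr_anova"
  )
}

#' @export
print.abr_anova <- function(x, ...) {
  cat("<abr_anova> response:", x$response, "\n")
  print(x$table)
  invisible(x)
}
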