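#' Derived nitrogen-cycling indices from gross rates
#'
#' Four dimensionless ratios summarizing the balance of NO3- production and
#' consumption: nitrification capacity `O_NH4 / M_N`; NO3- retention
#' capacity `(I_NO3 + D_NO3) / (O_NH4 + O_Nrec)` (consumption over
#' production of NO3-); the nitrification-to-immobilization ratio
#' `O_NH4 / I_NH4`; and the soil `NO3- / NH4+` concentration ratio. A zero
#' denominator flags the index undefined (`NA` with `defined = FALSE`), never
#' silently 0.
#'
#' @param rates Gross-rates data frame from [average_rates()] (columns
#'   `process`, `rate`) or a named vector of the ten process rates
#'   (mg N kg-1 day-1); totals `M_N`/`I_NH4` are formed from components when
#'   absent.
#' @param nh4_conc,no3_conc Soil inorganic N concentrations, mg N kg-1
#'   (optional; needed only for the concentration ratio).
#' @return Data frame with columns `index`, `value`, `defined`.
#' @export
#' @examples
#' derive_indices(c(M_Nlab = 2, M_Nrec = 1.95, I_NH4_Nlab = 0.2,
#'                  I_NH4_Nrec = 0.1, A_NH4 = 0, R_NH4 = 0, O_NH4 = 1.99,
#'                  O_Nrec = 0.01, D_NO3 = 0.1, I_NO3 = 0.9))
derive_indices <- function(rates, nh4_conc = NULL, no3_conc = NULL) {
  if (is.data.frame(rates)) rates <- setNames(rates$rate, rates$process)
  rates <- rates[!is.na(rates)]
  if (any(rates < 0)) stop("gross rates must be >= 0")
  get <- function(nm, parts = NULL) {
    if (nm %in% names(rates)) return(unname(rates[nm]))
    if (!is.null(parts) && all(parts %in% names(rates)))
      return(sum(rates[parts]))
    stop("rates are missing '", nm, "'")
  }
  m_n <- get("M_N", c("M_Nlab", "M_Nrec"))
  i_nh4 <- get("I_NH4", c("I_NH4_Nlab", "I_NH4_Nrec"))
  o_nh4 <- get("O_NH4")
  o_nrec <- get("O_Nrec")
  d_no3 <- get("D_NO3")
  i_no3 <- get("I_NO3")

  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  vals <- c(nitrification_capacity = ratio(o_nh4, m_n),
            no3_retention_capacity = ratio(i_no3 + d_no3, o_nh4 + o_nrec),
            o_over_i = ratio(o_nh4, i_nh4),
            no3_nh4_ratio = if (!is.null(nh4_conc) && !is.null(no3_conc))
              ratio(no3_conc, nh4_conc) else NA_real_)
  defined <- !is.na(vals)
  if (is.null(nh4_conc) || is.null(no3_conc))
    defined["no3_nh4_ratio"] <- NA
  data.frame(index = names(vals), value = unname(vals),
             defined = unname(defined), stringsAsFactors = FALSE)
}

#' Two-group comparison of a cohort variable
#'
#' Independent-samples t test (equal-variance by default, Welch optional) of
#' one variable between the two land-use groups, preceded by a
#' Kolmogorov-Smirnov normality check per group (against a normal with the
#' group's estimated mean and sd). The normality result is reported but never
#' gates the t test. Undefined values (`NA`) are dropped pairwise.
#'
#' @param cohort Cohort data frame with a `land_use` column (see
#'   [generate_cohort()]).
#' @param variable Name of the numeric column to compare.
#' @param var.equal Pool the variance (classical two-sample t test); `FALSE`
#'   gives the Welch test.
#' @return Object of class `n15_group_test`: `variable`, `groups` (per-group
#'   n, mean, se, KS statistic and p), `t`, `df`, `p_value`, `method`.
#' @export
compare_groups <- function(cohort, variable, var.equal = TRUE) {
  if (!variable %in% names(cohort)) stop("no column '", variable, "' in cohort")
  if (!"land_use" %in% names(cohort)) stop("cohort must have a land_use column")
  keep <- !is.na(cohort[[variable]])
  x <- cohort[[variable]][keep]
  g <- factor(cohort$land_use[keep])
  if (nlevels(g) != 2) stop("need exactly 2 land-use groups")
  n_by <- table(g)
  if (any(n_by < 2)) stop("each group needs >= 2 samples")
  groups <- do.call(rbind, lapply(levels(g), function(lv) {
    v <- x[g == lv]
    ks <- suppressWarnings(ks.test(v, "pnorm", mean(v), sd(v)))
    data.frame(land_use = lv, n = length(v), mean = mean(v),
               se = sd(v) / sqrt(length(v)), ks_D = unname(ks$statistic),
               ks_p = ks$p.value, stringsAsFactors = FALSE)
  }))
  tt <- t.test(x ~ g, var.equal = var.equal)
  structure(list(variable = variable, groups = groups,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, method = tt$method),
            class = "n15_group_test")
}

#' @export
print.n15_group_test <- function(x, ...) {
  cat("<n15_group_test> ", x$variable, ": t = ", signif(x$t, 4),
      ", df = ", signif(x$df, 4), ", p = ", signif(x$p_value, 4),
      " (", x$method, ")\n", sep = "")
  print(x$groups, digits = 4)
  invisible(x)
}

#' Pearson correlation between two cohort variables
#'
#' Standard product-moment correlation with a two-sided test. Rows where
#' either variable is `NA` (e.g. an undefined index) are dropped pairwise.
#'
#' @param cohort Cohort data frame.
#' @param x_variable,y_variable Column names.
#' @return List: `r`, `p_value`, `n`, the variable names.
#' @export
correlate <- function(cohort, x_variable, y_variable) {
  for (v in c(x_variable, y_variable))
    if (!v %in% names(cohort)) stop("no column '", v, "' in cohort")
  x <- cohort[[x_variable]]
  y <- cohort[[y_variable]]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in a variable")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       x_variable = x_variable, y_variable = y_variable)
}
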