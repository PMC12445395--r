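# Cohort report assembly: reproduces the standard analysis battery on an
# analyzed cohort table (group descriptives, hemodynamics, perfusion,
# subgroups, transmural comparisons, regression panels).

fmt_miqr <- function(x) {
  s <- summarize_median_iqr(x)
  sprintf("%.2f [%.2f-%.2f]", s["median"], s["q1"], s["q3"])
}

fmt_count <- function(flag) sprintf("%d [%.1f]", sum(flag), 100 * mean(flag))

group_row <- function(variable, sinus, af, p, n = NULL) {
  data.frame(variable = variable, sinus = sinus, af = af,
             p = p, stringsAsFactors = FALSE)
}

mw_row <- function(variable, values, is_af) {
  xs <- values[!is_af & !is.na(values)]
  ys <- values[is_af & !is.na(values)]
  if (!length(xs) || !length(ys))
    return(group_row(variable,
                     if (length(xs)) fmt_miqr(xs) else NA,
                     if (length(ys)) fmt_miqr(ys) else NA, NA_real_))
  t <- mann_whitney_u(xs, ys)
  group_row(variable, fmt_miqr(xs), fmt_miqr(ys), t$p_value)
}

count_row <- function(variable, flag, is_af) {
  tab <- table(factor(is_af, c(FALSE, TRUE)), factor(flag, c(FALSE, TRUE)))
  p <- tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
                error = function(e) NA_real_)
  group_row(variable, fmt_count(flag[!is_af]), fmt_count(flag[is_af]), p)
}

#' Run the full cohort analysis battery
#'
#' Produces the standard report on an analyzed cohort (output of
#' [apply_eligibility()]): baseline group comparison, rest/stress/change
#' hemodynamics, stress/rest MBF and MPR group comparisons, CVR comparisons,
#' LGE-free / preserved-LVEF / age-category subgroup comparisons, paired
#' endocardial-epicardial tests with endo/epi ratio comparisons, and
#' univariate (Pearson) plus multivariate linear regression panels for stress
#' MBF and MPR. Two-group comparisons use the Mann-Whitney U test, multi-group
#' comparisons Kruskal-Wallis, paired comparisons the Wilcoxon signed-rank
#' test; continuous cells are median [IQR], categorical cells count [%]. MPR
#' and rest rows are computed only over adenosine patients with rest imaging.
#' No multiple-testing correction is applied.
#'
#' @param analyzed analyzed cohort data frame (must carry the subgroup flags
#'   appended by [apply_eligibility()]).
#' @return An object of class `cohort_report`: a named list of data frames
#'   (`baseline`, `hemodynamics`, `perfusion`, `subgroups`, `endo_epi`,
#'   `univariate`, `multivariate`, `descriptives`) plus group counts.
#' @export
run_cohort_analyses <- function(analyzed) {
  req <- c("rhythm", "age", "sex", "lvef", "lge", "beta_blocker", "agent",
           "rest_hr", "rest_sbp", "rest_dbp", "stress_hr", "stress_sbp",
           "stress_dbp", "stress_mbf", "rest_mbf", "stress_endo_mbf",
           "stress_epi_mbf", "rest_endo_mbf", "rest_epi_mbf",
           "indexed_lv_mass", "lge_free", "lvef_preserved", "age_category",
           "mpr_analyzable", "mpr")
  missing_cols <- setdiff(req, names(analyzed))
  if (length(missing_cols))
    stop_invalid("analyzed cohort is missing columns: %s",
                 paste(missing_cols, collapse = ", "))
  co <- analyzed
  af <- as.character(co$rhythm) == "af"

  baseline <- rbind(
    mw_row("Age (years)", co$age, af),
    count_row("Male sex", co$sex == "male", af),
    count_row("Use of beta-blockers", co$beta_blocker, af),
    count_row("Adenosine agent", co$agent == "adenosine", af),
    mw_row("LV ejection fraction (%)", co$lvef, af),
    mw_row("Indexed LV myocardial mass (g/m2)", co$indexed_lv_mass, af),
    count_row("Any LGE", !co$lge_free, af))

  rest_map <- mean_arterial_pressure(co$rest_sbp, co$rest_dbp)
  stress_map <- mean_arterial_pressure(co$stress_sbp, co$stress_dbp)
  hemo <- rbind(
    mw_row("Rest heart rate (bpm)", co$rest_hr, af),
    mw_row("Rest systolic BP (mmHg)", co$rest_sbp, af),
    mw_row("Rest diastolic BP (mmHg)", co$rest_dbp, af),
    mw_row("Rest MAP (mmHg)", rest_map, af),
    mw_row("Rest RPP (mmHg bpm)",
           rate_pressure_product(co$rest_hr, co$rest_sbp), af),
    mw_row("Stress heart rate (bpm)", co$stress_hr, af),
    mw_row("Stress systolic BP (mmHg)", co$stress_sbp, af),
    mw_row("Stress diastolic BP (mmHg)", co$stress_dbp, af),
    mw_row("Stress MAP (mmHg)", stress_map, af),
    mw_row("Stress RPP (mmHg bpm)",
           rate_pressure_product(co$stress_hr, co$stress_sbp), af),
    mw_row("Change in heart rate (bpm)", co$stress_hr - co$rest_hr, af))

  rest_ok <- co$mpr_analyzable
  stress_cvr <- coronary_vascular_resistance(stress_map, co$stress_mbf)
  rest_cvr <- ifelse(rest_ok & !is.na(co$rest_mbf),
                     rest_map / co$rest_mbf, NA_real_)
  perf_rows <- rbind(
    mw_row("Stress MBF (mL/min/g)", co$stress_mbf, af),
    mw_row("Rest MBF (mL/min/g)", ifelse(rest_ok, co$rest_mbf, NA), af),
    mw_row("MPR", co$mpr, af),
    mw_row("Stress CVR (mmHg/(mL/min/g))", stress_cvr, af),
    mw_row("Rest CVR (mmHg/(mL/min/g))", rest_cvr, af))

  sub_rows <- list()
  for (sub in list(list(name = "LGE-free", keep = co$lge_free),
                   list(name = "Preserved LVEF", keep = co$lvef_preserved),
                   list(name = "Age < 55", keep = co$age_category == "young_adult"),
                   list(name = "Age 55-74", keep = co$age_category == "middle_aged"),
                   list(name = "Age >= 75", keep = co$age_category == "elderly"))) {
    k <- sub$keep
    if (sum(k & af) < 2 || sum(k & !af) < 2) next
    r1 <- mw_row(paste(sub$name, "stress MBF"), ifelse(k, co$stress_mbf, NA), af)
    r2 <- mw_row(paste(sub$name, "rest MBF"),
                 ifelse(k & rest_ok, co$rest_mbf, NA), af)
    r3 <- mw_row(paste(sub$name, "MPR"), ifelse(k, co$mpr, NA), af)
    sub_rows[[sub$name]] <- rbind(r1, r2, r3)
  }
  # across-age comparison within each rhythm (Kruskal-Wallis)
  kw_rows <- do.call(rbind, lapply(c("sinus", "af"), function(rh) {
    sel <- as.character(co$rhythm) == rh
    g_s <- split(co$stress_mbf[sel], co$age_category[sel])
    g_m <- split(co$mpr[sel][!is.na(co$mpr[sel])],
                 co$age_category[sel][!is.na(co$mpr[sel])])
    g_s <- g_s[vapply(g_s, length, 1L) > 0]
    g_m <- g_m[vapply(g_m, length, 1L) > 0]
    data.frame(
      variable = sprintf("Across age categories (%s)", rh),
      sinus = NA, af = NA,
      p = c(if (length(g_s) >= 2) kruskal_wallis(g_s)$p_value else NA,
            if (length(g_m) >= 2) kruskal_wallis(g_m)$p_value else NA))
  }))
  subgroups <- rbind(do.call(rbind, sub_rows), kw_rows)
  rownames(subgroups) <- NULL

  # paired endo vs epi within each rhythm + between-group ratio comparison
  ee_rows <- do.call(rbind, lapply(c("sinus", "af"), function(rh) {
    sel <- as.character(co$rhythm) == rh
    ws <- wilcoxon_signed_rank(co$stress_endo_mbf[sel] - co$stress_epi_mbf[sel])
    rsel <- sel & rest_ok & !is.na(co$rest_endo_mbf)
    wr <- wilcoxon_signed_rank(co$rest_endo_mbf[rsel] - co$rest_epi_mbf[rsel])
    data.frame(variable = sprintf(c("Endo vs epi stress MBF (%s)",
                                    "Endo vs epi rest MBF (%s)"), rh),
               sinus = NA, af = NA, p = c(ws$p_value, wr$p_value))
  }))
  ratio_stress <- co$stress_endo_mbf / co$stress_epi_mbf
  mpr_endo <- ifelse(rest_ok, co$stress_endo_mbf / co$rest_endo_mbf, NA)
  mpr_epi <- ifelse(rest_ok, co$stress_epi_mbf / co$rest_epi_mbf, NA)
  endo_epi <- rbind(
    ee_rows,
    mw_row("Endo/epi stress MBF ratio", ratio_stress, af),
    mw_row("Endo/epi MPR ratio", mpr_endo / mpr_epi, af))
  rownames(endo_epi) <- NULL

  # regression panels: LGE excluded as a confounder; MPR panel additionally
  # restricted to adenosine-with-rest patients
  codes <- data.frame(
    Age = co$age,
    Sex = ifelse(co$sex == "male", 2, 1),
    AF = as.integer(af),
    Beta_blocker = as.integer(co$beta_blocker),
    LVEF = co$lvef,
    Indexed_mass = co$indexed_lv_mass)
  empty_panel <- function(n) {
    list(uni = data.frame(covariate = character(0), R = numeric(0),
                          p = numeric(0)),
         multi = data.frame(covariate = character(0), B = numeric(0),
                            beta = numeric(0), p = numeric(0)),
         n = n)
  }
  make_panels <- function(outcome, keep) {
    keep <- keep & !is.na(outcome) & stats::complete.cases(codes)
    if (sum(keep) <= ncol(codes) + 2) return(empty_panel(sum(keep)))
    # covariates constant or aliased in the analysis subset carry no
    # independent information and would make the design rank deficient
    use <- names(codes)[vapply(codes, function(v) stats::sd(v[keep]) > 0,
                               logical(1))]
    Xm <- cbind(1, as.matrix(codes[keep, use, drop = FALSE]))
    qrX <- qr(Xm)
    if (qrX$rank < ncol(Xm)) {
      aliased <- setdiff(colnames(Xm)[qrX$pivot[-seq_len(qrX$rank)]], "")
      use <- setdiff(use, aliased)
    }
    uni <- do.call(rbind, lapply(use, function(v) {
      rp <- pearson_r(codes[[v]][keep], outcome[keep])
      data.frame(covariate = v, R = rp["r"], p = rp["p"], row.names = NULL)
    }))
    multi <- multivariate_linear(outcome[keep], codes[keep, use])
    list(uni = uni, multi = multi, n = sum(keep))
  }
  p_stress <- make_panels(co$stress_mbf, co$lge_free)
  p_mpr <- make_panels(co$mpr, co$lge_free & rest_ok)
  bind_outcome <- function(name, tab) {
    if (!nrow(tab)) return(NULL)
    cbind(outcome = name, as.data.frame(tab))
  }
  univariate <- rbind(bind_outcome("stress_mbf", p_stress$uni),
                      bind_outcome("mpr", p_mpr$uni))
  multivariate <- rbind(bind_outcome("stress_mbf", p_stress$multi),
                        bind_outcome("mpr", p_mpr$multi))

  dose <- co$adenosine_dose
  descriptives <- do.call(rbind, lapply(c("sinus", "af"), function(rh) {
    d <- dose[as.character(co$rhythm) == rh & !is.na(dose)]
    data.frame(variable = sprintf("Adenosine dose (ug/kg/min, %s)", rh),
               mean = mean(d), sd = stats::sd(d), n = length(d))
  }))

  structure(list(
    baseline = baseline, hemodynamics = hemo, perfusion = perf_rows,
    subgroups = subgroups, endo_epi = endo_epi,
    univariate = univariate, multivariate = multivariate,
    descriptives = descriptives,
    n = c(sinus = sum(!af), af = sum(af)),
    n_mpr = c(sinus = sum(rest_ok & !af), af = sum(rest_ok & af)),
    n_regression = c(stress_mbf = p_stress$n, mpr = p_mpr$n)),
    class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, digits = 3, ...) {
  cat(sprintf("Cohort analysis report: %d sinus / %d AF analyzed (%d / %d with MPR)\n\n",
              x$n["sinus"], x$n["af"], x$n_mpr["sinus"], x$n_mpr["af"]))
  for (nm in c("baseline", "hemodynamics", "perfusion", "subgroups",
               "endo_epi")) {
    cat("== ", nm, " ==\n", sep = "")
    print.data.frame(x[[nm]], digits = digits, row.names = FALSE)
    cat("\n")
  }
  cat("== regression (univariate) ==\n")
  print.data.frame(x$univariate, digits = digits, row.names = FALSE)
  cat("\n== regression (multivariate) ==\n")
  print.data.frame(x$multivariate, digits = digits, row.names = FALSE)
  cat(sprintf("   n: stress MBF %d, MPR %d\n",
              x$n_regression["stress_mbf"], x$n_regression["mpr"]))
  cat("\n== descriptives ==\n")
  print.data.frame(x$descriptives, digits = digits, row.names = FALSE)
  invisible(x)
}
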