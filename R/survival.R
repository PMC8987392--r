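# Per-variant outcome association: ordinal genotype encoding,
# Kaplan-Meier / log-rank comparison, multivariate Cox proportional
# hazards with the study's ordinal covariate scheme, and Bonferroni
# correction across the variants tested.

#' Default multivariate covariate set
#'
#' The clinical covariates entered alongside the genotype term, all as
#' ordinal/numeric encodings: Age (years), Percent_aneuploidy, Histology
#' (oligodendroglioma 1 / oligoastrocytoma 2 / astrocytoma 3), Grade
#' (G2 1 / G3 2), IDH_status (mutant 1 / WT 2), Mutation_count,
#' Chr7gainORChr10loss (1/2), MGMT_promoter_status (methylated 1 /
#' unmethylated 2), Chr1OR19q_codeletion (codel 1 / non-codel 2),
#' Treatment_site (1-3) and the third genotype principal component.
#' @export
DEFAULT_COVARIATES <- c(
  "Age", "Percent_aneuploidy", "Histology", "Grade", "IDH_status",
  "Mutation_count", "Chr7gainORChr10loss", "MGMT_promoter_status",
  "Chr1OR19q_codeletion", "Treatment_site", "PC3")

#' Ordinal genotype labels
#'
#' Homozygous_ref -> 0, Heterozygous -> 1, Homozygous_alt -> 2,
#' unknown -> `NA` (the patient is excluded from that variant's models).
#'
#' @param statuses Character vector of status values.
#' @return Integer vector of labels with `NA` for unknown.
#' @export
encode_labels <- function(statuses) {
  bad <- !statuses %in% STATUS_LEVELS
  if (any(bad)) stop("unrecognized status value: ", statuses[which(bad)[1]])
  unname(c(Homozygous_ref = 0L, Heterozygous = 1L, Homozygous_alt = 2L,
           unknown = NA_integer_)[statuses])
}

#' Kaplan-Meier curves and log-rank test by genotype
#'
#' Fits the product-limit estimator per genotype group and compares the
#' groups with the log-rank (Mantel-Haenszel) test; the p-value is taken
#' from a chi-square distribution with (number of groups - 1) degrees of
#' freedom. Patients with a missing label are dropped first.
#'
#' @param labels Ordinal genotype labels (group identity).
#' @param times Follow-up times (e.g. OS months).
#' @param events Event indicators (0 censored / 1 death).
#' @return A list: `fit` (the `survfit` object), `chisq`, `df`,
#'   `p_value`, `n_per_group`.
#' @export
km_logrank <- function(labels, times, events) {
  ok <- !is.na(labels) & !is.na(times) & !is.na(events)
  d <- data.frame(labels = labels[ok], time = times[ok], event = events[ok])
  if (length(unique(d$labels)) < 2L) {
    stop("log-rank test needs at least 2 non-empty genotype groups")
  }
  if (sum(d$event) == 0L) stop("log-rank test needs at least one event")
  fit <- survival::survfit(survival::Surv(time, event) ~ labels, data = d)
  sd <- survival::survdiff(survival::Surv(time, event) ~ labels, data = d, rho = 0)
  df <- length(sd$n) - 1L
  p <- 1 - stats::pchisq(sd$chisq, df)
  list(fit = fit, chisq = unname(sd$chisq), df = df, p_value = p,
       n_per_group = as.vector(sd$n))
}

#' Plot Kaplan-Meier curves by genotype
#'
#' Convenience base-graphics plot of a [km_logrank()] fit, one curve per
#' genotype group with the log-rank p-value annotated.
#'
#' @param km A list from [km_logrank()].
#' @param main Plot title.
#' @export
plot_km <- function(km, main = "Overall survival by genotype") {
  cols <- c("blue", "orange", "red")[seq_along(km$n_per_group)]
  graphics::plot(km$fit, col = cols, lty = 1, mark.time = TRUE,
                 xlab = "Follow up in months", ylab = "Overall survival",
                 main = main)
  graphics::legend("topright", legend = names(km$fit$strata), col = cols, lty = 1, bty = "n")
  graphics::text(stats::quantile(km$fit$time, 0.6), 0.05,
                 paste0("P = ", format(km$p_value, scientific = TRUE, digits = 3)))
  invisible(km)
}

#' Multivariate Cox proportional-hazards fit for one variant
#'
#' Fits `Surv(OS_months, OS_status) ~ labels + <covariates>` by partial
#' likelihood with Efron tie handling. The genotype enters as a single
#' ordinal numeric term (additive per-allele effect). Records with any
#' missing modeled field are dropped and their count reported; a constant
#' modeled covariate is an error naming the covariate.
#'
#' @param labels Ordinal genotype labels aligned to `clinical` rows.
#' @param clinical A table with `OS_months`, `OS_status` and the
#'   covariate columns.
#' @param covariates Character vector of covariate column names (default
#'   none; use [DEFAULT_COVARIATES] for the full clinical adjustment).
#' @return A list: `table` (`data.table` of term, coef, hazard_ratio,
#'   se, z, p_value), `loglik`, `n`, `n_dropped`, `fit`.
#' @export
cox_multivariate <- function(labels, clinical, covariates = character()) {
  cl <- data.table::as.data.table(clinical)
  missing_cov <- setdiff(covariates, names(cl))
  if (length(missing_cov)) {
    stop("clinical table lacks covariate column(s): ",
         paste(missing_cov, collapse = ", "))
  }
  d <- data.frame(OS_months = cl$OS_months, OS_status = cl$OS_status,
                  labels = as.numeric(labels))
  for (cv in covariates) d[[cv]] <- as.numeric(cl[[cv]])
  complete <- stats::complete.cases(d)
  n_dropped <- sum(!complete)
  d <- d[complete, , drop = FALSE]
  if (nrow(d) < 3L) stop("too few complete cases for Cox regression")
  for (term in c("labels", covariates)) {
    if (length(unique(d[[term]])) < 2L) {
      stop("modeled term is constant in the complete cases: ", term)
    }
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(OS_months, OS_status) ~",
    paste(c("labels", covariates), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = "efron"),
    warning = function(w) {
      if (grepl("did not converge", conditionMessage(w))) {
        stop("Cox fit did not converge: ", conditionMessage(w), call. = FALSE)
      }
      # monotone partial likelihood (a group with no events) is routine in
      # small per-variant strata; the inflated coefficient is reported as is
      if (grepl("coefficient may be infinite", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  s <- summary(fit)
  tab <- data.table::data.table(
    term = rownames(s$coefficients),
    coef = s$coefficients[, "coef"],
    hazard_ratio = exp(s$coefficients[, "coef"]),
    se = s$coefficients[, "se(coef)"],
    z = s$coefficients[, "z"],
    p_value = s$coefficients[, "Pr(>|z|)"])
  list(table = tab, loglik = fit$loglik[2L], n = nrow(d),
       n_dropped = n_dropped, fit = fit)
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)` with `m` the number of variants tested.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Number of tests (default `length(p)`; must be at least that).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("m must be at least the number of p-values")
  pmin(1, m * p)
}

#' Per-variant survival scan over a status matrix
#'
#' For every variant row, encodes genotypes ordinally, fits the
#' multivariate Cox model and collects the genotype-term statistics.
#' Variants whose genotype is constant (or with too few complete cases)
#' get `NA` statistics and are excluded from the multiplicity count.
#'
#' @param mat A status matrix whose columns are `Case_ID`s.
#' @param clinical Clinical table with a `Case_ID` column.
#' @param covariates Covariates for [cox_multivariate()].
#' @return A `data.table`: key columns, `n0`, `n1`, `n2`, `n_unknown`,
#'   `coef`, `hazard_ratio`, `z`, `p_value`, `p_bonferroni`.
#' @export
variant_survival_scan <- function(mat, clinical, covariates = character()) {
  dt <- data.table::as.data.table(mat)
  cl <- data.table::as.data.table(clinical)
  if (!"Case_ID" %in% names(cl)) stop("clinical table needs a Case_ID column")
  cases <- intersect(sample_cols(dt), cl$Case_ID)
  if (!length(cases)) stop("no status-matrix columns match clinical Case_IDs")
  cl <- cl[match(cases, cl$Case_ID)]
  rows <- vector("list", nrow(dt))
  for (i in seq_len(nrow(dt))) {
    statuses <- as.character(dt[i, cases, with = FALSE])
    lab <- encode_labels(statuses)
    res <- tryCatch(cox_multivariate(lab, cl, covariates), error = function(e) NULL)
    stat <- if (is.null(res)) {
      list(coef = NA_real_, hazard_ratio = NA_real_, z = NA_real_, p_value = NA_real_)
    } else {
      as.list(res$table[res$table$term == "labels",
                        c("coef", "hazard_ratio", "z", "p_value")])
    }
    rows[[i]] <- c(as.list(dt[i, KEY_COLS, with = FALSE]),
                   list(n0 = sum(lab == 0L, na.rm = TRUE),
                        n1 = sum(lab == 1L, na.rm = TRUE),
                        n2 = sum(lab == 2L, na.rm = TRUE),
                        n_unknown = sum(is.na(lab))),
                   stat)
  }
  out <- data.table::rbindlist(rows)
  valid <- !is.na(out$p_value)
  out$p_bonferroni <- NA_real_
  if (any(valid)) out$p_bonferroni[valid] <- bonferroni(out$p_value[valid], sum(valid))
  out[]
}
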