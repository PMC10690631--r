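#' Two-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Tests the effects of motion acceleration (MA: three levels) and motion
#' duration (MD: four levels) on a per-subject, per-condition summary
#' measure — interception accuracy (`mean_te`) or precision (`std_te`) —
#' using a full-factorial within-subject ANOVA. Sphericity violations are
#' handled with the Greenhouse-Geisser epsilon estimated from each effect's
#' within-subject covariance (via the multivariate-model machinery of
#' \pkg{car}); corrected p-values are reported alongside the uncorrected
#' ones.
#'
#' @param summaries Subject-by-condition summary table from
#'   [aggregate_trials()] (balanced: every subject must have every
#'   label-duration combination exactly once).
#' @param dv Dependent variable: `"mean_te"` or `"std_te"`.
#' @return A data frame of class `rm_anova` with one row per effect
#'   (MA, MD, MA:MD): `df_num`, `df_den`, `F`, `p`, `epsilon_gg`, `p_gg`.
#' @examples
#' \dontrun{
#' tr <- simulate_trials(generative_params(seed = 7))
#' sm <- aggregate_trials(filter_outliers(compute_te(tr)))
#' rm_anova(sm, "mean_te")
#' }
#' @export
rm_anova <- function(summaries, dv = c("mean_te", "std_te")) {
  dv <- match.arg(dv)
  key <- paste(summaries$label, summaries$duration_s)
  tab <- table(summaries$subject_id, key)
  if (any(tab != 1))
    stop("summaries must be balanced: one row per subject and condition")
  labels <- sort(unique(summaries$label))
  durations <- sort(unique(summaries$duration_s))
  if (length(labels) < 2 || length(durations) < 2)
    stop("need at least two levels of both acceleration and duration")
  # wide subject x condition matrix, columns ordered duration-within-label
  idata <- expand.grid(MD = factor(durations), MA = factor(labels))
  wide_key <- paste(idata$MA, idata$MD)
  subjects <- sort(unique(summaries$subject_id))
  Y <- matrix(NA_real_, length(subjects), nrow(idata),
              dimnames = list(subjects, wide_key))
  Y[cbind(match(summaries$subject_id, subjects), match(key, wide_key))] <-
    summaries[[dv]]
  fit <- stats::lm(Y ~ 1)
  aov_ml <- car::Anova(fit, idata = idata, idesign = ~ MA * MD, type = 3)
  s <- suppressWarnings(summary(aov_ml, multivariate = FALSE))
  uni <- s$univariate.tests
  adj <- s$pval.adjustments
  effects <- c("MA", "MD", "MA:MD")
  if (!all(effects %in% rownames(adj)))
    stop("too few subjects to estimate sphericity for every effect; ",
         "need more subjects than the largest effect's degrees of freedom")
  out <- data.frame(
    effect = effects,
    df_num = uni[effects, "num Df"],
    df_den = uni[effects, "den Df"],
    F = uni[effects, "F value"],
    p = uni[effects, "Pr(>F)"],
    epsilon_gg = adj[effects, "GG eps"],
    p_gg = adj[effects, "Pr(>F[GG])"],
    row.names = NULL
  )
  class(out) <- c("rm_anova", "data.frame")
  attr(out, "dv") <- dv
  out
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA on %s (Greenhouse-Geisser corrected)\n",
              attr(x, "dv")))
  df <- as.data.frame(x)
  df$F <- round(df$F, 3)
  df$epsilon_gg <- round(df$epsilon_gg, 3)
  df$p <- format.pval(df$p, digits = 3)
  df$p_gg <- format.pval(df$p_gg, digits = 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an ANOVA table as CSV or JSON
#'
#' @param x An `rm_anova` result.
#' @param path Output path; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_anova_table <- function(x, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(as.data.frame(x), path, digits = NA, dataframe = "rows")
  else
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
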