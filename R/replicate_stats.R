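# SuperPlot-style statistics: statistical testing is done on replicate
# medians only, never on pooled per-cell values, to avoid inflating n with
# pseudo-replication. ANOVA and Tukey-Kramer are delegated to the stats
# machinery of base R; this module owns the replicate-median contract and
# the transwell normalizations.

check_grouped <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("condition", "replicate", "value") %in% names(df)))
  if (!nrow(df)) stop("no values supplied")
  if (anyNA(df$value)) stop("undefined values must be excluded before testing")
  counts <- table(df$condition, df$replicate)
  invisible(df)
}

#' Replicate medians of grouped per-cell values
#'
#' @param df Long data frame with columns `condition`, `replicate`, `value`
#'   (one row per cell). `NA` values must be excluded beforehand.
#' @return Data frame `condition`, `replicate`, `median` with one row per
#'   (condition, replicate).
#' @export
replicate_medians <- function(df) {
  check_grouped(df)
  agg <- stats::aggregate(value ~ condition + replicate, data = df,
                          FUN = stats::median)
  names(agg)[names(agg) == "value"] <- "median"
  agg <- agg[order(agg$condition, agg$replicate), ]
  rownames(agg) <- NULL
  agg
}

#' One-way ANOVA on replicate medians
#'
#' Classical fixed-effects one-way ANOVA across conditions, applied to one
#' value per replicate (typically the replicate medians).
#'
#' @param medians Data frame with columns `condition` and `median` (or
#'   `value`), one row per replicate.
#' @return List with `F`, `p`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(medians) {
  v <- medians$median %||% medians$value
  g <- factor(medians$condition)
  if (nlevels(g) < 2) stop("ANOVA needs >= 2 conditions")
  if (any(table(g) < 2)) stop("every condition needs >= 2 replicate values")
  fit <- stats::aov(v ~ g)
  tab <- summary(fit)[[1]]
  Fv <- tab[["F value"]][1]
  pv <- tab[["Pr(>F)"]][1]
  if (tab[["Sum Sq"]][1] < .Machine$double.eps * sum(v^2 + 1)) {
    # no between-group variation at all (0/0 when groups are constants)
    Fv <- 0
    pv <- 1
  }
  list(F = Fv, p = pv,
       df_between = tab[["Df"]][1], df_within = tab[["Df"]][2])
}

#' Tukey (Tukey-Kramer) post hoc comparisons on replicate medians
#'
#' Pairwise studentized-range tests using the within-group mean square from
#' the one-way ANOVA; the Tukey-Kramer form handles unequal replicate counts
#' (designs mixing n = 4 and n = 5 replicates occur routinely).
#'
#' @inheritParams one_way_anova
#' @return Data frame `comparison`, `diff`, `p_adj`.
#' @export
tukey_hsd <- function(medians) {
  v <- medians$median %||% medians$value
  g <- factor(medians$condition)
  if (nlevels(g) < 2) stop("Tukey needs >= 2 conditions")
  if (any(table(g) < 2)) stop("every condition needs >= 2 replicate values")
  fit <- stats::aov(v ~ g)
  tk <- stats::TukeyHSD(fit)$g
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             p_adj = tk[, "p adj"], row.names = NULL)
}

#' SuperPlot summary of grouped per-cell values
#'
#' The replicate-median workflow in one call: per-replicate medians, per
#' condition the mean and sample SD of those medians, a one-way ANOVA across
#' conditions, and Tukey post hoc comparisons (when at least two conditions
#' have enough replicates).
#'
#' @inheritParams replicate_medians
#' @param tukey Compute Tukey comparisons (default when >= 2 conditions).
#' @return List of class `superplot_summary`: `medians`, `conditions` (mean,
#'   sd over replicate medians, n_replicates), `anova`, `tukey`.
#' @export
superplot_summary <- function(df, tukey = TRUE) {
  meds <- replicate_medians(df)
  conds <- do.call(rbind, lapply(split(meds, meds$condition), function(m) {
    data.frame(condition = m$condition[1],
               mean_of_medians = mean(m$median),
               sd_of_medians = if (nrow(m) < 2) 0 else stats::sd(m$median),
               n_replicates = nrow(m))
  }))
  rownames(conds) <- NULL
  res <- list(medians = meds, conditions = conds, anova = NULL, tukey = NULL)
  if (nlevels(factor(meds$condition)) >= 2 && all(conds$n_replicates >= 2)) {
    res$anova <- one_way_anova(meds)
    if (tukey) res$tukey <- tukey_hsd(meds)
  }
  structure(res, class = "superplot_summary")
}

#' @export
print.superplot_summary <- function(x, ...) {
  cat("<superplot_summary>\n")
  print(x$conditions)
  if (!is.null(x$anova))
    cat(sprintf("one-way ANOVA on replicate medians: F(%d,%d) = %.4g, p = %.4g\n",
                x$anova$df_between, x$anova$df_within, x$anova$F, x$anova$p))
  if (!is.null(x$tukey)) {
    cat("Tukey post hoc:\n")
    print(x$tukey)
  }
  invisible(x)
}

#' Transwell percent of input
#'
#' Transmigrated counts expressed as a percentage of the "input" condition
#' (the same cell volume pipetted directly into the lower well, i.e. the
#' 100%-transmigration reference).
#'
#' @param migrated Transmigrated cell count(s).
#' @param input Input-condition cell count (> 0).
#' @return Percentage(s), `100 * migrated / input`.
#' @export
transwell_percent_of_input <- function(migrated, input) {
  if (any(input <= 0)) stop("input count must be > 0")
  if (any(migrated < 0)) stop("counts must be >= 0")
  100 * migrated / input
}

#' Transwell migration index
#'
#' MI(c) = transmigrated count of condition c divided by the count of the
#' unstimulated reference condition, so the reference has MI = 1 and other
#' values are fold changes. When the reference count is 0 the index is not
#' computable (as happens for lines whose cells barely transmigrate) and all
#' MI values are `NA` with status `"not_computable"`.
#'
#' @param counts Named numeric vector of transmigrated counts, or data frame
#'   with columns `condition`, `count`.
#' @param reference Name of the unstimulated reference condition.
#' @return Data frame `condition`, `count`, `migration_index` with attribute
#'   `"status"` (`"ok"` or `"not_computable"`).
#' @export
migration_index <- function(counts, reference) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("condition", "count") %in% names(counts)))
    df <- counts
  } else {
    df <- data.frame(condition = names(counts), count = as.numeric(counts))
  }
  if (!reference %in% df$condition)
    stop("reference condition '", reference, "' not present")
  ref_count <- df$count[df$condition == reference][1]
  if (ref_count > 0) {
    df$migration_index <- df$count / ref_count
    status <- "ok"
  } else {
    df$migration_index <- NA_real_
    status <- "not_computable"
  }
  attr(df, "status") <- status
  df
}
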