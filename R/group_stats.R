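#' Normality and variance-homogeneity checks for group comparisons
#'
#' Per-group normality (Shapiro-Wilk, or one-sample Kolmogorov-Smirnov
#' against a standardised normal) and Levene's test of variance homogeneity
#' (mean-centred).
#'
#' @param values numeric outcomes.
#' @param groups group labels, same length as `values`; at least two groups
#'   with three or more observations each.
#' @param normality `"shapiro"` or `"ks"`.
#' @return List with `normality` (data.frame: group, n, statistic, p),
#'   `levene_p`, and the test names used.
#' @export
check_assumptions <- function(values, groups,
                              normality = c("shapiro", "ks")) {
  normality <- match.arg(normality)
  groups <- as.character(groups)
  .assert(length(values) == length(groups),
          "values and groups must have equal length")
  sizes <- table(groups)
  .assert(length(sizes) >= 2, "need at least two groups")
  if (any(sizes < 3))
    stop("every group needs at least 3 observations", call. = FALSE)
  rows <- lapply(names(sizes), function(g) {
    x <- values[groups == g]
    tst <- if (normality == "shapiro") shapiro.test(x)
           else suppressWarnings(ks.test((x - mean(x)) / sd(x), "pnorm"))
    data.frame(group = g, n = length(x),
               statistic = unname(tst$statistic), p = tst$p.value,
               stringsAsFactors = FALSE)
  })
  lev <- car::leveneTest(values ~ factor(groups), center = mean)
  list(normality = do.call(rbind, rows),
       normality_test = if (normality == "shapiro") "Shapiro-Wilk"
                        else "Kolmogorov-Smirnov",
       levene_p = lev[["Pr(>F)"]][1])
}

#' Compare outcome distributions across factor levels
#'
#' Two levels: two-sample t-test (equal variances, the classical form).
#' More than two: one-way ANOVA followed by all pairwise t-tests with
#' Bonferroni correction (raw p times the number of comparisons, capped at
#' 1). Assumption checks are attached to the result.
#'
#' @param values numeric outcomes.
#' @param labels factor levels, same length as `values`.
#' @param paired use a paired t-test (2-level case only; observations must
#'   be ordered consistently within level).
#' @param alpha significance threshold for the `significant` flags.
#' @param normality assumption check variant, see [check_assumptions()].
#' @return A `cmc_group_test`: list with `method`, `levels`, `omnibus`
#'   (statistic, df, p), `pairwise` (level_a, level_b, p_raw, p_corrected,
#'   significant), `assumptions`.
#' @export
compare_groups <- function(values, labels, paired = FALSE, alpha = 0.05,
                           normality = c("shapiro", "ks")) {
  labels <- as.character(labels)
  lev <- unique(labels)
  .assert(length(lev) >= 2, "need at least two levels")
  sizes <- table(labels)
  if (any(sizes < 2)) stop("every level needs >= 2 values", call. = FALSE)
  assumptions <- if (all(sizes >= 3))
    check_assumptions(values, labels, normality = match.arg(normality))
  else NULL
  if (length(lev) == 2) {
    tt <- t.test(values[labels == lev[1]], values[labels == lev[2]],
                 var.equal = TRUE, paired = paired)
    omnibus <- list(statistic = unname(tt$statistic),
                    df = unname(tt$parameter), p = tt$p.value)
    pairwise <- data.frame(level_a = lev[1], level_b = lev[2],
                           p_raw = tt$p.value, p_corrected = tt$p.value,
                           significant = tt$p.value < alpha,
                           stringsAsFactors = FALSE)
    method <- if (paired) "paired t-test" else "two-sample t-test"
  } else {
    if (paired)
      stop("paired comparisons are only supported for two levels",
           call. = FALSE)
    fit <- aov(values ~ factor(labels))
    tab <- anova(fit)
    omnibus <- list(statistic = tab[["F value"]][1],
                    df = tab[["Df"]][1:2], p = tab[["Pr(>F)"]][1])
    cmb <- utils::combn(lev, 2)
    m <- ncol(cmb)
    pairwise <- do.call(rbind, lapply(seq_len(m), function(i) {
      a <- cmb[1, i]; b <- cmb[2, i]
      p <- t.test(values[labels == a], values[labels == b],
                  var.equal = TRUE)$p.value
      data.frame(level_a = a, level_b = b, p_raw = p,
                 p_corrected = min(1, p * m),
                 significant = min(1, p * m) < alpha,
                 stringsAsFactors = FALSE)
    }))
    method <- "one-way ANOVA + Bonferroni post-hoc"
  }
  structure(list(method = method, levels = lev, omnibus = omnibus,
                 pairwise = pairwise, assumptions = assumptions,
                 alpha = alpha),
            class = "cmc_group_test")
}

#' @export
print.cmc_group_test <- function(x, ...) {
  cat(x$method, "across", paste(x$levels, collapse = ", "), "\n")
  cat(sprintf("  omnibus p = %.4g\n", x$omnibus$p))
  print(x$pairwise, row.names = FALSE)
  if (!is.null(x$assumptions))
    cat(sprintf("  assumptions: %s min p = %.3g; Levene p = %.3g\n",
                x$assumptions$normality_test,
                min(x$assumptions$normality$p),
                x$assumptions$levene_p))
  invisible(x)
}

# one tidy row per pairwise comparison, omnibus columns repeated
.tidy_test <- function(test, ...) {
  info <- data.frame(..., stringsAsFactors = FALSE)
  cbind(info[rep(1, nrow(test$pairwise)), , drop = FALSE],
        omnibus_p = test$omnibus$p, test$pairwise, row.names = NULL)
}

#' Run the four surface-contact connectivity studies
#'
#' Study 1: connectivity averaged over muscles, compared across surfaces for
#' each EEG channel and band. Study 2: averaged over channels, compared
#' across surfaces per muscle and band. Study 3: broadband per-pair
#' connectivity compared across muscles within each channel, and across
#' surfaces within each (channel, muscle) pair. Study 4: subject-level mean
#' MI (EEG channels averaged) compared across muscles per surface. The unit
#' of analysis is the subject-level aggregate throughout.
#'
#' @param pbc_records a `cmc_pbc` (or `NULL` to skip studies 1-3).
#' @param mi_table a `cmc_mi` (or `NULL` to skip study 4).
#' @param alpha significance threshold.
#' @return A `cmc_studies` list of tidy data.frames (`study1` ... `study4`;
#'   absent inputs give `NULL` entries).
#' @export
run_studies <- function(pbc_records = NULL, mi_table = NULL, alpha = 0.05) {
  out <- list(study1 = NULL, study2 = NULL, study3 = NULL, study4 = NULL)
  if (!is.null(pbc_records)) {
    .assert(length(unique(pbc_records$surface)) >= 2,
            "need records from at least two surfaces")
    agg1 <- pbc_aggregate(pbc_records, "per_channel")
    out$study1 <- do.call(rbind, lapply(
      split(agg1, list(agg1$eeg_channel, agg1$band), drop = TRUE),
      function(d) .tidy_test(compare_groups(d$rho, d$surface, alpha = alpha),
                             eeg_channel = d$eeg_channel[1],
                             band = d$band[1])))
    agg2 <- pbc_aggregate(pbc_records, "per_muscle")
    out$study2 <- do.call(rbind, lapply(
      split(agg2, list(agg2$muscle, agg2$band), drop = TRUE),
      function(d) .tidy_test(compare_groups(d$rho, d$surface, alpha = alpha),
                             muscle = d$muscle[1], band = d$band[1])))
    if ("all" %in% pbc_records$band) {
      agg3 <- pbc_aggregate(pbc_records, "per_pair")
      by_muscle <- do.call(rbind, lapply(
        split(agg3, list(agg3$eeg_channel, agg3$surface), drop = TRUE),
        function(d) .tidy_test(compare_groups(d$rho, d$muscle, alpha = alpha),
                               comparison = "muscles_within_channel",
                               eeg_channel = d$eeg_channel[1],
                               surface = d$surface[1])))
      by_surface <- do.call(rbind, lapply(
        split(agg3, list(agg3$eeg_channel, agg3$muscle), drop = TRUE),
        function(d) .tidy_test(compare_groups(d$rho, d$surface, alpha = alpha),
                               comparison = "surfaces_within_pair",
                               eeg_channel = d$eeg_channel[1],
                               surface = NA_character_,
                               muscle = d$muscle[1])))
      by_muscle$muscle <- NA_character_
      out$study3 <- rbind(by_muscle[, union(names(by_muscle),
                                            names(by_surface))],
                          by_surface[, union(names(by_muscle),
                                             names(by_surface))])
    }
    rownames(out$study1) <- rownames(out$study2) <- NULL
    if (!is.null(out$study3)) rownames(out$study3) <- NULL
  }
  if (!is.null(mi_table)) {
    # subject-level mean MI over the whole series, channels already averaged
    agg4 <- aggregate(mi ~ subject + surface + muscle,
                      data = as.data.frame(mi_table), FUN = mean)
    out$study4 <- do.call(rbind, lapply(
      split(agg4, agg4$surface, drop = TRUE),
      function(d) .tidy_test(compare_groups(d$mi, d$muscle, alpha = alpha),
                             surface = d$surface[1])))
    rownames(out$study4) <- NULL
  }
  class(out) <- "cmc_studies"
  out
}

#' @export
print.cmc_studies <- function(x, ...) {
  for (nm in names(x)) {
    if (is.null(x[[nm]])) next
    cat(nm, ":", nrow(x[[nm]]), "comparisons,",
        sum(x[[nm]]$significant), "significant\n")
  }
  invisible(x)
}
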