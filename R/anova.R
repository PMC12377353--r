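# Factorial analysis of coactivation: two-way (phase x speed) ANOVA,
# Tukey HSD post-hoc comparisons, and Cohen's f effect sizes.

check_cc_observations <- function(obs) {
  req <- c("speed", "phase", "cc")
  if (!is.data.frame(obs) || !all(req %in% names(obs)))
    abort("`obs` must be a data frame with columns speed, phase, cc")
  if (any(!is.finite(obs$cc)))
    abort("`cc` values must be finite")
  obs$phase <- factor(obs$phase)
  obs$speed <- factor(obs$speed)
  if (nlevels(obs$phase) < 2 || nlevels(obs$speed) < 2)
    abort("need at least 2 levels of both phase and speed")
  cells <- table(obs$phase, obs$speed)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    abort(sprintf("empty design cell: phase '%s' x speed '%s'",
                  rownames(cells)[empty[1]], colnames(cells)[empty[2]]))
  }
  obs
}

#' Two-way (phase x speed) ANOVA on coactivation values
#'
#' Fits `cc ~ phase * speed` and returns Type-II sums of squares, degrees of
#' freedom, F and p for the two main effects, their interaction and the
#' residual. Type II is robust to the mild imbalance left by discarded
#' cycles and coincides with Type I/III on balanced designs.
#'
#' @param obs Data frame of observations with columns `speed`, `phase`,
#'   `cc` (one row per observational unit, e.g. one mean CC per
#'   subject x speed x phase cell) and optionally `subject`.
#' @return An object of class `anova_table`: data frame with columns
#'   `source` (`phase`, `speed`, `phase:speed`, `residual`), `ss`, `df`,
#'   `f`, `p`.
#' @export
two_way_anova <- function(obs) {
  obs <- check_cc_observations(obs)
  fit <- stats::lm(cc ~ phase * speed, data = obs)
  rss <- sum(stats::residuals(fit)^2)
  # car refuses a zero residual SS; fall back to the sequential decomposition,
  # which coincides with type II on the (necessarily balanced) degenerate data
  a2 <- if (rss > .Machine$double.eps * max(1, sum(obs$cc^2))) {
    car::Anova(fit, type = 2)
  } else {
    a1 <- suppressWarnings(stats::anova(fit))  # the perfect-fit warning is expected here
    data.frame(`Sum Sq` = a1$`Sum Sq`, Df = a1$Df,
               `F value` = a1$`F value`, `Pr(>F)` = a1$`Pr(>F)`,
               row.names = rownames(a1), check.names = FALSE)
  }
  rn <- rownames(a2)
  pick <- function(label) which(rn == label)
  out <- data.frame(
    source = c("phase", "speed", "phase:speed", "residual"),
    ss = a2$`Sum Sq`[c(pick("phase"), pick("speed"),
                       pick("phase:speed"), pick("Residuals"))],
    df = a2$Df[c(pick("phase"), pick("speed"),
                 pick("phase:speed"), pick("Residuals"))],
    f = c(a2$`F value`[c(pick("phase"), pick("speed"), pick("phase:speed"))], NA),
    p = c(a2$`Pr(>F)`[c(pick("phase"), pick("speed"), pick("phase:speed"))], NA))
  # a factor with zero effect variance has F = 0 by convention, even when the
  # residual variance is also zero (all observations identical); SS at the
  # level of least-squares round-off counts as zero
  out$ss[out$ss < .Machine$double.eps * max(1, sum(obs$cc^2))] <- 0
  zero <- out$source != "residual" & out$ss == 0
  out$f[zero] <- 0
  out$p[zero] <- 1
  structure(out, class = c("anova_table", "data.frame"))
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", ""))))
}

#' @export
print.anova_table <- function(x, ...) {
  d <- as.data.frame(x)
  d$stars <- significance_stars(d$p)
  cat("Two-way ANOVA (Type II SS)\n")
  print(format(d, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Recompute ANOVA F statistics from printed sums of squares
#'
#' Given the effect sums of squares and degrees of freedom together with the
#' residual row, returns `F = (SS/df) / (SS_err/df_err)` for each effect —
#' the arithmetic needed to audit a published ANOVA table without its raw
#' data. p-values follow from the F distribution.
#'
#' @param ss,df Numeric vectors of effect sums of squares and degrees of
#'   freedom (equal length, names preserved).
#' @param ss_error,df_error Residual sum of squares and degrees of freedom.
#' @return Data frame with columns `ss`, `df`, `f`, `p`.
#' @export
#' @examples
#' anova_f_from_ss(c(phase = 7336.39), 3, ss_error = 35816.19, df_error = 188)
anova_f_from_ss <- function(ss, df, ss_error, df_error) {
  if (length(ss) != length(df)) abort("`ss` and `df` must have equal length")
  if (!is_number(ss_error) || !is_number(df_error) ||
      ss_error <= 0 || df_error <= 0)
    abort("residual SS and df must be positive")
  f <- (ss / df) / (ss_error / df_error)
  data.frame(ss = ss, df = df, f = f,
             p = stats::pf(f, df, df_error, lower.tail = FALSE),
             row.names = names(ss))
}

#' Tukey HSD pairwise comparisons for one factor
#'
#' All pairwise comparisons of one factor's levels with the studentized-range
#' correction, controlling the family-wise error rate at `conf_level`. The
#' factor is analysed one-way on the supplied observations, i.e. the other
#' factor is pooled — appropriate after a non-significant companion effect.
#' Group sizes are taken from the observation table, not assumed equal.
#'
#' @param obs Data frame with columns `speed`, `phase`, `cc`.
#' @param factor Which factor to compare: `"phase"` or `"speed"`.
#' @param conf_level Family-wise confidence level (default 0.95).
#' @return Data frame with columns `pair`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(obs, factor = c("phase", "speed"), conf_level = 0.95) {
  factor <- match.arg(factor)
  req <- c(factor, "cc")
  if (!is.data.frame(obs) || !all(req %in% names(obs)))
    abort(sprintf("`obs` must contain columns %s", paste(req, collapse = ", ")))
  g <- base::factor(obs[[factor]])
  if (nlevels(g) < 2)
    abort(sprintf("configuration error: factor '%s' has fewer than 2 levels", factor))
  d <- data.frame(cc = obs$cc, g = g)
  fit <- stats::aov(cc ~ g, data = d)
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$g
  data.frame(pair = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL)
}

#' Cohen's f effect size from an ANOVA table
#'
#' Default variant (`"ss_ratio"`): `f = sqrt(SS_effect / SS_error)`, the
#' partial-eta-squared form `f = sqrt(eta2_p / (1 - eta2_p))`. The
#' alternative `"eta_squared"` uses the total-SS-based eta squared,
#' `f = sqrt(eta2 / (1 - eta2))` with `eta2 = SS_effect / SS_total`. The
#' variant used is recorded in the result because published values do not
#' always state theirs.
#'
#' @param anova An [two_way_anova()] result (or any `anova_table` with the
#'   effect and `residual` rows).
#' @param effect Row label of the effect (default `"phase"`).
#' @param variant `"ss_ratio"` (default) or `"eta_squared"`.
#' @return An object of class `effect_size`: list with `cohen_f`, `effect`,
#'   `variant`, `magnitude` (see [classify_effect_size()]).
#' @export
cohens_f <- function(anova, effect = "phase",
                     variant = c("ss_ratio", "eta_squared")) {
  variant <- match.arg(variant)
  if (!inherits(anova, "anova_table")) abort("`anova` must be an anova_table")
  if (!effect %in% anova$source)
    abort(sprintf("effect '%s' not present in the table", effect))
  ss_e <- anova$ss[anova$source == effect]
  ss_err <- anova$ss[anova$source == "residual"]
  if (!length(ss_err) || ss_err <= 0)
    abort("undefined effect size: residual SS is zero or missing")
  f <- switch(variant,
    ss_ratio = sqrt(ss_e / ss_err),
    eta_squared = {
      eta2 <- ss_e / sum(anova$ss)
      sqrt(eta2 / (1 - eta2))
    })
  structure(list(cohen_f = f, effect = effect, variant = variant,
                 magnitude = classify_effect_size(f)),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's f (%s, variant '%s') = %.4f [%s]\n",
              x$effect, x$variant, x$cohen_f, x$magnitude))
  invisible(x)
}

#' Classify a Cohen's f value
#'
#' Conventional cut-offs: f of 0.10 is a small effect, 0.25 medium, and
#' values higher than 0.40 large. Intervals are lower-inclusive:
#' `[0, 0.10)` negligible, `[0.10, 0.25)` small, `[0.25, 0.40)` medium,
#' `>= 0.40` large.
#'
#' @param f Non-negative Cohen's f value.
#' @return One of `"negligible"`, `"small"`, `"medium"`, `"large"`.
#' @export
#' @examples
#' classify_effect_size(0.4123)
classify_effect_size <- function(f) {
  if (!is_number(f) || f < 0)
    abort("contract violation: `f` must be a non-negative number")
  if (f < 0.10) "negligible"
  else if (f < 0.25) "small"
  else if (f < 0.40) "medium"
  else "large"
}
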