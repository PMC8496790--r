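#' Round half away from zero
#'
#' Conventional "round half up" used for the integer summaries (R's
#' `round()` rounds half to even, which does not match how study tables
#' are customarily printed).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Summarize shortest-captured S2 intervals
#'
#' Produces the per-animal and per-position descriptive summaries of the
#' shortest captured S2 coupling interval: mean and sample standard
#' deviation (n - 1 denominator), both rounded half-up to whole
#' milliseconds. Missing entries are skipped. Groups with fewer than two
#' non-missing values keep their mean but get an undefined (NA) SD and are
#' flagged.
#'
#' @param s2 data.frame with columns `animal`, `position`, `s2_ms`, and
#'   optionally `class` (per-position summaries are then computed within
#'   class).
#' @return list with data.frames `by_animal` and `by_position`, each with
#'   columns `n`, `mean_ms`, `sd_ms`, `flagged`.
#' @export
summarize_s2 <- function(s2) {
  stopifnot(all(c("animal", "position", "s2_ms") %in% names(s2)))
  summarize_group <- function(df, key_cols) {
    keys <- unique(df[key_cols])
    rows <- lapply(seq_len(nrow(keys)), function(r) {
      sel <- rep(TRUE, nrow(df))
      for (k in key_cols) sel <- sel & df[[k]] == keys[[k]][r]
      v <- df$s2_ms[sel]
      v <- v[!is.na(v)]
      data.frame(
        keys[r, , drop = FALSE],
        n = length(v),
        mean_ms = if (length(v)) round_half_up(mean(v)) else NA_real_,
        sd_ms = if (length(v) >= 2L) round_half_up(stats::sd(v)) else NA_real_,
        flagged = length(v) < 2L,
        row.names = NULL
      )
    })
    do.call(rbind, rows)
  }
  by_animal <- summarize_group(s2, "animal")
  pos_keys <- if ("class" %in% names(s2)) c("class", "position") else "position"
  by_position <- summarize_group(s2, pos_keys)
  list(by_animal = by_animal, by_position = by_position)
}

#' Fit the clustered mixed-effects model
#'
#' REML linear mixed model for one outcome of the pacing study:
#' `outcome ~ class + train + position + class:train + class:position`
#' with a random intercept per animal — 9 fixed-effect predictor terms for
#' the 2-class, 2-train, 4-position design. Main effects are assessed with
#' post-fit marginal (adjusted-mean) Wald tests: marginal means average
#' over the levels of the other factors (mean centering), and contrasts
#' are tested with asymptotic Wald z statistics, two-sided.
#'
#' A singular fit (zero estimated animal variance) is returned with
#' ICC = 0 and a convergence note rather than an error.
#'
#' @param table data.frame from [make_study_table()] (columns `animal`,
#'   `class`, `position`, `train`, and the outcome).
#' @param outcome name of the outcome column.
#' @param marginal compute marginal means and Wald contrasts (default
#'   TRUE; disable for speed inside large simulations).
#' @return a `model_fit`: list with `fixed` (coefficient table),
#'   `n_predictors` (non-intercept fixed-effect terms), `animal_var`,
#'   `resid_var`, `icc`, `note`, `n_obs`, and — when `marginal` — `means`
#'   (marginal means per factor) and `contrasts` (class effect,
#'   train-within-class effects, position joint Wald test).
#' @export
fit_mixed <- function(table, outcome = "outcome", marginal = TRUE) {
  stopifnot(outcome %in% names(table))
  for (v in c("animal", "class", "position", "train"))
    if (!v %in% names(table)) stop("missing column: ", v, call. = FALSE)
  cls_per_animal <- tapply(table$class, table$animal, function(x) x[1])
  if (length(unique(table$animal)) < 2L || min(table(cls_per_animal)) < 1L ||
      length(unique(table$class)) < 2L)
    stop("need at least two animals and both classes to fit the model",
         call. = FALSE)
  dat <- table
  dat$.y <- dat[[outcome]]
  dat$animal <- factor(dat$animal)
  dat$class <- factor(dat$class, levels = unique(c("control", dat$class)))
  dat$position <- factor(dat$position)
  dat$train <- factor(dat$train)

  fit <- lme4::lmer(
    .y ~ class + train + position + class:train + class:position +
      (1 | animal),
    data = dat, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  animal_var <- vc$vcov[vc$grp == "animal"]
  resid_var <- vc$vcov[vc$grp == "Residual"]
  icc <- if (animal_var + resid_var > 0) animal_var / (animal_var + resid_var) else 0
  note <- if (lme4::isSingular(fit)) "singular fit: animal variance estimated at zero" else NULL

  cf <- summary(fit)$coefficients
  out <- list(
    fixed = data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                       se = cf[, "Std. Error"], row.names = NULL),
    n_predictors = nrow(cf) - 1L,
    animal_var = animal_var, resid_var = resid_var, icc = icc,
    note = note, n_obs = nrow(dat), model = fit
  )

  if (marginal) {
    # asymptotic df = Wald z tests; the "misleading due to interactions"
    # note is expected — comparing marginal means in the presence of the
    # interactions is exactly the intended mean-centered main-effect test
    quiet <- function(x) suppressMessages(x)
    em_class <- quiet(emmeans::emmeans(fit, ~class, data = dat,
                                       lmer.df = "asymptotic"))
    em_tc <- quiet(emmeans::emmeans(fit, ~train | class, data = dat,
                                    lmer.df = "asymptotic"))
    em_pos <- quiet(emmeans::emmeans(fit, ~position, data = dat,
                                     lmer.df = "asymptotic"))
    class_con <- as.data.frame(emmeans::contrast(em_class, "revpairwise"))
    train_con <- as.data.frame(emmeans::contrast(em_tc, "revpairwise",
                                                 by = "class"))
    pos_joint <- as.data.frame(
      emmeans::test(emmeans::contrast(em_pos, "pairwise"), joint = TRUE))
    out$means <- list(class = as.data.frame(em_class),
                      train_by_class = as.data.frame(em_tc),
                      position = as.data.frame(em_pos))
    out$contrasts <- list(class = class_con, train_by_class = train_con,
                          position_joint = pos_joint)
  }
  class(out) <- "model_fit"
  out
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf(
    "<model_fit> %d obs, %d predictor terms; animal var %.3g, residual var %.3g, ICC %.3f\n",
    x$n_obs, x$n_predictors, x$animal_var, x$resid_var, x$icc))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  if (!is.null(x$contrasts)) {
    cc <- x$contrasts$class
    cat(sprintf("  class effect: %.2f (SE %.2f, p = %.3g)\n",
                cc$estimate, cc$SE, cc$p.value))
    tc <- x$contrasts$train_by_class
    for (r in seq_len(nrow(tc)))
      cat(sprintf("  S2-S1 in %s: %.2f (SE %.2f, p = %.3g)\n",
                  tc$class[r], tc$estimate[r], tc$SE[r], tc$p.value[r]))
  }
  invisible(x)
}

#' Design effect for a clustered sample
#'
#' `D_eff = 1 + (average cluster size - 1) * ICC`: the factor by which
#' clustering inflates the variance of a mean relative to an independent
#' sample, used to discount the nominal sample size.
#'
#' @param avg_cluster_size mean observations per cluster (>= 1).
#' @param icc intraclass correlation coefficient in \[0, 1\].
#' @return the design effect (>= 1).
#' @export
design_effect <- function(avg_cluster_size, icc) {
  if (!is.numeric(avg_cluster_size) || avg_cluster_size < 1)
    stop("avg_cluster_size must be >= 1", call. = FALSE)
  if (!is.numeric(icc) || icc < 0 || icc > 1)
    stop("icc must lie in [0, 1]", call. = FALSE)
  1 + (avg_cluster_size - 1) * icc
}

#' Effective sample size of a clustered sample
#'
#' `n_obs / D_eff`, rounded to an integer (half-up by default).
#'
#' @param n_obs number of observations (>= 1).
#' @param d_eff design effect (>= 1), see [design_effect()].
#' @param rounding `"nearest"` (half-up), `"floor"`, or `"ceiling"`.
#' @return integer effective sample size.
#' @export
effective_sample_size <- function(n_obs, d_eff,
                                  rounding = c("nearest", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  if (n_obs < 1) stop("n_obs must be >= 1", call. = FALSE)
  if (d_eff < 1) stop("d_eff must be >= 1", call. = FALSE)
  x <- n_obs / d_eff
  as.integer(switch(rounding,
    nearest = round_half_up(x),
    floor = floor(x),
    ceiling = ceiling(x)
  ))
}
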