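## Habitat effects on energetic cost: linear mixed models.
##
## Three per-trip responses are modeled against the five-level habitat
## category (reference: urban), with a bird random intercept:
##   duration_h  -> log transform
##   flapping_h  -> square-root transform
##   rate_kJ_h   -> log transform
## Each model is compared against a null model with only the random
## intercept (likelihood-ratio test on ML fits plus delta-AICc), with
## Tukey-adjusted pairwise category contrasts summarized as letter
## groups, and marginal/conditional R-squared:
##   R2m = s2f / (s2f + s2a + s2e)
##   R2c = (s2f + s2a) / (s2f + s2a + s2e)
## where s2f is the variance of the fixed-effect predictor, s2a the
## random-intercept variance and s2e the residual variance.

habitat_levels <- c("urban", "marine", "intertidal", "terrestrial", "mixed")

response_transforms <- c(duration_h = "log", flapping_h = "sqrt",
                         rate_kJ_h = "log")

#' Build the model table with transformed response
#'
#' @param trip_summaries Data frame with one row per kept trip:
#'   `bird_id`, `category` and the response column.
#' @param response One of `"duration_h"`, `"flapping_h"`, `"rate_kJ_h"`.
#' @return Data frame `y` (transformed response), `category` (factor,
#'   reference urban), `bird_id` (factor).
#' @export
transform_response <- function(trip_summaries, response = names(response_transforms)) {
  response <- match.arg(response)
  tr <- response_transforms[[response]]
  v <- trip_summaries[[response]]
  if (is.null(v)) stop("no column `", response, "` in trip summaries",
                       call. = FALSE)
  if (tr == "log" && any(v <= 0)) {
    stop("non-positive ", response, " under log transform in trip(s): ",
         paste(head(which(v <= 0), 10), collapse = ", "), call. = FALSE)
  }
  if (tr == "sqrt" && any(v < 0)) {
    stop("negative ", response, " under sqrt transform", call. = FALSE)
  }
  y <- if (tr == "log") log(v) else sqrt(v)
  data.frame(
    y = y,
    category = factor(trip_summaries$category,
                      levels = intersect(habitat_levels,
                                         unique(trip_summaries$category))),
    bird_id = factor(trip_summaries$bird_id)
  )
}

## Small-sample-corrected AIC.
aicc <- function(fit) {
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  n <- stats::nobs(fit)
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit the habitat-category mixed model
#'
#' Random-intercept linear model `y ~ category + (1 | bird_id)`,
#' REML for the reported estimates, ML refits for the null comparison.
#'
#' @param model_table Output of [transform_response()].
#' @param alpha Significance level for the letter groups (default 0.05).
#' @return A `habitat_model_fit`: list with `fit` (the merMod),
#'   `estimates` (per-level estimate, SE, letter), `chisq`, `df`,
#'   `p_value`, `delta_aicc`, `varcomp` (s2f, s2a, s2e), `r2m`, `r2c`,
#'   `singular` (TRUE when the between-bird variance collapsed to 0),
#'   `contrasts` (Tukey-adjusted pairwise tests).
#' @export
fit_habitat_model <- function(model_table, alpha = 0.05) {
  if (nlevels(droplevels(model_table$bird_id)) < 2) {
    stop("need >= 2 birds for a random intercept", call. = FALSE)
  }
  if (nlevels(droplevels(model_table$category)) < 2) {
    stop("need >= 2 habitat categories", call. = FALSE)
  }
  fit <- lmerTest::lmer(y ~ category + (1 | bird_id), data = model_table,
                        REML = TRUE)
  singular <- lme4::isSingular(fit)
  fit_ml <- lme4::lmer(y ~ category + (1 | bird_id), data = model_table,
                       REML = FALSE)
  null_ml <- lme4::lmer(y ~ 1 + (1 | bird_id), data = model_table,
                        REML = FALSE)
  lrt <- stats::anova(null_ml, fit_ml)
  chisq <- lrt$Chisq[2]
  df <- lrt$Df[2]
  p <- lrt$`Pr(>Chisq)`[2]
  delta_aicc <- aicc(null_ml) - aicc(fit_ml)

  vc <- as.data.frame(lme4::VarCorr(fit))
  s2a <- vc$vcov[vc$grp == "bird_id"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  X <- stats::model.matrix(fit)
  pred <- as.vector(X %*% lme4::fixef(fit))
  s2f <- mean((pred - mean(pred))^2)

  emm <- emmeans::emmeans(fit, "category", lmer.df = "satterthwaite")
  ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "tukey"))
  letters <- cld_letters(levels(droplevels(model_table$category)),
                         ctr, alpha,
                         order_by = summary(emm)$emmean)
  est <- summary(fit)$coefficients
  levs <- levels(droplevels(model_table$category))
  estimates <- data.frame(
    level = levs,
    term = rownames(est),
    estimate = est[, "Estimate"],
    se = est[, "Std. Error"],
    letter = letters[levs],
    row.names = NULL
  )
  out <- list(fit = fit, estimates = estimates, chisq = chisq, df = df,
              p_value = p, delta_aicc = delta_aicc,
              varcomp = c(s2f = s2f, s2a = s2a, s2e = s2e),
              r2m = r2_mixed(s2f, s2a, s2e)[["r2m"]],
              r2c = r2_mixed(s2f, s2a, s2e)[["r2c"]],
              singular = singular, contrasts = ctr, alpha = alpha)
  class(out) <- "habitat_model_fit"
  out
}

#' @export
print.habitat_model_fit <- function(x, ...) {
  cat(sprintf(
    "Habitat mixed model: chisq = %.2f (df %d), p = %.3g, dAICc = %.2f\n",
    x$chisq, x$df, x$p_value, x$delta_aicc))
  cat(sprintf("R2m = %.3f, R2c = %.3f%s\n", x$r2m, x$r2c,
              if (x$singular) " (singular: between-bird variance ~ 0)" else ""))
  print(x$estimates, digits = 3)
  invisible(x)
}

#' Marginal and conditional R-squared from variance components
#'
#' @param s2f Fixed-effect predictor variance.
#' @param s2a Random-intercept variance.
#' @param s2e Residual variance.
#' @return Named numeric `r2m`, `r2c`.
#' @examples
#' r2_mixed(1, 0, 1)  # both 0.5
#' @export
r2_mixed <- function(s2f, s2a, s2e) {
  if (any(c(s2f, s2a, s2e) < 0)) stop("variances must be >= 0", call. = FALSE)
  tot <- s2f + s2a + s2e
  if (tot == 0) stop("all variance components are zero", call. = FALSE)
  c(r2m = s2f / tot, r2c = (s2f + s2a) / tot)
}

## Compact letter display by insert-and-absorb on the non-significant
## pairs. `ctr` is the emmeans pairwise contrast table with columns
## `contrast` ("a - b") and `p.value`.
cld_letters <- function(levels, ctr, alpha, order_by = NULL) {
  sig <- matrix(FALSE, length(levels), length(levels),
                dimnames = list(levels, levels))
  for (i in seq_len(nrow(ctr))) {
    pair <- strsplit(as.character(ctr$contrast[i]), " - ", fixed = TRUE)[[1]]
    pair <- gsub("^\\(|\\)$", "", pair)
    if (ctr$p.value[i] < alpha) {
      sig[pair[1], pair[2]] <- sig[pair[2], pair[1]] <- TRUE
    }
  }
  if (!is.null(order_by)) levels <- levels[order(-order_by)]
  groups <- list(levels)
  for (a in levels) for (b in levels) {
    if (a >= b || !sig[a, b]) next
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      if (all(c(a, b) %in% g)) {
        groups[[gi]] <- setdiff(g, a)
        groups[[length(groups) + 1]] <- setdiff(g, b)
      }
    }
    ## absorb: drop groups contained in another
    keep <- rep(TRUE, length(groups))
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i != j && keep[j] && all(groups[[i]] %in% groups[[j]]) &&
          length(groups[[i]]) < length(groups[[j]])) keep[i] <- FALSE
    }
    groups <- unique(groups[keep])
  }
  ## assign letters in the display order of the first member
  first_pos <- vapply(groups, function(g) min(match(g, levels)), numeric(1))
  groups <- groups[order(first_pos)]
  out <- setNames(rep("", length(levels)), levels)
  for (gi in seq_along(groups)) {
    for (m in groups[[gi]]) out[m] <- paste0(out[m], letters[gi])
  }
  out
}

#' Simulate per-trip responses under the habitat-category mixed model
#'
#' Parametric generator for calibration studies: draws trips with
#' category effects, a bird random intercept and residual noise on the
#' transformed scale. Defaults plant the category effect sizes and
#' variance components of a flight-cost analysis at a realistic scale
#' (605 trips, 17 birds; category mix ~ (0.11, 0.14, 0.45, 0.21,
#' 0.09)).
#'
#' @param effects Named category effects on the transformed scale
#'   (reference level first, effect 0).
#' @param intercept Intercept (reference-level mean).
#' @param n_trips,n_birds Sizes.
#' @param sigma_a,sigma_e Random-intercept and residual sds.
#' @param category_probs Sampling weights for categories.
#' @param seed Integer seed or NULL.
#' @return Data frame `y`, `category`, `bird_id` (a model table).
#' @export
simulate_habitat_response <- function(
    effects = c(urban = 0, marine = -0.40, intertidal = -0.35,
                terrestrial = -0.77, mixed = -0.06),
    intercept = 1.22, n_trips = 605, n_birds = 17,
    sigma_a = 0.21, sigma_e = 0.58,
    category_probs = c(urban = 66, marine = 88, intertidal = 271,
                       terrestrial = 127, mixed = 55),
    seed = NULL) {
  gen <- function() {
    cats <- sample(names(effects), n_trips, replace = TRUE,
                   prob = category_probs[names(effects)])
    birds <- sample(sprintf("bird%02d", seq_len(n_birds)), n_trips,
                    replace = TRUE)
    b <- setNames(rnorm(n_birds, 0, sigma_a),
                  sprintf("bird%02d", seq_len(n_birds)))
    y <- intercept + effects[cats] + b[birds] + rnorm(n_trips, 0, sigma_e)
    data.frame(y = unname(y),
               category = factor(cats, levels = names(effects)),
               bird_id = factor(birds))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}
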