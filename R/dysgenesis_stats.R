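# Cross-level statistics for hybrid dysgenesis assays and the qPCR
# expression / splicing-efficiency analysis.

#' Proportion of dysgenic F1 females
#'
#' @param n_dysgenic,n_normal counts of dysgenic and normal F1 females
#'   (vectorized).
#' @return `n_dysgenic / (n_dysgenic + n_normal)`.
#' @examples
#' dysgenic_proportion(20, 80)
#' @export
dysgenic_proportion <- function(n_dysgenic, n_normal) {
  tot <- n_dysgenic + n_normal
  if (any(tot < 1)) stop("each scored cross needs at least one F1 female")
  n_dysgenic / tot
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Sums the hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table
#' (within relative tolerance 1e-7), computed on the log scale for
#' numerical safety. Used to compare the proportions of dysgenic and normal
#' females between reciprocal crosses.
#'
#' @param a,b,c,d cell counts of the table `rbind(c(a, b), c(c, d))`.
#' @return two-sided p-value; an all-zero table yields 1.
#' @examples
#' fisher_exact_2x2(3, 1, 1, 3)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  m <- a + b          # row 1 margin
  n <- c + d          # row 2 margin
  s <- a + c          # column 1 margin
  if (m + n == 0) return(1)
  k <- max(0, s - n):min(s, m)
  logp <- dhyper(k, m, n, s, log = TRUE)
  logp_obs <- dhyper(a, m, n, s, log = TRUE)
  p <- sum(exp(logp[logp <= logp_obs + log(1 + 1e-7)]))
  min(1, p)
}

#' Per-line resistance from a cross count table
#'
#' Resistance is `1 - mean(dysgenic proportion)` across the repeated
#' crosses of each line in the dysgenic direction (means of repeated
#' crosses, one value per line).
#'
#' @param crosses a cross count table (see [simulate_cross_counts()]).
#' @param log_transform return `log(resistance)` instead.
#' @return named numeric vector per line.
#' @export
resistance_from_crosses <- function(crosses, log_transform = FALSE) {
  d <- crosses[crosses$direction == "dysgenic", , drop = FALSE]
  if (nrow(d) == 0) stop("no crosses in the dysgenic direction")
  prop <- dysgenic_proportion(d$n_dysgenic, d$n_normal)
  res <- 1 - tapply(prop, d$line, mean)
  out <- stats::setNames(as.numeric(res), names(res))
  if (log_transform) log(out) else out
}

#' Binomial GLM for the maternal-line effect
#'
#' Fits a logistic regression of dysgenic vs normal F1 counts on maternal
#' line plus tester subline (dysgenic direction only), and compares it to
#' the subline-only model by a likelihood-ratio test. Fitting is by
#' iteratively reweighted least squares (deviance change < 1e-8, at most
#' 50 iterations); the first line in lexicographic order is the reference
#' level. A fitted coefficient exceeding 15 in absolute value flags
#' (quasi-)separation; the p-value is still reported with a warning status.
#'
#' @param crosses cross count table with columns `line`, `tester_subline`,
#'   `direction`, `n_dysgenic`, `n_normal`.
#' @return list with `coefficients`, `deviance_full`, `deviance_null`,
#'   `lrt_stat`, `df`, `p`, `separation`.
#' @export
line_effect_glm <- function(crosses) {
  d <- crosses[crosses$direction == "dysgenic", , drop = FALSE]
  if (length(unique(d$line)) < 2) stop("need at least 2 lines")
  d$line <- factor(d$line, levels = sort_c(unique(d$line)))
  use_subline <- length(unique(d$tester_subline)) > 1
  ctrl <- glm.control(epsilon = 1e-8, maxit = 50)
  y <- cbind(d$n_dysgenic, d$n_normal)
  full <- if (use_subline)
    glm(y ~ line + tester_subline, family = stats::binomial, data = d,
        control = ctrl)
  else
    glm(y ~ line, family = stats::binomial, data = d, control = ctrl)
  null <- if (use_subline)
    glm(y ~ tester_subline, family = stats::binomial, data = d,
        control = ctrl)
  else
    glm(y ~ 1, family = stats::binomial, data = d, control = ctrl)
  lrt <- null$deviance - full$deviance
  df <- null$df.residual - full$df.residual
  list(coefficients = coef(full),
       deviance_full = full$deviance,
       deviance_null = null$deviance,
       lrt_stat = lrt, df = df,
       p = pchisq(lrt, df, lower.tail = FALSE),
       separation = any(abs(coef(full)) > 15))
}

#' Pearson correlation between two dysgenesis screens
#'
#' Standard Pearson correlation with the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` and a two-sided p from the t
#' distribution with `n - 2` degrees of freedom. Vectors are matched by
#' name when both are named.
#'
#' @param x,y per-line proportions from two screens (n >= 3, both
#'   non-constant).
#' @return list with `r`, `t`, `df`, `p`, `n`.
#' @export
screen_correlation <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    x <- x[common]; y <- y[common]
  }
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("inputs must be non-constant")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value, n = length(x))
}

#' Classify the most and least resistant lines
#'
#' The `k` lines with the lowest mean dysgenic proportion are classified
#' resistant, the `k` highest susceptible. Ties at either boundary are
#' broken lexicographically by line name and flagged.
#'
#' @param line_means named vector of per-line mean dysgenic proportions.
#' @param k number of lines per extreme (`k <= floor(n/2)`).
#' @return list with `resistant`, `susceptible` (character vectors of line
#'   names) and `ties` (logical).
#' @export
classify_extremes <- function(line_means, k) {
  n <- length(line_means)
  stopifnot(k >= 1, k <= floor(n / 2))
  nm <- names(line_means)
  if (is.null(nm)) stop("line_means must be named")
  ord_res <- nm[order(line_means, nm, method = "radix")]
  ord_sus <- nm[order(-line_means, nm, method = "radix")]
  v <- sort(line_means)
  ties <- (k < n && sort(line_means)[k] ==
             sort(line_means)[k + 1]) ||
    (k < n && sort(-line_means)[k] == sort(-line_means)[k + 1])
  list(resistant = ord_res[seq_len(k)],
       susceptible = ord_sus[seq_len(k)],
       ties = isTRUE(ties))
}

#' qPCR relative expression and splicing efficiency
#'
#' Per replicate and condition, `expr(target) =
#' efficiency^-(Ct_target - Ct_reference)` (the delta-Ct identity, with
#' amplification efficiency 2 per cycle by default), and
#' `splicing_efficiency = spliced_expr / total_expr`.
#'
#' @param qpcr long Ct table with columns `line`, `direction`,
#'   `temperature`, `replicate`, `target` (`spliced`, `total`,
#'   `reference`), `ct`.
#' @param efficiency amplification efficiency per cycle.
#' @return data frame per (line, direction, temperature, replicate) with
#'   `spliced_expr`, `total_expr`, `splicing_efficiency`.
#' @export
relative_expression <- function(qpcr, efficiency = 2) {
  key <- c("line", "direction", "temperature", "replicate")
  wide <- stats::reshape(qpcr[, c(key, "target", "ct")],
                         idvar = key, timevar = "target",
                         direction = "wide")
  names(wide) <- sub("^ct\\.", "", names(wide))
  for (tg in c("spliced", "total", "reference"))
    if (is.null(wide[[tg]])) wide[[tg]] <- NA_real_
  if (anyNA(wide$reference))
    stop("missing reference-gene Ct for some condition cells")
  wide$spliced_expr <- efficiency^-(wide$spliced - wide$reference)
  wide$total_expr <- efficiency^-(wide$total - wide$reference)
  wide$splicing_efficiency <- ifelse(
    !is.na(wide$total_expr) & wide$total_expr > 0,
    wide$spliced_expr / wide$total_expr, NA_real_)
  rownames(wide) <- NULL
  wide[, c(key, "spliced_expr", "total_expr", "splicing_efficiency")]
}

#' Box-Cox transformation by profile likelihood
#'
#' Selects the power `lambda` maximizing the Box-Cox profile log-likelihood
#' over a grid on `[-2, 2]` (step 0.01), and returns the transformed
#' values `(x^lambda - 1) / lambda` (or `log(x)` at `lambda = 0`).
#'
#' @param x positive values (n >= 5).
#' @param grid candidate lambda grid.
#' @return list with `lambda`, `transformed`, and the profile `loglik`
#'   (data frame `lambda`, `loglik`).
#' @export
boxcox_lambda <- function(x, grid = seq(-2, 2, by = 0.01)) {
  if (any(x <= 0)) stop("Box-Cox requires strictly positive values")
  if (length(x) < 5) stop("need at least 5 observations")
  n <- length(x)
  slx <- sum(log(x))
  ll <- vapply(grid, function(l) {
    y <- if (abs(l) < 1e-12) log(x) else (x^l - 1) / l
    -n / 2 * log(mean((y - mean(y))^2)) + (l - 1) * slx
  }, numeric(1))
  lambda <- grid[which.max(ll)]
  y <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  list(lambda = lambda, transformed = y,
       loglik = data.frame(lambda = grid, loglik = ll))
}

#' ANOVA of spliced expression or splicing efficiency
#'
#' Sequential (type-I) sums of squares for the model
#' `response ~ direction + temperature + line`, in that factor order.
#'
#' @param data data frame with columns `direction`, `temperature`, `line`
#'   and the response.
#' @param response name of the response column.
#' @return the ANOVA table as a data frame (`term`, `df`, `sum_sq`,
#'   `mean_sq`, `F`, `p`).
#' @export
splicing_anova <- function(data, response) {
  d <- data
  d$.y <- d[[response]]
  d$direction <- factor(d$direction)
  d$temperature <- factor(d$temperature)
  d$line <- factor(d$line)
  terms <- c("direction", "temperature", "line")
  terms <- terms[vapply(terms, function(t) nlevels(d[[t]]) > 1, logical(1))]
  if (length(terms) == 0) stop("no factor with more than one level")
  fml <- as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fit <- lm(fml, data = d)
  if (any(is.na(coef(fit)))) stop("singular design")
  av <- anova(fit)
  data.frame(term = rownames(av), df = av$Df, sum_sq = av$`Sum Sq`,
             mean_sq = av$`Mean Sq`, F = av$`F value`, p = av$`Pr(>F)`,
             stringsAsFactors = FALSE)
}
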