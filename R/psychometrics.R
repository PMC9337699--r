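# Psychometric-function fitting against the true LLR and the decomposition
# of choice errors into bias, noise and variance; group summaries.

#' Fit a three-parameter psychometric function
#'
#' Fits the lapse-rate logistic
#' \deqn{\rho_b(\mathrm{LLR}) = \alpha + \frac{1 - 2\alpha}{1 + e^{-\beta(\mathrm{LLR} - \phi)}}}
#' to a subject-block's high-jar responses by Bernoulli maximum likelihood on
#' per-trial outcomes (\code{method = "ml"}, default) or by least squares on
#' per-LLR proportions (\code{method = "ls"}). The abscissa is the true LLR
#' of each observed sample, computed by the ideal observer; at
#' \code{LLR = phi} the fitted curve equals 0.5 for any lapse rate.
#'
#' Optimization uses \code{optim(L-BFGS-B)} from a deterministic grid of 12
#' start points, with bounds \code{alpha} in [0, 0.5], \code{beta} in
#' (0, 50], \code{phi} in [-20, 20]. Datasets in which every response is the
#' same are fit at the boundary and flagged \code{degenerate}.
#'
#' @param trials Trial data for one subject-block with responses.
#' @param block The [block_config()].
#' @param method \code{"ml"} or \code{"ls"}.
#' @return Object of class \code{psychometric_fit}: \code{alpha},
#'   \code{beta}, \code{phi}, derived \code{bias} (phi clipped to [-10, 10];
#'   positive values mean more low-jar choices), \code{noise} (1/|beta|),
#'   \code{variance} (see [bias_noise_variance()]),
#'   \code{variance_normalized}, per-LLR table \code{by_llr}, the
#'   log-likelihood and a \code{degenerate} flag.
#' @export
fit_psychometric <- function(trials, block, method = c("ml", "ls")) {
  method <- match.arg(method)
  tr <- trials[!is.na(trials$response), , drop = FALSE]
  llr <- vapply(seq_len(nrow(tr)), function(i)
    llr_by_count(block, tr$n[i])[[tr$rare_count[i] + 1L]], numeric(1))
  y <- as.numeric(tr$response == "high")
  key <- signif(llr, 10)
  if (length(unique(key)) < 3L)
    stop("psychometric fit needs at least 3 distinct LLR values", call. = FALSE)
  by_llr <- stats::aggregate(y, by = list(llr = key),
                             FUN = function(v) c(n = length(v), p = mean(v)))
  by_llr <- data.frame(llr = by_llr$llr, n = by_llr$x[, "n"],
                       p_obs = by_llr$x[, "p"])
  obj <- if (method == "ml") {
    function(par) {
      p <- clip(psychometric_curve(llr, par[1], par[2], par[3]), 1e-10, 1 - 1e-10)
      -sum(y * log(p) + (1 - y) * log(1 - p))
    }
  } else {
    function(par) {
      p <- psychometric_curve(by_llr$llr, par[1], par[2], par[3])
      sum(by_llr$n * (by_llr$p_obs - p)^2)
    }
  }
  starts <- expand.grid(alpha = c(0.02, 0.15), beta = c(0.5, 2, 10),
                        phi = c(-2, 1))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[s, ]), obj, method = "L-BFGS-B",
                   lower = c(0, 1e-3, -20), upper = c(0.5, 50, 20)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("psychometric optimization failed", call. = FALSE)
  par <- best$par
  fitted <- psychometric_curve(by_llr$llr, par[1], par[2], par[3])
  v <- sum(by_llr$n * abs(by_llr$p_obs - fitted)) / nrow(by_llr)
  structure(list(alpha = par[1], beta = par[2], phi = par[3],
                 bias = clip(par[3], -10, 10),
                 noise = 1 / abs(par[2]),
                 variance = v,
                 variance_normalized = sum(by_llr$n * abs(by_llr$p_obs - fitted)) /
                   sum(by_llr$n),
                 by_llr = transform(by_llr, p_fit = fitted),
                 logLik = if (method == "ml") -best$value else NA_real_,
                 objective = best$value, method = method,
                 degenerate = length(unique(y)) == 1L,
                 block = block$name),
            class = "psychometric_fit")
}

#' Evaluate the lapse-rate logistic
#'
#' @param llr LLR values.
#' @param alpha Lapse rate in [0, 0.5].
#' @param beta Slope (> 0).
#' @param phi LLR of indifference.
#' @export
psychometric_curve <- function(llr, alpha, beta, phi) {
  alpha + (1 - 2 * alpha) / (1 + exp(-beta * (llr - phi)))
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric fit | block %s> alpha = %.3f, beta = %.3f, phi = %.3f\n",
    x$block, x$alpha, x$beta, x$phi))
  cat(sprintf("  bias = %.3f, noise = %.3f, variance = %.4f%s\n",
              x$bias, x$noise, x$variance,
              if (x$degenerate) " [degenerate: single response]" else ""))
  invisible(x)
}

#' Bias, noise and variance of a fitted psychometric function
#'
#' Bias is the indifference point phi clipped to [-10, 10] (positive values
#' correspond to more low-jar selections); noise is the inverse slope
#' 1/|beta|; variance is the weighted mean absolute residual
#' \deqn{v = \frac1x \sum_i n_i |P_{obs,i} - \rho_{fit,i}|}
#' over the x distinct LLR values (n_i trials at LLR value i). The division
#' by the number of LLR values (rather than the trial total) follows the
#' printed definition; \code{variance_normalized} in the fit divides by the
#' trial total instead.
#'
#' @param fit A \code{psychometric_fit}.
#' @return Named vector \code{c(bias, noise, variance)}.
#' @export
bias_noise_variance <- function(fit) {
  c(bias = fit$bias, noise = fit$noise, variance = fit$variance)
}

#' Map a selected model to its strategy group
#'
#' Nearly Ideal (Noisy Bayesian Set rho), Mistuned Bayesian (Noisy Bayesian
#' or Prior Bayesian) or Heuristic (Variable Rare, Rare Ball, Guess).
#'
#' @param model Vector of model tags.
#' @return Character vector of group labels.
#' @export
strategy_group <- function(model) {
  out <- rep(NA_character_, length(model))
  out[model == "noisy_bayes_set_rho"] <- "Nearly Ideal"
  out[model %in% c("noisy_bayes", "prior_bayes")] <- "Mistuned Bayesian"
  out[model %in% HEURISTIC_MODELS] <- "Heuristic"
  out
}

#' Group summaries of bias and variance
#'
#' Given per-subject-block psychometric measures labelled by selected-model
#' group, computes per-group medians, bootstrap means with percentile 95%
#' confidence intervals (1000 uniform resamples by default), and two-sided
#' Wilcoxon rank-sum tests of each group against the Nearly Ideal group for
#' bias and for variance.
#'
#' @param df Data frame with columns \code{block}, \code{group} (or
#'   \code{selected_model}, converted via [strategy_group()]), \code{bias}
#'   and \code{variance}.
#' @param n_boot Bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return List with \code{summary} (one row per block-group-measure) and
#'   \code{tests} (Wilcoxon p-values against Nearly Ideal). Empty groups are
#'   omitted with a warning.
#' @export
group_summaries <- function(df, n_boot = 1000L, seed = 1L) {
  if (is.null(df$group)) df$group <- strategy_group(df$selected_model)
  set.seed(seed)
  rows <- list(); tests <- list()
  for (blk in unique(df$block)) {
    sub <- df[df$block == blk, ]
    for (grp in c("Nearly Ideal", "Mistuned Bayesian", "Heuristic")) {
      vals <- sub[sub$group == grp, ]
      if (nrow(vals) == 0L) {
        warning(sprintf("no subjects in group '%s' for block %s", grp, blk),
                call. = FALSE)
        next
      }
      for (measure in c("bias", "variance")) {
        x <- vals[[measure]]
        boots <- vapply(seq_len(n_boot), function(i)
          mean(sample(x, length(x), replace = TRUE)), numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          block = blk, group = grp, measure = measure, n = length(x),
          median = stats::median(x), boot_mean = mean(boots),
          ci_lo = stats::quantile(boots, 0.025, names = FALSE),
          ci_hi = stats::quantile(boots, 0.975, names = FALSE))
      }
      if (grp != "Nearly Ideal") {
        ref <- sub[sub$group == "Nearly Ideal", ]
        if (nrow(ref) > 0L) {
          for (measure in c("bias", "variance")) {
            p <- tryCatch(
              stats::wilcox.test(vals[[measure]], ref[[measure]],
                                 exact = FALSE)$p.value,
              error = function(e) NA_real_)
            tests[[length(tests) + 1L]] <- data.frame(
              block = blk, group = grp, measure = measure, p_wilcoxon = p)
          }
        }
      }
    }
  }
  list(summary = do.call(rbind, rows),
       tests = if (length(tests)) do.call(rbind, tests) else NULL)
}
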