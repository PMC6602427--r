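# Evaluation statistics: regression metrics, correlation-comparison tests
# and hotspot classification.

# tie-corrected Kendall tau-b, O(n^2) sign enumeration
kendall_tau_b <- function(x, y) {
  n <- length(x)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sx <- sign(x[pr[, 2]] - x[pr[, 1]])
  sy <- sign(y[pr[, 2]] - y[pr[, 1]])
  s <- sum(sx * sy)
  n0 <- n * (n - 1) / 2
  n1 <- n0 - sum(sx != 0)
  n2 <- n0 - sum(sy != 0)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) return(NA_real_)
  s / den
}

#' Regression evaluation metrics
#'
#' Pearson correlation, tie-corrected Kendall tau-b and RMSE between
#' predicted and observed ddG.  With zero variance in either vector the
#' correlations are \code{NA} (undefined) while the RMSE is still
#' reported.
#'
#' @param pred,obs numeric vectors of equal length >= 2 (kcal/mol).
#' @return named list: \code{pearson}, \code{kendall}, \code{rmse},
#'   \code{n}.
#' @export
regression_metrics <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs differ in length")
  if (length(pred) < 2) stop("need >= 2 observations")
  if (any(!is.finite(pred)) || any(!is.finite(obs)))
    stop("pred and obs must be finite")
  rmse <- sqrt(mean((pred - obs)^2))
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0)
    return(list(pearson = NA_real_, kendall = NA_real_, rmse = rmse,
                n = length(pred)))
  list(pearson = stats::cor(pred, obs),
       kendall = kendall_tau_b(pred, obs),
       rmse = rmse, n = length(pred))
}

#' Fisher r-to-z test for two independent correlations
#'
#' Two-tailed p-value for the difference of two Pearson correlations via
#' \eqn{z = (\mathrm{atanh}(r_1) - \mathrm{atanh}(r_2)) /
#' \sqrt{1/(n_1-3) + 1/(n_2-3)}}.
#'
#' @param r1,r2 correlations with |r| < 1.
#' @param n1,n2 sample sizes (>= 4).
#' @return p-value in (0, 1].
#' @export
fisher_r_to_z_test <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| must be < 1 for the r-to-z transformation")
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in both samples")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  2 * stats::pnorm(-abs(z))
}

#' Kendall tau to Pearson r (Greiner's relation)
#'
#' \eqn{r = \sin(\pi \tau / 2)}; used before comparing a rank correlation
#' with a Pearson correlation through the Fisher r-to-z test.
#'
#' @param tau Kendall correlation in [-1, 1].
#' @return equivalent Pearson correlation.
#' @export
tau_to_r <- function(tau) {
  stopifnot(all(abs(tau) <= 1))
  sin(pi * tau / 2)
}

#' Hotspot classification metrics
#'
#' Binarises predicted and observed ddG at a destabilisation threshold
#' (default 2 kcal/mol): under the package's native sign convention
#' (\code{"native"}) a hotspot is a mutation with ddG <= -threshold; under
#' \code{"skempi"} it is ddG >= threshold.  Reports per-class recall and
#' precision; a class absent from the observations yields \code{NA}
#' recall.
#'
#' @param pred_ddg,obs_ddg numeric vectors of equal length.
#' @param threshold destabilisation threshold in kcal/mol (> 0).
#' @param sign_convention \code{"native"} (destabilising < 0) or \code{"skempi"} (negated scale).
#' @return named list with \code{hotspot_recall}, \code{hotspot_precision},
#'   \code{nonhotspot_recall}, \code{nonhotspot_precision} and the counts.
#' @export
hotspot_metrics <- function(pred_ddg, obs_ddg, threshold = 2.0,
                            sign_convention = c("native", "skempi")) {
  sign_convention <- match.arg(sign_convention)
  if (length(pred_ddg) != length(obs_ddg)) stop("length mismatch")
  if (threshold <= 0) stop("threshold must be > 0")
  is_hot <- function(v) if (sign_convention == "native") v <= -threshold
    else v >= threshold
  ph <- is_hot(pred_ddg); oh <- is_hot(obs_ddg)
  tp <- sum(ph & oh); fp <- sum(ph & !oh)
  fn <- sum(!ph & oh); tn <- sum(!ph & !oh)
  rec <- function(num, den) if (den == 0) NA_real_ else num / den
  list(hotspot_recall = rec(tp, tp + fn),
       hotspot_precision = rec(tp, tp + fp),
       nonhotspot_recall = rec(tn, tn + fp),
       nonhotspot_precision = rec(tn, tn + fn),
       counts = c(tp = tp, fp = fp, fn = fn, tn = tn))
}

#' Evaluate predictions under a split plan
#'
#' Trains and tests a model per split group/fold and reports per-group
#' regression metrics plus their pooled summary.
#'
#' @param features data.frame of feature rows.
#' @param targets numeric ddG vector.
#' @param plan a \code{ppi_split_plan}.
#' @param config model configuration.
#' @param seed training seed.
#' @return list with \code{per_group} data.frame and \code{pooled} metrics
#'   (all held-out predictions against observations).
#' @export
evaluate_split <- function(features, targets, plan,
                           config = model_config(), seed = 1) {
  df <- features_as_df(features)
  asg <- plan$assignments
  per <- list(); pooled_pred <- numeric(0); pooled_obs <- numeric(0)
  run_one <- function(test_rows, label) {
    train_rows <- setdiff(seq_len(nrow(df)), test_rows)
    m <- train_model(df[train_rows, , drop = FALSE], targets[train_rows],
                     config, seed)
    p <- predict_ddg(m, df[test_rows, , drop = FALSE])
    pooled_pred <<- c(pooled_pred, p)
    pooled_obs <<- c(pooled_obs, targets[test_rows])
    mm <- if (length(test_rows) >= 2 && stats::sd(targets[test_rows]) > 0)
      regression_metrics(p, targets[test_rows])
    else list(pearson = NA_real_, kendall = NA_real_,
              rmse = sqrt(mean((p - targets[test_rows])^2)),
              n = length(test_rows))
    data.frame(group = label, pearson = mm$pearson, kendall = mm$kendall,
               rmse = mm$rmse, n = mm$n, stringsAsFactors = FALSE)
  }
  if (plan$scheme == "stratified_kfold_paired") {
    for (r in unique(asg$rep)) for (f in unique(asg$fold)) {
      rows <- asg$row[asg$rep == r & asg$fold == f]
      per[[length(per) + 1]] <- run_one(rows, sprintf("rep%d_fold%d", r, f))
    }
  } else {
    for (g in unique(asg$group)) {
      per[[length(per) + 1]] <- run_one(asg$row[asg$group == g], g)
    }
  }
  list(per_group = do.call(rbind, per),
       pooled = regression_metrics(pooled_pred, pooled_obs))
}

#' Write an evaluation report as JSON
#'
#' @param report list from \code{\link{evaluate_split}} or
#'   \code{\link{regression_metrics}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_evaluation_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
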