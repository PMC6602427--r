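# Synthetic feature/target simulator for parameter-recovery studies of the
# regressor, independent of any structure.  The layout mimics the real
# feature vector: a handful of binary flag-like slots carrying the planted
# signal plus continuous nuisance slots.

#' Simulate a feature table with a planted target
#'
#' Generates \code{n} rows with five binary signal slots and
#' \code{n_noise} standard-normal nuisance slots.  The target is a fixed
#' linear combination of the five signal slots plus Gaussian noise, so the
#' attainable accuracy is known by construction and held-out performance
#' measures how well the learner recovers the planted function.
#'
#' @param n number of rows.
#' @param seed integer seed.
#' @param noise_sd noise standard deviation (kcal/mol scale).
#' @param n_noise number of nuisance slots.
#' @param antisymmetric if \code{TRUE}, rows come in forward/reverse pairs:
#'   the signal slots are sign-flipped and the target negated, mimicking
#'   reverse-mutation augmentation (\code{n} must be even).
#' @return list with \code{features} (data.frame), \code{targets},
#'   \code{truth} (noise-free target) and \code{coefficients}.
#' @export
simulate_feature_table <- function(n = 500, seed = 1, noise_sd = 0.1,
                                   n_noise = 15, antisymmetric = FALSE) {
  coefs <- c(2, 1.5, -2, 1, -1.2)
  with_local_seed(seed, {
    if (antisymmetric) {
      stopifnot(n %% 2 == 0)
      half <- n / 2
      sig <- matrix(stats::rbinom(half * 5, 1, 0.5), half, 5)
      sig <- rbind(sig, -sig)
    } else {
      sig <- matrix(stats::rbinom(n * 5, 1, 0.5), n, 5)
    }
    noise <- matrix(stats::rnorm(nrow(sig) * n_noise), nrow(sig), n_noise)
    truth <- as.numeric(sig %*% coefs)
    eps <- stats::rnorm(nrow(sig), 0, noise_sd)
    if (antisymmetric) eps[(half + 1):n] <- -eps[1:half]
    df <- as.data.frame(cbind(sig, noise))
    names(df) <- c(paste0("signal", 1:5), paste0("nuisance", seq_len(n_noise)))
    list(features = df, targets = truth + eps, truth = truth,
         coefficients = coefs)
  })
}
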