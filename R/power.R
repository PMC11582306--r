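#' Design variants used in the power study
#'
#' `"ely1"`: one ever/last-year pair; `"ely1q"`: one pair plus a third
#' dichotomous question; `"ely2"`: two ever/last-year pairs. All questions
#' share the randomization probability `p`.
#'
#' @param variant One of `"ely1"`, `"ely1q"`, `"ely2"`.
#' @param p Randomization probability.
#' @return An [rr_design()].
#' @export
rr_power_design <- function(variant = c("ely1", "ely1q", "ely2"), p = 5/6) {
  variant <- match.arg(variant)
  switch(variant,
         ely1 = rr_design(rr_ely_pair(p)),
         ely1q = rr_design(rr_ely_pair(p), rr_question(p)),
         ely2 = rr_design(rr_ely_pair(p), rr_ely_pair(p)))
}

## true-category probabilities of a power-study cell: mass pi_never on the
## all-never category, the rest split equally over the remaining categories
power_cell_probs <- function(design, pi_never) {
  K <- length(design$categories)
  pr <- c(pi_never, rep((1 - pi_never) / (K - 1L), K - 1L))
  names(pr) <- design$categories
  pr
}

## deterministic sub-seed per grid cell / replicate stream
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + 7919 * i) %% 2147483629L) + 1L
}

#' Monte-Carlo power to detect SP-no saying/cheating
#'
#' For every combination of design variant, never-carrier prevalence
#' `pi_never`, SP-no prevalence `theta` and sample size `n`, simulates `reps`
#' datasets (remaining true-category mass split equally), fits the null and
#' SP-no models, and rejects when the chosen test of `theta = 0` is
#' significant at `alpha`. The default test is the likelihood-ratio statistic
#' `2 (logLik_spno - logLik_null)` on 1 df; `test = "wald"` uses
#' `(theta_hat / se)^2`. Negative `theta` estimates are retained, so both
#' tests are two-sided in `theta`.
#'
#' Each grid cell uses an independent sub-seed derived deterministically from
#' `seed`, so cells are reproducible individually and jointly.
#'
#' @param variants Character vector of [rr_power_design()] variants.
#' @param pi_never,theta,n Numeric grids.
#' @param p Randomization probability shared by all questions.
#' @param reps Replicates per cell.
#' @param alpha Significance level.
#' @param seed Master seed.
#' @param test `"lr"` or `"wald"`.
#' @param n_starts Starts per fit.
#' @return A data frame with one row per cell: the grid coordinates,
#'   `rejection_rate` and its Monte-Carlo standard error
#'   `sqrt(rate (1 - rate) / reps)`.
#' @export
rr_power_grid <- function(variants = "ely1", pi_never = 0.9,
                          theta = c(0, .05, .1, .15, .2),
                          n = c(200, 500, 1000), p = 5/6,
                          reps = 1000L, alpha = 0.05, seed = 1L,
                          test = c("lr", "wald"), n_starts = 2L) {
  test <- match.arg(test)
  stopifnot(reps >= 1, alpha > 0, alpha < 1)
  grid <- expand.grid(variant = variants, pi_never = pi_never,
                      theta = theta, n = n,
                      stringsAsFactors = FALSE)
  crit <- stats::qchisq(1 - alpha, 1L)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    design <- rr_power_design(g$variant, p)
    probs <- power_cell_probs(design, g$pi_never)
    cell_seed <- derive_seed(seed, i)
    local_seed(cell_seed)
    rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
    rej <- logical(reps)
    for (r in seq_len(reps)) {
      cts <- rr_simulate(design, probs, theta = g$theta, n = g$n,
                         seed = rep_seeds[r])
      rej[r] <- theta_test_rejects(design, cts, test, crit, alpha,
                                   n_starts, rep_seeds[r])
    }
    rate <- mean(rej)
    out[[i]] <- data.frame(g, reps = reps, alpha = alpha,
                           rejection_rate = rate,
                           mc_std_error = sqrt(rate * (1 - rate) / reps))
  }
  do.call(rbind, out)
}

theta_test_rejects <- function(design, counts, test, crit, alpha, n_starts, seed) {
  ## repeated small-sample fits: individual convergence warnings are expected
  ## for near-boundary replicates and are not informative here
  f1 <- suppressWarnings(rr_fit(design, counts, model = "sp_no",
                                n_starts = n_starts, seed = seed,
                                se = test == "wald"))
  if (test == "wald") {
    z2 <- (f1$theta / f1$std_errors["theta"])^2
    return(is.finite(z2) && z2 > crit)
  }
  f0 <- suppressWarnings(rr_fit(design, counts, model = "null",
                                n_starts = n_starts, seed = seed, se = FALSE))
  2 * (f1$loglik - f0$loglik) > crit
}

#' Efficiency and power comparison across randomization probabilities
#'
#' For each value of `p`, reports (a) the empirical standard error of the
#' last-year prevalence estimate under the ever/last-year design versus a
#' single last-year question at matched sample size (both simulated without
#' evasive responding, fitted with the null model), and (b) the Monte-Carlo
#' power of the likelihood-ratio test to detect `theta` in the ever/last-year
#' design. The ever/last-year design estimates the last-year prevalence more
#' precisely, and a `p` closer to 0.5 increases the power to detect evasive
#' responding (at the cost of less precise prevalence estimates).
#'
#' @param p_values Randomization probabilities to compare.
#' @param probs True category probabilities `c(nn, yn, yy)` of the
#'   ever/last-year design.
#' @param theta SP-no prevalence for the power arm.
#' @param n Sample size per replicate.
#' @param reps Replicates.
#' @param alpha Significance level of the LR test.
#' @param seed Master seed.
#' @param n_starts Starts per fit.
#' @return A data frame with one row per `p`: `se_lastyear_ely`,
#'   `se_lastyear_single`, `power_theta`.
#' @export
rr_efficiency_compare <- function(p_values = c(2/3, 5/6),
                                  probs = c(nn = .8, yn = .1, yy = .1),
                                  theta = .1, n = 1000L, reps = 500L,
                                  alpha = 0.05, seed = 1L, n_starts = 2L) {
  probs <- align_probs(probs, c("nn", "yn", "yy"))
  crit <- stats::qchisq(1 - alpha, 1L)
  out <- vector("list", length(p_values))
  for (i in seq_along(p_values)) {
    p <- p_values[i]
    d_ely <- rr_design(rr_ely_pair(p))
    d_one <- rr_design(rr_question(p))
    pi_y <- probs[3L]
    local_seed(derive_seed(seed, i))
    rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
    est_ely <- est_one <- numeric(reps)
    rej <- logical(reps)
    for (r in seq_len(reps)) {
      s <- rep_seeds[r]
      cts <- rr_simulate(d_ely, probs, n = n, seed = s)
      est_ely[r] <- suppressWarnings(
        rr_fit(d_ely, cts, model = "null", n_starts = n_starts,
               seed = s, se = FALSE))$probs["yy"]
      cts1 <- rr_simulate(d_one, c(n = 1 - pi_y, y = pi_y), n = n,
                          seed = s + 1L)
      est_one[r] <- suppressWarnings(
        rr_fit(d_one, cts1, model = "null", n_starts = n_starts,
               seed = s, se = FALSE))$probs["y"]
      ctsp <- rr_simulate(d_ely, probs, theta = theta, n = n, seed = s + 2L)
      rej[r] <- theta_test_rejects(d_ely, ctsp, "lr", crit, alpha, n_starts, s)
    }
    out[[i]] <- data.frame(p = p,
                           se_lastyear_ely = stats::sd(est_ely),
                           se_lastyear_single = stats::sd(est_one),
                           power_theta = mean(rej),
                           theta = theta, n = n, reps = reps)
  }
  do.call(rbind, out)
}
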