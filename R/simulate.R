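#' Simulate randomized-response profile counts
#'
#' Respondent-level generation under any supported design. For each
#' respondent, in documented draw order: (1) SP-no/cheater membership with
#' probability `theta` (members answer "no" to every question, irrespective of
#' the randomizer); (2) for adherent respondents, the true category from
#' `probs`; (3) per question: first the item-evasion draw where flagged, then
#' the randomized answer, equal to the (possibly edited) true answer with
#' that question's probability `p`; (4) for ever/last-year blocks with
#' `theta_yy_yn > 0`, a last-year carrier whose randomized pair came out `yy`
#' reports `yn` instead with conditional probability
#' `theta_yy_yn / (1 - theta)` (so expected proportions match the
#' SP(last-year) transition matrix); (5) item-specific evasion: on flagged
#' questions a respondent whose true answer is "yes" responds, with the given
#' probability, as a non-carrier would — the truthful "yes" is replaced by
#' "no" before the randomizer noise is applied. This pre-randomization
#' editing is equivalent to reallocating true-category mass (carriers of that
#' item behave as non-carriers), which is why it depresses only that item's
#' prevalence estimate and leaves the remaining parameters untouched.
#'
#' For the sub-samples design `n` may be a length-2 vector of sub-sample
#' sizes; a single `n` is split as evenly as possible.
#'
#' @param design An [rr_design()].
#' @param probs Adherent true-category probabilities (named or design order).
#' @param theta SP-no/cheater prevalence in `[0, 1]`.
#' @param theta_yy_yn Last-year editing probability (ever/last-year designs).
#' @param item_evasion Optional vector of per-question evasion probabilities
#'   (length = number of questions, in design order; recycled scalars allowed).
#' @param n Sample size (or per-sub-sample sizes).
#' @param seed Optional integer seed; the same seed reproduces the counts
#'   exactly.
#' @return Named integer vector of profile counts summing to `sum(n)`.
#' @examples
#' d <- rr_design(rr_ely_pair(5/6))
#' rr_simulate(d, c(nn = .8, yn = .1, yy = .1), theta = .1, n = 500, seed = 1)
#' @export
rr_simulate <- function(design, probs, theta = 0, theta_yy_yn = 0,
                        item_evasion = NULL, n, seed = NULL) {
  stopifnot(inherits(design, "rr_design"))
  probs <- align_probs(probs, design$categories)
  if (theta < 0 || theta > 1)
    stop("`theta` must be in [0, 1] for simulation", call. = FALSE)
  if (theta_yy_yn < 0 || theta + theta_yy_yn > 1)
    stop("need 0 <= theta_yy_yn and theta + theta_yy_yn <= 1", call. = FALSE)
  if (theta_yy_yn > 0 && theta >= 1)
    stop("editing requires theta < 1", call. = FALSE)
  if (!is.null(seed)) local_seed(seed)

  if (design$subsamples) {
    if (length(n) == 1L) n <- c(ceiling(n / 2), floor(n / 2))
    stopifnot(length(n) == 2L, all(n >= 0))
    p <- design$blocks[[1L]]$rand$p
    out <- integer(4L)
    for (s in 1:2) {
      ns <- n[s]
      if (ns == 0L) next
      sp <- stats::runif(ns) < theta
      truth <- sample.int(2L, ns, replace = TRUE, prob = probs) == 2L  # TRUE = y
      match_p <- if (s == 1L) p else 1 - p   # complementary in sub-sample 2
      obs <- ifelse(stats::runif(ns) < match_p, truth, !truth)
      obs[sp] <- FALSE
      out[(s - 1L) * 2L + 1:2] <- tabulate(obs + 1L, 2L)
    }
    names(out) <- design$profiles
    return(out)
  }

  ntot <- n
  stopifnot(length(ntot) == 1L, ntot >= 1)
  Q <- design$n_questions
  sp <- stats::runif(ntot) < theta
  cat_idx <- sample.int(length(probs), ntot, replace = TRUE, prob = probs)
  labels <- design$categories[cat_idx]
  ev <- if (is.null(item_evasion)) rep(0, Q) else rep_len(item_evasion, Q)
  if (any(ev < 0 | ev > 1))
    stop("`item_evasion` entries must be probabilities", call. = FALSE)
  obs <- matrix(FALSE, ntot, Q)   # TRUE = "y"
  for (q in seq_len(Q)) {
    truth <- substr(labels, q, q) == "y"
    ## item-specific evasion: a true "yes" is edited to "no" pre-randomization
    if (ev[q] > 0) truth <- truth & !(stats::runif(ntot) < ev[q])
    pq <- question_p(design)[q]
    obs[, q] <- ifelse(stats::runif(ntot) < pq, truth, !truth)
  }
  ## last-year editing within each ever/last-year block
  if (theta_yy_yn > 0) {
    cedit <- theta_yy_yn / (1 - theta)
    offs <- block_char_offsets(design)
    for (b in ely_blocks(design)) {
      j <- offs[[b]]
      is_yy <- substr(labels, j[1L], j[1L]) == "y" &
               substr(labels, j[2L], j[2L]) == "y"
      edit <- is_yy & obs[, j[1L]] & obs[, j[2L]] & stats::runif(ntot) < cedit
      obs[edit, j[2L]] <- FALSE
    }
  }
  obs[sp, ] <- FALSE
  idx <- as.integer(obs %*% 2L^((Q - 1L):0)) + 1L
  out <- tabulate(idx, 2L^Q)
  names(out) <- design$profiles
  out
}

question_p <- function(design) {
  unlist(lapply(design$blocks, function(b) rep(b$rand$p, b$n_questions)))
}

#' Sensitivity of the SP-no fit to item-specific evasion
#'
#' Repeatedly simulates a design with one ever/last-year pair plus one single
#' question, applying extra evasion to the single question only, fits the
#' SP-no model to each replicate and summarizes the bias of every estimate.
#' The expected pattern: the ever/last-year category estimates and `theta`
#' remain unbiased, while the single-question ("extra") prevalence is
#' underestimated, because the saturated margin of the extra question absorbs
#' its excess evasive responses.
#'
#' @param design An [rr_design()] with one ever/last-year block and one single
#'   block, in that order.
#' @param probs Adherent true-category probabilities.
#' @param theta SP-no prevalence used in the simulation.
#' @param evasion Extra evasion probability on the single question.
#' @param n Sample size per replicate.
#' @param reps Number of replicates.
#' @param seed Integer seed.
#' @param n_starts Starts per fit (fits are small; a few suffice).
#' @return A data frame with one row per parameter: truth, mean estimate,
#'   bias and Monte-Carlo standard error of the mean.
#' @export
rr_sensitivity_evasion <- function(design, probs, theta, evasion, n, reps,
                                   seed = 1L, n_starts = 3L) {
  kinds <- vapply(design$blocks, `[[`, character(1L), "kind")
  if (!identical(kinds, c("ever_last_year", "single")))
    stop("expected a design of one ever/last-year pair plus one single question",
         call. = FALSE)
  probs <- align_probs(probs, design$categories)
  Q <- design$n_questions
  ev <- c(rep(0, Q - 1L), evasion)
  est <- matrix(NA_real_, reps, length(probs) + 1L)
  local_seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, reps)
  for (r in seq_len(reps)) {
    cts <- rr_simulate(design, probs, theta = theta, item_evasion = ev,
                       n = n, seed = seeds[r])
    fit <- suppressWarnings(rr_fit(design, cts, model = "sp_no",
                                   n_starts = n_starts, seed = seeds[r],
                                   se = FALSE))
    est[r, ] <- fit$estimates
  }
  truth <- c(probs, theta)
  data.frame(parameter = c(design$categories, "theta"),
             truth = truth,
             mean_estimate = colMeans(est),
             bias = colMeans(est) - truth,
             mc_se = apply(est, 2L, stats::sd) / sqrt(reps),
             row.names = NULL)
}
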