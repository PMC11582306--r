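#' Forward map from true-category probabilities to observed-profile probabilities
#'
#' Computes `pi_star = P %*% pi` for the requested bias structure, as an exact
#' matrix product with no renormalization. For `bias = "cdm"` the probability
#' vector must include the cheater category (labelled `"c"`, last); for the
#' SP-no and SP(last-year) mixtures the class probability is passed as `theta`.
#'
#' @param design An [rr_design()].
#' @param probs Named (or design-ordered) probability vector over the adherent
#'   true categories; includes the cheater probability for `"cdm"`. Must sum
#'   to 1.
#' @param bias,theta,theta_yy_yn See [rr_design_matrix()].
#' @return Named vector of observed-profile probabilities, summing to 1 within
#'   each sub-sample block. The sub-sample membership of each entry is in
#'   `attr(, "block")`.
#' @examples
#' d <- rr_design(rr_question(0.8), subsamples = TRUE)
#' rr_forward(d, c(n = .8, y = .2))                     # (.68, .32, .32, .68)
#' rr_forward(d, c(n = .7, y = .2, c = .1), bias = "cdm")
#' @export
rr_forward <- function(design, probs, bias = c("none", "cdm", "sp_no", "sp_last_year"),
                       theta = 0, theta_yy_yn = 0) {
  bias <- match.arg(bias)
  Tm <- rr_design_matrix(design, bias = bias, theta = theta,
                         theta_yy_yn = theta_yy_yn)
  probs <- align_probs(probs, colnames(Tm))
  out <- as.numeric(unclass(Tm) %*% probs)
  names(out) <- rownames(Tm)
  attr(out, "block") <- attr(Tm, "block")
  out
}

align_probs <- function(probs, labels, tol = 1e-10) {
  if (!is.numeric(probs) || length(probs) != length(labels))
    stop(sprintf("expected %d probabilities for categories (%s)",
                 length(labels), paste(labels, collapse = ", ")), call. = FALSE)
  if (!is.null(names(probs))) {
    if (!setequal(names(probs), labels))
      stop("probability names do not match the design's true categories",
           call. = FALSE)
    probs <- probs[labels]
  }
  if (any(probs < -tol))
    stop("probabilities must be non-negative", call. = FALSE)
  if (abs(sum(probs) - 1) > tol)
    stop("probabilities must sum to 1", call. = FALSE)
  as.numeric(probs)
}

#' Log-linear probabilities for true response profiles
#'
#' Cell probabilities of the joint distribution of several dichotomous
#' sensitive attributes under a log-linear model with dummy coding (true
#' response `n` as reference, reference effects fixed at 0). With `pairwise =
#' NULL` this is the full independence model (main effects only), the
#' identification used by the two-question SP-no model; with all pairwise
#' interactions it is the no-three-way-interaction model for three questions.
#'
#' @param main Numeric vector of main effects, one per question (the
#'   log-linear effect of a `y` response).
#' @param pairwise Optional numeric vector of pairwise interaction effects, in
#'   the order (AB, AC, BC, ...) of `utils::combn(Q, 2)`.
#' @return Named probability vector over the `2^Q` true profiles (lexicographic,
#'   `n` before `y`, first question slowest), with the normalizing constant
#'   `lambda0` as an attribute.
#' @examples
#' # marginals (.5, .5) x (.8, .2): product structure pi_yy = .5 * .2
#' rr_loglinear_probs(main = c(0, log(.2 / .8)))
#' @export
rr_loglinear_probs <- function(main, pairwise = NULL) {
  Q <- length(main)
  if (Q < 2L) stop("need at least two questions", call. = FALSE)
  cells <- cross_labels(rep(list(c("n", "y")), Q))
  X <- loglinear_model_matrix(cells, Q, include_pairwise = !is.null(pairwise))
  coefs <- c(main, pairwise)
  if (length(coefs) != ncol(X))
    stop(sprintf("expected %d parameters, got %d", ncol(X), length(coefs)),
         call. = FALSE)
  lp <- as.numeric(X %*% coefs)
  if (any(!is.finite(lp))) stop("non-finite linear predictor", call. = FALSE)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  names(pr) <- cells
  attr(pr, "lambda0") <- -log(sum(exp(lp)))
  pr
}

loglinear_model_matrix <- function(cells, Q, include_pairwise = FALSE) {
  ind <- vapply(seq_len(Q), function(q) substr(cells, q, q) == "y",
                logical(length(cells)))
  X <- ind * 1
  colnames(X) <- paste0("main", seq_len(Q))
  if (include_pairwise) {
    pairs <- utils::combn(Q, 2L)
    P <- apply(pairs, 2L, function(ij) (ind[, ij[1L]] & ind[, ij[2L]]) * 1)
    colnames(P) <- apply(pairs, 2L, function(ij) paste0("pair", ij[1L], ij[2L]))
    X <- cbind(X, P)
  }
  X
}

#' Correspondence between the CDM and SP-no parameters (sub-samples design)
#'
#' The cheater-detection model (categories `n`, `y`, `c`) and the SP-no model
#' (categories `n`, `y` plus SP-no probability `theta`) for the sub-samples
#' design are reparameterizations of each other; the mapping depends on the
#' assumed true status of the evasive class. `"theta_equal"` assumes carriers
#' and non-carriers are equally likely to be SP-no sayers; `"theta_n_zero"`
#' assumes only carriers are (cheaters count as carriers, the upper bound);
#' `"theta_y_zero"` assumes only non-carriers are (the lower bound).
#' `rr_spno_to_cdm()` is the exact closed-form inverse.
#'
#' @param tau Named vector `c(n = , y = , c = )` of CDM category probabilities.
#' @param variant One of `"theta_equal"`, `"theta_n_zero"`, `"theta_y_zero"`.
#' @return `rr_cdm_to_spno()`: list with `pi` (named `c(n, y)`) and `theta`.
#'   `rr_spno_to_cdm()`: named vector `c(n, y, c)`.
#' @examples
#' rr_cdm_to_spno(c(n = .7, y = .2, c = .1), "theta_equal")
#' @export
rr_cdm_to_spno <- function(tau, variant = c("theta_equal", "theta_n_zero", "theta_y_zero")) {
  variant <- match.arg(variant)
  tau <- align_probs(tau, c("n", "y", "c"))
  tn <- tau[1L]; ty <- tau[2L]; tc <- tau[3L]
  out <- switch(variant,
    theta_equal = {
      if (tc >= 1) stop("tau_c = 1: correspondence undefined", call. = FALSE)
      list(pi = c(n = tn / (1 - tc), y = ty / (1 - tc)), theta = tc)
    },
    theta_n_zero = list(pi = c(n = tn, y = ty + tc), theta = tc / (1 - tn)),
    theta_y_zero = list(pi = c(n = tn + tc, y = ty), theta = tc / (1 - ty)))
  out$variant <- variant
  out
}

#' @rdname rr_cdm_to_spno
#' @param pi Named vector `c(n = , y = )` of SP-no adherent probabilities.
#' @param theta SP-no probability.
#' @export
rr_spno_to_cdm <- function(pi, theta, variant = c("theta_equal", "theta_n_zero", "theta_y_zero")) {
  variant <- match.arg(variant)
  pi <- align_probs(pi, c("n", "y"))
  pn <- pi[1L]; py <- pi[2L]
  tau <- switch(variant,
    theta_equal = c(n = pn * (1 - theta), y = py * (1 - theta), c = theta),
    theta_n_zero = {
      tc <- theta * (1 - pn)
      c(n = pn, y = py - tc, c = tc)
    },
    theta_y_zero = {
      tc <- theta * (1 - py)
      c(n = pn - tc, y = py, c = tc)
    })
  tau
}

#' Fraction of actually misreported responses
#'
#' The SP-no/cheating prevalence `theta` is not the proportion of misreported
#' answers: most evasive respondents are required to answer "no" by the
#' randomizer anyway. With a design in which a non-carrier answers "no" with
#' probability `p_nn`, the proportion of responses in the whole sample that are
#' actually misreported is
#' `theta * (1 - pi_y) * (1 - p_nn) + theta * pi_y * p_nn`.
#'
#' @param pi_y Prevalence of carriers.
#' @param theta Prevalence of SP-no sayers/cheaters.
#' @param p_nn Probability that a non-carrier must answer "no".
#' @return The misreported-response fraction.
#' @examples
#' rr_misreport_fraction(pi_y = .1, theta = .2, p_nn = 5/6)  # about 0.047
#' @export
rr_misreport_fraction <- function(pi_y, theta, p_nn) {
  for (a in list(pi_y, theta, p_nn))
    if (!is.numeric(a) || any(a < 0) || any(a > 1))
      stop("all arguments must be probabilities in [0, 1]", call. = FALSE)
  theta * (1 - pi_y) * (1 - p_nn) + theta * pi_y * p_nn
}

#' Exact cheater-detection solution for the sub-samples design
#'
#' Solves the saturated CDM linear system for the conditional observed
#' probabilities of the two sub-samples, returning the category probabilities
#' `(n, y, c)` and the implied interval estimate of the carrier prevalence:
#' lower bound `tau_y` (adherent carriers) and upper bound `tau_y + tau_c`
#' (adherent carriers plus cheaters).
#'
#' @param pistar Vector of conditional observed probabilities
#'   `(n|1, y|1, n|2, y|2)`; each sub-sample pair must sum to 1.
#' @param rand Randomization probability or [rr_rand()] object.
#' @return List with `tau` (named vector) and `bounds` (`lower`, `upper`).
#' @examples
#' rr_cdm_invert_subsamples(c(.7, .3, .4, .6), 0.8)  # tau = (.7, .2, .1)
#' @export
rr_cdm_invert_subsamples <- function(pistar, rand) {
  rand <- as_rr_rand(rand)
  if (length(pistar) != 4L || any(pistar < 0) ||
      abs(sum(pistar[1:2]) - 1) > 1e-8 || abs(sum(pistar[3:4]) - 1) > 1e-8)
    stop("`pistar` must be (n|1, y|1, n|2, y|2) with each pair summing to 1",
         call. = FALSE)
  A <- unclass(rr_add_cheater(rr_tm_subsamples(rand)))
  tau <- qr.solve(A, as.numeric(pistar))
  names(tau) <- colnames(A)
  list(tau = tau,
       bounds = c(lower = unname(tau["y"]),
                  upper = unname(tau["y"] + tau["c"])))
}
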