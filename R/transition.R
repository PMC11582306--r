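#' Transition matrices of randomized-response designs
#'
#' A transition matrix holds the conditional probabilities
#' P(observed response profile | true category): rows are labelled by observed
#' profiles, columns by true categories, and within each sub-sample block every
#' column sums to 1. The forward model of every design is
#' `pi_star = P %*% pi`.
#'
#' @name rr_tmat
#' @keywords internal
NULL

new_rr_tmat <- function(m, block = rep(1L, nrow(m))) {
  attr(m, "block") <- block
  class(m) <- c("rr_tmat", class(m))
  m
}

#' @export
print.rr_tmat <- function(x, ...) {
  m <- x
  attributes(m)[c("block", "class")] <- NULL
  dim(m) <- dim(x)
  dimnames(m) <- dimnames(x)
  print(m, ...)
  if (length(unique(attr(x, "block"))) > 1L)
    cat("row blocks:", paste(attr(x, "block"), collapse = " "), "\n")
  invisible(x)
}

## validate column sums per block and entry range
check_tmat <- function(m, tol = 1e-12, entries = TRUE) {
  block <- attr(m, "block")
  if (is.null(block)) block <- rep(1L, nrow(m))
  for (b in unique(block)) {
    cs <- colSums(m[block == b, , drop = FALSE])
    if (any(abs(cs - 1) > tol))
      stop("transition-matrix columns must sum to 1 within each block",
           call. = FALSE)
  }
  if (entries && (any(m < -tol) || any(m > 1 + tol)))
    stop("transition-matrix entries must lie in [0, 1]", call. = FALSE)
  invisible(m)
}

#' 2x2 transition matrix of a single RR question
#'
#' For the symmetric design the matrix is `[[p, q], [q, p]]` with rows and
#' columns `(n, y)`. Warner's design, the forced response design and the
#' unrelated-question design all reduce to this form, which is why they are
#' mathematically equivalent. An asymmetric matrix with
#' `p_{n|n} != p_{y|y}` may be requested via `p_nn`; this general form is
#' supported for single 2x2 matrices only.
#'
#' @param rand An [rr_rand()] object or a probability `p`. Interpreted as
#'   `p_{y|y}` when `p_nn` is supplied.
#' @param p_nn Optional `p_{n|n}` for the asymmetric form of the design.
#' @return A 2x2 transition matrix (class `"rr_tmat"`).
#' @examples
#' rr_tm_single(0.8)
#' @export
rr_tm_single <- function(rand, p_nn = NULL) {
  rand <- as_rr_rand(rand)
  if (is.null(p_nn)) {
    m <- matrix(c(rand$p, rand$q, rand$q, rand$p), 2L, 2L,
                dimnames = list(c("n", "y"), c("n", "y")))
  } else {
    if (!is.numeric(p_nn) || length(p_nn) != 1L || p_nn <= 0 || p_nn > 1)
      stop("`p_nn` must be a probability in (0, 1]", call. = FALSE)
    if (isTRUE(all.equal(p_nn, 0.5)))
      warning("p_nn = 0.5: the non-carrier responses are uninformative",
              call. = FALSE)
    ## rows r = n, y; cols t = n, y; entries p_{r|t}
    m <- matrix(c(p_nn, 1 - p_nn, 1 - rand$p, rand$p), 2L, 2L,
                dimnames = list(c("n", "y"), c("n", "y")))
  }
  check_tmat(new_rr_tmat(m))
}

#' 4x2 transition matrix of the sub-samples design
#'
#' Two non-overlapping sub-samples are interviewed with complementary
#' randomization probabilities: `p = p_{n|n} = p_{y|y}` in sub-sample 1 and
#' `p = p_{n|y} = p_{y|n}` in sub-sample 2. Rows are the conditional observed
#' responses `(n|1, y|1, n|2, y|2)`; each sub-sample block's columns sum to 1.
#' Under instruction adherence `pi*_{n|1} + pi*_{n|2} = 1`, which is the
#' testable implication that the cheater-detection model exploits.
#'
#' @inheritParams rr_tm_single
#' @return A 4x2 blocked transition matrix.
#' @examples
#' rr_tm_subsamples(0.8)
#' @export
rr_tm_subsamples <- function(rand) {
  rand <- as_rr_rand(rand)
  p <- rand$p; q <- rand$q
  m <- rbind(c(p, q), c(q, p), c(q, p), c(p, q))
  dimnames(m) <- list(c("n|1", "y|1", "n|2", "y|2"), c("n", "y"))
  check_tmat(new_rr_tmat(m, block = c(1L, 1L, 2L, 2L)))
}

#' 4x3 transition matrix of the ever/last-year design
#'
#' Both questions of the pair share the randomization probability `p`. The true
#' profile `ny` (never used, yet used last year) is impossible, so the matrix
#' has observed rows `(nn, ny, yn, yy)` but only the three true categories
#' `(nn, yn, yy)`: never, former, and last-year carriers.
#'
#' @inheritParams rr_tm_single
#' @return A 4x3 transition matrix.
#' @examples
#' rr_tm_ely(5/6)
#' @export
rr_tm_ely <- function(rand) {
  rand <- as_rr_rand(rand)
  p <- rand$p; q <- rand$q
  m <- cbind(nn = c(p^2, p * q, q * p, q^2),
             yn = c(q * p, q^2, p^2, p * q),
             yy = c(q^2, q * p, p * q, p^2))
  rownames(m) <- c("nn", "ny", "yn", "yy")
  check_tmat(new_rr_tmat(m))
}

#' Kronecker product of transition matrices
#'
#' Combines the matrices of independent question blocks into the matrix of the
#' joint design, e.g. `P_{8x6} = P_{4x3} %x% P_{2x2}` for an ever/last-year
#' pair plus a third question. Row and column labels are concatenated with the
#' leftmost factor varying slowest. Replacing a factor with an identity matrix
#' leaves that variable unrandomized (a directly-questioned or non-randomized
#' classification variable).
#'
#' @param ... Transition matrices (or a single list of them). Blocked
#'   (sub-sample) matrices cannot be combined this way.
#' @return The Kronecker-product transition matrix.
#' @examples
#' rr_kronecker(rr_tm_ely(5/6), rr_tm_single(5/6))
#' @export
rr_kronecker <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1L]]) && !is.matrix(mats[[1L]]))
    mats <- mats[[1L]]
  if (length(mats) == 0L) stop("need at least one matrix", call. = FALSE)
  if (any(vapply(mats, function(m) length(unique(attr(m, "block"))) > 1L,
                 logical(1L))))
    stop("blocked (sub-sample) matrices cannot enter a Kronecker product",
         call. = FALSE)
  out <- Reduce(function(a, b) {
    k <- kronecker(unclass(a), unclass(b))
    dimnames(k) <- list(cross_labels(list(rownames(a), rownames(b))),
                        cross_labels(list(colnames(a), colnames(b))))
    k
  }, mats)
  check_tmat(new_rr_tmat(out))
}

#' Append the cheater category to a transition matrix
#'
#' The cheater-detection model adds a latent true category `c` of respondents
#' who answer "no" to every question irrespective of the randomizer. Its column
#' is the indicator of the all-"no" observed profile within each sub-sample
#' block, so per-block column sums remain 1.
#'
#' @param tm A transition matrix built by the constructors in this package.
#' @return The matrix with one extra column labelled `"c"`.
#' @examples
#' rr_add_cheater(rr_tm_subsamples(0.8))
#' rr_add_cheater(rr_tm_ely(5/6))
#' @export
rr_add_cheater <- function(tm) {
  block <- attr(tm, "block")
  if (is.null(block)) block <- rep(1L, nrow(tm))
  lab <- gsub("[^ny]", "", rownames(tm))
  allno <- !grepl("y", lab) & nzchar(lab)
  for (b in unique(block)) {
    if (sum(allno & block == b) != 1L)
      stop("no unique all-'no' observed profile in block ", b, call. = FALSE)
  }
  out <- cbind(unclass(tm), c = as.numeric(allno))
  check_tmat(new_rr_tmat(out, block = block))
}

#' SP(last-year) transition matrix for one ever/last-year pair
#'
#' Extends the ever/last-year matrix with two bias parameters: `theta`, the
#' probability of belonging to the self-protective all-"no" class, and
#' `theta_yy_yn`, the probability that a last-year carrier answers `yn` (edits
#' the last-year answer to "no") when the randomizer produced `yy`. Both
#' parameters are folded into the matrix so columns still sum to 1.
#'
#' `theta` may be mildly negative (down to `theta_lower`), mirroring the
#' estimation convention under which the SP-no parameter is unbounded below;
#' `theta + theta_yy_yn` must not exceed 1.
#'
#' @inheritParams rr_tm_single
#' @param theta SP-no class probability.
#' @param theta_yy_yn Last-year editing probability.
#' @param theta_lower Lower bound accepted for the two bias parameters.
#' @return A 4x3 transition matrix.
#' @examples
#' rr_tm_sp_lastyear(5/6, theta = 0.1, theta_yy_yn = 0.2)
#' @export
rr_tm_sp_lastyear <- function(rand, theta, theta_yy_yn, theta_lower = -0.5) {
  rand <- as_rr_rand(rand)
  check_theta(theta, theta_lower)
  check_theta(theta_yy_yn, theta_lower)
  if (theta + theta_yy_yn > 1 + 1e-12)
    stop("theta + theta_yy_yn must not exceed 1", call. = FALSE)
  p <- rand$p
  base <- unclass(rr_tm_ely(rand))
  m <- (1 - theta) * base
  m[1L, ] <- m[1L, ] + theta            # SP-no mass lands on the all-"no" row
  m["yn", "yy"] <- m["yn", "yy"] + theta_yy_yn * p^2
  m["yy", "yy"] <- m["yy", "yy"] - theta_yy_yn * p^2
  check_tmat(new_rr_tmat(m), entries = theta >= 0 && theta_yy_yn >= 0)
}

check_theta <- function(theta, theta_lower = -0.5) {
  if (!is.numeric(theta) || any(!is.finite(theta)))
    stop("bias parameters must be finite numbers", call. = FALSE)
  if (any(theta < theta_lower - 1e-12) || any(theta > 1 + 1e-12))
    stop(sprintf("bias parameter outside [%g, 1]", theta_lower), call. = FALSE)
  invisible(theta)
}

## per-ELY-block edit matrix: null matrix plus conditional edit `cedit`
## moving p^2 of the yy column from row yy to row yn
ely_edit_matrix <- function(rand, cedit) {
  m <- unclass(rr_tm_ely(rand))
  p <- rand$p
  m["yn", "yy"] <- m["yn", "yy"] + cedit * p^2
  m["yy", "yy"] <- m["yy", "yy"] - cedit * p^2
  m
}

#' Transition matrix of a full design, with optional bias structure
#'
#' Builds the observed-by-true transition matrix for any supported design:
#' the Kronecker product over question blocks (or the 4x2 sub-samples matrix),
#' optionally augmented for a response-bias model. `"cdm"` appends the cheater
#' column; `"sp_no"` mixes the adherent matrix with the all-"no" indicator,
#' `(1 - theta) P + theta e 1'` (for the sub-samples design `theta` may be a
#' per-category vector `c(n = , y = )`); `"sp_last_year"` additionally moves
#' last-year carriers from `yy` to `yn` responses in every ever/last-year
#' block, applying `theta_yy_yn` symmetrically when there are two pairs.
#'
#' @param design An [rr_design()].
#' @param bias One of `"none"`, `"cdm"`, `"sp_no"`, `"sp_last_year"`.
#' @param theta SP-no/cheater probability (ignored for `"none"`/`"cdm"`).
#' @param theta_yy_yn Last-year editing probability (`"sp_last_year"` only).
#' @param theta_lower Lower bound accepted for bias parameters.
#' @return A transition matrix with per-block columns summing to 1.
#' @examples
#' d <- rr_design(rr_ely_pair(5/6), rr_question(5/6))
#' dim(rr_design_matrix(d))                    # 8 x 6
#' dim(rr_design_matrix(d, bias = "cdm"))      # 8 x 7
#' @export
rr_design_matrix <- function(design, bias = c("none", "cdm", "sp_no", "sp_last_year"),
                             theta = 0, theta_yy_yn = 0, theta_lower = -0.5) {
  stopifnot(inherits(design, "rr_design"))
  bias <- match.arg(bias)
  if (design$subsamples) {
    base <- rr_tm_subsamples(design$blocks[[1L]]$rand)
  } else if (length(design$blocks) == 1L) {
    base <- block_null_tm(design$blocks[[1L]])
  } else {
    base <- rr_kronecker(lapply(design$blocks, block_null_tm))
  }
  if (bias == "none") return(base)
  if (bias == "cdm") return(rr_add_cheater(base))
  check_theta(theta, theta_lower)
  if (bias == "sp_no") {
    block <- attr(base, "block")
    e <- as.numeric(seq_len(nrow(base)) %in% allno_rows(design))
    if (length(theta) == 1L) {
      m <- (1 - theta) * unclass(base) + theta * (e %o% rep(1, ncol(base)))
    } else {
      ## per-category SP-no probabilities (sub-samples variant)
      if (length(theta) != ncol(base))
        stop("per-category `theta` must have one entry per true category",
             call. = FALSE)
      check_theta(theta, theta_lower)
      m <- sweep(unclass(base), 2L, 1 - theta, "*") + e %o% theta
    }
    dimnames(m) <- dimnames(base)
    return(check_tmat(new_rr_tmat(m, block = block), entries = all(theta >= 0)))
  }
  ## sp_last_year
  if (length(ely_blocks(design)) == 0L)
    stop("sp_last_year requires at least one ever/last-year block", call. = FALSE)
  if (design$subsamples)
    stop("sp_last_year is not defined for the sub-samples design", call. = FALSE)
  check_theta(theta_yy_yn, theta_lower)
  if (theta + theta_yy_yn > 1 + 1e-12)
    stop("theta + theta_yy_yn must not exceed 1", call. = FALSE)
  if (theta >= 1) stop("sp_last_year requires theta < 1", call. = FALSE)
  cedit <- theta_yy_yn / (1 - theta)
  mats <- lapply(design$blocks, function(b) {
    if (b$kind == "ever_last_year") {
      m <- ely_edit_matrix(b$rand, cedit)
      new_rr_tmat(m)
    } else block_null_tm(b)
  })
  edited <- if (length(mats) == 1L) mats[[1L]] else rr_kronecker(mats)
  m <- (1 - theta) * unclass(edited)
  m[allno_rows(design), ] <- m[allno_rows(design), ] + theta
  dimnames(m) <- dimnames(edited)
  check_tmat(new_rr_tmat(m), entries = theta >= 0 && theta_yy_yn >= 0)
}

block_null_tm <- function(block) {
  switch(block$kind,
         single = rr_tm_single(block$rand),
         ever_last_year = rr_tm_ely(block$rand),
         stop("unknown block kind", call. = FALSE))
}
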