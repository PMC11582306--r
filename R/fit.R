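#' Multinomial log-likelihood kernel
#'
#' `sum(n_r * log(pi_star_r))`, the kernel of the (product-)multinomial
#' log-likelihood; the multinomial coefficient is omitted throughout the
#' package. A zero model probability with a positive count yields `-Inf` with
#' a diagnostic attribute naming the offending profiles.
#'
#' @param probs Observed-profile probabilities.
#' @param counts Observed frequencies (same length/order; non-negative).
#' @return The log-likelihood kernel value.
#' @examples
#' rr_loglik(c(.25, .25, .25, .25), c(10, 20, 30, 40))  # 100 * log(1/4)
#' @export
rr_loglik <- function(probs, counts) {
  if (length(probs) != length(counts))
    stop("`probs` and `counts` must have the same length", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  pos <- counts > 0
  if (any(probs[pos] <= 0)) {
    bad <- which(pos & probs <= 0)
    out <- -Inf
    attr(out, "zero_probability_profiles") <-
      if (is.null(names(counts))) bad else names(counts)[bad]
    return(out)
  }
  sum(counts[pos] * log(probs[pos]))
}

## ---- internal model context ------------------------------------------------

BIG_NLL <- 1e10

## set the seed for the duration of the calling function, then restore the
## caller's RNG stream (registered via on.exit in the caller's frame)
local_seed <- function(seed, envir = parent.frame()) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    ex <- bquote(assign(".Random.seed", .(old), envir = globalenv()))
    do.call(on.exit, list(ex, add = TRUE), envir = envir)
  }
  set.seed(seed)
}

## softmax with the first category as reference (beta_1 = 0)
softmax_ref <- function(beta) {
  e <- exp(c(0, beta) - max(0, beta))
  e / sum(e)
}

## parameterization + forward machinery for one design/model/structure combo
model_context <- function(design, model, structure, theta_lower = -0.5) {
  K <- length(design$categories)
  Tm <- rr_design_matrix(design)
  Tmat <- unclass(Tm)
  block <- attr(Tm, "block")
  e <- as.numeric(seq_len(nrow(Tmat)) %in% allno_rows(design))

  if (structure != "saturated") {
    kinds <- vapply(design$blocks, `[[`, character(1L), "kind")
    Q <- length(kinds)
    if (any(kinds != "single") || design$subsamples)
      stop("log-linear structures apply to multiple-single-question designs only",
           call. = FALSE)
    if (structure == "independence" && Q < 2L)
      stop("independence structure needs at least two questions", call. = FALSE)
    if (structure == "no_threeway" && Q != 3L)
      stop("the no-three-way structure is defined for three questions", call. = FALSE)
    X <- loglinear_model_matrix(design$categories, Q,
                                include_pairwise = structure == "no_threeway")
    cat_npar <- ncol(X)
    cat_names <- colnames(X)
    cat_probs <- function(b) {
      lp <- as.numeric(X %*% b)
      pr <- exp(lp - max(lp))
      pr / sum(pr)
    }
  } else if (model == "cdm") {
    ## softmax over adherent categories plus the cheater category
    cat_npar <- K
    cat_names <- paste0("beta_", c(design$categories[-1L], "c"))
    cat_probs <- softmax_ref
  } else {
    cat_npar <- K - 1L
    cat_names <- paste0("beta_", design$categories[-1L])
    cat_probs <- softmax_ref
  }

  if (model == "cdm" && structure == "saturated") {
    Tc <- unclass(rr_add_cheater(Tm))
    probs_fun <- function(par) as.numeric(Tc %*% cat_probs(par))
    natural <- function(par) {
      tau <- cat_probs(par)
      names(tau) <- c(design$categories, "c")
      list(probs = tau)
    }
    npar <- cat_npar; lower <- rep(-Inf, npar); upper <- rep(Inf, npar)
    par_names <- cat_names
  } else if (model == "cdm") {
    ## log-linear adherent distribution scaled by (1 - tau_c), cheater appended
    Tc <- cbind(Tmat, e)
    npar <- cat_npar + 1L
    par_names <- c(cat_names, "tau_c")
    lower <- c(rep(-Inf, cat_npar), 0); upper <- c(rep(Inf, cat_npar), 1)
    probs_fun <- function(par) {
      tc <- par[npar]
      as.numeric(Tc %*% c((1 - tc) * cat_probs(par[-npar]), tc))
    }
    natural <- function(par) {
      tc <- par[npar]
      tau <- c((1 - tc) * cat_probs(par[-npar]), tc)
      names(tau) <- c(design$categories, "c")
      list(probs = tau)
    }
  } else if (model == "null") {
    npar <- cat_npar; par_names <- cat_names
    lower <- rep(-Inf, npar); upper <- rep(Inf, npar)
    probs_fun <- function(par) as.numeric(Tmat %*% cat_probs(par))
    natural <- function(par) {
      pi <- cat_probs(par); names(pi) <- design$categories
      list(probs = pi)
    }
  } else if (model == "sp_no") {
    npar <- cat_npar + 1L
    par_names <- c(cat_names, "theta")
    lower <- c(rep(-Inf, cat_npar), theta_lower)
    upper <- c(rep(Inf, cat_npar), 1)
    probs_fun <- function(par) {
      th <- par[npar]
      (1 - th) * as.numeric(Tmat %*% cat_probs(par[-npar])) + th * e
    }
    natural <- function(par) {
      pi <- cat_probs(par[-npar]); names(pi) <- design$categories
      list(probs = pi, theta = par[npar])
    }
  } else if (model == "sp_last_year") {
    if (length(ely_blocks(design)) == 0L || design$subsamples)
      stop("sp_last_year requires an ever/last-year block", call. = FALSE)
    npar <- cat_npar + 2L
    par_names <- c(cat_names, "theta", "theta_yy_yn")
    lower <- c(rep(-Inf, cat_npar), theta_lower, theta_lower)
    upper <- c(rep(Inf, cat_npar), 1, 1)
    nulls <- lapply(design$blocks, function(b) unclass(block_null_tm(b)))
    is_ely <- vapply(design$blocks, `[[`, character(1L), "kind") == "ever_last_year"
    edited_kron <- function(cedit) {
      mats <- nulls
      for (j in which(is_ely)) {
        m <- mats[[j]]
        p <- design$blocks[[j]]$rand$p
        m["yn", "yy"] <- m["yn", "yy"] + cedit * p^2
        m["yy", "yy"] <- m["yy", "yy"] - cedit * p^2
        mats[[j]] <- m
      }
      Reduce(kronecker, mats)
    }
    probs_fun <- function(par) {
      th <- par[npar - 1L]; tyy <- par[npar]
      if (th + tyy > 1 || th >= 1) return(rep(-1, nrow(Tmat)))
      (1 - th) * as.numeric(edited_kron(tyy / (1 - th)) %*% cat_probs(par[seq_len(cat_npar)])) +
        th * e
    }
    natural <- function(par) {
      pi <- cat_probs(par[seq_len(cat_npar)]); names(pi) <- design$categories
      list(probs = pi, theta = par[npar - 1L], theta_yy_yn = par[npar])
    }
  } else stop("unknown model", call. = FALSE)

  n_cells <- nrow(Tmat) - length(unique(block))
  list(design = design, model = model, structure = structure,
       npar = npar, par_names = par_names, lower = lower, upper = upper,
       probs_fun = probs_fun, natural = natural, block = block,
       k = npar, df = n_cells - npar, cat_npar = cat_npar)
}

## multi-start PORT optimization of the multinomial kernel
ml_multistart <- function(ctx, counts, n_starts = 20L, seed = 1L,
                          control = list()) {
  if (ctx$df < -1e-9)
    stop(sprintf("model not identified: %d free parameters for %d non-redundant cells",
                 ctx$k, ctx$k + ctx$df), call. = FALSE)
  pos <- counts > 0
  nll <- function(par) {
    ps <- ctx$probs_fun(par)
    if (any(!is.finite(ps)) || any(ps[pos] <= 0)) return(BIG_NLL)
    -sum(counts[pos] * log(ps[pos]))
  }
  ctrl <- utils::modifyList(list(iter.max = 1000L, eval.max = 2000L,
                                 rel.tol = 1e-12), control)
  nb <- ctx$cat_npar
  extra <- ctx$npar - nb
  ## seed the starts without disturbing the caller's RNG stream
  local_seed(seed)
  best <- NULL; best_start <- NA_integer_; objectives <- rep(NA_real_, n_starts)
  for (s in seq_len(n_starts)) {
    start <- if (s == 1L) c(rep(0, nb), rep(0.05, extra))
             else c(stats::rnorm(nb, 0, 1), stats::runif(extra, 0, 0.3))
    o <- tryCatch(stats::nlminb(start, nll, lower = ctx$lower,
                                upper = ctx$upper, control = ctrl),
                  error = function(e) NULL)
    if (is.null(o) || !is.finite(o$objective) || o$objective >= BIG_NLL) next
    objectives[s] <- o$objective
    if (is.null(best) || o$objective < best$objective - 1e-9) {
      best <- o; best_start <- s
    }
  }
  if (is.null(best))
    stop("optimization failed for every start", call. = FALSE)
  ## polish: restart from the incumbent to finish any slow boundary crawl
  o2 <- tryCatch(stats::nlminb(best$par, nll, lower = ctx$lower,
                               upper = ctx$upper, control = ctrl),
                 error = function(e) NULL)
  if (!is.null(o2) && is.finite(o2$objective) && o2$objective <= best$objective)
    best <- o2
  ## converged when the optimizer says so, the gradient (projected onto the
  ## feasible box) vanishes, or several starts agree on the optimum
  gr <- tryCatch(pracma::grad(nll, best$par), error = function(e) NULL)
  if (!is.null(gr)) {
    at_lo <- best$par <= ctx$lower + 1e-10
    at_hi <- best$par >= ctx$upper - 1e-10
    gr[(at_lo & gr > 0) | (at_hi & gr < 0)] <- 0
  }
  converged <- best$convergence == 0L ||
    (!is.null(gr) && max(abs(gr)) < 1e-6 * (1 + abs(best$objective))) ||
    sum(objectives < best$objective + 1e-6, na.rm = TRUE) >= 2L
  list(par = best$par, objective = best$objective,
       converged = converged,
       n_conv = sum(objectives < best$objective + 1e-6, na.rm = TRUE),
       n_starts = n_starts, best_start = best_start, nll = nll)
}

#' Fit a randomized-response model by maximum likelihood
#'
#' Maximizes the multinomial kernel `n' log(pi_star)` over unconstrained
#' parameters: category probabilities through the softmax map (first category
#' as reference; under a log-linear `structure`, through its dummy-coded
#' effects) and the bias parameters `theta`/`theta_yy_yn` on their natural
#' scale, bounded in `[theta_lower, 1]` so that mildly negative SP-no
#' estimates are admissible. Optimization uses the PORT quasi-Newton routine
#' ([stats::nlminb()]) with `n_starts` seeded starts plus a polishing restart
#' from the incumbent; the best converged start wins, ties broken by the
#' lowest start index.
#'
#' Standard errors are delta-method: the observed information on the working
#' scale is inverted and propagated through the numerically differentiated
#' map to the natural scale. `G2 = 2 n' log(n / nhat)` (with `0 log 0 = 0`) is
#' referred to chi-squared on `df` = non-redundant cells minus free
#' parameters; `AIC = 2k - 2 logLik` counts `k` free identified parameters,
#' so AIC differences and rankings are meaningful, not absolute values.
#'
#' @param design An [rr_design()].
#' @param counts Observed profile frequencies, named by profile or in design
#'   order. Non-negative; non-integer expected frequencies are allowed (the
#'   kernel is scale-free), e.g. to fit a model to exact probabilities.
#' @param model `"null"`, `"sp_no"`, `"cdm"` or `"sp_last_year"`.
#' @param structure `"saturated"` leaves the adherent category probabilities
#'   unrestricted; `"independence"` (main effects only) and `"no_threeway"`
#'   (all pairwise interactions) impose the log-linear identification used
#'   with designs of 2 resp. 3 separate single questions.
#' @param n_starts Number of random starts.
#' @param seed Seed for the random starts.
#' @param se Compute delta-method standard errors.
#' @param theta_lower Lower bound for the bias parameters.
#' @param control Passed to [stats::nlminb()] (merged into the defaults).
#' @return An object of class `"rr_fit"`: estimates and standard errors on the
#'   natural scale, `loglik`, `aic`, `g2`, `df`, `p_value`, `fitted`
#'   frequencies, convergence diagnostics.
#' @examples
#' d <- rr_design(rr_ely_pair(5/6))
#' fit <- rr_fit(d, c(nn = 1468, ny = 287, yn = 368, yy = 146))
#' fit
#' @export
rr_fit <- function(design, counts,
                   model = c("null", "sp_no", "cdm", "sp_last_year"),
                   structure = c("saturated", "independence", "no_threeway"),
                   n_starts = 20L, seed = 1L, se = TRUE,
                   theta_lower = -0.5, control = list()) {
  model <- match.arg(model)
  structure <- match.arg(structure)
  counts <- align_counts(counts, design)
  ctx <- model_context(design, model, structure, theta_lower)
  opt <- ml_multistart(ctx, counts, n_starts = n_starts, seed = seed,
                       control = control)
  if (!opt$converged)
    warning("no start converged cleanly; reporting the best point found",
            call. = FALSE)

  nat <- ctx$natural(opt$par)
  ps <- ctx$probs_fun(opt$par)
  names(ps) <- design$profiles
  blk <- ctx$block
  nb_tot <- tapply(counts, blk, sum)[as.character(blk)]
  fitted <- as.numeric(nb_tot) * ps
  names(fitted) <- design$profiles
  loglik <- -opt$objective
  gof <- rr_g2(counts, fitted, ctx$df)

  est <- c(nat$probs,
           if (!is.null(nat$theta)) c(theta = nat$theta),
           if (!is.null(nat$theta_yy_yn)) c(theta_yy_yn = nat$theta_yy_yn))
  boundary <- any(nat$probs < 1e-6) ||
    (!is.null(nat$theta) && abs(nat$theta - theta_lower) < 1e-6)

  std <- rep(NA_real_, length(est)); names(std) <- names(est)
  vcov_nat <- NULL; se_ok <- FALSE
  if (se) {
    g <- function(par) {
      nn <- ctx$natural(par)
      c(nn$probs, nn$theta, nn$theta_yy_yn)
    }
    H <- tryCatch(pracma::hessian(opt$nll, opt$par), error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
    if (!is.null(V) && all(is.finite(V)) && all(diag(V) > -1e-8)) {
      J <- pracma::jacobian(g, opt$par)
      vcov_nat <- J %*% V %*% t(J)
      dimnames(vcov_nat) <- list(names(est), names(est))
      std <- sqrt(pmax(diag(vcov_nat), 0))
      se_ok <- TRUE
    }
  }

  structure(list(design = design, model = model, structure = structure,
                 estimates = est, probs = nat$probs,
                 theta = nat$theta, theta_yy_yn = nat$theta_yy_yn,
                 std_errors = std, se_available = se_ok, vcov = vcov_nat,
                 loglik = loglik, k = ctx$k, aic = 2 * ctx$k - 2 * loglik,
                 g2 = gof$g2, df = ctx$df, p_value = gof$p_value,
                 observed = counts, fitted = fitted,
                 profile_probs = ps, block = blk,
                 converged = opt$converged, n_starts_used = opt$n_starts,
                 best_start = opt$best_start, boundary = boundary,
                 par = opt$par, par_names = ctx$par_names, seed = seed),
            class = "rr_fit")
}

align_counts <- function(counts, design) {
  profiles <- design$profiles
  if (!is.numeric(counts) || length(counts) != length(profiles))
    stop(sprintf("expected %d profile frequencies (%s)", length(profiles),
                 paste(profiles, collapse = ", ")), call. = FALSE)
  if (!is.null(names(counts))) {
    if (!setequal(names(counts), profiles))
      stop("count names do not match the design's observed profiles", call. = FALSE)
    counts <- counts[profiles]
  } else names(counts) <- profiles
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative", call. = FALSE)
  counts
}

#' Deviance goodness of fit
#'
#' `G2 = 2 * sum(n * log(n / nhat))` with the convention `0 * log(0/x) = 0`,
#' referred to the chi-squared distribution on `df` degrees of freedom. With
#' `df = 0` the statistic is still reported but the p-value is undefined
#' (`NA`).
#'
#' @param observed Observed frequencies.
#' @param fitted Fitted frequencies from a converged fit.
#' @param df Residual degrees of freedom.
#' @return List with `g2`, `df` and `p_value`.
#' @examples
#' rr_g2(c(10, 20), c(12, 18), df = 1)
#' @export
rr_g2 <- function(observed, fitted, df) {
  if (length(observed) != length(fitted))
    stop("`observed` and `fitted` must have the same length", call. = FALSE)
  pos <- observed > 0
  if (any(fitted[pos] <= 0))
    stop("fitted frequency 0 where a positive count was observed", call. = FALSE)
  g2 <- 2 * sum(observed[pos] * log(observed[pos] / fitted[pos]))
  if (g2 < -1e-8) stop("negative deviance: fitted values are inconsistent",
                       call. = FALSE)
  g2 <- max(g2, 0)
  list(g2 = g2, df = df,
       p_value = if (df > 0) stats::pchisq(g2, df, lower.tail = FALSE) else NA_real_)
}

#' Likelihood-ratio test between nested fits
#'
#' `2 * (logLik_alt - logLik_null) = G2_null - G2_alt`, referred to chi-squared
#' with `df = k_alt - k_null`. Used to test `theta = 0` against a free SP-no
#' parameter; negative estimates are retained, making the test two-sided in
#' `theta`.
#'
#' @param fit_null,fit_alt Nested [rr_fit()] results on the same data.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
rr_lr_test <- function(fit_null, fit_alt) {
  stopifnot(inherits(fit_null, "rr_fit"), inherits(fit_alt, "rr_fit"))
  if (!isTRUE(all.equal(unname(fit_null$observed), unname(fit_alt$observed))))
    stop("fits are not based on the same data", call. = FALSE)
  df <- fit_alt$k - fit_null$k
  if (df <= 0) stop("models are not nested (df <= 0)", call. = FALSE)
  stat <- 2 * (fit_alt$loglik - fit_null$loglik)
  if (stat < 0 && stat > -1e-6) stat <- 0
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' @export
logLik.rr_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = sum(object$observed),
            class = "logLik")
}

#' @export
coef.rr_fit <- function(object, ...) object$estimates

#' @export
vcov.rr_fit <- function(object, ...) object$vcov

#' @export
print.rr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("RR %s model (%s)%s\n", x$model, x$structure,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  tab <- data.frame(estimate = round(x$estimates, digits),
                    std.error = round(x$std_errors, digits))
  print(tab)
  cat(sprintf("logLik (kernel) %.2f   AIC %.1f   G2(%d) = %.3f%s\n",
              x$loglik, x$aic, x$df, x$g2,
              if (!is.na(x$p_value)) sprintf(", p = %.3f", x$p_value) else ""))
  if (x$boundary)
    cat("note: solution on or near the boundary of the parameter space\n")
  invisible(x)
}
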