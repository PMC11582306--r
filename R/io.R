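#' Read and write profile-count files
#'
#' Counts are stored as CSV with a mandatory header: one column per question
#' (named `q1`, `q2`, ... in design order, values `n`/`y`), an optional
#' `subsample` column (values 1/2) for the sub-samples design, and an integer
#' `count` column. Every profile of the design must appear exactly once.
#'
#' @param path File path.
#' @param design The [rr_design()] the counts belong to.
#' @return `rr_read_counts()`: named count vector in design profile order.
#' @examples
#' d <- rr_design(rr_ely_pair(5/6))
#' f <- tempfile(fileext = ".csv")
#' rr_write_counts(c(nn = 5, ny = 1, yn = 2, yy = 1), d, f)
#' rr_read_counts(f, d)
#' @export
rr_read_counts <- function(path, design) {
  stopifnot(inherits(design, "rr_design"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  Q <- design$n_questions
  qcols <- paste0("q", seq_len(Q))
  need <- c(qcols, if (design$subsamples) "subsample", "count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  ans <- as.matrix(df[qcols])
  if (!all(ans %in% c("n", "y")))
    stop("answer columns must contain only 'n' or 'y'", call. = FALSE)
  lab <- apply(ans, 1L, paste, collapse = "")
  if (design$subsamples) lab <- paste0(lab, "|", df$subsample)
  cnt <- suppressWarnings(as.numeric(df$count))
  if (any(is.na(cnt)) || any(cnt < 0))
    stop("`count` must be non-negative numbers", call. = FALSE)
  dup <- lab[duplicated(lab)]
  if (length(dup))
    stop("duplicate profile row(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  absent <- setdiff(design$profiles, lab)
  if (length(absent))
    stop("missing profile row(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(lab, design$profiles)
  if (length(extra))
    stop("unknown profile row(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  out <- cnt[match(design$profiles, lab)]
  names(out) <- design$profiles
  out
}

#' @rdname rr_read_counts
#' @param counts Named (or design-ordered) count vector.
#' @export
rr_write_counts <- function(counts, design, path) {
  counts <- align_counts(counts, design)
  Q <- design$n_questions
  bare <- sub("\\|.*$", "", names(counts))
  df <- as.data.frame(do.call(rbind, strsplit(bare, "")),
                      stringsAsFactors = FALSE)
  names(df) <- paste0("q", seq_len(Q))
  if (design$subsamples)
    df$subsample <- sub("^.*\\|", "", names(counts))
  df$count <- unname(counts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a design configuration file
#'
#' YAML (or JSON, by file extension) with fields `blocks` (a list of
#' `{kind: single|ever_last_year, p: <probability>}`), optional logical
#' `subsamples`, and optional `bias_structure` (stored as an attribute; the
#' bias model is chosen at fit time).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [rr_design()] (with attribute `bias_structure` if configured).
#' @export
rr_read_design <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  if (is.null(cfg$blocks) || !length(cfg$blocks))
    stop("design file must list at least one block", call. = FALSE)
  blocks <- lapply(cfg$blocks, function(b) {
    if (is.null(b$kind) || is.null(b$p))
      stop("each block needs `kind` and `p`", call. = FALSE)
    switch(b$kind,
           single = rr_question(b$p),
           ever_last_year = rr_ely_pair(b$p),
           stop("unknown block kind: ", b$kind, call. = FALSE))
  })
  d <- rr_design(blocks, subsamples = isTRUE(cfg$subsamples))
  if (!is.null(cfg$bias_structure))
    attr(d, "bias_structure") <- cfg$bias_structure
  d
}

#' Write a transition matrix as labelled CSV
#'
#' @param tm A transition matrix.
#' @param path Output path.
#' @export
rr_write_tmat <- function(tm, path) {
  df <- as.data.frame(unclass(tm))
  df <- cbind(profile = rownames(tm), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fit report as structured JSON
#'
#' The report contains the model identifier, estimates and standard errors,
#' log-likelihood kernel, AIC, deviance with df and p-value, observed and
#' fitted frequencies, and convergence diagnostics — the machine-readable
#' counterpart of the printed fit table.
#'
#' @param fit An [rr_fit()] result.
#' @param path Output path (`.json`).
#' @return The path, invisibly.
#' @export
rr_write_report <- function(fit, path) {
  stopifnot(inherits(fit, "rr_fit"))
  rep <- list(
    model = fit$model,
    structure = fit$structure,
    estimates = as.list(fit$estimates),
    std_errors = as.list(fit$std_errors),
    loglik = fit$loglik,
    aic = fit$aic,
    g2 = fit$g2,
    df = fit$df,
    p_value = fit$p_value,
    observed = as.list(fit$observed),
    fitted = as.list(fit$fitted),
    converged = fit$converged,
    n_starts_used = fit$n_starts_used,
    best_start = fit$best_start,
    boundary = fit$boundary)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
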