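#' Randomization specification for a symmetric RR question
#'
#' A randomized-response (RR) question is characterized by the probability `p`
#' that the recorded answer equals the true answer, identical for carriers and
#' non-carriers (`p = p_{y|y} = p_{n|n}`, the symmetric design). The complement
#' `q = 1 - p` is the probability that the randomizer flips the answer.
#'
#' At `p = 0.5` the observed responses carry no information about the
#' prevalence of the sensitive attribute; the design is uninformative and a
#' warning is issued. `p = 1` corresponds to direct questioning.
#'
#' @param p Probability in (0, 1] that the randomized response equals the true
#'   response.
#' @return An object of class `"rr_rand"`: a list with elements `p`, `q` and
#'   the logical flag `uninformative`.
#' @examples
#' rr_rand(5/6)
#' @export
rr_rand <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p))
    stop("`p` must be a single finite number", call. = FALSE)
  if (p <= 0 || p > 1)
    stop("randomization probability `p` must be in (0, 1]", call. = FALSE)
  uninf <- isTRUE(all.equal(p, 0.5))
  if (uninf)
    warning("p = 0.5: the design is uninformative (observed responses do not ",
            "depend on the true prevalence)", call. = FALSE)
  structure(list(p = p, q = 1 - p, uninformative = uninf), class = "rr_rand")
}

as_rr_rand <- function(x) {
  if (inherits(x, "rr_rand")) return(x)
  rr_rand(x)
}

#' @export
print.rr_rand <- function(x, ...) {
  cat(sprintf("RR randomization: p = %.6g, q = %.6g%s\n", x$p, x$q,
              if (x$uninformative) "  [uninformative]" else ""))
  invisible(x)
}

#' Question blocks of an RR design
#'
#' A design is an ordered sequence of question blocks. `rr_question()` declares
#' a single dichotomous sensitive question with true categories `n`/`y`.
#' `rr_ely_pair()` declares an ever/last-year pair: two questions on the same
#' attribute ("ever" and "in the last 12 months") sharing one randomization
#' probability. The true profile `ny` (never, yet used last year) is impossible,
#' so the pair has three true categories: `nn` (never), `yn` (former) and `yy`
#' (last-year carrier). This structural zero is what frees a degree of freedom
#' for response-bias parameters.
#'
#' @param p Randomization probability, or an [rr_rand()] object.
#' @return An object of class `"rr_block"`.
#' @examples
#' rr_ely_pair(5/6)
#' rr_question(0.8)
#' @export
rr_question <- function(p) {
  structure(list(kind = "single", rand = as_rr_rand(p),
                 n_questions = 1L,
                 profiles = c("n", "y"),
                 categories = c("n", "y")),
            class = "rr_block")
}

#' @rdname rr_question
#' @export
rr_ely_pair <- function(p) {
  structure(list(kind = "ever_last_year", rand = as_rr_rand(p),
                 n_questions = 2L,
                 profiles = c("nn", "ny", "yn", "yy"),
                 categories = c("nn", "yn", "yy")),
            class = "rr_block")
}

## cross labels so that the first factor varies slowest (Kronecker order)
cross_labels <- function(lst) {
  Reduce(function(a, b) as.vector(t(outer(a, b, paste0))), lst)
}

#' Layout of a randomized-response design
#'
#' Combines question blocks into a design. Observed response profiles are
#' labelled by one `n`/`y` letter per question, ordered lexicographically with
#' `n` before `y` and the first-listed block varying slowest (the Kronecker
#' order). True categories are the cross of the per-block categories (the
#' impossible `ny` ever/last-year profile is omitted, never carried as a
#' zero-probability column).
#'
#' The sub-samples design (`subsamples = TRUE`) interviews two non-overlapping
#' groups with complementary randomization probabilities (`p` in sub-sample 1,
#' `q = 1 - p` in sub-sample 2) and requires exactly one single-question block.
#' Its profiles are labelled `n|1, y|1, n|2, y|2`.
#'
#' @param ... Question blocks created by [rr_question()] or [rr_ely_pair()]
#'   (alternatively a single list of blocks).
#' @param subsamples Logical; use the two-sub-sample design.
#' @return An object of class `"rr_design"` with elements `blocks`,
#'   `subsamples`, `profiles`, `categories`, `block_id` (sub-sample membership
#'   of each profile row) and `n_questions`.
#' @examples
#' rr_design(rr_ely_pair(5/6), rr_question(5/6))  # ever/last-year + extra question
#' rr_design(rr_question(0.8), subsamples = TRUE) # sub-samples design
#' @export
rr_design <- function(..., subsamples = FALSE) {
  blocks <- list(...)
  if (length(blocks) == 1L && !inherits(blocks[[1L]], "rr_block") &&
      is.list(blocks[[1L]]))
    blocks <- blocks[[1L]]
  if (length(blocks) == 0L) stop("a design needs at least one block", call. = FALSE)
  if (!all(vapply(blocks, inherits, logical(1L), "rr_block")))
    stop("all blocks must be created by rr_question() or rr_ely_pair()", call. = FALSE)
  if (subsamples) {
    if (length(blocks) != 1L || blocks[[1L]]$kind != "single")
      stop("the sub-samples design requires exactly one single-question block",
           call. = FALSE)
    profiles <- c("n|1", "y|1", "n|2", "y|2")
    block_id <- c(1L, 1L, 2L, 2L)
    categories <- c("n", "y")
  } else {
    profiles <- cross_labels(lapply(blocks, `[[`, "profiles"))
    categories <- cross_labels(lapply(blocks, `[[`, "categories"))
    block_id <- rep(1L, length(profiles))
  }
  structure(list(blocks = blocks, subsamples = subsamples,
                 profiles = profiles, categories = categories,
                 block_id = block_id,
                 n_questions = sum(vapply(blocks, `[[`, integer(1L), "n_questions"))),
            class = "rr_design")
}

#' @export
print.rr_design <- function(x, ...) {
  kinds <- vapply(x$blocks, function(b)
    sprintf("%s(p = %.4g)", b$kind, b$rand$p), character(1L))
  cat("RR design:", paste(kinds, collapse = " x "),
      if (x$subsamples) "[sub-samples]" else "", "\n")
  cat("  observed profiles:", paste(x$profiles, collapse = " "), "\n")
  cat("  true categories:  ", paste(x$categories, collapse = " "), "\n")
  invisible(x)
}

## character positions of the questions of block b within a profile label
block_char_offsets <- function(design) {
  nq <- vapply(design$blocks, `[[`, integer(1L), "n_questions")
  ends <- cumsum(nq)
  starts <- ends - nq + 1L
  Map(seq, starts, ends)
}

## indices of ever/last-year blocks
ely_blocks <- function(design) {
  which(vapply(design$blocks, `[[`, character(1L), "kind") == "ever_last_year")
}

## all-"no" profile row(s): one per sub-sample block
allno_rows <- function(design) {
  lab <- gsub("[^ny]", "", design$profiles)
  idx <- which(!grepl("y", lab))
  if (length(idx) != length(unique(design$block_id)))
    stop("design has no unique all-'no' profile per block", call. = FALSE)
  idx
}
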