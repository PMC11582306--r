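#' Bundled doping-survey frequency tables
#'
#' Observed randomized-response profile frequencies of two Dutch doping
#' surveys, both using `p = 5/6` for every question.
#'
#' * `"study1"`: 2,269 male gym users; an ever/last-year pair on anabolic
#'   steroids plus a single "ever" question on SARMs (8 profiles).
#' * `"study1_anabolics_collapsed"`: the same survey collapsed over the SARMs
#'   index (4 ever/last-year profiles), computed by summation.
#' * `"study2"`: 1,050 Dutch elite athletes (2014, Doping Authority
#'   Netherlands); two ever/last-year pairs, on anabolics and on blood
#'   manipulations (16 profiles). Two answer-format variants with identical
#'   `p` were pooled in the original analysis.
#'
#' @param name Fixture name.
#' @return An object of class `"rr_study"`: a list with `name`, `design`,
#'   `counts` and a provenance `note`.
#' @examples
#' sum(rr_study_fixture("study1")$counts)  # 2269
#' @export
rr_study_fixture <- function(name = c("study1", "study1_anabolics_collapsed",
                                      "study2")) {
  name <- match.arg(name)
  p <- 5 / 6
  if (name == "study2") {
    design <- rr_design(rr_ely_pair(p), rr_ely_pair(p))
    counts <- c(521, 89, 93, 21, 86, 23, 22, 10,
                93, 18, 19, 10, 22, 7, 8, 8)
    names(counts) <- design$profiles
    note <- paste("Two ever/last-year RR question pairs (anabolics, blood",
                  "manipulations) answered by 1,050 Dutch elite athletes; two",
                  "pooled answer formats, p = 5/6 throughout.")
  } else {
    design <- rr_design(rr_ely_pair(p), rr_question(p))
    counts <- c(1220, 248, 226, 61, 290, 78, 114, 32)
    names(counts) <- design$profiles
    note <- paste("Ever/last-year RR questions on anabolic steroids plus an",
                  "ever question on SARMs answered by 2,269 male gym users;",
                  "p = 5/6 throughout.")
    if (name == "study1_anabolics_collapsed") {
      collapsed <- rr_collapse_block(counts, design, block_index = 2L)
      design <- collapsed$design
      counts <- collapsed$counts
      note <- paste(note, "Collapsed over the SARMs index.")
    }
  }
  structure(list(name = name, design = design, counts = counts, note = note),
            class = "rr_study")
}

#' @export
print.rr_study <- function(x, ...) {
  cat("RR study fixture:", x$name, sprintf("(n = %d)\n", sum(x$counts)))
  print(x$counts)
  cat(strwrap(x$note, width = 76), sep = "\n")
  invisible(x)
}

#' Collapse profile counts over a question block
#'
#' Sums the observed frequencies over the answers to one question block,
#' returning the counts and design of the reduced layout. Only whole blocks
#' can be dropped.
#'
#' @param counts Profile frequencies for `design`.
#' @param design An [rr_design()] without sub-samples.
#' @param block_index Index of the block to sum over.
#' @return List with the reduced `design` and `counts`.
#' @examples
#' s1 <- rr_study_fixture("study1")
#' rr_collapse_block(s1$counts, s1$design, 2)$counts
#' @export
rr_collapse_block <- function(counts, design, block_index) {
  stopifnot(inherits(design, "rr_design"), !design$subsamples)
  counts <- align_counts(counts, design)
  if (length(design$blocks) < 2L)
    stop("cannot collapse the only block of a design", call. = FALSE)
  if (block_index < 1L || block_index > length(design$blocks))
    stop("no such block", call. = FALSE)
  keep_chars <- unlist(block_char_offsets(design)[-block_index])
  key <- vapply(strsplit(names(counts), ""), function(ch)
    paste(ch[keep_chars], collapse = ""), character(1L))
  new_design <- rr_design(design$blocks[-block_index])
  agg <- tapply(counts, key, sum)
  out <- as.numeric(agg[new_design$profiles])
  names(out) <- new_design$profiles
  list(design = new_design, counts = out)
}
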