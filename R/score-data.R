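#' Construct a score sample from genuine and impostor scores
#'
#' A score sample holds the two raw sets of match scores that all ROC
#' quantities are computed from: the genuine (positive-class, same-subject)
#' scores and the impostor (negative-class, different-subject) scores.
#'
#' @param genuine Numeric vector of genuine (same-subject) match scores.
#' @param impostor Numeric vector of impostor (different-subject) match scores.
#' @param label Optional free-text identifier for the sample (e.g. an
#'   algorithm name).
#' @return A tibble of class `score_sample` with columns `label`
#'   (`"genuine"` or `"impostor"`) and `score`, in input order within each
#'   class. The identifier is stored in the `"sample_label"` attribute.
#' @examples
#' s <- score_sample(c(3, 3, 2, 1), c(3, 2, 2, 1, 1, 0))
#' n_genuine(s)
#' n_impostor(s)
#' @export
score_sample <- function(genuine, impostor, label = NULL) {
  genuine <- validate_scores(genuine, "genuine")
  impostor <- validate_scores(impostor, "impostor")
  out <- tibble::tibble(
    label = rep(c("genuine", "impostor"), c(length(genuine), length(impostor))),
    score = c(genuine, impostor)
  )
  attr(out, "sample_label") <- label %||% "sample"
  class(out) <- c("score_sample", class(out))
  out
}

validate_scores <- function(x, which) {
  if (length(x) == 0) {
    stop(which, " set empty: at least one ", which, " score is required",
         call. = FALSE)
  }
  if (!is.numeric(x)) {
    stop(which, " scores must be numeric", call. = FALSE)
  }
  bad <- which(!is.finite(x))
  if (length(bad) > 0) {
    stop("non-finite ", which, " score at position ", bad[1], call. = FALSE)
  }
  as.numeric(x)
}

#' Coerce a data frame of labelled scores to a score sample
#'
#' @param x A data frame with columns `label` and `score`, or an existing
#'   `score_sample`.
#' @param label Optional sample identifier.
#' @return A `score_sample` tibble.
#' @export
as_score_sample <- function(x, label = NULL) {
  if (inherits(x, "score_sample")) {
    return(x)
  }
  if (!is.data.frame(x) || !all(c("label", "score") %in% names(x))) {
    stop("`x` must be a data frame with columns `label` and `score`",
         call. = FALSE)
  }
  lab <- tolower(as.character(x$label))
  ok <- lab %in% c("genuine", "impostor")
  if (!all(ok)) {
    stop("label column must contain only 'genuine' and 'impostor'; found '",
         x$label[which(!ok)[1]], "' at row ", which(!ok)[1], call. = FALSE)
  }
  score_sample(x$score[lab == "genuine"], x$score[lab == "impostor"],
               label = label)
}

#' @export
print.score_sample <- function(x, ...) {
  cat("<score_sample> ", attr(x, "sample_label"),
      ": ", n_genuine(x), " genuine, ", n_impostor(x), " impostor scores\n",
      sep = "")
  NextMethod()
}

#' Extract the genuine or impostor scores of a sample
#'
#' @param x A `score_sample` or a data frame with `label`/`score` columns.
#' @return Numeric vector of scores in stored order.
#' @export
genuine_scores <- function(x) {
  x <- as_score_sample(x)
  x$score[x$label == "genuine"]
}

#' @rdname genuine_scores
#' @export
impostor_scores <- function(x) {
  x <- as_score_sample(x)
  x$score[x$label == "impostor"]
}

#' @rdname genuine_scores
#' @export
n_genuine <- function(x) length(genuine_scores(x))

#' @rdname genuine_scores
#' @export
n_impostor <- function(x) length(impostor_scores(x))

#' Read score files into a score sample
#'
#' Two on-disk layouts are supported: a pair of plain-text files with one
#' score per line (`genuine` + `impostor`), or a single delimited file
#' (`scores`) with columns `label,score` where the label is `genuine` or
#' `impostor`. Comma, tab and semicolon delimiters are auto-detected; a
#' header line is skipped if present. Row order is preserved.
#'
#' @param scores Path to a delimited label+score file.
#' @param genuine,impostor Paths to one-score-per-line files (used when
#'   `scores` is not given).
#' @param label Optional sample identifier (defaults to the file name).
#' @return A `score_sample` tibble.
#' @export
read_scores <- function(scores = NULL, genuine = NULL, impostor = NULL,
                        label = NULL) {
  if (!is.null(scores)) {
    df <- read_labelled_file(scores)
    return(as_score_sample(df, label = label %||% basename(scores)))
  }
  if (is.null(genuine) || is.null(impostor)) {
    stop("supply either `scores` or both `genuine` and `impostor` paths",
         call. = FALSE)
  }
  g <- read_score_column(genuine)
  i <- read_score_column(impostor)
  if (length(g) == 0) stop("genuine set empty in ", genuine, call. = FALSE)
  if (length(i) == 0) stop("impostor set empty in ", impostor, call. = FALSE)
  score_sample(g, i, label = label %||% basename(genuine))
}

read_score_column <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  lines <- trimws(readr::read_lines(path))
  keep <- lines != ""
  lines <- lines[keep]
  rows <- which(keep)
  vals <- suppressWarnings(as.numeric(lines))
  bad <- which(is.na(vals))
  if (length(bad) > 0) {
    stop("non-numeric score '", lines[bad[1]], "' at row ", rows[bad[1]],
         " of ", path, call. = FALSE)
  }
  vals
}

read_labelled_file <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  lines <- trimws(readr::read_lines(path))
  keep <- lines != ""
  lines <- lines[keep]
  rows <- which(keep)
  if (length(lines) == 0) stop("no rows in ", path, call. = FALSE)
  parts <- strsplit(lines, "[,\t;]")
  n_fields <- lengths(parts)
  if (any(n_fields != 2)) {
    bad <- which(n_fields != 2)[1]
    stop("expected two fields (label, score) at row ", rows[bad], " of ",
         path, call. = FALSE)
  }
  lab <- trimws(vapply(parts, `[`, character(1), 1))
  raw <- trimws(vapply(parts, `[`, character(1), 2))
  # tolerate a header row
  if (tolower(lab[1]) == "label") {
    lab <- lab[-1]; raw <- raw[-1]; rows <- rows[-1]
  }
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(val))
  if (length(bad) > 0) {
    stop("non-numeric score '", raw[bad[1]], "' at row ", rows[bad[1]],
         " of ", path, call. = FALSE)
  }
  known <- tolower(lab) %in% c("genuine", "impostor")
  if (!all(known)) {
    stop("unknown label '", lab[which(!known)[1]], "' at row ",
         rows[which(!known)[1]], " of ", path,
         "; labels must be 'genuine' or 'impostor'", call. = FALSE)
  }
  if (!any(tolower(lab) == "genuine")) stop("genuine set empty in ", path, call. = FALSE)
  if (!any(tolower(lab) == "impostor")) stop("impostor set empty in ", path, call. = FALSE)
  tibble::tibble(label = tolower(lab), score = val)
}

#' Pair the score samples of two algorithms
#'
#' For two-algorithm comparison the scores must be ordinally paired: the
#' j-th genuine (impostor) score of algorithm A and the j-th of algorithm B
#' come from the same underlying comparison and co-vary. Class sizes must
#' therefore match exactly.
#'
#' @param sample_a,sample_b `score_sample` objects (or labelled data frames).
#' @return A list of class `paired_score_sample` with elements `sample_a`
#'   and `sample_b`.
#' @export
paired_score_sample <- function(sample_a, sample_b) {
  sample_a <- as_score_sample(sample_a)
  sample_b <- as_score_sample(sample_b)
  if (n_genuine(sample_a) != n_genuine(sample_b)) {
    stop("genuine score counts differ: A has ", n_genuine(sample_a),
         ", B has ", n_genuine(sample_b), call. = FALSE)
  }
  if (n_impostor(sample_a) != n_impostor(sample_b)) {
    stop("impostor score counts differ: A has ", n_impostor(sample_a),
         ", B has ", n_impostor(sample_b), call. = FALSE)
  }
  structure(list(sample_a = sample_a, sample_b = sample_b),
            class = "paired_score_sample")
}

#' @export
print.paired_score_sample <- function(x, ...) {
  cat("<paired_score_sample> A: ", attr(x$sample_a, "sample_label"),
      ", B: ", attr(x$sample_b, "sample_label"),
      " (", n_genuine(x$sample_a), " genuine / ",
      n_impostor(x$sample_a), " impostor pairs)\n", sep = "")
  invisible(x)
}

#' Read paired score files for two algorithms
#'
#' @param scores_a,scores_b Paths to labelled `label,score` files for
#'   algorithms A and B, row-index paired.
#' @param genuine_a,impostor_a,genuine_b,impostor_b Alternatively, paths to
#'   one-score-per-line files per class and algorithm.
#' @return A `paired_score_sample`.
#' @export
read_paired_scores <- function(scores_a = NULL, scores_b = NULL,
                               genuine_a = NULL, impostor_a = NULL,
                               genuine_b = NULL, impostor_b = NULL) {
  a <- read_scores(scores = scores_a, genuine = genuine_a,
                   impostor = impostor_a, label = "A")
  b <- read_scores(scores = scores_b, genuine = genuine_b,
                   impostor = impostor_b, label = "B")
  paired_score_sample(a, b)
}

#' Write a score sample to disk
#'
#' Writes the delimited `label,score` format that [read_scores()] reads.
#'
#' @param x A `score_sample`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(x, path) {
  x <- as_score_sample(x)
  readr::write_csv(tibble::tibble(label = x$label, score = x$score), path,
                   col_names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
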