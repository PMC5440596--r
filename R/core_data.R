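#' @useDynLib grtkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm pnorm qnorm rnorm optim runif rlnorm plogis
#'   qlogis pchisq t.test ks.test cor setNames
#' @importFrom utils read.csv write.csv head modifyList
NULL

# Canonical stimulus/response order of the 2x2 identification design and the
# level of each dimension in each position.
.grt_order <- c("A1B1", "A2B1", "A1B2", "A2B2")
.grt_levels_a <- c(1L, 2L, 1L, 2L)
.grt_levels_b <- c(1L, 1L, 2L, 2L)

#' Construct a 4x4 confusion matrix for the 2x2 identification task
#'
#' The unit of identification data: a stimulus-by-response count table with
#' both rows and columns in the fixed order A1B1, A2B1, A1B2, A2B2. Rows are
#' stimuli, columns are responses, and each cell holds the number of trials
#' on which that stimulus received that response.
#'
#' @param counts a 4x4 matrix (or something coercible to one) of nonnegative
#'   integral counts in the canonical order.
#' @param labels optional character vector of four stimulus labels.
#' @return an object of class `grt_cm`: the validated integer count matrix
#'   with the labels attached as dimnames.
#' @examples
#' cm <- grt_confusion_matrix(matrix(c(140, 36, 34, 40,
#'                                     89, 91,  4, 66,
#'                                     85,  5, 90, 70,
#'                                     20, 59,  8, 163), 4, 4, byrow = TRUE))
#' rowSums(cm)
#' @export
grt_confusion_matrix <- function(counts, labels = NULL) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(4L, 4L)))
    stop("confusion matrix must be 4x4, got ", nrow(counts), "x",
         ncol(counts), call. = FALSE)
  mode(counts) <- "numeric"
  bad <- which(is.na(counts), arr.ind = TRUE)
  if (nrow(bad))
    stop("missing count in cell (", bad[1, 1], ", ", bad[1, 2], ")",
         call. = FALSE)
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("negative count in cell (", bad[1, 1], ", ", bad[1, 2], ")",
         call. = FALSE)
  bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integral count in cell (", bad[1, 1], ", ", bad[1, 2], ")",
         call. = FALSE)
  counts <- round(counts)
  zr <- which(rowSums(counts) == 0)
  if (length(zr))
    stop("row ", zr[1], " (stimulus ", .grt_order[zr[1]],
         ") has a zero trial total", call. = FALSE)
  if (is.null(labels)) labels <- .grt_order
  if (length(labels) != 4L)
    stop("labels must have length 4", call. = FALSE)
  dimnames(counts) <- list(stimulus = labels, response = labels)
  structure(counts, class = c("grt_cm", "matrix"))
}

#' Read a confusion matrix from a CSV file or literal text
#'
#' Expects a 4x4 comma-separated table, optionally with a single header row
#' and/or a leading label column (auto-detected when the first field of data
#' rows is non-numeric).
#'
#' @param source a file path, or a character vector containing CSV text.
#' @return a [grt_confusion_matrix()] object.
#' @export
read_confusion_matrix <- function(source) {
  df <- .read_csv_flexible(source)
  labels <- NULL
  if (ncol(df) == 5L && !is.numeric(df[[1]])) {
    labels <- as.character(df[[1]])
    df <- df[-1]
  }
  if (ncol(df) != 4L || nrow(df) != 4L)
    stop("confusion matrix file must contain a 4x4 table, got ",
         nrow(df), "x", ncol(df), call. = FALSE)
  hdr <- attr(df, "grt_header")
  if (is.null(labels) && !is.null(hdr)) {
    hd <- if (length(hdr) == 5L) hdr[-1] else hdr
    if (length(hd) == 4L) labels <- hd
  }
  m <- as.matrix(df)
  if (!is.numeric(m))
    stop("confusion matrix cells must be numeric", call. = FALSE)
  grt_confusion_matrix(m, labels = labels)
}

#' Write a confusion matrix to CSV
#'
#' @param cm a `grt_cm` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_confusion_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "grt_cm"))
  write.csv(as.data.frame(unclass(cm)[, , drop = FALSE]), path,
            row.names = FALSE)
  invisible(path)
}

# Reads CSV from a path or literal text; detects and strips a non-numeric
# header row, storing it in attr "grt_header". Comma separator, "." decimal.
.read_csv_flexible <- function(source) {
  if (length(source) == 1L && !grepl("[,\n]", source) && file.exists(source)) {
    lines <- readLines(source)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty input", call. = FALSE)
  first <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  has_header <- all(is.na(suppressWarnings(as.numeric(first[-1])))) ||
    anyNA(suppressWarnings(as.numeric(first[-1])))
  header <- NULL
  if (has_header) {
    header <- trimws(first)
    lines <- lines[-1]
  }
  df <- read.csv(text = paste(lines, collapse = "\n"), header = FALSE,
                 stringsAsFactors = FALSE)
  attr(df, "grt_header") <- header
  df
}

#' Clamp proportions away from 0 and 1
#'
#' Sensitivity measures and proportion tests require proportions strictly
#' inside (0, 1); values are clamped into \[1e-10, 1 - 1e-10\] (so an exact
#' zero becomes 1e-10 and an exact one becomes 1 - 1e-10), with a warning
#' per replaced value.
#'
#' @param p numeric vector of proportions in \[0, 1\].
#' @return the sanitized vector.
#' @export
sanitize_proportion <- function(p) {
  if (any(is.na(p) | p < 0 | p > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  for (i in which(p < 1e-10)) {
    warning("proportion of ", p[i], " replaced with 1e-10", call. = FALSE)
    p[i] <- 1e-10
  }
  for (i in which(p > 1 - 1e-10)) {
    warning("proportion of ", p[i], " replaced with 1 - 1e-10",
            call. = FALSE)
    p[i] <- 1 - 1e-10
  }
  p
}

#' Construct a Garner filtering-task trial table
#'
#' One row per trial with five columns: `block` (1 = baseline, 2 =
#' filtering), `relevant` (level of the relevant dimension, 1 or 2),
#' `irrelevant` (level of the irrelevant dimension, 1 or 2), `accuracy`
#' (0/1), and `rt` (positive response time, in whatever unit the data were
#' collected).
#'
#' @param df a data frame (or matrix) with the five columns above, in order.
#' @return a validated `garner_trials` data frame; trial order is preserved.
#' @export
garner_trials <- function(df) {
  df <- as.data.frame(df)
  attr(df, "grt_header") <- NULL
  if (ncol(df) != 5L)
    stop("Garner trial table must have 5 columns (block, relevant, ",
         "irrelevant, accuracy, rt), got ", ncol(df), call. = FALSE)
  names(df) <- c("block", "relevant", "irrelevant", "accuracy", "rt")
  for (col in names(df)) {
    if (!is.numeric(df[[col]]) || anyNA(df[[col]]))
      stop("column '", col, "' must be numeric with no missing values",
           call. = FALSE)
  }
  chk <- function(col, allowed) {
    bad <- which(!df[[col]] %in% allowed)
    if (length(bad))
      stop("column '", col, "' has value ", df[[col]][bad[1]], " at trial ",
           bad[1], "; allowed: ", paste(allowed, collapse = ", "),
           call. = FALSE)
  }
  chk("block", 1:2)
  chk("relevant", 1:2)
  chk("irrelevant", 1:2)
  chk("accuracy", 0:1)
  bad <- which(df$rt <= 0)
  if (length(bad))
    stop("nonpositive response time at trial ", bad[1], call. = FALSE)
  for (col in c("block", "relevant", "irrelevant", "accuracy"))
    df[[col]] <- as.integer(df[[col]])
  df$rt <- as.numeric(df$rt)
  class(df) <- c("garner_trials", "data.frame")
  df
}

#' Read a Garner trial table from a CSV file or literal text
#'
#' @inheritParams read_confusion_matrix
#' @return a [garner_trials()] data frame.
#' @export
read_garner_trials <- function(source) {
  df <- .read_csv_flexible(source)
  garner_trials(df)
}

#' Write a Garner trial table to CSV
#'
#' @param trials a `garner_trials` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_garner_trials <- function(trials, path) {
  stopifnot(inherits(trials, "garner_trials"))
  out <- as.data.frame(trials)
  out$rt <- sprintf("%.17g", out$rt)  # lossless round trip
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.grt_cm <- function(x, ...) {
  cat("2x2 identification confusion matrix (stimulus x response)\n")
  print(unclass(x))
  invisible(x)
}
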