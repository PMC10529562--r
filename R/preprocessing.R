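# The five preprocessing operators on the beat matrix A (m beats x n samples).
# Column-wise operators (standardize/extremum/mean/std) act per sample
# position over the beat population; the per-beat self-processing operator
# acts along each row, which makes it invariant to the per-beat affine
# amplitude differences that separate source databases.

colSds <- function(A) {
  m <- nrow(A)
  mu <- colMeans(A)
  sqrt(colSums(sweep(A, 2, mu)^2) / (m - 1))
}

rowSds <- function(A) {
  n <- ncol(A)
  mu <- rowMeans(A)
  sqrt(rowSums((A - mu)^2) / (n - 1))
}

#' Column-wise standardization (zero mean, unit sample sd per sample position)
#'
#' `a'[i,j] = (a[i,j] - mean(col j)) / sd(col j)` with the sample standard
#' deviation (denominator m-1). Every column of the result has mean 0 and
#' sample sd 1.
#'
#' @param A Numeric matrix, m beats x n samples, m >= 2.
#' @param stats Optional list `list(center, scale)` of precomputed column
#'   statistics (as fitted on a training split); when supplied they are
#'   applied unchanged, avoiding test-set leakage.
#' @return Matrix of the same shape; the statistics used are attached as
#'   `attr(, "stats")`.
#' @export
standardizeColumns <- function(A, stats = NULL) {
  A <- as.matrix(A)
  if (is.null(stats)) {
    if (nrow(A) < 2) stop("standardizeColumns needs m >= 2 beats", call. = FALSE)
    s <- colSds(A)
    if (any(s == 0))
      stop("zero-variance column(s): ",
           paste(utils::head(which(s == 0), 5), collapse = ", "), call. = FALSE)
    stats <- list(center = colMeans(A), scale = s)
  }
  out <- sweep(sweep(A, 2, stats$center), 2, stats$scale, "/")
  attr(out, "stats") <- stats
  out
}

#' Column-wise extremum (min-max) scaling to [0, 1]
#'
#' `a'[i,j] = (a[i,j] - min(col j)) / (max(col j) - min(col j))`. Constant
#' columns are mapped to 0 with a warning rather than failing.
#'
#' @inheritParams standardizeColumns
#' @param stats Optional list `list(min, max)` from a training split.
#' @return Matrix of the same shape with `attr(, "stats")`.
#' @export
extremumScale <- function(A, stats = NULL) {
  A <- as.matrix(A)
  if (is.null(stats)) {
    if (nrow(A) < 2) stop("extremumScale needs m >= 2 beats", call. = FALSE)
    stats <- list(min = apply(A, 2, min), max = apply(A, 2, max))
  }
  rng <- stats$max - stats$min
  flat <- rng == 0
  if (any(flat)) {
    warning(sum(flat), " constant column(s) mapped to 0", call. = FALSE)
    rng[flat] <- 1
  }
  out <- sweep(sweep(A, 2, stats$min), 2, rng, "/")
  out[, flat] <- 0
  attr(out, "stats") <- stats
  out
}

#' Column-wise mean scaling
#'
#' Divides each column by its mean, `a'[i,j] = a[i,j] / mean(col j)`,
#' retaining relative differences between sample positions.
#'
#' @inheritParams standardizeColumns
#' @param stats Optional list `list(center)` from a training split.
#' @return Matrix of the same shape with `attr(, "stats")`.
#' @export
meanScale <- function(A, stats = NULL) {
  A <- as.matrix(A)
  if (is.null(stats)) {
    mu <- colMeans(A)
    if (any(mu == 0))
      stop("zero-mean column(s): ",
           paste(utils::head(which(mu == 0), 5), collapse = ", "), call. = FALSE)
    stats <- list(center = mu)
  }
  out <- sweep(A, 2, stats$center, "/")
  attr(out, "stats") <- stats
  out
}

#' Column-wise standard-deviation scaling
#'
#' Divides each column by its sample standard deviation without centring,
#' `a'[i,j] = a[i,j] / sd(col j)`; output columns have sample sd 1.
#'
#' @inheritParams standardizeColumns
#' @param stats Optional list `list(scale)` from a training split.
#' @return Matrix of the same shape with `attr(, "stats")`.
#' @export
stdScale <- function(A, stats = NULL) {
  A <- as.matrix(A)
  if (is.null(stats)) {
    if (nrow(A) < 2) stop("stdScale needs m >= 2 beats", call. = FALSE)
    s <- colSds(A)
    if (any(s == 0))
      stop("zero-variance column(s): ",
           paste(utils::head(which(s == 0), 5), collapse = ", "), call. = FALSE)
    stats <- list(scale = s)
  }
  out <- sweep(A, 2, stats$scale, "/")
  attr(out, "stats") <- stats
  out
}

#' Per-beat self-processing normalization
#'
#' Normalizes along the heartbeat dimension: each beat (row) has its own mean
#' subtracted and is divided by its own sample standard deviation (denominator
#' n-1), so every row of the result has mean 0 and sample sd 1. Because each
#' beat supplies its own statistics, the operator is invariant to per-beat
#' affine amplitude changes `alpha * x + beta` (alpha > 0) — exactly the gain
#' and offset differences between recording devices and databases — and it is
#' idempotent.
#'
#' Flatline beats (zero row sd) cannot be normalized; they are removed and
#' reported in `attr(, "dropped")` (row indices) rather than aborting.
#'
#' @param A Numeric matrix, m beats x n samples, n >= 2.
#' @return Matrix of the kept rows, normalized; dropped row indices in
#'   `attr(, "dropped")`.
#' @export
selfProcess <- function(A) {
  A <- as.matrix(A)
  if (ncol(A) < 2) stop("selfProcess needs n >= 2 samples per beat",
                        call. = FALSE)
  s <- rowSds(A)
  dropped <- which(s == 0)
  if (length(dropped)) {
    A <- A[-dropped, , drop = FALSE]
    s <- s[-dropped]
  }
  out <- (A - rowMeans(A)) / s
  attr(out, "dropped") <- dropped
  out
}

#' Preprocessing operator names
#' @return Character vector of the recognised operator names.
#' @export
preprocessingMethods <- function() {
  c("none", "standardize", "extremum", "mean", "std", "self")
}

# Column-wise operators need fitted statistics; "none"/"self" are stateless.
isColumnwise <- function(method) {
  method %in% c("standardize", "extremum", "mean", "std")
}

#' Apply a preprocessing operator by name
#'
#' Dispatches to one of the five operators (or the identity). For column-wise
#' operators, `stats` carries statistics fitted on a training split; when
#' `NULL` the statistics are fitted on `A` itself (pooled behaviour).
#'
#' @param A Numeric beat matrix.
#' @param method One of [preprocessingMethods()].
#' @param stats Optional fitted statistics list.
#' @return The transformed matrix, with `attr(, "stats")` (column-wise
#'   methods) or `attr(, "dropped")` (self).
#' @export
applyPreprocessor <- function(A, method, stats = NULL) {
  method <- match.arg(method, preprocessingMethods())
  switch(method,
    none = A,
    standardize = standardizeColumns(A, stats),
    extremum = extremumScale(A, stats),
    mean = meanScale(A, stats),
    std = stdScale(A, stats),
    self = selfProcess(A)
  )
}

#' Apply a preprocessing operator to a BeatDataset
#'
#' Transforms the beat matrix in place, updating labels/provenance when the
#' self-processing operator drops flatline beats (logged in the drop log).
#' Column-wise operators applied here use pooled statistics over the whole
#' dataset; to fit on a training split only, leave the operator pending and
#' let [stratifiedSplit()] resolve it (see [integrateDatabases()]).
#'
#' @param dataset A [BeatDataset-class].
#' @param method One of [preprocessingMethods()].
#' @param stats Optional fitted statistics for column-wise operators.
#' @return The transformed [BeatDataset-class].
#' @export
preprocessDataset <- function(dataset, method, stats = NULL) {
  stopifnot(is(dataset, "BeatDataset"))
  method <- match.arg(method, preprocessingMethods())
  if (method == "none") {
    dataset@preprocessing$applied <- "none"
    dataset@preprocessing$pending <- "none"
    return(dataset)
  }
  A <- applyPreprocessor(dataset@beats, method, stats)
  if (method == "self") {
    dropped <- attr(A, "dropped")
    if (length(dropped)) {
      extra <- data.frame(
        record_id = dataset@sourceRecord[dropped],
        r_index = NA_integer_,
        reason = rep("flatline beat (zero sd) under self-processing",
                     length(dropped)))
      dataset@dropLog <- rbind(dataset@dropLog, extra)
      dataset@labels <- dataset@labels[-dropped]
      dataset@sourceDb <- dataset@sourceDb[-dropped]
      dataset@sourceRecord <- dataset@sourceRecord[-dropped]
    }
  }
  attr(A, "stats") <- NULL
  attr(A, "dropped") <- NULL
  dataset@beats <- A
  dataset@preprocessing$applied <- method
  dataset@preprocessing$pending <- "none"
  validObject(dataset)
  dataset
}
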