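#' Scoring configuration for PML classification
#'
#' Bundles the metric choice, decision threshold and minimum run length used
#' to turn a per-read pseudo-matching-length (PML) profile into a host /
#' non-host call. The default thresholds are the analytically calibrated
#' values derived from a theoretical 150 bp host read containing a single
#' contiguous matching run of 31 bases: 31 for the maximum metric, 3.306 for
#' the average metric, and 0.175 for the custom run-weighted metric with
#' minimum run length `w = 5`.
#'
#' @param metric One of `"custom"`, `"maximum"`, `"average"`.
#' @param threshold Decision threshold; defaults to the calibrated value for
#'   the chosen metric.
#' @param w Minimum run length in bases (strict: runs of length > `w`
#'   contribute); only used by the custom metric.
#' @return An object of class `score_config`.
#' @export
score_config <- function(metric = c("custom", "maximum", "average"),
                         threshold = NULL, w = 5L) {
  metric <- match.arg(metric)
  if (is.null(threshold)) {
    threshold <- switch(metric, maximum = 31, average = 3.306, custom = 0.175)
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0,
            is.numeric(w), length(w) == 1L, w >= 0)
  structure(list(metric = metric, threshold = threshold, w = as.integer(w)),
            class = "score_config")
}

#' @export
print.score_config <- function(x, ...) {
  cat("score_config: metric=", x$metric, " threshold=", x$threshold,
      " w=", x$w, "\n", sep = "")
  invisible(x)
}

.check_pml <- function(pml) {
  pml <- as.integer(pml)
  if (!length(pml) || any(is.na(pml)) || any(pml < 0)) {
    stop("a PML vector must be a non-empty vector of non-negative integers")
  }
  pml
}

#' Decompose a PML vector into matching runs
#'
#' A run is a maximal segment over which successive values decrease by
#' exactly 1, starting at an entry point (position 1, or any position whose
#' value exceeds the previous value minus 1). Zero values belong to no run.
#' For an uninterrupted exact match the run decays fully (e.g. 31, 30, ...,
#' 1) and its length equals its starting value; runs superseded early by a
#' longer fresh match are shorter than their starting value.
#'
#' @param pml Integer vector of per-position matching lengths.
#' @return A data.frame with columns `start` (1-based), `length` (number of
#'   positions in the segment -- the run length `r` used by the custom
#'   metric) and `value` (PML at the run start).
#' @export
#' @examples
#' decompose_runs(c(5, 4, 3, 2, 1, 0, 0, 7, 6, 5, 4, 3, 2, 1))
decompose_runs <- function(pml) {
  pml <- .check_pml(pml)
  n <- length(pml)
  pos <- pml > 0L
  prev <- c(0L, pml[-n])
  entry <- pos & (pml > prev - 1L)
  if (!any(entry)) {
    return(data.frame(start = integer(), length = integer(),
                      value = integer()))
  }
  grp <- cumsum(entry)
  starts <- which(entry)
  lens <- tabulate(grp[pos], nbins = length(starts))
  data.frame(start = starts, length = lens, value = pml[starts])
}

#' PML score metrics
#'
#' `score_maximum` returns the largest matching length in the profile;
#' `score_average` the mean over all read positions (zeros included);
#' `score_custom` the run-weighted metric
#' \deqn{\frac{1}{2L}\Big(\max(\mathrm{PML}) +
#'   \big(\sum_{r \in R} r\big)\,\ln(|R|+1)\Big),}
#' where `R` is the set of matching runs strictly longer than `w` bases and
#' each run contributes its length `r`. The natural logarithm is used; an
#' empty `R` contributes nothing. Scores are pure functions of the PML
#' vector.
#'
#' @param pml Integer vector of per-position matching lengths.
#' @param w Minimum run length (strict inequality), default 5.
#' @return A single numeric score.
#' @export
#' @examples
#' pml <- c(31:1, rep(0, 119)) # theoretical 150 bp read, one run of 31
#' score_maximum(pml) # 31
#' score_average(pml) # 496/150
#' round(score_custom(pml), 3) # 0.175
score_maximum <- function(pml) {
  max(.check_pml(pml))
}

#' @rdname score_maximum
#' @export
score_average <- function(pml) {
  mean(.check_pml(pml))
}

#' @rdname score_maximum
#' @export
score_custom <- function(pml, w = 5L) {
  pml <- .check_pml(pml)
  L <- length(pml)
  runs <- decompose_runs(pml)
  r <- runs$length[runs$length > w]
  (max(pml) + sum(r) * log(length(r) + 1)) / (2 * L)
}

#' Score and classify reads from their PML profiles
#'
#' A read is called `"host"` when its score is greater than or equal to the
#' configured threshold (the calibrated thresholds are defined by the
#' boundary-case theoretical read, which is intended to be caught).
#'
#' @param pml_list A list of PML vectors (as from [matching_lengths()]), or
#'   a single PML vector for `classify_read`.
#' @param config A [score_config()].
#' @return `score_reads`: numeric vector of scores. `classify_reads`:
#'   character vector of `"host"` / `"nonhost"`. `classify_read`: a single
#'   call.
#' @export
score_reads <- function(pml_list, config = score_config()) {
  stopifnot(inherits(config, "score_config"))
  if (!is.list(pml_list)) pml_list <- list(pml_list)
  f <- switch(config$metric,
    maximum = score_maximum,
    average = score_average,
    custom = function(p) score_custom(p, w = config$w)
  )
  vapply(pml_list, f, numeric(1))
}

#' @rdname score_reads
#' @export
classify_reads <- function(pml_list, config = score_config()) {
  ifelse(score_reads(pml_list, config) >= config$threshold, "host", "nonhost")
}

#' @rdname score_reads
#' @param pml A single PML vector.
#' @export
classify_read <- function(pml, config = score_config()) {
  classify_reads(list(.check_pml(pml)), config)[1]
}

#' Grid search over custom-metric thresholds and run lengths
#'
#' Evaluates host recall/precision and microbial loss for every combination
#' of decision threshold and minimum run length on ground-truth labeled PML
#' profiles. The default grid is thresholds 0.145 to 0.200 in steps of 0.005
#' (12 values) by minimum run lengths 2 to 12 (11 values), i.e. 132
#' combinations.
#'
#' @param pml_list List of PML vectors.
#' @param labels Character vector of ground-truth labels, `"human"` or
#'   `"microbial"`, one per profile.
#' @param thresholds Numeric vector of thresholds to evaluate.
#' @param w_values Integer vector of minimum run lengths to evaluate.
#' @return A data.frame with one row per (threshold, w): `threshold`, `w`,
#'   `recall_human` (fraction of human profiles called host),
#'   `precision_human` (human fraction of host calls; `NA` when nothing is
#'   called host) and `microbial_loss_rate` (fraction of microbial profiles
#'   called host).
#' @export
grid_search <- function(pml_list, labels,
                        thresholds = seq(0.145, 0.200, by = 0.005),
                        w_values = 2:12) {
  if (!length(pml_list)) stop("grid_search needs a non-empty labeled set")
  stopifnot(length(labels) == length(pml_list),
            all(labels %in% c("human", "microbial")))
  human <- labels == "human"
  out <- vector("list", length(w_values) * length(thresholds))
  k <- 0L
  for (w in w_values) {
    scores <- vapply(pml_list, score_custom, numeric(1), w = w)
    for (t in thresholds) {
      called <- scores >= t
      tp <- sum(called & human)
      fp <- sum(called & !human)
      k <- k + 1L
      out[[k]] <- data.frame(
        threshold = t, w = as.integer(w),
        recall_human = tp / sum(human),
        precision_human = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
        microbial_loss_rate = fp / sum(!human)
      )
    }
  }
  do.call(rbind, out)
}
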