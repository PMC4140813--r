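## Interspike-interval regularity: CV (SD/mean of ISIs) and CV2 (mean of
## 2|ISI_{n+1}-ISI_n|/(ISI_n+ISI_{n+1}) over adjacent pairs, range [0, 2],
## nearly insensitive to slow rate drift), plus epoch-restricted ISI
## extraction and the paired Wilcoxon comparison.

#' Coefficient of variation of interspike intervals
#'
#' Sample standard deviation (n-1 denominator) over the mean.
#'
#' @param isis numeric vector of interspike intervals (>= 2 values).
#' @return CV, dimensionless.
#' @export
cv_isi <- function(isis) {
  if (length(isis) < 2) stop("CV needs at least 2 intervals", call. = FALSE)
  stats::sd(isis) / mean(isis)
}

#' CV2: regularity of adjacent interspike intervals
#'
#' Mean over adjacent pairs of `2 * |ISI_{n+1} - ISI_n| / (ISI_n +
#' ISI_{n+1})`. Each term lies in [0, 2]; a perfectly periodic train
#' gives 0 and i.i.d. exponential intervals give values near 1.
#'
#' @param isis numeric vector of interspike intervals (>= 2 values, all
#'   positive).
#' @return CV2, dimensionless, in [0, 2].
#' @examples
#' cv2_isi(c(0.010, 0.030))  # 2*0.02/0.04 = 1
#' @export
cv2_isi <- function(isis) {
  if (length(isis) < 2) stop("CV2 needs at least 2 intervals", call. = FALSE)
  if (any(isis <= 0)) stop("CV2 requires positive intervals", call. = FALSE)
  a <- isis[-length(isis)]
  b <- isis[-1]
  mean(2 * abs(b - a) / (a + b))
}

#' Epoch-restricted interspike intervals for one unit
#'
#' Collects simple-spike ISIs whose both endpoints fall inside the same
#' epoch of the same trial. The light-off epoch is the pre-onset window
#' `[skip, on)`; the light-on epoch is `[on, off)`. Intervals spanning a
#' light transition are excluded by construction; intervals containing a
#' complex spike (and hence a climbing-fiber pause) are excluded as well.
#' Adjacent-interval pairs for CV2 are taken within the surviving
#' contiguous runs only, never across an exclusion.
#'
#' @param events a [spike_events()] table for a single unit (unaligned).
#' @param protocol a [light_protocol()] table.
#' @param epoch `"on"` or `"off"`.
#' @param skip seconds dropped at each trial start for the off epoch.
#' @return A list of numeric vectors, one per contiguous run of included
#'   intervals (concatenate with `unlist()` for CV; feed to
#'   [cv2_pooled()] for CV2).
#' @export
epoch_isis <- function(events, protocol, epoch = c("on", "off"), skip = 0.1) {
  epoch <- match.arg(epoch)
  if (length(unique(events$unit_id)) > 1) {
    stop("epoch_isis is per unit; got multiple unit_id values", call. = FALSE)
  }
  protocol <- light_protocol(protocol)
  runs <- list()
  for (tr in unique(events$trial_id)) {
    pr <- protocol[protocol$trial_id == tr, ]
    if (nrow(pr) == 0) stop("trial_id not found in protocol: ", tr, call. = FALSE)
    win <- if (epoch == "on") c(pr$light_on_s, pr$light_off_s) else
      c(skip, pr$light_on_s)
    sel <- events$trial_id == tr
    ss <- sort(events$time_s[sel & events$event_type == "simple"])
    ss <- ss[ss >= win[1] & ss < win[2]]
    if (length(ss) < 2) next
    cs <- events$time_s[sel & events$event_type == "complex"]
    isis <- diff(ss)
    ## exclude intervals containing a complex spike (pause-inflated)
    contains_cs <- vapply(seq_along(isis), function(i) {
      any(cs >= ss[i] & cs < ss[i + 1])
    }, logical(1))
    ## split into contiguous runs of included intervals
    ok <- !contains_cs
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      runs[[length(runs) + 1]] <- isis[starts[j]:ends[j]]
    }
  }
  runs
}

#' CV2 pooled over contiguous interval runs
#'
#' Computes CV2 terms within each run of at least two intervals and
#' averages them, so adjacent-interval pairs never straddle an excluded
#' interval or a trial boundary.
#'
#' @param runs list of ISI vectors, as returned by [epoch_isis()].
#' @return CV2, or `NA` when no run has two intervals.
#' @export
cv2_pooled <- function(runs) {
  terms <- unlist(lapply(runs, function(isis) {
    if (length(isis) < 2) return(numeric(0))
    a <- isis[-length(isis)]
    b <- isis[-1]
    2 * abs(b - a) / (a + b)
  }))
  if (length(terms) == 0) return(NA_real_)
  mean(terms)
}

#' Paired Wilcoxon signed-rank comparison of regularity
#'
#' Two-sided Wilcoxon signed-rank test on per-unit (on - off)
#' differences; the exact distribution is used for n <= 25 without ties,
#' the normal approximation with continuity correction above.
#'
#' @param on,off paired per-unit values (same length, n >= 5).
#' @return List with `statistic`, `p_value`, `n`; `p_value` is `NA` with
#'   a warning when all differences are zero.
#' @export
paired_regularity_test <- function(on, off) {
  if (length(on) != length(off)) stop("paired vectors differ in length", call. = FALSE)
  keep <- !is.na(on) & !is.na(off)
  on <- on[keep]; off <- off[keep]
  if (length(on) < 5) stop("need at least 5 pairs", call. = FALSE)
  d <- on - off
  if (all(d == 0)) {
    warning("all paired differences are zero: test undefined", call. = FALSE)
    return(list(statistic = NA_real_, p_value = NA_real_, n = length(on)))
  }
  wt <- stats::wilcox.test(on, off, paired = TRUE,
                           exact = length(on) <= 25 && !any(d == 0) &&
                             !anyDuplicated(abs(d)),
                           correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value, n = length(on))
}
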