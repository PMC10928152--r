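# ---- race-model SSRT -------------------------------------------------------

#' Estimate the stop-signal reaction time (SSRT)
#'
#' Race-model estimate of stopping speed from a trial table. The default
#' integration method takes the go-RT percentile at the observed probability
#' of responding on stop trials and subtracts the mean stop-signal delay;
#' go omissions are assigned the maximum go RT before the percentile is
#' taken (consensus convention). The percentile is the `ceiling(p * n)`-th
#' order statistic. A mean method (mean go RT minus mean SSD) is available
#' behind the `method` flag.
#'
#' @param trials a `data.frame` as produced by
#'   [generate_race_model_trials()]: columns `trial_type`, `rt`,
#'   `responded`, `ssd`.
#' @param method `"integration"` (default) or `"mean"`.
#' @return SSRT in ms, with attributes `p_respond` and `mean_ssd`. `NA`
#'   (with attribute `inestimable = TRUE`) when stop accuracy is 0 or 1.
#' @export
estimate_ssrt <- function(trials, method = c("integration", "mean")) {
  method <- match.arg(method)
  stopifnot(all(c("trial_type", "rt", "responded", "ssd") %in% names(trials)))
  stop_tr <- trials[trials$trial_type == "stop", ]
  go_tr <- trials[trials$trial_type == "go", ]
  if (nrow(stop_tr) < 20L) stop("need at least 20 stop trials")
  p_resp <- mean(stop_tr$responded)
  mean_ssd <- mean(stop_tr$ssd)
  if (p_resp <= 0 || p_resp >= 1) {
    out <- NA_real_
    attr(out, "inestimable") <- TRUE
    attr(out, "p_respond") <- p_resp
    return(out)
  }
  go_rt <- go_tr$rt
  go_rt[!go_tr$responded | is.na(go_rt)] <- max(go_rt, na.rm = TRUE)
  ssrt <- if (method == "integration") {
    srt <- sort(go_rt)
    srt[ceiling(p_resp * length(srt))] - mean_ssd
  } else {
    mean(go_rt) - mean_ssd
  }
  attr(ssrt, "p_respond") <- p_resp
  attr(ssrt, "mean_ssd") <- mean_ssd
  ssrt
}

# ---- task-specific cognitive-control indices -------------------------------

#' Cognitive-control index for a task
#'
#' Computes the per-subject scalar control index for one of the supported
#' tasks, oriented so that larger values always mean better cognitive
#' control:
#' \describe{
#'   \item{axcpt}{`z(AY RT) - z(BX RT)` (z-scores across the sample): a
#'     composite of proactive (long AY) and reactive (short BX) control.}
#'   \item{cuedts, stroop}{negative congruency cost
#'     `-(incongruent RT - congruent RT)`: a smaller cost is better control.
#'     The raw signed cost is attached as attribute `"raw_cost"`.}
#'   \item{sternberg, rp}{efficiency `accuracy / RT` on the demanding
#'     condition, z-standardized across the sample.}
#'   \item{sst}{`1000 / SSRT` in 1/s: faster stopping is better control.}
#' }
#'
#' @param task one of `"axcpt"`, `"cuedts"`, `"sternberg"`, `"stroop"`,
#'   `"sst"`, `"rp"`.
#' @param behavior `data.frame` of per-subject summaries with the columns
#'   the task needs (`ay_rt`/`bx_rt`; `congruent_rt`/`incongruent_rt`;
#'   `acc`/`rt`; `ssrt_ms`). Missing columns raise an error naming them.
#' @return Numeric vector of indices (one per row), larger = better control.
#' @export
control_index <- function(task = c("axcpt", "cuedts", "sternberg", "stroop",
                                   "sst", "rp"),
                          behavior) {
  task <- match.arg(task)
  need <- switch(task,
                 axcpt = c("ay_rt", "bx_rt"),
                 cuedts = , stroop = c("congruent_rt", "incongruent_rt"),
                 sternberg = , rp = c("acc", "rt"),
                 sst = "ssrt_ms")
  missing_cols <- setdiff(need, names(behavior))
  if (length(missing_cols)) {
    stop("missing behavioral column(s): ", paste(missing_cols, collapse = ", "))
  }
  switch(task,
         axcpt = as.vector(scale(behavior$ay_rt) - scale(behavior$bx_rt)),
         cuedts = , stroop = {
           cost <- behavior$incongruent_rt - behavior$congruent_rt
           out <- -cost
           attr(out, "raw_cost") <- cost
           out
         },
         sternberg = , rp = as.vector(scale(behavior$acc / behavior$rt)),
         sst = 1000 / behavior$ssrt_ms)
}

# ---- paired condition contrasts --------------------------------------------

#' Paired two-tailed t-test with Cohen's d
#'
#' Paired t on the within-subject differences, with the paired-design effect
#' size `d_z = mean(diff) / sd(diff)` (a pooled-sd variant is available
#' behind `d_method`). Zero-variance differences leave `t` undefined,
#' flagged.
#'
#' @param x,y equal-length per-subject vectors (n >= 3).
#' @param d_method `"dz"` (default) or `"pooled"`.
#' @return List with `t`, `df`, `p_value` (two-tailed), `d`, `mean_diff`,
#'   and `undefined` flag.
#' @export
paired_condition_test <- function(x, y, d_method = c("dz", "pooled")) {
  d_method <- match.arg(d_method)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  diffs <- x - y
  n <- length(diffs)
  sd_d <- stats::sd(diffs)
  if (sd_d == 0) {
    equal <- mean(diffs) == 0
    return(list(t = if (equal) 0 else NaN, df = n - 1,
                p_value = if (equal) 1 else NaN, d = if (equal) 0 else NaN,
                mean_diff = mean(diffs), undefined = !equal))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  d <- if (d_method == "dz") mean(diffs) / sd_d else
    mean(diffs) / sqrt((stats::var(x) + stats::var(y)) / 2)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, d = d, mean_diff = mean(diffs),
       undefined = FALSE)
}
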