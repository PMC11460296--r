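#' Physical volume of a binary mask
#'
#' Voxel count times voxel volume in mm^3, converted to cm^3.
#'
#' @param mask binary array
#' @param spacing voxel spacing in mm
#' @return volume in cm^3
#' @export
mask_volume_cm3 <- function(mask, spacing) {
  sum(mask == 1) * prod(spacing) / 1000
}

#' Mean, 95% confidence interval and median
#'
#' Normal-theory t interval: mean +/- t(0.975, n-1) * sd / sqrt(n).
#'
#' @param values numeric vector, n >= 2
#' @return named list `(mean, lower, upper, median, n)`
#' @export
ci95 <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("confidence interval undefined for n < 2")
  m <- mean(values)
  half <- stats::qt(0.975, n - 1) * stats::sd(values) / sqrt(n)
  list(mean = m, lower = m - half, upper = m + half,
       median = stats::median(values), n = n)
}

#' Stratify evaluation records into gland-volume quartiles
#'
#' Cases are ranked by reference gland volume and split at the empirical
#' 25/50/75 percentiles (linear interpolation) into Q1-Q4 using half-open
#' intervals; boundary ties resolve by case-id order so the partition is
#' exact and quartile counts differ by at most 1. Per quartile the
#' mean/median/95% CI of Dice is reported.
#'
#' @param records data.frame with columns `case_id`, `dice`,
#'   `reference_volume_cm3` (one structure's rows, e.g. gland only)
#' @return data.frame, one row per quartile
#' @export
quartile_stratify <- function(records) {
  n <- nrow(records)
  if (n < 4) stop("need at least 4 cases for quartile stratification")
  records <- records[order(records$reference_volume_cm3, records$case_id), ]
  # rank-based split at the 25/50/75 positions; cases tied on a percentile
  # boundary resolve by case-id order, so counts differ by at most 1
  target <- rep(n %/% 4L, 4L) + (seq_len(4L) <= n %% 4L)
  q_of <- rep(1:4, times = target)
  out <- lapply(1:4, function(q) {
    d <- records$dice[q_of == q]
    ci <- if (length(d) >= 2) ci95(d)
          else list(mean = mean(d), lower = NA_real_, upper = NA_real_,
                    median = stats::median(d), n = length(d))
    data.frame(quartile = paste0("Q", q), n = length(d),
               volume_min = min(records$reference_volume_cm3[q_of == q]),
               volume_max = max(records$reference_volume_cm3[q_of == q]),
               dice_mean = ci$mean, dice_lower = ci$lower,
               dice_upper = ci$upper, dice_median = ci$median,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Unpooled (Welch) two-sample volume comparison
#'
#' @param a,b numeric vectors (each n >= 2)
#' @return list `(t, p)` with the two-sided Welch p-value
#' @export
compare_volumes_unpooled <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = Inf * sign(mean(a) - mean(b)), p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' One-tailed paired comparison of two models' per-case scores
#'
#' Paired differences are tested one-tailed in the direction of the larger
#' sample mean; the better model is declared the winner at p < 0.05,
#' otherwise the models are reported as statistically the same. All-zero
#' differences are a declared tie with p = 0.5 by convention.
#'
#' @param scores_a,scores_b equal-length per-case score vectors, paired by
#'   case
#' @param labels length-2 model names
#' @return list `(t, p_one_tailed, winner)`; `winner` is a label or
#'   `"statistically the same"`
#' @export
compare_models_paired <- function(scores_a, scores_b,
                                  labels = c("a", "b")) {
  if (length(scores_a) != length(scores_b))
    stop("paired comparison needs equal-length score vectors")
  d <- scores_b - scores_a
  if (all(d == 0))
    return(list(t = 0, p_one_tailed = 0.5,
                winner = "statistically the same"))
  better <- if (mean(d) >= 0) 2L else 1L
  alt <- if (better == 2L) "greater" else "less"
  if (stats::sd(d) == 0) {
    # constant nonzero difference: the paired t statistic degenerates;
    # declare the direction with p -> 0
    return(list(t = Inf * sign(mean(d)), p_one_tailed = 0,
                winner = labels[better]))
  }
  ht <- stats::t.test(scores_b, scores_a, paired = TRUE,
                      alternative = alt)
  winner <- if (ht$p.value < 0.05) labels[better]
            else "statistically the same"
  list(t = unname(ht$statistic), p_one_tailed = ht$p.value,
       winner = winner)
}

#' Summarize a cohort's evaluation records
#'
#' Per structure: n, mean/median/95% CI of Dice, Hausdorff distance and
#' reference volume, plus the gland-volume quartile block.
#'
#' @param records data.frame from [evaluate_cohort()]
#' @return list with `by_structure` (data.frame) and `quartiles`
#'   (data.frame for the gland rows)
#' @export
cohort_summary <- function(records) {
  by_structure <- do.call(rbind, lapply(split(records, records$structure),
    function(r) {
      dci <- ci95(r$dice)
      vci <- ci95(r$reference_volume_cm3)
      hd <- r$hausdorff_mm[is.finite(r$hausdorff_mm)]
      data.frame(structure = r$structure[1], n = nrow(r),
                 dice_mean = dci$mean, dice_lower = dci$lower,
                 dice_upper = dci$upper, dice_median = dci$median,
                 hd_mean = if (length(hd)) mean(hd) else NA_real_,
                 hd_median = if (length(hd)) stats::median(hd) else NA_real_,
                 volume_mean = vci$mean, volume_lower = vci$lower,
                 volume_upper = vci$upper, volume_median = vci$median,
                 stringsAsFactors = FALSE)
    }))
  gl <- records[records$structure == "gland", ]
  quart <- if (nrow(gl) >= 4) quartile_stratify(gl) else NULL
  list(by_structure = by_structure, quartiles = quart)
}

#' Write / read evaluation records as CSV
#' @param records data.frame of evaluation records
#' @param path CSV path
#' @export
write_eval_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eval_records
#' @export
read_eval_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
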