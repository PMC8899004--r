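#' Contrast partition coefficient from T1 values
#'
#' The partition coefficient lambda is the ratio of the contrast-induced
#' change in longitudinal relaxation rate (delta R1 = 1/T1_post - 1/T1_pre)
#' in myocardium to that in blood. All T1 values in milliseconds; vectorized.
#'
#' @param t1_myo_pre,t1_myo_post native and post-contrast myocardial T1 (ms).
#' @param t1_blood_pre,t1_blood_post native and post-contrast blood T1 (ms).
#' @return lambda (dimensionless, positive).
#' @export
partition_coefficient <- function(t1_myo_pre, t1_myo_post,
                                  t1_blood_pre, t1_blood_post) {
  vals <- cbind(t1_myo_pre, t1_myo_post, t1_blood_pre, t1_blood_post)
  if (any(vals <= 0, na.rm = TRUE)) stop("T1 values must be positive")
  if (any(t1_myo_post >= t1_myo_pre | t1_blood_post >= t1_blood_pre,
          na.rm = TRUE)) {
    stop("post-contrast T1 must be shorter than native T1 ",
         "(invalid contrast dynamics)")
  }
  num <- 1 / t1_myo_post - 1 / t1_myo_pre
  den <- 1 / t1_blood_post - 1 / t1_blood_pre
  if (any(den <= 0, na.rm = TRUE)) {
    stop("degenerate blood T1 dynamics (non-positive delta R1)")
  }
  num / den
}

#' Extracellular volume fraction (percent)
#'
#' ECV = 100 (1 - Hct) lambda, with lambda the partition coefficient and Hct
#' the hematocrit fraction; a direct surrogate of interstitial fibrosis.
#'
#' @inheritParams partition_coefficient
#' @param hct hematocrit as a fraction in \[0, 1).
#' @return ECV in percent.
#' @export
ecv_percent <- function(t1_myo_pre, t1_myo_post, t1_blood_pre, t1_blood_post,
                        hct) {
  if (any(hct < 0 | hct >= 1, na.rm = TRUE)) stop("hct must be in [0, 1)")
  lambda <- partition_coefficient(t1_myo_pre, t1_myo_post,
                                  t1_blood_pre, t1_blood_post)
  100 * (1 - hct) * lambda
}

#' Exclude participants with prior MI or heart failure
#'
#' Removes participants whose fibrosis could be replacement scar from a prior
#' clinical event rather than interstitial fibrosis.
#'
#' @param participants phenotype data.frame with `mi_history`/`hf_history`.
#' @return list with `included` and `excluded` data.frames
#'   (`nrow(included) + nrow(excluded) == nrow(participants)`).
#' @export
apply_exclusions <- function(participants) {
  req <- c("mi_history", "hf_history")
  if (!all(req %in% names(participants))) {
    stop("phenotype table lacks mi_history/hf_history")
  }
  flags <- participants$mi_history | participants$hf_history
  if (anyNA(flags)) {
    stop("missing MI/HF history for participant(s): ",
         paste(participants$id[is.na(flags)], collapse = ", "))
  }
  list(
    included = participants[!flags, , drop = FALSE],
    excluded = participants[flags, , drop = FALSE]
  )
}

#' Quantile threshold for the case definition
#'
#' Returns the q-quantile of the non-missing values under the
#' linear-interpolation convention (R quantile type 7 by default).
#'
#' @param values numeric vector (missing values dropped).
#' @param q quantile in (0,1); 0.75 marks the top quartile.
#' @param type quantile algorithm passed to [stats::quantile()].
#' @return the threshold (numeric scalar).
#' @export
quartile_threshold <- function(values, q = 0.75, type = 7) {
  stopifnot(q > 0, q < 1)
  values <- values[!is.na(values)]
  if (length(values) < 4L) stop("need at least 4 non-missing values")
  unname(stats::quantile(values, probs = q, type = type))
}

#' Assign case/control status by the top-quartile union rule
#'
#' A participant is a case when ECV is strictly above the ECV threshold or
#' native T1 is strictly above the native-T1 threshold; thresholds default to
#' the top-quartile boundary of the supplied (post-exclusion) population but
#' may be given explicitly to reproduce a published split. When `ecv` is
#' missing it is derived from T1 values and hematocrit.
#'
#' @param participants post-exclusion phenotype data.frame with `ecv` and
#'   `native_t1` (ECV derivable from T1 columns + `hct` where missing).
#' @param q quantile defining "highest quartile" (default 0.75).
#' @param thresholds optional list/vector with `ecv` and `native_t1`
#'   thresholds overriding the empirical quantiles.
#' @param type quantile algorithm (see [quartile_threshold()]).
#' @return list of class `case_assignment`: `status` (data.frame id, ecv,
#'   native_t1, status, category), `definition` (thresholds and rule) and
#'   `decomposition` (counts: ecv_only, t1_only, both, cases, controls).
#' @export
assign_case_status <- function(participants, q = 0.75, thresholds = NULL,
                               type = 7) {
  ecv <- participants$ecv
  derivable <- is.na(ecv) &
    !is.na(participants$t1_myo_pre) & !is.na(participants$t1_myo_post) &
    !is.na(participants$t1_blood_pre) & !is.na(participants$t1_blood_post) &
    !is.na(participants$hct)
  if (any(derivable)) {
    ecv[derivable] <- ecv_percent(
      participants$t1_myo_pre[derivable], participants$t1_myo_post[derivable],
      participants$t1_blood_pre[derivable],
      participants$t1_blood_post[derivable], participants$hct[derivable]
    )
  }
  t1 <- participants$native_t1
  if (anyNA(ecv) || anyNA(t1)) {
    stop("missing ECV or native T1 for participant(s): ",
         paste(participants$id[is.na(ecv) | is.na(t1)], collapse = ", "))
  }
  if (is.null(thresholds)) {
    thr_ecv <- quartile_threshold(ecv, q = q, type = type)
    thr_t1 <- quartile_threshold(t1, q = q, type = type)
  } else {
    thr_ecv <- as.numeric(thresholds[["ecv"]])
    thr_t1 <- as.numeric(thresholds[["native_t1"]])
    stopifnot(is.finite(thr_ecv), is.finite(thr_t1))
  }
  high_ecv <- ecv > thr_ecv
  high_t1 <- t1 > thr_t1
  category <- rep("none", length(ecv))
  category[high_ecv & !high_t1] <- "ecv_only"
  category[!high_ecv & high_t1] <- "t1_only"
  category[high_ecv & high_t1] <- "both"
  status <- ifelse(high_ecv | high_t1, "case", "control")
  decomposition <- c(
    ecv_only = sum(category == "ecv_only"),
    t1_only = sum(category == "t1_only"),
    both = sum(category == "both"),
    cases = sum(status == "case"),
    controls = sum(status == "control")
  )
  structure(list(
    status = data.frame(
      id = participants$id, ecv = ecv, native_t1 = t1,
      status = status, category = category, stringsAsFactors = FALSE
    ),
    definition = list(
      ecv_threshold = thr_ecv, native_t1_threshold = thr_t1, q = q,
      rule = "case iff ecv > ecv_threshold OR native_t1 > native_t1_threshold",
      empirical = is.null(thresholds)
    ),
    decomposition = decomposition
  ), class = "case_assignment")
}

#' @export
print.case_assignment <- function(x, ...) {
  d <- x$decomposition
  cat(sprintf(
    "Case definition: ECV > %.4g%% or native T1 > %.6g ms\n",
    x$definition$ecv_threshold, x$definition$native_t1_threshold
  ))
  cat(sprintf(
    "  cases %d (ECV-only %d, T1-only %d, both %d); controls %d\n",
    d["cases"], d["ecv_only"], d["t1_only"], d["both"], d["controls"]
  ))
  invisible(x)
}
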