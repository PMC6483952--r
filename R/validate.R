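#' Generational train/validation split
#'
#' Orders animals by birth year (ascending; ties broken by animal id) and
#' assigns the oldest `floor(n * train_fraction)` to the training set and
#' the remaining youngest animals to the validation set. The default
#' fraction 0.875 reproduces the 7:1 generational layout used to train on
#' older proven bulls and validate on the youngest cohort.
#'
#' @param records data.frame with `animal_id` and `birth_year` columns
#'   (no missing birth years).
#' @param train_fraction Fraction in `(0, 1)`.
#' @return List with character vectors `train` and `validation`.
#' @export
generational_split <- function(records, train_fraction = 0.875) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)")
  }
  if (any(is.na(records$birth_year))) {
    stop("every animal needs a birth year")
  }
  ord <- order(records$birth_year, records$animal_id)
  ids <- records$animal_id[ord]
  n_train <- floor(nrow(records) * train_fraction)
  list(train = ids[seq_len(n_train)],
       validation = ids[seq(n_train + 1, length(ids))])
}

#' Pearson correlation between EBV and DGV
#'
#' Standard product-moment correlation; undefined (returned as `NA` with
#' a warning) when either vector is constant or fewer than 3 pairs exist.
#'
#' @param ebv,dgv Numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
pearson_r <- function(ebv, dgv) {
  if (length(ebv) != length(dgv)) stop("vectors must have equal length")
  if (length(ebv) < 3) {
    warning("fewer than 3 pairs; correlation undefined")
    return(NA_real_)
  }
  if (stats::sd(ebv) == 0 || stats::sd(dgv) == 0) {
    warning("constant vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(ebv, dgv)
}

#' Regression of EBV on DGV
#'
#' Simple least squares with EBV as the response and DGV as the
#' regressor: `slope = cov(ebv, dgv) / var(dgv)`,
#' `intercept = mean(ebv) - slope * mean(dgv)`. A slope above 1 signals
#' that the dispersion of the genomic predictions is underestimated
#' (over-shrunk DGVs).
#'
#' @param ebv,dgv Numeric vectors of equal length (>= 3, `var(dgv) > 0`).
#' @return Named vector `c(slope, intercept)` (`NA`s when undefined).
#' @export
regress_ebv_on_dgv <- function(ebv, dgv) {
  if (length(ebv) != length(dgv)) stop("vectors must have equal length")
  if (length(ebv) < 3 || stats::var(dgv) == 0) {
    warning("regression undefined (need >= 3 pairs and non-constant DGV)")
    return(c(slope = NA_real_, intercept = NA_real_))
  }
  slope <- stats::cov(ebv, dgv) / stats::var(dgv)
  c(slope = slope, intercept = mean(ebv) - slope * mean(dgv))
}

#' Score DGV against EBV on train and validation subsets
#'
#' @param records Proof records with `animal_id` and the comparison target
#'   column (`ebv` by default; `tbv` available in simulation studies when
#'   supplied).
#' @param dgv data.frame from [predict_dgv()].
#' @param split List from [generational_split()].
#' @param target Column of `records` to compare against (default
#'   `"ebv"`).
#' @return data.frame with one row per subset: `subset`, `n`,
#'   `pearson_r`, `slope`, `intercept`. Train-set statistics are
#'   in-sample.
#' @export
validation_report <- function(records, dgv, split, target = "ebv") {
  stopifnot(target %in% names(records))
  out <- lapply(c("train", "validation"), function(s) {
    ids <- split[[s]]
    e <- records[[target]][match(ids, records$animal_id)]
    d <- dgv$dgv[match(ids, dgv$animal_id)]
    r <- pearson_r(e, d)
    b <- regress_ebv_on_dgv(e, d)
    data.frame(subset = s, n = length(ids), pearson_r = r,
               slope = b[["slope"]], intercept = b[["intercept"]])
  })
  do.call(rbind, out)
}
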