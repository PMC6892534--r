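#' Dichotomise HbA1c into diabetes status
#'
#' Applies the diagnostic threshold for type-2 diabetes: values strictly above
#' the threshold are coded 1.  A value exactly at the threshold maps to 0.
#'
#' @param hba1c_values Numeric vector of HbA1c percentages.
#' @param threshold Diagnostic threshold (%); default 6.5.
#' @return Integer 0/1 vector.
#' @examples
#' dichotomize(c(5.8, 6.5, 6.51))
#' @export
dichotomize <- function(hba1c_values, threshold = 6.5) {
  stopifnot(is.numeric(hba1c_values), all(is.finite(hba1c_values)))
  as.integer(hba1c_values > threshold)
}

#' Simulate one cohort from a joint Gaussian
#'
#' Draws `n` i.i.d. individuals from the scenario's reduced-form multivariate
#' normal over (weight_0, weight_1, weight_2, hba1c) and derives diabetes
#' status by thresholding HbA1c at 6.5%.
#'
#' @param jg A `joint_gaussian` from [build_joint_gaussian()].
#' @param n Number of individuals (>= 2).
#' @param seed Integer seed; the draw is deterministic given `seed`.
#' @return A `data.frame` of class `cohort_data` with columns `id`,
#'   `weight_0`, `weight_1`, `weight_2`, `hba1c`, `diabetes`.
#' @examples
#' jg <- build_joint_gaussian(scenario_spec("A"))
#' head(simulate_cohort(jg, 100, seed = 1))
#' @export
simulate_cohort <- function(jg, n, seed) {
  stopifnot(inherits(jg, "joint_gaussian"), n >= 2,
            is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))
  X <- MASS::mvrnorm(n, mu = jg$mean, Sigma = jg$covariance)
  out <- data.frame(id = seq_len(n),
                    weight_0 = X[, "weight_0"],
                    weight_1 = X[, "weight_1"],
                    weight_2 = X[, "weight_2"],
                    hba1c = X[, "hba1c"])
  out$diabetes <- dichotomize(out$hba1c)
  class(out) <- c("cohort_data", "data.frame")
  out
}

#' Reshape a cohort to the long format consumed by the mixed models
#'
#' Produces three rows per individual with age centred (default at one year),
#' so `time_centered` takes the values -1, 0, 1.
#'
#' @param cohort A `cohort_data` frame.
#' @param center_age Age (years) at which to centre; default 1.
#' @param keep_outcome Include the repeated `diabetes` column (set `FALSE` to
#'   hand the data to an outcome-agnostic model).
#' @return A `data.frame` with columns `id`, `time_centered`, `weight` and,
#'   unless `keep_outcome = FALSE`, `diabetes`; sorted by id then time.
#' @export
to_long <- function(cohort, center_age = 1, keep_outcome = TRUE) {
  stopifnot(is.data.frame(cohort),
            all(c("id", "weight_0", "weight_1", "weight_2") %in% names(cohort)))
  n <- nrow(cohort)
  ages <- c(0, 1, 2)
  long <- data.frame(
    id = rep(cohort$id, each = 3L),
    time_centered = rep(ages - center_age, times = n),
    weight = as.vector(t(as.matrix(cohort[, c("weight_0", "weight_1",
                                              "weight_2")])))
  )
  if (keep_outcome) {
    stopifnot("diabetes" %in% names(cohort))
    long$diabetes <- rep(cohort$diabetes, each = 3L)
  }
  long
}

#' Reshape long-format weights back to wide
#'
#' Inverse of [to_long()]; the round trip is exact.
#'
#' @param long Long-format frame with `id`, `time_centered`, `weight` and
#'   optionally `diabetes`.
#' @param center_age Centring age used when the long frame was built.
#' @return A wide `data.frame` with one row per id.
#' @export
to_wide <- function(long, center_age = 1) {
  stopifnot(all(c("id", "time_centered", "weight") %in% names(long)))
  long <- long[order(long$id, long$time_centered), ]
  ids <- unique(long$id)
  W <- matrix(long$weight, ncol = 3L, byrow = TRUE)
  out <- data.frame(id = ids, weight_0 = W[, 1], weight_1 = W[, 2],
                    weight_2 = W[, 3])
  if ("diabetes" %in% names(long))
    out$diabetes <- long$diabetes[match(ids, long$id)]
  out
}

#' Write or read a cohort as CSV with fixed column names
#'
#' @param cohort A `cohort_data` frame.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a `cohort_data` frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path)
  stopifnot(all(c("id", "weight_0", "weight_1", "weight_2", "hba1c",
                  "diabetes") %in% names(out)))
  class(out) <- c("cohort_data", "data.frame")
  out
}
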