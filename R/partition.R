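#' Age partition for piecewise-constant transition intensities
#'
#' Defines the left-closed, right-open age intervals on which the transition
#' intensities of the natural-history model are constant. The first cutpoint
#' is the initiation age \code{t0} of the disease process: women are assumed
#' free of breast cancer before that age. The last interval is open-ended.
#'
#' @param cutpoints Strictly increasing, finite ages in years. The default
#'   \code{c(40, 50, 60)} gives the intervals \eqn{[40,50)}, \eqn{[50,60)} and
#'   \eqn{[60,\infty)}.
#' @return An object of class \code{age_partition} with elements
#'   \code{cutpoints}, \code{t0} and \code{n_intervals}.
#' @examples
#' age_partition()
#' age_partition(c(40, 55))
#' @export
age_partition <- function(cutpoints = c(40, 50, 60)) {
  if (!is.numeric(cutpoints) || length(cutpoints) < 1L)
    stop("`cutpoints` must be a non-empty numeric vector of ages")
  if (any(!is.finite(cutpoints)))
    stop("`cutpoints` must be finite; the last interval is open-ended implicitly")
  cutpoints <- as.numeric(cutpoints)
  if (is.unsorted(cutpoints, strictly = TRUE))
    stop("`cutpoints` must be strictly increasing")
  structure(
    list(cutpoints = cutpoints, t0 = cutpoints[1L],
         n_intervals = length(cutpoints)),
    class = "age_partition"
  )
}

#' @export
print.age_partition <- function(x, ...) {
  cat("Age partition (", x$n_intervals, " intervals, t0 = ", x$t0, "):\n  ",
      paste(interval_labels(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Interval labels of an age partition
#'
#' @param partition An [age_partition].
#' @return Character vector like \code{"[40,50)"}.
#' @export
interval_labels <- function(partition) {
  stopifnot(inherits(partition, "age_partition"))
  hi <- c(partition$cutpoints[-1L], Inf)
  sprintf("[%s,%s)", format(partition$cutpoints, trim = TRUE),
          ifelse(is.finite(hi), format(hi, trim = TRUE), "Inf"))
}

#' Index of the age interval containing an age
#' @param partition An [age_partition].
#' @param age Ages in years (vectorised); must be at or above \code{t0}.
#' @return Integer interval indices.
#' @export
interval_index <- function(partition, age) {
  stopifnot(inherits(partition, "age_partition"))
  if (any(age < partition$t0))
    stop("age below the initiation age t0 = ", partition$t0)
  findInterval(age, partition$cutpoints)
}

#' Natural-history model parameters
#'
#' Bundles the transition intensities of the four-state model: the onset rate
#' \code{lambda12} (free of cancer to progressive preclinical phase, per
#' woman-year), the progression rate \code{lambda23} (preclinical to clinical
#' phase), the dimensionless ratio \code{r} of the non-progressive onset rate
#' \code{lambda14} to \code{lambda12} (a single scalar shared by all age
#' intervals), and the test sensitivity \code{S}. \code{lambda12} and
#' \code{lambda23} are one value per age interval; scalars are recycled when
#' used with a partition.
#'
#' @param lambda12 Onset rate(s) per woman-year, one per age interval.
#' @param lambda23 Progression rate(s) per woman-year, one per age interval.
#' @param r Ratio lambda14 / lambda12, a single non-negative scalar.
#' @param S Test sensitivity, a probability.
#' @return An object of class \code{model_parameters}.
#' @examples
#' # Non-homogeneous estimates of the kind the model produces
#' model_parameters(lambda12 = c(0.0015, 0.00276, 0.00381),
#'                  lambda23 = c(0.385, 0.464, 0.284),
#'                  r = 0.00182, S = 0.880)
#' @export
model_parameters <- function(lambda12, lambda23, r = 0, S = 1) {
  if (!is.numeric(lambda12) || any(!is.finite(lambda12)) || any(lambda12 < 0))
    stop("`lambda12` must be finite and non-negative")
  if (!is.numeric(lambda23) || any(!is.finite(lambda23)) || any(lambda23 < 0))
    stop("`lambda23` must be finite and non-negative")
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r < 0)
    stop("`r` must be a single non-negative number")
  if (!is.numeric(S) || length(S) != 1L || !is.finite(S) || S < 0 || S > 1)
    stop("`S` must be a probability in [0, 1]")
  structure(
    list(lambda12 = as.numeric(lambda12), lambda23 = as.numeric(lambda23),
         r = as.numeric(r), S = as.numeric(S)),
    class = "model_parameters"
  )
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Four-state natural-history parameters\n")
  cat("  lambda12:", paste(signif(x$lambda12, 5), collapse = ", "), "\n")
  cat("  lambda23:", paste(signif(x$lambda23, 5), collapse = ", "), "\n")
  cat("  r (lambda14/lambda12):", signif(x$r, 5),
      "   S (sensitivity):", signif(x$S, 5), "\n")
  invisible(x)
}

# Internal: validate and align parameters with a partition, returning the flat
# list the numerical kernels use.
.par_engine <- function(params, partition) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(partition, "age_partition"))
  L <- partition$n_intervals
  l12 <- params$lambda12
  l23 <- params$lambda23
  if (length(l12) == 1L) l12 <- rep(l12, L)
  if (length(l23) == 1L) l23 <- rep(l23, L)
  if (length(l12) != L || length(l23) != L)
    stop("parameter vectors must have one entry per age interval (", L, ")")
  list(l12 = l12, l23 = l23, r = params$r, S = params$S,
       cuts = partition$cutpoints, t0 = partition$t0)
}
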