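# Random model populations: uniform parameter sampling, evaluation against
# the measurement bounds, and pairwise parameter correlations.

#' Sample a random model population
#'
#' Draws each of the 48 parameters independently and uniformly from its
#' published sampling range; reproducible from the seed.
#'
#' @param n Number of models (>= 1).
#' @param seed Integer seed.
#' @param ranges Parameter table (defaults to [parameter_table()]); ranges with
#'   `lower >= upper` raise an error naming the parameter.
#' @return Data.frame of `n` rows by 48 parameter columns (published units),
#'   with a `model_id` column first.
#' @export
sample_population <- function(n, seed = 1L, ranges = parameter_table()) {
  if (n < 1) stop("n must be at least 1")
  bad <- ranges$lower >= ranges$upper
  if (any(bad)) {
    stop("malformed sampling range for parameter(s): ",
         paste(ranges$name[bad], collapse = ", "))
  }
  set.seed(seed)
  draws <- vapply(seq_len(nrow(ranges)),
                  function(i) stats::runif(n, ranges$lower[i], ranges$upper[i]),
                  numeric(n))
  draws <- matrix(draws, nrow = n)
  colnames(draws) <- ranges$name
  cbind(data.frame(model_id = seq_len(n)), as.data.frame(draws))
}

#' Evaluate and validate a model population
#'
#' Computes the seven intrinsic measurements for every parameter set and flags
#' the models whose measurements all fall inside the experimental bounds.
#' Per-model integration failures mark that model invalid and the run
#' continues.
#'
#' @param population Data.frame from [sample_population()] (or any data.frame
#'   with the 48 parameter columns).
#' @param bounds Validation bounds.
#' @param dt Integration step, ms.
#' @param early_exit Short-circuit the probe sequence once a model is certainly
#'   invalid (cheaper; measurement entries after the failing stage are `NA`).
#' @return List with `parameters` (the input), `measurements` (one row per
#'   model: the seven measurements plus `valid`), and `n_valid`.
#' @export
evaluate_population <- function(population, bounds = validation_bounds(),
                                dt = 0.025, early_exit = TRUE) {
  pnames <- parameter_table()$name
  stopifnot(all(pnames %in% names(population)))
  rows <- lapply(seq_len(nrow(population)), function(i) {
    pars <- as.list(population[i, pnames])
    m <- tryCatch(
      measure_all(build_model(pars, warn_range = FALSE), dt = dt,
                  bounds = bounds, early_exit = early_exit),
      error = function(e) {
        data.frame(f250 = NA_real_, v_ap = NA_real_, r_in = NA_real_,
                   z_max = NA_real_, f_r = NA_real_, q = NA_real_,
                   phi_l = NA_real_, valid = FALSE)
      })
    m$model_id <- population$model_id[i] %||% i
    m
  })
  meas <- do.call(rbind, rows)
  meas <- meas[, c("model_id", setdiff(names(meas), "model_id"))]
  list(parameters = population, measurements = meas,
       n_valid = sum(meas$valid))
}

#' Pairwise correlations among the 48 parameters
#'
#' Correlation coefficient for every unordered pair of parameters across a set
#' of (typically valid) models: 48 parameters give choose(48, 2) = 1128
#' coefficients.
#'
#' @param parameters Data.frame with the 48 parameter columns (rows = models,
#'   at least 3).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `matrix` (48 x 48 symmetric, unit diagonal) and `pairs`
#'   (data.frame: `param1`, `param2`, `r` for each of the 1128 unordered
#'   pairs; a constant parameter column yields `NA` coefficients).
#' @export
pairwise_correlations <- function(parameters, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  pnames <- parameter_table()$name
  stopifnot(all(pnames %in% names(parameters)))
  x <- as.matrix(parameters[, pnames])
  if (nrow(x) < 3) stop("at least 3 models are required for correlations")
  constant <- apply(x, 2, function(col) stats::sd(col) == 0)
  cm <- suppressWarnings(stats::cor(x, method = method))
  diag(cm) <- 1
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- data.frame(param1 = pnames[idx[, 1]], param2 = pnames[idx[, 2]],
                      r = cm[idx], stringsAsFactors = FALSE)
  if (any(constant)) {
    pairs$r[pairs$param1 %in% pnames[constant] |
              pairs$param2 %in% pnames[constant]] <- NA_real_
  }
  list(matrix = cm, pairs = pairs)
}
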