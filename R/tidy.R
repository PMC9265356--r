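#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted Markov transition matrix
#'
#' @param x a `markov_fit`.
#' @param ... unused.
#' @return Tibble with `from`, `to`, `n_cells`, `probability`.
#' @method tidy markov_fit
#' @export
tidy.markov_fit <- function(x, ...) {
  cls <- rownames(x$P)
  tidyr::expand_grid(from = cls, to = cls) |>
    dplyr::mutate(n_cells = as.vector(t(x$counts)),
                  probability = as.vector(t(x$P)))
}

#' @rdname tidy.markov_fit
#' @method glance markov_fit
#' @export
glance.markov_fit <- function(x, ...) {
  tibble::tibble(n_classes = nrow(x$P), n_cells = sum(x$counts),
                 interval = x$interval,
                 stay_fraction = sum(diag(x$counts)) / sum(x$counts))
}

#' Tidy a suitability model
#'
#' @param x a `suitability_model`.
#' @param ... unused.
#' @return Tibble of per-class mean suitability probability.
#' @method tidy suitability_model
#' @export
tidy.suitability_model <- function(x, ...) {
  mp <- colMeans(x$prob, na.rm = TRUE)
  tibble::tibble(class = names(mp), mean_probability = unname(mp))
}

#' @rdname tidy.suitability_model
#' @method glance suitability_model
#' @export
glance.suitability_model <- function(x, ...) {
  tibble::tibble(hidden = x$hidden, sample_n = x$sample_n,
                 train_accuracy = x$train_accuracy, seed = x$seed)
}

#' Tidy a cellular-automaton run
#'
#' @param x a `ca_run`.
#' @param ... unused.
#' @return The per-iteration per-class log tibble (`iteration`, `class`,
#'   `gap`, `inertia`, `conversions`).
#' @method tidy ca_run
#' @export
tidy.ca_run <- function(x, ...) x$log

#' @rdname tidy.ca_run
#' @method glance ca_run
#' @export
glance.ca_run <- function(x, ...) {
  tibble::tibble(iterations = x$iterations, converged = x$converged,
                 max_abs_residual = max(abs(x$residual)),
                 total_conversions = if (nrow(x$log)) sum(x$log$conversions)
                                     else 0L)
}

#' Tidy a conflict assessment
#'
#' @param x a `conflict_result`.
#' @param ... unused.
#' @return The per-unit tibble.
#' @method tidy conflict_result
#' @export
tidy.conflict_result <- function(x, ...) x$units

#' @rdname tidy.conflict_result
#' @method glance conflict_result
#' @export
glance.conflict_result <- function(x, ...) {
  tibble::tibble(n_units = x$partition$n_units,
                 n_dates = length(unique(x$units$date)),
                 unit_size = x$unit_size, connectivity = x$connectivity,
                 pool = x$pool,
                 mean_scci = mean(x$units$scci_norm))
}
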