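#' Fit a Markov transition matrix from two dated rasters
#'
#' `P[a, b]` is the fraction of date-1 class-`a` cells that are class `b`
#' at date 2. Rows of classes absent at date 1 are set to the identity row
#' (with a message). Cells that are nodata at either date are excluded.
#'
#' @param lu_t1,lu_t2 categorical [land_raster()]s with equal geometry.
#' @param interval calibration interval in years (metadata).
#' @return A `markov_fit`: list with `P` (row-stochastic matrix), `counts`
#'   (transition count matrix), `S_t1`, `S_t2` (class cell counts),
#'   `interval`.
#' @export
fit_markov <- function(lu_t1, lu_t2, interval = NA_real_) {
  check_same_geometry(lu_t1, lu_t2)
  classes <- lu_t1$classes
  keep <- lu_t1$values != lu_t1$nodata & lu_t2$values != lu_t2$nodata &
    !is.na(lu_t1$values) & !is.na(lu_t2$values)
  a <- factor(lu_t1$values[keep], levels = unname(classes))
  b <- factor(lu_t2$values[keep], levels = unname(classes))
  counts <- table(a, b)
  counts <- matrix(as.integer(counts), nrow(counts),
                   dimnames = list(names(classes), names(classes)))
  rs <- rowSums(counts)
  P <- counts / ifelse(rs == 0, 1, rs)
  if (any(rs == 0)) {
    message("class(es) ", paste(names(classes)[rs == 0], collapse = ", "),
            " absent at date 1; identity rows used")
    for (i in which(rs == 0)) P[i, i] <- 1
  }
  structure(list(P = P, counts = counts,
                 S_t1 = rowSums(counts), S_t2 = colSums(counts),
                 interval = interval),
            class = "markov_fit")
}

#' @export
print.markov_fit <- function(x, ...) {
  cat(sprintf("<markov_fit> %d classes, %s-year interval, %d cells\n",
              nrow(x$P), format(x$interval), sum(x$counts)))
  print(round(x$P, 4))
  invisible(x)
}

#' Project class demand with the Markov chain
#'
#' `S(t+m) = (P')^m S(t)`: one step per calibration interval. The horizon
#' must be a positive multiple of the interval; otherwise re-calibrate the
#' matrix on a matching interval or pass the nearest multiple explicitly.
#' Total demand is conserved exactly.
#'
#' @param P row-stochastic transition matrix (or a `markov_fit`).
#' @param S_base class state vector at the base date (cells or km2).
#' @param steps number of interval steps `m` (default 1).
#' @param horizon,interval alternative to `steps`: project `horizon` years
#'   with a matrix calibrated over `interval` years.
#' @return Numeric vector: projected class quantities (same units as
#'   `S_base`).
#' @examples
#' P <- rbind(c(0.9, 0.1), c(0, 1))
#' project_demand(P, c(100, 0), steps = 2)  # (81, 19)
#' @export
project_demand <- function(P, S_base, steps = 1, horizon = NULL,
                           interval = NULL) {
  if (inherits(P, "markov_fit")) {
    interval <- interval %||% P$interval
    P <- P$P
  }
  check_row_stochastic(P)
  if (!is.null(horizon)) {
    if (is.null(interval) || is.na(interval)) {
      stop("`horizon` needs a calibration `interval`", call. = FALSE)
    }
    if (horizon <= 0 || horizon %% interval != 0) {
      stop(sprintf(paste("horizon %s is not a positive multiple of the",
                         "calibration interval %s; re-calibrate the matrix",
                         "or accept the nearest multiple"),
                   horizon, interval), call. = FALSE)
    }
    steps <- horizon / interval
  }
  S <- as.numeric(S_base)
  for (i in seq_len(steps)) S <- drop(t(P) %*% S)
  stats::setNames(S, rownames(P))
}

#' Convert a demand vector to integer cell counts
#'
#' Largest-remainder rounding so the cell total is conserved exactly.
#'
#' @param demand demand per class (km2 or cells, any non-negative scale).
#' @param total_cells number of data cells the demand must sum to.
#' @return Integer vector summing to `total_cells`.
#' @export
demand_to_cells <- function(demand, total_cells) {
  if (any(demand < 0)) stop("negative demand", call. = FALSE)
  stats::setNames(
    largest_remainder(demand / sum(demand) * total_cells, total_cells),
    names(demand))
}

#' Train the neural-network suitability model
#'
#' Single-hidden-layer feed-forward classifier (logistic hidden units,
#' softmax output) trained on uniformly sampled cells: inputs are the
#' standardized driver values, target the observed class. If a class
#' present on the raster is missing from the uniform sample, the sample is
#' re-drawn with stratification (every present class guaranteed). Predicted
#' probabilities are renormalized so each cell's class probabilities sum
#' to 1.
#'
#' @param lu categorical [land_raster()].
#' @param drivers a `driver_stack` of standardized driver rasters.
#' @param sample_frac fraction of data cells sampled for training
#'   (default 0.08, within the usual 5-10% sampling convention).
#' @param hidden hidden-layer size (default 12).
#' @param seed integer seed (sampling and weight initialization).
#' @param maxit optimizer iterations.
#' @return A `suitability_model`: list with `prob` (cells x 6 matrix of
#'   suitability probabilities, rows summing to 1), `fit` (the nnet
#'   object), `sample_idx`, `train_accuracy`.
#' @export
train_suitability <- function(lu, drivers, sample_frac = 0.08, hidden = 12,
                              seed = 1L, maxit = 200) {
  stopifnot(is_land_raster(lu))
  v <- as.vector(lu$values)
  data_idx <- which(v != lu$nodata & !is.na(v))
  n_s <- max(hidden * 6L, round(sample_frac * length(data_idx)))
  if (n_s > length(data_idx)) stop("sample larger than cell count", call. = FALSE)
  set.seed(seed)
  idx <- sample(data_idx, n_s)
  present <- sort(unique(v[data_idx]))
  if (!all(present %in% v[idx])) {
    # stratified redraw: proportional, but at least 2 cells per class
    idx <- unlist(lapply(present, function(k) {
      cells_k <- data_idx[v[data_idx] == k]
      nk <- max(2L, min(length(cells_k), round(n_s * length(cells_k) / length(data_idx))))
      sample(cells_k, nk)
    }))
  }
  X <- vapply(drivers, as.vector, numeric(length(v)))
  y <- factor(v[idx], levels = present)
  fit <- nnet::nnet(X[idx, , drop = FALSE], nnet::class.ind(y),
                    size = hidden, softmax = TRUE, maxit = maxit,
                    trace = FALSE)
  pr <- stats::predict(fit, X[data_idx, , drop = FALSE])
  prob <- matrix(0, length(data_idx), 6,
                 dimnames = list(NULL, names(lu_classes())))
  prob[, as.integer(colnames(pr))] <- pr
  prob <- prob / rowSums(prob)
  full <- matrix(NA_real_, length(v), 6,
                 dimnames = list(NULL, names(lu_classes())))
  full[data_idx, ] <- prob
  pred_cls <- present[max.col(pr, ties.method = "first")]
  structure(list(prob = full, fit = fit, sample_idx = idx,
                 train_accuracy = mean(present[max.col(
                   pr[match(idx, data_idx), , drop = FALSE],
                   ties.method = "first")] == v[idx]),
                 hidden = hidden, sample_n = length(idx), seed = seed),
            class = "suitability_model")
}

#' @export
print.suitability_model <- function(x, ...) {
  cat(sprintf("<suitability_model> %d hidden units, %d training cells, train accuracy %.3f\n",
              x$hidden, x$sample_n, x$train_accuracy))
  invisible(x)
}

#' Neighborhood effect of a class
#'
#' Share of class-`k` cells in the N x N Moore window around each cell
#' (center excluded), divided by `N^2 - 1` and multiplied by the class
#' neighborhood weight. Edge cells use the truncated window with the
#' denominator unchanged.
#'
#' @param lu categorical [land_raster()] (or plain matrix).
#' @param k class code.
#' @param N odd window edge >= 3.
#' @param weight neighborhood weight of class `k` in `[0, 1]`.
#' @return Numeric matrix of the same shape.
#' @export
neighborhood_effect <- function(lu, k, N = 3, weight = 1) {
  if (N %% 2 == 0 || N < 3) stop("window `N` must be odd and >= 3", call. = FALSE)
  m <- if (is_land_raster(lu)) lu$values else lu
  ind <- (m == k) * 1
  half <- (N - 1) / 2
  nr <- nrow(ind); nc <- ncol(ind)
  pad <- matrix(0, nr + 2 * half, nc + 2 * half)
  pad[half + seq_len(nr), half + seq_len(nc)] <- ind
  acc <- matrix(0, nr, nc)
  for (dr in -half:half) for (dc in -half:half) {
    if (dr == 0 && dc == 0) next
    acc <- acc + pad[half + dr + seq_len(nr), half + dc + seq_len(nc)]
  }
  acc / (N^2 - 1) * weight
}

#' Adaptive inertia update
#'
#' Per-class multiplier steering the cellular automaton toward demand. With
#' `D` the demand-minus-count gap, the coefficient is unchanged when
#' `D(t-2) <= D(t-1)`; multiplied by `D(t-2)/D(t-1)` when
#' `0 > D(t-2) > D(t-1)` (overshoot worsening); and multiplied by
#' `D(t-1)/D(t-2)` when `D(t-1) > D(t-2) > 0` (shortfall worsening). The
#' `"absolute"` convention compares absolute gaps instead (unchanged when
#' `|D(t-1)| <= |D(t-2)|`, otherwise the same ratios). A zero denominator
#' gap is treated as converged for that class (unchanged).
#'
#' @param inertia current per-class coefficients (> 0).
#' @param D_prev1 gap at t-1 (demand - count), per class.
#' @param D_prev2 gap at t-2, per class.
#' @param convention `"printed"` (default) or `"absolute"`.
#' @return Updated inertia vector.
#' @export
update_inertia <- function(inertia, D_prev1, D_prev2,
                           convention = c("printed", "absolute")) {
  convention <- match.arg(convention)
  out <- inertia
  for (k in seq_along(inertia)) {
    d1 <- D_prev1[k]; d2 <- D_prev2[k]
    if (d1 == 0 || d2 == 0) next
    adjust <-
      if (convention == "printed") {
        if (0 > d2 && d2 > d1) d2 / d1
        else if (d1 > d2 && d2 > 0) d1 / d2
        else 1
      } else {
        if (abs(d1) <= abs(d2)) 1
        else if (d1 < 0) d2 / d1
        else d1 / d2
      }
    out[k] <- inertia[k] * adjust
  }
  out
}

#' Cellular-automaton land-use allocation
#'
#' Allocates a demand vector onto the landscape. Per iteration, each cell's
#' conversion probability to class k is
#' `TProb = sp[p,k] * Omega[p,k] * Inertia[k] * M[c(p),k]` with `sp` the
#' neural-network suitability, `Omega` the Moore-neighborhood effect, the
#' adaptive inertia of [update_inertia()], and `M` the 0/1 conversion
#' allowance matrix (the `1 - cost` factor). Cells are visited in
#' descending order of their best achievable `TProb` (ties broken at
#' random, seeded); a cell converts to its best class only while that class
#' is under demand and its current class over demand. Restricted cells and
#' disallowed transitions never convert. Iteration stops when every class
#' count is within `max(tol_frac * demand, tol_cells)` of demand, or at
#' `max_iter`, or when no further conversion is possible (the unmet
#' residual per class is then reported).
#'
#' @param lu starting categorical [land_raster()].
#' @param suitability a `suitability_model` (or a cells x 6 probability
#'   matrix).
#' @param demand_cells integer demand per class, summing to the data cell
#'   count (see [demand_to_cells()]).
#' @param allowance 6 x 6 0/1 matrix, `allowance[c, k] = 1` if c -> k is
#'   allowed (diagonal 1).
#' @param weights per-class neighborhood weights in `[0, 1]`.
#' @param restriction optional logical matrix; `TRUE` cells never change.
#' @param N Moore window edge (odd, default 3).
#' @param max_iter iteration cap (default 300).
#' @param tol_frac,tol_cells convergence tolerance: per class
#'   `|count - demand| <= max(tol_frac * demand, tol_cells)`.
#' @param seed seed for tie-breaking.
#' @param inertia_convention passed to [update_inertia()].
#' @return A `ca_run`: list with `raster` (final [land_raster()]),
#'   `log` (per-iteration per-class tibble: gap, inertia, conversions),
#'   `converged`, `iterations`, `residual` (final demand - count).
#' @export
allocate_landuse <- function(lu, suitability, demand_cells,
                             allowance = matrix(1, 6, 6),
                             weights = rep(1, 6), restriction = NULL,
                             N = 3, max_iter = 300, tol_frac = 0.005,
                             tol_cells = 10, seed = 1L,
                             inertia_convention = "printed") {
  stopifnot(is_land_raster(lu))
  sp <- if (inherits(suitability, "suitability_model")) suitability$prob
        else suitability
  v <- as.vector(lu$values)
  data_idx <- which(v != lu$nodata & !is.na(v))
  if (sum(demand_cells) != length(data_idx)) {
    stop("demand must sum to the data cell count", call. = FALSE)
  }
  if (any(diag(allowance) != 1)) stop("allowance diagonal must be 1", call. = FALSE)
  restr <- if (is.null(restriction)) rep(FALSE, length(v))
           else as.vector(restriction)
  set.seed(seed)
  K <- 6L
  cur <- v
  inertia <- rep(1, K)
  D_hist <- list()
  log_rows <- vector("list", max_iter)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    counts <- tabulate(cur[data_idx], nbins = K)
    D <- demand_cells - counts
    tol <- pmax(tol_frac * demand_cells, tol_cells)
    if (all(abs(D) <= tol)) { converged <- TRUE; break }
    if (it >= 3) {
      inertia <- update_inertia(inertia, D_hist[[length(D_hist)]],
                                D_hist[[length(D_hist) - 1]],
                                inertia_convention)
    }
    cur_m <- matrix(cur, nrow(lu$values), ncol(lu$values))
    tp <- matrix(0, length(v), K)
    under <- which(D > 0)
    for (k in under) {
      om <- neighborhood_effect(cur_m, k, N, weights[k])
      tp[, k] <- sp[, k] * as.vector(om) * inertia[k] *
        allowance[cbind(cur, rep(k, length(cur)))]
    }
    over_src <- which(D < 0)
    cand <- data_idx[cur[data_idx] %in% over_src & !restr[data_idx]]
    if (!length(cand) || !length(under)) break
    tp_c <- tp[cand, under, drop = FALSE]
    best_k <- under[max.col(tp_c, ties.method = "random")]
    best_p <- tp_c[cbind(seq_along(cand), match(best_k, under))]
    ok <- best_p > 0
    cand <- cand[ok]; best_k <- best_k[ok]; best_p <- best_p[ok]
    if (!length(cand)) break
    ord <- order(best_p, stats::runif(length(best_p)), decreasing = TRUE)
    conv_n <- integer(K)
    Dw <- D
    for (i in ord) {
      p <- cand[i]; k <- best_k[i]; src <- cur[p]
      if (Dw[src] < 0 && Dw[k] > 0) {
        cur[p] <- k
        Dw[src] <- Dw[src] + 1L
        Dw[k] <- Dw[k] - 1L
        conv_n[k] <- conv_n[k] + 1L
      }
    }
    log_rows[[it]] <- tibble::tibble(
      iteration = it, class = names(lu_classes()), gap = D,
      inertia = inertia, conversions = conv_n)
    D_hist[[length(D_hist) + 1]] <- D
    if (sum(conv_n) == 0) break
  }
  counts <- tabulate(cur[data_idx], nbins = K)
  residual <- stats::setNames(demand_cells - counts, names(lu_classes()))
  if (!converged && all(abs(residual) <= pmax(tol_frac * demand_cells, tol_cells))) {
    converged <- TRUE
  }
  if (!converged) {
    warning("allocation stopped with unmet residual: ",
            paste(sprintf("%s=%d", names(residual), residual), collapse = ", "),
            call. = FALSE)
  }
  structure(list(
    raster = land_raster(matrix(cur, nrow(lu$values), ncol(lu$values)),
                         cell_size = lu$cell_size, nodata = lu$nodata,
                         classes = lu$classes),
    log = dplyr::bind_rows(log_rows[!vapply(log_rows, is.null, logical(1))]),
    converged = converged, iterations = it, residual = residual),
    class = "ca_run")
}

#' @export
print.ca_run <- function(x, ...) {
  cat(sprintf("<ca_run> %d iterations, %s; max |residual| = %d cells\n",
              x$iterations, if (x$converged) "converged" else "NOT converged",
              max(abs(x$residual))))
  invisible(x)
}

#' Cohen's kappa between two categorical rasters
#'
#' Chance-corrected cell-by-cell agreement from the K x K confusion matrix:
#' `(po - pe) / (1 - pe)`. Equals 1 iff the rasters are identical (on data
#' cells) and is symmetric in its arguments.
#'
#' @param actual,simulated categorical [land_raster()]s of equal geometry.
#' @return Kappa in `[-1, 1]`.
#' @export
kappa_coefficient <- function(actual, simulated) {
  check_same_geometry(actual, simulated)
  keep <- actual$values != actual$nodata & simulated$values != simulated$nodata
  a <- actual$values[keep]; b <- simulated$values[keep]
  lev <- sort(unique(c(a, b)))
  cm <- table(factor(a, lev), factor(b, lev))
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}
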