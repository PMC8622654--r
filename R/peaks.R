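#' Build a conductance histogram
#'
#' Bins per-event single-channel conductances on a regular grid. The grid is
#' anchored one bin below the smallest sample so every event is counted.
#' Amplitude analysis is usually based on 500-1000 events; fewer events give
#' noisy peak fits and trigger a warning.
#'
#' @param samples_pS Conductance samples in pS (>= 1 value).
#' @param bin_width_pS Bin width in pS; default 0.5.
#' @return A `conductance_histogram`: list with `bin_edges_pS`, `counts`,
#'   `n_events`.
#' @export
build_conductance_histogram <- function(samples_pS, bin_width_pS = 0.5) {
  if (!length(samples_pS)) stop("no conductance samples supplied")
  stopifnot(bin_width_pS > 0, all(is.finite(samples_pS)))
  if (length(samples_pS) < 500 || length(samples_pS) > 1000)
    warning(sprintf("event count %d outside the recommended 500-1000 range",
                    length(samples_pS)), call. = FALSE)
  lo <- floor(min(samples_pS) / bin_width_pS) * bin_width_pS - bin_width_pS
  hi <- ceiling(max(samples_pS) / bin_width_pS) * bin_width_pS + bin_width_pS
  edges <- seq(lo, hi, by = bin_width_pS)
  if (utils::tail(edges, 1) < hi) edges <- c(edges, utils::tail(edges, 1) + bin_width_pS)
  counts <- graphics::hist(samples_pS, breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  structure(list(bin_edges_pS = edges, counts = as.integer(counts),
                 n_events = length(samples_pS)),
            class = "conductance_histogram")
}

#' @export
print.conductance_histogram <- function(x, ...) {
  occ <- which(x$counts > 0)
  cat(sprintf("Conductance histogram: %d events in %d bins of %.3g pS, occupied %.3g-%.3g pS\n",
              x$n_events, length(x$counts),
              diff(x$bin_edges_pS[1:2]),
              x$bin_edges_pS[min(occ)], x$bin_edges_pS[max(occ) + 1L]))
  invisible(x)
}

# per-bin probabilities of a normal mixture; optionally conditioned on the
# histogram range (renormalized). The fit uses raw probabilities: with
# renormalization a component pushed far outside the range degenerates into
# a near-geometric tail over the bins and can swallow outlier bins.
.mixture_bin_probs <- function(edges, means, sds, weights, renormalize = FALSE) {
  p <- numeric(length(edges) - 1L)
  for (j in seq_along(means))
    p <- p + weights[j] * diff(stats::pnorm(edges, means[j], sds[j]))
  if (renormalize) {
    tot <- sum(p)
    if (tot <= 0) return(rep(NA_real_, length(p)))
    p <- p / tot
  }
  p
}

# pack/unpack: (means, log sds, logit-ish weights via softmax on k-1 params)
.unpack_mix <- function(par, k) {
  means <- par[seq_len(k)]
  sds <- exp(par[k + seq_len(k)])
  if (k == 1L) w <- 1 else {
    z <- c(par[2 * k + seq_len(k - 1L)], 0)
    w <- exp(z - max(z)); w <- w / sum(w)
  }
  list(means = means, sds = sds, weights = w)
}

#' Fit normal peaks to a conductance histogram
#'
#' Maximum-likelihood fit of a normal mixture to the binned event counts
#' (multinomial likelihood over bins, bin probabilities from the normal
#' CDF), so the fit respects the binning rather than the raw samples.
#' Initial means come from the local maxima of the histogram; three
#' deterministic jittered restarts are attempted on poor convergence.
#' A chi-square goodness-of-fit test against the fitted mixture is attached
#' (see [chi_square_gof()]).
#'
#' @param hist A `conductance_histogram`.
#' @param n_peaks Number of normal components (>= 1).
#' @return A `peak_fits` object: list of per-peak `peak_fit`s (fields
#'   `mean_pS`, `sd_pS`, `weight`), sorted by mean, with the chi-square
#'   summary (`chi2`, `dof`, `p_value`, `reject`) as attributes.
#' @export
fit_normal_peaks <- function(hist, n_peaks = 1L) {
  stopifnot(inherits(hist, "conductance_histogram"), n_peaks >= 1L)
  edges <- hist$bin_edges_pS
  counts <- hist$counts
  mids <- (utils::head(edges, -1) + utils::tail(edges, -1)) / 2
  occupied <- which(counts > 0)
  if (length(occupied) < 2L)
    stop("degenerate histogram: all events fall in a single bin; use a smaller bin width")
  if (hist$n_events < 50 * n_peaks)
    stop("need at least 50 events per requested peak")

  # moment estimates from the binned data
  w_mean <- sum(mids * counts) / hist$n_events
  w_sd <- sqrt(max(sum((mids - w_mean)^2 * counts) / hist$n_events,
                   (diff(edges[1:2]) / 4)^2))

  # initial means at the n_peaks highest local maxima (fallback: quantile grid)
  is_max <- which(diff(sign(diff(c(-Inf, counts, -Inf)))) == -2)
  is_max <- is_max[order(counts[is_max], decreasing = TRUE)]
  init_means <- mids[utils::head(is_max, n_peaks)]
  if (length(init_means) < n_peaks)
    init_means <- c(init_means,
                    w_mean + w_sd * seq(-1, 1, length.out = n_peaks - length(init_means)))
  init_sds <- rep(max(w_sd / n_peaks, diff(edges[1:2]) / 4), n_peaks)

  nll <- function(par) {
    m <- .unpack_mix(par, n_peaks)
    if (any(m$sds <= 0) || any(!is.finite(m$means))) return(1e10)
    p <- .mixture_bin_probs(edges, m$means, m$sds, m$weights)
    if (any(!is.finite(p))) return(1e10)
    pc <- p[counts > 0]
    if (any(pc <= 1e-300)) return(1e10)
    -sum(counts[counts > 0] * log(pc))
  }

  make_par <- function(jit) {
    c(init_means + jit * init_sds, log(init_sds * (1 + abs(jit))),
      if (n_peaks > 1) rep(0, n_peaks - 1L))
  }
  best <- NULL
  for (jit in c(0, -0.5, 0.5, 1)) {   # deterministic restarts
    fit <- tryCatch(
      stats::optim(make_par(jit), nll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      fit <- tryCatch(
        stats::optim(fit$par, nll, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-14)),
        error = function(e) fit)
    }
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || best$value >= 1e10)
    stop("normal-mixture fit failed to converge; diagnostics: ",
         "n_bins = ", length(counts), ", n_events = ", hist$n_events)

  m <- .unpack_mix(best$par, n_peaks)
  ord <- order(m$means)
  peaks <- lapply(ord, function(j) {
    structure(list(mean_pS = m$means[j], sd_pS = m$sds[j], weight = m$weights[j]),
              class = "peak_fit")
  })
  gof <- tryCatch(
    chi_square_gof(hist, list(means = m$means[ord], sds = m$sds[ord],
                              weights = m$weights[ord])),
    error = function(e) {   # too few pooled bins: fit stands, test unavailable
      warning(conditionMessage(e), call. = FALSE)
      list(chi2 = NA_real_, dof = NA_integer_, p_value = NA_real_, reject = NA)
    })
  structure(peaks, class = "peak_fits",
            chi2 = gof$chi2, dof = gof$dof, p_value = gof$p_value,
            reject = gof$reject, logLik = -best$value)
}

#' @export
print.peak_fits <- function(x, ...) {
  cat(sprintf("Normal-mixture fit: %d peak(s); chi2 = %.2f (dof %d, p = %.3f%s)\n",
              length(x), attr(x, "chi2"), attr(x, "dof"), attr(x, "p_value"),
              if (isTRUE(attr(x, "reject"))) ", rejected at 0.05" else ""))
  for (p in x)
    cat(sprintf("  mean %.3f pS, sd %.3f pS, weight %.3f\n",
                p$mean_pS, p$sd_pS, p$weight))
  invisible(x)
}

#' Chi-square goodness of fit of a mixture to a histogram
#'
#' Pearson chi-square of the observed bin counts against the expected
#' counts under the fitted mixture. Bins are pooled (each into the
#' smaller-expectation neighbour) until every expected count is at least 5.
#' Degrees of freedom are pooled bins minus 1 minus the number of fitted
#' mixture parameters (3 per peak minus the weight-sum constraint). The
#' distribution hypothesis is rejected at p < 0.05.
#'
#' @param hist A `conductance_histogram`.
#' @param model Fitted mixture: a `peak_fits` object or a list with
#'   `means`, `sds`, `weights`.
#' @param min_expected Pooling threshold for expected counts; default 5.
#' @return List with `chi2`, `dof`, `p_value`, `reject`.
#' @export
chi_square_gof <- function(hist, model, min_expected = 5) {
  if (inherits(model, "peak_fits"))
    model <- list(means = vapply(model, `[[`, 0, "mean_pS"),
                  sds = vapply(model, `[[`, 0, "sd_pS"),
                  weights = vapply(model, `[[`, 0, "weight"))
  k <- length(model$means)
  n_params <- 3L * k - 1L
  p <- .mixture_bin_probs(hist$bin_edges_pS, model$means, model$sds,
                          model$weights, renormalize = TRUE)
  expected <- p * hist$n_events
  observed <- hist$counts

  # pool adjacent bins until all expected >= min_expected
  while (length(expected) > 1L && min(expected) < min_expected) {
    i <- which.min(expected)
    j <- if (i == 1L) 2L
         else if (i == length(expected)) i - 1L
         else if (expected[i - 1L] <= expected[i + 1L]) i - 1L else i + 1L
    expected[j] <- expected[j] + expected[i]
    observed[j] <- observed[j] + observed[i]
    expected <- expected[-i]; observed <- observed[-i]
  }
  dof <- length(expected) - 1L - n_params
  if (dof < 1L)
    stop("too few pooled bins (", length(expected),
         ") for a chi-square test with ", n_params, " fitted parameters")
  chi2 <- sum((observed - expected)^2 / expected)
  p_value <- stats::pchisq(chi2, dof, lower.tail = FALSE)
  list(chi2 = chi2, dof = dof, p_value = p_value, reject = p_value < 0.05)
}

#' Write histogram bins and peak fits to disk
#'
#' Bins go to `<stem>_bins.csv`; the peak parameters and the chi-square
#' summary go to `<stem>_peaks.json`.
#'
#' @param hist A `conductance_histogram`.
#' @param peaks A `peak_fits` object.
#' @param stem Output path stem.
#' @return The two paths, invisibly.
#' @export
write_histogram_outputs <- function(hist, peaks, stem) {
  bins <- data.frame(bin_lo_pS = utils::head(hist$bin_edges_pS, -1),
                     bin_hi_pS = utils::tail(hist$bin_edges_pS, -1),
                     count = hist$counts)
  csv <- paste0(stem, "_bins.csv")
  utils::write.csv(bins, csv, row.names = FALSE)
  js <- paste0(stem, "_peaks.json")
  obj <- list(peaks = lapply(peaks, unclass),
              chi2 = attr(peaks, "chi2"), dof = attr(peaks, "dof"),
              p_value = attr(peaks, "p_value"))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), js)
  invisible(c(csv, js))
}
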