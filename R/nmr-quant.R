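## Quantitative 1D spectrum analysis: peak fitting (pseudo-Voigt by
## default, linear baseline per window) to obtain areas and FWHM
## linewidths, and the A:B composition ratio from reporter-carbon peak
## areas (K Cgamma near 23 ppm for the cationic chain, E Cdelta near
## 181 ppm for the anionic chain), each area normalized by the number of
## contributing carbons per chain.

#' Construct a 1D spectrum
#'
#' @param ppm strictly monotone chemical-shift axis (ppm).
#' @param intensity intensities (arbitrary units), same length.
#' @return object of class \code{nmr_spectrum}.
#' @export
nmr_spectrum <- function(ppm, intensity) {
  stopifnot(length(ppm) == length(intensity), all(is.finite(ppm)),
            all(is.finite(intensity)))
  dp <- diff(ppm)
  if (!(all(dp > 0) || all(dp < 0))) {
    stop("ppm axis must be strictly monotone")
  }
  structure(list(ppm = ppm, intensity = intensity),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("1D spectrum: %d points, %.2f to %.2f ppm\n",
              length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' @export
plot.nmr_spectrum <- function(x, ...) {
  graphics::plot(x$ppm, x$intensity, type = "l",
                 xlim = rev(range(x$ppm)),
                 xlab = "chemical shift (ppm)", ylab = "intensity", ...)
  invisible(x)
}

#' Read a two-column ppm/intensity CSV
#'
#' @param path CSV path (columns ppm, intensity; header optional).
#' @return an \code{\link{nmr_spectrum}}.
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  ## normalize unicode minus signs, detect header
  has_header <- grepl("[A-Za-z]", first)
  raw <- readLines(path)
  raw <- gsub("−", "-", raw)  # normalize unicode minus
  tab <- utils::read.csv(text = paste(raw, collapse = "\n"),
                         header = has_header)
  nmr_spectrum(as.numeric(tab[[1]]), as.numeric(tab[[2]]))
}

## --- analytic peak shapes (unit area) --------------------------------

gaussian_shape <- function(x, center, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  stats::dnorm(x, center, sigma)
}

lorentzian_shape <- function(x, center, fwhm) {
  g <- fwhm / 2
  (g / pi) / ((x - center)^2 + g^2)
}

peak_shape <- function(x, center, fwhm, area, shape, mixing = 0.5) {
  base <- switch(shape,
                 gaussian = gaussian_shape(x, center, fwhm),
                 lorentzian = lorentzian_shape(x, center, fwhm),
                 pseudo_voigt = mixing * lorentzian_shape(x, center, fwhm) +
                   (1 - mixing) * gaussian_shape(x, center, fwhm),
                 stop("unknown peak shape: ", shape))
  area * base
}

#' Synthesize a spectrum from peak parameters
#'
#' Sum of analytic peak shapes plus an optional linear baseline plus
#' Gaussian noise; deterministic for a fixed seed.
#'
#' @param peaks data.frame with columns \code{center}, \code{fwhm},
#'   \code{area} and optionally \code{shape} (default pseudo_voigt) and
#'   \code{mixing}.
#' @param ppm_range length-2 numeric range of the axis.
#' @param n_points number of samples.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param baseline length-2 numeric (intercept, slope).
#' @param seed optional RNG seed.
#' @return an \code{\link{nmr_spectrum}}.
#' @export
synth_spectrum <- function(peaks, ppm_range = c(0, 200), n_points = 4000,
                           noise_sd = 0, baseline = c(0, 0),
                           seed = NULL) {
  stopifnot(noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  x <- seq(ppm_range[1], ppm_range[2], length.out = n_points)
  y <- baseline[1] + baseline[2] * x
  if (nrow(peaks)) {
    if (is.null(peaks$shape)) peaks$shape <- "pseudo_voigt"
    if (is.null(peaks$mixing)) peaks$mixing <- 0.5
    for (r in seq_len(nrow(peaks))) {
      y <- y + peak_shape(x, peaks$center[r], peaks$fwhm[r],
                          peaks$area[r], peaks$shape[r], peaks$mixing[r])
    }
  }
  if (noise_sd > 0) y <- y + stats::rnorm(n_points, 0, noise_sd)
  nmr_spectrum(x, y)
}

## pick initial peak centers: highest maxima of the lightly smoothed
## trace, enforcing a minimum separation so noise spikes on one peak do
## not claim two slots
pick_peaks <- function(x, y, n_peaks, min_sep = NULL) {
  n <- length(y)
  ys <- if (n >= 7) {
    sm <- as.numeric(stats::filter(y, rep(1 / 5, 5), sides = 2))
    ifelse(is.na(sm), y, sm)
  } else y
  if (is.null(min_sep)) min_sep <- diff(range(x)) / (4 * n_peaks)
  avail <- rep(TRUE, n)
  centers <- numeric(0)
  for (p in seq_len(n_peaks)) {
    if (!any(avail)) break
    idx <- which(avail)[which.max(ys[avail])]
    centers <- c(centers, x[idx])
    avail <- avail & abs(x - x[idx]) > min_sep
  }
  while (length(centers) < n_peaks) {
    centers <- c(centers, mean(range(x)))
  }
  centers
}

fit_window <- function(x, y, n_peaks, baseline_order, shape) {
  span <- diff(range(x))
  centers0 <- pick_peaks(x, y, n_peaks)
  fwhm0 <- rep(span / 10, n_peaks)
  dx <- mean(abs(diff(x)))
  area0 <- vapply(centers0, function(c0) {
    amp <- max(y[which.min(abs(x - c0))], 1e-8)
    amp * fwhm0[1] * 1.2
  }, numeric(1))
  nb <- baseline_order + 1
  par0 <- c(rep(0, nb), rbind(centers0, fwhm0, area0,
                              rep(0.5, n_peaks)))
  lower <- c(rep(-Inf, nb),
             rbind(rep(min(x), n_peaks), rep(2 * dx, n_peaks),
                   rep(0, n_peaks), rep(0, n_peaks)))
  upper <- c(rep(Inf, nb),
             rbind(rep(max(x), n_peaks), rep(span, n_peaks),
                   rep(Inf, n_peaks), rep(1, n_peaks)))
  if (shape != "pseudo_voigt") {
    ## fix mixing by pinning its bounds
    mix_idx <- nb + 4 * seq_len(n_peaks)
    lower[mix_idx] <- 0.5; upper[mix_idx] <- 0.5; par0[mix_idx] <- 0.5
  }
  model <- function(par) {
    yb <- rep(0, length(x))
    for (b in seq_len(nb)) yb <- yb + par[b] * x^(b - 1)
    for (p in seq_len(n_peaks)) {
      o <- nb + 4 * (p - 1)
      yb <- yb + peak_shape(x, par[o + 1], par[o + 2], par[o + 3],
                            shape, par[o + 4])
    }
    yb
  }
  fit <- minpack.lm::nls.lm(par = par0,
                            fn = function(par) y - model(par),
                            lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500))
  converged <- fit$info %in% 1:4
  ## 1-sigma uncertainties from the fit covariance
  se <- rep(NA_real_, length(par0))
  dof <- length(x) - length(par0)
  if (converged && dof > 0) {
    cv <- tryCatch({
      s2 <- fit$deviance / dof
      s2 * solve(fit$hessian)
    }, error = function(e) NULL)
    if (!is.null(cv)) {
      dg <- diag(cv)
      se <- ifelse(dg > 0, sqrt(dg), NA_real_)
    }
  }
  peaks <- lapply(seq_len(n_peaks), function(p) {
    o <- nb + 4 * (p - 1)
    structure(list(center = fit$par[o + 1], fwhm = fit$par[o + 2],
                   area = fit$par[o + 3], mixing = fit$par[o + 4],
                   shape = shape,
                   se = c(center = se[o + 1], fwhm = se[o + 2],
                          area = se[o + 3], mixing = se[o + 4])),
              class = "peak_fit")
  })
  ord <- order(vapply(peaks, function(p) p$center, numeric(1)))
  list(peaks = peaks[ord], converged = converged,
       baseline = fit$par[seq_len(nb)], deviance = fit$deviance,
       message = fit$message)
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf("Peak (%s): center %.4f ppm, FWHM %.4f ppm, area %.4g\n",
              x$shape, x$center, x$fwhm, x$area))
  if (!all(is.na(x$se))) {
    cat(sprintf("  1-sigma: center %.2g, fwhm %.2g, area %.2g\n",
                x$se["center"], x$se["fwhm"], x$se["area"]))
  }
  invisible(x)
}

#' Fit baseline-plus-peaks models within spectral windows
#'
#' Nonlinear least squares (Levenberg-Marquardt) of a polynomial baseline
#' plus \code{n_peaks} analytic peaks in each window, initialized by local
#' maxima. Windows that fail to converge are reported with diagnostics but
#' do not abort the remaining windows.
#'
#' @param spectrum an \code{\link{nmr_spectrum}}.
#' @param regions list of regions, each \code{list(window = c(lo, hi),
#'   n_peaks = k)}.
#' @param baseline_order polynomial baseline order per window (default 1,
#'   linear).
#' @param shape \code{"pseudo_voigt"} (default; Lorentzian/Gaussian mixing
#'   fitted), \code{"gaussian"} or \code{"lorentzian"}.
#' @return object of class \code{nmr_fit}: a list of per-region results
#'   with elements \code{peaks} (list of \code{peak_fit}),
#'   \code{converged}, \code{baseline} and \code{window}.
#' @export
fit_peaks <- function(spectrum, regions, baseline_order = 1,
                      shape = c("pseudo_voigt", "gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  res <- lapply(regions, function(rg) {
    w <- sort(rg$window)
    if (w[1] < min(spectrum$ppm) || w[2] > max(spectrum$ppm)) {
      stop("fit window [", w[1], ", ", w[2], "] outside the ppm axis")
    }
    stopifnot(rg$n_peaks >= 1)
    sel <- spectrum$ppm >= w[1] & spectrum$ppm <= w[2]
    out <- tryCatch(
      fit_window(spectrum$ppm[sel], spectrum$intensity[sel], rg$n_peaks,
                 baseline_order, shape),
      error = function(e) list(peaks = list(), converged = FALSE,
                               baseline = NULL, deviance = NA,
                               message = conditionMessage(e)))
    out$window <- w
    out
  })
  structure(list(regions = res, shape = shape), class = "nmr_fit")
}

#' @export
print.nmr_fit <- function(x, ...) {
  cat("Peak fits (", x$shape, "):\n", sep = "")
  for (rg in x$regions) {
    cat(sprintf(" window [%.2f, %.2f] ppm: %s\n", rg$window[1],
                rg$window[2],
                if (rg$converged) "converged" else
                  paste("NOT converged:", rg$message)))
    for (p in rg$peaks) {
      cat("  "); print(p)
    }
  }
  invisible(x)
}

#' @export
coef.nmr_fit <- function(object, ...) {
  do.call(rbind, lapply(seq_along(object$regions), function(i) {
    rg <- object$regions[[i]]
    if (!length(rg$peaks)) return(NULL)
    do.call(rbind, lapply(rg$peaks, function(p) {
      data.frame(region = i, center = p$center, fwhm = p$fwhm,
                 area = p$area, mixing = p$mixing)
    }))
  }))
}

#' Reporter-carbon multiplicities of a peptide pair
#'
#' Counts the K residues on chain A (one Cgamma each) and the E residues
#' on chain B (one Cdelta each), the normalizations used by
#' \code{\link{composition_from_areas}}.
#'
#' @param pair a \code{\link{peptide_pair}}.
#' @return named numeric vector \code{c(n_K_per_A, n_E_per_B)}.
#' @export
reporter_multiplicities <- function(pair) {
  c(n_K_per_A = sum(seq_chars(pair$seq_A) == "K"),
    n_E_per_B = sum(seq_chars(pair$seq_B) == "E"))
}

#' A:B composition ratio from reporter peak areas
#'
#' \code{ratio = (area_K / n_K_per_A) / (area_E / n_E_per_B)}: each peak
#' area is normalized by the number of contributing carbons on its chain
#' before taking the ratio. Invariant under global intensity scaling.
#'
#' @param fit_K_Cgamma \code{peak_fit} (or bare area) of the K Cgamma peak
#'   near 23 ppm.
#' @param fit_E_Cdelta \code{peak_fit} (or bare area) of the E Cdelta peak
#'   near 181 ppm.
#' @param multiplicities named vector \code{c(n_K_per_A, n_E_per_B)}, e.g.
#'   from \code{\link{reporter_multiplicities}}.
#' @return object of class \code{composition_result} with the ratio and
#'   its ingredients.
#' @export
composition_from_areas <- function(fit_K_Cgamma, fit_E_Cdelta,
                                   multiplicities) {
  area_K <- if (inherits(fit_K_Cgamma, "peak_fit")) fit_K_Cgamma$area
  else as.numeric(fit_K_Cgamma)
  area_E <- if (inherits(fit_E_Cdelta, "peak_fit")) fit_E_Cdelta$area
  else as.numeric(fit_E_Cdelta)
  m <- multiplicities
  if (!all(c("n_K_per_A", "n_E_per_B") %in% names(m))) {
    stop("multiplicities must name n_K_per_A and n_E_per_B")
  }
  if (any(m[c("n_K_per_A", "n_E_per_B")] <= 0)) {
    stop("reporter multiplicities must be positive")
  }
  stopifnot(area_K > 0, area_E > 0)
  ratio <- (area_K / m[["n_K_per_A"]]) / (area_E / m[["n_E_per_B"]])
  structure(list(ratio_A_to_B = ratio, area_K = area_K, area_E = area_E,
                 multiplicities = m), class = "composition_result")
}

#' @export
print.composition_result <- function(x, ...) {
  cat(sprintf("A:B composition ratio = %.3f\n", x$ratio_A_to_B))
  cat(sprintf("  K Cgamma area %.4g / %d carbons; E Cdelta area %.4g / %d carbons\n",
              x$area_K, x$multiplicities[["n_K_per_A"]],
              x$area_E, x$multiplicities[["n_E_per_B"]]))
  invisible(x)
}

#' Parse a CLI window specification
#'
#' Format: \code{"20:26=1,178:184=1"} (window lo:hi = number of peaks).
#'
#' @param spec specification string.
#' @return list of regions for \code{\link{fit_peaks}}.
#' @export
parse_windows <- function(spec) {
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    m <- regmatches(p, regexec("^\\s*([-0-9.]+):([-0-9.]+)=(\\d+)\\s*$", p))[[1]]
    if (length(m) != 4) stop("bad window spec: ", p)
    list(window = c(as.numeric(m[2]), as.numeric(m[3])),
         n_peaks = as.integer(m[4]))
  })
}
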