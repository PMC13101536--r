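#' Per-OTU occurrence frequency and mean relative abundance
#'
#' The two axes of the Sloan neutral model fit: `p`, the mean across samples
#' of an OTU's within-sample relative abundance, and `freq`, the fraction of
#' samples in which its count reaches the detection limit. OTUs never
#' detected are dropped.
#'
#' @param table samples x OTUs count matrix.
#' @param d_reads detection limit in reads (default 1).
#' @return data.frame: `otu_id`, `p`, `freq`.
#' @export
occurrence_frequency <- function(table, d_reads = 1) {
  if (d_reads < 1) stop("detection limit must be >= 1 read")
  rel <- table / rowSums(table)
  p <- colMeans(rel)
  freq <- colMeans(table >= d_reads)
  keep <- freq > 0
  data.frame(otu_id = colnames(table)[keep], p = p[keep], freq = freq[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Neutral-model predicted occurrence frequency
#'
#' Under Sloan's neutral model an OTU with metacommunity relative abundance p
#' has local relative abundance Beta(Nm p, Nm (1-p)) at stationarity; its
#' probability of exceeding the detection limit `dbar` (detection reads over
#' sample depth) is the upper Beta tail
#' F(p) = 1 - I_dbar(Nm p, Nm (1-p)), with I the regularized incomplete beta
#' function. Monotone increasing in p for fixed Nm and dbar.
#'
#' @param p relative abundance(s) in (0, 1).
#' @param Nm product of community size and migration rate, > 0.
#' @param dbar detection limit as a relative abundance, in (0, 1).
#' @export
predicted_frequency <- function(p, Nm, dbar) {
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)")
  if (Nm <= 0) stop("Nm must be > 0")
  if (dbar <= 0 || dbar >= 1) stop("dbar must lie in (0, 1)")
  1 - pbeta(dbar, Nm * p, Nm * (1 - p))
}

# Wilson score interval for x successes of n at level 1 - alpha
.wilson <- function(phat, n, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  den <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / den
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / den
  cbind(lower = pmax(center - half, 0), upper = pmin(center + half, 1))
}

#' Fit the neutral occurrence-frequency curve to (p, freq) diagnostics
#'
#' The least-squares engine behind [fit_ncm()], exposed so the curve can be
#' fit to externally computed occurrence/abundance diagnostics: minimizes
#' sum_i (freq_i - F(p_i; Nm, dbar))^2 over Nm > 0 by bounded scalar search
#' on log(Nm) in [log 0.1, log 1e6] across 5 multistart subintervals
#' (tolerance 1e-8).
#'
#' @param p per-OTU mean relative abundances in (0, 1).
#' @param freq per-OTU observed occurrence frequencies in (0, 1].
#' @param dbar detection limit as a relative abundance.
#' @return list: `Nm`, `r_squared`, `sse`.
#' @export
fit_ncm_curve <- function(p, freq, dbar) {
  if (length(p) != length(freq)) stop("p and freq must be the same length")
  sse <- function(logNm) sum((freq - predicted_frequency(p, exp(logNm), dbar))^2)
  cuts <- seq(log(0.1), log(1e6), length.out = 6)
  best <- NULL
  for (i in seq_len(5)) {
    o <- optimise(sse, interval = c(cuts[i], cuts[i + 1]), tol = 1e-8)
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  if (!is.finite(best$objective)) stop("neutral-model fit failed to converge")
  sst <- sum((freq - mean(freq))^2)
  list(Nm = exp(best$minimum),
       r_squared = if (sst > 0) 1 - best$objective / sst else NA_real_,
       sse = best$objective)
}

#' Fit the Sloan neutral community model
#'
#' Estimates the single free parameter Nm by least squares on the
#' frequency-abundance curve: minimize sum_i (freq_i - F(p_i; Nm, dbar))^2
#' over Nm > 0, by bounded scalar search on log(Nm) in [log 0.1, log 1e6]
#' with 5 multistart subintervals (tolerance 1e-8). N is the mean sample
#' read depth and m = Nm / N. Goodness of fit is R^2 = 1 - SSE/SST (can be
#' negative; reported as is). The 95% bands are Wilson score intervals for
#' the predicted frequency at n = number of samples; OTUs above the upper
#' band are over-represented relative to neutrality ("above"), below the
#' lower band under-represented ("below"), and within the band neutral
#' (band edges count as neutral).
#'
#' @param table samples x OTUs count matrix.
#' @param d_reads detection limit in reads (default 1).
#' @return object of class `ncm_fit`: list with `Nm`, `m`, `N`, `r_squared`,
#'   `dbar`, `d_reads`, `neutral_fraction`, `n_samples`, `n_otus`, and
#'   per-OTU data.frame `otus` (`otu_id`, `p`, `freq`, `predicted`,
#'   `lower95`, `upper95`, `partition`).
#' @export
fit_ncm <- function(table, d_reads = 1) {
  of <- occurrence_frequency(table, d_reads)
  if (nrow(of) < 10) stop("need >= 10 detected OTUs to fit the neutral model")
  N <- mean(rowSums(table))
  dbar <- d_reads / N
  p <- pmin(pmax(of$p, 1e-12), 1 - 1e-12)
  freq <- of$freq
  curve <- fit_ncm_curve(p, freq, dbar)
  Nm <- curve$Nm
  pred <- predicted_frequency(p, Nm, dbar)
  r2 <- curve$r_squared
  n_samples <- nrow(table)
  band <- .wilson(pred, n_samples)
  partition <- ifelse(freq > band[, "upper"], "above",
                      ifelse(freq < band[, "lower"], "below", "neutral"))
  otus <- data.frame(of, predicted = pred, lower95 = band[, "lower"],
                     upper95 = band[, "upper"], partition = partition,
                     stringsAsFactors = FALSE)
  structure(list(Nm = Nm, m = Nm / N, N = N, d_reads = d_reads, dbar = dbar,
                 r_squared = r2, neutral_fraction = mean(partition == "neutral"),
                 n_samples = n_samples, n_otus = nrow(otus), otus = otus),
            class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  samples: %d   OTUs: %d   N (mean depth): %.1f\n",
              x$n_samples, x$n_otus, x$N))
  cat(sprintf("  Nm = %.2f   m = %.4f   R2 = %.3f\n", x$Nm, x$m, x$r_squared))
  cat(sprintf("  neutral fraction: %.1f%% of OTUs within 95%% bands\n",
              100 * x$neutral_fraction))
  invisible(x)
}

#' Compare neutral-model fits across community subsets
#'
#' Tabulates migration rate, goodness of fit and neutral fraction for named
#' group fits (e.g. all / generalist / specialist taxa), sorted by m
#' descending. A comparison artifact only; no inference is attached.
#'
#' @param fits named list of `ncm_fit` objects (>= 2).
#' @return data.frame sorted by decreasing m.
#' @export
compare_group_fits <- function(fits) {
  if (length(fits) < 2) stop("need >= 2 fits to compare")
  df <- do.call(rbind, lapply(names(fits), function(g) {
    f <- fits[[g]]
    data.frame(group = g, m = f$m, Nm = f$Nm, r_squared = f$r_squared,
               neutral_fraction = f$neutral_fraction, n_otus = f$n_otus,
               stringsAsFactors = FALSE)
  }))
  df[order(-df$m), , drop = FALSE]
}
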