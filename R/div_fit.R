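#' Fit the two-replichore model to a cumulative GC skew curve
#'
#' Models the cumulative total GC skew of a circular replicon as a global
#' linear drift plus a closed triangular wave: rising with slope `a1 > 0` from
#' the origin window over an arc of `div * n` windows to the terminus, falling
#' with slope `a2 < 0` back to the origin, continuous at both breakpoints and
#' closed over the circle (`a1 * div + a2 * (1 - div) = 0` after drift
#' removal). `div` is the predicted leading-strand fraction of the replicon.
#'
#' Breakpoints are found by exhaustive search over (ori, ter) window pairs —
#' a full search when `n <= coarse_points`, otherwise a grid of
#' `coarse_points` candidate windows followed by local refinement around the
#' best coarse pair; drift, intercept and amplitude are solved by least
#' squares at each pair. The objective is piecewise-linear in the breakpoints,
#' so the global search is exact on its grid and has no local-minimum issues.
#'
#' @param profile a `cumulative_profile` of class `total`.
#' @param topology `"circular"` (default) or `"linear"`; the model presumes
#'   circular bidirectional replication, so linear input is refused unless
#'   `force_linear = TRUE`.
#' @param force_linear allow fitting a linear replicon (closure retained; the
#'   triangle is still periodic on the window grid).
#' @param coarse_points maximum number of candidate breakpoints per axis
#'   before refinement (<= 512 by construction; default 64).
#' @return object of class `div_fit`: `replicon_id`, `div`, `ori_window`,
#'   `ter_window` (0-based window indices), `slope_lead`, `slope_lag`,
#'   `drift`, `intercept`, `rms_residual`, `n_windows`, `window_size`,
#'   `degenerate`.
#' @export
fit_div <- function(profile, topology = "circular", force_linear = FALSE,
                    coarse_points = 64L) {
  if (!inherits(profile, "cumulative_profile"))
    stop("fit_div expects a cumulative_profile")
  if (!is.null(profile$skew_class) && profile$skew_class != "total")
    stop("fit_div expects the total-skew cumulative profile")
  if (topology == "linear" && !force_linear)
    stop("replicon is linear; the two-replichore model presumes a circular ",
         "chromosome (use force_linear = TRUE to override)")
  y <- profile$cumulative
  n <- length(y)
  if (n < 8L) stop("fit_div requires at least 8 windows, got ", n)

  if (n <= coarse_points) {
    cand <- seq_len(n) - 1L
    best <- div_search(y, cand, cand)
  } else {
    step <- n / coarse_points
    cand <- unique(as.integer(floor((seq_len(coarse_points) - 1L) * step)))
    best <- div_search(y, cand, cand)
    w <- as.integer(ceiling(step))
    ref_o <- unique((best$ori + (-w:w)) %% n)
    ref_t <- unique((best$ter + (-w:w)) %% n)
    best <- div_search(y, ref_o, ref_t)
  }

  L1 <- (best$ter - best$ori) %% n
  div <- L1 / n
  degenerate <- div < 1 / n + 1e-12 || div > 1 - 1 / n - 1e-12
  structure(list(replicon_id = profile$replicon_id, div = div,
                 ori_window = best$ori, ter_window = best$ter,
                 slope_lead = best$a1, slope_lag = best$a2,
                 drift = best$drift, intercept = best$intercept,
                 rms_residual = sqrt(best$rss / n), n_windows = n,
                 window_size = profile$window_size,
                 degenerate = degenerate),
            class = "div_fit")
}

# exhaustive least-squares search over ordered (ori, ter) pairs.
# For each pair the model y = c + d*x + a1*T is linear in (c, d, a1) where T
# is the unit closed triangle: slope +1 on the rising arc ori->ter, slope
# -L1/L2 on the falling arc. Only fits with a1 > 0 qualify (ori must start
# the rising segment); the swapped pair covers the mirror case.
div_search <- function(y, ori_cand, ter_cand) {
  n <- length(y)
  x <- seq_len(n) - 1L
  # near-ties arise when a breakpoint falls on the linear-domain boundary
  # (the kink there is unobservable and drift absorbs the difference);
  # among equally-fitting pairs prefer the one needing the least drift
  eps <- 1e-9 * (sum(y^2) + 1)
  best <- list(rss = Inf, ori = NA_integer_, ter = NA_integer_,
               a1 = NA_real_, a2 = NA_real_, drift = Inf,
               intercept = NA_real_)
  for (ori in ori_cand) {
    u <- (x - ori) %% n
    for (ter in ter_cand) {
      L1 <- (ter - ori) %% n
      if (L1 < 1L || L1 > n - 1L) next
      L2 <- n - L1
      Tri <- ifelse(u <= L1, u, L1 - (L1 / L2) * (u - L1))
      fit <- .lm.fit(cbind(1, x, Tri), y)
      a1 <- fit$coefficients[3L]
      if (is.na(a1) || a1 <= 0) next
      rss <- sum(fit$residuals^2)
      if (rss < best$rss - eps ||
          (rss < best$rss + eps &&
           abs(fit$coefficients[2L]) < abs(best$drift))) {
        best <- list(rss = rss, ori = as.integer(ori), ter = as.integer(ter),
                     a1 = a1, a2 = -a1 * L1 / L2,
                     drift = fit$coefficients[2L],
                     intercept = fit$coefficients[1L])
      }
    }
  }
  if (!is.finite(best$rss))
    stop("degenerate fit: no breakpoint pair with positive leading slope")
  best
}

#' Evaluate the fitted two-replichore model
#'
#' Returns the fitted curve on the window grid, useful for residual
#' inspection and plotting.
#'
#' @param fit a `div_fit`.
#' @return numeric vector of length `n_windows`.
#' @export
predict_div_fit <- function(fit) {
  n <- fit$n_windows
  x <- seq_len(n) - 1L
  u <- (x - fit$ori_window) %% n
  L1 <- (fit$ter_window - fit$ori_window) %% n
  L2 <- n - L1
  Tri <- ifelse(u <= L1, u, L1 - (L1 / L2) * (u - L1))
  fit$intercept + fit$drift * x + fit$slope_lead * Tri
}

#' Write div fits to TSV
#'
#' Window indices are converted to 1-based base-pair coordinates
#' (window start) for interchange.
#'
#' @param fits list of `div_fit` (or a single one).
#' @param path output TSV.
#' @export
write_div_tsv <- function(fits, path) {
  if (inherits(fits, "div_fit")) fits <- list(fits)
  df <- do.call(rbind, lapply(fits, function(f)
    data.frame(replicon_id = f$replicon_id, div = f$div,
               ori_bp = f$ori_window * f$window_size + 1L,
               ter_bp = f$ter_window * f$window_size + 1L,
               slope_lead = f$slope_lead, slope_lag = f$slope_lag,
               drift = f$drift, rms_residual = f$rms_residual,
               stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
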