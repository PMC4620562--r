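#' Zwanzig FEP increment between mapping windows
#'
#' Free energy change from window m's mapping potential to the one at
#' `lam_next`, estimated by exponential averaging over window m's samples:
#' `dF = -(1/beta) * log < exp(-beta * (eps_next - eps_m)) >_m`,
#' evaluated with a max-shift (log-sum-exp) guard against overflow.
#'
#' @param samples_m a `"window_samples"` object (see [run_fep_windows()]).
#' @param lam_next target mapping parameter in `[0, 1]`.
#' @return free energy increment, kcal/mol.
#' @export
fep_increment <- function(samples_m, lam_next) {
  stopifnot(inherits(samples_m, "window_samples"))
  s <- samples_m$samples
  if (nrow(s) == 0L) stop("empty window samples", call. = FALSE)
  beta <- 1 / (KB * samples_m$temperature)
  du <- mapping_potential(s$eps1, s$eps2, lam_next) -
    mapping_potential(s$eps1, s$eps2, samples_m$lam)
  a <- -beta * du
  m <- max(a)
  -(1 / beta) * (m + log(mean(exp(a - m))))
}

#' Assemble a free-energy profile on the energy-gap coordinate
#'
#' Classic EVB umbrella-sampling assembly: each window m contributes
#' `dG(X_j) = dG_FEP(m) - (1/beta) * log < 1[X in bin j] * exp(-beta (E_g - eps_m)) >_m`
#' where `dG_FEP(m)` is the cumulative Zwanzig free energy up to window m.
#' Where several windows populate a bin, the window with the larger count in
#' that bin owns it. The profile is anchored so the reactant-side minimum
#' (gap X < 0) is zero. Bins with fewer than `min_counts` samples are
#' flagged unusable rather than interpolated.
#'
#' @param windows list of `"window_samples"` from [run_fep_windows()].
#' @param n_bins number of gap-coordinate bins over the sampled range.
#' @param min_counts usable-bin count threshold.
#' @param standard_state label carried into the profile.
#' @return object of class `"free_energy_profile"` with fields `bin_centers`,
#'   `dG`, `counts`, `usable`, `temperature`, `replicate_id`,
#'   `standard_state`.
#' @export
assemble_profile <- function(windows, n_bins = 300L, min_counts = 10L,
                             standard_state = "1M") {
  if (length(windows) < 2L) stop("need >= 2 windows", call. = FALSE)
  stopifnot(all(vapply(windows, inherits, TRUE, "window_samples")))
  temperature <- windows[[1]]$temperature
  beta <- 1 / (KB * temperature)
  lams <- vapply(windows, `[[`, numeric(1), "lam")

  # cumulative FEP offsets along the window chain
  dG_fep <- c(0, cumsum(vapply(seq_len(length(windows) - 1L), function(m) {
    fep_increment(windows[[m]], lams[m + 1L])
  }, numeric(1))))

  gaps <- lapply(windows, function(w) w$samples$eps1 - w$samples$eps2)
  rng <- range(unlist(gaps))
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2

  counts <- matrix(0L, length(windows), n_bins)
  wterm <- matrix(NA_real_, length(windows), n_bins)
  for (m in seq_along(windows)) {
    s <- windows[[m]]$samples
    bin <- findInterval(gaps[[m]], edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    a <- -beta * (s$e_ground - s$e_map)
    amax <- max(a)
    n_m <- length(a)
    for (j in unique(bin)) {
      sel <- bin == j
      counts[m, j] <- sum(sel)
      wterm[m, j] <- -(1 / beta) *
        (amax + log(sum(exp(a[sel] - amax)) / n_m))
    }
  }

  # coverage: consecutive windows must overlap on the gap coordinate
  for (m in seq_len(length(windows) - 1L)) {
    hi_m <- stats::quantile(gaps[[m]], 0.99, names = FALSE)
    lo_n <- stats::quantile(gaps[[m + 1L]], 0.01, names = FALSE)
    if (min(max(gaps[[m]]), max(gaps[[m + 1L]])) <
        max(min(gaps[[m]]), min(gaps[[m + 1L]]))) {
      stop("gap-coverage hole between windows ", m, " and ", m + 1L,
           ": no samples in X in [", signif(min(hi_m, lo_n), 5), ", ",
           signif(max(hi_m, lo_n), 5), "] kcal/mol", call. = FALSE)
    }
  }

  tot <- colSums(counts)
  owner <- apply(counts, 2, which.max)
  dG <- vapply(seq_len(n_bins), function(j) {
    if (tot[j] == 0) return(NA_real_)
    dG_fep[owner[j]] + wterm[owner[j], j]
  }, numeric(1))
  cnt <- vapply(seq_len(n_bins), function(j) counts[owner[j], j], integer(1))
  usable <- !is.na(dG) & cnt >= min_counts

  # anchor at the reactant-side minimum (gap X < 0)
  left <- usable & centers < 0
  if (!any(left)) left <- usable
  dG <- dG - min(dG[left])

  structure(list(bin_centers = centers, dG = dG, counts = cnt,
                 usable = usable, temperature = temperature,
                 replicate_id = windows[[1]]$replicate_id,
                 standard_state = standard_state),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("Free-energy profile at %.1f K (replicate %d): %d/%d usable bins\n",
              x$temperature, x$replicate_id, sum(x$usable), length(x$dG)))
  invisible(x)
}

#' Barrier and reaction free energy from a profile
#'
#' The transition state is the global maximum of the (largest contiguous)
#' usable block of bins, the reactant state the deepest minimum on its low-X
#' side and the product state the deepest minimum on its high-X side; each
#' stationary value is refined by a 3-point quadratic fit around the
#' extremal bin. A profile without an interior maximum raises a "no barrier"
#' error rather than returning zero.
#'
#' @param profile a `"free_energy_profile"` (or any list with `bin_centers`,
#'   `dG`, `usable`, `temperature`).
#' @return object of class `"barrier_result"`: `dG_act`, `dG_rxn`,
#'   `X_reactant`, `X_ts`, `X_product`, `temperature`, `replicate_id`.
#' @export
barrier_and_reaction <- function(profile) {
  use <- which(profile$usable)
  if (!length(use)) stop("no usable bins", call. = FALSE)
  # restrict to the longest contiguous usable block (outlier tail bins can
  # be isolated and are not part of the reaction path)
  runs <- split(use, cumsum(c(1L, diff(use) != 1L)))
  use <- runs[[which.max(lengths(runs))]]
  x <- profile$bin_centers[use]
  g <- profile$dG[use]
  n <- length(g)
  if (n < 5L) stop("too few usable bins for stationary-point analysis",
                   call. = FALSE)
  # transition state: global maximum of the usable block; it must be
  # interior, with the reactant (product) state the deepest minimum on its
  # low-X (high-X) side. This reading is robust to noisy sparse bins on the
  # basin flanks, which can fake shallow local minima.
  i_ts <- which.max(g)
  if (i_ts <= 2L || i_ts >= n - 1L) {
    stop("no barrier: profile has no interior maximum", call. = FALSE)
  }
  i_r <- which.min(g[seq_len(i_ts - 1L)])
  i_p <- i_ts + which.min(g[seq(i_ts + 1L, n)])
  if (g[i_ts] <= g[i_r] + 1e-9 || g[i_ts] <= g[i_p] + 1e-9) {
    stop("no barrier: profile is monotone around its maximum", call. = FALSE)
  }
  ref <- function(i) {
    if (i <= 1L || i >= n) return(c(x[i], g[i]))
    .quad_refine(x[(i - 1L):(i + 1L)], g[(i - 1L):(i + 1L)])
  }
  r <- ref(i_r); ts <- ref(i_ts); p <- ref(i_p)
  structure(list(dG_act = ts[2] - r[2], dG_rxn = p[2] - r[2],
                 X_reactant = r[1], X_ts = ts[1], X_product = p[1],
                 temperature = profile$temperature,
                 replicate_id = profile$replicate_id),
            class = "barrier_result")
}

# Vertex of the parabola through three points; falls back to the middle
# point when the fit is degenerate or the vertex escapes the bracket.
.quad_refine <- function(x, y) {
  x <- unname(x); y <- unname(y)
  A <- cbind(1, x, x^2)
  co <- tryCatch(unname(solve(A, y)), error = function(e) NULL)
  if (is.null(co) || co[3] == 0) return(c(x[2], y[2]))
  xv <- -co[2] / (2 * co[3])
  if (xv < min(x) || xv > max(x)) return(c(x[2], y[2]))
  c(xv, co[1] + co[2] * xv + co[3] * xv^2)
}

#' @export
print.barrier_result <- function(x, ...) {
  cat(sprintf("dG_act = %.3f, dG_rxn = %.3f kcal/mol at %.1f K (replicate %d)\n",
              x$dG_act, x$dG_rxn, x$temperature, x$replicate_id))
  invisible(x)
}

#' Average replicate barrier results per temperature
#'
#' Groups a flat list of [barrier_and_reaction()] results by temperature and
#' reports the per-temperature mean and standard error of the mean
#' (sample SD / sqrt(n), n >= 2) of both `dG_act` and `dG_rxn`.
#'
#' @param results list of `"barrier_result"` objects.
#' @return object of class `"replicate_scan"`: a data frame with columns
#'   `temperature`, `n`, `dG_act`, `sem_act`, `dG_rxn`, `sem_rxn`.
#' @export
average_replicates <- function(results) {
  stopifnot(length(results) > 0,
            all(vapply(results, inherits, TRUE, "barrier_result")))
  tt <- vapply(results, `[[`, numeric(1), "temperature")
  ga <- vapply(results, `[[`, numeric(1), "dG_act")
  gr <- vapply(results, `[[`, numeric(1), "dG_rxn")
  out <- do.call(rbind, lapply(sort(unique(tt)), function(T1) {
    sel <- tt == T1
    n <- sum(sel)
    if (n < 2L) {
      stop("temperature group ", T1, " K has fewer than 2 replicates",
           call. = FALSE)
    }
    data.frame(temperature = T1, n = n,
               dG_act = mean(ga[sel]), sem_act = stats::sd(ga[sel]) / sqrt(n),
               dG_rxn = mean(gr[sel]), sem_rxn = stats::sd(gr[sel]) / sqrt(n))
  }))
  class(out) <- c("replicate_scan", "data.frame")
  out
}

#' @export
print.replicate_scan <- function(x, ...) {
  cat("Replicate temperature scan (mean +/- s.e.m., kcal/mol):\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %5.0f K (n=%2d): dG_act = %7.3f +/- %.3f, dG_rxn = %8.3f +/- %.3f\n",
                x$temperature[i], x$n[i], x$dG_act[i], x$sem_act[i],
                x$dG_rxn[i], x$sem_rxn[i]))
  }
  invisible(x)
}

#' Write sampled profiles and scan summaries as plain text
#'
#' `write_profiles_csv()` writes one row per bin
#' (`bin_center, dG, counts, usable, temperature, replicate`);
#' `write_scan_json()` writes the per-temperature means and s.e.m.
#'
#' @param profiles list of `"free_energy_profile"` objects.
#' @param scan a `"replicate_scan"`.
#' @param path output file path.
#' @export
write_profiles_csv <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(bin_center = p$bin_centers, dG = p$dG, counts = p$counts,
               usable = p$usable, temperature = p$temperature,
               replicate = p$replicate_id)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
write_scan_json <- function(scan, path) {
  jsonlite::write_json(as.data.frame(unclass(scan)), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}
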