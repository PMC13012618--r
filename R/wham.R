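# Weighted histogram analysis method: reconstruct the unbiased free-energy
# profile from umbrella-sampling windows with harmonic biases, plus state
# free-energy differences.

#' Reaction-coordinate state definition
#' @param name state label
#' @param lower,upper interval bounds (nm); one may be infinite
#' @return list of class `state_definition`
#' @export
state_definition <- function(name, lower, upper) {
  if (!(lower < upper)) stop("state interval is empty")
  structure(list(name = name, lower = lower, upper = upper),
            class = "state_definition")
}

#' WHAM free-energy profile from an umbrella dataset
#'
#' Iterates the self-consistent WHAM equations (per-bin unbiased density
#' and per-window free-energy offsets f_i) until the largest change in
#' ln f_i falls below `tolerance`. G(xi) = -kBT ln p(xi), anchored so the
#' minimum is zero; reported both in kT and kcal/mol.
#'
#' @param ds an `umbrella_dataset`
#' @param n_bins number of bins over the sampled range (default 100)
#' @param tolerance convergence threshold on max |delta ln f_i| (kT)
#' @param max_iter iteration cap
#' @param breaks optional explicit bin edges (overrides `n_bins`)
#' @return object of class `free_energy_profile`: `xi` (bin centers, nm),
#'   `G_kT`, `G` (kcal/mol), `density` (normalized), `offsets_kT`,
#'   `breaks`, `temperature`, `iterations`, `converged`, `err` (NULL until
#'   [bootstrap_error()] fills it)
#' @export
wham <- function(ds, n_bins = 100, tolerance = 1e-8, max_iter = 1e5,
                 breaks = NULL) {
  win <- ds$windows
  if (any(vapply(win, function(w) length(w$xi) == 0, logical(1))))
    stop("every window must contain samples")
  kT <- kBT_kJ(ds$temperature)
  centers <- vapply(win, `[[`, numeric(1), "center")
  ord <- order(centers)
  # pairwise overlap along the window ordering
  rng <- t(vapply(win, function(w) range(w$xi), numeric(2)))
  for (q in seq_len(length(win) - 1)) {
    i <- ord[q]; j <- ord[q + 1]
    if (rng[i, 2] <= rng[j, 1])
      stop(sprintf(
        "no histogram overlap between windows at %.3f and %.3f nm",
        centers[i], centers[j]))
  }
  all_xi <- unlist(lapply(win, `[[`, "xi"))
  if (is.null(breaks)) breaks <- seq(min(all_xi), max(all_xi),
                                     length.out = n_bins + 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  width <- diff(breaks)
  nb <- length(mids)
  nw <- length(win)
  h <- matrix(0, nw, nb)      # histogram counts
  n_i <- numeric(nw)
  for (w in seq_len(nw)) {
    xi <- win[[w]]$xi
    xi <- xi[xi >= breaks[1] & xi <= breaks[nb + 1]]
    h[w, ] <- graphics::hist(xi, breaks = breaks, plot = FALSE)$counts
    n_i[w] <- length(xi)
  }
  # bias Boltzmann factors at bin centers
  cmat <- matrix(NA_real_, nw, nb)
  for (w in seq_len(nw)) {
    u <- 0.5 * win[[w]]$k * (mids - win[[w]]$center)^2
    cmat[w, ] <- exp(-u / kT)
  }
  nbins_tot <- colSums(h)
  lnf <- numeric(nw)
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    denom <- colSums((n_i * exp(lnf)) * cmat)
    p <- ifelse(denom > 0, nbins_tot / denom, 0)
    p <- p / sum(p * width)
    lnf_new <- -log(pmax(as.vector(cmat %*% (p * width)), 1e-300))
    lnf_new <- lnf_new - lnf_new[1]
    delta <- max(abs(lnf_new - lnf))
    lnf <- lnf_new
    if (delta < tolerance) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    warning(sprintf("WHAM not converged after %d iterations (residual %g)",
                    iter, delta))
  g_kt <- -log(pmax(p, 1e-300))
  occupied <- p > 0
  g_kt <- g_kt - min(g_kt[occupied])
  g_kt[!occupied] <- NA_real_
  structure(list(xi = mids, G_kT = g_kt,
                 G = g_kt * kT / .const$kcal_kJ,
                 density = p, offsets_kT = lnf, breaks = breaks,
                 temperature = ds$temperature, iterations = iter,
                 converged = converged, err = NULL),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat("free_energy_profile:", length(x$xi), "bins over",
      sprintf("[%.3f, %.3f] nm;", min(x$xi), max(x$xi)),
      "max G =", sprintf("%.2f kcal/mol", max(x$G, na.rm = TRUE)),
      if (x$converged) "" else "(NOT converged)", "\n")
  invisible(x)
}

#' Export a profile as TSV (xi, G kcal/mol, G kT, err)
#' @param profile a `free_energy_profile`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_profile <- function(profile, path) {
  utils::write.table(
    data.frame(xi = profile$xi, G_kcal = profile$G, G_kT = profile$G_kT,
               err_kcal = profile$err %||% rep(NA_real_,
                                               length(profile$xi))),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Free-energy difference between two reaction-coordinate states
#'
#' delta G = -kBT ln( P(B) / P(A) ) from the unbiased density integrated
#' over each state interval, reported in kcal/mol (B relative to A).
#' When bootstrap replicates are supplied the error is the standard
#' deviation of the replicate differences.
#'
#' @param profile a `free_energy_profile`
#' @param state_a,state_b [state_definition()]s overlapping the profile
#' @param bootstrap optional result of [bootstrap_error()]
#' @return list with `delta_G` (kcal/mol), `delta_G_kT`, `err`
#'   (kcal/mol or NA)
#' @export
delta_g <- function(profile, state_a, state_b, bootstrap = NULL) {
  kT <- kBT_kJ(profile$temperature)
  integrate_state <- function(dens, st) {
    w <- diff(profile$breaks)
    inside <- profile$xi >= st$lower & profile$xi <= st$upper
    sum(dens[inside] * w[inside])
  }
  pa <- integrate_state(profile$density, state_a)
  pb <- integrate_state(profile$density, state_b)
  if (pa <= 0 || pb <= 0)
    stop("a state has zero integrated density in the profile range")
  dg_kt <- -log(pb / pa)
  err <- NA_real_
  if (!is.null(bootstrap)) {
    reps <- vapply(seq_len(nrow(bootstrap$density_replicates)),
                   function(r) {
      dr <- bootstrap$density_replicates[r, ]
      pa_r <- integrate_state(dr, state_a)
      pb_r <- integrate_state(dr, state_b)
      if (pa_r <= 0 || pb_r <= 0) return(NA_real_)
      -log(pb_r / pa_r)
    }, numeric(1))
    err <- stats::sd(reps, na.rm = TRUE) * kT / .const$kcal_kJ
  }
  list(delta_G = dg_kt * kT / .const$kcal_kJ, delta_G_kT = dg_kt,
       err = err)
}

#' WHAM profiles from truncated windows (convergence diagnostic)
#'
#' Re-solves WHAM using only the first fraction of every window's series,
#' on the bin grid of the full-data profile so the profiles are directly
#' comparable; all profiles are anchored at the full-profile minimum bin.
#'
#' @param ds an `umbrella_dataset`
#' @param fractions vector of fractions in (0, 1]
#' @param n_bins,tolerance passed to [wham()]
#' @return list with `fractions` and `profiles` (one per fraction, same
#'   order)
#' @export
convergence_profile <- function(ds, fractions = c(0.25, 0.5, 0.75, 1),
                                n_bins = 100, tolerance = 1e-8) {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  full <- wham(ds, n_bins = n_bins, tolerance = tolerance)
  anchor_bin <- which.min(full$G_kT)
  profiles <- lapply(fractions, function(fr) {
    trunc_ds <- ds
    trunc_ds$windows <- lapply(ds$windows, function(w) {
      keep <- max(1, floor(length(w$xi) * fr))
      if (keep < 1) stop("fraction leaves an empty window")
      w$xi <- w$xi[seq_len(keep)]
      w$time <- w$time[seq_len(keep)]
      w
    })
    p <- wham(trunc_ds, tolerance = tolerance, breaks = full$breaks)
    shift <- p$G_kT[anchor_bin]
    p$G_kT <- p$G_kT - shift
    p$G <- p$G_kT * kBT_kJ(p$temperature) / .const$kcal_kJ
    p
  })
  list(fractions = fractions, profiles = profiles)
}
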