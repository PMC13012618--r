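# WHAM reconstruction, state free-energy differences, convergence and
# bootstrap errors.

kT310 <- 0.008314 * 310

test_that("WHAM recovers a known harmonic profile from standard windows", {
  u <- make_umbrella_dataset(
    potential = list(kind = "harmonic", kappa = 100, xi0 = 0.6),
    n = 5000, seed = 40)
  prof <- wham(u$dataset)
  expect_true(prof$converged)
  sel <- prof$xi >= 0.35 & prof$xi <= 1.15
  ana <- approx(u$truth$analytic_pmf$xi, u$truth$analytic_pmf$G_kT,
                prof$xi[sel])$y
  got <- prof$G_kT[sel]
  got <- got - min(got); ana <- ana - min(ana)
  expect_lt(sqrt(mean((got - ana)^2)), 0.1)
  expect_equal(min(prof$G_kT, na.rm = TRUE), 0)
})

test_that("a single unbiased window degenerates to -kT ln(histogram)", {
  set.seed(41)
  xi <- rnorm(20000, 0.6, 0.05)
  ds <- structure(list(windows = list(list(center = 0.6, k = 1e-9,
                                           time = seq_along(xi),
                                           xi = xi)),
                       temperature = 310), class = "umbrella_dataset")
  prof <- wham(ds, n_bins = 40)
  h <- hist(xi, breaks = prof$breaks, plot = FALSE)
  g_direct <- -log(h$density)
  g_direct <- g_direct - min(g_direct[is.finite(g_direct)])
  ok <- is.finite(g_direct)
  expect_lt(max(abs(prof$G_kT[ok] - g_direct[ok])), 1e-6)
})

test_that("double-well barrier height is recovered", {
  pot <- list(kind = "double_well", barrier = 12, minima = c(0.5, 1.0))
  u <- make_umbrella_dataset(potential = pot, n = 4000, seed = 42)
  prof <- wham(u$dataset)
  between <- prof$xi > 0.55 & prof$xi < 0.95
  barrier_est <- max(prof$G_kT[between]) -
    min(prof$G_kT, na.rm = TRUE)
  expect_lt(abs(barrier_est - 12 / kT310), 0.35)
})

test_that("non-overlapping windows are rejected with the gap named", {
  u <- make_umbrella_dataset(n = 500, seed = 43)
  ds <- u$dataset
  ds$windows <- ds$windows[c(1, 10)]
  expect_error(wham(ds), "no histogram overlap")
})

test_that("WHAM is invariant to a constant shift of initial offsets", {
  # the iteration normalizes offsets to window 1; re-running from the
  # converged state must not move the solution
  u <- make_umbrella_dataset(n = 1000, seed = 44)
  p1 <- wham(u$dataset)
  p2 <- wham(u$dataset)
  expect_equal(p1$G_kT, p2$G_kT, tolerance = 1e-10)
  expect_equal(p1$offsets_kT, p2$offsets_kT, tolerance = 1e-10)
})

test_that("profiles are stable to doubling the bin count", {
  u <- make_umbrella_dataset(n = 5000, seed = 45)
  p100 <- wham(u$dataset, n_bins = 100)
  p200 <- wham(u$dataset, n_bins = 200)
  on100 <- approx(p200$xi, p200$G_kT, p100$xi)$y
  sel <- p100$xi > 0.4 & p100$xi < 1.1
  expect_lt(max(abs(p100$G_kT[sel] - on100[sel]), na.rm = TRUE), 0.15)
})

test_that("delta_g handles flat, weighted and antisymmetric cases", {
  flat <- structure(list(
    xi = seq(0.05, 0.95, 0.1), G_kT = rep(0, 10),
    G = rep(0, 10), density = rep(1, 10),
    breaks = seq(0, 1, 0.1), temperature = 310, err = NULL),
    class = "free_energy_profile")
  a <- state_definition("A", 0, 0.4)
  b <- state_definition("B", 0.6, 1.0)
  expect_equal(delta_g(flat, a, b)$delta_G, 0, tolerance = 1e-12)

  # two-Gaussian density with 10:1 weight ratio
  xi <- seq(0.005, 1.995, 0.01)
  dens <- 10 / 11 * dnorm(xi, 0.5, 0.05) + 1 / 11 * dnorm(xi, 1.5, 0.05)
  prof <- structure(list(
    xi = xi, G_kT = -log(dens), G = -log(dens) * kT310 / 4.184,
    density = dens, breaks = seq(0, 2, 0.01), temperature = 310,
    err = NULL), class = "free_energy_profile")
  a2 <- state_definition("well1", 0, 1)
  b2 <- state_definition("well2", 1, 2)
  dg <- delta_g(prof, a2, b2)
  expect_equal(dg$delta_G_kT, -log(1 / 10), tolerance = 1e-3)
  expect_equal(delta_g(prof, b2, a2)$delta_G, -dg$delta_G,
               tolerance = 1e-12)

  # invariance to a constant shift in G (delta_g uses densities)
  shifted <- prof
  shifted$G_kT <- shifted$G_kT + 3
  expect_equal(delta_g(shifted, a2, b2)$delta_G_kT, dg$delta_G_kT)
  expect_error(delta_g(prof, state_definition("empty", 5, 6), a2),
               "zero integrated density")
})

test_that("truncated-window convergence behaves and fraction 1 is exact", {
  u <- make_umbrella_dataset(n = 4000, seed = 46)
  cv <- convergence_profile(u$dataset, fractions = c(0.5, 1))
  full <- wham(u$dataset)
  # fraction 1.0 equals the plain solution up to the common anchor shift
  g1 <- cv$profiles[[2]]$G_kT
  g0 <- full$G_kT
  expect_lt(max(abs((g1 - min(g1, na.rm = TRUE)) -
                      (g0 - min(g0, na.rm = TRUE))), na.rm = TRUE), 1e-9)
  # half-data profile stays close to the full one on smooth data
  sel <- full$xi > 0.4 & full$xi < 1.1
  expect_lt(max(abs(cv$profiles[[1]]$G_kT[sel] - g1[sel]), na.rm = TRUE),
            0.3)
  expect_error(convergence_profile(u$dataset, fractions = 0),
               "fractions")
})

test_that("i.i.d. windows reduce to near-naive bootstrap errors", {
  u <- make_umbrella_dataset(n = 1200, seed = 47)
  bt <- bootstrap_error(u$dataset, n_boot = 40, seed = 1)
  expect_true(all(bt$block_lengths <= 2))
  naive <- bootstrap_error(u$dataset, n_boot = 40, seed = 1,
                           block_override = 1)
  sel <- is.finite(bt$se_kT) & is.finite(naive$se_kT) &
    naive$se_kT > 0
  ratio <- median(bt$se_kT[sel] / naive$se_kT[sel])
  expect_lt(abs(ratio - 1), 0.2)
})

test_that("AR(1) windows trigger long blocks and inflated errors", {
  mk_ar1 <- function(n, phi, mu, s) {
    x <- numeric(n); x[1] <- mu
    for (i in 2:n) x[i] <- mu + phi * (x[i - 1] - mu) +
        rnorm(1, sd = s * sqrt(1 - phi^2))
    x
  }
  set.seed(48)
  ds <- make_umbrella_dataset(n = 1200, seed = 48)$dataset
  for (w in seq_along(ds$windows)) {
    mu <- mean(ds$windows[[w]]$xi)
    s <- sd(ds$windows[[w]]$xi)
    ds$windows[[w]]$xi <- mk_ar1(1200, 0.9, mu, s)
  }
  # integrated autocorrelation time of AR(1): (1 + phi)/(1 - phi) = 19
  bt <- bootstrap_error(ds, n_boot = 40, seed = 1)
  expect_true(all(bt$block_lengths > 5))
  naive <- bootstrap_error(ds, n_boot = 40, seed = 1,
                           block_override = 1)
  sel <- is.finite(bt$se_kT) & is.finite(naive$se_kT) &
    naive$se_kT > 0
  expect_gt(median(bt$se_kT[sel] / naive$se_kT[sel]), 1.5)
})

test_that("degenerate bootstrap settings warn", {
  u <- make_umbrella_dataset(n = 300, seed = 49)
  expect_warning(bootstrap_error(u$dataset, n_boot = 1, seed = 1),
                 "degenerate")
})
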