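# Ac-225 decay-chain kinetics: nuclide constants, the two-nuclide
# parent/daughter activity-ratio relation, its inversion to activities at
# sacrifice, free Bi-213 quantification, and the detector frame-coincidence
# correction.

#' Construct a nuclide record
#'
#' @param name Nuclide identifier, e.g. `"Ac-225"`.
#' @param half_life Half-life as seconds or a string with unit suffix
#'   (see [parse_duration()]).
#' @param alpha_energy_MeV Alpha-particle energy in MeV (0 if the nuclide is
#'   not an alpha emitter).
#' @param alpha_yield Alpha emissions of this nuclide per chain decay
#'   (dimensionless, in \[0, 1\]).
#' @return A one-row tibble with columns `name`, `half_life_s`,
#'   `alpha_energy_MeV`, `alpha_yield`, `lambda` (decay constant, 1/s).
#' @export
nuclide <- function(name, half_life, alpha_energy_MeV = 0, alpha_yield = 0) {
  hl <- parse_duration(half_life)
  if (any(hl <= 0)) abort("half_life must be > 0", class = "alphadose3d_domain_error")
  if (any(alpha_yield < 0 | alpha_yield > 1)) {
    abort("alpha_yield must be in [0, 1]", class = "alphadose3d_domain_error")
  }
  tibble(
    name = name, half_life_s = hl,
    alpha_energy_MeV = alpha_energy_MeV, alpha_yield = alpha_yield,
    lambda = log(2) / hl
  )
}

#' Construct a decay chain
#'
#' A decay chain is a tibble of nuclides (one row each) with `parent` and
#' `daughter` attributes naming the long-lived parent and the kinetically
#' relevant daughter used by the two-nuclide activity relations.
#'
#' @param nuclides A tibble of nuclide rows as produced by [nuclide()]
#'   (rows may be bound together).
#' @param parent Name of the parent nuclide (must be the longest-lived).
#' @param daughter Name of the daughter used in parent/daughter relations.
#' @param alphas_per_chain Total alpha emissions per chain decay; checked
#'   against the sum of `alpha_yield` within `yield_tol`.
#' @param yield_tol Tolerance for the alpha-yield sum check.
#' @return A `decay_chain` object (tibble subclass).
#' @export
decay_chain <- function(nuclides, parent, daughter,
                        alphas_per_chain = 4, yield_tol = 0.02) {
  stopifnot(is.data.frame(nuclides))
  if (!parent %in% nuclides$name) abort("parent not in nuclide list")
  if (!daughter %in% nuclides$name) abort("daughter not in nuclide list")
  if (max(nuclides$half_life_s) != nuclides$half_life_s[nuclides$name == parent]) {
    abort("parent must have the longest half-life", class = "alphadose3d_domain_error")
  }
  ys <- sum(nuclides$alpha_yield)
  if (abs(ys - alphas_per_chain) > yield_tol) {
    abort(sprintf("alpha yields sum to %.3f, expected ~%d", ys, alphas_per_chain),
          class = "alphadose3d_domain_error")
  }
  structure(
    as_tibble(nuclides),
    parent = parent, daughter = daughter,
    alphas_per_chain = alphas_per_chain,
    class = c("decay_chain", class(as_tibble(nuclides)))
  )
}

#' The default Ac-225 decay chain
#'
#' Loads the shipped constants (Ac-225 9.9 d, Fr-221 4.8 min, At-217 32 ms,
#' Bi-213 45.6 min, Po-213 3.72 us, with 4 alpha emissions per chain decay)
#' or a user configuration of the same YAML schema.
#'
#' @param config Optional path to a YAML file overriding the shipped
#'   constants.
#' @return A `decay_chain`.
#' @examples
#' ch <- ac225_chain()
#' chain_lambda(ch, "Bi-213")
#' @export
ac225_chain <- function(config = NULL) {
  path <- config %||% system.file("extdata", "ac225_chain.yaml",
                                  package = "alphadose3d", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  nucs <- purrr::map_dfr(cfg$nuclides, function(n) {
    nuclide(n$name, n$half_life, n$alpha_energy_MeV %||% 0, n$alpha_yield %||% 0)
  })
  decay_chain(nucs, parent = cfg$parent, daughter = cfg$daughter,
              alphas_per_chain = cfg$alphas_per_chain %||% 4)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decay constant of a chain member
#'
#' @param chain A `decay_chain`.
#' @param name Nuclide name; defaults to the chain parent.
#' @return Decay constant in 1/s.
#' @export
chain_lambda <- function(chain, name = attr(chain, "parent")) {
  i <- match(name, chain$name)
  if (is.na(i)) abort(paste0("nuclide '", name, "' not in chain"))
  chain$lambda[i]
}

.chain_lambdas <- function(chain) {
  la <- chain_lambda(chain, attr(chain, "parent"))
  lb <- chain_lambda(chain, attr(chain, "daughter"))
  if (lb <= la) {
    abort("daughter decay constant must exceed the parent's",
          class = "alphadose3d_singularity_error")
  }
  list(la = la, lb = lb, k = lb / (lb - la))
}

#' Daughter/parent activity ratio at a time after sacrifice
#'
#' Evolves the Bi-213/Ac-225 activity ratio forward from its value `r0` at
#' sacrifice: `r(t) = (r0 - k) exp(-(lb - la) t) + k`, with
#' `k = lb / (lb - la)`. As `t` grows the ratio relaxes to the transient
#' equilibrium value `k` (about 1.003 for Ac-225/Bi-213); `equilibrium_one`
#' replaces `k` by exactly 1 for workflows that treat equilibrium as unity.
#'
#' @param r0 Activity ratio `A_b(0)/A_a(0)` at sacrifice (dimensionless,
#'   non-negative).
#' @param t Time since sacrifice in seconds (vectorised, >= 0).
#' @param chain A `decay_chain`.
#' @param equilibrium_one If `TRUE`, use 1 in place of `lb/(lb - la)`.
#' @return Activity ratio(s) at time `t`.
#' @examples
#' ratio_at_time(14.7, 3600, ac225_chain())
#' @export
ratio_at_time <- function(r0, t, chain, equilibrium_one = FALSE) {
  if (any(r0 < 0)) abort("r0 must be >= 0", class = "alphadose3d_domain_error")
  if (any(t < 0)) abort("t must be >= 0", class = "alphadose3d_domain_error")
  l <- .chain_lambdas(chain)
  k <- if (equilibrium_one) 1 else l$k
  (r0 - k) * exp(-(l$lb - l$la) * t) + k
}

#' Daughter activity at sacrifice from a later measurement
#'
#' Inverts the forward ratio relation: given measured activities
#' `A_b(t)`, `A_a(t)` at `t` seconds post-sacrifice, returns
#' `A_b(0) = A_b(t) e^{lb t} - k A_a(t) (e^{lb t} - e^{la t})`.
#'
#' @param Ab_t Measured daughter activity (Bq) at time `t`.
#' @param Aa_t Measured parent activity (Bq) at time `t`.
#' @param t Time since sacrifice in seconds (>= 0).
#' @param chain A `decay_chain`.
#' @return Daughter activity at sacrifice, `A_b(0)` (Bq).
#' @export
initial_daughter_activity <- function(Ab_t, Aa_t, t, chain) {
  if (any(t < 0)) abort("t must be >= 0", class = "alphadose3d_domain_error")
  if (any(Ab_t < 0) || any(Aa_t < 0)) {
    abort("activities must be >= 0", class = "alphadose3d_domain_error")
  }
  l <- .chain_lambdas(chain)
  Ab_t * exp(l$lb * t) - l$k * Aa_t * (exp(l$lb * t) - exp(l$la * t))
}

#' Fit the initial daughter/parent ratio from a post-sacrifice series
#'
#' The forward ratio relation is linear in `r0` at fixed decay constants:
#' `r(t) = k + (r0 - k) exp(-(lb - la) t)`. The estimator is therefore a
#' (optionally weighted) linear least-squares fit of `ratio - k` on
#' `exp(-(lb - la) t)` through the origin.
#'
#' @param series A data frame with columns `time_s` (post-sacrifice, s),
#'   `ratio` (`A_b/A_a`, > 0) and optionally `sigma` (1-sigma weights).
#' @param chain A `decay_chain`.
#' @param equilibrium_one Use 1 in place of `lb/(lb - la)` (see
#'   [ratio_at_time()]).
#' @return A list with `r0` (estimate), `r2` (coefficient of determination
#'   of the fitted curve against the observed ratios), and `fitted`
#'   (a tibble with `time_s`, `ratio`, `fit`).
#' @export
fit_initial_ratio <- function(series, chain, equilibrium_one = FALSE) {
  stopifnot(is.data.frame(series), all(c("time_s", "ratio") %in% names(series)))
  if (nrow(series) < 2) abort("need >= 2 time points", class = "alphadose3d_design_error")
  if (length(unique(series$time_s)) < 2) {
    abort("all times identical: degenerate design", class = "alphadose3d_design_error")
  }
  if (any(series$ratio <= 0)) abort("ratios must be > 0", class = "alphadose3d_domain_error")
  l <- .chain_lambdas(chain)
  k <- if (equilibrium_one) 1 else l$k
  x <- exp(-(l$lb - l$la) * series$time_s)
  y <- series$ratio - k
  w <- if ("sigma" %in% names(series) && all(is.finite(series$sigma)) &&
           all(series$sigma > 0)) 1 / series$sigma^2 else rep(1, nrow(series))
  slope <- sum(w * x * y) / sum(w * x^2)
  r0 <- slope + k
  fit <- k + slope * x
  ss_res <- sum(w * (series$ratio - fit)^2)
  ss_tot <- sum(w * (series$ratio - stats::weighted.mean(series$ratio, w))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(r0 = r0, r2 = r2,
       fitted = tibble(time_s = series$time_s, ratio = series$ratio, fit = fit))
}

#' Free-daughter excess activity at sacrifice
#'
#' The amount of redistributed ("free") daughter present at sacrifice is the
#' excess of total daughter activity over the parent-supported activity,
#' `max(A_b(0) - A_a(0), 0)`. Ratios within `tol` of 1 are flagged as
#' secular equilibrium; ratios below 1 are flagged as deficits (e.g. blood,
#' from which free daughter has been cleared) and clamped to zero excess.
#'
#' @param Ab0 Daughter activity at sacrifice (Bq, >= 0).
#' @param Aa0 Parent activity at sacrifice (Bq, >= 0).
#' @param tol Equilibrium tolerance on `|A_b/A_a - 1|` (default 0.05).
#' @return A list with `excess_Bq`, `ratio`, `equilibrium` (logical) and
#'   `deficit` (logical).
#' @examples
#' free_daughter_excess(147, 10)
#' @export
free_daughter_excess <- function(Ab0, Aa0, tol = 0.05) {
  if (any(Ab0 < 0) || any(Aa0 < 0)) {
    abort("activities must be >= 0", class = "alphadose3d_domain_error")
  }
  ratio <- ifelse(Aa0 > 0, Ab0 / Aa0, NA_real_)
  list(
    excess_Bq = pmax(Ab0 - Aa0, 0),
    ratio = ratio,
    equilibrium = !is.na(ratio) & abs(ratio - 1) < tol,
    deficit = !is.na(ratio) & ratio < 1
  )
}

#' Frame-coincidence correction factor for frame-based alpha cameras
#'
#' A chain decay whose short-lived daughter decays within the same camera
#' frame as its parent registers the two alpha events as one. With the
#' parent decay uniformly distributed within a frame of period `T` and the
#' daughter delay exponential with constant `lambda`, the same-frame
#' probability is `P = 1 - (1 - exp(-lambda T)) / (lambda T)`. One of
#' `alphas_per_chain` counted alphas is then lost with probability `P`,
#' giving the multiplicative count correction `1 / (1 - P / alphas)`.
#' At the 40 ms frame period and 32 ms At-217 half-life of the Ac-225
#' chain this evaluates to 1.09.
#'
#' @param frame_period Camera frame period in seconds (> 0).
#' @param daughter_half_life Short-lived daughter half-life in seconds (> 0).
#' @param alphas_per_chain Alpha emissions per chain decay (>= 1).
#' @return Correction factor (dimensionless, >= 1).
#' @examples
#' frame_coincidence_factor(0.040, 0.032, 4)
#' @export
frame_coincidence_factor <- function(frame_period, daughter_half_life,
                                     alphas_per_chain = 4) {
  frame_period <- parse_duration(frame_period)
  daughter_half_life <- parse_duration(daughter_half_life)
  if (any(frame_period <= 0) || any(daughter_half_life <= 0) ||
      any(alphas_per_chain < 1)) {
    abort("inputs must be positive (alphas_per_chain >= 1)",
          class = "alphadose3d_domain_error")
  }
  lam <- log(2) / daughter_half_life
  x <- lam * frame_period
  p <- 1 - (1 - exp(-x)) / x
  1 / (1 - p / alphas_per_chain)
}

#' Same-frame coincidence probability (analytic)
#'
#' The probability `P` underlying [frame_coincidence_factor()]; exposed for
#' Monte Carlo cross-checks.
#'
#' @inheritParams frame_coincidence_factor
#' @return Probability in (0, 1).
#' @export
frame_coincidence_probability <- function(frame_period, daughter_half_life) {
  frame_period <- parse_duration(frame_period)
  daughter_half_life <- parse_duration(daughter_half_life)
  if (any(frame_period <= 0) || any(daughter_half_life <= 0)) {
    abort("inputs must be positive", class = "alphadose3d_domain_error")
  }
  lam <- log(2) / daughter_half_life
  x <- lam * frame_period
  1 - (1 - exp(-x)) / x
}

#' Decay-correct a count or activity value
#'
#' Multiplies by `2^(elapsed / half_life)`: positive `elapsed` corrects a
#' later measurement back to an earlier reference (e.g. sacrifice), negative
#' `elapsed` corrects forward.
#'
#' @param value Counts or activity (any consistent unit; vectorised).
#' @param elapsed Elapsed time in seconds (may be negative).
#' @param half_life Half-life in seconds (> 0).
#' @return Corrected value in the same unit.
#' @export
decay_correct <- function(value, elapsed, half_life) {
  elapsed <- parse_duration(elapsed)
  half_life <- parse_duration(half_life)
  if (any(half_life <= 0)) abort("half_life must be > 0", class = "alphadose3d_domain_error")
  value * 2^(elapsed / half_life)
}

#' Read a ratio series CSV
#'
#' Columns: `time_s`, `ratio`, optional `sigma`.
#'
#' @param path CSV path.
#' @return Tibble validated as a ratio series (times strictly increasing,
#'   ratios > 0).
#' @export
read_ratio_series <- function(path) {
  df <- as_tibble(utils::read.csv(path))
  stopifnot(all(c("time_s", "ratio") %in% names(df)))
  if (any(diff(df$time_s) <= 0)) {
    abort("times must be strictly increasing", class = "alphadose3d_domain_error")
  }
  if (any(df$ratio <= 0)) abort("ratios must be > 0", class = "alphadose3d_domain_error")
  df
}
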