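# Synthetic TCRC generator. Real RTCA screening data for the 63-compound
# HepG2 panel are not publicly deposited, so every pipeline stage is
# exercised on generated curves that share the assay's structure:
# hourly sampling 0-72 h, 11 concentrations in 1:3 serial dilution plus
# a negative control, cluster-specific concentration- and time-dependent
# kill dynamics, and the skewed cluster-size distribution of the panel
# (20 compounds in the largest cluster down to 4 in the smallest).

#' Negative-control growth curve
#'
#' Logistic-style proliferation of untreated cells on the normalized
#' cell-index scale: `g(t) = 1 + (G - 1) * (1 - exp(-r t)) /
#' (1 + exp(-r (t - t_half)))`, anchored at `g(0) = 1` and
#' non-decreasing for the defaults.
#'
#' @param t Hours (>= 0); vectorized.
#' @param G Plateau NCI level (default 8, a typical confluent well).
#' @param r Growth rate per hour (default 0.12).
#' @param t_half Hour of half-maximal growth (default 24).
#' @return NCI values.
#' @export
growth_curve <- function(t, G = 8, r = 0.12, t_half = 24) {
  stopifnot(all(t >= 0), G >= 1, r > 0)
  1 + (G - 1) * (1 - exp(-r * t)) / (1 + exp(-r * (t - t_half)))
}

#' Define an MOA archetype for the generator
#'
#' An archetype is the parametric "mode of action" shared by all
#' compounds of one synthetic cluster: how fast cells die (`k_max`),
#' how steeply death depends on concentration (`hill`, `ec50`), how
#' long after treatment the effect starts (`lag`), an optional
#' transient stimulation (hormetic bump) and an optional recovery
#' (killing stops after `recovery_dur` hours).
#'
#' @param label Cluster label, e.g. `"C1"`.
#' @param k_max Maximal kill rate (1/h), >= 0.
#' @param hill Hill coefficient of the concentration response, > 0.
#' @param ec50 Concentration of half-maximal effect (same unit as the
#'   generator's concentrations).
#' @param lag Onset lag (h) before any effect.
#' @param transient_amp Amplitude of a transient stimulation (0 = none).
#' @param transient_tau Hour at which the transient peaks.
#' @param recovery If `TRUE`, killing stops `recovery_dur` hours after
#'   onset and the curve re-joins growth kinetics.
#' @param recovery_dur Active-kill duration (h) when `recovery`.
#' @return A list of class `moa_archetype`.
#' @export
moa_archetype <- function(label, k_max, hill = 1, ec50, lag = 0,
                          transient_amp = 0, transient_tau = 12,
                          recovery = FALSE, recovery_dur = 24) {
  stopifnot(k_max >= 0, hill > 0, ec50 > 0, lag >= 0,
            transient_amp >= 0, transient_tau > 0, recovery_dur > 0)
  structure(list(label = label, k_max = k_max, hill = hill, ec50 = ec50,
                 lag = lag, transient_amp = transient_amp,
                 transient_tau = transient_tau, recovery = recovery,
                 recovery_dur = recovery_dur),
            class = "moa_archetype")
}

#' Generator configuration
#'
#' @param archetypes List of [moa_archetype()] objects.
#' @param counts Integer vector (same length): compounds per cluster.
#' @param top_conc Highest tested concentration (default 100, arbitrary
#'   molar-scale unit).
#' @param dilution Serial dilution factor between neighbouring
#'   concentrations (default 3).
#' @param n_conc Number of concentrations (default 11).
#' @param t_end Last monitored hour (default 72; hourly grid from 0).
#' @param sigma_mult Multiplicative log-normal noise sd (default 0.05).
#' @param sigma_add Additive baseline noise sd in NCI units (default 0.01).
#' @param jitter_sd Log-normal sd of per-compound parameter jitter
#'   around the archetype (default 0.15).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(archetypes, counts, top_conc = 100,
                             dilution = 3, n_conc = 11L, t_end = 72,
                             sigma_mult = 0.05, sigma_add = 0.01,
                             jitter_sd = 0.15) {
  stopifnot(length(archetypes) == length(counts), all(counts >= 1),
            dilution > 1, top_conc > 0, n_conc >= 1, t_end >= 1,
            sigma_mult >= 0, sigma_add >= 0, jitter_sd >= 0)
  structure(list(archetypes = archetypes, counts = as.integer(counts),
                 top_conc = top_conc, dilution = dilution,
                 n_conc = as.integer(n_conc), t_end = t_end,
                 sigma_mult = sigma_mult, sigma_add = sigma_add,
                 jitter_sd = jitter_sd),
            class = "generator_config")
}

concentration_ladder <- function(config) {
  config$top_conc / config$dilution^(seq_len(config$n_conc) - 1)
}

# deterministic survival / response factor for one concentration
survival_factor <- function(t, conc, p) {
  if (conc <= 0) return(rep(1, length(t)))
  frac <- conc^p$hill / (conc^p$hill + p$ec50^p$hill)
  active <- pmax(0, t - p$lag)
  if (isTRUE(p$recovery)) active <- pmin(active, p$recovery_dur)
  s <- exp(-p$k_max * frac * active)
  if (p$transient_amp > 0) {
    u <- pmax(0, t - p$lag) / p$transient_tau
    s <- s * (1 + p$transient_amp * frac * u * exp(1 - u))
  }
  s
}

#' Generate one chemical's TCRC set
#'
#' Each curve is `NCI(t, c) = g(t) * s(t, c) * exp(eps_mult) + eps_add`
#' with `g` the [growth_curve()] and `s` the archetype's
#' concentration-dependent survival/response factor; concentration 0
#' (the negative control) gives the pure growth curve. Deterministic
#' given the RNG state (or `seed`).
#'
#' @param params An [moa_archetype()] (possibly with jittered fields) --
#'   the per-compound parameters.
#' @param config A [generator_config()].
#' @param chemical_id Identifier for the generated compound.
#' @param label Cluster label stored on the set (default the
#'   archetype's).
#' @param noise Apply measurement noise (default `TRUE`).
#' @param seed Optional integer seed.
#' @return A [tcrc_set()].
#' @export
generate_tcrc_set <- function(params, config, chemical_id = "chem",
                              label = params$label, noise = TRUE,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, config$t_end, by = 1)
  g <- growth_curve(tt)
  concs <- concentration_ladder(config)
  make_curve <- function(conc, conc_field) {
    y <- g * survival_factor(tt, conc, params)
    if (noise) {
      y <- y * exp(stats::rnorm(length(tt), 0, config$sigma_mult)) +
        stats::rnorm(length(tt), 0, config$sigma_add)
    }
    tcrc(tt, y, conc_field, chemical_id)
  }
  curves <- lapply(concs, function(cc) make_curve(cc, cc))
  nc <- make_curve(0, "negative_control")
  tcrc_set(chemical_id, curves, nc, label = label,
           n_curves = config$n_conc)
}

jitter_params <- function(arch, config) {
  jl <- function(v) v * exp(stats::rnorm(1, 0, config$jitter_sd))
  arch$k_max <- jl(arch$k_max)
  arch$ec50 <- jl(arch$ec50)
  arch$hill <- jl(arch$hill)
  arch$lag <- max(0, arch$lag + stats::rnorm(1, 0, 2 * config$jitter_sd / 0.15))
  if (arch$transient_amp > 0) arch$transient_amp <- jl(arch$transient_amp)
  arch
}

#' Generate a labeled synthetic dataset
#'
#' Draws `counts[i]` compounds from archetype `i`, jittering each
#' compound's kinetic parameters log-normally around the archetype
#' values (compounds sharing an MOA are similar, not identical), then
#' simulates every compound's 11 curves plus negative control.
#'
#' @param config A [generator_config()], e.g. from [preset_config()].
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return List with `sets` (list of [tcrc_set()]) and `labels`.
#' @export
generate_dataset <- function(config, seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  sets <- list()
  for (i in seq_along(config$archetypes)) {
    arch <- config$archetypes[[i]]
    for (j in seq_len(config$counts[i])) {
      params <- jitter_params(arch, config)
      id <- sprintf("%s_%02d", arch$label, j)
      sets[[length(sets) + 1]] <-
        generate_tcrc_set(params, config, chemical_id = id,
                          label = arch$label)
    }
  }
  list(sets = sets,
       labels = vapply(sets, function(s) s$label, character(1)))
}

#' Shipped generator presets
#'
#' * `"separable"` -- the default stated world: 7 clusters sized
#'   20, 5, 4, 5, 6, 10, 13 (63 compounds, mirroring the skewed panel
#'   composition) with distinct kill kinetics per cluster: fast
#'   DNA/RNA-type kill, slow late-onset kill, potent rapid kill,
#'   hormetic transient stimulation, kill-then-recovery, shallow dose
#'   response, and delayed strong kill.
#' * `"null"` -- identical cluster sizes but every cluster uses the same
#'   archetype: labels carry no information, so any classifier should
#'   sit at the majority baseline.
#' * `"window"` -- two clusters (20 and 13 compounds) whose dynamics are
#'   identical (pure growth) before hour 36 and diverge only afterwards;
#'   used to exercise DRC-guided time-window selection.
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [generator_config()] (e.g.
#'   `sigma_mult`).
#' @return A [generator_config()].
#' @export
preset_config <- function(name = c("separable", "null", "window"), ...) {
  name <- match.arg(name)
  conc <- function(rank) 100 / 3^(rank - 1)
  arche <- list(
    moa_archetype("C1",  k_max = 0.08, hill = 1.5, ec50 = conc(6),
                  lag = 6),
    moa_archetype("C2",  k_max = 0.04, hill = 1.0, ec50 = conc(4),
                  lag = 24),
    moa_archetype("C3",  k_max = 0.15, hill = 2.0, ec50 = conc(8),
                  lag = 2),
    moa_archetype("C4",  k_max = 0.03, hill = 1.0, ec50 = conc(5),
                  lag = 10, transient_amp = 0.5, transient_tau = 12),
    moa_archetype("C6",  k_max = 0.10, hill = 1.2, ec50 = conc(6),
                  lag = 4, recovery = TRUE, recovery_dur = 20),
    moa_archetype("C8",  k_max = 0.06, hill = 0.6, ec50 = conc(5),
                  lag = 8),
    moa_archetype("C10", k_max = 0.12, hill = 1.2, ec50 = conc(5),
                  lag = 16))
  counts <- c(20L, 5L, 4L, 5L, 6L, 10L, 13L)
  cfg <- switch(name,
    separable = generator_config(arche, counts, ...),
    null = {
      base <- arche[[1]]
      same <- lapply(seq_along(arche), function(i) {
        a <- base; a$label <- arche[[i]]$label; a
      })
      generator_config(same, counts, ...)
    },
    window = {
      a <- moa_archetype("C1",  k_max = 0.10, hill = 1.5, ec50 = conc(6),
                         lag = 36)
      b <- moa_archetype("C10", k_max = 0.035, hill = 0.7, ec50 = conc(4),
                         lag = 36)
      generator_config(list(a, b), c(20L, 13L), ...)
    })
  cfg
}
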