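#' Reference maximal conductance densities for the OLM cell models
#'
#' Per-region maximal conductance densities (pS/um^2) for the nine voltage-
#' and calcium-gated channel types of the OLM cell models: H (hyperpolarization-
#' activated cyclic nucleotide-gated), NaT (transient sodium), Kdrf/Kdrs
#' (fast/slow delayed rectifier potassium), KA (A-type potassium), M
#' (M-type potassium), CaT/CaL (T-/L-type calcium) and KCa
#' (calcium-dependent potassium).  Calcium channels and KCa are restricted
#' to dendrites; KA, M and H are somatodendritic.
#'
#' @param cell_id 1 or 2, selecting the reference parameter set.
#' @return A tibble with columns `channel`, `region`, `density`.
#' @export
olm_channel_table <- function(cell_id = 1) {
  if (!cell_id %in% c(1, 2)) stop("cell_id must be 1 or 2", call. = FALSE)
  tb <- tibble::tribble(
    ~channel, ~region, ~cell1,   ~cell2,
    "NaT",    "soma",   70.99,    75.09,
    "NaT",    "dend",   99.48,    64.68,
    "NaT",    "axon",   66.42,   140.89,
    "Kdrf",   "soma",  115.47,    91.15,
    "Kdrf",   "dend",   50.49,    52.52,
    "Kdrf",   "axon",  155.97,   144.03,
    "Kdrs",   "soma",    0.0054,   0.0070,
    "Kdrs",   "dend",    0.0038,   0.0062,
    "Kdrs",   "axon",    0.0082,   0.0024,
    "KA",     "soma",   76.08,   110.18,
    "KA",     "dend",   76.08,   110.18,
    "CaL",    "dend",   47.19,    22.01,
    "CaT",    "dend",    1.01,     3.74,
    "KCa",    "dend",    0.14,     7.08,
    "M",      "soma",    0.14,     0.18,
    "M",      "dend",    0.14,     0.18,
    "H",      "soma",    0.1063,   0.0608,
    "H",      "dend",    0.1063,   0.0608
  )
  dplyr::select(
    dplyr::mutate(tb, density = if (cell_id == 1) tb$cell1 else tb$cell2),
    "channel", "region", "density"
  )
}

# Default gating parameterization ("OLM-like"): generic Hodgkin-Huxley form
# I = gbar * m^p * h^q * (V - E) with Boltzmann steady states
# x_inf(V) = 1 / (1 + exp(-(V - vhalf)/k)) and bell-shaped time constants
# tau(V) = tmin + tamp / (exp((V-vt)/ka) + exp(-(V-vt)/kb)).
# KCa activation is driven by the calcium pool: m_inf = ca/(ca + kd).
default_gating <- function() {
  g <- function(vhalf, k, tmin, tamp = 0, vt = vhalf, ka = 20, kb = 20) {
    c(vhalf = vhalf, k = k, tmin = tmin, tamp = tamp, vt = vt,
      ka = ka, kb = kb)
  }
  list(
    NaT = list(p = 3L, q = 1L, E = 50,
               act = g(-38, 6, 0.03, 0.12, -38, 18, 18),
               inact = g(-58, -7, 0.4, 7, -60, 16, 16)),
    Kdrf = list(p = 4L, q = 0L, E = -85,
                act = g(-27, 9, 0.4, 4.5, -40, 22, 22)),
    Kdrs = list(p = 4L, q = 0L, E = -85,
                act = g(-25, 10, 5, 80, -40, 25, 25)),
    KA = list(p = 1L, q = 1L, E = -85,
              act = g(-45, 8, 0.4, 1.8, -45, 20, 20),
              inact = g(-72, -7, 8, 40, -70, 20, 20)),
    M = list(p = 1L, q = 0L, E = -85,
             act = g(-33, 8, 20, 120, -35, 20, 20)),
    H = list(p = 1L, q = 0L, E = -30,
             act = g(-85, -8, 40, 180, -85, 18, 18)),
    CaT = list(p = 2L, q = 1L, E = 120,
               act = g(-52, 5.5, 1.5, 4, -52, 18, 18),
               inact = g(-75, -6, 15, 70, -75, 20, 20)),
    CaL = list(p = 2L, q = 0L, E = 120,
               act = g(-22, 6, 1, 2.5, -22, 18, 18)),
    KCa = list(p = 1L, q = 0L, E = -85, ca_gated = TRUE,
               act = c(kd = 0.002, unused = 0, tau = 4)),
    leak = list(p = 0L, q = 0L, E = -75)
  )
}

#' Construct a channel set
#'
#' A channel set couples per-region maximal conductance densities with
#' gating schemes and reversal potentials for each mechanism.  The default
#' gating parameterization is a generic Hodgkin-Huxley-style ("OLM-like")
#' scheme: fast activating/inactivating NaT, fast and slow delayed
#' rectifiers, inactivating KA, slow non-inactivating M, hyperpolarization-
#' activated H with a depolarized reversal (-30 mV), low-threshold
#' inactivating CaT, high-threshold CaL, and KCa driven by a single
#' exponentially decaying calcium pool fed by the calcium currents.  Every
#' rate parameter can be overridden through `gating`.
#'
#' @param densities Tibble with columns `channel`, `region`, `density`
#'   (pS/um^2), e.g. from [olm_channel_table()].
#' @param gating Named list of gating-scheme overrides merged over the
#'   package defaults; each entry may carry `p`, `q`, `E`, `act`, `inact`,
#'   `ca_gated`.
#' @param e_leak Leak reversal potential (mV).
#' @param g_leak Leak conductance density (pS/um^2), applied to all regions.
#' @param ca Calcium-pool parameters: `tau` (ms), `rest`, `scale`
#'   (pool units per pA/um^2 of calcium influx).
#' @param density_scale Named numeric: per-channel multipliers applied to
#'   `densities` (used to rescale the reference densities for reduced
#'   morphologies).
#' @return An object of class `ivl_channel_set`.
#' @export
channel_set <- function(densities,
                        gating = list(),
                        e_leak = -75,
                        g_leak = 0.55,
                        ca = list(tau = 100, rest = 1e-5, scale = 0.1),
                        density_scale = NULL) {
  stopifnot(all(c("channel", "region", "density") %in% names(densities)))
  if (any(densities$density < 0)) {
    stop("conductance densities must be >= 0", call. = FALSE)
  }
  if (!is.null(density_scale)) {
    for (nm in names(density_scale)) {
      sel <- densities$channel == nm
      densities$density[sel] <- densities$density[sel] * density_scale[[nm]]
    }
  }
  base <- default_gating()
  for (nm in names(gating)) {
    if (is.null(base[[nm]])) base[[nm]] <- list()
    base[[nm]] <- utils::modifyList(base[[nm]], gating[[nm]])
  }
  base$leak$E <- e_leak
  densities <- dplyr::bind_rows(
    densities,
    tibble::tibble(channel = "leak", region = c("soma", "dend", "axon"),
                   density = g_leak)
  )
  structure(
    list(densities = densities, gating = base, ca = ca),
    class = "ivl_channel_set"
  )
}

#' @export
print.ivl_channel_set <- function(x, ...) {
  cat("<ivl_channel_set> channels:",
      paste(unique(x$densities$channel), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a channel set into its density table
#' @param x An `ivl_channel_set`.
#' @param ... Unused.
#' @export
tidy.ivl_channel_set <- function(x, ...) x$densities

#' Reference channel set for an OLM cell model
#'
#' Combines the reference densities from [olm_channel_table()] with the
#' default gating parameterization.
#'
#' @inheritParams olm_channel_table
#' @param ... Passed to [channel_set()].
#' @export
olm_channel_set <- function(cell_id = 1, ...) {
  channel_set(olm_channel_table(cell_id), ...)
}

#' Disable all voltage-gated channels in a channel set
#'
#' Returns a copy of the channel set with every mechanism except the leak
#' removed; optionally resets the leak reversal (used during voltage-clamp
#' weight fitting, where all voltage-gated channels are blocked and the
#' leak reversal is moved to the clamp potential so that the cell rests at
#' the holding voltage).
#'
#' @param channels An `ivl_channel_set`.
#' @param e_leak Optional replacement leak reversal potential (mV).
#' @export
block_active_channels <- function(channels, e_leak = NULL) {
  channels$densities <- dplyr::filter(channels$densities,
                                      .data$channel == "leak")
  channels$gating <- channels$gating["leak"]
  if (!is.null(e_leak)) channels$gating$leak$E <- e_leak
  channels
}

# convert to the engine's channel list for a given morphology
channels_to_engine <- function(channels, morph) {
  cm <- morph$compartments
  gt <- channels$gating
  nm <- unique(channels$densities$channel)
  lapply(nm, function(ch) {
    gg <- gt[[ch]]
    if (is.null(gg)) stop("no gating scheme for channel '", ch, "'",
                          call. = FALSE)
    dens <- channels$densities[channels$densities$channel == ch, ]
    g <- numeric(nrow(cm))
    for (r in seq_len(nrow(dens))) {
      sel <- cm$region == dens$region[r]
      g[sel] <- g[sel] + dens$density[r]
    }
    g <- g * cm$area * 1e-6   # pS -> uS
    list(
      name = ch, g = g, E = gg$E,
      p = as.integer(gg$p), q = as.integer(gg$q),
      act = if (gg$p > 0) unname(gg$act) else numeric(7),
      inact = if (gg$q > 0) unname(gg$inact) else numeric(7),
      ca_gated = isTRUE(gg$ca_gated),
      is_ca = ch %in% c("CaT", "CaL")
    )
  })
}
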