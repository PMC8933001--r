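#' Genotype presets for the synthetic notum generator
#'
#' Encodes each genotype's row geometry (SOP count and spacing, given as
#' mean ± SD), the position of the first divider (SOP0), and the contagion
#' parameters driving its division-time curve:
#'
#' * `control` — 13 ± 1 SOPs per row spaced 30 ± 9 µm, SOP0 anteromedial
#'   (fraction 0.3 along the row), rho = 40, mu = 0.52.
#' * `sca_null` — the neurogenic scabrous null: 18 ± 3 SOPs spaced
#'   22 ± 7.2 µm, SOP0 uniformly located, mu reduced to 0.31.
#' * `rac1_dn` — dominant-negative Rac1 (short protrusions): control
#'   geometry, SOP0 uniformly located, mu = 0.36.
#' * `dl_sca_het` — Dl/sca double heterozygote: control geometry, the
#'   flattest wave, mu = 0.25.
#'
#' Perturbed genotypes differ from control only in mu (and geometry where
#' it differs biologically): rho is invariant across presets. A single
#' time scale (minutes per model time unit) is shared by all genotypes,
#' chosen so a control row completes its wave in about two hours.
#'
#' @param genotype One of `"control"`, `"sca_null"`, `"rac1_dn"`,
#'   `"dl_sca_het"`.
#' @param seed Integer seed stored in the config; all randomness in
#'   [generate_notum()] derives deterministically from it.
#' @param noise_sd_min SD (minutes) of Gaussian observation noise added to
#'   non-seed division times.
#' @return A `genotype_config` list.
#' @export
genotype_preset <- function(genotype = c("control", "sca_null", "rac1_dn",
                                         "dl_sca_het"),
                            seed = 1L, noise_sd_min = 5) {
  genotype <- match.arg(genotype)
  geom <- switch(genotype,
    control    = list(n_mean = 13, n_sd = 1, sp_mean = 30, sp_sd = 9),
    sca_null   = list(n_mean = 18, n_sd = 3, sp_mean = 22, sp_sd = 7.2),
    rac1_dn    = list(n_mean = 13, n_sd = 1, sp_mean = 30, sp_sd = 9),
    dl_sca_het = list(n_mean = 13, n_sd = 1, sp_mean = 30, sp_sd = 9))
  mu <- switch(genotype, control = 0.52, sca_null = 0.31,
               rac1_dn = 0.36, dl_sca_het = 0.25)
  sop0_fraction <- switch(genotype, control = 0.3, dl_sca_het = 0.3,
                          sca_null = NA_real_, rac1_dn = NA_real_)
  config <- list(name = genotype,
                 n_rows_per_notum = 3L,
                 n_sops_mean = geom$n_mean, n_sops_sd = geom$n_sd,
                 spacing_mean_um = geom$sp_mean, spacing_sd_um = geom$sp_sd,
                 sop0_fraction = sop0_fraction,
                 contagion = contagion_params(rho = 40, mu = mu),
                 time_scale_min = 55,
                 noise_sd_min = noise_sd_min,
                 seed = as.integer(seed))
  validate_genotype_config(config)
  structure(config, class = "genotype_config")
}

validate_genotype_config <- function(config) {
  stopifnot(is.list(config),
            config$n_sops_mean >= 2,
            config$spacing_mean_um > 0,
            is.na(config$sop0_fraction) ||
              (config$sop0_fraction >= 0 && config$sop0_fraction <= 1),
            inherits(config$contagion, "contagion_params"),
            config$time_scale_min > 0,
            config$noise_sd_min >= 0)
  invisible(config)
}

# deterministic per-notum substream seed, kept within 32-bit integer range
derive_seed <- function(seed, notum_index) {
  as.integer((as.numeric(seed) * 7919 + notum_index * 104729) %%
               .Machine$integer.max)
}

#' Generate one synthetic notum
#'
#' Draws, for each of the configured rows, a SOP count (rounded normal,
#' clipped to >= 3) and inter-SOP gaps (normal, clipped to >= 1 µm), places
#' SOP0 at the configured fraction along the row (or uniformly when the
#' preset leaves it unlocalised), obtains noise-free division times from
#' the contagion model via [simulate_row()], and adds i.i.d. Gaussian
#' observation noise to the non-seed cells, floored at 0.1 min so no cell
#' precedes SOP0. Row positions and recording-start offsets are arbitrary
#' (the analysis is translation-invariant). All randomness derives
#' deterministically from `(config$seed, notum_index)`; the caller's RNG
#' state is left untouched.
#'
#' @param config A [genotype_preset()] (or compatible) configuration.
#' @param notum_index Positive integer identifying the notum; also selects
#'   the RNG substream.
#' @return A [notum_dataset()].
#' @export
generate_notum <- function(config, notum_index = 1L) {
  validate_genotype_config(config)
  notum_index <- as.integer(notum_index)
  stopifnot(notum_index >= 1L)
  withr::with_seed(derive_seed(config$seed, notum_index), {
    rows <- lapply(seq_len(config$n_rows_per_notum), function(r) {
      n <- max(3L, as.integer(round(rnorm(1, config$n_sops_mean,
                                          config$n_sops_sd))))
      gaps <- pmax(rnorm(n - 1L, config$spacing_mean_um,
                         config$spacing_sd_um), 1)
      pos <- runif(1, 50, 150) + c(0, cumsum(gaps))
      frac <- if (is.na(config$sop0_fraction)) runif(1)
              else config$sop0_fraction
      i0 <- min(max(1L, as.integer(round(frac * (n - 1L))) + 1L), n)
      series <- simulate_row(config$contagion,
                             n_ant = i0 - 1L, n_post = n - i0,
                             spacing_um = config$spacing_mean_um,
                             time_scale = config$time_scale_min)
      t_rel <- series$time_min
      noise <- rnorm(n, 0, config$noise_sd_min)
      noise[series$rank == 0L] <- 0
      t_rel <- ifelse(series$rank == 0L, 0, pmax(t_rel + noise, 0.1))
      t0 <- runif(1, 5, 20)  # recording-start offset, min
      tibble::tibble(notum_id = sprintf("notum%03d", notum_index),
                     row_id = sprintf("R%d", r),
                     side = "unspecified",
                     position_um = pos,
                     division_time_min = t0 + t_rel,
                     genotype = config$name)
    })
    notum_dataset(do.call(rbind, rows),
                  metadata = list(genotype = config$name,
                                  notum_index = notum_index,
                                  seed = config$seed))
  })
}

#' Generate a cohort of synthetic nota
#'
#' `n_nota` independent datasets drawn from per-index substreams of the
#' config seed.
#'
#' @inheritParams generate_notum
#' @param n_nota Number of nota (>= 1).
#' @return A list of [notum_dataset()] objects.
#' @export
generate_cohort <- function(config, n_nota = 16L) {
  n_nota <- as.integer(n_nota)
  stopifnot(n_nota >= 1L)
  lapply(seq_len(n_nota), function(i) generate_notum(config, i))
}

#' Bind a cohort into one record table
#'
#' @param cohort A list of [notum_dataset()] objects.
#' @return A single [notum_dataset()] with all records.
#' @export
bind_cohort <- function(cohort) {
  stopifnot(length(cohort) >= 1L)
  notum_dataset(do.call(rbind, lapply(cohort, tibble::as_tibble)),
                metadata = attr(cohort[[1L]], "metadata")["genotype"])
}
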