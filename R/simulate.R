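# Deterministic 32-bit sub-seed from a string key and a base seed, so that
# per-protein and per-spot draws are pure functions of (master seed, identity).
.sub_seed <- function(key, base) {
  h <- as.double(base %% 2147483647L)
  for (v in utf8ToInt(as.character(key))) {
    h <- (h * 31 + v) %% 2147483647
  }
  as.integer(h)
}

# Truncated-normal draws by inverse-CDF so a single runif stream drives them.
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Spot-to-spot noise model
#'
#' Describes the stochastic layer between a spot's expected peak heights and
#' what the instrument records: multiplicative lognormal intensity noise,
#' mass-proportional m/z jitter, a per-mode detection threshold, and the
#' centroid export capacity.
#'
#' The default `intensity_sigma_log` (0.7033, natural-log scale) gives a
#' relative standard deviation of `sqrt(exp(sigma^2) - 1) = 0.80`, the
#' upper end of spot-to-spot intensity irreproducibility seen in MALDI.
#' Jitter coefficients are Da of m/z standard deviation per Da of mass and
#' differ by mode (linear TOF assigns m/z far less reproducibly than
#' reflectron); the defaults keep four jitter sigmas below the default bin
#' tolerances at every range midpoint, the guiding principle of bin sizing.
#' Detection thresholds are per mode as well: the linear-mode floor
#' (`lod_intact`) is calibrated so that a default intact spot retains at
#' most ~10 peaks above 10 kDa, and the reflectron floor (`lod_digested`)
#' places a median-abundance 1 kDa peptide one decade above it. `max_peaks`
#' bounds the exported centroid list to the most intense peaks, as
#' peak-picking software does.
#'
#' @param intensity_sigma_log lognormal sigma (natural log) of the
#'   multiplicative intensity noise.
#' @param jitter_intact,jitter_digested m/z jitter coefficients
#'   (Da sd per Da).
#' @param lod_intact,lod_digested detection thresholds in signal units.
#' @param max_peaks centroid export capacity per spot.
#' @return List of class `noise_model`.
#' @export
noise_model <- function(intensity_sigma_log = 0.7033,
                        jitter_intact = 1.8e-4,
                        jitter_digested = 2e-5,
                        lod_intact = 1.0,
                        lod_digested = 0.1,
                        max_peaks = 2000L) {
  if (intensity_sigma_log < 0) stop("intensity_sigma_log must be >= 0")
  if (jitter_intact < 0 || jitter_digested < 0) stop("jitter must be >= 0")
  if (lod_intact < 0 || lod_digested < 0) stop("lod must be >= 0")
  if (max_peaks < 1) stop("max_peaks must be >= 1")
  structure(list(intensity_sigma_log = intensity_sigma_log,
                 jitter_intact = jitter_intact,
                 jitter_digested = jitter_digested,
                 lod_intact = lod_intact,
                 lod_digested = lod_digested,
                 max_peaks = as.integer(max_peaks)),
            class = "noise_model")
}

#' Relative standard deviation implied by a noise model
#'
#' `sqrt(exp(sigma^2) - 1)` for the multiplicative lognormal intensity
#' noise; the default model gives 0.80 to within 1e-3.
#'
#' @param noise a [noise_model()].
#' @return RSD as a fraction.
#' @export
noise_rsd <- function(noise = noise_model()) {
  sqrt(exp(noise$intensity_sigma_log^2) - 1)
}

#' Draw multiplicative intensity-noise factors
#'
#' Samples the lognormal factors applied to expected peak heights; useful
#' for checking the replicate RSD the model produces.
#'
#' @param n number of draws.
#' @param noise a [noise_model()].
#' @param seed optional seed.
#' @return Numeric vector of positive factors with median 1.
#' @export
sample_intensity_noise <- function(n, noise = noise_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stats::rlnorm(n, meanlog = 0, sdlog = noise$intensity_sigma_log)
}

#' Mass-level tryptic digestion model
#'
#' Digestion is modelled in mass space: fragment masses are drawn from a
#' truncated normal centred in the 700-1500 Da band where tryptic peptides
#' predominantly fall, clipped to `clip`. Fragments are drawn until the
#' remaining protein mass falls below the lower clip; a remainder of at
#' least `min_fragment` is emitted as a final fragment, anything smaller is
#' merged into the last fragment. The fragment list of a protein is
#' deterministic (sub-seeded by the protein id), so the same protein yields
#' the same fragment m/z in every sample - without that, no cross-sample
#' peptide pattern would exist to learn.
#'
#' @param mean,sd fragment mass distribution parameters in Da.
#' @param clip length-2 lower/upper clip of drawn fragment masses in Da.
#' @param min_fragment smallest emitted fragment in Da.
#' @return List of class `digestion_model`.
#' @export
digestion_model <- function(mean = 1100, sd = 300, clip = c(500, 3000),
                            min_fragment = 200) {
  if (clip[1] >= clip[2] || min_fragment <= 0 || min_fragment > clip[1]) {
    stop("need min_fragment <= clip[1] < clip[2]")
  }
  structure(list(mean = mean, sd = sd, clip = clip,
                 min_fragment = min_fragment),
            class = "digestion_model")
}

#' Digest one protein into fragment masses
#'
#' @param mass protein mass in Da (>= the model's `min_fragment`).
#' @param id protein identifier; together with `base_seed` it fixes the
#'   fragment list, which is identical across calls and across samples.
#' @param model a [digestion_model()].
#' @param base_seed master seed the per-protein sub-seed is derived from.
#' @return Numeric vector of fragment masses summing to at most `mass`.
#' @export
digest_protein <- function(mass, id, model = digestion_model(),
                           base_seed = 1L) {
  if (mass < model$min_fragment) {
    stop("protein lighter than the minimum fragment")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(.sub_seed(id, base_seed))
  lower <- model$clip[1]
  if (mass < lower) {
    return(mass)  # below the draw range: the protein is its own fragment
  }
  frags <- numeric(0)
  remaining <- mass
  repeat {
    # batch of draws; loop again only in the rare case the batch runs out
    n <- max(4L, ceiling(remaining / model$mean) + 4L)
    draws <- .rtruncnorm(n, model$mean, model$sd, lower, model$clip[2])
    for (d in draws) {
      if (remaining < lower) break
      d <- min(d, remaining)
      frags <- c(frags, d)
      remaining <- remaining - d
    }
    if (remaining < lower) break
  }
  if (remaining >= model$min_fragment) {
    frags <- c(frags, remaining)
  } else if (remaining > 0 && length(frags)) {
    frags[length(frags)] <- frags[length(frags)] + remaining
  }
  excess <- sum(frags) - mass  # float drift from the running subtraction
  if (excess > 0) frags[length(frags)] <- frags[length(frags)] - excess
  frags
}

#' Simulation configuration
#'
#' Bundles the generative model of a two-class experiment: the proteome's
#' mass/abundance distributions, the class-difference preset, spot counts
#' per role, the attenuation slope, acquisition windows, and the noise and
#' digestion sub-models.
#'
#' The proteome default emulates a bacterial complement of 5445 proteins
#' above 3 kDa with log10-mass ~ Normal(4.46, 0.55) truncated to
#' \[3000, 200000\] Da, which puts roughly 80% of proteins above 10 kDa.
#' The `easy` preset gives each class 50 specific proteins drawn without
#' restriction (chemically dissimilar samples); the `hard` preset gives each
#' class only 5 specific proteins, all heavier than 20 kDa and in the bottom
#' abundance quartile - differences that intact linear-TOF acquisition
#' cannot see.
#'
#' @param seed master seed; the entire dataset is a pure function of it and
#'   this config.
#' @param n_proteins proteome size.
#' @param mass_mu,mass_sigma mean and sd of log10 mass.
#' @param mass_bounds truncation bounds of mass in Da.
#' @param abundance_sigma sd of log10 relative molar abundance (mean 0).
#' @param preset `"easy"` or `"hard"`.
#' @param n_specific class-specific proteins per class; default by preset
#'   (50 easy, 5 hard).
#' @param spots_per_class spots per class for each of train and score
#'   (default 48, i.e. 192 spots per mode).
#' @param slope_magnitude attenuation slope magnitude (default 2).
#' @param window_intact,window_digested acquisition m/z windows in Da.
#' @param noise a [noise_model()].
#' @param digestion a [digestion_model()].
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_proteins = 5445L,
                       mass_mu = 4.46, mass_sigma = 0.55,
                       mass_bounds = c(3000, 200000),
                       abundance_sigma = 0.8,
                       preset = c("easy", "hard"),
                       n_specific = NULL,
                       spots_per_class = 48L,
                       slope_magnitude = 2,
                       window_intact = c(500, 20000),
                       window_digested = c(200, 7000),
                       noise = noise_model(),
                       digestion = digestion_model()) {
  preset <- match.arg(preset)
  if (is.null(n_specific)) {
    n_specific <- if (preset == "easy") 50L else 5L
  }
  if (n_proteins < 1 || spots_per_class < 1 || n_specific < 1) {
    stop("counts must be >= 1")
  }
  if (slope_magnitude < 0) stop("slope_magnitude must be >= 0")
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 mass_mu = mass_mu, mass_sigma = mass_sigma,
                 mass_bounds = mass_bounds,
                 abundance_sigma = abundance_sigma,
                 preset = preset, n_specific = as.integer(n_specific),
                 spots_per_class = as.integer(spots_per_class),
                 slope_magnitude = slope_magnitude,
                 window_intact = window_intact,
                 window_digested = window_digested,
                 noise = noise, digestion = digestion),
            class = "sim_config")
}

#' Sample a synthetic proteome
#'
#' Draws `n_proteins` proteins with truncated log10-normal masses and
#' log10-normal relative abundances, deterministically per seed.
#'
#' @param config a [sim_config()].
#' @param seed seed; defaults to the config's master seed.
#' @return data.frame of class `sim_proteome` with columns `id`, `mass`
#'   (Da), `abundance` (relative molar units).
#' @export
sample_proteome <- function(config = sim_config(), seed = config$seed) {
  set.seed(seed)
  n <- config$n_proteins
  lmass <- .rtruncnorm(n, config$mass_mu, config$mass_sigma,
                       log10(config$mass_bounds[1]),
                       log10(config$mass_bounds[2]))
  abundance <- 10^stats::rnorm(n, 0, config$abundance_sigma)
  out <- data.frame(id = sprintf("P%05d", seq_len(n)),
                    mass = 10^lmass, abundance = abundance)
  class(out) <- c("sim_proteome", "data.frame")
  out
}

#' Partition a proteome into shared and class-specific sets
#'
#' The class difference is encoded by reserving disjoint sets of proteins
#' for each class; everything else is shared. The `easy` preset draws the
#' class-specific proteins without restriction; the `hard` preset draws
#' them from proteins heavier than 20 kDa whose abundance lies in the
#' bottom quartile of the proteome - the high-mass, low-abundance regime
#' where intact MALDI detection fails.
#'
#' @param proteome a [sample_proteome()] result.
#' @param config a [sim_config()]; its `preset` and `n_specific` apply.
#' @param seed seed for the selection; defaults to the master seed + 1.
#' @return List of class `class_pair`: `shared`, `class_a`, `class_b`
#'   (disjoint data.frames), `preset`.
#' @export
make_class_pair <- function(proteome, config = sim_config(),
                            seed = config$seed + 1L) {
  stopifnot(inherits(proteome, "sim_proteome"))
  set.seed(seed)
  n_spec <- config$n_specific
  if (config$preset == "hard") {
    eligible <- which(proteome$mass > 20000 &
                        proteome$abundance <
                          stats::quantile(proteome$abundance, 0.25))
  } else {
    eligible <- seq_len(nrow(proteome))
  }
  if (length(eligible) < 2 * n_spec) {
    stop("not enough eligible proteins for ", config$preset,
         " preset class-specific sets (need ", 2 * n_spec, ", have ",
         length(eligible), ")")
  }
  picked <- sample(eligible, 2 * n_spec)
  a <- picked[seq_len(n_spec)]
  b <- picked[n_spec + seq_len(n_spec)]
  structure(list(shared = proteome[-picked, , drop = FALSE],
                 class_a = proteome[a, , drop = FALSE],
                 class_b = proteome[b, , drop = FALSE],
                 preset = config$preset),
            class = "class_pair")
}

#' @export
print.class_pair <- function(x, ...) {
  cat(sprintf(
    "<class_pair> preset '%s': %d shared, %d + %d class-specific proteins\n",
    x$preset, nrow(x$shared), nrow(x$class_a), nrow(x$class_b)))
  invisible(x)
}

# Digest every protein of a table once; fragment identity is a property of
# the protein, so this is shared by all spots of a dataset.
.digest_table <- function(proteins, model, base_seed) {
  frag_list <- lapply(seq_len(nrow(proteins)), function(i) {
    digest_protein(proteins$mass[i], proteins$id[i], model, base_seed)
  })
  data.frame(
    protein_id = rep(proteins$id, lengths(frag_list)),
    abundance = rep(proteins$abundance, lengths(frag_list)),
    mass = unlist(frag_list)
  )
}

#' Render one MALDI spot as a peak list
#'
#' In intact mode, each protein of the sample contributes one candidate
#' peak at its (jittered) mass with expected height
#' `abundance * (mass / 1000)^(-slope_magnitude)`; in digested mode each
#' tryptic fragment contributes a candidate at the (jittered) fragment mass
#' with the same power law applied to the fragment mass. Candidates are
#' multiplied by lognormal spot noise, kept if the noisy height reaches the
#' mode's detection threshold and the m/z lies inside the mode's
#' acquisition window, and the `max_peaks` most intense survivors form the
#' exported centroid list.
#'
#' @param class_id `"a"` or `"b"`: which class-specific proteins join the
#'   shared proteome in this sample.
#' @param mode `"intact"` or `"digested"`.
#' @param pair a [make_class_pair()] result.
#' @param config a [sim_config()] (its `noise` sub-model applies).
#' @param spot_seed integer seed for this spot's noise draws.
#' @param fragments optional pre-digested fragment table for all of the
#'   pair's proteins (see [generate_dataset()]); computed on the fly when
#'   missing.
#' @param spot_id spot identifier for the returned peak list.
#' @return A [peaklist()].
#' @export
render_spot <- function(class_id = c("a", "b"),
                        mode = c("intact", "digested"),
                        pair, config = sim_config(), spot_seed = 1L,
                        fragments = NULL, spot_id = "spot") {
  class_id <- match.arg(class_id)
  mode <- match.arg(mode)
  stopifnot(inherits(pair, "class_pair"))
  noise <- config$noise
  present <- rbind(pair$shared,
                   if (class_id == "a") pair$class_a else pair$class_b)
  if (mode == "intact") {
    mass <- present$mass
    abundance <- present$abundance
    jitter_coeff <- noise$jitter_intact
    lod <- noise$lod_intact
    window <- config$window_intact
  } else {
    if (is.null(fragments)) {
      fragments <- .digest_table(present, config$digestion, config$seed)
    } else {
      fragments <- fragments[fragments$protein_id %in% present$id, ,
                             drop = FALSE]
    }
    mass <- fragments$mass
    abundance <- fragments$abundance
    jitter_coeff <- noise$jitter_digested
    lod <- noise$lod_digested
    window <- config$window_digested
  }
  set.seed(spot_seed)
  mz <- mass + stats::rnorm(length(mass), 0, jitter_coeff * mass)
  expected <- abundance * (mass / 1000)^(-config$slope_magnitude)
  height <- expected *
    stats::rlnorm(length(mass), 0, noise$intensity_sigma_log)
  keep <- height >= lod & mz >= window[1] & mz <= window[2]
  mz <- mz[keep]
  height <- height[keep]
  if (length(mz) > noise$max_peaks) {
    top <- order(height, decreasing = TRUE)[seq_len(noise$max_peaks)]
    mz <- mz[top]
    height <- height[top]
  }
  peaklist(mz, height, spot_id = spot_id, mode = mode)
}

#' Render a complete two-class dataset in memory
#'
#' Generates train and score spots for both classes in one or both
#' acquisition modes, together with the manifest tying spots to labels and
#' roles. Class "a" spots carry the `"positive"` label. Everything is a
#' pure function of the config (master seed included): per-protein fragment
#' identity is sub-seeded by protein id, per-spot noise by the spot id.
#'
#' @param config a [sim_config()].
#' @param modes modes to render (default both).
#' @return List of class `sim_dataset`: `peaklists` (named list),
#'   `manifest` (a `spot_manifest` whose `file` column holds the would-be
#'   file names), `proteome`, `pair`, `config`.
#' @export
render_dataset <- function(config = sim_config(),
                           modes = c("intact", "digested")) {
  modes <- match.arg(modes, several.ok = TRUE)
  proteome <- sample_proteome(config)
  pair <- make_class_pair(proteome, config)
  fragments <- if ("digested" %in% modes) {
    .digest_table(rbind(pair$shared, pair$class_a, pair$class_b),
                  config$digestion, config$seed)
  }
  design <- expand.grid(i = seq_len(config$spots_per_class),
                        class_id = c("a", "b"),
                        role = c("train", "score"),
                        mode = modes,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$label <- ifelse(design$class_id == "a", "positive", "negative")
  design$spot_id <- sprintf("%s_%s_%s_%02d", design$mode, design$role,
                            design$label, design$i)
  peaklists <- lapply(seq_len(nrow(design)), function(j) {
    render_spot(design$class_id[j], design$mode[j], pair, config,
                spot_seed = .sub_seed(design$spot_id[j], config$seed),
                fragments = fragments, spot_id = design$spot_id[j])
  })
  names(peaklists) <- design$spot_id
  manifest <- spot_manifest(design$spot_id,
                            file = paste0(design$spot_id, ".csv"),
                            label = design$label, role = design$role,
                            mode = design$mode, check_files = FALSE)
  structure(list(peaklists = peaklists, manifest = manifest,
                 proteome = proteome, pair = pair, config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<sim_dataset> preset '%s': %d spots (%s)\n", x$config$preset,
    length(x$peaklists), paste(unique(x$manifest$mode), collapse = " + ")))
  invisible(x)
}

#' Generate a dataset on disk
#'
#' Renders a dataset (see [render_dataset()]) and writes one peak-list CSV
#' per spot, a `manifest.csv`, and the resolved configuration as
#' `sim_config.json` for provenance. Byte-identical across runs with the
#' same config.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param modes modes to render.
#' @return The `spot_manifest` (with resolved file paths), invisibly.
#' @export
generate_dataset <- function(config = sim_config(), dir,
                             modes = c("intact", "digested")) {
  if (missing(dir)) stop("an output directory is required")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- render_dataset(config, modes)
  for (id in names(ds$peaklists)) {
    write_peaklist(ds$peaklists[[id]], file.path(dir, paste0(id, ".csv")))
  }
  manifest <- ds$manifest
  manifest$file <- file.path(dir, manifest$file)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  cfg <- ds$config
  cfg$noise <- unclass(cfg$noise)
  cfg$digestion <- unclass(cfg$digestion)
  jsonlite::write_json(unclass(cfg), file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(spot_manifest(manifest$spot_id, manifest$file, manifest$label,
                          manifest$role, manifest$mode))
}
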