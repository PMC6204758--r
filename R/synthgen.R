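#' Specify a synthetic two-category population
#'
#' Defines the generative model used by [gen_population()]. Each subject i
#' in category c (coded s_i = -1 or +1) gets feature values
#' \deqn{x_{if} = (d_f/2) s_i t_{if} + a_i u_f + \sigma_f (\sqrt{\rho}\, h_i +
#'   \sqrt{1-\rho}\, e_{if}),}
#' where `d_f` is the target per-feature standardized mean difference
#' (Cohen's d, in total-SD units), and `t_if` is a per-subject congruence
#' mixture: `t_if = g_i + (1 - g_i) eta_if` with `g_i` drawn from a Beta
#' distribution whose mean is `effect_correlation` and `eta_if ~ N(1, 1)`.
#' Subjects with g near 1 express every category offset at its population
#' value (internally consistent, "dimorphic" regime); subjects with low g
#' express an idiosyncratic amount of each offset (mosaic regime). The
#' noise scale `sigma_f` is chosen analytically so each feature has unit
#' within-category variance, hence the empirical Cohen's d of feature f
#' converges to `d_f` for every value of `effect_correlation`; the dial
#' moves the cross-feature correlation of a subject's displacements, not
#' the marginal effect sizes.
#'
#' When `volume_like = TRUE` the Gaussian scores are mapped to positive
#' volumes coupled to a latent total intracranial volume (ICV):
#' `v_if = base_f exp(tau x_if) (ICV_i / icv0)^1`, with
#' `ICV_i = icv0 exp(z_i)`, `z_i ~ N(s_i icv_sigma size_factor_d / 2,
#' icv_sigma^2)`, so the Cohen's d of log ICV equals `size_factor_d` and the
#' allometric exponent of every feature is exactly 1 (which makes
#' power-proportion recovery a sharp test). ICV is recorded in the output
#' whether or not it multiplies the features.
#'
#' @param n_per_category Subjects per category; a length-2 vector gives
#'   unequal counts (first category first).
#' @param n_features Number of features.
#' @param d_vector Target per-feature Cohen's d; recycled to `n_features`.
#' @param effect_correlation Congruence dial in \[0, 1\]: 1 = fully
#'   consistent (species-like dimorphism), 0 = independent mosaic.
#' @param noise_rho Equicorrelation of the noise across features; must keep
#'   the implied covariance positive definite.
#' @param axis_noise Variance of an extra noise factor aligned with the
#'   normalized `d_vector` direction. Morphometric data typically carry
#'   substantial individual variation along the very axis that separates
#'   the category means, which keeps multivariate classifiers far from
#'   perfect even when many univariate effects are present; this parameter
#'   reproduces that property. 0 disables it.
#' @param size_factor_d Cohen's d of the latent log ICV.
#' @param discretize Rating-scale grid step in SD units; 0 (default) keeps
#'   features continuous. Behavioral items are answered on coarse scales,
#'   and the resulting tie masses straddle quantile-based zone boundaries -
#'   a property the mosaicism analysis is sensitive to - while leaving
#'   standardized mean differences essentially unchanged.
#' @param volume_like Couple features multiplicatively to ICV (see above)?
#' @param tau Log-scale feature noise when `volume_like` (dimensionless).
#' @param icv0 Reference ICV (arbitrary units, default 1500 as in cm^3).
#' @param icv_sigma SD of log ICV (default 0.1, a ~10 percent size CV).
#' @param category_labels Length-2 character vector of category names.
#' @param age_range Length-2 numeric; ages drawn uniformly in years.
#' @param concentration Beta concentration of the congruence mixture.
#' @param seed Integer seed; fixing it fixes the output bit-for-bit.
#' @return An object of class `population_spec`.
#' @seealso [gen_population()], [preset_population()]
#' @export
population_spec <- function(n_per_category = 100L,
                            n_features = 10L,
                            d_vector = 0,
                            effect_correlation = 0.2,
                            noise_rho = 0,
                            axis_noise = 0,
                            size_factor_d = 0,
                            discretize = 0,
                            volume_like = FALSE,
                            tau = 0.05,
                            icv0 = 1500,
                            icv_sigma = 0.1,
                            category_labels = c("female", "male"),
                            age_range = c(18, 79),
                            concentration = 4,
                            seed = 1L) {
  n_per_category <- as.integer(rep_len(n_per_category, 2L))
  n_features <- as.integer(n_features)
  d_vector <- rep_len(as.numeric(d_vector), n_features)
  stopifnot(all(n_per_category >= 1L), n_features >= 1L,
            all(is.finite(d_vector)),
            effect_correlation >= 0, effect_correlation <= 1,
            icv_sigma > 0, tau > 0, icv0 > 0, concentration > 0,
            discretize >= 0,
            length(category_labels) == 2L,
            !anyDuplicated(category_labels))
  if (noise_rho >= 1 ||
      (n_features > 1L && noise_rho <= -1 / (n_features - 1L)))
    stop("'noise_rho' implies a non-positive-definite covariance",
         call. = FALSE)
  stopifnot(axis_noise >= 0)
  vt <- congruence_variance(effect_correlation, concentration)
  u2 <- if (any(d_vector != 0)) d_vector^2 / sum(d_vector^2) else
    rep(0, n_features)
  if (any((d_vector / 2)^2 * vt + axis_noise * u2 >= 1))
    stop(paste("congruence plus axis-noise variance exceeds the unit",
               "feature variance; reduce |d_vector| or axis_noise"),
         call. = FALSE)
  structure(list(n_per_category = n_per_category, n_features = n_features,
                 d_vector = d_vector,
                 effect_correlation = effect_correlation,
                 noise_rho = noise_rho, axis_noise = axis_noise,
                 size_factor_d = size_factor_d, discretize = discretize,
                 volume_like = volume_like, tau = tau, icv0 = icv0,
                 icv_sigma = icv_sigma, category_labels = category_labels,
                 age_range = as.numeric(age_range),
                 concentration = concentration, seed = as.integer(seed)),
            class = "population_spec")
}

# Var(t) for t = g + (1-g) eta, eta ~ N(1,1), g ~ Beta(ec*nu, (1-ec)*nu):
# E[t] = 1, Var(t) = E[(1-g)^2], with 1-g ~ Beta((1-ec)*nu, ec*nu).
congruence_variance <- function(ec, nu) {
  if (ec <= 0) return(1)
  if (ec >= 1) return(0)
  a <- (1 - ec) * nu
  a * (a + 1) / (nu * (nu + 1))
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec> %s/%s: %d+%d subjects, %d features\n",
              x$category_labels[1L], x$category_labels[2L],
              x$n_per_category[1L], x$n_per_category[2L], x$n_features))
  cat(sprintf("  |d| in [%.2f, %.2f], effect_correlation %.2f, rho %.2f\n",
              min(abs(x$d_vector)), max(abs(x$d_vector)),
              x$effect_correlation, x$noise_rho))
  cat(sprintf("  size_factor_d %.2f (%s), seed %d\n", x$size_factor_d,
              if (x$volume_like) "volume-coupled" else "uncoupled",
              x$seed))
  invisible(x)
}

#' Generate a synthetic population
#'
#' Draws a [feature_table] from the model described in [population_spec()].
#' Output is deterministic for a fixed `spec$seed` and does not perturb the
#' caller's RNG state.
#'
#' @param spec A [population_spec].
#' @param site Site label recorded for all subjects.
#' @return A [feature_table] with category, icv, age, and site metadata.
#' @examples
#' x <- gen_population(population_spec(n_per_category = 50, d_vector = 0.5))
#' x
#' @export
gen_population <- function(spec, site = "site1") {
  stopifnot(inherits(spec, "population_spec"))
  restore <- local_rng(spec$seed)
  on.exit(restore())
  out <- gen_population_impl(spec, site)
  out
}

gen_population_impl <- function(spec, site = "site1", id_prefix = "S") {
  n <- sum(spec$n_per_category)
  p <- spec$n_features
  s <- rep(c(-1, 1), spec$n_per_category)       # category sign
  category <- rep(spec$category_labels, spec$n_per_category)

  g <- draw_congruence(n, spec$effect_correlation, spec$concentration)
  eta <- matrix(stats::rnorm(n * p, mean = 1, sd = 1), n, p)
  tmat <- g + (1 - g) * eta                      # per-subject congruence mix

  vt <- congruence_variance(spec$effect_correlation, spec$concentration)
  u <- if (any(spec$d_vector != 0))
    spec$d_vector / sqrt(sum(spec$d_vector^2)) else rep(0, p)
  sigma_f <- sqrt(pmax(0, 1 - (spec$d_vector / 2)^2 * vt -
                         spec$axis_noise * u^2))
  h <- stats::rnorm(n)
  e <- matrix(stats::rnorm(n * p), n, p)
  noise <- sqrt(spec$noise_rho) * h + sqrt(1 - spec$noise_rho) * e
  a <- stats::rnorm(n, sd = sqrt(spec$axis_noise))

  x <- tmat * (s %o% (spec$d_vector / 2)) + a %o% u +
    sweep(noise, 2L, sigma_f, `*`)

  zeta <- stats::rnorm(n, mean = s * spec$icv_sigma * spec$size_factor_d / 2,
                       sd = spec$icv_sigma)
  icv <- spec$icv0 * exp(zeta)
  age <- stats::runif(n, spec$age_range[1L], spec$age_range[2L])

  if (spec$discretize > 0)
    x <- round(x / spec$discretize) * spec$discretize

  if (spec$volume_like) {
    base_f <- exp(stats::runif(p, log(2), log(20)))
    x <- sweep(exp(spec$tau * x), 2L, base_f, `*`) * (icv / spec$icv0)
    colnames(x) <- sprintf("vol_%03d", seq_len(p))
  } else {
    colnames(x) <- sprintf("feat_%03d", seq_len(p))
  }
  feature_table(x, category = factor(category, levels = spec$category_labels),
                subject_id = sprintf("%s%04d", id_prefix, seq_len(n)),
                site = rep(site, n), icv = icv, age = age)
}

draw_congruence <- function(n, ec, nu) {
  if (ec <= 0) return(rep(0, n))
  if (ec >= 1) return(rep(1, n))
  stats::rbeta(n, ec * nu, (1 - ec) * nu)
}

#' Generate a strongly dimorphic population
#'
#' Thin wrapper over [gen_population()] that insists the spec sits in the
#' species-like regime (high congruence, large effects), where a 2-cluster
#' k-means division recovers the category essentially perfectly.
#'
#' @param spec A [population_spec] with `effect_correlation >= 0.9` and mean
#'   `|d| >= 2`.
#' @param site Site label.
#' @return A [feature_table].
#' @export
gen_dimorphic <- function(spec, site = "site1") {
  stopifnot(inherits(spec, "population_spec"))
  if (spec$effect_correlation < 0.9)
    stop("dimorphic generation requires effect_correlation >= 0.9",
         call. = FALSE)
  if (mean(abs(spec$d_vector)) < 2)
    stop("dimorphic generation requires mean |d| >= 2", call. = FALSE)
  gen_population(spec, site = site)
}

#' Generate a multi-site population
#'
#' Draws one population per site from a shared [population_spec], then
#' applies site-specific location/scale distortions *after* the category
#' structure: `x -> (x + location_s) * scale_s` on the standardized feature
#' scale. This emulates samples collected at different sites with different
#' spreads over feature space; per-site z-scoring should largely undo the
#' distortion, which is what the supervised transfer protocol assumes.
#'
#' @param spec A [population_spec] with `volume_like = FALSE` (site
#'   distortions are defined on the standardized feature scale);
#'   `n_per_category` applies per site.
#' @param n_sites Number of sites (>= 2).
#' @param site_names Optional character vector of site names.
#' @param location Per-site additive offsets (SD units), recycled.
#' @param scale Per-site multiplicative spreads, recycled; must be > 0.
#' @param age_ranges Optional list of per-site age ranges overriding
#'   `spec$age_range`.
#' @return A [feature_table] with a `site` column covering all sites.
#' @examples
#' spec <- population_spec(n_per_category = 30, n_features = 5, seed = 7)
#' x <- gen_multisite(spec, n_sites = 2, location = c(0, 1))
#' table(x$site)
#' @export
gen_multisite <- function(spec, n_sites,
                          site_names = paste0("site", seq_len(n_sites)),
                          location = 0, scale = 1, age_ranges = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (n_sites < 2L) stop("'n_sites' must be at least 2", call. = FALSE)
  if (spec$volume_like)
    stop("multi-site generation requires a non-volume-coupled spec",
         call. = FALSE)
  location <- rep_len(location, n_sites)
  scale <- rep_len(scale, n_sites)
  if (any(scale <= 0)) stop("site scales must be positive", call. = FALSE)
  restore <- local_rng(spec$seed)
  on.exit(restore())
  parts <- vector("list", n_sites)
  for (si in seq_len(n_sites)) {
    sp <- spec
    if (!is.null(age_ranges)) sp$age_range <- age_ranges[[si]]
    t0 <- gen_population_impl(sp, site = site_names[si],
                              id_prefix = sprintf("%s_", site_names[si]))
    t0$features <- (t0$features + location[si]) * scale[si]
    parts[[si]] <- t0
  }
  rbind_tables(parts)
}

rbind_tables <- function(parts) {
  feature_table(do.call(rbind, lapply(parts, function(x) x$features)),
                category = factor(
                  unlist(lapply(parts, function(x) as.character(x$category))),
                  levels = levels(parts[[1L]]$category)),
                subject_id = unlist(lapply(parts, `[[`, "subject_id")),
                site = unlist(lapply(parts, `[[`, "site")),
                icv = unlist(lapply(parts, `[[`, "icv")),
                age = unlist(lapply(parts, `[[`, "age")))
}

#' Named population presets
#'
#' Ready-made [population_spec]s calibrated to the three contrasting regimes
#' the pipeline is designed to distinguish, plus a multi-site variant.
#' The per-feature effect sizes of each preset are drawn once from a fixed
#' internal stream, so a preset denotes the same population model regardless
#' of the simulation seed:
#'
#' * `brain_volumes` - 116 regional volumes, 466 subjects per category,
#'   per-feature d ~ U(-0.5, 0.5), effect correlation 0.2, noise
#'   equicorrelation 0.3, ICV-coupled volumes with log-ICV d = 2. Most
#'   separation between categories is carried by overall size, as in human
#'   regional gray-matter volumes.
#' * `brain_thickness` - 68 cortical-thickness features, 559 per category,
#'   same overlap regime but with features not coupled to ICV.
#' * `primate_faces` - 190 inter-landmark distances (20 landmarks), 31 + 59
#'   subjects, |d| = 2.5 with effect correlation 0.95: two genuinely
#'   distinct clusters, the species-difference comparator.
#' * `gendered_behaviors` - 10 behavior scores, 101 per category, |d| = 1.2
#'   with effect correlation 0.1: large univariate effects with almost
#'   independent mosaic structure.
#' * `multisite_brain` - 116 ICV-corrected-like features at four sites
#'   (boston, telaviv, cambridge, beijing) with site-specific location and
#'   scale distortions; boston is age-restricted to 18-35.
#'
#' @param name Preset name (see above).
#' @param n_per_category Optional override of the preset's per-category n.
#' @param seed Simulation seed stored in the returned spec.
#' @return A [population_spec]; for `multisite_brain` the spec carries the
#'   site layout in attribute `"sites"` (consumed by [gen_preset()]).
#' @seealso [gen_preset()] to draw a table directly.
#' @export
preset_population <- function(name = c("brain_volumes", "brain_thickness",
                                       "primate_faces", "gendered_behaviors",
                                       "multisite_brain"),
                              n_per_category = NULL, seed = 1L) {
  name <- match.arg(name)
  fixed_d <- function(p, draw, stream) {
    restore <- local_rng(stream)
    on.exit(restore())
    draw(p)
  }
  spec <- switch(name,
    brain_volumes = population_spec(
      n_per_category = n_per_category %||% 466L, n_features = 116L,
      d_vector = fixed_d(116L, function(p) stats::runif(p, -0.5, 0.5), 1161L),
      effect_correlation = 0.2, noise_rho = 0.3, axis_noise = 0.4,
      size_factor_d = 2, volume_like = TRUE,
      age_range = c(18, 79), seed = seed),
    brain_thickness = population_spec(
      n_per_category = n_per_category %||% 559L, n_features = 68L,
      d_vector = fixed_d(68L, function(p) stats::runif(p, -0.5, 0.5), 681L),
      effect_correlation = 0.2, noise_rho = 0.3, axis_noise = 1.9,
      size_factor_d = 2, volume_like = FALSE,
      age_range = c(18, 35), seed = seed),
    primate_faces = population_spec(
      n_per_category = n_per_category %||% c(31L, 59L), n_features = 190L,
      d_vector = fixed_d(190L, function(p) 2.5 * sign(stats::runif(p, -1, 1)),
                         1901L),
      effect_correlation = 0.95, noise_rho = 0.2,
      size_factor_d = 0, volume_like = FALSE,
      category_labels = c("capuchin", "macaque"),
      age_range = c(4, 30), seed = seed),
    gendered_behaviors = population_spec(
      n_per_category = n_per_category %||% 101L, n_features = 10L,
      d_vector = fixed_d(10L, function(p) 1.2 * sign(stats::runif(p, -1, 1)),
                         101L),
      effect_correlation = 0.1, noise_rho = 0.1, discretize = 1,
      size_factor_d = 0, volume_like = FALSE,
      category_labels = c("female", "male"),
      age_range = c(18, 25), seed = seed),
    multisite_brain = {
      sp <- population_spec(
        n_per_category = n_per_category %||% 150L, n_features = 116L,
        d_vector = fixed_d(116L, function(p) stats::runif(p, -0.5, 0.5),
                           1162L),
        effect_correlation = 0.2, noise_rho = 0.3, axis_noise = 3.7,
        size_factor_d = 0, volume_like = FALSE,
        age_range = c(18, 79), seed = seed)
      attr(sp, "sites") <- list(
        names = c("boston", "telaviv", "cambridge", "beijing"),
        location = c(0, 0.6, 0.2, 0.8),
        scale = c(1, 1.25, 1.05, 1.35),
        age_ranges = list(c(18, 35), c(18, 79), c(18, 79), c(18, 79)))
      sp
    })
  attr(spec, "preset") <- name
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw a feature table from a named preset
#'
#' @param name Preset name, see [preset_population()].
#' @param seed Simulation seed.
#' @param n_per_category Optional per-category n override.
#' @return A [feature_table].
#' @examples
#' gen_preset("gendered_behaviors", seed = 3)
#' @export
gen_preset <- function(name, seed = 1L, n_per_category = NULL) {
  spec <- preset_population(name, n_per_category = n_per_category,
                            seed = seed)
  sites <- attr(spec, "sites")
  if (is.null(sites)) {
    gen_population(spec, site = attr(spec, "preset"))
  } else {
    gen_multisite(spec, n_sites = length(sites$names),
                  site_names = sites$names, location = sites$location,
                  scale = sites$scale, age_ranges = sites$age_ranges)
  }
}
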