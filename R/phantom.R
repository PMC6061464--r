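#' Describe one synthetic stone
#'
#' A stone is modelled as a smooth attenuation peak added to the
#' background. Three radial profiles are available: `gaussian`
#' (`peak * exp(-r2/2)` with `r2` the squared Mahalanobis distance in
#' units of `sigma`), `truncated-gaussian` (the same, cut to zero beyond
#' 3 sigma), and `uniform-ellipsoid` (`peak` inside the ellipsoid with
#' semi-axes `sigma`, zero outside; a flat-topped stone that stresses the
#' segmentation).
#'
#' @param center_mm physical center (x, y, z) in mm.
#' @param peak_hu peak attenuation added at the center (HU).
#' @param sigma_mm profile half-width per axis in mm (scalar recycled to 3).
#' @param profile one of `"gaussian"`, `"truncated-gaussian"`,
#'   `"uniform-ellipsoid"`.
#' @return A `phantom_stone` list.
#' @export
phantom_stone <- function(center_mm, peak_hu, sigma_mm,
                          profile = c("gaussian", "truncated-gaussian",
                                      "uniform-ellipsoid")) {
  profile <- match.arg(profile)
  center_mm <- as.numeric(center_mm)
  sigma_mm <- rep_len(as.numeric(sigma_mm), 3L)
  if (length(center_mm) != 3L) stop("`center_mm` must have length 3")
  if (any(sigma_mm <= 0)) stop("`sigma_mm` must be strictly positive")
  if (!is.finite(peak_hu)) stop("`peak_hu` must be finite")
  structure(list(center_mm = center_mm, peak_hu = peak_hu,
                 sigma_mm = sigma_mm, profile = profile),
            class = "phantom_stone")
}

# support radius (mm, per axis) outside which the profile is ~0
stone_support <- function(stone) {
  switch(stone$profile,
         "gaussian" = 3 * stone$sigma_mm,
         "truncated-gaussian" = 3 * stone$sigma_mm,
         "uniform-ellipsoid" = stone$sigma_mm)
}

# analytic volume of the half-maximum region (mm^3)
stone_halfmax_volume <- function(stone) {
  s <- prod(stone$sigma_mm)
  switch(stone$profile,
         "gaussian" = ,
         "truncated-gaussian" = 4 / 3 * pi * s * (2 * log(2))^1.5,
         "uniform-ellipsoid" = 4 / 3 * pi * s)
}

#' Specify a synthetic CT phantom
#'
#' Defines the grid, background, noise and stone content of a phantom
#' volume. Defaults mirror a thin-slice urinary-tract protocol:
#' 0.8 x 0.8 mm in-plane pixels, 1 mm contiguous slices, background near
#' 0 HU (urine/soft tissue approximated to water). Each stone's peak must
#' clear `2 * (background + 5 * noise_sd)` so that the half-of-peak
#' segmentation rule is meaningful.
#'
#' @param shape grid shape `(nx, ny, nz)` in voxels.
#' @param spacing voxel spacing `(dx, dy, dz)` in mm.
#' @param stones list of [phantom_stone] objects.
#' @param background_hu background mean (HU).
#' @param noise_sd additive Gaussian noise standard deviation (HU).
#' @param seed integer seed recorded in the spec; `NULL` means no noise
#'   seeding (only valid when `noise_sd = 0`).
#' @param allow_overlap set `TRUE` to permit overlapping stone supports.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape, spacing = c(0.8, 0.8, 1.0),
                         stones = list(), background_hu = 0,
                         noise_sd = 0, seed = NULL,
                         allow_overlap = FALSE) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(shape) != 3L || any(shape < 1L)) stop("bad `shape`")
  if (length(spacing) != 3L || any(spacing <= 0)) stop("bad `spacing`")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (noise_sd > 0 && is.null(seed))
    stop("a `seed` is required when `noise_sd > 0`")
  for (s in stones) {
    if (!inherits(s, "phantom_stone")) stop("`stones` must be phantom_stone objects")
    if (s$peak_hu <= 2 * (background_hu + 5 * noise_sd))
      stop(sprintf(
        "stone peak %.0f HU must exceed 2*(background + 5*noise sd) = %.0f HU",
        s$peak_hu, 2 * (background_hu + 5 * noise_sd)))
  }
  structure(list(shape = shape, spacing = spacing, stones = stones,
                 background_hu = background_hu, noise_sd = noise_sd,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 allow_overlap = isTRUE(allow_overlap)),
            class = "phantom_spec")
}

#' Generate a phantom volume with ground truth
#'
#' Renders the phantom described by a [phantom_spec]: each voxel value is
#' `background + sum over stones of peak * profile + N(0, noise_sd)`.
#' Identical specs (including seed) give bit-identical volumes.
#'
#' @param spec a [phantom_spec].
#' @return A list with elements `volume` (an [hu_volume]) and `truth`
#'   (`phantom_truth`: per-stone true peak, center, sigma, profile and
#'   analytic half-maximum volume in mm^3, plus the seed and noise sd).
#' @examples
#' sp <- phantom_spec(c(32, 32, 24), stones = list(
#'   phantom_stone(c(12.8, 12.8, 12), peak_hu = 600, sigma_mm = 2)))
#' ph <- make_phantom(sp)
#' max(ph$volume$voxels)
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  sp <- spec$spacing
  ext <- (d - 1) * sp
  margin <- 3 * sp
  for (s in spec$stones) {
    supp <- stone_support(s)
    if (any(s$center_mm - supp < margin) ||
        any(s$center_mm + supp > ext - margin))
      stop("stone at (", paste(round(s$center_mm, 1), collapse = ","),
           ") mm does not fit inside the grid with a 3-voxel margin")
  }
  if (!spec$allow_overlap && length(spec$stones) > 1L) {
    for (a in seq_along(spec$stones))
      for (b in seq_len(a - 1L)) {
        ca <- spec$stones[[a]]$center_mm
        cb <- spec$stones[[b]]$center_mm
        ra <- max(stone_support(spec$stones[[a]]))
        rb <- max(stone_support(spec$stones[[b]]))
        if (sqrt(sum((ca - cb)^2)) < ra + rb)
          stop("stones ", b, " and ", a,
               " overlap; use allow_overlap = TRUE to permit this")
      }
  }
  x <- (seq_len(d[1]) - 1) * sp[1]
  y <- (seq_len(d[2]) - 1) * sp[2]
  z <- (seq_len(d[3]) - 1) * sp[3]
  vox <- array(spec$background_hu, d)
  for (s in spec$stones) {
    r2x <- ((x - s$center_mm[1]) / s$sigma_mm[1])^2
    r2y <- ((y - s$center_mm[2]) / s$sigma_mm[2])^2
    r2z <- ((z - s$center_mm[3]) / s$sigma_mm[3])^2
    r2 <- outer(outer(r2x, r2y, `+`), r2z, `+`)
    contrib <- switch(s$profile,
      "gaussian" = s$peak_hu * exp(-r2 / 2),
      "truncated-gaussian" = s$peak_hu * exp(-r2 / 2) * (r2 <= 9),
      "uniform-ellipsoid" = s$peak_hu * (r2 <= 1))
    vox <- vox + contrib
  }
  if (spec$noise_sd > 0) {
    vox <- vox + with_seed(spec$seed,
      array(stats::rnorm(prod(d), sd = spec$noise_sd), d))
  }
  truth <- structure(list(
    stones = lapply(spec$stones, function(s) list(
      peak_hu = s$peak_hu, center_mm = s$center_mm,
      sigma_mm = s$sigma_mm, profile = s$profile,
      halfmax_volume_mm3 = stone_halfmax_volume(s))),
    seed = spec$seed, noise_sd = spec$noise_sd), class = "phantom_truth")
  list(volume = hu_volume(vox, sp), truth = truth)
}

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a labelled synthetic cohort of stone phantoms
#'
#' Draws `n_ua` uric-acid-like and `n_ca` calcium-like single-stone
#' phantoms. Peak attenuations follow the published group moments
#' (UA ~ Normal(559, 139) HU truncated to the observed 365-966 HU range;
#' Ca ~ Normal(1275, 306) HU truncated to 301-1938 HU). Stone widths
#' encode the size-attenuation relation that motivates the peak point
#' Laplacian: UA stones are broad, and broader at higher peaks, while
#' low-attenuating Ca stones are small and sharply peaked. Half-maximum
#' diameters span roughly 1.5-11 mm.
#'
#' @param n_ua,n_ca group sizes (>= 0).
#' @param seed integer seed; the full cohort is reproducible from it.
#' @param noise_sd noise standard deviation in HU (default 15, a plausible
#'   figure for a 120 kVp abdominal protocol).
#' @param shape,spacing per-phantom grid geometry.
#' @return A list of length `n_ua + n_ca`; each element has `volume`,
#'   `truth`, and `label` (`"UA"` or `"non-UA/Mix"`).
#' @export
make_cohort <- function(n_ua, n_ca, seed, noise_sd = 15,
                        shape = c(48, 48, 44),
                        spacing = c(0.8, 0.8, 1.0)) {
  stopifnot(n_ua >= 0, n_ca >= 0)
  n <- n_ua + n_ca
  if (n == 0L) return(list())
  labels <- c(rep("UA", n_ua), rep("non-UA/Mix", n_ca))
  params <- with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      if (labels[i] == "UA") {
        peak <- rnorm_trunc(1, 559, 139, 365, 966)
        # broad stones, broader at high attenuation: ppLapl stays low and
        # nearly uncorrelated with maxHU
        sxy <- 0.9 + 1.8 * (peak - 365) / 601 + stats::runif(1, 0, 0.5)
      } else {
        peak <- rnorm_trunc(1, 1275, 306, 301, 1938)
        # small and sharply peaked when faint, broad when dense: the
        # published size-attenuation arch for calcium stones
        sxy <- 0.55 + 4.0 * ((peak - 301) / 1637)^2 + stats::runif(1, 0, 0.3)
      }
      sz <- sxy * stats::runif(1, 0.85, 1.15)
      offset <- stats::runif(3, -0.5, 0.5) * spacing
      sub_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      list(peak = peak, sigma = c(sxy, sxy, sz), offset = offset,
           sub_seed = sub_seed, label = labels[i])
    })
  })
  lapply(params, function(p) {
    center <- (shape - 1) * spacing / 2 + p$offset
    sp <- phantom_spec(shape, spacing,
                       stones = list(phantom_stone(center, p$peak, p$sigma)),
                       noise_sd = noise_sd,
                       seed = if (noise_sd > 0) p$sub_seed else NULL)
    ph <- make_phantom(sp)
    list(volume = ph$volume, truth = ph$truth, label = p$label)
  })
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v >= lo && v <= hi) break
    }
    out[i] <- v
  }
  out
}
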