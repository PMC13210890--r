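#' Construct a scattering phantom from explicit layers
#'
#' A phantom is an ordered stack of planar layers, each with a depth
#' (`z_top`, µm), a `thickness` (µm), a lateral `reflectivity_map` in
#' \[0, 1\], an attenuation coefficient `scattering_mu` (1/µm), and a
#' `crosstalk_strength` (dimensionless) controlling how much diffuse
#' crosstalk field the layer sheds. Optional spherical `defects` perturb the
#' reflectivity of the sub-layers they intersect.
#'
#' @param layers List of layers; each a list with fields `z_top`, `thickness`,
#'   `reflectivity_map`, `scattering_mu`, `crosstalk_strength`.
#' @param defects Optional list of `list(center = c(x, y, z), radius,
#'   contrast)` entries (µm) recorded for provenance.
#' @return An object of class `"scattering_phantom"`.
#' @seealso [make_phantom()] for the named recipes.
#' @export
scattering_phantom <- function(layers, defects = list()) {
  if (length(layers) == 0) stop("phantom needs at least one layer", call. = FALSE)
  z_top <- vapply(layers, function(l) l$z_top, numeric(1))
  thick <- vapply(layers, function(l) l$thickness, numeric(1))
  ord <- order(z_top)
  layers <- layers[ord]; z_top <- z_top[ord]; thick <- thick[ord]
  for (l in layers) {
    if (l$scattering_mu < 0) stop("scattering_mu must be >= 0", call. = FALSE)
    if (l$crosstalk_strength < 0) stop("crosstalk_strength must be >= 0", call. = FALSE)
    r <- range(l$reflectivity_map)
    if (r[1] < 0 || r[2] > 1) stop("reflectivity_map values must lie in [0, 1]", call. = FALSE)
    if (l$thickness < 0) stop("layer thickness must be >= 0", call. = FALSE)
  }
  if (length(layers) > 1) {
    ends <- z_top + thick
    if (any(z_top[-1] < ends[-length(ends)] - 1e-9)) {
      stop("geometry error: layers overlap in depth", call. = FALSE)
    }
  }
  structure(list(layers = layers, defects = defects), class = "scattering_phantom")
}

#' @export
print.scattering_phantom <- function(x, ...) {
  cat(sprintf("<scattering_phantom> %d layer(s), %d defect(s)\n",
              length(x$layers), length(x$defects)))
  invisible(x)
}

new_layer <- function(z_top, thickness, reflectivity_map, scattering_mu = 0,
                      crosstalk_strength = 0) {
  list(z_top = z_top, thickness = thickness, reflectivity_map = reflectivity_map,
       scattering_mu = scattering_mu, crosstalk_strength = crosstalk_strength)
}

#' Generate one of the standard test phantoms
#'
#' Three recipes cover the canonical validation objects: a three-bar
#' resolution target (`"bar_target"`), a single reflecting plane behind a
#' diffusive slab (`"plane_behind_diffuser"`), and a thick two-layer
#' attenuating slab with an embedded spherical defect
#' (`"two_layer_slab_with_defect"`). Slabs are discretized into thin
#' sub-layers (spacing `dz_sub`) so that depth-resolved reconstructions sample
#' the Beer-Lambert decay continuously.
#'
#' @param recipe One of `"bar_target"`, `"plane_behind_diffuser"`,
#'   `"two_layer_slab_with_defect"`.
#' @param config An [optical_config()] fixing the lateral grid.
#' @param seed Integer seed for any stochastic texture (unused by the default
#'   smooth recipes, kept for provenance).
#' @param ... Recipe parameters, see Details.
#'
#' @details
#' `bar_target`: `period` (px, bar width is `period/2`), `reflectivity`
#'   (default 1), `background` (default 0), `z` (µm, default 100).
#'
#' `plane_behind_diffuser`: `z_plane` (default 300 µm), `reflectivity`
#'   (default 0.8), `mu` (diffuser attenuation, 1/µm, default 0.002),
#'   `diffuser_thickness` (default 150 µm), `crosstalk_strength` (default 1).
#'   With `mu = 0` the diffuser vanishes and a single crosstalk-free plane is
#'   returned.
#'
#' `two_layer_slab_with_defect`: `thickness1`, `thickness2` (default 300 µm
#'   each), `mu1`, `mu2` (default 0.0015, 0.003 1/µm), `r1`, `r2` (sub-layer
#'   reflectivity, default 0.4, 0.5), `crosstalk_strength` (default 1),
#'   `defect_center` (µm, default mid-lateral at the layer interface),
#'   `defect_radius` (default 90 µm), `defect_contrast` (multiplier on
#'   reflectivity inside the defect, default 0.2), `dz_sub` (default 25 µm).
#'
#' @return A [scattering_phantom()].
#' @examples
#' cfg <- optical_config(nx = 32, ny = 32, n_k = 16)
#' ph <- make_phantom("bar_target", cfg, period = 8)
#' range(ph$layers[[1]]$reflectivity_map)
#' @export
make_phantom <- function(recipe = c("bar_target", "plane_behind_diffuser",
                                    "two_layer_slab_with_defect"),
                         config, seed = 0, ...) {
  recipe <- match.arg(recipe)
  stopifnot(inherits(config, "optical_config"))
  p <- list(...)
  nx <- config$nx; ny <- config$ny
  switch(recipe,
    bar_target = {
      period <- p$period %||% 8L
      if (period < 2) stop("bar period must be >= 2 px", call. = FALSE)
      refl <- p$reflectivity %||% 1
      bg <- p$background %||% 0
      z <- p$z %||% 100
      w <- period %/% 2L
      map <- matrix(bg, nx, ny)
      group_w <- 3L * w + 2L * w             # 3 bars separated by 2 gaps
      x0 <- max(1L, (nx - group_w) %/% 2L + 1L)
      for (b in 0:2) {
        cols <- x0 + b * 2L * w + 0:(w - 1L)
        cols <- cols[cols >= 1 & cols <= nx]
        map[cols, ] <- refl
      }
      scattering_phantom(list(new_layer(z, 1, map)))
    },
    plane_behind_diffuser = {
      mu <- p$mu %||% 0.002
      if (mu < 0) stop("scattering_mu must be >= 0", call. = FALSE)
      z_plane <- p$z_plane %||% 300
      refl <- p$reflectivity %||% 0.8
      d <- p$diffuser_thickness %||% 150
      ct <- p$crosstalk_strength %||% 1
      plane <- new_layer(z_plane, 1, matrix(refl, nx, ny))
      if (mu == 0) {
        scattering_phantom(list(plane))
      } else {
        diffuser <- new_layer(0, d, matrix(0, nx, ny), scattering_mu = mu,
                              crosstalk_strength = ct)
        scattering_phantom(list(diffuser, plane))
      }
    },
    two_layer_slab_with_defect = {
      t1 <- p$thickness1 %||% 300; t2 <- p$thickness2 %||% 300
      mu1 <- p$mu1 %||% 0.0015;   mu2 <- p$mu2 %||% 0.003
      r1 <- p$r1 %||% 0.4;        r2 <- p$r2 %||% 0.5
      ct <- p$crosstalk_strength %||% 1
      dz <- p$dz_sub %||% 25
      radius <- p$defect_radius %||% 90
      contrast <- p$defect_contrast %||% 0.2
      pitch <- config$pixel_pitch_obj
      center <- p$defect_center %||% c(nx / 2 * pitch, ny / 2 * pitch, t1)
      xs <- (seq_len(nx) - 0.5) * pitch
      ys <- (seq_len(ny) - 0.5) * pitch
      layers <- list()
      add_slab <- function(layers, z0, thickness, mu, r) {
        n_sub <- max(1L, round(thickness / dz))
        dzi <- thickness / n_sub
        for (i in seq_len(n_sub)) {
          z <- z0 + (i - 1) * dzi
          map <- matrix(r, nx, ny)
          zc <- z + dzi / 2
          dz_def <- zc - center[3]
          if (abs(dz_def) < radius) {
            rad_lat <- sqrt(radius^2 - dz_def^2)
            inside <- outer((xs - center[1])^2, (ys - center[2])^2, "+") <= rad_lat^2
            map[inside] <- pmin(1, pmax(0, r * contrast))
          }
          # crosstalk strength is per sub-layer so the shed diffuse energy
          # follows the local attenuation of that slab
          layers[[length(layers) + 1L]] <- new_layer(
            z, dzi, map, scattering_mu = mu, crosstalk_strength = ct)
        }
        layers
      }
      layers <- add_slab(layers, 0, t1, mu1, r1)
      layers <- add_slab(layers, t1, t2, mu2, r2)
      scattering_phantom(layers, defects = list(list(
        center = center, radius = radius, contrast = contrast)))
    }
  )
}
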