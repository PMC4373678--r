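# Optional geometric helper: relative solvent accessibility from
# coordinates, for evidence bundles that lack an annotation table.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# Near-uniform unit sphere points (deterministic golden-spiral lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = cos(theta) * sin(phi), y = sin(theta) * sin(phi), z = cos(phi))
}

#' Relative solvent accessibility from atomic coordinates
#'
#' Shrake-Rupley style numerical accessibility: each heavy atom is
#' surrounded by a deterministic lattice of test points on its
#' solvent-expanded sphere (van der Waals radius + probe); points buried
#' inside any neighbouring atom's expanded sphere are discarded.
#' Per-residue accessible area is normalised by the residue's
#' theoretical maximum (Tien et al. 2013) and clamped to \[0, 1\].
#'
#' With coarse fixtures (e.g. CA-only traces) the estimate is
#' correspondingly coarse; packaged bundles therefore carry RSA as an
#' input annotation and this helper is a fallback.
#'
#' @param structure Atom data.frame as from [read_structure()].
#' @param n_points Sphere test points per atom.
#' @param probe Probe radius in Angstrom (water, 1.4).
#' @return data.frame with `position` and `rsa`.
#' @export
compute_rsa <- function(structure, n_points = 960L, probe = 1.4) {
  heavy <- structure[!grepl("^H", structure$elety), , drop = FALSE]
  if (nrow(heavy) == 0L) stop("no heavy atoms in structure", call. = FALSE)
  elem <- substr(gsub("^[0-9]", "", heavy$elety), 1L, 1L)
  radius <- VDW_RADII[elem]
  radius[is.na(radius)] <- 1.70
  radius <- unname(radius) + probe
  xyz <- as.matrix(heavy[, c("x", "y", "z")])
  pts <- sphere_points(n_points)
  asa <- numeric(nrow(heavy))
  for (i in seq_len(nrow(heavy))) {
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(d < radius[i] + radius & seq_along(d) != i)
    test <- sweep(pts * radius[i], 2L, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- sqrt(colSums((t(test) - xyz[j, ])^2))
      exposed <- exposed & dj >= radius[j]
      if (!any(exposed)) break
    }
    asa[i] <- 4 * pi * radius[i]^2 * mean(exposed)
  }
  res <- split(seq_len(nrow(heavy)), heavy$resno)
  pos <- as.integer(names(res))
  area <- vapply(res, function(ii) sum(asa[ii]), numeric(1))
  one <- AA_THREE_TO_ONE[paste0(
    substr(heavy$resid[vapply(res, `[`, integer(1), 1L)], 1, 1),
    tolower(substr(heavy$resid[vapply(res, `[`, integer(1), 1L)], 2, 3)))]
  max_asa <- MAX_ASA[one]
  max_asa[is.na(max_asa)] <- mean(MAX_ASA)
  data.frame(position = pos, rsa = pmin(pmax(area / max_asa, 0), 1),
             row.names = NULL)
}
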