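# 63-channel 10-5 montage used throughout: recorded labels, idealized
# spherical positions, and the frontal labels dropped before decoding.

#' Recorded EEG montage
#'
#' The 63 extended 10-5 electrode labels of the recording setup
#' (reference CPz and ground AFz are not data channels).
#'
#' @return character vector of 63 channel labels.
#' @export
eeg_montage <- function() {
  c("Fp1", "Fp2", "AF3", "AFz", "AF4",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "FFC3h", "FCC1h", "FCC2h", "FCC4h",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "CCP3h", "CCP1h", "CCP2h", "CCP4h",
    "TP7", "CP5", "CP3", "CP1", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO3", "POz", "PO4", "O1", "Oz", "O2")
}

#' Frontal channels removed before decoding
#'
#' Frontopolar and anterior-frontal labels dropped after ocular correction
#' to minimise residual eye-artifact contamination, leaving 58 channels.
#'
#' @return character vector of 5 labels.
#' @export
frontal_drop_channels <- function() c("Fp1", "Fp2", "AF3", "AFz", "AF4")

# Spherical linear interpolation between two unit vectors.
slerp <- function(p, q, t) {
  om <- acos(max(-1, min(1, sum(p * q))))
  if (om < 1e-12) return(p)
  (sin((1 - t) * om) * p + sin(t * om) * q) / sin(om)
}

# Unit vector at inclination r (radians from vertex) and azimuth az
# (radians; 0 = right ear, pi/2 = nasion). x = right, y = anterior, z = up.
sph_point <- function(r_deg, az_deg) {
  r <- r_deg * pi / 180; az <- az_deg * pi / 180
  c(sin(r) * cos(az), sin(r) * sin(az), cos(r))
}

#' Idealized 10-5 electrode positions
#'
#' Unit-sphere coordinates constructed geometrically from the label
#' semantics of the 10-5 system: sagittal rows at 18-degree steps from the
#' vertex, outer electrodes on the 10%-circle, lateral positions by
#' spherical interpolation along each row, and `h`-suffixed labels at
#' half-step lateral offsets. These are idealized positions (not digitised
#' head coordinates); they are used for synthetic scalp topographies and
#' spherical-spline channel interpolation only.
#'
#' @param labels channel labels; defaults to the full montage.
#' @return data.frame with columns `label`, `x`, `y`, `z` (unit sphere;
#'   x right, y anterior, z up).
#' @export
electrode_positions <- function(labels = eeg_montage()) {
  # anterior-posterior inclination of each sagittal row (deg from vertex;
  # negative = anterior) and azimuth of the row's outer (10%-circle) end
  # on the left hemisphere
  rows <- list(
    Fp  = list(ap = -72, edge_az = 108),
    AF  = list(ap = -54, edge_az = 126),
    F   = list(ap = -36, edge_az = 144),
    FFC = list(ap = -27, edge_az = 153),
    FC  = list(ap = -18, edge_az = 162),
    FCC = list(ap = -9,  edge_az = 171),
    C   = list(ap = 0,   edge_az = 180),
    CCP = list(ap = 9,   edge_az = 189),
    CP  = list(ap = 18,  edge_az = 198),
    P   = list(ap = 36,  edge_az = 216),
    PO  = list(ap = 54,  edge_az = 234),
    O   = list(ap = 72,  edge_az = 252))
  one <- function(lab) {
    # normalise prefixes: Fp1 -> row Fp; TP7 -> CP row edge; FT7 -> FC edge;
    # T7 -> C row edge
    row_of <- function(lab) {
      if (grepl("^Fp", lab)) "Fp"
      else if (grepl("^AF", lab)) "AF"
      else if (grepl("^FFC", lab)) "FFC"
      else if (grepl("^FCC", lab)) "FCC"
      else if (grepl("^FT", lab)) "FC"
      else if (grepl("^FC", lab)) "FC"
      else if (grepl("^F", lab)) "F"
      else if (grepl("^TP", lab)) "CP"
      else if (grepl("^T", lab)) "C"
      else if (grepl("^CCP", lab)) "CCP"
      else if (grepl("^CP", lab)) "CP"
      else if (grepl("^C", lab)) "C"
      else if (grepl("^PO", lab)) "PO"
      else if (grepl("^P", lab)) "P"
      else if (grepl("^O", lab)) "O"
      else stop("unknown electrode label: ", lab)
    }
    rw <- rows[[row_of(lab)]]
    suffix <- regmatches(lab, regexpr("([0-9]+h?|z)$", lab))
    if (!length(suffix)) stop("unparsable electrode label: ", lab)
    half <- grepl("h$", suffix)
    numpart <- sub("h$", "", suffix)
    ap <- rw$ap
    mid <- sph_point(abs(ap), if (ap <= 0) 90 else 270)
    if (numpart == "z" || numpart == "") {
      if (numpart == "") stop("unlateralised label without z: ", lab)
      return(mid)
    }
    n <- as.integer(numpart)
    left <- n %% 2 == 1
    # lateral fraction of the way from midline to the row's outer end;
    # T/FT/TP and 7/8-numbered labels sit on the outer circle itself
    # Fp1/Fp2 and O1/O2 are the outer-circle ends of their short rows
    frac <- if (grepl("^(T|FT|TP|Fp|O)[0-9]", lab)) 1 else (n + 1) / 8
    if (half) frac <- frac - 1 / 16
    edge_az <- if (left) rw$edge_az else 180 - rw$edge_az
    edge <- sph_point(72, edge_az %% 360)
    slerp(mid, edge, frac)
  }
  xyz <- t(vapply(labels, one, numeric(3)))
  data.frame(label = labels, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

# Great-circle (angular) distance matrix between electrode unit vectors.
electrode_arc <- function(pos) {
  xyz <- as.matrix(pos[, c("x", "y", "z")])
  cosang <- tcrossprod(xyz)
  cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
  acos(cosang)
}

# Perrin-type spherical-spline g function evaluated at cos(angle).
# m = 4, truncated Legendre series.
spline_g <- function(cosang, m = 4, nterms = 20) {
  # Legendre polynomials by recurrence, accumulated
  out <- array(0, dim = dim(as.matrix(cosang)))
  x <- as.matrix(cosang)
  pnm1 <- matrix(1, nrow(x), ncol(x))  # P0
  pn <- x                              # P1
  for (n in seq_len(nterms)) {
    out <- out + (2 * n + 1) / (n^m * (n + 1)^m) * pn
    pnp1 <- ((2 * n + 1) * x * pn - n * pnm1) / (n + 1)
    pnm1 <- pn; pn <- pnp1
  }
  out / (4 * pi)
}

#' Spherical-spline interpolation of EEG channels
#'
#' Reconstructs the signal at target electrodes from the remaining
#' electrodes with a spherical spline (m = 4, truncated
#' Legendre expansion, light Tikhonov regularisation), the standard
#' approach for replacing bad EEG channels.
#'
#' @param data channels-by-samples matrix (rownames = labels).
#' @param bad labels (or indices) of the channels to reconstruct.
#' @param pos electrode positions as from [electrode_positions()] for all
#'   rows of `data`.
#' @param lambda ridge regularisation added to the spline system.
#' @return `data` with the bad rows replaced by their interpolation.
#' @export
spherical_interpolate <- function(data, bad, pos, lambda = 1e-5) {
  labels <- rownames(data)
  if (is.character(bad)) bad <- match(bad, labels)
  stopifnot(!anyNA(bad))
  good <- setdiff(seq_len(nrow(data)), bad)
  arc <- electrode_arc(pos)
  G <- spline_g(cos(arc[good, good, drop = FALSE]))
  Gt <- spline_g(cos(arc[bad, good, drop = FALSE]))
  ng <- length(good)
  # spline system with constant term: [G + lambda I, 1; 1', 0]
  A <- rbind(cbind(G + lambda * diag(ng), 1), c(rep(1, ng), 0))
  rhs <- rbind(data[good, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  data[bad, ] <- cbind(Gt, 1) %*% sol
  data
}
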