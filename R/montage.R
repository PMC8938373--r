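# Electrode montage: 64-channel 10-10 layout on the unit sphere plus
# EOG/mastoid auxiliaries, and the four 7-channel analysis ROIs.

#' @keywords internal
.slerp <- function(a, b, t) {
  # great-circle interpolation between unit vectors a and b
  omega <- acos(max(-1, min(1, sum(a * b))))
  if (omega < 1e-12) return(a)
  (sin((1 - t) * omega) * a + sin(t * omega) * b) / sin(omega)
}

#' @keywords internal
.sph <- function(incl_deg, azim_deg) {
  # inclination from the vertex (Cz), azimuth from the front (+y),
  # positive azimuth towards the left hemisphere
  th <- incl_deg * pi / 180
  ph <- azim_deg * pi / 180
  c(x = -sin(th) * sin(ph), y = sin(th) * cos(ph), z = cos(th))
}

# The four regions of interest: a centroid electrode combined with its six
# nearest neighbours (left/right x frontal/parietal).
.roi_lists <- list(
  "left frontal"   = c("AF3", "F5", "F3", "F1", "FC5", "FC3", "FC1"),
  "right frontal"  = c("AF4", "F6", "F4", "F2", "FC6", "FC4", "FC2"),
  "left parietal"  = c("PO3", "P5", "P3", "P1", "CP5", "CP3", "CP1"),
  "right parietal" = c("PO4", "P6", "P4", "P2", "CP6", "CP4", "CP2")
)
.roi_centroids <- c("left frontal" = "F3", "right frontal" = "F4",
                    "left parietal" = "P3", "right parietal" = "P4")

#' Build the recording montage
#'
#' Constructs the 64-channel 10-10 scalp layout used by the recording
#' system (BioSemi ActiveTwo naming), with idealized unit-sphere positions
#' built geometrically: midline electrodes at 10\% steps along the
#' nasion-inion arc, the outer ring at 72 degrees inclination, and
#' intermediate electrodes by great-circle interpolation between the
#' midline and the outer ring. Four auxiliary channels (VEOG, HEOG, M1,
#' M2) are appended with nominal below-equator positions.
#'
#' The montage carries the four topographic analysis regions, each a
#' centroid electrode (F3, F4, P3, P4) combined with its 6 nearest
#' neighbours.
#'
#' @param config optional list; `roi_map` overrides the region
#'   definitions (named list of 7-channel character vectors).
#' @return An object of class `montage`: a list with `channels` (a
#'   data.frame with `label`, `type` in eeg/eog/ref, and unit-sphere
#'   `x`, `y`, `z`), `roi_map`, and `roi_centroids`.
#' @examples
#' m <- make_montage()
#' m$roi_map[["left parietal"]]
#' @export
make_montage <- function(config = list()) {
  midline <- list(
    Fpz = c(72, 0), AFz = c(54, 0), Fz = c(36, 0), FCz = c(18, 0),
    Cz = c(0, 0), CPz = c(18, 180), Pz = c(36, 180), POz = c(54, 180),
    Oz = c(72, 180), Iz = c(90, 180)
  )
  # outer ring (10% circle), azimuth measured from the front; +left/-right
  ring_az <- c(Fp = 18, AF = 36, F = 54, FT = 72, T = 90, TP = 108,
               P = 126, PO = 144, O = 162)
  outer <- list()
  for (row in names(ring_az)) {
    lab_l <- switch(row, Fp = "Fp1", AF = "AF7", F = "F7", FT = "FT7",
                    T = "T7", TP = "TP7", P = "P7", PO = "PO7", O = "O1")
    lab_r <- switch(row, Fp = "Fp2", AF = "AF8", F = "F8", FT = "FT8",
                    T = "T8", TP = "TP8", P = "P8", PO = "PO8", O = "O2")
    outer[[lab_l]] <- c(72, ring_az[[row]])
    outer[[lab_r]] <- c(72, -ring_az[[row]])
  }
  outer[["P9"]]  <- c(90, 126)
  outer[["P10"]] <- c(90, -126)

  pos <- list()
  for (nm in names(midline)) pos[[nm]] <- .sph(midline[[nm]][1], midline[[nm]][2])
  for (nm in names(outer))   pos[[nm]] <- .sph(outer[[nm]][1], outer[[nm]][2])

  # intermediate electrodes: slerp from the midline electrode of a row to
  # the outer-ring electrode of that row
  inter <- list(
    AF = list(mid = "AFz", out = c("AF7", "AF8"),
              labs = list(c(AF3 = 0.5), c(AF4 = 0.5))),
    F  = list(mid = "Fz", out = c("F7", "F8"),
              labs = list(c(F1 = 0.25, F3 = 0.5, F5 = 0.75),
                          c(F2 = 0.25, F4 = 0.5, F6 = 0.75))),
    FC = list(mid = "FCz", out = c("FT7", "FT8"),
              labs = list(c(FC1 = 0.25, FC3 = 0.5, FC5 = 0.75),
                          c(FC2 = 0.25, FC4 = 0.5, FC6 = 0.75))),
    C  = list(mid = "Cz", out = c("T7", "T8"),
              labs = list(c(C1 = 0.25, C3 = 0.5, C5 = 0.75),
                          c(C2 = 0.25, C4 = 0.5, C6 = 0.75))),
    CP = list(mid = "CPz", out = c("TP7", "TP8"),
              labs = list(c(CP1 = 0.25, CP3 = 0.5, CP5 = 0.75),
                          c(CP2 = 0.25, CP4 = 0.5, CP6 = 0.75))),
    P  = list(mid = "Pz", out = c("P7", "P8"),
              labs = list(c(P1 = 0.25, P3 = 0.5, P5 = 0.75),
                          c(P2 = 0.25, P4 = 0.5, P6 = 0.75))),
    PO = list(mid = "POz", out = c("PO7", "PO8"),
              labs = list(c(PO3 = 0.5), c(PO4 = 0.5)))
  )
  for (row in inter) {
    for (side in 1:2) {
      labs <- row$labs[[side]]
      for (k in seq_along(labs)) {
        pos[[names(labs)[k]]] <-
          .slerp(pos[[row$mid]], pos[[row$out[side]]], labs[[k]])
      }
    }
  }

  scalp_order <- c(
    "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3",
    "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1",
    "P3", "P5", "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz",
    "Pz", "CPz", "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4",
    "F6", "F8", "FT8", "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4",
    "C6", "T8", "TP8", "CP6", "CP4", "CP2", "P2", "P4", "P6", "P8",
    "P10", "PO8", "PO4", "O2"
  )
  stopifnot(length(scalp_order) == 64, !anyDuplicated(scalp_order))
  xyz <- t(vapply(scalp_order, function(l) pos[[l]], numeric(3)))

  aux <- rbind(
    VEOG = .sph(104, 10),  # below the left eye
    HEOG = .sph(98, 40),   # outer canthus (bipolar derivation recorded as one channel)
    M1   = .sph(100, 108), # left mastoid, below TP7
    M2   = .sph(100, -108)
  )
  channels <- data.frame(
    label = c(scalp_order, rownames(aux)),
    type = c(rep("eeg", 64), "eog", "eog", "ref", "ref"),
    x = c(xyz[, 1], aux[, 1]), y = c(xyz[, 2], aux[, 2]),
    z = c(xyz[, 3], aux[, 3]),
    stringsAsFactors = FALSE
  )
  rownames(channels) <- NULL

  roi_map <- config$roi_map
  if (is.null(roi_map)) roi_map <- .roi_lists
  lens <- vapply(roi_map, length, integer(1))
  if (any(lens != 7L)) stop("every ROI must contain exactly 7 channels")
  missing <- setdiff(unlist(roi_map), channels$label)
  if (length(missing)) stop("ROI channels not in montage: ",
                            paste(missing, collapse = ", "))

  structure(list(channels = channels, roi_map = roi_map,
                 roi_centroids = .roi_centroids),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", sum(x$channels$type == "eeg"), " scalp + ",
      sum(x$channels$type != "eeg"), " auxiliary channels; ",
      length(x$roi_map), " ROIs\n", sep = "")
  invisible(x)
}

#' Great-circle (geodesic) distance between montage channels
#'
#' @param montage a `montage`.
#' @param labels optional subset of channel labels.
#' @return symmetric matrix of geodesic distances in radians on the unit
#'   sphere.
#' @export
channel_distances <- function(montage, labels = NULL) {
  ch <- montage$channels
  if (!is.null(labels)) {
    idx <- match(labels, ch$label)
    if (anyNA(idx)) stop("unknown channel label(s)")
    ch <- ch[idx, ]
  }
  p <- as.matrix(ch[, c("x", "y", "z")])
  p <- p / sqrt(rowSums(p^2))
  cosang <- tcrossprod(p)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  d <- acos(cosang)
  dimnames(d) <- list(ch$label, ch$label)
  d
}

#' Gaussian spatial weighting around a channel
#'
#' Weight per scalp channel of a source centred at `center`, falling off
#' as a Gaussian in geodesic distance on the unit sphere. Used by the
#' recording simulator for ERP and blink topographies.
#'
#' @param montage a `montage`.
#' @param center a channel label.
#' @param fwhm_rad full width at half maximum of the Gaussian, radians.
#' @return named weight vector over the 64 scalp channels (1 at the
#'   center).
#' @export
spatial_weights <- function(montage, center, fwhm_rad = 1.0) {
  eeg <- montage$channels$label[montage$channels$type == "eeg"]
  d <- channel_distances(montage)[center, eeg]
  sigma <- fwhm_rad / (2 * sqrt(2 * log(2)))
  w <- exp(-d^2 / (2 * sigma^2))
  names(w) <- eeg
  w
}
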