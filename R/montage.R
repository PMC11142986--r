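#' Standard 30-channel scalp montage
#'
#' Schematic 10/20 head coordinates for the 30 scalp electrodes used in the
#' analyses (x: left negative / right positive; y: nasion positive / inion
#' negative; unit head radius). A synthetic `EOG` channel (a pure ocular
#' reference trace used by the simulator and by ICA-based artifact removal)
#' is appended when `with_eog = TRUE`.
#'
#' @param with_eog append the synthetic `EOG` reference channel
#' @return data.frame with columns `label`, `x`, `y`
#' @export
default_montage <- function(with_eog = TRUE) {
  m <- data.frame(
    label = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
              "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
              "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
              "CP3", "CP4", "POz", "O1", "O2"),
    x = c(-0.30, 0.30, -0.80, -0.40, 0.00, 0.40, 0.80,
          -0.65, -0.20, 0.20, 0.65, -0.95, -0.45, 0.00, 0.45, 0.95,
          -0.65, -0.20, 0.20, 0.65, -0.80, -0.40, 0.00, 0.40, 0.80,
          -0.45, 0.45, 0.00, -0.30, 0.30),
    y = c(0.95, 0.95, 0.60, 0.55, 0.55, 0.55, 0.60,
          0.30, 0.30, 0.30, 0.30, 0.00, 0.00, 0.00, 0.00, 0.00,
          -0.30, -0.30, -0.30, -0.30, -0.60, -0.55, -0.55, -0.55, -0.60,
          -0.30, -0.30, -0.75, -0.95, -0.95),
    stringsAsFactors = FALSE
  )
  if (with_eog)
    m <- rbind(m, data.frame(label = "EOG", x = 0, y = 1.10))
  m
}

# Gaussian spatial profile over the montage, normalized to 1 at `center`
# (a channel label). Channels not on the scalp (EOG) get weight 0 unless
# they are the center themselves.
topo_weights <- function(montage, center, width = 0.55) {
  i <- match(center, montage$label)
  if (is.na(i)) stop("unknown center channel: ", center)
  d2 <- (montage$x - montage$x[i])^2 + (montage$y - montage$y[i])^2
  w <- exp(-d2 / (2 * width^2))
  w[montage$label == "EOG"] <- 0
  w / max(w)
  }

#' Canonical topography weight sets
#'
#' Frontal-midline-maximal (theta), parietal-midline-maximal (alpha) and
#' frontal ocular-projection weights over a montage. Weights are
#' nonnegative with maximum 1 at Fz, Pz and Fp1/Fp2 respectively.
#'
#' @param montage data.frame as returned by [default_montage()]
#' @return named list of numeric weight vectors (`theta`, `alpha`, `eog`),
#'   each of length `nrow(montage)`
#' @export
default_topographies <- function(montage = default_montage()) {
  eog <- {
    d2 <- (montage$x - 0)^2 + (montage$y - 1.25)^2
    w <- exp(-d2 / (2 * 0.40^2))
    w[montage$label == "EOG"] <- 0
    w / max(w)
  }
  list(theta = topo_weights(montage, "Fz"),
       alpha = topo_weights(montage, "Pz"),
       eog   = eog)
}
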